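#' Read and write the tab-separated interchange formats
#'
#' All stages exchange plain TSV files: lifespan tables (`line`, `sex`,
#' `temperature`, `vial`, `lifespan_days`), pooled allele counts
#' (`variant_id`, `chrom`, `pos`, `ref`, `alt`, `sex`, `temperature`,
#' `replicate`, `pool_type`, `ref_reads`, `alt_reads`, `pool_size`), line
#' genotype matrices (first column `line`, one column per variant), and
#' two-column gene-to-GO annotations.  Writers emit a `# seed:` /
#' `# ctxlife:` comment header; readers skip comment lines.
#'
#' @param data the table to write.
#' @param path file path.
#' @param seed optional seed recorded in the header.
#' @return `read_*` return data frames; `write_*` return `path` invisibly.
#' @name ctxlife_io
NULL

write_tsv_with_header <- function(data, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  cat("# ctxlife: ", as.character(packageVersion("ctxlife")), "\n",
      sep = "", file = con)
  if (!is.null(seed)) cat("# seed: ", seed, "\n", sep = "", file = con)
  utils::write.table(data, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname ctxlife_io
#' @export
write_lifespan_table <- function(data, path, seed = NULL) {
  validate_lifespan_table(data)
  write_tsv_with_header(
    data[, c("line", "sex", "temperature", "vial", "lifespan_days")],
    path, seed)
}

#' @rdname ctxlife_io
#' @export
read_lifespan_table <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = c(line = "character",
                                        sex = "character",
                                        temperature = "character"))
  validate_lifespan_table(d)
  d
}

#' @rdname ctxlife_io
#' @export
write_pooled_counts <- function(data, path, seed = NULL) {
  validate_pooled_counts(data)
  write_tsv_with_header(as.data.frame(data), path, seed)
}

#' @rdname ctxlife_io
#' @export
read_pooled_counts <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = c(sex = "character",
                                        temperature = "character"))
  validate_pooled_counts(d)
  class(d) <- c("pooled_counts", "data.frame")
  d
}

#' Export pooled counts in popoolation sync format
#'
#' One row per variant position, one `A:T:C:G:N:del` column per pool,
#' ordered by (sex, temperature, replicate, pool type).  Only the ref and
#' alt nucleotides carry counts.
#'
#' @param data a `pooled_counts` data frame.
#' @param path output path.
#' @return `path`, invisibly; the pool order is stored in a `# pools:`
#'   header comment.
#' @export
write_sync <- function(data, path) {
  validate_pooled_counts(data)
  data <- as.data.frame(data)
  pool_key <- interaction(data$sex, data$temperature, data$replicate,
                          data$pool_type, sep = ":", drop = TRUE)
  pools <- levels(pool_key)
  nts <- c("A", "T", "C", "G")
  vkeys <- unique(data[, c("variant_id", "chrom", "pos", "ref", "alt")])
  lines_out <- vapply(seq_len(nrow(vkeys)), function(i) {
    vr <- vkeys[i, ]
    cols <- vapply(pools, function(pl) {
      row <- data[data$variant_id == vr$variant_id & pool_key == pl, ]
      cnt <- setNames(rep(0L, 6), c(nts, "N", "del"))
      if (nrow(row) == 1) {
        cnt[row$ref] <- row$ref_reads
        cnt[row$alt] <- row$alt_reads
      }
      paste(cnt, collapse = ":")
    }, character(1))
    paste(c(vr$chrom, vr$pos, vr$ref, cols), collapse = "\t")
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  cat("# pools: ", paste(pools, collapse = ","), "\n", sep = "", file = con)
  writeLines(lines_out, con)
  invisible(path)
}

#' Write a founder panel as a minimal GT-only VCF
#'
#' Founders are homozygous haploid-like carriers, emitted as `0/0` or
#' `1/1` genotype calls at 1-based positions.
#'
#' @param panel a [simulate_founder_genotypes()] result.
#' @param path output path (plain text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_founder_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "founder_panel"))
  v <- panel$variants
  H <- panel$haplotypes
  founders <- sprintf("founder_%02d", seq_len(nrow(H)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", founders), collapse = "\t")), con)
  gt <- ifelse(t(H) == 1, "1/1", "0/0")   # variants x founders
  body <- vapply(seq_len(nrow(v)), function(i)
    paste(c(v$chrom[i], v$pos[i], v$variant_id[i], v$ref[i], v$alt[i],
            ".", "PASS", ".", "GT", gt[i, ]), collapse = "\t"),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a biallelic genotype matrix from VCF or TSV
#'
#' VCF input (via the vcfR package) converts GT calls of fully homozygous
#' lines to dosages 0/2 (heterozygous or missing calls become `NA`); matrix
#' TSV input expects a `line` column followed by one dosage column per
#' variant.
#'
#' @param path `.vcf` or `.tsv` file.
#' @return lines x variants numeric dosage matrix with line ids as
#'   rownames.
#' @export
read_genotype_matrix <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF requires the vcfR package")
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    dos[gt %in% c("0/0", "0|0")] <- 0
    dos[gt %in% c("1/1", "1|1")] <- 2
    ids <- vcfR::getID(vcf)
    if (all(is.na(ids))) ids <- paste0(vcfR::getCHROM(vcf), ":",
                                       vcfR::getPOS(vcf))
    rownames(dos) <- ids
    return(t(dos))
  }
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (names(d)[1] != "line") stop("genotype TSV must start with a 'line' column")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$line
  m
}

#' Read gene models from BED or GFF3
#'
#' BED input (0-based, half-open) is converted to 1-based inclusive
#' coordinates; GFF3 input keeps its 1-based inclusive coordinates and uses
#' rows of type `gene` (falling back to all rows).  Parsing is delegated to
#' rtracklayer.
#'
#' @param path `.bed`, `.gff`, `.gff3` or `.gtf` file.
#' @return data frame with `gene_id`, `chrom`, `start`, `end`, `length`
#'   (bp, `end - start + 1`).
#' @export
read_gene_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading gene models requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  if ("type" %in% names(md) && any(md$type == "gene"))
    gr <- gr[md$type == "gene"]
  md <- S4Vectors::mcols(gr)
  id <- if ("gene_id" %in% names(md)) md$gene_id
        else if ("ID" %in% names(md)) md$ID
        else if ("Name" %in% names(md)) md$Name
        else if ("name" %in% names(md)) md$name
        else paste0("gene_", seq_along(gr))
  out <- data.frame(gene_id = as.character(id),
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),  # rtracklayer already 1-based
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene_id)) stop("duplicate gene ids in ", path)
  out$length <- out$end - out$start + 1
  out
}

#' @rdname ctxlife_io
#' @export
read_go_annotations <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term") %in% names(d)))
    stop("GO annotation TSV needs columns gene_id and term")
  d
}

#' Validate pipeline input tables
#'
#' Schema and sanity checks for the interchange tables.  Hard errors
#' (missing required columns, negative life spans, an H pool without its C
#' counterpart) stop with a located message; soft issues are collected as
#' warnings in the returned report.
#'
#' @param data the table to check.
#' @return invisibly `TRUE`; called for its side effect of stopping on a
#'   malformed table.
#' @export
validate_lifespan_table <- function(data) {
  need <- c("line", "sex", "temperature", "vial", "lifespan_days")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("lifespan table is missing required column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(!is.na(data$lifespan_days) & data$lifespan_days <= 0)
  if (length(bad) > 0)
    stop("non-positive life span at record(s) ",
         paste(head(bad, 5), collapse = ", "))
  if (anyNA(data$lifespan_days))
    warning(sum(is.na(data$lifespan_days)), " missing life span value(s)")
  invisible(TRUE)
}

#' @rdname validate_lifespan_table
#' @export
validate_pooled_counts <- function(data) {
  need <- c("variant_id", "chrom", "pos", "ref", "alt", "sex", "temperature",
            "replicate", "pool_type", "ref_reads", "alt_reads", "pool_size")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("pooled counts table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (any(data$ref_reads < 0 | data$alt_reads < 0))
    stop("negative read counts")
  if (!all(data$pool_type %in% c("H", "C")))
    stop("pool_type must be 'H' or 'C'")
  ctx <- unique(data[, c("sex", "temperature", "replicate")])
  for (i in seq_len(nrow(ctx))) {
    sub <- data[data$sex == ctx$sex[i] & data$temperature == ctx$temperature[i] &
                  data$replicate == ctx$replicate[i], ]
    types <- unique(sub$pool_type)
    if (!all(c("H", "C") %in% types))
      stop("context ", ctx$sex[i], ":", ctx$temperature[i], ":rep",
           ctx$replicate[i], " has an ", types[1],
           " pool but no matching ", setdiff(c("H", "C"), types), " pool")
  }
  invisible(TRUE)
}

#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates the stages in dependency order: simulate (or load) the
#' lifespan panel, panel-level quantitative genetics, micro-environmental
#' variance analysis, xQTL simulation and Z tests, and GO enrichment of the
#' xQTL genes, writing one TSV per result into `out_dir` together with a
#' JSON manifest recording the configuration, seed and package version.
#' Re-running with the same configuration and seed reproduces the outputs
#' byte for byte.
#'
#' @param config either a list or the path of a YAML file with (all
#'   optional) entries: `seed`; `out_dir`; `stages` (character subset of
#'   `quantgen`, `microenv`, `xqtl`, `enrichment`); `panel` (arguments of
#'   [panel_design()]); `lifespan_tsv` (use this table instead of
#'   simulating); `aip` (arguments of [aip_cohort_spec()] plus `n_variants`);
#'   `thresholds` (`xqtl_report_p`, `n_perm`, `gene_window`).
#' @return the manifest list, invisibly; outputs are written to `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% "ctxlife_out"
  stages <- config$stages %||% c("quantgen", "microenv", "xqtl", "enrichment")
  thr <- config$thresholds %||% list()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(stage, n)
    message(sprintf("[%s] %s: %d records (%.1fs elapsed)",
                    format(Sys.time(), "%H:%M:%S"), stage, n,
                    proc.time()[["elapsed"]] - t0))

  manifest <- list(package = "ctxlife",
                   version = as.character(packageVersion("ctxlife")),
                   seed = seed, stages = stages, config = config)

  if (!is.null(config$lifespan_tsv)) {
    panel <- read_lifespan_table(config$lifespan_tsv)
  } else {
    pd <- do.call(panel_design, config$panel %||% list(n_lines = 50))
    panel <- simulate_lifespan_panel(pd, true_components(), seed = seed)
    write_lifespan_table(panel, file.path(out_dir, "lifespan_panel.tsv"),
                         seed = seed)
  }
  log_stage("simulate", nrow(panel))

  if ("quantgen" %in% stages) {
    rep_q <- quantgen_report(panel)
    write_tsv_with_header(rep_q$per_temperature,
                          file.path(out_dir, "quantgen_per_temperature.tsv"),
                          seed)
    write_tsv_with_header(rep_q$gsi, file.path(out_dir, "quantgen_gsi.tsv"),
                          seed)
    write_tsv_with_header(do.call(rbind, rep_q$cross_temperature),
                          file.path(out_dir, "quantgen_gei.tsv"), seed)
    log_stage("quantgen", nrow(rep_q$per_temperature))
  }

  if ("microenv" %in% stages) {
    grp <- suppressWarnings(split_replicate_groups(panel))
    me <- ln_sigma_eps(grp)
    write_tsv_with_header(me, file.path(out_dir, "microenv_lnsigma.tsv"), seed)
    vh <- rbind(
      cbind(test_table = "brown_forsythe",
            brown_forsythe(panel)[, c("sex", "temperature", "statistic", "p")]),
      cbind(test_table = "cochran_c",
            cochran_c_by_context(panel)[, c("sex", "temperature",
                                            "statistic", "p")]))
    write_tsv_with_header(vh, file.path(out_dir, "microenv_varhet.tsv"), seed)
    log_stage("microenv", nrow(me))
  }

  xstats <- NULL
  if ("xqtl" %in% stages) {
    aip_cfg <- config$aip %||% list()
    n_var <- aip_cfg$n_variants %||% 500
    aip_cfg$n_variants <- NULL
    fp <- simulate_founder_genotypes(n_founders = 40, n_variants = n_var,
                                     seed = seed)
    spec <- do.call(aip_cohort_spec, aip_cfg)
    cohort <- simulate_aip_cohort(fp, spec, seed = seed + 1)
    counts <- pool_select_and_sequence(cohort, seed = seed + 2)
    write_pooled_counts(counts, file.path(out_dir, "pooled_counts.tsv"), seed)
    xstats <- z_test_hc(counts, report_p = thr$xqtl_report_p %||% 1e-7)
    write_tsv_with_header(xstats, file.path(out_dir, "xqtl_stats.tsv"), seed)
    log_stage("xqtl", nrow(xstats))
  }

  if ("enrichment" %in% stages && !is.null(xstats)) {
    # toy universe spanning the simulated variants
    v <- unique(xstats$variant_id)
    set.seed(seed + 3)
    genes <- data.frame(gene_id = sprintf("g%03d", 1:50), chrom = "2L",
                        start = seq(1, 20e6, length.out = 50),
                        stringsAsFactors = FALSE)
    genes$start <- round(genes$start)
    genes$end <- genes$start + sample(2000:20000, 50, replace = TRUE)
    genes$length <- genes$end - genes$start + 1
    counts <- read_pooled_counts(file.path(out_dir, "pooled_counts.tsv"))
    vmeta <- unique(counts[, c("variant_id", "chrom", "pos")])
    gmap <- map_variants_to_genes(vmeta, genes,
                                  window_bp = thr$gene_window %||% 1000)
    hit_genes <- unique(gmap$gene_id[gmap$variant_id %in%
                                       xstats$variant_id[xstats$reported]])
    if (length(hit_genes) >= 1) {
      ann <- data.frame(gene_id = rep(genes$gene_id, 2),
                        term = rep(c("GO:A", "GO:B"), each = 50)[
                          seq_len(2 * 50)],
                        stringsAsFactors = FALSE)
      enr <- go_enrichment(hit_genes, genes, ann,
                           n_perm = thr$n_perm %||% 1000, seed = seed)
      write_tsv_with_header(enr, file.path(out_dir, "enrichment.tsv"), seed)
      log_stage("enrichment", nrow(enr))
    } else {
      log_stage("enrichment", 0L)
    }
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
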