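#' Map variants to genes by proximity
#'
#' A variant maps to every gene whose body, extended by `window_bp` on both
#' sides, overlaps its position ("in or near" a gene); a variant may map to
#' several genes, and variants beyond the window of any gene map to none.
#' Interval overlap uses GenomicRanges.
#'
#' @param variants data frame with `variant_id`, `chrom`, `pos` (1-based).
#' @param genes data frame with `gene_id`, `chrom`, `start`, `end`
#'   (1-based, inclusive; see [read_gene_models()] for BED/GFF3 input).
#' @param window_bp flanking window in bp (default 1000).
#' @return data frame with one row per (variant, gene) pair: `variant_id`,
#'   `gene_id`, `distance` (0 inside the gene body).
#' @export
map_variants_to_genes <- function(variants, genes, window_bp = 1000) {
  need_v <- c("variant_id", "chrom", "pos")
  need_g <- c("gene_id", "chrom", "start", "end")
  if (!all(need_v %in% names(variants)))
    stop("variants needs columns: ", paste(need_v, collapse = ", "))
  if (!all(need_g %in% names(genes)))
    stop("genes needs columns: ", paste(need_g, collapse = ", "))
  if (any(genes$start > genes$end)) stop("gene start > end")
  unknown <- setdiff(unique(variants$chrom), unique(genes$chrom))
  if (length(unknown) > 0 && all(variants$chrom %in% unknown))
    stop("no variant chromosome matches the gene models: ",
         paste(unknown, collapse = ", "))

  vg <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(pmax(1, genes$start - window_bp),
                                                genes$end + window_bp))
  hits <- GenomicRanges::findOverlaps(vg, gg)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  dist <- pmax(0, pmax(genes$start[si] - variants$pos[qi],
                       variants$pos[qi] - genes$end[si]))
  out <- data.frame(variant_id = variants$variant_id[qi],
                    gene_id = genes$gene_id[si],
                    distance = dist,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Gene-length-corrected GO enrichment by weighted permutation
#'
#' Longer genes harbour more variants and are therefore more likely to be
#' hit by chance in an association study.  This test corrects for that bias
#' by building the null distribution of each GO term's overlap from random
#' gene sets of the same size drawn without replacement with probability
#' proportional to gene length (sequential draw-remove-renormalize).  The
#' permutation p-value is \eqn{(B+1)/(N+1)}, with \eqn{B} the number of the
#' \eqn{N} samplings whose overlap is at least the observed one.  A naive
#' (length-blind) hypergeometric p-value is reported alongside for
#' comparison, and Benjamini-Hochberg FDR is computed across terms for both.
#'
#' @param gene_set character vector of candidate genes (must be a subset of
#'   the universe).
#' @param universe data frame with `gene_id` and `length` (bp) for every
#'   candidate-eligible gene.
#' @param annotations data frame with `gene_id`, `term` (gene-to-GO-term
#'   pairs); terms with no annotated universe gene are skipped.
#' @param n_perm number of permutations N.
#' @param seed integer seed (permutation p-values are seed-reproducible).
#' @param weighted set `FALSE` for equal-probability sampling (then the
#'   permutation test estimates the hypergeometric null).
#' @return data frame of class `enrichment_result`, one row per term:
#'   `term`, `n_annotated` (universe genes with the term), `k_obs`
#'   (observed overlap), `perm_mean` (null mean overlap), `B`, `N`,
#'   `p_perm`, `fdr_perm`, `p_hyper`, `fdr_hyper`.
#' @export
go_enrichment <- function(gene_set, universe, annotations,
                          n_perm = 10000, seed = 1, weighted = TRUE) {
  if (!all(c("gene_id", "length") %in% names(universe)))
    stop("universe needs columns gene_id and length")
  if (!all(c("gene_id", "term") %in% names(annotations)))
    stop("annotations need columns gene_id and term")
  gene_set <- unique(as.character(gene_set))
  extra <- setdiff(gene_set, universe$gene_id)
  if (length(extra) > 0)
    stop("gene_set contains genes outside the universe: ",
         paste(head(extra, 3), collapse = ", "))
  if (any(universe$length <= 0)) stop("gene lengths must be positive")

  ann <- unique(annotations[annotations$gene_id %in% universe$gene_id,
                            c("gene_id", "term"), drop = FALSE])
  skipped <- setdiff(unique(annotations$term), unique(ann$term))
  if (length(skipped) > 0)
    message("skipping ", length(skipped),
            " term(s) with no annotated universe gene")
  terms <- sort(unique(ann$term))
  if (length(terms) == 0) stop("no annotated term overlaps the universe")

  n_univ <- nrow(universe)
  m <- length(gene_set)
  gidx <- setNames(seq_len(n_univ), universe$gene_id)

  # sparse universe-gene x term membership
  M <- Matrix::sparseMatrix(i = gidx[ann$gene_id],
                            j = match(ann$term, terms),
                            x = 1, dims = c(n_univ, length(terms)))
  obs <- as.numeric(Matrix::colSums(M[gidx[gene_set], , drop = FALSE]))
  n_annot <- as.numeric(Matrix::colSums(M))

  set.seed(seed)
  w <- if (weighted) universe$length else rep(1, n_univ)
  B <- numeric(length(terms))
  null_sum <- numeric(length(terms))
  for (b in seq_len(n_perm)) {
    draw <- sample.int(n_univ, m, replace = FALSE, prob = w)
    cnt <- as.numeric(Matrix::colSums(M[draw, , drop = FALSE]))
    B <- B + (cnt >= obs)
    null_sum <- null_sum + cnt
  }
  p_perm <- (B + 1) / (n_perm + 1)
  p_hyper <- phyper(obs - 1, n_annot, n_univ - n_annot, m,
                    lower.tail = FALSE)
  out <- data.frame(term = terms, n_annotated = n_annot, k_obs = obs,
                    perm_mean = null_sum / n_perm,
                    B = B, N = n_perm,
                    p_perm = p_perm,
                    fdr_perm = p.adjust(p_perm, "BH"),
                    p_hyper = p_hyper,
                    fdr_hyper = p.adjust(p_hyper, "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Overlap of gene lists across studies
#'
#' Tabulates which genes recur in several independent gene lists (e.g.
#' candidate lists from different mapping studies), returns the pairwise
#' overlap matrix, and optionally tests the overlap between the union of the
#' lists and a reference list against a stated universe by the
#' hypergeometric distribution.
#'
#' @param lists named list of character vectors (>= 2).
#' @param min_lists report genes present in at least this many lists.
#' @param reference optional character vector (e.g. genes known from mutant
#'   studies) to test for over-representation in the union of `lists`.
#' @param universe_size universe size for the hypergeometric test (required
#'   with `reference`).
#' @return list with `genes` (data frame: `gene_id`, `n_lists`, membership
#'   flags), `recurrent` (genes in >= `min_lists` lists), `pairwise`
#'   (overlap count matrix), and optionally `reference_test` (overlap and
#'   hypergeometric p).
#' @examples
#' study_overlap(list(a = c("A", "B", "C"), b = c("B", "C", "D"),
#'                    c = "E"))$recurrent
#' @export
study_overlap <- function(lists, min_lists = 2, reference = NULL,
                          universe_size = NULL) {
  if (length(lists) < 2) stop("need >= 2 gene lists")
  if (any(lengths(lists) == 0)) stop("empty gene list")
  if (is.null(names(lists)))
    names(lists) <- paste0("list", seq_along(lists))
  all_genes <- sort(unique(unlist(lists)))
  member <- sapply(lists, function(l) all_genes %in% l)
  genes <- data.frame(gene_id = all_genes, n_lists = rowSums(member),
                      member, stringsAsFactors = FALSE)
  pairwise <- crossprod(member)
  recurrent <- genes$gene_id[genes$n_lists >= min_lists]

  out <- list(genes = genes, recurrent = recurrent, pairwise = pairwise)
  if (!is.null(reference)) {
    if (is.null(universe_size))
      stop("universe_size is required for the reference overlap test")
    union_genes <- all_genes
    k <- length(intersect(union_genes, reference))
    p <- phyper(k - 1, length(reference),
                universe_size - length(reference),
                length(union_genes), lower.tail = FALSE)
    out$reference_test <- data.frame(
      n_union = length(union_genes), n_reference = length(reference),
      overlap = k, universe = universe_size, p_hyper = p)
  }
  out
}
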