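#' Simulate founder haplotypes for an outbred population
#'
#' Generates a biallelic founder panel: `n_founders` homozygous founder
#' lines by `n_variants` variants, with per-variant population frequencies
#' drawn from a minor-allele-frequency spectrum.  Every variant is forced to
#' segregate among the founders (0 < realized frequency < 1) by redrawing
#' monomorphic columns.
#'
#' @param n_founders number of founder lines (>= 2).
#' @param n_variants number of variants.
#' @param maf_spec either a length-2 numeric vector giving the bounds of a
#'   uniform allele-frequency spectrum, a single number (a point mass), or a
#'   function `f(n)` returning `n` frequencies in (0, 1).
#' @param seed integer seed.
#' @return list of class `founder_panel` with elements `haplotypes`
#'   (founders x variants 0/1 matrix), `variants` (data frame: `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`), `freq` (realized founder alt-allele
#'   frequencies), and `n_founders`.
#' @examples
#' fp <- simulate_founder_genotypes(40, 100, seed = 1)
#' range(fp$freq)
#' @export
simulate_founder_genotypes <- function(n_founders = 40, n_variants,
                                       maf_spec = c(0.05, 0.5), seed) {
  if (n_founders < 2)
    stop("n_founders must be >= 2 (a single founder cannot segregate)")
  set.seed(seed)
  draw_freq <- if (is.function(maf_spec)) {
    maf_spec
  } else if (length(maf_spec) == 1) {
    function(n) rep(maf_spec, n)
  } else {
    function(n) runif(n, maf_spec[1], maf_spec[2])
  }
  p <- draw_freq(n_variants)
  if (any(p <= 0 | p >= 1)) stop("maf_spec must yield frequencies in (0, 1)")
  H <- matrix(rbinom(n_founders * n_variants, 1, rep(p, each = n_founders)),
              n_founders, n_variants)
  # redraw monomorphic variants until all segregate
  repeat {
    cs <- colSums(H)
    mono <- which(cs == 0 | cs == n_founders)
    if (length(mono) == 0) break
    H[, mono] <- rbinom(n_founders * length(mono), 1,
                        rep(p[mono], each = n_founders))
  }
  variants <- data.frame(
    variant_id = sprintf("v%05d", seq_len(n_variants)),
    chrom = "2L",
    pos = sort(sample.int(20e6, n_variants)),
    ref = "A", alt = "T",
    stringsAsFactors = FALSE)
  structure(list(haplotypes = H, variants = variants,
                 freq = colMeans(H), n_founders = n_founders),
            class = "founder_panel")
}

#' Specification of an outbred xQTL cohort
#'
#' Describes the extreme-QTL (xQTL) experiment simulated by
#' [simulate_aip_cohort()]: an aged cohort per sex, temperature and
#' replicate, selection of the longest-lived fraction into a pool, a
#' same-size pool of random young individuals as control, and
#' pooled sequencing at a per-pool coverage drawn from a range.
#'
#' @param cohort_size aged individuals per sex, temperature and replicate.
#' @param pool_size individuals per sequenced pool.
#' @param top_fraction fraction of the cohort selected into the long-lived
#'   pool (`cohort_size * top_fraction` must be >= `pool_size`; the
#'   reference design has 960 x 0.10 = 96).
#' @param replicates number of independent replicate cohorts.
#' @param coverage integer range (length 2) of sequencing depth per pool and
#'   variant.
#' @param sexes,temperatures context labels.
#' @param effects per-variant, per-context additive effects on life span in
#'   days per alt allele: a data frame with columns `variant_id`, `effect`,
#'   and optional `sex` / `temperature` columns (NA = applies to all).
#'   Signs may differ between contexts, encoding antagonistic pleiotropy.
#' @param baseline mean life span (days).
#' @param sigma_env residual (environmental) life span SD in days.  The
#'   reference study does not determine this quantity for the outbred
#'   population; it is a free parameter.
#' @return list of class `aip_spec`.
#' @export
aip_cohort_spec <- function(cohort_size = 960, pool_size = 96,
                            top_fraction = 0.10, replicates = 2,
                            coverage = c(130, 156),
                            sexes = c("F", "M"),
                            temperatures = c("18", "25", "28"),
                            effects = NULL,
                            baseline = 45, sigma_env = 12) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  if (round(cohort_size * top_fraction) < pool_size)
    stop("top_fraction x cohort_size (",
         round(cohort_size * top_fraction),
         ") is smaller than pool_size (", pool_size, ")")
  if (!is.null(effects)) {
    if (!all(c("variant_id", "effect") %in% names(effects)))
      stop("effects must have columns variant_id and effect")
  }
  structure(list(cohort_size = as.integer(cohort_size),
                 pool_size = as.integer(pool_size),
                 top_fraction = top_fraction,
                 replicates = as.integer(replicates),
                 coverage = as.integer(coverage),
                 sexes = sexes, temperatures = temperatures,
                 effects = effects, baseline = baseline,
                 sigma_env = sigma_env),
            class = "aip_spec")
}

# per-variant effect vector for one context
aip_context_effects <- function(spec, n_variants, variant_ids, sex, temp) {
  beta <- numeric(n_variants)
  eff <- spec$effects
  if (is.null(eff) || nrow(eff) == 0) return(beta)
  unknown <- setdiff(eff$variant_id, variant_ids)
  if (length(unknown) > 0)
    stop("effects reference unknown variant id(s): ",
         paste(head(unknown, 3), collapse = ", "))
  sex_col <- if ("sex" %in% names(eff)) eff$sex else rep(NA, nrow(eff))
  temp_col <- if ("temperature" %in% names(eff)) eff$temperature else
    rep(NA, nrow(eff))
  use <- (is.na(sex_col) | sex_col == sex) &
    (is.na(temp_col) | temp_col == temp)
  idx <- match(eff$variant_id[use], variant_ids)
  beta[idx] <- beta[idx] + eff$effect[use]
  beta
}

#' Simulate aged outbred cohorts from a founder panel
#'
#' Draws individual genotypes per variant from the founder allele
#' frequencies (0/1/2 alt copies, linkage equilibrium) for each sex,
#' temperature and replicate cohort, and assigns each individual a life span
#' baseline + sum(effect x dosage) + Gaussian noise, honouring per-context
#' effect signs.
#'
#' @param panel a [simulate_founder_genotypes()] panel.
#' @param spec an [aip_cohort_spec()].
#' @param seed integer seed.
#' @return list of class `aip_cohort` with `contexts`, a list (one element
#'   per sex:temperature:replicate) of `genotypes` (individuals x variants
#'   dosage matrix) and `lifespan` (numeric vector), plus the `panel` and
#'   `spec`.
#' @export
simulate_aip_cohort <- function(panel, spec, seed) {
  stopifnot(inherits(panel, "founder_panel"), inherits(spec, "aip_spec"))
  set.seed(seed)
  p <- panel$freq
  V <- length(p)
  ids <- panel$variants$variant_id
  n <- spec$cohort_size
  contexts <- list()
  for (s in spec$sexes) {
    for (t in spec$temperatures) {
      beta <- aip_context_effects(spec, V, ids, s, t)
      for (r in seq_len(spec$replicates)) {
        G <- matrix(rbinom(n * V, 2, rep(p, each = n)), n, V)
        y <- spec$baseline + drop(G %*% beta) + rnorm(n, 0, spec$sigma_env)
        contexts[[paste(s, t, r, sep = ":")]] <-
          list(sex = s, temperature = t, replicate = r,
               genotypes = G, lifespan = y)
      }
    }
  }
  structure(list(contexts = contexts, panel = panel, spec = spec),
            class = "aip_cohort")
}

#' Select extreme pools and simulate pooled sequencing
#'
#' For each cohort (sex x temperature x replicate): the long-lived (H) pool
#' is the top `top_fraction` of individuals by life span (ties broken by
#' simulated order), truncated to `pool_size`; the control (C) pool consists
#' of `pool_size` young individuals drawn fresh from the founder allele
#' frequencies, mirroring the independently collected young control pools of
#' the experimental design.  Read counts per variant and pool are binomial
#' draws from the pool's true allele frequency at a depth drawn uniformly
#' from the coverage range.
#'
#' @param cohort a [simulate_aip_cohort()] result.
#' @param spec the [aip_cohort_spec()] (defaults to the one in `cohort`).
#' @param seed integer seed.
#' @param exact_counts if `TRUE`, skip read sampling and report allele
#'   counts as `2 * pool_size * f_pool` (an infinite-coverage limit used for
#'   calibration checks).
#' @return data frame of class `pooled_counts` with columns `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `sex`, `temperature`, `replicate`,
#'   `pool_type` ("H"/"C"), `ref_reads`, `alt_reads`, `pool_size`.
#' @export
pool_select_and_sequence <- function(cohort, spec = cohort$spec, seed,
                                     exact_counts = FALSE) {
  stopifnot(inherits(cohort, "aip_cohort"))
  set.seed(seed)
  v <- cohort$panel$variants
  V <- nrow(v)
  p <- cohort$panel$freq
  n_top <- round(spec$cohort_size * spec$top_fraction)
  if (n_top < spec$pool_size)
    stop("top fraction x cohort size < pool size")
  rows <- list()
  for (ctx in cohort$contexts) {
    ord <- order(ctx$lifespan, decreasing = TRUE)
    h_idx <- ord[seq_len(spec$pool_size)]
    f_H <- colMeans(ctx$genotypes[h_idx, , drop = FALSE]) / 2
    # fresh young individuals for the control pool
    Gc <- matrix(rbinom(spec$pool_size * V, 2, rep(p, each = spec$pool_size)),
                 spec$pool_size, V)
    f_C <- colMeans(Gc) / 2
    for (pool in c("H", "C")) {
      f <- if (pool == "H") f_H else f_C
      if (exact_counts) {
        depth <- rep(2L * spec$pool_size, V)
        alt <- round(f * depth)
      } else {
        depth <- sample(seq(spec$coverage[1], spec$coverage[2]), V,
                        replace = TRUE)
        alt <- rbinom(V, depth, f)
      }
      rows[[length(rows) + 1]] <- data.frame(
        variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
        ref = v$ref, alt = v$alt,
        sex = ctx$sex, temperature = ctx$temperature,
        replicate = ctx$replicate, pool_type = pool,
        ref_reads = depth - alt, alt_reads = alt,
        pool_size = spec$pool_size,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pooled_counts", "data.frame")
  out
}

#' Genotype matrix of inbred lines derived from founder haplotypes
#'
#' Convenience generator for line-mean association tests: treats each
#' founder haplotype draw as a fully inbred line (dosage 0/2) and returns a
#' lines x variants matrix, optionally with missing calls.
#'
#' @param n_lines number of inbred lines.
#' @param n_variants number of variants.
#' @param maf_spec allele-frequency spectrum (see
#'   [simulate_founder_genotypes()]).
#' @param missing_rate fraction of calls set to `NA`.
#' @param seed integer seed.
#' @return list with `dosage` (lines x variants matrix, values 0/2/NA,
#'   rownames line ids) and `variants` (variant metadata with realized
#'   `maf`).
#' @export
simulate_line_genotypes <- function(n_lines, n_variants,
                                    maf_spec = c(0.05, 0.5),
                                    missing_rate = 0, seed) {
  fp <- simulate_founder_genotypes(n_founders = n_lines,
                                   n_variants = n_variants,
                                   maf_spec = maf_spec, seed = seed)
  dos <- 2 * fp$haplotypes
  rownames(dos) <- sprintf("line_%03d", seq_len(n_lines))
  colnames(dos) <- fp$variants$variant_id
  if (missing_rate > 0) {
    nmiss <- round(missing_rate * length(dos))
    dos[sample.int(length(dos), nmiss)] <- NA
  }
  af <- colMeans(dos, na.rm = TRUE) / 2
  fp$variants$maf <- pmin(af, 1 - af)
  list(dosage = dos, variants = fp$variants)
}
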