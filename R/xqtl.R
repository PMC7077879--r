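#' Pool allele-frequency estimate and its sampling variance
#'
#' Estimates the alt-allele frequency of a sequenced pool as
#' \eqn{\hat f = alt/(ref+alt)} and its variance under a two-stage binomial
#' model: individuals sampled into the pool (2 x pool-size chromosomes for
#' diploids), then reads sampled from the pool, giving
#' \deqn{Var(\hat f) = \tilde f(1-\tilde f)\left(\frac{1}{2\,n_{pool}} + \frac{1}{reads}\right).}
#' Inside the variance a moderated frequency
#' \eqn{\tilde f = (alt + 0.5)/(reads + 1)} is used so that variants fixed
#' in a sample of reads do not get a zero variance; the point estimate is
#' unmoderated.
#'
#' @param ref_reads,alt_reads read counts (vectors allowed).
#' @param pool_size number of diploid individuals in the pool.
#' @return data frame with `f_hat`, `var_f`, `reads`.
#' @examples
#' estimate_pool_frequency(100, 100, pool_size = 96)
#' @export
estimate_pool_frequency <- function(ref_reads, alt_reads, pool_size = 96) {
  reads <- ref_reads + alt_reads
  if (any(reads <= 0)) stop("each pool needs at least one read")
  if (any(ref_reads < 0 | alt_reads < 0)) stop("read counts must be >= 0")
  f_hat <- alt_reads / reads
  f_mod <- (alt_reads + 0.5) / (reads + 1)
  var_f <- f_mod * (1 - f_mod) * (1 / (2 * pool_size) + 1 / reads)
  data.frame(f_hat = f_hat, var_f = var_f, reads = reads)
}

#' xQTL Z test of allele-frequency differences between extreme and control pools
#'
#' For each variant within each sex-by-temperature context, compares the
#' alt-allele frequency of the long-lived (H) pool with the random young
#' control (C) pool.  Per replicate, \eqn{\Delta f_r = \hat f_{H,r} - \hat
#' f_{C,r}}; replicates are combined as the mean
#' \eqn{\bar{\Delta f} = \frac{1}{R}\sum_r \Delta f_r} with model-based
#' variance \eqn{Var = \sum_{pools} Var(\hat f)/R^2}.  The statistic
#' \eqn{Z = \bar{\Delta f}/\sqrt{Var}} is referred to the standard normal
#' (two-sided).  The empirical between-replicate variance of \eqn{\Delta
#' f_r} is reported as a diagnostic but not used in the test (two replicates
#' are too few for a stable empirical variance).
#'
#' @param counts a `pooled_counts` data frame (see
#'   [pool_select_and_sequence()] or [read_pooled_counts()]): columns
#'   `variant_id`, `sex`, `temperature`, `replicate`, `pool_type`,
#'   `ref_reads`, `alt_reads`, `pool_size`.
#' @param report_p reporting threshold on the two-sided p-value (the
#'   reference analysis flags p < 1e-7).
#' @param bonferroni_alpha family-wise level used for the Bonferroni
#'   annotation; the per-variant cutoff is `bonferroni_alpha` divided by the
#'   number of analyzed variants.
#' @return data frame of class `xqtl_stat`: one row per variant x context
#'   with `f_H`, `f_C` (averaged over replicates), `delta_f`, `var_delta_f`,
#'   `Z`, `p`, `reported` (p < `report_p`), `bonferroni` flags, and the
#'   between-replicate diagnostic `var_delta_f_emp`.
#' @export
z_test_hc <- function(counts, report_p = 1e-7, bonferroni_alpha = 0.05) {
  need <- c("variant_id", "sex", "temperature", "replicate", "pool_type",
            "ref_reads", "alt_reads", "pool_size")
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0)
    stop("counts is missing required column(s): ", paste(miss, collapse = ", "))
  counts <- as.data.frame(counts)
  est <- estimate_pool_frequency(counts$ref_reads, counts$alt_reads,
                                 counts$pool_size)
  counts$f_hat <- est$f_hat
  counts$var_f <- est$var_f

  key <- interaction(counts$variant_id, counts$sex, counts$temperature,
                     counts$replicate, drop = TRUE)
  # require both pool types in every variant x context x replicate
  has <- tapply(counts$pool_type, key, function(x) all(c("H", "C") %in% x))
  if (!all(has))
    stop("every variant x context x replicate needs both an H and a C pool")

  wide_h <- counts[counts$pool_type == "H", ]
  wide_c <- counts[counts$pool_type == "C", ]
  m <- merge(wide_h[, c("variant_id", "sex", "temperature", "replicate",
                        "f_hat", "var_f")],
             wide_c[, c("variant_id", "sex", "temperature", "replicate",
                        "f_hat", "var_f")],
             by = c("variant_id", "sex", "temperature", "replicate"),
             suffixes = c("_H", "_C"))
  m$delta_r <- m$f_hat_H - m$f_hat_C
  m$var_r <- m$var_f_H + m$var_f_C

  grp <- interaction(m$variant_id, m$sex, m$temperature, drop = TRUE)
  agg <- function(x, f) as.numeric(tapply(x, grp, f))
  R <- agg(m$delta_r, length)
  out <- data.frame(
    variant_id = as.character(tapply(as.character(m$variant_id), grp, `[`, 1)),
    sex = as.character(tapply(as.character(m$sex), grp, `[`, 1)),
    temperature = as.character(tapply(as.character(m$temperature), grp, `[`, 1)),
    n_replicates = R,
    f_H = agg(m$f_hat_H, mean),
    f_C = agg(m$f_hat_C, mean),
    delta_f = agg(m$delta_r, mean),
    var_delta_f = agg(m$var_r, sum) / R^2,
    var_delta_f_emp = agg(m$delta_r, function(x)
      if (length(x) > 1) var(x) else NA_real_),
    stringsAsFactors = FALSE)
  out$Z <- out$delta_f / sqrt(out$var_delta_f)
  out$p <- 2 * pnorm(-abs(out$Z))
  out$reported <- out$p < report_p
  n_tests <- length(unique(out$variant_id))
  out$bonferroni <- out$p < bonferroni_alpha / n_tests
  attr(out, "bonferroni_cutoff") <- bonferroni_alpha / n_tests
  rownames(out) <- NULL
  class(out) <- c("xqtl_stat", "data.frame")
  out
}

#' Cross-context Z test of xQTL effects
#'
#' Tests whether the allele-frequency response to longevity selection,
#' \eqn{\bar{\Delta f}}, differs between two contexts (the two sexes within
#' a temperature, a pair of temperatures within a sex, or the sex difference
#' of a temperature difference).  Because the contexts use independent
#' cohorts, \eqn{\Delta\Delta f = \bar{\Delta f}_A - \bar{\Delta f}_B} has
#' variance \eqn{Var_A + Var_B}, and
#' \eqn{Z = \Delta\Delta f/\sqrt{Var_A + Var_B}} is referred to the standard
#' normal.
#'
#' @param stats_a,stats_b `xqtl_stat` data frames (or any data frame with
#'   `variant_id`, `delta_f`, `var_delta_f`) for the two contexts, matched
#'   by `variant_id`.
#' @param label contrast label carried into the result.
#' @param report_p reporting threshold on the two-sided p-value.
#' @return data frame of class `cross_context_stat` with `variant_id`,
#'   `contrast`, `delta_f_a`, `delta_f_b`, `ddelta_f`, `var_ddelta_f`, `Z`,
#'   `p`, `reported`.
#' @export
cross_context_z <- function(stats_a, stats_b, label = "A_vs_B",
                            report_p = 1e-7) {
  need <- c("variant_id", "delta_f", "var_delta_f")
  if (!all(need %in% names(stats_a)) || !all(need %in% names(stats_b)))
    stop("inputs must carry variant_id, delta_f and var_delta_f")
  m <- merge(stats_a[, need], stats_b[, need], by = "variant_id",
             suffixes = c("_a", "_b"))
  if (nrow(m) == 0) stop("no shared variants between the two contexts")
  out <- data.frame(
    variant_id = m$variant_id, contrast = label,
    delta_f_a = m$delta_f_a, delta_f_b = m$delta_f_b,
    ddelta_f = m$delta_f_a - m$delta_f_b,
    var_ddelta_f = m$var_delta_f_a + m$var_delta_f_b,
    stringsAsFactors = FALSE)
  out$Z <- out$ddelta_f / sqrt(out$var_ddelta_f)
  out$p <- 2 * pnorm(-abs(out$Z))
  out$reported <- out$p < report_p
  class(out) <- c("cross_context_stat", "data.frame")
  out
}

#' Context-dependence summary of xQTL results
#'
#' Classifies each variant across a set of per-context xQTL analyses and
#' summarizes, per gene, pairs of variants with opposite allele-frequency
#' responses.  A variant significant (at `report_p`) in exactly one context
#' is "context-specific"; significant in several contexts with opposite
#' `delta_f` signs, "antagonistic"; significant in several contexts with
#' consistent signs, "concordant"; otherwise "not_significant".
#'
#' Gene-level counts follow the reference analysis: for every gene, pairs of
#' distinct significant variants with opposite `delta_f` signs are counted
#' (i) in the same sex and temperature, (ii) in the same sex across
#' temperatures, (iii) in the same temperature across sexes, and (iv) across
#' both sex and temperature.
#'
#' @param stats an `xqtl_stat` data frame covering all contexts (rows =
#'   variant x context).
#' @param gene_map optional data frame mapping `variant_id` to `gene_id`
#'   (e.g. from [map_variants_to_genes()]).
#' @param report_p significance threshold.
#' @return list with `variant_class` (per-variant label + number of
#'   significant contexts), `delta_f_correlation` (context x context Pearson
#'   correlation matrix of `delta_f` over all variants), and (when
#'   `gene_map` is given) `gene_summary` with the four opposite-effect pair
#'   counts per gene.
#' @export
antagonism_summary <- function(stats, gene_map = NULL, report_p = 1e-7) {
  stats <- as.data.frame(stats)
  stats$context <- paste(stats$sex, stats$temperature, sep = ":")
  sig <- stats[stats$p < report_p, , drop = FALSE]

  per_var <- split(sig, sig$variant_id)
  variant_class <- data.frame(
    variant_id = unique(stats$variant_id), stringsAsFactors = FALSE)
  cls <- vapply(variant_class$variant_id, function(v) {
    s <- per_var[[v]]
    if (is.null(s) || nrow(s) == 0) return("not_significant")
    if (nrow(s) == 1) return("context_specific")
    sgn <- sign(s$delta_f)
    if (length(unique(sgn)) > 1) "antagonistic" else "concordant"
  }, character(1))
  variant_class$n_significant <- vapply(variant_class$variant_id, function(v) {
    s <- per_var[[v]]
    if (is.null(s)) 0L else nrow(s)
  }, integer(1))
  variant_class$class <- cls

  ctxs <- sort(unique(stats$context))
  dmat <- sapply(ctxs, function(cc) {
    x <- stats[stats$context == cc, c("variant_id", "delta_f")]
    setNames(x$delta_f, x$variant_id)[variant_class$variant_id]
  })
  corr <- suppressWarnings(cor(dmat, use = "pairwise.complete.obs"))

  out <- list(variant_class = variant_class, delta_f_correlation = corr)

  if (!is.null(gene_map)) {
    sig2 <- merge(sig, gene_map[, c("variant_id", "gene_id")],
                  by = "variant_id")
    gene_rows <- lapply(split(sig2, sig2$gene_id), function(g) {
      pairs <- if (nrow(g) < 2) NULL else utils::combn(nrow(g), 2)
      n_same <- n_xtemp <- n_xsex <- n_xboth <- 0L
      if (!is.null(pairs)) {
        for (j in seq_len(ncol(pairs))) {
          a <- g[pairs[1, j], ]; b <- g[pairs[2, j], ]
          if (a$variant_id == b$variant_id) next
          if (sign(a$delta_f) * sign(b$delta_f) >= 0) next
          same_sex <- a$sex == b$sex
          same_temp <- a$temperature == b$temperature
          if (same_sex && same_temp) n_same <- n_same + 1L
          else if (same_sex) n_xtemp <- n_xtemp + 1L
          else if (same_temp) n_xsex <- n_xsex + 1L
          else n_xboth <- n_xboth + 1L
        }
      }
      data.frame(gene_id = g$gene_id[1], n_sig_variants =
                   length(unique(g$variant_id)),
                 opposite_same_context = n_same,
                 opposite_across_temperature = n_xtemp,
                 opposite_across_sex = n_xsex,
                 opposite_across_both = n_xboth,
                 stringsAsFactors = FALSE)
    })
    gene_summary <- do.call(rbind, gene_rows)
    rownames(gene_summary) <- NULL
    out$gene_summary <- gene_summary
  }
  out
}
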