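#' Derive line-level phenotypes for association mapping
#'
#' From a table of individual records (or of micro-environmental variance
#' values), computes per-line means for every sex-by-temperature context and
#' assembles the derived phenotypes of a context-dependent association
#' analysis: per temperature, the female mean, male mean, sex average and
#' sex difference (oriented male minus female); per sex, the difference
#' between each pair of temperatures (oriented higher minus lower); and the
#' sex difference of each temperature difference (the sex-by-temperature
#' interaction phenotype).  A line missing any constituent context has the
#' corresponding derived phenotype set to `NA`.
#'
#' @param data a data frame with columns `line`, `sex`, `temperature` and
#'   the response (individual lifespan records or a `microenv_table`).
#' @param response response column.
#' @return data frame, one row per line, with columns
#'   `F_<t>`, `M_<t>`, `avg_<t>`, `sexdiff_<t>` for each temperature `t`;
#'   `F_<hi>m<lo>` and `M_<hi>m<lo>` for each temperature pair;
#'   `avg_<hi>m<lo>` and `sexdiff_<hi>m<lo>` for the average/sex difference
#'   of the temperature differences.
#' @examples
#' d <- simulate_lifespan_panel(panel_design(n_lines = 6), true_components(),
#'                              seed = 1)
#' head(derive_phenotypes(d))
#' @export
derive_phenotypes <- function(data, response = "lifespan_days") {
  data <- as.data.frame(data)
  need <- c("line", "sex", "temperature", response)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("data is missing required column(s): ", paste(miss, collapse = ", "))
  lines <- sort(unique(as.character(data$line)))
  sexes <- sort(unique(as.character(data$sex)))
  if (!all(sexes %in% c("F", "M")))
    stop("sex labels must be 'F' and 'M'")
  temps <- unique(as.character(data$temperature))
  # numeric ordering when labels are numeric-like, so "higher minus lower"
  # is well defined
  tnum <- suppressWarnings(as.numeric(temps))
  temps <- if (!anyNA(tnum)) temps[order(tnum)] else sort(temps)

  cell_mean <- tapply(data[[response]],
                      list(factor(as.character(data$line), levels = lines),
                           factor(as.character(data$sex), levels = c("F", "M")),
                           factor(as.character(data$temperature),
                                  levels = temps)),
                      mean)

  out <- data.frame(line = lines, stringsAsFactors = FALSE)
  for (t in temps) {
    f <- cell_mean[, "F", t]; m <- cell_mean[, "M", t]
    out[[paste0("F_", t)]] <- f
    out[[paste0("M_", t)]] <- m
    out[[paste0("avg_", t)]] <- (f + m) / 2
    out[[paste0("sexdiff_", t)]] <- m - f
  }
  if (length(temps) >= 2) {
    prs <- utils::combn(temps, 2, simplify = FALSE)
    for (pr in prs) {
      lo <- pr[1]; hi <- pr[2]   # temps sorted ascending
      tag <- paste0(hi, "m", lo)
      for (s in c("F", "M"))
        out[[paste0(s, "_", tag)]] <-
          cell_mean[, s, hi] - cell_mean[, s, lo]
      out[[paste0("avg_", tag)]] <-
        (out[[paste0("F_", tag)]] + out[[paste0("M_", tag)]]) / 2
      out[[paste0("sexdiff_", tag)]] <-
        out[[paste0("M_", tag)]] - out[[paste0("F_", tag)]]
    }
  }
  rownames(out) <- NULL
  out
}

#' Single-marker line-mean association scan
#'
#' Regresses a line-level phenotype on per-variant allele dosage.  The
#' phenotype is first residualized on the fixed covariates (e.g. Wolbachia
#' infection status and inversion karyotypes) by ordinary least squares, and
#' each variant is then tested by simple linear regression of the residual
#' on dosage, the standard two-step large-scan approximation.  Variants are
#' oriented to the minor allele at scan time (effects are in phenotype units
#' per minor allele) and filtered at `maf_min`; missing dosages are dropped
#' per variant and the MAF recomputed on the genotyped lines.
#'
#' @param pheno named numeric vector (names = line ids), or a data frame
#'   from [derive_phenotypes()] together with `phenotype` naming the column.
#' @param geno lines x variants dosage matrix (inbred lines: 0/2, `NA`
#'   allowed), rownames = line ids.
#' @param covariates optional data frame of per-line covariates (rownames or
#'   `line` column matching line ids); factors and numerics allowed.
#' @param phenotype column name when `pheno` is a data frame.
#' @param maf_min minor-allele-frequency filter; variants with MAF <=
#'   `maf_min` are excluded.
#' @param report_p reporting threshold (the reference analysis flags
#'   p < 1e-5).
#' @return data frame of class `scan_result`: `variant_id`, `n` (lines
#'   used), `maf`, `effect` (per minor allele), `se`, `t`, `p`, `reported`.
#' @export
marker_scan <- function(pheno, geno, covariates = NULL, phenotype = NULL,
                        maf_min = 0.05, report_p = 1e-5) {
  if (is.data.frame(pheno)) {
    if (is.null(phenotype))
      stop("give `phenotype` (column name) when pheno is a data frame")
    y <- setNames(pheno[[phenotype]], pheno$line)
  } else {
    y <- pheno
  }
  if (is.null(names(y))) stop("phenotype must be named by line id")
  y <- y[!is.na(y)]
  common <- intersect(names(y), rownames(geno))
  if (length(common) < 3) stop("fewer than 3 lines shared between phenotype and genotypes")
  y <- y[common]
  G <- geno[common, , drop = FALSE]

  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    if ("line" %in% names(cv)) {
      rownames(cv) <- cv$line
      cv$line <- NULL
    }
    cv <- cv[common, , drop = FALSE]
    if (anyNA(cv)) stop("covariates must be complete for all scanned lines")
    X <- stats::model.matrix(~ ., data = cv)
    if (qr(X)$rank < ncol(X)) stop("singular covariate design")
    y <- stats::resid(stats::lm.fit(X, y))
    names(y) <- common
  }

  # minor-allele orientation and MAF over genotyped lines
  n_ok <- colSums(!is.na(G))
  af <- colMeans(G, na.rm = TRUE) / 2
  flip <- !is.na(af) & af > 0.5
  G[, flip] <- 2 - G[, flip]
  maf <- pmin(af, 1 - af)
  keep <- which(!is.na(maf) & maf > maf_min & n_ok >= 3)
  if (length(keep) == 0) stop("no variant passes the MAF filter")

  res <- lapply(keep, function(j) {
    g <- G[, j]
    ok <- !is.na(g)
    yy <- y[ok]; gg <- g[ok]
    n <- length(yy)
    vg <- var(gg)
    if (vg == 0) return(c(n = n, effect = NA, se = NA, t = NA, p = NA))
    b <- stats::cov(yy, gg) / vg
    a <- mean(yy) - b * mean(gg)
    rss <- sum((yy - a - b * gg)^2)
    df <- n - 2
    se <- sqrt(rss / df / ((n - 1) * vg))
    tstat <- b / se
    c(n = n, effect = b, se = se, t = tstat,
      p = 2 * pt(-abs(tstat), df))
  })
  out <- as.data.frame(do.call(rbind, res))
  out <- cbind(data.frame(variant_id = colnames(G)[keep],
                          stringsAsFactors = FALSE),
               out, maf = unname(maf[keep]))
  out$reported <- !is.na(out$p) & out$p < report_p
  rownames(out) <- NULL
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Classify variant effects across contexts
#'
#' Given per-context scan results over a shared variant set, labels every
#' variant that is reported in at least one context as context-specific
#' (significant in exactly one context), antagonistic (significant in
#' several contexts with opposite effect signs) or concordant (several
#' contexts, same sign), and computes the Spearman correlation matrix of
#' effects between contexts.  When a genotype matrix is supplied, pairwise
#' linkage disequilibrium (squared genotype correlation) among the reported
#' variants is returned as well.
#'
#' @param scans named list of `scan_result` data frames (one per context).
#' @param geno optional dosage matrix for the LD summary.
#' @param report_p significance threshold (defaults to the scans' flags).
#' @return list with `variant_class`, `effect_correlation` (Spearman,
#'   pairwise-complete), and optional `ld_r2` among reported variants.
#' @export
classify_effects <- function(scans, geno = NULL, report_p = NULL) {
  if (length(scans) < 2) stop("need >= 2 contexts")
  ids <- Reduce(intersect, lapply(scans, function(s) s$variant_id))
  if (length(ids) == 0) stop("contexts share no variants")
  eff <- sapply(scans, function(s)
    setNames(s$effect, s$variant_id)[ids])
  sig <- sapply(scans, function(s) {
    flag <- if (is.null(report_p)) s$reported else
      (!is.na(s$p) & s$p < report_p)
    setNames(flag, s$variant_id)[ids]
  })
  n_sig <- rowSums(sig, na.rm = TRUE)
  cls <- rep("not_significant", length(ids))
  one <- n_sig == 1
  multi <- n_sig > 1
  cls[one] <- "context_specific"
  if (any(multi)) {
    cls[multi] <- vapply(which(multi), function(i) {
      sgn <- sign(eff[i, sig[i, ] %in% TRUE])
      if (length(unique(sgn)) > 1) "antagonistic" else "concordant"
    }, character(1))
  }
  variant_class <- data.frame(variant_id = ids, n_significant = n_sig,
                              class = cls, stringsAsFactors = FALSE)
  effect_correlation <- suppressWarnings(
    cor(eff, method = "spearman", use = "pairwise.complete.obs"))

  out <- list(variant_class = variant_class,
              effect_correlation = effect_correlation)
  if (!is.null(geno)) {
    rep_ids <- ids[n_sig > 0]
    if (length(rep_ids) >= 2) {
      sub <- geno[, rep_ids, drop = FALSE]
      out$ld_r2 <- suppressWarnings(
        cor(sub, use = "pairwise.complete.obs")^2)
    }
  }
  out
}
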