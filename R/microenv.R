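#' Split replicate vials into two pooled replicate groups
#'
#' For the micro-environmental variance analysis, the replicate vials of each
#' (line, sex, temperature) cell are pooled into two groups: the first half
#' of the vials (in vial-id order) as "Replicate 1" and the second half as
#' "Replicate 2" (e.g. vials 1-12 vs 13-24 for a 24-vial panel, or 1-24 vs
#' 25-48 for a 48-vial knockdown assay).  Cells with an odd or insufficient
#' number of vials cannot be split into equal halves and are dropped with a
#' warning.
#'
#' @param data a lifespan table with columns `line`, `sex`, `temperature`,
#'   `vial` plus any response columns.
#' @param split_point number of vials in the first group; the default `NULL`
#'   uses half of the vials present in each cell.
#' @param group_col name of the output column.
#' @return `data` with an added integer column (1 or 2); rows from
#'   unsplittable cells are removed.
#' @examples
#' d <- simulate_lifespan_panel(panel_design(n_lines = 4), true_components(),
#'                              seed = 1)
#' table(split_replicate_groups(d)$rep_group)
#' @export
split_replicate_groups <- function(data, split_point = NULL,
                                   group_col = "rep_group") {
  need <- c("line", "sex", "temperature", "vial")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("data is missing required column(s): ", paste(miss, collapse = ", "))
  data <- as.data.frame(data)
  key <- interaction(data$line, data$sex, data$temperature, drop = TRUE)
  grp <- rep(NA_integer_, nrow(data))
  dropped <- character(0)
  for (cell in levels(key)) {
    i <- which(key == cell)
    vials <- sort(unique(data$vial[i]))
    nv <- length(vials)
    half <- if (is.null(split_point)) nv %/% 2 else split_point
    if (nv < 2 || nv != 2 * half) {
      dropped <- c(dropped, cell)
      next
    }
    grp[i] <- ifelse(match(data$vial[i], vials) <= half, 1L, 2L)
  }
  if (length(dropped) > 0)
    warning(length(dropped), " cell(s) could not be split into two equal ",
            "vial groups and were dropped: ",
            paste(head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  data[[group_col]] <- grp
  data[!is.na(grp), , drop = FALSE]
}

#' Micro-environmental variance phenotype ln(sigma_eps)
#'
#' Computes, for each (line, sex, temperature, replicate group), the
#' within-group variance of the trait over all individuals (pooling across
#' vials, so that both between-vial and within-vial micro-environmental
#' variation are included) and the derived phenotype
#' \eqn{\ln\sigma_\epsilon = \ln\sqrt{S^2}} with \eqn{S^2} the unbiased
#' (n-1) sample variance.  Groups with fewer than 2 flies, or with zero
#' variance (for which the log is undefined), are flagged and excluded.
#'
#' @param data output of [split_replicate_groups()] (or any table with a
#'   replicate-group column).
#' @param response trait column.
#' @param group_col replicate-group column name.
#' @return data frame of class `microenv_table` with columns `line`, `sex`,
#'   `temperature`, `rep_group`, `n`, `s2`, and `ln_sigma_eps`; an attribute
#'   `"excluded"` lists dropped groups and the reason.
#' @examples
#' d <- split_replicate_groups(
#'   simulate_lifespan_panel(panel_design(n_lines = 4), true_components(),
#'                           seed = 1))
#' head(ln_sigma_eps(d))
#' @export
ln_sigma_eps <- function(data, response = "lifespan_days",
                         group_col = "rep_group") {
  need <- c("line", "sex", "temperature", group_col, response)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("data is missing required column(s): ", paste(miss, collapse = ", "))
  data <- as.data.frame(data)
  fac <- list(line = data$line, sex = data$sex,
              temperature = data$temperature, rep_group = data[[group_col]])
  agg_n <- stats::aggregate(data[[response]], fac, length)
  agg_v <- stats::aggregate(data[[response]], fac, var)
  out <- agg_n
  names(out)[names(out) == "x"] <- "n"
  out$s2 <- agg_v$x
  bad <- out$n < 2 | is.na(out$s2) | out$s2 <= 0
  excluded <- out[bad, c("line", "sex", "temperature", "rep_group", "n", "s2")]
  if (nrow(excluded) > 0)
    excluded$reason <- ifelse(excluded$n < 2, "n < 2", "zero variance")
  out <- out[!bad, , drop = FALSE]
  out$ln_sigma_eps <- log(sqrt(out$s2))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("microenv_table", "data.frame")
  out
}

#' Brown-Forsythe test of within-line variance heterogeneity
#'
#' Tests whether the within-line variance of the trait differs among lines,
#' separately for each sex-by-temperature context.  Each observation is
#' transformed to its absolute deviation from the line median,
#' \eqn{z_{ij} = |y_{ij} - \tilde y_j|}, and heterogeneity is assessed by a
#' one-way ANOVA F test on \eqn{z} with (k-1, N-k) degrees of freedom.
#'
#' @param data a lifespan table with columns `line`, `sex`, `temperature`
#'   and the response.
#' @param response trait column.
#' @param by character vector of context columns; default sex and
#'   temperature (one test per combination present in the data).
#' @return data frame of class `varhet_result`: one row per context with
#'   `test`, context labels, `k` (lines), `df1`, `df2`, `statistic`, `p`.
#' @examples
#' d <- simulate_lifespan_panel(panel_design(n_lines = 20), true_components(),
#'                              seed = 1)
#' brown_forsythe(d)
#' @export
brown_forsythe <- function(data, response = "lifespan_days",
                           by = c("sex", "temperature")) {
  data <- as.data.frame(data)
  ctx <- interaction(data[by], drop = TRUE, sep = ":")
  out <- do.call(rbind, lapply(levels(ctx), function(cc) {
    sub <- data[ctx == cc, , drop = FALSE]
    counts <- table(sub$line)
    keep <- names(counts)[counts >= 2]
    if (length(keep) < length(counts[counts > 0]))
      warning("context ", cc, ": ", sum(counts > 0) - length(keep),
              " line(s) with n < 2 excluded")
    sub <- sub[sub$line %in% keep, , drop = FALSE]
    if (length(keep) < 2)
      stop("context ", cc, ": need >= 2 lines with n >= 2")
    y <- sub[[response]]
    line <- factor(sub$line)
    med <- tapply(y, line, median)
    z <- abs(y - med[as.character(line)])
    k <- nlevels(line); N <- length(z)
    zbar <- tapply(z, line, mean); n_j <- tabulate(line)
    ss_b <- sum(n_j * (zbar - mean(z))^2)
    ss_w <- sum((z - zbar[as.integer(line)])^2)
    df1 <- k - 1; df2 <- N - k
    if (ss_w == 0) {
      stat <- if (ss_b == 0) 0 else Inf
      p <- if (ss_b == 0) 1 else 0
    } else {
      stat <- (ss_b / df1) / (ss_w / df2)
      p <- pf(stat, df1, df2, lower.tail = FALSE)
    }
    ctxvals <- sub[1, by, drop = FALSE]
    rownames(ctxvals) <- NULL
    cbind(data.frame(test = "brown_forsythe", stringsAsFactors = FALSE),
          ctxvals,
          data.frame(k = k, df1 = df1, df2 = df2, statistic = stat, p = p))
  }))
  rownames(out) <- NULL
  class(out) <- c("varhet_result", "data.frame")
  out
}

#' Cochran's C test of variance heterogeneity
#'
#' Tests whether the largest of k group variances is larger than expected
#' under homogeneity, using \eqn{C = \max_j S^2_j / \sum_i S^2_i}.  The
#' p-value uses the classical critical-value relation
#' \deqn{C_{crit}(\alpha) = [1 + (k-1)/F_{\alpha/k}(\nu, (k-1)\nu)]^{-1}}
#' with \eqn{\nu} the (average) within-group degrees of freedom, inverted at
#' the observed C: \eqn{p = \min(1,\; k\,P[F_{\nu,(k-1)\nu} > (k-1)C/(1-C)])}.
#'
#' @param s2 numeric vector of group (line) variances.
#' @param n per-group sample sizes (scalar or vector; averaged for the
#'   degrees of freedom).
#' @return one-row data frame of class `varhet_result` with `test`, `k`,
#'   `nu`, `statistic` (C) and `p`.
#' @examples
#' cochran_c(c(4, 1, 1), n = 10)
#' @export
cochran_c <- function(s2, n) {
  if (any(s2 < 0)) stop("variances must be non-negative")
  k <- length(s2)
  if (k < 2) stop("need >= 2 variances")
  if (any(n < 2)) stop("group sizes must be >= 2")
  C <- max(s2) / sum(s2)
  nu <- mean(n) - 1
  if (C >= 1) {
    p <- 0
  } else {
    fstat <- (k - 1) * C / (1 - C)
    p <- min(1, k * pf(fstat, nu, (k - 1) * nu, lower.tail = FALSE))
  }
  out <- data.frame(test = "cochran_c", k = k, nu = nu, statistic = C, p = p,
                    stringsAsFactors = FALSE)
  class(out) <- c("varhet_result", "data.frame")
  out
}

#' Cochran's C test per sex-by-temperature context
#'
#' Convenience wrapper computing per-line variances within each context of a
#' lifespan table and applying [cochran_c()].
#'
#' @inheritParams brown_forsythe
#' @return data frame with one row per context: context labels, average `n`,
#'   `k`, `statistic`, `p`.
#' @export
cochran_c_by_context <- function(data, response = "lifespan_days",
                                 by = c("sex", "temperature")) {
  data <- as.data.frame(data)
  ctx <- interaction(data[by], drop = TRUE, sep = ":")
  out <- do.call(rbind, lapply(levels(ctx), function(cc) {
    sub <- data[ctx == cc, , drop = FALSE]
    n_j <- tapply(sub[[response]], sub$line, length)
    s2_j <- tapply(sub[[response]], sub$line, var)
    keep <- !is.na(s2_j) & n_j >= 2
    res <- cochran_c(s2_j[keep], n = n_j[keep])
    ctxvals <- sub[1, by, drop = FALSE]
    rownames(ctxvals) <- NULL
    cbind(res[, "test", drop = FALSE], ctxvals,
          res[, c("k", "nu", "statistic", "p")])
  }))
  rownames(out) <- NULL
  class(out) <- c("varhet_result", "data.frame")
  out
}
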