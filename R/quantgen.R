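#' Fit REML variance components for a replicated line design
#'
#' Partitions variation in a trait measured on replicated inbred lines into
#' among-line, line-by-sex, line-by-temperature, line-by-sex-by-temperature,
#' replicate-vial, and residual components, using the cross-classified mixed
#' model
#' \deqn{Y = \mu + L + S + T + LS + LT + ST + LST + Rep(LT) + S.Rep(LT) + \epsilon}
#' with sex and temperature fixed and all line-containing terms and the
#' vial terms random.  Reduced models (per temperature across sexes, per sex
#' across temperatures, or within one sex-by-temperature cell) drop the terms
#' that are not identifiable in that slice of the data.
#'
#' Estimation is REML via [lme4::lmer()]; the boundary constraint of lme4
#' guarantees non-negative variance components.  Unbalanced data (e.g. whole
#' line-by-temperature cells missing) are handled natively; no imputation is
#' performed.
#'
#' @param data a data frame with columns `line`, `sex`, `temperature`,
#'   `vial` (ignored when `include_vial = FALSE`) and the response column.
#' @param model one of `"full"` (both sexes, all temperatures),
#'   `"by_temperature"` (both sexes within one temperature),
#'   `"by_sex"` (one sex across temperatures), or `"within"` (a single
#'   sex-by-temperature cell).
#' @param response name of the response column (default `"lifespan_days"`).
#' @param include_vial include `Rep(LxT)` (and, in two-sex models,
#'   `S x Rep(LxT)`) random vial terms.  Use `FALSE` for group-level
#'   responses such as the micro-environmental variance phenotype.
#' @param lrt compute likelihood-ratio tests for each random term by
#'   refitting without it (p-value from an equal mixture of chi-squared 0 and
#'   1 df, the standard boundary correction).
#' @param ... further arguments passed to [lme4::lmer()].
#'
#' @return an object of class `vc_fit`: a list with elements
#'   \item{components}{named numeric vector of variance components
#'     (`sigma2_L`, `sigma2_LS`, `sigma2_LT`, `sigma2_LST`, `sigma2_vial`,
#'     `sigma2_sexvial`, `sigma2_eps`; only the terms present in the model)}
#'   \item{anova_table}{data frame with one row per random term: estimate,
#'     LRT chi-squared and p-value (if `lrt = TRUE`), plus rows for fixed
#'     effects with F statistics from the Wald test}
#'   \item{means}{named vector of observed sex (or context) means of the
#'     response}
#'   \item{model,response}{the request}
#'   \item{logLik}{REML log-likelihood}
#'   \item{converged}{logical}
#'   \item{degenerate}{`TRUE` when the response is constant}
#'   \item{fit}{the underlying `merMod` object}
#' @examples
#' set.seed(1)
#' d <- simulate_lifespan_panel(panel_design(n_lines = 30, vials_per_line_per_temp = 4),
#'                              true_components(), seed = 1)
#' fit <- fit_variance_components(subset(d, temperature == "25"),
#'                                model = "by_temperature", lrt = FALSE)
#' fit$components
#' @export
fit_variance_components <- function(data,
                                    model = c("full", "by_temperature",
                                              "by_sex", "within"),
                                    response = "lifespan_days",
                                    include_vial = TRUE,
                                    lrt = TRUE,
                                    ...) {
  model <- match.arg(model)
  need <- c("line", "sex", "temperature", response)
  if (include_vial) need <- c(need, "vial")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("data is missing required column(s): ", paste(miss, collapse = ", "))
  data <- as.data.frame(data)
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  data$line <- factor(data$line)
  data$sex <- factor(data$sex)
  data$temperature <- factor(data$temperature)

  n_sex <- nlevels(droplevels(data$sex))
  n_temp <- nlevels(droplevels(data$temperature))
  if (nlevels(droplevels(data$line)) < 2)
    stop("at least 2 lines are required to estimate among-line variance")
  switch(model,
    full = {
      if (n_sex < 2 || n_temp < 2)
        stop("'full' model needs both sexes and >= 2 temperatures")
    },
    by_temperature = {
      if (n_temp != 1) stop("'by_temperature' model expects data from a single temperature")
      if (n_sex < 2) stop("'by_temperature' model needs both sexes")
    },
    by_sex = {
      if (n_sex != 1) stop("'by_sex' model expects data from a single sex")
      if (n_temp < 2) stop("'by_sex' model needs >= 2 temperatures")
    },
    within = {
      if (n_sex != 1 || n_temp != 1)
        stop("'within' model expects a single sex-by-temperature cell")
    })

  y <- data[[response]]
  if (stats::var(y) == 0) {
    # constant response: all components are zero by definition
    terms <- vc_random_terms(model, include_vial)
    comp <- setNames(rep(0, length(terms) + 1), c(terms, "sigma2_eps"))
    return(structure(list(components = comp, anova_table = NULL,
                          means = vc_context_means(data, response, model),
                          model = model, response = response,
                          logLik = NA_real_, converged = TRUE,
                          degenerate = TRUE, fit = NULL),
                     class = "vc_fit"))
  }

  if (include_vial) {
    # Rep(LxT): a vial is nested in line x temperature
    data$vial_unit <- interaction(data$line, data$temperature, data$vial,
                                  drop = TRUE)
  }

  rand <- vc_random_terms(model, include_vial)
  fixed <- switch(model,
    full = paste0("`", response, "` ~ sex * temperature"),
    by_temperature = paste0("`", response, "` ~ sex"),
    by_sex = paste0("`", response, "` ~ temperature"),
    within = paste0("`", response, "` ~ 1"))
  form <- as.formula(paste(fixed, "+", paste(vc_term_formula(rand),
                                             collapse = " + ")))
  fit <- lme4::lmer(form, data = data, REML = TRUE, ...)
  comp <- vc_extract(fit, rand)

  conv <- length(fit@optinfo$conv$lme4) == 0
  tab <- vc_anova_table(fit, data, form, rand, comp, lrt = lrt)

  structure(list(components = comp, anova_table = tab,
                 means = vc_context_means(data, response, model),
                 model = model, response = response,
                 logLik = as.numeric(logLik(fit)), converged = conv,
                 degenerate = FALSE, fit = fit),
            class = "vc_fit")
}

# random terms per model; names are the component labels
vc_random_terms <- function(model, include_vial) {
  terms <- switch(model,
    full = c("sigma2_L", "sigma2_LS", "sigma2_LT", "sigma2_LST"),
    by_temperature = c("sigma2_L", "sigma2_LS"),
    by_sex = c("sigma2_L", "sigma2_LT"),
    within = "sigma2_L")
  if (include_vial) {
    terms <- c(terms, "sigma2_vial")
    if (model %in% c("full", "by_temperature"))
      terms <- c(terms, "sigma2_sexvial")
  }
  terms
}

vc_term_formula <- function(terms) {
  map <- c(sigma2_L = "(1 | line)",
           sigma2_LS = "(1 | line:sex)",
           sigma2_LT = "(1 | line:temperature)",
           sigma2_LST = "(1 | line:sex:temperature)",
           sigma2_vial = "(1 | vial_unit)",
           sigma2_sexvial = "(1 | sex:vial_unit)")
  unname(map[terms])
}

vc_grouping_name <- function(term) {
  c(sigma2_L = "line", sigma2_LS = "line:sex",
    sigma2_LT = "line:temperature", sigma2_LST = "line:sex:temperature",
    sigma2_vial = "vial_unit", sigma2_sexvial = "sex:vial_unit")[[term]]
}

vc_extract <- function(fit, rand) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- setNames(numeric(length(rand) + 1), c(rand, "sigma2_eps"))
  for (term in rand) {
    grp <- vc_grouping_name(term)
    row <- vc$grp == grp
    comp[term] <- if (any(row)) vc$vcov[row][1] else 0
  }
  comp["sigma2_eps"] <- vc$vcov[vc$grp == "Residual"]
  comp
}

vc_context_means <- function(data, response, model) {
  if (model %in% c("full", "by_temperature")) {
    tapply(data[[response]], droplevels(data$sex), mean)
  } else if (model == "by_sex") {
    tapply(data[[response]], droplevels(data$temperature), mean)
  } else {
    c(mean = mean(data[[response]]))
  }
}

vc_anova_table <- function(fit, data, form, rand, comp, lrt) {
  rows <- data.frame(term = names(comp),
                     type = c(rep("random", length(rand)), "residual"),
                     estimate = unname(comp),
                     chisq = NA_real_, df = NA_real_, p = NA_real_,
                     stringsAsFactors = FALSE)
  if (lrt) {
    full_ml <- as.numeric(logLik(fit))
    for (term in rand) {
      reduced <- setdiff(rand, term)
      if (length(reduced) == 0) next
      rform <- stats::update.formula(
        form, paste(". ~ . -", vc_term_formula(term)))
      rfit <- try(lme4::lmer(rform, data = data, REML = TRUE), silent = TRUE)
      if (inherits(rfit, "try-error")) next
      chi <- max(0, 2 * (full_ml - as.numeric(logLik(rfit))))
      i <- rows$term == term
      rows$chisq[i] <- chi
      rows$df[i] <- 1
      # boundary-corrected 0.5*chi0 + 0.5*chi1 mixture
      rows$p[i] <- 0.5 * pchisq(chi, df = 1, lower.tail = FALSE)
    }
  }
  rows
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("REML variance components (", x$model, " model, response: ",
      x$response, ")\n", sep = "")
  if (x$degenerate) cat("  [degenerate fit: constant response]\n")
  print(round(x$components, 4))
  invisible(x)
}

#' Derived quantitative-genetic statistics
#'
#' Computes broad-sense heritability, coefficients of genetic and
#' environmental variation, and cross-context genetic correlations from a set
#' of variance components.
#'
#' The definitions are
#' \deqn{H^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_\epsilon)}
#' with \eqn{\sigma^2_G} the sum of all line-containing components in the
#' fitted model (among-line plus any line-by-context interactions);
#' \deqn{CV_G = 100\,\sigma_G/\bar X, \quad CV_\epsilon = 100\,\sigma_\epsilon/\bar X}
#' with \eqn{\bar X} the average of the sex means in the analyzed context;
#' \deqn{r_{GMF} = \sigma^2_L/(\sigma^2_L + \sigma^2_{LS})}
#' (cross-sex genetic correlation, from a per-temperature two-sex model);
#' \deqn{r_{GT} = \sigma^2_L/(\sigma^2_L + \sigma^2_{LT})}
#' (cross-temperature genetic correlation, from a per-sex model); and
#' \deqn{r_{GST} = \sigma^2_L/(\sigma^2_L + \sigma^2_{LS} + \sigma^2_{LT} + \sigma^2_{LST})}
#' from the full model.  Replicate-vial components are reported but excluded
#' from \eqn{\sigma^2_P} (an alternative including them is returned as
#' `h2_incl_vial`).
#'
#' @param vc a `vc_fit` object from [fit_variance_components()], or a named
#'   numeric vector with elements among `sigma2_L`, `sigma2_LS`, `sigma2_LT`,
#'   `sigma2_LST`, `sigma2_vial`, `sigma2_sexvial`, `sigma2_eps`.
#' @param means optional numeric vector of context (e.g. per-sex) means;
#'   taken from `vc` when it is a `vc_fit`.  `CV_G`/`CV_eps` use their
#'   average.
#' @return a list of class `derived_genetics` with elements `sigma2_G`,
#'   `sigma2_P`, `H2`, `CV_G`, `CV_eps`, `r_GMF`, `r_GT`, `r_GST`,
#'   `h2_incl_vial`, and `means`.  Statistics whose inputs are absent are
#'   `NA`; statistics with a zero denominator are `NaN`.
#' @examples
#' derive_genetics(c(sigma2_L = 354.38, sigma2_LS = 84.98,
#'                   sigma2_eps = 689.24),
#'                 means = c(F = 77.86, M = 84.97))
#' @export
derive_genetics <- function(vc, means = NULL) {
  if (inherits(vc, "vc_fit")) {
    if (is.null(means)) means <- vc$means
    vc <- vc$components
  }
  vc <- vc[!is.na(vc)]
  if (any(vc < 0)) stop("variance components must be non-negative")
  comp <- function(x) if (x %in% names(vc)) unname(vc[x]) else NA_real_
  line_terms <- intersect(names(vc),
                          c("sigma2_L", "sigma2_LS", "sigma2_LT", "sigma2_LST"))
  if (length(line_terms) == 0)
    stop("no line-containing variance component found")
  s2_G <- sum(vc[line_terms])
  s2_eps <- comp("sigma2_eps")
  if (is.na(s2_eps)) stop("sigma2_eps is required")
  s2_P <- s2_G + s2_eps

  ratio <- function(num, den) {
    if (is.na(num) || is.na(den)) return(NA_real_)
    if (den == 0) return(NaN)
    num / den
  }
  mbar <- if (!is.null(means)) mean(means) else NA_real_

  s2_vial <- sum(vc[intersect(names(vc), c("sigma2_vial", "sigma2_sexvial"))])
  out <- list(
    sigma2_G = s2_G,
    sigma2_P = s2_P,
    H2 = ratio(s2_G, s2_P),
    CV_G = if (is.na(mbar)) NA_real_ else ratio(100 * sqrt(s2_G), mbar),
    CV_eps = if (is.na(mbar)) NA_real_ else ratio(100 * sqrt(s2_eps), mbar),
    r_GMF = if (is.na(comp("sigma2_LS")) || !is.na(comp("sigma2_LT")))
      NA_real_ else ratio(comp("sigma2_L"), comp("sigma2_L") + comp("sigma2_LS")),
    r_GT = if (is.na(comp("sigma2_LT")) || !is.na(comp("sigma2_LS")))
      NA_real_ else ratio(comp("sigma2_L"), comp("sigma2_L") + comp("sigma2_LT")),
    r_GST = if (any(is.na(c(comp("sigma2_LS"), comp("sigma2_LT"),
                            comp("sigma2_LST"))))) NA_real_ else
      ratio(comp("sigma2_L"),
            comp("sigma2_L") + comp("sigma2_LS") + comp("sigma2_LT") +
              comp("sigma2_LST")),
    h2_incl_vial = ratio(s2_G, s2_P + s2_vial),
    means = means
  )
  class(out) <- "derived_genetics"
  out
}

#' @export
print.derived_genetics <- function(x, ...) {
  v <- unlist(x[c("sigma2_G", "sigma2_P", "H2", "CV_G", "CV_eps",
                  "r_GMF", "r_GT", "r_GST")])
  print(round(v[!is.na(v)], 4))
  invisible(x)
}

#' Decompose a two-context interaction variance
#'
#' Splits the line-by-context (sex or temperature) interaction variance for a
#' pair of contexts into a rank-order-change term and a genetic-scale-change
#' term:
#' \deqn{\sigma^2_{int} = \sigma_A \sigma_B (1 - r) + (\sigma_A - \sigma_B)^2/2}
#' where \eqn{\sigma_A, \sigma_B} are the square roots of the among-line
#' variance components in the two contexts and \eqn{r} is the cross-context
#' genetic correlation.  The first term reflects changes in the rank order of
#' lines between contexts; the second reflects differences in the magnitude
#' of among-line variance.  The rank share is
#' \eqn{100\cdot rank/(rank + scale)} percent.
#'
#' The identity \eqn{rank + scale = (\sigma_A^2 + \sigma_B^2)/2 -
#' r\,\sigma_A\sigma_B} holds exactly.
#'
#' @param sigma_a,sigma_b non-negative genetic standard deviations in the two
#'   contexts (e.g. females/males, or two temperatures).
#' @param r cross-context genetic correlation in \[-1, 1\].
#' @param label_a,label_b optional context labels carried into the result.
#' @return a data frame of class `interaction_decomposition` with columns
#'   `context_a`, `context_b`, `sigma_a`, `sigma_b`, `r`, `rank_term`,
#'   `scale_term`, `interaction_variance` and `pct_rank`.  When both terms
#'   are zero the percentage is undefined and returned as `NA`.
#'   All arguments are vectorized.
#' @examples
#' decompose_interaction(20.51, 21.40, 0.806)  # GSI for life span at 18 C
#' @export
decompose_interaction <- function(sigma_a, sigma_b, r,
                                  label_a = NA_character_,
                                  label_b = NA_character_) {
  if (any(sigma_a < 0) || any(sigma_b < 0))
    stop("genetic standard deviations must be non-negative")
  if (any(r < -1) || any(r > 1))
    stop("correlation must lie in [-1, 1]")
  rank_term <- sigma_a * sigma_b * (1 - r)
  scale_term <- (sigma_a - sigma_b)^2 / 2
  total <- rank_term + scale_term
  pct <- ifelse(total == 0, NA_real_, 100 * rank_term / total)
  out <- data.frame(context_a = label_a, context_b = label_b,
                    sigma_a = sigma_a, sigma_b = sigma_b, r = r,
                    rank_term = rank_term, scale_term = scale_term,
                    interaction_variance = total, pct_rank = pct,
                    stringsAsFactors = FALSE)
  class(out) <- c("interaction_decomposition", "data.frame")
  out
}

#' Aggregate pairwise interaction decompositions over several contexts
#'
#' For `t` contexts (e.g. three temperatures) with genetic standard
#' deviations `sigmas` and pairwise genetic correlations `r_mat`, computes
#' the per-pair decomposition and the aggregate interaction variance
#' \deqn{\sigma^2_{LT} = \sum_{i<j} [2\sigma_i\sigma_j(1-r_{ij}) +
#'   (\sigma_i-\sigma_j)^2] / (t(t-1))}
#' i.e. the average of the pairwise two-context terms.
#'
#' @param sigmas named vector of per-context genetic SDs.
#' @param r_mat symmetric matrix of pairwise genetic correlations (only the
#'   upper triangle is used).
#' @return list with `pairs` (an `interaction_decomposition` data frame, one
#'   row per context pair) and `aggregate` (rank/scale/total averaged over
#'   pairs).
#' @export
decompose_interaction_multi <- function(sigmas, r_mat) {
  t <- length(sigmas)
  if (t < 2) stop("need >= 2 contexts")
  if (!all(dim(r_mat) == c(t, t))) stop("r_mat must be ", t, " x ", t)
  idx <- which(upper.tri(r_mat), arr.ind = TRUE)
  labs <- names(sigmas)
  if (is.null(labs)) labs <- as.character(seq_len(t))
  pairs <- decompose_interaction(sigmas[idx[, 1]], sigmas[idx[, 2]],
                                 r_mat[idx],
                                 label_a = labs[idx[, 1]],
                                 label_b = labs[idx[, 2]])
  agg <- c(rank_term = mean(pairs$rank_term),
           scale_term = mean(pairs$scale_term),
           interaction_variance = mean(pairs$interaction_variance))
  list(pairs = pairs, aggregate = agg)
}

#' Fixed-genotype mixed-model ANOVA
#'
#' Partitions variation in life span between two genotypes (e.g. an RNAi
#' knockdown and its co-isogenic control) across sexes and temperatures with
#' the model
#' \deqn{Y = \mu + G + S + T + GS + GT + ST + GST + Rep(GT) + S.Rep(GT) + \epsilon}
#' where genotype, sex and temperature are fixed and the replicate-vial terms
#' random.  Reduced models (per sex, per temperature, or both) drop the
#' factors absent from the data slice.
#'
#' Fixed-effect tests are Type-III-style Wald chi-squared tests on the fitted
#' mixed model (each term's coefficients tested jointly against zero, with
#' sum-to-zero contrasts so that main effects are evaluated at the centre of
#' the design); p-values are from the chi-squared distribution.
#'
#' @param data data frame with columns `genotype`, `sex`, `temperature`,
#'   `vial`, and the response.
#' @param response response column name.
#' @param include_vial include the random replicate terms.
#' @return data frame with one row per fixed term: `term`, `chisq`, `df`,
#'   `p`; attribute `"fit"` carries the `merMod` object and attribute
#'   `"components"` the random-effect variances.
#' @examples
#' d <- simulate_rnai_experiment(effect = 8, seed = 1)
#' fixed_effect_anova(d)
#' @export
fixed_effect_anova <- function(data, response = "lifespan_days",
                               include_vial = TRUE) {
  need <- c("genotype", "sex", "temperature", response)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("data is missing required column(s): ", paste(miss, collapse = ", "))
  data <- as.data.frame(data)
  data$genotype <- factor(data$genotype)
  if (nlevels(data$genotype) != 2)
    stop("exactly 2 genotype levels are required (treatment vs control), got ",
         nlevels(data$genotype))
  data$sex <- factor(data$sex)
  data$temperature <- factor(data$temperature)
  n_sex <- nlevels(data$sex)
  n_temp <- nlevels(data$temperature)

  fixed_terms <- "genotype"
  if (n_sex > 1) fixed_terms <- c(fixed_terms, "sex", "genotype:sex")
  if (n_temp > 1) fixed_terms <- c(fixed_terms, "temperature",
                                   "genotype:temperature")
  if (n_sex > 1 && n_temp > 1)
    fixed_terms <- c(fixed_terms, "sex:temperature",
                     "genotype:sex:temperature")
  factors <- c("genotype", if (n_sex > 1) "sex", if (n_temp > 1) "temperature")
  fixed <- paste0("`", response, "` ~ ", paste(factors, collapse = " * "))

  rand <- character(0)
  if (include_vial) {
    if (!"vial" %in% names(data)) stop("data is missing required column(s): vial")
    data$rep_unit <- interaction(data$genotype, data$temperature, data$vial,
                                 drop = TRUE)
    rand <- "(1 | rep_unit)"
    if (n_sex > 1) rand <- c(rand, "(1 | sex:rep_unit)")
  }

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  if (length(rand) > 0) {
    form <- as.formula(paste(fixed, "+", paste(rand, collapse = " + ")))
    fit <- lme4::lmer(form, data = data, REML = TRUE)
    beta <- lme4::fixef(fit)
    Vb <- as.matrix(stats::vcov(fit))
    assign_map <- attr(stats::model.matrix(fit), "assign")
    term_labels <- attr(stats::terms(as.formula(fixed)), "term.labels")
    vcdf <- as.data.frame(lme4::VarCorr(fit))
    comps <- setNames(vcdf$vcov, vcdf$grp)
  } else {
    fit <- lm(as.formula(fixed), data = data)
    beta <- stats::coef(fit)
    Vb <- stats::vcov(fit)
    assign_map <- attr(stats::model.matrix(fit), "assign")
    term_labels <- attr(stats::terms(fit), "term.labels")
    comps <- c(Residual = summary(fit)$sigma^2)
  }

  rows <- lapply(seq_along(term_labels), function(k) {
    j <- which(assign_map == k)
    b <- beta[j]
    W <- tryCatch(drop(t(b) %*% solve(Vb[j, j, drop = FALSE], b)),
                  error = function(e) NA_real_)
    data.frame(term = term_labels[k], chisq = W, df = length(j),
               p = pchisq(W, df = length(j), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fit") <- fit
  attr(out, "components") <- comps
  out
}

#' Panel-level quantitative-genetic report
#'
#' Runs the per-temperature two-sex models, the per-sex cross-temperature
#' models and the full model on a lifespan table and assembles the derived
#' statistics (heritability, CVs, cross-sex and cross-temperature
#' correlations, and the rank/scale decomposition of the interaction
#' variances) in one set of tables.
#'
#' @param data a lifespan table (see [simulate_lifespan_panel()]).
#' @param response response column.
#' @param include_vial passed to [fit_variance_components()].
#' @param lrt compute likelihood-ratio tests (slower).
#' @return list with `per_temperature` (data frame: components, H2, CVs,
#'   r_GMF and the GSI decomposition per temperature), `gsi` and `gei`
#'   decomposition tables, `cross_temperature` (per sex), and `full`
#'   (the full-model `vc_fit` plus r_GST).
#' @export
quantgen_report <- function(data, response = "lifespan_days",
                            include_vial = TRUE, lrt = FALSE) {
  data$temperature <- factor(data$temperature)
  data$sex <- factor(data$sex)
  temps <- levels(data$temperature)
  sexes <- levels(data$sex)

  per_temp <- lapply(temps, function(tt) {
    fit <- fit_variance_components(data[data$temperature == tt, ],
                                   model = "by_temperature",
                                   response = response,
                                   include_vial = include_vial, lrt = lrt)
    dg <- derive_genetics(fit)
    list(fit = fit, derived = dg)
  })
  names(per_temp) <- temps

  per_temp_df <- do.call(rbind, lapply(temps, function(tt) {
    x <- per_temp[[tt]]
    data.frame(temperature = tt,
               mean_F = unname(x$fit$means[1]), mean_M = unname(x$fit$means[2]),
               sigma2_L = unname(x$fit$components["sigma2_L"]),
               sigma2_LS = unname(x$fit$components["sigma2_LS"]),
               sigma2_G = x$derived$sigma2_G,
               sigma2_eps = unname(x$fit$components["sigma2_eps"]),
               sigma2_P = x$derived$sigma2_P,
               H2 = x$derived$H2, CV_G = x$derived$CV_G,
               CV_eps = x$derived$CV_eps, r_GMF = x$derived$r_GMF,
               stringsAsFactors = FALSE)
  }))

  # GSI decomposition per temperature: sex-specific genetic SDs from
  # per-sex-within-temperature models
  gsi <- do.call(rbind, lapply(temps, function(tt) {
    s2 <- vapply(sexes, function(ss) {
      f <- fit_variance_components(
        data[data$temperature == tt & data$sex == ss, ],
        model = "within", response = response,
        include_vial = include_vial, lrt = FALSE)
      unname(f$components["sigma2_L"])
    }, numeric(1))
    r <- per_temp_df$r_GMF[per_temp_df$temperature == tt]
    cbind(temperature = tt,
          decompose_interaction(sqrt(s2[1]), sqrt(s2[2]), r,
                                label_a = sexes[1], label_b = sexes[2]))
  }))

  # cross-temperature models per sex
  cross_temp <- lapply(sexes, function(ss) {
    pairs <- utils::combn(temps, 2, simplify = FALSE)
    do.call(rbind, lapply(pairs, function(pr) {
      sub <- data[data$sex == ss & data$temperature %in% pr, ]
      sub$temperature <- droplevels(sub$temperature)
      fit <- fit_variance_components(sub, model = "by_sex",
                                     response = response,
                                     include_vial = include_vial, lrt = lrt)
      r <- derive_genetics(fit)$r_GT
      s2 <- vapply(pr, function(tt) {
        f <- fit_variance_components(
          data[data$temperature == tt & data$sex == ss, ],
          model = "within", response = response,
          include_vial = include_vial, lrt = FALSE)
        unname(f$components["sigma2_L"])
      }, numeric(1))
      cbind(sex = ss,
            decompose_interaction(sqrt(s2[1]), sqrt(s2[2]), r,
                                  label_a = pr[1], label_b = pr[2]))
    }))
  })
  names(cross_temp) <- sexes

  full <- fit_variance_components(data, model = "full", response = response,
                                  include_vial = include_vial, lrt = lrt)
  full_dg <- derive_genetics(full)

  list(per_temperature = per_temp_df, gsi = gsi,
       cross_temperature = cross_temp,
       full = list(fit = full, derived = full_dg))
}
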