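#' Design of a replicated inbred-line lifespan panel
#'
#' Describes the dimensions of a DGRP-style lifespan experiment: inbred lines
#' reared in replicate vials at several temperatures, with both sexes housed
#' together (3 flies per sex per vial in the reference design, giving
#' 72 flies/sex/line/temperature from 24 vials).  Whole line-by-temperature
#' cells can be dropped to emulate poor viability of some lines at extreme
#' temperatures.
#'
#' @param n_lines number of inbred lines.
#' @param temperatures character vector of temperature labels.
#' @param sexes two sex labels.
#' @param vials_per_line_per_temp replicate vials per line and temperature.
#' @param flies_per_sex_per_vial flies of each sex per vial.
#' @param missing_line_fraction_per_temp named numeric vector (one entry per
#'   temperature) giving the fraction of lines whose whole cell is dropped at
#'   that temperature.  The default mirrors the reference panel, where 3 of
#'   186 lines failed at 18 C and 9 of 186 at 28 C.
#' @return list of class `panel_design`.
#' @export
panel_design <- function(n_lines = 186,
                         temperatures = c("18", "25", "28"),
                         sexes = c("F", "M"),
                         vials_per_line_per_temp = 24,
                         flies_per_sex_per_vial = 3,
                         missing_line_fraction_per_temp = NULL) {
  stopifnot(n_lines >= 1, vials_per_line_per_temp >= 1,
            flies_per_sex_per_vial >= 1, length(sexes) == 2)
  if (is.null(missing_line_fraction_per_temp)) {
    missing_line_fraction_per_temp <- setNames(rep(0, length(temperatures)),
                                               temperatures)
    if (all(c("18", "28") %in% temperatures)) {
      missing_line_fraction_per_temp["18"] <- 3 / 186
      missing_line_fraction_per_temp["28"] <- 9 / 186
    }
  }
  if (is.null(names(missing_line_fraction_per_temp)))
    names(missing_line_fraction_per_temp) <- temperatures
  if (any(missing_line_fraction_per_temp < 0 |
          missing_line_fraction_per_temp > 1))
    stop("missing_line_fraction_per_temp must be in [0, 1]")
  structure(list(n_lines = as.integer(n_lines),
                 temperatures = as.character(temperatures),
                 sexes = as.character(sexes),
                 vials_per_line_per_temp = as.integer(vials_per_line_per_temp),
                 flies_per_sex_per_vial = as.integer(flies_per_sex_per_vial),
                 missing_line_fraction_per_temp =
                   missing_line_fraction_per_temp),
            class = "panel_design")
}

#' Generative variance structure of a lifespan panel
#'
#' Holds the "true" parameters of the synthetic lifespan generator: the
#' grand means per sex and temperature, the standard deviations of the
#' random line, line-by-sex, line-by-temperature, line-by-sex-by-temperature
#' and vial effects, and a log-normal model of the line-specific residual
#' standard deviation that makes the micro-environmental variance itself
#' heritable.  A fly's residual SD is
#' \deqn{\exp(\mu_{\ln\sigma}[s,t] + a_{line} + b_{line\times sex} + c_{line\times temp})}
#' so the between-line spread of the log residual SD is directly comparable
#' to an \eqn{\ln\sigma_\epsilon} analysis.
#'
#' The defaults are calibrated to the reference panel: sex-by-temperature
#' means of 77.9/85.0 (18 C), 41.6/44.2 (25 C) and 27.2/26.8 (28 C) days;
#' genetic components such that a single-temperature analysis recovers an
#' among-line variance of about 68 days^2 and a line-by-sex variance of about
#' 29 days^2 at 25 C with cross-sex correlation ~0.70, cross-temperature
#' correlation ~0.44 and overall cross-context correlation ~0.31; and
#' per-context mean log residual SDs of about 3.2, 2.45 and 2.14 (i.e.
#' residual variances of roughly 690, 134 and 73 days^2).
#'
#' @param means matrix (sexes x temperatures) of mean life spans in days.
#' @param sigma_L,sigma_LS,sigma_LT,sigma_LST,sigma_vial standard deviations
#'   (days) of the random effects.
#' @param logsd_mean matrix (sexes x temperatures) of mean log residual SD.
#' @param logsd_line,logsd_line_sex,logsd_line_temp SDs of the line-level
#'   log-residual-SD effects (dimensionless, log scale).
#' @param floor lower truncation for simulated life spans (days); values
#'   below it are set to the floor.
#' @return list of class `true_components`.
#' @export
true_components <- function(means = rbind(F = c(`18` = 77.86, `25` = 41.60,
                                                `28` = 27.15),
                                          M = c(`18` = 84.97, `25` = 44.17,
                                                `28` = 26.77)),
                            sigma_L = sqrt(30),
                            sigma_LS = sqrt(13),
                            sigma_LT = sqrt(38.1),
                            sigma_LST = sqrt(15.8),
                            sigma_vial = 2,
                            logsd_mean = rbind(F = c(`18` = 3.22, `25` = 2.45,
                                                     `28` = 2.16),
                                               M = c(`18` = 3.27, `25` = 2.44,
                                                     `28` = 2.12)),
                            logsd_line = 0.23,
                            logsd_line_sex = 0.12,
                            logsd_line_temp = 0.20,
                            floor = 1) {
  sds <- c(sigma_L, sigma_LS, sigma_LT, sigma_LST, sigma_vial,
           logsd_line, logsd_line_sex, logsd_line_temp)
  if (any(sds < 0)) stop("standard deviations must be non-negative")
  if (floor < 0) stop("truncation floor must be non-negative")
  structure(list(means = means, sigma_L = sigma_L, sigma_LS = sigma_LS,
                 sigma_LT = sigma_LT, sigma_LST = sigma_LST,
                 sigma_vial = sigma_vial, logsd_mean = logsd_mean,
                 logsd_line = logsd_line, logsd_line_sex = logsd_line_sex,
                 logsd_line_temp = logsd_line_temp, floor = floor),
            class = "true_components")
}

#' Simulate a replicated inbred-line lifespan panel
#'
#' Draws one life span record per fly under the generative counterpart of
#' the cross-classified mixed model: life span = context mean + line +
#' line-by-sex + line-by-temperature + line-by-sex-by-temperature + vial +
#' residual, with the residual SD line-specific on the log scale (see
#' [true_components()]).  Values below the truncation floor are set to the
#' floor.  The same seed always yields the identical table.
#'
#' @param design a [panel_design()].
#' @param components a [true_components()]; its `means` and `logsd_mean`
#'   matrices must cover the design's sexes and temperatures (a single
#'   scalar is recycled).
#' @param seed integer seed.
#' @return data frame with columns `line`, `sex`, `temperature`, `vial`,
#'   `lifespan_days`.
#' @examples
#' d <- simulate_lifespan_panel(panel_design(n_lines = 5), true_components(),
#'                              seed = 42)
#' nrow(d)
#' @export
simulate_lifespan_panel <- function(design, components, seed) {
  stopifnot(inherits(design, "panel_design"),
            inherits(components, "true_components"))
  set.seed(seed)
  sexes <- design$sexes
  temps <- design$temperatures
  nl <- design$n_lines
  nv <- design$vials_per_line_per_temp
  nf <- design$flies_per_sex_per_vial
  lines <- sprintf("line_%03d", seq_len(nl))

  get_cell <- function(mat, s, t) {
    if (length(mat) == 1) return(as.numeric(mat))
    if (is.matrix(mat)) {
      si <- if (s %in% rownames(mat)) s else match(s, sexes)
      ti <- if (t %in% colnames(mat)) t else match(t, temps)
      return(mat[si, ti])
    }
    as.numeric(mat)
  }

  # line-level random effects, drawn once
  eff_L <- rnorm(nl, 0, components$sigma_L)
  eff_LS <- matrix(rnorm(nl * 2, 0, components$sigma_LS), nl, 2,
                   dimnames = list(NULL, sexes))
  eff_LT <- matrix(rnorm(nl * length(temps), 0, components$sigma_LT), nl,
                   length(temps), dimnames = list(NULL, temps))
  eff_LST <- array(rnorm(nl * 2 * length(temps), 0, components$sigma_LST),
                   dim = c(nl, 2, length(temps)),
                   dimnames = list(NULL, sexes, temps))
  lsd_L <- rnorm(nl, 0, components$logsd_line)
  lsd_LS <- matrix(rnorm(nl * 2, 0, components$logsd_line_sex), nl, 2,
                   dimnames = list(NULL, sexes))
  lsd_LT <- matrix(rnorm(nl * length(temps), 0, components$logsd_line_temp),
                   nl, length(temps), dimnames = list(NULL, temps))

  # whole-cell missingness per temperature
  present <- matrix(TRUE, nl, length(temps), dimnames = list(NULL, temps))
  for (t in temps) {
    fr <- components_missing_fraction(design, t)
    n_drop <- round(fr * nl)
    if (n_drop > 0) present[sample.int(nl, n_drop), t] <- FALSE
  }

  blocks <- list()
  for (t in temps) {
    keep <- which(present[, t])
    if (length(keep) == 0) next
    # vial effects shared by the two sexes housed in the same vial
    vial_eff <- matrix(rnorm(length(keep) * nv, 0, components$sigma_vial),
                       length(keep), nv)
    for (s in sexes) {
      mu <- get_cell(components$means, s, t)
      lmu <- get_cell(components$logsd_mean, s, t)
      n_per_line <- nv * nf
      li <- rep(keep, each = n_per_line)
      vi <- rep(rep(seq_len(nv), each = nf), times = length(keep))
      gmean <- mu + eff_L[li] + eff_LS[li, s] + eff_LT[li, t] +
        eff_LST[cbind(li, match(s, sexes), match(t, temps))] +
        vial_eff[cbind(match(li, keep), vi)]
      res_sd <- exp(lmu + lsd_L[li] + lsd_LS[li, s] + lsd_LT[li, t])
      y <- gmean + rnorm(length(li), 0, res_sd)
      y <- pmax(y, components$floor)
      blocks[[length(blocks) + 1]] <-
        data.frame(line = lines[li], sex = s, temperature = t, vial = vi,
                   lifespan_days = y, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

components_missing_fraction <- function(design, t) {
  fr <- design$missing_line_fraction_per_temp
  if (t %in% names(fr)) unname(fr[t]) else 0
}

#' Simulate a two-genotype knockdown lifespan assay
#'
#' Generates a lifespan data set for one RNAi-style contrast: two genotypes
#' (treatment and co-isogenic control) by two sexes by `temperatures`, with
#' replicate vials.  Used to exercise [fixed_effect_anova()].
#'
#' @param effect genotype main effect in days (treatment minus control);
#'   `effect_sex` adds a further shift applied to females only (a
#'   genotype-by-sex interaction).
#' @param effect_sex female-specific additional genotype effect (days).
#' @param n_vials replicate vials per genotype and temperature.
#' @param flies_per_sex_per_vial flies of each sex per vial.
#' @param temperatures temperature labels.
#' @param mean control mean life span (days).
#' @param sigma_vial,sigma_eps vial-effect and residual SDs (days).
#' @param seed integer seed.
#' @return data frame with `genotype`, `sex`, `temperature`, `vial`,
#'   `lifespan_days`.
#' @export
simulate_rnai_experiment <- function(effect = 0, effect_sex = 0,
                                     n_vials = 48,
                                     flies_per_sex_per_vial = 3,
                                     temperatures = c("18", "25", "28"),
                                     mean = 45, sigma_vial = 2,
                                     sigma_eps = 10, seed) {
  set.seed(seed)
  blocks <- list()
  for (g in c("control", "treatment")) {
    for (t in temperatures) {
      vial_eff <- rnorm(n_vials, 0, sigma_vial)
      for (s in c("F", "M")) {
        n <- n_vials * flies_per_sex_per_vial
        vi <- rep(seq_len(n_vials), each = flies_per_sex_per_vial)
        mu <- mean + (g == "treatment") * effect +
          (g == "treatment") * (s == "F") * effect_sex
        y <- mu + vial_eff[vi] + rnorm(n, 0, sigma_eps)
        blocks[[length(blocks) + 1]] <-
          data.frame(genotype = g, sex = s, temperature = t, vial = vi,
                     lifespan_days = pmax(y, 1), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
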