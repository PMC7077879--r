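test_that("REML matches the closed-form ANOVA estimator on a balanced one-way layout", {
  set.seed(21)
  k <- 40; n <- 10
  line <- rep(sprintf("l%02d", 1:k), each = n)
  y <- rep(rnorm(k, 0, 6), each = n) + rnorm(k * n, 0, 4) + 50
  d <- data.frame(line = line, sex = "F", temperature = "25",
                  lifespan_days = y)
  fit <- fit_variance_components(d, model = "within", include_vial = FALSE,
                                 lrt = FALSE)
  oracle <- moments_one_way(y, line)
  expect_gt(oracle["sigma2_L"], 0)  # oracle applies when interior
  expect_equal(unname(fit$components["sigma2_L"]),
               unname(oracle["sigma2_L"]), tolerance = 1e-6)
  expect_equal(unname(fit$components["sigma2_eps"]),
               unname(oracle["sigma2_eps"]), tolerance = 1e-6)
})

test_that("a constant response gives a degenerate all-zero fit", {
  d <- data.frame(line = rep(c("a", "b"), each = 4), sex = "F",
                  temperature = "25", lifespan_days = 40)
  fit <- fit_variance_components(d, model = "within", include_vial = FALSE)
  expect_true(fit$degenerate)
  expect_true(all(fit$components == 0))
})

test_that("null genetic variance is estimated at the boundary most of the time", {
  hits <- 0
  for (i in 1:40) {
    set.seed(100 + i)
    d <- data.frame(line = rep(sprintf("l%02d", 1:15), each = 6),
                    sex = "F", temperature = "25",
                    lifespan_days = rnorm(90, 50, 5))
    fit <- fit_variance_components(d, model = "within",
                                   include_vial = FALSE, lrt = FALSE)
    if (fit$components["sigma2_L"] < 1e-6) hits <- hits + 1
  }
  # ~50% of REML estimates sit at the zero boundary under the null;
  # require clear evidence of boundary behaviour
  expect_gt(hits, 10)
})

test_that("derived statistics reproduce the printed panel parameters", {
  # life span at 18C
  dg <- derive_genetics(c(sigma2_L = 354.38, sigma2_LS = 84.98,
                          sigma2_eps = 689.24),
                        means = c(F = 77.86, M = 84.97))
  expect_equal(round(dg$H2, 2), 0.39)
  expect_equal(round(dg$CV_G, 2), 25.75)
  expect_equal(round(dg$CV_eps, 2), 32.25)

  # life span at 25C
  dg25 <- derive_genetics(c(sigma2_L = 68.14, sigma2_LS = 28.77,
                            sigma2_eps = 133.77),
                          means = c(F = 41.60, M = 44.17))
  expect_equal(round(dg25$H2, 2), 0.42)
  expect_equal(round(dg25$CV_G, 2), 22.96)
  expect_equal(round(dg25$r_GMF, 2), 0.70)

  # micro-environmental variability block, 18C and 25C
  dgm <- derive_genetics(c(sigma2_L = 0.0531, sigma2_LS = 0.0210,
                           sigma2_eps = 0.0268),
                         means = c(F = 3.22, M = 3.27))
  expect_equal(round(dgm$H2, 2), 0.73)
  dgm25 <- derive_genetics(c(sigma2_L = 0.0553, sigma2_LS = 0.0132,
                             sigma2_eps = 0.0354))
  expect_equal(round(dgm25$r_GMF, 3), 0.807)
})

test_that("cross-context correlations behave at the edges", {
  expect_equal(derive_genetics(c(sigma2_L = 5, sigma2_LS = 0,
                                 sigma2_eps = 1))$r_GMF, 1)
  dg <- derive_genetics(c(sigma2_L = 0, sigma2_LS = 0, sigma2_eps = 1))
  expect_true(is.nan(dg$r_GMF))
  expect_error(derive_genetics(c(sigma2_L = -1, sigma2_eps = 1)),
               "non-negative")
})

test_that("interaction decomposition reproduces the printed GSI/GEI terms", {
  # sex-by-line, life span 18C (printed to 2 decimals; the input r to 3)
  d1 <- decompose_interaction(20.51, 21.40, 0.806)
  expect_lt(abs(d1$rank_term - 85.14), 0.02)
  expect_lt(abs(d1$scale_term - 0.39), 0.01)
  expect_lt(abs(d1$pct_rank - 99.5), 0.06)

  # temperature-by-line, female 25C/28C
  d2 <- decompose_interaction(9.47, 6.41, 0.487)
  expect_lt(abs(d2$rank_term - 31.14), 0.02)
  expect_lt(abs(d2$scale_term - 4.68), 0.01)
  expect_lt(abs(d2$pct_rank - 86.9), 0.1)

  # female 18C/25C
  d3 <- decompose_interaction(20.51, 9.47, 0.384)
  expect_lt(abs(d3$rank_term - 119.65), 0.02)
  expect_lt(abs(d3$scale_term - 60.94), 0.02)
  expect_lt(abs(d3$pct_rank - 66.3), 0.1)
})

test_that("decomposition handles the degenerate equal-scale, r = 1 case", {
  d <- decompose_interaction(3, 3, 1)
  expect_equal(d$rank_term, 0)
  expect_equal(d$scale_term, 0)
  expect_true(is.na(d$pct_rank))
})

test_that("rank + scale equals the interaction variance identity exactly", {
  set.seed(33)
  for (i in 1:200) {
    sa <- runif(1, 0, 30); sb <- runif(1, 0, 30); r <- runif(1, -1, 1)
    d <- decompose_interaction(sa, sb, r)
    expect_equal(d$rank_term + d$scale_term,
                 (sa^2 + sb^2) / 2 - r * sa * sb, tolerance = 1e-12)
  }
})

test_that("multi-context aggregate averages the pairwise terms", {
  sig <- c(`18` = 20.51, `25` = 9.47, `28` = 6.41)
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.384
  r[1, 3] <- r[3, 1] <- 0.206
  r[2, 3] <- r[3, 2] <- 0.487
  agg <- decompose_interaction_multi(sig, r)
  expect_equal(nrow(agg$pairs), 3)
  expect_equal(unname(agg$aggregate["rank_term"]),
               mean(agg$pairs$rank_term))
  expect_equal(unname(agg$aggregate["interaction_variance"]),
               mean(agg$pairs$interaction_variance))
})

test_that("H2 and correlations are location-invariant; CVs rescale correctly", {
  d <- small_panel(n_lines = 15, vials = 4, seed = 41, temps = "25")
  d25 <- d[d$temperature == "25", ]
  f1 <- fit_variance_components(d25, model = "by_temperature", lrt = FALSE)
  d_shift <- d25
  d_shift$lifespan_days <- d_shift$lifespan_days + 100
  f2 <- fit_variance_components(d_shift, model = "by_temperature", lrt = FALSE)
  g1 <- derive_genetics(f1); g2 <- derive_genetics(f2)
  expect_equal(g1$H2, g2$H2, tolerance = 1e-4)
  expect_equal(g1$r_GMF, g2$r_GMF, tolerance = 1e-4)

  d_scale <- d25
  d_scale$lifespan_days <- d_scale$lifespan_days * 2
  f3 <- fit_variance_components(d_scale, model = "by_temperature", lrt = FALSE)
  g3 <- derive_genetics(f3)
  # doubling the trait doubles sigma and the mean: CVs unchanged
  expect_equal(g1$CV_G, g3$CV_G, tolerance = 1e-3)
  expect_equal(g1$CV_eps, g3$CV_eps, tolerance = 1e-3)
})

test_that("fixed-genotype ANOVA detects planted effects with the right structure", {
  d <- simulate_rnai_experiment(effect = 8, n_vials = 24, sigma_eps = 5,
                                seed = 51)
  tab <- fixed_effect_anova(d)
  expect_lt(tab$p[tab$term == "genotype"], 1e-3)

  # female-only effect: genotype-by-sex interaction detected
  d2 <- simulate_rnai_experiment(effect = 0, effect_sex = 6, n_vials = 24,
                                 sigma_eps = 4, seed = 52)
  tab2 <- fixed_effect_anova(d2)
  expect_lt(tab2$p[tab2$term == "genotype:sex"], 1e-3)
  # sign of the sex-specific contrast matches the construction
  mns <- tapply(d2$lifespan_days, list(d2$genotype, d2$sex), mean)
  expect_gt((mns["treatment", "F"] - mns["control", "F"]) -
              (mns["treatment", "M"] - mns["control", "M"]), 0)

  expect_error(fixed_effect_anova(transform(d, genotype = "control")),
               "2 genotype levels")
})

test_that("genotype F p-values are uniform under the null", {
  ps <- vapply(1:60, function(i) {
    d <- simulate_rnai_experiment(effect = 0, n_vials = 6,
                                  temperatures = "25", sigma_eps = 6,
                                  seed = 600 + i)
    tab <- fixed_effect_anova(d)
    tab$p[tab$term == "genotype"]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
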