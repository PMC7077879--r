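test_that("derived phenotypes follow the stated orientation conventions", {
  d <- data.frame(line = "l1",
                  sex = rep(c("F", "M"), each = 2),
                  temperature = "25",
                  lifespan_days = c(10, 10, 12, 12))
  ph <- derive_phenotypes(d)
  expect_equal(ph$F_25, 10)
  expect_equal(ph$M_25, 12)
  expect_equal(ph$avg_25, 11)
  expect_equal(ph$sexdiff_25, 2)  # male minus female
})

test_that("temperature differences are oriented higher minus lower and propagate missingness", {
  d <- expand.grid(line = c("l1", "l2"), sex = c("F", "M"),
                   temperature = c("18", "25"), stringsAsFactors = FALSE)
  d$lifespan_days <- c(80, 70, 85, 75,   # 18C: l1, l2 x F, M
                       40, 35, 45, 38)   # 25C
  d <- d[!(d$line == "l2" & d$temperature == "18"), ]  # l2 missing at 18C
  ph <- derive_phenotypes(d)
  i1 <- ph$line == "l1"
  expect_equal(ph$F_25m18[i1], 40 - 80)
  expect_equal(ph$sexdiff_25m18[i1], (45 - 85) - (40 - 80))
  i2 <- ph$line == "l2"
  expect_true(is.na(ph$F_25m18[i2]))
  expect_true(is.na(ph$sexdiff_18[i2]))
  expect_false(is.na(ph$F_25[i2]))
})

test_that("sex-difference phenotype variance is ~2x the line-by-sex variance", {
  comp <- true_components(means = 40, sigma_L = 0, sigma_LS = 4,
                          sigma_LT = 0, sigma_LST = 0, sigma_vial = 0,
                          logsd_mean = log(3), logsd_line = 0,
                          logsd_line_sex = 0, logsd_line_temp = 0, floor = 0)
  d <- simulate_lifespan_panel(
    panel_design(n_lines = 400, temperatures = "25",
                 vials_per_line_per_temp = 24,
                 missing_line_fraction_per_temp = c(`25` = 0)),
    comp, seed = 71)
  ph <- derive_phenotypes(d)
  # var(M - F) = 2 sigma2_LS + 2 var(line-mean noise)
  noise <- 2 * 3^2 / 72
  expect_equal(var(ph$sexdiff_25), 2 * 16 + noise, tolerance = 0.15 * 32)
})

test_that("marker scan filters on MAF and recovers a constructed signal", {
  gl <- simulate_line_genotypes(60, 50, maf_spec = c(0.2, 0.5), seed = 72)
  dos <- gl$dosage
  # force one variant below the MAF threshold
  dos[, 1] <- 0; dos[1:2, 1] <- 2  # MAF 2/60 = 0.033
  y <- setNames(dos[, 7] * 1.0, rownames(dos))  # phenotype == dosage
  sc <- marker_scan(y, dos, maf_min = 0.05)
  expect_false("v00001" %in% sc$variant_id)
  row <- sc[sc$variant_id == "v00007", ]
  expect_equal(row$effect, 1.0, tolerance = 1e-10)
  expect_lt(row$p, 1e-200)
})

test_that("effects are reported per minor allele", {
  set.seed(73)
  dos <- matrix(sample(c(0, 2), 200, replace = TRUE, prob = c(0.2, 0.8)),
                100, 2, dimnames = list(sprintf("l%03d", 1:100),
                                        c("v1", "v2")))
  # alt allele is the major allele for v1 (freq 0.8): scan flips orientation
  y <- setNames(dos[, 1] * 0.5 + rnorm(100, 0, 0.1), rownames(dos))
  sc <- marker_scan(y, dos, maf_min = 0.01)
  expect_lt(sc$effect[sc$variant_id == "v1"], 0)  # minor allele lowers y
})

test_that("p-values are uniform when the phenotype is permuted", {
  gl <- simulate_line_genotypes(80, 3000, maf_spec = c(0.1, 0.5), seed = 74)
  set.seed(75)
  y <- setNames(rnorm(80), rownames(gl$dosage))
  sc <- marker_scan(y, gl$dosage)
  ks <- suppressWarnings(stats::ks.test(sc$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("covariate residualization removes a confounded signal", {
  set.seed(76)
  n <- 80
  wolb <- rep(c("y", "n"), each = n / 2)
  dos <- matrix(ifelse(runif(n) < ifelse(wolb == "y", 0.8, 0.2), 2, 0),
                n, 1, dimnames = list(sprintf("l%03d", 1:n), "v1"))
  y <- setNames(10 * (wolb == "y") + rnorm(n, 0, 0.5), rownames(dos))
  cv <- data.frame(wolbachia = wolb, row.names = rownames(dos))
  sc_raw <- marker_scan(y, dos, maf_min = 0.01)
  sc_adj <- marker_scan(y, dos, covariates = cv, maf_min = 0.01)
  expect_lt(sc_raw$p, 1e-6)       # confounded signal
  expect_gt(sc_adj$p, 1e-4)       # gone after adjustment
})

test_that("scan statistics are equivariant under phenotype shift and scale", {
  gl <- simulate_line_genotypes(50, 30, seed = 77)
  set.seed(78)
  y <- setNames(rnorm(50, 40, 5), rownames(gl$dosage))
  a <- marker_scan(y, gl$dosage)
  b <- marker_scan(y + 100, gl$dosage)
  c <- marker_scan(y * 2, gl$dosage)
  expect_equal(a$effect, b$effect, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)
  expect_equal(2 * a$effect, c$effect, tolerance = 1e-10)
  expect_equal(a$p, c$p, tolerance = 1e-10)
})

test_that("planted additive variants are recovered with correct signs", {
  gl <- simulate_line_genotypes(186, 400, maf_spec = c(0.1, 0.5), seed = 79)
  set.seed(80)
  causal <- sample(400, 5)
  beta <- c(1, 1, 1, -1, -1)  # in units of the residual SD below
  y <- drop(gl$dosage[, causal] %*% beta) + rnorm(186, 0, 1.2)
  names(y) <- rownames(gl$dosage)
  sc <- marker_scan(y, gl$dosage, report_p = 1e-5)
  hit <- sc[sc$variant_id %in% colnames(gl$dosage)[causal] & sc$reported, ]
  expect_gte(nrow(hit), 4)  # >= 80% power at this effect size
  # orientation: dosage columns are already minor-allele coded (maf <= 0.5),
  # so recovered effect signs match the planted ones
  planted <- setNames(beta, colnames(gl$dosage)[causal])
  expect_true(all(sign(hit$effect) == sign(planted[hit$variant_id])))
})

test_that("variants are classified by cross-context significance pattern", {
  mk <- function(eff, p) data.frame(variant_id = c("a", "b", "c"),
                                    effect = eff, p = p,
                                    reported = p < 1e-5)
  s1 <- mk(c(2, 1.5, 0.1), c(1e-8, 1e-7, 0.5))
  s2 <- mk(c(-3, 1.2, 0.2), c(1e-9, 1e-6, 0.4))
  cl <- classify_effects(list(f = s1, m = s2))
  vc <- cl$variant_class
  expect_equal(vc$class[vc$variant_id == "a"], "antagonistic")
  expect_equal(vc$class[vc$variant_id == "b"], "concordant")
  expect_equal(vc$class[vc$variant_id == "c"], "not_significant")
})

test_that("sign-flipped causal architecture yields negative cross-sex effect correlation", {
  gl <- simulate_line_genotypes(150, 60, maf_spec = c(0.2, 0.5), seed = 81)
  set.seed(82)
  beta_f <- rnorm(60, 0, 1)
  beta_m <- -beta_f  # fully antagonistic
  yf <- drop(gl$dosage %*% beta_f) + rnorm(150, 0, 2)
  ym <- drop(gl$dosage %*% beta_m) + rnorm(150, 0, 2)
  names(yf) <- names(ym) <- rownames(gl$dosage)
  sf <- marker_scan(yf, gl$dosage)
  sm <- marker_scan(ym, gl$dosage)
  cl <- classify_effects(list(f = sf, m = sm))
  expect_lt(cl$effect_correlation["f", "m"], -0.3)
})
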