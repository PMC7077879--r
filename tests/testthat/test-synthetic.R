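test_that("degenerate generator returns the context mean everywhere", {
  comp <- true_components(means = 40, sigma_L = 0, sigma_LS = 0,
                          sigma_LT = 0, sigma_LST = 0, sigma_vial = 0,
                          logsd_mean = -Inf, logsd_line = 0,
                          logsd_line_sex = 0, logsd_line_temp = 0)
  d <- simulate_lifespan_panel(
    panel_design(n_lines = 3, vials_per_line_per_temp = 2,
                 missing_line_fraction_per_temp = c(`18` = 0, `25` = 0,
                                                    `28` = 0)),
    comp, seed = 1)
  expect_true(all(d$lifespan_days == 40))
})

test_that("reference design yields 72 records per sex, line and temperature", {
  d <- simulate_lifespan_panel(
    panel_design(n_lines = 4, vials_per_line_per_temp = 24,
                 flies_per_sex_per_vial = 3,
                 missing_line_fraction_per_temp = c(`18` = 0, `25` = 0,
                                                    `28` = 0)),
    true_components(), seed = 2)
  counts <- table(d$line, d$sex, d$temperature)
  expect_true(all(counts == 72))
})

test_that("whole line-by-temperature cells are dropped per the missing fractions", {
  d <- simulate_lifespan_panel(
    panel_design(n_lines = 20, vials_per_line_per_temp = 2,
                 missing_line_fraction_per_temp = c(`18` = 0.25, `25` = 0,
                                                    `28` = 0.5)),
    true_components(), seed = 3)
  n_lines <- tapply(d$line, d$temperature, function(x) length(unique(x)))
  expect_equal(as.vector(n_lines[c("18", "25", "28")]), c(15, 20, 10))
})

test_that("identical seeds give identical panels, different seeds differ", {
  des <- panel_design(n_lines = 5, vials_per_line_per_temp = 3)
  a <- simulate_lifespan_panel(des, true_components(), seed = 7)
  b <- simulate_lifespan_panel(des, true_components(), seed = 7)
  c <- simulate_lifespan_panel(des, true_components(), seed = 8)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("life spans never fall below the truncation floor", {
  comp <- true_components(means = 5, floor = 1)
  d <- simulate_lifespan_panel(panel_design(n_lines = 10), comp, seed = 4)
  expect_true(all(d$lifespan_days >= 1))
  expect_true(any(d$lifespan_days == 1))  # truncation actually binds at mean 5
})

test_that("moment-matching: among-line variance is recovered on a one-way layout", {
  # pure line + residual generator, method-of-moments oracle
  # mean far above the floor so truncation never distorts the moments
  comp <- true_components(means = 300, sigma_L = 20, sigma_LS = 0,
                          sigma_LT = 0, sigma_LST = 0, sigma_vial = 0,
                          logsd_mean = log(26), logsd_line = 0,
                          logsd_line_sex = 0, logsd_line_temp = 0,
                          floor = 0)
  d <- simulate_lifespan_panel(
    panel_design(n_lines = 500, temperatures = "25",
                 vials_per_line_per_temp = 8,
                 missing_line_fraction_per_temp = c(`25` = 0)),
    comp, seed = 5)
  sub <- d[d$sex == "F", ]
  est <- moments_one_way(sub$lifespan_days, sub$line)
  expect_lt(abs(est["sigma2_L"] - 400) / 400, 0.15)
  expect_lt(abs(est["sigma2_eps"] - 676) / 676, 0.15)
})

test_that("founder panels segregate and honour the frequency spectrum", {
  fp <- simulate_founder_genotypes(40, 1000, seed = 1)
  expect_true(all(fp$freq > 0 & fp$freq < 1))
  expect_equal(dim(fp$haplotypes), c(40, 1000))

  # point mass 0.5 with 2 founders: exactly one carrier per variant
  fp2 <- simulate_founder_genotypes(2, 50, maf_spec = 0.5, seed = 2)
  expect_true(all(colSums(fp2$haplotypes) == 1))

  expect_error(simulate_founder_genotypes(1, 10, seed = 1), "n_founders")
})

test_that("realized founder frequencies follow a uniform maf spectrum", {
  fp <- simulate_founder_genotypes(200, 10000, maf_spec = c(0.05, 0.5),
                                   seed = 3)
  # with 200 founders the realized frequency is close to the drawn one;
  # compare the realized histogram with the uniform(0.05, 0.5) density
  h <- hist(fp$freq, breaks = seq(0, 1, 0.05), plot = FALSE)
  inside <- h$mids > 0.075 & h$mids < 0.475
  expected <- 10000 * 0.05 / 0.45
  expect_true(all(abs(h$counts[inside] - expected) / expected < 0.15))
})

test_that("cohort life spans respond to planted effects as constructed", {
  fp <- simulate_founder_genotypes(40, 50, seed = 4)
  eff <- data.frame(variant_id = "v00010", effect = 10)
  spec <- aip_cohort_spec(sexes = "F", temperatures = "25", replicates = 1,
                          effects = eff, sigma_env = 5)
  cohort <- simulate_aip_cohort(fp, spec, seed = 5)
  ctx <- cohort$contexts[[1]]
  dos <- ctx$genotypes[, 10]
  m2 <- mean(ctx$lifespan[dos == 2])
  m0 <- mean(ctx$lifespan[dos == 0])
  expect_lt(abs((m2 - m0) - 20), 3)
})

test_that("sex-antagonistic effects flip the dosage slope between sexes", {
  fp <- simulate_founder_genotypes(40, 20, seed = 6)
  eff <- data.frame(variant_id = c("v00003", "v00003"),
                    effect = c(5, -5), sex = c("F", "M"),
                    temperature = NA)
  spec <- aip_cohort_spec(sexes = c("F", "M"), temperatures = "25",
                          replicates = 1, effects = eff, sigma_env = 5)
  cohort <- simulate_aip_cohort(fp, spec, seed = 7)
  slope <- vapply(cohort$contexts, function(ctx)
    coef(lm(ctx$lifespan ~ ctx$genotypes[, 3]))[2], numeric(1))
  expect_gt(slope[1], 0)  # female cohort
  expect_lt(slope[2], 0)  # male cohort
})

test_that("unknown variant ids in the effect model are rejected", {
  fp <- simulate_founder_genotypes(10, 5, seed = 8)
  spec <- aip_cohort_spec(sexes = "F", temperatures = "25", replicates = 1,
                          effects = data.frame(variant_id = "nope",
                                               effect = 1))
  expect_error(simulate_aip_cohort(fp, spec, seed = 1), "unknown variant")
})

test_that("pool sequencing respects the coverage range and selection direction", {
  fp <- simulate_founder_genotypes(40, 100, seed = 9)
  eff <- data.frame(variant_id = "v00001", effect = 15)
  spec <- aip_cohort_spec(sexes = "F", temperatures = "25",
                          effects = eff, sigma_env = 8)
  cohort <- simulate_aip_cohort(fp, spec, seed = 10)
  counts <- pool_select_and_sequence(cohort, seed = 11)
  depth <- counts$ref_reads + counts$alt_reads
  expect_true(all(depth >= 130 & depth <= 156))

  # large positive effect: alt frequency higher in H than C in both reps
  for (r in 1:2) {
    sub <- counts[counts$variant_id == "v00001" & counts$replicate == r, ]
    fH <- with(sub[sub$pool_type == "H", ], alt_reads / (alt_reads + ref_reads))
    fC <- with(sub[sub$pool_type == "C", ], alt_reads / (alt_reads + ref_reads))
    expect_gt(fH, fC)
  }
})

test_that("with top fraction 1 and exact counts, mean delta_f is ~0 (no selection)", {
  fp <- simulate_founder_genotypes(40, 200, maf_spec = c(0.2, 0.5), seed = 12)
  spec <- aip_cohort_spec(cohort_size = 96, pool_size = 96, top_fraction = 1,
                          replicates = 2, sexes = "F", temperatures = "25",
                          sigma_env = 8)
  cohort <- simulate_aip_cohort(fp, spec, seed = 13)
  counts <- pool_select_and_sequence(cohort, seed = 14, exact_counts = TRUE)
  xs <- z_test_hc(counts)
  # per-variant delta_f averages to ~0 across 200 variants
  expect_lt(abs(mean(xs$delta_f)), 0.01)
})
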