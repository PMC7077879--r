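# small shared fixtures, built in code

small_panel <- function(n_lines = 20, vials = 8, seed = 11,
                        temps = c("18", "25", "28")) {
  simulate_lifespan_panel(
    panel_design(n_lines = n_lines, temperatures = temps,
                 vials_per_line_per_temp = vials,
                 missing_line_fraction_per_temp =
                   setNames(rep(0, length(temps)), temps)),
    true_components(), seed = seed)
}

toy_gene_models <- function() {
  g <- data.frame(
    gene_id = paste0("g", 1:4),
    chrom = c("2L", "2L", "2L", "3R"),
    start = c(1000, 5000, 5500, 2000),
    end = c(1999, 5399, 7999, 2999),
    stringsAsFactors = FALSE)
  g$length <- g$end - g$start + 1
  g
}

# closed-form one-way ANOVA variance-component estimator (balanced):
# sigma2_L = (MS_between - MS_within) / n_per_group
moments_one_way <- function(y, group) {
  group <- factor(group)
  k <- nlevels(group)
  n <- length(y) / k
  gm <- tapply(y, group, mean)
  ms_b <- n * sum((gm - mean(y))^2) / (k - 1)
  ms_w <- sum((y - gm[as.integer(group)])^2) / (length(y) - k)
  c(sigma2_L = (ms_b - ms_w) / n, sigma2_eps = ms_w)
}
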