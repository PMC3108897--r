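# Independent oracles used across the suite. These are deliberately written
# from first principles (explicit sum formulas / normal equations), not by
# calling the code paths they check.

# LRS by explicit normal equations for a single 0/1 regressor
lrs_oracle <- function(y, x) {
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  rss0 <- sum((y - sum(y) / n)^2)
  sxx <- sum(x^2) - sum(x)^2 / n
  if (sxx == 0 || rss0 == 0) return(0)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  rss1 <- rss0 - sxy^2 / sxx
  n * log(rss0 / rss1)
}

# Pearson r by the raw sum formula
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Partial correlation by regression residuals: correlate the residuals of
# primary ~ controls and target ~ controls
partial_oracle_residual <- function(data, primary, target, controls) {
  if (length(controls) == 0) {
    return(stats::cor(data[[primary]], data[[target]]))
  }
  f <- function(v) {
    stats::resid(stats::lm(
      stats::reformulate(controls, response = v),
      data = data
    ))
  }
  stats::cor(f(primary), f(target))
}

# First-order partial correlation closed form
partial_oracle_first_order <- function(r_xy, r_xz, r_yz) {
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}

# Small standard panel used by several tests: two chromosomes, strong cis
# effects on known markers, moderate noise.
make_test_panel <- function(n_strains = 40, seed = 101, noise_sd = 0.5,
                            beta = 2, n_biological = 2) {
  cfg <- sim_config(
    n_strains = n_strains,
    chromosomes = c(`1` = 100, `2` = 100),
    marker_spacing = 10, seed = seed
  )
  geno <- simulate_ri_genotypes(cfg)
  probes <- sprintf("p%02d", 1:8)
  ann <- tibble::tibble(
    probe_id = probes,
    symbol = toupper(probes),
    chr = c("1", "1", "2", "2", "1", "2", "1", "2"),
    mb = c(20, 50, 10, 70, 80, 40, 60, 90)
  )
  cis_markers <- c("m1_003", "m1_006", "m2_002", "m2_008", "m1_009", "m2_005", "m1_007", "m2_010")
  arch <- true_architecture(
    probes,
    cis_effects = tibble::tibble(probe = probes, marker = cis_markers, beta = beta),
    noise_sd = noise_sd
  )
  sim <- simulate_expression(geno, arch, n_biological = n_biological, seed = seed + 1)
  normalized <- normalize_arrays(sim$expression)
  summary <- strain_means(normalized, sim$samples)
  list(
    cfg = cfg, geno = geno, annotation = ann, arch = arch, sim = sim,
    normalized = normalized, summary = summary
  )
}
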