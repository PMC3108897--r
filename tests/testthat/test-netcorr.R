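summary_from_matrix <- function(M, prefix = "p") {
  colnames(M) <- sprintf("%s%02d", prefix, seq_len(ncol(M)))
  dplyr::bind_cols(
    tibble::tibble(strain = sprintf("S%02d", seq_len(nrow(M)))),
    tibble::as_tibble(M)
  )
}

test_that("Pearson matrices match the sum-formula oracle on small instances", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    M <- matrix(rnorm(n * 4), ncol = 4)
    sm <- summary_from_matrix(M)
    cm <- pearson_matrix(sm)
    expect_equal(unname(diag(cm)), rep(1, 4))
    expect_true(isSymmetric(unclass(cm)))
    for (i in 1:3) {
      for (j in (i + 1):4) {
        expect_equal(cm[i, j], pearson_oracle(M[, i], M[, j]), tolerance = 1e-12)
      }
    }
  }
})

test_that("exact linear dependence gives r = 1", {
  sm <- summary_from_matrix(cbind(c(1, 2, 3), c(2, 4, 6)))
  cm <- pearson_matrix(sm)
  expect_equal(cm["p01", "p02"], 1)
})

test_that("zero-variance probes are flagged and set to NA", {
  sm <- summary_from_matrix(cbind(c(1, 2, 3), c(5, 5, 5)))
  expect_warning(cm <- pearson_matrix(sm), "zero-variance")
  expect_true(all(is.na(cm["p02", ])))
  expect_equal(cm["p01", "p01"], 1)
})

test_that("extreme pairs match the published network matrix", {
  cm <- retina_network_cor()
  ex <- cor_extremes(cm)
  mn <- ex[ex$which == "min", ]
  mx <- ex[ex$which == "max", ]
  expect_setequal(c(mn$probe1, mn$probe2), c("Id2", "Zbed4"))
  expect_equal(mn$r, 0.54)
  expect_setequal(c(mx$probe1, mx$probe2), c("Sox2", "Pax6"))
  expect_equal(mx$r, 0.95)
})

test_that("extremes are order invariant and defined for 2x2", {
  cm <- retina_network_cor()
  perm <- sample(nrow(cm))
  ex1 <- cor_extremes(cm)
  ex2 <- cor_extremes(structure(unclass(cm)[perm, perm], class = class(cm)))
  expect_equal(ex1$r, ex2$r)
  expect_setequal(
    c(ex1$probe1, ex1$probe2),
    c(ex2$probe1, ex2$probe2)
  )
  two <- structure(unclass(cm)[1:2, 1:2], class = class(cm))
  ex <- cor_extremes(two)
  expect_equal(ex$r[1], ex$r[2])
  expect_error(cor_extremes(cm[1, 1, drop = FALSE]), "at least 2")
})

test_that("trait collections recover a latent co-expression module", {
  set.seed(88)
  n <- 40
  latent <- rnorm(n)
  module <- sapply(1:20, function(i) latent + rnorm(n, sd = 0.5))
  noise <- matrix(rnorm(n * 200), ncol = 200)
  M <- cbind(module, noise)
  sm <- summary_from_matrix(M)
  seedp <- "p01"
  top <- top_correlates(sm, seedp, n = 25)
  expect_false(seedp %in% top$probe)
  module_ids <- sprintf("p%02d", 2:20)
  expect_true(all(module_ids %in% top$probe[1:25]))
  # ranked by |r| descending
  expect_true(all(diff(abs(top$r)) <= 1e-12))
})

test_that("collection edge cases behave", {
  sm <- summary_from_matrix(matrix(rnorm(30), ncol = 3))
  expect_equal(nrow(top_correlates(sm, "p01", n = 0)), 0)
  expect_warning(top <- top_correlates(sm, "p01", n = 10), "only 2 probes")
  expect_equal(nrow(top), 2)
  expect_error(top_correlates(sm, "missing"), "not found")
})

test_that("correlation comparison intersects thresholded correlate sets", {
  set.seed(99)
  n <- 50
  shared <- rnorm(n)
  seed_a <- shared + rnorm(n, sd = 0.4)
  seed_b <- shared + rnorm(n, sd = 0.4)
  on_shared <- sapply(1:5, function(i) shared + rnorm(n, sd = 0.4))
  only_a <- sapply(1:5, function(i) seed_a + rnorm(n, sd = 0.1) + 2 * rnorm(n))
  M <- cbind(seed_a, seed_b, on_shared, only_a, matrix(rnorm(n * 30), ncol = 30))
  sm <- summary_from_matrix(M)
  seeds <- c("p01", "p02")
  hit <- correlation_comparison(sm, seeds, threshold = 0.5)
  expect_true(all(sprintf("p%02d", 3:7) %in% hit$probe))
  # impossible threshold
  expect_equal(nrow(correlation_comparison(sm, seeds, threshold = 1.01)), 0)
  # monotone shrinkage and consistency with per-seed collections
  lo <- correlation_comparison(sm, seeds, threshold = 0.3)
  hi <- correlation_comparison(sm, seeds, threshold = 0.6)
  expect_true(all(hi$probe %in% lo$probe))
  for (s in seeds) {
    per_seed <- abs(suppressWarnings(stats::cor(
      as.matrix(sm[setdiff(names(sm), c("strain", seeds))]), sm[[s]]
    )))[, 1]
    expect_true(all(per_seed[hit$probe] >= 0.5))
  }
})

test_that("partial correlation with no controls is the raw correlation", {
  cm <- retina_network_cor()
  pc <- partial_correlation(cm, "Gap43", "Pten")
  expect_equal(pc$r_partial, pc$r_raw)
  expect_equal(pc$delta, 0)
  expect_equal(pc$r_raw, 0.58)
})

test_that("first-order partial collapses to raw r when controls are uncorrelated", {
  cm <- diag(3)
  cm[1, 2] <- cm[2, 1] <- 0.6
  dimnames(cm) <- list(c("x", "y", "z"), c("x", "y", "z"))
  pc <- partial_correlation(cm, "x", "y", "z")
  expect_equal(pc$r_partial, 0.6, tolerance = 1e-12)
})

test_that("published-matrix partial agrees with two independent oracles", {
  cm <- retina_network_cor()
  pc <- partial_correlation(cm, "Pax6", "Neurod1", "Pcna")
  first_order <- partial_oracle_first_order(
    r_xy = cm["Pax6", "Neurod1"], r_xz = cm["Pax6", "Pcna"], r_yz = cm["Neurod1", "Pcna"]
  )
  expect_equal(pc$r_partial, first_order, tolerance = 1e-12)
  # residual-regression oracle on data realizing the same correlations
  set.seed(4)
  L <- chol(unclass(cm)[c("Pax6", "Neurod1", "Pcna"), c("Pax6", "Neurod1", "Pcna")])
  Z <- matrix(rnorm(3000 * 3), ncol = 3) %*% L
  dat <- as.data.frame(Z)
  names(dat) <- c("Pax6", "Neurod1", "Pcna")
  emp <- pearson_matrix(dplyr::bind_cols(tibble::tibble(strain = as.character(1:3000)), dat))
  pc_emp <- partial_correlation(emp, "Pax6", "Neurod1", "Pcna")
  expect_equal(
    pc_emp$r_partial,
    partial_oracle_residual(dat, "Pax6", "Neurod1", "Pcna"),
    tolerance = 1e-9
  )
})

test_that("degenerate control sets are rejected", {
  cm <- retina_network_cor()
  expect_error(partial_correlation(cm, "Pax6", "Pax6", "Pcna"), "differ")
  expect_error(partial_correlation(cm, "Pax6", "Neurod1", "Pax6"), "disjoint")
  sing <- diag(3)
  sing[upper.tri(sing)] <- sing[lower.tri(sing)] <- 1
  dimnames(sing) <- list(c("x", "y", "z"), c("x", "y", "z"))
  expect_error(partial_correlation(sing, "x", "y", "z"), "singular")
})

test_that("network edge lists follow the absolute-threshold rule", {
  cm <- retina_network_cor()
  all_edges <- network_graph(cm, threshold = 0)
  expect_equal(nrow(all_edges), choose(8, 2))
  # the published core network is complete at threshold 0.5
  expect_equal(nrow(network_graph(cm, threshold = 0.5)), choose(8, 2))
  # negative correlations keep their sign but count by |r|
  m <- diag(2)
  m[1, 2] <- m[2, 1] <- -0.6
  dimnames(m) <- list(c("a", "b"), c("a", "b"))
  e <- network_graph(m, threshold = 0.5)
  expect_equal(nrow(e), 1)
  expect_equal(e$r, -0.6)
})
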