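toy_geno <- function(alleles_by_marker, chr = "1", mb = NULL) {
  m <- length(alleles_by_marker)
  n <- length(alleles_by_marker[[1]])
  strains <- sprintf("S%02d", seq_len(n))
  if (is.null(mb)) mb <- seq(10, by = 10, length.out = m)
  mk <- names(alleles_by_marker)
  if (is.null(mk)) mk <- sprintf("mk%02d", seq_len(m))
  calls <- do.call(rbind, alleles_by_marker)
  colnames(calls) <- strains
  dplyr::bind_cols(
    tibble::tibble(
      marker = mk,
      chr = rep_len(chr, m), cm = mb * 0.5, mb = mb
    ),
    tibble::as_tibble(calls)
  )
}

test_that("LRS matches the brute-force normal-equations oracle", {
  # spec-style 8-strain toy
  g <- toy_geno(list(strsplit("BBBBDDDD", "")[[1]]))
  trait <- stats::setNames(c(1, 2, 1, 2, 5, 6, 5, 6), geno_strains(g))
  scan <- lrs_scan(g, trait)
  x <- c(0, 0, 0, 0, 1, 1, 1, 1)
  expect_equal(scan$lrs, lrs_oracle(unname(trait), x), tolerance = 1e-12)
  expect_equal(scan$direction, "D")

  # randomized small instances, 3..10 strains
  set.seed(202)
  for (rep in 1:60) {
    n <- sample(3:10, 1)
    alleles <- sample(c("B", "D"), n, replace = TRUE)
    g <- toy_geno(list(alleles))
    y <- stats::setNames(rnorm(n), geno_strains(g))
    scan <- lrs_scan(g, y)
    expect_equal(scan$lrs, lrs_oracle(unname(y), as.numeric(alleles == "D")),
      tolerance = 1e-9
    )
  }
})

test_that("a constant trait has zero LRS everywhere", {
  g <- toy_geno(list(
    c("B", "B", "D", "D", "B"),
    c("D", "B", "D", "B", "D")
  ))
  scan <- lrs_scan(g, stats::setNames(rep(4.2, 5), geno_strains(g)))
  expect_equal(scan$lrs, c(0, 0))
})

test_that("LRS is affine invariant; direction flips under negation", {
  g <- toy_geno(list(c("B", "B", "B", "D", "D", "D", "B", "D")))
  y <- stats::setNames(c(1, 1.5, 0.8, 3, 3.3, 2.9, 1.2, 3.1), geno_strains(g))
  s0 <- lrs_scan(g, y)
  s1 <- lrs_scan(g, 2 * y + 5)
  s2 <- lrs_scan(g, -y)
  expect_equal(s0$lrs, s1$lrs, tolerance = 1e-12)
  expect_equal(s0$direction, s1$direction)
  expect_equal(s0$lrs, s2$lrs, tolerance = 1e-12)
  expect_equal(s0$direction, "D")
  expect_equal(s2$direction, "B")
})

test_that("heterozygous and unknown calls are dropped per marker", {
  g <- toy_geno(list(c("B", "B", "U", "D", "D", "H")))
  y <- stats::setNames(c(1, 2, 100, 5, 6, -50), geno_strains(g))
  scan <- lrs_scan(g, y)
  expect_equal(scan$n, 4L)
  expect_equal(scan$lrs, lrs_oracle(c(1, 2, 5, 6), c(0, 0, 1, 1)), tolerance = 1e-9)
})

test_that("markers with too few informative strains are skipped with a warning", {
  g <- toy_geno(list(
    c("B", "D", "U", "U", "U"),
    c("B", "D", "B", "D", "B")
  ))
  y <- stats::setNames(c(1, 2, 3, 4, 5), geno_strains(g))
  expect_warning(scan <- lrs_scan(g, y), "skipped")
  expect_equal(scan$marker, "mk02")
})

test_that("peak calling breaks LRS ties toward the smaller genome coordinate", {
  scan <- tibble::tibble(
    marker = c("a", "b"), chr = c("1", "3"), mb = c(50, 10),
    cum_mb = c(50, 210), n = 20L, lrs = c(20, 20), direction = "D"
  )
  expect_equal(peak_qtl(scan)$marker, "a")
  expect_equal(peak_qtl(scan[1, ])$marker, "a")
  expect_error(peak_qtl(scan[0, ]), "empty")
})

test_that("cis/trans classification follows the windowed rule", {
  # same chromosome, within the window (Dok5-like geometry)
  expect_equal(classify_cis_trans("2", 170.7, "2", 173.4, 20), "cis")
  # different chromosome is always trans
  expect_equal(classify_cis_trans("2", 170, "12", 40, 20), "trans")
  # boundary is inclusive
  expect_equal(classify_cis_trans("2", 100, "2", 120, 20), "cis")
  expect_equal(classify_cis_trans("2", 100, "2", 120.01, 20), "trans")
  # unlocated probes are 'none'
  expect_equal(classify_cis_trans(NA, NA, "2", 120, 20), "none")
})

test_that("mapped eQTLs recover implanted cis architecture", {
  pan <- make_test_panel(n_strains = 40, seed = 101)
  qtl <- map_eqtl(pan$summary, pan$geno, pan$annotation)
  truth <- pan$arch$cis_effects
  for (i in seq_len(nrow(truth))) {
    row <- qtl[qtl$probe_id == truth$probe[i], ]
    true_mb <- pan$geno$mb[pan$geno$marker == truth$marker[i]]
    true_chr <- pan$geno$chr[pan$geno$marker == truth$marker[i]]
    expect_equal(row$peak_chr, true_chr)
    expect_lte(abs(row$peak_mb - true_mb), 10)
    expect_equal(row$class, "cis")
  }
  # implanted effects are positive: D haplotype is the high allele
  expect_true(all(qtl$direction == "D"))
})

test_that("the significant-QTL census counts and partitions correctly", {
  qtl <- tibble::tibble(
    probe_id = sprintf("p%d", 1:5),
    chr = c("1", "1", NA, "2", "2"), mb = c(10, 20, NA, 30, 40),
    peak_marker = "m", peak_chr = c("1", "2", "1", "2", "2"),
    peak_mb = c(12, 90, 10, 35, 41),
    lrs = c(20, 16, 18, 14, 25), direction = "D",
    class = c("cis", "trans", "none", "cis", "cis"), mean_expr = 8
  )
  class(qtl) <- c("qtl_tbl", class(qtl))
  cs <- count_significant(qtl, 15)
  expect_equal(cs$total, 4)
  expect_equal(cs$n_cis, 2)
  expect_equal(cs$n_trans, 1)
  expect_equal(cs$n_unlocated, 1)
  expect_equal(count_significant(qtl[0, ], 15)$total, 0)
  # monotone in the threshold
  totals <- vapply(c(10, 15, 20, 30), function(t) count_significant(qtl, t)$total, numeric(1))
  expect_true(all(diff(totals) <= 0))
})

test_that("the transcriptome map partitions into cis and trans points", {
  pan <- make_test_panel(n_strains = 40, seed = 101)
  qtl <- map_eqtl(pan$summary, pan$geno, pan$annotation)
  pts <- transcriptome_map(qtl, pan$geno, threshold = 15)
  cs <- count_significant(qtl, 15)
  expect_equal(nrow(pts), cs$n_cis + cs$n_trans)
  # an all-cis panel plots within the window band around the diagonal
  cis_pts <- pts[pts$class == "cis", ]
  expect_true(all(abs(cis_pts$peak_cum_mb - cis_pts$gene_cum_mb) <= 20))
  expect_equal(nrow(transcriptome_map(qtl, pan$geno, threshold = Inf)), 0)
})

test_that("cumulative genome coordinates increase along the ordered genome", {
  cfg <- sim_config(n_strains = 3, chromosomes = c(`1` = 50, `2` = 30, `3` = 40), marker_spacing = 10, seed = 1)
  map <- marker_map(simulate_ri_genotypes(cfg))
  expect_true(all(diff(map$cum_mb) > 0))
  # chromosome 1 spans its last marker (50 Mb) plus one 10-Mb gap
  expect_equal(map$cum_mb[map$marker == "m2_001"], 60)
})
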