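#' Marker map with cumulative genome coordinates
#'
#' Orders markers by chromosome (order of first appearance) and position, and
#' adds a cumulative coordinate in Mb measured from the start of the first
#' chromosome, so the whole genome lies on one axis (e.g. ~1-2600 Mb for a
#' mouse autosome panel).
#'
#' @param geno Genotype tibble (`marker`, `chr`, `cm`, `mb`, strains).
#' @return Tibble `marker`, `chr`, `cm`, `mb`, `cum_mb`.
#' @export
marker_map <- function(geno) {
  map <- dplyr::select(tibble::as_tibble(geno), "marker", dplyr::any_of("cm"), "chr", "mb")
  chrs <- unique(map$chr)
  offset <- stats::setNames(cumsum(c(0, utils::head(chr_spans(map), -1))), chrs)
  map |>
    dplyr::mutate(
      chr = factor(.data$chr, levels = chrs),
      cum_mb = .data$mb + unname(offset[as.character(.data$chr)])
    ) |>
    dplyr::arrange(.data$chr, .data$mb) |>
    dplyr::mutate(chr = as.character(.data$chr))
}

# per-chromosome span used for cumulative coordinates: the last marker plus
# one median inter-marker gap, so chromosome starts never collide with the
# previous chromosome's end and cumulative coordinates are strictly increasing
chr_spans <- function(map) {
  vapply(unique(map$chr), function(ch) {
    mb <- sort(map$mb[map$chr == ch])
    pad <- if (length(mb) > 1) stats::median(diff(mb)) else 1
    max(mb) + max(pad, .Machine$double.eps)
  }, numeric(1))
}

# genotype calls as a strains x markers 0/1 matrix (B=0, D=1, H/U -> NA)
geno_numeric <- function(geno, strains = geno_strains(geno)) {
  calls <- as.matrix(geno[, strains, drop = FALSE])
  x <- matrix(NA_real_, nrow = length(strains), ncol = nrow(geno),
    dimnames = list(strains, geno$marker)
  )
  x[t(calls) == "B"] <- 0
  x[t(calls) == "D"] <- 1
  x
}

# Core scan: Y (strains x probes), X (strains x markers, 0/1/NA).
# Returns list(lrs, r, n): markers x probes matrices.
scan_core <- function(Y, X) {
  p <- ncol(Y)
  m <- ncol(X)
  ok_y <- !is.na(Y)
  r <- suppressWarnings(stats::cor(X, Y, use = "pairwise.complete.obs"))
  n <- crossprod((!is.na(X)) * 1, ok_y * 1) # complete pairs per marker x probe
  r[is.na(r)] <- 0 # monomorphic marker or constant trait: no linkage
  r2 <- pmin(r^2, 1 - 1e-12)
  lrs <- -n * log1p(-r2)
  lrs[n < 3] <- NA_real_
  list(lrs = lrs, r = r, n = n)
}

#' Genome scan of one trait by single-marker regression LRS
#'
#' At each marker, strains with known homozygous alleles are coded B = 0,
#' D = 1 and the trait is regressed on the code. The likelihood ratio
#' statistic is `LRS = n * ln(RSS0 / RSS1)`, comparing the mean-only model
#' (RSS0) with the one-marker linear model (RSS1); equivalently
#' `-n * ln(1 - R^2)`. The allele direction records which haplotype has the
#' higher trait value. Heterozygous (`H`) and unknown (`U`) calls are dropped
#' per marker; markers with fewer than 3 informative strains are skipped with
#' a warning, and monomorphic markers score LRS 0 with undefined direction.
#'
#' @param geno Genotype tibble.
#' @param trait Named numeric vector (names = strains) or a tibble with
#'   columns `strain` and `value`.
#' @return Tibble `marker`, `chr`, `mb`, `cum_mb`, `n`, `lrs`, `direction`
#'   (`"B"`/`"D"`/`NA`), one row per scanned marker.
#' @export
lrs_scan <- function(geno, trait) {
  if (is.data.frame(trait)) {
    stopifnot(all(c("strain", "value") %in% names(trait)))
    trait <- stats::setNames(trait$value, trait$strain)
  }
  strains <- intersect(geno_strains(geno), names(trait))
  if (length(strains) < 3) stop("fewer than 3 strains shared by genotypes and trait", call. = FALSE)
  y <- trait[strains]
  X <- geno_numeric(geno, strains)
  sc <- scan_core(matrix(y, ncol = 1, dimnames = list(strains, "trait")), X)
  map <- marker_map(geno)
  res <- tibble::tibble(
    marker = colnames(X),
    n = as.integer(unname(sc$n[, 1])),
    lrs = unname(sc$lrs[, 1]),
    r = unname(sc$r[, 1])
  ) |>
    dplyr::mutate(direction = dplyr::case_when(
      .data$r > 0 ~ "D",
      .data$r < 0 ~ "B",
      TRUE ~ NA_character_
    ))
  skipped <- is.na(res$lrs)
  if (any(skipped)) {
    warning(sum(skipped), " marker(s) skipped: fewer than 3 informative strains",
      call. = FALSE
    )
    res <- res[!skipped, , drop = FALSE]
  }
  dplyr::inner_join(map, dplyr::select(res, -"r"), by = "marker") |>
    dplyr::select("marker", "chr", "mb", "cum_mb", "n", "lrs", "direction")
}

#' Peak QTL of a genome scan
#'
#' Returns the marker with maximal LRS; ties are broken by the smallest
#' cumulative genome coordinate (closest to the start of chromosome 1).
#'
#' @param scan Tibble from [lrs_scan()].
#' @return One-row tibble with the peak marker's row.
#' @export
peak_qtl <- function(scan) {
  if (is.null(scan) || nrow(scan) == 0) stop("empty scan", call. = FALSE)
  scan |>
    dplyr::arrange(dplyr::desc(.data$lrs), .data$cum_mb) |>
    dplyr::slice(1)
}

#' Classify QTL peaks as cis or trans
#'
#' A peak is cis when it lies on the transcript's own chromosome within
#' `window` Mb of the transcript (inclusive), trans otherwise; transcripts
#' with no genomic location are classified `"none"`. The default 20-Mb window
#' matches the exclusion buffer used in candidate searches.
#'
#' @param gene_chr,gene_mb Transcript location (vectorized).
#' @param peak_chr,peak_mb Peak location (vectorized).
#' @param window Cis window in Mb (> 0), boundary inclusive.
#' @return Character vector: `"cis"`, `"trans"` or `"none"`.
#' @export
classify_cis_trans <- function(gene_chr, gene_mb, peak_chr, peak_mb, window = 20) {
  stopifnot(window > 0)
  dplyr::case_when(
    is.na(gene_chr) | is.na(gene_mb) ~ "none",
    as.character(gene_chr) == as.character(peak_chr) &
      abs(gene_mb - peak_mb) <= window ~ "cis",
    TRUE ~ "trans"
  )
}

#' Map eQTLs for every probe of a strain summary
#'
#' Runs a single-marker LRS scan per probe over the per-strain means, calls
#' the peak (ties to the smallest cumulative coordinate) and classifies it
#' cis/trans against the probe's annotated location.
#'
#' @param summary Strain-summary tibble from [strain_means()] (`strain`,
#'   optional `n_samples`, probe columns).
#' @param geno Genotype tibble.
#' @param annotation Tibble with columns `probe_id`, `symbol`, `chr`, `mb`
#'   (and optionally `description`, `probe_target`). Probes absent from the
#'   annotation are kept with unknown location.
#' @param cis_window Cis window in Mb (default 20).
#' @return A `qtl_tbl` tibble: `probe_id`, `symbol`, `chr`, `mb`,
#'   `peak_marker`, `peak_chr`, `peak_mb`, `lrs`, `direction`, `class`,
#'   `mean_expr`.
#' @export
map_eqtl <- function(summary, geno, annotation = NULL, cis_window = 20) {
  summary <- tibble::as_tibble(summary)
  stopifnot("strain" %in% names(summary))
  probes <- setdiff(names(summary), c("strain", "n_samples"))
  strains <- intersect(summary$strain, geno_strains(geno))
  if (length(strains) < 3) stop("fewer than 3 strains shared by genotypes and summary", call. = FALSE)
  Y <- as.matrix(summary[match(strains, summary$strain), probes, drop = FALSE])
  rownames(Y) <- strains
  X <- geno_numeric(geno, strains)
  sc <- scan_core(Y, X)
  map <- marker_map(geno)
  ord <- match(map$marker, colnames(X))

  # peak per probe on the genome-ordered scan; ties -> lowest cumulative Mb
  lrs_o <- sc$lrs[ord, , drop = FALSE]
  lrs_o[is.na(lrs_o)] <- -Inf
  peak_i <- apply(lrs_o, 2, which.max)
  peak_lrs <- lrs_o[cbind(peak_i, seq_along(probes))]
  peak_r <- sc$r[ord, , drop = FALSE][cbind(peak_i, seq_along(probes))]

  res <- tibble::tibble(
    probe_id = probes,
    peak_marker = map$marker[peak_i],
    peak_chr = map$chr[peak_i],
    peak_mb = map$mb[peak_i],
    lrs = peak_lrs,
    direction = dplyr::case_when(peak_r > 0 ~ "D", peak_r < 0 ~ "B", TRUE ~ NA_character_),
    mean_expr = colMeans(Y, na.rm = TRUE)
  )
  if (is.null(annotation)) {
    annotation <- tibble::tibble(
      probe_id = character(), symbol = character(),
      chr = character(), mb = numeric()
    )
  }
  annotation <- tibble::as_tibble(annotation)
  res <- res |>
    dplyr::left_join(
      dplyr::select(annotation, "probe_id", dplyr::any_of(c("symbol", "description", "probe_target")), "chr", "mb"),
      by = "probe_id"
    ) |>
    dplyr::mutate(class = classify_cis_trans(
      .data$chr, .data$mb, .data$peak_chr, .data$peak_mb, cis_window
    )) |>
    dplyr::select(
      "probe_id", dplyr::any_of(c("symbol", "description", "probe_target")),
      "chr", "mb", "peak_marker", "peak_chr", "peak_mb", "lrs", "direction",
      "class", "mean_expr"
    )
  class(res) <- c("qtl_tbl", class(res))
  attr(res, "cis_window") <- cis_window
  res
}

#' Census of significant QTLs
#'
#' Counts probes whose peak LRS meets the significance threshold (default 15,
#' the conventional genome-wide "significant QTL" cut for these panels),
#' split into cis, trans and unlocated.
#'
#' @param qtl A `qtl_tbl` from [map_eqtl()].
#' @param threshold LRS threshold, inclusive (default 15).
#' @return One-row tibble: `total`, `n_cis`, `n_trans`, `n_unlocated`.
#' @export
count_significant <- function(qtl, threshold = 15) {
  sig <- qtl[!is.na(qtl$lrs) & qtl$lrs >= threshold, , drop = FALSE]
  tibble::tibble(
    total = nrow(sig),
    n_cis = sum(sig$class == "cis"),
    n_trans = sum(sig$class == "trans"),
    n_unlocated = sum(sig$class == "none")
  )
}

#' Transcriptome map (genome graph) point set
#'
#' For every significant, genomically located probe, pairs the cumulative
#' genome coordinate of its peak QTL (x) with that of the transcript itself
#' (y) and assigns an LRS tier for the conventional colour scale (blue =
#' low, green = intermediate, red = high LRS). Cis points fall on the
#' diagonal band; vertical bands off the diagonal are trans hotspots.
#'
#' @param qtl A `qtl_tbl` from [map_eqtl()].
#' @param geno Genotype tibble (for the marker map / chromosome offsets).
#' @param threshold Minimum LRS (default 15).
#' @param tiers Increasing LRS cutpoints separating tiers (default
#'   `c(25, 50)`).
#' @return Tibble `probe_id`, `peak_cum_mb`, `gene_cum_mb`, `lrs`, `class`,
#'   `tier`.
#' @export
transcriptome_map <- function(qtl, geno, threshold = 15, tiers = c(25, 50)) {
  map <- marker_map(geno)
  chrs <- unique(map$chr)
  offset <- stats::setNames(cumsum(c(0, utils::head(chr_spans(map), -1))), chrs)
  breaks <- unique(c(threshold, tiers[tiers > threshold], Inf))
  labels <- c("low", "intermediate", "high")[seq_len(length(breaks) - 1)]
  qtl |>
    dplyr::filter(!is.na(.data$lrs), .data$lrs >= threshold, .data$class != "none") |>
    dplyr::mutate(
      peak_cum_mb = .data$peak_mb + unname(offset[as.character(.data$peak_chr)]),
      gene_cum_mb = .data$mb + unname(offset[as.character(.data$chr)]),
      tier = if (length(labels)) {
        cut(.data$lrs, breaks = breaks, labels = labels, right = FALSE, include.lowest = TRUE)
      } else {
        factor(rep(NA_character_, dplyr::n()), levels = "high")
      }
    ) |>
    dplyr::select("probe_id", "peak_cum_mb", "gene_cum_mb", "lrs", "class", "tier")
}
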