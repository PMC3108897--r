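#' QTL heat map of a trait collection
#'
#' Scans every probe of a trait collection against the whole genome and
#' assembles the signed-LRS matrix behind a QTL heat map: rows are collection
#' probes (in collection order, i.e. by correlation with the seed), columns
#' are markers in genome order, and each cell is the scan LRS signed by the
#' allele direction — positive where the D haplotype carries the higher
#' expression, negative where the B haplotype does. Vertical stripes shared
#' by many rows are candidate signature (trans) bands.
#'
#' @param collection A `trait_collection` from [top_correlates()], a tibble
#'   with a `probe` column, or a character vector of probe ids.
#' @param summary Strain-summary tibble holding those probes.
#' @param geno Genotype tibble.
#' @return A list of class `qtl_heatmap`: `values` (probes x markers signed
#'   LRS matrix), `map` (marker map with `cum_mb`), `probes`.
#' @export
qtl_heatmap <- function(collection, summary, geno) {
  probes <- if (is.character(collection)) {
    collection
  } else {
    tibble::as_tibble(collection)$probe
  }
  if (!length(probes)) stop("empty collection", call. = FALSE)
  summary <- tibble::as_tibble(summary)
  have <- intersect(probes, names(summary))
  dropped <- setdiff(probes, have)
  if (length(dropped)) {
    warning("probe(s) without expression data dropped: ", paste(dropped, collapse = ", "),
      call. = FALSE
    )
  }
  if (!length(have)) stop("no collection probe has expression data", call. = FALSE)
  strains <- intersect(summary$strain, geno_strains(geno))
  Y <- as.matrix(summary[match(strains, summary$strain), have, drop = FALSE])
  rownames(Y) <- strains
  X <- geno_numeric(geno, strains)
  sc <- scan_core(Y, X)
  map <- marker_map(geno)
  ord <- match(map$marker, colnames(X))
  signed <- t(sc$lrs[ord, , drop = FALSE] * sign(sc$r[ord, , drop = FALSE]))
  rownames(signed) <- have
  colnames(signed) <- map$marker
  structure(
    list(values = signed, map = map, probes = have),
    class = "qtl_heatmap"
  )
}

#' Detect signature (trans) bands in a QTL heat map
#'
#' Operationalizes the visual band-reading of QTL heat maps: the genome is
#' cut into fixed-width bins; for each collection probe the maximal `|LRS|`
#' within a bin is taken; a bin qualifies when the fraction of probes meeting
#' the LRS threshold is at least `support_fraction`; adjacent qualifying bins
#' on the same chromosome are merged into one band. Support statistics for a
#' merged band are recomputed over the whole merged interval.
#'
#' @param hm A `qtl_heatmap` from [qtl_heatmap()].
#' @param bin_mb Bin width in Mb (default 25).
#' @param lrs_threshold Per-probe `|LRS|` threshold inside the bin
#'   (default 15, the significant-QTL cut).
#' @param support_fraction Minimum fraction of collection probes supporting a
#'   bin (default 0.3).
#' @return Tibble of bands sorted by genome coordinate: `chr`, `start_mb`,
#'   `end_mb`, `n_support`, `support_fraction`.
#' @export
detect_bands <- function(hm, bin_mb = 25, lrs_threshold = 15, support_fraction = 0.3) {
  stopifnot(inherits(hm, "qtl_heatmap"))
  if (bin_mb <= 0) stop("`bin_mb` must be > 0", call. = FALSE)
  if (support_fraction <= 0 || support_fraction > 1) {
    stop("`support_fraction` must be in (0, 1]", call. = FALSE)
  }
  map <- hm$map
  n_probes <- nrow(hm$values)
  bins <- map |>
    dplyr::mutate(bin = floor(.data$mb / bin_mb)) |>
    dplyr::group_by(.data$chr, .data$bin) |>
    dplyr::summarise(
      start_mb = .data$bin[1] * bin_mb,
      end_mb = (.data$bin[1] + 1) * bin_mb,
      markers = list(.data$marker),
      .groups = "drop"
    )
  support_in <- function(markers) {
    cols <- match(markers, colnames(hm$values))
    block <- abs(hm$values[, cols, drop = FALSE])
    peak <- apply(block, 1, max, na.rm = TRUE)
    sum(peak >= lrs_threshold)
  }
  bins$n_support <- vapply(bins$markers, support_in, numeric(1))
  bins$frac <- bins$n_support / n_probes
  chr_order <- unique(map$chr)
  qual <- bins |>
    dplyr::filter(.data$frac >= support_fraction) |>
    dplyr::mutate(chr = factor(.data$chr, levels = chr_order)) |>
    dplyr::arrange(.data$chr, .data$bin)
  if (nrow(qual) == 0) {
    return(tibble::tibble(
      chr = character(), start_mb = numeric(), end_mb = numeric(),
      n_support = integer(), support_fraction = numeric()
    ))
  }
  # merge runs of adjacent qualifying bins within a chromosome
  run <- cumsum(c(TRUE, !(qual$chr[-1] == qual$chr[-nrow(qual)] &
    qual$bin[-1] == qual$bin[-nrow(qual)] + 1)))
  merged <- qual |>
    dplyr::mutate(run = run) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(
      chr = as.character(.data$chr[1]),
      start_mb = min(.data$start_mb),
      end_mb = max(.data$end_mb),
      markers = list(unlist(.data$markers)),
      .groups = "drop"
    )
  merged$n_support <- as.integer(vapply(merged$markers, support_in, numeric(1)))
  merged |>
    dplyr::mutate(
      support_fraction = .data$n_support / n_probes,
      chr = factor(.data$chr, levels = chr_order)
    ) |>
    dplyr::arrange(.data$chr, .data$start_mb) |>
    dplyr::mutate(chr = as.character(.data$chr)) |>
    dplyr::select("chr", "start_mb", "end_mb", "n_support", "support_fraction")
}
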