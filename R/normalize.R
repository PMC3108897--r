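#' Global per-array normalization onto the 2z+8 scale
#'
#' Applies the four-step global normalization used for RI-panel array data:
#' take log2 of each raw signal, compute each array's mean and standard
#' deviation, and rescale each array as `2 * z + 8` where `z` is the
#' within-array z-score of the log2 signal. Every normalized array then has
#' mean exactly 8 and standard deviation exactly 2; one normalized unit equals
#' half a within-array SD of log2 signal.
#'
#' The z-score uses the sample (n-1) standard deviation. Input is assumed to
#' be already background-adjusted signal (e.g. rank-invariant normalized by
#' the array vendor's software); no batch correction is applied.
#'
#' @param expr Tibble with a `probe_id` column and one numeric column of raw
#'   signal per array (sample). All signals must be strictly positive.
#' @return Tibble of the same shape on the 2z+8 scale.
#' @export
#' @examples
#' raw <- tibble::tibble(probe_id = c("p1", "p2", "p3"), a1 = c(1, 2, 4))
#' normalize_arrays(raw) # a1 becomes 6, 8, 10
normalize_arrays <- function(expr) {
  expr <- tibble::as_tibble(expr)
  if (!"probe_id" %in% names(expr)) stop("`expr` must have a `probe_id` column", call. = FALSE)
  arrays <- setdiff(names(expr), "probe_id")
  if (!length(arrays)) stop("no array columns to normalize", call. = FALSE)
  out <- expr
  for (a in arrays) {
    x <- expr[[a]]
    if (!is.numeric(x)) stop(sprintf("array `%s` is not numeric", a), call. = FALSE)
    if (any(!is.na(x) & x <= 0)) {
      stop(sprintf("array `%s` has non-positive signal; log2 undefined", a), call. = FALSE)
    }
    lx <- log2(x)
    s <- stats::sd(lx, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop(sprintf("array `%s` is degenerate (zero variance)", a), call. = FALSE)
    }
    out[[a]] <- 2 * (lx - mean(lx, na.rm = TRUE)) / s + 8
  }
  out
}

#' Summarize normalized arrays into per-strain means
#'
#' Technical replicates (samples sharing a `replicate_group`) are averaged
#' first; the resulting independent biological samples are then averaged per
#' strain. Sexes are pooled. This two-stage average weights each biological
#' sample equally regardless of how many technical replicates it has.
#'
#' @param normalized Tibble from [normalize_arrays()] (`probe_id` + sample
#'   columns).
#' @param samples Sample sheet tibble with columns `sample`, `strain` and
#'   optionally `replicate_group` (defaults to one group per sample, i.e. all
#'   samples biological).
#' @return Tibble with one row per strain: `strain`, `n_samples` (number of
#'   arrays contributing), then one numeric column per probe.
#' @export
strain_means <- function(normalized, samples) {
  normalized <- tibble::as_tibble(normalized)
  samples <- tibble::as_tibble(samples)
  stopifnot("probe_id" %in% names(normalized))
  if (!all(c("sample", "strain") %in% names(samples))) {
    stop("`samples` must have columns `sample` and `strain`", call. = FALSE)
  }
  if (!"replicate_group" %in% names(samples)) {
    samples$replicate_group <- samples$sample
  }
  cols <- setdiff(names(normalized), "probe_id")
  unmapped <- setdiff(cols, samples$sample)
  if (length(unmapped)) {
    stop("samples with no strain assignment: ", paste(unmapped, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(is.na(samples$strain) | samples$strain == "")) {
    stop("sample sheet contains samples with no strain assignment", call. = FALSE)
  }
  samples <- samples[samples$sample %in% cols, , drop = FALSE]

  long <- normalized |>
    tidyr::pivot_longer(-"probe_id", names_to = "sample", values_to = "value") |>
    dplyr::inner_join(samples, by = "sample")
  tech <- long |>
    dplyr::group_by(.data$strain, .data$replicate_group, .data$probe_id) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  means <- tech |>
    dplyr::group_by(.data$strain, .data$probe_id) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "probe_id", values_from = "value")
  counts <- samples |>
    dplyr::count(.data$strain, name = "n_samples")
  dplyr::left_join(counts, means, by = "strain") |>
    dplyr::select("strain", "n_samples", dplyr::all_of(normalized$probe_id)) |>
    dplyr::arrange(.data$strain)
}
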