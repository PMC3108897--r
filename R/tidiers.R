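#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a correlation matrix into a long pair table
#'
#' @param x A `cor_mat`.
#' @param upper_only Keep only the upper triangle (default `TRUE`).
#' @param ... Unused.
#' @return Tibble `probe1`, `probe2`, `r`.
#' @export
tidy.cor_mat <- function(x, upper_only = TRUE, ...) {
  m <- unclass(x)
  idx <- if (upper_only) which(upper.tri(m), arr.ind = TRUE) else which(row(m) != col(m), arr.ind = TRUE)
  tibble::tibble(
    probe1 = rownames(m)[idx[, 1]],
    probe2 = colnames(m)[idx[, 2]],
    r = m[idx]
  )
}

#' Tidy a QTL heat map into a long cell table
#'
#' @param x A `qtl_heatmap`.
#' @param ... Unused.
#' @return Tibble `probe`, `marker`, `chr`, `mb`, `cum_mb`, `signed_lrs`;
#'   `probe` is a factor in collection (row) order.
#' @export
tidy.qtl_heatmap <- function(x, ...) {
  vals <- x$values
  long <- tibble::tibble(
    probe = factor(rep(rownames(vals), times = ncol(vals)), levels = rev(rownames(vals))),
    marker = rep(colnames(vals), each = nrow(vals)),
    signed_lrs = as.vector(vals)
  )
  dplyr::left_join(long, dplyr::select(x$map, "marker", "chr", "mb", "cum_mb"),
    by = "marker"
  )
}

#' One-row summary of an eQTL mapping result
#'
#' @param x A `qtl_tbl` from [map_eqtl()].
#' @param threshold Significance threshold passed to [count_significant()].
#' @param ... Unused.
#' @return One-row tibble: `n_probes`, `total`, `n_cis`, `n_trans`,
#'   `n_unlocated`, `cis_window`, `threshold`.
#' @export
glance.qtl_tbl <- function(x, threshold = 15, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_probes = nrow(x)),
    count_significant(x, threshold),
    tibble::tibble(
      cis_window = attr(x, "cis_window") %||% NA_real_,
      threshold = threshold
    )
  )
}
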