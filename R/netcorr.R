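#' Pearson correlation matrix over strain means
#'
#' Computes the probe-by-probe Pearson correlation of per-strain mean
#' expression, using pairwise-complete observations so strains with missing
#' values for some probes still contribute where they can. Probes with zero
#' variance are flagged with a warning and their row/column set to `NA`.
#'
#' @param summary Strain-summary tibble (`strain`, optional `n_samples`,
#'   probe columns) or any tibble of numeric trait columns plus a `strain`
#'   column.
#' @param probes Optional character vector restricting/ordering the probes.
#' @return A symmetric numeric matrix of class `cor_mat` with unit diagonal.
#' @export
pearson_matrix <- function(summary, probes = NULL) {
  summary <- tibble::as_tibble(summary)
  vars <- setdiff(names(summary), c("strain", "n_samples"))
  if (!is.null(probes)) {
    missing_p <- setdiff(probes, vars)
    if (length(missing_p)) stop("unknown probes: ", paste(missing_p, collapse = ", "), call. = FALSE)
    vars <- probes
  }
  M <- as.matrix(summary[, vars, drop = FALSE])
  if (nrow(M) < 3) stop("need at least 3 strains", call. = FALSE)
  sds <- apply(M, 2, stats::sd, na.rm = TRUE)
  flat <- !is.na(sds) & sds == 0
  cm <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))
  if (any(flat)) {
    warning("zero-variance probe(s): ", paste(vars[flat], collapse = ", "), call. = FALSE)
    cm[flat, ] <- NA_real_
    cm[, flat] <- NA_real_
  }
  diag(cm) <- ifelse(flat, NA_real_, 1)
  structure(cm, class = c("cor_mat", class(cm)))
}

#' Extreme off-diagonal correlations
#'
#' Scans the upper triangle of a correlation matrix and reports the pair with
#' the lowest and the pair with the highest correlation.
#'
#' @param cm Correlation matrix (e.g. from [pearson_matrix()]).
#' @return Tibble with rows `min` and `max`: `which`, `probe1`, `probe2`, `r`.
#' @export
cor_extremes <- function(cm) {
  cm <- unclass(cm)
  if (nrow(cm) < 2) stop("need at least 2 probes", call. = FALSE)
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  vals <- cm[ut]
  if (all(is.na(vals))) stop("all off-diagonal correlations undefined", call. = FALSE)
  pick <- function(i) {
    tibble::tibble(
      probe1 = rownames(cm)[ut[i, 1]],
      probe2 = colnames(cm)[ut[i, 2]],
      r = vals[i]
    )
  }
  dplyr::bind_rows(
    dplyr::mutate(pick(which.min(vals)), which = "min", .before = 1),
    dplyr::mutate(pick(which.max(vals)), which = "max", .before = 1)
  )
}

#' Top correlates of a seed trait
#'
#' Ranks every other probe by its Pearson correlation with the seed across
#' strain means and returns the strongest `n`. Ranking uses `|r|` by default
#' (so strong negative correlates are retained, the convention of trait
#' collections); ties are broken by probe id.
#'
#' @param summary Strain-summary tibble.
#' @param seed Seed probe id (a column of `summary`).
#' @param n Collection size (e.g. the customary top 100).
#' @param rank One of `"absolute"` (default) or `"signed"`.
#' @return A `trait_collection` tibble: `probe`, `r`, sorted by rank; the
#'   seed itself is excluded. Attribute `seed` records the seed probe.
#' @export
top_correlates <- function(summary, seed, n = 100, rank = c("absolute", "signed")) {
  rank <- match.arg(rank)
  summary <- tibble::as_tibble(summary)
  vars <- setdiff(names(summary), c("strain", "n_samples"))
  if (!seed %in% vars) stop("seed probe not found: ", seed, call. = FALSE)
  y <- summary[[seed]]
  if (stats::sd(y, na.rm = TRUE) == 0) stop("seed probe has zero variance", call. = FALSE)
  others <- setdiff(vars, seed)
  if (n > length(others)) {
    warning("requested ", n, " correlates but only ", length(others), " probes available",
      call. = FALSE
    )
    n <- length(others)
  }
  r <- suppressWarnings(stats::cor(
    as.matrix(summary[, others, drop = FALSE]), y,
    use = "pairwise.complete.obs"
  ))[, 1]
  res <- tibble::tibble(probe = others, r = r) |>
    dplyr::filter(!is.na(.data$r))
  key <- if (rank == "absolute") abs(res$r) else res$r
  res <- res[order(-key, res$probe), , drop = FALSE] |> utils::head(n)
  structure(res, seed = seed, class = c("trait_collection", class(res)))
}

#' Correlation comparison across several seed traits
#'
#' Finds the probes whose expression correlates with every one of the seed
#' traits at or above a threshold (on `|r|`) — the intersecting trait set
#' shared by a network of seeds.
#'
#' @param summary Strain-summary tibble.
#' @param seeds Character vector of at least 2 seed probe ids.
#' @param threshold Minimum `|r|` against each seed (default 0.5).
#' @return Tibble `probe`, one `r_<seed>` column per seed, and `min_abs_r`,
#'   sorted by `min_abs_r` descending. Seeds themselves are excluded.
#' @export
correlation_comparison <- function(summary, seeds, threshold = 0.5) {
  if (length(seeds) < 2) stop("need at least 2 seed traits", call. = FALSE)
  summary <- tibble::as_tibble(summary)
  vars <- setdiff(names(summary), c("strain", "n_samples"))
  missing_s <- setdiff(seeds, vars)
  if (length(missing_s)) stop("unknown seeds: ", paste(missing_s, collapse = ", "), call. = FALSE)
  others <- setdiff(vars, seeds)
  R <- suppressWarnings(stats::cor(
    as.matrix(summary[, others, drop = FALSE]),
    as.matrix(summary[, seeds, drop = FALSE]),
    use = "pairwise.complete.obs"
  ))
  keep <- !is.na(rowSums(R)) & apply(abs(R) >= threshold, 1, all)
  out <- tibble::as_tibble(R[keep, , drop = FALSE], .name_repair = "minimal")
  names(out) <- paste0("r_", seeds)
  out <- dplyr::bind_cols(tibble::tibble(probe = others[keep]), out)
  out$min_abs_r <- if (nrow(out)) apply(abs(R[keep, , drop = FALSE]), 1, min) else numeric(0)
  dplyr::arrange(out, dplyr::desc(.data$min_abs_r))
}

#' Partial correlation between two traits controlling for others
#'
#' Computes the raw Pearson correlation between `primary` and `target` and
#' the partial correlation after removing the linear dependence of both on
#' the control traits, via the precision (inverse correlation) matrix of the
#' submatrix over `{primary, target, controls}`:
#' `r_partial = -Omega[1,2] / sqrt(Omega[1,1] * Omega[2,2])`.
#' Both components are reported along with their difference, because a large
#' change after controlling indicates that the controls carry the shared
#' signal.
#'
#' @param x A correlation matrix (e.g. [pearson_matrix()]) or a
#'   strain-summary tibble.
#' @param primary,target Trait ids.
#' @param controls Character vector of control trait ids (disjoint from
#'   primary/target); may be empty, in which case `r_partial == r_raw`.
#' @return One-row tibble: `primary`, `target`, `controls` (slash-separated),
#'   `r_raw`, `r_partial`, `delta` (= `r_partial - r_raw`).
#' @export
partial_correlation <- function(x, primary, target, controls = character()) {
  if (primary == target) stop("primary and target must differ", call. = FALSE)
  if (any(c(primary, target) %in% controls)) {
    stop("controls must be disjoint from primary/target", call. = FALSE)
  }
  cm <- if (inherits(x, "cor_mat") || is.matrix(x)) unclass(x) else unclass(pearson_matrix(x))
  ids <- c(primary, target, controls)
  missing_i <- setdiff(ids, rownames(cm))
  if (length(missing_i)) stop("unknown traits: ", paste(missing_i, collapse = ", "), call. = FALSE)
  sub <- cm[ids, ids, drop = FALSE]
  r_raw <- sub[1, 2]
  if (length(controls) == 0) {
    r_partial <- r_raw
  } else {
    om <- tryCatch(solve(sub), error = function(e) {
      stop("correlation submatrix is singular; partial correlation undefined", call. = FALSE)
    })
    r_partial <- -om[1, 2] / sqrt(om[1, 1] * om[2, 2])
  }
  tibble::tibble(
    primary = primary, target = target,
    controls = paste(controls, collapse = "/"),
    r_raw = r_raw, r_partial = r_partial,
    delta = r_partial - r_raw
  )
}

#' Correlation network edge list
#'
#' Builds the weighted, signed edge list of the correlation network: one edge
#' per probe pair with `|r| >=` the threshold, weighted by the signed
#' correlation (edges span -1 to 1; negative edges are retained).
#'
#' @param x A correlation matrix or strain-summary tibble.
#' @param probes Optional restriction to a probe subset.
#' @param threshold Minimum `|r|` for an edge (default 0.5).
#' @return A `net_edges` tibble: `source`, `target`, `r`.
#' @export
network_graph <- function(x, probes = NULL, threshold = 0.5) {
  cm <- if (inherits(x, "cor_mat") || is.matrix(x)) unclass(x) else unclass(pearson_matrix(x, probes))
  if (!is.null(probes) && is.matrix(x)) cm <- cm[probes, probes, drop = FALSE]
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[ut]
  keep <- !is.na(r) & abs(r) >= threshold
  out <- tibble::tibble(
    source = rownames(cm)[ut[keep, 1]],
    target = colnames(cm)[ut[keep, 2]],
    r = r[keep]
  )
  structure(out, class = c("net_edges", class(out)))
}
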