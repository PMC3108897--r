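#' Search a genomic region for cis-acting candidate genes
#'
#' Implements the candidate-gene search behind trans-band dissection: within
#' a target region, select probes whose gene lies in the region and whose
#' peak QTL is cis-acting (same chromosome, within the exclusion buffer),
#' with peak LRS and mean expression inside broad search ranges. All bounds
#' are inclusive; coordinates are Mb.
#'
#' @param qtl A `qtl_tbl` from [map_eqtl()] (annotated, classified).
#' @param region_chr Chromosome of the target region.
#' @param region_start,region_end Region bounds in Mb (inclusive).
#' @param lrs_range Search range for peak LRS (default `c(15, 2000)`).
#' @param mean_range Search range for mean expression on the 2z+8 scale
#'   (default `c(7.5, 60)`).
#' @param cis_buffer Maximum gene-to-peak distance in Mb for a cis call
#'   (default 20).
#' @return A candidate-record tibble: `symbol`, `description` (if present),
#'   `probe_id`, `probe_target` (if present), `chr`, `mb`, `qtl_chr`,
#'   `qtl_mb`, `locus`, `max_lrs`, `mean_expr`.
#' @export
search_cis_candidates <- function(qtl, region_chr, region_start, region_end,
                                  lrs_range = c(15, 2000),
                                  mean_range = c(7.5, 60),
                                  cis_buffer = 20) {
  if (region_end < region_start) stop("empty region: end < start", call. = FALSE)
  qtl <- tibble::as_tibble(qtl)
  if (!"symbol" %in% names(qtl)) qtl$symbol <- NA_character_
  qtl |>
    dplyr::filter(
      !is.na(.data$chr), !is.na(.data$mb),
      as.character(.data$chr) == as.character(region_chr),
      .data$mb >= region_start, .data$mb <= region_end,
      as.character(.data$peak_chr) == as.character(.data$chr),
      abs(.data$peak_mb - .data$mb) <= cis_buffer,
      .data$lrs >= lrs_range[1], .data$lrs <= lrs_range[2],
      .data$mean_expr >= mean_range[1], .data$mean_expr <= mean_range[2]
    ) |>
    dplyr::transmute(
      symbol = .data$symbol,
      description = if ("description" %in% names(qtl)) .data$description else NA_character_,
      probe_id = .data$probe_id,
      probe_target = if ("probe_target" %in% names(qtl)) .data$probe_target else NA_character_,
      chr = as.character(.data$chr), mb = .data$mb,
      qtl_chr = as.character(.data$peak_chr), qtl_mb = .data$peak_mb,
      locus = .data$peak_marker,
      max_lrs = .data$lrs, mean_expr = .data$mean_expr
    ) |>
    dplyr::arrange(.data$mb, .data$probe_id)
}

# A record counts as annotated when it carries a proper gene symbol:
# not empty, not a RIKEN clone id ("...Rik"), not a bare EST/GenBank
# accession (e.g. AW120700).
is_annotated_symbol <- function(symbol) {
  !is.na(symbol) & symbol != "" &
    !grepl("Rik$", symbol) &
    !grepl("^[A-Z]{1,2}[0-9]{5,}$", symbol)
}

#' Refine candidate records to a final gene list
#'
#' Applies the refinement rules to a candidate-record table: drop records
#' without a proper gene annotation (missing symbols, RIKEN `...Rik` clones,
#' bare EST accessions); drop records below the significant-linkage LRS cut
#' (default 17, p <= 0.05) or below the array-wide mean expression floor
#' (default 8 on the 2z+8 scale); drop explicitly excluded genes (e.g. a
#' gene already analysed as part of the network itself); then collapse
#' duplicate probes per gene, keeping the probe with maximal LRS. The
#' record-level drops commute; deduplication runs last so that a gene whose
#' strongest probe fails a filter can still be represented by a passing
#' probe.
#'
#' @param records Candidate-record tibble from [search_cis_candidates()] (or
#'   the packaged printed tables, see [retina_candidates()]).
#' @param lrs_min Minimum `max_lrs` (inclusive; default 17).
#' @param mean_min Minimum `mean_expr` (inclusive; default 8).
#' @param exclude Gene symbols to drop regardless of the filters.
#' @param keep Allow-list of gene symbols exempt from the LRS/mean filters
#'   (the manual exception pathway for e.g. a strong cis gene just under the
#'   expression floor); never applied automatically.
#' @param cv_min Optional minimum coefficient of variation; applied only when
#'   the records carry a `cv` column.
#' @return Tibble of surviving records, one row per gene, sorted by genome
#'   position; the final gene list is its `symbol` column.
#' @export
refine_candidates <- function(records, lrs_min = 17, mean_min = 8,
                              exclude = character(), keep = character(),
                              cv_min = NULL) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) return(records)
  needed <- c("symbol", "probe_id", "max_lrs", "mean_expr")
  missing_c <- setdiff(needed, names(records))
  if (length(missing_c)) {
    stop("records lack columns: ", paste(missing_c, collapse = ", "), call. = FALSE)
  }
  kept <- records |>
    dplyr::filter(
      is_annotated_symbol(.data$symbol),
      !.data$symbol %in% exclude,
      .data$symbol %in% keep |
        (.data$max_lrs >= lrs_min & .data$mean_expr >= mean_min)
    )
  if (!is.null(cv_min) && "cv" %in% names(kept)) {
    kept <- dplyr::filter(kept, .data$cv >= cv_min)
  }
  out <- kept |>
    dplyr::group_by(.data$symbol) |>
    dplyr::slice_max(.data$max_lrs, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  if (all(c("chr", "mb") %in% names(out))) {
    out <- dplyr::arrange(out, .data$chr, .data$mb, .data$symbol)
  } else {
    out <- dplyr::arrange(out, .data$symbol)
  }
  out
}

#' Prioritize candidates by correlation with a network
#'
#' Keeps the candidates whose expression correlates with at least one
#' network gene at `|r| >=` the threshold, and annotates every kept
#' candidate with its signed correlation to each network gene — a positive
#' sign reads as a candidate tracking the network, a negative sign as a
#' potential negative modulator.
#'
#' @param candidates Refined candidate tibble (needs `probe_id` and
#'   `symbol`), or a character vector of trait column names.
#' @param summary Strain-summary tibble containing both the candidate and
#'   the network traits as columns.
#' @param network Character vector of network trait column names.
#' @param r_threshold Minimum `|r|` against at least one network gene
#'   (default 0.5).
#' @return Long tibble over kept candidates: `candidate`, `network_gene`,
#'   `r`. Attribute `dropped` lists the candidates that failed the
#'   threshold.
#' @export
prioritize_by_network <- function(candidates, summary, network, r_threshold = 0.5) {
  summary <- tibble::as_tibble(summary)
  if (is.character(candidates)) {
    cand <- tibble::tibble(label = candidates, column = candidates)
  } else {
    candidates <- tibble::as_tibble(candidates)
    cand <- tibble::tibble(
      label = if ("symbol" %in% names(candidates)) candidates$symbol else candidates$probe_id,
      column = candidates$probe_id
    )
  }
  missing_c <- setdiff(c(cand$column, network), names(summary))
  if (length(missing_c)) {
    stop("traits absent from summary: ", paste(missing_c, collapse = ", "), call. = FALSE)
  }
  R <- suppressWarnings(stats::cor(
    as.matrix(summary[, cand$column, drop = FALSE]),
    as.matrix(summary[, network, drop = FALSE]),
    use = "pairwise.complete.obs"
  ))
  keep <- apply(abs(R) >= r_threshold, 1, any, na.rm = TRUE)
  long <- tibble::tibble(
    candidate = rep(cand$label, times = length(network)),
    network_gene = rep(network, each = nrow(cand)),
    r = as.vector(R)
  ) |>
    dplyr::filter(.data$candidate %in% cand$label[keep]) |>
    dplyr::arrange(.data$candidate, .data$network_gene)
  structure(long, dropped = cand$label[!keep])
}

#' Packaged candidate-gene tables from the mouse retina BXD study
#'
#' Printed candidate-record tables for the two trans-band regions dissected
#' in the Gap43/Pten retinal ganglion cell network of the HEI Retina
#' Database (BXD panel): the distal chromosome 2 band (169-182 Mb, 18
#' records) and the chromosome 15 band (82-92 Mb, 20 records). Columns
#' mirror [search_cis_candidates()] output.
#'
#' @param region `"chr2"` or `"chr15"`.
#' @return Candidate-record tibble.
#' @export
retina_candidates <- function(region = c("chr2", "chr15")) {
  region <- match.arg(region)
  file <- system.file("extdata",
    paste0("retina_candidates_", region, ".tsv"),
    package = "bxdnet", mustWork = TRUE
  )
  readr::read_tsv(file, show_col_types = FALSE,
    col_types = readr::cols(
      symbol = "c", description = "c", probe_id = "c", probe_target = "c",
      chr = "c", qtl_chr = "c", locus = "c", .default = "d"
    )
  )
}

#' Packaged correlation matrix of the Gap43/Pten network core
#'
#' The published 8-gene Pearson correlation matrix of the Gap43/Pten
#' retinal network core (Neurod1, Pax6, Pcna, Sox2, Id2, Gap43, Pten,
#' Zbed4) over BXD strain means.
#'
#' @return A symmetric `cor_mat` matrix.
#' @export
retina_network_cor <- function() {
  file <- system.file("extdata", "retina_network_cor.tsv",
    package = "bxdnet", mustWork = TRUE
  )
  tb <- readr::read_tsv(file, show_col_types = FALSE)
  m <- as.matrix(tb[, -1])
  rownames(m) <- tb[[1]]
  structure(m, class = c("cor_mat", class(m)))
}
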