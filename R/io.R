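#' Write / read genotypes in a GeneNetwork-style text dialect
#'
#' Tab-separated text with a header row naming the fixed columns
#' (`Chr`, `Locus`, `cM`, `Mb`) followed by one column per strain; each body
#' row holds a marker's chromosome, name, genetic and physical position and
#' one allele code per strain. Allele codes are restricted to `B`, `D`, `H`
#' (heterozygous) and `U` (unknown).
#'
#' @param geno Genotype tibble (`marker`, `chr`, `cm`, `mb`, strain columns).
#' @param path File path.
#' @return `write_genotypes()` returns `path` invisibly; `read_genotypes()`
#'   returns a genotype tibble.
#' @export
write_genotypes <- function(geno, path) {
  strains <- geno_strains(geno)
  header <- c("Chr", "Locus", "cM", "Mb", strains)
  body <- cbind(
    geno$chr, geno$marker,
    format(geno$cm, trim = TRUE, scientific = FALSE),
    format(geno$mb, trim = TRUE, scientific = FALSE),
    as.matrix(geno[, strains, drop = FALSE])
  )
  lines <- c(
    paste(header, collapse = "\t"),
    apply(body, 1, paste, collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|@)", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) stop("genotype file has no data rows", call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 5 || !identical(header[1:4], c("Chr", "Locus", "cM", "Mb"))) {
    stop("genotype header must start with Chr, Locus, cM, Mb followed by strain names",
      call. = FALSE
    )
  }
  strains <- header[-(1:4)]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  n_col <- length(header)
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != n_col) {
      stop(sprintf(
        "line %d: %d fields but header declares %d strains (%d fields)",
        i + 1L, length(f), length(strains), n_col
      ), call. = FALSE)
    }
    alleles <- f[-(1:4)]
    bad <- !alleles %in% c("B", "D", "H", "U")
    if (any(bad)) {
      stop(sprintf(
        "line %d: invalid allele code '%s' for strain %s",
        i + 1L, alleles[bad][1], strains[bad][1]
      ), call. = FALSE)
    }
    out[[i]] <- f
  }
  m <- do.call(rbind, out)
  markers <- m[, 2]
  dup <- duplicated(markers)
  if (any(dup)) {
    stop("duplicated marker name(s): ", paste(unique(markers[dup]), collapse = ", "),
      call. = FALSE
    )
  }
  calls <- m[, -(1:4), drop = FALSE]
  colnames(calls) <- strains
  dplyr::bind_cols(
    tibble::tibble(
      marker = markers,
      chr = m[, 1],
      cm = as.numeric(m[, 3]),
      mb = as.numeric(m[, 4])
    ),
    tibble::as_tibble(calls)
  )
}

#' Write / read an expression matrix with its sample sheet
#'
#' The expression matrix is TSV with probes as rows (`probe_id` column) and
#' samples as columns; the sample sheet is TSV with columns `sample`,
#' `strain` and optionally `sex` and `replicate_group`. On read, every sheet
#' sample must be present in the matrix; matrix samples absent from the
#' sheet are dropped with a warning.
#'
#' @param expr Expression tibble (`probe_id` + sample columns).
#' @param path,sample_sheet_path File paths.
#' @param samples Sample sheet tibble (for writing).
#' @return Readers return tibbles; writers return the path invisibly.
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr, path)
  invisible(path)
}

#' @rdname write_expression
#' @export
write_sample_sheet <- function(samples, path) {
  readr::write_tsv(samples, path)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path, sample_sheet_path = NULL) {
  expr <- readr::read_tsv(path, show_col_types = FALSE,
    col_types = readr::cols(probe_id = "c", .default = "c")
  )
  if (!"probe_id" %in% names(expr)) stop("expression matrix lacks a probe_id column", call. = FALSE)
  for (col in setdiff(names(expr), "probe_id")) {
    x <- expr[[col]]
    conv <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "NA" & is.na(conv))
    if (length(bad)) {
      stop(sprintf(
        "non-numeric expression value '%s' at probe %s, sample %s",
        x[bad[1]], expr$probe_id[bad[1]], col
      ), call. = FALSE)
    }
    expr[[col]] <- conv
  }
  if (is.null(sample_sheet_path)) {
    return(expr)
  }
  sheet <- readr::read_tsv(sample_sheet_path, show_col_types = FALSE,
    col_types = readr::cols(.default = "c")
  )
  if (!all(c("sample", "strain") %in% names(sheet))) {
    stop("sample sheet must have columns `sample` and `strain`", call. = FALSE)
  }
  cols <- setdiff(names(expr), "probe_id")
  absent <- setdiff(sheet$sample, cols)
  if (length(absent)) {
    stop("sheet sample(s) absent from matrix: ", paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  extra <- setdiff(cols, sheet$sample)
  if (length(extra)) {
    warning("matrix sample(s) not in sheet dropped: ", paste(extra, collapse = ", "),
      call. = FALSE
    )
    expr <- expr[, c("probe_id", sheet$sample), drop = FALSE]
  }
  list(expression = expr, samples = sheet)
}

#' Write / read a strain summary table
#'
#' @param summary Strain-summary tibble from [strain_means()].
#' @param path File path.
#' @export
write_strain_summary <- function(summary, path) {
  readr::write_tsv(summary, path)
  invisible(path)
}

#' @rdname write_strain_summary
#' @export
read_strain_summary <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
    col_types = readr::cols(strain = "c", .default = "d")
  )
}

#' Pipeline configuration
#'
#' Bundles input paths (or in-memory objects) and every analysis threshold,
#' each defaulting to its conventional value: cis window and exclusion
#' buffer 20 Mb, significant-QTL LRS 15, candidate LRS 17, candidate mean
#' floor 8, search ranges LRS 15-2000 and mean 7.5-60, correlation
#' threshold 0.5, band bin 25 Mb with support fraction 0.3, collection size
#' 100. Unknown keys are rejected.
#'
#' @param genotypes,expression,samples,annotation Paths or objects.
#' @param out_dir Output directory for stage TSVs and the run manifest.
#' @param ... Threshold overrides (see Details).
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes, expression, samples, annotation = NULL,
                            out_dir = tempfile("bxdnet_run_"), ..., seed = 1) {
  defaults <- list(
    cis_window = 20, lrs_significant = 15, lrs_candidate = 17,
    mean_min = 8, lrs_search = c(15, 2000), mean_search = c(7.5, 60),
    cis_buffer = 20, correlation_min = 0.5, band_bin_mb = 25,
    band_support = 0.3, collection_size = 100,
    seed_probe = NULL, region = NULL, exclude = character()
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, dots)
  cfg$genotypes <- genotypes
  cfg$expression <- expression
  cfg$samples <- samples
  cfg$annotation <- annotation
  cfg$out_dir <- out_dir
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes normalize -> strain means -> eQTL mapping/classification, and,
#' when configured, the trait-collection/heat-map/band stage (a `seed_probe`
#' is set) and the candidate search/refinement stage (a `region` is set).
#' Every stage writes its table as TSV into `out_dir`, and a JSON manifest
#' records the seed, thresholds and completed stages so a run can be
#' reproduced exactly.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, f) {
    tryCatch(f(), error = function(e) {
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  as_obj <- function(x, reader) if (is.character(x) && length(x) == 1) reader(x) else tibble::as_tibble(x)

  geno <- stage("read_genotypes", function() {
    if (is.character(config$genotypes)) read_genotypes(config$genotypes) else config$genotypes
  })
  expr <- stage("read_expression", function() as_obj(config$expression, read_expression))
  samples <- stage("read_samples", function() {
    as_obj(config$samples, function(p) {
      readr::read_tsv(p, show_col_types = FALSE, col_types = readr::cols(.default = "c"))
    })
  })
  annotation <- if (is.null(config$annotation)) {
    NULL
  } else {
    stage("read_annotation", function() {
      as_obj(config$annotation, function(p) readr::read_tsv(p, show_col_types = FALSE))
    })
  }

  completed <- character()
  mark <- function(name) completed <<- c(completed, name)

  normalized <- stage("normalize", function() normalize_arrays(expr))
  readr::write_tsv(normalized, file.path(config$out_dir, "normalized.tsv"))
  mark("normalize")

  summary <- stage("strain_means", function() strain_means(normalized, samples))
  write_strain_summary(summary, file.path(config$out_dir, "strain_summary.tsv"))
  mark("strain_means")

  qtl <- stage("map_eqtl", function() {
    map_eqtl(summary, geno, annotation, cis_window = config$cis_window)
  })
  readr::write_tsv(qtl, file.path(config$out_dir, "qtl.tsv"))
  mark("map_eqtl")

  census <- count_significant(qtl, config$lrs_significant)
  readr::write_tsv(census, file.path(config$out_dir, "qtl_census.tsv"))
  mark("census")

  collection <- heatmap <- bands <- NULL
  if (!is.null(config$seed_probe)) {
    collection <- stage("collection", function() {
      top_correlates(summary, config$seed_probe, n = config$collection_size)
    })
    readr::write_tsv(collection, file.path(config$out_dir, "collection.tsv"))
    heatmap <- stage("heatmap", function() qtl_heatmap(collection, summary, geno))
    hm_tbl <- tibble::as_tibble(heatmap$values, rownames = "probe")
    readr::write_tsv(hm_tbl, file.path(config$out_dir, "heatmap.tsv"))
    bands <- stage("bands", function() {
      detect_bands(heatmap,
        bin_mb = config$band_bin_mb,
        lrs_threshold = config$lrs_significant,
        support_fraction = config$band_support
      )
    })
    readr::write_tsv(bands, file.path(config$out_dir, "signature_bands.tsv"))
    mark("signature")
  }

  candidates <- refined <- NULL
  if (!is.null(config$region)) {
    candidates <- stage("candidates", function() {
      search_cis_candidates(qtl,
        region_chr = config$region$chr,
        region_start = config$region$start,
        region_end = config$region$end,
        lrs_range = config$lrs_search,
        mean_range = config$mean_search,
        cis_buffer = config$cis_buffer
      )
    })
    readr::write_tsv(candidates, file.path(config$out_dir, "candidates.tsv"))
    refined <- stage("refine", function() {
      refine_candidates(candidates,
        lrs_min = config$lrs_candidate,
        mean_min = config$mean_min,
        exclude = config$exclude
      )
    })
    readr::write_tsv(refined, file.path(config$out_dir, "candidates_refined.tsv"))
    mark("candidates")
  }

  manifest <- list(
    package = "bxdnet",
    version = as.character(utils::packageVersion("bxdnet")),
    seed = config$seed,
    thresholds = config[c(
      "cis_window", "lrs_significant", "lrs_candidate", "mean_min",
      "lrs_search", "mean_search", "cis_buffer", "correlation_min",
      "band_bin_mb", "band_support", "collection_size"
    )],
    seed_probe = config$seed_probe,
    region = config$region,
    stages_completed = completed
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(list(
    normalized = normalized, summary = summary, qtl = qtl, census = census,
    collection = collection, heatmap = heatmap, bands = bands,
    candidates = candidates, refined = refined, manifest = manifest
  ))
}
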