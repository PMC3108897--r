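#' Configure a synthetic RI panel
#'
#' Describes the panel geometry used by [simulate_ri_genotypes()]: how many
#' fully inbred strains, the chromosomes and their physical lengths, marker
#' spacing, and the map scaling used to convert physical distance to genetic
#' distance. Defaults emulate a BXD-like family: 75 strains over 19 autosomes
#' (roughly 2,560 Mb of genome, so cumulative coordinates span ~1-2600 Mb).
#'
#' @param n_strains Number of RI strains (>= 2).
#' @param chromosomes Named numeric vector of chromosome lengths in Mb, in
#'   genome order.
#' @param marker_spacing Distance between adjacent markers in Mb (> 0).
#' @param cm_per_mb Map scaling: centiMorgans per megabase (default 0.5, a
#'   typical genome-wide average for the mouse).
#' @param mating `"sib"` (default; brother-sister mated RI lines such as BXD)
#'   or `"selfing"`. Controls the map-expansion formula, see
#'   [ri_map_expansion()].
#' @param u_rate Per-call probability of replacing a genotype with an unknown
#'   (`"U"`) call, to exercise missing-data handling. Default 0 (fully typed).
#' @param seed Integer seed; identical seeds give identical panels.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_strains = 20, chromosomes = c(chr1 = 100), seed = 1)
sim_config <- function(n_strains = 75,
                       chromosomes = mouse_autosomes(),
                       marker_spacing = 5,
                       cm_per_mb = 0.5,
                       mating = c("sib", "selfing"),
                       u_rate = 0,
                       seed = 1) {
  mating <- match.arg(mating)
  if (n_strains < 2) stop("`n_strains` must be at least 2", call. = FALSE)
  if (length(chromosomes) == 0 || any(chromosomes <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  if (marker_spacing <= 0) stop("`marker_spacing` must be > 0", call. = FALSE)
  if (cm_per_mb <= 0) stop("`cm_per_mb` must be > 0", call. = FALSE)
  if (u_rate < 0 || u_rate > 1) stop("`u_rate` must be in [0, 1]", call. = FALSE)
  if (is.null(names(chromosomes))) {
    names(chromosomes) <- as.character(seq_along(chromosomes))
  }
  structure(
    list(
      n_strains = as.integer(n_strains),
      chromosomes = chromosomes,
      marker_spacing = marker_spacing,
      cm_per_mb = cm_per_mb,
      mating = mating,
      u_rate = u_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Approximate mouse autosome lengths in Mb
#'
#' @return Named numeric vector of 19 autosome lengths.
#' @export
mouse_autosomes <- function() {
  c(
    `1` = 195, `2` = 182, `3` = 160, `4` = 157, `5` = 152, `6` = 150,
    `7` = 145, `8` = 129, `9` = 124, `10` = 131, `11` = 122, `12` = 120,
    `13` = 120, `14` = 125, `15` = 104, `16` = 98, `17` = 95, `18` = 91,
    `19` = 61
  )
}

#' Haldane recombination fraction
#'
#' Converts a genetic distance in centiMorgans to a single-meiosis
#' recombination fraction under the Haldane (no-interference) map function,
#' r = (1 - exp(-2d/100)) / 2.
#'
#' @param d_cm Genetic distance in cM (>= 0).
#' @return Recombination fraction in \[0, 0.5).
#' @export
haldane_r <- function(d_cm) {
  stopifnot(all(d_cm >= 0))
  0.5 * (1 - exp(-2 * d_cm / 100))
}

#' RI map expansion
#'
#' In recombinant inbred lines, repeated rounds of meiosis inflate the
#' frequency of observed recombinant haplotypes between linked markers
#' relative to a single meiosis. For sib-mated autosomes the fixed-line
#' switching probability is R = 4r / (1 + 6r); for selfed lines it is
#' R = 2r / (1 + 2r).
#'
#' @param r Single-meiosis recombination fraction(s).
#' @param mating `"sib"` or `"selfing"`.
#' @return Expected fraction of strains whose alleles differ between the two
#'   markers.
#' @export
ri_map_expansion <- function(r, mating = c("sib", "selfing")) {
  mating <- match.arg(mating)
  switch(mating,
    sib = 4 * r / (1 + 6 * r),
    selfing = 2 * r / (1 + 2 * r)
  )
}

#' Simulate genotypes for a fully inbred RI panel
#'
#' Each strain is an independent realisation of a two-state Markov chain along
#' each chromosome: the allele at the first marker is B or D with equal
#' probability, and the allele switches between adjacent markers with
#' probability equal to the RI map expansion of the Haldane recombination
#' fraction implied by the marker spacing (see [ri_map_expansion()]).
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `marker`, `chr`, `cm`, `mb` followed by one
#'   column per strain holding allele codes (`"B"`/`"D"`, plus `"U"` when
#'   `u_rate > 0`).
#' @export
#' @examples
#' geno <- simulate_ri_genotypes(sim_config(n_strains = 10, seed = 42))
simulate_ri_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  map <- build_marker_grid(config)
  n <- config$n_strains
  strains <- sprintf("BXS%03d", seq_len(n))

  calls <- matrix(NA_character_, nrow = nrow(map), ncol = n)
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    cm <- map$cm[idx]
    # switching probability between consecutive markers on this chromosome
    R <- ri_map_expansion(haldane_r(diff(cm)), config$mating)
    first <- sample(c("B", "D"), n, replace = TRUE)
    chrom <- matrix(NA_character_, nrow = length(idx), ncol = n)
    chrom[1L, ] <- first
    if (length(idx) > 1L) {
      for (k in seq_along(R)) {
        flip <- stats::runif(n) < R[k]
        prev <- chrom[k, ]
        chrom[k + 1L, ] <- ifelse(flip, ifelse(prev == "B", "D", "B"), prev)
      }
    }
    calls[idx, ] <- chrom
  }
  if (config$u_rate > 0) {
    u <- stats::runif(length(calls)) < config$u_rate
    calls[u] <- "U"
  }
  colnames(calls) <- strains
  dplyr::bind_cols(map, tibble::as_tibble(calls))
}

# marker grid for a sim_config: marker every `marker_spacing` Mb per chromosome
build_marker_grid <- function(config) {
  purrr::imap_dfr(as.list(config$chromosomes), function(len, ch) {
    mb <- seq(0, len, by = config$marker_spacing)
    tibble::tibble(
      marker = sprintf("m%s_%03d", ch, seq_along(mb)),
      chr = ch,
      cm = mb * config$cm_per_mb,
      mb = mb
    )
  })
}

#' Strain columns of a genotype table
#'
#' @param geno Genotype tibble as produced by [simulate_ri_genotypes()] or
#'   [read_genotypes()].
#' @return Character vector of strain column names.
#' @export
geno_strains <- function(geno) {
  setdiff(names(geno), c("marker", "chr", "cm", "mb"))
}

#' Declare the true eQTL architecture of a synthetic panel
#'
#' Records every implanted effect so downstream recovery can be scored against
#' ground truth: cis effects (one marker driving its own probe), trans
#' regulators (one hotspot marker driving a set of target probes), and latent
#' co-expression modules (probes loading on a shared strain-level factor).
#'
#' @param probes Character vector of probe ids.
#' @param baseline Per-probe baseline mean on the log2 scale; scalar or vector
#'   named by probe (default 8).
#' @param cis_effects Tibble with columns `probe`, `marker`, `beta` (log2
#'   expression units per D allele), or `NULL`.
#' @param trans_regulators Tibble with columns `marker`, `probe`, `beta`, or
#'   `NULL`.
#' @param modules Tibble with columns `module`, `probe`, `loading`, or `NULL`.
#' @param noise_sd Residual SD in log2 units (>= 0).
#' @return A list of class `true_architecture`.
#' @export
true_architecture <- function(probes,
                              baseline = 8,
                              cis_effects = NULL,
                              trans_regulators = NULL,
                              modules = NULL,
                              noise_sd = 0.3) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  probes <- as.character(probes)
  if (anyDuplicated(probes)) stop("duplicated probe ids", call. = FALSE)
  base <- rep_len(baseline, length(probes))
  if (!is.null(names(baseline))) base <- baseline[probes]
  names(base) <- probes
  chk <- function(tb, cols, what) {
    if (is.null(tb)) {
      proto <- lapply(cols, function(cl) {
        if (cl %in% c("beta", "loading")) numeric() else character()
      })
      return(tibble::tibble(!!!rlang::set_names(proto, cols)))
    }
    tb <- tibble::as_tibble(tb)
    if (!all(cols %in% names(tb))) {
      stop(sprintf("`%s` needs columns %s", what, paste(cols, collapse = ", ")), call. = FALSE)
    }
    bad <- setdiff(tb$probe, probes)
    if (length(bad)) stop(sprintf("unknown probes in `%s`: %s", what, paste(bad, collapse = ", ")), call. = FALSE)
    tb
  }
  structure(
    list(
      probes = probes,
      baseline = base,
      cis_effects = chk(cis_effects, c("probe", "marker", "beta"), "cis_effects"),
      trans_regulators = chk(trans_regulators, c("marker", "probe", "beta"), "trans_regulators"),
      modules = chk(modules, c("module", "probe", "loading"), "modules"),
      noise_sd = noise_sd
    ),
    class = "true_architecture"
  )
}

#' Simulate raw array expression for an RI panel
#'
#' Generates raw (linear-scale) signal so that taking log2 downstream recovers
#' an additive linear model: for sample i of strain s and probe j,
#' `signal = 2 ^ (baseline_j + sum(beta * x_s) + sum(loading * latent_s) + e_ij)`
#' where `x_s` codes the strain's allele at the effect marker (B = 0, D = 1),
#' `latent_s` is a strain-level standard normal module factor, and
#' `e_ij ~ N(0, noise_sd^2)`. Genetic and module effects are shared by all
#' samples of a strain; residual noise is per sample.
#'
#' @param geno Genotype tibble from [simulate_ri_genotypes()].
#' @param arch A [true_architecture()] whose markers all exist in `geno`.
#' @param n_biological Independent biological samples per strain (default 2).
#' @param n_technical Technical replicates per biological sample (default 1).
#' @param seed Integer seed.
#' @return A list with `expression` (tibble: `probe_id` + one column per
#'   sample, raw signal), `samples` (tibble: `sample`, `strain`, `sex`,
#'   `replicate_group`), and `truth` (tibble of implanted effects:
#'   `probe`, `kind`, `marker`, `module`, `effect`).
#' @export
simulate_expression <- function(geno, arch, n_biological = 2, n_technical = 1,
                                seed = 1) {
  stopifnot(inherits(arch, "true_architecture"))
  markers_needed <- unique(c(arch$cis_effects$marker, arch$trans_regulators$marker))
  missing_m <- setdiff(markers_needed, geno$marker)
  if (length(missing_m)) {
    stop("architecture references unknown markers: ", paste(missing_m, collapse = ", "),
      call. = FALSE
    )
  }
  set.seed(seed)
  strains <- geno_strains(geno)
  n_s <- length(strains)
  probes <- arch$probes
  n_p <- length(probes)

  # strain-level genetic value per probe
  g <- matrix(0, nrow = n_p, ncol = n_s, dimnames = list(probes, strains))
  x_at <- function(marker) {
    row <- geno[geno$marker == marker, strains, drop = FALSE]
    x <- as.numeric(unlist(row) == "D")
    x[unlist(row) == "U" | unlist(row) == "H"] <- NA_real_
    # unknown calls contribute the panel-average genotype (0.5)
    x[is.na(x)] <- 0.5
    x
  }
  eff <- dplyr::bind_rows(
    dplyr::transmute(arch$cis_effects, probe = .data$probe, marker = .data$marker, beta = .data$beta),
    dplyr::transmute(arch$trans_regulators, probe = .data$probe, marker = .data$marker, beta = .data$beta)
  )
  if (nrow(eff)) {
    for (m in unique(eff$marker)) {
      x <- x_at(m)
      sub <- eff[eff$marker == m, ]
      for (k in seq_len(nrow(sub))) {
        g[sub$probe[k], ] <- g[sub$probe[k], ] + as.numeric(sub$beta[k]) * x
      }
    }
  }
  # strain-level latent module factors
  if (nrow(arch$modules)) {
    for (mod in unique(arch$modules$module)) {
      latent <- stats::rnorm(n_s)
      sub <- arch$modules[arch$modules$module == mod, ]
      for (k in seq_len(nrow(sub))) {
        g[sub$probe[k], ] <- g[sub$probe[k], ] + as.numeric(sub$loading[k]) * latent
      }
    }
  }

  sheet <- tidyr::expand_grid(
    strain = strains,
    bio = seq_len(n_biological),
    tech = seq_len(n_technical)
  ) |>
    dplyr::mutate(
      sample = sprintf("%s_b%d_t%d", .data$strain, .data$bio, .data$tech),
      sex = ifelse(.data$bio %% 2 == 1, "F", "M"),
      replicate_group = sprintf("%s_b%d", .data$strain, .data$bio)
    ) |>
    dplyr::select("sample", "strain", "sex", "replicate_group")

  idx <- match(sheet$strain, strains)
  mu <- arch$baseline[probes] + g[, idx, drop = FALSE]
  noise <- matrix(stats::rnorm(n_p * nrow(sheet), sd = arch$noise_sd),
    nrow = n_p
  )
  signal <- 2^(mu + noise)
  colnames(signal) <- sheet$sample
  expr <- dplyr::bind_cols(
    tibble::tibble(probe_id = probes),
    tibble::as_tibble(signal)
  )

  truth <- dplyr::bind_rows(
    dplyr::transmute(arch$cis_effects,
      probe = .data$probe, kind = "cis",
      marker = .data$marker, module = NA_character_, effect = as.numeric(.data$beta)
    ),
    dplyr::transmute(arch$trans_regulators,
      probe = .data$probe, kind = "trans",
      marker = .data$marker, module = NA_character_, effect = as.numeric(.data$beta)
    ),
    dplyr::transmute(arch$modules,
      probe = .data$probe, kind = "module",
      marker = NA_character_, module = as.character(.data$module), effect = as.numeric(.data$loading)
    )
  )
  list(expression = expr, samples = sheet, truth = truth)
}
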