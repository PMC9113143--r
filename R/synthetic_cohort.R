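#' Specification of a synthetic single-cell mtDNA cohort
#'
#' Describes a cohort of single cells with per-site, strand-resolved mtDNA
#' allele counts and planted ground truth. The generator emulates the
#' structure of single-cell ATAC-derived mtDNA count tables: germline variants
#' near VAF 1 shared by all cells, somatic variants (explicit VAF table or
#' Wright-Fisher simulated per cell type), homopolymer artifact sites,
#' strand-asymmetric oxidative-damage errors (G>T / C>A), and per-cell depth
#' variation.
#'
#' @param cell_types Tibble with `label`, `n_cells`, `baseline_copy_number`.
#' @param depth_mean Mean per-site read depth.
#' @param depth_dispersion Negative-binomial size parameter of per-site depth
#'   (smaller = more overdispersed).
#' @param depth_cell_shape Gamma shape of the per-cell depth factor (mean 1);
#'   models cell-to-cell coverage variation.
#' @param germline_variants Tibble with `site` and `alt` (reference base taken
#'   from `genome`); planted at true VAF 1 in every cell.
#' @param somatic_vafs Explicit somatic plan: tibble with `site`, `alt`,
#'   `vaf`, `n_carriers`; each variant is planted at `vaf` in `n_carriers`
#'   randomly chosen cells. Somatic plants may not use the damage substitution
#'   types G>T / C>A (those are, by design, removed by the filter cascade).
#' @param somatic_sim Alternative somatic source: named list mapping cell-type
#'   labels to [sim_params()]; each cell's true VAFs then come from an
#'   independent Wright-Fisher lineage and are assigned random sites.
#' @param error_rate Background per-read substitution error probability
#'   applied at every site (alt base drawn at random); 0 disables.
#' @param artifact_sites Integer positions seeded with spurious alt reads
#'   (defaults to none; use [default_site_blacklist()] to exercise the
#'   blacklist filter).
#' @param artifact_vaf,artifact_cell_fraction Apparent VAF of artifact alt
#'   reads and the fraction of cells showing them.
#' @param n_damage_sites Number of G/C sites planted with damage-type
#'   (G>T or C>A) alt reads.
#' @param damage_rate Per-read alt probability at damage sites.
#' @param damage_strand_bias Forward-read fraction of damage alt reads
#'   (strongly asymmetric, mirroring the oxidative-damage mechanism).
#' @param strand_fwd,strand_sd Expected forward-read fraction and its
#'   per-(cell, site) Gaussian noise for genuine alleles.
#' @param total_read_scale Scale linking the copy-number proxy to baseline
#'   copies: `total_reads = mito_reads * total_read_scale / baseline`.
#' @param genome Reference sequence (defaults to the bundled synthetic one).
#' @param seed Integer RNG seed; identical seeds give identical cohorts.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(cell_types = tibble::tibble(label = "B", n_cells = 50L,
                                                    baseline_copy_number = 500),
                        depth_mean = 60, depth_dispersion = 8,
                        depth_cell_shape = 8,
                        germline_variants = NULL,
                        somatic_vafs = NULL,
                        somatic_sim = NULL,
                        error_rate = 0,
                        artifact_sites = integer(0),
                        artifact_vaf = 0.10, artifact_cell_fraction = 0.5,
                        n_damage_sites = 0L,
                        damage_rate = 0.05, damage_strand_bias = 0.95,
                        strand_fwd = 0.5, strand_sd = 0.02,
                        total_read_scale = 5000,
                        genome = synthetic_mt_genome(),
                        seed = 1L) {
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  if (!all(c("label", "n_cells", "baseline_copy_number") %in% names(cell_types))) {
    note("cell_types: needs columns label, n_cells, baseline_copy_number")
  } else if (any(cell_types$n_cells <= 0)) {
    note("cell_types: n_cells must be > 0")
  }
  check_sites <- function(sites, field) {
    if (length(sites) > 0 && (any(sites < 1) || any(sites > MT_GENOME_LENGTH))) {
      note(sprintf("%s: sites must lie in 1..%d", field, MT_GENOME_LENGTH))
    }
  }
  if (!is.null(germline_variants)) check_sites(germline_variants$site, "germline_variants")
  if (!is.null(somatic_vafs)) {
    check_sites(somatic_vafs$site, "somatic_vafs")
    if (any(somatic_vafs$vaf < 0 | somatic_vafs$vaf > 1)) {
      note("somatic_vafs: vaf must lie in [0, 1]")
    }
  }
  check_sites(artifact_sites, "artifact_sites")
  for (field in c("error_rate", "artifact_vaf", "artifact_cell_fraction",
                  "damage_rate", "damage_strand_bias", "strand_fwd")) {
    val <- get(field)
    if (val < 0 || val > 1) note(sprintf("%s: must lie in [0, 1]", field))
  }
  if (depth_mean < 0) note("depth_mean: must be >= 0")
  if (depth_dispersion <= 0) note("depth_dispersion: must be > 0")
  if (!is.null(somatic_sim) &&
      !all(vapply(somatic_sim, inherits, logical(1), "sim_params"))) {
    note("somatic_sim: every element must be a sim_params object")
  }
  if (length(problems) > 0) {
    stop("invalid cohort specification:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  structure(list(
    cell_types = tibble::as_tibble(cell_types),
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    depth_cell_shape = depth_cell_shape,
    germline_variants = germline_variants, somatic_vafs = somatic_vafs,
    somatic_sim = somatic_sim, error_rate = error_rate,
    artifact_sites = as.integer(artifact_sites),
    artifact_vaf = artifact_vaf,
    artifact_cell_fraction = artifact_cell_fraction,
    n_damage_sites = as.integer(n_damage_sites),
    damage_rate = damage_rate, damage_strand_bias = damage_strand_bias,
    strand_fwd = strand_fwd, strand_sd = strand_sd,
    total_read_scale = total_read_scale,
    genome = genome, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Strand-resolved counts at one (cell, site)
#'
#' Draws alt reads binomially from the true VAF (inflated by a per-read error
#' rate), then splits ref and alt reads between strands.
#'
#' @param true_vaf True variant allele fraction in `[0, 1]`.
#' @param depth Total read depth (>= 0).
#' @param strand_fwd Expected forward-read fraction for ref and (by default)
#'   alt reads.
#' @param error_rate Per-read probability that a reference molecule is read as
#'   the alt base.
#' @param alt_strand_fwd Forward fraction for alt reads (set near 1 to emulate
#'   strand-asymmetric damage).
#' @return Named integer vector `ref_fwd`, `ref_rev`, `alt_fwd`, `alt_rev`
#'   summing to `depth`.
#' @export
simulate_site_counts <- function(true_vaf, depth, strand_fwd = 0.5,
                                 error_rate = 0, alt_strand_fwd = strand_fwd) {
  if (depth < 0) stop("depth must be >= 0")
  stopifnot(true_vaf >= 0, true_vaf <= 1, error_rate >= 0, error_rate <= 1)
  p_alt <- true_vaf + (1 - true_vaf) * error_rate
  alt <- rbinom(1, depth, p_alt)
  ref <- depth - alt
  alt_fwd <- rbinom(1, alt, alt_strand_fwd)
  ref_fwd <- rbinom(1, ref, strand_fwd)
  c(ref_fwd = ref_fwd, ref_rev = ref - ref_fwd,
    alt_fwd = alt_fwd, alt_rev = alt - alt_fwd)
}

#' Generate a synthetic cohort with ground truth
#'
#' Produces a strand-resolved allele-count matrix plus the truth table of
#' every planted variant (class `germline`, `somatic`, `artifact` or
#' `damage_error`) and per-cell true VAFs. Identical seeds give identical
#' cohorts.
#'
#' @param spec A [cohort_spec()].
#' @return List with `matrix` (an [allele_count_matrix()]) and `truth` (list
#'   of `variants` and `cell_vafs` tibbles).
#' @export
#' @examples
#' spec <- cohort_spec(cell_types = tibble::tibble(label = "B", n_cells = 4,
#'                                                 baseline_copy_number = 500),
#'                     depth_mean = 30, seed = 7)
#' cohort <- generate_cohort(spec)
#' cohort$matrix$cells
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  L <- MT_GENOME_LENGTH

  cells <- spec$cell_types |>
    dplyr::rowwise() |>
    dplyr::reframe(cell_id = sprintf("%s_%04d", .data$label, seq_len(.data$n_cells)),
                   cell_type = .data$label,
                   baseline = .data$baseline_copy_number)
  n_cells <- nrow(cells)

  # --- planted variants ------------------------------------------------------
  plants <- list()   # per-class tibbles: site, alt, cell_idx, true_vaf, class
  variants <- list() # variant registry: site, ref, alt, class
  used_sites <- integer(0)
  claim_sites <- function(sites, field) {
    if (any(sites %in% used_sites)) {
      stop(sprintf("%s: sites overlap a previously planted variant", field))
    }
    used_sites <<- c(used_sites, sites)
  }

  if (!is.null(spec$germline_variants) && nrow(spec$germline_variants) > 0) {
    gv <- spec$germline_variants
    claim_sites(gv$site, "germline_variants")
    variants$germline <- tibble(site = as.integer(gv$site),
                                ref = mt_ref_base(gv$site, spec$genome),
                                alt = gv$alt, class = "germline")
    plants$germline <- tidyr::crossing(
      tibble(site = as.integer(gv$site), alt = gv$alt),
      tibble(cell_idx = seq_len(n_cells))) |>
      dplyr::mutate(true_vaf = 1, class = "germline",
                    alt_bias = NA_real_)
  }

  if (!is.null(spec$somatic_vafs) && nrow(spec$somatic_vafs) > 0) {
    sv <- spec$somatic_vafs
    ref <- mt_ref_base(sv$site, spec$genome)
    damage_like <- (ref == "G" & sv$alt == "T") | (ref == "C" & sv$alt == "A")
    if (any(damage_like)) {
      stop("somatic_vafs: somatic plants may not be G>T / C>A substitutions ",
           "(sites ", paste(sv$site[damage_like], collapse = ", "), ")")
    }
    claim_sites(sv$site, "somatic_vafs")
    variants$somatic <- tibble(site = as.integer(sv$site), ref = ref,
                               alt = sv$alt, class = "somatic")
    plants$somatic <- lapply(seq_len(nrow(sv)), function(i) {
      carriers <- sample.int(n_cells, min(sv$n_carriers[i], n_cells))
      tibble(site = as.integer(sv$site[i]), alt = sv$alt[i],
             cell_idx = carriers, true_vaf = sv$vaf[i],
             class = "somatic", alt_bias = NA_real_)
    }) |> dplyr::bind_rows()
  }

  if (!is.null(spec$somatic_sim) && length(spec$somatic_sim) > 0) {
    sim_rows <- list()
    sim_vars <- list()
    for (label in names(spec$somatic_sim)) {
      idx <- which(cells$cell_type == label)
      params <- spec$somatic_sim[[label]]
      for (ci in idx) {
        vafs <- cpp_simulate_lineage(params$N0, params$alpha, params$Td,
                                     params$Ta, params$u)
        if (length(vafs) == 0) next
        sites <- sample_free_sites(length(vafs), used_sites, spec$genome)
        used_sites <- c(used_sites, sites)
        ref <- mt_ref_base(sites, spec$genome)
        alt <- random_alt(ref, avoid_damage = TRUE)
        sim_vars[[length(sim_vars) + 1L]] <-
          tibble(site = sites, ref = ref, alt = alt, class = "somatic")
        sim_rows[[length(sim_rows) + 1L]] <-
          tibble(site = sites, alt = alt, cell_idx = ci, true_vaf = vafs,
                 class = "somatic", alt_bias = NA_real_)
      }
    }
    if (length(sim_rows) > 0) {
      variants$somatic_sim <- dplyr::bind_rows(sim_vars)
      plants$somatic_sim <- dplyr::bind_rows(sim_rows)
    }
  }

  if (length(spec$artifact_sites) > 0) {
    as_ <- setdiff(spec$artifact_sites, used_sites)
    claim_sites(as_, "artifact_sites")
    ref <- mt_ref_base(as_, spec$genome)
    alt <- random_alt(ref, avoid_damage = TRUE)
    variants$artifact <- tibble(site = as_, ref = ref, alt = alt,
                                class = "artifact")
    plants$artifact <- lapply(seq_along(as_), function(i) {
      n_show <- max(1L, round(spec$artifact_cell_fraction * n_cells))
      tibble(site = as_[i], alt = alt[i],
             cell_idx = sample.int(n_cells, n_show),
             true_vaf = spec$artifact_vaf, class = "artifact",
             alt_bias = NA_real_)
    }) |> dplyr::bind_rows()
  }

  if (spec$n_damage_sites > 0) {
    gc_sites <- setdiff(which(strsplit(spec$genome, "", fixed = TRUE)[[1]]
                              %in% c("G", "C")), used_sites)
    ds <- sort(sample(gc_sites, spec$n_damage_sites))
    claim_sites(ds, "damage sites")
    ref <- mt_ref_base(ds, spec$genome)
    alt <- ifelse(ref == "G", "T", "A")
    variants$damage <- tibble(site = ds, ref = ref, alt = alt,
                              class = "damage_error")
    plants$damage <- tidyr::crossing(
      tibble(site = ds, alt = alt),
      tibble(cell_idx = seq_len(n_cells))) |>
      dplyr::mutate(true_vaf = spec$damage_rate, class = "damage_error",
                    alt_bias = spec$damage_strand_bias)
  }

  variant_tbl <- dplyr::bind_rows(variants)
  if (nrow(variant_tbl) == 0) {
    variant_tbl <- tibble(site = integer(0), ref = character(0),
                          alt = character(0), class = character(0))
  }
  variant_tbl <- variant_tbl |>
    dplyr::arrange(.data$site) |>
    dplyr::mutate(variant_id = sprintf("%d%s>%s", .data$site, .data$ref,
                                       .data$alt), .before = 1)
  plant_tbl <- dplyr::bind_rows(plants)

  # --- depth and read sampling ----------------------------------------------
  cell_factor <- rgamma(n_cells, shape = spec$depth_cell_shape,
                        rate = spec$depth_cell_shape)
  depth <- rnbinom(n_cells * L,
                   mu = rep(spec$depth_mean * cell_factor, each = L),
                   size = spec$depth_dispersion)
  dim(depth) <- c(L, n_cells)

  if (nrow(plant_tbl) > 0) {
    plant_tbl <- plant_tbl |>
      dplyr::mutate(depth = depth[cbind(.data$site, .data$cell_idx)],
                    p_alt = .data$true_vaf +
                      (1 - .data$true_vaf) * spec$error_rate,
                    alt_n = rbinom(dplyr::n(), .data$depth, .data$p_alt))
  } else {
    plant_tbl <- tibble(site = integer(0), alt = character(0),
                        cell_idx = integer(0), true_vaf = numeric(0),
                        class = character(0), alt_bias = numeric(0),
                        depth = integer(0), alt_n = integer(0))
  }

  # Background sequencing errors at unplanted (cell, site) pairs.
  err_tbl <- NULL
  if (spec$error_rate > 0) {
    n_err <- rbinom(1, sum(depth), spec$error_rate)
    if (n_err > 0) {
      flat <- sample.int(n_cells * L, n_err, replace = TRUE,
                         prob = as.numeric(depth))
      err_tbl <- tibble(site = ((flat - 1L) %% L) + 1L,
                        cell_idx = ((flat - 1L) %/% L) + 1L) |>
        dplyr::count(.data$site, .data$cell_idx, name = "alt_n") |>
        dplyr::anti_join(plant_tbl, by = c("site", "cell_idx")) |>
        dplyr::mutate(ref = mt_ref_base(.data$site, spec$genome),
                      alt = random_alt(.data$ref),
                      depth = depth[cbind(.data$site, .data$cell_idx)],
                      alt_n = pmin(.data$alt_n, .data$depth),
                      alt_bias = NA_real_)
    }
  }

  alt_rows <- dplyr::bind_rows(
    plant_tbl |>
      dplyr::left_join(variant_tbl |> dplyr::select("site", "alt", "ref"),
                       by = c("site", "alt")) |>
      dplyr::select("site", "cell_idx", "ref", "alt", "depth", "alt_n",
                    "alt_bias"),
    if (!is.null(err_tbl)) {
      err_tbl |> dplyr::select("site", "cell_idx", "ref", "alt", "depth",
                               "alt_n", "alt_bias")
    }
  )

  # Strand split.
  if (nrow(alt_rows) > 0) {
    p_fwd <- pmin(pmax(rnorm(nrow(alt_rows), spec$strand_fwd, spec$strand_sd),
                       0), 1)
    alt_p <- ifelse(is.na(alt_rows$alt_bias), p_fwd, alt_rows$alt_bias)
    ref_n <- alt_rows$depth - alt_rows$alt_n
    alt_rows <- alt_rows |>
      dplyr::mutate(ref_n = ref_n,
                    alt_fwd = rbinom(dplyr::n(), .data$alt_n, alt_p),
                    alt_rev = .data$alt_n - .data$alt_fwd,
                    ref_fwd = rbinom(dplyr::n(), ref_n, p_fwd),
                    ref_rev = ref_n - .data$ref_fwd)
  }

  # Reference-only rows for every covered (cell, site) not in alt_rows.
  nz <- which(depth > 0)
  base_tbl <- tibble(site = ((nz - 1L) %% L) + 1L,
                     cell_idx = ((nz - 1L) %/% L) + 1L,
                     depth = depth[nz])
  if (nrow(alt_rows) > 0) {
    base_tbl <- base_tbl |>
      dplyr::anti_join(alt_rows, by = c("site", "cell_idx"))
  }
  p_fwd_base <- pmin(pmax(rnorm(nrow(base_tbl), spec$strand_fwd,
                                spec$strand_sd), 0), 1)
  base_tbl <- base_tbl |>
    dplyr::mutate(ref = mt_ref_base(.data$site, spec$genome),
                  alt = NA_character_,
                  ref_fwd = rbinom(dplyr::n(), .data$depth, p_fwd_base),
                  ref_rev = .data$depth - .data$ref_fwd,
                  alt_fwd = 0L, alt_rev = 0L)

  counts <- dplyr::bind_rows(
    if (nrow(alt_rows) > 0) {
      alt_rows |> dplyr::select("site", "cell_idx", "ref", "alt", "ref_fwd",
                                "ref_rev", "alt_fwd", "alt_rev")
    },
    base_tbl |> dplyr::select("site", "cell_idx", "ref", "alt", "ref_fwd",
                              "ref_rev", "alt_fwd", "alt_rev")
  ) |>
    dplyr::mutate(cell_id = cells$cell_id[.data$cell_idx]) |>
    dplyr::filter(.data$ref_fwd + .data$ref_rev + .data$alt_fwd +
                    .data$alt_rev > 0) |>
    dplyr::arrange(.data$cell_idx, .data$site) |>
    dplyr::select("cell_id", "site", "ref", "alt", "ref_fwd", "ref_rev",
                  "alt_fwd", "alt_rev")

  mito <- counts |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(mito_reads = sum(.data$ref_fwd + .data$ref_rev +
                                        .data$alt_fwd + .data$alt_rev),
                     .groups = "drop")
  cell_meta <- cells |>
    dplyr::left_join(mito, by = "cell_id") |>
    dplyr::mutate(mito_reads = ifelse(is.na(.data$mito_reads), 0L,
                                      .data$mito_reads),
                  total_reads = pmax(
                    round(.data$mito_reads * spec$total_read_scale /
                            .data$baseline), 1)) |>
    dplyr::select("cell_id", "cell_type", "mito_reads", "total_reads")

  cell_vafs <- plant_tbl |>
    dplyr::filter(.data$class %in% c("germline", "somatic")) |>
    dplyr::left_join(variant_tbl |> dplyr::select("variant_id", "site", "alt"),
                     by = c("site", "alt")) |>
    dplyr::mutate(cell_id = cells$cell_id[.data$cell_idx]) |>
    dplyr::select("variant_id", "cell_id", "true_vaf")

  list(matrix = allele_count_matrix(counts, cell_meta),
       truth = list(variants = variant_tbl |>
                      dplyr::select("variant_id", "site", "ref", "alt",
                                    "class"),
                    cell_vafs = cell_vafs))
}

# Sample n sites uniformly, avoiding already-claimed positions.
sample_free_sites <- function(n, used, genome) {
  free <- setdiff(seq_len(MT_GENOME_LENGTH), used)
  if (length(free) < n) stop("no free sites left to plant mutations")
  sort(sample(free, n))
}

# Random alternate base differing from ref; optionally avoid the damage
# substitution types G>T and C>A (which the filter cascade removes).
random_alt <- function(ref, avoid_damage = FALSE) {
  bases <- c("A", "C", "G", "T")
  vapply(ref, function(r) {
    choices <- setdiff(bases, r)
    if (avoid_damage) {
      if (r == "G") choices <- setdiff(choices, "T")
      if (r == "C") choices <- setdiff(choices, "A")
    }
    sample(choices, 1)
  }, character(1), USE.NAMES = FALSE)
}
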