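#' Default end-to-end pipeline configuration
#'
#' Demo-scale defaults: a two-cell-type synthetic cohort whose B-like cells
#' carry Wright-Fisher bottleneck heteroplasmy, the default filter cascade,
#' and a reduced-K ABC run (the full-scale K = 1e6 / eta = 0.001 run is a
#' config change away).
#'
#' @return Nested named list of per-stage settings.
#' @export
pipeline_defaults <- function() {
  list(
    cohort = list(
      n_cells = 150L, cell_type = "B", baseline_copy_number = 500,
      depth_mean = 60, depth_dispersion = 8,
      n_germline = 5L, n_artifact = 6L, n_damage = 8L,
      sim = list(alpha = 0.85, Td = 15L, Ta = 25L, mu = 1e-7)
    ),
    filters = list(),          # overrides for filter_config()
    spectrum = list(normalization = "per_cell_mean"),
    abc = list(K = 10000L, eta = 0.01, n_cells_sim = 25L, mu = 1e-7,
               n0 = 500, nb_min = 10),
    dnds = list(strata = c(0, 0.1, 0.9, 1)),
    seed = 1L,
    log_level = "info"
  )
}

#' Validate a pipeline configuration
#'
#' Loads a YAML file (or takes a list), applies defaults, rejects unknown
#' keys and out-of-range values, and reports every violation at once.
#'
#' @param config Path to a YAML file, a list, or `NULL` for all defaults.
#' @return The populated configuration list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file does not exist: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (is.null(config)) config <- list()
  defaults <- pipeline_defaults()
  problems <- character(0)

  unknown_top <- setdiff(names(config), names(defaults))
  if (length(unknown_top) > 0) {
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown_top, collapse = ", ")))
  }
  for (sect in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[sect]]) && is.list(config[[sect]]) &&
        sect != "filters") {
      unk <- setdiff(names(config[[sect]]), names(defaults[[sect]]))
      if (length(unk) > 0) {
        problems <- c(problems, paste0("unknown key(s) in ", sect, ": ",
                                       paste(unk, collapse = ", ")))
      }
    }
  }
  cfg <- modifyList(defaults, config[intersect(names(config),
                                               names(defaults))])

  if (cfg$abc$eta <= 0 || cfg$abc$eta > 1) {
    problems <- c(problems, "abc$eta must lie in (0, 1]")
  }
  if (cfg$abc$K * cfg$abc$eta < 1) {
    problems <- c(problems, "abc$K * abc$eta must be >= 1")
  }
  if (cfg$cohort$n_cells <= 0) {
    problems <- c(problems, "cohort$n_cells must be > 0")
  }
  fc <- cfg$filters
  if (!is.null(fc$strand_low) || !is.null(fc$strand_high)) {
    lo <- if (is.null(fc$strand_low)) 0.30 else fc$strand_low
    hi <- if (is.null(fc$strand_high)) 0.70 else fc$strand_high
    if (lo >= hi) problems <- c(problems,
                                "filters$strand_low must be < strand_high")
  }
  if (length(problems) > 0) {
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  cfg
}

stage_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 7919 + stage_index * 104729) %% 2147483647)
}

pipeline_log <- function(level, cfg, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes the stages in order -- synthetic cohort generation, the
#' somatic-variant filter cascade, spectrum computation, ABC inference of the
#' bottleneck parameters, and dN/dS -- each stage consuming the previous
#' stage's outputs, and writes every stage's output files plus a run manifest
#' (config hash, seed, per-file checksums, wall-clock per stage) to
#' `out_dir`. Identical config + seed give identical checksums.
#'
#' @param config Passed to [validate_config()].
#' @param out_dir Output directory.
#' @param seed Global seed; per-stage substreams are derived from it (a stage
#'   can be rerun independently with identical results).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = NULL, out_dir = "mitobottleneck_run",
                         seed = NULL) {
  cfg <- validate_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  files <- character(0)
  t_stage <- function(name, fn) {
    t0 <- proc.time()["elapsed"]
    res <- tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[name] <<- unname(proc.time()["elapsed"] - t0)
    pipeline_log("info", cfg, "stage %s done in %.1fs", name, timings[name])
    res
  }

  # -- synth ------------------------------------------------------------------
  cohort <- t_stage("synth", function() {
    cc <- cfg$cohort
    set.seed(stage_seed(cfg$seed, 1L))
    genome <- synthetic_mt_genome()
    free <- setdiff(seq_len(MT_GENOME_LENGTH), default_site_blacklist())
    germ_sites <- sort(sample(free, cc$n_germline))
    germ <- tibble(site = germ_sites,
                   alt = random_alt(mt_ref_base(germ_sites, genome),
                                    avoid_damage = TRUE))
    spec <- cohort_spec(
      cell_types = tibble(label = cc$cell_type, n_cells = cc$n_cells,
                          baseline_copy_number = cc$baseline_copy_number),
      depth_mean = cc$depth_mean, depth_dispersion = cc$depth_dispersion,
      germline_variants = germ,
      somatic_sim = setNames(list(sim_params(
        alpha = cc$sim$alpha, Td = cc$sim$Td, Ta = cc$sim$Ta,
        N0 = cc$baseline_copy_number, mu = cc$sim$mu)), cc$cell_type),
      artifact_sites = head(default_site_blacklist(), cc$n_artifact),
      n_damage_sites = cc$n_damage,
      seed = stage_seed(cfg$seed, 1L))
    out <- generate_cohort(spec)
    files <<- c(files, write_cohort(out$matrix, file.path(out_dir, "cohort"),
                                    truth = out$truth))
    out
  })

  # -- callvars ---------------------------------------------------------------
  calls <- t_stage("callvars", function() {
    set.seed(stage_seed(cfg$seed, 2L))
    fcfg <- do.call(filter_config, cfg$filters)
    res <- call_somatic_variants(cohort$matrix, fcfg)
    vcf <- file.path(out_dir, "somatic_variants.vcf")
    write_variants_vcf(res$variants, vcf)
    vt <- file.path(out_dir, "cell_variant_vaf.tsv")
    readr::write_tsv(res$cvm$vaf, vt, progress = FALSE)
    files <<- c(files, vcf, vt)
    res
  })

  # -- spectrum ---------------------------------------------------------------
  spectrum <- t_stage("spectrum", function() {
    vafs <- calls$cvm$vaf$vaf
    sp <- vaf_spectrum(vafs[vafs > 0], n_cells = nrow(calls$cvm$cells),
                       normalization = cfg$spectrum$normalization,
                       cell_type = cfg$cohort$cell_type)
    sf <- file.path(out_dir, "spectrum.tsv")
    write_spectrum(sp, sf)
    files <<- c(files, sf)
    sp
  })

  # -- abc --------------------------------------------------------------------
  posterior <- t_stage("abc", function() {
    ac <- cfg$abc
    abc_cfg <- abc_config(K = ac$K, eta = ac$eta,
                          n_cells_sim = ac$n_cells_sim, mu = ac$mu,
                          seed = stage_seed(cfg$seed, 3L))
    prior <- prior_spec(N0 = ac$n0, nb_min = ac$nb_min)
    post <- abc_reject(spectrum, abc_cfg, prior)
    pf <- file.path(out_dir, "posterior.tsv")
    readr::write_tsv(tibble::as_tibble(post), pf, progress = FALSE)
    sf <- file.path(out_dir, "posterior_summary.tsv")
    readr::write_tsv(posterior_summary(post), sf, progress = FALSE)
    files <<- c(files, pf, sf)
    post
  })

  # -- dnds -------------------------------------------------------------------
  dnds <- t_stage("dnds", function() {
    per_variant <- calls$cvm$vaf |>
      dplyr::filter(.data$vaf > 0) |>
      dplyr::group_by(.data$site, .data$ref, .data$alt) |>
      dplyr::summarise(vaf = max(.data$vaf), .groups = "drop")
    res <- compute_dnds(per_variant, strata = cfg$dnds$strata)
    df <- file.path(out_dir, "dnds.tsv")
    readr::write_tsv(res, df, progress = FALSE)
    files <<- c(files, df)
    res
  })

  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("mitobottleneck")),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    files = as.list(setNames(unname(tools::md5sum(unname(files))),
                             basename(unname(files)))),
    wallclock_sec = as.list(round(timings, 3))
  )
  manifest_tmp <- file.path(out_dir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, manifest_tmp, auto_unbox = TRUE, digits = NA)
  file.rename(manifest_tmp, file.path(out_dir, "manifest.json"))
  pipeline_log("info", cfg, "pipeline complete: %s", out_dir)
  invisible(list(manifest = manifest, cohort = cohort, calls = calls,
                 spectrum = spectrum, posterior = posterior, dnds = dnds))
}
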