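#' Prior specification for bottleneck-parameter inference
#'
#' Uniform priors over the dilution rate `alpha`, the diluting divisions
#' `Td ~ U{0..30}` and the total divisions `Ta ~ U{10..40}` (integers), with
#' two joint constraints: `Ta >= Td`, and the retention rule
#' `Nb = N0 * alpha^Td > nb_min` that discards draws in which the mtDNA
#' population would effectively go extinct. The `alpha` range defaults to
#' (0, 1): the dilution rate is a fraction of molecules replicating, and the
#' retention rule prunes the infeasible region.
#'
#' @param alpha_range Numeric length-2 range of the continuous `alpha` prior.
#' @param td_range Integer range of `Td` (inclusive).
#' @param ta_range Integer range of `Ta` (inclusive).
#' @param N0 Baseline copy number used by the retention rule.
#' @param nb_min Retention threshold on `Nb` (strict; default 10).
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(alpha_range = c(0, 1), td_range = c(0L, 30L),
                       ta_range = c(10L, 40L), N0 = 500, nb_min = 10) {
  stopifnot(length(alpha_range) == 2, alpha_range[1] >= 0,
            alpha_range[2] <= 1, alpha_range[1] < alpha_range[2],
            td_range[1] <= td_range[2], ta_range[1] <= ta_range[2],
            ta_range[2] >= td_range[1], N0 >= 1, nb_min >= 0)
  structure(list(alpha_range = alpha_range,
                 td_range = as.integer(td_range),
                 ta_range = as.integer(ta_range),
                 N0 = N0, nb_min = nb_min),
            class = "prior_spec")
}

#' Sample parameter draws from the prior
#'
#' Rejection-samples until every draw satisfies both `Ta >= Td` and the
#' retention rule `Nb > nb_min`.
#'
#' @param spec A [prior_spec()].
#' @param n Number of draws.
#' @param max_rounds Resampling rounds before declaring the spec infeasible.
#' @return Tibble with `alpha`, `Td`, `Ta`, `Nb`.
#' @export
sample_prior <- function(spec, n = 1, max_rounds = 1000L) {
  stopifnot(inherits(spec, "prior_spec"), n >= 1)
  out <- vector("list", 0)
  got <- 0L
  for (round in seq_len(max_rounds)) {
    m <- max(n - got, 0L)
    if (m == 0L) break
    # Oversample: acceptance can be well below 1 under the retention rule.
    m2 <- as.integer(ceiling(m * 2.5) + 16L)
    alpha <- runif(m2, spec$alpha_range[1], spec$alpha_range[2])
    td <- sample(spec$td_range[1]:spec$td_range[2], m2, replace = TRUE)
    ta <- sample(spec$ta_range[1]:spec$ta_range[2], m2, replace = TRUE)
    nb <- spec$N0 * alpha^td
    ok <- ta >= td & nb > spec$nb_min & alpha > 0
    if (any(ok)) {
      out[[length(out) + 1L]] <- tibble(alpha = alpha[ok], Td = td[ok],
                                        Ta = ta[ok], Nb = nb[ok])
      got <- got + sum(ok)
    }
    if (got >= n) break
  }
  if (got < n) {
    stop("prior_spec appears infeasible: could not satisfy Ta >= Td and ",
         "Nb > nb_min after ", max_rounds, " resampling rounds")
  }
  dplyr::bind_rows(out)[seq_len(n), ]
}

#' ABC run configuration
#'
#' @param K Number of prior draws (default 1e6).
#' @param eta Acceptance fraction: the `floor(K * eta)` draws with smallest
#'   distance are retained (default 0.001, giving 1,000 accepted draws at the
#'   default `K`).
#' @param n_cells_sim Simulated lineages per draw. Because spectra are
#'   compared on the per-cell-mean scale, this may be much smaller than the
#'   observed cohort; the default trades per-draw noise against run time.
#' @param mu Per-site per-division mutation rate (default 1e-7).
#' @param L Genome length (bp).
#' @param detection_floor Simulated VAFs below this are dropped before
#'   binning (default 0.05).
#' @param normalization `"per_cell_mean"` (default) or `"raw"`; must match
#'   the scale of the observed spectrum.
#' @param seed Optional seed set at the start of [abc_reject()].
#' @return Object of class `abc_config`.
#' @export
abc_config <- function(K = 1e6, eta = 0.001, n_cells_sim = 25L, mu = 1e-7,
                       L = MT_GENOME_LENGTH, detection_floor = 0.05,
                       normalization = c("per_cell_mean", "raw"),
                       seed = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(eta > 0, eta <= 1, K >= 1, K * eta >= 1, n_cells_sim >= 1,
            mu >= 0)
  structure(list(K = as.integer(K), eta = eta,
                 n_cells_sim = as.integer(n_cells_sim), mu = mu,
                 L = as.integer(L), u = mu * L,
                 detection_floor = detection_floor,
                 normalization = normalization, seed = seed),
            class = "abc_config")
}

observed_vector <- function(observed, cfg) {
  if (inherits(observed, "vaf_spectrum")) {
    if (observed$normalization != cfg$normalization) {
      stop("observed spectrum normalization (", observed$normalization,
           ") does not match abc_config (", cfg$normalization, ")")
    }
    observed <- observed$counts
  }
  if (length(observed) != 19) stop("observed spectrum must have 19 bins")
  as.numeric(observed)
}

#' Euclidean distance between two spectra
#'
#' The ABC discrepancy measure: straight Euclidean distance between two
#' 19-bin summary vectors on a common normalization scale.
#'
#' @param a,b [vaf_spectrum()] objects or bare numeric 19-vectors.
#' @return Non-negative scalar distance.
#' @export
spectrum_distance <- function(a, b) {
  get_counts <- function(x) {
    if (inherits(x, "vaf_spectrum")) x$counts else as.numeric(x)
  }
  a <- get_counts(a)
  b <- get_counts(b)
  stopifnot(length(a) == 19, length(b) == 19)
  sqrt(sum((a - b)^2))
}

#' Rejection-sampling ABC over the dilution-bottleneck parameters
#'
#' For each of `K` prior draws, simulates a cohort under the Wright-Fisher
#' dilution model, summarizes it as the 19-bin VAF spectrum, and computes the
#' Euclidean distance to the observed spectrum. The `floor(K * eta)` draws
#' with the smallest distances form the posterior sample; ties at the cutoff
#' are broken by draw order.
#'
#' @param observed A [vaf_spectrum()] object or bare 19-vector on the scale
#'   named in `cfg$normalization`.
#' @param cfg An [abc_config()].
#' @param prior A [prior_spec()].
#' @return Object of class `abc_posterior`: tibble of accepted draws
#'   (`alpha`, `Td`, `Ta`, `Nb`, `distance`) with the config, prior and all-K
#'   distance summary in attributes.
#' @export
abc_reject <- function(observed, cfg = abc_config(), prior = prior_spec()) {
  stopifnot(inherits(cfg, "abc_config"), inherits(prior, "prior_spec"))
  obs <- observed_vector(observed, cfg)
  n_accept <- floor(cfg$K * cfg$eta)
  if (n_accept < 1) stop("K * eta must be >= 1")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  draws <- sample_prior(prior, n = cfg$K)
  dist <- cpp_abc_distances(draws$alpha, as.integer(draws$Td),
                            as.integer(draws$Ta), as.integer(prior$N0),
                            cfg$u, cfg$n_cells_sim, obs,
                            cfg$detection_floor,
                            cfg$normalization == "per_cell_mean")
  ord <- order(dist)            # stable: ties broken by draw order
  acc <- ord[seq_len(n_accept)]
  posterior <- draws[acc, ] |>
    dplyr::mutate(distance = dist[acc])
  structure(posterior, class = c("abc_posterior", class(posterior)),
            cfg = cfg, prior = prior,
            max_accepted = max(posterior$distance),
            min_rejected = if (cfg$K > n_accept) {
              min(dist[ord[(n_accept + 1):cfg$K]])
            } else NA_real_)
}

#' Posterior means and 95% credible intervals
#'
#' @param posterior An [abc_reject()] result.
#' @return Tibble with `parameter` (`alpha`, `Td`, `Ta`, `Nb`), `mean`,
#'   `ci_low` (2.5th percentile), `ci_high` (97.5th percentile).
#' @export
posterior_summary <- function(posterior) {
  stopifnot(inherits(posterior, "abc_posterior") || is.data.frame(posterior))
  if (nrow(posterior) == 0) stop("posterior is empty")
  params <- c("alpha", "Td", "Ta", "Nb")
  dplyr::bind_rows(lapply(params, function(p) {
    x <- posterior[[p]]
    tibble(parameter = p, mean = mean(x),
           ci_low = unname(quantile(x, 0.025)),
           ci_high = unname(quantile(x, 0.975)))
  }))
}

#' Mutation-rate model selection
#'
#' Runs the ABC procedure once per candidate mutation rate and selects the
#' rate whose accepted draws have the smallest mean distance to the observed
#' spectrum.
#'
#' @inheritParams abc_reject
#' @param mu_candidates Candidate per-site rates (default `1e-8` and `1e-7`).
#' @return List with `best_mu`, `scores` (tibble of per-mu mean accepted
#'   distance) and `posteriors` (named list of `abc_posterior` objects).
#' @export
model_select_mu <- function(observed, cfg = abc_config(),
                            prior = prior_spec(),
                            mu_candidates = c(1e-8, 1e-7)) {
  stopifnot(length(mu_candidates) >= 1)
  posteriors <- list()
  scores <- lapply(mu_candidates, function(mu) {
    cfg_mu <- cfg
    cfg_mu$mu <- mu
    cfg_mu$u <- mu * cfg$L
    post <- abc_reject(observed, cfg_mu, prior)
    posteriors[[as.character(mu)]] <<- post
    tibble(mu = mu, mean_accepted_distance = mean(post$distance))
  }) |> dplyr::bind_rows()
  best <- scores$mu[which.min(scores$mean_accepted_distance)]
  list(best_mu = best, scores = scores, posteriors = posteriors)
}

#' Posterior-predictive averaged spectrum
#'
#' Simulates `n_reps` cohorts at the posterior-mean parameters (`Td`, `Ta`
#' rounded to integers) and returns the element-wise mean spectrum with the
#' per-bin spread, the check behind the bottleneck-vs-control spectrum
#' comparison.
#'
#' @param posterior An [abc_reject()] result (or anything
#'   [posterior_summary()] accepts).
#' @param cfg An [abc_config()]; `n_cells_sim` lineages are simulated per
#'   replicate unless `n_cells` is given.
#' @param n_reps Number of replicate cohorts (default 100).
#' @param n_cells Cells per replicate cohort (default `cfg$n_cells_sim`).
#' @return List with `mean_counts`, `sd_counts` (length-19), `spectra`
#'   (`n_reps` x 19 matrix) and `params` (the `sim_params` used).
#' @export
posterior_predictive <- function(posterior, cfg = abc_config(), n_reps = 100,
                                 n_cells = cfg$n_cells_sim) {
  summ <- posterior_summary(posterior)
  get_mean <- function(p) summ$mean[summ$parameter == p]
  prior <- attr(posterior, "prior")
  N0 <- if (!is.null(prior)) prior$N0 else 500
  td <- as.integer(round(get_mean("Td")))
  ta <- max(as.integer(round(get_mean("Ta"))), td)
  params <- sim_params(alpha = min(get_mean("alpha"), 1), Td = td, Ta = ta,
                       N0 = N0, mu = cfg$mu, L = cfg$L, n_cells = n_cells,
                       detection_floor = cfg$detection_floor)
  spectra <- replicate_spectra(params, n_reps, cfg$normalization)
  list(mean_counts = colMeans(spectra),
       sd_counts = apply(spectra, 2, stats::sd),
       spectra = spectra, params = params)
}

#' Replicate cohort spectra at fixed parameters
#'
#' @param params A [sim_params()] object.
#' @param n_reps Number of independent cohorts.
#' @param normalization Spectrum scale.
#' @return `n_reps` x 19 matrix of spectra.
#' @export
replicate_spectra <- function(params, n_reps,
                              normalization = "per_cell_mean") {
  t(vapply(seq_len(n_reps), function(i) {
    cs <- cpp_simulate_cellset(params$n_cells, params$N0, params$alpha,
                               params$Td, params$Ta, params$u)
    vafs <- unlist(cs, use.names = FALSE)
    vafs <- vafs[vafs >= params$detection_floor]
    vaf_spectrum(vafs, n_cells = params$n_cells,
                 normalization = normalization)$counts
  }, numeric(19)))
}
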