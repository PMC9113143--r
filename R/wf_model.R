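#' Minimal copy number through the dilution bottleneck
#'
#' Under the dilution model only a fraction `alpha` of mtDNA molecules
#' replicates per cell division, so after `Td` diluting divisions the copy
#' number reaches its minimum
#' \deqn{N_b = N_0 \, \alpha^{T_d}.}
#'
#' @param N0 Baseline mtDNA copy number per cell (500 for B/T lineages, 300
#'   for NK).
#' @param alpha Dilution rate per division, in (0, 1].
#' @param Td Number of diluting divisions (non-negative integer).
#' @return The real-valued minimal copy number (the integer trajectory of the
#'   simulator rounds per generation; see [copy_number_trajectory()]).
#' @export
#' @examples
#' bottleneck_size(500, 0.9, 10) # 174.34
bottleneck_size <- function(N0, alpha, Td) {
  stopifnot(all(N0 >= 1), all(alpha > 0), all(alpha <= 1), all(Td >= 0))
  N0 * alpha^Td
}

#' Per-division mutation influx probability
#'
#' The number of new somatic mutations acquired per mitochondrial genome per
#' cell division is Poisson with mean `u`, the genome-wide mutation rate
#' `u = mu * L` (`L` = 16,569 bp).
#'
#' @param u Genome-wide per-division mutation rate (>= 0).
#' @param k Non-negative integer mutation count(s).
#' @return P(X = k) under Poisson(u).
#' @export
#' @examples
#' mutation_pmf(1e-7 * 16569, 0)
mutation_pmf <- function(u, k) {
  stopifnot(all(u >= 0), all(k >= 0), all(k == floor(k)))
  stats::dpois(k, u)
}

#' Wright-Fisher dilution-model parameters
#'
#' Bundles and validates the parameters of the dilution-bottleneck model:
#' baseline copy number `N0`, dilution rate `alpha`, diluting divisions `Td`,
#' total divisions `Ta` from the lymphoid-primed progenitor (LMPP) to the
#' mature cell, and per-site per-division mutation rate `mu`. The genome-wide
#' rate `u = mu * L` and minimal copy number `Nb = N0 * alpha^Td` are derived.
#'
#' @param alpha Dilution rate in (0, 1]; `alpha = 1` is the no-bottleneck
#'   control.
#' @param Td Diluting divisions, integer >= 0.
#' @param Ta Total divisions, integer >= `Td`.
#' @param N0 Baseline copy number (default 500; use 300 for NK cohorts).
#' @param mu Per-site per-division mutation rate (default 1e-7).
#' @param L Genome length in bp (default 16,569).
#' @param n_cells Lineages per simulated cohort.
#' @param detection_floor VAFs below this are treated as undetectable when
#'   summarizing simulated cells (default 0.05, the first spectrum edge).
#' @param seed Optional integer seed applied by the simulating functions.
#' @return An object of class `sim_params`.
#' @export
#' @examples
#' p <- sim_params(alpha = 0.85, Td = 15, Ta = 25)
#' p$Nb
sim_params <- function(alpha, Td, Ta, N0 = 500, mu = 1e-7, L = MT_GENOME_LENGTH,
                       n_cells = 100, detection_floor = 0.05, seed = NULL) {
  stopifnot(length(alpha) == 1, alpha > 0, alpha <= 1,
            length(Td) == 1, Td >= 0, Td == floor(Td),
            length(Ta) == 1, Ta >= Td, Ta == floor(Ta),
            N0 >= 1, mu >= 0, L >= 1, n_cells >= 1,
            detection_floor >= 0, detection_floor <= 1)
  structure(list(
    N0 = as.integer(N0), alpha = alpha, Td = as.integer(Td),
    Ta = as.integer(Ta), mu = mu, L = as.integer(L), u = mu * L,
    Nb = N0 * alpha^Td, n_cells = as.integer(n_cells),
    detection_floor = detection_floor, seed = seed
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "Wright-Fisher dilution model: N0 = %d, alpha = %.3f, Td = %d, Ta = %d\n",
    x$N0, x$alpha, x$Td, x$Ta))
  cat(sprintf("  Nb = N0 * alpha^Td = %.2f; u = mu * L = %.3g (mu = %.1g)\n",
              x$Nb, x$u, x$mu))
  cat(sprintf("  cohort: %d cells, detection floor %.2f\n",
              x$n_cells, x$detection_floor))
  invisible(x)
}

#' Copy-number trajectory of the dilution model
#'
#' Integer copy number at each generation 0..Ta: `Td` diluting generations
#' with `N_{t+1} = round(alpha * N_t)`, a sustained phase at the bottleneck
#' minimum through development, and recovery to `N0` at the final
#' (maturation) division.
#'
#' @param params A [sim_params()] object.
#' @return Integer vector of length `Ta + 1` (generation 0 first).
#' @export
copy_number_trajectory <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$N0
  traj <- integer(params$Ta + 1L)
  traj[1] <- n
  dil <- min(params$Td, params$Ta)
  for (t in seq_len(params$Ta)) {
    n <- if (t <= dil) {
      as.integer(round(params$alpha * n))
    } else if (t == params$Ta) {
      params$N0
    } else {
      n
    }
    if (n < 1) stop("mtDNA population extinct: trajectory reached 0 copies")
    traj[t + 1L] <- n
  }
  traj
}

#' One Wright-Fisher generation
#'
#' Resamples every segregating mutation's copy count binomially into the next
#' generation of `next_N` genome copies (sampling with replacement), prunes
#' lost mutations and adds `Poisson(u * next_N)` new mutations at one copy
#' each.
#'
#' @param state List with elements `N` (current copy number) and `counts`
#'   (numeric vector of per-mutation copy counts in `[0, N]`).
#' @param next_N Copy number of the next generation (>= 1).
#' @param u Genome-wide per-division mutation rate.
#' @return Updated state list with `N = next_N`.
#' @export
evolve_generation <- function(state, next_N, u) {
  stopifnot(is.list(state), !is.null(state$N), !is.null(state$counts))
  if (next_N < 1) stop("mtDNA population extinct: next_N < 1")
  counts <- cpp_evolve_generation(as.numeric(state$counts),
                                  as.integer(state$N),
                                  as.integer(next_N), u)
  list(N = as.integer(next_N), counts = counts)
}

#' Simulate one cell lineage through the bottleneck
#'
#' Runs a single LMPP-to-mature-cell lineage for `Ta` generations under the
#' dilution model: `Td` diluting divisions down to the bottleneck minimum
#' `Nb`, a sustained low-copy phase while the cell completes development, and
#' a rapid recovery to the baseline `N0` at the final maturation division.
#' Returns the final heteroplasmy (VAF) of every mutation still segregating
#' or fixed, as copy count over final copy number. No detection floor is
#' applied here.
#'
#' @param params A [sim_params()] object.
#' @return Numeric vector of VAFs in (0, 1] (possibly empty).
#' @export
simulate_lineage <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  cpp_simulate_lineage(params$N0, params$alpha, params$Td, params$Ta, params$u)
}

#' Simulate a cohort of independent cell lineages
#'
#' @param params A [sim_params()] object; `params$n_cells` lineages are run
#'   (independent cells, each from its own LMPP ancestor). If `params$seed`
#'   is set the RNG is seeded first.
#' @return Object of class `simulated_cellset`: a list of per-cell VAF
#'   vectors with the parameters attached as an attribute.
#' @export
#' @examples
#' cs <- simulate_cellset(sim_params(0.8, 10, 20, n_cells = 5, seed = 1))
#' lengths(cs)
simulate_cellset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  cells <- cpp_simulate_cellset(params$n_cells, params$N0, params$alpha,
                                params$Td, params$Ta, params$u)
  structure(cells, class = "simulated_cellset", params = params)
}

#' Spectrum of a simulated cohort
#'
#' Pools all per-cell VAFs at or above the detection floor and bins them into
#' the 19-bin spectrum.
#'
#' @param cellset A [simulate_cellset()] result.
#' @param normalization `"raw"` counts or `"per_cell_mean"` (counts divided by
#'   the number of cells).
#' @return A [vaf_spectrum()] object.
#' @export
cellset_spectrum <- function(cellset, normalization = "per_cell_mean") {
  stopifnot(inherits(cellset, "simulated_cellset"))
  params <- attr(cellset, "params")
  vafs <- unlist(cellset, use.names = FALSE)
  vafs <- vafs[vafs >= params$detection_floor]
  vaf_spectrum(vafs, n_cells = length(cellset), normalization = normalization)
}

#' Neutral drift replicates at constant population size
#'
#' Evolves `reps` independent constant-size Wright-Fisher populations from a
#' standing allele at `count0` copies for a fixed number of generations (no
#' new mutations) and returns the final copy counts. Intended for checking
#' drift theory (heterozygosity decay, martingale property).
#'
#' @param N Population (copy) number.
#' @param count0 Starting copies of the focal allele, in `[0, N]`.
#' @param generations Number of generations.
#' @param reps Number of replicates.
#' @return Numeric vector of final copy counts, length `reps`.
#' @export
drift_replicates <- function(N, count0, generations, reps) {
  cpp_drift_replicates(as.integer(N), as.integer(count0),
                       as.integer(generations), as.integer(reps))
}

#' Monte Carlo fixation probability of a neutral allele
#'
#' @inheritParams drift_replicates
#' @param max_gen Safety cap on generations per replicate (absorption at
#'   constant N = 20-50 occurs far sooner in practice).
#' @return Estimated probability that the allele fixes rather than being lost
#'   (theory: `count0 / N`).
#' @export
fixation_probability <- function(N, count0, reps, max_gen = 10000L) {
  cpp_fixation_probability(as.integer(N), as.integer(count0),
                           as.integer(reps), as.integer(max_gen))
}
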