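# R-side interface to the direct-method Gillespie engine (src/ssa.cpp).

ssa_par_vector <- function(params, protocol, variant) {
  v <- as_variant(variant)
  g <- if (v$name == "CBS_HYBRID_TETR") tet_relief(protocol$d_atc, params) else 1
  c(alpha1 = params$alpha1, alpha2 = params$alpha2,
    beta1 = params$beta1, beta2 = params$beta2,
    K1 = params$K1, K2 = params$K2, n1 = params$n1, n2 = params$n2,
    delta1 = params$delta1, delta2 = params$delta2,
    c12eff = params$c12 * g, c21 = params$c21,
    lambda1 = params$lambda1, lambda2 = params$lambda2,
    copy_scale = params$copy_scale,
    two_strain = as.numeric(v$name == "TWO_STRAIN_CBS"))
}

#' Exact stochastic trajectory of the circuit reaction network
#'
#' Direct-method Gillespie realization of the 4-channel network (production
#' and first-order removal of each module protein) at system size `volume`
#' (molecules per concentration unit). The C6 dose step at `protocol$t_c6` is
#' handled exactly by truncating the pending waiting time at the epoch
#' boundary and redrawing. Reproducible bit-exactly for a given seed.
#'
#' @param params,protocol,variant model specification.
#' @param volume system-size factor converting concentration to molecule
#'   counts; the default (5) puts activated states near 400-500 molecules.
#' @param seed integer RNG seed (required: stochastic results must be
#'   reproducible).
#' @param init initial counts, default `(0, 0)`.
#' @param sample_times times (hours) at which the state is recorded; default
#'   a 0.1 h grid over the protocol horizon.
#' @param occupancy_max optional length-2 count cap; when given, the sampler
#'   also accumulates the time each lattice state was occupied (capped at
#'   these counts), the natural estimator of the stationary distribution.
#' @param max_events safety cap on the number of reaction events.
#' @return object of class `ssa_trajectory`: list with `times`, `states`
#'   (matrix, columns `N1`, `N2`), `final`, `n_events`, `volume`, `seed`,
#'   `fate` (NA until classified), and `occupancy` when requested.
#' @export
ssa_trajectory <- function(params, protocol, variant, volume = 5, seed,
                           init = c(0, 0), sample_times = NULL,
                           occupancy_max = NULL, max_events = 5e8) {
  if (missing(seed)) stop("ssa_trajectory: seed must be given explicitly")
  if (volume <= 0) stop("ssa_trajectory: volume must be positive")
  if (protocol$t_end <= 0) stop("ssa_trajectory: t_end must be positive")
  if (is.null(sample_times))
    sample_times <- seq(0, protocol$t_end, by = 0.1)
  sample_times <- sort(sample_times)
  par <- ssa_par_vector(params, protocol, variant)
  uA <- induction_input(protocol$d_lara, params$Ka, params$na)
  uC <- induction_input(protocol$d_c6, params$Kc, params$nc)
  occ <- if (is.null(occupancy_max)) c(0L, 0L) else as.integer(occupancy_max)
  set.seed(as.integer(seed))
  raw <- .ssa_run_cpp(par, uA, uC, protocol$t_c6, protocol$t_end, volume,
                      init[1], init[2], sample_times, occ[1], occ[2],
                      max_events)
  out <- list(times = sample_times,
              states = cbind(N1 = raw$N1, N2 = raw$N2),
              final = raw$final, n_events = raw$n_events,
              volume = volume, seed = as.integer(seed),
              protocol = protocol, fate = NA_character_)
  if (!is.null(raw$occupancy)) out$occupancy <- raw$occupancy
  structure(out, class = "ssa_trajectory")
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat("<ssa_trajectory> ", x$n_events, " events, final (",
      x$final[1], ", ", x$final[2], ") counts, fate ", x$fate, "\n", sep = "")
  invisible(x)
}

# deterministic counter-based derivation of per-cell seeds from a master
# seed, independent of evaluation order
cell_seed <- function(master, i) {
  as.integer((as.double(master) + as.double(i) * 1000003) %% 2147483647)
}

#' Terminal-fate distribution over a stochastic population
#'
#' Runs `n_cells` independent SSA realizations from the same initial counts;
#' per-cell seeds are derived from the master seed by a fixed counter scheme
#' (`(seed + i * 1000003) mod 2^31 - 1`), so each cell's trajectory is
#' independent of the order of execution. Terminal states are classified
#' against thresholds derived from the deterministic stable fixed points
#' (scaled to counts by `volume`) unless thresholds are supplied.
#'
#' @inheritParams ssa_trajectory
#' @param n_cells number of cells (>= 1).
#' @param thresholds optional length-2 count thresholds; default derived via
#'   [find_fixed_points()] + [fate_thresholds()] at the protocol's doses.
#' @param init initial counts per cell.
#' @return list with `fractions` (named numeric over fates present, sums to
#'   1), `fates` (per-cell labels), `terminal` (n_cells x 2 count matrix),
#'   `thresholds`.
#' @export
fate_distribution <- function(params, protocol, variant, volume = 5,
                              n_cells = 200, seed, thresholds = NULL,
                              init = c(0, 0)) {
  if (missing(seed)) stop("fate_distribution: seed must be given explicitly")
  if (n_cells < 1) stop("fate_distribution: n_cells must be >= 1")
  if (is.null(thresholds)) {
    fps <- find_fixed_points(params, protocol, variant)
    thresholds <- fate_thresholds(fps, params) * volume
  }
  terminal <- matrix(NA_real_, n_cells, 2)
  for (i in seq_len(n_cells)) {
    tr <- ssa_trajectory(params, protocol, variant, volume = volume,
                         seed = cell_seed(seed, i), init = init,
                         sample_times = protocol$t_end)
    terminal[i, ] <- tr$final
  }
  fates <- classify_fate(terminal / volume, thresholds / volume)
  frac <- table(fates) / n_cells
  list(fractions = stats::setNames(as.numeric(frac), names(frac)),
       fates = fates, terminal = terminal, thresholds = thresholds)
}
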