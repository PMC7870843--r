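# Synthetic flow-cytometry populations: extrinsic parameter noise, SSA or
# ODE endpoints, an instrument model (fluorescence gains, autofluorescence,
# log-normal measurement noise, FSC-A/FSC-H scatter with injected doublets),
# and two-strain mixtures.
#
# Reporter placement: GFP reports module 1 (the AraC arm), RFP reports
# module 2 (the LuxR arm). Fate labels are written (RFP, GFP) = (module 2,
# module 1): "HL" is high-RFP/low-GFP.

lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean exactly 1
}

#' Draw per-cell parameter sets with extrinsic noise
#'
#' Applies independent multiplicative log-normal perturbations with
#' coefficient of variation `extrinsic_cv` (mean-corrected, so the expected
#' value equals the base parameter) to the production rates `alpha1`,
#' `alpha2` and removal rates `delta1`, `delta2`. Other fields are shared
#' across cells, mimicking cell-to-cell variability in expression capacity
#' and growth/degradation.
#'
#' @param base a `circuit_params` object.
#' @param extrinsic_cv coefficient of variation (>= 0).
#' @param n number of cells.
#' @param seed integer RNG seed.
#' @return list of `n` `circuit_params` objects.
#' @export
sample_cell_params <- function(base, extrinsic_cv, n = 1, seed) {
  if (extrinsic_cv < 0) stop("sample_cell_params: extrinsic_cv must be >= 0")
  if (missing(seed)) stop("sample_cell_params: seed must be given")
  set.seed(as.integer(seed))
  f <- matrix(lognormal_factor(4 * n, extrinsic_cv), ncol = 4)
  lapply(seq_len(n), function(i)
    circuit_params(list(alpha1 = base$alpha1 * f[i, 1],
                        alpha2 = base$alpha2 * f[i, 2],
                        delta1 = base$delta1 * f[i, 3],
                        delta2 = base$delta2 * f[i, 4]),
                   .base = base))
}

#' Instrument model: map expression states to flow-cytometry channels
#'
#' `gfp = (auto_gfp + gain_gfp * m1) * noise`, `rfp = (auto_rfp +
#' gain_rfp * m2) * noise` with multiplicative log-normal measurement noise
#' of coefficient of variation `measurement_cv`. Forward scatter `fsc_a` is
#' log-normal around a fixed cell-size mode; `fsc_h = fsc_a * ratio` where
#' the ratio is near 1 for singlets. A `doublet_fraction` of events gets
#' doubled `fsc_a` (and summed fluorescence) with a depressed `fsc_h/fsc_a`
#' ratio, so that scatter-ratio gating can remove them.
#'
#' @param state matrix of per-cell `(m1, m2)` expression states (or a
#'   length-2 vector).
#' @param gains length-2 fluorescence gains `(gfp, rfp)` per expression unit.
#' @param autofluorescence length-2 channel floors.
#' @param measurement_cv multiplicative noise CV (>= 0).
#' @param seed integer RNG seed.
#' @param doublet_fraction fraction of events rendered as doublets.
#' @return data.frame with columns `gfp`, `rfp`, `fsc_a`, `fsc_h`,
#'   `is_doublet`.
#' @export
fluorescence_channels <- function(state, gains = c(50, 50),
                                  autofluorescence = c(100, 100),
                                  measurement_cv = 0.2, seed,
                                  doublet_fraction = 0) {
  if (any(gains < 0)) stop("fluorescence_channels: gains must be nonnegative")
  if (measurement_cv < 0) stop("fluorescence_channels: measurement_cv < 0")
  if (missing(seed)) stop("fluorescence_channels: seed must be given")
  m <- if (is.matrix(state)) state else matrix(state, ncol = 2)
  n <- nrow(m)
  set.seed(as.integer(seed))
  is_doublet <- stats::runif(n) < doublet_fraction
  mult <- ifelse(is_doublet, 2, 1)  # doublets carry two cells' worth
  gfp <- (autofluorescence[1] + gains[1] * m[, 1]) * mult *
    lognormal_factor(n, measurement_cv)
  rfp <- (autofluorescence[2] + gains[2] * m[, 2]) * mult *
    lognormal_factor(n, measurement_cv)
  fsc_a <- stats::rlnorm(n, meanlog = log(5e4), sdlog = 0.25) * mult
  ratio <- ifelse(is_doublet,
                  stats::rlnorm(n, meanlog = log(0.6), sdlog = 0.05),
                  stats::rlnorm(n, meanlog = 0, sdlog = 0.02))
  data.frame(gfp = gfp, rfp = rfp, fsc_a = fsc_a, fsc_h = fsc_a * ratio,
             is_doublet = is_doublet)
}

#' Simulate a flow-cytometry-like single-cell population
#'
#' Per cell: draw a parameter set with extrinsic noise, run the circuit to
#' the end of the protocol (exact SSA, or deterministic ODE plus instrument
#' noise only), then map the endpoint through the instrument model. Fates
#' are classified from the model state (before measurement noise) against
#' thresholds derived from the base parameter set's stable fixed points.
#'
#' For the two-strain circuit each cell carries a single module: set
#' `strain` to `"M1"` (GFP-bearing AraC strain: RFP stays at
#' autofluorescence) or `"M2"` (RFP-bearing LuxR strain); the partner
#' module's level in the shared coculture is simulated alongside and acts as
#' the C6 field, but is not reported by the cell.
#'
#' @param variant a `model_variant` or name.
#' @param params a `circuit_params`, or NULL for the variant preset.
#' @param protocol an `induction_protocol`.
#' @param n_cells population size; 10,000 events matches one recorded flow
#'   sample.
#' @param mode `"SSA"` (single-cell stochastic kinetics) or
#'   `"ODE_PLUS_NOISE"` (deterministic endpoint, variability from extrinsic
#'   noise + instrument only).
#' @param extrinsic_cv extrinsic noise CV applied to alpha and delta.
#' @param volume SSA system size.
#' @param seed integer master seed.
#' @param strain `"single"`, `"M1"` or `"M2"` (see above).
#' @param doublet_fraction injected doublet fraction (default 5%).
#' @param gains,autofluorescence,measurement_cv instrument model settings.
#' @return object of class `cell_population`: data.frame with columns
#'   `gfp`, `rfp`, `fsc_a`, `fsc_h`, `is_doublet`, `m1`, `m2`, `strain`,
#'   `fate`; attributes `protocol`, `seed`, `mode`, `thresholds`, `gains`,
#'   `autofluorescence`.
#' @export
simulate_population <- function(variant, params = NULL, protocol,
                                n_cells = 10000,
                                mode = c("SSA", "ODE_PLUS_NOISE"),
                                extrinsic_cv = 0.15, volume = 5, seed,
                                strain = c("single", "M1", "M2"),
                                doublet_fraction = 0.05,
                                gains = c(50, 50),
                                autofluorescence = c(100, 100),
                                measurement_cv = 0.2) {
  mode <- match.arg(mode)
  strain <- match.arg(strain)
  v <- as_variant(variant)
  if (missing(seed)) stop("simulate_population: seed must be given")
  if (n_cells < 1) stop("simulate_population: n_cells must be >= 1")
  if (is.null(params)) params <- make_variant_params(v)
  fps <- find_fixed_points(params, protocol, v)
  thr <- fate_thresholds(fps, params)
  cells <- sample_cell_params(params, extrinsic_cv, n = n_cells,
                              seed = cell_seed(seed, 0))
  states <- matrix(NA_real_, n_cells, 2)
  for (i in seq_len(n_cells)) {
    if (mode == "SSA") {
      tr <- ssa_trajectory(cells[[i]], protocol, v, volume = volume,
                           seed = cell_seed(seed, i),
                           sample_times = protocol$t_end)
      states[i, ] <- tr$final / volume
    } else {
      states[i, ] <- terminal_state(cells[[i]], protocol, v)$state
    }
  }
  fate <- classify_fate(states, thr)
  report <- states
  if (strain == "M1") report[, 2] <- 0  # RFP not carried by this strain
  if (strain == "M2") report[, 1] <- 0
  ch <- fluorescence_channels(report, gains = gains,
                              autofluorescence = autofluorescence,
                              measurement_cv = measurement_cv,
                              seed = cell_seed(seed, n_cells + 1),
                              doublet_fraction = doublet_fraction)
  pop <- cbind(ch, m1 = states[, 1], m2 = states[, 2],
               strain = if (strain == "single") "A" else strain,
               fate = fate, stringsAsFactors = FALSE)
  structure(pop, class = c("cell_population", "data.frame"),
            protocol = protocol, seed = as.integer(seed), mode = mode,
            thresholds = thr, gains = gains,
            autofluorescence = autofluorescence)
}

#' Mix two strain populations into a consortium sample
#'
#' Randomly interleaves per-cell records from two populations at a target
#' fraction of population A. If one input limits the target ratio, the other
#' is subsampled (without replacement) to honor it.
#'
#' @param popA,popB `cell_population` objects (per-cell records kept).
#' @param fractionA target fraction of A cells in `[0, 1]`.
#' @param seed integer seed for the interleave.
#' @return a `cell_population` with both strain tags.
#' @export
mix_strains <- function(popA, popB, fractionA = 0.5, seed = 1) {
  if (fractionA < 0 || fractionA > 1)
    stop("mix_strains: fractionA must be in [0, 1]")
  nA <- nrow(popA); nB <- nrow(popB)
  set.seed(as.integer(seed))
  if (fractionA == 1) return(popA)
  if (fractionA == 0) return(popB)
  n_tot <- min(floor(nA / fractionA), floor(nB / (1 - fractionA)))
  kA <- round(fractionA * n_tot); kB <- n_tot - kA
  idxA <- sample.int(nA, kA); idxB <- sample.int(nB, kB)
  out <- rbind(as.data.frame(popA)[idxA, , drop = FALSE],
               as.data.frame(popB)[idxB, , drop = FALSE])
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cell_population", "data.frame"),
            protocol = attr(popA, "protocol"), seed = as.integer(seed),
            mode = attr(popA, "mode"), thresholds = attr(popA, "thresholds"),
            gains = attr(popA, "gains"),
            autofluorescence = attr(popA, "autofluorescence"))
}

#' Write a population as CSV with a metadata sidecar
#'
#' @param pop a `cell_population`.
#' @param path output CSV path; metadata goes to `<path>_meta.csv`.
#' @return invisibly, the paths written.
#' @export
write_population_csv <- function(pop, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(pop), path, row.names = FALSE)
  pr <- attr(pop, "protocol")
  meta <- data.frame(
    key = c("seed", "mode", "d_lara", "d_c6", "d_atc", "t_c6", "t_end",
            "threshold_m1", "threshold_m2"),
    value = c(attr(pop, "seed"), attr(pop, "mode"), pr$d_lara, pr$d_c6,
              pr$d_atc, pr$t_c6, pr$t_end, attr(pop, "thresholds")[1],
              attr(pop, "thresholds")[2]))
  meta_path <- sub("\\.csv$", "_meta.csv", path)
  utils::write.csv(meta, meta_path, row.names = FALSE)
  invisible(c(path, meta_path))
}
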