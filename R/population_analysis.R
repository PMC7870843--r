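# Population-level analysis: scatter gating, fate fractions, dose-response
# summaries, and the continuous two-segment piecewise-linear fit of the
# RFP-vs-GFP trade-off curve.

#' Singlet gating on the FSC-A/FSC-H ratio
#'
#' Keeps events whose `fsc_h / fsc_a` ratio lies inside the band; doublets
#' (depressed ratio) and aggregates fall outside. The retained fraction is
#' reported as an attribute.
#'
#' @param pop a `cell_population`.
#' @param ratio_band length-2 `(low, high)` bounds on `fsc_h / fsc_a`.
#' @return the gated `cell_population` (attribute `gated_fraction`).
#' @export
gate_singlets <- function(pop, ratio_band = c(0.85, 1.15)) {
  ratio <- pop$fsc_h / pop$fsc_a
  keep <- ratio >= ratio_band[1] & ratio <= ratio_band[2]
  if (!any(keep)) warning("gate_singlets: no events inside the ratio band")
  out <- pop[keep, , drop = FALSE]
  for (a in c("protocol", "seed", "mode", "thresholds", "gains",
              "autofluorescence"))
    attr(out, a) <- attr(pop, a)
  class(out) <- class(pop)
  attr(out, "gated_fraction") <- mean(keep)
  out
}

#' Fate fractions of a population
#'
#' Classifies events from their fluorescence channels: channels are mapped
#' back to expression scale using the population's instrument settings
#' (`(channel - autofluorescence) / gain`) and compared to the model-derived
#' thresholds. Returns overall and per-strain fractions (each summing to 1).
#'
#' @param pop a `cell_population`.
#' @param thresholds optional length-2 expression-scale thresholds; default
#'   the thresholds recorded on the population (a note is emitted).
#' @return list with `overall` (named fractions) and `by_strain` (table).
#' @export
fate_fractions <- function(pop, thresholds = NULL) {
  if (is.null(thresholds)) {
    thresholds <- attr(pop, "thresholds")
    message("fate_fractions: using preset-derived thresholds (",
            paste(signif(thresholds, 4), collapse = ", "), ")")
  }
  gains <- attr(pop, "gains") %||% c(50, 50)
  auto <- attr(pop, "autofluorescence") %||% c(100, 100)
  m1_hat <- pmax((pop$gfp - auto[1]) / gains[1], 0)
  m2_hat <- pmax((pop$rfp - auto[2]) / gains[2], 0)
  fate <- classify_fate(cbind(m1_hat, m2_hat), thresholds)
  tab <- table(factor(fate, levels = FATE_LABELS))
  by_strain <- prop.table(table(pop$strain,
                                factor(fate, levels = FATE_LABELS)),
                          margin = 1)
  list(overall = stats::setNames(as.numeric(tab) / sum(tab), FATE_LABELS),
       by_strain = by_strain)
}

#' Simulated plate-reader dose-response
#'
#' For each dose on the axis, reads out the population-average (or
#' deterministic) reporter levels at the end of the induction window, with
#' the blank (autofluorescence) subtracted, and normalizes each channel to
#' its maximum over the sweep.
#'
#' @param variant a `model_variant` or name.
#' @param params a `circuit_params`, or NULL for the variant preset.
#' @param doses L-arabinose dose axis (monotone).
#' @param responder `"MEAN"` or `"MEDIAN"` population summary (population
#'   mode only).
#' @param mode `"ODE"` (deterministic endpoint per dose) or `"POPULATION"`
#'   (mean over a simulated population with extrinsic noise).
#' @param t_end induction window, hours.
#' @param n_cells population size per dose (population mode).
#' @param seed master seed (population mode).
#' @param dose_axis which inducer the axis refers to: `"d_lara"`, `"d_c6"`
#'   or `"d_atc"` (the others held at 0).
#' @return data.frame with columns `dose`, `gfp`, `rfp`, `gfp_norm`,
#'   `rfp_norm`.
#' @export
dose_response_curve <- function(variant, params = NULL, doses,
                                responder = c("MEAN", "MEDIAN"),
                                mode = c("ODE", "POPULATION"), t_end = 16,
                                n_cells = 400, seed = 1,
                                dose_axis = "d_lara") {
  responder <- match.arg(responder)
  mode <- match.arg(mode)
  v <- as_variant(variant)
  if (!length(doses)) stop("dose_response_curve: empty dose axis")
  if (is.null(params)) params <- make_variant_params(v)
  gfp <- rfp <- numeric(length(doses))
  for (i in seq_along(doses)) {
    args <- list(d_lara = 0, d_c6 = 0, d_atc = 0, t_end = t_end)
    args[[dose_axis]] <- doses[i]
    pr <- do.call(induction_protocol, args)
    if (mode == "ODE") {
      st <- terminal_state(params, pr, v)$state
      gfp[i] <- st[1]; rfp[i] <- st[2]
    } else {
      pop <- simulate_population(v, params, pr, n_cells = n_cells,
                                 mode = "ODE_PLUS_NOISE", seed = seed + i,
                                 doublet_fraction = 0, measurement_cv = 0)
      f <- if (responder == "MEAN") mean else stats::median
      auto <- attr(pop, "autofluorescence")
      gains <- attr(pop, "gains")
      gfp[i] <- f((pop$gfp - auto[1]) / gains[1])
      rfp[i] <- f((pop$rfp - auto[2]) / gains[2])
    }
  }
  data.frame(dose = doses, gfp = gfp, rfp = rfp,
             gfp_norm = gfp / max(gfp), rfp_norm = rfp / max(rfp))
}

#' Continuous piecewise-linear (hinge) fit with model selection
#'
#' Fits a single line and a continuous two-segment hinge
#' `y = b0 + b1 x + b2 (x - c)+` by least squares, searching breakpoint
#' candidates over the interior x-quantiles (5th to 95th percentile, one
#' percentile steps), and selects 1 vs 2 segments by BIC (the hinge pays for
#' 2 extra parameters: the second slope and the breakpoint). The hinge is
#' adopted only when it improves BIC by more than 2 (positive evidence),
#' which keeps the false-positive rate on plain noisy lines near zero.
#'
#' @param x,y numeric vectors (at least 6 points).
#' @param max_segments 1 or 2.
#' @return object of class `piecewise_fit`: list with `n_segments`,
#'   `breakpoint` (NA for one segment), `slopes`, `intercepts`, `sse`,
#'   `bic` (named, both models), `candidates` (breakpoint score table).
#' @export
fit_piecewise_linear <- function(x, y, max_segments = 2) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 6) stop("fit_piecewise_linear: need at least 6 points")
  fit1 <- stats::lm(y ~ x)
  sse1 <- sum(stats::resid(fit1)^2)
  bic <- function(sse, k) n * log(max(sse, 1e-300) / n) + k * log(n)
  out1 <- list(n_segments = 1L, breakpoint = NA_real_,
               slopes = unname(stats::coef(fit1)[2]),
               intercepts = unname(stats::coef(fit1)[1]), sse = sse1,
               bic = c(one = bic(sse1, 2), two = NA),
               candidates = NULL)
  class(out1) <- "piecewise_fit"
  if (max_segments < 2) return(out1)
  if (length(unique(x)) < 4 || sse1 < 1e-12 * stats::var(y) * n) {
    out1$note <- "degenerate or exactly linear input; single segment"
    return(out1)
  }
  cand <- unique(stats::quantile(x, probs = seq(0.05, 0.95, by = 0.01),
                                 names = FALSE, type = 7))
  # breakpoints must leave at least 2 points strictly on each side
  xs <- sort(x)
  cand <- cand[cand > xs[2] & cand < xs[n - 1]]
  if (!length(cand)) return(out1)
  scores <- data.frame(breakpoint = cand, sse = NA_real_)
  best <- NULL
  for (i in seq_along(cand)) {
    h <- pmax(x - cand[i], 0)
    f <- stats::lm(y ~ x + h)
    sse <- sum(stats::resid(f)^2)
    scores$sse[i] <- sse
    if (is.null(best) || sse < best$sse)
      best <- list(sse = sse, c = cand[i], coef = stats::coef(f))
  }
  bic2 <- bic(best$sse, 4)
  if (bic2 < bic(sse1, 2) - 2) {
    b <- best$coef
    slope_left <- unname(b[2]); slope_right <- unname(b[2] + b[3])
    structure(list(n_segments = 2L, breakpoint = best$c,
                   slopes = c(left = slope_left, right = slope_right),
                   intercepts = c(left = unname(b[1]),
                                  right = unname(b[1] - b[3] * best$c)),
                   sse = best$sse,
                   bic = c(one = bic(sse1, 2), two = bic2),
                   candidates = scores),
              class = "piecewise_fit")
  } else {
    out1$bic["two"] <- bic2
    out1$candidates <- scores
    out1
  }
}

#' @export
print.piecewise_fit <- function(x, ...) {
  if (x$n_segments == 1) {
    cat(sprintf("<piecewise_fit> 1 segment, slope %.4g, sse %.4g\n",
                x$slopes[1], x$sse))
  } else {
    cat(sprintf(
      "<piecewise_fit> 2 segments, breakpoint %.4g, slopes (%.4g, %.4g), sse %.4g\n",
      x$breakpoint, x$slopes[1], x$slopes[2], x$sse))
  }
  invisible(x)
}
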