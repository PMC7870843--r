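#' @useDynLib cbswitch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

VARIANT_NAMES <- c("CBS_IDEAL", "CBS_COMPETITION", "SBS_COMPETITION",
                   "CBS_HYBRID_TETR", "TWO_STRAIN_CBS")
LINK_REGIMES <- c("WEAK_M1_TO_M2", "WEAK_M2_TO_M1", "BALANCED")
FATE_LABELS <- c("LL", "LH", "HL", "HH")

PARAM_FIELDS <- c("alpha1", "alpha2", "beta1", "beta2", "K1", "K2", "n1", "n2",
                  "delta1", "delta2", "c12", "c21", "lambda1", "lambda2",
                  "Ka", "na", "Kc", "nc", "Kt", "nt", "tetR_strength",
                  "copy_scale")

#' Kinetic parameter set for a two-module switch circuit
#'
#' Bundles every constant of the reduced two-variable circuit models: maximal
#' production rates (`alpha`), basal leak fractions (`beta`), self-activation
#' Hill constants (`K`, `n`), removal rates (`delta`, degradation-tag turnover
#' plus dilution lumped together), inter-module connection weights (`c12`:
#' module 1 drives module 2 via effective C6 synthesis; `c21`: module 2 drives
#' module 1), resource-demand coefficients (`lambda`, zero disables
#' competition), inducer dose-response constants for L-arabinose (`Ka`, `na`),
#' C6 homoserine lactone (`Kc`, `nc`) and aTc/TetR relief (`Kt`, `nt`,
#' `tetR_strength`), and a plasmid copy-number multiplier (`copy_scale`).
#'
#' Concentrations are in arbitrary expression units, time in hours, doses in
#' the experimental units (% w/v L-ara, molar C6, ng/ml aTc).
#'
#' @param ... named numeric values for any of the fields listed above.
#' @param .base optional existing `circuit_params` object used as the starting
#'   point; `...` overrides individual fields.
#' @return an object of class `circuit_params` (a validated named list).
#' @export
circuit_params <- function(..., .base = NULL) {
  defaults <- list(
    alpha1 = 100, alpha2 = 100, beta1 = 0.01, beta2 = 0.01,
    K1 = 20, K2 = 20, n1 = 2, n2 = 2,
    delta1 = 1, delta2 = 1,
    c12 = 0, c21 = 0, lambda1 = 0, lambda2 = 0,
    Ka = 9.5e-4, na = 2, Kc = 5e-8, nc = 2,
    Kt = 20, nt = 2, tetR_strength = 0,
    copy_scale = 1
  )
  p <- if (is.null(.base)) defaults else unclass(.base)
  ov <- list(...)
  if (length(ov) == 1L && is.list(ov[[1]]) && is.null(names(ov)[1]))
    ov <- ov[[1]]
  if (length(ov)) {
    bad <- setdiff(names(ov), PARAM_FIELDS)
    if (length(bad))
      stop("unknown circuit_params field(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- lapply(ov, as.numeric)
  }
  p <- p[PARAM_FIELDS]
  class(p) <- "circuit_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  chk <- function(cond, field, msg) {
    if (!cond) stop("invalid circuit_params: field '", field, "' ", msg,
                    call. = FALSE)
  }
  for (f in PARAM_FIELDS)
    chk(is.numeric(p[[f]]) && length(p[[f]]) == 1L && is.finite(p[[f]]),
        f, "must be a finite scalar")
  for (f in c("alpha1", "alpha2", "K1", "K2", "delta1", "delta2",
              "Ka", "Kc", "Kt", "copy_scale"))
    chk(p[[f]] > 0, f, "must be strictly positive")
  for (f in c("n1", "n2", "na", "nc", "nt"))
    chk(p[[f]] >= 1, f, "must be a Hill coefficient >= 1")
  for (f in c("beta1", "beta2"))
    chk(p[[f]] >= 0 && p[[f]] < 1, f, "must lie in [0, 1)")
  for (f in c("lambda1", "lambda2", "c12", "c21", "tetR_strength"))
    chk(p[[f]] >= 0, f, "must be nonnegative")
  invisible(p)
}

#' Circuit model variant
#'
#' Names one member of the model family: the ideal cascading switches
#' (`CBS_IDEAL`, no resource competition), the same circuit with a shared
#' resource pool (`CBS_COMPETITION`), the two separated switches coupled only
#' through resources (`SBS_COMPETITION`), the hybrid variant whose module-1 to
#' module-2 link is gated by TetR and relieved by aTc (`CBS_HYBRID_TETR`), and
#' the two-strain division-of-labor circuit with decoupled resource pools and
#' no module-2 to module-1 link (`TWO_STRAIN_CBS`).
#'
#' @param name one of `r paste(VARIANT_NAMES, collapse = ", ")`.
#' @param link_regime default connection-strength calibration, one of
#'   `WEAK_M1_TO_M2`, `WEAK_M2_TO_M1`, `BALANCED`. Only `CBS_IDEAL` ships
#'   presets for more than one regime.
#' @return an object of class `model_variant`.
#' @export
model_variant <- function(name, link_regime = "WEAK_M2_TO_M1") {
  name <- match.arg(name, VARIANT_NAMES)
  link_regime <- match.arg(link_regime, LINK_REGIMES)
  structure(list(name = name, link_regime = link_regime),
            class = "model_variant")
}

as_variant <- function(variant) {
  if (inherits(variant, "model_variant")) return(variant)
  if (is.character(variant) && length(variant) == 1L)
    return(model_variant(variant))
  stop("variant must be a model_variant or a variant name")
}

#' Inducer dosing protocol
#'
#' Piecewise-constant induction: L-arabinose and aTc are applied from time 0,
#' C6 from its addition time `t_c6` (hours). Doses are zero before their
#' addition time and constant afterwards, mirroring bolus additions to a
#' culture.
#'
#' @param d_lara L-arabinose dose (% w/v).
#' @param d_c6 C6 homoserine lactone dose (molar).
#' @param d_atc aTc dose (ng/ml); only meaningful for the hybrid TetR variant.
#' @param t_c6 C6 addition time in hours (0 = at inoculation).
#' @param t_end simulation horizon in hours; the default matches a 16 h
#'   overnight induction window.
#' @return an object of class `induction_protocol`.
#' @export
induction_protocol <- function(d_lara = 0, d_c6 = 0, d_atc = 0,
                               t_c6 = 0, t_end = 16) {
  stopifnot(d_lara >= 0, d_c6 >= 0, d_atc >= 0,
            t_c6 >= 0, t_end > 0, t_c6 <= t_end)
  structure(list(d_lara = d_lara, d_c6 = d_c6, d_atc = d_atc,
                 t_c6 = t_c6, t_end = t_end),
            class = "induction_protocol")
}

preset_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "presets.yaml", package = "cbswitch")
      if (!nzchar(path)) stop("preset file not found")
      cache <<- yaml::read_yaml(path)
    }
    cache
  }
})

#' Calibrated default parameters for a model variant
#'
#' Returns the frozen preset parameter set for a variant (and, for the ideal
#' circuit, a link regime), optionally with field overrides. Presets live in
#' `inst/extdata/presets.yaml` and were calibrated once so that each variant
#' reproduces its reference phase-plane topology; they are data, not code.
#'
#' @param variant a `model_variant` or variant name.
#' @param overrides named list of `circuit_params` fields to override.
#' @return a `circuit_params` object satisfying the variant's structural
#'   invariants (`lambda = 0` for the ideal circuit, `c12 = c21 = 0` for the
#'   separated switches, `c21 = 0` for the two-strain circuit).
#' @export
make_variant_params <- function(variant, overrides = list()) {
  v <- as_variant(variant)
  tab <- preset_table()
  entry <- tab[[v$name]]
  if (is.null(entry)) stop("no preset for variant ", v$name)
  if (!is.null(entry[[v$link_regime]])) entry <- entry[[v$link_regime]]
  p <- circuit_params(entry)
  if (length(overrides)) p <- circuit_params(overrides, .base = p)
  # structural invariants that overrides may not break
  if (v$name == "CBS_IDEAL" && (p$lambda1 != 0 || p$lambda2 != 0))
    stop("CBS_IDEAL requires lambda1 = lambda2 = 0")
  if (v$name == "SBS_COMPETITION" && (p$c12 != 0 || p$c21 != 0))
    stop("SBS_COMPETITION requires c12 = c21 = 0")
  if (v$name == "TWO_STRAIN_CBS" && p$c21 != 0)
    stop("TWO_STRAIN_CBS requires c21 = 0 (AraC cannot travel between cells)")
  p
}

#' Reference induction protocol for a variant preset
#'
#' The dosing conditions under which each preset's reference phase-plane
#' topology was calibrated (for the separated-switch preset these are the
#' printed reference doses, 9.5e-4 % L-ara and 5e-8 M C6).
#'
#' @inheritParams make_variant_params
#' @param t_end horizon in hours.
#' @return an `induction_protocol`.
#' @export
reference_protocol <- function(variant, t_end = 16) {
  v <- as_variant(variant)
  doses <- switch(v$name,
    CBS_IDEAL       = list(d_lara = 9.5e-4, d_c6 = 0, d_atc = 0),
    CBS_COMPETITION = list(d_lara = 9.5e-4, d_c6 = 0, d_atc = 0),
    SBS_COMPETITION = list(d_lara = 9.5e-4, d_c6 = 5e-8, d_atc = 0),
    CBS_HYBRID_TETR = list(d_lara = 9.5e-4, d_c6 = 0, d_atc = 100),
    TWO_STRAIN_CBS  = list(d_lara = 9.5e-4, d_c6 = 0, d_atc = 0))
  induction_protocol(d_lara = doses$d_lara, d_c6 = doses$d_c6,
                     d_atc = doses$d_atc, t_c6 = 0, t_end = t_end)
}

#' Upper bound of the invariant state box
#'
#' Forward trajectories from nonnegative states can never exceed
#' `copy_scale * alpha_i / delta_i` per axis (production is bounded by the
#' maximal rate); used to size grids and lattices.
#'
#' @param params a `circuit_params` object.
#' @return numeric length-2 vector of per-axis bounds.
#' @export
state_bound <- function(params) {
  c(params$copy_scale * params$alpha1 / params$delta1,
    params$copy_scale * params$alpha2 / params$delta2)
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("<circuit_params>\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' @export
print.model_variant <- function(x, ...) {
  cat("<model_variant>", x$name, "/", x$link_regime, "\n")
  invisible(x)
}
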