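# Deterministic right-hand sides of the two-module circuit family.
#
# State (m1, m2): expression level of module 1 (AraC arm, GFP reporter) and
# module 2 (LuxR arm, RFP reporter). Each module self-activates through a Hill
# function of an effective input; the inter-module links enter the inputs, and
# a shared (or per-strain) resource pool rescales production.

#' Activating Hill response
#'
#' `x^n / (K^n + x^n)`: the fraction of a promoter driven by an activator at
#' level `x` with half-maximal threshold `K` and cooperativity `n`.
#'
#' @param x activator level (nonnegative; vectorized).
#' @param K half-maximal threshold, strictly positive.
#' @param n Hill coefficient, at least 1.
#' @return values in `[0, 1)`, monotone nondecreasing in `x`.
#' @export
hill_activation <- function(x, K, n) {
  if (!is.numeric(K) || any(K <= 0)) stop("hill_activation: K must be > 0")
  if (!is.numeric(n) || any(n < 1)) stop("hill_activation: n must be >= 1")
  if (any(x < 0)) stop("hill_activation: x must be nonnegative")
  xn <- (x / K)^n
  xn / (1 + xn)
}

#' Inducer dose to active-regulator fraction
#'
#' Maps an external inducer dose (L-ara, C6 or aTc) to the fraction of its
#' cognate regulator in the active form, as a Hill response. Zero dose gives
#' zero activity.
#'
#' @param dose inducer dose in its own units (nonnegative; vectorized).
#' @param K half-maximal dose.
#' @param n Hill coefficient, at least 1.
#' @return fraction in `[0, 1)`.
#' @export
induction_input <- function(dose, K, n) {
  if (any(dose < 0)) stop("induction_input: dose must be nonnegative")
  hill_activation(dose, K, n)
}

#' TetR relief factor for the hybrid Para/tet link
#'
#' The hybrid variant routes the module-1 to module-2 connection through a
#' promoter jointly controlled by AraC and TetR; aTc inactivates TetR and
#' releases the link. The relief factor multiplies `c12`:
#' `g = 1 / (1 + tetR_strength / (1 + (d_atc/Kt)^nt))`, so `g` rises from
#' `1/(1 + tetR_strength)` at zero aTc towards 1 at saturating aTc.
#'
#' @param d_atc aTc dose (ng/ml, nonnegative; vectorized).
#' @param params a `circuit_params` object (fields `Kt`, `nt`,
#'   `tetR_strength`).
#' @return relief factor in `(0, 1]`.
#' @export
tet_relief <- function(d_atc, params) {
  if (any(d_atc < 0)) stop("tet_relief: d_atc must be nonnegative")
  tet_active <- params$tetR_strength / (1 + (d_atc / params$Kt)^params$nt)
  1 / (1 + tet_active)
}

# doses in force at a given time (C6 steps on at t_c6)
active_inputs <- function(protocol, time, params) {
  u_A <- induction_input(protocol$d_lara, params$Ka, params$na)
  u_C <- if (time >= protocol$t_c6)
    induction_input(protocol$d_c6, params$Kc, params$nc) else 0
  list(u_A = u_A, u_C = u_C)
}

#' Promoter activities of the two modules
#'
#' Activity of module i is `beta_i + (1 - beta_i) * H(input_i; K_i, n_i)`
#' where `H` is [hill_activation()]. The effective inputs carry the induction
#' and the inter-module links:
#' `input_1 = m1 * u_A * (1 + c21 * m2)` (L-ara gates AraC self-activation,
#' module 2 boosts it through the c21 link) and
#' `input_2 = m2 * (u_C + c12 * m1 * u_A * g_tet)` (LuxR self-activation
#' driven by external C6 plus C6 synthesized by module 1; the synthesis runs
#' through the arabinose-dependent promoter, so it carries the active-AraC
#' fraction `u_A` — without L-arabinose the module-1 to module-2 link is
#' silent. `g_tet` is the TetR relief for the hybrid variant, 1 otherwise).
#'
#' @param m1,m2 module expression levels (nonnegative; vectorized).
#' @param protocol an `induction_protocol`.
#' @param time current time in hours (decides whether C6 is present).
#' @param params a `circuit_params`.
#' @param variant a `model_variant` or name.
#' @return list with components `a1`, `a2`, each in `(0, 1]`.
#' @export
promoter_activities <- function(m1, m2, protocol, time, params, variant) {
  v <- as_variant(variant)
  if (any(m1 < 0) || any(m2 < 0))
    stop("promoter_activities: state must be nonnegative")
  u <- active_inputs(protocol, time, params)
  g <- if (v$name == "CBS_HYBRID_TETR") tet_relief(protocol$d_atc, params) else 1
  in1 <- m1 * u$u_A * (1 + params$c21 * m2)
  in2 <- m2 * (u$u_C + params$c12 * m1 * u$u_A * g)
  list(a1 = params$beta1 + (1 - params$beta1) *
              hill_activation(in1, params$K1, params$n1),
       a2 = params$beta2 + (1 - params$beta2) *
              hill_activation(in2, params$K2, params$n2))
}

#' Fraction of shared expression resources available to a module
#'
#' One-strain circuits share a single pool: both modules see
#' `1 / (1 + lambda1 * a1 + lambda2 * a2)`, so activity of either module
#' depletes what the other can draw (the indirect mutual inhibition behind the
#' winner-takes-all behavior). The two-strain circuit hosts each module in its
#' own cell, decoupling the pools: module i sees `1 / (1 + lambda_i * a_i)`
#' regardless of the other module's activity.
#'
#' @param activity1,activity2 promoter activities in `[0, 1]` (vectorized).
#' @param params a `circuit_params` (fields `lambda1`, `lambda2`).
#' @param module which module's share, 1 or 2.
#' @param variant a `model_variant` or name.
#' @return fraction in `(0, 1]`; exactly 1 when both lambdas are 0.
#' @export
resource_fraction <- function(activity1, activity2, params, module, variant) {
  v <- as_variant(variant)
  stopifnot(module %in% c(1, 2))
  if (any(activity1 < 0 | activity1 > 1) || any(activity2 < 0 | activity2 > 1))
    stop("resource_fraction: activities must lie in [0, 1]")
  if (v$name == "TWO_STRAIN_CBS") {
    if (module == 1) 1 / (1 + params$lambda1 * activity1)
    else 1 / (1 + params$lambda2 * activity2)
  } else {
    1 / (1 + params$lambda1 * activity1 + params$lambda2 * activity2)
  }
}

#' Right-hand side of the circuit ODE
#'
#' `dm_i/dt = copy_scale * alpha_i * R_i * a_i - delta_i * m_i`, with `a_i`
#' from [promoter_activities()] and `R_i` from [resource_fraction()].
#' Production is bounded, so the box `[0, copy_scale * alpha_i / delta_i]` is
#' forward-invariant.
#'
#' @param state numeric length-2 `(m1, m2)`, nonnegative. `m1` and `m2` may
#'   also be equal-length vectors for grid evaluation.
#' @param time hours.
#' @param params a `circuit_params`.
#' @param protocol an `induction_protocol`.
#' @param variant a `model_variant` or name.
#' @return list with `dm1`, `dm2` (and the intermediate `a1`, `a2`, `r1`,
#'   `r2` as attributes-free list entries).
#' @export
circuit_rhs <- function(state, time, params, protocol, variant) {
  if (is.list(state)) {
    m1 <- state$m1; m2 <- state$m2
  } else {
    m1 <- state[[1]]; m2 <- state[[2]]
  }
  if (any(!is.finite(m1)) || any(!is.finite(m2)) || any(m1 < 0) || any(m2 < 0))
    stop("circuit_rhs: state must be finite and nonnegative")
  v <- as_variant(variant)
  a <- promoter_activities(m1, m2, protocol, time, params, v)
  r1 <- resource_fraction(a$a1, a$a2, params, 1, v)
  r2 <- resource_fraction(a$a1, a$a2, params, 2, v)
  list(dm1 = params$copy_scale * params$alpha1 * r1 * a$a1 - params$delta1 * m1,
       dm2 = params$copy_scale * params$alpha2 * r2 * a$a2 - params$delta2 * m2,
       a1 = a$a1, a2 = a$a2, r1 = r1, r2 = r2)
}

#' Integrate the circuit ODE
#'
#' Wraps [deSolve::ode()] (lsoda) around [circuit_rhs()], splitting the
#' integration at the C6 addition time so the dose step is resolved exactly.
#'
#' @param params,protocol,variant model specification.
#' @param init initial state `(m1, m2)`, default uninduced `(0, 0)`.
#' @param times output time points in hours; default 0 to `protocol$t_end`
#'   in 161 steps.
#' @param ... passed to [deSolve::ode()].
#' @return data.frame with columns `time`, `m1`, `m2`.
#' @export
integrate_circuit <- function(params, protocol, variant, init = c(0, 0),
                              times = NULL, ...) {
  v <- as_variant(variant)
  if (is.null(times)) times <- seq(0, protocol$t_end, length.out = 161)
  f <- function(t, y, parms) {
    d <- circuit_rhs(pmax(y, 0), t, params, protocol, v)
    list(c(d$dm1, d$dm2))
  }
  tc <- protocol$t_c6
  run <- function(tt, y0) {
    if (length(tt) < 2) return(cbind(time = tt, m1 = y0[1], m2 = y0[2]))
    out <- deSolve::ode(y = c(m1 = y0[1], m2 = y0[2]), times = tt, func = f,
                        parms = NULL, ...)
    unname(out)
  }
  if (tc > 0 && tc < protocol$t_end) {
    # integrate each dosing epoch separately; C6 switches on at t_c6
    t1 <- sort(unique(c(times[times <= tc], tc)))
    t2 <- sort(unique(c(tc, times[times >= tc])))
    o1 <- run(t1, init)
    o2 <- run(t2, c(o1[nrow(o1), 2], o1[nrow(o1), 3]))
    keep1 <- o1[, 1] %in% times
    keep2 <- o2[, 1] %in% times & !(o2[, 1] %in% o1[keep1, 1])
    out <- rbind(o1[keep1, , drop = FALSE], o2[keep2, , drop = FALSE])
  } else {
    out <- run(sort(unique(times)), init)
  }
  data.frame(time = out[, 1], m1 = pmax(out[, 2], 0), m2 = pmax(out[, 3], 0))
}

#' Terminal state of a deterministic trajectory
#'
#' Integrates from `init` to `protocol$t_end` and reports the final state
#' together with a settledness flag: the state is settled when it moved less
#' than `tol_frac` of the state-box size between `t_end / 2` and `t_end`.
#'
#' @inheritParams integrate_circuit
#' @param tol_frac movement tolerance as a fraction of the box diagonal.
#' @return list with `state` (length-2), `settled` (logical).
#' @export
terminal_state <- function(params, protocol, variant, init = c(0, 0),
                           tol_frac = 0.01) {
  tt <- c(0, protocol$t_end / 2, protocol$t_end)
  tt <- sort(unique(c(tt, protocol$t_c6)))
  tr <- integrate_circuit(params, protocol, variant, init = init, times = tt)
  last <- c(tr$m1[nrow(tr)], tr$m2[nrow(tr)])
  half <- which.min(abs(tr$time - protocol$t_end / 2))
  mid <- c(tr$m1[half], tr$m2[half])
  box <- sqrt(sum(state_bound(params)^2))
  list(state = last, settled = sqrt(sum((last - mid)^2)) < tol_frac * box)
}
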