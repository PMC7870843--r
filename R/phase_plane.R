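# Phase-plane analysis on the (m1, m2) plane: nullclines, fixed points with
# stability, separatrices, vector field, and fold (saddle-node) detection.

#' Fate-classification thresholds from stable fixed points
#'
#' Per axis, the threshold separating "low" from "high" expression is the
#' midpoint between the lowest and highest stable-attractor coordinate. The
#' midpoint is only meaningful when the attractors genuinely separate into
#' low and high groups, so it is used only when the spread exceeds 20% of
#' the axis bound; otherwise the threshold falls back to a quarter of the
#' axis bound, which cleanly separates leak-level from activated expression
#' in all presets.
#'
#' @param fixed_points data.frame from [find_fixed_points()].
#' @param params a `circuit_params` (for the fallback scale).
#' @return numeric length-2 vector `(theta1, theta2)`.
#' @export
fate_thresholds <- function(fixed_points, params) {
  bound <- state_bound(params)
  st <- fixed_points[fixed_points$stability == "STABLE", , drop = FALSE]
  thr <- bound / 4
  for (i in 1:2) {
    x <- if (i == 1) st$m1 else st$m2
    if (length(x) >= 2 && diff(range(x)) > 0.2 * bound[i])
      thr[i] <- (min(x) + max(x)) / 2
  }
  thr
}

#' Quadrant fate label of a state
#'
#' Labels a state by whether each module is above its threshold. The first
#' letter reports module 2 (the LuxR arm, RFP reporter) and the second letter
#' module 1 (the AraC arm, GFP reporter), matching the high-RFP/low-GFP style
#' quadrant naming: `HL` = module 2 high, module 1 low. States exactly at a
#' threshold count as high.
#'
#' @param state length-2 `(m1, m2)` or a 2-column matrix of states.
#' @param thresholds length-2 `(theta1, theta2)` from [fate_thresholds()].
#' @return character fate label(s) from `LL`, `LH`, `HL`, `HH`.
#' @export
classify_fate <- function(state, thresholds) {
  m <- if (is.matrix(state)) state else matrix(state, ncol = 2)
  b1 <- ifelse(m[, 1] >= thresholds[1], "H", "L")  # module 1 (GFP)
  b2 <- ifelse(m[, 2] >= thresholds[2], "H", "L")  # module 2 (RFP)
  paste0(b2, b1)
}

# axis grid graded toward zero: self-activation circuits place leak-level
# states orders of magnitude below the activated states, so a uniform grid
# misses near-axis roots; augment with log-spaced points down to 1e-6 of the
# bound
graded_axis <- function(bound, n) {
  sort(unique(c(seq(0, bound, length.out = n),
                bound * 10^seq(-6, -0.3, length.out = max(12, n %/% 3)))))
}

rhs_grid <- function(m1, m2, params, protocol, variant, time = 0) {
  g <- expand.grid(m1 = m1, m2 = m2)
  d <- circuit_rhs(list(m1 = g$m1, m2 = g$m2), time, params, protocol, variant)
  list(f1 = matrix(d$dm1, nrow = length(m1)),
       f2 = matrix(d$dm2, nrow = length(m1)))
}

#' Nullcline of one module
#'
#' For each grid value of the opposing variable, finds every root of
#' `dm_which/dt = 0` in the own variable by sign-change bracketing plus
#' `uniroot` refinement, then links roots across adjacent slices into
#' branches. Branch breaks occur at fold points where the root count changes.
#'
#' @param which 1 or 2, the module whose rate is zeroed.
#' @param params,protocol,variant model specification.
#' @param grid number of slices per axis (default 201) or a list with
#'   components `n` and `upper` (axis upper bounds, default the invariant
#'   box).
#' @param time evaluation time (doses in force), default after all additions.
#' @return data.frame with columns `m1`, `m2`, `branch` (integer id); ordered
#'   along each branch. Zero rows if the slice never changes sign.
#' @export
nullcline <- function(which, params, protocol, variant, grid = 201,
                      time = NULL) {
  stopifnot(which %in% c(1, 2))
  if (is.null(time)) time <- protocol$t_end
  bound <- state_bound(params) * 1.02
  if (is.list(grid)) {
    n <- grid$n %||% 201
    if (!is.null(grid$upper)) bound <- grid$upper
  } else n <- grid
  own <- which
  opp <- 3 - which
  own_ax <- graded_axis(bound[own], 4 * n)  # finer along the own axis
  opp_ax <- graded_axis(bound[opp], n)

  f_scalar <- function(x, y_opp) {
    st <- if (own == 1) list(m1 = x, m2 = y_opp) else list(m1 = y_opp, m2 = x)
    d <- circuit_rhs(st, time, params, protocol, variant)
    if (own == 1) d$dm1 else d$dm2
  }

  roots_per_slice <- vector("list", length(opp_ax))
  for (j in seq_along(opp_ax)) {
    vals <- f_scalar(own_ax, opp_ax[j])
    s <- sign(vals)
    idx <- which(s[-1] * s[-length(s)] < 0)
    r <- numeric(0)
    for (i in idx) {
      r <- c(r, stats::uniroot(f_scalar, lower = own_ax[i],
                               upper = own_ax[i + 1], y_opp = opp_ax[j],
                               tol = 1e-12 * bound[own])$root)
    }
    r <- c(r, own_ax[vals == 0])
    roots_per_slice[[j]] <- sort(unique(r))
  }

  # link roots across slices into branches by nearest-neighbor continuation
  jump_tol <- 0.12 * bound[own]
  branches <- list()   # each: list(own = ..., opp = ..., open = TRUE)
  next_id <- 1L
  pts <- list()
  active <- integer(0)  # branch ids with a point at the previous slice
  prev_pos <- numeric(0)
  for (j in seq_along(opp_ax)) {
    r <- roots_per_slice[[j]]
    assigned <- rep(NA_integer_, length(r))
    used <- logical(length(active))
    if (length(r) && length(active)) {
      for (k in order(r)) {
        d <- abs(prev_pos - r[k])
        d[used] <- Inf
        if (length(d) && min(d) < jump_tol) {
          w <- which.min(d)
          assigned[k] <- active[w]
          used[w] <- TRUE
        }
      }
    }
    for (k in seq_along(r)) {
      if (is.na(assigned[k])) {
        assigned[k] <- next_id
        next_id <- next_id + 1L
      }
      pts[[length(pts) + 1L]] <- c(own = r[k], opp = opp_ax[j],
                                   branch = assigned[k])
    }
    active <- assigned
    prev_pos <- r
  }
  if (!length(pts))
    return(data.frame(m1 = numeric(0), m2 = numeric(0), branch = integer(0)))
  m <- do.call(rbind, pts)
  out <- if (own == 1)
    data.frame(m1 = m[, "own"], m2 = m[, "opp"], branch = as.integer(m[, "branch"]))
  else
    data.frame(m1 = m[, "opp"], m2 = m[, "own"], branch = as.integer(m[, "branch"]))
  out[order(out$branch, if (own == 1) out$m2 else out$m1), , drop = FALSE]
}

#' Fold (saddle-node) points of a nullcline
#'
#' Detects the opposing-variable values at which the number of nullcline
#' roots changes by two (a fold of the bistable branch). Folds are named
#' positionally `SN1`, `SN2`, ... in increasing opposing-variable order;
#' the mapping to activation/deactivation thresholds is by position.
#'
#' @inheritParams nullcline
#' @return data.frame with columns `name`, `opposing_value`,
#'   `branch_count_low`, `branch_count_high`.
#' @export
nullcline_folds <- function(which, params, protocol, variant, grid = 201,
                            time = NULL) {
  nc <- nullcline(which, params, protocol, variant, grid = grid, time = time)
  opp <- if (which == 1) nc$m2 else nc$m1
  if (!nrow(nc))
    return(data.frame(name = character(0), opposing_value = numeric(0),
                      branch_count_low = integer(0),
                      branch_count_high = integer(0)))
  cnt <- table(opp)
  vals <- as.numeric(names(cnt))
  o <- order(vals)
  vals <- vals[o]; k <- as.integer(cnt)[o]
  ch <- which(diff(k) != 0)
  if (!length(ch))
    return(data.frame(name = character(0), opposing_value = numeric(0),
                      branch_count_low = integer(0),
                      branch_count_high = integer(0)))
  data.frame(name = paste0("SN", seq_along(ch)),
             opposing_value = (vals[ch] + vals[ch + 1]) / 2,
             branch_count_low = k[ch], branch_count_high = k[ch + 1])
}

numeric_jacobian <- function(loc, params, protocol, variant, time,
                             h_frac = 1e-6) {
  bound <- state_bound(params)
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    h <- max(h_frac * bound[j], h_frac * abs(loc[j]), 1e-10)
    up <- loc; up[j] <- loc[j] + h
    dn <- loc; dn[j] <- max(loc[j] - h, 0)
    du <- circuit_rhs(up, time, params, protocol, variant)
    dd <- circuit_rhs(dn, time, params, protocol, variant)
    J[1, j] <- (du$dm1 - dd$dm1) / (up[j] - dn[j])
    J[2, j] <- (du$dm2 - dd$dm2) / (up[j] - dn[j])
  }
  J
}

#' Linear stability of a fixed point
#'
#' Central-difference Jacobian at the point (step scaled to the state box),
#' eigenvalues, and classification: both real parts negative = `STABLE`,
#' opposite signs = `SADDLE`, both positive = `UNSTABLE`. A real part within
#' `1e-6` (scaled by `delta`) of zero raises a marginality error so the
#' caller can refine rather than misclassify near a bifurcation.
#'
#' @param location length-2 fixed-point location (must be a root to
#'   tolerance).
#' @param params,protocol,variant model specification.
#' @param time evaluation time, default end of protocol.
#' @return list with `eigenvalues` (complex length-2) and `stability`.
#' @export
classify_stability <- function(location, params, protocol, variant,
                               time = NULL) {
  if (is.null(time)) time <- protocol$t_end
  J <- numeric_jacobian(location, params, protocol, variant, time)
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  scale <- max(params$delta1, params$delta2)
  if (any(abs(re) < 1e-6 * scale))
    stop("MARGINAL: eigenvalue real part within tolerance of zero at (",
         paste(signif(location, 6), collapse = ", "), ")")
  stability <- if (all(re < 0)) "STABLE" else if (all(re > 0)) "UNSTABLE"
               else "SADDLE"
  list(eigenvalues = ev, stability = stability)
}

newton_refine <- function(start, params, protocol, variant, time,
                          tol, max_iter = 60) {
  x <- pmax(start, 0)
  bound <- state_bound(params) * 1.05
  for (it in seq_len(max_iter)) {
    d <- circuit_rhs(x, time, params, protocol, variant)
    f <- c(d$dm1, d$dm2)
    if (max(abs(f)) < tol) return(x)
    J <- numeric_jacobian(x, params, protocol, variant, time)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {   # damping: accept only residual-reducing steps
      xn <- pmin(pmax(x + lam * step, 0), bound)
      dn <- circuit_rhs(xn, time, params, protocol, variant)
      if (max(abs(c(dn$dm1, dn$dm2))) < max(abs(f)) || lam < 1e-4) break
      lam <- lam / 2
    }
    if (max(abs(x - xn)) < 1e-14 * max(bound)) return(NULL)
    x <- xn
  }
  d <- circuit_rhs(x, time, params, protocol, variant)
  if (max(abs(c(d$dm1, d$dm2))) < tol) x else NULL
}

#' Find all fixed points in the invariant box
#'
#' Scans a grid for cells where both components of the vector field change
#' sign among the cell corners, refines each candidate with a damped Newton
#' iteration, deduplicates by distance, and classifies stability. Candidates
#' on which Newton fails are dropped with a warning, never an error.
#'
#' @param params,protocol,variant model specification.
#' @param grid_density grid points per axis for the scan (>= 50).
#' @param time evaluation time, default end of protocol (all doses in force).
#' @param tol_rhs root tolerance on `|rhs|`, in rate units scaled to the box.
#' @return data.frame with columns `m1`, `m2`, `eig1_re`, `eig1_im`,
#'   `eig2_re`, `eig2_im`, `stability`, `fate`; fate labels are assigned with
#'   [fate_thresholds()] computed from the stable set itself.
#' @export
find_fixed_points <- function(params, protocol, variant, grid_density = 120,
                              time = NULL, tol_rhs = NULL) {
  stopifnot(grid_density >= 50)
  if (is.null(time)) time <- protocol$t_end
  bound <- state_bound(params) * 1.02
  if (is.null(tol_rhs)) tol_rhs <- 1e-8 * max(bound)
  ax1 <- graded_axis(bound[1], grid_density)
  ax2 <- graded_axis(bound[2], grid_density)
  fg <- rhs_grid(ax1, ax2, params, protocol, variant, time = time)
  s1 <- sign(fg$f1); s2 <- sign(fg$f2)
  cell_change <- function(s) {
    nr <- nrow(s); nc <- ncol(s)
    a <- s[-nr, -nc]; b <- s[-1, -nc]; c2 <- s[-nr, -1]; d <- s[-1, -1]
    mn <- pmin(a, b, c2, d); mx <- pmax(a, b, c2, d)
    mn < 0 & mx > 0 | mn == 0 | mx == 0
  }
  cand <- which(cell_change(s1) & cell_change(s2), arr.ind = TRUE)
  roots <- list()
  dropped <- 0L
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    start <- c((ax1[i] + ax1[i + 1]) / 2, (ax2[j] + ax2[j + 1]) / 2)
    r <- newton_refine(start, params, protocol, variant, time, tol_rhs)
    if (is.null(r)) dropped <- dropped + 1L else roots[[length(roots) + 1L]] <- r
  }
  # the origin region can be missed when leak makes f1, f2 > 0 on the whole
  # first cell; also seed corners of the box
  for (start in list(c(0, 0), c(bound[1], 0), c(0, bound[2]), bound * 0.9)) {
    r <- newton_refine(start, params, protocol, variant, time, tol_rhs)
    if (!is.null(r)) roots[[length(roots) + 1L]] <- r
  }
  if (dropped > 0)
    warning(dropped, " fixed-point candidate(s) dropped: Newton did not converge")
  if (!length(roots))
    return(data.frame(m1 = numeric(0), m2 = numeric(0), eig1_re = numeric(0),
                      eig1_im = numeric(0), eig2_re = numeric(0),
                      eig2_im = numeric(0), stability = character(0),
                      fate = character(0)))
  pts <- do.call(rbind, roots)
  dedup_r <- 1e-4 * max(bound)
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(pts))) {
      if (j <= i || !keep[j]) next
      if (sqrt(sum((pts[i, ] - pts[j, ])^2)) < dedup_r) keep[j] <- FALSE
    }
  }
  pts <- pts[keep, , drop = FALSE]
  res <- data.frame(m1 = pts[, 1], m2 = pts[, 2])
  cls <- lapply(seq_len(nrow(res)), function(i) {
    tryCatch(classify_stability(c(res$m1[i], res$m2[i]), params, protocol,
                                variant, time = time),
             error = function(e) list(eigenvalues = c(NA, NA),
                                      stability = "MARGINAL"))
  })
  res$eig1_re <- vapply(cls, function(x) Re(x$eigenvalues[1]), 0)
  res$eig1_im <- vapply(cls, function(x) Im(x$eigenvalues[1]), 0)
  res$eig2_re <- vapply(cls, function(x) Re(x$eigenvalues[2]), 0)
  res$eig2_im <- vapply(cls, function(x) Im(x$eigenvalues[2]), 0)
  res$stability <- vapply(cls, function(x) x$stability, "")
  thr <- fate_thresholds(res, params)
  res$fate <- classify_fate(cbind(res$m1, res$m2), thr)
  attr(res, "thresholds") <- thr
  res[order(res$m1 + res$m2), , drop = FALSE]
}

#' Stable manifold of a saddle (separatrix)
#'
#' Traces the basin boundary through a saddle by integrating the
#' unit-speed, time-reversed flow from two seeds offset by a small epsilon
#' along the saddle's stable eigenvector, clipping at the invariant box or a
#' fixed arc length. The two half-branches are concatenated through the
#' saddle.
#'
#' @param saddle one row of a [find_fixed_points()] result with stability
#'   `SADDLE`, or a length-2 location.
#' @param params,protocol,variant model specification.
#' @param arc_length maximum arc length traced per half-branch, default 1.5
#'   box diagonals.
#' @param time evaluation time, default end of protocol.
#' @param step arc-length integration step, default box diagonal / 2000.
#' @return data.frame with columns `m1`, `m2`, ordered along the curve.
#' @export
separatrix <- function(saddle, params, protocol, variant, arc_length = NULL,
                       time = NULL, step = NULL) {
  if (is.null(time)) time <- protocol$t_end
  if (is.data.frame(saddle)) {
    if (!identical(saddle$stability[1], "SADDLE"))
      stop("separatrix: fixed point is not a SADDLE")
    loc <- c(saddle$m1[1], saddle$m2[1])
  } else loc <- as.numeric(saddle)
  bound <- state_bound(params) * 1.02
  diag_len <- sqrt(sum(bound^2))
  if (is.null(arc_length)) arc_length <- 1.5 * diag_len
  if (is.null(step)) step <- diag_len / 2000
  J <- numeric_jacobian(loc, params, protocol, variant, time)
  ev <- eigen(J)
  re <- Re(ev$values)
  if (!(any(re < 0) && any(re > 0)))
    stop("separatrix: point is not a saddle (eigenvalues ",
         paste(signif(re, 4), collapse = ", "), ")")
  vstab <- Re(ev$vectors[, which.min(re)])
  vstab <- vstab / sqrt(sum(vstab^2))
  eps <- 1e-6 * diag_len
  trace_half <- function(sgn) {
    x <- loc + sgn * eps * vstab
    n_steps <- ceiling(arc_length / step)
    out <- matrix(NA_real_, n_steps + 1, 2)
    out[1, ] <- x
    vfield <- function(y) {
      y <- pmin(pmax(y, 0), bound)
      d <- circuit_rhs(y, time, params, protocol, variant)
      v <- -c(d$dm1, d$dm2)         # time-reversed flow
      nv <- sqrt(sum(v^2))
      if (nv < 1e-12) v * 0 else v / nv
    }
    m <- 1L
    for (k in seq_len(n_steps)) {
      k1 <- vfield(x)
      k2 <- vfield(x + step / 2 * k1)
      k3 <- vfield(x + step / 2 * k2)
      k4 <- vfield(x + step * k3)
      x <- x + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (any(x < -1e-9) || any(x > bound + 1e-9)) break
      m <- m + 1L
      out[m, ] <- pmin(pmax(x, 0), bound)
    }
    out[seq_len(m), , drop = FALSE]
  }
  upper <- trace_half(+1)
  lower <- trace_half(-1)
  pts <- rbind(upper[rev(seq_len(nrow(upper))), , drop = FALSE],
               loc, lower)
  data.frame(m1 = pts[, 1], m2 = pts[, 2])
}

#' Full phase portrait
#'
#' Bundles nullclines, fixed points (with stability and fate labels), a
#' separatrix from every saddle, and a vector-field sample grid. Deterministic
#' for fixed inputs.
#'
#' @param params,protocol,variant model specification.
#' @param grid nullcline slices per axis (also used, halved, for the field).
#' @param grid_density fixed-point scan density.
#' @param time evaluation time, default end of protocol.
#' @return object of class `phase_portrait`: list with `nullcline1`,
#'   `nullcline2`, `fixed_points`, `separatrices` (list of data.frames),
#'   `field` (data.frame `m1`, `m2`, `dm1`, `dm2`), `thresholds`.
#' @export
phase_portrait <- function(params, protocol, variant, grid = 201,
                           grid_density = 120, time = NULL) {
  if (is.null(time)) time <- protocol$t_end
  fps <- find_fixed_points(params, protocol, variant,
                           grid_density = grid_density, time = time)
  n1 <- nullcline(1, params, protocol, variant, grid = grid, time = time)
  n2 <- nullcline(2, params, protocol, variant, grid = grid, time = time)
  seps <- list()
  sad <- fps[fps$stability == "SADDLE", , drop = FALSE]
  for (i in seq_len(nrow(sad)))
    seps[[i]] <- separatrix(sad[i, , drop = FALSE], params, protocol, variant,
                            time = time)
  bound <- state_bound(params)
  ax1 <- seq(0, bound[1], length.out = 21)
  ax2 <- seq(0, bound[2], length.out = 21)
  g <- expand.grid(m1 = ax1, m2 = ax2)
  d <- circuit_rhs(list(m1 = g$m1, m2 = g$m2), time, params, protocol, variant)
  field <- data.frame(m1 = g$m1, m2 = g$m2, dm1 = d$dm1, dm2 = d$dm2)
  structure(list(nullcline1 = n1, nullcline2 = n2, fixed_points = fps,
                 separatrices = seps, field = field,
                 thresholds = attr(fps, "thresholds")),
            class = "phase_portrait")
}

#' @export
print.phase_portrait <- function(x, ...) {
  cat("<phase_portrait>\n")
  cat("  fixed points:\n")
  fp <- x$fixed_points
  for (i in seq_len(nrow(fp)))
    cat(sprintf("    (%8.3f, %8.3f)  %-8s %s\n", fp$m1[i], fp$m2[i],
                fp$stability[i], fp$fate[i]))
  cat("  separatrices:", length(x$separatrices), "\n")
  invisible(x)
}

#' Write a phase portrait as CSV tables
#'
#' One file per element (`nullclines.csv`, `fixed_points.csv`,
#' `separatrices.csv`, `field.csv`) under `dir`.
#'
#' @param portrait a `phase_portrait`.
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths written.
#' @export
write_portrait_csv <- function(portrait, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nc <- rbind(cbind(portrait$nullcline1, module = 1L),
              cbind(portrait$nullcline2, module = 2L))
  sep <- if (length(portrait$separatrices))
    do.call(rbind, lapply(seq_along(portrait$separatrices), function(i)
      cbind(portrait$separatrices[[i]], separatrix = i)))
  else data.frame(m1 = numeric(0), m2 = numeric(0), separatrix = integer(0))
  paths <- file.path(dir, c("nullclines.csv", "fixed_points.csv",
                            "separatrices.csv", "field.csv"))
  utils::write.csv(nc, paths[1], row.names = FALSE)
  utils::write.csv(portrait$fixed_points, paths[2], row.names = FALSE)
  utils::write.csv(sep, paths[3], row.names = FALSE)
  utils::write.csv(portrait$field, paths[4], row.names = FALSE)
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
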