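# Fate maps over inducer-dose and protocol space.

axis_spec <- function(values = NULL, from = NULL, to = NULL, n = 20,
                      scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (is.null(values)) {
    values <- if (scale == "log") exp(seq(log(from), log(to), length.out = n))
              else seq(from, to, length.out = n)
  }
  values
}

#' Log-spaced dose axis bracketing a reference dose
#'
#' Default fate-map axes span 4 decades centered on the reference dose (two
#' decades either side), log-spaced.
#'
#' @param reference reference dose (> 0).
#' @param n grid points.
#' @param decades total decades spanned.
#' @return numeric dose grid.
#' @export
dose_axis <- function(reference, n = 20, decades = 4) {
  exp(seq(log(reference) - decades / 2 * log(10),
          log(reference) + decades / 2 * log(10), length.out = n))
}

map_thresholds <- function(params, protocol, variant) {
  fps <- find_fixed_points(params, protocol, variant)
  fate_thresholds(fps, params)
}

classify_terminal <- function(params, protocol, variant, init, mode,
                              n_seeds, seed, thresholds, volume,
                              cell_counter) {
  if (mode == "DETERMINISTIC") {
    ts <- terminal_state(params, protocol, variant, init = init)
    if (!ts$settled) return("UNSETTLED")
    classify_fate(ts$state, thresholds)
  } else {
    fates <- character(n_seeds)
    for (s in seq_len(n_seeds)) {
      tr <- ssa_trajectory(params, protocol, variant, volume = volume,
                           seed = cell_seed(seed, cell_counter + s),
                           init = round(init * volume),
                           sample_times = protocol$t_end)
      fates[s] <- classify_fate(tr$final / volume, thresholds)
    }
    tab <- sort(table(fates), decreasing = TRUE)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) > 1)
      warning("stochastic fate tie at a grid point; choosing '",
              sort(winners)[1], "'")
    sort(winners)[1]
  }
}

new_fate_map <- function(grid, axis1_name, axis2_name, mode) {
  structure(list(grid = grid, axis1 = axis1_name, axis2 = axis2_name,
                 mode = mode), class = "fate_map")
}

#' Deterministic or stochastic fate map over two inducer-dose axes
#'
#' For every `(L-ara, C6)` grid point, runs the circuit from the uninduced
#' state to `t_end` (ODE, or majority fate over `n_seeds` SSA runs) and
#' classifies the terminal fate. Thresholds are derived once from the stable
#' fixed points at the map's reference doses (the grid medians), so labels
#' are comparable across the map. Trajectories still moving at `t_end`
#' (movement over the second half above 1% of the box) are labeled
#' `UNSETTLED` and excluded from region counts.
#'
#' @param variant,params model specification.
#' @param lara_axis,c6_axis dose grids (monotone; see [dose_axis()]).
#' @param init initial state, default uninduced `(0, 0)`.
#' @param t_end horizon in hours.
#' @param mode `"DETERMINISTIC"` or `"STOCHASTIC"`.
#' @param n_seeds SSA replicates per grid point in stochastic mode.
#' @param seed master seed (stochastic mode).
#' @param volume SSA system size (stochastic mode).
#' @param thresholds optional fixed classification thresholds.
#' @return object of class `fate_map`: list with `grid` (data.frame `axis1`,
#'   `axis2`, `label`), axis names, and `mode`.
#' @export
dose_sweep <- function(variant, params, lara_axis, c6_axis, init = c(0, 0),
                       t_end = 16, mode = c("DETERMINISTIC", "STOCHASTIC"),
                       n_seeds = 32, seed = 1, volume = 5,
                       thresholds = NULL) {
  mode <- match.arg(mode)
  stopifnot(!is.unsorted(lara_axis), !is.unsorted(c6_axis))
  if (is.null(thresholds)) {
    ref <- induction_protocol(d_lara = stats::median(lara_axis),
                              d_c6 = stats::median(c6_axis), t_end = t_end)
    thresholds <- map_thresholds(params, ref, variant)
  }
  g <- expand.grid(axis1 = lara_axis, axis2 = c6_axis)
  g$label <- NA_character_
  for (k in seq_len(nrow(g))) {
    pr <- induction_protocol(d_lara = g$axis1[k], d_c6 = g$axis2[k],
                             t_end = t_end)
    g$label[k] <- classify_terminal(params, pr, variant, init, mode,
                                    n_seeds, seed, thresholds, volume,
                                    cell_counter = (k - 1) * n_seeds)
  }
  if (any(g$label == "UNSETTLED"))
    warning(sum(g$label == "UNSETTLED"), " grid point(s) UNSETTLED at t_end")
  new_fate_map(g, "d_lara", "d_c6", mode)
}

#' Fate map over C6 dose and C6 addition time
#'
#' L-arabinose is applied at time 0 at a fixed dose; C6 is applied at each
#' addition time on the `t_c6` axis. Late C6 addition lets module 1 commit
#' (cross the separatrix) before module 2 can compete, so rows at late
#' addition shift toward module-1-only fates.
#'
#' @inheritParams dose_sweep
#' @param c6_axis C6 dose grid.
#' @param t_c6_axis C6 addition times (hours, within `[0, t_end]`).
#' @param d_lara fixed L-arabinose dose (should activate module 1 on its
#'   own; the preset reference dose qualifies).
#' @return a `fate_map` with axes `d_c6`, `t_c6`.
#' @export
sequential_induction_map <- function(variant, params, c6_axis, t_c6_axis,
                                     d_lara = 9.5e-4, t_end = 16,
                                     mode = c("DETERMINISTIC", "STOCHASTIC"),
                                     n_seeds = 32, seed = 1, volume = 5,
                                     thresholds = NULL) {
  mode <- match.arg(mode)
  stopifnot(!is.unsorted(c6_axis), !is.unsorted(t_c6_axis))
  if (is.null(thresholds)) {
    ref <- induction_protocol(d_lara = d_lara,
                              d_c6 = stats::median(c6_axis), t_end = t_end)
    thresholds <- map_thresholds(params, ref, variant)
  }
  g <- expand.grid(axis1 = c6_axis, axis2 = t_c6_axis)
  g$label <- NA_character_
  for (k in seq_len(nrow(g))) {
    pr <- induction_protocol(d_lara = d_lara, d_c6 = g$axis1[k],
                             t_c6 = g$axis2[k], t_end = t_end)
    g$label[k] <- classify_terminal(params, pr, variant, c(0, 0), mode,
                                    n_seeds, seed, thresholds, volume,
                                    cell_counter = (k - 1) * n_seeds)
  }
  new_fate_map(g, "d_c6", "t_c6", mode)
}

#' Fate map over aTc (and L-arabinose) for the hybrid TetR variant
#'
#' Sweeps the aTc dose that relieves TetR repression of the module-1 to
#' module-2 link, optionally crossed with an L-arabinose axis.
#'
#' @inheritParams dose_sweep
#' @param params hybrid-variant parameters (`tetR_strength > 0`).
#' @param atc_axis aTc dose grid (ng/ml).
#' @param lara_axis optional L-arabinose axis; default the single fixed dose.
#' @param d_lara fixed L-arabinose dose when `lara_axis` is not given.
#' @return a `fate_map` with axes `d_lara`, `d_atc`.
#' @export
atc_sweep <- function(params, atc_axis, d_lara = 9.5e-4, lara_axis = NULL,
                      t_end = 16, mode = c("DETERMINISTIC", "STOCHASTIC"),
                      n_seeds = 32, seed = 1, volume = 5,
                      thresholds = NULL) {
  mode <- match.arg(mode)
  variant <- model_variant("CBS_HYBRID_TETR")
  if (is.null(lara_axis)) lara_axis <- d_lara
  if (is.null(thresholds)) {
    ref <- induction_protocol(d_lara = max(lara_axis),
                              d_atc = stats::median(atc_axis), t_end = t_end)
    thresholds <- map_thresholds(params, ref, variant)
  }
  g <- expand.grid(axis1 = lara_axis, axis2 = atc_axis)
  g$label <- NA_character_
  for (k in seq_len(nrow(g))) {
    pr <- induction_protocol(d_lara = g$axis1[k], d_atc = g$axis2[k],
                             t_end = t_end)
    g$label[k] <- classify_terminal(params, pr, variant, c(0, 0), mode,
                                    n_seeds, seed, thresholds, volume,
                                    cell_counter = (k - 1) * n_seeds)
  }
  new_fate_map(g, "d_lara", "d_atc", mode)
}

#' Number of distinct fate regions on a map
#'
#' Counts the distinct non-`UNSETTLED` labels present. With
#' `connected = TRUE` additionally returns the number of 4-connected
#' same-label components on the grid.
#'
#' @param map a `fate_map`.
#' @param connected also compute the connected-component count.
#' @return integer count (with attribute `components` when requested).
#' @export
count_fate_regions <- function(map, connected = FALSE) {
  g <- map$grid
  if (!nrow(g)) stop("count_fate_regions: empty map")
  labs <- setdiff(unique(g$label), "UNSETTLED")
  n <- length(labs)
  if (connected) {
    a1 <- sort(unique(g$axis1)); a2 <- sort(unique(g$axis2))
    lab <- matrix(g$label[order(match(g$axis2, a2), match(g$axis1, a1))],
                  nrow = length(a1))
    comp <- matrix(0L, nrow(lab), ncol(lab))
    nc <- 0L
    for (i in seq_len(nrow(lab))) for (j in seq_len(ncol(lab))) {
      if (comp[i, j] > 0L || lab[i, j] == "UNSETTLED") next
      nc <- nc + 1L
      stack <- list(c(i, j))
      while (length(stack)) {
        ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        x <- ij[1]; y <- ij[2]
        if (x < 1 || y < 1 || x > nrow(lab) || y > ncol(lab)) next
        if (comp[x, y] > 0L || lab[x, y] != lab[i, j]) next
        comp[x, y] <- nc
        stack <- c(stack, list(c(x - 1, y), c(x + 1, y),
                               c(x, y - 1), c(x, y + 1)))
      }
    }
    attr(n, "components") <- nc
  }
  n
}

#' Fraction of coactivated (HH) grid cells
#'
#' Share of settled grid cells labeled `HH` — the map-level measure of how
#' much of dose space still supports coactivation of both switches. Under
#' increasing resource competition this fraction shrinks toward zero
#' (winner-takes-all).
#'
#' @param map a `fate_map`.
#' @return fraction in `[0, 1]`.
#' @export
coactivation_fraction <- function(map) {
  g <- map$grid
  if (!nrow(g)) stop("coactivation_fraction: empty map")
  settled <- g$label != "UNSETTLED"
  if (!any(settled)) return(0)
  mean(g$label[settled] == "HH")
}

#' @export
print.fate_map <- function(x, ...) {
  cat("<fate_map> ", x$axis1, " x ", x$axis2, " (", x$mode, ")\n", sep = "")
  print(table(x$grid$label))
  invisible(x)
}

#' Write a fate map as long-format CSV
#'
#' Columns `axis1`, `axis2`, `label` plus a comment-free header; axis names
#' and mode go to a JSON-less sidecar CSV (`<path>_meta.csv`).
#'
#' @param map a `fate_map`.
#' @param path output CSV path.
#' @return invisibly, the paths written.
#' @export
write_fate_map_csv <- function(map, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(map$grid, path, row.names = FALSE)
  meta <- data.frame(key = c("axis1", "axis2", "mode"),
                     value = c(map$axis1, map$axis2, map$mode))
  meta_path <- sub("\\.csv$", "_meta.csv", path)
  utils::write.csv(meta, meta_path, row.names = FALSE)
  invisible(c(path, meta_path))
}
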