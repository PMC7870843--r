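# Shared helpers: preset shortcuts and an independent brute-force
# fixed-point oracle.

preset <- function(name, regime = "WEAK_M2_TO_M1", ...) {
  make_variant_params(model_variant(name, regime), overrides = list(...))
}

all_presets <- function() {
  list(
    ideal_1b = list(p = preset("CBS_IDEAL", "WEAK_M1_TO_M2"),
                    v = model_variant("CBS_IDEAL", "WEAK_M1_TO_M2"),
                    pr = reference_protocol("CBS_IDEAL")),
    ideal_1c = list(p = preset("CBS_IDEAL", "WEAK_M2_TO_M1"),
                    v = model_variant("CBS_IDEAL", "WEAK_M2_TO_M1"),
                    pr = reference_protocol("CBS_IDEAL")),
    cbs_comp = list(p = preset("CBS_COMPETITION"),
                    v = model_variant("CBS_COMPETITION"),
                    pr = reference_protocol("CBS_COMPETITION")),
    sbs = list(p = preset("SBS_COMPETITION"),
               v = model_variant("SBS_COMPETITION"),
               pr = reference_protocol("SBS_COMPETITION")),
    hybrid = list(p = preset("CBS_HYBRID_TETR"),
                  v = model_variant("CBS_HYBRID_TETR"),
                  pr = reference_protocol("CBS_HYBRID_TETR")),
    two_strain = list(p = preset("TWO_STRAIN_CBS"),
                      v = model_variant("TWO_STRAIN_CBS"),
                      pr = reference_protocol("TWO_STRAIN_CBS")))
}

# Brute-force sign-pattern scan: counts grid cells in which both components
# of the vector field change sign among the four corners. The axes use the
# same graded (linear + near-zero log) construction as the package grids:
# leak-level roots sit orders of magnitude below the activated states and a
# uniform oracle grid cannot resolve them. Root refinement, Newton, and
# deduplication are not involved: this is a pure sign-pattern count.
brute_force_root_count <- function(params, protocol, variant, n = 500,
                                   time = NULL) {
  if (is.null(time)) time <- protocol$t_end
  bound <- state_bound(params) * 1.02
  gax <- function(b) sort(unique(c(seq(0, b, length.out = n),
                                   b * 10^seq(-6, -0.3,
                                              length.out = max(12, n %/% 3)))))
  ax1 <- gax(bound[1]); ax2 <- gax(bound[2])
  g <- expand.grid(m1 = ax1, m2 = ax2)
  d <- circuit_rhs(list(m1 = g$m1, m2 = g$m2), time, params, protocol,
                   variant)
  f1 <- matrix(d$dm1, nrow = length(ax1))
  f2 <- matrix(d$dm2, nrow = length(ax1))
  change <- function(s) {
    nr <- nrow(s); nc <- ncol(s)
    a <- s[-nr, -nc]; b <- s[-1, -nc]; c2 <- s[-nr, -1]; dd <- s[-1, -1]
    pmin(a, b, c2, dd) < 0 & pmax(a, b, c2, dd) > 0
  }
  flagged <- change(sign(f1)) & change(sign(f2))
  # distinct roots appear as clusters of flagged cells; label 8-connected
  # components, then merge components whose centers fall within 3% of the
  # box (shallow-angle crossings can break one root's cells into pieces,
  # while genuine roots in every preset are >5% of the box apart)
  comp <- matrix(0L, nrow(flagged), ncol(flagged))
  ncomp <- 0L
  idx <- which(flagged, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    if (comp[i, j] > 0L) next
    ncomp <- ncomp + 1L
    stack <- list(c(i, j))
    while (length(stack)) {
      ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      x <- ij[1]; y <- ij[2]
      if (x < 1 || y < 1 || x > nrow(flagged) || y > ncol(flagged)) next
      if (!flagged[x, y] || comp[x, y] > 0L) next
      comp[x, y] <- ncomp
      for (dx in -1:1) for (dy in -1:1)
        if (dx || dy) stack <- c(stack, list(c(x + dx, y + dy)))
    }
  }
  if (ncomp == 0L) return(0L)
  # a cluster holds a transversal crossing only if its cells' corners cover
  # all four (sign f1, sign f2) quadrant patterns; close-approach chains
  # (nullclines passing without crossing) show at most three
  pat <- 2L * (f1 > 0) + (f2 > 0)
  keep <- logical(ncomp)
  centers <- matrix(0, ncomp, 2)
  for (k in seq_len(ncomp)) {
    cells <- which(comp == k, arr.ind = TRUE)
    pats <- integer(0)
    for (r in seq_len(nrow(cells))) {
      i <- cells[r, 1]; j <- cells[r, 2]
      pats <- union(pats, c(pat[i, j], pat[i + 1, j], pat[i, j + 1],
                            pat[i + 1, j + 1]))
    }
    keep[k] <- length(pats) >= 4
    centers[k, ] <- c(mean(cells[, 1]), mean(cells[, 2]))  # index space
  }
  kept <- which(keep)
  if (!length(kept)) return(0L)
  # merge kept pieces of one broken chain (within a few grid cells)
  groups <- seq_along(kept)
  for (a in seq_along(kept)) for (b in seq_along(kept)) {
    if (b <= a) next
    if (max(abs(centers[kept[a], ] - centers[kept[b], ])) < 5)
      groups[groups == groups[b]] <- groups[a]
  }
  length(unique(groups))
}

stable_fates <- function(fps) sort(fps$fate[fps$stability == "STABLE"])
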