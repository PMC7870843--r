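# Chemical master equation on a truncated count lattice: stationary
# distribution and quasi-potential landscape.

lattice_index <- function(i1, i2, n1) i1 + 1L + (n1 + 1L) * i2  # 0-based counts

#' Build the CME transition-rate operator on a truncated lattice
#'
#' Sparse generator `Q` over the `(N1max+1) x (N2max+1)` count lattice with
#' the 4 reaction channels; `Q[j, i]` is the rate from lattice state `i` to
#' `j`, and columns sum to zero. The truncation boundary is reflecting:
#' production propensities are zeroed at the edge (removal needs no
#' treatment). Production rates at the edge before zeroing are summed into a
#' `mass_leak_rate` diagnostic.
#'
#' @param params,protocol,variant model specification.
#' @param volume system-size factor (molecules per concentration unit).
#' @param truncation length-2 `(N1max, N2max)`; default 1.6 x the largest
#'   stable-attractor counts (checked).
#' @param check_attractors verify the deterministic attractors lie well
#'   inside the lattice (default TRUE); raises a TRUNCATION error otherwise.
#' @param time evaluation time for doses, default end of protocol.
#' @return object of class `cme_generator`: list with sparse `Q`, `N1max`,
#'   `N2max`, `volume`, `mass_leak_rate`, and the model spec.
#' @export
build_generator <- function(params, protocol, variant, volume,
                            truncation = NULL, check_attractors = TRUE,
                            time = NULL) {
  v <- as_variant(variant)
  if (is.null(time)) time <- protocol$t_end
  fps <- NULL
  if (is.null(truncation) || check_attractors) {
    fps <- find_fixed_points(params, protocol, v, time = time)
    st <- fps[fps$stability == "STABLE", , drop = FALSE]
    amax <- c(max(st$m1, 0), max(st$m2, 0)) * volume
    if (is.null(truncation))
      truncation <- pmax(ceiling(1.6 * amax), 30)
    if (check_attractors && any(truncation < amax))
      stop("TRUNCATION: lattice (", truncation[1], ", ", truncation[2],
           ") smaller than a deterministic attractor at counts (",
           paste(round(amax), collapse = ", "), ")")
  }
  n1 <- as.integer(truncation[1]); n2 <- as.integer(truncation[2])
  cnt <- expand.grid(i1 = 0:n1, i2 = 0:n2)
  m1 <- cnt$i1 / volume; m2 <- cnt$i2 / volume
  d <- circuit_rhs(list(m1 = m1, m2 = m2), time, params, protocol, v)
  prod1 <- volume * params$copy_scale * params$alpha1 * d$r1 * d$a1
  prod2 <- volume * params$copy_scale * params$alpha2 * d$r2 * d$a2
  deg1 <- params$delta1 * cnt$i1
  deg2 <- params$delta2 * cnt$i2
  edge1 <- cnt$i1 == n1
  edge2 <- cnt$i2 == n2
  mass_leak_rate <- sum(prod1[edge1]) + sum(prod2[edge2])
  prod1[edge1] <- 0
  prod2[edge2] <- 0

  id <- lattice_index(cnt$i1, cnt$i2, n1)
  from <- c(id, id, id[cnt$i1 > 0], id[cnt$i2 > 0])
  to <- c(lattice_index(pmin(cnt$i1 + 1L, n1), cnt$i2, n1),
          lattice_index(cnt$i1, pmin(cnt$i2 + 1L, n2), n1),
          lattice_index(cnt$i1[cnt$i1 > 0] - 1L, cnt$i2[cnt$i1 > 0], n1),
          lattice_index(cnt$i1[cnt$i2 > 0], cnt$i2[cnt$i2 > 0] - 1L, n1))
  rate <- c(prod1, prod2, deg1[cnt$i1 > 0], deg2[cnt$i2 > 0])
  keep <- rate > 0 & from != to
  nstate <- (n1 + 1L) * (n2 + 1L)
  Q <- Matrix::sparseMatrix(i = to[keep], j = from[keep], x = rate[keep],
                            dims = c(nstate, nstate))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::colSums(Q)
  structure(list(Q = Q, N1max = n1, N2max = n2, volume = volume,
                 mass_leak_rate = mass_leak_rate, params = params,
                 protocol = protocol, variant = v, fixed_points = fps),
            class = "cme_generator")
}

#' Stationary distribution of a CME generator
#'
#' Solves `Q p = 0`, `sum(p) = 1` by replacing one balance equation with the
#' normalization row and factorizing the sparse system; falls back to power
#' iteration on the uniformized chain if the direct solve is ill-conditioned.
#' The result is checked for nonnegativity (to round-off) and residual below
#' `1e-10`.
#'
#' @param generator a `cme_generator` from [build_generator()].
#' @return object of class `stationary_distribution`: list with
#'   `probabilities` (matrix, rows = N1 counts 0..N1max, cols = N2 counts),
#'   `N1max`, `N2max`, `volume`, `residual`, `truncation_mass_leak`
#'   (boundary production rate x stationary boundary mass).
#' @export
stationary_distribution <- function(generator) {
  Q <- generator$Q
  n <- nrow(Q)
  A <- Q
  A[1, ] <- 1
  b <- c(1, rep(0, n - 1))
  p <- tryCatch(as.numeric(Matrix::solve(A, b)), error = function(e) NULL)
  ok <- function(p) !is.null(p) && all(is.finite(p)) &&
    min(p) > -1e-8 && max(abs(Q %*% pmax(p, 0) / sum(pmax(p, 0)))) < 1e-10
  if (!ok(p)) {
    # power iteration on the uniformized chain P = I + Q / rate_max
    rate_max <- max(abs(Matrix::diag(Q))) * 1.05
    P <- Matrix::Diagonal(n) + Q / rate_max
    p <- rep(1 / n, n)
    for (it in seq_len(200000L)) {
      p_new <- as.numeric(P %*% p)
      p_new <- pmax(p_new, 0); p_new <- p_new / sum(p_new)
      if (max(abs(p_new - p)) < 1e-14) { p <- p_new; break }
      p <- p_new
    }
    if (max(abs(Q %*% p)) > 1e-8)
      stop("stationary_distribution: no convergence; the chain may be ",
           "numerically reducible on this lattice")
  }
  p <- pmax(p, 0); p <- p / sum(p)
  res <- max(abs(Q %*% p))
  pm <- matrix(p, nrow = generator$N1max + 1L)
  edge_mass <- sum(pm[nrow(pm), ]) + sum(pm[, ncol(pm)])
  structure(list(probabilities = pm, N1max = generator$N1max,
                 N2max = generator$N2max, volume = generator$volume,
                 residual = res,
                 truncation_mass_leak = edge_mass,
                 generator = generator),
            class = "stationary_distribution")
}

#' Quasi-potential landscape from a stationary distribution
#'
#' `U = -ln(max(p, floor))`. Potential wells (local minima of U, equivalently
#' local maxima of p) are enumerated after a 3 x 3 mean smoothing that
#' suppresses single-lattice-site noise, and matched to the deterministic
#' stable fixed points by nearest neighbor within a capture radius.
#'
#' @param dist a `stationary_distribution`.
#' @param floor probability floor keeping U finite on empty states (> 0).
#' @param capture_radius well-to-attractor matching radius in counts;
#'   default 25% of the lattice diagonal.
#' @return list with `potential` (matrix, same shape as the probabilities),
#'   `wells` (data.frame `N1`, `N2`, `potential`, `probability`),
#'   `well_attractor_match` (data.frame linking wells to stable fixed points,
#'   when the generator carried them).
#' @export
quasi_potential <- function(dist, floor = 1e-30, capture_radius = NULL) {
  if (floor <= 0) stop("quasi_potential: floor must be > 0")
  p <- dist$probabilities
  U <- -log(pmax(p, floor))
  # 3x3 mean smoothing with edge replication
  n1 <- nrow(p); n2 <- ncol(p)
  pad <- matrix(0, n1 + 2, n2 + 2)
  pad[2:(n1 + 1), 2:(n2 + 1)] <- p
  pad[1, ] <- pad[2, ]; pad[n1 + 2, ] <- pad[n1 + 1, ]
  pad[, 1] <- pad[, 2]; pad[, n2 + 2] <- pad[, n2 + 1]
  sm <- (pad[1:n1, 1:n2] + pad[1:n1, 2:(n2 + 1)] + pad[1:n1, 3:(n2 + 2)] +
         pad[2:(n1 + 1), 1:n2] + pad[2:(n1 + 1), 2:(n2 + 1)] +
         pad[2:(n1 + 1), 3:(n2 + 2)] +
         pad[3:(n1 + 2), 1:n2] + pad[3:(n1 + 2), 2:(n2 + 1)] +
         pad[3:(n1 + 2), 3:(n2 + 2)]) / 9
  # local maxima of the smoothed probability (8-neighborhood, strict on ties
  # broken by index order), ignoring negligible mass
  wells <- list()
  thr <- max(sm) * 1e-6
  for (i in 1:n1) for (j in 1:n2) {
    v <- sm[i, j]
    if (v < thr) next
    nb <- sm[max(1, i - 1):min(n1, i + 1), max(1, j - 1):min(n2, j + 1)]
    if (v >= max(nb) && sum(nb == v) == 1)
      wells[[length(wells) + 1L]] <- c(i - 1L, j - 1L, v)
  }
  wdf <- if (length(wells)) {
    m <- do.call(rbind, wells)
    data.frame(N1 = m[, 1], N2 = m[, 2],
               potential = U[cbind(m[, 1] + 1, m[, 2] + 1)],
               probability = p[cbind(m[, 1] + 1, m[, 2] + 1)])
  } else data.frame(N1 = integer(0), N2 = integer(0),
                    potential = numeric(0), probability = numeric(0))
  match_df <- NULL
  gen <- dist$generator
  if (!is.null(gen$fixed_points) && nrow(wdf)) {
    st <- gen$fixed_points[gen$fixed_points$stability == "STABLE", ,
                           drop = FALSE]
    if (nrow(st)) {
      if (is.null(capture_radius))
        capture_radius <- 0.25 * sqrt((dist$N1max + 1)^2 + (dist$N2max + 1)^2)
      rows <- lapply(seq_len(nrow(st)), function(k) {
        tgt <- c(st$m1[k], st$m2[k]) * dist$volume
        dd <- sqrt((wdf$N1 - tgt[1])^2 + (wdf$N2 - tgt[2])^2)
        w <- which.min(dd)
        data.frame(fate = st$fate[k], attractor_N1 = tgt[1],
                   attractor_N2 = tgt[2], well_N1 = wdf$N1[w],
                   well_N2 = wdf$N2[w], distance = dd[w],
                   within_capture = dd[w] <= capture_radius)
      })
      match_df <- do.call(rbind, rows)
    }
  }
  list(potential = U, wells = wdf, well_attractor_match = match_df)
}

#' Write a stationary distribution and potential as CSV matrices
#'
#' @param dist a `stationary_distribution`.
#' @param qp optional result of [quasi_potential()].
#' @param dir output directory.
#' @return invisibly, paths written (`probabilities.csv`, `potential.csv`,
#'   `lattice_meta.csv`).
#' @export
write_landscape_csv <- function(dist, qp = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("probabilities.csv", "potential.csv",
                            "lattice_meta.csv"))
  utils::write.table(dist$probabilities, paths[1], sep = ",",
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(qp))
    utils::write.table(qp$potential, paths[2], sep = ",",
                       row.names = FALSE, col.names = FALSE)
  meta <- data.frame(key = c("N1max", "N2max", "volume", "residual",
                             "truncation_mass_leak"),
                     value = c(dist$N1max, dist$N2max, dist$volume,
                               dist$residual, dist$truncation_mass_leak))
  utils::write.csv(meta, paths[3], row.names = FALSE)
  invisible(paths)
}
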