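# Named end-to-end runs reproducing each figure-level computation. Every
# scenario is fully determined by (name, frozen preset, seed) and writes CSV
# artifacts plus a manifest of headline quantities.

SCENARIO_NAMES <- c("FIG1B", "FIG1C", "FIG2E_2F", "FIG2A_CURVE", "FIG3C",
                    "FIG3D_3E", "SEQUENTIAL_MAP", "FIG4_SIM", "FIG5_MIXTURE")

#' Run a named figure-level scenario
#'
#' Executes the frozen module chain for one scenario and writes its
#' artifacts under `out_dir`:
#' \describe{
#'   \item{FIG1B / FIG1C}{ideal-circuit phase portraits (weak module-1-to-2
#'     and weak module-2-to-1 regimes); reports the stable fate set.}
#'   \item{FIG2E_2F}{competition-circuit phase portrait plus CME
#'     quasi-potential landscape; reports stable fates and well count.}
#'   \item{FIG2A_CURVE}{simulated plate-reader dose-response and the
#'     two-segment piecewise-linear fit.}
#'   \item{FIG3C}{separated-switch deterministic fate map over the
#'     L-ara x C6 dose plane; reports the region count.}
#'   \item{FIG3D_3E}{separated-switch portrait at the printed reference
#'     doses, stochastic fate distribution from a common initial state, and
#'     the CME landscape.}
#'   \item{SEQUENTIAL_MAP}{fate map over C6 dose x C6 addition time at
#'     fixed L-ara.}
#'   \item{FIG4_SIM}{hybrid-circuit fate map over L-ara x aTc.}
#'   \item{FIG5_MIXTURE}{two-strain populations along an L-ara ladder,
#'     mixed per dose; reports subpopulation coexistence.}
#' }
#'
#' @param name scenario name, one of
#'   `r paste(SCENARIO_NAMES, collapse = ", ")`.
#' @param out_dir output directory (created).
#' @param seed integer seed for the stochastic stages.
#' @return invisibly, the manifest: list with `name`, `seed`, `files`,
#'   `quantities` (named list of headline numbers/strings).
#' @export
run_scenario <- function(name, out_dir, seed = 1) {
  name <- match.arg(name, SCENARIO_NAMES)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  q <- list()
  add <- function(f) files <<- c(files, f)

  portrait_stage <- function(variant, protocol, tag) {
    p <- make_variant_params(variant)
    pp <- phase_portrait(p, protocol, variant)
    add(write_portrait_csv(pp, file.path(out_dir, tag)))
    pp
  }

  if (name %in% c("FIG1B", "FIG1C")) {
    v <- model_variant("CBS_IDEAL",
                       if (name == "FIG1B") "WEAK_M1_TO_M2" else "WEAK_M2_TO_M1")
    pp <- portrait_stage(v, reference_protocol(v), "portrait")
    st <- pp$fixed_points[pp$fixed_points$stability == "STABLE", ]
    q$n_stable <- nrow(st)
    q$stable_fates <- paste(sort(st$fate), collapse = ",")
  } else if (name == "FIG2E_2F") {
    v <- model_variant("CBS_COMPETITION")
    pr <- reference_protocol(v)
    pp <- portrait_stage(v, pr, "portrait")
    st <- pp$fixed_points[pp$fixed_points$stability == "STABLE", ]
    q$n_stable <- nrow(st)
    q$stable_fates <- paste(sort(st$fate), collapse = ",")
    p <- make_variant_params(v)
    gen <- build_generator(p, pr, v, volume = 0.8)
    dist <- stationary_distribution(gen)
    qp <- quasi_potential(dist)
    add(write_landscape_csv(dist, qp, file.path(out_dir, "landscape")))
    q$n_wells <- nrow(qp$wells)
    q$wells_match_attractors <- all(qp$well_attractor_match$within_capture)
  } else if (name == "FIG2A_CURVE") {
    v <- model_variant("CBS_COMPETITION")
    p <- make_variant_params(v)
    doses <- dose_axis(9.5e-4, n = 48)
    curve <- dose_response_curve(v, p, doses)
    f <- file.path(out_dir, "dose_response.csv")
    utils::write.csv(curve, f, row.names = FALSE); add(f)
    fit <- fit_piecewise_linear(curve$gfp_norm, curve$rfp_norm)
    q$n_segments <- fit$n_segments
    if (fit$n_segments == 2) {
      q$breakpoint <- fit$breakpoint
      q$slope_steep <- unname(fit$slopes["left"])
      q$slope_shallow <- unname(fit$slopes["right"])
    }
  } else if (name == "FIG3C") {
    v <- model_variant("SBS_COMPETITION")
    p <- make_variant_params(v)
    map <- dose_sweep(v, p, dose_axis(9.5e-4, 20), dose_axis(5e-8, 20))
    add(write_fate_map_csv(map, file.path(out_dir, "fate_map.csv")))
    q$n_regions <- count_fate_regions(map)
    q$labels_present <- paste(sort(setdiff(unique(map$grid$label),
                                           "UNSETTLED")), collapse = ",")
    q$coactivation_fraction <- coactivation_fraction(map)
  } else if (name == "FIG3D_3E") {
    v <- model_variant("SBS_COMPETITION")
    p <- make_variant_params(v)
    pr <- reference_protocol(v)
    pp <- portrait_stage(v, pr, "portrait")
    st <- pp$fixed_points[pp$fixed_points$stability == "STABLE", ]
    q$n_stable <- nrow(st)
    q$stable_fates <- paste(sort(st$fate), collapse = ",")
    fd <- fate_distribution(p, pr, v, volume = 5, n_cells = 200, seed = seed)
    f <- file.path(out_dir, "fate_distribution.csv")
    utils::write.csv(data.frame(fate = names(fd$fractions),
                                fraction = fd$fractions), f,
                     row.names = FALSE); add(f)
    q$n_distinct_fates <- length(fd$fractions)
    q$fate_fractions <- paste(sprintf("%s=%.3f", names(fd$fractions),
                                      fd$fractions), collapse = ";")
    gen <- build_generator(p, pr, v, volume = 0.8)
    dist <- stationary_distribution(gen)
    qp <- quasi_potential(dist)
    add(write_landscape_csv(dist, qp, file.path(out_dir, "landscape")))
    q$n_wells <- nrow(qp$wells)
  } else if (name == "SEQUENTIAL_MAP") {
    v <- model_variant("SBS_COMPETITION")
    p <- make_variant_params(v)
    map <- sequential_induction_map(v, p, dose_axis(5e-8, 9),
                                    seq(0, 4, by = 0.5), d_lara = 9.5e-4,
                                    mode = "STOCHASTIC", n_seeds = 32,
                                    seed = seed)
    add(write_fate_map_csv(map, file.path(out_dir, "sequential_map.csv")))
    q$n_regions <- count_fate_regions(map)
    ref_row <- map$grid[abs(map$grid$axis1 - 5e-8) ==
                          min(abs(map$grid$axis1 - 5e-8)), ]
    q$ref_dose_fates_by_time <- paste(
      ref_row$label[order(ref_row$axis2)], collapse = ">")
  } else if (name == "FIG4_SIM") {
    p <- make_variant_params("CBS_HYBRID_TETR")
    map <- atc_sweep(p, atc_axis = c(0, 2^(0:8)),
                     lara_axis = dose_axis(9.5e-4, 10))
    add(write_fate_map_csv(map, file.path(out_dir, "atc_map.csv")))
    q$n_regions <- count_fate_regions(map)
    hi_ara <- max(map$grid$axis1)
    top <- map$grid[map$grid$axis1 == hi_ara, ]
    q$high_lara_no_atc <- top$label[which.min(top$axis2)]
    q$high_lara_high_atc <- top$label[which.max(top$axis2)]
  } else if (name == "FIG5_MIXTURE") {
    v <- model_variant("TWO_STRAIN_CBS")
    p <- make_variant_params(v)
    doses <- 9.5e-4 * 10^seq(-1.5, 1.5, by = 0.75)
    rows <- list()
    for (i in seq_along(doses)) {
      pr <- induction_protocol(d_lara = doses[i])
      popA <- simulate_population(v, p, pr, n_cells = 500, mode = "SSA",
                                  seed = seed + 100 * i, strain = "M1")
      popB <- simulate_population(v, p, pr, n_cells = 500, mode = "SSA",
                                  seed = seed + 100 * i + 50, strain = "M2")
      mix <- mix_strains(popA, popB, 0.5, seed = seed + i)
      ff <- suppressMessages(fate_fractions(gate_singlets(mix)))
      rows[[i]] <- data.frame(dose = doses[i], t(ff$overall))
    }
    tab <- do.call(rbind, rows)
    f <- file.path(out_dir, "mixture_fates.csv")
    utils::write.csv(tab, f, row.names = FALSE); add(f)
    hi <- tab[nrow(tab), ]
    q$high_dose_HL <- hi$HL
    q$high_dose_LH <- hi$LH
    q$coexistence_at_high_dose <- hi$HL > 0.2 && hi$LH > 0.2
  }

  manifest <- list(name = name, seed = as.integer(seed), files = files,
                   quantities = q)
  mf <- file.path(out_dir, "manifest.csv")
  utils::write.csv(
    data.frame(key = c("name", "seed", names(q)),
               value = c(name, seed,
                         vapply(q, function(x) paste(format(x), collapse = ";"),
                                ""))),
    mf, row.names = FALSE)
  manifest$files <- c(manifest$files, mf)
  invisible(manifest)
}

#' Validate a scenario manifest against an expectations table
#'
#' Compares the manifest's headline quantities with expected values; numeric
#' expectations compare with a relative tolerance, strings exactly. Missing
#' keys are reported, never fatal.
#'
#' @param manifest result of [run_scenario()].
#' @param expectations named list (or data.frame with `key`, `value`) of
#'   expected quantities.
#' @param rtol relative tolerance for numeric comparisons.
#' @return data.frame with columns `key`, `expected`, `actual`, `pass`;
#'   attribute `all_pass`.
#' @export
validate_outputs <- function(manifest, expectations, rtol = 1e-6) {
  if (is.data.frame(expectations))
    expectations <- stats::setNames(as.list(expectations$value),
                                    expectations$key)
  rows <- lapply(names(expectations), function(k) {
    exp_v <- expectations[[k]]
    act_v <- manifest$quantities[[k]]
    if (is.null(act_v))
      return(data.frame(key = k, expected = format(exp_v),
                        actual = NA_character_, pass = FALSE))
    num <- suppressWarnings(as.numeric(exp_v))
    pass <- if (!is.na(num) && is.numeric(act_v)) {
      abs(act_v - num) <= rtol * max(1, abs(num))
    } else identical(format(act_v), format(exp_v))
    data.frame(key = k, expected = format(exp_v), actual = format(act_v),
               pass = pass)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(key = character(0), expected = character(0),
                         actual = character(0), pass = logical(0))
  attr(out, "all_pass") <- all(out$pass)
  out
}
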