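#' Configure an activation scenario
#'
#' Bundles everything the inverse driver needs: the activated edge set
#' and target multiplier, which edges may adapt, clipping bounds, and
#' the solver parameters.
#'
#' @param activated Vector of activated edge ids.
#' @param multiplier Target flow multiplier (default 1.3, i.e. +30%).
#' @param adaptable `"all"` (default), a vector of edge ids, or a
#'   function `f(net)` returning a logical mask over edges.
#' @param bounds `NULL` or `c(lo, hi)` clipping bounds on alpha (e.g.
#'   `c(0.85, 1.15)` to restrict changes to +/-15%).
#' @param dt Time step in ms (default 0.4).
#' @param n_avg Averaging-window length in steps (default 500).
#' @param spin_up Spin-up steps towards stationarity before the baseline
#'   window (default 1000; ignored for plasma-only runs).
#' @param init_ht Initial seeding tube haematocrit (default 0.3).
#' @param tol Convergence tolerance on the filtered cost (default 1e-5,
#'   i.e. < 0.32% flow discrepancy).
#' @param gamma Explicit gradient step size, or `NULL` (default) to set
#'   it from `step0`.
#' @param step0 With `gamma = NULL`: the step size is chosen so the
#'   first update changes the largest-gradient alpha by `step0`
#'   (default 0.02).
#' @param epsilon Secondary-constraint weight once activated (default 1).
#' @param secondary Run phase 2 at all? (default TRUE).
#' @param rho_factor Geometric reduction factor for `rho_min`
#'   (default 0.7).
#' @param rho_tol_rel Relative band around `rho_min` within which the
#'   filtered `rho` counts as reconverged in phase 2 (default 0.02).
#' @param level_budget Iteration budget per `rho_min` level before it is
#'   declared infeasible (default 300).
#' @param max_reductions Number of successful `rho_min` reductions after
#'   which the driver stops (default 4).
#' @param max_iter Overall iteration budget (default 2000).
#' @param filter_window Moving-average window for convergence detection
#'   on the noisy cost (default 10).
#' @param eta Relative pressure-drop threshold of the representative
#'   transmissibility regularization (default 1e-8).
#' @param plasma_only Deterministic plasma-only model (default FALSE).
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(activated, multiplier = 1.3, adaptable = "all",
                            bounds = NULL, dt = 0.4, n_avg = 500,
                            spin_up = 1000, init_ht = 0.3, tol = 1e-5,
                            gamma = NULL, step0 = 0.02, epsilon = 1,
                            secondary = TRUE, rho_factor = 0.7,
                            rho_tol_rel = 0.02,
                            level_budget = 300, max_reductions = 4,
                            max_iter = 2000, filter_window = 10,
                            eta = 1e-8, plasma_only = FALSE) {
  stopifnot(multiplier > 0, length(activated) >= 1, n_avg >= 1, tol > 0)
  if (!is.null(bounds)) stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  mask_fun <- if (is.function(adaptable)) {
    adaptable
  } else if (identical(adaptable, "all")) {
    function(net) rep(TRUE, nrow(net$edges))
  } else {
    ids <- adaptable
    function(net) net$edges$edge_id %in% ids
  }
  structure(list(activated = activated, multiplier = multiplier,
                 adaptable_mask = mask_fun, bounds = bounds, dt = dt,
                 n_avg = n_avg, spin_up = spin_up, init_ht = init_ht,
                 tol = tol, gamma = gamma, step0 = step0, epsilon = epsilon,
                 secondary = secondary, rho_factor = rho_factor,
                 rho_tol_rel = rho_tol_rel,
                 level_budget = level_budget,
                 max_reductions = max_reductions, max_iter = max_iter,
                 filter_window = filter_window, eta = eta,
                 plasma_only = plasma_only),
            class = "scenario_config")
}

#' Normalized per-edge flow change
#'
#' `Delta<q_ij> = dir0_ij (<q_ij> - <q_ij>0) / qbar0`: the change of the
#' averaged flow along the baseline direction, normalized by the mean
#' baseline flow rate in the activated region, so a value of 1 equals
#' the typical activated baseline flow.
#'
#' @param final,baseline `time_averaged_field`s on the same network.
#' @param target An [activation_target()] (supplies `dir0` for every
#'   edge and the baseline activated mean).
#' @return Per-edge dimensionless flow change.
#' @export
normalized_flow_change <- function(final, baseline, target) {
  if (target$qbar0 == 0) stop("baseline activated mean flow is zero")
  target$dir0_all * (final$q - baseline$q) / target$qbar0
}

#' Relative flow-resistance change of a single vessel
#'
#' For plasma flow the resistance scales with the inverse fourth power
#' of the diameter, so a relative diameter `alpha` changes the
#' resistance by `1/alpha^4 - 1` (e.g. a 5% dilation reduces it by
#' 17.7%).
#'
#' @param alpha Relative diameter (> 0, vectorised).
#' @return Relative resistance change (dimensionless; negative for
#'   dilation).
#' @export
resistance_change <- function(alpha) {
  if (any(alpha <= 0)) stop("resistance_change: alpha must be positive")
  1 / alpha^4 - 1
}

#' Partial-length equivalent diameter change
#'
#' If only the fraction `beta` of a vessel's length can react, the
#' relative diameter `alpha_beta = (beta / (1/alpha^4 - 1 + beta))^(1/4)`
#' over that fraction yields the same flow resistance as `alpha` over
#' the whole length (series resistances:
#' `beta / alpha_beta^4 + (1 - beta) = 1/alpha^4`).
#'
#' @param alpha Whole-length relative diameter (> 0).
#' @param beta Reacting length fraction in (0, 1].
#' @return The equivalent relative diameter `alpha_beta`.
#' @export
partial_length_equivalent <- function(alpha, beta) {
  if (any(alpha <= 0)) stop("partial_length_equivalent: alpha must be positive")
  if (any(beta <= 0) || any(beta > 1)) {
    stop("partial_length_equivalent: beta must lie in (0, 1]")
  }
  denom <- 1 / alpha^4 - 1 + beta
  if (any(denom <= 0)) {
    stop("partial_length_equivalent: dilation too large to be absorbed by ",
         "the reacting fraction (1/alpha^4 - 1 + beta <= 0)")
  }
  (beta / denom)^0.25
}

#' Per-edge change report for a converged scenario
#'
#' Combines relative diameter changes, normalized flow changes,
#' generation labels and (if coordinates exist) edge midpoints into one
#' table.
#'
#' @param net A [vascular_network()].
#' @param result An `inverse_result` from [run_inverse()].
#' @param labels Optional generation labels from [label_generations()]
#'   (computed from the result's activated set when omitted).
#' @param max_gen Passed to [label_generations()] when labels are
#'   computed here.
#' @return data.frame: `edge_id`, `generation`, `alpha`,
#'   `alpha_minus_1`, `delta_q_norm`, `x_mid_um`, `y_mid_um`, `z_mid_um`.
#' @export
change_report <- function(net, result, labels = NULL, max_gen = 10) {
  if (is.null(labels)) {
    labels <- label_generations(net, result$target$act_ids, max_gen)
  }
  dq <- normalized_flow_change(result$final_avg, result$baseline_avg,
                               result$target)
  data.frame(edge_id = net$edges$edge_id,
             generation = labels,
             alpha = result$alpha,
             alpha_minus_1 = result$alpha - 1,
             delta_q_norm = dq,
             x_mid_um = (net$nodes$x_um[net$from] + net$nodes$x_um[net$to]) / 2,
             y_mid_um = (net$nodes$y_um[net$from] + net$nodes$y_um[net$to]) / 2,
             z_mid_um = (net$nodes$z_um[net$from] + net$nodes$z_um[net$to]) / 2)
}

#' Per-generation summary of diameter and flow changes
#'
#' @param report A [change_report()] data frame.
#' @return data.frame with one row per labelled generation present in
#'   the report: n, mean/min/max of `alpha - 1` and of the normalized
#'   flow change.  Unlabelled edges and empty generations are absent.
#' @export
generation_summary <- function(report) {
  rep2 <- report[!is.na(report$generation), , drop = FALSE]
  gens <- sort(unique(rep2$generation))
  out <- lapply(gens, function(g) {
    r <- rep2[rep2$generation == g, ]
    data.frame(generation = g, n = nrow(r),
               alpha_mean = mean(r$alpha_minus_1),
               alpha_min = min(r$alpha_minus_1),
               alpha_max = max(r$alpha_minus_1),
               dq_mean = mean(r$delta_q_norm),
               dq_min = min(r$delta_q_norm),
               dq_max = max(r$delta_q_norm))
  })
  do.call(rbind, out)
}

#' Radial binning of edge-level changes around an activation center
#'
#' Assigns edges to distance bins by the ratio `r / r_act` of their
#' midpoint distance to the given center, and averages the diameter and
#' flow changes per bin.
#'
#' @param report A [change_report()] data frame (needs midpoints).
#' @param center Numeric `c(x, y, z)` of the activation center in um.
#' @param r_act Activation radius in um.
#' @param breaks Bin edges on the `r/r_act` axis
#'   (default `seq(0, 5, by = 0.5)`).
#' @return data.frame per non-empty bin: `r_over_ract_lo/hi`, `n`,
#'   `alpha_mean`, `dq_mean`.
#' @export
radial_binning <- function(report, center, r_act,
                           breaks = seq(0, 5, by = 0.5)) {
  if (any(is.na(report$x_mid_um)) || any(is.na(report$y_mid_um))) {
    stop("radial_binning needs edge midpoint coordinates")
  }
  z <- report$z_mid_um
  z[is.na(z)] <- 0
  cz <- if (length(center) >= 3) center[3] else 0
  r <- sqrt((report$x_mid_um - center[1])^2 +
              (report$y_mid_um - center[2])^2 + (z - cz)^2) / r_act
  bin <- cut(r, breaks, include.lowest = TRUE, right = FALSE)
  keep <- !is.na(bin)
  out <- lapply(levels(bin), function(lv) {
    sel <- keep & bin == lv
    if (!any(sel)) return(NULL)
    i <- match(lv, levels(bin))
    data.frame(r_over_ract_lo = breaks[i], r_over_ract_hi = breaks[i + 1],
               n = sum(sel),
               alpha_mean = mean(report$alpha_minus_1[sel]),
               dq_mean = mean(report$delta_q_norm[sel]))
  })
  do.call(rbind, out)
}
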