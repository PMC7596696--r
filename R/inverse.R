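#' Define an activation target
#'
#' Freezes the baseline information that the inverse problem needs about
#' the activated edge set: the baseline flow directions `dir0 = sgn(<q>0)`
#' (along the stored edge orientation), the total activated length, the
#' baseline length-averaged activated flow `qbar0`, and the target
#' `q_tar = multiplier * qbar0` (or an explicit `q_tar`).
#'
#' @param net A [vascular_network()].
#' @param activated Vector of activated edge ids.
#' @param baseline_avg `time_averaged_field` of the baseline window.
#' @param multiplier Target flow multiplier (e.g. 1.3 for a 30% increase).
#' @param q_tar Optional explicit target in um^3/ms (overrides
#'   `multiplier`).
#' @return Object of class `activation_target`.
#' @export
activation_target <- function(net, activated, baseline_avg,
                              multiplier = 1.3, q_tar = NULL) {
  stopifnot(multiplier > 0)
  act_idx <- match(activated, net$edges$edge_id)
  if (anyNA(act_idx)) {
    stop("unknown activated edge id(s): ",
         paste(activated[is.na(act_idx)], collapse = ", "))
  }
  if (length(act_idx) == 0) stop("activated edge set must not be empty")
  dir0_all <- sign(baseline_avg$q)
  nzero <- sum(dir0_all == 0)
  if (nzero > 0) {
    warning(sprintf(paste0("%d edge(s) with exactly zero baseline flow; ",
                           "dir0 set to +1 along stored orientation"), nzero))
    dir0_all[dir0_all == 0] <- 1
  }
  l_act <- sum(net$edges$length_um[act_idx])
  qbar0 <- sum(net$edges$length_um[act_idx] * dir0_all[act_idx] *
                 baseline_avg$q[act_idx]) / l_act
  if (is.null(q_tar)) q_tar <- multiplier * qbar0
  if (q_tar == 0) stop("target flow rate must be non-zero")
  structure(list(act_idx = act_idx, act_ids = activated,
                 n_act = sort(unique(c(net$from[act_idx], net$to[act_idx]))),
                 dir0 = dir0_all[act_idx], dir0_all = dir0_all,
                 l_act = l_act, qbar0 = qbar0, q_tar = q_tar,
                 q0 = baseline_avg$q),
            class = "activation_target")
}

#' Length-averaged activated flow rate
#'
#' The length-weighted, direction-signed mean of the time-averaged flow
#' over the activated edges,
#' `qbar_sim = 1/l_act * sum l_ij dir0_ij <q_ij>`.
#'
#' @param avg `time_averaged_field`.
#' @param target An [activation_target()].
#' @param net The network (for edge lengths).
#' @return Scalar flow rate in um^3/ms.
#' @export
activated_average <- function(avg, target, net) {
  sum(net$edges$length_um[target$act_idx] * target$dir0 *
        avg$q[target$act_idx]) / target$l_act
}

#' Representative transmissibility of the averaged flow field
#'
#' `Ttilde = <q> / (<p_i> - <p_j>)` wherever the averaged pressure drop
#' exceeds `eta` times the network pressure scale; elsewhere (and
#' wherever the ratio comes out non-positive, an averaging-noise
#' artefact) it falls back to the window mean of the instantaneous
#' transmissibility.
#'
#' @param avg `time_averaged_field` (needs `q`, `p` and `trans_mean`).
#' @param net A [vascular_network()].
#' @param eta Relative pressure-drop threshold (default 1e-8).
#' @param ctx Internal solver context (for the pressure scale).
#' @return List: `trans` (per-edge Ttilde, all positive) and `n_fallback`.
#' @export
representative_transmissibility <- function(avg, net, eta = 1e-8, ctx = NULL) {
  if (is.null(ctx)) ctx <- make_flow_context(net)
  dp <- avg$p[net$from] - avg$p[net$to]
  ok <- abs(dp) > eta * ctx$pressure_scale
  tt <- ifelse(ok, avg$q / dp, avg$trans_mean)
  bad <- !is.finite(tt) | tt <= 0
  tt[bad] <- avg$trans_mean[bad]
  list(trans = tt, n_fallback = sum(!ok | bad))
}

#' Representative relative viscosity
#'
#' Inverts Poiseuille's law at the representative transmissibility:
#' `mutilde_rel = pi d^4 / (128 l mu_p Ttilde)` with the current
#' diameter `d = alpha d0`.  For steady plasma-only flow this equals 1.
#'
#' @param ttilde Per-edge representative transmissibility.
#' @param net A [vascular_network()].
#' @param alpha Per-edge relative diameters (default 1).
#' @param mu_p Plasma viscosity in Pa.ms.
#' @return Per-edge representative relative viscosity.
#' @export
representative_viscosity <- function(ttilde, net, alpha = NULL, mu_p = 1.2) {
  if (is.null(alpha)) alpha <- rep(1, nrow(net$edges))
  d <- alpha * net$edges$diameter_um
  pi * d^4 / (128 * net$edges$length_um * mu_p * ttilde)
}

#' Derivative of the representative transmissibility w.r.t. alpha
#'
#' `dTtilde/dalpha = pi d0^4 alpha^3 / (32 l mu_p mutilde_rel)`, the
#' exact derivative of Poiseuille's law at frozen representative
#' viscosity (the approximation `dmutilde_rel/dalpha = 0` is baked in:
#' an exact analytical derivative of the stochastic viscosity field does
#' not exist, and the approximate direction always agrees with the exact
#' one, so only the convergence rate is affected).
#'
#' @param net A [vascular_network()].
#' @param alpha Per-edge relative diameters.
#' @param mu_rel_tilde Per-edge representative relative viscosity.
#' @param mu_p Plasma viscosity in Pa.ms.
#' @return Per-edge derivative values.
#' @export
dTtilde_dalpha <- function(net, alpha, mu_rel_tilde, mu_p = 1.2) {
  pi * net$edges$diameter_um^4 * alpha^3 /
    (32 * net$edges$length_um * mu_p * mu_rel_tilde)
}

#' Two-term cost of the inverse problem
#'
#' `J = ((qbar_sim - q_tar)/q_tar)^2 + epsilon (rho - rho_min)^2`, where
#' `rho` is the Euclidean norm of the flow changes outside the activated
#' set, normalized by the target: `rho = sqrt(sum_{e not act}
#' ((<q_e> - <q_e>0)/q_tar)^2)`.  `epsilon = 0` disables the secondary
#' term.
#'
#' @param avg Current `time_averaged_field`.
#' @param target An [activation_target()] (carries the baseline flows).
#' @param net The network.
#' @param epsilon Secondary-constraint weight.
#' @param rho_min Current lower bound for `rho`.
#' @return List `J`, `term1`, `term2`, `rho`, `qbar_sim`.
#' @export
flow_cost <- function(avg, target, net, epsilon = 0, rho_min = 0) {
  qbar <- activated_average(avg, target, net)
  nonact <- setdiff(seq_len(nrow(net$edges)), target$act_idx)
  rho <- sqrt(sum(((avg$q[nonact] - target$q0[nonact]) / target$q_tar)^2))
  term1 <- ((qbar - target$q_tar) / target$q_tar)^2
  term2 <- epsilon * (rho - rho_min)^2
  list(J = term1 + term2, term1 = term1, term2 = term2, rho = rho,
       qbar_sim = qbar)
}

#' Adjoint-based gradient of the cost w.r.t. relative diameters
#'
#' Linearizes the averaged flow field around the representative state
#' (`<q_e> = Ttilde_e (<p_i> - <p_j>)`), assembles the cost partials
#' w.r.t. alpha and the averaged pressures analytically, solves the
#' adjoint system `A^T lambda = -dJ/d<p>` on the interior nodes (the
#' Dirichlet rows are eliminated symmetrically, so the adjoint solve
#' reuses the forward system matrix), and returns the total gradient
#' `dJ/dalpha = dJdirect + (lambda_i - lambda_j)(<p_i> - <p_j>)
#' dTtilde/dalpha` per edge.
#'
#' @param net A [vascular_network()].
#' @param avg Current `time_averaged_field`.
#' @param target An [activation_target()].
#' @param ttilde Per-edge representative transmissibilities.
#' @param dtda Per-edge `dTtilde/dalpha` values.
#' @param epsilon,rho_min Secondary-constraint weight and bound.
#' @param ctx Internal solver context.
#' @return List: `grad` (per-edge total gradient), `lambda` (per-node
#'   adjoint variable, zero at boundaries), `cost` (the [flow_cost()]
#'   evaluated at the linearized state).
#' @export
adjoint_gradient <- function(net, avg, target, ttilde, dtda,
                             epsilon = 0, rho_min = 0, ctx = NULL) {
  if (is.null(ctx)) ctx <- make_flow_context(net)
  ne <- nrow(net$edges)
  dp <- avg$p[net$from] - avg$p[net$to]
  qlin <- ttilde * dp
  avg_lin <- avg
  avg_lin$q <- qlin
  cost <- flow_cost(avg_lin, target, net, epsilon, rho_min)

  # dJ/d<q_e> of the linearized cost
  djdq <- numeric(ne)
  lw <- net$edges$length_um[target$act_idx] * target$dir0 / target$l_act
  djdq[target$act_idx] <- 2 * (cost$qbar_sim - target$q_tar) /
    target$q_tar^2 * lw
  if (epsilon > 0) {
    nonact <- setdiff(seq_len(ne), target$act_idx)
    if (cost$rho > 0) {
      djdq[nonact] <- djdq[nonact] + 2 * epsilon *
        (cost$rho - rho_min) / cost$rho *
        (qlin[nonact] - target$q0[nonact]) / target$q_tar^2
    }
  }
  # direct partial dJ/dalpha through Ttilde(alpha)
  djda_direct <- djdq * dp * dtda
  # dJ/d<p>: <q_e> depends on p_i (+Ttilde) and p_j (-Ttilde)
  contrib <- djdq * ttilde
  djdp_acc <- rowsum(c(contrib, -contrib), c(net$from, net$to))
  djdp <- numeric(ctx$nn)
  djdp[as.integer(rownames(djdp_acc))] <- djdp_acc[, 1]

  lambda <- numeric(ctx$nn)
  ni <- length(ctx$interior)
  if (ni > 0) {
    a <- interior_matrix(ctx, ttilde)
    rhs <- -djdp[ctx$interior]
    lam <- as.numeric(Matrix::solve(a, rhs))
    # one step of iterative refinement, then a backward-stable residual
    # check relative to ||A|| ||lambda|| + ||rhs||
    res <- as.numeric(a %*% lam) - rhs
    lam <- lam - as.numeric(Matrix::solve(a, res))
    res <- as.numeric(a %*% lam) - rhs
    denom <- max(Matrix::norm(a, "I") * max(abs(lam)), max(abs(rhs)), 1e-300)
    if (max(abs(res)) > 1e-10 * denom) {
      stop("adjoint solve failed its residual bound")
    }
    lambda[ctx$interior] <- lam
  }
  grad <- djda_direct + (lambda[net$from] - lambda[net$to]) * dp * dtda
  list(grad = grad, lambda = lambda, cost = cost)
}

#' Gradient-descent update of the relative diameters
#'
#' `alpha <- alpha - gamma * grad` on the adaptable edges, then clipped
#' to the configured bounds; non-adaptable edges stay untouched.
#'
#' @param alpha Per-edge relative diameters.
#' @param grad Per-edge gradient.
#' @param gamma Step size.
#' @param adaptable Logical mask over edges.
#' @param bounds `NULL` or `c(lo, hi)` clipping bounds on alpha.
#' @return Updated alpha vector.
#' @export
update_alpha <- function(alpha, grad, gamma, adaptable = NULL, bounds = NULL) {
  if (is.null(adaptable)) adaptable <- rep(TRUE, length(alpha))
  new <- alpha
  new[adaptable] <- alpha[adaptable] - gamma * grad[adaptable]
  if (!is.null(bounds)) {
    new[adaptable] <- pmin(pmax(new[adaptable], bounds[1]), bounds[2])
  }
  # physical floor: a vessel cannot vanish; far outside the empirical
  # laws' validity in any case
  new[adaptable] <- pmax(new[adaptable], 0.05)
  new
}

#' Solve the inverse diameter-adaptation problem
#'
#' Full driver: establishes the baseline averaged state, then iterates
#' { forward averaging window -> cost -> adjoint gradient -> diameter
#' update } until the (moving-average filtered) cost falls below `tol`.
#' Phase 1 runs without secondary constraints (`epsilon = 0`).  Phase 2
#' activates the secondary term, initializes `rho_min` just below the
#' phase-1 `rho`, and geometrically reduces `rho_min` after each
#' reconvergence until the primary target can no longer be reached
#' within the per-level iteration budget, at which point the last
#' feasible state is restored.
#'
#' @param net A [vascular_network()].
#' @param config A [scenario_config()].
#' @param params A [rheology_params()].
#' @param seed Integer seed for all stochastic components.
#' @return Object of class `inverse_result`: final `alpha`, per-iteration
#'   `history` data frame, the `target`, baseline and final averaged
#'   fields, `status`, and the effective step size `gamma`.
#' @export
run_inverse <- function(net, config, params = rheology_params(), seed = 1L) {
  set.seed(seed)
  ctx <- make_flow_context(net)
  ne <- nrow(net$edges)
  adaptable <- config$adaptable_mask(net)
  if (!any(adaptable)) stop("adaptable edge set must not be empty")
  alpha <- rep(1, ne)

  plasma <- isTRUE(config$plasma_only)
  rbcs <- if (plasma) NULL else initialize_rbcs(net, config$init_ht, params)
  if (!plasma && config$spin_up > 0) {
    sp <- run_forward(net, rbcs, params, config$dt, config$spin_up,
                      alpha, ctx = ctx)
    rbcs <- sp$rbcs
  }
  base <- run_forward(net, rbcs, params, config$dt, config$n_avg,
                      alpha, ctx = ctx)
  rbcs <- base$rbcs
  target <- activation_target(net, config$activated, base$avg,
                              multiplier = config$multiplier)
  boundary_nodes <- which(ctx$fixed)
  inflow0 <- sum(pmax(base$avg$b[boundary_nodes], 0))

  eps <- 0
  rho_min <- 0
  gamma <- config$gamma
  phase <- 1L
  level_iter <- 0L
  n_reduce <- 0L
  feasible <- NULL
  status <- "running"
  hist <- vector("list", config$max_iter)
  qwin <- numeric(0)
  rwin <- numeric(0)
  avg <- NULL

  for (nu in seq_len(config$max_iter)) {
    fw <- run_forward(net, rbcs, params, config$dt, config$n_avg,
                      alpha, ctx = ctx)
    rbcs <- fw$rbcs
    avg <- fw$avg
    cost <- flow_cost(avg, target, net, eps, rho_min)
    # filtered convergence statistic: the moving-average filter is
    # applied to the flow statistics BEFORE squaring -- averaging the
    # quadratic cost itself would leave a variance floor that the
    # tolerance could not distinguish from a genuine target mismatch
    qwin <- c(qwin, cost$qbar_sim)
    rwin <- c(rwin, cost$rho)
    if (length(qwin) > config$filter_window) {
      qwin <- qwin[-1]
      rwin <- rwin[-1]
    }
    j_filt <- ((mean(qwin) - target$q_tar) / target$q_tar)^2 +
      eps * (mean(rwin) - rho_min)^2
    # convergence can only be declared on a full filter window, so a
    # rising transient cannot cancel against an overshoot
    window_full <- length(qwin) >= config$filter_window
    term1_filt <- ((mean(qwin) - target$q_tar) / target$q_tar)^2
    # level convergence: primary term below tol; in phase 2 the filtered
    # rho must additionally sit within a relative band of rho_min (the
    # stochastic norm over all non-activated edges carries measurement
    # noise that a squared absolute tolerance cannot resolve)
    level_done <- window_full && term1_filt <= config$tol &&
      (phase == 1L ||
         abs(mean(rwin) - rho_min) <= config$rho_tol_rel * rho_min)
    inflow <- sum(pmax(avg$b[boundary_nodes], 0))
    hist[[nu]] <- data.frame(iteration = nu, J = cost$J, J_filtered = j_filt,
                             term1 = cost$term1, term2 = cost$term2,
                             rho = cost$rho, rho_min = rho_min,
                             epsilon = eps, qbar_sim = cost$qbar_sim,
                             boundary_inflow = inflow, phase = phase)
    if (!level_done) {
      level_iter <- level_iter + 1L
      if (phase == 2L && level_iter > config$level_budget) {
        # current rho_min infeasible: restore last feasible state
        if (!is.null(feasible)) {
          alpha <- feasible$alpha
          rho_min <- feasible$rho_min
          avg <- feasible$avg
          qwin <- feasible$qwin
          rwin <- feasible$rwin
          status <- "min_rho_reached"
        } else {
          status <- "phase2_not_converged"
        }
        break
      }
      tt <- representative_transmissibility(avg, net, config$eta, ctx)
      mu_t <- representative_viscosity(tt$trans, net, alpha, params$mu_p)
      dtda <- dTtilde_dalpha(net, alpha, mu_t, params$mu_p)
      adj <- adjoint_gradient(net, avg, target, tt$trans, dtda,
                              eps, rho_min, ctx)
      if (is.null(gamma)) {
        g0 <- max(abs(adj$grad[adaptable]))
        if (g0 == 0) g0 <- 1
        gamma <- config$step0 / g0
      }
      alpha <- update_alpha(alpha, adj$grad, gamma, adaptable, config$bounds)
    } else {
      if (phase == 1L) {
        if (!config$secondary) { status <- "converged"; break }
        eps <- config$epsilon
        # the phase-1 state is itself feasible at its own rho
        feasible <- list(alpha = alpha, rho_min = mean(rwin), avg = avg,
                         qwin = qwin, rwin = rwin)
        rho_min <- config$rho_factor * mean(rwin)
        phase <- 2L
        # the secondary term changes the gradient scale by orders of
        # magnitude; re-derive the step size from the first phase-2
        # gradient unless gamma was fixed explicitly
        if (is.null(config$gamma)) gamma <- NULL
        level_iter <- 0L
        qwin <- numeric(0)
        rwin <- numeric(0)
      } else {
        feasible <- list(alpha = alpha, rho_min = rho_min, avg = avg,
                         qwin = qwin, rwin = rwin)
        n_reduce <- n_reduce + 1L
        if (n_reduce >= config$max_reductions) {
          status <- "reduction_budget_reached"
          break
        }
        rho_min <- config$rho_factor * rho_min
        level_iter <- 0L
        qwin <- numeric(0)
        rwin <- numeric(0)
      }
    }
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  if (status == "running") {
    status <- if (phase == 1L) "phase1_not_converged" else "phase2_not_converged"
    warning(sprintf(paste0("inverse solver stopped without convergence ",
                           "(%s) after %d iterations; consider a smaller ",
                           "step size or a feasibility check of the target"),
                    status, nrow(history)))
  }
  structure(list(alpha = alpha, history = history, target = target,
                 baseline_avg = base$avg, final_avg = avg,
                 adaptable = adaptable, status = status, gamma = gamma,
                 boundary_inflow0 = inflow0, seed = seed,
                 qbar_filtered = mean(qwin), rho_filtered = mean(rwin),
                 config = config),
            class = "inverse_result")
}

#' @export
print.inverse_result <- function(x, ...) {
  qr <- x$history$qbar_sim[nrow(x$history)] / x$target$qbar0
  cat(sprintf(paste0("<inverse_result> status: %s, %d iterations\n",
                     "  activated flow: %.3fx baseline (target %.3fx)\n",
                     "  alpha range on adaptable edges: [%.4f, %.4f]\n"),
              x$status, nrow(x$history), qr, x$target$q_tar / x$target$qbar0,
              min(x$alpha[x$adaptable]), max(x$alpha[x$adaptable])))
  invisible(x)
}
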