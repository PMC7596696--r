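params <- rheology_params()

# deterministic averaged field from a plasma-only solve, with optionally
# perturbed alpha
plasma_avg <- function(net, alpha = NULL) {
  run_forward(net, NULL, params, n_steps = 1, alpha = alpha)$avg
}

test_that("representative transmissibility recovers steady and averaged states", {
  net <- path_net()
  avg <- plasma_avg(net)
  tt <- representative_transmissibility(avg, net)
  expect_equal(tt$trans, avg$trans_mean, tolerance = 1e-12)
  expect_equal(tt$n_fallback, 0)

  # hand-built 3-sample series: q = 1,2,3 and dp = 1,2,3 -> 2/2 = 1
  fake <- structure(list(q = mean(c(1, 2, 3)),
                         p = c(mean(c(1, 2, 3)), 0),
                         trans_mean = 99, n_steps = 3, dt = 1),
                    class = "time_averaged_field")
  net1 <- single_edge_net(p_in = 2, p_out = 0)
  tt1 <- representative_transmissibility(fake, net1)
  expect_equal(tt1$trans, 1)

  # degenerate: zero pressure drop falls back without dividing by zero
  fake0 <- structure(list(q = 0, p = c(0, 0), trans_mean = 0.5),
                     class = "time_averaged_field")
  tt0 <- representative_transmissibility(fake0, net1)
  expect_equal(tt0$trans, 0.5)
  expect_equal(tt0$n_fallback, 1)
})

test_that("representative viscosity inverts Poiseuille's law", {
  net <- path_net()
  avg <- plasma_avg(net)
  tt <- representative_transmissibility(avg, net)
  mu <- representative_viscosity(tt$trans, net, mu_p = params$mu_p)
  expect_equal(mu, rep(1, 3), tolerance = 1e-12)
  # identity: mu * Ttilde == pi d^4 / (128 l mu_p) for any alpha
  alpha <- c(1.1, 0.9, 1.02)
  mu2 <- representative_viscosity(tt$trans, net, alpha, params$mu_p)
  lhs <- mu2 * tt$trans
  rhs <- pi * (alpha * net$edges$diameter_um)^4 /
    (128 * net$edges$length_um * params$mu_p)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("activated average is a direction-aware length-weighted mean", {
  net <- vascular_network(
    nodes = data.frame(node_id = 1:3, is_boundary = c(TRUE, FALSE, TRUE),
                       pressure_pa = c(100, NA, 0)),
    edges = data.frame(edge_id = 1:2, node_a = c(1, 2), node_b = c(2, 3),
                       diameter_um = 4.5, length_um = c(75, 150)))
  fake <- structure(list(q = c(1, 4), p = c(2, 1, 0), trans_mean = c(1, 1)),
                    class = "time_averaged_field")
  tgt <- activation_target(net, c(1, 2), fake, multiplier = 1.3)
  expect_equal(activated_average(fake, tgt, net), (75 * 1 + 150 * 4) / 225)
  # flipping stored orientation flips both dir0 and q: average unchanged
  net2 <- net
  net2$edges$node_a <- c(2, 2)
  net2$edges$node_b <- c(1, 3)
  net2 <- vascular_network(net2$nodes, net2$edges)
  fake2 <- fake
  fake2$q <- c(-1, 4)
  tgt2 <- activation_target(net2, c(1, 2), fake2, multiplier = 1.3)
  expect_equal(activated_average(fake2, tgt2, net2), 3)
})

test_that("cost terms follow their definitions", {
  net <- path_net()
  avg <- plasma_avg(net)
  tgt <- activation_target(net, 2, avg, multiplier = 1.3)
  # at baseline with epsilon = 0: term1 = ((1 - 1.3)/1.3)^2
  cost <- flow_cost(avg, tgt, net, epsilon = 0)
  expect_equal(cost$term1, (0.3 / 1.3)^2, tolerance = 1e-12)
  expect_equal(cost$term2, 0)
  expect_equal(cost$rho, 0)
  # q_sim = 1.1 q_tar with epsilon = 0 -> J = 0.01 / 1.3^0 ... exact arithmetic
  avg2 <- avg
  avg2$q <- avg$q * 1.3 * 1.1
  cost2 <- flow_cost(avg2, activation_target(net, 2, avg, q_tar = avg$q[2] * 1.3),
                     net, epsilon = 0)
  expect_equal(cost2$term1, 0.01, tolerance = 1e-10)
  # rho: two non-activated edges changed by +-q_tar -> sqrt(2)
  avg3 <- avg
  qt <- tgt$q_tar
  avg3$q <- avg$q + c(qt, 0, -qt) * tgt$dir0_all
  cost3 <- flow_cost(avg3, tgt, net, epsilon = 1, rho_min = 0)
  expect_equal(cost3$rho, sqrt(2), tolerance = 1e-12)
  # both targets met exactly -> J = 0
  avg4 <- avg
  avg4$q <- avg$q
  avg4$q[tgt$act_idx] <- avg$q[tgt$act_idx] * 1.3
  cost4 <- flow_cost(avg4, tgt, net, epsilon = 1, rho_min = 0)
  expect_equal(cost4$J, 0, tolerance = 1e-20)
})

test_that("dTtilde/dalpha matches its closed form and a finite difference", {
  net <- random_net(n_nodes = 8, n_extra = 6, seed = 9)
  ne <- nrow(net$edges)
  alpha <- rep(1, ne)
  dtda <- dTtilde_dalpha(net, alpha, rep(1, ne), params$mu_p)
  t0 <- pi * net$edges$diameter_um^4 / (128 * net$edges$length_um * params$mu_p)
  expect_equal(dtda, 4 * t0, tolerance = 1e-12)
  # ratio identity (dT/da)/T = 4/alpha at fixed representative viscosity
  alpha2 <- seq(0.85, 1.15, length.out = ne)
  mu_t <- runif(ne, 1, 3)
  tt <- pi * (alpha2 * net$edges$diameter_um)^4 /
    (128 * net$edges$length_um * params$mu_p * mu_t)
  dtda2 <- dTtilde_dalpha(net, alpha2, mu_t, params$mu_p)
  expect_equal(dtda2 / tt, 4 / alpha2, tolerance = 1e-12)
  # centered finite difference of T(alpha) with frozen viscosity
  h <- 1e-6
  fd <- (pi * ((alpha2 + h) * net$edges$diameter_um)^4 -
           pi * ((alpha2 - h) * net$edges$diameter_um)^4) /
    (2 * h * 128 * net$edges$length_um * params$mu_p * mu_t)
  expect_equal(dtda2, fd, tolerance = 1e-6)
})

test_that("adjoint gradient equals finite differences of the averaged cost", {
  # oracle: J(alpha) evaluated through an independent dense linear solve
  # with frozen representative viscosity
  for (seed in c(3, 17)) {
    net <- random_net(n_nodes = 9, n_extra = 8, seed = seed)
    ne <- nrow(net$edges)
    set.seed(seed + 100)
    alpha0 <- runif(ne, 0.92, 1.08)
    base_avg <- plasma_avg(net)                 # baseline (alpha = 1)
    avg <- plasma_avg(net, alpha = alpha0)      # current state
    tgt <- activation_target(net, c(1, 2), base_avg, multiplier = 1.3)
    tt <- representative_transmissibility(avg, net)
    mu_t <- representative_viscosity(tt$trans, net, alpha0, params$mu_p)
    dtda <- dTtilde_dalpha(net, alpha0, mu_t, params$mu_p)

    j_dense <- function(a, eps, rho_min) {
      trans <- pi * (a * net$edges$diameter_um)^4 /
        (128 * net$edges$length_um * params$mu_p * mu_t)
      p <- dense_reference_solve(net, trans)
      q <- trans * (p[net$from] - p[net$to])
      qbar <- sum(net$edges$length_um[tgt$act_idx] * tgt$dir0 *
                    q[tgt$act_idx]) / tgt$l_act
      nonact <- setdiff(seq_len(ne), tgt$act_idx)
      rho <- sqrt(sum(((q[nonact] - tgt$q0[nonact]) / tgt$q_tar)^2))
      ((qbar - tgt$q_tar) / tgt$q_tar)^2 + eps * (rho - rho_min)^2
    }
    for (eps in c(0, 0.7)) {
      rho_min <- 0.013
      adj <- adjoint_gradient(net, avg, tgt, tt$trans, dtda, eps, rho_min)
      fd <- vapply(seq_len(ne), function(e) {
        h <- 1e-6
        ap <- alpha0; am <- alpha0
        ap[e] <- ap[e] + h; am[e] <- am[e] - h
        (j_dense(ap, eps, rho_min) - j_dense(am, eps, rho_min)) / (2 * h)
      }, numeric(1))
      scale <- max(abs(fd))
      expect_lt(max(abs(adj$grad - fd) / pmax(abs(fd), 1e-4 * scale)), 1e-5)
    }
  }
})

test_that("gradient vanishes when the target is met with epsilon = 0", {
  net <- path_net()
  avg <- plasma_avg(net)
  tgt <- activation_target(net, 2, avg, q_tar = NULL, multiplier = 1.3)
  tgt$q_tar <- activated_average(avg, tgt, net)  # target = current
  tt <- representative_transmissibility(avg, net)
  mu_t <- representative_viscosity(tt$trans, net, mu_p = params$mu_p)
  dtda <- dTtilde_dalpha(net, rep(1, 3), mu_t, params$mu_p)
  adj <- adjoint_gradient(net, avg, tgt, tt$trans, dtda, 0, 0)
  expect_equal(adj$grad, rep(0, 3), tolerance = 1e-15)
})

test_that("single-edge closed-form gradient is reproduced", {
  # one vessel between fixed pressures, plasma-only, epsilon = 0:
  # dJ/dalpha = 2 (q/q_tar - 1) (dp / q_tar) * 4 T / alpha
  net <- single_edge_net(p_in = 120, p_out = 20)
  avg <- plasma_avg(net)
  tgt <- activation_target(net, 1, avg, multiplier = 1.3)
  tt <- representative_transmissibility(avg, net)
  mu_t <- representative_viscosity(tt$trans, net, mu_p = params$mu_p)
  dtda <- dTtilde_dalpha(net, 1, mu_t, params$mu_p)
  adj <- adjoint_gradient(net, avg, tgt, tt$trans, dtda, 0, 0)
  q <- avg$q[1]
  closed <- 2 * (q / tgt$q_tar - 1) * (100 / tgt$q_tar) * 4 * tt$trans[1]
  expect_equal(adj$grad[1], closed, tolerance = 1e-12)
})

test_that("alpha updates are plain clipped gradient steps", {
  alpha <- c(1, 1, 1)
  grad <- c(0, -2, 1)
  expect_equal(update_alpha(alpha, grad, 0.1), c(1, 1.2, 0.9))
  # zero gradient is a fixed point
  expect_equal(update_alpha(alpha, c(0, 0, 0), 0.5), alpha)
  # halving gamma halves the step
  d1 <- update_alpha(alpha, grad, 0.1) - alpha
  d2 <- update_alpha(alpha, grad, 0.05) - alpha
  expect_equal(d1, 2 * d2)
  # clipping to +-15%
  expect_equal(update_alpha(alpha, grad, 0.2, bounds = c(0.85, 1.15)),
               c(1, 1.15, 0.85))
  # non-adaptable edges never change
  mask <- c(FALSE, TRUE, TRUE)
  out <- update_alpha(alpha, grad, 0.5, adaptable = mask)
  expect_equal(out[1], 1)
})

test_that("single-vessel inversion converges to the fourth-root solution", {
  net <- single_edge_net(p_in = 200, p_out = 0)
  cfg <- scenario_config(activated = 1, multiplier = 1.3, secondary = FALSE,
                         plasma_only = TRUE, n_avg = 1, spin_up = 0,
                         max_iter = 500)
  res <- run_inverse(net, cfg, seed = 1)
  expect_equal(res$status, "converged")
  expect_equal(res$alpha[1], 1.3^0.25, tolerance = 1e-3)
})

test_that("non-adaptable edges keep alpha = 1 through a full inversion", {
  net <- path_net(p_in = 300)
  cfg <- scenario_config(activated = 2, multiplier = 1.2,
                         adaptable = c(1, 2), secondary = FALSE,
                         plasma_only = TRUE, n_avg = 1, spin_up = 0,
                         max_iter = 500)
  res <- run_inverse(net, cfg, seed = 1)
  expect_equal(res$alpha[3], 1)
  expect_equal(res$status, "converged")
  qratio <- res$history$qbar_sim[nrow(res$history)] / res$target$qbar0
  expect_equal(qratio, 1.2, tolerance = 0.01)
})

test_that("filtered cost is non-increasing in the deterministic limit", {
  net <- path_net(p_in = 300)
  cfg <- scenario_config(activated = 2, multiplier = 1.25, secondary = FALSE,
                         plasma_only = TRUE, n_avg = 1, spin_up = 0,
                         max_iter = 400, filter_window = 1)
  res <- run_inverse(net, cfg, seed = 1)
  dj <- diff(res$history$J_filtered)
  expect_true(all(dj <= 1e-12))
})

test_that("infeasibly small rho_min makes the driver revert to the last feasible state", {
  # plasma path network: reaching the target requires changing flow in
  # series edges (rho cannot go to zero); a tiny floor is infeasible
  net <- path_net(p_in = 300)
  cfg <- scenario_config(activated = 2, multiplier = 1.25,
                         adaptable = "all", secondary = TRUE, epsilon = 1,
                         rho_factor = 1e-6,  # jumps straight to near-zero
                         level_budget = 40, max_reductions = 3,
                         plasma_only = TRUE, n_avg = 1, spin_up = 0,
                         max_iter = 600)
  res <- run_inverse(net, cfg, seed = 1)
  expect_equal(res$status, "min_rho_reached")
  # restored state still meets the primary target
  qratio <- activated_average(res$final_avg, res$target, net) / res$target$qbar0
  expect_equal(qratio, 1.25, tolerance = 0.02)
})
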