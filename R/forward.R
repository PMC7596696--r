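#' Seed a network with red blood cells at a uniform tube haematocrit
#'
#' Places `round(H_t * vessel volume / V_rbc)` point particles on every
#' edge, uniformly spaced along its length.  Used as the warm-start state
#' before spin-up towards statistical stationarity.
#'
#' @param net A [vascular_network()].
#' @param ht Initial tube haematocrit (default 0.3).
#' @param params A [rheology_params()].
#' @return An object of class `rbc_population`: flat vectors `edge`
#'   (edge index) and `pos` (arc-length position in um, measured along
#'   the stored edge orientation), plus injection/exit counters.
#' @export
initialize_rbcs <- function(net, ht = 0.3, params = rheology_params()) {
  stopifnot(ht >= 0, ht < 1)
  d <- net$edges$diameter_um
  l <- net$edges$length_um
  n <- round(ht * (pi / 4 * d^2 * l) / params$v_rbc)
  edge <- rep(seq_along(n), n)
  pos <- unlist(lapply(seq_along(n), function(e) {
    if (n[e] == 0) numeric(0) else (seq_len(n[e]) - 0.5) / n[e] * l[e]
  }), use.names = FALSE)
  if (is.null(pos)) pos <- numeric(0)
  structure(list(edge = as.integer(edge), pos = as.numeric(pos),
                 injected = 0L, exited = 0L,
                 initial_total = length(edge),
                 inject_acc = NULL),
            class = "rbc_population")
}

#' @export
print.rbc_population <- function(x, ...) {
  cat(sprintf("<rbc_population> %d particles (injected %d, exited %d)\n",
              length(x$edge), x$injected, x$exited))
  invisible(x)
}

# Precomputed index structures for repeated pressure solves on one
# network topology.  The reduced system eliminates fixed-pressure
# (Dirichlet) rows symmetrically, so the interior matrix is symmetric
# positive definite and shared between forward and adjoint solves.
make_flow_context <- function(net) {
  nn <- nrow(net$nodes)
  ne <- nrow(net$edges)
  fixed <- net$nodes$is_boundary & !is.na(net$nodes$pressure_pa)
  interior <- which(!fixed)
  imap <- integer(nn)
  imap[interior] <- seq_along(interior)
  fr <- net$from
  to <- net$to

  ti <- integer(0); tj <- integer(0); te <- integer(0); ts <- numeric(0)
  rr <- integer(0); re <- integer(0); rp <- numeric(0)
  pfix <- net$nodes$pressure_pa
  for (e in seq_len(ne)) {
    i <- fr[e]; j <- to[e]
    ii <- imap[i]; jj <- imap[j]
    if (ii > 0) { ti <- c(ti, ii); tj <- c(tj, ii); te <- c(te, e); ts <- c(ts, 1) }
    if (jj > 0) { ti <- c(ti, jj); tj <- c(tj, jj); te <- c(te, e); ts <- c(ts, 1) }
    if (ii > 0 && jj > 0) {
      # upper triangle only: the reduced matrix is assembled symmetric
      ti <- c(ti, min(ii, jj)); tj <- c(tj, max(ii, jj))
      te <- c(te, e); ts <- c(ts, -1)
    }
    if (ii > 0 && jj == 0) { rr <- c(rr, ii); re <- c(re, e); rp <- c(rp, pfix[j]) }
    if (jj > 0 && ii == 0) { rr <- c(rr, jj); re <- c(re, e); rp <- c(rp, pfix[i]) }
  }
  pscale <- if (sum(fixed) >= 2) diff(range(pfix[fixed])) else max(abs(pfix[fixed]), 1)
  adj <- vector("list", nn)
  for (i in seq_len(nn)) adj[[i]] <- integer(0)
  for (e in seq_len(ne)) {
    adj[[fr[e]]] <- c(adj[[fr[e]]], e)
    adj[[to[e]]] <- c(adj[[to[e]]], e)
  }
  list(nn = nn, ne = ne, fixed = fixed, interior = interior, imap = imap,
       ti = ti, tj = tj, te = te, ts = ts,
       rr = rr, re = re, rp = rp,
       p_fixed = pfix, pressure_scale = pscale,
       adj = adj,
       cache = new.env(parent = emptyenv()))
}

# Assemble the reduced interior system matrix for given per-edge
# transmissibilities, reusing a cached sparsity pattern after the first
# call (the pattern is fixed by the network topology).
interior_matrix <- function(ctx, trans) {
  vals <- trans[ctx$te] * ctx$ts
  if (is.null(ctx$cache$a)) {
    ni <- length(ctx$interior)
    a <- Matrix::sparseMatrix(i = ctx$ti, j = ctx$tj, x = vals,
                              dims = c(ni, ni), symmetric = TRUE)
    # map triplet k to its position in the CSC x slot (uplo = "U",
    # triplets already satisfy ti <= tj)
    ptr <- a@p
    pos <- integer(length(ctx$ti))
    for (k in seq_along(pos)) {
      j <- ctx$tj[k]
      slice <- (ptr[j] + 1L):ptr[j + 1L]
      pos[k] <- slice[match(ctx$ti[k] - 1L, a@i[slice])]
    }
    ctx$cache$a <- a
    ctx$cache$xpos <- pos
    a
  } else {
    a <- ctx$cache$a
    a@x <- rowsum(vals, ctx$cache$xpos)[, 1]
    # drop factorizations cached inside the object: they belong to the
    # previous values of x
    a@factors <- list()
    ctx$cache$a <- a
    a
  }
}

# Solve the nodal pressure system for given per-edge transmissibilities.
# Returns full pressure vector (fixed values at Dirichlet nodes).
solve_pressures <- function(ctx, trans) {
  p <- ctx$p_fixed
  ni <- length(ctx$interior)
  if (ni == 0L) return(p)
  a <- interior_matrix(ctx, trans)
  rhs <- numeric(ni)
  if (length(ctx$rr)) {
    add <- trans[ctx$re] * ctx$rp
    agg <- rowsum(add, ctx$rr)
    rhs[as.integer(rownames(agg))] <- agg[, 1]
  }
  sol <- tryCatch({
    # reuse the symbolic Cholesky factorization across steps
    if (is.null(ctx$cache$chol)) {
      ctx$cache$chol <- Matrix::Cholesky(a, LDL = FALSE)
    } else {
      ctx$cache$chol <- Matrix::.updateCHMfactor(ctx$cache$chol, a, mult = 0)
    }
    Matrix::solve(ctx$cache$chol, rhs, system = "A")
  }, error = function(e) {
    stop("pressure system is singular (interior component without a ",
         "fixed-pressure node?): ", conditionMessage(e))
  })
  p[ctx$interior] <- as.numeric(sol)
  p
}

#' RBC velocity in a vessel
#'
#' Because of the Fahraeus effect RBCs travel faster than the bulk:
#' `v_rbc = q / (pi/4 d^2) * H_d/H_t`, signed like the flow rate `q`.
#' The ratio is evaluated through the identity
#' `H_d/H_t = 1 / (H_d + (1 - H_d) r(d))`, which carries the analytic
#' limit `1/r(d)` as `H_t -> 0`.
#'
#' @param q Signed flow rate in um^3/ms (vectorised).
#' @param d Vessel diameter in um.
#' @param h_t Tube haematocrit.
#' @param params A [rheology_params()] (unused by the default laws but
#'   kept for signature stability).
#' @return Signed RBC velocity in um/ms.
#' @export
rbc_velocity <- function(q, d, h_t, params = rheology_params()) {
  if (any(d <= 0)) stop("rbc_velocity: diameter must be positive")
  q / (pi / 4 * d^2) * hd_ht_ratio(h_t, d)
}

#' Instantaneous pressure/flow solve for the current RBC distribution
#'
#' Computes per-edge transmissibilities from the current diameters and
#' tube haematocrits (through the relative apparent viscosity), solves
#' the linear nodal flow-balance system for the pressures, and derives
#' flow rates, boundary source terms and RBC velocities.
#'
#' @param net A [vascular_network()].
#' @param rbcs An `rbc_population`, or `NULL` for plasma-only flow.
#' @param params A [rheology_params()].
#' @param alpha Optional per-edge relative diameters (default 1).
#' @param ctx Optional precomputed solver context (internal reuse).
#' @return An object of class `flow_state` with elements `p` (Pa),
#'   `q` (um^3/ms, signed along stored edge orientation), `trans`,
#'   `mu_rel`, `ht`, `hd`, `v_rbc` and `b` (nodal source terms).
#' @export
assemble_and_solve <- function(net, rbcs = NULL, params = rheology_params(),
                               alpha = NULL, ctx = NULL) {
  if (is.null(ctx)) ctx <- make_flow_context(net)
  ne <- ctx$ne
  d0 <- net$edges$diameter_um
  l <- net$edges$length_um
  if (is.null(alpha)) alpha <- rep(1, ne)
  d <- alpha * d0
  if (is.null(rbcs)) {
    ht <- numeric(ne)
    n_rbc <- integer(ne)
  } else {
    n_rbc <- tabulate(rbcs$edge, nbins = ne)
    ht <- n_rbc * params$v_rbc / (d^2 * pi / 4 * l)
  }
  hd <- discharge_from_tube(pmin(ht, 1), d)
  # viscosity evaluated at a capped haematocrit to stay inside the
  # validity range of the empirical law; packing above the cap is
  # reported by the caller via max(ht)
  h_visc <- if (params$viscosity_haematocrit == "discharge") {
    pmin(hd, 0.95)
  } else {
    pmin(ht, 0.95)
  }
  mu_rel <- relative_viscosity(h_visc, d)
  trans <- pi * d^4 / (128 * l * params$mu_p * mu_rel)
  p <- solve_pressures(ctx, trans)
  q <- trans * (p[net$from] - p[net$to])
  # nodal residual: zero at interior nodes, source/sink at boundaries
  b <- numeric(ctx$nn)
  qacc <- rowsum(c(q, -q), c(net$from, net$to))
  b[as.integer(rownames(qacc))] <- qacc[, 1]
  v <- q / (pi / 4 * d^2) / (hd + (1 - hd) * fahraeus_r(d))
  structure(list(p = p, q = q, trans = trans, mu_rel = mu_rel,
                 ht = ht, hd = hd,
                 n_rbc = n_rbc, v_rbc = v, b = b, d = d),
            class = "flow_state")
}

# Pick a daughter edge for one RBC at a divergent bifurcation.
# out_e: edge indices of the outflow daughters; out_q: their unsigned
# flow rates; d: current diameters.  The two-daughter empirical law is
# applied pairwise, pooling the remainder (diameter = largest remaining).
sample_daughter <- function(out_e, out_q, d, hd_parent, d_parent) {
  while (length(out_e) > 1L) {
    qa <- out_q[1L]
    qtot <- sum(out_q)
    fq <- if (qtot > 0) qa / qtot else 1 / length(out_e)
    d_pool <- max(d[out_e[-1L]])
    pr <- phase_separation_probability(fq, hd_parent, d_parent,
                                       d[out_e[1L]], d_pool)
    if (stats::runif(1) < pr) return(out_e[1L])
    out_e <- out_e[-1L]
    out_q <- out_q[-1L]
  }
  out_e[1L]
}

#' Advance the RBC population by one time step
#'
#' Moves each particle by `v_rbc * dt` along its edge.  A particle
#' reaching the downstream node is handed to a downstream edge: sampled
#' from the phase-separation law at divergent bifurcations, deterministic
#' at pass-throughs and convergent bifurcations.  At most one junction is
#' crossed per step; residual travel is applied in the receiving edge at
#' its current velocity.  Particles reaching a fixed-pressure boundary
#' node exit and are counted; inflow boundaries inject particles through
#' a fractional accumulator that maintains the prescribed inflow tube
#' haematocrit in long-run average.
#'
#' A packing rule bounds the tube haematocrit: an RBC never enters an
#' edge that already holds `ht_warn` worth of cell volume; it is
#' rerouted to a free daughter, or stalls at the junction until space
#' opens.  (Particles are points otherwise - there is no volume
#' exclusion or overtaking within an edge.)
#'
#' Uses the R random number stream for the bifurcation sampling; seed it
#' with [set.seed()] (or via the `seed` argument of [run_forward()]) for
#' reproducibility.
#'
#' @param net A [vascular_network()].
#' @param rbcs Current `rbc_population`.
#' @param flow `flow_state` computed for this population.
#' @param dt Time step in ms.
#' @param params A [rheology_params()].
#' @param ctx Internal: precomputed solver context.
#' @return The advanced `rbc_population`.
#' @export
advance_rbcs <- function(net, rbcs, flow, dt, params = rheology_params(),
                         ctx = NULL) {
  if (is.null(ctx)) ctx <- make_flow_context(net)
  if (dt < 0) stop("advance_rbcs: time step must be non-negative")
  ne <- nrow(net$edges)
  l <- net$edges$length_um
  d <- flow$d
  v <- flow$v_rbc
  q <- flow$q
  edge <- rbcs$edge
  pos <- rbcs$pos + v[rbcs$edge] * dt
  exited <- rbcs$exited
  fixedp <- net$nodes$is_boundary & !is.na(net$nodes$pressure_pa)
  # packing rule: an edge holds at most ht_warn worth of cell volume;
  # a cell never enters a full edge (rerouted or stalled instead)
  cap_n <- pmax(floor(params$ht_warn * (pi / 4 * d^2 * l) / params$v_rbc), 1L)
  n_cur <- tabulate(edge, nbins = ne)

  cross_fwd <- v[edge] > 0 & pos >= l[edge]
  cross_bwd <- v[edge] < 0 & pos <= 0
  crossing <- which(cross_fwd | cross_bwd)
  drop <- logical(length(edge))

  if (length(crossing)) {
    # deterministic processing order: by edge, then front-most first
    ord <- crossing[order(edge[crossing],
                          -(pos[crossing] * sign(v[edge[crossing]])))]
    for (k in ord) {
      e <- edge[k]
      fwd <- v[e] > 0
      node <- if (fwd) net$to[e] else net$from[e]
      t_res <- if (fwd) (pos[k] - l[e]) / v[e] else pos[k] / v[e]
      if (fixedp[node]) {
        drop[k] <- TRUE
        exited <- exited + 1L
        n_cur[e] <- n_cur[e] - 1L
        next
      }
      inc <- ctx$adj[[node]]
      inc <- inc[inc != e]
      out_sign <- ifelse(net$from[inc] == node, 1, -1)
      out_q <- q[inc] * out_sign
      keep_out <- out_q > 0 & n_cur[inc] < cap_n[inc]
      if (!any(keep_out)) {
        pos[k] <- if (fwd) l[e] else 0
        next
      }
      oe <- inc[keep_out]
      oq <- out_q[keep_out]
      if (length(oe) > 1L) {
        ord_q <- order(-oq)
        # hd can momentarily reach 1 when a constriction shrinks an
        # edge around its current cells; keep the law's domain open
        e2 <- sample_daughter(oe[ord_q], oq[ord_q], d,
                              min(flow$hd[e], 0.99), d[e])
      } else {
        e2 <- oe
      }
      travel <- abs(v[e2]) * t_res
      if (net$from[e2] == node) {
        pos[k] <- min(travel, l[e2])
      } else {
        pos[k] <- max(l[e2] - travel, 0)
      }
      n_cur[e] <- n_cur[e] - 1L
      n_cur[e2] <- n_cur[e2] + 1L
      edge[k] <- e2
    }
  }
  if (any(drop)) {
    edge <- edge[!drop]
    pos <- pos[!drop]
  }
  pos <- pmin(pmax(pos, 0), l[edge])

  # inflow injection: one fractional accumulator per inflow edge
  acc <- rbcs$inject_acc
  if (is.null(acc)) acc <- numeric(ne)
  injected <- rbcs$injected
  inlets <- which(fixedp & !is.na(net$nodes$ht_in))
  for (nb in inlets) {
    ht_in <- net$nodes$ht_in[nb]
    if (ht_in <= 0) next
    inc <- ctx$adj[[nb]]
    out_sign <- ifelse(net$from[inc] == nb, 1, -1)
    oe <- inc[q[inc] * out_sign > 0]
    for (e in oe) {
      lambda <- ht_in * (pi / 4 * d[e]^2) / params$v_rbc  # cells per um
      acc[e] <- min(acc[e] + abs(v[e]) * dt * lambda, 1.5)
      while (acc[e] >= 1 && n_cur[e] < cap_n[e]) {
        acc[e] <- acc[e] - 1
        entry <- if (net$from[e] == nb) 0 else l[e]
        edge <- c(edge, e)
        pos <- c(pos, entry)
        n_cur[e] <- n_cur[e] + 1L
        injected <- injected + 1L
      }
    }
  }
  structure(list(edge = edge, pos = pos, injected = injected,
                 exited = exited, initial_total = rbcs$initial_total,
                 inject_acc = acc),
            class = "rbc_population")
}

#' Run the forward biphasic simulator over an averaging window
#'
#' Alternates instantaneous pressure/flow solves and RBC advection for
#' `n_steps` time steps and returns the arithmetic means of flow rates,
#' pressures and boundary source terms over the window, together with the
#' end-of-window particle state.  With `rbcs = NULL` the flow is
#' plasma-only, deterministic, and the averages equal the single solve.
#'
#' @param net A [vascular_network()].
#' @param rbcs `rbc_population` or `NULL` (plasma-only).
#' @param params A [rheology_params()].
#' @param dt Time step in ms (default 0.4).
#' @param n_steps Number of steps in the averaging window (default 500).
#' @param alpha Optional per-edge relative diameters.
#' @param seed Optional integer seed for the bifurcation sampling.
#' @param ctx Internal: precomputed solver context.
#' @return List with elements `avg` (class `time_averaged_field`:
#'   per-edge `q`, `trans_mean`, per-node `p`, `b`, plus `n_steps`, `dt`,
#'   `max_ht`) and `rbcs` (final population) and `last` (final
#'   `flow_state`).
#' @export
run_forward <- function(net, rbcs = NULL, params = rheology_params(),
                        dt = 0.4, n_steps = 500, alpha = NULL, seed = NULL,
                        ctx = NULL) {
  stopifnot(n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ctx)) ctx <- make_flow_context(net)
  if (is.null(rbcs)) {
    fs <- assemble_and_solve(net, NULL, params, alpha, ctx)
    avg <- structure(list(q = fs$q, p = fs$p, b = fs$b,
                          trans_mean = fs$trans, n_steps = n_steps, dt = dt,
                          max_ht = 0),
                     class = "time_averaged_field")
    return(list(avg = avg, rbcs = NULL, last = fs))
  }
  ne <- ctx$ne
  sq <- numeric(ne); st <- numeric(ne)
  sp <- numeric(ctx$nn); sb <- numeric(ctx$nn)
  max_ht <- 0
  fs <- NULL
  for (step in seq_len(n_steps)) {
    fs <- assemble_and_solve(net, rbcs, params, alpha, ctx)
    sq <- sq + fs$q; st <- st + fs$trans
    sp <- sp + fs$p; sb <- sb + fs$b
    mh <- max(fs$ht)
    if (mh > max_ht) max_ht <- mh
    rbcs <- advance_rbcs(net, rbcs, fs, dt, params, ctx)
  }
  if (max_ht > params$ht_warn) {
    warning(sprintf("tube haematocrit reached %.3f (> %.2f) during window",
                    max_ht, params$ht_warn))
  }
  avg <- structure(list(q = sq / n_steps, p = sp / n_steps, b = sb / n_steps,
                        trans_mean = st / n_steps, n_steps = n_steps, dt = dt,
                        max_ht = max_ht),
                   class = "time_averaged_field")
  list(avg = avg, rbcs = rbcs, last = fs)
}
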