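# Small fixture networks, built in code.

# one vessel between two fixed-pressure nodes
single_edge_net <- function(p_in = 100, p_out = 0, d = 4.5, l = 75) {
  vascular_network(
    nodes = data.frame(node_id = 1:2, is_boundary = TRUE,
                       pressure_pa = c(p_in, p_out)),
    edges = data.frame(edge_id = 1, node_a = 1, node_b = 2,
                       diameter_um = d, length_um = l))
}

# two identical parallel vessels between the same fixed-pressure nodes
parallel_net <- function(p_in = 100, p_out = 0) {
  vascular_network(
    nodes = data.frame(node_id = 1:2, is_boundary = TRUE,
                       pressure_pa = c(p_in, p_out)),
    edges = data.frame(edge_id = 1:2, node_a = 1, node_b = 2,
                       diameter_um = 4.5, length_um = 75))
}

# path graph a-b-c-d (edges 1,2,3), pressures fixed at the two ends
path_net <- function(p_in = 100, p_out = 0) {
  vascular_network(
    nodes = data.frame(node_id = 1:4,
                       is_boundary = c(TRUE, FALSE, FALSE, TRUE),
                       pressure_pa = c(p_in, NA, NA, p_out)),
    edges = data.frame(edge_id = 1:3, node_a = 1:3, node_b = 2:4,
                       diameter_um = 4.5, length_um = 75))
}

# symmetric Y: inlet feeds a parent that splits into two equal daughters
y_net <- function(p_in = 200, d_a = 5, d_b = 5) {
  vascular_network(
    nodes = data.frame(node_id = 1:4,
                       is_boundary = c(TRUE, FALSE, TRUE, TRUE),
                       pressure_pa = c(p_in, NA, 0, 0),
                       ht_in = c(0.3, NA, NA, NA)),
    edges = data.frame(edge_id = 1:3, node_a = c(1, 2, 2),
                       node_b = c(2, 3, 4),
                       diameter_um = c(6, d_a, d_b), length_um = 75))
}

# connected random network with n_nodes nodes, pressures fixed at two
# nodes; diameters/lengths drawn from seeded uniforms
random_net <- function(n_nodes = 10, n_extra = 8, seed = 1,
                       p_in = 200, p_out = 0) {
  set.seed(seed)
  path <- cbind(seq_len(n_nodes - 1), seq(2, n_nodes))
  all_pairs <- t(utils::combn(n_nodes, 2))
  extra <- all_pairs[sample(nrow(all_pairs), n_extra), , drop = FALSE]
  ed <- unique(rbind(path, extra))
  vascular_network(
    nodes = data.frame(node_id = seq_len(n_nodes),
                       is_boundary = c(TRUE, rep(FALSE, n_nodes - 2), TRUE),
                       pressure_pa = c(p_in, rep(NA, n_nodes - 2), p_out)),
    edges = data.frame(edge_id = seq_len(nrow(ed)),
                       node_a = ed[, 1], node_b = ed[, 2],
                       diameter_um = stats::runif(nrow(ed), 3, 7),
                       length_um = stats::runif(nrow(ed), 50, 100)))
}

# dense (base-R) reference solve of the nodal pressure system for given
# per-edge transmissibilities; independent of the package's sparse path
dense_reference_solve <- function(net, trans) {
  nn <- nrow(net$nodes)
  l_mat <- matrix(0, nn, nn)
  for (e in seq_len(nrow(net$edges))) {
    i <- net$from[e]; j <- net$to[e]
    l_mat[i, i] <- l_mat[i, i] + trans[e]
    l_mat[j, j] <- l_mat[j, j] + trans[e]
    l_mat[i, j] <- l_mat[i, j] - trans[e]
    l_mat[j, i] <- l_mat[j, i] - trans[e]
  }
  fixed <- which(net$nodes$is_boundary & !is.na(net$nodes$pressure_pa))
  interior <- setdiff(seq_len(nn), fixed)
  p <- numeric(nn)
  p[fixed] <- net$nodes$pressure_pa[fixed]
  if (length(interior)) {
    p[interior] <- solve(l_mat[interior, interior, drop = FALSE],
                         -l_mat[interior, fixed, drop = FALSE] %*% p[fixed])
  }
  p
}
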