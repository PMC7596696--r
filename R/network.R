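#' Construct a vascular network object
#'
#' A vascular network is a graph of nodes (junctions, with optional 3-D
#' coordinates in um) and edges (vessel segments with baseline diameter
#' and length in um).  Boundary nodes carry fixed pressures (Pa); inflow
#' boundary nodes may additionally prescribe an inflow tube haematocrit.
#' Edge orientation is the stored `(node_a, node_b)` order; all signed
#' per-edge quantities (flow rate, baseline direction) refer to it.
#'
#' @param nodes data.frame with columns `node_id`, optional `x_um`,
#'   `y_um`, `z_um`, `is_boundary` (logical), `pressure_pa` (NA for
#'   interior nodes) and `ht_in` (NA where not an RBC inflow).
#' @param edges data.frame with columns `edge_id`, `node_a`, `node_b`,
#'   `diameter_um`, `length_um` and optional `type`.
#' @return An object of class `vascular_network`.
#' @export
vascular_network <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need_n <- c("node_id")
  need_e <- c("edge_id", "node_a", "node_b", "diameter_um", "length_um")
  miss_n <- setdiff(need_n, names(nodes))
  miss_e <- setdiff(need_e, names(edges))
  if (length(miss_n)) {
    stop("nodes table is missing column(s): ", paste(miss_n, collapse = ", "))
  }
  if (length(miss_e)) {
    stop("edges table is missing column(s): ", paste(miss_e, collapse = ", "))
  }
  for (col in c("x_um", "y_um", "z_um")) {
    if (is.null(nodes[[col]])) nodes[[col]] <- NA_real_
  }
  if (is.null(nodes$is_boundary)) nodes$is_boundary <- FALSE
  if (is.null(nodes$pressure_pa)) nodes$pressure_pa <- NA_real_
  if (is.null(nodes$ht_in)) nodes$ht_in <- NA_real_
  if (is.null(edges$type)) edges$type <- NA_character_
  nodes$is_boundary <- as.logical(nodes$is_boundary)
  nodes$is_boundary[is.na(nodes$is_boundary)] <- FALSE

  if (anyDuplicated(nodes$node_id)) stop("duplicate node_id values")
  if (anyDuplicated(edges$edge_id)) stop("duplicate edge_id values")

  from <- match(edges$node_a, nodes$node_id)
  to <- match(edges$node_b, nodes$node_id)
  bad <- which(is.na(from) | is.na(to))
  if (length(bad)) {
    stop(sprintf("edge row %d (edge_id %s) references unknown node id(s): %s",
                 bad[1], edges$edge_id[bad[1]],
                 paste(setdiff(c(edges$node_a[bad[1]], edges$node_b[bad[1]]),
                               nodes$node_id), collapse = ", ")))
  }
  self <- which(from == to)
  if (length(self)) {
    stop(sprintf("edge row %d (edge_id %s) connects a node to itself",
                 self[1], edges$edge_id[self[1]]))
  }
  bad_d <- which(!is.finite(edges$diameter_um) | edges$diameter_um <= 0)
  if (length(bad_d)) {
    stop(sprintf("edge row %d (edge_id %s): diameter must be positive",
                 bad_d[1], edges$edge_id[bad_d[1]]))
  }
  bad_l <- which(!is.finite(edges$length_um) | edges$length_um <= 0)
  if (length(bad_l)) {
    stop(sprintf("edge row %d (edge_id %s): length must be positive",
                 bad_l[1], edges$edge_id[bad_l[1]]))
  }
  fixed <- nodes$is_boundary & !is.na(nodes$pressure_pa)
  if (!any(fixed)) {
    stop("network needs at least one boundary node with a fixed pressure")
  }
  if (any(!is.finite(nodes$pressure_pa[fixed]))) {
    stop("fixed boundary pressures must be finite")
  }
  ht <- nodes$ht_in[!is.na(nodes$ht_in)]
  if (any(ht < 0 | ht >= 1)) stop("inflow tube haematocrit must lie in [0, 1)")

  net <- structure(list(nodes = nodes, edges = edges,
                        from = from, to = to),
                   class = "vascular_network")
  if (!network_is_connected(net)) {
    stop("network graph is not connected")
  }
  net
}

# breadth-first connectivity check over the undirected graph
network_is_connected <- function(net) {
  nn <- nrow(net$nodes)
  if (nn <= 1L) return(TRUE)
  adj <- node_adjacency(net)
  seen <- logical(nn)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    for (e in adj[[cur]]) {
      nb <- if (net$from[e] == cur) net$to[e] else net$from[e]
      if (!seen[nb]) {
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  all(seen)
}

# list: per node index, integer vector of incident edge indices
node_adjacency <- function(net) {
  nn <- nrow(net$nodes)
  adj <- vector("list", nn)
  for (i in seq_len(nn)) adj[[i]] <- integer(0)
  for (e in seq_len(nrow(net$edges))) {
    adj[[net$from[e]]] <- c(adj[[net$from[e]]], e)
    adj[[net$to[e]]] <- c(adj[[net$to[e]]], e)
  }
  adj
}

#' @export
print.vascular_network <- function(x, ...) {
  nb <- sum(x$nodes$is_boundary)
  cat(sprintf(paste0("<vascular_network> %d nodes (%d boundary), %d edges\n",
                     "  diameters %.2f-%.2f um, lengths %.1f-%.1f um\n"),
              nrow(x$nodes), nb, nrow(x$edges),
              min(x$edges$diameter_um), max(x$edges$diameter_um),
              min(x$edges$length_um), max(x$edges$length_um)))
  invisible(x)
}

#' Generate a planar honeycomb capillary lattice
#'
#' Builds an artificial hexagonal network approximating a highly
#' interconnected capillary bed: `n_rows` x `n_cols` hexagonal cells whose
#' sides are vessel segments of uniform diameter `d0` and length `l`.
#' Every interior node has degree 3.  One inlet and one outlet node on
#' opposite lattice sides carry constant pressures; the inlet additionally
#' prescribes the inflow tube haematocrit.
#'
#' @param n_rows,n_cols Number of hexagonal cells per direction (>= 2).
#' @param d0 Uniform baseline vessel diameter in um (default 4.5).
#' @param l Uniform vessel length in um (default 75); also the geometric
#'   hexagon side, so coordinates are metrically consistent.
#' @param p_in,p_out Inlet/outlet pressures in Pa.
#' @param ht_in Inflow tube haematocrit (default 0.3).
#' @param inlet,outlet Node selectors: `"west"`/`"east"` (extreme node in
#'   x), or an explicit node id.
#' @return A [vascular_network()].
#' @examples
#' net <- build_hexagonal_network(4, 4)
#' @export
build_hexagonal_network <- function(n_rows, n_cols, d0 = 4.5, l = 75,
                                    p_in = 8000, p_out = 0, ht_in = 0.3,
                                    inlet = "west", outlet = "east") {
  if (n_rows < 2 || n_cols < 2) {
    stop("hexagonal lattice needs n_rows >= 2 and n_cols >= 2 to contain ",
         "a centered activated region")
  }
  stopifnot(d0 > 0, l > 0)
  s <- l
  # flat-top hexagon cells; cell (r, c) center:
  #   x = 1.5 s c, y = sqrt(3) s r + (c odd) sqrt(3)/2 s
  verts <- list()
  edges_a <- integer(0)
  edges_b <- integer(0)
  key_env <- new.env(hash = TRUE, parent = emptyenv())
  coords_x <- numeric(0)
  coords_y <- numeric(0)
  vid_of <- function(x, y) {
    key <- paste(round(x / s, 6), round(y / s, 6), sep = "_")
    id <- key_env[[key]]
    if (is.null(id)) {
      id <- length(coords_x) + 1L
      coords_x[[id]] <<- x
      coords_y[[id]] <<- y
      key_env[[key]] <- id
    }
    id
  }
  ang <- (0:5) * pi / 3
  for (r in seq_len(n_rows) - 1L) {
    for (c in seq_len(n_cols) - 1L) {
      cx <- 1.5 * s * c
      cy <- sqrt(3) * s * r + (c %% 2) * sqrt(3) / 2 * s
      vx <- cx + s * cos(ang)
      vy <- cy + s * sin(ang)
      ids <- vapply(1:6, function(k) vid_of(vx[k], vy[k]), integer(1))
      for (k in 1:6) {
        a <- ids[k]
        b <- ids[if (k == 6) 1 else k + 1]
        edges_a <- c(edges_a, min(a, b))
        edges_b <- c(edges_b, max(a, b))
      }
    }
  }
  ekey <- paste(edges_a, edges_b, sep = "-")
  keep <- !duplicated(ekey)
  edges_a <- edges_a[keep]
  edges_b <- edges_b[keep]

  nn <- length(coords_x)
  nodes <- data.frame(node_id = seq_len(nn),
                      x_um = coords_x, y_um = coords_y, z_um = 0,
                      is_boundary = FALSE, pressure_pa = NA_real_,
                      ht_in = NA_real_)
  pick <- function(sel) {
    if (is.character(sel) && sel %in% c("west", "east")) {
      ord <- order(if (sel == "west") nodes$x_um else -nodes$x_um, nodes$y_um)
      nodes$node_id[ord[1]]
    } else {
      if (!sel %in% nodes$node_id) stop("unknown node id for inlet/outlet: ", sel)
      sel
    }
  }
  n_in <- pick(inlet)
  n_out <- pick(outlet)
  if (n_in == n_out) stop("inlet and outlet must be distinct nodes")
  nodes$is_boundary[nodes$node_id %in% c(n_in, n_out)] <- TRUE
  nodes$pressure_pa[nodes$node_id == n_in] <- p_in
  nodes$pressure_pa[nodes$node_id == n_out] <- p_out
  nodes$ht_in[nodes$node_id == n_in] <- ht_in

  edges <- data.frame(edge_id = seq_along(edges_a),
                      node_a = edges_a, node_b = edges_b,
                      diameter_um = d0, length_um = l,
                      type = "C")
  vascular_network(nodes, edges)
}

#' Select the n edges closest to the network centroid
#'
#' Utility for placing a centered activated region: ranks edges by the
#' Euclidean distance of their midpoint to the mean node position and
#' returns the `n` closest edge ids (ties broken by edge id).
#'
#' @param net A [vascular_network()] with coordinates.
#' @param n Number of edges to select.
#' @param exclude_boundary_touching If TRUE (default), edges incident to a
#'   fixed-pressure boundary node are never selected.
#' @return Vector of `n` edge ids.
#' @export
select_central_edges <- function(net, n, exclude_boundary_touching = TRUE) {
  if (any(is.na(net$nodes$x_um)) || any(is.na(net$nodes$y_um))) {
    stop("select_central_edges needs node coordinates")
  }
  cx <- mean(net$nodes$x_um)
  cy <- mean(net$nodes$y_um)
  mx <- (net$nodes$x_um[net$from] + net$nodes$x_um[net$to]) / 2
  my <- (net$nodes$y_um[net$from] + net$nodes$y_um[net$to]) / 2
  dist <- sqrt((mx - cx)^2 + (my - cy)^2)
  ok <- rep(TRUE, nrow(net$edges))
  if (exclude_boundary_touching) {
    bnd <- which(net$nodes$is_boundary)
    ok <- !(net$from %in% bnd | net$to %in% bnd)
  }
  if (sum(ok) < n) {
    stop(sprintf(paste0("lattice too small to contain a centered activated ",
                        "region of %d edges (%d eligible)"), n, sum(ok)))
  }
  idx <- which(ok)[order(dist[ok], net$edges$edge_id[ok])][seq_len(n)]
  net$edges$edge_id[idx]
}

#' Label edges by adjacency generation around an activated set
#'
#' Breadth-first shells over edge adjacency (edges sharing a node):
#' the activated edges are generation 0, their neighbours generation 1,
#' and so on up to `max_gen`; edges farther away are `NA`.
#'
#' @param net A [vascular_network()].
#' @param activated Vector of activated edge ids (generation 0).
#' @param max_gen Largest generation to label (default 5).
#' @return Integer vector over edges (in `net$edges` order): the
#'   generation, or `NA` beyond `max_gen`.
#' @export
label_generations <- function(net, activated, max_gen = 5) {
  if (length(activated) == 0) stop("activated edge set must not be empty")
  act_idx <- match(activated, net$edges$edge_id)
  if (anyNA(act_idx)) {
    stop("unknown activated edge id(s): ",
         paste(activated[is.na(act_idx)], collapse = ", "))
  }
  ne <- nrow(net$edges)
  gen <- rep(NA_integer_, ne)
  gen[act_idx] <- 0L
  adj <- node_adjacency(net)
  frontier <- act_idx
  k <- 0L
  while (k < max_gen && length(frontier)) {
    nodes_k <- unique(c(net$from[frontier], net$to[frontier]))
    nxt <- unique(unlist(adj[nodes_k]))
    nxt <- nxt[is.na(gen[nxt])]
    gen[nxt] <- k + 1L
    frontier <- nxt
    k <- k + 1L
  }
  gen
}

#' Read / write a vascular network as CSV tables
#'
#' `write_network()` writes `nodes.csv`
#' (`node_id,x_um,y_um,z_um,is_boundary,pressure_pa,ht_in`) and
#' `edges.csv` (`edge_id,node_a,node_b,diameter_um,length_um,type`);
#' `read_network()` reads them back.  Numeric fields are written with
#' full double precision, so read after write is the identity on all
#' fields.
#'
#' @param nodes_path,edges_path Paths of the two CSV files (UTF-8, header
#'   row mandatory).
#' @return `read_network()` returns a [vascular_network()];
#'   `write_network()` returns the two paths invisibly.
#' @export
read_network <- function(nodes_path, edges_path) {
  nodes <- utils::read.csv(nodes_path, stringsAsFactors = FALSE)
  edges <- utils::read.csv(edges_path, stringsAsFactors = FALSE)
  vascular_network(nodes, edges)
}

#' @rdname read_network
#' @param net A [vascular_network()].
#' @export
write_network <- function(net, nodes_path, edges_path) {
  fmt <- function(df) {
    for (col in names(df)) {
      if (is.numeric(df[[col]])) {
        out <- rep(NA_character_, length(df[[col]]))
        ok <- !is.na(df[[col]])
        out[ok] <- format(df[[col]][ok], digits = 17, trim = TRUE,
                          scientific = FALSE)
        df[[col]] <- out
      }
    }
    df
  }
  utils::write.csv(fmt(net$nodes), nodes_path, row.names = FALSE, quote = FALSE,
                   na = "")
  utils::write.csv(fmt(net$edges), edges_path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(c(nodes_path, edges_path))
}

#' Read / write an activated-edge list
#'
#' One-column CSV (`edge_id`) naming the activated edges.
#'
#' @param path CSV path.
#' @return `read_edge_set()` returns the vector of edge ids.
#' @export
read_edge_set <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"edge_id" %in% names(df)) stop("activated edge file needs an edge_id column")
  df$edge_id
}

#' @rdname read_edge_set
#' @param edge_ids Vector of edge ids.
#' @export
write_edge_set <- function(edge_ids, path) {
  utils::write.csv(data.frame(edge_id = edge_ids), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
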