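# Independent oracles used across tests. Deliberately naive: plain-R
# breadth-first path walks, quadrature, and double loops, sharing no code
# with the package's engines.

# random tree skeleton: node i >= 2 attaches to a random earlier node
random_tree_skeleton <- function(n, seed, span_nm = 1000,
                                 radius_range = c(0.5, 3)) {
  set.seed(seed)
  parent <- c(NA, vapply(seq_len(n)[-1],
                         function(i) sample.int(i - 1, 1), integer(1)))
  nodes <- data.frame(id = seq_len(n),
                      x = runif(n, 0, span_nm),
                      y = runif(n, 0, span_nm),
                      z = runif(n, 0, span_nm),
                      radius = runif(n, radius_range[1], radius_range[2]))
  neurite_skeleton(nodes, data.frame(from = parent[-1], to = seq_len(n)[-1]))
}

# a straight chain along x with given spacings and radii
chain_skeleton <- function(spacing_nm, radii) {
  n <- length(radii)
  stopifnot(length(spacing_nm) == n - 1)
  nodes <- data.frame(id = seq_len(n), x = c(0, cumsum(spacing_nm)),
                      y = 0, z = 0, radius = radii)
  neurite_skeleton(nodes, data.frame(from = seq_len(n - 1),
                                     to = seq_len(n)[-1]))
}

# node-to-node path as a sequence of edge indices, by BFS parent pointers
oracle_path_edges <- function(skel, from_id, to_id) {
  ids <- skel$nodes$id
  n <- length(ids)
  adj <- vector("list", n)
  for (e in seq_len(nrow(skel$edges))) {
    a <- match(skel$edges$from[e], ids)
    b <- match(skel$edges$to[e], ids)
    adj[[a]] <- rbind(adj[[a]], c(b, e))
    adj[[b]] <- rbind(adj[[b]], c(a, e))
  }
  src <- match(from_id, ids); dst <- match(to_id, ids)
  par_node <- rep(NA_integer_, n); par_edge <- rep(NA_integer_, n)
  visited <- rep(FALSE, n); visited[src] <- TRUE
  queue <- src
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == dst) break
    for (k in seq_len(NROW(adj[[v]]))) {
      w <- adj[[v]][k, 1]
      if (!visited[w]) {
        visited[w] <- TRUE
        par_node[w] <- v; par_edge[w] <- adj[[v]][k, 2]
        queue <- c(queue, w)
      }
    }
  }
  path <- integer(0); v <- dst
  while (v != src) { path <- c(par_edge[v], path); v <- par_node[v] }
  path
}

oracle_node_dist <- function(skel, from_id, to_id,
                             metric = c("real", "electrotonic")) {
  metric <- match.arg(metric)
  if (from_id == to_id) return(0)
  w <- if (metric == "real") skel$edges$length else skel$edges$elen
  sum(w[oracle_path_edges(skel, from_id, to_id)])
}

# partial edge weight from offset x1 to x2 (offsets from the 'from' node)
oracle_partial <- function(skel, e, x1, x2, metric) {
  if (metric == "real") return(abs(x2 - x1))
  ed <- skel$edges[e, ]
  r1 <- skel$nodes$radius[match(ed$from, skel$nodes$id)]
  r2 <- skel$nodes$radius[match(ed$to, skel$nodes$id)]
  quad_cone(ed$length, r1, r2, min(x1, x2), max(x1, x2))
}

# numerical quadrature of the electrotonic integrand over a cone
quad_cone <- function(d, r1, r2, x1 = 0, x2 = d) {
  if (x1 == x2) return(0)
  stats::integrate(function(x) 1 / sqrt((r2 - r1) / d * x + r1),
                   x1, x2, rel.tol = 1e-12, abs.tol = 0)$value
}

# distance between two on-edge locations on a tree: direct if co-edge,
# else best endpoint-to-endpoint combination (the unique tree path)
oracle_location_dist <- function(skel, e1, o1, e2, o2,
                                 metric = c("real", "electrotonic")) {
  metric <- match.arg(metric)
  if (e1 == e2) return(oracle_partial(skel, e1, o1, o2, metric))
  ends <- function(e) c(skel$edges$from[e], skel$edges$to[e])
  len1 <- skel$edges$length[e1]; len2 <- skel$edges$length[e2]
  best <- Inf
  for (u in 1:2) for (v in 1:2) {
    a <- ends(e1)[u]; b <- ends(e2)[v]
    d <- oracle_partial(skel, e1, if (u == 1) 0 else len1, o1, metric) +
      oracle_node_dist(skel, a, b, metric) +
      oracle_partial(skel, e2, if (v == 1) 0 else len2, o2, metric)
    best <- min(best, d)
  }
  best
}

# naive double-loop inhibition sum over synapse pairs
oracle_inhibition <- function(D_nm, source_kc, target_kc, lambda_um) {
  kcs <- sort(unique(c(source_kc, target_kc)))
  s <- matrix(0, length(kcs), length(kcs), dimnames = list(kcs, kcs))
  for (k1 in kcs) for (k2 in kcs) {
    acc <- 0
    for (i in which(source_kc == k1)) for (j in which(target_kc == k2))
      acc <- acc + exp(-D_nm[i, j] / (lambda_um * 1e3))
    s[k1, k2] <- acc
  }
  s
}

# mapped-location data.frame for hand-placed points
manual_locations <- function(skel, edge_index, offset_nm,
                             ids = seq_along(edge_index)) {
  df <- data.frame(synapse_id = ids, edge_index = edge_index,
                   offset_nm = offset_nm)
  attr(df, "skeleton_signature") <- aplspread:::skeleton_signature(skel)
  df
}
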