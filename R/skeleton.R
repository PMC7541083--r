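#' Construct a neurite skeleton
#'
#' A neurite skeleton is a rooted geometric tree: nodes carry 3D positions
#' (nm) and radii (nm), edges carry both their real (Euclidean) length and
#' their electrotonic length, i.e. the length normalized by the square root
#' of the radius, treating each edge as a truncated cone between its
#' endpoint radii.
#'
#' Radii that are missing or non-positive are clamped to the smallest
#' positive radius present (SWC exports often contain sentinel radii, and
#' the electrotonic form is undefined at zero radius). Loading fails with a
#' diagnostic if the graph is not a single connected tree.
#'
#' @param nodes data.frame with columns \code{id}, \code{x}, \code{y},
#'   \code{z}, \code{radius} (all positions/radii in nm after scaling).
#' @param edges data.frame with columns \code{from}, \code{to} (node ids).
#' @param unit_scale nm per input coordinate unit already applied (kept as
#'   metadata; 8 for hemibrain pixels).
#' @return An object of class \code{neurite_skeleton}: list with
#'   \code{nodes}, \code{edges} (with \code{length} and \code{elen} in nm
#'   and nm^(1/2)), \code{graph} (igraph, vertex names = node ids) and
#'   \code{unit_scale}.
#' @export
neurite_skeleton <- function(nodes, edges, unit_scale = 1) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  need <- c("id", "x", "y", "z", "radius")
  if (!all(need %in% names(nodes)))
    stop("nodes must have columns: ", paste(need, collapse = ", "))
  if (!all(c("from", "to") %in% names(edges)))
    stop("edges must have columns: from, to")
  if (anyDuplicated(nodes$id))
    stop("duplicated node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  nodes$radius <- clamp_radii(nodes$radius)

  bad_ref <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(bad_ref))
    stop("edges reference absent nodes: ", paste(bad_ref, collapse = ", "))

  idx_from <- match(edges$from, nodes$id)
  idx_to <- match(edges$to, nodes$id)
  dx <- nodes$x[idx_to] - nodes$x[idx_from]
  dy <- nodes$y[idx_to] - nodes$y[idx_from]
  dz <- nodes$z[idx_to] - nodes$z[idx_from]
  edges$length <- sqrt(dx^2 + dy^2 + dz^2)
  edges$elen <- segment_electrotonic_length(edges$length,
                                            nodes$radius[idx_from],
                                            nodes$radius[idx_to])

  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$from), to = as.character(edges$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$id)))
  comps <- igraph::components(g)
  if (comps$no > 1)
    stop("skeleton is not connected: ", comps$no, " components (sizes ",
         paste(comps$csize, collapse = ", "), ")")
  if (igraph::ecount(g) != igraph::vcount(g) - 1)
    stop("skeleton contains cycles: ", igraph::ecount(g), " edges for ",
         igraph::vcount(g), " nodes")

  structure(list(nodes = nodes, edges = edges, graph = g,
                 unit_scale = unit_scale),
            class = "neurite_skeleton")
}

clamp_radii <- function(r) {
  r[!is.finite(r)] <- NA_real_
  pos <- r[!is.na(r) & r > 0]
  if (!length(pos)) stop("no positive radius present; cannot clamp")
  r[is.na(r) | r <= 0] <- min(pos)
  r
}

#' @export
print.neurite_skeleton <- function(x, ...) {
  tot <- skeleton_totals(x)
  cat("neurite_skeleton:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat(sprintf("  total length %.6g m; electrotonic %.6g m^1/2; ratio %.6g m^1/2\n",
              tot$real_m, tot$electrotonic_m12, tot$ratio_m12))
  invisible(x)
}

#' Read an SWC skeleton file
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent; '#' comments).
#' Coordinates and radii are multiplied by \code{unit_scale} to obtain nm.
#'
#' @param path file path.
#' @param unit_scale nm per coordinate unit in the file (use 8 for hemibrain
#'   pixel coordinates; 1000 for files in um).
#' @return \code{\link{neurite_skeleton}}.
#' @export
read_swc <- function(path, unit_scale = 1) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"),
                           colClasses = c("integer", "integer", "numeric",
                                          "numeric", "numeric", "numeric",
                                          "integer"))
  if (!nrow(tab)) stop("SWC file is empty: ", path)
  missing_parent <- tab$parent != -1 & !(tab$parent %in% tab$id)
  if (any(missing_parent))
    stop("SWC nodes reference absent parents: node(s) ",
         paste(tab$id[missing_parent], collapse = ", "))
  roots <- sum(tab$parent == -1)
  if (roots != 1)
    stop("SWC must have exactly one root (parent -1); found ", roots)
  nodes <- data.frame(id = tab$id,
                      x = tab$x * unit_scale,
                      y = tab$y * unit_scale,
                      z = tab$z * unit_scale,
                      radius = tab$radius * unit_scale)
  child <- tab$id[tab$parent != -1]
  parent <- tab$parent[tab$parent != -1]
  neurite_skeleton(nodes, data.frame(from = parent, to = child),
                   unit_scale = unit_scale)
}

#' Write a skeleton as SWC
#'
#' Inverse of \code{\link{read_swc}}: coordinates are divided by
#' \code{unit_scale}. The tree is re-rooted at the lowest node id.
#'
#' @param skel a \code{neurite_skeleton}.
#' @param path output path.
#' @param unit_scale nm per output coordinate unit.
#' @export
write_swc <- function(skel, path, unit_scale = skel$unit_scale) {
  stopifnot(inherits(skel, "neurite_skeleton"))
  root <- as.character(min(skel$nodes$id))
  # parent of each vertex in a BFS tree from the root
  bfs <- igraph::bfs(skel$graph, root = root, father = TRUE)
  vn <- igraph::V(skel$graph)$name
  father <- as.integer(bfs$father)
  parent_id <- ifelse(is.na(father), -1L, as.integer(vn[father]))
  ord <- match(as.character(skel$nodes$id), vn)
  out <- data.frame(id = skel$nodes$id, type = 0L,
                    x = skel$nodes$x / unit_scale,
                    y = skel$nodes$y / unit_scale,
                    z = skel$nodes$z / unit_scale,
                    radius = skel$nodes$radius / unit_scale,
                    parent = parent_id[ord])
  out <- out[order(out$id), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con)
  utils::write.table(format(out, trim = TRUE, digits = 15), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Electrotonic length of a truncated-cone segment
#'
#' For a segment of length \code{d} whose radius tapers linearly from
#' \code{r1} to \code{r2}, the electrotonic length is
#' \code{integral(0,d) dx / sqrt(r(x))} = \code{2*d*(sqrt(r2)-sqrt(r1))/(r2-r1)},
#' reducing to the cylinder form \code{d/sqrt(r1)} as \code{r2 -> r1}.
#' Vectorized over all arguments.
#'
#' @param d segment length (nm), >= 0.
#' @param r1,r2 endpoint radii (nm), > 0.
#' @return electrotonic length in nm^(1/2) units.
#' @export
segment_electrotonic_length <- function(d, r1, r2) {
  partial_electrotonic_distance(d, r1, r2, 0, d)
}

#' Electrotonic distance between two points on one truncated cone
#'
#' Positions \code{x1 <= x2} are measured from the end with radius
#' \code{r1}. Equals \code{\link{segment_electrotonic_length}} when
#' \code{(x1, x2) = (0, d)}.
#'
#' @inheritParams segment_electrotonic_length
#' @param x1,x2 positions along the segment (nm), \code{0 <= x1 <= x2 <= d}.
#' @export
partial_electrotonic_distance <- function(d, r1, r2, x1, x2) {
  n <- max(length(d), length(r1), length(r2), length(x1), length(x2))
  d <- rep_len(d, n); r1 <- rep_len(r1, n); r2 <- rep_len(r2, n)
  x1 <- rep_len(x1, n); x2 <- rep_len(x2, n)
  if (any(d < 0)) stop("segment length must be >= 0")
  if (any(r1 <= 0) || any(r2 <= 0)) stop("radii must be > 0")
  if (any(x1 < -1e-9 | x2 > d + 1e-9 | x1 > x2 + 1e-9))
    stop("positions must satisfy 0 <= x1 <= x2 <= d")
  x1 <- pmin(pmax(x1, 0), d); x2 <- pmin(pmax(x2, 0), d)
  out <- numeric(n)
  # relative taper below epsilon: cylinder form (continuous switch)
  cyl <- d == 0 | abs(r2 - r1) <= 1e-12 * pmax(r1, r2)
  out[cyl] <- (x2[cyl] - x1[cyl]) / sqrt(r1[cyl])
  cn <- !cyl
  if (any(cn)) {
    a <- (r2[cn] - r1[cn]) / d[cn]
    out[cn] <- 2 * d[cn] *
      (sqrt(a * x2[cn] + r1[cn]) - sqrt(a * x1[cn] + r1[cn])) /
      (r2[cn] - r1[cn])
  }
  out
}

#' Whole-skeleton length totals and the lambda/k conversion ratio
#'
#' Sums per-edge real and electrotonic lengths. The ratio (total real length
#' over total electrotonic length, in m^(1/2)) converts between the space
#' constant in real space (lambda) and in electrotonic space (k):
#' lambda = k * ratio.
#'
#' @param skel a \code{neurite_skeleton}.
#' @return list with \code{real_m}, \code{electrotonic_m12},
#'   \code{ratio_m12}, and the nm-scale totals \code{real_nm},
#'   \code{electrotonic_nm12}.
#' @export
skeleton_totals <- function(skel) {
  stopifnot(inherits(skel, "neurite_skeleton"))
  real_nm <- sum(skel$edges$length)
  elec_nm12 <- sum(skel$edges$elen)
  real_m <- real_nm / .NM_PER_M
  elec_m12 <- elec_nm12 * .ELECTROTONIC_NM_TO_M12
  list(real_m = real_m, electrotonic_m12 = elec_m12,
       ratio_m12 = real_m / elec_m12,
       real_nm = real_nm, electrotonic_nm12 = elec_nm12)
}
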