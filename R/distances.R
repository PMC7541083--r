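#' Exact along-skeleton distances between mapped synapse sets
#'
#' Builds an augmented graph in which every mapped location splits its host
#' edge at its offset, then runs multi-source Dijkstra
#' (\code{igraph::distances}) so that within-edge offsets are respected
#' exactly. On a tree the shortest path is the unique path.
#'
#' @param skel a \code{\link{neurite_skeleton}}.
#' @param sources,targets mapped synapse data.frames from
#'   \code{\link{map_synapses}} on this skeleton.
#' @param metric \code{"real"} (nm) or \code{"electrotonic"} (nm^(1/2);
#'   each edge treated as a truncated cone, partial offsets included).
#' @return numeric matrix (sources x targets) with \code{dimnames} from
#'   \code{synapse_id} and attributes \code{metric} and \code{units}.
#' @export
pairwise_distances <- function(skel, sources, targets,
                               metric = c("real", "electrotonic")) {
  metric <- match.arg(metric)
  stopifnot(inherits(skel, "neurite_skeleton"))
  check_mapped_to(skel, sources)
  check_mapped_to(skel, targets)

  loc <- unique(rbind(sources[, c("edge_index", "offset_nm")],
                      targets[, c("edge_index", "offset_nm")]))
  rownames(loc) <- NULL
  loc$vertex <- paste0("p", seq_len(nrow(loc)))

  g <- augment_graph(skel, loc, metric)
  loc_key <- paste(loc$edge_index, loc$offset_nm)
  sv <- loc$vertex[match(paste(sources$edge_index, sources$offset_nm),
                         loc_key)]
  tv <- loc$vertex[match(paste(targets$edge_index, targets$offset_nm),
                         loc_key)]
  su <- unique(sv); tu <- unique(tv)
  Du <- igraph::distances(g, v = su, to = tu, algorithm = "dijkstra")
  D <- Du[match(sv, su), match(tv, tu), drop = FALSE]
  dimnames(D) <- list(as.character(sources$synapse_id),
                      as.character(targets$synapse_id))
  attr(D, "metric") <- metric
  attr(D, "units") <- if (metric == "real") "nm" else "nm^1/2"
  D
}

# Build the synapse-augmented weighted graph. loc: data.frame
# (edge_index, offset_nm, vertex).
augment_graph <- function(skel, loc, metric) {
  ed <- skel$edges
  nd <- skel$nodes
  ia <- match(ed$from, nd$id)
  ib <- match(ed$to, nd$id)
  from <- character(0); to <- character(0); w <- numeric(0)
  by_edge <- split(seq_len(nrow(loc)), loc$edge_index)
  plain <- setdiff(seq_len(nrow(ed)), as.integer(names(by_edge)))
  if (length(plain)) {
    from <- paste0("n", ed$from[plain])
    to <- paste0("n", ed$to[plain])
    w <- if (metric == "real") ed$length[plain] else ed$elen[plain]
  }
  for (nm in names(by_edge)) {
    e <- as.integer(nm)
    idx <- by_edge[[nm]]
    ord <- order(loc$offset_nm[idx])
    offs <- loc$offset_nm[idx][ord]
    verts <- c(paste0("n", ed$from[e]), loc$vertex[idx][ord],
               paste0("n", ed$to[e]))
    brk <- c(0, offs, ed$length[e])
    wseg <- if (metric == "real") diff(brk) else
      partial_electrotonic_distance(ed$length[e], nd$radius[ia[e]],
                                    nd$radius[ib[e]],
                                    brk[-length(brk)], brk[-1])
    from <- c(from, verts[-length(verts)])
    to <- c(to, verts[-1])
    w <- c(w, wseg)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to),
    directed = FALSE,
    vertices = data.frame(name = c(paste0("n", nd$id), loc$vertex)))
  igraph::E(g)$weight <- w
  g
}

#' 3D positions of mapped locations
#'
#' Interpolates each mapped (edge, offset) location back to coordinates.
#'
#' @param skel a \code{neurite_skeleton}.
#' @param mapped mapped synapse data.frame.
#' @return matrix (n x 3) of positions in nm.
#' @export
location_positions <- function(skel, mapped) {
  check_mapped_to(skel, mapped)
  ed <- skel$edges[mapped$edge_index, ]
  ia <- match(ed$from, skel$nodes$id)
  ib <- match(ed$to, skel$nodes$id)
  t <- ifelse(ed$length > 0, mapped$offset_nm / ed$length, 0)
  A <- cbind(skel$nodes$x[ia], skel$nodes$y[ia], skel$nodes$z[ia])
  B <- cbind(skel$nodes$x[ib], skel$nodes$y[ib], skel$nodes$z[ib])
  A + t * (B - A)
}

#' Distances under alternative spatial conventions
#'
#' Three conventions for the distance that attenuates signal between two
#' locations: along the skeleton in electrotonic space (truncated-cone,
#' radius-normalized; use with the electrotonic space constant k), along
#' the skeleton in real space (equivalent to treating all neurites as
#' having the same radius; use with lambda), or along the 1D backbone after
#' projecting each location to its nearest backbone position.
#'
#' @param skel a \code{neurite_skeleton}.
#' @param sources,targets mapped synapse data.frames.
#' @param mode one of \code{"skeleton_electrotonic"},
#'   \code{"skeleton_real_uniform_radius"}, \code{"backbone"}.
#' @param backbone a \code{\link{build_backbone}} object (required for
#'   backbone mode); its coordinates are um, skeleton coordinates nm.
#' @return distance matrix as in \code{\link{pairwise_distances}}; backbone
#'   mode returns nm with attribute \code{metric = "backbone"}.
#' @export
distance_mode <- function(skel, sources, targets,
                          mode = c("skeleton_electrotonic",
                                   "skeleton_real_uniform_radius",
                                   "backbone"),
                          backbone = NULL) {
  mode <- match.arg(mode)
  if (mode == "skeleton_electrotonic")
    return(pairwise_distances(skel, sources, targets, "electrotonic"))
  if (mode == "skeleton_real_uniform_radius")
    return(pairwise_distances(skel, sources, targets, "real"))
  if (is.null(backbone)) stop("backbone mode requires a backbone")
  ps <- location_positions(skel, sources) / .NM_PER_UM
  pt <- location_positions(skel, targets) / .NM_PER_UM
  as_ <- project_to_backbone(backbone, ps)
  at_ <- project_to_backbone(backbone, pt)
  D <- backbone_arc_distance(as_, at_) * .NM_PER_UM
  dimnames(D) <- list(as.character(sources$synapse_id),
                      as.character(targets$synapse_id))
  attr(D, "metric") <- "backbone"
  attr(D, "units") <- "nm"
  D
}
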