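#' Generate a toy mushroom-body skeleton
#'
#' Builds a Y-shaped neurite skeleton emulating the gross geometry of the
#' mushroom body: a peduncle/calyx branch and vertical and horizontal lobe
#' branches joined at one junction, each carrying parallel neurite chains
#' with heterogeneous radii. Matching backbone key points are returned so
#' volumetric and backbone-projection code can run on the same geometry.
#' Deterministic under a fixed seed.
#'
#' @param branch_lengths_um named lengths (um) of the three branches. The
#'   defaults put the vertical-lobe tip ~260 um from the dorsal calyx in
#'   the distance-from-calyx coordinate.
#' @param n_neurites parallel neurite chains per branch.
#' @param node_spacing_um node spacing along each chain.
#' @param radius_mean_um log-normal radius location (neurites average
#'   ~0.5 um in diameter).
#' @param radius_sdlog log-normal sd of radii.
#' @param radius_max_um clamp for the largest radii (diameters up to ~3 um
#'   occur but are rare).
#' @param neurite_offset_um perpendicular spacing between parallel chains.
#' @param seed integer seed.
#' @return object of class \code{toy_mushroom_body}: \code{skeleton}
#'   (\code{\link{neurite_skeleton}}, nm), \code{key_points} (um),
#'   \code{backbone}, \code{routes} (per neurite: ordered node ids from
#'   calyx tip to a lobe tip with cumulative arc um), \code{params}.
#' @export
make_toy_skeleton <- function(branch_lengths_um = c(vertical = 100,
                                                    horizontal = 90,
                                                    pedcalyx = 160),
                              n_neurites = 2, node_spacing_um = 5,
                              radius_mean_um = 0.25, radius_sdlog = 0.4,
                              radius_max_um = 1.5,
                              neurite_offset_um = 1.5, seed = 1) {
  need <- c("vertical", "horizontal", "pedcalyx")
  if (!all(need %in% names(branch_lengths_um)))
    stop("branch_lengths_um must name: ", paste(need, collapse = ", "))
  if (any(branch_lengths_um <= 0)) stop("branch lengths must be positive")
  dirs <- list(vertical = c(0, 0, 1), horizontal = c(1, 0, 0),
               pedcalyx = c(0, 1, 0))
  perp <- list(vertical = c(1, 0, 0), horizontal = c(0, 0, 1),
               pedcalyx = c(1, 0, 0))

  res <- with_seed(seed, {
    nodes <- data.frame(id = 1L, x = 0, y = 0, z = 0, radius = 1)  # junction (um)
    edges <- data.frame(from = integer(0), to = integer(0))
    branch_of_edge <- character(0)
    chains <- list()  # [[branch]][[k]] = node ids junction -> tip
    next_id <- 2L
    for (nm in need) {
      L <- branch_lengths_um[[nm]]
      s <- seq(node_spacing_um, L, by = node_spacing_um)
      if (max(s) < L) s <- c(s, L)
      chains[[nm]] <- vector("list", n_neurites)
      for (k in seq_len(n_neurites)) {
        off <- (k - (n_neurites + 1) / 2) * neurite_offset_um
        P <- outer(s, dirs[[nm]]) +
          matrix(perp[[nm]] * off, length(s), 3, byrow = TRUE)
        r <- pmin(pmax(stats::rlnorm(length(s), log(radius_mean_um),
                                     radius_sdlog), 0.05), radius_max_um)
        ids <- next_id:(next_id + length(s) - 1L)
        next_id <- next_id + length(s)
        nodes <- rbind(nodes, data.frame(id = ids, x = P[, 1], y = P[, 2],
                                         z = P[, 3], radius = r))
        edges <- rbind(edges, data.frame(from = c(1L, ids[-length(ids)]),
                                         to = ids))
        branch_of_edge <- c(branch_of_edge, rep(nm, length(ids)))
        chains[[nm]][[k]] <- c(1L, ids)
      }
    }
    list(nodes = nodes, edges = edges, branch_of_edge = branch_of_edge,
         chains = chains)
  })

  nodes_nm <- res$nodes
  nodes_nm[c("x", "y", "z", "radius")] <-
    nodes_nm[c("x", "y", "z", "radius")] * .NM_PER_UM
  skel <- neurite_skeleton(nodes_nm, res$edges, unit_scale = .NM_PER_UM)

  key_points <- list(
    vertical = rbind(c(0, 0, 0),
                     dirs$vertical * branch_lengths_um[["vertical"]]),
    horizontal = rbind(c(0, 0, 0),
                       dirs$horizontal * branch_lengths_um[["horizontal"]]),
    pedcalyx = rbind(c(0, 0, 0),
                     dirs$pedcalyx * branch_lengths_um[["pedcalyx"]]))
  backbone <- build_backbone(key_points, calyx_branch = "pedcalyx")

  # one route per (lobe, neurite): calyx tip -> junction -> lobe tip
  routes <- list()
  for (lobe in c("vertical", "horizontal")) {
    for (k in seq_len(length(res$chains$pedcalyx))) {
      ids <- c(rev(res$chains$pedcalyx[[k]][-1]), res$chains[[lobe]][[k]])
      P <- as.matrix(skel$nodes[match(ids, skel$nodes$id),
                                c("x", "y", "z")]) / .NM_PER_UM
      arc <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
      routes[[length(routes) + 1]] <-
        list(lobe = lobe, neurite = k, nodes = ids, arc_um = arc)
    }
  }
  structure(list(skeleton = skel, key_points = key_points,
                 backbone = backbone, routes = routes,
                 branch_of_edge = res$branch_of_edge,
                 params = list(branch_lengths_um = branch_lengths_um,
                               n_neurites = n_neurites,
                               node_spacing_um = node_spacing_um,
                               seed = seed)),
            class = "toy_mushroom_body")
}

# position (nm) at arc position a (um) along a route; small perpendicular
# jitter keeps synapses off the exact skeleton line
route_position <- function(skel, route, a_um, jitter_um = 0.05) {
  a <- pmin(pmax(a_um, 0), max(route$arc_um))
  i <- pmin(findInterval(a, route$arc_um, rightmost.closed = TRUE),
            length(route$nodes) - 1)
  P <- as.matrix(skel$nodes[match(route$nodes, skel$nodes$id),
                            c("x", "y", "z")])
  t <- (a - route$arc_um[i]) / (route$arc_um[i + 1] - route$arc_um[i])
  pos <- P[i, , drop = FALSE] + t * (P[i + 1, , drop = FALSE] -
                                       P[i, , drop = FALSE])
  pos + matrix(stats::rnorm(length(a) * 3, 0, jitter_um * .NM_PER_UM),
               ncol = 3)
}

#' Generate spatially clustered reciprocal synapses for synthetic KCs
#'
#' Each Kenyon cell is given an anchor position on one neurite route; its
#' input (APL->KC) and output (KC->APL) synapses are placed at
#' along-skeleton displacements from the anchor drawn from a normal of
#' scale sigma truncated to the route extent. Small sigma co-locates a KC's synapses, producing
#' disproportionate self-inhibition; shuffling identities destroys it.
#' Ground-truth assignments are returned.
#'
#' @param toy a \code{\link{make_toy_skeleton}} object.
#' @param n_kc number of Kenyon cells.
#' @param n_in,n_out APL->KC and KC->APL synapses per KC (defaults near
#'   the observed per-KC means of ~50).
#' @param sigma_um along-skeleton clustering scale.
#' @param subtype_props named proportions of subtypes.
#' @param calyx_um extent of the calyx region from the dorsal calyx tip
#'   (for region labels).
#' @param seed integer seed.
#' @param routes which neurite routes KCs may occupy (indices into
#'   \code{toy$routes}); restrict to one route to study mixing limits.
#' @return list: \code{synapses} (data.frame in
#'   \code{\link{read_synapse_table}} layout, positions nm),
#'   \code{truth} (per-KC anchor, route, subtype).
#' @export
make_synthetic_synapses <- function(toy, n_kc = 20, n_in = 50, n_out = 50,
                                    sigma_um = 10,
                                    subtype_props = c(gamma = 0.35,
                                                      alphabeta = 0.45,
                                                      alphapbetap = 0.20),
                                    calyx_um = 40, seed = 1,
                                    routes = seq_along(toy$routes)) {
  stopifnot(inherits(toy, "toy_mushroom_body"))
  if (sigma_um <= 0) stop("sigma_um must be positive")
  if (n_in < 1 || n_out < 1) stop("each KC needs >= 1 synapse per direction")
  skel <- toy$skeleton
  L_ped <- toy$params$branch_lengths_um[["pedcalyx"]]
  n_sub <- round(subtype_props / sum(subtype_props) * n_kc)
  while (sum(n_sub) < n_kc) n_sub[1] <- n_sub[1] + 1
  while (sum(n_sub) > n_kc) n_sub[which.max(n_sub)] <-
    n_sub[which.max(n_sub)] - 1
  subtype <- rep(names(n_sub), n_sub)

  with_seed(seed, {
    kc_id <- sprintf("KC%03d", seq_len(n_kc))
    route_idx <- routes[sample.int(length(routes), n_kc, replace = TRUE)]
    rows <- vector("list", n_kc)
    anchors <- numeric(n_kc)
    sid <- 0L
    for (i in seq_len(n_kc)) {
      route <- toy$routes[[route_idx[i]]]
      Lr <- max(route$arc_um)
      anchors[i] <- stats::runif(1, 0.1 * Lr, 0.9 * Lr)
      n_syn <- n_in + n_out
      # truncated normal via inverse CDF: no probability mass piles up at
      # the route ends, and sigma >> route length tends to uniform
      plo <- stats::pnorm((0 - anchors[i]) / sigma_um)
      phi <- stats::pnorm((Lr - anchors[i]) / sigma_um)
      a <- anchors[i] + sigma_um *
        stats::qnorm(stats::runif(n_syn, plo, phi))
      pos <- route_position(skel, route, a)
      region <- ifelse(a < calyx_um, "CA(R)",
                       ifelse(a < L_ped, "PED(R)",
                              ifelse(route$lobe == "vertical",
                                     "aL(R)", "hL(R)")))
      rows[[i]] <- data.frame(
        synapse_id = sid + seq_len(n_syn),
        direction = rep(c("APL_to_KC", "KC_to_APL"), c(n_in, n_out)),
        kc_id = kc_id[i],
        x = pos[, 1], y = pos[, 2], z = pos[, 3],
        region = region,
        confidence = stats::runif(n_syn, 0.7, 1))
      sid <- sid + n_syn
    }
    list(synapses = do.call(rbind, rows),
         truth = data.frame(kc_id = kc_id, subtype = subtype,
                            route = route_idx, anchor_arc_um = anchors))
  })
}

#' Generate a synthetic dye/stimulus profile
#'
#' Per-segment values A * exp(-|x - x0|/ell) plus Gaussian noise along the
#' backbone coordinate, emulating the co-ejected red-dye profile used to
#' define the stimulus extent.
#'
#' @param segments data.frame with \code{segment}, \code{branch},
#'   \code{distance_um}.
#' @param ejection_segment segment id of the ejection site.
#' @param amplitude peak amplitude A.
#' @param ell_um decay length (a half-strength distance of 10-25 um
#'   corresponds to ell of about 14-36 um).
#' @param noise_sd additive Gaussian noise SD.
#' @param seed integer seed.
#' @return the input data.frame with a \code{value} column.
#' @export
make_dye_profile <- function(segments, ejection_segment, amplitude = 1,
                             ell_um = 30, noise_sd = 0, seed = 1) {
  if (ell_um <= 0) stop("ell_um must be positive")
  ej <- segments$segment == ejection_segment
  if (!any(ej)) stop("ejection segment not in table")
  x0 <- mean(segments$distance_um[ej])
  out <- segments
  out$value <- amplitude * exp(-abs(segments$distance_um - x0) / ell_um)
  if (noise_sd > 0)
    out$value <- out$value +
      with_seed(seed, stats::rnorm(nrow(out), 0, noise_sd))
  out
}

shift_array3 <- function(a, o, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- lapply(1:3, function(i) max(1, 1 - o[i]):min(d[i], d[i] - o[i]))
  dst <- lapply(1:3, function(i) src[[i]] + o[i])
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Generate a synthetic volumetric movie with known dF/F
#'
#' Voxel fluorescence is background + F0 * (1 + dF/F of the voxel's node
#' at time t) + Gaussian noise; voxels outside the mask sit at background.
#' An optional integer shift translates the volume, for testing
#' \code{\link{align_recordings}}. With zero noise and shift,
#' \code{\link{compute_dff}} recovers the truth exactly.
#'
#' @param seg a \code{\link{assign_voxels}} segment map defining node
#'   geometry.
#' @param dff_truth matrix (nodes x T) of ground-truth dF/F curves.
#' @param f0 baseline fluorescence above background (must be positive).
#' @param background background fluorescence.
#' @param noise_sd Gaussian noise SD.
#' @param shift integer (z, y, x) translation applied to the volume.
#' @param seed integer seed.
#' @return list: \code{movie} (T, Z, Y, X), \code{mask}, \code{labels}
#'   (shifted), \code{dff_truth}, \code{f0}, \code{background},
#'   \code{shift}.
#' @export
make_synthetic_movie <- function(seg, dff_truth, f0 = 100, background = 50,
                                 noise_sd = 0, shift = c(0, 0, 0),
                                 seed = 1) {
  stopifnot(inherits(seg, "segment_map"))
  if (f0 <= 0) stop("f0 must be positive")
  if (nrow(dff_truth) != nrow(seg$nodes))
    stop("dff_truth must have one row per node")
  labels <- shift_array3(seg$labels, as.integer(shift), fill = 0L)
  d <- dim(labels)
  nt <- ncol(dff_truth)
  movie <- array(background, c(nt, d))
  inmask <- which(labels != 0)
  lab <- labels[inmask]
  for (t in seq_len(nt)) {
    vol <- array(background, d)
    vol[inmask] <- background + f0 * (1 + dff_truth[lab, t])
    movie[t, , , ] <- vol
  }
  if (noise_sd > 0)
    movie <- movie + with_seed(seed,
      array(stats::rnorm(length(movie), 0, noise_sd), dim(movie)))
  list(movie = movie, mask = labels != 0, labels = labels,
       dff_truth = dff_truth, f0 = f0, background = background,
       shift = as.integer(shift))
}
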