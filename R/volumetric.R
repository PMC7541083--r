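#' Build a mushroom-body backbone skeleton
#'
#' The backbone is a polyline graph of three branches (vertical lobe,
#' horizontal lobe, peduncle/calyx) meeting at one junction, used as the 1D
#' coordinate along which volumetric signals are quantified. Each branch is
#' given as an ordered matrix of key points (um); every branch must start
#' at the shared junction point.
#'
#' @param key_points named list of three (or more) n x 3 matrices in um;
#'   first row of each = the junction.
#' @param calyx_branch name of the branch whose far end is the dorsal
#'   calyx; distance-from-calyx coordinates are measured from that
#'   endpoint.
#' @return object of class \code{backbone}: per-branch polylines with
#'   cumulative arc lengths, branch lengths, junction, calyx branch.
#' @export
build_backbone <- function(key_points, calyx_branch = "pedcalyx") {
  if (is.null(names(key_points)) || any(!nzchar(names(key_points))))
    stop("key_points must be a named list of branches")
  if (!calyx_branch %in% names(key_points))
    stop("calyx_branch '", calyx_branch, "' not among branches")
  junction <- key_points[[1]][1, ]
  branches <- lapply(names(key_points), function(nm) {
    P <- as.matrix(key_points[[nm]])
    if (nrow(P) < 2 || ncol(P) != 3)
      stop("branch '", nm, "' needs >= 2 points with 3 coordinates")
    if (sqrt(sum((P[1, ] - junction)^2)) > 1e-6)
      stop("branch '", nm, "' does not start at the shared junction")
    seg <- sqrt(rowSums((P[-1, , drop = FALSE] -
                           P[-nrow(P), , drop = FALSE])^2))
    if (any(seg <= 0)) stop("branch '", nm, "' has a zero-length segment")
    list(points = P, cumlen = c(0, cumsum(seg)), length = sum(seg))
  })
  names(branches) <- names(key_points)
  structure(list(branches = branches, junction = junction,
                 calyx_branch = calyx_branch),
            class = "backbone")
}

#' @export
print.backbone <- function(x, ...) {
  cat("backbone:", length(x$branches), "branches; lengths (um):",
      paste(sprintf("%s=%.1f", names(x$branches),
                    vapply(x$branches, `[[`, numeric(1), "length")),
            collapse = ", "), "\n")
  invisible(x)
}

# interpolate the point at arc position s (from the junction) on a branch
point_at_arc <- function(branch, s) {
  s <- pmin(pmax(s, 0), branch$length)
  i <- findInterval(s, branch$cumlen, rightmost.closed = TRUE)
  i <- pmin(i, nrow(branch$points) - 1)
  t <- (s - branch$cumlen[i]) / (branch$cumlen[i + 1] - branch$cumlen[i])
  branch$points[i, , drop = FALSE] +
    t * (branch$points[i + 1, , drop = FALSE] -
           branch$points[i, , drop = FALSE])
}

#' Evenly spaced backbone nodes
#'
#' Places nodes every \code{spacing_um} along each branch, starting at the
#' junction (shared junction node emitted once, for the first branch).
#'
#' @param backbone a \code{\link{build_backbone}} object.
#' @param spacing_um node spacing in um (20 for across-fly comparisons, 10
#'   for higher-resolution analyses).
#' @return data.frame: \code{node}, \code{branch}, \code{arc_um} (from the
#'   junction), \code{dist_from_calyx_um}, \code{x}, \code{y}, \code{z}.
#' @export
backbone_nodes <- function(backbone, spacing_um = 20) {
  stopifnot(inherits(backbone, "backbone"), spacing_um > 0)
  Lcal <- backbone$branches[[backbone$calyx_branch]]$length
  out <- NULL
  first <- TRUE
  for (nm in names(backbone$branches)) {
    br <- backbone$branches[[nm]]
    s <- seq(0, br$length, by = spacing_um)
    if (!first) s <- s[-1]  # junction node emitted once
    first <- FALSE
    P <- do.call(rbind, lapply(s, function(si) point_at_arc(br, si)))
    dc <- if (nm == backbone$calyx_branch) Lcal - s else Lcal + s
    out <- rbind(out, data.frame(branch = nm, arc_um = s,
                                 dist_from_calyx_um = dc,
                                 x = P[, 1], y = P[, 2], z = P[, 3]))
  }
  out$node <- seq_len(nrow(out))
  out[, c("node", "branch", "arc_um", "dist_from_calyx_um",
          "x", "y", "z")]
}

#' Project points onto the backbone
#'
#' Each point is assigned its nearest position on any branch polyline
#' (perpendicular foot, clamped), giving a branch label and an arc
#' coordinate from the junction.
#'
#' @param backbone a \code{backbone}.
#' @param points n x 3 matrix (um).
#' @return data.frame \code{branch}, \code{arc_um}, \code{residual_um}.
#' @export
project_to_backbone <- function(backbone, points) {
  points <- matrix(points, ncol = 3)
  n <- nrow(points)
  branch <- character(n); arc <- numeric(n); resid <- rep(Inf, n)
  for (nm in names(backbone$branches)) {
    br <- backbone$branches[[nm]]
    P <- br$points
    for (i in seq_len(nrow(P) - 1)) {
      A <- P[i, ]; B <- P[i + 1, ]
      AB <- B - A
      len2 <- sum(AB^2)
      t <- ((points[, 1] - A[1]) * AB[1] + (points[, 2] - A[2]) * AB[2] +
              (points[, 3] - A[3]) * AB[3]) / len2
      t <- pmin(pmax(t, 0), 1)
      dx <- A[1] + t * AB[1] - points[, 1]
      dy <- A[2] + t * AB[2] - points[, 2]
      dz <- A[3] + t * AB[3] - points[, 3]
      d <- sqrt(dx^2 + dy^2 + dz^2)
      better <- d < resid
      resid[better] <- d[better]
      branch[better] <- nm
      arc[better] <- br$cumlen[i] + t[better] * sqrt(len2)
    }
  }
  data.frame(branch = branch, arc_um = arc, residual_um = resid)
}

# along-backbone distance between projected positions: same branch ->
# |arc difference|; different branches -> via the junction (a + b)
backbone_arc_distance <- function(pa, pb) {
  D <- outer(pa$arc_um, pb$arc_um, `+`)
  same <- outer(pa$branch, pb$branch, `==`)
  D[same] <- abs(outer(pa$arc_um, pb$arc_um, `-`))[same]
  D
}

#' Standardize backbones across recordings
#'
#' The standard backbone takes the arithmetic mean length of each branch
#' across recordings. Each individual backbone is mapped onto it by
#' placing its nodes at spacing x * spacing_um, where x is the ratio of
#' the individual branch length to the standard branch length, so node i
#' of every recording sits at standard arc i * spacing_um.
#'
#' @param backbones list of \code{backbone} objects with identical branch
#'   topology.
#' @param spacing_um base node spacing on the standard backbone.
#' @return list: \code{branch_lengths} (standard, um), \code{standard} (a
#'   straight-branch \code{backbone} with the standard lengths, oriented
#'   like the first input), \code{nodes} (standard node table), and
#'   \code{placements} (per recording: branch, index, individual arc_um,
#'   standard arc_um, scale x).
#' @export
standardize_backbones <- function(backbones, spacing_um = 20) {
  stopifnot(length(backbones) >= 1)
  nms <- names(backbones[[1]]$branches)
  for (b in backbones)
    if (!identical(names(b$branches), nms))
      stop("backbones have mismatched branch topology")
  L <- sapply(backbones, function(b)
    vapply(b$branches, `[[`, numeric(1), "length"))
  L <- matrix(L, nrow = length(nms), dimnames = list(nms, NULL))
  std_len <- rowMeans(L)

  # standard geometry: straight branches from the junction of the first
  # backbone, along each branch's end-to-end direction, at the mean length
  b1 <- backbones[[1]]
  kp <- lapply(nms, function(nm) {
    br <- b1$branches[[nm]]
    v <- br$points[nrow(br$points), ] - br$points[1, ]
    v <- v / sqrt(sum(v^2))
    rbind(b1$junction, b1$junction + v * std_len[[nm]])
  })
  names(kp) <- nms
  standard <- build_backbone(kp, calyx_branch = b1$calyx_branch)

  placements <- lapply(seq_along(backbones), function(r) {
    do.call(rbind, lapply(nms, function(nm) {
      x <- unname(L[nm, r]) / std_len[[nm]]
      idx <- 0:floor(std_len[[nm]] / spacing_um)
      data.frame(recording = r, branch = nm, index = idx,
                 arc_um = idx * x * spacing_um,
                 standard_arc_um = idx * spacing_um, scale = x)
    }))
  })
  list(branch_lengths = std_len, standard = standard,
       spacing_um = spacing_um,
       nodes = backbone_nodes(standard, spacing_um),
       placements = placements)
}

#' Voronoi assignment of voxels to backbone nodes
#'
#' Labels every in-mask voxel with its nearest node in physical (um)
#' coordinates, honoring anisotropic voxel size. Ties go to the lower node
#' index. Voxel indices are 0-based with physical positions at voxel
#' centers: axis coordinate = (index0 + 0.5) * voxel size.
#'
#' @param mask 3D array (Z, Y, X); nonzero = inside the mushroom body.
#' @param nodes data.frame with \code{x}, \code{y}, \code{z} (um), e.g.
#'   from \code{\link{backbone_nodes}}.
#' @param voxel_size_um physical voxel size, named or ordered (z, y, x).
#' @return object of class \code{segment_map}: \code{labels} (integer
#'   array, 0 outside mask), \code{nodes}, \code{counts} (voxels per
#'   node), \code{voxel_size_um}.
#' @export
assign_voxels <- function(mask, nodes, voxel_size_um = c(1, 1, 1)) {
  stopifnot(length(dim(mask)) == 3, length(voxel_size_um) == 3)
  idx <- which(mask != 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("mask is empty")
  cz <- (idx[, 1] - 0.5) * voxel_size_um[1]
  cy <- (idx[, 2] - 0.5) * voxel_size_um[2]
  cx <- (idx[, 3] - 0.5) * voxel_size_um[3]
  best <- rep.int(1L, nrow(idx))
  bestd <- (cx - nodes$x[1])^2 + (cy - nodes$y[1])^2 + (cz - nodes$z[1])^2
  for (j in seq_len(nrow(nodes))[-1]) {
    d <- (cx - nodes$x[j])^2 + (cy - nodes$y[j])^2 + (cz - nodes$z[j])^2
    closer <- d < bestd        # strict: ties keep the lower node index
    best[closer] <- j
    bestd[closer] <- d[closer]
  }
  labels <- array(0L, dim(mask))
  labels[mask != 0] <- best
  counts <- tabulate(best, nbins = nrow(nodes))
  structure(list(labels = labels, nodes = nodes, counts = counts,
                 voxel_size_um = voxel_size_um),
            class = "segment_map")
}

#' Per-node dF/F time series from a volumetric movie
#'
#' For each backbone node, fluorescence is averaged over the node's
#' Voronoi voxels at each frame; the background is subtracted; the
#' baseline F0 is the mean over the pre-stimulus frames; and
#' dF/F = (F - F0) / (F0 - background). Nodes with F0 <= background are
#' set to NaN with a warning.
#'
#' @param movie 4D array (T, Z, Y, X).
#' @param seg a \code{\link{assign_voxels}} segment map on the movie's
#'   spatial grid.
#' @param background scalar background fluorescence (e.g. mean of an empty
#'   ROI).
#' @param prestim_frames integer frame indices of the pre-stimulus period.
#' @param channel \code{"green"} or \code{"red"} (used by the exclusion
#'   rule).
#' @param frame_time_s frame interval in seconds (optional metadata).
#' @return object of class \code{dff_profile}: \code{dff} (nodes x T),
#'   \code{f} (raw node means), \code{f0}, plus metadata.
#' @export
compute_dff <- function(movie, seg, background = 0, prestim_frames,
                        channel = c("green", "red"), frame_time_s = NULL) {
  channel <- match.arg(channel)
  stopifnot(inherits(seg, "segment_map"), length(dim(movie)) == 4)
  if (!identical(dim(movie)[-1], dim(seg$labels)))
    stop("movie spatial dimensions do not match the segment map")
  if (!length(prestim_frames) || any(prestim_frames < 1) ||
      any(prestim_frames > dim(movie)[1]))
    stop("prestim_frames must be a non-empty set of valid frame indices")
  inmask <- which(seg$labels != 0)
  lab <- seg$labels[inmask]
  nt <- dim(movie)[1]
  nn <- nrow(seg$nodes)
  f <- matrix(NA_real_, nn, nt)
  labf <- factor(lab, levels = seq_len(nn))
  for (t in seq_len(nt)) {
    vol <- movie[t, , , ]
    means <- tapply(vol[inmask], labf, mean)
    f[, t] <- as.numeric(means)
  }
  f0 <- rowMeans(f[, prestim_frames, drop = FALSE])
  denom <- f0 - background
  bad <- !is.na(denom) & denom <= 0
  if (any(bad))
    warning(sum(bad), " node(s) with F0 <= background set to NaN")
  dff <- (f - f0) / denom
  dff[bad, ] <- NaN
  structure(list(dff = dff, f = f, f0 = f0, background = background,
                 prestim_frames = prestim_frames, channel = channel,
                 frame_time_s = frame_time_s, nodes = seg$nodes,
                 smoothing = "none"),
            class = "dff_profile")
}

#' Boxcar smoothing and temporal interpolation of dF/F traces
#'
#' Boxcar smoothing (5 frames, or the number of frames closest to 1 s) is
#' applied only for displaying traces or finding peak responses; averages
#' over stimulus windows are always computed from unsmoothed data. Linear
#' interpolation resamples traces to a common frame time (0.2 s default)
#' for across-recording averaging.
#'
#' @param profile a \code{\link{compute_dff}} profile.
#' @param mode \code{"none"}, \code{"trace_boxcar_5frames"} or
#'   \code{"trace_boxcar_1s"}.
#' @param frame_time_s frame interval (defaults to the profile's); required
#'   for \code{"trace_boxcar_1s"} or interpolation.
#' @param frame_time_out_s if non-NULL, interpolate to this frame time.
#' @return a \code{dff_profile} with smoothed / resampled \code{dff}.
#' @export
smooth_and_interpolate <- function(profile,
                                   mode = c("none", "trace_boxcar_5frames",
                                            "trace_boxcar_1s"),
                                   frame_time_s = profile$frame_time_s,
                                   frame_time_out_s = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "dff_profile"))
  x <- profile$dff
  if (mode != "none") {
    width <- if (mode == "trace_boxcar_5frames") 5L else {
      if (is.null(frame_time_s)) stop("frame interval required for 1 s boxcar")
      max(1L, round(1 / frame_time_s))
    }
    x <- t(apply(x, 1, boxcar, width = width))
  }
  if (!is.null(frame_time_out_s)) {
    if (is.null(frame_time_s))
      stop("frame interval required for interpolation")
    t_in <- (seq_len(ncol(x)) - 1) * frame_time_s
    t_out <- seq(0, max(t_in), by = frame_time_out_s)
    x <- t(apply(x, 1, function(v) {
      if (all(is.na(v))) return(rep(NA_real_, length(t_out)))
      stats::approx(t_in, v, xout = t_out)$y
    }))
    profile$frame_time_s <- frame_time_out_s
  }
  profile$dff <- x
  profile$smoothing <- mode
  profile
}

# centered moving average; edges use the available partial window
boxcar <- function(v, width) {
  if (width <= 1) return(v)
  ok <- !is.na(v)
  num <- stats::filter(ifelse(ok, v, 0), rep(1, width), sides = 2)
  den <- stats::filter(as.numeric(ok), rep(1, width), sides = 2)
  half <- (width - 1) %/% 2
  n <- length(v)
  # stats::filter leaves NAs at the margins; recompute them directly
  for (i in which(is.na(num) | is.na(den))) {
    win <- max(1, i - half):min(n, i + half + (1 - width %% 2))
    num[i] <- sum(v[win], na.rm = TRUE)
    den[i] <- sum(ok[win])
  }
  out <- as.numeric(num) / pmax(as.numeric(den), 1)
  out[den == 0] <- NA_real_
  out
}

#' Exclude noisy nodes
#'
#' Masks (NaN) nodes whose dF/F standard deviation during the pre-stimulus
#' period exceeds the channel threshold: 1.0 for the green channel, 0.7
#' for the red channel. High baseline noise indicates poor signal in that
#' segment.
#'
#' @param profile a \code{dff_profile}.
#' @param thresholds named per-channel SD thresholds.
#' @return the profile with noisy nodes masked and an \code{excluded}
#'   logical vector.
#' @export
exclude_noisy_nodes <- function(profile,
                                thresholds = c(green = 1.0, red = 0.7)) {
  stopifnot(inherits(profile, "dff_profile"))
  thr <- thresholds[[profile$channel]]
  pres <- profile$dff[, profile$prestim_frames, drop = FALSE]
  sds <- apply(pres, 1, stats::sd)
  excl <- !is.na(sds) & sds > thr
  profile$dff[excl, ] <- NaN
  profile$excluded <- excl
  message(sum(excl), " node(s) excluded (prestim SD > ", thr, ", ",
          profile$channel, " channel)")
  profile
}

#' Normalized inhibitory effect
#'
#' Per node: (mean dF/F in the quantification window with drug - mean
#' without) divided by the peak dF/F without drug. Window means use
#' unsmoothed data; the peak is taken from the boxcar-smoothed trace.
#' Normalizing by the peak rather than the window mean is robust when the
#' odor response is low. Nodes whose peak is <= 0 return NaN with a
#' warning.
#'
#' @param odor_only,odor_plus_drug \code{dff_profile}s on the same segment
#'   map (odor alone, and odor with APL stimulation or GABA).
#' @param window_frames frame indices of the quantification window (the
#'   gray-shaded interval of the figures; supplied by the user).
#' @param peak_mode smoothing mode for the peak (see
#'   \code{\link{smooth_and_interpolate}}).
#' @return numeric vector, one effect value per node (negative =
#'   suppression).
#' @export
normalized_inhibitory_effect <- function(odor_only, odor_plus_drug,
                                         window_frames,
                                         peak_mode = "trace_boxcar_5frames") {
  stopifnot(inherits(odor_only, "dff_profile"),
            inherits(odor_plus_drug, "dff_profile"))
  if (nrow(odor_only$dff) != nrow(odor_plus_drug$dff))
    stop("profiles are not on the same segment map")
  if (any(window_frames < 1) || any(window_frames > ncol(odor_only$dff)))
    stop("window_frames out of range")
  m_odor <- rowMeans(odor_only$dff[, window_frames, drop = FALSE])
  m_drug <- rowMeans(odor_plus_drug$dff[, window_frames, drop = FALSE])
  smoothed <- smooth_and_interpolate(odor_only, mode = peak_mode)
  peak <- apply(smoothed$dff, 1, function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  bad <- !is.na(peak) & peak <= 0
  if (any(bad))
    warning(sum(bad), " node(s) with non-positive peak set to NaN")
  eff <- (m_drug - m_odor) / peak
  eff[bad] <- NaN
  eff
}

#' Align recordings by integer translation
#'
#' Finds, for each recording, the integer 3D translation (z, y, x voxels)
#' maximizing the normalized cross-correlation of its time-averaged
#' reference image with the first recording's, searching exhaustively
#' within \code{max_shift} voxels per axis. No subvoxel registration.
#'
#' @param reference_images list of 3D arrays on the same voxel grid.
#' @param max_shift search radius in voxels per axis.
#' @return integer matrix (n recordings x 3); first row is (0, 0, 0).
#' @export
align_recordings <- function(reference_images, max_shift = 10) {
  stopifnot(length(reference_images) >= 1)
  ref <- reference_images[[1]]
  if (stats::sd(ref) == 0) stop("reference image is flat; cannot align")
  dims <- dim(ref)
  offsets <- matrix(0L, length(reference_images), 3)
  shifts <- as.matrix(expand.grid(dz = -max_shift:max_shift,
                                  dy = -max_shift:max_shift,
                                  dx = -max_shift:max_shift))
  for (r in seq_along(reference_images)[-1]) {
    mov <- reference_images[[r]]
    if (!identical(dim(mov), dims)) stop("recordings differ in voxel grid")
    best <- -Inf; best_o <- c(0L, 0L, 0L)
    for (s in seq_len(nrow(shifts))) {
      o <- shifts[s, ]
      rng <- lapply(1:3, function(a)
        max(1, 1 - o[a]):min(dims[a], dims[a] - o[a]))
      if (any(vapply(rng, length, integer(1)) < 2)) next
      a <- ref[rng[[1]], rng[[2]], rng[[3]]]
      b <- mov[rng[[1]] + o[1], rng[[2]] + o[2], rng[[3]] + o[3]]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      cc <- stats::cor(as.numeric(a), as.numeric(b))
      if (cc > best) { best <- cc; best_o <- o }
    }
    offsets[r, ] <- as.integer(best_o)
  }
  colnames(offsets) <- c("dz", "dy", "dx")
  offsets
}
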