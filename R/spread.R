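#' Sample random points on a skeleton
#'
#' Places \code{n} points uniformly by real arc length: edges are drawn
#' with probability proportional to their length, offsets uniformly within
#' the edge. Points landing on excluded edges (e.g. the soma neurite,
#' outside the mushroom body) are flagged rather than dropped.
#'
#' @param skel a \code{\link{neurite_skeleton}}.
#' @param n number of points (the reference analysis uses ~10,000; scale
#'   down for small fixtures).
#' @param seed integer seed.
#' @param excluded_edges integer indices into \code{skel$edges} whose
#'   points are flagged \code{excluded}.
#' @return data.frame with \code{synapse_id} (point id),
#'   \code{edge_index}, \code{offset_nm}, \code{excluded}; carries the
#'   skeleton signature so it can be fed to
#'   \code{\link{pairwise_distances}}.
#' @export
sample_skeleton_points <- function(skel, n = 10000, seed = 1,
                                   excluded_edges = integer(0)) {
  stopifnot(inherits(skel, "neurite_skeleton"))
  if (n <= 0) stop("n must be positive")
  len <- skel$edges$length
  pts <- with_seed(seed, {
    e <- sample.int(nrow(skel$edges), n, replace = TRUE, prob = len)
    data.frame(synapse_id = seq_len(n), edge_index = e,
               offset_nm = stats::runif(n) * len[e])
  })
  pts$excluded <- pts$edge_index %in% excluded_edges
  if (all(pts$excluded)) warning("all sampled points are on excluded edges")
  attr(pts, "skeleton_signature") <- skeleton_signature(skel)
  pts
}

#' Assign points to backbone segments
#'
#' Projects point positions onto the backbone and bins the
#' distance-from-calyx coordinate into segments of \code{spacing_um}.
#'
#' @param backbone a \code{\link{build_backbone}} object (um).
#' @param points_um n x 3 matrix of positions in um (e.g.
#'   \code{\link{location_positions}} / 1000).
#' @param spacing_um segment length along the backbone (10 um in the
#'   skeleton-registered analyses).
#' @return data.frame \code{segment} (1-based bin of distance-from-calyx),
#'   \code{branch}, \code{dist_from_calyx_um}, \code{residual_um}.
#' @export
points_to_segments <- function(backbone, points_um, spacing_um = 10) {
  pr <- project_to_backbone(backbone, points_um)
  Lcal <- backbone$branches[[backbone$calyx_branch]]$length
  dc <- ifelse(pr$branch == backbone$calyx_branch,
               Lcal - pr$arc_um, Lcal + pr$arc_um)
  data.frame(segment = pmax(1L, as.integer(ceiling(dc / spacing_um))),
             branch = pr$branch, dist_from_calyx_um = dc,
             residual_um = pr$residual_um)
}

#' Fit exponential decay curves to a stimulus (dye) profile
#'
#' Fits A * exp(-|x - x0| / ell) per branch to per-segment dye dF/F
#' values, with x the 1D backbone coordinate and x0 the position of the
#' ejection segment. Where a segment appears under more than one branch
#' (a shared trunk traversed by fits from two directions),
#' \code{\link{fitted_stimulus}} averages the branch fits.
#'
#' @param profile data.frame with columns \code{segment}, \code{branch},
#'   \code{distance_um} (1D coordinate, e.g. distance from the dorsal
#'   calyx) and \code{value}.
#' @param ejection_segment segment id where the dye was ejected.
#' @return object of class \code{stimulus_profile}: per-branch
#'   \code{amplitude}, \code{ell_um} fits and \code{x0_um}.
#' @export
fit_stimulus_decay <- function(profile, ejection_segment) {
  need <- c("segment", "branch", "distance_um", "value")
  if (!all(need %in% names(profile)))
    stop("profile needs columns: ", paste(need, collapse = ", "))
  ej <- profile$segment == ejection_segment
  if (!any(ej)) stop("ejection segment ", ejection_segment, " not in profile")
  x0 <- mean(profile$distance_um[ej])
  fits <- list()
  for (br in unique(profile$branch)) {
    rows <- profile[profile$branch == br & is.finite(profile$value), ]
    if (nrow(rows) < 4)
      stop("branch '", br, "': need >= 4 finite segments, have ", nrow(rows))
    x <- abs(rows$distance_um - x0)
    y <- rows$value
    # log-linear start values (floored to keep logs finite)
    pos <- pmax(y, max(y) * 1e-6)
    lmfit <- stats::lm(log(pos) ~ x)
    start <- list(A = exp(stats::coef(lmfit)[[1]]),
                  ell = max(-1 / min(stats::coef(lmfit)[[2]], -1e-12),
                            diff(range(x)) / 10))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-x / ell), start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) stop("branch '", br, "': exponential fit failed (",
                               conditionMessage(e), ")"))
    A <- stats::coef(fit)[["A"]]
    ell <- stats::coef(fit)[["ell"]]
    if (!is.finite(ell) || ell <= 0 || A <= 0)
      stop("branch '", br, "': degenerate fit (A = ", signif(A, 3),
           ", ell = ", signif(ell, 3), ")")
    if (ell > 50 * diff(range(x)))
      stop("branch '", br, "': no decay over the sampled range (ell = ",
           signif(ell, 3), " um); profile is effectively constant")
    fits[[br]] <- list(amplitude = A, ell_um = ell)
  }
  structure(list(fits = fits, x0_um = x0,
                 ejection_segment = ejection_segment),
            class = "stimulus_profile")
}

#' @export
print.stimulus_profile <- function(x, ...) {
  cat("stimulus_profile: ejection at x0 =", format(x$x0_um), "um\n")
  for (nm in names(x$fits))
    cat(sprintf("  %s: A = %.4g, ell = %.4g um\n", nm,
                x$fits[[nm]]$amplitude, x$fits[[nm]]$ell_um))
  invisible(x)
}

#' Evaluate fitted stimulus values
#'
#' Predicts the fitted stimulus for each row of a profile table (branch +
#' 1D coordinate) and averages predictions per segment, so segments listed
#' under several branches get the mean of the overlapping fits.
#'
#' @param sp a \code{\link{fit_stimulus_decay}} object.
#' @param profile data.frame with \code{segment}, \code{branch},
#'   \code{distance_um}.
#' @return data.frame \code{segment}, \code{value}.
#' @export
fitted_stimulus <- function(sp, profile) {
  stopifnot(inherits(sp, "stimulus_profile"))
  pred <- vapply(seq_len(nrow(profile)), function(i) {
    f <- sp$fits[[profile$branch[i]]]
    if (is.null(f)) return(NA_real_)
    f$amplitude * exp(-abs(profile$distance_um[i] - sp$x0_um) / f$ell_um)
  }, numeric(1))
  agg <- stats::aggregate(list(value = pred),
                          list(segment = profile$segment), mean,
                          na.rm = TRUE)
  agg[order(agg$segment), ]
}

#' Simulate activity spread over random skeleton points
#'
#' Given points on the skeleton, a per-point stimulus amplitude, and a
#' space constant, the simulated activity of segment s is the stimulus-
#' weighted count of every pair between points in s and all points:
#' activity(s) = (1/N_s) * sum_{j in s} sum_k stim(p_k) *
#' exp(-d(p_j, p_k)/space constant). With uniform unit stimulus this is
#' the plain weighted pair count. Self-pairs are included (an O(1/N)
#' contribution). Branch-point current division is ignored: decay depends
#' only on shortest-path distance.
#'
#' @param distances point x point matrix from
#'   \code{\link{pairwise_distances}} or \code{\link{distance_mode}} (rows
#'   = receiving points, columns = stimulated points; square for the usual
#'   case).
#' @param segment segment id per row point.
#' @param stimulus per-point stimulus amplitude per column point (e.g. the
#'   fitted dye value at each point's segment), or a single number.
#' @param spec a \code{\link{space_constant}}.
#' @param normalize divide by the maximum segment activity (the
#'   convention used for comparing with measured profiles).
#' @return data.frame \code{segment}, \code{n_points}, \code{activity},
#'   \code{normalized}; empty segments are absent (reported via attribute
#'   \code{segments_missing} when \code{segment} is a factor with unused
#'   levels).
#' @export
simulate_activity <- function(distances, segment, stimulus, spec,
                              normalize = TRUE) {
  stopifnot(nrow(distances) == length(segment))
  stim <- rep_len(stimulus, ncol(distances))
  W <- pair_weight(distances, spec)
  per_point <- as.numeric(W %*% stim)
  f <- if (is.factor(segment)) segment else factor(segment)
  act <- tapply(per_point, f, mean)
  n <- tapply(per_point, f, length)
  present <- !is.na(act)
  out <- data.frame(segment = names(act)[present],
                    n_points = as.integer(n[present]),
                    activity = as.numeric(act[present]))
  out$normalized <- if (normalize) out$activity / max(out$activity) else NA
  if (any(!present))
    attr(out, "segments_missing") <- names(act)[!present]
  out
}
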