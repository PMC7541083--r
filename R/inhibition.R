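#' Specify a space constant
#'
#' Signals decay as exp(-d / space constant). In real space the constant is
#' lambda (um, possibly Inf) applied to real along-skeleton distances; in
#' electrotonic space it is k (m^(1/2)) applied to radius-normalized
#' distances. When the skeleton's conversion ratio is supplied, the other
#' form is filled in via lambda = k * ratio.
#'
#' @param lambda_um space constant in um (may be \code{Inf}: no decay).
#' @param k_m12 electrotonic space constant in m^(1/2).
#' @param conversion_ratio_m12 lambda/k ratio from
#'   \code{\link{skeleton_totals}}.
#' @param mode which metric the weights are computed in; defaults to the
#'   form given directly.
#' @return object of class \code{space_constant}.
#' @export
space_constant <- function(lambda_um = NULL, k_m12 = NULL,
                           conversion_ratio_m12 = NULL,
                           mode = NULL) {
  if (is.null(lambda_um) && is.null(k_m12))
    stop("give lambda_um and/or k_m12")
  if (!is.null(lambda_um) && lambda_um <= 0) stop("lambda must be > 0")
  if (!is.null(k_m12) && k_m12 <= 0) stop("k must be > 0")
  if (!is.null(conversion_ratio_m12)) {
    if (is.null(k_m12) && is.finite(lambda_um))
      k_m12 <- lambda_um * 1e-6 / conversion_ratio_m12
    if (is.null(lambda_um))
      lambda_um <- k_m12 * conversion_ratio_m12 * 1e6
    if (is.infinite(lambda_um)) k_m12 <- Inf
  }
  if (is.null(mode))
    mode <- if (!is.null(k_m12) && is.null(lambda_um)) "electrotonic"
            else if (is.null(k_m12)) "real"
            else if (missing(lambda_um)) "electrotonic" else "real"
  mode <- match.arg(mode, c("real", "electrotonic"))
  if (mode == "electrotonic" && is.null(k_m12))
    stop("electrotonic mode needs k_m12 (directly or via the ratio)")
  structure(list(mode = mode, lambda_um = lambda_um, k_m12 = k_m12,
                 conversion_ratio_m12 = conversion_ratio_m12),
            class = "space_constant")
}

#' @export
print.space_constant <- function(x, ...) {
  cat(sprintf("space_constant (%s): lambda = %s um; k = %s m^1/2\n",
              x$mode,
              if (is.null(x$lambda_um)) "?" else format(x$lambda_um),
              if (is.null(x$k_m12)) "?" else format(x$k_m12)))
  invisible(x)
}

#' Exponential pair weight
#'
#' Weight of a synapse (or point) pair: exp(-d/lambda) for real distances
#' (d in nm), exp(-d_electrotonic/k) for electrotonic distances (d in
#' nm^(1/2)). An infinite space constant gives weight 1 everywhere.
#'
#' @param d distance(s) in the native units of the spec's mode; matrices
#'   from \code{\link{pairwise_distances}} are checked for metric agreement.
#' @param spec a \code{\link{space_constant}}.
#' @return weights in (0, 1], same shape as \code{d}.
#' @export
pair_weight <- function(d, spec) {
  stopifnot(inherits(spec, "space_constant"))
  met <- attr(d, "metric")
  if (!is.null(met) && met %in% c("real", "electrotonic") &&
      met != spec$mode)
    stop("distance metric '", met, "' does not match space constant mode '",
         spec$mode, "'")
  if (any(d < 0)) stop("distances must be >= 0")
  if (spec$mode == "real") {
    if (is.infinite(spec$lambda_um)) return(array(1, dim = dim(d) %||% length(d)))
    w <- exp(-d / (spec$lambda_um * .NM_PER_UM))
  } else {
    if (is.infinite(spec$k_m12)) return(array(1, dim = dim(d) %||% length(d)))
    w <- exp(-(d * .ELECTROTONIC_NM_TO_M12) / spec$k_m12)
  }
  attributes(w) <- attributes(d)[c("dim", "dimnames")]
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inhibition matrix s(k1, k2)
#'
#' s(k1, k2) models how strongly Kenyon cell k1 inhibits Kenyon cell k2 via
#' APL: the sum over every pair of a KC1->APL synapse i and an APL->KC2
#' synapse j of exp(-d(i, j)/space constant), with d the along-skeleton
#' distance. Each synapse record contributes one term even when several
#' records share a skeleton location.
#'
#' @param distances matrix from \code{\link{pairwise_distances}}: rows are
#'   KC->APL (output) synapses, columns APL->KC (input) synapses.
#' @param source_kc,target_kc Kenyon-cell id per row / per column.
#' @param spec a \code{\link{space_constant}}.
#' @param kc_ids optional full roster of Kenyon-cell ids (metadata); every
#'   synapse's kc must appear in it, and KCs with no synapses in a
#'   direction get zero rows/columns rather than being dropped.
#' @param subtype optional named vector (names = kc ids) of subtype labels,
#'   stored as an attribute.
#' @return matrix s (KC1 x KC2) with attributes \code{spec} and
#'   \code{subtype}.
#' @export
compute_inhibition_matrix <- function(distances, source_kc, target_kc,
                                      spec, kc_ids = NULL, subtype = NULL) {
  stopifnot(nrow(distances) == length(source_kc),
            ncol(distances) == length(target_kc))
  if (is.null(kc_ids)) {
    kc_ids <- sort(unique(c(as.character(source_kc),
                            as.character(target_kc))))
  } else {
    kc_ids <- as.character(kc_ids)
    bad <- setdiff(unique(c(as.character(source_kc),
                            as.character(target_kc))), kc_ids)
    if (length(bad))
      stop("kc_id(s) absent from metadata: ", paste(bad, collapse = ", "))
  }
  W <- pair_weight(distances, spec)
  fs <- factor(as.character(source_kc), levels = kc_ids)
  ft <- factor(as.character(target_kc), levels = kc_ids)
  # sum rows by KC1
  s1 <- matrix(0, length(kc_ids), ncol(W))
  agg <- rowsum(W, fs)
  s1[match(rownames(agg), kc_ids), ] <- agg
  # sum columns by KC2
  s <- matrix(0, length(kc_ids), length(kc_ids),
              dimnames = list(kc_ids, kc_ids))
  agg2 <- rowsum(t(s1), ft)
  s[, match(rownames(agg2), kc_ids)] <- t(agg2)
  attr(s, "spec") <- spec
  if (!is.null(subtype)) attr(s, "subtype") <- subtype[kc_ids]
  s
}

#' Self- versus lateral-inhibition imbalance
#'
#' For each Kenyon cell k1, the ratio of self-inhibition s(k1, k1) to the
#' arithmetic mean of s(k1, k2) over the other Kenyon cells k2 != k1 (all
#' of them, or only those of the same subtype). A ratio above 1 means the
#' cell inhibits itself disproportionately.
#'
#' @param s inhibition matrix from \code{\link{compute_inhibition_matrix}}.
#' @param grouping \code{"all"} or \code{"same_subtype"}.
#' @param subtype named subtype label per KC (defaults to the matrix
#'   attribute); required for \code{"same_subtype"}.
#' @return list of class \code{imbalance_summary}: \code{ratios}
#'   data.frame (kc, subtype, ratio), \code{median}, \code{q25},
#'   \code{q75}, \code{n_excluded} (KCs dropped for a singleton group or a
#'   non-finite ratio).
#' @export
self_other_ratio <- function(s, grouping = c("all", "same_subtype"),
                             subtype = attr(s, "subtype")) {
  grouping <- match.arg(grouping)
  kc <- rownames(s)
  n <- length(kc)
  if (n < 2) stop("need at least 2 KCs")
  if (grouping == "same_subtype" && is.null(subtype))
    stop("same_subtype grouping needs subtype labels")
  ratio <- rep(NA_real_, n)
  excluded <- logical(n)
  for (i in seq_len(n)) {
    others <- if (grouping == "all") setdiff(seq_len(n), i)
              else setdiff(which(subtype == subtype[i]), i)
    if (!length(others)) { excluded[i] <- TRUE; next }
    ratio[i] <- s[i, i] / mean(s[i, others])
  }
  bad <- !excluded & !is.finite(ratio)
  if (any(excluded))
    warning(sum(excluded), " KC(s) excluded: singleton group")
  excluded <- excluded | bad
  ratio[excluded] <- NA_real_
  keep <- ratio[!excluded]
  structure(list(
    ratios = data.frame(kc = kc,
                        subtype = if (is.null(subtype)) NA else
                          as.character(subtype),
                        ratio = ratio, stringsAsFactors = FALSE),
    grouping = grouping,
    median = stats::median(keep),
    q25 = unname(stats::quantile(keep, 0.25)),
    q75 = unname(stats::quantile(keep, 0.75)),
    n_excluded = sum(excluded)), class = "imbalance_summary")
}

#' @export
print.imbalance_summary <- function(x, ...) {
  cat(sprintf(
    "self/other inhibition ratio (%s): median %.3f [IQR %.3f-%.3f], n = %d (%d excluded)\n",
    x$grouping, x$median, x$q25, x$q75,
    sum(!is.na(x$ratios$ratio)), x$n_excluded))
  invisible(x)
}

#' Display ordering of Kenyon cells
#'
#' Groups KCs by subtype (subtypes in order of first appearance) and
#' orders within each subtype by average-linkage agglomerative clustering
#' on correlation distance between matrix rows, so similar KCs sit next to
#' each other. Display-only: no analysis depends on this order. Subtypes
#' stay contiguous; degenerate groups (fewer than 3 members, or identical
#' rows) keep their input order.
#'
#' @param s inhibition matrix.
#' @param subtype subtype label per KC (defaults to matrix attribute).
#' @return character vector of KC ids in display order.
#' @export
order_kcs_for_display <- function(s, subtype = attr(s, "subtype")) {
  kc <- rownames(s)
  if (is.null(subtype)) subtype <- rep("all", length(kc))
  out <- character(0)
  for (st in unique(as.character(subtype))) {
    members <- which(as.character(subtype) == st)
    if (length(members) < 3) { out <- c(out, kc[members]); next }
    rows <- s[members, , drop = FALSE]
    sds <- apply(rows, 1, stats::sd)
    d <- if (any(sds == 0)) stats::dist(rows)
         else stats::as.dist(1 - stats::cor(t(rows)))
    if (all(d < .Machine$double.eps^0.5)) {
      out <- c(out, kc[members])
    } else {
      hc <- stats::hclust(d, method = "average")
      out <- c(out, kc[members][hc$order])
    }
  }
  out
}
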