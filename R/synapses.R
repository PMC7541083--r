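#' Read a synapse table
#'
#' CSV with header columns \code{synapse_id, direction, kc_id, x, y, z,
#' region, confidence}. Direction must be \code{KC_to_APL} (Kenyon cell
#' output onto APL) or \code{APL_to_KC} (APL output onto a Kenyon cell).
#' Rows with a missing coordinate are rejected with a warning; an unknown
#' direction token is an error. No confidence threshold is applied.
#'
#' @param path CSV path.
#' @param unit_scale nm per coordinate unit in the file (8 for hemibrain
#'   pixels).
#' @return data.frame of synapse records with positions in nm.
#' @export
read_synapse_table <- function(path, unit_scale = 1) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("synapse_id", "direction", "kc_id", "x", "y", "z",
            "region", "confidence")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("synapse table lacks columns: ", paste(miss, collapse = ", "))
  if (!nrow(tab)) return(tab[, need])
  bad_dir <- setdiff(unique(tab$direction), c("KC_to_APL", "APL_to_KC"))
  if (length(bad_dir))
    stop("unknown direction token(s): ", paste(bad_dir, collapse = ", "))
  incomplete <- !stats::complete.cases(tab[, c("x", "y", "z")])
  if (any(incomplete)) {
    warning(sum(incomplete), " row(s) with missing coordinates rejected")
    tab <- tab[!incomplete, ]
  }
  tab$x <- tab$x * unit_scale
  tab$y <- tab$y * unit_scale
  tab$z <- tab$z * unit_scale
  tab[, need]
}

#' Map synapses onto the nearest point of a skeleton
#'
#' Each synapse is assigned the nearest point on any skeleton edge (the
#' perpendicular foot, clamped to the segment). Ties are broken by the
#' lowest edge in canonical order (sorted endpoint ids), so a synapse
#' equidistant from two nodes maps to the lowest node id. The mapping is
#' deterministic given the skeleton and records.
#'
#' @param skel a \code{\link{neurite_skeleton}}.
#' @param synapses data.frame of synapse records (see
#'   \code{\link{read_synapse_table}}), positions in nm.
#' @param warn_distance_nm warn when a Euclidean mapping residual exceeds
#'   this (default Inf: never).
#' @return the input data.frame plus \code{edge_index} (row of
#'   \code{skel$edges}), \code{offset_nm} (distance along the edge from its
#'   \code{from} endpoint) and \code{mapping_distance_nm}. Attribute
#'   \code{skeleton_signature} ties the mapping to its skeleton.
#' @export
map_synapses <- function(skel, synapses, warn_distance_nm = Inf) {
  stopifnot(inherits(skel, "neurite_skeleton"))
  ed <- skel$edges
  nd <- skel$nodes
  ia <- match(ed$from, nd$id)
  ib <- match(ed$to, nd$id)
  A <- cbind(nd$x[ia], nd$y[ia], nd$z[ia])
  D <- cbind(nd$x[ib], nd$y[ib], nd$z[ib]) - A
  len2 <- pmax(rowSums(D^2), .Machine$double.eps)
  key1 <- pmin(ed$from, ed$to)
  key2 <- pmax(ed$from, ed$to)

  n <- nrow(synapses)
  edge_index <- integer(n)
  offset <- numeric(n)
  resid <- numeric(n)
  for (s in seq_len(n)) {
    p <- c(synapses$x[s], synapses$y[s], synapses$z[s])
    t <- ((p[1] - A[, 1]) * D[, 1] + (p[2] - A[, 2]) * D[, 2] +
            (p[3] - A[, 3]) * D[, 3]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- A[, 1] + t * D[, 1] - p[1]
    dy <- A[, 2] + t * D[, 2] - p[2]
    dz <- A[, 3] + t * D[, 3] - p[3]
    d2 <- dx^2 + dy^2 + dz^2
    m <- min(d2)
    cand <- which(d2 <= m + 1e-9 * (1 + m))
    best <- cand[order(key1[cand], key2[cand])[1]]
    edge_index[s] <- best
    offset[s] <- t[best] * ed$length[best]
    resid[s] <- sqrt(d2[best])
  }
  if (is.finite(warn_distance_nm) && any(resid > warn_distance_nm))
    warning(sum(resid > warn_distance_nm),
            " synapse(s) mapped farther than ", warn_distance_nm, " nm")
  out <- synapses
  out$edge_index <- edge_index
  out$offset_nm <- offset
  out$mapping_distance_nm <- resid
  attr(out, "skeleton_signature") <- skeleton_signature(skel)
  out
}

skeleton_signature <- function(skel) {
  c(nrow(skel$nodes), nrow(skel$edges), sum(skel$edges$length))
}

check_mapped_to <- function(skel, mapped) {
  sig <- attr(mapped, "skeleton_signature")
  if (is.null(sig) || !isTRUE(all.equal(sig, skeleton_signature(skel))))
    stop("synapses were not mapped onto this skeleton")
}

#' Count unique mapped skeleton locations per direction
#'
#' Several synapse records can share one skeleton location (APL presynaptic
#' densities are polyadic); each record still contributes one term to the
#' inhibition sum, but unique-location counts are reported separately.
#'
#' @param mapped output of \code{\link{map_synapses}}.
#' @return named integer vector of unique (edge, offset) locations per
#'   direction.
#' @export
count_unique_locations <- function(mapped) {
  loc <- paste(mapped$edge_index, signif(mapped$offset_nm, 12))
  vapply(split(loc, mapped$direction), function(v) length(unique(v)),
         integer(1))
}

#' Filter synapses by region
#'
#' The built-in \code{"calyx"} rule keeps, among APL->KC synapses, those
#' with y below a threshold (hemibrain convention: y < 20000 pixels =
#' 160 um, i.e. posterior to the peduncle) and not annotated in the PED(R)
#' ROI; KC->APL synapses pass unchanged. Alternatively supply a predicate
#' function taking the data.frame and returning a logical vector.
#'
#' @param synapses synapse data.frame (mapped or not).
#' @param rule \code{"calyx"} or a predicate function.
#' @param y_max_nm y threshold in nm for the calyx rule (default 160 um).
#' @param excluded_region region label excluded by the calyx rule.
#' @return the filtered data.frame (attributes preserved).
#' @export
filter_synapses <- function(synapses, rule = "calyx",
                            y_max_nm = 20000 * .NM_PER_HEMIBRAIN_PIXEL,
                            excluded_region = "PED(R)") {
  if (is.function(rule)) {
    keep <- rule(synapses)
    if (!is.logical(keep) || length(keep) != nrow(synapses))
      stop("predicate must return one logical per row")
    keep[is.na(keep)] <- FALSE
  } else if (identical(rule, "calyx")) {
    if (!all(c("direction", "y", "region") %in% names(synapses)))
      stop("calyx rule needs columns direction, y, region")
    apl_kc <- synapses$direction == "APL_to_KC"
    keep <- !apl_kc |
      (synapses$y < y_max_nm & synapses$region != excluded_region)
  } else stop("unknown rule: ", rule)
  out <- synapses[keep, , drop = FALSE]
  attr(out, "skeleton_signature") <- attr(synapses, "skeleton_signature")
  out
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Shuffle Kenyon-cell identities of synapses
#'
#' Permutes the \code{kc_id} labels uniformly at random within each
#' direction independently, leaving locations untouched. The per-direction
#' multiset of labels is preserved. This is the null model in which the
#' spatial relation between a Kenyon cell's input and output synapses is
#' destroyed.
#'
#' @param synapses synapse data.frame.
#' @param seed integer seed (required; the shuffle is reproducible).
#' @param directions which directions to shuffle.
#' @return data.frame with permuted \code{kc_id}.
#' @export
shuffle_synapse_identities <- function(synapses, seed,
                                       directions = c("KC_to_APL",
                                                      "APL_to_KC")) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  out <- synapses
  with_seed(seed, {
    for (dir in directions) {
      idx <- which(out$direction == dir)
      if (length(idx) > 1)
        out$kc_id[idx] <- out$kc_id[idx][sample.int(length(idx))]
    }
  })
  attr(out, "skeleton_signature") <- attr(synapses, "skeleton_signature")
  out
}
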