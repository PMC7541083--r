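#' Aggregate transcript-level TPM to gene x cell-type means
#'
#' TPM values are summed across splice variants for each gene, log10 is
#' taken with zeros mapped to log10 of a floor (default 0.01, i.e. -2,
#' below the smallest nonzero TPM in the reference dataset), and the
#' arithmetic mean of log10(TPM) is taken across biological replicates per
#' cell type (equivalently, the geometric mean of TPM).
#'
#' @param tpm numeric matrix, transcripts x columns, TPM >= 0.
#' @param gene_id gene identifier per transcript row.
#' @param cell_type cell-type label per column (replicates share a label).
#' @param tpm_floor value substituted for zero TPM before log10.
#' @return matrix genes x cell types of mean log10(TPM).
#' @export
aggregate_gene_expression <- function(tpm, gene_id, cell_type,
                                      tpm_floor = 0.01) {
  tpm <- as.matrix(tpm)
  stopifnot(nrow(tpm) == length(gene_id), ncol(tpm) == length(cell_type))
  if (any(tpm < 0)) stop("negative TPM values")
  gene_tpm <- rowsum(tpm, group = as.character(gene_id))
  lg <- log10(pmax(gene_tpm, tpm_floor))
  ct <- factor(cell_type)
  means <- t(rowsum(t(lg), ct) / as.numeric(table(ct)))
  colnames(means) <- levels(ct)
  means
}

#' Screen for genes at the focal cell type's extremes
#'
#' Returns genes whose focal-type mean log10(TPM) is strictly higher (or
#' lower) than every other cell type's. Ties fail the strict comparison.
#'
#' @param mat gene x cell-type matrix from
#'   \code{\link{aggregate_gene_expression}}.
#' @param focal focal cell-type column name (e.g. \code{"APL"}).
#' @param direction \code{"higher"} or \code{"lower"}.
#' @return list: \code{genes} (character), \code{count}.
#' @export
screen_apl_extremes <- function(mat, focal = "APL",
                                direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  if (!focal %in% colnames(mat))
    stop("focal column '", focal, "' missing")
  if (ncol(mat) < 2) stop("need at least 2 cell types")
  others <- mat[, setdiff(colnames(mat), focal), drop = FALSE]
  hit <- if (direction == "higher")
    mat[, focal] > apply(others, 1, max)
  else
    mat[, focal] < apply(others, 1, min)
  list(genes = rownames(mat)[hit], count = sum(hit))
}

#' Drop genes with low expression outside the focal type
#'
#' Keeps genes whose mean TPM across the non-focal cell types is at least
#' \code{threshold}. The mean is computed on the TPM scale from the
#' per-type geometric means (10^mean log10 TPM).
#'
#' @param mat gene x cell-type matrix of mean log10(TPM).
#' @param genes gene subset to filter (default all).
#' @param focal focal cell type excluded from the mean.
#' @param threshold minimum mean TPM (default 1).
#' @return character vector of retained genes.
#' @export
filter_low_expression <- function(mat, genes = rownames(mat),
                                  focal = "APL", threshold = 1) {
  if (threshold < 0) stop("threshold must be >= 0")
  others <- setdiff(colnames(mat), focal)
  mean_tpm <- rowMeans(10^mat[genes, others, drop = FALSE])
  genes[mean_tpm >= threshold]
}
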