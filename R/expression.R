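#' RPKM: reads per kilobase of gene per million mapped reads
#'
#' RPKM = numReads / (geneLength/1000 * totalNumReads/1,000,000).
#' Vectorized over genes.
#'
#' @param num_reads reads assigned to the gene (>= 0).
#' @param gene_length gene length in bp (> 0).
#' @param total_num_reads total mapped reads in the library (> 0).
#' @return numeric vector of RPKM values.
#' @export
rpkm <- function(num_reads, gene_length, total_num_reads) {
  if (any(gene_length <= 0)) stop("gene_length must be positive")
  if (any(total_num_reads <= 0)) stop("total_num_reads must be positive")
  if (any(num_reads < 0)) stop("num_reads must be non-negative")
  num_reads / (gene_length / 1000 * total_num_reads / 1e6)
}

#' Fold-change screen on RPKM values
#'
#' Flags genes whose condition/control RPKM ratio is strictly greater
#' than `fold` (default 3, the milk-vs-laboratory-medium upregulation
#' screen). Replicate matrices are reduced to per-gene means by default;
#' `mode = "per_replicate"` instead requires every replicate pair to pass.
#' Genes with control RPKM 0 but condition RPKM > 0 are included and
#' flagged infinite; genes at 0 in both conditions are excluded.
#'
#' @param condition named numeric vector (or genes x replicates matrix)
#'   of RPKM under the condition of interest.
#' @param control RPKM under the control; same genes (and replicate count
#'   in `per_replicate` mode).
#' @param fold ratio threshold, strict (default 3).
#' @param mode `"mean"` (default) or `"per_replicate"`.
#' @return data.frame: `gene_id`, `rpkm_condition`, `rpkm_control`
#'   (means), `fold_change` (Inf when control is 0), `infinite`, `pass`.
#' @export
fold_screen <- function(condition, control, fold = 3,
                        mode = c("mean", "per_replicate")) {
  mode <- match.arg(mode)
  cond <- if (is.matrix(condition)) condition else as.matrix(condition)
  ctrl <- if (is.matrix(control)) control else as.matrix(control)
  if (is.null(rownames(cond)) || is.null(rownames(ctrl)))
    stop("condition and control must carry gene names")
  if (!identical(sort(rownames(cond)), sort(rownames(ctrl))))
    stop("condition and control gene sets differ")
  ctrl <- ctrl[rownames(cond), , drop = FALSE]
  if (any(cond < 0) || any(ctrl < 0)) stop("RPKM values must be >= 0")

  ratio1 <- function(x, y) ifelse(y > 0, x / y, ifelse(x > 0, Inf, NaN))
  if (mode == "mean") {
    mc <- rowMeans(cond); mk <- rowMeans(ctrl)
    fc <- ratio1(mc, mk)
    pass <- !is.nan(fc) & fc > fold
  } else {
    if (ncol(cond) != ncol(ctrl))
      stop("per_replicate mode needs equal replicate counts")
    fcs <- ratio1(cond, ctrl)
    pass <- apply(fcs, 1, function(r) all(!is.nan(r) & r > fold))
    mc <- rowMeans(cond); mk <- rowMeans(ctrl)
    fc <- ratio1(mc, mk)
  }
  out <- data.frame(gene_id = rownames(cond),
                    rpkm_condition = as.numeric(rowMeans(cond)),
                    rpkm_control = as.numeric(rowMeans(ctrl)),
                    fold_change = as.numeric(fc),
                    infinite = is.infinite(fc),
                    pass = as.logical(pass), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Expression screen from a gene read-count table
#'
#' Computes per-condition RPKM from raw counts and library sizes, then
#' applies [fold_screen()].
#'
#' @param counts data.frame with columns `gene_id`, `length_bp`,
#'   `reads_condition`, `reads_control`.
#' @param total_condition,total_control library sizes; default = column
#'   sums of the respective count columns.
#' @param fold ratio threshold (default 3).
#' @return the [fold_screen()] data.frame with RPKM columns.
#' @export
expression_screen <- function(counts, total_condition = NULL,
                              total_control = NULL, fold = 3) {
  stopifnot(all(c("gene_id", "length_bp", "reads_condition",
                  "reads_control") %in% names(counts)))
  if (is.null(total_condition)) total_condition <- sum(counts$reads_condition)
  if (is.null(total_control)) total_control <- sum(counts$reads_control)
  cond <- setNames(rpkm(counts$reads_condition, counts$length_bp,
                        total_condition), counts$gene_id)
  ctrl <- setNames(rpkm(counts$reads_control, counts$length_bp,
                        total_control), counts$gene_id)
  fold_screen(cond, ctrl, fold = fold)
}
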