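#' Phenotypic impact factor of target genes
#'
#' For each target gene i with group mean log2 expression e1 (low) and
#' e2 (high), \code{PIF_i = 0.5 (e1 + e2) (e1 - e2)}: the group
#' difference weighted by abundance. Swapping group labels negates PIF.
#'
#' @param logexpr genes x samples log2 matrix.
#' @param meta sample metadata (needs \code{sample} and \code{sire}).
#' @param targets character vector of target genes.
#' @return data frame with gene, \code{e1}, \code{e2} and \code{pif}.
#' @export
compute_pif <- function(logexpr, meta, targets = rownames(logexpr)) {
  meta <- meta[match(colnames(logexpr), meta$sample), , drop = FALSE]
  if (anyNA(meta$sample)) stop("meta does not cover every sample")
  lo <- meta$sire == "low"; hi <- meta$sire == "high"
  if (sum(lo) < 3 || sum(hi) < 3)
    stop("need >= 3 samples in each sire group")
  missing <- setdiff(targets, rownames(logexpr))
  if (length(missing)) stop("unknown target(s): ",
                            paste(head(missing, 5), collapse = ", "))
  e1 <- rowMeans(logexpr[targets, lo, drop = FALSE])
  e2 <- rowMeans(logexpr[targets, hi, drop = FALSE])
  data.frame(gene = targets, e1 = unname(e1), e2 = unname(e2),
             pif = unname(0.5 * (e1 + e2) * (e1 - e2)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Regulatory impact factor scores for transcription factors
#'
#' Scores each TF against a target set (typically the union of DE and TS
#' genes) by combining target abundance, target differential expression
#' and differential TF-target co-expression between sire groups:
#' \deqn{RIF1_j = (1/n_t) \sum_i PIF_i (r1_{ij} - r2_{ij})^2}
#' \deqn{RIF2_j = (1/n_t) \sum_i [(e1_i r1_{ij})^2 - (e2_i r2_{ij})^2]}
#' where r1 and r2 are TF-target Pearson correlations computed across the
#' samples of the low and high group respectively (tissues pooled). Raw
#' scores are z-standardised across scored TFs. TFs with zero variance
#' within a group are skipped with a warning.
#'
#' @param logexpr genes x samples log2 matrix.
#' @param meta sample metadata.
#' @param tf_list character vector of TF gene ids.
#' @param targets character vector of target gene ids.
#' @return data frame with tf, \code{mean_expr}, \code{rif1},
#'   \code{rif2}, \code{z_rif1}, \code{z_rif2}.
#' @export
compute_rif <- function(logexpr, meta, tf_list, targets) {
  meta <- meta[match(colnames(logexpr), meta$sample), , drop = FALSE]
  if (anyNA(meta$sample)) stop("meta does not cover every sample")
  lo <- meta$sire == "low"; hi <- meta$sire == "high"
  if (sum(lo) < 3 || sum(hi) < 3)
    stop("need >= 3 samples in each sire group")
  tf_list <- intersect(tf_list, rownames(logexpr))
  targets <- setdiff(intersect(targets, rownames(logexpr)), tf_list)
  if (length(tf_list) == 0) stop("no TFs present in the expression matrix")
  if (length(targets) == 0) stop("no targets present")

  drop_tf <- vapply(tf_list, function(g)
    var(logexpr[g, lo]) == 0 || var(logexpr[g, hi]) == 0, logical(1))
  if (any(drop_tf)) {
    warning("skipping ", sum(drop_tf),
            " TF(s) with zero within-group variance")
    tf_list <- tf_list[!drop_tf]
    if (length(tf_list) == 0) stop("no scorable TFs remain")
  }
  keep_t <- vapply(targets, function(g)
    var(logexpr[g, lo]) > 0 && var(logexpr[g, hi]) > 0, logical(1))
  targets <- targets[keep_t]
  if (length(targets) == 0) stop("no targets with within-group variance")

  pif <- compute_pif(logexpr, meta, targets)
  r1 <- cor(t(logexpr[targets, lo, drop = FALSE]),
            t(logexpr[tf_list, lo, drop = FALSE]))
  r2 <- cor(t(logexpr[targets, hi, drop = FALSE]),
            t(logexpr[tf_list, hi, drop = FALSE]))

  rif1 <- colMeans(pif$pif * (r1 - r2)^2)
  rif2 <- colMeans((pif$e1 * r1)^2 - (pif$e2 * r2)^2)
  zstd <- function(x)
    if (length(x) > 1 && sd(x) > 0) (x - mean(x)) / sd(x) else x * 0

  data.frame(tf = tf_list,
             mean_expr = unname(rowMeans(logexpr[tf_list, , drop = FALSE])),
             rif1 = unname(rif1), rif2 = unname(rif2),
             z_rif1 = unname(zstd(rif1)), z_rif2 = unname(zstd(rif2)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select abundant, consistently associated TFs
#'
#' A TF is selected when either standardised RIF score is extreme
#' (\code{|z| >= z_cut}) and its mean log2 expression reaches the
#' abundance cut (default: the median across scored TFs).
#'
#' @param scores a [compute_rif()] result.
#' @param z_cut threshold on \code{|z_rif1|} / \code{|z_rif2|}.
#' @param abundance_cut minimum mean log2 expression; \code{NULL} uses
#'   the across-TF median.
#' @return the selected rows of \code{scores}, with a \code{selected}
#'   column added to the full table as attribute \code{"scores"}.
#' @export
select_tf <- function(scores, z_cut = 2, abundance_cut = NULL) {
  stopifnot(is.data.frame(scores), z_cut >= 0)
  if (is.null(abundance_cut))
    abundance_cut <- stats::median(scores$mean_expr)
  sel <- (abs(scores$z_rif1) >= z_cut | abs(scores$z_rif2) >= z_cut) &
    scores$mean_expr >= abundance_cut
  scores$selected <- sel
  out <- scores[sel, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scores") <- scores
  out
}
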