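#' Construct a count matrix container
#'
#' Bundles a gene x sample matrix of raw read counts with per-gene lengths
#' (bp) and per-sample total mapped reads. Totals default to the column
#' sums of the counts when not supplied by the aligner; the source is
#' recorded so downstream RPKM values are auditable.
#'
#' @param counts integer-like gene x sample matrix with dimnames.
#' @param lengths named numeric vector of gene lengths in bp.
#' @param totals optional named numeric vector of total mapped reads per
#'   sample.
#' @return an object of class \code{count_matrix}.
#' @export
count_matrix <- function(counts, lengths, totals = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (any(counts < 0)) stop("counts must be non-negative")
  lengths <- lengths[rownames(counts)]
  if (anyNA(lengths) || any(lengths <= 0))
    stop("every gene needs a positive length")
  if (is.null(totals)) {
    totals <- colSums(counts)
    src <- "column_sums"
  } else {
    totals <- totals[colnames(counts)]
    if (anyNA(totals)) stop("totals missing for some samples")
    src <- "supplied"
  }
  structure(list(counts = counts, lengths = lengths, totals = totals,
                 totals_source = src),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (totals: %s)\n",
              nrow(x$counts), ncol(x$counts), x$totals_source))
  invisible(x)
}

#' Discard low-depth samples
#'
#' Samples with fewer than \code{min_reads} total mapped reads are
#' discarded; the boundary is inclusive (a sample with exactly
#' \code{min_reads} is kept, mirroring "less than 10 million ...
#' discarded").
#'
#' @param cm a [count_matrix()].
#' @param min_reads minimum total mapped reads (default 10 million).
#' @return the filtered \code{count_matrix}; removed sample ids are
#'   attached as attribute \code{"removed"} and reported via [message()].
#' @export
qc_samples <- function(cm, min_reads = 1e7) {
  stopifnot(inherits(cm, "count_matrix"), min_reads >= 0)
  keep <- cm$totals >= min_reads
  if (!any(keep)) stop("all samples fall below min_reads")
  removed <- colnames(cm$counts)[!keep]
  if (length(removed))
    message("qc_samples: discarded ", length(removed), " sample(s): ",
            paste(removed, collapse = ", "))
  out <- count_matrix(cm$counts[, keep, drop = FALSE], cm$lengths,
                      if (cm$totals_source == "supplied")
                        cm$totals[keep] else NULL)
  attr(out, "removed") <- removed
  out
}

#' RPKM normalisation
#'
#' Computes reads per kilobase of gene per million mapped reads:
#' \code{RPKM = count * 1e9 / (length * total)}.
#'
#' @param cm a [count_matrix()].
#' @param meta optional sample metadata (sample, animal, sire, tissue) to
#'   attach; rows are matched to samples by the \code{sample} column.
#' @return an object of class \code{expr_matrix} holding the RPKM matrix.
#' @export
compute_rpkm <- function(cm, meta = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(cm$totals <= 0))
    stop("zero total mapped reads for a retained sample")
  rpkm <- cm$counts * 1e9 / outer(cm$lengths, cm$totals)
  if (!is.null(meta)) {
    meta <- validate_sample_meta(meta)
    meta <- meta[match(colnames(rpkm), meta$sample), , drop = FALSE]
    if (anyNA(meta$sample)) stop("meta does not cover every sample")
    rownames(meta) <- NULL
  }
  structure(list(rpkm = rpkm, meta = meta, log2 = NULL, log2_offset = NA_real_),
            class = "expr_matrix")
}

#' Validate sample metadata
#'
#' Checks that every sample maps to exactly one animal, sire group and
#' tissue, and that each animal belongs to a single sire group.
#'
#' @param meta data frame with columns sample, animal, sire, tissue.
#' @return the validated data frame (invisibly usable).
#' @export
validate_sample_meta <- function(meta) {
  need <- c("sample", "animal", "sire", "tissue")
  if (!all(need %in% names(meta)))
    stop("meta must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$sample)) stop("duplicate sample ids in meta")
  bad <- tapply(meta$sire, meta$animal, function(s) length(unique(s)) > 1)
  if (any(bad))
    stop("animal(s) assigned to more than one sire group: ",
         paste(names(bad)[bad], collapse = ", "))
  meta
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples%s\n",
              nrow(x$rpkm), ncol(x$rpkm),
              if (!is.null(x$log2))
                sprintf(" (log2, offset %g)", x$log2_offset) else ""))
  invisible(x)
}

# per-gene mean RPKM by tissue (genes x tissues)
tissue_means <- function(em) {
  if (is.null(em$meta)) stop("expr_matrix has no sample metadata attached")
  tis <- unique(em$meta$tissue)
  out <- vapply(tis, function(tt)
    rowMeans(em$rpkm[, em$meta$tissue == tt, drop = FALSE]),
    numeric(nrow(em$rpkm)))
  colnames(out) <- tis
  out
}

#' Expressed-gene filter
#'
#' A gene counts as expressed when its summarised RPKM reaches at least
#' \code{threshold} (default 0.2) in at least one tissue; the complement
#' is the not-expressed set ("RPKM < 0.2 in any of the tissues"). The
#' boundary is inclusive: a tissue mean of exactly 0.2 is expressed.
#'
#' @param em an \code{expr_matrix} with metadata attached.
#' @param threshold RPKM threshold.
#' @param by summarise per tissue as the mean over the tissue's samples
#'   (\code{"tissue_mean"}, default) or test each sample individually
#'   (\code{"any_sample"}).
#' @return list with character vectors \code{expressed} and
#'   \code{not_expressed}, plus the settings used.
#' @export
filter_expressed <- function(em, threshold = 0.2,
                             by = c("tissue_mean", "any_sample")) {
  stopifnot(inherits(em, "expr_matrix"), threshold >= 0)
  by <- match.arg(by)
  peak <- if (by == "tissue_mean")
    apply(tissue_means(em), 1, max) else apply(em$rpkm, 1, max)
  # threshold 0 still requires some signal
  ok <- if (threshold > 0) peak >= threshold else peak > 0
  list(expressed = rownames(em$rpkm)[ok],
       not_expressed = rownames(em$rpkm)[!ok],
       threshold = threshold, by = by)
}

#' Restrict an expression matrix to a gene subset
#'
#' @param em an \code{expr_matrix}.
#' @param genes character vector of gene ids to keep.
#' @return the subset \code{expr_matrix}.
#' @export
subset_genes <- function(em, genes) {
  stopifnot(inherits(em, "expr_matrix"))
  missing <- setdiff(genes, rownames(em$rpkm))
  if (length(missing)) stop("unknown gene(s): ",
                            paste(head(missing, 5), collapse = ", "))
  em$rpkm <- em$rpkm[genes, , drop = FALSE]
  if (!is.null(em$log2)) em$log2 <- em$log2[genes, , drop = FALSE]
  em
}

#' Per-gene tissue expression shares
#'
#' For each gene, the share of tissue j is its mean RPKM in tissue j
#' divided by the sum of mean RPKM over all tissues. Genes with zero
#' total expression get NA shares and are excluded from TS calling.
#'
#' @param em an \code{expr_matrix} with metadata attached.
#' @return genes x tissues matrix of shares summing to 1 per gene;
#'   zero-total genes carry NA rows.
#' @export
tissue_share <- function(em) {
  tm <- tissue_means(em)
  tot <- rowSums(tm)
  sh <- tm / tot
  sh[tot == 0, ] <- NA_real_
  sh
}

#' Tissue-specificity classification (two-thirds rule)
#'
#' A gene is tissue specific when one tissue holds at least
#' \code{threshold} (default 2/3) of its total expression across tissues;
#' the boundary is inclusive ("at least two-thirds").
#'
#' @param shares genes x tissues share matrix from [tissue_share()].
#' @param threshold dominant-share threshold in (0.5, 1].
#' @return data frame with gene, dominant \code{tissue}, \code{share} and
#'   \code{is_ts}; genes with undefined shares are dropped.
#' @export
classify_tissue_specific <- function(shares, threshold = 2 / 3) {
  stopifnot(is.matrix(shares), threshold > 0.5, threshold <= 1)
  ok <- !apply(is.na(shares), 1, any)
  sh <- shares[ok, , drop = FALSE]
  dom <- max.col(sh, ties.method = "first")
  data.frame(gene = rownames(sh),
             tissue = colnames(sh)[dom],
             share = sh[cbind(seq_len(nrow(sh)), dom)],
             is_ts = sh[cbind(seq_len(nrow(sh)), dom)] >= threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' log2 transformation of RPKM
#'
#' Computes \code{log2(RPKM + offset)} and stores it on the
#' \code{expr_matrix}. The default offset of 0.2 (the expressed-gene
#' threshold) keeps zero cells among retained genes finite.
#'
#' @param em an \code{expr_matrix}.
#' @param offset non-negative pseudo-value; must be positive when zeros
#'   are present.
#' @return \code{em} with \code{$log2} filled in and the offset recorded.
#' @export
log2_transform <- function(em, offset = 0.2) {
  stopifnot(inherits(em, "expr_matrix"), offset >= 0)
  if (offset == 0 && any(em$rpkm == 0))
    stop("offset 0 with zero RPKM values present")
  em$log2 <- log2(em$rpkm + offset)
  em$log2_offset <- offset
  em
}
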