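#' Pearson correlation matrix over samples
#'
#' Correlates the log2 expression of the requested nodes across all
#' retained samples. Zero-variance nodes are dropped with a warning
#' (their correlations are undefined); exact symmetry and a unit diagonal
#' are enforced.
#'
#' @param logexpr genes x samples numeric matrix (log2 expression).
#' @param nodes optional character vector of genes to use (default: all).
#' @return an object of class \code{correlation_structure}: list with the
#'   correlation matrix \code{R} and the node ids.
#' @export
correlation_matrix <- function(logexpr, nodes = rownames(logexpr)) {
  stopifnot(is.matrix(logexpr))
  if (ncol(logexpr) < 3) stop("need >= 3 samples for correlations")
  missing <- setdiff(nodes, rownames(logexpr))
  if (length(missing)) stop("unknown node(s): ",
                            paste(head(missing, 5), collapse = ", "))
  X <- logexpr[nodes, , drop = FALSE]
  v <- apply(X, 1, var)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance node(s)")
    X <- X[v > 0, , drop = FALSE]
  }
  R <- cor(t(X))
  R <- (R + t(R)) / 2
  diag(R) <- 1
  structure(list(R = R, nodes = rownames(R)),
            class = "correlation_structure")
}

#' First-order partial correlation
#'
#' \code{r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))}:
#' the correlation between x and y after conditioning on z.
#'
#' @param r_xy,r_xz,r_yz pairwise Pearson correlations.
#' @return the partial correlation (vectorised over its arguments).
#' @export
partial_correlation <- function(r_xy, r_xz, r_yz) {
  den <- (1 - r_xz^2) * (1 - r_yz^2)
  if (any(den <= 1e-24))
    stop("degenerate conditioning: |r_xz| or |r_yz| equals 1")
  (r_xy - r_xz * r_yz) / sqrt(den)
}

#' PCIT significance mask
#'
#' For every trio of nodes the three first-order partial correlations are
#' computed and averaged against their direct correlations into a local
#' tolerance \code{eps}; an edge x-y is eliminated when \code{|r_xy| <=
#' eps * |r_xz|} and \code{|r_xy| <= eps * |r_yz|} for at least one third
#' node z. Pairs never eliminated are significant. Ratio terms whose
#' direct correlation is below 1e-12 in absolute value are skipped when
#' forming \code{eps}. With fewer than 3 nodes no trio exists and every
#' pair is vacuously significant.
#'
#' @param cs a [correlation_matrix()] result (or a bare correlation
#'   matrix).
#' @return logical symmetric matrix; \code{TRUE} marks significant pairs,
#'   diagonal \code{FALSE}.
#' @export
pcit_significant <- function(cs) {
  R <- if (inherits(cs, "correlation_structure")) cs$R else as.matrix(cs)
  n <- nrow(R)
  if (n < 2) stop("need >= 2 nodes")
  if (n == 2) {
    mask <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2,
                   dimnames = dimnames(R))
    return(mask)
  }
  scan <- pcit_scan_cpp(R, FALSE)
  mask <- !scan$eliminated
  diag(mask) <- FALSE
  dimnames(mask) <- dimnames(R)
  mask
}

#' Edge acceptance by the 2-SD rule
#'
#' Standardises the chosen statistic (raw correlation by default, or the
#' mean first-order partial correlation with \code{stat = "partial"})
#' and accepts PCIT-significant pairs at least \code{k} standard
#' deviations from the mean (two-sided). By default the mean and SD are
#' taken over all candidate pairs; \code{standardize = "significant"}
#' restricts them to the PCIT-surviving pairs, which degenerates on
#' strongly structured data (the survivors are the strong tail, whose
#' 2-SD band can exceed |r| = 1, accepting nothing — see the vignette).
#'
#' @param cs a [correlation_matrix()] result.
#' @param mask significance mask from [pcit_significant()].
#' @param k threshold in standard deviations (default 2).
#' @param stat statistic to standardise: \code{"raw"} correlations
#'   (default) or mean \code{"partial"} correlations.
#' @param standardize reference distribution for the mean and SD:
#'   \code{"all"} pairs (default) or \code{"significant"} pairs only.
#' @param sided \code{"one"} (default) accepts the upper tail (\code{z >=
#'   k}, the literal "greater than two standard deviations from the
#'   mean", which keeps co-expression and discards the cross-tissue
#'   anti-correlations); \code{"two"} accepts \code{|z| >= k}.
#' @return data frame edge list over significant pairs: \code{gene_a <
#'   gene_b}, the correlation weight \code{r}, the standardised statistic
#'   \code{z} and \code{accepted}.
#' @export
threshold_edges <- function(cs, mask, k = 2, stat = c("raw", "partial"),
                            standardize = c("all", "significant"),
                            sided = c("one", "two")) {
  stopifnot(inherits(cs, "correlation_structure"), k >= 0)
  stat <- match.arg(stat)
  standardize <- match.arg(standardize)
  sided <- match.arg(sided)
  R <- cs$R
  stopifnot(identical(dim(mask), dim(R)))
  ut <- upper.tri(R)
  sig <- which(mask & ut, arr.ind = TRUE)
  edges <- data.frame(gene_a = rownames(R)[sig[, 1]],
                      gene_b = colnames(R)[sig[, 2]],
                      r = R[sig], stringsAsFactors = FALSE)
  S <- if (stat == "raw") R else pcit_scan_cpp(R, TRUE)$mean_partial
  ref <- if (standardize == "all") S[ut] else S[sig]
  val <- S[sig]
  if (nrow(edges) < 2 || length(ref) < 2 || sd(ref) == 0) {
    if (nrow(edges) > 0)
      warning("degenerate statistic over candidate pairs; ",
              "no edges accepted")
    edges$z <- rep(0, nrow(edges))
    edges$accepted <- rep(FALSE, nrow(edges))
  } else {
    edges$z <- (val - mean(ref)) / sd(ref)
    edges$accepted <- if (sided == "one") edges$z >= k else
      abs(edges$z) >= k
  }
  edges
}

#' Full PCIT network inference
#'
#' Convenience wrapper: correlation matrix over the node set, PCIT trio
#' elimination, then the 2-SD acceptance rule.
#'
#' @inheritParams correlation_matrix
#' @inheritParams threshold_edges
#' @return the [threshold_edges()] edge list.
#' @export
pcit <- function(logexpr, nodes = rownames(logexpr), k = 2,
                 stat = c("raw", "partial"), sided = c("one", "two")) {
  cs <- correlation_matrix(logexpr, nodes)
  threshold_edges(cs, pcit_significant(cs), k = k, stat = match.arg(stat),
                  sided = match.arg(sided))
}
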