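#' Fit the crossed random-effects model by REML
#'
#' Fits \code{Y_ijkl = mu + G_i + GT_ij + GA_ik + GS_il + e_ijkl} on a
#' genes x samples matrix of log2 expression, where gene (G), gene by
#' tissue (GT), gene by animal (GA) and gene by sire group (GS) are
#' independent random effects and the residual is i.i.d. Because every
#' random factor is crossed with gene, genes are independent with a
#' common m x m marginal covariance (m = number of samples), so the
#' restricted likelihood factorises over genes and is maximised directly
#' over the five variance components (L-BFGS-B, components bounded below
#' by a numerical floor of 1e-8 x var(Y)).
#'
#' @param Y numeric genes x samples matrix (log2 expression), finite.
#' @param meta sample metadata (sample, animal, sire, tissue); matched to
#'   \code{colnames(Y)}.
#' @param max_iter maximum optimizer iterations.
#' @param tol relative convergence tolerance.
#' @return an object of class \code{mm_fit}: \code{mu}, named
#'   \code{varcomp} (\code{G}, \code{GT}, \code{GA}, \code{GS}, \code{e}),
#'   the restricted log-likelihood, \code{converged} and
#'   \code{iterations}.
#' @export
fit_variance_components <- function(Y, meta, max_iter = 200, tol = 1e-6) {
  Y <- as.matrix(Y)
  if (!all(is.finite(Y))) stop("Y must be finite")
  meta <- validate_sample_meta(meta)
  meta <- meta[match(colnames(Y), meta$sample), , drop = FALSE]
  if (anyNA(meta$sample)) stop("meta does not cover every sample in Y")
  if (nrow(Y) < 2) stop("need at least 2 genes")
  if (length(unique(meta$tissue)) < 2 || length(unique(meta$animal)) < 2 ||
      length(unique(meta$sire)) < 2)
    stop("degenerate design: need >= 2 tissues, animals and sire groups")

  m <- ncol(Y); G <- nrow(Y)
  vtot <- var(as.vector(Y))
  if (vtot == 0) {
    return(structure(list(
      mu = Y[1, 1], varcomp = c(G = 0, GT = 0, GA = 0, GS = 0, e = 0),
      loglik = NA_real_, converged = TRUE, iterations = 0L, meta = meta),
      class = "mm_fit"))
  }

  sim <- list(
    G  = matrix(1, m, m),
    GT = outer(meta$tissue, meta$tissue, "=="),
    GA = outer(meta$animal, meta$animal, "=="),
    GS = outer(meta$sire, meta$sire, "=="),
    e  = diag(m))
  tY <- t(Y)
  n_eval <- 0L

  nll <- function(s) {
    n_eval <<- n_eval + 1L
    V <- s[1] * sim$G + s[2] * sim$GT + s[3] * sim$GA + s[4] * sim$GS +
      s[5] * sim$e
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    W <- chol2inv(R)
    Tm <- W %*% tY
    a <- colSums(Tm)
    s11 <- sum(W)
    mu <- sum(a) / (G * s11)
    quad <- sum(tY * Tm) - 2 * mu * sum(a) + mu^2 * G * s11
    0.5 * (G * 2 * sum(log(diag(R))) + log(G * s11) + quad)
  }

  init <- rep(vtot / 5, 5)
  lower <- c(rep(1e-8 * vtot, 4), 1e-6 * vtot)
  opt <- optim(pmax(init, lower), nll, method = "L-BFGS-B", lower = lower,
               control = list(maxit = max_iter,
                              factr = max(tol / .Machine$double.eps, 10)))
  s <- opt$par
  # recover mu at the optimum
  V <- s[1] * sim$G + s[2] * sim$GT + s[3] * sim$GA + s[4] * sim$GS +
    s[5] * sim$e
  W <- chol2inv(chol(V))
  mu <- sum(W %*% tY) / (G * sum(W))

  structure(list(
    mu = mu,
    varcomp = setNames(s, c("G", "GT", "GA", "GS", "e")),
    loglik = -opt$value, converged = opt$convergence == 0,
    iterations = n_eval, meta = meta),
    class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("crossed random-effects REML fit\n")
  cat(sprintf("  mu = %.4f  (%s, %d likelihood evaluations)\n", x$mu,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(round(x$varcomp, 6))
  invisible(x)
}

#' BLUP solutions of the mixed model
#'
#' Solves the random effects at the REML variance components: for gene i
#' with centred data r_i, the BLUP of a factor level is sigma^2_q times
#' the sum of V^{-1} r_i over the samples at that level. Shrinkage toward
#' zero grows as the factor's variance ratio shrinks.
#'
#' @param Y the genes x samples log2 matrix used for the fit.
#' @param meta sample metadata.
#' @param fit a converged [fit_variance_components()] result.
#' @return an object of class \code{mm_blups}: per-gene \code{G}, matrices
#'   \code{GT} (genes x tissues), \code{GA} (genes x animals), \code{GS}
#'   (genes x sires), the sire contrast \code{d} (low - high), and
#'   \code{residuals}.
#' @export
solve_blups <- function(Y, meta, fit) {
  stopifnot(inherits(fit, "mm_fit"))
  if (!fit$converged)
    stop("refusing to solve BLUPs from a non-converged fit")
  Y <- as.matrix(Y)
  meta <- validate_sample_meta(meta)
  meta <- meta[match(colnames(Y), meta$sample), , drop = FALSE]
  s <- fit$varcomp
  m <- ncol(Y)
  if (all(s == 0)) {
    z <- matrix(0, nrow(Y), 1, dimnames = list(rownames(Y), NULL))
    tis <- unique(meta$tissue); ani <- unique(meta$animal)
    sir <- unique(meta$sire)
    return(structure(list(
      G = setNames(rep(0, nrow(Y)), rownames(Y)),
      GT = z[, rep(1, length(tis)), drop = FALSE],
      GA = z[, rep(1, length(ani)), drop = FALSE],
      GS = z[, rep(1, length(sir)), drop = FALSE],
      d = setNames(rep(0, nrow(Y)), rownames(Y)),
      residuals = Y - fit$mu), class = "mm_blups"))
  }
  V <- s["G"] * matrix(1, m, m) +
    s["GT"] * outer(meta$tissue, meta$tissue, "==") +
    s["GA"] * outer(meta$animal, meta$animal, "==") +
    s["GS"] * outer(meta$sire, meta$sire, "==") +
    s["e"] * diag(m)
  W <- chol2inv(chol(V))
  Tm <- W %*% t(Y - fit$mu)          # m x genes

  level_sums <- function(f) {
    lev <- unique(f)
    out <- vapply(lev, function(l)
      colSums(Tm[f == l, , drop = FALSE]), numeric(ncol(Tm)))
    colnames(out) <- lev
    out                               # genes x levels
  }
  Gb  <- s["G"] * colSums(Tm)
  GTb <- s["GT"] * level_sums(meta$tissue)
  GAb <- s["GA"] * level_sums(meta$animal)
  GSb <- s["GS"] * level_sums(meta$sire)
  names(Gb) <- rownames(Y)
  rownames(GTb) <- rownames(GAb) <- rownames(GSb) <- rownames(Y)

  fitted <- fit$mu + Gb +
    GTb[, meta$tissue, drop = FALSE] +
    GAb[, meta$animal, drop = FALSE] +
    GSb[, meta$sire, drop = FALSE]
  d <- if (all(c("low", "high") %in% colnames(GSb)))
    GSb[, "low"] - GSb[, "high"] else GSb[, 1] - GSb[, 2]

  structure(list(G = Gb, GT = GTb, GA = GAb, GS = GSb, d = d,
                 residuals = Y - fitted),
            class = "mm_blups")
}

#' Differential-expression calls by the 2-SD rule
#'
#' Standardises the gene-by-sire BLUP contrasts d_i = GS_i,low -
#' GS_i,high across genes and flags a gene as DE when its standardised
#' contrast is at least \code{k} standard deviations from the mean
#' (default k = 2). Per-tissue log2 fold changes (low - high group mean
#' of log2 expression within tissue) are attached for reporting.
#'
#' @param blups an [solve_blups()] result.
#' @param Y,meta the log2 matrix and metadata used for the fit.
#' @param k threshold in standard deviations.
#' @return data frame with gene, \code{d}, \code{z}, \code{is_de} and one
#'   \code{log2fc_<tissue>} column per tissue.
#' @export
call_de <- function(blups, Y, meta, k = 2) {
  stopifnot(inherits(blups, "mm_blups"), k >= 0)
  d <- blups$d
  if (length(d) < 10) stop("need >= 10 genes to estimate the SD of d")
  s <- sd(d)
  if (s == 0 || !is.finite(s)) {
    warning("zero SD of gene-by-sire contrasts; no DE calls made")
    z <- rep(0, length(d))
    is_de <- rep(FALSE, length(d))
  } else {
    z <- (d - mean(d)) / s
    is_de <- abs(z) >= k
  }
  meta <- meta[match(colnames(Y), meta$sample), , drop = FALSE]
  out <- data.frame(gene = names(d), d = unname(d), z = unname(z),
                    is_de = unname(is_de), row.names = NULL,
                    stringsAsFactors = FALSE)
  for (tt in unique(meta$tissue)) {
    lo <- meta$tissue == tt & meta$sire == "low"
    hi <- meta$tissue == tt & meta$sire == "high"
    out[[paste0("log2fc_", tt)]] <-
      rowMeans(Y[, lo, drop = FALSE]) - rowMeans(Y[, hi, drop = FALSE])
  }
  out
}

#' Simulate directly from the crossed random-effects model
#'
#' Draws every random effect of \code{Y = mu + G + GT + GA + GS + e} from
#' independent normals at the given variance components. Used for
#' parameter-recovery and null-calibration checks.
#'
#' @param meta sample metadata defining tissues, animals and sires.
#' @param n_genes number of genes.
#' @param varcomp named vector of variances (\code{G}, \code{GT},
#'   \code{GA}, \code{GS}, \code{e}).
#' @param mu overall mean.
#' @return genes x samples matrix.
#' @export
simulate_mixed <- function(meta, n_genes,
                           varcomp = c(G = 1, GT = 0.5, GA = 0.25,
                                       GS = 0.1, e = 0.5),
                           mu = 5) {
  meta <- validate_sample_meta(meta)
  tis <- unique(meta$tissue); ani <- unique(meta$animal)
  sir <- unique(meta$sire)
  genes <- sprintf("g%05d", seq_len(n_genes))
  Gb <- rnorm(n_genes, 0, sqrt(varcomp["G"]))
  GT <- matrix(rnorm(n_genes * length(tis), 0, sqrt(varcomp["GT"])),
               n_genes, length(tis), dimnames = list(genes, tis))
  GA <- matrix(rnorm(n_genes * length(ani), 0, sqrt(varcomp["GA"])),
               n_genes, length(ani), dimnames = list(genes, ani))
  GS <- matrix(rnorm(n_genes * length(sir), 0, sqrt(varcomp["GS"])),
               n_genes, length(sir), dimnames = list(genes, sir))
  E <- matrix(rnorm(n_genes * nrow(meta), 0, sqrt(varcomp["e"])),
              n_genes, nrow(meta))
  Y <- mu + Gb + GT[, meta$tissue, drop = FALSE] +
    GA[, meta$animal, drop = FALSE] + GS[, meta$sire, drop = FALSE] + E
  dimnames(Y) <- list(genes, meta$sample)
  Y
}
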