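# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

# Balanced method-of-moments (ANOVA) variance-component estimator for the
# crossed random model Y = mu + G + GT + GA + GS + e, derived from the
# expected mean squares of the balanced decomposition.
anova_varcomp <- function(Y, meta) {
  G <- nrow(Y)
  tis <- unique(meta$tissue); ani <- unique(meta$animal)
  sir <- unique(meta$sire)
  t_ <- length(tis); a_ <- length(ani); s_ <- length(sir)
  as_ <- a_ / s_
  grand <- mean(Y)
  yg <- rowMeans(Y)
  Mt <- vapply(tis, function(tt)
    rowMeans(Y[, meta$tissue == tt, drop = FALSE]), numeric(G))
  Ma <- vapply(ani, function(aa)
    rowMeans(Y[, meta$animal == aa, drop = FALSE]), numeric(G))
  Ms <- vapply(sir, function(ss)
    rowMeans(Y[, meta$sire == ss, drop = FALSE]), numeric(G))
  sire_of_animal <- vapply(ani, function(aa)
    unique(meta$sire[meta$animal == aa]), character(1))

  ms_g  <- t_ * a_ * sum((yg - grand)^2) / (G - 1)
  ms_gt <- a_ * sum((Mt - yg)^2) / (G * (t_ - 1))
  ms_gs <- t_ * as_ * sum((Ms - yg)^2) / (G * (s_ - 1))
  ms_ga <- t_ * sum((Ma - Ms[, sire_of_animal])^2) / (G * (a_ - s_))
  res <- Y - Mt[, match(meta$tissue, tis)] -
    Ma[, match(meta$animal, ani)] + yg
  ms_e <- sum(res^2) / (G * (t_ - 1) * (a_ - 1))

  c(G  = (ms_g - ms_gt - ms_gs + ms_e) / (t_ * a_),
    GT = (ms_gt - ms_e) / a_,
    GA = (ms_ga - ms_e) / t_,
    GS = (ms_gs - ms_ga) / (t_ * as_),
    e  = ms_e)
}

# Naive triple-loop PCIT elimination, written directly from the trio rule.
naive_pcit_mask <- function(R) {
  n <- nrow(R)
  elim <- matrix(FALSE, n, n)
  part <- function(rxy, rxz, ryz) {
    den <- (1 - rxz^2) * (1 - ryz^2)
    if (den < 1e-24) return(0)
    (rxy - rxz * ryz) / sqrt(den)
  }
  if (n >= 3) {
    for (x in 1:(n - 2)) for (y in (x + 1):(n - 1)) for (z in (y + 1):n) {
      rxy <- R[x, y]; rxz <- R[x, z]; ryz <- R[y, z]
      pxy <- part(rxy, rxz, ryz)
      pxz <- part(rxz, rxy, ryz)
      pyz <- part(ryz, rxy, rxz)
      s <- 0; m <- 0
      if (abs(rxy) > 1e-12) { s <- s + abs(pxy / rxy); m <- m + 1 }
      if (abs(rxz) > 1e-12) { s <- s + abs(pxz / rxz); m <- m + 1 }
      if (abs(ryz) > 1e-12) { s <- s + abs(pyz / ryz); m <- m + 1 }
      if (m == 0) next
      eps <- s / m
      if (abs(rxy) <= eps * abs(rxz) && abs(rxy) <= eps * abs(ryz))
        elim[x, y] <- elim[y, x] <- TRUE
      if (abs(rxz) <= eps * abs(rxy) && abs(rxz) <= eps * abs(ryz))
        elim[x, z] <- elim[z, x] <- TRUE
      if (abs(ryz) <= eps * abs(rxy) && abs(ryz) <= eps * abs(rxz))
        elim[y, z] <- elim[z, y] <- TRUE
    }
  }
  mask <- !elim
  diag(mask) <- FALSE
  dimnames(mask) <- dimnames(R)
  mask
}

# Upper-tail hypergeometric probability P(X >= k) by explicit summation.
hyper_tail <- function(k, K, N, n) {
  hi <- min(K, n)
  if (k > hi) return(0)
  j <- max(k, 0):hi
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# Small balanced design for fast tests.
small_design <- function(seed = 1, n_genes = 150) {
  experiment_design(animals_per_sire = 4,
                    tissues = c("pituitary", "muscle", "liver"),
                    n_genes = n_genes, n_tf = 15, n_snp_genes = 15,
                    seed = seed)
}

small_params <- function(...) {
  args <- list(n_hub_tf = 2, hub_module_size = 8, depth_mean = 5e5)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_params, args)
}

# Random correlation matrix from random Gaussian data.
random_cor <- function(n, m = n + 5) {
  X <- matrix(rnorm(n * m), n, m)
  R <- cor(t(X))
  dimnames(R) <- list(paste0("n", 1:n), paste0("n", 1:n))
  R
}
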