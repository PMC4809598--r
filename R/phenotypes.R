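#' Average daily gain from a 14-d weight series
#'
#' ADG is the slope of the least-squares regression of body weight on
#' days on feed; all weigh dates in the period are used.
#'
#' @param day numeric days (period start = day 0).
#' @param weight body weights (kg) on those days.
#' @return slope in kg/d.
#' @export
compute_adg <- function(day, weight) {
  stopifnot(length(day) == length(weight))
  if (length(day) < 3) stop("need >= 3 weigh dates")
  unname(coef(lm.fit(cbind(1, day), weight))[2])
}

#' Metabolic mid-weight
#'
#' \code{MMW = (mean period body weight)^0.75}, a proxy for maintenance
#' requirements.
#'
#' @param weight body weights (kg) over the period.
#' @return MMW in kg^0.75.
#' @export
compute_mmw <- function(weight) {
  if (length(weight) < 1 || any(weight <= 0))
    stop("weights must be positive")
  mean(weight)^0.75
}

#' Residual feed intake by intercept-containing least squares
#'
#' Fits \code{DMI = b0 + b1 ADG + b2 MMW + RFI} across animals (both
#' sire groups together, within period) by OLS; RFI is the residual, so
#' its mean is 0 to machine precision and it is orthogonal to ADG and
#' MMW.
#'
#' @param dmi mean daily dry-matter intake per animal (kg DM/d).
#' @param adg average daily gain per animal (kg/d).
#' @param mmw metabolic mid-weight per animal (kg^0.75).
#' @param animal optional animal ids.
#' @return object of class \code{rfi_fit}: \code{coefficients}
#'   (\code{b0}, \code{b1}, \code{b2}) and a per-animal \code{table} with
#'   dmi, adg, mmw and rfi.
#' @export
compute_rfi <- function(dmi, adg, mmw, animal = NULL) {
  n <- length(dmi)
  stopifnot(length(adg) == n, length(mmw) == n)
  if (n < 3) stop("need >= 3 animals")
  X <- cbind(1, adg, mmw)
  if (qr(X)$rank < 3)
    stop("rank-deficient design: ADG and MMW collinear (or constant)")
  fit <- lm.fit(X, dmi)
  structure(list(
    coefficients = setNames(unname(fit$coefficients),
                            c("b0", "b1", "b2")),
    table = data.frame(
      animal = if (is.null(animal)) paste0("a", seq_len(n)) else animal,
      dmi = dmi, adg = adg, mmw = mmw, rfi = unname(fit$residuals),
      row.names = NULL, stringsAsFactors = FALSE)),
    class = "rfi_fit")
}

#' Feed conversion ratio
#'
#' \code{FCR = DMI / ADG} per animal; undefined (NA, flagged by warning)
#' when ADG is 0.
#'
#' @param dmi mean daily dry-matter intake (kg DM/d).
#' @param adg average daily gain (kg/d).
#' @return FCR values.
#' @export
compute_fcr <- function(dmi, adg) {
  out <- dmi / adg
  if (any(adg == 0)) {
    warning("ADG of 0: FCR undefined for ", sum(adg == 0), " animal(s)")
    out[adg == 0] <- NA_real_
  }
  out
}

#' Carcass specific gravity
#'
#' \code{SG = CW / (CW - CW_H2O)} where CW is the carcass weight in air
#' and CW_H2O its weight suspended in water. Higher values indicate
#' leaner carcasses.
#'
#' @param cw carcass weight in air (kg).
#' @param cw_h2o carcass weight in water (kg).
#' @return specific gravity (dimensionless).
#' @export
carcass_specific_gravity <- function(cw, cw_h2o) {
  if (any(cw_h2o < 0)) stop("cw_h2o must be >= 0")
  if (any(cw <= cw_h2o)) stop("requires CW > CW_H2O")
  cw / (cw - cw_h2o)
}

#' Feeding-behaviour summaries from bunk-visit events
#'
#' @param duration_min visit durations in minutes.
#' @param days number of recorded days (> 0).
#' @return list with \code{visits_per_day}, \code{min_per_visit} (NA when
#'   there are no events) and \code{min_per_day}.
#' @export
summarize_feeding <- function(duration_min, days) {
  if (days <= 0) stop("zero recorded days")
  n <- length(duration_min)
  list(visits_per_day = n / days,
       min_per_visit = if (n > 0) mean(duration_min) else NA_real_,
       min_per_day = sum(duration_min) / days)
}

#' Sire-group difference for a trait
#'
#' Difference of group means (low - high) with a two-sample t-test
#' p-value; Welch's unequal-variance test by default, pooled variance on
#' request. Degenerate identical groups report p = 1.
#'
#' @param values trait values.
#' @param groups factor/character with levels \code{low} and \code{high}.
#' @param var_equal use the pooled-variance t-test.
#' @return list with \code{difference}, \code{t}, \code{df}, \code{p}.
#' @export
group_difference <- function(values, groups, var_equal = FALSE) {
  x <- values[groups == "low"]; y <- values[groups == "high"]
  if (length(x) < 2 || length(y) < 2)
    stop("need >= 2 animals per sire group")
  diff <- mean(x) - mean(y)
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  if (vx + vy == 0) {
    return(list(difference = diff, t = if (diff == 0) 0 else Inf,
                df = NA_real_, p = if (diff == 0) 1 else 0))
  }
  if (var_equal) {
    sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
      (length(x) + length(y) - 2)
    se <- sqrt(sp2 * (1 / length(x) + 1 / length(y)))
    df <- length(x) + length(y) - 2
  } else {
    se <- sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  }
  tstat <- diff / se
  list(difference = diff, t = tstat, df = df,
       p = 2 * pt(-abs(tstat), df))
}

#' Analytic power for two-group RNA-seq differential expression
#'
#' Normal-approximation power for detecting a fold change \code{fc} with
#' \code{n} biological replicates per group at level \code{alpha}, with
#' per-group log-count variance \code{1/depth + cv^2} (technical Poisson
#' plus biological overdispersion). The underlying sample-size formula is
#' \code{n = 2 (z_{1-alpha/2} + z_power)^2 (1/depth + cv^2) / ln(fc)^2}.
#'
#' @param n replicates per group.
#' @param fc fold change on the ratio scale (> 1).
#' @param cv biological coefficient of variation.
#' @param alpha two-sided test level.
#' @param depth expected counts per gene (Inf for the high-depth regime).
#' @return power in (0, 1).
#' @export
de_power <- function(n, fc = 1.8, cv = 0.4, alpha = 0.05, depth = Inf) {
  stopifnot(n > 0, cv > 0, alpha > 0, alpha < 1, fc >= 1, depth > 0)
  if (fc == 1) return(alpha)
  sigma2 <- 1 / depth + cv^2
  ncp <- sqrt(n * log(fc)^2 / (2 * sigma2))
  pnorm(ncp - qnorm(1 - alpha / 2))
}

#' Replicates required for a target power
#'
#' Inverts the [de_power()] formula:
#' \code{n = 2 (z_{1-alpha/2} + z_power)^2 (1/depth + cv^2) / ln(fc)^2},
#' rounded up.
#'
#' @inheritParams de_power
#' @param power target power in (alpha, 1).
#' @return integer replicates per group.
#' @export
required_n <- function(power = 0.8, fc = 1.8, cv = 0.4, alpha = 0.05,
                       depth = Inf) {
  stopifnot(power > 0, power < 1, cv > 0, depth > 0)
  if (fc == 1) {
    if (power > alpha) stop("fold change 1 cannot reach power above alpha")
    return(Inf)
  }
  sigma2 <- 1 / depth + cv^2
  ceiling(2 * (qnorm(1 - alpha / 2) + qnorm(power))^2 * sigma2 / log(fc)^2)
}

#' Simulated power by negative-binomial counts and a Wald test
#'
#' Per gene, draws \code{n} negative-binomial counts per group (group 2
#' mean multiplied by \code{fc}, dispersion \code{cv^2}) and applies a
#' two-group Wald test on the log group means with delta-method variance
#' \code{(1/mean + cv^2)/n} per group, using the known simulation
#' dispersion. Power is the rejection fraction over genes.
#'
#' @inheritParams de_power
#' @param depth mean counts per gene in group 1.
#' @param n_genes number of simulated genes (Monte Carlo replicates).
#' @return empirical power.
#' @export
simulate_de_power <- function(n = 8, fc = 1.8, cv = 0.4, alpha = 0.05,
                              depth = 2000, n_genes = 2000) {
  stopifnot(n >= 2, fc > 0, cv > 0, is.finite(depth), depth > 0)
  size <- 1 / cv^2
  x1 <- matrix(rnbinom(n_genes * n, mu = depth, size = size), n_genes, n)
  x2 <- matrix(rnbinom(n_genes * n, mu = depth * fc, size = size),
               n_genes, n)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ok <- m1 > 0 & m2 > 0
  se <- sqrt((1 / m1[ok] + cv^2) / n + (1 / m2[ok] + cv^2) / n)
  z <- (log(m2[ok]) - log(m1[ok])) / se
  mean(abs(z) > qnorm(1 - alpha / 2))
}

#' Derive all feedlot phenotypes from a phenotype table
#'
#' Convenience wrapper over the individual derivations: per-animal ADG,
#' MMW, mean daily DMI, the RFI regression, FCR, feeding-behaviour
#' summaries and carcass specific gravity, plus sire-group differences
#' (low - high) with Welch p-values for each trait.
#'
#' @param pheno a [simulate_phenotypes()] result or a structurally
#'   identical list of tables.
#' @return list with the per-animal \code{table}, the \code{rfi_fit} and
#'   a \code{group_differences} data frame (trait, mean, difference, p).
#' @export
derive_phenotypes <- function(pheno) {
  an <- pheno$animals
  adg <- vapply(an$animal, function(a) {
    w <- pheno$weights[pheno$weights$animal == a, ]
    compute_adg(w$day, w$weight)
  }, numeric(1))
  mmw <- vapply(an$animal, function(a)
    compute_mmw(pheno$weights$weight[pheno$weights$animal == a]),
    numeric(1))
  dmi <- vapply(an$animal, function(a)
    mean(pheno$intake$dmi[pheno$intake$animal == a]), numeric(1))
  rfi <- compute_rfi(dmi, adg, mmw, animal = an$animal)
  fcr <- compute_fcr(dmi, adg)
  days <- pheno$period_days
  feed <- lapply(an$animal, function(a)
    summarize_feeding(pheno$events$duration_min[pheno$events$animal == a],
                      days))
  sg <- carcass_specific_gravity(pheno$carcass$cw, pheno$carcass$cw_h2o)

  tab <- data.frame(
    animal = an$animal, sire = an$sire,
    adg = unname(adg), mmw = unname(mmw), dmi = unname(dmi),
    rfi = rfi$table$rfi, fcr = fcr,
    visits_per_day = vapply(feed, `[[`, numeric(1), "visits_per_day"),
    min_per_visit = vapply(feed, `[[`, numeric(1), "min_per_visit"),
    min_per_day = vapply(feed, `[[`, numeric(1), "min_per_day"),
    specific_gravity = sg,
    row.names = NULL, stringsAsFactors = FALSE)

  traits <- c("mmw", "adg", "dmi", "fcr", "rfi", "visits_per_day",
              "min_per_visit", "min_per_day", "specific_gravity")
  gd <- do.call(rbind, lapply(traits, function(tr) {
    g <- group_difference(tab[[tr]], tab$sire)
    data.frame(trait = tr, mean = mean(tab[[tr]], na.rm = TRUE),
               difference = g$difference, p = g$p,
               stringsAsFactors = FALSE)
  }))
  list(table = tab, rfi_fit = rfi, group_differences = gd)
}
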