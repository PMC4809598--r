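test_that("ADG is the least-squares slope of weight on days", {
  expect_equal(compute_adg(c(0, 14, 28), c(300, 314, 328)), 1.0)
  expect_equal(compute_adg(c(0, 14, 28, 42), rep(400, 4)), 0)
  # slope invariant to a weight offset
  d <- c(0, 14, 28, 42, 56)
  w <- 300 + 1.4 * d + c(0.5, -1, 2, 0, -0.3)
  expect_equal(compute_adg(d, w), compute_adg(d, w + 50))
  expect_error(compute_adg(c(0, 14), c(1, 2)), ">= 3")
})

test_that("MMW is mean weight to the 0.75 power", {
  expect_equal(compute_mmw(100), 31.6228, tolerance = 1e-4)
  expect_equal(compute_mmw(1), 1)
  expect_equal(compute_mmw(256), 64)
  expect_equal(compute_mmw(c(250, 270)), 260^0.75)
  expect_error(compute_mmw(c(100, -5)), "positive")
  # strictly increasing in mean weight
  expect_true(compute_mmw(301) > compute_mmw(300))
})

test_that("RFI is a zero-mean residual orthogonal to ADG and MMW", {
  set.seed(1)
  n <- 16
  adg <- rnorm(n, 1.7, 0.2); mmw <- rnorm(n, 75, 4)
  dmi <- -1 + 2 * adg + 0.1 * mmw + rnorm(n, 0, 0.3)
  fit <- compute_rfi(dmi, adg, mmw)
  expect_lt(abs(mean(fit$table$rfi)), 1e-10)
  expect_lt(abs(sum(fit$table$rfi * adg)), 1e-8)
  expect_lt(abs(sum(fit$table$rfi * mmw)), 1e-8)
  # noiseless data returns the planted coefficients exactly
  fit0 <- compute_rfi(1 + 2 * adg + 0.05 * mmw, adg, mmw)
  expect_equal(unname(fit0$coefficients), c(1, 2, 0.05), tolerance = 1e-8)
  # saturated fit: 3 animals, 3 parameters
  fit3 <- compute_rfi(c(8, 9, 10), adg[1:3], mmw[1:3])
  expect_equal(max(abs(fit3$table$rfi)), 0, tolerance = 1e-8)
  expect_error(compute_rfi(dmi, adg, 2 * adg), "rank-deficient")
})

test_that("FCR is DMI/ADG with an undefined flag at ADG 0", {
  expect_equal(compute_fcr(8, 2), 4)
  expect_equal(compute_fcr(9.55, 1.71), 5.585, tolerance = 1e-3)
  expect_equal(compute_fcr(2 * 9.55, 2 * 1.71), compute_fcr(9.55, 1.71))
  expect_warning(out <- compute_fcr(c(8, 8), c(2, 0)), "undefined")
  expect_true(is.na(out[2]))
})

test_that("carcass specific gravity follows CW/(CW - CW_H2O)", {
  expect_equal(carcass_specific_gravity(300, 0), 1.0)
  expect_equal(carcass_specific_gravity(324, 24), 1.08)
  # strictly decreasing in the water weight... i.e. increasing in CW_H2O
  expect_true(carcass_specific_gravity(324, 30) >
                carcass_specific_gravity(324, 24))
  expect_gt(carcass_specific_gravity(300, 1), 1)
  expect_error(carcass_specific_gravity(300, 300), "CW > CW_H2O")
  expect_error(carcass_specific_gravity(300, -1), ">= 0")
})

test_that("feeding summaries obey their identities", {
  s <- summarize_feeding(rep(2, 10), days = 1)
  expect_equal(s$visits_per_day, 10)
  expect_equal(s$min_per_visit, 2)
  expect_equal(s$min_per_day, 20)
  expect_equal(s$visits_per_day * s$min_per_visit, s$min_per_day)
  s0 <- summarize_feeding(numeric(0), days = 5)
  expect_equal(s0$visits_per_day, 0)
  expect_true(is.na(s0$min_per_visit))
  expect_equal(s0$min_per_day, 0)
  expect_error(summarize_feeding(1, days = 0), "zero recorded days")
})

test_that("group differences handle degenerate and planted cases", {
  g <- rep(c("low", "high"), each = 4)
  same <- group_difference(rep(5, 8), g)
  expect_equal(same$difference, 0)
  expect_equal(same$p, 1)
  set.seed(2)
  x <- rnorm(8, 0, 1e-6) + ifelse(g == "low", 0.5, 0)
  gd <- group_difference(x, g)
  expect_equal(gd$difference, 0.5, tolerance = 1e-5)
  expect_lt(gd$p, 1e-6)
  swapped <- group_difference(x, ifelse(g == "low", "high", "low"))
  expect_equal(swapped$difference, -gd$difference)
  expect_equal(swapped$p, gd$p)
  # pooled variance option agrees with t.test
  set.seed(3)
  y <- rnorm(8)
  tt <- t.test(y[g == "low"], y[g == "high"], var.equal = TRUE)
  gp <- group_difference(y, g, var_equal = TRUE)
  expect_equal(gp$p, tt$p.value, tolerance = 1e-10)
  tw <- t.test(y[g == "low"], y[g == "high"])
  gw <- group_difference(y, g)
  expect_equal(gw$p, tw$p.value, tolerance = 1e-10)
  expect_error(group_difference(y[1:5], g[1:5]), ">= 2")
})

test_that("analytic power behaves across its arguments", {
  # null case: fold change 1 returns alpha
  expect_equal(de_power(8, fc = 1), 0.05)
  # the study design reaches 80% power in the high-depth regime
  expect_gte(de_power(8, 1.8, 0.4, 0.05, depth = Inf), 0.80)
  # monotone in n, fc and depth; decreasing in cv
  expect_true(de_power(10, 1.8, 0.4) > de_power(8, 1.8, 0.4))
  expect_true(de_power(8, 2.0, 0.4) > de_power(8, 1.8, 0.4))
  expect_true(de_power(8, 1.8, 0.4, depth = 1e4) >
                de_power(8, 1.8, 0.4, depth = 10))
  expect_true(de_power(8, 1.8, 0.3) > de_power(8, 1.8, 0.5))
  # inversion: the stated design needs at most 8 per group
  expect_lte(required_n(0.8, 1.8, 0.4, 0.05, depth = Inf), 8)
  expect_equal(required_n(0.8, 1.8, 0.4, 0.05, depth = Inf),
               ceiling(2 * (qnorm(0.975) + qnorm(0.8))^2 * 0.16 /
                         log(1.8)^2))
  expect_error(required_n(0.8, fc = 1), "cannot reach")
})

test_that("simulated power tracks the analytic value", {
  set.seed(5)
  p <- simulate_de_power(n = 8, fc = 1.8, cv = 0.4, alpha = 0.05,
                         depth = 2000, n_genes = 1500)
  expect_equal(p, de_power(8, 1.8, 0.4, 0.05, depth = 2000),
               tolerance = 0.05)
  set.seed(6)
  null_p <- simulate_de_power(n = 8, fc = 1, cv = 0.4, depth = 2000,
                              n_genes = 1500)
  expect_lt(abs(null_p - 0.05), 0.02)
})

test_that("derive_phenotypes assembles a full trait table", {
  ph <- derive_phenotypes(simulate_phenotypes(small_design(seed = 17)))
  expect_equal(nrow(ph$table), 8)
  expect_true(all(c("adg", "mmw", "dmi", "rfi", "fcr", "visits_per_day",
                    "specific_gravity") %in% names(ph$table)))
  expect_lt(abs(mean(ph$table$rfi)), 1e-10)
  expect_true(all(ph$table$specific_gravity > 1))
  gd <- ph$group_differences
  expect_equal(gd$mean[gd$trait == "rfi"], 0, tolerance = 1e-10)
})
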