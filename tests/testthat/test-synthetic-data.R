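test_that("identical seed and parameters give bit-identical output", {
  d <- small_design(seed = 42)
  s1 <- simulate_expression(d, small_params())
  s2 <- simulate_expression(d, small_params())
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$truth, s2$truth)
  p1 <- simulate_phenotypes(d)
  p2 <- simulate_phenotypes(d)
  expect_identical(p1$weights, p2$weights)
  expect_identical(p1$events, p2$events)
})

test_that("design invariants are enforced", {
  expect_error(experiment_design(animals_per_sire = 1), "animals_per_sire")
  expect_error(experiment_design(tissues = c("a", "a")), "unique")
  expect_error(experiment_design(n_genes = 50, n_tf = 40, n_snp_genes = 20),
               "exceed")
  expect_error(
    simulate_expression(small_design(),
                        small_params(n_hub_tf = 2, hub_module_size = 100)),
    "infeasible")
})

test_that("per-sample totals equal the target depth", {
  s <- simulate_expression(small_design(seed = 3), small_params())
  expect_true(all(colSums(s$counts$counts) == 5e5))
})

test_that("planted DE log2 ratio is recovered at vanishing noise", {
  # cv -> 0, deep depth, animal effects off: per-tissue group log2 ratio
  # of planted DE genes equals the planted fold change within Poisson
  # error
  d <- small_design(seed = 9, n_genes = 200)
  p <- small_params(biological_cv = 0, animal_sd = 0, de_log2fc = 1,
                    de_fraction = 0.2, n_hub_tf = 0, depth_mean = 5e6)
  s <- simulate_expression(d, p)
  em <- compute_rpkm(s$counts, s$meta)
  lo <- s$meta$sire == "low"; hi <- s$meta$sire == "high"
  de <- names(s$truth$true_de)
  ratio <- log2(rowMeans(em$rpkm[de, lo]) / rowMeans(em$rpkm[de, hi]))
  expect_equal(unname(ratio), unname(s$truth$true_de), tolerance = 0.1)
})

test_that("de_fraction 0 builds a null with empty truth", {
  # enough genes that compositional coupling through the fixed library
  # size cannot shift the panel-wide group difference
  s <- simulate_expression(small_design(seed = 2, n_genes = 500),
                           small_params(de_fraction = 0, n_hub_tf = 0))
  expect_length(s$truth$true_de, 0)
  em <- compute_rpkm(s$counts, s$meta)
  lo <- s$meta$sire == "low"; hi <- s$meta$sire == "high"
  dif <- log2(rowMeans(em$rpkm[, lo]) + 0.2) -
    log2(rowMeans(em$rpkm[, hi]) + 0.2)
  expect_lt(abs(mean(dif)), 0.05)
})

test_that("2/3 classifier recovers all planted TS genes at cv -> 0", {
  d <- small_design(seed = 5, n_genes = 200)
  s <- simulate_expression(d, small_params(biological_cv = 0,
                                           animal_sd = 0, n_hub_tf = 0,
                                           depth_mean = 5e6))
  em <- compute_rpkm(s$counts, s$meta)
  ts <- classify_tissue_specific(tissue_share(em))
  called <- ts$gene[ts$is_ts]
  expect_true(all(names(s$truth$true_ts) %in% called))
  # and the dominant tissue matches the planted one
  dom <- setNames(ts$tissue, ts$gene)[names(s$truth$true_ts)]
  expect_identical(unname(dom), unname(s$truth$true_ts))
})

test_that("hub modules are recorded and feasible", {
  s <- simulate_expression(small_design(seed = 4), small_params())
  expect_length(s$truth$true_hubs, 2)
  mem <- unlist(s$truth$true_hubs)
  expect_true(all(mem %in% s$annotation$gene))
  expect_false(any(mem %in% names(s$truth$true_hubs)))
  expect_true(all(names(s$truth$true_hubs) %in%
                    s$annotation$gene[s$annotation$is_tf]))
})

test_that("noiseless phenotypes recover the planted structure", {
  # with no sire shift, noiseless DMI is exactly linear in ADG and MMW
  # and the planted coefficients come back to machine precision
  d <- small_design(seed = 8)
  p0 <- pheno_params(weight_noise_sd = 0, rfi_noise_sd = 0,
                     daily_dmi_sd = 0, rfi_delta = 0)
  ph0 <- derive_phenotypes(simulate_phenotypes(d, p0))
  expect_equal(unname(ph0$rfi_fit$coefficients), c(-1.3, 2.0, 0.10),
               tolerance = 1e-8)
  expect_equal(max(abs(ph0$table$rfi)), 0, tolerance = 1e-8)

  # with a planted shift, the residual group difference recovers it up
  # to the (finite-sample) projection of the group contrast onto the
  # ADG/MMW design (expected leakage ~ 2/(n_animals - 1))
  p1 <- pheno_params(weight_noise_sd = 0, rfi_noise_sd = 0,
                     daily_dmi_sd = 0, rfi_delta = -0.5)
  g <- derive_phenotypes(
    simulate_phenotypes(experiment_design(seed = 8), p1))$table
  dif <- mean(g$rfi[g$sire == "low"]) - mean(g$rfi[g$sire == "high"])
  expect_lt(abs(dif - (-0.5)), 0.15)
})

test_that("RFI group difference equals the shift exactly when the groups
           are covariate-balanced", {
  # mirrored pairs: every low animal has a high twin with identical ADG
  # and MMW, so the group contrast is orthogonal to the design and the
  # planted shift lands entirely in the residuals
  adg <- c(1.2, 1.5, 1.8, 2.1); mmw <- c(70, 76, 79, 88)
  delta <- -0.5
  dmi <- 1 + 2 * c(adg, adg) + 0.1 * c(mmw, mmw) +
    rep(c(delta / 2, -delta / 2), each = 4)
  fit <- compute_rfi(dmi, c(adg, adg), c(mmw, mmw))
  dif <- mean(fit$table$rfi[1:4]) - mean(fit$table$rfi[5:8])
  expect_equal(dif, delta, tolerance = 1e-10)
})

test_that("zero growth slope gives ADG 0 and MMW = w0^0.75", {
  d <- small_design(seed = 6)
  p <- pheno_params(adg_mean = 0, adg_sd = 0, weight_noise_sd = 0)
  ph <- simulate_phenotypes(d, p)
  w <- ph$weights[ph$weights$animal == ph$animals$animal[1], ]
  expect_equal(compute_adg(w$day, w$weight), 0, tolerance = 1e-12)
  expect_equal(compute_mmw(w$weight), w$weight[1]^0.75, tolerance = 1e-10)
})

test_that("planted bunk-visit rate difference is recovered", {
  d <- experiment_design(animals_per_sire = 8, seed = 13)
  ph <- simulate_phenotypes(d)
  g <- derive_phenotypes(ph)$table
  dif <- mean(g$visits_per_day[g$sire == "low"]) -
    mean(g$visits_per_day[g$sire == "high"])
  # Poisson process over 70 d per animal: se of the difference ~ 0.45
  expect_equal(dif, -12.9, tolerance = 2)
  expect_true(all(ph$weights$weight > 0))
})

test_that("bad phenotype parameters error", {
  expect_error(pheno_params(initial_weight_mean = -5), "positive")
})
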