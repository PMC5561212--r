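test_that("simulators are deterministic under a fixed seed", {
  p <- colony_sim_params(image_size = 128, colony_radius = 120,
                         noise_sd = 8, seed = 3)
  a <- simulate_colony_image(p)
  b <- simulate_colony_image(p)
  expect_identical(a$image$intensities, b$image$intensities)

  cp <- cohort_sim_params(doses = c(0, 1, 2, 4), true_ldc = 2, seed = 5)
  expect_identical(simulate_feature_table(cp), simulate_feature_table(cp))

  v1 <- simulate_viability(true_ic50 = 3, max_dose = 100, seed = 8)
  v2 <- simulate_viability(true_ic50 = 3, max_dose = 100, seed = 8)
  expect_identical(v1$viability, v2$viability)
})

test_that("parameter validation rejects impossible colonies and cohorts", {
  expect_error(colony_sim_params(ring_center = 0.95, ring_width = 0.3),
               "within")
  expect_error(colony_sim_params(noise_sd = -1), "noise_sd")
  expect_error(cohort_sim_params(doses = c(0, 2, 1)), "ascending")
  expect_error(cohort_sim_params(doses = c(0, 1, 2), true_ldc = 5),
               "true_ldc")
  expect_error(cohort_sim_params(doses = c(0, 1), replicates_per_dose = 1),
               "replicates")
  expect_error(simulate_viability(true_ic50 = 10, true_bottom = 1.2,
                                  max_dose = 10),
               "true_top")
  expect_error(simulate_colony_image(colony_sim_params(), dose = -1), "dose")
})

test_that("disruption modes move the ring as designed, monotonically", {
  p <- colony_sim_params(image_size = 128, colony_radius = 120, noise_sd = 0)
  doses <- c(0, 1, 5, 25, 125)

  ctrl <- simulate_colony_image(p)$truth
  expect_equal(ctrl$ring_center_effective, 0.65)

  block <- disruption_model("migration_block", potency = 5)
  rc <- vapply(doses, function(d)
    simulate_colony_image(p, block, d)$truth$ring_center_effective, 1)
  expect_true(all(diff(rc) > 0))
  expect_gt(rc[5], 0.65)

  accel <- disruption_model("migration_accel", potency = 5)
  rc2 <- vapply(doses, function(d)
    simulate_colony_image(p, accel, d)$truth$ring_center_effective, 1)
  expect_true(all(diff(rc2) < 0))

  dim_ <- disruption_model("diff_loss", potency = 5)
  ri <- vapply(doses, function(d)
    simulate_colony_image(p, dim_, d)$truth$ring_intensity_effective, 1)
  expect_true(all(diff(ri) < 0))

  loss <- disruption_model("cell_loss", potency = 5)
  rad <- vapply(doses, function(d)
    simulate_colony_image(p, loss, d)$truth$radius, 1)
  expect_true(all(diff(rad) < 0))

  # ring parameters always stay inside the unit radius
  for (d in doses) {
    t1 <- simulate_colony_image(p, block, d)$truth
    expect_lte(t1$ring_center_effective + t1$ring_width / 2, 1)
    t2 <- simulate_colony_image(p, accel, d)$truth
    expect_gte(t2$ring_center_effective - t2$ring_width / 2, 0)
  }
})

test_that("feature cohorts honour their distributional contract", {
  doses <- c(0, 1, 2, 4, 8)
  cp <- cohort_sim_params(doses = doses, replicates_per_dose = 3000,
                          true_ldc = 4,
                          effect_sizes = c(area = 2, position = 5,
                                           sd = 0, cv = 0),
                          seed = 11)
  tab <- simulate_feature_table(cp)
  ctrl <- tab[tab$dose == 0, ]
  # control moments match the requested baselines / SDs (3000 replicates)
  expect_equal(mean(ctrl$position), 0.65, tolerance = 0.005)
  expect_equal(sd(ctrl$position), 0.02, tolerance = 0.05)
  # below the true LDC: unshifted; at and above: shifted by effect * SD
  expect_equal(mean(tab$position[tab$dose == 2]), 0.65, tolerance = 0.005)
  expect_equal(mean(tab$position[tab$dose == 4]), 0.65 + 5 * 0.02,
               tolerance = 0.005)
  expect_equal(mean(tab$area[tab$dose == 8]), 0.4 + 2 * 0.03,
               tolerance = 0.01)
  expect_equal(mean(tab$sd[tab$dose == 8]), 0.08, tolerance = 0.002)
})

test_that("null cohorts yield censored calls at about the theoretical rate", {
  # with no effect anywhere, the call is non-censored only when the top dose
  # is significant in some feature: rate = 1 - (1 - alpha)^4 under the null
  doses <- c(0, 1, 2, 4, 8)
  alpha <- 0.05   # larger alpha keeps the Monte-Carlo error manageable
  called <- vapply(1:400, function(s) {
    tab <- simulate_feature_table(
      cohort_sim_params(doses = doses, replicates_per_dose = 12,
                        true_ldc = NA, seed = s))
    !is_censored(call_ldc_from_table(tab, alpha = alpha)$ldc)
  }, TRUE)
  expected <- 1 - (1 - alpha)^4
  expect_lt(abs(mean(called) - expected), 0.04)
})

test_that("viability simulator matches the 4PL exactly at zero noise", {
  v <- simulate_viability(true_top = 1, true_bottom = 0.1, true_ic50 = 4,
                          hill = 2, max_dose = 500, cv_noise = 0, seed = 1)
  expect_equal(length(unique(v$dose)), 8L)       # 8-point 5-fold series
  expect_equal(max(v$dose) / sort(unique(v$dose))[7], 5)
  mu <- 0.1 + 0.9 / (1 + (v$dose / 4)^2)
  expect_equal(v$viability, mu)
})

test_that("colony TIFF round-trips through disk with its truth sidecar", {
  p <- colony_sim_params(image_size = 128, colony_radius = 100,
                         noise_sd = 5, seed = 2)
  sim <- simulate_colony_image(p)
  tmp <- withr::local_tempfile(fileext = ".tif")
  paths <- write_colony_tiff(sim, tmp)
  expect_true(all(file.exists(paths)))

  truth <- jsonlite::read_json(paths[["truth"]])
  img <- read_colony_tiff(paths[["image"]], pixel_size = truth$pixel_size)
  restored <- img$intensities * truth$intensity_scale
  # 16-bit quantization only
  expect_lt(max(abs(restored - sim$image$intensities)),
            truth$intensity_scale / 2^15)
  expect_equal(truth$radius, sim$truth$radius)
})
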