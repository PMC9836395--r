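test_that("the Bicoid gradient is exponential with the stated decay length", {
  bp <- simulate_bicoid_profile(amplitude = 250, length_const = 0.2)
  i1 <- which(bp$ap_fraction == 0.20)
  i2 <- which(bp$ap_fraction == 0.40)
  expect_equal(bp$mean[i1] / bp$mean[i2], exp(1), tolerance = 1e-12)
  # the gradient crosses the default Kb (30 AU) in the 35-50% EL window,
  # where the expression boundary sits
  cross <- bp$ap_fraction[which.min(abs(bp$mean - 30))]
  expect_gte(cross, 0.35)
  expect_lte(cross, 0.50)
  expect_error(simulate_bicoid_profile(grid = numeric(0)), "empty")
  expect_error(simulate_bicoid_profile(amplitude = -1), "amplitude")
})

test_that("the Runt profile is logistic, and null embryos have none", {
  rp <- simulate_runt_profile(floor = 10, ceiling = 120, midpoint = 0.35,
                              steepness = 20)
  expect_true(all(rp$mean >= 0))
  expect_true(all(diff(rp$mean) > 0))
  # half-maximal crossing at the midpoint
  mid_val <- approx(rp$ap_fraction, rp$mean, xout = 0.35)$y
  expect_equal(mid_val, (10 + 120) / 2, tolerance = 1e-9)
  flat <- simulate_runt_profile(floor = 50, ceiling = 50)
  expect_true(all(flat$mean == 50))
  null <- simulate_runt_profile(runt_null = TRUE)
  expect_true(all(null$mean == 0) && all(null$sem == 0))
})

test_that("simulated rate profiles are the model forward-pushed through noise", {
  truth0 <- noiseless_truth()
  bic <- simulate_bicoid_profile(scale_sd = 0)
  run <- simulate_runt_profile(scale_sd = 0)
  prof <- simulate_rate_profiles("011", truth0, bic, run, n_embryos = 3,
                                 seed = 5)
  pred <- predict_profile(bic, run, enhancer_architecture("011"),
                          truth0$activation[["011"]], truth0$repression)
  expect_equal(prof[["011_runt_wt"]]$mean, pred$mean, tolerance = 1e-12)
  expect_true(all(prof[["011_runt_wt"]]$sem == 0))
  # runt-null shares activation parameters by construction
  pred0 <- predict_profile(bic, NULL, enhancer_architecture("011"),
                           truth0$activation[["011"]], truth0$repression,
                           genotype = "runt_null")
  expect_equal(prof[["011_runt_null"]]$mean, pred0$mean, tolerance = 1e-12)
  # determinism under a fixed seed
  truth <- default_ground_truth()
  a <- simulate_rate_profiles(c("000", "111"), truth, bic, run, seed = 42)
  b <- simulate_rate_profiles(c("000", "111"), truth, bic, run, seed = 42)
  expect_identical(a, b)
  expect_error(simulate_rate_profiles("000", truth, bic, run, n_embryos = 1),
               "n_embryos")
})

test_that("profile SEM scales as one over the square root of embryo number", {
  truth <- default_ground_truth()
  bic <- simulate_bicoid_profile()
  run <- simulate_runt_profile()
  mean_sem <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      p <- simulate_rate_profiles("000", truth, bic, run, n_embryos = n,
                                  seed = s, genotypes = "runt_null")
      mean(p[["000_runt_null"]]$sem[1:8])  # high-signal bins
    }, numeric(1)))
  }
  r <- mean_sem(4, 1:200) / mean_sem(16, 1:200)
  expect_gt(r, 2 * 0.8)
  expect_lt(r, 2 * 1.2)
})

test_that("cooperative truths shift repression in the direction of their sign", {
  truth <- default_ground_truth()
  neut <- neutral_truth()
  bic <- simulate_bicoid_profile()
  run <- simulate_runt_profile()
  mid <- 3:10  # bins where both Runt and Bicoid act
  # [011]: omega_rrp > 1 -> less repression than the neutral prediction
  w011 <- predict_profile(bic, run, enhancer_architecture("011"),
                          truth$activation[["011"]], truth$repression)$mean
  n011 <- predict_profile(bic, run, enhancer_architecture("011"),
                          truth$activation[["011"]], neut$repression)$mean
  expect_true(all(w011[mid] >= n011[mid]))
  # [110]: omega_rr > 1 with omega_rrp << 1 -> more repression than neutral
  w110 <- predict_profile(bic, run, enhancer_architecture("110"),
                          truth$activation[["110"]], truth$repression)$mean
  n110 <- predict_profile(bic, run, enhancer_architecture("110"),
                          truth$activation[["110"]], neut$repression)$mean
  expect_true(all(w110[mid] <= n110[mid]))
})

test_that("MS2 traces rise linearly from onset and plateau", {
  tr <- simulate_ms2_traces(rate = 5, t_on = 2, plateau_time = 12,
                            noise_sd = 0, seed = 1)[[1]]
  on <- !is.na(tr$fluorescence)
  expect_true(all(tr$time_min[!on] <= 2 + 1e-9))
  in_rise <- on & tr$time_min <= 12
  expect_equal(tr$fluorescence[in_rise], 5 * (tr$time_min[in_rise] - 2),
               tolerance = 1e-12)
  expect_true(all(tr$fluorescence[on & tr$time_min > 12] == 5 * 10))
  # a silent locus never produces fluorescence
  silent <- simulate_ms2_traces(rate = 0, seed = 1)[[1]]
  expect_true(all(is.na(silent$fluorescence)))
})

test_that("ground truth round-trips through its YAML sidecar", {
  truth <- default_ground_truth()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_ground_truth(truth, path)
  back <- read_ground_truth(path)
  expect_equal(back, truth, tolerance = 1e-12)
  # and the reloaded truth regenerates the dataset bit-identically
  bic <- simulate_bicoid_profile()
  run <- simulate_runt_profile()
  expect_identical(simulate_rate_profiles("110", truth, bic, run, seed = 9),
                   simulate_rate_profiles("110", back, bic, run, seed = 9))
})

test_that("the study bundle is complete and deterministic", {
  st <- simulate_study(seed = 4)
  expect_setequal(names(st$profiles),
                  c(paste0(all_construct_ids(), "_runt_null"),
                    paste0(all_construct_ids(), "_runt_wt")))
  expect_identical(st$profiles, simulate_study(seed = 4)$profiles)
  expect_false(identical(st$profiles, simulate_study(seed = 5)$profiles))
})
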