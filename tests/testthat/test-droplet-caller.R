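test_that("two well-separated spikes give a threshold between them", {
  set.seed(31)
  amp <- sample(rep(c(1000, 9000), each = 500))
  ctrl <- new_droplet_well("CTRL", "ch1", amp, role = "positive_control")
  fit <- fit_control_density(ctrl)
  expect_gt(fit$minimum, 1000)
  expect_lt(fit$minimum, 9000)
  expect_equal(fit$neg_median, 1000)
  expect_equal(sort(round(fit$maxima, -2)), c(1000, 9000))
})

test_that("a unimodal control is rejected as a control failure", {
  set.seed(32)
  uni <- new_droplet_well("CTRL", "ch1", rnorm(8000, 2000, 300),
                          role = "positive_control")
  expect_error(fit_control_density(uni), "control failure.*CTRL")
  flat <- new_droplet_well("CTRL", "ch1", rep(2000, 100),
                           role = "positive_control")
  expect_error(fit_control_density(flat), "control failure")
  test_well <- new_droplet_well("W1", "ch1", rnorm(100, 2000, 300))
  expect_error(fit_control_density(test_well), "positive control")
})

test_that("the fitted bandwidth is the smallest two-mode bandwidth to tolerance", {
  set.seed(33)
  for (i in 1:10) {
    ctrl <- make_control(n = 6000,
                         neg = runif(1, 1500, 2500),
                         pos = runif(1, 7000, 9000),
                         spread = runif(1, 200, 400),
                         occupancy = runif(1, 0.3, 0.7))
    fit <- fit_control_density(ctrl)
    expect_equal(count_density_maxima(ctrl$amplitudes, fit$bandwidth), 2L)
    if (!is.na(fit$bracket_lo)) {
      expect_gt(count_density_maxima(ctrl$amplitudes, fit$bracket_lo), 2L)
      expect_lte((fit$bandwidth - fit$bracket_lo) / fit$bracket_lo,
                 1.01e-3)
    }
    # mode count is non-increasing in bandwidth
    counts <- vapply(fit$bandwidth * c(1, 1.5, 2, 4, 8),
                     function(h) count_density_maxima(ctrl$amplitudes, h),
                     integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("normalization recovers constructed offsets and flags all-positive wells", {
  set.seed(34)
  ctrl <- make_control()
  fit <- fit_control_density(ctrl)
  # identity
  same <- new_droplet_well("W0", "ch1", ctrl$amplitudes)
  n0 <- normalize_well(same, fit)
  expect_equal(n0$shift, 0)
  # constructed +500 offset
  up <- new_droplet_well("W1", "ch1", ctrl$amplitudes + 500)
  n1 <- normalize_well(up, fit)
  expect_equal(n1$shift, -500)
  expect_equal(n1$well$amplitudes, ctrl$amplitudes)
  # no identifiable negative population
  allpos <- new_droplet_well("W2", "ch1", rnorm(2000, 8000, 300))
  n2 <- normalize_well(allpos, fit)
  expect_equal(n2$flags, "no_negative_population")
  expect_equal(n2$shift, 0)
  expect_equal(n2$well$amplitudes, allpos$amplitudes)
})

test_that("droplet calls are shift-invariant and match generator ground truth", {
  spec <- plate_gen_spec(c(W1 = 120, NTC = 0), droplets_per_well = 16000,
                         rain_fraction = 0, seed = 35L)
  plate <- generate_plate(spec)
  res <- call_plate(plate)
  truth <- stats::setNames(plate$truth$occupied, plate$truth$well)
  calls <- stats::setNames(res$calls$P, res$calls$well)
  # clean plate: every occupied droplet and nothing else crosses the cut
  expect_equal(calls[["W1"]], truth[["W1"]])
  expect_equal(calls[["NTC"]], 0L)
  # adding a constant to a test well leaves its call unchanged
  w <- plate$wells$W1
  shifted <- new_droplet_well(w$well_id, w$channel, w$amplitudes + 300)
  c_orig <- call_droplets(normalize_well(w, res$fit), res$fit)
  c_shift <- call_droplets(normalize_well(shifted, res$fit), res$fit)
  expect_equal(c_shift$P, c_orig$P)
  expect_equal(c_shift$N, c_orig$N)
  expect_equal(c_shift$shift, c_orig$shift - 300)
})

test_that("the classified positive fraction tracks true occupancy over replicate plates", {
  set.seed(36)
  p_hat <- truth_occ <- numeric(20)
  for (i in 1:20) {
    plate <- generate_plate(plate_gen_spec(
      c(W = 200), droplets_per_well = 8000, rain_fraction = 0,
      seed = 100L + i))
    res <- call_plate(plate)
    p_hat[i] <- res$calls$P[res$calls$well == "W"]
    truth_occ[i] <- plate$truth$occupied[plate$truth$well == "W"]
  }
  expect_equal(p_hat, truth_occ)
  expect_lt(abs(mean(p_hat) - 8000 * (1 - exp(-200 / 8000))),
            4 * sd(truth_occ) / sqrt(20) + 4 * sqrt(200) / sqrt(20))
})
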