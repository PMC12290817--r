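test_that("normalized amplitude and distance follow their definitions", {
  expect_identical(normalized_amplitude(rep(0, 14), kappa = 15), 0)
  expect_identical(normalized_amplitude(rep(1, 14), kappa = 15), 1)
  expect_equal(normalized_amplitude(c(3, 4)), sqrt(12.5))
  expect_identical(normalized_distance(1:14, 1:14, kappa = 15), 0)
  # antipodal collinear vectors of norm sqrt(14): normalized distance 2
  v <- c(sqrt(14), rep(0, 13))
  expect_equal(normalized_distance(v, -v, kappa = 15), 2)
  expect_error(normalized_distance(1:3, 1:4), "equal length")
  expect_error(normalized_amplitude(1:5, kappa = 15), "kappa")
  # matrix input vectorizes over rows
  m <- rbind(rep(1, 14), rep(2, 14))
  expect_equal(normalized_amplitude(m, kappa = 15), c(1, 2))
})

test_that("the hypersphere baseline matches Monte-Carlo and known chords", {
  mc <- function(sphere_dim, N = 4e4, seed = 1) {
    withr::with_seed(seed, {
      x <- matrix(rnorm(N * (sphere_dim + 1)), N)
      y <- matrix(rnorm(N * (sphere_dim + 1)), N)
    })
    x <- x / sqrt(rowSums(x^2))
    y <- y / sqrt(rowSums(y^2))
    mean(sqrt(rowSums((x - y)^2)))
  }
  expect_equal(expected_random_distance(1), 4 / pi) # circle chord
  expect_equal(expected_random_distance(2), 4 / 3) # sphere chord
  for (n in c(1, 2, 5, 14)) {
    expect_equal(expected_random_distance(n), mc(n), tolerance = 0.005)
  }
  # monotone increase towards sqrt(2)
  vals <- vapply(1:60, expected_random_distance, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_lt(sqrt(2) - vals[60], 0.005)
  expect_error(expected_random_distance(0), "positive")
  expect_error(expected_random_distance(2.5), "positive")
})

test_that("mean normalized distance of standardized patterns nears the baseline", {
  withr::with_seed(2, {
    Y <- matrix(rnorm(400 * 14), 400, 14)
  })
  d <- as.vector(dist(Y)) / sqrt(14)
  expect_equal(mean(d), expected_random_distance(14), tolerance = 0.015)
})

test_that("pairwise sets cover exactly the within-run recurring pairs", {
  seqs <- make_sequences(2, seed = 51)
  spec <- parcel_spec("p1", n_vox = 45, n_t = 1, identity_snr = 0.3)
  prs <- simulate_parcel(spec, seqs, the_graph, seed = 3)
  rec <- prs$trial_meta$is_recurring
  sub <- fit_dlda(prs$responses[rec, ], prs$trial_meta$object_id[rec])
  Y <- project_subspace(sub, prs$responses)
  dset <- compute_pairwise(Y, prs$trial_meta, observer_id = 7L, parcel_id = "p1")
  expect_identical(nrow(dset), as.integer(2 * choose(180, 2)))
  expect_true(all(dset$delay >= 1))
  expect_true(all(dset$k < dset$l))
  expect_true(all(dset$i <= 15 & dset$j <= 15)) # singulars excluded
  expect_true(all(dset$d_raw >= 0))
  # spot-check one record against a hand-computed distance
  row <- dset[5000, ]
  ki <- which(prs$trial_meta$run_id == row$run_id &
    prs$trial_meta$trial_index == row$k)
  li <- which(prs$trial_meta$run_id == row$run_id &
    prs$trial_meta$trial_index == row$l)
  expect_equal(row$d_raw, normalized_distance(Y[ki, ], Y[li, ], kappa = 15))
  expect_error(compute_pairwise(Y, prs$trial_meta[1:10, ]), "aligned")
})

test_that("delay profiles average by delay and correction recenters them", {
  d <- fake_dset(
    i = rep(1:5, 4), j = rep(2:6, 4),
    delay = rep(1:4, each = 5), d = rep(c(1, 2, 3, 4), each = 5) + 0.1 * (1:20 %% 2)
  )
  prof <- delay_profile(d)
  expect_identical(prof$delay, 1:4)
  expect_equal(prof$t_mean, c(1.06, 2.04, 3.06, 4.04))
  expect_equal(attr(prof, "grand_mean"), mean(prof$t_mean))
  corr <- residual_correct(d, prof)
  per_delay <- as.vector(tapply(corr$d_corr, corr$delay, mean))
  expect_equal(per_delay, rep(attr(prof, "grand_mean"), 4))
  # flat profile: correction is the identity
  flat <- fake_dset(i = rep(1, 6), j = rep(2, 6), delay = 1:6, d = rep(1.4, 6))
  expect_equal(residual_correct(flat, delay_profile(flat))$d_corr, flat$d_raw)
  # idempotence: recomputing the profile on corrected distances changes nothing
  prof2 <- delay_profile(transform(corr, d_raw = d_corr))
  corr2 <- residual_correct(transform(corr, d_raw = d_corr), prof2)
  expect_equal(corr2$d_corr, corr$d_corr, tolerance = 1e-12)
  # missing delay is an error, not a silent fallback
  expect_error(
    residual_correct(fake_dset(1, 2, delay = 9L, d = 1), prof),
    "delay"
  )
})

test_that("calibrated drift produces the short-delay distance dip", {
  res <- sim_corrected_dset(61, identity_snr = 0, drift_sd = 0.43, runs = 4)
  prof <- res$profile
  rel <- prof$t_mean / attr(prof, "grand_mean")
  dip <- mean(rel[prof$delay < 4])
  expect_lt(abs((1 - dip) - 0.05), 0.02) # ~5% smaller at delays < 4
  # monotone recovery: delays 6..15 sit above the short-delay level
  expect_gt(mean(rel[prof$delay %in% 6:15]), dip)
  # corrected distances are flat across delays
  corr_prof <- delay_profile(transform(res$dset, d_raw = d_corr))
  rel_corr <- corr_prof$t_mean / attr(corr_prof, "grand_mean")
  expect_lt(max(abs(rel_corr[corr_prof$delay < 10] - 1)), 0.01)
})

test_that("drift-free data yields a flat delay profile", {
  res <- sim_corrected_dset(62, identity_snr = 0, drift_sd = 0, runs = 3)
  prof <- res$profile
  rel <- prof$t_mean / attr(prof, "grand_mean")
  expect_lt(max(abs(rel[prof$delay <= 20] - 1)), 0.03)
})
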