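test_that("noiseless B-factors are fit exactly with perfect correlation", {
  raw_msf <- c(0.5, 1.2, 0.8, 2.0, 1.1)
  exp_b <- 2.0 * msf_to_bfactor(raw_msf)
  fit <- fit_scale(raw_msf, exp_b)
  expect_equal(fit$scale_kbt_over_gamma, 2.0, tolerance = 1e-12)
  expect_equal(fit$pearson_r, 1.0, tolerance = 1e-12)
  expect_equal(fit$n_residues, 5L)
})

test_that("the generating scale is recovered from noisy synthetic B-factors", {
  withr::with_seed(17, {
    raw_msf <- stats::runif(200, 0.2, 2)
    raw_b <- msf_to_bfactor(raw_msf)
    exp_b <- 3.7 * raw_b + stats::rnorm(200, sd = 0.05 * mean(3.7 * raw_b))
  })
  fit <- fit_scale(raw_msf, exp_b)
  expect_lt(abs(fit$scale_kbt_over_gamma - 3.7) / 3.7, 0.02)
  expect_gt(fit$pearson_r, 0.95)
})

test_that("the fitted correlation is invariant to positive rescaling", {
  withr::with_seed(18, {
    raw <- stats::runif(50, 0.1, 3)
    expb <- 5 * raw + stats::rnorm(50, sd = 0.3)
  })
  expb <- pmax(expb, 0.01)
  r0 <- fit_scale(raw, expb)$pearson_r
  expect_equal(fit_scale(10 * raw, expb)$pearson_r, r0, tolerance = 1e-12)
  expect_equal(fit_scale(raw, 0.3 * expb)$pearson_r, r0, tolerance = 1e-12)
})

test_that("degenerate scale-fit inputs raise errors", {
  expect_error(fit_scale(c(1, 2, 3), rep(4, 3)), "constant")
  expect_error(fit_scale(1:2, 1:2), "3 residues")
  expect_error(fit_scale(1:4, 1:3), "length")
})

test_that("difference-distance maps are symmetric, antisymmetric under swap", {
  pair <- make_conformer_pair(seed = 7, angle_deg = 30)
  p <- pair_residues(pair$open, pair$closed)
  d_ab <- difference_distance(pair$open, pair$closed, p)
  expect_equal(unname(d_ab$delta), unname(t(d_ab$delta)))
  expect_equal(diag(d_ab$delta), rep(0, length(p$idx_a)))
  d_ba <- difference_distance(pair$closed, pair$open, pair_residues(pair$closed, pair$open))
  expect_equal(d_ba$delta, -d_ab$delta)
  expect_equal(d_ba$classes, -d_ab$classes)
  # self-comparison: all zero, all unchanged
  d_aa <- difference_distance(pair$open, pair$open)
  expect_true(all(d_aa$delta == 0))
  expect_true(all(d_aa$classes == 0L))
})

test_that("a rigid hinge rotation changes only cross-domain distances", {
  pair <- make_conformer_pair(seed = 8, angle_deg = 30)
  lab <- pair$labels
  d <- difference_distance(pair$open, pair$closed, threshold = 1.5)
  ia <- lab$domain_a; ib <- lab$domain_b
  expect_lt(max(abs(d$delta[ia, ia])), 1e-6)
  expect_lt(max(abs(d$delta[ib, ib])), 1e-6)
  expect_gte(max(abs(d$delta[ia, ib])), 1.5)
  expect_true(any(d$classes[ia, ib] != 0L))
})

test_that("slow-mode fluctuation differences compare normalized shapes", {
  pair <- make_conformer_pair(seed = 9, angle_deg = 41.3)
  p <- pair_residues(pair$open, pair$closed)
  ga <- enm_decompose(build_kirchhoff(pair$open))
  gb <- enm_decompose(build_kirchhoff(pair$closed))
  sa <- gnm_mode_msf(ga, 1); sb <- gnm_mode_msf(gb, 1)
  # identical structures -> all-zero difference
  expect_equal(fluctuation_difference(sa, sa, pair_residues(pair$open, pair$open)),
               rep(0, n_residues(pair$open)))
  fd <- fluctuation_difference(sa, sb, p)
  expect_equal(sum(fd), 0, tolerance = 1e-12)    # full coverage
  # the linker is the common near-zero region of both profiles
  expect_false(which.max(abs(fd)) %in% pair$labels$linker)
  # mismatched mode selections refuse to subtract
  pa <- gnm_msf(ga, modes = 2); pb <- gnm_msf(gb, modes = 3)
  expect_error(fluctuation_difference(pa, pb, p), "mode selections")
})

test_that("hinges are the near-zero local minima of the slow-mode profile", {
  profile <- rep(1, 100)
  profile[48:52] <- c(0.5, 0.2, 0.001, 0.2, 0.5)
  h <- find_hinges(profile)
  expect_equal(h$hinge_index, 50L)
  # consecutive qualifying residues merge into one region
  profile2 <- rep(1, 100)
  profile2[50:53] <- c(0.002, 0.001, 0.0015, 0.03)
  h2 <- find_hinges(profile2)
  expect_equal(h2$hinge_index, 51L)
  expect_warning(h3 <- find_hinges(rep(1, 20)), "flat")
  expect_length(h3$hinge_index, 0L)
  expect_error(find_hinges(c(1, 2)), "window")
})

test_that("dumbbell hinge detection lands inside the labelled linker", {
  hits <- vapply(1:20, function(seed) {
    d <- make_dumbbell(seed = seed)
    lab <- attr(d, "labels")
    g <- enm_decompose(build_kirchhoff(d))
    h <- find_hinges(gnm_mode_msf(g, 1))
    length(h$hinge_index) > 0 && all(h$hinge_index %in% lab$linker)
  }, logical(1))
  expect_gte(sum(hits), 18L)
})

test_that("fast-mode averages are unit-sum localization profiles", {
  g <- enm_decompose(build_kirchhoff(path3()))
  # fastest mode lambda = 3, u = (1, -2, 1)/sqrt(6)
  expect_equal(fast_mode_profile(g, 1), c(1/6, 2/3, 1/6), tolerance = 1e-9)
  s <- random_connected_structure(80, seed = 91)
  gg <- enm_decompose(build_kirchhoff(s))
  expect_equal(sum(fast_mode_profile(gg, 10)), 1, tolerance = 1e-12)
  expect_equal(fast_mode_profile(gg, 1), gg$vectors[, 80]^2, tolerance = 1e-12)
  expect_equal(sum(fast_mode_profile(gg, 10, weighted = TRUE)), 1, tolerance = 1e-12)
  expect_error(fast_mode_profile(g, 3), "non-zero modes")
})

test_that("hot residues are strict local maxima above the floor", {
  spike <- rep(0.01, 50); spike[25] <- 0.5
  expect_equal(find_hot_residues(spike)$peak_index, 25L)
  expect_length(find_hot_residues(rep(0.02, 50))$peak_index, 0L)
  expect_equal(find_hot_residues(c(1/6, 2/3, 1/6))$peak_index, 2L)
})

test_that("hot residues on a dumbbell are tightly packed (high contact number)", {
  d <- make_dumbbell(seed = 10)
  g <- enm_decompose(build_kirchhoff(d))
  hr <- find_hot_residues(fast_mode_profile(g, 10), cutoff_used = 7.3)
  cn <- contact_numbers(d, 7.3)
  expect_gt(length(hr$peak_index), 0L)
  expect_gt(mean(cn[hr$peak_index]), mean(cn))
})

test_that("self-comparison yields a zero rotation angle", {
  d <- make_dumbbell(seed = 11)
  lab <- attr(d, "labels")
  r <- rotation_angle(d, d, fixed_domain = lab$domain_a, moving_domain = lab$domain_b)
  expect_equal(r$angle_deg, 0, tolerance = 1e-6)
  expect_equal(r$rmsd_fixed, 0, tolerance = 1e-9)
})

test_that("generator rotation angles are recovered exactly, and under jitter", {
  for (theta in c(5, 25, 41.3, 90)) {
    pair <- make_conformer_pair(seed = 12, angle_deg = theta)
    lab <- pair$labels
    r <- rotation_angle(pair$open, pair$closed,
                        fixed_domain = lab$domain_a, moving_domain = lab$domain_b)
    expect_equal(r$angle_deg, theta, tolerance = 1e-6)
    rj <- rotation_angle(jitter_structure(pair$open, 0.2, seed = 13),
                         jitter_structure(pair$closed, 0.2, seed = 14),
                         fixed_domain = lab$domain_a, moving_domain = lab$domain_b)
    expect_lt(abs(rj$angle_deg - theta), 1)
  }
})

test_that("rotation angles are invariant under global rigid motions", {
  pair <- make_conformer_pair(seed = 15, angle_deg = 33)
  lab <- pair$labels
  withr::with_seed(16, {
    rot_a <- random_rotation_matrix(); rot_b <- random_rotation_matrix()
    sh_a <- stats::rnorm(3, sd = 30); sh_b <- stats::rnorm(3, sd = 30)
  })
  r0 <- rotation_angle(pair$open, pair$closed,
                       fixed_domain = lab$domain_a, moving_domain = lab$domain_b)
  r1 <- rotation_angle(rigid_motion(pair$open, rot_a, sh_a),
                       rigid_motion(pair$closed, rot_b, sh_b),
                       fixed_domain = lab$domain_a, moving_domain = lab$domain_b)
  expect_equal(r1$angle_deg, r0$angle_deg, tolerance = 1e-6)
})

test_that("degenerate domain selections are rejected", {
  line <- make_chain(20, 3.8, "line")
  expect_error(rotation_angle(line, line, fixed_domain = 1:10, moving_domain = 11:20),
               "collinear")
  d <- make_dumbbell(seed = 17)
  lab <- attr(d, "labels")
  expect_error(rotation_angle(d, d, fixed_domain = 1:2, moving_domain = lab$domain_b),
               "3 paired")
})
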