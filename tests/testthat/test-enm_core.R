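# The path-3 chain (contacts 1-2, 2-3) and the two-bead dimer are solvable
# by hand from the eigenpairs of their 3x3 / 2x2 matrices; those closed-form
# values anchor the whole GNM/ANM stack.

test_that("Kirchhoff matrix construction matches the contact graph", {
  expect_equal(unname(build_kirchhoff(calpha_with_resnums(1))$kirchhoff),
               matrix(0, 1, 1))
  two <- make_chain(2, 3.8, "line")
  expect_equal(unname(build_kirchhoff(two, 7.3)$kirchhoff),
               rbind(c(1, -1), c(-1, 1)))
  g <- build_kirchhoff(path3(), 7.3)
  expect_equal(unname(g$kirchhoff),
               rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)))
  # cutoff comparison is inclusive
  touch <- make_chain(2, 7.3, "line")
  expect_equal(unname(build_kirchhoff(touch, 7.3)$kirchhoff),
               rbind(c(1, -1), c(-1, 1)))
})

test_that("Kirchhoff invariants hold on an irregular structure", {
  s <- random_connected_structure(60, seed = 21)
  g <- build_kirchhoff(s, 7.3)
  k <- g$kirchhoff
  expect_equal(unname(k), unname(t(k)))
  expect_lt(max(abs(rowSums(k))), 1e-9)
  off <- k[row(k) != col(k)]
  expect_true(all(off %in% c(0, -1)))
  expect_equal(unname(diag(k)), as.numeric(contact_numbers(s, 7.3)))
  d <- enm_decompose(g)
  expect_true(all(d$values >= -1e-9))
  expect_equal(unname(crossprod(d$vectors)), diag(60), tolerance = 1e-8)
})

test_that("contact numbers count neighbours within the cutoff", {
  expect_equal(contact_numbers(path3(), 7.3), c(1L, 2L, 1L))
  expect_equal(mean(contact_numbers(path3(), 7.3)), 4 / 3)
  expect_equal(contact_numbers(calpha_with_resnums(1), 7.3), 0L)
})

test_that("path-3 eigendecomposition gives {0, 1, 3} and a single zero mode", {
  g <- enm_decompose(build_kirchhoff(path3()))
  expect_equal(g$values, c(0, 1, 3), tolerance = 1e-9)
  expect_equal(g$n_zero, 1L)
})

test_that("disconnected networks are flagged with their component count", {
  far <- make_chain(5, 8.0, "line")  # no pair within 7.3
  expect_warning(g <- enm_decompose(build_kirchhoff(far, 7.3)),
                 "5 connected component")
  expect_equal(g$n_zero, 5L)
  # two clusters -> two components
  s <- calpha_structure("A", 1:4,
                        coords = rbind(c(0, 0, 0), c(3.8, 0, 0),
                                       c(100, 0, 0), c(103.8, 0, 0)))
  expect_warning(g2 <- enm_decompose(build_kirchhoff(s, 7.3)),
                 "2 connected component")
  expect_equal(g2$n_zero, 2L)
})

test_that("GNM fluctuations reproduce the path-3 pseudo-inverse", {
  g <- enm_decompose(build_kirchhoff(path3()))
  expect_equal(gnm_msf(g)$msf, c(5/3, 2/3, 5/3), tolerance = 1e-9)
  # slowest mode only: lambda = 1, u = (1, 0, -1)/sqrt(2)
  expect_equal(gnm_msf(g, modes = 2)$msf, c(3/2, 0, 3/2), tolerance = 1e-9)
  # linearity in the kBT/gamma scale
  expect_equal(gnm_msf(g, scale = 2)$msf, 2 * gnm_msf(g)$msf)
  expect_error(gnm_msf(g, modes = 1), "zero")
  expect_error(gnm_msf(g, modes = 7), "range")
})

test_that("B-factor conversion is (8 pi^2 / 3) per unit msf", {
  expect_equal(msf_to_bfactor(0), 0)
  expect_equal(msf_to_bfactor(1), 8 * pi^2 / 3)
  expect_equal(msf_to_bfactor(5/3), 40 * pi^2 / 9, tolerance = 1e-12)
  expect_error(msf_to_bfactor(c(1, -0.1)), ">= 0")
  p <- gnm_msf(enm_decompose(build_kirchhoff(path3())))
  expect_equal(p$bfactor_pred, 8 * pi^2 / 3 * p$msf)
})

test_that("cross-correlations reproduce the path-3 closed form and bounds", {
  g <- enm_decompose(build_kirchhoff(path3()))
  cc <- cross_correlation(g)$c
  expect_equal(cc[1, 3], -0.8, tolerance = 1e-9)
  expect_equal(cc[1, 2], -1 / sqrt(10), tolerance = 1e-9)
  expect_equal(diag(cc), rep(1, 3))

  s <- random_connected_structure(50, seed = 31)
  cm <- cross_correlation(enm_decompose(build_kirchhoff(s)))$c
  expect_equal(unname(cm), unname(t(cm)))
  expect_equal(diag(cm), rep(1, 50), tolerance = 1e-9)
  expect_true(all(abs(cm) <= 1 + 1e-9))
})

test_that("cross-correlation refuses disconnected networks", {
  far <- make_chain(6, 8.0, "line")
  g <- suppressWarnings(enm_decompose(build_kirchhoff(far, 7.3)))
  expect_error(cross_correlation(g), "connected")
})

test_that("the two-bead ANM matches its hand-computed spectrum", {
  a <- enm_decompose(build_hessian(two_beads(), 15))
  expect_equal(a$n_zero, 5L)
  expect_equal(a$values[6], 2, tolerance = 1e-9)
  expect_equal(unname(a$hessian[1:2 * 3 - 2, 1:2 * 3 - 2]),
               rbind(c(1, -1), c(-1, 1)))
  expect_true(all(a$hessian[, c(2, 3, 5, 6)] == 0))
  expect_equal(anm_msf(a)$msf, c(3/4, 3/4), tolerance = 1e-9)
})

test_that("Hessian superelements satisfy translation invariance", {
  s <- random_connected_structure(30, seed = 41)
  a <- build_hessian(s, 15)
  h <- a$hessian
  expect_equal(unname(h), unname(t(h)))
  # H annihilates uniform translations along each axis
  for (axis in 1:3) {
    t_vec <- rep(diag(3)[axis, ], 30)
    expect_lt(max(abs(h %*% t_vec)), 1e-9)
  }
  d <- enm_decompose(a)
  expect_gte(min(d$values), -1e-8 * max(d$values))
  expect_equal(d$n_zero, 6L)
})

test_that("coincident positions within the cutoff are rejected by name", {
  s <- calpha_structure("A", 1:2, coords = rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_error(build_hessian(s, 15), "residues 1 and 2")
})

test_that("GNM and ANM spectra are invariant under rigid motions", {
  s <- random_connected_structure(40, seed = 51)
  withr::with_seed(52, {
    rot <- random_rotation_matrix()
    shift <- stats::rnorm(3, sd = 20)
  })
  s2 <- rigid_motion(s, rot, shift)
  g1 <- enm_decompose(build_kirchhoff(s)); g2 <- enm_decompose(build_kirchhoff(s2))
  expect_equal(g1$values, g2$values, tolerance = 1e-8)
  a1 <- enm_decompose(build_hessian(s)); a2 <- enm_decompose(build_hessian(s2))
  expect_equal(a1$values, a2$values, tolerance = 1e-8)
})

test_that("pseudo-inverse diagonals equal the per-mode sums (GNM and ANM)", {
  for (seed in c(61, 62, 63)) {
    n <- c(25, 60, 120)[seed - 60]
    s <- random_connected_structure(n, seed = seed)
    g <- enm_decompose(build_kirchhoff(s))
    idx <- seq_along(g$values)[-seq_len(g$n_zero)]
    v <- g$vectors[, idx]
    pinv_diag <- diag(v %*% (t(v) / g$values[idx]))
    expect_equal(gnm_msf(g)$msf, 3 * pinv_diag, tolerance = 1e-8)

    a <- enm_decompose(build_hessian(s))
    mode_sum <- Reduce(`+`, lapply(seq_len(3 * n - a$n_zero), function(k) {
      anm_mode_fluctuation(a, k)$msf
    }))
    expect_equal(anm_msf(a)$msf, 3 * mode_sum, tolerance = 1e-8)
  }
})

test_that("single ANM modes report unit-norm blocks and directions", {
  a <- enm_decompose(build_hessian(two_beads(), 15))
  m1 <- anm_mode_fluctuation(a, 1)
  # antiparallel displacements along the bond (x) axis
  expect_lt(sum(m1$directions[1, ] * m1$directions[2, ]), 0)
  expect_equal(abs(m1$directions[, 1]), rep(1 / sqrt(2), 2), tolerance = 1e-9)
  expect_equal(m1$directions[, 2:3], matrix(0, 2, 2), ignore_attr = TRUE)

  s <- random_connected_structure(20, seed = 71)
  aa <- enm_decompose(build_hessian(s))
  for (k in c(1, 5, 3 * 20 - 6)) {
    expect_equal(sum(anm_mode_fluctuation(aa, k)$directions^2), 1, tolerance = 1e-8)
  }
  expect_error(anm_mode_fluctuation(aa, 0), "range")
  expect_error(anm_mode_fluctuation(aa, 3 * 20 - 5), "range")
})

test_that("slowest dumbbell ANM mode moves the two domains in opposition", {
  d <- make_dumbbell(seed = 6)
  lab <- attr(d, "labels")
  m1 <- anm_mode_fluctuation(enm_decompose(build_hessian(d)), 1)
  da <- colMeans(m1$directions[lab$domain_a, ])
  db <- colMeans(m1$directions[lab$domain_b, ])
  expect_lt(sum(da * db), 0)
})

test_that("eigenvector sign convention makes decomposition deterministic", {
  s <- random_connected_structure(30, seed = 81)
  g1 <- enm_decompose(build_kirchhoff(s))
  g2 <- enm_decompose(build_kirchhoff(s))
  expect_identical(g1$vectors, g2$vectors)
  for (k in seq_len(30)) {
    expect_gt(g1$vectors[which.max(abs(g1$vectors[, k])), k], 0)
  }
})
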