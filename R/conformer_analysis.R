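#' Fit the kBT/gamma scale against experimental B-factors
#'
#' The elastic network predicts fluctuation shapes up to the overall spring
#' stiffness; the single free parameter kBT/gamma is chosen so the predicted
#' B-factor curve best fits the deposited crystallographic B-factors, by
#' least squares through the origin: `c = sum(exp * raw_b) / sum(raw_b^2)`
#' with `raw_b = (8 pi^2 / 3) raw_msf`. The Pearson correlation between
#' predicted and experimental B-factors is scale-invariant and is the usual
#' figure of merit for ENM B-factor prediction.
#'
#' @param raw_msf unscaled mean-square fluctuations (profile computed at
#'   kBT/gamma = 1), or a `fluctuation_profile`.
#' @param exp_b experimental B-factors (Angstrom^2), same length, not
#'   constant.
#' @return object of class `scale_fit`: list with `scale_kbt_over_gamma`
#'   (Angstrom^2), `pearson_r`, `n_residues`.
#' @export
fit_scale <- function(raw_msf, exp_b) {
  if (inherits(raw_msf, "fluctuation_profile")) {
    raw_msf <- raw_msf$msf / raw_msf$scale_kbt_over_gamma
  }
  if (length(raw_msf) != length(exp_b)) stop("profile and B-factor lengths differ")
  if (length(raw_msf) < 3L) stop("need at least 3 residues to fit a scale")
  if (stats::sd(exp_b) == 0) {
    stop("experimental B-factors are constant; correlation is undefined")
  }
  raw_b <- msf_to_bfactor(raw_msf)
  scale <- max(0, sum(exp_b * raw_b) / sum(raw_b^2))
  structure(list(scale_kbt_over_gamma = scale,
                 pearson_r = stats::cor(raw_b, exp_b),
                 n_residues = length(raw_b)),
            class = "scale_fit")
}

#' @export
print.scale_fit <- function(x, ...) {
  cat(sprintf("B-factor scale fit: kBT/gamma = %.4g A^2, Pearson r = %.3f (n = %d)\n",
              x$scale_kbt_over_gamma, x$pearson_r, x$n_residues))
  invisible(x)
}

#' Difference-distance map between two conformers
#'
#' `delta_ij = R_ij(A) - R_ij(B)` over paired residues: inter-residue
#' distance changes between two conformations. Blocks of near-zero delta
#' identify rigid domains; large cross-domain entries are the signature of a
#' hinge motion. Entries at or beyond the threshold are classed +1
#' (increase) / -1 (decrease), else 0.
#'
#' @param a,b `calpha` structures.
#' @param pairing a [pair_residues()] result (computed if `NULL`).
#' @param threshold classification threshold in Angstrom (default 1.5).
#' @return object of class `ddm`: list with `delta` (symmetric, zero
#'   diagonal), `classes` (integer -1/0/+1 matrix), `threshold`, `pairing`.
#' @export
difference_distance <- function(a, b, pairing = NULL, threshold = 1.5) {
  if (is.null(pairing)) pairing <- pair_residues(a, b)
  if (length(pairing$idx_a) < 2L) stop("need at least 2 paired residues")
  da <- pair_distances(a$coords[pairing$idx_a, , drop = FALSE])
  db <- pair_distances(b$coords[pairing$idx_b, , drop = FALSE])
  delta <- da - db
  classes <- matrix(0L, nrow(delta), ncol(delta))
  classes[delta >= threshold] <- 1L
  classes[delta <= -threshold] <- -1L
  structure(list(delta = delta, classes = classes, threshold = threshold,
                 pairing = pairing),
            class = "ddm")
}

#' Slowest-mode fluctuation difference between two conformers
#'
#' Per-residue difference (A minus B) of the slow-mode fluctuation shapes.
#' Because the two conformers carry different fitted kBT/gamma scales, each
#' profile is first normalized to unit sum (over all its residues), so the
#' difference compares shapes, not absolute amplitudes; with full pairing
#' coverage it sums to zero.
#'
#' @param profile_a,profile_b `fluctuation_profile`s computed from the same
#'   mode selection, or plain numeric mode-shape vectors.
#' @param pairing a [pair_residues()] result linking the two profiles'
#'   structures.
#' @return numeric vector over paired residues (ordered by A).
#' @export
fluctuation_difference <- function(profile_a, profile_b, pairing) {
  get_msf <- function(p) if (inherits(p, "fluctuation_profile")) p$msf else as.numeric(p)
  if (inherits(profile_a, "fluctuation_profile") &&
      inherits(profile_b, "fluctuation_profile") &&
      !identical(profile_a$mode_subset, profile_b$mode_subset)) {
    stop("profiles were computed from different mode selections")
  }
  pa <- get_msf(profile_a); pb <- get_msf(profile_b)
  pa <- pa / sum(pa); pb <- pb / sum(pb)
  pa[pairing$idx_a] - pb[pairing$idx_b]
}

# Run-merge qualifying residues; report the profile minimum (maximum for
# peaks) of each run.
merge_runs <- function(idx, profile, take_min = TRUE) {
  if (length(idx) == 0L) return(integer(0))
  runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  unname(vapply(runs,
                function(r) r[if (take_min) which.min(profile[r]) else which.max(profile[r])],
                integer(1)))
}

#' Detect hinge residues from a slow-mode profile
#'
#' Hinge residues sit at the near-zero minima of the slowest-mode
#' mean-square fluctuation profile: the network rotates its domains about
#' them. A residue qualifies when it is a minimum within +/-`window`
#' positions and its value lies below `threshold_fraction` of the profile
#' maximum; consecutive qualifying residues are merged into one hinge region
#' reported by its minimum.
#'
#' @param profile slowest-mode per-residue msf (numeric), or a
#'   `fluctuation_profile`.
#' @param threshold_fraction amplitude floor as a fraction of the profile
#'   maximum (default 0.05 - "fluctuations approximating zero").
#' @param window half-width of the local-minimum neighbourhood in residues
#'   (default 2).
#' @param resnum optional residue labels (defaults to 1..N).
#' @return object of class `hinge_report`: list with `hinge_residues`
#'   (labels), `hinge_index` (positions), `profile`,
#'   `minima_threshold_fraction`.
#' @export
find_hinges <- function(profile, threshold_fraction = 0.05, window = 2L,
                        resnum = NULL) {
  if (inherits(profile, "fluctuation_profile")) profile <- profile$msf
  n <- length(profile)
  if (n < 2L * window + 1L) stop("profile too short for the requested window")
  if (is.null(resnum)) resnum <- seq_len(n)
  if (max(profile) == min(profile)) {
    warning("flat fluctuation profile; no hinges identifiable")
    idx <- integer(0)
  } else {
    is_local_min <- vapply(seq_len(n), function(i) {
      nb <- max(1L, i - window):min(n, i + window)
      profile[i] <= min(profile[nb])
    }, logical(1))
    qualifying <- which(is_local_min & profile < threshold_fraction * max(profile))
    idx <- merge_runs(qualifying, profile, take_min = TRUE)
  }
  structure(list(hinge_residues = resnum[idx], hinge_index = idx,
                 profile = profile,
                 minima_threshold_fraction = threshold_fraction),
            class = "hinge_report")
}

#' @export
print.hinge_report <- function(x, ...) {
  cat(sprintf("hinge residues (%d): %s\n", length(x$hinge_residues),
              paste(x$hinge_residues, collapse = ", ")))
  invisible(x)
}

#' Averaged fast-mode shape
#'
#' Mean over the `n_modes` largest-eigenvalue GNM modes of the squared
#' eigenvector components. High-frequency modes are highly localized; the
#' peaks of this profile mark tightly packed, kinetically hot residues. The
#' unweighted mean of unit-norm squared vectors sums to 1 over residues; an
#' eigenvalue-weighted variant (weights lambda_k, renormalized) is available
#' behind `weighted`.
#'
#' @param g a `gnm` object.
#' @param n_modes number of fastest modes to average (default 10).
#' @param weighted weight modes by eigenvalue instead of uniformly.
#' @return numeric per-residue vector summing to 1.
#' @export
fast_mode_profile <- function(g, n_modes = 10L, weighted = FALSE) {
  g <- ensure_decomposed(g)
  n <- length(g$values)
  n_nonzero <- n - g$n_zero
  if (n_modes > n_nonzero) {
    stop(sprintf("n_modes = %d exceeds the %d available non-zero modes",
                 n_modes, n_nonzero))
  }
  idx <- (n - n_modes + 1L):n
  u2 <- g$vectors[, idx, drop = FALSE]^2
  w <- if (weighted) g$values[idx] / sum(g$values[idx]) else rep(1 / n_modes, n_modes)
  as.numeric(u2 %*% w)
}

#' Detect kinetically hot residues from a fast-mode profile
#'
#' Strict local maxima within +/-`window` whose value exceeds
#' `mean + floor_sd * sd` of the profile.
#'
#' @param profile fast-mode per-residue profile.
#' @param floor_sd peak floor in profile standard deviations above the mean
#'   (default 1).
#' @param window half-width of the local-maximum neighbourhood (default 2).
#' @param resnum optional residue labels (defaults to 1..N).
#' @param cutoff_used contact cutoff recorded for reporting (optional).
#' @return object of class `hot_report`: list with `peak_residues`,
#'   `peak_index`, `profile`, `cutoff_used`.
#' @export
find_hot_residues <- function(profile, floor_sd = 1.0, window = 2L,
                              resnum = NULL, cutoff_used = NA_real_) {
  n <- length(profile)
  if (is.null(resnum)) resnum <- seq_len(n)
  floor_val <- mean(profile) + floor_sd * stats::sd(profile)
  idx <- which(vapply(seq_len(n), function(i) {
    nb <- setdiff(max(1L, i - window):min(n, i + window), i)
    length(nb) > 0L && all(profile[i] > profile[nb]) && profile[i] > floor_val
  }, logical(1)))
  structure(list(peak_residues = resnum[idx], peak_index = idx,
                 profile = profile, cutoff_used = cutoff_used),
            class = "hot_report")
}

#' @export
print.hot_report <- function(x, ...) {
  cat(sprintf("hot residues (%d%s): %s\n", length(x$peak_residues),
              if (is.na(x$cutoff_used)) "" else sprintf(", cutoff %.1f A", x$cutoff_used),
              paste(x$peak_residues, collapse = ", ")))
  invisible(x)
}

# Kabsch: proper rotation R minimizing ||Q - P R'|| over centered point
# rows, i.e. R %*% p_i ~ q_i. Returns list(R, reflected).
kabsch_rotation <- function(p, q) {
  pc <- sweep(p, 2L, colMeans(p))
  qc <- sweep(q, 2L, colMeans(q))
  sv <- svd(pc)$d
  if (sv[2L] < 1e-9 * max(sv[1L], 1)) {
    stop("degenerate (collinear) point selection; rotation is underdetermined")
  }
  h <- crossprod(pc, qc)           # sum p q^T
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  reflected <- d < 0
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = r, reflected = reflected)
}

superpose_transform <- function(p, q) {
  # rigid transform taking q onto p (least squares): x -> R (x - cq) + cp
  k <- kabsch_rotation(q, p)
  list(R = k$R, cp = colMeans(p), cq = colMeans(q), reflected = k$reflected)
}

apply_transform <- function(coords, tr) {
  sweep(tcrossprod(sweep(coords, 2L, tr$cq), tr$R), 2L, tr$cp, "+")
}

match_domain <- function(s, idx_struct, residues) {
  which(s$resnum[idx_struct] %in% residues)
}

#' Rigid rotation angle between two domains of two conformers
#'
#' A two-stage least-squares measure of the inter-domain rotation that
#' separates two conformations: stage 1 superposes structure B onto A over
#' the fixed-domain C-alpha set (optimal Kabsch rigid fit), removing any
#' global motion; stage 2 finds the optimal rotation R aligning the moving
#' domain of superposed B onto A and reports
#' `angle = acos((trace(R) - 1) / 2)` in degrees. This is a simplified
#' superposition analogue of domain-motion tools that also search for the
#' domain decomposition; here the domains are supplied.
#'
#' @param a,b `calpha` structures (e.g. open and closed conformers).
#' @param pairing a [pair_residues()] result (computed if `NULL`).
#' @param fixed_domain integer vector of author residue numbers forming the
#'   reference (fixed) domain, e.g. `c(1:100, 236:259)`.
#' @param moving_domain residue numbers of the rotating domain, e.g.
#'   `c(108:231, 269:271)`.
#' @return object of class `rotation_result`: list with `angle_deg` in
#'   [0, 180], `fixed_domain`, `moving_domain`, `rmsd_fixed` (Angstrom, after
#'   stage-1 superposition), `reflected` (TRUE when the raw optimal alignment
#'   was a reflection, corrected to a proper rotation).
#' @export
rotation_angle <- function(a, b, pairing = NULL, fixed_domain, moving_domain) {
  if (is.null(pairing)) pairing <- pair_residues(a, b)
  fixed_sel <- match_domain(a, pairing$idx_a, fixed_domain)
  moving_sel <- match_domain(a, pairing$idx_a, moving_domain)
  if (length(fixed_sel) < 3L || length(moving_sel) < 3L) {
    stop("each domain needs at least 3 paired residues")
  }
  pa <- a$coords[pairing$idx_a, , drop = FALSE]
  pb <- b$coords[pairing$idx_b, , drop = FALSE]
  tr <- superpose_transform(pa[fixed_sel, , drop = FALSE],
                            pb[fixed_sel, , drop = FALSE])
  pb_sup <- apply_transform(pb, tr)
  rmsd_fixed <- sqrt(mean(rowSums((pb_sup[fixed_sel, , drop = FALSE] -
                                   pa[fixed_sel, , drop = FALSE])^2)))
  k2 <- kabsch_rotation(pb_sup[moving_sel, , drop = FALSE],
                        pa[moving_sel, , drop = FALSE])
  r2 <- k2$R
  # atan2 form of the rotation angle: well-conditioned near 0 and 180 deg,
  # unlike acos((trace - 1)/2)
  sin_part <- sqrt((r2[3, 2] - r2[2, 3])^2 + (r2[1, 3] - r2[3, 1])^2 +
                   (r2[2, 1] - r2[1, 2])^2) / 2
  cos_part <- (sum(diag(r2)) - 1) / 2
  angle <- atan2(sin_part, cos_part) * 180 / pi
  reflected <- tr$reflected || k2$reflected
  if (reflected) warning("optimal alignment was a reflection; corrected to a proper rotation")
  structure(list(angle_deg = angle, fixed_domain = fixed_domain,
                 moving_domain = moving_domain, rmsd_fixed = rmsd_fixed,
                 reflected = reflected),
            class = "rotation_result")
}

#' @export
print.rotation_result <- function(x, ...) {
  cat(sprintf("inter-domain rotation: %.3f deg (fixed-domain rmsd %.3f A)\n",
              x$angle_deg, x$rmsd_fixed))
  invisible(x)
}
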