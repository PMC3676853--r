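#' Generate an idealized C-alpha chain
#'
#' Line mode places collinear points at the given spacing; helix mode builds
#' ideal alpha-helix geometry (rise 1.5 A, radius 2.3 A, 100 degree twist per
#' residue; `spacing` is ignored there). Residues are numbered sequentially
#' from 1 on chain A. Useful as exactly solvable network substrates.
#'
#' @param n number of residues.
#' @param spacing consecutive C-alpha separation in Angstrom (line mode;
#'   default 3.8, the canonical virtual-bond length).
#' @param geometry `"line"` or `"helix"`.
#' @return a `calpha` structure.
#' @export
make_chain <- function(n, spacing = 3.8, geometry = c("line", "helix")) {
  stopifnot(n >= 1L, spacing > 0)
  geometry <- match.arg(geometry)
  i <- seq_len(n) - 1L
  coords <- switch(geometry,
    line  = cbind(i * spacing, 0, 0),
    helix = {
      theta <- i * 100 * pi / 180
      cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
    })
  calpha_structure(chain = "A", resnum = seq_len(n), resname = "GLY",
                   coords = coords, source_label = paste0("synthetic-", geometry))
}

# Uniform points in a sphere of given radius with pairwise min separation,
# by rejection sampling. Consumes the current RNG stream.
sample_cluster <- function(n, radius, min_separation, max_attempts = 20000L) {
  pts <- matrix(NA_real_, n, 3L)
  got <- 0L
  for (attempt in seq_len(max_attempts)) {
    p <- stats::runif(3L, -radius, radius)
    if (sum(p^2) > radius^2) next
    if (got > 0L) {
      d2 <- rowSums(sweep(pts[seq_len(got), , drop = FALSE], 2L, p)^2)
      if (min(d2) < min_separation^2) next
    }
    got <- got + 1L
    pts[got, ] <- p
    if (got == n) return(pts)
  }
  stop(sprintf(
    "could not place %d points with min separation %.2f A in a %.1f A sphere; increase domain_radius",
    n, min_separation, radius))
}

#' Generate a synthetic two-domain dumbbell structure
#'
#' Emulates the architecture of a two-domain hinge protein (two compact
#' globular domains joined by a short linker) at the level the elastic
#' network sees: two compact random C-alpha clusters connected by a
#' collinear linker at 3.8 A spacing, with a contact graph guaranteed
#' connected at 7.3 A. Ground-truth labels (domain and linker index sets)
#' travel with the structure so hinge detection and rotation recovery can be
#' scored against them.
#'
#' @param n_domain_a,n_domain_b residue counts of the two domains (>= 4).
#' @param linker_length linker residue count.
#' @param domain_radius sphere radius of each domain cluster in Angstrom.
#' @param min_separation minimum inter-residue distance in Angstrom
#'   (default 3.8, steric exclusion at C-alpha resolution).
#' @param seed integer RNG seed; identical spec + seed gives identical
#'   coordinates.
#' @return a `calpha` structure with attribute `labels`: list with
#'   `domain_a`, `linker`, `domain_b` (integer residue indices) and the
#'   generating spec.
#' @export
make_dumbbell <- function(n_domain_a = 40L, n_domain_b = 40L,
                          linker_length = 5L, domain_radius = 11,
                          min_separation = 3.8, seed = 1L) {
  stopifnot(n_domain_a >= 4L, n_domain_b >= 4L, linker_length >= 1L,
            min_separation > 0)
  withr::with_seed(seed, {
    for (attempt in 1:50) {
      pa <- sample_cluster(n_domain_a, domain_radius, min_separation)
      pb <- sample_cluster(n_domain_b, domain_radius, min_separation)
      # linker leaves domain A at its +x extreme and enters B at its -x
      # extreme along a gentle helix (radius 1.2 A, 120 deg twist) with
      # consecutive spacing exactly 3.8 A; a straight or planar linker
      # would leave its nodes transversely unconstrained in the ANM
      # (spurious zero modes), since a node's springs only resist motion
      # along the bond directions
      a_exit <- pa[which.max(pa[, 1L]), ]
      r_lnk <- 1.2; phi <- 2 * pi / 3
      dx <- sqrt(3.8^2 - (2 * r_lnk * sin(phi / 2))^2)
      zig <- function(k) a_exit + c(k * dx, r_lnk * (cos(k * phi) - 1),
                                    r_lnk * sin(k * phi))
      linker <- t(vapply(seq_len(linker_length), zig, numeric(3L)))
      b_entry_target <- zig(linker_length + 1L)
      pb <- sweep(pb, 2L, b_entry_target - pb[which.min(pb[, 1L]), ], "+")
      coords <- rbind(pa, linker, pb)
      s <- calpha_structure(chain = "A", resnum = seq_len(nrow(coords)),
                            resname = "GLY", coords = coords,
                            source_label = sprintf("synthetic-dumbbell-seed%d", seed))
      d <- pair_distances(coords)
      adj <- d <= 7.3; diag(adj) <- FALSE
      if (count_components(adj) == 1L && min(d[upper.tri(d)]) >= min_separation - 1e-9) {
        attr(s, "labels") <- list(
          domain_a = seq_len(n_domain_a),
          linker = n_domain_a + seq_len(linker_length),
          domain_b = n_domain_a + linker_length + seq_len(n_domain_b),
          spec = list(n_domain_a = n_domain_a, n_domain_b = n_domain_b,
                      linker_length = linker_length,
                      domain_radius = domain_radius,
                      min_separation = min_separation, seed = seed))
        return(s)
      }
    }
    stop("dumbbell generation failed to produce a connected, clash-free structure; increase domain_radius")
  })
}

#' Rotate part of a structure rigidly about an axis
#'
#' Applies a Rodrigues rotation of `angle_deg` about the axis through
#' `axis_point` with direction `axis_direction` to the selected residues,
#' leaving all others untouched. Intra-selection and intra-complement
#' pairwise distances are preserved exactly; only cross-set distances
#' change - the geometry of an ideal hinge motion.
#'
#' @param s a `calpha` structure.
#' @param axis_point 3-vector on the rotation axis (Angstrom).
#' @param axis_direction 3-vector axis direction (normalized internally;
#'   zero length is an error).
#' @param angle_deg rotation angle in degrees.
#' @param moving integer residue indices to rotate (non-empty).
#' @return a `calpha` structure (labels attribute preserved).
#' @export
apply_hinge_rotation <- function(s, axis_point, axis_direction, angle_deg, moving) {
  stopifnot(length(moving) >= 1L)
  nrm <- sqrt(sum(axis_direction^2))
  if (nrm < 1e-12) stop("axis direction has zero length")
  k <- axis_direction / nrm
  theta <- angle_deg * pi / 180
  kx <- matrix(c(0, k[3L], -k[2L], -k[3L], 0, k[1L], k[2L], -k[1L], 0), 3L, 3L)
  r <- diag(3L) + sin(theta) * kx + (1 - cos(theta)) * (kx %*% kx)
  out <- s
  p <- sweep(s$coords[moving, , drop = FALSE], 2L, axis_point)
  out$coords[moving, ] <- sweep(tcrossprod(p, r), 2L, axis_point, "+")
  attr(out, "labels") <- attr(s, "labels")
  out
}

#' Generate an open/closed synthetic conformer pair
#'
#' Convenience wrapper: builds a dumbbell ("open" form) and a "closed" form
#' in which domain B is rotated by `angle_deg` about an axis through the
#' linker midpoint, perpendicular to the linker (the hinge-closure
#' geometry). The true angle and axis are recorded in the labels.
#'
#' @inheritParams make_dumbbell
#' @param angle_deg hinge closure angle in degrees (default 41.3, a
#'   realistic periplasmic-binding-protein domain closure).
#' @return list with `open`, `closed` (`calpha` structures) and `labels`
#'   (domains, linker, true angle).
#' @export
make_conformer_pair <- function(n_domain_a = 40L, n_domain_b = 40L,
                                linker_length = 5L, domain_radius = 11,
                                min_separation = 3.8, seed = 1L,
                                angle_deg = 41.3) {
  open <- make_dumbbell(n_domain_a, n_domain_b, linker_length, domain_radius,
                        min_separation, seed)
  lab <- attr(open, "labels")
  # hinge axis through the last linker residue: rotation about a point on
  # the chain preserves the linker-to-domain-B bond length, so the closed
  # form stays a connected contact graph
  axis_point <- open$coords[lab$linker[length(lab$linker)], ]
  closed <- apply_hinge_rotation(open, axis_point,
                                 axis_direction = c(0, 0, 1),
                                 angle_deg = angle_deg, moving = lab$domain_b)
  closed$source_label <- paste0(open$source_label, "-closed")
  lab$true_angle_deg <- angle_deg
  lab$axis_point <- axis_point
  lab$axis_direction <- c(0, 0, 1)
  list(open = open, closed = closed, labels = lab)
}

#' Synthesize an experimental-like B-factor column
#'
#' Emulates a deposited B-factor column: the structure's own GNM prediction
#' at the given kBT/gamma scale plus i.i.d. Gaussian noise with standard
#' deviation `noise_sd_fraction * mean(B)`; negative draws are clamped to
#' zero (their count is attached as attribute `n_clamped`). With the noise
#' at zero, [fit_scale()] recovers `scale` exactly.
#'
#' @param s a `calpha` structure with a connected contact graph at `cutoff`.
#' @param cutoff GNM cutoff in Angstrom.
#' @param scale true kBT/gamma in Angstrom^2 (default 5.64, a typical fitted
#'   value for a crystallographic two-domain protein).
#' @param noise_sd_fraction noise sd as a fraction of the mean B (default
#'   0.05).
#' @param seed integer RNG seed.
#' @return numeric B-factor vector (Angstrom^2) with attribute `n_clamped`.
#' @export
synth_bfactors <- function(s, cutoff = 7.3, scale = 5.64,
                           noise_sd_fraction = 0.05, seed = 1L) {
  stopifnot(scale > 0, noise_sd_fraction >= 0)
  g <- suppressWarnings(enm_decompose(build_kirchhoff(s, cutoff)))
  if (g$n_zero != 1L) {
    stop("contact graph is disconnected at cutoff ", cutoff,
         " A; B-factors from the GNM are undefined")
  }
  b <- gnm_msf(g, scale = scale)$bfactor_pred
  withr::with_seed(seed, {
    noisy <- b + stats::rnorm(length(b), sd = noise_sd_fraction * mean(b))
  })
  n_clamped <- sum(noisy < 0)
  noisy[noisy < 0] <- 0
  attr(noisy, "n_clamped") <- n_clamped
  noisy
}

#' Perturb coordinates with Gaussian jitter
#'
#' @param s a `calpha` structure.
#' @param sd displacement standard deviation per coordinate in Angstrom
#'   (0 is the identity).
#' @param seed integer RNG seed.
#' @return a `calpha` structure.
#' @export
jitter_structure <- function(s, sd, seed = 1L) {
  stopifnot(sd >= 0)
  out <- s
  if (sd > 0) {
    withr::with_seed(seed, {
      out$coords <- s$coords + matrix(stats::rnorm(3L * n_residues(s), sd = sd),
                                      ncol = 3L)
    })
  }
  attr(out, "labels") <- attr(s, "labels")
  out
}
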