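BFACTOR_PER_MSF <- 8 * pi^2 / 3  # B = (8 pi^2 / 3) <dR^2>

pair_distances <- function(coords) unname(as.matrix(stats::dist(coords)))

#' Build the GNM Kirchhoff (connectivity) matrix
#'
#' The Gaussian Network Model represents a protein as C-alpha nodes joined by
#' identical springs whenever two nodes lie within a cutoff distance. Its
#' dynamics are governed by the graph Laplacian of that contact graph: the
#' Kirchhoff matrix has -1 for each contact (inclusive cutoff comparison),
#' 0 otherwise, and minus the row sum of off-diagonals (the contact degree)
#' on the diagonal. The uniform spring constant gamma is factored out and
#' reintroduced only through the fitted kBT/gamma scale.
#'
#' @param s a `calpha` structure.
#' @param cutoff contact cutoff r_c in Angstrom (default 7.3, the value used
#'   throughout the single-structure GNM analyses here).
#' @return object of class `gnm`: list with `kirchhoff` (N x N), `cutoff`,
#'   and (after [enm_decompose()]) `values`, `vectors`, `n_zero`.
#' @export
build_kirchhoff <- function(s, cutoff = 7.3) {
  stopifnot(inherits(s, "calpha"), cutoff > 0)
  d <- pair_distances(s$coords)
  contact <- (d <= cutoff)
  diag(contact) <- FALSE
  k <- -1 * contact
  diag(k) <- rowSums(contact)
  structure(list(kirchhoff = k, cutoff = cutoff,
                 values = NULL, vectors = NULL, n_zero = NULL,
                 structure = s),
            class = "gnm")
}

#' Per-residue contact numbers
#'
#' Number of other residues within the cutoff of each residue; identical to
#' the Kirchhoff diagonal. Tightly packed ("kinetically hot") residues stand
#' out as peaks of this profile.
#'
#' @param s a `calpha` structure.
#' @param cutoff contact cutoff in Angstrom.
#' @return integer vector of length N.
#' @export
contact_numbers <- function(s, cutoff = 7.3) {
  stopifnot(cutoff > 0)
  d <- pair_distances(s$coords)
  contact <- (d <= cutoff)
  diag(contact) <- FALSE
  as.integer(rowSums(contact))
}

#' Build the ANM Hessian matrix
#'
#' The Anisotropic Network Model extends the GNM to fluctuation directions:
#' the 3N x 3N Hessian of the harmonic network potential, evaluated at the
#' input (equilibrium) geometry, has 3 x 3 superelements
#' `H_ij = -(1/d_ij^2) (r_j - r_i)(r_j - r_i)^T` for contacts i != j and
#' `H_ii = -sum_j H_ij` (translation invariance). Gamma is factored out.
#'
#' @param s a `calpha` structure with at least 2 residues.
#' @param cutoff contact cutoff in Angstrom (default 15; the ANM needs a
#'   larger interaction range than the GNM to be stable).
#' @return object of class `anm`: list with `hessian` (3N x 3N), `cutoff`,
#'   and (after [enm_decompose()]) `values`, `vectors`, `n_zero`.
#' @export
build_hessian <- function(s, cutoff = 15) {
  stopifnot(inherits(s, "calpha"), cutoff > 0)
  n <- n_residues(s)
  if (n < 2L) stop("ANM requires at least 2 residues")
  d <- pair_distances(s$coords)
  h <- matrix(0, 3L * n, 3L * n)
  contact <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  if (nrow(contact) > 0L && any(d[contact] < 1e-6)) {
    bad <- contact[which(d[contact] < 1e-6)[1L], ]
    stop(sprintf("coincident C-alpha positions for residues %d and %d",
                 bad[1L], bad[2L]))
  }
  for (p in seq_len(nrow(contact))) {
    i <- contact[p, 1L]; j <- contact[p, 2L]
    rij <- s$coords[j, ] - s$coords[i, ]
    blk <- -tcrossprod(rij) / d[i, j]^2
    ii <- (3L * (i - 1L) + 1L):(3L * i)
    jj <- (3L * (j - 1L) + 1L):(3L * j)
    h[ii, jj] <- blk
    h[jj, ii] <- blk
    h[ii, ii] <- h[ii, ii] - blk
    h[jj, jj] <- h[jj, jj] - blk
  }
  structure(list(hessian = h, cutoff = cutoff,
                 values = NULL, vectors = NULL, n_zero = NULL,
                 structure = s),
            class = "anm")
}

# Fix eigenvector sign: largest-magnitude component made positive.
fix_eigenvector_signs <- function(v) {
  for (k in seq_len(ncol(v))) {
    i <- which.max(abs(v[, k]))
    if (v[i, k] < 0) v[, k] <- -v[, k]
  }
  v
}

count_components <- function(adj) {
  # connected components of a logical adjacency matrix by BFS
  n <- nrow(adj)
  seen <- logical(n)
  comp <- 0L
  for (start in seq_len(n)) {
    if (seen[start]) next
    comp <- comp + 1L
    frontier <- start
    seen[start] <- TRUE
    while (length(frontier) > 0L) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nb] <- TRUE
      frontier <- nb
    }
  }
  comp
}

#' Eigen-decompose an elastic network model
#'
#' Computes ascending eigenvalues and orthonormal eigenvectors of the
#' Kirchhoff matrix (GNM) or Hessian (ANM) and identifies the numerically
#' zero modes corresponding to rigid-body motion. A mode is zero iff
#' lambda < 1e-10 * max(lambda, 1), a dimensionless threshold robust across
#' network sizes. Eigenvector signs are fixed by making the
#' largest-magnitude component positive, so outputs are deterministic.
#'
#' A connected GNM has exactly 1 zero mode and a 3D connected ANM has 6
#' (5 for collinear sets); more zero modes indicate a disconnected contact
#' graph, which is flagged with the component count but not fatal.
#'
#' @param x a `gnm` or `anm` object (or a plain symmetric matrix).
#' @param ... unused.
#' @return the input object with `values`, `vectors` and `n_zero` filled
#'   (for a plain matrix, a list with those elements).
#' @export
enm_decompose <- function(x, ...) UseMethod("enm_decompose")

decompose_symmetric <- function(m, expected_zero = NULL, adj_fun = NULL) {
  if (max(abs(m - t(m))) > 1e-8) stop("matrix is not symmetric")
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  values <- e$values[ord]
  vectors <- fix_eigenvector_signs(e$vectors[, ord, drop = FALSE])
  n_zero <- sum(values < 1e-10 * max(max(values), 1))
  if (!is.null(expected_zero) && n_zero > expected_zero && !is.null(adj_fun)) {
    warning(sprintf(
      "underconstrained elastic network: %d zero modes (expected %d), %d connected component(s)",
      n_zero, expected_zero, count_components(adj_fun())))
  }
  list(values = values, vectors = vectors, n_zero = n_zero)
}

#' @export
enm_decompose.gnm <- function(x, ...) {
  dec <- decompose_symmetric(x$kirchhoff, expected_zero = 1L,
                             adj_fun = function() x$kirchhoff < 0)
  x[names(dec)] <- dec
  x
}

#' @export
enm_decompose.anm <- function(x, ...) {
  adj_fun <- function() {
    n <- nrow(x$hessian) / 3L
    # residues i,j are in contact iff their off-diagonal superelement is nonzero
    blk <- abs(x$hessian) > 0
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1L)) {
      ii <- (3L * i - 2L):(3L * i)
      for (j in (i + 1L):n) {
        jj <- (3L * j - 2L):(3L * j)
        adj[i, j] <- adj[j, i] <- any(blk[ii, jj])
      }
    }
    adj
  }
  dec <- decompose_symmetric(x$hessian, expected_zero = 6L, adj_fun = adj_fun)
  x[names(dec)] <- dec
  x
}

#' @export
enm_decompose.matrix <- function(x, ...) decompose_symmetric(x)

ensure_decomposed <- function(m) {
  if (is.null(m$values)) enm_decompose(m) else m
}

#' @export
print.gnm <- function(x, ...) {
  cat(sprintf("GNM: %d residues, cutoff %.2f A%s\n", nrow(x$kirchhoff), x$cutoff,
              if (is.null(x$values)) "" else sprintf(", %d zero mode(s)", x$n_zero)))
  invisible(x)
}

#' @export
print.anm <- function(x, ...) {
  cat(sprintf("ANM: %d residues (3N = %d), cutoff %.2f A%s\n",
              nrow(x$hessian) / 3L, nrow(x$hessian), x$cutoff,
              if (is.null(x$values)) "" else sprintf(", %d zero mode(s)", x$n_zero)))
  invisible(x)
}

new_fluctuation_profile <- function(msf, scale, model_kind, mode_subset) {
  structure(list(msf = msf, bfactor_pred = msf_to_bfactor(msf),
                 scale_kbt_over_gamma = scale, model_kind = model_kind,
                 mode_subset = mode_subset),
            class = "fluctuation_profile")
}

#' @export
print.fluctuation_profile <- function(x, ...) {
  cat(sprintf("%s fluctuation profile: %d residues, modes %s, kBT/gamma = %g A^2\n",
              x$model_kind, length(x$msf),
              if (identical(x$mode_subset, "all")) "all"
              else paste(x$mode_subset, collapse = ","),
              x$scale_kbt_over_gamma))
  invisible(x)
}

#' GNM mean-square fluctuations
#'
#' Per-residue mean-square fluctuations from the Kirchhoff pseudo-inverse,
#' `msf_i = (3 kBT/gamma) [Gamma^+]_ii`, optionally restricted to a subset of
#' modes (`msf_i(k) = (3 kBT/gamma) lambda_k^-1 u_k[i]^2` summed over the
#' subset). Predicted B-factors are `(8 pi^2 / 3) msf`.
#'
#' @param g a `gnm` object (decomposed on demand).
#' @param scale kBT/gamma in Angstrom^2 (default 1: unscaled shape, as fed to
#'   [fit_scale()]).
#' @param modes `"all"` (all non-zero modes) or integer indices into the
#'   ascending eigenvalue list; requesting a zero mode is an error.
#' @return a `fluctuation_profile`: list with `msf`, `bfactor_pred`,
#'   `scale_kbt_over_gamma`, `model_kind`, `mode_subset`.
#' @export
gnm_msf <- function(g, scale = 1, modes = "all") {
  stopifnot(inherits(g, "gnm"), scale > 0)
  g <- ensure_decomposed(g)
  n <- length(g$values)
  if (identical(modes, "all")) {
    idx <- seq_len(n)[-seq_len(g$n_zero)]
    subset_label <- "all"
  } else {
    idx <- as.integer(modes)
    if (any(idx < 1L | idx > n)) stop("mode index out of range")
    zero <- idx[idx <= g$n_zero]
    if (length(zero) > 0L) {
      stop("mode ", zero[1L], " is a zero (rigid-body) mode; it carries no fluctuation")
    }
    subset_label <- idx
  }
  u2 <- g$vectors[, idx, drop = FALSE]^2
  msf <- scale * 3 * as.numeric(u2 %*% (1 / g$values[idx]))
  new_fluctuation_profile(msf, scale, "GNM", subset_label)
}

#' Convert mean-square fluctuations to B-factors
#'
#' Crystallographic temperature factors relate to mean-square displacement
#' by `B = (8 pi^2 / 3) <dR^2>`.
#'
#' @param msf non-negative numeric vector in Angstrom^2.
#' @return numeric vector of B-factors in Angstrom^2.
#' @export
msf_to_bfactor <- function(msf) {
  if (any(msf < 0)) stop("mean-square fluctuations must be >= 0")
  BFACTOR_PER_MSF * msf
}

#' Normalized cross-correlations between residue fluctuations
#'
#' `C_ij = <dR_i . dR_j> / sqrt(<dR_i^2><dR_j^2>)` from the full Kirchhoff
#' pseudo-inverse (all non-zero modes). +1 means fully correlated motion,
#' -1 fully anticorrelated; the diagonal is exactly 1. In two-domain
#' proteins the inter-domain block is typically strongly negative.
#'
#' @param g a `gnm` object for a connected network (single zero mode).
#' @return object of class `cross_correlation`: list with `c` (N x N).
#' @export
cross_correlation <- function(g) {
  stopifnot(inherits(g, "gnm"))
  g <- ensure_decomposed(g)
  if (g$n_zero != 1L) {
    stop("cross-correlation requires a connected network (got ",
         g$n_zero, " zero modes); correlations across disconnected components are undefined")
  }
  idx <- seq_along(g$values)[-seq_len(g$n_zero)]
  v <- g$vectors[, idx, drop = FALSE]
  ginv <- v %*% (t(v) / g$values[idx])
  dvar <- diag(ginv)
  if (any(dvar <= 0)) stop("zero mean-square fluctuation at residue ",
                           which(dvar <= 0)[1L], "; cannot normalize")
  cmat <- ginv / sqrt(tcrossprod(dvar))
  diag(cmat) <- 1
  structure(list(c = cmat), class = "cross_correlation")
}

#' ANM mean-square fluctuations
#'
#' `msf_i = (3 kBT/gamma) trace([H^+]_ii)` where `[H^+]_ii` is the i-th 3x3
#' diagonal superelement of the Hessian pseudo-inverse (zero modes excluded).
#'
#' @param a an `anm` object.
#' @param scale kBT/gamma in Angstrom^2.
#' @return a `fluctuation_profile`.
#' @export
anm_msf <- function(a, scale = 1) {
  stopifnot(inherits(a, "anm"), scale > 0)
  a <- ensure_decomposed(a)
  nz <- seq_along(a$values)[-seq_len(a$n_zero)]
  if (length(nz) < 1L) stop("ANM has no non-zero modes")
  u2 <- a$vectors[, nz, drop = FALSE]^2
  per_coord <- as.numeric(u2 %*% (1 / a$values[nz]))
  n <- length(per_coord) / 3L
  msf <- scale * 3 * colSums(matrix(per_coord, nrow = 3L))
  new_fluctuation_profile(msf, scale, "ANM", "all")
}

#' Per-residue fluctuation and direction of a single ANM mode
#'
#' The slow ANM modes of a two-domain protein are its functional motions
#' (domain rotation, hinge bending, twisting); this returns the per-residue
#' mean-square fluctuation `lambda_k^-1 |u_k block i|^2` and the 3-vector
#' direction of motion of each residue in mode k.
#'
#' @param a an `anm` object.
#' @param k mode ordinal among non-zero modes (1 = slowest).
#' @return list with `msf` (length N), `directions` (N x 3, eigenvector
#'   blocks under the deterministic sign convention), `eigenvalue`, `mode`.
#' @export
anm_mode_fluctuation <- function(a, k) {
  stopifnot(inherits(a, "anm"))
  a <- ensure_decomposed(a)
  n_nonzero <- length(a$values) - a$n_zero
  if (k < 1L || k > n_nonzero) {
    stop(sprintf("mode ordinal %d out of range (1..%d non-zero modes)", k, n_nonzero))
  }
  col <- a$n_zero + k
  u <- matrix(a$vectors[, col], ncol = 3L, byrow = TRUE)
  colnames(u) <- c("x", "y", "z")
  list(msf = rowSums(u^2) / a$values[col], directions = u,
       eigenvalue = a$values[col], mode = k)
}

#' Per-residue fluctuation of a single GNM mode
#'
#' `msf_i(k) = lambda_k^-1 u_k[i]^2` (unit kBT/gamma). Mode 1 is the slowest
#' non-zero mode, whose near-zero minima mark the hinge residues.
#'
#' @param g a `gnm` object.
#' @param k mode ordinal among non-zero modes (1 = slowest).
#' @return numeric vector of length N.
#' @export
gnm_mode_msf <- function(g, k = 1L) {
  g <- ensure_decomposed(g)
  n_nonzero <- length(g$values) - g$n_zero
  if (k < 1L || k > n_nonzero) {
    stop(sprintf("mode ordinal %d out of range (1..%d non-zero modes)", k, n_nonzero))
  }
  col <- g$n_zero + k
  g$vectors[, col]^2 / g$values[col]
}
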