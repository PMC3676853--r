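#' Assemble a run configuration
#'
#' A flat, human-editable bundle of the knobs shared by the pipeline
#' drivers. Defaults are the values used throughout the analyses here: GNM
#' cutoff 7.3 A, fast-mode secondary cutoffs 7.3 and 9 A, ANM cutoff 15 A,
#' fastest-10-mode average, 1.5 A difference-distance threshold.
#'
#' @param gnm_cutoff GNM contact cutoff (Angstrom).
#' @param fast_cutoffs cutoffs at which the fast-mode/contact-number
#'   analysis is repeated.
#' @param anm_cutoff ANM contact cutoff (Angstrom).
#' @param n_fast_modes number of fastest modes averaged.
#' @param ddm_threshold difference-distance classification threshold
#'   (Angstrom).
#' @param fixed_domain,moving_domain residue-number vectors defining the
#'   reference and rotating domains for [rotation_angle()] (may be `NULL`).
#' @param seed integer seed for any stochastic step.
#' @return object of class `enm_config` (a flat named list).
#' @export
enm_config <- function(gnm_cutoff = 7.3, fast_cutoffs = c(7.3, 9.0),
                       anm_cutoff = 15, n_fast_modes = 10L,
                       ddm_threshold = 1.5, fixed_domain = NULL,
                       moving_domain = NULL, seed = 1L) {
  stopifnot(gnm_cutoff > 0, all(fast_cutoffs > 0), anm_cutoff > 0,
            n_fast_modes >= 1L, ddm_threshold > 0)
  structure(list(gnm_cutoff = gnm_cutoff, fast_cutoffs = fast_cutoffs,
                 anm_cutoff = anm_cutoff, n_fast_modes = as.integer(n_fast_modes),
                 ddm_threshold = ddm_threshold, fixed_domain = fixed_domain,
                 moving_domain = moving_domain, seed = as.integer(seed)),
            class = "enm_config")
}

#' Write / read a run configuration
#'
#' Configurations round-trip losslessly through a flat JSON document.
#' @param config an [enm_config()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` an
#'   `enm_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(enm_config, raw[!vapply(raw, is.null, logical(1))])
}

read_input <- function(x, chain = NULL, model = 1L) {
  if (inherits(x, "calpha")) x else read_calpha(x, chain = chain, model = model)
}

#' Single-structure GNM analysis
#'
#' Runs the full GNM battery on one structure and writes its outputs under
#' `out_dir`: a per-residue CSV (msf, predicted and experimental B-factors,
#' slowest-mode profile, fast-mode profile and contact numbers at each fast
#' cutoff), the cross-correlation matrix as dense CSV, and a summary JSON
#' with the B-factor scale fit, hinge residues and hot residues.
#'
#' @param input a `calpha` structure or a PDB path.
#' @param out_dir output directory (created if needed).
#' @param config an [enm_config()].
#' @param chain,model forwarded to [read_calpha()] for path input.
#' @return invisibly, the summary list.
#' @export
run_gnm <- function(input, out_dir, config = enm_config(), chain = NULL,
                    model = 1L) {
  s <- read_input(input, chain, model)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  g <- suppressWarnings(enm_decompose(build_kirchhoff(s, config$gnm_cutoff)))
  if (g$n_zero != 1L) {
    stop("contact graph disconnected at ", config$gnm_cutoff, " A (",
         g$n_zero, " zero modes); GNM analysis aborted")
  }
  raw <- gnm_msf(g)
  slow <- gnm_mode_msf(g, 1L)
  fit <- if (!is.null(s$exp_bfactor) && stats::sd(s$exp_bfactor) > 0) {
    fit_scale(raw, s$exp_bfactor)
  }
  scale <- if (is.null(fit)) 1 else fit$scale_kbt_over_gamma
  prof <- gnm_msf(g, scale = scale)
  hinges <- find_hinges(slow, resnum = s$resnum)
  cols <- list(msf = prof$msf, bfactor_pred = prof$bfactor_pred)
  if (!is.null(s$exp_bfactor)) cols$bfactor_exp <- s$exp_bfactor
  cols$slow_mode_msf <- slow
  hot <- list()
  for (rc in config$fast_cutoffs) {
    grc <- if (rc == config$gnm_cutoff) g else
      enm_decompose(build_kirchhoff(s, rc))
    fp <- fast_mode_profile(grc, config$n_fast_modes)
    cn <- contact_numbers(s, rc)
    tag <- gsub("\\.", "p", format(rc))
    cols[[paste0("fast_profile_", tag)]] <- fp
    cols[[paste0("contact_number_", tag)]] <- cn
    hr <- find_hot_residues(fp, resnum = s$resnum, cutoff_used = rc)
    hot[[tag]] <- list(cutoff = rc, peak_residues = hr$peak_residues,
                       mean_contact_all = mean(cn),
                       mean_contact_hot = if (length(hr$peak_index))
                         mean(cn[hr$peak_index]) else NA)
  }
  write_profile_table(s, cols, file.path(out_dir, "gnm_profiles.csv"))
  write_matrix_csv(cross_correlation(g)$c,
                   file.path(out_dir, "cross_correlation.csv"))
  summary <- list(
    source = s$source_label, n_residues = n_residues(s),
    gnm_cutoff = config$gnm_cutoff,
    scale_kbt_over_gamma = if (is.null(fit)) NULL else fit$scale_kbt_over_gamma,
    pearson_r = if (is.null(fit)) NULL else fit$pearson_r,
    hinge_residues = hinges$hinge_residues,
    hot_residues = hot)
  jsonlite::write_json(summary, file.path(out_dir, "gnm_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Single-structure ANM analysis
#'
#' Writes per-mode per-residue fluctuation and direction CSVs for the
#' `n_modes` slowest ANM modes, the all-mode ANM msf profile, and a summary
#' JSON (fitted scale and per-mode eigenvalues).
#'
#' @inheritParams run_gnm
#' @param n_modes number of slow modes to report (default 3: rotation,
#'   bending, twisting in a two-domain protein).
#' @return invisibly, the summary list.
#' @export
run_anm <- function(input, out_dir, config = enm_config(), n_modes = 3L,
                    chain = NULL, model = 1L) {
  s <- read_input(input, chain, model)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  a <- enm_decompose(build_hessian(s, config$anm_cutoff))
  raw <- anm_msf(a)
  fit <- if (!is.null(s$exp_bfactor) && stats::sd(s$exp_bfactor) > 0) {
    fit_scale(raw, s$exp_bfactor)
  }
  scale <- if (is.null(fit)) 1 else fit$scale_kbt_over_gamma
  prof <- anm_msf(a, scale = scale)
  cols <- list(msf = prof$msf, bfactor_pred = prof$bfactor_pred)
  eigs <- numeric(n_modes)
  for (k in seq_len(n_modes)) {
    mk <- anm_mode_fluctuation(a, k)
    eigs[k] <- mk$eigenvalue
    cols[[paste0("mode", k, "_msf")]] <- mk$msf
    cols[[paste0("mode", k, "_dx")]] <- mk$directions[, 1L]
    cols[[paste0("mode", k, "_dy")]] <- mk$directions[, 2L]
    cols[[paste0("mode", k, "_dz")]] <- mk$directions[, 3L]
  }
  write_profile_table(s, cols, file.path(out_dir, "anm_profiles.csv"))
  summary <- list(
    source = s$source_label, n_residues = n_residues(s),
    anm_cutoff = config$anm_cutoff, n_zero_modes = a$n_zero,
    scale_kbt_over_gamma = if (is.null(fit)) NULL else fit$scale_kbt_over_gamma,
    pearson_r = if (is.null(fit)) NULL else fit$pearson_r,
    mode_eigenvalues = eigs)
  jsonlite::write_json(summary, file.path(out_dir, "anm_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Two-conformer comparison
#'
#' Pairs the residues of two conformers and writes the difference-distance
#' matrix with its -1/0/+1 classification, the slowest-mode fluctuation
#' difference profile, and a rotation JSON (angle, domains, fixed-domain
#' rmsd, pairing coverage). Domain definitions come from the config; when
#' absent the rotation step is skipped.
#'
#' @param input_a,input_b `calpha` structures or PDB paths (conformers A and
#'   B, e.g. open and closed).
#' @inheritParams run_gnm
#' @return invisibly, the summary list.
#' @export
run_compare <- function(input_a, input_b, out_dir, config = enm_config()) {
  a <- read_input(input_a); b <- read_input(input_b)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pairing <- pair_residues(a, b)
  ddm <- difference_distance(a, b, pairing, config$ddm_threshold)
  write_matrix_csv(ddm$delta, file.path(out_dir, "difference_distance.csv"))
  write_matrix_csv(ddm$classes, file.path(out_dir, "difference_distance_classes.csv"))
  ga <- enm_decompose(build_kirchhoff(a, config$gnm_cutoff))
  gb <- enm_decompose(build_kirchhoff(b, config$gnm_cutoff))
  fd <- fluctuation_difference(gnm_mode_msf(ga, 1L), gnm_mode_msf(gb, 1L), pairing)
  sub <- subset_calpha(a, pairing$idx_a)
  write_profile_table(sub, list(slow_mode_fluct_diff = fd),
                      file.path(out_dir, "fluctuation_difference.csv"))
  rot <- NULL
  if (!is.null(config$fixed_domain) && !is.null(config$moving_domain)) {
    r <- rotation_angle(a, b, pairing, config$fixed_domain, config$moving_domain)
    rot <- list(angle_deg = r$angle_deg, rmsd_fixed = r$rmsd_fixed,
                fixed_domain = config$fixed_domain,
                moving_domain = config$moving_domain)
  }
  summary <- list(source_a = a$source_label, source_b = b$source_label,
                  n_pairs = length(pairing$idx_a), coverage = pairing$coverage,
                  ddm_threshold = config$ddm_threshold, rotation = rot)
  jsonlite::write_json(summary, file.path(out_dir, "compare_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Generate and write a synthetic conformer pair
#'
#' Writes open and closed synthetic dumbbell conformers as CA-only PDB files
#' (with a synthetic B-factor column on the open form) plus a ground-truth
#' labels JSON (domain masks, linker, true rotation angle, true kBT/gamma).
#'
#' @param out_dir output directory.
#' @param angle_deg true hinge rotation angle (degrees).
#' @param scale true kBT/gamma used for the synthetic B-factors.
#' @param noise_sd_fraction B-factor noise level.
#' @param seed integer seed.
#' @param ... forwarded to [make_conformer_pair()].
#' @return invisibly, list with paths and labels.
#' @export
run_synth <- function(out_dir, angle_deg = 41.3, scale = 5.64,
                      noise_sd_fraction = 0.05, seed = 1L, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pair <- make_conformer_pair(seed = seed, angle_deg = angle_deg, ...)
  pair$open$exp_bfactor <- as.numeric(synth_bfactors(
    pair$open, scale = scale, noise_sd_fraction = noise_sd_fraction, seed = seed))
  pair$closed$exp_bfactor <- as.numeric(synth_bfactors(
    pair$closed, scale = scale, noise_sd_fraction = noise_sd_fraction,
    seed = seed + 1L))
  open_path <- file.path(out_dir, "synthetic_open.pdb")
  closed_path <- file.path(out_dir, "synthetic_closed.pdb")
  write_calpha_pdb(pair$open, open_path)
  write_calpha_pdb(pair$closed, closed_path)
  labels <- c(pair$labels,
              list(true_scale_kbt_over_gamma = scale,
                   noise_sd_fraction = noise_sd_fraction, seed = seed))
  jsonlite::write_json(labels, file.path(out_dir, "synthetic_labels.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(open = open_path, closed = closed_path, labels = labels))
}
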