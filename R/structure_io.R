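#' Construct a C-alpha structure
#'
#' The package's central container: one node per residue, holding the residue
#' identifier (chain, author residue number, insertion code), the 3-letter
#' residue name, the C-alpha coordinates in Angstrom and, when available, the
#' experimental B-factor column in Angstrom squared.
#'
#' @param chain character vector of chain identifiers, one per residue.
#' @param resnum integer vector of author residue numbers.
#' @param icode character vector of insertion codes ("" when absent).
#' @param resname character vector of 3-letter residue names.
#' @param coords numeric N x 3 matrix of C-alpha positions (Angstrom).
#' @param exp_bfactor optional numeric vector of experimental B-factors
#'   (Angstrom^2), non-negative, length N.
#' @param source_label free-text provenance label (file name, PDB ID, ...).
#'
#' @return An object of class `calpha`: a list with elements `chain`,
#'   `resnum`, `icode`, `resname`, `coords`, `exp_bfactor`, `source_label`.
#' @export
calpha_structure <- function(chain, resnum, icode = NULL, resname = NULL,
                             coords, exp_bfactor = NULL, source_label = "") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  n <- nrow(coords)
  if (n < 1L) stop("structure must contain at least one residue")
  chain <- rep_len(as.character(chain), n)
  resnum <- rep_len(as.integer(resnum), n)
  if (is.null(icode)) icode <- ""
  icode <- rep_len(as.character(icode), n)
  if (is.null(resname)) resname <- "UNK"
  resname <- rep_len(as.character(resname), n)
  if (length(chain) != n || length(resnum) != n) {
    stop("residue identifiers and coords disagree in length")
  }
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  key <- paste(chain, resnum, icode, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicated residue identifier: ", key[duplicated(key)][1L])
  }
  if (!is.null(exp_bfactor)) {
    exp_bfactor <- as.numeric(exp_bfactor)
    if (length(exp_bfactor) != n) stop("exp_bfactor must have one value per residue")
    if (any(!is.finite(exp_bfactor)) || any(exp_bfactor < 0)) {
      stop("exp_bfactor values must be finite and >= 0")
    }
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(
    list(chain = chain, resnum = resnum, icode = icode, resname = resname,
         coords = coords, exp_bfactor = exp_bfactor,
         source_label = as.character(source_label)),
    class = "calpha"
  )
}

#' @export
print.calpha <- function(x, ...) {
  cat(sprintf("C-alpha structure: %d residues, chains %s%s\n",
              n_residues(x), paste(unique(x$chain), collapse = ","),
              if (is.null(x$exp_bfactor)) "" else ", with experimental B-factors"))
  if (nzchar(x$source_label)) cat("  source:", x$source_label, "\n")
  invisible(x)
}

#' Number of residues in a structure
#' @param s a `calpha` structure.
#' @return integer count.
#' @export
n_residues <- function(s) nrow(s$coords)

residue_key <- function(s) paste(s$chain, s$resnum, s$icode, sep = "|")

#' Subset a C-alpha structure by residue index
#' @param s a `calpha` structure.
#' @param idx integer indices (in current residue order).
#' @return a `calpha` structure with the selected residues.
#' @export
subset_calpha <- function(s, idx) {
  calpha_structure(s$chain[idx], s$resnum[idx], s$icode[idx], s$resname[idx],
                   s$coords[idx, , drop = FALSE],
                   if (is.null(s$exp_bfactor)) NULL else s$exp_bfactor[idx],
                   s$source_label)
}

#' Read C-alpha atoms and B-factors from a PDB file
#'
#' Parses a (possibly gzipped) PDB file and returns one record per residue
#' that has a C-alpha atom, in file order, with the B-factor column copied to
#' `exp_bfactor`. HETATM records (waters, ligands) are excluded, so a bound
#' sugar never enters the elastic network; non-standard residues with a CA
#' atom are kept. Alternate locations are resolved to the highest-occupancy
#' conformer, ties broken by the alphabetically first altloc code.
#'
#' @param path path to a PDB file (plain or `.gz`).
#' @param chain optional chain identifier. When `NULL` and the file has
#'   several chains, the first chain containing C-alpha atoms is used with a
#'   warning (crystal structures of monomeric proteins rarely need more).
#' @param model model ordinal for multi-model files (default 1, the
#'   deposited crystal-structure convention).
#'
#' @return a [calpha_structure()].
#' @export
read_calpha <- function(path, chain = NULL, model = 1L) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  atoms <- pdb$atom
  n_models <- nrow(pdb$xyz)
  if (model < 1L || model > n_models) {
    stop(sprintf("model %d requested but file '%s' has %d model(s)",
                 model, path, n_models))
  }
  if (model > 1L) {
    xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
    atoms$x <- xyz[, 1L]; atoms$y <- xyz[, 2L]; atoms$z <- xyz[, 3L]
  }
  ca <- atoms[atoms$type == "ATOM" & atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no C-alpha atoms found in ", path)
  ca$chain[is.na(ca$chain)] <- " "
  if (!is.null(chain)) {
    if (!chain %in% ca$chain) {
      stop(sprintf("chain '%s' not present in '%s' (chains with CA: %s)",
                   chain, path, paste(unique(ca$chain), collapse = ", ")))
    }
    ca <- ca[ca$chain == chain, , drop = FALSE]
  } else {
    chains <- unique(ca$chain)
    if (length(chains) > 1L) {
      warning(sprintf("file '%s' has chains %s; using first chain '%s'",
                      path, paste(chains, collapse = ","), chains[1L]))
    }
    ca <- ca[ca$chain == chains[1L], , drop = FALSE]
  }
  ca$insert[is.na(ca$insert)] <- ""
  ca$alt[is.na(ca$alt)] <- ""
  ca$o[is.na(ca$o)] <- 1
  key <- paste(ca$chain, ca$resno, ca$insert, sep = "|")
  # altloc resolution: highest occupancy, tie -> alphabetically first code
  keep <- unlist(lapply(split(seq_len(nrow(ca)), factor(key, levels = unique(key))),
                        function(rows) {
    if (length(rows) == 1L) return(rows)
    sub <- ca[rows, ]
    rows[order(-sub$o, sub$alt)][1L]
  }), use.names = FALSE)
  keep <- sort(keep)  # preserve file order
  ca <- ca[keep, , drop = FALSE]
  b <- ca$b
  # an all-zero column is a placeholder, not a measurement
  has_b <- all(is.finite(b)) && all(b >= 0) && any(b > 0)
  calpha_structure(ca$chain, ca$resno, ca$insert, ca$resid,
                   cbind(ca$x, ca$y, ca$z),
                   exp_bfactor = if (has_b) b else NULL,
                   source_label = basename(path))
}

#' Pair residues between two conformers of the same protein
#'
#' Matches residues by (chain, residue number, insertion code) so per-residue
#' quantities (distances, fluctuations) can be subtracted between an open and
#' a closed structure. Unmatched residues are dropped.
#'
#' @param a,b `calpha` structures.
#' @return object of class `residue_pairing`: list with `idx_a`, `idx_b`
#'   (parallel integer indices, ordered by `a`'s sequence) and `coverage`
#'   (fraction of `a`'s residues paired).
#' @export
pair_residues <- function(a, b) {
  stopifnot(inherits(a, "calpha"), inherits(b, "calpha"))
  m <- match(residue_key(a), residue_key(b))
  idx_a <- which(!is.na(m))
  idx_b <- m[idx_a]
  if (length(idx_a) == 0L) {
    stop(sprintf("no residues in common between '%s' and '%s'",
                 a$source_label, b$source_label))
  }
  structure(list(idx_a = idx_a, idx_b = idx_b,
                 coverage = length(idx_a) / n_residues(a)),
            class = "residue_pairing")
}

#' @export
print.residue_pairing <- function(x, ...) {
  cat(sprintf("residue pairing: %d pairs, coverage %.3f\n",
              length(x$idx_a), x$coverage))
  invisible(x)
}

#' Write a per-residue profile table as CSV
#'
#' @param s a `calpha` structure supplying the residue identifier columns.
#' @param values named list (or data.frame) of numeric vectors, one value per
#'   residue; may be empty for a header-only file.
#' @param path output file path.
#' @return invisibly, the data.frame written.
#' @export
write_profile_table <- function(s, values, path) {
  values <- as.list(values)
  for (nm in names(values)) {
    if (length(values[[nm]]) != n_residues(s)) {
      stop(sprintf("column '%s' has length %d but structure has %d residues",
                   nm, length(values[[nm]]), n_residues(s)))
    }
  }
  df <- data.frame(chain = s$chain, resnum = s$resnum, icode = s$icode,
                   resname = s$resname, stringsAsFactors = FALSE)
  for (nm in names(values)) df[[nm]] <- values[[nm]]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Write a C-alpha structure as a PDB file
#'
#' Emits standard ATOM records (CA only, occupancy 1.00) so synthetic
#' structures can be fed back through the file interface. The `exp_bfactor`
#' column, when present, fills the B-factor field.
#'
#' @param s a `calpha` structure.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_calpha_pdb <- function(s, path) {
  b <- if (is.null(s$exp_bfactor)) rep(0, n_residues(s)) else s$exp_bfactor
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(s$coords)),
                   resno = s$resnum, chain = s$chain, resid = s$resname,
                   insert = ifelse(nzchar(s$icode), s$icode, ""),
                   elety = rep("CA", n_residues(s)),
                   o = rep(1, n_residues(s)), b = b)
  invisible(path)
}

#' Export a matrix as dense CSV
#' @param m numeric matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a matrix as coordinate-format sparse text
#'
#' Writes non-zero entries as `i,j,value` with 1-based indices.
#' @param m numeric matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_matrix_sparse <- function(m, path) {
  nz <- which(m != 0, arr.ind = TRUE)
  df <- data.frame(i = nz[, 1L], j = nz[, 2L], value = m[nz])
  df <- df[order(df$i, df$j), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
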