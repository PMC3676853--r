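# Fixtures are built in code: hand-formatted PDB records and small exactly
# solvable network substrates.

pdb_atom_line <- function(serial, name = "CA", alt = "", resname = "ALA",
                          chain = "A", resno, icode = "", x, y, z,
                          occ = 1.00, b = 0.00, type = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          type, serial, paste0(" ", name), alt, resname, chain, resno, icode,
          x, y, z, occ, b)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# single ALA with one CA atom
fixture_single_ala <- function() {
  write_pdb_fixture(pdb_atom_line(1, resno = 1, x = 1, y = 2, z = 3, b = 10))
}

# 3 residues; residue 2 in altlocs A (x=1) and B (x=9) with given occupancies
fixture_altloc <- function(occ_a = 0.5, occ_b = 0.5) {
  write_pdb_fixture(c(
    pdb_atom_line(1, resno = 1, x = 0, y = 0, z = 0),
    pdb_atom_line(2, alt = "A", resno = 2, x = 1, y = 0, z = 0, occ = occ_a),
    pdb_atom_line(3, alt = "B", resno = 2, x = 9, y = 0, z = 0, occ = occ_b),
    pdb_atom_line(4, resno = 3, x = 4, y = 0, z = 0)))
}

# two chains plus a HETATM ligand with a CA-named atom
fixture_two_chains <- function() {
  write_pdb_fixture(c(
    pdb_atom_line(1, chain = "A", resno = 1, x = 0, y = 0, z = 0),
    pdb_atom_line(2, chain = "A", resno = 2, x = 3.8, y = 0, z = 0),
    pdb_atom_line(3, chain = "B", resno = 1, x = 0, y = 10, z = 0),
    pdb_atom_line(4, chain = "B", resno = 2, x = 3.8, y = 10, z = 0),
    pdb_atom_line(5, chain = "B", resno = 3, x = 7.6, y = 10, z = 0),
    pdb_atom_line(6, resname = "RIB", chain = "A", resno = 500,
                  x = 1, y = 1, z = 1, type = "HETATM")))
}

# structure with residues numbered `resnums` on a line, 3.8 A apart
calpha_with_resnums <- function(resnums, chain = "A") {
  calpha_structure(chain, resnums,
                   coords = cbind(3.8 * seq_along(resnums), 0, 0))
}

# the exactly solvable path-3 GNM substrate (contacts 1-2 and 2-3 only)
path3 <- function() make_chain(3, 3.8, "line")

# two beads 1 A apart along x: the exactly solvable ANM substrate
two_beads <- function() {
  calpha_structure("A", 1:2, coords = rbind(c(0, 0, 0), c(1, 0, 0)))
}

random_rotation_matrix <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_motion <- function(s, rot = diag(3), shift = c(0, 0, 0)) {
  out <- s
  out$coords <- sweep(s$coords %*% t(rot), 2, shift, "+")
  attr(out, "labels") <- attr(s, "labels")
  out
}

# connected irregular test structure: jittered ideal helix
random_connected_structure <- function(n, seed) {
  jitter_structure(make_chain(n, geometry = "helix"), sd = 0.3, seed = seed)
}
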