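# In-code fixtures shared across test files.

pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     occ = 1, altloc = " ", element = "C") {
  sprintf("ATOM  %5d  %-3s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, altloc, resname, chain, resno, x, y, z, occ, 0,
          element)
}

# three residues: ALA1 (N/CA/CB), GLY2 (CA), ALA3 (CA, no CB)
tripeptide_pdb <- function() {
  c(pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0, element = "N"),
    pdb_line(2, "CA", "ALA", "A", 1, 1.458, 0, 0),
    pdb_line(3, "CB", "ALA", "A", 1, 2.0, 1.4, 0),
    pdb_line(4, "CA", "GLY", "A", 2, 3.0, 1.0, 0),
    pdb_line(5, "CA", "ALA", "A", 3, 6.0, 5.0, 0),
    "END")
}

# a small rigid body structure with CA/CB per residue at given CA coords
body_structure <- function(ca, chain = "A", resname = "ALA") {
  n <- nrow(ca)
  lines <- character(0)
  s <- 0L
  for (i in seq_len(n)) {
    s <- s + 1L
    lines <- c(lines, pdb_line(s, "CA", resname, chain, i,
                               ca[i, 1], ca[i, 2], ca[i, 3]))
    s <- s + 1L
    lines <- c(lines, pdb_line(s, "CB", resname, chain, i,
                               ca[i, 1] + 1.0, ca[i, 2], ca[i, 3]))
  }
  parse_structure(c(lines, "END"), "pdb")
}

# build a two-chain structure whose pair i has an exact CB-CB distance d[i];
# pairs are spaced far apart in y so they do not interfere
planted_distance_complex <- function(d) {
  n <- length(d)
  atoms_r <- data.frame(
    serial = seq_len(n), elety = "CB", altloc = "", resname = "ALA",
    chain = "R", resno = seq_len(n), insert = "",
    x = 0, y = 50 * seq_len(n), z = 0, occ = 1, element = "C",
    stringsAsFactors = FALSE)
  atoms_a <- atoms_r
  atoms_a$chain <- "A"
  atoms_a$x <- d
  atoms_a$serial <- n + seq_len(n)
  st <- structure(list(atoms = rbind(atoms_r, atoms_a)),
                  class = "xl_structure")
  st
}

random_rotation <- function() {
  axis_rotation(stats::rnorm(3), stats::runif(1, 0, 360))
}
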