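# Synthetic structure fixtures (no deposited coordinates are bundled;
# these are stand-ins built in code and labelled synthetic).

# A synthetic two-chain alpha-helical dimer: two ideal poly-CA helices
# packed side by side, dense enough to bury a real interface. Not a model
# of any deposited structure.
synthetic_helix_dimer <- function(n_res = 40, spacing = 5.0) {
  helix <- function(chain, x0) {
    t <- seq_len(n_res)
    # ideal alpha-helix CA trace: radius 2.3 A, rise 1.5 A, 100 deg/res
    ang <- t * 100 * pi / 180
    data.frame(chain = chain, resno = t, resid = "ALA", elety = "CA",
               x = x0 + 2.3 * cos(ang), y = 2.3 * sin(ang), z = 1.5 * t,
               stringsAsFactors = FALSE)
  }
  structure_model(rbind(helix("A", 0), helix("B", spacing)),
                  source_id = "synthetic-helix-dimer")
}

# A central atom fully enclosed by a dense shell of atoms.
buried_atom_fixture <- function() {
  pts <- foamygag:::fibonacci_sphere(80) * 3.0
  shell <- data.frame(chain = "A", resno = seq_len(nrow(pts)) + 1,
                      resid = "GLY", elety = "C",
                      x = pts[, 1], y = pts[, 2], z = pts[, 3],
                      stringsAsFactors = FALSE)
  centre <- data.frame(chain = "A", resno = 1, resid = "GLY", elety = "C",
                       x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  structure_model(rbind(centre, shell))
}

# Minimal PDB text (3 atoms, one with A/B altlocs, a water, a hydrogen)
# for parser tests; written to a tempfile by the caller.
minimal_pdb_text <- function() {
  c("HEADER    SYNTHETIC TEST FIXTURE",
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  CB AALA A   1      12.759   7.095  -4.989  0.60  0.00           C",
    "ATOM      4  CB BALA A   1      12.900   7.200  -5.100  0.40  0.00           C",
    "ATOM      5  H   ALA A   1      10.500   5.500  -7.000  1.00  0.00           H",
    "HETATM    6  O   HOH A 101       0.000   0.000   0.000  1.00  0.00           O",
    "END")
}

rigid_transform <- function(xyz, angle = 0.7, shift = c(3, -2, 7)) {
  R <- matrix(c(cos(angle), -sin(angle), 0,
                sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  sweep(xyz %*% t(R), 2, shift, "+")
}
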