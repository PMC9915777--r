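# Shared fixtures, all built in code.

# Hand-enumerable calibration set: 4 P and 4 B records with known ddG.
toy_calibration_table <- function() {
  variant_table(
    gene = rep("GJB2", 8),
    protein_change = sprintf("p.Ala%dVal", 1:8),
    classification = c(rep("P", 4), rep("B", 4)),
    ddg_fold = c(2.5, 2.0, 1.0, 0.5, 0.1, 0.2, 1.9, -0.3),
    cadd = c(30, 28, 22, 20, 10, 12, 18, 8)
  )
}

# Deterministic 20-residue toy helix with a planted pLDDT ramp.
helix_plddt <- function() seq(5, 100, length.out = 20)

helix_pdb_path <- function() {
  path <- file.path(tempdir(), "vusfold-helix20.pdb")
  if (!file.exists(path)) {
    writeLines(generate_toy_structure(20, helix_plddt()), path)
  }
  path
}

# 27 single-CA "residues" on a 3x3x3 grid with 3.5 A spacing; the central
# residue (number 14) is fully buried.
cluster_pdb_path <- function() {
  path <- file.path(tempdir(), "vusfold-cluster27.pdb")
  if (!file.exists(path)) {
    g <- expand.grid(x = 0:2, y = 0:2, z = 0:2) * 3.5
    lines <- sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00 50.00           C",
      seq_len(27), seq_len(27), g$x, g$y, g$z)
    writeLines(c(lines, "END"), path)
  }
  path
}

extdata <- function(file) {
  system.file("extdata", file, package = "vusfold", mustWork = TRUE)
}
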