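# Shrake-Rupley solvent accessible surface area.
#
# Each atom is inflated by the probe radius and covered with a
# deterministic quasi-uniform point lattice (golden-spiral); a point is
# accessible when it falls outside every neighbouring atom's inflated
# sphere. The accessible fraction times the inflated sphere area is the
# atom's SASA.

# van der Waals radii (Angstrom) by element; the fallback covers rare
# heteroatoms conservatively.
vdw_radius <- function(element) {
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
             P = 1.80, SE = 1.90)
  r <- radii[toupper(element)]
  r[is.na(r)] <- 1.80
  unname(r)
}

# n quasi-uniform unit vectors via the golden-spiral (Fibonacci) lattice.
sphere_points <- function(n) {
  stopifnot(n >= 1)
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Per-atom SASA for coordinates `xyz` (n x 3) and element symbols.
atom_sasa <- function(xyz, elements, probe_radius = 1.4, n_points = 960) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3, nrow(xyz) == length(elements))
  n <- nrow(xyz)
  radii <- vdw_radius(elements) + probe_radius
  pts <- sphere_points(n_points)
  out <- numeric(n)
  max_r <- max(radii)
  for (i in seq_len(n)) {
    ri <- radii[i]
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nbr <- which(d2 < (ri + max_r)^2 & d2 > 0)
    nbr <- nbr[sqrt(d2[nbr]) < ri + radii[nbr]]
    surf <- pts * ri
    surf <- sweep(surf, 2, xyz[i, ], "+")
    accessible <- rep(TRUE, n_points)
    for (j in nbr) {
      if (!any(accessible)) break
      rj2 <- radii[j]^2
      dj2 <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
        (surf[, 3] - xyz[j, 3])^2
      accessible <- accessible & dj2 >= rj2
    }
    out[i] <- 4 * pi * ri^2 * sum(accessible) / n_points
  }
  out
}

#' Theoretical maximum accessible surface area per residue type
#'
#' Tien et al. (2013) theoretical maximum ASA values (Angstrom^2) for the
#' twenty standard amino acids, used to normalize absolute SASA to a
#' relative (percent) accessibility. Residue types outside this table get
#' no relative value.
#'
#' @return Named numeric vector keyed by 3-letter residue code.
#' @export
max_asa_table <- function() {
  c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
    GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
    LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
    SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)
}
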