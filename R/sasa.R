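# Shrake-Rupley solvent-accessible surface area.
#
# Used as the accessibility source when no DSSP output is supplied. A
# deterministic golden-spiral point set makes results reproducible for a
# fixed point count.

# van der Waals radii (Angstroms) for the elements found in protein
# structures without hydrogens
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

golden_spiral_points <- function(n) {
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a spherical probe over the structure: each atom is covered with a
#' deterministic golden-spiral point set on its solvent-expanded sphere
#' (radius = van der Waals radius + probe radius); a point is accessible if
#' it lies outside every other atom's expanded sphere. The atom's ASA is
#' the accessible fraction times the sphere area, and residue ASA is the
#' sum over the residue's atoms.
#'
#' @param structure A `structure_model`.
#' @param probe_radius Probe radius in Angstroms (water: 1.4).
#' @param n_points Points per atom sphere; 960 gives ~1-2% accuracy.
#' @return Data frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `acc` (absolute ASA, square Angstroms), one row per residue in
#'   structure order.
#' @export
shrake_rupley_sasa <- function(structure, probe_radius = 1.4,
                               n_points = 960) {
  at <- structure$atoms
  rad <- VDW_RADII[at$elesy]
  if (any(is.na(rad))) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(at$elesy[is.na(rad)]), collapse = ", "))
  }
  rad <- unname(rad) + probe_radius
  xyz <- cbind(at$x, at$y, at$z)
  sphere <- golden_spiral_points(n_points)
  n <- nrow(xyz)
  atom_asa <- numeric(n)
  # pairwise distances once; neighbours are atoms whose expanded spheres
  # can occlude this atom's sphere
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    cut <- (rad[i] + rad)^2
    nb <- which(d2[i, ] < cut)
    nb <- nb[nb != i]
    pts <- sweep(sphere * rad[i], 2, xyz[i, ], "+")
    if (length(nb) == 0L) {
      frac <- 1
    } else {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(free)) break
        dx <- pts[free, 1] - xyz[j, 1]
        dy <- pts[free, 2] - xyz[j, 2]
        dz <- pts[free, 3] - xyz[j, 3]
        free[free] <- dx * dx + dy * dy + dz * dz >= rad[j]^2
      }
      frac <- mean(free)
    }
    atom_asa[i] <- frac * 4 * pi * rad[i]^2
  }
  key <- paste(at$chain, at$resno, at$insert, sep = "\r")
  res <- structure$residues
  rkey <- paste(res$chain, res$resno, res$insert, sep = "\r")
  acc <- as.numeric(tapply(atom_asa, factor(key, levels = rkey), sum))
  data.frame(chain = res$chain, resno = res$resno, insert = res$insert,
             resid = res$resid, acc = acc, stringsAsFactors = FALSE)
}
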