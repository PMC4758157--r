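# Shrake-Rupley solvent-accessible surface area.
#
# Each atom is inflated by the probe radius and covered with a deterministic
# quasi-uniform point set (generalised-spiral / golden-angle lattice); points
# falling inside any neighbouring inflated sphere are occluded, and the
# accessible fraction times the inflated sphere area gives the atom's SASA.
# Per-residue SASA is the sum over the residue's atoms.

# n quasi-uniform unit-sphere points (golden-angle spiral); deterministic.
sphere_points <- function(n) {
  if (n < 1) stop("n_points must be >= 1")
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Shrake-Rupley per-residue solvent-accessible surface area
#'
#' Computes SASA for one chain considered in isolation (the exposure of the
#' unbound monomer), in A^2, summed per residue.
#'
#' @param structure a [complex_structure()].
#' @param chain chain id to analyse.
#' @param probe_radius solvent probe radius in A (default 1.4, water).
#' @param n_points quadrature points per atom (default 960); accuracy
#'   improves as points increase, converging to the exact spherical areas.
#' @return data.frame with `residue_index`, `residue_type`, `sasa`.
#' @export
shrake_rupley_sasa <- function(structure, chain, probe_radius = 1.4,
                               n_points = 960) {
  if (n_points < 1) stop("n_points must be >= 1")
  at <- structure$atoms
  if (!chain %in% at$chain_id) stop("chain not in structure: ", chain)
  at <- at[at$chain_id == chain, , drop = FALSE]
  pts <- sphere_points(n_points)

  xyz <- as.matrix(at[, c("x", "y", "z")])
  R <- at$vdw_radius + probe_radius
  n <- nrow(at)
  atom_sasa <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (R[i] + R)^2 & seq_len(n) != i)
    p <- pts * R[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (p[free, 1] - xyz[j, 1])^2 + (p[free, 2] - xyz[j, 2])^2 +
        (p[free, 3] - xyz[j, 3])^2
      free[free] <- dj2 >= R[j]^2
    }
    atom_sasa[i] <- 4 * pi * R[i]^2 * sum(free) / n_points
  }

  agg <- stats::aggregate(atom_sasa,
                          by = list(residue_index = at$residue_index),
                          FUN = sum)
  type <- at$residue_type[match(agg$residue_index, at$residue_index)]
  out <- data.frame(residue_index = agg$residue_index,
                    residue_type = type, sasa = agg$x)
  out[order(out$residue_index), ]
}
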