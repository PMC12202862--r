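#' Deterministic Shrake-Rupley solvent accessible surface area
#'
#' Classic rolling-probe SASA: each heavy atom is expanded by the probe
#' radius, a quasi-uniform point lattice is placed on the expanded sphere,
#' and the accessible fraction is the share of lattice points not inside any
#' neighbor's expanded sphere. The lattice is a golden-spiral (Fibonacci)
#' point set, so the computation involves no random numbers and is exactly
#' reproducible. Neighbor candidates are pruned by the exact geometric bound
#' (centers closer than the sum of expanded radii), which cannot change the
#' result relative to an all-pairs check.
#'
#' @param chain An `rsalor_chain` from [read_pdb_chain()].
#' @param probe_radius Probe (solvent) radius in Angstrom; default 1.4.
#' @param n_sphere_points Lattice points per atom (>= 20); default 100.
#' @param occluders `"chain"` (default) to let only the chain's own atoms
#'   occlude, or `"all-chains"` to include every other chain's heavy atoms
#'   as additional occluders (relevant when scoring interface residues in a
#'   complex).
#' @return The chain's `atoms` tibble with an added `sasa` column (Angstrom^2).
#' @export
shrake_rupley <- function(chain, probe_radius = 1.4, n_sphere_points = 100L,
                          occluders = c("chain", "all-chains")) {
  stopifnot(inherits(chain, "rsalor_chain"))
  occluders <- match.arg(occluders)
  if (probe_radius <= 0) abort("probe_radius must be positive")
  if (n_sphere_points < 20L) abort("n_sphere_points must be at least 20")
  extra <- if (occluders == "all-chains") chain$other_atoms else NULL
  atoms <- chain$atoms
  atoms$sasa <- sasa_per_atom(
    xyz = cbind(atoms$x, atoms$y, atoms$z),
    radii = atoms$radius,
    probe = probe_radius,
    n_points = as.integer(n_sphere_points),
    occ_xyz = if (!is.null(extra)) cbind(extra$x, extra$y, extra$z),
    occ_radii = extra$radius
  )
  atoms
}

# Golden-spiral lattice: n quasi-uniform points on the unit sphere.
golden_spiral <- function(n) {
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (k - 1)
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

sasa_per_atom <- function(xyz, radii, probe, n_points,
                          occ_xyz = NULL, occ_radii = NULL) {
  n <- nrow(xyz)
  lattice <- golden_spiral(n_points)
  all_xyz <- rbind(xyz, occ_xyz)
  all_exp <- c(radii, occ_radii) + probe
  exp_r <- radii + probe
  out <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (all_xyz[, 1] - xyz[i, 1])^2 +
          (all_xyz[, 2] - xyz[i, 2])^2 +
          (all_xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (exp_r[i] + all_exp)^2)
    nb <- nb[nb != i]
    if (length(nb) == 0L) {
      out[i] <- 4 * pi * exp_r[i]^2
      next
    }
    pts <- lattice * exp_r[i]
    px <- pts[, 1] + xyz[i, 1]
    py <- pts[, 2] + xyz[i, 2]
    pz <- pts[, 3] + xyz[i, 3]
    buried <- rep(FALSE, n_points)
    for (j in nb) {
      buried <- buried |
        ((px - all_xyz[j, 1])^2 + (py - all_xyz[j, 2])^2 +
         (pz - all_xyz[j, 3])^2 < all_exp[j]^2)
    }
    out[i] <- 4 * pi * exp_r[i]^2 * sum(!buried) / n_points
  }
  out
}

#' Per-residue relative solvent accessibility
#'
#' Sums atomic SASA per residue and normalizes by the residue type's
#' theoretical maximum accessible surface area (Tien et al. 2013 values):
#' `RSA = 100 * SASA / maxASA(aa)`, in percent. Values above 100 (possible
#' for residues more exposed than the tripeptide reference, e.g. chain
#' termini) are preserved in `rsa` and capped at 100 in `rsa_clipped`; only
#' the clipped value enters scoring, so a fully exposed residue gets zero
#' structural weight, never a negative one.
#'
#' @param chain An `rsalor_chain`.
#' @param per_atom_sasa Optional result of [shrake_rupley()]; computed with
#'   the parameters below when omitted.
#' @param max_asa Named vector of reference maximum ASA per one-letter code.
#' @inheritParams shrake_rupley
#' @return A tibble of class `rsalor_rsa`: `residue_key`, `resno`, `insert`,
#'   `aa`, `n_atoms`, `sasa`, `rsa`, `rsa_clipped`.
#' @export
rsa_profile <- function(chain, per_atom_sasa = NULL, probe_radius = 1.4,
                        n_sphere_points = 100L,
                        occluders = c("chain", "all-chains"),
                        max_asa = MAX_ASA) {
  stopifnot(inherits(chain, "rsalor_chain"))
  if (is.null(per_atom_sasa)) {
    per_atom_sasa <- shrake_rupley(chain, probe_radius, n_sphere_points,
                                   occluders)
  }
  prof <- per_atom_sasa %>%
    group_by(.data$residue_key, .data$resno, .data$insert, .data$aa) %>%
    summarise(n_atoms = dplyr::n(), sasa = sum(.data$sasa), .groups = "drop")
  # restore chain (file) order lost by grouping
  prof <- prof[match(chain$residues$residue_key, prof$residue_key), ,
               drop = FALSE]
  ref <- unname(max_asa[prof$aa])
  unknown <- is.na(ref)
  if (any(unknown)) {
    warn(sprintf("%d residue(s) without max-ASA reference excluded",
                 sum(unknown)))
    prof <- prof[!unknown, , drop = FALSE]
    ref <- ref[!unknown]
  }
  prof$rsa <- 100 * prof$sasa / ref
  prof$rsa_clipped <- pmin(prof$rsa, 100)
  class(prof) <- c("rsalor_rsa", class(prof))
  prof
}
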