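# Group-group nonbonded interaction energies (direct minimum-image pair
# sums of the Coulomb and 12-6 Lennard-Jones forms) and the relative
# stability factor of a eutectic pair against water.

# Shared pair setup: minimum-image distances with self/intramolecular
# pairs and (optionally) beyond-cutoff pairs masked out.
.pair_energy_setup <- function(frame, top, ia, ib, cutoff) {
  if (length(intersect(ia, ib))) {
    stop("groups must be disjoint at the atom level")
  }
  box <- as.numeric(frame$box)
  dm <- .pair_dist_matrix(frame$positions[ia, , drop = FALSE],
                          frame$positions[ib, , drop = FALSE], box)
  dm[outer(top$molecule_id[ia], top$molecule_id[ib], "==")] <- NA
  if (!is.null(cutoff)) dm[dm > cutoff] <- NA
  dm
}

#' Coulomb interaction energy between two groups
#'
#' Direct minimum-image sum `k_e sum q_i q_j / r_ij` over intermolecular
#' A-B pairs, with `k_e = 332.0636 kcal A / (mol e^2)` (the standard MD
#' convention for `e^2 / (4 pi eps0)`).
#'
#' @param frame An `md_frame`.
#' @param top An `md_topology` carrying partial charges.
#' @param group_a,group_b Disjoint atom selections.
#' @param cutoff Optional pair-distance cutoff (Angstrom); `NULL` sums all
#'   minimum-image pairs.
#' @return Energy in kcal/mol.
#' @export
coulomb_energy <- function(frame, top, group_a, group_b, cutoff = NULL) {
  ia <- .resolve_group(group_a, top)
  ib <- .resolve_group(group_b, top)
  dm <- .pair_energy_setup(frame, top, ia, ib, cutoff)
  tiny <- which(!is.na(dm) & dm < 1e-6, arr.ind = TRUE)
  if (nrow(tiny)) {
    stop(sprintf("singularity: atoms %d and %d overlap (r < 1e-6 A)",
                 ia[tiny[1, 1]], ib[tiny[1, 2]]))
  }
  qq <- outer(top$charge[ia], top$charge[ib])
  .COULOMB_K * sum(qq / dm, na.rm = TRUE)
}

#' Lennard-Jones (12-6) interaction energy between two groups
#'
#' Direct minimum-image sum of
#' `D0_ij [ (R0_ij/r)^12 - 2 (R0_ij/r)^6 ]` with Lorentz-Berthelot
#' combination: `D0_ij = sqrt(D0_i D0_j)`, `R0_ij = (R0_i + R0_j)/2`.
#' The single-pair minimum is `-D0_ij` at `r = R0_ij`.
#'
#' @inheritParams coulomb_energy
#' @param combining Combining rule; only `"lb"` (Lorentz-Berthelot) is
#'   implemented.
#' @return Energy in kcal/mol.
#' @export
vdw_energy <- function(frame, top, group_a, group_b, combining = "lb",
                       cutoff = NULL) {
  combining <- match.arg(combining, "lb")
  ia <- .resolve_group(group_a, top)
  ib <- .resolve_group(group_b, top)
  if (any(top$d0[c(ia, ib)] < 0)) stop("negative Lennard-Jones well depth D0")
  dm <- .pair_energy_setup(frame, top, ia, ib, cutoff)
  d0 <- sqrt(outer(top$d0[ia], top$d0[ib]))
  r0 <- outer(top$r0[ia], top$r0[ib], "+") / 2
  s6 <- (r0 / dm)^6
  sum(d0 * (s6^2 - 2 * s6), na.rm = TRUE)
}

#' Time-averaged pairwise interaction energy report
#'
#' Averages Coulomb and Lennard-Jones group-group energies over all frames
#' for a list of named group pairs; the total is their sum by construction
#' (the layout of the interaction-energy tables customary for eutectic
#' mixtures in water: Salt-water, Salt-FAs, FAs-water).
#'
#' @param traj An `md_trajectory` with topology.
#' @param pairs Named list; each element is `list(a = <group>, b = <group>)`.
#' @param cutoff Optional distance cutoff (Angstrom).
#' @param topology Optional topology override.
#' @return data.frame with columns `pair`, `e_vdw`, `e_coul`, `e_total`
#'   (kcal/mol).
#' @export
interaction_energy_report <- function(traj, pairs, cutoff = NULL,
                                      topology = NULL) {
  top <- .traj_topology(traj, topology)
  nf <- n_frames(traj)
  out <- data.frame(pair = names(pairs), e_vdw = 0, e_coul = 0, e_total = 0,
                    stringsAsFactors = FALSE)
  for (p in seq_along(pairs)) {
    ev <- ec <- 0
    for (k in seq_len(nf)) {
      fr <- get_frame(traj, k)
      ev <- ev + vdw_energy(fr, top, pairs[[p]]$a, pairs[[p]]$b, cutoff = cutoff)
      ec <- ec + coulomb_energy(fr, top, pairs[[p]]$a, pairs[[p]]$b, cutoff = cutoff)
    }
    out$e_vdw[p] <- ev / nf
    out$e_coul[p] <- ec / nf
  }
  out$e_total <- out$e_vdw + out$e_coul
  out
}

#' Relative stability factor of a eutectic pair in water
#'
#' `S = IE(HBA-HBD) / (IE(HBA-water) + IE(HBD-water))`: the ratio of the
#' acceptor-donor interaction energy to the combined interaction of either
#' component with water. With attractive (negative) energies S is
#' positive; larger S means the eutectic pair better resists disruption by
#' water. S is scale-free: multiplying all three energies by a constant
#' leaves it unchanged.
#'
#' @param ie_hba_hbd HBA-HBD interaction energy (kcal/mol).
#' @param ie_hba_water HBA-water interaction energy (kcal/mol).
#' @param ie_hbd_water HBD-water interaction energy (kcal/mol).
#' @return The dimensionless factor S, or `NA` (with a warning) when the
#'   denominator is zero.
#' @examples
#' stability_factor(-29.5729, -18.5965, -257.1292)  # 0.10726
#' @export
stability_factor <- function(ie_hba_hbd, ie_hba_water, ie_hbd_water) {
  denom <- ie_hba_water + ie_hbd_water
  if (!is.finite(denom) || denom == 0) {
    warning("stability factor undefined: zero denominator")
    return(NA_real_)
  }
  ie_hba_hbd / denom
}
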