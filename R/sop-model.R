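# Self-organized polymer (SOP) model construction and energetics.
#
# One bead per residue at the Calpha position. The potential is
#   V_T = V_FENE + V_NB^ATT + V_NB^REP
# with FENE backbone bonds, native-contact Lennard-Jones attractions of
# depth eh at the native separations, a generic (sigma/r)^6 repulsion for
# non-native pairs, and the (i, i+2) repulsion with its own sigma.

#' SOP force-field parameters
#'
#' Only the attraction depth `eh` is system-calibrated (1.5 kcal/mol for
#' both variants studied here); the remaining constants are the standard
#' literature choices for this model family.
#'
#' @param eh Native-contact well depth (kcal/mol).
#' @param el Repulsive prefactor (kcal/mol).
#' @param sigma Non-native repulsion length (A).
#' @param sigma13 (i, i+2) repulsion length (A).
#' @param k_fene FENE stiffness (kcal/mol/A^2).
#' @param R0_fene FENE extension tolerance (A).
#' @return A `sop_parameters` list.
#' @export
sop_parameters <- function(eh = 1.5, el = 1, sigma = 3.8, sigma13 = 3.8,
                           k_fene = 20, R0_fene = 2) {
  stopifnot(eh > 0, el >= 0, k_fene > 0, R0_fene > 0)
  p <- list(eh = eh, el = el, sigma = sigma, sigma13 = sigma13,
            k_fene = k_fene, R0_fene = R0_fene)
  class(p) <- "sop_parameters"
  p
}

#' Build a SOP topology from a structure and its contact map
#'
#' @param s A `cdh_structure`.
#' @param cmap A SOP-flavor `contact_map` ([native_contacts_sop()]).
#' @param params [sop_parameters()].
#' @return A `sop_topology` list: bead coordinates (`coords`, Calpha, A),
#'   consecutive-bond native lengths (`bond_r0`), the native pair table
#'   (`native`) and the force-field parameters.
#' @export
build_sop_topology <- function(s, cmap, params = sop_parameters()) {
  if (!identical(attr(cmap, "flavor"), "sop")) {
    abort("cmap must be a sop-flavor contact map")
  }
  xyz <- ca_coords(s)
  n <- nrow(xyz)
  bond_r0 <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
  if (any(bond_r0 > 4.5)) {
    abort(sprintf("chain break: native bond %d is %.2f A (> 4.5 A)",
                  which(bond_r0 > 4.5)[1], max(bond_r0)))
  }
  top <- list(coords = unname(xyz), n_beads = n, bond_r0 = bond_r0,
              native = tibble(i = cmap$i, j = cmap$j, r0 = cmap$r0),
              params = params)
  class(top) <- "sop_topology"
  top
}

#' @export
print.sop_topology <- function(x, ...) {
  cat(sprintf("<sop_topology> %d beads, %d native pairs, eh = %g kcal/mol\n",
              x$n_beads, nrow(x$native), x$params$eh))
  invisible(x)
}

cpp_params <- function(top) {
  c(top$params[c("eh", "el", "sigma", "sigma13", "k_fene", "R0_fene")],
    list(bond_r0 = top$bond_r0))
}

#' SOP potential energy (and optionally forces)
#'
#' Evaluates the three terms of the SOP potential at given coordinates. At
#' the native coordinates `V_FENE` is exactly zero and `V_NB^ATT` equals
#' `-eh` times the number of native pairs.
#'
#' @param top A `sop_topology`.
#' @param coords Bead coordinate matrix (defaults to the native
#'   coordinates).
#' @param forces If `TRUE`, also return the analytic forces
#'   (kcal/mol/A).
#' @return A list with `V_total`, `V_fene`, `V_att`, `V_rep` (kcal/mol) and
#'   optionally `forces` (n x 3 matrix).
#' @export
potential_energy <- function(top, coords = NULL, forces = FALSE) {
  coords <- coords %||% top$coords
  .sop_energy(coords, top$native$i, top$native$j, top$native$r0,
              cpp_params(top), forces)
}

#' Relax a SOP conformation to its nearest energy minimum
#'
#' Limited-memory BFGS minimization on the analytic gradient, followed by a
#' steepest-descent polish. Used to prepare exact mechanical-equilibrium
#' starting points: the soft non-native repulsions make crystallographic
#' coordinates slightly off-minimum, so zero-temperature dynamics from raw
#' coordinates would drift.
#'
#' @param top A `sop_topology`.
#' @param coords Starting coordinates (default native).
#' @param max_steps Iteration cap.
#' @return Relaxed coordinate matrix.
#' @export
sop_minimize <- function(top, coords = NULL, max_steps = 20000) {
  coords <- coords %||% top$coords
  n <- nrow(coords)
  fn <- function(par) {
    .sop_energy(matrix(par, n, 3), top$native$i, top$native$j,
                top$native$r0, cpp_params(top), FALSE)$V_total
  }
  gr <- function(par) {
    -as.vector(.sop_energy(matrix(par, n, 3), top$native$i, top$native$j,
                           top$native$r0, cpp_params(top), TRUE)$forces)
  }
  o <- stats::optim(as.vector(coords), fn, gr, method = "L-BFGS-B",
                    control = list(maxit = max_steps, factr = 10,
                                   pgtol = 1e-12))
  .sop_minimize(matrix(o$par, n, 3), top$native$i, top$native$j,
                top$native$r0, cpp_params(top), 2000L, 1e-10, 1e-4)
}

# fraction of native contacts currently formed (d < factor * r0)
native_fraction <- function(top, coords, factor = 1.25) {
  d <- sqrt(rowSums((coords[top$native$i, , drop = FALSE] -
                       coords[top$native$j, , drop = FALSE])^2))
  mean(d < factor * top$native$r0)
}
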