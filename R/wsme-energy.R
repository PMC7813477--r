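# Energetics of the block WSME model.
#
# A microstate's free energy sums, over "licensed" native contacts (both
# partner residues inside folded islands, and cross-island contacts only
# when the interaction flag is on):
#   - a van der Waals energy xi per atomic contact,
#   - a solvation free energy dCp_cont * ((T - T_ref) - T*log(T/T_ref))
#     per atomic contact,
#   - Debye-Hueckel screened electrostatics over charged residue pairs,
# minus T times the conformational entropy of every folded residue
# (secondary-structure class dependent; prolines cost nothing).
# The fully unfolded state is the zero of both F and H.

#' Parameters of the block WSME model
#'
#' Defaults are the wild-type calorimetric fit values: van der Waals energy
#' per atomic native contact, conformational entropies per residue for the
#' strand/helix and coil/glycine classes (prolines are fixed at zero), heat
#' capacity change per native contact, and the solution conditions entering
#' the Debye-Hueckel term. `T_ref` is the solvation reference temperature
#' and `eps_eff` the effective dielectric constant; both follow the usual
#' conventions of this model family and are configurable.
#'
#' @param xi Van der Waals energy per atomic native contact (J/mol, < 0).
#' @param dS_strand_helix,dS_coil_gly,dS_pro Conformational entropies
#'   (J/mol/K per residue, <= 0).
#' @param dCp_cont Heat-capacity change per atomic native contact
#'   (J/mol/K, <= 0).
#' @param ionic_mM Ionic strength (mM, > 0).
#' @param pH Solution pH (only 7 is parameterized: charges are Asp/Glu -1,
#'   Lys/Arg +1, His neutral).
#' @param T_ref Solvation reference temperature (K).
#' @param eps_eff Effective dielectric constant.
#' @return A `wsme_parameters` list.
#' @export
wsme_parameters <- function(xi = -62.8, dS_strand_helix = -19.5,
                            dS_coil_gly = -25.6, dS_pro = 0,
                            dCp_cont = -0.68, ionic_mM = 20, pH = 7,
                            T_ref = 385, eps_eff = 29) {
  if (dCp_cont > 0) abort("dCp_cont must be <= 0")
  assert_scalar_number(ionic_mM, "ionic_mM", positive = TRUE)
  p <- list(xi = xi, dS_strand_helix = dS_strand_helix,
            dS_coil_gly = dS_coil_gly, dS_pro = dS_pro,
            dCp_cont = dCp_cont, ionic_mM = ionic_mM, pH = pH,
            T_ref = T_ref, eps_eff = eps_eff)
  class(p) <- "wsme_parameters"
  p
}

# per-residue entropy (J/mol/K) from the class table
residue_entropies <- function(ss, params) {
  cls <- ss$class[order(ss$resno)]
  unname(c(strand_or_helix = params$dS_strand_helix,
           coil_or_glycine = params$dS_coil_gly,
           proline = params$dS_pro)[cls])
}

# padded 2-D cumulative sum; rect sums are O(1) lookups
padded_cumsum2 <- function(K) {
  nb <- nrow(K)
  C <- matrix(0, nb + 1L, nb + 1L)
  C[-1, -1] <- if (nb == 1L) K else t(apply(apply(K, 2, cumsum), 1, cumsum))
  C
}

rect_sum <- function(C, a, b, c_, d) {
  C[cbind(b + 1L, d + 1L)] - C[cbind(a, d + 1L)] -
    C[cbind(b + 1L, c_)] + C[cbind(a, c_)]
}

# islands with NA bounds become the empty interval [1, 0]
island_bounds <- function(states) {
  list(a1 = ifelse(is.na(states$a1), 1L, states$a1),
       b1 = ifelse(is.na(states$a1), 0L, states$b1),
       a2 = ifelse(is.na(states$a2), 1L, states$a2),
       b2 = ifelse(is.na(states$a2), 0L, states$b2))
}

# licensed sum of a symmetric block matrix K over every state
licensed_block_sum <- function(K, states) {
  C <- padded_cumsum2(K)
  Dc <- c(0, cumsum(diag(K)))
  ib <- island_bounds(states)
  intra <- function(a, b) {
    (rect_sum(C, a, b, a, b) + (Dc[b + 1L] - Dc[a])) / 2
  }
  out <- intra(ib$a1, ib$b1) + intra(ib$a2, ib$b2)
  out + ifelse(states$w, rect_sum(C, ib$a1, ib$b1, ib$a2, ib$b2), 0)
}

#' Assemble a bWSME model system
#'
#' Precomputes everything needed to score the full microstate ensemble:
#' the block partition, per-state licensed atomic-contact counts, folded
#' conformational entropy, and the licensing matrix for the charged contact
#' pairs entering the Debye-Hueckel term.
#'
#' @param cmap A WSME-flavor `contact_map` (see [native_contacts_wsme()] or
#'   [synth_contact_map()]).
#' @param ss Secondary-structure class table
#'   (see [assign_secondary_structure()]).
#' @param params A [wsme_parameters()] object.
#' @param block_size Residues per block (default 3).
#' @return A `wsme_system` list with the enumerated `states` tibble and the
#'   per-state precomputations.
#' @export
wsme_system <- function(cmap, ss, params = wsme_parameters(), block_size = 3L) {
  if (!identical(attr(cmap, "flavor"), "wsme")) {
    abort("cmap must be a wsme-flavor contact map")
  }
  nb <- ceiling(attr(cmap, "n_residues") / block_size)
  wsme_system_states(cmap, ss, params, block_size, enumerate_microstates(nb))
}

#' @export
print.wsme_system <- function(x, ...) {
  cat(sprintf("<wsme_system> %d residues, %d blocks, %d microstates\n",
              x$n_residues, x$n_blocks, nrow(x$states)))
  invisible(x)
}

# per-state free energy and enthalpy (J/mol) at temperature T
wsme_state_energies <- function(system, T) {
  if (T <= 0) abort("temperature must be > 0 K")
  p <- system$params
  solv_free <- p$dCp_cont * ((T - p$T_ref) - T * log(T / p$T_ref))
  solv_enth <- p$dCp_cont * (T - p$T_ref)
  e_dh <- if (is.null(system$dh)) 0 else {
    kappa <- debye_kappa(p$ionic_mM / 1000, p$eps_eff, T)
    as.numeric(system$L %*% (system$dh$coef * exp(-kappa * system$dh$r0)))
  }
  F <- system$cnt * (p$xi + solv_free) + e_dh - T * system$S_fold
  H <- system$cnt * (p$xi + solv_enth) + e_dh
  tibble(F = F, H = H, n_folded = system$n_folded)
}

#' Free energy of a single microstate
#'
#' Scores one microstate against the full model Hamiltonian. The fully
#' unfolded state is the reference: its free energy and enthalpy are exactly
#' zero.
#'
#' @param state A one-row tibble or list with `a1`, `b1`, `a2`, `b2`, `w`
#'   (island bounds in block indices; `NA` for absent islands).
#' @param cmap WSME-flavor contact map.
#' @param ss Secondary-structure class table.
#' @param params A [wsme_parameters()] object.
#' @param T Temperature (K).
#' @param block_size Residues per block.
#' @return A named numeric vector with `F` and `H` (J/mol).
#' @export
microstate_free_energy <- function(state, cmap, ss, params = wsme_parameters(),
                                   T = 310, block_size = 3L) {
  sys <- wsme_system_single(cmap, ss, params, block_size, state)
  e <- wsme_state_energies(sys, T)
  c(F = e$F[1], H = e$H[1])
}

# system restricted to one explicit state (cheap path for single states)
wsme_system_single <- function(cmap, ss, params, block_size, state) {
  st <- tibble(a1 = as.integer(state$a1 %||% NA), b1 = as.integer(state$b1 %||% NA),
               a2 = as.integer(state$a2 %||% NA), b2 = as.integer(state$b2 %||% NA),
               w = isTRUE(state$w))
  sys <- wsme_system_states(cmap, ss, params, block_size, st)
  sys
}

# internal: like wsme_system but over a caller-supplied state table
wsme_system_states <- function(cmap, ss, params, block_size, states) {
  full <- wsme_system_stub(cmap, ss, params, block_size)
  ib <- island_bounds(states)
  cnt <- licensed_block_sum(full$K_cnt, states)
  sc <- full$sc
  S_fold <- (sc[ib$b1 + 1L] - sc[ib$a1]) + (sc[ib$b2 + 1L] - sc[ib$a2])
  L <- NULL
  if (!is.null(full$dh)) {
    L <- matrix(0, nrow(states), nrow(full$dh))
    for (k in seq_len(nrow(full$dh))) {
      fi1 <- ib$a1 <= full$dh$bi[k] & full$dh$bi[k] <= ib$b1
      fi2 <- ib$a2 <= full$dh$bi[k] & full$dh$bi[k] <= ib$b2
      fj1 <- ib$a1 <= full$dh$bj[k] & full$dh$bj[k] <= ib$b1
      fj2 <- ib$a2 <= full$dh$bj[k] & full$dh$bj[k] <= ib$b2
      L[, k] <- as.numeric((fi1 & fj1) | (fi2 & fj2) |
                             (((fi1 & fj2) | (fi2 & fj1)) & states$w))
    }
  }
  out <- list(partition = full$part, params = params, states = states,
              n_blocks = full$nb, n_residues = full$n_res,
              cnt = cnt, S_fold = S_fold, dh = full$dh, L = L,
              n_folded = state_n_folded(states))
  class(out) <- "wsme_system"
  out
}

wsme_system_stub <- function(cmap, ss, params, block_size) {
  n_res <- attr(cmap, "n_residues")
  part <- block_partition(n_res, block_size)
  nb <- nrow(part)
  blk_of <- rep(part$block, part$last - part$first + 1L)
  bi <- blk_of[cmap$i]; bj <- blk_of[cmap$j]
  K_cnt <- matrix(0, nb, nb)
  for (k in seq_len(nrow(cmap))) {
    K_cnt[bi[k], bj[k]] <- K_cnt[bi[k], bj[k]] + cmap$n_atomic[k]
    if (bi[k] != bj[k]) K_cnt[bj[k], bi[k]] <- K_cnt[bj[k], bi[k]] + cmap$n_atomic[k]
  }
  s_res <- residue_entropies(ss, params)
  s_blk <- as.numeric(tapply(s_res, blk_of, sum))
  dh <- NULL
  q <- attr(cmap, "charges")
  if (!is.null(q)) {
    qi <- q[cmap$i]; qj <- q[cmap$j]
    sel <- which(qi != 0 & qj != 0)
    if (length(sel) > 0) {
      dh <- tibble(bi = bi[sel], bj = bj[sel], r0 = cmap$r0[sel],
                   coef = .COULOMB_KCAL * 4184 * qi[sel] * qj[sel] /
                     (params$eps_eff * cmap$r0[sel]))
    }
  }
  list(part = part, nb = nb, n_res = n_res, K_cnt = K_cnt,
       sc = c(0, cumsum(s_blk)), dh = dh)
}

#' Partition function and state populations
#'
#' Computes the canonical partition function and per-state Boltzmann
#' probabilities from microstate free energies, in log space for numerical
#' stability.
#'
#' @param F Per-state free energies (J/mol), unfolded reference at 0.
#' @param T Temperature (K).
#' @return A list with `logZ`, `Z` and the probability vector `p`
#'   (sums to 1).
#' @export
partition_function <- function(F, T) {
  if (T <= 0) abort("temperature must be > 0 K")
  if (!all(is.finite(F))) abort("free energies must be finite")
  lw <- -F / (.R_GAS * T)
  lZ <- logsumexp(lw)
  list(logZ = lZ, Z = exp(lZ), p = exp(lw - lZ))
}
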