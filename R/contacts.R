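# Native contact maps, least-squares superposition and secondary-structure
# classes derived from backbone dihedrals.

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

heavy_atoms <- function(s) s[s$element != "H" & s$element != "D", ]

sidechain_atoms <- function(s) {
  h <- heavy_atoms(s)
  h[h$atom %!in% .BACKBONE_ATOMS, ]
}

# residue-pair minimum distances between two atom sets, returned as a
# 3-column matrix (i, j, min_dist); n_pairs additionally counts atom pairs
# under `count_within`
residue_pair_scan <- function(a, cutoff, min_sep, count_within = NULL) {
  xyz <- as.matrix(a[, c("x", "y", "z")])
  res <- a$resno
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  d2[d2 < 0] <- 0
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  hit <- hit[res[hit[, 2]] - res[hit[, 1]] >= min_sep, , drop = FALSE]
  if (nrow(hit) == 0L) {
    return(tibble(i = integer(), j = integer(), n_atomic = integer()))
  }
  key <- paste(res[hit[, 1]], res[hit[, 2]])
  tab <- table(key)
  ij <- do.call(rbind, strsplit(names(tab), " "))
  tibble(
    i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
    n_atomic = as.integer(tab)
  ) |> arrange(.data$i, .data$j)
}

ca_dist_for_pairs <- function(s, i, j) {
  ca <- ca_coords(s)
  sqrt(rowSums((ca[i, , drop = FALSE] - ca[j, , drop = FALSE])^2))
}

new_contact_map <- function(pairs, flavor, n_res, charges = NULL) {
  out <- as_tibble(pairs)
  attr(out, "flavor") <- flavor
  attr(out, "n_residues") <- n_res
  if (!is.null(charges)) attr(out, "charges") <- charges
  class(out) <- c("contact_map", class(out))
  out
}

#' Native contact map for the SOP coarse-grained model
#'
#' A residue pair (i, j) with `|i - j| >= 3` is a native contact if the two
#' Calpha atoms are closer than 8 Angstrom, or any pair of side-chain heavy
#' atoms (all non-hydrogens excluding N, CA, C, O) is closer than
#' 5.2 Angstrom. The stored native distance `r0` is the Calpha-Calpha
#' distance, which parameterizes the attractive Lennard-Jones wells of the
#' SOP potential.
#'
#' @param s A `cdh_structure`.
#' @param ca_cutoff,sc_cutoff Calpha and side-chain heavy-atom cutoffs (A).
#' @return A `contact_map` tibble with columns `i`, `j`, `r0` and attribute
#'   `flavor = "sop"`.
#' @export
native_contacts_sop <- function(s, ca_cutoff = 8, sc_cutoff = 5.2) {
  n_res <- n_residues(s)
  if (n_res < 4L) {
    warn("fewer than 4 residues: SOP contact map is empty")
    return(new_contact_map(tibble(i = integer(), j = integer(), r0 = numeric()),
                           "sop", n_res))
  }
  ca <- s[s$atom == "CA", ]
  ca_hits <- residue_pair_scan(ca, ca_cutoff, 3L)
  sc <- sidechain_atoms(s)
  sc_hits <- if (nrow(sc) > 0) residue_pair_scan(sc, sc_cutoff, 3L) else
    tibble(i = integer(), j = integer(), n_atomic = integer())
  pairs <- dplyr::distinct(dplyr::bind_rows(ca_hits[, c("i", "j")],
                                            sc_hits[, c("i", "j")])) |>
    arrange(.data$i, .data$j)
  pairs$r0 <- ca_dist_for_pairs(s, pairs$i, pairs$j)
  new_contact_map(pairs, "sop", n_res)
}

# residue charges at pH 7: D/E -1, K/R +1, His and termini neutral
residue_charges <- function(resnames) {
  q <- numeric(length(resnames))
  q[resnames %in% c("ASP", "GLU")] <- -1
  q[resnames %in% c("LYS", "ARG")] <- +1
  q
}

#' Native contact map for the WSME folding model
#'
#' A residue pair (i, j) with `|i - j| >= 2` is in native contact if any two
#' heavy atoms are closer than 6 Angstrom. The map records the number of
#' heavy-atom pairs under the cutoff (`n_atomic`): the van der Waals term of
#' the model is an energy per atomic contact, so this multiplicity carries
#' the packing density of the native fold. Residue charges at pH 7
#' (Asp/Glu -1, Lys/Arg +1, His and termini neutral) are attached for the
#' Debye-Hueckel electrostatic term.
#'
#' @param s A `cdh_structure`.
#' @param cutoff Heavy-atom distance cutoff (A).
#' @return A `contact_map` tibble with columns `i`, `j`, `r0` (Calpha-Calpha
#'   distance), `n_atomic`, and attributes `flavor = "wsme"` and `charges`
#'   (per-residue charge vector).
#' @export
native_contacts_wsme <- function(s, cutoff = 6) {
  n_res <- n_residues(s)
  ca <- s[s$atom == "CA", ]
  ca <- ca[order(ca$resno), ]
  charges <- residue_charges(ca$resname)
  if (n_res < 3L) {
    warn("fewer than 3 residues: WSME contact map is empty")
    return(new_contact_map(
      tibble(i = integer(), j = integer(), r0 = numeric(), n_atomic = integer()),
      "wsme", n_res, charges))
  }
  hits <- residue_pair_scan(heavy_atoms(s), cutoff, 2L)
  hits$r0 <- ca_dist_for_pairs(s, hits$i, hits$j)
  new_contact_map(hits[, c("i", "j", "r0", "n_atomic")], "wsme", n_res, charges)
}

#' Kabsch least-squares superposition and RMSD
#'
#' Superposes paired atoms of two structures by the Kabsch SVD algorithm
#' (with the reflection guard, so the returned rotation is proper) and
#' reports the residual RMSD. Atoms are paired by renumbered residue index
#' (and atom name for multi-atom selections) on the intersection of the two
#' structures.
#'
#' @param a,b `cdh_structure` objects.
#' @param selection `"ca"` (default), `"heavy"` or `"all"`.
#' @return A list with `rotation` (3x3), `translation` (length 3, applied to
#'   `b` after rotation), `rmsd` (A) and `n_atoms`.
#' @export
superpose_rmsd <- function(a, b, selection = c("ca", "heavy", "all")) {
  selection <- match.arg(selection)
  pick <- function(s) {
    s <- switch(selection, ca = s[s$atom == "CA", ], heavy = heavy_atoms(s), all = s)
    s$key <- paste(s$resno, s$atom)
    s
  }
  pa <- pick(a); pb <- pick(b)
  common <- intersect(pa$key, pb$key)
  if (length(common) < 3L) abort("fewer than 3 paired atoms between the structures")
  ma <- as.matrix(pa[match(common, pa$key), c("x", "y", "z")])
  mb <- as.matrix(pb[match(common, pb$key), c("x", "y", "z")])
  ca_ <- colMeans(ma); cb_ <- colMeans(mb)
  A <- sweep(ma, 2, ca_); B <- sweep(mb, 2, cb_)
  sv <- svd(crossprod(B, A))          # rotation applied to B to match A
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Brot <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((A - Brot)^2)))
  list(rotation = R, translation = as.numeric(ca_ - cb_ %*% t(R)),
       rmsd = rmsd, n_atoms = length(common))
}

# four-point torsion angle (radians, wrapped to (-pi, pi])
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  -atan2(sum(m1 * n2), sum(n1 * n2))
}

# per-residue phi/psi (degrees) for a single conformation
backbone_phi_psi <- function(s, coords = NULL) {
  need <- c("N", "CA", "C")
  bb <- s[s$atom %in% need, ]
  if (!is.null(coords)) {
    bb_idx <- which(s$atom %in% need)
    bb$x <- coords[bb_idx, 1]; bb$y <- coords[bb_idx, 2]; bb$z <- coords[bb_idx, 3]
  }
  res <- sort(unique(s$resno))
  get <- function(r, nm) {
    row <- bb[bb$resno == r & bb$atom == nm, ]
    if (nrow(row) == 0L) return(NULL)
    c(row$x[1], row$y[1], row$z[1])
  }
  res_chain <- vapply(res, function(r) s$chain[s$resno == r][1], character(1))
  phi <- psi <- rep(NA_real_, length(res))
  for (k in seq_along(res)) {
    r <- res[k]
    Nk <- get(r, "N"); CAk <- get(r, "CA"); Ck <- get(r, "C")
    if (is.null(Nk) || is.null(CAk) || is.null(Ck)) next
    if (k > 1L && res_chain[k - 1L] == res_chain[k]) {
      Cprev <- get(res[k - 1L], "C")
      if (!is.null(Cprev)) phi[k] <- torsion_angle(Cprev, Nk, CAk, Ck) * 180 / pi
    }
    if (k < length(res) && res_chain[k + 1L] == res_chain[k]) {
      Nnext <- get(res[k + 1L], "N")
      if (!is.null(Nnext)) psi[k] <- torsion_angle(Nk, CAk, Ck, Nnext) * 180 / pi
    }
  }
  tibble(resno = res, phi = phi, psi = psi)
}

#' Assign conformational-entropy classes from backbone dihedrals
#'
#' Classifies each residue into one of the three conformational-entropy
#' classes of the folding model: `strand_or_helix` (non-Gly, non-Pro
#' residues whose phi/psi sit in the canonical helix or strand basins for at
#' least two consecutive residues), `coil_or_glycine` (everything else,
#' including all glycines), and `proline`. A user-supplied override table
#' wins over the dihedral-based assignment.
#'
#' @param s A `cdh_structure`.
#' @param override Optional tibble with columns `resno`, `class`.
#' @return A tibble with columns `resno`, `resname`, `class`.
#' @export
assign_secondary_structure <- function(s, override = NULL) {
  ca <- s[s$atom == "CA", ]; ca <- ca[order(ca$resno), ]
  out <- tibble(resno = ca$resno, resname = ca$resname)
  if (!is.null(override)) {
    cls <- override$class[match(out$resno, override$resno)]
    if (anyNA(cls)) abort("override must cover every residue")
  } else {
    bb_ok <- vapply(out$resno, function(r) {
      all(c("N", "CA", "C") %in% s$atom[s$resno == r])
    }, logical(1))
    if (!all(bb_ok)) {
      abort(sprintf("missing backbone atoms for residue(s): %s",
                    paste(out$resno[!bb_ok], collapse = ", ")))
    }
    tors <- backbone_phi_psi(s)
    in_helix <- !is.na(tors$phi) & !is.na(tors$psi) &
      tors$phi >= -100 & tors$phi <= -30 & tors$psi >= -80 & tors$psi <= -5
    in_strand <- !is.na(tors$phi) & !is.na(tors$psi) &
      tors$phi >= -180 & tors$phi <= -90 & tors$psi >= 90 & tors$psi <= 180
    basin <- in_helix | in_strand
    run2 <- basin & (c(FALSE, basin[-length(basin)]) | c(basin[-1], FALSE))
    cls <- ifelse(run2, "strand_or_helix", "coil_or_glycine")
    cls[out$resname == "GLY"] <- "coil_or_glycine"
  }
  cls[out$resname == "PRO"] <- "proline"
  out$class <- cls
  out
}
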