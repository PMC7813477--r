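# Synthetic toy structures with hand-checkable contact truth.
# Part of the synthetic-data module: every downstream stage can be exercised
# without any external structure download.

# brute-force truth computed with plain loops, deliberately independent of
# the vectorized scanners in contacts.R
brute_force_contacts <- function(s, flavor = c("sop", "wsme")) {
  flavor <- match.arg(flavor)
  res <- sort(unique(s$resno))
  xyz <- as.matrix(s[, c("x", "y", "z")])
  out <- list()
  for (a in seq_along(res)) {
    for (b in seq_along(res)) {
      if (b <= a) next
      i <- res[a]; j <- res[b]
      sep <- j - i
      ai <- which(s$resno == i); aj <- which(s$resno == j)
      pair_d <- function(sel_i, sel_j) {
        dm <- Inf; cnt <- 0L
        for (p in sel_i) for (q in sel_j) {
          d <- sqrt(sum((xyz[p, ] - xyz[q, ])^2))
          if (d < dm) dm <- d
          cnt <- cnt + 1L
        }
        dm
      }
      ca_i <- ai[s$atom[ai] == "CA"]; ca_j <- aj[s$atom[aj] == "CA"]
      d_ca <- sqrt(sum((xyz[ca_i[1], ] - xyz[ca_j[1], ])^2))
      if (flavor == "sop") {
        if (sep < 3) next
        sc_i <- ai[s$atom[ai] %!in% .BACKBONE_ATOMS & s$element[ai] != "H"]
        sc_j <- aj[s$atom[aj] %!in% .BACKBONE_ATOMS & s$element[aj] != "H"]
        d_sc <- if (length(sc_i) && length(sc_j)) pair_d(sc_i, sc_j) else Inf
        if (d_ca < 8 || d_sc < 5.2) {
          out[[length(out) + 1L]] <- tibble(i = i, j = j, r0 = d_ca)
        }
      } else {
        if (sep < 2) next
        hv_i <- ai[s$element[ai] != "H"]; hv_j <- aj[s$element[aj] != "H"]
        n_at <- 0L
        for (p in hv_i) for (q in hv_j) {
          if (sqrt(sum((xyz[p, ] - xyz[q, ])^2)) < 6) n_at <- n_at + 1L
        }
        if (n_at > 0L) {
          out[[length(out) + 1L]] <- tibble(i = i, j = j, r0 = d_ca, n_atomic = n_at)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(if (flavor == "sop") tibble(i = integer(), j = integer(), r0 = numeric())
           else tibble(i = integer(), j = integer(), r0 = numeric(), n_atomic = integer()))
  }
  dplyr::bind_rows(out)
}

#' Build a toy structure with known contact truth
#'
#' Ideal-geometry test folds: a beta hairpin (two 150/-150-degree strands
#' joined by a two-residue turn), an alpha helix (phi = -57, psi = -47), or
#' a two-chain antiparallel beta sheet. Each structure ships with a sidecar
#' truth object (`attr(, "truth")`): the SOP- and WSME-flavor contact lists
#' recomputed by an independent brute-force loop, and the per-residue
#' secondary-structure classes implied by the dihedrals used in
#' construction. The builders are deterministic; coordinates are rounded to
#' PDB precision so regeneration is byte-identical.
#'
#' @param kind `"hairpin"`, `"helix"` or `"two_strand_sheet"`.
#' @param n_residues Total residue count, 6-60.
#' @param path Optional: write the structure (PDB) and sidecar truth (JSON)
#'   to `path` and `paste0(path, ".truth.json")`.
#' @return A `cdh_structure` with attribute `truth`.
#' @export
make_toy_structure <- function(kind = c("hairpin", "helix", "two_strand_sheet"),
                               n_residues = 16, path = NULL) {
  kind <- match.arg(kind)
  if (n_residues < 6 || n_residues > 60) abort("n_residues must be in 6..60")
  n <- as.integer(n_residues)
  # truth classes implied by the dihedrals used in construction: basin
  # membership of the requested (phi, psi) plus the two-consecutive rule,
  # independent of the coordinate-derived assignment
  ss_from_dihedrals <- function(phi, psi) {
    phi[1] <- NA; psi[length(psi)] <- NA
    basin <- !is.na(phi) & !is.na(psi) &
      ((phi >= -100 & phi <= -30 & psi >= -80 & psi <= -5) |
         (phi >= -180 & phi <= -90 & psi >= 90 & psi <= 180))
    run2 <- basin & (c(FALSE, basin[-length(basin)]) | c(basin[-1], FALSE))
    ifelse(run2, "strand_or_helix", "coil_or_glycine")
  }
  if (kind == "helix") {
    s <- build_peptide(-57, -47, n = n, resnames = "ALA")
    ss_truth <- ss_from_dihedrals(rep(-57, n), rep(-47, n))
  } else if (kind == "hairpin") {
    n1 <- (n - 2L) %/% 2L; n2 <- n - 2L - n1
    phi <- c(rep(-150, n1), 80, 70, rep(-150, n2))
    psi <- c(rep(150, n1), 60, 40, rep(150, n2))
    s <- build_peptide(phi, psi, n = n, resnames = "VAL")
    ss_truth <- ss_from_dihedrals(phi, psi)
  } else {
    n1 <- n %/% 2L; n2 <- n - n1
    s1 <- build_peptide(-135, 135, n = n1, resnames = "THR", chain = "A")
    s2 <- build_peptide(-135, 135, n = n2, resnames = "THR", chain = "B")
    # antiparallel partner: rotate pi about y, offset in y by typical
    # inter-strand spacing
    R <- diag(c(-1, 1, -1))
    ca1 <- ca_coords(s1)
    s2 <- transform_structure(s2, R, shift = c(max(ca1[, 1]) + min(ca1[, 1]), 4.8, 0.5))
    s2$resno <- s2$resno + n1
    atoms <- dplyr::bind_rows(as_tibble(s1), as_tibble(s2))
    s <- new_cdh_structure(atoms)
    ss_truth <- c(ss_from_dihedrals(rep(-135, n1), rep(135, n1)),
                  ss_from_dihedrals(rep(-135, n2), rep(135, n2)))
  }
  ca <- s[s$atom == "CA", ]; ca <- ca[order(ca$resno), ]
  truth <- list(
    kind = kind, n_residues = n,
    contacts_sop = brute_force_contacts(s, "sop"),
    contacts_wsme = brute_force_contacts(s, "wsme"),
    ss = tibble(resno = seq_len(n), resname = ca$resname, class = ss_truth)
  )
  attr(s, "truth") <- truth
  if (!is.null(path)) {
    write_structure(s, path)
    truth_json <- truth
    truth_json$contacts_sop <- as.data.frame(truth_json$contacts_sop)
    truth_json$contacts_wsme <- as.data.frame(truth_json$contacts_wsme)
    truth_json$ss <- as.data.frame(truth_json$ss)
    jsonlite::write_json(truth_json, paste0(path, ".truth.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  s
}
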