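# Hydrogen-bond event detection, persistence filtering and the critical
# persistence of the bond network.

.HB_DONOR_SC <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  LYS = "NZ", TRP = "NE1", HIS = c("ND1", "NE2"),
  ARG = c("NE", "NH1", "NH2"))
.HB_ACCEPTOR_SC <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"))

hb_sites <- function(s, role = c("donor", "acceptor")) {
  role <- match.arg(role)
  tab <- if (role == "donor") .HB_DONOR_SC else .HB_ACCEPTOR_SC
  bb <- if (role == "donor") s$atom == "N" & s$resname != "PRO" else s$atom == "O"
  sc <- rep(FALSE, nrow(s))
  for (rn in names(tab)) {
    sc <- sc | (s$resname == rn & s$atom %in% tab[[rn]])
  }
  which(bb | sc)
}

#' Detect hydrogen bonds along a trajectory
#'
#' Geometric criterion per frame: a donor and acceptor heavy atom of
#' different residues form a bond when their distance is at most 3.5 A and
#' the donor-H...acceptor angle is at least 120 degrees (when the donor's
#' hydrogen is present in the structure); without hydrogens a stricter
#' distance-only criterion of 3.3 A is used. Donors are backbone amides
#' and side-chain N/O-H groups; acceptors are backbone carbonyls and
#' side-chain O/N lone-pair carriers.
#'
#' @param traj A trajectory (list with `structure` and `coords`, e.g. from
#'   [read_trajectory()]).
#' @param dist_hd Distance cutoff with hydrogens (A).
#' @param dist_only Distance cutoff without hydrogens (A).
#' @param min_angle Donor-H...acceptor angle cutoff (degrees).
#' @return An `hbond_events` tibble of present bonds (`donor`, `acceptor`
#'   residue indices, `frame`) with attribute `n_frames`.
#' @export
detect_hbonds <- function(traj, dist_hd = 3.5, dist_only = 3.3,
                          min_angle = 120) {
  s <- traj$structure
  don <- hb_sites(s, "donor"); acc <- hb_sites(s, "acceptor")
  if (length(don) == 0L || length(acc) == 0L) {
    warn("no polar donor/acceptor atoms found: empty event table")
    out <- tibble(donor = integer(), acceptor = integer(), frame = integer())
    attr(out, "n_frames") <- length(traj$coords)
    class(out) <- c("hbond_events", class(out))
    return(out)
  }
  # attached hydrogens: nearest H in the same residue within 1.3 A
  hyd <- which(s$element == "H")
  find_h <- function(i, fr) {
    cand <- hyd[s$resno[hyd] == s$resno[i]]
    if (length(cand) == 0L) return(NA_integer_)
    d <- sqrt(rowSums((fr[cand, , drop = FALSE] -
                         matrix(fr[i, ], length(cand), 3, byrow = TRUE))^2))
    if (min(d) > 1.3) NA_integer_ else cand[which.min(d)]
  }
  rows <- list()
  for (f in seq_along(traj$coords)) {
    fr <- traj$coords[[f]]
    dd <- fr[don, , drop = FALSE]; aa <- fr[acc, , drop = FALSE]
    d2 <- outer(rowSums(dd^2), rowSums(aa^2), "+") - 2 * tcrossprod(dd, aa)
    d2[d2 < 0] <- 0
    hit <- which(d2 <= dist_hd^2, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    di <- don[hit[, 1]]; ai <- acc[hit[, 2]]
    ok <- s$resno[di] != s$resno[ai]
    di <- di[ok]; ai <- ai[ok]
    keep <- logical(length(di))
    for (k in seq_along(di)) {
      d <- sqrt(sum((fr[di[k], ] - fr[ai[k], ])^2))
      h <- find_h(di[k], fr)
      if (is.na(h)) {
        keep[k] <- d <= dist_only
      } else {
        v1 <- fr[di[k], ] - fr[h, ]; v2 <- fr[ai[k], ] - fr[h, ]
        ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                   sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        keep[k] <- d <= dist_hd && ang >= min_angle
      }
    }
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- tibble(
        donor = s$resno[di[keep]], acceptor = s$resno[ai[keep]], frame = f) |>
        dplyr::distinct()
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(donor = integer(), acceptor = integer(), frame = integer())
  attr(out, "n_frames") <- length(traj$coords)
  class(out) <- c("hbond_events", class(out))
  out
}

#' Per-pair hydrogen-bond persistence
#'
#' @param events An `hbond_events` table.
#' @return Tibble with `donor`, `acceptor`, `p` (fraction of frames the
#'   bond is present; donor/acceptor order normalized so donor < acceptor
#'   for undirected analyses is *not* applied - pairs are kept as
#'   detected).
#' @export
hbond_persistence <- function(events) {
  n_frames <- attr(events, "n_frames")
  if (is.null(n_frames)) abort("event table lacks the n_frames attribute")
  events |>
    dplyr::count(.data$donor, .data$acceptor, name = "n_present") |>
    dplyr::mutate(p = .data$n_present / n_frames) |>
    dplyr::select("donor", "acceptor", "p")
}

#' Persistence-filtered hydrogen-bond network
#'
#' Keeps bonds present in at least `threshold` of the frames (default the
#' critical persistence of 0.25 used to remove transient bonds) and builds
#' the residue graph.
#'
#' @param events An `hbond_events` table.
#' @param threshold Minimum persistence in [0, 1].
#' @return A `persistence_network` list: `edges` (donor, acceptor, p),
#'   `graph` (igraph, undirected), `threshold`.
#' @export
persistence_network <- function(events, threshold = 0.25) {
  if (threshold < 0 || threshold > 1) abort("threshold must be in [0, 1]")
  pers <- hbond_persistence(events)
  edges <- pers[pers$p >= threshold, ]
  nodes <- sort(unique(c(pers$donor, pers$acceptor)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$donor),
               to = as.character(edges$acceptor),
               weight = edges$p),
    directed = FALSE, vertices = data.frame(name = as.character(nodes)))
  out <- list(edges = edges, graph = g, threshold = threshold)
  class(out) <- "persistence_network"
  out
}

#' @export
print.persistence_network <- function(x, ...) {
  cat(sprintf("<persistence_network> %d edge(s) at p >= %.2f\n",
              nrow(x$edges), x$threshold))
  invisible(x)
}

#' Critical persistence of the hydrogen-bond network
#'
#' For each minimum-persistence threshold `p_min`, builds the network of
#' bonds with persistence >= p_min and records the size of its largest
#' connected component. The critical persistence `p_crit` is the threshold
#' at the steepest drop of that curve (the last `p_min` before the largest
#' collapse).
#'
#' @param events An `hbond_events` table (must contain at least one pair).
#' @param p_grid Thresholds to scan.
#' @return A list with `p_crit` (NA if the curve is flat) and `curve`
#'   (tibble: `p_min`, `largest_cluster`).
#' @export
critical_persistence <- function(events, p_grid = seq(0, 1, by = 0.01)) {
  if (nrow(events) == 0L) abort("empty hydrogen-bond event table")
  pers <- hbond_persistence(events)
  nodes <- sort(unique(c(pers$donor, pers$acceptor)))
  sizes <- vapply(p_grid, function(pm) {
    e <- pers[pers$p >= pm, ]
    if (nrow(e) == 0L) return(1L)
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(e$donor), to = as.character(e$acceptor)),
      directed = FALSE, vertices = data.frame(name = as.character(nodes)))
    max(igraph::components(g)$csize)
  }, numeric(1))
  curve <- tibble(p_min = p_grid, largest_cluster = as.integer(sizes))
  drops <- -diff(sizes)
  p_crit <- if (all(drops == 0)) {
    warn("largest-cluster curve is flat: p_crit undefined")
    NA_real_
  } else {
    p_grid[which.max(drops)]
  }
  list(p_crit = p_crit, curve = curve)
}
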