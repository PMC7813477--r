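# Circular cross-correlation analysis of backbone dihedrals.
#
# The circular correlation coefficient (Jammalamadaka-SenGupta form) of two
# angle series x, y is
#   r = sum sin(x - xbar) sin(y - ybar) /
#       sqrt(sum sin^2(x - xbar) * sum sin^2(y - ybar))
# with circular means xbar, ybar. It is invariant to rigid rotation of
# either series and lies in [-1, 1].

circular_mean <- function(x) atan2(mean(sin(x)), mean(cos(x)))

# mean resultant length (1 - circular variance)
circular_resultant <- function(x) sqrt(mean(sin(x))^2 + mean(cos(x))^2)

#' Circular correlation coefficient of two angle series
#'
#' @param x,y Angle vectors (radians), equal length >= 30.
#' @param min_var Degeneracy guard: series whose centered sine variance is
#'   below this are reported as `NA` (undefined), not 0.
#' @return The coefficient in [-1, 1], or `NA` for degenerate input.
#' @export
circular_correlation <- function(x, y, min_var = 1e-6) {
  if (length(x) != length(y)) abort("series must have equal length")
  if (length(x) < 30L) abort("need at least 30 paired angles")
  sx <- sin(x - circular_mean(x))
  sy <- sin(y - circular_mean(y))
  vx <- sum(sx^2); vy <- sum(sy^2)
  if (vx / length(x) < min_var || vy / length(y) < min_var) {
    warn("degenerate angle series: circular correlation undefined")
    return(NA_real_)
  }
  sum(sx * sy) / sqrt(vx * vy)
}

#' Compute backbone dihedral series from a trajectory
#'
#' Standard phi (C'-N-CA-C') and psi (N-CA-C'-N) torsions for every frame,
#' wrapped to (-pi, pi]. phi of the first and psi of the last residue of
#' each chain are undefined and omitted.
#'
#' @param traj A trajectory as returned by [read_trajectory()] (a list with
#'   `structure` and `coords`).
#' @return A numeric matrix (frames x dihedrals, radians) with columns
#'   named `phi_<resno>` / `psi_<resno>` and attribute `mapping` (tibble:
#'   column, resno, angle).
#' @export
compute_dihedrals <- function(traj) {
  s <- traj$structure
  res <- sort(unique(s$resno))
  res_chain <- vapply(res, function(r) s$chain[s$resno == r][1], character(1))
  idx <- function(r, nm) {
    i <- which(s$resno == r & s$atom == nm)
    if (length(i) == 0L) NA_integer_ else i[1]
  }
  iN <- vapply(res, idx, integer(1), nm = "N")
  iCA <- vapply(res, idx, integer(1), nm = "CA")
  iC <- vapply(res, idx, integer(1), nm = "C")
  specs <- list()
  for (k in seq_along(res)) {
    if (k > 1 && res_chain[k - 1] == res_chain[k] &&
        !anyNA(c(iC[k - 1], iN[k], iCA[k], iC[k]))) {
      specs[[length(specs) + 1L]] <- list(
        name = paste0("phi_", res[k]), resno = res[k], angle = "phi",
        atoms = c(iC[k - 1], iN[k], iCA[k], iC[k]))
    }
    if (k < length(res) && res_chain[k + 1] == res_chain[k] &&
        !anyNA(c(iN[k], iCA[k], iC[k], iN[k + 1]))) {
      specs[[length(specs) + 1L]] <- list(
        name = paste0("psi_", res[k]), resno = res[k], angle = "psi",
        atoms = c(iN[k], iCA[k], iC[k], iN[k + 1]))
    }
  }
  if (length(specs) == 0L) abort("no complete backbone dihedral found")
  frames <- traj$coords
  n_f <- length(frames)
  # vectorized four-point torsion across frames, one dihedral at a time
  torsion_frames <- function(atoms) {
    P <- lapply(1:4, function(a) {
      t(vapply(frames, function(fr) fr[atoms[a], ], numeric(3)))
    })
    b1 <- P[[2]] - P[[1]]; b2 <- P[[3]] - P[[2]]; b3 <- P[[4]] - P[[3]]
    crossm <- function(a, b) {
      cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
            a[, 3] * b[, 1] - a[, 1] * b[, 3],
            a[, 1] * b[, 2] - a[, 2] * b[, 1])
    }
    n1 <- crossm(b1, b2); n2 <- crossm(b2, b3)
    m1 <- crossm(n1, b2) / sqrt(rowSums(b2^2))
    wrap_angle(-atan2(rowSums(m1 * n2), rowSums(n1 * n2)))
  }
  X <- vapply(specs, function(sp) torsion_frames(sp$atoms), numeric(n_f))
  X <- matrix(X, nrow = n_f)
  colnames(X) <- vapply(specs, `[[`, character(1), "name")
  attr(X, "mapping") <- tibble(
    column = colnames(X),
    resno = vapply(specs, `[[`, integer(1), "resno"),
    angle = vapply(specs, `[[`, character(1), "angle"))
  X
}

#' Circular correlation map with Z-score filtering
#'
#' Computes the circular correlation coefficient for every pair of dihedral
#' series, standardizes the absolute coefficients against the full
#' coefficient matrix (self-referential standardization: the unit diagonal
#' anchors the scale, which is what makes the filter conservative enough
#' that maps of independent angles come out empty), and retains only pairs
#' with Z above the threshold (2.5 by default). When a residue mapping is available the map is also reduced to
#' residue level by taking the maximum absolute coefficient over the up to
#' four (phi/psi) x (phi/psi) combinations of each residue pair.
#'
#' @param X Matrix of angle series (frames x dihedrals; e.g.
#'   [compute_dihedrals()] or [make_dihedral_series()] output).
#' @param z_threshold Z-score retention threshold.
#' @param min_var Degeneracy guard per series.
#' @return A `circ_corr_map` list: `r` (coefficient matrix), `z` (Z-score
#'   matrix), `filtered` (r where Z > threshold, else NA), `pairs` (tibble
#'   of retained pairs), `residue` (residue-level max-|r| matrix, when a
#'   mapping is attached), `z_threshold`.
#' @export
correlation_map <- function(X, z_threshold = 2.5, min_var = 1e-6) {
  if (ncol(X) < 2L) abort("need at least 2 dihedral series")
  mu <- apply(X, 2, circular_mean)
  S <- sin(sweep(X, 2, mu))
  v <- colSums(S^2)
  degen <- v / nrow(X) < min_var
  if (all(degen)) abort("all angle series are degenerate")
  r <- crossprod(S) / sqrt(outer(v, v))
  r[degen, ] <- NA; r[, degen] <- NA
  diag(r) <- 1
  pop <- abs(r)
  mu_pop <- mean(pop, na.rm = TRUE); sd_pop <- stats::sd(pop, na.rm = TRUE)
  z <- (abs(r) - mu_pop) / sd_pop
  diag(z) <- NA
  filtered <- ifelse(!is.na(z) & z > z_threshold, r, NA)
  ut <- which(upper.tri(r) & !is.na(z) & z > z_threshold, arr.ind = TRUE)
  pairs <- tibble(i = ut[, 1], j = ut[, 2],
                  dihedral_i = colnames(X)[ut[, 1]],
                  dihedral_j = colnames(X)[ut[, 2]],
                  r = r[ut], z = z[ut])
  residue <- NULL
  mapping <- attr(X, "mapping")
  if (!is.null(mapping)) {
    resn <- sort(unique(mapping$resno))
    residue <- matrix(NA_real_, length(resn), length(resn),
                      dimnames = list(resn, resn))
    grp <- match(mapping$resno, resn)
    absr <- abs(r)
    for (a in seq_along(resn)) {
      ia <- which(grp == a)
      for (b in a:length(resn)) {
        ib <- which(grp == b)
        m <- suppressWarnings(max(absr[ia, ib, drop = FALSE], na.rm = TRUE))
        if (is.finite(m)) residue[a, b] <- residue[b, a] <- m
      }
    }
  }
  out <- list(r = r, z = z, filtered = filtered, pairs = pairs,
              residue = residue, z_threshold = z_threshold)
  class(out) <- "circ_corr_map"
  out
}

#' @export
print.circ_corr_map <- function(x, ...) {
  cat(sprintf("<circ_corr_map> %d dihedrals, %d pair(s) retained at Z > %.2g\n",
              ncol(x$r), nrow(x$pairs), x$z_threshold))
  invisible(x)
}

#' Differential circular correlation map
#'
#' Elementwise `|r_a| - |r_b|`: positive entries mark correlations stronger
#' in the first map, negative entries correlations stronger in the second.
#'
#' @param a,b `circ_corr_map` objects (or plain matrices) with identical
#'   dihedral indexing.
#' @return A matrix of `|r_a| - |r_b|`.
#' @export
differential_map <- function(a, b) {
  ra <- if (inherits(a, "circ_corr_map")) a$r else a
  rb <- if (inherits(b, "circ_corr_map")) b$r else b
  if (!identical(dim(ra), dim(rb))) abort("maps have different dimensions")
  abs(ra) - abs(rb)
}
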