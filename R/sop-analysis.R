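# Rupture detection, worm-like-chain contour-length analysis, unfolding
# pathway classification and contact-map evolution for pulling trajectories.

# printed cluster centers of the second rupture event:
# (peak force kcal/mol/A, contour-length gain nm)
.PATHWAY_CENTERS <- matrix(c(2.41, 10.90,   # low-force unzipping
                             3.75, 13.67),  # high-force shearing
                           nrow = 2, byrow = TRUE,
                           dimnames = list(c("low_force_unzipping",
                                             "high_force_shearing"),
                                           c("F_u_kcal", "dLc_nm")))

# accept either a pulling_trajectory or any tibble with ext_nm + force col
force_extension <- function(traj) {
  F_pN <- if ("F_pN" %in% names(traj)) traj$F_pN else traj$force_pN
  tibble(ext_nm = traj$ext_nm, F_pN = F_pN)
}

#' Detect rupture events in a force-extension curve
#'
#' The force trace is smoothed with a local polynomial (Savitzky-Golay)
#' filter; rupture peaks are local maxima of the smoothed force that exceed
#' the noise floor (median + `n_mad` MAD of the smoothed trace) and are
#' followed by a force drop of at least `drop_frac` of the peak value
#' before the next retained peak (or the end of the trace). Events are
#' returned in order of extension.
#'
#' @param traj A `pulling_trajectory` or tibble with `ext_nm` and `F_pN`.
#' @param window Smoothing window (odd number of samples).
#' @param n_mad Noise-floor multiplier.
#' @param drop_frac Required fractional force drop after a peak.
#' @return A `rupture_events` tibble: `ordinal`, `idx`, `ext_nm`,
#'   `F_pN`, `F_kcal`, and the smoothing window used (attribute).
#' @export
detect_ruptures <- function(traj, window = 51L, n_mad = 4, drop_frac = 0.3) {
  fx <- force_extension(traj)
  n <- nrow(fx)
  if (n < 1000L) abort("rupture detection needs >= 1000 samples")
  window <- min(as.integer(window), if (n %% 2 == 0) n - 1L else n - 2L)
  if (window %% 2L == 0L) window <- window + 1L
  fs <- as.numeric(signal::sgolayfilt(fx$F_pN, p = 3, n = window))
  # noise floor from the raw trace: smoothing shrinks the MAD of pure noise
  floor_ <- stats::median(fx$F_pN) + n_mad * stats::mad(fx$F_pN)
  cand <- which(diff(sign(diff(fs))) < 0) + 1L
  cand <- cand[fs[cand] > floor_]
  keep <- integer()
  k <- 1L
  while (k <= length(cand)) {
    cur <- cand[k]
    k <- k + 1L
    while (k <= length(cand)) {
      seg <- fs[cur:cand[k]]
      if (min(seg) <= (1 - drop_frac) * fs[cur]) break  # genuine drop
      # no drop between the two candidates: merge, keep the higher
      if (fs[cand[k]] > fs[cur]) cur <- cand[k]
      k <- k + 1L
    }
    # require the drop after the final candidate too
    tail_min <- min(fs[cur:n])
    if (tail_min <= (1 - drop_frac) * fs[cur]) keep <- c(keep, cur)
  }
  out <- tibble(
    ordinal = seq_along(keep), idx = keep,
    ext_nm = fx$ext_nm[keep], F_pN = fs[keep],
    F_kcal = fs[keep] / .KCAL_PER_A_IN_PN)
  attr(out, "window") <- window
  attr(out, "noise_floor_pN") <- floor_
  class(out) <- c("rupture_events", class(out))
  out
}

# fit a single WLC contour length to a rising edge (persistence fixed)
fit_wlc_edge <- function(x, F, persistence_nm, kBT = .KBT_PN_NM_300K) {
  sel <- F > max(F) * 0.25 & x > 0
  x <- x[sel]; F <- F[sel]
  if (length(x) < 8) return(NA_real_)
  sse <- function(Lc) {
    sum((wlc_force(x, Lc, persistence_nm, kBT) - F)^2)
  }
  up <- max(x) * 4
  o <- try(stats::optimize(sse, c(max(x) * 1.001, up), tol = 1e-6),
           silent = TRUE)
  if (inherits(o, "try-error")) return(NA_real_)
  if (o$minimum > up * 0.99) return(NA_real_)   # not converged to an edge
  o$minimum
}

#' Contour-length gains between successive ruptures
#'
#' Fits the interpolated worm-like-chain force law to the rising edge
#' before and after each rupture (contour length free, persistence length
#' fixed) and reports the gain `dLc` as the difference of successive fitted
#' contour lengths. The `"raw"` method instead uses peak-to-peak extension
#' differences.
#'
#' @param traj Trajectory (as in [detect_ruptures()]).
#' @param events A `rupture_events` table.
#' @param persistence_nm WLC persistence length (nm).
#' @param method `"wlc"` or `"raw"`.
#' @return `events` with added columns `Lc_nm` (edge before the event) and
#'   `dLc_nm` (NA when no successor edge exists or a fit failed).
#' @export
contour_length_gain <- function(traj, events, persistence_nm = 0.4,
                                method = c("wlc", "raw")) {
  method <- match.arg(method)
  fx <- force_extension(traj)
  n <- nrow(fx)
  if (nrow(events) == 0L) {
    events$Lc_nm <- numeric(0); events$dLc_nm <- numeric(0)
    return(events)
  }
  if (method == "raw") {
    events$Lc_nm <- events$ext_nm
    events$dLc_nm <- c(diff(events$ext_nm), NA_real_)
    return(events)
  }
  bounds <- c(1L, events$idx, n)
  Lc <- purrr::map_dbl(seq_len(nrow(events) + 1L), function(k) {
    lo <- bounds[k]; hi <- bounds[k + 1L]
    seg <- fx[lo:hi, ]
    fit_wlc_edge(seg$ext_nm, seg$F_pN, persistence_nm)
  })
  events$Lc_nm <- Lc[seq_len(nrow(events))]
  events$dLc_nm <- Lc[-1] - Lc[-length(Lc)]
  flagged <- is.na(events$dLc_nm)
  if (any(flagged[-nrow(events)])) {
    warn("WLC fit did not converge for some edges; dLc set to NA")
  }
  events
}

#' Classify an unfolding event into the shearing or unzipping pathway
#'
#' Nearest-center assignment of the classifying rupture (by convention the
#' second) in standardized (peak force, contour-length gain) space. The
#' default centers are the two observed pathway centers: low-force
#' unzipping at (2.41 kcal/mol/A, 10.90 nm) and high-force shearing at
#' (3.75 kcal/mol/A, 13.67 nm). Ties go to the low-force pathway. With
#' `refit = TRUE` the centers are re-estimated by 2-means on the supplied
#' events (seeded from the default centers, hence deterministic).
#'
#' @param events Tibble with columns `F_kcal` and `dLc_nm` (one row per
#'   classifying event).
#' @param centers 2x2 matrix (rows: low, high; columns: force kcal/mol/A,
#'   dLc nm).
#' @param refit Re-estimate centers by 2-means on `events`.
#' @return `events` with an added `pathway` factor
#'   (`low_force_unzipping` / `high_force_shearing`; NA when `dLc_nm` is
#'   missing).
#' @export
classify_pathway <- function(events, centers = .PATHWAY_CENTERS,
                             refit = FALSE) {
  X <- cbind(events$F_kcal, events$dLc_nm)
  if (refit) {
    ok <- stats::complete.cases(X)
    if (sum(ok) >= 4) {
      km <- stats::kmeans(X[ok, , drop = FALSE], centers = centers)
      centers <- km$centers
      # keep row semantics: low-force row first
      o <- order(centers[, 1])
      centers <- centers[o, , drop = FALSE]
      rownames(centers) <- rownames(.PATHWAY_CENTERS)
    }
  }
  mu <- colMeans(centers)
  sd_ <- apply(centers, 2, stats::sd)
  zc <- sweep(sweep(centers, 2, mu), 2, sd_, "/")
  zx <- sweep(sweep(X, 2, mu), 2, sd_, "/")
  d_low <- sqrt(rowSums(sweep(zx, 2, zc[1, ])^2))
  d_high <- sqrt(rowSums(sweep(zx, 2, zc[2, ])^2))
  lab <- ifelse(is.na(d_low) | is.na(d_high), NA_character_,
                ifelse(d_high < d_low, "high_force_shearing",
                       "low_force_unzipping"))      # tie -> low force
  events$pathway <- factor(lab, levels = rownames(.PATHWAY_CENTERS))
  attr(events, "centers") <- centers
  events
}

#' Native-contact evolution along a trajectory
#'
#' A native contact (i, j) counts as present in a frame when the current
#' bead distance is below `factor` times its native distance.
#'
#' @param traj A `pulling_trajectory` run with `stride_frames > 0`.
#' @param top The `sop_topology` (defaults to the trajectory's own).
#' @param factor Distance tolerance factor.
#' @return A list with `fraction` (tibble: frame, q) and `per_pair`
#'   (tibble: i, j, lifetime = fraction of frames present, last_frame).
#' @export
contact_map_evolution <- function(traj, top = NULL, factor = 1.25) {
  top <- top %||% attr(traj, "topology")
  frames <- attr(traj, "frames")
  if (is.null(frames)) abort("trajectory has no stored frames (stride_frames = 0)")
  pres <- vapply(frames, function(fr) {
    d <- sqrt(rowSums((fr[top$native$i, , drop = FALSE] -
                         fr[top$native$j, , drop = FALSE])^2))
    d < factor * top$native$r0
  }, logical(nrow(top$native)))
  pres <- matrix(pres, nrow = nrow(top$native))
  last <- apply(pres, 1, function(z) if (any(z)) max(which(z)) else 0L)
  list(
    fraction = tibble(frame = seq_len(ncol(pres)), q = colMeans(pres)),
    per_pair = tibble(i = top$native$i, j = top$native$j,
                      lifetime = rowMeans(pres), last_frame = last))
}
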