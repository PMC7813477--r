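# Seeded synthetic-data generators. Each generator emulates the statistical
# structure of one experimental input of the pipeline (calorimetry, melts,
# stopped-flow traces, dihedral series, H-bond event streams, worm-like-chain
# force-extension curves) so that every analysis stage can be exercised and
# validated offline against planted truth.

#' Synthetic beta-sandwich contact map
#'
#' Builds a WSME-flavor contact map for an EC1-like beta-sandwich domain
#' without needing a crystal structure: nine strands connected by loops,
#' antiparallel strand pairings with realistic heavy-atom contact
#' multiplicities, local (|i-j| of 2-4) backbone contacts, and core packing
#' contacts. The per-residue atomic contact density defaults to that of
#' compact globular domains (roughly 28 heavy-atom neighbours within 6 A
#' per atom and ~8 heavy atoms per residue, i.e. ~225 incident atomic
#' contacts per residue), which also places the model's thermal transition
#' in the experimentally relevant range.
#'
#' The companion secondary-structure table (strand residues as
#' `strand_or_helix`, loops as `coil_or_glycine`, a few prolines) is
#' attached as `attr(, "ss")`. The `"s47p"` variant converts residue 47 to
#' proline and thins the contacts of the loop around it, mimicking a
#' point mutation that lowers the native packing density.
#'
#' @param n_residues Domain size (default 102).
#' @param variant `"wt"` or `"s47p"`.
#' @param density Target atomic contacts per residue (incident; default 225).
#' @param seed Random seed.
#' @return A `contact_map` (flavor `"wsme"`) with attributes `charges` and
#'   `ss`.
#' @export
synth_contact_map <- function(n_residues = 102, variant = c("wt", "s47p"),
                              density = 225, seed = 1) {
  variant <- match.arg(variant)
  n <- as.integer(n_residues)
  # both variants share one base map (the two crystal structures are nearly
  # identical); the mutant is derived from it below
  withr_seed(derive_seed(seed, "cmap"))
  # strand layout: 9 strands separated by loops, scaled to n
  n_strands <- 9L
  strand_len <- max(4L, round(n * 0.55 / n_strands))
  gap <- max(2L, round((n - n_strands * strand_len) / (n_strands - 1)))
  starts <- cumsum(c(2L, rep(strand_len + gap, n_strands - 1L)))
  starts <- starts[starts + 1L <= n]
  strands <- purrr::map(starts, ~ seq(.x, min(.x + strand_len - 1L, n)))
  in_strand <- sort(unique(unlist(strands)))
  pairs <- list()
  add <- function(i, j, n_at, r0) {
    ok <- i >= 1 & j <= n & (j - i) >= 2 & n_at > 0
    if (any(ok)) {
      pairs[[length(pairs) + 1L]] <<- tibble(
        i = as.integer(i[ok]), j = as.integer(j[ok]),
        r0 = r0[ok], n_atomic = as.integer(n_at[ok]))
    }
  }
  # local backbone packing
  for (sep in 2:4) {
    i <- seq_len(n - sep)
    add(i, i + sep, stats::rpois(length(i), c(15, 8, 4)[sep - 1]),
        stats::rnorm(length(i), c(5.4, 6.5, 7.5)[sep - 1], 0.2))
  }
  # antiparallel strand pairings (sheet 1: odd strands, sheet 2: even)
  pairing <- rbind(c(1, 2), c(2, 3), c(3, 8), c(4, 7), c(5, 8),
                   c(2, 9), c(8, 9), c(6, 7), c(5, 6))
  pairing <- pairing[pairing[, 1] <= length(strands) &
                       pairing[, 2] <= length(strands), , drop = FALSE]
  for (r in seq_len(nrow(pairing))) {
    s1 <- strands[[pairing[r, 1]]]; s2 <- rev(strands[[pairing[r, 2]]])
    m <- min(length(s1), length(s2))
    i <- pmin(s1[1:m], s2[1:m]); j <- pmax(s1[1:m], s2[1:m])
    add(i, j, stats::rpois(m, 18), stats::rnorm(m, 5.1, 0.3))
    add(i - 1, j + 1, stats::rpois(m, 7), stats::rnorm(m, 6.3, 0.3))
  }
  # core packing: random strand-residue pairs until target density reached
  cur <- sum(purrr::map_int(pairs, ~ sum(.x$n_atomic)))
  target <- round(density * n / 2)
  if (cur < target) {
    need <- target - cur
    n_extra <- ceiling(need / 12)
    ii <- sample(in_strand, n_extra * 3, replace = TRUE)
    jj <- sample(in_strand, n_extra * 3, replace = TRUE)
    lo <- pmin(ii, jj); hi <- pmax(ii, jj)
    keep <- which(hi - lo >= 5)[seq_len(min(n_extra, sum(hi - lo >= 5)))]
    add(lo[keep], hi[keep], stats::rpois(length(keep), 12),
        stats::rnorm(length(keep), 6.8, 0.6))
  }
  cm <- dplyr::bind_rows(pairs) |>
    dplyr::group_by(.data$i, .data$j) |>
    dplyr::summarise(r0 = .data$r0[1], n_atomic = sum(.data$n_atomic),
                     .groups = "drop") |>
    arrange(.data$i, .data$j)
  cm$r0 <- pmax(cm$r0, 3.8)
  # residue classes and charges
  cls <- rep("coil_or_glycine", n)
  cls[in_strand] <- "strand_or_helix"
  pro_sites <- setdiff(seq(6, n - 4, by = 26), in_strand)[1:3]
  pro_sites <- pro_sites[!is.na(pro_sites)]
  cls[pro_sites] <- "proline"
  resname <- rep("ALA", n)
  resname[cls == "proline"] <- "PRO"
  charged_sites <- sample(setdiff(seq_len(n), pro_sites), round(0.22 * n))
  q <- numeric(n)
  q[charged_sites] <- sample(c(-1, 1), length(charged_sites), replace = TRUE)
  resname[q == -1] <- "GLU"; resname[q == 1] <- "LYS"
  if (variant == "s47p") {
    withr_seed(derive_seed(seed, "s47p"))
    site <- min(47L, n - 1L)
    cls[site] <- "proline"; resname[site] <- "PRO"; q[site] <- 0
    near <- cm$i %in% (site - 2):(site + 2) | cm$j %in% (site - 2):(site + 2)
    thin <- near & stats::runif(nrow(cm)) < 0.35
    cm$n_atomic[near] <- pmax(1L, round(cm$n_atomic[near] * 0.75))
    cm <- cm[!(thin & cm$n_atomic <= 3), ]
  }
  out <- new_contact_map(cm, "wsme", n, charges = q)
  attr(out, "ss") <- tibble(resno = seq_len(n), resname = resname, class = cls)
  attr(out, "variant") <- variant
  out
}

# set the RNG seed locally (restores the caller's RNG state on exit of the
# *calling* generator; generators call this once at entry)
withr_seed <- function(seed) {
  set.seed(as.integer(seed))
  invisible(seed)
}

#' Synthetic calorimetry thermogram
#'
#' Two-state mode generates the van't Hoff excess heat capacity
#' `Cp(T) = dH^2/(R T^2) K/(1+K)^2` with `K = exp(-dH/R (1/T - 1/Tm))`;
#' its peak sits exactly at `Tm` and its integral over the transition is
#' `dH`. Model mode (`from_bwsme`) evaluates a [wsme_system()] heat
#' capacity. Gaussian noise is added with standard deviation `noise` times
#' the curve maximum.
#'
#' @param model `"two_state"` or `"from_bwsme"`.
#' @param T_grid Temperature grid (K), within 280-380.
#' @param dH,Tm Two-state van't Hoff enthalpy (kJ/mol) and midpoint (K).
#' @param system A [wsme_system()] (model mode).
#' @param noise Relative noise level.
#' @param seed Random seed.
#' @return A `thermogram` tibble (`T_K`, `Cp_kJ`) with attribute `truth`
#'   recording the generating parameters and the noise-free curve.
#' @export
make_thermogram <- function(model = c("two_state", "from_bwsme"),
                            T_grid = seq(280, 380, by = 0.5),
                            dH = 300, Tm = 339.2, system = NULL,
                            noise = 0, seed = 1) {
  model <- match.arg(model)
  if (min(T_grid) < 280 - 1e-9 || max(T_grid) > 380 + 1e-9) {
    abort("T_grid must lie within 280-380 K")
  }
  withr_seed(derive_seed(seed, "thermogram"))
  if (model == "two_state") {
    dH_J <- dH * 1000
    K <- exp(-dH_J / .R_GAS * (1 / T_grid - 1 / Tm))
    cp <- dH_J^2 / (.R_GAS * T_grid^2) * K / (1 + K)^2 / 1000
    truth <- list(model = model, dH = dH, Tm = Tm, seed = seed)
  } else {
    if (is.null(system)) abort("from_bwsme mode needs a wsme_system")
    cp <- heat_capacity_curve(system, T_grid)$Cp_kJ
    truth <- list(model = model, params = system$params, seed = seed)
  }
  eps <- stats::rnorm(length(T_grid), 0, noise * max(abs(cp)))
  out <- tibble(T_K = T_grid, Cp_kJ = cp + eps)
  attr(out, "truth") <- c(truth, list(noise = noise, Cp_clean = cp))
  class(out) <- c("thermogram", class(out))
  out
}

#' Synthetic equilibrium unfolding curve
#'
#' Two-state melt in raw signal units: the unfolded fraction follows
#' `1/(1 + exp(dG/RT))` with `dG = dH (1 - T/Tm)` (thermal mode) or
#' `dG = m (Cm - c)` (chemical mode), mapped between folded and unfolded
#' baselines with optional Gaussian noise.
#'
#' @param mode `"thermal"` or `"chemical"`.
#' @param x Abscissa grid: temperature (K) or denaturant (M).
#' @param midpoint Tm (K) or Cm (M).
#' @param steepness dH (kJ/mol) for thermal; m-value (kJ/mol/M) for
#'   chemical.
#' @param theta_f,theta_u Folded/unfolded baseline signals.
#' @param noise Relative noise (fraction of the baseline span).
#' @param seed Random seed.
#' @return A tibble (`x`, `signal`) with attribute `truth` (generating
#'   parameters and the clean unfolded fraction).
#' @export
make_melt_curve <- function(mode = c("thermal", "chemical"),
                            x = seq(295, 365, by = 2.5), midpoint = 339.2,
                            steepness = 300, theta_f = -4000, theta_u = -1500,
                            noise = 0, seed = 1) {
  mode <- match.arg(mode)
  withr_seed(derive_seed(seed, "melt"))
  dG <- if (mode == "thermal") {
    steepness * 1000 * (1 - x / midpoint) / (.R_GAS * x)
  } else {
    T0 <- 298.15
    steepness * 1000 * (midpoint - x) / (.R_GAS * T0)
  }
  f_u <- 1 / (1 + exp(dG))
  signal <- theta_f + (theta_u - theta_f) * f_u
  signal <- signal + stats::rnorm(length(x), 0, noise * abs(theta_u - theta_f))
  out <- tibble(x = x, signal = signal)
  attr(out, "truth") <- list(mode = mode, midpoint = midpoint,
                             steepness = steepness, theta_f = theta_f,
                             theta_u = theta_u, noise = noise, f_u = f_u,
                             seed = seed)
  out
}

#' Synthetic stopped-flow kinetic trace
#'
#' Bi-exponential fluorescence decay
#' `A_f exp(-k_f t) + A_s exp(-k_s t) + offset` sampled log-uniformly
#' between the mixing dead time and the acquisition end, with Gaussian
#' noise proportional to the signal span.
#'
#' @param k_fast,k_slow Rate constants (1/s).
#' @param A_fast,A_slow Amplitudes (signal units).
#' @param offset Signal offset.
#' @param dead_time Mixing dead time (s); no samples before it.
#' @param duration Acquisition window (s).
#' @param n Number of samples.
#' @param noise Relative noise level.
#' @param seed Random seed.
#' @param conc Denaturant concentration (M), carried as metadata.
#' @return A `kinetic_trace` tibble (`t_s`, `signal`) with attributes
#'   `conc` and `truth`.
#' @export
make_kinetic_trace <- function(k_fast = 93.7, k_slow = 9.9, A_fast = 0.6,
                               A_slow = 0.4, offset = 1, dead_time = 0.003,
                               duration = 10, n = 1500, noise = 0, seed = 1,
                               conc = 0) {
  stopifnot(k_fast > 0, k_slow > 0)
  withr_seed(derive_seed(seed, "kintrace"))
  t <- exp(seq(log(dead_time), log(duration), length.out = n))
  sig <- A_fast * exp(-k_fast * t) + A_slow * exp(-k_slow * t) + offset
  span <- abs(A_fast) + abs(A_slow)
  sig <- sig + stats::rnorm(n, 0, noise * span)
  out <- tibble(t_s = t, signal = sig)
  attr(out, "conc") <- conc
  attr(out, "truth") <- list(k_fast = k_fast, k_slow = k_slow,
                             A_fast = A_fast, A_slow = A_slow,
                             offset = offset, noise = noise, seed = seed)
  class(out) <- c("kinetic_trace", class(out))
  out
}

#' Synthetic refolding ladder across denaturant concentrations
#'
#' Generates one [make_kinetic_trace()] per denaturant concentration with
#' rates following linear log-rate laws
#' `ln k(c) = ln k0 + slope * c` for each phase, and amplitude fractions
#' following a linear trend (used for amplitude-crossover analyses).
#'
#' @param conc Concentration ladder (M).
#' @param k0_fast,k0_slow Zero-denaturant rates (1/s).
#' @param slope_fast,slope_slow Refolding-branch slopes (1/M, negative).
#' @param af0,af_slope Fast-phase amplitude fraction at 0 M and its slope
#'   per M.
#' @param total_amp Total amplitude.
#' @param noise,seed,n,duration As in [make_kinetic_trace()].
#' @return A list with `traces` (list of `kinetic_trace`) and `truth`
#'   (tibble of per-concentration generating values).
#' @export
make_chevron_ladder <- function(conc = seq(0.2, 1.4, by = 0.2),
                                k0_fast = 93.7, k0_slow = 9.9,
                                slope_fast = -1.5, slope_slow = -1.5,
                                af0 = 0.73, af_slope = -0.16,
                                total_amp = 1, noise = 0.02, seed = 1,
                                n = 1500, duration = 10) {
  kf <- exp(log(k0_fast) + slope_fast * conc)
  ks <- exp(log(k0_slow) + slope_slow * conc)
  af <- pmin(0.95, pmax(0.05, af0 + af_slope * conc))
  traces <- purrr::map(seq_along(conc), function(i) {
    make_kinetic_trace(kf[i], ks[i], A_fast = total_amp * af[i],
                       A_slow = total_amp * (1 - af[i]), noise = noise,
                       seed = derive_seed(seed, paste0("ladder", i)),
                       conc = conc[i], n = n, duration = duration)
  })
  list(traces = traces,
       truth = tibble(conc = conc, k_fast = kf, k_slow = ks, af_frac = af,
                      k0_fast = k0_fast, k0_slow = k0_slow,
                      slope_fast = slope_fast, slope_slow = slope_slow))
}

# von Mises sampler (Best & Fisher); kappa = 0 falls back to uniform
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- mu + sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f)))
      i <- i + 1L
    }
  }
  wrap_angle(out)
}

wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y == -pi, pi, y)
}

# concentration parameter whose von Mises mean resultant length equals rho
kappa_for_resultant <- function(rho) {
  if (rho <= 0) return(0)
  if (rho >= 0.999) rho <- 0.999
  stats::uniroot(function(k) besselI(k, 1) / besselI(k, 0) - rho,
                 c(1e-6, 500))$root
}

# noise concentration giving circular correlation `s` between a von Mises
# base series (concentration kappa_base) and base + noise. The expected
# coefficient is A1(k) * sqrt((1 - A2(kb)) / (1 - A2(kb) A2(k))): the first
# factor is the noise resultant, the second the sine-variance attenuation
# of the broadened partner.
kappa_for_target <- function(s, kappa_base) {
  if (s <= 0) return(0)
  if (s >= 0.995) s <- 0.995
  A <- function(n, k) besselI(k, n) / besselI(k, 0)
  if (kappa_base <= 0) return(kappa_for_resultant(s))
  a2b <- A(2, kappa_base)
  f <- function(k) {
    A(1, k) * sqrt((1 - a2b) / (1 - a2b * A(2, k))) - s
  }
  stats::uniroot(f, c(1e-6, 500))$root
}

#' Synthetic dihedral-angle series with planted circular correlations
#'
#' Base angles are i.i.d. von Mises around a random per-dihedral mean, with
#' concentration `kappa_base` (default 2, i.e. fluctuations of roughly
#' +-40 degrees around a basin, as backbone dihedrals show within a
#' secondary-structure element; `kappa_base = 0` gives uniform angles for
#' null calibrations). For each planted pair the second series is the
#' first plus von Mises noise whose concentration is chosen so the
#' circular correlation matches the requested strength: for a concentrated
#' base the expected coefficient equals the mean resultant length of the
#' noise, which is inverted in closed form. (With a uniform base the
#' sample circular means are degenerate and the coefficient of a planted
#' pair is attenuated by an arbitrary rotation, so calibration targets
#' are only honoured for `kappa_base > 0`.)
#'
#' @param n_dihedrals Number of angle series (columns).
#' @param n_frames Number of frames (rows).
#' @param pairs Tibble with columns `i`, `j`, `strength` (each in `[0, 1)`)
#'   of planted correlated pairs; `j` is overwritten from `i`.
#' @param kappa_base Concentration of the independent base angles
#'   (0 = uniform).
#' @param seed Random seed.
#' @return A numeric matrix (`n_frames x n_dihedrals`, radians) with
#'   attribute `truth` (the planted pair table).
#' @export
make_dihedral_series <- function(n_dihedrals = 20, n_frames = 5000,
                                 pairs = NULL, kappa_base = 2, seed = 1) {
  if (!is.null(pairs) && any(pairs$strength < 0 | pairs$strength >= 1)) {
    abort("planted strengths must be in [0, 1)")
  }
  withr_seed(derive_seed(seed, "dihedrals"))
  mu <- stats::runif(n_dihedrals, -pi, pi)
  X <- matrix(0, n_frames, n_dihedrals)
  for (k in seq_len(n_dihedrals)) {
    X[, k] <- rvonmises(n_frames, mu[k], kappa_base)
  }
  if (!is.null(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      kap <- kappa_for_target(pairs$strength[r], kappa_base)
      X[, pairs$j[r]] <- wrap_angle(X[, pairs$i[r]] +
                                      rvonmises(n_frames, 0, kap))
    }
  }
  colnames(X) <- paste0("d", seq_len(n_dihedrals))
  attr(X, "truth") <- pairs
  X
}

#' Synthetic hydrogen-bond event stream
#'
#' Per-frame Bernoulli (optionally two-state Markov) presence draws for a
#' set of donor-acceptor residue pairs with target persistences. At 5000+
#' frames the empirical persistence is within ~2% of the target.
#'
#' @param pairs Tibble with columns `donor`, `acceptor`, `p` (target
#'   persistence in `[0, 1]`).
#' @param n_frames Number of frames.
#' @param flip_rate Optional Markov switching rate (per frame) towards the
#'   stationary persistence; `NULL` for i.i.d. draws.
#' @param exact If `TRUE`, each pair is present in exactly
#'   `round(p * n_frames)` evenly spread frames (deterministic planted
#'   truth) instead of Bernoulli draws.
#' @param seed Random seed.
#' @return An `hbond_events` tibble of present bonds (`donor`, `acceptor`,
#'   `frame`) with attributes `n_frames` and `truth`.
#' @export
make_hbond_events <- function(pairs, n_frames = 5000, flip_rate = NULL,
                              exact = FALSE, seed = 1) {
  stopifnot(all(pairs$p >= 0 & pairs$p <= 1))
  withr_seed(derive_seed(seed, "hbonds"))
  rows <- purrr::map(seq_len(nrow(pairs)), function(r) {
    p <- pairs$p[r]
    pres <- if (exact) {
      z <- logical(n_frames)
      k <- round(p * n_frames)
      if (k > 0) z[floor(seq_len(k) * n_frames / k)] <- TRUE
      z
    } else if (is.null(flip_rate)) {
      stats::runif(n_frames) < p
    } else {
      z <- logical(n_frames)
      z[1] <- stats::runif(1) < p
      on_rate <- flip_rate * p; off_rate <- flip_rate * (1 - p)
      for (f in 2:n_frames) {
        z[f] <- if (z[f - 1]) stats::runif(1) > off_rate else stats::runif(1) < on_rate
      }
      z
    }
    tibble(donor = pairs$donor[r], acceptor = pairs$acceptor[r],
           frame = which(pres))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_frames") <- as.integer(n_frames)
  attr(out, "truth") <- pairs
  class(out) <- c("hbond_events", class(out))
  out
}

# worm-like chain interpolation formula: force (pN) at extension x (nm)
wlc_force <- function(x, Lc, p_nm = 0.4, kBT = .KBT_PN_NM_300K) {
  t <- pmin(x / Lc, 0.995)
  (kBT / p_nm) * (1 / (4 * (1 - t)^2) - 0.25 + t)
}

# inverse of wlc_force in x for a given force
wlc_extension <- function(F, Lc, p_nm = 0.4, kBT = .KBT_PN_NM_300K) {
  vapply(F, function(f) {
    stats::uniroot(function(x) wlc_force(x, Lc, p_nm, kBT) - f,
                   c(1e-6, Lc * 0.995))$root
  }, numeric(1))
}

#' Synthetic multi-segment worm-like-chain force-extension curve
#'
#' Concatenated WLC rising edges: segment k follows the interpolated WLC
#' force law with contour length `contour_nm[k]` up to its planted rupture
#' force, where the force drops instantaneously onto the next segment's
#' curve. Used as planted truth for rupture detection and contour-length
#' gain estimation.
#'
#' @param contour_nm Increasing contour lengths (nm), one per segment.
#' @param rupture_pN Rupture force of each segment but the last (recycled).
#' @param persistence_nm WLC persistence length (nm).
#' @param n Number of samples.
#' @param noise Relative force noise.
#' @param seed Random seed.
#' @return A tibble (`ext_nm`, `F_pN`) with attribute `truth` (segment
#'   table including rupture extensions).
#' @export
make_wlc_trace <- function(contour_nm = c(20, 30.9, 44.57),
                           rupture_pN = 250, persistence_nm = 0.4,
                           n = 4000, noise = 0, seed = 1) {
  if (is.unsorted(contour_nm, strictly = TRUE)) {
    abort("contour lengths must be strictly increasing")
  }
  withr_seed(derive_seed(seed, "wlc"))
  ns <- length(contour_nm)
  rupture_pN <- rep_len(rupture_pN, ns - 1)
  x_rupt <- purrr::map_dbl(seq_len(ns - 1), function(k) {
    wlc_extension(rupture_pN[k], contour_nm[k], persistence_nm)
  })
  F_end <- if (length(rupture_pN)) max(rupture_pN) * 1.2 else 300
  x_max <- wlc_extension(F_end, contour_nm[ns], persistence_nm)
  x <- seq(0.02, x_max, length.out = n)
  seg <- findInterval(x, c(0, x_rupt, Inf))  # active segment per x
  F <- wlc_force(x, contour_nm[seg], persistence_nm)
  F <- pmax(0, F + stats::rnorm(n, 0, noise * max(F)))
  out <- tibble(ext_nm = x, F_pN = F)
  attr(out, "truth") <- list(
    segments = tibble(contour_nm = contour_nm,
                      rupture_pN = c(rupture_pN, NA),
                      x_rupt = c(x_rupt, NA)),
    persistence_nm = persistence_nm, noise = noise, seed = seed)
  out
}
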