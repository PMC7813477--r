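# Observables of the bWSME model: heat-capacity curves, DSC fitting, and
# free-energy profiles/surfaces over the structured-block order parameter.

#' Model heat-capacity curve
#'
#' The excess heat capacity is the temperature derivative of the ensemble
#' mean enthalpy, evaluated by central differences on a temperature grid.
#'
#' @param system A [wsme_system()].
#' @param T_grid Strictly increasing temperature grid (K), spacing <= 0.5 K.
#' @return A `thermogram` tibble with columns `T_K`, `Cp_kJ` (kJ/mol/K) and
#'   attribute `Tm` (temperature of the Cp maximum).
#' @export
heat_capacity_curve <- function(system, T_grid) {
  dT <- diff(T_grid)
  if (any(dT <= 0)) abort("temperature grid must be strictly increasing")
  if (any(dT > 0.5 + 1e-9)) abort("temperature grid spacing must be <= 0.5 K")
  Hbar <- vapply(T_grid, function(T) {
    e <- wsme_state_energies(system, T)
    pf <- partition_function(e$F, T)
    sum(pf$p * e$H)
  }, numeric(1))
  n <- length(T_grid)
  Cp <- numeric(n)
  Cp[2:(n - 1)] <- (Hbar[3:n] - Hbar[1:(n - 2)]) / (T_grid[3:n] - T_grid[1:(n - 2)])
  Cp[1] <- (Hbar[2] - Hbar[1]) / dT[1]
  Cp[n] <- (Hbar[n] - Hbar[n - 1]) / dT[n - 1]
  out <- tibble(T_K = T_grid, Cp_kJ = Cp / 1000)
  attr(out, "Tm") <- T_grid[which.max(Cp)]
  class(out) <- c("thermogram", class(out))
  out
}

#' Fit the bWSME model to a calorimetry thermogram
#'
#' Least-squares fit of model excess heat capacity to an experimental (or
#' synthetic) thermogram over a chosen subset of free parameters. A linear
#' baseline fitted to the pre-transition region of the experimental curve
#' is subtracted before comparison. Optimization is deterministic: a coarse
#' grid around the starting values followed by Nelder-Mead refinement.
#'
#' @param experimental Tibble with columns `T_K` and `Cp_kJ`.
#' @param cmap,ss Contact map and secondary-structure table defining the
#'   system.
#' @param free Character vector naming the free parameters, a subset of
#'   `c("xi", "dS_strand_helix", "dS_coil_gly")`.
#' @param fixed A [wsme_parameters()] object supplying all fixed values and
#'   the starting point of the free ones.
#' @param block_size Residues per block.
#' @param baseline `"linear"` (fit and subtract a pre-transition linear
#'   baseline) or `"none"`.
#' @param grid_span,grid_n Relative half-width and size of the coarse
#'   search grid per free parameter.
#' @return A `dsc_fit` list with `params` (fitted [wsme_parameters()]),
#'   `estimates` (tibble of free-parameter values), `rms_residual`
#'   (kJ/mol/K), `at_bound` flag, and `curve` (tibble with experimental and
#'   fitted Cp).
#' @export
fit_dsc <- function(experimental, cmap, ss, free = "xi",
                    fixed = wsme_parameters(), block_size = 3L,
                    baseline = c("linear", "none"),
                    grid_span = 0.08, grid_n = 7L) {
  baseline <- match.arg(baseline)
  allowed <- c("xi", "dS_strand_helix", "dS_coil_gly")
  if (any(free %!in% allowed)) {
    abort(sprintf("free parameters must be among: %s", paste(allowed, collapse = ", ")))
  }
  Tg <- experimental$T_K
  cp_exp <- experimental$Cp_kJ
  if (baseline == "linear") {
    pre <- seq_len(max(3L, floor(length(Tg) * 0.15)))
    bl <- stats::lm(cp_exp[pre] ~ Tg[pre])
    cp_exp <- cp_exp - (stats::coef(bl)[1] + stats::coef(bl)[2] * Tg)
  }
  make_params <- function(theta) {
    p <- fixed
    p[free] <- as.list(theta)
    class(p) <- "wsme_parameters"
    p
  }
  obj <- function(theta) {
    sys <- wsme_system(cmap, ss, make_params(theta), block_size)
    cp_mod <- heat_capacity_curve(sys, Tg)$Cp_kJ
    sqrt(mean((cp_mod - cp_exp)^2))
  }
  theta0 <- unlist(fixed[free])
  if (length(free) == 0L) {
    rms <- obj(numeric(0))
    sys <- wsme_system(cmap, ss, fixed, block_size)
    curve <- tibble(T_K = Tg, Cp_exp = cp_exp,
                    Cp_fit = heat_capacity_curve(sys, Tg)$Cp_kJ)
    out <- list(params = fixed, estimates = tibble(parameter = character(),
                                                   estimate = numeric()),
                rms_residual = rms, at_bound = FALSE, curve = curve)
    class(out) <- "dsc_fit"
    return(out)
  }
  # coarse axis-aligned grid around the start, one parameter at a time
  theta <- theta0
  for (k in seq_along(free)) {
    cand <- theta0[k] * (1 + seq(-grid_span, grid_span, length.out = grid_n))
    vals <- vapply(cand, function(v) {
      th <- theta; th[k] <- v; obj(th)
    }, numeric(1))
    theta[k] <- cand[which.min(vals)]
  }
  opt <- if (length(free) == 1L) {
    step <- abs(theta0) * 2 * grid_span / (grid_n - 1)
    o <- stats::optimize(function(v) obj(v), c(theta - step, theta + step),
                         tol = abs(theta0) * 1e-5)
    list(par = stats::setNames(o$minimum, free), value = o$objective)
  } else {
    stats::optim(theta, obj, method = "Nelder-Mead",
                 control = list(maxit = 200, reltol = 1e-6))
  }
  lower <- theta0 * (1 + grid_span); upper <- theta0 * (1 - grid_span)
  at_bound <- any(abs(opt$par - pmin(lower, upper)) < 1e-8 * abs(theta0) |
                    abs(opt$par - pmax(lower, upper)) < 1e-8 * abs(theta0))
  params_fit <- make_params(opt$par)
  sys <- wsme_system(cmap, ss, params_fit, block_size)
  curve <- tibble(T_K = Tg, Cp_exp = cp_exp,
                  Cp_fit = heat_capacity_curve(sys, Tg)$Cp_kJ)
  out <- list(params = params_fit,
              estimates = tibble(parameter = free, estimate = unname(opt$par),
                                 start = unname(theta0)),
              rms_residual = opt$value, at_bound = at_bound, curve = curve)
  class(out) <- "dsc_fit"
  out
}

#' @export
print.dsc_fit <- function(x, ...) {
  cat("<dsc_fit>\n")
  print(x$estimates)
  cat(sprintf("RMS residual: %.4g kJ/mol/K%s\n", x$rms_residual,
              if (x$at_bound) " (parameter at search bound!)" else ""))
  invisible(x)
}

# locate local minima and intervening barriers on a discrete profile
profile_features <- function(n, F) {
  ok <- is.finite(F)
  idx <- which(ok)
  Fo <- F[idx]
  m <- length(Fo)
  is_min <- vapply(seq_len(m), function(k) {
    left <- if (k > 1) Fo[k] < Fo[k - 1] else TRUE
    right <- if (k < m) Fo[k] < Fo[k + 1] else TRUE
    left && right
  }, logical(1))
  mins <- idx[is_min]
  labels <- rep("I", length(mins))
  if (length(mins) > 0) {
    labels[which.min(n[mins])] <- "U"
    labels[which.max(n[mins])] <- "N"
  }
  barriers <- NULL
  if (length(mins) >= 2) {
    barriers <- vector("list", length(mins) - 1)
    for (k in seq_len(length(mins) - 1)) {
      lo <- mins[k]; hi <- mins[k + 1]
      between <- idx[idx > lo & idx < hi]
      if (length(between) == 0) next
      top <- between[which.max(F[between])]
      barriers[[k]] <- tibble(
        from_n = n[lo], to_n = n[hi], barrier_n = n[top],
        height_from_kJ = F[top] - F[lo], height_to_kJ = F[top] - F[hi])
    }
    barriers <- dplyr::bind_rows(barriers)
  }
  list(
    minima = tibble(n = n[mins], F_kJ = F[mins], label = labels),
    barriers = barriers %||% tibble(from_n = integer(), to_n = integer(),
                                    barrier_n = integer(),
                                    height_from_kJ = numeric(),
                                    height_to_kJ = numeric())
  )
}

#' One-dimensional free-energy profile
#'
#' Free energy as a function of the number of structured blocks, the natural
#' order parameter of the model: `F(n) = -RT log sum_m exp(-F_m/RT)` over
#' microstates with n folded blocks, shifted so the global minimum is zero.
#' Local minima are labelled U (fewest structured blocks), N (most) and I
#' (any in between); barriers are the maxima between adjacent minima.
#'
#' @param system A [wsme_system()].
#' @param T Evaluation temperature (K), default 310.
#' @return An `fe_profile` tibble with columns `n`, `F_kJ`, and attributes
#'   `minima`, `barriers`, `T`, `logZ`.
#' @export
free_energy_profile <- function(system, T = 310) {
  e <- wsme_state_energies(system, T)
  RT <- .R_GAS * T
  lse <- logsumexp_by(-e$F / RT, factor(e$n_folded, levels = 0:system$n_blocks))
  Fn <- -RT * lse
  n <- 0:system$n_blocks
  missing_bins <- !is.finite(Fn)
  shift <- min(Fn[!missing_bins])
  Fn <- (Fn - shift) / 1000
  out <- tibble(n = n, F_kJ = ifelse(missing_bins, NA_real_, Fn))
  feats <- profile_features(out$n, out$F_kJ)
  attr(out, "minima") <- feats$minima
  attr(out, "barriers") <- feats$barriers
  attr(out, "T") <- T
  attr(out, "logZ") <- logsumexp(-e$F / RT)
  class(out) <- c("fe_profile", class(out))
  out
}

#' Two-dimensional free-energy surface
#'
#' Free energy over (blocks folded in the N-terminal half, blocks folded in
#' the C-terminal half), the coordinate pair that exposes which half of the
#' domain structures first.
#'
#' @param system A [wsme_system()].
#' @param T Temperature (K).
#' @param split Last block counted in the N-terminal half (default half the
#'   blocks).
#' @return An `fe_surface` tibble with columns `n_nterm`, `n_cterm`, `F_kJ`
#'   (NA for unreachable bins) and attributes `T`, `split`, `logZ`.
#' @export
free_energy_surface <- function(system, T = 310, split = NULL) {
  nb <- system$n_blocks
  split <- split %||% (nb %/% 2L)
  if (split < 1 || split >= nb) abort("split must be in 1..(n_blocks - 1)")
  e <- wsme_state_energies(system, T)
  RT <- .R_GAS * T
  left <- state_n_folded_left(system$states, split)
  right <- system$n_folded - left
  key <- factor(paste(left, right),
                levels = as.vector(outer(0:split, 0:(nb - split),
                                         function(a, b) paste(a, b))))
  lse <- logsumexp_by(-e$F / RT, key)
  grid <- expand.grid(n_nterm = 0:split, n_cterm = 0:(nb - split))
  Fab <- -RT * lse[match(paste(grid$n_nterm, grid$n_cterm), names(lse))]
  shift <- min(Fab[is.finite(Fab)])
  out <- tibble(n_nterm = grid$n_nterm, n_cterm = grid$n_cterm,
                F_kJ = ifelse(is.finite(Fab), (Fab - shift) / 1000, NA_real_))
  attr(out, "T") <- T
  attr(out, "split") <- split
  attr(out, "logZ") <- logsumexp(-e$F / RT)
  class(out) <- c("fe_surface", class(out))
  out
}
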