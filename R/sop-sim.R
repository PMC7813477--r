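# Overdamped Langevin dynamics for the SOP model: thermal equilibration and
# constant-velocity pulling with a cantilever spring.

#' Pulling / dynamics configuration
#'
#' Defaults reproduce the study protocol where printed (35 pN/nm cantilever,
#' 2.5 um/s along the N-to-C vector, terminal beads as handles) and the
#' standard overdamped-integrator choices where not: friction `zeta` of 50
#' kcal mol^-1 ps A^-2 and a time step of 0.04 of the stiffest bond
#' relaxation time `zeta/k_FENE` (the FENE nonlinearity raises the
#' effective stiffness under load, so the margin is deliberate). Pulling at the experimental speed is an
#' opt-in long-running mode; analyses in this package run the same physics
#' at faster desk-scale speeds (see the vignette).
#'
#' @param k_spring_pN_nm Cantilever stiffness (pN/nm).
#' @param speed_um_s Anchor speed (um/s).
#' @param temperature Temperature (K).
#' @param zeta Friction coefficient (kcal mol^-1 ps A^-2).
#' @param dt Time step (ps); default 0.08 * zeta / k_fene.
#' @param k_fene FENE stiffness used for the default time step.
#' @return A `pulling_config` list; Angstrom/ps equivalents are precomputed
#'   (`k_spring` in kcal/mol/A^2, `speed` in A/ps).
#' @export
pulling_config <- function(k_spring_pN_nm = 35, speed_um_s = 2.5,
                           temperature = 300, zeta = 50, dt = NULL,
                           k_fene = 20) {
  dt <- dt %||% (0.04 * zeta / k_fene)
  cfg <- list(
    k_spring_pN_nm = k_spring_pN_nm,
    k_spring = k_spring_pN_nm / .KCAL_PER_A_IN_PN / 10,
    speed_um_s = speed_um_s,
    speed = speed_um_s * 1e-8,
    temperature = temperature, zeta = zeta, dt = dt)
  class(cfg) <- "pulling_config"
  cfg
}

new_pulling_trajectory <- function(raw, top, cfg, seed, pull, axis = NULL) {
  out <- tibble(
    time_ps = raw$time_ps,
    force_kcal = raw$force_kcal,
    force_pN = raw$force_kcal * .KCAL_PER_A_IN_PN,
    ext_nm = raw$e2e_A / 10)
  attr(out, "config") <- cfg
  attr(out, "seed") <- seed
  attr(out, "pull") <- pull
  attr(out, "axis") <- axis
  attr(out, "frames") <- raw$frames
  attr(out, "final") <- raw$final
  attr(out, "topology") <- top
  class(out) <- c("pulling_trajectory", class(out))
  out
}

#' Constant-velocity pulling simulation
#'
#' Overdamped Langevin dynamics with the N-terminal bead fixed and a
#' cantilever spring on the C-terminal bead whose anchor moves at constant
#' speed along the native N-to-C vector. The recorded cantilever force is
#' `k_spring * (anchor displacement - pulled-bead displacement)` projected
#' on the pulling axis. Trajectories are bit-reproducible for a given seed.
#'
#' @param top A `sop_topology`.
#' @param config A [pulling_config()]; set `speed_um_s` large (e.g. 1e5 or
#'   more) for desk-scale runs.
#' @param n_steps Number of integration steps.
#' @param seed Integer seed for the thermal noise.
#' @param start Starting coordinates (default: minimized native
#'   coordinates; pass [equilibrate()] output for thermalized starts, or
#'   `start = top$coords` to skip preparation).
#' @param stride_sample Force-sampling stride (steps).
#' @param stride_frames Coordinate-frame stride (0 = do not store frames).
#' @return A `pulling_trajectory` tibble (`time_ps`, `force_kcal`,
#'   `force_pN`, `ext_nm`) with the configuration, seed, frames and final
#'   coordinates as attributes.
#' @export
run_pulling <- function(top, config = pulling_config(), n_steps = 1e5,
                        seed = 1, start = NULL, stride_sample = 10L,
                        stride_frames = 0L) {
  start <- start %||% sop_minimize(top)
  n <- top$n_beads
  axis <- start[n, ] - start[1, ]
  axis <- axis / sqrt(sum(axis^2))
  sim <- list(n_steps = n_steps, dt = config$dt, zeta = config$zeta,
              temperature = config$temperature, seed = seed,
              stride_sample = as.integer(stride_sample),
              stride_frames = as.integer(stride_frames),
              pull = TRUE, k_spring = config$k_spring, speed = config$speed,
              fixed_bead = 1L, pulled_bead = n, axis = axis)
  raw <- .sop_run(start, top$native$i, top$native$j, top$native$r0,
                  cpp_params(top), sim)
  new_pulling_trajectory(raw, top, config, seed, pull = TRUE, axis = axis)
}

#' Free (unpulled) Langevin dynamics
#'
#' @inheritParams run_pulling
#' @return A `pulling_trajectory` (force column zero) whose `final`
#'   attribute holds the end coordinates.
#' @export
run_dynamics <- function(top, config = pulling_config(), n_steps = 1e5,
                         seed = 1, start = NULL, stride_sample = 100L,
                         stride_frames = 0L) {
  start <- start %||% top$coords
  sim <- list(n_steps = n_steps, dt = config$dt, zeta = config$zeta,
              temperature = config$temperature, seed = seed,
              stride_sample = as.integer(stride_sample),
              stride_frames = as.integer(stride_frames),
              pull = FALSE)
  raw <- .sop_run(start, top$native$i, top$native$j, top$native$r0,
                  cpp_params(top), sim)
  new_pulling_trajectory(raw, top, config, seed, pull = FALSE)
}

#' Thermal equilibration ensemble
#'
#' Runs independent thermal simulations from the native state with distinct
#' derived seeds and returns the end coordinates, flagging any replica whose
#' native-contact fraction dropped below 0.8 (partial unfolding during
#' equilibration).
#'
#' @param top A `sop_topology`.
#' @param config A [pulling_config()] (its pulling fields are ignored).
#' @param n_replicas Number of independent runs.
#' @param n_steps Steps per run.
#' @param seed Base seed; replica k uses a seed derived from (seed, k).
#' @return A list with `coords` (list of end-coordinate matrices),
#'   `summary` (tibble: replica, seed, q_native, flagged) and `ok` (indices
#'   of unflagged replicas).
#' @export
equilibrate <- function(top, config = pulling_config(), n_replicas = 10,
                        n_steps = 2e4, seed = 1) {
  start <- sop_minimize(top)
  res <- purrr::map(seq_len(n_replicas), function(k) {
    sk <- derive_seed(seed, paste0("equil", k))
    tr <- run_dynamics(top, config, n_steps, seed = sk, start = start,
                       stride_sample = max(1L, as.integer(n_steps)))
    list(coords = attr(tr, "final"), seed = sk,
         q = native_fraction(top, attr(tr, "final")))
  })
  q <- purrr::map_dbl(res, "q")
  flagged <- q < 0.8
  if (any(flagged)) {
    warn(sprintf("%d replica(s) lost >20%% of native contacts during equilibration",
                 sum(flagged)))
  }
  list(coords = purrr::map(res, "coords"),
       summary = tibble(replica = seq_len(n_replicas),
                        seed = purrr::map_dbl(res, "seed"),
                        q_native = q, flagged = flagged),
       ok = which(!flagged))
}
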