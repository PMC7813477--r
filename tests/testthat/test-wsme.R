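# Block WSME model: state space, energetics, thermodynamic observables.

test_that("block partition tiles the chain; 102 residues give 34 blocks", {
  p <- block_partition(102, 3)
  expect_equal(nrow(p), 34L)
  expect_equal(p$first[1], 1L)
  expect_equal(p$last[34], 102L)
  expect_true(all(p$first[-1] == p$last[-34] + 1L))
  # trailing partial block
  p2 <- block_partition(10, 3)
  expect_equal(nrow(p2), 4L)
  expect_equal(p2$last[4] - p2$first[4] + 1L, 1L)
})

test_that("microstate counts match the closed form and the printed values", {
  expect_equal(nrow(enumerate_microstates(1)), 2L)
  expect_equal(nrow(enumerate_microstates(3)), 9L)
  for (n in 1:12) {
    expect_equal(nrow(enumerate_microstates(n)), count_microstates(n))
    expect_equal(count_microstates(n), length(oracle_enumerate(n)))
  }
  expect_equal(count_microstates(34), 105316)
  expect_equal(count_microstates(102), 8847804)
  expect_error(enumerate_microstates(151), "refused")
})

test_that("enumerated states are valid and unique", {
  st <- enumerate_microstates(6)
  # islands ordered, disjoint, separated by >= 1 unfolded block
  two <- !is.na(st$a2)
  expect_true(all(st$b1[two] + 1L < st$a2[two]))
  expect_true(all(st$a1[!is.na(st$a1)] <= st$b1[!is.na(st$a1)]))
  key <- paste(st$a1, st$b1, st$a2, st$b2, st$w)
  expect_equal(anyDuplicated(key), 0L)
  # w only meaningful (and duplicated) for two-island states
  expect_true(all(!st$w[!two]))
})

test_that("the all-unfolded state has exactly zero free energy and enthalpy", {
  tw <- toy_wsme()
  e <- microstate_free_energy(list(a1 = NA, b1 = NA, a2 = NA, b2 = NA, w = FALSE),
                              tw$cmap, tw$ss, wsme_parameters(), T = 310)
  expect_identical(unname(e["F"]), 0)
  expect_identical(unname(e["H"]), 0)
})

test_that("a fully folded 2-block toy matches hand algebra at T_ref", {
  # 6 coil residues, one uncharged atomic contact between blocks
  cm <- tibble::tibble(i = 2L, j = 5L, r0 = 6.0, n_atomic = 1L)
  cm <- cdhfold:::new_contact_map(cm, "wsme", 6L, charges = rep(0, 6))
  ss <- tibble::tibble(resno = 1:6, resname = "ALA", class = "coil_or_glycine")
  p <- wsme_parameters()
  e <- microstate_free_energy(list(a1 = 1, b1 = 2, a2 = NA, b2 = NA, w = FALSE),
                              cm, ss, p, T = p$T_ref)
  # at T = T_ref the solvation term vanishes: F = xi - T * 6 * dS_coil
  expect_equal(unname(e["F"]), p$xi - p$T_ref * 6 * p$dS_coil_gly,
               tolerance = 1e-12)
  expect_equal(unname(e["H"]), p$xi, tolerance = 1e-12)
})

test_that("folding a proline contributes zero conformational entropy", {
  cm <- tibble::tibble(i = 1L, j = 3L, r0 = 5.0, n_atomic = 2L)
  cm <- cdhfold:::new_contact_map(cm, "wsme", 3L, charges = rep(0, 3))
  ss_pro <- tibble::tibble(resno = 1:3, resname = "PRO", class = "proline")
  ss_coil <- tibble::tibble(resno = 1:3, resname = "ALA",
                            class = "coil_or_glycine")
  p <- wsme_parameters()
  st <- list(a1 = 1, b1 = 1, a2 = NA, b2 = NA, w = FALSE)
  e_pro <- microstate_free_energy(st, cm, ss_pro, p, T = p$T_ref,
                                  block_size = 3L)
  e_coil <- microstate_free_energy(st, cm, ss_coil, p, T = p$T_ref,
                                   block_size = 3L)
  expect_equal(unname(e_coil["F"] - e_pro["F"]),
               -p$T_ref * 3 * p$dS_coil_gly, tolerance = 1e-9)
})

test_that("cross-island contacts are licensed only when w is on", {
  # contact between residues in blocks 1 and 3 (islands [1,1] and [3,3])
  cm <- tibble::tibble(i = 1L, j = 9L, r0 = 6.0, n_atomic = 5L)
  cm <- cdhfold:::new_contact_map(cm, "wsme", 9L, charges = rep(0, 9))
  ss <- tibble::tibble(resno = 1:9, resname = "ALA", class = "coil_or_glycine")
  p <- wsme_parameters()
  off <- microstate_free_energy(list(a1 = 1, b1 = 1, a2 = 3, b2 = 3, w = FALSE),
                                cm, ss, p, T = p$T_ref)
  on <- microstate_free_energy(list(a1 = 1, b1 = 1, a2 = 3, b2 = 3, w = TRUE),
                               cm, ss, p, T = p$T_ref)
  expect_equal(unname(on["F"] - off["F"]), 5 * p$xi, tolerance = 1e-9)
})

test_that("partition function matches the two-state closed form and is stable", {
  F <- c(0, 4200)
  for (T in c(250, 310, 400)) {
    pf <- partition_function(F, T)
    expect_equal(sum(pf$p), 1, tolerance = 1e-12)
    expect_equal(pf$p[2], 1 / (1 + exp(4200 / (8.31446261815324 * T))),
                 tolerance = 1e-12)
  }
  # gauge invariance and log-space stability at extreme energies
  pf1 <- partition_function(c(0, 5e5, 1e6), 250)
  pf2 <- partition_function(c(0, 5e5, 1e6) + 3e5, 250)
  expect_equal(pf1$p, pf2$p, tolerance = 1e-12)
  expect_true(all(is.finite(pf1$p)))
})

test_that("engine free energies and Z match exhaustive enumeration", {
  tw <- toy_wsme()   # 24 residues -> 8 blocks
  params <- wsme_parameters()
  sys <- wsme_system(tw$cmap, tw$ss, params)
  for (T in c(290, 340)) {
    e <- cdhfold:::wsme_state_energies(sys, T)
    pf <- partition_function(e$F, T)
    orc <- oracle_Z(tw$cmap, tw$ss, params, T, 3L)
    expect_equal(nrow(sys$states), orc$n_states)
    expect_equal(pf$Z, orc$Z, tolerance = 1e-10)
    # 1D profile bin weights agree with oracle bin sums (up to the shift)
    prof <- free_energy_profile(sys, T)
    RT <- 8.31446261815324 * T
    ok <- !is.na(prof$F_kJ)
    wts <- exp(-prof$F_kJ[ok] * 1000 / RT)
    orc_bins <- orc$bins[as.character(prof$n[ok])]
    expect_equal(unname(wts / sum(wts)),
                 as.numeric(orc_bins) / sum(orc_bins), tolerance = 1e-10)
  }
})

test_that("profile and surface bins conserve the partition function", {
  tw <- toy_wsme()
  sys <- wsme_system(tw$cmap, tw$ss, wsme_parameters())
  T <- 320; RT <- 8.31446261815324 * T
  e <- cdhfold:::wsme_state_energies(sys, T)
  logZ <- partition_function(e$F, T)$logZ
  prof <- free_energy_profile(sys, T)
  expect_equal(attr(prof, "logZ"), logZ, tolerance = 1e-12)
  # sum over profile bins of exp(-F/RT) recovers Z up to the global shift
  ok <- !is.na(prof$F_kJ)
  shift <- logZ - log(sum(exp(-prof$F_kJ[ok] * 1000 / RT)))
  surf <- free_energy_surface(sys, T, split = 4L)
  ok2 <- !is.na(surf$F_kJ)
  shift2 <- logZ - log(sum(exp(-surf$F_kJ[ok2] * 1000 / RT)))
  expect_equal(shift, shift2, tolerance = 1e-10)
  # marginals of the surface match the profile
  marg <- tapply(exp(-surf$F_kJ[ok2] * 1000 / RT),
                 (surf$n_nterm + surf$n_cterm)[ok2], sum)
  pr <- exp(-prof$F_kJ[ok] * 1000 / RT)
  names(pr) <- prof$n[ok]
  expect_equal(as.numeric(marg[names(pr)]), as.numeric(pr), tolerance = 1e-10)
})

test_that("populations obey detailed balance with respect to F", {
  tw <- toy_wsme()
  sys <- wsme_system(tw$cmap, tw$ss, wsme_parameters())
  T <- 310
  e <- cdhfold:::wsme_state_energies(sys, T)
  pf <- partition_function(e$F, T)
  i <- c(2, 10, 50); j <- c(5, 200, 3)
  expect_equal(pf$p[i] / pf$p[j],
               exp(-(e$F[i] - e$F[j]) / (8.31446261815324 * T)),
               tolerance = 1e-12)
})

test_that("heat capacity behaves like the two-state oracle on a 1-block system", {
  # single block, one contact: closed-form two-state system
  cm <- tibble::tibble(i = 1L, j = 3L, r0 = 5.0, n_atomic = 400L)
  cm <- cdhfold:::new_contact_map(cm, "wsme", 3L, charges = rep(0, 3))
  ss <- tibble::tibble(resno = 1:3, resname = "ALA", class = "coil_or_glycine")
  params <- wsme_parameters(dCp_cont = 0)
  sys <- wsme_system(cm, ss, params)
  expect_equal(nrow(sys$states), 2L)
  Tg <- seq(280, 380, 0.25)
  cp <- heat_capacity_curve(sys, Tg)
  # closed-form two-state heat capacity:
  # dG_fold(T) = n*xi - T*sum(dS); Cp = (n*xi)^2/(R T^2) p (1 - p)
  R <- 8.31446261815324
  dG <- 400 * params$xi - Tg * 3 * params$dS_coil_gly
  p_f <- 1 / (1 + exp(dG / (R * Tg)))
  cp_closed <- (400 * params$xi)^2 / (R * Tg^2) * p_f * (1 - p_f) / 1000
  expect_equal(cp$Cp_kJ[5:397], cp_closed[5:397], tolerance = 1e-4)
  expect_lt(abs(attr(cp, "Tm") - Tg[which.max(cp_closed)]), 0.5)
  # flat when interactions and entropies vanish
  sys0 <- wsme_system(cm, ss, wsme_parameters(xi = 0, dS_strand_helix = 0,
                                              dS_coil_gly = 0, dCp_cont = 0))
  cp0 <- heat_capacity_curve(sys0, Tg)
  expect_lt(max(abs(cp0$Cp_kJ)), 1e-10)
  # deepening xi raises Tm
  sys2 <- wsme_system(cm, ss, wsme_parameters(xi = params$xi * 1.1,
                                              dCp_cont = 0))
  expect_gt(attr(heat_capacity_curve(sys2, Tg), "Tm"), attr(cp, "Tm"))
  expect_error(heat_capacity_curve(sys, rev(Tg)), "increasing")
})

test_that("barrier heights are invariant to the global free-energy shift", {
  tw <- toy_wsme()
  sys <- wsme_system(tw$cmap, tw$ss, wsme_parameters())
  prof <- free_energy_profile(sys, 330)
  bars <- attr(prof, "barriers")
  # recompute features after adding a constant: heights unchanged
  shifted <- prof
  shifted$F_kJ <- shifted$F_kJ + 12.34
  f2 <- cdhfold:::profile_features(shifted$n, shifted$F_kJ)
  if (nrow(bars) > 0) {
    expect_equal(f2$barriers$height_from_kJ, bars$height_from_kJ,
                 tolerance = 1e-12)
  }
  expect_error(cdhfold:::wsme_state_energies(sys, -5), "> 0")
})

test_that("refitting a synthetic thermogram recovers the generating entropy", {
  cm <- synth_contact_map(60, "wt", seed = 4)
  ss <- attr(cm, "ss")
  truth <- wsme_parameters()
  sys <- wsme_system(cm, ss, truth)
  Tg <- seq(290, 380, 0.5)
  th <- make_thermogram("from_bwsme", T_grid = Tg, system = sys,
                        noise = 0.01, seed = 9)
  start <- wsme_parameters(dS_strand_helix = -18)   # ~8% off
  fit <- fit_dsc(th, cm, ss, free = "dS_strand_helix", fixed = start,
                 baseline = "none", grid_n = 5)
  expect_lt(abs(fit$estimates$estimate - truth$dS_strand_helix) /
              abs(truth$dS_strand_helix), 0.05)
  expect_false(fit$at_bound)
})

test_that("fit_dsc with no free parameters returns the fixed set and residual", {
  tw <- toy_wsme()
  sys <- wsme_system(tw$cmap, tw$ss, wsme_parameters())
  Tg <- seq(300, 360, 0.5)
  th <- make_thermogram("from_bwsme", T_grid = Tg, system = sys, noise = 0,
                        seed = 2)
  fit <- fit_dsc(th, tw$cmap, tw$ss, free = character(0),
                 fixed = wsme_parameters(), baseline = "none")
  expect_equal(nrow(fit$estimates), 0L)
  expect_lt(fit$rms_residual, 1e-10)
  expect_error(fit_dsc(th, tw$cmap, tw$ss, free = "T_ref"), "must be among")
})
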