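# SOP coarse-grained model: topology, energetics, dynamics, rupture and
# pathway analysis.

test_that("topology construction mirrors the contact map and guards breaks", {
  two <- cdhfold:::new_cdh_structure(tibble::tibble(
    atom = "CA", element = "C", resno = 1:2, resname = "ALA", chain = "A",
    x = c(0, 3.8), y = 0, z = 0))
  cm2 <- suppressWarnings(native_contacts_sop(two))
  top2 <- build_sop_topology(two, cm2)
  expect_length(top2$bond_r0, 1L)
  expect_equal(nrow(top2$native), 0L)
  s <- hairpin16()
  cm <- native_contacts_sop(s)
  top <- hairpin_top()
  expect_equal(nrow(top$native), nrow(cm))
  broken <- cdhfold:::new_cdh_structure(tibble::tibble(
    atom = "CA", element = "C", resno = 1:5, resname = "ALA", chain = "A",
    x = c(0, 3.8, 7.6, 14, 17.8), y = 0, z = 0))
  expect_error(build_sop_topology(broken, suppressWarnings(native_contacts_sop(broken))),
               "chain break")
  expect_error(build_sop_topology(s, native_contacts_wsme(s)), "sop-flavor")
})

test_that("native-state energies take their analytic values", {
  top <- hairpin_top()
  pe <- potential_energy(top)
  expect_equal(pe$V_fene, 0, tolerance = 1e-12)
  expect_equal(pe$V_att, -top$params$eh * nrow(top$native), tolerance = 1e-10)
  expect_gt(pe$V_rep, 0)
  # isolated native pair exactly at r0: attractive term is -eh
  pair <- cdhfold:::new_cdh_structure(tibble::tibble(
    atom = "CA", element = "C", resno = 1:4, resname = "GLY", chain = "A",
    x = c(0, 3, 4.5, 4.5), y = c(0, 1.5, 1.2, -2.3), z = 0))
  cmp <- tibble::tibble(i = 1L, j = 4L,
                        r0 = sqrt(sum((c(4.5, -2.3, 0))^2)))
  cmp <- cdhfold:::new_contact_map(cmp, "sop", 4L)
  topp <- build_sop_topology(pair, cmp, sop_parameters(el = 0))
  expect_equal(potential_energy(topp)$V_att, -1.5, tolerance = 1e-12)
  # FENE blows up informatively beyond R0
  stretched <- topp$coords
  stretched[1, ] <- stretched[1, ] - c(2.5, 0, 0)
  expect_error(potential_energy(topp, stretched), "FENE")
})

test_that("analytic forces match the numerical gradient", {
  top <- hairpin_top()
  set.seed(3)
  x <- top$coords + matrix(rnorm(3 * top$n_beads, 0, 0.05), ncol = 3)
  f_an <- potential_energy(top, x, forces = TRUE)$forces
  h <- 1e-6
  num <- matrix(0, top$n_beads, 3)
  for (i in seq_len(top$n_beads)) for (d in 1:3) {
    xp <- x; xp[i, d] <- xp[i, d] + h
    xm <- x; xm[i, d] <- xm[i, d] - h
    num[i, d] <- -(potential_energy(top, xp)$V_total -
                     potential_energy(top, xm)$V_total) / (2 * h)
  }
  expect_lt(max(abs(num - f_an)) / max(abs(f_an)), 1e-5)
})

test_that("zero-temperature, zero-speed dynamics is mechanically quiet", {
  top <- hairpin_top()
  xm <- hairpin_min()
  expect_lt(max(abs(potential_energy(top, xm, forces = TRUE)$forces)), 1e-5)
  cfg <- pulling_config(speed_um_s = 0, temperature = 0)
  tr <- run_pulling(top, cfg, n_steps = 1e6, seed = 1, start = xm,
                    stride_sample = 10000)
  expect_lt(max(abs(tr$force_pN)), 1e-6)
  expect_lt(max(abs(attr(tr, "final") - xm)), 1e-3)
})

test_that("trajectories are bit-identical for identical seeds", {
  top <- hairpin_top()
  cfg <- pulling_config(speed_um_s = 1e5, temperature = 300)
  a <- run_pulling(top, cfg, n_steps = 2e4, seed = 99, start = hairpin_min())
  b <- run_pulling(top, cfg, n_steps = 2e4, seed = 99, start = hairpin_min())
  c <- run_pulling(top, cfg, n_steps = 2e4, seed = 100, start = hairpin_min())
  expect_identical(a$force_kcal, b$force_kcal)
  expect_identical(attr(a, "final"), attr(b, "final"))
  expect_false(identical(a$force_kcal, c$force_kcal))
})

test_that("equilibration returns distinct, mostly native replicas", {
  top <- hairpin_top()
  cfg0 <- pulling_config(temperature = 0)
  eq0 <- equilibrate(top, cfg0, n_replicas = 2, n_steps = 1000, seed = 1)
  expect_lt(max(abs(eq0$coords[[1]] - hairpin_min())), 1e-3)
  cfg <- pulling_config(temperature = 300)
  eq <- suppressWarnings(
    equilibrate(top, cfg, n_replicas = 5, n_steps = 5000, seed = 1))
  expect_equal(nrow(eq$summary), 5L)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_gt(max(abs(eq$coords[[i]] - eq$coords[[j]])), 0)
  }
  expect_true(all(eq$summary$q_native[eq$ok] >= 0.8))
})

test_that("equilibrium native-contact fraction is consistent with a long run", {
  top <- hairpin_top()
  cfg <- pulling_config(temperature = 300)
  eq <- equilibrate(top, cfg, n_replicas = 8, n_steps = 4000, seed = 3)
  q_ens <- mean(eq$summary$q_native)
  long <- run_dynamics(top, cfg, n_steps = 8000 * 8, seed = 77,
                       start = hairpin_min(), stride_frames = 4000L)
  q_long <- mean(vapply(attr(long, "frames")[-1], function(fr)
    cdhfold:::native_fraction(top, fr), numeric(1)))
  expect_lt(abs(q_ens - q_long), 0.1)
})

test_that("rupture detection finds planted sawtooth peaks and nothing in noise", {
  set.seed(5)
  n <- 3000
  x <- seq(0, 30, length.out = n)
  apex <- c(8, 16, 24)
  F <- numeric(n)
  seg_start <- 0
  for (a in apex) {
    sel <- x > seg_start & x <= a
    # convex rising edge, as in a worm-like-chain sawtooth
    F[sel] <- 150 * ((x[sel] - seg_start) / (a - seg_start))^4
    seg_start <- a
  }
  F <- F + rnorm(n, 0, 4)
  tr <- tibble::tibble(ext_nm = x, F_pN = F)
  ev <- detect_ruptures(tr, window = 51)
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$ext_nm, apex, tolerance = 0.05)
  flat <- tibble::tibble(ext_nm = x, F_pN = rnorm(n, 0, 4))
  expect_equal(nrow(detect_ruptures(flat)), 0L)
  expect_error(detect_ruptures(tr[1:500, ]), "1000")
})

test_that("rupture detection equals the brute-force scan at the same thresholds", {
  top <- hairpin_top()
  cfg <- pulling_config(speed_um_s = 4e4, temperature = 300,
                        k_spring_pN_nm = 200)
  tr <- run_pulling(top, cfg, n_steps = 6e5, seed = 12, start = hairpin_min(),
                    stride_sample = 50)
  ev <- detect_ruptures(tr, window = 151, n_mad = 1.5)
  fs <- as.numeric(signal::sgolayfilt(tr$force_pN, p = 3, n = 151))
  expect_equal(ev$idx, oracle_rupture_scan(tr$force_pN, fs, 1.5, 0.3))
})

test_that("rupture forces increase with pulling speed", {
  top <- hairpin_top()
  speeds <- c(3e4, 1e5, 3e5)
  res <- tidyr::expand_grid(speed = speeds, seed = 1:3)
  peak <- purrr::pmap_dbl(res, function(speed, seed) {
    cfg <- pulling_config(speed_um_s = speed, temperature = 300)
    nst <- round(45 / (cfg$speed * cfg$dt))
    tr <- run_pulling(top, cfg, n_steps = nst, seed = seed,
                      start = hairpin_min(),
                      stride_sample = max(1L, nst %/% 8000L))
    fs <- signal::sgolayfilt(tr$force_pN, p = 3, n = 151)
    max(fs)
  })
  rho <- cor(res$speed, peak, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("contour-length gains recover planted worm-like-chain truth", {
  tr <- make_wlc_trace(contour_nm = c(20, 30.9, 44.57),
                       rupture_pN = c(180, 260), noise = 0.01, seed = 2)
  ev <- detect_ruptures(tr, window = 51, n_mad = 1)
  expect_gte(nrow(ev), 2L)
  ev <- ev[1:2, ]
  gains <- contour_length_gain(tr, ev, persistence_nm = 0.4)
  expect_equal(gains$dLc_nm, c(10.90, 13.67), tolerance = 0.1 / 10.9)
  # pulling-speed (sampling-density) invariance of the geometry
  tr2 <- make_wlc_trace(contour_nm = c(20, 30.9, 44.57),
                        rupture_pN = c(180, 260), n = 1500, noise = 0.01,
                        seed = 5)
  ev2 <- detect_ruptures(tr2, window = 51, n_mad = 1)[1:2, ]
  gains2 <- contour_length_gain(tr2, ev2, persistence_nm = 0.4)
  expect_equal(gains2$dLc_nm, gains$dLc_nm, tolerance = 0.05)
  # single-event trace has no successor gain (WLC needs a next edge);
  single <- make_wlc_trace(contour_nm = 20, rupture_pN = numeric(0),
                           n = 1200, seed = 3)
  expect_equal(nrow(detect_ruptures(single, n_mad = 1)), 0L)
  # raw method: peak-to-peak extension differences
  raw <- contour_length_gain(tr, ev, method = "raw")
  expect_equal(raw$dLc_nm[1], diff(ev$ext_nm)[1], tolerance = 1e-12)
})

test_that("pathway classification reproduces the printed cluster centers", {
  ev <- tibble::tibble(F_kcal = c(3.75, 2.41), dLc_nm = c(13.67, 10.90))
  out <- classify_pathway(ev)
  expect_equal(as.character(out$pathway),
               c("high_force_shearing", "low_force_unzipping"))
  # exact standardized midpoint ties to the low-force pathway
  mid <- tibble::tibble(F_kcal = mean(c(3.75, 2.41)),
                        dLc_nm = mean(c(13.67, 10.90)))
  expect_equal(as.character(classify_pathway(mid)$pathway),
               "low_force_unzipping")
  # missing gain stays unclassified
  na_ev <- tibble::tibble(F_kcal = 3, dLc_nm = NA_real_)
  expect_true(is.na(classify_pathway(na_ev)$pathway))
  # 2-means refit on well-separated synthetic clusters
  set.seed(8)
  clus <- tibble::tibble(
    F_kcal = c(rnorm(20, 2.4, 0.05), rnorm(20, 3.8, 0.05)),
    dLc_nm = c(rnorm(20, 10.9, 0.2), rnorm(20, 13.7, 0.2)))
  ref <- classify_pathway(clus, refit = TRUE)
  expect_equal(as.character(ref$pathway),
               rep(c("low_force_unzipping", "high_force_shearing"), each = 20))
})

test_that("contact-map evolution tracks native contacts and break order", {
  top <- hairpin_top()
  n <- top$n_beads
  native <- top$coords
  extended <- cbind(3.95 * (seq_len(n) - 1), 0, 0)
  # synthetic monotone stretch: linear interpolation native -> extended
  frames <- purrr::map(seq(0, 1, length.out = 21), function(a) {
    (1 - a) * native + a * extended
  })
  traj <- tibble::tibble(time_ps = 0, force_kcal = 0, force_pN = 0,
                         ext_nm = 0)
  attr(traj, "frames") <- frames
  evo <- contact_map_evolution(traj, top)
  expect_equal(evo$fraction$q[1], 1)
  expect_equal(evo$fraction$q[21], 0)
  expect_true(all(diff(evo$fraction$q) <= 1e-12))
  # break order equals brute-force recomputation
  brute_last <- integer(nrow(top$native))
  for (k in seq_len(nrow(top$native))) {
    i <- top$native$i[k]; j <- top$native$j[k]
    present <- vapply(frames, function(fr)
      sqrt(sum((fr[i, ] - fr[j, ])^2)) < 1.25 * top$native$r0[k], logical(1))
    brute_last[k] <- max(which(present))
  }
  expect_equal(evo$per_pair$last_frame, brute_last)
})
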