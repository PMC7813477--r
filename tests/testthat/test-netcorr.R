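# Dihedral circular correlations and hydrogen-bond persistence networks.

test_that("backbone dihedrals hit canonical values and wrap cleanly", {
  helix <- make_toy_structure("helix", 12)
  traj <- list(structure = helix,
               coords = list(as.matrix(helix[, c("x", "y", "z")])))
  X <- compute_dihedrals(traj)
  map <- attr(X, "mapping")
  interior <- map$resno %in% 3:10
  phis <- X[1, interior & map$angle == "phi"] * 180 / pi
  psis <- X[1, interior & map$angle == "psi"] * 180 / pi
  expect_true(all(abs(phis - (-57)) < 1))
  expect_true(all(abs(psis - (-47)) < 1))
  # planar all-trans zigzag: torsions at the +-180 wrap point
  zig <- build_peptide(180, 180, n = 8, resnames = "GLY")
  Xz <- compute_dihedrals(list(structure = zig,
                               coords = list(as.matrix(zig[, c("x", "y", "z")]))))
  expect_true(all(abs(abs(Xz[1, ]) * 180 / pi - 180) < 1e-6 |
                    abs(Xz[1, ]) < 1e-6))
  expect_true(all(Xz[1, ] > -pi & Xz[1, ] <= pi))
})

test_that("dihedral extraction matches the bio3d torsion reference", {
  skip_if_not_installed("bio3d")
  s <- make_toy_structure("hairpin", 16)
  set.seed(10)
  frames <- purrr::map(1:5, function(i) {
    as.matrix(s[, c("x", "y", "z")]) + matrix(rnorm(nrow(s) * 3, 0, 0.15),
                                              ncol = 3)
  })
  X <- compute_dihedrals(list(structure = s, coords = frames))
  map <- attr(X, "mapping")
  for (f in 1:5) {
    s2 <- s
    s2$x <- frames[[f]][, 1]; s2$y <- frames[[f]][, 2]; s2$z <- frames[[f]][, 3]
    tmp <- withr::local_tempfile(fileext = ".pdb")
    write_structure(s2, tmp)
    tt <- bio3d::torsion.pdb(bio3d::read.pdb(tmp))
    ours_phi <- X[f, map$angle == "phi"] * 180 / pi
    ref_phi <- tt$phi[!is.na(tt$phi)]
    expect_equal(unname(ours_phi), unname(ref_phi), tolerance = 1e-3)
    ours_psi <- X[f, map$angle == "psi"] * 180 / pi
    ref_psi <- tt$psi[!is.na(tt$psi)]
    expect_equal(unname(ours_psi), unname(ref_psi), tolerance = 1e-3)
  }
})

test_that("circular correlation identities hold", {
  set.seed(2)
  x <- cdhfold:::rvonmises(2000, 0.4, 1.2)
  expect_equal(circular_correlation(x, x), 1, tolerance = 1e-12)
  expect_equal(circular_correlation(x, -x), -1, tolerance = 1e-12)
  # invariance under rigid rotation of either series
  expect_equal(circular_correlation(x, cdhfold:::wrap_angle(x + 2.1)), 1,
               tolerance = 1e-9)
  y <- cdhfold:::wrap_angle(x + cdhfold:::rvonmises(2000, 0, 3))
  r1 <- circular_correlation(x, y)
  r2 <- circular_correlation(cdhfold:::wrap_angle(x - 1.3), y)
  expect_equal(r1, r2, tolerance = 1e-9)
  expect_error(circular_correlation(x[1:10], x[1:10] * 0), "30")
  expect_warning(r0 <- circular_correlation(x, rep(0.5, 2000)), "degenerate")
  expect_true(is.na(r0))
})

test_that("vectorized coefficient equals the loop oracle and the sin-Pearson identity", {
  set.seed(6)
  x <- cdhfold:::rvonmises(500, 0, 0.5)
  y <- cdhfold:::wrap_angle(x + cdhfold:::rvonmises(500, 0, 2))
  r <- circular_correlation(x, y)
  expect_equal(r, oracle_circ_corr(x, y), tolerance = 1e-12)
  # identity with Pearson correlation of the sin-centered series
  cm <- function(v) atan2(mean(sin(v)), mean(cos(v)))
  expect_equal(r, cor(sin(x - cm(x)), sin(y - cm(y))), tolerance = 1e-12)
})

test_that("planted dependence reaches its calibrated strength", {
  X <- make_dihedral_series(2, 10000, pairs = tibble::tibble(
    i = 1L, j = 2L, strength = 0.8), seed = 4)
  r <- circular_correlation(X[, 1], X[, 2])
  expect_lt(abs(r - 0.8), 0.05)
})

test_that("correlation maps retain planted pairs and reject nulls", {
  # planted pair among independents is the only retention
  X <- make_dihedral_series(50, 5000,
                            pairs = tibble::tibble(i = 7L, j = 31L,
                                                   strength = 0.8),
                            seed = 3)
  cm <- correlation_map(X)
  expect_equal(cm$z_threshold, 2.5)
  expect_equal(nrow(cm$pairs), 1L)
  expect_equal(c(cm$pairs$i, cm$pairs$j), c(7L, 31L))
  expect_gt(cm$pairs$r, 0.6)
  # matrix structure
  expect_true(isSymmetric(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 50))
  expect_true(all(abs(cm$r) <= 1 + 1e-12))
  # null maps stay empty in nearly all seeds
  fp <- vapply(1:25, function(s) {
    nrow(correlation_map(make_dihedral_series(20, 5000, kappa_base = 0,
                                              seed = s))$pairs)
  }, integer(1))
  expect_lte(sum(fp) / (25 * 190), 0.015)
  expect_error(correlation_map(X[, 1, drop = FALSE]), "at least 2")
})

test_that("differential maps are antisymmetric and expose planted weakening", {
  Xa <- make_dihedral_series(12, 4000,
                             pairs = tibble::tibble(i = c(2L, 5L), j = c(9L, 11L),
                                                    strength = c(0.8, 0.7)),
                             seed = 5)
  Xb <- make_dihedral_series(12, 4000,
                             pairs = tibble::tibble(i = 2L, j = 9L,
                                                    strength = 0.8),
                             seed = 5)
  ma <- correlation_map(Xa); mb <- correlation_map(Xb)
  expect_equal(differential_map(ma, ma), matrix(0, 12, 12),
               ignore_attr = TRUE)
  d <- differential_map(ma, mb)
  expect_equal(d, -differential_map(mb, ma), tolerance = 1e-12)
  # the pair weakened in b shows up positive in a - b
  expect_gt(d[5, 11], 0.3)
  expect_lt(abs(d[2, 9]), 0.2)
  expect_error(differential_map(ma, correlation_map(Xa[, 1:5])), "dimensions")
})

test_that("hydrogen bonds are detected by geometry", {
  # ideal N-H...O=C at 2.9 A, 180 degrees
  atoms <- tibble::tibble(
    atom = c("N", "CA", "C", "O", "H", "CA", "N", "C", "O"),
    element = c("N", "C", "C", "O", "H", "C", "N", "C", "O"),
    resno = c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L),
    resname = "ALA", chain = "A",
    x = c(0, -1.4, -2.1, -2.0, 0.95, 4.7, 5.2, 4.2, 2.85),
    y = c(0, 0.6, -0.5, -1.7, 0, 1.5, 2.7, 0.5, 0.4),
    z = 0)
  s <- cdhfold:::new_cdh_structure(atoms)
  traj <- list(structure = s, coords = list(as.matrix(atoms[, c("x", "y", "z")])))
  ev <- detect_hbonds(traj)
  expect_true(any(ev$donor == 1 & ev$acceptor == 2))
  far <- atoms
  far$x[far$resno == 2] <- far$x[far$resno == 2] + 5
  trj2 <- list(structure = cdhfold:::new_cdh_structure(far),
               coords = list(as.matrix(far[, c("x", "y", "z")])))
  expect_equal(nrow(detect_hbonds(trj2)), 0L)
})

test_that("hydrogen-bond persistence matches planted occupancy", {
  ev <- make_hbond_events(tibble::tibble(donor = 5, acceptor = 9, p = 0.46),
                          n_frames = 5000, seed = 1)
  expect_lt(abs(hbond_persistence(ev)$p - 0.46), 0.02)
  evm <- make_hbond_events(tibble::tibble(donor = 1, acceptor = 2, p = 0.62),
                           n_frames = 5000, flip_rate = 0.2, seed = 2)
  expect_lt(abs(hbond_persistence(evm)$p - 0.62), 0.04)
})

test_that("persistence networks filter transient bonds", {
  pairs <- tibble::tibble(donor = c(47, 81, 3), acceptor = c(81, 94, 60),
                          p = c(0.46, 0.62, 0.10))
  ev <- make_hbond_events(pairs, 5000, exact = TRUE, seed = 1)
  all_edges <- persistence_network(ev, 0)
  expect_equal(nrow(all_edges$edges), 3L)
  filtered <- persistence_network(ev, 0.25)
  expect_equal(sort(filtered$edges$p), c(0.46, 0.62))
  # aggregation oracle: count rows per pair directly
  brute <- table(paste(ev$donor, ev$acceptor))
  keep <- names(brute)[brute / 5000 >= 0.25]
  expect_setequal(paste(filtered$edges$donor, filtered$edges$acceptor), keep)
  expect_error(persistence_network(ev, 1.5), "\\[0, 1\\]")
})

test_that("critical persistence finds the planted fragmentation threshold", {
  pairs <- tibble::tibble(
    donor = c(1, 2, 3, 4, 5, 6),
    acceptor = c(2, 3, 4, 10, 11, 12),
    p = c(0.9, 0.8, 0.7, 0.25, 0.25, 0.25))
  ev <- make_hbond_events(pairs, 5000, exact = TRUE, seed = 2)
  cp <- critical_persistence(ev)
  expect_equal(cp$p_crit, 0.25)
  expect_true(all(diff(cp$curve$largest_cluster) <= 0))
  # a single 46%-persistent bond: cluster of 2 until p_min passes 0.46
  ev1 <- make_hbond_events(tibble::tibble(donor = 5, acceptor = 9, p = 0.46),
                           5000, exact = TRUE, seed = 1)
  c1 <- critical_persistence(ev1)
  expect_equal(c1$curve$largest_cluster[c1$curve$p_min <= 0.46], rep(2L, 47))
  expect_true(all(c1$curve$largest_cluster[c1$curve$p_min > 0.46] == 1L))
  expect_error(critical_persistence(ev1[0, ]), "empty")
  flat <- make_hbond_events(tibble::tibble(donor = 1, acceptor = 2, p = 1),
                            100, exact = TRUE, seed = 1)
  expect_warning(cf <- critical_persistence(flat), "flat")
  expect_true(is.na(cf$p_crit))
})
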