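# Independent oracle implementations used across the suite. These are
# deliberately written as plain loops / exhaustive enumerations, sharing no
# code with the package internals they check.

R_GAS <- 8.31446261815324

# ---- exhaustive WSME oracle -------------------------------------------------

# all SSA/DSA(+w) states of an n-block chain, found by filtering every
# binary string by its number of folded islands
oracle_enumerate <- function(n) {
  states <- list()
  for (code in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(code))[1:n]
    r <- rle(bits)
    n_islands <- sum(r$values == 1)
    if (n_islands > 2) next
    states[[length(states) + 1L]] <- list(bits = bits, w = FALSE)
    if (n_islands == 2) {
      states[[length(states) + 1L]] <- list(bits = bits, w = TRUE)
    }
  }
  states
}

# free energy of one oracle state by direct loops over contacts/residues
oracle_state_F <- function(bits, w, cmap, ss, params, T, block_size) {
  n_res <- attr(cmap, "n_residues")
  blk <- ceiling(seq_len(n_res) / block_size)
  folded_blk <- which(bits == 1)
  # island id per folded block
  island <- integer(length(bits))
  cur <- 0L
  for (b in seq_along(bits)) {
    if (bits[b] == 1) {
      if (b == 1 || bits[b - 1] == 0) cur <- cur + 1L
      island[b] <- cur
    }
  }
  q <- attr(cmap, "charges")
  kappa <- sqrt(2.52838e23 * (params$ionic_mM / 1000) /
                  (params$eps_eff * T)) * 1e-10
  solv <- params$dCp_cont * ((T - params$T_ref) - T * log(T / params$T_ref))
  Fv <- 0
  for (k in seq_len(nrow(cmap))) {
    bi <- blk[cmap$i[k]]; bj <- blk[cmap$j[k]]
    if (bits[bi] == 0 || bits[bj] == 0) next
    if (island[bi] != island[bj] && !w) next
    Fv <- Fv + cmap$n_atomic[k] * (params$xi + solv)
    if (!is.null(q) && q[cmap$i[k]] != 0 && q[cmap$j[k]] != 0) {
      Fv <- Fv + 332.0636 * 4184 * q[cmap$i[k]] * q[cmap$j[k]] /
        (params$eps_eff * cmap$r0[k]) * exp(-kappa * cmap$r0[k])
    }
  }
  dS <- c(strand_or_helix = params$dS_strand_helix,
          coil_or_glycine = params$dS_coil_gly, proline = params$dS_pro)
  for (res in seq_len(n_res)) {
    if (bits[blk[res]] == 1) {
      Fv <- Fv - T * dS[[ss$class[ss$resno == res]]]
    }
  }
  Fv
}

# partition function and per-bin sums by direct summation
oracle_Z <- function(cmap, ss, params, T, block_size) {
  n_res <- attr(cmap, "n_residues")
  nb <- ceiling(n_res / block_size)
  states <- oracle_enumerate(nb)
  Fs <- vapply(states, function(st)
    oracle_state_F(st$bits, st$w, cmap, ss, params, T, block_size), numeric(1))
  nf <- vapply(states, function(st) sum(st$bits), numeric(1))
  w <- exp(-Fs / (R_GAS * T))
  list(Z = sum(w), n_states = length(states),
       bins = tapply(w, nf, sum))
}

# ---- rupture-scan oracle ----------------------------------------------------

# literal re-statement of the detection rule as a stepwise loop
oracle_rupture_scan <- function(F_raw, F_smooth, n_mad, drop_frac) {
  n <- length(F_smooth)
  floor_ <- median(F_raw) + n_mad * mad(F_raw)
  cand <- integer()
  for (i in 2:(n - 1)) {
    if (F_smooth[i] > F_smooth[i - 1] && F_smooth[i] >= F_smooth[i + 1] &&
        F_smooth[i] > floor_) {
      cand <- c(cand, i)
    }
  }
  keep <- integer(); k <- 1
  while (k <= length(cand)) {
    cur <- cand[k]; k <- k + 1
    while (k <= length(cand)) {
      if (min(F_smooth[cur:cand[k]]) <= (1 - drop_frac) * F_smooth[cur]) break
      if (F_smooth[cand[k]] > F_smooth[cur]) cur <- cand[k]
      k <- k + 1
    }
    if (min(F_smooth[cur:n]) <= (1 - drop_frac) * F_smooth[cur]) {
      keep <- c(keep, cur)
    }
  }
  keep
}

# ---- misc -------------------------------------------------------------------

# circular correlation restated as a scalar loop
oracle_circ_corr <- function(x, y) {
  cmean <- function(v) atan2(sum(sin(v)) / length(v), sum(cos(v)) / length(v))
  mx <- cmean(x); my <- cmean(y)
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_along(x)) {
    num <- num + sin(x[i] - mx) * sin(y[i] - my)
    dx <- dx + sin(x[i] - mx)^2
    dy <- dy + sin(y[i] - my)^2
  }
  num / sqrt(dx * dy)
}

# shared small fixtures (built once per test run)
fixture_env <- new.env()
get_fixture <- function(name, build) {
  if (!exists(name, envir = fixture_env, inherits = FALSE)) {
    assign(name, build(), envir = fixture_env)
  }
  get(name, envir = fixture_env, inherits = FALSE)
}

hairpin16 <- function() get_fixture("hairpin16", function() make_toy_structure("hairpin", 16))
hairpin_top <- function() get_fixture("hairpin_top", function() {
  s <- hairpin16()
  build_sop_topology(s, native_contacts_sop(s))
})
hairpin_min <- function() get_fixture("hairpin_min", function() sop_minimize(hairpin_top()))

# small synthetic wsme system (8 blocks) for oracle comparisons
toy_wsme <- function(n_res = 24, seed = 11) {
  get_fixture(paste0("toywsme", n_res, "_", seed), function() {
    cm <- synth_contact_map(n_res, "wt", density = 80, seed = seed)
    list(cmap = cm, ss = attr(cm, "ss"))
  })
}
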