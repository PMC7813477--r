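# Internal helpers shared across modules.

#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map2 pmap
#' @importFrom Rcpp sourceCpp
#' @useDynLib cdhfold, .registration = TRUE
NULL

# gas constant, J mol^-1 K^-1
.R_GAS <- 8.31446261815324
# Boltzmann constant in kcal mol^-1 K^-1
.KB_KCAL <- 0.0019872041
# 1 kcal mol^-1 A^-1 in pN
.KCAL_PER_A_IN_PN <- 69.479
# Coulomb constant for q1*q2/r in e^2/A -> kcal mol^-1
.COULOMB_KCAL <- 332.0636
# kB*T at 300 K in pN nm (for worm-like chain fits)
.KBT_PN_NM_300K <- 4.114195

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# grouped log-sum-exp: returns named vector of lse(x) per group level
logsumexp_by <- function(x, g) {
  sp <- split(x, g)
  vapply(sp, logsumexp, numeric(1))
}

# Debye screening parameter kappa in 1/Angstrom.
# ionic strength in mol/L, eps = relative dielectric, T in K.
debye_kappa <- function(ionic_M, eps, T) {
  # kappa^2 = 2 * N_A * e^2 * (1000 * I) / (eps0 * eps_r * kB * T), SI
  # collapsing constants: kappa [1/m] = sqrt(2.52838e23 * I / (eps * T))
  sqrt(2.52838e23 * ionic_M / (eps * T)) * 1e-10
}

`%!in%` <- function(x, y) !(x %in% y)

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0", name))
  invisible(x)
}

# deterministic child seed derived from a user seed and a stream label,
# kept below 2^31
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
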