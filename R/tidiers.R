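# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.biexp_fit <- function(x, ...) {
  tibble(term = c("k_fast", "k_slow", "A_fast", "A_slow", "offset"),
         estimate = c(x$k_fast, x$k_slow, x$A_fast, x$A_slow, x$offset),
         std.error = unname(x$se))
}

#' @export
glance.biexp_fit <- function(x, ...) {
  tibble(k_fast = x$k_fast, k_slow = x$k_slow,
         amp_fraction_fast = amplitude_fraction(x),
         rms = x$rms, degenerate = x$degenerate, conc = x$conc, nobs = x$n)
}

#' @export
tidy.chevron_fit <- function(x, ...) {
  tibble(term = c("log_k0", "slope"),
         estimate = c(x$log_k0, x$slope),
         std.error = c(x$se_log_k0, x$se_slope))
}

#' @export
glance.chevron_fit <- function(x, ...) {
  tibble(branch = x$branch, k0 = x$k0, se_k0 = x$se_k0,
         slope = x$slope, nobs = x$n)
}

#' @export
tidy.dsc_fit <- function(x, ...) {
  tibble(term = x$estimates$parameter, estimate = x$estimates$estimate)
}

#' @export
glance.dsc_fit <- function(x, ...) {
  tibble(rms_residual = x$rms_residual, at_bound = x$at_bound,
         n_free = nrow(x$estimates))
}

#' @export
glance.fe_profile <- function(x, ...) {
  mins <- attr(x, "minima"); bars <- attr(x, "barriers")
  tibble(T = attr(x, "T"),
         n_minima = nrow(mins),
         n_unfolded = if (any(mins$label == "U")) mins$n[mins$label == "U"] else NA_integer_,
         n_intermediate = if (any(mins$label == "I")) mins$n[mins$label == "I"][1] else NA_integer_,
         n_native = if (any(mins$label == "N")) mins$n[mins$label == "N"] else NA_integer_,
         max_barrier_kJ = if (nrow(bars)) max(bars$height_from_kJ) else NA_real_)
}
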