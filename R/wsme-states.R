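# Block partition and microstate enumeration for the block
# Wako-Saito-Munoz-Eaton (bWSME) model.
#
# The state space is the single-sequence approximation (one folded island),
# the double-sequence approximation (two disjoint, non-adjacent folded
# islands), and the DSA states duplicated with the cross-island interaction
# switched on ("w"): 1 + C(n+1, 2) + 2 * C(n+1, 4) states for n units.

#' Partition residues into consecutive blocks
#'
#' @param n_residues Number of residues.
#' @param block_size Residues per block (default 3; the trailing block takes
#'   the remainder when the block size does not divide the residue count).
#' @return A tibble with columns `block`, `first`, `last`.
#' @export
block_partition <- function(n_residues, block_size = 3L) {
  assert_scalar_number(n_residues, "n_residues", positive = TRUE)
  assert_scalar_number(block_size, "block_size", positive = TRUE)
  n_b <- ceiling(n_residues / block_size)
  first <- (seq_len(n_b) - 1L) * block_size + 1L
  last <- pmin(first + block_size - 1L, n_residues)
  out <- tibble(block = seq_len(n_b), first = as.integer(first), last = as.integer(last))
  attr(out, "n_residues") <- as.integer(n_residues)
  attr(out, "block_size") <- as.integer(block_size)
  out
}

#' Closed-form microstate count
#'
#' Number of states in the SSA + DSA + DSA-with-interaction space:
#' `1 + choose(n+1, 2) + 2 * choose(n+1, 4)`.
#'
#' @param n_units Number of folding units (blocks, or residues for the
#'   residue-level model).
#' @return Numeric count (exact for all practical n).
#' @export
count_microstates <- function(n_units) {
  1 + choose(n_units + 1, 2) + 2 * choose(n_units + 1, 4)
}

#' Enumerate the SSA/DSA microstates
#'
#' Returns every microstate of an n-unit chain as island bounds: the fully
#' unfolded state (all bounds `NA`), all single islands `[a1, b1]`, and all
#' pairs of disjoint islands separated by at least one unfolded unit, each
#' pair listed twice - once with the cross-island interaction absent
#' (`w = FALSE`) and once present (`w = TRUE`).
#'
#' @param n_units Number of folding units (capped at 150: the two-island
#'   space grows as n^4).
#' @return A tibble with integer columns `a1`, `b1`, `a2`, `b2` and logical
#'   `w`. One row per microstate.
#' @export
enumerate_microstates <- function(n_units) {
  assert_scalar_number(n_units, "n_units", positive = TRUE)
  n <- as.integer(n_units)
  if (n > 150L) abort("n_units > 150: enumeration refused (memory guard)")
  # single islands
  singles <- expand.grid(a1 = seq_len(n), b1 = seq_len(n))
  singles <- singles[singles$a1 <= singles$b1, , drop = FALSE]
  singles <- tibble(a1 = as.integer(singles$a1), b1 = as.integer(singles$b1),
                    a2 = NA_integer_, b2 = NA_integer_, w = FALSE)
  # two islands via the boundary bijection: strictly increasing
  # y1 < y2 < y3 < y4 in 1..n+1 maps to islands [y1, y2-1], [y3, y4-1]
  doubles <- NULL
  if (n >= 3L) {
    cmb <- utils::combn(n + 1L, 4L)
    doubles <- tibble(
      a1 = as.integer(cmb[1, ]), b1 = as.integer(cmb[2, ] - 1L),
      a2 = as.integer(cmb[3, ]), b2 = as.integer(cmb[4, ] - 1L),
      w = FALSE
    )
    doubles <- dplyr::bind_rows(doubles, dplyr::mutate(doubles, w = TRUE))
  }
  empty <- tibble(a1 = NA_integer_, b1 = NA_integer_,
                  a2 = NA_integer_, b2 = NA_integer_, w = FALSE)
  out <- dplyr::bind_rows(empty, singles, doubles)
  attr(out, "n_units") <- n
  out
}

# number of folded units per state
state_n_folded <- function(states) {
  n1 <- ifelse(is.na(states$a1), 0L, states$b1 - states$a1 + 1L)
  n2 <- ifelse(is.na(states$a2), 0L, states$b2 - states$a2 + 1L)
  as.integer(n1 + n2)
}

# folded units of each state falling inside blocks 1..split
state_n_folded_left <- function(states, split) {
  ov <- function(a, b) pmax(0L, pmin(b, as.integer(split)) - a + 1L)
  n1 <- ifelse(is.na(states$a1), 0L, ov(states$a1, states$b1))
  n2 <- ifelse(is.na(states$a2), 0L, ov(states$a2, states$b2))
  as.integer(n1 + n2)
}
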