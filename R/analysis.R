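# Reliability and sizing models: per-unit accuracy accumulation across a
# register, repetition-code majority-vote decoding, and breadth/depth/volume
# resource totals from the measured per-unit constants (breadth 4 qubits,
# transpiled depth 40 gates per one-bit unit).

#' Accuracy of a serialized s-bit register operation
#'
#' One-bit arithmetic units are chained across the register, so a per-unit
#' accuracy `w` compounds to `w^s`. The measured worst case `w = 0.57` at
#' `s = 9` gives 6.35e-3.
#'
#' @param w per-unit accuracy probability in `[0, 1]`.
#' @param s register size in bits, `>= 1`.
#' @return probability `w^s`.
#' @export
register_accuracy <- function(w, s) {
  if (!is.finite(w) || w < 0 || w > 1) stop("w must be in [0,1]", call. = FALSE)
  s <- as.integer(s)
  if (s < 1) stop("s must be >= 1", call. = FALSE)
  w^s
}

#' Majority-vote (repetition code) decoding error
#'
#' One logical bit is stored in `n_rep` replicas, each independently wrong
#' with probability `e`; readout takes the majority, and ties (possible for
#' even `n_rep`) count as failure. The error is the exact binomial tail
#' `P(X >= ceiling(n_rep/2))` with `X ~ Binomial(n_rep, e)`. At `e = 0.43`,
#' `n_rep = 16` this is 0.37.
#'
#' @param e per-replica error probability in `[0, 1]`.
#' @param n_rep number of replicas, `>= 1`.
#' @return decoding error probability.
#' @export
majority_vote_error <- function(e, n_rep) {
  if (!is.finite(e) || e < 0 || e > 1) stop("e must be in [0,1]", call. = FALSE)
  n_rep <- as.integer(n_rep)
  if (n_rep < 1) stop("n_rep must be >= 1", call. = FALSE)
  thr <- ceiling(n_rep / 2)
  sum(stats::dbinom(thr:n_rep, n_rep, e))
}

#' Circuit resource totals for an s-bit register
#'
#' The one-bit units measured on hardware have breadth 4 qubits and
#' transpiled depth 40 gates; register-level circuits chain them linearly,
#' so breadth `= 4s`, depth `= 40s`, volume `= 160s`. At `s = 6`:
#' 24 / 240 / 960.
#'
#' @param s register size in bits, `>= 1`.
#' @param unit_breadth qubits per one-bit unit (default 4).
#' @param unit_depth transpiled gates per one-bit unit (default 40).
#' @return a `resource_estimate` list: `s`, `unit_breadth`, `unit_depth`,
#'   `breadth`, `depth`, `volume`.
#' @export
estimate_resources <- function(s, unit_breadth = 4L, unit_depth = 40L) {
  s <- as.integer(s)
  if (s < 1) stop("s must be >= 1", call. = FALSE)
  unit_breadth <- as.integer(unit_breadth)
  unit_depth <- as.integer(unit_depth)
  structure(list(s = s, unit_breadth = unit_breadth, unit_depth = unit_depth,
                 breadth = unit_breadth * s,
                 depth = unit_depth * s,
                 volume = unit_breadth * unit_depth * s),
            class = "resource_estimate")
}

#' @export
print.resource_estimate <- function(x, ...) {
  cat(sprintf("s=%d: breadth %d qubits, depth %d gates, volume %d\n",
              x$s, x$breadth, x$depth, x$volume))
  invisible(x)
}

#' Combined error-model report
#'
#' @param w per-unit accuracy (default 0.57, the measured worst case).
#' @param s register size in bits.
#' @param n_rep majority-vote replicas.
#' @return list with `register_accuracy`, `majority_vote_error` (at
#'   `e = 1 - w`), and the [estimate_resources()] figures.
#' @export
error_model <- function(w = 0.57, s = 9L, n_rep = 16L) {
  list(w = w, e = 1 - w, s = as.integer(s), n_rep = as.integer(n_rep),
       register_accuracy = register_accuracy(w, s),
       majority_vote_error = majority_vote_error(1 - w, n_rep),
       resources = unclass(estimate_resources(s)))
}
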