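# Dense statevector engine. A state over q qubits is a complex vector of
# length 2^q with unit norm; entry i+1 is the amplitude of basis state |i>,
# where bit j of i is qubit j (qubit 0 least significant). Gate application
# runs in the C++ kernel (src/gates.cpp).

parse_init <- function(init, n_qubits) {
  if (is.character(init)) {
    init <- gsub("\\s", "", init)
    if (!grepl("^[01]*$", init)) stop("init bitstring must be binary", call. = FALSE)
    bits <- as.integer(rev(strsplit(init, "")[[1]]))  # MSB-first text -> qubit order
  } else {
    bits <- as.integer(init)  # vector indexed by qubit
  }
  if (length(bits) != n_qubits) {
    stop(sprintf("init width %d != qubit count %d", length(bits), n_qubits),
         call. = FALSE)
  }
  sum(bits * 2^(seq_along(bits) - 1))
}

basis_state <- function(n_qubits, index = 0) {
  amp <- complex(2^n_qubits)
  amp[index + 1] <- 1 + 0i
  amp
}

GATE_CODES <- c(X = 0L, H = 1L, Z = 2L, RY = 3L)

flatten_gates <- function(gates) {
  G <- length(gates)
  list(kind = vapply(gates, function(g) GATE_CODES[[g$kind]], integer(1)),
       tmask = vapply(gates, function(g) as.integer(2^g$target), integer(1)),
       cmask = vapply(gates, function(g) as.integer(sum(2^g$controls)), integer(1)),
       param = vapply(gates, function(g) {
         if (is.null(g$param)) 0 else as.numeric(g$param)
       }, numeric(1)))
}

apply_gates <- function(amp, gates) {
  if (length(gates) == 0) return(amp)
  f <- flatten_gates(gates)
  .apply_circuit_cpp(amp, f$kind, f$tmask, f$cmask, f$param)
}

#' Simulate a circuit on a classical initial bitstring
#'
#' Applies each gate's unitary in order to the initial basis state (or a
#' supplied statevector). Norm is preserved to 1e-9 by construction.
#'
#' @param qc a [qcircuit()].
#' @param init initial state: an MSB-first bitstring (`"0101"`), an integer
#'   0/1 vector indexed by qubit, or a full complex amplitude vector of
#'   length `2^n_qubits`.
#' @return complex amplitude vector of length `2^n_qubits` (class
#'   `quantum_state`, attribute `n_qubits`).
#' @export
simulate <- function(qc, init = strrep("0", qc$n_qubits)) {
  stopifnot(inherits(qc, "qcircuit"))
  N <- 2^qc$n_qubits
  amp <- if (is.complex(init) && length(init) == N) {
    as.complex(init)
  } else {
    basis_state(qc$n_qubits, parse_init(init, qc$n_qubits))
  }
  amp <- apply_gates(amp, qc$gates)
  structure(amp, n_qubits = qc$n_qubits, class = "quantum_state")
}

state_probs <- function(state) {
  p <- Mod(as.complex(state))^2
  tot <- sum(p)
  if (abs(tot - 1) > 1e-6) stop("state is not normalized", call. = FALSE)
  p / tot
}

index_to_bitstring <- function(i, n_qubits) {
  vapply(i, function(v) {
    paste(rev((v %/% 2^(0:(n_qubits - 1))) %% 2), collapse = "")
  }, character(1))
}

#' Sample measurement outcomes from a state
#'
#' Multinomial sampling from the squared amplitude magnitudes; deterministic
#' under a fixed seed. `measure_qubits` measures only a subset of qubits
#' (marginal distribution).
#'
#' @param state a `quantum_state` (see [simulate()]).
#' @param shots number of samples, `>= 1` (circuit experiments in this
#'   package default to 1024).
#' @param seed integer RNG seed.
#' @return a `measurement_histogram`: list with `counts` (named integer
#'   vector, names are MSB-first bitstrings of the measured qubits) and
#'   `shots`.
#' @export
measure <- function(state, shots = 1024L, seed = 1L) {
  n_qubits <- attr(state, "n_qubits")
  measure_qubits(state, seq_len(n_qubits) - 1L, shots, seed)
}

#' @rdname measure
#' @param qubits 0-based indices of the qubits to measure.
#' @export
measure_qubits <- function(state, qubits, shots = 1024L, seed = 1L) {
  shots <- as.integer(shots)
  if (shots < 1) stop("shots must be >= 1", call. = FALSE)
  qubits <- as.integer(qubits)
  p <- state_probs(state)
  idx <- seq_along(p) - 1
  key <- rep(0, length(p))
  for (j in seq_along(qubits)) {
    key <- key + (bitwAnd(idx, 2^qubits[j]) != 0) * 2^(j - 1)
  }
  marg <- as.numeric(rowsum(p, key))
  keys <- sort(unique(key))
  draw <- with_seed(seed, {
    sample.int(length(keys), shots, replace = TRUE, prob = marg)
  })
  counts <- tabulate(draw, nbins = length(keys))
  keep <- marg > 0 | counts > 0
  counts <- counts[keep]
  names(counts) <- index_to_bitstring(keys[keep], max(length(qubits), 1L))
  structure(list(counts = counts, shots = shots,
                 values = keys[keep], probs = marg[keep]),
            class = "measurement_histogram")
}

#' @export
print.measurement_histogram <- function(x, ...) {
  cat(sprintf("<measurement_histogram> %d shots\n", x$shots))
  ord <- order(x$counts, decreasing = TRUE)
  for (i in utils::head(ord, 8)) {
    cat(sprintf("  |%s>  %5d  (%.3f)\n", names(x$counts)[i], x$counts[i],
                x$counts[i] / x$shots))
  }
  invisible(x)
}

#' Noisy circuit execution with a bit-flip channel
#'
#' Monte-Carlo trajectories: each shot replays the circuit and, after every
#' gate, flips each touched qubit (target and controls) independently with
#' probability `p`, then measures all qubits once. `p = 0` reproduces the
#' noiseless [simulate()]+[measure()] distribution. This is a qualitative
#' stand-in for hardware noise, not a calibrated device model.
#'
#' @param qc a [qcircuit()].
#' @param init initial bitstring (as in [simulate()]).
#' @param p flip probability in `[0, 1]`.
#' @param shots number of trajectories.
#' @param seed integer seed (deterministic histogram under a fixed seed).
#' @return a `measurement_histogram`.
#' @export
apply_bitflip_noise <- function(qc, init = strrep("0", qc$n_qubits),
                                p = 0, shots = 1024L, seed = 1L) {
  if (!is.finite(p) || p < 0 || p > 1) stop("p must be in [0,1]", call. = FALSE)
  shots <- as.integer(shots)
  N <- 2^qc$n_qubits
  start <- basis_state(qc$n_qubits, parse_init(init, qc$n_qubits))
  xflip <- function(q) list(kind = "X", target = q, controls = integer(),
                            param = NULL)
  outcomes <- with_seed(seed, {
    vapply(seq_len(shots), function(sh) {
      amp <- start
      for (g in qc$gates) {
        amp <- apply_gates(amp, list(g))
        if (p > 0) {
          touched <- c(g$target, g$controls)
          flips <- touched[stats::runif(length(touched)) < p]
          if (length(flips) > 0) {
            amp <- apply_gates(amp, lapply(flips, xflip))
          }
        }
      }
      pr <- Mod(amp)^2
      sample.int(N, 1L, prob = pr) - 1L
    }, integer(1))
  })
  tab <- table(outcomes)
  keys <- as.integer(names(tab))
  counts <- as.integer(tab)
  names(counts) <- index_to_bitstring(keys, qc$n_qubits)
  structure(list(counts = counts, shots = shots, values = keys,
                 probs = counts / shots),
            class = "measurement_histogram")
}

# probability-weighted frequency of a predicate on measured bitstrings
histogram_frequency <- function(hist, predicate) {
  sum(hist$counts[vapply(names(hist$counts), predicate, logical(1))]) / hist$shots
}
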