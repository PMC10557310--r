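# Grover-search feature detectors.
#
# A window of n quantized values is encoded as a uniform superposition of
# its k = n-1 (value_hi, value_lo) pairs, tagged by an index register of
# a = ceil(log2(k)) qubits (unused index branches have zero amplitude).
# Value registers are w = s + 2 bits wide so that v_hi - v_lo - incr is
# exact in two's complement for every admissible pair; an s-bit difference
# register would wrap. Oracles phase-flip exactly the components whose pair
# violates the feature rule (phase kickback through a flag qubit prepared
# as (|0> - |1>)/sqrt(2)); Grover iterations then amplify any violator.

#' Register layout for a window encoding
#'
#' @param k number of superposed components (`n - 1` for a window of `n`).
#' @param s value register size in bits (quantized codes are `< 2^s`).
#' @return a `window_encoding` list of qubit index vectors: `index`,
#'   `v_lo`, `v_hi`, `ancilla` (carry chain), `helper` (abs sign), `orq`
#'   (violation OR), `flag`, plus `k`, `s`, `w`, `n_qubits`.
#' @export
window_encoding <- function(k, s) {
  k <- as.integer(k); s <- as.integer(s)
  if (k < 1) stop("need at least one component", call. = FALSE)
  if (s < 1) stop("s must be >= 1", call. = FALSE)
  a <- if (k > 1) ceiling(log2(k)) else 0L
  w <- s + 2L
  q <- 0L
  index <- if (a > 0) q + 0:(a - 1L) else integer(0); q <- q + a
  v_lo <- q + 0:(w - 1L); q <- q + w
  v_hi <- q + 0:(w - 1L); q <- q + w
  ancilla <- q; helper <- q + 1L; orq <- q + 2L; flag <- q + 3L
  structure(list(index = as.integer(index), v_lo = v_lo, v_hi = v_hi,
                 ancilla = ancilla, helper = helper, orq = orq, flag = flag,
                 k = k, s = s, w = w, a = as.integer(a),
                 n_qubits = q + 4L),
            class = "window_encoding")
}

# gates preparing a uniform superposition over indices 0..k-1 of `qubits`
# (LSB first), recursing MSB-down; zero-valued controls are X-wrapped.
uniform_prep_gates <- function(qc, qubits, k, ctrl_q = integer(), ctrl_v = integer()) {
  a <- length(qubits)
  if (a == 0 || k <= 1) return(qc)
  with_ctrl <- function(qc, emit) {
    zero <- ctrl_q[ctrl_v == 0]
    for (q in zero) qc <- qc_gate(qc, "X", q)
    qc <- emit(qc, ctrl_q)
    for (q in zero) qc <- qc_gate(qc, "X", q)
    qc
  }
  if (k == 2^a) {
    for (q in qubits) {
      qc <- with_ctrl(qc, function(qc, cq) qc_gate(qc, "H", q, controls = cq))
    }
    return(qc)
  }
  msb <- qubits[a]
  half <- 2^(a - 1L)
  k0 <- min(k, half); k1 <- k - k0
  if (k1 == 0) {
    return(uniform_prep_gates(qc, qubits[-a], k0, ctrl_q, ctrl_v))
  }
  theta <- 2 * acos(sqrt(k0 / k))
  qc <- with_ctrl(qc, function(qc, cq) qc_gate(qc, "RY", msb, controls = cq,
                                               param = theta))
  qc <- uniform_prep_gates(qc, qubits[-a], k0, c(ctrl_q, msb), c(ctrl_v, 0L))
  uniform_prep_gates(qc, qubits[-a], k1, c(ctrl_q, msb), c(ctrl_v, 1L))
}

# load classical value `v` into register `reg` for index-component `i`
load_value_gates <- function(qc, enc, i, reg, v) {
  if (enc$a > 0) {
    ibits <- (i %/% 2^(0:(enc$a - 1L))) %% 2L
    zero <- enc$index[ibits == 0]
    for (q in zero) qc <- qc_gate(qc, "X", q)
    for (j in seq_along(reg)) {
      if ((v %/% 2^(j - 1L)) %% 2L == 1L) {
        qc <- qc_gate(qc, "X", reg[j], controls = enc$index)
      }
    }
    for (q in zero) qc <- qc_gate(qc, "X", q)
  } else {
    for (j in seq_along(reg)) {
      if ((v %/% 2^(j - 1L)) %% 2L == 1L) qc <- qc_gate(qc, "X", reg[j])
    }
  }
  qc
}

#' Prepare a superposition of value pairs
#'
#' Builds the state-preparation circuit for `k = length(hi)` components:
#' `(1/sqrt(k)) sum_i |i> |hi_i> |lo_i>` over the index and value registers,
#' with the flag qubit in `(|0> - |1>)/sqrt(2)` and all ancillas zero. For a
#' sharp-increase window `hi` / `lo` are the consecutive value pairs; for
#' near-to-constant, `hi` is the center value replicated and `lo` the
#' neighbours.
#'
#' @param hi,lo equal-length integer vectors of quantized values, `< 2^s`.
#' @param s value register size in bits.
#' @return list with `circuit` (a [qcircuit()]) and `encoding`
#'   (a [window_encoding()]).
#' @export
build_pair_superposition <- function(hi, lo, s) {
  hi <- as.integer(hi); lo <- as.integer(lo)
  if (length(hi) != length(lo) || length(hi) < 1) {
    stop("hi and lo must be equal-length, non-empty", call. = FALSE)
  }
  if (any(hi < 0 | hi >= 2^s | lo < 0 | lo >= 2^s)) {
    stop("values must lie in [0, 2^s)", call. = FALSE)
  }
  enc <- window_encoding(length(hi), s)
  qc <- qcircuit(enc$n_qubits)
  qc <- qc_gate(qc, "X", enc$flag)
  qc <- qc_gate(qc, "H", enc$flag)
  qc <- uniform_prep_gates(qc, enc$index, enc$k)
  for (i in seq_len(enc$k) - 1L) {
    qc <- load_value_gates(qc, enc, i, enc$v_hi, hi[i + 1L])
    qc <- load_value_gates(qc, enc, i, enc$v_lo, lo[i + 1L])
  }
  list(circuit = qc, encoding = enc)
}

#' Sharp-increase violation oracle
#'
#' Phase-flips the components whose pair difference `hi - lo` is strictly
#' below `incr`: the circuit computes `hi - lo - incr` in two's complement
#' on the (widened) `v_hi` register, kicks the sign bit back into the flag,
#' and uncomputes. Registers are restored exactly.
#'
#' @param enc a [window_encoding()].
#' @param incr threshold, `0 < incr < 2^(s-1)`.
#' @return a [qcircuit()] fragment over `enc$n_qubits` qubits.
#' @export
build_increase_oracle <- function(enc, incr) {
  incr <- as.integer(incr)
  if (incr <= 0 || incr >= 2^(enc$s - 1)) {
    stop("incr must satisfy 0 < incr < 2^(s-1)", call. = FALSE)
  }
  cmp <- qcircuit(enc$n_qubits)
  cmp <- subtract_in_place_gates(cmp, src = enc$v_lo, tgt = enc$v_hi,
                                 c0 = enc$ancilla)
  cmp <- add_constant_gates(cmp, enc$v_hi, 2^enc$w - incr)
  sign <- enc$v_hi[enc$w]
  qc <- cmp
  qc <- qc_gate(qc, "X", enc$flag, controls = sign)
  qc_extend(qc, circuit_inverse(cmp))
}

#' Near-to-constant violation oracle
#'
#' Phase-flips the components with `|hi - lo| >= epsilon` (`hi` holds the
#' center value `P0`, `lo` a neighbour). The circuit subtracts, takes the
#' two's-complement absolute value, and tests the high-order bits: for
#' `epsilon = 2^kk` the violation is "any bit above the epsilon'th leading
#' zero is set", collected by an OR into an ancilla; for other `epsilon` it
#' falls back to a comparator (subtract `epsilon`, test the sign). All
#' working registers are uncomputed.
#'
#' @param enc a [window_encoding()].
#' @param epsilon tolerance, `0 < epsilon <= 2^(s-1)`.
#' @return a [qcircuit()] fragment.
#' @export
build_near_constant_oracle <- function(enc, epsilon) {
  epsilon <- as.integer(epsilon)
  if (epsilon <= 0 || epsilon > 2^(enc$s - 1)) {
    stop("epsilon must satisfy 0 < epsilon <= 2^(s-1)", call. = FALSE)
  }
  w <- enc$w
  cmp <- qcircuit(enc$n_qubits)
  cmp <- subtract_in_place_gates(cmp, src = enc$v_lo, tgt = enc$v_hi,
                                 c0 = enc$ancilla)
  cmp <- abs_in_place_gates(cmp, enc$v_hi, enc$helper)
  kk <- log2(epsilon)
  if (kk == round(kk)) {
    # leading-zero test: violation iff any bit kk..w-1 of |diff| is set
    high <- enc$v_hi[(kk + 1L):w]
    for (q in high) cmp <- qc_gate(cmp, "X", q)
    cmp <- qc_gate(cmp, "X", enc$orq, controls = high)
    cmp <- qc_gate(cmp, "X", enc$orq)
    for (q in high) cmp <- qc_gate(cmp, "X", q)
  } else {
    # comparator: |diff| - epsilon >= 0  <=>  sign bit clear
    cmp <- add_constant_gates(cmp, enc$v_hi, 2^w - epsilon)
    cmp <- qc_gate(cmp, "X", enc$v_hi[w])
    cmp <- qc_gate(cmp, "X", enc$orq, controls = enc$v_hi[w])
    cmp <- qc_gate(cmp, "X", enc$v_hi[w])
  }
  qc <- cmp
  qc <- qc_gate(qc, "X", enc$flag, controls = enc$orq)
  qc_extend(qc, circuit_inverse(cmp))
}

# reflection about the all-zeros state of the whole register set
reflect_zero_gates <- function(qc) {
  n <- qc$n_qubits
  for (q in 0:(n - 1L)) qc <- qc_gate(qc, "X", q)
  if (n == 1) {
    qc <- qc_gate(qc, "Z", 0)
  } else {
    qc <- qc_gate(qc, "Z", 0, controls = 1:(n - 1L))
  }
  for (q in 0:(n - 1L)) qc <- qc_gate(qc, "X", q)
  qc
}

#' Grover search over a window encoding
#'
#' Applies `iterations` rounds of oracle + diffusion (reflection about the
#' prepared state) and measures the index register.
#'
#' @param prep state-preparation circuit (from
#'   [build_pair_superposition()]).
#' @param oracle violation oracle circuit (same qubit count).
#' @param enc the [window_encoding()].
#' @param iterations number of Grover rounds, `>= 0`.
#' @param shots measurement samples.
#' @param seed RNG seed for the measurement.
#' @return list: `candidate` (modal 0-based index), `histogram`
#'   (a `measurement_histogram` over the index register), `state` (final
#'   statevector).
#' @export
grover_search <- function(prep, oracle, enc, iterations, shots = 1024L,
                          seed = 1L) {
  iterations <- as.integer(iterations)
  if (iterations < 0) stop("iterations must be >= 0", call. = FALSE)
  state <- grover_state(prep, oracle, enc, iterations)
  if (enc$a == 0) {
    hist <- structure(list(counts = stats::setNames(as.integer(shots), "0"),
                           shots = as.integer(shots), values = 0L, probs = 1),
                      class = "measurement_histogram")
    return(list(candidate = 0L, histogram = hist, state = state))
  }
  hist <- measure_qubits(state, enc$index, shots = shots, seed = seed)
  candidate <- hist$values[which.max(hist$counts)]
  list(candidate = as.integer(candidate), histogram = hist, state = state)
}

# final statevector after `iterations` Grover rounds (no measurement)
grover_state <- function(prep, oracle, enc, iterations) {
  state <- simulate(prep)
  if (iterations > 0) {
    inv_prep <- circuit_inverse(prep)
    diff_qc <- qc_extend(qc_extend(inv_prep, reflect_zero_gates(qcircuit(prep$n_qubits))),
                         prep)
    round_qc <- qc_extend(oracle, diff_qc)
    for (j in seq_len(iterations)) state <- simulate(round_qc, init = state)
  }
  state
}

#' Marked component set of an oracle (statevector readout)
#'
#' Simulates `prep`, applies `oracle`, and reports the 0-based index
#' components whose amplitude acquired a relative phase of -1. Used to
#' check oracle soundness against the classical rule.
#'
#' @inheritParams grover_search
#' @return integer vector of marked component indices.
#' @export
oracle_marked_set <- function(prep, oracle, enc) {
  before <- simulate(prep)
  after <- simulate(oracle, init = before)
  nz <- which(Mod(before) > 1e-9)
  ratio <- Re(after[nz] / before[nz])
  idx <- nz - 1L
  comp <- if (enc$a > 0) {
    vapply(idx, function(i) {
      sum(((i %/% 2^enc$index) %% 2L) * 2^(seq_along(enc$index) - 1L))
    }, numeric(1))
  } else rep(0, length(idx))
  marked <- unique(comp[ratio < -0.5])
  clean <- unique(comp[ratio > 0.5])
  if (length(intersect(marked, clean)) > 0) {
    stop("oracle applied a non-uniform phase within a component", call. = FALSE)
  }
  sort(as.integer(marked))
}

classical_violators <- function(hi, lo, kind, params) {
  d <- hi - lo
  which(switch(kind,
               increase = d < params$incr,
               decrease = d < params$incr,   # pairs already swapped
               constant = abs(d) >= params$epsilon)) - 1L
}

window_pairs <- function(window, kind, params) {
  n <- length(window)
  switch(kind,
    increase = list(hi = window[-1], lo = window[-n]),
    decrease = list(hi = window[-n], lo = window[-1]),
    constant = {
      c0 <- center_index(n, params$mode)
      list(hi = rep(window[c0 + 1L], n - 1L), lo = window[-(c0 + 1L)])
    },
    stop("no pair encoding for kind ", kind, call. = FALSE))
}

#' Quantum feature decision for one window
#'
#' Runs the Grover detector: prepares the pair superposition over the
#' `k = n-1` occupied branches, applies oracle+diffusion rounds, measures
#' the index register and verifies the observed indices classically,
#' repeating `repeats` times with derived seeds. Because the marked count
#' is unknown, the repeats cycle through iteration counts
#' `{floor(pi/4*sqrt(k)), 0, 1}` (a fixed count can null the marked mass
#' when `m/k = 3/4`). The feature is declared present iff no verified
#' violating component is found. Peaks and valleys run the increase and
#' decrease detectors on the two half-windows and AND the decisions.
#'
#' @param window integer vector of quantized values, each `< 2^s`.
#' @param kind one of `"constant"`, `"increase"`, `"decrease"`, `"peak"`,
#'   `"valley"`.
#' @param params a [feature_params()].
#' @param s value register size in bits.
#' @param shots measurement samples per repeat.
#' @param seed integer seed (decision deterministic given the seed).
#' @param repeats classical-verification rounds (default 3).
#' @return list: `decision` (logical), `counterexample` (0-based violating
#'   component index, or `NULL`), `histograms`, `kind`.
#' @export
detect_feature_quantum <- function(window, kind, params, s,
                                   shots = 1024L, seed = 1L, repeats = 3L) {
  kind <- match.arg(kind, FEATURE_KINDS)
  window <- as.integer(window)
  n <- length(window)
  if (n < 2) stop("window too short", call. = FALSE)
  if (any(window < 0 | window >= 2^s)) {
    stop("window values must be quantized to [0, 2^s)", call. = FALSE)
  }
  if (kind %in% c("peak", "valley")) {
    if (n %% 2L != 0L || n < 4L) {
      stop("peak/valley windows need even n >= 4", call. = FALSE)
    }
    h <- n %/% 2L
    kinds2 <- if (kind == "peak") c("increase", "decrease") else c("decrease", "increase")
    left <- detect_feature_quantum(window[1:h], kinds2[1], params, s,
                                   shots, seed, repeats)
    right <- detect_feature_quantum(window[(h + 1L):n], kinds2[2], params, s,
                                    shots, seed + 1L, repeats)
    return(list(decision = left$decision && right$decision,
                counterexample = c(left$counterexample, right$counterexample),
                histograms = c(left$histograms, right$histograms),
                kind = kind))
  }
  pr <- window_pairs(window, kind, params)
  ps <- build_pair_superposition(pr$hi, pr$lo, s)
  oracle <- switch(kind,
    increase = ,
    decrease = build_increase_oracle(ps$encoding, params$incr),
    constant = build_near_constant_oracle(ps$encoding, params$epsilon))
  k <- ps$encoding$k
  # the number of marked components is unknown; the single-marked count
  # floor(pi/4 sqrt(k)) can drive the marked mass to exactly zero when
  # m/k = 3/4, so the repeats cycle through iteration counts {j*, 0, 1}
  # (0 = bare superposition) and every observed index is verified.
  j_star <- floor(pi / 4 * sqrt(k))
  iter_schedule <- rep_len(unique(c(j_star, 0L, 1L)), repeats)
  seeds <- with_seed(seed, sample.int(2^30, repeats))
  histograms <- list()
  counterexample <- NULL
  violators <- classical_violators(pr$hi, pr$lo, kind, params)
  state_cache <- list()
  for (r in seq_len(repeats)) {
    observed <- if (ps$encoding$a == 0) 0L else {
      kj <- as.character(iter_schedule[r])
      if (is.null(state_cache[[kj]])) {
        state_cache[[kj]] <- grover_state(ps$circuit, oracle, ps$encoding,
                                          iter_schedule[r])
      }
      hist <- measure_qubits(state_cache[[kj]], ps$encoding$index,
                             shots = shots, seed = seeds[r])
      histograms[[r]] <- hist
      as.integer(hist$values[order(hist$counts, decreasing = TRUE)])
    }
    hit <- observed[observed %in% violators]
    if (length(hit) > 0) {
      counterexample <- hit[1]
      break
    }
  }
  list(decision = is.null(counterexample), counterexample = counterexample,
       histograms = histograms, kind = kind)
}

#' Scan a signal with the quantum detectors
#'
#' Reuses the classical scanning/merging logic of [scan_features()] with
#' [detect_feature_quantum()] as the window predicate. Seeds are derived
#' per window position for reproducibility.
#'
#' @inheritParams scan_features
#' @param s value register size in bits.
#' @param shots,seed,repeats forwarded to [detect_feature_quantum()].
#' @return a [feature_calls()] data frame.
#' @export
scan_features_quantum <- function(signal, params, s, kinds = FEATURE_KINDS,
                                  shots = 256L, seed = 1L, repeats = 3L) {
  counter <- new.env()
  counter$i <- 0L
  detector <- function(window, kind, p) {
    counter$i <- counter$i + 1L
    detect_feature_quantum(window, kind, p, s = s, shots = shots,
                           seed = (seed + counter$i) %% 2^30,
                           repeats = repeats)$decision
  }
  scan_features(signal, params, kinds = kinds, detector = detector)
}
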