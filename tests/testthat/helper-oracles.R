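# Independent brute-force oracles: each feature rule re-evaluated as a bare
# quantifier loop, kept deliberately separate from the package detectors.

brute_near_constant <- function(window, center, epsilon) {
  p0 <- window[center + 1]
  for (i in seq_along(window)) {
    if (i == center + 1) next
    if (!(abs(p0 - window[i]) < epsilon)) return(FALSE)
  }
  TRUE
}

brute_sharp_increase <- function(window, incr) {
  for (i in seq_len(length(window) - 1)) {
    if (!(window[i + 1] - window[i] >= incr)) return(FALSE)
  }
  TRUE
}

brute_sharp_decrease <- function(window, incr) {
  for (i in seq_len(length(window) - 1)) {
    if (!(window[i + 1] - window[i] <= -incr)) return(FALSE)
  }
  TRUE
}

brute_peak <- function(window, incr) {
  h <- length(window) / 2
  brute_sharp_increase(window[1:h], incr) &&
    brute_sharp_decrease(window[(h + 1):length(window)], incr)
}

brute_valley <- function(window, incr) {
  h <- length(window) / 2
  brute_sharp_decrease(window[1:h], incr) &&
    brute_sharp_increase(window[(h + 1):length(window)], incr)
}

# one-bit subtraction truth table: rows (carry_in, q1, q2) -> result, carry
SUBTRACTION_TABLE <- data.frame(
  c0 = c(0, 0, 0, 0, 1, 1, 1, 1),
  q1 = c(0, 0, 1, 1, 0, 0, 1, 1),
  q2 = c(0, 1, 0, 1, 0, 1, 0, 1),
  result = c(0, 1, 1, 0, 1, 0, 0, 1),
  carry  = c(0, 1, 0, 0, 1, 1, 0, 1)
)

# all windows of length n over alphabet 0:(A-1), as a matrix (rows = windows)
all_windows <- function(n, A = 4) {
  as.matrix(expand.grid(rep(list(0:(A - 1)), n)))
}

# classical decision for a window, matching detect_feature_quantum semantics
classical_decision <- function(window, kind, params) {
  n <- length(window)
  switch(kind,
    constant = brute_near_constant(window, n %/% 2, params$epsilon),
    increase = brute_sharp_increase(window, params$incr),
    decrease = brute_sharp_decrease(window, params$incr),
    peak     = brute_peak(window, params$incr),
    valley   = brute_valley(window, params$incr))
}

# classical per-pair violation predicates mirrored from the oracle contracts
pair_violates_increase <- function(hi, lo, incr) hi - lo < incr
pair_violates_constant <- function(hi, lo, epsilon) abs(hi - lo) >= epsilon

# uniform-superposition circuit over both value registers of an encoding
# (flag prepared for kickback); covers every (hi, lo) pair at once
all_pairs_prep <- function(enc) {
  qc <- qcircuit(enc$n_qubits)
  qc <- qc_gate(qc, "X", enc$flag)
  qc <- qc_gate(qc, "H", enc$flag)
  for (q in c(enc$v_lo[1:enc$s], enc$v_hi[1:enc$s])) qc <- qc_gate(qc, "H", q)
  qc
}

# marked (hi, lo) pairs of an oracle under the all-pairs superposition
all_pairs_marked <- function(enc, oracle) {
  before <- simulate(all_pairs_prep(enc))
  after <- simulate(oracle, init = before)
  nz <- which(Mod(before) > 1e-9)
  ratio <- Re(after[nz] / before[nz])
  idx <- nz - 1
  dec <- function(reg) {
    vapply(idx, function(i) {
      sum(((i %/% 2^reg) %% 2) * 2^(seq_along(reg) - 1))
    }, numeric(1))
  }
  key <- paste(dec(enc$v_hi), dec(enc$v_lo))
  flips <- tapply(ratio, key, function(r) {
    if (all(r < -0.5)) TRUE else if (all(r > 0.5)) FALSE else NA
  })
  stopifnot(!anyNA(flips))  # phase must be uniform within a pair
  pairs <- do.call(rbind, lapply(strsplit(names(flips), " "), as.numeric))
  data.frame(hi = pairs[, 1], lo = pairs[, 2], marked = as.logical(flips))
}
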