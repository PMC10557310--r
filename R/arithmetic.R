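# Reversible arithmetic building blocks: one-qubit borrow subtraction
# (result and carry), ripple-borrow register subtraction (Cuccaro-style
# adder on the complemented minuend), and two's-complement absolute value.

#' One-bit subtraction truth functions
#'
#' For minuend `q1`, subtrahend `q2` and incoming borrow `carry_in`:
#' `result = q1 XOR q2 XOR carry_in` and the outgoing borrow is
#' `majority(NOT q1, q2, carry_in)`. Vectorized over bits.
#'
#' @param carry_in,q1,q2 bits (0/1).
#' @return bit vector.
#' @export
full_subtractor_result <- function(carry_in, q1, q2) {
  stopifnot(all(c(carry_in, q1, q2) %in% c(0, 1)))
  bitwXor(bitwXor(as.integer(q1), as.integer(q2)), as.integer(carry_in))
}

#' @rdname full_subtractor_result
#' @export
full_subtractor_carry <- function(carry_in, q1, q2) {
  stopifnot(all(c(carry_in, q1, q2) %in% c(0, 1)))
  nq1 <- 1L - as.integer(q1)
  as.integer(nq1 + as.integer(q2) + as.integer(carry_in) >= 2L)
}

#' Reversible one-qubit subtraction circuits
#'
#' Four-qubit circuits over `q0` = incoming borrow, `q1` = minuend, `q2` =
#' subtrahend and `q3` = a fresh output qubit (initially `|0>`), writing the
#' subtraction result (resp. the outgoing borrow) onto `q3`. Synthesized
#' over X/CX/CCX from the truth functions; noiseless simulation reproduces
#' the truth table on all 8 basis inputs.
#'
#' @return a [qcircuit()] over 4 qubits.
#' @export
build_subtractor_result_circuit <- function() {
  qc <- qcircuit(4)
  qc <- qc_gate(qc, "X", 3, controls = 0)   # carry_in
  qc <- qc_gate(qc, "X", 3, controls = 1)   # q1
  qc <- qc_gate(qc, "X", 3, controls = 2)   # q2
  qc
}

#' @rdname build_subtractor_result_circuit
#' @export
build_subtractor_carry_circuit <- function() {
  # majority(~q1, q2, c) = ~q1&q2 XOR ~q1&c XOR q2&c
  qc <- qcircuit(4)
  qc <- qc_gate(qc, "X", 1)
  qc <- qc_gate(qc, "X", 3, controls = c(1, 2))
  qc <- qc_gate(qc, "X", 3, controls = c(1, 0))
  qc <- qc_gate(qc, "X", 1)
  qc <- qc_gate(qc, "X", 3, controls = c(2, 0))
  qc
}

# Cuccaro ripple-carry addition: tgt <- tgt + src (mod 2^w), src and the
# carry-in ancilla c0 restored. Optionally copies the carry-out onto
# `carry_out` between the MAJ and UMA half-chains.
cuccaro_add_gates <- function(qc, src, tgt, c0, carry_out = NULL) {
  w <- length(src)
  stopifnot(length(tgt) == w)
  maj <- function(qc, c, b, a) {
    qc <- qc_gate(qc, "X", b, controls = a)
    qc <- qc_gate(qc, "X", c, controls = a)
    qc_gate(qc, "X", a, controls = c(c, b))
  }
  uma <- function(qc, c, b, a) {
    qc <- qc_gate(qc, "X", a, controls = c(c, b))
    qc <- qc_gate(qc, "X", c, controls = a)
    qc_gate(qc, "X", b, controls = c)
  }
  carries <- c(c0, src[-w])
  for (j in seq_len(w)) qc <- maj(qc, carries[j], tgt[j], src[j])
  if (!is.null(carry_out)) qc <- qc_gate(qc, "X", carry_out, controls = src[w])
  for (j in rev(seq_len(w))) qc <- uma(qc, carries[j], tgt[j], src[j])
  qc
}

# tgt <- tgt - src (mod 2^w, two's complement), via r - b = ~(~r + b).
# If borrow_out is given it receives 1 iff tgt < src (carry of ~r + b).
subtract_in_place_gates <- function(qc, src, tgt, c0, borrow_out = NULL) {
  for (q in tgt) qc <- qc_gate(qc, "X", q)
  qc <- cuccaro_add_gates(qc, src, tgt, c0, carry_out = borrow_out)
  for (q in tgt) qc <- qc_gate(qc, "X", q)
  qc
}

# reg <- reg + C (mod 2^w) for a classical constant C, controlled on the
# (optional) extra control qubits; no ancilla (MCX increment cascades).
add_constant_gates <- function(qc, reg, C, extra_controls = integer()) {
  w <- length(reg)
  C <- C %% 2^w
  for (j in seq_len(w) - 1L) {
    if (bitwAnd(C, 2^j) == 0) next
    # add 2^j: increment the subregister reg[j..w-1]
    for (t in rev(seq(j + 1L, w - 1L, length.out = max(0L, w - 1L - j)))) {
      qc <- qc_gate(qc, "X", reg[t + 1L],
                    controls = c(extra_controls, reg[(j + 1L):t]))
    }
    if (length(extra_controls) > 0) {
      qc <- qc_gate(qc, "X", reg[j + 1L], controls = extra_controls)
    } else {
      qc <- qc_gate(qc, "X", reg[j + 1L])
    }
  }
  qc
}

#' Ripple-borrow register subtraction circuit
#'
#' Circuit over two `s`-bit data registers `a` (qubits `0..s-1`) and `b`
#' (`s..2s-1`), an `s`-bit result register (`2s..3s-1`), a borrow qubit
#' (`3s`) and one carry-chain ancilla (`3s+1`, restored to 0). For
#' classical inputs the result register receives `(a - b) mod 2^s` (two's
#' complement) and the borrow qubit is 1 iff `a < b`; superposed inputs are
#' handled by linearity.
#'
#' @param s register size in bits, `>= 1`.
#' @return a [qcircuit()] over `3s + 2` qubits with a `registers` attribute.
#' @export
build_ripple_subtractor <- function(s) {
  s <- as.integer(s)
  if (s < 1) stop("s must be >= 1", call. = FALSE)
  a <- 0:(s - 1); b <- s + 0:(s - 1); res <- 2L * s + 0:(s - 1)
  borrow <- 3L * s; c0 <- 3L * s + 1L
  qc <- qcircuit(3L * s + 2L)
  for (j in seq_len(s)) qc <- qc_gate(qc, "X", res[j], controls = a[j])
  qc <- subtract_in_place_gates(qc, src = b, tgt = res, c0 = c0,
                                borrow_out = borrow)
  attr(qc, "registers") <- list(a = a, b = b, result = res,
                                borrow = borrow, ancilla = c0)
  qc
}

#' Two's-complement absolute value circuit
#'
#' Circuit over an `s`-bit register (qubits `0..s-1`, sign at `s-1`) plus a
#' helper qubit (`s`). Negative inputs are replaced by their two's
#' complement (complement all bits, add one), positive inputs pass through;
#' the most negative value `-2^(s-1)` has no positive counterpart and maps
#' to itself. The helper records whether the input was negative (it cannot
#' be uncomputed, since the sign is erased from the output).
#'
#' @param s register size in bits, `>= 2`.
#' @return a [qcircuit()] over `s + 1` qubits with a `registers` attribute.
#' @export
build_abs_circuit <- function(s) {
  s <- as.integer(s)
  if (s < 2) stop("s must be >= 2", call. = FALSE)
  reg <- 0:(s - 1); h <- s
  qc <- qcircuit(s + 1L)
  qc <- abs_in_place_gates(qc, reg, h)
  attr(qc, "registers") <- list(value = reg, helper = h)
  qc
}

# |reg| in place using helper qubit h (h <- sign; then conditional negate)
abs_in_place_gates <- function(qc, reg, h) {
  s <- length(reg)
  sign <- reg[s]
  qc <- qc_gate(qc, "X", h, controls = sign)
  for (q in reg) qc <- qc_gate(qc, "X", q, controls = h)
  add_constant_gates(qc, reg, 1, extra_controls = h)
}

# classical two's complement helpers (oracles for tests and verification)
to_twos_complement <- function(x, s) {
  x %% 2^s
}
from_twos_complement <- function(code, s) {
  ifelse(code >= 2^(s - 1), code - 2^s, code)
}

#' Run a circuit on classical register inputs and read registers back
#'
#' Convenience for exercising the arithmetic circuits: packs named register
#' values into an initial bitstring, simulates, and decodes the (basis)
#' output state back into register values. Errors if the output is not a
#' single basis state.
#'
#' @param qc a circuit with a `registers` attribute (qubit index lists).
#' @param inputs named list of classical register values (unsigned codes).
#' @return named list of register values.
#' @export
run_classical <- function(qc, inputs = list()) {
  regs <- attr(qc, "registers")
  if (is.null(regs)) stop("circuit has no register map", call. = FALSE)
  bits <- integer(qc$n_qubits)
  for (nm in names(inputs)) {
    q <- regs[[nm]]
    v <- inputs[[nm]]
    bits[q + 1L] <- (v %/% 2^(seq_along(q) - 1L)) %% 2L
  }
  st <- simulate(qc, bits)
  i <- which(Mod(st) > 1 - 1e-9)
  if (length(i) != 1) stop("output is not a classical basis state", call. = FALSE)
  i <- i - 1L
  out <- lapply(regs, function(q) sum(((i %/% 2^q) %% 2L) * 2^(seq_along(q) - 1L)))
  out
}
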