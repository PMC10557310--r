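# Reversible circuit representation.
#
# Qubit 0 is the least significant bit; printed bitstrings are
# most-significant-first. Gates are {X, H, Z, RY} with an arbitrary set of
# (positive) control qubits, which covers CX/CCX/multi-controlled-X and
# multi-controlled-Z; RY appears only in state preparation (uniform
# superposition over a non-power-of-two number of branches).

GATE_KINDS <- c("X", "H", "Z", "RY")

#' Create an empty reversible circuit
#'
#' @param n_qubits positive integer, at most 24 (dense statevector cap).
#' @return a `qcircuit` object.
#' @export
qcircuit <- function(n_qubits) {
  n_qubits <- as.integer(n_qubits)
  if (n_qubits < 1) stop("n_qubits must be >= 1", call. = FALSE)
  if (n_qubits > 24) {
    stop("dense simulation capped at 24 qubits (requested ", n_qubits, ")",
         call. = FALSE)
  }
  structure(list(n_qubits = n_qubits, gates = list()), class = "qcircuit")
}

#' Append a gate to a circuit
#'
#' @param qc a [qcircuit()].
#' @param kind one of `"X"`, `"H"`, `"Z"`, `"RY"`.
#' @param target target qubit index (0-based).
#' @param controls integer vector of control qubit indices (may be empty).
#' @param param rotation angle for `"RY"`.
#' @return the extended circuit.
#' @export
qc_gate <- function(qc, kind, target, controls = integer(), param = NULL) {
  stopifnot(inherits(qc, "qcircuit"))
  kind <- match.arg(kind, GATE_KINDS)
  target <- as.integer(target)
  controls <- as.integer(controls)
  if (target < 0 || target >= qc$n_qubits ||
      any(controls < 0) || any(controls >= qc$n_qubits)) {
    stop("qubit index out of range", call. = FALSE)
  }
  if (target %in% controls) stop("target must not be a control", call. = FALSE)
  if (anyDuplicated(controls)) stop("duplicate control qubit", call. = FALSE)
  if (kind == "RY" && (is.null(param) || !is.finite(param))) {
    stop("RY needs a finite angle", call. = FALSE)
  }
  qc$gates[[length(qc$gates) + 1L]] <-
    list(kind = kind, target = target, controls = controls, param = param)
  qc
}

# append a list of gates (or another circuit's gates)
qc_extend <- function(qc, gates) {
  if (inherits(gates, "qcircuit")) gates <- gates$gates
  qc$gates <- c(qc$gates, gates)
  qc
}

#' Invert a circuit
#'
#' Reverses the gate list and inverts each gate (X/H/Z and their controlled
#' versions are self-inverse; RY negates its angle). Applying a circuit and
#' then its inverse restores any state.
#'
#' @param qc a [qcircuit()].
#' @return the inverse circuit.
#' @export
circuit_inverse <- function(qc) {
  inv <- qc
  inv$gates <- rev(lapply(qc$gates, function(g) {
    if (g$kind == "RY") g$param <- -g$param
    g
  }))
  inv
}

#' Circuit size measures
#'
#' `circuit_breadth` is the qubit count; `circuit_depth` the length of the
#' longest dependency chain (gates sharing a qubit cannot be parallel).
#'
#' @param qc a [qcircuit()].
#' @return integer.
#' @export
circuit_breadth <- function(qc) qc$n_qubits

#' @rdname circuit_breadth
#' @export
circuit_depth <- function(qc) {
  lvl <- integer(qc$n_qubits)
  for (g in qc$gates) {
    qs <- c(g$target, g$controls) + 1L
    d <- max(lvl[qs]) + 1L
    lvl[qs] <- d
  }
  max(lvl, 0L)
}

#' @export
print.qcircuit <- function(x, ...) {
  cat(sprintf("<qcircuit> %d qubits, %d gates, depth %d\n",
              x$n_qubits, length(x$gates), circuit_depth(x)))
  invisible(x)
}

#' Serialize / deserialize a circuit as line-oriented text
#'
#' First line is a `#`-prefixed JSON metadata header (at least `n_qubits`);
#' each following line is one gate: `KIND [angle] control... target`
#' (`RY` carries its angle right after the kind). Round-trips exactly.
#'
#' @param qc a [qcircuit()].
#' @param path file path.
#' @param meta optional extra metadata list merged into the header.
#' @return `path` invisibly; `read_circuit` returns the circuit (header
#'   metadata in attribute `meta`).
#' @export
write_circuit <- function(qc, path, meta = list()) {
  hdr <- jsonlite::toJSON(c(list(n_qubits = qc$n_qubits), meta),
                          auto_unbox = TRUE, digits = NA)
  lines <- vapply(qc$gates, function(g) {
    parts <- c(g$kind,
               if (g$kind == "RY") sprintf("%.17g", g$param),
               as.character(g$controls), as.character(g$target))
    paste(parts, collapse = " ")
  }, character(1))
  writeLines(c(paste0("# ", hdr), lines), path)
  invisible(path)
}

#' @rdname write_circuit
#' @export
read_circuit <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !startsWith(lines[1], "# ")) {
    stop("missing circuit metadata header", call. = FALSE)
  }
  meta <- jsonlite::fromJSON(sub("^# ", "", lines[1]))
  qc <- qcircuit(meta$n_qubits)
  for (ln in lines[-1]) {
    if (!nzchar(trimws(ln))) next
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    kind <- f[1]
    if (kind == "RY") {
      param <- as.numeric(f[2])
      rest <- as.integer(f[-(1:2)])
    } else {
      param <- NULL
      rest <- as.integer(f[-1])
    }
    target <- rest[length(rest)]
    controls <- rest[-length(rest)]
    qc <- qc_gate(qc, kind, target, controls, param)
  }
  attr(qc, "meta") <- meta
  qc
}
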