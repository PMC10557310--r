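test_that("basic gate semantics: X, H, HH on |0>", {
  st <- simulate(qc_gate(qcircuit(1), "X", 0))
  expect_equal(as.complex(st), c(0 + 0i, 1 + 0i))

  st <- simulate(qc_gate(qcircuit(1), "H", 0))
  expect_equal(as.complex(st), c(1, 1) / sqrt(2) + 0i, tolerance = 1e-12)

  qc <- qc_gate(qc_gate(qcircuit(1), "H", 0), "H", 0)
  expect_equal(as.complex(simulate(qc)), c(1 + 0i, 0 + 0i), tolerance = 1e-12)
})

test_that("circuit validation and the 24-qubit cap", {
  expect_error(qcircuit(25), "capped at 24")
  expect_error(qc_gate(qcircuit(2), "X", 2), "out of range")
  expect_error(qc_gate(qcircuit(2), "X", 0, controls = 0), "control")
})

test_that("measurement: basis states, balanced states, determinism", {
  st <- simulate(qc_gate(qcircuit(2), "X", 1))
  h <- measure(st, shots = 1024, seed = 3)
  expect_equal(h$counts, c("10" = 1024L))

  st <- simulate(qc_gate(qcircuit(1), "H", 0))
  h <- measure(st, shots = 10000, seed = 5)
  expect_true(all(abs(h$counts - 5000) < 5 * sqrt(10000 * 0.25)))

  h2 <- measure(st, shots = 10000, seed = 5)
  expect_identical(h$counts, h2$counts)
  expect_error(measure(structure(c(1 + 0i, 1 + 0i), n_qubits = 1), 10),
               "not normalized")
})

test_that("subtractor truth functions and circuits match the 8-row table", {
  for (r in seq_len(nrow(SUBTRACTION_TABLE))) {
    row <- SUBTRACTION_TABLE[r, ]
    expect_equal(full_subtractor_result(row$c0, row$q1, row$q2), row$result)
    expect_equal(full_subtractor_carry(row$c0, row$q1, row$q2), row$carry)
    init <- c(row$c0, row$q1, row$q2, 0)  # qubit order c0,q1,q2,out
    st_r <- simulate(build_subtractor_result_circuit(), init)
    st_c <- simulate(build_subtractor_carry_circuit(), init)
    # noiseless runs put 100% of 1024 shots on the expected bitstring
    h_r <- measure(st_r, shots = 1024, seed = r)
    h_c <- measure(st_c, shots = 1024, seed = r)
    expect_equal(unname(h_r$counts), 1024L)
    expect_equal(substr(names(h_r$counts), 1, 1), as.character(row$result))
    expect_equal(unname(h_c$counts), 1024L)
    expect_equal(substr(names(h_c$counts), 1, 1), as.character(row$carry))
  }
})

test_that("ripple subtractor matches classical subtraction on all pairs", {
  for (s in c(2, 3)) {
    qc <- build_ripple_subtractor(s)
    for (a in 0:(2^s - 1)) {
      for (b in 0:(2^s - 1)) {
        out <- run_classical(qc, list(a = a, b = b))
        expect_equal(out$result, (a - b) %% 2^s)
        expect_equal(out$borrow, as.numeric(a < b))
        expect_equal(out$a, a)        # inputs preserved
        expect_equal(out$b, b)
        expect_equal(out$ancilla, 0)  # carry chain uncomputed
      }
    }
  }
  # spec examples, s = 3
  qc <- build_ripple_subtractor(3)
  expect_equal(run_classical(qc, list(a = 5, b = 3))[c("result", "borrow")],
               list(result = 2, borrow = 0))
  expect_equal(run_classical(qc, list(a = 3, b = 5))[c("result", "borrow")],
               list(result = 6, borrow = 1))  # 110 = -2 two's complement
})

test_that("absolute-value circuit implements two's complement abs", {
  for (s in c(3, 4)) {
    qc <- build_abs_circuit(s)
    for (x in 0:(2^s - 1)) {
      v <- squigq:::from_twos_complement(x, s)
      expected <- if (v == -2^(s - 1)) v %% 2^s else abs(v)
      expect_equal(run_classical(qc, list(value = x))$value, expected)
    }
  }
})

test_that("subtractor acts linearly on superposed inputs", {
  s <- 2
  qc0 <- build_ripple_subtractor(s)
  regs <- attr(qc0, "registers")
  # put register a into a balanced superposition of all 4 values, b = 2
  qc <- qcircuit(qc0$n_qubits)
  for (q in regs$a) qc <- qc_gate(qc, "H", q)
  qc <- qc_gate(qc, "X", regs$b[2])  # b = 2
  qc <- qc_extend(qc, qc0)
  st <- simulate(qc)
  nz <- which(Mod(st) > 1e-9) - 1
  expect_length(nz, 4)
  expect_equal(Mod(st[nz + 1]), rep(0.5, 4), tolerance = 1e-12)
  for (i in nz) {
    aval <- sum(((i %/% 2^regs$a) %% 2) * 2^(0:(s - 1)))
    rval <- sum(((i %/% 2^regs$result) %% 2) * 2^(0:(s - 1)))
    bor <- (i %/% 2^regs$borrow) %% 2
    # each branch equals the classical single-pair run
    cl <- run_classical(qc0, list(a = aval, b = 2))
    expect_equal(rval, cl$result)
    expect_equal(bor, cl$borrow)
  }
})

test_that("circuits are reversible and norm-preserving", {
  set.seed(21)
  qc <- qcircuit(6)
  for (i in 1:60) {
    kind <- sample(c("X", "H", "Z", "RY"), 1)
    t <- sample(0:5, 1)
    ctrl <- setdiff(sample(0:5, sample(0:2, 1)), t)
    qc <- qc_gate(qc, kind, t, ctrl,
                  param = if (kind == "RY") runif(1, -pi, pi) else NULL)
  }
  amp0 <- complex(real = rnorm(64), imaginary = rnorm(64))
  amp0 <- amp0 / sqrt(sum(Mod(amp0)^2))
  fwd <- simulate(qc, init = amp0)
  expect_equal(sum(Mod(fwd)^2), 1, tolerance = 1e-9)
  back <- simulate(circuit_inverse(qc), init = as.complex(fwd))
  expect_lt(max(Mod(as.complex(back) - amp0)), 1e-9)
})

test_that("breadth/depth count qubits and dependency chains", {
  qc <- qcircuit(3)
  qc <- qc_gate(qc, "H", 0)
  qc <- qc_gate(qc, "H", 1)          # parallel with previous
  qc <- qc_gate(qc, "X", 2, controls = 0)
  expect_equal(circuit_breadth(qc), 3)
  expect_equal(circuit_depth(qc), 2)
})

test_that("circuit text serialization round-trips", {
  qc <- build_subtractor_carry_circuit()
  qc <- qc_gate(qc, "RY", 0, controls = 2, param = 0.12345)
  f <- withr::local_tempfile()
  write_circuit(qc, f, meta = list(label = "carry"))
  back <- read_circuit(f)
  expect_equal(back$n_qubits, qc$n_qubits)
  expect_equal(back$gates, qc$gates)
  expect_equal(attr(back, "meta")$label, "carry")
})

test_that("bit-flip noise: p=0 reduces to noiseless, accuracy decays with p", {
  qc <- build_subtractor_result_circuit()
  init <- "0110"  # q2=1,q1=1,c0=0 (MSB-first: out,q2,q1,c0)
  clean <- measure(simulate(qc, init), shots = 2048, seed = 9)
  noisy0 <- apply_bitflip_noise(qc, init, p = 0, shots = 2048, seed = 9)
  expect_identical(clean$counts, noisy0$counts)

  expected <- names(clean$counts)[which.max(clean$counts)]
  acc <- vapply(c(0, 0.02, 0.05, 0.1), function(p) {
    h <- apply_bitflip_noise(qc, init, p = p, shots = 4096, seed = 31)
    sum(h$counts[names(h$counts) == expected]) / h$shots
  }, numeric(1))
  expect_equal(acc[1], 1)
  expect_true(all(diff(acc) < 0))

  expect_error(apply_bitflip_noise(qc, init, p = 1.5), "\\[0,1\\]")
})

test_that("heavy noise drives a deep circuit to near-uniform", {
  qc <- qcircuit(2)
  for (i in 1:10) {
    qc <- qc_gate(qc, "X", i %% 2, controls = (i + 1) %% 2)
  }
  h <- apply_bitflip_noise(qc, "01", p = 0.5, shots = 8000, seed = 12)
  # each of 4 outcomes ~ uniform within 5 sigma
  expect_true(all(abs(h$counts - 2000) < 5 * sqrt(8000 * 0.25 * 0.75)))
})
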