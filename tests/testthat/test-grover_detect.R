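test_that("pair superposition matches the window-encoding invariant", {
  # n=2: one component, amplitude 1 (up to the flag's (|0>-|1>)/sqrt(2))
  ps <- build_pair_superposition(hi = 3, lo = 1, s = 3)
  st <- simulate(ps$circuit)
  nz <- which(Mod(st) > 1e-9)
  expect_length(nz, 2)  # flag 0/1 halves
  expect_equal(Mod(st[nz]), rep(1 / sqrt(2), 2), tolerance = 1e-12)

  # n=3: two components at 1/sqrt(2) each
  ps <- build_pair_superposition(hi = c(3, 5), lo = c(1, 3), s = 3)
  st <- simulate(ps$circuit)
  expect_length(which(Mod(st) > 1e-9), 4)
  expect_equal(sum(Mod(st)^2), 1, tolerance = 1e-12)

  # n=5, s=3: amplitudes exactly the stated encoding
  hi <- c(1, 3, 5, 2); lo <- c(0, 2, 4, 1)
  ps <- build_pair_superposition(hi, lo, s = 3)
  enc <- ps$encoding
  st <- as.complex(simulate(ps$circuit))
  expected <- complex(length(st))
  for (i in seq_len(enc$k) - 1L) {
    base <- sum(2^enc$index[((i %/% 2^(0:(enc$a - 1))) %% 2) == 1]) +
      sum(2^enc$v_hi[((hi[i + 1] %/% 2^(0:(enc$w - 1))) %% 2) == 1]) +
      sum(2^enc$v_lo[((lo[i + 1] %/% 2^(0:(enc$w - 1))) %% 2) == 1])
    expected[base + 1] <- expected[base + 1] + 1 / sqrt(2 * enc$k)
    expected[base + 2^enc$flag + 1] <- -1 / sqrt(2 * enc$k)
  }
  expect_lt(max(Mod(st - expected)), 1e-12)

  expect_error(build_pair_superposition(8, 0, s = 3), "2\\^s")
})

test_that("oracles mark exactly the violating pairs, exhaustively (s <= 4)", {
  for (s in 2:4) {
    enc <- window_encoding(1, s)
    incrs <- unique(pmax(1, c(1, 2, 2^(s - 1) - 1)))
    for (incr in incrs[incrs < 2^(s - 1)]) {
      tab <- all_pairs_marked(enc, build_increase_oracle(enc, incr))
      expect_identical(tab$marked,
                       pair_violates_increase(tab$hi, tab$lo, incr))
    }
    epss <- unique(c(1, 2, 3, 2^(s - 1)))
    for (eps in epss[epss <= 2^(s - 1)]) {
      tab <- all_pairs_marked(enc, build_near_constant_oracle(enc, eps))
      expect_identical(tab$marked,
                       pair_violates_constant(tab$hi, tab$lo, eps))
    }
  }
})

test_that("windowed oracles mark the classical violating components", {
  # spec examples: [1,3,5] incr 2 -> none; [1,2,5] incr 2 -> component 0
  p135 <- build_pair_superposition(c(3, 5), c(1, 3), s = 3)
  o <- build_increase_oracle(p135$encoding, 2)
  expect_equal(oracle_marked_set(p135$circuit, o, p135$encoding), integer(0))

  p125 <- build_pair_superposition(c(2, 5), c(1, 2), s = 3)
  o <- build_increase_oracle(p125$encoding, 2)
  expect_equal(oracle_marked_set(p125$circuit, o, p125$encoding), 0L)

  # strictly increasing window, incr = 1: nothing marked
  w <- c(0, 2, 3, 6, 7)
  ps <- build_pair_superposition(w[-1], w[-5], s = 3)
  o <- build_increase_oracle(ps$encoding, 1)
  expect_equal(oracle_marked_set(ps$circuit, o, ps$encoding), integer(0))

  # near-constant: P0=4 with neighbours {5,7}, eps=2 -> only the 7 marked
  ps <- build_pair_superposition(c(4, 4), c(5, 7), s = 4)
  o <- build_near_constant_oracle(ps$encoding, 2)
  expect_equal(oracle_marked_set(ps$circuit, o, ps$encoding), 1L)

  # randomized windows across n <= 6, s <= 4: marked set == violating set
  set.seed(14)
  for (rep in 1:25) {
    s <- sample(2:4, 1); n <- sample(2:6, 1)
    w <- sample(0:(2^s - 1), n, replace = TRUE)
    incr <- sample(seq_len(2^(s - 1) - 1), 1)
    ps <- build_pair_superposition(w[-1], w[-n], s)
    o <- build_increase_oracle(ps$encoding, incr)
    expect_equal(oracle_marked_set(ps$circuit, o, ps$encoding),
                 as.integer(which(diff(w) < incr) - 1L))
  }
})

test_that("Grover amplification follows the closed-form rotation", {
  for (cfg in list(c(4, 1), c(4, 2), c(4, 3), c(5, 1), c(5, 2), c(3, 1),
                   c(2, 1))) {
    k <- cfg[1]; m <- cfg[2]
    hi <- c(rep(0, m), rep(7, k - m)); lo <- rep(0, k)  # diff 0 violates incr=2
    ps <- build_pair_superposition(hi, lo, 3)
    orc <- build_increase_oracle(ps$encoding, 2)
    theta <- asin(sqrt(m / k))
    for (j in 0:2) {
      st <- squigq:::grover_state(ps$circuit, orc, ps$encoding, j)
      h <- measure_qubits(st, ps$encoding$index, shots = 8, seed = 1)
      mass <- sum(h$probs[h$values < m])
      expect_equal(mass, sin((2 * j + 1) * theta)^2, tolerance = 1e-9)
    }
  }
})

test_that("one marked of four is measured with certainty after one round", {
  hi <- c(0, 7, 7, 7); lo <- rep(0, 4)
  ps <- build_pair_superposition(hi, lo, 3)
  orc <- build_increase_oracle(ps$encoding, 2)
  res <- grover_search(ps$circuit, orc, ps$encoding, iterations = 1,
                       shots = 512, seed = 2)
  expect_equal(res$candidate, 0L)
  expect_equal(unname(res$histogram$counts), 512L)
})

test_that("no marked component leaves the index distribution uniform", {
  hi <- c(7, 7, 7, 7); lo <- rep(0, 4)
  ps <- build_pair_superposition(hi, lo, 3)
  orc <- build_increase_oracle(ps$encoding, 2)
  for (iters in 0:1) {
    st <- squigq:::grover_state(ps$circuit, orc, ps$encoding, iters)
    h <- measure_qubits(st, ps$encoding$index, shots = 8, seed = 1)
    expect_equal(h$probs, rep(0.25, 4), tolerance = 1e-9)
  }
})

test_that("quantum decisions equal classical decisions, exhaustive n <= 3", {
  params <- feature_params(n = 4, epsilon = 2, incr = 2)
  for (n in 2:3) {
    wins <- all_windows(n, A = 8)
    for (i in seq_len(nrow(wins))) {
      w <- wins[i, ]
      for (kind in c("increase", "decrease", "constant")) {
        got <- detect_feature_quantum(w, kind, params, s = 3, shots = 128,
                                      seed = i)$decision
        expect_identical(got, classical_decision(w, kind, params))
      }
    }
  }
})

test_that("quantum peak/valley decisions are exhaustive at n = 4", {
  params <- feature_params(n = 4, epsilon = 2, incr = 2)
  wins <- all_windows(4, A = 8)
  for (i in seq_len(nrow(wins))) {
    w <- wins[i, ]
    for (kind in c("peak", "valley")) {
      got <- detect_feature_quantum(w, kind, params, s = 3, shots = 64,
                                    seed = i)$decision
      expect_identical(got, classical_decision(w, kind, params))
    }
  }
})

test_that("quantum decisions agree on seeded samples at n in {4,5,6}", {
  # full 8^n sweeps exceed the test budget in a dense simulator; the sample
  # is seeded and mixed across kinds (documented in the methods vignette)
  params <- feature_params(n = 4, epsilon = 2, incr = 2)
  set.seed(77)
  for (rep in 1:60) {
    n <- sample(4:5, 1)
    w <- sample(0:7, n, replace = TRUE)
    for (kind in c("increase", "decrease", "constant")) {
      got <- detect_feature_quantum(w, kind, params, s = 3, shots = 128,
                                    seed = rep)$decision
      expect_identical(got, classical_decision(w, kind, params))
    }
  }
  for (rep in 1:40) {
    w <- sample(0:7, 6, replace = TRUE)
    for (kind in c("peak", "valley")) {
      got <- detect_feature_quantum(w, kind, params, s = 3, shots = 128,
                                    seed = rep)$decision
      expect_identical(got, classical_decision(w, kind, params))
    }
  }
})

test_that("a near-constant violation returns the outlier's index", {
  params <- feature_params(n = 4, epsilon = 2, incr = 2)
  w <- c(4, 4, 4, 7)  # center idx 2 (value 4); outlier neighbour is 7
  res <- detect_feature_quantum(w, "constant", params, s = 3, seed = 3)
  expect_false(res$decision)
  # neighbours of the center in order: 4,4,7 -> violating component 2
  expect_equal(res$counterexample, 2L)
})

test_that("quantum detection is deterministic under a fixed seed", {
  params <- feature_params(n = 4, epsilon = 2, incr = 2)
  w <- c(1, 5, 2, 6)
  a <- detect_feature_quantum(w, "increase", params, s = 3, seed = 11)
  b <- detect_feature_quantum(w, "increase", params, s = 3, seed = 11)
  expect_identical(a$decision, b$decision)
  expect_identical(a$counterexample, b$counterexample)
})

test_that("detector input validation", {
  params <- feature_params(n = 4, epsilon = 2, incr = 2)
  expect_error(detect_feature_quantum(c(9, 1), "increase", params, s = 3),
               "2\\^s")
  expect_error(detect_feature_quantum(c(1, 2, 3), "peak", params, s = 3),
               "even")
  enc <- window_encoding(2, 3)
  expect_error(build_increase_oracle(enc, 0), "incr")
  expect_error(build_increase_oracle(enc, 4), "incr")
  expect_error(build_near_constant_oracle(enc, 0), "epsilon")
})
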