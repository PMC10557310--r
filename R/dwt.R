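# Multilevel periodic orthogonal discrete wavelet transform (Mallat pyramid).
#
# The analysis step computes, for scaling filter g of length L and wavelet
# filter h[m] = (-1)^m g[L-1-m] (quadrature mirror),
#   a[k] = sum_m g[m] x[(2k+m) mod N],   d[k] = sum_m h[m] x[(2k+m) mod N].
# Because the filter bank is orthonormal, the synthesis step is the adjoint
# and reconstruction is exact to machine precision.

dwt_filters <- list(
  # Haar: the analytically checkable case ((1,1) -> (sqrt(2), 0)).
  haar = c(1, 1) / sqrt(2),
  # Daubechies extremal-phase, 4 taps.
  d4 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
  # Least-asymmetric (symmlet) 8 taps, the waveslim default for squiggle work.
  la8 = c(-0.0757657147893407, -0.0296355276459541, 0.4976186676324578,
          0.8037387518052163, 0.2978577956055422, -0.0992195435769354,
          -0.0126039672622612, 0.0322231006040713)
)

get_dwt_filter <- function(filter_id) {
  g <- dwt_filters[[filter_id]]
  if (is.null(g)) {
    stop("unknown wavelet filter ", deparse(filter_id),
         "; available: ", paste(names(dwt_filters), collapse = ", "),
         call. = FALSE)
  }
  L <- length(g)
  list(g = g, h = (-1)^(seq_len(L) - 1) * rev(g), L = L)
}

dwt_step <- function(x, f) {
  N <- length(x)
  half <- N %/% 2L
  k2 <- 2L * (seq_len(half) - 1L)
  a <- numeric(half); d <- numeric(half)
  for (m in seq_len(f$L) - 1L) {
    xi <- x[(k2 + m) %% N + 1L]
    a <- a + f$g[m + 1L] * xi
    d <- d + f$h[m + 1L] * xi
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d, f) {
  half <- length(a)
  N <- 2L * half
  x <- numeric(N)
  k2 <- 2L * (seq_len(half) - 1L)
  for (m in seq_len(f$L) - 1L) {
    # for fixed m the targets (2k+m) mod N are pairwise distinct (stride 2, N even)
    idx <- (k2 + m) %% N + 1L
    x[idx] <- x[idx] + f$g[m + 1L] * a + f$h[m + 1L] * d
  }
  x
}

#' Forward multilevel discrete wavelet transform
#'
#' Periodic (circular) orthogonal DWT. The output has the same length as the
#' input and is laid out coarsest-first: `[A_J, D_J, D_(J-1), ..., D_1]`
#' where `A_J` is the level-`J` approximation block and `D_j` the level-`j`
#' detail block.
#'
#' Inputs whose length is not a multiple of `2^levels` are truncated to the
#' largest such multiple (with a message).
#'
#' @param x numeric vector.
#' @param levels number of decomposition levels, `>= 1`.
#' @param filter_id one of `"haar"`, `"d4"`, `"la8"` (default).
#' @return numeric vector of transform coefficients, coarsest-first layout,
#'   with attributes `levels` and `filter_id`.
#' @export
forward_dwt <- function(x, levels = 2L, filter_id = "la8") {
  levels <- as.integer(levels)
  if (levels < 1) stop("levels must be >= 1", call. = FALSE)
  f <- get_dwt_filter(filter_id)
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("non-finite values in input", call. = FALSE)
  x <- dwt_truncate(x, levels)
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    st <- dwt_step(a, f)
    a <- st$a
    details[[j]] <- st$d
  }
  # layout: A_J, then D_J (coarsest detail) ... D_1 (finest)
  out <- c(a, unlist(details[seq(levels, 1)], use.names = FALSE))
  structure(out, levels = levels, filter_id = filter_id)
}

#' Inverse multilevel discrete wavelet transform
#'
#' Interprets `v` as a coefficient vector in the coarsest-first layout of
#' [forward_dwt()] and reconstructs the time-domain sequence. Length is
#' preserved; `forward_dwt(inverse_dwt(v))` recovers `v` to machine
#' precision. This is also the dimensionality-reduction step applied to raw
#' squiggle data (the raw trace itself is read as a coefficient vector).
#'
#' @inheritParams forward_dwt
#' @param v numeric coefficient vector.
#' @return numeric vector of the same (possibly truncated) length, with
#'   attributes `levels` and `filter_id`.
#' @export
inverse_dwt <- function(v, levels = 2L, filter_id = "la8") {
  levels <- as.integer(levels)
  if (levels < 1) stop("levels must be >= 1", call. = FALSE)
  f <- get_dwt_filter(filter_id)
  v <- as.numeric(v)
  if (any(!is.finite(v))) stop("non-finite values in input", call. = FALSE)
  v <- dwt_truncate(v, levels)
  N <- length(v)
  if (N == 0) return(structure(numeric(0), levels = levels, filter_id = filter_id))
  nA <- N / 2^levels
  a <- v[seq_len(nA)]
  pos <- nA
  for (j in seq(levels, 1)) {
    nD <- N / 2^j
    d <- v[pos + seq_len(nD)]
    pos <- pos + nD
    a <- idwt_step(a, d, f)
  }
  structure(a, levels = levels, filter_id = filter_id)
}

dwt_truncate <- function(x, levels) {
  block <- 2^levels
  keep <- (length(x) %/% block) * block
  if (keep < length(x)) {
    message(sprintf("dwt: truncating input from %d to %d samples (multiple of 2^%d)",
                    length(x), keep, levels))
    x <- x[seq_len(keep)]
  }
  x
}
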