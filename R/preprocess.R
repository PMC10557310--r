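#' Duplicate every sample of a signal
#'
#' Records each data point twice, doubling the length. This strengthens the
#' local feature variation that survives the wavelet reduction step.
#'
#' @param signal numeric vector or [squiggle_signal()].
#' @return vector of length `2 * length(signal)` with
#'   `out[2i] == out[2i+1] == in[i]`.
#' @export
duplicate_samples <- function(signal) {
  x <- as.numeric(signal)
  rep(x, each = 2L)
}

#' Smallest register size covering a value set
#'
#' The number of bits/qubits `s` such that `2^s >= num_values`; e.g. 50
#' distinct values need `s = 6` (`2^6 = 64`), 400 need `s = 9`
#' (`2^9 = 512`).
#'
#' @param num_values count of distinct representable values, `>= 1`.
#' @return integer register size in bits.
#' @export
required_register_size <- function(num_values) {
  if (length(num_values) != 1 || !is.finite(num_values) || num_values < 1) {
    stop("num_values must be a single integer >= 1", call. = FALSE)
  }
  num_values <- as.numeric(num_values)
  s <- 0L
  while (2^s < num_values) s <- s + 1L
  s
}

#' Clamp and quantize a transformed signal
#'
#' In-range values are rounded half-away-from-zero and offset so that `lo`
#' maps to code 0; anything falling outside `[lo, hi)` is recorded as the
#' sentinel (the largest code). With the default `[-25, 25)` this yields 50
#' in-range codes plus the sentinel, hence register size `s = 6`.
#'
#' @param values numeric vector (e.g. [inverse_dwt()] output).
#' @param lo,hi clamp bounds, `lo < hi` (integers; half-open `[lo, hi)`).
#' @return a `quantized_signal` list: `codes` (integers in `[0, 2^s)`),
#'   `s`, `sentinel`, `lo`, `hi`, `n_codes`.
#' @export
clamp_quantize <- function(values, lo = -25, hi = 25) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("non-finite values", call. = FALSE)
  if (!(lo < hi)) stop("need lo < hi", call. = FALSE)
  lo <- as.integer(lo); hi <- as.integer(hi)
  rounded <- sign(values) * floor(abs(values) + 0.5)   # half away from zero
  n_in <- hi - lo                                       # codes 0 .. n_in-1
  sentinel <- n_in                                      # reserved top code
  codes <- as.integer(rounded) - lo
  out_of_range <- rounded < lo | rounded >= hi
  codes[out_of_range] <- sentinel
  s <- required_register_size(n_in + 1L)
  structure(list(codes = as.integer(codes), s = s, sentinel = sentinel,
                 lo = lo, hi = hi, n_codes = n_in + 1L),
            class = "quantized_signal")
}

#' @export
print.quantized_signal <- function(x, ...) {
  cat(sprintf("<quantized_signal> %d codes, s=%d bits, sentinel=%d (%.1f%% of codes), clamp [%d,%d)\n",
              length(x$codes), x$s, x$sentinel,
              100 * mean(x$codes == x$sentinel), x$lo, x$hi))
  invisible(x)
}

#' Full squiggle dimensionality-reduction pipeline
#'
#' duplicate samples -> inverse DWT (`levels`, `filter_id`) -> clamp and
#' quantize to `[lo, hi)`.
#'
#' @inheritParams forward_dwt
#' @inheritParams clamp_quantize
#' @param signal raw squiggle readings.
#' @param duplicate record each point twice first (default `TRUE`).
#' @return a `quantized_signal` (see [clamp_quantize()]) with the
#'   intermediate `transformed` values attached as an element.
#' @export
preprocess_squiggle <- function(signal, duplicate = TRUE, levels = 2L,
                                filter_id = "la8", lo = -25, hi = 25) {
  x <- as.numeric(signal)
  if (duplicate) x <- duplicate_samples(x)
  tr <- inverse_dwt(x, levels = levels, filter_id = filter_id)
  q <- clamp_quantize(tr, lo = lo, hi = hi)
  q$transformed <- as.numeric(tr)
  q
}
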