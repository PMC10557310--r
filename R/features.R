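#' Detector thresholds for squiggle features
#'
#' @param n window length (consecutive values). `n >= 2`; even for
#'   peak/valley (the window splits into two halves of `n/2`).
#' @param epsilon near-to-constant tolerance, `> 0` (current units): a
#'   window is near-constant when every value is strictly within `epsilon`
#'   of the center value.
#' @param incr minimum significant increase, `> 0`: a sharp increase needs
#'   every consecutive difference `>= incr`.
#' @param mode neighbour topology for near-constant: `"centered"` (default;
#'   center value is the middle sample), `"left"` (center is the last
#'   sample, neighbours precede it) or `"right"` (center first).
#' @return a `feature_params` list.
#' @export
feature_params <- function(n = 4L, epsilon = 2, incr = 2,
                           mode = c("centered", "left", "right")) {
  n <- as.integer(n)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (!is.finite(epsilon) || epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (!is.finite(incr) || incr <= 0) stop("incr must be > 0", call. = FALSE)
  structure(list(n = n, epsilon = epsilon, incr = incr,
                 mode = match.arg(mode)),
            class = "feature_params")
}

center_index <- function(n, mode) {
  switch(mode,
         centered = n %/% 2L,     # 0-based middle sample
         left = n - 1L,
         right = 0L)
}

#' Near-to-constant window test
#'
#' True iff `|window[center] - window[i]| < epsilon` for every other `i`
#' (strict inequality).
#'
#' @param window numeric vector.
#' @param center 0-based index of the reference value `P0`.
#' @param epsilon tolerance, `> 0`.
#' @return logical scalar.
#' @export
is_near_constant <- function(window, center, epsilon) {
  if (length(window) == 0) stop("empty window", call. = FALSE)
  if (center < 0 || center >= length(window)) {
    stop("center out of range", call. = FALSE)
  }
  p0 <- window[center + 1L]
  all(abs(p0 - window[-(center + 1L)]) < epsilon)
}

#' Sharp increase / decrease window tests
#'
#' A window is a sharp increase when every consecutive difference
#' `window[i+1] - window[i] >= incr` (non-strict); a sharp decrease when
#' every consecutive difference `<= -incr`.
#'
#' @param window numeric vector of length `>= 2`.
#' @param incr threshold difference.
#' @return logical scalar.
#' @export
is_sharp_increase <- function(window, incr) {
  if (length(window) < 2) stop("window length must be >= 2", call. = FALSE)
  all(diff(window) >= incr)
}

#' @rdname is_sharp_increase
#' @export
is_sharp_decrease <- function(window, incr) {
  if (length(window) < 2) stop("window length must be >= 2", call. = FALSE)
  all(diff(window) <= -incr)
}

#' Peak / valley window tests
#'
#' For an even window length `n >= 4`: a peak is a sharp increase over the
#' first `n/2` values followed by a sharp decrease over the last `n/2`; a
#' valley is the mirror image.
#'
#' @inheritParams is_sharp_increase
#' @return logical scalar.
#' @export
is_peak <- function(window, incr) {
  n <- length(window)
  if (n < 4 || n %% 2L != 0L) stop("peak window length must be even and >= 4", call. = FALSE)
  h <- n %/% 2L
  is_sharp_increase(window[1:h], incr) &&
    is_sharp_decrease(window[(h + 1L):n], incr)
}

#' @rdname is_peak
#' @export
is_valley <- function(window, incr) {
  n <- length(window)
  if (n < 4 || n %% 2L != 0L) stop("valley window length must be even and >= 4", call. = FALSE)
  h <- n %/% 2L
  is_sharp_decrease(window[1:h], incr) &&
    is_sharp_increase(window[(h + 1L):n], incr)
}

window_detect <- function(window, kind, params) {
  switch(kind,
    constant = is_near_constant(window, center_index(length(window), params$mode),
                                params$epsilon),
    increase = is_sharp_increase(window, params$incr),
    decrease = is_sharp_decrease(window, params$incr),
    peak     = is_peak(window, params$incr),
    valley   = is_valley(window, params$incr),
    stop("unknown feature kind ", kind, call. = FALSE))
}

merge_runs <- function(starts, n) {
  # maximal-run merge of equal-length windows into [start, end) intervals
  if (length(starts) == 0) return(NULL)
  starts <- sort(starts)
  brk <- c(0L, which(diff(starts) > n), length(starts))
  lapply(seq_len(length(brk) - 1L), function(i) {
    run <- starts[(brk[i] + 1L):brk[i + 1L]]
    c(start = run[1], end = run[length(run)] + n, count = length(run))
  })
}

#' Scan a signal with the classical feature detectors
#'
#' Slides every detector across the trace; overlapping or abutting windows
#' of the same kind merge into maximal-run interval calls. Peak/valley
#' calls take precedence: increase/decrease calls overlapping them are
#' dropped from the report.
#'
#' @param signal numeric vector or [squiggle_signal()].
#' @param params a [feature_params()].
#' @param kinds which detectors to run (default all; peak/valley need even
#'   `n`).
#' @param detector window predicate used for each kind; the default is the
#'   classical rule set. Override (e.g. with a quantum detector wrapper) to
#'   reuse the scanning/merging logic.
#' @return a [feature_calls()] data frame (`score` = number of firing
#'   windows merged into the call).
#' @export
scan_features <- function(signal, params, kinds = FEATURE_KINDS,
                          detector = window_detect) {
  x <- as.numeric(signal)
  n <- params$n
  if (n > length(x)) stop("window length exceeds signal length", call. = FALSE)
  kinds <- match.arg(kinds, FEATURE_KINDS, several.ok = TRUE)
  if (n %% 2L != 0L) kinds <- setdiff(kinds, c("peak", "valley"))
  starts0 <- 0:(length(x) - n)   # 0-based window starts
  calls <- list()
  for (kind in kinds) {
    fired <- starts0[vapply(starts0, function(st) {
      isTRUE(detector(x[(st + 1L):(st + n)], kind, params))
    }, logical(1))]
    for (run in merge_runs(fired, n)) {
      calls[[length(calls) + 1L]] <-
        data.frame(start = run[["start"]], end = run[["end"]], kind = kind,
                   score = run[["count"]], stringsAsFactors = FALSE)
    }
  }
  if (length(calls) == 0) return(feature_calls())
  df <- do.call(rbind, calls)
  pv <- df[df$kind %in% c("peak", "valley"), , drop = FALSE]
  if (nrow(pv) > 0) {
    keep <- vapply(seq_len(nrow(df)), function(i) {
      if (!df$kind[i] %in% c("increase", "decrease")) return(TRUE)
      !any(df$start[i] < pv$end & pv$start < df$end[i])
    }, logical(1))
    df <- df[keep, , drop = FALSE]
  }
  feature_calls(df$kind, df$start, df$end, df$score)
}

#' Compare feature calls with planted annotations
#'
#' Overlap-based interval matching: an annotation is recovered when a call
#' of the same kind overlaps it; a call is correct when it overlaps a
#' same-kind annotation.
#'
#' @param calls,truth [feature_calls()] data frames.
#' @return list with `precision`, `recall`, counts.
#' @export
evaluate_calls <- function(calls, truth) {
  overlaps <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i) {
      any(b$kind == a$kind[i] & a$start[i] < b$end & b$start < a$end[i])
    }, logical(1))
  }
  tp_calls <- if (nrow(calls)) sum(overlaps(calls, truth)) else 0L
  hit_truth <- if (nrow(truth)) sum(overlaps(truth, calls)) else 0L
  list(precision = if (nrow(calls)) tp_calls / nrow(calls) else NA_real_,
       recall = if (nrow(truth)) hit_truth / nrow(truth) else NA_real_,
       n_calls = nrow(calls), n_truth = nrow(truth),
       matched_calls = tp_calls, recovered_truth = hit_truth)
}
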