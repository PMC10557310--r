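#' Squiggle signal container
#'
#' A squiggle is the time-ordered sequence of picoampere-scale current
#' readings a nanopore sequencer records while a nucleic-acid strand
#' translocates the pore. Raw readings are integers, by default within
#' `[300, 700]`; transformed signals (wavelet output) may be real-valued.
#'
#' @param readings numeric vector of current readings.
#' @param raw_range length-2 numeric, the admissible raw range; `NULL` to
#'   skip range checking (used for transformed/real-valued signals).
#' @return an object of class `squiggle_signal`: the readings vector with a
#'   `raw_range` attribute.
#' @export
squiggle_signal <- function(readings, raw_range = NULL) {
  readings <- as.numeric(readings)
  if (any(!is.finite(readings))) {
    stop("squiggle readings must all be finite", call. = FALSE)
  }
  if (!is.null(raw_range)) {
    stopifnot(length(raw_range) == 2, raw_range[1] < raw_range[2])
    bad <- readings < raw_range[1] | readings > raw_range[2]
    if (any(bad)) {
      stop(sprintf("%d reading(s) outside raw range [%g, %g]",
                   sum(bad), raw_range[1], raw_range[2]), call. = FALSE)
    }
  }
  structure(readings, class = "squiggle_signal", raw_range = raw_range)
}

#' @export
print.squiggle_signal <- function(x, ...) {
  cat(sprintf("<squiggle_signal> length %d", length(x)))
  if (length(x) > 0) {
    cat(sprintf(", range [%g, %g]", min(x), max(x)))
  }
  cat("\n")
  invisible(x)
}

FEATURE_KINDS <- c("constant", "increase", "decrease", "peak", "valley")

#' Feature annotations and calls
#'
#' Intervals are 0-based, half-open `[start, end)`. `kind` is one of
#' `"constant"`, `"increase"`, `"decrease"`, `"peak"`, `"valley"`.
#'
#' @param kind character vector of feature kinds.
#' @param start,end integer vectors, 0-based half-open bounds.
#' @param score optional numeric score per call (defaults to `NA`).
#' @return a `data.frame` with columns `start`, `end`, `kind`, `score`,
#'   sorted by `start`.
#' @export
feature_calls <- function(kind = character(), start = integer(),
                          end = integer(), score = NA_real_) {
  kind <- as.character(kind)
  if (!all(kind %in% FEATURE_KINDS)) {
    stop("unknown feature kind: ",
         paste(setdiff(kind, FEATURE_KINDS), collapse = ", "), call. = FALSE)
  }
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0) || any(end <= start)) {
    stop("feature intervals must satisfy 0 <= start < end", call. = FALSE)
  }
  df <- data.frame(start = start, end = end, kind = kind,
                   score = rep_len(as.numeric(score), length(kind)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a squiggle trace from a plain-text file
#'
#' @param path file path; one value per line (dialect `"one-per-line"`) or a
#'   chosen column of a TSV (dialect `"tsv-column"`). Lines starting with `#`
#'   are comments.
#' @param dialect `"one-per-line"` (default) or `"tsv-column"`.
#' @param column for `"tsv-column"`, the 1-based column index.
#' @param raw_range optional range check forwarded to [squiggle_signal()].
#' @return a [squiggle_signal()].
#' @export
read_signal <- function(path, dialect = c("one-per-line", "tsv-column"),
                        column = 1L, raw_range = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) return(squiggle_signal(numeric(0), raw_range))
  tok <- if (dialect == "one-per-line") {
    trimws(lines)
  } else {
    vapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
      if (length(f) < column) NA_character_ else f[[column]]
    }, character(1))
  }
  vals <- suppressWarnings(as.numeric(tok))
  if (any(is.na(vals))) {
    bad <- which(is.na(vals))[1]
    stop(sprintf("malformed value %s at line %d of %s",
                 deparse(tok[bad]), lineno[bad], path), call. = FALSE)
  }
  squiggle_signal(vals, raw_range)
}

#' Write a squiggle trace (or any numeric sequence) to a plain-text file
#'
#' Integers are written exactly; reals with 15 significant digits so that a
#' read/write round trip errs by less than 1e-9.
#'
#' @param signal numeric vector or [squiggle_signal()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  x <- as.numeric(signal)
  txt <- ifelse(x == round(x) & abs(x) < 2^52,
                sprintf("%d", as.integer(round(pmin(pmax(x, -2^31 + 1), 2^31 - 1)))),
                sprintf("%.15g", x))
  # large exact integers beyond int range: fall back to %.15g
  big <- x == round(x) & abs(x) >= 2^31
  txt[big] <- sprintf("%.15g", x[big])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(txt, con)
  invisible(path)
}

#' Read / write feature call tables
#'
#' TSV with header `start end kind score`, 0-based half-open intervals.
#'
#' @param path file path.
#' @return `read_calls`: a [feature_calls()] data frame.
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  feature_calls(df$kind, df$start, df$end, df$score)
}

#' @rdname read_calls
#' @param calls a [feature_calls()] data frame.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls[, c("start", "end", "kind", "score")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a synthetic squiggle plan segment table
#'
#' @param kind segment kinds (see [feature_calls()]).
#' @param length segment lengths (samples). Peak/valley lengths must be even.
#' @param level base current level per segment.
#' @param slope per-sample gradient for ramp-like segments (ignored for
#'   `constant`; for `valley` the dip is `level - slope * depth`).
#' @return a `squiggle_plan` data frame.
#' @export
squiggle_plan <- function(kind, length, level, slope = 0) {
  kind <- as.character(kind)
  if (!all(kind %in% FEATURE_KINDS)) {
    stop("unknown segment kind", call. = FALSE)
  }
  length <- as.integer(length)
  if (any(length <= 0)) stop("segment lengths must be positive", call. = FALSE)
  if (any(kind %in% c("peak", "valley") & length %% 2L != 0L)) {
    stop("peak/valley segment lengths must be even", call. = FALSE)
  }
  df <- data.frame(kind = kind, length = length,
                   level = as.numeric(level),
                   slope = rep_len(as.numeric(slope), base::length(kind)),
                   stringsAsFactors = FALSE)
  class(df) <- c("squiggle_plan", class(df))
  df
}

segment_values <- function(kind, len, level, slope) {
  i <- seq_len(len) - 1
  switch(kind,
    constant = rep(level, len),
    increase = level + slope * i,
    decrease = level - slope * i,
    peak     = level + slope * pmin(i, len - 1 - i),
    valley   = level - slope * pmin(i, len - 1 - i),
    stop("unknown segment kind ", kind))
}

#' Generate a synthetic squiggle with planted, annotated features
#'
#' Emulates a raw nanopore current trace as piecewise near-constant segments
#' with planted sharp ramps, peaks and valleys, plus additive rounded
#' Gaussian noise clipped to `value_range`. With `sd = 0` the output equals
#' the noiseless plan exactly, and every planted annotation is recoverable
#' by the classical detectors.
#'
#' @param plan a [squiggle_plan()] data frame.
#' @param sd noise standard deviation (current units), `>= 0`.
#' @param seed integer seed; the call is deterministic given the seed.
#' @param value_range clip range for the emitted readings (default the raw
#'   squiggle range `c(300, 700)`); `NULL` disables clipping.
#' @param integer_readings round readings to integers (default `TRUE`, as
#'   sequencers record integer currents).
#' @return a list with elements `signal` (a [squiggle_signal()]), `truth`
#'   (a [feature_calls()] annotation table covering every segment), and
#'   `seed`.
#' @export
generate_squiggle <- function(plan, sd = 0, seed = 1L,
                              value_range = c(300, 700),
                              integer_readings = TRUE) {
  stopifnot(inherits(plan, "squiggle_plan"))
  if (!is.finite(sd) || sd < 0) stop("sd must be >= 0", call. = FALSE)
  vals <- unlist(lapply(seq_len(nrow(plan)), function(r) {
    segment_values(plan$kind[r], plan$length[r], plan$level[r], plan$slope[r])
  }), use.names = FALSE)
  if (is.null(vals)) vals <- numeric(0)
  if (sd > 0) {
    vals <- with_seed(seed, vals + stats::rnorm(length(vals), 0, sd))
  }
  if (integer_readings) vals <- round(vals)
  if (!is.null(value_range)) {
    vals <- pmin(pmax(vals, value_range[1]), value_range[2])
  }
  ends <- cumsum(plan$length)
  starts <- c(0L, ends[-length(ends)])
  truth <- feature_calls(plan$kind, starts, ends)
  list(signal = squiggle_signal(vals, raw_range = NULL),
       truth = truth, seed = as.integer(seed))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# `seed` is forced first: a lazily evaluated, RNG-consuming seed expression
# would otherwise be rolled back with the snapshot and repeat itself.
with_seed <- function(seed, expr) {
  seed <- as.integer(seed)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
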