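`%||%` <- function(a, b) if (is.null(a)) b else a

as_date <- function(x) {
  if (inherits(x, "Date")) x else as.Date(x)
}

#' Intersection of two closed day windows
#'
#' @param s1,e1,s2,e2 `Date` endpoints (inclusive).
#' @return `c(start, end)` as Dates, or `NULL` when the windows are disjoint.
#' @keywords internal
overlap_window <- function(s1, e1, s2, e2) {
  s <- max(as_date(s1), as_date(s2))
  e <- min(as_date(e1), as_date(e2))
  if (s > e) NULL else c(s, e)
}

# deterministic substream seeds derived from a single global seed; kept
# small so seed arithmetic stays well inside .Machine$integer.max
sub_seed <- function(seed, stream, index = 0L) {
  (as.integer(seed) * 97L + stream * 7919L + index) %% 2147483647L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
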