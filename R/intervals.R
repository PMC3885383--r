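#' Merged half-open interval sets
#'
#' A `warning_set` is a set of disjoint, sorted, half-open intervals
#' `[start_s, end_s)` in seconds from record start. Overlapping or abutting
#' input intervals are merged on construction, so a single prolonged warning
#' replaces any run of consecutive triggered warnings.
#'
#' @param start_s,end_s numeric vectors of interval starts and ends (seconds).
#' @return An object of class `warning_set`: a data frame with columns
#'   `start_s` and `end_s`, sorted and disjoint.
#' @examples
#' warning_set(c(0, 3600), c(5400, 9000))  # overlapping -> one interval
#' @export
warning_set <- function(start_s = numeric(), end_s = numeric()) {
  stopifnot(length(start_s) == length(end_s))
  keep <- end_s > start_s
  m <- merge_intervals(start_s[keep], end_s[keep])
  structure(m, class = c("warning_set", "data.frame"))
}

#' @export
print.warning_set <- function(x, ...) {
  cat(sprintf("<warning_set> %d interval(s), total %.1f s\n",
              nrow(x), total_interval_length(x)))
  if (nrow(x) > 0L) print(as.data.frame(x), ...)
  invisible(x)
}

# Merge possibly overlapping/abutting half-open intervals into a disjoint,
# sorted set. Abutting intervals ([a,b), [b,c)) are merged.
merge_intervals <- function(start_s, end_s) {
  if (length(start_s) == 0L) {
    return(data.frame(start_s = numeric(), end_s = numeric()))
  }
  o <- order(start_s, end_s)
  s <- start_s[o]
  e <- end_s[o]
  # running maximum of ends; a new interval begins where start exceeds it
  emax <- cummax(e)
  new_run <- c(TRUE, s[-1L] > emax[-length(emax)])
  grp <- cumsum(new_run)
  data.frame(start_s = s[new_run],
             end_s = as.numeric(tapply(e, grp, max)),
             row.names = NULL)
}

#' Total length of an interval set
#' @param iv a [warning_set()] or data frame of disjoint half-open
#'   intervals with columns `start_s`, `end_s`.
#' @return Total covered time in seconds.
#' @export
total_interval_length <- function(iv) {
  if (nrow(iv) == 0L) return(0)
  sum(iv$end_s - iv$start_s)
}

# Length of the intersection of two disjoint sorted interval sets.
intersect_interval_length <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  tot <- 0
  j <- 1L
  for (i in seq_len(nrow(a))) {
    while (j <= nrow(b) && b$end_s[j] <= a$start_s[i]) j <- j + 1L
    k <- j
    while (k <= nrow(b) && b$start_s[k] < a$end_s[i]) {
      tot <- tot + max(0, min(a$end_s[i], b$end_s[k]) -
                          max(a$start_s[i], b$start_s[k]))
      k <- k + 1L
    }
  }
  tot
}

# Clip a disjoint sorted interval set to [lo, hi).
clip_intervals <- function(iv, lo, hi) {
  s <- pmax(iv$start_s, lo)
  e <- pmin(iv$end_s, hi)
  keep <- e > s
  data.frame(start_s = s[keep], end_s = e[keep], row.names = NULL)
}

# Indices i with lo <= x[i] < hi for sorted x (half-open range query).
which_in_range <- function(x_sorted, lo, hi) {
  i1 <- findInterval(lo, x_sorted, left.open = TRUE) + 1L
  i2 <- findInterval(hi, x_sorted, left.open = TRUE)
  if (i2 >= i1) seq.int(i1, i2) else integer(0)
}
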