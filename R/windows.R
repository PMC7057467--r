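#' Build age-contiguous sliding windows over samples
#'
#' Pools age-adjacent samples into overlapping windows so that correlations
#' and standard deviations are estimable at every time step even when a
#' sampling period holds only 1-5 samples. Windows start at sample indices
#' `1, 1+step, 1+2*step, ...`; if the stepping would leave a trailing
#' stretch uncovered, a final window anchored at `S - window_size + 1` is
#' appended (no window is ever smaller than `window_size`). Each window is
#' labelled by the median age of its members.
#'
#' @param ds An `ExpressionDataset` whose samples are sorted by ascending
#'   age (as produced by [filter_by_age()]).
#' @param window_size Samples per window; at least 3 (Pearson correlation
#'   needs three points).
#' @param step Offset between consecutive window starts, in `[1, window_size]`.
#'
#' @return An object of class `sample_windows`: a list of windows, each a
#'   list with `index`, `sample_ids` and `age_label`.
#' @export
build_windows <- function(ds, window_size = 4, step = 1) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  window_size <- as.integer(window_size)
  step <- as.integer(step)
  if (window_size < 3) stop("`window_size` must be >= 3")
  if (step < 1 || step > window_size) stop("`step` must lie in [1, window_size]")
  ages <- ds$meta$age_years
  S <- length(ages)
  if (S < window_size) {
    stop(sprintf("need at least %d samples, have %d", window_size, S))
  }
  if (is.unsorted(ages)) stop("samples must be sorted by ascending age")

  last <- S - window_size + 1L
  starts <- seq.int(1L, last, by = step)
  if (starts[length(starts)] != last) starts <- c(starts, last)
  starts <- unique(starts)

  windows <- lapply(seq_along(starts), function(i) {
    members <- starts[i]:(starts[i] + window_size - 1L)
    list(
      index = i,
      start = starts[i],
      sample_ids = ds$meta$sample_id[members],
      age_label = stats::median(ages[members])
    )
  })
  structure(windows, class = "sample_windows")
}

#' @export
print.sample_windows <- function(x, ...) {
  cat(sprintf("%d sliding windows of %d samples\n",
              length(x), length(x[[1]]$sample_ids)))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.sample_windows <- function(x, ...) {
  data.frame(
    window_index = vapply(x, `[[`, integer(1), "index"),
    start = vapply(x, `[[`, integer(1), "start"),
    n = vapply(x, function(w) length(w$sample_ids), integer(1)),
    age_label = vapply(x, `[[`, numeric(1), "age_label")
  )
}

# Resolve a window argument to a character vector of sample ids.
window_sample_ids <- function(window) {
  if (is.character(window)) return(window)
  if (is.list(window) && !is.null(window$sample_ids)) return(window$sample_ids)
  stop("`window` must be a window from build_windows() or a vector of sample ids")
}
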