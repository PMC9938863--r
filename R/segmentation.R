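#' Construct a syllable segmentation
#'
#' An ordered set of non-overlapping, half-open sample-index intervals
#' `[start, end)` (0-based) marking syllables within one signal.
#'
#' @param starts integer vector of 0-based interval start samples.
#' @param ends integer vector of end samples (exclusive), same length.
#' @param n_samples optional signal length used to validate that all
#'   intervals lie within the signal.
#' @return an object of class `syllable_segmentation` (a data.frame with
#'   columns `start` and `end`).
#' @examples
#' syllable_segmentation(c(0, 1000), c(800, 1900), n_samples = 2000)
#' @export
syllable_segmentation <- function(starts, ends, n_samples = NULL) {
  starts <- as.integer(round(starts))
  ends <- as.integer(round(ends))
  if (length(starts) != length(ends))
    stop("`starts` and `ends` must have the same length")
  if (length(starts)) {
    if (any(ends <= starts)) stop("every interval must be non-empty (end > start)")
    if (any(starts < 0)) stop("interval starts must be >= 0")
    if (is.unsorted(starts, strictly = TRUE)) stop("intervals must be sorted")
    if (length(starts) > 1 && any(starts[-1] < ends[-length(ends)]))
      stop("intervals must be pairwise disjoint")
    if (!is.null(n_samples) && any(ends > n_samples))
      stop("intervals must lie within the signal")
  }
  structure(data.frame(start = starts, end = ends),
            class = c("syllable_segmentation", "data.frame"))
}

is_segmentation <- function(x) inherits(x, "syllable_segmentation")

assert_segmentation <- function(x, n_samples = NULL, arg = "seg") {
  if (!is_segmentation(x)) stop(sprintf("`%s` must be a syllable_segmentation", arg))
  syllable_segmentation(x$start, x$end, n_samples = n_samples)
}

#' Number of syllables in a segmentation
#' @param seg a `syllable_segmentation`.
#' @return integer syllable count.
#' @export
n_syllables <- function(seg) nrow(seg)

#' Write a segmentation sidecar file
#'
#' Tab-separated plain text: `syllable_index<TAB>start_sample<TAB>end_sample`,
#' 0-based half-open intervals, one row per syllable.
#'
#' @param seg a `syllable_segmentation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(seg, path) {
  seg <- assert_segmentation(seg)
  df <- data.frame(syllable_index = seq_len(nrow(seg)) - 1L,
                   start_sample = seg$start, end_sample = seg$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a segmentation sidecar file
#' @param path path written by [write_seg()].
#' @return a `syllable_segmentation`.
#' @export
read_seg <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  syllable_segmentation(df$start_sample, df$end_sample)
}
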