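# Quantile density accessibility (QDA): the accessibility signal is
# reduced to a family of binary tracks, one per quantile threshold q.
# Positions whose score is >= the bp-weighted q-quantile of the scored
# signal are accessible (a = 1), all others inaccessible (a = 0). q = 0
# keeps every scored position; rising q keeps a nested, shrinking top
# fraction of the genome, which is what makes "the model considers the
# top (1-q) of the genome accessible" literal.
#
# Positions with zero signal carry no assay evidence (bedGraph gaps are
# zero-filled on read); they are excluded from the quantile computation
# and are always inaccessible. This is why, for sparse assays, even
# QDA = 0 can correspond to less than 100% of the genome.

#' Threshold an accessibility signal at one QDA quantile
#'
#' @param signal a [signal_track()] of non-negative accessibility scores.
#' @param q quantile in `[0, 0.99]`.
#' @return An `AccessibilityTrack`: a binary [signal_track()] with
#'   attributes `qda` (the quantile) and `threshold` (the score cutoff).
#' @export
apply_qda <- function(signal, q) {
  stopifnot(q >= 0, q <= 0.99)
  pooled <- unlist(signal, use.names = FALSE)
  scored <- pooled[pooled > 0]
  if (length(scored) == 0)
    stop("constant-zero signal: no quantile defined")
  thr <- as.numeric(quantile(scored, probs = q, names = FALSE))
  out <- lapply(signal, function(v) as.numeric(v > 0 & v >= thr))
  structure(signal_track(out), qda = q, threshold = thr,
            class = c("AccessibilityTrack", "SignalTrack"))
}

#' Constant all-accessible track
#'
#' Convenience constructor for the accessibility-free limit (every base
#' fully accessible), used e.g. when fitting a model that ignores
#' chromatin state.
#'
#' @param seq_lengths named integer vector of sequence lengths.
#' @return An `AccessibilityTrack` of ones.
#' @export
uniform_accessibility <- function(seq_lengths) {
  out <- lapply(seq_lengths, function(L) rep(1, L))
  structure(signal_track(out), qda = NA_real_, threshold = NA_real_,
            class = c("AccessibilityTrack", "SignalTrack"))
}

#' Default QDA grid
#'
#' `0, 0.1, ..., 0.9, 0.95, 0.99`: endpoints at 0 and 0.99 with a finer
#' top end because classification windows span QDA 0-0.2 (dense) and
#' 0.8-0.95 (open).
#'
#' @return Numeric vector of quantiles.
#' @export
default_qda_grid <- function() c(seq(0, 0.9, by = 0.1), 0.95, 0.99)

#' QDA family of accessibility tracks
#'
#' @param signal a [signal_track()].
#' @param grid strictly increasing quantiles in `[0, 0.99]`.
#' @return Named list of `AccessibilityTrack`s, one per grid value.
#' @export
qda_family <- function(signal, grid = default_qda_grid()) {
  stopifnot(length(grid) >= 1, !is.unsorted(grid, strictly = TRUE),
            all(grid >= 0), all(grid <= 0.99))
  out <- lapply(grid, function(q) apply_qda(signal, q))
  names(out) <- format_qda(grid)
  out
}

format_qda <- function(q) sprintf("qda_%0.2f", q)

#' Accessible fraction of a track
#'
#' @param access an `AccessibilityTrack`.
#' @return Fraction of bp with `a = 1`.
#' @export
accessible_fraction <- function(access) {
  pooled <- unlist(access, use.names = FALSE)
  mean(pooled == 1)
}

#' Export accessible segments of a binary track as intervals
#'
#' @param access an `AccessibilityTrack`.
#' @return Interval data frame of maximal accessible runs (0-based
#'   half-open).
#' @export
accessible_segments <- function(access) {
  rows <- lapply(names(access), function(s) {
    r <- rle(access[[s]] == 1)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(seqname = s, start = starts[keep], end = ends[keep],
               score = NA_real_, strand = ".", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- genomic_intervals(character(0), integer(0), integer(0))
  out
}
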