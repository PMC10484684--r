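# PWM construction and genome scanning. The per-site log-odds sum w_j is
# the binding-energy proxy entering the occupancy equation, so the scanner
# lives here rather than being delegated: it must follow the package's
# N-base rule (N contributes the column minimum, keeping score and signal
# tracks position-synchronised over real genomes).

#' Convert a position frequency matrix to a log-odds PWM
#'
#' Each entry is
#' `log2( (count + pseudocount * background) / column_total / background )`,
#' where `column_total` is the pseudocount-corrected column sum. With a
#' uniform PFM and uniform background all entries are 0.
#'
#' @param pfm a `PFM` from [read_jaspar_pfm()] or a bare 4 x m matrix with
#'   rows A,C,G,T.
#' @param pseudocount positive regulariser added per column (distributed by
#'   background frequency); default 1, the JASPAR-style convention.
#' @param background length-4 base frequencies (A,C,G,T), summing to 1.
#' @return A `PWM` object: list with `matrix` (4 x m log2-odds),
#'   `pseudocount`, `background`, `max_score`, `min_score`.
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 1,
                       background = rep(0.25, 4)) {
  mat <- if (inherits(pfm, "PFM")) pfm$matrix else pfm
  stopifnot(is.matrix(mat), nrow(mat) == 4)
  if (abs(sum(background) - 1) > 1e-9)
    stop("background frequencies must sum to 1")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 && any(colSums(mat) == 0))
    stop("zero total column count with zero pseudocount")
  if (pseudocount == 0 && any(mat == 0))
    warning("zero counts with zero pseudocount give -Inf log-odds")
  adj <- mat + pseudocount * background
  freq <- sweep(adj, 2, colSums(adj), "/")
  w <- log2(freq / background)
  rownames(w) <- c("A", "C", "G", "T")
  # accumulate column extremes with plain double addition, matching the
  # scanner's accumulation order, so scanned scores never drift outside
  # [min_score, max_score] by rounding
  max_score <- 0; min_score <- 0
  for (k in seq_len(ncol(w))) {
    max_score <- max_score + max(w[, k])
    min_score <- min_score + min(w[, k])
  }
  structure(list(matrix = w, pseudocount = pseudocount,
                 background = background,
                 max_score = max_score, min_score = min_score),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM: %d columns, score range [%.3f, %.3f]\n",
              ncol(x$matrix), x$min_score, x$max_score))
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' @param pwm a `PWM`.
#' @return Character string of per-column best bases.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$matrix)[apply(pwm$matrix, 2, which.max)],
        collapse = "")
}

# A,C,G,T,N -> 1..5; anything else rejected upstream by read_fasta
encode_dna <- function(seq) {
  code <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T", "N"))
  if (any(is.na(code))) stop("sequence contains letters outside A,C,G,T,N")
  code
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# reverse complement of a PWM: reverse columns, swap A<->T, C<->G
pwm_revcomp_matrix <- function(w) {
  w[c(4, 3, 2, 1), rev(seq_len(ncol(w))), drop = FALSE]
}

scan_one <- function(code, w) {
  m <- ncol(w)
  n <- length(code) - m + 1L
  # row 5 (N) scores the column minimum
  lut <- rbind(w, apply(w, 2, min))
  scores <- numeric(n)
  for (k in seq_len(m)) {
    scores <- scores + lut[cbind(code[k:(k + n - 1L)], k)]
  }
  scores
}

#' Scan sequences with a PWM
#'
#' Scores every window of width `m` on each sequence: the score at start
#' position `j` (0-based) is the sum of matrix entries for the m-mer
#' starting there. With `strand_policy = "max_of_both"` (default; ChIP
#' peaks are unstranded) the score is the maximum of the forward-strand
#' score and the reverse-complement score of the same window. N bases
#' contribute the column minimum.
#'
#' @param sequences named character vector from [read_fasta()].
#' @param pwm a `PWM` from [pfm_to_pwm()].
#' @param strand_policy `"max_of_both"` or `"forward"`.
#' @return A `ScoreTrack`: named list of numeric score vectors of length
#'   `sequence length - m + 1`, with attributes `motif_width` and
#'   `strand_policy`.
#' @export
pwm_scan <- function(sequences, pwm,
                     strand_policy = c("max_of_both", "forward")) {
  strand_policy <- match.arg(strand_policy)
  if (length(sequences) == 0) stop("empty sequence set")
  m <- ncol(pwm$matrix)
  if (any(nchar(sequences) < m))
    stop("motif wider than shortest sequence")
  wrc <- pwm_revcomp_matrix(pwm$matrix)
  out <- lapply(sequences, function(s) {
    code <- encode_dna(s)
    fwd <- scan_one(code, pwm$matrix)
    if (strand_policy == "forward") fwd
    else pmax(fwd, scan_one(code, wrc))
  })
  structure(out, motif_width = m, strand_policy = strand_policy,
            class = "ScoreTrack")
}

#' @export
print.ScoreTrack <- function(x, ...) {
  cat("ScoreTrack:", length(x), "sequence(s), motif width",
      attr(x, "motif_width"), "\n")
  invisible(x)
}

#' Export a score track as a wiggle-compatible signal track
#'
#' Scores are padded at the tail (last `m - 1` positions repeat the final
#' site score) so the result has one value per bp.
#'
#' @param scores a `ScoreTrack`.
#' @param seq_lengths named integer vector of the scanned sequence lengths.
#' @return A [signal_track()].
#' @export
score_track_to_signal <- function(scores, seq_lengths) {
  m <- attr(scores, "motif_width")
  vals <- lapply(names(scores), function(s) {
    v <- scores[[s]]
    c(v, rep(v[length(v)], seq_lengths[[s]] - length(v)))
  })
  names(vals) <- names(scores)
  signal_track(vals)
}
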