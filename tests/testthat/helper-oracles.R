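# Independent oracles and tiny fixtures shared across test files.
# Oracles are deliberately naive (loops, O(n^2) counting) so they cannot
# share a bug with the vectorised implementation paths they check.

# concordant-pair AUC: P(score_pos > score_neg) + 0.5 P(tie)
brute_auc <- function(labels, scores) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# per-window PWM score by explicit letter lookup
brute_window_score <- function(seq, w, at) {
  letters <- strsplit(seq, "")[[1]]
  s <- 0
  for (k in seq_len(ncol(w))) {
    b <- letters[at + k - 1]
    s <- s + if (b == "N") min(w[, k]) else w[b, k]
  }
  unname(s)
}

brute_revcomp <- function(seq) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(seq, "")[[1]]]), collapse = "")
}

# direct weighted-sum convolution with edge renormalisation at one index
brute_smooth_at <- function(x, kernel, i) {
  half <- (length(kernel) - 1) %/% 2
  num <- 0; den <- 0
  for (j in seq_along(kernel)) {
    idx <- i + j - 1 - half
    if (idx >= 1 && idx <= length(x)) {
      num <- num + kernel[j] * x[idx]
      den <- den + kernel[j]
    }
  }
  num / den
}

# scalar occupancy-equation evaluation, no shifting tricks
brute_occupancy <- function(w, a, N, lambda, L, n) {
  x <- a * exp(w / lambda)
  N * x / (N * x + L * n * mean(x))
}

# 2-column toy PFM: consensus "AC"
toy_pfm <- function() {
  mat <- matrix(c(8, 0, 0, 0,
                  0, 8, 0, 0), nrow = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  structure(list(matrix = mat, id = "TOY", name = "toy"), class = "PFM")
}

# wrap a bare numeric vector as a single-sequence ScoreTrack
as_score_track <- function(v, m = 1L, name = "s") {
  structure(setNames(list(v), name), motif_width = as.integer(m),
            strand_policy = "forward", class = "ScoreTrack")
}

# small fast analysis options reused by pipeline-level tests
fast_opts <- function() {
  list(bin_bp = 25000, n_train = 6, n_validate = 12,
       qda_grid = c(0, 0.1, 0.2, 0.8, 0.9, 0.95),
       N_grid = c(5, 50, 500, 5000, 5e4),
       lambda_grid = c(0.5, 1, 2, 4))
}
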