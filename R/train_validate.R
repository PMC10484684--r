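# Training and validation: the genome is tiled into fixed-width bins,
# bins are ranked by ChIP peak content, the top bins train (N, lambda) by
# grid-search MSE against the rescaled ChIP profile, and the following
# bins validate the prediction by ROC AUC over fixed-width windows.

region_key <- function(regions) {
  sprintf("%s:%d-%d", regions$seqname, regions$start, regions$end)
}

#' Tile a genome into fixed-width bins
#'
#' @param seq_lengths named integer vector of sequence lengths (bp).
#' @param bin_bp bin width; the last bin of each sequence may be short.
#' @return Interval data frame of tiling bins (0-based half-open).
#' @export
bin_genome <- function(seq_lengths, bin_bp = 50000) {
  stopifnot(bin_bp >= 1)
  rows <- lapply(names(seq_lengths), function(s) {
    L <- seq_lengths[[s]]
    starts <- seq(0L, L - 1L, by = bin_bp)
    data.frame(seqname = s, start = starts,
               end = pmin(starts + bin_bp, L),
               score = NA_real_, strand = ".", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# peak -> bin assignment by peak midpoint (avoids double counting peaks
# spanning bin edges); returns per-bin peak count and total peak signal
peak_stats_per_bin <- function(bins, peaks) {
  count <- integer(nrow(bins)); signal <- numeric(nrow(bins))
  if (nrow(peaks)) {
    mid <- floor((peaks$start + peaks$end) / 2)
    for (s in unique(bins$seqname)) {
      bi <- which(bins$seqname == s)
      bi <- bi[order(bins$start[bi])]   # permutation-proof assignment
      pi <- which(peaks$seqname == s)
      if (!length(pi)) next
      idx <- findInterval(mid[pi], bins$start[bi])
      ok <- idx >= 1 & mid[pi] < bins$end[bi][pmax(idx, 1)]
      tab <- tapply(rep(1L, sum(ok)), idx[ok], sum)
      count[bi[as.integer(names(tab))]] <- as.integer(tab)
      sc <- peaks$score[pi]; sc[is.na(sc)] <- 0
      sg <- tapply(sc[ok], idx[ok], sum)
      signal[bi[as.integer(names(sg))]] <- as.numeric(sg)
    }
  }
  data.frame(count = count, signal = signal)
}

rank_bins <- function(bins, peaks) {
  st <- peak_stats_per_bin(bins, peaks)
  ord <- order(-st$count, -st$signal, bins$seqname, bins$start)
  list(order = ord, stats = st)
}

#' Select training and validation bins by ChIP peak content
#'
#' Bins are ranked by the number of ChIP peaks whose midpoint they
#' contain (ties broken by total peak signal, then coordinate); the top
#' `n_train` bins train the model and the following `n_validate` bins
#' validate it.
#'
#' @param bins tiling bins from [bin_genome()].
#' @param peaks ChIP peak intervals.
#' @param n_train,n_validate numbers of training / validation bins.
#' @return List with `training` and `validation` interval data frames
#'   (disjoint), each carrying the peak count as `score`.
#' @export
rank_and_select <- function(bins, peaks, n_train = 10, n_validate = 50) {
  if (nrow(bins) < n_train + n_validate)
    stop("too few bins: need at least ", n_train + n_validate)
  rk <- rank_bins(bins, peaks)
  if (all(rk$stats$count == 0)) stop("insufficient signal: no peaks in any bin")
  ord <- rk$order
  take <- function(i) {
    out <- bins[ord[i], , drop = FALSE]
    out$score <- rk$stats$count[ord[i]]
    rownames(out) <- NULL
    out
  }
  list(training = take(seq_len(n_train)),
       validation = take(n_train + seq_len(n_validate)))
}

#' Strong / medium / weak region groups
#'
#' Among the peak-bearing bins ranked by peak count, selects the top
#' `group_size` (strong), `group_size` bins centred at the median rank
#' (medium) and the bottom `group_size` (weak).
#'
#' @inheritParams rank_and_select
#' @param group_size bins per group.
#' @return List with `strong`, `medium`, `weak` interval data frames.
#' @export
select_strength_groups <- function(bins, peaks, group_size = 50) {
  rk <- rank_bins(bins, peaks)
  ord <- rk$order[rk$stats$count[rk$order] >= 1]
  n <- length(ord)
  if (n < 3 * group_size)
    stop("too few peak-bearing bins: need at least ", 3 * group_size)
  mid_start <- floor((n - group_size) / 2) + 1L
  take <- function(i) {
    out <- bins[ord[i], , drop = FALSE]
    out$score <- rk$stats$count[ord[i]]
    rownames(out) <- NULL
    out
  }
  list(strong = take(seq_len(group_size)),
       medium = take(mid_start:(mid_start + group_size - 1L)),
       weak = take((n - group_size + 1L):n))
}

#' Extract and scan region sequences
#'
#' @param genome named character vector from [read_fasta()].
#' @param regions interval data frame.
#' @param pwm a `PWM`.
#' @param strand_policy see [pwm_scan()].
#' @return A `ScoreTrack` keyed by `seqname:start-end`.
#' @export
scan_regions <- function(genome, regions, pwm,
                         strand_policy = "max_of_both") {
  seqs <- substring(genome[regions$seqname], regions$start + 1,
                    regions$end)
  names(seqs) <- region_key(regions)
  pwm_scan(seqs, pwm, strand_policy)
}

#' Slice a signal track by regions
#'
#' @param track a [signal_track()].
#' @param regions interval data frame.
#' @return Named list (by `seqname:start-end`) of per-bp value vectors.
#' @export
track_slice <- function(track, regions) {
  out <- lapply(seq_len(nrow(regions)), function(i) {
    track[[regions$seqname[i]]][(regions$start[i] + 1):regions$end[i]]
  })
  names(out) <- region_key(regions)
  out
}

# min-max rescale a pooled list of vectors to [0, 1]
rescale01 <- function(vecs) {
  pooled <- unlist(vecs, use.names = FALSE)
  lo <- min(pooled); hi <- max(pooled)
  if (hi == lo) return(lapply(vecs, function(v) rep(0, length(v))))
  lapply(vecs, function(v) (v - lo) / (hi - lo))
}

#' Grid-search fit of the occupancy parameters (N, lambda)
#'
#' For every grid pair the model profile is computed over the training
#' regions and smoothed; prediction and ChIP signal are each min-max
#' rescaled to `[0, 1]` over the pooled training set (the MSE compares
#' profile shapes - site-level occupancy is a near-delta spike per bound
#' site, so after any averaging kernel its amplitude is no longer on the
#' ChIP scale) and the pair minimising the mean squared error wins (ties
#' resolved towards smaller N, then smaller lambda).
#'
#' @param scores `ScoreTrack` over the training regions
#'   ([scan_regions()]).
#' @param access_slices per-region accessibility ([track_slice()] of an
#'   `AccessibilityTrack`).
#' @param chip_slices per-region ChIP signal ([track_slice()]).
#' @param N_grid,lambda_grid numeric grids of candidate values.
#' @param L,n genome length (bp) and ploidy.
#' @param kernel,bandwidth_bp smoothing kernel for the predicted profile.
#' @return A `FitResult`: list with `N`, `lambda`, `mse` (the minimum),
#'   `mse_surface` (matrix lambda x N), and the smoothing descriptor.
#' @export
fit_parameters <- function(scores, access_slices, chip_slices,
                           N_grid = default_N_grid(),
                           lambda_grid = default_lambda_grid(),
                           L, n = 1,
                           kernel = "gaussian", bandwidth_bp = 100) {
  stopifnot(length(N_grid) >= 1, length(lambda_grid) >= 1)
  m <- attr(scores, "motif_width")
  keys <- names(scores)
  chip01 <- rescale01(chip_slices[keys])
  site_a <- lapply(keys, function(k) site_accessibility(access_slices[[k]], m))
  names(site_a) <- keys
  shift <- max(vapply(scores, max, numeric(1)))
  k_vec <- smoothing_kernel(kernel, bandwidth_bp)
  dens <- lapply(keys, function(k)
    conv_edge_weights(length(scores[[k]]), k_vec))
  names(dens) <- keys
  N_grid <- sort(N_grid); lambda_grid <- sort(lambda_grid)
  surface <- matrix(NA_real_, nrow = length(lambda_grid),
                    ncol = length(N_grid),
                    dimnames = list(as.character(lambda_grid),
                                    as.character(N_grid)))
  n_bp <- sum(lengths(chip01))
  for (li in seq_along(lambda_grid)) {
    lam <- lambda_grid[li]
    ax <- lapply(keys, function(k)
      site_a[[k]] * exp((scores[[k]] - shift) / lam))
    names(ax) <- keys
    mean_ax <- sum(vapply(ax, sum, numeric(1))) / sum(lengths(ax))
    for (ni in seq_along(N_grid)) {
      N <- N_grid[ni]
      denom_bg <- L * n * mean_ax
      pred_bp <- lapply(keys, function(k) {
        num <- N * ax[[k]]
        P <- if (denom_bg == 0) numeric(length(num))
             else num / (num + denom_bg)
        pred <- conv_same_renorm(P, k_vec, dens[[k]])
        c(pred, rep(pred[length(pred)],
                    length(chip01[[k]]) - length(pred)))
      })
      pred01 <- rescale01(pred_bp)
      sse <- sum(vapply(seq_along(keys), function(i)
        sum((pred01[[i]] - chip01[[keys[i]]])^2), numeric(1)))
      surface[li, ni] <- sse / n_bp
    }
  }
  if (any(!is.finite(surface)))
    stop("non-finite MSE at grid pair(s): ",
         paste(which(!is.finite(surface)), collapse = ","))
  # ties -> smaller N, then smaller lambda: scan N-major in ascending order
  best <- c(NA_integer_, NA_integer_); best_mse <- Inf
  for (ni in seq_along(N_grid)) for (li in seq_along(lambda_grid)) {
    if (surface[li, ni] < best_mse) {
      best_mse <- surface[li, ni]; best <- c(li, ni)
    }
  }
  structure(list(N = N_grid[best[2]], lambda = lambda_grid[best[1]],
                 mse = best_mse, mse_surface = surface,
                 kernel = list(type = kernel, bandwidth_bp = bandwidth_bp)),
            class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf("FitResult: N = %g, lambda = %g (MSE = %.4g)\n",
              x$N, x$lambda, x$mse))
  invisible(x)
}

#' Default N grid
#'
#' Decades 1 to 1e6 with 1x/2x/5x sub-steps: spans the physically
#' plausible range of bound-molecule counts.
#' @return Numeric vector.
#' @export
default_N_grid <- function()
  sort(as.vector(outer(c(1, 2, 5), 10^(0:6))))

#' Default lambda grid
#'
#' 0.25 to 5 in steps of 0.25.
#' @return Numeric vector.
#' @export
default_lambda_grid <- function() seq(0.25, 5, by = 0.25)

#' Predicted ChIP-like profile over regions
#'
#' Occupancy under the supplied parameters, smoothed and padded to bp
#' resolution.
#'
#' @inheritParams fit_parameters
#' @param params a [model_parameters()].
#' @return Named list of per-bp predicted values, one vector per region.
#' @export
predict_regions <- function(scores, access_slices, params,
                            kernel = "gaussian", bandwidth_bp = 100) {
  access <- signal_track(access_slices[names(scores)])
  occ <- site_occupancy(scores, access, params)
  pred <- smooth_profile(occ, kernel, bandwidth_bp)
  lens <- vapply(access_slices[names(scores)], length, integer(1))
  profile_to_bp(pred, lens)
}

#' ROC AUC (Mann-Whitney form)
#'
#' Rank statistic with midrank ties: equals the probability that a random
#' positive outscores a random negative, counting ties as one half.
#'
#' @param labels logical (or 0/1) vector.
#' @param scores numeric vector.
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.logical(labels)
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Validate a predicted profile against ChIP peaks by ROC AUC
#'
#' Validation regions are tiled into consecutive `window_bp` windows; a
#' window is a positive if it overlaps a ChIP peak by at least 1 bp, and
#' its score is the maximum of the predicted profile inside it.
#'
#' @param regions validation interval data frame.
#' @param predicted_bp per-region per-bp predicted values
#'   ([predict_regions()]).
#' @param peaks ChIP peak intervals.
#' @param window_bp window width (default 100).
#' @return List with `auc` (`NA` plus a `flagged` note if one class is
#'   absent), `n_pos`, `n_neg`.
#' @export
validate_auc <- function(regions, predicted_bp, peaks, window_bp = 100) {
  labs <- logical(0); sc <- numeric(0)
  pk_ir <- split(intervals_to_iranges(peaks), peaks$seqname)
  for (i in seq_len(nrow(regions))) {
    key <- region_key(regions[i, , drop = FALSE])
    v <- predicted_bp[[key]]
    starts <- seq(0L, length(v) - 1L, by = window_bp)
    ends <- pmin(starts + window_bp, length(v))
    win_ir <- IRanges::IRanges(regions$start[i] + starts + 1L,
                               regions$start[i] + ends)
    s <- regions$seqname[i]
    lab <- if (!is.null(pk_ir[[s]]))
      IRanges::overlapsAny(win_ir, pk_ir[[s]]) else rep(FALSE, length(win_ir))
    wsc <- vapply(seq_along(starts), function(w)
      max(v[(starts[w] + 1):ends[w]]), numeric(1))
    labs <- c(labs, lab); sc <- c(sc, wsc)
  }
  auc <- roc_auc(labs, sc)
  list(auc = auc, n_pos = sum(labs), n_neg = sum(!labs),
       flagged = is.na(auc))
}

#' AUC across the QDA family for one dataset
#'
#' For each QDA value the accessibility track is re-thresholded, (N,
#' lambda) are re-fitted on the training regions under that track
#' (unless `fixed_params` is given), and the validation AUC is computed.
#'
#' @param genome named character vector of sequences.
#' @param access_signal raw accessibility [signal_track()].
#' @param chip_signal ChIP [signal_track()].
#' @param peaks ChIP peak intervals.
#' @param training,validation region sets from [rank_and_select()].
#' @param pwm a `PWM`.
#' @param qda_grid quantile grid.
#' @param N_grid,lambda_grid fit grids.
#' @param L,n genome length and ploidy (defaults: total supplied genome,
#'   diploid not assumed - n = 1).
#' @param kernel,bandwidth_bp smoothing kernel.
#' @param window_bp validation window width.
#' @param fixed_params optional [model_parameters()] to skip refitting.
#' @return List with `auc` (named numeric, one entry per QDA value) and
#'   `fits` (per-QDA `FitResult` or the fixed parameters).
#' @export
auc_over_qda <- function(genome, access_signal, chip_signal, peaks,
                         training, validation, pwm,
                         qda_grid = default_qda_grid(),
                         N_grid = default_N_grid(),
                         lambda_grid = default_lambda_grid(),
                         L = sum(nchar(genome)), n = 1,
                         kernel = "gaussian", bandwidth_bp = 100,
                         window_bp = 100, fixed_params = NULL) {
  train_scores <- scan_regions(genome, training, pwm)
  valid_scores <- scan_regions(genome, validation, pwm)
  chip_train <- track_slice(chip_signal, training)
  # QDA thresholds come from the genome-wide score distribution, but the
  # binary tracks are only ever consumed over the selected regions, so
  # compute thresholds once and binarise slices on demand
  pooled <- unlist(access_signal, use.names = FALSE)
  scored <- pooled[pooled > 0]
  if (length(scored) == 0) stop("constant-zero accessibility signal")
  thrs <- as.numeric(quantile(scored, probs = qda_grid, names = FALSE))
  raw_train <- track_slice(access_signal, training)
  raw_valid <- track_slice(access_signal, validation)
  binarise <- function(slices, thr)
    lapply(slices, function(v) as.numeric(v > 0 & v >= thr))
  aucs <- setNames(rep(NA_real_, length(qda_grid)), format_qda(qda_grid))
  fits <- vector("list", length(qda_grid))
  names(fits) <- format_qda(qda_grid)
  for (qi in seq_along(qda_grid)) {
    q <- qda_grid[qi]
    res <- tryCatch({
      acc_train <- binarise(raw_train, thrs[qi])
      acc_valid <- binarise(raw_valid, thrs[qi])
      if (is.null(fixed_params)) {
        fit <- fit_parameters(train_scores, acc_train, chip_train,
                              N_grid, lambda_grid, L = L, n = n,
                              kernel = kernel, bandwidth_bp = bandwidth_bp)
        params <- model_parameters(fit$N, fit$lambda, L, n)
      } else {
        fit <- fixed_params
        params <- fixed_params
      }
      pred <- predict_regions(valid_scores, acc_valid, params,
                              kernel, bandwidth_bp)
      va <- validate_auc(validation, pred, peaks, window_bp)
      list(auc = va$auc, fit = fit)
    }, error = function(e) list(auc = NA_real_, fit = NULL))
    aucs[qi] <- res$auc
    fits[[qi]] <- res$fit
  }
  list(auc = aucs, fits = fits)
}
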