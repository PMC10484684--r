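# Classification of a TF's dependence on DNA accessibility from its
# AUC-vs-QDA profile. Two window means summarise the profile: prediction
# accuracy when (almost) the whole genome is considered accessible
# (dense window, QDA 0-0.2) and when only the most accessible top is
# (open window, QDA 0.8-0.95). The signed difference open - dense routes
# the open-preferring (ADF) vs dense-preferring (IDF) branches; its
# magnitude measures how strongly accessibility matters.

#' Default classification thresholds
#'
#' `high` (0.8) is the accuracy bar an AUC window mean must clear;
#' `poor` (0.65) the bar below which a dataset counts as poorly
#' predicted; `small`/`large` (0.1 / 0.3) bound the window-mean
#' difference separating no / partial / strong accessibility dependence.
#' Window bounds are the QDA ranges the means are taken over.
#'
#' @return Named list of thresholds.
#' @export
classification_thresholds <- function() {
  list(high = 0.8, poor = 0.65, small = 0.1, large = 0.3,
       dense_window = c(0, 0.2), open_window = c(0.8, 0.95))
}

#' Classify a TF from its AUC-vs-QDA row
#'
#' Computes the mean AUC over the dense window (QDA in `[0, 0.2]`) and
#' the open window (QDA in `[0.8, 0.95]`) and applies the threshold
#' rules, with `d = |mean_open - mean_dense|` and the sign of the
#' difference selecting the open- or dense-favouring branch:
#' * `AIF` - both means above `high` and `d` below `small`;
#' * `ADF` / `IDF` - `d` above `large` and the favoured mean above
#'   `high`;
#' * `partial_AIF_ADF` / `partial_AIF_IDF` - `d` between `small` and
#'   `large` (inclusive) and the favoured mean above `high`;
#' * `poorly_predicted` - both means below `poor`;
#' * `other` - anything else.
#'
#' Bounds on `high` and `poor` are strict, the `small <= d <= large`
#' band is inclusive.
#'
#' @param auc_row numeric AUC values, one per QDA grid entry.
#' @param qda_grid the QDA values the row is indexed by.
#' @param thresholds see [classification_thresholds()].
#' @param dataset optional dataset id carried into the result.
#' @return A `TFClassification`: list with `dataset`, `mean_dense_auc`,
#'   `mean_open_auc`, `difference` (signed, open - dense), `label`.
#' @export
classify_tf <- function(auc_row, qda_grid = default_qda_grid(),
                        thresholds = classification_thresholds(),
                        dataset = NA_character_) {
  stopifnot(length(auc_row) == length(qda_grid))
  th <- thresholds
  in_dense <- qda_grid >= th$dense_window[1] & qda_grid <= th$dense_window[2]
  in_open <- qda_grid >= th$open_window[1] & qda_grid <= th$open_window[2]
  if (!any(in_dense) || !any(in_open))
    stop("QDA grid has no entries in a classification window")
  if (all(is.na(auc_row[in_dense])) || all(is.na(auc_row[in_open])))
    stop("NA AUC entries cover a whole classification window")
  mean_dense <- mean(auc_row[in_dense], na.rm = TRUE)
  mean_open <- mean(auc_row[in_open], na.rm = TRUE)
  diff_signed <- mean_open - mean_dense
  d <- abs(diff_signed)
  open_side <- diff_signed >= 0
  label <-
    if (mean_dense > th$high && mean_open > th$high && d < th$small) "AIF"
    else if (d > th$large && open_side && mean_open > th$high) "ADF"
    else if (d > th$large && !open_side && mean_dense > th$high) "IDF"
    else if (d >= th$small && d <= th$large && open_side &&
             mean_open > th$high) "partial_AIF_ADF"
    else if (d >= th$small && d <= th$large && !open_side &&
             mean_dense > th$high) "partial_AIF_IDF"
    else if (mean_dense < th$poor && mean_open < th$poor) "poorly_predicted"
    else "other"
  structure(list(dataset = dataset, mean_dense_auc = mean_dense,
                 mean_open_auc = mean_open, difference = diff_signed,
                 label = label), class = "TFClassification")
}

#' @export
print.TFClassification <- function(x, ...) {
  cat(sprintf("%s: %s (dense %.3f, open %.3f, diff %+.3f)\n",
              ifelse(is.na(x$dataset), "dataset", x$dataset), x$label,
              x$mean_dense_auc, x$mean_open_auc, x$difference))
  invisible(x)
}

#' Classify every row of an AUC matrix
#'
#' @param auc_matrix datasets x QDA values matrix.
#' @param qda_grid QDA values labelling the columns.
#' @param thresholds see [classification_thresholds()].
#' @return Data frame with one row per dataset: means, signed
#'   difference, label.
#' @export
classify_matrix <- function(auc_matrix, qda_grid = default_qda_grid(),
                            thresholds = classification_thresholds()) {
  rows <- lapply(seq_len(nrow(auc_matrix)), function(i) {
    cl <- classify_tf(auc_matrix[i, ], qda_grid, thresholds,
                      dataset = rownames(auc_matrix)[i])
    data.frame(dataset = cl$dataset, mean_dense_auc = cl$mean_dense_auc,
               mean_open_auc = cl$mean_open_auc,
               difference = cl$difference, label = cl$label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' k-means clustering of AUC-vs-QDA rows
#'
#' Seeded Lloyd k-means (via [stats::kmeans()]) over the rows of an AUC
#' matrix, the assumption-free companion to the threshold rules.
#'
#' @param auc_matrix datasets x QDA values matrix, no NA rows.
#' @param k number of clusters (2 separates accessibility-independent
#'   from dependent behaviour; 5 resolves subgroups).
#' @param seed RNG seed (mandatory: assignments must be reproducible).
#' @param n_start random restarts.
#' @return List with `cluster` (named assignments), `centers`,
#'   `tot_withinss`.
#' @export
kmeans_classes <- function(auc_matrix, k = 2, seed, n_start = 25) {
  if (missing(seed)) stop("a seed is required for reproducible clustering")
  if (anyNA(auc_matrix)) stop("AUC matrix contains NA rows")
  if (k > nrow(auc_matrix)) stop("k exceeds the number of datasets")
  set.seed(seed)
  km <- kmeans(auc_matrix, centers = k, nstart = n_start,
               iter.max = 100, algorithm = "Lloyd")
  list(cluster = setNames(km$cluster, rownames(auc_matrix)),
       centers = km$centers, tot_withinss = km$tot.withinss)
}

#' Rescale a bound-molecule count to another cell type
#'
#' `N_target = N_source * (mrna_target / mrna_source) * phospho_factor`;
#' the specificity factor lambda is left unchanged by contract (it is a
#' property of the TF-DNA interaction, not of abundance).
#'
#' @param N_source fitted N in the source cell type.
#' @param mrna_source,mrna_target mRNA levels of the TF in source and
#'   target cells.
#' @param phospho_factor optional additional scaling, e.g. for a change
#'   in the phosphorylated fraction of the TF.
#' @return Rescaled N.
#' @export
rescale_concentration <- function(N_source, mrna_source, mrna_target,
                                  phospho_factor = 1) {
  if (any(c(N_source, mrna_source, mrna_target, phospho_factor) <= 0))
    stop("all concentration inputs must be positive")
  N_source * (mrna_target / mrna_source) * phospho_factor
}

top_k_peaks <- function(peaks, top_k) {
  if (is.null(top_k) || is.na(top_k) || top_k >= nrow(peaks)) return(peaks)
  sc <- peaks$score
  if (all(is.na(sc))) stop("peaks need scores for top-k selection")
  peaks[order(-sc)[seq_len(top_k)], , drop = FALSE]
}

#' Pairwise peak-set overlap counts and Jaccard indices
#'
#' Overlap counts intervals of one set sharing at least 1 bp with the
#' other; the Jaccard index is computed on merged covered bp. Used to
#' check whether jointly classified TFs merely co-occupy the same
#' (e.g. high-occupancy target) regions.
#'
#' @param peak_sets named list of interval data frames.
#' @param top_k optionally restrict each set to its `top_k` strongest
#'   peaks (by score) first; `NULL` keeps all.
#' @return List of symmetric matrices `count` (intervals of set i
#'   overlapping set j) and `jaccard`.
#' @export
peak_overlap_matrix <- function(peak_sets, top_k = NULL) {
  stopifnot(length(peak_sets) >= 2)
  sets <- lapply(peak_sets, top_k_peaks, top_k = top_k)
  grs <- lapply(sets, function(x)
    GenomicRanges::GRanges(x$seqname, intervals_to_iranges(x)))
  nm <- names(peak_sets)
  n <- length(sets)
  count <- matrix(0L, n, n, dimnames = list(nm, nm))
  jac <- matrix(1, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { count[i, j] <- length(grs[[i]]); next }
    count[i, j] <- sum(IRanges::overlapsAny(grs[[i]], grs[[j]]))
    if (j < i) next
    ri <- GenomicRanges::reduce(grs[[i]])
    rj <- GenomicRanges::reduce(grs[[j]])
    inter <- sum(BiocGenerics::width(GenomicRanges::intersect(ri, rj)))
    uni <- sum(BiocGenerics::width(GenomicRanges::union(ri, rj)))
    jac[i, j] <- jac[j, i] <- if (uni == 0) 0 else inter / uni
  }
  list(count = count, jaccard = jac)
}

#' Mean ChIP signal at accessibility extremes
#'
#' Ranks candidate regions by their mean accessibility signal and
#' averages the ChIP signal over aligned windows (region midpoint +/-
#' `flank_bp`) for the `k` most and `k` least accessible regions. A TF
#' whose ChIP signal at the least accessible regions rivals the most
#' accessible ones binds dense chromatin.
#'
#' @param chip_signal,access_signal [signal_track()]s.
#' @param regions candidate interval data frame (at least `2 * k` rows).
#' @param k regions per extreme group.
#' @param flank_bp half-width of the aligned window.
#' @return List with `top` and `bottom` mean signal vectors (length
#'   `2 * flank_bp + 1`) and the selected region sets.
#' @export
signal_at_accessibility_extremes <- function(chip_signal, access_signal,
                                             regions, k = 1000,
                                             flank_bp = 1000) {
  if (nrow(regions) < 2 * k)
    stop("need at least 2*k = ", 2 * k, " regions")
  acc_mean <- vapply(track_slice(access_signal, regions), mean, numeric(1))
  ord <- order(-acc_mean)
  grab <- function(idx) {
    prof <- matrix(NA_real_, length(idx), 2 * flank_bp + 1)
    for (r in seq_along(idx)) {
      i <- idx[r]
      mid <- floor((regions$start[i] + regions$end[i]) / 2)
      s <- regions$seqname[i]
      L <- length(chip_signal[[s]])
      pos <- (mid - flank_bp):(mid + flank_bp)
      ok <- pos >= 0 & pos < L
      prof[r, ok] <- chip_signal[[s]][pos[ok] + 1]
    }
    colMeans(prof, na.rm = TRUE)
  }
  top_idx <- ord[seq_len(k)]
  bot_idx <- ord[(length(ord) - k + 1):length(ord)]
  list(top = grab(top_idx), bottom = grab(bot_idx),
       top_regions = regions[top_idx, ], bottom_regions = regions[bot_idx, ])
}

#' Split peaks into TSS-proximal and TSS-distal sets
#'
#' A peak is proximal when its midpoint lies within `proximal_bp` of the
#' nearest TSS interval; the partition is exhaustive and disjoint.
#'
#' @param peaks peak intervals.
#' @param tss TSS intervals (non-empty).
#' @param proximal_bp promoter-proximal distance (default 2000).
#' @return List with `proximal` and `distal` interval data frames.
#' @export
split_peaks_by_tss <- function(peaks, tss, proximal_bp = 2000) {
  if (nrow(tss) == 0) stop("TSS set is empty")
  mid <- floor((peaks$start + peaks$end) / 2)
  pk <- GenomicRanges::GRanges(peaks$seqname,
                               IRanges::IRanges(mid + 1L, mid + 1L))
  ts <- GenomicRanges::GRanges(tss$seqname, intervals_to_iranges(tss))
  d <- suppressWarnings(GenomicRanges::distanceToNearest(pk, ts))
  dist <- rep(Inf, nrow(peaks))
  dist[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
  prox <- dist <= proximal_bp
  list(proximal = peaks[prox, , drop = FALSE],
       distal = peaks[!prox, , drop = FALSE])
}
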