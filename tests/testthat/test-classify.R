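# helper: build an AUC row whose window means are exactly the given pair
row_for <- function(mean_dense, mean_open,
                    grid = c(0, 0.1, 0.2, 0.8, 0.9, 0.95)) {
  vals <- numeric(length(grid))
  vals[grid <= 0.2] <- mean_dense
  vals[grid >= 0.8] <- mean_open
  vals
}
grid6 <- c(0, 0.1, 0.2, 0.8, 0.9, 0.95)

test_that("threshold rules reproduce the canonical class examples", {
  lab <- function(d, o) classify_tf(row_for(d, o), grid6)$label
  expect_equal(lab(0.85, 0.90), "AIF")
  expect_equal(lab(0.45, 0.90), "ADF")
  expect_equal(lab(0.90, 0.45), "IDF")
  expect_equal(lab(0.70, 0.95), "partial_AIF_ADF")
  expect_equal(lab(0.95, 0.70), "partial_AIF_IDF")
  expect_equal(lab(0.60, 0.60), "poorly_predicted")
  expect_equal(lab(0.75, 0.78), "other")
})

test_that("boundary conventions are strict on means, inclusive on the band", {
  lab <- function(d, o) classify_tf(row_for(d, o), grid6)$label
  expect_equal(lab(0.80, 0.80), "other")      # "above 0.8" is strict
  expect_equal(lab(0.65, 0.65), "other")      # "below 0.65" is strict
  # values in sixteenths keep the differences exactly representable
  expect_equal(lab(0.8125, 0.9375), "partial_AIF_ADF")  # d = 0.125
  expect_equal(lab(0.5, 0.875), "ADF")                  # d = 0.375
  expect_equal(lab(0.875, 0.625), "partial_AIF_IDF")    # d = 0.25
  expect_equal(lab(0.5625, 0.9375), "ADF")              # d = 0.375
})

test_that("every point of the unit square receives exactly one label", {
  vals <- seq(0, 1, by = 0.01)
  labels <- c("AIF", "ADF", "IDF", "partial_AIF_ADF", "partial_AIF_IDF",
              "poorly_predicted", "other")
  seen <- character(0)
  for (d in vals) {
    row <- row_for(d, 0)   # reuse structure; set open below
    for (o in vals) {
      row[grid6 >= 0.8] <- o
      lab <- classify_tf(row, grid6)$label
      if (!(lab %in% labels)) stop("unknown label ", lab)
      seen <- union(seen, lab)
    }
  }
  expect_setequal(seen, labels)
})

test_that("classification is invariant to grid refinement preserving means", {
  coarse <- classify_tf(row_for(0.7, 0.92), grid6)
  fine_grid <- c(0, 0.05, 0.1, 0.15, 0.2, 0.8, 0.85, 0.9, 0.95)
  fine <- classify_tf(row_for(0.7, 0.92, fine_grid), fine_grid)
  expect_equal(fine$label, coarse$label)
  expect_equal(fine$mean_dense_auc, coarse$mean_dense_auc)
  expect_equal(fine$mean_open_auc, coarse$mean_open_auc)
})

test_that("rows with NA windows or missing window coverage error", {
  row <- row_for(0.9, 0.9)
  row[grid6 <= 0.2] <- NA
  expect_error(classify_tf(row, grid6), "NA AUC")
  expect_error(classify_tf(c(0.9, 0.9), c(0.4, 0.5)), "window")
})

test_that("classify_matrix labels each dataset row", {
  m <- rbind(a = row_for(0.9, 0.92), b = row_for(0.4, 0.9))
  out <- classify_matrix(m, grid6)
  expect_equal(out$label, c("AIF", "ADF"))
  expect_equal(out$dataset, c("a", "b"))
})

test_that("k-means separates identical-row groups and is reproducible", {
  m <- rbind(matrix(rep(c(0.9, 0.9, 0.9, 0.9, 0.9, 0.9), 4),
                    nrow = 4, byrow = TRUE),
             matrix(rep(c(0.2, 0.2, 0.2, 0.9, 0.9, 0.9), 4),
                    nrow = 4, byrow = TRUE))
  rownames(m) <- paste0("tf", 1:8)
  km <- kmeans_classes(m, k = 2, seed = 99)
  expect_length(unique(km$cluster[1:4]), 1L)
  expect_length(unique(km$cluster[5:8]), 1L)
  expect_false(km$cluster[1] == km$cluster[5])
  km2 <- kmeans_classes(m, k = 2, seed = 99)
  expect_identical(km$cluster, km2$cluster)

  set.seed(1)
  jm <- m + matrix(rnorm(48, 0, 1e-3), nrow = 8)
  kn <- kmeans_classes(jm, k = nrow(jm), seed = 5)
  expect_equal(kn$tot_withinss, 0, tolerance = 1e-12)
  expect_error(kmeans_classes(m, k = 9, seed = 1), "exceeds")
  expect_error(kmeans_classes(m, k = 2), "seed")
})

test_that("k-means inertia beats random assignments on a toy matrix", {
  set.seed(30)
  m <- matrix(runif(60), nrow = 10)
  km <- kmeans_classes(m, k = 3, seed = 7)
  inertia <- function(assign) {
    sum(vapply(unique(assign), function(g) {
      rows <- m[assign == g, , drop = FALSE]
      sum(sweep(rows, 2, colMeans(rows))^2)
    }, numeric(1)))
  }
  rand <- replicate(100, inertia(sample(1:3, 10, replace = TRUE)))
  expect_lte(km$tot_withinss, min(rand) + 1e-9)
})

test_that("concentration rescaling is proportional with lambda untouched", {
  expect_equal(rescale_concentration(100, 5, 5), 100)
  expect_equal(rescale_concentration(100, 5, 10), 200)
  expect_equal(rescale_concentration(500, 1, 0.3, 1.5), 225)
  expect_error(rescale_concentration(0, 1, 1), "positive")
  expect_error(rescale_concentration(10, 1, -2), "positive")
})

test_that("peak overlap counts and Jaccard match an all-pairs oracle", {
  a <- genomic_intervals("c", c(0, 100, 200, 300), c(50, 150, 250, 350))
  b <- genomic_intervals("c", c(40, 400, 210, 600), c(90, 450, 260, 650))
  d <- genomic_intervals("c", c(1000, 1100), c(1050, 1150))
  om <- peak_overlap_matrix(list(A = a, B = b, D = d))
  brute_count <- function(x, y) {
    n <- 0
    for (i in seq_len(nrow(x))) {
      hit <- FALSE
      for (j in seq_len(nrow(y)))
        if (x$seqname[i] == y$seqname[j] &&
            x$start[i] < y$end[j] && y$start[j] < x$end[i]) hit <- TRUE
      n <- n + hit
    }
    n
  }
  expect_equal(om$count["A", "B"], brute_count(a, b))
  expect_equal(om$count["B", "A"], brute_count(b, a))
  expect_equal(om$count["A", "D"], 0L)
  expect_equal(om$jaccard["A", "D"], 0)
  self <- peak_overlap_matrix(list(X = a, Y = a))
  expect_equal(self$jaccard["X", "Y"], 1)
  expect_equal(self$count["X", "Y"], nrow(a))
})

test_that("top-k selection uses peak scores", {
  a <- genomic_intervals("c", c(0, 100, 200), c(50, 150, 250),
                         score = c(5, 1, 3))
  b <- genomic_intervals("c", c(0, 200), c(50, 250), score = c(2, 9))
  om <- peak_overlap_matrix(list(A = a, B = b), top_k = 1)
  # top peak of A is [0,50), top of B is [200,250): disjoint
  expect_equal(om$count["A", "B"], 0L)
})

test_that("accessibility-extreme signal means match hand computation", {
  chip <- signal_track(list(c = c(1:10, rep(0, 10), rep(5, 10), 21:50)))
  access <- signal_track(list(c = rep(c(9, 1, 5, 3, 8), each = 10)))
  regions <- bin_genome(c(c = 50L), 10)
  out <- signal_at_accessibility_extremes(chip, access, regions,
                                          k = 2, flank_bp = 2)
  # accessibility ranks regions (by mean): r1=9, r5=8, r3=5, r4=3, r2=1
  # midpoints at 5, 45 (top) and 15, 35 (bottom); windows are mid +/- 2
  top_mean <- colMeans(rbind(chip$c[4:8], chip$c[44:48]))
  bot_mean <- colMeans(rbind(chip$c[14:18], chip$c[34:38]))
  expect_equal(out$top, top_mean)
  expect_equal(out$bottom, bot_mean)
  # chip == access ranks top group above bottom group
  out2 <- signal_at_accessibility_extremes(access, access, regions, 2, 2)
  expect_gt(mean(out2$top), mean(out2$bottom))
  const <- signal_track(list(c = rep(4, 50)))
  out3 <- signal_at_accessibility_extremes(const, access, regions, 2, 2)
  expect_equal(mean(out3$top), mean(out3$bottom))
  expect_error(signal_at_accessibility_extremes(chip, access, regions,
                                                k = 3, flank_bp = 2),
               "regions")
})

test_that("TSS split partitions peaks by nearest-TSS distance", {
  peaks <- genomic_intervals("c", c(0, 900, 5000, 9000, 12000, 20000),
                             c(100, 1000, 5100, 9100, 12100, 20100))
  tss <- genomic_intervals("c", c(1000, 10000), c(1001, 10001))
  sp <- split_peaks_by_tss(peaks, tss, proximal_bp = 2000)
  mids <- floor((peaks$start + peaks$end) / 2)
  brute_dist <- vapply(mids, function(m)
    min(abs(m - 1000), abs(m - 10000)), numeric(1))
  expect_equal(sort(floor((sp$proximal$start + sp$proximal$end) / 2)),
               sort(mids[brute_dist <= 2000]))
  expect_equal(nrow(sp$proximal) + nrow(sp$distal), nrow(peaks))
  expect_length(intersect(sp$proximal$start, sp$distal$start), 0L)
  expect_error(split_peaks_by_tss(peaks,
    genomic_intervals(character(0), integer(0), integer(0))), "empty")
})
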