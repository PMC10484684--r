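make_peaks <- function(seqname, mids, width = 10, score = 1) {
  genomic_intervals(rep(seqname, length(mids)), mids - width / 2,
                    mids + width / 2, score = score)
}

test_that("genome binning tiles each sequence and conserves bp", {
  bins <- bin_genome(c(chr1 = 120000L), 50000)
  expect_equal(bins$start, c(0, 50000, 100000))
  expect_equal(bins$end, c(50000, 100000, 120000))
  one <- bin_genome(c(chr1 = 30000L), 50000)
  expect_equal(nrow(one), 1L)
  multi <- bin_genome(c(a = 70000L, b = 120001L), 25000)
  expect_equal(sum(multi$end - multi$start), 70000 + 120001)
})

test_that("bins rank by peak count with training and validation disjoint", {
  set.seed(20)
  bins <- bin_genome(c(chr = 1000000L), 10000)   # 100 bins
  # bin i gets i peaks (distinct counts)
  mids <- unlist(lapply(seq_len(100), function(i)
    bins$start[i] + seq(100, 9900, length.out = i)))
  peaks <- make_peaks("chr", round(mids))
  sel <- rank_and_select(bins, peaks, n_train = 10, n_validate = 50)
  expect_equal(sel$training$score, 100:91)
  expect_equal(sel$validation$score, 90:41)
  key_t <- paste(sel$training$start, sel$training$end)
  key_v <- paste(sel$validation$start, sel$validation$end)
  expect_length(intersect(key_t, key_v), 0L)

  # permuting bin order leaves the selection unchanged
  perm <- sample(nrow(bins))
  sel2 <- rank_and_select(bins[perm, ], peaks, 10, 50)
  expect_equal(sort(paste(sel2$training$start)), sort(paste(sel$training$start)))
})

test_that("degenerate ranking inputs error", {
  bins <- bin_genome(c(chr = 100000L), 10000)
  expect_error(rank_and_select(bins, make_peaks("chr", 5000), 10, 50),
               "too few bins")
  bins2 <- bin_genome(c(chr = 1000000L), 10000)
  nopeaks <- genomic_intervals(character(0), integer(0), integer(0))
  expect_error(rank_and_select(bins2, nopeaks, 10, 50),
               "insufficient signal")
})

test_that("strength groups sit at the top, middle and bottom ranks", {
  bins <- bin_genome(c(chr = 3000000L), 10000)   # 300 bins
  mids <- unlist(lapply(seq_len(300), function(i)
    bins$start[i] + seq(100, 9900, length.out = i)))
  peaks <- make_peaks("chr", round(mids))
  gr <- select_strength_groups(bins, peaks, group_size = 50)
  expect_equal(gr$strong$score, 300:251)         # ranks 1-50
  expect_equal(gr$medium$score, 175:126)         # ranks 126-175
  expect_equal(gr$weak$score, 50:1)              # ranks 251-300
  # exactly 3 * group_size peak-bearing bins partition cleanly
  gr2 <- select_strength_groups(bins[1:150, ], peaks, group_size = 50)
  all_scores <- sort(c(gr2$strong$score, gr2$medium$score, gr2$weak$score))
  expect_equal(all_scores, sort(150:1))
  gr3 <- select_strength_groups(bins, peaks, group_size = 1)
  expect_equal(gr3$strong$score, 300)
  expect_equal(gr3$weak$score, 1)
  expect_error(select_strength_groups(bins[1:100, ], peaks, 50),
               "too few")
})

test_that("Mann-Whitney AUC matches the concordant-pair oracle", {
  labels <- c(1, 0, 1, 0, 0, 1)
  scores <- c(.9, .8, .7, .4, .3, .2)
  expect_equal(roc_auc(labels, scores), brute_auc(labels, scores))
  expect_equal(roc_auc(c(1, 1, 0, 0), c(4, 3, 2, 1)), 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(2, 4)), 0.5)
  expect_true(is.na(roc_auc(c(1, 1), c(1, 2))))
  set.seed(21)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    lab <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    sc <- sample(1:5, n, replace = TRUE)
    expect_equal(roc_auc(lab, sc), brute_auc(lab, sc))
  }
})

test_that("AUC is invariant under monotone score transforms and matches pROC", {
  set.seed(22)
  lab <- sample(c(0, 1), 40, replace = TRUE)
  sc <- rnorm(40)
  expect_equal(roc_auc(lab, sc), roc_auc(lab, exp(sc)))
  expect_equal(roc_auc(lab, sc), roc_auc(lab, rank(sc)))
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(lab, sc), ref, tolerance = 1e-12)
})

test_that("window validation labels by peak overlap and scores by max", {
  region <- genomic_intervals("chr", 0, 600)
  pred <- setNames(list(c(rep(0.9, 100), rep(0.1, 100), rep(0.8, 100),
                          rep(0.2, 100), rep(0.05, 100), rep(0.7, 100))),
                   region_key <- "chr:0-600")
  peaks <- make_peaks("chr", c(50, 250, 550), width = 20)
  va <- validate_auc(region, pred, peaks, window_bp = 100)
  expect_equal(va$n_pos, 3L)
  expect_equal(va$n_neg, 3L)
  expect_equal(va$auc, brute_auc(c(1, 0, 1, 0, 0, 1),
                                 c(.9, .1, .8, .2, .05, .7)))
  # single-class labelling is flagged, not an error
  va2 <- validate_auc(region, pred,
                      genomic_intervals(character(0), integer(0), integer(0)),
                      window_bp = 100)
  expect_true(is.na(va2$auc))
  expect_true(va2$flagged)
})

test_that("a 1x1 grid returns that pair and noiseless refits recover truth", {
  set.seed(23)
  scn <- synthetic_scenario("accessibility_independent", seed = 23,
                            genome_bp = 2e5, pfm = default_motif_pfm(60))
  ds <- generate_dataset(scn)
  bins <- bin_genome(c(chrS = 2e5L), 25000)
  sel <- rank_and_select(bins, ds$peaks, 3, 3)
  pwm <- pfm_to_pwm(scn$pfm)
  ts <- scan_regions(ds$genome, sel$training, pwm)
  ones <- uniform_accessibility(c(chrS = 2e5L))
  acc_sl <- track_slice(ones, sel$training)

  single <- fit_parameters(ts, acc_sl, track_slice(ds$chip, sel$training),
                           N_grid = 77, lambda_grid = 1.3, L = 2e5)
  expect_equal(single$N, 77)
  expect_equal(single$lambda, 1.3)
  expect_true(is.finite(single$mse))

  # noiseless ChIP generated from the model at an on-grid pair
  truth <- model_parameters(500, 1, 2e5, 1)
  noiseless <- predict_regions(ts, acc_sl, truth)
  fit <- fit_parameters(ts, acc_sl, noiseless,
                        N_grid = c(50, 500, 5000),
                        lambda_grid = c(0.5, 1, 2), L = 2e5)
  expect_equal(fit$N, 500)
  expect_equal(fit$lambda, 1)
  expect_lt(fit$mse, 1e-20)
})

test_that("the fitted pair attains the exhaustive-surface minimum", {
  set.seed(24)
  scn <- synthetic_scenario("accessibility_independent", seed = 24,
                            genome_bp = 2e5)
  ds <- generate_dataset(scn)
  bins <- bin_genome(c(chrS = 2e5L), 25000)
  sel <- rank_and_select(bins, ds$peaks, 3, 3)
  pwm <- pfm_to_pwm(scn$pfm)
  ts <- scan_regions(ds$genome, sel$training, pwm)
  acc_sl <- track_slice(uniform_accessibility(c(chrS = 2e5L)),
                        sel$training)
  chip_sl <- track_slice(ds$chip, sel$training)
  N_grid <- c(10, 500, 2e4); lambda_grid <- c(0.5, 1, 2)
  fit <- fit_parameters(ts, acc_sl, chip_sl, N_grid, lambda_grid, L = 2e5)
  # independent surface via the public prediction path
  chip01 <- tfoccupancy:::rescale01(chip_sl[names(ts)])
  for (N in N_grid) for (lam in lambda_grid) {
    pred <- predict_regions(ts, acc_sl, model_parameters(N, lam, 2e5))
    pred01 <- tfoccupancy:::rescale01(pred)
    mse <- sum(vapply(seq_along(pred01), function(i)
      sum((pred01[[i]] - chip01[[i]])^2), numeric(1))) /
      sum(lengths(chip01))
    expect_gte(mse + 1e-15, fit$mse)
    expect_equal(mse, fit$mse_surface[as.character(lam), as.character(N)],
                 tolerance = 1e-12)
  }
})

test_that("a single-value QDA grid yields a single AUC entry", {
  scn <- synthetic_scenario("accessibility_independent", seed = 25,
                            genome_bp = 2e5)
  ds <- generate_dataset(scn)
  bins <- bin_genome(c(chrS = 2e5L), 25000)
  sel <- rank_and_select(bins, ds$peaks, 3, 3)
  res <- auc_over_qda(ds$genome, ds$access, ds$chip, ds$peaks,
                      sel$training, sel$validation, pfm_to_pwm(scn$pfm),
                      qda_grid = 0, N_grid = c(50, 500),
                      lambda_grid = 1, L = 2e5)
  expect_length(res$auc, 1L)
  expect_true(res$auc >= 0 && res$auc <= 1)
})
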