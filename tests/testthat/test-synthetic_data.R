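test_that("generation is byte-identical under a fixed seed", {
  scn <- synthetic_scenario("open_only", seed = 5, genome_bp = 5e4)
  d1 <- generate_dataset(scn)
  d2 <- generate_dataset(scn)
  expect_identical(d1$genome, d2$genome)
  expect_identical(d1$access$chrS, d2$access$chrS)
  expect_identical(d1$chip$chrS, d2$chip$chrS)
  expect_identical(d1$peaks, d2$peaks)
})

test_that("the truth BED carries one record per planted site", {
  scn <- synthetic_scenario("accessibility_independent", seed = 6,
                            genome_bp = 5e4, n_sites = 20)
  g <- generate_genome(scn)
  expect_equal(nrow(g$sites), 20L)
  m <- ncol(scn$pfm$matrix)
  expect_true(all(g$sites$end - g$sites$start == m))
  expect_true(all(g$sites$start >= 0 & g$sites$end <= 5e4))
  # non-overlapping
  o <- order(g$sites$start)
  expect_true(all(diff(g$sites$start[o]) >= m))
})

test_that("planted sites score higher than random positions on average", {
  scn <- synthetic_scenario("accessibility_independent", seed = 7,
                            genome_bp = 1e5, n_sites = 30)
  g <- generate_genome(scn)
  scores <- pwm_scan(g$genome, pfm_to_pwm(scn$pfm))$chrS
  at_sites <- scores[g$sites$start + 1]
  set.seed(1)
  random <- scores[sample(length(scores), 500)]
  expect_gt(mean(at_sites), mean(random) + 5)
})

test_that("island bp fraction lands within 2% of target at megabase scale", {
  scn <- synthetic_scenario("open_only", seed = 8, genome_bp = 1e6,
                            island_fraction = 0.1)
  a <- generate_accessibility(scn)
  frac <- sum(a$islands$end - a$islands$start) / 1e6
  expect_lt(abs(frac - 0.1), 0.02)
})

test_that("zero noise yields exactly two accessibility levels", {
  scn <- synthetic_scenario("open_only", seed = 9, genome_bp = 2e4,
                            noise_sd = 0)
  a <- generate_accessibility(scn)
  expect_setequal(unique(a$signal$chrS),
                  c(scn$dense_level, scn$open_level))
})

test_that("QDA at the island quantile recovers approximately the islands", {
  scn <- synthetic_scenario("open_only", seed = 10, genome_bp = 2e5,
                            island_fraction = 0.1)
  a <- generate_accessibility(scn)
  acc <- apply_qda(a$signal, 0.9)
  island_mask <- logical(2e5)
  for (i in seq_len(nrow(a$islands)))
    island_mask[(a$islands$start[i] + 1):a$islands$end[i]] <- TRUE
  open <- acc$chrS == 1
  # overlap agreement between the QDA-selected set and the island truth
  expect_gt(sum(open & island_mask) / sum(island_mask), 0.85)
  expect_lt(mean(open & !island_mask), 0.03)
})

test_that("a TF-free scenario yields an all-zero track and no peaks", {
  scn <- synthetic_scenario("open_only", seed = 11, genome_bp = 3e4,
                            n_sites = 0, background_rate = 0,
                            N_true = 1e-6)
  ds <- generate_dataset(scn)
  expect_equal(max(ds$chip$chrS), 0)
  expect_equal(nrow(ds$peaks), 0L)
})

test_that("open_only confines binding to the most accessible chromatin", {
  scn <- synthetic_scenario("open_only", seed = 12, genome_bp = 3e5)
  ds <- generate_dataset(scn)
  mask <- apply_qda(ds$access, 0.95)
  mids <- floor((ds$peaks$start + ds$peaks$end) / 2)
  expect_gte(mean(mask$chrS[mids + 1] == 1), 0.95)
})

test_that("accessibility_independent peaks are covered by open islands", {
  scn <- synthetic_scenario("accessibility_independent", seed = 13,
                            genome_bp = 3e5)
  ds <- generate_dataset(scn)
  island_mask <- logical(3e5)
  for (i in seq_len(nrow(ds$islands)))
    island_mask[(ds$islands$start[i] + 1):ds$islands$end[i]] <- TRUE
  mids <- floor((ds$peaks$start + ds$peaks$end) / 2)
  expect_gte(mean(island_mask[mids + 1]), 0.9)
})

test_that("dense_preferring binding avoids the open top decile", {
  scn <- synthetic_scenario("dense_preferring", seed = 14, genome_bp = 3e5)
  ds <- generate_dataset(scn)
  top <- apply_qda(ds$access, 0.9)
  mids <- floor((ds$peaks$start + ds$peaks$end) / 2)
  expect_lte(mean(top$chrS[mids + 1] == 1), 0.1)
})

test_that("written datasets re-read without loss through io functions", {
  scn <- synthetic_scenario("open_only", seed = 15, genome_bp = 3e4)
  ds <- generate_dataset(scn)
  dir <- file.path(tempdir(), "synth_ds")
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  genome <- read_fasta(paths["genome"])
  expect_identical(genome, ds$genome)
  lens <- setNames(nchar(genome), names(genome))
  access <- read_signal(paths["access"], "bedGraph", lens)
  expect_equal(access$chrS, ds$access$chrS)
  chip <- read_signal(paths["chip"], "bedGraph", lens)
  expect_equal(chip$chrS, ds$chip$chrS)
  peaks <- read_intervals(paths["peaks"], "bed")
  expect_equal(peaks$start, ds$peaks$start)
  expect_equal(peaks$end, ds$peaks$end)
  pfm <- read_jaspar_pfm(paths["pfm"])
  expect_equal(unname(pfm$matrix), unname(scn$pfm$matrix))
  unlink(dir, recursive = TRUE)
})
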