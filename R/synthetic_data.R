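# Seeded synthetic data with the statistical structure the analysis
# assumes: a random genome with planted motif instances, a block-
# structured accessibility track (open islands over a dense background),
# and ChIP counts Poisson-sampled around the model's own occupancy
# profile under a regime-specific binding mask.
#
# The three regimes emulate the operational phenotypes the classifier
# must recover:
#  * accessibility_independent - every strong site is bound and the
#    accessibility assay reports the bound sites as open (a TF that opens
#    or book-marks its sites); sites are sparse, as real strong binding
#    sites are.
#  * open_only - motif instances are abundant but only those in the most
#    accessible decile are bound: the unbound inaccessible instances act
#    as the sequence decoys that degrade low-QDA predictions.
#  * dense_preferring - binding is confined to instances outside the top
#    accessibility decile.

#' Default synthetic motif
#'
#' A 12-column PFM with one dominant base per column (85 of 100 counts):
#' informative enough that chance consensus matches are negligible at
#' megabase scale, degenerate enough that planted instances span a range
#' of affinities.
#'
#' @param dominant counts (of 100) of the preferred base per column;
#'   lower values give a more degenerate motif.
#' @return A `PFM` object.
#' @export
default_motif_pfm <- function(dominant = 85) {
  stopifnot(dominant > 25, dominant <= 100)
  cons <- c("T", "G", "A", "C", "T", "G", "C", "A", "T", "C", "A", "G")
  rest <- (100 - dominant) / 3
  mat <- matrix(rest, nrow = 4, ncol = length(cons),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (k in seq_along(cons)) mat[cons[k], k] <- dominant
  structure(list(matrix = mat, id = "SYN0001", name = "synthetic_tf"),
            class = "PFM")
}

#' Define a synthetic scenario
#'
#' All randomness downstream is fixed by `seed`. Defaults describe a
#' 1 Mb haploid genome with a realistic open-chromatin fraction (4% of
#' bp in islands) and regime-appropriate planted-site density:
#' accessibility-independent TFs get 60 sparse strong sites per Mb (all
#' bound), the accessibility-sensitive regimes get denser motif
#' landscapes of which only a chromatin-selected subset is bound.
#'
#' @param regime one of `"accessibility_independent"`, `"open_only"`,
#'   `"dense_preferring"`.
#' @param seed integer seed fixing all randomness.
#' @param genome_bp genome length.
#' @param gc GC fraction of the background sequence.
#' @param n_sites planted motif instances (`NULL` = regime default per Mb:
#'   60 / 6000 / 200).
#' @param pfm motif as a `PFM`.
#' @param island_fraction target fraction of bp in open islands.
#' @param island_len_bp mean island length.
#' @param open_level,dense_level accessibility score levels for islands
#'   and background.
#' @param noise_sd multiplicative (log-normal) noise on segment scores;
#'   0 gives exactly two levels.
#' @param segment_bp background segment granularity.
#' @param N_true,lambda_true occupancy parameters generating the ChIP
#'   signal.
#' @param depth expected ChIP reads per bp at a fully occupied site.
#' @param background_rate uniform background reads per bp.
#' @param peak_factor peaks require expected signal above
#'   `peak_factor * background_rate`.
#' @param kernel,bandwidth_bp smoothing applied to the occupancy before
#'   sampling counts.
#' @return A `SyntheticScenario` list.
#' @export
synthetic_scenario <- function(regime = c("accessibility_independent",
                                          "open_only", "dense_preferring"),
                               seed = 1L, genome_bp = 1e6, gc = 0.41,
                               n_sites = NULL, pfm = default_motif_pfm(),
                               island_fraction = 0.04, island_len_bp = 600,
                               open_level = 10, dense_level = 0.5,
                               noise_sd = 0.15, segment_bp = 500,
                               N_true = 500, lambda_true = 1,
                               depth = 50, background_rate = 0.5,
                               peak_factor = 5,
                               kernel = "gaussian", bandwidth_bp = 100) {
  regime <- match.arg(regime)
  if (is.null(n_sites)) {
    per_mb <- switch(regime, accessibility_independent = 60,
                     open_only = 6000, dense_preferring = 200)
    n_sites <- max(1L, round(per_mb * genome_bp / 1e6))
  }
  stopifnot(n_sites >= 0)
  m <- ncol(pfm$matrix)
  stopifnot(genome_bp >= 10 * m, island_fraction > 0, island_fraction < 1,
            N_true > 0, lambda_true > 0)
  structure(list(regime = regime, seed = as.integer(seed),
                 genome_bp = as.integer(genome_bp), gc = gc,
                 n_sites = as.integer(n_sites), pfm = pfm,
                 island_fraction = island_fraction,
                 island_len_bp = island_len_bp, open_level = open_level,
                 dense_level = dense_level, noise_sd = noise_sd,
                 segment_bp = segment_bp, N_true = N_true,
                 lambda_true = lambda_true, depth = depth,
                 background_rate = background_rate,
                 peak_factor = peak_factor, kernel = kernel,
                 bandwidth_bp = bandwidth_bp, seqname = "chrS"),
            class = "SyntheticScenario")
}

# non-overlapping start positions with minimum separation, by redraw
sample_site_starts <- function(n, L, m, max_retry = 100) {
  starts <- sort(sample.int(L - m + 1L, n) - 1L)
  for (it in seq_len(max_retry)) {
    ok <- c(TRUE, diff(starts) >= m)
    if (all(ok)) return(starts)
    n_bad <- sum(!ok)
    starts <- sort(c(starts[ok], sample.int(L - m + 1L, n_bad) - 1L))
  }
  stop("could not place ", n, " non-overlapping sites after ", max_retry,
       " retries")
}

sample_motif_instance <- function(pfm) {
  prob <- sweep(pfm$matrix, 2, colSums(pfm$matrix), "/")
  paste(vapply(seq_len(ncol(prob)), function(k)
    sample(rownames(prob), 1, prob = prob[, k]), character(1)),
    collapse = "")
}

#' Generate the synthetic genome with planted motif instances
#'
#' Background bases are i.i.d. at the scenario GC; planted instances are
#' sampled column-wise from the PFM and inserted on a random strand at
#' non-overlapping positions.
#'
#' @param scenario a [synthetic_scenario()].
#' @return List with `genome` (named character vector) and `sites`
#'   (truth interval data frame with strand).
#' @export
generate_genome <- function(scenario) {
  set.seed(scenario$seed)
  L <- scenario$genome_bp
  m <- ncol(scenario$pfm$matrix)
  p <- c((1 - scenario$gc) / 2, scenario$gc / 2, scenario$gc / 2,
         (1 - scenario$gc) / 2)
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p)
  starts <- if (scenario$n_sites == 0) integer(0)
            else sample_site_starts(scenario$n_sites, L, m)
  strands <- ifelse(runif(scenario$n_sites) < 0.5, "+", "-")
  for (i in seq_along(starts)) {
    inst <- sample_motif_instance(scenario$pfm)
    if (strands[i] == "-") inst <- revcomp(inst)
    bases[(starts[i] + 1):(starts[i] + m)] <- strsplit(inst, "")[[1]]
  }
  genome <- setNames(paste(bases, collapse = ""), scenario$seqname)
  sites <- if (length(starts) == 0)
    genomic_intervals(character(0), integer(0), integer(0))
  else genomic_intervals(rep(scenario$seqname, length(starts)), starts,
                         starts + m, strand = strands)
  list(genome = genome, sites = sites)
}

# non-overlapping islands totalling >= target bp (greedy redraw)
place_islands <- function(L, target_bp, len_mean, fixed_centers = integer(0),
                          len_sd_frac = 0.25, max_retry = 200) {
  draw_len <- function(k) pmax(50L, round(rnorm(k, len_mean,
                                                len_sd_frac * len_mean)))
  starts <- integer(0); ends <- integer(0)
  if (length(fixed_centers)) {
    lens <- draw_len(length(fixed_centers))
    starts <- pmax(0L, as.integer(fixed_centers - lens %/% 2))
    ends <- pmin(L, starts + lens)
    o <- order(starts); starts <- starts[o]; ends <- ends[o]
    # merge overlapping islands so every fixed centre stays covered
    ir <- IRanges::reduce(IRanges::IRanges(starts + 1L, ends))
    starts <- BiocGenerics::start(ir) - 1L
    ends <- BiocGenerics::end(ir)
  }
  it <- 0
  while (sum(ends - starts) < target_bp && it < max_retry) {
    it <- it + 1
    len <- draw_len(1)
    st <- sample.int(L - len, 1) - 1L
    en <- st + len
    if (!any(st < ends & en > starts)) {
      o <- order(c(starts, st))
      starts <- c(starts, st)[o]; ends <- c(ends, en)[o]
    }
  }
  data.frame(start = starts, end = ends)
}

#' Generate the synthetic accessibility track
#'
#' Open islands (high score) over a dense background (low score), both
#' with per-segment multiplicative log-normal noise. In the
#' accessibility-independent regime islands are centred on the planted
#' sites (the assay sees bound sites as open) and random islands are
#' added up to the target fraction; otherwise all islands are random.
#'
#' @param scenario a [synthetic_scenario()].
#' @param sites truth sites from [generate_genome()] (used only by the
#'   accessibility-independent regime).
#' @return List with `signal` (a [signal_track()]) and `islands`
#'   (interval data frame).
#' @export
generate_accessibility <- function(scenario, sites = NULL) {
  set.seed(scenario$seed + 1000L)
  L <- scenario$genome_bp
  target <- round(scenario$island_fraction * L)
  centers <- integer(0)
  if (scenario$regime == "accessibility_independent" && !is.null(sites)) {
    centers <- floor((sites$start + sites$end) / 2)
  }
  isl <- place_islands(L, target, scenario$island_len_bp, centers)
  vals <- numeric(L)
  noise <- function(k) {
    if (scenario$noise_sd == 0) rep(1, k)
    else exp(rnorm(k, 0, scenario$noise_sd))
  }
  # dense background in segment_bp chunks, each with one noisy value
  seg_starts <- seq(0L, L - 1L, by = scenario$segment_bp)
  seg_ends <- pmin(seg_starts + scenario$segment_bp, L)
  seg_vals <- scenario$dense_level * noise(length(seg_starts))
  for (i in seq_along(seg_starts))
    vals[(seg_starts[i] + 1):seg_ends[i]] <- seg_vals[i]
  isl_vals <- scenario$open_level * noise(nrow(isl))
  for (i in seq_len(nrow(isl)))
    vals[(isl$start[i] + 1):isl$end[i]] <- isl_vals[i]
  signal <- signal_track(setNames(list(vals), scenario$seqname))
  islands <- genomic_intervals(scenario$seqname, isl$start, isl$end)
  list(signal = signal, islands = islands)
}

# Regime-specific accessibility used to generate (not analyse) binding.
# open_only binds the top accessibility ventile; dense_preferring binds a
# mid-accessibility band (moderately closed, mappable chromatin: sites
# there are invisible to the model whenever only the open top of the
# genome is considered accessible, but fully visible at low QDA).
regime_binding_access <- function(scenario, access_signal) {
  switch(scenario$regime,
    accessibility_independent =
      uniform_accessibility(track_lengths(access_signal)),
    open_only = apply_qda(access_signal, 0.95),
    dense_preferring = {
      pooled <- unlist(access_signal, use.names = FALSE)
      scored <- pooled[pooled > 0]
      lo <- as.numeric(quantile(scored, 0.3))
      hi <- as.numeric(quantile(scored, 0.9))
      band <- lapply(access_signal, function(v)
        as.numeric(v > 0 & v >= lo & v < hi))
      structure(signal_track(band), qda = NA_real_, threshold = NA_real_,
                class = c("AccessibilityTrack", "SignalTrack"))
    })
}

#' Generate synthetic ChIP signal and peaks
#'
#' Expected coverage is `depth * smoothed P_bound` (computed at the
#' scenario's true parameters under the regime binding mask) plus a
#' uniform background; per-bp counts are Poisson-sampled. Peaks are
#' maximal runs where the noiseless expected signal exceeds both
#' `peak_factor * background_rate` and 20% of its own maximum, scored by
#' their peak expected signal.
#'
#' @param scenario a [synthetic_scenario()].
#' @param genome named character vector from [generate_genome()].
#' @param access_signal accessibility [signal_track()] from
#'   [generate_accessibility()].
#' @return List with `chip` (counts [signal_track()]), `peaks`
#'   (interval data frame), `expected` (noiseless expected signal).
#' @export
generate_chip <- function(scenario, genome, access_signal) {
  set.seed(scenario$seed + 2000L)
  pwm <- pfm_to_pwm(scenario$pfm)
  scores <- pwm_scan(genome, pwm)
  bind_acc <- regime_binding_access(scenario, access_signal)
  params <- model_parameters(scenario$N_true, scenario$lambda_true,
                             L = scenario$genome_bp, n = 1)
  occ <- site_occupancy(scores, bind_acc, params)
  pred <- smooth_profile(occ, scenario$kernel, scenario$bandwidth_bp)
  pred_bp <- profile_to_bp(pred, track_lengths(access_signal))
  # fragment-pileup gain: every bound molecule contributes a whole
  # fragment of reads, so an isolated saturated site reaches ~depth
  gain <- 1 / max(smoothing_kernel(scenario$kernel, scenario$bandwidth_bp))
  expected <- lapply(pred_bp, function(v) scenario$depth * gain * v)
  lambda_counts <- lapply(expected, function(v)
    v + scenario$background_rate)
  chip <- signal_track(lapply(lambda_counts, function(v)
    rpois(length(v), v)))
  peaks <- call_peaks(expected, scenario$peak_factor,
                      scenario$background_rate)
  list(chip = chip, peaks = peaks, expected = signal_track(expected))
}

# maximal runs of expected signal above threshold; min_expected is an
# absolute floor (reads/bp) so a TF-free track yields no peaks
call_peaks <- function(expected, peak_factor, background_rate,
                       min_width = 20L, rel_floor = 0.2,
                       min_expected = 1) {
  rows <- lapply(names(expected), function(s) {
    v <- expected[[s]]
    thr <- max(peak_factor * background_rate, rel_floor * max(v),
               min_expected)
    r <- rle(v > thr)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths
    keep <- r$values & r$lengths >= min_width
    if (!any(keep)) return(NULL)
    sc <- vapply(which(keep), function(i)
      max(v[(starts[i] + 1):ends[i]]), numeric(1))
    data.frame(seqname = s, start = starts[keep], end = ends[keep],
               score = sc, strand = ".", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out))
    out <- genomic_intervals(character(0), integer(0), integer(0))
  out
}

# Sites the model actually binds appreciably under unrestricted
# accessibility: planted instances with strong sampled letters plus any
# spontaneous near-consensus match. These are the positions an
# accessibility-independent TF renders open in a real assay, so the
# island generator anchors on them.
bound_site_anchors <- function(scenario, genome, min_occupancy = 0.1) {
  pwm <- pfm_to_pwm(scenario$pfm)
  scores <- pwm_scan(genome, pwm)
  params <- model_parameters(scenario$N_true, scenario$lambda_true,
                             L = scenario$genome_bp, n = 1)
  ones <- uniform_accessibility(setNames(nchar(genome), names(genome)))
  occ <- site_occupancy(scores, ones, params)
  m <- ncol(scenario$pfm$matrix)
  rows <- lapply(names(occ), function(s) {
    idx <- which(occ[[s]] >= min_occupancy)
    if (!length(idx)) return(NULL)
    # cluster nearby hits (overlapping windows of one site)
    grp <- cumsum(c(1L, diff(idx) > 2L * m))
    starts <- vapply(split(idx, grp), function(g)
      as.integer(round(mean(g))) - 1L, integer(1))
    data.frame(seqname = s, start = starts, end = starts + m,
               score = NA_real_, strand = ".", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) genomic_intervals(character(0), integer(0), integer(0))
  else out
}

#' Generate a complete synthetic dataset
#'
#' Runs genome, accessibility and ChIP generation and returns every
#' truth object alongside the data. In the accessibility-independent
#' regime the islands are anchored on every site the model binds
#' appreciably (planted or spontaneous), since such a TF keeps its bound
#' sites accessible.
#'
#' @param scenario a [synthetic_scenario()].
#' @return List with `genome`, `sites`, `access`, `islands`, `chip`,
#'   `peaks`, `expected`, `scenario`.
#' @export
generate_dataset <- function(scenario) {
  g <- generate_genome(scenario)
  anchors <- if (scenario$regime == "accessibility_independent")
    bound_site_anchors(scenario, g$genome) else g$sites
  a <- generate_accessibility(scenario, anchors)
  c_ <- generate_chip(scenario, g$genome, a$signal)
  list(genome = g$genome, sites = g$sites, access = a$signal,
       islands = a$islands, chip = c_$chip, peaks = c_$peaks,
       expected = c_$expected, scenario = scenario)
}

#' Write a synthetic dataset to disk
#'
#' Emits FASTA, accessibility and ChIP bedGraphs, truth/peak BEDs and
#' the motif in JASPAR text format; truth files always accompany the
#' data.
#'
#' @param dataset from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return Named vector of the written paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    access = file.path(dir, "accessibility.bedGraph"),
    chip = file.path(dir, "chip.bedGraph"),
    peaks = file.path(dir, "chip_peaks.bed"),
    sites = file.path(dir, "true_sites.bed"),
    islands = file.path(dir, "open_islands.bed"),
    pfm = file.path(dir, "motif.jaspar"))
  write_fasta(dataset$genome, paths["genome"])
  write_signal(dataset$access, paths["access"], "bedGraph")
  write_signal(dataset$chip, paths["chip"], "bedGraph")
  write_intervals(dataset$peaks, paths["peaks"])
  write_intervals(dataset$sites, paths["sites"])
  write_intervals(dataset$islands, paths["islands"])
  write_jaspar_pfm(dataset$scenario$pfm, paths["pfm"])
  paths
}
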