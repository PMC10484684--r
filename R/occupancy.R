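# The statistical-thermodynamics occupancy model. For a site j with PWM
# score w_j and accessibility a_j, the probability that a TF molecule is
# bound is
#
#   P_j = N a_j e^{w_j / lambda} /
#         ( N a_j e^{w_j / lambda} + L n < a_i e^{w_i / lambda} > )
#
# with N the number of TF molecules bound to the genome, lambda the
# specificity scaling factor, L and n the genome length and ploidy, and
# < . > the mean over all scanned sites of the analysed sequence set.
# Exponentials are computed after shifting all scores by their maximum;
# the shift cancels exactly in the ratio, so scores of any magnitude are
# numerically safe.

#' Occupancy model parameters
#'
#' @param N positive number of TF molecules bound to the genome.
#' @param lambda positive specificity scaling factor; low values sharpen
#'   the distinction between strong and weak sites.
#' @param L genome length in bp (a genome-scale constant, even when the
#'   model is evaluated over a sub-region).
#' @param n ploidy.
#' @return A `ModelParameters` object.
#' @export
model_parameters <- function(N, lambda, L, n = 1L) {
  stopifnot(N > 0, lambda > 0, L >= 1, n >= 1)
  structure(list(N = N, lambda = lambda, L = as.numeric(L),
                 n = as.integer(n)), class = "ModelParameters")
}

#' @export
print.ModelParameters <- function(x, ...) {
  cat(sprintf("ModelParameters: N = %g, lambda = %g, L = %g bp, n = %d\n",
              x$N, x$lambda, x$L, x$n))
  invisible(x)
}

# mean accessibility over the m bases a site covers, per sequence
site_accessibility <- function(access_vec, m) {
  n <- length(access_vec) - m + 1L
  if (m == 1L) return(access_vec)
  cs <- cumsum(c(0, access_vec))
  (cs[(m + 1):(n + m)] - cs[1:n]) / m
}

#' Per-site binding probability under the occupancy model
#'
#' `scores` and `access` must cover the same sequences; accessibility is
#' supplied per bp and averaged over each m-bp site. The normalising mean
#' is taken over all scanned sites of the supplied set (pooled across
#' sequences) unless a precomputed `background_mean` is given, which
#' permits genome-scale normalisation when evaluating sub-regions.
#'
#' @param scores a `ScoreTrack` from [pwm_scan()].
#' @param access a [signal_track()] (or `AccessibilityTrack`) with per-bp
#'   values in `[0, 1]` on the same sequences.
#' @param params a [model_parameters()] object.
#' @param background_mean optional precomputed value of
#'   `< a_i e^{(w_i - w_max)/lambda} >` together with its shift, as
#'   returned by [occupancy_background()].
#' @return An `OccupancyProfile`: named list of per-site probabilities in
#'   `[0, 1]`, aligned with `scores`.
#' @export
site_occupancy <- function(scores, access, params, background_mean = NULL) {
  stopifnot(inherits(params, "ModelParameters"))
  m <- attr(scores, "motif_width")
  if (!all(names(scores) %in% names(access)))
    stop("accessibility track missing sequences present in scores")
  a <- lapply(names(scores), function(s) {
    av <- access[[s]]
    if (length(av) != length(scores[[s]]) + m - 1L)
      stop("accessibility and score lengths inconsistent for ", s)
    if (any(av < 0 | av > 1)) stop("accessibility values outside [0, 1]")
    site_accessibility(av, m)
  })
  names(a) <- names(scores)
  if (is.null(background_mean)) {
    shift <- max(vapply(scores, max, numeric(1)))
    ax <- mapply(function(w, av) av * exp((w - shift) / params$lambda),
                 scores, a, SIMPLIFY = FALSE)
    mean_ax <- sum(vapply(ax, sum, numeric(1))) / sum(lengths(ax))
  } else {
    shift <- background_mean$shift
    ax <- mapply(function(w, av) av * exp((w - shift) / params$lambda),
                 scores, a, SIMPLIFY = FALSE)
    mean_ax <- background_mean$mean
  }
  if (mean_ax == 0) {
    # degenerate: all sites inaccessible; numerator vanishes everywhere too
    out <- lapply(scores, function(w) numeric(length(w)))
    return(structure(out, motif_width = m, class = "OccupancyProfile"))
  }
  denom_bg <- params$L * params$n * mean_ax
  out <- lapply(ax, function(x) {
    num <- params$N * x
    num / (num + denom_bg)
  })
  structure(out, motif_width = m, class = "OccupancyProfile")
}

#' Precompute the occupancy normalisation term
#'
#' Returns the shifted mean `< a_i e^{(w_i - shift)/lambda} >` over all
#' scanned sites, for reuse across [site_occupancy()] calls that should
#' share one normalisation (e.g. genome-wide background for region-level
#' evaluation).
#'
#' @inheritParams site_occupancy
#' @param lambda specificity factor the mean is computed under.
#' @return List with `mean` and `shift`.
#' @export
occupancy_background <- function(scores, access, lambda) {
  m <- attr(scores, "motif_width")
  shift <- max(vapply(scores, max, numeric(1)))
  tot <- 0; cnt <- 0
  for (s in names(scores)) {
    av <- site_accessibility(access[[s]], m)
    x <- av * exp((scores[[s]] - shift) / lambda)
    tot <- tot + sum(x); cnt <- cnt + length(x)
  }
  list(mean = tot / cnt, shift = shift)
}

#' @export
print.OccupancyProfile <- function(x, ...) {
  cat("OccupancyProfile:", length(x), "sequence(s), max P =",
      format(max(vapply(x, max, numeric(1))), digits = 4), "\n")
  invisible(x)
}

smoothing_kernel <- function(type = c("gaussian", "boxcar"), bandwidth_bp) {
  type <- match.arg(type)
  stopifnot(bandwidth_bp >= 1)
  if (type == "boxcar") {
    k <- rep(1, round(bandwidth_bp))
  } else {
    half <- ceiling(3 * bandwidth_bp)
    k <- exp(-0.5 * ((-half:half) / bandwidth_bp)^2)
  }
  k / sum(k)
}

# linear convolution via FFT, padded to a friendly length; returns the
# "same"-aligned central part with edge renormalisation so that a constant
# input maps to itself
conv_same_renorm <- function(x, k, den = NULL) {
  n <- length(x); kl <- length(k)
  if (n == 0) return(x)
  if (kl == 1) return(x * k / k)
  N2 <- stats::nextn(n + kl - 1L)
  fk <- stats::fft(c(k, numeric(N2 - kl)))
  num <- Re(stats::fft(stats::fft(c(x, numeric(N2 - n))) * fk,
                       inverse = TRUE)) / N2
  off <- (kl - 1L) %/% 2L
  if (is.null(den)) den <- conv_edge_weights(n, k)
  out <- num[(off + 1L):(off + n)] / den
  pmax(out, 0)
}

# edge normalisation weights: the kernel mass actually inside the signal
conv_edge_weights <- function(n, k) {
  kl <- length(k)
  N2 <- stats::nextn(n + kl - 1L)
  fk <- stats::fft(c(k, numeric(N2 - kl)))
  den <- Re(stats::fft(stats::fft(c(rep(1, n), numeric(N2 - n))) * fk,
                       inverse = TRUE)) / N2
  off <- (kl - 1L) %/% 2L
  den[(off + 1L):(off + n)]
}

#' Smooth an occupancy profile into a ChIP-like predicted profile
#'
#' Discrete convolution with a normalised kernel, mimicking the fragment-
#' size smearing of a ChIP experiment; edges are renormalised so that a
#' constant profile maps to itself. The default Gaussian kernel
#' (bandwidth = standard deviation, evaluated on a +/-3 sigma window)
#' reflects typical ChIP fragment-size smearing; the bandwidth is a free
#' choice recorded in the output.
#'
#' @param occ an `OccupancyProfile` (or any named list of numeric
#'   vectors).
#' @param kernel `"gaussian"` or `"boxcar"`.
#' @param bandwidth_bp Gaussian sigma or boxcar width, in bp.
#' @return A `PredictedProfile`: named list of smoothed non-negative
#'   vectors with a `kernel` attribute.
#' @export
smooth_profile <- function(occ, kernel = c("gaussian", "boxcar"),
                           bandwidth_bp = 100) {
  kernel <- match.arg(kernel)
  k <- smoothing_kernel(kernel, bandwidth_bp)
  out <- lapply(occ, conv_same_renorm, k = k)
  structure(out,
            kernel = list(type = kernel, bandwidth_bp = bandwidth_bp),
            motif_width = attr(occ, "motif_width"),
            class = "PredictedProfile")
}

#' @export
print.PredictedProfile <- function(x, ...) {
  kr <- attr(x, "kernel")
  cat(sprintf("PredictedProfile: %d sequence(s), %s kernel (%g bp)\n",
              length(x), kr$type, kr$bandwidth_bp))
  invisible(x)
}

# site-level profile -> per-bp profile (pad tail with the final value so
# track lengths match the sequence lengths)
profile_to_bp <- function(profile, seq_lengths) {
  vals <- lapply(names(profile), function(s) {
    v <- profile[[s]]
    c(v, rep(v[length(v)], seq_lengths[[s]] - length(v)))
  })
  names(vals) <- names(profile)
  vals
}
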