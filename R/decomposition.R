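#' Empirical mode decomposition of a trace
#'
#' Sifts a trace into intrinsic mode functions (IMFs) plus a residual.  Each
#' IMF is an oscillatory component whose envelope mean is locally near zero
#' and whose extrema and zero-crossing counts differ by at most one; the
#' residual carries the remaining trend.  Envelopes are cubic splines through
#' the extrema with mirrored boundary extension; sifting stops on a
#' Cauchy-type criterion (relative squared change below \code{sd_thresh})
#' or after \code{max_sift} iterations.
#'
#' The decomposition is complete by construction: the IMFs and residual sum
#' back to the input to machine precision.
#'
#' @param trace a \code{\link{time_series}} with at least 16 samples.
#' @param max_imfs maximum number of IMFs to extract; default
#'   \code{floor(log2(n)) - 1}.
#' @param sd_thresh Cauchy sifting-stop threshold (default 0.2).
#' @param max_sift cap on sifting iterations per IMF (default 50).
#' @return An object of class \code{imf_set}: list with \code{imfs} (matrix,
#'   one column per IMF), \code{residual}, \code{mean_inst_freq} (Hz per
#'   IMF), \code{sampling_rate}, \code{source_id}, \code{params}.  A monotone
#'   input yields zero IMFs and \code{residual == input}.
#' @seealso \code{\link{ceemdan}}, \code{\link{assemble_band}}
#' @export
sift_emd <- function(trace, max_imfs = NULL, sd_thresh = 0.2, max_sift = 50L) {
  stopifnot(inherits(trace, "time_series"))
  x <- trace$samples
  n <- length(x)
  if (n < 16L) stop("trace too short to decompose (need >= 16 samples)")
  if (is.null(max_imfs)) max_imfs <- max(1L, floor(log2(n)) - 1L)
  res <- .emd_c(x, as.integer(max_imfs), sd_thresh, as.integer(max_sift))
  new_imf_set(res$imfs, res$residual, trace,
              params = list(method = "emd", sd_thresh = sd_thresh,
                            max_sift = max_sift, max_imfs = max_imfs))
}

new_imf_set <- function(imfs, residual, trace, params) {
  imfs <- as.matrix(imfs)
  mif <- if (ncol(imfs) > 0)
    vapply(seq_len(ncol(imfs)), function(k) {
      f <- tryCatch(mean_instantaneous_frequency(imfs[, k], trace$sampling_rate),
                    error = function(e) NA_real_)
      f
    }, numeric(1))
  else numeric(0)
  structure(list(imfs = imfs, residual = as.numeric(residual),
                 mean_inst_freq = mif,
                 sampling_rate = trace$sampling_rate,
                 source_id = trace$channel_id, params = params),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs + residual (%s, source %s)\n",
              ncol(x$imfs), x$params$method, x$source_id))
  if (ncol(x$imfs) > 0)
    cat("  mean inst. freq (Hz):",
        paste(sprintf("%.2f", x$mean_inst_freq), collapse = ", "), "\n")
  invisible(x)
}

#' Complete ensemble EMD with adaptive noise (CEEMDAN)
#'
#' Noise-assisted variant of \code{\link{sift_emd}} that extracts each mode
#' as the ensemble mean of first IMFs over noise-perturbed copies of the
#' current residual, which suppresses mode mixing on real signals.  At stage
#' k the k-th EMD mode of each stored noise realization is added with
#' amplitude \code{noise_sd * sd(input)} scaled by the current residual's
#' relative amplitude.  Because each extracted mode is subtracted from the
#' running residual, the IMFs and final residual sum back to the input to
#' machine precision, as for plain EMD.
#'
#' The decomposition is deterministic given \code{seed}: all noise
#' realizations are drawn up front from R's RNG.
#'
#' @inheritParams sift_emd
#' @param n_realizations ensemble size (>= 2; default 100).
#' @param noise_sd noise amplitude as a fraction of the input's standard
#'   deviation (> 0; default 0.2).
#' @param seed integer seed for the noise ensemble.
#' @return An \code{imf_set}; see \code{\link{sift_emd}}.
#' @export
ceemdan <- function(trace, n_realizations = 100L, noise_sd = 0.2, seed = 1L,
                    max_imfs = NULL, sd_thresh = 0.2, max_sift = 50L) {
  stopifnot(inherits(trace, "time_series"))
  if (n_realizations < 2L) stop("n_realizations must be >= 2")
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("noise_sd must be > 0")
  x <- trace$samples
  n <- length(x)
  if (n < 16L) stop("trace too short to decompose (need >= 16 samples)")
  sdx <- stats::sd(x)
  if (sdx == 0) {   # degenerate: constant input, residual only
    return(new_imf_set(matrix(numeric(0), n, 0), x, trace,
                       params = list(method = "ceemdan", seed = seed,
                                     n_realizations = n_realizations,
                                     noise_sd = noise_sd)))
  }
  if (is.null(max_imfs)) max_imfs <- max(1L, floor(log2(n)) - 1L)

  rng <- local({ set.seed(as.integer(seed)); function(k) stats::rnorm(k) })
  W <- matrix(rng(n * n_realizations), n, n_realizations)
  # pre-decompose every noise realization once; its modes seed later stages
  noise_modes <- lapply(seq_len(n_realizations), function(i)
    .emd_c(W[, i], as.integer(max_imfs), sd_thresh, as.integer(max_sift))$imfs)

  imfs <- matrix(0, n, 0)
  resid <- x
  for (k in seq_len(max_imfs)) {
    if (.n_extrema_c(resid) < 4L) break
    beta <- noise_sd * stats::sd(resid)   # stage noise tracks the residual scale
    acc <- numeric(n)
    for (i in seq_len(n_realizations)) {
      nm <- noise_modes[[i]]
      pert <- if (ncol(nm) >= k) resid + beta * nm[, k] else resid
      acc <- acc + .first_imf_c(pert, sd_thresh, as.integer(max_sift))
    }
    mode_k <- acc / n_realizations
    if (stats::sd(mode_k) < 1e-12 * sdx) break
    imfs <- cbind(imfs, mode_k)
    resid <- resid - mode_k
  }
  colnames(imfs) <- NULL
  new_imf_set(imfs, resid, trace,
              params = list(method = "ceemdan", seed = seed,
                            n_realizations = n_realizations,
                            noise_sd = noise_sd, sd_thresh = sd_thresh,
                            max_sift = max_sift, max_imfs = max_imfs))
}

#' Amplitude-weighted mean instantaneous frequency
#'
#' Instantaneous frequency is the derivative of the unwrapped phase of the
#' analytic signal (Hilbert transform via FFT); the returned mean is weighted
#' by the analytic envelope so that low-amplitude phase noise does not
#' dominate.
#'
#' @param imf numeric vector (one IMF) or \code{time_series}.
#' @param rate sampling rate in Hz (ignored when \code{imf} is a
#'   \code{time_series}).
#' @return mean instantaneous frequency in Hz.
#' @export
mean_instantaneous_frequency <- function(imf, rate) {
  if (inherits(imf, "time_series")) { rate <- imf$sampling_rate; imf <- imf$samples }
  x <- as.numeric(imf)
  zc <- sum(diff(sign(x - mean(x))) != 0)
  if (zc < 2 || stats::sd(x) < .Machine$double.eps * max(1, abs(mean(x))))
    stop("instantaneous frequency undefined for a (near-)constant input")
  z <- analytic_signal(x)
  ph <- unwrap_phase(Arg(z))
  instf <- diff(ph) * rate / (2 * pi)
  amp <- Mod(z)
  w <- (amp[-1] + amp[-length(amp)]) / 2
  f <- sum(instf * w) / sum(w)
  if (!is.finite(f) || f <= 0)
    stop("instantaneous frequency undefined (non-positive estimate)")
  f
}

# analytic signal via FFT: zero out negative frequencies, double positives
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  cumsum(c(p[1], dp))
}

#' Assemble a frequency-band signal from IMFs
#'
#' Sums the IMFs whose mean instantaneous frequency falls inside the band's
#' edges.  IMFs falling in the gaps between the canonical bands (14--25 Hz,
#' above 120 Hz) stay unassigned rather than being forced into a band.  An
#' empty membership yields an all-zero band signal flagged \code{empty}.
#'
#' @param imfset an \code{imf_set} derived from \code{source}.
#' @param band a \code{\link{band_definition}}.
#' @param source the raw \code{time_series} the decomposition came from; its
#'   standard deviation is stored for relative-power normalization.
#' @return An object of class \code{band_signal}: \code{band}, \code{samples},
#'   \code{source_sd}, \code{member_imfs}, \code{sampling_rate}, \code{empty}.
#' @export
assemble_band <- function(imfset, band, source) {
  stopifnot(inherits(imfset, "imf_set"), inherits(band, "band_definition"),
            inherits(source, "time_series"))
  if (band$f_high >= source$sampling_rate / 2)
    stop("band extends beyond the Nyquist frequency")
  if (length(imfset$residual) != length(source$samples))
    stop("imf_set and source trace have different lengths")
  members <- which(!is.na(imfset$mean_inst_freq) &
                   imfset$mean_inst_freq >= band$f_low &
                   imfset$mean_inst_freq <= band$f_high)
  samples <- if (length(members) > 0)
    rowSums(imfset$imfs[, members, drop = FALSE])
  else numeric(length(source$samples))
  structure(list(band = band, samples = samples,
                 source_sd = stats::sd(source$samples),
                 member_imfs = members,
                 sampling_rate = source$sampling_rate,
                 empty = length(members) == 0L),
            class = "band_signal")
}

#' @export
print.band_signal <- function(x, ...) {
  cat(sprintf("<band_signal> %s [%g-%g Hz] from IMFs {%s}%s\n",
              x$band$label, x$band$f_low, x$band$f_high,
              paste(x$member_imfs, collapse = ","),
              if (x$empty) " (empty)" else ""))
  invisible(x)
}
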