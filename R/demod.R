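# Inversion of one pulse train into per-line-scan phase and loss profiles:
# pulse synchronization, band separation, envelope extraction, Hilbert phase,
# unwrapping, background removal, and calibration-free transmittance.

#' Split line scans out of a pulse train
#'
#' Windows the sample stream into one column per pulse. The window length is
#' `round(period * sampling_rate)`; the period is taken from the train's
#' configuration, or estimated from the autocorrelation of the samples when
#' `estimate = TRUE` (or when the train is a bare numeric vector).
#'
#' @param train A `pulse_train`, or a numeric sample vector.
#' @param sampling_rate GS/s; required when `train` is a bare vector.
#' @param estimate Force autocorrelation-based period estimation.
#' @return A numeric matrix, one column per line scan, with attribute
#'   `period_ns`.
#' @export
segment_pulses <- function(train, sampling_rate = NULL, estimate = FALSE) {
  if (inherits(train, "pulse_train")) {
    samples <- train$samples
    fs <- 1 / train$time_step
    period <- if (estimate) estimate_pulse_period(samples, fs)
              else train$pulse_period
  } else {
    samples <- as.numeric(train)
    if (is.null(sampling_rate)) stop("sampling_rate required", call. = FALSE)
    fs <- sampling_rate
    period <- estimate_pulse_period(samples, fs)
  }
  w <- round(period * fs)
  n_win <- length(samples) %/% w
  if (n_win < 1) stop("sample stream shorter than one period", call. = FALSE)
  m <- matrix(samples[seq_len(n_win * w)], nrow = w)
  attr(m, "period_ns") <- period
  m
}

#' Estimate the pulse repetition period by autocorrelation
#'
#' FFT-based circular autocorrelation of the (mean-removed) samples; the
#' period is the lag of the strongest peak within `lag_range`.
#'
#' @param samples Numeric vector.
#' @param sampling_rate GS/s.
#' @param lag_range Plausible period range in ns.
#' @return Period in ns.
#' @export
estimate_pulse_period <- function(samples, sampling_rate,
                                  lag_range = c(5, 200)) {
  x <- samples - mean(samples)
  n <- length(x)
  ac <- Re(stats::fft(Mod(stats::fft(x))^2, inverse = TRUE)) / n
  lags <- round(lag_range * sampling_rate)
  lags[2] <- min(lags[2], n %/% 2)
  if (lags[1] >= lags[2]) stop("stream too short to estimate period",
                               call. = FALSE)
  win <- ac[(lags[1] + 1):(lags[2] + 1)]
  if (max(win) <= 0) stop("no periodicity detected", call. = FALSE)
  (lags[1] + which.max(win) - 1) / sampling_rate
}

#' Separate baseband and carrier bands of a line scan
#'
#' Zero-phase FFT filter: the baseband response is 1 below
#' `cutoff - transition/2`, 0 above `cutoff + transition/2`, with a raised
#' cosine in between; the carrier band is the complement, so the two outputs
#' sum exactly to the input.
#'
#' @param scan Numeric samples of one line scan.
#' @param sampling_rate GS/s.
#' @param cutoff Band split frequency, GHz; must sit strictly between the
#'   baseband content and the fringe carrier, and below Nyquist.
#' @param transition Raised-cosine transition width, GHz.
#' @return List with `baseband` and `carrier` numeric vectors.
#' @export
split_bands <- function(scan, sampling_rate, cutoff = 3, transition = 0.2) {
  if (cutoff >= sampling_rate / 2)
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  n <- length(scan)
  fr <- (seq_len(n) - 1) / n * sampling_rate
  fr <- pmin(fr, sampling_rate - fr)    # two-sided spectrum
  lo <- cutoff - transition / 2
  w <- ifelse(fr < lo, 1,
              ifelse(fr > cutoff + transition / 2, 0,
                     0.5 * (1 + cos(pi * (fr - lo) / transition))))
  base <- Re(stats::fft(stats::fft(scan) * w, inverse = TRUE)) / n
  list(baseband = base, carrier = scan - base)
}

#' Envelope of a carrier-band signal by moving minimum/maximum
#'
#' Envelope estimate `(moving max - moving min) / 2` over a window of at
#' least one carrier period, followed by a moving-average smooth of the same
#' window. Nonnegative by construction.
#'
#' @param signal Carrier-band samples.
#' @param window Window length in samples (default: one carrier period plus
#'   one when a config is supplied to [demodulate()]; here mandatory).
#' @return Envelope samples, same length as `signal`.
#' @export
envelope_minmax <- function(signal, window) {
  if (window < 2) stop("window must be at least 2 samples", call. = FALSE)
  n <- length(signal)
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window - 1L - half_lo
  shift <- function(v, k) {
    if (k > 0) c(v[(k + 1):n], rep(v[n], k))
    else if (k < 0) c(rep(v[1], -k), v[1:(n + k)])
    else v
  }
  mx <- signal; mn <- signal
  for (k in seq(-half_lo, half_hi)) {
    if (k == 0) next
    s <- shift(signal, k)
    mx <- pmax(mx, s); mn <- pmin(mn, s)
  }
  env <- (mx - mn) / 2
  k <- rep(1 / window, window)
  sm <- stats::filter(c(rep(env[1], window), env, rep(env[n], window)),
                      k, sides = 2)
  pmax(0, as.numeric(sm)[(window + 1):(window + n)])
}

#' Instantaneous phase from the analytic signal
#'
#' Hilbert-transform demodulation: the analytic signal is formed in the
#' frequency domain (positive frequencies doubled, negative zeroed) and its
#' argument returned as the wrapped instantaneous phase. For a pure tone the
#' phase slope over time equals the carrier frequency.
#'
#' @param carrier_band Band-limited samples around the carrier.
#' @return Wrapped phase in radians, same length as the input.
#' @export
analytic_phase <- function(carrier_band) {
  if (all(carrier_band == 0))
    stop("phase of an all-zero signal is undefined", call. = FALSE)
  Arg(analytic_signal(carrier_band))
}

#' @rdname analytic_phase
#' @export
analytic_signal <- function(carrier_band) {
  n <- length(carrier_band)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else h[2:((n + 1) / 2)] <- 2
  stats::fft(stats::fft(carrier_band) * h, inverse = TRUE) / n
}

#' Unwrap a phase sequence
#'
#' Adds integer multiples of 2pi to successive samples so that consecutive
#' differences fall within (-pi, pi]. Output minus input is everywhere an
#' integer multiple of 2pi.
#'
#' @param wrapped Phase samples in radians.
#' @return Continuous phase, same length.
#' @export
unwrap_phase <- function(wrapped) {
  as.numeric(signal::unwrap(wrapped))
}

#' Remove the background fringe phase
#'
#' Subtracts the unwrapped phase of an empty reference pulse (the linear
#' fringe ramp plus the initial phase constant) from an unwrapped cell-pulse
#' phase, then removes the per-scan residual offset (including any 2pi branch
#' difference) by subtracting the median over `interior` samples, which are
#' overwhelmingly off-cell.
#'
#' @param unwrapped Unwrapped phase of the cell pulse, rad.
#' @param empty_reference Unwrapped phase of an empty pulse from the same
#'   configuration and stream, rad; same length.
#' @param interior Optional index vector over which the median offset is
#'   computed (default: all samples).
#' @return Cell-induced phase, rad; approximately 0 off-cell.
#' @export
remove_background <- function(unwrapped, empty_reference, interior = NULL) {
  if (length(unwrapped) != length(empty_reference))
    stop("phase vectors must have equal length", call. = FALSE)
  phi <- unwrapped - empty_reference
  if (is.null(interior)) interior <- seq_along(phi)
  phi - stats::median(phi[interior])
}

#' Calibration-free cell transmittance
#'
#' Recovers the cell-attributable round-trip power factor from three measured
#' baseband envelopes:
#' \deqn{T_c = \frac{I_{cell} - I_{ref}}{I_{empty} - I_{ref}},}
#' where `ref_env` is the reference-arm-only recording (sample arm blocked).
#' All common factors -- beam-splitter ratio, substrate reflectance, buffer
#' transmittance, input envelope -- cancel, so no prior knowledge of them is
#' needed. Samples where the denominator falls below `floor_frac` of its
#' maximum are returned as `NA` (flagged as masked).
#'
#' @param total_env Baseband envelope of the cell pulse.
#' @param empty_env Baseband envelope of an empty pulse.
#' @param ref_env Reference-arm-only intensity envelope.
#' @param floor_frac Denominator floor as a fraction of its maximum.
#' @return Per-sample transmittance; `NA` where masked.
#' @export
extract_transmittance <- function(total_env, empty_env, ref_env,
                                  floor_frac = 0.05) {
  stopifnot(length(total_env) == length(empty_env),
            length(empty_env) == length(ref_env))
  den <- empty_env - ref_env
  ok <- den > floor_frac * max(den)
  tc <- rep(NA_real_, length(den))
  tc[ok] <- (total_env[ok] - ref_env[ok]) / den[ok]
  tc
}

# ---- one-scan and stream demodulation ---------------------------------------

#' Demodulate a single line scan
#'
#' Full inversion of one pulse window: band separation, Hilbert phase of the
#' carrier band, unwrapping, background-phase removal against the empty
#' reference, interference-envelope extraction, and calibration-free
#' transmittance from the baseband envelopes. Results are restricted to the
#' stretched band; `interior` marks the samples (5% band edges trimmed) on
#' which phase statistics are reliable, Hilbert edge artifacts excluded.
#'
#' @param scan Full-window samples of one pulse.
#' @param cfg The [optical_config()].
#' @param empty_scan Full-window samples of an empty pulse of the same
#'   stream (same `phi0`).
#' @param ref_scan Full-window reference-arm-only samples.
#' @param cutoff Band split frequency, GHz.
#' @param edge_frac Fraction of the band excluded at each edge.
#' @return A `linescan_decomp`: list with band-length vectors `phase`
#'   (cell phase, rad), `tc`, `baseband`, `interference_env`, `carrier_phase`
#'   (unwrapped), scalar `energy` (baseband energy of the scan), and index
#'   vector `interior` (relative to the band).
#' @export
demodulate_scan <- function(scan, cfg, empty_scan, ref_scan, cutoff = 3,
                            edge_frac = 0.05) {
  nb <- band_samples(cfg)
  off <- band_offset(cfg)
  idx <- (off + 1):(off + nb)
  fs <- cfg$sampling_rate
  sc <- split_bands(scan, fs, cutoff)
  se <- split_bands(empty_scan, fs, cutoff)
  u_cell <- unwrap_phase(analytic_phase(sc$carrier))
  u_empty <- unwrap_phase(analytic_phase(se$carrier))
  interior <- (round(edge_frac * nb) + 1):(nb - round(edge_frac * nb))
  phi <- remove_background(u_cell[idx], u_empty[idx], interior)
  win <- ceiling(fs / fringe_frequency(cfg)) + 1
  ii <- envelope_minmax(sc$carrier, win)[idx]
  tc <- extract_transmittance(sc$baseband[idx], se$baseband[idx],
                              ref_scan[idx])
  structure(list(phase = phi, tc = tc, baseband = sc$baseband[idx],
                 interference_env = ii, carrier_phase = u_cell[idx],
                 energy = sum(sc$baseband[idx]), interior = interior),
            class = "linescan_decomp")
}

#' Demodulate every pulse of a train
#'
#' Applies [demodulate_scan()] to each line scan, generating the calibration
#' pulses from the train's configuration and initial fringe phase (physically
#' equivalent to using recorded empty frames of the same stream).
#'
#' @param train A `pulse_train`.
#' @param cutoff Band split frequency, GHz.
#' @return List of `linescan_decomp`, one per pulse.
#' @export
demodulate <- function(train, cutoff = 3) {
  cfg <- train$cfg
  cal <- reference_and_empty_pulses(cfg, phi0 = train$phi0)
  scans <- segment_pulses(train)
  lapply(seq_len(ncol(scans)), function(p)
    demodulate_scan(scans[, p], cfg, cal$empty$samples,
                    cal$reference$samples, cutoff))
}
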