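#' Short-time power spectrogram
#'
#' Hann-windowed short-time spectral estimate of one channel, scaled as
#' one-sided power spectral density so that the summed power of a frame
#' (times the frequency-bin width) recovers the variance of the windowed
#' frame up to the standard window correction.
#'
#' @param ts a `meso_ts` time series.
#' @param channel channel name (default `"h_e"`).
#' @param window analysis window length, ms.
#' @param overlap fractional overlap of consecutive windows in `[0, 1)`.
#' @param nfft FFT length (zero-padded when longer than the window);
#'   default the next power of two at least 4x the window length, giving
#'   interpolated frequency resolution for ridge extraction.
#' @param demean subtract each segment's mean before windowing (constant
#'   detrend per frame, default TRUE); without it, baseline offsets leak
#'   into the lowest frequency bins.
#' @return An object of class `meso_specgram`: list with `t` (frame
#'   centers, ms), `frequency` (Hz), `power` (frequency x time matrix,
#'   mV^2/Hz), `window`, `overlap`.
#' @export
power_spectrogram <- function(ts, channel = "h_e", window = 500,
                              overlap = 0.75, nfft = NULL, demean = TRUE) {
  x <- channel_vector(ts, channel)
  dt <- attr(ts, "record_dt")
  fs <- 1000 / dt  # Hz
  nwin <- round(window / dt)
  if (nwin > length(x)) stop("window longer than the record")
  if (nwin < 8) stop("window too short")
  if (is.null(nfft)) nfft <- 2^ceiling(log2(4 * nwin))
  hop <- max(1, round(nwin * (1 - overlap)))
  starts <- seq(1, length(x) - nwin + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1))  # Hann
  u <- sum(w^2)
  nf <- nfft %/% 2 + 1
  pow <- matrix(0, nf, length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j] + seq_len(nwin) - 1]
    if (demean) seg <- seg - mean(seg)  # constant detrend per segment
    seg <- seg * w
    X <- stats::fft(c(seg, numeric(nfft - nwin)))[seq_len(nf)]
    p <- Mod(X)^2 / (fs * u)
    p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]  # one-sided
    pow[, j] <- p
  }
  freq <- (seq_len(nf) - 1) * fs / nfft
  tc <- ts$t[starts] + (nwin - 1) * dt / 2
  structure(list(t = tc, frequency = freq, power = pow,
                 window = window, overlap = overlap, nfft = nfft,
                 fs = fs, nwin = nwin),
            class = "meso_specgram")
}

odd_count <- function(n) { n <- round(n); if (n %% 2 == 0) n + 1L else as.integer(n) }

# centered moving average with edge values extended
moving_average <- function(x, n) {
  if (n <= 1) return(x)
  m <- as.numeric(stats::filter(x, rep(1 / n, n), sides = 2))
  ok <- which(!is.na(m))
  m[seq_len(ok[1] - 1)] <- m[ok[1]]
  last <- ok[length(ok)]
  if (last < length(m)) m[(last + 1):length(m)] <- m[last]
  m
}

channel_vector <- function(ts, channel) {
  stopifnot(inherits(ts, "meso_ts"))
  if (!channel %in% names(ts)) stop("no channel named '", channel, "'")
  as.numeric(ts[[channel]])
}

# dominant (ridge) frequency per spectrogram frame, restricted to a band
ridge_frequency <- function(sg, band = c(1, 40)) {
  sel <- sg$frequency >= band[1] & sg$frequency <= band[2]
  f <- sg$frequency[sel]
  apply(sg$power[sel, , drop = FALSE], 2, function(p) f[which.max(p)])
}

#' Segment a trace into bursts and suppression
#'
#' Envelope-threshold segmentation: a slowly varying local baseline (moving
#' average over `baseline` ms) is removed from the channel, the moving-RMS
#' envelope of the residual is computed over a smoothing window, and spans
#' where the envelope exceeds an amplitude threshold are taken as bursts
#' after closing sub-threshold gaps shorter than `min_gap` and discarding
#' bursts shorter than `min_burst`.  The baseline removal makes the
#' segmentation sensitive to oscillatory amplitude only: the tonic
#' depolarization shift between burst and suppression states does not
#' register as envelope.  Deterministic; invariant to constant offsets of
#' the channel.
#'
#' @param ts a `meso_ts` time series.
#' @param channel channel name.
#' @param smooth RMS smoothing window, ms.
#' @param baseline local-baseline (moving-average) window, ms; long relative
#'   to the oscillation period so the oscillation itself is preserved.
#' @param threshold envelope threshold, mV; `NULL` (default) uses 10% of the
#'   95th percentile of the absolute baseline-removed signal, but never less
#'   than `threshold_floor`.
#' @param threshold_floor absolute lower bound of the automatic threshold,
#'   mV; keeps numerically flat (isoelectric) records from being segmented
#'   on rounding-level ripple.
#' @param min_burst minimum burst duration, ms.
#' @param min_gap sub-threshold gaps shorter than this are absorbed into the
#'   surrounding burst, ms.
#' @return An object of class `meso_segments`: list with data frames
#'   `bursts` and `suppression` (columns `start`, `end`, ms; jointly
#'   covering the analyzed span), `threshold`, `smooth`, `span`.
#' @export
segment_bursts <- function(ts, channel = "h_e", smooth = 50, baseline = 100,
                           threshold = NULL, min_burst = 200, min_gap = 200,
                           threshold_floor = 0.1) {
  x <- channel_vector(ts, channel)
  dt <- attr(ts, "record_dt")
  x <- x - mean(x)
  xc <- x - moving_average(x, max(1L, odd_count(baseline / dt)))
  env <- sqrt(moving_average(xc^2, max(1L, odd_count(smooth / dt))))
  if (is.null(threshold))
    threshold <- max(0.1 * stats::quantile(abs(xc), 0.95, names = FALSE),
                     threshold_floor)
  on <- env > threshold

  # close short gaps
  r <- rle(on)
  if (length(r$lengths) > 1) {
    interior <- seq_along(r$values)
    gap_ok <- !r$values & (r$lengths * dt) < min_gap &
      interior > 1 & interior < length(r$values)
    r$values[gap_ok] <- TRUE
    on <- inverse.rle(r)
    r <- rle(on)
  }
  # drop short bursts
  short <- r$values & (r$lengths * dt) < min_burst
  r$values[short] <- FALSE
  on <- inverse.rle(r)
  r <- rle(on)

  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  t0 <- ts$t[1]; t1 <- ts$t[length(ts$t)]
  iv <- data.frame(start = ts$t[starts], end = ts$t[ends])
  bursts <- iv[r$values, , drop = FALSE]
  supp <- iv[!r$values, , drop = FALSE]
  rownames(bursts) <- rownames(supp) <- NULL
  structure(list(bursts = bursts, suppression = supp,
                 threshold = threshold, smooth = smooth,
                 span = c(t0, t1), channel = channel),
            class = "meso_segments")
}

#' @export
print.meso_segments <- function(x, ...) {
  cat(sprintf(paste0("<meso_segments> %d bursts over [%g, %g] ms ",
                     "(threshold %.4g mV, smoothing %g ms)\n"),
              nrow(x$bursts), x$span[1], x$span[2], x$threshold, x$smooth))
  invisible(x)
}

#' Burst statistics
#'
#' Durations, suppression ratio and per-burst dominant frequencies for a
#' segmentation.  The suppression ratio is the fraction of the analyzed
#' span classified as suppression (so suppression ratio plus burst-time
#' fraction is exactly 1).  Duration means and medians exclude intervals
#' truncated by the record boundaries (their true length is unknown and
#' including them biases the statistics); the suppression ratio always
#' covers the whole span.  Onset and offset dominant frequencies are the
#' spectrogram ridge (argmax within `band`) averaged over frames whose
#' centers fall in the first and last quarter of each burst; bursts too
#' short to contain a frame center fall back to the periodogram peak of the
#' quarter itself.
#'
#' @param seg a [segment_bursts()] result.
#' @param ts the time series the segmentation came from.
#' @param window,overlap spectrogram parameters (see [power_spectrogram()]).
#' @param band frequency band for the dominant-frequency search, Hz;
#'   restricted below the harmonics of the intra-burst oscillation.
#' @return An object of class `meso_burststats`: list with `n_bursts`,
#'   `mean_burst_ms`, `median_burst_ms`, `mean_suppression_ms`,
#'   `median_suppression_ms`, `suppression_ratio`, `onset_freq_hz`,
#'   `offset_freq_hz` (means across bursts; `NA` when there are no bursts)
#'   and the per-burst table `bursts`.
#' @export
burst_statistics <- function(seg, ts, window = 500, overlap = 0.75,
                             band = c(1, 40)) {
  stopifnot(inherits(seg, "meso_segments"))
  span <- diff(seg$span)
  if (span <= 0) stop("empty analyzed span")
  supp_t <- sum(seg$suppression$end - seg$suppression$start)
  burst_t <- sum(seg$bursts$end - seg$bursts$start)
  interior <- function(iv) iv[iv$start > seg$span[1] & iv$end < seg$span[2], ,
                              drop = FALSE]
  supp_dur <- with(interior(seg$suppression), end - start)
  n <- nrow(seg$bursts)
  if (n == 0) {
    return(structure(list(
      n_bursts = 0L, mean_burst_ms = NA_real_, median_burst_ms = NA_real_,
      mean_suppression_ms = mean_or_na(supp_dur),
      median_suppression_ms = median_or_na(supp_dur),
      suppression_ratio = supp_t / (supp_t + burst_t),
      onset_freq_hz = NA_real_, offset_freq_hz = NA_real_,
      bursts = data.frame()), class = "meso_burststats"))
  }
  sg <- power_spectrogram(ts, seg$channel, window = window, overlap = overlap)
  ridge <- ridge_frequency(sg, band)
  qfreq <- function(lo, hi) {
    # only frames whose whole window lies inside the quarter: frames that
    # straddle a burst edge see the burst/suppression baseline step as
    # spurious low-frequency power
    inq <- (sg$t - window / 2) >= lo & (sg$t + window / 2) <= hi
    if (any(inq)) return(mean(ridge[inq]))
    # burst quarter shorter than the frame spacing: periodogram fallback
    dt <- attr(ts, "record_dt")
    sel <- ts$t >= lo & ts$t <= hi
    x <- channel_vector(ts, seg$channel)[sel]
    if (length(x) < 8) return(NA_real_)
    x <- x - mean(x)
    nfft <- 2^ceiling(log2(max(4 * length(x), 64)))
    X <- Mod(stats::fft(c(x, numeric(nfft - length(x)))))^2
    f <- (seq_len(nfft %/% 2 + 1) - 1) * (1000 / dt) / nfft
    inb <- f >= band[1] & f <= band[2]
    f[inb][which.max(X[seq_along(f)][inb])]
  }
  dur <- seg$bursts$end - seg$bursts$start
  whole <- seg$bursts$start > seg$span[1] & seg$bursts$end < seg$span[2]
  if (!any(whole)) whole <- rep(TRUE, n)  # keep statistics defined
  onset <- offset <- numeric(n)
  for (b in seq_len(n)) {
    q <- dur[b] / 4
    onset[b] <- qfreq(seg$bursts$start[b], seg$bursts$start[b] + q)
    offset[b] <- qfreq(seg$bursts$end[b] - q, seg$bursts$end[b])
  }
  per <- cbind(seg$bursts, duration = dur, onset_freq_hz = onset,
               offset_freq_hz = offset)
  structure(list(
    n_bursts = n,
    mean_burst_ms = mean(dur[whole]),
    median_burst_ms = stats::median(dur[whole]),
    mean_suppression_ms = mean_or_na(supp_dur),
    median_suppression_ms = median_or_na(supp_dur),
    suppression_ratio = supp_t / (supp_t + burst_t),
    onset_freq_hz = mean(onset[whole], na.rm = TRUE),
    offset_freq_hz = mean(offset[whole], na.rm = TRUE),
    bursts = per), class = "meso_burststats")
}

mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
median_or_na <- function(x) if (length(x)) stats::median(x) else NA_real_

#' @export
print.meso_burststats <- function(x, ...) {
  cat(sprintf(paste0("<meso_burststats> %d bursts, mean duration %.0f ms, ",
                     "mean suppression %.0f ms, suppression ratio %.3f\n"),
              x$n_bursts, x$mean_burst_ms, x$mean_suppression_ms,
              x$suppression_ratio))
  if (x$n_bursts > 0)
    cat(sprintf("  dominant frequency: onset %.2f Hz -> offset %.2f Hz\n",
                x$onset_freq_hz, x$offset_freq_hz))
  invisible(x)
}

#' Parameter sweep of bursting statistics
#'
#' Runs one simulation per parameter combination and tabulates the burst
#' statistics.  Symbols are resolved first against the model parameters
#' (e.g. `"p_ee"`, `"eps_ii"`, `"Gamma_ii"`) and then against the slow
#' configuration (`"theta_e"`, `"theta_i"`, `"k_e"`, `"k_i"`, `"kappa_e"`,
#' `"kappa_i"`, `"mu_e"`, `"mu_i"`, `"xi_e"`, `"xi_i"`).  Each run starts
#' from the preset initial conditions (the fixed point of that combination's
#' fast system, with slow amplitudes at their resting values); rows where a
#' simulation fails carry `NA` statistics and the error message.
#'
#' @param P base [model_parameters()].
#' @param slow base [slow_config()] (may be `NULL`).
#' @param sweep named list of value vectors, crossed into a grid; or a data
#'   frame of explicit combinations.
#' @param settings [sim_settings()] used for every run.
#' @param segment_args list of overrides passed to [segment_bursts()].
#' @param channel analyzed channel.
#' @return A data frame: one row per combination with the swept symbols,
#'   `n_bursts`, `mean_burst_ms`, `mean_suppression_ms`,
#'   `suppression_ratio`, `onset_freq_hz`, `offset_freq_hz`, `isoelectric`
#'   (no bursts), and `error` (`NA` on success).
#' @export
sweep_bursting <- function(P, slow, sweep, settings,
                           segment_args = list(), channel = "h_e") {
  grid <- if (is.data.frame(sweep)) sweep else expand.grid(sweep,
                                                           KEEP.OUT.ATTRS = FALSE)
  slow_syms <- c("mu_e", "mu_i", "theta_e", "theta_i", "k_e", "k_i",
                 "kappa_e", "kappa_i", "xi_e", "xi_i")
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    Pi <- P; si <- slow
    for (sym in names(grid)) {
      val <- grid[i, sym]
      if (is_model_symbol(sym)) {
        Pi <- set_param_value(Pi, sym, val)
      } else if (sym %in% slow_syms) {
        if (is.null(si)) stop("symbol ", sym, " requires a slow configuration")
        fl <- sub("_(e|i)$", "", sym)
        lb <- sub("^.*_", "", sym)
        si[[fl]][lb] <- as.numeric(val)
      } else stop("symbol ", sym, " not resolvable in model or slow config")
    }
    row <- as.list(grid[i, , drop = FALSE])
    stats <- tryCatch({
      ts <- simulate_model(Pi, si, settings)
      seg <- do.call(segment_bursts,
                     c(list(ts = ts, channel = channel), segment_args))
      bs <- burst_statistics(seg, ts)
      list(n_bursts = bs$n_bursts, mean_burst_ms = bs$mean_burst_ms,
           mean_suppression_ms = bs$mean_suppression_ms,
           suppression_ratio = bs$suppression_ratio,
           onset_freq_hz = bs$onset_freq_hz,
           offset_freq_hz = bs$offset_freq_hz,
           isoelectric = bs$n_bursts == 0, error = NA_character_)
    }, error = function(e) {
      list(n_bursts = NA_integer_, mean_burst_ms = NA_real_,
           mean_suppression_ms = NA_real_, suppression_ratio = NA_real_,
           onset_freq_hz = NA_real_, offset_freq_hz = NA_real_,
           isoelectric = NA, error = conditionMessage(e))
    })
    out[[i]] <- c(row, stats)
  }
  do.call(rbind, lapply(out, function(r) as.data.frame(r,
                                                       stringsAsFactors = FALSE)))
}

is_model_symbol <- function(sym) {
  !inherits(tryCatch(split_symbol(sym), error = function(e) e), "error")
}

#' Welch power spectral density
#'
#' Average of the short-time spectra of [power_spectrogram()] across frames:
#' the standard segment-averaged one-sided PSD estimate.
#'
#' @inheritParams power_spectrogram
#' @return Data frame with columns `frequency` (Hz) and `power` (mV^2/Hz).
#' @export
welch_psd <- function(ts, channel = "h_e", window = 2000, overlap = 0.5,
                      nfft = NULL) {
  sg <- power_spectrogram(ts, channel, window = window, overlap = overlap,
                          nfft = nfft)
  data.frame(frequency = sg$frequency, power = rowMeans(sg$power))
}
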