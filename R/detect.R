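#' Detect pen clicks in an audio stream
#'
#' Clicks are short impulsive bursts, sparse in time (roughly 10-20 per
#' second during an injection).  Detection is deliberately simple: a moving
#' RMS envelope (window `window` seconds), a threshold of `threshold_sd`
#' noise standard deviations above zero, and a refractory period during
#' which further threshold crossings are ignored.  The noise scale is
#' estimated robustly from the envelope itself (median absolute deviation
#' about the median plus the median), so the sparse clicks do not inflate
#' it.  Each accepted event is reported at its envelope peak.
#'
#' @param audio numeric sample vector (or a list with `samples` and
#'   `sample_rate`, as from [read_wav()]).
#' @param sample_rate sampling rate in Hz (ignored if `audio` carries one).
#' @param threshold_sd detection threshold in noise-SD units (default 6).
#' @param refractory minimum separation between clicks in seconds
#'   (default 0.02).
#' @param window RMS window length in seconds (default 0.001).
#' @param volume_per_click,subject_id,medium passed to [click_train()].
#' @return a [click_train()]; empty (zero clicks) for silent or too-short
#'   audio.
#' @export
detect_clicks <- function(audio, sample_rate = NULL, threshold_sd = 6,
                          refractory = 0.02, window = 0.001,
                          volume_per_click = uL_to_m3(10),
                          subject_id = "unknown",
                          medium = c("air", "tissue")) {
  medium <- match.arg(medium)
  if (is.list(audio)) {
    sample_rate <- audio$sample_rate
    audio <- audio$samples
  }
  if (is.null(sample_rate) || sample_rate <= 0)
    pp_stop("invalid_input", "sample_rate must be positive")
  audio <- as.numeric(audio)
  if (any(!is.finite(audio)))
    pp_stop("invalid_input", "audio contains non-finite samples")

  empty <- click_train(numeric(0), volume_per_click, subject_id, medium)
  w <- max(3L, as.integer(round(sample_rate * window)))
  if (length(audio) < 2L * w) return(empty)

  env <- sqrt(filter(audio^2, rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0
  env <- as.numeric(env)

  noise <- mad(env, constant = 1.4826)
  floor_lvl <- median(env) + threshold_sd * noise
  if (noise == 0) {
    # digitally silent background: any strictly positive envelope is a hit
    floor_lvl <- max(median(env), .Machine$double.eps)
    if (max(env) <= floor_lvl) return(empty)
  }
  above <- env > floor_lvl
  if (!any(above)) return(empty)

  # contiguous supra-threshold runs -> candidate peaks
  edges <- diff(c(FALSE, above, FALSE))
  starts <- which(edges == 1L)
  ends <- which(edges == -1L) - 1L
  peak_idx <- mapply(function(s, e) s - 1L + which.max(env[s:e]), starts, ends)
  peak_t <- (peak_idx - 1) / sample_rate
  peak_a <- env[peak_idx]

  # greedy refractory pass in time order
  keep <- logical(length(peak_t))
  last <- -Inf
  for (i in seq_along(peak_t)) {
    if (peak_t[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- peak_t[i]
    }
  }
  times <- peak_t[keep]
  if (length(times) >= 2 && any(diff(times) <= 0))
    times <- sort(unique(times))
  click_train(times, volume_per_click, subject_id, medium)
}

#' Render a click train as synthetic audio
#'
#' Each click becomes a damped sinusoid burst
#' `exp(-t/tau) * sin(2 pi f t)`; Gaussian background noise is added at the
#' requested signal-to-noise ratio (peak amplitude over noise SD, in dB).
#' This is the acoustic stand-in used to exercise [detect_clicks()]; it
#' makes no attempt at realism beyond being impulsive and sparse.
#'
#' @param train a [click_train()].
#' @param sample_rate Hz (default 16000).
#' @param f_burst burst frequency in Hz (default 3000).
#' @param tau burst decay time in seconds (default 0.002).
#' @param snr_db peak signal-to-noise ratio in dB; `Inf` for noise-free.
#' @param duration total length in seconds (default: last click + 0.2 s).
#' @return list with `samples` and `sample_rate`, as [read_wav()].
#' @export
clicks_to_audio <- function(train, sample_rate = 16000, f_burst = 3000,
                            tau = 0.002, snr_db = Inf, duration = NULL) {
  stopifnot(inherits(train, "click_train"))
  if (is.null(duration))
    duration <- if (length(train$times)) max(train$times) + 0.2 else 0.5
  n <- ceiling(duration * sample_rate)
  x <- numeric(n)
  burst_len <- ceiling(6 * tau * sample_rate)
  tb <- (seq_len(burst_len) - 1) / sample_rate
  burst <- exp(-tb / tau) * sin(2 * pi * f_burst * tb)
  for (tc in train$times) {
    i0 <- floor(tc * sample_rate) + 1L
    idx <- i0:min(n, i0 + burst_len - 1L)
    x[idx] <- x[idx] + burst[seq_along(idx)]
  }
  if (is.finite(snr_db)) {
    noise_sd <- max(abs(burst)) / 10^(snr_db / 20)
    x <- x + rnorm(n, sd = noise_sd)
  }
  peak <- max(abs(x), 1)
  list(samples = x / (1.05 * peak), sample_rate = sample_rate)
}
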