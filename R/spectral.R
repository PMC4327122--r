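## Frequency-domain feature pipeline: FFT magnitude spectrum, primary /
## secondary peak grouping, FIR low-pass filtering with 1-in-5
## downsampling, spectrum enveloping, and magnitude-difference-driven
## selection of the filter parameters (omega_1, delta_omega).

#' One-sided amplitude spectrum
#'
#' FFT magnitude spectrum with amplitude scaling `2|X_k|/N` (DC and, for
#' even `N`, the Nyquist bin unhalved at `|X_k|/N`), so a unit-amplitude
#' sinusoid shows magnitude ~1 at its bin.  Frequency resolution is
#' `rate/N`.  The DC bin is kept in the histogram but excluded from peak
#' searches.
#'
#' @param signal numeric vector, at least 16 samples at a uniform rate.
#' @param rate sample rate in Hz.
#' @return a `spectrum_histogram`: data frame `freq`, `mag` with
#'   attributes `rate` and `n`.
#' @export
spectrum_histogram <- function(signal, rate) {
  n <- length(signal)
  if (n < 16L) stop_contract("spectrum needs at least 16 samples")
  X <- stats::fft(signal)
  half <- floor(n / 2) + 1L
  mag <- Mod(X[seq_len(half)]) / n * 2
  mag[1L] <- Mod(X[1L]) / n
  if (n %% 2L == 0L) mag[half] <- Mod(X[half]) / n
  out <- data.frame(freq = (seq_len(half) - 1L) * rate / n, mag = mag)
  attr(out, "rate") <- rate
  attr(out, "n") <- n
  class(out) <- c("spectrum_histogram", "data.frame")
  out
}

#' Primary and secondary spectral peak groups
#'
#' The primary peak is the global maximum bin (DC excluded).  Local maxima
#' whose magnitude exceeds a quarter of the primary's are secondary peaks;
#' candidate bins adjacent within one frequency-resolution step merge into
#' one group represented by the taller bin.
#'
#' @param spec a `spectrum_histogram`.
#' @return list with `primary` (`freq`, `mag`) and `secondaries` (data
#'   frame of `freq`, `mag`, possibly empty).
#' @export
peak_groups <- function(spec) {
  mag <- spec$mag
  if (all(mag == 0)) stop_contract("all-zero spectrum has no peaks")
  idx <- 2:length(mag)           # exclude DC
  pk <- idx[which.max(mag[idx])]
  thresh <- mag[pk] / 4
  ## local maxima among non-DC bins
  is_max <- vapply(idx, function(i) {
    left <- if (i > 2L) mag[i - 1L] else -Inf
    right <- if (i < length(mag)) mag[i + 1L] else -Inf
    mag[i] > left && mag[i] >= right
  }, logical(1L))
  cand <- idx[is_max & mag[idx] > thresh]
  cand <- setdiff(cand, pk)
  ## merge candidates adjacent within one resolution step (neighbouring
  ## bins), keep the taller representative; also drop bins adjacent to the
  ## primary (same group)
  cand <- cand[abs(cand - pk) > 1L]
  sec <- integer(0)
  while (length(cand)) {
    grp <- cand[c(TRUE, diff(cand) == 1L)]
    run_end <- which(diff(cand) != 1L)[1L]
    grp <- if (is.na(run_end)) cand else cand[seq_len(run_end)]
    sec <- c(sec, grp[which.max(mag[grp])])
    cand <- setdiff(cand, grp)
  }
  list(primary = list(freq = spec$freq[pk], mag = mag[pk]),
       secondaries = data.frame(freq = spec$freq[sec], mag = mag[sec]))
}

#' Filter parameters for the envelope pipeline
#'
#' @param w1 normalized sampling/cutoff parameter, cutoff divided by the
#'   Nyquist frequency, in (0, 1).
#' @param dw increment frequency (Nyquist-normalized grid step), > 0.
#' @param order FIR filter order (default 20).
#' @param factor downsampling factor (default: keep one point in five).
#' @param dE achieved magnitude difference (filled by
#'   [select_filter_params()]).
#' @return a list of class `filter_params`.
#' @export
filter_params <- function(w1 = 0.115, dw = 0.1, order = 20L, factor = 5L,
                          dE = NA_real_) {
  if (w1 <= 0 || w1 >= 1) stop_contract("w1 must lie in (0, 1)")
  if (dw <= 0) stop_contract("dw must be positive")
  if (order < 1L) stop_contract("filter order must be >= 1")
  structure(list(w1 = w1, dw = dw, order = as.integer(order),
                 factor = as.integer(factor), dE = dE),
            class = "filter_params")
}

## Hamming-windowed sinc low-pass taps; unit DC gain, cutoff = w1 * Nyquist.
fir_lowpass <- function(order = 20L, w1 = 0.115) {
  k <- seq(-order / 2, order / 2)
  h <- ifelse(k == 0, w1, sin(pi * w1 * k) / (pi * k))
  h <- h * (0.54 + 0.46 * cos(2 * pi * k / order))  # Hamming
  h / sum(h)
}

#' Low-pass filter and downsample a signal
#'
#' Applies an order-20 (21-tap) windowed-sinc FIR low-pass with cutoff
#' `w1 * Nyquist`, drops the `order/2`-sample transients at both ends of
#' the centred (zero-phase-aligned) output, then keeps every `factor`-th
#' sample starting from the first retained one.  Output length is
#' `length(seq(1, N - order, by = factor))`.
#'
#' @param signal numeric vector longer than `order * factor`.
#' @param params a [filter_params()].
#' @return the filtered, downsampled signal.
#' @export
lowpass_downsample <- function(signal, params = filter_params()) {
  n <- length(signal)
  if (n <= params$order * params$factor)
    stop_contract("signal too short for filter order and factor")
  h <- fir_lowpass(params$order, params$w1)
  y <- stats::filter(signal, h, method = "convolution", sides = 2L)
  y <- as.numeric(y)
  y <- y[!is.na(y)]                       # drop order/2 transients each end
  y[seq(1L, length(y), by = params$factor)]
}

#' Upper envelope of a spectrum
#'
#' Peak bins are detected on the Nyquist-normalized frequency grid anchored
#' at `w1` with step `dw` (the tallest bin within each grid interval), the
#' knots are connected by linear interpolation, and the result is raised to
#' the original magnitude wherever the chain dips below it -- so the
#' envelope dominates the original pointwise and equals it at the retained
#' peaks.
#'
#' @param spec a `spectrum_histogram`.
#' @param w1 grid anchor, normalized to Nyquist.
#' @param dw grid step, normalized to Nyquist; must be at least the
#'   spectrum's frequency resolution.
#' @return a `spectrum_histogram` with enveloped magnitudes.
#' @export
envelope_spectrum <- function(spec, w1 = 0.115, dw = 0.1) {
  rate <- attr(spec, "rate")
  nyq <- rate / 2
  u <- spec$freq / nyq
  res <- (rate / attr(spec, "n")) / nyq
  if (dw < res)
    stop_contract("dw (", dw, ") is below the frequency resolution (",
                  format(res), ")")
  edges <- sort(unique(c(seq(w1, 0, by = -dw), seq(w1, 1 + dw, by = dw))))
  edges <- pmin(pmax(edges, 0), max(u))
  kn_u <- kn_m <- numeric(0)
  for (i in seq_len(length(edges) - 1L)) {
    sel <- which(u >= edges[i] & (u < edges[i + 1L] |
                                    (i == length(edges) - 1L & u <= edges[i + 1L])))
    if (!length(sel)) next
    top <- sel[which.max(spec$mag[sel])]
    kn_u <- c(kn_u, u[top]); kn_m <- c(kn_m, spec$mag[top])
  }
  ## bound interpolation with the end bins
  if (kn_u[1L] > u[1L]) { kn_u <- c(u[1L], kn_u); kn_m <- c(spec$mag[1L], kn_m) }
  nu <- length(u)
  if (kn_u[length(kn_u)] < u[nu]) {
    kn_u <- c(kn_u, u[nu]); kn_m <- c(kn_m, spec$mag[nu])
  }
  env <- stats::approx(kn_u, kn_m, xout = u, ties = "ordered")$y
  out <- spec
  out$mag <- pmax(env, spec$mag)
  out
}

#' Magnitude difference between enveloped and original spectra
#'
#' `dE = sum(f_enveloped^2) - sum(f_original^2)`; nonnegative whenever the
#' envelope dominates pointwise, and 0 when they coincide.
#'
#' @param enveloped,original `spectrum_histogram` objects on the same
#'   frequency grid.
#' @return scalar `dE`.
#' @export
magnitude_difference <- function(enveloped, original) {
  if (nrow(enveloped) != nrow(original) ||
      any(abs(enveloped$freq - original$freq) > 1e-9))
    stop_contract("spectra must share one frequency grid")
  sum(enveloped$mag^2) - sum(original$mag^2)
}

#' Select envelope filter parameters over a spectrum collection
#'
#' For every spectrum and every `(w1, dw)` grid pair the magnitude
#' difference of the enveloped versus original spectrum is computed.  Per
#' spectrum the pair minimizing `dE` is selected; across the collection the
#' modal (most-counts) winning pair is returned, ties broken toward smaller
#' `dw` then smaller `w1`.  The full `dE` table is retained as attribute
#' `table`.
#'
#' @param spectra list of `spectrum_histogram` objects.
#' @param w1_grid,dw_grid candidate parameter grids.
#' @return a [filter_params()] with `dE` set to the winning pair's mean
#'   `dE` over the collection, and attributes `table` (data frame
#'   `spectrum`, `w1`, `dw`, `dE`) and `winners` (per-spectrum argmin
#'   pairs).
#' @export
select_filter_params <- function(spectra, w1_grid, dw_grid) {
  if (!length(spectra) || !length(w1_grid) || !length(dw_grid))
    stop_contract("spectra and parameter grids must be nonempty")
  grid <- expand.grid(w1 = w1_grid, dw = dw_grid)
  tab <- do.call(rbind, lapply(seq_along(spectra), function(s) {
    dE <- vapply(seq_len(nrow(grid)), function(g)
      magnitude_difference(
        envelope_spectrum(spectra[[s]], grid$w1[g], grid$dw[g]),
        spectra[[s]]), numeric(1L))
    data.frame(spectrum = s, w1 = grid$w1, dw = grid$dw, dE = dE)
  }))
  winners <- do.call(rbind, lapply(split(tab, tab$spectrum), function(d) {
    d <- d[order(d$dE, d$dw, d$w1), ]
    d[1L, ]
  }))
  key <- paste(winners$w1, winners$dw)
  counts <- table(key)
  top <- names(counts)[counts == max(counts)]
  ## tie-break toward smaller dw, then smaller w1
  parse2 <- function(k) as.numeric(strsplit(k, " ")[[1L]])
  vals <- t(vapply(top, parse2, numeric(2L)))
  best <- vals[order(vals[, 2L], vals[, 1L]), , drop = FALSE][1L, ]
  sel <- tab$w1 == best[1L] & tab$dw == best[2L]
  out <- filter_params(w1 = best[1L], dw = best[2L],
                       dE = mean(tab$dE[sel]))
  attr(out, "table") <- tab
  attr(out, "winners") <- winners
  out
}

#' Write a spectrum as two-column CSV
#'
#' @param spec a `spectrum_histogram`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  utils::write.csv(data.frame(hz = spec$freq, magnitude = spec$mag), path,
                   row.names = FALSE)
  invisible(path)
}
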