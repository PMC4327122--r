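## Synthetic exercise-signal simulator.
##
## No recording of the original thirteen participants is deposited, so the
## package ships a generator that emulates the documented *signatures* of the
## six rehabilitation exercises: the peak included angle between consecutive
## acceleration vectors (approximately 80, 20, 80, 20, 40 and 160 degrees for
## Ex.1-6), the waveform family of the angle trace (gentle slopes, nodal
## amplitude modulation, impulse spikes), and the spectral peak groups of the
## acceleration components (for the wall-climbing exercise, primaries at
## (0.2, 0.25, 0.25) Hz, secondaries at (0.4, 0.55, 0.55) Hz and a minor
## 0.8 Hz component on a_y).
##
## Construction: the acceleration vector is a slowly tilting unit-gravity
## direction (sinusoids at the template frequencies, which fixes the
## spectrum) plus a sign-alternating dither along a horizontal axis whose
## magnitude is tan(theta/2) of the target included-angle waveform -- the
## angle between consecutive total vectors then traces that waveform.  The
## dither axis has no z component, so the a_z spectrum stays clean.

#' Exercise signal template
#'
#' @param id exercise number 1--6.
#' @param name short label.
#' @param family waveform family of the included-angle trace: `"gentle"`
#'   (smooth rise and fall), `"nodal"` (amplitude-modulated with nodes
#'   between peaks) or `"impulse"` (sparse two-tick spikes).
#' @param peak_angle peak included angle in degrees, in (0, 180].
#' @param base unit gravity direction at rest (3-vector, g).
#' @param freq per-axis fundamental frequencies (Hz), below the 4 Hz
#'   Nyquist limit of the 8 packets/s stream.
#' @param amp per-axis fundamental amplitudes (g).
#' @param sec_freq,sec_ratio per-axis secondary frequencies and their
#'   amplitude ratio relative to the fundamental (> 0.25 registers as a
#'   secondary spectral peak).
#' @param minor optional extra component, `list(axis=, freq=, ratio=)`.
#' @param theta_freq fundamental of the included-angle waveform (Hz).
#' @param noise_sd additive Gaussian noise SD (g).
#' @param duration session length in seconds.
#' @return an object of class `exercise_template`.
#' @export
exercise_template <- function(id, name, family, peak_angle, base, freq, amp,
                              sec_freq, sec_ratio = 0.35, minor = NULL,
                              theta_freq, noise_sd = 0.02, duration = 60) {
  stopifnot(peak_angle > 0, peak_angle <= 180, all(freq < PACKET_RATE / 2),
            all(sec_freq < PACKET_RATE / 2), theta_freq < PACKET_RATE / 2)
  base <- base / sqrt(sum(base^2))
  structure(list(id = as.integer(id), name = name,
                 family = match.arg(family, c("gentle", "nodal", "impulse")),
                 peak_angle = peak_angle, base = base, freq = freq,
                 amp = amp, sec_freq = sec_freq, sec_ratio = sec_ratio,
                 minor = minor, theta_freq = theta_freq,
                 noise_sd = noise_sd, duration = duration),
            class = "exercise_template")
}

#' Default templates for the six rehabilitation exercises
#'
#' Pinned to the documented signatures: Ex.1 scapula (gentle, 80 deg),
#' Ex.2 Codman pendulum (gentle, 20 deg), Ex.3 finger wall-climbing (nodal,
#' 80 deg, fundamentals (0.2, 0.25, 0.25) Hz, secondaries (0.4, 0.55,
#' 0.55) Hz plus a minor 0.8 Hz a_y component), Ex.4 back shoulder circling
#' (impulse, 20 deg), Ex.5 towel (nodal, 40 deg), Ex.6 spiral rotation
#' (impulse, 160 deg).  Frequencies not documented for an exercise are
#' chosen once at plausible repetition rates (0.3--0.75 Hz).
#'
#' @return list of six [exercise_template()] objects.
#' @export
default_templates <- function() {
  list(
    exercise_template(1L, "scapula", "gentle", 80,
                      base = c(0.20, -0.10, -0.97),
                      freq = c(0.5, 0.5, 0.5), amp = c(0.18, 0.22, 0.25),
                      sec_freq = c(1.0, 1.0, 1.0), theta_freq = 0.5),
    exercise_template(2L, "pendulum", "gentle", 20,
                      base = c(0.05, 0.15, -0.99),
                      freq = c(0.70, 0.75, 0.75), amp = c(0.25, 0.20, 0.15),
                      sec_freq = c(1.40, 1.50, 1.50), theta_freq = 0.75),
    exercise_template(3L, "wall_climb", "nodal", 80,
                      base = c(-0.15, 0.20, -0.96),
                      freq = c(0.20, 0.25, 0.25), amp = c(0.22, 0.25, 0.25),
                      sec_freq = c(0.40, 0.55, 0.55),
                      minor = list(axis = "ay", freq = 0.8, ratio = 0.30),
                      theta_freq = 0.25),
    exercise_template(4L, "back_circle", "impulse", 20,
                      base = c(0.30, 0.10, -0.95),
                      freq = c(0.50, 0.55, 0.50), amp = c(0.20, 0.15, 0.22),
                      sec_freq = c(1.00, 1.10, 1.00), theta_freq = 0.5),
    exercise_template(5L, "towel", "nodal", 40,
                      base = c(-0.25, -0.15, -0.95),
                      freq = c(0.30, 0.35, 0.30), amp = c(0.24, 0.18, 0.20),
                      sec_freq = c(0.60, 0.70, 0.60), theta_freq = 0.3),
    exercise_template(6L, "spiral", "impulse", 160,
                      base = c(0.10, -0.25, -0.96),
                      freq = c(0.60, 0.65, 0.60), amp = c(0.15, 0.20, 0.18),
                      sec_freq = c(1.20, 1.30, 1.20), theta_freq = 0.6)
  )
}

## Target included-angle waveform (degrees) at the sample ticks.
theta_waveform <- function(template, t) {
  f0 <- template$theta_freq
  peak <- template$peak_angle
  switch(template$family,
    gentle = peak * 0.5 * (1 - cos(2 * pi * f0 * t)),
    nodal = peak * 0.5 * (1 - cos(2 * pi * f0 * t)) *
      abs(cos(2 * pi * (f0 / 5) * t)),
    impulse = {
      th <- rep(2, length(t))
      period <- round(PACKET_RATE / f0)        # ticks per spike
      tick <- round(t * PACKET_RATE)
      spike <- (tick %% period) %in% c(0L, 1L) # two-tick spikes
      th[spike] <- peak
      th
    })
}

#' Simulate one exercise session
#'
#' Generates a calibrated sample stream at 8 samples/s whose consecutive
#' acceleration vectors trace the template's included-angle waveform and
#' whose per-axis spectra carry the template's frequency groups.  Amplitudes
#' receive a seeded per-session jitter of +/- 10 percent (a crude stand-in
#' for inter-subject variability); Gaussian noise is added to all channels.
#'
#' @param template an [exercise_template()].
#' @param seed integer RNG seed; identical seeds give identical sessions.
#' @param duration session length in seconds (default from template).
#' @return a `calibrated_samples` data frame with attribute `ground_truth`
#'   (ideal per-tick included angle, component frequencies, template, seed).
#' @export
simulate_exercise <- function(template, seed = 1L,
                              duration = template$duration) {
  n <- as.integer(round(duration * PACKET_RATE))
  t <- (seq_len(n) - 1L) / PACKET_RATE
  with_seed(derive_seed(seed, template$id), {
    jit <- 1 + stats::runif(3, -0.1, 0.1)
    phases <- c(0, 2.1, 4.2)
    slow <- matrix(0, n, 3)
    for (j in 1:3) {
      slow[, j] <- template$base[j] +
        jit[j] * template$amp[j] * sin(2 * pi * template$freq[j] * t + phases[j]) +
        jit[j] * template$amp[j] * template$sec_ratio *
          sin(2 * pi * template$sec_freq[j] * t + phases[j] / 2)
    }
    if (!is.null(template$minor)) {
      jx <- match(template$minor$axis, c("ax", "ay", "az"))
      slow[, jx] <- slow[, jx] + jit[jx] * template$amp[jx] *
        template$minor$ratio * sin(2 * pi * template$minor$freq * t + 1.3)
    }
    ## dither along a horizontal axis orthogonal to the rest direction
    e <- c(-template$base[2], template$base[1], 0)
    e <- e / sqrt(sum(e^2))
    theta_ideal <- theta_waveform(template, t)
    bnorm <- sqrt(rowSums(slow^2))
    ## the slow tilt already rotates the vector tick-to-tick; subtract that
    ## rotation from the target so the *total* consecutive angle traces the
    ## waveform instead of overshooting on fast low-angle templates
    dots <- rowSums(slow[-n, , drop = FALSE] * slow[-1L, , drop = FALSE])
    phi <- acos(pmin(pmax(dots / (bnorm[-n] * bnorm[-1L]), -1), 1)) * 180 / pi
    phi_avg <- (c(phi[1L], phi) + c(phi, phi[n - 1L])) / 2
    resid <- pmax(theta_ideal - phi_avg, 0)
    J <- tan(pmin(resid, 179) / 2 * pi / 180) * bnorm *
      (-1)^(seq_len(n) - 1L)
    acc <- slow + outer(J, e) +
      matrix(stats::rnorm(3 * n, 0, template$noise_sd), n, 3)
    ## angular-velocity channels: differentiated tilt plus noise (the
    ## recognition features ignore them; they complete the packet format)
    gyro <- matrix(0, n, 3)
    for (j in 1:3) {
      gyro[, j] <- 60 * jit[j] * template$amp[j] * template$freq[j] *
        cos(2 * pi * template$freq[j] * t + phases[j]) +
        stats::rnorm(n, 0, 25 * template$noise_sd)
    }
    gyro <- pmin(pmax(gyro, -499), 499)
    out <- data.frame(t = t, ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
                      wx = gyro[, 1], wy = gyro[, 2], wz = gyro[, 3],
                      node_id = 2L)
    class(out) <- c("calibrated_samples", "data.frame")
    attr(out, "ground_truth") <- list(
      theta_ideal = theta_ideal, freq = template$freq,
      sec_freq = template$sec_freq, template = template, seed = seed)
    out
  })
}

#' ADC model configuration
#'
#' @param bits ADC bit depth.
#' @param count_sd SD (in counts) of the Gaussian count scatter inside one
#'   128-count block.
#' @return a list.
#' @export
adc_config <- function(bits = 10L, count_sd = 2) {
  list(bits = as.integer(bits), count_sd = count_sd)
}

#' Encode a sample stream as a sensor packet log
#'
#' Inverts the calibration of [packets_to_samples()]: each sample becomes
#' one packet whose six channel blocks hold 128 rounded Gaussian ADC counts
#' centred on the quantized true value.  Optional corruption injects the
#' defects the node filter must catch, with a ground-truth manifest.
#'
#' @param samples a `calibrated_samples` stream.
#' @param adc an [adc_config()].
#' @param calibration channel calibrations (see [default_calibration()]).
#' @param corruption `NULL`, or `list(truncate=, out_of_range=, duplicate=)`
#'   rates in `[0, 1)`; corrupted packet sets are disjoint.
#' @param seed integer RNG seed.
#' @return a `packet_log` with attribute `manifest` (data frame of corrupted
#'   packet index / seq / reason; empty when `corruption` is `NULL`).
#' @export
encode_session <- function(samples, adc = adc_config(),
                           calibration = default_calibration(),
                           corruption = NULL, seed = 1L) {
  n <- nrow(samples)
  maxc <- 2^adc$bits - 1
  with_seed(derive_seed(seed, 7L), {
    counts <- matrix(NA_integer_, n, 6L * BLOCK_LEN)
    for (j in seq_along(CHANNELS)) {
      cal <- calibration[[CHANNELS[j]]]
      centre <- (samples[[CHANNELS[j]]] + cal$baseline) / cal$scale + cal$offset
      blk <- matrix(stats::rnorm(n * BLOCK_LEN, mean = rep(centre, BLOCK_LEN),
                                 sd = adc$count_sd), n, BLOCK_LEN)
      blk <- pmin(pmax(round(blk), 0), maxc)
      counts[, ((j - 1L) * BLOCK_LEN + 1L):(j * BLOCK_LEN)] <- as.integer(blk)
    }
    sq <- seq_len(n) - 1L
    manifest <- data.frame(index = integer(0), seq = integer(0),
                           reason = character(0))
    if (!is.null(corruption)) {
      pool <- sample(2:n)   # packet 1 stays intact (duplicate needs a prior)
      take <- function(rate) {
        k <- min(round(rate * n), length(pool))
        if (k == 0L) return(integer(0))
        out <- pool[seq_len(k)]
        pool <<- pool[-seq_len(k)]
        sort(out)
      }
      tr <- take(corruption$truncate %||% 0)
      oo <- take(corruption$out_of_range %||% 0)
      du <- take(corruption$duplicate %||% 0)
      for (i in tr) {  # drop the tail of one random channel block
        ch <- sample(6L, 1L)
        cut <- sample(BLOCK_LEN - 1L, 1L)
        cols <- ((ch - 1L) * BLOCK_LEN + cut + 1L):(ch * BLOCK_LEN)
        counts[i, cols] <- NA_integer_
      }
      for (i in oo) counts[i, sample(6L * BLOCK_LEN, 1L)] <-
        as.integer(maxc + sample(1:100, 1L))
      for (i in du) sq[i] <- sq[sample(i - 1L, 1L)]
      manifest <- data.frame(
        index = c(tr, oo, du),
        seq = sq[c(tr, oo, du)],
        reason = rep(c("incomplete", "out_of_range", "duplicate_seq"),
                     c(length(tr), length(oo), length(du))))
      manifest <- manifest[order(manifest$index), ]
      rownames(manifest) <- NULL
    }
    log <- packet_log(samples$node_id, sq, samples$t, counts)
    attr(log, "manifest") <- manifest
    log
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
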