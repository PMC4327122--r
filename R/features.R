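## Feature extraction: the included-angle derivative feature and the
## overlapping 25-s window entries that feed the network.
##
## One data entry spans 25 s at 8 samples/s on four features
## (a_x, a_y, a_z, theta), i.e. n = 25 * 8 * (3 + 1) = 800 values.  The
## final quarter of each entry is identical to the first quarter of the
## next, so the stride is 150 ticks.

#' Included angle between two acceleration vectors
#'
#' The derivative tilt feature: the angle between two spatial vectors,
#' obtained through their dot product, in degrees.  The result is clamped
#' into `[0, 180]` against rounding overflow of the arccosine argument.
#'
#' @param a1,a2 numeric 3-vectors; must be nonzero.
#' @return angle in degrees.
#' @export
included_angle <- function(a1, a2) {
  n1 <- sqrt(sum(a1^2)); n2 <- sqrt(sum(a2^2))
  if (n1 == 0 || n2 == 0)
    stop_contract("included_angle is undefined for a zero vector")
  acos(pmin(pmax(sum(a1 * a2) / (n1 * n2), -1), 1)) * 180 / pi
}

#' Included-angle series of a sample stream
#'
#' Computes the included angle between every pair of consecutive
#' acceleration vectors.  The raw series is one shorter than the input; it
#' is padded at the start by repeating the first angle so the four feature
#' streams stay tick-aligned.  A zero acceleration vector yields a 0-degree
#' angle with a warning (rather than aborting bulk processing).
#'
#' @param samples a `calibrated_samples` data frame (columns `ax, ay, az`)
#'   or a numeric matrix with three columns; at least 2 rows.
#' @return numeric vector of angles in degrees, same length as the input.
#' @export
angle_series <- function(samples) {
  a <- if (is.data.frame(samples)) cbind(samples$ax, samples$ay, samples$az)
       else as.matrix(samples)
  n <- nrow(a)
  if (n < 2L) stop_contract("angle_series needs at least 2 samples")
  nrm <- sqrt(rowSums(a^2))
  if (any(nrm == 0)) warning("zero acceleration vector; angle set to 0")
  dots <- rowSums(a[-n, , drop = FALSE] * a[-1L, , drop = FALSE])
  den <- nrm[-n] * nrm[-1L]
  cosv <- ifelse(den == 0, 1, pmin(pmax(dots / ifelse(den == 0, 1, den), -1), 1))
  th <- acos(cosv) * 180 / pi
  c(th[1L], th)
}

#' Assemble overlapping window entries
#'
#' Slices a sample stream into 200-tick (25 s) entries with a 150-tick
#' stride, so that the final quarter of each entry equals the first quarter
#' of the next.  Each entry is flattened to an 800-vector ordered as 200
#' values of `a_x`, then `a_y`, then `a_z`, then `theta`.  A trailing
#' partial window is discarded; fewer than 200 samples yields an empty
#' result with a warning.
#'
#' @param samples a `calibrated_samples` data frame.
#' @param label exercise number 1--6, or `NA` for unlabeled streams.
#' @return an object of class `motion_windows`: list with `values` (800 x k
#'   matrix), `label`, `start_time`, `rate`, `ticks`, `stride`.
#' @export
make_windows <- function(samples, label = NA_integer_) {
  n <- nrow(samples)
  if (n < WINDOW_TICKS) {
    warning("fewer than ", WINDOW_TICKS, " samples; no windows produced")
    return(structure(list(values = matrix(numeric(0), 4L * WINDOW_TICKS, 0L),
                          label = integer(0), start_time = numeric(0),
                          rate = PACKET_RATE, ticks = WINDOW_TICKS,
                          stride = WINDOW_STRIDE),
                     class = "motion_windows"))
  }
  theta <- angle_series(samples)
  starts <- seq(1L, n - WINDOW_TICKS + 1L, by = WINDOW_STRIDE)
  vals <- vapply(starts, function(s) {
    idx <- s:(s + WINDOW_TICKS - 1L)
    c(samples$ax[idx], samples$ay[idx], samples$az[idx], theta[idx])
  }, numeric(4L * WINDOW_TICKS))
  vals <- matrix(vals, nrow = 4L * WINDOW_TICKS)
  structure(list(values = vals,
                 label = rep(as.integer(label), length(starts)),
                 start_time = samples$t[starts], rate = PACKET_RATE,
                 ticks = WINDOW_TICKS, stride = WINDOW_STRIDE),
            class = "motion_windows")
}

#' @export
print.motion_windows <- function(x, ...) {
  cat("<motion_windows> ", ncol(x$values), " windows of ", nrow(x$values),
      " values (", x$ticks, " ticks x 4 features), label(s) ",
      paste(unique(x$label), collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Number of windows
#' @param x a `motion_windows` object.
#' @export
length.motion_windows <- function(x) ncol(x$values)

#' Combine window sets
#' @param ... `motion_windows` objects with identical geometry.
#' @return a `motion_windows` object.
#' @export
c.motion_windows <- function(...) {
  ws <- list(...)
  structure(list(values = do.call(cbind, lapply(ws, `[[`, "values")),
                 label = unlist(lapply(ws, `[[`, "label")),
                 start_time = unlist(lapply(ws, `[[`, "start_time")),
                 rate = ws[[1L]]$rate, ticks = ws[[1L]]$ticks,
                 stride = ws[[1L]]$stride),
            class = "motion_windows")
}

#' Build the global motion and target matrices
#'
#' The training procedure consumes a global motion matrix `M` of six cells
#' (one per exercise), each holding the first `m` window columns of that
#' exercise (800 x m), and a matching global target matrix `T` of six
#' one-hot cells (6 x m, row k equal to 1 for exercise k): the target
#' dimension must match the six-neuron output layer, so target cells are
#' 6 x m, not 800 x m like the motion cells.
#'
#' @param windows list of six `motion_windows` objects, element k holding
#'   windows of exercise k, each supplying at least `m` windows.
#' @param m windows per exercise (conventionally 18, 36 or 72).
#' @return list with `M` (class `motion_matrix`: `cells`, list of six
#'   800 x m matrices) and `T` (class `target_matrix`: `cells`, list of six
#'   6 x m one-hot matrices).
#' @export
build_matrices <- function(windows, m) {
  if (length(windows) != N_EXERCISES)
    stop_contract("build_matrices expects one window set per exercise (6)")
  Mc <- vector("list", N_EXERCISES)
  Tc <- vector("list", N_EXERCISES)
  for (k in seq_len(N_EXERCISES)) {
    w <- windows[[k]]
    if (ncol(w$values) < m)
      stop_contract("exercise ", k, " supplies only ", ncol(w$values),
                    " windows; ", m, " required")
    Mc[[k]] <- w$values[, seq_len(m), drop = FALSE]
    tk <- matrix(0, N_EXERCISES, m)
    tk[k, ] <- 1
    Tc[[k]] <- tk
  }
  list(M = structure(list(cells = Mc, m = m), class = "motion_matrix"),
       T = structure(list(cells = Tc, m = m), class = "target_matrix"))
}

## Flatten a motion/target matrix (or plain matrix) into one wide matrix,
## with the per-column exercise labels.
flatten_cells <- function(x) {
  if (inherits(x, "motion_matrix") || inherits(x, "target_matrix")) {
    mat <- do.call(cbind, x$cells)
    lab <- rep(seq_along(x$cells), vapply(x$cells, ncol, 1L))
    list(mat = mat, label = lab)
  } else {
    list(mat = as.matrix(x), label = NULL)
  }
}
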