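## Packet-log I/O, validation filtering, ADC conversion and calibration.
##
## A sensor node samples six analog channels (tri-axial acceleration,
## tri-axial angular velocity).  For every usable packet the node collects
## 128 ADC counts per channel; the empirical distribution of those counts is
## approximately Gaussian around the true level, and the mean count of the
## block is the digital estimate of the analog value.  The base station
## receives eight packets per second per node.

#' Construct a packet log
#'
#' A packet log is the in-memory form of a stream of sensor packets.  It is
#' stored column-wise: scalar fields as vectors and the six 128-count channel
#' blocks of every packet as one integer matrix row.  Channel block order is
#' `ax, ay, az, wx, wy, wz`.  Missing counts (incomplete blocks) are `NA`.
#'
#' @param node_id integer vector, 1 = upper arm, 2 = wrist.
#' @param seq integer packet counters.
#' @param t packet times in seconds.
#' @param counts integer matrix with one row per packet and `6 * 128`
#'   columns (channel blocks in order).
#' @return an object of class `packet_log`.
#' @export
packet_log <- function(node_id, seq, t, counts) {
  n <- length(seq)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (length(node_id) == 1L) node_id <- rep.int(as.integer(node_id), n)
  if (length(node_id) != n || length(t) != n || nrow(counts) != n)
    stop_contract("packet_log fields must agree in length")
  if (ncol(counts) != 6L * BLOCK_LEN)
    stop_contract("counts must have ", 6L * BLOCK_LEN, " columns (6 blocks of ",
                  BLOCK_LEN, " counts)")
  structure(list(node_id = as.integer(node_id), seq = as.integer(seq),
                 t = as.numeric(t), counts = counts),
            class = "packet_log")
}

#' @export
length.packet_log <- function(x) length(x$seq)

#' @export
print.packet_log <- function(x, ...) {
  cat("<packet_log> ", length(x), " packets, node(s) ",
      paste(unique(x$node_id), collapse = ","),
      ", t in [", format(min(x$t)), ", ", format(max(x$t)), "] s\n", sep = "")
  invisible(x)
}

## Subset a packet log by packet index.
subset_packets <- function(log, idx) {
  packet_log(log$node_id[idx], log$seq[idx], log$t[idx],
             log$counts[idx, , drop = FALSE])
}

csv_header <- function() {
  c("node_id", "seq", "t",
    paste0(rep(CHANNELS, each = BLOCK_LEN), "_c", seq_len(BLOCK_LEN)))
}

#' Write a packet log to disk
#'
#' Two dialects are defined by this package (the original radio payload has
#' no public byte-level description): a CSV dialect with one row per packet
#' (`node_id, seq, t`, then 6 x 128 counts) and an equivalent little-endian
#' binary dialect.  Missing counts are empty CSV fields / `0xFFFF` sentinels.
#'
#' @param log a `packet_log`.
#' @param path output file.
#' @param dialect `"csv"` or `"binary"`.
#' @return `path`, invisibly.
#' @seealso [parse_packet_log()]
#' @export
write_packet_log <- function(log, path, dialect = c("csv", "binary")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    counts <- log$counts
    cc <- matrix(as.character(counts), nrow = nrow(counts))
    cc[is.na(counts)] <- ""
    rows <- cbind(log$node_id, log$seq, format(log$t, trim = TRUE), cc)
    lines <- c(paste(csv_header(), collapse = ","),
               apply(rows, 1L, paste, collapse = ","))
    writeLines(lines, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar("RRPK", con, nchars = 4L, eos = NULL)
    writeBin(c(1L, 6L, BLOCK_LEN), con, size = 2L, endian = "little")
    writeBin(length(log), con, size = 4L, endian = "little")
    for (i in seq_len(length(log))) {
      writeBin(log$node_id[i], con, size = 1L)
      writeBin(log$seq[i], con, size = 4L, endian = "little")
      writeBin(log$t[i], con, size = 8L, endian = "little")
      blk <- log$counts[i, ]
      blk[is.na(blk)] <- 65535L
      writeBin(blk, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Parse a packet log file
#'
#' Reads a packet log written in either of the package dialects (see
#' [write_packet_log()]).  Malformed records are never silently repaired: a
#' CSV row with the wrong field count raises a parse error naming the line.
#'
#' @param path file to read.
#' @param dialect `"csv"` or `"binary"`.
#' @return a `packet_log` in file order with `seq` preserved.
#' @export
parse_packet_log <- function(path, dialect = c("csv", "binary")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_contract("cannot read packet log: ", path)
  if (dialect == "csv") parse_packet_csv(path) else parse_packet_bin(path)
}

parse_packet_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop_contract("empty packet log: ", path)
  nfield <- 3L + 6L * BLOCK_LEN
  body <- lines[-1L]
  body <- body[nzchar(body)]
  fields <- strsplit(body, ",", fixed = TRUE)
  ## trailing empty fields are dropped by strsplit; recover them from commas
  ncommas <- lengths(regmatches(body, gregexpr(",", body, fixed = TRUE)))
  got <- ncommas + 1L
  bad <- which(got != nfield)
  if (length(bad)) {
    stop_contract(sprintf(
      "parse error at line %d of %s: expected %d fields, got %d",
      bad[1L] + 1L, path, nfield, got[bad[1L]]))
  }
  fields <- lapply(fields, function(f) c(f, rep("", nfield - length(f))))
  m <- do.call(rbind, fields)
  counts <- suppressWarnings(matrix(as.integer(m[, -(1:3), drop = FALSE]),
                                    nrow = nrow(m)))
  packet_log(as.integer(m[, 1L]), as.integer(m[, 2L]), as.numeric(m[, 3L]),
             counts)
}

parse_packet_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(magic, "RRPK"))
    stop_contract("parse error in ", path, ": bad magic bytes")
  hdr <- readBin(con, "integer", n = 3L, size = 2L, endian = "little")
  if (hdr[2L] != 6L || hdr[3L] != BLOCK_LEN)
    stop_contract("parse error in ", path, ": unexpected channel geometry")
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  node_id <- integer(n); sq <- integer(n); tt <- numeric(n)
  counts <- matrix(NA_integer_, n, 6L * BLOCK_LEN)
  for (i in seq_len(n)) {
    node_id[i] <- readBin(con, "integer", n = 1L, size = 1L)
    sq[i] <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    tt[i] <- readBin(con, "double", n = 1L, size = 8L, endian = "little")
    blk <- readBin(con, "integer", n = 6L * BLOCK_LEN, size = 2L,
                   signed = FALSE, endian = "little")
    if (length(blk) < 6L * BLOCK_LEN)
      stop_contract("parse error in ", path, ": truncated record ", i)
    blk[blk == 65535L] <- NA_integer_
    counts[i, ] <- blk
  }
  packet_log(node_id, sq, tt, counts)
}

#' Exclude invalid and incomplete packets
#'
#' Mirrors the validation step of the receiving base node: a packet is
#' rejected iff any channel block is incomplete (fewer than 128 counts), any
#' count is outside the ADC range, or its `seq` duplicates an already-seen
#' `seq` (first occurrence kept).  Filtering never raises on bad data; it
#' reports.  When a packet fails several checks it is counted once, under
#' the first matching reason in the order incomplete, out-of-range,
#' duplicate.
#'
#' @param log a `packet_log`.
#' @param bits ADC bit depth; counts must lie in `[0, 2^bits - 1]`.
#' @return a list with `valid` (a `packet_log`), `report` (rejection counts
#'   by reason) and `rejected` (per-packet index, seq and reason).
#' @export
filter_packets <- function(log, bits = 10L) {
  maxc <- 2^bits - 1
  incomplete <- rowSums(is.na(log$counts)) > 0L
  oor <- !incomplete &
    (rowSums(log$counts < 0L, na.rm = TRUE) +
       rowSums(log$counts > maxc, na.rm = TRUE)) > 0L
  dup <- duplicated(log$seq) & !incomplete & !oor
  reason <- rep(NA_character_, length(log))
  reason[dup] <- "duplicate_seq"
  reason[oor] <- "out_of_range"
  reason[incomplete] <- "incomplete"
  bad <- !is.na(reason)
  report <- data.frame(
    reason = c("incomplete", "out_of_range", "duplicate_seq"),
    count = c(sum(incomplete), sum(oor), sum(dup)))
  rejected <- data.frame(index = which(bad), seq = log$seq[bad],
                         reason = reason[bad])
  list(valid = subset_packets(log, !bad), report = report,
       rejected = rejected)
}

#' Channel calibration
#'
#' Linear calibration of one channel: `value = (mean_counts - offset) *
#' scale - baseline`.  `baseline` carries the initial-placement reading that
#' is subtracted so that measurements are relative to the starting posture.
#'
#' @param offset counts at physical zero.
#' @param scale physical units per count (g/count for acceleration,
#'   deg/s per count for angular velocity); must be nonzero.
#' @param baseline initial-placement value to subtract (physical units).
#' @return an object of class `channel_calibration`.
#' @export
channel_calibration <- function(offset, scale, baseline = 0) {
  if (scale == 0) stop_contract("calibration scale must be nonzero")
  structure(list(offset = offset, scale = scale, baseline = baseline),
            class = "channel_calibration")
}

#' Default calibration for all six channels
#'
#' The ADC depth and physical ranges of the original node are not public;
#' the package default maps a 10-bit ADC (0--1023, mid-scale zero) onto
#' +/- 2 g for the acceleration channels and +/- 500 deg/s for the
#' angular-velocity channels, typical MEMS ranges.
#'
#' @param bits ADC bit depth.
#' @param acc_range,gyro_range full-scale magnitude (g, deg/s).
#' @return named list of six [channel_calibration()] objects in channel
#'   order `ax, ay, az, wx, wy, wz`.
#' @export
default_calibration <- function(bits = 10L, acc_range = 2, gyro_range = 500) {
  full <- 2^bits
  mid <- full / 2
  acc <- channel_calibration(mid, 2 * acc_range / full)
  gyr <- channel_calibration(mid, 2 * gyro_range / full)
  stats::setNames(list(acc, acc, acc, gyr, gyr, gyr), CHANNELS)
}

#' Convert one ADC count block to a physical value
#'
#' The node collects 128 counts per channel per packet; their histogram
#' approximates a Gaussian probability density and its mean count is the
#' digital reading.  The histogram mean equals the arithmetic sample mean,
#' which is what is computed here.
#'
#' @param block complete numeric vector of 128 in-range counts.
#' @param cal a [channel_calibration()].
#' @return `(mean(block) - offset) * scale - baseline`.
#' @export
adc_to_value <- function(block, cal) {
  if (length(block) != BLOCK_LEN || anyNA(block))
    stop_contract("adc_to_value requires a complete block of ", BLOCK_LEN,
                  " counts")
  (mean(block) - cal$offset) * cal$scale - cal$baseline
}

#' Convert filtered packets to calibrated samples
#'
#' One calibrated sample per packet: every channel block is reduced to its
#' mean count and mapped through its channel calibration.  Packets must
#' already have passed [filter_packets()].
#'
#' @param log a `packet_log` of valid packets.
#' @param calibration named list of six [channel_calibration()] objects
#'   (see [default_calibration()]).
#' @return a `data.frame` of class `calibrated_samples` with columns
#'   `t, ax, ay, az, wx, wy, wz, node_id`; timestamps strictly increasing.
#' @export
packets_to_samples <- function(log, calibration = default_calibration()) {
  if (length(log) && any(diff(log$t) <= 0))
    stop_contract("packet timestamps must be strictly increasing")
  if (anyNA(log$counts))
    stop_contract("packets_to_samples requires filtered (complete) packets")
  out <- data.frame(t = log$t)
  for (j in seq_along(CHANNELS)) {
    cols <- ((j - 1L) * BLOCK_LEN + 1L):(j * BLOCK_LEN)
    cal <- calibration[[CHANNELS[j]]]
    out[[CHANNELS[j]]] <-
      (rowMeans(log$counts[, cols, drop = FALSE]) - cal$offset) * cal$scale -
      cal$baseline
  }
  out$node_id <- log$node_id
  class(out) <- c("calibrated_samples", "data.frame")
  out
}

#' Write / read calibrated samples as CSV
#'
#' @param samples a `calibrated_samples` data frame.
#' @param path file path.
#' @return `path` (write) or the samples (read), invisibly for write.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(as.data.frame(samples)[c("t", CHANNELS, "node_id")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("calibrated_samples", "data.frame")
  out
}

#' Read / write calibration config files
#'
#' INI-style key-value file, one `[nodeN.channel]` section per node/channel,
#' keys `offset`, `scale`, `baseline`.
#'
#' @param path file path.
#' @param calibration named list of [channel_calibration()] per channel.
#' @param node node id used in section names.
#' @return for reading, a named list of `channel_calibration` objects.
#' @export
read_calibration <- function(path, node = 2L) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- NA_character_
  vals <- list()
  for (ln in lines) {
    if (startsWith(ln, "[")) {
      section <- gsub("\\[|\\]", "", ln)
    } else {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L) stop_contract("bad calibration line: ", ln)
      vals[[section]][[trimws(kv[1L])]] <- as.numeric(trimws(kv[2L]))
    }
  }
  out <- list()
  for (ch in CHANNELS) {
    sec <- vals[[paste0("node", node, ".", ch)]]
    if (is.null(sec)) stop_contract("calibration missing for channel ", ch)
    out[[ch]] <- channel_calibration(sec$offset, sec$scale,
                                     if (is.null(sec$baseline)) 0 else sec$baseline)
  }
  out
}

#' @rdname read_calibration
#' @export
write_calibration <- function(calibration, path, node = 2L) {
  lines <- character(0)
  for (ch in names(calibration)) {
    cal <- calibration[[ch]]
    lines <- c(lines, paste0("[node", node, ".", ch, "]"),
               paste0("offset = ", format(cal$offset, digits = 17)),
               paste0("scale = ", format(cal$scale, digits = 17)),
               paste0("baseline = ", format(cal$baseline, digits = 17)), "")
  }
  writeLines(lines, path)
  invisible(path)
}
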