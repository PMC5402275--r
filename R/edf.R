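# Minimal European Data Format (EDF) I/O: ASCII header + 16-bit samples
# in 1-second data records. Supports what the pipeline needs -- a small
# number of uniformly sampled signals with integer per-second rates --
# not the full annotation (EDF+) spec.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

.edf_num <- function(x, width) .edf_pad(format(x, trim = TRUE), width)

#' Write waveforms to an EDF file
#'
#' Samples are scaled to 16-bit integers using each signal's physical
#' range; the quantization step is `range / 65535`. Records are one
#' second long, so each signal's sampling rate must be a positive
#' integer and all signals must share a duration of a whole number of
#' seconds (the tail is truncated to whole records with a warning).
#'
#' @param waves named list of [waveform()] tibbles; names become signal
#'   labels (conventionally `ABP`, `FLOW`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(waves, path) {
  if (is.null(names(waves)) || any(names(waves) == ""))
    stop("`waves` must be a named list", call. = FALSE)
  ns <- length(waves)
  fs <- vapply(waves, wave_fs, numeric(1))
  if (any(abs(fs - round(fs)) > 1e-9) || any(fs < 1))
    stop("EDF export needs integer sampling rates", call. = FALSE)
  n_rec <- min(vapply(waves, function(w) nrow(w) %/% wave_fs(w), numeric(1)))
  if (n_rec < 1) stop("signals shorter than one EDF record", call. = FALSE)
  if (any(vapply(waves, nrow, numeric(1)) > n_rec * fs))
    warning("signal tails truncated to whole 1 s EDF records")

  phys_min <- phys_max <- dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    v <- waves[[i]]$value[seq_len(n_rec * fs[i])]
    v[!is.finite(v)] <- 0
    lo <- min(v); hi <- max(v)
    if (hi - lo < 1e-9) hi <- lo + 1        # constant signal: avoid /0
    phys_min[[i]] <- lo; phys_max[[i]] <- hi
    dig[[i]] <- as.integer(round((v - lo) / (hi - lo) * 65535 - 32768))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad("X X X X", 80), .edf_pad("Startdate X", 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_num(256 * (1 + ns), 8), .edf_pad("", 44),
    .edf_num(n_rec, 8), .edf_num(1, 8), .edf_num(ns, 4)
  )
  hdr <- paste0(
    hdr,
    paste(vapply(names(waves), .edf_pad, character(1), width = 16),
          collapse = ""),
    paste(rep(.edf_pad("", 80), ns), collapse = ""),
    paste(vapply(waves, function(w) .edf_pad(wave_units(w), 8),
                 character(1)), collapse = ""),
    paste(vapply(phys_min, .edf_num, character(1), width = 8),
          collapse = ""),
    paste(vapply(phys_max, .edf_num, character(1), width = 8),
          collapse = ""),
    paste(rep(.edf_num(-32768, 8), ns), collapse = ""),
    paste(rep(.edf_num(32767, 8), ns), collapse = ""),
    paste(rep(.edf_pad("", 80), ns), collapse = ""),
    paste(vapply(fs, .edf_num, character(1), width = 8), collapse = ""),
    paste(rep(.edf_pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  for (rec in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((rec - 1) * fs[i] + 1):(rec * fs[i])
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read one signal from an EDF file
#'
#' @param path EDF file path.
#' @param channel signal label to extract (e.g. `"ABP"`, `"FLOW"`).
#' @return a [waveform()] tibble.
#' @export
read_edf <- function(path, channel) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes (recomputed)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)            # transducer
  units <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)            # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  j <- match(channel, labels)
  if (is.na(j))
    stop(sprintf("channel `%s` not in EDF (has: %s)", channel,
                 paste(labels, collapse = ", ")), call. = FALSE)
  out <- numeric(n_rec * spr[j])
  for (rec in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[i], size = 2,
                     endian = "little", signed = TRUE)
      if (i == j) out[((rec - 1) * spr[j] + 1):(rec * spr[j])] <- raw
    }
  }
  phys <- pmin[j] + (out - dmin[j]) * (pmax[j] - pmin[j]) /
    (dmax[j] - dmin[j])
  fs <- spr[j] / rec_dur
  waveform(phys, fs = fs,
           channel = if (channel %in% c("ABP", "FLOW")) channel else "ABP",
           units = units[j])
}
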