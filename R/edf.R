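# Minimal European Data Format (EDF) support: continuous recordings with a
# single sampling rate across channels, 16-bit samples. Physical dimensions
# of uV/mV/V are honored and converted to microvolts on read.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, width = 1, format = "g", digits = 7)
  if (nchar(s) > width) s <- formatC(x, width = 1, format = "g", digits = 4)
  edf_pad(s, width)
}

#' @noRd
write_edf <- function(rec, path) {
  k <- nrow(rec$data); n <- ncol(rec$data)
  phys_min <- apply(rec$data, 1L, min)
  phys_max <- apply(rec$data, 1L, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_max[flat] + 1
  dig_min <- -32768L; dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8L), edf_pad("X", 80L), edf_pad("Startdate X X X X", 80L),
    edf_pad("01.01.00", 8L), edf_pad("00.00.00", 8L),
    edf_pad(256L * (1L + k), 8L), edf_pad("", 44L),
    edf_pad(1L, 8L), edf_num(n / rec$fs, 8L), edf_pad(k, 4L))
  field <- function(vals, width) paste(vapply(vals, edf_pad, "", width = width),
                                       collapse = "")
  hdr <- paste0(hdr,
    field(rec$channel_names, 16L),
    field(rep("", k), 80L),
    field(rep("uV", k), 8L),
    field(vapply(phys_min, edf_num, "", width = 8L), 8L),
    field(vapply(phys_max, edf_num, "", width = 8L), 8L),
    field(rep(dig_min, k), 8L),
    field(rep(dig_max, k), 8L),
    field(rep("", k), 80L),
    field(rep(n, k), 8L),
    field(rep("", k), 32L))
  writeChar(hdr, con, eos = NULL)
  # one data record holding the whole recording, signal by signal
  for (ch in seq_len(k)) {
    # parse back the header's truncated physical range so read inverts exactly
    lo <- as.numeric(edf_num(phys_min[ch], 8L))
    hi <- as.numeric(edf_num(phys_max[ch], 8L))
    scale <- (dig_max - dig_min) / (hi - lo)
    dig <- as.integer(round((pmin(pmax(rec$data[ch, ], lo), hi) - lo) * scale) + dig_min)
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' @noRd
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8L)  # version
  rd(80L); rd(80L); rd(8L); rd(8L)
  header_bytes <- as.integer(rd(8L))
  rd(44L)
  n_records <- as.integer(rd(8L))
  record_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  if (is.na(ns) || ns < 1L)
    stop("EDF file declares no signals", call. = FALSE)
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16L); rdv(80L)
  dims <- rdv(8L)
  pmin <- as.numeric(rdv(8L)); pmax <- as.numeric(rdv(8L))
  dmin <- as.numeric(rdv(8L)); dmax <- as.numeric(rdv(8L))
  rdv(80L)
  spr <- as.integer(rdv(8L))
  rdv(32L)
  seek(con, header_bytes)
  if (n_records < 0L)
    stop("EDF files with unknown record count are not supported", call. = FALSE)
  if (length(unique(spr)) != 1L)
    stop("channels with differing sampling rates are not supported", call. = FALSE)
  fs <- spr[1L] / record_dur
  dat <- matrix(0, nrow = ns, ncol = spr[1L] * n_records)
  for (rec_i in seq_len(n_records)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr[ch])
        stop("EDF file truncated in data record ", rec_i, call. = FALSE)
      phys <- pmin[ch] + (dig - dmin[ch]) * (pmax[ch] - pmin[ch]) / (dmax[ch] - dmin[ch])
      dat[ch, (rec_i - 1L) * spr[ch] + seq_len(spr[ch])] <- phys
    }
  }
  unit_scale <- vapply(dims, function(d) switch(tolower(d),
    "uv" = 1, "µv" = 1, "mv" = 1e3, "v" = 1e6, 1), 0)
  dat <- dat * unit_scale
  recording(dat, fs = fs, channel_names = make.unique(labels))
}
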