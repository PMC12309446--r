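# Minimal EDF (European Data Format) reader/writer: fixed 256-byte header,
# 256 bytes per signal, 16-bit little-endian samples in 1-second data records.
# Covers plain continuous EDF as produced by write_edf(); annotations and
# discontinuous EDF+ are out of scope.

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1L, width)
}

read_edf_ascii <- function(con, width) {
  trimws(rawToChar(readBin(con, "raw", n = width)))
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_edf_ascii(con, 8)
  if (version != "0") stop("not an EDF file (version field '", version, "')",
                           call. = FALSE)
  readBin(con, "raw", n = 80 + 80 + 8 + 8)      # patient, recording, date, time
  read_edf_ascii(con, 8)                        # header byte count
  read_edf_ascii(con, 44)                       # reserved
  n_rec <- as.integer(read_edf_ascii(con, 8))
  rec_dur <- as.numeric(read_edf_ascii(con, 8))
  ns <- as.integer(read_edf_ascii(con, 4))
  if (is.na(ns) || ns < 1) stop("corrupt EDF header", call. = FALSE)
  labels <- vapply(seq_len(ns), function(i) read_edf_ascii(con, 16), "")
  for (i in seq_len(ns)) readBin(con, "raw", n = 80)   # transducer
  dims <- vapply(seq_len(ns), function(i) read_edf_ascii(con, 8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) read_edf_ascii(con, 8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) read_edf_ascii(con, 8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) read_edf_ascii(con, 8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) read_edf_ascii(con, 8), ""))
  for (i in seq_len(ns)) readBin(con, "raw", n = 80)   # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) read_edf_ascii(con, 8), ""))
  for (i in seq_len(ns)) readBin(con, "raw", n = 32)   # reserved
  if (length(unique(spr)) != 1L)
    stop("mixed sampling rates across EDF signals are not supported",
         call. = FALSE)
  fs <- spr[1] / rec_dur
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, endian = "little",
                     signed = TRUE)
      phys <- pmin_[i] + gain[i] * (dig - dmin_[i])
      data[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  # single internal unit: microvolts
  data[dims == "V", ] <- data[dims == "V", , drop = FALSE] * 1e6
  data[dims == "mV", ] <- data[dims == "mV", , drop = FALSE] * 1e3
  list(data = data, fs = fs, labels = labels)
}

write_edf <- function(rec, path) {
  x <- rec$data
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF export needs an integer sampling rate", call. = FALSE)
  spr <- as.integer(round(fs))
  n_rec <- ncol(x) %/% spr
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)",
                      call. = FALSE)
  if (n_rec * spr != ncol(x))
    warning("EDF export truncates a trailing partial second (",
            ncol(x) - n_rec * spr, " samples)")
  ns <- nrow(x)
  pmin_ <- apply(x[, 1:(n_rec * spr), drop = FALSE], 1, min)
  pmax_ <- apply(x[, 1:(n_rec * spr), drop = FALSE], 1, max)
  flat <- pmax_ - pmin_ <= 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin_ <- -32768; dmax_ <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_field(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr(paste("Startdate 01-JAN-2026", "X", "X", "eegqc"), 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 + 256 * ns, 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8)
  wr(ns, 4)
  for (l in rec$labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (v in pmin_) wr(formatC(v, format = "g", digits = 7), 8)
  for (v in pmax_) wr(formatC(v, format = "g", digits = 7), 8)
  for (i in seq_len(ns)) wr(dmin_, 8)
  for (i in seq_len(ns)) wr(dmax_, 8)
  for (i in seq_len(ns)) wr("HP:0Hz", 80)
  for (i in seq_len(ns)) wr(spr, 8)
  for (i in seq_len(ns)) wr("", 32)
  gain <- (dmax_ - dmin_) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(ns)) {
      dig <- as.integer(round(dmin_ + gain[i] * (x[i, idx] - pmin_[i])))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
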