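# Plain-text round-tripping for the package's matrix-shaped objects
# (leadfield, connectivity, delay), atlas tables, montages and EEG traces,
# plus a minimal EDF codec (16-bit, one data record per second) for
# interoperability with clinical EEG viewers. No external format library
# for EDF exists in this R stack, so the fixed-layout header is read and
# written directly per the published format.

#' Write / read a square or rectangular named numeric matrix
#'
#' Tab-delimited with a header row of column names and a leading `name`
#' column of row names; the standard on-disk form for leadfield and
#' connectivity matrices.
#'
#' @param m Numeric matrix with dimnames.
#' @param path File path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` the
#'   matrix.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("matrix must carry row and column names")
  }
  df <- data.frame(name = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write / read an atlas table
#' @param atlas A [brain_atlas()].
#' @param path File path.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "brain_atlas"))
  utils::write.table(as.data.frame(atlas), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  brain_atlas(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write / read a montage as a derivation-per-line text file
#'
#' Each line is `"Fp1-F3"`; an optional `# chain:` comment groups the
#' following derivations into a named anterior-to-posterior chain.
#'
#' @param montage An `"eeg_montage"` data frame.
#' @param path File path.
#' @export
write_montage <- function(montage, path) {
  lines <- character(0)
  for (ch in unique(montage$chain)) {
    lines <- c(lines, paste0("# chain: ", ch),
               montage$name[montage$chain == ch])
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  chain <- "chain1"
  rows <- list()
  for (ln in lines) {
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("chain:\\s*(\\S+)", ln))[[1]]
      if (length(m) == 2) chain <- m[2]
      next
    }
    parts <- strsplit(ln, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed derivation line: ", ln)
    rows[[length(rows) + 1L]] <- data.frame(
      name = ln, anode = parts[1], cathode = parts[2], chain = chain,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("eeg_montage", "data.frame")
  out
}

#' Write / read an EEG recording as delimited text
#'
#' Tab-delimited samples (one column per channel, microvolts) preceded by
#' two comment lines recording the sampling rate and the reference.
#'
#' @param eeg An [eeg_recording()].
#' @param path File path.
#' @export
write_eeg_delimited <- function(eeg, path) {
  stopifnot(inherits(eeg, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs: %.10g", eeg$fs),
               sprintf("# reference: %s", eeg$reference)), con)
  utils::write.table(eeg$samples, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_eeg_delimited
#' @export
read_eeg_delimited <- function(path) {
  hdr <- readLines(path, n = 2)
  fs <- as.numeric(sub("# fs:\\s*", "", hdr[1]))
  ref <- sub("# reference:\\s*", "", hdr[2])
  samples <- as.matrix(utils::read.delim(path, skip = 2, check.names = FALSE))
  eeg_recording(samples, fs, ref)
}

.edf_pad <- function(x, width) {
  s <- sprintf("%-*s", width, as.character(x))
  substr(s, 1, width)
}

# format a number so it fits an 8-character EDF header field without
# truncation (reducing significant digits as needed)
.edf_num8 <- function(v) {
  for (d in 7:2) {
    s <- sprintf("%.*g", d, v)
    if (nchar(s) <= 8) return(s)
  }
  stop("physical range does not fit an EDF header field: ", v)
}

#' Write an EEG recording to EDF
#'
#' European Data Format, 16-bit little-endian samples, physical dimension
#' microvolts, one data record per second (the recording is zero-padded to
#' a whole number of seconds; the true sample count is recoverable from the
#' stored duration). The physical range is set per channel from the data,
#' so the quantisation error is at most half a physical bin.
#'
#' @param eeg An [eeg_recording()] with an integer number of samples per
#'   second.
#' @param path Output path.
#' @param patient,recording Free-text EDF identification fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(eeg, path, patient = "X", recording = "spikewave") {
  stopifnot(inherits(eeg, "eeg_recording"))
  fs <- eeg$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export needs an integer sampling rate")
  fs <- as.integer(round(fs))
  X <- eeg$samples
  ns <- ncol(X)
  n_rec <- as.integer(ceiling(nrow(X) / fs))
  pad <- n_rec * fs - nrow(X)
  if (pad > 0) X <- rbind(X, matrix(0, pad, ns, dimnames = list(NULL, colnames(X))))
  # physical bounds widened by a relative margin larger than the 7-digit
  # header rounding, then re-parsed from their header representation, so
  # writer and reader quantize against identical values and no sample is
  # clipped by header truncation
  phys_min <- pmin(apply(X, 2, min), -1) * (1 + 1e-4) - 1e-9
  phys_max <- pmax(apply(X, 2, max), 1) * (1 + 1e-4) + 1e-9
  phys_min_s <- vapply(phys_min, .edf_num8, character(1))
  phys_max_s <- vapply(phys_max, .edf_num8, character(1))
  phys_min <- as.numeric(phys_min_s)
  phys_max <- as.numeric(phys_max_s)
  dig_min <- -32768
  dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(.edf_pad(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)
  wr(patient, 80)
  wr(recording, 80)
  wr(format(as.Date("2000-01-01"), "%d.%m.%y"), 8)
  wr("00.00.00", 8)
  wr(256 + ns * 256, 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8) # record duration, seconds
  wr(ns, 4)
  for (nm in colnames(X)) wr(nm, 16)
  for (i in seq_len(ns)) wr("EEG", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(phys_min_s[i], 8)
  for (i in seq_len(ns)) wr(phys_max_s[i], 8)
  for (i in seq_len(ns)) wr(dig_min, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  gain <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((X[rows, i] - phys_min[i]) * gain[i]) + dig_min
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con, size = 2,
               endian = "little")
    }
  }
  attr(path, "true_samples") <- nrow(eeg$samples)
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any 16-bit EDF with equal
#' per-channel rates)
#'
#' @param path EDF file path.
#' @return An [eeg_recording()] (referential tag; re-tag with
#'   `eeg_recording()` if the channels are bipolar derivations).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L) stop("channels with unequal sampling rates")
  fs <- spr[1] / rec_dur
  X <- matrix(0, n_rec * spr[1], ns, dimnames = list(NULL, labels))
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2, endian = "little")
      X[((r - 1) * spr[1] + 1):(r * spr[1]), i] <-
        phys_min[i] + (dig - dig_min[i]) * gain[i]
    }
  }
  eeg_recording(X, fs, "referential")
}

#' Write a score report (human-readable text + machine-readable JSON twin)
#'
#' @param score An `"eeg_ies_score"`.
#' @param path Base path; `.txt` and `.json` siblings are written.
#' @return Character vector of the two paths, invisibly.
#' @export
write_score_report <- function(score, path) {
  stopifnot(inherits(score, "eeg_ies_score"))
  txt <- paste0(path, ".txt")
  jsn <- paste0(path, ".json")
  con <- file(txt, "w")
  sink(con)
  print(score)
  sink()
  close(con)
  jsonlite::write_json(
    list(earned = score$earned, available = score$available,
         maximum = score$maximum, percentage = score$percentage),
    jsn, auto_unbox = TRUE, digits = NA)
  invisible(c(txt, jsn))
}
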