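## BrainVision three-file dialect: INI-style text header (.vhdr), little-
## endian IEEE float32 multiplexed binary (.eeg), and a text marker file
## (.vmrk). Only this dialect is supported; other encodings are rejected
## loudly rather than guessed.

#' Write a recording and its events as a BrainVision triplet
#'
#' Emits `<basepath>.vhdr` (header), `<basepath>.eeg` (multiplexed
#' little-endian float32) and `<basepath>.vmrk` (stimulus markers, one per
#' trial, description = condition name verbatim, positions in samples from
#' recording start).
#'
#' @param rec A `raw_recording`.
#' @param events A `session_plan` (or data.frame with `onset_s`,
#'   `duration_s`, `condition`).
#' @param basepath Output path without extension.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_brainvision <- function(rec, events, basepath) {
  fs <- rec$sample_rate_hz
  base <- basename(basepath)
  paths <- paste0(basepath, c(".vhdr", ".eeg", ".vmrk"))
  names(paths) <- c("vhdr", "eeg", "vmrk")

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", base),
    sprintf("MarkerFile=%s.vmrk", base),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nrow(rec$data)),
    sprintf("SamplingInterval=%s", format(1e6 / fs, scientific = FALSE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(rec$data)), rec$channel_labels)
  )
  tryCatch(writeLines(hdr, paths["vhdr"], useBytes = FALSE),
           error = function(e) stop_invalid("cannot write header: ", conditionMessage(e)))

  con <- file(paths["eeg"], "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(rec$data), con, size = 4L, endian = "little")

  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", base),
    "",
    "[Marker Infos]",
    sprintf("Mk%d=Stimulus,%s,%d,%d,0",
            seq_len(nrow(events)),
            events$condition,
            as.integer(round(events$onset_s * fs)),
            as.integer(round(events$duration_s * fs)))
  )
  writeLines(mk, paths["vmrk"])
  invisible(paths)
}

parse_ini_value <- function(lines, key) {
  hit <- grep(sprintf("^%s=", key), lines, value = TRUE)
  if (!length(hit)) stop_invalid(sprintf("header is missing '%s'", key))
  sub(sprintf("^%s=", key), "", hit[1])
}

#' Read a BrainVision triplet
#'
#' Inverse of [write_brainvision()] for the supported dialect (multiplexed
#' IEEE_FLOAT_32). Marker-encoded events come back with onset, duration and
#' condition; sequence/block indices are not representable in the marker
#' dialect and are returned as NA (use the TSV event sidecar for the full
#' plan).
#'
#' @param basepath Path without extension (expects .vhdr/.eeg/.vmrk).
#' @return List with `recording` (a `raw_recording`) and `events` (a
#'   data.frame: onset_s, duration_s, condition, sequence, block).
#' @export
read_brainvision <- function(basepath) {
  vhdr <- paste0(basepath, ".vhdr")
  if (!file.exists(vhdr)) stop_invalid("missing header file: ", vhdr)
  lines <- readLines(vhdr, encoding = "UTF-8", warn = FALSE)

  fmt <- parse_ini_value(lines, "BinaryFormat")
  if (fmt != "IEEE_FLOAT_32") {
    stop_invalid(sprintf("unsupported BinaryFormat '%s' (only IEEE_FLOAT_32)", fmt))
  }
  orient <- parse_ini_value(lines, "DataOrientation")
  if (orient != "MULTIPLEXED") {
    stop_invalid(sprintf("unsupported DataOrientation '%s'", orient))
  }
  nch <- as.integer(parse_ini_value(lines, "NumberOfChannels"))
  fs <- 1e6 / as.numeric(parse_ini_value(lines, "SamplingInterval"))
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  labels <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                   `[`, character(1), 1)
  if (length(labels) != nch) stop_invalid("channel info count disagrees with NumberOfChannels")

  eegf <- paste0(basepath, ".eeg")
  nbytes <- file.size(eegf)
  if (is.na(nbytes)) stop_invalid("missing binary file: ", eegf)
  if (nbytes %% (4L * nch) != 0) {
    stop_invalid(sprintf("binary size %d is not a multiple of %d channels x 4 bytes",
                         nbytes, nch))
  }
  nsamp <- nbytes / (4L * nch)
  con <- file(eegf, "rb")
  on.exit(close(con), add = TRUE)
  vals <- readBin(con, "numeric", n = nch * nsamp, size = 4L, endian = "little")
  data <- matrix(vals, nrow = nch, dimnames = list(labels, NULL))

  vmrk <- paste0(basepath, ".vmrk")
  mk <- grep("^Mk[0-9]+=Stimulus,", readLines(vmrk, warn = FALSE), value = TRUE)
  parts <- strsplit(sub("^Mk[0-9]+=", "", mk), ",")
  events <- data.frame(
    onset_s = vapply(parts, function(p) as.numeric(p[3]), numeric(1)) / fs,
    duration_s = vapply(parts, function(p) as.numeric(p[4]), numeric(1)) / fs,
    condition = vapply(parts, `[`, character(1), 2),
    sequence = NA_integer_, block = NA_integer_,
    stringsAsFactors = FALSE
  )

  kinds <- ifelse(grepl("^EMG", labels), "EMG", "EEG")
  rec <- structure(list(data = data, sample_rate_hz = fs,
                        channel_labels = labels, channel_kinds = kinds,
                        start_time = 0),
                   class = "raw_recording")
  list(recording = rec, events = events)
}
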