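# EDF (European Data Format) 16-bit read/write.
#
# No EDF package ships with the supported stack, so the fixed-layout format
# is implemented directly: a 256-byte global header, 256 bytes per signal,
# then data records of little-endian int16 samples. One data record spans
# 1 second, so the record length must be an integer number of seconds.
# Annotations travel in a sidecar CSV ("<file>_annotations.csv") with
# columns label,start_s,end_s.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)
}

annotation_sidecar <- function(path) {
  paste0(sub("\\.edf$", "", path, ignore.case = TRUE), "_annotations.csv")
}

# Fixed physical range giving 0.1 uV resolution over +/- 3276.7 uV.
EDF_PHYS_MAX <- 3276.7
EDF_DIG_MAX <- 32767L

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16 bits over a fixed +/-3276.7 microvolt
#' physical range (0.1 uV resolution). Annotations are written to a sidecar
#' CSV next to the file. The header carries a fixed start date/time so that
#' identical recordings produce byte-identical files.
#'
#' @param rec A [recording()].
#' @param path Output path (`.edf`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stopf("EDF writer requires integer fs")
  n <- nrow(rec$data)
  if (n %% fs != 0)
    stopf("record length (%d samples) must be a whole number of seconds", n)
  if (max(abs(rec$data)) > EDF_PHYS_MAX)
    stopf("amplitudes exceed the EDF 16-bit physical range (+/-%g uV)",
          EDF_PHYS_MAX)
  ns <- ncol(rec$data)
  n_rec <- n %/% fs
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8L),
    edf_pad(rec$patient_id, 80L),
    edf_pad(paste("Startdate 01-JAN-2024", rec$patient_id), 80L),
    "01.01.24", "00.00.00",
    edf_pad(256L * (1L + ns), 8L),
    edf_pad("", 44L),
    edf_pad(n_rec, 8L),
    edf_pad(1L, 8L),
    edf_pad(ns, 4L))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  fld(rec$channels$label, 16L)
  fld(paste("kind:", rec$channels$kind), 80L)
  fld(rep("uV", ns), 8L)
  fld(rep(-EDF_PHYS_MAX, ns), 8L)
  fld(rep(EDF_PHYS_MAX, ns), 8L)
  fld(rep(-EDF_DIG_MAX, ns), 8L)
  fld(rep(EDF_DIG_MAX, ns), 8L)
  fld(rep("", ns), 80L)
  fld(rep(round(fs), ns), 8L)
  fld(rep("", ns), 32L)
  dig <- round(rec$data / EDF_PHYS_MAX * EDF_DIG_MAX)
  storage.mode(dig) <- "integer"
  # records: for each second, all samples of signal 1, then signal 2, ...
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(dig[rows, , drop = FALSE]), con, size = 2L,
             endian = "little")
  }
  if (nrow(rec$annotations))
    utils::write.csv(rec$annotations, annotation_sidecar(path),
                     row.names = FALSE)
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Channel kinds are recovered from the transducer field when the file was
#' written by [write_edf()], otherwise inferred from labels (`LTh*`/`RTh*`
#' are DBS contacts, anything else scalp). A sidecar annotations CSV is
#' loaded when present.
#'
#' @param path Path to a 16-bit EDF file with a uniform sampling rate.
#' @return A [recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8L)
  if (!nzchar(version)) stopf("malformed EDF header in %s", path)
  patient_id <- rd(80L)
  rd(80L); rd(8L); rd(8L)                     # recording id, date, time
  rd(8L); rd(44L)                             # header bytes, reserved
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  if (is.na(ns) || ns < 1L) stopf("EDF file has no signals")
  rds <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rds(16L)
  transducer <- rds(80L)
  rds(8L)                                     # dimension
  phys_min <- as.numeric(rds(8L))
  phys_max <- as.numeric(rds(8L))
  dig_min <- as.numeric(rds(8L))
  dig_max <- as.numeric(rds(8L))
  rds(80L)                                    # prefiltering
  spr <- as.integer(rds(8L))
  rds(32L)
  if (length(unique(spr)) != 1L)
    stopf("mixed sampling rates are not supported")
  fs <- spr[1L] / rec_dur
  n <- n_rec * spr[1L]
  data <- matrix(0, nrow = n, ncol = ns)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, integer(), n = spr[1L] * ns, size = 2L,
                     endian = "little")
    rows <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    data[rows, ] <- matrix(block, ncol = ns)
  }
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (j in seq_len(ns))
    data[, j] <- phys_min[j] + (data[, j] - dig_min[j]) * scale[j]
  kind <- sub("^kind: ", "", transducer)
  infer <- !kind %in% c("scalp", "dbs-left", "dbs-right")
  kind[infer] <- ifelse(grepl("^LTh", labels[infer]), "dbs-left",
                 ifelse(grepl("^RTh", labels[infer]), "dbs-right", "scalp"))
  side_csv <- annotation_sidecar(path)
  ann <- if (file.exists(side_csv))
    utils::read.csv(side_csv, stringsAsFactors = FALSE) else NULL
  recording(data, fs, data.frame(label = labels, kind = kind),
            annotations = ann, patient_id = patient_id)
}
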