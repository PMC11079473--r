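#' Multichannel EEG/LFP recording
#'
#' Container for a scalp + DBS-lead recording: a samples-by-channels matrix
#' in microvolts, a channel table, state annotations, and a patient id.
#' Time is seconds from record start, samples are 0-based in external
#' interfaces, and annotation intervals are half-open `[start, end)`.
#'
#' @param data Numeric matrix, samples x channels, microvolts.
#' @param fs Sampling rate, Hz (all channels share it).
#' @param channels Data frame with columns `label` and `kind`
#'   (`"scalp"`, `"dbs-left"`, `"dbs-right"`).
#' @param annotations Data frame with columns `label`
#'   (`sleep` / `awake` / `seizure`), `start_s`, `end_s`. May be empty.
#' @param patient_id Identifier stored with the recording.
#' @return An object of class `recording`.
#' @export
recording <- function(data, fs, channels, annotations = NULL,
                      patient_id = "pt") {
  data <- as.matrix(data)
  if (ncol(data) == 0L) stopf("recording must have at least one channel")
  assert_scalar_num(fs, "fs", lower = 1e-9)
  if (!is.data.frame(channels) ||
      !all(c("label", "kind") %in% names(channels)))
    stopf("'channels' needs columns 'label' and 'kind'")
  if (nrow(channels) != ncol(data))
    stopf("channel table has %d rows but data has %d columns",
          nrow(channels), ncol(data))
  if (anyDuplicated(channels$label)) stopf("duplicate channel labels")
  bad <- setdiff(channels$kind, c("scalp", "dbs-left", "dbs-right"))
  if (length(bad)) stopf("unknown channel kind: %s", paste(bad, collapse = ", "))
  colnames(data) <- channels$label
  if (is.null(annotations))
    annotations <- data.frame(label = character(), start_s = numeric(),
                              end_s = numeric())
  dur <- nrow(data) / fs
  ann <- annotations[annotations$label != "seizure", , drop = FALSE]
  if (nrow(ann)) {
    if (any(ann$start_s < 0 | ann$end_s > dur + 1e-9))
      stopf("annotations extend beyond the %0.1f s record", dur)
    ss <- ann[order(ann$start_s), ]
    if (nrow(ss) > 1L && any(ss$start_s[-1L] < ss$end_s[-nrow(ss)] - 1e-9))
      stopf("sleep/awake annotations overlap")
  }
  structure(list(data = data, fs = fs, channels = channels,
                 annotations = annotations, patient_id = patient_id),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording '%s'>: %d channels x %.1f s @ %g Hz, %d annotations\n",
              x$patient_id, ncol(x$data), nrow(x$data) / x$fs, x$fs,
              nrow(x$annotations)))
  invisible(x)
}

#' @export
duration.recording <- function(x) nrow(x$data) / x$fs

#' Record duration in seconds
#' @param x A recording.
#' @export
duration <- function(x) UseMethod("duration")

channel_index <- function(rec, labels) {
  i <- match(labels, rec$channels$label)
  if (anyNA(i))
    stopf("channel(s) not in recording: %s",
          paste(labels[is.na(i)], collapse = ", "))
  i
}

# Channel labels of one DBS lead in depth order (contact 0 = deepest).
lead_channels <- function(rec, side = c("left", "right")) {
  side <- match.arg(side)
  kind <- paste0("dbs-", side)
  rec$channels$label[rec$channels$kind == kind]
}
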