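# Montage construction. A montage view carries the derivation table and the
# derived signals; phase reversal on adjacent bipolar DBS channels localizes
# a generator to the shared contact, while the monopolar view preserves
# absolute amplitude against the common reference.

# Canonical longitudinal scalp chains (10-20); chains are built from the
# channels actually present, skipping absent electrodes, since bandages
# usually force some of F3/F4/C3/C4 to be left out.
SCALP_CHAINS <- list(
  `left-parasagittal`  = c("Fp1", "F3", "C3", "P3", "O1"),
  `left-temporal`      = c("Fp1", "F7", "T3", "T5", "O1"),
  `right-parasagittal` = c("Fp2", "F4", "C4", "P4", "O2"),
  `right-temporal`     = c("Fp2", "F8", "T4", "T6", "O2"))

new_montage_view <- function(rec, derivations, mode) {
  i <- channel_index(rec, derivations$minuend)
  signals <- rec$data[, i, drop = FALSE]
  has_sub <- !is.na(derivations$subtrahend)
  if (any(has_sub)) {
    j <- channel_index(rec, derivations$subtrahend[has_sub])
    signals[, has_sub] <- signals[, has_sub, drop = FALSE] -
      rec$data[, j, drop = FALSE]
  }
  colnames(signals) <- derivations$name
  structure(list(derivations = derivations, signals = signals,
                 fs = rec$fs, mode = mode, patient_id = rec$patient_id,
                 cache = new.env(parent = emptyenv())),
            class = "montage_view")
}

#' @export
print.montage_view <- function(x, ...) {
  cat(sprintf("<%s montage>: %d derived channels @ %g Hz\n",
              x$mode, nrow(x$derivations), x$fs))
  invisible(x)
}

#' Build a bipolar montage
#'
#' `"dbs-adjacent"` derives the three adjacent-contact differences per lead
#' (0-1, 1-2, 2-3; contact 0 is the deepest). `"scalp-longitudinal"`
#' chains the available scalp electrodes along the standard longitudinal
#' runs. Each derived signal is minuend minus subtrahend, sample-wise.
#'
#' @param rec A [recording()].
#' @param scheme `"dbs-adjacent"` or `"scalp-longitudinal"`.
#' @return A `montage_view` with columns `name`, `minuend`, `subtrahend`,
#'   `side` in its derivation table.
#' @export
make_bipolar <- function(rec, scheme = c("dbs-adjacent", "scalp-longitudinal")) {
  scheme <- match.arg(scheme)
  if (scheme == "dbs-adjacent") {
    rows <- list()
    for (side in c("left", "right")) {
      ch <- lead_channels(rec, side)
      if (length(ch) == 0L) next
      if (length(ch) < 2L)
        stopf("%s lead has %d contact(s); bipolar needs at least 2",
              side, length(ch))
      k <- seq_len(length(ch) - 1L)
      rows[[side]] <- data.frame(
        name = paste0(ch[k], "-", ch[k + 1L]),
        minuend = ch[k], subtrahend = ch[k + 1L], side = side)
    }
    if (!length(rows)) stopf("recording has no DBS lead channels")
    der <- do.call(rbind, rows)
  } else {
    present <- rec$channels$label[rec$channels$kind == "scalp"]
    rows <- list()
    for (cn in names(SCALP_CHAINS)) {
      ch <- intersect(SCALP_CHAINS[[cn]], present)
      if (length(ch) < 2L) next
      k <- seq_len(length(ch) - 1L)
      rows[[cn]] <- data.frame(
        name = paste0(ch[k], "-", ch[k + 1L]),
        minuend = ch[k], subtrahend = ch[k + 1L],
        side = sub("-.*", "", cn))
    }
    if (!length(rows)) stopf("not enough scalp channels for a bipolar chain")
    der <- do.call(rbind, rows)
    der <- der[!duplicated(der$name), ]
  }
  rownames(der) <- NULL
  new_montage_view(rec, der, mode = "bipolar")
}

#' Build a monopolar (referential) montage
#'
#' @param rec A [recording()].
#' @param reference `"as-recorded"` (identity: channels stay referenced to
#'   the acquisition reference, e.g. extracranial G2) or the label of a
#'   channel to re-reference against.
#' @param kinds Channel kinds to include; defaults to the DBS leads.
#' @return A `montage_view`.
#' @export
make_monopolar <- function(rec, reference = "as-recorded",
                           kinds = c("dbs-left", "dbs-right")) {
  keep <- rec$channels$kind %in% kinds
  if (!any(keep)) stopf("no channels of kind %s", paste(kinds, collapse = "/"))
  lab <- rec$channels$label[keep]
  sub <- if (identical(reference, "as-recorded")) NA_character_ else {
    channel_index(rec, reference)  # errors if missing
    reference
  }
  der <- data.frame(
    name = lab, minuend = lab, subtrahend = sub,
    side = c(scalp = "scalp", `dbs-left` = "left", `dbs-right` = "right")[
      rec$channels$kind[keep]])
  rownames(der) <- NULL
  new_montage_view(rec, der, mode = "monopolar")
}

# Derived channels of one side of a view.
view_side <- function(view, side) {
  which(view$derivations$side == side)
}
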