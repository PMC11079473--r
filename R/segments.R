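#' Select analysis segments of a given vigilance state
#'
#' Picks the earliest intervals annotated with `state` totalling exactly
#' `minutes`, keeping every selected sample at least `seizure_gap_hours`
#' away from any seizure annotation. Intervals are half-open `[start, end)`
#' in seconds; the last one is trimmed so the total is exact. Selection is
#' earliest-first and therefore idempotent and order-stable.
#'
#' @param rec A [recording()] with state annotations.
#' @param state `"sleep"` or `"awake"`.
#' @param minutes Total duration to select (default 20).
#' @param seizure_gap_hours Minimum distance from seizures (default 2).
#' @return Data frame with `start_s`, `end_s`.
#' @export
select_segments <- function(rec, state = c("sleep", "awake"), minutes = 20,
                            seizure_gap_hours = 2) {
  state <- match.arg(state)
  assert_scalar_num(minutes, "minutes", lower = 1e-9)
  ann <- rec$annotations
  if (!nrow(ann)) stopf("recording has no annotations")
  iv <- ann[ann$label == state, c("start_s", "end_s"), drop = FALSE]
  if (!nrow(iv)) stopf("no '%s' annotations present", state)
  iv <- iv[order(iv$start_s), , drop = FALSE]
  gap <- seizure_gap_hours * 3600
  sz <- ann[ann$label == "seizure", , drop = FALSE]
  for (k in seq_len(nrow(sz))) {
    lo <- sz$start_s[k] - gap
    hi <- sz$end_s[k] + gap
    out <- list()
    for (r in seq_len(nrow(iv))) {
      s <- iv$start_s[r]; e <- iv$end_s[r]
      if (e <= lo || s >= hi) { out[[length(out) + 1L]] <- c(s, e); next }
      if (s < lo) out[[length(out) + 1L]] <- c(s, lo)
      if (e > hi) out[[length(out) + 1L]] <- c(hi, e)
    }
    iv <- if (length(out)) {
      m <- do.call(rbind, out)
      data.frame(start_s = m[, 1L], end_s = m[, 2L])
    } else iv[0L, , drop = FALSE]
  }
  need <- minutes * 60
  have <- if (nrow(iv)) sum(iv$end_s - iv$start_s) else 0
  if (have < need - 1e-9)
    stopf("only %.1f min of eligible '%s' data; %.1f min requested (short by %.1f min)",
          have / 60, state, minutes, (need - have) / 60)
  sel <- list()
  acc <- 0
  for (r in seq_len(nrow(iv))) {
    if (acc >= need - 1e-12) break
    len <- iv$end_s[r] - iv$start_s[r]
    take <- min(len, need - acc)
    sel[[length(sel) + 1L]] <- c(iv$start_s[r], iv$start_s[r] + take)
    acc <- acc + take
  }
  m <- do.call(rbind, sel)
  data.frame(start_s = m[, 1L], end_s = m[, 2L])
}

# Total minutes covered by a segment table.
segment_minutes <- function(segments) sum(segments$end_s - segments$start_s) / 60
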