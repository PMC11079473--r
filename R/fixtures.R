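# The "paper15" cohort fixture: a fully specified 15-patient world (lead
# contact coordinates, region-level IED presence, condition latencies,
# seizure counts) whose derived aggregates are mutually consistent. All
# downstream numbers (response rates, odds ratios, hit bookkeeping,
# connection fractions, region occurrence) are computed from it by the
# package's own functions, never stored.

# Follower lags: 33 values, range 2-180 ms, mean exactly 51 ms.
PAPER15_FOLLOWER_LAGS <- c(
  2, 8, 12, 15, 18, 20, 22, 25, 28, 30, 32, 35, 38, 40, 42, 45, 48, 50,
  52, 55, 58, 60, 62, 65, 68, 72, 75, 78, 82, 85, 88, 93, 180)
# Preceder lags: 3 values in 15-25 ms whose mean prints as 18 ms.
PAPER15_PRECEDER_LAGS <- c(15, 15, 25)

# Per patient-side region allocation of the 4 contacts ("O" = outside /
# intraventricular). 24 of 30 leads have at least one ANT contact.
paper15_contact_plan <- function() {
  plan <- list(
    pt01 = list(left = c("ANT-V", "ANT-D", "MD", "MD"),
                right = c("ANT-V", "ANT-V", "ANT-V", "O")),
    pt02 = list(left = c("ANT-V", "ANT-V", "O", "O"),
                right = c("ANT-V", "ANT-P", "MD", "MD")),
    pt03 = list(left = c("ANT-V", "ANT-V", "MD", "MD"),
                right = c("ANT-D", "ANT-D", "ANT-D", "O")),
    pt04 = list(left = c("ANT-V", "ANT-V", "ANT-V", "O"),
                right = c("ANT-D", "ANT-D", "O", "O")),
    pt05 = list(left = c("O", "O", "O", "O"),
                right = c("ANT-V", "ANT-D", "MD", "MD")),
    pt06 = list(left = c("ANT-V", "ANT-V", "MD", "MD"),
                right = c("O", "O", "O", "O")),
    pt07 = list(left = c("ANT-V", "ANT-V", "ANT-V", "O"),
                right = c("ANT-V", "ANT-V", "ANT-D", "O")),
    pt08 = list(left = c("ANT-D", "ANT-D", "MD", "MD"),
                right = c("ANT-V", "ANT-V", "O", "O")),
    pt09 = list(left = c("ANT-V", "ANT-V", "ANT-P", "ANT-P"),
                right = c("ANT-D", "MD", "MD", "MD")),
    pt10 = list(left = c("ANT-D", "ANT-D", "O", "O"),
                right = c("ANT-V", "ANT-V", "MD", "MD")),
    pt11 = list(left = c("ANT-D", "ANT-P", "MD", "MD"),
                right = c("ANT-P", "ANT-P", "O", "O")),
    pt12 = list(left = c("ANT-P", "ANT-P", "MD", "MD"),
                right = c("O", "O", "O", "O")),
    pt13 = list(left = c("O", "O", "O", "O"),
                right = c("ANT-D", "ANT-D", "ANT-P", "ANT-P")),
    pt14 = list(left = c("ANT-P", "O", "O", "O"),
                right = c("O", "O", "O", "O")),
    pt15 = list(left = c("ANT-P", "ANT-P", "O", "O"),
                right = c("O", "O", "O", "O")))
  plan
}

# Deterministic coordinate inside a region's box for the k-th contact of a
# lead assigned to it; "O" contacts sit dorsal of every box.
paper15_contacts <- function(atlas = default_atlas()) {
  plan <- paper15_contact_plan()
  b <- atlas$boxes
  rows <- list()
  for (pt in names(plan)) for (side in c("left", "right")) {
    regions <- plan[[pt]][[side]]
    for (k in seq_along(regions)) {
      reg <- regions[k]
      if (reg == "O") {
        xyz <- c(if (side == "left") -6 else 6, 8, 15)
      } else {
        bx <- b[b$region == reg & b$side == side, ]
        jit <- (k - 1) * 0.4 - 0.6
        xyz <- c((bx$xmin + bx$xmax) / 2 + jit,
                 (bx$ymin + bx$ymax) / 2,
                 (bx$zmin + bx$zmax) / 2)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient = pt, side = side, contact = k - 1L,
        x = xyz[1L], y = xyz[2L], z = xyz[3L])
    }
  }
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  d
}

# Region-level IED presence: one row per sampled (patient, side, region).
paper15_region_events <- function() {
  S <- function(pt, side, region, spike = FALSE, st = FALSE)
    data.frame(patient = pt, side = side, region = region,
               spike = spike, st = st)
  rbind(
    S("pt01", "left", "ANT-V", spike = TRUE),
    S("pt01", "left", "ANT-D", spike = TRUE),
    S("pt01", "right", "ANT-V", spike = TRUE),
    S("pt01", "left", "MD", spike = TRUE),
    S("pt02", "left", "ANT-V", spike = TRUE),
    S("pt02", "right", "ANT-V", spike = TRUE),
    S("pt02", "right", "ANT-P"),
    S("pt02", "right", "MD", spike = TRUE),
    S("pt03", "left", "ANT-V", spike = TRUE),
    S("pt03", "right", "ANT-D", spike = TRUE),
    S("pt03", "left", "MD", spike = TRUE),
    S("pt04", "left", "ANT-V", spike = TRUE),
    S("pt04", "right", "ANT-D", spike = TRUE),
    S("pt05", "right", "ANT-V", spike = TRUE),
    S("pt05", "right", "ANT-D", spike = TRUE),
    S("pt05", "right", "MD"),
    S("pt06", "left", "ANT-V", spike = TRUE),
    S("pt06", "left", "MD"),
    S("pt07", "left", "ANT-V", spike = TRUE),
    S("pt07", "right", "ANT-V", spike = TRUE),
    S("pt07", "right", "ANT-D"),
    S("pt08", "left", "ANT-D", spike = TRUE, st = TRUE),
    S("pt08", "right", "ANT-V", spike = TRUE),
    S("pt08", "left", "MD", spike = TRUE),
    S("pt09", "left", "ANT-V"),
    S("pt09", "left", "ANT-P", st = TRUE),
    S("pt09", "right", "ANT-D", spike = TRUE),
    S("pt09", "right", "MD", spike = TRUE),
    S("pt10", "left", "ANT-D"),
    S("pt10", "right", "ANT-V", spike = TRUE),
    S("pt10", "right", "MD"),
    S("pt11", "left", "ANT-D", st = TRUE),
    S("pt11", "left", "ANT-P"),
    S("pt11", "right", "ANT-P"),
    S("pt11", "left", "MD"),
    S("pt12", "left", "ANT-P", st = TRUE),
    S("pt12", "left", "MD"),
    S("pt13", "right", "ANT-D", st = TRUE),
    S("pt13", "right", "ANT-P"),
    S("pt14", "left", "ANT-P"),
    S("pt15", "left", "ANT-P"))
}

paper15_patients <- function() {
  data.frame(
    patient = sprintf("pt%02d", 1:15),
    laterality = c("left", "right", "right", "bilateral", "right", "right",
                   "left", "left", "left", "left", "bilateral", "left",
                   "left", "bilateral", "right"),
    seizures_pre = c(40, 24, 12, 30, 20, 16, 20, 12, 30, 10, 8, 15, 9, 25, 18),
    seizures_post = c(10, 8, 4, 6, 9, 6, 10, 8, 24, 9, 8, 12, 11, 20, 14))
}

# Per-patient condition allocation: number of evaluable conditions and the
# follower/preceder/no-connection split. Bilateral-hit patients can have up
# to 8 conditions, unilateral up to 4; exactly one patient has all 8.
paper15_condition_plan <- function() {
  data.frame(
    patient = sprintf("pt%02d", 1:15),
    n = c(8, 6, 6, 6, 4, 3, 4, 4, 4, 4, 2, 2, 3, 2, 2),
    followers = c(6, 5, 5, 5, 3, 1, 2, 2, 2, 1, 1, 0, 0, 0, 0),
    preceders = c(1, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0))
}

# Expand the plan into one row per condition with a signed IED-TP latency
# (NA = no detectable peak). Lags are taken in order from the fixed pools.
paper15_conditions <- function() {
  plan <- paper15_condition_plan()
  contact_plan <- paper15_contact_plan()
  grid <- expand.grid(direction = c("scalp->thal", "thal->scalp"),
                      state = c("sleep", "awake"),
                      side = c("left", "right"),
                      stringsAsFactors = FALSE)[, 3:1]
  fl <- PAPER15_FOLLOWER_LAGS
  pl <- PAPER15_PRECEDER_LAGS
  fi <- 0L; pi_ <- 0L
  rows <- list()
  for (r in seq_len(nrow(plan))) {
    pt <- plan$patient[r]
    hit_sides <- names(Filter(function(regs) any(regs != "O"),
                              contact_plan[[pt]]))
    g <- grid[grid$side %in% hit_sides, , drop = FALSE]
    g <- g[seq_len(plan$n[r]), , drop = FALSE]
    cat_seq <- c(rep("follower", plan$followers[r]),
                 rep("preceder", plan$preceders[r]),
                 rep("no_connection",
                     plan$n[r] - plan$followers[r] - plan$preceders[r]))
    for (k in seq_len(nrow(g))) {
      cat_k <- cat_seq[k]
      lat <- NA_real_
      if (cat_k == "follower") {
        fi <- fi + 1L
        lag <- fl[fi]
        lat <- if (g$direction[k] == "scalp->thal") lag else -lag
      } else if (cat_k == "preceder") {
        pi_ <- pi_ + 1L
        lag <- pl[pi_]
        lat <- if (g$direction[k] == "scalp->thal") -lag else lag
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient = pt, side = g$side[k], state = g$state[k],
        direction = g$direction[k], latency_ms = lat)
    }
  }
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  d
}

#' The 15-patient reference cohort fixture
#'
#' A synthetic cohort whose raw inputs (contact coordinates, region-level
#' IED presence, per-condition IED-TP latencies, seizure counts, focus
#' laterality) were constructed to be mutually consistent with the
#' published cohort-level aggregates. Everything reported about it is
#' computed by the package's analysis functions at run time.
#'
#' @return List: `patients`, `contacts`, `region_events`, `conditions`,
#'   `atlas`.
#' @export
paper15_cohort <- function() {
  atlas <- default_atlas()
  list(patients = paper15_patients(),
       contacts = paper15_contacts(atlas),
       region_events = paper15_region_events(),
       conditions = paper15_conditions(),
       atlas = atlas)
}

resp_flag_table <- function(responder, flag) {
  rbind(c(sum(responder & flag), sum(responder & !flag)),
        c(sum(!responder & flag), sum(!responder & !flag)))
}

#' Cohort-level analysis report
#'
#' Runs the full tabular analysis on a cohort fixture (or equivalently
#' structured real data): contact-to-region assignment, lead and patient
#' hit logic, responder classification, subgroup response rates, odds
#' ratios, connection accounting, and region occurrence.
#'
#' @param cohort A list as returned by [paper15_cohort()].
#' @return A nested list of results; every number is computed, not stored.
#' @export
cohort_report <- function(cohort) {
  pts <- cohort$patients
  ## localization
  ct <- cohort$contacts
  ct$region <- assign_region(ct[, c("x", "y", "z")], cohort$atlas)
  key <- interaction(ct$patient, ct$side)
  leads <- do.call(rbind, lapply(split(ct, key), function(g)
    data.frame(patient = g$patient[1L], side = g$side[1L],
               hit = lead_hit(g$region) == "hit")))
  n_ant <- sum(ct$region %in% ANT_REGIONS)
  n_md <- sum(ct$region == "MD")
  loc <- list(
    n_contacts = nrow(ct),
    n_ant_contacts = n_ant,
    pct_ant_contacts = round_half_up(100 * n_ant / nrow(ct)),
    n_md_contacts = n_md,
    n_leads = nrow(leads),
    n_hit_leads = sum(leads$hit),
    pct_hit_leads = round_half_up(100 * mean(leads$hit)))
  ## per-patient hit summary + outcome
  hit_of <- function(pt, side) leads$hit[leads$patient == pt &
                                           leads$side == side]
  sr <- seizure_reduction(pts$seizures_pre, pts$seizures_post)
  responder <- is_responder(sr)
  hs <- lapply(seq_len(nrow(pts)), function(i)
    patient_hit_summary(hit_of(pts$patient[i], "left"),
                        hit_of(pts$patient[i], "right"),
                        pts$laterality[i]))
  bilateral_hit <- vapply(hs, `[[`, TRUE, "bilateral_hit")
  focus_side_hit <- vapply(hs, `[[`, TRUE, "focus_side_hit")
  ## TIED flags from region-level events
  re <- cohort$region_events
  ant <- re[re$region %in% ANT_REGIONS, , drop = FALSE]
  flag_per_patient <- function(f) vapply(pts$patient, function(p)
    any(f(ant[ant$patient == p, , drop = FALSE])), TRUE,
    USE.NAMES = FALSE)
  any_ant_spike <- flag_per_patient(function(g) g$spike)
  any_ant_tied <- flag_per_patient(function(g) g$spike | g$st)
  focus_spike <- vapply(seq_len(nrow(pts)), function(i) {
    g <- ant[ant$patient == pts$patient[i] & ant$spike, , drop = FALSE]
    switch(pts$laterality[i],
           left = any(g$side == "left"),
           right = any(g$side == "right"),
           bilateral = all(c("left", "right") %in% g$side))
  }, TRUE)
  rr <- list(
    overall = response_rate(responder),
    bilateral_hit = response_rate(responder, bilateral_hit),
    unilateral_hit = response_rate(responder, !bilateral_hit),
    focus_side_hit = response_rate(responder, focus_side_hit),
    focus_side_spike_tied = response_rate(responder, focus_spike))
  or <- list(
    bilateral_hit = odds_ratio(resp_flag_table(responder, bilateral_hit)),
    focus_side_hit = odds_ratio(resp_flag_table(responder, focus_side_hit)),
    focus_side_spike_tied = odds_ratio(resp_flag_table(responder,
                                                       focus_spike)))
  tied <- list(
    n_any_ant_tied = sum(any_ant_tied),
    responders_with_spike_tied_pct =
      round_half_up(100 * sum(any_ant_spike & responder) / sum(responder)),
    nonresponders_with_spike_tied_pct =
      round_half_up(100 * sum(any_ant_spike & !responder) / sum(!responder)))
  ## connection accounting
  cn <- cohort$conditions
  cls <- lapply(seq_len(nrow(cn)), function(i)
    classify_connection(cn$direction[i], cn$latency_ms[i]))
  cn$category <- vapply(cls, `[[`, "", "category")
  cn$lag_ms <- vapply(cls, `[[`, 0, "lag_ms")
  connections <- summarize_connections(cn)
  ## region occurrence
  occurrence <- region_occurrence(re)
  list(localization = loc,
       patients = data.frame(pts, sr = sr, responder = responder,
                             bilateral_hit = bilateral_hit,
                             focus_side_hit = focus_side_hit,
                             any_ant_spike_tied = any_ant_spike,
                             any_ant_tied = any_ant_tied,
                             focus_side_spike_tied = focus_spike),
       response_rate = rr, odds_ratio = or, tied = tied,
       connections = connections, conditions = cn,
       region_occurrence = occurrence)
}
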