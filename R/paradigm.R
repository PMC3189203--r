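#' Ultimatum-game offer types
#'
#' The five proposer:responder splits used in the repeated ultimatum game,
#' written as the percentage of the stake retained by the proposer versus
#' offered to the responder ("50:50" ... "90:10").
#'
#' @param label Character vector of offer labels, e.g. `"80:20"`.
#' @return A data frame with columns `label`, `proposer_share`,
#'   `responder_share` (fractions summing to 1 per row).
#' @examples
#' offer_type(c("50:50", "90:10"))
#' @export
offer_type <- function(label) {
  label <- as.character(label)
  parts <- strsplit(label, ":", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    stop("unknown offer label(s): ", paste(label[bad], collapse = ", "))
  }
  prop <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L))) / 100
  resp <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L))) / 100
  ok <- is.finite(prop) & is.finite(resp) & prop > 0 & prop <= 1 &
    abs(prop + resp - 1) < 1e-9
  if (!all(ok)) {
    stop("unknown offer label(s): ", paste(label[!ok], collapse = ", "))
  }
  data.frame(label = label, proposer_share = prop, responder_share = resp,
             stringsAsFactors = FALSE)
}

#' Default offer composition of a 60-trial session
#'
#' Number of trials per offer type in one session: 6 even splits (50:50),
#' 8 of 65:35, 12 of 70:30, 21 of 80:20 and 13 of 90:10.
#'
#' @return Named integer vector of per-type trial counts.
#' @export
default_offer_counts <- function() {
  c("50:50" = 6L, "65:35" = 8L, "70:30" = 12L, "80:20" = 21L, "90:10" = 13L)
}

#' Trial phase durations in seconds
#'
#' Each 22 s trial shows the stake amount (2 s), the offer (12 s), the
#' response screen (4 s) and the payoff (4 s). The offer therefore appears
#' 2 s after trial onset, which is the reference point for all scan
#' indexing downstream.
#'
#' @return Named numeric vector `c(amount, offer, response, payoff)`.
#' @export
trial_phase_durations <- function() {
  c(amount = 2, offer = 12, response = 4, payoff = 4)
}

#' Build a randomized ultimatum-game offer schedule
#'
#' Draws a deterministic (seeded) uniform shuffle of the configured offer
#' types and lays trials out back-to-back at 22 s spacing. Decisions are
#' left `NA` ("pending") until simulated or observed.
#'
#' @param counts Named integer vector mapping offer labels to trial counts;
#'   defaults to [default_offer_counts()].
#' @param seed Integer seed for the shuffle.
#' @param stake_euros Stake split in every trial (euros).
#' @return A data frame of class `ug_schedule` with one row per trial:
#'   `trial_index`, `onset_s`, `offer_label`, `proposer_share`,
#'   `responder_share`, `decision` (NA until set), `payoff_responder`.
#'   Attributes `stake_euros` and `phase_durations_s` carry the session
#'   constants.
#' @examples
#' sched <- build_offer_schedule(seed = 7)
#' table(sched$offer_label)
#' @export
build_offer_schedule <- function(counts = default_offer_counts(), seed = 1L,
                                 stake_euros = 3) {
  if (length(counts) && (is.null(names(counts)) || any(!nzchar(names(counts)))))
    stop("'counts' must be a named vector of offer labels")
  if (any(unlist(counts) < 0)) stop("offer counts must be nonnegative")
  counts <- counts[counts > 0]
  labels <- rep(names(counts), times = as.integer(counts))
  if (length(labels)) {
    types <- offer_type(names(counts))  # validates labels
    rng <- local_rng(seed)
    labels <- labels[sample.int(length(labels))]
    rng()
  }
  info <- if (length(labels)) offer_type(labels) else
    data.frame(label = character(), proposer_share = numeric(),
               responder_share = numeric())
  n <- length(labels)
  sched <- data.frame(
    trial_index = seq_len(n),
    onset_s = (seq_len(n) - 1) * sum(trial_phase_durations()),
    offer_label = info$label,
    proposer_share = info$proposer_share,
    responder_share = info$responder_share,
    decision = rep(NA_integer_, n),
    payoff_responder = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
  attr(sched, "stake_euros") <- stake_euros
  attr(sched, "phase_durations_s") <- trial_phase_durations()
  class(sched) <- c("ug_schedule", "data.frame")
  sched
}

# Seed the session RNG locally and restore the caller's RNG state on the
# returned function's invocation. Keeps package randomness insulated from
# user scripts.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}

#' Responder payoff of a revealed trial
#'
#' An accepted offer pays the responder their share of the stake; a rejected
#' offer pays nothing to either player.
#'
#' @param responder_share Fraction of the stake offered to the responder.
#' @param decision 1 (accept) or 0 (reject); `NA` is an error (pending).
#' @param stake_euros Stake (euros), default 3.
#' @return Payoff in euros.
#' @examples
#' responder_payoff(0.10, decision = 1)  # 0.30
#' responder_payoff(0.50, decision = 0)  # 0
#' @export
responder_payoff <- function(responder_share, decision, stake_euros = 3) {
  if (any(is.na(decision))) stop("decision still pending; payoff undefined")
  if (!all(decision %in% c(0, 1))) stop("decision must be 0 (reject) or 1 (accept)")
  ifelse(decision == 1, responder_share * stake_euros, 0)
}

#' Logistic responder behavior parameters
#'
#' Two-parameter logistic acceptance model in the responder's share:
#' P(accept) = logistic((responder_share - threshold_share) * slope).
#' Defaults place the 50% point at a 25% share with a steep slope, giving
#' near-certain acceptance of even splits and a sharp drop in acceptance
#' between the 70:30 and 80:20 offers, the categorical border seen in
#' repeated ultimatum-game behavior.
#'
#' @param threshold_share Responder share at which acceptance is 50%.
#' @param slope Logistic steepness (per unit share); must be >= 0.
#' @return List of class `ug_behavior`.
#' @export
behavior_params <- function(threshold_share = 0.25, slope = 30) {
  if (slope < 0) stop("slope must be >= 0")
  structure(list(threshold_share = threshold_share, slope = slope),
            class = "ug_behavior")
}

#' Acceptance probability of the logistic responder
#'
#' @param responder_share Fraction(s) offered to the responder.
#' @param params A [behavior_params()] object.
#' @return Probability of acceptance in `[0, 1]`.
#' @export
acceptance_probability <- function(responder_share, params = behavior_params()) {
  stats::plogis((responder_share - params$threshold_share) * params$slope)
}

#' Simulate responder decisions for a schedule
#'
#' Draws Bernoulli accept/reject decisions from the logistic behavior model
#' and fills in payoffs.
#'
#' @param schedule A `ug_schedule`.
#' @param params A [behavior_params()] object.
#' @param seed Integer seed.
#' @return The schedule with `decision` (1 accept / 0 reject) and
#'   `payoff_responder` filled in.
#' @export
simulate_decisions <- function(schedule, params = behavior_params(), seed = 1L) {
  restore <- local_rng(seed)
  on.exit(restore())
  p <- acceptance_probability(schedule$responder_share, params)
  schedule$decision <- as.integer(stats::runif(nrow(schedule)) < p)
  schedule$payoff_responder <- responder_payoff(
    schedule$responder_share, schedule$decision, attr(schedule, "stake_euros"))
  schedule
}

#' Write / read session event tables
#'
#' Events are exchanged as plain tab-separated text with columns
#' `onset`, `duration`, `trial_index`, `offer_label`, `decision`, `payoff`,
#' one file per session.
#'
#' @param schedule A `ug_schedule`.
#' @param path File path for the TSV.
#' @return `write_events` returns `path` invisibly; `read_events` returns a
#'   `ug_schedule`.
#' @export
write_events <- function(schedule, path) {
  out <- data.frame(
    onset = schedule$onset_s,
    duration = sum(trial_phase_durations()),
    trial_index = schedule$trial_index,
    offer_label = schedule$offer_label,
    decision = schedule$decision,
    payoff = schedule$payoff_responder
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "n/a")
  invisible(path)
}

#' @rdname write_events
#' @param stake_euros Stake used when reconstructing the schedule.
#' @export
read_events <- function(path, stake_euros = 3) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
                           stringsAsFactors = FALSE)
  info <- offer_type(tab$offer_label)
  sched <- data.frame(
    trial_index = as.integer(tab$trial_index),
    onset_s = as.numeric(tab$onset),
    offer_label = info$label,
    proposer_share = info$proposer_share,
    responder_share = info$responder_share,
    decision = as.integer(tab$decision),
    stringsAsFactors = FALSE
  )
  sched$payoff_responder <- as.numeric(tab$payoff)
  attr(sched, "stake_euros") <- stake_euros
  attr(sched, "phase_durations_s") <- trial_phase_durations()
  class(sched) <- c("ug_schedule", "data.frame")
  sched
}
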