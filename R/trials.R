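#' Parse a behavioral event log into a trial table
#'
#' Trials are delimited by Home-well triggers: a trial starts when the
#' subject triggers H and receives the Home reward (which turns the cue on),
#' runs outbound to the last Goal-well trigger, and the inbound leg runs
#' from that last Goal trigger back to the next Home trigger. The decision
#' is the branch of the first triggered Goal well; a trial is correct when
#' the decision matches the cued branch (LC -> left / G3-G4, RC -> right /
#' G1-G2), and rewarded iff correct. Switch trials are those whose cue
#' differs from the previous trial's cue.
#'
#' Exclusions: trials with goal triggers on both branches ("change of mind"
#' trajectories, which are neither cleanly correct nor incorrect) and trials
#' with no cue or no goal trigger are marked `excluded` with a reason but
#' kept in the table; a trailing partial trial (no terminating Home trigger)
#' is dropped with a warning.
#'
#' @param events data.frame with columns t, kind, payload (see
#'   [session_data()])
#' @return data.frame with one row per trial: trial_id, cue, decision,
#'   correct, rewarded, switch, goal_well, t_out0, t_out1, t_in0, t_in1,
#'   excluded, reason
#' @export
parse_trials <- function(events) {
  stopifnot(is.data.frame(events), all(c("t", "kind", "payload") %in%
                                         names(events)))
  if (is.unsorted(events$t)) stop("parse_trials: event log not time-ordered")
  ht <- which(events$kind == "well_trigger" & events$payload == "H")
  if (length(ht) < 2) {
    warning("parse_trials: fewer than two Home triggers; no complete trial")
    return(empty_trial_table())
  }
  n <- length(ht) - 1L
  out <- empty_trial_table(n)
  for (i in seq_len(n)) {
    idx <- (ht[i] + 1L):(ht[i + 1L] - 1L)
    ev <- events[idx, , drop = FALSE]
    t_start <- events$t[ht[i]]
    t_end <- events$t[ht[i + 1L]]
    out$trial_id[i] <- i
    cue_ev <- ev[ev$kind == "cue_on", , drop = FALSE]
    goal_ev <- ev[ev$kind == "well_trigger" &
                    ev$payload %in% c("G1", "G2", "G3", "G4"), , drop = FALSE]
    if (nrow(cue_ev) == 0) {
      out$excluded[i] <- TRUE
      out$reason[i] <- "no_cue"
      next
    }
    out$cue[i] <- cue_ev$payload[1]
    if (nrow(goal_ev) == 0) {
      out$excluded[i] <- TRUE
      out$reason[i] <- "no_goal_trigger"
      next
    }
    branches <- unique(goal_branch(goal_ev$payload))
    out$decision[i] <- goal_branch(goal_ev$payload[1])
    out$goal_well[i] <- goal_ev$payload[1]
    t_last_goal <- goal_ev$t[nrow(goal_ev)]
    out$t_out0[i] <- t_start
    out$t_out1[i] <- t_last_goal
    out$t_in0[i] <- t_last_goal
    out$t_in1[i] <- t_end
    cued_branch <- if (out$cue[i] == "LC") "L" else "R"
    out$correct[i] <- out$decision[i] == cued_branch
    out$rewarded[i] <- out$correct[i]
    if (length(branches) > 1) {
      out$excluded[i] <- TRUE
      out$reason[i] <- "change_of_mind"
    }
  }
  # trailing events after the last H trigger form an unfinished trial
  if (ht[length(ht)] < nrow(events) &&
      any(events$kind[(ht[length(ht)] + 1L):nrow(events)] == "cue_on")) {
    warning("parse_trials: dropping unfinished trailing trial")
  }
  out$switch <- c(FALSE, out$cue[-1] != out$cue[-n])
  out$switch[is.na(out$switch)] <- FALSE
  out
}

empty_trial_table <- function(n = 0) {
  data.frame(trial_id = rep(NA_integer_, n), cue = rep(NA_character_, n),
             decision = rep(NA_character_, n), correct = rep(NA, n),
             rewarded = rep(NA, n), switch = rep(FALSE, n),
             goal_well = rep(NA_character_, n),
             t_out0 = rep(NA_real_, n), t_out1 = rep(NA_real_, n),
             t_in0 = rep(NA_real_, n), t_in1 = rep(NA_real_, n),
             excluded = rep(FALSE, n), reason = rep(NA_character_, n),
             stringsAsFactors = FALSE)
}

#' Session-level task performance
#'
#' Fraction of correct decisions among non-excluded trials (p_se), overall
#' and restricted to switch trials (cue different from the previous trial).
#'
#' @param trials a trial table from [parse_trials()]
#' @return list with p_se, n_trials, p_switch, n_switch
#' @export
session_performance <- function(trials) {
  use <- trials[!trials$excluded & !is.na(trials$correct), , drop = FALSE]
  if (nrow(use) == 0) stop("session_performance: no usable trials")
  sw <- use[use$switch, , drop = FALSE]
  list(p_se = mean(use$correct),
       n_trials = nrow(use),
       p_switch = if (nrow(sw)) mean(sw$correct) else NA_real_,
       n_switch = nrow(sw))
}
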