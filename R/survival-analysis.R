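#' Kaplan-Meier curve of ongoing pregnancy
#'
#' Product-limit estimate of the probability that a pregnancy is still
#' ongoing at each gestational week, fitted through the survival package.
#' With no censoring (the default: every pregnancy ends in an observed
#' delivery) this equals one minus the empirical CDF of delivery times.
#'
#' @param time Gestational age at delivery (weeks), one per participant.
#' @param event Event indicators (default all 1; a censoring flag is
#'   retained for generality).
#' @return Data frame with `time`, `survival`, `at_risk`, `n_event`.
#' @export
km_estimate <- function(time, event = rep(1L, length(time))) {
  stop_if_not(length(time) >= 1 && sum(event) >= 1,
              "at least one observed event is required")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, survival = fit$surv, at_risk = fit$n.risk,
             n_event = fit$n.event)
}

#' Log-rank test between two predicted risk groups
#'
#' Chi-square statistic `(O1 - E1)^2 / V` with hypergeometric variance
#' accumulated over distinct event times (survival::survdiff), compared to
#' the upper tail of chi-square with 1 df.
#'
#' @param time Event times.
#' @param group Two-level group labels (e.g. `"high"`/`"low"`).
#' @param event Event indicators (default all 1).
#' @return List with `statistic`, `df`, `p`.
#' @export
log_rank <- function(time, group, event = rep(1L, length(time))) {
  group <- as.character(group)
  lev <- unique(group)
  stop_if_not(length(lev) == 2, "exactly two groups required")
  for (g in lev) {
    stop_if_not(sum(event[group == g]) >= 1,
                "group '%s' has no observed events", g)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- unname(sd$chisq)
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Difference in median gestational age at delivery between risk groups
#'
#' @param time Delivery times (weeks).
#' @param group Labels `"high"`/`"low"` per participant.
#' @return Low-group median minus high-group median, in weeks (positive when
#'   high-risk pregnancies deliver earlier).
#' @export
median_delivery_gap <- function(time, group) {
  group <- as.character(group)
  stop_if_not(any(group == "high") && any(group == "low"),
              "both risk groups must be non-empty")
  stats::median(time[group == "low"]) - stats::median(time[group == "high"])
}

#' Per-participant risk groups for survival analysis
#'
#' Classifies each participant by the risk class of their earliest
#' qualifying sample (gestational age at draw at most `ga_max` weeks by
#' default) under the transferred threshold, and joins the delivery time.
#'
#' @param samples Scored sample table with columns `participant_id`,
#'   `ga_sample_wk` and `score`.
#' @param participants Participant table with `ga_delivery_wk`.
#' @param model Threshold model for classification.
#' @param ga_max Latest qualifying sampling GA (default 24 weeks).
#' @return Data frame with `participant_id`, `group` (outcome),
#'   `risk_group`, `ga_delivery_wk`.
#' @export
survival_risk_groups <- function(samples, participants, model, ga_max = 24) {
  s <- samples[samples$ga_sample_wk <= ga_max & !is.na(samples$score), ,
               drop = FALSE]
  s <- s[order(s$participant_id, s$ga_sample_wk), ]
  first <- s[!duplicated(s$participant_id), ]
  risk <- apply_threshold(first$score, model)
  idx <- match(first$participant_id, participants$participant_id)
  data.frame(participant_id = first$participant_id,
             group = participants$group[idx],
             risk_group = risk,
             ga_delivery_wk = participants$ga_delivery_wk[idx],
             stringsAsFactors = FALSE)
}
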