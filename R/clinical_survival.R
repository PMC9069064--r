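# Responder dichotomisation and progression-free-survival comparisons.

#' Classify responders by a PFS cutoff
#'
#' Responder ("R") iff progression-free survival strictly exceeds the
#' cutoff (default 3 months). Patients censored at or before the cutoff are
#' indeterminate (`NA`); a patient censored beyond the cutoff already has
#' PFS beyond it and is a responder.
#'
#' @param pfsMonths positive PFS times in months.
#' @param events logical event indicators (TRUE = progression observed);
#'   default all TRUE.
#' @param cutoff months (default 3).
#' @return character vector in \{"R", "NR", NA\}.
#' @examples
#' classifyResponders(c(3.5, 3.0, 2.0), c(TRUE, TRUE, FALSE))
#' @export
classifyResponders <- function(pfsMonths, events = NULL, cutoff = 3) {
  if (any(pfsMonths <= 0, na.rm = TRUE)) stop("pfs_months must be > 0")
  if (is.null(events)) events <- rep(TRUE, length(pfsMonths))
  out <- ifelse(pfsMonths > cutoff, "R",
                ifelse(events, "NR", NA_character_))
  out[is.na(pfsMonths)] <- NA_character_
  out
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate via [survival::survfit()]; censored subjects
#' leave the risk set without producing a step, and ties at an event time
#' follow the standard convention (events before censorings).
#'
#' @param times positive event/censoring times.
#' @param events logical event indicators.
#' @return data.frame with columns `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`.
#' @export
kmEstimate <- function(times, events) {
  if (any(times <= 0)) stop("times must be > 0")
  stopifnot(length(times) == length(events))
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square (1 df) via [survival::survdiff()].
#'
#' @param times positive times.
#' @param events logical event indicators.
#' @param groups two-level group labels; each group needs >= 1 event.
#' @return list with `chi2` and `p`.
#' @export
logrankTest <- function(times, events, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2L) stop("exactly 2 groups required")
  if (any(tapply(as.integer(events), groups, sum) < 1L))
    stop("each group needs >= 1 event")
  sd <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ groups)
  chi2 <- sd$chisq
  list(chi2 = unname(chi2), p = stats::pchisq(unname(chi2), df = 1L,
                                              lower.tail = FALSE))
}

#' Clinical strata for survival comparison
#'
#' Builds the stratification factors used for PFS curve comparisons:
#' antibiotics exposure, tumour mutational burden dichotomised at
#' 5.6 mutations/Mb, HLA-E level, and the four-way TMB x HLA-E combination.
#'
#' @param meta per-patient or per-sample metadata data.frame (or an
#'   [ICTCohort-class]); one row per patient is used.
#' @param tmbCut TMB cutpoint (default 5.6).
#' @return data.frame with columns `patient_id`, `pfs_months`, `pfs_event`,
#'   `atb` ("ATB"/"noATB"), `tmb` ("TMBhigh"/"TMBlow"), `hla_e`
#'   ("HLAEhigh"/"HLAElow") and `tmb_hla` (four-level interaction).
#' @export
survivalStrata <- function(meta, tmbCut = 5.6) {
  if (is(meta, "ICTCohort")) meta <- sampleMeta(meta)
  pat <- meta[!duplicated(meta$patient_id), ]
  tmb <- ifelse(pat$tmb > tmbCut, "TMBhigh", "TMBlow")
  hla <- ifelse(pat$hla_e == "high", "HLAEhigh", "HLAElow")
  data.frame(patient_id = pat$patient_id,
             pfs_months = pat$pfs_months, pfs_event = pat$pfs_event,
             atb = ifelse(pat$atb, "ATB", "noATB"),
             tmb = tmb, hla_e = hla,
             tmb_hla = paste(tmb, hla, sep = "."),
             stringsAsFactors = FALSE)
}
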