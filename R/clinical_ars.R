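#' Change rate of a symptom subscale score
#'
#' The relative improvement of a DIBS subscale from its most severe point:
#' `(S_max - S_pre) / S_max`, where `S_max` is the subscale score at the
#' most severe point of the illness and `S_pre` the score three months
#' before death. Undefined (`NA`) when `S_max` is 0. A record whose score
#' worsened after the recorded maximum yields a negative change rate; it is
#' retained and flagged rather than clipped.
#'
#' @param s_max,s_pre Subscale scores (non-negative; vectorized).
#' @return Change rate in `(-Inf, 1]`, `NA` where `S_max = 0`.
#' @export
change_rate <- function(s_max, s_pre) {
  out <- (s_max - s_pre) / s_max
  out[!is.na(s_max) & s_max == 0] <- NA_real_
  out
}

#' Antipsychotic responsiveness score
#'
#' The ratio of the change rate of a DIBS subscale score to the daily
#' chlorpromazine-equivalent dose three months before death (units:
#' improvement fraction per mg/day). Undefined when the dose is 0 (patient
#' off antipsychotics) or missing.
#'
#' @param change_rate Dimensionless improvement fraction.
#' @param cpeq Daily CP-eq dose in mg/day (vectorized).
#' @return ARS values; `NA` where `cpeq <= 0`.
#' @export
ars <- function(change_rate, cpeq) {
  out <- change_rate / cpeq
  out[!is.na(cpeq) & cpeq <= 0] <- NA_real_
  out
}

#' Build the per-patient antipsychotic responsiveness table
#'
#' Computes change rates and ARS for the positive, negative and general
#' psychopathology subscales of every record, flagging per-subscale
#' exclusions (zero most-severe score, zero/missing dose, missing fields)
#' without dropping the other subscales of the same patient.
#'
#' @param records Clinical data frame with columns `patient_id`, `cpeq_3mo`
#'   and `dibs_{pos,neg,gen}_{max,3mo}` (see [simulate_clinical()]).
#' @return Data frame with per-subscale change rates (`cr_pos, cr_neg,
#'   cr_gen`), ARS values (`ars_pos, ars_neg, ars_gen`) and exclusion
#'   reasons; attribute `"n_evaluable"` gives the per-subscale count of
#'   non-missing ARS values.
#' @export
build_ars_table <- function(records) {
  need <- c("patient_id", "cpeq_3mo",
            paste0("dibs_", rep(c("pos", "neg", "gen"), each = 2),
                   c("_max", "_3mo")))
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop_nddprs("clinical records lack column(s): ",
                paste(missing_cols, collapse = ", "),
                class = "nddprs_validation_error")
  if (nrow(records) == 0) {
    out <- data.frame(patient_id = character(0))
    attr(out, "n_evaluable") <- c(pos = 0L, neg = 0L, gen = 0L)
    return(out)
  }
  out <- data.frame(patient_id = records$patient_id,
                    stringsAsFactors = FALSE)
  for (s in c("pos", "neg", "gen")) {
    smax <- records[[paste0("dibs_", s, "_max")]]
    spre <- records[[paste0("dibs_", s, "_3mo")]]
    cr <- change_rate(smax, spre)
    a <- ars(cr, records$cpeq_3mo)
    reason <- rep(NA_character_, nrow(records))
    reason[is.na(smax) | is.na(spre)] <- "missing_dibs"
    reason[!is.na(smax) & smax == 0] <- "smax_zero"
    reason[is.na(reason) & is.na(records$cpeq_3mo)] <- "missing_cpeq"
    reason[is.na(reason) & !is.na(records$cpeq_3mo) &
             records$cpeq_3mo <= 0] <- "cpeq_zero"
    reason[is.na(reason) & !is.na(cr) & cr < 0] <- "worsened_after_max"
    out[[paste0("cr_", s)]] <- cr
    out[[paste0("ars_", s)]] <- a
    out[[paste0("flag_", s)]] <- reason
  }
  attr(out, "n_evaluable") <- c(pos = sum(!is.na(out$ars_pos)),
                                neg = sum(!is.na(out$ars_neg)),
                                gen = sum(!is.na(out$ars_gen)))
  out
}
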