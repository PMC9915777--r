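# Clinical logic for turning an upgraded priority VUS into a genetic
# diagnosis. An autosomal dominant (AD) case needs only the upgraded
# variant; an autosomal recessive (AR) case additionally needs a second
# pathogenic or likely pathogenic variant in the same gene, not refuted
# by segregation analysis. Unavailable segregation does not block the
# diagnosis but leaves it flagged unconfirmed.

#' Evaluate one patient case
#'
#' Applies the diagnostic upgrade rule to a single case. The outcome is
#' `definitive` when the priority VUS was upgraded (prioritized) and the
#' genotype supports the inheritance mode: for AD nothing more is
#' required; for AR the second variant must be classified P or LP and
#' segregation must not be refuted. Everything else is `inconclusive`.
#' `segregation_flag` is `confirmed` only for confirmed segregation;
#' unavailable segregation yields a diagnosis flagged `unconfirmed`.
#'
#' @param case One-row data.frame (or list) with the patient-case fields
#'   of [read_patient_cases()].
#' @param upgraded Logical: did the case's priority VUS pass
#'   prioritization?
#' @return List with `status` (`"definitive"`/`"inconclusive"`),
#'   `rationale` (text), `segregation_flag`
#'   (`"confirmed"`/`"unconfirmed"`/`"refuted"`).
#' @export
evaluate_patient <- function(case, upgraded) {
  stopifnot(is.logical(upgraded), length(upgraded) == 1, !is.na(upgraded))
  inh <- case$inheritance
  stopifnot(inh %in% c("AR", "AD"))
  if (inh == "AR" && !is.na(case$second_variant) &&
      is.na(case$second_classification)) {
    stop("AR case with a second variant but no classification")
  }
  seg <- case$segregation
  seg_flag <- switch(seg, confirmed = "confirmed", refuted = "refuted",
                     unavailable = "unconfirmed",
                     stop("unknown segregation status: ", seg))
  if (!upgraded) {
    return(list(status = "inconclusive",
                rationale = "priority variant was not prioritized",
                segregation_flag = seg_flag))
  }
  if (inh == "AD") {
    return(list(status = "definitive",
                rationale = "upgraded variant in an autosomal dominant gene",
                segregation_flag = seg_flag))
  }
  second_path <- !is.na(case$second_classification) &&
    case$second_classification %in% c("P", "LP")
  if (!second_path) {
    return(list(status = "inconclusive",
                rationale = "AR case without a second P/LP variant",
                segregation_flag = seg_flag))
  }
  if (seg == "refuted") {
    return(list(status = "inconclusive",
                rationale = "segregation refutes a trans configuration",
                segregation_flag = seg_flag))
  }
  list(status = "definitive",
       rationale = "upgraded variant in trans with a second P/LP variant",
       segregation_flag = seg_flag)
}

#' Evaluate a patient cohort against a prioritized-variant set
#'
#' Looks each case's (gene, priority_variant) up in the prioritized set,
#' applies [evaluate_patient()], and summarizes the outcomes.
#'
#' @param cases Patient-case data.frame from [read_patient_cases()].
#' @param prioritized data.frame with columns `gene` and `protein_change`
#'   (e.g. the output of [select_priority_vus()]), or a character vector
#'   of `"gene:protein_change"` keys.
#' @return List with `outcomes` (the case table plus `upgraded`,
#'   `status`, `segregation_flag`, `rationale` columns) and `counts`
#'   (list: `definitive`, `definitive_with_confirmed_segregation`,
#'   `inconclusive`).
#' @export
evaluate_cohort <- function(cases, prioritized) {
  keys <- if (is.character(prioritized)) prioritized else {
    paste(prioritized$gene, prioritized$protein_change, sep = ":")
  }
  n <- nrow(cases)
  status <- character(n)
  seg_flag <- character(n)
  rationale <- character(n)
  upgraded <- logical(n)
  for (i in seq_len(n)) {
    case <- cases[i, , drop = FALSE]
    upgraded[i] <- paste(case$gene, case$priority_variant,
                         sep = ":") %in% keys
    res <- evaluate_patient(case, upgraded[i])
    status[i] <- res$status
    seg_flag[i] <- res$segregation_flag
    rationale[i] <- res$rationale
  }
  outcomes <- cbind(cases,
                    data.frame(upgraded = upgraded, status = status,
                               segregation_flag = seg_flag,
                               rationale = rationale,
                               stringsAsFactors = FALSE))
  list(
    outcomes = outcomes,
    counts = list(
      definitive = sum(status == "definitive"),
      definitive_with_confirmed_segregation =
        sum(status == "definitive" & seg_flag == "confirmed"),
      inconclusive = sum(status == "inconclusive")
    )
  )
}
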