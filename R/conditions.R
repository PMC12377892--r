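#' Registry of the sixteen modelled smoking-related conditions
#'
#' Canonical identifiers, labels, ICD-10 code lists, acute/chronic handling,
#' report groups and the flag for conditions whose attributable events cannot
#' be reported (no relative measures exist for non-ischemic heart disease
#' events, so its event cells are emitted as not applicable).
#'
#' Acute conditions (AMI, non-AMI coronary events, stroke, pneumonia) are
#' modelled as recurrent annual events with a case fatality; chronic
#' conditions (COPD, the cancers, leukemia, non-ischemic heart disease) are
#' absorbing disease states entered through an incidence hazard and left
#' through an annual in-state mortality hazard.
#'
#' @return data.frame with one row per condition: `condition_id`, `label`,
#'   `group` (one of the seven cost-report groups), `acute`,
#'   `event_af_computable`, `icd10`.
#' @export
condition_registry <- function() {
  data.frame(
    condition_id = c(
      "ami", "coronary_non_ami", "heart_non_ischemic", "stroke", "pneumonia",
      "copd", "lung_cancer", "oropharyngeal_cancer", "esophageal_cancer",
      "stomach_cancer", "pancreatic_cancer", "renal_cancer",
      "laryngeal_cancer", "cervical_cancer", "bladder_cancer", "leukemia"
    ),
    label = c(
      "Acute myocardial infarction", "Ischemic heart disease (non-AMI)",
      "Non-ischemic heart disease", "Stroke", "Pneumonia", "COPD",
      "Lung cancer", "Oropharyngeal cancer", "Esophageal cancer",
      "Stomach cancer", "Pancreatic cancer", "Kidney cancer",
      "Laryngeal cancer", "Cervical cancer", "Bladder cancer", "Leukemia"
    ),
    group = c(
      "cardiovascular", "cardiovascular", "cardiovascular", "stroke",
      "pneumonia", "copd", "lung_cancer", "other_cancers", "other_cancers",
      "other_cancers", "other_cancers", "other_cancers", "other_cancers",
      "other_cancers", "other_cancers", "other_cancers"
    ),
    acute = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
              FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    event_af_computable = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
                            TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    icd10 = c(
      "I210-I229", "I200-I209", "I30-I52",
      "I60;I61;I63;I64;I620;I621;I629;I678;I679;I690-I694;I698",
      "J100-J189", "J400-J439;J44X", "C330-C349", "C000-C009;C140;C142;C148",
      "C150-C159", "C160-C169", "C250-C259", "C64X-C65X", "C320-C329",
      "C530-C539", "C670-C679", "C920"
    ),
    stringsAsFactors = FALSE
  )
}

#' Seven condition groups used in cost and scenario reports
#' @return character vector of group ids in report order.
#' @export
condition_groups <- function() {
  c("copd", "cardiovascular", "lung_cancer", "other_cancers",
    "shs_other", "stroke", "pneumonia")
}

group_labels <- function() {
  c(copd = "COPD", cardiovascular = "Cardiovascular diseases",
    lung_cancer = "Lung cancer", other_cancers = "Other types of cancer",
    shs_other = "Exposure to environmental smoke and other causes",
    stroke = "Stroke", pneumonia = "Pneumonia")
}
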