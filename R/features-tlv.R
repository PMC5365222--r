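#' Target lesion volume
#'
#' Sums each patient's target-lesion sizes (one row in the lesion table
#' is one lesion). Patients absent from the lesion table have zero
#' target lesions and TLV 0. A lesion row with a missing size is
#' excluded from the sum when the patient has at least one observed
#' size; a patient whose sizes are all missing gets `NA` and must go
#' through [impute_tlv()] - missing sizes are never silently zeroed.
#'
#' @param lesions a [lesion_table()].
#' @param patient_ids patients to score (default: all ids present in
#'   `lesions`).
#' @return named numeric vector of TLVs (`NA` = needs imputation).
#' @export
compute_tlv <- function(lesions, patient_ids = NULL) {
  stopifnot(inherits(lesions, "lesion_table"))
  if (is.null(patient_ids)) patient_ids <- unique(lesions$patient_id)
  patient_ids <- as.character(patient_ids)
  out <- setNames(numeric(length(patient_ids)), patient_ids)
  idx <- split(seq_len(nrow(lesions)), lesions$patient_id)
  for (pid in intersect(patient_ids, names(idx))) {
    sizes <- lesions$size[idx[[pid]]]
    out[pid] <- if (all(is.na(sizes))) NA_real_
                else sum(sizes, na.rm = TRUE)
  }
  out
}

#' Count a patient's lesions
#'
#' @param lesions a [lesion_table()].
#' @param patient_ids patients to count for.
#' @param non_bone_only count only non-bone lesions.
#' @return named integer vector (0 for patients with no lesion rows).
#' @export
count_lesions <- function(lesions, patient_ids = NULL,
                          non_bone_only = FALSE) {
  stopifnot(inherits(lesions, "lesion_table"))
  if (is.null(patient_ids)) patient_ids <- unique(lesions$patient_id)
  patient_ids <- as.character(patient_ids)
  keep <- if (non_bone_only) lesions$is_bone %in% 0 else
    rep(TRUE, nrow(lesions))
  tab <- table(factor(lesions$patient_id[keep], levels = patient_ids))
  setNames(as.integer(tab), patient_ids)
}

#' Impute target lesion volume from a reference cohort
#'
#' For trials where lesion sizes were not recorded, TLV is imputed from
#' trials where they were: within each survival stratum (died /
#' censored) of the reference, the average TLV per lesion is the total
#' observed TLV divided by the total lesion count; a target patient's
#' imputed TLV is that stratum average multiplied by the patient's
#' non-bone lesion count.
#'
#' @param ref_tlv per-patient observed TLVs in the reference (no `NA`).
#' @param ref_lesion_count per-patient lesion counts in the reference,
#'   aligned with `ref_tlv`.
#' @param ref_event 0/1 death indicator for the reference patients.
#' @param target_nonbone_count per-patient non-bone lesion counts in the
#'   target cohort.
#' @param target_event 0/1 death indicator for the target patients.
#' @return numeric vector of imputed TLVs aligned with the target.
#' @export
impute_tlv <- function(ref_tlv, ref_lesion_count, ref_event,
                       target_nonbone_count, target_event) {
  stopifnot(length(ref_tlv) == length(ref_lesion_count),
            length(ref_tlv) == length(ref_event),
            length(target_nonbone_count) == length(target_event))
  if (anyNA(ref_tlv))
    stop("reference TLVs must be observed (no NA)", call. = FALSE)
  if (!all(ref_event %in% c(0, 1)) || !all(target_event %in% c(0, 1)))
    stop("event indicators must be coded 0/1", call. = FALSE)
  # a stratum average is required only if the target contains patients
  # in that stratum
  per_lesion <- vapply(c(died = 1, censored = 0), function(s) {
    if (!any(target_event == s)) return(NA_real_)
    sel <- ref_event == s
    nm <- if (s == 1) "died" else "censored"
    if (!any(sel))
      stop("empty reference stratum: ", nm, call. = FALSE)
    nles <- sum(ref_lesion_count[sel])
    if (nles == 0)
      stop("reference stratum ", nm, " has zero lesions", call. = FALSE)
    sum(ref_tlv[sel]) / nles
  }, numeric(1))
  unname(ifelse(target_event == 1, per_lesion[["died"]],
                per_lesion[["censored"]]) * target_nonbone_count)
}
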