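#' Ordinal age-risk recoding
#'
#' Age groups showed a non-monotone relation with survival in the
#' source cohorts, so age enters the models as an ordinal risk code
#' rather than a linear term: 0 for patients older than 75, 1 for
#' patients younger than 65, and 2 for ages 65-75 (both boundaries
#' inclusive).
#'
#' @param age_years positive numeric vector (`NA` passes through).
#' @return integer vector with values in \{0, 1, 2\}.
#' @export
recode_age_risk <- function(age_years) {
  age_years <- as.numeric(age_years)
  if (any(age_years[!is.na(age_years)] <= 0))
    stop("ages must be > 0", call. = FALSE)
  ifelse(is.na(age_years), NA_integer_,
  ifelse(age_years > 75, 0L,
  ifelse(age_years < 65, 1L, 2L)))
}

#' Binary race recoding
#'
#' Case-insensitive: labels "white" or "other" map to 1, every other
#' label (e.g. "black", "asian") maps to 0; missing labels stay
#' missing.
#'
#' @param race_label character vector.
#' @return integer 0/1 vector.
#' @export
recode_race <- function(race_label) {
  race_label <- as.character(race_label)
  out <- ifelse(is.na(race_label) | !nzchar(race_label), NA_integer_,
                as.integer(tolower(race_label) %in% c("white", "other")))
  out
}

#' Dual ECOG coding
#'
#' Emits the ECOG performance status both as a numeric column and as
#' one-hot indicator columns, so a model search can pick either
#' representation.
#'
#' @param ecog integer-valued vector of ECOG scores.
#' @return data.frame with `ecog_num` and one `ecog_<level>` indicator
#'   per observed level.
#' @export
recode_ecog <- function(ecog) {
  ecog <- as.numeric(ecog)
  out <- data.frame(ecog_num = ecog)
  for (l in sort(unique(ecog[!is.na(ecog)]))) {
    out[[paste0("ecog_", l)]] <-
      ifelse(is.na(ecog), NA_integer_, as.integer(ecog == l))
  }
  out
}
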