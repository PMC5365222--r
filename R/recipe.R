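#' Feature recipe: declarative derived-feature construction
#'
#' A recipe lists the derived features to build from a raw cohort and
#' lesion table: merged binary blocks (any of the three merge modes),
#' protective/harmful item counts with the composite harm/pro score,
#' target lesion volume with trial-level imputation, laboratory
#' principal components, and the age/race/ECOG recodings. Recipes are
#' plain lists and can be read from YAML with [read_recipe()].
#'
#' Recognised elements:
#' \describe{
#'   \item{blocks}{named list; each entry `list(columns=, mode=)`
#'     creates one merged column with the entry's name.}
#'   \item{protective_harmful}{`list(columns=, threshold=)`; adds
#'     `sum_protective`, `sum_harmful` and `harm_pro`.}
#'   \item{tlv}{`list(impute_trials=)`; adds `tlv`, imputing patients
#'     in the listed trials from the remaining trials' observed
#'     lesions.}
#'   \item{pca}{`list(labs=, n_components=, loading_threshold=)`; adds
#'     `lab_pc1`, `lab_pc2`, ... restricted at fit time to the labs
#'     whose PC1 loading is significant.}
#'   \item{age_column, race_column, ecog_column}{column names for the
#'     recodings; each adds `age_risk` / `race_bin` / the dual ECOG
#'     coding.}
#' }
#'
#' @param recipe a recipe list.
#' @param cohort a [cohort_table()] (training data; all supervised
#'   pieces - z-score weights, PCA, TLV stratum means - are estimated
#'   here).
#' @param lesions optional [lesion_table()].
#' @return list with `cohort` (augmented [cohort_table()]) and
#'   `transformers` (a `feature_transformers` object for
#'   [apply_features()]).
#' @export
build_features <- function(recipe, cohort, lesions = NULL) {
  outcome <- as_surv_outcome(cohort)
  tr <- list(recipe = recipe)
  new_cols <- list()
  new_tags <- character()

  for (bn in names(recipe$blocks)) {
    blk <- recipe$blocks[[bn]]
    m <- as.matrix(as.data.frame(cohort)[, blk$columns, drop = FALSE])
    res <- merge_binary_block(m, mode = blk$mode, outcome = outcome)
    new_cols[[bn]] <- res$score
    new_tags[bn] <- "numeric"
    tr$blocks[[bn]] <- res$weights
  }

  ph <- recipe$protective_harmful
  if (!is.null(ph)) {
    m <- as.matrix(as.data.frame(cohort)[, ph$columns, drop = FALSE])
    labels <- classify_protective_harmful(
      m, outcome, threshold = ph$threshold %||% 1.64,
      flip_sign = isTRUE(ph$flip_sign))
    pro <- labels$feature[labels$label == "protective"]
    harm <- labels$feature[labels$label == "harmful"]
    m0 <- m; m0[is.na(m0)] <- 0
    sp <- if (length(pro)) rowSums(m0[, pro, drop = FALSE]) else
      numeric(nrow(cohort))
    sh <- if (length(harm)) rowSums(m0[, harm, drop = FALSE]) else
      numeric(nrow(cohort))
    new_cols$sum_protective <- sp
    new_cols$sum_harmful <- sh
    new_tags[c("sum_protective", "sum_harmful")] <- "numeric"
    tr$protective <- pro; tr$harmful <- harm
    hp <- tryCatch(derive_harm_pro(sp, sh, outcome),
                   error = function(e) NULL)
    if (!is.null(hp)) {
      new_cols$harm_pro <- hp$score
      new_tags["harm_pro"] <- "numeric"
      tr$harm_pro <- hp[c("z_harm", "z_pro")]
    }
  }

  if (!is.null(recipe$tlv)) {
    if (is.null(lesions))
      stop("recipe requests TLV but no lesion table given", call. = FALSE)
    imp_trials <- recipe$tlv$impute_trials %||% character()
    tlv <- compute_tlv(lesions, cohort$patient_id)
    cnt_nb <- count_lesions(lesions, cohort$patient_id,
                            non_bone_only = TRUE)
    cnt <- count_lesions(lesions, cohort$patient_id)
    ref <- !(cohort$trial %in% imp_trials) & !is.na(tlv)
    need <- (cohort$trial %in% imp_trials) | is.na(tlv)
    if (any(need)) {
      tlv[need] <- impute_tlv(tlv[ref], cnt[ref], cohort$event[ref],
                              cnt_nb[need], cohort$event[need])
      # remember stratum means for new data
      tr$tlv_per_lesion <- c(
        died = sum(tlv[ref & cohort$event == 1]) /
          sum(cnt[ref & cohort$event == 1]),
        censored = sum(tlv[ref & cohort$event == 0]) /
          sum(cnt[ref & cohort$event == 0]))
    }
    new_cols$tlv <- unname(tlv)
    new_tags["tlv"] <- "numeric"
  }

  if (!is.null(recipe$pca)) {
    p <- recipe$pca
    labm <- as.matrix(as.data.frame(cohort)[, p$labs, drop = FALSE])
    labm <- median_impute(labm)
    tr$lab_medians <- attr(labm, "medians")
    meta <- fit_lab_pca(labm, n_components = p$n_components %||% 2,
                        loading_threshold = p$loading_threshold %||% 0.25)
    tr$pca <- meta
    scores <- project_lab_pca(meta, labm)
    for (j in seq_len(ncol(scores))) {
      cn <- paste0("lab_pc", j)
      new_cols[[cn]] <- scores[, j]
      new_tags[cn] <- "numeric"
    }
  }

  if (!is.null(recipe$age_column)) {
    new_cols$age_risk <- recode_age_risk(cohort[[recipe$age_column]])
    new_tags["age_risk"] <- "ordinal"
  }
  if (!is.null(recipe$race_column)) {
    new_cols$race_bin <- recode_race(cohort[[recipe$race_column]])
    new_tags["race_bin"] <- "binary"
  }
  if (!is.null(recipe$ecog_column)) {
    ec <- recode_ecog(cohort[[recipe$ecog_column]])
    for (cn in names(ec)) {
      new_cols[[cn]] <- ec[[cn]]
      new_tags[cn] <- if (cn == "ecog_num") "numeric" else "binary"
    }
  }

  out <- as.data.frame(cohort)
  for (cn in names(new_cols)) out[[cn]] <- new_cols[[cn]]
  schema <- c(attr(cohort, "schema"), new_tags)
  tr$derived <- names(new_cols)
  structure_out <- list(
    cohort = cohort_table(out, schema),
    transformers = structure(tr, class = "feature_transformers"))
  structure_out
}

median_impute <- function(m, medians = NULL) {
  if (is.null(medians))
    medians <- apply(m, 2, median, na.rm = TRUE)
  for (j in seq_len(ncol(m)))
    m[is.na(m[, j]), j] <- medians[j]
  attr(m, "medians") <- medians
  m
}

#' Apply fitted feature transformers to a new cohort
#'
#' Reapplies every supervised piece of a [build_features()] fit - merge
#' weights, protective/harmful memberships, harm/pro z-scores, TLV
#' stratum means, lab medians and PCA loadings - to new data without
#' re-estimating anything, preserving the train/test separation.
#'
#' @param transformers `feature_transformers` from [build_features()].
#' @param cohort new [cohort_table()] with the same raw columns.
#' @param lesions optional new [lesion_table()].
#' @return augmented [cohort_table()].
#' @export
apply_features <- function(transformers, cohort, lesions = NULL) {
  stopifnot(inherits(transformers, "feature_transformers"))
  tr <- transformers
  recipe <- tr$recipe
  new_cols <- list()
  new_tags <- character()

  for (bn in names(recipe$blocks)) {
    m <- as.matrix(as.data.frame(cohort)[, recipe$blocks[[bn]]$columns,
                                         drop = FALSE])
    new_cols[[bn]] <- apply_merge_weights(tr$blocks[[bn]], m)
    new_tags[bn] <- "numeric"
  }
  if (!is.null(recipe$protective_harmful)) {
    m <- as.matrix(as.data.frame(cohort)[, recipe$protective_harmful$columns,
                                         drop = FALSE])
    m[is.na(m)] <- 0
    sp <- if (length(tr$protective))
      rowSums(m[, tr$protective, drop = FALSE]) else numeric(nrow(cohort))
    sh <- if (length(tr$harmful))
      rowSums(m[, tr$harmful, drop = FALSE]) else numeric(nrow(cohort))
    new_cols$sum_protective <- sp
    new_cols$sum_harmful <- sh
    new_tags[c("sum_protective", "sum_harmful")] <- "numeric"
    if (!is.null(tr$harm_pro)) {
      new_cols$harm_pro <- tr$harm_pro$z_harm * sh + tr$harm_pro$z_pro * sp
      new_tags["harm_pro"] <- "numeric"
    }
  }
  if (!is.null(recipe$tlv)) {
    if (is.null(lesions))
      stop("recipe requests TLV but no lesion table given", call. = FALSE)
    tlv <- compute_tlv(lesions, cohort$patient_id)
    need <- is.na(tlv) | cohort$trial %in%
      (recipe$tlv$impute_trials %||% character())
    if (any(need)) {
      if (is.null(tr$tlv_per_lesion))
        stop("no TLV stratum means were fitted; cannot impute",
             call. = FALSE)
      cnt_nb <- count_lesions(lesions, cohort$patient_id,
                              non_bone_only = TRUE)
      tlv[need] <- ifelse(cohort$event[need] == 1,
                          tr$tlv_per_lesion[["died"]],
                          tr$tlv_per_lesion[["censored"]]) * cnt_nb[need]
    }
    new_cols$tlv <- unname(tlv)
    new_tags["tlv"] <- "numeric"
  }
  if (!is.null(recipe$pca)) {
    labm <- as.matrix(as.data.frame(cohort)[, recipe$pca$labs,
                                            drop = FALSE])
    labm <- median_impute(labm, tr$lab_medians)
    scores <- project_lab_pca(tr$pca, labm)
    for (j in seq_len(ncol(scores))) {
      cn <- paste0("lab_pc", j)
      new_cols[[cn]] <- scores[, j]
      new_tags[cn] <- "numeric"
    }
  }
  if (!is.null(recipe$age_column)) {
    new_cols$age_risk <- recode_age_risk(cohort[[recipe$age_column]])
    new_tags["age_risk"] <- "ordinal"
  }
  if (!is.null(recipe$race_column)) {
    new_cols$race_bin <- recode_race(cohort[[recipe$race_column]])
    new_tags["race_bin"] <- "binary"
  }
  if (!is.null(recipe$ecog_column)) {
    ec <- recode_ecog(cohort[[recipe$ecog_column]])
    for (cn in names(ec)) {
      new_cols[[cn]] <- ec[[cn]]
      new_tags[cn] <- if (cn == "ecog_num") "numeric" else "binary"
    }
  }
  out <- as.data.frame(cohort)
  for (cn in names(new_cols)) out[[cn]] <- new_cols[[cn]]
  cohort_table(out, c(attr(cohort, "schema"), new_tags))
}

#' @rdname build_features
#' @param path YAML recipe file.
#' @export
read_recipe <- function(path) {
  if (!file.exists(path)) stop("recipe file not found: ", path,
                               call. = FALSE)
  yaml::read_yaml(path)
}
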