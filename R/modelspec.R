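#' Cox model term specification
#'
#' The object the CAFS search operates on: an ordered set of main-effect
#' covariate names, an ordered set of unordered pairwise interaction
#' terms, and a set of covariates banned from the search. Interaction
#' pairs are order-insensitive (`{A,B}` equals `{B,A}`) and must satisfy
#' the hierarchy rule: both members appear among the main terms.
#'
#' @param main character vector of covariate names (may be empty).
#' @param interactions list of length-2 character vectors, or a character
#'   vector of `"A:B"` labels.
#' @param exclude character vector of covariate names banned from the
#'   feature space for searches started from this spec.
#' @return a `model_spec` object.
#' @export
model_spec <- function(main = character(), interactions = list(),
                       exclude = character()) {
  main <- as.character(main)
  if (anyDuplicated(main))
    stop("duplicate main terms: ",
         paste(unique(main[duplicated(main)]), collapse = ", "),
         call. = FALSE)
  if (is.character(interactions))
    interactions <- strsplit(interactions, ":", fixed = TRUE)
  interactions <- lapply(interactions, function(p) {
    p <- as.character(p)
    if (length(p) != 2 || p[1] == p[2])
      stop("interaction terms must pair two distinct names", call. = FALSE)
    sort(p)
  })
  if (anyDuplicated(vapply(interactions, paste, "", collapse = ":")))
    stop("duplicate interaction terms", call. = FALSE)
  for (p in interactions) {
    if (!all(p %in% main))
      stop("interaction {", paste(p, collapse = ","),
           "} violates hierarchy: both members must be main terms",
           call. = FALSE)
  }
  structure(list(main = main, interactions = interactions,
                 exclude = unique(as.character(exclude))),
            class = "model_spec")
}

interaction_labels <- function(spec) {
  vapply(spec$interactions, paste, "", collapse = ":")
}

#' @export
format.model_spec <- function(x, ...) {
  terms <- c(x$main, interaction_labels(x))
  if (!length(terms)) return("<model_spec> (empty)")
  paste0("<model_spec> ", paste(terms, collapse = " + "))
}

#' @export
print.model_spec <- function(x, ...) {
  cat(format(x), "\n")
  if (length(x$exclude))
    cat("  excluded: ", paste(x$exclude, collapse = ", "), "\n")
  invisible(x)
}

spec_key <- function(spec) {
  paste(c(sort(spec$main), sort(interaction_labels(spec))),
        collapse = "|")
}

spec_equal <- function(a, b) spec_key(a) == spec_key(b)

n_spec_terms <- function(spec) length(spec$main) + length(spec$interactions)
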