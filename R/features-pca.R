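#' Principal-component metafeatures from laboratory values
#'
#' Centers and unit-scales each laboratory column, performs PCA (via
#' [stats::prcomp()]) and retains the top components as new features.
#' Laboratories whose absolute loading on the first component reaches
#' `loading_threshold` are reported as `significant_labs` - the subset
#' that drives the dominant axis of variation (in practice, a latent
#' disease-severity factor).
#'
#' @param labs numeric matrix (patients x labs), complete (impute
#'   first); at least 2 columns.
#' @param n_components number of components to retain.
#' @param loading_threshold absolute PC1-loading cutoff for
#'   `significant_labs` (default 0.25).
#' @return a `lab_pca` object: `lab_names`, `center`, `scale`,
#'   `loadings` (labs x components, orthonormal columns), `sdev`,
#'   `n_components`, `significant_labs`.
#' @export
fit_lab_pca <- function(labs, n_components = 2, loading_threshold = 0.25) {
  labs <- as.matrix(labs)
  if (ncol(labs) < 2) stop("need at least 2 labs", call. = FALSE)
  if (anyNA(labs)) stop("lab matrix must be complete", call. = FALSE)
  if (n_components < 1 || n_components > ncol(labs))
    stop("n_components must be in 1..", ncol(labs), call. = FALSE)
  sds <- apply(labs, 2, sd)
  if (any(sds == 0))
    stop("constant lab column(s): ",
         paste(colnames(labs)[sds == 0], collapse = ", "), call. = FALSE)
  pc <- prcomp(labs, center = TRUE, scale. = TRUE)
  loadings <- pc$rotation[, seq_len(n_components), drop = FALSE]
  lab_names <- colnames(labs) %||% paste0("lab", seq_len(ncol(labs)))
  sig <- lab_names[abs(loadings[, 1]) >= loading_threshold]
  structure(list(
    lab_names = lab_names,
    center = setNames(as.numeric(pc$center), lab_names),
    scale = setNames(as.numeric(pc$scale), lab_names),
    loadings = loadings,
    sdev = pc$sdev[seq_len(n_components)],
    n_components = n_components,
    loading_threshold = loading_threshold,
    significant_labs = sig), class = "lab_pca")
}

#' @export
print.lab_pca <- function(x, ...) {
  cat(sprintf(
    "<lab_pca> %d labs -> %d component(s); PC1-significant: %s\n",
    length(x$lab_names), x$n_components,
    paste(x$significant_labs, collapse = ", ")))
  invisible(x)
}

#' Project lab values onto fitted principal components
#'
#' Applies the stored centering, scaling and loadings:
#' `((x - center)/scale) %*% loadings`. Deterministic; projecting the
#' training matrix reproduces the fit-time scores.
#'
#' @param meta a `lab_pca` from [fit_lab_pca()].
#' @param labs numeric matrix with the same lab columns as the fit.
#' @return matrix of component scores (patients x components).
#' @export
project_lab_pca <- function(meta, labs) {
  stopifnot(inherits(meta, "lab_pca"))
  labs <- as.matrix(labs)
  if (ncol(labs) != length(meta$lab_names))
    stop("lab matrix must have the same columns as the fit", call. = FALSE)
  if (!is.null(colnames(labs)) &&
      !identical(colnames(labs), meta$lab_names))
    stop("lab columns differ from fit: expected ",
         paste(meta$lab_names, collapse = ", "), call. = FALSE)
  if (anyNA(labs))
    stop("missing lab value(s); impute before projecting", call. = FALSE)
  std <- sweep(sweep(labs, 2, meta$center), 2, meta$scale, "/")
  std %*% meta$loadings
}
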