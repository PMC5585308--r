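#' Expression set: feature-by-sample matrix plus sample annotation
#'
#' The common currency of the pipeline: a numeric feature x sample matrix
#' tagged with its scale (`log2` intensities, raw `counts`, or qPCR `ct`
#' cycle thresholds) and a per-sample annotation tibble. For qPCR data an
#' optional logical flag matrix marks unreliable/undetermined wells.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   Row names are feature ids; column names must match `samples$sample_id`.
#' @param samples tibble of sample annotations with columns `sample_id`,
#'   `age` (P2/P9/P23/P45), `layer` (LII/LDeep, or NA for qPCR), `animal_id`,
#'   `platform` (array/rnaseq/qpcr) and optionally `group_extra`.
#' @param scale one of `"log2"`, `"counts"`, `"ct"`.
#' @param mask optional logical matrix, same dimensions as `values`; `TRUE`
#'   flags a value as unreliable (only meaningful for `scale = "ct"`).
#'
#' @return an object of class `expr_set`.
#' @export
expr_set <- function(values, samples, scale = c("log2", "counts", "ct"),
                     mask = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values))) abort("`values` must have feature row names")
  if (anyDuplicated(rownames(values))) abort("duplicate feature ids")
  samples <- validate_samples(samples)
  if (is.null(colnames(values))) {
    if (ncol(values) != nrow(samples)) {
      abort(sprintf("dimension mismatch: %d columns vs %d samples",
                    ncol(values), nrow(samples)))
    }
    colnames(values) <- samples$sample_id
  } else {
    missing <- setdiff(samples$sample_id, colnames(values))
    if (length(missing)) {
      abort(paste0("samples absent from the expression table: ",
                   paste(missing, collapse = ", ")))
    }
    values <- values[, samples$sample_id, drop = FALSE]
  }
  if (scale == "counts") {
    ok <- is.finite(values) & values >= 0 & abs(values - round(values)) < 1e-8
    if (!all(ok)) abort("count matrix must contain non-negative integers")
  }
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), dim(values))) {
      abort("`mask` must be a logical matrix with the dimensions of `values`")
    }
    dimnames(mask) <- dimnames(values)
  }
  structure(list(values = values, samples = samples, scale = scale,
                 mask = mask),
            class = "expr_set")
}

#' Validate a sample annotation tibble
#'
#' @param samples data frame of sample annotations.
#' @return the annotation as a tibble with `age`, `layer`, `platform`
#'   normalised to the expected level sets.
#' @export
validate_samples <- function(samples) {
  samples <- as_tibble(samples)
  need <- c("sample_id", "age", "layer", "animal_id", "platform")
  missing <- setdiff(need, names(samples))
  if (length(missing)) {
    abort(paste0("sample sheet lacks columns: ", paste(missing, collapse = ", ")))
  }
  samples <- mutate(samples,
                    across(all_of(need), as.character),
                    layer = ifelse(.data$layer %in% c("NA", ""), NA_character_,
                                   .data$layer))
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id")
  if (!all(samples$age %in% the_ages)) abort("age must be one of P2/P9/P23/P45")
  if (!all(samples$platform %in% c("array", "rnaseq", "qpcr"))) {
    abort("platform must be array, rnaseq or qpcr")
  }
  bad_layer <- !is.na(samples$layer) & !samples$layer %in% the_layers
  if (any(bad_layer)) abort("layer must be LII, LDeep or NA")
  na_layer <- is.na(samples$layer) & samples$platform != "qpcr"
  if (any(na_layer)) abort("layer may be NA only for qPCR samples")
  samples
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("<expr_set> %d features x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  if (!is.null(x$mask)) {
    cat(sprintf("  flagged cells: %d\n", sum(x$mask)))
  }
  cat("  samples: ",
      paste(head(x$samples$sample_id, 6), collapse = ", "),
      if (ncol(x$values) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' Long-format view of an expression set
#'
#' @param x an `expr_set`.
#' @param ... unused.
#' @return a tibble with one row per (feature, sample) cell, joined with the
#'   sample annotation.
#' @export
as_tibble.expr_set <- function(x, ...) {
  long <- tibble(
    feature_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
  if (!is.null(x$mask)) long$flagged <- as.vector(x$mask)
  left_join(long, x$samples, by = "sample_id")
}

#' Subset an expression set by features and/or samples
#'
#' @param x an `expr_set`.
#' @param features character vector of feature ids (default all).
#' @param sample_ids character vector of sample ids (default all).
#' @return the subsetted `expr_set`.
#' @export
subset_expr <- function(x, features = NULL, sample_ids = NULL) {
  stopifnot(inherits(x, "expr_set"))
  features <- features %||% rownames(x$values)
  sample_ids <- sample_ids %||% colnames(x$values)
  missing_f <- setdiff(features, rownames(x$values))
  if (length(missing_f)) {
    abort(paste0("unknown features: ", paste(head(missing_f, 5), collapse = ", ")))
  }
  expr_set(x$values[features, sample_ids, drop = FALSE],
           filter(x$samples, .data$sample_id %in% sample_ids),
           scale = x$scale,
           mask = if (!is.null(x$mask)) x$mask[features, sample_ids, drop = FALSE])
}

#' Per-feature median expression
#'
#' The per-feature median of the normalized log2 values, the summary used
#' for minimum-expression filters.
#'
#' @param x an `expr_set`.
#' @return named numeric vector of row medians.
#' @export
feature_medians <- function(x) {
  stopifnot(inherits(x, "expr_set"))
  apply(x$values, 1, median, na.rm = TRUE)
}
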