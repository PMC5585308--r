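set_provenance <- function(x, method, params) {
  attr(x, "provenance") <- list(method = method, params = params)
  x
}

#' Normalization provenance
#'
#' @param x an object returned by a normalization step.
#' @return the provenance record (method tag + parameters) or NULL.
#' @export
provenance <- function(x) attr(x, "provenance")

#' Filter features by detection presence
#'
#' Keeps features detected in at least `min_present_fraction` of the samples
#' of at least one age x layer group (a detected-above-background surrogate
#' for unpublished array filter criteria). Detection defaults to `count > 0`
#' for counts, unflagged wells for masked Ct data, and non-missing values
#' otherwise; an explicit logical `detected` matrix overrides this.
#'
#' @param x an [expr_set].
#' @param min_present_fraction minimum within-group presence fraction.
#' @param detected optional logical matrix, same shape as the values.
#' @return the filtered [expr_set].
#' @export
filter_features <- function(x, min_present_fraction = 0.5, detected = NULL) {
  stopifnot(inherits(x, "expr_set"))
  if (is.null(detected)) {
    detected <- switch(x$scale,
                       counts = x$values > 0,
                       ct = if (is.null(x$mask)) !is.na(x$values) else !x$mask,
                       !is.na(x$values))
  }
  stopifnot(identical(dim(detected), dim(x$values)))
  group <- paste(x$samples$age, x$samples$layer, sep = ".")
  keep_by_group <- vapply(unique(group), function(g) {
    rowMeans(detected[, group == g, drop = FALSE]) >= min_present_fraction
  }, logical(nrow(x$values)))
  keep <- apply(as.matrix(keep_by_group), 1, any)
  if (!any(keep)) warn("all features removed by presence filter")
  out <- subset_expr(x, features = rownames(x$values)[keep])
  set_provenance(out, "filter_features",
                 list(min_present_fraction = min_present_fraction))
}

#' Quantile normalization
#'
#' Forces every sample to share one distribution: each column's sorted
#' values are replaced by the mean of the column-sorted values; tied values
#' within a column receive the mean of their quantile values. Output columns
#' are exact permutations of one another (up to tie averaging).
#'
#' @param x an [expr_set] (no missing values).
#' @return the normalized [expr_set].
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "expr_set"))
  v <- x$values
  if (anyNA(v)) abort("quantile normalization requires a complete matrix")
  ref <- rowMeans(apply(v, 2, sort))
  out <- apply(v, 2, function(col) {
    o <- order(col)
    mapped <- numeric(length(col))
    mapped[o] <- ref
    ## tied input values share the mean of the quantile values they span
    ave(mapped, match(col, col), FUN = mean)
  })
  dimnames(out) <- dimnames(v)
  res <- expr_set(out, x$samples, scale = "log2")
  set_provenance(res, "quantile", list())
}

#' TMM scaling factors
#'
#' Trimmed mean of M-values between-library scaling. The reference is the
#' sample whose 75th-percentile count fraction is closest to the mean of
#' those; each sample's factor is 2^(precision-weighted doubly trimmed mean
#' of log ratios vs the reference), excluding features with a zero count in
#' either library pairwise; factors are rescaled to geometric mean 1.
#'
#' @param x a counts-scale [expr_set] with at least two samples.
#' @param trim_M two-sided trim fraction on log-ratios.
#' @param trim_A two-sided trim fraction on average log intensity.
#' @return named per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(x, trim_M = 0.30, trim_A = 0.05) {
  stopifnot(inherits(x, "expr_set"), x$scale == "counts",
            ncol(x$values) >= 2)
  counts <- x$values
  lib <- colSums(counts)
  if (any(lib == 0)) abort("sample with zero total count")
  f75 <- apply(sweep(counts, 2, lib, "/"), 2, quantile, probs = 0.75)
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref], trim_M, trim_A)
  }, 1.0)
  fac <- fac / exp(mean(log(fac)))
  res <- setNames(fac, colnames(counts))
  set_provenance(res, "tmm", list(trim_M = trim_M, trim_A = trim_A, ref = ref))
}

tmm_pair <- function(obs, ref, n_obs, n_ref, trim_M, trim_A) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a) & w > 0
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  if (!length(m) || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_M) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_A) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2)) return(1)
  2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

#' Log counts-per-million
#'
#' `log2((count + prior) / (effective library + 1) x 1e6)` with effective
#' library = raw library x scaling factor; the prior keeps zero counts
#' finite.
#'
#' @param x a counts-scale [expr_set].
#' @param factors per-sample scaling factors (e.g. from [tmm_factors()]);
#'   default all 1.
#' @param prior prior count.
#' @return a log2-scale [expr_set].
#' @export
log_cpm <- function(x, factors = NULL, prior = 0.5) {
  stopifnot(inherits(x, "expr_set"), x$scale == "counts")
  if (any(x$values < 0)) abort("negative counts")
  factors <- factors %||% setNames(rep(1, ncol(x$values)), colnames(x$values))
  eff <- colSums(x$values) * factors[colnames(x$values)]
  out <- log2(sweep(x$values + prior, 2, eff + 1, "/") * 1e6)
  res <- expr_set(out, x$samples, scale = "log2")
  set_provenance(res, "log_cpm",
                 list(prior = prior, size_factors = unname(factors)))
}

#' Voom-style precision weights
#'
#' Fits the design per feature, smooths sqrt(residual sd) against mean
#' log-CPM with lowess, and returns weights = (trend prediction)^-4 clipped
#' to [1e-6, 1e6] (constant within a feature). A single-feature input gets
#' unit weights with a message.
#'
#' @param x a log2-scale [expr_set].
#' @param design design matrix (rows = samples).
#' @param span lowess span.
#' @return feature x sample weight matrix.
#' @export
precision_weights <- function(x, design, span = 0.5) {
  stopifnot(inherits(x, "expr_set"))
  v <- x$values
  df_resid <- nrow(design) - qr(design)$rank
  if (df_resid <= 0) abort("no residual degrees of freedom")
  if (nrow(v) < 2) {
    inform("fewer than 2 features: returning unit precision weights")
    w <- matrix(1, nrow(v), ncol(v), dimnames = dimnames(v))
    return(set_provenance(w, "precision_weights", list(span = span)))
  }
  fit <- lm.fit(design, t(v))
  s <- sqrt(colSums(as.matrix(fit$residuals)^2) / df_resid)
  mu <- rowMeans(v)
  lw <- lowess(mu, sqrt(s), f = span)
  pred <- approx(lw$x, lw$y, xout = mu, rule = 2, ties = mean)$y
  w_feat <- pmin(pmax(pred^-4, 1e-6), 1e6)
  w <- matrix(w_feat, nrow(v), ncol(v), dimnames = dimnames(v))
  set_provenance(w, "precision_weights", list(span = span))
}

#' Delta-Ct normalization
#'
#' Per sample, subtracts the mean Ct over the features that are reliably
#' detected (unmasked) in every sample, and negates, so higher output means
#' higher expression and downstream fold changes read like the other
#' platforms. Features flagged in any sample are dropped.
#'
#' @param x a ct-scale [expr_set] (with its mask).
#' @return a log2-like [expr_set] of negated centered Ct values.
#' @export
delta_ct_normalize <- function(x) {
  stopifnot(inherits(x, "expr_set"), x$scale == "ct")
  mask <- x$mask %||% matrix(FALSE, nrow(x$values), ncol(x$values),
                             dimnames = dimnames(x$values))
  universal <- rowSums(mask) == 0 & rowSums(is.na(x$values)) == 0
  if (!any(universal)) abort("no feature is reliably detected in all samples")
  v <- x$values[universal, , drop = FALSE]
  centered <- -sweep(v, 2, colMeans(v), "-")
  res <- expr_set(centered, x$samples, scale = "log2")
  set_provenance(res, "delta_ct", list(n_reference = sum(universal)))
}
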