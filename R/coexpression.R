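cor_distance <- function(values) {
  sds <- apply(values, 1, sd)
  if (any(sds < 1e-12)) abort("zero-variance profile in correlation distance")
  1 - cor(t(values))
}

#' Pearson-correlation dendrogram of expression profiles
#'
#' Distance is 1 - Pearson correlation across all samples; average linkage.
#' Feature order gives deterministic tie-breaking.
#'
#' @param x a log2-scale [expr_set].
#' @param features features to cluster (default all); zero-variance
#'   profiles are an error.
#' @return an `hclust` object with feature ids as labels.
#' @export
correlation_dendrogram <- function(x, features = NULL) {
  stopifnot(inherits(x, "expr_set"))
  features <- features %||% rownames(x$values)
  if (length(features) < 2) abort("need at least 2 features")
  v <- x$values[features, , drop = FALSE]
  hclust(as.dist(cor_distance(v)), method = "average")
}

dispersion_w <- function(D, labels) {
  sum(vapply(split(seq_along(labels), labels), function(idx) {
    if (length(idx) < 2) return(0)
    sum(D[idx, idx]) / (2 * length(idx))
  }, 1.0))
}

gap_select_k <- function(values, max_k, B) {
  n <- nrow(values)
  ks <- seq_len(min(max_k, n - 1))
  if (length(ks) < 2) return(1L)
  D <- cor_distance(values)
  hc <- hclust(as.dist(D), method = "average")
  logW <- vapply(ks, function(k) log(max(dispersion_w(D, cutree(hc, k)),
                                         1e-12)), 1.0)
  rng <- apply(values, 2, range)
  logWstar <- matrix(0, B, length(ks))
  for (b in seq_len(B)) {
    ref <- vapply(seq_len(ncol(values)),
                  function(j) runif(n, rng[1, j], rng[2, j]),
                  numeric(n))
    Dr <- cor_distance(ref)
    hcr <- hclust(as.dist(Dr), method = "average")
    logWstar[b, ] <- vapply(ks, function(k) {
      log(max(dispersion_w(Dr, cutree(hcr, k)), 1e-12))
    }, 1.0)
  }
  gap <- colMeans(logWstar) - logW
  s <- apply(logWstar, 2, sd) * sqrt(1 + 1 / B)
  for (i in seq_along(ks)[-length(ks)]) {
    if (gap[i] >= gap[i + 1] - s[i + 1]) return(ks[i])
  }
  ks[which.max(gap)]
}

#' Co-expression modules by recursive gap-statistic thresholding (PART)
#'
#' Recursively partitions the correlation dendrogram: at each subtree the
#' number of clusters k is chosen by the gap statistic (B reference
#' datasets drawn uniform over the per-sample range of the current
#' features, same 1 - Pearson distance, average linkage, one-standard-error
#' rule). k = 1 stops and emits the subtree as a module; otherwise the
#' subtree is cut into k parts and each is recursed into. Parts smaller
#' than `min_size` become outliers (label 0).
#'
#' @param x a log2-scale [expr_set].
#' @param features features to cluster (default all).
#' @param min_size minimum module size.
#' @param max_k maximum clusters considered per split.
#' @param B number of gap-statistic reference datasets.
#' @param seed integer seed (reference draws).
#' @return a `module_assignment` tibble (`feature_id`, `module`; 0 =
#'   outlier), with module labels 1..k in order of emission.
#' @export
part_partition <- function(x, features = NULL, min_size = 5, max_k = 10,
                           B = 50, seed = 1) {
  stopifnot(inherits(x, "expr_set"))
  features <- features %||% rownames(x$values)
  v <- x$values[features, , drop = FALSE]
  sds <- apply(v, 1, sd)
  if (any(sds < 1e-12)) {
    warn(sprintf("excluding %d zero-variance feature(s) from clustering",
                 sum(sds < 1e-12)))
    v <- v[sds >= 1e-12, , drop = FALSE]
  }
  labels <- setNames(rep(0L, length(features)), features)
  if (nrow(v) < max(2, min_size)) {
    return(structure(tibble(feature_id = features,
                            module = unname(labels)),
                     class = c("module_assignment", class(tibble()))))
  }
  set.seed(as.integer(seed))
  counter <- new.env()
  counter$next_label <- 1L
  recurse <- function(ids) {
    if (length(ids) < min_size) return()
    sub <- v[ids, , drop = FALSE]
    k <- gap_select_k(sub, max_k = max_k, B = B)
    if (k == 1) {
      labels[ids] <<- counter$next_label
      counter$next_label <- counter$next_label + 1L
      return()
    }
    hc <- hclust(as.dist(cor_distance(sub)), method = "average")
    parts <- cutree(hc, k)
    for (p in seq_len(k)) {
      members <- ids[parts == p]
      if (length(members) >= min_size) recurse(members)
      ## smaller parts stay outliers (label 0)
    }
  }
  recurse(rownames(v))
  structure(tibble(feature_id = features, module = unname(labels[features])),
            class = c("module_assignment", class(tibble())))
}

#' Representative module profiles
#'
#' Features are z-scored across samples; the representative is the
#' per-module mean of the standardized member profiles. Outliers (label 0)
#' are excluded.
#'
#' @param x a log2-scale [expr_set].
#' @param assignment a `module_assignment` tibble.
#' @return a tibble with one row per (module, sample): `module`,
#'   `sample_id`, `representative`, `n_members`, joined with the sample
#'   annotation.
#' @export
module_profiles <- function(x, assignment) {
  stopifnot(inherits(x, "expr_set"))
  keep <- filter(assignment, .data$module > 0)
  if (!nrow(keep)) abort("no module members")
  v <- x$values[keep$feature_id, , drop = FALSE]
  z <- t(scale(t(v)))
  out <- as_tibble(z) |>
    mutate(module = keep$module) |>
    tidyr::pivot_longer(-"module", names_to = "sample_id",
                        values_to = "value") |>
    group_by(.data$module, .data$sample_id) |>
    summarise(representative = mean(.data$value),
              n_members = n(), .groups = "drop") |>
    left_join(x$samples, by = "sample_id")
  arrange(out, .data$module,
          match(.data$sample_id, colnames(x$values)))
}
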