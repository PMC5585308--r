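#' Design matrices for the laminar contrasts
#'
#' Builds a cell-means design over the age x layer groups, optionally with
#' animal as a fixed blocking factor. Blocking columns are sum-coded within
#' each age (animals are nested in age), which keeps the design full rank.
#'
#' @param samples sample annotation tibble (layers must be non-missing).
#' @param blocking include within-age animal blocking columns.
#' @return a design matrix with one column per age.layer cell (named as the
#'   cells) plus any blocking columns.
#' @export
design_cells <- function(samples, blocking = FALSE) {
  samples <- validate_samples(samples)
  if (anyNA(samples$layer)) abort("cell-means design needs non-missing layers")
  cells <- paste(samples$age, samples$layer, sep = ".")
  lev <- as.vector(outer(the_ages, the_layers, paste, sep = "."))
  lev <- lev[lev %in% cells]
  X <- vapply(lev, function(l) as.numeric(cells == l), numeric(length(cells)))
  if (blocking) {
    for (a in intersect(the_ages, samples$age)) {
      animals <- unique(samples$animal_id[samples$age == a])
      if (length(animals) < 2) next
      last <- animals[length(animals)]
      for (an in animals[-length(animals)]) {
        col <- as.numeric(samples$animal_id == an) -
          as.numeric(samples$animal_id == last)
        X <- cbind(X, col)
        colnames(X)[ncol(X)] <- paste0("blk_", an)
      }
    }
  }
  rownames(X) <- samples$sample_id
  X
}

#' Contrast vectors over the design cells
#'
#' `contrast_age` is mean(P23/P45) - mean(P2/P9) pooled over layers;
#' `contrast_layer` is mean(LII) - mean(LDeep) pooled over ages (or within
#' one age when `age` is given). Entries on blocking columns are zero.
#'
#' @param design a design matrix from [design_cells()].
#' @param age for the layer contrast, restrict to one age.
#' @return a named contrast vector (length = ncol(design)).
#' @export
contrast_age <- function(design) {
  cells <- colnames(design)[colnames(design) %in%
                              outer(the_ages, the_layers, paste, sep = ".")]
  late <- cells[grepl("^P23\\.|^P45\\.", cells)]
  early <- setdiff(cells, late)
  if (!length(late) || !length(early)) abort("contrast with an empty side")
  v <- setNames(numeric(ncol(design)), colnames(design))
  v[late] <- 1 / length(late)
  v[early] <- -1 / length(early)
  v
}

#' @rdname contrast_age
#' @export
contrast_layer <- function(design, age = NULL) {
  cells <- colnames(design)[colnames(design) %in%
                              outer(the_ages, the_layers, paste, sep = ".")]
  if (!is.null(age)) cells <- cells[startsWith(cells, paste0(age, "."))]
  lii <- cells[endsWith(cells, ".LII")]
  ldeep <- cells[endsWith(cells, ".LDeep")]
  if (!length(lii) || !length(ldeep)) abort("contrast with an empty side")
  v <- setNames(numeric(ncol(design)), colnames(design))
  v[lii] <- 1 / length(lii)
  v[ldeep] <- -1 / length(ldeep)
  v
}

trigamma_inverse <- function(y, tol = 1e-8, max_iter = 50) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(max_iter)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) < tol * x) break
  }
  x
}

estimate_ebayes <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 1e-12
  if (!any(ok)) abort("no feature with positive residual variance")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    ## no excess dispersion of the log variances: variances are exchangeable
    d0 <- Inf
    s0_sq <- mean(s2[ok])
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Linear-model differential expression with moderated t
#'
#' Per-feature (optionally weighted) least squares for an arbitrary design,
#' empirical-Bayes shrinkage of the residual variances toward a prior
#' variance `s0_sq` with prior degrees of freedom `d0` estimated by the
#' method of moments on the log variances (trigamma inversion by Newton
#' iteration), moderated t statistics on `df_residual + d0` degrees of
#' freedom, and Benjamini-Hochberg adjusted two-sided p values.
#' Zero-variance features are excluded from the moment estimation and
#' reinstated with the prior variance.
#'
#' @param x a log2-scale [expr_set].
#' @param design design matrix (rows = samples of `x`, in order).
#' @param contrast numeric contrast vector over the design columns.
#' @param weights optional positive feature x sample weight matrix.
#' @param prior optional list(d0, s0_sq) forcing the prior instead of
#'   estimating it (d0 = 0 reproduces the ordinary t; d0 = Inf pools all
#'   variances at s0_sq).
#' @param contrast_name label stored in the result table.
#' @return a `moderated_fit`: tidy() gives the per-feature table
#'   (`feature_id`, `lfc`, `t_mod`, `p_raw`, `p_adj`, `mean_expr`,
#'   `df_total`, `contrast_name`), glance() the prior parameters.
#' @export
fit_and_moderate <- function(x, design, contrast, weights = NULL,
                             prior = NULL, contrast_name = "contrast") {
  stopifnot(inherits(x, "expr_set"))
  v <- x$values
  design <- as.matrix(design)
  if (nrow(design) != ncol(v)) abort("design rows must match samples")
  if (qr(design)$rank < ncol(design)) abort("design matrix is rank deficient")
  df <- nrow(design) - ncol(design)
  if (df < 1) abort("no residual degrees of freedom")
  contrast <- as.numeric(contrast)
  stopifnot(length(contrast) == ncol(design))
  if (!is.null(weights)) {
    stopifnot(identical(dim(weights), dim(v)))
    if (any(weights <= 0)) abort("weights must be strictly positive")
  }

  n_feat <- nrow(v)
  if (is.null(weights)) {
    qrX <- qr(design)
    coef <- qr.coef(qrX, t(v))
    resid <- t(v) - design %*% coef
    s2 <- colSums(resid^2) / df
    xtxi <- chol2inv(chol(crossprod(design)))
    su <- rep(sqrt(drop(t(contrast) %*% xtxi %*% contrast)), n_feat)
    lfc <- drop(t(coef) %*% contrast)
  } else {
    lfc <- su <- s2 <- numeric(n_feat)
    for (g in seq_len(n_feat)) {
      w <- weights[g, ]
      fit <- lm.wfit(design, v[g, ], w)
      s2[g] <- sum(w * fit$residuals^2) / df
      xtxi <- chol2inv(chol(crossprod(sqrt(w) * design)))
      su[g] <- sqrt(drop(t(contrast) %*% xtxi %*% contrast))
      lfc[g] <- sum(contrast * fit$coefficients)
    }
  }

  eb <- prior %||% estimate_ebayes(s2, df)
  zero_var <- !(is.finite(s2) & s2 > 1e-12)
  if (any(zero_var)) {
    inform(sprintf("%d zero-variance feature(s) given the prior variance",
                   sum(zero_var)))
    s2[zero_var] <- eb$s0_sq
  }
  s2_post <- if (is.infinite(eb$d0)) {
    rep(eb$s0_sq, n_feat)
  } else {
    (eb$d0 * eb$s0_sq + df * s2) / (eb$d0 + df)
  }
  df_total <- df + eb$d0
  t_mod <- lfc / (su * sqrt(s2_post))
  p_raw <- 2 * pt(-abs(t_mod), df = df_total)

  table <- tibble(feature_id = rownames(v),
                  lfc = lfc,
                  t_mod = t_mod,
                  p_raw = p_raw,
                  p_adj = bh_adjust(p_raw),
                  mean_expr = apply(v, 1, median),
                  df_total = df_total,
                  contrast_name = contrast_name)
  structure(list(table = table,
                 ebayes = list(d0 = eb$d0, s0_sq = eb$s0_sq),
                 df_residual = df,
                 contrast = contrast,
                 contrast_name = contrast_name),
            class = "moderated_fit")
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat(sprintf("<moderated_fit> %s: %d features, d0 = %.3g, s0^2 = %.3g\n",
              x$contrast_name, nrow(x$table), x$ebayes$d0, x$ebayes$s0_sq))
  invisible(x)
}

#' @export
tidy.moderated_fit <- function(x, ...) x$table

#' @export
glance.moderated_fit <- function(x, ...) {
  tibble(contrast_name = x$contrast_name,
         n_features = nrow(x$table),
         df_residual = x$df_residual,
         d0 = x$ebayes$d0,
         s0_sq = x$ebayes$s0_sq)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adj_k = min over j >= k of p_(j) * m / j`, capped at 1, returned in the
#' input order.
#'
#' @param p numeric p values in [0, 1].
#' @return adjusted p values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) abort("p values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric())
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  adj <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(m)
  out[o] <- adj
  ## adj_k >= p_k holds mathematically; guard against 1-ulp rounding
  pmax(out, p)
}

#' Call differentially expressed features
#'
#' Features with `p_adj < alpha` and `|lfc| > lfc_min`, labelled by
#' direction (positive lfc = up in the contrast numerator).
#'
#' @param fit a `moderated_fit` or its tidy table.
#' @param alpha BH-adjusted significance threshold.
#' @param lfc_min strict absolute log2 fold-change cutoff (0 = moderated t
#'   only).
#' @return tibble of called features with `lfc`, `p_adj` and `direction`.
#' @export
call_de <- function(fit, alpha = 0.05, lfc_min = 0) {
  tab <- if (inherits(fit, "moderated_fit")) fit$table else as_tibble(fit)
  filter(tab, .data$p_adj < alpha, abs(.data$lfc) > lfc_min) |>
    mutate(direction = ifelse(.data$lfc > 0, "up", "down")) |>
    select("feature_id", "lfc", "p_adj", "direction")
}

#' Run the study's standard contrasts
#'
#' Fits the age contrast (P2/P9 vs P23/P45, cell-means design), and the
#' pooled and per-age layer contrasts (with animal as a fixed blocking
#' factor, since layer samples are paired within animal), then reports the
#' DE sets and their overlap counts. A contrast with an empty side is
#' skipped with a warning.
#'
#' @param x a log2-scale [expr_set].
#' @param weights optional precision-weight matrix.
#' @param alpha,lfc_min thresholds passed to [call_de()].
#' @return a `contrast_results` list: `fits` (named `moderated_fit`s),
#'   `de_sets` (named feature-id vectors; `layer_any` is the union of the
#'   pooled and per-age layer calls), and `venn` (overlap counts between the
#'   age set and the layer union).
#' @export
run_all_contrasts <- function(x, weights = NULL, alpha = 0.05, lfc_min = 0) {
  stopifnot(inherits(x, "expr_set"))
  fits <- list()
  de_sets <- list()
  X_age <- design_cells(x$samples, blocking = FALSE)
  fits$age <- fit_and_moderate(x, X_age, contrast_age(X_age),
                               weights = weights, contrast_name = "age")
  X_blk <- design_cells(x$samples, blocking = TRUE)
  fits$layer <- fit_and_moderate(x, X_blk, contrast_layer(X_blk),
                                 weights = weights, contrast_name = "layer")
  for (a in intersect(the_ages, unique(x$samples$age))) {
    nm <- paste0("layer_", a)
    cv <- tryCatch(contrast_layer(X_blk, age = a), error = function(e) NULL)
    if (is.null(cv)) {
      warn(sprintf("skipping %s: a side is empty", nm))
      next
    }
    fits[[nm]] <- fit_and_moderate(x, X_blk, cv, weights = weights,
                                   contrast_name = nm)
  }
  de_sets <- lapply(fits, function(f) call_de(f, alpha, lfc_min)$feature_id)
  layer_any <- unique(unlist(de_sets[startsWith(names(de_sets), "layer")]))
  de_sets$layer_any <- layer_any
  age_set <- de_sets$age
  venn <- tibble(
    set = c("age_only", "layer_only", "both", "either"),
    n = c(length(setdiff(age_set, layer_any)),
          length(setdiff(layer_any, age_set)),
          length(intersect(age_set, layer_any)),
          length(union(age_set, layer_any))))
  structure(list(fits = fits, de_sets = de_sets, venn = venn,
                 alpha = alpha, lfc_min = lfc_min),
            class = "contrast_results")
}

#' @export
print.contrast_results <- function(x, ...) {
  cat("<contrast_results>\n")
  for (nm in names(x$fits)) {
    cat(sprintf("  %-10s %4d DE (BH < %g)\n", nm,
                length(x$de_sets[[nm]]), x$alpha))
  }
  invisible(x)
}

#' @export
tidy.contrast_results <- function(x, ...) {
  bind_rows(lapply(x$fits, tidy))
}
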