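#' Spearman rank correlation with average ties
#'
#' Ranks both vectors (average ranks for ties) and takes the Pearson
#' correlation of the ranks.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return the correlation in [-1, 1].
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

match_platform_samples <- function(a, b) {
  key <- function(s) paste(s$animal_id, s$layer, sep = "|")
  ka <- key(a$samples); kb <- key(b$samples)
  shared <- intersect(ka, kb)
  list(a = a$samples$sample_id[match(shared, ka)],
       b = b$samples$sample_id[match(shared, kb)])
}

#' Spearman correlations of miRNA-target pairs
#'
#' For every target record whose miRNA and gene are present in the
#' matrices, computes Spearman's rho over the samples shared between the
#' two platforms (matched by animal and layer; at least 3 required).
#'
#' @param mirna,mrna log2-scale [expr_set]s.
#' @param targets target-record tibble (`mirna_id`, `gene_id`, `source`,
#'   `context_score`).
#' @return a pair-correlation tibble: the target record plus `rho` and
#'   `n_samples`.
#' @export
pair_correlations <- function(mirna, mrna, targets) {
  stopifnot(inherits(mirna, "expr_set"), inherits(mrna, "expr_set"))
  matched <- match_platform_samples(mirna, mrna)
  if (length(matched$a) < 3) abort("fewer than 3 shared samples")
  mv <- mirna$values[, matched$a, drop = FALSE]
  gv <- mrna$values[, matched$b, drop = FALSE]
  present <- filter(targets, .data$mirna_id %in% rownames(mv),
                    .data$gene_id %in% rownames(gv))
  rank_rows <- function(M) {
    out <- t(apply(M, 1, rank, ties.method = "average"))
    rownames(out) <- rownames(M)
    out
  }
  mr <- rank_rows(mv[unique(present$mirna_id), , drop = FALSE])
  gr <- rank_rows(gv[unique(present$gene_id), , drop = FALSE])
  present$rho <- vapply(seq_len(nrow(present)), function(i) {
    cor(mr[present$mirna_id[i], ], gr[present$gene_id[i], ])
  }, 1.0)
  present$n_samples <- length(matched$a)
  present
}

#' The three-requirement negatively-correlated target filter
#'
#' Keeps pairs that (1) are conserved predicted or validated targets,
#' (2) have both the miRNA and the gene differentially expressed in the
#' layer contrast, or both in the age contrast, and (3) are strongly
#' negatively correlated, Spearman's rho strictly below `rho_max`.
#'
#' @param pairs pair-correlation tibble from [pair_correlations()].
#' @param mirna_de list with `age` and `layer` character vectors of DE
#'   miRNA ids.
#' @param gene_de list with `age` and `layer` character vectors of DE gene
#'   ids.
#' @param rho_max strict upper bound on rho (default -0.5).
#' @return the candidate-target tibble with logical DE flags
#'   (`mirna_age`, `mirna_layer`, `gene_age`, `gene_layer`).
#' @export
three_requirement_filter <- function(pairs, mirna_de, gene_de,
                                     rho_max = -0.5) {
  stopifnot(all(c("age", "layer") %in% names(mirna_de)),
            all(c("age", "layer") %in% names(gene_de)))
  mutate(pairs,
         mirna_age = .data$mirna_id %in% mirna_de$age,
         mirna_layer = .data$mirna_id %in% mirna_de$layer,
         gene_age = .data$gene_id %in% gene_de$age,
         gene_layer = .data$gene_id %in% gene_de$layer) |>
    filter(.data$source %in% c("predicted_conserved", "validated"),
           (.data$mirna_age & .data$gene_age) |
             (.data$mirna_layer & .data$gene_layer),
           .data$rho < rho_max)
}

#' Rank candidate targets
#'
#' Applies the minimum-expression filter (gene median normalized log2
#' expression >= `min_median_expr`) and, optionally, requires the gene to
#' be differentially expressed in both the age and layer contrasts, then
#' orders by best (most negative) context score, then most negative rho,
#' ties broken by gene id.
#'
#' @param candidates candidate tibble from [three_requirement_filter()].
#' @param gene_median named vector of per-gene median normalized log2
#'   expression (see [feature_medians()]).
#' @param min_median_expr minimum gene median expression.
#' @param require_both_contrasts require gene DE in both contrasts.
#' @return the ranked candidate tibble with `gene_median_expr` and `rank`.
#' @export
rank_candidates <- function(candidates, gene_median, min_median_expr = 5,
                            require_both_contrasts = TRUE) {
  out <- mutate(candidates,
                gene_median_expr = unname(gene_median[.data$gene_id])) |>
    filter(.data$gene_median_expr >= min_median_expr)
  if (require_both_contrasts) {
    out <- filter(out, .data$gene_age & .data$gene_layer)
  }
  out |>
    arrange(.data$context_score, .data$rho, .data$gene_id) |>
    mutate(rank = dplyr::row_number())
}

#' Most highly expressed miRNAs
#'
#' miRNAs whose median expression lies in the top `q` fraction; ties at the
#' boundary are all included.
#'
#' @param x a log2-scale [expr_set].
#' @param q top fraction in (0, 1].
#' @return character vector of miRNA ids.
#' @export
expression_quartile_filter <- function(x, q = 0.25) {
  if (q <= 0 || q > 1) abort("q must be in (0, 1]")
  med <- feature_medians(x)
  k <- max(1L, ceiling(q * length(med)))
  cut <- sort(med, decreasing = TRUE)[k]
  names(med)[med >= cut]
}

#' Fraction of a gene's predicted sites from the modal module
#'
#' For each gene in the target table, the fraction of its predicted
#' targeting miRNAs (those with module labels; outliers excluded) that
#' belong to the most common (modal) module among them. Genes with no
#' labelled targeting miRNA are missing.
#'
#' @param targets target-record tibble.
#' @param assignment `module_assignment` tibble.
#' @return tibble (`gene_id`, `n_sites`, `modal_module`,
#'   `same_module_fraction`).
#' @export
same_module_site_fraction <- function(targets, assignment) {
  labelled <- filter(assignment, .data$module > 0)
  mod <- setNames(labelled$module, labelled$feature_id)
  distinct(targets, .data$mirna_id, .data$gene_id) |>
    mutate(module = unname(mod[.data$mirna_id])) |>
    filter(!is.na(.data$module)) |>
    group_by(.data$gene_id) |>
    summarise(n_sites = n(),
              modal_module = {
                tt <- table(.data$module)
                as.integer(names(tt)[which.max(tt)])
              },
              same_module_fraction = max(table(.data$module)) / n(),
              .groups = "drop")
}

#' Mann-Whitney U test (exact or tie-corrected normal)
#'
#' Tests whether `x` is stochastically smaller than `y` (one-sided by
#' default). The statistic is U = #{x_i > y_j} + 0.5 #{ties}. With at most
#' 8 observations per side the p value is computed by exact enumeration of
#' all C(n+m, n) group assignments of the combined values (valid under
#' ties); otherwise by the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param x,y numeric samples.
#' @param alternative `"less"` (x smaller), `"greater"`, or `"two.sided"`.
#' @param exact_max largest per-side size for exact enumeration.
#' @return list with `U`, `p`, `method`.
#' @export
mann_whitney_u <- function(x, y, alternative = c("less", "greater",
                                                 "two.sided"),
                           exact_max = 8) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  n <- length(x); m <- length(y)
  u_stat <- function(xv, yv) {
    r <- rank(c(xv, yv), ties.method = "average")
    sum(r[seq_along(xv)]) - length(xv) * (length(xv) + 1) / 2
  }
  u <- u_stat(x, y)
  if (n <= exact_max && m <= exact_max) {
    comb <- combn(n + m, n)
    vals <- c(x, y)
    us <- apply(comb, 2, function(idx) u_stat(vals[idx], vals[-idx]))
    p_less <- mean(us <= u)
    p_greater <- mean(us >= u)
    method <- "exact"
  } else {
    mu <- n * m / 2
    ties <- table(c(x, y))
    nn <- n + m
    sig <- sqrt(n * m / 12 * ((nn + 1) - sum(ties^3 - ties) /
                                (nn * (nn - 1))))
    p_less <- pnorm((u - mu + 0.5) / sig)
    p_greater <- pnorm((u - mu - 0.5) / sig, lower.tail = FALSE)
    method <- "normal"
  }
  p <- switch(alternative,
              less = p_less,
              greater = p_greater,
              two.sided = min(1, 2 * min(p_less, p_greater)))
  list(U = u, p = p, method = method)
}

#' Correlation-skew test of conserved versus control target pairs
#'
#' One-sided Mann-Whitney U test of whether conserved-pair correlations are
#' stochastically smaller (more negative) than control-pair correlations,
#' with optional stacked stringency filters applied to the conserved side
#' first: a stricter context-score threshold, restriction to the most
#' highly expressed miRNAs, and a minimum same-module site fraction for the
#' target gene. The direction (conserved more negative) is fixed a priori.
#'
#' @param pairs pair-correlation tibble from [pair_correlations()].
#' @param conserved_sources sources forming the conserved side.
#' @param context_max optional strict context-score threshold (filter a).
#' @param top_mirnas optional miRNA ids to keep, e.g. from
#'   [expression_quartile_filter()] (filter b).
#' @param min_same_module_fraction optional minimum gene same-module site
#'   fraction (filter c); needs `site_fractions`.
#' @param site_fractions tibble from [same_module_site_fraction()].
#' @return list with `U`, `p_one_sided`, `n_conserved`, `n_control`, and an
#'   `ecdf_data` tibble for plotting.
#' @export
correlation_skew_test <- function(pairs,
                                  conserved_sources = "predicted_conserved",
                                  context_max = NULL,
                                  top_mirnas = NULL,
                                  min_same_module_fraction = NULL,
                                  site_fractions = NULL) {
  control <- filter(pairs, .data$source %in%
                      c("predicted_conserved", "predicted_all"))
  conserved <- filter(pairs, .data$source %in% conserved_sources)
  if (!is.null(context_max)) {
    conserved <- filter(conserved, .data$context_score < context_max)
  }
  if (!is.null(top_mirnas)) {
    conserved <- filter(conserved, .data$mirna_id %in% top_mirnas)
  }
  if (!is.null(min_same_module_fraction)) {
    if (is.null(site_fractions)) {
      abort("site_fractions is needed for the same-module filter")
    }
    ok <- site_fractions$gene_id[
      site_fractions$same_module_fraction >= min_same_module_fraction]
    conserved <- filter(conserved, .data$gene_id %in% ok)
  }
  if (!nrow(conserved)) abort("conserved side is empty after filtering")
  if (!nrow(control)) abort("control side is empty")
  mw <- mann_whitney_u(conserved$rho, control$rho, alternative = "less")
  ecdf_data <- bind_rows(
    tibble(set = "conserved", rho = conserved$rho),
    tibble(set = "control", rho = control$rho))
  list(U = mw$U, p_one_sided = mw$p, method = mw$method,
       n_conserved = nrow(conserved), n_control = nrow(control),
       ecdf_data = ecdf_data)
}
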