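#' Select enrichment query genes from a DE table
#'
#' Genes with |log fold change| strictly greater than `lfc_min` in the
#' stated direction (the boundary value itself is excluded).
#'
#' @param fit a `moderated_fit` or tidy DE table.
#' @param lfc_min strict absolute LFC threshold (default 0.5).
#' @param direction `"up"` (positive lfc) or `"down"`.
#' @param alpha optional BH threshold also required (NULL = LFC only).
#' @return character vector of gene ids.
#' @export
select_query_genes <- function(fit, lfc_min = 0.5,
                               direction = c("up", "down"), alpha = NULL) {
  direction <- match.arg(direction)
  tab <- if (inherits(fit, "moderated_fit")) fit$table else as_tibble(fit)
  if (!is.null(alpha)) tab <- filter(tab, .data$p_adj < alpha)
  tab <- if (direction == "up") {
    filter(tab, .data$lfc > lfc_min)
  } else {
    filter(tab, .data$lfc < -lfc_min)
  }
  tab$feature_id
}

fisher_or <- function(a, b, c_, d) {
  if (any(c(a, b, c_, d) == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    (a * d) / (b * c_)
  }
}

#' Fisher's exact over-representation analysis
#'
#' Per term (intersected with the universe; terms larger than
#' `max_term_size` universe genes are dropped before testing): one-sided
#' hypergeometric p for enrichment, BH adjustment over the tested terms,
#' and the sample odds ratio ad/bc with the Haldane-Anscombe 0.5 correction
#' when any cell is zero.
#'
#' @param query character vector of query genes (subset of the universe;
#'   genes outside it are dropped with a warning).
#' @param universe character vector of background genes.
#' @param terms term tibble from [read_gmt()] or [simulate_terms()].
#' @param max_term_size drop terms with more universe genes than this.
#' @param alpha significance threshold on the adjusted p.
#' @param blocklist term ids to drop before testing (manual curation
#'   stand-in).
#' @return an enrichment tibble (`term_id`, `term_name`, `term_size`,
#'   `universe_size`, `query_size`, `overlap`, `odds_ratio`, `p_raw`,
#'   `p_adj`, `significant`).
#' @export
fisher_enrichment <- function(query, universe, terms, max_term_size = 2500,
                              alpha = 0.05, blocklist = character()) {
  universe <- unique(universe)
  query <- unique(query)
  if (!length(query) || !length(universe)) abort("empty query or universe")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warn(sprintf("%d query gene(s) outside the universe dropped",
                 length(outside)))
    query <- intersect(query, universe)
    if (!length(query)) abort("empty query after universe intersection")
  }
  terms <- filter(terms, !.data$term_id %in% blocklist)
  term_genes <- lapply(terms$genes, intersect, y = universe)
  sizes <- lengths(term_genes)
  keep <- sizes > 0 & sizes <= max_term_size
  terms <- terms[keep, ]
  term_genes <- term_genes[keep]
  sizes <- sizes[keep]
  if (!nrow(terms)) {
    return(tibble(term_id = character(), term_name = character(),
                  term_size = integer(), universe_size = integer(),
                  query_size = integer(), overlap = integer(),
                  odds_ratio = numeric(), p_raw = numeric(),
                  p_adj = numeric(), significant = logical()))
  }
  n_u <- length(universe)
  n_q <- length(query)
  overlap <- vapply(term_genes, function(g) length(intersect(g, query)), 1L)
  p_raw <- phyper(overlap - 1, sizes, n_u - sizes, n_q, lower.tail = FALSE)
  or <- vapply(seq_along(overlap), function(i) {
    a <- overlap[i]
    fisher_or(a, n_q - a, sizes[i] - a, n_u - n_q - sizes[i] + a)
  }, 1.0)
  tibble(term_id = terms$term_id,
         term_name = terms$term_name,
         term_size = sizes,
         universe_size = n_u,
         query_size = n_q,
         overlap = overlap,
         odds_ratio = or,
         p_raw = p_raw,
         p_adj = bh_adjust(p_raw)) |>
    mutate(significant = .data$p_adj < alpha) |>
    arrange(.data$p_adj, .data$term_id)
}

#' Long-format dot-matrix export of enrichment results
#'
#' Binds per-gene-set enrichment tables into one long table with
#' -log10(adjusted p) and odds ratio capped for display (values above the
#' caps are rounded down to them); uncapped values are kept alongside.
#'
#' @param records_by_geneset named list of enrichment tibbles.
#' @param or_cap display cap on the odds ratio (default 12).
#' @param neg_log_p_cap display cap on -log10 adjusted p (default 15).
#' @param significant_only keep only records flagged significant.
#' @return long tibble (`gene_set`, `term_id`, `term_name`, `odds_ratio`,
#'   `neg_log_p`, `or_capped`, `neg_log_p_capped`).
#' @export
export_dot_matrix <- function(records_by_geneset, or_cap = 12,
                              neg_log_p_cap = 15, significant_only = TRUE) {
  long <- bind_rows(records_by_geneset, .id = "gene_set")
  if (significant_only && "significant" %in% names(long)) {
    long <- filter(long, .data$significant)
  }
  mutate(long,
         neg_log_p = -log10(.data$p_adj),
         or_capped = pmin(.data$odds_ratio, or_cap),
         neg_log_p_capped = pmin(.data$neg_log_p, neg_log_p_cap)) |>
    select("gene_set", "term_id", "term_name", "odds_ratio", "neg_log_p",
           "or_capped", "neg_log_p_capped")
}
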