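#' Group design and pairwise contrast for arbitrary sample groups
#'
#' Cell-means design over an arbitrary grouping column (e.g. the
#' stellate/rest qPCR groups).
#'
#' @param samples sample annotation tibble.
#' @param column grouping column name.
#' @return design matrix with one column per group.
#' @export
design_groups <- function(samples, column = "group_extra") {
  g <- samples[[column]]
  if (is.null(g) || anyNA(g)) abort(sprintf("missing grouping column '%s'", column))
  lev <- sort(unique(g))
  X <- vapply(lev, function(l) as.numeric(g == l), numeric(length(g)))
  rownames(X) <- samples$sample_id
  X
}

#' @param design design matrix from [design_groups()].
#' @param numerator,denominator group names.
#' @rdname design_groups
#' @export
contrast_pair <- function(design, numerator, denominator) {
  v <- setNames(numeric(ncol(design)), colnames(design))
  if (!numerator %in% names(v) || !denominator %in% names(v)) {
    abort("contrast group not in design")
  }
  v[numerator] <- 1
  v[denominator] <- -1
  v
}

#' Principal-component QC of an expression matrix
#'
#' Feature-centered PCA of the samples; per-component variance fractions
#' sum to 1.
#'
#' @param x an [expr_set] with >= 2 samples.
#' @return a `pca_qc` list: `fractions` (variance fractions) and `scores`
#'   (tibble of sample scores joined with the annotation).
#' @export
pca_qc <- function(x) {
  stopifnot(inherits(x, "expr_set"), ncol(x$values) >= 2)
  pc <- prcomp(t(x$values), center = TRUE, scale. = FALSE)
  fractions <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(pc$x) |>
    mutate(sample_id = rownames(pc$x)) |>
    left_join(x$samples, by = "sample_id")
  structure(list(fractions = fractions, scores = scores), class = "pca_qc")
}

#' @export
print.pca_qc <- function(x, ...) {
  cat("<pca_qc> variance fractions:",
      paste0(sprintf("%.1f%%", 100 * head(x$fractions, 5)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Cross-platform concordance
#'
#' Spearman correlation between per-feature summary values (medians by
#' default) of two platforms over their shared features.
#'
#' @param a,b [expr_set]s.
#' @param feature_map optional tibble (`feature_a`, `feature_b`) mapping
#'   ids between platforms; default identity on shared row names.
#' @param min_shared minimum number of shared features.
#' @return list with `rho`, `p` (two-sided, t approximation) and
#'   `n_features`.
#' @export
platform_concordance <- function(a, b, feature_map = NULL, min_shared = 10) {
  stopifnot(inherits(a, "expr_set"), inherits(b, "expr_set"))
  med_a <- feature_medians(a)
  med_b <- feature_medians(b)
  if (is.null(feature_map)) {
    shared <- intersect(names(med_a), names(med_b))
    feature_map <- tibble(feature_a = shared, feature_b = shared)
  }
  feature_map <- filter(feature_map, .data$feature_a %in% names(med_a),
                        .data$feature_b %in% names(med_b))
  n <- nrow(feature_map)
  if (n < min_shared) abort("too few shared features")
  rho <- spearman_rho(med_a[feature_map$feature_a],
                      med_b[feature_map$feature_b])
  tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
  list(rho = rho, p = 2 * pt(-abs(tt), df = n - 2), n_features = n)
}

#' Pipeline run configuration
#'
#' Either a simulation block or a list of input paths must be given (not
#' neither). Paths are read with the package readers; the simulation block
#' is a [simulation_config()].
#'
#' @param simulation optional `sim_config`.
#' @param inputs optional named list of paths: `mirna`, `mirna_samples`,
#'   `mrna_counts`, `mrna_samples`, `ct`, `ct_samples`, `targets_targetscan`,
#'   `targets_mirtarbase`, `loci_gff`, `gmt`.
#' @param seed run seed; every randomized stage draws from a fixed child
#'   seed derived from it.
#' @param alpha,lfc_min DE thresholds.
#' @param rho_max three-requirement correlation threshold.
#' @param min_median_expr candidate-ranking expression floor.
#' @param enrich_lfc_min,max_term_size enrichment input/term-size filters.
#' @param max_gap genomic-cluster chaining gap (bp).
#' @param min_module_size,max_k,gap_B PART parameters.
#' @param skew_context_max,skew_top_frac,skew_min_same_module stacked skew
#'   filter settings.
#' @param n_perm co-membership permutations.
#' @return a `run_config` list.
#' @export
pipeline_config <- function(simulation = NULL, inputs = NULL, seed = 1,
                            alpha = 0.05, lfc_min = 0, rho_max = -0.5,
                            min_median_expr = 5, enrich_lfc_min = 0.5,
                            max_term_size = 2500, max_gap = 10000,
                            min_module_size = 5, max_k = 10, gap_B = 50,
                            skew_context_max = -0.3, skew_top_frac = 0.25,
                            skew_min_same_module = 0.5, n_perm = 1000) {
  if (is.null(simulation) && is.null(inputs)) {
    abort("either a simulation block or input paths must be given")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    return(simulate_dataset(sim))
  }
  p <- config$inputs
  list(
    mirna = read_expression(p$mirna, p$mirna_samples, scale = "log2"),
    mrna_counts = read_expression(p$mrna_counts, p$mrna_samples,
                                  scale = "counts"),
    ct = if (!is.null(p$ct)) read_ct(p$ct, p$ct_samples),
    targets = bind_rows(
      if (!is.null(p$targets_targetscan))
        read_targetscan_context(p$targets_targetscan),
      if (!is.null(p$targets_mirtarbase))
        read_mirtarbase(p$targets_mirtarbase)),
    loci = if (!is.null(p$loci_gff)) read_mirbase_gff(p$loci_gff),
    terms = if (!is.null(p$gmt)) read_gmt(p$gmt),
    truth = NULL)
}

#' Run the full analysis pipeline
#'
#' simulate/load -> normalize (array filter + quantile; TMM + log-CPM +
#' quantile + precision weights; delta-Ct) -> differential expression over
#' the standard contrasts -> PART co-expression modules of the DE miRNAs ->
#' genomic cluster calling and module co-membership association ->
#' negatively-correlated target integration, ranking and correlation-skew
#' tests -> Fisher term enrichment -> PCA and cross-platform concordance
#' QC. Deterministic given the config seed; when `out_dir` is given all
#' tables are written as TSV (dendrogram as Newick, loci as GFF3) plus a
#' JSON run report.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return a `pipeline_report` list with all stage results and a `summary`
#'   block of the headline counts.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  data <- load_pipeline_inputs(config)

  ## --- normalize ---
  mirna_norm <- quantile_normalize(filter_features(data$mirna))
  if (!is.null(data$mrna_counts)) {
    factors <- tmm_factors(data$mrna_counts)
    mrna_lcpm <- quantile_normalize(log_cpm(data$mrna_counts, factors))
    w_design <- design_cells(mrna_lcpm$samples, blocking = FALSE)
    mrna_weights <- precision_weights(mrna_lcpm, w_design)
  } else {
    factors <- NULL; mrna_lcpm <- data$mrna; mrna_weights <- NULL
  }
  ct_norm <- if (!is.null(data$ct)) delta_ct_normalize(data$ct)

  ## --- differential expression ---
  mirna_de <- run_all_contrasts(mirna_norm, alpha = config$alpha,
                                lfc_min = config$lfc_min)
  mrna_de <- run_all_contrasts(mrna_lcpm, weights = mrna_weights,
                               alpha = config$alpha,
                               lfc_min = config$lfc_min)
  ct_fit <- NULL
  if (!is.null(ct_norm) && "group_extra" %in% names(ct_norm$samples)) {
    Xg <- design_groups(ct_norm$samples)
    groups <- colnames(Xg)
    ct_fit <- fit_and_moderate(ct_norm, Xg,
                               contrast_pair(Xg, groups[2], groups[1]),
                               contrast_name = paste0(groups[2], "_vs_",
                                                      groups[1]))
  }

  ## --- co-expression modules over the DE miRNAs ---
  de_features <- union(mirna_de$de_sets$age, mirna_de$de_sets$layer_any)
  modules <- NULL; dendro <- NULL; profiles <- NULL
  if (length(de_features) >= config$min_module_size) {
    dendro <- correlation_dendrogram(mirna_norm, de_features)
    modules <- part_partition(mirna_norm, de_features,
                              min_size = config$min_module_size,
                              max_k = config$max_k, B = config$gap_B,
                              seed = config$seed + 11)
    if (any(modules$module > 0)) {
      profiles <- module_profiles(mirna_norm, modules)
    }
  }

  ## --- genomic clusters ---
  clusters <- NULL; association <- NULL
  if (!is.null(data$loci)) {
    clusters <- call_clusters(data$loci, max_gap = config$max_gap)
    if (!is.null(modules) && nrow(clusters) &&
        sum(modules$module > 0) >= 2) {
      association <- co_membership_test(clusters, modules,
                                        n_perm = config$n_perm,
                                        seed = config$seed + 12)
    }
  }

  ## --- target integration ---
  pairs <- NULL; candidates <- NULL; ranked <- NULL
  skew <- NULL; skew_stacked <- NULL
  if (!is.null(data$targets) && nrow(data$targets)) {
    pairs <- pair_correlations(mirna_norm, mrna_lcpm, data$targets)
    mirna_sets <- list(age = mirna_de$de_sets$age,
                       layer = mirna_de$de_sets$layer_any)
    gene_sets <- list(age = mrna_de$de_sets$age,
                      layer = mrna_de$de_sets$layer_any)
    candidates <- three_requirement_filter(pairs, mirna_sets, gene_sets,
                                           rho_max = config$rho_max)
    ranked <- rank_candidates(candidates, feature_medians(mrna_lcpm),
                              min_median_expr = config$min_median_expr)
    skew <- correlation_skew_test(pairs)
    sf <- if (!is.null(modules)) same_module_site_fraction(data$targets,
                                                           modules)
    skew_stacked <- tryCatch(
      correlation_skew_test(
        pairs,
        context_max = config$skew_context_max,
        top_mirnas = expression_quartile_filter(mirna_norm,
                                                config$skew_top_frac),
        min_same_module_fraction = if (!is.null(sf))
          config$skew_min_same_module,
        site_fractions = sf),
      error = function(e) NULL)
  }

  ## --- enrichment ---
  enrichment <- NULL; dot_matrix <- NULL
  if (!is.null(data$terms) && nrow(data$terms)) {
    universe <- rownames(mrna_lcpm$values)
    queries <- list(
      mrna_age_up = select_query_genes(mrna_de$fits$age,
                                       config$enrich_lfc_min, "up",
                                       alpha = config$alpha),
      mrna_age_down = select_query_genes(mrna_de$fits$age,
                                         config$enrich_lfc_min, "down",
                                         alpha = config$alpha),
      mrna_layer_up = select_query_genes(mrna_de$fits$layer,
                                         config$enrich_lfc_min, "up",
                                         alpha = config$alpha),
      mrna_layer_down = select_query_genes(mrna_de$fits$layer,
                                           config$enrich_lfc_min, "down",
                                           alpha = config$alpha))
    queries <- queries[lengths(queries) > 0]
    enrichment <- lapply(queries, fisher_enrichment, universe = universe,
                         terms = data$terms,
                         max_term_size = config$max_term_size,
                         alpha = config$alpha)
    if (length(enrichment)) dot_matrix <- export_dot_matrix(enrichment)
  }

  ## --- QC ---
  qc_pca <- pca_qc(mirna_norm)
  concordance <- NULL
  if (!is.null(data$mrna_counts) &&
      length(intersect(rownames(mirna_norm$values),
                       rownames(mrna_lcpm$values))) >= 10) {
    concordance <- platform_concordance(mirna_norm, mrna_lcpm)
  }

  summary <- list(
    n_de = lapply(mirna_de$de_sets, length),
    n_de_mrna = lapply(mrna_de$de_sets, length),
    venn = mirna_de$venn,
    n_modules = if (!is.null(modules)) length(setdiff(unique(modules$module), 0L)) else 0L,
    module_sizes = if (!is.null(modules)) as.list(table(modules$module[modules$module > 0])) else list(),
    n_outliers = if (!is.null(modules)) sum(modules$module == 0) else NA_integer_,
    n_genomic_clusters = if (!is.null(clusters)) length(unique(clusters$cluster_id)) else 0L,
    association = if (!is.null(association)) {
      association[c("odds_ratio", "fisher_p", "perm_p")]
    },
    n_candidates = if (!is.null(candidates)) nrow(candidates) else 0L,
    n_ranked = if (!is.null(ranked)) nrow(ranked) else 0L,
    skew_p = if (!is.null(skew)) skew$p_one_sided,
    skew_stacked_p = if (!is.null(skew_stacked)) skew_stacked$p_one_sided,
    n_significant_terms = if (!is.null(enrichment)) {
      sum(vapply(enrichment, function(e) sum(e$significant), 1L))
    } else 0L,
    pca_fractions = head(qc_pca$fractions, 5),
    concordance_rho = if (!is.null(concordance)) concordance$rho,
    provenance = list(package = "lamir",
                      version = as.character(utils::packageVersion("lamir")),
                      seed = config$seed))

  report <- structure(
    list(summary = summary, config = config,
         normalized = list(mirna = mirna_norm, mrna = mrna_lcpm,
                           ct = ct_norm, tmm_factors = factors,
                           weights = mrna_weights),
         de = list(mirna = mirna_de, mrna = mrna_de, ct = ct_fit),
         modules = modules, dendrogram = dendro, profiles = profiles,
         clusters = clusters, association = association,
         pairs = pairs, candidates = candidates, ranked = ranked,
         skew = skew, skew_stacked = skew_stacked,
         enrichment = enrichment, dot_matrix = dot_matrix,
         pca = qc_pca, concordance = concordance,
         truth = data$truth),
    class = "pipeline_report")
  if (!is.null(out_dir)) write_pipeline_outputs(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_report>\n")
  cat(sprintf("  DE miRNAs: age %d, layer (any) %d\n",
              s$n_de$age, s$n_de$layer_any))
  cat(sprintf("  modules: %d (+%s outliers)\n", s$n_modules,
              s$n_outliers))
  cat(sprintf("  genomic clusters: %d\n", s$n_genomic_clusters))
  cat(sprintf("  candidate targets: %d (ranked: %d)\n",
              s$n_candidates, s$n_ranked))
  if (!is.null(s$skew_p)) cat(sprintf("  skew p: %.3g\n", s$skew_p))
  invisible(x)
}

#' @export
glance.pipeline_report <- function(x, ...) {
  s <- x$summary
  tibble(n_de_age = s$n_de$age, n_de_layer = s$n_de$layer_any,
         n_modules = s$n_modules,
         n_genomic_clusters = s$n_genomic_clusters,
         n_candidates = s$n_candidates,
         skew_p = s$skew_p %||% NA_real_,
         concordance_rho = s$concordance_rho %||% NA_real_)
}

write_pipeline_outputs <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  write_expression(report$normalized$mirna, fp("mirna_normalized.tsv"),
                   fp("mirna_samples.tsv"))
  write_expression(report$normalized$mrna, fp("mrna_normalized.tsv"),
                   fp("mrna_samples.tsv"))
  if (!is.null(report$normalized$tmm_factors)) {
    readr::write_tsv(tibble(sample_id = names(report$normalized$tmm_factors),
                            tmm_factor = unname(report$normalized$tmm_factors)),
                     fp("tmm_factors.tsv"))
  }
  for (nm in names(report$de$mirna$fits)) {
    readr::write_tsv(tidy(report$de$mirna$fits[[nm]]),
                     fp(paste0("de_mirna_", nm, ".tsv")))
  }
  for (nm in names(report$de$mrna$fits)) {
    readr::write_tsv(tidy(report$de$mrna$fits[[nm]]),
                     fp(paste0("de_mrna_", nm, ".tsv")))
  }
  if (!is.null(report$de$ct)) {
    readr::write_tsv(tidy(report$de$ct), fp("de_ct.tsv"))
  }
  if (!is.null(report$modules)) {
    readr::write_tsv(report$modules, fp("modules.tsv"))
  }
  if (!is.null(report$dendrogram)) {
    ape::write.tree(ape::as.phylo(report$dendrogram), fp("dendrogram.nwk"))
  }
  if (!is.null(report$profiles)) {
    readr::write_tsv(report$profiles, fp("module_profiles.tsv"))
  }
  if (!is.null(report$clusters)) {
    readr::write_tsv(report$clusters, fp("genomic_clusters.tsv"))
  }
  if (!is.null(report$ranked)) {
    readr::write_tsv(report$ranked, fp("candidate_targets.tsv"))
  }
  if (!is.null(report$dot_matrix)) {
    readr::write_tsv(report$dot_matrix, fp("enrichment_dot_matrix.tsv"))
  }
  summary <- report$summary
  summary$venn <- NULL
  jsonlite::write_json(
    c(summary, list(venn = report$de$mirna$venn)),
    fp("report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE,
    force = TRUE)
  invisible(report)
}
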