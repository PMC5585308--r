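#' Planted co-expression module shapes
#'
#' Eight mean log2-shift profiles over the 4 age x 2 layer cells, emulating
#' the qualitative module patterns seen in laminar cortical development: an
#' age ramp up and down (sharp change between P9 and P23), a constant
#' laminar offset in either direction, an age-by-layer interaction (laminar
#' difference that reverses between young and old animals) in either
#' direction, and an early laminar transient (layer difference confined to
#' P2/P9) in either direction. The shapes are pairwise orthogonal or exact
#' mirrors over the eight cells, so modules are mutually distinguishable
#' under correlation distance, and every shape is detectable by at least one
#' of the pipeline's contrasts (age, pooled layer, or per-age layer).
#'
#' @return an 8 x 8 numeric matrix; rows are modules, columns the
#'   `age.layer` cells, unit coefficients (scaled by `effect_size`).
#' @export
default_module_shapes <- function() {
  cells <- as.vector(outer(the_ages, the_layers, paste, sep = "."))
  ramp <- c(-1, -1, 1, 1)
  layer_off <- c(1, 1, 1, 1)
  transient <- c(-1, 1, 0, 0)
  shapes <- rbind(
    age_up = c(ramp, ramp),
    age_down = -c(ramp, ramp),
    lii_up = c(layer_off, -layer_off),
    ldeep_up = -c(layer_off, -layer_off),
    interaction_pos = c(ramp, -ramp),
    interaction_neg = -c(ramp, -ramp),
    early_laminar_pos = c(transient, -transient),
    early_laminar_neg = -c(transient, -transient))
  colnames(shapes) <- cells
  shapes
}

#' Simulation configuration
#'
#' Defines the study design the generator emulates: paired LII/LDeep samples
#' from the same animal at P2/P9/P23/P45, log2-Gaussian expression with
#' planted module shapes, anti-correlated miRNA-driven target genes,
#' genomically clustered co-module miRNAs, and a stellate-vs-rest qPCR
#' contrast. Baseline-dependent measurement noise (lowly expressed miRNAs
#' are noisier) and informative context scores / co-module target sites are
#' part of the generative model; see the methods vignette.
#'
#' @param n_animals_per_age animals per age; each contributes one LII and
#'   one LDeep sample.
#' @param n_mirna,n_mrna feature counts.
#' @param n_modules number of planted co-expression modules (rows taken from
#'   `module_shapes`).
#' @param module_shapes unit-coefficient shift matrix, modules x age.layer
#'   cells.
#' @param module_fraction fraction of miRNAs assigned to modules; the rest
#'   are unregulated background.
#' @param effect_size planted shift magnitude in log2 units multiplying the
#'   shape coefficients.
#' @param effect_sd sd of the per-feature multiplicative loading around 1.
#' @param noise_sd residual log2 noise sd at high expression.
#' @param expr_noise_slope how much extra noise the lowest-baseline miRNAs
#'   get (multiplier runs 1..1+slope from the top to the bottom of the
#'   baseline range).
#' @param baseline_range,gene_baseline_range uniform baseline log2 ranges.
#' @param frac_true_targets fraction of genes that are planted miRNA targets.
#' @param target_slope regulation slope (log2 mRNA per log2 miRNA), < 0.
#' @param driver_weight_power true-target driver miRNAs are sampled with
#'   probability proportional to their baseline percentile to this power
#'   (abundant miRNAs are more likely to exert detectable repression).
#' @param false_conserved_ratio,nonconserved_ratio numbers of false
#'   conserved-predicted and non-conserved predicted pairs, as multiples of
#'   the true-pair count.
#' @param validated_fraction fraction of true pairs also emitted as
#'   validated records.
#' @param context_range_true,context_range_false context-score ranges for
#'   true and false conserved sites (true sites score more negative).
#' @param background_sites_lambda Poisson mean of extra random non-conserved
#'   sites per target-table gene.
#' @param n_comodule_sites,p_comodule extra weak sites on true target genes
#'   drawn from the driver's module with probability `p_comodule`.
#' @param mrna_de_fraction fraction of non-target genes given their own
#'   planted shape (so gene DE sets are non-trivial).
#' @param cluster_fraction per module, fraction of its miRNAs placed in one
#'   genomic cluster; remaining loci are isolated.
#' @param max_intra_cluster_gap_bp maximum within-cluster inter-locus gap.
#' @param n_ct_features,n_ct_replicates,n_ct_up,ct_effect,ct_noise_sd,ct_flag_fraction
#'   qPCR simulation: feature count, replicates per group, planted
#'   stellate-up miRNAs, their delta-Ct (negative = lower Ct = up), noise,
#'   and the fraction of wells flagged Undetermined at random.
#' @param nb_dispersion negative-binomial dispersion used when converting
#'   log2 expression to RNA-seq-like counts.
#' @param n_terms,term_size_range GMT simulation: number of terms and the
#'   size range.
#' @param seed single integer seed; every stage draws from a fixed child
#'   seed derived from it.
#' @return a validated `sim_config` list.
#' @export
simulation_config <- function(n_animals_per_age = 3,
                              n_mirna = 160,
                              n_mrna = 400,
                              n_modules = 8,
                              module_shapes = default_module_shapes(),
                              module_fraction = 0.75,
                              effect_size = 2,
                              effect_sd = 0.1,
                              noise_sd = 0.5,
                              expr_noise_slope = 1,
                              baseline_range = c(4, 12),
                              gene_baseline_range = c(6, 11),
                              frac_true_targets = 0.2,
                              target_slope = -1,
                              driver_weight_power = 4,
                              false_conserved_ratio = 3,
                              nonconserved_ratio = 4,
                              validated_fraction = 0.2,
                              context_range_true = c(-0.8, -0.2),
                              context_range_false = c(-0.5, -0.101),
                              background_sites_lambda = 2,
                              n_comodule_sites = 2,
                              p_comodule = 0.9,
                              mrna_de_fraction = 0.25,
                              cluster_fraction = 0.75,
                              max_intra_cluster_gap_bp = 10000,
                              n_ct_features = 60,
                              n_ct_replicates = 5,
                              n_ct_up = 7,
                              ct_effect = -3,
                              ct_noise_sd = 0.3,
                              ct_flag_fraction = 0.05,
                              nb_dispersion = 0.1,
                              n_terms = 40,
                              term_size_range = c(15, 60),
                              seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_animals_per_age >= 2, n_mirna > 0, n_mrna > 0,
            n_modules >= 1, n_modules <= nrow(module_shapes),
            noise_sd > 0, target_slope < 0,
            frac_true_targets >= 0, frac_true_targets <= 1,
            cluster_fraction >= 0, cluster_fraction <= 1)
  if (round(frac_true_targets * n_mrna) > n_mrna) {
    abort("frac_true_targets implies more target genes than n_mrna")
  }
  structure(cfg, class = "sim_config")
}

child_seed <- function(config, stage) {
  offsets <- c(design = 101L, expression = 202L, loci = 303L,
               targets = 404L, ct = 505L, terms = 606L, counts = 707L)
  as.integer((config$seed + offsets[[stage]]) %% .Machine$integer.max)
}

#' Simulate the paired laminar design
#'
#' For each age, `n_animals_per_age` animals each contribute one LII and one
#' LDeep sample (paired within animal).
#'
#' @param config a [simulation_config()].
#' @param platform platform tag for the samples.
#' @return a sample annotation tibble.
#' @export
simulate_design <- function(config, platform = "array") {
  stopifnot(inherits(config, "sim_config"))
  grid <- tidyr::expand_grid(age = the_ages,
                             animal = seq_len(config$n_animals_per_age),
                             layer = the_layers)
  mutate(grid,
         animal_id = paste0(.data$age, "_a", .data$animal),
         sample_id = paste0(.data$animal_id, "_", .data$layer, "_", platform),
         platform = platform) |>
    select("sample_id", "age", "layer", "animal_id", "platform") |>
    validate_samples()
}

sim_feature_values <- function(ids, baselines, shift_cells, cell_of_sample,
                               noise_sd, noise_mult) {
  n_s <- length(cell_of_sample)
  shift <- shift_cells[, cell_of_sample, drop = FALSE]
  noise <- matrix(rnorm(length(ids) * n_s, sd = noise_sd), nrow = length(ids)) *
    noise_mult
  v <- baselines + shift + noise
  rownames(v) <- ids
  v
}

#' Simulate miRNA and mRNA expression with ground truth
#'
#' miRNA values are baseline + per-feature loading x module shape shift +
#' Gaussian noise (noisier for low-baseline miRNAs); each planted target
#' gene is `baseline + target_slope x (its driver miRNA's realized centered
#' value) + noise`; a fraction of non-target genes carry their own planted
#' shapes; the rest are independent noise.
#'
#' @param config a [simulation_config()].
#' @return a list with `mirna` and `mrna` [expr_set]s (log2 scale) and a
#'   `truth` list (`module`, `targets`, per-contrast DE feature sets).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config, "expression"))
  mirna_design <- simulate_design(config, platform = "array")
  mrna_design <- simulate_design(config, platform = "rnaseq")
  cells <- colnames(config$module_shapes)
  cell_of <- function(design) paste(design$age, design$layer, sep = ".")

  ## --- miRNAs ---
  n_mod_feat <- round(config$module_fraction * config$n_mirna)
  mirna_ids <- sprintf("mir-%03d", seq_len(config$n_mirna))
  module <- rep(0L, config$n_mirna)
  module[seq_len(n_mod_feat)] <- rep_len(seq_len(config$n_modules), n_mod_feat)
  baselines <- runif(config$n_mirna, config$baseline_range[1],
                     config$baseline_range[2])
  pctl <- (baselines - config$baseline_range[1]) /
    diff(config$baseline_range)
  noise_mult <- 1 + config$expr_noise_slope * (1 - pctl)
  loading <- 1 + rnorm(config$n_mirna, sd = config$effect_sd)
  shapes <- config$module_shapes[seq_len(config$n_modules), cells, drop = FALSE]
  shift <- matrix(0, config$n_mirna, length(cells),
                  dimnames = list(mirna_ids, cells))
  in_mod <- module > 0
  shift[in_mod, ] <- loading[in_mod] * config$effect_size *
    shapes[module[in_mod], , drop = FALSE]
  mirna_values <- sim_feature_values(mirna_ids, baselines, shift,
                                     cell_of(mirna_design),
                                     config$noise_sd, noise_mult)
  colnames(mirna_values) <- mirna_design$sample_id
  mirna <- expr_set(mirna_values, mirna_design, scale = "log2")

  ## --- true targets ---
  n_true <- round(config$frac_true_targets * config$n_mrna)
  gene_ids <- sprintf("gene-%04d", seq_len(config$n_mrna))
  target_gene <- gene_ids[seq_len(n_true)]
  module_mirnas <- mirna_ids[in_mod]
  driver_w <- (pmax(pctl[in_mod], 1e-3))^config$driver_weight_power
  drivers <- sample(module_mirnas, n_true, replace = TRUE, prob = driver_w)

  ## --- mRNAs ---
  gene_base <- runif(config$n_mrna, config$gene_baseline_range[1],
                     config$gene_baseline_range[2])
  gene_shift <- matrix(0, config$n_mrna, length(cells),
                       dimnames = list(gene_ids, cells))
  non_target <- setdiff(gene_ids, target_gene)
  n_de_free <- round(config$mrna_de_fraction * length(non_target))
  de_free <- sample(non_target, n_de_free)
  free_shape <- sample.int(config$n_modules, n_de_free, replace = TRUE)
  gene_loading <- 1 + rnorm(config$n_mrna, sd = config$effect_sd)
  gene_shift[de_free, ] <- gene_loading[match(de_free, gene_ids)] *
    config$effect_size * shapes[free_shape, , drop = FALSE]
  mrna_values <- sim_feature_values(gene_ids, gene_base, gene_shift,
                                    cell_of(mrna_design),
                                    config$noise_sd, 1)
  ## planted targets track their driver's realized (centered) expression;
  ## driver and gene samples are matched by (animal, layer)
  m_idx <- match(paste(mrna_design$animal_id, mrna_design$layer),
                 paste(mirna_design$animal_id, mirna_design$layer))
  for (i in seq_len(n_true)) {
    centered <- mirna_values[drivers[i], m_idx] - baselines[match(drivers[i], mirna_ids)]
    mrna_values[target_gene[i], ] <- gene_base[i] +
      config$target_slope * centered +
      rnorm(ncol(mrna_values), sd = config$noise_sd)
  }
  colnames(mrna_values) <- mrna_design$sample_id
  mrna <- expr_set(mrna_values, mrna_design, scale = "log2")

  ## --- planted DE truth from the shift matrices ---
  contrast_of <- function(sh) {
    late <- grepl("^P23\\.|^P45\\.", colnames(sh))
    lii <- grepl("\\.LII$", colnames(sh))
    age_lfc <- rowMeans(sh[, late, drop = FALSE]) -
      rowMeans(sh[, !late, drop = FALSE])
    layer_by_age <- vapply(the_ages, function(a) {
      sh[, paste(a, "LII", sep = ".")] - sh[, paste(a, "LDeep", sep = ".")]
    }, numeric(nrow(sh)))
    pooled <- rowMeans(sh[, lii, drop = FALSE]) -
      rowMeans(sh[, !lii, drop = FALSE])
    list(age = abs(age_lfc) > 1e-9,
         layer = abs(pooled) > 1e-9 |
           apply(abs(layer_by_age) > 1e-9, 1, any))
  }
  mir_truth <- contrast_of(shift)
  ## planted genes: true targets mirror their driver's shape
  gene_eff <- gene_shift
  gene_eff[target_gene, ] <- config$target_slope *
    shift[drivers, , drop = FALSE]
  gene_truth <- contrast_of(gene_eff)

  truth <- list(
    module = tibble(feature_id = mirna_ids, module = module),
    targets = tibble(mirna_id = drivers, gene_id = target_gene),
    de_age_mirna = mirna_ids[mir_truth$age],
    de_layer_mirna = mirna_ids[mir_truth$layer],
    de_age_gene = gene_ids[gene_truth$age],
    de_layer_gene = gene_ids[gene_truth$layer])
  list(mirna = mirna, mrna = mrna, truth = truth)
}

#' Convert log2 expression to RNA-seq-like counts
#'
#' Exponentiates to a per-cell mean, scales by a lognormal per-sample depth,
#' and draws negative-binomial counts, so the TMM / log-CPM paths are
#' exercised on data with realistic overdispersion.
#'
#' @param x a log2-scale [expr_set].
#' @param dispersion NB dispersion (1/size).
#' @param mean_depth target library size.
#' @param seed integer seed.
#' @return a counts-scale [expr_set].
#' @export
simulate_counts <- function(x, dispersion = 0.1, mean_depth = 1e6, seed = 1) {
  stopifnot(inherits(x, "expr_set"))
  set.seed(as.integer(seed))
  rel <- 2^x$values
  rel <- sweep(rel, 2, colSums(rel), "/")
  depth <- mean_depth * exp(rnorm(ncol(rel), sd = 0.2))
  mu <- sweep(rel, 2, depth, "*")
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow = nrow(mu), dimnames = dimnames(x$values))
  samples <- mutate(x$samples, platform = "rnaseq")
  expr_set(counts, samples, scale = "counts")
}

#' Simulate genomic miRNA loci with planted clusters
#'
#' Per module, `cluster_fraction` of its miRNAs are chained on one
#' chromosome with inter-locus gaps below `max_intra_cluster_gap_bp`; all
#' remaining loci are placed at least 10x that gap apart.
#'
#' @param config a [simulation_config()].
#' @param module truth module tibble (`feature_id`, `module`).
#' @return list with `loci` tibble and `true_clusters` (list of id vectors).
#' @export
simulate_loci <- function(config, module) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config, "loci"))
  gap <- config$max_intra_cluster_gap_bp
  far <- 10L * gap
  loci <- list()
  true_clusters <- list()
  chrom_i <- 0L
  cursor <- new.env()
  place <- function(ids, chrom, start0, gaps) {
    width <- round(runif(length(ids), 60, 120))
    starts <- start0 + cumsum(c(0, head(width, -1) + gaps))
    tibble(mirna_id = ids, chrom = chrom, start = starts,
           end = starts + width - 1,
           strand = sample(c("+", "-"), length(ids), replace = TRUE))
  }
  isolated <- character()
  for (m in sort(unique(module$module))) {
    ids <- module$feature_id[module$module == m]
    if (m == 0) { isolated <- c(isolated, ids); next }
    k <- round(config$cluster_fraction * length(ids))
    chrom_i <- chrom_i + 1L
    chrom <- paste0("chr", chrom_i)
    if (k >= 2) {
      members <- ids[seq_len(k)]
      gaps <- round(runif(k - 1, 0.2 * gap, 0.8 * gap))
      loci[[length(loci) + 1]] <- place(members, chrom, 1e6, gaps)
      true_clusters[[length(true_clusters) + 1]] <- members
      isolated <- c(isolated, ids[-seq_len(k)])
    } else {
      isolated <- c(isolated, ids)
    }
  }
  if (length(isolated)) {
    chrom <- paste0("chr", chrom_i + 1L)
    gaps <- round(runif(length(isolated) - 1, far, 2 * far))
    loci[[length(loci) + 1]] <- place(isolated, chrom, 1e6,
                                      if (length(isolated) > 1) gaps else numeric())
  }
  list(loci = bind_rows(loci), true_clusters = true_clusters)
}

#' Simulate target-prediction tables
#'
#' Emits true pairs as strongly scored conserved predictions (a fraction
#' also validated), false conserved pairs with weaker scores, non-conserved
#' control pairs, random background sites on every listed gene, and weak
#' co-module sites on true target genes.
#'
#' @param config a [simulation_config()].
#' @param truth truth list from [simulate_expression()].
#' @return a target-record tibble (`mirna_id`, `gene_id`, `source`,
#'   `context_score`).
#' @export
simulate_targets <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config, "targets"))
  mirna_ids <- truth$module$feature_id
  module <- setNames(truth$module$module, mirna_ids)
  module_mirnas <- mirna_ids[module > 0]
  gene_ids <- unique(c(truth$targets$gene_id,
                       sprintf("gene-%04d", seq_len(config$n_mrna))))
  n_true <- nrow(truth$targets)
  runif_in <- function(n, rng) runif(n, min(rng), max(rng))

  true_rec <- mutate(truth$targets, source = "predicted_conserved",
                     context_score = runif_in(n_true, config$context_range_true))
  validated <- slice_sample(truth$targets,
                            n = round(config$validated_fraction * n_true)) |>
    mutate(source = "validated", context_score = NA_real_)

  rand_pairs <- function(n, genes) {
    tibble(mirna_id = sample(module_mirnas, n, replace = TRUE),
           gene_id = sample(genes, n, replace = TRUE))
  }
  non_target_genes <- setdiff(gene_ids, truth$targets$gene_id)
  false_cons <- rand_pairs(round(config$false_conserved_ratio * n_true),
                           non_target_genes) |>
    mutate(source = "predicted_conserved",
           context_score = runif_in(n(), config$context_range_false))
  noncons <- rand_pairs(round(config$nonconserved_ratio * n_true),
                        non_target_genes) |>
    mutate(source = "predicted_all",
           context_score = runif(n(), -0.099, -0.001))

  table_genes <- unique(c(true_rec$gene_id, false_cons$gene_id,
                          noncons$gene_id))
  n_bg <- rpois(length(table_genes), config$background_sites_lambda)
  background <- tibble(
    gene_id = rep(table_genes, n_bg),
    mirna_id = sample(module_mirnas, sum(n_bg), replace = TRUE),
    source = "predicted_all",
    context_score = runif(sum(n_bg), -0.099, -0.001))

  comod <- purrr::map2_dfr(truth$targets$mirna_id, truth$targets$gene_id,
    function(m, g) {
      same <- runif(config$n_comodule_sites) < config$p_comodule
      pool_same <- setdiff(module_mirnas[module[module_mirnas] == module[[m]]], m)
      pick <- vapply(same, function(s) {
        if (s && length(pool_same)) sample(pool_same, 1)
        else sample(module_mirnas, 1)
      }, "")
      tibble(mirna_id = pick, gene_id = g, source = "predicted_all",
             context_score = runif(length(pick), -0.099, -0.001))
    })

  bind_rows(true_rec, validated, false_cons, noncons, background, comod) |>
    group_by(.data$mirna_id, .data$gene_id, .data$source) |>
    summarise(context_score = ifelse(all(is.na(.data$context_score)),
                                     NA_real_, min(.data$context_score,
                                                   na.rm = TRUE)),
              .groups = "drop")
}

#' Simulate a stellate-vs-rest qPCR Ct experiment
#'
#' Two groups of `n_ct_replicates` samples; planted up-regulated miRNAs have
#' `ct_effect` lower Ct (higher expression) in the stellate group; a random
#' fraction of wells is flagged Undetermined.
#'
#' @param config a [simulation_config()].
#' @return list with `ct` (a masked ct-scale [expr_set]) and `truth_up`
#'   (character vector of planted up-regulated miRNAs).
#' @export
simulate_ct <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config, "ct"))
  ids <- sprintf("mir-%03d", seq_len(config$n_ct_features))
  groups <- rep(c("stellate", "rest"), each = config$n_ct_replicates)
  samples <- tibble(
    sample_id = paste0(groups, "_r", rep(seq_len(config$n_ct_replicates), 2)),
    age = "P2", layer = NA_character_,
    animal_id = paste0("ctanimal_", seq_along(groups)),
    platform = "qpcr", group_extra = groups)
  up <- ids[seq_len(min(config$n_ct_up, length(ids)))]
  base <- runif(length(ids), 22, 32)
  values <- matrix(base, nrow = length(ids), ncol = length(groups))
  values[ids %in% up, groups == "stellate"] <-
    values[ids %in% up, groups == "stellate"] + config$ct_effect
  values <- values + matrix(rnorm(length(values), sd = config$ct_noise_sd),
                            nrow = nrow(values))
  dimnames(values) <- list(ids, samples$sample_id)
  mask <- matrix(runif(length(values)) < config$ct_flag_fraction,
                 nrow = nrow(values), dimnames = dimnames(values))
  values[mask] <- NA_real_
  list(ct = expr_set(values, samples, scale = "ct", mask = mask),
       truth_up = up)
}

#' Simulate term annotations (GMT-style)
#'
#' Random gene-set terms plus one term concentrated in the planted
#' age-responsive genes, so the enrichment stage has signal to find.
#'
#' @param config a [simulation_config()].
#' @param truth truth list from [simulate_expression()].
#' @return a term tibble as from [read_gmt()].
#' @export
simulate_terms <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config, "terms"))
  genes <- sprintf("gene-%04d", seq_len(config$n_mrna))
  sizes <- round(runif(config$n_terms, config$term_size_range[1],
                       config$term_size_range[2]))
  terms <- tibble(
    term_id = sprintf("T%03d", seq_len(config$n_terms)),
    term_name = sprintf("random term %d", seq_len(config$n_terms)),
    genes = lapply(sizes, function(s) sample(genes, s)))
  planted_pool <- unique(c(truth$de_age_gene, truth$targets$gene_id))
  planted <- tibble(
    term_id = "T_planted",
    term_name = "planted age-responsive set",
    genes = list(sample(planted_pool, min(40, length(planted_pool)))))
  bind_rows(terms, planted)
}

#' Simulate a full dataset
#'
#' Bundles design, expression, counts, loci, target tables, qPCR data and
#' term annotations with the complete ground truth.
#'
#' @param config a [simulation_config()].
#' @return a named list (`mirna`, `mrna`, `mrna_counts`, `loci`, `targets`,
#'   `ct`, `terms`, `truth`).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  expr <- simulate_expression(config)
  loci <- simulate_loci(config, expr$truth$module)
  targets <- simulate_targets(config, expr$truth)
  ct <- simulate_ct(config)
  truth <- expr$truth
  truth$clusters <- loci$true_clusters
  truth$ct_up <- ct$truth_up
  list(mirna = expr$mirna,
       mrna = expr$mrna,
       mrna_counts = simulate_counts(expr$mrna,
                                     dispersion = config$nb_dispersion,
                                     seed = child_seed(config, "counts")),
       loci = loci$loci,
       targets = targets,
       ct = ct$ct,
       terms = simulate_terms(config, truth),
       truth = truth)
}
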