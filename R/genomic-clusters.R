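#' Call genomic miRNA clusters by gap chaining
#'
#' Per chromosome, loci are sorted by start and chained while the gap to
#' the next locus (next start - previous end, floored at 0 for overlaps) is
#' at most `max_gap` (inclusive at the boundary, strand-agnostic); maximal
#' chains with at least two members are emitted.
#'
#' @param loci loci tibble (`mirna_id`, `chrom`, `start`, `end`, 1-based
#'   inclusive).
#' @param max_gap maximum inter-locus gap in bp (default 10 kb).
#' @return tibble of cluster members (`cluster_id`, `mirna_id`, `chrom`,
#'   `start`, `end`, `n_members`, `span`), ordered by coordinate.
#' @export
call_clusters <- function(loci, max_gap = 10000) {
  stopifnot(all(c("mirna_id", "chrom", "start", "end") %in% names(loci)))
  if (any(loci$start > loci$end)) abort("locus with start > end")
  ordered <- arrange(loci, .data$chrom, .data$start, .data$end,
                     .data$mirna_id)
  chained <- ordered |>
    group_by(.data$chrom) |>
    mutate(run_end = cummax(.data$end),
           gap = .data$start - lag(.data$run_end, default = NA),
           new_chain = is.na(.data$gap) | pmax(.data$gap, 0) > max_gap,
           chain = cumsum(.data$new_chain)) |>
    group_by(.data$chrom, .data$chain) |>
    mutate(n_members = n(),
           span = max(.data$end) - min(.data$start) + 1) |>
    ungroup() |>
    filter(.data$n_members >= 2)
  if (!nrow(chained)) {
    return(tibble(cluster_id = character(), mirna_id = character(),
                  chrom = character(), start = integer(), end = integer(),
                  n_members = integer(), span = integer()))
  }
  chained |>
    mutate(cluster_id = paste0("cluster_",
                               match(paste(.data$chrom, .data$chain),
                                     unique(paste(.data$chrom, .data$chain))))) |>
    select("cluster_id", "mirna_id", "chrom", "start", "end",
           "n_members", "span")
}

#' Association between genomic clustering and module co-membership
#'
#' Over all unordered pairs of module-labelled miRNAs (outliers excluded),
#' cross-tabulates same-genomic-cluster against same-module membership and
#' reports the sample odds ratio (ad/bc; missing when a margin is zero),
#' the one-sided Fisher (hypergeometric) p, and a permutation p from
#' shuffling module labels. Pairs are not independent, so the Fisher p is
#' descriptive; the permutation p is the calibrated one. `perm_p` is the
#' conservative (1 + #extreme)/(B + 1) value; `perm_p_smoothed` randomizes
#' over ties and is exactly uniform under the null, for calibration
#' diagnostics.
#'
#' @param clusters cluster membership tibble from [call_clusters()].
#' @param assignment `module_assignment` tibble.
#' @param n_perm number of label permutations.
#' @param seed integer seed for the permutations.
#' @return list with `table` (2x2 matrix), `odds_ratio`, `fisher_p`,
#'   `perm_p`, `perm_p_smoothed`, `n_pairs`.
#' @export
co_membership_test <- function(clusters, assignment, n_perm = 1000,
                               seed = 1) {
  labelled <- filter(assignment, .data$module > 0)
  if (nrow(labelled) < 2) abort("need at least 2 module-labelled miRNAs")
  cl <- setNames(clusters$cluster_id, clusters$mirna_id)
  ids <- labelled$feature_id
  mods <- labelled$module
  cls <- unname(cl[ids])
  if (sum(!is.na(cls)) < 2) abort("need at least 2 clustered miRNAs with labels")
  pr <- combn(length(ids), 2)
  same_cluster <- !is.na(cls[pr[1, ]]) & !is.na(cls[pr[2, ]]) &
    cls[pr[1, ]] == cls[pr[2, ]]
  same_mod_of <- function(mods) mods[pr[1, ]] == mods[pr[2, ]]
  same_module <- same_mod_of(mods)
  a <- sum(same_cluster & same_module)
  b <- sum(same_cluster & !same_module)
  c_ <- sum(!same_cluster & same_module)
  d <- sum(!same_cluster & !same_module)
  tab <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
                dimnames = list(c("same_cluster", "diff_cluster"),
                                c("same_module", "diff_module")))
  margins <- c(a + b, c_ + d, a + c_, b + d)
  or <- if (any(margins == 0)) NA_real_ else (a * d) / (b * c_)
  fisher_p <- phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)
  set.seed(as.integer(seed))
  perm_a <- vapply(seq_len(n_perm), function(i) {
    sum(same_cluster & same_mod_of(sample(mods)))
  }, 1.0)
  n_ge <- sum(perm_a >= a)
  n_gt <- sum(perm_a > a)
  perm_p <- (1 + n_ge) / (n_perm + 1)
  perm_p_smoothed <- (n_gt + runif(1) * (1 + n_ge - n_gt)) / (n_perm + 1)
  list(table = tab, odds_ratio = or, fisher_p = fisher_p,
       perm_p = perm_p, perm_p_smoothed = perm_p_smoothed,
       n_pairs = ncol(pr))
}
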