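#' Read an expression table with its sample sheet
#'
#' The table is TSV with feature ids in the first column and one column per
#' sample; the sample sheet is a TSV with the sample annotation columns
#' (`sample_id`, `age`, `layer`, `animal_id`, `platform`, optionally
#' `group_extra`). Samples are returned in sample-sheet order; a sheet sample
#' missing from the table is an error.
#'
#' @param table_path path to the expression TSV.
#' @param sample_sheet_path path to the sample sheet TSV.
#' @param scale scale tag of the values (`"log2"` or `"counts"`).
#' @return an [expr_set].
#' @export
read_expression <- function(table_path, sample_sheet_path,
                            scale = c("log2", "counts")) {
  scale <- match.arg(scale)
  samples <- read_sample_sheet(sample_sheet_path)
  tab <- readr::read_tsv(table_path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (anyDuplicated(tab[[1]])) abort("duplicate feature ids in expression table")
  values <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage <- matrix(as.numeric(values), nrow = nrow(values),
                                     dimnames = list(tab[[1]], colnames(values))))
  if (anyNA(storage) && !anyNA(values)) abort("non-numeric cell in expression table")
  expr_set(storage, samples, scale = scale)
}

#' Write an expression set to TSV
#'
#' Inverse of [read_expression()]; values are written in full precision so the
#' reader/writer pair round-trips.
#'
#' @param x an [expr_set].
#' @param table_path output path for the expression TSV.
#' @param sample_sheet_path optional output path for the sample sheet TSV.
#' @return `x`, invisibly.
#' @export
write_expression <- function(x, table_path, sample_sheet_path = NULL) {
  stopifnot(inherits(x, "expr_set"))
  out <- bind_cols(tibble(feature_id = rownames(x$values)),
                   as_tibble(x$values))
  readr::write_tsv(out, table_path)
  if (!is.null(sample_sheet_path)) write_sample_sheet(x$samples, sample_sheet_path)
  invisible(x)
}

#' Read / write a sample sheet
#'
#' @param path TSV path.
#' @return a validated sample annotation tibble.
#' @export
read_sample_sheet <- function(path) {
  validate_samples(readr::read_tsv(path, show_col_types = FALSE,
                                   col_types = readr::cols(.default = "c")))
}

#' @param samples sample annotation tibble.
#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(samples, path) {
  readr::write_tsv(validate_samples(samples), path)
  invisible(samples)
}

#' Read a qPCR Ct table with reliability flags
#'
#' Cells are either numeric cycle-threshold values or the literal flags
#' `Undetermined` / `Unreliable` (matched case-insensitively). Flagged cells
#' are recorded in a parallel logical mask and their value set to `NA`.
#' Any other non-numeric token is an error.
#'
#' @inheritParams read_expression
#' @return an [expr_set] with `scale = "ct"` and a `mask` matrix.
#' @export
read_ct <- function(table_path, sample_sheet_path) {
  samples <- read_sample_sheet(sample_sheet_path)
  tab <- readr::read_tsv(table_path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (anyDuplicated(tab[[1]])) abort("duplicate feature ids in Ct table")
  chars <- as.matrix(tab[, -1, drop = FALSE])
  flag <- matrix(tolower(chars) %in% c("undetermined", "unreliable"),
                 nrow = nrow(chars))
  suppressWarnings(num <- matrix(as.numeric(chars), nrow = nrow(chars)))
  bad <- !flag & is.na(num) & !is.na(chars)
  if (any(bad)) {
    abort(paste0("unknown token in Ct table: ",
                 paste(unique(chars[bad]), collapse = ", ")))
  }
  num[flag] <- NA_real_
  dimnames(num) <- dimnames(flag) <- list(tab[[1]], colnames(chars))
  expr_set(num, samples, scale = "ct", mask = flag)
}

#' Write a Ct table, re-encoding flagged cells
#'
#' @param x a `ct`-scale [expr_set] with a mask.
#' @param table_path output TSV path.
#' @param sample_sheet_path optional sample sheet output path.
#' @param flag_string token written for masked cells.
#' @return `x`, invisibly.
#' @export
write_ct <- function(x, table_path, sample_sheet_path = NULL,
                     flag_string = "Undetermined") {
  stopifnot(inherits(x, "expr_set"), x$scale == "ct")
  chars <- matrix(as.character(x$values), nrow = nrow(x$values),
                  dimnames = dimnames(x$values))
  if (!is.null(x$mask)) chars[x$mask] <- flag_string
  out <- bind_cols(tibble(feature_id = rownames(chars)), as_tibble(chars))
  readr::write_tsv(out, table_path)
  if (!is.null(sample_sheet_path)) write_sample_sheet(x$samples, sample_sheet_path)
  invisible(x)
}

#' Read a TargetScan-style context-score table
#'
#' Reads a site-level TSV in the layout of TargetScan's conserved-site
#' context-score tables and returns one record per (miRNA, gene) pair with
#' the best (minimum, i.e. strongest) context score. Pairs with a score
#' strictly below `score_threshold` are tagged `predicted_conserved`, the
#' rest `predicted_all`; the inequality is strict, so a score exactly at the
#' threshold stays `predicted_all`.
#'
#' @param path TSV path.
#' @param score_threshold conserved-call threshold on the context score
#'   (default -0.1; more negative = stronger predicted repression).
#' @param columns named character vector mapping the roles `gene`, `mirna`
#'   and `score` to column names in the file; the default matches the
#'   TargetScan v6.2 conserved-site context-score layout.
#' @return a tibble of target records (`mirna_id`, `gene_id`, `source`,
#'   `context_score`).
#' @export
read_targetscan_context <- function(path, score_threshold = -0.1,
                                    columns = c(gene = "Gene Symbol",
                                                mirna = "miRNA",
                                                score = "context+ score")) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  missing <- setdiff(unname(columns), names(tab))
  if (length(missing)) {
    abort(paste0("mapped column(s) absent from file: ",
                 paste(missing, collapse = ", ")))
  }
  tibble(mirna_id = as.character(tab[[columns[["mirna"]]]]),
         gene_id = as.character(tab[[columns[["gene"]]]]),
         context_score = as.numeric(tab[[columns[["score"]]]])) |>
    group_by(.data$mirna_id, .data$gene_id) |>
    summarise(context_score = min(.data$context_score), .groups = "drop") |>
    mutate(source = ifelse(.data$context_score < score_threshold,
                           "predicted_conserved", "predicted_all")) |>
    select("mirna_id", "gene_id", "source", "context_score")
}

#' Read a miRTarBase-style validated-target table
#'
#' @param path TSV path.
#' @param columns named character vector mapping `mirna` and `gene` roles to
#'   column names.
#' @return a tibble of target records with `source = "validated"` and missing
#'   context scores.
#' @export
read_mirtarbase <- function(path, columns = c(mirna = "miRNA",
                                              gene = "Target Gene")) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  missing <- setdiff(unname(columns), names(tab))
  if (length(missing)) {
    abort(paste0("mapped column(s) absent from file: ",
                 paste(missing, collapse = ", ")))
  }
  distinct(tibble(mirna_id = as.character(tab[[columns[["mirna"]]]]),
                  gene_id = as.character(tab[[columns[["gene"]]]]),
                  source = "validated",
                  context_score = NA_real_))
}

#' Read miRNA loci from a miRBase GFF3 file
#'
#' Coordinates are kept 1-based inclusive, the GFF/GenomicRanges convention.
#' By default hairpin records (`miRNA_primary_transcript`) are returned;
#' mature records can be selected instead.
#'
#' @param path GFF3 path.
#' @param feature_type GFF feature type(s) to keep.
#' @return a loci tibble (`mirna_id`, `chrom`, `start`, `end`, `strand`).
#' @export
read_mirbase_gff <- function(path,
                             feature_type = c("miRNA_primary_transcript",
                                              "miRNA")) {
  feature_type <- match.arg(feature_type)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  ids <- if (!is.null(gr$Name)) as.character(gr$Name) else NA_character_
  ids[is.na(ids)] <- if (!is.null(gr$ID)) as.character(gr$ID)[is.na(ids)] else NA
  if (anyNA(ids)) abort("GFF record without ID/Name attribute")
  tibble(mirna_id = ids,
         chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr),
         end = GenomicRanges::end(gr),
         strand = as.character(GenomicRanges::strand(gr)))
}

#' Write miRNA loci as GFF3
#'
#' @param loci loci tibble as returned by [read_mirbase_gff()].
#' @param path output path.
#' @param feature_type GFF feature type to write.
#' @return `loci`, invisibly.
#' @export
write_loci_gff <- function(loci, path,
                           feature_type = "miRNA_primary_transcript") {
  stopifnot(all(c("mirna_id", "chrom", "start", "end", "strand") %in% names(loci)))
  if (any(loci$start > loci$end)) abort("locus with start > end")
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start, end = loci$end),
    strand = ifelse(loci$strand %in% c("+", "-"), loci$strand, "*"))
  gr$type <- feature_type
  gr$ID <- loci$mirna_id
  gr$Name <- loci$mirna_id
  gr$source <- "lamir"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(loci)
}

#' Read term annotations from a GMT file
#'
#' Standard GMT: one term per line, tab-separated fields `term_id`,
#' `term_name`, then member genes. Duplicate genes within a line are
#' deduplicated; a line with fewer than three fields is an error.
#'
#' @param path GMT path.
#' @return a tibble with `term_id`, `term_name` and a `genes` list-column.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble(term_id = character(), term_name = character(),
                  genes = list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short)) {
    abort(sprintf("GMT line %d has fewer than 3 fields", which(short)[1]))
  }
  out <- tibble(term_id = vapply(fields, `[[`, "", 1),
                term_name = vapply(fields, `[[`, "", 2),
                genes = lapply(fields, function(f) unique(f[-(1:2)])))
  if (anyDuplicated(out$term_id)) abort("duplicate term_id in GMT")
  out
}

#' Write term annotations as GMT
#'
#' @param terms tibble as returned by [read_gmt()].
#' @param path output path.
#' @return `terms`, invisibly.
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(seq_len(nrow(terms)), function(i) {
    paste(c(terms$term_id[i], terms$term_name[i], terms$genes[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(terms)
}
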