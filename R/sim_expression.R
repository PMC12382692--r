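#' Simulate an expression count matrix with planted fold changes
#'
#' Counts are negative-binomial with mean `expr_mean` (size
#' `expr_dispersion`); genes in the planted DEG panel have their mean scaled
#' by `2^deg_log2fc` in the low-villus (LVH) group, so positive
#' `deg_log2fc` means higher expression in LVH, matching the LVH-vs-HVH
#' fold-change orientation used throughout.
#'
#' @param config A [sim_config()].
#' @param sim A `sim_genome` result for the same config.
#' @return A list of class `sim_expression`: `counts` (genes x samples
#'   integer matrix), `lengths` (effective gene lengths in bp, the exon
#'   union), `truth` (list with `deg_gene_ids` and per-gene true
#'   `expr_log2fc`), `samples`, `groups`.
#' @export
simulate_expression <- function(config, sim) {
  stopifnot(inherits(config, "sim_config"), inherits(sim, "sim_genome"))
  genes <- sim$models$genes
  panels <- planted_panels(config, genes$gene_id)
  set.seed(child_seed(config$seed, "expression"))

  npg <- config$n_samples_per_group
  samples <- c(paste0("HVH_", seq_len(npg)), paste0("LVH_", seq_len(npg)))
  groups <- stats::setNames(rep(c("HVH", "LVH"), each = npg), samples)
  ng <- nrow(genes)

  lfc <- stats::setNames(rep(0, ng), genes$gene_id)
  lfc[panels$deg] <- config$deg_log2fc
  mu <- cbind(matrix(config$expr_mean, ng, npg),
              matrix(config$expr_mean * 2^lfc, ng, npg))
  counts <- matrix(stats::rnbinom(ng * 2L * npg, mu = as.vector(mu),
                                  size = config$expr_dispersion),
                   nrow = ng,
                   dimnames = list(genes$gene_id, samples))
  storage.mode(counts) <- "integer"
  truth <- list(deg_gene_ids = panels$deg, expr_log2fc = lfc)
  structure(list(counts = counts, lengths = gene_lengths(sim$models),
                 truth = truth, samples = samples, groups = groups),
            class = "sim_expression")
}

#' Effective gene lengths (exon-union width)
#'
#' @param models A `gene_models` object.
#' @return Named integer vector of summed exon widths per gene; genes
#'   without exon features fall back to their genomic span.
#' @export
gene_lengths <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  ex <- models$features[models$features$type == "exon", , drop = FALSE]
  len <- tapply(ex$end - ex$start + 1L, ex$gene_id, sum)
  out <- stats::setNames(models$genes$end - models$genes$start + 1L,
                         models$genes$gene_id)
  out[names(len)] <- as.integer(len)
  out
}

#' Simulate the histology phenotype table
#'
#' Villus heights are normal around the group means (defaults 379.3 um for
#' the high-villus group and 290.7 um for the low-villus group), crypt
#' depths analogous. Negative draws, which the normal model admits but the
#' measurement cannot, are resampled.
#'
#' @param config A [sim_config()].
#' @return A `data.frame` (class `phenotype_table`) with columns `sample`,
#'   `group`, `villus_height`, `crypt_depth` and the recomputed `ratio`
#'   (villus height / crypt depth).
#' @export
simulate_phenotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "phenotype"))
  npg <- config$n_samples_per_group
  samples <- c(paste0("HVH_", seq_len(npg)), paste0("LVH_", seq_len(npg)))
  group <- rep(c("HVH", "LVH"), each = npg)

  rpos <- function(n, mean, sd) {
    x <- stats::rnorm(n, mean, sd)
    while (any(x <= 0)) {
      x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
    }
    x
  }
  vh <- c(rpos(npg, config$vh_mean_high, config$vh_sd),
          rpos(npg, config$vh_mean_low, config$vh_sd))
  cd <- c(rpos(npg, config$cd_mean_high, config$cd_sd),
          rpos(npg, config$cd_mean_low, config$cd_sd))
  phenotype_table(data.frame(sample = samples, group = group,
                             villus_height = vh, crypt_depth = cd,
                             stringsAsFactors = FALSE))
}

#' Validate a phenotype table and recompute the villus/crypt ratio
#'
#' @param df Data frame with columns `sample`, `group`, `villus_height`,
#'   `crypt_depth`. Any pre-existing `ratio` column is discarded and
#'   recomputed.
#' @return The validated data frame with class `phenotype_table`.
#' @export
phenotype_table <- function(df) {
  need <- c("sample", "group", "villus_height", "crypt_depth")
  if (!all(need %in% names(df))) {
    stop("phenotype_table: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  if (length(unique(df$group)) < 2L || any(table(df$group) < 1L)) {
    stop("phenotype_table: need two non-empty groups", call. = FALSE)
  }
  df$ratio <- df$villus_height / df$crypt_depth
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Write a complete synthetic study to a directory
#'
#' Runs all four generators for one configuration and writes `genome.fa`,
#' `genes.gtf`, `sites.vcf` (multi-sample), `expression.tsv`,
#' `gene_lengths.tsv`, `phenotypes.tsv` and `truth.json`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a list with the in-memory stage results
#'   (`genome`, `editing`, `expression`, `phenotypes`) and `dir`.
#' @export
write_study <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- simulate_genome(config)
  ed <- simulate_editing(config, g)
  ex <- simulate_expression(config, g)
  ph <- simulate_phenotypes(config)

  write_genome_fasta(g, file.path(dir, "genome.fa"))
  write_gene_models_gtf(g$models, file.path(dir, "genes.gtf"))
  write_variant_vcf(ed$variants, file.path(dir, "sites.vcf"))
  write_count_matrix(ex$counts, file.path(dir, "expression.tsv"))
  utils::write.table(
    data.frame(gene_id = names(ex$lengths), length = unname(ex$lengths)),
    file.path(dir, "gene_lengths.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(ph), file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- c(ed$truth, ex$truth["expr_log2fc"])
  truth$deg_gene_ids <- ex$truth$deg_gene_ids
  write_truth(truth, file.path(dir, "truth.json"))
  invisible(list(genome = g, editing = ed, expression = ex, phenotypes = ph,
                 dir = dir))
}

#' Write a genes-by-samples count matrix as TSV
#' @param counts Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genes-by-samples count matrix from TSV
#' @param path TSV with a `gene_id` first column and one column per sample.
#' @return Numeric matrix with gene rownames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (all(m == round(m), na.rm = TRUE) && max(m, na.rm = TRUE) < .Machine$integer.max) {
    storage.mode(m) <- "integer"
  }
  m
}
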