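#' Run the complete pipeline on a synthetic study
#'
#' Chains every stage on one configuration: simulate genome, annotation,
#' variant records, expression counts and phenotypes; call, classify and
#' annotate editing sites; aggregate edited reads per gene; test
#' differential editing (REGs, |log2FC| > 1, p < 0.05) and differential
#' expression (DEGs, |log2FC| >= 1, p < 0.05), both oriented LVH vs HVH;
#' run over-representation and preranked GSEA against gene sets; build the
#' nine-quadrant integration; and compute the phenotype statistics (Welch
#' tests on villus height, crypt depth and their ratio) plus Pearson
#' correlations between phenotype and the expression of the jointly planted
#' genes. When `gene_sets` is `NULL`, a default collection is built from
#' the planted ground-truth panels plus random sets of matched sizes, so
#' enrichment has both true and null sets to rank.
#'
#' @param config A [sim_config()].
#' @param gene_sets Optional named list of gene sets.
#' @param n_perm GSEA permutations (default 500).
#' @param out_dir Optional directory; when given, [build_report()] writes
#'   the full table bundle there.
#' @return A list of class `study_result` with elements `config`, `sites`,
#'   `gene_editing`, `expression`, `tpm`, `reg`, `deg`, `overlap`, `pca`,
#'   `histogram`, `ora`, `gsea`, `quadrants`, `phenotypes`,
#'   `phenotype_tests`, `correlations`, `truth`, `thresholds`.
#' @export
run_study <- function(config, gene_sets = NULL, n_perm = 500L,
                      out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  g <- simulate_genome(config)
  ed <- simulate_editing(config, g)
  ex <- simulate_expression(config, g)
  ph <- simulate_phenotypes(config)
  groups <- ed$groups

  es <- call_editing_sites(ed$variants, g$models, g$genome,
                           window = config$flank_window)
  gem <- aggregate_gene_editing(es, g$models)
  reg <- diff_test(gem, groups[colnames(gem)], track = "editing")
  deg <- diff_test(ex$counts, groups[colnames(ex$counts)],
                   track = "expression")
  tpm_mat <- tpm(ex$counts, ex$lengths)

  overlap <- group_overlap(es, groups)
  hist_tab <- frequency_histogram(es, groups)
  pca <- editing_pca(es$frequency)

  if (is.null(gene_sets)) {
    set.seed(child_seed(config$seed, "genesets") + 17L)
    pool <- rownames(ex$counts)
    gene_sets <- list(planted_reg_panel = ed$truth$reg_gene_ids,
                      planted_deg_panel = ex$truth$deg_gene_ids)
    for (k in 1:5) {
      gene_sets[[paste0("random_set_", k)]] <-
        sample(pool, length(ex$truth$deg_gene_ids))
    }
  }
  reg_hits <- reg$gene_id[reg$call != "NS"]
  ora <- ora_test(reg_hits, gene_sets, universe = reg$gene_id)
  ranks <- stats::setNames(deg$log2FoldChange, deg$gene_id)
  ranks <- ranks[!is.na(ranks)]
  gsea <- gsea_preranked(ranks, gene_sets, n_perm = n_perm,
                         seed = child_seed(config$seed, "genesets") + 29L)

  quad <- nine_quadrant(reg, deg, t = 1)

  pheno_tests <- lapply(c(villus_height = "villus_height",
                          crypt_depth = "crypt_depth", ratio = "ratio"),
                        function(f) group_ttest(ph, f,
                                                groups = c("HVH", "LVH")))
  vh <- ph$villus_height[match(colnames(tpm_mat), ph$sample)]
  correlations <- do.call(rbind, lapply(ed$truth$joint_gene_ids, function(gid) {
    r <- pearson_phenotype_correlation(tpm_mat[gid, ], vh)
    data.frame(gene_id = gid, r = r$r, p_value = r$p_value, n = r$n,
               stringsAsFactors = FALSE)
  }))

  thresholds <- list(
    hard_filter = hard_filter_thresholds(),
    retention = retention_thresholds(),
    reg = list(lfc = 1, comparison = "gt", p = 0.05),
    deg = list(lfc = 1, comparison = "ge", p = 0.05),
    quadrant_t = 1,
    gsea = list(weight = 1, n_perm = n_perm, min_size = 5),
    flank_window = config$flank_window,
    seed = config$seed)

  truth <- c(ed$truth, ex$truth["expr_log2fc"])
  res <- structure(list(config = config, sites = es, gene_editing = gem,
                        expression = ex$counts, tpm = tpm_mat,
                        reg = reg, deg = deg, overlap = overlap, pca = pca,
                        histogram = hist_tab, ora = ora, gsea = gsea,
                        quadrants = quad, phenotypes = ph,
                        phenotype_tests = pheno_tests,
                        correlations = correlations,
                        truth = truth, thresholds = thresholds),
                   class = "study_result")
  if (!is.null(out_dir)) build_report(res, out_dir)
  res
}

#' @export
print.study_result <- function(x, ...) {
  reg_n <- attr(x$reg, "counts")
  deg_n <- attr(x$deg, "counts")
  cat("Editome study result\n")
  cat(sprintf("  retained sites: %d; shared between groups: %d\n",
              nrow(x$sites$sites), unname(x$overlap$counts["shared"])))
  cat(sprintf("  REGs: %d up, %d down of %d genes; DEGs: %d up, %d down of %d\n",
              reg_n["n_up"], reg_n["n_down"], reg_n["n_total"],
              deg_n["n_up"], deg_n["n_down"], deg_n["n_total"]))
  cat(sprintf("  quadrant-9 genes: %d (of %d jointly tested)\n",
              sum(x$quadrants$quadrant == 9L), nrow(x$quadrants)))
  cat(sprintf("  villus height Welch p = %.3g (HVH %.1f vs LVH %.1f um)\n",
              x$phenotype_tests$villus_height$p_value,
              x$phenotype_tests$villus_height$means[1],
              x$phenotype_tests$villus_height$means[2]))
  invisible(x)
}

#' Write the study-style report bundle
#'
#' Writes every stage output of a [run_study()] result as TSV tables plus a
#' machine-readable JSON manifest of all thresholds used: retained sites
#' and filter audit, class/region/effect summary tables, gene-level editing
#' matrix, REG and DEG tables with up/down counts, group-overlap and
#' frequency-histogram tables, PCA coordinates, enrichment tables, the
#' quadrant table, phenotype statistics and correlations. Output is
#' deterministic: rerunning the same configuration reproduces the bundle
#' byte for byte.
#'
#' @param result A `study_result` from [run_study()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
build_report <- function(result, dir) {
  stopifnot(inherits(result, "study_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_editing_sites(result$sites, file.path(dir, "editing_sites.tsv"),
                      file.path(dir, "filter_audit.tsv"))
  w(data.frame(table(class = result$sites$sites$edit_class)),
    "site_classes.tsv")
  w(data.frame(table(region = result$sites$sites$region)),
    "site_regions.tsv")
  w(data.frame(table(effect = result$sites$sites$coding_effect)),
    "site_effects.tsv")
  write_count_matrix(result$gene_editing, file.path(dir, "gene_editing.tsv"))
  write_count_matrix(result$expression, file.path(dir, "expression.tsv"))
  w(cbind(data.frame(gene_id = rownames(result$tpm)),
          round(as.data.frame(result$tpm), 4)), "tpm.tsv")
  fmt_res <- function(r) {
    r$baseMean <- round(r$baseMean, 4)
    for (cc in c("log2FoldChange", "lfcSE", "stat", "pvalue", "padj")) {
      r[[cc]] <- signif(r[[cc]], 6)
    }
    r
  }
  w(fmt_res(result$reg), "reg_results.tsv")
  w(fmt_res(result$deg), "deg_results.tsv")
  w(data.frame(set = names(result$overlap$counts),
               n_sites = as.integer(result$overlap$counts)),
    "group_overlap.tsv")
  w(result$histogram, "frequency_histogram.tsv")
  w(cbind(data.frame(sample = rownames(result$pca$coords)),
          round(as.data.frame(result$pca$coords), 6)), "pca_coords.tsv")
  w(data.frame(component = seq_along(result$pca$explained),
               explained = round(result$pca$explained, 6)),
    "pca_explained.tsv")
  ora <- result$ora
  ora$p_value <- signif(ora$p_value, 6)
  w(ora, "ora_results.tsv")
  gs <- result$gsea
  for (cc in c("es", "nes", "p_value")) gs[[cc]] <- signif(gs[[cc]], 6)
  w(gs, "gsea_results.tsv")
  quad <- result$quadrants
  quad$editing_lfc <- signif(quad$editing_lfc, 6)
  quad$expression_lfc <- signif(quad$expression_lfc, 6)
  w(quad, "quadrants.tsv")
  w(data.frame(gene_id = attr(result$quadrants, "single_track")),
    "single_track_genes.tsv")
  ph <- as.data.frame(result$phenotypes)
  ph$villus_height <- round(ph$villus_height, 3)
  ph$crypt_depth <- round(ph$crypt_depth, 3)
  ph$ratio <- round(ph$ratio, 5)
  w(ph, "phenotypes.tsv")
  pt <- do.call(rbind, lapply(names(result$phenotype_tests), function(f) {
    t <- result$phenotype_tests[[f]]
    data.frame(field = f, group1 = t$groups[1], group2 = t$groups[2],
               mean1 = round(t$means[1], 4), mean2 = round(t$means[2], 4),
               sd1 = round(t$sds[1], 4), sd2 = round(t$sds[2], 4),
               t = round(t$t, 5), df = round(t$df, 4),
               p_value = signif(t$p_value, 6), stringsAsFactors = FALSE)
  }))
  w(pt, "phenotype_tests.tsv")
  corr <- result$correlations
  corr$r <- round(corr$r, 5)
  corr$p_value <- signif(corr$p_value, 6)
  w(corr, "correlations.tsv")
  jsonlite::write_json(result$thresholds, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
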