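small_panels <- list(n_reg_genes = 3, n_deg_genes = 3, n_joint_genes = 2)

small_config <- function(...) {
  do.call(sim_config, c(list(...), small_panels))
}

test_that("config validation rejects impossible parameter combinations", {
  expect_s3_class(small_config(n_genes = 10, seed = 1), "sim_config")
  expect_error(sim_config(base_edit_freq = 0.5, reg_freq_shift = 0.6),
               "exceeds 1")
  expect_error(sim_config(n_genes = 10, n_reg_genes = 11), "larger than")
  expect_error(sim_config(n_joint_genes = 30), "exceeds a planted panel")
  expect_error(sim_config(n_samples_per_group = 1), "at least 2")
  expect_error(sim_config(mean_depth = -5), "positive")
})

test_that("simulated genomes are deterministic and byte-identical on disk", {
  cfg <- small_config(n_genes = 15, seed = 9)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$models$features, g2$models$features)

  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.fa"); f2 <- file.path(d, "b.fa")
  write_genome_fasta(g1, f1); write_genome_fasta(g2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  t1 <- file.path(d, "a.gtf"); t2 <- file.path(d, "b.gtf")
  write_gene_models_gtf(g1$models, t1); write_gene_models_gtf(g2$models, t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("gene layout is non-overlapping with in-frame CDS on both strands", {
  st <- cached_study(seed = 42, n_genes = 60)
  genes <- st$g$models$genes
  # pairwise-disjoint intervals by brute scan
  for (i in seq_len(nrow(genes) - 1L)) {
    for (j in (i + 1L):nrow(genes)) {
      expect_true(genes$end[i] < genes$start[j] ||
                    genes$end[j] < genes$start[i])
    }
  }
  expect_true(all(genes$cds_len %% 3L == 0L))
  expect_setequal(unique(genes$strand), c("+", "-"))

  # CDS built on the coding strand: starts with ATG, single terminal stop
  feats <- st$g$models$features
  for (gid in genes$gene_id[genes$biotype == "protein_coding"][1:10]) {
    d <- feats[feats$gene_id == gid & feats$type == "CDS", , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    s <- paste(vapply(seq_len(nrow(d)), function(k) {
      as.character(Biostrings::subseq(st$g$genome[["chr1"]],
                                      d$start[k], d$end[k]))
    }, ""), collapse = "")
    if (genes$strand[genes$gene_id == gid] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    expect_identical(substr(s, 1, 3), "ATG")
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1L)))
  }
})

test_that("gene models survive a GTF round trip", {
  st <- cached_study(seed = 42, n_genes = 60)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gene_models_gtf(st$g$models, path)
  back <- read_gene_models(path)
  expect_setequal(back$genes$gene_id, st$g$models$genes$gene_id)
  key <- function(f) {
    sort(paste(f$gene_id, f$type, f$start, f$end, f$strand))
  }
  expect_identical(key(back$features), key(st$g$models$features))
  m <- match(st$g$models$genes$gene_id, back$genes$gene_id)
  expect_identical(back$genes$biotype[m], st$g$models$genes$biotype)
  expect_identical(back$genes$cds_len[m], st$g$models$genes$cds_len)
})

test_that("an undersized genome length is a sizing error", {
  cfg <- small_config(n_genes = 10, seed = 2)
  expect_error(simulate_genome(cfg, genome_length = 1000L), "smaller than")
  g <- simulate_genome(cfg, genome_length = 10000000L)
  expect_identical(length(g$genome[["chr1"]]), 10000000L)
})

test_that("edited reads respect binomial support and the VCF round-trips", {
  st <- cached_study(seed = 42, n_genes = 60)
  v <- st$ed$variants
  expect_true(all(v$alt_depth <= v$depth))
  expect_true(all(v$alt_depth >= 0L))

  path <- withr::local_tempfile(fileext = ".vcf")
  write_variant_vcf(v, path)
  v2 <- suppressWarnings(read_variant_vcf(path))
  expect_identical(v2$records$pos, v$records$pos)
  expect_identical(v2$records$ref, v$records$ref)
  expect_identical(v2$records$alt, v$records$alt)
  expect_equal(v2$records$qd, v$records$qd)
  expect_equal(v2$records$sor, v$records$sor)
  expect_identical(unname(v2$depth), unname(v$depth))
  expect_identical(unname(v2$alt_depth), unname(v$alt_depth))
  expect_equal(unname(v2$bq), unname(v$bq))
  expect_identical(v2$samples, v$samples)
})

test_that("VCF output is deterministic", {
  cfg <- small_config(n_genes = 12, seed = 5)
  g <- simulate_genome(cfg)
  d <- withr::local_tempdir()
  p1 <- file.path(d, "a.vcf"); p2 <- file.path(d, "b.vcf")
  write_variant_vcf(simulate_editing(cfg, g), p1)
  write_variant_vcf(simulate_editing(cfg, g), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("null editing config plants no group frequency difference", {
  cfg <- sim_config(n_genes = 80, n_reg_genes = 0, n_deg_genes = 0,
                    n_joint_genes = 0, reg_freq_shift = 0, seed = 8)
  g <- simulate_genome(cfg)
  ed <- simulate_editing(cfg, g)
  tr <- ed$truth$site_truth
  expect_true(all(tr$f_high == tr$f_low))
  # empirical group difference averages near zero over sites
  v <- ed$variants
  grp <- ed$groups
  f <- v$alt_depth / pmax(v$depth, 1L)
  dbar <- rowMeans(f[, grp == "HVH", drop = FALSE]) -
    rowMeans(f[, grp == "LVH", drop = FALSE])
  expect_lt(abs(mean(dbar)), 0.01)
})

test_that("planted decoys each violate exactly the planted criterion", {
  st <- cached_study(seed = 42, n_genes = 60)
  tr <- st$ed$truth$site_truth
  hf <- hard_filter(st$ed$variants)
  planted <- !is.na(tr$decoy_criterion)
  expect_gt(sum(planted), 0L)
  expect_true(all(!hf$pass[planted]))
  for (i in which(planted)) {
    expect_true(grepl(tr$decoy_criterion[i], hf$reasons[i], fixed = TRUE))
  }
})

test_that("ground truth round-trips through JSON unchanged", {
  st <- cached_study(seed = 42, n_genes = 60)
  truth <- c(st$ed$truth, st$ex$truth["expr_log2fc"])
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(truth, path)
  back <- read_truth(path)
  expect_identical(back$reg_gene_ids, truth$reg_gene_ids)
  expect_identical(back$deg_gene_ids, truth$deg_gene_ids)
  expect_identical(back$joint_gene_ids, truth$joint_gene_ids)
  expect_equal(back$reg_true_log2fc, truth$reg_true_log2fc)
  expect_equal(back$expr_log2fc, truth$expr_log2fc)
  expect_equal(back$site_truth$pos, truth$site_truth$pos)
  expect_equal(back$site_truth$f_high, truth$site_truth$f_high)
  # planted ids exist in the annotation
  expect_true(all(truth$reg_gene_ids %in% st$g$models$genes$gene_id))
  expect_true(all(truth$deg_gene_ids %in% st$g$models$genes$gene_id))
})

test_that("write_study materializes a complete, readable study directory", {
  cfg <- small_config(n_genes = 12, seed = 21)
  d <- withr::local_tempdir()
  st <- write_study(cfg, d)
  expect_setequal(list.files(d),
                  c("genome.fa", "genes.gtf", "sites.vcf", "expression.tsv",
                    "gene_lengths.tsv", "phenotypes.tsv", "truth.json"))
  models <- read_gene_models(file.path(d, "genes.gtf"))
  expect_identical(models$genes$gene_id, st$genome$models$genes$gene_id)
  v <- suppressWarnings(read_variant_vcf(file.path(d, "sites.vcf")))
  expect_identical(v$records$pos, st$editing$variants$records$pos)
  counts <- read_count_matrix(file.path(d, "expression.tsv"))
  expect_identical(counts, st$expression$counts)
  truth <- read_truth(file.path(d, "truth.json"))
  expect_identical(truth$deg_gene_ids, st$expression$truth$deg_gene_ids)
})

test_that("expression matrix has the right shape and planted fold changes", {
  st <- cached_study(seed = 42, n_genes = 60)
  cfg <- st$cfg
  expect_identical(dim(st$ex$counts),
                   c(cfg$n_genes, 2L * cfg$n_samples_per_group))
  expect_identical(rownames(st$ex$counts), st$g$models$genes$gene_id)
  # same seed reproduces the matrix exactly
  ex2 <- simulate_expression(cfg, st$g)
  expect_identical(st$ex$counts, ex2$counts)
  # planted genes have higher LVH means on average
  lv <- st$ex$groups == "LVH"
  planted <- rownames(st$ex$counts) %in% st$ex$truth$deg_gene_ids
  ratio <- rowMeans(st$ex$counts[planted, lv]) /
    rowMeans(st$ex$counts[planted, !lv])
  expect_gt(median(log2(ratio)), 1.5)
})

test_that("phenotypes match the configured group means", {
  cfg <- small_config(n_genes = 10, seed = 3, vh_sd = 0, cd_sd = 0)
  ph <- simulate_phenotypes(cfg)
  expect_true(all(ph$villus_height[ph$group == "HVH"] == 379.3))
  expect_true(all(ph$villus_height[ph$group == "LVH"] == 290.7))
  expect_equal(ph$ratio, ph$villus_height / ph$crypt_depth)

  # determinism
  cfg2 <- small_config(n_genes = 10, seed = 3)
  expect_identical(simulate_phenotypes(cfg2), simulate_phenotypes(cfg2))

  # large-replicate means approach the configured group centres
  cfgN <- small_config(n_genes = 10, n_samples_per_group = 2000, seed = 3)
  phN <- simulate_phenotypes(cfgN)
  expect_equal(mean(phN$villus_height[phN$group == "HVH"]), 379.3,
               tolerance = 0.01)
  expect_equal(mean(phN$villus_height[phN$group == "LVH"]), 290.7,
               tolerance = 0.01)
})
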