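test_that("hard filter flags each criterion and passes exact boundaries", {
  v <- toy_variants(qd = c(1.5, 10))
  hf <- hard_filter(v, depth_deviation = FALSE)
  expect_false(hf$pass[1])
  expect_identical(hf$reasons[1], "QD")
  expect_true(hf$pass[2])

  # boundary values are not violations (strict inequalities)
  vb <- toy_variants(qd = 2.0, fs = 60.0, mqranksum = -12.5,
                     readposranksum = -8.0, mq = 40.0, sor = 3.0)
  expect_true(hard_filter(vb, depth_deviation = FALSE)$pass)

  # each criterion individually
  cases <- list(
    list(args = list(qd = 1.9), reason = "QD"),
    list(args = list(fs = 60.1), reason = "FS"),
    list(args = list(mqranksum = -12.6), reason = "MQRankSum"),
    list(args = list(readposranksum = -8.1), reason = "ReadPosRankSum"),
    list(args = list(mq = 39.9), reason = "MQ"),
    list(args = list(sor = 3.1), reason = "SOR"))
  for (cs in cases) {
    hf <- hard_filter(do.call(toy_variants, cs$args),
                      depth_deviation = FALSE)
    expect_false(hf$pass)
    expect_identical(hf$reasons, cs$reason)
  }
})

test_that("depth-deviation rule discards sites with outlier sample depths", {
  d <- matrix(c(50L, 50L, 50L, 50L,
                10L, 50L, 50L, 50L,    # 10 < mean(40)/3
                50L, 50L, 50L, 500L),  # 500 > 3*mean(162.5)
              nrow = 3, byrow = TRUE)
  v <- toy_variants(qd = c(10, 10, 10), depth = d,
                    alt_depth = matrix(5L, 3, 4), bq = 35, n_samples = 4L)
  hf <- hard_filter(v)
  expect_identical(hf$pass, c(TRUE, FALSE, FALSE))
  expect_identical(hf$reasons[2:3], c("depth_dev", "depth_dev"))
  # rule can be disabled
  expect_true(all(hard_filter(v, depth_deviation = FALSE)$pass))
})

test_that("missing annotations follow the configured policy", {
  v <- toy_variants(qd = c(NA, 10))
  hf <- hard_filter(v, depth_deviation = FALSE)
  expect_false(hf$pass[1])
  expect_identical(hf$reasons[1], "missing:QD")
  hf2 <- hard_filter(v, depth_deviation = FALSE, missing = "pass")
  expect_true(all(hf2$pass))
})

test_that("hard filter and retention agree with the brute-force re-checker", {
  st <- cached_study(seed = 42, n_genes = 60)
  v <- st$ed$variants
  hf <- hard_filter(v)
  orc <- oracle_hard_filter(v)
  expect_identical(hf$pass, orc$pass)
  got <- lapply(strsplit(hf$reasons, ","), function(x) sort(x[nzchar(x)]))
  expect_identical(got, orc$reasons)

  rt <- retain_site(v)
  orc2 <- oracle_retain(v)
  expect_identical(unname(rt$call_retained), unname(orc2$call_retained))
  expect_identical(unname(rt$site_retained), unname(orc2$site_retained))
})

test_that("editing frequency is alt over total depth with guarded errors", {
  expect_equal(editing_frequency(3, 5), 0.6)
  expect_equal(editing_frequency(5, 5), 1.0)
  expect_equal(editing_frequency(0, 10), 0.0)
  expect_error(editing_frequency(1, 0), "positive")
  expect_error(editing_frequency(6, 5), "exceeds")
})

test_that("retention boundaries are inclusive as printed", {
  # depth 5, alt 3, BQ 25, f 0.6: every threshold exactly at its boundary
  v <- toy_variants(depth = 5L, alt_depth = 3L, bq = 25, n_samples = 1L)
  rt <- retain_site(v)
  expect_true(rt$site_retained)

  cases <- list(list(depth = 20L, alt_depth = 1L, bq = 35),  # alt 1 < 3
                list(depth = 4L, alt_depth = 3L, bq = 35),   # depth 4 < 5
                list(depth = 20L, alt_depth = 8L, bq = 24.9),
                list(depth = 40L, alt_depth = 3L, bq = 35))  # f 0.075 < 0.1
  for (cs in cases) {
    rt <- retain_site(do.call(toy_variants, c(cs, n_samples = 1L)))
    expect_false(rt$site_retained)
  }
})

test_that("retained set grows monotonically as thresholds relax", {
  st <- cached_study(seed = 42, n_genes = 60)
  v <- st$ed$variants
  th <- retention_thresholds()
  base <- retain_site(v, th)$site_retained
  th$min_depth <- 3L
  relaxed <- retain_site(v, th)$site_retained
  expect_true(all(relaxed[base]))
  expect_gte(sum(relaxed), sum(base))

  th2 <- retention_thresholds()
  th2$min_alt_depth <- 2L
  relaxed2 <- retain_site(v, th2)$site_retained
  expect_true(all(relaxed2[base]))
})

test_that("substitution classes cover all 12 changes on both strands", {
  subs <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  subs <- subs[subs$ref != subs$alt, ]
  expected <- function(r, a) {
    p <- paste0(r, ">", a)
    if (p %in% c("A>G", "T>C")) "A-to-I"
    else if (p %in% c("C>T", "G>A")) "C-to-U"
    else "other"
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(nrow(subs))) {
    r <- subs$ref[i]; a <- subs$alt[i]
    plus <- classify_substitution(r, a, "+")
    expect_identical(plus$edit_class, expected(r, a))
    expect_identical(plus$substitution, paste0(r, ">", a))
    # minus strand: complemented before lookup
    minus <- classify_substitution(r, a, "-")
    expect_identical(minus$edit_class, expected(comp[[r]], comp[[a]]))
    # default-mode strand consistency
    expect_identical(plus$edit_class,
                     classify_substitution(comp[[r]], comp[[a]], "-")$edit_class)
  }
  # unknown strand flagged, classified literally
  u <- classify_substitution("C", "T", "*")
  expect_true(u$strand_unresolved)
  expect_identical(u$edit_class, "C-to-U")
})

test_that("literal mode reads the printed pairs verbatim", {
  expect_identical(classify_substitution("T", "A", "+", mode = "literal")$edit_class,
                   "A-to-I")
  expect_identical(classify_substitution("T", "C", "+", mode = "literal")$edit_class,
                   "other")
  expect_identical(classify_substitution("C", "T", "+", mode = "literal")$edit_class,
                   "C-to-U")
  expect_error(classify_substitution("N", "A"), "A, C, G or T")
  expect_error(classify_substitution("A", "A"), "must differ")
})

test_that("region annotation matches a hand-built two-strand gene model", {
  # gp (+): exon 101-200 (5'UTR 101-150, CDS 151-200), intron 201-300,
  #         exon 301-460 (CDS 301-400, 3'UTR 401-460)
  # gm (-): mirrored layout; transcript runs right to left, so the 5'UTR
  #         is the rightmost block: exon 5101-5260 (3'UTR 5101-5160,
  #         CDS 5161-5260), intron 5261-5300, exon 5301-5460
  #         (CDS 5301-5400, 5'UTR 5401-5460)
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                      start = c(101L, 5101L), end = c(460L, 5460L),
                      strand = c("+", "-"),
                      biotype = "protein_coding",
                      tx_len = 0L, utr5_len = 0L, cds_len = 0L,
                      stringsAsFactors = FALSE)
  features <- data.frame(
    gene_id = c(rep("gp", 6), rep("gm", 6)),
    type = c("exon", "five_prime_utr", "CDS", "exon", "CDS",
             "three_prime_utr",
             "exon", "three_prime_utr", "CDS", "exon", "CDS",
             "five_prime_utr"),
    chrom = "chr1",
    start = c(101L, 101L, 151L, 301L, 301L, 401L,
              5101L, 5101L, 5161L, 5301L, 5301L, 5401L),
    end = c(200L, 150L, 200L, 460L, 400L, 460L,
            5260L, 5160L, 5260L, 5460L, 5400L, 5460L),
    strand = c(rep("+", 6), rep("-", 6)),
    stringsAsFactors = FALSE)
  models <- editomics:::new_gene_models(genes, features)

  cases <- rbind(
    data.frame(pos = 120L, region = "5UTR"),
    data.frame(pos = 160L, region = "exonic"),     # plus CDS
    data.frame(pos = 202L, region = "splicing"),   # 2 bp into intron
    data.frame(pos = 250L, region = "intronic"),
    data.frame(pos = 299L, region = "splicing"),
    data.frame(pos = 420L, region = "3UTR"),
    data.frame(pos = 50L, region = "upstream"),    # window 400 before TSS
    data.frame(pos = 700L, region = "downstream"),
    data.frame(pos = 3000L, region = "intergenic"),
    data.frame(pos = 5120L, region = "3UTR"),      # minus: 3'UTR at left
    data.frame(pos = 5420L, region = "5UTR"),
    data.frame(pos = 5290L, region = "intronic"),
    data.frame(pos = 5262L, region = "splicing"),
    data.frame(pos = 5350L, region = "exonic"),
    data.frame(pos = 5500L, region = "upstream"),  # right of minus gene
    data.frame(pos = 5050L, region = "downstream"))
  ann <- annotate_region(rep("chr1", nrow(cases)), cases$pos, models,
                         window = 400L)
  expect_identical(as.character(ann$region), cases$region)
  expect_error(annotate_region("chrX", 5L, models), "unknown contig")
})

test_that("region annotation equals the interval-scan oracle on simulations", {
  st <- cached_study(seed = 42, n_genes = 60)
  sites <- st$es$sites
  ann <- annotate_region(sites$chrom, sites$pos, st$g$models, window = 1000L)
  orc <- oracle_region(sites$chrom, sites$pos, st$g$models, window = 1000L)
  expect_identical(as.character(ann$region), orc$region)
  expect_identical(ann$gene_id, orc$gene_id)
})

test_that("coding effects follow the genetic code, including CAA to UAA", {
  # one-exon plus-strand gene, CDS = ATG CAA CTT TAA at positions 101-112
  genome <- Biostrings::DNAStringSet(paste0(
    paste(rep("G", 100), collapse = ""), "ATGCAACTTTAA",
    paste(rep("G", 100), collapse = "")))
  names(genome) <- "chr1"
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 101L,
                      end = 112L, strand = "+", biotype = "protein_coding",
                      tx_len = 12L, utr5_len = 0L, cds_len = 12L,
                      stringsAsFactors = FALSE)
  features <- data.frame(gene_id = "g1", type = c("exon", "CDS"),
                         chrom = "chr1", start = 101L, end = 112L,
                         strand = "+", stringsAsFactors = FALSE)
  models <- editomics:::new_gene_models(genes, features)
  # C-to-U at first base of codon 2: CAA -> TAA (premature stop)
  eff <- annotate_coding_effect("chr1", 104L, "C", "T", models, genome)
  expect_identical(as.character(eff), "stopgain")
  # CTT -> CTC: synonymous (Leu)
  eff2 <- annotate_coding_effect("chr1", 109L, "T", "C", models, genome)
  expect_identical(as.character(eff2), "synonymous")
  # TAA -> CAA: stoploss
  eff3 <- annotate_coding_effect("chr1", 110L, "T", "C", models, genome)
  expect_identical(as.character(eff3), "stoploss")
  # outside CDS: noncoding
  eff4 <- annotate_coding_effect("chr1", 50L, "G", "A", models, genome)
  expect_identical(as.character(eff4), "noncoding")

  # same codons on the minus strand
  genome_m <- Biostrings::DNAStringSet(paste0(
    paste(rep("G", 100), collapse = ""),
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString("ATGCAACTTTAA"))),
    paste(rep("G", 100), collapse = "")))
  names(genome_m) <- "chr1"
  genes$strand <- "-"
  features$strand <- "-"
  models_m <- editomics:::new_gene_models(genes, features)
  # codon-2 C (transcript) sits at genomic position 109 as G; C>T on the
  # coding strand is G>A on the reference strand
  eff_m <- annotate_coding_effect("chr1", 109L, "G", "A", models_m, genome_m)
  expect_identical(as.character(eff_m), "stopgain")
})

test_that("all nine single-base variants of sampled codons match the lookup", {
  codons <- c("CAA", "TGG", "ATG", "TTA", "TCG", "GGG", "AAA", "TAC",
              "CGA", "TAT")
  pad <- paste(rep("G", 99), collapse = "")
  for (codon in codons) {
    genome <- Biostrings::DNAStringSet(paste0(pad, "ATG", codon, "TAA", pad))
    names(genome) <- "chr1"
    genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 100L,
                        end = 108L, strand = "+",
                        biotype = "protein_coding", tx_len = 9L,
                        utr5_len = 0L, cds_len = 9L, stringsAsFactors = FALSE)
    features <- data.frame(gene_id = "g1", type = c("exon", "CDS"),
                           chrom = "chr1", start = 100L, end = 108L,
                           strand = "+", stringsAsFactors = FALSE)
    models <- editomics:::new_gene_models(genes, features)
    for (off in 1:3) {
      ref <- substr(codon, off, off)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        eff <- annotate_coding_effect("chr1", 102L + off, ref, alt,
                                      models, genome)
        expect_identical(as.character(eff),
                         oracle_codon_effect(codon, off, alt),
                         info = paste(codon, off, alt))
      }
    }
  }
})

test_that("the calling pipeline composes filters and annotates sites", {
  st <- cached_study(seed = 42, n_genes = 60)
  es <- st$es
  v <- st$ed$variants
  hf <- hard_filter(v)
  rt <- retain_site(v)
  expect_identical(nrow(es$sites), sum(hf$pass & rt$site_retained))
  expect_identical(nrow(es$audit), nrow(v$records))
  # retained frequencies lie inside the retention band
  f <- es$frequency[es$call_retained]
  expect_true(all(f >= 0.10 & f <= 1.00))
  # masked positions are excluded
  mask <- data.frame(chrom = "chr1", start = min(v$records$pos),
                     end = stats::median(v$records$pos))
  es2 <- call_editing_sites(v, st$g$models, st$g$genome, exclude = mask)
  expect_true(all(es2$sites$pos > stats::median(v$records$pos)))
  expect_true(any(es2$audit$stage == "masked"))
})
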