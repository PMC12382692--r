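HARD_FILTER_CRITERIA <- c("QD", "FS", "MQRankSum", "ReadPosRankSum",
                          "MQ", "SOR", "depth_dev")

# Planted gene panels (REG / DEG / jointly planted), derived from the master
# seed alone so the editing and expression generators agree on them.
planted_panels <- function(config, gene_ids) {
  set.seed(child_seed(config$seed, "genesets"))
  joint <- sample(gene_ids, config$n_joint_genes)
  pool <- setdiff(gene_ids, joint)
  reg_extra <- sample(pool, config$n_reg_genes - config$n_joint_genes)
  pool <- setdiff(pool, reg_extra)
  deg_extra <- sample(pool, config$n_deg_genes - config$n_joint_genes)
  list(reg = sort(c(joint, reg_extra)),
       deg = sort(c(joint, deg_extra)),
       joint = sort(joint))
}

#' Assemble a variant-record set from its components
#'
#' Container used throughout the calling pipeline: one row of site-level
#' annotations per candidate record plus per-sample depth, edited-read
#' depth and mean alt base-quality matrices.
#'
#' @param records Data frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   the quality annotations `qd`, `fs`, `mqranksum`, `readposranksum`,
#'   `mq`, `sor` (NA allowed).
#' @param depth,alt_depth,bq Sites x samples matrices.
#' @param samples Sample ids (column order of the matrices).
#' @param contig_lengths Named vector of contig lengths (for VCF output).
#' @return A `variant_records` object.
#' @export
variant_records <- function(records, depth, alt_depth, bq, samples,
                            contig_lengths = NULL) {
  need <- c("chrom", "pos", "ref", "alt", "qd", "fs", "mqranksum",
            "readposranksum", "mq", "sor")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("variant_records: records lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(records$ref == records$alt)) {
    stop("variant_records: ref and alt must differ", call. = FALSE)
  }
  if (is.null(contig_lengths)) {
    contig_lengths <- tapply(records$pos, records$chrom, max)
  }
  new_variant_records(records, depth, alt_depth, bq, samples, contig_lengths)
}

new_variant_records <- function(records, depth, alt_depth, bq, samples,
                                contig_lengths) {
  stopifnot(nrow(records) == nrow(depth),
            identical(dim(depth), dim(alt_depth)),
            identical(dim(depth), dim(bq)),
            ncol(depth) == length(samples))
  storage.mode(depth) <- "integer"
  storage.mode(alt_depth) <- "integer"
  if (any(alt_depth > depth, na.rm = TRUE)) {
    stop("variant_records: alt_depth exceeds depth", call. = FALSE)
  }
  colnames(depth) <- colnames(alt_depth) <- colnames(bq) <- samples
  structure(list(records = records, depth = depth, alt_depth = alt_depth,
                 bq = bq, samples = samples, contig_lengths = contig_lengths),
            class = "variant_records")
}

#' @export
print.variant_records <- function(x, ...) {
  cat(sprintf("variant_records: %d candidate sites x %d samples\n",
              nrow(x$records), length(x$samples)))
  invisible(x)
}

#' Number of candidate sites in a variant set
#' @param x A `variant_records` object.
#' @return Integer count of records.
#' @export
n_variants <- function(x) nrow(x$records)

#' Simulate per-sample editing variant records with planted ground truth
#'
#' For every gene a Poisson number of candidate sites is placed (mostly
#' inside the gene body, some in the flanking windows), plus a small set of
#' intergenic sites. Site depths are negative-binomial, edited-read counts
#' binomial at the site's true group frequency; genes in the planted REG
#' panel have their frequency shifted upward by `reg_freq_shift` in the
#' high-villus group. A `canonical_fraction` of sites are constructed as
#' strand-consistent A-to-I or C-to-U substitutions. Site-level quality
#' annotations (QD, FS, MQRankSum, ReadPosRankSum, MQ, SOR) are drawn from
#' clearly passing ranges, except for a `decoy_fraction` of records each
#' planted to violate exactly one hard-filter criterion (including the
#' depth-deviation rule, planted as one sample at ten times the mean depth).
#'
#' @param config A [sim_config()].
#' @param sim A `sim_genome` result for the same config.
#' @return A list of class `sim_editing`: `variants` (a `variant_records`
#'   object), `truth` (ground-truth list with panels, per-site true group
#'   frequencies, decoy attributions and true per-gene editing log2 fold
#'   changes), `samples` and `groups`.
#' @export
simulate_editing <- function(config, sim) {
  stopifnot(inherits(config, "sim_config"), inherits(sim, "sim_genome"))
  genes <- sim$models$genes
  panels <- planted_panels(config, genes$gene_id)
  set.seed(child_seed(config$seed, "editing"))

  npg <- config$n_samples_per_group
  samples <- c(paste0("HVH_", seq_len(npg)), paste0("LVH_", seq_len(npg)))
  groups <- stats::setNames(rep(c("HVH", "LVH"), each = npg), samples)
  chrom_seq <- strsplit(as.character(sim$genome[["chr1"]]), "")[[1]]
  glen <- length(chrom_seq)
  w <- config$flank_window

  pos_l <- integer(0); ref_l <- character(0); alt_l <- character(0)
  gene_l <- character(0); strand_l <- character(0); canon_l <- logical(0)

  pick_site <- function(lo, hi, strand, canonical) {
    # For canonical sites the base on the gene strand must be A or C.
    for (try in 1:80) {
      p <- sample(lo:hi, 1L)
      b <- chrom_seq[p]
      onstrand <- if (strand == "-") comp_base(b) else b
      if (!canonical || onstrand %in% c("A", "C")) {
        return(list(pos = p, ref = b, onstrand = onstrand))
      }
    }
    list(pos = p, ref = b, onstrand = onstrand)
  }
  canonical_alt <- function(onstrand_ref, strand) {
    a <- if (onstrand_ref == "A") "G" else if (onstrand_ref == "C") "T"
    else if (onstrand_ref == "T") "C" else "A"   # literal fallback
    if (strand == "-") comp_base(a) else a
  }
  other_alt <- function(ref) {
    # Avoid the strand-collapsed canonical partner so the class is 'other'.
    partner <- c(A = "G", T = "C", C = "T", G = "A")[[ref]]
    sample(setdiff(BASES, c(ref, partner)), 1L)
  }

  for (i in seq_len(nrow(genes))) {
    n_s <- max(1L, stats::rpois(1L, config$mean_sites_per_gene))
    for (k in seq_len(n_s)) {
      in_body <- stats::runif(1) < 0.85
      lo <- if (in_body) genes$start[i] else genes$start[i] - w
      hi <- if (in_body) genes$end[i] else genes$end[i] + w
      canonical <- stats::runif(1) < config$canonical_fraction
      s <- pick_site(max(1L, lo), min(glen, hi), genes$strand[i], canonical)
      canonical <- canonical && s$onstrand %in% c("A", "C")
      alt <- if (canonical) canonical_alt(s$onstrand, genes$strand[i])
             else other_alt(s$ref)
      pos_l <- c(pos_l, s$pos); ref_l <- c(ref_l, s$ref); alt_l <- c(alt_l, alt)
      gene_l <- c(gene_l, genes$gene_id[i])
      strand_l <- c(strand_l, genes$strand[i]); canon_l <- c(canon_l, canonical)
    }
  }

  # Intergenic sites: outside every gene span +/- flank window.
  n_ig <- round(config$intergenic_fraction * length(pos_l))
  spans <- cbind(pmax(1L, genes$start - w), pmin(glen, genes$end + w))
  ig <- 0L
  while (ig < n_ig) {
    p <- sample.int(glen, 1L)
    if (any(p >= spans[, 1] & p <= spans[, 2])) next
    ref <- chrom_seq[p]
    canonical <- stats::runif(1) < config$canonical_fraction
    alt <- if (canonical) c(A = "G", T = "C", C = "T", G = "A")[[ref]]
           else other_alt(ref)
    pos_l <- c(pos_l, p); ref_l <- c(ref_l, ref); alt_l <- c(alt_l, alt)
    gene_l <- c(gene_l, NA_character_)
    strand_l <- c(strand_l, "*"); canon_l <- c(canon_l, canonical)
    ig <- ig + 1L
  }

  ord <- order(pos_l)
  pos_l <- pos_l[ord]; ref_l <- ref_l[ord]; alt_l <- alt_l[ord]
  gene_l <- gene_l[ord]; strand_l <- strand_l[ord]; canon_l <- canon_l[ord]
  dup <- duplicated(pos_l)
  pos_l <- pos_l[!dup]; ref_l <- ref_l[!dup]; alt_l <- alt_l[!dup]
  gene_l <- gene_l[!dup]; strand_l <- strand_l[!dup]; canon_l <- canon_l[!dup]
  ns <- length(pos_l)
  nsamp <- length(samples)

  f_base <- stats::runif(ns, config$base_edit_freq - config$freq_jitter,
                         config$base_edit_freq + config$freq_jitter)
  is_reg <- !is.na(gene_l) & gene_l %in% panels$reg
  f_low <- f_base
  f_high <- f_base + ifelse(is_reg, config$reg_freq_shift, 0)
  if (any(f_high > 1)) {
    stop("simulate_editing: reg_freq_shift pushes a true frequency above 1",
         call. = FALSE)
  }

  depth <- matrix(stats::rnbinom(ns * nsamp, mu = config$mean_depth,
                                 size = config$depth_dispersion),
                  nrow = ns, ncol = nsamp)
  fmat <- cbind(matrix(f_high, ns, npg), matrix(f_low, ns, npg))
  altd <- matrix(stats::rbinom(ns * nsamp, as.vector(depth), as.vector(fmat)),
                 nrow = ns, ncol = nsamp)
  bq <- matrix(round(stats::runif(ns * nsamp, 30, 40), 1), ns, nsamp)
  low_bq <- matrix(stats::runif(ns * nsamp) < 0.02, ns, nsamp)
  bq[low_bq] <- round(stats::runif(sum(low_bq), 15, 24), 1)

  info <- data.frame(
    qd = round(stats::runif(ns, 5, 30), 2),
    fs = round(stats::runif(ns, 0, 30), 2),
    mqranksum = round(stats::runif(ns, -5, 5), 2),
    readposranksum = round(stats::runif(ns, -4, 4), 2),
    mq = round(stats::runif(ns, 45, 60), 2),
    sor = round(stats::runif(ns, 0.5, 2.5), 2))

  n_decoy <- round(config$decoy_fraction * ns)
  decoy_criterion <- rep(NA_character_, ns)
  if (n_decoy > 0L) {
    decoy_idx <- sample.int(ns, n_decoy)
    crit <- rep_len(HARD_FILTER_CRITERIA, n_decoy)
    decoy_criterion[decoy_idx] <- crit
    for (j in seq_len(n_decoy)) {
      s <- decoy_idx[j]
      switch(crit[j],
        QD = { info$qd[s] <- round(stats::runif(1, 0, 1.9), 2) },
        FS = { info$fs[s] <- round(stats::runif(1, 65, 120), 2) },
        MQRankSum = { info$mqranksum[s] <- round(stats::runif(1, -20, -13), 2) },
        ReadPosRankSum = {
          info$readposranksum[s] <- round(stats::runif(1, -12, -8.5), 2)
        },
        MQ = { info$mq[s] <- round(stats::runif(1, 10, 35), 2) },
        SOR = { info$sor[s] <- round(stats::runif(1, 3.2, 6), 2) },
        depth_dev = {
          jj <- sample.int(nsamp, 1L)
          depth[s, jj] <- round(10 * config$mean_depth)
          altd[s, jj] <- stats::rbinom(1L, depth[s, jj], fmat[s, jj])
        })
    }
  }

  records <- data.frame(chrom = "chr1", pos = pos_l, ref = ref_l, alt = alt_l,
                        info, stringsAsFactors = FALSE)
  variants <- new_variant_records(records, depth, altd, bq, samples,
                                  c(chr1 = glen))

  site_truth <- data.frame(
    chrom = "chr1", pos = pos_l, ref = ref_l, alt = alt_l,
    gene_id = gene_l, strand = strand_l, canonical = canon_l,
    decoy_criterion = decoy_criterion,
    f_high = f_high, f_low = f_low, stringsAsFactors = FALSE)
  reg_lfc <- vapply(panels$reg, function(g) {
    idx <- which(!is.na(gene_l) & gene_l == g)
    if (length(idx) == 0L) return(NA_real_)
    log2(sum(f_low[idx]) / sum(f_high[idx]))
  }, 1.0)
  truth <- list(reg_gene_ids = panels$reg, deg_gene_ids = panels$deg,
                joint_gene_ids = panels$joint, site_truth = site_truth,
                reg_true_log2fc = reg_lfc)

  structure(list(variants = variants, truth = truth, samples = samples,
                 groups = groups),
            class = "sim_editing")
}

#' Write variant records as a multi-sample VCF 4.2 file
#'
#' Emits the six site-level quality annotations as INFO fields and per-sample
#' genotype, depth, allelic depths and mean alt base quality as
#' `GT:DP:AD:BQ`. The output parses cleanly with
#' [VariantAnnotation::readVcf()] (see [read_variant_vcf()]).
#'
#' @param variants A `variant_records` object (or a `sim_editing` result).
#' @param path Output path (plain-text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, path) {
  if (inherits(variants, "sim_editing")) variants <- variants$variants
  stopifnot(inherits(variants, "variant_records"))
  r <- variants$records
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(variants$contig_lengths),
            unname(variants$contig_lengths)),
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Variant confidence by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias phred p\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Symmetric odds ratio strand bias\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=BQ,Number=1,Type=Float,Description=\"Mean base quality of alt reads\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", variants$samples), collapse = "\t"))
  info <- sprintf("QD=%.2f;FS=%.2f;MQRankSum=%.2f;ReadPosRankSum=%.2f;MQ=%.2f;SOR=%.2f",
                  r$qd, r$fs, r$mqranksum, r$readposranksum, r$mq, r$sor)
  geno <- matrix("", nrow(r), length(variants$samples))
  for (j in seq_along(variants$samples)) {
    geno[, j] <- sprintf("0/1:%d:%d,%d:%.1f", variants$depth[, j],
                         variants$depth[, j] - variants$alt_depth[, j],
                         variants$alt_depth[, j], variants$bq[, j])
  }
  body <- paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", ".", info,
                "GT:DP:AD:BQ",
                apply(geno, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF of candidate editing sites
#'
#' Parses a (multi-sample) VCF 4.x through [VariantAnnotation::readVcf()],
#' keeping biallelic SNVs, and assembles the `variant_records` container the
#' calling pipeline consumes. Expects INFO fields QD, FS, MQRankSum,
#' ReadPosRankSum, MQ and SOR and FORMAT fields DP, AD and BQ; missing INFO
#' values are kept as `NA` and handled by the filter's missing-field policy.
#'
#' @param path VCF file path.
#' @return A `variant_records` object.
#' @export
read_variant_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  ref <- as.character(VariantAnnotation::ref(vcf))
  keep <- n_alt == 1L & nchar(ref) == 1L
  alt <- rep(NA_character_, length(ref))
  alt[n_alt == 1L] <- as.character(unlist(alt_list[n_alt == 1L]))
  keep <- keep & !is.na(alt) & nchar(alt) == 1L
  vcf <- vcf[keep]
  rr <- rr[keep]

  info <- VariantAnnotation::info(vcf)
  getinfo <- function(name) {
    if (name %in% colnames(info)) as.numeric(info[[name]])
    else rep(NA_real_, length(rr))
  }
  records <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = ref[keep], alt = alt[keep],
    qd = getinfo("QD"), fs = getinfo("FS"),
    mqranksum = getinfo("MQRankSum"),
    readposranksum = getinfo("ReadPosRankSum"),
    mq = getinfo("MQ"), sor = getinfo("SOR"),
    stringsAsFactors = FALSE)

  g <- VariantAnnotation::geno(vcf)
  samples <- colnames(g$DP)
  depth <- matrix(as.integer(g$DP), nrow(records), length(samples))
  ad <- g$AD
  if (is.array(ad) && length(dim(ad)) == 3L) {
    alt_depth <- matrix(as.integer(ad[, , 2L]), nrow(records), length(samples))
  } else {
    alt_depth <- matrix(vapply(ad, function(x) as.integer(x[2L]), 1L),
                        nrow(records), length(samples))
  }
  bq <- matrix(as.numeric(g$BQ), nrow(records), length(samples))
  clen <- GenomeInfoDb::seqlengths(rr)
  if (all(is.na(clen))) {
    clen <- tapply(records$pos, records$chrom, max)
  }
  new_variant_records(records, depth, alt_depth, bq, samples, clen)
}

#' Infer phenotype groups from sample names
#'
#' Sample names of the form `<GROUP>_<replicate>` (e.g. `HVH_1`, `LVH_3`)
#' are split on the final underscore.
#'
#' @param samples Character vector of sample ids.
#' @return Named character vector mapping sample id to group label.
#' @export
sample_groups <- function(samples) {
  stats::setNames(sub("_[^_]*$", "", samples), samples)
}

#' Serialize ground truth to JSON
#' @param truth Ground-truth list from [simulate_editing()] /
#'   [simulate_expression()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  # named numeric vectors serialize as JSON objects so names survive
  for (f in c("reg_true_log2fc", "expr_log2fc")) {
    if (!is.null(truth[[f]]) && !is.list(truth[[f]])) {
      truth[[f]] <- as.list(truth[[f]])
    }
  }
  jsonlite::write_json(truth, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read ground truth back from JSON
#' @param path JSON path written by [write_truth()].
#' @return The ground-truth list.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$reg_true_log2fc)) {
    x$reg_true_log2fc <- unlist(x$reg_true_log2fc)
  }
  if (!is.null(x$expr_log2fc)) x$expr_log2fc <- unlist(x$expr_log2fc)
  x
}
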