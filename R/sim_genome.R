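BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

revcomp_chars <- function(x) rev(chartr("ACGT", "TGCA", x))

# Runs of TRUE in a logical vector, returned as (start, end) local indices.
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

sense_codons <- function() {
  all <- as.vector(outer(as.vector(outer(BASES, BASES, paste0)), BASES, paste0))
  stops <- c("TAA", "TAG", "TGA")
  setdiff(all, stops)
}

#' Simulate a reference genome with gene models
#'
#' Generates one random chromosome carrying `n_genes` non-overlapping genes.
#' Each gene has a single transcript with one or two introns; coding genes
#' carry a 5'UTR, a CDS (length divisible by 3, starting with ATG and ending
#' in a stop codon, internal codons sense-only) and a 3'UTR, while a
#' `noncoding_fraction` of genes are lncRNA-like (exons only). Strand is
#' assigned at random and minus-strand genes are laid down as the reverse
#' complement of their transcript construction, so region and coding-effect
#' annotation can be exercised on both strands. Genes are separated by gaps
#' wider than twice the flanking annotation window.
#'
#' @param config A [sim_config()].
#' @param genome_length Optional total chromosome length (bp). The layout is
#'   sized automatically; supplying a value smaller than the required span is
#'   an error, a larger value pads the chromosome tail.
#' @return A list of class `sim_genome`: `genome` (a named
#'   [Biostrings::DNAStringSet-class] with one chromosome), `models` (a
#'   `gene_models` object, see [read_gene_models()]), and `config`.
#' @seealso [write_genome_fasta()], [write_gene_models_gtf()]
#' @export
simulate_genome <- function(config, genome_length = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "genome"))

  n <- config$n_genes
  w <- config$flank_window
  gene_rows <- vector("list", n)
  feat_rows <- vector("list", n)
  seq_parts <- character(2L * n + 1L)

  cursor <- 0L
  for (i in seq_len(n)) {
    gap <- 2L * w + sample(200:600, 1L)
    seq_parts[2L * i - 1L] <- random_dna(gap)
    cursor <- cursor + gap

    strand <- sample(c("+", "-"), 1L)
    coding <- runif(1) >= config$noncoding_fraction
    if (coding) {
      utr5_len <- sample(60:150, 1L)
      n_codons <- sample(60:200, 1L)
      cds_len <- 3L * n_codons
      utr3_len <- sample(80:200, 1L)
      cds_seq <- c("ATG",
                   sample(sense_codons(), n_codons - 2L, replace = TRUE),
                   sample(c("TAA", "TAG", "TGA"), 1L))
      tx_seq <- strsplit(paste0(random_dna(utr5_len),
                                paste(cds_seq, collapse = ""),
                                random_dna(utr3_len)), "")[[1]]
    } else {
      utr5_len <- 0L
      cds_len <- 0L
      utr3_len <- 0L
      tx_seq <- strsplit(random_dna(sample(300:800, 1L)), "")[[1]]
    }
    tx_len <- length(tx_seq)

    n_int <- sample(1:2, 1L)
    intron_lens <- sample(80:300, n_int, replace = TRUE)
    breaks <- sort(sample(20:(tx_len - 20L), n_int))

    # Plus-orientation layout: transcript segments interleaved with introns.
    seg_bounds <- c(0L, breaks, tx_len)
    loc_seq <- character(0)
    loc_tpos <- integer(0)
    for (k in seq_len(length(seg_bounds) - 1L)) {
      a <- seg_bounds[k] + 1L
      b <- seg_bounds[k + 1L]
      loc_seq <- c(loc_seq, tx_seq[a:b])
      loc_tpos <- c(loc_tpos, a:b)
      if (k <= n_int) {
        ilen <- intron_lens[k]
        loc_seq <- c(loc_seq, strsplit(random_dna(ilen), "")[[1]])
        loc_tpos <- c(loc_tpos, rep(NA_integer_, ilen))
      }
    }
    span <- length(loc_seq)
    if (strand == "-") {
      loc_seq <- revcomp_chars(loc_seq)
      loc_tpos <- rev(loc_tpos)
    }

    gstart <- cursor + 1L
    gend <- cursor + span
    cursor <- gend
    seq_parts[2L * i] <- paste(loc_seq, collapse = "")

    gid <- sprintf("G%04d", i)
    gene_rows[[i]] <- data.frame(
      gene_id = gid, chrom = "chr1", start = gstart, end = gend,
      strand = strand, biotype = if (coding) "protein_coding" else "lncRNA",
      tx_len = tx_len, utr5_len = utr5_len, cds_len = cds_len,
      stringsAsFactors = FALSE)

    feat <- list()
    exon_runs <- logical_runs(!is.na(loc_tpos))
    feat$exon <- exon_runs
    if (coding) {
      feat$five_prime_utr <- logical_runs(!is.na(loc_tpos) & loc_tpos <= utr5_len)
      feat$CDS <- logical_runs(!is.na(loc_tpos) &
                                 loc_tpos > utr5_len &
                                 loc_tpos <= utr5_len + cds_len)
      feat$three_prime_utr <- logical_runs(!is.na(loc_tpos) &
                                             loc_tpos > utr5_len + cds_len)
    }
    feat <- feat[vapply(feat, nrow, 1L) > 0L]
    fdf <- do.call(rbind, lapply(names(feat), function(ty) {
      data.frame(gene_id = gid, type = ty, chrom = "chr1",
                 start = feat[[ty]]$start + gstart - 1L,
                 end = feat[[ty]]$end + gstart - 1L,
                 strand = strand, stringsAsFactors = FALSE)
    }))
    feat_rows[[i]] <- fdf
  }
  tail_gap <- 2L * w + sample(200:600, 1L)
  seq_parts[2L * n + 1L] <- random_dna(tail_gap)
  cursor <- cursor + tail_gap

  if (!is.null(genome_length)) {
    if (genome_length < cursor) {
      stop("simulate_genome: requested genome_length ", genome_length,
           " bp is smaller than the ", cursor,
           " bp needed for the configured gene layout", call. = FALSE)
    }
    if (genome_length > cursor) {
      seq_parts <- c(seq_parts, random_dna(genome_length - cursor))
      cursor <- genome_length
    }
  }

  genome <- Biostrings::DNAStringSet(paste(seq_parts, collapse = ""))
  names(genome) <- "chr1"
  models <- new_gene_models(do.call(rbind, gene_rows),
                            do.call(rbind, feat_rows))
  structure(list(genome = genome, models = models, config = config),
            class = "sim_genome")
}

new_gene_models <- function(genes, features) {
  rownames(genes) <- NULL
  rownames(features) <- NULL
  structure(list(genes = genes, features = features), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes (%d coding) on %d sequence(s)\n",
              nrow(x$genes), sum(x$genes$biotype == "protein_coding"),
              length(unique(x$genes$chrom))))
  invisible(x)
}

#' Write the simulated genome as FASTA
#'
#' @param sim A `sim_genome` object.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(sim, path) {
  Biostrings::writeXStringSet(sim$genome, filepath = path)
  invisible(path)
}

#' Write gene models as GTF
#'
#' Emits gene, transcript, exon, CDS and UTR features (one transcript per
#' gene, id `<gene_id>.t1`) through [rtracklayer::export()].
#'
#' @param models A `gene_models` object (or a `sim_genome`).
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(models, path) {
  if (inherits(models, "sim_genome")) models <- models$models
  stopifnot(inherits(models, "gene_models"))
  g <- models$genes
  f <- models$features
  rows <- rbind(
    data.frame(gene_id = g$gene_id, type = "gene", chrom = g$chrom,
               start = g$start, end = g$end, strand = g$strand,
               biotype = g$biotype, stringsAsFactors = FALSE),
    data.frame(gene_id = g$gene_id, type = "transcript", chrom = g$chrom,
               start = g$start, end = g$end, strand = g$strand,
               biotype = g$biotype, stringsAsFactors = FALSE),
    data.frame(gene_id = f$gene_id, type = f$type, chrom = f$chrom,
               start = f$start, end = f$end, strand = f$strand,
               biotype = g$biotype[match(f$gene_id, g$gene_id)],
               stringsAsFactors = FALSE))
  ord <- order(match(rows$gene_id, g$gene_id),
               match(rows$type, c("gene", "transcript", "exon",
                                  "five_prime_utr", "CDS", "three_prime_utr")),
               rows$start)
  rows <- rows[ord, , drop = FALSE]
  # CDS phase: bases to skip before the first complete codon of each piece,
  # accumulated in transcript order (descending genomic start on minus)
  rows$phase <- NA_integer_
  for (gid in unique(rows$gene_id[rows$type == "CDS"])) {
    idx <- which(rows$gene_id == gid & rows$type == "CDS")
    idx <- idx[order(rows$start[idx],
                     decreasing = rows$strand[idx[1]] == "-")]
    before <- cumsum(c(0L, (rows$end[idx] - rows$start[idx] + 1L)))
    rows$phase[idx] <- (3L - before[-length(before)] %% 3L) %% 3L
  }
  gr <- GenomicRanges::GRanges(
    seqnames = rows$chrom,
    ranges = IRanges::IRanges(rows$start, rows$end),
    strand = rows$strand)
  S4Vectors::mcols(gr)$type <- rows$type
  S4Vectors::mcols(gr)$phase <- rows$phase
  S4Vectors::mcols(gr)$gene_id <- rows$gene_id
  S4Vectors::mcols(gr)$transcript_id <- ifelse(
    rows$type == "gene", NA_character_, paste0(rows$gene_id, ".t1"))
  S4Vectors::mcols(gr)$gene_biotype <- rows$biotype
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read gene models from a GTF/GFF3 file
#'
#' Imports annotation through [rtracklayer::import()] and collapses it to the
#' per-gene feature table the annotation routines use (exon, CDS and UTR
#' intervals, unioned across isoforms when several transcripts are present).
#' Gene biotype is taken from a `gene_biotype` or `gene_type` attribute when
#' available, defaulting to `protein_coding` for genes with CDS features and
#' `lncRNA` otherwise.
#'
#' @param path GTF or GFF3 file.
#' @return A `gene_models` object.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  gid <- as.character(mc$gene_id)
  bty <- if ("gene_biotype" %in% colnames(mc)) {
    as.character(mc$gene_biotype)
  } else if ("gene_type" %in% colnames(mc)) {
    as.character(mc$gene_type)
  } else {
    rep(NA_character_, length(gr))
  }
  keep_types <- c("exon", "CDS", "five_prime_utr", "three_prime_utr")
  fi <- type %in% keep_types & !is.na(gid)
  features <- data.frame(
    gene_id = gid[fi], type = type[fi],
    chrom = as.character(GenomicRanges::seqnames(gr))[fi],
    start = GenomicRanges::start(gr)[fi], end = GenomicRanges::end(gr)[fi],
    strand = as.character(GenomicRanges::strand(gr))[fi],
    stringsAsFactors = FALSE)
  # Union overlapping intervals per gene and type (multi-isoform input).
  features <- do.call(rbind, lapply(
    split(features, paste(features$gene_id, features$type, sep = "\r")),
    function(d) {
      ir <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
      data.frame(gene_id = d$gene_id[1], type = d$type[1], chrom = d$chrom[1],
                 start = IRanges::start(ir), end = IRanges::end(ir),
                 strand = d$strand[1], stringsAsFactors = FALSE)
    }))
  rownames(features) <- NULL

  gi <- type == "gene" & !is.na(gid)
  if (any(gi)) {
    genes <- data.frame(
      gene_id = gid[gi],
      chrom = as.character(GenomicRanges::seqnames(gr))[gi],
      start = GenomicRanges::start(gr)[gi], end = GenomicRanges::end(gr)[gi],
      strand = as.character(GenomicRanges::strand(gr))[gi],
      biotype = bty[gi], stringsAsFactors = FALSE)
  } else {
    # Some GTFs carry no explicit gene rows; derive spans from features.
    genes <- do.call(rbind, lapply(split(features, features$gene_id),
      function(d) data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
                             start = min(d$start), end = max(d$end),
                             strand = d$strand[1], biotype = NA_character_,
                             stringsAsFactors = FALSE)))
  }
  has_cds <- genes$gene_id %in% features$gene_id[features$type == "CDS"]
  genes$biotype[is.na(genes$biotype)] <-
    ifelse(has_cds[is.na(genes$biotype)], "protein_coding", "lncRNA")
  cds_w <- vapply(genes$gene_id, function(g) {
    d <- features[features$gene_id == g & features$type == "CDS", , drop = FALSE]
    if (nrow(d) == 0L) 0L else sum(d$end - d$start + 1L)
  }, 1L)
  u5_w <- vapply(genes$gene_id, function(g) {
    d <- features[features$gene_id == g & features$type == "five_prime_utr", ,
                  drop = FALSE]
    if (nrow(d) == 0L) 0L else sum(d$end - d$start + 1L)
  }, 1L)
  ex_w <- vapply(genes$gene_id, function(g) {
    d <- features[features$gene_id == g & features$type == "exon", , drop = FALSE]
    if (nrow(d) == 0L) 0L else sum(d$end - d$start + 1L)
  }, 1L)
  genes$tx_len <- ex_w
  genes$utr5_len <- u5_w
  genes$cds_len <- cds_w
  ord <- order(genes$chrom, genes$start)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL
  new_gene_models(genes, features)
}
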