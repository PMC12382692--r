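#' Default hard-filter thresholds for candidate variant triage
#'
#' The six GATK-style site-level criteria: a record fails if QD < 2.0,
#' FS > 60.0, MQRankSum < -12.5, ReadPosRankSum < -8.0, MQ < 40.0 or
#' SOR > 3.0 (all strict inequalities: a record exactly at a boundary
#' passes). The seventh, the depth-deviation rule, is applied by
#' [hard_filter()] itself: a site is discarded when any sample's depth falls
#' below one third of, or above three times, the cross-sample mean depth at
#' that site.
#'
#' @return Named list of thresholds.
#' @export
hard_filter_thresholds <- function() {
  list(qd_min = 2.0, fs_max = 60.0, mqranksum_min = -12.5,
       readposranksum_min = -8.0, mq_min = 40.0, sor_max = 3.0,
       depth_dev_low = 1 / 3, depth_dev_high = 3)
}

#' Hard-filter candidate variant records
#'
#' Applies the seven-criterion battery (see [hard_filter_thresholds()]) to
#' every record and reports, per record, whether it passes and the full list
#' of violated criteria.
#'
#' @param variants A `variant_records` object.
#' @param thresholds Threshold list, default [hard_filter_thresholds()].
#' @param depth_deviation Apply the depth-deviation rule (default `TRUE`).
#' @param missing Policy for records with a missing quality annotation:
#'   `"fail"` (default, fail closed with reason `missing:<field>`) or
#'   `"pass"` (ignore the missing criterion).
#' @return Data frame with one row per record: site key columns, `pass`,
#'   and `reasons` (comma-separated violated criteria, `""` when passing).
#' @export
hard_filter <- function(variants, thresholds = hard_filter_thresholds(),
                        depth_deviation = TRUE,
                        missing = c("fail", "pass")) {
  stopifnot(inherits(variants, "variant_records"))
  missing <- match.arg(missing)
  r <- variants$records
  th <- thresholds
  n <- nrow(r)

  crit <- list(
    QD = r$qd < th$qd_min,
    FS = r$fs > th$fs_max,
    MQRankSum = r$mqranksum < th$mqranksum_min,
    ReadPosRankSum = r$readposranksum < th$readposranksum_min,
    MQ = r$mq < th$mq_min,
    SOR = r$sor > th$sor_max)

  reasons <- vector("list", n)
  for (nm in names(crit)) {
    v <- crit[[nm]]
    miss <- is.na(v)
    v[miss] <- FALSE
    for (i in which(v)) reasons[[i]] <- c(reasons[[i]], nm)
    if (missing == "fail") {
      for (i in which(miss)) {
        reasons[[i]] <- c(reasons[[i]], paste0("missing:", nm))
      }
    }
  }
  if (depth_deviation) {
    m <- rowMeans(variants$depth)
    dev <- variants$depth < m * th$depth_dev_low |
      variants$depth > m * th$depth_dev_high
    for (i in which(rowSums(dev) > 0L)) {
      reasons[[i]] <- c(reasons[[i]], "depth_dev")
    }
  }
  data.frame(chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt,
             pass = lengths(reasons) == 0L,
             reasons = vapply(reasons, function(x) {
               paste(x, collapse = ",")
             }, ""),
             stringsAsFactors = FALSE)
}

#' Editing frequency of a sample call
#'
#' The proportion of reads supporting the edited base among all reads at the
#' site in that sample.
#'
#' @param alt_depth Edited-read count(s).
#' @param depth Total read depth(s); must be positive.
#' @return `alt_depth / depth`, in `[0, 1]`.
#' @examples
#' editing_frequency(3, 5)  # 0.6
#' @export
editing_frequency <- function(alt_depth, depth) {
  if (any(depth <= 0, na.rm = TRUE)) {
    stop("editing_frequency: depth must be positive; frequency is undefined ",
         "at zero depth", call. = FALSE)
  }
  if (any(alt_depth > depth, na.rm = TRUE)) {
    stop("editing_frequency: alt_depth exceeds depth", call. = FALSE)
  }
  alt_depth / depth
}

#' Site-retention thresholds
#'
#' A sample call is retained iff mean base quality >= 25, depth >= 5,
#' alternate-allele depth >= 3 and editing frequency in [0.10, 1.00]
#' (all boundaries inclusive).
#'
#' @return Named list of retention thresholds.
#' @export
retention_thresholds <- function() {
  list(min_bq = 25, min_depth = 5L, min_alt_depth = 3L,
       freq_min = 0.10, freq_max = 1.00)
}

#' Apply site-retention rules to per-sample calls
#'
#' Evaluates the per-sample retention criteria at every record and retains a
#' site when at least `min_samples` sample calls survive.
#'
#' @param variants A `variant_records` object.
#' @param thresholds Retention thresholds, default [retention_thresholds()].
#' @param min_samples Minimum retained sample calls for the site itself to
#'   be retained (default 1).
#' @return List: `call_retained` (logical sites x samples matrix),
#'   `site_retained` (logical vector), `frequency` (numeric matrix, `NA`
#'   where depth is zero), and `reject_reason` (first failing criterion per
#'   non-retained site, `""` for retained sites).
#' @export
retain_site <- function(variants, thresholds = retention_thresholds(),
                        min_samples = 1L) {
  stopifnot(inherits(variants, "variant_records"))
  th <- thresholds
  d <- variants$depth
  a <- variants$alt_depth
  freq <- ifelse(d > 0L, a / d, NA_real_)

  ok_bq <- variants$bq >= th$min_bq
  ok_depth <- d >= th$min_depth
  ok_alt <- a >= th$min_alt_depth
  ok_freq <- !is.na(freq) & freq >= th$freq_min & freq <= th$freq_max
  call_retained <- ok_bq & ok_depth & ok_alt & ok_freq
  call_retained[is.na(call_retained)] <- FALSE
  site_retained <- rowSums(call_retained) >= min_samples

  reject_reason <- character(nrow(d))
  for (i in which(!site_retained)) {
    # report the criterion that failed in the most sample calls
    fails <- c(base_quality = sum(!ok_bq[i, ], na.rm = TRUE),
               depth = sum(!ok_depth[i, ], na.rm = TRUE),
               alt_depth = sum(!ok_alt[i, ], na.rm = TRUE),
               frequency = sum(!ok_freq[i, ], na.rm = TRUE))
    reject_reason[i] <- names(which.max(fails))
  }
  list(call_retained = call_retained, site_retained = site_retained,
       frequency = freq, reject_reason = reject_reason)
}

SUBSTITUTION_LEVELS <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
                         "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")

#' Classify a base substitution into an editing class
#'
#' Records the literal (reference-orientation) base change and maps it to an
#' editing class. In the default `"collapsed"` mode the strand-collapsed
#' pairs A>G / T>C are called A-to-I and C>T / G>A are called C-to-U, so the
#' class is invariant under strand complementation. The `"literal"` mode
#' instead maps A>G or T>A to A-to-I and C>T or G>A to C-to-U, reading the
#' pairs exactly as sometimes tabulated, at the cost of breaking strand
#' symmetry. For minus-strand genes both bases are complemented before the
#' lookup; sites with unknown strand (`"*"`) are classified in literal
#' orientation and flagged `strand_unresolved`.
#'
#' @param ref,alt Reference and alternate bases (single A/C/G/T characters;
#'   vectorized).
#' @param strand Gene strand per site: `"+"`, `"-"` or `"*"` (unknown).
#' @param mode `"collapsed"` (default) or `"literal"`.
#' @return Data frame with `substitution` (literal, e.g. `"A>G"`),
#'   `edit_class` (`"A-to-I"`, `"C-to-U"` or `"other"`) and
#'   `strand_unresolved`.
#' @export
classify_substitution <- function(ref, alt, strand = "*",
                                  mode = c("collapsed", "literal")) {
  mode <- match.arg(mode)
  n <- max(length(ref), length(alt), length(strand))
  ref <- toupper(rep_len(ref, n))
  alt <- toupper(rep_len(alt, n))
  strand <- rep_len(strand, n)
  if (!all(ref %in% BASES) || !all(alt %in% BASES)) {
    stop("classify_substitution: bases must be A, C, G or T", call. = FALSE)
  }
  if (any(ref == alt)) {
    stop("classify_substitution: ref and alt must differ", call. = FALSE)
  }
  eff_ref <- ifelse(strand == "-", comp_base(ref), ref)
  eff_alt <- ifelse(strand == "-", comp_base(alt), alt)
  pair <- paste0(eff_ref, ">", eff_alt)
  cls <- if (mode == "collapsed") {
    ifelse(pair %in% c("A>G", "T>C"), "A-to-I",
           ifelse(pair %in% c("C>T", "G>A"), "C-to-U", "other"))
  } else {
    ifelse(pair %in% c("A>G", "T>A"), "A-to-I",
           ifelse(pair %in% c("C>T", "G>A"), "C-to-U", "other"))
  }
  data.frame(substitution = paste0(ref, ">", alt), edit_class = cls,
             strand_unresolved = strand == "*", stringsAsFactors = FALSE)
}

REGION_LEVELS <- c("splicing", "exonic", "5UTR", "3UTR", "intronic",
                   "ncRNA_intronic", "upstream", "downstream", "intergenic")

# Gene-model interval table used by region annotation: one row per
# (category, interval), with categories ordered by annotation precedence.
region_intervals <- function(models, window = 1000L, splice_bp = 2L) {
  g <- models$genes
  f <- models$features
  out <- list()
  add <- function(cat, gene_id, start, end) {
    if (length(start) == 0L) return()
    keep <- end >= start
    if (!any(keep)) return()
    out[[length(out) + 1L]] <<- data.frame(
      category = cat, gene_id = gene_id[keep],
      start = start[keep], end = end[keep], stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    ex <- f[f$gene_id == gid & f$type == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    # Introns: gaps between consecutive exons inside the gene span.
    if (nrow(ex) > 1L) {
      istart <- ex$end[-nrow(ex)] + 1L
      iend <- ex$start[-1L] - 1L
      ok <- iend >= istart
      istart <- istart[ok]; iend <- iend[ok]
      cat_int <- if (g$biotype[i] == "protein_coding") "intronic"
                 else "ncRNA_intronic"
      # splice-site windows: first/last `splice_bp` bases inside the intron
      add("splicing", rep(gid, length(istart)),
          istart, pmin(iend, istart + splice_bp - 1L))
      add("splicing", rep(gid, length(istart)),
          pmax(istart, iend - splice_bp + 1L), iend)
      add(cat_int, rep(gid, length(istart)), istart, iend)
    }
    cds <- f[f$gene_id == gid & f$type == "CDS", , drop = FALSE]
    add("exonic", rep(gid, nrow(cds)), cds$start, cds$end)
    u5 <- f[f$gene_id == gid & f$type == "five_prime_utr", , drop = FALSE]
    add("5UTR", rep(gid, nrow(u5)), u5$start, u5$end)
    u3 <- f[f$gene_id == gid & f$type == "three_prime_utr", , drop = FALSE]
    add("3UTR", rep(gid, nrow(u3)), u3$start, u3$end)
    if (g$biotype[i] != "protein_coding" && nrow(ex) > 0L) {
      # non-coding exons count as exonic (no CDS/UTR structure)
      add("exonic", rep(gid, nrow(ex)), ex$start, ex$end)
    }
    if (g$strand[i] == "-") {
      add("upstream", gid, g$end[i] + 1L, g$end[i] + window)
      add("downstream", gid, max(1L, g$start[i] - window), g$start[i] - 1L)
    } else {
      add("upstream", gid, max(1L, g$start[i] - window), g$start[i] - 1L)
      add("downstream", gid, g$end[i] + 1L, g$end[i] + window)
    }
  }
  res <- do.call(rbind, out)
  res$chrom <- g$chrom[match(res$gene_id, g$gene_id)]
  res
}

#' Annotate the genomic region of sites
#'
#' Assigns each position exactly one region by the precedence order
#' splicing > CDS-exonic > 5'UTR > 3'UTR > intronic (ncRNA_intronic for
#' non-coding host genes) > upstream > downstream > intergenic. Splicing
#' means within `splice_bp` (default 2) bases of an exon-intron boundary on
#' the intron side; upstream/downstream are strand-aware windows of
#' `window` bp flanking the gene. Exons of non-coding genes count as exonic.
#'
#' @param chrom,pos Site coordinates (1-based).
#' @param models A `gene_models` object.
#' @param window Flanking window width in bp (default 1000).
#' @param splice_bp Splice-region width inside the intron (default 2).
#' @return Data frame with `region` (factor over the precedence levels) and
#'   `gene_id` (`NA` for intergenic sites).
#' @export
annotate_region <- function(chrom, pos, models, window = 1000L,
                            splice_bp = 2L) {
  stopifnot(inherits(models, "gene_models"))
  if (length(models$genes$chrom) &&
      any(!chrom %in% c(models$genes$chrom, NA))) {
    bad <- setdiff(unique(chrom), models$genes$chrom)
    stop("annotate_region: unknown contig(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  iv <- region_intervals(models, window = window, splice_bp = splice_bp)
  site_gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  iv_gr <- GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start, iv$end))
  hits <- GenomicRanges::findOverlaps(site_gr, iv_gr)

  region <- rep("intergenic", length(pos))
  gene_id <- rep(NA_character_, length(pos))
  prec <- match(iv$category, REGION_LEVELS)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  for (i in unique(qh)) {
    cand <- sh[qh == i]
    best <- cand[order(prec[cand], iv$gene_id[cand])][1L]
    region[i] <- iv$category[best]
    gene_id[i] <- iv$gene_id[best]
  }
  data.frame(region = factor(region, levels = REGION_LEVELS),
             gene_id = gene_id, stringsAsFactors = FALSE)
}

EFFECT_LEVELS <- c("synonymous", "nonsynonymous", "stopgain", "stoploss",
                   "noncoding")

#' Annotate the coding effect of CDS sites
#'
#' Substitutes the edited base into its codon (strand-aware), translates
#' reference and edited codon with the standard genetic code, and calls the
#' effect: same amino acid = synonymous; sense to stop = stopgain; stop to
#' sense = stoploss; otherwise nonsynonymous. Sites outside a CDS are
#' `noncoding`.
#'
#' @param chrom,pos,ref,alt Site coordinates and bases (reference
#'   orientation; vectorized).
#' @param models A `gene_models` object whose CDS lengths are divisible by 3.
#' @param genome Named [Biostrings::DNAStringSet-class] with the reference
#'   sequence.
#' @return Character vector of effects (factor over the effect levels).
#' @export
annotate_coding_effect <- function(chrom, pos, ref, alt, models, genome) {
  stopifnot(inherits(models, "gene_models"))
  gc_tab <- Biostrings::GENETIC_CODE
  f <- models$features
  g <- models$genes
  n <- length(pos)
  chrom <- rep_len(chrom, n)
  ref <- rep_len(ref, n)
  alt <- rep_len(alt, n)
  eff <- rep("noncoding", n)

  cds_by_gene <- split(f[f$type == "CDS", , drop = FALSE],
                       f$gene_id[f$type == "CDS"])
  cds_seq_cache <- new.env(parent = emptyenv())
  get_cds <- function(gid) {
    if (!is.null(cds_seq_cache[[gid]])) return(cds_seq_cache[[gid]])
    d <- cds_by_gene[[gid]]
    d <- d[order(d$start), , drop = FALSE]
    if (sum(d$end - d$start + 1L) %% 3L != 0L) {
      stop("annotate_coding_effect: CDS length of ", gid,
           " is not divisible by 3", call. = FALSE)
    }
    pieces <- vapply(seq_len(nrow(d)), function(k) {
      as.character(Biostrings::subseq(genome[[d$chrom[k]]],
                                      d$start[k], d$end[k]))
    }, "")
    s <- paste(pieces, collapse = "")
    strand <- g$strand[g$gene_id == gid]
    if (strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    obj <- list(seq = strsplit(s, "")[[1]], intervals = d, strand = strand)
    cds_seq_cache[[gid]] <- obj
    obj
  }

  for (i in seq_len(n)) {
    hit_gid <- NULL
    for (gid in names(cds_by_gene)) {
      d <- cds_by_gene[[gid]]
      if (any(d$chrom == chrom[i] & d$start <= pos[i] & d$end >= pos[i])) {
        hit_gid <- gid
        break
      }
    }
    if (is.null(hit_gid)) next
    cds <- get_cds(hit_gid)
    d <- cds$intervals
    # CDS-local (coding-strand) coordinate of the site
    k <- which(d$start <= pos[i] & d$end >= pos[i])[1L]
    plus_pos <- sum(d$end[seq_len(k - 1L)] - d$start[seq_len(k - 1L)] + 1L) +
      (pos[i] - d$start[k] + 1L)
    cpos <- if (cds$strand == "-") length(cds$seq) - plus_pos + 1L else plus_pos
    ref_c <- if (cds$strand == "-") comp_base(ref[i]) else ref[i]
    alt_c <- if (cds$strand == "-") comp_base(alt[i]) else alt[i]
    if (cds$seq[cpos] != ref_c) {
      warning("annotate_coding_effect: reference base mismatch at ",
              chrom[i], ":", pos[i], call. = FALSE)
    }
    codon_idx <- (cpos - 1L) %/% 3L
    off <- (cpos - 1L) %% 3L + 1L
    codon <- cds$seq[(codon_idx * 3L + 1L):(codon_idx * 3L + 3L)]
    codon_alt <- codon
    codon_alt[off] <- alt_c
    aa_ref <- gc_tab[[paste(codon, collapse = "")]]
    aa_alt <- gc_tab[[paste(codon_alt, collapse = "")]]
    eff[i] <- if (aa_ref == aa_alt) "synonymous"
      else if (aa_alt == "*" && aa_ref != "*") "stopgain"
      else if (aa_ref == "*" && aa_alt != "*") "stoploss"
      else "nonsynonymous"
  }
  factor(eff, levels = EFFECT_LEVELS)
}

#' Call retained, classified, annotated editing sites
#'
#' The full site-calling pipeline: hard-filter the candidate records, apply
#' the per-sample retention rules, and classify and annotate the surviving
#' sites (substitution class, genomic region, coding effect, host gene). An
#' optional exclusion mask (data frame of `chrom`, `start`, `end`, 1-based
#' inclusive) removes known-variant positions before filtering.
#'
#' @param variants A `variant_records` object (see [read_variant_vcf()]).
#' @param models A `gene_models` object.
#' @param genome Named [Biostrings::DNAStringSet-class]; when `NULL`, coding
#'   effects are not annotated (all `noncoding`).
#' @param hard_thresholds,retain_thresholds Threshold lists.
#' @param depth_deviation,missing Passed to [hard_filter()].
#' @param min_samples Passed to [retain_site()].
#' @param class_mode Passed to [classify_substitution()].
#' @param window Flanking-window width for region annotation (bp).
#' @param exclude Optional mask data frame (`chrom`, `start`, `end`).
#' @return An `editing_sites` object: `sites` (one row per retained site
#'   with class/region/effect/gene annotations), matrices `frequency`,
#'   `call_retained`, `depth`, `alt_depth` over retained sites, `samples`,
#'   and `audit` (per-candidate filter outcome with rejection reasons).
#' @export
call_editing_sites <- function(variants, models, genome = NULL,
                               hard_thresholds = hard_filter_thresholds(),
                               retain_thresholds = retention_thresholds(),
                               depth_deviation = TRUE,
                               missing = "fail",
                               min_samples = 1L,
                               class_mode = "collapsed",
                               window = 1000L,
                               exclude = NULL) {
  stopifnot(inherits(variants, "variant_records"))
  r <- variants$records

  masked <- rep(FALSE, nrow(r))
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    for (k in seq_len(nrow(exclude))) {
      masked <- masked | (r$chrom == exclude$chrom[k] &
                            r$pos >= exclude$start[k] &
                            r$pos <= exclude$end[k])
    }
  }
  hf <- hard_filter(variants, hard_thresholds,
                    depth_deviation = depth_deviation, missing = missing)
  rt <- retain_site(variants, retain_thresholds, min_samples = min_samples)

  stage <- ifelse(masked, "masked",
                  ifelse(!hf$pass, "hard_filter",
                         ifelse(!rt$site_retained, "retention", "retained")))
  reason <- ifelse(masked, "excluded_position",
                   ifelse(!hf$pass, hf$reasons,
                          ifelse(!rt$site_retained, rt$reject_reason, "")))
  audit <- data.frame(chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt,
                      stage = stage, reason = reason,
                      stringsAsFactors = FALSE)
  keep <- stage == "retained"

  sites <- r[keep, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  rownames(sites) <- NULL
  reg <- annotate_region(sites$chrom, sites$pos, models, window = window)
  gstrand <- models$genes$strand[match(reg$gene_id, models$genes$gene_id)]
  gstrand[is.na(gstrand)] <- "*"
  cls <- classify_substitution(sites$ref, sites$alt, gstrand,
                               mode = class_mode)
  sites$substitution <- cls$substitution
  sites$edit_class <- cls$edit_class
  sites$strand_unresolved <- cls$strand_unresolved
  sites$region <- reg$region
  sites$gene_id <- reg$gene_id
  if (!is.null(genome)) {
    sites$coding_effect <- annotate_coding_effect(
      sites$chrom, sites$pos, sites$ref, sites$alt, models, genome)
  } else {
    sites$coding_effect <- factor(rep("noncoding", nrow(sites)),
                                  levels = EFFECT_LEVELS)
  }

  structure(list(sites = sites,
                 frequency = rt$frequency[keep, , drop = FALSE],
                 call_retained = rt$call_retained[keep, , drop = FALSE],
                 depth = variants$depth[keep, , drop = FALSE],
                 alt_depth = variants$alt_depth[keep, , drop = FALSE],
                 samples = variants$samples,
                 audit = audit),
            class = "editing_sites")
}

#' @export
print.editing_sites <- function(x, ...) {
  cat(sprintf("editing_sites: %d retained sites x %d samples (%d candidates)\n",
              nrow(x$sites), length(x$samples), nrow(x$audit)))
  if (nrow(x$sites)) {
    tab <- table(x$sites$edit_class)
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write retained sites and the filter audit as TSV
#'
#' @param es An `editing_sites` object.
#' @param sites_path Output TSV for retained sites (per-sample depth, alt
#'   depth and frequency appended as `<sample>.dp` / `.alt` / `.freq`).
#' @param audit_path Optional output TSV for the per-candidate filter audit.
#' @return `sites_path`, invisibly.
#' @export
write_editing_sites <- function(es, sites_path, audit_path = NULL) {
  stopifnot(inherits(es, "editing_sites"))
  out <- es$sites
  for (s in es$samples) {
    out[[paste0(s, ".dp")]] <- es$depth[, s]
    out[[paste0(s, ".alt")]] <- es$alt_depth[, s]
    out[[paste0(s, ".freq")]] <- round(es$frequency[, s], 6)
  }
  utils::write.table(out, sites_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(audit_path)) {
    utils::write.table(es$audit, audit_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(sites_path)
}
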