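# Independent re-implementations used as oracles. Deliberately written as
# plain per-record loops, sharing no code with the package internals.

oracle_hard_filter <- function(variants, depth_deviation = TRUE) {
  r <- variants$records
  n <- nrow(r)
  pass <- logical(n)
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    rs <- character(0)
    chk <- function(val, bad, name) {
      if (is.na(val)) paste0("missing:", name)
      else if (bad(val)) name
      else NULL
    }
    rs <- c(rs, chk(r$qd[i], function(v) v < 2.0, "QD"))
    rs <- c(rs, chk(r$fs[i], function(v) v > 60.0, "FS"))
    rs <- c(rs, chk(r$mqranksum[i], function(v) v < -12.5, "MQRankSum"))
    rs <- c(rs, chk(r$readposranksum[i], function(v) v < -8.0,
                    "ReadPosRankSum"))
    rs <- c(rs, chk(r$mq[i], function(v) v < 40.0, "MQ"))
    rs <- c(rs, chk(r$sor[i], function(v) v > 3.0, "SOR"))
    if (depth_deviation) {
      d <- variants$depth[i, ]
      m <- mean(d)
      if (any(d < m / 3 | d > 3 * m)) rs <- c(rs, "depth_dev")
    }
    pass[i] <- length(rs) == 0L
    reasons[[i]] <- sort(rs)
  }
  list(pass = pass, reasons = reasons)
}

oracle_retain <- function(variants) {
  n <- nrow(variants$records)
  m <- length(variants$samples)
  kept <- matrix(FALSE, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d <- variants$depth[i, j]
      a <- variants$alt_depth[i, j]
      q <- variants$bq[i, j]
      if (d <= 0) next
      f <- a / d
      kept[i, j] <- q >= 25 && d >= 5 && a >= 3 && f >= 0.10 && f <= 1.00
    }
  }
  list(call_retained = kept, site_retained = rowSums(kept) >= 1L)
}

# Full running-sum GSEA walk over every rank position.
oracle_gsea_es <- function(hit_pos, scores, weight = 1) {
  N <- length(scores)
  hit <- rep(FALSE, N)
  hit[hit_pos] <- TRUE
  w <- abs(scores)^weight
  nr <- sum(w[hit])
  inc <- numeric(N)
  if (nr == 0) {
    inc[hit] <- 1 / sum(hit)
  } else {
    inc[hit] <- w[hit] / nr
  }
  inc[!hit] <- -1 / (N - sum(hit))
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

# Brute-force interval-scan region annotation with explicit precedence.
oracle_region <- function(chrom, pos, models, window = 1000L,
                          splice_bp = 2L) {
  g <- models$genes
  f <- models$features
  out_region <- character(length(pos))
  out_gene <- rep(NA_character_, length(pos))
  for (s in seq_along(pos)) {
    best_rank <- Inf
    best_region <- "intergenic"
    best_gene <- NA_character_
    consider <- function(rank, region, gid) {
      if (rank < best_rank ||
          (rank == best_rank && !is.na(best_gene) && gid < best_gene)) {
        best_rank <<- rank
        best_region <<- region
        best_gene <<- gid
      }
    }
    for (i in seq_len(nrow(g))) {
      if (g$chrom[i] != chrom[s]) next
      gid <- g$gene_id[i]
      ex <- f[f$gene_id == gid & f$type == "exon", , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      p <- pos[s]
      if (nrow(ex) > 1L) {
        for (k in seq_len(nrow(ex) - 1L)) {
          is0 <- ex$end[k] + 1L
          ie0 <- ex$start[k + 1L] - 1L
          if (ie0 < is0) next
          if ((p >= is0 && p <= min(ie0, is0 + splice_bp - 1L)) ||
              (p >= max(is0, ie0 - splice_bp + 1L) && p <= ie0)) {
            consider(1, "splicing", gid)
          }
          if (p >= is0 && p <= ie0) {
            if (g$biotype[i] == "protein_coding") consider(5, "intronic", gid)
            else consider(6, "ncRNA_intronic", gid)
          }
        }
      }
      inside <- function(type) {
        d <- f[f$gene_id == gid & f$type == type, , drop = FALSE]
        nrow(d) > 0L && any(d$start <= p & d$end >= p)
      }
      if (inside("CDS")) consider(2, "exonic", gid)
      if (g$biotype[i] != "protein_coding" && inside("exon")) {
        consider(2, "exonic", gid)
      }
      if (inside("five_prime_utr")) consider(3, "5UTR", gid)
      if (inside("three_prime_utr")) consider(4, "3UTR", gid)
      if (g$strand[i] == "-") {
        if (p > g$end[i] && p <= g$end[i] + window) consider(7, "upstream", gid)
        if (p < g$start[i] && p >= g$start[i] - window) {
          consider(8, "downstream", gid)
        }
      } else {
        if (p < g$start[i] && p >= g$start[i] - window) {
          consider(7, "upstream", gid)
        }
        if (p > g$end[i] && p <= g$end[i] + window) consider(8, "downstream", gid)
      }
    }
    out_region[s] <- best_region
    out_gene[s] <- best_gene
  }
  data.frame(region = out_region, gene_id = out_gene,
             stringsAsFactors = FALSE)
}

oracle_size_factors <- function(counts) {
  ok <- apply(counts, 1L, function(x) all(x > 0))
  ratios <- matrix(NA_real_, sum(ok), ncol(counts))
  idx <- which(ok)
  for (ii in seq_along(idx)) {
    gm <- prod(counts[idx[ii], ])^(1 / ncol(counts))
    ratios[ii, ] <- counts[idx[ii], ] / gm
  }
  sf <- apply(ratios, 2L, median)
  sf / prod(sf)^(1 / length(sf))
}

oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# Codon-effect lookup straight off the standard genetic code.
oracle_codon_effect <- function(codon, pos_in_codon, alt_base) {
  gc_tab <- Biostrings::GENETIC_CODE
  mutated <- codon
  substr(mutated, pos_in_codon, pos_in_codon) <- alt_base
  a1 <- gc_tab[[codon]]
  a2 <- gc_tab[[mutated]]
  if (a1 == a2) "synonymous"
  else if (a2 == "*" && a1 != "*") "stopgain"
  else if (a1 == "*" && a2 != "*") "stoploss"
  else "nonsynonymous"
}
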