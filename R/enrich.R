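#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of member gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, "")
  out
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' overlap between a hit list and a gene set, both intersected with the
#' tested universe.
#'
#' @param hits Character vector of hit gene ids (e.g. REG calls).
#' @param gene_set Character vector of set member ids.
#' @param universe All tested gene ids.
#' @return List: `overlap`, `set_size` (post-intersection), `n_hits`,
#'   `universe_size`, `p_value`.
#' @export
ora_hypergeometric <- function(hits, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) {
    stop("ora_hypergeometric: empty universe", call. = FALSE)
  }
  hits <- intersect(unique(hits), universe)
  set_u <- intersect(unique(gene_set), universe)
  k <- length(intersect(hits, set_u))
  p <- stats::phyper(k - 1L, length(set_u),
                     length(universe) - length(set_u),
                     length(hits), lower.tail = FALSE)
  list(overlap = k, set_size = length(set_u), n_hits = length(hits),
       universe_size = length(universe), p_value = p)
}

#' Over-representation analysis across a gene-set collection
#'
#' @param hits,universe As in [ora_hypergeometric()].
#' @param gene_sets Named list of gene sets (see [read_gmt()]). Sets empty
#'   after intersection with the universe are skipped.
#' @return Data frame sorted by p-value: `set`, `overlap`, `set_size`,
#'   `p_value`.
#' @export
ora_test <- function(hits, gene_sets, universe) {
  rows <- lapply(names(gene_sets), function(nm) {
    r <- ora_hypergeometric(hits, gene_sets[[nm]], universe)
    if (r$set_size == 0L) return(NULL)
    data.frame(set = nm, overlap = r$overlap, set_size = r$set_size,
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set = character(), overlap = integer(),
                      set_size = integer(), p_value = numeric()))
  }
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Weighted Kolmogorov-Smirnov-style enrichment score of one set against a
# ranked list. `hit_pos` are 1-based positions of set members in the
# ranking, `scores` the full ranking metric. Hit steps are |score|^weight
# normalized over the set; miss steps are uniform. The ES is the running
# sum's maximum deviation from zero.
gsea_es <- function(hit_pos, scores, weight = 1) {
  N <- length(scores)
  k <- length(hit_pos)
  hit_pos <- sort(hit_pos)
  w <- abs(scores[hit_pos])^weight
  nr <- sum(w)
  if (nr == 0) w[] <- 1 / k else w <- w / nr
  miss <- 1 / (N - k)
  cum_w <- cumsum(w)
  idx <- seq_len(k)
  peaks <- cum_w - (hit_pos - idx) * miss          # just after each hit
  valleys <- cum_w - w - (hit_pos - idx) * miss    # just before each hit
  # candidates interleaved in walk order so exact |ES| ties resolve to the
  # earliest extremum of the running sum, as a full walk would
  cand <- as.vector(rbind(valleys, peaks))
  cand[which.max(abs(cand))]
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted running-sum GSEA on a preranked list. Genes are sorted
#' by the ranking metric (descending); walking down the list, the running
#' sum rises by the set-normalized |metric|^weight at members and falls
#' uniformly at non-members; the enrichment score (ES) is the maximum
#' deviation from zero. Significance comes from gene-label permutations
#' (random sets of the same size), sign-matched, with the +1-corrected
#' estimate, so p >= 1/(n_perm + 1). The normalized score (NES) divides the
#' ES by the mean |ES| of same-sign permutations.
#'
#' @param ranks Named numeric vector: ranking metric (e.g. log2 fold
#'   change) per gene id; names must be unique.
#' @param gene_sets Named list of gene sets; sets with fewer than
#'   `min_size` members in the ranking are skipped.
#' @param weight Hit-increment exponent (default 1).
#' @param n_perm Number of gene-label permutations (default 1000,
#'   minimum 100).
#' @param seed Optional seed for the permutations (deterministic output
#'   when set).
#' @param min_size Minimum post-intersection set size (default 5).
#' @return Data frame: `set`, `size`, `es`, `nes`, `p_value`, `direction`.
#' @export
gsea_preranked <- function(ranks, gene_sets, weight = 1, n_perm = 1000L,
                           seed = NULL, min_size = 5L) {
  if (anyDuplicated(names(ranks))) {
    stop("gsea_preranked: duplicate gene ids in ranking", call. = FALSE)
  }
  if (n_perm < 100L) {
    stop("gsea_preranked: n_perm must be at least 100", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  ord <- order(ranks, decreasing = TRUE)
  scores <- ranks[ord]
  ids <- names(ranks)[ord]
  N <- length(scores)

  rows <- lapply(names(gene_sets), function(nm) {
    pos <- which(ids %in% gene_sets[[nm]])
    k <- length(pos)
    if (k < min_size || k >= N) return(NULL)
    es <- gsea_es(pos, scores, weight)
    perm <- vapply(seq_len(n_perm), function(b) {
      gsea_es(sample.int(N, k), scores, weight)
    }, 1.0)
    # sign-matched: a positive ES is referred to the positive tail of the
    # permutation null (and mirrored for negative), the classic convention;
    # comparing against the whole null would halve p for a sign picked by
    # the data and break null uniformity
    if (es >= 0) {
      p <- (1 + sum(perm >= es)) / (1 + sum(perm >= 0))
      same <- perm[perm > 0]
    } else {
      p <- (1 + sum(perm <= es)) / (1 + sum(perm < 0))
      same <- perm[perm < 0]
    }
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    data.frame(set = nm, size = k, es = es, nes = nes, p_value = p,
               direction = ifelse(es >= 0, "top", "bottom"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p_value = numeric(),
                      direction = character()))
  }
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
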