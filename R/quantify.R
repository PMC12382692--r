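#' Aggregate edited reads to the gene level
#'
#' Sums, per gene and sample, the edited-read (alt) counts over every
#' retained editing site assigned to that gene, with every site weighted
#' equally. Sites without a host gene (intergenic) are dropped; genes with
#' no retained site are absent from the matrix.
#'
#' @param es An `editing_sites` object.
#' @param models Optional `gene_models`; when supplied, site gene ids are
#'   checked against the annotation and an unknown id is an error.
#' @return Integer matrix genes x samples of summed edited-read counts, with
#'   attribute `site_index`: a list mapping each gene to the row indices of
#'   its contributing sites in `es$sites`.
#' @export
aggregate_gene_editing <- function(es, models = NULL) {
  stopifnot(inherits(es, "editing_sites"))
  gid <- es$sites$gene_id
  if (!is.null(models)) {
    unknown <- setdiff(stats::na.omit(unique(gid)), models$genes$gene_id)
    if (length(unknown)) {
      stop("aggregate_gene_editing: sites reference unknown gene id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  keep <- !is.na(gid)
  if (!any(keep)) {
    m <- matrix(0L, 0L, length(es$samples),
                dimnames = list(NULL, es$samples))
    attr(m, "site_index") <- list()
    return(m)
  }
  a <- es$alt_depth[keep, , drop = FALSE]
  g <- gid[keep]
  m <- rowsum(a, group = g)
  storage.mode(m) <- "integer"
  colnames(m) <- es$samples
  attr(m, "site_index") <- split(which(keep), g)[rownames(m)]
  m
}

#' Transcripts-per-million normalization
#'
#' TPM(g, j) = (count / length_kb) / sum_g(count / length_kb) * 1e6, using
#' the effective gene length (exon-union width). Columns therefore sum to
#' one million. A sample with zero total counts cannot be normalized; its
#' column is left at zero and reported in the `zero_samples` attribute.
#'
#' @param counts Genes x samples count matrix (gene rownames).
#' @param lengths Named vector of effective gene lengths in bp; must cover
#'   all genes in `counts` and be positive.
#' @return TPM matrix of the same shape, with attribute `zero_samples`.
#' @export
tpm <- function(counts, lengths) {
  lengths <- lengths[rownames(counts)]
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    stop("tpm: every gene needs a positive effective length", call. = FALSE)
  }
  rate <- counts / (lengths / 1000)
  denom <- colSums(rate)
  zero <- denom == 0
  denom[zero] <- 1
  out <- sweep(rate, 2L, denom, "/") * 1e6
  attr(out, "zero_samples") <- colnames(counts)[zero]
  if (any(zero)) {
    warning("tpm: sample(s) with zero counts left unnormalized: ",
            paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
  }
  out
}

#' Histogram of editing frequencies per group
#'
#' Bins the editing frequencies of retained sample calls, separately per
#' phenotype group. Default bins have width 0.05 and cover the retained
#' range [0.1, 1] (left edge included via the first bin).
#'
#' @param es An `editing_sites` object.
#' @param groups Named character vector mapping sample id to group label
#'   (see [sample_groups()]).
#' @param breaks Bin edges (default `seq(0.1, 1, by = 0.05)`).
#' @return Data frame with `group`, `bin_low`, `bin_high`, `count`; the
#'   counts per group sum to the number of retained sample calls.
#' @export
frequency_histogram <- function(es, groups,
                                breaks = seq(0.1, 1, by = 0.05)) {
  stopifnot(inherits(es, "editing_sites"))
  out <- list()
  for (grp in unique(groups)) {
    cols <- names(groups)[groups == grp]
    f <- es$frequency[, cols, drop = FALSE]
    kept <- es$call_retained[, cols, drop = FALSE]
    vals <- f[kept]
    h <- graphics::hist(vals, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE, right = TRUE)
    out[[grp]] <- data.frame(group = grp,
                             bin_low = breaks[-length(breaks)],
                             bin_high = breaks[-1L],
                             count = h$counts,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

site_key <- function(sites) {
  paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
}

#' Shared and group-exclusive editing sites
#'
#' A site (identified by chrom, pos, ref, alt) is present in a group when it
#' has at least `min_samples` retained sample calls within that group. The
#' three returned sets partition the union of sites present in either group.
#'
#' @param es An `editing_sites` object.
#' @param groups Named character vector mapping sample id to one of exactly
#'   two group labels.
#' @param min_samples Minimum retained calls for within-group presence.
#' @return List with the two exclusive sets (named `only_<group>`),
#'   `shared`, and `counts` (named integer vector).
#' @export
group_overlap <- function(es, groups, min_samples = 1L) {
  stopifnot(inherits(es, "editing_sites"))
  labs <- unique(groups)
  if (length(labs) != 2L) {
    stop("group_overlap: exactly two groups required", call. = FALSE)
  }
  keys <- site_key(es$sites)
  present <- lapply(labs, function(grp) {
    cols <- names(groups)[groups == grp]
    keys[rowSums(es$call_retained[, cols, drop = FALSE]) >= min_samples]
  })
  shared <- intersect(present[[1]], present[[2]])
  only1 <- setdiff(present[[1]], present[[2]])
  only2 <- setdiff(present[[2]], present[[1]])
  out <- list(only1, shared, only2)
  names(out) <- c(paste0("only_", labs[1]), "shared", paste0("only_", labs[2]))
  out$counts <- c(stats::setNames(length(only1), paste0("only_", labs[1])),
                  shared = length(shared),
                  stats::setNames(length(only2), paste0("only_", labs[2])))
  out
}

#' Principal component analysis of editing frequencies
#'
#' Samples are the observations and sites the variables. Frequencies missing
#' because of zero depth are imputed as 0, each site is centred across
#' samples, and the centred matrix is decomposed by SVD. Component signs
#' follow a deterministic convention: the largest-magnitude site loading of
#' each component is made positive.
#'
#' @param freq Sites x samples numeric matrix of editing frequencies
#'   (e.g. `es$frequency`).
#' @return List: `coords` (samples x components), `explained`
#'   (variance fractions summing to 1 over all components), `loadings`
#'   (sites x components), `sdev`.
#' @export
editing_pca <- function(freq) {
  if (ncol(freq) < 2L) {
    stop("editing_pca: at least two samples required", call. = FALSE)
  }
  x <- freq
  x[is.na(x)] <- 0
  xc <- x - rowMeans(x)
  if (all(abs(xc) < 1e-12)) {
    warning("editing_pca: frequency matrix is constant across samples; ",
            "no variance to decompose", call. = FALSE)
    k <- ncol(x) - 1L
    return(list(coords = matrix(0, ncol(x), k,
                                dimnames = list(colnames(x), paste0("PC", seq_len(k)))),
                explained = rep(NA_real_, k),
                loadings = matrix(0, nrow(x), k), sdev = rep(0, k)))
  }
  sv <- svd(t(xc))
  d <- sv$d
  explained <- d^2 / sum(d^2)
  for (k in seq_along(d)) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) {
      sv$v[, k] <- -sv$v[, k]
      sv$u[, k] <- -sv$u[, k]
    }
  }
  coords <- sv$u %*% diag(d, length(d))
  dimnames(coords) <- list(colnames(freq), paste0("PC", seq_along(d)))
  colnames(sv$v) <- paste0("PC", seq_along(d))
  list(coords = coords, explained = explained, loadings = sv$v,
       sdev = d / sqrt(max(1L, ncol(freq) - 1L)))
}
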