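#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: for every gene with nonzero counts in
#' all samples the count is divided by the gene's geometric mean across
#' samples, and the sample's factor is the median of these ratios. Factors
#' are rescaled to geometric mean 1. When no gene is nonzero in every
#' sample, the method is undefined and the function falls back to
#' total-count ratios with a warning.
#'
#' @param counts Genes x samples count matrix.
#' @return Named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  logc <- log(counts)
  loggeo <- rowMeans(logc)
  ok <- is.finite(loggeo)
  if (!any(ok)) {
    warning("size_factors: no gene has nonzero counts in every sample; ",
            "falling back to total-count ratios", call. = FALSE)
    sf <- colSums(counts)
    sf <- sf / exp(mean(log(sf)))
    return(stats::setNames(sf, colnames(counts)))
  }
  sf <- apply(logc[ok, , drop = FALSE], 2L, function(lc) {
    exp(stats::median(lc - loggeo[ok]))
  })
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Per-gene dispersion by method of moments with trend shrinkage
#'
#' For each gene the NB dispersion alpha (Var = mu + alpha * mu^2) is
#' estimated from size-factor-normalized counts as
#' `alpha = (v - m) / m^2`, where `m` is the overall normalized mean and
#' `v` the pooled within-group variance, floored at `1e-8`. Gene-wise
#' estimates are then shrunk toward a parametric mean-dispersion trend
#' `alpha(m) = a0 + a1/m` (fitted over all genes, coefficients constrained
#' non-negative) with weight `shrink_weight`; with few replicates the
#' gene-wise moment estimate is very noisy and the trend carries most of
#' the information. All-zero genes get `NA` and are excluded from testing.
#'
#' @param counts Genes x samples count matrix.
#' @param group Factor/character vector of group labels per sample.
#' @param sf Size factors (default [size_factors()]).
#' @param shrink_weight Weight of the trend in the shrunken estimate,
#'   in [0, 1].
#' @return Named numeric vector of dispersions (`NA` for all-zero genes),
#'   with the fitted trend coefficients in attribute `trend`.
#' @export
estimate_dispersion <- function(counts, group, sf = size_factors(counts),
                                shrink_weight = 0.65) {
  group <- as.factor(group)
  if (any(table(group) < 2L)) {
    stop("estimate_dispersion: need >= 2 samples per group", call. = FALSE)
  }
  nc <- sweep(counts, 2L, sf, "/")
  m <- rowMeans(nc)
  v <- numeric(nrow(nc))
  for (g in levels(group)) {
    sub <- nc[, group == g, drop = FALSE]
    dfree <- ncol(sub) - 1L
    v <- v + apply(sub, 1L, stats::var) * dfree
  }
  v <- v / (length(group) - nlevels(group))

  raw <- pmax((v - m) / m^2, 1e-8)
  raw[m == 0] <- NA_real_

  use <- !is.na(raw) & m > 0
  a0 <- stats::median(raw[use])
  a1 <- 0
  if (sum(use) >= 10L) {
    fit <- try(stats::lm(raw[use] ~ I(1 / m[use])), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      cf <- pmax(stats::coef(fit), 0)
      a0 <- unname(cf[1]); a1 <- unname(cf[2])
    }
  }
  trend <- pmax(a0 + a1 / m, 1e-8)
  alpha <- (1 - shrink_weight) * raw + shrink_weight * trend
  alpha[!use] <- NA_real_
  out <- stats::setNames(pmax(alpha, 1e-8), rownames(counts))
  out[!use] <- NA_real_
  attr(out, "trend") <- c(a0 = a0, a1 = a1)
  out
}

#' Per-gene negative-binomial Wald test for a two-group design
#'
#' Fits, for every gene, the NB generalized linear model
#' `mu_gj = s_j * q_g * 2^(beta_g * x_j)` with `x_j = 1` for the treatment
#' group, dispersion fixed at the supplied per-gene estimate (the GLM is fit
#' with [stats::glm()] and the [MASS::negative.binomial()] family, with the
#' log size factor as offset). The Wald statistic `z = beta / SE(beta)` is
#' referred to the standard normal, two-sided. The reported
#' `log2FoldChange` is the treatment-vs-reference contrast: with
#' `reference = "HVH"` and treatment `"LVH"`, positive values mean higher
#' in LVH.
#'
#' @param counts Genes x samples count matrix.
#' @param group Group labels per sample (character/factor, two levels).
#' @param reference Reference group level (denominator of the fold change).
#' @param sf Size factors (default [size_factors()]).
#' @param dispersions Per-gene dispersions (default [estimate_dispersion()]).
#' @return Data frame (one row per gene): `gene_id`, `baseMean`
#'   (mean normalized count), `log2FoldChange`, `lfcSE`, `stat`, `pvalue`,
#'   `padj` (Benjamini-Hochberg, informational only), `converged`.
#'   All-zero or non-converging genes carry `NA` statistics.
#' @export
nb_wald_test <- function(counts, group, reference = NULL,
                         sf = size_factors(counts),
                         dispersions = NULL) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) {
    stop("nb_wald_test: exactly two groups required", call. = FALSE)
  }
  if (!is.null(reference)) group <- stats::relevel(group, ref = reference)
  if (any(table(group) < 2L)) {
    stop("nb_wald_test: need >= 2 samples per group", call. = FALSE)
  }
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersion(counts, group, sf)
  }
  x <- as.integer(group) - 1L
  off <- log(sf)
  nc <- sweep(counts, 2L, sf, "/")
  n <- nrow(counts)
  lfc <- se <- stat <- pval <- rep(NA_real_, n)
  conv <- rep(FALSE, n)

  for (i in seq_len(n)) {
    alpha <- dispersions[i]
    if (is.na(alpha) || all(counts[i, ] == 0L)) next
    y <- counts[i, ]
    fam <- MASS::negative.binomial(theta = 1 / alpha, link = "log")
    fit <- try(suppressWarnings(
      stats::glm(y ~ x, family = fam, offset = off,
                 control = stats::glm.control(maxit = 50))), silent = TRUE)
    if (inherits(fit, "try-error") || !fit$converged) next
    # The NB variance is fully specified by theta; fix the GLM dispersion
    # at 1 so the Wald SE comes from the NB Fisher information and not a
    # Pearson quasi-dispersion estimate.
    cf <- summary(fit, dispersion = 1)$coefficients
    if (nrow(cf) < 2L) next
    conv[i] <- TRUE
    lfc[i] <- cf[2L, 1L] / log(2)
    se[i] <- cf[2L, 2L] / log(2)
    z <- cf[2L, 1L] / cf[2L, 2L]
    stat[i] <- z
    pval[i] <- 2 * stats::pnorm(-abs(z))
  }
  res <- data.frame(gene_id = rownames(counts),
                    baseMean = rowMeans(nc),
                    log2FoldChange = lfc, lfcSE = se, stat = stat,
                    pvalue = pval,
                    padj = stats::p.adjust(pval, method = "BH"),
                    converged = conv,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Classify differential results into up/down/NS calls
#'
#' A gene is called up when its log2 fold change exceeds the threshold and
#' its p-value is below `alpha`, down for the mirrored condition, NS
#' otherwise. The fold-change comparison is strict (`>`) with
#' `strict = "gt"` (the editing-track convention) and inclusive (`>=`) with
#' `strict = "ge"` (the expression-track convention).
#'
#' @param results Data frame from [nb_wald_test()].
#' @param lfc_threshold Absolute log2-fold-change threshold (default 1).
#' @param p_threshold Raw p-value threshold (default 0.05).
#' @param strict `"gt"` or `"ge"` fold-change comparison.
#' @return `results` with a `call` factor column (`up`, `down`, `NS`);
#'   attribute `counts` holds `n_up`, `n_down`, `n_total`.
#' @export
classify_calls <- function(results, lfc_threshold = 1, p_threshold = 0.05,
                           strict = c("gt", "ge")) {
  strict <- match.arg(strict)
  lfc <- results$log2FoldChange
  p <- results$pvalue
  exceed <- if (strict == "gt") abs(lfc) > lfc_threshold
            else abs(lfc) >= lfc_threshold
  sig <- !is.na(p) & !is.na(lfc) & p < p_threshold & exceed
  call <- rep("NS", nrow(results))
  call[sig & lfc > 0] <- "up"
  call[sig & lfc < 0] <- "down"
  results$call <- factor(call, levels = c("up", "down", "NS"))
  attr(results, "counts") <- c(n_up = sum(call == "up"),
                               n_down = sum(call == "down"),
                               n_total = nrow(results))
  results
}

#' Differential testing of a count track with study conventions
#'
#' Convenience wrapper running [size_factors()], [estimate_dispersion()],
#' [nb_wald_test()] and [classify_calls()] with the per-track thresholds:
#' the editing track calls differentially edited genes (REGs) at
#' |log2FC| > 1 and p < 0.05, the expression track calls differentially
#' expressed genes (DEGs) at |log2FC| >= 1 and p < 0.05. Fold changes are
#' oriented treatment vs reference (default LVH vs HVH: positive = higher
#' in LVH). P-values are raw; a Benjamini-Hochberg `padj` column is carried
#' along for reference but plays no part in the calls.
#'
#' @param counts Genes x samples count matrix.
#' @param group Group labels per sample.
#' @param track `"editing"` (REGs, strict `>`) or `"expression"`
#'   (DEGs, `>=`).
#' @param reference Reference group (default `"HVH"` when present).
#' @param lfc_threshold,p_threshold Call thresholds.
#' @param shrink_weight Dispersion trend shrinkage weight.
#' @return Classified results data frame (see [classify_calls()]).
#' @export
diff_test <- function(counts, group, track = c("editing", "expression"),
                      reference = NULL, lfc_threshold = 1,
                      p_threshold = 0.05, shrink_weight = 0.65) {
  track <- match.arg(track)
  group <- as.factor(group)
  if (is.null(reference) && "HVH" %in% levels(group)) reference <- "HVH"
  if (!is.null(reference)) group <- stats::relevel(group, ref = reference)
  sf <- size_factors(counts)
  disp <- estimate_dispersion(counts, group, sf,
                              shrink_weight = shrink_weight)
  res <- nb_wald_test(counts, group, sf = sf, dispersions = disp)
  classify_calls(res, lfc_threshold, p_threshold,
                 strict = if (track == "editing") "gt" else "ge")
}
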