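QUADRANT_LABELS <- c("edit_down", "edit_ns", "edit_up")

# Default quadrant index lookup. Rows: expression trichotomy (down, ns, up);
# columns: editing trichotomy (down, ns, up). Anchored so that
# (edit_up, expr_down) -> 1, (edit_ns, expr_ns) -> 5 and
# (edit_down, expr_up) -> 9 (high expression with low editing).
default_quadrant_lookup <- function() {
  m <- matrix(NA_integer_, 3L, 3L,
              dimnames = list(c("expr_down", "expr_ns", "expr_up"),
                              c("edit_down", "edit_ns", "edit_up")))
  for (e in 0:2) {          # expression: down=0, ns=1, up=2
    for (d in 0:2) {        # editing:    down=0, ns=1, up=2
      m[e + 1L, d + 1L] <- 1L + (2L - d) + 3L * e
    }
  }
  m
}

#' Nine-quadrant integration of editing and expression fold changes
#'
#' Joins the editing and expression differential results on gene id and
#' trichotomizes each log2 fold change at the threshold `t`: down when
#' lfc <= -t, up when lfc >= t, ns otherwise. The pair of trichotomies
#' places each gene in one of nine quadrants; the default numeric lookup
#' puts (edit_up, expr_down) in quadrant 1, the double-ns centre in 5 and
#' (edit_down, expr_up) — high expression with low editing — in 9. Corner
#' quadrants 1, 3, 7 and 9, where both tracks change, are flagged
#' high-confidence. Genes present in only one track are excluded from the
#' quadrant table and reported in the `single_track` attribute.
#'
#' @param editing_results,expression_results Data frames with `gene_id` and
#'   `log2FoldChange` (e.g. from [diff_test()]); genes with `NA` fold
#'   change are treated as single-track.
#' @param t Absolute log2-fold-change threshold (default 1).
#' @param lookup 3x3 integer lookup matrix (rows expr_down/ns/up, columns
#'   edit_down/ns/up); default [default_quadrant_lookup()].
#' @return Data frame: `gene_id`, `editing_lfc`, `expression_lfc`,
#'   `edit_state`, `expr_state`, `label`, `quadrant`, `high_confidence`;
#'   attribute `single_track` lists genes tested in only one omics track.
#' @export
nine_quadrant <- function(editing_results, expression_results, t = 1,
                          lookup = default_quadrant_lookup()) {
  stopifnot(t > 0)
  ed <- editing_results[, c("gene_id", "log2FoldChange")]
  ex <- expression_results[, c("gene_id", "log2FoldChange")]
  names(ed)[2] <- "editing_lfc"
  names(ex)[2] <- "expression_lfc"
  joint <- merge(ed, ex, by = "gene_id")
  ok <- !is.na(joint$editing_lfc) & !is.na(joint$expression_lfc)
  single <- sort(unique(c(setdiff(ed$gene_id, ex$gene_id),
                          setdiff(ex$gene_id, ed$gene_id),
                          joint$gene_id[!ok])))
  joint <- joint[ok, , drop = FALSE]
  if (nrow(joint) == 0L) {
    stop("nine_quadrant: no gene tested in both tracks", call. = FALSE)
  }
  tri <- function(lfc) ifelse(lfc <= -t, 0L, ifelse(lfc >= t, 2L, 1L))
  d <- tri(joint$editing_lfc)
  e <- tri(joint$expression_lfc)
  joint$edit_state <- c("edit_down", "edit_ns", "edit_up")[d + 1L]
  joint$expr_state <- c("expr_down", "expr_ns", "expr_up")[e + 1L]
  joint$label <- paste(joint$edit_state, joint$expr_state, sep = ".")
  joint$quadrant <- lookup[cbind(e + 1L, d + 1L)]
  joint$high_confidence <- joint$quadrant %in% c(1L, 3L, 7L, 9L)
  joint <- joint[order(joint$quadrant, joint$gene_id), , drop = FALSE]
  rownames(joint) <- NULL
  attr(joint, "single_track") <- single
  joint
}

#' Pearson correlation between a per-sample quantity and a phenotype
#'
#' Sample Pearson coefficient with the two-sided p-value from the
#' t-transform on n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length (n >= 3), e.g. per-sample
#'   expression of an editing enzyme and villus height.
#' @return List: `r`, `p_value`, `n`.
#' @export
pearson_phenotype_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    stop("pearson_phenotype_correlation: length mismatch", call. = FALSE)
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop("pearson_phenotype_correlation: need at least 3 paired values",
         call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_phenotype_correlation: zero variance; correlation ",
         "undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Two-group t test on a phenotype field
#'
#' Welch's unequal-variance t test by default (robust at n = 4 per group),
#' with the classical Student test available via `var_equal = TRUE`.
#' The contrast is `group1 - group2` in the order given by `groups`
#' (default: alphabetical level order, HVH - LVH for the study labels).
#'
#' @param phenotypes A `phenotype_table` (or data frame with `group` and
#'   the requested field).
#' @param field Column to test (e.g. `"villus_height"`).
#' @param groups Optional length-2 character vector fixing the contrast
#'   order.
#' @param var_equal Use the pooled-variance Student test.
#' @return List: `groups`, `means`, `sds`, `n`, `t`, `df`, `p_value`.
#' @export
group_ttest <- function(phenotypes, field = "villus_height", groups = NULL,
                        var_equal = FALSE) {
  if (!field %in% names(phenotypes)) {
    stop("group_ttest: no field '", field, "' in phenotype table",
         call. = FALSE)
  }
  labs <- if (is.null(groups)) sort(unique(phenotypes$group)) else groups
  if (length(labs) != 2L) {
    stop("group_ttest: exactly two groups required", call. = FALSE)
  }
  x <- phenotypes[[field]][phenotypes$group == labs[1]]
  y <- phenotypes[[field]][phenotypes$group == labs[2]]
  if (length(x) < 2L || length(y) < 2L) {
    stop("group_ttest: each group needs at least 2 observations",
         call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(groups = labs,
       means = stats::setNames(c(mean(x), mean(y)), labs),
       sds = stats::setNames(c(stats::sd(x), stats::sd(y)), labs),
       n = stats::setNames(c(length(x), length(y)), labs),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
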