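#' Configuration for a synthetic editome study
#'
#' Bundles every tunable of the synthetic-data generator: study design
#' (two phenotype groups, `n_samples_per_group` biological replicates each),
#' the editing model (negative-binomial site depths, binomially sampled
#' edited reads), the expression model (negative-binomial counts with
#' planted log2 fold changes), and the histology phenotypes (normal villus
#' heights and crypt depths per group, in micrometres).
#'
#' Ground-truth effects are planted in three gene panels: `n_reg_genes`
#' genes whose editing frequency is shifted upward by `reg_freq_shift` in
#' the high-villus (HVH) group, `n_deg_genes` genes whose expression mean is
#' scaled by `2^deg_log2fc` in the low-villus (LVH) group, and
#' `n_joint_genes` genes planted in both panels (these are the genes the
#' nine-quadrant integration should recover in its corner quadrants).
#'
#' @param n_genes Number of genes to simulate.
#' @param n_samples_per_group Biological replicates per phenotype group.
#' @param mean_sites_per_gene Poisson mean of editing sites per gene
#'   (at least one site is always placed).
#' @param mean_depth Negative-binomial mean read depth per site and sample.
#' @param depth_dispersion Negative-binomial size parameter for depths
#'   (larger = closer to Poisson).
#' @param base_edit_freq Baseline true editing frequency; per-site baselines
#'   are drawn uniformly from `base_edit_freq` plus/minus `freq_jitter`.
#' @param freq_jitter Half-width of the per-site baseline frequency draw.
#' @param n_reg_genes Genes with a group-shifted editing frequency.
#' @param reg_freq_shift Additive frequency shift applied in the HVH group
#'   at planted REG genes. With the defaults (baseline 0.2, shift 0.6) the
#'   true gene-level edited-count log2 fold change (LVH vs HVH) is close
#'   to -2.
#' @param n_deg_genes Genes with a planted expression fold change.
#' @param deg_log2fc Log2 fold change (LVH vs HVH) planted at DEG genes;
#'   positive means higher expression in LVH.
#' @param n_joint_genes Genes planted as both REG and DEG (drawn first,
#'   then topped up to the panel sizes with disjoint extras).
#' @param expr_mean,expr_dispersion Negative-binomial mean and size for
#'   baseline expression counts.
#' @param vh_mean_high,vh_mean_low Group mean villus heights (micrometres).
#' @param vh_sd Within-group villus-height standard deviation.
#' @param cd_mean_high,cd_mean_low,cd_sd Crypt-depth analogues.
#' @param decoy_fraction Fraction of variant records planted to violate
#'   exactly one hard-filter criterion.
#' @param canonical_fraction Target fraction of sites that are
#'   strand-consistent A-to-I or C-to-U substitutions.
#' @param noncoding_fraction Fraction of genes simulated as non-coding
#'   (lncRNA-like: exons but no CDS).
#' @param intergenic_fraction Fraction of additional sites placed between
#'   genes (no host gene).
#' @param flank_window Width (bp) of the upstream/downstream annotation
#'   windows flanking each gene.
#' @param seed Master seed; per-stage child seeds are derived from it, so
#'   a config is fully deterministic.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 20, seed = 7)
#' cfg$n_samples_per_group
#' @export
sim_config <- function(n_genes = 200,
                       n_samples_per_group = 4,
                       mean_sites_per_gene = 4,
                       mean_depth = 50,
                       depth_dispersion = 20,
                       base_edit_freq = 0.2,
                       freq_jitter = 0.1,
                       n_reg_genes = 20,
                       reg_freq_shift = 0.6,
                       n_deg_genes = 20,
                       deg_log2fc = 2,
                       n_joint_genes = 10,
                       expr_mean = 300,
                       expr_dispersion = 25,
                       vh_mean_high = 379.3,
                       vh_mean_low = 290.7,
                       vh_sd = 25,
                       cd_mean_high = 215,
                       cd_mean_low = 185,
                       cd_sd = 18,
                       decoy_fraction = 0.05,
                       canonical_fraction = 0.85,
                       noncoding_fraction = 0.1,
                       intergenic_fraction = 0.05,
                       flank_window = 1000,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_samples_per_group = as.integer(n_samples_per_group),
    mean_sites_per_gene = mean_sites_per_gene,
    mean_depth = mean_depth,
    depth_dispersion = depth_dispersion,
    base_edit_freq = base_edit_freq,
    freq_jitter = freq_jitter,
    n_reg_genes = as.integer(n_reg_genes),
    reg_freq_shift = reg_freq_shift,
    n_deg_genes = as.integer(n_deg_genes),
    deg_log2fc = deg_log2fc,
    n_joint_genes = as.integer(n_joint_genes),
    expr_mean = expr_mean,
    expr_dispersion = expr_dispersion,
    vh_mean_high = vh_mean_high,
    vh_mean_low = vh_mean_low,
    vh_sd = vh_sd,
    cd_mean_high = cd_mean_high,
    cd_mean_low = cd_mean_low,
    cd_sd = cd_sd,
    decoy_fraction = decoy_fraction,
    canonical_fraction = canonical_fraction,
    noncoding_fraction = noncoding_fraction,
    intergenic_fraction = intergenic_fraction,
    flank_window = as.integer(flank_window),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos <- c("n_genes", "n_samples_per_group", "mean_sites_per_gene",
           "mean_depth", "depth_dispersion", "expr_mean", "expr_dispersion",
           "flank_window")
  for (f in c("vh_sd", "cd_sd")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 0) {
      stop("sim_config: '", f, "' must be a single non-negative number",
           call. = FALSE)
    }
  }
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0) {
      stop("sim_config: '", f, "' must be a single positive number",
           call. = FALSE)
    }
  }
  frac <- c("base_edit_freq", "freq_jitter", "reg_freq_shift",
            "decoy_fraction", "canonical_fraction", "noncoding_fraction",
            "intergenic_fraction")
  for (f in frac) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("sim_config: '", f, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$base_edit_freq + cfg$freq_jitter + cfg$reg_freq_shift > 1) {
    stop("sim_config: base_edit_freq + freq_jitter + reg_freq_shift ",
         "exceeds 1; shifted editing frequencies would leave [0, 1]",
         call. = FALSE)
  }
  if (cfg$base_edit_freq - cfg$freq_jitter < 0) {
    stop("sim_config: base_edit_freq - freq_jitter is negative", call. = FALSE)
  }
  if (cfg$n_reg_genes > cfg$n_genes || cfg$n_deg_genes > cfg$n_genes) {
    stop("sim_config: planted gene panels larger than n_genes", call. = FALSE)
  }
  if (cfg$n_joint_genes > min(cfg$n_reg_genes, cfg$n_deg_genes)) {
    stop("sim_config: n_joint_genes exceeds a planted panel size",
         call. = FALSE)
  }
  if (cfg$n_samples_per_group < 2L) {
    stop("sim_config: need at least 2 samples per group", call. = FALSE)
  }
  invisible(cfg)
}

# Per-stage child seed derived from the master seed; keeps every generator
# stage independently reproducible and all seeds well below 2^31.
child_seed <- function(seed, stage) {
  offsets <- c(genome = 101L, editing = 211L, expression = 307L,
               phenotype = 401L, genesets = 503L)
  (abs(as.integer(seed)) %% 100000000L) * 7L + offsets[[stage]]
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic editome study configuration\n")
  cat(sprintf("  genes: %d (%d REG, %d DEG, %d joint), samples: %d per group\n",
              x$n_genes, x$n_reg_genes, x$n_deg_genes, x$n_joint_genes,
              x$n_samples_per_group))
  cat(sprintf("  depth ~ NB(mean %.0f, size %.0f); baseline editing %.2f +/- %.2f; HVH shift +%.2f\n",
              x$mean_depth, x$depth_dispersion, x$base_edit_freq,
              x$freq_jitter, x$reg_freq_shift))
  cat(sprintf("  expression ~ NB(mean %.0f, size %.0f); planted log2FC %.1f (LVH vs HVH)\n",
              x$expr_mean, x$expr_dispersion, x$deg_log2fc))
  cat(sprintf("  villus height: %.1f vs %.1f um (sd %.1f); seed %d\n",
              x$vh_mean_high, x$vh_mean_low, x$vh_sd, x$seed))
  invisible(x)
}
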