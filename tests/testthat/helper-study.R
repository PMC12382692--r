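# Shared small synthetic studies, generated once per test run.

.study_cache <- new.env(parent = emptyenv())

cached_study <- function(seed = 42, n_genes = 60, ...) {
  key <- paste(seed, n_genes, ...)
  if (is.null(.study_cache[[key]])) {
    cfg <- sim_config(n_genes = n_genes, seed = seed, ...)
    g <- simulate_genome(cfg)
    ed <- simulate_editing(cfg, g)
    ex <- simulate_expression(cfg, g)
    ph <- simulate_phenotypes(cfg)
    es <- call_editing_sites(ed$variants, g$models, g$genome)
    .study_cache[[key]] <- list(cfg = cfg, g = g, ed = ed, ex = ex, ph = ph,
                                es = es)
  }
  .study_cache[[key]]
}

# Minimal hand-built variant set for boundary tests: one record per row of
# the supplied annotation values, constant per-sample matrices unless given.
toy_variants <- function(qd = 10, fs = 5, mqranksum = 0, readposranksum = 0,
                         mq = 50, sor = 1, depth = 20L, alt_depth = 8L,
                         bq = 35, n_samples = 2L) {
  n <- max(lengths(list(qd, fs, mqranksum, readposranksum, mq, sor)))
  rec <- data.frame(chrom = "chr1", pos = seq_len(n) * 10L,
                    ref = "A", alt = "G",
                    qd = rep_len(qd, n), fs = rep_len(fs, n),
                    mqranksum = rep_len(mqranksum, n),
                    readposranksum = rep_len(readposranksum, n),
                    mq = rep_len(mq, n), sor = rep_len(sor, n),
                    stringsAsFactors = FALSE)
  mk <- function(x) {
    if (is.matrix(x)) x else matrix(rep_len(x, n * n_samples), n, n_samples)
  }
  variant_records(rec, mk(depth), mk(alt_depth), mk(bq),
                  paste0("S", seq_len(n_samples)),
                  c(chr1 = max(rec$pos) + 100L))
}
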