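# Fixtures built in code: tiny expression matrices, annotations, cohorts.

toy_expression <- function(n_samples = 3, genes = c("GA", "GB", "GC", "GD"),
                           seed = 42, scale = "fpkm") {
  set.seed(seed)
  m <- matrix(round(stats::rexp(n_samples * length(genes), 1 / 10), 3),
              n_samples, length(genes),
              dimnames = list(sprintf("S%02d", seq_len(n_samples)), genes))
  expression_matrix(m, scale = scale)
}

toy_annotation <- function() {
  gene_annotation(symbol = c("GA", "GB", "GC", "GD"),
                  chromosome = c("2", "2", "10", "X"),
                  tss = c(500, 100, 50, 10))
}

# A small scaled matrix whose columns are already in pixel order.
toy_scaled <- function(n_samples = 2, n_genes = 16, seed = 7) {
  set.seed(seed)
  v <- matrix(sample(0:255, n_samples * n_genes, replace = TRUE),
              n_samples, n_genes,
              dimnames = list(sprintf("S%02d", seq_len(n_samples)),
                              sprintf("G%03d", seq_len(n_genes))))
  storage.mode(v) <- "integer"
  order <- structure(colnames(v), class = "gene_order")
  structure(list(values = v, order = order,
                 scaler = structure(list(gene = colnames(v),
                                         min = rep(0, n_genes),
                                         max = rep(255, n_genes)),
                                    class = "scaler_params")),
            class = "scaled_matrix")
}

# Small planted-signal cohort for fast CNN tests: 16x16 images.
small_cohort <- function(n = 120, genes = 256, seed = 5, delta = 3,
                         alpha = 0.6) {
  cfg <- synthetic_config(n_samples = n, n_genes = genes, n_blocks = 8,
                          alpha = alpha, informative_frac = 0.25,
                          delta = delta, missing_frac = 0,
                          include_survival = FALSE, seed = seed)
  simulate_cohort(cfg)
}

cohort_stack <- function(cohort, height, width, channels = 1) {
  ord <- shared_gene_order(cohort$annotation,
                           list(colnames(cohort$expression$values)),
                           height * width * channels)
  rs <- rescale_per_gene(log2_transform(cohort$expression), ord)
  pm <- make_pixel_map(ord, aio_config(height, width, channels))
  list(stack = build_aios(rs$scaled, pm), order = ord, scaled = rs$scaled,
       pmap = pm, scaler = rs$scaler)
}
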