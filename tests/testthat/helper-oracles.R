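# Independent reference implementations used to check the package's
# statistics, kept deliberately naive.

# hypergeometric upper tail P(X >= x) by direct combinatorial summation
hyper_tail_enum <- function(x, white, black, drawn) {
  js <- max(x, 0):min(white, drawn)
  if (!length(js) || x > min(white, drawn)) return(0)
  sum(choose(white, js) * choose(black, drawn - js)) /
    choose(white + black, drawn)
}

# Fisher's combined probability test
fisher_combine_ref <- function(p) {
  pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

# literal Benjamini-Hochberg step-up
bh_ref <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    js <- which(p[o] >= p[o][i])
    q[o[i]] <- min(p[o][js] * n / js)
  }
  pmin(q, 1)
}

# small shared fixtures
fixture_tree <- function(n_taxa = 4, depth = 0.3, seed = 5,
                         fg = "t2") {
  tr <- simulate_tree(n_taxa, depth = depth, seed = seed)
  set_foreground(tr, fg)
}

fixture_params <- function(...) branch_site_params(...)

# small but complete pipeline configuration for smoke and determinism runs
tiny_config <- function(out_dir = NULL, stages = c("simulate", "orthologs",
                                                   "scan", "expression",
                                                   "enrich"), seed = 3) {
  run_config(seed = seed, n_taxa = 4, n_genes_scan = 4, n_codons = 120,
             frac_selected = 0.5, n_genes_expr = 500, n_psg_expr = 20,
             n_genes_catalog = 4, n_species_catalog = 2, n_starts = 1,
             tree_depth = 0.25, stages = stages, out_dir = out_dir)
}
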