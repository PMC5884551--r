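# The synthetic-data generators: trees, codon alignments under the
# branch-site mixture, aging count matrices and CDS catalogs.

test_that("simulated trees have the promised shape and determinism", {
  tr2 <- simulate_tree(2, depth = 0.1, seed = 7)
  expect_equal(ape::Ntip(tr2), 2)
  total <- sum(tr2$edge.length)
  expect_gt(total, 0.1)   # 2 branches, each in [0.05, 0.15]
  expect_lt(total, 0.3)
  tr6 <- simulate_tree(6, depth = 0.3, seed = 1)
  expect_equal(ape::Ntip(tr6), 6)
  expect_equal(nrow(tr6$edge), 10)  # 2n - 2 branches in a rooted binary tree
  expect_true(all(tr6$edge.length > 0))
  expect_false(anyDuplicated(tr6$tip.label) > 0)
  expect_identical(write_newick(simulate_tree(6, 0.3, seed = 1)),
                   write_newick(simulate_tree(6, 0.3, seed = 1)))
  expect_error(simulate_tree(1, 0.1, 1), "invalid-argument")
})

test_that("codon alignments follow the site-class mixture", {
  tr <- fixture_tree(5, depth = 0.15, seed = 3, fg = "t1")
  par <- fixture_params(p0 = 0.5, p1 = 0.3, omega2 = 4)
  sim <- simulate_codon_alignment(tr, par, n_codons = 10000, seed = 17)
  # class frequencies within 3 binomial SDs of (0.5, 0.3, 0.125, 0.075)
  expected <- c(0.5, 0.3, 0.125, 0.075)
  obs <- as.numeric(table(sim$truth$site_class)) / 10000
  sds <- sqrt(expected * (1 - expected) / 10000)
  expect_true(all(abs(obs - expected) <= 3 * sds))
  # no stop codon can ever be emitted
  expect_false(any(unclass(sim$alignment) %in% psgscan:::STOP_CODONS))
  expect_true(sim$truth$selected)
})

test_that("degenerate alignment regimes collapse as expected", {
  tr <- fixture_tree(4, depth = 0.2, seed = 3, fg = "t1")
  # zero-length branches: every sequence equals the root draw
  tr0 <- tr
  tr0$edge.length <- rep(0, nrow(tr$edge))
  sim0 <- simulate_codon_alignment(tr0, fixture_params(), n_codons = 30,
                                   seed = 2)
  m <- unclass(sim0$alignment)
  for (i in 2:nrow(m)) expect_identical(m[i, ], m[1, ])
  # p0 + p1 = 1: truth contains no selected-class sites
  simn <- simulate_codon_alignment(tr, fixture_params(p0 = 0.7, p1 = 0.3,
                                                      omega2 = 9),
                                   n_codons = 400, seed = 2)
  expect_equal(sum(simn$truth$site_class %in% c("2a", "2b")), 0)
  expect_false(simn$truth$selected)
  # determinism: identical seed gives byte-identical alignments
  s1 <- simulate_codon_alignment(tr, fixture_params(), 50, seed = 9)
  s2 <- simulate_codon_alignment(tr, fixture_params(), 50, seed = 9)
  expect_identical(s1$alignment, s2$alignment)
  expect_identical(s1$truth, s2$truth)
  expect_error(simulate_codon_alignment(tr, fixture_params(), 10,
                                        foreground = "nope", seed = 1),
               "unknown-branch")
})

test_that("count simulation plants the antagonistic-pleiotropy signal", {
  # null world: no regulation anywhere
  cs0 <- simulate_counts(count_sim_spec(n_genes = 300, frac_regulated = 0,
                                        n_psg = 0, seed = 5))
  expect_true(all(cs0$truth$lfc_a == 0))
  expect_true(all(cs0$truth$lfc_b == 0))
  # forced quadrant I: every planted PSG is down in A, up in B
  cs1 <- simulate_counts(count_sim_spec(n_genes = 300, n_psg = 60,
                                        q1_prob = 1, seed = 6))
  planted <- cs1$truth$planted_q1
  expect_equal(sum(planted), 60)
  expect_true(all(cs1$truth$lfc_a[planted] < 0))
  expect_true(all(cs1$truth$lfc_b[planted] > 0))
  # counts are non-negative integers with the right dimensions
  expect_true(all(cs1$counts_a >= 0))
  expect_equal(dim(cs1$counts_a), c(300, 9))   # 6 young + 3 old
  expect_equal(dim(cs1$counts_b), c(300, 9))   # 4 young + 5 old
  # dispersion -> 0 approaches the Poisson limit: variance ~ mean
  csp <- simulate_counts(count_sim_spec(n_genes = 400, n_young_a = 150,
                                        n_old_a = 150, dispersion = 1e-8,
                                        frac_regulated = 0, n_psg = 0,
                                        seed = 7))
  young <- attr(csp$counts_a, "condition") == "young"
  mu <- rowMeans(csp$counts_a[, young])
  v <- apply(csp$counts_a[, young], 1, var)
  keep <- mu > 50
  expect_equal(median(v[keep] / mu[keep]), 1, tolerance = 0.15)
  # group means recover the 2^LFC ratio at large replicate counts
  csr <- simulate_counts(count_sim_spec(n_genes = 200, n_young_a = 200,
                                        n_old_a = 200, dispersion = 0.02,
                                        frac_regulated = 1, n_psg = 0,
                                        seed = 8))
  old <- attr(csr$counts_a, "condition") == "old"
  ratio <- log2(rowMeans(csr$counts_a[, old]) /
                  rowMeans(csr$counts_a[, !old]))
  keep <- rowMeans(csr$counts_a) > 100
  expect_lt(median(abs(ratio - csr$truth$lfc_a)[keep]), 0.1)
})

test_that("CDS catalogs are valid coding sequences with known orthology", {
  cs <- simulate_cds_catalog(6, 3, isoforms_per_gene = 2,
                             divergence = 0.04, seed = 9)
  cat <- cs$catalog
  expect_equal(nrow(cat), 6 * 3 * 2)
  for (s in cat$seq) {
    expect_equal(nchar(s) %% 3, 0)
    cod <- psgscan:::split_codons(s)
    expect_equal(cod[1], "ATG")
    expect_true(cod[length(cod)] %in% psgscan:::STOP_CODONS)
    expect_false(any(cod[-length(cod)] %in% psgscan:::STOP_CODONS))
  }
  # divergence 0: orthologs are identical sequences across species
  cs0 <- simulate_cds_catalog(3, 2, divergence = 0, seed = 10)
  byg <- split(cs0$catalog$seq, cs0$catalog$gene)
  for (g in byg) expect_equal(length(unique(g)), 1)
  # 1 gene, 1 isoform, 2 species: exactly one true ortholog pair
  cs1 <- simulate_cds_catalog(1, 2, seed = 11)
  expect_equal(nrow(cs1$truth), 2)
  expect_equal(unique(cs1$truth$ortholog), cs1$truth$gene[1])
  # truth covers every gene in every species exactly once
  expect_equal(nrow(unique(cs$truth[c("gene", "species")])), 18)
})
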