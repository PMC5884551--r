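# Differential expression, quadrant classification and the pleiotropy
# statistics.

test_that("size factors follow the median-of-ratios definition", {
  set.seed(12)
  m <- matrix(rpois(600, 50) + 1L, nrow = 100)
  colnames(m) <- paste0("s", 1:6)
  rownames(m) <- paste0("g", 1:100)
  # two identical samples get identical factors
  cm2 <- count_matrix(m[, c(1, 1, 2, 3)],
                      condition = c("young", "young", "old", "old"))
  sf2 <- size_factors(cm2)
  expect_equal(sf2[1], sf2[2])
  # doubling one sample doubles its factor relative to the original
  m3 <- cbind(a = m[, 1], b = 2 * m[, 1], c = m[, 2], d = m[, 3])
  sf3 <- size_factors(count_matrix(m3, rep(c("young", "old"), each = 2)))
  expect_equal(unname(sf3["b"] / sf3["a"]), 2, tolerance = 1e-12)
  expect_equal(exp(mean(log(sf3))), 1, tolerance = 1e-12)
  # permuting samples permutes factors
  perm <- c(3, 1, 4, 2)
  sfp <- size_factors(count_matrix(m3[, perm],
                                   rep(c("young", "old"), 2)))
  expect_equal(unname(sfp), unname(sf3[perm]), tolerance = 1e-12)
  # no gene expressed everywhere
  z <- matrix(0L, 5, 4, dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  z[1, 1] <- 10L
  expect_error(size_factors(count_matrix(z, rep(c("young", "old"), each = 2))),
               "normalization-error")
})

test_that("the NB Wald test is calibrated under the null", {
  # label shuffling on unregulated data: p-values ~ uniform
  cs <- simulate_counts(count_sim_spec(n_genes = 2000, frac_regulated = 0,
                                       n_psg = 0, seed = 101))
  de <- de_test(cs$counts_a)
  typeI <- mean(de$p_value < 0.05)
  expect_gte(typeI, 0.02)
  expect_lte(typeI, 0.09)
  # identical counts in every sample: LFC ~ 0
  flat <- matrix(7L, nrow = 3, ncol = 6,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:6)))
  de_flat <- de_test(count_matrix(flat, rep(c("young", "old"), each = 3)))
  expect_equal(de_flat$lfc, rep(0, 3), tolerance = 1e-12)
  # an all-zero gene reports LFC 0, p 1, without erroring
  flat2 <- flat
  flat2[2, ] <- 0L
  de0 <- de_test(count_matrix(flat2, rep(c("young", "old"), each = 3)))
  expect_equal(de0$lfc[2], 0)
  expect_equal(de0$p_value[2], 1)
})

test_that("planted fold-changes are recovered with the right sign", {
  cs <- simulate_counts(count_sim_spec(n_genes = 1500, n_young_a = 5,
                                       n_old_a = 5, dispersion = 0.05,
                                       frac_regulated = 0, n_psg = 300,
                                       q1_prob = 1, lfc_mean = 2,
                                       lfc_sd = 1e-6, seed = 103))
  de <- de_test(cs$counts_a)
  planted <- cs$truth$planted_q1
  expect_gte(mean(sign(de$lfc[planted]) == sign(cs$truth$lfc_a[planted])),
             0.95)
})

test_that("quadrant classification partitions jointly regulated genes", {
  de_a <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                     lfc = c(-1, -2, 3, -1),
                     q_value = c(0.01, 0.05, 0.02, 0.5),
                     regulated = c(TRUE, TRUE, TRUE, FALSE))
  de_b <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                     lfc = c(1, -1, -2, 2),
                     q_value = c(0.02, 0.01, 0.01, 0.01),
                     regulated = c(TRUE, TRUE, TRUE, TRUE))
  qt <- classify_quadrants(de_a, de_b, psgs = "g1")
  expect_equal(nrow(qt), 3)          # g4 regulated in B only -> excluded
  expect_equal(qt$quadrant[qt$gene == "g1"], factor("I", levels = c("I", "II", "III", "IV")))
  expect_equal(as.character(qt$quadrant[qt$gene == "g2"]), "II")
  expect_equal(as.character(qt$quadrant[qt$gene == "g3"]), "III")
  # each placed gene is in exactly one quadrant and counts add up
  expect_equal(sum(attr(qt, "counts")), nrow(qt))
  expect_true(qt$psg[qt$gene == "g1"])
})

test_that("the quadrant Fisher test equals hypergeometric enumeration", {
  # 3 PSGs in quadrant I, 1 elsewhere; 1 background in I, 3 elsewhere
  qt <- data.frame(gene = letters[1:8],
                   quadrant = factor(c("I", "I", "I", "II", "I", "III",
                                       "IV", "II"),
                                     levels = c("I", "II", "III", "IV")),
                   psg = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                           FALSE))
  expect_equal(quadrant_fisher(qt), 17 / 70, tolerance = 1e-12)
  # all configurations on a small universe match the enumeration oracle
  set.seed(9)
  for (i in 1:30) {
    N <- sample(8:30, 1)
    nq1 <- sample(1:(N - 1), 1)
    npsg <- sample(1:(N - 1), 1)
    tab <- data.frame(
      gene = paste0("g", 1:N),
      quadrant = factor(c(rep("I", nq1), rep("II", N - nq1)),
                        levels = c("I", "II", "III", "IV")),
      psg = sample(c(rep(TRUE, npsg), rep(FALSE, N - npsg))))
    x <- sum(tab$psg & tab$quadrant == "I")
    expect_equal(quadrant_fisher(tab),
                 hyper_tail_enum(x, nq1, N - nq1, npsg),
                 tolerance = 1e-12)
  }
  # proportional allocation (2 of 5 PSGs in every quadrant) is not enriched
  tab0 <- data.frame(gene = paste0("g", 1:20),
                     quadrant = factor(rep(c("I", "II", "III", "IV"),
                                           each = 5),
                                       levels = c("I", "II", "III", "IV")),
                     psg = rep(c(TRUE, TRUE, FALSE, FALSE, FALSE), 4))
  expect_gte(quadrant_fisher(tab0), 0.5)
  # degenerate margins warn and return 1
  tab1 <- tab0
  tab1$psg <- TRUE
  expect_warning(p1 <- quadrant_fisher(tab1), "degenerate")
  expect_equal(p1, 1)
})

test_that("the Lancaster combination generalizes Fisher's method", {
  # equal weights of 2 reduce exactly to Fisher
  set.seed(5)
  for (i in 1:10) {
    p <- runif(sample(2:6, 1))
    expect_equal(lancaster_combine(p, rep(2, length(p))),
                 fisher_combine_ref(p), tolerance = 1e-12)
  }
  expect_equal(lancaster_combine(c(0.05, 0.05), c(2, 2)),
               fisher_combine_ref(c(0.05, 0.05)), tolerance = 1e-12)
  # a single p-value is returned unchanged for any weight
  for (w in c(0.5, 2, 7)) {
    expect_equal(lancaster_combine(0.2, w), 0.2, tolerance = 1e-12)
  }
  # mean preservation: p-values whose chi-square deviates sit exactly at
  # their df mean combine to ~0.5 for large k (central limit)
  p_mean <- pchisq(2, df = 2, lower.tail = FALSE)  # exp(-1)
  expect_equal(lancaster_combine(rep(p_mean, 400), rep(2, 400)), 0.5,
               tolerance = 0.05)
  expect_warning(lancaster_combine(c(0, 0.5), c(2, 2)), "clamped")
  expect_error(lancaster_combine(c(0.1, 0.2), c(2, -1)))
})

test_that("the directionality test combines the two species' tails", {
  de_sig <- function(n, frac_dn, psg_dn, genes, psgs) {
    dn <- c(rep(TRUE, round(n * frac_dn)), rep(FALSE, n - round(n * frac_dn)))
    is_psg <- genes %in% psgs
    lfc <- ifelse(dn, -1, 1)
    # push PSGs toward the requested direction deterministically
    lfc[is_psg] <- ifelse(seq_len(sum(is_psg)) <= round(sum(is_psg) * psg_dn),
                          -1, 1)
    data.frame(gene = genes, lfc = lfc, q_value = 0.01, regulated = TRUE)
  }
  genes <- paste0("g", 1:200)
  psgs <- paste0("g", 1:40)
  de_a <- de_sig(200, 0.5, 0.9, genes, psgs)   # PSGs mostly down in A
  de_b <- de_sig(200, 0.5, 0.1, genes, psgs)   # PSGs mostly up in B
  res <- directionality_test(de_a, de_b, psgs)
  expect_lt(res$p_value, 0.01)
  # combination lies between the component behaviors: one strong, one
  # null component still gives a smallish combined p
  de_b_null <- de_sig(200, 0.5, 0.5, genes, psgs)
  res2 <- directionality_test(de_a, de_b_null, psgs)
  expect_lt(res2$p_value, max(res2$p_a, res2$p_b) * 1.0001)
  expect_gt(res2$p_value, min(res2$p_a, res2$p_b) / 1e3)
  # no regulated PSGs in a species -> that component is 1
  de_a_empty <- de_a
  de_a_empty$regulated <- !(de_a_empty$gene %in% psgs)
  res3 <- directionality_test(de_a_empty, de_b, psgs)
  expect_equal(res3$p_a, 1)
})

test_that("the minimal NB test agrees directionally with DESeq2", {
  # independent cross-check against the reference NB implementation: the
  # two tests should order and sign fold-changes the same way, without
  # any claim of numerical equivalence
  cs <- simulate_counts(count_sim_spec(n_genes = 300, n_psg = 60,
                                       q1_prob = 1, frac_regulated = 0.2,
                                       seed = 301))
  cm <- cs$counts_a
  de <- de_test(cm)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      countData = unclass(cm),
      colData = data.frame(condition = attr(cm, "condition")),
      design = ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds, contrast = c("condition", "old", "young"))
  })
  ok <- !is.na(res$padj) & de$base_mean > 5
  expect_gt(cor(de$lfc[ok], res$log2FoldChange[ok]), 0.9)
  both_called <- ok & de$q_value < 0.05 & res$padj < 0.05
  expect_gt(sum(both_called), 20)
  expect_gte(mean(sign(de$lfc[both_called]) ==
                    sign(res$log2FoldChange[both_called])), 0.99)
})
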