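# The pruning likelihood against the brute-force enumeration reference,
# plus the structural invariants of the branch-site likelihood.

test_that("pruning equals brute-force enumeration over internal states", {
  tr <- fixture_tree(4, depth = 0.3, seed = 5, fg = "t2")
  cases <- list(
    fixture_params(kappa = 2.5, omega0 = 0.15, omega2 = 5, p0 = 0.5,
                   p1 = 0.3),
    fixture_params(kappa = 0.8, omega0 = 0.6, omega2 = 1.5, p0 = 0.25,
                   p1 = 0.55, scale = 1.7),
    fixture_params(kappa = 4, omega0 = 0.05, omega2 = 12, p0 = 0.4,
                   p1 = 0.4))
  for (j in seq_along(cases)) {
    par <- cases[[j]]
    sim <- simulate_codon_alignment(tr, par, n_codons = 20, seed = 9 + j)
    for (model in c("alternative", "null")) {
      lp <- log_likelihood(sim$alignment, tr, par, model = model)
      le <- log_likelihood(sim$alignment, tr, par, model = model,
                           method = "enumeration")
      expect_lt(abs(lp - le), 1e-8)
    }
  }
})

test_that("gaps and ambiguous codons act as missing data", {
  tr <- fixture_tree(4, depth = 0.3, seed = 5, fg = "t2")
  par <- fixture_params(omega2 = 3, p0 = 0.5, p1 = 0.3)
  sim <- simulate_codon_alignment(tr, par, n_codons = 12, seed = 4)
  a <- unclass(sim$alignment)
  a[2, 3] <- "---"
  a[4, 7] <- "ANA"
  aln <- codon_alignment(a)
  lp <- log_likelihood(aln, tr, par)
  le <- log_likelihood(aln, tr, par, method = "enumeration")
  expect_lt(abs(lp - le), 1e-8)
  # an all-gap column multiplies the likelihood by exactly 1
  b <- cbind(a, matrix("---", nrow = 4, ncol = 1))
  expect_equal(log_likelihood(codon_alignment(b), tr, par), lp,
               tolerance = 1e-10)
})

test_that("two identical one-codon sequences at zero distance give ln pi", {
  tr <- ape::read.tree(text = "(A:0,B:0);")
  tr$node.label <- "r"
  tr <- set_foreground(tr, "A")
  par <- fixture_params()
  aln <- codon_alignment(c(A = "ATG", B = "ATG"))
  expect_equal(log_likelihood(aln, tr, par),
               log(par$pi[match("ATG", psgscan:::SENSE_CODONS)]),
               tolerance = 1e-10)
})

test_that("the likelihood is invariant to re-rooting (reversibility)", {
  tr <- fixture_tree(4, depth = 0.25, seed = 8, fg = "t1")
  par <- fixture_params(kappa = 1.8, omega0 = 0.3, omega2 = 4, p0 = 0.45,
                        p1 = 0.35)
  sim <- simulate_codon_alignment(tr, par, n_codons = 40, seed = 3)
  l0 <- log_likelihood(sim$alignment, tr, par)
  # reroot on the branch above t4 (away from the foreground branch)
  tr2 <- ape::root(tr, outgroup = "t4", resolve.root = TRUE)
  tr2 <- set_foreground(tr2, "t1")
  l1 <- log_likelihood(sim$alignment, tr2, par)
  expect_equal(l0, l1, tolerance = 1e-6)
})

test_that("rescaling branch lengths and the scale factor cancels", {
  tr <- fixture_tree(4, depth = 0.3, seed = 5, fg = "t2")
  par <- fixture_params(omega2 = 6, p0 = 0.5, p1 = 0.3, scale = 1)
  sim <- simulate_codon_alignment(tr, par, n_codons = 30, seed = 11)
  l0 <- log_likelihood(sim$alignment, tr, par)
  tr_scaled <- tr
  tr_scaled$edge.length <- tr$edge.length * 3
  par_scaled <- par
  par_scaled$scale <- par$scale / 3
  l1 <- log_likelihood(sim$alignment, tr_scaled, par_scaled)
  expect_equal(l0, l1, tolerance = 1e-8)
})

test_that("likelihood input errors are classified", {
  tr <- simulate_tree(4, depth = 0.3, seed = 5)  # no foreground set
  par <- fixture_params()
  tr_fg <- set_foreground(tr, "t2")
  sim <- simulate_codon_alignment(tr_fg, par, n_codons = 5, seed = 2)
  expect_error(log_likelihood(sim$alignment, tr, par), "missing-foreground")
  bad <- sim$alignment
  rownames(bad)[1] <- "not_a_tip"
  expect_error(log_likelihood(bad, tr_fg, par), "species-mismatch")
})

test_that("the LRT maps log-likelihoods to chi-square(1) p-values", {
  expect_equal(lrt(-50, -50), list(statistic = 0, p_value = 1))
  # chi-square(1) reference points
  r1 <- lrt(-100, -100 - 3.841 / 2)
  expect_equal(r1$statistic, 3.841, tolerance = 1e-12)
  expect_equal(r1$p_value, 0.05, tolerance = 1e-3)
  r2 <- lrt(-100, -100 - 6.635 / 2)
  expect_equal(r2$p_value, 0.01, tolerance = 1e-4)
  # a worse alternative is clamped at zero
  expect_equal(lrt(-101, -100)$statistic, 0)
  # boundary mixture halves the tail
  expect_equal(lrt(-100, -102, mixture = TRUE)$p_value,
               lrt(-100, -102)$p_value / 2)
  expect_equal(lrt(-100, -100, mixture = TRUE)$p_value, 1)
})

test_that("site posteriors are normalized and respect zero-mass classes", {
  tr <- fixture_tree(4, depth = 0.3, seed = 5, fg = "t2")
  par <- fixture_params(omega2 = 6, p0 = 0.5, p1 = 0.3)
  sim <- simulate_codon_alignment(tr, par, n_codons = 50, seed = 13)
  sp <- site_posteriors(sim$alignment, tr, par)
  expect_equal(unname(rowSums(sp$posteriors)), rep(1, 50),
               tolerance = 1e-10)
  # p0 + p1 = 1: classes 2a/2b have no mass, nothing can be selected
  par0 <- fixture_params(omega2 = 6, p0 = 0.6, p1 = 0.4)
  sp0 <- site_posteriors(sim$alignment, tr, par0)
  expect_equal(nrow(sp0$selected), 0)
  expect_equal(max(sp0$posteriors[, c("2a", "2b")]), 0)
})
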