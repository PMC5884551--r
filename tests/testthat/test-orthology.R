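# Translation, protein alignment, reciprocal-best-hit assignment,
# isoform selection, the dual-assembly merge and codon-alignment
# construction.

test_that("CDS translation follows the universal code and its edge cases", {
  expect_equal(translate_cds("ATGAAATAA"), "MK")
  expect_equal(translate_cds("ATGANA"), "MX")
  expect_equal(translate_cds("atgaaa"), "MK")
  expect_error(translate_cds("ATGTAAAAA"), "frame-error")
  expect_error(translate_cds("ATGA"), "invalid-argument")
})

test_that("local protein alignment scores follow the SW conventions", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  # self-alignment of a 10-mer: sum of its diagonal substitution scores
  s <- "MKVLAWHRDE"
  res <- align_pair(s, s)
  aa <- strsplit(s, "")[[1]]
  expect_equal(res$score, sum(diag(BLOSUM62[aa, aa])))
  expect_equal(unname(res$alignment["a"]), s)
  # single-residue pair with negative substitution score: empty local
  # alignment wins, score 0 (brute force over the single 1x1 cell)
  expect_equal(align_pair("A", "W")$score, max(BLOSUM62["A", "W"], 0))
  # scores are never negative and are symmetric
  for (pair in list(c("MKVLAW", "MKVLAW"), c("MKVLAW", "WAMK"),
                    c("CCC", "WWW"))) {
    s1 <- align_pair(pair[1], pair[2])$score
    s2 <- align_pair(pair[2], pair[1])$score
    expect_gte(s1, 0)
    expect_equal(s1, s2)
  }
  expect_error(align_pair("", "MK"), "invalid-argument")
})

test_that("reciprocal best hits define the ortholog groups", {
  # identical single-gene catalogs -> one group containing both species
  seq1 <- "ATGAAACCCGGGTTTAGCATCGAGTGGCATAAA"
  cat1 <- data.frame(gene = "gA", species = c("anchor", "sp2"),
                     isoform = "iso1", source = "transcriptome",
                     seq = seq1)
  gr <- assign_orthologs(cat1, "anchor")
  expect_length(gr, 1)
  expect_setequal(names(gr$gA$candidates), c("anchor", "sp2"))
  # a species gene whose best anchor hit is X, while X's best hit is
  # another gene, is excluded from X's group
  anc <- simulate_cds_catalog(2, 1, divergence = 0, seed = 3)$catalog
  anc$species <- "anchor"
  sp <- anc[anc$gene == "g001", , drop = FALSE]
  sp$species <- "sp2"
  # sp2 carries only (a copy of) g001; add a second sp2 gene that is a
  # slightly mutated copy of g001 -> its best anchor hit is g001, but
  # g001's best sp2 hit is the exact copy, so the mutated one drops out
  mut <- sp
  mut$gene <- "g_dup"
  mut$seq <- sub("ATG", "ATGAAAAAAAAA", mut$seq)  # weaker hit to g001
  gr2 <- assign_orthologs(rbind(anc, sp, mut), "anchor")
  expect_equal(gr2$g001$candidates$sp2$gene, "g001")
  expect_false("sp2" %in% names(gr2$g002$candidates))
  expect_error(assign_orthologs(anc, "missing_species"),
               "invalid-argument")
})

test_that("RBH is order-invariant and recovers simulated orthology", {
  cs <- simulate_cds_catalog(12, 3, divergence = 0.08, seed = 21)
  gr_fwd <- assign_orthologs(cs$catalog, "sp1")
  shuffled <- cs$catalog[rev(seq_len(nrow(cs$catalog))), ]
  gr_rev <- assign_orthologs(shuffled, "sp1")
  recovered <- function(gr) {
    vapply(names(gr), function(g) {
      all(vapply(c("sp2", "sp3"), function(sp) {
        sp %in% names(gr[[g]]$candidates) &&
          all(gr[[g]]$candidates[[sp]]$gene == g)
      }, logical(1)))
    }, logical(1))
  }
  expect_true(all(recovered(gr_fwd)))   # 100% at divergence <= 0.1
  expect_equal(recovered(gr_fwd), recovered(gr_rev))
  # a diverged paralog of an existing gene loses to the true ortholog
  cs2 <- simulate_cds_catalog(4, 2, divergence = 0.03, seed = 22)
  cat2 <- cs2$catalog
  par <- cat2[cat2$species == "sp2" & cat2$gene == "g002", , drop = FALSE]
  par$gene <- "g002_paralog"
  par$seq <- simulate_cds_catalog(1, 2, divergence = 0.25,
                                  seed = 22)$catalog$seq[1]
  # paralog built by heavy mutation of the ortholog itself
  par$seq <- local({
    cod <- psgscan:::split_codons(cat2$seq[cat2$species == "sp2" &
                                             cat2$gene == "g002"][1])
    set.seed(1)
    body <- 2:(length(cod) - 1)
    idx <- sample(body, length(body) %/% 3)
    cod[idx] <- sample(setdiff(psgscan:::SENSE_CODONS, "ATG"),
                       length(idx), replace = TRUE)
    paste(cod, collapse = "")
  })
  gr3 <- assign_orthologs(rbind(cat2, par), "sp1")
  expect_equal(gr3$g002$candidates$sp2$gene, "g002")
})

test_that("isoform selection picks the best match to the anchor", {
  cs <- simulate_cds_catalog(1, 2, isoforms_per_gene = 1,
                             divergence = 0.02, seed = 31)
  cat <- cs$catalog
  # add a half-length isoform for sp2: the full-length one must win
  full <- cat[cat$species == "sp2", , drop = FALSE]
  short <- full
  short$isoform <- "iso2"
  ncod <- nchar(full$seq) %/% 3
  short$seq <- paste0(paste(psgscan:::split_codons(full$seq)[1:(ncod %/% 2)],
                            collapse = ""), "TAA")
  gr <- assign_orthologs(rbind(cat, short), "sp1")
  sel <- select_isoforms(gr$g001)
  expect_equal(sel$chosen$sp2$isoform, "iso1")
  # single candidate: that isoform is chosen
  expect_equal(sel$chosen$sp1$isoform, "iso1")
  # equal-scoring, equal-length candidates: lexicographic tie-break
  twin <- cat[cat$species == "sp2", , drop = FALSE]
  twin$isoform <- "iso2"
  gr2 <- assign_orthologs(rbind(cat, twin), "sp1")
  sel2 <- select_isoforms(gr2$g001)
  expect_equal(sel2$chosen$sp2$isoform, "iso1")
})

test_that("the dual-assembly merge prefers transcriptome CDSs", {
  mk_group <- function(anchor_gene, species_present) {
    structure(list(anchor_gene = anchor_gene, anchor_species = "anchor",
                   candidates = c(
                     list(anchor = data.frame(
                       gene = anchor_gene, species = "anchor",
                       isoform = "iso1", source = "transcriptome",
                       seq = "ATGAAATAA")),
                     species_present),
                   chosen = list()),
              class = "ortholog_group")
  }
  rec <- function(src) data.frame(gene = "gX", species = "dual",
                                  isoform = "iso1", source = src,
                                  seq = "ATGCCCTAA")
  tx <- list(g1 = mk_group("g1", list(dual = rec("transcriptome"))),
             g2 = mk_group("g2", NULL),
             g3 = mk_group("g3", NULL))
  gen <- list(g1 = mk_group("g1", list(dual = rec("genome"))),
              g2 = mk_group("g2", list(dual = rec("genome"))))
  merged <- merge_dual_assemblies(tx, gen, "dual")
  # both sources: transcriptome retained
  expect_equal(merged$g1$candidates$dual$source, "transcriptome")
  # genome-derived only: genome CDS used
  expect_equal(merged$g2$candidates$dual$source, "genome")
  # neither: species absent
  expect_false("dual" %in% names(merged$g3$candidates))
})

test_that("codon alignments are built, filtered and lossless", {
  # identical sequences: gap-free alignment of length CDS/3
  seqA <- "ATGAAACCCGGGTTTAGCATCGAGTGGCATTAA"
  cat0 <- data.frame(gene = "g1", species = c("anchor", "sp2"),
                     isoform = "iso1", source = "transcriptome",
                     seq = seqA)
  gr0 <- assign_orthologs(cat0, "anchor")
  a0 <- build_codon_alignment(gr0$g1)
  expect_equal(ncol(a0), nchar(seqA) / 3 - 1)  # stop trimmed
  expect_false(any(a0 == "---"))
  # an internal 3-nt deletion makes exactly one gap column in that row
  cs <- simulate_cds_catalog(1, 2, divergence = 0.01, seed = 41)
  cat1 <- cs$catalog
  i2 <- cat1$species == "sp2"
  cod <- psgscan:::split_codons(cat1$seq[i2])
  cat1$seq[i2] <- paste(cod[-25], collapse = "")
  gr1 <- assign_orthologs(cat1, "sp1")
  a1 <- build_codon_alignment(gr1$g001)
  expect_equal(sum(a1["sp2", ] == "---"), 1)
  expect_equal(sum(a1["sp1", ] == "---"), 0)
  # losslessness: ungapping reproduces the input CDS minus its stop
  for (sp in rownames(a1)) {
    orig <- cat1$seq[cat1$species == sp]
    expect_equal(ungap_row(a1, sp),
                 substr(orig, 1, nchar(orig) - 3))
  }
  # a 2-species group where one member covers only a sliver errors out
  tiny <- cat0
  tiny$seq[2] <- "ATGAAATAA"
  gr2 <- assign_orthologs(tiny, "anchor")
  expect_error(build_codon_alignment(gr2$g1), "insufficient-taxa")
})
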