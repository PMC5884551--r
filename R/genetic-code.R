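# Universal genetic code machinery shared by the codon model, the
# simulators and the orthology stage.  The 61 sense codons, in the fixed
# order below, are the state space of every rate matrix in the package.

CODON_NUCS <- c("T", "C", "A", "G")

ALL_CODONS <- local({
  g <- expand.grid(p3 = CODON_NUCS, p2 = CODON_NUCS, p1 = CODON_NUCS,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
})

STOP_CODONS <- c("TAA", "TAG", "TGA")

SENSE_CODONS <- ALL_CODONS[!(ALL_CODONS %in% STOP_CODONS)]

N_SENSE <- length(SENSE_CODONS)

CODON_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  unname(gc[SENSE_CODONS])
})

# Pairwise single-nucleotide change classification among sense codons.
# 0 = identical or >1 position differs; 1 = synonymous transversion;
# 2 = synonymous transition; 3 = nonsynonymous transversion;
# 4 = nonsynonymous transition.
CODON_PAIR_TYPE <- local({
  n <- N_SENSE
  m <- matrix(0L, n, n, dimnames = list(SENSE_CODONS, SENSE_CODONS))
  sp <- strsplit(SENSE_CODONS, "")
  is_ts <- function(x, y) {
    (x == "A" & y == "G") | (x == "G" & y == "A") |
      (x == "C" & y == "T") | (x == "T" & y == "C")
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- which(sp[[i]] != sp[[j]])
      if (length(d) != 1L) next
      ts <- is_ts(sp[[i]][d], sp[[j]][d])
      syn <- CODON_AA[i] == CODON_AA[j]
      m[i, j] <- if (syn) {
        if (ts) 2L else 1L
      } else {
        if (ts) 4L else 3L
      }
    }
  }
  m
})

# Map codon strings to 1-based sense-codon indices; gaps and ambiguous
# codons map to NA (treated as missing data downstream).
codon_index <- function(codons) {
  match(codons, SENSE_CODONS)
}

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    stop("invalid-argument: sequence length not divisible by 3", call. = FALSE)
  }
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}
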