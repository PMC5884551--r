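#' Construct a codon alignment
#'
#' A codon alignment is the unit of selection testing: in-frame aligned
#' coding sequences over the 61 sense codons of the universal code, with
#' \code{"---"} marking alignment gaps.  Stop codons are not allowed;
#' codons containing characters other than A, C, G, T (e.g. N) are kept
#' and treated as missing data by the likelihood machinery.
#'
#' @param seqs named character vector of aligned nucleotide sequences
#'   (equal lengths, divisible by 3) or a character matrix of codon
#'   strings (rows = species, columns = codon sites).
#' @return An object of class \code{"codon_alignment"}: a character matrix
#'   of codon strings with species as row names.
#' @examples
#' codon_alignment(c(sp1 = "ATGAAA", sp2 = "ATGAAG"))
#' @export
codon_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
      stop("invalid-argument: sequences must have unique names", call. = FALSE)
    }
    seqs <- toupper(seqs)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      stop("invalid-argument: aligned sequences must have equal length",
           call. = FALSE)
    }
    m <- do.call(rbind, lapply(seqs, split_codons))
    rownames(m) <- names(seqs)
  }
  if (nrow(m) < 2L) {
    stop("invalid-argument: a codon alignment needs at least 2 species",
         call. = FALSE)
  }
  if (any(m %in% STOP_CODONS)) {
    stop("invalid-argument: stop codon in alignment", call. = FALSE)
  }
  class(m) <- c("codon_alignment", class(m))
  m
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment: ", nrow(x), " species x ", ncol(x), " codons\n",
      sep = "")
  show <- min(ncol(x), 15L)
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s %s%s\n", rownames(x)[i],
                paste(x[i, seq_len(show)], collapse = ""),
                if (ncol(x) > show) "..." else ""))
  }
  invisible(x)
}

n_codons <- function(aln) ncol(aln)

aln_species <- function(aln) rownames(aln)

# 0-based state matrix for the C++ core; -1 = gap or ambiguous codon.
codon_states <- function(aln) {
  idx <- codon_index(aln)
  idx[is.na(idx)] <- 0L
  m <- matrix(idx - 1L, nrow = nrow(aln), dimnames = dimnames(aln))
  m
}

# Collapse identical site patterns; returns list(states = ntaxa x npat,
# weights, map = site -> pattern index).
compress_patterns <- function(states) {
  key <- apply(states, 2, paste, collapse = ",")
  u <- !duplicated(key)
  map <- match(key, key[u])
  list(states = states[, u, drop = FALSE],
       weights = as.numeric(tabulate(map, nbins = sum(u))),
       map = map)
}

#' Remove alignment gaps from one species' row
#'
#' Ungaps a row of a codon alignment, recovering the species' input coding
#' sequence (minus any trimmed terminal stop) when no alignment columns
#' were filtered.
#'
#' @param aln a \code{codon_alignment}.
#' @param species species (row) name.
#' @return A nucleotide string.
#' @export
ungap_row <- function(aln, species) {
  row <- aln[species, ]
  paste(row[row != "---"], collapse = "")
}
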