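# File formats: FASTA (CDS catalogs and codon alignments), tab-delimited
# count matrices with a sample sheet, gene-term annotation tables, and
# the plain-text run configuration.

#' Read and write FASTA
#'
#' \code{read_fasta} reads a (wrapped or unwrapped) FASTA file into a
#' named character vector, uppercasing sequences.  With
#' \code{catalog = TRUE} headers must follow the CDS-catalog grammar
#' \code{gene|isoform|source} and the result is a catalog data frame for
#' the given species; a malformed header is reported with its line
#' number.
#'
#' @param path file path.
#' @param catalog parse headers as CDS-catalog records.
#' @param species species id attached to catalog records.
#' @return Named character vector, or a catalog data frame.
#' @export
read_fasta <- function(path, catalog = FALSE, species = NA_character_) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- names(ss)
  if (!catalog) return(seqs)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 3L)
  if (length(bad)) {
    lines <- readLines(path, warn = FALSE)
    hdr <- paste0(">", names(seqs)[bad[1]])
    ln <- which(startsWith(lines, hdr))[1]
    stop("parse-error: header '", names(seqs)[bad[1]],
         "' (line ", ln, ") does not match gene|isoform|source",
         call. = FALSE)
  }
  data.frame(gene = vapply(parts, `[`, "", 1),
             species = species,
             isoform = vapply(parts, `[`, "", 2),
             source = vapply(parts, `[`, "", 3),
             seq = unname(seqs), stringsAsFactors = FALSE)
}

#' @rdname read_fasta
#' @param x named character vector of sequences, or a catalog data frame
#'   (headers are rebuilt as \code{gene|isoform|source}).
#' @param width line-wrap width.
#' @export
write_fasta <- function(x, path, width = 70) {
  if (is.data.frame(x)) {
    seqs <- x$seq
    names(seqs) <- paste(x$gene, x$isoform, x$source, sep = "|")
    x <- seqs
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(x)) {
    writeLines(paste0(">", nm), con)
    s <- x[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))),
               con)
  }
  invisible(path)
}

#' Read a codon alignment from FASTA
#'
#' @param path FASTA file of equal-length, in-frame aligned sequences.
#' @return A \code{\link{codon_alignment}}.
#' @export
read_alignment_fasta <- function(path) {
  codon_alignment(read_fasta(path))
}

#' @rdname read_alignment_fasta
#' @param aln the alignment to write.
#' @export
write_alignment_fasta <- function(aln, path) {
  seqs <- apply(aln, 1, paste, collapse = "")
  write_fasta(seqs, path)
}

#' Read count matrices with a sample sheet
#'
#' The counts file is tab-delimited with genes in rows (first column =
#' gene id) and samples in columns; the sample sheet is tab-delimited
#' with columns \code{sample}, \code{condition} (young/old) and
#' \code{species}.
#'
#' @param counts_path,samples_path file paths.
#' @return Named list of \code{\link{count_matrix}} objects, one per
#'   species.
#' @export
read_counts <- function(counts_path, samples_path) {
  m <- read.delim(counts_path, row.names = 1, check.names = FALSE)
  sheet <- read.delim(samples_path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "condition", "species") %in% names(sheet)))
  missing <- setdiff(sheet$sample, colnames(m))
  if (length(missing)) {
    stop("parse-error: samples absent from count table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lapply(split(sheet, sheet$species), function(sh) {
    count_matrix(as.matrix(m[, sh$sample, drop = FALSE]),
                 condition = sh$condition, species = sh$species[1])
  })
}

#' @rdname read_counts
#' @param cm a \code{\link{count_matrix}} to write.
#' @param path output path.
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(gene = rownames(cm), unclass(cm), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-term annotation table
#'
#' @param path two-column tab-delimited file (gene, term), no header.
#' @param universe optional gene universe.
#' @return An \code{\link{annotation_map}}.
#' @export
read_annotation <- function(path, universe = NULL) {
  df <- read.delim(path, header = FALSE, col.names = c("gene", "term"),
                   stringsAsFactors = FALSE)
  annotation_map(df$gene, df$term, universe = universe)
}

# tab-delimited result table with a comment header naming the thresholds
write_result_table <- function(df, path, thresholds = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(thresholds)) {
    writeLines(paste0("# ", paste(names(thresholds), unlist(thresholds),
                                  sep = "=", collapse = " ")), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
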