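# Ortholog assignment by reciprocal best hits (RBH) against an anchor
# species, isoform selection, the dual-assembly merge rule, and
# construction of the per-group codon alignment.  Protein similarity is
# exact Smith-Waterman-Gotoh scoring (BLOSUM62, gap open 11 / extend 1,
# BLAST's defaults) via Biostrings; at desk scale no heuristic search is
# needed, and the RBH semantics are unchanged.

#' Translate an in-frame CDS to protein
#'
#' Universal genetic code; a terminal stop codon is dropped, an internal
#' stop is an error, and codons containing ambiguous characters translate
#' to \code{X}.
#'
#' @param cds nucleotide string, length divisible by 3.
#' @return Protein string.
#' @examples
#' translate_cds("ATGAAATAA")  # "MK"
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  codons <- split_codons(cds)
  n <- length(codons)
  if (n > 0 && codons[n] %in% STOP_CODONS) codons <- codons[-n]
  aa <- CODON_AA[codon_index(codons)]
  if (any(codons %in% STOP_CODONS)) {
    stop("frame-error: internal stop codon", call. = FALSE)
  }
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Optimal local protein alignment
#'
#' Smith-Waterman-Gotoh local alignment under affine gap costs.  Scores
#' follow the local convention that the empty alignment scores 0, so the
#' returned score is never negative.
#'
#' @param a,b protein strings (non-empty).
#' @param matrix substitution matrix name (from Biostrings) or matrix.
#' @param gap_open,gap_extend positive gap penalties (a gap of length L
#'   costs \code{gap_open + L * gap_extend}).
#' @return List with \code{score} and \code{alignment} (the aligned
#'   substrings of \code{a} and \code{b}; empty when the best local
#'   alignment is empty).
#' @export
align_pair <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                       gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) {
    stop("invalid-argument: empty sequence", call. = FALSE)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend)
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(list(score = 0, alignment = c(a = "", b = "")))
  }
  list(score = sc,
       alignment = c(a = as.character(Biostrings::alignedPattern(pa)),
                     b = as.character(Biostrings::alignedSubject(pa))))
}

# Vectorized local score of many proteins against one (clamped at 0).
local_scores <- function(proteins, subject, matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(proteins), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, scoreOnly = TRUE)
  pmax(sc, 0)
}

validate_catalog <- function(catalog) {
  need <- c("gene", "species", "isoform", "source", "seq")
  if (!is.data.frame(catalog) || !all(need %in% names(catalog))) {
    stop("invalid-argument: a CDS catalog needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  catalog$seq <- toupper(catalog$seq)
  catalog
}

# deterministic best hit: max score, ties to the lexicographically
# smallest id
best_hit <- function(ids, scores) {
  m <- max(scores)
  cand <- sort(ids[scores == m])
  cand[1]
}

#' Assign ortholog groups by reciprocal best hits
#'
#' For every anchor-species gene, a gene of another species joins the
#' group iff the two genes are each other's best-scoring partner
#' (reciprocal best hit), where the gene-level score is the maximum local
#' alignment score over all isoform pairs.  Ties break deterministically
#' by score then lexicographic gene id.  An optional grouping table
#' (columns \code{anchor_gene}, \code{group_id}) merges anchor genes into
#' pre-defined groups; without it every anchor gene seeds its own group.
#'
#' @param catalog a CDS catalog data frame (columns gene, species,
#'   isoform, source, seq), covering the anchor and all other species.
#' @param anchor anchor species id (must appear in the catalog).
#' @param grouping optional data frame (anchor_gene, group_id).
#' @return A list of \code{"ortholog_group"} objects, each with the
#'   anchor gene id, per-species candidate isoform records and (after
#'   \code{\link{select_isoforms}}) one chosen CDS per species.
#' @export
assign_orthologs <- function(catalog, anchor, grouping = NULL) {
  catalog <- validate_catalog(catalog)
  if (!(anchor %in% catalog$species)) {
    stop("invalid-argument: anchor species not in catalog", call. = FALSE)
  }
  catalog$prot <- vapply(catalog$seq, translate_cds, character(1),
                         USE.NAMES = FALSE)
  anc <- catalog[catalog$species == anchor, , drop = FALSE]
  others <- setdiff(unique(catalog$species), anchor)

  groups <- list()
  for (g in sort(unique(anc$gene))) {
    rec <- anc[anc$gene == g, , drop = FALSE]
    groups[[g]] <- structure(
      list(anchor_gene = g, anchor_species = anchor,
           candidates = stats::setNames(list(rec), anchor),
           chosen = list()),
      class = "ortholog_group")
  }

  for (sp in others) {
    spc <- catalog[catalog$species == sp, , drop = FALSE]
    # isoform-level scores against every anchor isoform, aggregated to
    # gene-level maxima
    gene_scores <- matrix(-Inf, nrow = length(unique(anc$gene)),
                          ncol = length(unique(spc$gene)),
                          dimnames = list(sort(unique(anc$gene)),
                                          sort(unique(spc$gene))))
    for (i in seq_len(nrow(spc))) {
      sc <- local_scores(anc$prot, spc$prot[i])
      agg <- tapply(sc, anc$gene, max)
      col <- spc$gene[i]
      gene_scores[names(agg), col] <- pmax(gene_scores[names(agg), col],
                                           agg)
    }
    # reciprocal best hits
    best_anchor_for <- apply(gene_scores, 2, function(s) {
      best_hit(rownames(gene_scores), s)
    })
    best_sp_for <- apply(gene_scores, 1, function(s) {
      best_hit(colnames(gene_scores), s)
    })
    for (g in names(best_sp_for)) {
      cand <- best_sp_for[[g]]
      if (best_anchor_for[[cand]] == g) {
        groups[[g]]$candidates[[sp]] <-
          spc[spc$gene == cand, , drop = FALSE]
      }
    }
  }

  if (!is.null(grouping)) {
    stopifnot(all(c("anchor_gene", "group_id") %in% names(grouping)))
    merged <- list()
    for (gid in unique(grouping$group_id)) {
      members <- grouping$anchor_gene[grouping$group_id == gid]
      members <- intersect(members, names(groups))
      if (!length(members)) next
      base <- groups[[members[1]]]
      for (m in members[-1]) {
        for (sp in names(groups[[m]]$candidates)) {
          base$candidates[[sp]] <- rbind(base$candidates[[sp]],
                                         groups[[m]]$candidates[[sp]])
        }
      }
      merged[[as.character(gid)]] <- base
    }
    ungrouped <- setdiff(names(groups), grouping$anchor_gene)
    groups <- c(merged, groups[ungrouped])
  }
  groups
}

#' @export
print.ortholog_group <- function(x, ...) {
  cat("Ortholog group '", x$anchor_gene, "' (anchor ", x$anchor_species,
      ")\n", sep = "")
  for (sp in names(x$candidates)) {
    ch <- if (sp %in% names(x$chosen)) {
      paste0(" -> ", x$chosen[[sp]]$isoform)
    } else {
      ""
    }
    cat(sprintf("  %-8s %d candidate isoform(s)%s\n", sp,
                nrow(x$candidates[[sp]]), ch))
  }
  invisible(x)
}

# anchor's own representative: longest CDS, ties lexicographic isoform id
anchor_representative <- function(group) {
  rec <- group$candidates[[group$anchor_species]]
  ord <- order(-nchar(rec$seq), rec$isoform)
  rec[ord[1], , drop = FALSE]
}

#' Select best matching isoforms within an ortholog group
#'
#' Per species, picks the isoform with the highest local alignment score
#' to the anchor's representative isoform (the anchor's longest CDS, ties
#' by isoform id).  Score ties break by longest CDS, then lexicographic
#' isoform id.
#'
#' @param group an \code{"ortholog_group"} from
#'   \code{\link{assign_orthologs}}.
#' @return The group with one chosen record per species.
#' @export
select_isoforms <- function(group) {
  anc <- anchor_representative(group)
  anc_prot <- translate_cds(anc$seq)
  group$chosen[[group$anchor_species]] <- anc
  for (sp in setdiff(names(group$candidates), group$anchor_species)) {
    rec <- group$candidates[[sp]]
    if (!nrow(rec)) next
    sc <- local_scores(vapply(rec$seq, translate_cds, character(1),
                              USE.NAMES = FALSE), anc_prot)
    ord <- order(-sc, -nchar(rec$seq), rec$isoform)
    group$chosen[[sp]] <- rec[ord[1], , drop = FALSE]
  }
  group
}

#' Merge transcriptome- and genome-based ortholog groups for one species
#'
#' Implements the dual-assembly rule: within each group the species'
#' transcriptome-derived CDS is kept whenever the transcriptome run
#' contributed one; genome-derived CDSs are used only for groups where it
#' did not.
#'
#' @param groups_tx,groups_gen ortholog group lists from two
#'   \code{\link{assign_orthologs}} runs indexed by the same anchor genes
#'   (transcriptome-based and genome-based assemblies of \code{species}).
#' @param species the dual-assembly species id.
#' @return The merged group list.
#' @export
merge_dual_assemblies <- function(groups_tx, groups_gen, species) {
  out <- groups_tx
  for (g in names(groups_gen)) {
    if (!(g %in% names(out))) {
      out[[g]] <- groups_gen[[g]]
      next
    }
    has_tx <- species %in% names(out[[g]]$candidates) &&
      nrow(out[[g]]$candidates[[species]]) > 0
    has_gen <- species %in% names(groups_gen[[g]]$candidates) &&
      nrow(groups_gen[[g]]$candidates[[species]]) > 0
    if (!has_tx && has_gen) {
      out[[g]]$candidates[[species]] <- groups_gen[[g]]$candidates[[species]]
      out[[g]]$chosen[[species]] <- NULL
    }
  }
  out
}

#' Build the codon alignment of an ortholog group
#'
#' Aligns the chosen proteins (selecting isoforms first if needed) and
#' back-translates to codons, so every alignment column is one codon.
#' Each non-anchor protein is aligned globally to the anchor's chosen
#' protein under the same scoring as \code{\link{align_pair}} and
#' projected onto anchor coordinates; insertions relative to the anchor
#' from different species occupy merged insertion columns.  Columns with
#' more than 50\% gaps are then removed, and species left with fewer than
#' 50\% non-gap codons are dropped.
#'
#' @param group an \code{"ortholog_group"}.
#' @return A \code{\link{codon_alignment}} whose rows are species ids.
#' @export
build_codon_alignment <- function(group) {
  if (!length(group$chosen)) group <- select_isoforms(group)
  sps <- names(group$chosen)
  if (length(sps) < 2L) {
    stop("insufficient-taxa: fewer than 2 species in group", call. = FALSE)
  }
  trim_stop <- function(s) {
    cod <- split_codons(s)
    if (cod[length(cod)] %in% STOP_CODONS) cod <- cod[-length(cod)]
    cod
  }
  codons <- lapply(sps, function(sp) trim_stop(group$chosen[[sp]]$seq))
  names(codons) <- sps
  prots <- vapply(sps, function(sp) translate_cds(group$chosen[[sp]]$seq),
                  character(1))
  anchor <- group$anchor_species
  L <- length(codons[[anchor]])

  # per species: match[p] = residue index aligned to anchor position p
  # (NA = gap) and ins[[p+1]] = residue indices inserted after position p
  proj <- list()
  for (sp in setdiff(sps, anchor)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(prots[anchor]), Biostrings::AAString(prots[sp]),
      type = "global", substitutionMatrix = "BLOSUM62", gapOpening = 11,
      gapExtension = 1)
    arow <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    brow <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    match_vec <- rep(NA_integer_, L)
    ins <- vector("list", L + 1L)
    ai <- 0L
    bi <- 0L
    for (k in seq_along(arow)) {
      if (arow[k] != "-" && brow[k] != "-") {
        ai <- ai + 1L
        bi <- bi + 1L
        match_vec[ai] <- bi
      } else if (arow[k] != "-") {
        ai <- ai + 1L
      } else {
        bi <- bi + 1L
        ins[[ai + 1L]] <- c(ins[[ai + 1L]], bi)
      }
    }
    proj[[sp]] <- list(match = match_vec, ins = ins)
  }

  ins_len <- vapply(seq_len(L + 1L), function(p) {
    if (!length(proj)) return(0L)
    max(vapply(proj, function(pr) length(pr$ins[[p]]), integer(1)))
  }, integer(1))

  ncol_total <- L + sum(ins_len)
  aln <- matrix("---", nrow = length(sps), ncol = ncol_total,
                dimnames = list(sps, NULL))
  # column offsets: insertion block after position p starts at off[p+1]
  col_of_pos <- integer(L)
  ins_start <- integer(L + 1L)
  cur <- 0L
  for (p in 0:L) {
    ins_start[p + 1L] <- cur + 1L
    cur <- cur + ins_len[p + 1L]
    if (p < L) {
      col_of_pos[p + 1L] <- cur + 1L
      cur <- cur + 1L
    }
  }
  aln[anchor, col_of_pos] <- codons[[anchor]]
  for (sp in setdiff(sps, anchor)) {
    pr <- proj[[sp]]
    ok <- !is.na(pr$match)
    aln[sp, col_of_pos[ok]] <- codons[[sp]][pr$match[ok]]
    for (p in 0:L) {
      v <- pr$ins[[p + 1L]]
      if (length(v)) {
        cols <- ins_start[p + 1L] + seq_along(v) - 1L
        aln[sp, cols] <- codons[[sp]][v]
      }
    }
  }

  gap_frac <- colMeans(aln == "---")
  aln <- aln[, gap_frac <= 0.5, drop = FALSE]
  keep <- rowMeans(aln != "---") >= 0.5
  aln <- aln[keep, , drop = FALSE]
  if (nrow(aln) < 2L) {
    stop("insufficient-taxa: fewer than 2 species survive alignment filters",
         call. = FALSE)
  }
  codon_alignment(aln)
}
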