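# The multi-branch scan: per-branch gene tests, Benjamini-Hochberg
# candidate calling, convergence control reruns, multi-branch union and
# PSG-vs-tested bias checks.

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: the q-value of the i-th
#' smallest p is \code{min over j >= i of p_(j) * n / j}, returned in the
#' input order.
#'
#' @param p p-values in [0, 1].
#' @return q-values in [0, 1].
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("invalid-argument: p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Call candidate genes at an FDR threshold
#'
#' Candidates are the genes with q-value strictly below the threshold
#' (default 0.1).
#'
#' @param records data frame with columns \code{gene} and \code{q_value}.
#' @param threshold FDR threshold (strict inequality).
#' @return Character vector of candidate gene ids.
#' @export
call_candidates <- function(records, threshold = 0.1) {
  if (!nrow(records)) return(character(0))
  records$gene[records$q_value < threshold]
}

# species-presence rule: a gene enters a branch's test only if its
# alignment contains at least one species of the foreground clade and at
# least one of the sister clade (for ancestral branches the sister taxon
# is what anchors the timing of the signal).
testable_for_branch <- function(aln, tree, foreground) {
  child <- node_id(tree, foreground)
  tips <- ape::Ntip(tree)
  clade <- if (child <= tips) {
    tree$tip.label[child]
  } else {
    ape::extract.clade(tree, child)$tip.label
  }
  parent <- tree$edge[tree$edge[, 2] == child, 1]
  sibs <- tree$edge[tree$edge[, 1] == parent, 2]
  sibs <- setdiff(sibs, child)
  sister <- unlist(lapply(sibs, function(s) {
    if (s <= tips) tree$tip.label[s] else ape::extract.clade(tree, s)$tip.label
  }))
  sp <- aln_species(aln)
  any(clade %in% sp) && any(sister %in% sp) &&
    (child > tips || foreground %in% sp)
}

#' Scan one foreground branch for positively selected genes
#'
#' Runs the branch-site test on every testable gene, converts the
#' per-gene p-values to Benjamini-Hochberg q-values, calls candidates at
#' \code{q < q_threshold}, and subjects each candidate to control reruns
#' (fresh random-start refits); only candidates approved in every control
#' run become PSGs.
#'
#' @param alignments named list of \code{\link{codon_alignment}} objects
#'   (names are gene ids).
#' @param tree phylogeny shared by all genes.
#' @param foreground node label of the branch to test.
#' @param q_threshold candidate FDR threshold (strict).
#' @param n_starts optimization starts per fit.
#' @param n_control number of control reruns per candidate.
#' @param seed integer seed.
#' @return An object of class \code{"scan_result"}: the branch id, the
#'   per-gene record table (gene, lnl_null, lnl_alt, statistic, p, q,
#'   candidate, control p-values, approved, selected sites) and summary
#'   counts.
#' @export
scan_branch <- function(alignments, tree, foreground, q_threshold = 0.1,
                        n_starts = 3, n_control = 2, seed = NULL) {
  keep <- vapply(alignments, testable_for_branch, logical(1), tree = tree,
                 foreground = foreground)
  alignments <- alignments[keep]
  genes <- names(alignments)
  fits <- vector("list", length(genes))
  rec <- data.frame(gene = genes, branch = foreground,
                    lnl_null = NA_real_, lnl_alt = NA_real_,
                    statistic = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  warm <- NULL
  for (i in seq_along(genes)) {
    ft <- branch_site_test(alignments[[i]], tree, foreground = foreground,
                           n_starts = n_starts,
                           seed = derive_seed(seed, 100 + i),
                           init_null = warm)
    warm <- ft$null$params
    fits[[i]] <- ft
    rec$lnl_null[i] <- ft$null$lnL
    rec$lnl_alt[i] <- ft$alt$lnL
    rec$statistic[i] <- ft$statistic
    rec$p_value[i] <- ft$p_value
  }
  rec$q_value <- bh_fdr(rec$p_value)
  cand <- call_candidates(rec, q_threshold)
  rec$candidate <- rec$gene %in% cand
  p_max <- if (length(cand)) max(rec$p_value[rec$candidate]) else NA_real_
  rec$approved <- FALSE
  rec$control_p <- ""
  for (i in which(rec$candidate)) {
    cr <- control_reruns(alignments[[i]], tree, foreground,
                         p_max = p_max, n_runs = n_control,
                         n_starts = n_starts,
                         seed = derive_seed(seed, 10000 + i))
    rec$approved[i] <- cr$approved
    rec$control_p[i] <- paste(signif(cr$p_values, 6), collapse = ",")
  }
  rec$selected_sites <- vapply(seq_along(genes), function(i) {
    s <- fits[[i]]$selected
    if (!nrow(s)) return("")
    paste(sprintf("%d:%.3f", s$site, s$posterior), collapse = ",")
  }, character(1))
  structure(list(branch = foreground, records = rec,
                 counts = c(tested = nrow(rec),
                            candidates = sum(rec$candidate),
                            psgs = sum(rec$approved)),
                 q_threshold = q_threshold),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("Branch-site scan on branch '%s': %d genes tested, %d candidates (q < %g), %d approved PSGs\n",
              x$branch, x$counts["tested"], x$counts["candidates"],
              x$q_threshold, x$counts["psgs"]))
  invisible(x)
}

#' Control reruns of a candidate gene
#'
#' Refits the nested model pair from fresh random starts the requested
#' number of times.  A candidate is approved when every rerun's nominal
#' p-value stays within the branch's significance region, i.e. at or
#' below the largest nominal p among the main run's candidates; a rerun
#' that fails to fit vetoes approval.
#'
#' @inheritParams scan_branch
#' @param aln the candidate gene's alignment.
#' @param p_max largest nominal p among the main run's candidates.
#' @param n_runs number of control reruns.
#' @return List with \code{approved} and the rerun \code{p_values}.
#' @export
control_reruns <- function(aln, tree, foreground, p_max, n_runs = 2,
                           n_starts = 3, seed = NULL) {
  ps <- numeric(0)
  for (r in seq_len(n_runs)) {
    ft <- tryCatch(
      branch_site_test(aln, tree, foreground = foreground,
                       n_starts = n_starts, seed = derive_seed(seed, r)),
      error = function(e) e)
    if (inherits(ft, "error")) {
      return(list(approved = FALSE, p_values = c(ps, NA), failed = TRUE))
    }
    ps <- c(ps, ft$p_value)
  }
  list(approved = all(ps <= p_max), p_values = ps, failed = FALSE)
}

#' Union of PSGs across branches
#'
#' Collapses per-branch scans into the non-redundant PSG set and a table
#' of genes found on multiple branches.
#'
#' @param scans list of \code{\link{scan_branch}} results.
#' @return List with \code{psgs} (sorted unique approved gene ids) and
#'   \code{multi_branch} (data frame gene / branches / n_branches for
#'   genes approved on more than one branch).
#' @export
union_psgs <- function(scans) {
  hits <- do.call(rbind, lapply(scans, function(s) {
    s$records[s$records$approved, c("gene", "branch")]
  }))
  if (is.null(hits) || !nrow(hits)) {
    return(list(psgs = character(0),
                multi_branch = data.frame(gene = character(0),
                                          branches = character(0),
                                          n_branches = integer(0))))
  }
  hits <- unique(hits)
  spl <- split(hits$branch, hits$gene)
  multi <- spl[vapply(spl, length, integer(1)) > 1]
  list(psgs = sort(unique(hits$gene)),
       multi_branch = data.frame(
         gene = names(multi),
         branches = vapply(multi, function(b) {
           paste(sort(b), collapse = ",")
         }, character(1)),
         n_branches = vapply(multi, length, integer(1)),
         row.names = NULL))
}

#' Bias checks of PSGs against all tested genes
#'
#' Compares PSGs with the other tested genes on four alignment features
#' -- taxon coverage (species count), alignment length in codons, mean GC
#' fraction, and the cross-species standard deviation of GC -- using
#' two-sided Mann-Whitney rank tests.  Features identical across all
#' genes give p = 1 by convention.
#'
#' @param psgs PSG gene ids (subset of \code{tested}, at least 2).
#' @param tested all tested gene ids.
#' @param alignments named list of the genes' codon alignments (the same
#'   alignment versions used in the scan).
#' @return A data frame of class \code{"bias_report"}: feature, PSG and
#'   non-PSG medians, and the rank-test p-value.
#' @export
bias_check <- function(psgs, tested, alignments) {
  if (length(psgs) < 2) {
    stop("insufficient-set: need at least 2 PSGs", call. = FALSE)
  }
  if (!all(psgs %in% tested)) {
    stop("invalid-argument: psgs must be a subset of tested", call. = FALSE)
  }
  gc_of <- function(aln) {
    chars <- strsplit(paste(aln[aln != "---"], collapse = ""), "")[[1]]
    mean(chars %in% c("G", "C"))
  }
  feats <- data.frame(
    gene = tested,
    taxon_coverage = vapply(alignments[tested], nrow, integer(1)),
    length_codons = vapply(alignments[tested], ncol, integer(1)),
    gc_mean = vapply(alignments[tested], gc_of, numeric(1)),
    gc_sd = vapply(alignments[tested], function(a) {
      g <- vapply(rownames(a), function(s) gc_of(a[s, , drop = FALSE]),
                  numeric(1))
      sd(g)
    }, numeric(1)))
  is_psg <- feats$gene %in% psgs
  rows <- lapply(c("taxon_coverage", "length_codons", "gc_mean", "gc_sd"),
                 function(f) {
    x <- feats[[f]][is_psg]
    y <- feats[[f]][!is_psg]
    p <- if (length(unique(c(x, y))) == 1L) {
      1
    } else {
      suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
    }
    data.frame(feature = f, psg_median = median(x), other_median = median(y),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bias_report", class(out))
  out
}
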