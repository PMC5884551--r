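# Synthetic-data generators.  They produce every input the pipeline
# consumes -- trees, codon alignments evolved under the branch-site
# mixture, two-species young/old count matrices with a planted
# antagonistic-pleiotropy signal, and multi-isoform CDS catalogs -- along
# with ground-truth tables for parameter-recovery and error-rate tests.

#' Simulate a rodent-scale phylogeny
#'
#' Random rooted binary tree with branch lengths on the scale of a few
#' hundredths of a substitution per site, mimicking the depth of a rodent
#' phylogeny.  Any branch can subsequently be tagged as the foreground of
#' a branch-site scan via \code{\link{set_foreground}}.
#'
#' @param n_taxa number of tips (>= 2).
#' @param depth typical branch length in expected substitutions per codon;
#'   individual branches are jittered uniformly in [0.5, 1.5] x depth.
#' @param seed integer seed; identical seeds give identical trees.
#' @return A \code{phylo} object with unique tip labels \code{t1..tn} and
#'   internal node labels \code{n1..}.
#' @export
simulate_tree <- function(n_taxa, depth = 0.05, seed = NULL) {
  if (n_taxa < 2) {
    stop("invalid-argument: need at least 2 taxa", call. = FALSE)
  }
  stopifnot(depth > 0)
  with_seed(seed, {
    if (n_taxa == 2) {
      tree <- ape::read.tree(text = "(t1:1,t2:1);")
    } else {
      tree <- ape::rtree(n_taxa, rooted = TRUE)
      tree$tip.label <- paste0("t", seq_len(n_taxa))
    }
    tree$edge.length <- depth * runif(nrow(tree$edge), 0.5, 1.5)
    tree$node.label <- paste0("n", seq_len(tree$Nnode))
    tree
  })
}

#' Simulate a codon alignment under the branch-site model
#'
#' Draws each site's class from the Model A mixture proportions, then
#' evolves it by exact sampling from the codon transition-probability
#' matrices: the root codon is drawn from the stationary distribution and
#' each branch applies \code{exp(Qt)} for the class's background (or, on
#' the foreground branch, foreground) generator.  The state space contains
#' only sense codons, so simulated alignments never contain stop codons.
#'
#' @param tree a \code{phylo} with branch lengths (expected substitutions
#'   per codon, the same scaling the likelihood uses).
#' @param params a \code{\link{branch_site_params}} object.
#' @param n_codons number of codon sites (>= 1).
#' @param foreground node label of the foreground branch; defaults to the
#'   tree's foreground attribute.
#' @param seed integer seed.
#' @return List with \code{alignment} (a \code{\link{codon_alignment}})
#'   and \code{truth} (per-site class labels in \code{site_class}, and the
#'   gene-level \code{selected} flag: TRUE when the generating regime has
#'   positive mass on classes 2a/2b with omega2 > 1).
#' @export
simulate_codon_alignment <- function(tree, params, n_codons,
                                     foreground = NULL, seed = NULL) {
  stopifnot(n_codons >= 1)
  po <- tree_postorder(tree, foreground)
  if (po$fg_edge == 0L) {
    stop("unknown-branch: no foreground branch designated", call. = FALSE)
  }
  mix <- mixture_layout(params)
  tfac <- params$scale / mix$rate
  bg_w <- c(params$omega0, 1, params$omega0, 1)
  fg_w <- c(params$omega0, 1, params$omega2, params$omega2)
  with_seed(seed, {
    cls <- sample.int(4, n_codons, replace = TRUE, prob = mix$prop)
    root_state <- sample.int(N_SENSE, n_codons, replace = TRUE,
                             prob = params$pi)
    ntaxa <- length(po$tips)
    ntot <- max(po$edge)
    states <- matrix(NA_integer_, ntot, n_codons)
    states[ntaxa + 1L, ] <- root_state
    pmats <- list()  # cached per (omega, length) pair
    pm_for <- function(w, len) {
      key <- paste0(format(w, digits = 12), "@", format(len, digits = 12))
      if (is.null(pmats[[key]])) {
        Q <- build_rate_matrix(params$kappa, w, params$pi)
        pmats[[key]] <<- transition_probabilities(Q, len * tfac, params$pi)
      }
      pmats[[key]]
    }
    # preorder = reversed postorder edge list
    for (e in rev(seq_along(po$lengths))) {
      pa <- po$edge[e, 1]
      ch <- po$edge[e, 2]
      child <- integer(n_codons)
      for (cl in sort(unique(cls))) {
        w <- if (e == po$fg_edge) fg_w[cl] else bg_w[cl]
        P <- pm_for(w, po$lengths[e])
        idx <- which(cls == cl)
        ps <- states[pa, idx]
        for (s in unique(ps)) {
          k <- idx[ps == s]
          child[k] <- sample.int(N_SENSE, length(k), replace = TRUE,
                                 prob = P[s, ])
        }
      }
      states[ch, ] <- child
    }
    seqs <- vapply(seq_len(ntaxa), function(i) {
      paste(SENSE_CODONS[states[i, ]], collapse = "")
    }, character(1))
    names(seqs) <- po$tips
    truth <- list(
      site_class = factor(c("0", "1", "2a", "2b")[cls],
                          levels = c("0", "1", "2a", "2b")),
      selected = params$omega2 > 1 && (mix$prop[3] + mix$prop[4]) > 1e-12)
    list(alignment = codon_alignment(seqs), truth = truth)
  })
}

#' Specification for the two-species aging count simulator
#'
#' Bundles the knobs of \code{\link{simulate_counts}}.  Defaults mirror
#' the liver RNA-seq cohorts of the motivating study: species A (the
#' long-lived species) with 6 young and 3 old samples, species B (the
#' short-lived species) with 4 young and 5 old samples.
#'
#' @param n_genes number of genes.
#' @param n_young_a,n_old_a,n_young_b,n_old_b samples per age group per
#'   species (each >= 2).
#' @param dispersion negative binomial dispersion (variance = mu +
#'   dispersion * mu^2), shared across genes.
#' @param frac_regulated probability that a (non-planted) gene is
#'   age-regulated in a given species.
#' @param lfc_mean,lfc_sd magnitude distribution of true log2
#'   fold-changes (normal, truncated below at 0.25).
#' @param n_psg number of genes flagged as PSGs.
#' @param q1_prob probability that a PSG is planted in quadrant I (down
#'   with age in species A, up in species B).
#' @param seed integer seed.
#' @return An object of class \code{"count_sim_spec"}.
#' @export
count_sim_spec <- function(n_genes = 2000, n_young_a = 6, n_old_a = 3,
                           n_young_b = 4, n_old_b = 5, dispersion = 0.05,
                           frac_regulated = 0.3, lfc_mean = 2, lfc_sd = 0.5,
                           n_psg = 50, q1_prob = 0.8, seed = NULL) {
  stopifnot(n_genes >= 1, n_young_a >= 2, n_old_a >= 2, n_young_b >= 2,
            n_old_b >= 2, dispersion > 0, frac_regulated >= 0,
            frac_regulated <= 1, q1_prob >= 0, q1_prob <= 1,
            n_psg <= n_genes)
  structure(as.list(environment()), class = "count_sim_spec")
}

#' Simulate young/old count matrices for two species
#'
#' Negative binomial counts for a two-species aging comparison with a
#' planted antagonistic-pleiotropy signal: a configurable fraction of the
#' PSG set is regulated in quadrant I (negative log2 fold-change with age
#' in the long-lived species A, positive in the short-lived species B);
#' other genes are regulated independently in each species with random
#' direction.  Old-group means are the young means scaled by 2^LFC.
#'
#' @param spec a \code{\link{count_sim_spec}}.
#' @return List with \code{counts_a}, \code{counts_b} (see
#'   \code{\link{count_matrix}}) and \code{truth}: a data frame of the
#'   true per-species log2 fold-changes, PSG membership and quadrant-I
#'   planting flags.
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "count_sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_genes
    genes <- sprintf("g%04d", seq_len(n))
    base <- rlnorm(n, meanlog = log(200), sdlog = 1.2)
    draw_mag <- function(k) pmax(abs(rnorm(k, spec$lfc_mean, spec$lfc_sd)),
                                 0.25)
    psg <- rep(FALSE, n)
    psg[seq_len(spec$n_psg)] <- TRUE
    planted <- psg & (runif(n) < spec$q1_prob)
    lfc_a <- lfc_b <- numeric(n)
    reg_a <- runif(n) < spec$frac_regulated
    reg_b <- runif(n) < spec$frac_regulated
    sgn_a <- sample(c(-1, 1), n, replace = TRUE)
    sgn_b <- sample(c(-1, 1), n, replace = TRUE)
    lfc_a[reg_a] <- sgn_a[reg_a] * draw_mag(sum(reg_a))
    lfc_b[reg_b] <- sgn_b[reg_b] * draw_mag(sum(reg_b))
    lfc_a[planted] <- -draw_mag(sum(planted))
    lfc_b[planted] <- draw_mag(sum(planted))

    nb_mat <- function(mu_y, mu_o, ny, no, prefix) {
      m <- cbind(matrix(rnbinom(n * ny, mu = rep(mu_y, ny),
                                size = 1 / spec$dispersion), n, ny),
                 matrix(rnbinom(n * no, mu = rep(mu_o, no),
                                size = 1 / spec$dispersion), n, no))
      dimnames(m) <- list(genes, paste0(prefix, c(paste0("y", seq_len(ny)),
                                                  paste0("o", seq_len(no)))))
      count_matrix(m, condition = rep(c("young", "old"), c(ny, no)),
                   species = prefix)
    }
    counts_a <- nb_mat(base, base * 2^lfc_a, spec$n_young_a, spec$n_old_a,
                       "A_")
    counts_b <- nb_mat(base, base * 2^lfc_b, spec$n_young_b, spec$n_old_b,
                       "B_")
    truth <- data.frame(gene = genes, lfc_a = lfc_a, lfc_b = lfc_b,
                        psg = psg, planted_q1 = planted,
                        stringsAsFactors = FALSE)
    list(counts_a = counts_a, counts_b = counts_b, truth = truth)
  })
}

#' Simulate multi-isoform CDS catalogs with known orthology
#'
#' Generates an ancestral coding sequence per gene (ATG start, sense-codon
#' body, terminal stop) and derives each species' ortholog by codon-wise
#' nucleotide mutation at the requested divergence, never introducing
#' internal stops.  Additional isoforms of a gene are internal-deletion
#' variants sharing the flanking exon-like core.  The truth table pairs
#' every gene across species.
#'
#' @param n_genes,n_species,isoforms_per_gene all >= 1.
#' @param divergence expected substitutions per site from the ancestor to
#'   each species.
#' @param seed integer seed.
#' @return List with \code{catalog} (a data frame of CDS records: gene,
#'   species, isoform, source, seq) and \code{truth} (ortholog pairing:
#'   each gene maps to itself in every species).
#' @export
simulate_cds_catalog <- function(n_genes, n_species, isoforms_per_gene = 1,
                                 divergence = 0.05, seed = NULL) {
  stopifnot(n_genes >= 1, n_species >= 1, isoforms_per_gene >= 1,
            divergence >= 0)
  with_seed(seed, {
    genes <- sprintf("g%03d", seq_len(n_genes))
    species <- paste0("sp", seq_len(n_species))
    anc <- lapply(seq_len(n_genes), function(i) {
      len <- sample(100:300, 1)
      c("ATG", sample(SENSE_CODONS, len, replace = TRUE),
        sample(STOP_CODONS, 1))
    })
    mutate_codons <- function(codons, rate) {
      body <- seq(2L, length(codons) - 1L)
      for (i in body) {
        nt <- strsplit(codons[i], "")[[1]]
        hit <- which(runif(3) < rate)
        if (!length(hit)) next
        repeat {
          cand <- nt
          for (h in hit) cand[h] <- sample(setdiff(CODON_NUCS, nt[h]), 1)
          cand_codon <- paste(cand, collapse = "")
          if (!(cand_codon %in% STOP_CODONS)) {
            codons[i] <- cand_codon
            break
          }
        }
      }
      codons
    }
    rows <- list()
    for (s in species) {
      for (gi in seq_len(n_genes)) {
        cod <- mutate_codons(anc[[gi]], divergence)
        for (iso in seq_len(isoforms_per_gene)) {
          cc <- cod
          if (iso > 1L) {
            # internal deletion keeping start, stop and a shared core
            nb <- length(cc) - 2L
            dlen <- max(1L, floor(nb * 0.25))
            dstart <- sample(seq(2L, length(cc) - dlen - 1L), 1)
            cc <- cc[-(dstart:(dstart + dlen - 1L))]
          }
          rows[[length(rows) + 1L]] <- data.frame(
            gene = genes[gi], species = s, isoform = paste0("iso", iso),
            source = "transcriptome", seq = paste(cc, collapse = ""),
            stringsAsFactors = FALSE)
        }
      }
    }
    truth <- expand.grid(gene = genes, species = species,
                         stringsAsFactors = FALSE)
    truth$ortholog <- truth$gene
    list(catalog = do.call(rbind, rows), truth = truth)
  })
}
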