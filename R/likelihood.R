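#' Branch-site model log-likelihood
#'
#' Log-likelihood of a codon alignment under the branch-site model
#' (Model A).  Each site is a mixture over the four site classes; on the
#' foreground branch a class uses its foreground dN/dS, on all other
#' branches its background dN/dS.  All generators share one scale factor
#' chosen so the mixture-average background rate is one substitution per
#' codon per unit branch length, making branch lengths comparable between
#' the nested alternative/null pair.  Gap and ambiguous codons are missing
#' data (partial likelihood one over all 61 states).
#'
#' @param aln a \code{\link{codon_alignment}}; species must match the tree
#'   tips.
#' @param tree a \code{phylo} with branch lengths; the foreground branch
#'   must be set on the tree or passed via \code{foreground}.
#' @param params a \code{\link{branch_site_params}} object.
#' @param model \code{"alternative"} (omega2 free) or \code{"null"}
#'   (omega2 forced to 1).
#' @param foreground optional node label naming the foreground branch,
#'   overriding the tree attribute.
#' @param method \code{"pruning"} (Felsenstein pruning, the production
#'   path) or \code{"enumeration"} (brute-force sum over all internal-node
#'   state assignments, a slow reference usable up to 4 taxa).
#' @return The log-likelihood (a scalar).
#' @export
log_likelihood <- function(aln, tree, params,
                           model = c("alternative", "null"),
                           foreground = NULL,
                           method = c("pruning", "enumeration")) {
  model <- match.arg(model)
  method <- match.arg(method)
  po <- tree_postorder(tree, foreground)
  if (po$fg_edge == 0L) {
    stop("missing-foreground: no foreground branch designated", call. = FALSE)
  }
  if (!setequal(po$tips, aln_species(aln))) {
    stop("species-mismatch: alignment species and tree tips differ",
         call. = FALSE)
  }
  w2 <- if (model == "null") 1 else params$omega2
  if (method == "enumeration") {
    return(enum_loglik(aln, po, params, w2))
  }
  st <- codon_states(aln)[po$tips, , drop = FALSE]
  cp <- compress_patterns(st)
  res <- bs_core_cpp(cp$states, cp$weights, po$edge, po$lengths, po$fg_edge,
                     params$pi, CODON_PAIR_TYPE, params$kappa, params$omega0,
                     w2, params$p0, params$p1, params$scale, FALSE)
  res$lnL
}

# Mixture proportions and the shared generator scale (mixture-average
# background rate = 1), mirroring the C++ core.
mixture_layout <- function(params) {
  p0 <- params$p0
  p1 <- params$p1
  rest <- 1 - p0 - p1
  prop <- c(p0, p1, rest * p0 / (p0 + p1), rest * p1 / (p0 + p1))
  rate_of <- function(w) {
    Q <- build_rate_matrix(params$kappa, w, params$pi)
    -sum(params$pi * diag(Q))
  }
  rate <- (prop[1] + prop[3]) * rate_of(params$omega0) +
    (prop[2] + prop[4]) * rate_of(1)
  list(prop = prop, rate = rate)
}

# Brute-force reference likelihood: literal sum over every assignment of
# codon states to the internal nodes.  Independent of the pruning core
# (pure R generator + matrix exponential).  Exponential in the number of
# internal nodes; guarded to <= 4 taxa.
enum_loglik <- function(aln, po, params, w2) {
  ntaxa <- length(po$tips)
  if (ntaxa > 4L) {
    stop("invalid-argument: enumeration reference limited to 4 taxa",
         call. = FALSE)
  }
  st <- codon_states(aln)[po$tips, , drop = FALSE] + 1L  # 1-based, 0 = missing
  mix <- mixture_layout(params)
  tfac <- params$scale / mix$rate
  bg_w <- c(params$omega0, 1, params$omega0, 1)
  fg_w <- c(params$omega0, 1, w2, w2)
  internals <- sort(unique(po$edge[, 1]))
  grid <- as.matrix(expand.grid(rep(list(seq_len(N_SENSE)),
                                    length(internals))))
  colnames(grid) <- internals
  root <- ntaxa + 1L
  nsite <- ncol(st)
  site_lik <- matrix(0, nsite, 4)
  for (cl in 1:4) {
    P <- lapply(seq_along(po$lengths), function(e) {
      w <- if (e == po$fg_edge) fg_w[cl] else bg_w[cl]
      Q <- build_rate_matrix(params$kappa, w, params$pi)
      transition_probabilities(Q, po$lengths[e] * tfac, params$pi)
    })
    g_of <- function(node) grid[, as.character(node)]
    for (s in seq_len(nsite)) {
      vals <- params$pi[g_of(root)]
      for (e in seq_along(po$lengths)) {
        pa <- po$edge[e, 1]
        ch <- po$edge[e, 2]
        if (ch <= ntaxa) {
          obs <- st[ch, s]
          if (obs == 0L) next  # missing tip: sums to 1
          vals <- vals * P[[e]][cbind(g_of(pa), obs)]
        } else {
          vals <- vals * P[[e]][cbind(g_of(pa), g_of(ch))]
        }
      }
      site_lik[s, cl] <- sum(vals)
    }
  }
  sum(log(as.numeric(site_lik %*% mix$prop)))
}

#' Likelihood-ratio test of positive selection
#'
#' Compares the alternative branch-site model (omega2 free) with its null
#' (omega2 = 1).  The statistic is \code{max(0, 2 (lnL_alt - lnL_null))}
#' and the p-value comes from the chi-square reference with one degree of
#' freedom (the conservative standard), or optionally from the 50:50
#' mixture of a point mass at zero and chi-square 1.
#'
#' @param lnl_alt,lnl_null fitted log-likelihoods of the nested pair.
#' @param mixture use the 50:50 boundary mixture instead of plain
#'   chi-square 1.
#' @return List with \code{statistic} and \code{p_value}.
#' @examples
#' lrt(-100, -101.92)  # statistic 3.841, p ~ 0.05
#' @export
lrt <- function(lnl_alt, lnl_null, mixture = FALSE) {
  stat <- max(0, 2 * (lnl_alt - lnl_null))
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  if (mixture) p <- if (stat <= 0) 1 else 0.5 * p
  list(statistic = stat, p_value = p)
}

#' Naive empirical Bayes site posteriors
#'
#' Posterior probability of each site class at every alignment site,
#' computed by plugging the fitted parameters into Bayes' rule
#' (proportion times class likelihood over site likelihood).  Sites whose
#' posterior mass on the selected classes (2a + 2b) reaches the threshold
#' are reported as positively selected sites.
#'
#' @inheritParams log_likelihood
#' @param params fitted alternative-model parameters.
#' @param threshold posterior cutoff for calling a selected site
#'   (default 0.5; sites at 0.95 are additionally flagged).
#' @return List with \code{posteriors} (sites x classes 0/1/2a/2b) and
#'   \code{selected} (data frame of site, posterior, strong flag).
#' @export
site_posteriors <- function(aln, tree, params, foreground = NULL,
                            threshold = 0.5) {
  po <- tree_postorder(tree, foreground)
  if (po$fg_edge == 0L) {
    stop("missing-foreground: no foreground branch designated", call. = FALSE)
  }
  st <- codon_states(aln)[po$tips, , drop = FALSE]
  cp <- compress_patterns(st)
  res <- bs_core_cpp(cp$states, cp$weights, po$edge, po$lengths, po$fg_edge,
                     params$pi, CODON_PAIR_TYPE, params$kappa, params$omega0,
                     params$omega2, params$p0, params$p1, params$scale, TRUE)
  post <- res$posteriors[cp$map, , drop = FALSE]
  colnames(post) <- c("0", "1", "2a", "2b")
  rownames(post) <- NULL
  sel_p <- post[, "2a"] + post[, "2b"]
  hit <- which(sel_p >= threshold)
  list(posteriors = post,
       selected = data.frame(site = hit, posterior = sel_p[hit],
                             strong = sel_p[hit] >= 0.95))
}
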