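#' Branch-site model parameters (Model A)
#'
#' Parameter container for the branch-site codon model.  Model A mixes
#' four site classes: class 0 (purifying, \code{omega0 < 1} on all
#' branches), class 1 (neutral, omega = 1 everywhere), and classes 2a/2b
#' which behave like 0/1 on background branches but evolve with
#' \code{omega2 >= 1} on the designated foreground branch.  The null
#' hypothesis of the test fixes \code{omega2 = 1}.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega0 dN/dS of the purifying class, in (0, 1).
#' @param omega2 foreground dN/dS of the selected classes, >= 1.
#' @param p0,p1 proportions of classes 0 and 1, in (0, 1) with
#'   \code{p0 + p1 <= 1}; classes 2a/2b receive the remainder split
#'   p0:(p0+p1) and p1:(p0+p1).
#' @param pi codon equilibrium frequencies over the 61 sense codons
#'   (default uniform); must sum to 1.
#' @param scale tree scale factor s > 0 multiplying all branch lengths.
#' @return An object of class \code{"branch_site_params"}.
#' @seealso \code{\link{site_class_layout}}, \code{\link{branch_site_test}}
#' @export
branch_site_params <- function(kappa = 2, omega0 = 0.2, omega2 = 3,
                               p0 = 0.45, p1 = 0.45, pi = NULL, scale = 1) {
  if (is.null(pi)) pi <- rep(1 / N_SENSE, N_SENSE)
  stopifnot(kappa > 0, omega0 > 0, omega0 < 1, omega2 >= 1,
            p0 > 0, p0 < 1, p1 > 0, p1 < 1, p0 + p1 <= 1,
            length(pi) == N_SENSE, all(pi >= 0), scale > 0)
  if (abs(sum(pi) - 1) > 1e-8) {
    stop("invalid-argument: pi must sum to 1", call. = FALSE)
  }
  structure(list(kappa = kappa, omega0 = omega0, omega2 = omega2,
                 p0 = p0, p1 = p1, pi = pi, scale = scale),
            class = "branch_site_params")
}

#' @export
print.branch_site_params <- function(x, ...) {
  lay <- site_class_layout(x)
  cat("Branch-site model parameters\n")
  cat(sprintf("  kappa = %.4g  omega0 = %.4g  omega2 = %.4g  scale = %.4g\n",
              x$kappa, x$omega0, x$omega2, x$scale))
  print(lay, row.names = FALSE)
  invisible(x)
}

#' Site-class layout of the branch-site model
#'
#' Expands the parameter set into the four-class mixture table: per class
#' its proportion and its background/foreground dN/dS.
#'
#' @param params a \code{\link{branch_site_params}} object.
#' @return A data frame with columns \code{class}, \code{proportion},
#'   \code{omega_background}, \code{omega_foreground}.
#' @examples
#' site_class_layout(branch_site_params(p0 = 0.5, p1 = 0.3))
#' @export
site_class_layout <- function(params) {
  p0 <- params$p0
  p1 <- params$p1
  rest <- 1 - p0 - p1
  p2a <- rest * p0 / (p0 + p1)
  p2b <- rest * p1 / (p0 + p1)
  data.frame(class = c("0", "1", "2a", "2b"),
             proportion = c(p0, p1, p2a, p2b),
             omega_background = c(params$omega0, 1, params$omega0, 1),
             omega_foreground = c(params$omega0, 1, params$omega2,
                                  params$omega2),
             stringsAsFactors = FALSE)
}

#' F3x4 codon equilibrium frequencies
#'
#' Estimates codon frequencies from the observed nucleotide composition at
#' the three codon positions (the F3x4 estimator): the frequency of a
#' codon is the product of its three position-specific nucleotide
#' frequencies, with stop codons removed and the rest renormalized.
#' Position frequencies are floored at 1e-6 so codons containing a
#' nucleotide unseen at some position keep nonzero mass.
#'
#' @param aln a \code{\link{codon_alignment}}.
#' @return Numeric vector of 61 frequencies (named by codon) summing to 1.
#' @export
f3x4_frequencies <- function(aln) {
  if (length(aln) == 0) {
    stop("invalid-argument: empty alignment", call. = FALSE)
  }
  codons <- aln[aln != "---"]
  pos <- matrix(vapply(1:3, function(p) substr(codons, p, p),
                       character(length(codons))), ncol = 3)
  freq <- matrix(0, nrow = 3, ncol = 4, dimnames = list(NULL, CODON_NUCS))
  for (p in 1:3) {
    tab <- table(factor(pos[, p], levels = CODON_NUCS))
    f <- as.numeric(tab) / max(sum(tab), 1)
    f <- pmax(f, 1e-6)
    freq[p, ] <- f / sum(f)
  }
  pi <- vapply(SENSE_CODONS, function(cd) {
    prod(freq[cbind(1:3, match(strsplit(cd, "")[[1]], CODON_NUCS))])
  }, numeric(1))
  pi / sum(pi)
}

#' Goldman-Yang codon rate matrix
#'
#' Builds the 61x61 generator of the codon substitution process: rates are
#' zero between codons differing at more than one position; otherwise
#' \code{pi_j} times kappa for transitions and omega for nonsynonymous
#' changes.  The diagonal makes rows sum to zero.  The matrix is
#' reversible with respect to \code{pi}.
#'
#' @param kappa transition/transversion rate ratio.
#' @param omega nonsynonymous/synonymous rate ratio (dN/dS).
#' @param pi codon equilibrium frequencies (61, summing to 1).
#' @return 61x61 generator matrix with codon dimnames.
#' @export
build_rate_matrix <- function(kappa, omega, pi) {
  stopifnot(kappa > 0, omega >= 0, length(pi) == N_SENSE)
  Q <- matrix(0, N_SENSE, N_SENSE,
              dimnames = list(SENSE_CODONS, SENSE_CODONS))
  tt <- CODON_PAIR_TYPE
  Q[tt == 1L] <- 1
  Q[tt == 2L] <- kappa
  Q[tt == 3L] <- omega
  Q[tt == 4L] <- omega * kappa
  Q <- sweep(Q, 2, pi, `*`)
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probabilities of a codon generator
#'
#' Computes \code{P(t) = exp(Qt)}.  When the stationary distribution
#' \code{pi} is supplied, the reversible generator is symmetrized and
#' decomposed with a symmetric eigensolver; otherwise a general
#' eigendecomposition is used.
#'
#' @param Q generator matrix (rows summing to 0).
#' @param t branch length, >= 0.
#' @param pi optional stationary distribution for the symmetrized path.
#' @return Stochastic matrix \code{P(t)} (rows sum to 1, entries >= 0).
#' @export
transition_probabilities <- function(Q, t, pi = NULL) {
  if (t < 0) stop("invalid-argument: negative branch length", call. = FALSE)
  if (!is.null(pi)) {
    sp <- sqrt(pi)
    B <- sweep(sweep(Q, 1, sp, `*`), 2, sp, `/`)
    B <- (B + t(B)) / 2
    e <- eigen(B, symmetric = TRUE)
    P <- sweep(e$vectors, 1, sp, `/`) %*%
      (exp(e$values * t) * t(sweep(e$vectors, 1, sp, `*`)))
  } else {
    e <- eigen(Q)
    P <- Re(e$vectors %*% (exp(e$values * t) * solve(e$vectors)))
  }
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q)
  P
}
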