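# Maximum-likelihood fitting of the branch-site model and the user-facing
# branch_site_test() constructor with its S3 methods.

# parameter packing: unconstrained vector <-> branch_site_params
pack_params <- function(params, model) {
  p0 <- params$p0
  p1 <- params$p1
  rest <- max(1 - p0 - p1, 1e-8)
  x <- c(log(params$kappa),
         stats::qlogis(params$omega0),
         log(p0 / rest), log(p1 / rest),
         log(params$scale))
  if (model == "alternative") {
    x <- append(x, log(max(params$omega2 - 1, 1e-6)), after = 2)
  }
  x
}

unpack_params <- function(x, model, pi) {
  if (model == "alternative") {
    kappa <- exp(x[1]); omega0 <- stats::plogis(x[2])
    omega2 <- 1 + exp(x[3]); a <- x[4]; b <- x[5]; scale <- exp(x[6])
  } else {
    kappa <- exp(x[1]); omega0 <- stats::plogis(x[2])
    omega2 <- 1; a <- x[3]; b <- x[4]; scale <- exp(x[5])
  }
  e <- exp(c(a, b, 0))
  p <- e / sum(e)
  list(kappa = kappa, omega0 = omega0, omega2 = omega2,
       p0 = p[1], p1 = p[2], pi = pi, scale = scale)
}

fit_bounds <- function(model) {
  lo <- c(log(0.05), -10, -12, -12, log(0.02))
  hi <- c(log(50), 10, 12, 12, log(50))
  if (model == "alternative") {
    lo <- append(lo, -10, after = 2)
    hi <- append(hi, log(99), after = 2)
  }
  list(lower = lo, upper = hi)
}

random_start <- function(model) {
  # start ranges: kappa in [0.5,5], omega0 in [0.01,0.9], omega2 in [1,10],
  # (p0, p1) Dirichlet-ish, scale around 1
  g <- rgamma(3, shape = 1)
  p <- g / sum(g)
  p <- 0.9 * p + 0.1 / 3  # keep away from the simplex boundary
  list(kappa = runif(1, 0.5, 5), omega0 = runif(1, 0.01, 0.9),
       omega2 = runif(1, 1.01, 10), p0 = p[1], p1 = p[2],
       scale = exp(runif(1, log(0.3), log(3))))
}

#' Fit the branch-site model by maximum likelihood
#'
#' Bounded quasi-Newton (L-BFGS-B) optimization of the branch-site model
#' over (kappa, omega0, omega2 [alternative only], p0, p1, tree scale),
#' with the class proportions handled through a softmax transform.  The
#' best of \code{n_starts} starts is returned: one deterministic start
#' (or the supplied \code{init}) plus random restarts drawn from wide
#' parameter ranges.  Codon frequencies are held fixed at their F3x4
#' estimate (or at \code{pi}).  The input tree's relative branch lengths
#' are fixed; only the single scale factor is estimated.
#'
#' @inheritParams log_likelihood
#' @param n_starts number of optimization starts (>= 1).
#' @param seed integer seed controlling the random restarts.
#' @param pi optional codon frequencies; default F3x4 from the alignment.
#' @param init optional \code{\link{branch_site_params}} used as the first
#'   start.
#' @return List with elements \code{params} (the MLE as a
#'   \code{branch_site_params}), \code{lnL}, \code{model},
#'   \code{convergence} and \code{n_starts}.
#' @export
fit_branch_site_model <- function(aln, tree,
                                  model = c("alternative", "null"),
                                  foreground = NULL, n_starts = 3,
                                  seed = NULL, pi = NULL, init = NULL) {
  model <- match.arg(model)
  stopifnot(n_starts >= 1)
  po <- tree_postorder(tree, foreground)
  if (po$fg_edge == 0L) {
    stop("missing-foreground: no foreground branch designated", call. = FALSE)
  }
  if (!setequal(po$tips, aln_species(aln))) {
    stop("species-mismatch: alignment species and tree tips differ",
         call. = FALSE)
  }
  if (is.null(pi)) pi <- f3x4_frequencies(aln)
  st <- codon_states(aln)[po$tips, , drop = FALSE]
  cp <- compress_patterns(st)

  negll <- function(x) {
    p <- unpack_params(x, model, pi)
    -bs_core_cpp(cp$states, cp$weights, po$edge, po$lengths, po$fg_edge,
                 pi, CODON_PAIR_TYPE, p$kappa, p$omega0, p$omega2,
                 p$p0, p$p1, p$scale, FALSE)$lnL
  }
  # forward-difference gradient reusing the last objective value
  cache <- new.env(parent = emptyenv())
  fn <- function(x) {
    v <- negll(x)
    cache$x <- x
    cache$f <- v
    v
  }
  gr <- function(x) {
    f0 <- if (!is.null(cache$x) && identical(cache$x, x)) {
      cache$f
    } else {
      negll(x)
    }
    h <- 1e-6 * pmax(abs(x), 1)
    vapply(seq_along(x), function(i) {
      xi <- x
      xi[i] <- xi[i] + h[i]
      (negll(xi) - f0) / h[i]
    }, numeric(1))
  }

  starts <- list(init %||% list(kappa = 2, omega0 = 0.3, omega2 = 2.5,
                                p0 = 0.45, p1 = 0.45, scale = 1))
  if (n_starts > 1) {
    starts <- c(starts, with_seed(seed, replicate(n_starts - 1,
                                                  random_start(model),
                                                  simplify = FALSE)))
  }
  bd <- fit_bounds(model)
  best <- NULL
  fails <- character(0)
  for (s in starts) {
    x0 <- pack_params(s, model)
    x0 <- pmin(pmax(x0, bd$lower), bd$upper)
    fit <- tryCatch(
      optim(x0, fn, gr, method = "L-BFGS-B", lower = bd$lower,
            upper = bd$upper, control = list(factr = 1e9, maxit = 300)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      fails <- c(fails, conditionMessage(fit))
      next
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("fit-error: all optimization starts failed (",
         paste(unique(fails), collapse = "; "), ")", call. = FALSE)
  }
  p <- unpack_params(best$par, model, pi)
  params <- branch_site_params(kappa = p$kappa, omega0 = p$omega0,
                               omega2 = max(p$omega2, 1), p0 = p$p0,
                               p1 = p$p1, pi = pi, scale = p$scale)
  list(params = params, lnL = -best$value, model = model,
       convergence = best$convergence, n_starts = length(starts))
}

#' Branch-site test of positive selection
#'
#' The package's core fit: tests whether a designated foreground branch of
#' the phylogeny carries sites evolving with dN/dS > 1.  Fits the null
#' model (omega2 = 1) and the alternative (omega2 free) by maximum
#' likelihood, compares them with a likelihood-ratio test against the
#' chi-square(1) reference, and computes naive empirical Bayes posterior
#' probabilities that each site belongs to a selected class.
#'
#' The alternative fit always includes a start at the null MLE, so the
#' nesting inequality \code{lnL_alt >= lnL_null} holds up to optimizer
#' tolerance.
#'
#' @inheritParams fit_branch_site_model
#' @param init_null optional warm start for the null fit (e.g. the
#'   previous gene's null MLE when scanning many genes on one tree).
#' @param mixture use the 50:50 boundary mixture null distribution instead
#'   of plain chi-square(1).
#' @param posterior_threshold posterior cutoff for reporting selected
#'   sites.
#' @return An object of class \code{"branch_site_fit"} with components
#'   \code{alt}, \code{null} (fits), \code{statistic}, \code{p_value},
#'   \code{posteriors}, \code{selected}, \code{foreground},
#'   \code{n_codons} and \code{species}.
#' @examples
#' \donttest{
#' tr <- simulate_tree(4, depth = 0.3, seed = 1)
#' tr <- set_foreground(tr, tr$tip.label[1])
#' sim <- simulate_codon_alignment(tr, branch_site_params(omega2 = 8,
#'   p0 = 0.4, p1 = 0.4), n_codons = 150, seed = 1)
#' fit <- branch_site_test(sim$alignment, tr, seed = 1)
#' fit
#' }
#' @export
branch_site_test <- function(aln, tree, foreground = NULL, n_starts = 3,
                             seed = NULL, pi = NULL, mixture = FALSE,
                             posterior_threshold = 0.5, init_null = NULL) {
  if (is.null(pi)) pi <- f3x4_frequencies(aln)
  fg <- foreground %||% get_foreground(tree)
  null_fit <- fit_branch_site_model(aln, tree, model = "null",
                                    foreground = fg, n_starts = n_starts,
                                    seed = derive_seed(seed, 1), pi = pi,
                                    init = init_null)
  # warm start the alternative from the null MLE, but with omega2 off the
  # boundary: at omega2 = 1 the log(omega2 - 1) coordinate has vanishing
  # gradient and the optimizer could never leave the null
  alt_init <- null_fit$params
  alt_init$omega2 <- 2.5
  alt_fit <- fit_branch_site_model(aln, tree, model = "alternative",
                                   foreground = fg, n_starts = n_starts,
                                   seed = derive_seed(seed, 2), pi = pi,
                                   init = alt_init)
  if (alt_fit$lnL < null_fit$lnL) {
    # boundary case: the alternative attains at least the null maximum
    alt_fit$params <- null_fit$params
    alt_fit$params$omega2 <- 1
    alt_fit$lnL <- null_fit$lnL
  }
  test <- lrt(alt_fit$lnL, null_fit$lnL, mixture = mixture)
  post <- site_posteriors(aln, tree, alt_fit$params, foreground = fg,
                          threshold = posterior_threshold)
  structure(list(alt = alt_fit, null = null_fit,
                 statistic = test$statistic, p_value = test$p_value,
                 mixture = mixture, posteriors = post$posteriors,
                 selected = post$selected,
                 posterior_threshold = posterior_threshold,
                 foreground = fg, n_codons = n_codons(aln),
                 species = aln_species(aln), tree = tree,
                 call = match.call()),
            class = "branch_site_fit")
}

#' @export
print.branch_site_fit <- function(x, ...) {
  cat("Branch-site test of positive selection\n")
  cat(sprintf("  foreground branch: %s   (%d species, %d codons)\n",
              x$foreground, length(x$species), x$n_codons))
  cat(sprintf("  lnL (null) = %.4f   lnL (alt) = %.4f\n",
              x$null$lnL, x$alt$lnL))
  cat(sprintf("  2*dlnL = %.4f   p = %.4g%s\n", x$statistic, x$p_value,
              if (x$mixture) "  (boundary mixture null)" else ""))
  cat(sprintf("  omega2 = %.3f on the foreground; %d selected site(s) at posterior >= %.2f\n",
              x$alt$params$omega2, nrow(x$selected), x$posterior_threshold))
  invisible(x)
}

#' @method summary branch_site_fit
#' @export
summary.branch_site_fit <- function(object, ...) {
  structure(list(fit = object,
                 layout = site_class_layout(object$alt$params)),
            class = "summary.branch_site_fit")
}

#' @export
print.summary.branch_site_fit <- function(x, ...) {
  print(x$fit)
  cat("\nFitted site-class mixture (alternative model):\n")
  print(x$layout, row.names = FALSE, digits = 4)
  cat(sprintf("\nkappa = %.3f, tree scale = %.3f\n",
              x$fit$alt$params$kappa, x$fit$alt$params$scale))
  if (nrow(x$fit$selected)) {
    cat("\nSelected sites (naive empirical Bayes):\n")
    print(x$fit$selected, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @method coef branch_site_fit
#' @export
coef.branch_site_fit <- function(object, ...) {
  p <- object$alt$params
  lay <- site_class_layout(p)
  c(kappa = p$kappa, omega0 = p$omega0, omega2 = p$omega2,
    p0 = p$p0, p1 = p$p1, p2a = lay$proportion[3], p2b = lay$proportion[4],
    scale = p$scale)
}

#' @method logLik branch_site_fit
#' @export
logLik.branch_site_fit <- function(object, model = c("alternative", "null"),
                                   ...) {
  model <- match.arg(model)
  val <- if (model == "alternative") object$alt$lnL else object$null$lnL
  structure(val, df = if (model == "alternative") 6 else 5,
            nobs = object$n_codons, class = "logLik")
}

#' @method plot branch_site_fit
#' @export
plot.branch_site_fit <- function(x, ...) {
  sel <- x$posteriors[, "2a"] + x$posteriors[, "2b"]
  graphics::barplot(sel, names.arg = seq_along(sel), border = NA,
                    col = ifelse(sel >= x$posterior_threshold,
                                 "firebrick", "grey60"),
                    xlab = "codon site",
                    ylab = "posterior P(class 2a or 2b)",
                    ylim = c(0, 1), ...)
  graphics::abline(h = x$posterior_threshold, lty = 2)
  invisible(x)
}

#' @export
simulate.branch_site_fit <- function(object, nsim = 1, seed = NULL, ...) {
  lapply(seq_len(nsim), function(i) {
    simulate_codon_alignment(object$tree, object$alt$params,
                             n_codons = object$n_codons,
                             foreground = object$foreground,
                             seed = derive_seed(seed, i))$alignment
  })
}
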