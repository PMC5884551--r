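# Young-vs-old differential expression and the antagonistic-pleiotropy
# statistics: quadrant classification, the one-sided quadrant-I Fisher
# test and the Lancaster directional combination.

#' Construct a count matrix
#'
#' Gene-by-sample integer counts for one species' aging comparison, with
#' a young/old condition label per sample.
#'
#' @param counts non-negative integer matrix, genes in rows (named),
#'   samples in columns (named).
#' @param condition character/factor of \code{"young"}/\code{"old"} per
#'   sample; at least 2 samples per condition.
#' @param species species id.
#' @return An object of class \code{"count_matrix"}.
#' @export
count_matrix <- function(counts, condition, species = "sp") {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("invalid-argument: counts must be non-negative integers",
         call. = FALSE)
  }
  condition <- factor(condition, levels = c("young", "old"))
  if (length(condition) != ncol(counts) || anyNA(condition)) {
    stop("invalid-argument: one young/old label per sample required",
         call. = FALSE)
  }
  if (any(table(condition) < 2)) {
    stop("invalid-argument: at least 2 samples per condition", call. = FALSE)
  }
  structure(counts, condition = condition, species = species,
            class = c("count_matrix", "matrix"))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("Count matrix (%s): %d genes x %d samples (%d young, %d old)\n",
              attr(x, "species"), nrow(x), ncol(x),
              sum(attr(x, "condition") == "young"),
              sum(attr(x, "condition") == "old")))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: each sample's counts are compared to
#' the per-gene geometric mean across samples, and the factor is the
#' median of those ratios over genes expressed in all samples.  Factors
#' are rescaled to geometric mean one.
#'
#' @param counts a \code{\link{count_matrix}} or plain count matrix.
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  m <- unclass(counts)
  use <- rowSums(m > 0) == ncol(m)
  if (!any(use)) {
    stop("normalization-error: no gene expressed in all samples",
         call. = FALSE)
  }
  lg <- log(m[use, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(median(col - geo)))
  sf / exp(mean(log(sf)))
}

#' Minimal negative binomial differential-expression test
#'
#' Young-vs-old test per gene: counts are normalized with median-of-ratios
#' size factors, the NB dispersion is moment-estimated per gene (floored
#' at 1e-8) and shrunk halfway toward a mean-dispersion trend, and the
#' log2 fold-change (old vs young) is tested with a Wald statistic whose
#' standard error comes from the NB variance function by the delta method.
#' q-values are Benjamini-Hochberg; genes are flagged regulated at
#' q <= 0.1.  This is a deliberately small-scale approximation of the
#' standard NB DE machinery, not a numerical match to it; externally
#' produced LFC/q tables can be substituted anywhere a DE table is
#' consumed.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param q_threshold FDR threshold for the regulated flag.
#' @return Data frame of class \code{"de_result"}: gene, base_mean, lfc,
#'   se, stat, p_value, q_value, regulated.
#' @export
de_test <- function(counts, q_threshold = 0.1) {
  cond <- attr(counts, "condition")
  m <- unclass(counts)
  sf <- size_factors(m)
  norm <- sweep(m, 2, sf, `/`)
  young <- cond == "young"
  old <- cond == "old"
  ny <- sum(young)
  no <- sum(old)
  my <- rowMeans(norm[, young, drop = FALSE])
  mo <- rowMeans(norm[, old, drop = FALSE])
  vy <- apply(norm[, young, drop = FALSE], 1, var)
  vo <- apply(norm[, old, drop = FALSE], 1, var)

  # per-gene moment dispersion pooled over the two groups
  dgrp <- function(v, mu) ifelse(mu > 0, (v - mu) / mu^2, 0)
  disp_raw <- pmax(((ny - 1) * dgrp(vy, my) + (no - 1) * dgrp(vo, mo)) /
                     (ny + no - 2), 1e-8)
  base_mean <- (my + mo) / 2
  # mean-dispersion trend: disp ~ a0 + a1/mean, fitted on expressed genes
  expressed <- base_mean > 0
  trend <- rep(1e-8, length(base_mean))
  if (sum(expressed) > 10) {
    fit <- stats::lm(disp_raw[expressed] ~ I(1 / base_mean[expressed]))
    co <- pmax(stats::coef(fit), 0)
    trend[expressed] <- pmax(co[1] + co[2] / base_mean[expressed], 1e-8)
  }
  disp <- pmax(0.5 * disp_raw + 0.5 * trend, 1e-8)

  eps <- 0.5
  lfc <- log2((mo + eps) / (my + eps))
  # delta-method variance of the log2 mean ratio under NB sampling
  s_inv <- sum(1 / sf[young])
  o_inv <- sum(1 / sf[old])
  var_my <- my * s_inv / ny^2 + disp * my^2 / ny
  var_mo <- mo * o_inv / no^2 + disp * mo^2 / no
  se2 <- (var_my / (my + eps)^2 + var_mo / (mo + eps)^2) / log(2)^2
  se <- sqrt(pmax(se2, 1e-12))
  stat <- lfc / se
  p <- 2 * pnorm(-abs(stat))
  allzero <- my == 0 & mo == 0
  lfc[allzero] <- 0
  stat[allzero] <- 0
  p[allzero] <- 1
  q <- bh_fdr(p)
  out <- data.frame(gene = rownames(m), base_mean = base_mean, lfc = lfc,
                    se = se, stat = stat, p_value = p, q_value = q,
                    regulated = q <= q_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("de_result", class(out))
  attr(out, "species") <- attr(counts, "species")
  out
}

#' Classify jointly regulated genes into aging quadrants
#'
#' Genes regulated (q <= 0.1) in both species are placed in a quadrant by
#' the signs of their log2 fold-changes (species A, species B): quadrant I
#' = (-, +) (down with age in the long-lived species, up in the
#' short-lived one), II = (-, -), III = (+, -), IV = (+, +).  Genes with a
#' fold-change of exactly zero are excluded.  Genes regulated in only one
#' species do not enter the table.
#'
#' @param de_a,de_b \code{\link{de_test}} results for species A (long-
#'   lived) and B (short-lived).
#' @param psgs character vector of positively selected gene ids.
#' @return A data frame of class \code{"quadrant_table"} (gene, lfc_a,
#'   lfc_b, quadrant, psg) with a quadrant-by-membership count table in
#'   \code{attr(, "counts")}.
#' @export
classify_quadrants <- function(de_a, de_b, psgs) {
  a <- de_a[de_a$regulated & de_a$lfc != 0, c("gene", "lfc")]
  names(a) <- c("gene", "lfc_a")
  b <- de_b[de_b$regulated & de_b$lfc != 0, c("gene", "lfc")]
  names(b) <- c("gene", "lfc_b")
  tab <- merge(a, b, by = "gene")
  quadrant <- ifelse(tab$lfc_a < 0,
                     ifelse(tab$lfc_b > 0, "I", "II"),
                     ifelse(tab$lfc_b > 0, "IV", "III"))
  tab$quadrant <- factor(quadrant, levels = c("I", "II", "III", "IV"))
  tab$psg <- tab$gene %in% psgs
  counts <- table(quadrant = tab$quadrant, psg = tab$psg)
  structure(tab, counts = counts, class = c("quadrant_table", class(tab)))
}

#' @export
print.quadrant_table <- function(x, ...) {
  cat("Aging-regulation quadrants (genes regulated in both species):",
      nrow(x), "genes\n")
  print(attr(x, "counts"))
  invisible(x)
}

#' One-sided Fisher test for PSG excess in quadrant I
#'
#' Tests whether PSGs are overrepresented in quadrant I (down-regulated
#' with age in the long-lived species, up-regulated in the short-lived
#' one) against the sum of quadrants II, III and IV, using the one-sided
#' Fisher exact test (hypergeometric upper tail).
#'
#' @param table a \code{\link{classify_quadrants}} result.
#' @return One-sided p-value.
#' @export
quadrant_fisher <- function(table) {
  n_total <- nrow(table)
  n_q1 <- sum(table$quadrant == "I")
  n_psg <- sum(table$psg)
  x <- sum(table$psg & table$quadrant == "I")
  if (n_total == 0 || n_q1 == 0 || n_psg == 0 || n_q1 == n_total ||
      n_psg == n_total) {
    warning("quadrant_fisher: degenerate margin, p = 1")
    return(1)
  }
  phyper(x - 1, n_q1, n_total - n_q1, n_psg, lower.tail = FALSE)
}

#' Lancaster p-value combination
#'
#' Weighted generalization of Fisher's method: each p-value is converted
#' to a chi-square deviate with its weight as degrees of freedom, the
#' deviates are summed, and the sum is referred to chi-square with the
#' total weight.  Equal weights of 2 recover Fisher's method exactly.
#'
#' @param p p-values in (0, 1]; zeros are clamped to the smallest positive
#'   double with a warning.
#' @param w positive weights (degrees of freedom), one per p-value.
#' @return Combined p-value.
#' @examples
#' lancaster_combine(c(0.05, 0.05), c(2, 2))  # Fisher's method
#' @export
lancaster_combine <- function(p, w = rep(2, length(p))) {
  stopifnot(length(p) == length(w), all(w > 0), all(p >= 0), all(p <= 1))
  if (any(p == 0)) {
    warning("lancaster_combine: p = 0 clamped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  T <- sum(qchisq(p, df = w, lower.tail = FALSE))
  pchisq(T, df = sum(w), lower.tail = FALSE)
}

#' Directional antagonistic-pleiotropy test
#'
#' Per species, a one-sided Fisher exact test asks whether PSGs prefer
#' the longevity-consistent regulation direction among that species'
#' regulated genes: down-regulation with age in the long-lived species A,
#' up-regulation in the short-lived species B.  The two one-sided
#' p-values are combined with the Lancaster procedure at equal weights 2
#' (i.e. Fisher's method).
#'
#' @inheritParams classify_quadrants
#' @return List with the per-species p-values \code{p_a}, \code{p_b} and
#'   the combined \code{p_value}.
#' @export
directionality_test <- function(de_a, de_b, psgs) {
  one_sided <- function(de, downward) {
    reg <- de[de$regulated & de$lfc != 0, , drop = FALSE]
    if (!nrow(reg)) return(1)
    consistent <- if (downward) reg$lfc < 0 else reg$lfc > 0
    is_psg <- reg$gene %in% psgs
    if (!any(is_psg) || !any(consistent) || all(consistent)) return(1)
    x <- sum(is_psg & consistent)
    phyper(x - 1, sum(consistent), sum(!consistent), sum(is_psg),
           lower.tail = FALSE)
  }
  p_a <- one_sided(de_a, downward = TRUE)
  p_b <- one_sided(de_b, downward = FALSE)
  list(p_a = p_a, p_b = p_b,
       p_value = lancaster_combine(c(p_a, p_b), c(2, 2)))
}
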