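# Negative-binomial differential expression between day 7 and day 42:
# median-of-ratios normalization, method-of-moments dispersion with trend
# shrinkage, an exact conditional test on group sums, and BH adjustment.

#' Median-of-ratios size factors
#'
#' Per-sample scale factors: the median, over features, of the ratio of each
#' sample's count to the per-feature geometric mean. Features containing any
#' zero are excluded from the median. No pseudo-reference fallback is
#' applied: if no feature has all-positive counts, this fails loudly.
#'
#' @param counts integer matrix, features x samples.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  loggeo <- rowMeans(log(counts))
  ok <- is.finite(loggeo)
  if (!any(ok))
    stop("no feature with all-positive counts; cannot compute size factors ",
         "(pseudo-reference fallback is deliberately not applied)")
  sf <- apply(counts, 2, function(col) {
    exp(stats::median(log(col[ok]) - loggeo[ok]))
  })
  names(sf) <- colnames(counts)
  sf
}

#' Method-of-moments NB dispersion with trend shrinkage
#'
#' Per feature, on normalized counts: `alpha_raw = max(0, (s2 - m) / m^2)`
#' where `m` is the grand mean and `s2` the df-weighted pooled
#' within-condition variance (conditions with a single sample contribute no
#' degrees of freedom). Raw estimates are shrunk toward a trend (lowess of
#' alpha on log mean across features of similar abundance) with
#' empirical-Bayes weight `df / (df + prior_df)`: with few residual degrees
#' of freedom the per-feature moment estimate is nearly uninformative and
#' the trend dominates, which keeps the downstream exact test calibrated.
#'
#' @param norm_counts normalized count matrix, features x samples.
#' @param condition character vector, one condition label per sample.
#' @param prior_df prior degrees of freedom governing shrinkage strength.
#' @return per-feature dispersion alpha >= 0.
#' @export
estimate_dispersion <- function(norm_counts, condition, prior_df = 10) {
  norm_counts <- as.matrix(norm_counts)
  if (length(condition) != ncol(norm_counts))
    stop("condition must have one entry per sample")
  tab <- table(condition)
  if (!any(tab >= 2))
    stop("cannot estimate dispersion: no condition has >= 2 samples")
  m <- rowMeans(norm_counts)
  ss <- 0; df <- 0
  for (cond in names(tab)) {
    idx <- which(condition == cond)
    if (length(idx) >= 2) {
      sub <- norm_counts[, idx, drop = FALSE]
      ss <- ss + rowSums((sub - rowMeans(sub))^2)
      df <- df + length(idx) - 1
    }
  }
  s2 <- ss / df
  alpha_raw <- ifelse(m > 0, pmax(0, (s2 - m) / m^2), 0)

  n <- length(alpha_raw)
  x <- log(m + 1)
  if (n >= 10 && stats::var(x) > 0) {
    lo <- stats::lowess(x, alpha_raw, f = 2 / 3, iter = 0)
    trend <- stats::approx(lo$x, lo$y, xout = x, rule = 2, ties = mean)$y
  } else {
    trend <- rep(mean(alpha_raw), n)
  }
  w <- df / (df + prior_df)
  alpha <- pmax(0, w * alpha_raw + (1 - w) * trend)
  names(alpha) <- rownames(norm_counts)
  alpha
}

#' Exact conditional NB test on group sums
#'
#' Conditions on the total of the two group sums. Group sums of normalized
#' counts are rounded to integer pseudo-counts; the sum of n i.i.d.
#' NB(mu, size = 1/alpha) variables is NB(n*mu, size = n/alpha), and under a
#' shared mean the conditional law of one group sum given the total is free
#' of mu. The two-sided p-value is the sum of the probabilities of all
#' partitions no more likely than the observed one (ties included). At
#' alpha = 0 this reduces to the conditional binomial.
#'
#' @param counts_a,counts_b normalized count vectors for the two groups
#'   (one value per replicate).
#' @param alpha NB dispersion (scalar, >= 0).
#' @return two-sided p-value.
#' @export
nb_exact_test <- function(counts_a, counts_b, alpha = 0) {
  if (length(counts_a) == 0 || length(counts_b) == 0)
    stop("both groups must be non-empty")
  if (alpha < 0) stop("alpha must be >= 0")
  n_a <- length(counts_a); n_b <- length(counts_b)
  a <- round(sum(counts_a)); b <- round(sum(counts_b))
  total <- a + b
  if (total == 0) {
    warning("total count is zero; p = 1")
    return(1)
  }
  x <- 0:total
  if (alpha == 0) {
    logp <- stats::dbinom(x, total, n_a / (n_a + n_b), log = TRUE)
  } else {
    # shared prob parameter cancels in the conditional law; any value works
    p0 <- 0.5
    logp <- stats::dnbinom(x, size = n_a / alpha, prob = p0, log = TRUE) +
      stats::dnbinom(total - x, size = n_b / alpha, prob = p0, log = TRUE)
    logp <- logp - logsumexp(logp)
  }
  obs <- logp[a + 1]
  keep <- logp <= obs + 1e-7
  min(1, sum(exp(logp[keep])))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted p-values (same order), capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Screening profile for an assay
#'
#' circRNA: p-only screen at raw p < 0.05 (no fold-change floor).
#' miRNA: fold-change cutoff 1.5 and raw p < 0.05. mRNA and lncRNA use the
#' same screen as miRNA (their published thresholds come from a prior study
#' and are not restated).
#'
#' @param assay one of "circrna", "mirna", "mrna", "lncrna".
#' @return list(fc_cutoff, p_cutoff, use_adjusted).
#' @export
de_profile <- function(assay = c("circrna", "mirna", "mrna", "lncrna")) {
  assay <- match.arg(assay)
  fc <- if (assay == "circrna") 1 else 1.5
  list(fc_cutoff = fc, p_cutoff = 0.05, use_adjusted = FALSE)
}

#' Direction calls from fold changes and p-values
#'
#' direction = up if log2fc >= log2(fc_cutoff) and p < p_cutoff; down if
#' log2fc <= -log2(fc_cutoff) and p < p_cutoff; otherwise ns. With
#' fc_cutoff = 1 the sign of log2fc decides (log2fc = 0 exactly is ns).
#'
#' @param records data.frame with columns log2fc, p_raw, p_adj.
#' @param fc_cutoff linear fold-change cutoff >= 1.
#' @param p_cutoff p-value cutoff.
#' @param use_adjusted call on p_adj instead of p_raw.
#' @return records with a `direction` column added.
#' @export
call_de <- function(records, fc_cutoff = 1, p_cutoff = 0.05,
                    use_adjusted = FALSE) {
  if (fc_cutoff < 1) stop("fc_cutoff must be >= 1")
  p <- if (use_adjusted) records$p_adj else records$p_raw
  lt <- log2(fc_cutoff)
  up <- p < p_cutoff & records$log2fc >= lt & records$log2fc > 0
  dn <- p < p_cutoff & records$log2fc <= -lt & records$log2fc < 0
  records$direction <- ifelse(up, "up", ifelse(dn, "down", "ns"))
  records
}

#' Differential expression between day 7 and day 42
#'
#' Drops all-zero features, computes median-of-ratios size factors,
#' method-of-moments dispersion, the exact conditional NB test per feature,
#' BH adjustment, and direction calls at the assay's screening profile.
#' log2 fold changes are log2 of the (pseudo-counted) normalized day42/day7
#' group means.
#'
#' @param counts integer count matrix, features x samples.
#' @param design data.frame with columns sample, condition; conditions must
#'   be day7 and day42 (day7 is the baseline).
#' @param profile a [de_profile()] list (or an assay name).
#' @return data.frame(feature, log2fc, p_raw, p_adj, direction).
#' @export
de_analysis <- function(counts, design, profile = "mrna") {
  if (is.character(profile)) profile <- de_profile(profile)
  counts <- as.matrix(counts)
  samples <- colnames(counts)
  if (!all(samples %in% design$sample))
    stop("every sample in the count matrix must appear in the design")
  condition <- design$condition[match(samples, design$sample)]
  if (!all(c("day7", "day42") %in% condition))
    stop("both conditions (day7, day42) must be present")

  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  alpha <- estimate_dispersion(norm, condition)

  ia <- which(condition == "day7"); ib <- which(condition == "day42")
  mean_a <- rowMeans(norm[, ia, drop = FALSE])
  mean_b <- rowMeans(norm[, ib, drop = FALSE])
  log2fc <- log2((mean_b + 0.5) / (mean_a + 0.5))
  p_raw <- vapply(seq_len(nrow(norm)), function(f) {
    suppressWarnings(nb_exact_test(norm[f, ia], norm[f, ib], alpha[f]))
  }, numeric(1))
  res <- data.frame(feature = rownames(counts), log2fc = log2fc,
                    p_raw = p_raw, p_adj = bh_adjust(p_raw),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  call_de(res, profile$fc_cutoff, profile$p_cutoff, profile$use_adjusted)
}
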