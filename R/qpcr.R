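# qPCR relative quantification by the 2^-ddCt method against the rp49
# reference gene and the day-7 calibrator group, Welch t-tests between
# conditions, and direction-concordance calls against RNA-seq.

#' Relative quantification by 2^-ddCt
#'
#' Per sample and gene: dCt = Ct_gene - Ct_reference; ddCt = dCt minus the
#' mean dCt over calibrator-condition replicates of that gene;
#' RQ = 2^-ddCt. Amplification efficiency is fixed at 2.
#'
#' @param ct data.frame(sample, condition, gene, ct); the reference gene
#'   must be measured in every sample.
#' @param reference_gene reference (housekeeping) gene id.
#' @param calibrator calibrator condition (ddCt = 0 there on average).
#' @return data.frame(gene, sample, condition, dct, ddct, rq).
#' @export
delta_delta_ct <- function(ct, reference_gene = "rp49", calibrator = "day7") {
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  if (!calibrator %in% ct$condition)
    stop("calibrator condition '", calibrator, "' not present")
  ref <- ct[ct$gene == reference_gene, , drop = FALSE]
  missing_ref <- setdiff(unique(ct$sample), ref$sample)
  if (length(missing_ref) > 0)
    stop("reference gene '", reference_gene, "' missing in sample(s): ",
         paste(missing_ref, collapse = ", "))
  ref_ct <- stats::setNames(ref$ct, ref$sample)

  targ <- ct  # reference rows kept: they self-normalize to RQ = 1
  targ$dct <- targ$ct - ref_ct[targ$sample]
  out <- do.call(rbind, lapply(split(targ, targ$gene), function(g) {
    cal_mean <- mean(g$dct[g$condition == calibrator])
    g$ddct <- g$dct - cal_mean
    g$rq <- 2^(-g$ddct)
    g
  }))
  out <- out[, c("gene", "sample", "condition", "dct", "ddct", "rq")]
  out <- out[order(out$gene, out$condition, out$sample), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene group comparison of ddCt values
#'
#' Two-sided Welch (unequal-variance) t-test on ddCt values between the two
#' conditions, with significance stars: "*" for 0.01 <= p < 0.05, "**" for
#' p < 0.01.
#'
#' @param rq a [delta_delta_ct()] table.
#' @param conditions the two condition labels to compare.
#' @return data.frame(gene, mean_log2_rq, p, stars); `mean_log2_rq` is the
#'   mean of -ddCt in the non-calibrator (second) condition.
#' @export
group_test <- function(rq, conditions = c("day7", "day42")) {
  out <- do.call(rbind, lapply(split(rq, rq$gene), function(g) {
    x <- g$ddct[g$condition == conditions[1]]
    y <- g$ddct[g$condition == conditions[2]]
    if (length(x) < 2 || length(y) < 2)
      stop("gene ", g$gene[1], ": need >= 2 replicates per group")
    p <- if (stats::sd(c(x, y)) == 0) 1 else {
      tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1)
    }
    data.frame(gene = g$gene[1], mean_log2_rq = mean(-y), p = p,
               stars = if (p < 0.01) "**" else if (p < 0.05) "*" else "",
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Direction concordance between qPCR and RNA-seq
#'
#' A gene is concordant "(+)" when the sign of its mean log2 RQ in the
#' day-42 group matches its RNA-seq DE direction and both calls are
#' significant (qPCR p < 0.05 and DE direction != ns). Genes missing from
#' the DE table get NA (logged).
#'
#' @param qp a [group_test()] table.
#' @param de a DE table ([de_analysis()]) covering the assayed genes.
#' @param p_cutoff significance cutoff for the qPCR test.
#' @return `qp` with columns de_direction and concordant added.
#' @export
concordance <- function(qp, de, p_cutoff = 0.05) {
  dir <- stats::setNames(de$direction, de$feature)
  qp$de_direction <- unname(dir[qp$gene])
  missing <- qp$gene[is.na(qp$de_direction)]
  if (length(missing) > 0)
    message("gene(s) missing from DE table, concordance undefined: ",
            paste(missing, collapse = ", "))
  qpcr_dir <- ifelse(qp$mean_log2_rq > 0, "up",
                     ifelse(qp$mean_log2_rq < 0, "down", "ns"))
  qp$concordant <- ifelse(is.na(qp$de_direction), NA,
                          qp$p < p_cutoff & qp$de_direction != "ns" &
                            qpcr_dir == qp$de_direction)
  qp
}
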