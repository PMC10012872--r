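# Synthetic-data generator emulating the two-age fly study design:
# day 7 vs day 42, RNA-seq (mRNA/lncRNA/circRNA) with 2 biological
# replicates, miRNA-seq with 5, NB-distributed counts with planted fold
# changes, and planted sponge/miRNA/mRNA triples carrying real seed sites.

#' Simulation configuration
#'
#' Defaults encode the emulated study design: two conditions (day7, day42),
#' 2 biological replicates for RNA-seq and 5 for miRNA-seq, negative-binomial
#' counts with variance \eqn{\mu + \alpha \mu^2}, planted absolute log2 fold
#' change of 2 on ceRNA triple members, and full-complement planted binding
#' sites (an 8mer seed plus 3' supplementary pairing).
#'
#' @param n_mrna,n_lncrna,n_circrna,n_mirna number of features per class.
#' @param n_triples_planted number of planted (sponge, miRNA, mRNA) triples.
#' @param reps_rnaseq,reps_mirnaseq biological replicates per condition for
#'   the RNA-seq and miRNA-seq assays.
#' @param baseline_mean expected baseline (day7) count per feature.
#' @param log2fc_effect planted |log2 fold change| for triple members.
#' @param dispersion NB dispersion alpha >= 0 (variance mu + alpha*mu^2);
#'   0 gives Poisson counts.
#' @param utr_length,sponge_length,mirna_length sequence lengths (nt) for
#'   mRNA 3'UTRs, sponges (circRNA/lncRNA) and miRNAs.
#' @param sites_per_pair planted binding sites per (miRNA, target) pair.
#' @param ct_replicates qPCR biological replicates per condition.
#' @param ct_noise_sd Gaussian noise sd (cycles) on simulated Ct values.
#' @param seed RNG seed; all generators are deterministic given the config.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_mrna = 60, n_lncrna = 15, n_circrna = 15,
                       n_mirna = 20, n_triples_planted = 10,
                       reps_rnaseq = 2, reps_mirnaseq = 5,
                       baseline_mean = 500, log2fc_effect = 2.0,
                       dispersion = 0.05,
                       utr_length = 600, sponge_length = 800,
                       mirna_length = 22, sites_per_pair = 1,
                       ct_replicates = 3, ct_noise_sd = 0.2,
                       seed = 1L) {
  cfg <- list(n_mrna = as.integer(n_mrna), n_lncrna = as.integer(n_lncrna),
              n_circrna = as.integer(n_circrna), n_mirna = as.integer(n_mirna),
              n_triples_planted = as.integer(n_triples_planted),
              reps_rnaseq = as.integer(reps_rnaseq),
              reps_mirnaseq = as.integer(reps_mirnaseq),
              baseline_mean = baseline_mean, log2fc_effect = log2fc_effect,
              dispersion = dispersion,
              utr_length = as.integer(utr_length),
              sponge_length = as.integer(sponge_length),
              mirna_length = as.integer(mirna_length),
              sites_per_pair = as.integer(sites_per_pair),
              ct_replicates = as.integer(ct_replicates),
              ct_noise_sd = ct_noise_sd, seed = as.integer(seed))
  counts <- c("n_mrna", "n_lncrna", "n_circrna", "n_mirna", "reps_rnaseq",
              "reps_mirnaseq", "utr_length", "sponge_length", "mirna_length",
              "sites_per_pair", "ct_replicates")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop(sprintf("config field '%s' must be a count >= 1", f))
  }
  if (cfg$n_triples_planted < 0L)
    stop("n_triples_planted must be >= 0")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  if (cfg$ct_noise_sd < 0) stop("ct_noise_sd must be >= 0")
  if (cfg$baseline_mean <= 0) stop("baseline_mean must be positive")
  lim <- min(cfg$n_circrna + cfg$n_lncrna, cfg$n_mirna, cfg$n_mrna)
  if (cfg$n_triples_planted > lim)
    stop(sprintf("n_triples_planted (%d) exceeds min(sponges, miRNAs, mRNAs) = %d",
                 cfg$n_triples_planted, lim))
  if (cfg$mirna_length < 19L)
    stop("mirna_length must be >= 19")
  # a planted site spans the full miRNA length on the target
  if (cfg$mirna_length * cfg$sites_per_pair > min(cfg$utr_length, cfg$sponge_length))
    stop("planted sites do not fit in the target sequences; increase target length")
  class(cfg) <- "sim_config"
  cfg
}

#' Sample design table for the simulated study
#'
#' @param config a [sim_config()].
#' @return data.frame with columns sample, condition (day7/day42), assay
#'   (rnaseq/mirnaseq), replicate.
#' @export
sim_design <- function(config) {
  mk <- function(assay, reps, prefix) {
    do.call(rbind, lapply(c("day7", "day42"), function(cond) {
      data.frame(sample = sprintf("%s_%s_r%d", prefix, sub("day", "d", cond),
                                  seq_len(reps)),
                 condition = cond, assay = assay,
                 replicate = seq_len(reps), stringsAsFactors = FALSE)
    }))
  }
  rbind(mk("rnaseq", config$reps_rnaseq, "rna"),
        mk("mirnaseq", config$reps_mirnaseq, "mir"))
}

#' Generate synthetic sequences with planted miRNA binding sites
#'
#' Background composition is i.i.d. uniform A/C/G/U. For every planted
#' (miRNA, target) pair the target carries, at a recorded position, a
#' full-complement site: the reverse complement of miRNA positions 2..L
#' followed by an A opposite miRNA position 1. The recorded ground-truth
#' coordinates are the 8mer seed span (reverse complement of positions 2-8
#' plus the A anchor), which is what the site scanner reports.
#'
#' Planted triples split half (up, down, up) and half (down, up, down) so
#' both admissible ceRNA sign patterns are exercised; sponges alternate
#' between circRNA and lncRNA.
#'
#' @param config a [sim_config()].
#' @return list with `sequences` (named character vectors: mirna, mrna,
#'   lncrna, circrna), `truth` (planted_triples, planted_sites, true_log2fc)
#'   and `config`.
#' @export
simulate_sequences <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$mirna_length

  rand_seq <- function(n, len) {
    vapply(seq_len(n), function(i) {
      paste(sample(RNA_BASES, len, replace = TRUE), collapse = "")
    }, character(1))
  }
  mirna <- rand_seq(config$n_mirna, L)
  names(mirna) <- sprintf("sim-miR-%03d", seq_len(config$n_mirna))
  mrna <- rand_seq(config$n_mrna, config$utr_length)
  names(mrna) <- sprintf("gene%03d", seq_len(config$n_mrna))
  lncrna <- rand_seq(config$n_lncrna, config$sponge_length)
  names(lncrna) <- sprintf("XLOC_%06d", 100000L + seq_len(config$n_lncrna))
  circrna <- rand_seq(config$n_circrna, config$sponge_length)
  names(circrna) <- sprintf("sim_circ_%07d", seq_len(config$n_circrna))

  nt <- config$n_triples_planted
  planted_triples <- data.frame(sponge = character(0), sponge_class = character(0),
                                mirna = character(0), mrna = character(0),
                                dir_sponge = character(0), dir_mirna = character(0),
                                dir_mrna = character(0), stringsAsFactors = FALSE)
  planted_sites <- data.frame(mirna = character(0), target = character(0),
                              target_class = character(0), start = integer(0),
                              end = integer(0), seed_class = character(0),
                              stringsAsFactors = FALSE)
  all_feats <- c(names(mrna), names(lncrna), names(circrna), names(mirna))
  true_log2fc <- stats::setNames(rep(0, length(all_feats)), all_feats)

  if (nt > 0) {
    # alternate sponge classes; sample members without replacement
    ci <- sample(names(circrna)); li <- sample(names(lncrna))
    sponge_pool <- character(nt)
    i_c <- 1L; i_l <- 1L
    for (i in seq_len(nt)) {
      use_circ <- (i %% 2 == 1L && i_c <= length(ci)) || i_l > length(li)
      if (use_circ) {
        sponge_pool[i] <- ci[i_c]; i_c <- i_c + 1L
      } else {
        sponge_pool[i] <- li[i_l]; i_l <- i_l + 1L
      }
    }
    t_mirna <- sample(names(mirna), nt)
    t_mrna <- sample(names(mrna), nt)
    n_up <- ceiling(nt / 2)
    dir_sponge <- rep(c("up", "down"), c(n_up, nt - n_up))
    dir_mirna <- ifelse(dir_sponge == "up", "down", "up")
    planted_triples <- data.frame(
      sponge = sponge_pool,
      sponge_class = ifelse(sponge_pool %in% names(circrna), "circRNA", "lncRNA"),
      mirna = t_mirna, mrna = t_mrna,
      dir_sponge = dir_sponge, dir_mirna = dir_mirna, dir_mrna = dir_sponge,
      stringsAsFactors = FALSE)

    eff <- config$log2fc_effect
    sgn <- function(d) ifelse(d == "up", eff, -eff)
    true_log2fc[planted_triples$sponge] <- sgn(planted_triples$dir_sponge)
    true_log2fc[planted_triples$mirna] <- sgn(planted_triples$dir_mirna)
    true_log2fc[planted_triples$mrna] <- sgn(planted_triples$dir_mrna)

    # plant full-complement sites (8mer seed + 3' supplementary pairing)
    plant <- function(target_seq, mir_seq, n_sites) {
      tl <- nchar(target_seq)
      site <- paste0(rna_revcomp(substr(mir_seq, 2, L)), "A")
      taken <- integer(0)
      starts <- integer(0)
      attempts <- 0
      while (length(starts) < n_sites && attempts < 1000) {
        attempts <- attempts + 1
        s <- sample.int(tl - L + 1, 1)
        if (!any(abs(s - taken) < L)) {
          taken <- c(taken, s)
          starts <- c(starts, s)
          substr(target_seq, s, s + L - 1) <- site
        }
      }
      if (length(starts) < n_sites)
        stop("could not place non-overlapping planted sites; target too short")
      list(seq = target_seq, starts = sort(starts))
    }

    for (i in seq_len(nt)) {
      tri <- planted_triples[i, ]
      mir_seq <- mirna[[tri$mirna]]
      for (side in c("sponge", "mrna")) {
        id <- tri[[side]]
        cls <- if (side == "mrna") "mRNA_3UTR" else tri$sponge_class
        pool <- if (cls == "mRNA_3UTR") "mrna" else if (cls == "circRNA") "circrna" else "lncrna"
        res <- plant(get(pool)[[id]], mir_seq, config$sites_per_pair)
        if (pool == "mrna") mrna[[id]] <- res$seq
        if (pool == "circrna") circrna[[id]] <- res$seq
        if (pool == "lncrna") lncrna[[id]] <- res$seq
        planted_sites <- rbind(planted_sites, data.frame(
          mirna = tri$mirna, target = id, target_class = cls,
          start = res$starts + L - 8L, end = res$starts + L - 1L,
          seed_class = "8mer", stringsAsFactors = FALSE))
      }
    }
  }

  list(sequences = list(mirna = mirna, mrna = mrna,
                        lncrna = lncrna, circrna = circrna),
       truth = list(planted_triples = planted_triples,
                    planted_sites = planted_sites,
                    true_log2fc = true_log2fc),
       config = config)
}

#' Simulate NB count matrices for each assay
#'
#' Counts are drawn NB(mu, alpha) with variance \eqn{\mu + \alpha\mu^2};
#' log2(mu_day42 / mu_day7) equals the planted log2 fold change. Per-sample
#' library-size factors are drawn log-uniform in [0.7, 1.4] so that
#' normalization is non-trivial. Deterministic given (truth, config).
#'
#' @param truth the `truth` element of [simulate_sequences()] output (or the
#'   whole output list).
#' @param config the matching [sim_config()].
#' @return list of per-class count matrices (`mrna`, `lncrna`, `circrna`,
#'   `mirna`; features x samples), plus `design` (see [sim_design()]) and
#'   `size_factors_true` (named per-sample).
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(truth$truth)) truth <- truth$truth
  set.seed(config$seed + 1L)
  design <- sim_design(config)
  sf <- exp(stats::runif(nrow(design), log(0.7), log(1.4)))
  names(sf) <- design$sample

  lfc <- truth$true_log2fc
  draw <- function(ids, samples) {
    m <- matrix(0L, nrow = length(ids), ncol = length(samples),
                dimnames = list(ids, samples))
    cond <- design$condition[match(samples, design$sample)]
    for (j in seq_along(samples)) {
      mu <- config$baseline_mean * 2^(lfc[ids] * (cond[j] == "day42")) *
        sf[samples[j]]
      m[, j] <- if (config$dispersion == 0) {
        stats::rpois(length(ids), mu)
      } else {
        stats::rnbinom(length(ids), size = 1 / config$dispersion, mu = mu)
      }
    }
    m
  }
  rna_samples <- design$sample[design$assay == "rnaseq"]
  mir_samples <- design$sample[design$assay == "mirnaseq"]
  ids_of <- function(prefix_regex) {
    grep(prefix_regex, names(lfc), value = TRUE)
  }
  list(mrna = draw(ids_of("^gene"), rna_samples),
       lncrna = draw(ids_of("^XLOC_"), rna_samples),
       circrna = draw(ids_of("^sim_circ_"), rna_samples),
       mirna = draw(ids_of("^sim-miR-"), mir_samples),
       design = design, size_factors_true = sf)
}

#' Simulate a qPCR Ct table
#'
#' Ct = Ct_ref + dCt_true + Gaussian noise, with the reference gene rp49
#' measured in every sample; the between-condition ddCt equals the planted
#' -log2fc in expectation, so downstream relative quantities recover
#' 2^(log2fc).
#'
#' @param truth as in [simulate_counts()].
#' @param config the matching [sim_config()].
#' @param genes genes to assay; default: all planted triple members.
#' @return data.frame(sample, condition, gene, ct) including rp49 rows.
#' @export
simulate_ct <- function(truth, config, genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(truth$truth)) truth <- truth$truth
  set.seed(config$seed + 2L)
  if (is.null(genes)) {
    tri <- truth$planted_triples
    genes <- unique(c(tri$sponge, tri$mirna, tri$mrna))
  }
  if (length(genes) == 0)
    stop("no genes to assay: no planted triples and none supplied")
  lfc <- truth$true_log2fc[genes]
  lfc[is.na(lfc)] <- 0
  conds <- rep(c("day7", "day42"), each = config$ct_replicates)
  samples <- sprintf("qpcr_%s_r%d", sub("day", "d", conds),
                     rep(seq_len(config$ct_replicates), 2))
  base_dct <- stats::setNames(stats::runif(length(genes), 2, 8), genes)
  rows <- vector("list", length(samples))
  for (j in seq_along(samples)) {
    ct_ref <- 20 + stats::rnorm(1, 0, config$ct_noise_sd)
    dct <- base_dct - lfc * (conds[j] == "day42") +
      stats::rnorm(length(genes), 0, config$ct_noise_sd)
    rows[[j]] <- data.frame(sample = samples[j], condition = conds[j],
                            gene = c("rp49", genes),
                            ct = c(ct_ref, ct_ref + dct),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a gene -> GO annotation map for the synthetic mRNA universe
#'
#' Assigns 1-4 random GO terms per gene from a small synthetic vocabulary and
#' additionally annotates all planted-triple mRNAs with one shared term so
#' that enrichment of recovered network targets is non-trivial.
#'
#' @param truth as in [simulate_counts()].
#' @param config the matching [sim_config()].
#' @param n_terms size of the synthetic GO vocabulary.
#' @return data.frame(gene, go_id, term, namespace).
#' @export
simulate_go_map <- function(truth, config, n_terms = 15) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(truth$truth)) truth <- truth$truth
  set.seed(config$seed + 3L)
  genes <- grep("^gene", names(truth$true_log2fc), value = TRUE)
  terms <- data.frame(
    go_id = sprintf("GO:%07d", seq_len(n_terms)),
    term = sprintf("synthetic process %d", seq_len(n_terms)),
    namespace = sample(c("BP", "CC", "MF"), n_terms, replace = TRUE,
                       prob = c(0.6, 0.2, 0.2)),
    stringsAsFactors = FALSE)
  rows <- lapply(genes, function(g) {
    k <- sample(1:4, 1)
    idx <- sample.int(n_terms, k)
    cbind(data.frame(gene = g, stringsAsFactors = FALSE), terms[idx, ])
  })
  out <- do.call(rbind, rows)
  planted <- unique(truth$planted_triples$mrna)
  if (length(planted) > 0) {
    extra_id <- sprintf("GO:%07d", n_terms + 1L)
    out <- rbind(out, data.frame(gene = planted, go_id = extra_id,
                                 term = "planted network process",
                                 namespace = "BP", stringsAsFactors = FALSE))
  }
  out <- unique(out)
  rownames(out) <- NULL
  out
}
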