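# End-to-end pipeline driver: simulate -> differential expression ->
# binding sites -> ceRNA network -> GO enrichment -> qPCR concordance,
# with a machine-readable manifest. Deterministic given (config, seed).

#' Run the full synthetic ceRNA pipeline
#'
#' Executes all six stages on synthetic data and writes every intermediate
#' as a plain-text artifact (FASTA, TSV, JSON) under `out_dir`, plus a
#' manifest (seed, package version, per-stage row counts). Rerunning with
#' the same config into a fresh directory is byte-identical.
#'
#' Binding sites are scanned for DE features only; triples require all
#' members DE, so restricting the scan does not change the network.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param apply_mechanism apply the ceRNA sign-consistency filter to the
#'   exported network (the unfiltered triple table is always written too).
#' @param min_score,max_energy site-prediction thresholds.
#' @return (invisibly) list with all in-memory stage results and the
#'   manifest.
#' @export
run_all <- function(config = sim_config(), out_dir,
                    apply_mechanism = TRUE,
                    min_score = 140, max_energy = -10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name) message("[", name, "] ...")
  manifest <- list(package = "ceRNAfly",
                   version = as.character(utils::packageVersion("ceRNAfly")),
                   seed = config$seed, stages = list())

  # -- simulate ------------------------------------------------------------
  stage("simulate")
  sim <- simulate_sequences(config)
  cm <- simulate_counts(sim$truth, config)
  ct <- simulate_ct(sim$truth, config)
  gomap <- simulate_go_map(sim$truth, config)
  for (cls in c("mirna", "mrna", "lncrna", "circrna")) {
    write_fasta(sim$sequences[[cls]], file.path(out_dir, paste0(cls, ".fa")))
    utils::write.table(
      data.frame(feature = rownames(cm[[cls]]), cm[[cls]],
                 check.names = FALSE),
      file.path(out_dir, paste0("counts_", cls, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  }
  write_tsv(cm$design, file.path(out_dir, "design.tsv"))
  write_tsv(ct, file.path(out_dir, "ct.tsv"))
  write_tsv(gomap, file.path(out_dir, "go_map.tsv"))
  jsonlite::write_json(sim$truth[c("planted_triples", "planted_sites")],
                       file.path(out_dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA)
  manifest$stages$simulate <- list(
    n_features = length(sim$truth$true_log2fc),
    n_planted_triples = nrow(sim$truth$planted_triples),
    n_planted_sites = nrow(sim$truth$planted_sites))

  # -- differential expression --------------------------------------------
  stage("de")
  de_tables <- list()
  for (cls in c("mrna", "lncrna", "circrna", "mirna")) {
    de_tables[[cls]] <- de_analysis(cm[[cls]], cm$design, de_profile(cls))
    write_tsv(de_tables[[cls]], file.path(out_dir, paste0("de_", cls, ".tsv")))
  }
  manifest$stages$de <- lapply(de_tables, function(t) {
    list(n_tested = nrow(t), n_de = sum(t$direction != "ns"))
  })

  # -- binding sites (DE features only) ------------------------------------
  stage("sites")
  de_feats <- function(cls) {
    t <- de_tables[[cls]]; t$feature[t$direction != "ns"]
  }
  mir_de <- sim$sequences$mirna[intersect(names(sim$sequences$mirna),
                                          de_feats("mirna"))]
  scan <- function(cls, label) {
    tg <- sim$sequences[[cls]][intersect(names(sim$sequences[[cls]]),
                                         de_feats(cls))]
    if (length(tg) == 0 || length(mir_de) == 0) {
      return(suppressWarnings(
        predict_targets(character(0), character(0), label)))
    }
    predict_targets(mir_de, tg, label, min_score = min_score,
                    max_energy = max_energy)
  }
  sites <- rbind(scan("circrna", "circRNA"),
                 scan("lncrna", "lncRNA"),
                 scan("mrna", "mRNA_3UTR"))
  write_tsv(sites, file.path(out_dir, "sites.tsv"))
  manifest$stages$sites <- list(n_sites = nrow(sites))

  # -- network -------------------------------------------------------------
  stage("net")
  triples <- find_triples(sites, de_tables)
  write_tsv(triples, file.path(out_dir, "triples_unfiltered.tsv"))
  filtered <- mechanism_filter(triples)
  final_triples <- if (apply_mechanism) filtered else triples
  write_tsv(filtered, file.path(out_dir, "triples.tsv"))
  net <- export_network(final_triples)
  write_tsv(net$edges, file.path(out_dir, "network_edges.tsv"))
  write_tsv(net$nodes, file.path(out_dir, "network_nodes.tsv"))
  manifest$stages$net <- list(n_triples_unfiltered = nrow(triples),
                              n_triples_mechanism = nrow(filtered),
                              n_edges = nrow(net$edges),
                              n_nodes = nrow(net$nodes))

  # -- enrichment ----------------------------------------------------------
  stage("enrich")
  query <- unique(triples$mrna)
  enr <- if (length(query) > 0) {
    top_terms(hypergeom_enrich(query, gomap), n_top = 30)
  } else {
    data.frame(go_id = character(0), term = character(0),
               namespace = character(0), k = integer(0), n = integer(0),
               K = integer(0), N = integer(0), p_raw = numeric(0),
               p_adj = numeric(0), stringsAsFactors = FALSE)
  }
  write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
  manifest$stages$enrich <- list(n_query = length(query),
                                 n_terms = nrow(enr))

  # -- qPCR ----------------------------------------------------------------
  stage("qpcr")
  rq <- delta_delta_ct(ct)
  qp <- group_test(rq)
  de_all <- do.call(rbind, de_tables)
  qp <- concordance(qp[qp$gene != "rp49", , drop = FALSE], de_all)
  write_tsv(rq, file.path(out_dir, "rq.tsv"))
  write_tsv(qp, file.path(out_dir, "qpcr_concordance.tsv"))
  manifest$stages$qpcr <- list(n_genes = nrow(qp),
                               n_concordant = sum(qp$concordant, na.rm = TRUE))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sim = sim, counts = cm, de = de_tables, sites = sites,
                 triples = triples, triples_mechanism = filtered,
                 network = net, enrichment = enr, rq = rq,
                 qpcr = qp, manifest = manifest))
}

#' Precision and recall of planted-triple recovery
#'
#' Runs the full pipeline in memory (no file output) and compares the
#' mechanism-filtered triple set against the planted ground truth.
#'
#' @param config a [sim_config()].
#' @param min_score,max_energy site-prediction thresholds.
#' @return list(precision, recall, n_recovered, n_planted).
#' @export
recover_triples <- function(config = sim_config(),
                            min_score = 140, max_energy = -10) {
  sim <- simulate_sequences(config)
  cm <- simulate_counts(sim$truth, config)
  de_tables <- lapply(stats::setNames(nm = c("mrna", "lncrna", "circrna", "mirna")),
                      function(cls) de_analysis(cm[[cls]], cm$design,
                                                de_profile(cls)))
  de_feats <- function(cls) {
    t <- de_tables[[cls]]; t$feature[t$direction != "ns"]
  }
  mir_de <- sim$sequences$mirna[intersect(names(sim$sequences$mirna),
                                          de_feats("mirna"))]
  scan <- function(cls, label) {
    tg <- sim$sequences[[cls]][intersect(names(sim$sequences[[cls]]),
                                         de_feats(cls))]
    if (length(tg) == 0 || length(mir_de) == 0)
      return(suppressWarnings(predict_targets(character(0), character(0), label)))
    predict_targets(mir_de, tg, label, min_score = min_score,
                    max_energy = max_energy)
  }
  sites <- rbind(scan("circrna", "circRNA"), scan("lncrna", "lncRNA"),
                 scan("mrna", "mRNA_3UTR"))
  found <- mechanism_filter(find_triples(sites, de_tables))
  key <- function(t) paste(t$sponge, t$mirna, t$mrna, sep = "|")
  truth_keys <- key(sim$truth$planted_triples)
  found_keys <- key(found)
  tp <- length(intersect(found_keys, truth_keys))
  list(precision = if (length(found_keys) == 0) NA_real_ else tp / length(found_keys),
       recall = if (length(truth_keys) == 0) NA_real_ else tp / length(truth_keys),
       n_recovered = length(found_keys), n_planted = length(truth_keys))
}
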