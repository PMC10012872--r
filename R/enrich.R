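# GO term enrichment of network target genes: one-sided (upper-tail)
# hypergeometric test per term with BH correction, flat annotation (no
# DAG ancestor propagation), reporting the top terms by raw p.

#' Hypergeometric GO enrichment
#'
#' For each GO term with at least one query member: p = P(X >= k) under
#' Hypergeometric(N, K, n) where N is the background size, K the number of
#' background genes carrying the term, n the query size and k the overlap.
#' Unannotated background genes count toward N. BH adjustment is applied
#' across all tested terms.
#'
#' @param query character vector of gene ids (must be within background).
#' @param gomap data.frame(gene, go_id, term, namespace); namespace in
#'   BP/CC/MF; GO ids must match "GO:" + 7 digits.
#' @param background character vector of gene ids; default: all genes in
#'   the annotation map plus the query.
#' @return data.frame(go_id, term, namespace, k, n, K, N, p_raw, p_adj),
#'   sorted by p_raw then go_id.
#' @export
hypergeom_enrich <- function(query, gomap, background = NULL) {
  query <- unique(query)
  if (length(query) == 0) stop("query gene set is empty")
  bad_ids <- unique(gomap$go_id[!grepl("^GO:[0-9]{7}$", gomap$go_id)])
  if (length(bad_ids) > 0)
    stop("malformed GO id(s): ", paste(utils::head(bad_ids, 5), collapse = ", "))
  gomap <- unique(gomap[, c("gene", "go_id", "term", "namespace")])
  if (is.null(background)) background <- union(unique(gomap$gene), query)
  background <- unique(background)
  off <- setdiff(query, background)
  if (length(off) > 0)
    stop("query gene(s) absent from background: ",
         paste(utils::head(off, 10), collapse = ", "))

  gomap <- gomap[gomap$gene %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(query)
  terms <- unique(gomap[, c("go_id", "term", "namespace")])
  res <- lapply(seq_len(nrow(terms)), function(i) {
    genes <- gomap$gene[gomap$go_id == terms$go_id[i]]
    K <- length(genes)
    k <- length(intersect(genes, query))
    if (k == 0) return(NULL)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(go_id = terms$go_id[i], term = terms$term[i],
               namespace = terms$namespace[i], k = k, n = n, K = K, N = N,
               p_raw = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    return(data.frame(go_id = character(0), term = character(0),
                      namespace = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p_raw = numeric(0),
                      p_adj = numeric(0), stringsAsFactors = FALSE))
  res$p_adj <- bh_adjust(res$p_raw)
  res <- res[order(res$p_raw, res$go_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Top enriched terms by lowest p
#'
#' @param results a [hypergeom_enrich()] table.
#' @param n_top number of terms to keep (fewer returned if fewer exist).
#' @param by ranking column (default raw p); ties broken by GO id.
#' @return ranked subset of `results`.
#' @export
top_terms <- function(results, n_top = 30, by = "p_raw") {
  if (nrow(results) == 0) return(results)
  ord <- order(results[[by]], results$go_id)
  out <- results[ord[seq_len(min(n_top, nrow(results)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}
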