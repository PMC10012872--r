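# ceRNA triple construction: a sponge (circRNA or lncRNA) and an mRNA that
# share predicted binding sites for the same DE miRNA, plus the
# sign-consistency ("ceRNA mechanism") filter.

#' Build candidate ceRNA triples from binding sites and DE tables
#'
#' One triple per (sponge, miRNA, mRNA) combination with at least one
#' predicted site on each side and all three members differentially
#' expressed (direction != ns). Directions are taken from the DE tables.
#'
#' @param sites a [predict_targets()] table covering sponge-class targets
#'   (circRNA and/or lncRNA) and mRNA 3'UTR targets.
#' @param de_tables named list of DE tables (see [de_analysis()]); must
#'   contain `mirna`, `mrna`, and `circrna` and/or `lncrna`.
#' @return data.frame(sponge, sponge_class, mirna, mrna, dir_sponge,
#'   dir_mirna, dir_mrna, n_sites_sponge, n_sites_mrna), sorted by
#'   (sponge, mirna, mrna).
#' @export
find_triples <- function(sites, de_tables) {
  sponge_classes <- intersect(c("circrna", "lncrna"),
                              tolower(unique(sites$target_class)))
  needed <- c("mirna", "mrna", sponge_classes)
  missing <- setdiff(needed, names(de_tables))
  if (length(missing) > 0)
    stop("missing DE table(s) for assay: ", paste(missing, collapse = ", "))

  de_dir <- function(assay) {
    tab <- de_tables[[assay]]
    keep <- tab$direction != "ns"
    stats::setNames(tab$direction[keep], tab$feature[keep])
  }
  dir_mirna <- de_dir("mirna")
  dir_mrna <- de_dir("mrna")
  dir_sponge <- c(if ("circrna" %in% names(de_tables)) de_dir("circrna"),
                  if ("lncrna" %in% names(de_tables)) de_dir("lncrna"))

  empty <- data.frame(sponge = character(0), sponge_class = character(0),
                      mirna = character(0), mrna = character(0),
                      dir_sponge = character(0), dir_mirna = character(0),
                      dir_mrna = character(0), n_sites_sponge = integer(0),
                      n_sites_mrna = integer(0), stringsAsFactors = FALSE)
  if (nrow(sites) == 0) return(empty)

  sp <- sites[sites$target_class %in% c("circRNA", "lncRNA") &
                sites$target %in% names(dir_sponge) &
                sites$mirna %in% names(dir_mirna), , drop = FALSE]
  mr <- sites[sites$target_class == "mRNA_3UTR" &
                sites$target %in% names(dir_mrna) &
                sites$mirna %in% names(dir_mirna), , drop = FALSE]
  if (nrow(sp) == 0 || nrow(mr) == 0) return(empty)

  sp_agg <- stats::aggregate(list(n_sites_sponge = sp$start),
                             by = list(sponge = sp$target,
                                       sponge_class = sp$target_class,
                                       mirna = sp$mirna), FUN = length)
  mr_agg <- stats::aggregate(list(n_sites_mrna = mr$start),
                             by = list(mirna = mr$mirna, mrna = mr$target),
                             FUN = length)
  tri <- merge(sp_agg, mr_agg, by = "mirna")
  if (nrow(tri) == 0) return(empty)
  tri$dir_sponge <- unname(dir_sponge[tri$sponge])
  tri$dir_mirna <- unname(dir_mirna[tri$mirna])
  tri$dir_mrna <- unname(dir_mrna[tri$mrna])
  tri <- tri[, c("sponge", "sponge_class", "mirna", "mrna", "dir_sponge",
                 "dir_mirna", "dir_mrna", "n_sites_sponge", "n_sites_mrna")]
  tri <- tri[order(tri$sponge, tri$mirna, tri$mrna), , drop = FALSE]
  rownames(tri) <- NULL
  tri
}

#' ceRNA-mechanism sign-consistency filter
#'
#' A triple conforms to the ceRNA mechanism when the sponge and mRNA share
#' a direction and the miRNA runs opposite: of the eight possible direction
#' triplets exactly (up, down, up) and (down, up, down) pass. Triples with
#' any member at ns are rejected (reason messaged).
#'
#' @param triples a [find_triples()] table.
#' @return the conforming subset, with a `mechanism_pass` column (all TRUE
#'   in the returned rows); the input with flags is attached as
#'   attribute "all".
#' @export
mechanism_filter <- function(triples) {
  if (nrow(triples) == 0) {
    triples$mechanism_pass <- logical(0)
    return(triples)
  }
  ns <- triples$dir_sponge == "ns" | triples$dir_mirna == "ns" |
    triples$dir_mrna == "ns"
  if (any(ns))
    message(sum(ns), " triple(s) rejected: member direction is ns")
  pass <- !ns & triples$dir_sponge == triples$dir_mrna &
    triples$dir_mirna != triples$dir_sponge
  triples$mechanism_pass <- pass
  out <- triples[pass, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- triples
  out
}

#' Export a triple table as a bipartite network
#'
#' Sponge-miRNA and miRNA-mRNA edges, deduplicated, plus a node attribute
#' table (class, direction). Stable ordering.
#'
#' @param triples a triple table.
#' @return list(edges = data.frame(from, to, edge_type),
#'   nodes = data.frame(id, class, direction)).
#' @export
export_network <- function(triples) {
  if (nrow(triples) == 0) {
    return(list(edges = data.frame(from = character(0), to = character(0),
                                   edge_type = character(0),
                                   stringsAsFactors = FALSE),
                nodes = data.frame(id = character(0), class = character(0),
                                   direction = character(0),
                                   stringsAsFactors = FALSE)))
  }
  edges <- rbind(
    data.frame(from = triples$sponge, to = triples$mirna,
               edge_type = "sponge-miRNA", stringsAsFactors = FALSE),
    data.frame(from = triples$mirna, to = triples$mrna,
               edge_type = "miRNA-mRNA", stringsAsFactors = FALSE))
  edges <- unique(edges)
  edges <- edges[order(edges$edge_type, edges$from, edges$to), , drop = FALSE]
  nodes <- rbind(
    data.frame(id = triples$sponge, class = triples$sponge_class,
               direction = triples$dir_sponge, stringsAsFactors = FALSE),
    data.frame(id = triples$mirna, class = "miRNA",
               direction = triples$dir_mirna, stringsAsFactors = FALSE),
    data.frame(id = triples$mrna, class = "mRNA",
               direction = triples$dir_mrna, stringsAsFactors = FALSE))
  nodes <- unique(nodes)
  nodes <- nodes[order(nodes$class, nodes$id), , drop = FALSE]
  rownames(edges) <- NULL; rownames(nodes) <- NULL
  list(edges = edges, nodes = nodes)
}
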