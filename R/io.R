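# Shared readers/writers: FASTA (via Biostrings), the transcribed table of
# differentially expressed circRNAs, and byte-stable TSV output.

#' Read a FASTA file
#'
#' Wrapping-agnostic (Biostrings parser). Ids are the first whitespace
#' token of each header; duplicate ids, empty sequences and non-IUPAC
#' characters are rejected. Lowercase is normalized to uppercase.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(!nzchar(seqs)))
    stop("empty sequence for id(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  iupac <- "^[ACGTURYSWKMBDHVN-]+$"
  bad <- ids[!grepl(iupac, seqs)]
  if (length(bad) > 0)
    stop("non-IUPAC character(s) in record(s): ", paste(bad, collapse = ", "))
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width (nt).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' The packaged table of DE circRNAs between day 7 and day 42
#'
#' 29 records (id, optional circBase id, signed log2 fold change, p-value,
#' source gene) transcribed once from the published screen, shipped as a
#' plain-text fixture so downstream checks run offline.
#'
#' @param path override the packaged fixture (TSV with columns circ_id,
#'   circbase_id, log2fc, p_value, source_gene).
#' @return validated data.frame of class `table2`.
#' @export
table2_fixture <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table2_de_circrna.tsv",
                        package = "ceRNAfly", mustWork = TRUE)
  tab <- read_tsv(path)
  need <- c("circ_id", "log2fc", "p_value", "source_gene")
  if (!all(need %in% names(tab)))
    stop("malformed fixture: need columns ", paste(need, collapse = ", "))
  if (any(is.na(tab$log2fc)) || any(is.na(tab$p_value)) ||
      any(tab$p_value < 0 | tab$p_value > 1) || any(tab$log2fc == 0))
    stop("malformed fixture row(s): fold changes must be signed and ",
         "p-values in [0, 1]")
  class(tab) <- c("table2", class(tab))
  tab
}

#' Classify the DE circRNA table at a p-value cutoff
#'
#' @param fixture a [table2_fixture()] table.
#' @param p_cutoff raw p-value cutoff.
#' @return list(total, up, down): counts of records with p < cutoff, split
#'   by fold-change sign.
#' @export
classify_table2 <- function(fixture, p_cutoff = 0.05) {
  sig <- fixture$p_value < p_cutoff
  list(total = sum(sig),
       up = sum(sig & fixture$log2fc > 0),
       down = sum(sig & fixture$log2fc < 0))
}
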