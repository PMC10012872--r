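#' @keywords internal
"_PACKAGE"

RNA_BASES <- c("A", "C", "G", "U")

#' Reverse a character string
#' @noRd
rev_string <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Complement of an RNA string (no reversal)
#' @noRd
rna_complement <- function(x) chartr("ACGU", "UGCA", x)

#' Reverse complement of an RNA string
#' @param x character vector of RNA sequences (A/C/G/U).
#' @return character vector of reverse complements.
#' @examples
#' rna_revcomp("GGAAUGU")  # "ACAUUCC"
#' @export
rna_revcomp <- function(x) rna_complement(rev_string(x))

#' Normalize a nucleotide string to uppercase RNA
#'
#' DNA input (T) is converted to U with a warning rather than rejected.
#' @noRd
norm_rna <- function(x, what = "sequence") {
  x <- toupper(x)
  if (grepl("T", x, fixed = TRUE)) {
    warning(sprintf("%s contains T; converting to U", what), call. = FALSE)
    x <- gsub("T", "U", x, fixed = TRUE)
  }
  bad <- gsub("[ACGU]", "", x)
  if (nzchar(bad)) {
    stop(sprintf("%s contains non-RNA characters: %s", what,
                 paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")),
         call. = FALSE)
  }
  x
}

#' Write a data frame as a byte-stable TSV
#'
#' Header row, tab delimiters, no quoting, "\n" line endings.
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' log-sum-exp, numerically stable
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
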