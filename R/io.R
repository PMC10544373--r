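#' Read a feature-by-sample abundance TSV
#'
#' Expects features as rows (first column = feature ids) and one column per
#' sample, as written by [write_community()].
#'
#' @param path TSV path.
#' @return Numeric matrix with feature row names and sample column names.
#' @export
read_abundance_tsv <- function(path) {
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Read genome sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_genomes_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

write_tsv <- function(x, path, rownames = FALSE) {
  write.table(x, path, sep = "\t", quote = FALSE,
              row.names = rownames, col.names = if (rownames) NA else TRUE)
}
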