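#' TPM normalisation of a genome-by-sample count table
#'
#' Converts read counts (or mean-depth coverage) per genome per sample into
#' transcripts-per-million-style relative abundances: length-normalised rates
#' rescaled so every sample column sums to 1e6.
#'
#' @param counts numeric matrix, genomes (rows) x samples (columns),
#'   non-negative. Row names are genome ids.
#' @param lengths named numeric vector of genome lengths in bp; must cover
#'   every genome with a nonzero count. Ignored (may be `NULL`) when
#'   `measure = "coverage"`, where values are already per-base rates.
#' @param measure `"counts"` (default; numerator is count/length) or
#'   `"coverage"` (numerator is the value itself, e.g. mean depth).
#' @return Numeric matrix of the same shape with attribute `level = "genome"`;
#'   each sample column sums to 1e6 (all-zero samples stay all-zero, with a
#'   warning).
#' @export
tpm_normalize <- function(counts, lengths = NULL,
                          measure = c("counts", "coverage")) {
  measure <- match.arg(measure)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (measure == "counts") {
    if (is.null(lengths)) stop("lengths required for measure = 'counts'")
    need <- rownames(counts)[rowSums(counts) > 0]
    missing_len <- setdiff(need, names(lengths))
    if (length(missing_len))
      stop("missing genome length for: ", paste(missing_len, collapse = ", "))
    len <- lengths[rownames(counts)]
    len[is.na(len)] <- 1 # zero-count genomes without a length
    if (any(len <= 0)) stop("genome lengths must be positive")
    rate <- counts / len
  } else {
    rate <- counts
  }
  tot <- colSums(rate)
  empty <- tot == 0
  if (any(empty)) {
    warning(sum(empty), " all-zero sample(s) left as zero rows")
    tot[empty] <- 1
  }
  tpm <- sweep(rate, 2L, tot, "/") * 1e6
  attr(tpm, "level") <- "genome"
  tpm
}

#' Read a GTDB-style taxonomy table
#'
#' @param path TSV with columns `genome_id` and `lineage`
#'   (`d__...;p__...;...;s__...`), optionally `kingdom`.
#' @return See [parse_taxonomy()].
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  parse_taxonomy(df$genome_id, df$lineage, df$kingdom)
}

#' Parse GTDB-style lineage strings into a taxonomy table
#'
#' @param genome_id character vector of unique genome ids.
#' @param lineage lineage strings with exactly 7 prefix-coded ranks
#'   (`d__;p__;c__;o__;f__;g__;s__`); empty ranks allowed.
#' @param kingdom optional kingdom flags (`bacteria`/`archaea`/`virus`);
#'   derived from the domain rank when absent.
#' @return data.frame with `genome_id`, `kingdom`, and one column per rank
#'   (`domain` ... `species`), prefix stripped.
#' @export
parse_taxonomy <- function(genome_id, lineage, kingdom = NULL) {
  if (anyDuplicated(genome_id)) stop("genome ids must be unique")
  parts <- strsplit(lineage, ";", fixed = TRUE)
  bad <- lengths(parts) != 7L
  if (any(bad))
    stop("lineage must have 7 ranks; offending: ",
         paste(genome_id[bad][seq_len(min(3, sum(bad)))], collapse = ", "))
  mat <- do.call(rbind, parts)
  for (j in seq_len(7L)) mat[, j] <- sub(paste0("^\\s*", TAX_PREFIXES[j]), "", mat[, j])
  colnames(mat) <- TAX_RANKS
  if (is.null(kingdom)) {
    dom <- tolower(mat[, "domain"])
    kingdom <- ifelse(dom == "archaea", "archaea",
                      ifelse(dom == "viruses" | dom == "virus", "virus", "bacteria"))
  }
  data.frame(genome_id = genome_id, kingdom = kingdom, mat,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Roll genome-level abundances up to a higher taxonomic rank
#'
#' The abundance of a clade is the sum of its member genomes' abundances, so
#' per-sample totals are conserved at every rank.
#'
#' @param abund genome-level abundance matrix (genomes x samples), as from
#'   [tpm_normalize()].
#' @param taxonomy data.frame from [parse_taxonomy()].
#' @param rank one of `genome`, `species`, `genus`, `family`, `order`,
#'   `class`, `phylum`, `domain`.
#' @param unclassified how to treat genomes with an empty name at `rank`:
#'   `"bucket"` (default) pools them under `"unclassified"`, `"drop"` removes
#'   them, `"error"` fails.
#' @return Abundance matrix at the requested rank (attribute `level` set).
#'   Genomes absent from `taxonomy` are an error.
#' @export
rollup <- function(abund, taxonomy, rank,
                   unclassified = c("bucket", "drop", "error")) {
  unclassified <- match.arg(unclassified)
  rank <- match.arg(rank, c("genome", TAX_RANKS))
  if (rank == "genome") {
    attr(abund, "level") <- "genome"
    return(abund)
  }
  idx <- match(rownames(abund), taxonomy$genome_id)
  if (anyNA(idx))
    stop("genomes absent from taxonomy: ",
         paste(head(rownames(abund)[is.na(idx)], 3), collapse = ", "))
  labels <- taxonomy[[rank]][idx]
  empty <- is.na(labels) | labels == ""
  if (any(empty)) {
    if (unclassified == "error")
      stop(sum(empty), " genome(s) unclassified at rank ", rank)
    if (unclassified == "drop") {
      abund <- abund[!empty, , drop = FALSE]
      labels <- labels[!empty]
    } else labels[empty] <- "unclassified"
  }
  out <- rowsum(abund, group = labels)
  out <- out[order(rownames(out)), , drop = FALSE]
  attr(out, "level") <- rank
  out
}

#' Firmicutes-to-Bacteroidota ratio per sample
#'
#' Numerator is the summed abundance of the Firmicutes group (Firmicutes,
#' Firmicutes_A, Firmicutes_B, Firmicutes_C - i.e. Bacillota); denominator is
#' Bacteroidota. Samples with zero Bacteroidota yield `NA` (flagged
#' undefined) rather than infinity.
#'
#' @param phylum_abund phylum-level abundance matrix (phyla x samples).
#' @return Named numeric vector of per-sample ratios (`NA` where undefined).
#' @export
fb_ratio <- function(phylum_abund) {
  firm_labels <- c("Firmicutes", "Firmicutes_A", "Firmicutes_B", "Firmicutes_C")
  present <- intersect(firm_labels, rownames(phylum_abund))
  if (!length(present))
    stop("no Firmicutes/Firmicutes_A/B/C phylum present")
  firm <- colSums(phylum_abund[present, , drop = FALSE])
  bact <- if ("Bacteroidota" %in% rownames(phylum_abund))
    phylum_abund["Bacteroidota", ] else rep(0, ncol(phylum_abund))
  ratio <- ifelse(bact > 0, firm / bact, NA_real_)
  names(ratio) <- colnames(phylum_abund)
  ratio
}

#' Rarefaction curve of feature richness over samples
#'
#' A feature (genome, gene...) is "present" in a sample when its abundance
#' strictly exceeds `presence_threshold` (default 100 TPM). For each subset
#' size n, `reps` random sample subsets are drawn without replacement and the
#' number of features present in at least one drawn sample is recorded.
#'
#' @param abund features x samples abundance matrix.
#' @param presence_threshold strict presence cutoff (default 100).
#' @param reps random subsets per n (default 100).
#' @param seed optional RNG seed.
#' @return data.frame with columns `n`, `mean`, `sd`. The mean is
#'   non-decreasing in n and at n = ncol the count is the exact union with
#'   sd 0.
#' @export
rarefy_features <- function(abund, presence_threshold = 100, reps = 100,
                            seed = NULL) {
  if (presence_threshold < 0) stop("presence_threshold must be >= 0")
  if (reps < 1) stop("reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  pres <- abund > presence_threshold
  ns <- ncol(pres)
  res <- matrix(NA_real_, nrow = ns, ncol = reps)
  for (n in seq_len(ns)) {
    for (r in seq_len(reps)) {
      take <- sample.int(ns, n)
      res[n, r] <- sum(rowSums(pres[, take, drop = FALSE]) > 0)
    }
  }
  data.frame(n = seq_len(ns),
             mean = rowMeans(res),
             sd = apply(res, 1L, sd))
}
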