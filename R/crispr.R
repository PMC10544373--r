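#' Detect CRISPR arrays in host genomes
#'
#' CRT-style detection: an exact seed k-mer (k = minimum repeat length) that
#' recurs at spacings compatible with repeat+spacer periods seeds a candidate
#' array; the seed is extended left and right to the maximal unit shared by
#' every instance. Arrays are accepted when they have at least `min_repeats`
#' repeat copies, repeat and spacer lengths inside the given ranges, and
#' mutually non-identical spacers (which drops plain tandem repeats).
#' Coordinates are 0-based half-open.
#'
#' @param genomes named character vector (or `DNAStringSet`) of host genome
#'   sequences.
#' @param min_repeats minimum repeat copies (default 3).
#' @param repeat_len allowed repeat-unit length range in bp (default
#'   c(19, 38)).
#' @param spacer_len allowed spacer length range in bp (default c(19, 48)).
#' @return data.frame of spacers, one row each: `host_id`, `array_id`,
#'   `repeat_seq`, `spacer_seq`, `array_start`, `array_end`,
#'   `spacer_start`, `spacer_end`, `n_repeats`. Zero rows when nothing is
#'   found.
#' @export
detect_crispr <- function(genomes, min_repeats = 3,
                          repeat_len = c(19, 38), spacer_len = c(19, 48)) {
  genomes <- as_seq_vector(genomes)
  out <- lapply(names(genomes), function(gid) {
    detect_crispr_one(genomes[[gid]], gid, min_repeats, repeat_len, spacer_len)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(host_id = character(), array_id = character(),
                      repeat_seq = character(), spacer_seq = character(),
                      array_start = integer(), array_end = integer(),
                      spacer_start = integer(), spacer_end = integer(),
                      n_repeats = integer(), stringsAsFactors = FALSE)
  res
}

detect_crispr_one <- function(seq_chr, gid, min_repeats, repeat_len,
                              spacer_len) {
  L <- nchar(seq_chr)
  k <- repeat_len[1]
  if (L < 200) return(NULL)
  codes <- dna_to_int(seq_chr)
  km <- kmer_codes(codes, k)
  period_min <- repeat_len[1] + spacer_len[1]
  period_max <- repeat_len[2] + spacer_len[2]

  dup_codes <- unique(km[duplicated(km)])
  dup_codes <- dup_codes[!is.na(dup_codes)]
  if (!length(dup_codes)) return(NULL)
  pos_by_code <- split(which(km %in% dup_codes), km[km %in% dup_codes])

  arrays <- list()
  for (pp in pos_by_code) {
    pp <- sort(pp)
    gaps <- diff(pp)
    ok <- gaps >= period_min & gaps <= period_max
    # maximal runs of in-range gaps
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= (min_repeats - 1L))) {
      occ <- pp[starts[j]:(ends[j] + 1L)]
      arr <- refine_array(codes, occ, k, repeat_len, spacer_len, min_repeats)
      if (!is.null(arr)) arrays[[length(arrays) + 1L]] <- arr
    }
  }
  if (!length(arrays)) return(NULL)
  # dedup overlapping candidates (one array seeds from many k-mers, and
  # boundary-spanning seeds can yield shifted sub-arrays): greedily keep
  # the candidate with the most repeat copies, then the longest span
  ord <- order(-vapply(arrays, function(a) length(a$occ), numeric(1)),
               -vapply(arrays, function(a) a$end - a$start, numeric(1)),
               vapply(arrays, function(a) a$start, numeric(1)))
  arrays <- arrays[ord]
  kept <- list()
  for (a in arrays) {
    clash <- any(vapply(kept, function(b)
      a$start < b$end && b$start < a$end, logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- a
  }
  kept <- kept[order(vapply(kept, function(a) a$start, numeric(1)))]
  rows <- lapply(seq_along(kept), function(ai) {
    a <- kept[[ai]]
    data.frame(host_id = gid,
               array_id = sprintf("%s_crispr%d", gid, ai),
               repeat_seq = a$repeat_seq,
               spacer_seq = a$spacers,
               array_start = a$start, array_end = a$end,
               spacer_start = a$spacer_start, spacer_end = a$spacer_end,
               n_repeats = length(a$occ),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# extend seed occurrences to the maximal common repeat unit and extract
# spacers; returns NULL when the candidate fails the acceptance rules
refine_array <- function(codes, occ, k, repeat_len, spacer_len, min_repeats) {
  L <- length(codes)
  # extend left while every instance shares the character
  left <- 0L
  while (occ[1] - left - 1L >= 1L &&
         k + left < repeat_len[2] &&
         length(unique(codes[occ - left - 1L])) == 1L) left <- left + 1L
  right <- 0L
  while (occ[length(occ)] + k + right <= L &&
         k + left + right < repeat_len[2] &&
         length(unique(codes[occ + k + right])) == 1L) right <- right + 1L
  rep_start <- occ - left           # 1-based starts of repeat instances
  rep_len <- k + left + right
  if (rep_len < repeat_len[1] || rep_len > repeat_len[2]) return(NULL)
  nrep <- length(occ)
  if (nrep < min_repeats) return(NULL)
  sp_start <- rep_start[-nrep] + rep_len # 1-based spacer starts
  sp_end <- rep_start[-1] - 1L           # 1-based inclusive ends
  sp_len <- sp_end - sp_start + 1L
  if (any(sp_len < spacer_len[1] | sp_len > spacer_len[2])) return(NULL)
  spacers <- vapply(seq_along(sp_start), function(i)
    int_to_dna(codes[sp_start[i]:sp_end[i]]), character(1))
  if (anyDuplicated(spacers)) return(NULL) # tandem-repeat filter
  list(occ = rep_start,
       start = rep_start[1] - 1L,                   # 0-based half-open
       end = rep_start[nrep] + rep_len - 1L,
       repeat_seq = int_to_dna(codes[rep_start[1]:(rep_start[1] + rep_len - 1L)]),
       spacers = spacers,
       spacer_start = sp_start - 1L,
       spacer_end = sp_end)
}

as_seq_vector <- function(x) {
  if (inherits(x, "XStringSet")) x <- as.character(x)
  if (is.null(names(x))) stop("sequences must be named")
  as.list(x)
}
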