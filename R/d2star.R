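#' d2* oligonucleotide dissimilarity between two sequences
#'
#' Background-corrected k-mer dissimilarity: k-mer counts are pooled over
#' both strands, expected counts are derived from an order-`markov_order`
#' Markov model fitted to the same (strand-pooled) sequence, counts are
#' centred (X = N_w - E_w) and standardised by sqrt(E_w), and
#' D2* = sum_w X_w Y_w / sqrt(E^X_w E^Y_w). The dissimilarity is
#' 0.5 * (1 - D2* / sqrt(sum X^2/E^X * sum Y^2/E^Y)), which lies in
#' \[0, 1\]: 0 for identical composition, symmetric in its arguments.
#'
#' @param x_seq,y_seq DNA strings (character scalars).
#' @param k word length (default 6).
#' @param markov_order background model order (default 2).
#' @param pseudo_expectation floor applied to zero expected counts of
#'   observed words (default 1e-8).
#' @return Dissimilarity in \[0, 1\].
#' @export
d2star <- function(x_seq, y_seq, k = 6, markov_order = 2,
                   pseudo_expectation = 1e-8) {
  px <- d2star_profile(x_seq, k, markov_order, pseudo_expectation)
  py <- d2star_profile(y_seq, k, markov_order, pseudo_expectation)
  num <- sum(px$xt * py$xt / sqrt(px$e * py$e))
  den <- sqrt(sum(px$xt^2 / px$e) * sum(py$xt^2 / py$e))
  0.5 * (1 - num / den)
}

# centred counts and Markov-expected counts for all 4^k words of one
# sequence, both strands pooled
d2star_profile <- function(seq_chr, k, markov_order, pseudo_expectation) {
  r <- markov_order
  if (nchar(seq_chr) < 4^r * 10)
    stop("sequence too short to estimate an order-", r, " background")
  s <- Biostrings::DNAString(seq_chr)
  src <- Biostrings::reverseComplement(s)
  cnt <- function(width) {
    Biostrings::oligonucleotideFrequency(s, width = width) +
      Biostrings::oligonucleotideFrequency(src, width = width)
  }
  nk <- cnt(k)
  c_r1 <- cnt(r + 1)       # (r+1)-mer counts -> transition numerators
  c_r <- cnt(r)            # r-mer counts -> denominators / initial law
  total_k <- sum(nk)

  # word digits: 4^k x k matrix of base indices (lexicographic ACGT order)
  words <- as.matrix(expand.grid(rev(replicate(k, 0:3, simplify = FALSE))))[, k:1, drop = FALSE]
  # code of the r-mer starting at position i of each word
  code_at <- function(i, len) {
    cc <- rep(0L, 4^k)
    for (j in i:(i + len - 1L)) cc <- cc * 4L + words[, j]
    cc + 1L
  }
  logp_r <- log(c_r / sum(c_r))
  # (r+1)-mer lexicographic index = context-code * 4 + next-base, so the
  # transition P(b | ctx) = c_r1[ctx, b] / c_r[ctx]
  logtrans <- log(c_r1) - log(rep(c_r, each = 4L))

  lp <- logp_r[code_at(1L, r)]
  for (i in seq_len(k - r)) {
    lp <- lp + logtrans[code_at(i, r + 1L)]
  }
  e <- total_k * exp(lp)
  zero <- e <= 0
  if (any(zero & nk > 0)) {
    message(sum(zero & nk > 0), " observed word(s) with zero expectation; ",
            "floored at ", pseudo_expectation)
  }
  e[e < pseudo_expectation] <- pseudo_expectation
  list(xt = nk - e, e = e)
}

#' Predict virus hosts from d2* composition similarity
#'
#' For each virus, hosts are ranked by ascending d2* dissimilarity; at most
#' `top_n` hosts with score <= `max_score` are emitted. Ties are broken by
#' lexicographic host id so reports are deterministic.
#'
#' @param viruses,hosts named character vectors / `DNAStringSet`.
#' @param max_score maximum admissible dissimilarity (default 0.25).
#' @param top_n maximum hosts per virus (default 5).
#' @param k,markov_order passed to [d2star()].
#' @return data.frame of evidence: `virus_id`, `host_id`, `channel`
#'   ("kmer"), `score` (d2* dissimilarity), `rank`.
#' @export
predict_kmer_hosts <- function(viruses, hosts, max_score = 0.25, top_n = 5,
                               k = 6, markov_order = 2) {
  viruses <- as_seq_vector(viruses)
  hosts <- as_seq_vector(hosts)
  hprof <- lapply(hosts, d2star_profile, k = k, markov_order = markov_order,
                  pseudo_expectation = 1e-8)
  rows <- list()
  for (vid in names(viruses)) {
    vp <- d2star_profile(viruses[[vid]], k, markov_order, 1e-8)
    sv <- sum(vp$xt^2 / vp$e)
    scores <- vapply(hprof, function(hp) {
      num <- sum(vp$xt * hp$xt / sqrt(vp$e * hp$e))
      0.5 * (1 - num / sqrt(sv * sum(hp$xt^2 / hp$e)))
    }, numeric(1))
    ord <- order(scores, names(scores))
    sel <- ord[scores[ord] <= max_score]
    sel <- sel[seq_len(min(top_n, length(sel)))]
    if (length(sel))
      rows[[vid]] <- data.frame(virus_id = vid, host_id = names(scores)[sel],
                                channel = "kmer", score = unname(scores[sel]),
                                rank = seq_along(sel),
                                stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(virus_id = character(), host_id = character(),
                      channel = character(), score = numeric(),
                      rank = integer(), stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}
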