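#' Random order-r Markov nucleotide composition model
#'
#' Draws a transition matrix over the four nucleotides with one row per
#' length-`order` context. Rows are independent flat Dirichlet draws, giving
#' genomes distinguishable oligonucleotide composition - the signal exploited
#' by the d2* host-prediction channel.
#'
#' @param order Markov order (context length), a positive integer.
#' @return A `markov_model`: list with `order` and `trans`, a 4^order x 4
#'   row-stochastic matrix (rows = base-4 context codes, columns = A,C,G,T).
#' @export
markov_model_random <- function(order = 2L) {
  stopifnot(order >= 1L)
  nctx <- 4L^order
  g <- matrix(rgamma(nctx * 4L, shape = 1), nrow = nctx)
  trans <- g / rowSums(g)
  colnames(trans) <- DNA_BASES4
  structure(list(order = as.integer(order), trans = trans),
            class = "markov_model")
}

#' Fit an order-r Markov model from a sequence
#'
#' Maximum-likelihood transition probabilities from observed (order+1)-mer
#' counts, with add-one smoothing so unseen contexts stay usable.
#'
#' @param seq_chr a DNA string (character scalar, A/C/G/T).
#' @param order Markov order.
#' @return A `markov_model` (see [markov_model_random()]).
#' @export
markov_model_fit <- function(seq_chr, order = 2L) {
  codes <- dna_to_int(seq_chr)
  codes <- codes[!is.na(codes)]
  k <- order + 1L
  km <- kmer_codes(codes, k)
  counts <- tabulate(km + 1L, nbins = 4L^k)
  cmat <- matrix(counts, nrow = 4L^order, ncol = 4L, byrow = TRUE) + 1
  trans <- cmat / rowSums(cmat)
  colnames(trans) <- DNA_BASES4
  structure(list(order = as.integer(order), trans = trans),
            class = "markov_model")
}

#' Sample a sequence from a Markov composition model
#'
#' @param model a `markov_model`.
#' @param len sequence length in bp.
#' @return A DNA string of length `len`.
#' @export
markov_sample <- function(model, len) {
  r <- model$order
  stopifnot(len >= r)
  cum <- t(apply(model$trans, 1L, cumsum))
  init <- sample.int(4L, r, replace = TRUE) - 1L
  u <- runif(len - r)
  codes <- markov_chain_sample(as.integer(len), cum, as.integer(init), u)
  int_to_dna(codes)
}

# rolling base-4 codes of all k-mers of an integer-coded sequence;
# windows containing NA (ambiguous base) are dropped via NA propagation
kmer_codes <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(integer(0))
  m <- n - k + 1L
  out <- numeric(m)
  for (j in seq_len(k)) {
    out <- out * 4 + codes[j:(j + m - 1L)]
  }
  out
}
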