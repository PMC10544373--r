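# Independent brute-force oracles. These deliberately use naive string /
# arithmetic implementations, not the package's code paths.

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# all-positions Hamming scan of a spacer against one virus (both strands,
# terminal overhangs allowed); returns the minimal mismatch count among
# placements whose span exceeds min_cov * spacer length, or NULL
oracle_spacer_best <- function(spacer, virus, min_cov = 0.95) {
  plen <- nchar(spacer)
  best <- NULL
  for (subj in c(virus, oracle_revcomp(virus))) {
    L <- nchar(subj)
    for (start in seq(-plen + 1L, L)) { # 1-based, may hang off either end
      a <- max(1L, start); b <- min(L, start + plen - 1L)
      span <- b - a + 1L
      if (span <= min_cov * plen) next
      sub_s <- substring(subj, a, b)
      sub_p <- substring(spacer, a - start + 1L, b - start + 1L)
      mm <- sum(strsplit(sub_s, "")[[1]] != strsplit(sub_p, "")[[1]])
      if (is.null(best) || mm < best) best <- mm
    }
  }
  best
}

# naive d2*: enumerate all 4^k words with explicit per-word Markov
# probability products, counts by literal substring scanning
oracle_d2star <- function(x, y, k = 6, r = 2) {
  bases <- c("A", "C", "G", "T")
  words <- apply(expand.grid(rep(list(bases), k))[, k:1], 1, paste,
                 collapse = "")
  count_words <- function(s, len) {
    ss <- c(s, oracle_revcomp(s))
    ww <- apply(expand.grid(rep(list(bases), len))[, len:1, drop = FALSE],
                1, paste, collapse = "")
    cnt <- setNames(numeric(length(ww)), ww)
    for (sq in ss) {
      n <- nchar(sq)
      subs <- substring(sq, 1:(n - len + 1), len:n)
      tt <- table(subs)
      cnt[names(tt)] <- cnt[names(tt)] + tt
    }
    cnt
  }
  profile <- function(s) {
    nk <- count_words(s, k)
    c1 <- count_words(s, r + 1)
    c0 <- count_words(s, r)
    total <- sum(nk)
    e <- vapply(words, function(w) {
      p <- c0[substr(w, 1, r)] / sum(c0)
      for (i in 1:(k - r)) {
        ctx <- substr(w, i, i + r - 1)
        nxt <- substr(w, i, i + r)
        p <- p * c1[nxt] / c0[ctx]
      }
      unname(total * p)
    }, numeric(1))
    e[e < 1e-8] <- 1e-8
    list(xt = unname(nk[words]) - e, e = e)
  }
  px <- profile(x); py <- profile(y)
  num <- sum(px$xt * py$xt / sqrt(px$e * py$e))
  den <- sqrt(sum(px$xt^2 / px$e) * sum(py$xt^2 / py$e))
  0.5 * (1 - num / den)
}

# Clarke's ANOSIM R from explicit mean ranks
oracle_anosim_R <- function(d, groups) {
  n <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  vals <- d[upper.tri(d)]
  rk <- rank(vals)
  within <- groups[pairs[, 1]] == groups[pairs[, 2]]
  (mean(rk[!within]) - mean(rk[within])) / (n * (n - 1) / 4)
}

# naive fuzzy c-means iteration from given initial centroids
oracle_fcm <- function(x, init, m = 2, iters = 200) {
  v <- init
  c <- nrow(v)
  for (it in seq_len(iters)) {
    u <- matrix(0, nrow(x), c)
    for (i in seq_len(nrow(x))) {
      dists <- apply(v, 1, function(vc) sqrt(sum((x[i, ] - vc)^2)))
      if (any(dists == 0)) {
        u[i, dists == 0] <- 1 / sum(dists == 0)
      } else {
        for (kk in seq_len(c))
          u[i, kk] <- 1 / sum((dists[kk] / dists)^(2 / (m - 1)))
      }
    }
    for (kk in seq_len(c))
      v[kk, ] <- colSums(u[, kk]^m * x) / sum(u[, kk]^m)
  }
  d2 <- as.matrix(dist(rbind(x, v)))[seq_len(nrow(x)),
                                     nrow(x) + seq_len(c), drop = FALSE]^2
  list(u = u, v = v, objective = sum(u^m * d2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random DNA string for fixtures
rnd_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                      replace = TRUE), collapse = "")

small_genome_set <- function(seed = 7, n_hosts = 4, n_viruses = 4, ...) {
  generate_genomes(synthetic_config(seed = seed, n_hosts = n_hosts,
                                    n_viruses = n_viruses,
                                    host_length = 8000, virus_length = 4000,
                                    ...))
}
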