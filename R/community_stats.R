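#' Bray-Curtis dissimilarity between samples
#'
#' d(i,j) = sum(|x_i - x_j|) / sum(x_i + x_j) over features, for every pair
#' of sample columns.
#'
#' @param abund non-negative features x samples matrix.
#' @return A symmetric `n x n` matrix with zero diagonal, entries in
#'   \[0, 1\], dimnames = sample ids. A pair of all-zero samples gets
#'   distance 0 with a warning.
#' @export
bray_curtis <- function(abund) {
  abund <- as.matrix(abund)
  if (any(abund < 0)) stop("abundances must be non-negative")
  manh <- as.matrix(dist(t(abund), method = "manhattan"))
  tot <- colSums(abund)
  denom <- outer(tot, tot, "+")
  zero_pair <- denom == 0
  if (any(zero_pair & upper.tri(zero_pair)))
    warning("pair(s) of all-zero samples: distance set to 0")
  denom[zero_pair] <- 1
  d <- manh / denom
  diag(d) <- 0
  dimnames(d) <- list(colnames(abund), colnames(abund))
  d
}

check_distance <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0))
    stop("d must be a symmetric zero-diagonal distance matrix")
  d
}

#' Analysis of similarities (ANOSIM)
#'
#' Clarke's rank-based test of whether between-group dissimilarities exceed
#' within-group ones. R = (mean between-group rank - mean within-group rank)
#' divided by n(n-1)/4, with midranks for ties; the permutation p-value uses
#' the add-one rule, so it is never exactly zero.
#'
#' @param d symmetric distance matrix.
#' @param groups group labels, one per sample; every group needs >= 2
#'   samples and there must be >= 2 groups.
#' @param n_perm number of label permutations (default 999).
#' @param seed optional RNG seed.
#' @return List with `statistic` (R, in \[-1, 1\]), `p_value`,
#'   `n_permutations`.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- check_distance(d)
  n <- nrow(d)
  groups <- as.factor(groups)
  stopifnot(length(groups) == n)
  if (nlevels(droplevels(groups)) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 samples")
  if (!is.null(seed)) set.seed(seed)
  lt <- lower.tri(d)
  rk <- rank(d[lt]) # midranks for ties
  denom <- n * (n - 1) / 4
  stat <- function(g) {
    within <- outer(g, g, "==")[lt]
    (mean(rk[!within]) - mean(rk[within])) / denom
  }
  r_obs <- stat(groups)
  ge <- 0L
  for (i in seq_len(n_perm)) {
    if (stat(groups[sample.int(n)]) >= r_obs) ge <- ge + 1L
  }
  list(statistic = r_obs,
       p_value = (1 + ge) / (1 + n_perm),
       n_permutations = n_perm)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the variance of a distance matrix among the factors of a
#' design table, with sequential (Type I) sums of squares in the order
#' given, and tests each factor's pseudo-F by permuting sample identities.
#' The distance matrix is Gower-centred (G = -1/2 J D^2 J); factor sums of
#' squares are traces of projection-matrix products.
#'
#' @param d symmetric distance matrix.
#' @param design data.frame of factors/covariates, rows aligned with `d`.
#' @param n_perm permutations (default 999); p uses the add-one rule.
#' @param seed optional RNG seed.
#' @return Object of class `permanova`: data.frame with one row per factor
#'   plus `Residual` and `Total`, columns `Df`, `SumOfSqs`, `F`, `R2`,
#'   `adjR2`, `p`. Sequential factor R2 plus residual R2 sum to 1.
#' @export
permanova <- function(d, design, n_perm = 999, seed = NULL) {
  d <- check_distance(d)
  n <- nrow(d)
  design <- as.data.frame(design)
  stopifnot(nrow(design) == n)
  for (j in seq_along(design))
    if (is.character(design[[j]])) design[[j]] <- factor(design[[j]])
  lv <- vapply(design, function(x)
    if (is.factor(x)) min(table(droplevels(x))) else 2L, numeric(1))
  if (any(lv < 2)) stop("each factor level must appear >= 2 times")
  if (!is.null(seed)) set.seed(seed)

  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (d * d) %*% J
  ss_total <- sum(diag(G))

  # cumulative hat matrices for sequential partitioning
  terms <- names(design)
  hats <- vector("list", length(terms))
  dfs <- numeric(length(terms))
  X <- matrix(1, n, 1)
  rank_prev <- 1L
  for (j in seq_along(terms)) {
    xj <- design[[j]]
    if (is.factor(xj) && nlevels(droplevels(xj)) < 2) {
      Xj <- matrix(numeric(0), n, 0) # constant factor: zero-df null term
    } else {
      Xj <- model.matrix(~x, data.frame(x = xj))[, -1, drop = FALSE]
    }
    X <- cbind(X, Xj)
    q <- qr(X)
    dfs[j] <- q$rank - rank_prev
    if (dfs[j] == 0 && ncol(Xj) > 0)
      stop("rank-deficient design: factor '", terms[j],
           "' aliased with preceding terms")
    rank_prev <- q$rank
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    hats[[j]] <- tcrossprod(Q)
  }
  df_model <- sum(dfs)
  df_res <- n - 1 - df_model
  if (df_res <= 0) stop("no residual degrees of freedom")

  part_ss <- function(Gm) {
    tr <- vapply(hats, function(H) sum(H * Gm), numeric(1))
    ssq <- diff(c(sum(Gm) / n, tr)) # tr(H_j G) - tr(H_{j-1} G); H_0 = 11'/n
    res <- sum(diag(Gm)) - tr[length(tr)]
    list(ss = ssq, res = res)
  }
  obs <- part_ss(G)
  testable <- dfs > 0
  f_obs <- ifelse(testable, (obs$ss / dfs) / (obs$res / df_res), NA_real_)

  ge <- rep(0L, length(terms))
  for (i in seq_len(n_perm)) {
    p <- sample.int(n)
    pp <- part_ss(G[p, p])
    fp <- (pp$ss / dfs) / (pp$res / df_res)
    ge <- ge + (testable & !is.na(fp) & fp >= f_obs)
  }
  pval <- ifelse(testable, (1 + ge) / (1 + n_perm), NA_real_)

  r2 <- obs$ss / ss_total
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - dfs - 1)
  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    Df = c(dfs, df_res, n - 1),
    SumOfSqs = c(obs$ss, obs$res, ss_total),
    F = c(f_obs, NA, NA),
    R2 = c(r2, obs$res / ss_total, 1),
    adjR2 = c(adj_r2, NA, NA),
    p = c(pval, NA, NA),
    stringsAsFactors = FALSE
  )
  attr(out, "n_permutations") <- n_perm
  class(out) <- c("permanova", "data.frame")
  out
}

#' @export
print.permanova <- function(x, digits = 4, ...) {
  cat("PERMANOVA (sequential SS,", attr(x, "n_permutations"),
      "permutations)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
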