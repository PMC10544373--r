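#' Assemble subject-by-site F/B trajectory matrix
#'
#' Arranges per-sample F/B ratios into a subjects x ordered-GIT-sites matrix,
#' keeping only subjects observed at >= `min_sites` sites (the study design
#' retains goats with at least seven of the nine sites). Undefined ratios
#' (`NA`) count as missing.
#'
#' @param ratios named per-sample F/B ratios (see [fb_ratio()]).
#' @param subjects subject id per sample.
#' @param sites site per sample; levels of [git_sites()] or an ordered
#'   factor.
#' @param min_sites minimum observed sites per retained subject (default 7).
#' @return Numeric matrix subjects x sites (NA = missing), site columns in
#'   anatomical order.
#' @export
trajectory_matrix <- function(ratios, subjects, sites, min_sites = 7) {
  stopifnot(length(ratios) == length(subjects),
            length(ratios) == length(sites))
  site_levels <- if (is.factor(sites)) levels(sites) else
    intersect(git_sites(), unique(as.character(sites)))
  sites <- factor(as.character(sites), levels = site_levels)
  subjects <- as.character(subjects)
  subj_ids <- unique(subjects)
  m <- matrix(NA_real_, length(subj_ids), length(site_levels),
              dimnames = list(subj_ids, site_levels))
  for (i in seq_along(ratios)) {
    if (!is.na(ratios[i])) m[subjects[i], as.character(sites[i])] <- ratios[i]
  }
  obs <- rowSums(!is.na(m))
  keep <- obs >= min_sites
  if (any(!keep))
    message(sum(!keep), " subject(s) dropped (< ", min_sites, " sites)")
  m[keep, , drop = FALSE]
}

# per-row z-score after linear interpolation of interior gaps and
# nearest-observed extension at the boundaries
standardize_trajectories <- function(m) {
  t(apply(m, 1L, function(x) {
    if (sum(!is.na(x)) < 2) stop("subject with < 2 observed sites")
    if (anyNA(x)) {
      idx <- seq_along(x)
      x <- approx(idx[!is.na(x)], x[!is.na(x)], xout = idx, rule = 2)$y
    }
    (x - mean(x)) / sd(x)
  }))
}

#' Fuzzy c-means clustering of F/B trajectories
#'
#' Clusters per-subject trajectories with fuzzy c-means after the standard
#' time-course preprocessing: subjects with fewer than 2 observed sites are
#' excluded (warning), interior missing sites are linearly interpolated
#' (boundaries take the nearest observed value), and each subject's
#' trajectory is z-scored across sites so only the shape matters.
#' Memberships u_ik = 1 / sum_j (||x_i - v_k|| / ||x_i - v_j||)^(2/(m-1));
#' centroids are membership^m-weighted means; iteration stops when no
#' centroid moves more than `tol`.
#'
#' @param traj subjects x sites matrix (NA = missing), e.g. from
#'   [trajectory_matrix()].
#' @param c number of clusters (default 2).
#' @param m fuzzifier (> 1, default 2).
#' @param tol convergence tolerance on centroid movement (default 1e-6).
#' @param max_iter iteration cap (default 500).
#' @param seed optional RNG seed (random initial centroids are drawn from
#'   distinct subjects).
#' @param init optional c x sites matrix of initial centroids (on the
#'   standardized scale), overriding the random initialisation.
#' @return Object of class `fcm_fit`: list with `membership` (subjects x c,
#'   rows sum to 1), `centroids` (c x sites), `cluster` (hard labels,
#'   argmax membership, lowest index wins ties), `objective`
#'   (sum u^m d^2 trace across iterations, non-increasing), `standardized`
#'   (the preprocessed matrix).
#' @export
trajectory_cluster <- function(traj, c = 2, m = 2.0, tol = 1e-6,
                               max_iter = 500, seed = NULL, init = NULL) {
  stopifnot(m > 1, c >= 1)
  obs <- rowSums(!is.na(traj))
  if (any(obs < 2)) {
    warning(sum(obs < 2), " subject(s) with < 2 observed sites excluded")
    traj <- traj[obs >= 2, , drop = FALSE]
  }
  if (c > nrow(traj)) stop("more clusters than subjects")
  if (!is.null(seed)) set.seed(seed)
  x <- standardize_trajectories(traj)
  n <- nrow(x)

  v <- if (is.null(init)) x[sample.int(n, c), , drop = FALSE]
  else { stopifnot(nrow(init) == c, ncol(init) == ncol(x)); init }
  obj_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    d2 <- outer(rowSums(x^2), rowSums(v^2), "+") - 2 * x %*% t(v)
    d2[d2 < 0] <- 0
    u <- fcm_memberships(d2, m)
    obj_trace <- c(obj_trace, sum(u^m * d2))
    um <- u^m
    v_new <- (t(um) %*% x) / colSums(um)
    if (max(abs(v_new - v)) < tol) { v <- v_new; break }
    v <- v_new
  }
  d2 <- outer(rowSums(x^2), rowSums(v^2), "+") - 2 * x %*% t(v)
  d2[d2 < 0] <- 0
  u <- fcm_memberships(d2, m)
  hard <- apply(u, 1L, which.max) # ties: lower cluster index
  rownames(u) <- rownames(x)
  structure(list(membership = u, centroids = v,
                 cluster = setNames(hard, rownames(x)),
                 objective = obj_trace, standardized = x,
                 m = m, iterations = iter),
            class = "fcm_fit")
}

fcm_memberships <- function(d2, m) {
  n <- nrow(d2); c <- ncol(d2)
  u <- matrix(0, n, c)
  pow <- 1 / (m - 1)
  for (i in seq_len(n)) {
    di <- d2[i, ]
    if (any(di == 0)) {
      u[i, which(di == 0)] <- 1 / sum(di == 0) # on a centroid: crisp
    } else {
      w <- (1 / di)^pow
      u[i, ] <- w / sum(w)
    }
  }
  u
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat("Fuzzy c-means trajectory clustering\n")
  cat("  subjects:", nrow(x$membership), " clusters:", ncol(x$membership),
      " fuzzifier m =", x$m, "\n")
  cat("  cluster sizes:", paste(table(x$cluster), collapse = " / "), "\n")
  cat("  final objective:", format(tail(x$objective, 1), digits = 6),
      "after", x$iterations, "iterations\n")
  invisible(x)
}
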