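#' Genus-by-glycoside-hydrolase correlation screen
#'
#' Pearson correlation between each genus' abundance and each GH (glycoside
#' hydrolase) CAZyme family's summed abundance across shared samples,
#' computed on log10(TPM+1) by default. A pair is reported as a hit when
#' r >= `r_min` and the two-sided t-based p < `alpha`; the full table with
#' Benjamini-Hochberg q-values is returned alongside for transparency.
#'
#' @param genus_abund genera x samples TPM matrix.
#' @param gh samples x GH-family matrix (family ids like "GH13") or its
#'   transpose with families as rows; orientation is resolved by matching
#'   sample ids.
#' @param r_min correlation threshold (default 0.5).
#' @param alpha significance threshold on raw p (default 0.05).
#' @param transform `"log10"` (default, log10(TPM+1)) or `"raw"`.
#' @param pool_gh if `TRUE`, GH families are summed into one pooled GH
#'   abundance before correlating.
#' @param sections optional named sample -> section map; when given, each
#'   hit is annotated with the genus' section of maximal mean abundance
#'   (see [max_abundance_section()]).
#' @param known_cellulolytic optional character vector of genus names used
#'   to set the `known_cellulolytic` flag.
#' @return List with `hits` (rows satisfying the gates) and `all_pairs`
#'   (every testable pair with `genus`, `gh_family`, `r`, `p`, `q`, `n`).
#'   Zero-variance genera or families are skipped.
#' @export
correlate_genus_gh <- function(genus_abund, gh, r_min = 0.5, alpha = 0.05,
                               transform = c("log10", "raw"),
                               pool_gh = FALSE, sections = NULL,
                               known_cellulolytic = NULL) {
  transform <- match.arg(transform)
  genus_abund <- as.matrix(genus_abund)
  gh <- as.matrix(gh)
  if (!is.null(colnames(gh)) && all(grepl("^GH\\d+$", colnames(gh))))
    gh <- t(gh) # samples x families -> families x samples
  shared <- intersect(colnames(genus_abund), colnames(gh))
  if (length(shared) < 4) stop("need >= 4 shared samples")
  ga <- genus_abund[, shared, drop = FALSE]
  gm <- gh[, shared, drop = FALSE]
  if (pool_gh) gm <- matrix(colSums(gm), nrow = 1,
                            dimnames = list("GH_pooled", shared))
  tf <- if (transform == "log10") function(x) log10(x + 1) else identity
  ga <- tf(ga); gm <- tf(gm)

  ok_g <- apply(ga, 1L, var) > 0
  ok_f <- apply(gm, 1L, var) > 0
  if (any(!ok_g)) message(sum(!ok_g), " zero-variance genus(era) skipped")
  if (any(!ok_f)) message(sum(!ok_f), " zero-variance GH family(ies) skipped")
  ga <- ga[ok_g, , drop = FALSE]; gm <- gm[ok_f, , drop = FALSE]

  n <- length(shared)
  rmat <- cor(t(ga), t(gm)) # genera x families
  tstat <- rmat * sqrt((n - 2) / pmax(1 - rmat^2, .Machine$double.eps))
  pmat <- 2 * pt(-abs(tstat), df = n - 2)
  all_pairs <- data.frame(
    genus = rep(rownames(ga), times = ncol(rmat)),
    gh_family = rep(colnames(rmat), each = nrow(rmat)),
    r = as.vector(rmat), p = as.vector(pmat), n = n,
    stringsAsFactors = FALSE)
  all_pairs$q <- p.adjust(all_pairs$p, method = "BH")
  hits <- all_pairs[all_pairs$r >= r_min & all_pairs$p < alpha, , drop = FALSE]
  if (!is.null(sections)) {
    sec <- max_abundance_section(genus_abund, sections)
    hits$section <- unname(sec[hits$genus])
  }
  if (!is.null(known_cellulolytic))
    hits$known_cellulolytic <- hits$genus %in% known_cellulolytic
  rownames(hits) <- rownames(all_pairs) <- NULL
  list(hits = hits, all_pairs = all_pairs)
}

#' Section of maximal abundance per genus
#'
#' For each genus, the GIT section (stomach, small intestine, large
#' intestine, rectum) with the highest mean abundance; ties go to the
#' anatomically earlier section (stomach first).
#'
#' @param genus_abund genera x samples matrix.
#' @param sections named character vector mapping every sample id to a
#'   section of [git_section_order()].
#' @return Named character vector genus -> section.
#' @export
max_abundance_section <- function(genus_abund, sections) {
  genus_abund <- as.matrix(genus_abund)
  if (!all(colnames(genus_abund) %in% names(sections)))
    stop("every sample must be mapped to a section")
  sec <- factor(sections[colnames(genus_abund)],
                levels = git_section_order())
  if (any(!git_section_order() %in% levels(droplevels(sec)))) {
    absent <- setdiff(git_section_order(), as.character(sec))
    if (length(absent)) stop("empty section(s): ", paste(absent, collapse = ", "))
  }
  means <- sapply(git_section_order(), function(s)
    rowMeans(genus_abund[, sec == s, drop = FALSE]))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1,
                                           dimnames = list(rownames(genus_abund), git_section_order()))
  setNames(git_section_order()[apply(means, 1L, which.max)],
           rownames(genus_abund))
}
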