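#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file; top-level keys `seed`, `out_dir`, optional
#'   `simulate` (arguments of [synthetic_config()]) and per-stage parameter
#'   blocks (`rarefy`, `stats`, `fbcluster`, `lefse`, `gh_screen`,
#'   `vhost`), plus logical switches under `stages`.
#' @return Config list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Run the full analysis pipeline on a synthetic community
#'
#' Orchestrates simulate -> abundance profiling -> rarefaction -> community
#' statistics -> differential and GH screens -> trajectory clustering ->
#' four-channel virus-host network -> methanogen screen, writing per-stage
#' outputs and a machine-readable JSON report. Identical config and seed
#' reproduce an identical report.
#'
#' @param config list as returned by [read_run_config()], or a YAML path.
#'   All stage thresholds default to the study's values (presence TPM > 100,
#'   100 rarefaction reps, 999 permutations, LDA > 2 & p < 0.05, r >= 0.5,
#'   spacer mismatch <= 1 at > 95% coverage, homology > 90% over > 500 bp,
#'   d2* <= 0.25 with up to 5 hosts, >= 3 CRISPR repeats).
#' @return The report, invisibly (also written to
#'   `<out_dir>/report.json`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- config$seed %||% 1
  out_dir <- config$out_dir %||% tempfile("gitmicro_run_")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stages <- config$stages %||% list()
  on_stage <- function(name) isTRUE(stages[[name]] %||% TRUE)

  sim_args <- config$simulate %||% list()
  sim_args$seed <- sim_args$seed %||% seed
  cfg <- do.call(synthetic_config, sim_args)
  sim <- simulate_community(cfg)
  write_community(sim, file.path(out_dir, "community"))
  g <- sim$genomes
  report <- list(seed = seed, config = unclass(cfg))

  tpm <- tpm_normalize(sim$counts, g$host_lengths)
  phylum <- rollup(tpm, g$taxonomy, "phylum")
  genus <- rollup(tpm, g$taxonomy, "genus")
  write_tsv(round(tpm, 3), file.path(out_dir, "tpm_genome.tsv"), rownames = TRUE)
  write_tsv(round(genus, 3), file.path(out_dir, "tpm_genus.tsv"), rownames = TRUE)
  report$abundance <- list(
    n_genomes = nrow(tpm), n_samples = ncol(tpm),
    n_genera = nrow(genus), n_phyla = nrow(phylum),
    mean_fb_ratio = mean(fb_ratio(phylum), na.rm = TRUE))

  if (on_stage("rarefy")) {
    rar <- config$rarefy %||% list()
    curve <- rarefy_features(tpm, presence_threshold = rar$threshold %||% 100,
                             reps = rar$reps %||% 100,
                             seed = seed + 11)
    write_tsv(curve, file.path(out_dir, "rarefaction.tsv"))
    report$rarefaction <- list(
      final_richness = curve$mean[nrow(curve)],
      half_sample_richness = curve$mean[max(1, floor(nrow(curve) / 2))])
  }

  if (on_stage("stats")) {
    st <- config$stats %||% list()
    factors <- st$factors %||% c("site", "age", "feeding", "geography")
    d <- bray_curtis(tpm)
    pv <- permanova(d, sim$metadata[, factors, drop = FALSE],
                    n_perm = st$n_perm %||% 999, seed = seed + 21)
    an <- anosim_test(d, sim$metadata$section,
                      n_perm = st$n_perm %||% 999, seed = seed + 22)
    write_tsv(as.data.frame(pv), file.path(out_dir, "permanova.tsv"))
    report$stats <- list(
      permanova = setNames(as.list(round(pv$R2[seq_along(factors)], 4)),
                           factors),
      permanova_p = setNames(as.list(pv$p[seq_along(factors)]), factors),
      anosim_R = round(an$statistic, 4), anosim_p = an$p_value)
  }

  if (on_stage("lefse")) {
    lf <- config$lefse %||% list()
    classes <- sim$metadata[[lf$classes %||% "feeding"]]
    hits <- lefse_screen(genus, classes,
                         alpha = lf$alpha %||% 0.05,
                         lda_cutoff = lf$lda_cutoff %||% 2.0)
    write_tsv(hits, file.path(out_dir, "differential_taxa.tsv"))
    planted <- sim$truth$differential_genera$genus
    report$differential <- list(
      n_hits = nrow(hits), taxa = hits$taxon,
      planted_recovered = mean(planted %in% hits$taxon))
  }

  if (on_stage("fbcluster")) {
    fb <- config$fbcluster %||% list()
    ratios <- fb_ratio(phylum)
    traj <- trajectory_matrix(ratios, sim$metadata$subject,
                              factor(sim$metadata$site, levels = git_sites()),
                              min_sites = fb$min_sites %||% 7)
    fit <- trajectory_cluster(traj, c = fb$c %||% 2, seed = seed + 31)
    write_tsv(data.frame(subject = rownames(fit$membership),
                         round(fit$membership, 4),
                         cluster = fit$cluster),
              file.path(out_dir, "fb_clusters.tsv"))
    truth_cl <- sim$truth$trajectory_cluster[rownames(fit$membership)]
    report$fb_clusters <- list(
      n_subjects = nrow(fit$membership),
      sizes = as.list(table(fit$cluster)),
      ari_vs_truth = round(adjusted_rand_index(fit$cluster, truth_cl), 4))
  }

  if (on_stage("gh_screen")) {
    gs <- config$gh_screen %||% list()
    sections <- setNames(sim$metadata$section, sim$metadata$sample_id)
    scr <- correlate_genus_gh(genus, sim$gh,
                              r_min = gs$r_min %||% 0.5,
                              alpha = gs$alpha %||% 0.05,
                              sections = sections)
    write_tsv(scr$hits, file.path(out_dir, "gh_hits.tsv"))
    planted <- sim$truth$correlated_pairs
    found <- paste(scr$hits$genus, scr$hits$gh_family)
    report$gh_screen <- list(
      n_hits = nrow(scr$hits),
      planted_recovered = mean(paste(planted$genus, planted$gh_family)
                               %in% found))
  }

  if (on_stage("vhost")) {
    vh <- config$vhost %||% list()
    arrays <- detect_crispr(g$hosts,
                            min_repeats = vh$min_repeats %||% 3)
    ev_crispr <- if (nrow(arrays))
      match_spacers(arrays, g$viruses,
                    max_mismatch = vh$max_mismatch %||% 1,
                    min_cov = vh$min_cov %||% 0.95)
    else NULL
    ev_hom <- match_homology(g$viruses, g$hosts,
                             min_identity = vh$min_identity %||% 0.90,
                             min_len = vh$min_len %||% 500)
    ev_kmer <- predict_kmer_hosts(g$viruses, g$hosts,
                                  max_score = vh$kmer_max %||% 0.25,
                                  top_n = vh$top_hosts %||% 5)
    ev_bin <- bin_comembership(g$virus_bins, g$bins)
    evidence <- list(ev_crispr, ev_hom, ev_kmer, ev_bin)
    evidence <- evidence[!vapply(evidence, is.null, logical(1))]
    net <- integrate_evidence(evidence, g$lifestyles, g$taxonomy)
    meth <- methanogen_screen(net)
    write_tsv(net$edges, file.path(out_dir, "network_edges.tsv"))
    write_tsv(meth$edges, file.path(out_dir, "methanogen_edges.tsv"))

    truth_links <- sim$truth$planted_links
    recov <- vapply(c("crispr", "homology", "bin"), function(ch) {
      tl <- truth_links[truth_links$channel == ch, , drop = FALSE]
      if (!nrow(tl)) return(NA_real_)
      ev <- do.call(rbind, lapply(evidence, function(e)
        e[e$channel == ch, c("virus_id", "host_id"), drop = FALSE]))
      mean(paste(tl$virus_id, tl$host_id) %in%
             paste(ev$virus_id, ev$host_id))
    }, numeric(1))
    false_edges <- vapply(c("crispr", "homology"), function(ch) {
      tl <- truth_links[truth_links$channel == ch, , drop = FALSE]
      ev <- do.call(rbind, lapply(evidence, function(e)
        e[e$channel == ch, c("virus_id", "host_id"), drop = FALSE]))
      if (is.null(ev) || !nrow(ev)) return(0)
      sum(!paste(ev$virus_id, ev$host_id) %in%
            paste(tl$virus_id, tl$host_id))
    }, numeric(1))
    report$vhost <- list(
      edges_per_channel = as.list(table(unlist(lapply(evidence,
                                                      function(e) e$channel)))),
      n_edges = nrow(net$edges),
      consensus_histogram = as.list(table(net$edges$consensus)),
      specialist_fraction = round(mean(net$viruses$role == "specialist"), 4),
      recovery = as.list(round(recov, 4)),
      false_edges = as.list(false_edges),
      methanogen_targeting = length(meth$targeting_viruses),
      methanogen_lytic = length(meth$lytic_viruses))
  }

  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  message("report written to ", report_path)
  invisible(report)
}
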