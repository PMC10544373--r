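#' Configuration for the synthetic community generator
#'
#' Bundles and validates every knob of the synthetic multi-kingdom
#' community: genome sizing and composition models, the fraction of viruses
#' planted with each virus-host evidence channel, the sampling design
#' (subjects x GIT sites), and the planted community effects.
#'
#' @param seed RNG seed fixing every downstream draw.
#' @param n_hosts,n_viruses numbers of host MAGs and viral genomes.
#' @param host_length,virus_length genome lengths in bp (>= 1 kb).
#' @param markov_order order of the per-genome Markov composition models.
#' @param n_subjects,n_sites sampling design: subjects (goats) by ordered
#'   GIT sites (default 9, rumen to rectum); samples = subjects x sites.
#' @param frac_crispr_links,frac_homology_links,frac_kmer_links,frac_bin_links
#'   fractions of viruses planted with each evidence type, on disjoint
#'   virus subsets (their sum must be <= 1).
#' @param effect_size_differential fold change applied to each planted
#'   differential genus in its favoured feeding group (1 = no effect).
#' @param rho_gh target Pearson correlation of planted genus-GH pairs.
#' @param noise_sigma sd of the log10 count noise.
#' @param trajectory_contrast scales the two F/B trajectory archetypes
#'   (1 = full contrast as in the study, 0 = flat, i.e. no subject-level
#'   trajectory effect).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1, n_hosts = 20, n_viruses = 20,
                             host_length = 1e5, virus_length = 2e4,
                             markov_order = 2, n_subjects = 24, n_sites = 9,
                             frac_crispr_links = 0.25,
                             frac_homology_links = 0.25,
                             frac_kmer_links = 0.25,
                             frac_bin_links = 0.25,
                             effect_size_differential = 10,
                             rho_gh = 0.8, noise_sigma = 0.5,
                             trajectory_contrast = 1) {
  fr <- c(frac_crispr_links, frac_homology_links, frac_kmer_links,
          frac_bin_links)
  if (any(fr < 0 | fr > 1)) stop("link fractions must lie in [0, 1]")
  if (sum(fr) > 1 + 1e-9)
    stop("requested link fractions exceed available virus count ",
         "(channel subsets are disjoint; fractions must sum to <= 1)")
  if (host_length < 1000 || virus_length < 1000)
    stop("genome lengths must be >= 1 kb")
  if (n_sites < 7)
    warning("n_sites < 7: trajectory clustering expects >= 7 of 9 sites")
  if (n_sites > 9) stop("at most 9 GIT sites are defined")
  if (effect_size_differential < 1)
    stop("effect_size_differential is a fold change >= 1")
  structure(list(seed = seed, n_hosts = n_hosts, n_viruses = n_viruses,
                 host_length = host_length, virus_length = virus_length,
                 markov_order = markov_order, n_subjects = n_subjects,
                 n_sites = n_sites,
                 n_samples = n_subjects * n_sites,
                 frac_crispr_links = frac_crispr_links,
                 frac_homology_links = frac_homology_links,
                 frac_kmer_links = frac_kmer_links,
                 frac_bin_links = frac_bin_links,
                 effect_size_differential = effect_size_differential,
                 rho_gh = rho_gh, noise_sigma = noise_sigma,
                 trajectory_contrast = trajectory_contrast),
            class = "synthetic_config")
}

GH_FAMILIES <- c("GH2", "GH3", "GH5", "GH9", "GH10", "GH13", "GH26",
                 "GH43", "GH48", "GH94")

METHANOGEN_GENERA <- c("Methanomethylophilus", "Methanocorpusculum",
                       "Methanobrevibacter_A", "ISO4-G1")

# taxonomy scaffold: 4 archaeal methanogens when room allows, the rest split
# over the Firmicutes group, Bacteroidota, and two minor phyla
synthetic_taxonomy <- function(host_ids) {
  n <- length(host_ids)
  n_arch <- min(4L, max(0L, n - 4L))
  phyla <- character(n)
  genera <- character(n)
  kingdom <- rep("bacteria", n)
  arch_ph <- c("Thermoplasmatota", "Halobacterota", "Euryarchaeota",
               "Thermoplasmatota")
  if (n_arch > 0) {
    idx <- seq_len(n_arch)
    phyla[idx] <- arch_ph[idx]
    genera[idx] <- METHANOGEN_GENERA[idx]
    kingdom[idx] <- "archaea"
  }
  rest <- setdiff(seq_len(n), seq_len(n_arch))
  # Firmicutes group and Bacteroidota in near-equal numbers (mirroring the
  # catalog's 1503 Firmicutes_A vs 1479 Bacteroidota), minor phyla after
  nr <- length(rest)
  n_minor <- if (nr >= 10) 2L else 0L
  n_firm <- ceiling((nr - n_minor) / 2)
  n_bact <- nr - n_minor - n_firm
  pool <- c(rep(c("Firmicutes_A", "Firmicutes", "Firmicutes_B",
                  "Firmicutes_C"), length.out = n_firm),
            rep("Bacteroidota", n_bact),
            rep(c("Proteobacteria", "Verrucomicrobiota"),
                length.out = n_minor))
  phyla[rest] <- pool
  genera[rest] <- paste0("Genus_", host_ids[rest])
  lineage <- sprintf("d__%s;p__%s;c__C%s;o__O%s;f__F%s;g__%s;s__",
                     ifelse(kingdom == "archaea", "Archaea", "Bacteria"),
                     phyla, phyla, phyla, phyla, genera)
  parse_taxonomy(host_ids, lineage)
}

# random interval of `len` not overlapping previously used intervals
pick_interval <- function(genome_len, len, used, margin = 200) {
  for (i in 1:200) {
    start <- sample.int(genome_len - len - 2 * margin, 1) + margin
    end <- start + len - 1
    ok <- all(vapply(used, function(u)
      end + margin < u[1] || start - margin > u[2], logical(1)))
    if (ok) return(c(start, end))
  }
  stop("could not place a planted feature without overlap")
}

random_dna <- function(len) {
  paste(sample(DNA_BASES4, len, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq_chr, n_subs) {
  if (n_subs == 0) return(seq_chr)
  x <- strsplit(seq_chr, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(x), n_subs)
  x[pos] <- vapply(x[pos], function(b)
    sample(setdiff(DNA_BASES4, b), 1), character(1))
  paste(x, collapse = "")
}

#' Generate synthetic host and virus genomes with planted virus-host links
#'
#' Host genomes are drawn from per-host order-r Markov composition models.
#' Disjoint virus subsets are planted with one evidence channel each:
#' CRISPR-linked hosts carry an array (28 bp repeat, 32 bp spacers, 3-6
#' repeat copies) in which one spacer is a protospacer copied from the
#' linked virus with 0-1 substitutions; homology-linked hosts receive a
#' 1000 bp virus segment at 95% identity; kmer-linked viruses are sampled
#' from their host's own Markov model; bin-linked viral contigs are
#' assigned to the host's bin. Everything planted is recorded in the truth
#' ledger, together with the subject trajectory clusters, differential
#' genera, genus-GH pairs and lifestyle labels used by
#' [generate_abundance()].
#'
#' @param config a [synthetic_config()].
#' @return List of class `genome_set`: `hosts`, `viruses` (named DNA
#'   strings), `host_lengths`, `taxonomy`, `bins`, `lifestyles`, and
#'   `truth` (the truth ledger).
#' @export
generate_genomes <- function(config) {
  set.seed(config$seed)
  nh <- config$n_hosts; nv <- config$n_viruses
  host_ids <- sprintf("host%03d", seq_len(nh))
  virus_ids <- sprintf("vir%03d", seq_len(nv))

  taxonomy <- synthetic_taxonomy(host_ids)
  host_models <- lapply(seq_len(nh), function(i)
    markov_model_random(config$markov_order))
  host_lens <- round(config$host_length * runif(nh, 0.85, 1.15))
  hosts <- setNames(vapply(seq_len(nh), function(i)
    markov_sample(host_models[[i]], host_lens[i]), character(1)), host_ids)

  # disjoint channel assignment over a shuffled virus order
  n_ch <- floor(c(config$frac_crispr_links, config$frac_homology_links,
                  config$frac_kmer_links, config$frac_bin_links) * nv)
  if (sum(n_ch) > nv)
    stop("requested link fractions exceed available virus count")
  shuffled <- sample(virus_ids)
  channel_of <- setNames(rep(NA_character_, nv), virus_ids)
  at <- 0
  for (ch in c("crispr", "homology", "kmer", "bin")) {
    nn <- n_ch[match(ch, c("crispr", "homology", "kmer", "bin"))]
    if (nn > 0) channel_of[shuffled[at + seq_len(nn)]] <- ch
    at <- at + nn
  }
  link_host <- setNames(sample(host_ids, nv, replace = TRUE), virus_ids)

  viruses <- setNames(character(nv), virus_ids)
  for (v in virus_ids) {
    model <- if (identical(channel_of[[v]], "kmer"))
      host_models[[match(link_host[[v]], host_ids)]]
    else markov_model_random(config$markov_order)
    viruses[[v]] <- markov_sample(model, config$virus_length)
  }

  used <- setNames(rep(list(list()), nh), host_ids)
  links <- list()
  spacer_truth <- list()
  for (v in virus_ids) {
    ch <- channel_of[[v]]
    if (is.na(ch)) next
    h <- link_host[[v]]
    hi <- match(h, host_ids)
    if (ch == "crispr") {
      n_rep <- sample(3:6, 1)
      rep_unit <- random_dna(28)
      n_sp <- n_rep - 1
      sp <- vapply(seq_len(n_sp), function(i) random_dna(32), character(1))
      proto_at <- sample.int(n_sp, 1)
      vstart <- sample.int(nchar(viruses[[v]]) - 32, 1)
      proto <- substr(viruses[[v]], vstart, vstart + 31)
      sp[proto_at] <- mutate_dna(proto, sample(0:1, 1))
      array_seq <- paste0(rep_unit,
                          paste0(sp, rep_unit, collapse = ""))
      iv <- pick_interval(host_lens[hi], nchar(array_seq), used[[h]])
      used[[h]] <- c(used[[h]], list(iv))
      substr(hosts[[h]], iv[1], iv[2]) <- array_seq
      links[[length(links) + 1]] <-
        data.frame(virus_id = v, host_id = h, channel = "crispr",
                   stringsAsFactors = FALSE)
      spacer_truth[[length(spacer_truth) + 1]] <-
        data.frame(virus_id = v, host_id = h, spacer_seq = sp[proto_at],
                   protospacer = proto, virus_start = vstart - 1L,
                   stringsAsFactors = FALSE)
    } else if (ch == "homology") {
      # 1 kb planted segment, shrunk for small virus genomes but never
      # below the 600 bp planting floor
      seg_len <- min(1000L, nchar(viruses[[v]]) - 200L)
      if (seg_len < 600L)
        stop("virus_length too short to plant a >= 600 bp homology segment")
      vstart <- sample.int(nchar(viruses[[v]]) - seg_len, 1)
      seg <- substr(viruses[[v]], vstart, vstart + seg_len - 1L)
      seg <- mutate_dna(seg, round(0.05 * seg_len)) # 95% identity
      iv <- pick_interval(host_lens[hi], seg_len, used[[h]])
      used[[h]] <- c(used[[h]], list(iv))
      substr(hosts[[h]], iv[1], iv[2]) <- seg
      links[[length(links) + 1]] <-
        data.frame(virus_id = v, host_id = h, channel = "homology",
                   stringsAsFactors = FALSE)
    } else {
      links[[length(links) + 1]] <-
        data.frame(virus_id = v, host_id = h, channel = ch,
                   stringsAsFactors = FALSE)
    }
  }
  planted_links <- if (length(links)) do.call(rbind, links) else
    data.frame(virus_id = character(), host_id = character(),
               channel = character(), stringsAsFactors = FALSE)

  bins <- data.frame(contig_id = host_ids,
                     bin_id = paste0("bin_", host_ids),
                     genome_id = host_ids, stringsAsFactors = FALSE)
  bin_links <- planted_links[planted_links$channel == "bin", , drop = FALSE]
  virus_bins <- data.frame(
    contig_id = virus_ids, genome_id = virus_ids,
    bin_id = ifelse(virus_ids %in% bin_links$virus_id,
                    paste0("bin_", bin_links$host_id[
                      match(virus_ids, bin_links$virus_id)]),
                    paste0("vbin_", virus_ids)),
    stringsAsFactors = FALSE)

  lifestyle_truth <- setNames(sample(c("virulent", "temperate"), nv,
                                     replace = TRUE), virus_ids)
  lifestyles <- data.frame(
    virus_id = virus_ids,
    score = ifelse(lifestyle_truth == "virulent",
                   runif(nv, 0.55, 1), runif(nv, 0, 0.45)),
    stringsAsFactors = FALSE)

  # community-effect truth, consumed by generate_abundance()
  cluster <- setNames(rep(1:2, length.out = config$n_subjects),
                      sprintf("subj%02d", seq_len(config$n_subjects)))
  bact_genera <- taxonomy$genus[taxonomy$kingdom == "bacteria"]
  bacteroid <- taxonomy$genus[taxonomy$phylum == "Bacteroidota"]
  diff_pool <- setdiff(bact_genera, character(0))
  diff_gen <- sample(diff_pool, min(2, length(diff_pool)))
  differential <- data.frame(
    genus = diff_gen,
    direction = c("grass", "silage")[seq_along(diff_gen)],
    fold = config$effect_size_differential, stringsAsFactors = FALSE)
  hindgut_genus <- if (length(bacteroid)) sample(bacteroid, 1) else NA
  corr_pool <- setdiff(bact_genera, c(diff_gen, hindgut_genus))
  corr_gen <- sample(corr_pool, min(3, length(corr_pool)))
  correlated <- data.frame(
    genus = corr_gen,
    gh_family = sample(GH_FAMILIES, length(corr_gen)),
    target_rho = rep_len(config$rho_gh, length(corr_gen)),
    stringsAsFactors = FALSE)

  truth <- list(planted_links = planted_links,
                spacer_truth = do.call(rbind, spacer_truth),
                trajectory_cluster = cluster,
                differential_genera = differential,
                hindgut_genus = hindgut_genus,
                correlated_pairs = correlated,
                methanogen_hosts = host_ids[taxonomy$kingdom == "archaea"],
                lifestyle_truth = lifestyle_truth)

  structure(list(hosts = hosts, viruses = viruses,
                 host_lengths = setNames(host_lens, host_ids),
                 taxonomy = taxonomy, bins = bins, virus_bins = virus_bins,
                 lifestyles = lifestyles, truth = truth, config = config),
            class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("Synthetic genome set:", length(x$hosts), "hosts,",
      length(x$viruses), "viruses\n")
  cat("  planted links:",
      paste(names(table(x$truth$planted_links$channel)),
            table(x$truth$planted_links$channel), collapse = ", "), "\n")
  invisible(x)
}

# log10 F/B trajectory archetypes over the 9 ordered sites (values beyond
# n_sites are truncated): cluster 1 peaks at jejunum/ileum, cluster 2
# increases monotonically from rumen to rectum
trajectory_archetypes <- function(n_sites, contrast = 1) {
  # log10 F/B: cluster 1 sits near 1 with a sudden jump to ~8 at the
  # jejunum/ileum; cluster 2 rises steadily from ~0.7 to ~7 (the dynamic
  # range of the study's trajectory clusters)
  a1 <- c(0, 0, 0, 0, 0.9, 0.9, 0.18, 0.18, 0.18)
  a2 <- seq(-0.15, 0.85, length.out = 9)
  rbind(a1[seq_len(n_sites)], a2[seq_len(n_sites)]) * contrast
}

#' Generate group-structured abundance, metadata, and GH profiles
#'
#' Per-sample genome read counts are drawn log-normally around genome base
#' abundances with fixed site, geography, and age loadings; subjects follow
#' one of two Firmicutes/Bacteroidota trajectory archetypes (a jejunum/ileum
#' peak or a monotone rise along the GIT); planted differential genera are
#' scaled by the configured fold change in their favoured feeding group; a
#' hindgut-enriched genus is amplified 5x in the large intestine; GH-family
#' abundances share a latent factor with their planted genus tuned to the
#' target correlation.
#'
#' @param config a [synthetic_config()].
#' @param genomes a `genome_set` from [generate_genomes()] (carries the
#'   truth ledger).
#' @return List with `counts` (genomes x samples integer matrix),
#'   `metadata` (sample_id, subject, site, section, age, feeding,
#'   geography), `gh` (samples x GH families), `truth`.
#' @export
generate_abundance <- function(config, genomes) {
  set.seed(config$seed + 1)
  truth <- genomes$truth
  tax <- genomes$taxonomy
  nh <- config$n_hosts
  host_ids <- tax$genome_id
  sites <- git_sites()[seq_len(config$n_sites)]
  subj_ids <- names(truth$trajectory_cluster)

  metadata <- expand.grid(site = sites, subject = subj_ids,
                          stringsAsFactors = FALSE)[, c("subject", "site")]
  metadata$sample_id <- paste(metadata$subject, metadata$site, sep = "_")
  metadata$section <- unname(git_sections()[metadata$site])
  feeding <- setNames(rep(c("grass", "silage"),
                          length.out = length(subj_ids)),
                      sample(subj_ids))
  geography <- setNames(rep(c("farmA", "farmB", "farmC"),
                            length.out = length(subj_ids)), sample(subj_ids))
  age <- setNames(rep(c("young", "adult"), length.out = length(subj_ids)),
                  sample(subj_ids))
  metadata$feeding <- unname(feeding[metadata$subject])
  metadata$geography <- unname(geography[metadata$subject])
  metadata$age <- unname(age[metadata$subject])
  ns <- nrow(metadata)

  mu <- rnorm(nh, mean = 3, sd = 0.4)
  site_load <- matrix(rnorm(nh * length(sites), 0, 0.6), nh,
                      dimnames = list(host_ids, sites))
  # the hindgut genus' site structure IS its planted 5x enrichment
  if (!is.na(truth$hindgut_genus))
    site_load[tax$genus == truth$hindgut_genus, ] <- 0
  geo_load <- matrix(rnorm(nh * 3, 0, 0.25), nh,
                     dimnames = list(host_ids, c("farmA", "farmB", "farmC")))
  age_load <- matrix(rnorm(nh * 2, 0, 0.15), nh,
                     dimnames = list(host_ids, c("young", "adult")))

  arch <- trajectory_archetypes(config$n_sites, config$trajectory_contrast)
  is_firm <- tax$phylum %in% c("Firmicutes", "Firmicutes_A", "Firmicutes_B",
                               "Firmicutes_C")
  is_bact <- tax$phylum == "Bacteroidota"
  fold_log <- log10(config$effect_size_differential)

  logv <- matrix(0, nh, ns, dimnames = list(host_ids, metadata$sample_id))
  for (j in seq_len(ns)) {
    st <- metadata$site[j]
    lv <- mu + site_load[, st] + geo_load[, metadata$geography[j]] +
      age_load[, metadata$age[j]]
    if (nrow(truth$differential_genera)) {
      for (r in seq_len(nrow(truth$differential_genera))) {
        if (metadata$feeding[j] == truth$differential_genera$direction[r]) {
          sel <- tax$genus == truth$differential_genera$genus[r]
          lv[sel] <- lv[sel] + fold_log
        }
      }
    }
    if (!is.na(truth$hindgut_genus) &&
        metadata$section[j] == "large_intestine") {
      sel <- tax$genus == truth$hindgut_genus
      lv[sel] <- lv[sel] + log10(5)
    }
    logv[, j] <- lv
  }
  logv <- logv + matrix(rnorm(nh * ns, 0, config$noise_sigma), nh, ns)

  # plant the F/B trajectory at the community level: rescale each sample's
  # Firmicutes group up and Bacteroidota down by a common factor so the
  # realised log10(F/B) equals the subject's archetype value plus
  # sample-level log-normal noise (sd = noise_sigma / 2)
  if (any(is_firm) && any(is_bact)) {
    e_fb <- rnorm(ns, 0, config$noise_sigma / 2)
    for (j in seq_len(ns)) {
      si <- match(metadata$site[j], sites)
      cl <- truth$trajectory_cluster[[metadata$subject[j]]]
      target <- arch[cl, si] + e_fb[j]
      cur <- log10(sum(10^logv[is_firm, j]) / sum(10^logv[is_bact, j]))
      logv[is_firm, j] <- logv[is_firm, j] + (target - cur) / 2
      logv[is_bact, j] <- logv[is_bact, j] - (target - cur) / 2
    }
  }
  counts <- round(10^logv)
  storage.mode(counts) <- "integer"

  # GH-family profiles sharing a latent factor with their planted genus
  tpm <- tpm_normalize(counts, genomes$host_lengths)
  genus_tpm <- rollup(tpm, tax, "genus")
  gh <- matrix(NA_real_, ns, length(GH_FAMILIES),
               dimnames = list(metadata$sample_id, GH_FAMILIES))
  for (f in GH_FAMILIES) {
    hit <- truth$correlated_pairs[truth$correlated_pairs$gh_family == f, ,
                                  drop = FALSE]
    if (nrow(hit)) {
      z <- log10(genus_tpm[hit$genus[1], ] + 1)
      z <- (z - mean(z)) / sd(z)
      rho <- hit$target_rho[1]
      lg <- 4 + 0.4 * (rho * z + sqrt(max(0, 1 - rho^2)) * rnorm(ns))
    } else {
      lg <- 4 + 0.4 * rnorm(ns)
    }
    gh[, f] <- 10^lg
  }

  list(counts = counts, metadata = metadata, gh = gh, truth = truth)
}

#' Run the full synthetic community generator
#'
#' Convenience wrapper: [generate_genomes()] then [generate_abundance()].
#'
#' @param config a [synthetic_config()].
#' @return List of class `synthetic_community` with `genomes`, `counts`,
#'   `metadata`, `gh`, `truth`, `config`.
#' @export
simulate_community <- function(config = synthetic_config()) {
  genomes <- generate_genomes(config)
  ab <- generate_abundance(config, genomes)
  structure(list(genomes = genomes, counts = ab$counts,
                 metadata = ab$metadata, gh = ab$gh,
                 truth = genomes$truth, config = config),
            class = "synthetic_community")
}

#' Write a synthetic community to disk
#'
#' Emits host and virus FASTA, counts/metadata/bins/taxonomy/lifestyle/GH
#' TSV tables, and the truth ledger as JSON.
#'
#' @param sim a `synthetic_community` from [simulate_community()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_community <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- sim$genomes
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(g$hosts)), file.path(dir, "hosts.fasta"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(g$viruses)),
    file.path(dir, "viruses.fasta"))
  wt <- function(x, f, rn = FALSE)
    write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = rn, col.names = if (rn) NA else TRUE)
  wt(sim$counts, "counts.tsv", rn = TRUE)
  wt(sim$metadata, "metadata.tsv")
  wt(rbind(g$bins, g$virus_bins), "bins.tsv")
  tx <- data.frame(genome_id = g$taxonomy$genome_id,
                   lineage = apply(g$taxonomy[, TAX_RANKS], 1, function(r)
                     paste0(TAX_PREFIXES, r, collapse = ";")),
                   kingdom = g$taxonomy$kingdom)
  wt(tx, "taxonomy.tsv")
  wt(g$lifestyles, "lifestyle.tsv")
  wt(sim$gh, "gh.tsv", rn = TRUE)
  wt(data.frame(genome_id = names(g$host_lengths),
                length = unname(g$host_lengths)), "host_lengths.tsv")
  truth <- sim$truth
  truth$trajectory_cluster <- as.list(truth$trajectory_cluster)
  truth$lifestyle_truth <- as.list(truth$lifestyle_truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
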