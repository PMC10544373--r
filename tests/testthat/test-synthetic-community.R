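test_that("config validation enforces fractions, lengths, and sizing", {
  expect_error(synthetic_config(frac_crispr_links = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_config(frac_crispr_links = 0.5,
                                frac_homology_links = 0.4,
                                frac_kmer_links = 0.2), "exceed")
  expect_error(synthetic_config(host_length = 500), "1 kb")
  expect_warning(synthetic_config(n_sites = 5), "7")
  expect_error(synthetic_config(effect_size_differential = 0.5), "fold")
})

test_that("a fixed seed reproduces the community byte-for-byte", {
  cfg <- synthetic_config(seed = 71, n_hosts = 4, n_viruses = 4,
                          host_length = 3000, virus_length = 1500,
                          n_subjects = 4)
  s1 <- simulate_community(cfg)
  s2 <- simulate_community(cfg)
  expect_identical(s1$genomes$hosts, s2$genomes$hosts)
  expect_identical(s1$genomes$viruses, s2$genomes$viruses)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$gh, s2$gh)
  d1 <- tempfile(); d2 <- tempfile()
  write_community(s1, d1); write_community(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("planted crispr spacers are recoverable by direct substring scan", {
  g <- generate_genomes(synthetic_config(seed = 72, n_hosts = 5, n_viruses = 5,
                                         host_length = 6000,
                                         virus_length = 3000,
                                         frac_crispr_links = 1,
                                         frac_homology_links = 0,
                                         frac_kmer_links = 0,
                                         frac_bin_links = 0))
  truth <- g$truth
  expect_equal(nrow(truth$planted_links), 5)
  expect_true(all(truth$planted_links$channel == "crispr"))
  for (i in seq_len(nrow(truth$spacer_truth))) {
    st <- truth$spacer_truth[i, ]
    # spacer sits verbatim in the host genome
    expect_true(grepl(st$spacer_seq, g$hosts[[st$host_id]], fixed = TRUE))
    # and matches its protospacer in the virus within 1 substitution
    mm <- oracle_spacer_best(st$spacer_seq, g$viruses[[st$virus_id]])
    expect_lte(mm, 1)
  }
})

test_that("nothing is planted when every channel fraction is zero", {
  g <- small_genome_set(seed = 73, frac_crispr_links = 0,
                        frac_homology_links = 0, frac_kmer_links = 0,
                        frac_bin_links = 0)
  expect_equal(nrow(g$truth$planted_links), 0)
  expect_true(all(grepl("^vbin_", g$virus_bins$bin_id)))
})

test_that("counts are non-negative integers aligned with metadata", {
  sim <- simulate_community(synthetic_config(seed = 74, n_hosts = 8,
                                             n_viruses = 2,
                                             host_length = 2000,
                                             virus_length = 1000,
                                             n_subjects = 6))
  expect_type(sim$counts[1, 1], "integer")
  expect_true(all(sim$counts >= 0))
  expect_equal(ncol(sim$counts), nrow(sim$metadata))
  expect_equal(colnames(sim$counts), sim$metadata$sample_id)
  expect_equal(nrow(sim$metadata), 6 * 9)
  expect_setequal(unique(sim$metadata$section), git_section_order())
  # truth ledger covers every subject and references existing ids
  expect_setequal(names(sim$truth$trajectory_cluster),
                  unique(sim$metadata$subject))
  expect_true(all(sim$truth$planted_links$virus_id %in%
                    names(sim$genomes$viruses)))
  expect_true(all(sim$truth$planted_links$host_id %in%
                    names(sim$genomes$hosts)))
})

test_that("planted genus-GH pairs reach their target correlation", {
  # rho = 1: the latent factor is shared without noise
  sim <- simulate_community(synthetic_config(seed = 75, n_hosts = 10,
                                             n_viruses = 2,
                                             host_length = 2000,
                                             virus_length = 1000,
                                             n_subjects = 6, rho_gh = 1))
  tpm <- tpm_normalize(sim$counts, sim$genomes$host_lengths)
  genus <- rollup(tpm, sim$genomes$taxonomy, "genus")
  pair <- sim$truth$correlated_pairs[1, ]
  r <- cor(log10(genus[pair$genus, ] + 1),
           log10(sim$gh[, pair$gh_family] + 1))
  expect_gt(r, 0.999)
})

test_that("a null generator yields near-nominal false-positive rates", {
  # no planted effects: the differential screen's p-gate should fire at
  # about the nominal alpha
  hit <- 0; tot <- 0
  for (i in 1:12) {
    sim <- simulate_community(synthetic_config(
      seed = 760 + i, n_hosts = 12, n_viruses = 2, host_length = 2000,
      virus_length = 1000, n_subjects = 6,
      effect_size_differential = 1, trajectory_contrast = 0))
    tpm <- tpm_normalize(sim$counts, sim$genomes$host_lengths)
    genus <- rollup(tpm, sim$genomes$taxonomy, "genus")
    h <- lefse_screen(genus, sim$metadata$feeding, alpha = 0.05,
                      lda_cutoff = 0)
    hit <- hit + nrow(h); tot <- tot + nrow(genus)
  }
  expect_lt(hit / tot, 0.15) # small-sample guard; 200-replicate version
                             # runs in the acceptance suite
})

test_that("round-tripping community files preserves the tables", {
  sim <- simulate_community(synthetic_config(seed = 77, n_hosts = 5,
                                             n_viruses = 3,
                                             host_length = 2000,
                                             virus_length = 1000,
                                             n_subjects = 4))
  dir <- tempfile()
  write_community(sim, dir)
  counts <- read_abundance_tsv(file.path(dir, "counts.tsv"))
  expect_equal(counts, sim$counts, ignore_attr = TRUE)
  hosts <- read_genomes_fasta(file.path(dir, "hosts.fasta"))
  expect_equal(hosts, unlist(sim$genomes$hosts))
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_equal(tax$genus, sim$genomes$taxonomy$genus)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(length(truth$trajectory_cluster), 4)
})
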