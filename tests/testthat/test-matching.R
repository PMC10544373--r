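test_that("spacer matching accepts <=1 mismatch at >95% coverage only", {
  set.seed(41)
  virus <- rnd_dna(5000)
  proto <- substr(virus, 2001, 2032)
  mut1 <- proto; substr(mut1, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                                 substr(proto, 10, 10))[1]
  mut2 <- mut1; substr(mut2, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                                substr(proto, 20, 20))[1]
  spacers <- data.frame(host_id = c("h1", "h1", "h2"),
                        spacer_seq = c(proto, mut1, mut2))
  ev <- match_spacers(spacers, c(v1 = virus))
  # exact + 1-mismatch spacers hit (h1 keeps the best: 0 mismatches)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$host_id, "h1")
  expect_equal(ev$score, 0)
  expect_equal(ev$virus_start, 2000)
  expect_equal(ev$virus_end, 2032)
  # 2 substitutions: rejected entirely (h2 absent)
  expect_false("h2" %in% ev$host_id)
})

test_that("a 30/32 bp truncated protospacer fails the 95% coverage rule", {
  set.seed(42)
  proto <- rnd_dna(32)
  # virus starts exactly with the last 30 bases of the spacer
  virus <- paste0(substr(proto, 3, 32), rnd_dna(3000))
  ev <- match_spacers(data.frame(host_id = "h1", spacer_seq = proto),
                      c(v1 = virus))
  expect_equal(nrow(ev), 0)
  # 31/32 bp (96.9% > 95%) at the boundary is accepted
  virus31 <- paste0(substr(proto, 2, 32), rnd_dna(3000))
  ev31 <- match_spacers(data.frame(host_id = "h1", spacer_seq = proto),
                        c(v1 = virus31))
  expect_equal(nrow(ev31), 1)
  expect_equal(ev31$span, 31)
})

test_that("reverse-strand protospacers are reported on forward coordinates", {
  set.seed(43)
  virus <- rnd_dna(4000)
  proto <- oracle_revcomp(substr(virus, 1001, 1032))
  ev <- match_spacers(data.frame(host_id = "h1", spacer_seq = proto),
                      c(v1 = virus))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$strand, "-")
  expect_equal(ev$virus_start, 1000)
  expect_equal(ev$virus_end, 1032)
})

test_that("match_spacers agrees with the all-positions Hamming oracle", {
  set.seed(44)
  g <- small_genome_set(seed = 44, n_hosts = 3, n_viruses = 3,
                        frac_crispr_links = 1, frac_homology_links = 0,
                        frac_kmer_links = 0, frac_bin_links = 0)
  arrays <- detect_crispr(g$hosts)
  ev <- match_spacers(arrays, g$viruses)
  for (i in seq_len(nrow(arrays))) {
    for (vid in names(g$viruses)) {
      best <- oracle_spacer_best(arrays$spacer_seq[i], g$viruses[[vid]])
      hit <- ev[ev$virus_id == vid & ev$host_id == arrays$host_id[i], ]
      if (!is.null(best) && best <= 1) {
        expect_equal(nrow(hit), 1)
        expect_lte(hit$score, best) # pooled over the host's spacers
      }
    }
  }
  # and no reported pair lacks an oracle-confirmed spacer
  for (j in seq_len(nrow(ev))) {
    sps <- arrays$spacer_seq[arrays$host_id == ev$host_id[j]]
    bests <- vapply(sps, function(s)
      oracle_spacer_best(s, g$viruses[[ev$virus_id[j]]]) %||% 99L, numeric(1))
    expect_equal(min(bests), ev$score[j])
  }
})

test_that("homology matching honours the >90% / >500 bp rule", {
  set.seed(45)
  virus <- rnd_dna(6000)
  host_bg <- rnd_dna(20000)
  # identical 1 kb copy
  seg <- substr(virus, 2001, 3000)
  host1 <- paste0(substr(host_bg, 1, 8000), seg,
                  substr(host_bg, 9001, 20000))
  ev <- match_homology(c(v1 = virus), c(h1 = host1))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$score, 1.0)
  expect_gte(ev$length, 1000)
  expect_equal(ev$virus_start, 2000)
  expect_equal(ev$host_start, 8000)

  # 600 bp at 85% identity: rejected
  seg600 <- strsplit(substr(virus, 1001, 1600), "")[[1]]
  idx <- sample(600, 90)
  seg600[idx] <- vapply(seg600[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  host2 <- paste0(substr(host_bg, 1, 5000), paste(seg600, collapse = ""),
                  substr(host_bg, 5601, 20000))
  expect_equal(nrow(match_homology(c(v1 = virus), c(h2 = host2))), 0)

  # unrelated random sequences: nothing
  expect_equal(nrow(match_homology(c(v1 = virus), c(h3 = rnd_dna(20000)))), 0)

  # reverse-strand copy is found
  hostrc <- paste0(substr(host_bg, 1, 4000), oracle_revcomp(seg),
                   substr(host_bg, 5001, 20000))
  evrc <- match_homology(c(v1 = virus), c(h4 = hostrc))
  expect_equal(nrow(evrc), 1)
  expect_equal(evrc$strand, "-")
  expect_equal(evrc$score, 1.0)
})
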