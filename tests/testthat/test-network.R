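toy_taxonomy <- function() {
  parse_taxonomy(
    c("hB", "hM", "hB2"),
    c("d__Bacteria;p__Bacteroidota;c__;o__;f__;g__Prevotella;s__",
      "d__Archaea;p__Halobacterota;c__;o__;f__;g__Methanocorpusculum;s__",
      "d__Bacteria;p__Firmicutes_A;c__;o__;f__;g__GenX;s__"))
}

toy_evidence <- function() {
  data.frame(
    virus_id = c("v1", "v1", "v1", "v2", "v3"),
    host_id = c("hB", "hB", "hM", "hM", "hB2"),
    channel = c("crispr", "homology", "kmer", "bin", "crispr"),
    stringsAsFactors = FALSE)
}

toy_lifestyles <- function() c(v1 = 0.9, v2 = 0.2, v3 = 0.7)

test_that("bin co-membership links co-binned contigs and rejects double bins", {
  vb <- data.frame(contig_id = c("v1", "v2"), bin_id = c("bin_h1", "vbinX"),
                   genome_id = c("v1", "v2"))
  hb <- data.frame(contig_id = c("h1c1", "h1c2", "h2c1"),
                   bin_id = c("bin_h1", "bin_h1", "bin_h2"),
                   genome_id = c("h1", "h1", "h2"))
  ev <- bin_comembership(vb, hb)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$virus_id, "v1")
  expect_equal(ev$host_id, "h1")
  # no shared bins -> empty
  vb2 <- data.frame(contig_id = "v9", bin_id = "nope", genome_id = "v9")
  expect_equal(nrow(bin_comembership(vb2, hb)), 0)
  hb_bad <- rbind(hb, data.frame(contig_id = "h1c1", bin_id = "bin_h2",
                                 genome_id = "h1"))
  expect_error(bin_comembership(vb, hb_bad), "more than one bin")
})

test_that("evidence integration collapses channels with set semantics", {
  net <- integrate_evidence(toy_evidence(), toy_lifestyles(), toy_taxonomy())
  expect_equal(nrow(net$edges), 4)
  e11 <- net$edges[net$edges$virus_id == "v1" & net$edges$host_id == "hB", ]
  expect_equal(e11$consensus, 2)
  expect_equal(e11$channels, "crispr,homology")
  expect_equal(net$viruses$role[net$viruses$virus_id == "v1"], "generalist")
  expect_equal(net$viruses$role[net$viruses$virus_id == "v2"], "specialist")
  expect_equal(net$viruses$lifestyle,
               c("virulent", "temperate", "virulent"))
  # duplicated evidence rows do not inflate consensus
  net2 <- integrate_evidence(rbind(toy_evidence(), toy_evidence()),
                             toy_lifestyles(), toy_taxonomy())
  expect_equal(net2$edges, net$edges)
  # input order invariance
  net3 <- integrate_evidence(toy_evidence()[5:1, ], toy_lifestyles(),
                             toy_taxonomy())
  expect_equal(net3$edges, net$edges)
  # empty evidence -> empty network
  net0 <- integrate_evidence(toy_evidence()[0, ], toy_lifestyles(),
                             toy_taxonomy())
  expect_equal(nrow(net0$edges), 0)
  expect_error(integrate_evidence(data.frame(virus_id = "vZ", host_id = "hB",
                                             channel = "bin"),
                                  toy_lifestyles(), toy_taxonomy()),
               "unknown virus")
})

test_that("the methanogen screen separates lytic from temperate targeting", {
  net <- integrate_evidence(toy_evidence(), toy_lifestyles(), toy_taxonomy())
  scr <- methanogen_screen(net)
  # v1 (virulent) and v2 (temperate) both target the methanogen hM
  expect_setequal(scr$targeting_viruses, c("v1", "v2"))
  expect_equal(scr$lytic_viruses, "v1")
  # v3 targets only a bacterial host: excluded
  expect_false("v3" %in% scr$targeting_viruses)
  expect_true(all(scr$edges$host_id == "hM"))
  expect_error(methanogen_screen(net, character(0)), "empty")
  # a bacterial genus named like a methanogen is excluded by the kingdom rule
  tax2 <- toy_taxonomy()
  tax2$genus[tax2$genome_id == "hB2"] <- "Methanocorpusculum"
  net2 <- integrate_evidence(toy_evidence(), toy_lifestyles(), tax2)
  expect_false("v3" %in% methanogen_screen(net2)$targeting_viruses)
})

test_that("generator-planted bin links are recovered exactly", {
  g <- small_genome_set(seed = 61, n_hosts = 6, n_viruses = 10,
                        frac_crispr_links = 0, frac_homology_links = 0,
                        frac_kmer_links = 0, frac_bin_links = 1)
  ev <- bin_comembership(g$virus_bins, g$bins)
  truth <- g$truth$planted_links
  expect_setequal(paste(ev$virus_id, ev$host_id),
                  paste(truth$virus_id, truth$host_id))
})
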