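test_that("tpm_normalize implements the length-normalised rate formula", {
  # single feature takes the whole million
  one <- matrix(57, 1, 2, dimnames = list("gA", c("s1", "s2")))
  expect_equal(unname(tpm_normalize(one, c(gA = 1234))[1, ]), c(1e6, 1e6))

  counts <- matrix(c(100, 300), 2, 1, dimnames = list(c("gA", "gB"), "s1"))
  tpm <- tpm_normalize(counts, c(gA = 1000, gB = 2000))
  expect_equal(unname(tpm[, 1]), c(400000, 600000))

  eq <- matrix(c(5, 5), 2, 1, dimnames = list(c("gA", "gB"), "s1"))
  expect_equal(unname(tpm_normalize(eq, c(gA = 700, gB = 700))[, 1]),
               c(500000, 500000))
})

test_that("tpm columns sum to 1e6 and degenerate inputs are handled", {
  set.seed(1)
  counts <- matrix(rpois(60, 40), 6, 10,
                   dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  lens <- setNames(sample(1000:9000, 6), paste0("g", 1:6))
  tpm <- tpm_normalize(counts, lens)
  expect_true(all(abs(colSums(tpm) - 1e6) < 1e6 * 1e-6))
  expect_true(all(tpm >= 0))

  counts[, 3] <- 0
  expect_warning(tpm0 <- tpm_normalize(counts, lens), "all-zero")
  expect_equal(unname(tpm0[, 3]), rep(0, 6))

  expect_error(tpm_normalize(counts, lens[-1]), "g1")
  # coverage mode needs no lengths
  expect_warning(cov <- tpm_normalize(counts, measure = "coverage"),
                 "all-zero")
  expect_true(all(abs(colSums(cov)[-3] - 1e6) < 1))
})

test_that("rollup sums daughter clades and conserves per-sample totals", {
  tax <- parse_taxonomy(
    c("g1", "g2", "g3"),
    c("d__Bacteria;p__P1;c__;o__;f__;g__GenA;s__",
      "d__Bacteria;p__P1;c__;o__;f__;g__GenA;s__",
      "d__Bacteria;p__P2;c__;o__;f__;g__GenB;s__"))
  ab <- matrix(c(200, 300, 500, 100, 400, 500), 3, 2,
               dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  gen <- rollup(ab, tax, "genus")
  expect_equal(gen["GenA", "s1"], 500)
  phy <- rollup(ab, tax, "phylum")
  expect_equal(colSums(phy), colSums(ab))
  # genome-level roll-up is the identity
  expect_equal(rollup(ab, tax, "genome"), ab, ignore_attr = TRUE)
  # composing genus -> phylum equals direct phylum roll-up
  tax_g <- unique(tax[, c("genus", "phylum")])
  via <- rowsum(gen, tax_g$phylum[match(rownames(gen), tax_g$genus)])
  expect_equal(unname(via), unname(phy), ignore_attr = TRUE)
  expect_error(rollup(ab[1:2, ], tax[-1, ], "genus"), "absent")
})

test_that("fb_ratio combines the Firmicutes group and flags zero denominators", {
  ab <- matrix(c(10, 20, 15,
                 5, 5, 10,
                 3, 4, 0), 3, 3, byrow = FALSE,
               dimnames = list(c("Firmicutes", "Firmicutes_A", "Bacteroidota"),
                               c("s1", "s2", "s3")))
  r <- fb_ratio(ab)
  expect_equal(unname(r["s1"]), (10 + 20) / 15)
  expect_equal(unname(r["s2"]), (5 + 5) / 10)
  expect_true(is.na(r["s3"]))
  eqm <- matrix(c(7, 7), 2, 1,
                dimnames = list(c("Firmicutes_B", "Bacteroidota"), "s1"))
  expect_equal(unname(fb_ratio(eqm)), 1)
  nof <- matrix(1, 1, 1, dimnames = list("Bacteroidota", "s1"))
  expect_error(fb_ratio(nof), "Firmicutes")
})

test_that("rarefaction matches exhaustive subset enumeration on a small matrix", {
  ab <- matrix(c(150, 0, 0,
                 120, 130, 0,
                 0, 0, 90,
                 200, 50, 300), 4, 3, byrow = TRUE,
               dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  pres <- ab > 100
  exhaustive <- sapply(1:3, function(n) {
    subs <- combn(3, n)
    mean(apply(subs, 2, function(ix)
      sum(rowSums(pres[, ix, drop = FALSE]) > 0)))
  })
  curve <- rarefy_features(ab, presence_threshold = 100, reps = 4000, seed = 3)
  expect_equal(curve$mean, exhaustive, tolerance = 0.02)
  expect_true(all(diff(curve$mean) >= 0))
  # full set: exact union, zero variance
  expect_equal(curve$mean[3], sum(rowSums(pres) > 0))
  expect_equal(curve$sd[3], 0)
  # single-sample matrix gives a one-point curve
  single <- rarefy_features(ab[, 1, drop = FALSE], reps = 10, seed = 1)
  expect_equal(nrow(single), 1)
  expect_equal(single$mean, sum(ab[, 1] > 100))
  expect_error(rarefy_features(ab, presence_threshold = -1), "threshold")
})
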