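test_that("bray_curtis matches hand arithmetic and vegan on random data", {
  ab <- matrix(c(2, 2, 4, 0, 2, 2), 2, 3,
               dimnames = list(c("f1", "f2"), c("a", "b", "c")))
  d <- bray_curtis(ab)
  expect_equal(d["a", "b"], 0.5)    # (2+2)/(4+4)
  expect_equal(d["a", "c"], 0)      # identical samples
  disj <- matrix(c(3, 0, 0, 5), 2, 2,
                 dimnames = list(c("f1", "f2"), c("a", "b")))
  expect_equal(bray_curtis(disj)["a", "b"], 1)

  set.seed(4)
  m <- matrix(rpois(80, 10), 8, 10,
              dimnames = list(paste0("f", 1:8), paste0("s", 1:10)))
  d <- bray_curtis(m)
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  skip_if_not_installed("vegan")
  dv <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  expect_equal(unname(d), unname(dv), tolerance = 1e-12)
  expect_error(bray_curtis(-m), "non-negative")
})

test_that("ANOSIM R matches hand rank arithmetic and vegan; p uses add-one", {
  # 4-sample hand instance
  d <- matrix(0, 4, 4)
  d[upper.tri(d)] <- c(0.1, 0.8, 0.7, 0.9, 0.6, 0.2)
  d <- d + t(d)
  g <- c("A", "A", "B", "B")
  res <- anosim_test(d, g, n_perm = 99, seed = 1)
  expect_equal(res$statistic, oracle_anosim_R(d, g), tolerance = 1e-12)
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)

  # maximal separation: every between-distance above every within-distance
  dsep <- matrix(0.9, 6, 6)
  dsep[1:3, 1:3] <- 0.1; dsep[4:6, 4:6] <- 0.1; diag(dsep) <- 0
  expect_equal(anosim_test(dsep, rep(c("x", "y"), each = 3),
                           n_perm = 49, seed = 1)$statistic, 1)

  skip_if_not_installed("vegan")
  set.seed(9)
  m <- matrix(rpois(120, 12), 10, 12)
  colnames(m) <- paste0("s", 1:12)
  rownames(m) <- paste0("f", 1:10)
  g2 <- rep(c("u", "v", "w"), each = 4)
  dm <- bray_curtis(m)
  rv <- vegan::anosim(as.dist(dm), g2, permutations = 0)
  expect_equal(anosim_test(dm, g2, n_perm = 9, seed = 1)$statistic,
               unname(rv$statistic), tolerance = 1e-12)
  expect_error(anosim_test(dm, c("a", rep("b", 11))), ">= 2")
})

test_that("PERMANOVA pseudo-F equals classical one-way ANOVA F on 1-D data", {
  set.seed(11)
  y <- c(rnorm(6, 0), rnorm(6, 1.5))
  g <- factor(rep(c("a", "b"), each = 6))
  d <- as.matrix(dist(y))
  res <- permanova(d, data.frame(group = g), n_perm = 99, seed = 1)
  f_aov <- summary(aov(y ~ g))[[1]]$`F value`[1]
  expect_equal(res$F[1], f_aov, tolerance = 1e-9)
  expect_equal(sum(res$R2[1:2]), 1, tolerance = 1e-9)
})

test_that("sequential PERMANOVA agrees with vegan::adonis2 term partitioning", {
  skip_if_not_installed("vegan")
  set.seed(12)
  m <- matrix(rpois(300, 15), 15, 20)
  colnames(m) <- paste0("s", 1:20); rownames(m) <- paste0("f", 1:15)
  meta <- data.frame(site = factor(rep(c("r", "j", "c", "k"), 5)),
                     feed = factor(rep(c("g", "s"), each = 10)))
  d <- bray_curtis(m)
  mine <- permanova(d, meta, n_perm = 19, seed = 1)
  va <- vegan::adonis2(as.dist(d) ~ site + feed, data = meta,
                       permutations = 19, by = "terms")
  expect_equal(mine$SumOfSqs[1:3], va$SumOfSqs[1:3], tolerance = 1e-8)
  expect_equal(mine$F[1:2], va$F[1:2], tolerance = 1e-8)
  expect_equal(mine$R2[1:3], va$R2[1:3], tolerance = 1e-8)
  expect_equal(mine$Df[1:3], va$Df[1:3])
})

test_that("PERMANOVA handles null factors and rejects aliased designs", {
  set.seed(13)
  d <- bray_curtis(matrix(rpois(60, 9), 6, 10,
                          dimnames = list(paste0("f", 1:6), paste0("s", 1:10))))
  g <- factor(rep(c("a", "b"), 5))
  res <- permanova(d, data.frame(const = factor(rep("z", 10)), g = g),
                   n_perm = 19, seed = 1)
  expect_equal(res$SumOfSqs[1], 0)
  expect_equal(res$R2[1], 0)
  expect_true(is.na(res$F[1]))
  expect_error(permanova(d, data.frame(g = g, g2 = g), n_perm = 9),
               "aliased")
})
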