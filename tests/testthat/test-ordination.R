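as_sv_dist <- function(m, ids = sprintf("s%d", seq_len(nrow(m)))) {
  dimnames(m) <- list(ids, ids)
  m
}

test_that("PCoA handles degenerate and collinear configurations", {
  d0 <- as_sv_dist(matrix(0, 4, 4))
  ord0 <- sv_pcoa(d0, k = 2)
  expect_equal(unname(as.matrix(ord0$points[, -1])), matrix(0, 4, 2))

  # 3 points on a line at mutual distances 1, 1, 2
  dl <- as_sv_dist(rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0)))
  ordl <- sv_pcoa(dl, k = 2)
  ax1 <- sort(ordl$points$PCo1)
  expect_equal(diff(ax1), c(1, 1), tolerance = 1e-8)
  expect_lt(abs(ordl$eig[2]), 1e-8)

  # unit square: two equal positive eigenvalues
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  dsq <- as_sv_dist(as.matrix(dist(sq)))
  ordsq <- sv_pcoa(dsq, k = 3)
  expect_equal(ordsq$eig[1], ordsq$eig[2], tolerance = 1e-8)
  expect_gt(ordsq$eig[1], 0)
  expect_lt(abs(ordsq$eig[3]), 1e-8)
})

test_that("PCoA reconstructs Euclidean inter-point distances", {
  set.seed(9)
  x <- matrix(rnorm(15 * 4), 15, 4)
  d <- as_sv_dist(as.matrix(dist(x)), sprintf("s%d", 1:15))
  ord <- sv_pcoa(d, k = 14)
  rec <- as.matrix(dist(as.matrix(ord$points[, -1])))
  expect_equal(unname(rec), unname(unclass(d)[1:15, 1:15]), tolerance = 1e-8)
})

test_that("PCoA refuses undefined distance entries", {
  d <- as_sv_dist(matrix(0.5, 3, 3)); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- NA
  expect_error(sv_pcoa(d), "undefined")
})

test_that("PERMANOVA P is exact on the enumerable two-group toy", {
  m <- as_sv_dist(matrix(1, 6, 6))
  m[1:3, 1:3] <- 0; m[4:6, 4:6] <- 0; diag(m) <- 0
  meta <- data.frame(sample_id = sprintf("s%d", 1:6),
                     g = factor(rep(c("a", "b"), each = 3)))
  pv <- sv_permanova(m, ~ g, data = meta, exact = TRUE)
  # oracle: 20 distinct 3/3 assignments, 2 reproduce the separation
  expect_equal(tidy(pv)$p[1], 2 / 20)
  expect_equal(tidy(pv)$r2[1], 1)
})

test_that("PERMANOVA sequential decomposition matches vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(21)
  x <- matrix(rnorm(20 * 3), 20, 3)
  d <- as_sv_dist(as.matrix(dist(x)), sprintf("s%d", 1:20))
  meta <- data.frame(sample_id = sprintf("s%d", 1:20),
                     g = factor(rep(1:2, 10)), z = rnorm(20))
  mine <- tidy(sv_permanova(d, ~ g + z, data = meta, n_perm = 99, seed = 1))
  ref <- vegan::adonis2(stats::as.dist(d) ~ g + z, data = meta,
                        permutations = 99, by = "terms")
  expect_equal(mine$ss[1:2], ref$SumOfSqs[1:2], tolerance = 1e-10)
  expect_equal(mine$r2[1:2], ref$R2[1:2], tolerance = 1e-10)
  expect_equal(mine$f[1:2], ref$F[1:2], tolerance = 1e-10)
  expect_equal(sum(mine$r2[1:3]), 1 + mine$r2[4] - 1, tolerance = 1e-9)
})

test_that("PERMANOVA R2 partitions to one and P is seed-reproducible", {
  set.seed(2)
  x <- matrix(rnorm(12 * 2), 12, 2)
  d <- as_sv_dist(as.matrix(dist(x)), sprintf("s%d", 1:12))
  meta <- data.frame(sample_id = sprintf("s%d", 1:12),
                     g = factor(rep(1:3, 4)))
  p1 <- sv_permanova(d, ~ g, data = meta, n_perm = 199, seed = 5)
  p2 <- sv_permanova(d, ~ g, data = meta, n_perm = 199, seed = 5)
  expect_identical(tidy(p1)$p, tidy(p2)$p)
  tab <- tidy(p1)
  expect_equal(sum(tab$r2[tab$term != "Total"]), 1, tolerance = 1e-9)
  expect_gte(tab$p[1], 1 / 200)
  expect_lte(tab$p[1], 1)
})

test_that("a constant model term is flagged with undefined F", {
  set.seed(4)
  x <- matrix(rnorm(10 * 2), 10, 2)
  d <- as_sv_dist(as.matrix(dist(x)), sprintf("s%d", 1:10))
  meta <- data.frame(sample_id = sprintf("s%d", 1:10),
                     g = factor(rep(1:2, 5)), const = 1)
  pv <- tidy(sv_permanova(d, ~ g + const, data = meta, n_perm = 49, seed = 1))
  expect_true(is.na(pv$f[pv$term == "const"]))
  expect_true(is.na(pv$p[pv$term == "const"]))
})

test_that("variance partitioning gives zero incremental R2 to a duplicated block", {
  set.seed(6)
  x <- matrix(rnorm(18 * 3), 18, 3)
  d <- as_sv_dist(as.matrix(dist(x)), sprintf("s%d", 1:18))
  meta <- data.frame(sample_id = sprintf("s%d", 1:18),
                     a1 = rnorm(18), a2 = rnorm(18))
  meta$b1 <- meta$a1; meta$b2 <- meta$a2
  vp <- tidy(variance_partition(d, meta,
                                blocks = list(first = c("a1", "a2"),
                                              dup = c("b1", "b2")),
                                n_perm = 49, seed = 1))
  expect_gt(vp$r2[vp$term == "first"], 0)
  expect_equal(vp$r2[vp$term == "dup"], 0, tolerance = 1e-9)
})

test_that("abundance-driven distances put most variance on the abundance block", {
  set.seed(8)
  n <- 40
  pcs <- matrix(rnorm(n * 2), n, 2)
  pcs[1:20, 1] <- pcs[1:20, 1] + 4          # two abundance clusters
  d <- as_sv_dist(as.matrix(dist(pcs)), sprintf("s%d", 1:n))
  meta <- data.frame(sample_id = sprintf("s%d", 1:n),
                     p1 = pcs[, 1], p2 = pcs[, 2],
                     cohort = factor(rep(1:2, n / 2)))
  vp <- tidy(variance_partition(d, meta,
                                blocks = list(abundance = c("p1", "p2"),
                                              cohort = "cohort"),
                                n_perm = 99, seed = 1))
  expect_gt(vp$r2[vp$term == "abundance"], vp$r2[vp$term == "cohort"])
  expect_lt(vp$p[vp$term == "abundance"], 0.05)
})

test_that("axis group tests behave at the null and under strong separation", {
  pts <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                        PCo1 = rep(c(-1, 0, 1), 2), PCo2 = 0)
  ord <- structure(list(points = pts, eig = c(2, 0), var_explained = c(1, 0),
                        k = 2), class = "sv_pcoa")
  same <- axis_group_test(ord, 1, rep(c("a", "b"), each = 3))
  expect_lt(same$f, 1e-10)
  expect_gt(same$p, 0.99)

  set.seed(10)
  y <- c(rnorm(20), rnorm(20) + 10)
  ord2 <- structure(list(points = tibble::tibble(
    sample_id = sprintf("s%d", 1:40), PCo1 = y, PCo2 = 0),
    eig = c(2, 0), var_explained = c(1, 0), k = 2), class = "sv_pcoa")
  sep <- axis_group_test(ord2, 1, rep(c("a", "b"), each = 20))
  expect_lt(sep$p, 1e-6)
  expect_error(axis_group_test(ord2, 1, rep("a", 40)), "2 groups")
})

test_that("residualized axes are orthogonal to the covariates", {
  set.seed(12)
  n <- 30
  cov <- tibble::tibble(sample_id = sprintf("s%d", 1:n), PC1 = rnorm(n))
  y <- 2 * cov$PC1 + rnorm(n)
  ord <- structure(list(points = tibble::tibble(sample_id = cov$sample_id,
                                                PCo1 = y),
                        eig = 1, var_explained = 1, k = 1),
                   class = "sv_pcoa")
  res <- residualize_axes(ord, cov)
  expect_lt(abs(cor(res$points$PCo1, cov$PC1)), 1e-10)
})
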