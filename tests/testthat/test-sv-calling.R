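test_that("min_samp_cutoff is the smallest integer >= 10% of n", {
  expect_identical(min_samp_cutoff(164), 17L)
  expect_identical(min_samp_cutoff(338), 34L)
  expect_identical(min_samp_cutoff(100), 10L)
  expect_identical(min_samp_cutoff(1), 1L)
  expect_error(min_samp_cutoff(0), "integer")
})

test_that("normalization is median-based, scale-invariant, and flags presence", {
  m <- matrix(10, nrow = 3, ncol = 20,
              dimnames = list(c("a", "b", "c"), NULL))
  m["b", ] <- 20                      # doubled depths
  m["c", ] <- 0; m["c", 1] <- 5       # 5% breadth -> absent
  norm <- normalize_coverage(cov_from_matrix(m))
  pres <- sv_presence(norm)
  expect_true(all(pres$present[pres$sample_id %in% c("a", "b")]))
  expect_false(pres$present[pres$sample_id == "c"])
  ra <- norm$ratio[norm$sample_id == "a"]
  rb <- norm$ratio[norm$sample_id == "b"]
  expect_equal(ra, rep(1, 20))
  expect_equal(ra, rb)                # scale invariance
  expect_true(all(is.na(norm$ratio[norm$sample_id == "c"])))
})

test_that("an all-zero matrix yields all-absent samples without error", {
  norm <- normalize_coverage(cov_from_matrix(matrix(0, 4, 10)))
  expect_true(all(!sv_presence(norm)$present))
})

make_deletion_cov <- function(n = 20, bins = 30, del_bins = 11:13,
                              carriers = seq_len(n / 2), depth = 10) {
  m <- matrix(depth, n, bins, dimnames = list(sprintf("s%02d", 1:n), NULL))
  m[carriers, del_bins] <- 0
  m
}

test_that("a half-prevalence deletion block is called as one dSV with exact bounds", {
  norm <- normalize_coverage(cov_from_matrix(make_deletion_cov()))
  cat <- detect_sv_regions(norm, min_samples = 2)
  expect_identical(nrow(cat), 1L)
  expect_identical(cat$sv_class, "dSV")
  expect_equal(unname(cat$segments[[1]]), matrix(c(10L, 13L), 1))
  expect_identical(cat$region_id, "sp01:10-13")
})

test_that("deletions outside the prevalence band are not emitted", {
  low <- normalize_coverage(cov_from_matrix(make_deletion_cov(carriers = 1:2)))
  expect_identical(nrow(detect_sv_regions(low, min_samples = 2)), 0L)
  high <- normalize_coverage(cov_from_matrix(make_deletion_cov(carriers = 1:17)))
  expect_identical(nrow(detect_sv_regions(high, min_samples = 2)), 0L)
})

test_that("species below the present-sample cutoff are skipped with a reason", {
  norm <- normalize_coverage(cov_from_matrix(make_deletion_cov(n = 8)))
  cat <- detect_sv_regions(norm, min_samples = 10)
  expect_identical(nrow(cat), 0L)
  expect_match(attr(cat, "skipped"), "present samples < cutoff")
})

test_that("correlated separated blocks merge into one multi-segment region", {
  n <- 24
  m <- matrix(10, n, 40, dimnames = list(sprintf("s%02d", 1:n), NULL))
  scale <- seq(0.3, 3, length.out = n)    # identical per-sample signal
  m[, 6:8] <- 10 * scale
  m[, 21:23] <- 10 * scale
  norm <- normalize_coverage(cov_from_matrix(m))
  cat <- detect_sv_regions(norm, min_samples = 2)
  expect_identical(nrow(cat), 1L)
  expect_identical(cat$sv_class, "vSV")
  expect_identical(nrow(cat$segments[[1]]), 2L)
  expect_identical(cat$region_id, "sp01:5-8;20-23")
})

test_that("a region meeting both class rules is emitted once, as a dSV", {
  # half the samples at ratio 0 (deletion band) also makes the IQR large
  norm <- normalize_coverage(cov_from_matrix(make_deletion_cov()))
  cat <- detect_sv_regions(norm, min_samples = 2, var_thresh = 0.1)
  expect_identical(nrow(cat), 1L)
  expect_identical(cat$sv_class, "dSV")
})

test_that("genotyping follows the majority-of-bins rule and presence", {
  m <- make_deletion_cov()
  m[3, ] <- 0                              # absent sample
  norm <- normalize_coverage(cov_from_matrix(m))
  cat <- detect_sv_regions(norm, min_samples = 2)
  prof <- genotype_sv(cat, norm)
  g <- prof$genotype[match(sprintf("s%02d", 1:20), prof$sample_id)]
  expect_true(is.na(g[3]))
  expect_equal(g[c(1, 2, 4:10)], rep(1, 9))
  expect_equal(g[11:20], rep(0, 10))
})

test_that("a fully retained region genotypes 0 (dSV) and 1.0 (vSV)", {
  m <- matrix(10, 6, 10, dimnames = list(sprintf("s%02d", 1:6), NULL))
  norm <- normalize_coverage(cov_from_matrix(m))
  cat <- tibble::tibble(region_id = c("sp01:2-4", "sp01:6-8"),
                        species_id = "sp01",
                        sv_class = c("dSV", "vSV"),
                        segments = list(matrix(c(2L, 4L), 1),
                                        matrix(c(6L, 8L), 1)))
  prof <- genotype_sv(cat, norm)
  expect_equal(prof$genotype[prof$sv_class == "dSV"], rep(0, 6))
  expect_equal(prof$genotype[prof$sv_class == "vSV"], rep(1, 6))
})

test_that("genotyping errors on regions outside the genome", {
  norm <- normalize_coverage(cov_from_matrix(matrix(10, 4, 10)))
  cat <- tibble::tibble(region_id = "sp01:50-52", species_id = "sp01",
                        sv_class = "dSV",
                        segments = list(matrix(c(50L, 52L), 1)))
  expect_error(genotype_sv(cat, norm), "sp01:50-52")
})

test_that("projection equals genotyping and handles absent species", {
  norm <- normalize_coverage(cov_from_matrix(make_deletion_cov()))
  cat <- detect_sv_regions(norm, min_samples = 2)
  expect_identical(genotype_sv(cat, norm), project_sv(cat, norm))
  other <- normalize_coverage(cov_from_matrix(matrix(10, 5, 30),
                                              species = "sp99"))
  expect_warning(prof <- project_sv(cat, other), "absent")
  expect_true(all(is.na(prof$genotype)))
})

test_that("multiplying a sample's raw depths leaves genotypes unchanged", {
  m <- make_deletion_cov(depth = 10)
  norm1 <- normalize_coverage(cov_from_matrix(m))
  m2 <- m
  m2[5, ] <- m2[5, ] * 7.3
  norm2 <- normalize_coverage(cov_from_matrix(m2))
  cat <- detect_sv_regions(norm1, min_samples = 2)
  expect_equal(genotype_sv(cat, norm1)$genotype,
               genotype_sv(cat, norm2)$genotype)
})

test_that("profile filtering drops SVs observed below 5% and keeps 5% exactly", {
  n <- 100
  m <- matrix(NA_real_, n, 3,
              dimnames = list(sprintf("s%03d", 1:n),
                              c("sp01:1-2", "sp01:3-4", "sp01:5-6")))
  m[1:4, 1] <- 1      # 4% observed -> dropped
  m[1:5, 2] <- 1      # 5% exactly -> retained
  m[, 3] <- 0         # fully observed
  prof <- profile_from_matrix(m)
  out <- filter_sv_profile(prof)
  expect_identical(attr(out, "dropped"), "sp01:1-2")
  expect_setequal(unique(out$region_id), c("sp01:3-4", "sp01:5-6"))
  empty <- filter_sv_profile(prof[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("planted regions under Poisson noise are recovered with high bin overlap", {
  hits <- vapply(1:20, function(s) {
    set.seed(100 + s)
    n <- 40
    mu <- matrix(10, n, 50, dimnames = list(sprintf("s%02d", 1:n), NULL))
    mu[1:20, 21:25] <- 0
    m <- matrix(rpois(length(mu), mu), n, 50, dimnames = dimnames(mu))
    norm <- normalize_coverage(cov_from_matrix(m))
    cat <- detect_sv_regions(norm, min_samples = 4)
    found <- unlist(lapply(cat$segments[cat$sv_class == "dSV"], function(s2) {
      unlist(lapply(seq_len(nrow(s2)), function(i) s2[i, 1]:(s2[i, 2] - 1)))
    }))
    truth <- 20:24
    length(intersect(found, truth)) / length(union(found, truth))
  }, numeric(1))
  expect_true(mean(hits >= 0.9) >= 0.9)
})
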