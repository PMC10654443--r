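test_that("quartile coding follows the right-closed breakpoint convention", {
  expect_identical(quartile_code(1:8), c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_identical(quartile_code(c(1:8, NA)),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, NA))
  expect_warning(out <- quartile_code(rep(2, 10)), "distinct")
  expect_null(out)
  # rank invariance under a monotone transform
  set.seed(1)
  x <- stats::rexp(40)
  expect_identical(quartile_code(x), quartile_code(log(x)))
  expect_identical(quartile_code(x), quartile_code(rank(x)))
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(2)
  p <- runif(50)
  expect_true(all(bh_fdr(p) >= p))
  expect_true(all(bh_fdr(p) <= 1))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("covariate-free logistic beta equals the 2x2 log cross-product ratio", {
  # deleted: 8 responders / 2 non; retained: 2 responders / 8 non -> OR 16
  x <- c(rep(1, 10), rep(0, 10))
  y <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
  m <- matrix(x, ncol = 1,
              dimnames = list(sprintf("s%02d", 1:20), "sp01:1-2"))
  prof <- profile_from_matrix(m)
  clin <- tibble::tibble(sample_id = sprintf("s%02d", 1:20),
                         cohort = "c1", cancer_type = "melanoma",
                         age_bin = 1L, gender = 0L, response = y,
                         pfs12 = NA_integer_, irae = NA_integer_,
                         os_time = 100, os_event = 1L)
  rec <- sv_binary_assoc(prof, clin, "response", use_covariates = FALSE)
  expect_equal(rec$beta, log(16), tolerance = 1e-6)
  expect_equal(rec$effect, 16, tolerance = 1e-5)
})

test_that("subject and responder filters exclude under-powered comparisons", {
  m <- matrix(c(rep(1, 5), rep(0, 4), rep(NA, 11)), ncol = 1,
              dimnames = list(sprintf("s%02d", 1:20), "sp01:1-2"))
  clin <- null_clinical(20)
  clin$sample_id <- sprintf("s%02d", 1:20)
  rec <- sv_binary_assoc(profile_from_matrix(m), clin, "response")
  expect_match(rec$flag, "9 subjects < 10")
  expect_true(is.na(rec$beta))

  m2 <- matrix(rep(0:1, 10), ncol = 1,
               dimnames = list(sprintf("s%02d", 1:20), "sp01:1-2"))
  clin2 <- clin
  clin2$response <- c(rep(1, 2), rep(0, 18))
  rec2 <- sv_binary_assoc(profile_from_matrix(m2), clin2, "response")
  expect_match(rec2$flag, "2 responders < 3")
})

test_that("survival association applies the 20-subject floor and event checks", {
  set.seed(5)
  clin <- null_clinical(19)
  m <- matrix(rbinom(19, 1, 0.5), ncol = 1,
              dimnames = list(clin$sample_id, "sp01:1-2"))
  rec <- sv_survival_assoc(profile_from_matrix(m), clin)
  expect_match(rec$flag, "19 subjects < 20")

  clin2 <- null_clinical(30)
  clin2$os_event <- 0L
  m2 <- matrix(rbinom(30, 1, 0.5), ncol = 1,
               dimnames = list(clin2$sample_id, "sp01:1-2"))
  rec2 <- sv_survival_assoc(profile_from_matrix(m2), clin2)
  expect_match(rec2$flag, "no events")
})

test_that("Cox association recovers a planted hazard ratio", {
  set.seed(6)
  n <- 400
  clin <- null_clinical(n)
  x <- rbinom(n, 1, 0.5)
  clin$os_time <- rexp(n, rate = (1 / 365) * 2^x)
  clin$os_event <- 1L
  m <- matrix(x, ncol = 1, dimnames = list(clin$sample_id, "sp01:1-2"))
  rec <- sv_survival_assoc(profile_from_matrix(m), clin)
  expect_lt(abs(rec$beta - log(2)), 0.2)
  expect_true(rec$ci_lo < 2 && 2 < rec$ci_hi)
})

test_that("vSV genotypes enter as quartile codes", {
  set.seed(7)
  n <- 80
  clin <- null_clinical(n)
  g <- stats::rexp(n)
  m <- matrix(g, ncol = 1, dimnames = list(clin$sample_id, "sp01:1-2"))
  prof <- profile_from_matrix(m, sv_class = "vSV")
  rec <- sv_binary_assoc(prof, clin, "response", use_covariates = FALSE)
  # oracle: fit the quartile-coded model directly
  ref <- glm(clin$response ~ quartile_code(g), family = binomial())
  expect_equal(rec$beta, unname(coef(ref)[2]), tolerance = 1e-9)

  const <- profile_from_matrix(
    matrix(1, n, 1, dimnames = list(clin$sample_id, "sp01:3-4")), "vSV")
  rec2 <- sv_binary_assoc(const, clin, "response")
  expect_match(rec2$flag, "4 distinct")
})

test_that("FDR is adjusted within feature class, not pooled across classes", {
  set.seed(8)
  n <- 60
  clin <- null_clinical(n)
  m <- matrix(c(rbinom(n, 1, 0.5), stats::rexp(n), stats::rexp(n)), ncol = 3,
              dimnames = list(clin$sample_id,
                              c("sp01:1-2", "sp01:3-4", "sp01:5-6")))
  prof <- profile_from_matrix(m, sv_class = c("dSV", "vSV", "vSV"))
  rec <- sv_binary_assoc(prof, clin, "response")
  for (cl in unique(rec$feature_class)) {
    sub <- rec[rec$feature_class == cl & !is.na(rec$p), ]
    expect_equal(sub$fdr, bh_fdr(sub$p))
  }
  pooled <- bh_fdr(rec$p[!is.na(rec$p)])
  expect_false(isTRUE(all.equal(pooled, rec$fdr[!is.na(rec$p)])))
})

test_that("abundance association flags degenerate fits and reports ORs", {
  set.seed(9)
  n <- 120
  clin <- null_clinical(n)
  abund <- tibble::tibble(sample_id = clin$sample_id,
                          sp01 = stats::rexp(n) / 50,
                          sp02 = 0.01)
  rec <- abundance_assoc(abund, clin, "response")
  expect_match(rec$flag[rec$feature_id == "sp02"], "constant")
  ok <- rec[rec$feature_id == "sp01", ]
  expect_false(is.na(ok$beta))
  expect_equal(ok$effect, exp(ok$beta))
  expect_true(ok$ci_lo < ok$effect && ok$effect < ok$ci_hi)
})

test_that("species SV-makeup PERMANOVA skips small or degenerate species", {
  set.seed(10)
  clin <- null_clinical(9)
  m <- matrix(rbinom(9, 1, 0.5), ncol = 1,
              dimnames = list(clin$sample_id, "sp01:1-2"))
  rec <- species_sv_makeup_assoc(profile_from_matrix(m), clin, "response")
  expect_match(rec$flag, "n = 9 < 10")

  clin2 <- null_clinical(30)
  m2 <- matrix(1, 30, 1, dimnames = list(clin2$sample_id, "sp01:1-2"))
  rec2 <- species_sv_makeup_assoc(profile_from_matrix(m2), clin2, "response")
  expect_match(rec2$flag, "degenerate")

  clin3 <- null_clinical(40)
  m3 <- matrix(rbinom(80, 1, 0.5), 40, 2,
               dimnames = list(clin3$sample_id, c("sp01:1-2", "sp01:5-6")))
  rec3 <- species_sv_makeup_assoc(profile_from_matrix(m3), clin3, "response",
                                  n_perm = 99)
  expect_true(is.na(rec3$flag))
  expect_true(rec3$p >= 1 / 100 && rec3$p <= 1)
})

test_that("log-rank test matches the hand-computed two-group toy", {
  clin <- tibble::tibble(os_time = c(1, 2, 3, 4, 5, 6),
                         os_event = 1L)
  lr <- km_logrank(clin, rep(c("a", "b"), each = 3))
  # hand computation: O_a = 3, E_a = 3/6 + 2/5 + 1/4, V = 0.25 + 0.24 + 0.1875
  expect_equal(lr$chisq, (3 - 1.15)^2 / 0.6775, tolerance = 1e-8)
  expect_equal(lr$p, pchisq((3 - 1.15)^2 / 0.6775, 1, lower.tail = FALSE))

  ident <- tibble::tibble(os_time = rep(c(1, 2, 3), 2), os_event = 1L)
  lr2 <- km_logrank(ident, rep(c("a", "b"), each = 3))
  expect_lt(lr2$chisq, 1e-10)
  expect_gt(lr2$p, 0.999)
  expect_error(km_logrank(ident, rep("a", 6)), "2 groups")
})

test_that("effect concordance is rank-based over shared features", {
  a <- tibble::tibble(feature_id = sprintf("f%d", 1:5), beta = c(1, 2, 3, 4, 5))
  b <- tibble::tibble(feature_id = sprintf("f%d", 1:5), beta = c(2, 4, 6, 8, 10))
  expect_equal(effect_concordance(a, b)$rho, 1)
  b_rev <- tibble::tibble(feature_id = sprintf("f%d", 1:5),
                          beta = c(5, 4, 3, 2, 1))
  expect_equal(effect_concordance(a, b_rev)$rho, -1)
  expect_error(effect_concordance(a[1:2, ], b[1:2, ]), "3 shared")
})

test_that("clinical summaries recover planted response, PFS12 and OS effects", {
  set.seed(13)
  n <- 3000
  clin <- tibble::tibble(
    sample_id = sprintf("s%04d", 1:n), cohort = "c1",
    cancer_type = rep(c("melanoma", "RCC"), c(2000, 1000)),
    age_bin = sample(1:4, n, TRUE), gender = rbinom(n, 1, 0.5),
    response = rbinom(n, 1, rep(c(0.51, 0.16), c(2000, 1000))),
    pfs12 = rbinom(n, 1, rep(c(0.488, 0.3), c(2000, 1000))),
    irae = rbinom(n, 1, 0.3),
    os_time = NA_real_, os_event = NA_integer_
  )
  hr_true <- 0.1
  clin$os_time <- rexp(n, rate = (1 / 200) * hr_true^clin$response)
  clin$os_event <- 1L
  s <- summarize_clinical(clin)
  mel <- s$rates[s$rates$cancer_type == "melanoma", ]
  rcc <- s$rates[s$rates$cancer_type == "RCC", ]
  expect_lt(abs(mel$response_rate - 0.51), 0.03)
  expect_lt(abs(rcc$response_rate - 0.16), 0.03)
  expect_lt(abs(mel$pfs12_rate - 0.488), 0.03)
  expect_lt(abs(s$response_os$hr - hr_true), 0.03)
  expect_lt(s$response_os$logrank_p, 1e-10)
})
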