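# Tiny in-code fixture builders used across test files.

# samples x bins depth matrix -> long coverage tibble
cov_from_matrix <- function(m, species = "sp01") {
  samples <- rownames(m) %||% sprintf("s%02d", seq_len(nrow(m)))
  tibble::tibble(
    species_id = species,
    sample_id = rep(samples, times = ncol(m)),
    bin_index = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
    depth = as.vector(m)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# samples x regions genotype matrix -> sv_profile tibble
profile_from_matrix <- function(m, sv_class = "dSV", species = "sp01") {
  samples <- rownames(m) %||% sprintf("s%02d", seq_len(nrow(m)))
  regions <- colnames(m) %||% sprintf("%s:%d-%d", species,
                                      seq_len(ncol(m)), seq_len(ncol(m)) + 1L)
  out <- tibble::tibble(
    sample_id = rep(samples, times = ncol(m)),
    region_id = rep(regions, each = nrow(m)),
    species_id = species,
    sv_class = rep(rep(sv_class, length.out = ncol(m)), each = nrow(m)),
    genotype = as.vector(m)
  )
  class(out) <- c("sv_profile", class(out))
  out
}

# Brute-force double-loop distance oracles, written independently of the
# matrix-algebra implementation.
oracle_jaccard <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ok <- !is.na(x[i, ]) & !is.na(x[j, ])
      if (!any(ok)) {
        d[i, j] <- NA_real_
        next
      }
      a <- sum(x[i, ok] == 1 & x[j, ok] == 1)
      u <- sum(x[i, ok] == 1 | x[j, ok] == 1)
      d[i, j] <- if (u == 0) 0 else 1 - a / u
    }
  }
  diag(d) <- 0
  d
}

oracle_canberra <- function(x, scaled = TRUE) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      terms <- c()
      for (k in seq_len(ncol(x))) {
        xi <- x[i, k]; xj <- x[j, k]
        if (is.na(xi) || is.na(xj) || (xi == 0 && xj == 0)) next
        terms <- c(terms, abs(xi - xj) / (xi + xj))
      }
      d[i, j] <- if (length(terms) == 0) NA_real_ else {
        if (scaled) mean(terms) else sum(terms)
      }
    }
  }
  diag(d) <- 0
  d
}

# clinical table with independent covariates for association null tests
null_clinical <- function(n, cohort = "cohort1", event_rate = 0.5) {
  tibble::tibble(
    sample_id = sprintf("%s_s%04d", cohort, seq_len(n)),
    cohort = cohort, cancer_type = "melanoma",
    age_bin = sample(1:4, n, replace = TRUE),
    gender = rbinom(n, 1, 0.5),
    response = rbinom(n, 1, event_rate),
    pfs12 = rbinom(n, 1, event_rate),
    irae = rbinom(n, 1, 0.3),
    os_time = rexp(n, 1 / 365),
    os_event = rbinom(n, 1, 0.8)
  )
}
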