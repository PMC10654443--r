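#' Quartile-code a variable SV genotype
#'
#' Maps continuous copy-ratio genotypes to ordinal codes 1-4 by the 25%,
#' 50% and 75% empirical quantiles (type-7, right-closed: a value equal to a
#' breakpoint falls in the lower bucket). The codes are rank-based, so any
#' monotone transform of the genotypes gives identical codes. Missing values
#' stay missing.
#'
#' @param values Numeric vector of vSV genotypes.
#' @return Integer codes in 1..4 (NA preserved), or `NULL` (with a warning)
#'   when fewer than 4 distinct non-missing values make quartile coding
#'   meaningless.
#' @export
quartile_code <- function(values) {
  obs <- values[!is.na(values)]
  if (length(unique(obs)) < 4) {
    warn("fewer than 4 distinct values; feature unusable for quartile coding")
    return(NULL)
  }
  q <- quantile(obs, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  code <- 1L + (values > q[1]) + (values > q[2]) + (values > q[3])
  as.integer(code)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment. Association classes (dSVs, vSVs, species
#' abundance) are always adjusted independently of one another; this helper
#' adjusts one such class's P values.
#'
#' @param p Numeric vector of P values in `[0, 1]`.
#' @return Adjusted P values (monotone in the sorted order, capped at 1).
#' @export
bh_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("P values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# Fit one logistic association and return an AssocRecord row.
# x: numeric predictor (dSV 0/1 or vSV quartile code); covariates entered
# alongside. Flags separation / non-convergence instead of reporting an
# effect.
fit_logistic_record <- function(df, feature_id, feature_class, outcome_name,
                                cohort, use_covariates = TRUE) {
  n_used <- nrow(df)
  n_events <- sum(df$y)
  fail <- function(reason) {
    tibble(feature_id = feature_id, feature_class = feature_class,
           outcome = outcome_name, cohort = cohort,
           n = n_used, n_events = n_events,
           beta = NA_real_, se = NA_real_, effect = NA_real_,
           ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
           flag = reason)
  }
  if (sd(df$x) == 0) return(fail("degenerate: constant feature"))
  if (sd(df$y) == 0) return(fail("degenerate: constant outcome"))
  f <- if (use_covariates) y ~ x + age_bin + gender else y ~ x
  fit <- suppressWarnings(glm(f, data = df, family = binomial()))
  beta <- coef(fit)[["x"]]
  se <- sqrt(vcov(fit)["x", "x"])
  if (!fit$converged || !is.finite(beta) || !is.finite(se) || se > 10) {
    return(fail("separation or non-convergence"))
  }
  tibble(feature_id = feature_id, feature_class = feature_class,
         outcome = outcome_name, cohort = cohort,
         n = n_used, n_events = n_events,
         beta = beta, se = se, effect = exp(beta),
         ci_lo = exp(beta - 1.959963984540054 * se),
         ci_hi = exp(beta + 1.959963984540054 * se),
         p = 2 * pnorm(-abs(beta / se)), flag = NA_character_)
}

fit_cox_record <- function(df, feature_id, feature_class, cohort,
                           use_covariates = TRUE) {
  n_used <- nrow(df)
  n_events <- sum(df$os_event)
  fail <- function(reason) {
    tibble(feature_id = feature_id, feature_class = feature_class,
           outcome = "os", cohort = cohort, n = n_used, n_events = n_events,
           beta = NA_real_, se = NA_real_, effect = NA_real_,
           ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_, flag = reason)
  }
  if (n_events == 0) return(fail("no events (all censored)"))
  if (sd(df$x) == 0) return(fail("degenerate: constant feature"))
  f <- if (use_covariates) {
    survival::Surv(os_time, os_event) ~ x + age_bin + gender
  } else {
    survival::Surv(os_time, os_event) ~ x
  }
  fit <- tryCatch(
    suppressWarnings(survival::coxph(f, data = df)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(fail("cox fit failed"))
  beta <- coef(fit)[["x"]]
  se <- sqrt(vcov(fit)["x", "x"])
  if (!is.finite(beta) || !is.finite(se) || se > 10) {
    return(fail("monotone likelihood or non-convergence"))
  }
  tibble(feature_id = feature_id, feature_class = feature_class,
         outcome = "os", cohort = cohort, n = n_used, n_events = n_events,
         beta = beta, se = se, effect = exp(beta),
         ci_lo = exp(beta - 1.959963984540054 * se),
         ci_hi = exp(beta + 1.959963984540054 * se),
         p = 2 * pnorm(-abs(beta / se)), flag = NA_character_)
}

#' Per-cohort association of species abundance with a binary outcome
#'
#' Fits, within each cohort, `outcome ~ abundance + age_bin + gender`
#' (logistic) for every species, listwise-deleting samples with missing
#' outcome or covariates. Degenerate fits (constant abundance, separation,
#' non-convergence) are flagged rather than reported as effects.
#'
#' @param abund Wide abundance tibble (`sample_id` + species columns).
#' @param clin Clinical tibble with `sample_id`, `cohort`, `age_bin`,
#'   `gender` and the outcome column.
#' @param outcome Name of the binary outcome column (`"response"`,
#'   `"pfs12"` or `"irae"`).
#' @param use_covariates Adjust for age bin and gender (default) or fit the
#'   crude model.
#' @return Tibble of association records with per-cohort, per-class BH FDR
#'   (`fdr` column).
#' @export
abundance_assoc <- function(abund, clin, outcome, use_covariates = TRUE) {
  assert_columns(clin, c("sample_id", "cohort", "age_bin", "gender", outcome),
                 "clin")
  species <- setdiff(names(abund), "sample_id")
  recs <- list()
  for (co in sort(unique(clin$cohort))) {
    cl <- clin[clin$cohort == co, ]
    for (sp in species) {
      df <- tibble(
        sample_id = cl$sample_id,
        y = cl[[outcome]], age_bin = cl$age_bin, gender = cl$gender,
        x = abund[[sp]][match(cl$sample_id, abund$sample_id)]
      )
      df <- df[complete.cases(df), ]
      if (nrow(df) == 0) next
      recs[[length(recs) + 1]] <-
        fit_logistic_record(df, sp, "abundance", outcome, co, use_covariates)
    }
  }
  add_class_fdr(bind_rows(recs))
}

#' Per-cohort association of single SVs with a binary outcome
#'
#' For every SV and cohort, fits `outcome ~ SV + age_bin + gender`
#' (logistic). Deletion SVs enter as 0/1; variable SVs as their
#' within-cohort quartile code modeled as a continuous 1-4 predictor. An SV
#' is tested in a cohort only with at least `min_n` usable subjects and at
#' least `min_events` responders/events. BH FDR is applied per cohort,
#' outcome and SV class.
#'
#' @param profile An `sv_profile`.
#' @param clin Clinical tibble (see [abundance_assoc()]).
#' @param outcome Binary outcome column name.
#' @param min_n Minimum usable subjects per comparison.
#' @param min_events Minimum responders (outcome = 1) per comparison.
#' @inheritParams abundance_assoc
#' @return Tibble of association records; excluded SVs appear with a
#'   `flag` explaining the filter that removed them.
#' @export
sv_binary_assoc <- function(profile, clin, outcome, min_n = 10,
                            min_events = 3, use_covariates = TRUE) {
  assert_columns(clin, c("sample_id", "cohort", "age_bin", "gender", outcome),
                 "clin")
  recs <- list()
  for (co in sort(unique(clin$cohort))) {
    cl <- clin[clin$cohort == co, ]
    for (rid in sort(unique(profile$region_id))) {
      pr <- profile[profile$region_id == rid, ]
      klass <- pr$sv_class[1]
      df <- tibble(
        y = cl[[outcome]], age_bin = cl$age_bin, gender = cl$gender,
        x = pr$genotype[match(cl$sample_id, pr$sample_id)]
      )
      df <- df[complete.cases(df), ]
      skip <- function(reason) {
        tibble(feature_id = rid, feature_class = klass, outcome = outcome,
               cohort = co, n = nrow(df), n_events = sum(df$y),
               beta = NA_real_, se = NA_real_, effect = NA_real_,
               ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
               flag = reason)
      }
      if (nrow(df) < min_n) {
        recs[[length(recs) + 1]] <- skip(sprintf(
          "excluded: %d subjects < %d", nrow(df), min_n))
        next
      }
      if (sum(df$y) < min_events) {
        recs[[length(recs) + 1]] <- skip(sprintf(
          "excluded: %d responders < %d", sum(df$y), min_events))
        next
      }
      if (klass == "vSV") {
        qc <- withCallingHandlers(quartile_code(df$x),
                                  warning = function(w) {
                                    invokeRestart("muffleWarning")
                                  })
        if (is.null(qc)) {
          recs[[length(recs) + 1]] <-
            skip("excluded: < 4 distinct values for quartile coding")
          next
        }
        df$x <- as.numeric(qc)
      }
      recs[[length(recs) + 1]] <-
        fit_logistic_record(df, rid, klass, outcome, co, use_covariates)
    }
  }
  add_class_fdr(bind_rows(recs))
}

#' Per-cohort Cox association of single SVs with overall survival
#'
#' Fits `Surv(os_time, os_event) ~ SV + age_bin + gender` for every SV and
#' cohort, with variable SVs quartile-coded. An SV is tested only with at
#' least `min_n` usable subjects and at least one event.
#'
#' @inheritParams sv_binary_assoc
#' @param min_n Minimum usable subjects per comparison.
#' @return Tibble of association records (effect column holds the HR).
#' @export
sv_survival_assoc <- function(profile, clin, min_n = 20,
                              use_covariates = TRUE) {
  assert_columns(clin, c("sample_id", "cohort", "age_bin", "gender",
                         "os_time", "os_event"), "clin")
  recs <- list()
  for (co in sort(unique(clin$cohort))) {
    cl <- clin[clin$cohort == co, ]
    for (rid in sort(unique(profile$region_id))) {
      pr <- profile[profile$region_id == rid, ]
      klass <- pr$sv_class[1]
      df <- tibble(
        os_time = cl$os_time, os_event = cl$os_event,
        age_bin = cl$age_bin, gender = cl$gender,
        x = pr$genotype[match(cl$sample_id, pr$sample_id)]
      )
      df <- df[complete.cases(df), ]
      if (nrow(df) < min_n) {
        recs[[length(recs) + 1]] <- tibble(
          feature_id = rid, feature_class = klass, outcome = "os",
          cohort = co, n = nrow(df), n_events = sum(df$os_event),
          beta = NA_real_, se = NA_real_, effect = NA_real_,
          ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
          flag = sprintf("excluded: %d subjects < %d", nrow(df), min_n))
        next
      }
      if (klass == "vSV") {
        qc <- withCallingHandlers(quartile_code(df$x),
                                  warning = function(w) {
                                    invokeRestart("muffleWarning")
                                  })
        if (is.null(qc)) {
          recs[[length(recs) + 1]] <- tibble(
            feature_id = rid, feature_class = klass, outcome = "os",
            cohort = co, n = nrow(df), n_events = sum(df$os_event),
            beta = NA_real_, se = NA_real_, effect = NA_real_,
            ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
            flag = "excluded: < 4 distinct values for quartile coding")
          next
        }
        df$x <- as.numeric(qc)
      }
      recs[[length(recs) + 1]] <-
        fit_cox_record(df, rid, klass, co, use_covariates)
    }
  }
  add_class_fdr(bind_rows(recs))
}

# BH FDR within (cohort, outcome, feature_class) over testable records.
add_class_fdr <- function(records) {
  if (nrow(records) == 0) return(records)
  records |>
    group_by(.data$cohort, .data$outcome, .data$feature_class) |>
    mutate(fdr = {
      f <- rep(NA_real_, dplyr::n())
      ok <- !is.na(.data$p)
      f[ok] <- bh_fdr(.data$p[ok])
      f
    }) |>
    ungroup()
}

#' Species-level SV-makeup association via PERMANOVA
#'
#' For each species with enough genotyped samples, builds the species'
#' combined SV distance (Jaccard over its dSVs averaged with Canberra over
#' its vSVs) and tests `distance ~ outcome + age_bin + gender` by PERMANOVA.
#' Species with fewer than `min_n` usable samples are skipped, as are
#' species whose genotypes are identical across samples (zero distance
#' everywhere).
#'
#' @inheritParams sv_binary_assoc
#' @param n_perm Permutations per species.
#' @param seed RNG seed.
#' @param min_n Minimum genotyped samples per species.
#' @return Tibble with one row per species: outcome-term `r2`, pseudo-`f`,
#'   permutation `p` (or a `flag`).
#' @export
species_sv_makeup_assoc <- function(profile, clin, outcome, n_perm = 999,
                                    seed = 1, min_n = 10) {
  assert_columns(clin, c("sample_id", "cohort", "age_bin", "gender", outcome),
                 "clin")
  out <- list()
  for (sp in sort(unique(profile$species_id))) {
    pr <- profile[profile$species_id == sp, ]
    genotyped <- pr |>
      group_by(.data$sample_id) |>
      summarise(any_obs = any(!is.na(.data$genotype)), .groups = "drop")
    cl <- clin |>
      inner_join(filter(genotyped, .data$any_obs), by = "sample_id") |>
      filter(!is.na(.data[[outcome]]), !is.na(.data$age_bin),
             !is.na(.data$gender))
    res_row <- function(r2, f, p, flag) {
      tibble(species_id = sp, outcome = outcome, n = nrow(cl),
             r2 = r2, f = f, p = p, flag = flag)
    }
    if (nrow(cl) < min_n) {
      out[[length(out) + 1]] <- res_row(NA, NA, NA, sprintf(
        "skipped: n = %d < %d", nrow(cl), min_n))
      next
    }
    pr_used <- pr[pr$sample_id %in% cl$sample_id, ]
    d <- tryCatch(sv_distance(pr_used), error = function(e) NULL)
    if (is.null(d) || all(d == 0) || anyNA(d)) {
      out[[length(out) + 1]] <- res_row(NA, NA, NA,
                                        "degenerate: constant or undefined SV distance")
      next
    }
    fml <- stats::as.formula(paste("~", outcome, "+ age_bin + gender"))
    pv <- sv_permanova(d, fml, data = cl, n_perm = n_perm,
                       seed = derive_seed(seed, sp))
    row1 <- pv$table[1, ]
    out[[length(out) + 1]] <- res_row(row1$r2, row1$f, row1$p, NA_character_)
  }
  bind_rows(out)
}

#' Kaplan-Meier curves and log-rank test between groups
#'
#' @param clin Clinical tibble with `os_time` and `os_event`.
#' @param groups Vector of group labels aligned with `clin` rows (or the
#'   name of a column in `clin`).
#' @return A `km_logrank` list: `curves` (tidy product-limit estimates),
#'   `chisq`, `df`, `p` from the two-sided log-rank test.
#' @export
km_logrank <- function(clin, groups) {
  assert_columns(clin, c("os_time", "os_event"), "clin")
  if (is.character(groups) && length(groups) == 1 && groups %in% names(clin)) {
    groups <- clin[[groups]]
  }
  g <- factor(groups)
  if (nlevels(g) < 2) abort("need at least 2 groups")
  df <- data.frame(os_time = clin$os_time, os_event = clin$os_event, g = g)
  fit <- survival::survfit(survival::Surv(os_time, os_event) ~ g, data = df)
  sd_ <- survival::survdiff(survival::Surv(os_time, os_event) ~ g, data = df)
  k <- nlevels(g)
  curves <- tibble(
    group = rep(sub("^g=", "", rep(names(fit$strata), fit$strata)),
                times = 1),
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    surv = fit$surv, lower = fit$lower, upper = fit$upper
  )
  structure(list(curves = curves, chisq = sd_$chisq, df = k - 1,
                 p = pchisq(sd_$chisq, k - 1, lower.tail = FALSE)),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("<km_logrank> chisq = %.3f on %d df, log-rank P = %.3g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}

#' Effect-size concordance between two sets of associations
#'
#' Spearman correlation of effect sizes (betas) over the features shared by
#' two association tables — e.g. the same outcome in two cancer types.
#'
#' @param records_a,records_b Association tibbles with `feature_id` and
#'   `beta` columns.
#' @return Tibble with `n_shared`, `rho` and `p`.
#' @export
effect_concordance <- function(records_a, records_b) {
  a <- records_a[!is.na(records_a$beta), c("feature_id", "beta")]
  b <- records_b[!is.na(records_b$beta), c("feature_id", "beta")]
  shared <- inner_join(a, b, by = "feature_id", suffix = c("_a", "_b"))
  if (nrow(shared) < 3) abort("need at least 3 shared features")
  ct <- suppressWarnings(cor.test(shared$beta_a, shared$beta_b,
                                  method = "spearman"))
  tibble(n_shared = nrow(shared), rho = unname(ct$estimate), p = ct$p.value)
}

#' Cohort-level clinical summaries
#'
#' Response and PFS12 rates by cancer type, and the responder versus
#' non-responder overall-survival hazard ratio (unadjusted Cox) with its
#' log-rank P — the standard descriptive summaries of an ICI cohort table.
#'
#' @param clin Clinical tibble.
#' @return List with `rates` (tibble per cancer type: response and PFS12
#'   fractions) and `response_os` (tibble: HR, CI, log-rank P), the latter
#'   NULL when OS or response is unavailable.
#' @export
summarize_clinical <- function(clin) {
  rates <- clin |>
    group_by(.data$cancer_type) |>
    summarise(
      n = dplyr::n(),
      response_rate = mean(.data$response, na.rm = TRUE),
      pfs12_rate = mean(.data$pfs12, na.rm = TRUE),
      .groups = "drop"
    )
  response_os <- NULL
  ok <- !is.na(clin$response) & !is.na(clin$os_time) & !is.na(clin$os_event)
  if (sum(ok) > 2 && length(unique(clin$response[ok])) == 2) {
    df <- data.frame(os_time = clin$os_time[ok], os_event = clin$os_event[ok],
                     x = clin$response[ok], age_bin = 0, gender = 0)
    rec <- fit_cox_record(df, "response", "clinical", "all",
                          use_covariates = FALSE)
    lr <- km_logrank(clin[ok, ], clin$response[ok])
    response_os <- tibble(hr = rec$effect, ci_lo = rec$ci_lo,
                          ci_hi = rec$ci_hi, logrank_p = lr$p)
  }
  list(rates = rates, response_os = response_os)
}
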