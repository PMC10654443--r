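#' DerSimonian-Laird random-effects pooling
#'
#' Pools per-cohort effects with the DerSimonian-Laird moment estimator:
#' fixed-effect weights `w = 1/se^2` give Cochran's
#' `Q = sum(w * (beta - beta_FE)^2)`; the between-cohort variance is
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))`; random
#' weights `w* = 1/(se^2 + tau2)` give the pooled effect and its SE
#' `(sum(w*))^(-1/2)`. Heterogeneity P comes from `Q ~ chi-square(k - 1)`.
#' A single cohort passes through unchanged with `tau2` undefined.
#'
#' @param betas Per-cohort effect estimates (log-OR or log-HR).
#' @param ses Matching standard errors (positive).
#' @return One-row tibble: `k`, `beta`, `se`, `ci_lo`, `ci_hi` (on the
#'   exponentiated scale), `z`, `p`, `tau2`, `q`, `p_het`.
#' @export
dl_pool <- function(betas, ses) {
  if (length(betas) != length(ses)) abort("betas and ses differ in length")
  if (length(betas) == 0) abort("no cohorts to pool")
  if (any(!is.finite(ses) | ses <= 0)) abort("ses must be positive and finite")
  k <- length(betas)
  if (k == 1) {
    return(tibble(
      k = 1L, beta = betas, se = ses,
      ci_lo = exp(betas - 1.959963984540054 * ses),
      ci_hi = exp(betas + 1.959963984540054 * ses),
      z = betas / ses, p = 2 * pnorm(-abs(betas / ses)),
      tau2 = NA_real_, q = NA_real_, p_het = NA_real_
    ))
  }
  w <- 1 / ses^2
  beta_fe <- sum(w * betas) / sum(w)
  q <- sum(w * (betas - beta_fe)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (ses^2 + tau2)
  beta <- sum(wr * betas) / sum(wr)
  se <- sqrt(1 / sum(wr))
  z <- beta / se
  tibble(
    k = as.integer(k), beta = beta, se = se,
    ci_lo = exp(beta - 1.959963984540054 * se),
    ci_hi = exp(beta + 1.959963984540054 * se),
    z = z, p = 2 * pnorm(-abs(z)),
    tau2 = tau2, q = q,
    p_het = pchisq(q, k - 1, lower.tail = FALSE)
  )
}

#' Replication decision for a multi-cohort meta-analysis result
#'
#' A pooled association is a replicated candidate only when all three
#' criteria hold: (1) `p_meta <= 0.01`; (2) heterogeneity `p_het > 0.05`;
#' (3) per-cohort P at or below 0.2 in at least two cohorts whose effects
#' trend in the same direction (sign of beta; a beta of exactly zero counts
#' as neither direction).
#'
#' @param p_meta Pooled P value (raw, not FDR-adjusted).
#' @param p_het Cochran's Q heterogeneity P value.
#' @param cohort_p Per-cohort P values.
#' @param cohort_beta Per-cohort effect estimates.
#' @return `"replicated-candidate"` or `"not-significant"`.
#' @export
replication_decision <- function(p_meta, p_het, cohort_p, cohort_beta) {
  if (anyNA(c(p_meta, p_het))) return("unevaluable")
  ok <- !is.na(cohort_p) & !is.na(cohort_beta) & cohort_p <= 0.2 &
    cohort_beta != 0
  support <- max(sum(ok & cohort_beta > 0), sum(ok & cohort_beta < 0))
  if (p_meta <= 0.01 && p_het > 0.05 && support >= 2) {
    "replicated-candidate"
  } else {
    "not-significant"
  }
}

#' Significance decision when only one cohort measures an outcome
#'
#' @param fdr_p FDR-adjusted P value of the single-cohort association.
#' @return `"single-cohort-candidate"` when `fdr_p <= 0.1`,
#'   `"not-significant"` otherwise, `"unevaluable"` when missing.
#' @export
single_cohort_decision <- function(fdr_p) {
  if (is.na(fdr_p)) return("unevaluable")
  if (fdr_p <= 0.1) "single-cohort-candidate" else "not-significant"
}

#' Meta-analyze per-cohort association records
#'
#' Groups association records by feature, class and outcome, pools the
#' cohorts with usable (non-flagged) effects by DerSimonian-Laird, and
#' labels each pooled result with the replication rule (or, for
#' single-cohort outcomes, the FDR <= 0.1 rule). Cohort order never affects
#' the result.
#'
#' @param records Association tibble from [sv_binary_assoc()],
#'   [sv_survival_assoc()] or [abundance_assoc()] over one or more cohorts.
#' @return An `svmwas_meta` tibble: one row per (feature, outcome) with
#'   pooled effect, heterogeneity, per-cohort details (list-columns) and a
#'   `decision` label.
#' @export
meta_analyze <- function(records) {
  assert_columns(records, c("feature_id", "feature_class", "outcome",
                            "cohort", "beta", "se", "p"), "records")
  grp <- records |>
    arrange(.data$cohort) |>
    group_by(.data$feature_id, .data$feature_class, .data$outcome)
  out <- grp |>
    dplyr::group_modify(function(df, key) {
      usable <- df[!is.na(df$beta) & !is.na(df$se) & df$se > 0, ]
      base <- tibble(
        k = nrow(usable), n_total = sum(usable$n),
        cohorts = list(usable$cohort),
        cohort_beta = list(usable$beta), cohort_p = list(usable$p)
      )
      if (nrow(usable) == 0) {
        return(dplyr::bind_cols(base, tibble(
          beta = NA_real_, se = NA_real_, effect = NA_real_,
          ci_lo = NA_real_, ci_hi = NA_real_, z = NA_real_, p = NA_real_,
          tau2 = NA_real_, q = NA_real_, p_het = NA_real_,
          decision = "unevaluable")))
      }
      pooled <- dl_pool(usable$beta, usable$se)
      decision <- if (length(unique(df$cohort)) >= 2) {
        if (nrow(usable) >= 2) {
          replication_decision(pooled$p, pooled$p_het,
                               usable$p, usable$beta)
        } else {
          "unevaluable"
        }
      } else {
        single_cohort_decision(usable$fdr %||% NA_real_)
      }
      dplyr::bind_cols(base, tibble(
        beta = pooled$beta, se = pooled$se, effect = exp(pooled$beta),
        ci_lo = pooled$ci_lo, ci_hi = pooled$ci_hi,
        z = pooled$z, p = pooled$p,
        tau2 = pooled$tau2, q = pooled$q, p_het = pooled$p_het,
        decision = decision))
    }) |>
    ungroup()
  class(out) <- c("svmwas_meta", class(out))
  out
}
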