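#' Tidy a PCoA ordination
#' @param x An `sv_pcoa`.
#' @param ... Unused.
#' @return Tibble of sample coordinates.
#' @export
tidy.sv_pcoa <- function(x, ...) {
  x$points
}

#' Glance at a PCoA ordination
#' @param x An `sv_pcoa`.
#' @param ... Unused.
#' @return One-row tibble with sample count, retained axes, variance
#'   explained by the first two axes and the count of negative eigenvalues.
#' @export
glance.sv_pcoa <- function(x, ...) {
  tibble(
    n = nrow(x$points), k = x$k,
    var_pco1 = x$var_explained[1],
    var_pco2 = if (x$k >= 2) x$var_explained[2] else NA_real_,
    n_negative_eig = sum(x$eig < 0)
  )
}

#' Tidy a PERMANOVA result
#' @param x An `sv_permanova`.
#' @param ... Unused.
#' @return Per-term tibble (df, SS, R2, pseudo-F, permutation P) including
#'   the Residual and Total rows.
#' @export
tidy.sv_permanova <- function(x, ...) {
  x$table
}

#' Glance at a PERMANOVA result
#' @param x An `sv_permanova`.
#' @param ... Unused.
#' @return One-row tibble: sample count, permutations, exactness.
#' @export
glance.sv_permanova <- function(x, ...) {
  tibble(n = x$n, n_perm = x$n_perm, exact = x$exact)
}

#' Tidy pooled meta-analysis results
#' @param x An `svmwas_meta` tibble.
#' @param ... Unused.
#' @return The flat per-feature columns (list-columns of per-cohort detail
#'   dropped).
#' @export
tidy.svmwas_meta <- function(x, ...) {
  as_tibble(x[, !vapply(x, is.list, logical(1))])
}

#' Glance at pooled meta-analysis results
#' @param x An `svmwas_meta` tibble.
#' @param ... Unused.
#' @return One-row summary: features pooled, replicated / single-cohort
#'   candidates.
#' @export
glance.svmwas_meta <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_replicated = sum(x$decision == "replicated-candidate"),
    n_single_cohort = sum(x$decision == "single-cohort-candidate"),
    n_unevaluable = sum(x$decision == "unevaluable")
  )
}
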