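#' Principal coordinates analysis of an SV distance matrix
#'
#' Classical metric scaling: the squared distances are double-centered
#' (Gower), eigendecomposed, and the top `k` axes scaled by the square root
#' of their eigenvalues. Negative eigenvalues (possible for non-Euclidean SV
#' distances) are reported but excluded from the variance proportions.
#'
#' @param d An `sv_dist` matrix (complete: no undefined entries).
#' @param k Number of axes to retain.
#' @return An `sv_pcoa` object: `points` tibble (`sample_id`, `PCo1`, ...),
#'   `eig` (all eigenvalues, descending), `var_explained` per retained axis.
#' @export
sv_pcoa <- function(d, k = 2) {
  m <- as.matrix(d)
  if (anyNA(m)) {
    abort(paste("distance matrix has undefined entries; drop or impute the",
                "flagged pairs before ordination"))
  }
  k <- min(k, nrow(m) - 1)
  fit <- suppressWarnings(cmdscale(stats::as.dist(m), k = k, eig = TRUE))
  pts <- fit$points
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1)
  if (ncol(pts) < k) {   # cmdscale drops axes with ~zero eigenvalue
    pts <- cbind(pts, matrix(0, nrow(m), k - ncol(pts)))
  }
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- sum(eig[eig > 0])
  var_explained <- if (pos > 0) pmax(eig[seq_len(k)], 0) / pos else rep(0, k)
  structure(list(
    points = dplyr::bind_cols(tibble(sample_id = rownames(m)),
                              as_tibble(pts)),
    eig = eig, var_explained = var_explained, k = k
  ), class = "sv_pcoa")
}

#' @export
print.sv_pcoa <- function(x, ...) {
  cat(sprintf("<sv_pcoa> %d samples, %d axes (%.1f%%, %.1f%% ... of positive variance)\n",
              nrow(x$points), x$k, 100 * x$var_explained[1],
              100 * x$var_explained[min(2, x$k)]))
  invisible(x)
}

#' PERMANOVA on an SV distance matrix
#'
#' Permutational multivariate ANOVA with sequential (order-of-entry) sums of
#' squares from the Gower-centered distance matrix. Each term's pseudo-F is
#' compared with its distribution under unrestricted permutation of sample
#' rows; `P = (1 + #\{permuted F >= observed F\}) / (n_perm + 1)`. Results
#' are deterministic given `seed`. With `exact = TRUE` all `n! - 1`
#' non-identity permutations are enumerated instead (small n only), giving
#' exact permutation P values.
#'
#' @param d An `sv_dist` matrix (complete).
#' @param formula One-sided formula of covariate terms in entry order, e.g.
#'   `~ outcome + age_bin + gender`.
#' @param data Data frame with one row per sample; either in the order of
#'   `d`'s samples or carrying a `sample_id` column to match on.
#' @param n_perm Number of random permutations.
#' @param seed RNG seed for the permutations.
#' @param exact Enumerate all permutations (requires `nrow(d) <= 8`).
#' @return An `sv_permanova` object; `tidy()` gives per-term df, SS, R2,
#'   pseudo-F and P plus Residual/Total rows.
#' @export
sv_permanova <- function(d, formula, data, n_perm = 999, seed = 1,
                         exact = FALSE) {
  m <- as.matrix(d)
  if (anyNA(m)) abort("distance matrix has undefined entries")
  n <- nrow(m)
  data <- as.data.frame(data)
  if (!is.null(rownames(m)) && "sample_id" %in% names(data)) {
    if (!all(rownames(m) %in% data$sample_id)) {
      abort("data lacks rows for some samples in the distance matrix")
    }
    data <- data[match(rownames(m), data$sample_id), , drop = FALSE]
  }
  if (nrow(data) != n) abort("data must have one row per sample")
  mm <- model.matrix(formula, data = data)
  if (nrow(mm) != n) {
    abort("missing covariate values among included samples; drop them first")
  }
  groups <- attr(mm, "assign")
  labels <- attr(stats::terms(formula, data = data), "term.labels")
  permanova_core(m, mm, groups, labels, n_perm = n_perm, seed = seed,
                 exact = exact)
}

permanova_core <- function(m, mm, groups, labels, n_perm, seed, exact) {
  n <- nrow(m)
  a <- -0.5 * m^2
  cen <- diag(n) - matrix(1 / n, n, n)
  g <- cen %*% a %*% cen
  ss_total <- sum(diag(g))

  n_terms <- length(labels)
  hats <- vector("list", n_terms + 1)
  ranks <- integer(n_terms + 1)
  for (j in 0:n_terms) {
    x <- mm[, groups <= j, drop = FALSE]
    qrx <- qr(x)
    q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
    hats[[j + 1]] <- q %*% t(q)
    ranks[j + 1] <- qrx$rank
  }
  mlist <- lapply(seq_len(n_terms), function(j) hats[[j + 1]] - hats[[j]])
  dfs <- diff(ranks)
  h_full <- hats[[n_terms + 1]]
  df_res <- n - ranks[n_terms + 1]

  tol <- 1e-12 * max(1, abs(ss_total))
  zap <- function(x) ifelse(abs(x) < tol, 0, x)
  ss_fun <- function(gp) {
    ss <- zap(vapply(mlist, function(mj) sum(mj * gp), numeric(1)))
    ss_res <- zap(sum(diag(gp)) - sum(h_full * gp))
    list(ss = ss, ss_res = ss_res)
  }
  obs <- ss_fun(g)
  f_of <- function(ss, ss_res) {
    fs <- (ss / dfs) / (ss_res / df_res)
    fs[dfs == 0] <- NA_real_
    fs
  }
  f_obs <- f_of(obs$ss, obs$ss_res)

  perms <- if (exact) {
    if (n > 8) abort("exact enumeration limited to n <= 8")
    p <- all_permutations(n)
    p[!apply(p, 1, function(r) all(r == seq_len(n))), , drop = FALSE]
  } else {
    with_seed(seed, t(replicate(n_perm, sample.int(n))))
  }
  count_ge <- rep(0, n_terms)
  for (i in seq_len(nrow(perms))) {
    gp <- g[perms[i, ], perms[i, ]]
    pp <- ss_fun(gp)
    fp <- f_of(pp$ss, pp$ss_res)
    count_ge <- count_ge + as.numeric(!is.na(fp) & !is.na(f_obs) &
                                        fp >= f_obs)
  }
  n_used <- nrow(perms)
  pvals <- ifelse(is.na(f_obs), NA_real_, (1 + count_ge) / (n_used + 1))

  tab <- tibble(
    term = c(labels, "Residual", "Total"),
    df = c(dfs, df_res, n - 1),
    ss = c(obs$ss, obs$ss_res, ss_total),
    r2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    f = c(f_obs, NA, NA),
    p = c(pvals, NA, NA)
  )
  structure(list(table = tab, n = n, n_perm = n_used,
                 seed = if (exact) NA_integer_ else seed, exact = exact),
            class = "sv_permanova")
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' @export
print.sv_permanova <- function(x, ...) {
  cat(sprintf("<sv_permanova> n = %d, %d permutations%s\n", x$n, x$n_perm,
              if (x$exact) " (exact)" else ""))
  print(as.data.frame(x$table))
  invisible(x)
}

#' Top principal components of a species abundance table
#'
#' Standard PCA (centered, scaled) of the sample-by-species relative
#' abundance table, used as the "microbial composition" covariate block in
#' variance partitioning.
#'
#' @param abund Wide abundance tibble: `sample_id` then one column per
#'   species.
#' @param n_pcs Number of components to return.
#' @return Tibble `sample_id`, `PC1` ... `PCn`.
#' @export
abundance_pcs <- function(abund, n_pcs = 5) {
  assert_columns(abund, "sample_id", "abund")
  x <- as.matrix(abund[, setdiff(names(abund), "sample_id"), drop = FALSE])
  keep <- apply(x, 2, function(col) sd(col) > 0)
  p <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  n_pcs <- min(n_pcs, ncol(p$x))
  dplyr::bind_cols(tibble(sample_id = abund$sample_id),
                   as_tibble(p$x[, seq_len(n_pcs), drop = FALSE]))
}

#' Variance partitioning of an SV distance matrix by covariate blocks
#'
#' Runs PERMANOVA with named blocks of covariates entered in the given order
#' (e.g. the top abundance PCs first, then cohort, then age bin and gender);
#' each block is one multi-degree-of-freedom term, so its R2 is the
#' incremental SV-profile variance it explains after the blocks before it.
#'
#' @param d An `sv_dist` matrix.
#' @param data Data frame with one row per sample (`sample_id` column to
#'   match on, or ordered as `d`).
#' @param blocks Named list; each element is a character vector of column
#'   names in `data` forming one block.
#' @inheritParams sv_permanova
#' @return An `sv_permanova` with one row per block.
#' @export
variance_partition <- function(d, data, blocks, n_perm = 999, seed = 1,
                               exact = FALSE) {
  m <- as.matrix(d)
  data <- as.data.frame(data)
  if (!is.null(rownames(m)) && "sample_id" %in% names(data)) {
    data <- data[match(rownames(m), data$sample_id), , drop = FALSE]
  }
  if (nrow(data) != nrow(m)) abort("data must have one row per sample")
  bdat <- data.frame(row.names = seq_len(nrow(data)))
  for (nm in names(blocks)) {
    cols <- blocks[[nm]]
    assert_columns(data, cols, "data")
    if (length(cols) == 1 && !is.numeric(data[[cols]])) {
      bdat[[nm]] <- factor(data[[cols]])
    } else {
      bdat[[nm]] <- as.matrix(
        data.frame(lapply(data[cols], function(v) {
          if (is.numeric(v)) v else as.numeric(factor(v))
        }))
      )
    }
  }
  f <- stats::as.formula(paste("~", paste(names(blocks), collapse = " + ")))
  mm <- model.matrix(f, data = bdat)
  permanova_core(m, mm, attr(mm, "assign"), names(blocks),
                 n_perm = n_perm, seed = seed, exact = exact)
}

#' Group test on one ordination axis
#'
#' One-way ANOVA of a principal-coordinate axis across group labels,
#' optionally after residualizing the axis on covariates (e.g. abundance
#' PCs) with [residualize_axes()].
#'
#' @param ord An `sv_pcoa`.
#' @param axis Axis index (1 = PCo1).
#' @param groups Vector of group labels, one per sample (in the order of
#'   `ord$points`), or a data frame with `sample_id` and `group` columns.
#' @return Tibble with `f`, `df1`, `df2`, `p`.
#' @export
axis_group_test <- function(ord, axis, groups) {
  stopifnot(inherits(ord, "sv_pcoa"))
  y <- ord$points[[paste0("PCo", axis)]]
  if (is.data.frame(groups)) {
    assert_columns(groups, c("sample_id", "group"), "groups")
    groups <- groups$group[match(ord$points$sample_id, groups$sample_id)]
  }
  g <- factor(groups)
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(table(g) < 2)) abort("each group needs at least 2 samples")
  fit <- anova(stats::lm(y ~ g))
  tibble(f = fit$`F value`[1], df1 = fit$Df[1], df2 = fit$Df[2],
         p = fit$`Pr(>F)`[1])
}

#' Residualize ordination axes on covariates
#'
#' Replaces each retained axis by its residual from a linear regression on
#' the given covariates (the "correcting for microbial abundance" step
#' before axis-level group tests).
#'
#' @param ord An `sv_pcoa`.
#' @param covariates Data frame of numeric covariates with `sample_id`, e.g.
#'   from [abundance_pcs()].
#' @return The `sv_pcoa` with residualized axis coordinates.
#' @export
residualize_axes <- function(ord, covariates) {
  stopifnot(inherits(ord, "sv_pcoa"))
  assert_columns(covariates, "sample_id", "covariates")
  cv <- covariates[match(ord$points$sample_id, covariates$sample_id), ,
                   drop = FALSE]
  x <- as.matrix(cv[, setdiff(names(cv), "sample_id"), drop = FALSE])
  for (ax in paste0("PCo", seq_len(ord$k))) {
    ord$points[[ax]] <- stats::residuals(stats::lm(ord$points[[ax]] ~ x))
  }
  ord
}
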