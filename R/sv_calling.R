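#' Minimum sample cutoff for calling SVs in a species
#'
#' The caller only examines a species in a cohort when enough samples have
#' sufficient coverage of it. The cutoff is about 10% of the cohort size:
#' the smallest integer at least `0.10 * n_samples`.
#'
#' @param n_samples Number of samples in the cohort.
#' @return Integer cutoff.
#' @export
#' @examples
#' min_samp_cutoff(164) # 17
#' min_samp_cutoff(338) # 34
min_samp_cutoff <- function(n_samples) {
  n_samples <- assert_count(n_samples, "n_samples")
  as.integer(ceiling(0.10 * n_samples))
}

#' Median-normalize binned coverage and flag species presence
#'
#' For each (species, sample) the bin depths are divided by that sample's
#' median depth over its non-zero bins, putting every present sample on a
#' common copy-ratio scale (1 = typical single-copy coverage). A sample is
#' marked present for a species only if its median non-zero-bin depth is at
#' least `depth_min` reads and at least `breadth_min` of the bins are
#' non-zero; otherwise all its ratios are missing and every downstream
#' genotype for that species will be missing too.
#'
#' @param cov Long coverage tibble with columns `species_id`, `sample_id`,
#'   `bin_index`, `depth` (an optional `cohort` column is carried through).
#' @param depth_min Minimum median non-zero-bin depth (reads per bin).
#' @param breadth_min Minimum fraction of non-zero bins.
#' @return A tibble like `cov` with `depth` replaced by `ratio` (NA for
#'   absent samples), carrying a `presence` attribute: one row per
#'   (species, sample) with `present`, `median_depth` and `breadth`.
#'   Retrieve it with [sv_presence()].
#' @export
normalize_coverage <- function(cov, depth_min = 1, breadth_min = 0.10) {
  assert_columns(cov, c("species_id", "sample_id", "bin_index", "depth"), "cov")
  if (any(cov$depth < 0)) abort("coverage depths must be non-negative")
  pres <- cov |>
    group_by(.data$species_id, .data$sample_id) |>
    summarise(
      median_depth = if (any(.data$depth > 0)) {
        median(.data$depth[.data$depth > 0])
      } else {
        0
      },
      breadth = mean(.data$depth > 0),
      .groups = "drop"
    ) |>
    mutate(present = .data$median_depth >= depth_min &
             .data$breadth >= breadth_min)
  out <- cov |>
    left_join(select(pres, "species_id", "sample_id", "median_depth",
                     "present"),
              by = c("species_id", "sample_id")) |>
    mutate(ratio = ifelse(.data$present, .data$depth / .data$median_depth,
                          NA_real_)) |>
    select(-"depth", -"median_depth", -"present")
  attr(out, "presence") <- pres
  attr(out, "norm_params") <- list(depth_min = depth_min,
                                   breadth_min = breadth_min)
  class(out) <- c("sv_norm", class(out))
  out
}

#' Species-presence table of a normalized coverage object
#' @param norm Output of [normalize_coverage()].
#' @return Tibble with one row per (species, sample).
#' @export
sv_presence <- function(norm) {
  p <- attr(norm, "presence")
  if (is.null(p)) abort("no presence attribute; run normalize_coverage() first")
  p
}

# Pivot one species' ratios to a samples x bins matrix (NA rows = absent).
ratio_matrix <- function(norm, species) {
  sub <- norm[norm$species_id == species, , drop = FALSE]
  samples <- sort(unique(sub$sample_id))
  bins <- sort(unique(sub$bin_index))
  m <- matrix(NA_real_, nrow = length(samples), ncol = length(bins),
              dimnames = list(samples, as.character(bins)))
  m[cbind(match(sub$sample_id, samples), match(sub$bin_index, bins))] <-
    sub$ratio
  m
}

#' Detect deletion and variable SV regions in a discovery cohort
#'
#' Works species by species on median-normalized coverage. A species is
#' examined only when the number of present samples reaches
#' [min_samp_cutoff()] (or an explicit `min_samples`). Among present samples,
#' a bin is deletion-class when the fraction of samples with ratio below
#' `del_ratio` falls inside `del_band` (deleted in a substantial minority to
#' majority of carriers); a bin that is not deletion-class is variable-class
#' when the cross-sample IQR of its ratio exceeds `var_thresh`. Adjacent
#' same-class bins are merged into segments, and non-adjacent same-class
#' segments are merged into one multi-segment region when the correlation of
#' their per-sample mean signal exceeds `merge_r`. A region meeting both
#' class rules is kept as a deletion (dSV precedence).
#'
#' @param norm Output of [normalize_coverage()].
#' @param min_samples Present-sample floor per species; `NULL` uses
#'   [min_samp_cutoff()] of the cohort size.
#' @param del_ratio Ratio below which a bin is counted deleted in a sample.
#' @param del_band Two-sided band of deletion fractions that defines a
#'   deletion-class bin.
#' @param var_thresh IQR threshold defining a variable-class bin.
#' @param merge_r Per-sample signal correlation above which non-adjacent
#'   same-class segments are merged.
#' @return An `sv_catalog` tibble (`region_id`, `species_id`, `sv_class`,
#'   `segments` list-column) with the caller parameters and any skipped
#'   species recorded as attributes.
#' @export
detect_sv_regions <- function(norm, min_samples = NULL, del_ratio = 0.25,
                              del_band = c(0.25, 0.75), var_thresh = 0.75,
                              merge_r = 0.95) {
  pres <- sv_presence(norm)
  n_total <- length(unique(norm$sample_id))
  cutoff <- min_samples %||% min_samp_cutoff(n_total)
  species <- sort(unique(norm$species_id))
  skipped <- character(0)
  rows <- list()
  for (sp in species) {
    n_present <- sum(pres$present[pres$species_id == sp])
    if (n_present < cutoff) {
      skipped <- c(skipped, sprintf(
        "%s: %d present samples < cutoff %d", sp, n_present, cutoff))
      next
    }
    m <- ratio_matrix(norm, sp)
    m <- m[stats::complete.cases(m), , drop = FALSE]
    frac_del <- colMeans(m < del_ratio)
    iqr <- apply(m, 2, IQR)
    cls <- rep(NA_character_, ncol(m))
    cls[frac_del >= del_band[1] & frac_del <= del_band[2]] <- "dSV"
    cls[is.na(cls) & iqr > var_thresh] <- "vSV"
    bins <- as.integer(colnames(m))
    for (klass in c("dSV", "vSV")) {
      segs <- contiguous_segments(bins[!is.na(cls) & cls == klass])
      if (nrow(segs) == 0) next
      regions <- merge_correlated_segments(segs, m, bins, merge_r)
      for (r in regions) {
        rows[[length(rows) + 1]] <- tibble(
          region_id = region_id(sp, r), species_id = sp,
          sv_class = klass, segments = list(r)
        )
      }
    }
  }
  cat_tbl <- if (length(rows) > 0) bind_rows(rows) else {
    tibble(region_id = character(0), species_id = character(0),
           sv_class = character(0), segments = list())
  }
  cat_tbl <- arrange(cat_tbl, .data$region_id)
  attr(cat_tbl, "params") <- list(
    min_samples = cutoff, del_ratio = del_ratio, del_band = del_band,
    var_thresh = var_thresh, merge_r = merge_r, n_samples = n_total
  )
  attr(cat_tbl, "skipped") <- skipped
  class(cat_tbl) <- c("sv_catalog", class(cat_tbl))
  cat_tbl
}

# Runs of consecutive bin indices -> half-open segment matrix.
contiguous_segments <- function(bins) {
  if (length(bins) == 0) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  bins <- sort(bins)
  breaks <- which(diff(bins) > 1)
  starts <- bins[c(1, breaks + 1)]
  ends <- bins[c(breaks, length(bins))] + 1L
  cbind(start = starts, end = ends)
}

# Greedy single-pass merge of segments whose per-sample mean ratio signals
# correlate above merge_r; returns a list of segment matrices (regions).
merge_correlated_segments <- function(segs, m, bins, merge_r) {
  seg_signal <- function(seg_mat) {
    idx <- match(segment_bins(seg_mat), bins)
    rowMeans(m[, idx, drop = FALSE])
  }
  regions <- list(segs[1, , drop = FALSE])
  signals <- list(seg_signal(segs[1, , drop = FALSE]))
  if (nrow(segs) > 1) {
    for (i in 2:nrow(segs)) {
      seg <- segs[i, , drop = FALSE]
      sig <- seg_signal(seg)
      merged <- FALSE
      for (j in seq_along(regions)) {
        r <- suppressWarnings(stats::cor(signals[[j]], sig))
        if (is.finite(r) && r > merge_r) {
          regions[[j]] <- rbind(regions[[j]], seg)
          signals[[j]] <- seg_signal(regions[[j]])
          merged <- TRUE
          break
        }
      }
      if (!merged) {
        regions <- c(regions, list(seg))
        signals <- c(signals, list(sig))
      }
    }
  }
  regions
}

#' Genotype samples against an SV catalog
#'
#' For every catalog region and sample: a deletion genotype of 1 when more
#' than half of the region's bins have ratio below `del_ratio` (else 0), and
#' a variable genotype equal to the mean normalized ratio over the region's
#' bins. Samples absent for the species get missing genotypes.
#'
#' @param catalog An `sv_catalog` from [detect_sv_regions()].
#' @param norm Normalized coverage of the cohort to genotype (any cohort —
#'   genotyping a replication cohort against a discovery catalog is the
#'   cross-cohort projection; see [project_sv()]).
#' @param del_ratio Deleted-bin ratio threshold (defaults to the catalog's).
#' @return An `sv_profile` tibble: `sample_id`, `region_id`, `species_id`,
#'   `sv_class`, `genotype` (NA = missing).
#' @export
genotype_sv <- function(catalog, norm, del_ratio = NULL) {
  del_ratio <- del_ratio %||% attr(catalog, "params")$del_ratio %||% 0.25
  samples <- sort(unique(norm$sample_id))
  out <- vector("list", nrow(catalog))
  missing_species <- character(0)
  for (i in seq_len(nrow(catalog))) {
    sp <- catalog$species_id[i]
    seg <- catalog$segments[[i]]
    if (!sp %in% norm$species_id) {
      missing_species <- c(missing_species, sp)
      g <- rep(NA_real_, length(samples))
    } else {
      m <- ratio_matrix(norm, sp)
      idx <- match(segment_bins(seg), as.integer(colnames(m)))
      if (anyNA(idx)) {
        abort(sprintf("region %s lies outside the coverage matrix of %s",
                      catalog$region_id[i], sp))
      }
      sub <- m[, idx, drop = FALSE]
      g <- if (catalog$sv_class[i] == "dSV") {
        as.numeric(rowMeans(sub < del_ratio) > 0.5)
      } else {
        rowMeans(sub)
      }
      g <- unname(g[match(samples, rownames(m))])
    }
    out[[i]] <- tibble(sample_id = samples,
                       region_id = catalog$region_id[i],
                       species_id = sp,
                       sv_class = catalog$sv_class[i],
                       genotype = g)
  }
  if (length(missing_species) > 0) {
    warn(sprintf("species absent from coverage, regions all-missing: %s",
                 paste(unique(missing_species), collapse = ", ")))
  }
  prof <- bind_rows(out)
  class(prof) <- c("sv_profile", class(prof))
  prof
}

#' Project a discovery catalog onto a replication cohort
#'
#' Genotypes a replication cohort against the unchanged discovery regions,
#' keeping region ids identical so per-cohort association results line up in
#' the meta-analysis. Species missing from the replication coverage are
#' reported all-missing with a warning.
#'
#' @inheritParams genotype_sv
#' @return An `sv_profile` tibble (see [genotype_sv()]).
#' @export
project_sv <- function(catalog, norm, del_ratio = NULL) {
  genotype_sv(catalog, norm, del_ratio = del_ratio)
}

#' Drop SVs observed in too few samples
#'
#' Removes any SV whose genotype is non-missing in fewer than `min_frac` of
#' all samples (an SV absent from more than `1 - min_frac` of samples carries
#' too little information to test).
#'
#' @param profile An `sv_profile`.
#' @param min_frac Minimum fraction of samples with a non-missing genotype;
#'   an SV at exactly the threshold is retained.
#' @return Filtered `sv_profile`; dropped region ids are in the
#'   `dropped` attribute.
#' @export
filter_sv_profile <- function(profile, min_frac = 0.05) {
  if (nrow(profile) == 0) {
    attr(profile, "dropped") <- character(0)
    return(profile)
  }
  n_samples <- length(unique(profile$sample_id))
  rates <- profile |>
    group_by(.data$region_id) |>
    summarise(rate = sum(!is.na(.data$genotype)) / n_samples,
              .groups = "drop")
  dropped <- rates$region_id[rates$rate < min_frac]
  out <- filter(profile, !.data$region_id %in% dropped)
  attr(out, "dropped") <- dropped
  class(out) <- unique(c("sv_profile", class(out)))
  out
}
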