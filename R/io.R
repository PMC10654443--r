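# TSV/JSON readers and writers for every pipeline artifact. Dialect is fixed
# (tab-separated, UTF-8, '.' decimal, "NA" for missing) to avoid locale drift.

tsv_write <- function(df, path) {
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}

#' Read / write pipeline artifacts
#'
#' Plain-text interchange for every artifact the pipeline produces:
#' long coverage tables (`species_id`, `sample_id`, `bin_index`, `depth`),
#' clinical tables, wide abundance tables, SV catalogs (JSON), SV profiles
#' and square distance matrices (TSV with a sidecar JSON recording the
#' metric). Writing then reading any artifact reproduces the in-memory
#' object.
#'
#' @param path File path.
#' @param cov,clin,abund,catalog,profile,d Object to write.
#' @name svmwas_io
NULL

#' @rdname svmwas_io
#' @export
read_coverage_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          species_id = readr::col_character(),
                          sample_id = readr::col_character(),
                          bin_index = readr::col_integer(),
                          depth = readr::col_double()
                        ))
  assert_columns(df, c("species_id", "sample_id", "bin_index", "depth"),
                 basename(path))
  df
}

#' @rdname svmwas_io
#' @export
write_coverage_tsv <- function(cov, path) {
  tsv_write(cov[, intersect(c("species_id", "sample_id", "bin_index", "depth"),
                            names(cov))], path)
}

#' @rdname svmwas_io
#' @export
read_clinical_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          sample_id = readr::col_character(),
                          cohort = readr::col_character(),
                          cancer_type = readr::col_character(),
                          .default = readr::col_double()
                        ))
  assert_columns(df, clinical_columns(), basename(path))
  df$age_bin <- as.integer(df$age_bin)
  for (col in c("gender", "response", "pfs12", "irae", "os_event")) {
    df[[col]] <- as.integer(df[[col]])
  }
  df
}

clinical_columns <- function() {
  c("sample_id", "cohort", "cancer_type", "age_bin", "gender",
    "response", "pfs12", "irae", "os_time", "os_event")
}

#' @rdname svmwas_io
#' @export
write_clinical_tsv <- function(clin, path) {
  tsv_write(clin[, clinical_columns()], path)
}

#' @rdname svmwas_io
#' @export
read_abundance_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          sample_id = readr::col_character(),
                          .default = readr::col_double()
                        ))
  assert_columns(df, "sample_id", basename(path))
  df
}

#' @rdname svmwas_io
#' @export
write_abundance_tsv <- function(abund, path) {
  tsv_write(abund, path)
}

#' @rdname svmwas_io
#' @export
write_catalog_json <- function(catalog, path) {
  regions <- lapply(seq_len(nrow(catalog)), function(i) {
    seg <- catalog$segments[[i]]
    list(region_id = catalog$region_id[i],
         species_id = catalog$species_id[i],
         sv_class = catalog$sv_class[i],
         segments = lapply(seq_len(nrow(seg)),
                           function(j) c(seg[j, 1], seg[j, 2])))
  })
  jsonlite::write_json(
    list(regions = regions, params = attr(catalog, "params"),
         skipped = attr(catalog, "skipped")),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname svmwas_io
#' @export
read_catalog_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- bind_rows(lapply(raw$regions, function(r) {
    seg <- do.call(rbind, lapply(r$segments, function(s) {
      as.integer(unlist(s))
    }))
    colnames(seg) <- c("start", "end")
    tibble(region_id = r$region_id, species_id = r$species_id,
           sv_class = r$sv_class, segments = list(seg))
  }))
  attr(rows, "params") <- lapply(raw$params, function(p) {
    if (is.list(p)) unlist(p) else p
  })
  attr(rows, "skipped") <- unlist(raw$skipped) %||% character(0)
  class(rows) <- c("sv_catalog", class(rows))
  rows
}

#' @rdname svmwas_io
#' @export
write_profile_tsv <- function(profile, path) {
  tsv_write(profile[, c("sample_id", "region_id", "species_id", "sv_class",
                        "genotype")], path)
}

#' @rdname svmwas_io
#' @export
read_profile_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          sample_id = readr::col_character(),
                          region_id = readr::col_character(),
                          species_id = readr::col_character(),
                          sv_class = readr::col_character(),
                          genotype = readr::col_double()
                        ))
  class(df) <- c("sv_profile", class(df))
  df
}

#' @rdname svmwas_io
#' @export
write_dist_tsv <- function(d, path) {
  m <- as.matrix(unclass(d))
  df <- dplyr::bind_cols(tibble(sample_id = rownames(m)),
                         as_tibble(m, .name_repair = "minimal"))
  tsv_write(df, path)
  jsonlite::write_json(list(metric = attr(d, "metric") %||% "unknown"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname svmwas_io
#' @export
read_dist_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          sample_id = readr::col_character(),
                          .default = readr::col_double()
                        ))
  m <- as.matrix(df[, -1])
  rownames(m) <- df$sample_id
  metric <- "unknown"
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    metric <- jsonlite::read_json(side, simplifyVector = TRUE)$metric
  }
  finish_dist(m, df$sample_id, metric)
}

#' Validate a set of pipeline input files
#'
#' Schema-checks every provided TSV (required columns, value ranges) and
#' cross-references sample ids between coverage, clinical and abundance
#' tables.
#'
#' @param coverage Character vector of coverage TSV paths.
#' @param clinical Clinical TSV path (optional).
#' @param abundance Abundance TSV path (optional).
#' @return Tibble of issues (`severity`, `file`, `message`); zero rows means
#'   everything checked out.
#' @export
validate_inputs <- function(coverage = character(0), clinical = NULL,
                            abundance = NULL) {
  issues <- list()
  note <- function(severity, file, message) {
    issues[[length(issues) + 1]] <<- tibble(severity = severity,
                                            file = basename(file),
                                            message = message)
  }
  cov_samples <- character(0)
  for (f in coverage) {
    df <- tryCatch(read_coverage_tsv(f), error = function(e) {
      note("error", f, conditionMessage(e))
      NULL
    })
    if (is.null(df)) next
    if (any(df$depth < 0)) note("error", f, "negative depths")
    if (any(df$bin_index < 0)) note("error", f, "negative bin indices")
    cov_samples <- union(cov_samples, unique(df$sample_id))
  }
  clin_samples <- NULL
  if (!is.null(clinical)) {
    df <- tryCatch(read_clinical_tsv(clinical), error = function(e) {
      note("error", clinical, conditionMessage(e))
      NULL
    })
    if (!is.null(df)) {
      clin_samples <- df$sample_id
      for (col in c("response", "pfs12", "irae", "os_event")) {
        bad <- !is.na(df[[col]]) & !df[[col]] %in% c(0L, 1L)
        if (any(bad)) {
          note("error", clinical, sprintf("%s has values outside {0,1,NA}", col))
        }
      }
      if (any(!is.na(df$os_time) & df$os_time < 0)) {
        note("error", clinical, "negative os_time")
      }
      orphan <- setdiff(cov_samples, clin_samples)
      for (id in orphan) {
        note("warning", clinical,
             sprintf("sample %s in coverage absent from clinical", id))
      }
    }
  }
  if (!is.null(abundance)) {
    df <- tryCatch(read_abundance_tsv(abundance), error = function(e) {
      note("error", abundance, conditionMessage(e))
      NULL
    })
    if (!is.null(df)) {
      x <- as.matrix(df[, -1])
      if (any(x < 0) || any(rowSums(x) > 1 + 1e-8)) {
        note("error", abundance,
             "relative abundances must be >= 0 with row sums <= 1")
      }
    }
  }
  if (length(issues) == 0) {
    tibble(severity = character(0), file = character(0),
           message = character(0))
  } else {
    bind_rows(issues)
  }
}
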