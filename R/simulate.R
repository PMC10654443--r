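#' Describe a planted deletion SV
#'
#' Declares a deletion region to plant in the simulated coverage of one
#' species. Carriers of the deletion (a configurable fraction of all subjects)
#' have the region's bins at zero expected depth; the deletion genotype enters
#' the outcome models with the given log-odds / log-hazard effects.
#'
#' @param species Species index (1-based) the region belongs to.
#' @param segments Either `c(start, end)` for a single half-open bin segment
#'   (kbp units, 0-based) or a two-column matrix of segments.
#' @param prevalence Fraction of subjects carrying the deletion, in `[0, 1]`.
#' @param beta_response,beta_pfs12,beta_irae Log-odds ratio of the deletion on
#'   each binary outcome.
#' @param beta_os Log-hazard ratio of the deletion on overall survival.
#' @return One-row tibble describing the planted region.
#' @export
planted_dsv <- function(species, segments, prevalence,
                        beta_response = 0, beta_pfs12 = 0, beta_irae = 0,
                        beta_os = 0) {
  segments <- as_segment_matrix(segments)
  assert_prob(prevalence, "prevalence")
  tibble(
    species = as.integer(species), sv_class = "dSV",
    segments = list(segments), prevalence = prevalence, sd_log = NA_real_,
    beta_response = beta_response, beta_pfs12 = beta_pfs12,
    beta_irae = beta_irae, beta_os = beta_os
  )
}

#' Describe a planted variable-copy SV
#'
#' Declares a variable region: every subject carries it with a lognormal
#' per-subject copy ratio (median 1, spread `sd_log` on the log scale). The
#' within-cohort quartile code of the true copy ratio (centered at 2.5) enters
#' the outcome models with the given effect per quartile step.
#'
#' @inheritParams planted_dsv
#' @param sd_log SD of the per-subject log copy ratio.
#' @export
planted_vsv <- function(species, segments, sd_log = 0.75,
                        beta_response = 0, beta_pfs12 = 0, beta_irae = 0,
                        beta_os = 0) {
  segments <- as_segment_matrix(segments)
  if (sd_log < 0) abort("sd_log must be non-negative")
  tibble(
    species = as.integer(species), sv_class = "vSV",
    segments = list(segments), prevalence = NA_real_, sd_log = sd_log,
    beta_response = beta_response, beta_pfs12 = beta_pfs12,
    beta_irae = beta_irae, beta_os = beta_os
  )
}

as_segment_matrix <- function(segments) {
  if (is.numeric(segments) && is.null(dim(segments))) {
    segments <- matrix(segments, ncol = 2, byrow = TRUE)
  }
  segments <- as.matrix(segments)
  storage.mode(segments) <- "integer"
  colnames(segments) <- c("start", "end")
  if (any(segments[, 2] <= segments[, 1])) {
    abort("each segment must satisfy start < end (half-open bins)")
  }
  segments[order(segments[, 1]), , drop = FALSE]
}

#' Simulation configuration for multi-cohort SV studies
#'
#' Defines the study conditions the generator emulates: several cohorts of
#' ICI-treated subjects, a panel of gut species observed as 1-kbp binned read
#' coverage, planted deletion and variable regions with known outcome effects,
#' and clinical outcomes drawn from logistic (response, PFS12, irAEs) and
#' exponential proportional-hazards (OS) models with age bin, gender and a
#' random per-cohort intercept as covariates.
#'
#' @param n_cohorts,n_per_cohort,n_species,n_bins Study dimensions (counts).
#' @param detect_prob Probability a species is detected (non-zero coverage)
#'   in a sample; undetected species yield all-zero coverage and missing SV
#'   genotypes downstream.
#' @param planted_dsv,planted_vsv Tibbles from [planted_dsv()] /
#'   [planted_vsv()] (rows may be combined with `dplyr::bind_rows()`).
#' @param mean_depth Mean reads per 1-kbp bin for a detected species.
#' @param noise Per-bin depth noise: `"poisson"`, `"nbinom"` (overdispersed,
#'   size `nb_size`), or `"none"` (expected depth exactly; useful for
#'   noise-free caller tests).
#' @param nb_size Negative-binomial size (inverse dispersion) when
#'   `noise = "nbinom"`.
#' @param depth_sd_log SD of the per-sample-species lognormal depth factor.
#' @param intercepts Named numeric: logit-scale intercepts for `response`,
#'   `pfs12`, `irae`.
#' @param beta_age,beta_gender Covariate effects (log-odds per age bin step /
#'   for male gender) shared by the binary outcome models.
#' @param os_base_rate Baseline hazard (events per day) of the exponential OS
#'   model.
#' @param os_horizon Administrative censoring horizon in days.
#' @param os_dropout_rate Rate of independent exponential dropout censoring.
#' @param cohort_sd SD of the random per-cohort intercept shift.
#' @param cancer_types Character vector (length 1 or `n_cohorts`) of cancer
#'   type labels per cohort.
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(n_cohorts = 3, n_per_cohort = 100, n_species = 3,
                       n_bins = 100, detect_prob = 0.9,
                       planted_dsv = NULL, planted_vsv = NULL,
                       mean_depth = 10,
                       noise = c("poisson", "nbinom", "none"), nb_size = 10,
                       depth_sd_log = 0.3,
                       intercepts = c(response = 0, pfs12 = 0, irae = -1),
                       beta_age = 0, beta_gender = 0,
                       os_base_rate = 1 / 365, os_horizon = 730,
                       os_dropout_rate = 1 / 1500,
                       cohort_sd = 0.2,
                       cancer_types = "melanoma") {
  noise <- match.arg(noise)
  n_cohorts <- assert_count(n_cohorts, "n_cohorts")
  n_per_cohort <- assert_count(n_per_cohort, "n_per_cohort")
  n_species <- assert_count(n_species, "n_species")
  n_bins <- assert_count(n_bins, "n_bins")
  assert_prob(detect_prob, "detect_prob")
  if (mean_depth <= 0) abort("mean_depth must be positive")
  planted <- bind_rows(planted_dsv, planted_vsv)
  if (nrow(planted) > 0) {
    if (any(planted$species < 1 | planted$species > n_species)) {
      abort("planted SV references a species outside 1..n_species")
    }
    bad <- purrr::map_lgl(planted$segments, function(s) {
      any(s[, 1] < 0 | s[, 2] > n_bins)
    })
    if (any(bad)) abort("planted SV segments fall outside the genome (0..n_bins)")
  }
  if (!all(c("response", "pfs12", "irae") %in% names(intercepts))) {
    abort("intercepts must name response, pfs12 and irae")
  }
  if (!length(cancer_types) %in% c(1L, n_cohorts)) {
    abort("cancer_types must have length 1 or n_cohorts")
  }
  structure(list(
    n_cohorts = n_cohorts, n_per_cohort = n_per_cohort,
    n_species = n_species, n_bins = n_bins, detect_prob = detect_prob,
    planted = planted, mean_depth = mean_depth, noise = noise,
    nb_size = nb_size, depth_sd_log = depth_sd_log,
    intercepts = intercepts, beta_age = beta_age, beta_gender = beta_gender,
    os_base_rate = os_base_rate, os_horizon = os_horizon,
    os_dropout_rate = os_dropout_rate, cohort_sd = cohort_sd,
    cancer_types = rep(cancer_types, length.out = n_cohorts)
  ), class = "sim_config")
}

#' Simulate a multi-cohort SV study
#'
#' Draws binned coverage, species relative abundances, clinical outcomes and
#' the generating ground truth for every cohort in the configuration. One root
#' seed drives the whole simulation; per-cohort RNG streams are derived
#' deterministically from it, so identical config + seed gives identical
#' output.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer root seed.
#' @return A `sim_result` list with elements `coverage` (long tibble:
#'   `cohort`, `species_id`, `sample_id`, `bin_index`, `depth`), `abundance`
#'   (wide tibble: `sample_id` then one column per species), `clinical`
#'   (tibble of outcomes and covariates), and `truth` (planted regions,
#'   per-sample true genotypes, outcome linear predictors).
#' @export
simulate_cohorts <- function(config, seed = 1) {
  if (!inherits(config, "sim_config")) abort("config must come from sim_config()")
  species_ids <- sprintf("sp%02d", seq_len(config$n_species))
  planted <- config$planted
  if (nrow(planted) > 0) {
    planted$region_id <- purrr::map2_chr(
      planted$species, planted$segments,
      function(sp, seg) region_id(species_ids[sp], seg)
    )
  }

  # Species-level abundance means are a property of the panel, not a cohort.
  ab_mean <- with_seed(derive_seed(seed, "abundance-means"),
                       rnorm(config$n_species, mean = 0, sd = 1))

  per_cohort <- purrr::map(seq_len(config$n_cohorts), function(ci) {
    simulate_one_cohort(config, ci, species_ids, planted, ab_mean,
                        derive_seed(seed, paste0("cohort-", ci)))
  })

  coverage <- bind_rows(purrr::map(per_cohort, "coverage"))
  clinical <- bind_rows(purrr::map(per_cohort, "clinical"))
  abundance <- bind_rows(purrr::map(per_cohort, "abundance"))
  truth <- list(
    sv = if (nrow(planted) > 0) {
      as_tibble(planted[, c("region_id", "sv_class", "species", "segments",
                            "prevalence", "sd_log", "beta_response",
                            "beta_pfs12", "beta_irae", "beta_os")])
    } else {
      tibble()
    },
    genotypes = bind_rows(purrr::map(per_cohort, "truth_geno")),
    lp = bind_rows(purrr::map(per_cohort, "truth_lp"))
  )
  structure(list(coverage = coverage, abundance = abundance,
                 clinical = clinical, truth = truth,
                 config = config, seed = seed),
            class = "sim_result")
}

simulate_one_cohort <- function(config, ci, species_ids, planted, ab_mean,
                                cohort_seed) {
  n <- config$n_per_cohort
  cohort <- sprintf("cohort%d", ci)
  sample_ids <- sprintf("c%d_s%04d", ci, seq_len(n))
  with_seed(cohort_seed, {
    cohort_shift <- rnorm(1, 0, config$cohort_sd)
    age_bin <- sample(1:4, n, replace = TRUE)
    gender <- rbinom(n, 1, 0.5)

    detected <- matrix(rbinom(n * config$n_species, 1, config$detect_prob) == 1,
                       nrow = n)
    depth_factor <- matrix(
      exp(rnorm(n * config$n_species, 0, config$depth_sd_log)),
      nrow = n
    )
    if (config$noise == "none") depth_factor[] <- 1

    # True genotypes / copy ratios and the model covariate value they carry.
    geno <- NULL
    if (nrow(planted) > 0) {
      geno <- purrr::map(seq_len(nrow(planted)), function(i) {
        if (planted$sv_class[i] == "dSV") {
          g <- rbinom(n, 1, planted$prevalence[i])
          list(genotype = g, x = g)
        } else {
          r <- exp(rnorm(n, 0, planted$sd_log[i]))
          q <- quartile_code(r)
          list(genotype = r, x = q - 2.5)
        }
      })
    }

    lp_terms <- function(beta_col) {
      lp <- rep(cohort_shift, n) +
        config$beta_age * age_bin + config$beta_gender * gender
      if (nrow(planted) > 0) {
        for (i in seq_len(nrow(planted))) {
          lp <- lp + planted[[beta_col]][i] * geno[[i]]$x
        }
      }
      lp
    }
    lp_response <- config$intercepts[["response"]] + lp_terms("beta_response")
    lp_pfs12 <- config$intercepts[["pfs12"]] + lp_terms("beta_pfs12")
    lp_irae <- config$intercepts[["irae"]] + lp_terms("beta_irae")
    lp_os <- lp_terms("beta_os")

    response <- rbinom(n, 1, stats::plogis(lp_response))
    pfs12 <- rbinom(n, 1, stats::plogis(lp_pfs12))
    irae <- rbinom(n, 1, stats::plogis(lp_irae))
    t_event <- rexp(n, rate = config$os_base_rate * exp(lp_os))
    t_cens <- pmin(rexp(n, rate = config$os_dropout_rate), config$os_horizon)
    os_time <- pmin(t_event, t_cens)
    os_event <- as.integer(t_event <= t_cens)

    # Expected per-bin depth, then noise.
    depth_mat <- matrix(0, nrow = n, ncol = config$n_species * config$n_bins)
    for (sp in seq_len(config$n_species)) {
      cols <- (sp - 1) * config$n_bins + seq_len(config$n_bins)
      mu <- outer(depth_factor[, sp] * config$mean_depth,
                  rep(1, config$n_bins))
      if (nrow(planted) > 0) {
        for (i in which(planted$species == sp)) {
          bins <- segment_bins(planted$segments[[i]]) + 1L
          if (planted$sv_class[i] == "dSV") {
            mu[geno[[i]]$genotype == 1, bins] <- 0
          } else {
            mu[, bins] <- mu[, bins] * geno[[i]]$genotype
          }
        }
      }
      mu[!detected[, sp], ] <- 0
      obs <- switch(config$noise,
        poisson = matrix(rpois(length(mu), mu), nrow = n),
        nbinom = matrix(rnbinom(length(mu), mu = mu, size = config$nb_size),
                        nrow = n),
        none = mu
      )
      obs[!detected[, sp], ] <- 0
      depth_mat[, cols] <- obs
    }

    coverage <- tibble(
      cohort = cohort,
      species_id = rep(rep(species_ids, each = config$n_bins), each = n),
      sample_id = rep(sample_ids, times = config$n_species * config$n_bins),
      bin_index = rep(rep(seq_len(config$n_bins) - 1L, each = n),
                      times = config$n_species),
      depth = as.vector(depth_mat)
    ) |> arrange(.data$species_id, .data$sample_id, .data$bin_index)

    # Relative abundances: lognormal weights, zeroed when undetected, scaled
    # against an unlisted remainder so rows sum to < 1.
    w <- exp(sweep(matrix(rnorm(n * config$n_species, 0, 0.7), nrow = n),
                   2, ab_mean, "+"))
    w[!detected] <- 0
    other <- exp(rnorm(n, 1, 0.5))
    rel <- w / (rowSums(w) + other)
    abundance <- as_tibble(rel, .name_repair = "minimal")
    names(abundance) <- species_ids
    abundance <- dplyr::bind_cols(tibble(sample_id = sample_ids), abundance)

    clinical <- tibble(
      sample_id = sample_ids, cohort = cohort,
      cancer_type = config$cancer_types[ci],
      age_bin = age_bin, gender = gender,
      response = response, pfs12 = pfs12, irae = irae,
      os_time = os_time, os_event = os_event
    )

    truth_geno <- if (nrow(planted) > 0) {
      bind_rows(purrr::map(seq_len(nrow(planted)), function(i) {
        tibble(sample_id = sample_ids, cohort = cohort,
               region_id = planted$region_id[i],
               genotype_true = geno[[i]]$genotype,
               x_model = geno[[i]]$x)
      }))
    } else {
      tibble()
    }
    truth_lp <- tibble(sample_id = sample_ids, cohort = cohort,
                       cohort_shift = cohort_shift,
                       lp_response = lp_response, lp_pfs12 = lp_pfs12,
                       lp_irae = lp_irae, lp_os = lp_os)

    list(coverage = coverage, clinical = clinical, abundance = abundance,
         truth_geno = truth_geno, truth_lp = truth_lp)
  })
}

#' Write a simulated study to disk as plain-text fixtures
#'
#' Writes one coverage TSV per cohort plus a clinical TSV, an abundance TSV,
#' the planted-region catalog (JSON) and a manifest recording the files, the
#' seed and a hash of the configuration.
#'
#' @param sim A `sim_result` from [simulate_cohorts()].
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly, as a list.
#' @export
write_fixture_set <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohorts <- unique(sim$coverage$cohort)
  files <- character(0)
  for (co in cohorts) {
    f <- file.path(dir, paste0("coverage_", co, ".tsv"))
    write_coverage_tsv(filter(sim$coverage, .data$cohort == co), f)
    files <- c(files, basename(f))
  }
  if (nrow(sim$clinical) > 0) {
    write_clinical_tsv(sim$clinical, file.path(dir, "clinical.tsv"))
    write_abundance_tsv(sim$abundance, file.path(dir, "abundance.tsv"))
    files <- c(files, "clinical.tsv", "abundance.tsv")
  }
  if (nrow(sim$truth$sv) > 0) {
    truth <- sim$truth$sv
    truth$segments <- purrr::map(truth$segments, function(s) {
      lapply(seq_len(nrow(s)), function(i) c(s[i, 1], s[i, 2]))
    })
    jsonlite::write_json(truth, file.path(dir, "planted_regions.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, "planted_regions.json")
  }
  manifest <- list(files = files, seed = sim$seed,
                   config_hash = rlang::hash(unclass(sim$config)),
                   n_cohorts = length(cohorts))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read back a fixture set written by [write_fixture_set()]
#'
#' @param dir Directory containing the manifest and TSV files.
#' @return A list with `coverage`, `clinical`, `abundance` and `manifest`.
#' @export
read_fixture_set <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cov_files <- grep("^coverage_", manifest$files, value = TRUE)
  coverage <- bind_rows(purrr::map(cov_files, function(f) {
    co <- sub("^coverage_(.*)\\.tsv$", "\\1", f)
    mutate(read_coverage_tsv(file.path(dir, f)), cohort = co,
           .before = 1)
  }))
  clinical <- if ("clinical.tsv" %in% manifest$files) {
    read_clinical_tsv(file.path(dir, "clinical.tsv"))
  }
  abundance <- if ("abundance.tsv" %in% manifest$files) {
    read_abundance_tsv(file.path(dir, "abundance.tsv"))
  }
  list(coverage = coverage, clinical = clinical, abundance = abundance,
       manifest = manifest)
}
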