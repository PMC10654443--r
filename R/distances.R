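#' Jaccard distance between samples over deletion SVs
#'
#' Treats each sample's deleted dSVs (genotype 1) as a set and returns the
#' binary Jaccard distance `1 - |A intersect B| / |A union B|`, computed per
#' pair over the SVs where both samples have a non-missing genotype
#' (pairwise-complete). A pair whose union is empty (neither sample deleted
#' anywhere they are both observed) is at distance 0; a pair with no shared
#' non-missing SV is undefined (NA) and counted in the `n_undefined`
#' attribute.
#'
#' @param profile An `sv_profile`; only rows with `sv_class == "dSV"` are
#'   used.
#' @return An `sv_dist`: a symmetric numeric matrix with zero diagonal and a
#'   `metric` attribute.
#' @export
jaccard_dsv <- function(profile) {
  x <- profile_matrix(profile, "dSV")
  if (nrow(x) < 2) abort("need at least 2 samples")
  v <- !is.na(x)
  xz <- x
  xz[!v] <- 0
  a <- xz %*% t(xz)                      # |A intersect B|
  u <- xz %*% t(v) + v %*% t(xz) - a     # |A union B|
  nv <- v %*% t(1 * v)                   # shared non-missing SVs
  d <- 1 - a / u
  d[u == 0] <- 0
  d[nv == 0] <- NA_real_
  finish_dist(d, rownames(x), "jaccard")
}

#' Scaled Canberra distance between samples over variable SVs
#'
#' For each pair, the mean over valid vSVs of `|x - y| / (x + y)`, where a
#' vSV is valid when both genotypes are non-missing and not both zero (the
#' community-ecology scaled Canberra convention). With `scaled = FALSE` the
#' raw sum over valid terms is returned instead of the mean. Pairs with no
#' valid term are undefined (NA).
#'
#' @param profile An `sv_profile`; only rows with `sv_class == "vSV"` are
#'   used.
#' @param scaled Divide the Canberra sum by the number of valid terms
#'   (default) or return the raw sum.
#' @return An `sv_dist` matrix (entries in `[0, 1]` when scaled).
#' @export
canberra_vsv <- function(profile, scaled = TRUE) {
  x <- profile_matrix(profile, "vSV")
  if (nrow(x) < 2) abort("need at least 2 samples")
  n <- nrow(x)
  num <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  for (j in seq_len(ncol(x))) {
    xs <- x[, j]
    obs <- !is.na(xs)
    zero <- obs & xs == 0
    valid <- outer(obs, obs, "&") & !outer(zero, zero, "&")
    xs0 <- ifelse(obs, xs, 0)
    term <- abs(outer(xs0, xs0, "-")) / outer(xs0, xs0, "+")
    term[!valid | !is.finite(term)] <- 0
    num <- num + term
    cnt <- cnt + valid
  }
  d <- if (scaled) num / cnt else num
  d[cnt == 0] <- NA_real_
  finish_dist(d, rownames(x), if (scaled) "canberra" else "canberra-raw")
}

#' Combined SV distance
#'
#' Elementwise mean of the deletion (Jaccard) and variable (Canberra)
#' distances; where one of the two is undefined the other is used, and a
#' pair undefined in both stays undefined.
#'
#' @param dj,dc `sv_dist` matrices over the same samples (in any order).
#' @return An `sv_dist` matrix labelled `"combined"`.
#' @export
combined_sv_distance <- function(dj, dc) {
  if (!setequal(rownames(dj), rownames(dc))) {
    abort("distance matrices cover different sample sets")
  }
  dc <- dc[rownames(dj), rownames(dj)]
  both <- !is.na(dj) & !is.na(dc)
  d <- matrix(NA_real_, nrow(dj), ncol(dj), dimnames = dimnames(dj))
  d[both] <- (dj[both] + dc[both]) / 2
  d[is.na(dj) & !is.na(dc)] <- dc[is.na(dj) & !is.na(dc)]
  d[!is.na(dj) & is.na(dc)] <- dj[!is.na(dj) & is.na(dc)]
  finish_dist(d, rownames(dj), "combined")
}

#' Combined SV distance straight from a profile
#'
#' Convenience wrapper building the Jaccard (dSV), Canberra (vSV) and
#' combined distances from one profile; if the profile holds only one SV
#' class, that class's distance is returned as the combination.
#'
#' @param profile An `sv_profile`.
#' @return An `sv_dist` matrix.
#' @export
sv_distance <- function(profile) {
  has_d <- any(profile$sv_class == "dSV" & !is.na(profile$genotype))
  has_v <- any(profile$sv_class == "vSV" & !is.na(profile$genotype))
  if (has_d && has_v) {
    combined_sv_distance(jaccard_dsv(profile), canberra_vsv(profile))
  } else if (has_d) {
    jaccard_dsv(profile)
  } else if (has_v) {
    canberra_vsv(profile)
  } else {
    abort("profile holds no non-missing genotypes")
  }
}

profile_matrix <- function(profile, class) {
  assert_columns(profile, c("sample_id", "region_id", "sv_class", "genotype"),
                 "profile")
  sub <- profile[profile$sv_class == class, , drop = FALSE]
  samples <- sort(unique(profile$sample_id))
  regions <- sort(unique(sub$region_id))
  m <- matrix(NA_real_, length(samples), length(regions),
              dimnames = list(samples, regions))
  if (nrow(sub) > 0) {
    m[cbind(match(sub$sample_id, samples), match(sub$region_id, regions))] <-
      sub$genotype
  }
  m
}

finish_dist <- function(d, ids, metric) {
  dimnames(d) <- list(ids, ids)
  d <- (d + t(d)) / 2   # enforce exact symmetry against fp noise
  diag(d) <- 0
  attr(d, "metric") <- metric
  attr(d, "n_undefined") <- sum(is.na(d[upper.tri(d)]))
  class(d) <- c("sv_dist", class(d))
  d
}

#' @export
print.sv_dist <- function(x, ...) {
  cat(sprintf("<sv_dist> %s, %d samples, %d undefined pair(s)\n",
              attr(x, "metric"), nrow(x), attr(x, "n_undefined")))
  invisible(x)
}
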