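# Internal helpers shared across modules.

# Derive a child RNG seed from a root seed and a stream label, staying within
# the 32-bit integer range R requires for set.seed().
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.double(seed) * 48271 + h * 2654435) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("%s must lie in [0, 1]", what))
  }
  invisible(x)
}

assert_count <- function(x, what, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != floor(x)) {
    abort(sprintf("%s must be a single integer >= %d", what, min))
  }
  invisible(as.integer(x))
}

# Canonical region id: "species:start1-end1;start2-end2" with half-open
# [start, end) segments in kbp units (1 bin = 1 kbp).
region_id <- function(species_id, segments) {
  seg <- paste(sprintf("%d-%d", segments[, 1], segments[, 2]), collapse = ";")
  paste0(species_id, ":", seg)
}

parse_region_id <- function(id) {
  sp <- sub(":[^:]*$", "", id)
  seg_str <- sub("^.*:", "", id)
  parts <- strsplit(seg_str, ";", fixed = TRUE)[[1]]
  segs <- do.call(rbind, lapply(parts, function(p) {
    as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
  }))
  colnames(segs) <- c("start", "end")
  list(species_id = sp, segments = segs)
}

# Expand segment matrix to the 0-based bin indices it covers.
segment_bins <- function(segments) {
  unlist(lapply(seq_len(nrow(segments)), function(i) {
    seq.int(segments[i, 1], segments[i, 2] - 1L)
  }))
}
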