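# Expression pipeline: low-count filtering, median-of-ratios normalization,
# timepoint aggregation, step-wise-increase selection, fold changes and
# total-expression ranking.

#' Drop genes that never reach a minimum read count
#'
#' A gene is kept when its count reaches `min_reads` in at least one library;
#' a gene that stays below the threshold in every sample is removed.  Sample
#' set and gene order are preserved, and the operation is idempotent.
#'
#' @param counts Integer count matrix (genes x samples).
#' @param min_reads Minimum count a gene must reach in some library
#'   (default 10).
#' @return The filtered count matrix.
#' @export
filter_low_counts <- function(counts, min_reads = 10L) {
  validate_counts(counts)
  if (!is_count_scalar(min_reads)) stop_input("min_reads must be a non-negative integer")
  keep <- apply(counts, 1L, max) >= min_reads
  counts[keep, , drop = FALSE]
}

#' Estimate median-of-ratios size factors
#'
#' The standard count-normalization estimator: for each sample, the size
#' factor is the median, over genes with positive counts in every sample, of
#' the ratio of that gene's count to its across-sample geometric mean.
#' Factors are rescaled so their geometric mean is exactly 1, which makes
#' normalized expression comparable across runs without changing ratios
#' between samples.
#'
#' @param counts Integer count matrix (genes x samples).
#' @return A named numeric vector of positive per-sample size factors with
#'   geometric mean 1.
#' @export
estimate_size_factors <- function(counts) {
  validate_counts(counts)
  if (nrow(counts) == 0L || ncol(counts) == 0L) stop_input("count matrix is empty")
  reference <- rowSums(counts > 0) == ncol(counts)
  if (!any(reference)) {
    stop_input(paste0("no gene has positive counts in every sample; ",
                      "pre-filter the matrix before estimating size factors"))
  }
  logc <- log(counts[reference, , drop = FALSE])
  log_geo <- rowMeans(logc)
  log_sf <- apply(logc - log_geo, 2L, median)
  log_sf <- log_sf - mean(log_sf)  # geometric mean 1
  setNames(exp(log_sf), colnames(counts))
}

#' Normalize counts by size factors
#'
#' Element-wise division of every sample column by its size factor.
#'
#' @param counts Integer count matrix (genes x samples).
#' @param size_factors Named numeric vector covering all samples, as from
#'   [estimate_size_factors()].
#' @return A numeric matrix of normalized expression values.
#' @export
normalize_counts <- function(counts, size_factors) {
  validate_counts(counts)
  missing <- setdiff(colnames(counts), names(size_factors))
  if (length(missing)) {
    stop_input("no size factor for sample(s): %s", paste(missing, collapse = ", "))
  }
  f <- size_factors[colnames(counts)]
  if (any(!is.finite(f)) || any(f <= 0)) stop_input("size factors must be finite and positive")
  sweep(counts, 2L, f, "/")
}

#' Aggregate normalized expression into per-timepoint profiles
#'
#' With `mode = "mean"` every gene gets one profile: the mean of its
#' normalized expression over animals at each timepoint.  With
#' `mode = "per_animal"` each animal's own profile is retained (as a
#' genes x timepoints x animals array) so that step-wise increase can be
#' required of every individual separately.
#'
#' @param normalized Numeric matrix of normalized expression
#'   (genes x samples).
#' @param meta Sample metadata with columns `sample_id`, `animal_id`,
#'   `timepoint_minutes`.
#' @param mode `"mean"` (default) or `"per_animal"`.
#' @return An object of class `time_profiles`: a list with `timepoints`
#'   (sorted ascending), `mode`, and either `profiles` (matrix) or
#'   `profiles` (3-d array) plus `animals`.
#' @export
timepoint_profiles <- function(normalized, meta, mode = c("mean", "per_animal")) {
  mode <- match.arg(mode)
  meta <- match_metadata(normalized, meta)
  timepoints <- sort(unique(meta$timepoint_minutes))
  if (mode == "mean") {
    profiles <- vapply(timepoints, function(tp) {
      cols <- meta$sample_id[meta$timepoint_minutes == tp]
      rowMeans(normalized[, cols, drop = FALSE])
    }, numeric(nrow(normalized)))
    profiles <- matrix(profiles, nrow = nrow(normalized),
                       dimnames = list(rownames(normalized), paste0("t", timepoints)))
    out <- list(timepoints = timepoints, mode = mode, profiles = profiles)
  } else {
    animals <- sort(unique(meta$animal_id))
    arr <- array(NA_real_,
                 dim = c(nrow(normalized), length(timepoints), length(animals)),
                 dimnames = list(rownames(normalized), paste0("t", timepoints), animals))
    for (a in animals) {
      for (i in seq_along(timepoints)) {
        cols <- meta$sample_id[meta$animal_id == a &
                                 meta$timepoint_minutes == timepoints[i]]
        if (length(cols) == 0L) {
          stop_input("animal %s has no sample at timepoint %s", a, timepoints[i])
        }
        arr[, i, a] <- rowMeans(normalized[, cols, drop = FALSE])
      }
    }
    out <- list(timepoints = timepoints, mode = mode, profiles = arr,
                animals = animals)
  }
  structure(out, class = "time_profiles")
}

#' Select genes with step-wise increasing expression
#'
#' A gene is selected when its aggregated expression increases at every
#' consecutive timepoint transition -- strictly by default.  With
#' `unanimity = TRUE` (requires `per_animal` profiles) the increase must
#' hold in every animal's individual profile.
#'
#' @param profiles A `time_profiles` object from [timepoint_profiles()].
#' @param strict Require strict increases (default `TRUE`); otherwise
#'   non-decreasing steps qualify.
#' @param unanimity Require the pattern in every animal individually
#'   (default `FALSE`; needs `mode = "per_animal"` profiles).
#' @return Character vector of selected gene identifiers, in input order.
#' @export
select_stepwise_increasing <- function(profiles, strict = TRUE, unanimity = FALSE) {
  stopifnot(inherits(profiles, "time_profiles"))
  if (length(profiles$timepoints) < 2L) stop_input("need at least 2 timepoints")
  increasing <- function(mat) {
    d <- mat[, -1L, drop = FALSE] - mat[, -ncol(mat), drop = FALSE]
    if (strict) apply(d > 0, 1L, all) else apply(d >= 0, 1L, all)
  }
  if (unanimity) {
    if (profiles$mode != "per_animal") {
      stop_input("unanimity selection requires per_animal profiles")
    }
    ok <- Reduce(`&`, lapply(profiles$animals, function(a) {
      increasing(profiles$profiles[, , a, drop = TRUE])
    }))
  } else {
    mat <- if (profiles$mode == "mean") {
      profiles$profiles
    } else {
      apply(profiles$profiles, c(1L, 2L), mean)
    }
    ok <- increasing(mat)
  }
  rownames(profiles$profiles)[ok]
}

#' Per-gene fold change over the time course
#'
#' Ratio of expression at the last timepoint to baseline, with an optional
#' pseudocount added to both to guard against zero baselines.
#'
#' @param profiles A `time_profiles` object (mean mode).
#' @param pseudocount Non-negative value added to numerator and denominator
#'   (default 0; must be positive if any baseline value is 0).
#' @return Named numeric vector of fold changes.
#' @export
fold_changes <- function(profiles, pseudocount = 0) {
  stopifnot(inherits(profiles, "time_profiles"))
  if (!is.numeric(pseudocount) || pseudocount < 0) {
    stop_input("pseudocount must be a non-negative number")
  }
  mat <- if (profiles$mode == "mean") profiles$profiles else
    apply(profiles$profiles, c(1L, 2L), mean)
  baseline <- mat[, 1L]
  last <- mat[, ncol(mat)]
  if (pseudocount == 0 && any(baseline == 0)) {
    stop_input("zero baseline expression: use a positive pseudocount")
  }
  (last + pseudocount) / (baseline + pseudocount)
}

#' Rank genes by total normalized expression
#'
#' The score is the sum of normalized expression over all samples; genes are
#' sorted by descending score with ties broken by ascending gene identifier,
#' so the ordering is total and deterministic.
#'
#' @param normalized Numeric matrix of normalized expression
#'   (genes x samples).
#' @return A data frame with columns `gene_id`, `score`, `rank`, sorted by
#'   rank.
#' @export
rank_by_total_expression <- function(normalized) {
  if (!is.matrix(normalized) || nrow(normalized) == 0L) {
    stop_input("normalized matrix must be non-empty")
  }
  score <- rowSums(normalized)
  ord <- order(-score, rownames(normalized), method = "radix")
  data.frame(gene_id = rownames(normalized)[ord],
             score = unname(score[ord]),
             rank = seq_along(score),
             stringsAsFactors = FALSE)
}

validate_ranked <- function(ranked) {
  if (!is.data.frame(ranked) || !all(c("gene_id", "score") %in% colnames(ranked))) {
    stop_input("a ranked gene list needs columns gene_id and score")
  }
  if (anyDuplicated(ranked$gene_id)) stop_input("duplicate genes in ranked list")
  if (is.unsorted(rev(ranked$score))) {
    # scores must be non-increasing down the list
    stop_input("ranked list scores must be sorted in descending order")
  }
  ranked
}
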