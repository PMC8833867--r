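# Minimal running-sum gene-set enrichment engine: weighted enrichment score,
# gene-set permutation null, normalized scores and BH-adjusted q-values.

#' Construct a gene set
#'
#' @param name Set name.
#' @param genes Character vector of member gene identifiers (made unique;
#'   must be non-empty).
#' @param description Optional free-text description (kept for GMT output).
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, genes, description = "") {
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stop_input("gene set '%s' is empty", name)
  structure(list(name = as.character(name), genes = genes,
                 description = as.character(description)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Running-sum enrichment score of a gene set in a ranked list
#'
#' Walks the ranked list from top to bottom keeping a running deviation:
#' meeting a set member ("hit") increments by `|score|^p_weight / N_R`
#' (`N_R` = the sum of `|score|^p_weight` over hits), meeting a non-member
#' decrements by `1 / (N - N_H)`.  The enrichment score (ES) is the deviation
#' of maximal absolute value, signed; the leading edge contains the hits at
#' or before the extremum for positive ES, and at or after it for negative
#' ES.  With `p_weight = 0` the statistic reduces to the classic
#' Kolmogorov-Smirnov statistic between hit and miss positions.
#'
#' @param ranked Ranked gene list (data frame with `gene_id`, `score`, sorted
#'   by descending score).
#' @param set A [gene_set()].  Members absent from the ranked list are
#'   dropped (with a message); the remaining members must be a non-empty
#'   proper subset of the list.
#' @param p_weight Non-negative weighting exponent (default 1).
#' @return A list with `es`, `running_sum` (data frame `position`,
#'   `gene_id`, `deviation`), `extremum_position` and `leading_edge`.
#' @export
enrichment_score <- function(ranked, set, p_weight = 1) {
  ranked <- validate_ranked(ranked)
  stopifnot(inherits(set, "gene_set"))
  if (!is_real_scalar(p_weight) || p_weight < 0) {
    stop_input("p_weight must be a non-negative number")
  }
  hit <- ranked$gene_id %in% set$genes
  dropped <- length(setdiff(set$genes, ranked$gene_id))
  if (dropped > 0L) {
    message(sprintf("gene set '%s': dropping %d member(s) absent from the ranked list",
                    set$name, dropped))
  }
  if (!any(hit)) stop_input("gene set '%s' has no member in the ranked list", set$name)
  if (all(hit)) stop_input("gene set '%s' covers the entire ranked list", set$name)
  dev <- running_deviation(abs(ranked$score)^p_weight, hit)
  ext <- which.max(abs(dev))
  es <- dev[ext]
  hits_idx <- which(hit)
  leading <- if (es >= 0) hits_idx[hits_idx <= ext] else hits_idx[hits_idx >= ext]
  list(es = es,
       running_sum = data.frame(position = seq_along(dev),
                                gene_id = ranked$gene_id,
                                deviation = dev,
                                stringsAsFactors = FALSE),
       extremum_position = ext,
       leading_edge = ranked$gene_id[leading])
}

# Core running sum shared by enrichment_score() and the permutation null.
# `w` is |score|^p_weight for every position, `hit` a logical vector.
running_deviation <- function(w, hit) {
  n <- length(w)
  nh <- sum(hit)
  nr <- sum(w[hit])
  inc <- rep.int(-1 / (n - nh), n)
  if (nr > 0) {
    inc[hit] <- w[hit] / nr
  } else {
    # all hit weights zero (possible when p_weight > 0 and scores are 0):
    # fall back to equal hit increments so the sum still closes at 0
    inc[hit] <- 1 / nh
  }
  cumsum(inc)
}

fast_es <- function(w, n, hit_idx) {
  hit <- logical(n)
  hit[hit_idx] <- TRUE
  dev <- running_deviation(w, hit)
  dev[which.max(abs(dev))]
}

#' Permutation null distribution of the enrichment score
#'
#' Gene-set (membership) permutation: `n_perm` enrichment scores of sets of
#' `set_size` genes drawn uniformly at random from the ranked list.
#' Phenotype permutation is not offered because with three animals it is
#' degenerate.
#'
#' @param ranked Ranked gene list.
#' @param set_size Number of genes per random set (`0 < set_size < N`).
#' @param n_perm Number of permutations (at least 1).
#' @param p_weight Weighting exponent, as in [enrichment_score()].
#' @param seed Integer seed; the null is reproducible under a fixed seed.
#' @return Numeric vector of `n_perm` enrichment scores.
#' @export
permutation_null <- function(ranked, set_size, n_perm, p_weight = 1, seed = 1L) {
  ranked <- validate_ranked(ranked)
  n <- nrow(ranked)
  if (!is_count_scalar(set_size, min = 1) || set_size >= n) {
    stop_input("set_size must satisfy 0 < set_size < N")
  }
  if (!is_count_scalar(n_perm, min = 1)) stop_input("n_perm must be a positive integer")
  w <- abs(ranked$score)^p_weight
  with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      fast_es(w, n, sample.int(n, set_size))
    }, numeric(1L))
  })
}

#' Gene-set enrichment analysis over a collection of sets
#'
#' For every set: the enrichment score; a normalized score
#' `NES = ES / mean(|null ES| of the same sign)`; a nominal p-value, the
#' fraction of same-sign null scores at least as extreme with +1 smoothing
#' in numerator and denominator; and a Benjamini-Hochberg q-value across all
#' tested sets.  Null distributions are computed per distinct effective set
#' size and shared across sets of that size.
#'
#' @param ranked Ranked gene list.
#' @param sets List of [gene_set()] objects.  Sets that violate the
#'   [enrichment_score()] preconditions are skipped with a warning.
#' @param n_perm Number of permutations per set size (default 1000).
#' @param p_weight Weighting exponent (default 1).
#' @param seed Integer seed.
#' @return A data frame with one row per scored set: `set`, `size`, `es`,
#'   `nes`, `p`, `q`, `leading_edge_size`.  Empty input gives an empty
#'   frame.
#' @export
gsea <- function(ranked, sets, n_perm = 1000L, p_weight = 1, seed = 1L) {
  ranked <- validate_ranked(ranked)
  if (n_perm < 100L) {
    warning("n_perm < 100 gives very coarse p-values", call. = FALSE)
  }
  empty <- data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p = numeric(), q = numeric(),
                      leading_edge_size = integer(), stringsAsFactors = FALSE)
  if (length(sets) == 0L) return(empty)
  rows <- list()
  null_cache <- list()
  for (k in seq_along(sets)) {
    s <- sets[[k]]
    res <- tryCatch(enrichment_score(ranked, s, p_weight),
                    error = function(e) {
                      warning(sprintf("skipping set '%s': %s", s$name,
                                      conditionMessage(e)), call. = FALSE)
                      NULL
                    })
    if (is.null(res)) next
    size <- sum(ranked$gene_id %in% s$genes)
    key <- as.character(size)
    if (is.null(null_cache[[key]])) {
      null_cache[[key]] <- permutation_null(ranked, size, n_perm, p_weight,
                                            seed = seed + size)
    }
    null_es <- null_cache[[key]]
    same_sign <- if (res$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    p <- (1 + sum(abs(same_sign) >= abs(res$es))) / (1 + length(same_sign))
    denom <- mean(abs(same_sign))
    nes <- if (length(same_sign) && denom > 0) res$es / denom else NA_real_
    rows[[length(rows) + 1L]] <-
      data.frame(set = s$name, size = size, es = res$es, nes = nes, p = p,
                 q = NA_real_, leading_edge_size = length(res$leading_edge),
                 stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Gene set of the top-k genes of a reference ranking
#'
#' @param reference Ranked gene list.
#' @param k Number of leading genes to take (`1 <= k < N`).
#' @return A [gene_set()] named `top_<k>`.
#' @export
top_k_gene_set <- function(reference, k) {
  reference <- validate_ranked(reference)
  n <- nrow(reference)
  if (!is_count_scalar(k, min = 1) || k >= n) {
    stop_input("k must satisfy 1 <= k < N (N = %d)", n)
  }
  gene_set(sprintf("top_%d", k), reference$gene_id[seq_len(k)])
}
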