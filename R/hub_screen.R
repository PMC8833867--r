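# End-to-end driver: counts -> filtered -> normalized -> step-wise selection
# -> co-expression network -> trim -> centralities -> sum rank scores ->
# hub report.

#' Screen a breath-hold time course for hub genes
#'
#' Runs the full nomination pipeline on a count matrix and its sample
#' metadata: low-count filtering, median-of-ratios normalization, per-
#' timepoint aggregation, step-wise-increase selection, co-expression
#' network construction over the selected genes (or an externally supplied
#' network), exclusion of named genes followed by a single-pass trim of
#' nodes with 0 or 1 connection, the six centrality metrics, sum rank
#' scores, and the final hub report ordered by ascending sum rank score
#' with fold change as tie-break.
#'
#' @param counts Integer count matrix (genes x samples).
#' @param metadata Sample metadata (`sample_id`, `animal_id`,
#'   `timepoint_minutes`).
#' @param min_reads Low-count filter threshold (default 10).
#' @param min_abs_corr Absolute-correlation edge threshold for the
#'   co-expression network, applied to log2(normalized + 1) expression
#'   (default 0.98: with only a handful of samples, correlation estimates
#'   are noisy and a strict threshold keeps the edge set conservative).
#' @param graph Optional externally derived `gene_graph` over the selected
#'   genes; when supplied, `min_abs_corr` is ignored and the graph is
#'   restricted to the selected genes before trimming.
#' @param excluded_ids Node identifiers removed before trimming (default
#'   the two named small non-coding RNA families, RF00016 and RF00026).
#' @param strict,unanimity Selection flags, see
#'   [select_stepwise_increasing()].
#' @param pseudocount Fold-change pseudocount (default 0.5, applied only
#'   when a zero baseline makes it necessary).
#' @param iterate_trim Iterate the degree trim to the 2-core (default
#'   `FALSE`, single pass).
#' @return An object of class `hub_screen`: a list with `report` (the hub
#'   table), `selected`, `size_factors`, `profiles`, `fold_changes`,
#'   `graph`, `trimmed`, `centralities`, `rank_scores` and `call`.
#' @examples
#' sim <- generate_counts(synthetic_config(n_genes = 300, seed = 7))
#' fit <- hub_screen(sim$counts, sim$metadata)
#' print(fit)
#' head(summary(fit))
#' @export
hub_screen <- function(counts, metadata,
                       min_reads = 10L,
                       min_abs_corr = 0.98,
                       graph = NULL,
                       excluded_ids = c("RF00016", "RF00026"),
                       strict = TRUE,
                       unanimity = FALSE,
                       pseudocount = 0.5,
                       iterate_trim = FALSE) {
  validate_counts(counts)
  filtered <- filter_low_counts(counts, min_reads)
  if (nrow(filtered) == 0L) stop_input("no gene passes the low-count filter")
  size_factors <- estimate_size_factors(filtered)
  normalized <- normalize_counts(filtered, size_factors)
  mode <- if (unanimity) "per_animal" else "mean"
  profiles <- timepoint_profiles(normalized, metadata, mode = mode)
  selected <- select_stepwise_increasing(profiles, strict = strict,
                                         unanimity = unanimity)
  mean_profiles <- if (unanimity) {
    timepoint_profiles(normalized, metadata, mode = "mean")
  } else profiles
  pc <- if (any(mean_profiles$profiles[, 1L] == 0)) pseudocount else 0
  fc <- fold_changes(mean_profiles, pseudocount = pc)

  if (is.null(graph)) {
    # correlate on the log scale: raw normalized counts are log-normally
    # skewed and a single deep sample can dominate a 9-sample correlation
    graph <- if (length(selected) >= 2L) {
      build_coexpression_graph(log2(normalized + 1), selected, min_abs_corr)
    } else {
      gene_graph(selected)
    }
  } else {
    stopifnot(inherits(graph, "gene_graph"))
    graph <- subgraph_drop(graph, setdiff(graph$nodes, selected))
  }
  trimmed <- trim_graph(graph, excluded_ids = excluded_ids,
                        iterate = iterate_trim)
  if (length(trimmed$nodes)) {
    centralities <- compute_centralities(trimmed)
    rank_scores <- sum_rank_scores(centralities)
    report <- prioritize_hubs(rank_scores, fc)
  } else {
    centralities <- compute_centralities(trimmed)
    rank_scores <- data.frame(gene_id = character(),
                              sum_rank_score = numeric())
    report <- data.frame(gene_id = character(), sum_rank_score = numeric(),
                         fold_change = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(report = report,
                 selected = selected,
                 size_factors = size_factors,
                 profiles = mean_profiles,
                 fold_changes = fc,
                 graph = graph,
                 trimmed = trimmed,
                 centralities = centralities,
                 rank_scores = rank_scores,
                 n_genes_input = nrow(counts),
                 n_genes_filtered = nrow(filtered),
                 call = match.call()),
            class = "hub_screen")
}

#' @export
print.hub_screen <- function(x, n = 5L, ...) {
  cat("Breath-hold hub screen\n")
  cat(sprintf("  genes: %d input, %d after low-count filter, %d step-wise increasing\n",
              x$n_genes_input, x$n_genes_filtered, length(x$selected)))
  cat(sprintf("  network: %d nodes / %d edges; %d nodes / %d edges after trim\n",
              length(x$graph$nodes), nrow(x$graph$edges),
              length(x$trimmed$nodes), nrow(x$trimmed$edges)))
  if (nrow(x$report)) {
    cat(sprintf("  top hub: %s (sum rank score %.1f, fold change %.2f)\n",
                x$report$gene_id[1L], x$report$sum_rank_score[1L],
                x$report$fold_change[1L]))
    cat("\nLeading genes:\n")
    print(utils::head(x$report, n), row.names = FALSE)
  } else {
    cat("  no genes survive network trimming\n")
  }
  invisible(x)
}

#' Summarize a hub screen
#'
#' @param object A `hub_screen` object.
#' @param ... Unused.
#' @return The hub report merged with the six per-metric ranks, one row per
#'   surviving gene in hub order.
#' @export
summary.hub_screen <- function(object, ...) {
  if (!nrow(object$report)) return(object$report)
  merged <- merge(object$report, object$rank_scores[, setdiff(
    colnames(object$rank_scores), "sum_rank_score")], by = "gene_id",
    sort = FALSE)
  merged[order(match(merged$gene_id, object$report$gene_id)), , drop = FALSE]
}

#' Plot sum rank score against fold change
#'
#' The classic hub view: the most interesting genes sit at low sum rank
#' score (well connected) and high fold change (strongly induced); the top
#' gene is labelled.
#'
#' @param x A `hub_screen` object.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.hub_screen <- function(x, ...) {
  if (!nrow(x$report)) {
    warning("empty hub report; nothing to plot", call. = FALSE)
    return(invisible(x))
  }
  with(x$report, {
    plot(sum_rank_score, fold_change,
         xlab = "sum rank score (low = hub-like)",
         ylab = "fold change (last timepoint / baseline)", ...)
    graphics::text(sum_rank_score[1L], fold_change[1L],
                   labels = gene_id[1L], pos = 4, offset = 0.4)
  })
  invisible(x)
}
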