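# Seeded simulator for the study design the pipeline targets: a handful of
# animals sampled at a few timepoints of a breath hold, negative-binomial
# gene counts with a planted monotone-increasing subset and a planted
# co-expression hub module, a reference ranking with controlled top-k
# overlap, and replicate enzyme-activity tables with a time trend.

#' Simulation configuration
#'
#' Collects every parameter of the synthetic-data generators with the study
#' design as defaults: 3 animals x 3 timepoints (baseline, 3 min, 4.5 min)
#' of blood RNA-Seq-like counts.  Counts are negative binomial
#' (`variance = mu + dispersion * mu^2`) around log-normal per-gene baseline
#' means; planted monotone genes gain `step_log2fc` log2 units per timepoint
#' step.  Hub-module genes follow a shared latent "program" (a per-sample
#' Gaussian factor of scale `factor_sd` plus one per-animal offset common to
#' the whole module); the program is recentered within each timepoint so the
#' module's expected count-scale timepoint means follow the planted trend
#' exactly.  Module members add private log-scale noise around the program
#' while the module's seed gene -- the hub -- does not, so `hub_corr` is the
#' target hub-member correlation of log expression and member-member
#' correlations are roughly `hub_corr^2`.
#'
#' @param n_animals Number of animals (default 3).
#' @param timepoints_minutes Strictly increasing non-negative timepoints
#'   (default `c(0, 3, 4.5)`).
#' @param n_genes Number of genes (default 2000).
#' @param n_monotone Number of planted monotone genes, hub module included
#'   (default 30, roughly the ~1% of quantified genes reported as
#'   consistent risers in small blood time courses).
#' @param step_log2fc Planted per-step log2 increment (default 1).
#' @param baseline_mean_log_mu,baseline_mean_log_sigma Log-normal (natural
#'   log) parameters of per-gene baseline mean counts (defaults 4.6 and
#'   1.2: median ~100 counts).
#' @param dispersion Negative-binomial dispersion (default 0.01, the
#'   repeated-measures regime of well-expressed genes sampled from the same
#'   individual); values below 1e-12 switch to Poisson sampling.
#' @param library_size_range Range of multiplicative per-sample depth
#'   factors, drawn uniformly (default `c(0.7, 1.4)`).
#' @param hub_module_size Number of genes in the planted hub module,
#'   either 0 (no module) or at least 3 (default 10).
#' @param hub_corr Target log-scale correlation between a module member and
#'   the hub, in (0, 1) (default 0.999: a tight module whose recovery is
#'   limited by the pipeline, not by simulator noise).
#' @param factor_sd Scale of the latent module program on the natural-log
#'   mean (default 3.5, large enough that module correlation dominates
#'   counting noise at three animals x three timepoints).
#' @param animal_effect_sd Standard deviation of per-animal log-scale
#'   offsets mimicking individual-dependent expression: gene-by-animal
#'   offsets for background genes, one shared per-animal offset for the
#'   module (default 0.3).
#' @param background_edge_prob Probability of a background edge between any
#'   gene pair in the ground-truth edge list (default 0.001).
#' @param planted_min_baseline Lower floor on planted genes' baseline mean
#'   counts so that responders are well quantified (default 300).
#' @param assay_baseline Mean enzyme activity at baseline, arbitrary assay
#'   units (default 10).
#' @param assay_step_effect Additive per-timepoint-step shift in activity
#'   (default 2).
#' @param assay_noise_sd Gaussian replicate noise of the assay (default 1).
#' @param n_replicates Replicates per animal and timepoint (default 3).
#' @param seed Integer seed; all generators are bitwise-reproducible under
#'   it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_animals = 3L,
                             timepoints_minutes = c(0, 3, 4.5),
                             n_genes = 2000L,
                             n_monotone = 30L,
                             step_log2fc = 1,
                             baseline_mean_log_mu = 4.6,
                             baseline_mean_log_sigma = 1.2,
                             dispersion = 0.01,
                             library_size_range = c(0.7, 1.4),
                             hub_module_size = 10L,
                             hub_corr = 0.999,
                             factor_sd = 3.5,
                             animal_effect_sd = 0.3,
                             background_edge_prob = 0.001,
                             planted_min_baseline = 300,
                             assay_baseline = 10,
                             assay_step_effect = 2,
                             assay_noise_sd = 1,
                             n_replicates = 3L,
                             seed = 1L) {
  config <- structure(list(
    n_animals = n_animals, timepoints_minutes = timepoints_minutes,
    n_genes = n_genes, n_monotone = n_monotone, step_log2fc = step_log2fc,
    baseline_mean_log_mu = baseline_mean_log_mu,
    baseline_mean_log_sigma = baseline_mean_log_sigma,
    dispersion = dispersion, library_size_range = library_size_range,
    hub_module_size = hub_module_size, hub_corr = hub_corr,
    factor_sd = factor_sd, animal_effect_sd = animal_effect_sd,
    background_edge_prob = background_edge_prob,
    planted_min_baseline = planted_min_baseline,
    assay_baseline = assay_baseline, assay_step_effect = assay_step_effect,
    assay_noise_sd = assay_noise_sd, n_replicates = n_replicates,
    seed = seed), class = "synthetic_config")
  validate_config(config)
}

validate_config <- function(config) {
  fail <- function(field, why) stop_input("invalid config field `%s`: %s", field, why)
  c_ <- config
  if (!is_count_scalar(c_$n_animals, 1)) fail("n_animals", "must be a positive integer")
  tp <- c_$timepoints_minutes
  if (!is.numeric(tp) || length(tp) < 2L || any(tp < 0) || any(diff(tp) <= 0)) {
    fail("timepoints_minutes", "must be >= 2 strictly increasing non-negative values")
  }
  if (!is_count_scalar(c_$n_genes, 1)) fail("n_genes", "must be a positive integer")
  if (!is_count_scalar(c_$n_monotone, 0) || c_$n_monotone > c_$n_genes) {
    fail("n_monotone", "must be an integer in [0, n_genes]")
  }
  if (!is_real_scalar(c_$step_log2fc) || c_$step_log2fc <= 0) {
    fail("step_log2fc", "must be a positive real")
  }
  if (!is_real_scalar(c_$baseline_mean_log_mu)) fail("baseline_mean_log_mu", "must be a real")
  if (!is_real_scalar(c_$baseline_mean_log_sigma) || c_$baseline_mean_log_sigma < 0) {
    fail("baseline_mean_log_sigma", "must be a non-negative real")
  }
  if (!is_real_scalar(c_$dispersion) || c_$dispersion < 0) {
    fail("dispersion", "must be a non-negative real")
  }
  lr <- c_$library_size_range
  if (!is.numeric(lr) || length(lr) != 2L || any(lr <= 0) || lr[2L] < lr[1L]) {
    fail("library_size_range", "must be an increasing pair of positive reals")
  }
  if (!is_count_scalar(c_$hub_module_size, 0) ||
      (c_$hub_module_size > 0 && c_$hub_module_size < 3)) {
    fail("hub_module_size", "must be 0 or an integer >= 3")
  }
  if (c_$n_monotone + 0 > c_$n_genes) fail("n_monotone", "exceeds n_genes")
  if (c_$hub_module_size > c_$n_monotone) {
    fail("hub_module_size", "hub module must fit inside the monotone gene set")
  }
  if (!is_real_scalar(c_$hub_corr) || c_$hub_corr <= 0 || c_$hub_corr >= 1) {
    fail("hub_corr", "must lie strictly between 0 and 1")
  }
  if (!is_real_scalar(c_$factor_sd) || c_$factor_sd < 0) fail("factor_sd", "must be >= 0")
  if (!is_real_scalar(c_$animal_effect_sd) || c_$animal_effect_sd < 0) {
    fail("animal_effect_sd", "must be >= 0")
  }
  if (!is_real_scalar(c_$background_edge_prob) || c_$background_edge_prob < 0 ||
      c_$background_edge_prob > 1) {
    fail("background_edge_prob", "must lie in [0, 1]")
  }
  if (!is_real_scalar(c_$planted_min_baseline) || c_$planted_min_baseline <= 0) {
    fail("planted_min_baseline", "must be a positive real")
  }
  if (!is_real_scalar(c_$assay_baseline)) fail("assay_baseline", "must be a real")
  if (!is_real_scalar(c_$assay_step_effect)) fail("assay_step_effect", "must be a real")
  if (!is_real_scalar(c_$assay_noise_sd) || c_$assay_noise_sd < 0) {
    fail("assay_noise_sd", "must be >= 0")
  }
  if (!is_count_scalar(c_$n_replicates, 2)) fail("n_replicates", "must be an integer >= 2")
  if (!is.numeric(c_$seed) || length(c_$seed) != 1L || is.na(c_$seed)) {
    fail("seed", "must be a single integer")
  }
  config
}

#' Simulate a count matrix with planted structure
#'
#' Generates one sample per animal and timepoint.  On the natural-log mean
#' scale each gene receives a log-normal baseline, a planted
#' `log(2) * step_log2fc` increment per timepoint step (monotone genes
#' only), a gene-by-animal random offset (background genes), the shared
#' module program plus member-private noise (module genes), and a
#' per-sample library depth factor; counts are then drawn
#' negative-binomially.  The program is recentered within each timepoint so
#' the module's expected count-scale timepoint means follow the planted
#' trend exactly.
#'
#' @param config A [synthetic_config()].
#' @return A list with `counts` (integral-valued numeric matrix genes x
#'   samples),
#'   `metadata` (sample metadata data frame) and `truth`, a list with
#'   `monotone_gene_ids`, `hub_gene_id`, `module_gene_ids` and `true_edges`
#'   (data frame `from`/`to`: all within-module pairs plus random
#'   background pairs).
#' @export
generate_counts <- function(config) {
  config <- validate_config(config)
  n_tp <- length(config$timepoints_minutes)
  n_samples <- config$n_animals * n_tp
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  animals <- sprintf("d%d", seq_len(config$n_animals))
  meta <- data.frame(
    sample_id = as.vector(outer(animals, seq_len(n_tp),
                                function(a, t) sprintf("%s_t%d", a, t))),
    animal_id = rep(animals, times = n_tp),
    timepoint_minutes = rep(config$timepoints_minutes, each = config$n_animals),
    stringsAsFactors = FALSE)

  with_seed(config$seed, {
    monotone_idx <- sort(sample.int(config$n_genes, config$n_monotone))
    module_idx <- if (config$hub_module_size > 0) {
      sort(sample(monotone_idx, config$hub_module_size))
    } else integer(0)
    hub_idx <- if (length(module_idx)) sample(module_idx, 1L) else NA_integer_

    baseline <- rnorm(config$n_genes, config$baseline_mean_log_mu,
                      config$baseline_mean_log_sigma)
    baseline[monotone_idx] <- pmax(baseline[monotone_idx],
                                   log(config$planted_min_baseline))

    animal_eff <- matrix(rnorm(config$n_genes * config$n_animals,
                               sd = config$animal_effect_sd),
                         nrow = config$n_genes)

    # Latent module program: per-sample factor plus the module's shared
    # per-animal offset.  The program is recentered within each timepoint so
    # that the mean of exp(program) over the timepoint's samples is constant:
    # the module's expected count-scale timepoint means are then exactly the
    # planted trend, and the program only creates within-timepoint
    # covariation.
    module_animal <- rnorm(config$n_animals, sd = config$animal_effect_sd)
    animal_index <- rep(seq_len(config$n_animals), times = n_tp)
    program <- config$factor_sd * rnorm(n_samples) + module_animal[animal_index]
    if (config$n_animals > 1L && config$factor_sd > 0) {
      tp_of <- rep(seq_len(n_tp), each = config$n_animals)
      program <- program - log(ave(exp(program), tp_of)) +
        config$factor_sd^2 / 2
    }
    # Module genes follow one latent "program": a per-sample factor plus a
    # shared per-animal offset (the program's activity differs between
    # individuals as a unit, so individual variation is shared signal within
    # the module, not private noise).  Members -- but not the hub -- add
    # private noise on top, so the hub is the gene that tracks the program
    # most tightly; hub_corr is the member-to-hub log-scale correlation
    # target.  Module genes do not receive the per-gene animal offsets.
    member_noise_sd <- numeric(config$n_genes)
    members <- setdiff(module_idx, hub_idx)
    member_noise_sd[members] <- config$factor_sd *
      sqrt(1 / config$hub_corr^2 - 1)
    if (length(module_idx)) {
      animal_eff[module_idx, ] <- 0
    }

    lib <- runif(n_samples, config$library_size_range[1L],
                 config$library_size_range[2L])

    tp_index0 <- rep(seq_len(n_tp) - 1L, each = config$n_animals)
    trend <- numeric(config$n_genes)
    trend[monotone_idx] <- log(2) * config$step_log2fc
    in_module <- as.numeric(seq_len(config$n_genes) %in% module_idx)

    ln_mu <- outer(trend, tp_index0) +
      baseline +
      animal_eff[, animal_index, drop = FALSE] +
      outer(in_module, program) +
      matrix(rnorm(config$n_genes * n_samples, sd = member_noise_sd),
             nrow = config$n_genes) +
      rep(log(lib), each = config$n_genes)
    mu <- exp(ln_mu)

    counts <- if (config$dispersion < 1e-12) {
      rpois(length(mu), lambda = mu)
    } else {
      rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    }
    # stored as numeric: occasional module counts exceed .Machine$integer.max
    counts <- matrix(round(counts), nrow = config$n_genes,
                     dimnames = list(gene_ids, meta$sample_id))

    true_edges <- module_true_edges(gene_ids, module_idx,
                                    config$background_edge_prob)

    list(counts = counts,
         metadata = meta,
         truth = list(
           monotone_gene_ids = gene_ids[monotone_idx],
           hub_gene_id = if (is.na(hub_idx)) NA_character_ else gene_ids[hub_idx],
           module_gene_ids = gene_ids[module_idx],
           true_edges = true_edges))
  })
}

# All within-module pairs plus background pairs drawn with the given
# probability over all unordered gene pairs.
module_true_edges <- function(gene_ids, module_idx, background_edge_prob) {
  edges <- if (length(module_idx) >= 2L) {
    pairs <- utils::combn(gene_ids[module_idx], 2L)
    data.frame(from = pairs[1L, ], to = pairs[2L, ], stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
  }
  n <- length(gene_ids)
  n_pairs <- n * (n - 1) / 2
  if (background_edge_prob > 0 && n_pairs > 0) {
    m <- rbinom(1L, n_pairs, background_edge_prob)
    if (m > 0) {
      idx <- sample(n_pairs, m)
      # unrank the pair index: pairs (i, j), i < j, ordered by i then j;
      # row i holds n - i pairs, so cumulative row ends locate i
      row_end <- cumsum(n - seq_len(n - 1L))
      i <- findInterval(idx - 1, row_end) + 1L
      j <- idx - c(0, row_end)[i] + i
      bg <- data.frame(from = gene_ids[i], to = gene_ids[j],
                       stringsAsFactors = FALSE)
      edges <- unique(rbind(edges, bg))
    }
  }
  rownames(edges) <- NULL
  edges
}

#' Simulate a reference ranking with controlled top-k overlap
#'
#' Builds a "foreign reference" ranking (the stand-in for an independent
#' whole-blood expression ranking) whose top-`k` membership overlaps the
#' synthetic query ranking's top-`k` by exactly
#' `round(overlap_fraction * k)` genes.  The query ranking is the
#' total-expression ranking of the normalized simulated counts under the
#' same configuration.
#'
#' @param config A [synthetic_config()].
#' @param overlap_fraction Fraction of the top-`k` shared with the query
#'   ranking, in [0, 1].
#' @param k Size of the top block (default 100; needs
#'   `2 * k <=` number of filtered genes so that zero overlap is always
#'   constructible).
#' @return A list with `reference` (ranked gene list), `query` (ranked gene
#'   list) and `k`.
#' @export
generate_reference_ranking <- function(config, overlap_fraction, k = 100L) {
  config <- validate_config(config)
  if (!is_real_scalar(overlap_fraction) || overlap_fraction < 0 ||
      overlap_fraction > 1) {
    stop_input("overlap_fraction must lie in [0, 1]")
  }
  sim <- generate_counts(config)
  filtered <- filter_low_counts(sim$counts)
  normalized <- normalize_counts(filtered, estimate_size_factors(filtered))
  query <- rank_by_total_expression(normalized)
  n <- nrow(query)
  if (!is_count_scalar(k, 1) || 2L * k > n) {
    stop_input("k must satisfy 1 <= k <= N/2 (N = %d filtered genes)", n)
  }
  n_shared <- round(overlap_fraction * k)
  with_seed(config$seed + 1000L, {
    top_query <- query$gene_id[seq_len(k)]
    rest <- query$gene_id[-seq_len(k)]
    shared <- if (n_shared > 0) sample(top_query, n_shared) else character()
    fillers <- sample(rest, k - n_shared)
    top_ref <- sample(c(shared, fillers))
    below <- sample(setdiff(query$gene_id, top_ref))
    ref_ids <- c(top_ref, below)
  })
  reference <- data.frame(gene_id = ref_ids,
                          score = seq(n, 1),
                          rank = seq_len(n),
                          stringsAsFactors = FALSE)
  list(reference = reference, query = query, k = k)
}

#' Simulate a replicate enzyme-activity table
#'
#' Activity for animal a, timepoint index t (0-based), replicate r is
#' `assay_baseline + assay_step_effect * t + N(0, assay_noise_sd)`,
#' independent across replicates; deterministic under the configuration
#' seed.
#'
#' @param config A [synthetic_config()].
#' @return An assay table data frame (`animal_id`, `timepoint_minutes`,
#'   `replicate`, `activity`).
#' @export
generate_assay_data <- function(config) {
  config <- validate_config(config)
  animals <- sprintf("d%d", seq_len(config$n_animals))
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      animal_id = animals,
                      tp_index = seq_along(config$timepoints_minutes),
                      stringsAsFactors = FALSE)
  with_seed(config$seed + 2000L, {
    activity <- config$assay_baseline +
      config$assay_step_effect * (grid$tp_index - 1L) +
      rnorm(nrow(grid), sd = config$assay_noise_sd)
  })
  data.frame(animal_id = grid$animal_id,
             timepoint_minutes = config$timepoints_minutes[grid$tp_index],
             replicate = grid$replicate,
             activity = activity,
             stringsAsFactors = FALSE)
}

#' Write simulation ground truth to JSON
#'
#' @param truth The `truth` component of [generate_counts()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(monotone_gene_ids = truth$monotone_gene_ids,
         hub_gene_id = truth$hub_gene_id,
         module_gene_ids = truth$module_gene_ids,
         true_edges = truth$true_edges),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
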