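# Readers and writers for the plain-text interchange formats used throughout
# the pipeline: counts TSV, sample metadata TSV, edge-list TSV, GMT gene
# sets, assay tables, and simple ranked lists.

#' Read a gene-level count matrix from TSV
#'
#' The expected layout is a header row of sample identifiers, a first column
#' of gene identifiers (any header), and non-negative integer counts.
#' Validation is strict: non-integer or negative entries are rejected with
#' the offending file line, as are duplicated gene or sample identifiers.
#'
#' @param path Path to a tab-separated count file.
#' @return An integer matrix with genes as rows and samples as columns,
#'   carrying gene and sample identifiers as dimnames.
#' @seealso [write_counts()], [filter_low_counts()]
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop_input("count file not found: %s", path)
  raw <- read.delim(path, header = TRUE, colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop_input("count file needs a gene-id column plus at least one sample column")
  gene_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  values <- as.matrix(raw[, -1L, drop = FALSE])
  bad <- matrix(!grepl("^[0-9]+$", values), nrow = nrow(values))
  if (any(bad)) {
    row <- which(apply(bad, 1L, any))[1L]
    stop_input("non-integer or negative count at file line %d (gene %s)",
               row + 1L, gene_ids[row])
  }
  counts <- matrix(as.integer(values), nrow = nrow(raw),
                   dimnames = list(gene_ids, sample_ids))
  validate_counts(counts)
  counts
}

#' Write a count matrix to TSV
#'
#' @param counts Integer count matrix (genes x samples) with dimnames.
#' @param path Output path.
#' @param id_column Header for the gene-identifier column.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, id_column = "gene_id") {
  validate_counts(counts)
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_counts <- function(counts) {
  if (!is.matrix(counts)) stop_input("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_input("counts must carry gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) stop_input("duplicate gene identifiers in count matrix")
  if (anyDuplicated(colnames(counts))) stop_input("duplicate sample identifiers in count matrix")
  if (length(counts) &&
      (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts)))) {
    stop_input("counts must be non-negative integers")
  }
  invisible(counts)
}

#' Read sample metadata from TSV
#'
#' Requires columns `sample_id`, `animal_id` and `timepoint_minutes` (an
#' optional `batch` column is kept if present).  Each (animal, timepoint)
#' pair may appear at most once and at least two distinct timepoints are
#' required.
#'
#' @param path Path to a tab-separated metadata file.
#' @return A data frame of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop_input("metadata file not found: %s", path)
  meta <- read.delim(path, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
  validate_metadata(meta)
}

validate_metadata <- function(meta) {
  needed <- c("sample_id", "animal_id", "timepoint_minutes")
  missing <- setdiff(needed, colnames(meta))
  if (length(missing)) {
    stop_input("metadata is missing column(s): %s", paste(missing, collapse = ", "))
  }
  meta$sample_id <- as.character(meta$sample_id)
  meta$animal_id <- as.character(meta$animal_id)
  meta$timepoint_minutes <- as.numeric(meta$timepoint_minutes)
  if (anyDuplicated(meta$sample_id)) stop_input("duplicate sample_id in metadata")
  if (any(!is.finite(meta$timepoint_minutes)) || any(meta$timepoint_minutes < 0)) {
    stop_input("timepoint_minutes must be non-negative numbers")
  }
  if (length(unique(meta$timepoint_minutes)) < 2L) {
    stop_input("metadata must contain at least 2 distinct timepoints")
  }
  if (anyDuplicated(meta[, c("animal_id", "timepoint_minutes")])) {
    stop_input("each (animal, timepoint) pair may appear at most once")
  }
  meta
}

# Check that metadata covers exactly the samples of a count/normalized matrix.
match_metadata <- function(mat, meta) {
  meta <- validate_metadata(meta)
  missing <- setdiff(colnames(mat), meta$sample_id)
  if (length(missing)) {
    stop_input("metadata missing sample(s): %s", paste(missing, collapse = ", "))
  }
  meta[match(colnames(mat), meta$sample_id), , drop = FALSE]
}

#' Read an undirected edge list from TSV
#'
#' Expects columns `gene_a`, `gene_b` and optionally `weight`.  Duplicate and
#' reversed edges are collapsed (first weight wins); self-loops and
#' non-positive weights are rejected.
#'
#' @param path Path to a tab-separated edge-list file.
#' @return A [gene_graph()] object.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop_input("edge-list file not found: %s", path)
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  needed <- c("gene_a", "gene_b")
  if (!all(needed %in% colnames(df))) {
    stop_input("edge list needs columns gene_a and gene_b")
  }
  weight <- if ("weight" %in% colnames(df)) as.numeric(df$weight) else rep(1, nrow(df))
  gene_graph_from_edges(as.character(df$gene_a), as.character(df$gene_b), weight)
}

#' Write a graph's edge list to TSV
#'
#' @param graph A [gene_graph()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "gene_graph"))
  edges <- graph$edges
  colnames(edges) <- c("gene_a", "gene_b", "weight")
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT is the tab-separated gene-set format: one set per line, fields are the
#' set name, a free-text description, then the member genes.
#'
#' @param path Path to a GMT file.
#' @return A named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_input("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(line) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) stop_input("malformed GMT line: %s", substr(line, 1, 60))
    gene_set(fields[1L], fields[-(1:2)], description = fields[2L])
  })
  names(sets) <- vapply(sets, `[[`, character(1L), "name")
  if (anyDuplicated(names(sets))) stop_input("duplicate set names in GMT file")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets A list of [gene_set()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    stopifnot(inherits(s, "gene_set"))
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a replicate enzyme-activity table from TSV
#'
#' Expects columns `animal_id`, `timepoint_minutes`, `replicate` and
#' `activity`.
#'
#' @param path Path to a tab-separated assay table.
#' @return A data frame with one row per replicate measurement.
#' @export
read_assay_table <- function(path) {
  if (!file.exists(path)) stop_input("assay file not found: %s", path)
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  validate_assay_table(df)
}

validate_assay_table <- function(df) {
  needed <- c("animal_id", "timepoint_minutes", "replicate", "activity")
  missing <- setdiff(needed, colnames(df))
  if (length(missing)) {
    stop_input("assay table is missing column(s): %s", paste(missing, collapse = ", "))
  }
  df$timepoint_minutes <- as.numeric(df$timepoint_minutes)
  df$activity <- as.numeric(df$activity)
  if (any(!is.finite(df$activity))) stop_input("assay activities must be finite numbers")
  if (length(unique(df$timepoint_minutes)) < 2L) {
    stop_input("assay table needs at least 2 timepoint groups")
  }
  df
}

#' Write a ranked gene list to TSV
#'
#' @param ranked A ranked gene list as returned by
#'   [rank_by_total_expression()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranked_list <- function(ranked, path) {
  write.table(ranked, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
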