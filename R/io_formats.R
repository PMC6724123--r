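#' @keywords internal
"_PACKAGE"

# All tables in this package are tab-delimited with a header row;
# '#'-prefixed lines are comments. Gene identifiers are opaque strings.

LINE_LEVELS <- c("Ch", "Te")
TREATMENT_LEVELS <- c("LT", "N")
TIME_LEVELS <- c("T0", "T1", "T2")

read_table_raw <- function(path, what = "table") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      comment.char = "#", stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) stop("empty or unreadable ", what, " file: ",
                             path, " (", conditionMessage(e), ")",
                             call. = FALSE))
  if (nrow(df) == 0) stop("empty ", what, " file: ", path)
  df
}

#' Read a sample design table
#'
#' The design table describes the factorial layout of the experiment:
#' one row per sequencing sample, with columns `sample_id`, `line`
#' (`Ch` = Champagne, frost-tolerant; `Te` = Terese, frost-sensitive),
#' `treatment` (`LT` = low-temperature regime, `N` = control nursery),
#' `time` (`T0`, `T1`, `T2`) and `replicate`.
#'
#' @param path Path to a tab-delimited design table with a header row.
#' @return A data frame of class `sample_design` with validated factor
#'   columns, one row per sample.
#' @export
read_design <- function(path) {
  df <- read_table_raw(path, "design")
  validate_design(df)
}

#' Construct / validate a sample design
#'
#' @param df Data frame with columns `sample_id`, `line`, `treatment`,
#'   `time`, `replicate`.
#' @return The validated design with class `sample_design`.
#' @export
validate_design <- function(df) {
  required <- c("sample_id", "line", "treatment", "time", "replicate")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("design is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0) stop("design has no samples")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in design: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  check_levels <- function(col, levels) {
    bad <- which(!(df[[col]] %in% levels))
    if (length(bad) > 0)
      stop("unknown ", col, " level '", df[[col]][bad[1]],
           "' in design row ", bad[1],
           " (allowed: ", paste(levels, collapse = ", "), ")")
  }
  check_levels("line", LINE_LEVELS)
  check_levels("treatment", TREATMENT_LEVELS)
  check_levels("time", TIME_LEVELS)
  rep_num <- suppressWarnings(as.integer(df$replicate))
  if (any(is.na(rep_num)) || any(rep_num < 1))
    stop("replicate must be a positive integer")
  out <- data.frame(
    sample_id = as.character(df$sample_id),
    line = factor(df$line, levels = LINE_LEVELS),
    treatment = factor(df$treatment, levels = TREATMENT_LEVELS),
    time = factor(df$time, levels = TIME_LEVELS),
    replicate = rep_num,
    stringsAsFactors = FALSE
  )
  # balanced-design invariant: every present cell has the same replicate count
  cell <- interaction(out$line, out$treatment, out$time, drop = TRUE)
  counts <- table(cell)
  if (length(unique(as.integer(counts))) > 1)
    stop("unbalanced design: (line, treatment, time) cells have unequal ",
         "replicate counts")
  class(out) <- c("sample_design", "data.frame")
  out
}

#' The canonical 24-sample factorial design
#'
#' 2 lines x 2 treatments x 3 sampling times x 2 biological replicates.
#' Sample ids are of the form `ChLT0r1`.
#'
#' @return A `sample_design` with 24 rows.
#' @export
canonical_design <- function() {
  grid <- expand.grid(replicate = 1:2, time = TIME_LEVELS,
                      treatment = TREATMENT_LEVELS, line = LINE_LEVELS,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("line", "treatment", "time", "replicate")]
  grid$sample_id <- paste0(sub("TT", "T", paste0(grid$line, grid$treatment,
                                                 grid$time)),
                           "r", grid$replicate)
  validate_design(grid)
}

#' Condition label of each design row
#'
#' Collapses line, treatment and time into the 12 condition labels used
#' throughout (e.g. `ChLT0`), in the display order of the clustering
#' heatmaps: ChNT0..ChNT2, ChLT0..ChLT2, TeNT0..TeNT2, TeLT0..TeLT2.
#'
#' @param design A `sample_design`.
#' @return Factor of condition labels, one per sample.
#' @export
condition_labels <- function(design) {
  lab <- sub("TT", "T", paste0(design$line, design$treatment, design$time))
  factor(lab, levels = condition_order())
}

#' @rdname condition_labels
#' @export
condition_order <- function() {
  sub("TT", "T",
      as.vector(t(outer(c("ChN", "ChLT", "TeN", "TeLT"),
                        paste0("T", 0:2), paste0))))
}

#' Read a gene-by-sample count matrix
#'
#' The file is tab-delimited with gene ids in the first column and one
#' column per sample. Columns are reordered to the design's sample
#' order; files holding extra samples are subset to the design, but a
#' design sample missing from the file is an error.
#'
#' @param path Path to the count table.
#' @param design A `sample_design` giving the samples and their order.
#' @return Integer matrix, genes x samples, dimnames set.
#' @export
read_counts <- function(path, design) {
  df <- read_table_raw(path, "count")
  gene_ids <- as.character(df[[1]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids in count table")
  mat <- as.matrix(df[, -1, drop = FALSE])
  missing <- setdiff(design$sample_id, colnames(mat))
  if (length(missing) > 0)
    stop("design sample(s) missing from count file: ",
         paste(missing, collapse = ", "))
  mat <- mat[, design$sample_id, drop = FALSE]
  rownames(mat) <- gene_ids
  validate_counts(mat)
}

#' Validate a count matrix
#'
#' @param mat Numeric matrix of non-negative integer counts with gene
#'   row names and sample column names.
#' @return The matrix in integer storage mode.
#' @export
validate_counts <- function(mat) {
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop("missing count at gene '", rownames(mat)[idx[1]],
         "', sample '", colnames(mat)[idx[2]], "'")
  }
  bad <- which(mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative or non-integer count at gene '",
         rownames(mat)[bad[1, 1]], "', sample '",
         colnames(mat)[bad[1, 2]], "'")
  storage.mode(mat) <- "integer"
  mat
}

#' Write design / counts / generic tables
#'
#' Round-trip partners of the readers: `write_design()` and
#' `write_counts()` emit the exact tab-delimited dialect that
#' [read_design()] and [read_counts()] consume.
#'
#' @param design A `sample_design`.
#' @param mat Count matrix with dimnames.
#' @param df Any data frame.
#' @param path Output path.
#' @name io_writers
NULL

#' @rdname io_writers
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io_writers
#' @export
write_counts <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io_writers
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 12-column tabular BLAST hit file
#'
#' Standard tabular hit columns: query, subject, percent identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' E-value, bit score. No filtering is applied here; see
#' [link_filter()] for the linking thresholds.
#'
#' @param path Path to the hit file.
#' @return Data frame with one row per hit.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  cols <- c("query_id", "subject_id", "percent_identity",
            "alignment_length", "mismatches", "gap_opens", "qstart",
            "qend", "sstart", "send", "evalue", "bit_score")
  if (length(lines) == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), 12), cols))
    num <- setdiff(cols, c("query_id", "subject_id"))
    out[num] <- lapply(out[num], as.numeric)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12))
    stop("malformed tabular hit line ", which(nf < 12)[1],
         ": expected >= 12 tab-separated fields, got ", nf[nf < 12][1])
  rows <- lapply(fields, function(f) f[1:12])
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- cols
  num <- setdiff(cols, c("query_id", "subject_id"))
  for (cn in num) {
    v <- suppressWarnings(as.numeric(out[[cn]]))
    if (anyNA(v))
      stop("malformed tabular hit line ", which(is.na(v))[1],
           ": non-numeric value in column ", cn)
    out[[cn]] <- v
  }
  if (any(out$percent_identity < 0 | out$percent_identity > 100))
    stop("percent identity outside [0, 100]")
  if (any(out$evalue < 0)) stop("negative E-value")
  if (any(out$alignment_length < 1)) stop("non-positive alignment length")
  out
}

#' Read a GMT-style gene-set file
#'
#' Each line: term id, description, then member genes, tab-separated.
#' Members are deduplicated; blank lines are skipped.
#'
#' @param path Path to the gene-set file.
#' @return Named list: term id -> character vector of member genes.
#'   Term descriptions are kept in the `"descriptions"` attribute.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2)
  if (length(short) > 0)
    stop("gene-set line ", short[1], " has fewer than 2 fields")
  ids <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(ids))
    stop("duplicate term id: ", ids[duplicated(ids)][1])
  sets <- lapply(fields, function(f)
    unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- ids
  attr(sets, "descriptions") <- setNames(vapply(fields, `[[`, "", 2), ids)
  sets
}

#' Assemble an annotation bundle
#'
#' Carrier for the annotation sidecars used by the selection filters
#' and the functional summaries: per-gene best BLAST hit with E-value,
#' transcription-factor and kinase family labels, and GO term
#' memberships.
#'
#' @param best_hit Data frame with columns `gene_id`, `subject_id`,
#'   `evalue` (one row per gene), or NULL.
#' @param tf_family,kinase_family Data frames with columns `gene_id`,
#'   `family`, or NULL.
#' @param go_terms Named list term -> gene vector (as from
#'   [read_gene_sets()]), or NULL.
#' @return List of class `annotation_bundle`.
#' @export
annotation_bundle <- function(best_hit = NULL, tf_family = NULL,
                              kinase_family = NULL, go_terms = NULL) {
  empty_map <- function(cols) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    df
  }
  if (is.null(best_hit))
    best_hit <- data.frame(gene_id = character(0), subject_id = character(0),
                           evalue = numeric(0), stringsAsFactors = FALSE)
  if (any(best_hit$evalue < 0)) stop("negative E-value in best-hit map")
  if (anyDuplicated(best_hit$gene_id)) stop("duplicate gene in best-hit map")
  if (is.null(tf_family)) tf_family <- empty_map(c("gene_id", "family"))
  if (is.null(kinase_family)) kinase_family <- empty_map(c("gene_id", "family"))
  if (is.null(go_terms)) go_terms <- list()
  structure(list(best_hit = best_hit, tf_family = tf_family,
                 kinase_family = kinase_family, go_terms = go_terms),
            class = "annotation_bundle")
}
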