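# Data model and I/O: expression matrices, sample annotations, probe mappings,
# and the merged two-platform dataset that every normalization method consumes.

#' Construct an expression matrix
#'
#' A genes x samples matrix of natural-log expression values for one platform.
#' All values must be finite and gene/sample identifiers unique.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids Character vector of unique gene identifiers (rows).
#' @param sample_ids Character vector of unique sample identifiers (columns).
#' @return An `expression_matrix` object (a numeric matrix with dimnames and a
#'   class attribute).
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_validation("expression values must be numeric")
  if (is.null(gene_ids)) {
    if (nrow(values) > 0L) stop_validation("gene identifiers are required")
    gene_ids <- character(0)
  }
  if (is.null(sample_ids)) {
    if (ncol(values) > 0L) stop_validation("sample identifiers are required")
    sample_ids <- character(0)
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids))
    stop_validation("dimension mismatch between values and identifiers")
  if (anyDuplicated(gene_ids))
    stop_validation("duplicated gene ids: ",
                    paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop_validation("duplicated sample ids: ",
                    paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (any(!is.finite(values)))
    stop_validation("non-finite expression values present")
  dimnames(values) <- list(gene_ids, sample_ids)
  class(values) <- c("expression_matrix", class(values))
  values
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Read an expression matrix from a delimited text file
#'
#' First row holds sample ids, first column gene ids, body numeric. Values are
#' taken verbatim (no transformation); tab-delimited by default with commas
#' auto-detected from the header line.
#'
#' @param path Path to a TSV/CSV file.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2L) stop_parse("expression table needs gene ids plus >= 1 sample")
  gene_ids <- df[[1L]]
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_parse(sprintf("non-numeric cell at gene '%s', sample '%s' (value '%s')",
                       gene_ids[bad[1L, 1L]], colnames(body)[bad[1L, 2L]],
                       body[bad[1L, 1L], bad[1L, 2L]]))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    stop_parse(sprintf("missing value at gene '%s', sample '%s'",
                       gene_ids[bad[1L, 1L]], colnames(body)[bad[1L, 2L]]))
  }
  expression_matrix(num, gene_ids, colnames(body))
}

#' @noRd
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("\t", header) && grepl(",", header)) "," else "\t"
}

#' Read a sample annotation table
#'
#' Requires columns `sample_id`, `platform`, `treatment`; `study` is optional
#' (defaults to a single study label). Unknown extra columns are ignored with
#' a warning.
#'
#' @param path Path to a TSV/CSV file.
#' @return A `sample_annotation` data frame.
#' @export
read_sample_annotation <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  sample_annotation(df)
}

#' Construct a sample annotation
#'
#' @param df Data frame with columns `sample_id`, `platform`, `treatment` and
#'   optionally `study`.
#' @return A `sample_annotation` data frame.
#' @export
sample_annotation <- function(df) {
  required <- c("sample_id", "platform", "treatment")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop_parse("annotation missing required column(s): ",
               paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) stop_validation("no samples in annotation")
  extra <- setdiff(names(df), c(required, "study"))
  if (length(extra) > 0L)
    warning("ignoring unknown annotation column(s): ", paste(extra, collapse = ", "))
  if (!("study" %in% names(df))) df$study <- "study1"
  df <- df[, c(required, "study")]
  df[] <- lapply(df, as.character)
  if (anyDuplicated(df$sample_id))
    stop_validation("duplicated sample ids in annotation: ",
                    paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  rownames(df) <- df$sample_id
  class(df) <- c("sample_annotation", "data.frame")
  df
}

#' Construct a probe-to-gene mapping table
#'
#' @param df Data frame with columns `platform`, `probe_id`, `gene_id`;
#'   `(platform, probe_id)` pairs must be unique.
#' @return A `probe_mapping` data frame.
#' @export
probe_mapping <- function(df) {
  required <- c("platform", "probe_id", "gene_id")
  if (!all(required %in% names(df)))
    stop_parse("mapping requires columns: ", paste(required, collapse = ", "))
  df <- df[, required]
  df[] <- lapply(df, as.character)
  key <- paste(df$platform, df$probe_id, sep = "\r")
  if (anyDuplicated(key))
    stop_validation("duplicated (platform, probe) pairs in mapping")
  class(df) <- c("probe_mapping", "data.frame")
  df
}

#' Merge two single-platform matrices into a combined two-platform dataset
#'
#' Probes mapping to the same gene are averaged (arithmetic mean of log
#' values) within each platform; the gene list is the intersection of the two
#' platforms' mapped genes, sorted lexicographically, and both matrices are
#' reordered to it. The operation is idempotent.
#'
#' @param m1,m2 [expression_matrix()] objects for the two platforms.
#' @param annotation A [sample_annotation()] covering every sample of both
#'   matrices; the two platforms must carry distinct platform labels and no
#'   sample may appear on both.
#' @param mapping Optional [probe_mapping()]; when given, row ids of `m1`/`m2`
#'   are probe ids resolved through it, otherwise they are taken as gene ids.
#' @param discrete Logical; marks datasets holding integer codes (after
#'   quantile or normal discretization).
#' @return A `combined_dataset`: list with elements `platform1`, `platform2`
#'   (gene-aligned matrices), `annotation`, `platforms` (the two labels) and
#'   `discrete`.
#' @export
combined_dataset <- function(m1, m2, annotation, mapping = NULL,
                             discrete = FALSE) {
  annotation <- if (inherits(annotation, "sample_annotation")) annotation
                else sample_annotation(annotation)
  for (m in list(m1, m2)) {
    missing_samp <- setdiff(colnames(m), annotation$sample_id)
    if (length(missing_samp) > 0L)
      stop_validation("samples absent from annotation: ",
                      paste(missing_samp, collapse = ", "))
  }
  if (length(intersect(colnames(m1), colnames(m2))) > 0L)
    stop_validation("a sample appears on both platforms")
  p1 <- unique(annotation[colnames(m1), "platform"])
  p2 <- unique(annotation[colnames(m2), "platform"])
  if (length(p1) != 1L || length(p2) != 1L || p1 == p2)
    stop_validation("each matrix must map to exactly one distinct platform label")
  if (!is.null(mapping)) {
    m1 <- collapse_probes(m1, mapping, p1)
    m2 <- collapse_probes(m2, mapping, p2)
  } else {
    m1 <- collapse_duplicate_rows(m1)
    m2 <- collapse_duplicate_rows(m2)
  }
  genes <- sort(intersect(rownames(m1), rownames(m2)), method = "radix")
  if (length(genes) == 0L) stop_validation("empty gene intersection between platforms")
  d <- structure(list(
    platform1 = expression_matrix(m1[genes, , drop = FALSE]),
    platform2 = expression_matrix(m2[genes, , drop = FALSE]),
    annotation = annotation[c(colnames(m1), colnames(m2)), ],
    platforms = c(p1, p2),
    discrete = isTRUE(discrete)
  ), class = "combined_dataset")
  d
}

#' @noRd
collapse_probes <- function(m, mapping, platform) {
  map <- mapping[mapping$platform == platform, ]
  idx <- match(rownames(m), map$probe_id)
  keep <- !is.na(idx)
  if (!any(keep)) stop_validation("no probes of platform '", platform,
                                  "' resolve through the mapping")
  m <- m[keep, , drop = FALSE]
  gene <- map$gene_id[idx[keep]]
  average_by_gene(m, gene)
}

#' @noRd
collapse_duplicate_rows <- function(m) {
  if (!anyDuplicated(rownames(m))) return(m)
  average_by_gene(unclass(m), rownames(m))
}

#' @noRd
average_by_gene <- function(m, gene) {
  agg <- rowsum(unclass(m), group = gene)
  counts <- as.vector(table(gene)[rownames(agg)])
  agg / counts
}

#' @export
print.combined_dataset <- function(x, ...) {
  cat(sprintf("combined_dataset: %d genes; %s: %d samples, %s: %d samples%s\n",
              nrow(x$platform1), x$platforms[1L], ncol(x$platform1),
              x$platforms[2L], ncol(x$platform2),
              if (x$discrete) " (discrete)" else ""))
  invisible(x)
}

#' Genes of a combined dataset
#' @param d A `combined_dataset`.
#' @return Character vector of gene ids.
#' @export
dataset_genes <- function(d) rownames(d$platform1)

#' Merge the two platform matrices of a combined dataset column-wise
#' @param d A `combined_dataset`.
#' @return A genes x (all samples) matrix.
#' @export
merged_matrix <- function(d) cbind(unclass(d$platform1), unclass(d$platform2))

#' Replace the value matrices of a combined dataset
#' @noRd
replace_values <- function(d, v1, v2, discrete = d$discrete) {
  d$platform1 <- expression_matrix(v1, rownames(d$platform1), colnames(d$platform1))
  d$platform2 <- expression_matrix(v2, rownames(d$platform2), colnames(d$platform2))
  d$discrete <- discrete
  d
}

#' Write a combined dataset to delimited text files
#'
#' Emits `<prefix>_platform1.tsv`, `<prefix>_platform2.tsv` and
#' `<prefix>_annotation.tsv`; reading these back reproduces the dataset.
#' Discrete datasets are written with integer-formatted bodies.
#'
#' @param d A `combined_dataset`.
#' @param path_prefix Path prefix for the three output files.
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(d, path_prefix) {
  if (nrow(d$platform1) == 0L) stop_validation("refusing to write a 0-gene dataset")
  files <- paste0(path_prefix, c("_platform1.tsv", "_platform2.tsv", "_annotation.tsv"))
  for (i in 1:2) {
    m <- unclass(d[[i]])
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    whole <- all(m == round(m))
    if (d$discrete && whole) df[, -1L] <- lapply(df[, -1L, drop = FALSE], as.integer)
    utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                       files[i], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(as.data.frame(d$annotation), files[3L], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(files)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param path_prefix The prefix passed to [write_dataset()].
#' @param discrete Logical, mark the result as discrete.
#' @return A `combined_dataset`.
#' @export
read_dataset <- function(path_prefix, discrete = FALSE) {
  m1 <- read_expression_matrix(paste0(path_prefix, "_platform1.tsv"))
  m2 <- read_expression_matrix(paste0(path_prefix, "_platform2.tsv"))
  ann <- read_sample_annotation(paste0(path_prefix, "_annotation.tsv"))
  combined_dataset(m1, m2, ann, discrete = discrete)
}
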