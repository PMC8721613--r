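# I/O and validation for expression matrices, sample designs and marker sets.
#
# An ExpressionMatrix is a plain numeric matrix (genes in rows, samples in
# columns, RPKM units) with unique dimnames; a SampleDesign is a validated
# data.frame mapping samples to roles within donor-pair trios. Both are kept
# as base containers so downstream code composes with ordinary R tooling.

ROLE_LEVELS <- c("msc_mono", "ch_mono", "coculture")

#' Validate an expression matrix
#'
#' Checks the invariants every downstream stage relies on: a numeric matrix
#' with unique, non-empty gene and sample identifiers and finite,
#' non-negative values in every cell. Missing cells are an error, never
#' silently zero: a zero is meaningful in the expression floor filter, so it
#' must come from the data, not from imputation.
#'
#' @param mat Numeric matrix, genes in rows, samples in columns.
#' @return The matrix, invisibly, if valid; otherwise an error naming the
#'   first offending gene/sample cell.
#' @export
validate_expression_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("expression data must be a numeric matrix (genes x samples)")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(mat)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  if (anyDuplicated(colnames(mat)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", "))
  bad <- which(!is.finite(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "invalid expression value at gene '%s', sample '%s': %s (must be finite and >= 0)",
      rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]],
      format(mat[bad[1, 1], bad[1, 2]])))
  }
  invisible(mat)
}

#' Read a gene-by-sample expression table
#'
#' Reads a delimited text table with gene identifiers in the first column and
#' one column per sample (header row of sample ids), as distributed in GEO
#' supplementary files. Values are expected on the RPKM scale but any
#' non-negative abundance unit is accepted.
#'
#' @param path Path to the table.
#' @param delimiter Field delimiter; tab by default, use `","` for CSV.
#' @return A validated numeric matrix (genes x samples).
#' @export
read_expression_table <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("expression table not found: ", path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "#", quote = "\"")
  if (ncol(df) < 2) stop("expression table needs a gene id column plus >= 1 sample column: ", path)
  gene_ids <- df[[1]]
  vals <- df[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  if (nrow(df) == 1) num <- matrix(num, nrow = 1, dimnames = list(NULL, colnames(vals)))
  bad <- which(is.na(num) & !is.na(as.matrix(vals)), arr.ind = TRUE)
  if (length(bad) > 0) {
    stop(sprintf("non-numeric expression value at gene '%s', sample '%s': '%s'",
                 gene_ids[bad[1, 1]], colnames(vals)[bad[1, 2]],
                 as.matrix(vals)[bad[1, 1], bad[1, 2]]))
  }
  rownames(num) <- gene_ids
  validate_expression_matrix(num)
  num
}

#' Compute RPKM from raw counts
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `counts / ((gene_length/1e3) * (library_size/1e6))`. Library sizes are
#' taken as given (total or exon-mapped reads, at the caller's choice of
#' denominator) and are not recomputed from the count matrix.
#'
#' @param counts Non-negative count matrix (genes x samples).
#' @param gene_lengths Gene lengths in base pairs, one per row of `counts`.
#' @param library_sizes Mapped reads per sample, one per column of `counts`.
#' @return RPKM matrix with the dimnames of `counts`.
#' @export
compute_rpkm <- function(counts, gene_lengths, library_sizes) {
  counts <- as.matrix(counts)
  if (length(gene_lengths) != nrow(counts))
    stop("gene_lengths must have one entry per gene (row) of counts")
  if (length(library_sizes) != ncol(counts))
    stop("library_sizes must have one entry per sample (column) of counts")
  if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0))
    stop("gene lengths must be positive and finite")
  if (any(!is.finite(library_sizes)) || any(library_sizes <= 0))
    stop("library sizes must be positive and finite")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  rpkm <- counts / (outer(gene_lengths / 1e3, library_sizes / 1e6))
  dimnames(rpkm) <- dimnames(counts)
  rpkm
}

#' Read a sample design sheet
#'
#' The design sheet is a delimited table with columns `sample_id`, `role`
#' (`msc_mono`, `ch_mono` or `coculture`), `pair_id`, `sex` and optionally
#' `seeded_fraction` (the seeded MSC proportion, e.g. 0.8 for an 80/20
#' seeding). A sample may serve several pairs (one chondrocyte donor shared
#' across all pairs is the motivating design), so `sample_id` may repeat
#' across rows with different `pair_id`; within a pair each role must occur
#' exactly once, forming a complete monoculture/monoculture/coculture trio.
#'
#' @param path Path to the design sheet.
#' @param delimiter Field delimiter, tab by default.
#' @return A validated data.frame of class `coc_design`.
#' @export
read_design <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("design sheet not found: ", path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  as_design(df)
}

#' Construct a sample design from a data.frame
#'
#' @param df Data.frame with columns `sample_id`, `role`, `pair_id`, `sex`,
#'   and optionally `seeded_fraction`.
#' @return The validated design, class `coc_design`.
#' @export
as_design <- function(df) {
  need <- c("sample_id", "role", "pair_id", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("design sheet is missing column(s): ", paste(miss, collapse = ", "))
  if (!"seeded_fraction" %in% names(df)) df$seeded_fraction <- NA_real_
  bad_role <- setdiff(unique(df$role), ROLE_LEVELS)
  if (length(bad_role) > 0)
    stop("unknown role token(s): ", paste(bad_role, collapse = ", "),
         " (expected ", paste(ROLE_LEVELS, collapse = ", "), ")")
  for (p in unique(df$pair_id)) {
    rows <- df[df$pair_id == p, ]
    for (r in ROLE_LEVELS) {
      n <- sum(rows$role == r)
      if (n != 1L)
        stop(sprintf("pair '%s' must have exactly one %s sample (found %d)", p, r, n))
    }
  }
  df <- df[order(df$pair_id, match(df$role, ROLE_LEVELS)), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("coc_design", "data.frame")
  df
}

#' Check a design against an expression matrix
#'
#' @param design A `coc_design`.
#' @param mat Expression matrix whose samples the design refers to.
#' @return The design, invisibly; errors if a design sample is absent.
#' @export
check_design_matrix <- function(design, mat) {
  missing <- setdiff(design$sample_id, colnames(mat))
  if (length(missing) > 0)
    stop("design sample(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  invisible(design)
}

#' Look up one donor-pair trio
#'
#' @param design A `coc_design`.
#' @param pair_id Donor-pair identifier.
#' @return Named list with sample ids `msc_mono`, `ch_mono`, `coculture`.
#' @export
trio_samples <- function(design, pair_id) {
  rows <- design[design$pair_id == pair_id, ]
  if (nrow(rows) == 0) stop("no such pair in design: ", pair_id)
  out <- as.list(rows$sample_id[match(ROLE_LEVELS, rows$role)])
  names(out) <- ROLE_LEVELS
  out
}

#' Read a marker-gene list
#'
#' Accepts either a plain list (one gene id per line) or a two-column table
#' `gene_id`, `chromosome`. Marker genes are expected to be expressed
#' exclusively in the carrier population (e.g. chrY genes in male-donor MSCs
#' paired with female chondrocytes).
#'
#' @param path Path to the marker list.
#' @param carrier Which population carries the markers, `"msc"` or
#'   `"chondrocyte"`.
#' @return A list with `gene_ids`, `carrier` and `chromosome`.
#' @export
read_markers <- function(path, carrier = "msc") {
  if (!file.exists(path)) stop("marker list not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) {
    df <- utils::read.table(path, sep = "\t", header = grepl("gene_id", first),
                            stringsAsFactors = FALSE)
    ids <- df[[1]]
    chrom <- if (ncol(df) >= 2) df[[2]] else rep(NA_character_, length(ids))
  } else {
    ids <- readLines(path)
    ids <- ids[nzchar(trimws(ids))]
    chrom <- rep(NA_character_, length(ids))
  }
  marker_set(ids, carrier = carrier, chromosome = chrom)
}

#' Construct a marker set
#'
#' @param gene_ids Marker gene identifiers (non-empty, unique).
#' @param carrier `"msc"` or `"chondrocyte"`.
#' @param chromosome Optional chromosome labels (informational).
#' @return A list of class `marker_set`.
#' @export
marker_set <- function(gene_ids, carrier = "msc", chromosome = NULL) {
  if (length(gene_ids) == 0) stop("marker set must be non-empty")
  if (anyDuplicated(gene_ids)) stop("duplicate marker gene ids")
  carrier <- match.arg(carrier, c("msc", "chondrocyte"))
  if (is.null(chromosome)) chromosome <- rep(NA_character_, length(gene_ids))
  structure(list(gene_ids = as.character(gene_ids), carrier = carrier,
                 chromosome = chromosome),
            class = "marker_set")
}

#' Check markers against an expression matrix
#' @param markers A `marker_set`.
#' @param mat Expression matrix.
#' @return The marker set, invisibly; errors if any marker is absent.
#' @export
check_markers_matrix <- function(markers, mat) {
  missing <- setdiff(markers$gene_ids, rownames(mat))
  if (length(missing) > 0)
    stop("marker gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  invisible(markers)
}

#' Write a results table
#'
#' Writes a data.frame as TSV with deterministic column order (as given),
#' fixed 6-decimal formatting for numeric columns (allowing cell-exact
#' comparison on re-read), and optional `# key=value` header comment lines
#' recording the parameters that produced the table.
#'
#' @param path Output path.
#' @param table Data.frame to write.
#' @param header_comments Named character/numeric vector written as
#'   `# name=value` lines before the header, or NULL.
#' @return `path`, invisibly.
#' @export
write_results <- function(path, table, header_comments = NULL) {
  out <- table
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      fmt <- formatC(out[[j]], format = "f", digits = 6)
      fmt[is.na(out[[j]])] <- "NA"
      out[[j]] <- fmt
    }
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_comments)) {
    writeLines(sprintf("# %s=%s", names(header_comments),
                       vapply(header_comments, format, character(1))), con)
  }
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_table()]: gene ids in the first column
#' (`gene_id`), one column per sample. Values are written with full
#' precision so a write/read round-trip is value-exact.
#'
#' @param path Output path.
#' @param mat Expression matrix.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(path, mat) {
  validate_expression_matrix(mat)
  df <- data.frame(gene_id = rownames(mat),
                   format(mat, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
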