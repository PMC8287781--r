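#' Panel count table
#'
#' Container for raw NanoString-style panel counts: a non-negative integer
#' matrix (genes x samples) plus a per-gene code class. Code classes follow
#' the nCounter convention: `Endogenous` genes are the biological panel,
#' `Housekeeping` genes are normalization candidates, `Positive` and
#' `Negative` rows are the spike-in and background control probes.
#'
#' @param counts numeric matrix of counts, rows = genes, columns = samples,
#'   with complete dimnames. All entries must be non-negative integers.
#' @param code_class character vector, one of `"Endogenous"`,
#'   `"Housekeeping"`, `"Positive"`, `"Negative"` per gene, in row order (or
#'   named by gene id).
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer-valued matrix), `code_class` (named character vector),
#'   `gene_ids` and `sample_ids`.
#' @export
count_table <- function(counts, code_class) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  gene_ids <- rownames(counts)
  sample_ids <- colnames(counts)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("`counts` must have row names (gene ids) and column names (sample ids)")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (!is.numeric(counts) || anyNA(counts)) {
    stop("counts must be numeric and complete")
  }
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("negative or non-integer count at gene '%s', sample '%s' (value %s)",
                 gene_ids[bad[1, 1]], sample_ids[bad[1, 2]],
                 format(counts[bad[1, , drop = FALSE]])))
  }
  if (!is.null(names(code_class))) code_class <- code_class[gene_ids]
  code_class <- as.character(code_class)
  if (length(code_class) != nrow(counts)) {
    stop("`code_class` must have one entry per gene")
  }
  allowed <- c("Endogenous", "Housekeeping", "Positive", "Negative")
  if (!all(code_class %in% allowed)) {
    stop("unknown code class value(s): ",
         paste(setdiff(unique(code_class), allowed), collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "))
  }
  names(code_class) <- gene_ids
  structure(
    list(counts = counts, code_class = code_class,
         gene_ids = gene_ids, sample_ids = sample_ids),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  print(table(x$code_class))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Subset a count table by gene and/or sample
#'
#' @param x a [count_table()]
#' @param genes,samples character vectors of ids to keep (default: all)
#' @return a `count_table`
#' @export
subset_count_table <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "count_table"))
  if (is.null(genes)) genes <- x$gene_ids
  if (is.null(samples)) samples <- x$sample_ids
  missing_g <- setdiff(genes, x$gene_ids)
  if (length(missing_g)) stop("unknown gene id(s): ", paste(missing_g, collapse = ", "))
  missing_s <- setdiff(samples, x$sample_ids)
  if (length(missing_s)) stop("unknown sample id(s): ", paste(missing_s, collapse = ", "))
  count_table(x$counts[genes, samples, drop = FALSE], x$code_class[genes])
}

.delim_for <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a panel count table from delimited text
#'
#' Expected layout: first column `gene_id`, second column `code_class`,
#' remaining columns one per sample. Delimiter is auto-detected from the
#' file extension (`.csv` comma, `.tsv`/`.txt` tab) unless `sep` is given.
#' Gene and sample order are preserved exactly as in the file.
#'
#' @param path file path
#' @param sep optional field delimiter overriding extension-based detection
#' @return a [count_table()]
#' @export
read_count_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path, sep),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  need <- c("gene_id", "code_class")
  if (!all(need %in% names(df)[1:2])) {
    stop("count table must start with columns 'gene_id' and 'code_class'")
  }
  sample_cols <- setdiff(names(df), need)
  if (length(sample_cols) == 0) stop("count table has no sample columns")
  counts <- as.matrix(df[, sample_cols, drop = FALSE])
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene id(s): ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  }
  rownames(counts) <- df$gene_id
  storage.mode(counts) <- "double"
  count_table(counts, df$code_class)
}

#' Write a count table to delimited text
#'
#' Inverse of [read_count_table()]; integer counts round-trip bit-exactly.
#'
#' @param x a [count_table()]
#' @param path output file path (`.csv` or `.tsv`)
#' @param sep optional delimiter override
#' @export
write_count_table <- function(x, path, sep = NULL) {
  stopifnot(inherits(x, "count_table"))
  df <- data.frame(gene_id = x$gene_ids, code_class = unname(x$code_class),
                   x$counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = .delim_for(path, sep), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
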