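#' @keywords internal
.sample_vocab <- list(
  group      = c("sham", "TBI"),
  treatment  = c("none", "vehicle", "CR2-Crry"),
  timepoint  = c("baseline", "d3", "d7", "d28", "y1", "y2"),
  age_class  = c("12wk", "1y", "2y")
)

#' Validate a sample sheet
#'
#' Checks the five required columns, restricts categorical values to their
#' allowed vocabularies, and enforces the design constraint that sham
#' animals are untreated.
#'
#' @param df data frame with columns `sample_id`, `group`, `treatment`,
#'   `timepoint`, `age_class`
#' @return the validated data frame (character columns), invisibly usable
#'   downstream
#' @export
validate_sample_sheet <- function(df) {
  need <- c("sample_id", "group", "treatment", "timepoint", "age_class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  df <- df[, need]
  for (col in names(.sample_vocab)) {
    df[[col]] <- as.character(df[[col]])
    bad <- setdiff(unique(df[[col]]), .sample_vocab[[col]])
    if (length(bad)) {
      stop(sprintf("unknown %s value(s) %s; allowed: {%s}", col,
                   paste(shQuote(bad), collapse = ", "),
                   paste(.sample_vocab[[col]], collapse = ",")))
    }
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  offender <- df$sample_id[df$group == "sham" & df$treatment != "none"]
  if (length(offender)) {
    stop("sham samples must have treatment 'none': ", paste(offender, collapse = ", "))
  }
  df
}

#' Read a sample sheet
#'
#' @param path CSV (or TSV) file with columns `sample_id`, `group`,
#'   `treatment`, `timepoint`, `age_class`
#' @param sep optional delimiter override
#' @return validated data frame of sample metadata
#' @export
read_sample_sheet <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path, sep),
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_sample_sheet(df)
}

#' Select sample ids matching design factors
#'
#' Convenience filter over a sample sheet; `NULL` means "any".
#'
#' @param samples a sample sheet data frame
#' @param group,treatment,timepoint,age_class optional values to match
#' @return character vector of sample ids
#' @export
select_samples <- function(samples, group = NULL, treatment = NULL,
                           timepoint = NULL, age_class = NULL) {
  keep <- rep(TRUE, nrow(samples))
  if (!is.null(group)) keep <- keep & samples$group %in% group
  if (!is.null(treatment)) keep <- keep & samples$treatment %in% treatment
  if (!is.null(timepoint)) keep <- keep & samples$timepoint %in% timepoint
  if (!is.null(age_class)) keep <- keep & samples$age_class %in% age_class
  samples$sample_id[keep]
}

#' Read a gene annotation table
#'
#' Annotations map genes to panel pathways (a gene may belong to several,
#' separated by `;`) and optionally to marker classes and complement
#' classifications.
#'
#' @param path CSV/TSV with columns `gene_id`, `pathways`, and optionally
#'   `marker_classes`, `complement_class`, `complement_pathway`
#' @param sep optional delimiter override
#' @return data frame with list-columns `pathways` and `marker_classes`
#' @export
read_gene_annotations <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path, sep),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (!all(c("gene_id", "pathways") %in% names(df))) {
    stop("annotation table must have columns 'gene_id' and 'pathways'")
  }
  split_multi <- function(x) {
    lapply(x, function(s) {
      if (is.na(s) || !nzchar(s)) character(0) else trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  }
  out <- data.frame(gene_id = as.character(df$gene_id), stringsAsFactors = FALSE)
  out$pathways <- split_multi(df$pathways)
  out$marker_classes <- if ("marker_classes" %in% names(df)) {
    split_multi(df$marker_classes)
  } else rep(list(character(0)), nrow(df))
  out$complement_class <- if ("complement_class" %in% names(df)) {
    as.character(df$complement_class)
  } else NA_character_
  out$complement_pathway <- if ("complement_pathway" %in% names(df)) {
    as.character(df$complement_pathway)
  } else NA_character_
  if (any(vapply(out$pathways, function(p) any(!nzchar(p)), logical(1)))) {
    stop("empty pathway name in annotation table")
  }
  out
}

#' Expand annotations to one row per (gene, pathway)
#'
#' @param annotations output of [read_gene_annotations()] (or a data frame
#'   with `gene_id` and a `pathways` list-column)
#' @return data frame with columns `gene_id`, `pathway`
#' @export
annotation_pathway_long <- function(annotations) {
  n <- lengths(annotations$pathways)
  data.frame(
    gene_id = rep(annotations$gene_id, n),
    pathway = unlist(annotations$pathways, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Read gene sets in GMT format
#'
#' Standard tab-separated GMT: set name, description, then one gene per
#' field. Genes may appear in multiple sets.
#'
#' @param path GMT file path
#' @return named list of character vectors (unique gene ids per set)
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT parse error at line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(fields)))
    }
    name <- fields[[1]]
    if (name %in% names(sets)) stop("duplicate gene set name: ", name)
    genes <- unique(fields[-(1:2)])
    sets[[name]] <- genes[nzchar(genes)]
  }
  sets
}

#' Read a precomputed fold-change / p-value comparison table
#'
#' Ingestion path for externally computed per-contrast statistics (e.g.
#' nSolver exports). The column layout is configurable via `columns`; fold
#' changes may be on the signed convention (|fc| >= 1, negative =
#' downregulated) or plain ratios, which are converted to signed form.
#'
#' @param path CSV/TSV file
#' @param columns named character vector mapping the roles `gene`, `fc`,
#'   `p` (and optionally `fdr`) to column names in the file
#' @param contrast_id label attached to every row (or the name of a
#'   contrast column via `columns["contrast"]`)
#' @param fc_type `"signed"` (default) or `"ratio"`
#' @param sep optional delimiter override
#' @return data frame with columns `gene_id`, `contrast_id`, `fc_signed`,
#'   `log2fc`, `p_value`, and `fdr` (NA when not supplied)
#' @export
read_comparison_table <- function(path,
                                  columns = c(gene = "gene_id", fc = "fold_change", p = "p_value"),
                                  contrast_id = NULL,
                                  fc_type = c("signed", "ratio"),
                                  sep = NULL) {
  fc_type <- match.arg(fc_type)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path, sep),
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "fc", "p")
  miss <- setdiff(need, names(columns))
  if (length(miss)) stop("`columns` must map roles: ", paste(miss, collapse = ", "))
  absent <- setdiff(unname(columns), names(df))
  if (length(absent)) stop("column(s) not in file: ", paste(absent, collapse = ", "))
  p <- as.numeric(df[[columns[["p"]]]])
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-value outside [0,1] at row ",
         which(!is.finite(p) | p < 0 | p > 1)[1])
  }
  fc <- as.numeric(df[[columns[["fc"]]]])
  if (fc_type == "ratio") {
    if (any(fc <= 0)) stop("ratio fold changes must be positive")
    fc <- ifelse(fc >= 1, fc, -1 / fc)
  }
  if (any(abs(fc) < 1)) {
    stop("signed fold change with |value| < 1 at row ", which(abs(fc) < 1)[1],
         "; use fc_type = 'ratio' for plain ratios")
  }
  cid <- if ("contrast" %in% names(columns)) {
    as.character(df[[columns[["contrast"]]]])
  } else if (!is.null(contrast_id)) {
    rep(contrast_id, nrow(df))
  } else rep(NA_character_, nrow(df))
  out <- data.frame(
    gene_id = as.character(df[[columns[["gene"]]]]),
    contrast_id = cid,
    fc_signed = fc,
    log2fc = sign(fc) * log2(abs(fc)),
    p_value = p,
    stringsAsFactors = FALSE
  )
  out$fdr <- if ("fdr" %in% names(columns)) as.numeric(df[[columns[["fdr"]]]]) else NA_real_
  out
}

#' Write a tidy result table as CSV
#'
#' List-columns (e.g. time-point sets) are flattened to `+`-joined strings.
#'
#' @param df data frame
#' @param path output CSV path
#' @export
write_result_table <- function(df, path) {
  flat <- df
  for (col in names(flat)) {
    if (is.list(flat[[col]])) {
      flat[[col]] <- vapply(flat[[col]], function(v) {
        paste(as.character(v), collapse = "+")
      }, character(1))
    }
  }
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' Packaged marker-class gene lists
#'
#' Reactive astrocyte (A1, A2, PAN), disease-associated microglia (DAM) and
#' reactive oligodendrocyte marker genes shipped as an editable fixture
#' table; a gene may carry several classes.
#'
#' @return data frame with columns `gene_id`, `marker_class`
#' @export
marker_classes <- function() {
  path <- system.file("extdata", "marker_classes.csv", package = "tempodeg")
  if (!nzchar(path)) stop("marker fixture not found; is tempodeg installed?")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Packaged complement gene annotations
#'
#' The 11 complement-system genes of the neuroinflammation panel with their
#' complement class (initiator/enzyme/effector/receptor/regulator) and
#' pathway (classical/lectin/alternative/terminal/effector).
#'
#' @return data frame with columns `gene_id`, `complement_class`,
#'   `complement_pathway`
#' @export
complement_annotations <- function() {
  path <- system.file("extdata", "complement_annotations.csv", package = "tempodeg")
  if (!nzchar(path)) stop("complement fixture not found; is tempodeg installed?")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
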