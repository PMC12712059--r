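#' Read a gene-by-sample expression table
#'
#' Reads a delimited text table whose first column holds gene symbols and
#' whose header row holds sample identifiers. Gene symbols are uppercased;
#' duplicated symbols are collapsed by keeping the row with the highest
#' mean expression; rows containing any missing value are dropped. A load
#' report (counts of collapsed duplicates and dropped rows) is attached as
#' the `"load_report"` attribute.
#'
#' @param path path to a TSV or CSV file (delimiter sniffed from the
#'   extension, tab otherwise).
#' @param scale_tag `"counts"` for nonnegative integer counts,
#'   `"continuous"` for log-scale continuous values. Stored as the
#'   `"scale_tag"` attribute and consulted by downstream scoring.
#' @return a numeric matrix (genes x samples) with uppercase gene symbols
#'   as rownames, sample ids as colnames, and attributes `scale_tag` and
#'   `load_report`.
#' @seealso [write_expression_table()], [gsva_scores()]
#' @export
read_expression_table <- function(path, scale_tag = c("continuous", "counts")) {
  scale_tag <- match.arg(scale_tag)
  if (!file.exists(path)) stop("cannot read expression table: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "\"")
  if (ncol(raw) < 2L) stop("expression table needs a gene column and >= 1 sample", call. = FALSE)
  genes <- toupper(trimws(as.character(raw[[1L]])))
  vals <- raw[, -1L, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric expression values in column(s): ",
         paste(names(vals)[bad], collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  build_expression_matrix(m, scale_tag)
}

# Shared validation/cleanup used by the reader and the simulator's count
# path: drop rows with missing values, collapse duplicate symbols by
# highest mean (deterministic and order-independent: ties broken by symbol
# order of first occurrence after a stable sort on -mean).
build_expression_matrix <- function(m, scale_tag) {
  storage.mode(m) <- "double"
  n_missing <- sum(!stats::complete.cases(m))
  if (n_missing > 0) m <- m[stats::complete.cases(m), , drop = FALSE]
  n_dup <- 0L
  if (anyDuplicated(rownames(m))) {
    means <- rowMeans(m)
    # order by gene then decreasing mean so the kept row is the max-mean
    # row regardless of input row order
    o <- order(rownames(m), -means, method = "radix")
    m <- m[o, , drop = FALSE]
    keep <- !duplicated(rownames(m))
    n_dup <- sum(!keep)
    m <- m[keep, , drop = FALSE]
  }
  if (nrow(m) == 0L) stop("empty expression matrix after filtering", call. = FALSE)
  if (scale_tag == "counts" && any(m < 0)) {
    stop("negative values are not valid counts", call. = FALSE)
  }
  attr(m, "scale_tag") <- scale_tag
  attr(m, "load_report") <- list(duplicates_collapsed = n_dup,
                                 missing_rows_dropped = n_missing)
  m
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_table()]: first column `gene`, one column
#' per sample. Values round-trip bit-identically for integer counts and to
#' full double precision for continuous data.
#'
#' @param expr numeric matrix with gene rownames and sample colnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard gene-set exchange format: one set per line,
#' `name TAB description TAB gene TAB gene ...`. Genes are uppercased and
#' de-duplicated within each set.
#'
#' @param path path to a GMT file.
#' @return a named list of character vectors of gene symbols, with class
#'   `"gene_set_collection"` and a `"provenance"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("cannot read GMT file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no gene sets in ", path, call. = FALSE)
  sets <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("malformed GMT line (need name, description, >=1 gene): ",
           substr(ln, 1, 60), call. = FALSE)
    }
    nm <- fields[1L]
    if (nm %in% names(sets)) stop("duplicate gene-set name: ", nm, call. = FALSE)
    genes <- unique(toupper(trimws(fields[-(1:2)])))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) stop("empty gene set: ", nm, call. = FALSE)
    sets[[nm]] <- genes
  }
  gene_set_collection(sets, provenance = path)
}

#' Construct a gene-set collection
#'
#' @param sets named list of nonempty character vectors.
#' @param provenance free-text origin note.
#' @return the list with class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets, provenance = "") {
  stopifnot(is.list(sets), length(sets) > 0)
  if (is.null(names(sets)) || anyDuplicated(names(sets)) || any(!nzchar(names(sets)))) {
    stop("gene sets must have unique nonempty names", call. = FALSE)
  }
  if (any(lengths(sets) == 0L)) stop("every gene set must be nonempty", call. = FALSE)
  sets <- lapply(sets, function(g) unique(toupper(g)))
  structure(sets, class = "gene_set_collection", provenance = provenance)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene set collection:", length(x), "sets,",
      length(unique(unlist(x))), "distinct genes\n")
  show <- utils::head(names(x), 8)
  for (nm in show) cat(sprintf("  %-28s %d genes\n", nm, length(x[[nm]])))
  if (length(x) > length(show)) cat("  ...\n")
  invisible(x)
}

#' Write a gene-set collection to GMT
#'
#' @param sets a `gene_set_collection` or named list.
#' @param path output path.
#' @param description description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Append the overall-immune union set to a cell-type collection
#'
#' The consensus tumor-microenvironment framework scores 16 immune and 2
#' stromal cell types; the overall immune score is the enrichment of the
#' union of the 16 immune sets. This helper appends that union under the
#' name `Immune_Score`.
#'
#' @param sets a `gene_set_collection` containing the per-cell-type sets.
#' @param stromal_sets names of the stromal sets excluded from the union
#'   (default `Endothelial` and `Fibroblasts`).
#' @return the collection with an `Immune_Score` entry appended.
#' @export
build_consensus_sets <- function(sets, stromal_sets = c("Endothelial", "Fibroblasts")) {
  immune <- setdiff(names(sets), c(stromal_sets, "Immune_Score"))
  if (length(immune) == 0L) stop("no immune sets to union", call. = FALSE)
  union_set <- unique(toupper(unlist(sets[immune], use.names = FALSE)))
  out <- c(unclass(sets), list(Immune_Score = union_set))
  gene_set_collection(out, provenance = attr(sets, "provenance") %||% "")
}

# enumerations for clinical annotation ---------------------------------

.ancestry_levels <- c("African", "East Asian", "European", "Hispanic",
                      "Southeast Asian", "West Asian")
.age_levels <- c("<40", "40-49", "50-64", "65-74", ">=75")
.stage_levels <- c("I", "II", "III", "IV")
.pam50_levels <- c("Basal", "Her2", "LumA", "LumB")
.timepoint_levels <- c("baseline", "cycle2", "surgery")
.response_levels <- c("ypCR", "ypPR", "ypSD")

# self-reported race categories are reclassified to the six ancestry
# groups used throughout
.ancestry_synonyms <- c(
  "ASIAN" = "East Asian",
  "BLACK/AFRICAN AMERICAN" = "African",
  "BLACK" = "African",
  "AFRICAN AMERICAN" = "African",
  "HISPANIC/LATINO" = "Hispanic",
  "LATINO" = "Hispanic",
  "MIDDLE EASTERN/NORTH AFRICAN" = "West Asian",
  "WHITE/CAUCASIAN" = "European",
  "WHITE" = "European",
  "CAUCASIAN" = "European"
)

map_enum <- function(x, levels, synonyms = NULL) {
  x <- trimws(as.character(x))
  x[x == "" | toupper(x) == "NA"] <- NA_character_
  if (!is.null(synonyms)) {
    hit <- match(toupper(x), names(synonyms))
    x[!is.na(hit)] <- synonyms[hit[!is.na(hit)]]
  }
  # case-insensitive match against the enumeration itself
  idx <- match(toupper(x), toupper(levels))
  out <- ifelse(is.na(idx), NA_character_, levels[idx])
  n_unknown <- sum(!is.na(x) & is.na(out))
  attr(out, "n_unknown") <- n_unknown
  out
}

#' Read a clinical annotation table
#'
#' Reads a TSV/CSV with at least a `sample_id` column and any of:
#' `ancestry`, `age_group`, `stage`, `pam50`, `dataset_id`, `timepoint`,
#' `response`, `time`, `event`, `age`, `grade`. Self-reported race labels
#' are reclassified to the six ancestry categories (e.g. Black/African
#' American to African, White/Caucasian to European); values outside the
#' enumerations become `NA` with a warning giving the count.
#'
#' @param path path to the table.
#' @return a data.frame with validated annotation columns; the number of
#'   unrecognised category values is attached as attribute
#'   `"n_unknown_values"`.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("cannot read clinical table: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "NA", quote = "\"")
  validate_clinical(df)
}

#' @rdname read_clinical_table
#' @param df a data.frame holding the same columns, validated in place.
#' @export
validate_clinical <- function(df) {
  if (!"sample_id" %in% names(df)) stop("clinical table lacks a sample_id column", call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  enums <- list(
    ancestry = list(.ancestry_levels, .ancestry_synonyms),
    age_group = list(.age_levels, c("40–49" = "40-49", "50–64" = "50-64",
                                    "65–74" = "65-74", "≥75" = ">=75",
                                    "75+" = ">=75")),
    stage = list(.stage_levels, NULL),
    pam50 = list(.pam50_levels, c("LUMINAL A" = "LumA", "LUMINAL B" = "LumB",
                                  "BASAL-LIKE" = "Basal", "HER2-ENRICHED" = "Her2")),
    timepoint = list(.timepoint_levels, NULL),
    response = list(.response_levels, NULL)
  )
  n_unknown <- 0L
  for (col in names(enums)) {
    if (col %in% names(df)) {
      mapped <- map_enum(df[[col]], enums[[col]][[1L]], enums[[col]][[2L]])
      n_unknown <- n_unknown + attr(mapped, "n_unknown")
      attr(mapped, "n_unknown") <- NULL
      df[[col]] <- mapped
    }
  }
  key <- paste(df$sample_id,
               if ("dataset_id" %in% names(df)) df$dataset_id else "",
               if ("timepoint" %in% names(df)) df$timepoint else "",
               sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (sample_id, dataset_id, timepoint) in clinical table", call. = FALSE)
  }
  if (n_unknown > 0) {
    warning(n_unknown, " unrecognised category value(s) set to NA", call. = FALSE)
  }
  attr(df, "n_unknown_values") <- n_unknown
  df
}
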