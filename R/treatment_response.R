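# Longitudinal phenotype-transition tables and delta enrichment scores
# across treatment timepoints.

#' Cross-tabulate phenotype labels between two timepoints
#'
#' Patients present at both timepoints are cross-tabulated from-by-to;
#' patients missing either timepoint are excluded and counted. Row sums
#' equal the from-timepoint group sizes among linked patients (the
#' bookkeeping that, e.g., partitions 24 baseline-Hot patients into
#' 23 + 1).
#'
#' @param from,to data.frames with columns `patient_id` and `label`
#'   (phenotype or fibroblast subtype).
#' @param levels label order for the table (default Hot/Moderate/Cold;
#'   pass `c("NF","iCAF","myCAF")` for fibroblast transitions).
#' @param timepoint_pair length-2 character naming the timepoints.
#' @return object of class `"transition_table"`: the counts matrix with
#'   attributes `timepoint_pair`, `n_excluded`, `retention` (diagonal /
#'   row sum).
#' @export
transition_table <- function(from, to, levels = c("Hot", "Moderate", "Cold"),
                             timepoint_pair = c("from", "to")) {
  for (d in list(from, to)) {
    if (!all(c("patient_id", "label") %in% names(d))) {
      stop("from/to need patient_id and label columns", call. = FALSE)
    }
  }
  if (anyDuplicated(from$patient_id) || anyDuplicated(to$patient_id)) {
    stop("duplicate patient at one timepoint", call. = FALSE)
  }
  common <- intersect(from$patient_id, to$patient_id)
  n_excluded <- length(union(from$patient_id, to$patient_id)) - length(common)
  f <- factor(from$label[match(common, from$patient_id)], levels = levels)
  t2 <- factor(to$label[match(common, to$patient_id)], levels = levels)
  if (anyNA(f) || anyNA(t2)) stop("labels outside the supplied levels", call. = FALSE)
  counts <- table(from = f, to = t2)
  counts <- matrix(as.integer(counts), nrow = length(levels),
                   dimnames = list(from = levels, to = levels))
  rs <- rowSums(counts)
  retention <- ifelse(rs > 0, diag(counts) / rs, NA_real_)
  structure(counts, class = c("transition_table", "matrix"),
            timepoint_pair = timepoint_pair, n_excluded = n_excluded,
            retention = stats::setNames(retention, levels))
}

#' @export
print.transition_table <- function(x, ...) {
  tp <- attr(x, "timepoint_pair")
  cat("Phenotype transitions", tp[1], "->", tp[2],
      sprintf("(%d excluded)\n", attr(x, "n_excluded")))
  print(matrix(x, nrow = nrow(x), dimnames = dimnames(x)))
  cat("Retention:", paste(sprintf("%s %.2f", names(attr(x, "retention")),
                                  attr(x, "retention")), collapse = ", "), "\n")
  invisible(x)
}

#' Per-patient score differences between timepoints
#'
#' Elementwise `score(to) - score(from)` for patients present at both
#' timepoints; others are skipped and reported in the
#' `skipped_patients` attribute.
#'
#' @param from,to cell-type x patient enrichment score matrices
#'   (colnames are patient ids).
#' @return long data.frame with `patient_id`, `cell_type`, `delta`.
#' @export
delta_scores <- function(from, to) {
  shared_ct <- intersect(rownames(from), rownames(to))
  common <- intersect(colnames(from), colnames(to))
  if (length(common) == 0L) stop("no overlapping patients", call. = FALSE)
  skipped <- setdiff(union(colnames(from), colnames(to)), common)
  d <- to[shared_ct, common, drop = FALSE] - from[shared_ct, common, drop = FALSE]
  out <- data.frame(
    patient_id = rep(common, each = length(shared_ct)),
    cell_type = rep(shared_ct, times = length(common)),
    delta = as.vector(d),
    stringsAsFactors = FALSE
  )
  attr(out, "skipped_patients") <- skipped
  out
}

#' Compare scores (or deltas) between treatment-response groups
#'
#' Pairwise Wilcoxon rank-sum tests between response classes with
#' Benjamini-Hochberg adjustment (delegates to [wilcoxon_bh()]).
#'
#' @param values numeric scores or deltas per patient.
#' @param response response class per patient (ypCR/ypPR/ypSD).
#' @param paired paired comparisons.
#' @return data.frame as from [wilcoxon_bh()].
#' @export
response_compare <- function(values, response, paired = FALSE) {
  keep <- !is.na(response) & !is.na(values)
  response <- response[keep]; values <- values[keep]
  if (length(unique(response)) < 2L) stop("need >= 2 response groups", call. = FALSE)
  wilcoxon_bh(values, response, paired = paired)
}
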