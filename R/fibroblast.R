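# Fibroblast subtype classification: per-gene z-scoring of a fixed marker
# panel, seeded k-means into three clusters, and annotation of the
# clusters as NF (normal fibroblast), iCAF (inflammatory CAF) or myCAF
# (myofibroblast-like CAF) from the mean expression of small
# subtype-defining marker subsets.

#' Fibroblast subtype marker panel
#'
#' Literature-derived marker genes for normal fibroblasts (14 genes),
#' inflammatory CAFs (15 genes) and myofibroblast-like CAFs (15 genes).
#' Pan-matrix genes (CTHRC1, COL1A1, SPARC, COL3A1, COL1A2) are shared
#' between the iCAF and myCAF panels; the union spans 39 distinct genes.
#' The annotation subsets are disjoint and drive cluster naming.
#'
#' @return list of class `"fibroblast_panel"` with `nf_genes`,
#'   `icaf_genes`, `mycaf_genes` and `annotation_subsets`.
#' @export
fibroblast_markers <- function() {
  panel <- list(
    nf_genes = c("CFD", "GSN", "GPX3", "SOD3", "IGFBP6", "CLU", "CLEC3B",
                 "MT2A", "APOD", "PI16", "SLPI", "PLA2G2A", "MT1M", "MT1X"),
    icaf_genes = c("CTHRC1", "IL24", "COL3A1", "COL1A1", "SPARC", "LUM",
                   "ASPN", "CHI3L1", "COL1A2", "IGF1", "CXCL8", "CXCL3",
                   "CCN1", "CXCL1", "IGFBP3"),
    mycaf_genes = c("POSTN", "MMP11", "CTHRC1", "MMP1", "COL1A1", "SPARC",
                    "MFAP2", "SERPINH1", "COL3A1", "COL1A2", "THY1",
                    "TAGLN", "TPM2", "SFRP4", "ACTA2"),
    annotation_subsets = list(
      myCAF = c("POSTN", "ACTA2", "MMP11", "TAGLN"),
      iCAF = c("IL24", "CXCL8", "CXCL1", "IGFBP3"),
      NF = c("PI16", "CFD", "SLPI", "APOD", "CLEC3B")
    )
  )
  structure(panel, class = "fibroblast_panel")
}

panel_union <- function(panel) {
  unique(c(panel$nf_genes, panel$icaf_genes, panel$mycaf_genes))
}

#' Z-score the marker-gene submatrix
#'
#' Restricts the expression matrix to the marker panel genes (shared
#' genes appear once) and standardises each gene to mean 0, sd 1 across
#' samples (population sd). Genes with zero variance are set to all-zero
#' with a warning. Errors when fewer than half of the panel genes are
#' present.
#'
#' @param expr genes x samples matrix (counts or continuous; the
#'   procedure is scale-agnostic and the input `scale_tag` is recorded).
#' @param panel a [fibroblast_markers()] panel.
#' @return marker x sample z-matrix with attributes `missing_genes` and
#'   `scale_tag`.
#' @export
zscore_marker_matrix <- function(expr, panel = fibroblast_markers()) {
  if (ncol(expr) < 4L) stop("need at least 4 samples", call. = FALSE)
  union_genes <- panel_union(panel)
  present <- intersect(union_genes, toupper(rownames(expr)))
  missing <- setdiff(union_genes, present)
  if (length(present) < length(union_genes) / 2) {
    stop("fewer than 50% of panel genes present; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- expr[match(present, toupper(rownames(expr))), , drop = FALSE]
  rownames(m) <- present
  z <- m
  zero_var <- character(0)
  for (i in seq_len(nrow(m))) {
    s <- pop_sd(m[i, ])
    if (s == 0) {
      z[i, ] <- 0
      zero_var <- c(zero_var, rownames(m)[i])
    } else {
      z[i, ] <- (m[i, ] - mean(m[i, ])) / s
    }
  }
  if (length(zero_var)) {
    warning("zero-variance marker gene(s) set to zero: ",
            paste(zero_var, collapse = ", "), call. = FALSE)
  }
  attr(z, "missing_genes") <- missing
  attr(z, "scale_tag") <- attr(expr, "scale_tag") %||% "unknown"
  attr(z, "load_report") <- NULL
  z
}

#' Cluster samples in marker z-space
#'
#' Seeded k-means with k = 3 (k-means++ seeding, Lloyd iterations, 25
#' restarts). The default seed of 123 makes the clustering reproducible.
#'
#' @param z_matrix marker x sample z-matrix from [zscore_marker_matrix()].
#' @param seed integer seed (default 123).
#' @return integer cluster ids named by sample.
#' @export
cluster_fibroblasts <- function(z_matrix, seed = 123L) {
  n <- ncol(z_matrix)
  if (n < 3L) stop("need at least 3 samples for 3 clusters", call. = FALSE)
  cluster_samples(z_matrix, k = 3L, seed = seed)$cluster
}

#' Annotate fibroblast clusters from marker subset scores
#'
#' Computes the 3x3 cluster-by-label score matrix (mean z of each label's
#' annotation subset over each cluster's samples), then assigns labels
#' greedily: the globally largest remaining (cluster, label) score fixes
#' that pair, its row and column are removed, and the process repeats,
#' yielding a bijection. Exact ties are resolved by label priority
#' myCAF > iCAF > NF, then lower cluster id.
#'
#' @param cluster integer cluster ids per sample (exactly 3 clusters).
#' @param z_matrix marker x sample z-matrix.
#' @param panel a [fibroblast_markers()] panel.
#' @param seed seed recorded on the result (provenance only).
#' @return object of class `"fibroblast_call"` with `sample_ids`,
#'   `subtype`, `cluster`, `annotation_scores` (cluster x label) and
#'   `seed`.
#' @export
annotate_clusters <- function(cluster, z_matrix, panel = fibroblast_markers(),
                              seed = 123L) {
  cls <- sort(unique(cluster))
  if (length(cls) != 3L) stop("expected exactly 3 clusters", call. = FALSE)
  labels <- c("myCAF", "iCAF", "NF")  # priority order for tie-breaks
  score <- matrix(NA_real_, 3L, 3L, dimnames = list(paste0("cluster", cls), labels))
  for (li in seq_along(labels)) {
    sub <- intersect(panel$annotation_subsets[[labels[li]]], rownames(z_matrix))
    if (length(sub) < 2L) {
      stop("annotation subset for ", labels[li], " has < 2 genes present",
           call. = FALSE)
    }
    for (ci in seq_along(cls)) {
      cols <- which(cluster == cls[ci])
      score[ci, li] <- mean(z_matrix[sub, cols])
    }
  }
  assignment <- greedy_bijection(score)
  lab_of <- stats::setNames(assignment, cls)
  subtype <- unname(lab_of[as.character(cluster)])
  structure(list(
    sample_ids = colnames(z_matrix),
    subtype = stats::setNames(subtype, colnames(z_matrix)),
    cluster = stats::setNames(cluster, colnames(z_matrix)),
    annotation_scores = score,
    seed = as.integer(seed)
  ), class = "fibroblast_call")
}

# greedy max assignment over a 3x3 (cluster x label) score matrix;
# returns label per cluster row. Ties: column priority (matrix column
# order, myCAF first), then lower row index.
greedy_bijection <- function(score) {
  k <- nrow(score)
  out <- character(k)
  rows <- seq_len(k); cols <- seq_len(k)
  s <- score
  for (step in seq_len(k)) {
    best <- which(s == max(s, na.rm = TRUE), arr.ind = TRUE)
    # tie-break: prefer earlier column (label priority), then earlier row
    best <- best[order(best[, "col"], best[, "row"]), , drop = FALSE][1L, ]
    out[rows[best[1L]]] <- colnames(score)[cols[best[2L]]]
    s <- s[-best[1L], -best[2L], drop = FALSE]
    rows <- rows[-best[1L]]; cols <- cols[-best[2L]]
  }
  out
}

#' Classify samples into NF / iCAF / myCAF
#'
#' The fibroblast-subtype fitting function: z-scores the marker panel,
#' clusters samples into three groups with a fixed seed (default 123),
#' and annotates the clusters from the subtype-defining marker subsets.
#'
#' @param expr genes x samples expression matrix.
#' @param panel a [fibroblast_markers()] panel.
#' @param seed clustering seed (default 123).
#' @return object of class `"fibroblast_call"`.
#' @examples
#' co <- generate_cohort(cohort_config(n_samples = 60, seed = 3))
#' fc <- classify_fibroblasts(co$expression)
#' table(fc$subtype, co$truth$fibroblast_subtype)
#' @export
classify_fibroblasts <- function(expr, panel = fibroblast_markers(), seed = 123L) {
  z <- zscore_marker_matrix(expr, panel)
  cl <- cluster_fibroblasts(z, seed = seed)
  annotate_clusters(unname(cl), z, panel, seed = seed)
}

#' @export
print.fibroblast_call <- function(x, ...) {
  cat("Fibroblast subtype call (seed =", x$seed, ")\n")
  print(table(x$subtype))
  invisible(x)
}

#' @export
summary.fibroblast_call <- function(object, ...) {
  cat("Cluster x label annotation scores (mean marker z):\n")
  print(round(object$annotation_scores, 3))
  cat("\nSubtype counts:\n")
  print(table(object$subtype))
  invisible(object)
}
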