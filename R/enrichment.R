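# Single-sample gene-set enrichment by the rank-based weighted
# Kolmogorov-Smirnov random walk. Per gene, an expression-level statistic
# is estimated across samples (Gaussian-kernel CDF with bandwidth sd/4 for
# continuous data, empirical CDF for counts); per sample, genes are ranked
# by that statistic and a weighted walk over the ranked list yields a
# bounded enrichment score per gene set.

#' Parameters for the enrichment scorer
#'
#' @param tau weight exponent on the symmetric rank statistic (>= 0,
#'   default 1).
#' @param kernel `"auto"` picks the Gaussian-kernel CDF for continuous
#'   matrices and the empirical CDF for counts; either can be forced.
#' @param min_set_overlap minimum number of a set's genes that must be
#'   present in the matrix; smaller sets are skipped with a warning
#'   (default 5 — rank walks over fewer genes are noise-dominated).
#' @return list of class `"enrichment_params"`.
#' @export
enrichment_params <- function(tau = 1,
                              kernel = c("auto", "gaussian_cdf", "empirical_cdf"),
                              min_set_overlap = 5L) {
  kernel <- match.arg(kernel)
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  if (min_set_overlap < 1) stop("min_set_overlap must be >= 1", call. = FALSE)
  structure(list(tau = tau, kernel = kernel,
                 min_set_overlap = as.integer(min_set_overlap),
                 es_mode = "max_diff"),
            class = "enrichment_params")
}

# per-gene expression-level statistic across samples
expression_statistic <- function(expr, kernel) {
  n <- ncol(expr)
  z <- matrix(0, nrow(expr), n, dimnames = dimnames(expr))
  if (kernel == "gaussian_cdf") {
    for (i in seq_len(nrow(expr))) {
      xi <- expr[i, ]
      h <- stats::sd(xi) / 4
      if (h == 0) {
        z[i, ] <- n / 2  # constant gene: flat statistic
      } else {
        z[i, ] <- rowSums(stats::pnorm(outer(xi, xi, "-") / h))
      }
    }
  } else {
    for (i in seq_len(nrow(expr))) {
      xi <- expr[i, ]
      z[i, ] <- vapply(xi, function(v) sum(xi <= v), numeric(1))
    }
  }
  z
}

# weighted KS walk for one sample ordering; inset is logical over the
# ranked gene list, w the rank weights in ranked order
walk_es <- function(inset_ord, w_ord, tau, n_out) {
  wt <- w_ord^tau
  denom <- sum(wt[inset_ord])
  steps <- ifelse(inset_ord, wt / denom, -1 / n_out)
  cum <- cumsum(steps)
  max(c(cum, 0)) + min(c(cum, 0))
}

#' Single-sample gene-set enrichment scores
#'
#' For each sample, genes are ranked by the cross-sample CDF statistic
#' (decreasing; ties broken by gene order), the symmetric rank weight
#' `|N/2 - rank|` is formed, and a weighted Kolmogorov-Smirnov walk is run
#' down the ranked list: in-set steps are proportional to `weight^tau`
#' normalised over the set, out-of-set steps are `-1/(N - |S|)`. The
#' enrichment score is the maximum positive deviation plus the minimum
#' negative deviation of the walk, bounded in [-1, 1].
#'
#' @param expr genes x samples numeric matrix (as from
#'   [read_expression_table()] or a synthetic cohort); the `scale_tag`
#'   attribute selects the CDF kernel when `params$kernel = "auto"`.
#' @param sets a `gene_set_collection` (or named list of gene vectors).
#' @param params an [enrichment_params()] object.
#' @return matrix of class `"enrichment_scores"` (kept sets x samples)
#'   with attributes `params` and `skipped_sets`.
#' @examples
#' co <- generate_cohort(cohort_config(n_samples = 20, seed = 1))
#' es <- gsva_scores(co$expression, co$gene_sets)
#' range(es)  # within [-1, 1]
#' @export
gsva_scores <- function(expr, sets, params = enrichment_params()) {
  if (ncol(expr) < 2L) stop("need at least 2 samples", call. = FALSE)
  kernel <- params$kernel
  if (kernel == "auto") {
    kernel <- if (identical(attr(expr, "scale_tag"), "counts"))
      "empirical_cdf" else "gaussian_cdf"
  }
  genes <- toupper(rownames(expr))
  n_genes <- nrow(expr)
  z <- expression_statistic(expr, kernel)
  # degenerate when a sample's statistic carries no ordering at all
  flat <- apply(z, 2L, function(col) diff(range(col)) == 0)
  if (all(flat)) stop("degenerate ranks: constant expression statistic", call. = FALSE)

  keep <- vapply(sets, function(g) sum(toupper(g) %in% genes), integer(1))
  skipped <- names(sets)[keep < params$min_set_overlap]
  if (length(skipped)) {
    warning("skipping set(s) below min_set_overlap: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  kept <- setdiff(names(sets), skipped)
  if (length(kept) == 0L) stop("all gene sets skipped", call. = FALSE)

  set_idx <- lapply(sets[kept], function(g) which(genes %in% toupper(g)))
  scores <- matrix(NA_real_, length(kept), ncol(expr),
                   dimnames = list(kept, colnames(expr)))
  half <- n_genes / 2
  for (j in seq_len(ncol(expr))) {
    ord <- order(z[, j], decreasing = TRUE)  # ties by gene index
    w_ord <- abs(half - seq_len(n_genes))
    pos_of_gene <- integer(n_genes)
    pos_of_gene[ord] <- seq_len(n_genes)
    for (s in seq_along(set_idx)) {
      inset_ord <- logical(n_genes)
      inset_ord[pos_of_gene[set_idx[[s]]]] <- TRUE
      scores[s, j] <- walk_es(inset_ord, w_ord, params$tau,
                              n_genes - length(set_idx[[s]]))
    }
  }
  structure(scores, class = c("enrichment_scores", class(scores)),
            params = params, kernel_used = kernel, skipped_sets = skipped)
}

#' @export
print.enrichment_scores <- function(x, ...) {
  cat("Enrichment scores:", nrow(x), "gene sets x", ncol(x), "samples",
      sprintf("(range %.3f .. %.3f)\n", min(x), max(x)))
  invisible(x)
}

#' Overall immune score per sample
#'
#' The enrichment score of the union of the immune cell-type sets
#' (the `Immune_Score` entry produced by [build_consensus_sets()]).
#' `method = "mean"` instead averages the per-cell-type immune scores.
#'
#' @param scores an `enrichment_scores` matrix containing an
#'   `Immune_Score` row (for `method = "union"`).
#' @param method `"union"` (default) or `"mean"`.
#' @param stromal_sets set names excluded under `method = "mean"`.
#' @return named numeric vector, one score per sample.
#' @export
overall_immune_score <- function(scores, method = c("union", "mean"),
                                 stromal_sets = c("Endothelial", "Fibroblasts")) {
  method <- match.arg(method)
  if (method == "union") {
    if (!"Immune_Score" %in% rownames(scores)) {
      stop("scores lack an Immune_Score row; build sets with build_consensus_sets()",
           call. = FALSE)
    }
    scores["Immune_Score", ]
  } else {
    rows <- setdiff(rownames(scores), c(stromal_sets, "Immune_Score"))
    colMeans(scores[rows, , drop = FALSE])
  }
}

#' Immune-stromal ratio
#'
#' Per-sample ratio `immune score / (endothelial score + fibroblast
#' score)`. Samples whose denominator has magnitude below `1e-6` are
#' flagged undefined (ratio `NA`); negative denominators are permitted
#' but counted in the diagnostics attribute.
#'
#' @param scores an `enrichment_scores` matrix with rows `Immune_Score`,
#'   `Endothelial` and `Fibroblasts`.
#' @return data.frame with `sample_id`, `ratio`, `undefined_flag`;
#'   attribute `diagnostics` reports counts of undefined and
#'   negative-denominator samples.
#' @export
immune_stromal_ratio <- function(scores) {
  need <- c("Immune_Score", "Endothelial", "Fibroblasts")
  miss <- setdiff(need, rownames(scores))
  if (length(miss)) stop("scores lack required row(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  denom <- scores["Endothelial", ] + scores["Fibroblasts", ]
  undefined <- abs(denom) < 1e-6
  ratio <- ifelse(undefined, NA_real_, scores["Immune_Score", ] / denom)
  out <- data.frame(sample_id = colnames(scores), ratio = unname(ratio),
                    undefined_flag = unname(undefined),
                    stringsAsFactors = FALSE)
  attr(out, "diagnostics") <- list(n_undefined = sum(undefined),
                                   n_negative_denominator = sum(!undefined & denom < 0))
  out
}
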