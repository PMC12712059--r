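# Hot/Moderate/Cold immune phenotype assignment: row-scale the cell-type
# enrichment matrix, select the cluster number by a 3-index majority vote,
# run seeded k-means (k-means++ seeding, Lloyd iterations, 25 restarts),
# and name the clusters by their mean overall immune score.

#' Row-scale an enrichment matrix
#'
#' Standardises each cell-type row to mean 0, sd 1 across samples
#' (population sd). Constant rows are set to all-zero with a warning.
#'
#' @param scores cell-type x sample numeric matrix.
#' @return the scaled matrix.
#' @export
scale_rows <- function(scores) {
  if (ncol(scores) < 2L) stop("row scaling needs at least 2 samples", call. = FALSE)
  out <- scores
  const <- character(0)
  for (i in seq_len(nrow(scores))) {
    s <- pop_sd(scores[i, ])
    if (s == 0) {
      out[i, ] <- 0
      const <- c(const, rownames(scores)[i] %||% as.character(i))
    } else {
      out[i, ] <- (scores[i, ] - mean(scores[i, ])) / s
    }
  }
  if (length(const)) {
    warning("constant row(s) set to zero: ", paste(const, collapse = ", "),
            call. = FALSE)
  }
  class(out) <- "matrix"
  out
}

# k-means++ seeding: first center uniform, then D^2 sampling
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- colSums((t(x) - centers[1L, ])^2)
  if (k > 1L) for (j in 2:k) {
    if (all(d2 == 0)) idx <- sample.int(n, 1L)
    else idx <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, colSums((t(x) - centers[j, ])^2))
  }
  centers
}

#' Cluster samples by seeded k-means
#'
#' Lloyd iterations from k-means++ seedings, 25 restarts, up to 300
#' iterations each; the restart with the lowest within-cluster sum of
#' squares is kept. Deterministic given `seed`.
#'
#' @param scaled feature x sample matrix (samples are clustered).
#' @param k number of clusters (>= 2, or `k = n` for singletons).
#' @param seed integer seed.
#' @param nstart number of k-means++ restarts.
#' @return list with `cluster` (integer vector per sample), `centers`
#'   (k x features), `tot_withinss`.
#' @export
cluster_samples <- function(scaled, k, seed = 1L, nstart = 25L) {
  x <- t(scaled)
  n <- nrow(x)
  if (k < 1L || k > n) stop("k must be in 1..n samples", call. = FALSE)
  if (k == n) {
    return(list(cluster = stats::setNames(seq_len(n), rownames(x)),
                centers = x, tot_withinss = 0))
  }
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(nstart)) {
      cen <- kmeanspp_centers(x, k)
      fit <- suppressWarnings(
        stats::kmeans(x, centers = cen, iter.max = 300L, algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    list(cluster = stats::setNames(best$cluster, rownames(x)),
         centers = best$centers, tot_withinss = best$tot.withinss)
  })
}

# internal cluster-quality indices ------------------------------------

calinski_harabasz <- function(x, cluster) {
  n <- nrow(x); k <- length(unique(cluster))
  gm <- colMeans(x)
  w <- 0; b <- 0
  for (cl in unique(cluster)) {
    xi <- x[cluster == cl, , drop = FALSE]
    cm <- colMeans(xi)
    w <- w + sum(sweep(xi, 2, cm)^2)
    b <- b + nrow(xi) * sum((cm - gm)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

davies_bouldin <- function(x, cluster) {
  cls <- sort(unique(cluster)); k <- length(cls)
  cen <- t(vapply(cls, function(cl) colMeans(x[cluster == cl, , drop = FALSE]),
                  numeric(ncol(x))))
  s <- vapply(seq_along(cls), function(i) {
    xi <- x[cluster == cls[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2, cen[i, ])^2)))
  }, numeric(1))
  db <- 0
  for (i in seq_len(k)) {
    r <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      m <- sqrt(sum((cen[i, ] - cen[j, ])^2))
      r <- max(r, (s[i] + s[j]) / m)
    }
    db <- db + r
  }
  db / k
}

#' Select the number of clusters by index consensus
#'
#' For each candidate k, samples are clustered with [cluster_samples()];
#' the mean silhouette width, Calinski-Harabasz index (both maximised)
#' and Davies-Bouldin index (minimised) each vote for their optimal k.
#' The modal vote wins; ties go to the smallest k.
#'
#' @param scaled feature x sample matrix (already row-scaled).
#' @param k_range candidate cluster numbers (default 2:6).
#' @param seed integer seed.
#' @return the selected k; attribute `"votes"` carries the per-index
#'   optima.
#' @export
select_cluster_number <- function(scaled, k_range = 2:6, seed = 1L) {
  if (length(k_range) == 0L) stop("empty k_range", call. = FALSE)
  n <- ncol(scaled)
  if (n <= max(k_range)) stop("need more samples than max(k_range)", call. = FALSE)
  x <- t(scaled)
  d <- stats::dist(x)
  sil <- ch <- db <- stats::setNames(numeric(length(k_range)), k_range)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    cl <- cluster_samples(scaled, k, seed = seed)$cluster
    sil[i] <- mean(cluster::silhouette(cl, d)[, "sil_width"])
    ch[i] <- calinski_harabasz(x, cl)
    db[i] <- davies_bouldin(x, cl)
  }
  votes <- c(silhouette = k_range[which.max(sil)],
             calinski_harabasz = k_range[which.max(ch)],
             davies_bouldin = k_range[which.min(db)])
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  k_sel <- min(winners)
  structure(k_sel, votes = votes,
            indices = list(silhouette = sil, calinski_harabasz = ch,
                           davies_bouldin = db))
}

#' Name clusters Hot/Moderate/Cold by mean immune score
#'
#' With exactly 3 clusters, clusters are ranked by their mean overall
#' immune score: highest becomes Hot, middle Moderate, lowest Cold; ties
#' are broken by larger cluster first, then lower cluster id. With k != 3
#' the labels stay `Cluster1..k` and a warning is issued.
#'
#' @param cluster integer cluster ids per sample.
#' @param immune_score overall immune score per sample (same order).
#' @return list with `label` per sample, `cluster`, `k`,
#'   `cluster_mean_immune` (named by label, or cluster).
#' @export
assign_phenotype_labels <- function(cluster, immune_score) {
  if (length(cluster) != length(immune_score) || anyNA(immune_score)) {
    stop("every sample needs an immune score", call. = FALSE)
  }
  cls <- sort(unique(cluster))
  k <- length(cls)
  means <- vapply(cls, function(cl) mean(immune_score[cluster == cl]), numeric(1))
  sizes <- vapply(cls, function(cl) sum(cluster == cl), numeric(1))
  if (k != 3L) {
    warning("k = ", k, " clusters: phenotype naming withheld, using Cluster1..k",
            call. = FALSE)
    lab_of <- stats::setNames(paste0("Cluster", seq_len(k)), cls)
  } else {
    o <- order(-means, -sizes, cls)  # ties: larger cluster, then lower id
    lab_of <- character(3); names(lab_of) <- cls[o]
    lab_of[] <- c("Hot", "Moderate", "Cold")
  }
  label <- unname(lab_of[as.character(cluster)])
  cm <- stats::setNames(means, unname(lab_of[as.character(cls)]))
  list(label = label, cluster = cluster, k = k,
       cluster_mean_immune = cm[order(-cm)])
}

#' Fit an immune phenotype model
#'
#' The main phenotyping entry point: row-scales the cell-type scores,
#' selects k (or uses a fixed k), clusters the samples, and names the
#' clusters by mean overall immune score. Returns a classed fit with
#' `print`, `summary`, `predict` and `plot` methods; `predict` assigns
#' new score columns to the nearest fitted centroid.
#'
#' @param scores an `enrichment_scores` matrix including an
#'   `Immune_Score` row (excluded from the clustering features, used for
#'   labeling).
#' @param k `"auto"` (index-consensus selection) or a fixed integer.
#' @param k_range candidate k values when `k = "auto"`.
#' @param seed integer seed for clustering.
#' @return object of class `"immune_phenotype"`.
#' @examples
#' co <- generate_cohort(cohort_config(n_samples = 60, seed = 2))
#' es <- gsva_scores(co$expression, co$gene_sets)
#' fit <- immune_phenotype(es, k = 3, seed = 1)
#' table(fit$label, co$truth$phenotype)
#' @export
immune_phenotype <- function(scores, k = "auto", k_range = 2:6, seed = 1L) {
  imm <- overall_immune_score(scores)
  feat <- scores[setdiff(rownames(scores), "Immune_Score"), , drop = FALSE]
  scaled <- scale_rows(feat)
  k_sel <- if (identical(k, "auto")) {
    as.integer(select_cluster_number(scaled, k_range, seed = seed))
  } else as.integer(k)
  cl <- cluster_samples(scaled, k_sel, seed = seed)
  lab <- assign_phenotype_labels(unname(cl$cluster), unname(imm))
  structure(list(
    sample_ids = colnames(scores),
    label = stats::setNames(lab$label, colnames(scores)),
    cluster = stats::setNames(lab$cluster, colnames(scores)),
    k_selected = k_sel,
    cluster_mean_immune = lab$cluster_mean_immune,
    immune_score = imm,
    centers = cl$centers,
    row_center = rowMeans(feat),
    row_scale = apply(feat, 1L, pop_sd),
    seed = as.integer(seed),
    call = match.call()
  ), class = "immune_phenotype")
}

#' @export
print.immune_phenotype <- function(x, ...) {
  cat("Immune phenotype fit (k =", x$k_selected, ", seed =", x$seed, ")\n")
  print(table(x$label))
  cat("Cluster mean overall immune score:\n")
  print(round(x$cluster_mean_immune, 3))
  invisible(x)
}

#' @export
summary.immune_phenotype <- function(object, ...) {
  tab <- table(object$label)
  by_lab <- split(object$immune_score, object$label)
  s <- data.frame(
    label = names(tab),
    n = as.integer(tab),
    proportion = as.numeric(tab) / length(object$label),
    mean_immune = vapply(by_lab[names(tab)], mean, numeric(1)),
    sd_immune = vapply(by_lab[names(tab)], stats::sd, numeric(1)),
    row.names = NULL
  )
  structure(list(table = s, k = object$k_selected), class = "summary.immune_phenotype")
}

#' @export
print.summary.immune_phenotype <- function(x, ...) {
  cat("Immune phenotype summary (k =", x$k, ")\n")
  print(x$table, digits = 3)
  invisible(x)
}

#' @export
#' @param object an `immune_phenotype` fit.
#' @param newdata cell-type x sample score matrix with the fit's feature
#'   rows.
#' @param ... unused.
#' @rdname immune_phenotype
predict.immune_phenotype <- function(object, newdata, ...) {
  feats <- names(object$row_center)
  miss <- setdiff(feats, rownames(newdata))
  if (length(miss)) stop("newdata lacks feature row(s): ",
                         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  z <- (newdata[feats, , drop = FALSE] - object$row_center) /
    ifelse(object$row_scale == 0, 1, object$row_scale)
  x <- t(z)
  d <- vapply(seq_len(nrow(object$centers)), function(i) {
    rowSums(sweep(x, 2, object$centers[i, ])^2)
  }, numeric(nrow(x)))
  d <- matrix(d, nrow = nrow(x))
  cl <- max.col(-d, ties.method = "first")
  # map cluster id to fitted label via the training assignment
  lab_of <- tapply(object$label, object$cluster, function(l) l[1L])
  stats::setNames(as.character(lab_of[as.character(cl)]), colnames(newdata))
}

#' @export
plot.immune_phenotype <- function(x, ...) {
  graphics::boxplot(split(x$immune_score, x$label),
                    ylab = "overall immune score",
                    main = "Immune score by phenotype", ...)
  invisible(x)
}
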