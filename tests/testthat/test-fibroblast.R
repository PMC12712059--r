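test_that("marker panel matches the published lists", {
  p <- fibroblast_markers()
  expect_length(p$nf_genes, 14L)
  expect_length(p$icaf_genes, 15L)
  expect_length(p$mycaf_genes, 15L)
  # pan-matrix genes shared between the CAF panels are preserved
  shared <- intersect(p$icaf_genes, p$mycaf_genes)
  expect_setequal(shared, c("CTHRC1", "COL1A1", "SPARC", "COL3A1", "COL1A2"))
  # union spans 39 distinct genes (shared genes once)
  expect_length(unique(c(p$nf_genes, p$icaf_genes, p$mycaf_genes)), 39L)
  # annotation subsets are subsets of their panels
  expect_true(all(p$annotation_subsets$myCAF %in% p$mycaf_genes))
  expect_true(all(p$annotation_subsets$iCAF %in% p$icaf_genes))
  expect_true(all(p$annotation_subsets$NF %in% p$nf_genes))
  expect_setequal(p$annotation_subsets$myCAF, c("POSTN", "ACTA2", "MMP11", "TAGLN"))
  expect_setequal(p$annotation_subsets$iCAF, c("IL24", "CXCL8", "CXCL1", "IGFBP3"))
  expect_setequal(p$annotation_subsets$NF, c("PI16", "CFD", "SLPI", "APOD", "CLEC3B"))
})

test_that("marker z-scoring standardises per gene and reports coverage", {
  p <- fibroblast_markers()
  genes <- panel_genes <- unique(c(p$nf_genes, p$icaf_genes, p$mycaf_genes))
  set.seed(1)
  m <- matrix(rnorm(39 * 6), 39, 6, dimnames = list(genes, paste0("s", 1:6)))
  m["CFD", ] <- c(2, 4, 6, 2, 4, 6)
  z <- zscore_marker_matrix(m, p)
  expect_equal(nrow(z), 39L)
  expect_equal(unname(z["CFD", 1:3]), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_length(attr(z, "missing_genes"), 0L)
  # zero-variance gene zeroed with a warning
  m2 <- m; m2["GSN", ] <- 7
  expect_warning(z2 <- zscore_marker_matrix(m2, p), "GSN")
  expect_true(all(z2["GSN", ] == 0))
  # < 50% coverage errors and lists the missing genes
  m3 <- m[1:15, ]
  expect_error(zscore_marker_matrix(m3, p), "50%")
  expect_error(zscore_marker_matrix(m[, 1:3], p), "4 samples")
})

test_that("fibroblast clustering is reproducible with the fixed seed", {
  co <- generate_cohort(cohort_config(n_samples = 60, n_genes = 600, seed = 21))
  z <- zscore_marker_matrix(co$expression)
  expect_identical(cluster_fibroblasts(z, seed = 123),
                   cluster_fibroblasts(z, seed = 123))
  # n = 3: three singletons
  z3 <- z[, 1:3]
  expect_equal(sort(unname(cluster_fibroblasts(z3))), 1:3)
  expect_error(cluster_fibroblasts(z[, 1:2]), "3 samples")
})

test_that("cluster annotation applies the marker-subset scoring rule", {
  p <- fibroblast_markers()
  # construct a z-matrix where cluster 2 has top myCAF-subset expression,
  # cluster 1 top NF, cluster 3 top iCAF
  genes <- unique(c(p$nf_genes, p$icaf_genes, p$mycaf_genes))
  set.seed(2)
  n_per <- 10
  z <- matrix(rnorm(length(genes) * 3 * n_per, 0, 0.1), length(genes),
              dimnames = list(genes, paste0("s", 1:(3 * n_per))))
  cl <- rep(1:3, each = n_per)
  z[p$annotation_subsets$NF, cl == 1] <- z[p$annotation_subsets$NF, cl == 1] + 2
  z[p$annotation_subsets$myCAF, cl == 2] <- z[p$annotation_subsets$myCAF, cl == 2] + 2
  z[p$annotation_subsets$iCAF, cl == 3] <- z[p$annotation_subsets$iCAF, cl == 3] + 2
  call <- annotate_clusters(cl, z, p)
  expect_equal(unname(call$subtype[cl == 2][1]), "myCAF")
  expect_equal(unname(call$subtype[cl == 1][1]), "NF")
  expect_equal(unname(call$subtype[cl == 3][1]), "iCAF")
  # bijection over the three labels
  expect_setequal(unique(call$subtype), c("NF", "iCAF", "myCAF"))
  # matches the exhaustive max-total-score bijection here
  expect_equal(unname(call$subtype[match(1:3, call$cluster)]),
               oracle_best_bijection(call$annotation_scores))
})

test_that("adversarial annotation: one cluster maximal for two labels", {
  p <- fibroblast_markers()
  genes <- unique(c(p$nf_genes, p$icaf_genes, p$mycaf_genes))
  set.seed(3)
  n_per <- 8
  z <- matrix(rnorm(length(genes) * 3 * n_per, 0, 0.05), length(genes),
              dimnames = list(genes, paste0("s", 1:(3 * n_per))))
  cl <- rep(1:3, each = n_per)
  # cluster 1 is highest for BOTH myCAF and iCAF subsets, but its myCAF
  # excess is larger; cluster 2 is second for iCAF; cluster 3 leads NF
  z[p$annotation_subsets$myCAF, cl == 1] <- z[p$annotation_subsets$myCAF, cl == 1] + 3
  z[p$annotation_subsets$iCAF, cl == 1] <- z[p$annotation_subsets$iCAF, cl == 1] + 1.5
  z[p$annotation_subsets$iCAF, cl == 2] <- z[p$annotation_subsets$iCAF, cl == 2] + 1
  z[p$annotation_subsets$NF, cl == 3] <- z[p$annotation_subsets$NF, cl == 3] + 1
  call <- annotate_clusters(cl, z, p)
  lab_by_cluster <- unname(call$subtype[match(1:3, call$cluster)])
  expect_equal(lab_by_cluster, c("myCAF", "iCAF", "NF"))
  expect_equal(lab_by_cluster, oracle_best_bijection(call$annotation_scores))
})

test_that("end-to-end subtype recovery on planted-panel cohorts", {
  co <- generate_cohort(cohort_config(n_samples = 90, n_genes = 600, seed = 31))
  fc <- classify_fibroblasts(co$expression)
  expect_gte(mean(fc$subtype == co$truth$fibroblast_subtype), 0.9)
  # seed-123 determinism of the full path
  fc2 <- classify_fibroblasts(co$expression)
  expect_identical(fc$subtype, fc2$subtype)
  # count-scale input classifies equally well (scale-agnostic z-scoring)
  coc <- generate_cohort(cohort_config(n_samples = 90, n_genes = 600, seed = 31,
                                       scale_tag = "counts"))
  fcc <- classify_fibroblasts(coc$expression)
  expect_gte(mean(fcc$subtype == coc$truth$fibroblast_subtype), 0.85)
})
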