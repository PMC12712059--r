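# fixed 6-gene x 4-sample integer fixture; expected scores computed with
# the literal brute-force walk oracle (helper-oracles.R) and frozen
fixture_expr <- function() {
  matrix(c(5, 1, 2, 8,
           3, 7, 1, 2,
           9, 4, 6, 1,
           2, 8, 3, 5,
           7, 2, 9, 4,
           1, 6, 4, 7), nrow = 6, byrow = TRUE,
         dimnames = list(paste0("G", 1:6), paste0("S", 1:4)))
}
fixture_sets <- function() {
  gene_set_collection(list(SET_A = c("G1", "G3"), SET_B = c("G2", "G4", "G6")))
}

test_that("scores on the frozen fixture match the brute-force walk oracle", {
  expr <- fixture_expr()
  p <- enrichment_params(min_set_overlap = 2, kernel = "gaussian_cdf")
  es <- gsva_scores(expr, fixture_sets(), p)
  frozen_cont <- matrix(c(1, -1, -0.5, 1, -1/6, -0.75, -0.2, 1/3), 2, 4,
                        dimnames = list(c("SET_A", "SET_B"), paste0("S", 1:4)))
  expect_equal(unclass(es)[, ], frozen_cont, tolerance = 1e-9)

  pc <- enrichment_params(min_set_overlap = 2, kernel = "empirical_cdf")
  esc <- gsva_scores(expr, fixture_sets(), pc)
  frozen_counts <- matrix(c(1, -1, -0.5, 1, 0.5, -1, -0.2, 1/3), 2, 4,
                          dimnames = dimnames(frozen_cont))
  expect_equal(unclass(esc)[, ], frozen_counts, tolerance = 1e-9)
})

test_that("walk sign follows set placement in the ranking", {
  set.seed(7)
  m <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("G", 1:10), paste0("S", 1:3)))
  m[1:2, 1] <- m[1:2, 1] + 10   # set genes top-ranked in sample 1
  m[1:2, 2] <- m[1:2, 2] - 10   # bottom-ranked in sample 2
  es <- gsva_scores(m, gene_set_collection(list(S = c("G1", "G2"))),
                    enrichment_params(min_set_overlap = 1))
  expect_gt(es["S", "S1"], 0)
  expect_lt(es["S", "S2"], 0)
})

test_that("optimized scorer matches the oracle on random matrices, both kernels", {
  for (seed in 1:25) {
    set.seed(seed)
    ng <- sample(8:20, 1); ns <- sample(3:10, 1)
    m <- matrix(rnorm(ng * ns), ng, ns,
                dimnames = list(paste0("G", 1:ng), paste0("S", 1:ns)))
    k <- sample(2:max(2, ng %/% 3), 1)
    sets <- list(A = paste0("G", sample(ng, k)),
                 B = paste0("G", sample(ng, min(ng - 1, k + 2))))
    p <- enrichment_params(min_set_overlap = 1, kernel = "gaussian_cdf")
    es <- gsva_scores(m, gene_set_collection(sets), p)
    expect_equal(unclass(es)[, ], oracle_gsva(m, sets, kernel = "gaussian_cdf"),
                 tolerance = 1e-9)
    mi <- matrix(rpois(ng * ns, 20), ng, ns, dimnames = dimnames(m))
    pe <- enrichment_params(min_set_overlap = 1, kernel = "empirical_cdf")
    ese <- gsva_scores(mi, gene_set_collection(sets), pe)
    expect_equal(unclass(ese)[, ], oracle_gsva(mi, sets, kernel = "empirical_cdf"),
                 tolerance = 1e-9)
  }
})

test_that("scores stay bounded and are sample-permutation equivariant", {
  set.seed(42)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("G", 1:20), paste0("S", 1:10)))
  sets <- gene_set_collection(list(A = paste0("G", 1:6), B = paste0("G", 10:15)))
  es <- gsva_scores(m, sets, enrichment_params())
  expect_true(all(es >= -1 & es <= 1))
  perm <- sample(10)
  esp <- gsva_scores(m[, perm], sets, enrichment_params())
  expect_equal(unclass(esp)[, ], unclass(es)[, perm], tolerance = 1e-12)
})

test_that("raising in-set genes of one sample never lowers its enrichment", {
  set.seed(9)
  for (rep in 1:5) {
    m <- matrix(rnorm(150), 15, 10,
                dimnames = list(paste0("G", 1:15), paste0("S", 1:10)))
    genes <- paste0("G", sample(15, 5))
    sets <- gene_set_collection(list(A = genes))
    base <- gsva_scores(m, sets, enrichment_params())["A", "S1"]
    m2 <- m
    m2[genes, "S1"] <- m2[genes, "S1"] + 2
    shifted <- gsva_scores(m2, sets, enrichment_params())["A", "S1"]
    expect_gte(shifted, base)
  }
})

test_that("undersized sets are skipped and degenerate inputs rejected", {
  m <- fixture_expr()
  sets <- gene_set_collection(list(TINY = "G1", OK = c("G2", "G4", "G6")))
  expect_warning(es <- gsva_scores(m, sets, enrichment_params(min_set_overlap = 3)),
                 "TINY")
  expect_equal(rownames(es), "OK")
  expect_error(suppressWarnings(
    gsva_scores(m, gene_set_collection(list(TINY = "G1")), enrichment_params())),
    "all gene sets skipped")
  expect_error(gsva_scores(m[, 1, drop = FALSE], sets), "2 samples")
  const <- matrix(3, 6, 4, dimnames = dimnames(m))
  expect_error(gsva_scores(const, sets, enrichment_params(min_set_overlap = 1)),
               "degenerate ranks")
})

test_that("overall immune score is the union-set enrichment", {
  expr <- fixture_expr()
  sets <- build_consensus_sets(
    gene_set_collection(list(B_cells = c("G1", "G3"), NK_cells = c("G3", "G5"))),
    stromal_sets = character(0))
  p <- enrichment_params(min_set_overlap = 2, kernel = "gaussian_cdf")
  es <- gsva_scores(expr, sets, p)
  imm <- overall_immune_score(es)
  # equals the oracle walk on the union set
  o <- oracle_gsva(expr, list(U = c("G1", "G3", "G5")), kernel = "gaussian_cdf")
  expect_equal(unname(imm), unname(o["U", ]), tolerance = 1e-9)
  # single-set collection: union score equals that set's score
  one <- build_consensus_sets(gene_set_collection(list(B_cells = c("G1", "G3"))),
                              stromal_sets = character(0))
  es1 <- gsva_scores(expr, one, p)
  expect_equal(unname(es1["Immune_Score", ]), unname(es1["B_cells", ]))
  # missing union row errors
  expect_error(overall_immune_score(es[1:2, ]), "Immune_Score")
  # mean method averages the immune rows
  expect_equal(unname(overall_immune_score(es, method = "mean")),
               unname(colMeans(es[c("B_cells", "NK_cells"), ])))
})

test_that("immune-stromal ratio handles degenerate denominators", {
  sc <- matrix(c(0.6, 0.1, 0.2,
                 0.5, 0.3, -0.3,
                 0.0, 0.2, 0.1), nrow = 3,
               dimnames = list(c("Immune_Score", "Endothelial", "Fibroblasts"),
                               c("a", "b", "c")))
  r <- immune_stromal_ratio(sc)
  expect_equal(r$ratio[r$sample_id == "a"], 2.0)
  expect_true(r$undefined_flag[r$sample_id == "b"])
  expect_true(is.na(r$ratio[r$sample_id == "b"]))
  expect_equal(r$ratio[r$sample_id == "c"], 0.0)
  expect_equal(attr(r, "diagnostics")$n_undefined, 1L)
  expect_error(immune_stromal_ratio(sc[1:2, ]), "Fibroblasts")
})
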