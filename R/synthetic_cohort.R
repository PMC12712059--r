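# Synthetic cohorts with the statistical structure the pipeline assumes:
# phenotype-graded immune gene-set activity, stromal activity varying by
# group, three planted fibroblast subtypes via the marker panels, survival
# with hazard tied to immune activity, and Markov phenotype transitions
# across treatment timepoints.

.cell_types_immune <- c(
  "B_cells", "Cytotoxic_cells", "Dendritic_cells", "Eosinophils",
  "Macrophages", "Macrophages_M1", "Macrophages_M2", "Mast_cells",
  "Monocytes", "NK_cells", "Neutrophils", "Plasma_cells",
  "T_cells_CD4", "T_cells_CD8", "T_cells_gamma_delta", "T_regulatory_cells"
)
.cell_types_stromal <- c("Endothelial", "Fibroblasts")
.phenotype_levels <- c("Hot", "Moderate", "Cold")
.fibro_levels <- c("NF", "iCAF", "myCAF")

# cohort-composition frequencies emulating a large multi-dataset breast
# cancer compilation (European-dominated, mostly >=50y, mostly luminal)
.ancestry_freq <- c("European" = 0.830, "East Asian" = 0.075,
                    "African" = 0.033, "Hispanic" = 0.030,
                    "Southeast Asian" = 0.020, "West Asian" = 0.012)
.age_freq <- c("<40" = 0.10, "40-49" = 0.21, "50-64" = 0.35,
               "65-74" = 0.22, ">=75" = 0.12)
.stage_freq <- c("I" = 0.25, "II" = 0.40, "III" = 0.25, "IV" = 0.10)
.pam50_freq <- c("LumA" = 0.40, "LumB" = 0.32, "Her2" = 0.13, "Basal" = 0.15)

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the generator emulates: three
#' immune phenotypes at proportions 0.31/0.30/0.39, immune gene-set
#' shifts of +1.5 (Hot), +0.7 (Moderate) and 0 (Cold) log-expression
#' units over unit-variance Gaussian noise, stromal shifts graded the
#' same way at half the amplitude, three equally likely fibroblast
#' subtypes each over-expressing its own marker panel by +1.5, an
#' exponential survival model whose log-hazard is linear in the planted
#' immune score, and a phenotype transition matrix with strong Hot and
#' Moderate retention and weaker Cold retention.
#'
#' @param n_samples number of samples.
#' @param n_genes gene-universe size; must exceed the union of planted
#'   sets (18 cell-type sets of `genes_per_set` genes plus the 39
#'   distinct fibroblast marker genes).
#' @param phenotype_proportions named length-3 probability vector over
#'   Hot/Moderate/Cold.
#' @param immune_shift per-phenotype mean shift added to immune-set genes
#'   (log-expression units).
#' @param stromal_shift per-phenotype shift added to endothelial and
#'   fibroblast set genes.
#' @param fibroblast_mixture length-3 probability vector over NF/iCAF/myCAF.
#' @param fibroblast_shift shift added to a sample's own subtype panel.
#' @param noise_sd standard deviation of the baseline Gaussian noise.
#' @param genes_per_set genes per synthetic cell-type set.
#' @param scale_tag `"continuous"` (log-scale Gaussian) or `"counts"`
#'   (values exponentiated and Poisson-sampled).
#' @param survival list with `baseline_hazard`, `log_hazard_per_immune_unit`
#'   and `censor_rate`.
#' @param transition_matrix 3x3 row-stochastic phenotype transition
#'   probabilities per treatment step (rows and columns Hot/Moderate/Cold).
#' @param seed integer seed; identical config + seed reproduces the cohort
#'   bit-identically.
#' @return a validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_samples = 300L,
                          n_genes = 1000L,
                          phenotype_proportions = c(Hot = 0.31, Moderate = 0.30, Cold = 0.39),
                          immune_shift = c(Hot = 1.5, Moderate = 0.7, Cold = 0),
                          stromal_shift = c(Hot = 0.5, Moderate = 0.25, Cold = 0),
                          fibroblast_mixture = c(NF = 1/3, iCAF = 1/3, myCAF = 1/3),
                          fibroblast_shift = 1.5,
                          noise_sd = 1,
                          genes_per_set = 20L,
                          scale_tag = c("continuous", "counts"),
                          survival = list(baseline_hazard = 0.1,
                                          log_hazard_per_immune_unit = log(2),
                                          censor_rate = 0.4),
                          transition_matrix = default_transition_matrix(),
                          seed = 1L) {
  scale_tag <- match.arg(scale_tag)
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              phenotype_proportions = phenotype_proportions,
              immune_shift = immune_shift, stromal_shift = stromal_shift,
              fibroblast_mixture = fibroblast_mixture,
              fibroblast_shift = fibroblast_shift, noise_sd = noise_sd,
              genes_per_set = as.integer(genes_per_set), scale_tag = scale_tag,
              survival = survival, transition_matrix = transition_matrix,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

check_prob_vector <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop(what, " must be nonnegative and sum to 1 (within 1e-9)", call. = FALSE)
  }
  invisible(p)
}

validate_cohort_config <- function(cfg) {
  check_prob_vector(cfg$phenotype_proportions, "phenotype_proportions")
  check_prob_vector(cfg$fibroblast_mixture, "fibroblast_mixture")
  tm <- cfg$transition_matrix
  if (!is.matrix(tm) || any(dim(tm) != 3L)) stop("transition_matrix must be 3x3", call. = FALSE)
  apply(tm, 1L, check_prob_vector, what = "transition_matrix row")
  panel <- fibroblast_markers()
  n_planted <- 18L * cfg$genes_per_set + length(panel_union(panel))
  if (cfg$n_genes <= n_planted) {
    stop("n_genes (", cfg$n_genes, ") must exceed the planted-set union (",
         n_planted, ")", call. = FALSE)
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (length(cfg$immune_shift) != 3L || length(cfg$stromal_shift) != 3L) {
    stop("immune_shift and stromal_shift need one value per phenotype", call. = FALSE)
  }
  invisible(cfg)
}

#' Default phenotype transition matrix
#'
#' Rows/columns ordered Hot, Moderate, Cold. Diagonal retention 0.92,
#' 0.92, 0.52: Hot and Moderate tumors mostly retain their phenotype
#' across a treatment step while about half of Cold tumors warm up,
#' mirroring reported neoadjuvant retention patterns.
#'
#' @return a 3x3 row-stochastic matrix.
#' @export
default_transition_matrix <- function() {
  m <- matrix(c(0.92, 0.04, 0.04,
                0.04, 0.92, 0.04,
                0.24, 0.24, 0.52),
              nrow = 3, byrow = TRUE,
              dimnames = list(.phenotype_levels, .phenotype_levels))
  m
}

# gene universe layout: 18 disjoint cell-type sets of genes_per_set genes,
# then the fibroblast marker genes under their real symbols, then filler
synthetic_gene_universe <- function(cfg) {
  cell_types <- c(.cell_types_immune, .cell_types_stromal)
  sets <- list()
  idx <- 0L
  for (ct in cell_types) {
    sets[[ct]] <- sprintf("%s_G%03d", toupper(ct), seq_len(cfg$genes_per_set))
    idx <- idx + cfg$genes_per_set
  }
  panel_genes <- panel_union(fibroblast_markers())
  n_fill <- cfg$n_genes - idx - length(panel_genes)
  filler <- sprintf("FILLER_G%05d", seq_len(n_fill))
  list(genes = c(unlist(sets, use.names = FALSE), panel_genes, filler),
       sets = sets)
}

#' Generate a synthetic cohort
#'
#' Baseline expression is gene-wise Gaussian noise (mean 0, sd
#' `noise_sd`) on the log scale. Each sample's planted immune phenotype
#' adds `immune_shift[phenotype]` to all immune-set genes and
#' `stromal_shift[phenotype]` to the endothelial/fibroblast set genes;
#' its planted fibroblast subtype adds `fibroblast_shift` to that
#' subtype's own marker panel. With `scale_tag = "counts"` the log-scale
#' matrix is exponentiated (base 2, offset +5) and Poisson-sampled.
#'
#' @param config a [cohort_config()].
#' @return an object of class `"synthetic_cohort"`: list with
#'   `expression` (genes x samples matrix), `annotation` (data.frame),
#'   `gene_sets` (collection of the 18 cell-type sets plus the
#'   `Immune_Score` union), `truth` (planted phenotype, fibroblast
#'   subtype and immune score per sample) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  with_seed(config$seed, {
    n <- config$n_samples
    uni <- synthetic_gene_universe(config)
    sample_ids <- sprintf("S%04d", seq_len(n))
    phenotype <- sample(.phenotype_levels, n, replace = TRUE,
                        prob = config$phenotype_proportions)
    fibro <- sample(.fibro_levels, n, replace = TRUE,
                    prob = config$fibroblast_mixture)
    x <- matrix(stats::rnorm(length(uni$genes) * n, 0, config$noise_sd),
                nrow = length(uni$genes), ncol = n,
                dimnames = list(uni$genes, sample_ids))
    imm_genes <- unlist(uni$sets[.cell_types_immune], use.names = FALSE)
    str_genes <- unlist(uni$sets[.cell_types_stromal], use.names = FALSE)
    ishift <- config$immune_shift[phenotype]
    sshift <- config$stromal_shift[phenotype]
    x[imm_genes, ] <- x[imm_genes, ] + rep(ishift, each = length(imm_genes))
    x[str_genes, ] <- x[str_genes, ] + rep(sshift, each = length(str_genes))
    panel <- fibroblast_markers()
    panel_sets <- list(NF = panel$nf_genes, iCAF = panel$icaf_genes,
                       myCAF = panel$mycaf_genes)
    for (sub in .fibro_levels) {
      cols <- which(fibro == sub)
      if (length(cols)) {
        x[panel_sets[[sub]], cols] <- x[panel_sets[[sub]], cols] + config$fibroblast_shift
      }
    }
    if (config$scale_tag == "counts") {
      lambda <- 2^(x + 5)
      x[] <- stats::rpois(length(x), lambda)
    }
    expr <- build_expression_matrix(x, config$scale_tag)
    annotation <- data.frame(
      sample_id = sample_ids,
      ancestry = sample(names(.ancestry_freq), n, TRUE, .ancestry_freq),
      age_group = sample(names(.age_freq), n, TRUE, .age_freq),
      stage = sample(names(.stage_freq), n, TRUE, .stage_freq),
      pam50 = sample(names(.pam50_freq), n, TRUE, .pam50_freq),
      dataset_id = "SYNTH1",
      timepoint = "baseline",
      response = NA_character_,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      sample_id = sample_ids,
      phenotype = phenotype,
      fibroblast_subtype = fibro,
      immune_score_planted = unname(config$immune_shift[phenotype]),
      stringsAsFactors = FALSE
    )
    gene_sets <- build_consensus_sets(
      gene_set_collection(uni$sets, provenance = "synthetic cohort generator"))
    structure(list(expression = expr, annotation = annotation,
                   gene_sets = gene_sets, truth = truth, config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", ncol(x$expression), "samples x",
      nrow(x$expression), "genes (", attr(x$expression, "scale_tag"), ")\n")
  print(table(planted_phenotype = x$truth$phenotype))
  invisible(x)
}

#' Generate survival records tied to planted immune activity
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(log_hazard_per_immune_unit * immune_score)`.
#' Censoring times are uniform on (0, b) with b solved numerically so the
#' expected censored fraction equals `censor_rate`; censoring is
#' independent of the event process.
#'
#' @param truth data.frame with columns `sample_id` and
#'   `immune_score_planted` (the `truth` component of a cohort).
#' @param survival_params list with `baseline_hazard` (> 0),
#'   `log_hazard_per_immune_unit`, `censor_rate` in [0, 1).
#' @param seed integer seed.
#' @param endpoint endpoint label stored on the records.
#' @return data.frame with `sample_id`, `time`, `event` (1 = event,
#'   0 = censored), `endpoint`.
#' @export
generate_survival <- function(truth,
                              survival_params = list(baseline_hazard = 0.1,
                                                     log_hazard_per_immune_unit = log(2),
                                                     censor_rate = 0.4),
                              seed = 1L, endpoint = "OS") {
  h0 <- survival_params$baseline_hazard
  beta <- survival_params$log_hazard_per_immune_unit
  cr <- survival_params$censor_rate %||% 0
  if (!is.numeric(h0) || h0 <= 0) stop("baseline hazard must be positive", call. = FALSE)
  if (cr < 0 || cr >= 1) stop("censor_rate must be in [0, 1)", call. = FALSE)
  rate <- h0 * exp(beta * truth$immune_score_planted)
  with_seed(derive_seed(seed, "survival"), {
    t_event <- stats::rexp(length(rate), rate = rate)
    if (cr > 0) {
      # C ~ U(0, b) censors when C < T; for T ~ Exp(rate),
      # P(censored | b) = E[min(T, b)] / b = (1 - exp(-rate*b))/(rate*b),
      # decreasing in b from 1 to 0 -> unique root
      pfun <- function(b) mean((1 - exp(-rate * b)) / (rate * b)) - cr
      upper <- 1 / min(rate)
      while (pfun(upper) > 0) upper <- upper * 10
      b <- stats::uniroot(pfun, c(1e-9, upper), tol = 1e-10)$root
      t_cens <- stats::runif(length(rate), 0, b)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, length(rate))
    }
    data.frame(sample_id = truth$sample_id, time = time, event = event,
               endpoint = endpoint, stringsAsFactors = FALSE)
  })
}

#' Extend a cohort across treatment timepoints
#'
#' Per-timepoint phenotypes follow a Markov chain started at the planted
#' baseline phenotype; expression is regenerated per timepoint from the
#' current phenotype (fibroblast subtype is retained). A response class is
#' assigned per patient with probability increasing in the final-timepoint
#' immune score through a cumulative-logit link:
#' `P(ypCR) = plogis(2*s - 2)`, `P(ypCR or ypPR) = plogis(2*s - 0.5)`
#' where `s` is the planted immune shift of the final phenotype.
#'
#' @param cohort a baseline [generate_cohort()] result.
#' @param transition_matrix 3x3 row-stochastic matrix (default: the
#'   cohort config's).
#' @param n_timepoints number of timepoints including baseline (max 3,
#'   named baseline/cycle2/surgery).
#' @param seed integer seed.
#' @return an object of class `"synthetic_cohort_longitudinal"`: list of
#'   per-timepoint expression matrices, a long annotation data.frame
#'   (patient_id, timepoint, response), and long truth (per-timepoint
#'   phenotype).
#' @export
generate_longitudinal <- function(cohort,
                                  transition_matrix = cohort$config$transition_matrix,
                                  n_timepoints = 3L, seed = 1L) {
  apply(transition_matrix, 1L, check_prob_vector, what = "transition_matrix row")
  stopifnot(n_timepoints >= 2L, n_timepoints <= 3L)
  tps <- .timepoint_levels[seq_len(n_timepoints)]
  cfg <- cohort$config
  n <- cfg$n_samples
  with_seed(derive_seed(seed, "longitudinal"), {
    phen <- matrix(NA_character_, nrow = n, ncol = n_timepoints,
                   dimnames = list(cohort$truth$sample_id, tps))
    phen[, 1L] <- cohort$truth$phenotype
    for (t in 2:n_timepoints) {
      for (i in seq_len(n)) {
        phen[i, t] <- sample(.phenotype_levels, 1L,
                             prob = transition_matrix[phen[i, t - 1L], ])
      }
    }
    exprs <- vector("list", n_timepoints)
    names(exprs) <- tps
    exprs[[1L]] <- cohort$expression
    for (t in 2:n_timepoints) {
      cfg_t <- cohort$config
      cfg_t$seed <- cfg$seed + 7919L * (t - 1L)  # independent noise per timepoint
      tmp <- regenerate_expression(cfg_t, phen[, t], cohort$truth$fibroblast_subtype,
                                   cohort$truth$sample_id)
      exprs[[t]] <- tmp
    }
    s_final <- unname(cfg$immune_shift[phen[, n_timepoints]])
    p_cr <- stats::plogis(2 * s_final - 2)
    p_cr_pr <- stats::plogis(2 * s_final - 0.5)
    u <- stats::runif(n)
    response <- ifelse(u < p_cr, "ypCR", ifelse(u < p_cr_pr, "ypPR", "ypSD"))
    truth_long <- data.frame(
      patient_id = rep(rownames(phen), n_timepoints),
      timepoint = rep(tps, each = n),
      phenotype = as.vector(phen),
      stringsAsFactors = FALSE
    )
    annotation <- cohort$annotation
    annotation$response <- response
    structure(list(expressions = exprs, annotation = annotation,
                   truth = truth_long,
                   fibroblast_subtype = stats::setNames(cohort$truth$fibroblast_subtype,
                                                        cohort$truth$sample_id),
                   gene_sets = cohort$gene_sets, config = cfg,
                   transition_matrix = transition_matrix),
              class = "synthetic_cohort_longitudinal")
  })
}

# expression for a given phenotype vector, same gene universe/layout
regenerate_expression <- function(cfg, phenotype, fibro, sample_ids) {
  with_seed(cfg$seed, {
    uni <- synthetic_gene_universe(cfg)
    n <- length(sample_ids)
    x <- matrix(stats::rnorm(length(uni$genes) * n, 0, cfg$noise_sd),
                nrow = length(uni$genes), ncol = n,
                dimnames = list(uni$genes, sample_ids))
    imm_genes <- unlist(uni$sets[.cell_types_immune], use.names = FALSE)
    str_genes <- unlist(uni$sets[.cell_types_stromal], use.names = FALSE)
    x[imm_genes, ] <- x[imm_genes, ] + rep(cfg$immune_shift[phenotype], each = length(imm_genes))
    x[str_genes, ] <- x[str_genes, ] + rep(cfg$stromal_shift[phenotype], each = length(str_genes))
    panel <- fibroblast_markers()
    panel_sets <- list(NF = panel$nf_genes, iCAF = panel$icaf_genes,
                       myCAF = panel$mycaf_genes)
    for (sub in .fibro_levels) {
      cols <- which(fibro == sub)
      if (length(cols)) {
        x[panel_sets[[sub]], cols] <- x[panel_sets[[sub]], cols] + cfg$fibroblast_shift
      }
    }
    if (cfg$scale_tag == "counts") {
      lambda <- 2^(x + 5)
      x[] <- stats::rpois(length(x), lambda)
    }
    build_expression_matrix(x, cfg$scale_tag)
  })
}
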