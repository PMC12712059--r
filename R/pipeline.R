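# End-to-end orchestration: simulate (or load) -> score -> phenotype ->
# fibroblast -> ratio/survival -> association -> transitions, with plain
# TSV outputs and a reproducibility manifest.

#' Pipeline configuration
#'
#' Either `simulate` (a [cohort_config()] or list of its arguments) or
#' the input paths `expr`, `gmt` must be given; `clinical` is optional
#' for loaded data. All randomness flows from the named seeds.
#'
#' @param outdir output directory (created if needed).
#' @param simulate `NULL`, or cohort-generator settings.
#' @param expr,gmt,clinical input paths for pre-computed data.
#' @param scale_tag expression scale for loaded data.
#' @param k cluster number: `"auto"` or a fixed integer.
#' @param k_range candidate k when `k = "auto"`.
#' @param minprop cutpoint window parameter.
#' @param endpoint survival endpoint label.
#' @param balance_strata columns to balance before the association model
#'   (`NULL` to skip balancing).
#' @param longitudinal logical: extend a simulated cohort across three
#'   treatment timepoints and tabulate transitions.
#' @param seeds named list: `global` (simulation/survival), `clustering`,
#'   `fibroblast` (default 123).
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(outdir,
                            simulate = list(),
                            expr = NULL, gmt = NULL, clinical = NULL,
                            scale_tag = "continuous",
                            k = "auto", k_range = 2:6,
                            minprop = 0.1, endpoint = "OS",
                            balance_strata = NULL,
                            longitudinal = TRUE,
                            seeds = list(global = 1L, clustering = 1L,
                                         fibroblast = 123L)) {
  if (missing(outdir) || is.null(outdir)) stop("config missing field: outdir", call. = FALSE)
  if (is.null(simulate)) {
    if (is.null(expr)) stop("config missing field: expr", call. = FALSE)
    if (is.null(gmt)) stop("config missing field: gmt", call. = FALSE)
  }
  seeds$global <- seeds$global %||% 1L
  seeds$clustering <- seeds$clustering %||% 1L
  seeds$fibroblast <- seeds$fibroblast %||% 123L
  structure(list(outdir = outdir, simulate = simulate, expr = expr, gmt = gmt,
                 clinical = clinical, scale_tag = scale_tag, k = k,
                 k_range = k_range, minprop = minprop, endpoint = endpoint,
                 balance_strata = balance_strata, longitudinal = longitudinal,
                 seeds = seeds),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config()]
#'   arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, enrichment scoring, phenotyping, fibroblast
#' classification, immune-stromal ratio, survival stratification,
#' phenotype-covariate association and (for simulated longitudinal
#' cohorts) phenotype transitions, writing one TSV per stage plus a
#' `manifest.json` recording the package version, seeds and parameter
#' hash. Identical configs produce identical outputs.
#'
#' @param config a [pipeline_config()], a list of its arguments, or a
#'   path to a YAML file.
#' @return invisibly, a named list of the written file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  pathify <- function(f) file.path(config$outdir, f)

  # -- inputs -----------------------------------------------------------
  simulated <- !is.null(config$simulate)
  if (simulated) {
    co <- stage("simulate", {
      args <- config$simulate
      args$seed <- args$seed %||% config$seeds$global
      cohort <- generate_cohort(do.call(cohort_config, args))
      write_expression_table(cohort$expression, pathify("expression.tsv"))
      write_gmt(cohort$gene_sets, pathify("gene_sets.gmt"))
      write_schema_tsv(cohort$annotation, pathify("clinical.tsv"))
      write_schema_tsv(cohort$truth, pathify("truth.tsv"))
      cohort
    })
    expr <- co$expression
    sets <- co$gene_sets
    annotation <- co$annotation
    out$expression <- pathify("expression.tsv")
  } else {
    expr <- stage("load", read_expression_table(config$expr, config$scale_tag))
    sets <- stage("load", build_consensus_sets(read_gmt(config$gmt)))
    annotation <- if (!is.null(config$clinical))
      stage("load", read_clinical_table(config$clinical)) else NULL
  }

  # -- enrichment -------------------------------------------------------
  scores <- stage("score", gsva_scores(expr, sets))
  score_df <- data.frame(cell_type = rownames(scores), scores,
                         check.names = FALSE)
  write_schema_tsv(score_df, out$scores <- pathify("scores.tsv"))

  # -- phenotype --------------------------------------------------------
  fit <- stage("phenotype", immune_phenotype(scores, k = config$k,
                                             k_range = config$k_range,
                                             seed = config$seeds$clustering))
  write_schema_tsv(data.frame(sample_id = fit$sample_ids,
                              cluster = unname(fit$cluster),
                              label = unname(fit$label)),
                   out$phenotype <- pathify("phenotype.tsv"))

  # -- fibroblast -------------------------------------------------------
  fc <- stage("fibro", classify_fibroblasts(expr, seed = config$seeds$fibroblast))
  write_schema_tsv(data.frame(sample_id = fc$sample_ids,
                              cluster = unname(fc$cluster),
                              subtype = unname(fc$subtype)),
                   out$fibroblast <- pathify("fibroblast.tsv"))

  # -- immune-stromal ratio --------------------------------------------
  ratio <- stage("ratio", immune_stromal_ratio(scores))
  write_schema_tsv(ratio, out$ratio <- pathify("ratio.tsv"))

  # -- survival ---------------------------------------------------------
  if (simulated) {
    surv <- stage("survive", {
      rec <- generate_survival(co$truth, co$config$survival,
                               seed = config$seeds$global,
                               endpoint = config$endpoint)
      imm <- overall_immune_score(scores)
      cut <- optimal_cutpoint(rec$time, rec$event, unname(imm),
                              minprop = config$minprop,
                              variable = "overall_immune_score")
      lr <- logrank_test(rec$time, rec$event, fit$label)
      cx <- cox_fit(rec$time, rec$event,
                    data.frame(immune_score = unname(imm)))
      write_schema_tsv(
        data.frame(variable = cut$variable, cutpoint = cut$cutpoint,
                   statistic = cut$statistic,
                   logrank_chisq = lr$statistic, logrank_df = lr$df,
                   logrank_p = lr$p_value),
        out$survival <- pathify("survival.tsv"))
      write_schema_tsv(cx, out$cox <- pathify("cox.tsv"))
      rec
    })
  }

  # -- association ------------------------------------------------------
  if (!is.null(annotation)) {
    stage("associate", {
      ann <- annotation
      labs <- fit$label[match(ann$sample_id, fit$sample_ids)]
      if (!is.null(config$balance_strata)) {
        keep_ids <- stratified_balance(ann, config$balance_strata,
                                       seed = config$seeds$global)
        sel <- ann$sample_id %in% keep_ids
        ann <- ann[sel, , drop = FALSE]
        labs <- labs[sel]
      }
      assoc <- logistic_ovr(ann, labs)
      write_schema_tsv(assoc, out$associations <- pathify("associations.tsv"))
    })
  }

  # -- transitions ------------------------------------------------------
  if (simulated && isTRUE(config$longitudinal)) {
    stage("transitions", {
      lg <- generate_longitudinal(co, seed = config$seeds$global)
      tp <- unique(lg$truth$timepoint)
      tt <- transition_table(
        data.frame(patient_id = lg$truth$patient_id[lg$truth$timepoint == tp[1]],
                   label = lg$truth$phenotype[lg$truth$timepoint == tp[1]]),
        data.frame(patient_id = lg$truth$patient_id[lg$truth$timepoint == tp[2]],
                   label = lg$truth$phenotype[lg$truth$timepoint == tp[2]]),
        timepoint_pair = tp[1:2])
      df <- as.data.frame(as.table(matrix(tt, 3, 3,
                                          dimnames = dimnames(tt))))
      names(df) <- c("from", "to", "count")
      write_schema_tsv(df, out$transitions <- pathify("transitions.tsv"))
    })
  }

  # -- manifest ---------------------------------------------------------
  params <- unclass(config)[setdiff(names(config), "outdir")]
  pj <- jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile(); writeLines(pj, tf)
  manifest <- list(
    package = "tmephenotyper",
    version = as.character(utils::packageVersion("tmephenotyper")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seeds = config$seeds,
    parameter_hash = unname(tools::md5sum(tf)),
    outputs = vapply(out, basename, character(1))
  )
  unlink(tf)
  jsonlite::write_json(manifest, out$manifest <- pathify("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
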