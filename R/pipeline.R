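# End-to-end orchestration: simulate (or ingest) -> batch-correct ->
# consensus-cluster regulators -> differential expression -> m6A-related
# clusters -> signature -> score/cutoff/orientation -> survival summary
# (-> optional enrichment and response prediction), with plain TSV/JSON
# artifacts per stage.

#' Pipeline configuration
#'
#' Validated bundle of every pipeline threshold, mirroring the method's
#' defaults: consensus clustering with k = 2..10, 1000 replicates at 0.8
#' subsampling; DE at adjusted p < 0.01; univariate Cox filter at
#' p < 0.05; 500-tree random forest; cutpoint minprop 0.1; GSEA
#' significance at |NES| > 1 and nominal p < 0.05.
#'
#' @param simulation a [simulation_config()] describing the cohort to
#'   simulate, or `NULL` when `expression`/`clinical` are supplied.
#' @param expression,clinical,batch pre-built inputs (matrix, data.frame,
#'   factor) used when `simulation` is `NULL`.
#' @param regulators character vector of clustering features (default: the
#'   16-gene m6A panel).
#' @param k_max,reps,subsample consensus-clustering parameters.
#' @param de_alpha adjusted-p DE threshold.
#' @param cox_alpha univariate Cox threshold.
#' @param rf_trees random-forest size.
#' @param minprop cutpoint minimum group fraction.
#' @param nes_min,gsea_alpha GSEA significance thresholds.
#' @param roc_horizons time-dependent ROC horizons (years); clipped to the
#'   observed follow-up at run time.
#' @param gene_sets optional named list of gene sets for the enrichment
#'   stage.
#' @param response a [simulation_config()] for a response cohort, or
#'   `NULL` to skip the response stage.
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL,
                            expression = NULL, clinical = NULL, batch = NULL,
                            regulators = m6a_regulator_panel()$symbol,
                            k_max = 10, reps = 1000, subsample = 0.8,
                            de_alpha = 0.01, cox_alpha = 0.05,
                            rf_trees = 500, minprop = 0.1,
                            nes_min = 1, gsea_alpha = 0.05,
                            roc_horizons = c(5, 10, 15),
                            gene_sets = NULL,
                            response = NULL,
                            seed = 1) {
  for (nm in c("de_alpha", "cox_alpha", "minprop", "gsea_alpha", "subsample")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0 || v >= 1) {
      stop(sprintf("`%s` must lie strictly inside (0, 1), got %s", nm,
                   format(v)), call. = FALSE)
    }
  }
  k_max <- assert_count(k_max, "k_max", min = 2)
  reps <- assert_count(reps, "reps", min = 1)
  rf_trees <- assert_count(rf_trees, "rf_trees", min = 1)
  seed <- assert_count(seed, "seed", min = 0)
  if (is.null(simulation) && (is.null(expression) || is.null(clinical))) {
    stop("supply either `simulation` or `expression` + `clinical`",
         call. = FALSE)
  }
  structure(
    list(simulation = simulation, expression = expression,
         clinical = clinical, batch = batch, regulators = regulators,
         k_max = k_max, reps = reps, subsample = subsample,
         de_alpha = de_alpha, cox_alpha = cox_alpha, rf_trees = rf_trees,
         minprop = minprop, nes_min = nes_min, gsea_alpha = gsea_alpha,
         roc_horizons = roc_horizons, gene_sets = gene_sets,
         response = response, seed = seed),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Reads the scalar fields of [pipeline_config()] (plus an optional
#' `simulation:` and `response:` block of [simulation_config()] fields)
#' from a YAML file.
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) y$simulation <- do.call(simulation_config, y$simulation)
  if (!is.null(y$response)) y$response <- do.call(simulation_config, y$response)
  do.call(pipeline_config, y)
}

#' Run the full m6A-score pipeline
#'
#' Executes every stage in order on a simulated or supplied cohort and
#' returns (and optionally writes) the per-stage artifacts plus a summary:
#' chosen k, number of DEGs, signature size, cutoff, per-group median
#' survival, log-rank p, multivariate Cox hazard ratio of the score group,
#' and the time-dependent AUCs. Each stochastic stage runs under a seed
#' derived from `config$seed`, so the whole pipeline is bit-reproducible.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for TSV/JSON artifacts.
#' @return list of stage results (`cohort`, `consensus`, `clusters`, `de`,
#'   `related_consensus`, `signature`, `scores`, `survival`, optionally
#'   `enrichment` and `response`) plus `summary` (a flat list).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- cohort -----------------------------------------------------------
  cohort <- stage("input", {
    if (!is.null(config$simulation)) {
      generate_cohort(config$simulation)
    } else {
      expr <- config$expression
      assert_expression_matrix(expr)
      batch <- if (is.null(config$batch)) {
        factor(rep("cohort1", ncol(expr)))
      } else {
        factor(config$batch)
      }
      structure(list(expression = expr, batch = batch,
                     clinical = config$clinical, truth = NULL),
                class = "synthetic_cohort")
    }
  })
  clin <- cohort$clinical
  time <- clin$os_time
  event <- clin$os_event

  # -- batch correction -------------------------------------------------
  corrected <- stage("batch-correct", {
    if (nlevels(cohort$batch) >= 2L) {
      combat_adjust(cohort$expression, cohort$batch)$corrected
    } else {
      cohort$expression
    }
  })

  # -- consensus clustering of the regulator panel ----------------------
  regulators <- intersect(config$regulators, rownames(corrected))
  if (length(regulators) < 2L) {
    stop("pipeline stage 'cluster' failed: fewer than 2 regulator genes present",
         call. = FALSE)
  }
  consensus <- stage("cluster", consensus_cluster(
    subset_features(corrected, regulators),
    k_max = config$k_max, reps = config$reps,
    subsample = config$subsample, seed = seed + 101L
  ))
  chosen_k <- select_k(consensus)
  # the scoring track always contrasts the two-cluster split, as the
  # signature is defined between two m6A clusters
  raw_labels <- consensus$labels[, "2"]
  named <- stage("label", label_m6a_clusters(raw_labels, time, event))
  labels <- named$labels

  # -- differential expression -----------------------------------------
  de <- stage("de", moderated_de(corrected,
                                 factor(labels, levels = c("A", "B")),
                                 alpha_adj = config$de_alpha))
  degs <- de$gene[de$significant]
  if (length(degs) < 2L) {
    stop("pipeline stage 'de' failed: fewer than 2 DEGs at adjusted p < ",
         config$de_alpha, call. = FALSE)
  }

  # -- m6A-related clusters on the DEG matrix ---------------------------
  related <- stage("related-cluster", consensus_cluster(
    subset_features(corrected, degs),
    k_max = min(config$k_max, ncol(corrected) - 1L),
    reps = config$reps, subsample = config$subsample, seed = seed + 202L
  ))
  related_named <- label_m6a_clusters(related$labels[, "2"], time, event)

  # -- signature --------------------------------------------------------
  kept_rf <- stage("signature", rf_redundancy_filter(
    subset_features(corrected, degs), labels,
    n_trees = config$rf_trees, seed = seed + 303L
  ))
  prognostic <- stage("signature", cox_univariate_filter(
    corrected, time, event, genes = kept_rf, alpha = config$cox_alpha
  ))
  if (length(prognostic) < 2L) {
    stop("pipeline stage 'signature' failed: fewer than 2 prognostic genes",
         call. = FALSE)
  }
  model <- fit_signature(corrected, prognostic)
  scored <- score_samples(corrected, model)
  cutoff <- stage("cutoff", optimal_cutoff(scored$score, time, event,
                                           minprop = config$minprop))
  oriented <- stage("orient", orient_score(scored, model, time, event,
                                           as.numeric(cutoff)))
  score_table <- oriented$scores
  model <- oriented$model

  # -- survival summary -------------------------------------------------
  survres <- stage("survival", {
    grp <- score_table$group
    km_low <- km_fit(time[grp == "low"], event[grp == "low"])
    km_high <- km_fit(time[grp == "high"], event[grp == "high"])
    lr <- logrank_test(time, event, grp)
    covars <- data.frame(low_score = as.integer(grp == "low"))
    if (!is.null(clin$age)) covars$age <- clin$age
    if (!is.null(clin$stage)) {
      covars$advanced_stage <- as.integer(clin$stage %in% c("III", "IV"))
    }
    cox <- cox_fit(time, event, covars)
    horizons <- config$roc_horizons[config$roc_horizons <= max(time)]
    troc <- if (length(horizons) > 0L) {
      time_roc(time, event, -score_table$score, horizons)
    } else {
      NULL
    }
    list(km_low = km_low, km_high = km_high, logrank = lr, cox = cox,
         time_roc = troc)
  })

  # -- optional enrichment ----------------------------------------------
  enrichment <- NULL
  if (!is.null(config$gene_sets)) {
    enrichment <- stage("enrich", {
      gsva_like <- ssgsea_score(corrected, config$gene_sets)
      gsea <- gsea_two_group(corrected,
                             factor(score_table$group,
                                    levels = c("high", "low")),
                             config$gene_sets, n_perm = 200,
                             seed = seed + 404L,
                             nes_min = config$nes_min,
                             alpha = config$gsea_alpha)
      list(ssgsea = gsva_like, gsea = gsea)
    })
  }

  # -- optional response cohort -----------------------------------------
  response <- NULL
  if (!is.null(config$response)) {
    response <- stage("respond", {
      rc <- generate_response_cohort(config$response)
      rsc <- score_samples(rc$expression, model)
      roc <- binary_roc(rc$clinical$response, -rsc$score)
      burden_cor <- spearman_cor(rsc$score, rc$clinical$neoantigen_burden)
      list(cohort = rc, scores = rsc, roc = roc, burden_cor = burden_cor)
    })
  }

  hr_low <- survres$cox$coefficients$hr[
    survres$cox$coefficients$term == "low_score"]
  summary <- list(
    seed = seed,
    config_hash = rlang::hash(config),
    chosen_k = chosen_k,
    pac = as.list(consensus$pac),
    n_deg = length(degs),
    n_rf_kept = length(kept_rf),
    n_signature_genes = length(prognostic),
    cutoff = unname(score_table$cutoff[1L]),
    score_flipped = oriented$flipped,
    n_low = sum(score_table$group == "low"),
    n_high = sum(score_table$group == "high"),
    median_surv_low = survres$km_low$median,
    median_surv_high = survres$km_high$median,
    logrank_p = survres$logrank$p,
    cox_hr_low_score = hr_low,
    cox_p_low_score = survres$cox$coefficients$p[
      survres$cox$coefficients$term == "low_score"],
    time_auc = if (!is.null(survres$time_roc)) {
      stats::setNames(as.list(survres$time_roc$auc$auc),
                      paste0("y", survres$time_roc$auc$horizon))
    },
    response_auc = if (!is.null(response)) response$roc$auc,
    response_burden_rho = if (!is.null(response)) response$burden_cor$rho
  )

  result <- list(cohort = cohort, corrected = corrected,
                 consensus = consensus, chosen_k = chosen_k,
                 cluster_labels = labels, cluster_mapping = named$mapping,
                 de = de, related_consensus = related,
                 related_labels = related_named$labels,
                 signature = model, scores = score_table,
                 survival = survres, enrichment = enrichment,
                 response = response, summary = summary)

  if (!is.null(out_dir)) {
    write_expression(corrected, file.path(out_dir, "expression_corrected.tsv"))
    utils::write.table(
      data.frame(sample = colnames(corrected), m6a_cluster = labels,
                 related_cluster = related_named$labels),
      file.path(out_dir, "clusters.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(de, file.path(out_dir, "differential_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(score_table, file.path(out_dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(genes = model$genes, center = as.list(model$center),
           scale = as.list(model$scale),
           loadings = as.data.frame(model$loadings),
           cutoff = unname(score_table$cutoff[1L]),
           oriented = model$oriented),
      file.path(out_dir, "signature_model.json"), auto_unbox = TRUE,
      digits = NA)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
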