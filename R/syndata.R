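#' Configuration for a synthetic multi-cohort simulation
#'
#' Bundles and validates every knob of the synthetic-cohort generator.
#' The generated data carry the statistical structure the downstream
#' analysis assumes: two latent expression clusters driven by the regulator
#' panel plus a block of cluster-differential genes, additive per-cohort
#' batch shifts, cluster-dependent proportional hazards on censored
#' survival, and (for response cohorts) a binary response whose log-odds
#' shift with the latent score.
#'
#' @param n_samples samples per cohort (positive integer).
#' @param n_cohorts number of cohorts/batches (>= 1).
#' @param n_genes total genes; must be >= `n_regulators + n_deg`.
#' @param n_regulators number of regulator genes (default 16, named after
#'   the m6A panel of [m6a_regulator_panel()]).
#' @param n_deg number of cluster-differential genes beyond the regulators.
#' @param cluster_shift between-cluster mean difference, in units of the
#'   within-cluster SD (which is 1), applied independently to each
#'   regulator/DEG gene; cluster A is the low-expression, poor-prognosis
#'   cluster.
#' @param batch_shift additive offset (SD units) applied to all genes of
#'   cohort b as `batch_shift * (b - 1)`.
#' @param hazard_ratio_true hazard multiplier of cluster A relative to B.
#' @param baseline_hazard events per year for cluster B.
#' @param censor_rate expected fraction of administratively censored
#'   samples, in `[0, 1)`.
#' @param response_effect log-odds shift of response per SD of the latent
#'   score (response cohorts only).
#' @param neoantigen_cor target correlation (sign and rough magnitude)
#'   between latent score and neoantigen burden; negative by default.
#' @param seed integer seed; together with the config it fully determines
#'   the generated cohort.
#' @return An object of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(n_samples = 50, n_genes = 100, n_deg = 20, seed = 1)
#' @export
simulation_config <- function(n_samples = 150,
                              n_cohorts = 3,
                              n_genes = 2000,
                              n_regulators = 16,
                              n_deg = 200,
                              cluster_shift = 2,
                              batch_shift = 1,
                              hazard_ratio_true = 2,
                              baseline_hazard = 0.08,
                              censor_rate = 0.3,
                              response_effect = 0,
                              neoantigen_cor = -0.3,
                              seed = 1) {
  n_samples <- assert_count(n_samples, "n_samples", min = 2)
  n_cohorts <- assert_count(n_cohorts, "n_cohorts", min = 1)
  n_genes <- assert_count(n_genes, "n_genes", min = 1)
  n_regulators <- assert_count(n_regulators, "n_regulators", min = 1)
  n_deg <- assert_count(n_deg, "n_deg", min = 0)
  assert_scalar_number(cluster_shift, "cluster_shift", lower = 0)
  assert_scalar_number(batch_shift, "batch_shift")
  assert_scalar_number(hazard_ratio_true, "hazard_ratio_true")
  if (hazard_ratio_true <= 0) stop("`hazard_ratio_true` must be > 0", call. = FALSE)
  assert_scalar_number(baseline_hazard, "baseline_hazard")
  if (baseline_hazard <= 0) stop("`baseline_hazard` must be > 0", call. = FALSE)
  assert_scalar_number(censor_rate, "censor_rate", lower = 0, upper = 1 - 1e-9)
  assert_scalar_number(response_effect, "response_effect")
  assert_scalar_number(neoantigen_cor, "neoantigen_cor", lower = -1, upper = 1)
  seed <- assert_count(seed, "seed", min = 0)
  if (n_genes < n_regulators + n_deg) {
    stop("`n_genes` must be >= n_regulators + n_deg", call. = FALSE)
  }
  structure(
    list(n_samples = n_samples, n_cohorts = n_cohorts, n_genes = n_genes,
         n_regulators = n_regulators, n_deg = n_deg,
         cluster_shift = cluster_shift, batch_shift = batch_shift,
         hazard_ratio_true = hazard_ratio_true,
         baseline_hazard = baseline_hazard, censor_rate = censor_rate,
         response_effect = response_effect, neoantigen_cor = neoantigen_cor,
         seed = seed),
    class = "simulation_config"
  )
}

sim_gene_names <- function(config) {
  panel <- m6a_regulator_panel()$symbol
  reg <- if (config$n_regulators <= length(panel)) {
    panel[seq_len(config$n_regulators)]
  } else {
    c(panel, sprintf("REG%04d", seq_len(config$n_regulators - length(panel))))
  }
  deg <- if (config$n_deg > 0) sprintf("DEG%04d", seq_len(config$n_deg)) else character(0)
  n_noise <- config$n_genes - config$n_regulators - config$n_deg
  noise <- if (n_noise > 0) sprintf("GENE%05d", seq_len(n_noise)) else character(0)
  c(reg, deg, noise)
}

#' Generate a synthetic multi-cohort expression/survival dataset
#'
#' Expression for each gene is baseline-plus-noise on a log2-like scale
#' (baseline N(8, 0.25) across genes, within-cluster noise SD 1). Samples
#' are assigned to the two latent clusters by a fair coin; cluster B adds
#' `cluster_shift` to every regulator and DEG gene (so cluster A is the
#' low-expression cluster, matching its poorer prognosis). Cohort b adds
#' `batch_shift * (b - 1)` to all genes. Survival times are exponential
#' with hazard `baseline_hazard * hazard_ratio_true^(cluster == A)`, with
#' independent exponential censoring tuned so that the expected censored
#' fraction is `censor_rate`.
#'
#' The recorded truth (cluster labels, the latent score
#' `cluster_shift * (I(B) - 1/2)`, the differential gene list and the true
#' hazard ratio) is kept in a separate element so downstream stages cannot
#' leak it.
#'
#' @param config a [simulation_config()].
#' @return An object of class `synthetic_cohort`: a list with elements
#'   `expression` (genes x samples matrix), `batch` (per-sample cohort
#'   factor), `clinical` (data.frame: sample, os_time, os_event, age,
#'   stage, ldh, batch) and `truth` (list: cluster, latent_score,
#'   de_genes, hazard_ratio_true).
#' @examples
#' coh <- generate_cohort(simulation_config(n_samples = 40, n_cohorts = 2,
#'                                          n_genes = 60, n_deg = 20, seed = 7))
#' dim(coh$expression)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_samples * config$n_cohorts
  genes <- sim_gene_names(config)
  samples <- sprintf("S%04d", seq_len(n))
  batch <- factor(rep(sprintf("cohort%d", seq_len(config$n_cohorts)),
                      each = config$n_samples))

  cluster <- ifelse(stats::runif(n) < 0.5, "A", "B")
  latent <- config$cluster_shift * (as.numeric(cluster == "B") - 0.5)

  baseline <- stats::rnorm(config$n_genes, 8, 0.5)
  x <- matrix(stats::rnorm(config$n_genes * n), config$n_genes, n,
              dimnames = list(genes, samples))
  x <- x + baseline

  n_info <- config$n_regulators + config$n_deg
  info_idx <- seq_len(n_info)
  x[info_idx, cluster == "B"] <- x[info_idx, cluster == "B"] + config$cluster_shift

  batch_offset <- config$batch_shift * (as.numeric(batch) - 1)
  x <- x + rep(batch_offset, each = config$n_genes)

  haz <- config$baseline_hazard *
    config$hazard_ratio_true^(as.numeric(cluster == "A"))
  t_event <- stats::rexp(n, rate = haz)
  # independent exponential censoring; for exponential T with average rate
  # lambda-bar, a censoring rate mu gives P(censored) = mu / (lambda + mu)
  clin_time <- t_event
  status <- rep(1L, n)
  if (config$censor_rate > 0) {
    mu <- config$censor_rate / (1 - config$censor_rate) * mean(haz)
    t_cens <- stats::rexp(n, rate = mu)
    status <- as.integer(t_event <= t_cens)
    clin_time <- pmin(t_event, t_cens)
  }

  clinical <- data.frame(
    sample = samples,
    os_time = clin_time,
    os_event = status,
    age = round(stats::rnorm(n, 60, 10)),
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                   prob = c(0.2, 0.3, 0.3, 0.2)),
    ldh = sample(c("normal", "high"), n, replace = TRUE, prob = c(0.7, 0.3)),
    batch = as.character(batch),
    stringsAsFactors = FALSE
  )

  structure(
    list(expression = x,
         batch = batch,
         clinical = clinical,
         truth = list(cluster = stats::setNames(cluster, samples),
                      latent_score = stats::setNames(latent, samples),
                      de_genes = genes[info_idx],
                      hazard_ratio_true = config$hazard_ratio_true)),
    class = "synthetic_cohort"
  )
}

#' Generate a synthetic immunotherapy-response cohort
#'
#' Extends [generate_cohort()] with a per-sample binary response drawn from
#' `P(response) = plogis(intercept + response_effect * z)` where `z` is the
#' SD-standardized latent score and the intercept centres the response rate
#' at 0.5, and with a neoantigen-burden value correlated with the latent
#' score at the sign/magnitude of `config$neoantigen_cor` (negative by
#' default, mirroring the inverse score-burden association the score is
#' meant to reproduce).
#'
#' @inheritParams generate_cohort
#' @return A `synthetic_cohort` whose `clinical` gains `response` (0/1) and
#'   `neoantigen_burden` columns, and whose `truth` records the response
#'   probabilities used.
#' @export
generate_response_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    coh <- generate_cohort_impl(config)
    latent <- coh$truth$latent_score
    s <- stats::sd(latent)
    z <- if (s > 0) (latent - mean(latent)) / s else latent * 0
    p <- stats::plogis(config$response_effect * z)
    coh$clinical$response <- stats::rbinom(length(z), 1L, p)
    rho <- config$neoantigen_cor
    burden <- if (rho == 0) {
      stats::rnorm(length(z))
    } else {
      sign(rho) * z + stats::rnorm(length(z), sd = sqrt(1 / rho^2 - 1))
    }
    coh$clinical$neoantigen_burden <- 10 + 3 * burden
    coh$truth$response_prob <- stats::setNames(p, names(latent))
    coh
  })
}

#' Write a synthetic cohort to plain-text artifacts
#'
#' Writes `expression.tsv` (via [write_expression()]), `clinical.tsv` and
#' `truth.json` under `dir`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(cluster = as.list(cohort$truth$cluster),
         latent_score = as.list(cohort$truth$latent_score),
         de_genes = cohort$truth$de_genes,
         hazard_ratio_true = cohort$truth$hazard_ratio_true),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
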