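# End-to-end pipeline: indicators -> weights (COWA, PCA, game) ->
# rankings (all four methods) -> concordance, with every artifact
# written to a run directory and stamped with a configuration hash.

#' Pipeline configuration
#'
#' @param matrix_path CSV decision matrix (alternative to
#'   `profile_path` + `exams_path`).
#' @param profile_path,exams_path CSVs of equipment profiles and exam
#'   records; the decision matrix is then built from them.
#' @param panel_path CSV expert score panel (required for COWA and game
#'   weights; if absent, PCA weights alone drive the ranking).
#' @param rho Gray resolution factor (default 0.5).
#' @param alpha1,alpha2 Fusion preferences (default 0.5 / 0.5).
#' @param v VIKOR blend (default 0.5).
#' @param retention,retention_threshold PCA retention policy
#'   (default cumulative variance >= 0.85).
#' @param orientation Fusion orientation (default `"priority"`).
#' @param gray_degree_weighting `"weights"` or `"uniform"`.
#' @param seed Integer seed (echoed into outputs; only synthetic inputs
#'   consume randomness).
#' @param out_dir Output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(matrix_path = NULL, profile_path = NULL, exams_path = NULL,
                       panel_path = NULL, rho = 0.5, alpha1 = 0.5, alpha2 = 0.5,
                       v = 0.5, retention = "cumulative", retention_threshold = 0.85,
                       orientation = "priority", gray_degree_weighting = "weights",
                       seed = 1L, out_dir = "medequip-run") {
  if (is.null(matrix_path) && (is.null(profile_path) || is.null(exams_path))) {
    stop("config needs either matrix_path or profile_path + exams_path")
  }
  if (abs(alpha1 + alpha2 - 1) > 1e-9) stop("alpha1 + alpha2 must equal 1")
  if (rho <= 0 || rho > 1) stop("rho must lie in (0, 1]")
  structure(list(matrix_path = matrix_path, profile_path = profile_path,
                 exams_path = exams_path, panel_path = panel_path,
                 rho = rho, alpha1 = alpha1, alpha2 = alpha2, v = v,
                 retention = retention, retention_threshold = retention_threshold,
                 orientation = orientation,
                 gray_degree_weighting = gray_degree_weighting,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys are the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

config_hash <- function(config) {
  # stable content hash without extra dependencies: serialize the
  # analytic fields (the output location does not change the analysis)
  fields <- config[setdiff(sort(names(config)), "out_dir")]
  raw <- serialize(fields, NULL, version = 2)
  sprintf("%08x", sum(as.numeric(raw) * (seq_along(raw) %% 251)) %% .Machine$integer.max)
}

#' Run the full replacement-prioritization pipeline
#'
#' Stages: load or build the decision matrix; compute COWA weights from
#' the expert panel (when given), PCA weights from the matrix, and
#' their game-theoretic combination; rank with GRA, TOPSIS, GRA-TOPSIS
#' and VIKOR under the combined weights; compute the Kendall-W
#' concordance of the GRA / TOPSIS / GRA-TOPSIS scores.  All artifacts
#' are written under `config$out_dir` (matrix.csv, cowa.json, pca.json,
#' game.json, ranking_<method>.json, concordance.json, run.json) and
#' stamped with the configuration hash; a stage failure aborts with the
#' stage name.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the matrix, weights, rankings,
#'   concordance and the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  hash <- config_hash(config)

  matrix <- stage("indicators", {
    if (!is.null(config$matrix_path)) {
      read_decision_matrix(config$matrix_path)
    } else {
      build_decision_matrix(read_profiles(config$profile_path),
                            read_exams(config$exams_path))
    }
  })
  write_decision_matrix(matrix, file.path(config$out_dir, "matrix.csv"))

  pca <- stage("pca_weights", pca_weights(matrix, retention = config$retention,
                                          threshold = config$retention_threshold))
  write_weights(pca, file.path(config$out_dir, "pca.json"))

  weights <- pca
  cowa <- NULL
  if (!is.null(config$panel_path)) {
    cowa <- stage("cowa_weights", cowa_weights(read_expert_panel(config$panel_path)))
    write_weights(cowa, file.path(config$out_dir, "cowa.json"))
    weights <- stage("game_weights", combine_weights(cowa, pca))
    write_weights(weights, file.path(config$out_dir, "game.json"))
  }

  rankings <- stage("ranking", list(
    gra = rank_gra(matrix, weights, rho = config$rho,
                   gray_degree_weighting = config$gray_degree_weighting),
    topsis = rank_topsis(matrix, weights),
    gra_topsis = rank_gra_topsis(matrix, weights, rho = config$rho,
                                 alpha1 = config$alpha1, alpha2 = config$alpha2,
                                 orientation = config$orientation,
                                 gray_degree_weighting = config$gray_degree_weighting),
    vikor = rank_vikor(matrix, weights, v = config$v)
  ))
  for (nm in names(rankings)) {
    write_ranking(rankings[[nm]], file.path(config$out_dir, sprintf("ranking_%s.json", nm)))
  }

  conc <- stage("concordance", {
    sc <- cbind(GRA = rankings$gra$score, TOPSIS = rankings$topsis$score,
                `GRA-TOPSIS` = rankings$gra_topsis$score)
    rownames(sc) <- rankings$gra$equipment_id
    kendall_w(sc)
  })
  jsonlite::write_json(
    list(W = conc$W, chi2 = conc$chi2, df = conc$df, p_value = conc$p_value,
         rank_averages = as.list(conc$rank_averages),
         medians = as.list(conc$medians), config_hash = hash),
    file.path(config$out_dir, "concordance.json"), auto_unbox = TRUE, digits = NA
  )

  jsonlite::write_json(
    c(config[!vapply(config, is.null, logical(1))], list(config_hash = hash)),
    file.path(config$out_dir, "run.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(list(matrix = matrix, weights = list(cowa = cowa, pca = pca, combined = weights),
                 rankings = rankings, concordance = conc, out_dir = config$out_dir,
                 config_hash = hash))
}
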