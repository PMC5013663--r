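#' Pipeline configuration
#'
#' Declarative configuration for an end-to-end run: where the rearing
#' records come from (CSV paths, or a [scenario_config()] to simulate),
#' where outputs go, the analysis toggles, and the seed. Unknown keys are
#' rejected so a config file round-trips losslessly.
#'
#' @param out_dir Output directory (created if needed).
#' @param training,validation Paths to rearing-record CSVs, or `NULL` when
#'   `simulate` is given.
#' @param design Path to a site-design CSV (`site_id, block_id,
#'   treatment`), or `NULL`.
#' @param simulate A `scenario_config` to generate the inputs.
#' @param seed Integer seed for any stochastic stage.
#' @param log_expected Log-transform expected rates in the parasitism
#'   model.
#' @param exclude_within_intraspecific Drop within-habitat conspecific
#'   terms from the expected rate.
#' @param binary Use the binarized metaweb for the dependence stage.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, training = NULL, validation = NULL,
                            design = NULL, simulate = NULL, seed = 1L,
                            log_expected = FALSE,
                            exclude_within_intraspecific = FALSE,
                            binary = FALSE) {
  if (is.null(simulate) && (is.null(training) || is.null(validation))) {
    stop_edgeweb("either record paths or a simulation config is required")
  }
  structure(list(out_dir = out_dir, training = training,
                 validation = validation, design = design,
                 simulate = simulate, seed = as.integer(seed),
                 log_expected = log_expected,
                 exclude_within_intraspecific = exclude_within_intraspecific,
                 binary = binary),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes build-metaweb, dependence, predict and validate in sequence,
#' writing every intermediate artifact plus a machine-readable manifest
#' (seed, package version, per-file digests, collected warnings, stage
#' timings) and returning the validation results. Identical config and
#' inputs produce identical outputs. A failing stage aborts with the stage
#' name and the last good artifact.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the run manifest and the fitted results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   package_version =
                     as.character(utils::packageVersion("edgeweb")),
                   stages = list(), files = list(), warnings = list())
  warn_bucket <- character(0)
  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop_edgeweb("pipeline stage '", name, "' failed: ",
                     conditionMessage(e),
                     "; last good artifacts: ",
                     paste(names(manifest$files), collapse = ", "))
      }),
      warning = function(w) {
        warn_bucket <<- c(warn_bucket,
                          paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    manifest$stages[[name]] <<- list(
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }
  add_file <- function(label, path) {
    manifest$files[[label]] <<- list(path = basename(path),
                                     md5 = unname(tools::md5sum(path)))
  }

  # stage 0: inputs
  inputs <- run_stage("ingest", {
    if (!is.null(config$simulate)) {
      scen <- generate_scenario(config$simulate)
      tr_path <- file.path(config$out_dir, "training_records.csv")
      va_path <- file.path(config$out_dir, "validation_records.csv")
      write_rearing_records(scen$training, tr_path)
      write_rearing_records(scen$validation, va_path)
      utils::write.csv(scen$design,
                       file.path(config$out_dir, "design.csv"),
                       row.names = FALSE, quote = FALSE)
      list(training = scen$training, validation = scen$validation,
           design = scen$design)
    } else {
      design <- if (!is.null(config$design)) {
        utils::read.csv(config$design, stringsAsFactors = FALSE)
      } else NULL
      list(training = read_rearing_records(config$training),
           validation = read_rearing_records(config$validation),
           design = design)
    }
  })
  if (!is.null(config$simulate)) {
    add_file("training_records",
             file.path(config$out_dir, "training_records.csv"))
    add_file("validation_records",
             file.path(config$out_dir, "validation_records.csv"))
    add_file("design", file.path(config$out_dir, "design.csv"))
  }

  # stage 1: metaweb
  metaweb <- run_stage("build-metaweb", {
    w <- build_web(inputs$training, dataset = "training")
    if (config$binary) w <- binarize_web(w)
    write_web(w, file.path(config$out_dir, "metaweb.csv"))
    w
  })
  add_file("metaweb", file.path(config$out_dir, "metaweb.csv"))

  # stage 2: dependence
  dep <- run_stage("dependence", {
    d <- dependence_matrix(metaweb)
    idx <- which(d$values > 0, arr.ind = TRUE)
    long <- data.frame(
      host_i = d$hosts$taxon[idx[, 1]], habitat_A = d$hosts$habitat[idx[, 1]],
      host_j = d$sources$taxon[idx[, 2]],
      habitat_B = d$sources$habitat[idx[, 2]],
      d = d$values[idx])
    long <- long[order(long$host_i, long$habitat_A, long$host_j,
                       long$habitat_B, method = "radix"), , drop = FALSE]
    utils::write.csv(long, file.path(config$out_dir, "dependence.csv"),
                     row.names = FALSE, quote = FALSE)
    d
  })
  add_file("dependence", file.path(config$out_dir, "dependence.csv"))

  # stage 3: predictions
  table <- run_stage("predict", {
    panels <- site_panels(inputs$validation, inputs$design)
    tab <- assemble_prediction_table(
      dep, panels,
      exclude_within_intraspecific = config$exclude_within_intraspecific,
      quiet = TRUE)
    write_prediction_table(tab,
                           file.path(config$out_dir, "predictions.csv"))
    attr(tab, "panels") <- panels
    tab
  })
  add_file("predictions", file.path(config$out_dir, "predictions.csv"))

  # stage 4: validation statistics
  results <- run_stage("validate", {
    panels <- attr(table, "panels")
    baci <- baci_abundance_test(panels)
    parasitism <- fit_prediction_model(
      table, predictors = c("E", "habitat", "treatment"),
      log_expected = config$log_expected)
    abund <- abundance_change_model(table)
    anova <- tryCatch(dependence_anova(dependence_matrix(metaweb)),
                      error = function(e) NULL)
    report <- list(
      baci = list(interaction = baci$interaction, aic = baci$aic),
      parasitism = list(
        selected = parasitism$selected$label,
        coefficients = parasitism$selected$coefficients,
        aic = parasitism$selected$aic,
        r2 = as.list(parasitism$selected$r2),
        overdispersion = parasitism$selected$overdispersion[
          c("ratio", "p")],
        pcv = as.list(parasitism$selected$pcv)),
      abundance_change = list(
        selected = abund$selected$label,
        coefficients = abund$selected$coefficients,
        r2_multiple = abund$selected$r2_multiple),
      dependence_anova = if (!is.null(anova))
        list(letters = as.list(anova$letters),
             group_n = anova$group_n) else NULL)
    jsonlite::write_json(report,
                         file.path(config$out_dir, "model_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    list(baci = baci, parasitism = parasitism, abundance_change = abund,
         dependence_anova = anova)
  })
  add_file("model_report", file.path(config$out_dir, "model_report.json"))

  manifest$warnings <- as.list(warn_bucket)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(manifest = manifest, results = results,
                 metaweb = metaweb, dependence = dep, table = table))
}
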