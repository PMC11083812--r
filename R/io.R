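#' Read factor definitions from a YAML/JSON file
#'
#' The file holds a `factors:` list of `name`/`low`/`high`/`units` entries.
#'
#' @param path Path to a YAML (or JSON) factor file.
#' @return List of [bbd_factor()] objects.
#' @export
read_factors <- function(path) {
  spec <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                           simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(spec$factors)) spec <- spec$factors
  facs <- lapply(spec, function(f)
    bbd_factor(f$name, f$low, f$high, f$units %||% ""))
  stats::setNames(facs, vapply(facs, `[[`, character(1), "name"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a design table from CSV
#'
#' Expects a header `run,<factor columns>[,<response columns>]` with factor
#' settings in actual units; settings are converted to coded units against
#' the supplied factor definitions.  Runs whose coded settings are all zero
#' are marked as center replicates.
#'
#' @param path CSV path.
#' @param factors List of [bbd_factor()] objects or the path to a factor
#'   file for [read_factors()].
#' @return A `"bbd_design"` with any response columns attached.
#' @export
read_design_csv <- function(path, factors) {
  if (is.character(factors)) factors <- read_factors(factors)
  nms <- vapply(factors, `[[`, character(1), "name")
  names(factors) <- nms
  df <- utils::read.csv(path, check.names = FALSE)
  if (!nrow(df)) stop("design file is empty", call. = FALSE)
  if (!all(c("run", nms) %in% names(df)))
    stop("design CSV must have columns run, ",
         paste(nms, collapse = ", "), call. = FALSE)
  coded <- vapply(nms, function(nm)
    to_coded(factors[[nm]], df[[nm]]), numeric(nrow(df)))
  coded <- round(coded, 12)  # kill coding round-off from decimal actuals
  out <- data.frame(run = as.character(df$run), coded,
                    center = rowSums(abs(coded)) == 0,
                    stringsAsFactors = FALSE)
  for (nm in setdiff(names(df), c("run", nms))) out[[nm]] <- df[[nm]]
  structure(out, factors = factors, class = c("bbd_design", "data.frame"))
}

#' Write a design table to CSV
#'
#' Emits both actual and coded factor columns (`A`, `A_coded`, ...), the
#' center-replicate marker and any response columns, at full precision
#' (15 significant digits).
#'
#' @param design A [bbd_design()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  nms <- factor_names(design)
  act <- actual_settings(design)
  cod <- coded_settings(design)
  colnames(cod) <- paste0(nms, "_coded")
  out <- data.frame(run = design$run, act, cod, center = design$center,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in response_names(design)) out[[nm]] <- design[[nm]]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 15,
                                                   format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a release time course from CSV
#'
#' Auto-detects the schema from the header: `time_h,conc_mg_per_ml`
#' (measured aliquot concentrations; converted to cumulative percent via
#' [cumulative_release()] with the supplied vessel parameters) or
#' `time_h,cr_percent` (already cumulative).
#'
#' @param path CSV path.
#' @param Ve,Vo,m Vessel parameters, required for the concentration schema.
#' @return Data frame with `t` (hours) and `cr` (cumulative percent).
#' @export
read_release_csv <- function(path, Ve = NULL, Vo = NULL, m = NULL) {
  df <- utils::read.csv(path)
  if (all(c("time_h", "cr_percent") %in% names(df)))
    return(data.frame(t = df$time_h, cr = df$cr_percent))
  if (all(c("time_h", "conc_mg_per_ml") %in% names(df))) {
    if (is.null(Ve) || is.null(Vo) || is.null(m))
      stop("vessel parameters Ve, Vo, m are required for concentration data",
           call. = FALSE)
    ord <- order(df$time_h)
    df <- df[ord, ]
    return(data.frame(t = df$time_h,
                      cr = cumulative_release(df$conc_mg_per_ml, Ve, Vo, m)))
  }
  stop("unrecognized release CSV header: expected time_h with ",
       "conc_mg_per_ml or cr_percent", call. = FALSE)
}

# ---- packaged fixtures -----------------------------------------------------

slnopt_extdata <- function(file)
  system.file("extdata", file, package = "slnopt", mustWork = TRUE)

#' The packaged CBD solid-lipid-nanoparticle Box-Behnken study
#'
#' `cbd_sln_design()` returns the published 15-run Box-Behnken design of the
#' CBD-SLN formulation study (factors: glyceryl monostearate 1.5-2.5 g,
#' polysorbate 80 0.6-1.0 g, methanolic CBD 10-20 mg) with the four measured
#' responses: Y1 particle size (nm), Y2 polydispersity index, Y3
#' encapsulation efficiency (%), Y4 drug loading (%).
#' `cbd_sln_validation()` returns the study's confirmation-run table:
#' software-predicted and observed response values at the optimized
#' formulation (coded settings A = -0.8, B = -0.9, C = +1).
#'
#' @return A `"bbd_design"` (design) or data frame (validation).
#' @examples
#' des <- cbd_sln_design()
#' reduce_model(des, "Y3")$terms
#' @export
cbd_sln_design <- function() {
  read_design_csv(slnopt_extdata("cbd_sln_bbd.csv"),
                  slnopt_extdata("cbd_sln_factors.yaml"))
}

#' @rdname cbd_sln_design
#' @export
cbd_sln_validation <- function() {
  utils::read.csv(slnopt_extdata("cbd_sln_validation.csv"))
}

# ---- pipeline configuration ------------------------------------------------

config_known_keys <- c("factors", "responses", "alpha", "release",
                       "thresholds", "assay", "seed", "goal_anchors")

#' Load and validate a pipeline configuration
#'
#' The configuration (YAML or an equivalent list) declares the factor
#' definitions, per-response term sets (`auto` delegates to
#' [reduce_model()]) and desirability goals, release vessel parameters,
#' colloidal thresholds and the seed.  Unknown top-level keys are rejected.
#'
#' @param config Path to a YAML file, or a list with the same structure.
#' @return Validated configuration list of class `"slnopt_config"`.
#' @export
read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  unknown <- setdiff(names(config), config_known_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (key in c("factors", "responses"))
    if (is.null(config[[key]]))
      stop(sprintf("config key '%s' is required", key), call. = FALSE)
  config$factors <- lapply(config$factors, function(f) {
    for (fld in c("name", "low", "high"))
      if (is.null(f[[fld]]))
        stop(sprintf("config factors: field '%s' missing", fld),
             call. = FALSE)
    f
  })
  for (nm in names(config$responses)) {
    r <- config$responses[[nm]]
    if (is.null(r$goal) ||
        !r$goal %in% c("minimize", "maximize", "target", "in_range"))
      stop(sprintf("config responses.%s: 'goal' must be one of minimize/",
                   nm), "maximize/target/in_range", call. = FALSE)
  }
  config$alpha <- config$alpha %||% 0.05
  config$seed <- config$seed %||% 1
  structure(config, class = c("slnopt_config", "list"))
}

config_factors <- function(config) {
  facs <- lapply(config$factors, function(f)
    bbd_factor(f$name, f$low, f$high, f$units %||% ""))
  stats::setNames(facs, vapply(facs, `[[`, character(1), "name"))
}

# ---- pipeline --------------------------------------------------------------

#' Run the full formulation-optimization pipeline
#'
#' Executes, from a configuration and a measured design table: model fitting
#' (or backward reduction) per response, desirability optimization over the
#' coded cube, prediction-interval validation against supplied confirmation
#' data, and optionally release-kinetics fitting and plate-assay
#' summarization.  The report is returned as a list and, when `out_dir` is
#' given, written as `report.json` (full precision) plus `report.txt`
#' (tables formatted in the style of a formulation paper).
#'
#' @param config Path to a YAML config or a list (see [read_config()]).
#' @param design_csv Path to the design/response CSV, or a ready
#'   [bbd_design()].
#' @param release_csv Optional release time-course CSV path(s), named by
#'   sample.
#' @param assay_csv Optional long-format plate CSV path.
#' @param validation Optional data frame or CSV path with columns
#'   `response`, `observed` and optionally `predicted` (external software
#'   predictions; when present, percent error is computed against them,
#'   otherwise against this package's model predictions at the optimum).
#' @param out_dir Optional output directory for `report.json`/`report.txt`.
#' @return The report list, invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(config, design_csv, release_csv = NULL,
                         assay_csv = NULL, validation = NULL,
                         out_dir = NULL) {
  config <- read_config(config)
  facs <- config_factors(config)
  design <- if (inherits(design_csv, "bbd_design")) design_csv
  else read_design_csv(design_csv, facs)

  fits <- list(); goals <- list()
  for (nm in names(config$responses)) {
    r <- config$responses[[nm]]
    terms <- r$terms %||% "auto"
    fit <- if (identical(terms, "auto"))
      reduce_model(design, nm, alpha = config$alpha)
    else fit_rsm(design, nm, unlist(terms))
    y <- check_response(design, nm)
    goals[[nm]] <- desirability_goal(
      nm, r$goal,
      low = r$low %||% min(y), high = r$high %||% max(y),
      target = r$target, weight = r$weight %||% 1,
      importance = r$importance %||% 1,
      hard_max = r$hard_max, hard_min = r$hard_min)
    fits[[nm]] <- fit
  }

  opt <- optimize_desirability(fits, unname(goals), seed = config$seed)

  report <- list(
    config = unclass(config),
    models = lapply(fits, rsm_fit_report),
    optimum = opt[c("coded", "actual", "actual_rounded", "predicted",
                    "desirability", "D")]
  )

  if (!is.null(validation)) {
    if (is.character(validation)) validation <- utils::read.csv(validation)
    obs <- stats::setNames(validation$observed, validation$response)
    val <- validate_optimum(fits[validation$response], opt$coded, obs)
    if ("predicted" %in% names(validation)) {
      val$predicted_external <- validation$predicted
      val$pct_error <- percent_error(val$observed, validation$predicted)
    }
    report$validation <- val
  }

  if (!is.null(release_csv)) {
    rl <- config$release %||% list()
    paths <- if (is.list(release_csv) || length(release_csv) > 1)
      release_csv else list(release = release_csv)
    report$release <- lapply(paths, function(p) {
      dat <- read_release_csv(p, rl$Ve, rl$Vo, rl$m)
      keep <- dat$t > 0
      fits <- fit_all_kinetics(dat$t[keep], dat$cr[keep])
      best <- select_model(fits)
      list(table = kinetics_report(fits), best_model = best$model,
           best_parameters = as.list(best$parameters),
           mechanism = best$mechanism)
    })
  }

  if (!is.null(assay_csv)) {
    plate <- utils::read.csv(assay_csv)
    stim <- (config$assay %||% list())$stimulated %||% "stimulated"
    report$assay <- summarize_plate(plate, stimulated = stim)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         force = TRUE, pretty = TRUE)
    writeLines(format_pipeline_report(report),
               file.path(out_dir, "report.txt"))
    return(invisible(report))
  }
  report
}

# plain-text rendering, decimal places mirroring formulation-paper tables
format_pipeline_report <- function(report) {
  out <- c("Formulation optimization report", "")
  for (m in report$models)
    out <- c(out, m$equation,
             sprintf("  R2 = %.4f, adj R2 = %.4f, pred R2 = %.4f",
                     m$r_squared, m$adj_r_squared, m$pred_r_squared))
  o <- report$optimum
  out <- c(out, "", sprintf("Optimum (D = %.4f):", o$D),
           paste("  ", paste(sprintf("%s = %g", names(o$actual_rounded),
                                     o$actual_rounded), collapse = ", ")))
  if (!is.null(report$validation)) {
    v <- report$validation
    out <- c(out, "", "Validation (predicted vs observed):",
             sprintf("  %s: predicted %.4g [%.4g, %.4g], observed %.4g, %% error %.2f",
                     v$response, v$predicted, v$pi_low, v$pi_high,
                     v$observed, v$pct_error))
  }
  for (nm in names(report$release)) {
    r <- report$release[[nm]]
    out <- c(out, "", sprintf("Release kinetics (%s): best model %s (%s)",
                              nm, r$best_model, r$mechanism),
             utils::capture.output(print(r$table, row.names = FALSE,
                                         digits = 5)))
  }
  if (!is.null(report$assay))
    out <- c(out, "", "Assay summary:",
             utils::capture.output(print(report$assay, row.names = FALSE,
                                         digits = 4)))
  out
}
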