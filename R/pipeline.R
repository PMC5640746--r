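# End-to-end study replica: simulate (or ingest) the survey tables, build
# one clinical network per network id under the chosen rule, compute the
# metric and correlation tables, score patients, fit the Model-1 bivariate
# and Model-2 stepwise regressions for continuity and the SIX models, and
# bundle everything with a run manifest. The two sensitivity variants
# (often-only threshold; full-matrix scope) are the same run under a
# different build rule.

default_model_metrics <- function() {
  c("n_services", "comp_social_services", "dissimilarity",
    "centralization", "clustering", "density",
    "coleman_primary_care", "coleman_crisis_outreach",
    "coleman_social_rehab", "coleman_psychiatric_ward")
}

#' Run the full study pipeline
#'
#' Orchestrates simulate/ingest, network construction, metrics,
#' correlations, patient scoring and (optionally) the outcome models, and
#' returns an output bundle with a run manifest. Passing a
#' \code{\link{sim_config}} simulates the study at \code{seed}; passing a
#' list with \code{services}, \code{ties} and \code{patients} (data frames
#' or CSV paths) analyses existing data.
#'
#' @param input A \code{\link{sim_config}}, or a list with elements
#'   \code{services}, \code{ties}, \code{patients}.
#' @param seed Integer seed used for simulation.
#' @param threshold,scope Build rule; see \code{\link{build_network}}. The
#'   main analysis uses sometimes-or-often ties among participants only.
#' @param outcomes Continuity outcome columns to model.
#' @param model_metrics Network metrics entered in the models; defaults to
#'   \code{default_model_metrics()}, dropping any that are undefined or
#'   constant across the built networks (recorded in the manifest).
#' @param fit_models Fit the regression stages (set \code{FALSE} for
#'   structure-only runs, e.g. sensitivity build checks).
#' @param subscale_map ACSS subscale map for scoring.
#' @param out_dir Optional directory: writes the survey tables, metrics,
#'   summary, correlation, model tables, per-network GraphML files and the
#'   manifest (as YAML).
#' @return A list of class \code{carenets_bundle}: \code{manifest},
#'   \code{networks}, \code{metrics} (a \code{\link{metrics_table}}),
#'   \code{correlations}, \code{patient_table}, \code{patients} (scored),
#'   \code{continuity_models}, \code{six_models}, \code{model_table}
#'   (rendered rows from \code{\link{render_model_tables}}).
#' @export
run_study <- function(input = sim_config(), seed = 1L,
                      threshold = c("sometimes_or_often", "often_only"),
                      scope = c("participants_only", "full_matrix"),
                      outcomes = c("acss_total", "acss_relational_base"),
                      model_metrics = default_model_metrics(),
                      fit_models = TRUE,
                      subscale_map = default_subscale_map(),
                      out_dir = NULL) {
  threshold <- match.arg(threshold)
  scope <- match.arg(scope)
  stage <- "input"
  on_fail <- function(e) stop("pipeline failed at stage '", stage, "': ",
                              conditionMessage(e), call. = FALSE)
  tryCatch({
    if (inherits(input, "carenets_config")) {
      study <- generate_study(input, seed = seed)
      services <- study$services; ties_raw <- study$ties
      patients <- study$patients
      simulated <- TRUE
    } else {
      load_tab <- function(x, reader) if (is.character(x)) reader(x) else x
      services <- validate_roster(load_tab(input$services, read_roster))
      ties_raw <- load_tab(input$ties, function(p)
        read_ties(p, services, strict = FALSE))
      patients <- validate_patients(load_tab(input$patients, read_patients))
      simulated <- FALSE
    }
    if (!"complete" %in% names(patients))
      patients <- validate_patients(patients)

    stage <- "network_build"
    net_ids <- unique(services$network_id)
    networks <- lapply(net_ids, function(nid) {
      ros <- services[services$network_id == nid, ]
      tie <- ties_raw[ties_raw$network_id == nid, ]
      if (!"freq_code" %in% names(tie)) tie <- validate_ties(tie, ros)
      build_network(ros, tie, threshold = threshold, scope = scope)
    })

    stage <- "network_metrics"
    mt <- metrics_table(networks)
    usable <- model_metrics[vapply(model_metrics, function(m) {
      v <- mt$metrics[[m]]
      !is.null(v) && !anyNA(v) && stats::sd(v) > 0
    }, TRUE)]
    dropped <- setdiff(model_metrics, usable)
    corr <- if (length(net_ids) >= 3L)
      correlation_matrix(mt, select = c("n_services", "dissimilarity",
                                        "centralization", "density",
                                        "clustering",
                                        intersect(usable,
                                                  grep("^coleman", usable,
                                                       value = TRUE))))
    else NULL

    stage <- "patient_scores"
    patients <- score_patients(patients, subscale_map)
    ptab <- outcome_table(patients)

    continuity_models <- list()
    six_models <- list()
    if (fit_models) {
      stage <- "continuity_models"
      for (oc in outcomes) {
        for (m in usable)
          continuity_models[[paste(oc, m, sep = ".")]] <-
            fit_continuity(patients, m, mt, outcome = oc)
        continuity_models[[paste(oc, "stepwise", sep = ".")]] <-
          suppressWarnings(
            fit_continuity_stepwise(patients, usable, mt, outcome = oc))
      }
      stage <- "six_models"
      for (m in usable)
        six_models[[paste("six", m, sep = ".")]] <-
          fit_six(patients, m, mt, stage = "bivariate")
      six_p <- vapply(usable, function(m) {
        f <- six_models[[paste("six", m, sep = ".")]]
        f$coefficients$p[f$coefficients$term == m]
      }, numeric(1))
      six_cand <- usable[!is.na(six_p) & six_p < 0.05]
      if (length(six_cand) > 0L)
        six_models[["six.multivariate"]] <-
          fit_six(patients, six_cand, mt, stage = "multivariate")
    }

    stage <- "render"
    model_table <- if (fit_models && length(c(continuity_models, six_models)))
      render_model_tables(c(continuity_models, six_models)) else NULL
    manifest <- list(
      seed = seed, simulated = simulated,
      build_rule = list(threshold = threshold, scope = scope),
      n_networks = length(net_ids),
      n_services = nrow(services),
      n_participants = sum(services$participated),
      n_patients = nrow(patients),
      n_analysis = sum(patients$complete),
      model_metrics = usable,
      dropped_metrics = dropped,
      outcomes = if (fit_models) outcomes else character(0),
      package_version = as.character(utils::packageVersion("carenets")),
      timestamp = format(Sys.time(), tz = "UTC"))

    bundle <- structure(
      list(manifest = manifest, networks = networks, metrics = mt,
           correlations = corr, patient_table = ptab, patients = patients,
           continuity_models = continuity_models, six_models = six_models,
           model_table = model_table),
      class = "carenets_bundle")
    if (!is.null(out_dir)) write_bundle(bundle, services, ties_raw, out_dir)
    bundle
  }, error = on_fail)
}

write_bundle <- function(bundle, services, ties, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_roster(services, file.path(dir, "services.csv"))
  write_ties(ties, file.path(dir, "ties.csv"))
  write_patients(bundle$patients, file.path(dir, "patients.csv"))
  files <- c("services.csv", "ties.csv", "patients.csv")
  utils::write.csv(bundle$metrics$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$metrics$summary,
                   file.path(dir, "metrics_summary.csv"), row.names = FALSE)
  files <- c(files, "metrics.csv", "metrics_summary.csv")
  if (!is.null(bundle$correlations)) {
    utils::write.csv(bundle$correlations$r, file.path(dir, "correlations.csv"))
    files <- c(files, "correlations.csv")
  }
  utils::write.csv(bundle$patient_table$stats,
                   file.path(dir, "patient_descriptives.csv"),
                   row.names = FALSE)
  files <- c(files, "patient_descriptives.csv")
  if (!is.null(bundle$model_table)) {
    render_model_tables(c(bundle$continuity_models, bundle$six_models),
                        file.path(dir, "model_tables.csv"))
    files <- c(files, "model_tables.csv")
  }
  for (nw in bundle$networks) {
    f <- paste0("network_", nw$network_id, ".graphml")
    write_graphml(nw, file.path(dir, f))
    files <- c(files, f)
  }
  manifest <- bundle$manifest
  manifest$files <- files
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @export
print.carenets_bundle <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<carenets_bundle: %d networks, %d services (%d participating), %d patients (%d complete)>\n",
    m$n_networks, m$n_services, m$n_participants, m$n_patients, m$n_analysis))
  cat("  rule:", m$build_rule$threshold, "/", m$build_rule$scope, "\n")
  cat("  models:", length(x$continuity_models), "continuity,",
      length(x$six_models), "SIX\n")
  invisible(x)
}

#' Compare two pipeline runs (sensitivity analysis)
#'
#' Side-by-side coefficient / odds-ratio deltas and significance flips (at
#' p < 0.05) between two bundles fitted on the same inputs under different
#' build rules, as reported in sensitivity analyses of tie dichotomization
#' and network scope.
#'
#' @param bundle_a,bundle_b Two \code{\link{run_study}} bundles with the
#'   same outcomes.
#' @return A data frame with one row per (outcome, stage, term) present in
#'   both bundles: estimates, delta (b - a), p-values and
#'   \code{significance_flip}.
#' @export
sensitivity_compare <- function(bundle_a, bundle_b) {
  ta <- bundle_a$model_table
  tb <- bundle_b$model_table
  if (is.null(ta) || is.null(tb))
    stop("both bundles must include fitted models", call. = FALSE)
  if (!setequal(unique(ta$outcome), unique(tb$outcome)))
    stop("bundles have mismatched outcome sets", call. = FALSE)
  ka <- ta[ta$row_type == "network_covariate", ]
  kb <- tb[tb$row_type == "network_covariate", ]
  merged <- merge(ka, kb, by = c("outcome", "stage", "term"),
                  suffixes = c("_a", "_b"))
  merged$delta <- merged$estimate_b - merged$estimate_a
  merged$significance_flip <- (merged$p_a < 0.05) != (merged$p_b < 0.05)
  merged[order(merged$outcome, merged$stage, merged$term),
         c("outcome", "stage", "term", "estimate_a", "estimate_b", "delta",
           "p_a", "p_b", "significance_flip")]
}
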