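# Regressions linking network-level exposures to patient outcomes, with a
# network random intercept throughout. Continuity of care (ACSS totals and
# subscales): linear mixed model (REML), standardized coefficients (outcome
# z-scored over the analysis set, network covariate z-scored over the
# distinct network values), Wald t tests with Satterthwaite df. Social
# integration (SIX, 0..6): random-intercept proportional-odds model, odds
# ratios, latent-scale ICC with within-variance pi^2/3. Model 1 enters each
# network covariate separately; Model 2 is a forward-stepwise (or forced)
# multivariate model over the Model-1-significant covariates. ICC p-values
# are likelihood-ratio tests on the variance component against a 50:50
# chi-square mixture.

CONTROLS <- c("age", "sex", "honos", "recruitment_service_type")

#' Network-level intra-class correlation
#'
#' Share of outcome variance at the network level,
#' \eqn{\sigma^2_{between} / (\sigma^2_{between} + \sigma^2_{within})}.
#' For latent-scale ordinal (logistic) models the within-network variance
#' is \eqn{\pi^2 / 3}.
#'
#' @param between Between-network variance component.
#' @param within Within-network (residual) variance; ignored when
#'   \code{ordinal = TRUE}.
#' @param ordinal Use the logistic latent-scale within variance.
#' @return A fraction in \[0, 1\].
#' @export
#' @examples
#' icc(1, 1)            # 0.5
#' icc(1, ordinal = TRUE)  # 1 / (1 + pi^2/3)
icc <- function(between, within = NULL, ordinal = FALSE) {
  if (ordinal) within <- pi^2 / 3
  if (is.null(within)) stop("within variance required", call. = FALSE)
  if (between < 0 || within < 0)
    stop("variance components must be non-negative", call. = FALSE)
  if (between + within == 0)
    stop("ICC undefined: both variance components are zero", call. = FALSE)
  between / (between + within)
}

# Merge network metric columns onto the patient analysis set, z-scoring
# each metric over the distinct network values (each network counts once).
merge_metrics <- function(patients, metric_names, metrics) {
  if (inherits(metrics, "carenets_metrics")) metrics <- metrics$metrics
  x <- if ("complete" %in% names(patients))
    patients[patients$complete, ] else patients
  if (!all(x$network_id %in% metrics$network_id))
    stop("metrics missing for some patient network(s)", call. = FALSE)
  ix <- match(x$network_id, metrics$network_id)
  for (nm in metric_names) {
    v <- metrics[[nm]]
    if (is.null(v)) stop("unknown metric: ", nm, call. = FALSE)
    if (anyNA(v[unique(ix)]))
      stop("metric ", nm, " undefined for some network(s)", call. = FALSE)
    s <- stats::sd(v[metrics$network_id %in% unique(x$network_id)])
    if (is.na(s) || s == 0)
      stop("metric ", nm, " constant across networks", call. = FALSE)
    x[[paste0("z_", nm)]] <- (v[ix] - mean(v)) / s
  }
  if (length(unique(x$network_id)) < 2L)
    stop("need at least 2 networks", call. = FALSE)
  x
}

new_fit <- function(outcome, stage, type, coefficients, icc, icc_p, aic,
                    n, n_networks, metric_terms, model = NULL,
                    note = NULL) {
  structure(list(outcome = outcome, stage = stage, type = type,
                 coefficients = coefficients, icc = icc, icc_p = icc_p,
                 aic = aic, n = n, n_networks = n_networks,
                 metric_terms = metric_terms, model = model, note = note),
            class = "carenets_fit")
}

#' @export
print.carenets_fit <- function(x, digits = 3, ...) {
  eff <- if (x$type == "linear") "std beta" else "odds ratio"
  cat(sprintf("<carenets_fit %s | %s | %s model, n = %d patients in %d networks>\n",
              x$outcome, x$stage, x$type, x$n, x$n_networks))
  cf <- x$coefficients
  cf$estimate <- round(cf$estimate, digits)
  cf$p <- signif(cf$p, 2)
  names(cf)[names(cf) == "estimate"] <- eff
  print(cf, row.names = FALSE)
  cat(sprintf("ICC (network level) = %.1f%% (p = %.3g); AIC = %.1f\n",
              100 * x$icc, x$icc_p, x$aic))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' @export
summary.carenets_fit <- function(object, ...) {
  print(object, ...)
}

#' @export
coef.carenets_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

lmm_formula <- function(terms) {
  stats::as.formula(paste(".y ~", paste(c(terms, CONTROLS), collapse = " + "),
                          "+ (1 | network_id)"))
}

fit_lmm <- function(data, metric_terms, outcome) {
  zt <- paste0("z_", metric_terms)
  fit <- lmerTest::lmer(lmm_formula(zt), data = data, REML = TRUE)
  smr <- stats::coef(summary(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s_net <- vc$vcov[vc$grp == "network_id"]
  s_res <- vc$vcov[vc$grp == "Residual"]

  # ICC p: LRT of the variance component, ML, 50:50 chi-square mixture
  ml <- stats::update(fit, REML = FALSE)
  fixed_only <- stats::lm(
    stats::as.formula(paste(".y ~", paste(c(zt, CONTROLS), collapse = " + "))),
    data = data)
  lrt <- max(0, 2 * (as.numeric(stats::logLik(ml)) -
                       as.numeric(stats::logLik(fixed_only))))
  icc_p <- 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)

  keep <- rownames(smr) != "(Intercept)"
  coefs <- data.frame(term = sub("^z_", "", rownames(smr)[keep]),
                      estimate = smr[keep, "Estimate"],
                      se = smr[keep, "Std. Error"],
                      p = smr[keep, "Pr(>|t|)"])
  rownames(coefs) <- NULL
  if (anyNA(coefs$estimate))
    stop("singular fit: dropped coefficient for ",
         paste(coefs$term[is.na(coefs$estimate)], collapse = ", "),
         call. = FALSE)
  list(coefs = coefs, icc = icc(s_net, s_res), icc_p = icc_p,
       aic = stats::AIC(ml), fit = fit)
}

#' Continuity-of-care regression (Model 1, bivariate)
#'
#' Linear random-intercept model of a continuity score on a single
#' standardized network metric plus the four patient-level controls (age,
#' sex, HoNOS, recruitment service type). The outcome is z-scored over the
#' analysis set and the metric over the distinct network values, so the
#' metric coefficient is a standardized beta. Fixed-effect p-values are
#' Wald t tests with Satterthwaite denominator degrees of freedom;
#' the ICC p-value is a variance-component likelihood-ratio test against a
#' 50:50 chi-square mixture; AIC is from the ML refit.
#'
#' @param patients Scored patient table (\code{\link{score_patients}});
#'   incomplete records are excluded.
#' @param metric Name of one network metric column.
#' @param metrics A \code{\link{metrics_table}} or its \code{metrics} frame.
#' @param outcome Outcome column; \code{"acss_total"} (default) or any
#'   scored subscale such as \code{"acss_relational_base"}.
#' @return A \code{carenets_fit} with standardized betas, ICC and AIC.
#' @export
fit_continuity <- function(patients, metric, metrics,
                           outcome = "acss_total") {
  stopifnot(length(metric) == 1L)
  x <- merge_metrics(patients, metric, metrics)
  if (!outcome %in% names(x)) stop("unknown outcome: ", outcome, call. = FALSE)
  x$.y <- as.numeric(scale(x[[outcome]]))
  res <- fit_lmm(x, metric, outcome)
  new_fit(outcome, "bivariate", "linear", res$coefs, res$icc, res$icc_p,
          res$aic, nrow(x), length(unique(x$network_id)), metric,
          model = res$fit)
}

#' Continuity-of-care regression (Model 2, stepwise multivariate)
#'
#' Screens each candidate network metric with the bivariate model
#' (\code{\link{fit_continuity}}); metrics with p < 0.05 enter forward
#' stepwise selection (entry p < 0.05 on the Wald t test, removal at
#' p >= 0.05, entry ties broken by smaller p then alphabetically). Controls
#' are always retained. With no significant candidate the controls-only
#' model is returned with a warning.
#'
#' @inheritParams fit_continuity
#' @param candidate_metrics Metric names to screen.
#' @return A \code{carenets_fit}; the bivariate screen is attached as
#'   attribute \code{"screen"}.
#' @export
fit_continuity_stepwise <- function(patients, candidate_metrics, metrics,
                                    outcome = "acss_total") {
  screen <- lapply(candidate_metrics, function(m)
    fit_continuity(patients, m, metrics, outcome))
  names(screen) <- candidate_metrics
  pvals <- vapply(screen, function(f)
    f$coefficients$p[f$coefficients$term == f$metric_terms], numeric(1))
  candidates <- candidate_metrics[!is.na(pvals) & pvals < 0.05]

  x <- merge_metrics(patients, candidate_metrics, metrics)
  x$.y <- as.numeric(scale(x[[outcome]]))
  fit_p <- function(terms) {
    res <- tryCatch(fit_lmm(x, terms, outcome), error = function(e) NULL)
    if (is.null(res)) return(NULL)
    res
  }
  sel <- forward_select(candidates, fit_p, pvals)
  if (length(sel$terms) == 0L) {
    warning("no candidate metric significant at 0.05; ",
            "returning controls-only model", call. = FALSE)
    res <- fit_controls_only(x, outcome)
  } else res <- sel$fit
  out <- new_fit(outcome, "stepwise", "linear", res$coefs, res$icc,
                 res$icc_p, res$aic, nrow(x),
                 length(unique(x$network_id)), sel$terms, model = res$fit)
  attr(out, "screen") <- screen
  out
}

fit_controls_only <- function(x, outcome) {
  fit <- lmerTest::lmer(
    stats::as.formula(paste(".y ~", paste(CONTROLS, collapse = " + "),
                            "+ (1 | network_id)")), data = x, REML = TRUE)
  smr <- stats::coef(summary(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  keep <- rownames(smr) != "(Intercept)"
  list(coefs = data.frame(term = rownames(smr)[keep],
                          estimate = smr[keep, "Estimate"],
                          se = smr[keep, "Std. Error"],
                          p = smr[keep, "Pr(>|t|)"]),
       icc = icc(vc$vcov[vc$grp == "network_id"],
                 vc$vcov[vc$grp == "Residual"]),
       icc_p = NA_real_, aic = stats::AIC(stats::update(fit, REML = FALSE)),
       fit = fit)
}

# Forward selection with p < 0.05 entry and p >= 0.05 removal on the
# candidate (metric) terms only. fit_fun(terms) returns the fitted result
# (with $coefs) or NULL on failure. screen_p orders tie-broken entry.
forward_select <- function(candidates, fit_fun, screen_p,
                           alpha_enter = 0.05, alpha_remove = 0.05) {
  candidates <- candidates[order(screen_p[candidates], candidates)]
  selected <- character(0)
  fit <- NULL
  repeat {
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0L) break
    best <- NULL; best_p <- Inf; best_fit <- NULL
    for (cand in remaining) {
      f <- fit_fun(c(selected, cand))
      if (is.null(f)) next
      p <- f$coefs$p[f$coefs$term == cand]
      if (length(p) == 1L && !is.na(p) && p < best_p) {
        best <- cand; best_p <- p; best_fit <- f
      }
    }
    if (is.null(best) || best_p >= alpha_enter) break
    selected <- c(selected, best)
    fit <- best_fit
    # backward check on previously entered terms
    repeat {
      pm <- fit$coefs[fit$coefs$term %in% selected, ]
      if (nrow(pm) == 0L || max(pm$p) < alpha_remove) break
      worst <- pm$term[which.max(pm$p)]
      selected <- setdiff(selected, worst)
      if (length(selected) == 0L) { fit <- NULL; break }
      fit <- fit_fun(selected)
      if (is.null(fit)) break
    }
    if (length(selected) == 0L) break
  }
  list(terms = selected, fit = fit)
}

#' Social-integration regression (SIX score)
#'
#' Random-intercept proportional-odds model of the SIX total (0..6) on one
#' or more standardized network metrics plus the four patient-level
#' controls, fitted by maximum likelihood with Gauss-Hermite quadrature
#' (\code{\link{polr_mixed}}). Reports one odds ratio per covariate
#' (odds of higher social integration), latent-scale ICC
#' \eqn{\sigma^2_u / (\sigma^2_u + \pi^2/3)} with a likelihood-ratio
#' mixture p-value, and AIC. \code{stage = "bivariate"} takes a single
#' metric; \code{"multivariate"} forces all supplied metrics in;
#' \code{"stepwise"} screens each metric bivariately at p < 0.05 and then
#' selects forward as in \code{\link{fit_continuity_stepwise}}.
#'
#' A per-category multinomial fit without random effects (the flag
#' \code{multinomial = TRUE}) is available for comparison; it returns the
#' raw \code{nnet::multinom} fit rather than a \code{carenets_fit}.
#'
#' @inheritParams fit_continuity
#' @param metric_names One or more network metric names.
#' @param stage \code{"bivariate"}, \code{"multivariate"} or
#'   \code{"stepwise"}.
#' @param nq Quadrature nodes.
#' @param multinomial Fit a plain multinomial logit instead (no random
#'   intercept).
#' @param icc_test Compute the likelihood-ratio p-value for the network
#'   variance component (a second, sigma = 0 fit); disable in large
#'   simulation loops that only need the estimates.
#' @return A \code{carenets_fit} with odds ratios (or the multinom fit).
#' @export
fit_six <- function(patients, metric_names, metrics,
                    stage = c("bivariate", "multivariate", "stepwise"),
                    nq = 15L, multinomial = FALSE, icc_test = TRUE) {
  stage <- match.arg(stage)
  if (stage == "bivariate") stopifnot(length(metric_names) == 1L)
  x <- merge_metrics(patients, metric_names, metrics)
  if (length(unique(x$six_total)) < 2L)
    stop("SIX outcome is constant", call. = FALSE)

  if (multinomial) {
    if (!requireNamespace("nnet", quietly = TRUE))
      stop("nnet not available", call. = FALSE)
    f <- stats::as.formula(paste("factor(six_total) ~",
      paste(c(paste0("z_", metric_names), CONTROLS), collapse = " + ")))
    return(nnet::multinom(f, data = x, trace = FALSE))
  }

  fit_terms <- function(terms) {
    rhs <- c(if (length(terms)) paste0("z_", terms), CONTROLS)
    X <- stats::model.matrix(
      stats::as.formula(paste("~", paste(rhs, collapse = " + "))),
      data = x)[, -1]
    full <- polr_mixed(x$six_total, X, x$network_id, nq = nq)
    icc_p <- NA_real_
    if (icc_test) {
      null <- polr_mixed(x$six_total, X, x$network_id, nq = nq,
                         fixed_sigma0 = TRUE)
      lrt <- max(0, 2 * (full$logLik - null$logLik))
      icc_p <- 0.5 * stats::pchisq(lrt, 1, lower.tail = FALSE)
    }
    coefs <- data.frame(term = sub("^z_", "", names(full$beta)),
                        estimate = exp(full$beta), se = full$se,
                        p = full$p)
    rownames(coefs) <- NULL
    list(coefs = coefs, icc = icc(full$sigma^2, ordinal = TRUE),
         icc_p = icc_p, aic = full$aic, fit = full)
  }

  if (stage == "stepwise") {
    screen_p <- vapply(metric_names, function(m) {
      f <- fit_terms(m)
      f$coefs$p[f$coefs$term == m]
    }, numeric(1))
    candidates <- metric_names[!is.na(screen_p) & screen_p < 0.05]
    sel <- forward_select(candidates,
                          function(tt) tryCatch(fit_terms(tt),
                                                error = function(e) NULL),
                          screen_p)
    if (length(sel$terms) == 0L) {
      warning("no candidate metric significant at 0.05; ",
              "returning controls-only model", call. = FALSE)
      terms <- character(0)
      res <- fit_terms(character(0))
    } else {
      res <- sel$fit
      terms <- sel$terms
    }
  } else {
    res <- fit_terms(metric_names)
    terms <- metric_names
  }
  new_fit("six_total", stage, "ordinal", res$coefs, res$icc, res$icc_p,
          res$aic, nrow(x), length(unique(x$network_id)), terms,
          model = res$fit)
}

#' Render fitted models as a report table
#'
#' Flattens one or more \code{carenets_fit} objects into the familiar
#' covariate-rows / estimate-and-p-columns layout with ICC and AIC footer
#' rows, and optionally writes it as CSV. Reading the CSV back reproduces
#' the numbers exactly.
#'
#' @param results A \code{carenets_fit} or list of them.
#' @param path Optional CSV output path.
#' @return A data frame with columns outcome, stage, row_type, term,
#'   estimate, p.
#' @export
render_model_tables <- function(results, path = NULL) {
  if (inherits(results, "carenets_fit")) results <- list(results)
  tab <- do.call(rbind, lapply(results, function(f) {
    rows <- data.frame(outcome = f$outcome, stage = f$stage,
                       row_type = ifelse(f$coefficients$term %in%
                                           f$metric_terms,
                                         "network_covariate", "control"),
                       term = f$coefficients$term,
                       estimate = f$coefficients$estimate,
                       p = f$coefficients$p)
    rbind(rows,
          data.frame(outcome = f$outcome, stage = f$stage,
                     row_type = "icc", term = "icc_network_level",
                     estimate = f$icc, p = f$icc_p),
          data.frame(outcome = f$outcome, stage = f$stage,
                     row_type = "aic", term = "aic",
                     estimate = f$aic, p = NA_real_))
  }))
  rownames(tab) <- NULL
  if (!is.null(path)) {
    utils::write.csv(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  }
  tab
}
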