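#' BACI test of the herbivore-reduction treatment
#'
#' Fits a Poisson GLMM (log link) with plantation-side caterpillar counts
#' (transect basis) as the response, summed per site and timestep, and
#' `collection` (before/after), `treatment` (control/reduction) and their
#' interaction as fixed effects. Sites are nested within spatial blocks as
#' random intercepts. A significantly negative collection-by-treatment
#' interaction is the signature of a successful reduction: treated
#' plantations drop more between timesteps than controls do.
#'
#' @param panels A list of `site_panel`s (see [site_panels()]).
#' @return A `fit_report` with an extra `$interaction` element
#'   (`estimate`, `z`, `p`).
#' @export
baci_abundance_test <- function(panels) {
  if (inherits(panels, "site_panel")) panels <- list(panels)
  rows <- lapply(panels, function(p) {
    d <- p$data[p$data$habitat == "P", , drop = FALSE]
    data.frame(site_id = p$site_id, block_id = p$block_id,
               treatment = p$treatment,
               collection = c("before", "after"),
               count = c(sum(d$n_transect_t), sum(d$n_transect_t1)),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$collection <- factor(df$collection, levels = c("before", "after"))
  df$treatment <- factor(df$treatment, levels = c("control", "reduction"))
  both <- tapply(df$treatment, df$block_id,
                 function(x) length(unique(x)) == 2)
  if (length(unique(df$treatment)) < 2 || sum(both, na.rm = TRUE) < 2) {
    stop_edgeweb("BACI test needs >= 2 blocks containing both treatments")
  }
  rep_ <- fit_candidate(c("collection", "treatment",
                          "collection:treatment"),
                        "(1 | block_id / site_id)", df, "poisson",
                        response = "count", label = "BACI abundance GLMM")
  if (is.null(rep_$fit)) {
    # degenerate data (e.g. a constant response) can defeat the mixed
    # estimator; fall back to the fixed-effects GLM and label it
    rep_ <- fit_candidate(c("collection", "treatment",
                            "collection:treatment"), "none", df, "poisson",
                          response = "count",
                          label = "BACI abundance GLM (fixed-effects fallback)")
    if (is.null(rep_$fit)) {
      stop_edgeweb("BACI model failed to fit: ", rep_$notes)
    }
    rep_$fallback <- TRUE
  }
  ct <- rep_$coefficients
  row <- ct[grepl("^collectionafter:treatmentreduction$", ct$term), ]
  rep_$interaction <- list(estimate = row$estimate, z = row$statistic,
                           p = row$p)
  rep_
}

random_structure_candidates <- function(full = TRUE) {
  # prefix chains of block/site/forest plus each factor singly, plus a
  # fixed-effects-only model; "forest" is the site-by-habitat cluster
  c("(1 | block_id / site_id / habitat)",
    "(1 | block_id / site_id)",
    "(1 | block_id)",
    "(1 | site_id)",
    "(1 | site_id:habitat)",
    "none")
}

prepare_prediction_data <- function(table, predictors, log_expected,
                                    positive_only) {
  df <- as.data.frame(table)
  df <- df[df$included, , drop = FALSE]
  if (positive_only) df <- df[df$events > 0, , drop = FALSE]
  rate_vars <- intersect(predictors,
                         c("E", "E_within", "E_cross", "E_noself", "I"))
  if (log_expected && length(rate_vars)) {
    for (v in rate_vars) {
      keep <- df[[v]] > 0
      df <- df[keep, , drop = FALSE]
    }
    for (v in rate_vars) df[[v]] <- log(df[[v]])
  }
  df$habitat <- factor(df$habitat, levels = c("N", "P"))
  df$treatment <- factor(df$treatment, levels = c("control", "reduction"))
  df
}

#' Fit and select the parasitism prediction model
#'
#' Tests whether expected parasitism rates predict observed ones with a
#' binomial (logit) GLMM: the response is (events, trials - events) at
#' `t+1`, and the full fixed structure is the requested predictors with all
#' interactions up to `max_order`. Selection follows the two-stage AIC
#' procedure: the optimal random structure is chosen first (chains of
#' forest within site within block, each factor singly, or none) with the
#' full fixed structure, then all marginality-consistent fixed
#' sub-structures compete under that random structure; within 2 AIC points
#' the simpler model wins. Because hypothesis tests are on partial
#' coefficients, a retained cross-habitat term indicates explanatory power
#' beyond within-habitat collinearity.
#'
#' Attaches Nakagawa-Schielzeth R2, percent change in variance against the
#' intercept-only model, and the Pearson overdispersion check to the
#' selected report.
#'
#' @param table A `prediction_table`.
#' @param predictors Character vector of fixed-effect terms; any of
#'   `"E"`, `"E_within"`, `"E_cross"`, `"E_noself"`, `"I"`, `"habitat"`,
#'   `"treatment"`.
#' @param log_expected Log-transform the rate predictors (rows with zero
#'   rates are then excluded rather than offset).
#' @param positive_only Restrict to rows with observed parasitism at `t+1`
#'   (used for the within/cross contrast, where a zero cannot be
#'   attributed to either habitat).
#' @param max_order Highest interaction order in the full model.
#' @param random_candidates Random-structure candidate strings; default
#'   [random_structure_candidates()].
#' @param within AIC window for the parsimony rule.
#' @return List with `reports` (all fixed-structure candidates under the
#'   selected random structure), `random_reports`, `selected` (a
#'   `fit_report` with `$r2`, `$pcv`, `$overdispersion`), and `data`.
#' @export
fit_prediction_model <- function(table,
                                 predictors = c("E", "habitat", "treatment"),
                                 log_expected = FALSE,
                                 positive_only = FALSE,
                                 max_order = length(predictors),
                                 random_candidates = NULL,
                                 within = 2) {
  df <- prepare_prediction_data(table, predictors, log_expected,
                                positive_only)
  if (nrow(df) < 5) stop_edgeweb("too few included rows to fit a model")
  response <- "cbind(events, trials - events)"
  full_fixed <- unlist(lapply(
    seq_len(min(max_order, length(predictors))),
    function(ord) vapply(utils::combn(predictors, ord, simplify = FALSE),
                         paste, "", collapse = ":")))
  random_candidates <- random_candidates %||% random_structure_candidates()

  random_reports <- lapply(random_candidates, function(r)
    fit_candidate(full_fixed, r, df, "binomial", response = response,
                  label = paste0("full fixed + ", r)))
  best_random <- aic_select(random_reports, within = within)$random

  fixed_sets <- hierarchical_term_sets(predictors, max_order)
  reports <- lapply(fixed_sets, function(fx)
    fit_candidate(fx, best_random, df, "binomial", response = response,
                  label = paste0(
                    if (length(fx)) paste(fx, collapse = " + ") else "1",
                    if (!identical(best_random, "none"))
                      paste0(" + ", best_random) else "")))
  selected <- aic_select(reports, within = within)

  selected <- attach_diagnostics(selected, df, response, "binomial",
                                 best_random)
  list(reports = reports, random_reports = random_reports,
       selected = selected, data = df)
}

attach_diagnostics <- function(selected, df, response, family, random) {
  selected$r2 <- tryCatch(nakagawa_r2(selected$fit),
                          error = function(e) c(marginal = NA_real_,
                                                conditional = NA_real_))
  selected$overdispersion <- tryCatch(overdispersion_check(selected$fit),
                                      error = function(e) NULL)
  if (!identical(random, "none") && inherits(selected$fit, "merMod")) {
    null_rep <- fit_candidate(character(0), random, df, family,
                              response = response, label = "intercept-only")
    if (!is.null(null_rep$fit)) {
      selected$pcv <- tryCatch(pcv(selected$fit, null_rep$fit),
                               error = function(e) NULL)
      selected$null_report <- null_rep
    }
  }
  selected
}

#' Model of abundance change against expected parasitism
#'
#' Regresses the change in host abundance (`dN`, transect basis) on the
#' expected parasitism rate plus habitat and treatment. The full mixed
#' model (forest within site within block) is attempted first; when the
#' estimated random variances are (numerically) zero the model reduces to
#' an ordinary linear model and fixed structures are AIC-selected among
#' marginality-consistent candidates. Under apparent competition the `E`
#' slope is negative: hosts predicted to be attacked more decline more.
#'
#' @param table A `prediction_table`.
#' @param predictors Fixed-effect terms (default `E`, `habitat`,
#'   `treatment`).
#' @param max_order Highest interaction order in the full model.
#' @param within AIC window for the parsimony rule.
#' @return List with `reports`, `selected` (multiple R-squared attached for
#'   linear models as `$r2_multiple`), `mixed_attempt` (the full mixed
#'   fit), and `data`.
#' @export
abundance_change_model <- function(table,
                                   predictors = c("E", "habitat",
                                                  "treatment"),
                                   max_order = 2, within = 2) {
  df <- as.data.frame(table)
  df <- df[df$included, , drop = FALSE]
  if (nrow(df) < 5) stop_edgeweb("too few included rows to fit a model")
  df$habitat <- factor(df$habitat, levels = c("N", "P"))
  df$treatment <- factor(df$treatment, levels = c("control", "reduction"))
  full_fixed <- unlist(lapply(
    seq_len(min(max_order, length(predictors))),
    function(ord) vapply(utils::combn(predictors, ord, simplify = FALSE),
                         paste, "", collapse = ":")))
  mixed <- fit_candidate(full_fixed, "(1 | block_id / site_id / habitat)",
                         df, "gaussian", response = "dN",
                         label = "full mixed model")
  use_lm <- TRUE
  if (!is.null(mixed$fit)) {
    vc <- vapply(lme4::VarCorr(mixed$fit), function(v) sum(diag(v)), 0)
    resid_var <- stats::sigma(mixed$fit)^2
    use_lm <- all(vc < max(1e-8, 1e-6 * resid_var))
  }
  if (use_lm) {
    fixed_sets <- hierarchical_term_sets(predictors, max_order)
    reports <- lapply(fixed_sets, function(fx)
      fit_candidate(fx, "none", df, "gaussian", response = "dN",
                    label = if (length(fx)) paste(fx, collapse = " + ")
                            else "1"))
    selected <- aic_select(reports, within = within)
    selected$r2_multiple <-
      suppressWarnings(summary(selected$fit)$r.squared)
    selected$diagnostics <- list(
      shapiro_p = tryCatch(
        stats::shapiro.test(stats::residuals(selected$fit))$p.value,
        error = function(e) NA_real_),
      reduced_to_lm = TRUE)
  } else {
    fixed_sets <- hierarchical_term_sets(predictors, max_order)
    reports <- lapply(fixed_sets, function(fx)
      fit_candidate(fx, "(1 | block_id / site_id / habitat)", df,
                    "gaussian", response = "dN",
                    label = if (length(fx)) paste(fx, collapse = " + ")
                            else "1"))
    selected <- aic_select(reports, within = within)
    selected$r2 <- tryCatch(nakagawa_r2(selected$fit),
                            error = function(e) NULL)
    selected$diagnostics <- list(reduced_to_lm = FALSE)
  }
  list(reports = reports, selected = selected, mixed_attempt = mixed,
       data = df)
}

#' ANOVA of dependence magnitude by habitat pair
#'
#' Tests whether the magnitude of `log d` differs among the four ordered
#' habitat-pair classes (PP, PN, NP, NN - affected host's habitat first).
#' Only strictly positive dependences enter (the log is undefined
#' otherwise). Post-hoc pairwise comparisons use Tukey's HSD with compact
#' letter display.
#'
#' @param dep A full-pool, habitat-indexed `dependence_matrix`.
#' @param include_self Include conspecific (i = j) pairs (default `TRUE`).
#' @return List with `anova` (the ANOVA table), `posthoc` (Tukey
#'   contrasts), `letters` (compact letter display), `group_n`, and
#'   `data`.
#' @export
dependence_anova <- function(dep, include_self = TRUE) {
  stopifnot(inherits(dep, "dependence_matrix"))
  if (all(is.na(dep$pool_scope))) {
    stop_edgeweb("dependence ANOVA needs a habitat-indexed matrix")
  }
  idx <- which(dep$values > 0, arr.ind = TRUE)
  if (!include_self) {
    same <- dep$hosts$taxon[idx[, 1]] == dep$sources$taxon[idx[, 2]]
    idx <- idx[!same, , drop = FALSE]
  }
  df <- data.frame(
    habitat_pair = paste0(dep$hosts$habitat[idx[, 1]],
                          dep$sources$habitat[idx[, 2]]),
    log_d = log(dep$values[idx]), stringsAsFactors = FALSE)
  tab <- table(df$habitat_pair)
  dropped <- names(tab)[tab < 2]
  if (length(dropped)) {
    message("habitat-pair group(s) with < 2 values dropped: ",
            paste(dropped, collapse = ", "))
    df <- df[!df$habitat_pair %in% dropped, , drop = FALSE]
  }
  groups <- unique(df$habitat_pair)
  if (length(groups) < 2) {
    stop_edgeweb("need >= 2 habitat-pair groups with >= 2 values each")
  }
  if (nrow(df) - length(groups) < 1) {
    stop_edgeweb("no within-group degrees of freedom for the ANOVA")
  }
  df$habitat_pair <- factor(df$habitat_pair)
  fit <- stats::aov(log_d ~ habitat_pair, data = df)
  glht_fit <- multcomp::glht(fit,
                             linfct = multcomp::mcp(habitat_pair = "Tukey"))
  cld <- multcomp::cld(glht_fit)
  list(anova = summary(fit),
       posthoc = summary(glht_fit),
       letters = cld$mcletters$Letters,
       group_n = as.integer(tab[levels(df$habitat_pair)]),
       fit = fit, data = df)
}
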