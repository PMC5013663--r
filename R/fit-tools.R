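#' Fit reports
#'
#' Model fits throughout the validation stage are wrapped in a light
#' `fit_report` carrying the fitted object, the formula, coefficient table,
#' AIC, parameter count, convergence status, and (for mixed models) the
#' random-effects structure. Selection and diagnostics operate on these
#' reports rather than on raw fits so that fixed-effect GLMs and GLMMs can
#' compete in the same candidate set.
#'
#' @name fit_report
NULL

# Fit one candidate (glm, glmer or lmer depending on family/random part),
# capturing warnings so non-converged fits can be flagged and excluded from
# selection rather than raised.
fit_candidate <- function(fixed, random, data, family,
                          response = NULL, label = NULL) {
  fam <- if (is.character(family)) family else family$family
  rhs <- paste(fixed, collapse = " + ")
  if (rhs == "") rhs <- "1"
  warnings <- character(0)
  fit <- withCallingHandlers(
    tryCatch({
      if (is.null(random) || identical(random, "none")) {
        f <- stats::as.formula(paste(response, "~", rhs))
        if (fam == "gaussian") stats::lm(f, data = data)
        else stats::glm(f, data = data, family = family)
      } else {
        f <- stats::as.formula(paste(response, "~", rhs, "+", random))
        if (fam == "gaussian") {
          lme4::lmer(f, data = data, REML = FALSE,
                     control = lme4::lmerControl(calc.derivs = FALSE))
        } else {
          lme4::glmer(f, data = data, family = family,
                      control = lme4::glmerControl(calc.derivs = FALSE))
        }
      }
    }, error = function(e) e),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      # lme4 signals boundary (singular) fits as messages; a zero variance
      # estimate is a valid fit, so record it quietly
      invokeRestart("muffleMessage")
    })
  if (inherits(fit, "error")) {
    return(structure(list(fit = NULL, fixed = fixed, random = random,
                          family = fam, label = label,
                          converged = FALSE, aic = Inf, n_par = NA_integer_,
                          coefficients = NULL,
                          notes = conditionMessage(fit)),
                     class = "fit_report"))
  }
  converged <- TRUE
  if (inherits(fit, "merMod")) {
    msgs <- fit@optinfo$conv$lme4$messages
    if (!is.null(msgs) && any(grepl("failed to converge", msgs))) {
      converged <- FALSE
    }
    if (any(grepl("failed to converge|Model is nearly unidentifiable",
                  warnings))) {
      converged <- FALSE
    }
  }
  structure(list(fit = fit, fixed = fixed, random = random, family = fam,
                 label = label %||% paste0(rhs, if (!is.null(random) &&
                                                   !identical(random, "none"))
                   paste0(" + ", random) else ""),
                 converged = converged,
                 aic = tryCatch(stats::AIC(fit), error = function(e) Inf),
                 n_par = as.integer(attr(stats::logLik(fit), "df")),
                 coefficients = suppressWarnings(coef_table(fit)),
                 notes = if (length(warnings))
                   paste(warnings, collapse = "; ") else NULL),
            class = "fit_report")
}

coef_table <- function(fit) {
  s <- summary(fit)$coefficients
  out <- as.data.frame(s)
  nm <- colnames(s)
  names(out)[1:2] <- c("estimate", "se")
  stat_col <- grep("value$", nm)
  if (length(stat_col)) {
    names(out)[stat_col[1]] <- "statistic"
  }
  p_col <- grep("^Pr", nm)
  if (length(p_col)) names(out)[p_col[1]] <- "p"
  out$term <- rownames(s)
  rownames(out) <- NULL
  out[c("term", setdiff(names(out), "term"))]
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> %s [%s]%s\n", x$label, x$family,
              if (!x$converged) " (NOT converged)" else ""))
  cat(sprintf("  AIC %.2f, %s parameters\n", x$aic,
              if (is.na(x$n_par)) "?" else x$n_par))
  if (!is.null(x$coefficients)) {
    print(x$coefficients, digits = 3)
  }
  invisible(x)
}

#' Select a model by AIC with a parsimony rule
#'
#' The lowest-AIC converged report wins, except that every report within
#' `within` AIC points of the minimum competes and the one with the fewest
#' parameters is chosen (the parsimony rule). Residual ties break
#' deterministically: fewest random-effect terms first, then the
#' lexicographically first label, so selection is invariant to the order of
#' the candidate list.
#'
#' @param reports A list of `fit_report`s.
#' @param within AIC window for the parsimony rule (default 2).
#' @return The selected `fit_report`, with `$selected = TRUE`.
#' @export
aic_select <- function(reports, within = 2) {
  if (inherits(reports, "fit_report")) reports <- list(reports)
  ok <- Filter(function(r) isTRUE(r$converged) && is.finite(r$aic), reports)
  if (length(ok) == 0) {
    stop_edgeweb("no converged candidate models to select from")
  }
  aics <- vapply(ok, function(r) r$aic, 0)
  cand <- ok[aics <= min(aics) + within]
  n_par <- vapply(cand, function(r) as.numeric(r$n_par), 0)
  n_rand <- vapply(cand, function(r) {
    if (is.null(r$random) || identical(r$random, "none")) 0L
    else lengths(regmatches(r$random, gregexpr("\\|", r$random)))
  }, 0L)
  labels <- vapply(cand, function(r) r$label, "")
  pick <- order(n_par, n_rand, labels, method = "radix")[1]
  sel <- cand[[pick]]
  sel$selected <- TRUE
  sel
}

#' Nakagawa-Schielzeth R-squared for (generalized) mixed models
#'
#' Marginal R2 is the fixed-effect linear-predictor variance over the total
#' (fixed + summed random variances + distribution-specific variance +
#' residual variance for gaussian); conditional R2 adds the random
#' variances to the numerator. The distribution-specific variance is
#' `pi^2 / 3` for the binomial-logit family and `log(1 + 1/exp(b0))`
#' (log-normal approximation at the model intercept) for Poisson-log.
#'
#' Either pass a fitted model (`merMod`, `glm` or `lm`), or pass the
#' variance components directly (`var_fixed`, `var_random`, and
#' `var_resid` for gaussian) with a `family`.
#'
#' @param fit Optional fitted model.
#' @param family `"binomial"`, `"poisson"` or `"gaussian"`; taken from the
#'   fit when one is supplied.
#' @param var_fixed,var_random,var_resid Variance components for the
#'   component-form call; `var_random` may be a vector (one entry per
#'   random level) and is summed.
#' @return Named numeric vector `c(marginal = , conditional = )`.
#' @export
nakagawa_r2 <- function(fit = NULL, family = NULL, var_fixed = NULL,
                        var_random = NULL, var_resid = NULL) {
  if (inherits(fit, "fit_report")) fit <- fit$fit
  if (!is.null(fit)) {
    if (inherits(fit, "merMod")) {
      beta <- lme4::fixef(fit)
      X <- stats::model.matrix(fit)
      var_fixed <- stats::var(as.vector(X %*% beta))
      vc <- lme4::VarCorr(fit)
      var_random <- vapply(vc, function(v) sum(diag(v)), 0)
      fam <- stats::family(fit)$family
      if (fam == "gaussian") var_resid <- stats::sigma(fit)^2
      intercept <- unname(beta["(Intercept)"])
    } else {
      X <- stats::model.matrix(fit)
      var_fixed <- stats::var(as.vector(X %*% stats::coef(fit)))
      var_random <- 0
      fam <- if (inherits(fit, "glm")) stats::family(fit)$family
             else "gaussian"
      if (fam == "gaussian") {
        var_resid <- summary(fit)$sigma^2
      }
      intercept <- unname(stats::coef(fit)["(Intercept)"])
    }
    family <- fam
  } else {
    if (is.null(var_fixed) || is.null(var_random) || is.null(family)) {
      stop_edgeweb("supply either a fit or var_fixed + var_random + family")
    }
    intercept <- NULL
  }
  var_random_sum <- sum(var_random)
  var_dist <- switch(family,
    binomial = pi^2 / 3,
    poisson = {
      if (is.null(intercept)) {
        stop_edgeweb("poisson distribution-specific variance needs a fitted ",
                     "model (it depends on the intercept)")
      }
      log(1 + 1 / exp(intercept))
    },
    gaussian = {
      if (is.null(var_resid)) {
        stop_edgeweb("gaussian family needs var_resid")
      }
      var_resid
    },
    stop_edgeweb("unsupported family: ", family))
  denom <- var_fixed + var_random_sum + var_dist
  c(marginal = var_fixed / denom,
    conditional = (var_fixed + var_random_sum) / denom)
}

#' Percent change in variance components between two fits
#'
#' For each random-effect level shared by a full and a null
#' (intercept-only, same random structure) model, returns
#' `100 * (1 - var_full / var_null)`: how much of that level's variance the
#' fixed effects absorbed. A zero null variance makes the quantity
#' undefined and is reported as `NA`.
#'
#' @param full,null Fitted mixed models (or `fit_report`s) with identical
#'   random structures; alternatively named numeric vectors of variance
#'   components.
#' @return Named numeric vector of percent changes per level.
#' @export
pcv <- function(full, null) {
  comp <- function(x) {
    if (inherits(x, "fit_report")) x <- x$fit
    if (inherits(x, "merMod")) {
      vc <- lme4::VarCorr(x)
      vapply(vc, function(v) sum(diag(v)), 0)
    } else if (is.numeric(x)) {
      x
    } else {
      stop_edgeweb("pcv expects merMod fits or numeric variance vectors")
    }
  }
  vf <- comp(full)
  vn <- comp(null)
  if (!is.null(names(vf)) && !is.null(names(vn))) {
    common <- intersect(names(vn), names(vf))
    if (length(common) == 0 && length(vf) == length(vn)) {
      common <- names(vn)
      names(vf) <- names(vn)
    }
    vf <- vf[common]
    vn <- vn[common]
  }
  if (length(vf) != length(vn)) {
    stop_edgeweb("pcv requires identical random structures")
  }
  out <- ifelse(vn > 0, 100 * (1 - vf / vn), NA_real_)
  names(out) <- names(vn)
  out
}

#' Overdispersion check from Pearson residuals
#'
#' The ratio of the sum of squared Pearson residuals to the residual
#' degrees of freedom, with a chi-squared test. Ratios near 1 indicate a
#' well-specified count/binomial model; the working rule is ratio < 2 and a
#' non-significant test.
#'
#' @param fit A fitted `glm` or `merMod` (or a `fit_report`).
#' @return List with `ratio`, `chisq`, `df` and `p`.
#' @export
overdispersion_check <- function(fit) {
  if (inherits(fit, "fit_report")) fit <- fit$fit
  pr <- stats::residuals(fit, type = "pearson")
  rdf <- stats::df.residual(fit)
  if (is.na(rdf) || rdf <= 0) {
    stop_edgeweb("no residual degrees of freedom; overdispersion undefined")
  }
  chisq <- sum(pr^2)
  list(ratio = chisq / rdf, chisq = chisq, df = rdf,
       p = stats::pchisq(chisq, rdf, lower.tail = FALSE))
}

# Enumerate marginality-consistent fixed-effect structures: every subset of
# main effects and interactions (up to max_order) that contains all
# lower-order marginals of each retained interaction.
hierarchical_term_sets <- function(predictors, max_order = length(predictors)) {
  stopifnot(length(predictors) >= 1)
  terms <- character(0)
  for (ord in seq_len(min(max_order, length(predictors)))) {
    combs <- utils::combn(predictors, ord, simplify = FALSE)
    terms <- c(terms, vapply(combs, paste, "", collapse = ":"))
  }
  parts <- strsplit(terms, ":", fixed = TRUE)
  n <- length(terms)
  sets <- list(character(0))
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    chosen <- terms[idx]
    consistent <- all(vapply(idx, function(i) {
      p <- parts[[i]]
      if (length(p) == 1) return(TRUE)
      subs <- unlist(lapply(seq_len(length(p) - 1), function(k)
        vapply(utils::combn(p, k, simplify = FALSE), paste, "",
               collapse = ":")))
      all(subs %in% chosen)
    }, TRUE))
    if (consistent) sets <- c(sets, list(chosen))
  }
  sets
}
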