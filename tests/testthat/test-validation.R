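fake_report <- function(aic, n_par, label, random = "none",
                        converged = TRUE) {
  structure(list(aic = aic, n_par = n_par, label = label, random = random,
                 converged = converged),
            class = "fit_report")
}

test_that("AIC selection applies the two-point parsimony rule", {
  # within 2 points the simpler model wins
  sel <- aic_select(list(fake_report(100, 8, "complex"),
                         fake_report(101.5, 5, "simple")))
  expect_equal(sel$label, "simple")
  # beyond 2 points the lower AIC wins
  sel <- aic_select(list(fake_report(100, 8, "complex"),
                         fake_report(103, 5, "simple")))
  expect_equal(sel$label, "complex")
  # exact tie at equal complexity: lexicographic, order-invariant
  a <- fake_report(100, 5, "alpha")
  b <- fake_report(100, 5, "beta")
  expect_equal(aic_select(list(b, a))$label, "alpha")
  expect_equal(aic_select(list(a, b))$label, "alpha")
  # non-converged candidates never compete
  sel <- aic_select(list(fake_report(90, 3, "broken", converged = FALSE),
                         fake_report(100, 5, "sound")))
  expect_equal(sel$label, "sound")
  expect_error(aic_select(list(fake_report(90, 3, "broken",
                                           converged = FALSE))),
               "no converged")
})

test_that("Nakagawa R2 reproduces closed-form arithmetic", {
  r2 <- nakagawa_r2(var_fixed = 1, var_random = 1, family = "binomial")
  expect_equal(unname(r2["marginal"]), 1 / (2 + pi^2 / 3))
  expect_equal(unname(r2["conditional"]), 2 / (2 + pi^2 / 3))
  # no random variance: marginal equals conditional
  r2b <- nakagawa_r2(var_fixed = 2, var_random = 0, family = "binomial")
  expect_equal(unname(r2b["marginal"]), unname(r2b["conditional"]))
  # intercept-only fit: no fixed-effect variance, marginal 0
  df <- data.frame(y = rbinom(50, 1, 0.4))
  fit <- glm(y ~ 1, family = binomial, data = df)
  expect_equal(unname(nakagawa_r2(fit)["marginal"]), 0)
  # gaussian needs a residual variance and uses it in the denominator
  r2g <- nakagawa_r2(var_fixed = 1, var_random = 1, var_resid = 2,
                     family = "gaussian")
  expect_equal(unname(r2g["marginal"]), 0.25)
  expect_error(nakagawa_r2(var_fixed = 1, var_random = 0,
                           family = "gaussian"), "var_resid")
})

test_that("conditional R2 dominates marginal R2 on fitted mixed models", {
  set.seed(31)
  df <- data.frame(block = rep(1:8, each = 12), x = rnorm(96))
  df$y <- rbinom(96, 1, plogis(-0.5 + 0.8 * df$x + rnorm(8)[df$block]))
  fit <- lme4::glmer(y ~ x + (1 | block), data = df, family = binomial)
  r2 <- nakagawa_r2(fit)
  expect_gte(r2[["conditional"]], r2[["marginal"]])
  expect_true(all(r2 >= 0 & r2 <= 1))
})

test_that("percent change in variance follows its definition", {
  expect_equal(unname(pcv(full = 1, null = 2)), 50)
  expect_equal(unname(pcv(full = c(a = 1, b = 3), null = c(a = 1, b = 3))),
               c(0, 0))
  expect_true(is.na(pcv(full = c(a = 1), null = c(a = 0))))
  # a fixed effect that absorbs block differences shrinks the block-level
  # variance component
  set.seed(5)
  blocks <- rep(1:10, each = 10)
  shift <- rnorm(10, sd = 3)[blocks]
  df <- data.frame(y = shift + rnorm(100, sd = 0.5),
                   x = shift, block = blocks)
  full <- lme4::lmer(y ~ x + (1 | block), data = df, REML = FALSE)
  null <- lme4::lmer(y ~ 1 + (1 | block), data = df, REML = FALSE)
  expect_gt(unname(pcv(full, null)["block"]), 80)
})

test_that("overdispersion is detected and degenerate fits are refused", {
  set.seed(8)
  y_od <- rnbinom(300, mu = 5, size = 0.5)
  fit_od <- glm(y_od ~ 1, family = poisson)
  res <- overdispersion_check(fit_od)
  expect_gt(res$ratio, 2)
  expect_lt(res$p, 0.05)
  y_ok <- rpois(300, 5)
  res_ok <- overdispersion_check(glm(y_ok ~ 1, family = poisson))
  expect_lt(abs(res_ok$ratio - 1), 0.5)
  # saturated model: no residual degrees of freedom
  y <- rpois(4, 5)
  sat <- glm(y ~ factor(1:4), family = poisson)
  expect_error(overdispersion_check(sat), "degrees of freedom")
})

test_that("a deterministic linear relation is recovered exactly", {
  # dN = -3 * E with no noise: slope -3, multiple R2 = 1
  set.seed(2)
  tab <- data.frame(
    site_id = rep(sprintf("V%02d", 1:8), each = 6),
    block_id = rep(sprintf("B%02d", 1:4), each = 12),
    treatment = rep(c("control", "reduction"), each = 24),
    host_taxon = "H", habitat = rep(c("N", "P"), 24),
    E = runif(48, 0.05, 0.9))
  tab$dN <- -3 * tab$E
  tab$included <- TRUE
  res <- abundance_change_model(tab, predictors = "E")
  cf <- res$selected$coefficients
  expect_equal(cf$estimate[cf$term == "E"], -3, tolerance = 1e-8)
  expect_equal(res$selected$r2_multiple, 1, tolerance = 1e-8)
  expect_true(res$selected$diagnostics$reduced_to_lm)
})

test_that("a noisy negative abundance coupling yields a negative slope", {
  set.seed(3)
  recovered <- 0
  for (r in 1:5) {
    tab <- data.frame(
      site_id = rep(sprintf("V%02d", 1:16), each = 6),
      block_id = rep(sprintf("B%02d", 1:8), each = 12),
      treatment = rep(rep(c("control", "reduction"), each = 6), 8),
      host_taxon = "H", habitat = sample(c("N", "P"), 96, replace = TRUE),
      E = runif(96, 0, 0.8))
    tab$dN <- round(-8 * tab$E + rnorm(96, sd = 2))
    tab$included <- TRUE
    res <- abundance_change_model(tab)
    cf <- res$selected$coefficients
    slope <- cf$estimate[cf$term == "E"]
    if (length(slope) == 1 && slope < 0) recovered <- recovered + 1
  }
  expect_gte(recovered, 4)
})

test_that("habitat-pair ANOVA flags a shifted group with its own letter", {
  set.seed(12)
  n <- 60
  habs <- c("N", "P")
  hi <- sample(habs, n, TRUE)
  hj <- sample(habs, n, TRUE)
  vals <- matrix(0, n, n)
  diag_idx <- cbind(seq_len(n), sample(n))
  v <- rlnorm(n, -3, 0.5)
  v[hi == "P" & hj[diag_idx[, 2]] == "P"] <-
    v[hi == "P" & hj[diag_idx[, 2]] == "P"] * exp(2)
  vals[diag_idx] <- v
  dep <- fake_dependence(vals, hi, hj)
  res <- dependence_anova(dep)
  p <- res$anova[[1]][["Pr(>F)"]][1]
  expect_lt(p, 0.01)
  expect_false(res$letters[["PP"]] %in%
                 res$letters[setdiff(names(res$letters), "PP")])
})

test_that("the ANOVA refuses groups without within-group information", {
  vals <- matrix(0, 4, 4)
  diag(vals) <- rlnorm(4, -3, 0.5)
  dep <- fake_dependence(vals, c("N", "N", "P", "P"),
                         c("N", "P", "N", "P"))
  # one positive value per habitat-pair class: groups are dropped to
  # nothing and the fit is refused
  expect_error(suppressMessages(dependence_anova(dep)))
})

test_that("BACI interaction is null when all counts are equal", {
  mk_panel <- function(site, block, treatment) {
    site_panel(data.frame(
      host_taxon = c("A", "B"), habitat = c("P", "N"),
      n_transect_t = 20L, n_transect_t1 = 20L,
      n_total_t = 20L, n_total_t1 = 20L,
      reared_t = 10L, reared_t1 = 10L, attacks_t = 2L, attacks_t1 = 2L),
      site_id = site, block_id = block, treatment = treatment)
  }
  panels <- list(mk_panel("V01", "B01", "control"),
                 mk_panel("V02", "B01", "reduction"),
                 mk_panel("V03", "B02", "control"),
                 mk_panel("V04", "B02", "reduction"))
  res <- baci_abundance_test(panels)
  expect_lt(abs(res$interaction$estimate), 1e-6)
  # single-treatment data cannot identify an interaction
  expect_error(baci_abundance_test(panels[c(1, 3)]), "both treatments")
})

test_that("a self-consistent table yields a strongly positive parasitism slope", {
  # O generated to equal E with many trials: the slope is positive and
  # overwhelmingly significant
  set.seed(21)
  n <- 120
  tab <- data.frame(
    site_id = rep(sprintf("V%02d", 1:8), each = 15),
    block_id = rep(sprintf("B%02d", 1:4), each = 30),
    treatment = rep(c("control", "reduction"), each = 60),
    host_taxon = sprintf("H%03d", seq_len(n)),
    habitat = sample(c("N", "P"), n, TRUE),
    E = runif(n, 0.02, 0.9))
  tab$trials <- 400L
  tab$events <- rbinom(n, tab$trials, tab$E)
  tab$included <- TRUE
  fit <- fit_prediction_model(tab, predictors = "E",
                              random_candidates = c("(1 | block_id)",
                                                    "none"))
  cf <- fit$selected$coefficients
  row <- cf[cf$term == "E", ]
  expect_equal(nrow(row), 1)
  expect_gt(row$estimate, 0)
  expect_lt(row$p, 0.001)
  expect_gte(fit$selected$r2[["conditional"]],
             fit$selected$r2[["marginal"]])
})
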