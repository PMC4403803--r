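test_that("one-way ANOVA matches hand-computed sums of squares", {
  res <- anova_oneway(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # SSB = 13.5 on 1 df, SSW = 4 on 4 df -> F = 13.5 / 1 = 13.5
  expect_equal(res$statistic, 13.5)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 4)
  expect_equal(res$p_value, stats::pf(13.5, 1, 4, lower.tail = FALSE))

  flat <- anova_oneway(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(flat$statistic, 0)
})

test_that("two-group F equals the square of the pooled t statistic", {
  set.seed(55)
  for (i in 1:10) {
    g1 <- rnorm(6); g2 <- rnorm(7, mean = 0.5)
    f <- anova_oneway(c(g1, g2), rep(c("a", "b"), c(6, 7)))$statistic
    t <- stats::t.test(g1, g2, var.equal = TRUE)$statistic
    expect_equal(f, unname(t^2), tolerance = 1e-10)
  }
})

test_that("ANOVA is invariant to relabelling and location shifts", {
  set.seed(56)
  v <- rnorm(12); g <- rep(c("x", "y", "z"), 4)
  base <- anova_oneway(v, g)
  relab <- anova_oneway(v, c(x = "B", y = "C", z = "A")[g])
  expect_equal(relab$statistic, base$statistic)
  shifted <- anova_oneway(v + 100, g)
  expect_equal(shifted$statistic, base$statistic)
})

test_that("ANOVA validates its inputs", {
  expect_error(anova_oneway(1:5, rep("a", 5)), class = "phylospace_parameter_error")
  expect_error(anova_oneway(c(1, 2), c("a", "b")), class = "phylospace_parameter_error")
  expect_error(anova_oneway(c(1, 1, 2, 2), c("a", "a", "b", "b")),
               class = "phylospace_degenerate_matrix")
})

test_that("log percentage transform maps 0 to 0 and is monotone", {
  expect_equal(log_pct_alien(0), 0)
  expect_equal(log_pct_alien(exp(1) - 1), 1)
  pct <- sort(runif(20, 0, 100))
  expect_true(all(diff(log_pct_alien(pct)) > 0))
  expect_error(log_pct_alien(-1), class = "phylospace_domain_error")
})

fake_summaries <- function(n_per_group = 10, r_fun = NULL, noise_sd = 0) {
  veg <- rep(c("forest", "grassland"), each = n_per_group)
  set.seed(60)
  s <- tibble::tibble(
    plot_id = sprintf("p%02d", seq_len(2 * n_per_group)),
    vegetation = veg,
    richness = sample(10:40, 2 * n_per_group, replace = TRUE),
    pd = runif(2 * n_per_group, 900, 2300),
    density = runif(2 * n_per_group, 4, 16),
    pct_alien = runif(2 * n_per_group, 0, 12)
  )
  s$log_pct_alien <- log_pct_alien(s$pct_alien)
  if (is.null(r_fun)) {
    r_fun <- function(d) 0.2 + 0.01 * d$richness
  }
  s$mantel_r <- r_fun(s) + rnorm(nrow(s), 0, noise_sd)
  s
}

test_that("noise-free linear data is recovered exactly and GLM equals OLS", {
  s <- fake_summaries(r_fun = function(d)
    0.3 - 0.005 * d$richness + 0.2 * (d$vegetation == "grassland") +
      0.003 * d$richness * (d$vegetation == "grassland"))
  fits <- fit_mantel_glms(s, covariates = "richness")
  co <- coef(fits$richness)
  expect_equal(unname(co["(Intercept)"]), 0.3, tolerance = 1e-8)
  expect_equal(unname(co["richness"]), -0.005, tolerance = 1e-8)
  expect_equal(unname(co["vegetationgrassland"]), 0.2, tolerance = 1e-8)
  expect_equal(unname(co["vegetationgrassland:richness"]), 0.003, tolerance = 1e-8)

  # Gaussian identity-link GLM is ordinary least squares
  s2 <- fake_summaries(noise_sd = 0.05)
  fit <- fit_mantel_glms(s2, covariates = "pd")$pd
  ols <- stats::lm(mantel_r ~ vegetation * pd, data = s2)
  expect_equal(coef(fit), coef(ols), tolerance = 1e-10)
  expect_equal(unname(vcov(fit)), unname(vcov(ols)), tolerance = 1e-8)
  # residuals orthogonal to every design column
  X <- stats::model.matrix(ols)
  expect_lt(max(abs(crossprod(X, stats::resid(fit)))), 1e-8)
})

test_that("the default model set yields 12 non-intercept p-values over 4 models", {
  s <- fake_summaries(noise_sd = 0.05)
  fits <- fit_mantel_glms(s)
  expect_named(fits, c("richness", "pd", "density", "log_pct_alien"))
  td <- tidy(fits)
  non_int <- td[td$term != "(Intercept)", ]
  expect_equal(nrow(non_int), 12)
  expect_true(all(non_int$p.value >= 0 & non_int$p.value <= 1))
  gl <- glance(fits)
  expect_equal(nrow(gl), 4)
  # residual df = n_plots - n_terms
  expect_true(all(gl$df.residual == nrow(s) - 4))
})

test_that("degenerate designs are rejected with informative errors", {
  s <- fake_summaries()
  s$pd <- 1000 # constant covariate -> aliased interaction
  expect_error(fit_mantel_glms(s, covariates = "pd"),
               class = "phylospace_singular_fit")
  expect_error(fit_mantel_glms(fake_summaries(n_per_group = 2)),
               class = "phylospace_parameter_error")
  expect_error(fit_mantel_glms(dplyr::select(fake_summaries(), -density),
                               covariates = "density"),
               class = "phylospace_schema_error")
})

test_that("a vegetation-by-richness interaction sized for 0.9 power is detected", {
  # fixed design: 20 plots, even vegetation split, fixed covariate values
  n <- 20
  veg <- rep(c(0, 1), each = n / 2)
  rich <- rep(seq(10, 40, length.out = n / 2), 2)
  X <- cbind(1, veg, rich, veg * rich)
  sigma <- 0.1
  v_jj <- solve(crossprod(X))[4, 4]
  se_beta <- sigma * sqrt(v_jj)
  df <- n - 4
  tcrit <- stats::qt(0.975, df)
  power_at <- function(b) {
    ncp <- b / se_beta
    1 - stats::pt(tcrit, df, ncp) + stats::pt(-tcrit, df, ncp)
  }
  beta <- stats::uniroot(function(b) power_at(b) - 0.9, c(1e-6, 1))$root

  set.seed(61)
  rejections <- vapply(seq_len(200), function(i) {
    s <- tibble::tibble(
      plot_id = sprintf("p%02d", 1:n),
      vegetation = ifelse(veg == 1, "grassland", "forest"),
      richness = rich,
      mantel_r = 0.1 + beta * veg * rich + rnorm(n, 0, sigma)
    )
    td <- tidy(fit_mantel_glms(s, covariates = "richness"))
    td$p.value[td$term == "vegetationgrassland:richness"] < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.8)
})

test_that("vegetation ANOVAs cover the plot-level responses", {
  s <- fake_summaries(noise_sd = 0.05)
  res <- vegetation_anovas(s)
  expect_setequal(res$response, c("richness", "pd", "density", "pct_alien", "mantel_r"))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$df_within == 18))
})

test_that("plot summaries assemble per-plot descriptors with Mantel and PD columns", {
  set.seed(62)
  sim <- simulate_study(do.call(sim_params, small_sim_args()), seed = 9)
  m <- mantel_tests(sim$stem_map, sim$tree, n_perm = 99, seed = 1)
  pdn <- pd_null_tests(sim$stem_map, sim$tree, n_rep = 200, seed = 2)
  s <- plot_summaries(sim$stem_map, sim$tree, mantel = m, pd_null = pdn)
  expect_equal(nrow(s), 6)
  expect_true(all(c("richness", "pd", "density", "pct_alien", "log_pct_alien",
                    "mantel_r", "mantel_p", "pd_ses", "pd_classification")
                  %in% names(s)))
  by_hand <- table(sim$stem_map$plot_id)
  expect_equal(s$n_individuals[match(names(by_hand), s$plot_id)],
               as.integer(by_hand))
  expect_equal(s$pd[s$plot_id == s$plot_id[1]],
               faith_pd(sim$tree, unique(sim$stem_map$species[
                 sim$stem_map$plot_id == s$plot_id[1]])))
})
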