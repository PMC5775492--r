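make_dam_table <- function(n_per_pop, means, fl_mu = 800, fl_sd = 50,
                           slope = 0, egg_sd = 0.4, seed = 1) {
  set.seed(seed)
  pops <- names(means)
  do.call(rbind, lapply(pops, function(p) {
    fl <- rnorm(n_per_pop, fl_mu, fl_sd)
    data.frame(population = p,
               sire = sprintf("%s_S%02d", p, ceiling(seq_len(n_per_pop) / 2)),
               dam = sprintf("%s_D%02d", p, seq_len(n_per_pop)),
               egg_diameter_mm = means[[p]] + slope * (fl - fl_mu) +
                 rnorm(n_per_pop, 0, egg_sd),
               fork_length_mm = fl, stringsAsFactors = FALSE)
  }))
}

test_that("egg-size ANOVA detects a 1-SD population difference", {
  d <- make_dam_table(25, c(A = 7.0, B = 7.4), egg_sd = 0.4, seed = 2)
  res <- compare_egg_size(d)
  expect_lt(res$anova$p, 0.01)
  expect_equal(nrow(res$anova$tukey), 1)
})

test_that("a size-mediated difference vanishes under the length covariate", {
  # egg size depends only on female length; groups differ only in length
  set.seed(5)
  n <- 30
  d <- rbind(
    data.frame(population = "A", fork_length_mm = rnorm(n, 760, 40)),
    data.frame(population = "B", fork_length_mm = rnorm(n, 860, 40)))
  d$egg_diameter_mm <- 1 + 0.0075 * d$fork_length_mm + rnorm(2 * n, 0, 0.1)
  d$sire <- sprintf("S%02d", seq_len(2 * n)); d$dam <- sprintf("D%02d", seq_len(2 * n))
  res <- compare_egg_size(d)
  expect_lt(res$anova$p, 0.001)          # raw difference present
  expect_gt(res$ancova$p_population, 0.05)  # explained by female size
  expect_lt(res$ancova$p_covariate, 0.001)
  expect_error(compare_egg_size(d[d$population == "A", ]), "2 populations")
})

test_that("egg-size ANOVA p-values are well calibrated under the null", {
  ps <- vapply(1:40, function(r) {
    d <- make_dam_table(20, c(A = 7, B = 7, C = 7), seed = 300 + r)
    compare_egg_size(d)$anova$p
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
})

test_that("fixed-effect contribution variance matches closed forms", {
  d <- make_nested_data(6, 2, 6, seed = 1)
  d2 <- d; d2$population <- rep(c("A", "B"), length.out = nrow(d))
  fit <- fit_mixed_model(d2, model_spec("y"))
  cols <- which(fit$assign == match("population", fit$term_labels))
  # overwrite the estimate: balanced two-group contrast of size delta
  delta <- 1.4
  fit$fixef[cols] <- delta
  expect_equal(fixed_effect_variance(fit, "population"), delta^2 / 4)
  expect_error(fixed_effect_variance(fit, "egg_c"), "not in the model")

  d3 <- d; d3$population <- rep(c("A", "B", "C"), length.out = nrow(d))
  fit3 <- fit_mixed_model(d3, model_spec("y"))
  cols3 <- which(fit3$assign == match("population", fit3$term_labels))
  fit3$fixef[cols3] <- c(delta, 2 * delta)  # contributions 0, d, 2d
  expect_equal(fixed_effect_variance(fit3, "population"), (2 / 3) * delta^2)

  # all-zero estimates contribute nothing
  fit$fixef[cols] <- 0
  expect_equal(fixed_effect_variance(fit, "population"), 0)
})

test_that("contribution variance is invariant to factor coding", {
  d <- make_nested_data(8, 2, 6, seed = 7)
  d$population <- rep(c("A", "B", "C"), length.out = nrow(d))
  d$y <- d$y + c(A = 0, B = 1, C = 2)[d$population]
  f_trt <- fit_mixed_model(d, model_spec("y"))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  f_sum <- fit_mixed_model(d, model_spec("y"))
  expect_equal(fixed_effect_variance(f_trt, "population"),
               fixed_effect_variance(f_sum, "population"), tolerance = 1e-6)
})

test_that("variance partition fractions are coherent", {
  d <- make_nested_data(10, 2, 8, V_S = 0.5, V_D = 0.5, V_E = 1, seed = 4)
  f <- fit_mixed_model(d, model_spec("y"))
  p <- variance_partition(f)
  # intercept-only fixed part: full model variance is all random
  expect_equal(p$fraction_full, p$fraction_random, tolerance = 1e-10)
  expect_equal(p$fraction_full + p$fraction_residual, 1, tolerance = 1e-8)
  expect_equal(p$fraction_fixed + p$fraction_random, p$fraction_full,
               tolerance = 1e-10)
  fr <- c(p$fraction_population, p$fraction_egg, p$fraction_random,
          p$fraction_full, p$fraction_residual)
  expect_true(all(fr >= 0 & fr <= 1))

  # populations explain (nearly) everything
  off <- sim_one_trait(10, 10, V_S = 1e-4, V_D_resid = 1e-4, V_C = 0,
                       V_E = 1e-4, seed = 2)
  off$population <- ifelse(as.integer(factor(off$sire)) %% 2 == 0, "A", "B")
  off$y <- off$y + ifelse(off$population == "A", 0, 5)
  fp <- fit_mixed_model(off, model_spec("y"))
  expect_gt(variance_partition(fp)$fraction_population, 0.95)

  # interaction models are excluded from the partition
  d2 <- d; d2$population <- rep(c("A", "B"), length.out = nrow(d2))
  fi <- fit_mixed_model(d2, model_spec("y", include_egg = TRUE,
                                       include_interaction = TRUE))
  expect_error(variance_partition(fi), "interaction")
})

test_that("relative change is a percent reduction", {
  expect_equal(relative_change(0.8, 0.04), 95)
  expect_equal(relative_change(0.37, 0.37), 0)
  expect_equal(relative_change(0.5, 0.6), -20)
  expect_error(relative_change(0, 0.5), "nonzero")
})

test_that("least-squares means adjust for the covariate", {
  # no covariate, balanced: LS-means equal raw group means
  d <- make_nested_data(8, 2, 6, V_S = 0.1, V_D = 0.1, V_E = 0.5, seed = 11)
  d$population <- rep(c("A", "B"), each = nrow(d) / 2)
  d$sire <- paste0(d$population, d$sire); d$dam <- paste0(d$population, d$dam)
  d$family <- d$dam
  delta <- 2
  d$y <- d$y + ifelse(d$population == "B", delta, 0)
  f <- fit_mixed_model(d, model_spec("y"))
  ls <- least_squares_means(f, "population")
  raw <- as.numeric(tapply(d$y, d$population, mean))
  expect_equal(ls$means$emmean, raw, tolerance = 1e-3)
  expect_equal(-ls$pairs$estimate[1], raw[2] - raw[1], tolerance = 1e-3)
  expect_error(least_squares_means(f, "egg_c"), "not a fixed effect")

  # groups differing only through the egg covariate equalize
  d2 <- make_nested_data(20, 2, 8, V_S = 0.05, V_D = 0.02, V_E = 0.3,
                         beta_egg = 1, egg_mu = 7, seed = 12)
  d2b <- make_nested_data(20, 2, 8, V_S = 0.05, V_D = 0.02, V_E = 0.3,
                          beta_egg = 1, egg_mu = 7.8, seed = 13)
  d2b$population <- "P2"; d2b$sire <- sub("S", "T", d2b$sire)
  d2b$dam <- sub("D", "E", d2b$dam); d2b$family <- d2b$dam
  dd <- rbind(d2, d2b)
  f2 <- fit_mixed_model(dd, model_spec("y", include_egg = TRUE))
  ls2 <- least_squares_means(f2, "population")
  expect_gt(ls2$pairs$p.value[1], 0.05)
})

test_that("haldane rates follow the definition and its symmetries", {
  expect_equal(haldane_rate(10, 10, 1, 1, 20, 20, 10), 0)
  expect_equal(haldane_rate(10, 11, 1, 1, 20, 20, g = 1), 1)
  expect_error(haldane_rate(1, 2, 0, 0, 10, 10), "zero")
  expect_error(haldane_rate(1, 2, 1, 1, 1, 10), "n >= 2")
  # antisymmetry and scale invariance
  h <- haldane_rate(3, 5, 1.2, 0.8, 15, 18, 10)
  expect_equal(haldane_rate(5, 3, 0.8, 1.2, 18, 15, 10), -h)
  expect_equal(haldane_rate(30, 50, 12, 8, 15, 18, 10), h)
  expect_equal(pooled_sd(2, 2, 10, 10), 2)
})

make_fam_table <- function(seed, mu_a = 7.0, mu_b = 7.9, beta = 1.5,
                           n = 40, resid_sd = 0.25) {
  set.seed(seed)
  do.call(rbind, lapply(c("A", "B"), function(p) {
    mu <- if (p == "A") mu_a else mu_b
    egg <- rnorm(n, mu, 0.4)
    data.frame(population = p,
               sire = sprintf("%s_S%02d", p, ceiling(seq_len(n) / 2)),
               dam = sprintf("%s_D%02d", p, 1:n),
               family = sprintf("%s_D%02d", p, 1:n),
               egg_diameter_mm = egg,
               y = 2 + beta * egg + rnorm(n, 0, resid_sd),
               stringsAsFactors = FALSE)
  }))
}

test_that("controlling for egg size shrinks egg-mediated divergence", {
  # populations differ in the trait only through egg size; after egg control
  # the divergence rate should collapse in the bulk of replicates (the
  # interaction screen occasionally excludes a replicate by chance)
  shrunk <- 0L; kept <- 0L
  for (r in 1:10) {
    fam <- make_fam_table(seed = 700 + r)
    raw <- divergence_suite(fam, "y", g = 10, control_egg = FALSE)
    ctl <- divergence_suite(fam, "y", g = 10, control_egg = TRUE)
    if (!ctl$excluded) {
      kept <- kept + 1L
      if (abs(ctl$haldane) < abs(raw$haldane) / 2) shrunk <- shrunk + 1L
    }
  }
  expect_gte(kept, 7)
  expect_gte(shrunk, kept - 1L)

  # identical populations: near-zero rates (analytic SD of h is ~0.022 here)
  fam0 <- make_fam_table(seed = 32, mu_a = 7, mu_b = 7)
  raw0 <- divergence_suite(fam0, "y", g = 10)
  expect_lt(abs(raw0$haldane), 0.12)

  fam1 <- make_fam_table(seed = 733)
  both <- rbind(divergence_suite(fam1, "y", g = 10),
                divergence_suite(fam1, "y", g = 10, control_egg = TRUE))
  smry <- divergence_summary(both[!both$excluded, ])
  expect_lte(nrow(smry), 2)
  expect_gte(nrow(smry), 1)
})

test_that("traits without an egg relationship are excluded when controlling", {
  n_noegg <- 0L
  for (r in 1:10) {
    fam <- make_fam_table(seed = 800 + r, beta = 0, resid_sd = 0.5)
    ctl <- divergence_suite(fam, "y", g = 10, control_egg = TRUE)
    if (all(ctl$excluded) &&
        identical(unique(ctl$reason), "no egg-size relationship")) {
      n_noegg <- n_noegg + 1L
      expect_true(all(is.na(ctl$haldane)))
    }
  }
  expect_gte(n_noegg, 6)
})
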