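test_that("degenerate data drive the right components to zero", {
  # no residual noise: everything is absorbed by the dam term
  d <- make_nested_data(5, 2, 8, V_S = 0, V_D = 1, V_E = 0, seed = 2)
  f <- fit_mixed_model(d, model_spec("y"))
  expect_lt(f$varcomp[["V_E"]], 1e-8)
  expect_gt(f$varcomp[["V_D"]], 0.05)
})

test_that("REML equals the balanced-ANOVA estimators on a small fixture", {
  d <- make_nested_data(8, 2, 6, V_S = 1.5, V_D = 1, V_E = 1, seed = 5)
  ems <- anova_ems_varcomp(d, 2, 6)
  expect_true(all(ems > 0))  # interior, so the equivalence applies
  f <- fit_mixed_model(d, model_spec("y"))
  for (p in c("V_S", "V_D", "V_E")) {
    expect_equal(f$varcomp[[p]], ems[[p]], tolerance = 1e-4)
  }
})

test_that("model fitting validates its design preconditions", {
  d <- make_nested_data(4, 2, 5, seed = 1)
  expect_error(fit_mixed_model(d, model_spec("nope")), "not found")
  expect_error(fit_mixed_model(d[d$sire == "S001", ], model_spec("y")),
               "2 sires")
  expect_error(
    fit_mixed_model(d, model_spec("y", include_population = TRUE)),
    "single population")
  expect_error(
    fit_mixed_model(d, model_spec("y", include_egg = TRUE,
                                  include_interaction = TRUE)),
    "inestimable")
  d2 <- d; d2$dam[1] <- "D003"  # same dam label under two sires
  expect_error(fit_mixed_model(d2, model_spec("y")), "more than one sire")
  expect_error(model_spec("y", level = "family",
                          random_terms = c("sire", "dam")), "sire")
})

test_that("Wald tests match their closed forms", {
  w <- wald_test(c(0, 0), diag(2))
  expect_equal(w$statistic, 0)
  expect_equal(w$p, 1)
  b <- 1.7; se <- 0.4
  w1 <- wald_test(b, matrix(se^2))
  expect_equal(w1$statistic, (b / se)^2)
  expect_equal(w1$p, pchisq((b / se)^2, 1, lower.tail = FALSE))
  expect_error(wald_test(c(1, 2), matrix(0, 2, 2)), "rank")
})

test_that("egg-effect Wald test holds its size under the null", {
  n_rep <- 200
  rej <- 0L
  for (r in seq_len(n_rep)) {
    d <- make_nested_data(40, 2, 5, V_S = 0.3, V_D = 0.3, V_E = 1,
                          beta_egg = 0, seed = 5000 + r)
    f <- fit_mixed_model(d, model_spec("y", include_egg = TRUE))
    w <- wald_fixed_effects(f)
    if (w$p[w$effect == "egg_c"] < 0.05) rej <- rej + 1L
  }
  # binomial(200, 0.05) central 99% range
  expect_gte(rej, 3)
  expect_lte(rej, 19)
})

test_that("the interaction-drop rule keeps real slope heterogeneity", {
  # two populations with very different egg slopes: interaction retained
  set.seed(21)
  mk2pop <- function(b1, b2, seed) {
    d1 <- make_nested_data(12, 2, 10, V_S = 0.05, V_D = 0.05, V_E = 0.3,
                           beta_egg = b1, seed = seed)
    d2 <- make_nested_data(12, 2, 10, V_S = 0.05, V_D = 0.05, V_E = 0.3,
                           beta_egg = b2, seed = seed + 1)
    d2$population <- "P2"
    d2$sire <- sub("^S", "T", d2$sire); d2$dam <- sub("^D", "E", d2$dam)
    d2$family <- d2$dam
    rbind(d1, d2)
  }
  sel <- drop_nonsignificant_interaction(
    mk2pop(0.5, 2.0, 31), model_spec("y", include_egg = TRUE))
  expect_false(sel$dropped)
  expect_lt(sel$interaction_p, 0.05)

  # common slope: dropped in most replicates
  dropped <- vapply(1:20, function(r) {
    drop_nonsignificant_interaction(
      mk2pop(1, 1, 600 + 2 * r), model_spec("y", include_egg = TRUE))$dropped
  }, logical(1))
  expect_gte(mean(dropped), 0.8)

  # single population: interaction inestimable
  expect_error(drop_nonsignificant_interaction(
    make_nested_data(5, 2, 5, seed = 1),
    model_spec("y", include_egg = TRUE)), "inestimable")
})

test_that("heritability and maternal effect follow their definitions", {
  expect_equal(heritability(varcomp(1, 1, 1, 1)), 1)
  expect_equal(heritability(varcomp(0, 2, 0, 3)), 0)
  expect_equal(heritability(varcomp(0.13, 0.28, 0.05, 0.54)), 0.52)
  expect_equal(maternal_effect(varcomp(0.2, 0.2, 0, 0.6)), 0)
  expect_equal(maternal_effect(varcomp(0.13, 0.28, 0.05, 0.54)), 0.15)
  expect_warning(m <- maternal_effect(varcomp(0.3, 0.1, 0, 0.6)), "negative")
  expect_equal(m, -0.2)
  expect_error(heritability(varcomp(0, 0, 0, 0)), "> 0")
})

test_that("h2 and m2 are invariant to affine rescaling of the trait", {
  d <- make_nested_data(10, 2, 8, V_S = 0.8, V_D = 0.5, V_E = 1, seed = 9)
  f1 <- fit_mixed_model(d, model_spec("y"))
  d2 <- d; d2$y <- 3.2 * d$y - 40
  f2 <- fit_mixed_model(d2, model_spec("y"))
  expect_equal(unclass(f2$varcomp), 3.2^2 * unclass(f1$varcomp),
               tolerance = 1e-4)
  expect_equal(heritability(f2), heritability(f1), tolerance = 1e-5)
  expect_equal(suppressWarnings(maternal_effect(f2)),
               suppressWarnings(maternal_effect(f1)), tolerance = 1e-5)
})

test_that("RLRT is near zero without the component and detects a real one", {
  # component absent, residual dominant: statistic ~ 0, p near 1
  d0 <- make_nested_data(20, 2, 6, V_S = 0, V_D = 0.5, V_E = 100, seed = 4)
  r0 <- rlrt_variance_component(d0, model_spec("y"), "sire", nsim = 99,
                                seed = 1)
  expect_lt(r0$statistic, 0.2)
  expect_gt(r0$p, 0.5)

  # strong sire variance at 50 sires: detected
  d1 <- make_nested_data(50, 2, 10, V_S = 1, V_D = 0.3, V_E = 1, seed = 6)
  r1 <- rlrt_variance_component(d1, model_spec("y"), "sire", nsim = 99,
                                seed = 1)
  expect_lte(r1$p, 0.05)
  expect_error(rlrt_variance_component(d1, model_spec("y"), "container"),
               "random terms")
})

test_that("within-family resampling preserves structure and degenerates cleanly", {
  # trait constant within family: every replicate must reproduce the point
  # estimate exactly (resampling within families cannot change family means)
  d <- make_nested_data(6, 2, 5, V_S = 0.5, V_D = 0.5, V_E = 1, seed = 3)
  d$y <- ave(d$y, d$family)  # collapse to family means, zero within-family noise
  b <- suppressWarnings(family_bootstrap(d, model_spec("y"), n_iter = 20,
                                         seed = 1))
  expect_equal(b$n_fail, 0)
  for (p in colnames(b$replicates)) {
    expect_equal(unname(b$replicates[, p]), rep(b$point[[p]], nrow(b$replicates)),
                 tolerance = 1e-6)
  }
  # degenerate replicate distribution collapses the interval to the point
  ci <- b$ci
  expect_equal(ci$lower, ci$estimate, tolerance = 1e-6)
})

test_that("bootstrap spread tracks the sampling spread of h2", {
  gen <- function(seed) make_nested_data(12, 2, 10, V_S = 0.5, V_D = 0.5,
                                         V_E = 1, seed = seed)
  b <- family_bootstrap(gen(1), model_spec("y"), n_iter = 300, seed = 42)
  boot_sd <- sd(b$replicates[, "h2"], na.rm = TRUE)
  truth_h2 <- vapply(1:60, function(r) {
    heritability(fit_mixed_model(gen(100 + r), model_spec("y")))
  }, numeric(1))
  ratio <- boot_sd / sd(truth_h2)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("BCa intervals reduce correctly in the canonical special cases", {
  # symmetric replicates centred on the point, no acceleration: percentile
  reps <- qnorm(ppoints(999), mean = 5)
  ci <- bca_interval(reps, 5)
  expect_equal(unname(ci), unname(quantile(reps, c(0.025, 0.975), type = 6)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(attr(ci, "z0"), 0)
  # all replicates above the point: z0 pinned at its clipped extreme and the
  # interval sits wholly above the point estimate
  reps2 <- 5 + abs(rnorm(500))
  ci2 <- bca_interval(reps2, 5)
  expect_equal(attr(ci2, "z0"), qnorm(1 / 500))
  expect_gte(ci2[["lower"]], 5)
  # identical replicates: degenerate interval with a warning
  expect_warning(ci3 <- bca_interval(rep(2, 200), 2), "degenerate")
  expect_equal(unname(ci3), c(2, 2), ignore_attr = TRUE)
})

test_that("BCa agrees with the reference implementation on a mean", {
  skip_if_not_installed("boot")
  set.seed(8)
  x <- rexp(40)
  bt <- boot::boot(x, function(d, i) mean(d[i]), R = 2000)
  ref <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  jack <- vapply(seq_along(x), function(i) mean(x[-i]), numeric(1))
  ours <- bca_interval(as.numeric(bt$t), mean(x), jack)
  expect_equal(unname(ours), ref, tolerance = 0.02, ignore_attr = TRUE)
})

test_that("before/after comparison flags non-overlapping intervals", {
  mk <- function(est, lo, hi) {
    structure(list(ci = data.frame(parameter = "V_D", estimate = est,
                                   lower = lo, upper = hi)),
              class = "hs_boot")
  }
  same <- compare_before_after(mk(0.5, 0.4, 0.6), mk(0.5, 0.4, 0.6))
  expect_equal(same$pct_reduction, 0)
  expect_false(same$significant)
  sig <- compare_before_after(mk(0.15, 0.1, 0.2), mk(0.35, 0.3, 0.4))
  expect_true(sig$significant)
  expect_equal(sig$pct_reduction, 100 * (0.15 - 0.35) / 0.15)
})
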