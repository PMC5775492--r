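#' Compare egg diameter among populations (ANOVA and ANCOVA)
#'
#' One-way ANOVA of egg diameter on population, followed by an ANCOVA with
#' female fork length as a covariate (egg size scales positively with female
#' body size, so the covariate separates size-mediated from intrinsic
#' egg-size differences).  The fork-length x population interaction is tested
#' first and dropped when non-significant.  Pairwise population contrasts use
#' Tukey adjustment for both analyses.
#'
#' @param dams dam table with columns `population`, `egg_diameter_mm`,
#'   `fork_length_mm`.
#' @param alpha retention threshold for the interaction (default 0.05).
#' @return An object of class `hs_eggsize`: lists `anova` (`F`, `df`, `p`,
#'   `tukey`) and `ancova` (`interaction_p`, `dropped`, per-effect `F`/`p`,
#'   `adj_r_squared`, `pairs`).
#' @export
compare_egg_size <- function(dams, alpha = 0.05) {
  need <- c("population", "egg_diameter_mm", "fork_length_mm")
  miss <- setdiff(need, names(dams))
  if (length(miss)) stop_domain("dam table missing: ", paste(miss, collapse = ", "))
  d <- dams[complete.cases(dams[, need]), , drop = FALSE]
  d$population <- factor(d$population)
  if (nlevels(d$population) < 2) stop_domain("need at least 2 populations")
  if (any(table(d$population) < 2)) stop_domain("each population needs >= 2 dams")
  if (sd(d$fork_length_mm) == 0) stop_domain("fork-length covariate is constant")

  av <- aov(egg_diameter_mm ~ population, data = d)
  av_tab <- anova(av)
  tukey <- as.data.frame(TukeyHSD(av)$population)
  tukey$comparison <- rownames(tukey)
  rownames(tukey) <- NULL

  m_int <- lm(egg_diameter_mm ~ population * fork_length_mm, data = d)
  a_int <- car::Anova(m_int, type = 2)
  p_int <- a_int["population:fork_length_mm", "Pr(>F)"]
  dropped <- p_int > alpha
  m_fin <- if (dropped) lm(egg_diameter_mm ~ population + fork_length_mm, data = d)
           else m_int
  a_fin <- car::Anova(m_fin, type = 2)
  emm <- suppressMessages(emmeans::emmeans(m_fin, "population"))
  prs <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "tukey"))

  structure(
    list(anova = list(F = av_tab["population", "F value"],
                      df = unname(av_tab$Df),
                      p = av_tab["population", "Pr(>F)"],
                      tukey = tukey),
         ancova = list(interaction_p = p_int, dropped = dropped,
                       F_population = a_fin["population", "F value"],
                       p_population = a_fin["population", "Pr(>F)"],
                       F_covariate = a_fin["fork_length_mm", "F value"],
                       p_covariate = a_fin["fork_length_mm", "Pr(>F)"],
                       adj_r_squared = summary(m_fin)$adj.r.squared,
                       pairs = prs),
         n = nrow(d)),
    class = "hs_eggsize")
}

#' @export
print.hs_eggsize <- function(x, ...) {
  cat(sprintf("Egg-size ANOVA: F = %.3g (p = %.3g)\n", x$anova$F, x$anova$p))
  cat(sprintf("ANCOVA (fork length covariate%s): population F = %.3g (p = %.3g), covariate F = %.3g (p = %.3g)\n",
              if (x$ancova$dropped) ", interaction dropped" else "",
              x$ancova$F_population, x$ancova$p_population,
              x$ancova$F_covariate, x$ancova$p_covariate))
  invisible(x)
}

fixed_term_columns <- function(fit, effect) {
  pos <- match(effect, fit$term_labels)
  if (is.na(pos)) {
    stop_domain("effect '", effect, "' not in the model (have: ",
                paste(fit$term_labels, collapse = ", "), ")")
  }
  which(fit$assign == pos)
}

#' Variance contributed by one fixed effect
#'
#' The effect's design columns are multiplied by its coefficient estimates
#' and the variance of the resulting per-observation contribution is taken
#' over the modelled rows (population variance, i.e. divided by n).  This is
#' the fixed-effect variance of the Nakagawa-Schielzeth decomposition, and
#' it is invariant to the factor coding because the full block of columns is
#' used together.
#'
#' @param fit an `hs_fit`.
#' @param effect a fixed-effect term label, e.g. `"population"` or `"egg_c"`.
#' @return Numeric scalar (trait units squared).
#' @export
fixed_effect_variance <- function(fit, effect) {
  stopifnot(inherits(fit, "hs_fit"))
  cols <- fixed_term_columns(fit, effect)
  X <- model.matrix(fit$model)
  contrib <- as.numeric(X[, cols, drop = FALSE] %*% fit$fixef[cols])
  mean((contrib - mean(contrib))^2)
}

#' Nakagawa-Schielzeth variance partition of a fitted model
#'
#' The fixed-effect variance of the full model is the variance of the
#' combined fixed predictor `X beta` over the modelled rows; the total is
#' that plus the random-effect variances and the residual variance, and
#' `fraction_full = fraction_fixed + fraction_random`.  The population and
#' egg-size shares are additionally reported from their separate
#' per-effect contribution variances ([fixed_effect_variance()]).  When the
#' two effects are collinear (populations differ in egg size) the separate
#' shares sum to more than the combined fixed share -- the excess is twice
#' the covariance of the two contributions, reported as `fixed_covariance`.
#' Using the combined predictor for the total is what makes the full-model
#' fraction stable when a covariate merely reassigns variance between
#' fixed effects and the dam term.  Models containing a population x egg
#' interaction are rejected, because the population and egg shares cannot
#' then be separated (such traits are excluded from the partition).
#'
#' @param fit an `hs_fit`.
#' @return An object of class `hs_partition` with fields
#'   `fraction_population`, `fraction_egg`, `fraction_fixed`,
#'   `fraction_random`, `fraction_full`, `fraction_residual`,
#'   `fixed_covariance` and the underlying variances.
#' @export
variance_partition <- function(fit) {
  stopifnot(inherits(fit, "hs_fit"))
  if (any(grepl(":", fit$term_labels))) {
    stop_domain("variance partition is undefined with a population x egg ",
                "interaction; exclude this trait")
  }
  v_pop <- if ("population" %in% fit$term_labels)
    fixed_effect_variance(fit, "population") else 0
  v_egg <- if ("egg_c" %in% fit$term_labels)
    fixed_effect_variance(fit, "egg_c") else 0
  X <- model.matrix(fit$model)
  xb <- as.numeric(X %*% fit$fixef)
  v_fixed <- mean((xb - mean(xb))^2)
  vc <- fit$varcomp
  v_rand <- sum(vc[c("V_S", "V_D", "V_C")])
  v_res <- vc[["V_E"]]
  total <- v_fixed + v_rand + v_res
  if (total <= 0) stop_domain("zero total variance")
  structure(
    list(fraction_population = v_pop / total,
         fraction_egg = v_egg / total,
         fraction_fixed = v_fixed / total,
         fraction_random = unname(v_rand / total),
         fraction_full = unname((v_fixed + v_rand) / total),
         fraction_residual = unname(v_res / total),
         fixed_covariance = (v_fixed - v_pop - v_egg) / total,
         variances = c(population = v_pop, egg = v_egg, fixed = v_fixed,
                       random = unname(v_rand), residual = unname(v_res)),
         total = total),
    class = "hs_partition")
}

#' @export
print.hs_partition <- function(x, ...) {
  cat(sprintf(
    "Variance partition: population %.3f, egg %.3f, random %.3f, residual %.3f (full model %.3f)\n",
    x$fraction_population, x$fraction_egg, x$fraction_random,
    x$fraction_residual, x$fraction_full))
  invisible(x)
}

#' Percent relative change between two proportions
#'
#' `100 * (before - after) / before`; positive values are reductions.
#'
#' @param before,after numeric (before must be nonzero; `before > 0` for the
#'   usual reduction reading).
#' @return Percent change (vectorized).
#' @export
#' @examples
#' relative_change(0.8, 0.04)  # 95
relative_change <- function(before, after) {
  if (any(before == 0)) stop_domain("`before` must be nonzero")
  100 * (before - after) / before
}

#' Least-squares (adjusted) means for a fixed factor
#'
#' Adjusted means at the grand covariate mean, balanced over the other
#' factors, with Tukey-adjusted pairwise comparisons.
#'
#' @param fit an `hs_fit` (or a fitted `lm`/`merMod`).
#' @param factor name of the fixed factor (default `"population"`).
#' @return List with `means` (data frame: level, lsmean, SE, CI) and
#'   `pairs` (Tukey-adjusted pairwise contrasts).
#' @export
least_squares_means <- function(fit, factor = "population") {
  model <- if (inherits(fit, "hs_fit")) fit$model else fit
  if (inherits(fit, "hs_fit") && !factor %in% fit$term_labels) {
    stop_domain("'", factor, "' is not a fixed effect of the model")
  }
  emm <- suppressMessages(
    emmeans::emmeans(model, specs = factor, lmer.df = "asymptotic",
                     data = if (inherits(fit, "hs_fit")) fit$data else NULL))
  list(means = as.data.frame(summary(emm)),
       pairs = as.data.frame(emmeans::contrast(emm, "pairwise",
                                               adjust = "tukey")))
}

#' Pooled standard deviation of two samples
#'
#' `sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2))`.
#'
#' @param sd1,sd2 sample standard deviations.
#' @param n1,n2 sample sizes (>= 2).
#' @return Numeric scalar.
#' @export
pooled_sd <- function(sd1, sd2, n1, n2) {
  if (n1 < 2 || n2 < 2) stop_domain("need n >= 2 in each sample")
  if (sd1 < 0 || sd2 < 0) stop_domain("standard deviations must be >= 0")
  sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
}

#' Phenotypic divergence rate in haldanes
#'
#' `h = (mean2 - mean1) / (S_p * g)` where `S_p` is the pooled standard
#' deviation of the trait across the two populations and `g` the number of
#' generations since their separation.  The rate is antisymmetric under
#' swapping the populations and invariant to rescaling the trait.
#'
#' @param mean1,mean2 population trait means.
#' @param sd1,sd2 population trait standard deviations (not both zero).
#' @param n1,n2 sample sizes (>= 2).
#' @param g generations separated (default 10).
#' @return Numeric scalar, units 1/generation.
#' @export
#' @examples
#' # egg-diameter divergence between two river populations, ~10 generations
#' haldane_rate(6.6, 7.9, sd1 = 0.09 * sqrt(26), sd2 = 0.10 * sqrt(20),
#'              n1 = 26, n2 = 20, g = 10)
haldane_rate <- function(mean1, mean2, sd1, sd2, n1, n2, g = 10) {
  if (g <= 0) stop_domain("`g` must be > 0")
  sp <- pooled_sd(sd1, sd2, n1, n2)
  if (sp == 0) stop_domain("pooled standard deviation is zero")
  (mean2 - mean1) / (sp * g)
}

#' Pairwise divergence rates for a set of traits
#'
#' Computes, per trait and unordered population pair, the divergence rate in
#' haldanes from the family-level rows -- either from raw population means or
#' from egg-size-controlled least-squares means (the denominator stays the
#' raw pooled SD in both cases so the rates are on one scale).  When
#' controlling for egg size, traits with no egg-size relationship (Wald
#' p > 0.05) or with a population x egg interaction (p <= 0.05) are excluded
#' and flagged, since their egg-controlled means are not interpretable.
#'
#' @param data family-level table (see [family_trait_table()]) restricted to
#'   one temperature, with `population`, `sire`, `egg_diameter_mm` and the
#'   trait columns.
#' @param traits character vector of trait column names.
#' @param g generations separated (default 10).
#' @param control_egg compute egg-size-controlled rates (via LS-means from a
#'   sire-random-intercept model with the egg covariate)?
#' @return Data frame of class `hs_divergence`: `trait`, `pop1`, `pop2`,
#'   `haldane`, `controlled`, `excluded`, `reason`.
#' @export
divergence_suite <- function(data, traits, g = 10, control_egg = FALSE) {
  pops <- sort(unique(as.character(data$population)))
  if (length(pops) < 2) stop_domain("need >= 2 populations")
  pairs <- utils::combn(pops, 2, simplify = FALSE)

  rows <- list()
  for (tr in traits) {
    if (!tr %in% names(data)) stop_domain("trait column '", tr, "' not found")
    d <- data[!is.na(data[[tr]]), , drop = FALSE]
    by_pop <- split(d[[tr]], as.character(d$population))

    excluded <- FALSE; reason <- NA_character_; ls <- NULL
    if (control_egg) {
      spec <- model_spec(tr, level = "family", include_egg = TRUE,
                         random_terms = "sire")
      sel <- tryCatch(drop_nonsignificant_interaction(d, spec),
                      error = function(e) NULL)
      if (is.null(sel)) {
        excluded <- TRUE; reason <- "model failure"
      } else if (!sel$dropped) {
        excluded <- TRUE; reason <- "population x egg interaction"
      } else {
        w <- wald_fixed_effects(sel$fit)
        p_egg <- w$p[w$effect == "egg_c"]
        if (!length(p_egg) || p_egg > 0.05) {
          excluded <- TRUE; reason <- "no egg-size relationship"
        } else {
          lsm <- least_squares_means(sel$fit, "population")$means
          ls <- setNames(lsm$emmean, as.character(lsm$population))
        }
      }
    }
    for (pr in pairs) {
      x1 <- by_pop[[pr[1]]]; x2 <- by_pop[[pr[2]]]
      if (is.null(x1) || is.null(x2) || length(x1) < 2 || length(x2) < 2) next
      h <- NA_real_
      if (!control_egg) {
        h <- haldane_rate(mean(x1), mean(x2), sd(x1), sd(x2),
                          length(x1), length(x2), g)
      } else if (!excluded) {
        sp <- pooled_sd(sd(x1), sd(x2), length(x1), length(x2))
        h <- (ls[[pr[2]]] - ls[[pr[1]]]) / (sp * g)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, pop1 = pr[1], pop2 = pr[2], haldane = h,
        controlled = control_egg, excluded = excluded, reason = reason,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("hs_divergence", "data.frame")
  out
}

#' Mean divergence rate per population pair with a normal-theory CI
#'
#' Averages the per-trait divergence rates within each pair and returns
#' `mean +/- t * SE` over the traits.
#'
#' @param suite output of [divergence_suite()] (possibly several, rbind-ed).
#' @param level confidence level (default 0.95).
#' @return Data frame: `pop1`, `pop2`, `controlled`, `n_traits`,
#'   `mean_haldane`, `lower`, `upper`.
#' @export
divergence_summary <- function(suite, level = 0.95) {
  d <- suite[!suite$excluded & !is.na(suite$haldane), , drop = FALSE]
  key <- interaction(d$pop1, d$pop2, d$controlled, drop = TRUE)
  out <- do.call(rbind, lapply(split(d, key), function(g) {
    n <- nrow(g)
    m <- mean(g$haldane)
    se <- if (n > 1) sd(g$haldane) / sqrt(n) else NA_real_
    tq <- if (n > 1) qt(1 - (1 - level) / 2, n - 1) else NA_real_
    data.frame(pop1 = g$pop1[1], pop2 = g$pop2[1], controlled = g$controlled[1],
               n_traits = n, mean_haldane = m,
               lower = m - tq * se, upper = m + tq * se,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
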