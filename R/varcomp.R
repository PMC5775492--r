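#' Describe a variance-component mixed model
#'
#' The individual-level model is
#' `z = mu + P + [EG] + [P:EG] + sire + dam + [container] + e`
#' with independent random intercepts for sire, dam nested within sire, and
#' (for hatch-stage traits measured in replicate containers) container.
#' Family-level derived traits (growth rates, conversion efficiency) use
#' sire as the only random effect.
#'
#' @param trait name of the response column.
#' @param level `"individual"` or `"family"`; family-level models admit only
#'   the sire random term.
#' @param include_egg include the dam-level egg-diameter covariate (grand-mean
#'   centered within the modelled data).
#' @param include_interaction include the population x egg-size interaction
#'   (requires `include_egg` and at least two populations).
#' @param random_terms subset of `c("sire", "dam", "container")`.
#' @param temperature optional single temperature; the data are subset to it
#'   before fitting.
#' @param include_population include the population fixed effect; default
#'   (`NULL`) includes it exactly when the data contain more than one
#'   population.  Requesting it with a single population is an error.
#' @return An object of class `hs_modelspec`.
#' @export
model_spec <- function(trait,
                       level = c("individual", "family"),
                       include_egg = FALSE,
                       include_interaction = FALSE,
                       random_terms = c("sire", "dam"),
                       temperature = NULL,
                       include_population = NULL) {
  level <- match.arg(level)
  random_terms <- match.arg(random_terms, c("sire", "dam", "container"),
                            several.ok = TRUE)
  if (level == "family" && !identical(random_terms, "sire")) {
    stop_domain("family-level models use random_terms = \"sire\" only")
  }
  if (include_interaction && !include_egg) {
    stop_domain("the population x egg interaction requires `include_egg = TRUE`")
  }
  structure(
    list(trait = trait, level = level, include_egg = include_egg,
         include_interaction = include_interaction,
         random_terms = random_terms, temperature = temperature,
         include_population = include_population),
    class = "hs_modelspec")
}

as_varcomp <- function(x) {
  if (inherits(x, "hs_fit")) return(x$varcomp)
  if (inherits(x, "hs_varcomp")) return(x)
  if (is.numeric(x) && all(c("V_S", "V_D", "V_E") %in% names(x))) {
    return(varcomp(x[["V_S"]], x[["V_D"]],
                   if ("V_C" %in% names(x)) x[["V_C"]] else 0, x[["V_E"]]))
  }
  stop_domain("cannot interpret `x` as variance components")
}

#' Variance components of a half-sib model
#'
#' @param V_S,V_D,V_C,V_E sire, dam-within-sire, container and residual
#'   variances (trait units squared); `V_C` defaults to 0 for models without
#'   a container term.
#' @return A named numeric vector of class `hs_varcomp`.
#' @export
varcomp <- function(V_S, V_D, V_C = 0, V_E) {
  v <- c(V_S = V_S, V_D = V_D, V_C = V_C, V_E = V_E)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop_domain("variance components must be finite and >= 0")
  }
  structure(v, class = "hs_varcomp")
}

#' @export
print.hs_varcomp <- function(x, ...) {
  cat("Variance components: ",
      paste(sprintf("%s = %.4g", names(x), unclass(x)), collapse = ", "),
      "\n  V_P =", format(sum(x), digits = 5), "\n")
  invisible(x)
}

#' Extract variance components from a fitted model
#' @param fit an `hs_fit` from [fit_mixed_model()].
#' @return An `hs_varcomp` vector.
#' @export
variance_components <- function(fit) as_varcomp(fit)

build_model_formula <- function(spec, include_pop) {
  fixed <- "1"
  if (include_pop) fixed <- c(fixed, "population")
  if (spec$include_egg) fixed <- c(fixed, "egg_c")
  if (spec$include_interaction) fixed <- c(fixed, "population:egg_c")
  rand <- c(sire = "(1 | sire)", dam = "(1 | dam)",
            container = "(1 | container)")[spec$random_terms]
  as.formula(paste(spec$trait, "~",
                   paste(c(fixed, unname(rand)), collapse = " + ")))
}

#' Fit the nested half-sib mixed model by REML
#'
#' Fits the Gaussian linear mixed model described by the [model_spec()] with
#' independent random intercepts, by restricted maximum likelihood via
#' \pkg{lme4}.  Variance estimates are constrained to be non-negative
#' (boundary estimates of exactly zero are legitimate and reported as such).
#' The egg-size covariate, when present, enters grand-mean centered within
#' the modelled data so that the intercept and population effects stay
#' comparable before and after its inclusion.
#'
#' @param data offspring-level or family-level table containing the trait,
#'   `sire`, `dam` (and `container` if used), `population`,
#'   `egg_diameter_mm` (if `include_egg`) and optionally `temperature`.
#' @param spec an [model_spec()].
#' @return An object of class `hs_fit`: a list with the fitted
#'   \code{merMod} (`model`), fixed-effect estimates (`fixef`) and their
#'   covariance (`vcov`), `varcomp` (an `hs_varcomp`), the restricted
#'   log-likelihood (`logLik_reml`), design metadata and the modelled data.
#' @export
fit_mixed_model <- function(data, spec) {
  stopifnot(inherits(spec, "hs_modelspec"))
  if (!spec$trait %in% names(data)) {
    stop_domain("trait column '", spec$trait, "' not found")
  }
  d <- data
  if (!is.null(spec$temperature) && "temperature" %in% names(d)) {
    d <- d[d$temperature == spec$temperature, , drop = FALSE]
  }
  d <- d[!is.na(d[[spec$trait]]), , drop = FALSE]
  if (!nrow(d)) stop_domain("no usable rows for trait '", spec$trait, "'")
  for (col in c("sire", "dam")) {
    if (!col %in% names(d)) stop_domain("column '", col, "' required")
  }
  if (!"family" %in% names(d)) d$family <- d$dam
  # each dam must belong to exactly one sire (dam labels globally unique)
  ns <- tapply(d$sire, d$dam, function(s) length(unique(s)))
  if (any(ns > 1)) {
    stop_domain("dam label(s) appear under more than one sire: ",
                paste(head(names(ns)[ns > 1]), collapse = ", "))
  }
  if (length(unique(d$sire)) < 2L) stop_domain("need at least 2 sires")
  if ("container" %in% spec$random_terms && !"container" %in% names(d)) {
    stop_domain("container random term requested but no `container` column")
  }

  n_pop <- length(unique(d$population))
  include_pop <- spec$include_population %||% (n_pop > 1L)
  if (include_pop && n_pop < 2L) {
    stop_domain("population effect requested but the data hold a single population")
  }
  if (spec$include_interaction && !include_pop) {
    stop_domain("population x egg interaction is inestimable without >= 2 populations")
  }
  egg_center <- NA_real_
  if (spec$include_egg) {
    if (!"egg_diameter_mm" %in% names(d)) {
      stop_domain("`include_egg` requires an `egg_diameter_mm` column")
    }
    if (anyNA(d$egg_diameter_mm)) stop_domain("missing egg diameters")
    egg_center <- mean(d$egg_diameter_mm)
    d$egg_c <- d$egg_diameter_mm - egg_center
  }
  for (col in intersect(c("population", "sire", "dam", "container"), names(d))) {
    d[[col]] <- factor(d[[col]])
  }

  form <- build_model_formula(spec, include_pop)
  conv_warnings <- character()
  model <- withCallingHandlers(
    suppressMessages(
      lme4::lmer(form, data = d, REML = TRUE,
                 control = lme4::lmerControl(
                   calc.derivs = FALSE,
                   optCtrl = list(xtol_abs = 1e-10, ftol_abs = 1e-10)))),
    warning = function(w) {
      conv_warnings <<- c(conv_warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (any(grepl("failed to converge|unable to evaluate|Downdated",
                conv_warnings))) {
    stop_domain("mixed model did not converge for trait '", spec$trait, "': ",
                paste(unique(conv_warnings), collapse = "; "))
  }

  vc <- lme4::VarCorr(model)
  getv <- function(term) if (term %in% names(vc)) as.numeric(vc[[term]]) else 0
  comp <- varcomp(V_S = getv("sire"),
                  V_D = if ("dam" %in% spec$random_terms) getv("dam") else 0,
                  V_C = if ("container" %in% spec$random_terms) getv("container") else 0,
                  V_E = sigma(model)^2)

  X <- model.matrix(model)
  structure(
    list(model = model, spec = spec, formula = form, data = d,
         fixef = lme4::fixef(model),
         vcov = as.matrix(vcov(model)),
         varcomp = comp,
         logLik_reml = as.numeric(logLik(model)),
         n = nrow(d), n_sires = nlevels(d$sire), n_pop = n_pop,
         include_population = include_pop,
         term_labels = attr(terms(model), "term.labels"),
         assign = attr(X, "assign"),
         egg_center = egg_center,
         singular = lme4::isSingular(model),
         warnings = conv_warnings),
    class = "hs_fit")
}

#' @export
print.hs_fit <- function(x, ...) {
  cat("Half-sib REML fit:", deparse(x$formula), "\n")
  cat("  n =", x$n, "(", x$n_sires, "sires )  restricted logLik =",
      format(x$logLik_reml, digits = 6), "\n")
  print(x$varcomp)
  invisible(x)
}

#' Wald chi-square test for a block of coefficients
#'
#' `W = b' V^{-1} b` compared to a chi-square with `length(b)` degrees of
#' freedom.
#'
#' @param estimate coefficient vector.
#' @param vcov their covariance matrix (must be full rank).
#' @return List with `statistic`, `df`, `p`.
#' @export
wald_test <- function(estimate, vcov) {
  b <- as.numeric(estimate)
  V <- as.matrix(vcov)
  if (nrow(V) != length(b) || ncol(V) != length(b)) {
    stop_domain("dimension mismatch between estimate and vcov")
  }
  if (qr(V)$rank < length(b)) stop_domain("rank-deficient covariance matrix")
  stat <- as.numeric(t(b) %*% solve(V, b))
  list(statistic = stat, df = length(b),
       p = pchisq(stat, df = length(b), lower.tail = FALSE))
}

#' Type-II Wald tests for the fixed effects of a fitted model
#'
#' @param fit an `hs_fit`.
#' @return Data frame with one row per fixed effect: `effect`, `chisq`,
#'   `df`, `p`.
#' @export
wald_fixed_effects <- function(fit) {
  stopifnot(inherits(fit, "hs_fit"))
  a <- car::Anova(fit$model, type = 2, test.statistic = "Chisq")
  data.frame(effect = rownames(a), chisq = a$Chisq, df = a$Df,
             p = a[["Pr(>Chisq)"]], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Fit the egg-size model, dropping a non-significant interaction
#'
#' Fits the model with the population x egg-size interaction, tests the
#' interaction with a Type-II Wald test, and refits without it when its
#' p-value exceeds `alpha`.
#'
#' @param data model data (see [fit_mixed_model()]).
#' @param spec an [model_spec()] with `include_egg = TRUE`; its
#'   `include_interaction` flag is overridden to start `TRUE`.
#' @param alpha retention threshold for the interaction (default 0.05).
#' @return List with the final `spec`, the final `fit`, the interaction fit
#'   (`fit_interaction`), `interaction_p` and `dropped`.
#' @export
drop_nonsignificant_interaction <- function(data, spec, alpha = 0.05) {
  stopifnot(inherits(spec, "hs_modelspec"))
  if (!spec$include_egg) stop_domain("`spec` must include the egg covariate")
  spec_int <- spec
  spec_int$include_interaction <- TRUE
  fit_int <- fit_mixed_model(data, spec_int)
  w <- wald_fixed_effects(fit_int)
  row <- grepl(":", w$effect)
  if (!any(row)) stop_domain("interaction term not found in the fit")
  p_int <- w$p[row][1]
  if (p_int > alpha) {
    spec_out <- spec
    spec_out$include_interaction <- FALSE
    fit_out <- fit_mixed_model(data, spec_out)
    list(spec = spec_out, fit = fit_out, fit_interaction = fit_int,
         interaction_p = p_int, dropped = TRUE)
  } else {
    list(spec = spec_int, fit = fit_int, fit_interaction = fit_int,
         interaction_p = p_int, dropped = FALSE)
  }
}

#' Narrow-sense heritability from a half-sib design
#'
#' `h^2 = 4 V_S / (V_S + V_D + V_C + V_E)`: the sire variance captures one
#' quarter of the additive genetic variance in a half-sib/full-sib design.
#' Estimates can exceed 1; they are never negative.
#'
#' @param x an `hs_fit`, an `hs_varcomp`, or a named numeric vector with
#'   `V_S`, `V_D`, (`V_C`,) `V_E`.
#' @return Numeric scalar.
#' @export
#' @examples
#' heritability(varcomp(V_S = 0.13, V_D = 0.28, V_C = 0.05, V_E = 0.54))
heritability <- function(x) {
  vc <- as_varcomp(x)
  VP <- sum(vc)
  if (VP <= 0) stop_domain("total phenotypic variance must be > 0")
  4 * vc[["V_S"]] / VP
}

#' Maternal effect from a half-sib design
#'
#' `m^2 = (V_D - V_S) / V_P`: the dam variance in excess of the sire
#' variance, as a proportion of total phenotypic variance.  Negative values
#' (sampling noise) are reported as-is with a warning.
#'
#' @inheritParams heritability
#' @return Numeric scalar.
#' @export
maternal_effect <- function(x) {
  vc <- as_varcomp(x)
  VP <- sum(vc)
  if (VP <= 0) stop_domain("total phenotypic variance must be > 0")
  m2 <- (vc[["V_D"]] - vc[["V_S"]]) / VP
  if (m2 < 0) warning("negative maternal-effect estimate", call. = FALSE)
  m2
}

# closed-form REML log-likelihood of a fixed-effects-only linear model, for
# repeated evaluation at new responses with an unchanged design matrix
reml_loglik_lm_factory <- function(X) {
  qrX <- qr(X)
  p <- qrX$rank
  logdet <- sum(log(abs(diag(qrX$qr)[seq_len(p)])))
  n <- nrow(X)
  N <- n - p
  function(y) {
    rss <- sum(qr.resid(qrX, y)^2)
    0.5 * (-N * (log(2 * pi) + 1 - log(N) + log(rss))) - logdet
  }
}

#' Simulation-based restricted likelihood ratio test for a variance component
#'
#' Tests `H0: variance of `term` = 0` in the model described by `spec`.  The
#' statistic is twice the difference in restricted log-likelihood between the
#' full model and the model without the term (floored at zero).  Its null
#' distribution is obtained by a parametric bootstrap: `nsim` response
#' vectors are simulated from the fitted null model on the same design, both
#' models are refit to each, and the p-value is the plus-one-corrected
#' proportion of simulated statistics at least as large as the observed one.
#'
#' @param data model data.
#' @param spec an [model_spec()] whose `random_terms` include `term`.
#' @param term the random term under test (`"sire"`, `"dam"` or
#'   `"container"`).
#' @param nsim number of null simulations (default 1000).
#' @param seed optional integer seed for the simulations.
#' @param fail_tol maximum tolerated fraction of failed null refits.
#' @return An object of class `hs_rlrt`: `statistic`, `p`, `nsim` (successful
#'   simulations), `n_fail`, `term`.
#' @export
rlrt_variance_component <- function(data, spec, term, nsim = 1000,
                                    seed = NULL, fail_tol = 0.05) {
  stopifnot(inherits(spec, "hs_modelspec"))
  if (!term %in% spec$random_terms) {
    stop_domain("`term` must be one of the model's random terms")
  }
  full <- fit_mixed_model(data, spec)
  red_terms <- setdiff(spec$random_terms, term)
  d <- full$data

  if (length(red_terms)) {
    spec_red <- spec
    spec_red$random_terms <- red_terms
    spec_red$temperature <- NULL
    red <- fit_mixed_model(d, spec_red)
    ll_red <- red$logLik_reml
    null_model <- red$model
    null_is_mixed <- TRUE
  } else {
    labs <- attr(terms(full$model), "term.labels")
    fixed_form <- stats::formula(
      paste(spec$trait, "~", if (length(labs)) paste(labs, collapse = " + ")
            else "1"))
    null_model <- lm(fixed_form, data = d)
    ll_red <- as.numeric(logLik(null_model, REML = TRUE))
    null_is_mixed <- FALSE
  }
  observed <- max(0, 2 * (full$logLik_reml - ll_red))

  if (!is.null(seed)) set.seed(seed)
  y_obs <- full$data[[spec$trait]]
  if (null_is_mixed) {
    ysim <- stats::simulate(null_model, nsim = nsim)
  } else {
    mu <- fitted(null_model)
    s <- sigma(null_model)  # sqrt(RSS/(n-p)), the REML-scale estimate
    ysim <- as.data.frame(matrix(mu + rnorm(length(mu) * nsim, 0, s),
                                 ncol = nsim))
  }
  ll_lm_null <- if (!null_is_mixed) {
    reml_loglik_lm_factory(model.matrix(null_model))
  } else NULL

  one_stat <- function(y) {
    llf <- as.numeric(logLik(suppressMessages(lme4::refit(full$model, y))))
    llr <- if (null_is_mixed) {
      as.numeric(logLik(suppressMessages(lme4::refit(null_model, y))))
    } else {
      ll_lm_null(y)
    }
    max(0, 2 * (llf - llr))
  }
  # recompute the observed statistic through the identical refit pathway so
  # optimizer idiosyncrasies cancel between observed and simulated values
  observed <- tryCatch(one_stat(y_obs), error = function(e) observed,
                       warning = function(w) observed)

  stats_sim <- rep(NA_real_, nsim)
  for (i in seq_len(nsim)) {
    stats_sim[i] <- tryCatch(one_stat(ysim[[i]]),
                             error = function(e) NA_real_,
                             warning = function(w) NA_real_)
  }
  n_fail <- sum(is.na(stats_sim))
  if (n_fail > fail_tol * nsim) {
    stop_domain(sprintf("null refits failed in %d/%d simulations", n_fail, nsim))
  }
  ok <- stats_sim[!is.na(stats_sim)]
  structure(
    list(statistic = observed,
         p = perm_pvalue(sum(ok >= observed), length(ok)),
         nsim = length(ok), n_fail = n_fail, term = term),
    class = "hs_rlrt")
}

#' @export
print.hs_rlrt <- function(x, ...) {
  cat(sprintf("RLRT for '%s': statistic = %.4g, simulated p = %.4g (%d sims, %d failed)\n",
              x$term, x$statistic, x$p, x$nsim, x$n_fail))
  invisible(x)
}

extract_qg_params <- function(fit) {
  vc <- fit$varcomp
  h2 <- tryCatch(heritability(vc), error = function(e) NA_real_)
  m2 <- tryCatch(suppressWarnings(maternal_effect(vc)),
                 error = function(e) NA_real_)
  c(V_S = vc[["V_S"]], V_D = vc[["V_D"]], V_C = vc[["V_C"]],
    V_E = vc[["V_E"]], h2 = h2, m2 = m2)
}

#' Within-family bootstrap of the quantitative-genetic parameters
#'
#' Each replicate resamples offspring *within every family* with replacement,
#' preserving each family's sample size exactly (so the family structure and
#' the dam-level covariates are held fixed), refits the model, and records
#' the variance components, heritability and maternal effect.  Replicates
#' whose refit fails are dropped and counted.  BCa intervals use the
#' delete-one-family jackknife for the acceleration (the family is the
#' independent sampling unit).
#'
#' @param data model data.
#' @param spec an [model_spec()].
#' @param n_iter bootstrap replicates (default 1000).
#' @param seed optional integer seed.
#' @param level confidence level for the BCa intervals.
#' @return An object of class `hs_boot`: `point` (named parameter vector),
#'   `replicates` (matrix, one row per successful replicate), `jackknife`,
#'   `ci` (data frame: parameter, estimate, lower, upper), `n_iter`,
#'   `n_fail`.
#' @export
family_bootstrap <- function(data, spec, n_iter = 1000, seed = NULL,
                             level = 0.95) {
  if (n_iter < 2) stop_domain("`n_iter` must be >= 2")
  point_fit <- fit_mixed_model(data, spec)
  d <- point_fit$data
  spec2 <- spec
  spec2$temperature <- NULL  # d is already subset
  point <- extract_qg_params(point_fit)

  idx_by_fam <- split(seq_len(nrow(d)), d$family)
  if (!is.null(seed)) set.seed(seed)

  one_rep <- function() {
    idx <- unlist(lapply(idx_by_fam, function(ix) {
      ix[sample.int(length(ix), length(ix), replace = TRUE)]
    }), use.names = FALSE)
    tryCatch(extract_qg_params(fit_mixed_model(d[idx, , drop = FALSE], spec2)),
             error = function(e) NULL)
  }
  reps <- vector("list", n_iter)
  for (i in seq_len(n_iter)) reps[[i]] <- one_rep()
  failed <- vapply(reps, is.null, logical(1))
  if (all(failed)) stop_domain("all bootstrap refits failed")
  repmat <- do.call(rbind, reps[!failed])

  fams <- names(idx_by_fam)
  jack <- matrix(NA_real_, length(fams), length(point),
                 dimnames = list(fams, names(point)))
  for (f in seq_along(fams)) {
    dj <- d[d$family != fams[f], , drop = FALSE]
    jack[f, ] <- tryCatch(extract_qg_params(fit_mixed_model(dj, spec2)),
                          error = function(e) rep(NA_real_, length(point)))
  }

  ci <- do.call(rbind, lapply(names(point), function(pn) {
    reps_p <- repmat[, pn]
    reps_p <- reps_p[!is.na(reps_p)]
    jk <- jack[, pn]; jk <- jk[!is.na(jk)]
    bounds <- suppressWarnings(
      bca_interval(reps_p, point[[pn]],
                   jackknife_estimates = if (length(jk) >= 2) jk else NULL,
                   level = level))
    data.frame(parameter = pn, estimate = point[[pn]],
               lower = bounds[["lower"]], upper = bounds[["upper"]],
               stringsAsFactors = FALSE)
  }))
  structure(
    list(point = point, replicates = repmat, jackknife = jack, ci = ci,
         n_iter = n_iter, n_fail = sum(failed), level = level, spec = spec),
    class = "hs_boot")
}

#' @export
print.hs_boot <- function(x, ...) {
  cat(sprintf("Within-family bootstrap: %d replicates (%d failed), %.0f%% BCa intervals\n",
              x$n_iter, x$n_fail, 100 * x$level))
  print(x$ci, row.names = FALSE)
  invisible(x)
}

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' The bias correction `z0` is the normal quantile of the proportion of
#' replicates below the point estimate; the acceleration `a` is the
#' jackknife skewness `sum(u^3) / (6 * sum(u^2)^1.5)` with
#' `u = mean(jack) - jack`.  Adjusted percentile levels are clipped to
#' `[1/(B+1), B/(B+1)]`.
#'
#' @param replicates numeric vector of bootstrap replicate estimates.
#' @param point_estimate the estimate on the original data.
#' @param jackknife_estimates optional leave-one-out estimates; when absent,
#'   the acceleration is 0 (bias-corrected percentile interval).
#' @param level confidence level (default 0.95).
#' @return Named numeric `c(lower, upper)` with attributes `z0` and
#'   `acceleration`.
#' @export
bca_interval <- function(replicates, point_estimate,
                         jackknife_estimates = NULL, level = 0.95) {
  reps <- replicates[!is.na(replicates)]
  B <- length(reps)
  if (B < 2) stop_domain("need at least 2 bootstrap replicates")
  if (B < 100) {
    warning("fewer than 100 bootstrap replicates; BCa interval will be crude",
            call. = FALSE)
  }
  if (max(reps) - min(reps) == 0) {
    warning("degenerate bootstrap distribution; interval collapses to the point",
            call. = FALSE)
    out <- c(lower = point_estimate, upper = point_estimate)
    attr(out, "z0") <- 0; attr(out, "acceleration") <- 0
    return(out)
  }
  # ties with the point estimate count half, so a symmetric bootstrap
  # distribution gives exactly zero bias correction
  prop <- (sum(reps < point_estimate) + 0.5 * sum(reps == point_estimate)) / B
  prop <- min(max(prop, 1 / B), 1 - 1 / B)  # keep z0 finite at the extremes
  z0 <- qnorm(prop)
  a <- 0
  if (!is.null(jackknife_estimates)) {
    jk <- jackknife_estimates[!is.na(jackknife_estimates)]
    u <- mean(jk) - jk
    denom <- sum(u^2)
    if (denom > 0) a <- sum(u^3) / (6 * denom^1.5)
  }
  alpha <- (1 - level) / 2
  adj <- function(al) {
    z <- qnorm(al)
    p <- pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
    min(max(p, 1 / (B + 1)), B / (B + 1))
  }
  out <- c(lower = quantile(reps, adj(alpha), names = FALSE, type = 6),
           upper = quantile(reps, adj(1 - alpha), names = FALSE, type = 6))
  attr(out, "z0") <- z0
  attr(out, "acceleration") <- a
  out
}

#' Compare parameters before vs after the egg-size covariate
#'
#' Reports, per parameter, the absolute and percent change of the point
#' estimate and flags the change significant when the two BCa intervals do
#' not overlap.  Percent change is reported as a *reduction* (positive when
#' the parameter decreased after including egg size).
#'
#' @param result_before,result_after `hs_boot` objects for the same trait
#'   fitted without / with the egg covariate.
#' @return Data frame: `parameter`, `before`, `after`, `change`,
#'   `pct_reduction`, `lower/upper` for both, `significant`.
#' @export
compare_before_after <- function(result_before, result_after) {
  stopifnot(inherits(result_before, "hs_boot"), inherits(result_after, "hs_boot"))
  cb <- result_before$ci; ca <- result_after$ci
  params <- intersect(cb$parameter, ca$parameter)
  out <- do.call(rbind, lapply(params, function(pn) {
    b <- cb[cb$parameter == pn, ]; a <- ca[ca$parameter == pn, ]
    no_overlap <- (a$lower > b$upper) || (b$lower > a$upper)
    data.frame(parameter = pn, before = b$estimate, after = a$estimate,
               change = a$estimate - b$estimate,
               pct_reduction = if (b$estimate != 0)
                 100 * (b$estimate - a$estimate) / b$estimate else NA_real_,
               lower_before = b$lower, upper_before = b$upper,
               lower_after = a$lower, upper_after = a$upper,
               significant = no_overlap, stringsAsFactors = FALSE)
  }))
  class(out) <- c("hs_change", "data.frame")
  out
}
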