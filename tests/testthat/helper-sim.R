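# Balanced nested half-sib dataset generated directly from the linear model,
# independent of the package's own simulator.  One population; egg diameter
# is a dam-level covariate with slope beta_egg.
make_nested_data <- function(n_sires, n_dams = 2, n_off = 10,
                             V_S = 1, V_D = 1, V_E = 1, mu = 10,
                             beta_egg = 0, egg_mu = 7, egg_sd = 0.45,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_d_tot <- n_sires * n_dams
  sire_of <- rep(seq_len(n_sires), each = n_dams * n_off)
  dam_of <- rep(seq_len(n_d_tot), each = n_off)
  s_eff <- rnorm(n_sires, 0, sqrt(V_S))
  d_eff <- rnorm(n_d_tot, 0, sqrt(V_D))
  egg <- rnorm(n_d_tot, egg_mu, egg_sd)
  y <- mu + beta_egg * egg[dam_of] + s_eff[sire_of] + d_eff[dam_of] +
    rnorm(length(sire_of), 0, sqrt(V_E))
  data.frame(population = "P1",
             sire = sprintf("S%03d", sire_of),
             dam = sprintf("D%03d", dam_of),
             family = sprintf("D%03d", dam_of),
             egg_diameter_mm = egg[dam_of],
             y = y, stringsAsFactors = FALSE)
}

# Closed-form expected-mean-squares estimators for the balanced two-level
# nested random-effects ANOVA (sires / dams-in-sires / offspring): the
# independent oracle for REML on balanced designs with interior estimates.
anova_ems_varcomp <- function(d, n_dams, n_off) {
  ybar <- mean(d$y)
  sire_means <- tapply(d$y, d$sire, mean)
  dam_means <- tapply(d$y, d$dam, mean)
  dam_sire <- tapply(d$sire, d$dam, `[`, 1)
  s <- length(sire_means)
  ms_sire <- n_dams * n_off * sum((sire_means - ybar)^2) / (s - 1)
  ms_dam <- n_off *
    sum((dam_means - sire_means[dam_sire])^2) / (s * (n_dams - 1))
  dam_of_row <- d$dam
  mse <- sum((d$y - dam_means[dam_of_row])^2) / (s * n_dams * (n_off - 1))
  c(V_S = (ms_sire - ms_dam) / (n_dams * n_off),
    V_D = (ms_dam - mse) / n_off,
    V_E = mse)
}

# single-trait generator config built on the package's simulator
one_trait_params <- function(pop = "P", temp = 9.4, mu = 10, beta_egg = 0,
                             V_S = 0.1, V_D_resid = 0.2, V_C = 0, V_E = 0.5,
                             egg_mu = 7, egg_sd = 0.4, seed = 1) {
  blk <- list(mu = mu, beta_egg = beta_egg, V_S = V_S, V_D_resid = V_D_resid,
              V_C = V_C, V_E = V_E)
  traits <- list(y = setNames(list(blk), formatC(temp, format = "g")))
  sim_params(egg_mu = setNames(egg_mu, pop), egg_sd = egg_sd,
             female_length_mu = 800, female_length_sd = 60,
             length_egg_slope = 0, survival_prob = 1,
             traits = traits, seed = seed)
}

sim_one_trait <- function(n_sires, n_off_per_container, n_containers = 2,
                          temp = 9.4, seed = 1, ...) {
  spec <- design_spec(populations = setNames(n_sires, "P"),
                      dams_per_sire = 2,
                      eggs_per_container = n_off_per_container,
                      containers_per_family_per_temp = n_containers,
                      temperatures = temp)
  params <- one_trait_params(temp = temp, seed = seed, ...)
  ped <- build_design(spec, params)
  simulate_offspring(ped, spec, params)
}
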