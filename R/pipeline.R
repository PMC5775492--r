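offspring_required_cols <- c("population", "sire", "dam", "family",
                             "temperature", "egg_diameter_mm")
dam_required_cols <- c("population", "sire", "dam", "egg_diameter_mm",
                       "fork_length_mm")

validate_offspring <- function(off) {
  miss <- setdiff(offspring_required_cols, names(off))
  if (length(miss)) {
    stop_domain("offspring table missing column(s): ",
                paste(miss, collapse = ", "))
  }
  trait_cols <- intersect(
    c("hatch_length_mm", "yolk_length_mm", "yolk_height_mm",
      "swimup_length_mm", "juvenile_length_mm"), names(off))
  drop <- rep(FALSE, nrow(off))
  if (length(trait_cols)) {
    for (col in trait_cols) {
      bad <- !is.na(off[[col]]) & off[[col]] < 0
      drop <- drop | bad
    }
  }
  bad_egg <- is.na(off$egg_diameter_mm) | off$egg_diameter_mm <= 0
  drop <- drop | bad_egg
  if (any(drop)) {
    warning(sum(drop), " offspring row(s) dropped (negative lengths or ",
            "invalid egg diameter)", call. = FALSE)
    off <- off[!drop, , drop = FALSE]
  }
  ns <- tapply(off$sire, off$dam, function(s) length(unique(s)))
  if (any(ns > 1)) {
    stop_domain("dam label(s) under more than one sire: ",
                paste(head(names(ns)[ns > 1]), collapse = ", "))
  }
  off
}

validate_dams <- function(dams) {
  miss <- setdiff(dam_required_cols, names(dams))
  if (length(miss)) {
    stop_domain("dam table missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- is.na(dams$egg_diameter_mm) | dams$egg_diameter_mm <= 0 |
    (!is.na(dams$fork_length_mm) & dams$fork_length_mm <= 0)
  if (any(bad)) {
    warning(sum(bad), " dam row(s) dropped (invalid measurements)",
            call. = FALSE)
    dams <- dams[!bad, , drop = FALSE]
  }
  dams
}

#' Read and validate the offspring and dam phenotype tables
#'
#' Reads the two delimited tables (comma-separated, header row; leading
#' `#` comment lines are ignored), validates the required columns, drops
#' rows failing validation with a warning, and checks the dam-in-sire
#' nesting.
#'
#' @param offspring_path path to the offspring CSV (columns `population`,
#'   `sire`, `dam`, `family`, `temperature`, `egg_diameter_mm` and the trait
#'   columns).
#' @param dam_path path to the dam CSV (columns `population`, `sire`, `dam`,
#'   `egg_diameter_mm`, `fork_length_mm`).
#' @return List with validated `offspring` and `dams` data frames.
#' @export
read_phenotype_tables <- function(offspring_path, dam_path) {
  for (p in c(offspring_path, dam_path)) {
    if (!file.exists(p)) stop_domain("file not found: ", p)
    if (file.size(p) == 0) stop_domain("empty file: ", p)
  }
  off <- read.csv(offspring_path, comment.char = "#",
                  stringsAsFactors = FALSE)
  dams <- read.csv(dam_path, comment.char = "#", stringsAsFactors = FALSE)
  if (!nrow(off)) stop_domain("offspring table has no rows")
  list(offspring = validate_offspring(off), dams = validate_dams(dams))
}

#' Configuration for the end-to-end analysis pipeline
#'
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param out_dir output directory (`NULL` = write nothing).
#' @param offspring_path,dam_path optional input tables; when absent, a
#'   synthetic experiment is generated with [simulate_chinook_study()].
#' @param qg_traits individual-level traits for the quantitative-genetic
#'   comparison (before/after egg size).
#' @param mva_traits family-level trait columns for the multivariate stage
#'   (defaults to the derived family table's stage and growth traits).
#' @param n_boot bootstrap replicates per model (default 1000).
#' @param rlrt_nsim null simulations for the variance-component tests
#'   (0 skips them).
#' @param n_perm permutations for the multivariate tests.
#' @param g generations separated, for haldane rates.
#' @param temperatures subset of temperature treatments to analyse (`NULL` =
#'   all in the data).
#' @return A list of class `hs_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL,
                            offspring_path = NULL, dam_path = NULL,
                            qg_traits = c("hatch_length_mm", "swimup_length_mm"),
                            mva_traits = NULL,
                            n_boot = 1000, rlrt_nsim = 0, n_perm = 999,
                            g = 10, temperatures = NULL) {
  if (n_boot < 2 || n_perm < 1 || rlrt_nsim < 0 || g <= 0) {
    stop_domain("counts must be positive (`n_boot` >= 2)")
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 offspring_path = offspring_path, dam_path = dam_path,
                 qg_traits = qg_traits, mva_traits = mva_traits,
                 n_boot = n_boot, rlrt_nsim = rlrt_nsim, n_perm = n_perm,
                 g = g, temperatures = temperatures),
            class = "hs_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_domain(sprintf("[stage %s] %s", name, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes, deterministically under the configured seed: data loading or
#' synthesis, family-level trait derivation, the egg-size ANOVA/ANCOVA,
#' per-temperature variance-component models before/after egg size with
#' within-family bootstrap comparison, fixed-effect variance partitioning,
#' divergence rates with and without egg-size control, and the multivariate
#' stage (nMDS, overall and pairwise PERMANOVA, dispersion homogeneity,
#' Mantel correlation of trait vs egg-size distances).  All machine-readable
#' results are written to `out_dir` (JSON; summary tables as CSV), stamped
#' with the seed and configuration fingerprint.
#'
#' @param config an [pipeline_config()].
#' @return A list of class `hs_report` holding every stage's results plus
#'   seeds, package version, timestamp, and accumulated warnings.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "hs_config"))
  warnings_log <- character()
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))

  data <- pipeline_stage("data", {
    if (!is.null(config$offspring_path)) {
      td <- read_phenotype_tables(config$offspring_path, config$dam_path)
      list(offspring = td$offspring, dams = td$dams)
    } else {
      sim <- simulate_chinook_study(seed = config$seed)
      list(offspring = sim$offspring, dams = sim$pedigree)
    }
  })
  for (tr in config$qg_traits) {
    if (!tr %in% names(data$offspring)) {
      stop_domain("[stage data] unknown trait column: ", tr)
    }
  }

  fam <- pipeline_stage("traits", family_trait_table(data$offspring))
  eggcmp <- pipeline_stage("egg_size", compare_egg_size(data$dams))

  temps <- config$temperatures %||% sort(unique(data$offspring$temperature))
  container_traits <- c("hatch_length_mm", "yolk_length_mm", "yolk_height_mm")

  qg <- list(); partitions <- list(); divergence <- list(); mva <- list()
  for (tmp in temps) {
    tl <- temp_label(tmp)
    qg[[tl]] <- list()
    partitions[[tl]] <- list()
    for (tr in config$qg_traits) {
      rand <- if (tr %in% container_traits &&
                  "container" %in% names(data$offspring))
        c("sire", "dam", "container") else c("sire", "dam")
      spec_b <- model_spec(tr, include_egg = FALSE, random_terms = rand,
                           temperature = tmp)
      spec_a <- model_spec(tr, include_egg = TRUE, random_terms = rand,
                           temperature = tmp)
      res <- pipeline_stage(paste0("varcomp:", tr, "@", tl), {
        boot_b <- family_bootstrap(data$offspring, spec_b,
                                   n_iter = config$n_boot,
                                   seed = config$seed + 11L)
        sel <- drop_nonsignificant_interaction(data$offspring, spec_a)
        boot_a <- family_bootstrap(data$offspring, sel$spec,
                                   n_iter = config$n_boot,
                                   seed = config$seed + 13L)
        rl <- NULL
        if (config$rlrt_nsim > 0) {
          rl <- list(
            sire = rlrt_variance_component(data$offspring, spec_b, "sire",
                                           nsim = config$rlrt_nsim,
                                           seed = config$seed + 17L),
            dam = rlrt_variance_component(data$offspring, spec_b, "dam",
                                          nsim = config$rlrt_nsim,
                                          seed = config$seed + 19L))
        }
        list(before = boot_b, after = boot_a,
             interaction_p = sel$interaction_p,
             interaction_dropped = sel$dropped,
             change = compare_before_after(boot_b, boot_a), rlrt = rl)
      })
      qg[[tl]][[tr]] <- res
      partitions[[tl]][[tr]] <- pipeline_stage(paste0("partition:", tr, "@", tl), {
        if (res$interaction_dropped) {
          fit_b <- fit_mixed_model(data$offspring, spec_b)
          spec_a2 <- spec_a; spec_a2$include_interaction <- FALSE
          fit_a <- fit_mixed_model(data$offspring, spec_a2)
          list(before = variance_partition(fit_b),
               after = variance_partition(fit_a), excluded = FALSE)
        } else {
          note("trait %s at %s excluded from partition (interaction)", tr, tl)
          list(before = NULL, after = NULL, excluded = TRUE)
        }
      })
    }

    fam_t <- fam[fam$temperature == tmp, , drop = FALSE]
    div_traits <- intersect(
      c("hatch_length_mm", "yolk_volume_mm3", "swimup_length_mm",
        "juvenile_length_mm", "ysce", "growth_hatch_swimup",
        "growth_swimup_juvenile"),
      names(fam_t)[colSums(!is.na(fam_t)) > 0])
    div_traits <- div_traits[vapply(div_traits, function(tr)
      sum(!is.na(fam_t[[tr]])) >= 4, logical(1))]
    divergence[[tl]] <- pipeline_stage(paste0("divergence@", tl), {
      raw <- divergence_suite(fam_t, div_traits, g = config$g,
                              control_egg = FALSE)
      ctl <- divergence_suite(fam_t, div_traits, g = config$g,
                              control_egg = TRUE)
      both <- rbind(raw, ctl)
      list(rates = both, summary = divergence_summary(both))
    })

    mva[[tl]] <- pipeline_stage(paste0("multivariate@", tl), {
      mtraits <- config$mva_traits %||% div_traits
      mm <- fam_t[, mtraits, drop = FALSE]
      keep <- complete.cases(mm)
      mm <- mm[keep, , drop = FALSE]
      grp <- fam_t$population[keep]
      z <- zscore_matrix(mm)
      rownames(z) <- fam_t$family[keep]
      dmat <- euclidean_distances(z)
      em <- matrix(fam_t$egg_diameter_mm[keep],
                   dimnames = list(fam_t$family[keep], "egg"))
      degg <- dist(em)
      overall <- permanova(dmat, grp, n_perm = config$n_perm,
                           seed = config$seed + 23L)
      list(traits = mtraits,
           nmds = nmds_ordination(dmat, k = 2, seed = config$seed + 29L),
           permanova = overall,
           pairwise = if (overall$p <= 0.05)
             pairwise_permanova(dmat, grp, n_perm = config$n_perm,
                                seed = config$seed + 31L) else NULL,
           dispersion = dispersion_homogeneity(dmat, grp,
                                               n_perm = config$n_perm,
                                               seed = config$seed + 37L),
           mantel = mantel_test(dmat, degg, n_perm = config$n_perm,
                                seed = config$seed + 41L))
    })
  }

  report <- structure(
    list(config = config, egg_size = eggcmp, family_traits = fam,
         qg = qg, partitions = partitions, divergence = divergence,
         multivariate = mva,
         seed = config$seed,
         fingerprint = config_fingerprint(unclass(config)),
         version = as.character(packageVersion("halfsibqg")),
         timestamp = format(Sys.time(), tz = "UTC"),
         warnings = warnings_log),
    class = "hs_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.hs_report <- function(x, ...) {
  cat("halfsibqg pipeline report (seed", x$seed, ", config", x$fingerprint, ")\n")
  cat("  temperatures:", paste(names(x$qg), collapse = ", "), "\n")
  cat("  QG traits:", paste(x$config$qg_traits, collapse = ", "), "\n")
  if (length(x$warnings)) cat("  notes:", length(x$warnings), "\n")
  invisible(x)
}

report_json_payload <- function(report) {
  strip <- function(x) {
    if (inherits(x, "hs_boot")) {
      return(list(point = as.list(x$point), ci = x$ci, n_iter = x$n_iter,
                  n_fail = x$n_fail))
    }
    if (inherits(x, c("hs_permtest", "hs_rlrt", "hs_partition"))) {
      return(unclass(x))
    }
    if (inherits(x, "hs_nmds")) {
      return(list(stress = x$stress, acceptable = x$acceptable, k = x$k))
    }
    if (inherits(x, "hs_eggsize")) return(unclass(x))
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, strip))
    x
  }
  list(meta = list(seed = report$seed, fingerprint = report$fingerprint,
                   version = report$version, timestamp = report$timestamp),
       egg_size = strip(report$egg_size),
       qg = strip(report$qg),
       partitions = strip(report$partitions),
       divergence = strip(report$divergence),
       multivariate = strip(report$multivariate),
       warnings = report$warnings)
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_json_payload(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, na = "null")
  stamp <- sprintf("# halfsibqg seed=%d config=%s", report$seed,
                   report$fingerprint)
  # wide before/after parameter summary, one row per trait x temperature
  rows <- list()
  for (tl in names(report$qg)) {
    for (tr in names(report$qg[[tl]])) {
      ch <- report$qg[[tl]][[tr]]$change
      for (i in seq_len(nrow(ch))) {
        rows[[length(rows) + 1L]] <- data.frame(
          temperature = tl, trait = tr, parameter = ch$parameter[i],
          before = ch$before[i], after = ch$after[i],
          pct_reduction = ch$pct_reduction[i],
          significant = ch$significant[i], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) {
    con <- file(file.path(dir, "qg_summary.csv"), "w")
    writeLines(stamp, con)
    write.csv(do.call(rbind, rows), con, row.names = FALSE)
    close(con)
  }
  div <- do.call(rbind, lapply(names(report$divergence), function(tl) {
    d <- report$divergence[[tl]]$rates
    d$temperature <- tl
    d
  }))
  if (!is.null(div)) {
    con <- file(file.path(dir, "divergence_rates.csv"), "w")
    writeLines(stamp, con)
    write.csv(div, con, row.names = FALSE)
    close(con)
  }
  invisible(dir)
}
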