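#' Standardize trait columns to z-scores
#'
#' Columns are centered and scaled to unit (n-1) standard deviation prior to
#' computing Euclidean distances, so every trait contributes on a common
#' scale.
#'
#' @param x numeric matrix or data frame of traits (rows = samples).
#' @return Matrix of the same shape with column means 0 and SDs 1.
#' @export
zscore_matrix <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop_domain("all trait columns must be numeric")
  sds <- apply(m, 2, sd)
  bad <- which(sds == 0 | is.na(sds))
  if (length(bad)) {
    stop_domain("zero-variance trait column(s): ",
                paste(colnames(m)[bad] %||% bad, collapse = ", "))
  }
  scale(m, center = TRUE, scale = sds)
}

#' Euclidean distance matrix over trait rows
#'
#' Rows with missing values are dropped (with a message stating how many).
#'
#' @param x numeric matrix or data frame (rows = samples; row names become
#'   the distance labels).
#' @return A `stats::dist` object with attribute `metric = "euclidean"`.
#' @export
euclidean_distances <- function(x) {
  m <- as.matrix(x)
  cc <- complete.cases(m)
  if (!all(cc)) {
    message(sum(!cc), " row(s) with missing traits dropped")
    m <- m[cc, , drop = FALSE]
  }
  if (nrow(m) < 3) stop_domain("need at least 3 complete rows")
  d <- dist(m, method = "euclidean")
  attr(d, "metric") <- "euclidean"
  d
}

#' Nonmetric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 minimization (iterative monotone regression) from
#' multiple random starts, via \pkg{vegan}.  Stress is on the 0--1 scale; an
#' ordination is flagged acceptable when stress <= 0.15 (values above the
#' threshold are flagged, not rejected).
#'
#' @param d a `dist` object.
#' @param k target dimensionality (default 2); requires `n >= k + 2`.
#' @param n_restarts random starts (default 20).
#' @param seed optional integer seed; the same seed gives the same result.
#' @return An object of class `hs_nmds`: `points` (n x k configuration,
#'   centered), `stress`, `acceptable`, `converged`, `k`, `n_restarts`.
#' @export
nmds_ordination <- function(d, k = 2, n_restarts = 20, seed = NULL) {
  n <- attr(d, "Size")
  if (is.null(n)) stop_domain("`d` must be a dist object")
  if (n < k + 2) stop_domain("need n >= k + 2 samples")
  if (!is.null(seed)) set.seed(seed)
  ord <- vegan::metaMDS(d, k = k, try = n_restarts, trymax = n_restarts,
                        autotransform = FALSE, wascores = FALSE, trace = 0)
  structure(
    list(points = vegan::scores(ord, display = "sites"),
         stress = ord$stress,
         acceptable = ord$stress <= 0.15,
         converged = isTRUE(ord$converged) || (is.numeric(ord$converged) && ord$converged > 0),
         k = k, n_restarts = n_restarts),
    class = "hs_nmds")
}

#' @export
print.hs_nmds <- function(x, ...) {
  cat(sprintf("nMDS (k = %d): stress = %.4f (%s), %d random starts\n",
              x$k, x$stress,
              if (x$acceptable) "acceptable, <= 0.15" else "above 0.15",
              x$n_restarts))
  invisible(x)
}

permanova_stats <- function(d2, groups) {
  # d2: full squared-distance matrix; sums over unordered pairs
  N <- nrow(d2)
  a <- nlevels(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_among <- ss_total - ss_within
  f <- (ss_among / (a - 1)) / (ss_within / (N - a))
  c(F = f, R2 = ss_among / ss_total, ss_total = ss_total)
}

all_permutations <- function(n) {
  # all n! orderings of 1..n; intended for small n only
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1L)
    for (p in rest) {
      v <- c(i, ifelse(p >= i, p + 1L, p))
      out[[length(out) + 1L]] <- as.integer(v)
    }
  }
  out
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Pseudo-F from the partition of squared inter-point distances:
#' `SS_total = sum_{i<j} d_ij^2 / N`, `SS_within = sum_g sum_{i<j in g}
#' d_ij^2 / n_g`, `SS_among = SS_total - SS_within`,
#' `F = (SS_among/(a-1)) / (SS_within/(N-a))`, `R^2 = SS_among/SS_total`.
#' The p-value permutes the group labels freely, with the plus-one
#' correction; with `exhaustive = TRUE` every permutation is enumerated and
#' the p-value is the exact fraction (including the identity) with
#' `F >= F_obs`.
#'
#' @param d a `dist` object.
#' @param groups factor (or coercible) of group labels, one per sample;
#'   >= 2 groups with >= 2 samples each.
#' @param n_perm number of label permutations (default 999).
#' @param seed optional integer seed.
#' @param exhaustive enumerate all permutations (only for small n).
#' @return An object of class `hs_permtest` with `statistic` (pseudo-F),
#'   `R2`, `p`, `n_perm`, `method`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL,
                      exhaustive = FALSE) {
  groups <- factor(groups)
  m <- as.matrix(d)
  if (nrow(m) != length(groups)) stop_domain("`groups` length must match `d`")
  if (nlevels(groups) < 2) stop_domain("need >= 2 groups")
  if (any(table(groups) < 2)) stop_domain("every group needs >= 2 samples")
  d2 <- m^2
  obs <- permanova_stats(d2, groups)
  if (obs[["ss_total"]] <= 0) stop_domain("all samples identical (SS_total = 0)")

  if (exhaustive) {
    n <- length(groups)
    if (n > 9) stop_domain("exhaustive enumeration limited to n <= 9")
    perms <- all_permutations(n)
    fs <- vapply(perms, function(p) permanova_stats(d2, groups[p])[["F"]],
                 numeric(1))
    p_val <- mean(fs >= obs[["F"]])
    n_perm <- length(perms)
    method <- "permanova (exhaustive)"
  } else {
    if (!is.null(seed)) set.seed(seed)
    count <- 0L
    for (i in seq_len(n_perm)) {
      f_i <- permanova_stats(d2, sample(groups))[["F"]]
      if (f_i >= obs[["F"]]) count <- count + 1L
    }
    p_val <- perm_pvalue(count, n_perm)
    method <- "permanova"
  }
  structure(
    list(statistic = unname(obs[["F"]]), R2 = unname(obs[["R2"]]),
         p = p_val, n_perm = n_perm, method = method,
         df = c(nlevels(groups) - 1L, length(groups) - nlevels(groups))),
    class = "hs_permtest")
}

#' @export
print.hs_permtest <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g (%d permutations)\n",
              x$method, x$statistic,
              if (!is.null(x$R2)) sprintf(", R2 = %.3f", x$R2) else "",
              x$p, x$n_perm))
  invisible(x)
}

#' Pairwise PERMANOVA over all group pairs
#'
#' Runs [permanova()] on the sub-distance-matrix of every unordered pair of
#' groups (for Euclidean input, subsetting the matrix equals recomputing
#' distances on the subset).  Intended as the follow-up to a significant
#' overall test.
#'
#' @inheritParams permanova
#' @return Data frame: `group1`, `group2`, `F`, `R2`, `p`, `n_perm`.
#' @export
pairwise_permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  groups <- factor(groups)
  m <- as.matrix(d)
  prs <- utils::combn(levels(groups), 2, simplify = FALSE)
  if (!is.null(seed)) set.seed(seed)
  out <- do.call(rbind, lapply(prs, function(pr) {
    idx <- which(groups %in% pr)
    res <- permanova(as.dist(m[idx, idx]), droplevels(groups[idx]),
                     n_perm = n_perm, seed = NULL)
    data.frame(group1 = pr[1], group2 = pr[2], F = res$statistic,
               R2 = res$R2, p = res$p, n_perm = res$n_perm,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Permutation test for homogeneity of multivariate dispersion
#'
#' The multivariate analogue of Levene's test: distances from each sample to
#' its group centroid are computed in a principal-coordinate embedding of the
#' distance matrix (exact for Euclidean input), and the one-way ANOVA F on
#' those distances is compared to its permutation distribution.  Implemented
#' via [vegan::betadisper()] and [vegan::permutest.betadisper()].
#'
#' @inheritParams permanova
#' @return An `hs_permtest` with `statistic` (F) and permutation `p`.
#' @export
dispersion_homogeneity <- function(d, groups, n_perm = 999, seed = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_domain("need >= 2 groups")
  if (any(table(groups) < 2)) stop_domain("every group needs >= 2 samples")
  bd <- vegan::betadisper(d, groups, type = "centroid")
  if (!is.null(seed)) set.seed(seed)
  pt <- suppressMessages(vegan::permutest(bd, permutations = n_perm))
  tab <- pt$tab
  structure(
    list(statistic = tab$F[1], R2 = NULL, p = tab[1, "Pr(>F)"],
         n_perm = n_perm, method = "dispersion homogeneity",
         df = tab$Df[1:2]),
    class = "hs_permtest")
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle distance vectors; significance
#' by simultaneously permuting the rows and columns of the second matrix,
#' one-sided for positive association, with the plus-one correction.
#'
#' @param d1,d2 `dist` objects on the same samples in the same order.
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed.
#' @return An `hs_permtest` with `statistic` (r) and `p`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!identical(dim(m1), dim(m2))) stop_domain("distance matrices differ in size")
  n <- nrow(m1)
  if (n < 4) stop_domain("need at least 4 samples")
  l1 <- !is.null(rownames(m1)); l2 <- !is.null(rownames(m2))
  if (l1 && l2 && !identical(rownames(m1), rownames(m2))) {
    stop_domain("distance matrices have mismatched sample labels")
  }
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  if (sd(v1) == 0 || sd(m2[lt]) == 0) {
    stop_domain("constant lower triangle; Mantel r undefined")
  }
  r_obs <- cor(v1, m2[lt])
  if (!is.null(seed)) set.seed(seed)
  count <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n)
    if (cor(v1, m2[idx, idx][lt]) >= r_obs) count <- count + 1L
  }
  structure(
    list(statistic = r_obs, R2 = NULL, p = perm_pvalue(count, n_perm),
         n_perm = n_perm, method = "mantel", df = NULL),
    class = "hs_permtest")
}
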