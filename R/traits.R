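#' Yolk sac volume from length and height
#'
#' The yolk sac is modelled as a prolate spheroid:
#' `V = (pi/6) * L * H^2`, with `L` the yolk sac length (mm) and `H` its
#' height (mm).
#'
#' @param L yolk sac length, mm (vectorized).
#' @param H yolk sac height, mm.
#' @return Volume in mm^3.
#' @export
#' @examples
#' yolk_sac_volume(6, 2)  # 4*pi
yolk_sac_volume <- function(L, H) {
  if (any(L < 0, na.rm = TRUE) || any(H < 0, na.rm = TRUE)) {
    stop_domain("yolk sac dimensions must be non-negative")
  }
  (pi / 6) * L * H^2
}

#' Yolk sac conversion efficiency
#'
#' Length gained between hatch and swim-up per unit of yolk volume:
#' `Y = (L_S - L_H) / V`.  Negative values (shrinkage between the stages)
#' are permitted and returned as-is with a warning.
#'
#' @param L_S swim-up standard length, mm.
#' @param L_H hatch standard length, mm.
#' @param V yolk sac volume, mm^3 (must be > 0).
#' @return Efficiency in mm/mm^3.
#' @export
yolk_conversion_efficiency <- function(L_S, L_H, V) {
  if (any(V <= 0, na.rm = TRUE)) stop_domain("yolk volume must be > 0")
  y <- (L_S - L_H) / V
  if (any(y < 0, na.rm = TRUE)) {
    warning("negative conversion efficiency (swim-up length below hatch length)",
            call. = FALSE)
  }
  y
}

#' Growth rate on the degree-day scale
#'
#' `G = (L2 - L1) / delta_D`: change in standard length between two life
#' history stages per growing degree-day.
#'
#' @param L2 length at the later stage, mm.
#' @param L1 length at the earlier stage, mm.
#' @param delta_D growing degree-days between the stages (> 0).
#' @return Growth rate, mm per degree-day.
#' @export
#' @examples
#' growth_rate(40, 30, 300)
growth_rate <- function(L2, L1, delta_D) {
  if (any(delta_D <= 0, na.rm = TRUE)) stop_domain("`delta_D` must be > 0")
  (L2 - L1) / delta_D
}

#' Accumulated degree-days over a calendar window
#'
#' Growing degree-days are the cumulative sum of mean daily water
#' temperature.  The window is half-open on calendar days -- inclusive of
#' `start`, exclusive of `end` -- which makes accumulation exactly additive:
#' `degree_days(s, a, b) + degree_days(s, b, c) == degree_days(s, a, c)`.
#'
#' @param series data frame with columns `date` (Date or coercible) and
#'   `temp_c` (mean daily temperature, deg C); dates strictly increasing.
#' @param start,end window bounds (Dates or coercible); `start <= end`, both
#'   within the series range (`end` may be one day past the last date).
#' @return Degree-days (numeric scalar); 0 for an empty window.
#' @export
degree_days <- function(series, start, end) {
  if (!all(c("date", "temp_c") %in% names(series))) {
    stop_domain("`series` needs columns `date` and `temp_c`")
  }
  dates <- as.Date(series$date)
  if (any(diff(as.numeric(dates)) <= 0)) {
    stop_domain("series dates must be strictly increasing")
  }
  start <- as.Date(start); end <- as.Date(end)
  if (start > end) stop_domain("`start` must be <= `end`")
  if (start < min(dates) || end > max(dates) + 1) {
    stop_domain("window outside the temperature series range")
  }
  sum(series$temp_c[dates >= start & dates < end])
}

#' Aggregate offspring measurements to family-level derived traits
#'
#' Computes, per family x temperature, the family mean of each stage length,
#' the mean yolk sac volume, the yolk sac conversion efficiency from the
#' family mean lengths, and the degree-day growth rates (hatch to swim-up,
#' swim-up to juvenile).  Family means are the aggregation for the derived
#' growth traits; the degree-day intervals are family-specific when the
#' offspring table carries them.
#'
#' @param offspring offspring table as produced by [simulate_offspring()]
#'   (or read with [read_phenotype_tables()]), with columns `population`,
#'   `sire`, `dam`, `family`, `temperature`, `egg_diameter_mm` and the stage
#'   measurement columns `hatch_length_mm`, `yolk_length_mm`,
#'   `yolk_height_mm`, `swimup_length_mm`, `juvenile_length_mm` (any subset),
#'   plus optional `dd_hatch_swimup` / `dd_swimup_juvenile`.
#' @return A family-level data frame with one row per family x temperature:
#'   identifiers, `n_offspring`, the mean stage traits, `yolk_volume_mm3`,
#'   `ysce` (conversion efficiency), `growth_hatch_swimup` and
#'   `growth_swimup_juvenile` (NA where a stage is missing).
#' @export
family_trait_table <- function(offspring) {
  need <- c("population", "sire", "dam", "family", "temperature",
            "egg_diameter_mm")
  miss <- setdiff(need, names(offspring))
  if (length(miss)) {
    stop_domain("offspring table missing column(s): ", paste(miss, collapse = ", "))
  }
  key <- interaction(offspring$family, offspring$temperature, drop = TRUE)
  mean_by <- function(col) {
    if (!col %in% names(offspring)) return(NULL)
    tapply(offspring[[col]], key, function(v) mean(v, na.rm = TRUE))
  }
  first_by <- function(col) tapply(offspring[[col]], key, `[`, 1L)

  out <- data.frame(
    population = as.vector(first_by("population")),
    sire = as.vector(first_by("sire")),
    dam = as.vector(first_by("dam")),
    family = as.vector(first_by("family")),
    temperature = as.numeric(as.vector(first_by("temperature"))),
    egg_diameter_mm = as.numeric(as.vector(first_by("egg_diameter_mm"))),
    n_offspring = as.vector(tapply(rep(1L, nrow(offspring)), key, sum)),
    stringsAsFactors = FALSE)

  for (col in c("hatch_length_mm", "swimup_length_mm", "juvenile_length_mm")) {
    v <- mean_by(col)
    if (!is.null(v)) out[[col]] <- as.numeric(as.vector(v))
  }
  yl <- mean_by("yolk_length_mm"); yh <- mean_by("yolk_height_mm")
  if (!is.null(yl) && !is.null(yh)) {
    vol <- yolk_sac_volume(pmax(offspring$yolk_length_mm, 0),
                           pmax(offspring$yolk_height_mm, 0))
    out$yolk_volume_mm3 <- as.numeric(as.vector(tapply(vol, key, function(v) mean(v, na.rm = TRUE))))
  }
  if (!is.null(out$yolk_volume_mm3) && !is.null(out$swimup_length_mm) &&
      !is.null(out$hatch_length_mm)) {
    ok <- !is.na(out$yolk_volume_mm3) & out$yolk_volume_mm3 > 0
    out$ysce <- NA_real_
    if (any(ok)) {
      out$ysce[ok] <- suppressWarnings(
        yolk_conversion_efficiency(out$swimup_length_mm[ok],
                                   out$hatch_length_mm[ok],
                                   out$yolk_volume_mm3[ok]))
    }
  }
  if ("dd_hatch_swimup" %in% names(offspring) &&
      !is.null(out$swimup_length_mm) && !is.null(out$hatch_length_mm)) {
    dd <- as.numeric(as.vector(first_by("dd_hatch_swimup")))
    out$growth_hatch_swimup <- ifelse(
      !is.na(dd) & dd > 0,
      (out$swimup_length_mm - out$hatch_length_mm) / dd, NA_real_)
  }
  if ("dd_swimup_juvenile" %in% names(offspring) &&
      !is.null(out$juvenile_length_mm) && !is.null(out$swimup_length_mm)) {
    dd <- as.numeric(as.vector(first_by("dd_swimup_juvenile")))
    out$growth_swimup_juvenile <- ifelse(
      !is.na(dd) & dd > 0,
      (out$juvenile_length_mm - out$swimup_length_mm) / dd, NA_real_)
  }
  rownames(out) <- NULL
  out[order(out$temperature, out$population, out$family), , drop = FALSE]
}
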