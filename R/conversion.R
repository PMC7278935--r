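#' Elongation-conversion profile from a peak-area table
#'
#' Computes the per-product elongation conversion statistic from the GC-MS
#' peak areas of one yeast culture grown on an exogenous PUFA substrate.
#' Writing `S_k` for the summed areas of elongation product `k` and all
#' longer detected products, and `S_0 = S_1 +` substrate area:
#'
#' * `mode = "stepwise"` (default): `c_k = 100 * S_k / S_{k-1}` — the
#'   fraction of material reaching product `k-1` that was elongated at
#'   least once more. This reading reproduces the non-monotone columns of
#'   the published conversion tables.
#' * `mode = "cumulative_literal"`: `c_k = 100 * S_k / (S_k + substrate
#'   area)` — the formula read literally with the supplied substrate in
#'   every denominator; necessarily non-increasing in `k`.
#'
#' A product is reported as not detected (`NA` conversion, rendered
#' "n.d." on output) when it and every longer product fall below the
#' detection limit.
#'
#' @param table a peak-area tibble for a single sample with columns
#'   `sample_id`, `construct`, `substrate`, `fatty_acid`, `area`,
#'   `detected` (see [read_peak_csv()]).
#' @param mode `"stepwise"` or `"cumulative_literal"`.
#' @param lod limit of detection on the area scale; areas below it are
#'   treated as undetected (default 0).
#' @param digits decimals for rounding conversions (half-up); `NULL`
#'   keeps full precision. Default 1, matching the published tables.
#' @param max_carbons elongation ceiling (default 36).
#' @return A `conversion_profile` tibble with columns `substrate`,
#'   `product`, `conversion` (percent, `NA` = not detected); the `mode`
#'   is kept as an attribute.
#' @export
#' @examples
#' tbl <- tibble::tibble(
#'   sample_id = "s1", construct = "elovl4a", substrate = "20:5n-3",
#'   fatty_acid = c("20:5n-3", "22:5n-3", "24:5n-3"),
#'   area = c(800, 100, 100), detected = TRUE
#' )
#' stepwise_conversions(tbl)
stepwise_conversions <- function(table, mode = c("stepwise", "cumulative_literal"),
                                 lod = 0, digits = 1, max_carbons = 36L) {
  mode <- match.arg(mode)
  validate_peak_table(table)
  if (length(unique(table$sample_id)) != 1) {
    stop_vlcfa("`table` must hold a single sample; split multi-sample tables first",
               "vlcfa_bad_argument")
  }
  substrate <- unique(table$substrate[!is.na(table$substrate)])
  if (length(substrate) != 1) {
    stop_vlcfa("`table` must declare exactly one exogenous substrate",
               "vlcfa_bad_argument")
  }
  if (!substrate %in% table$fatty_acid) {
    stop_vlcfa(sprintf("substrate %s missing from the measurements", substrate),
               "vlcfa_bad_argument")
  }
  products <- product_series(substrate, max_carbons)

  area_of <- function(fa) {
    i <- match(fa, table$fatty_acid)
    a <- ifelse(is.na(i), 0, table$area[i])
    det <- ifelse(is.na(i), FALSE, table$detected[i])
    ifelse(det & a >= lod, a, 0)
  }
  prod_area <- area_of(products)
  sub_area <- area_of(substrate)

  s <- rev(cumsum(rev(prod_area)))            # S_k, k = 1..K
  s0 <- sub_area + (if (length(s)) s[1] else 0)
  if (s0 <= 0) {
    stop_vlcfa("substrate and all products undetected: conversion undefined",
               "vlcfa_degenerate_input")
  }
  denom <- switch(mode,
                  stepwise = c(s0, head(s, -1)),
                  cumulative_literal = s + sub_area)
  conv <- ifelse(s > 0 & denom > 0, 100 * s / denom, NA_real_)
  if (!is.null(digits)) conv <- round_half_up(conv, digits)

  out <- tibble(substrate = substrate, product = products, conversion = conv)
  structure(out, class = c("conversion_profile", class(out)),
            mode = mode, lod = lod)
}

#' Per-step elongation efficiencies implied by a conversion profile
#'
#' Inverts the conversion statistic under the steady-state cascade model
#' in which a fraction `e_k` of the material reaching chain length `k-1`
#' is elongated again. In stepwise mode the statistic *is* the efficiency
#' (`e_k = c_k / 100`). In cumulative-literal mode the efficiencies are
#' recovered through the tail sums `x_k = c_k / (100 - c_k)` (in units of
#' substrate area): `e_1 = x_1 / (1 + x_1)`, `e_k = x_k / x_{k-1}`.
#' Not-detected entries give `e_k = 0`; they must be trailing, as a dead
#' step starves every later product. Cumulative profiles that increase
#' with `k` are impossible under the model and raise an error naming the
#' offending step.
#'
#' @param profile a `conversion_profile` tibble (or any tibble with
#'   `product` and `conversion` columns).
#' @param mode conversion mode; defaults to the profile's own attribute.
#' @return numeric vector of efficiencies in `[0, 1]`, one per product.
#' @export
estimate_step_efficiencies <- function(profile, mode = NULL) {
  mode <- mode %||% attr(profile, "mode") %||% "stepwise"
  mode <- match.arg(mode, c("stepwise", "cumulative_literal"))
  conv <- profile$conversion
  if (all(is.na(conv))) return(rep(0, length(conv)))
  nd <- is.na(conv)
  if (any(nd) && any(!nd & cumsum(nd) > 0)) {
    bad <- which(!nd & cumsum(nd) > 0)[1]
    stop_vlcfa(sprintf("product %s detected after a not-detected step: inconsistent profile",
                       profile$product[bad]), "vlcfa_inconsistent_profile")
  }
  if (mode == "stepwise") {
    e <- ifelse(nd, 0, conv / 100)
    if (any(e < 0 | e > 1)) {
      stop_vlcfa("stepwise conversions must lie in [0, 100]", "vlcfa_inconsistent_profile")
    }
    return(e)
  }
  # cumulative_literal: invert via tail sums in substrate-area units
  if (any(conv[!nd] >= 100)) {
    stop_vlcfa("cumulative-literal conversion of 100% is not invertible (substrate fully consumed)",
               "vlcfa_inconsistent_profile")
  }
  x <- ifelse(nd, 0, conv / (100 - conv))
  e <- numeric(length(x))
  if (length(x)) e[1] <- x[1] / (1 + x[1])
  for (k in seq_along(x)[-1]) {
    if (x[k] == 0) { e[k] <- 0; next }
    e[k] <- x[k] / x[k - 1]
    if (e[k] > 1 + 1e-9) {
      stop_vlcfa(sprintf("cumulative-literal conversions increase at product %s: impossible under the cascade model",
                         profile$product[k]), "vlcfa_inconsistent_profile")
    }
    e[k] <- min(e[k], 1)
  }
  e
}

#' Reconstruct peak areas from a conversion profile
#'
#' Inverse of [stepwise_conversions()]: builds the (relative) areas of the
#' substrate and every product that reproduce the given conversions under
#' the steady-state cascade model. Useful for consistency checks on
#' published conversion columns whose raw areas were never reported.
#'
#' @param profile a `conversion_profile` tibble.
#' @param mode conversion mode; defaults to the profile's attribute.
#' @param total total substrate-pool area to distribute (default 1).
#' @param sample_id,construct metadata for the reconstructed table.
#' @return A peak-area tibble suitable for [stepwise_conversions()].
#' @export
conversions_to_areas <- function(profile, mode = NULL, total = 1,
                                 sample_id = "reconstructed",
                                 construct = "elovl4a") {
  mode <- mode %||% attr(profile, "mode") %||% "stepwise"
  e <- estimate_step_efficiencies(profile, mode)
  s <- total * cumprod(e)               # tail sums S_1..S_K
  areas <- c(total, s) - c(s, 0)        # substrate then product amounts
  fa <- c(profile$substrate[1], profile$product)
  tibble(
    sample_id = sample_id,
    construct = construct,
    substrate = profile$substrate[1],
    fatty_acid = fa,
    area = areas,
    detected = areas > 0
  )
}

#' Saturated fatty-acid profile (area % of total SFA >= C24)
#'
#' Expresses each saturated fatty acid from 24:0 to 34:0 as a percentage
#' of their summed peak areas, the normalization used when comparing the
#' very long-chain SFA complement of transformed versus control yeast.
#'
#' @param table a peak-area tibble for a single sample.
#' @param digits decimals for half-up rounding (default 1); `NULL` for
#'   full precision.
#' @return A tibble with columns `fatty_acid` (24:0 ... 34:0) and
#'   `percent`, summing to 100 within rounding.
#' @export
sfa_percent_profile <- function(table, digits = 1) {
  validate_peak_table(table)
  grid <- format_fa(seq(24L, 34L, 2L), 0L, "saturated")
  sub <- table |>
    filter(.data$fatty_acid %in% grid, .data$detected, .data$area > 0)
  if (nrow(sub) == 0) {
    stop_vlcfa("no saturated fatty acid >= C24 detected", "vlcfa_degenerate_input")
  }
  totals <- setNames(rep(0, length(grid)), grid)
  totals[sub$fatty_acid] <- sub$area
  pct <- 100 * totals / sum(totals)
  if (!is.null(digits)) pct <- round_half_up(pct, digits)
  tibble(fatty_acid = grid, percent = unname(pct))
}

# internal: schema check shared by the conversion statistics
validate_peak_table <- function(table) {
  need <- c("sample_id", "construct", "substrate", "fatty_acid", "area", "detected")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0) {
    stop_vlcfa(sprintf("peak-area table is missing column(s): %s",
                       paste(miss, collapse = ", ")), "vlcfa_bad_schema")
  }
  if (any(table$area < 0, na.rm = TRUE)) {
    stop_vlcfa("peak areas must be non-negative", "vlcfa_bad_schema")
  }
  if (anyDuplicated(table[, c("sample_id", "fatty_acid")])) {
    stop_vlcfa("duplicate (sample_id, fatty_acid) entries", "vlcfa_bad_schema")
  }
  invisible(table)
}

#' Coerce a data frame to a conversion profile
#'
#' Tags a tibble holding `substrate`, `product` and `conversion` columns
#' (percent scale, `NA` = not detected) with the `conversion_profile`
#' class and a conversion mode, e.g. to analyze a published table column.
#'
#' @param x data frame with `substrate`, `product`, `conversion`.
#' @param mode `"stepwise"` or `"cumulative_literal"`.
#' @return a `conversion_profile` tibble.
#' @export
as_conversion_profile <- function(x, mode = c("stepwise", "cumulative_literal")) {
  mode <- match.arg(mode)
  need <- c("substrate", "product", "conversion")
  if (!all(need %in% names(x))) {
    stop_vlcfa("need columns substrate, product, conversion", "vlcfa_bad_schema")
  }
  out <- as_tibble(x[, need])
  structure(out, class = c("conversion_profile", class(out)), mode = mode)
}
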