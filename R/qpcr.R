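#' Fit a qPCR standard curve
#'
#' Least-squares line of threshold cycle against log10 copy number from a
#' serial-dilution series of standards with known copy numbers. The fit
#' converts Ct values to absolute copy numbers ([ct_to_copies()]) and
#' reports the amplification efficiency `E = 10^(-1/slope) - 1` (1 for a
#' perfect doubling per cycle).
#'
#' @param dilutions tibble with columns `copies` (known copy numbers) and
#'   `ct`; at least 3 points with varying copy numbers.
#' @return A `standard_curve` object with elements `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `n` and the underlying `lm` fit; supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
#' @examples
#' std <- tibble::tibble(copies = 10^(2:7), ct = 38 - 3.32 * log10(copies))
#' fit_standard_curve(std)
fit_standard_curve <- function(dilutions) {
  if (!all(c("copies", "ct") %in% names(dilutions))) {
    stop_vlcfa("`dilutions` needs columns `copies` and `ct`", "vlcfa_bad_schema")
  }
  d <- dilutions |> filter(!is.na(.data$ct), !is.na(.data$copies))
  if (nrow(d) < 3) {
    stop_vlcfa("a standard curve needs at least 3 dilution points",
               "vlcfa_bad_argument")
  }
  if (any(d$copies <= 0)) {
    stop_vlcfa("copy numbers must be positive", "vlcfa_bad_argument")
  }
  if (length(unique(d$copies)) < 2) {
    stop_vlcfa("dilution points must span more than one copy number",
               "vlcfa_bad_argument")
  }
  d$log10_copies <- log10(d$copies)
  fit <- lm(ct ~ log10_copies, data = d)
  slope <- unname(coef(fit)[2])
  # noise-free standards fit exactly; the perfect-fit warning is expected
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(
    slope = slope,
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    efficiency = 10^(-1 / slope) - 1,
    n = nrow(d),
    model = fit
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve (%d points)\n", x$n))
  cat(sprintf("  Ct = %.3f %+.3f * log10(copies)\n", x$intercept, x$slope))
  cat(sprintf("  r^2 = %.4f, efficiency E = %.3f\n", x$r_squared, x$efficiency))
  invisible(x)
}

#' Convert threshold cycles to absolute copy numbers
#'
#' @param curve a `standard_curve` object.
#' @param ct numeric vector of threshold cycles (`NA` = undetermined,
#'   propagated as `NA` copies).
#' @return numeric vector of copy numbers.
#' @export
ct_to_copies <- function(curve, ct) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((ct - curve$intercept) / curve$slope)
}

#' Beta-actin-normalized relative expression index
#'
#' Converts each sample's Ct to absolute copies through its gene's
#' standard curve, then forms the per-fish ratio of target-gene copies to
#' reference-gene copies in the same tissue — the relative index used to
#' compare elovl4 expression across tissues. Fish missing the reference
#' measurement in a tissue are dropped with a warning.
#'
#' @param samples tibble with columns `fish_id`, `tissue`, `gene`, `ct`.
#' @param curves named list of `standard_curve` objects, one per gene
#'   (reference included).
#' @param reference reference gene name (default `"actb"`).
#' @return A tibble with one row per fish x tissue x target gene:
#'   `copies`, `ref_copies`, `relative_index`.
#' @export
relative_index <- function(samples, curves, reference = "actb") {
  need <- c("fish_id", "tissue", "gene", "ct")
  if (!all(need %in% names(samples))) {
    stop_vlcfa(sprintf("`samples` needs columns %s", paste(need, collapse = ", ")),
               "vlcfa_bad_schema")
  }
  missing_curves <- setdiff(unique(samples$gene), names(curves))
  if (length(missing_curves) > 0) {
    stop_vlcfa(sprintf("no standard curve for gene '%s'", missing_curves[1]),
               "vlcfa_bad_argument")
  }
  quant <- samples |>
    mutate(copies = purrr::map2_dbl(.data$gene, .data$ct,
                                    ~ ct_to_copies(curves[[.x]], .y)))
  ref <- quant |>
    filter(.data$gene == reference) |>
    select("fish_id", "tissue", ref_copies = "copies")
  targets <- quant |> filter(.data$gene != reference)
  joined <- left_join(targets, ref, by = c("fish_id", "tissue"))
  dropped <- joined |> filter(is.na(.data$ref_copies))
  if (nrow(dropped) > 0) {
    warn(sprintf("dropping %d record(s) without a %s measurement (e.g. fish %s, %s)",
                 nrow(dropped), reference, dropped$fish_id[1], dropped$tissue[1]))
  }
  joined |>
    filter(!is.na(.data$ref_copies)) |>
    mutate(relative_index = .data$copies / .data$ref_copies) |>
    select("fish_id", "tissue", "gene", "copies", "ref_copies", "relative_index")
}

#' Summarize relative expression by tissue
#'
#' Mean and standard deviation of the relative index per gene and tissue,
#' the form in which tissue expression profiles are reported.
#'
#' @param ri output of [relative_index()].
#' @return tibble with `gene`, `tissue`, `n`, `mean`, `sd`.
#' @export
summarize_expression <- function(ri) {
  ri |>
    group_by(.data$gene, .data$tissue) |>
    summarise(n = dplyr::n(), mean = mean(.data$relative_index),
              sd = sd(.data$relative_index), .groups = "drop")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = suppressWarnings(summary(x$model)$coefficients[, "Std. Error"]))
}

#' @exportS3Method generics::glance
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, efficiency = x$efficiency, n = x$n)
}
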