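#' Read a peak-area CSV
#'
#' Strict reader for the peak-area schema `sample_id, construct,
#' substrate, fatty_acid, area, detected` (header required, UTF-8).
#' Fatty acids are canonical shorthand strings; `substrate` may be empty
#' for SFA assays. Validation failures report the offending line number.
#'
#' @param path file path.
#' @return A peak-area tibble.
#' @export
read_peak_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    construct = readr::col_character(),
    substrate = readr::col_character(),
    fatty_acid = readr::col_character(),
    area = readr::col_character(),
    detected = readr::col_logical()
  ))
  extra <- setdiff(names(raw), c("sample_id", "construct", "substrate",
                                 "fatty_acid", "area", "detected"))
  if (length(extra) > 0) {
    stop_vlcfa(sprintf("unknown column(s) in %s: %s", path,
                       paste(extra, collapse = ", ")), "vlcfa_bad_schema")
  }
  area <- suppressWarnings(as.numeric(raw$area))
  bad <- which(is.na(area) & !is.na(raw$area))
  if (length(bad) > 0) {
    stop_vlcfa(sprintf("%s line %d: non-numeric area '%s'",
                       path, bad[1] + 1L, raw$area[bad[1]]), "vlcfa_bad_schema")
  }
  neg <- which(area < 0)
  if (length(neg) > 0) {
    stop_vlcfa(sprintf("%s line %d: negative area %s", path, neg[1] + 1L,
                       raw$area[neg[1]]), "vlcfa_bad_schema")
  }
  raw$area <- area
  dup <- which(duplicated(raw[, c("sample_id", "fatty_acid")]))
  if (length(dup) > 0) {
    stop_vlcfa(sprintf("%s line %d: duplicate (sample_id, fatty_acid) = (%s, %s)",
                       path, dup[1] + 1L, raw$sample_id[dup[1]],
                       raw$fatty_acid[dup[1]]), "vlcfa_bad_schema")
  }
  parse_fa(unique(raw$fatty_acid))  # validates shorthand, errors otherwise
  raw
}

#' Write a peak-area tibble as CSV
#'
#' @param table peak-area tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peak_csv <- function(table, path) {
  validate_peak_table(table)
  readr::write_csv(table[, c("sample_id", "construct", "substrate",
                             "fatty_acid", "area", "detected")], path)
  invisible(path)
}

#' Write a conversion profile as TSV
#'
#' Mirrors the published table layout (`substrate, product, conversion`)
#' with the literal token `n.d.` for not-detected products.
#'
#' @param profile a `conversion_profile` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  out <- profile |>
    mutate(conversion = ifelse(is.na(.data$conversion), "n.d.",
                               format(.data$conversion, trim = TRUE)))
  readr::write_tsv(out[, c("substrate", "product", "conversion")], path)
  invisible(path)
}

#' Read a conversion-profile TSV
#'
#' @param path file path (`substrate, product, conversion` with `n.d.`
#'   tokens).
#' @param mode conversion mode to attach (default `"stepwise"`).
#' @return a `conversion_profile` tibble (`NA` conversion = n.d.).
#' @export
read_profile_tsv <- function(path, mode = "stepwise") {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    substrate = readr::col_character(),
    product = readr::col_character(),
    conversion = readr::col_character()
  ))
  conv <- ifelse(raw$conversion %in% c("n.d.", "nd", "ND"), NA_character_,
                 raw$conversion)
  out <- tibble(substrate = raw$substrate, product = raw$product,
                conversion = suppressWarnings(as.numeric(conv)))
  structure(out, class = c("conversion_profile", class(out)), mode = mode)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file (nucleotide or protein; wrapped or unwrapped
#'   lines).
#' @return tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  tibble(id = names(set), sequence = unname(as.character(set)))
}

#' Write sequences to a FASTA file
#'
#' @param seqs tibble with columns `id` and `sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(setNames(seqs$sequence, seqs$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Pipeline configuration with documented defaults
#'
#' Collects the knobs shared across the pipeline: conversion mode and
#' detection limit, Tukey letter order, alignment parameters, the ER
#' retention C-terminal window, and the seed. Unknown names are rejected.
#'
#' @param ... overrides of the defaults.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    conversion_mode = "stepwise",
    lod = 0,
    letter_order = "ascending",
    gap_open = 11,
    gap_extend = 1,
    matrix_name = "BLOSUM62",
    c_terminal_window = 7L,
    max_carbons = 36L,
    seed = 1L
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0) {
    stop_vlcfa(sprintf("unknown config field '%s'", unknown[1]), "vlcfa_bad_schema")
  }
  structure(utils::modifyList(defaults, override), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with a subset of the [pipeline_config()] fields.
#' @return a `pipeline_config` list.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Write a pipeline configuration as YAML
#'
#' Serializing the active configuration next to every output keeps runs
#' reproducible.
#'
#' @param config a `pipeline_config` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Published Elovl4 conversion and SFA tables bundled with the package
#'
#' The percentage-conversion tables (one per species, both constructs and
#' all seven assayed PUFA substrates) and the saturated fatty-acid
#' profiles with their significance letters, as printed in the source
#' study; shipped as plain-text TSV under `extdata`. The raw peak areas
#' behind them were never published, so these serve as inputs for
#' consistency checks, not as recomputable ground truth.
#'
#' @param which `"conversions"` or `"sfa"`.
#' @param species `"sparus_aurata"`, `"solea_senegalensis"`, or `"both"`
#'   (ignored for `"sfa"`, which holds both).
#' @return A tibble; conversions have columns `species`, `construct`,
#'   `substrate`, `product`, `conversion` (`NA` = not detected).
#' @export
published_tables <- function(which = c("conversions", "sfa"),
                             species = c("both", "sparus_aurata",
                                         "solea_senegalensis")) {
  which <- match.arg(which)
  species <- match.arg(species)
  path <- function(f) system.file("extdata", f, package = "vlcfa", mustWork = TRUE)
  if (which == "sfa") {
    return(readr::read_tsv(path("elovl4_sfa_profiles.tsv"),
                           col_types = readr::cols(percent = readr::col_double(),
                                                   .default = readr::col_character())))
  }
  wanted <- if (species == "both") c("sparus_aurata", "solea_senegalensis") else species
  bind_rows(lapply(wanted, function(sp) {
    raw <- readr::read_tsv(path(sprintf("%s_elovl4_conversions.tsv", sp)),
                           col_types = readr::cols(.default = readr::col_character()))
    raw$conversion <- suppressWarnings(
      ifelse(raw$conversion == "n.d.", NA_character_, raw$conversion))
    raw$conversion <- as.numeric(raw$conversion)
    raw
  }))
}
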