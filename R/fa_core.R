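#' Parse fatty-acid shorthand notation
#'
#' Parses strings like `"22:6n-3"` or `"24:0"` into their components:
#' acyl-chain carbons, number of double bonds, and the omega series
#' (methyl-end position of the last double bond). Saturated fatty acids are
#' written without a series suffix (`"24:0"`); unsaturated ones must carry
#' one (`"20:5n-3"`). Chemically impossible combinations are rejected: a
#' chain of `c` carbons cannot hold `d` methylene-interrupted double bonds
#' ending at the n-x position unless `c >= 2 d + x`.
#'
#' @param x character vector of shorthand strings.
#' @return A tibble with one row per input and columns `fatty_acid`
#'   (canonical form), `carbons`, `double_bonds`, `series` (`"saturated"`
#'   or `"n-3"`, `"n-6"`, `"n-7"`, `"n-9"`, ...).
#' @export
#' @examples
#' parse_fa(c("22:6n-3", "24:0"))
parse_fa <- function(x) {
  if (length(x) == 0) return(tibble(fatty_acid = character(), carbons = integer(),
                                    double_bonds = integer(), series = character()))
  if (!is.character(x) || anyNA(x) || any(!nzchar(x))) {
    stop_vlcfa("fatty-acid shorthand must be non-empty strings", "vlcfa_parse_error")
  }
  m <- stringr::str_match(x, "^(\\d+):(\\d+)(?:n-(\\d+))?$")
  bad <- is.na(m[, 1])
  if (any(bad)) {
    stop_vlcfa(sprintf("malformed fatty-acid shorthand: '%s'", x[bad][1]),
               "vlcfa_parse_error")
  }
  carbons <- as.integer(m[, 2])
  db <- as.integer(m[, 3])
  npos <- suppressWarnings(as.integer(m[, 4]))
  if (any(carbons < 2)) {
    stop_vlcfa(sprintf("impossible chemistry in '%s': fewer than 2 carbons",
                       x[carbons < 2][1]), "vlcfa_parse_error")
  }
  sat_with_series <- db == 0 & !is.na(npos)
  if (any(sat_with_series)) {
    stop_vlcfa(sprintf("'%s': saturated fatty acids take no n-x series",
                       x[sat_with_series][1]), "vlcfa_parse_error")
  }
  unsat_without <- db > 0 & is.na(npos)
  if (any(unsat_without)) {
    stop_vlcfa(sprintf("'%s': unsaturated fatty acids require an n-x series",
                       x[unsat_without][1]), "vlcfa_parse_error")
  }
  bad_series <- !is.na(npos) & npos < 1
  if (any(bad_series)) {
    stop_vlcfa(sprintf("'%s': unknown series 'n-%d'", x[bad_series][1],
                       npos[bad_series][1]), "vlcfa_parse_error")
  }
  impossible <- db > 0 & carbons < 2L * db + npos
  if (any(impossible)) {
    stop_vlcfa(sprintf("impossible chemistry in '%s': %d carbons cannot hold %d double bonds in the n-%d series",
                       x[impossible][1], carbons[impossible][1],
                       db[impossible][1], npos[impossible][1]),
               "vlcfa_parse_error")
  }
  series <- ifelse(db == 0, "saturated", paste0("n-", npos))
  tibble(
    fatty_acid = format_fa(carbons, db, series),
    carbons = carbons,
    double_bonds = db,
    series = series
  )
}

#' Format fatty-acid components as canonical shorthand
#'
#' Inverse of [parse_fa()]: `format_fa(parse_fa(x)$carbons, ...)`
#' reproduces the canonical string.
#'
#' @param carbons integer vector of chain lengths.
#' @param double_bonds integer vector of double-bond counts.
#' @param series character vector: `"saturated"` or `"n-3"`, `"n-6"`, ...
#' @return character vector of shorthand strings.
#' @export
format_fa <- function(carbons, double_bonds, series) {
  n <- max(length(carbons), length(double_bonds), length(series))
  carbons <- rep_len(carbons, n)
  double_bonds <- rep_len(double_bonds, n)
  series <- rep_len(series, n)
  ifelse(double_bonds == 0,
         sprintf("%d:0", carbons),
         sprintf("%d:%d%s", carbons, double_bonds, series))
}

#' Elongate a fatty acid by two carbons per step
#'
#' Models the Elovl condensation reaction: each cycle extends the acyl
#' chain by two carbons, leaving double bonds and series untouched.
#'
#' @param fa character vector of shorthand strings.
#' @param steps positive integer, number of two-carbon elongation cycles.
#' @return character vector of elongated shorthand strings.
#' @export
#' @examples
#' elongate("20:5n-3")        # "22:5n-3"
#' elongate("18:3n-6", 9)     # "36:3n-6"
elongate <- function(fa, steps = 1L) {
  assert_scalar(steps, "steps", function(s) is.numeric(s) && s >= 1 && s == floor(s))
  p <- parse_fa(fa)
  format_fa(p$carbons + 2L * as.integer(steps), p$double_bonds, p$series)
}

#' Enumerate successive elongation products of a substrate
#'
#' All two-carbon elongation products of `substrate` up to a chain-length
#' ceiling, in increasing chain length; mirrors the product rows of the
#' conversion tables (C36 ceiling by default).
#'
#' @param substrate shorthand string for the starting fatty acid.
#' @param max_carbons maximum chain length to enumerate to (default 36).
#' @return character vector of products; empty when the substrate is
#'   already at the ceiling.
#' @export
#' @examples
#' product_series("18:4n-3")
product_series <- function(substrate, max_carbons = 36L) {
  assert_scalar(max_carbons, "max_carbons",
                function(m) is.numeric(m) && m == floor(m) && m >= 2)
  p <- parse_fa(substrate)
  if (nrow(p) != 1) stop_vlcfa("`substrate` must be a single fatty acid", "vlcfa_bad_argument")
  if (p$carbons > max_carbons) {
    stop_vlcfa(sprintf("substrate %s exceeds the %d-carbon ceiling",
                       substrate, max_carbons), "vlcfa_bad_argument")
  }
  if (p$carbons + 2L > max_carbons) return(character())
  lens <- seq(p$carbons + 2L, max_carbons, by = 2L)
  format_fa(lens, p$double_bonds, p$series)
}

#' Monoisotopic molecular-ion m/z of a fatty acid methyl ester
#'
#' The FAME of a fatty acid with `c` carbons and `d` double bonds has
#' elemental composition C(c+1) H(2(c+1)-2d) O2. The molecular-ion m/z is
#' the monoisotopic mass (C 12.000, H 1.00783, O 15.9949) rounded half-up
#' to one decimal, the convention of GC-MS SIM channel tables. One
#' elongation step adds exactly C2H4 (+28.0 u).
#'
#' @param fa character vector of shorthand strings.
#' @return numeric vector of m/z values (1 decimal).
#' @export
#' @examples
#' fame_molecular_ion_mz(c("24:0", "34:0"))  # 382.4, 522.5
fame_molecular_ion_mz <- function(fa) {
  p <- parse_fa(fa)
  n_c <- p$carbons + 1
  n_h <- 2 * (p$carbons + 1) - 2 * p$double_bonds
  round_half_up(12 * n_c + 1.00783 * n_h + 2 * 15.9949, 1)
}

# m/z fragments monitored for polyunsaturated FAME in SIM mode
PUFA_FRAGMENT_MZ <- c(79.1, 108.1, 150.1)

#' SIM acquisition channels for a fatty acid
#'
#' Saturated and monounsaturated FAME are monitored on their molecular
#' ion; polyunsaturated FAME (two or more double bonds) on the three
#' diagnostic polyene fragments m/z 79.1, 108.1 and 150.1.
#'
#' @param fa a single shorthand string.
#' @return A tibble with columns `fatty_acid`, `mz`, `channel_kind`
#'   (`"molecular_ion"` or `"pufa_fragment"`).
#' @export
#' @examples
#' sim_channels_for("26:0")
#' sim_channels_for("22:6n-3")
sim_channels_for <- function(fa) {
  p <- parse_fa(fa)
  if (nrow(p) != 1) stop_vlcfa("`fa` must be a single fatty acid", "vlcfa_bad_argument")
  if (p$double_bonds >= 2) {
    tibble(fatty_acid = p$fatty_acid, mz = PUFA_FRAGMENT_MZ,
           channel_kind = "pufa_fragment")
  } else {
    tibble(fatty_acid = p$fatty_acid, mz = fame_molecular_ion_mz(fa),
           channel_kind = "molecular_ion")
  }
}
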