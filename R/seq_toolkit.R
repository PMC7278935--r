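#' Translate a validated open reading frame
#'
#' Checks that the nucleotide sequence is a well-formed ORF — length a
#' multiple of three, starts with ATG, ends with a stop codon, no
#' internal stops — then translates it under the standard nuclear code,
#' excluding the terminal stop. The protein length is always
#' `nchar(nt) / 3 - 1`.
#'
#' @param nt a single DNA string (A/C/G/T).
#' @return single amino-acid string (1-letter code).
#' @export
#' @examples
#' translate_orf("ATGGCTTGTTAA")  # "MAC"
translate_orf <- function(nt) {
  assert_scalar(nt, "nt", function(x) is.character(x) && nzchar(x))
  nt <- toupper(nt)
  if (grepl("[^ACGT]", nt)) {
    stop_vlcfa("ORF contains non-ACGT characters", "vlcfa_bad_orf")
  }
  n <- nchar(nt)
  if (n %% 3 != 0) {
    stop_vlcfa(sprintf("ORF length %d is not a multiple of 3", n), "vlcfa_bad_orf")
  }
  if (substr(nt, 1, 3) != "ATG") {
    stop_vlcfa("ORF must begin with the ATG start codon", "vlcfa_bad_orf")
  }
  codons <- substring(nt, seq(1, n - 2, 3), seq(3, n, 3))
  stops <- c("TAA", "TAG", "TGA")
  if (!codons[length(codons)] %in% stops) {
    stop_vlcfa("ORF must end with a stop codon", "vlcfa_bad_orf")
  }
  if (any(codons[-length(codons)] %in% stops)) {
    stop_vlcfa("ORF contains an internal stop codon", "vlcfa_bad_orf")
  }
  as.character(Biostrings::translate(Biostrings::DNAString(substr(nt, 1, n - 3))))
}

#' Scan a protein for Elovl diagnostic motifs
#'
#' Reports every occurrence (overlaps included) of the histidine box
#' HxxHH anywhere in the sequence, and of the ER retention signal RxKxx
#' whose last residue lies within `c_terminal_window` residues of the
#' C-terminus.
#'
#' @param protein a single amino-acid string.
#' @param c_terminal_window window (in residues, from the C-terminus)
#'   within which an RxKxx match must end to count as a retention signal
#'   (default 7).
#' @return A tibble with columns `motif` (`histidine_box` /
#'   `er_retention`), `start` (1-based) and `match`.
#' @export
#' @examples
#' scan_motifs("MAHVVHHKLRQKAA")
scan_motifs <- function(protein, c_terminal_window = 7L) {
  assert_scalar(protein, "protein", function(x) is.character(x) && nzchar(x))
  protein <- toupper(protein)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", protein)) {
    stop_vlcfa("protein contains characters outside the amino-acid alphabet",
               "vlcfa_bad_argument")
  }
  n <- nchar(protein)
  find_all <- function(pattern) {
    m <- gregexpr(paste0("(?=(", pattern, "))"), protein, perl = TRUE)[[1]]
    starts <- as.integer(m)
    starts[starts > 0]
  }
  hb <- find_all("H..HH")
  er <- find_all("R.K..")
  er <- er[(er + 4L) >= (n - c_terminal_window + 1L)]
  match_at <- function(at) {
    if (length(at) == 0) character() else substring(protein, at, at + 4L)
  }
  bind_rows(
    tibble(motif = rep("histidine_box", length(hb)), start = hb,
           match = match_at(hb)),
    tibble(motif = rep("er_retention", length(er)), start = er,
           match = match_at(er))
  )
}

#' Percent identity from a global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 11, gap extend 1
#' by default); identity is the number of identical aligned positions
#' over all alignment columns (gaps included), as a percentage rounded to
#' the nearest integer.
#'
#' @param a,b amino-acid strings.
#' @param gap_open,gap_extend gap penalties (positive).
#' @param matrix_name substitution matrix name (default `"BLOSUM62"`).
#' @return percent identity (integer-valued numeric).
#' @export
#' @examples
#' global_identity("ACDEFGHIK", "ACDEFGHIR")  # 89
global_identity <- function(a, b, gap_open = 11, gap_extend = 1,
                            matrix_name = "BLOSUM62") {
  for (s in list(a, b)) {
    assert_scalar(s, "sequence", function(x) is.character(x) && nzchar(x))
    if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", toupper(s))) {
      stop_vlcfa("sequences must use the 1-letter amino-acid alphabet",
                 "vlcfa_bad_argument")
    }
  }
  # canonicalize argument order: equally-scoring tracebacks can differ in
  # column count, so identity is computed on a fixed orientation
  if (toupper(b) < toupper(a)) { tmp <- a; a <- b; b <- tmp }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    substitutionMatrix = matrix_name,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global"
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  round_half_up(100 * sum(p == s & p != "-") / length(p), 0)
}

#' Predict PCR amplicons on a template sequence
#'
#' Locates the forward primer on the plus strand and the
#' reverse-complement of the reverse primer downstream of it; each
#' compatible pair yields an amplicon whose length counts both primers.
#' By default matches must be exact; with `max_mismatches > 0` the 3'
#' terminal base of each primer site must still match exactly (a
#' mismatched 3' end does not prime).
#'
#' @param template DNA string.
#' @param forward,reverse primer sequences, both written 5'->3'
#'   (`reverse` binds the plus strand as its reverse complement); A/C/G/T
#'   only, length >= 15.
#' @param max_mismatches mismatches tolerated per primer site (default 0).
#' @return A tibble with one row per amplicon: `forward_start`,
#'   `reverse_end`, `length`; zero rows means no amplification.
#' @export
insilico_pcr <- function(template, forward, reverse, max_mismatches = 0L) {
  assert_scalar(template, "template", function(x) is.character(x) && nzchar(x))
  for (p in c(forward, reverse)) {
    assert_scalar(p, "primer", function(x) is.character(x) && nzchar(x))
    if (nchar(p) < 15 || grepl("[^ACGT]", toupper(p))) {
      stop_vlcfa("primers must be A/C/G/T and at least 15 nt", "vlcfa_bad_argument")
    }
  }
  template <- toupper(template)
  tmpl <- Biostrings::DNAString(template)
  site_hits <- function(site) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(site), tmpl,
                                     max.mismatch = max_mismatches)
    st <- Biostrings::start(hits); en <- Biostrings::end(hits)
    if (max_mismatches > 0 && length(st)) {
      # 3'-anchor: terminal base of the site must match the template
      last <- substr(site, nchar(site), nchar(site))
      keep <- substring(template, en, en) == last
      st <- st[keep]; en <- en[keep]
    }
    list(start = st, end = en)
  }
  fwd <- site_hits(toupper(forward))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(reverse))))
  # for the reverse primer the 3' end maps to the *start* of the rc site;
  # anchor on the first base of the rc site instead
  rev_hits <- {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(rc), tmpl,
                                     max.mismatch = max_mismatches)
    st <- Biostrings::start(hits); en <- Biostrings::end(hits)
    if (max_mismatches > 0 && length(st)) {
      keep <- substring(template, st, st) == substr(rc, 1, 1)
      st <- st[keep]; en <- en[keep]
    }
    list(start = st, end = en)
  }
  out <- tidyr::expand_grid(fi = seq_along(fwd$start), ri = seq_along(rev_hits$start))
  if (nrow(out) == 0) {
    return(tibble(forward_start = integer(), reverse_end = integer(),
                  length = integer()))
  }
  out <- out |>
    mutate(forward_start = fwd$start[.data$fi],
           forward_end = fwd$end[.data$fi],
           reverse_start = rev_hits$start[.data$ri],
           reverse_end = rev_hits$end[.data$ri]) |>
    filter(.data$reverse_start > .data$forward_end) |>
    mutate(length = .data$reverse_end - .data$forward_start + 1L) |>
    select("forward_start", "reverse_end", "length") |>
    arrange(.data$forward_start, .data$reverse_end)
  out
}
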