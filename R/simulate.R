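#' Default endogenous yeast fatty-acid background
#'
#' Mean peak areas (arbitrary response units) of the species a control
#' *S. cerevisiae* culture contributes to a chromatogram: the abundant
#' C16/C18 saturates and monounsaturates plus a trace very long-chain
#' saturated tail whose relative composition follows the control profile
#' observed in the yeast assays (about 12/75/9/3/1/0.3 % of the >= C24
#' saturates for 24:0 ... 34:0).
#'
#' @return named numeric vector of mean areas by fatty-acid shorthand.
#' @export
default_yeast_background <- function() {
  c("16:0" = 3.0e6, "18:0" = 1.2e6, "16:1n-7" = 2.5e6, "18:1n-9" = 2.8e6,
    "24:0" = 1.21e4, "26:0" = 7.50e4, "28:0" = 8.6e3, "30:0" = 2.7e3,
    "32:0" = 1.0e3, "34:0" = 3.0e2)
}

#' Parameters for a simulated elongation-cascade assay
#'
#' Bundles the ground truth driving [simulate_peak_table()]: the exogenous
#' PUFA substrate, per-step elongation efficiencies, uptake, supplied
#' concentration (defaulting to the chain-length compensation used in the
#' yeast cultures: 0.5 mM for C18, 0.75 mM for C20, 1 mM for C22
#' substrates), the endogenous background, the lognormal noise level, the
#' detection limit, and the replicate count.
#'
#' @param substrate shorthand string of the supplied PUFA.
#' @param efficiencies numeric vector of per-step efficiencies in `[0, 1]`,
#'   one per two-carbon step (steps beyond the vector are zero).
#' @param substrate_uptake fraction of supplied substrate taken up, in
#'   `(0, 1]`.
#' @param supplied_concentration mM; `NULL` picks the chain-length default.
#' @param background named numeric vector of endogenous mean areas.
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal replicate noise (default 0.1).
#' @param lod limit of detection on the area scale (default 0).
#' @param n_replicates number of replicate cultures (default 1, as in the
#'   PUFA assays).
#' @return A validated `cascade_params` list.
#' @export
cascade_params <- function(substrate, efficiencies,
                           substrate_uptake = 1,
                           supplied_concentration = NULL,
                           background = default_yeast_background(),
                           noise_cv = 0.1, lod = 0, n_replicates = 1L) {
  p <- parse_fa(substrate)
  if (is.null(supplied_concentration)) {
    supplied_concentration <- if (p$carbons <= 18) 0.5 else if (p$carbons <= 20) 0.75 else 1.0
  }
  if (any(efficiencies < 0 | efficiencies > 1)) {
    stop_vlcfa("efficiencies must lie in [0, 1]", "vlcfa_bad_argument")
  }
  if (substrate_uptake <= 0 || substrate_uptake > 1) {
    stop_vlcfa("substrate_uptake must lie in (0, 1]", "vlcfa_bad_argument")
  }
  if (noise_cv < 0) stop_vlcfa("noise_cv must be >= 0", "vlcfa_bad_argument")
  if (n_replicates < 1) stop_vlcfa("n_replicates must be >= 1", "vlcfa_bad_argument")
  structure(list(substrate = p$fatty_acid,
                 efficiencies = as.numeric(efficiencies),
                 substrate_uptake = substrate_uptake,
                 supplied_concentration = supplied_concentration,
                 background = background,
                 noise_cv = noise_cv, lod = lod,
                 n_replicates = as.integer(n_replicates)),
            class = "cascade_params")
}

# internal: lognormal factors with mean 1 and the given cv
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# internal: noise-free steady-state cascade amounts.
# A one-shot partition of the substrate pool a0: at each chain length a
# fraction e_k continues to the next elongation, so the material left at
# product k is a0 * e_1...e_k * (1 - e_{k+1}) and the tail sums telescope
# to S_k = a0 * e_1...e_k, making the stepwise statistic exactly e_k.
cascade_amounts <- function(a0, efficiencies, n_steps) {
  e <- c(efficiencies, rep(0, max(0, n_steps - length(efficiencies))))[seq_len(n_steps)]
  tail_s <- a0 * cumprod(e)
  c(substrate = a0 - (if (n_steps) tail_s[1] else 0),
    products = tail_s - c(tail_s[-1], 0))
}

#' Simulate peak-area tables for a PUFA elongation assay
#'
#' Generates `n_replicates` peak-area tables for one yeast culture
#' expressing an elongase and fed one exogenous PUFA substrate. The
#' substrate pool is proportional to supplied concentration times uptake;
#' product amounts follow the steady-state cascade closed form; every
#' area is then multiplied by an independent lognormal factor with the
#' configured coefficient of variation. Areas below the detection limit
#' are flagged undetected. With `noise_cv = 0` and `lod = 0`,
#' [stepwise_conversions()] recovers the efficiencies exactly.
#'
#' @param params a [cascade_params()] object.
#' @param construct construct label for the output tables.
#' @param species_tag free-text species tag.
#' @param seed integer seed; all randomness flows from it.
#' @param area_scale chromatographic response per (mM x uptake) of
#'   substrate pool (default 1e6).
#' @return A single tibble in the peak-area schema holding all
#'   replicates (split by `sample_id` for per-sample statistics).
#' @export
#' @examples
#' p <- cascade_params("20:5n-3", c(0.8, 0.5), noise_cv = 0)
#' tbl <- simulate_peak_table(p, seed = 1)
#' stepwise_conversions(tbl[tbl$sample_id == tbl$sample_id[1], ])
simulate_peak_table <- function(params, construct = "elovl4a",
                                species_tag = "synthetic", seed = NULL,
                                area_scale = 1e6) {
  stopifnot(inherits(params, "cascade_params"))
  if (!is.null(seed)) set.seed(seed)
  products <- product_series(params$substrate, 36L)
  a0 <- area_scale * params$supplied_concentration * params$substrate_uptake
  amounts <- cascade_amounts(a0, params$efficiencies, length(products))
  fa <- c(params$substrate, products)
  mean_area <- setNames(unname(amounts), fa)
  # merge endogenous background (summing on collision)
  for (b in names(params$background)) {
    mean_area[b] <- (if (b %in% names(mean_area)) mean_area[b] else 0) +
      params$background[[b]]
  }
  reps <- lapply(seq_len(params$n_replicates), function(r) {
    area <- unname(mean_area) * lognormal_noise(length(mean_area), params$noise_cv)
    tibble(
      sample_id = sprintf("%s_%s_rep%d", construct, params$substrate, r),
      construct = construct,
      species_tag = species_tag,
      substrate = params$substrate,
      fatty_acid = names(mean_area),
      area = area,
      detected = area >= params$lod & area > 0
    )
  })
  bind_rows(reps)
}

#' Simulate a triplicate VLC-SFA assay (construct vs control)
#'
#' Emulates the saturated fatty-acid comparison design: control yeast
#' contribute the endogenous >= C24 saturated tail alone, while
#' elongase-transformed yeast additionally elongate that tail. The shift
#' is applied cascade-style from 24:0 upward: at step `k` a fraction
#' `elovl_shift[k]` of the current 2k+22-carbon pool moves two carbons up.
#'
#' @param elovl_shift numeric vector of up to 5 per-step elongation
#'   fractions for 24:0->26:0 ... 32:0->34:0.
#' @param background named mean-area vector (default
#'   [default_yeast_background()]).
#' @param construct label for the transformed group.
#' @param noise_cv lognormal replicate noise cv (default 0.1).
#' @param lod detection limit (default 0).
#' @param n_replicates flasks per group (default 3, as in the assays).
#' @param seed integer seed.
#' @return A peak-area tibble holding both groups' replicates.
#' @export
simulate_sfa_assay <- function(elovl_shift, background = default_yeast_background(),
                               construct = "elovl4a", noise_cv = 0.1, lod = 0,
                               n_replicates = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(elovl_shift) > 5) {
    stop_vlcfa("elovl_shift has at most 5 steps (24:0 -> 34:0)", "vlcfa_bad_argument")
  }
  if (any(elovl_shift < 0 | elovl_shift > 1)) {
    stop_vlcfa("elovl_shift fractions must lie in [0, 1]", "vlcfa_bad_argument")
  }
  grid <- format_fa(seq(24L, 34L, 2L), 0L, "saturated")
  shift <- c(elovl_shift, rep(0, 5 - length(elovl_shift)))

  shifted <- background
  tail_areas <- ifelse(grid %in% names(background), background[grid], 0)
  names(tail_areas) <- grid
  for (k in seq_len(5)) {
    moved <- shift[k] * tail_areas[k]
    tail_areas[k] <- tail_areas[k] - moved
    tail_areas[k + 1] <- tail_areas[k + 1] + moved
  }
  shifted[grid] <- tail_areas

  one_group <- function(means, label) {
    bind_rows(lapply(seq_len(n_replicates), function(r) {
      area <- unname(means) * lognormal_noise(length(means), noise_cv)
      tibble(sample_id = sprintf("%s_rep%d", label, r),
             construct = label, species_tag = "synthetic",
             substrate = NA_character_,
             fatty_acid = names(means), area = area,
             detected = area >= lod & area > 0)
    }))
  }
  bind_rows(one_group(background, "control"), one_group(shifted, construct))
}

#' Simulate qPCR threshold cycles and a standard-curve dilution series
#'
#' Threshold cycles follow `Ct = intercept + slope * log10(copies)` plus
#' Gaussian noise; the dilution series spans the requested decades with
#' known copy numbers, as used for absolute quantification.
#'
#' @param copies tibble with columns `fish_id`, `tissue`, `gene`,
#'   `copies` (true transcript copy numbers; all positive).
#' @param slope cycles per log10(copies); must be negative (default
#'   -3.32, a perfectly efficient assay).
#' @param intercept cycles at 1 copy (default 38).
#' @param ct_noise_sd Gaussian Ct noise, cycles (default 0.15).
#' @param dilution_copies copy numbers of the standards (default
#'   10^(2:7), six points over five decades).
#' @param seed integer seed.
#' @return A list with `samples` (fish_id, tissue, gene, ct) and
#'   `standards` (gene, copies, ct).
#' @export
simulate_qpcr <- function(copies, slope = -3.32, intercept = 38,
                          ct_noise_sd = 0.15, dilution_copies = 10^(2:7),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (slope >= 0) stop_vlcfa("standard-curve slope must be negative", "vlcfa_bad_argument")
  if (any(copies$copies <= 0)) {
    stop_vlcfa("copy numbers must be positive", "vlcfa_bad_argument")
  }
  ct_of <- function(cp) intercept + slope * log10(cp) +
    rnorm(length(cp), 0, ct_noise_sd)
  genes <- unique(copies$gene)
  standards <- tibble(gene = rep(genes, each = length(dilution_copies)),
                      copies = rep(dilution_copies, length(genes)))
  standards$ct <- ct_of(standards$copies)
  samples <- copies |>
    mutate(ct = ct_of(.data$copies)) |>
    select("fish_id", "tissue", "gene", "ct")
  list(samples = samples, standards = standards)
}

CODON_TABLE <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  N = c("AAT", "AAC"), D = c("GAT", "GAC"), C = c("TGT", "TGC"),
  Q = c("CAA", "CAG"), E = c("GAA", "GAG"), G = c("GGT", "GGC", "GGA", "GGG"),
  H = c("CAT", "CAC"), I = c("ATT", "ATC", "ATA"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"), K = c("AAA", "AAG"),
  M = "ATG", F = c("TTT", "TTC"), P = c("CCT", "CCC", "CCA", "CCG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), W = "TGG", Y = c("TAT", "TAC"),
  V = c("GTT", "GTC", "GTA", "GTG")
)

#' Construct a synthetic ORF carrying the Elovl diagnostic motifs
#'
#' Builds a random open reading frame (ATG + sense codons + stop) whose
#' protein embeds a histidine box (HxxHH) and/or a C-terminal ER
#' retention signal (RxKxx) at requested 1-based residue positions, for
#' exercising the sequence toolkit on known ground truth.
#'
#' @param protein_length protein length in residues (>= 10), start
#'   methionine included; the ORF has `3 * (protein_length + 1)` nt.
#' @param histidine_box_at 1-based start of the HxxHH motif, or `NULL`.
#' @param er_retention_at 1-based start of the RxKxx motif; defaults to
#'   `protein_length - 4` (motif flush with the C-terminus); `NA` omits it.
#' @param seed integer seed.
#' @return list with elements `nucleotide` and `protein` (character).
#' @export
#' @examples
#' orf <- make_orf(322, histidine_box_at = 150, seed = 7)
#' nchar(orf$nucleotide)  # 969
make_orf <- function(protein_length, histidine_box_at = NULL,
                     er_retention_at = protein_length - 4L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  assert_scalar(protein_length, "protein_length",
                function(x) is.numeric(x) && x >= 10 && x == floor(x))
  L <- as.integer(protein_length)
  aa <- names(CODON_TABLE)
  # bias composition away from H/R/K so planted motifs dominate
  wt <- ifelse(aa %in% c("H", "R", "K"), 0.2, 1)
  residues <- c("M", sample(aa, L - 1L, replace = TRUE, prob = wt))

  spans <- list()
  plant <- function(residues, pattern_fixed, start, name) {
    idx <- start:(start + 4L)
    if (start < 2L || max(idx) > L) {
      stop_vlcfa(sprintf("%s motif at %d does not fit in a %d-residue protein",
                         name, start, L), "vlcfa_bad_argument")
    }
    for (sp in spans) {
      if (length(intersect(sp, idx)) > 0) {
        stop_vlcfa("requested motifs overlap", "vlcfa_bad_argument")
      }
    }
    spans[[length(spans) + 1L]] <<- idx
    x_pool <- setdiff(aa, c("H", "R", "K"))
    fill <- ifelse(is.na(pattern_fixed), sample(x_pool, 5, replace = TRUE),
                   pattern_fixed)
    residues[idx] <- fill
    residues
  }
  if (!is.null(histidine_box_at) && !is.na(histidine_box_at)) {
    residues <- plant(residues, c("H", NA, NA, "H", "H"),
                      as.integer(histidine_box_at), "histidine box")
  }
  if (!is.null(er_retention_at) && !is.na(er_retention_at)) {
    residues <- plant(residues, c("R", NA, "K", NA, NA),
                      as.integer(er_retention_at), "ER retention")
  }
  codons <- vapply(residues, function(r) sample(CODON_TABLE[[r]], 1), "",
                   USE.NAMES = FALSE)
  nt <- paste0(paste(codons, collapse = ""),
               sample(c("TAA", "TAG", "TGA"), 1))
  list(nucleotide = nt, protein = paste(residues, collapse = ""))
}
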