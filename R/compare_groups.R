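#' Compare replicate measurements across groups
#'
#' The statistical battery applied to the triplicate yeast SFA profiles
#' and to the tissue qPCR indices: Levene's test for homogeneity of
#' variances (mean-centered, as in SPSS), one-way ANOVA, and all-pairs
#' Tukey HSD summarized as a compact letter display — groups sharing a
#' letter do not differ at the chosen alpha. A Levene rejection is
#' reported but does not block the ANOVA.
#'
#' @param data a tidy tibble with one row per replicate measurement.
#' @param value,group unquoted column names of the measurement and the
#'   grouping factor.
#' @param variable optional unquoted column naming the measured variable
#'   (fatty acid, gene, ...); the battery is run once per variable.
#' @param alpha significance level for Tukey letters (default 0.05).
#' @param letter_order `"ascending"` (default; letter "a" to the group
#'   with the lowest mean) or `"descending"`.
#' @return A tibble with one row per variable x group: `n`, `mean`, `sd`,
#'   `letter`, and the per-variable `levene_p` and `anova_p`.
#' @export
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(
#'   group = rep(c("control", "elovl4a", "elovl4b"), each = 3),
#'   pct = rep(c(8.6, 20.8, 14.1), each = 3) + rnorm(9, 0, 0.5)
#' )
#' compare_groups(d, pct, group)
compare_groups <- function(data, value, group, variable = NULL,
                           alpha = 0.05,
                           letter_order = c("ascending", "descending")) {
  letter_order <- match.arg(letter_order)
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  variable <- rlang::enquo(variable)

  d <- tibble(
    value = rlang::eval_tidy(value, data),
    group = as.character(rlang::eval_tidy(group, data))
  )
  d$variable <- if (rlang::quo_is_null(variable)) "value" else
    as.character(rlang::eval_tidy(variable, data))

  d |>
    group_by(.data$variable) |>
    group_modify(~ compare_one_variable(.x, alpha, letter_order)) |>
    ungroup()
}

compare_one_variable <- function(d, alpha, letter_order) {
  counts <- table(d$group)
  if (length(counts) < 2) {
    stop_vlcfa("at least two groups are required", "vlcfa_insufficient_replication")
  }
  if (any(counts < 2)) {
    stop_vlcfa(sprintf("group '%s' has fewer than 2 replicates",
                       names(counts)[counts < 2][1]),
               "vlcfa_insufficient_replication")
  }
  d$group <- factor(d$group)
  lev <- car::leveneTest(value ~ group, data = d, center = mean)
  fit <- aov(value ~ group, data = d)
  an <- summary(fit)[[1]]
  tuk <- TukeyHSD(fit, conf.level = 1 - alpha)$group

  summ <- d |>
    group_by(.data$group) |>
    summarise(n = dplyr::n(), mean = mean(.data$value), sd = sd(.data$value),
              .groups = "drop") |>
    mutate(group = as.character(.data$group))

  letters <- tukey_letters(rownames(tuk), tuk[, "p adj"],
                           setNames(summ$mean, summ$group),
                           alpha, letter_order)
  summ |>
    mutate(letter = unname(letters[.data$group]),
           levene_p = lev[["Pr(>F)"]][1],
           anova_p = an[["Pr(>F)"]][1])
}

# Compact letter display by insert-and-absorb over the significance
# matrix: start from one set holding all groups; each significant pair
# splits every set containing both; sets absorbed by supersets are
# dropped. Letters follow the group ordering by mean.
tukey_letters <- function(pair_names, p_adj, means, alpha = 0.05,
                          letter_order = c("ascending", "descending")) {
  letter_order <- match.arg(letter_order)
  groups <- names(means)
  ord <- names(sort(means, decreasing = (letter_order == "descending")))

  sets <- list(groups)
  pairs <- strsplit(pair_names, "-", fixed = TRUE)
  sig <- p_adj <= alpha
  for (i in which(sig)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb: drop sets contained in another set
    keep <- vapply(seq_along(new_sets), function(j) {
      sj <- new_sets[[j]]
      !any(vapply(seq_along(new_sets), function(k) {
        k != j && all(sj %in% new_sets[[k]]) &&
          (length(new_sets[[k]]) > length(sj) || k < j)
      }, logical(1)))
    }, logical(1))
    sets <- new_sets[keep]
  }
  sets <- sets[lengths(sets) > 0]
  # order letter sets by the first (per letter_order) group they contain
  rank_of <- setNames(seq_along(ord), ord)
  sets <- sets[order(vapply(sets, function(s) min(rank_of[s]), 0))]
  out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets)) {
    for (g in sets[[i]]) out[g] <- paste0(out[g], letters[i])
  }
  out
}
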