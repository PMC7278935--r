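# shared fixture builders (all synthetic, built in code)

peak_tbl <- function(fa, area, substrate = NULL, sample_id = "s1",
                     construct = "elovl4a", detected = area > 0) {
  tibble::tibble(
    sample_id = sample_id, construct = construct,
    substrate = substrate %||% NA_character_,
    fatty_acid = fa, area = area, detected = detected
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force evaluation of the conversion statistic from raw
# areas, written as plain loops over tail sums
oracle_conversions <- function(sub_area, prod_areas, mode = "stepwise") {
  k_n <- length(prod_areas)
  s <- numeric(k_n)
  for (k in seq_len(k_n)) s[k] <- sum(prod_areas[k:k_n])
  out <- rep(NA_real_, k_n)
  for (k in seq_len(k_n)) {
    if (s[k] <= 0) next
    out[k] <- if (mode == "stepwise") {
      prev <- if (k == 1) sub_area + s[1] else s[k - 1]
      100 * s[k] / prev
    } else {
      100 * s[k] / (s[k] + sub_area)
    }
  }
  out
}

# random valid fatty-acid components for property tests
random_fa_components <- function(n) {
  carbons <- sample(seq(2L, 36L, 2L), n, replace = TRUE)
  db <- integer(n); series <- rep("saturated", n)
  unsat <- runif(n) < 0.6
  for (i in which(unsat)) {
    x <- sample(c(3L, 6L, 7L, 9L), 1)
    dmax <- floor((carbons[i] - x) / 2)
    if (dmax < 1) next
    db[i] <- sample.int(dmax, 1)
    series[i] <- paste0("n-", x)
  }
  tibble::tibble(carbons = carbons, double_bonds = db, series = series)
}
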