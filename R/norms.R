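#' Configuration for the synthetic reference population
#'
#' Describes the reference population from which synthetic norm tables are
#' built: age bands (half-open, in months) and a per-subtest raw-score
#' distribution, modeled as a binomial over the subtest's raw scale. These
#' tables are internally consistent stand-ins for proprietary normative
#' tables, calibrated only in the sense that the quantile construction
#' guarantees the published score moments; they model no real child
#' development.
#'
#' The default success probabilities equal the mean per-item score fraction
#' of the default [generator_config()] score distributions, so the reference
#' population describes the same kind of children the generator simulates
#' and generated children land mid-scale rather than at the table ceilings.
#'
#' @param age_bands List of `c(min_months, max_months)` pairs.
#' @param n_per_band Reference children drawn per band (default 10,000).
#' @param binom_prob Named list of per-subtest binomial success
#'   probabilities for raw-score draws.
#'
#' @return A list of class `norms_config`.
#' @export
norms_config <- function(age_bands = list(c(60L, 90L), c(90L, 120L)),
                         n_per_band = 10000L,
                         binom_prob = list(EV = 0.75, WS = 0.75,
                                           RS = 0.63, FS = 0.68)) {
  stopifnot(length(age_bands) >= 1, n_per_band >= 10)
  for (code in subtest_codes()) {
    p <- binom_prob[[code]]
    if (is.null(p) || p <= 0 || p >= 1) {
      stop_data("binom_prob$", code, " must lie strictly in (0, 1)")
    }
  }
  structure(list(age_bands = age_bands, n_per_band = as.integer(n_per_band),
                 binom_prob = binom_prob),
            class = "norms_config")
}

#' Draw a synthetic reference population of raw scores
#'
#' One row per reference child: the child's age band and a raw score for
#' each of the four subtests, drawn independently from the configured
#' binomial distributions (support is the full raw scale by construction).
#' Deterministic for a fixed seed.
#'
#' @param config A [norms_config()].
#' @param seed Integer seed.
#'
#' @return Tibble with columns `age_min_months`, `age_max_months`, `EV`,
#'   `WS`, `RS`, `FS`.
#' @export
reference_population <- function(config = norms_config(), seed = 42L) {
  stopifnot(inherits(config, "norms_config"))
  with_seed(derive_seed(seed, "refpop"), {
    bands <- lapply(config$age_bands, function(band) {
      draws <- lapply(setNames(subtest_codes(), subtest_codes()), function(code) {
        rbinom(config$n_per_band, subtest_params(code)$raw_max,
               config$binom_prob[[code]])
      })
      tibble::tibble(age_min_months = as.integer(band[1]),
                     age_max_months = as.integer(band[2]),
                     EV = draws$EV, WS = draws$WS, RS = draws$RS,
                     FS = draws$FS)
    })
    dplyr::bind_rows(bands)
  })
}

# Mid-quantile of each value of a discrete sample over support 0..max_val.
mid_quantiles <- function(x, max_val) {
  counts <- tabulate(x + 1L, nbins = max_val + 1L)
  cum <- cumsum(counts) / length(x)
  prev <- c(0, cum[-length(cum)])
  (prev + cum) / 2
}

# Map mid-quantiles to an integer score with the stated mean/SD via the
# normal quantile bands: score s covers quantiles in
# (Phi((s - mean - 0.5)/sd), Phi((s - mean + 0.5)/sd)], clamped at the
# tails; boundary ties break toward the lower score.
quantile_to_score <- function(q, mean, sd, lo, hi) {
  s <- ceiling(mean - 0.5 + sd * qnorm(q))
  s[q <= 0] <- lo
  s[q >= 1] <- hi
  pmin(hi, pmax(lo, as.integer(s)))
}

#' Build synthetic norm tables from a reference population
#'
#' Constructs the raw-to-scaled and scaled-sum-to-ELI lookup tables by
#' quantile matching (area transformation): within each subtest x age band,
#' a raw score whose mid-quantile in the reference distribution is q maps to
#' the scaled score whose normal band (mean 10, SD 3) contains q; the ELI
#' table is built the same way (mean 100, SD 15) over the FS + RS + WS
#' scaled-sum distribution that the scaled tables induce on the same
#' population. This guarantees the published moments — scaled mean 10, SD 3;
#' composite mean 100, SD 15 — up to integer discretization. Every raw value
#' 0..raw_max and every scaled sum 3..57 is covered; values outside the
#' sample's support inherit the boundary quantile, keeping the tables
#' gap-free and monotone.
#'
#' @param ref_pop A reference population from [reference_population()].
#'
#' @return A validated `norm_table`.
#' @export
build_norm_tables <- function(ref_pop) {
  needed <- c("age_min_months", "age_max_months", subtest_codes())
  stopifnot(all(needed %in% names(ref_pop)))
  sub_rows <- list()
  for (band_key in unique(ref_pop$age_min_months)) {
    band <- ref_pop[ref_pop$age_min_months == band_key, ]
    for (code in subtest_codes()) {
      x <- band[[code]]
      if (length(unique(x)) < 2) {
        stop_data("degenerate reference distribution for ", code,
                  " in band starting at ", band_key, " months")
      }
      raw_max <- subtest_params(code)$raw_max
      q <- mid_quantiles(x, raw_max)
      scaled <- quantile_to_score(q, 10, 3, 1L, 19L)
      runs <- rle(scaled)
      ends <- cumsum(runs$lengths)
      starts <- c(1L, head(ends, -1) + 1L)
      sub_rows[[length(sub_rows) + 1L]] <- tibble::tibble(
        subtest = code,
        age_min_months = band$age_min_months[1],
        age_max_months = band$age_max_months[1],
        raw_min = starts - 1L, raw_max = ends - 1L,
        scaled = as.integer(runs$values)
      )
    }
  }
  subtest_tables <- dplyr::bind_rows(sub_rows)

  # induced scaled-sum distribution over the same population
  partial <- norm_table_scaled_only(subtest_tables)
  sums <- integer(nrow(ref_pop))
  for (code in c("FS", "RS", "WS")) {
    for (band_key in unique(ref_pop$age_min_months)) {
      rows <- ref_pop$age_min_months == band_key
      lut <- scaled_lookup_vector(partial, code,
                                  ref_pop$age_min_months[rows][1])
      sums[rows] <- sums[rows] + lut[ref_pop[[code]][rows] + 1L]
    }
  }
  q_sum <- mid_quantiles(sums - 3L, 57L - 3L)
  eli <- quantile_to_score(q_sum, 100, 15, 45L, 155L)
  runs <- rle(eli)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  eli_table <- tibble::tibble(sum_min = starts + 2L, sum_max = ends + 2L,
                              eli = as.integer(runs$values))
  norm_table(subtest_tables, eli_table)
}

# Wrap a subtest table so scaled_score() can be used before the ELI table
# exists.
norm_table_scaled_only <- function(subtest_tables) {
  structure(list(subtest_tables = subtest_tables,
                 eli_table = tibble::tibble(sum_min = 3L, sum_max = 57L,
                                            eli = 100L)),
            class = "norm_table")
}

# Dense raw -> scaled lookup vector for one subtest and age; index raw + 1.
scaled_lookup_vector <- function(table, subtest, age_months) {
  st <- table$subtest_tables
  rows <- st[st$subtest == subtest & st$age_min_months <= age_months &
               age_months < st$age_max_months, ]
  if (nrow(rows) == 0) {
    stop_data("norm table has no ", subtest, " band covering age ",
              age_months, " months")
  }
  raw_max <- subtest_params(subtest)$raw_max
  lut <- integer(raw_max + 1L)
  for (i in seq_len(nrow(rows))) {
    lut[(rows$raw_min[i]:rows$raw_max[i]) + 1L] <- rows$scaled[i]
  }
  lut
}

# Dense scaled-sum -> ELI lookup vector; index sum - 2 (sums 3..57).
eli_lookup_vector <- function(table) {
  et <- table$eli_table
  lut <- integer(55L)
  for (i in seq_len(nrow(et))) {
    lut[(et$sum_min[i]:et$sum_max[i]) - 2L] <- et$eli[i]
  }
  lut
}

#' Score a population through a norm table
#'
#' Maps each child's raw scores through the raw-to-scaled tables (using the
#' lower edge of the child's age band) and the FS + RS + WS scaled sum
#' through the ELI table, using dense lookup vectors so large populations
#' score in milliseconds. Used to verify the calibration of built tables on
#' a fresh sample.
#'
#' @param ref_pop A reference population tibble.
#' @param table A `norm_table`.
#'
#' @return List with `scaled` (tibble: one column per subtest) and `eli`
#'   (integer vector, one per child).
#' @export
score_population <- function(ref_pop, table) {
  n <- nrow(ref_pop)
  scaled <- lapply(setNames(subtest_codes(), subtest_codes()),
                   function(code) integer(n))
  for (band_key in unique(ref_pop$age_min_months)) {
    rows <- ref_pop$age_min_months == band_key
    for (code in subtest_codes()) {
      lut <- scaled_lookup_vector(table, code, band_key)
      scaled[[code]][rows] <- lut[ref_pop[[code]][rows] + 1L]
    }
  }
  sums <- scaled$FS + scaled$RS + scaled$WS
  eli <- eli_lookup_vector(table)[sums - 2L]
  list(scaled = tibble::as_tibble(scaled), eli = eli)
}
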