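# Shared fixtures: configs are always built in code, never stored.

default_config <- function(seed = 1L, ...) {
  scenario_config(seed = seed, ...)
}

# one-ward, one-illness, one-severity minimal scenario
minimal_config <- function(seed = 1L) {
  scenario_config(
    illnesses = "flu", severities = "mild",
    weights = weight_table(matched = c(mild = 1), mismatched = c(mild = 1.5)),
    wards = data.frame(id = "W", specialty = "flu", capacity = 2L,
                       stringsAsFactors = FALSE),
    arrivals_per_day = 1L, mean_los_days = 2, n_days = 2L, seed = seed
  )
}

# a complete price list with one price everywhere except named overrides
flat_prices <- function(config, day, base = 5, ...) {
  keys <- pattern_grid(config)$key
  p <- stats::setNames(rep(base, length(keys)), keys)
  over <- list(...)
  for (k in names(over)) p[[k]] <- over[[k]]
  price_list(p, day, config)
}

# posted prices for all wards at a flat level, with per-ward overrides as
# named lists: ward_prices(cfg, 0, A = list(`pneumonia / mild` = 9))
ward_prices <- function(config, day, base = 5, ...) {
  over <- list(...)
  out <- list()
  for (wid in config$wards$id) {
    args <- c(list(config, day, base), over[[wid]])
    out[[wid]] <- do.call(flat_prices, args)
  }
  out
}

specialties_of <- function(config) {
  stats::setNames(config$wards$specialty, config$wards$id)
}

# independent Monte Carlo oracle for the specialty-premium acceptance
# probability: the physician accepts the specialty ward at price ratio r
# iff the multiplier m ~ U(lo, hi) satisfies m >= r
oracle_specialty_prob_mc <- function(ratio, lo = 1, hi = 2, n = 1e5, seed = 99) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  mean(stats::runif(n, lo, hi) >= ratio)
}
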