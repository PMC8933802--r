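test_that("a vacant specialty ward at the minimum price is always chosen", {
  cfg <- default_config()
  prices <- ward_prices(cfg, 0, base = 5)
  vac <- c(A = 40L, B = 40L, C = 40L)
  rng <- random_stream(1L)
  for (i in 1:50) {
    out <- select_ward(list(patient_id = "p", illness = "pneumonia",
                            severity = "mild"),
                       prices, vac, specialties_of(cfg),
                       cfg$multiplier_range, rng)
    expect_equal(out$ward, "B")
    expect_equal(out$reason, "lowest_price")  # price_s == p_min
    expect_false(is.na(out$multiplier))       # drawn: specialty was vacant
  }
})

test_that("with the specialty ward full, the cheapest vacant ward wins", {
  cfg <- default_config()
  key <- pattern_key("pneumonia", "mild")
  prices <- ward_prices(cfg, 0, base = 5)
  prices$A$prices[[key]] <- 7
  prices$C$prices[[key]] <- 5
  out <- select_ward(list(patient_id = "p", illness = "pneumonia",
                          severity = "mild"),
                     prices, c(A = 1L, B = 0L, C = 1L), specialties_of(cfg),
                     cfg$multiplier_range, random_stream(3L))
  expect_equal(out$ward, "C")
  expect_equal(out$reason, "lowest_price")
  expect_true(is.na(out$multiplier))  # specialty not vacant: no draw
  expect_equal(out$price_paid, 5)
})

test_that("no vacancy anywhere yields a no_vacancy outcome", {
  cfg <- default_config()
  out <- select_ward(list(patient_id = "p", illness = "pneumonia",
                          severity = "mild"),
                     ward_prices(cfg, 0), c(A = 0L, B = 0L, C = 0L),
                     specialties_of(cfg), cfg$multiplier_range,
                     random_stream(1L))
  expect_true(is.na(out$ward))
  expect_equal(out$reason, "no_vacancy")
})

test_that("specialty acceptance at price ratio 1.5 occurs with probability 0.5", {
  cfg <- default_config()
  key <- pattern_key("pneumonia", "mild")
  prices <- ward_prices(cfg, 0, base = 4)
  prices$B$prices[[key]] <- 6  # specialty at 1.5 x the best competing price
  rng <- random_stream(2718L)
  n <- 10000L
  chose_specialty <- logical(n)
  for (i in seq_len(n)) {
    out <- select_ward(list(patient_id = "p", illness = "pneumonia",
                            severity = "mild"),
                       prices, c(A = 1L, B = 1L, C = 1L), specialties_of(cfg),
                       cfg$multiplier_range, rng)
    chose_specialty[i] <- out$ward == "B"
  }
  se <- sqrt(0.5 * 0.5 / n)
  # closed form: P(m >= 1.5), m ~ U(1, 2)
  expect_equal(specialty_selection_prob(1.5), 0.5)
  expect_lt(abs(mean(chose_specialty) - 0.5), 3 * se)
  # and against the independent Monte Carlo oracle on the multiplier rule
  expect_lt(abs(mean(chose_specialty) - oracle_specialty_prob_mc(1.5)), 4 * se)
})

test_that("a specialty price 3x the minimum is never accepted", {
  cfg <- default_config()
  key <- pattern_key("pneumonia", "mild")
  prices <- ward_prices(cfg, 0, base = 2)
  prices$B$prices[[key]] <- 6
  rng <- random_stream(5L)
  for (i in 1:200) {
    out <- select_ward(list(patient_id = "p", illness = "pneumonia",
                            severity = "mild"),
                       prices, c(A = 1L, B = 1L, C = 1L), specialties_of(cfg),
                       cfg$multiplier_range, rng)
    expect_true(out$ward %in% c("A", "C"))
  }
})

test_that("specialty selection probability is monotone in its price (vs closed form)", {
  cfg <- default_config()
  key <- pattern_key("pneumonia", "mild")
  rng <- random_stream(31L)
  n <- 4000L
  ratios <- c(1.0, 1.2, 1.4, 1.6, 1.8, 2.0, 2.2)
  emp <- vapply(ratios, function(r) {
    prices <- ward_prices(cfg, 0, base = 5)
    prices$B$prices[[key]] <- 5 * r
    hits <- 0L
    for (i in seq_len(n)) {
      out <- select_ward(list(patient_id = "p", illness = "pneumonia",
                              severity = "mild"),
                         prices, c(A = 1L, B = 1L, C = 1L), specialties_of(cfg),
                         cfg$multiplier_range, rng)
      hits <- hits + (out$ward == "B")
    }
    hits / n
  }, numeric(1))
  theory <- vapply(ratios, specialty_selection_prob, numeric(1))
  expect_true(all(abs(emp - theory) <= 3 * sqrt(pmax(theory * (1 - theory), 0.25 / n) / n) + 1e-12))
  # weak monotone decrease of the closed form, mirrored by the simulation
  expect_true(all(diff(theory) <= 0))
  expect_true(all(diff(emp) <= 3 * sqrt(1 / n)))
})

test_that("ties at the minimum price are broken uniformly (chi-square)", {
  cfg <- default_config()
  prices <- ward_prices(cfg, 0, base = 5)
  rng <- random_stream(17L)
  n <- 10000L
  picks <- character(n)
  for (i in seq_len(n)) {
    # specialty ward B full; A and C tie at the minimum
    out <- select_ward(list(patient_id = "p", illness = "pneumonia",
                            severity = "mild"),
                       prices, c(A = 1L, B = 0L, C = 1L), specialties_of(cfg),
                       cfg$multiplier_range, rng)
    picks[i] <- out$ward
  }
  tab <- table(factor(picks, levels = c("A", "C")))
  gof <- chisq.test(tab, p = c(0.5, 0.5))
  expect_gt(gof$p.value, 0.001)
})

test_that("select_ward never returns a full ward", {
  cfg <- default_config()
  rng <- random_stream(23L)
  grid <- pattern_grid(cfg)
  for (i in 1:300) {
    vac <- stats::setNames(rs_draw(rng, "policy", sample(0:2, 3, replace = TRUE)),
                           c("A", "B", "C"))
    pat <- grid[rs_draw(rng, "policy", sample.int(9, 1)), ]
    prices <- ward_prices(cfg, 0, base = rs_draw(rng, "policy", runif(1, 1, 10)))
    out <- select_ward(list(patient_id = "p", illness = pat$illness,
                            severity = pat$severity),
                       prices, vac, specialties_of(cfg),
                       cfg$multiplier_range, rng)
    if (all(vac == 0L)) {
      expect_true(is.na(out$ward))
    } else {
      expect_gte(vac[[out$ward]], 1L)
    }
  }
})

test_that("the ward view exposes only patient counts of other wards", {
  cfg <- default_config()
  res <- run_session(cfg)
  view <- ward_view(res$state, "A", 10L)
  expect_s3_class(view, "ward_view")
  # own ward in full
  expect_true(all(c("occupancy", "workload", "balance", "specialty",
                    "capacity") %in% names(view$own_ward)))
  # others: bare integer counts, nothing else — no workloads, prices, balances
  expect_type(view$other_patient_counts, "integer")
  expect_named(view$other_patient_counts, c("B", "C"))
  expect_false("other_prices" %in% names(view))
  # the type carries nothing about other wards beyond the counts
  expect_setequal(names(view),
                  c("day", "own_ward", "other_patient_counts",
                    "own_price_history"))
})

test_that("pricing policies produce complete price lists from a view alone", {
  cfg <- default_config()
  state <- new_hospital_state(cfg)
  view <- ward_view(state, "A", 0L)
  rng <- random_stream(1L)

  # constant: every pattern priced at base, every day
  pl <- set_prices(make_policy(list(kind = "constant", base = 5), "A"),
                   view, cfg, rng)
  expect_equal(unname(pl$prices), rep(5, 9))

  # workload_linear with slope 0 reduces to constant
  pl0 <- set_prices(make_policy(list(kind = "workload_linear", base = 5,
                                     slope = 0), "A"), view, cfg, rng)
  expect_equal(pl0$prices, pl$prices)

  # hand-computed: base 2, slope 0.5, workload 10 -> 7 everywhere
  state$wards$A$workload <- 10
  view10 <- ward_view(state, "A", 0L)
  pl7 <- set_prices(make_policy(list(kind = "workload_linear", base = 2,
                                     slope = 0.5), "A"), view10, cfg, rng)
  expect_equal(unname(pl7$prices), rep(7, 9))

  # negative computed prices clip to zero with a warning
  expect_warning(
    pln <- set_prices(make_policy(list(kind = "workload_linear", base = -3,
                                       slope = 0), "A"), view, cfg, rng),
    "clipped"
  )
  expect_equal(unname(pln$prices), rep(0, 9))
})

test_that("replay policies error clearly on missing days or patterns", {
  cfg <- default_config()
  state <- new_hospital_state(cfg)
  view <- ward_view(state, "A", 5L)
  sched <- data.frame(day = 0L, ward = "A", illness = "pneumonia",
                      severity = "mild", price = 1, stringsAsFactors = FALSE)
  pol <- make_policy(list(kind = "replay", schedule = sched), "A")
  expect_error(set_prices(pol, view, cfg, random_stream(1L)), "no prices")
  view0 <- ward_view(state, "A", 0L)
  expect_error(set_prices(pol, view0, cfg, random_stream(1L)),
               "missing patterns")
})
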