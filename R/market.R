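# Token ledger, admission settlement, and the day/session engine sequencing
# price setting -> arrivals/allocation -> settlement -> discharge.

# ---- token ledger ----------------------------------------------------------

#' Create an empty token ledger
#'
#' The closed token economy: the hospital issues tokens to the physician as
#' consideration for each admission, and each issued token lands in exactly
#' one ward's balance, so total issuance always equals the sum of ward
#' balances.
#'
#' @param ward_ids Character vector of ward ids.
#' @return A `token_ledger` with zero balances and zero issuance.
#' @export
token_ledger <- function(ward_ids) {
  structure(list(
    ward_balances = stats::setNames(numeric(length(ward_ids)), ward_ids),
    hospital_issuance = 0
  ), class = "token_ledger")
}

#' Settle one admission on the ledger
#'
#' Pass-through pricing: the hospital issues exactly the agreed price and the
#' ward receives it, so ward income equals posted prices.
#'
#' @param ledger A `token_ledger`.
#' @param ward Receiving ward id.
#' @param price Agreed price in tokens (>= 0).
#' @return The updated ledger.
#' @export
settle_admission <- function(ledger, ward, price) {
  stopifnot(inherits(ledger, "token_ledger"))
  if (!ward %in% names(ledger$ward_balances)) {
    stop(sprintf("unknown ward '%s' in ledger", ward), call. = FALSE)
  }
  if (!is.finite(price) || price < 0) {
    stop("price must be a non-negative number", call. = FALSE)
  }
  ledger$ward_balances[[ward]] <- ledger$ward_balances[[ward]] + price
  ledger$hospital_issuance <- ledger$hospital_issuance + price
  ledger
}

#' Check token conservation on a ledger
#' @param ledger A `token_ledger`.
#' @return `TRUE` invisibly; errors if issuance differs from the balance sum.
#' @export
check_token_conservation <- function(ledger) {
  if (abs(ledger$hospital_issuance - sum(ledger$ward_balances)) > 1e-9) {
    stop("token conservation violated: issuance != sum of ward balances",
         call. = FALSE)
  }
  invisible(TRUE)
}

# ---- event recorder --------------------------------------------------------

new_event_recorder <- function() {
  rec <- new.env(parent = emptyenv())
  rec$events <- vector("list", 512L)
  rec$n <- 0L
  rec
}

record_event <- function(rec, day, kind, ...) {
  rec$n <- rec$n + 1L
  if (rec$n > length(rec$events)) {
    length(rec$events) <- 2L * length(rec$events)
  }
  rec$events[[rec$n]] <- c(list(day = as.integer(day), seq = rec$n, kind = kind),
                           list(...))
  invisible(rec)
}

#' Materialize an event recorder into a data frame
#' @noRd
events_df <- function(rec) {
  if (rec$n == 0L) return(empty_event_log())
  df <- data.table::rbindlist(rec$events[seq_len(rec$n)], fill = TRUE)
  data.table::setDF(df)
  # stable column order
  cols <- c("day", "seq", "kind", "ward", "patient_id", "illness", "severity",
            "price", "multiplier", "increment", "workload", "admit_day", "reason")
  for (m in setdiff(cols, names(df))) df[[m]] <- NA
  df[, cols]
}

#' An empty, correctly-typed event log
#' @return Zero-row event-log data frame.
#' @export
empty_event_log <- function() {
  data.frame(day = integer(), seq = integer(), kind = character(),
             ward = character(), patient_id = character(),
             illness = character(), severity = character(),
             price = numeric(), multiplier = numeric(), increment = numeric(),
             workload = numeric(), admit_day = integer(), reason = character(),
             stringsAsFactors = FALSE)
}

# ---- engine ----------------------------------------------------------------

.build_policies <- function(config) {
  specs <- config$policies
  pols <- list()
  for (wid in config$wards$id) {
    spec <- specs[[wid]] %||% specs[["default"]]
    pols[[wid]] <- make_policy(spec, ward_id = wid)
  }
  pols
}

.engine_day <- function(env, day) {
  config <- env$config
  state <- env$state
  specialties <- stats::setNames(config$wards$specialty, config$wards$id)

  # (1) each ward posts its daily price list from its own restricted view
  todays_prices <- list()
  for (wid in config$wards$id) {
    other_prices <- NULL
    if (config$show_other_prices) {
      other_prices <- lapply(env$history[setdiff(names(env$history), wid)],
                             function(h) if (length(h)) h[[length(h)]] else NULL)
    }
    view <- ward_view(state, wid, day, env$history[[wid]], other_prices)
    pl <- set_prices(env$policies[[wid]], view, config, env$rng)
    todays_prices[[wid]] <- pl
    env$history[[wid]] <- c(env$history[[wid]], list(pl))
    grid <- pattern_grid(config)
    for (i in seq_len(nrow(grid))) {
      record_event(env$rec, day, "price_set", ward = wid,
                   illness = grid$illness[i], severity = grid$severity[i],
                   price = unname(pl$prices[[grid$key[i]]]),
                   workload = view$own_ward$workload)
    }
    # day-start snapshot (state is untouched by price setting)
    env$snap_n <- env$snap_n + 1L
    env$snapshots[[env$snap_n]] <- list(
      day = as.integer(day), ward = wid,
      occupancy = nrow(state$wards[[wid]]$occupants),
      workload = state$wards[[wid]]$workload,
      balance = state$wards[[wid]]$balance
    )
  }

  do_discharge <- function(state) {
    step <- discharge_step(state, day, config, env$rng)
    d <- step$discharges
    for (i in seq_len(nrow(d))) {
      record_event(env$rec, day, "discharge", ward = d$ward[i],
                   patient_id = d$patient_id[i], illness = d$illness[i],
                   severity = d$severity[i], increment = d$increment[i],
                   admit_day = d$admit_day[i])
    }
    step$state
  }

  if (config$discharge_timing == "before_arrivals") state <- do_discharge(state)

  # (2) stochastic arrivals
  batch <- generate_arrivals(day, config, env$rng, first_id = state$next_patient)
  n_arr <- nrow(batch$patients)
  state$next_patient <- state$next_patient + n_arr
  arrivals <- lapply(seq_len(n_arr), function(i) {
    list(patient_id = batch$patients$patient_id[i],
         illness = batch$patients$illness[i],
         severity = batch$patients$severity[i])
  })
  for (p in arrivals) {
    record_event(env$rec, day, "arrival", patient_id = p$patient_id,
                 illness = p$illness, severity = p$severity)
  }

  # (3) sequential allocation: each arrival sees vacancies left by the previous
  for (p in arrivals) {
    if (env$mechanism == "token") {
      out <- select_ward(p, todays_prices, vacancies(state), specialties,
                         config$multiplier_range, env$rng)
      chosen <- out$ward
    } else {
      chosen <- command_select(p, vacancies(state), occupancy(state),
                               specialties, env$command_fallback, env$rng)
      out <- NULL
    }
    if (is.na(chosen)) {
      record_event(env$rec, day, "rejection", patient_id = p$patient_id,
                   illness = p$illness, severity = p$severity,
                   reason = "no_vacancy")
      env$rejections <- env$rejections + 1L
      next
    }
    state$wards[[chosen]] <- apply_admission(state$wards[[chosen]], p, day,
                                             config$weights)
    state$n_admitted <- state$n_admitted + 1L
    inc <- state$wards[[chosen]]$occupants$increment[
      nrow(state$wards[[chosen]]$occupants)]
    if (env$mechanism == "token") {
      env$ledger <- settle_admission(env$ledger, chosen, out$price_paid)
      state$wards[[chosen]]$balance <- env$ledger$ward_balances[[chosen]]
      record_event(env$rec, day, "admission", ward = chosen,
                   patient_id = p$patient_id, illness = p$illness,
                   severity = p$severity, price = out$price_paid,
                   multiplier = out$multiplier, increment = inc,
                   reason = out$reason)
    } else {
      reason <- if (identical(specialties[[chosen]], p$illness))
        "specialty" else env$command_fallback
      record_event(env$rec, day, "admission", ward = chosen,
                   patient_id = p$patient_id, illness = p$illness,
                   severity = p$severity, price = NA_real_,
                   increment = inc, reason = reason)
    }
  }

  # (4) day-end discharge so vacant beds appear for subsequent days
  if (config$discharge_timing == "day_end") state <- do_discharge(state)

  state$day <- day + 1L
  env$state <- state
  invisible(env)
}

#' Run one simulated day
#'
#' Sequences one day of the market: every ward's policy posts a price list
#' computed from its restricted [ward_view()]; the day's arrivals are
#' generated; the physician agent allocates them sequentially (admission +
#' token settlement at the chosen ward's posted price, or a rejection when no
#' ward has a vacancy); finally the random discharge step frees beds.
#'
#' @param state A `hospital_state` at day start.
#' @param policies Named list of `pricing_policy` objects, one per ward.
#' @param config A `scenario_config`.
#' @param rng A `random_stream`.
#' @param ledger A `token_ledger` (defaults to a fresh one).
#' @param history Named list of per-ward price-list histories.
#' @param day Day index; defaults to `state$day`.
#' @return List with `state`, `events` (this day's event-log rows), `ledger`,
#'   and `history`.
#' @export
run_day <- function(state, policies, config, rng,
                    ledger = token_ledger(config$wards$id),
                    history = NULL, day = state$day) {
  env <- new.env(parent = emptyenv())
  env$config <- config
  env$state <- state
  env$policies <- policies
  env$rng <- rng
  env$ledger <- ledger
  env$history <- history %||%
    stats::setNames(vector("list", nrow(config$wards)), config$wards$id)
  env$rec <- new_event_recorder()
  env$snapshots <- vector("list", 64L)
  env$snap_n <- 0L
  env$rejections <- 0L
  env$mechanism <- "token"
  .engine_day(env, day)
  list(state = env$state, events = events_df(env$rec), ledger = env$ledger,
       history = env$history)
}

#' Run a full session
#'
#' `n_days` consecutive days from an empty hospital, deterministic given the
#' config's seed. The token mechanism uses the physician agent's price rule;
#' the command mechanism (see [command_select()]) ignores prices and forces
#' specialty-first placement, as a baseline.
#'
#' @param config A validated `scenario_config`.
#' @param mechanism `"token"` (default) or `"command"`.
#' @param command_fallback Fallback rule for the command mechanism when the
#'   specialty ward is full: `"least_occupied"` or `"random_vacant"`.
#' @return A `session_result`: list with `config`, `mechanism`, final `state`,
#'   `log` (the full typed event log), `snapshots` (day-start per-ward
#'   occupancy/workload/balance), `ledger`, and `rejections`.
#' @export
run_session <- function(config, mechanism = c("token", "command"),
                        command_fallback = c("least_occupied", "random_vacant")) {
  mechanism <- match.arg(mechanism)
  command_fallback <- match.arg(command_fallback)
  config <- validate_config(config)

  env <- new.env(parent = emptyenv())
  env$config <- config
  env$state <- new_hospital_state(config)
  env$policies <- .build_policies(config)
  env$rng <- random_stream(config$seed)
  env$ledger <- token_ledger(config$wards$id)
  env$history <- stats::setNames(vector("list", nrow(config$wards)),
                                 config$wards$id)
  env$rec <- new_event_recorder()
  env$snapshots <- vector("list", 512L)
  env$snap_n <- 0L
  env$rejections <- 0L
  env$mechanism <- mechanism
  env$command_fallback <- command_fallback

  for (day in seq_len(config$n_days) - 1L) {
    if (env$snap_n + nrow(config$wards) > length(env$snapshots)) {
      length(env$snapshots) <- 2L * length(env$snapshots)
    }
    .engine_day(env, day)
  }

  snapshots <- if (env$snap_n > 0L) {
    df <- data.table::rbindlist(env$snapshots[seq_len(env$snap_n)])
    data.table::setDF(df)
    df
  } else {
    data.frame(day = integer(), ward = character(), occupancy = integer(),
               workload = numeric(), balance = numeric(),
               stringsAsFactors = FALSE)
  }

  structure(list(
    config = config, mechanism = mechanism, state = env$state,
    log = events_df(env$rec), snapshots = snapshots, ledger = env$ledger,
    rejections = env$rejections
  ), class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> %s mechanism | %d day(s) | %d admission(s), %d rejection(s)\n",
              x$mechanism, x$config$n_days, x$state$n_admitted, x$rejections))
  cat(sprintf("  issuance %.2f tokens | final occupancy: %s\n",
              x$ledger$hospital_issuance,
              paste(sprintf("%s=%d", names(occupancy(x$state)),
                            occupancy(x$state)), collapse = ", ")))
  invisible(x)
}

# ---- replay ----------------------------------------------------------------

#' Rebuild hospital state by replaying an event log
#'
#' Applies the log's admission and discharge events, in (day, seq) order, to
#' an empty hospital. The result must equal the state the engine produced
#' online; this is the audit path for the event-sourcing contract.
#'
#' @param log An event-log data frame.
#' @param config The `scenario_config` the log was produced under.
#' @return A `hospital_state`.
#' @export
replay_log <- function(log, config) {
  state <- new_hospital_state(config)
  log <- log[order(log$day, log$seq), , drop = FALSE]
  for (i in seq_len(nrow(log))) {
    kind <- log$kind[i]
    if (kind == "admission") {
      wid <- log$ward[i]
      w <- state$wards[[wid]]
      rec <- data.frame(patient_id = log$patient_id[i], illness = log$illness[i],
                        severity = log$severity[i], admit_day = log$day[i],
                        increment = log$increment[i], stringsAsFactors = FALSE)
      w$occupants <- rbind(w$occupants, rec)
      w$workload <- w$workload + log$increment[i]
      if (!is.na(log$price[i])) w$balance <- w$balance + log$price[i]
      state$wards[[wid]] <- w
      state$n_admitted <- state$n_admitted + 1L
    } else if (kind == "discharge") {
      wid <- log$ward[i]
      w <- state$wards[[wid]]
      keep <- w$occupants$patient_id != log$patient_id[i]
      w$workload <- w$workload - sum(w$occupants$increment[!keep])
      w$occupants <- w$occupants[keep, , drop = FALSE]
      state$wards[[wid]] <- w
      state$n_discharged <- state$n_discharged + 1L
    }
  }
  state$day <- if (nrow(log)) max(log$day) + 1L else 0L
  state$next_patient <- state$n_admitted + 1L
  state
}

#' Per-ward occupancy trajectory from an event log
#'
#' Tracks occupancy event-by-event (admissions +1, discharges -1), giving the
#' running and maximum simultaneous occupancy of every ward over the whole
#' session, at event resolution rather than day resolution.
#'
#' @param log An event-log data frame.
#' @param config The corresponding `scenario_config`.
#' @return List with `trajectory` (data frame: day, seq, ward, occupancy) and
#'   `max_occupancy` (named integer vector per ward).
#' @export
occupancy_trajectory <- function(log, config) {
  wards <- config$wards$id
  occ <- stats::setNames(integer(length(wards)), wards)
  max_occ <- occ
  moves <- log[log$kind %in% c("admission", "discharge"), , drop = FALSE]
  moves <- moves[order(moves$day, moves$seq), , drop = FALSE]
  n <- nrow(moves)
  traj <- data.frame(day = moves$day, seq = moves$seq, ward = moves$ward,
                     occupancy = integer(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    wid <- moves$ward[i]
    occ[[wid]] <- occ[[wid]] + if (moves$kind[i] == "admission") 1L else -1L
    if (occ[[wid]] > max_occ[[wid]]) max_occ[[wid]] <- occ[[wid]]
    traj$occupancy[i] <- occ[[wid]]
  }
  list(trajectory = traj, max_occupancy = max_occ)
}
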