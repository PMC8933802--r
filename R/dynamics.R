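# Stochastic processes driving occupancy: arrivals, admission bookkeeping,
# and per-day Bernoulli discharge (geometric length of stay).

#' Initialize an empty hospital state
#'
#' @param config A validated `scenario_config`.
#' @return A `hospital_state`: day counter, per-ward occupancy records
#'   (patient id, type, admit day, and the stored workload increment so
#'   discharge can reverse it exactly), running workload and token balance,
#'   and admission/discharge tallies.
#' @export
new_hospital_state <- function(config) {
  wards <- lapply(seq_len(nrow(config$wards)), function(i) {
    list(
      id        = config$wards$id[i],
      specialty = config$wards$specialty[i],
      capacity  = as.integer(config$wards$capacity[i]),
      occupants = data.frame(patient_id = character(), illness = character(),
                             severity = character(), admit_day = integer(),
                             increment = numeric(), stringsAsFactors = FALSE),
      workload  = 0,
      balance   = 0
    )
  })
  names(wards) <- config$wards$id
  structure(list(
    day = 0L,
    wards = wards,
    n_admitted = 0L,
    n_discharged = 0L,
    next_patient = 1L
  ), class = "hospital_state")
}

#' Total current occupancy per ward
#' @param state A `hospital_state`.
#' @return Named integer vector, ward id -> number of occupied beds.
#' @export
occupancy <- function(state) {
  vapply(state$wards, function(w) nrow(w$occupants), integer(1))
}

#' Vacant beds per ward
#' @param state A `hospital_state`.
#' @return Named integer vector, ward id -> vacant bed count.
#' @export
vacancies <- function(state) {
  vapply(state$wards, function(w) w$capacity - nrow(w$occupants), integer(1))
}

#' Generate one day's patient arrivals
#'
#' Draws `arrivals_per_day` patients i.i.d. from the configured arrival
#' distribution over (illness, severity) patterns. Arrival order within the
#' day is the allocation order.
#'
#' @param day Day index (>= 0).
#' @param config A `scenario_config`.
#' @param rng A `random_stream`; uses the `arrivals` substream.
#' @param first_id Integer id to assign to the first patient of the batch.
#' @return An `arrival_batch`: list with `day` and `patients`, a data frame
#'   with columns `patient_id`, `illness`, `severity`.
#' @export
generate_arrivals <- function(day, config, rng, first_id = 1L) {
  stopifnot(day >= 0)
  n <- config$arrivals_per_day
  grid <- pattern_grid(config)
  probs <- config$arrival_distribution[grid$key]
  idx <- if (n > 0L) {
    rs_draw(rng, "arrivals",
            sample.int(nrow(grid), n, replace = TRUE, prob = probs))
  } else integer()
  patients <- data.frame(
    patient_id = sprintf("p%06d", seq.int(first_id, length.out = n)),
    illness = grid$illness[idx],
    severity = grid$severity[idx],
    stringsAsFactors = FALSE
  )
  structure(list(day = day, patients = patients), class = "arrival_batch")
}

#' Admit a patient to a ward
#'
#' Adds the patient to the ward's occupancy record with the workload
#' increment given by [workload_increment()]; the increment is stored with
#' the record so a later discharge reverses it exactly.
#'
#' @param ward One ward entry of a `hospital_state`.
#' @param patient One-row data frame (or list) with `patient_id`, `illness`,
#'   `severity`.
#' @param day Admission day.
#' @param weights A `weight_table`.
#' @return The updated ward (list). Errors if the ward is full: the engine
#'   must never request an admission without a vacancy.
#' @export
apply_admission <- function(ward, patient, day, weights) {
  if (nrow(ward$occupants) >= ward$capacity) {
    stop(sprintf("capacity violation: ward %s is full (%d beds)",
                 ward$id, ward$capacity), call. = FALSE)
  }
  inc <- workload_increment(patient$illness, patient$severity, ward$specialty,
                            weights)
  rec <- data.frame(patient_id = patient$patient_id, illness = patient$illness,
                    severity = patient$severity, admit_day = as.integer(day),
                    increment = inc, stringsAsFactors = FALSE)
  ward$occupants <- rbind(ward$occupants, rec)
  ward$workload <- ward$workload + inc
  ward
}

#' One day's random discharges
#'
#' Every occupant admitted before `day` is independently discharged with
#' probability `1/mean_los_days` (same-day admissions are ineligible, so no
#' stay is shorter than one day). Length of stay is therefore geometric with
#' mean `mean_los_days`. Each discharged patient's stored workload increment
#' is subtracted from the ward.
#'
#' @param state A `hospital_state`.
#' @param day Current day index.
#' @param config A `scenario_config`.
#' @param rng A `random_stream`; uses the `discharge` substream.
#' @return List with `state` (updated) and `discharges`, a data frame of
#'   discharge records (`patient_id`, `ward`, `illness`, `severity`,
#'   `admit_day`, `increment`).
#' @export
discharge_step <- function(state, day, config, rng) {
  p <- 1 / config$mean_los_days
  out <- vector("list", length(state$wards))
  for (i in seq_along(state$wards)) {
    w <- state$wards[[i]]
    occ <- w$occupants
    eligible <- occ$admit_day < day
    n_el <- sum(eligible)
    go <- rep(FALSE, nrow(occ))
    if (n_el > 0L) {
      go[eligible] <- rs_draw(rng, "discharge", stats::runif(n_el)) < p
    }
    if (any(go)) {
      leaving <- occ[go, , drop = FALSE]
      w$occupants <- occ[!go, , drop = FALSE]
      w$workload <- w$workload - sum(leaving$increment)
      state$n_discharged <- state$n_discharged + nrow(leaving)
      leaving$ward <- w$id
      out[[i]] <- leaving
      state$wards[[i]] <- w
    }
  }
  discharges <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(discharges)) {
    discharges <- data.frame(patient_id = character(), illness = character(),
                             severity = character(), admit_day = integer(),
                             increment = numeric(), ward = character(),
                             stringsAsFactors = FALSE)
  }
  list(state = state, discharges = discharges)
}

#' Simulate independent lengths of stay through the discharge process
#'
#' Fills one large ward with `n` patients on day 0 and runs [discharge_step()]
#' day by day until the ward empties, recording each patient's stay. This
#' exercises the actual engine path, not a shortcut draw from a geometric
#' distribution, and is the basis for checking that the empirical mean stay
#' recovers `mean_los_days`.
#'
#' @param n Number of stays to simulate.
#' @param mean_los_days Mean length of stay (days).
#' @param seed RNG seed.
#' @param max_days Safety cap on simulated days.
#' @return Integer vector of `n` lengths of stay, in days.
#' @export
simulate_stays <- function(n, mean_los_days = 14, seed = 1L, max_days = 100000L) {
  config <- scenario_config(
    wards = data.frame(id = "W", specialty = default_illnesses()[1],
                       capacity = as.integer(n), stringsAsFactors = FALSE),
    arrivals_per_day = 0L, mean_los_days = mean_los_days, n_days = 0L,
    seed = seed
  )
  rng <- random_stream(seed)
  state <- new_hospital_state(config)
  w <- state$wards[[1]]
  w$occupants <- data.frame(
    patient_id = sprintf("p%06d", seq_len(n)),
    illness = config$illnesses[1], severity = config$severities[1],
    admit_day = 0L, increment = 1.0, stringsAsFactors = FALSE
  )
  w$workload <- sum(w$occupants$increment)
  state$wards[[1]] <- w

  stays <- integer(0)
  day <- 0L
  while (nrow(state$wards[[1]]$occupants) > 0L && day < max_days) {
    day <- day + 1L
    step <- discharge_step(state, day, config, rng)
    state <- step$state
    if (nrow(step$discharges)) {
      stays <- c(stays, day - step$discharges$admit_day)
    }
  }
  stays
}

#' Verify the workload identity of a state
#'
#' Checks, for every ward, that the incrementally maintained workload equals
#' the sum of the stored per-occupant increments (tolerance 1e-9).
#'
#' @param state A `hospital_state`.
#' @return `TRUE` invisibly, or an error naming the drifting ward.
#' @export
check_workload_identity <- function(state) {
  for (w in state$wards) {
    recomputed <- sum(w$occupants$increment)
    if (abs(w$workload - recomputed) > 1e-9) {
      stop(sprintf("workload drift in ward %s: incremental %.12g vs recomputed %.12g",
                   w$id, w$workload, recomputed), call. = FALSE)
    }
  }
  invisible(TRUE)
}
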