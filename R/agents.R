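# The physician agent's ward-selection rule and the pluggable nurse-manager
# pricing policies, with the information-asymmetry constraint enforced by the
# WardView type: a policy sees its own ward in full but only the number of
# patients admitted to other wards.

# ---- ward view -------------------------------------------------------------

#' Construct a ward manager's view of the hospital
#'
#' This is everything a pricing policy is allowed to observe: the manager's
#' own ward in full (occupancy, workload, balance, specialty, capacity), the
#' *patient counts only* of other wards, the day index, and the manager's own
#' price history. Other wards' workloads, balances, and (by default) prices
#' are deliberately absent from the type, so the asymmetry cannot be violated
#' by a policy even accidentally.
#'
#' @param state A `hospital_state`.
#' @param ward_id The observing ward.
#' @param day Current day.
#' @param price_history List of the ward's own previous `price_list`s.
#' @param other_prices Optional named list of other wards' price lists;
#'   included only when the scenario sets `show_other_prices` (a relaxation of
#'   the default strict asymmetry).
#' @return A `ward_view` object.
#' @export
ward_view <- function(state, ward_id, day, price_history = list(),
                      other_prices = NULL) {
  own <- state$wards[[ward_id]]
  if (is.null(own)) stop(sprintf("unknown ward '%s'", ward_id), call. = FALSE)
  occ <- occupancy(state)
  view <- list(
    day = day,
    own_ward = list(
      id = own$id, specialty = own$specialty, capacity = own$capacity,
      occupancy = nrow(own$occupants), workload = own$workload,
      balance = own$balance,
      occupants = own$occupants[, c("illness", "severity", "admit_day")]
    ),
    other_patient_counts = occ[setdiff(names(occ), ward_id)],
    own_price_history = price_history
  )
  if (!is.null(other_prices)) view$other_prices <- other_prices
  structure(view, class = "ward_view")
}

# ---- pricing policies ------------------------------------------------------

#' Build a pricing policy from a spec
#'
#' Policies stand in for the human nurse managers of the original game. Kinds:
#' \describe{
#'   \item{constant}{`base`: one price for every pattern, every day.}
#'   \item{workload_linear}{`base + slope * own current workload`, clipped at
#'     0, for every pattern; optional `noise_sd` adds mean-zero Gaussian
#'     jitter (drawn per day per pattern from the policy substream), giving a
#'     workload-independent source of price variation.}
#'   \item{random}{uniform prices on `[min, max]` per pattern per day.}
#'   \item{replay}{reads the day's prices from a recorded schedule (see
#'     [read_schedule()]); `schedule` may be a data frame or a CSV path.}
#'   \item{interactive}{prompts on the terminal with the same information the
#'     original web interface showed.}
#' }
#'
#' @param spec List with `kind` and kind-specific parameters.
#' @param ward_id Ward the policy prices for (needed by replay/interactive).
#' @return A `pricing_policy` object (subclassed by kind).
#' @export
make_policy <- function(spec, ward_id = NULL) {
  kind <- spec$kind
  if (is.null(kind) ||
      !kind %in% c("constant", "workload_linear", "random", "replay", "interactive")) {
    stop("unknown policy kind: ", deparse(kind), call. = FALSE)
  }
  pol <- spec
  pol$ward_id <- ward_id
  if (kind == "replay" && is.character(pol$schedule)) {
    pol$schedule <- read_schedule(pol$schedule)
  }
  structure(pol, class = c(paste0(kind, "_policy"), "pricing_policy"))
}

#' Set a ward's daily prices
#'
#' Dispatches on policy kind; every method consumes only a [ward_view()] (plus
#' the policy's own parameters and RNG substream) and returns a complete
#' non-negative [price_list()] for the day. Negative computed prices are
#' clipped to 0 with a warning.
#'
#' @param policy A `pricing_policy`.
#' @param view The ward's `ward_view` for the current day.
#' @param config A `scenario_config` (for the pattern grid).
#' @param rng A `random_stream`; stochastic policies use the `policy`
#'   substream.
#' @return A `price_list` effective for `view$day`.
#' @export
set_prices <- function(policy, view, config, rng) {
  stopifnot(inherits(policy, "pricing_policy"), inherits(view, "ward_view"))
  UseMethod("set_prices")
}

.pattern_base <- function(base, keys) {
  # base may be a scalar or a named per-pattern vector (or list, from YAML)
  base <- unlist(base)
  if (length(base) == 1L && is.null(names(base))) {
    stats::setNames(rep(as.numeric(base), length(keys)), keys)
  } else {
    missing <- setdiff(keys, names(base))
    if (length(missing)) {
      stop("policy base prices missing patterns: ",
           paste(missing, collapse = "; "), call. = FALSE)
    }
    stats::setNames(as.numeric(base[keys]), keys)
  }
}

.clip_prices <- function(prices, context) {
  if (any(prices < 0)) {
    warning(sprintf("%s: %d negative price(s) clipped to 0", context,
                    sum(prices < 0)), call. = FALSE)
    prices[prices < 0] <- 0
  }
  prices
}

#' @export
set_prices.constant_policy <- function(policy, view, config, rng) {
  keys <- pattern_grid(config)$key
  prices <- .clip_prices(.pattern_base(policy$base, keys), "constant policy")
  price_list(prices, view$day, config)
}

#' @export
set_prices.workload_linear_policy <- function(policy, view, config, rng) {
  keys <- pattern_grid(config)$key
  base <- .pattern_base(policy$base, keys)
  slope <- if (is.null(policy$slope)) 0 else as.numeric(policy$slope)
  prices <- base + slope * view$own_ward$workload
  noise_sd <- if (is.null(policy$noise_sd)) 0 else as.numeric(policy$noise_sd)
  if (noise_sd > 0) {
    prices <- prices + rs_draw(rng, "policy", stats::rnorm(length(keys), 0, noise_sd))
  }
  prices <- .clip_prices(prices, "workload_linear policy")
  price_list(prices, view$day, config)
}

#' @export
set_prices.random_policy <- function(policy, view, config, rng) {
  keys <- pattern_grid(config)$key
  lo <- if (is.null(policy$min)) 0 else as.numeric(policy$min)
  hi <- if (is.null(policy$max)) 10 else as.numeric(policy$max)
  prices <- stats::setNames(rs_draw(rng, "policy", stats::runif(length(keys), lo, hi)),
                            keys)
  price_list(prices, view$day, config)
}

#' @export
set_prices.replay_policy <- function(policy, view, config, rng) {
  sched <- policy$schedule
  rows <- sched[sched$day == view$day & sched$ward == policy$ward_id, , drop = FALSE]
  grid <- pattern_grid(config)
  if (nrow(rows) == 0L) {
    stop(sprintf("replay schedule has no prices for ward %s on day %d",
                 policy$ward_id, view$day), call. = FALSE)
  }
  prices <- stats::setNames(rows$price, pattern_key(rows$illness, rows$severity))
  missing <- setdiff(grid$key, names(prices))
  if (length(missing)) {
    stop(sprintf("replay schedule for ward %s, day %d is missing patterns: %s",
                 policy$ward_id, view$day, paste(missing, collapse = "; ")),
         call. = FALSE)
  }
  price_list(prices[grid$key], view$day, config)
}

#' @export
set_prices.interactive_policy <- function(policy, view, config, rng) {
  if (!interactive() && !isTRUE(policy$force_terminal)) {
    stop("interactive pricing requires a terminal session", call. = FALSE)
  }
  grid <- pattern_grid(config)
  cat(sprintf("\n== Day %d | ward %s (specialty: %s) ==\n", view$day,
              view$own_ward$id, view$own_ward$specialty))
  cat(sprintf("Your ward: %d/%d beds occupied, workload %.2f, balance %.2f tokens\n",
              view$own_ward$occupancy, view$own_ward$capacity,
              view$own_ward$workload, view$own_ward$balance))
  if (length(view$other_patient_counts)) {
    cat("Patients in other wards:",
        paste(sprintf("%s: %d", names(view$other_patient_counts),
                      view$other_patient_counts), collapse = ", "), "\n")
  }
  prices <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    repeat {
      ans <- readline(sprintf("Price for %s: ", grid$key[i]))
      val <- suppressWarnings(as.numeric(ans))
      if (is.finite(val) && val >= 0) break
      cat("Please enter a non-negative number.\n")
    }
    prices[i] <- val
  }
  price_list(stats::setNames(prices, grid$key), view$day, config)
}

# ---- physician agent -------------------------------------------------------

#' Physician agent's ward selection for one patient
#'
#' The emulated admission decision: among wards with a vacant bed, take the
#' lowest posted price for the patient's (illness, severity) pattern — unless
#' the ward specializing in the patient's illness is vacant, in which case a
#' premium is acceptable. Formally, with `m` drawn uniform on
#' `multiplier_range` fresh for every admission decision, the specialty ward
#' `s` is chosen iff `price_s <= m * p_min`; since `m >= 1`, a specialty ward
#' posting the minimum price is always chosen. Ties at the minimum are broken
#' uniformly at random from the dedicated `tiebreak` substream.
#'
#' @param patient List or one-row data frame with `illness`, `severity` (and
#'   optionally `patient_id`).
#' @param prices Named list: ward id -> `price_list` for the current day.
#' @param vacant Named integer vector: ward id -> vacant bed count.
#' @param specialties Named character vector: ward id -> specialty illness.
#' @param multiplier_range Numeric `c(lo, hi)`, `1 <= lo <= hi`.
#' @param rng A `random_stream`; uses `multiplier` and `tiebreak` substreams.
#' @return A `selection_outcome`: list with `ward` (id or `NA`), `price_paid`,
#'   `lowest_price`, `specialty_price`, `multiplier` (sampled iff the
#'   specialty ward was vacant), and `reason` in
#'   `{"lowest_price", "specialty_premium", "no_vacancy"}`.
#' @export
select_ward <- function(patient, prices, vacant, specialties,
                        multiplier_range, rng) {
  key <- pattern_key(patient$illness, patient$severity)
  candidates <- names(vacant)[vacant >= 1L]
  if (length(candidates) == 0L) {
    return(structure(list(
      patient_id = patient$patient_id %||% NA_character_,
      ward = NA_character_, price_paid = NA_real_, lowest_price = NA_real_,
      specialty_price = NA_real_, multiplier = NA_real_, reason = "no_vacancy"
    ), class = "selection_outcome"))
  }
  cand_prices <- vapply(candidates, function(wid) {
    pl <- prices[[wid]]
    if (is.null(pl) || !key %in% names(pl$prices)) {
      stop(sprintf("no posted price for pattern '%s' at ward %s", key, wid),
           call. = FALSE)
    }
    unname(pl$prices[[key]])
  }, numeric(1))
  p_min <- min(cand_prices)

  s <- names(specialties)[specialties == patient$illness]
  s <- if (length(s)) s[1] else NA_character_
  multiplier <- NA_real_
  specialty_price <- if (!is.na(s) && s %in% candidates) cand_prices[[s]] else NA_real_

  if (!is.na(s) && s %in% candidates) {
    # fresh multiplier for every admission decision in which the specialty
    # ward is an option
    multiplier <- rs_draw(rng, "multiplier",
                          stats::runif(1, multiplier_range[1], multiplier_range[2]))
    if (specialty_price <= multiplier * p_min) {
      reason <- if (specialty_price == p_min) "lowest_price" else "specialty_premium"
      return(structure(list(
        patient_id = patient$patient_id %||% NA_character_,
        ward = s, price_paid = unname(specialty_price), lowest_price = p_min,
        specialty_price = unname(specialty_price), multiplier = multiplier,
        reason = reason
      ), class = "selection_outcome"))
    }
  }

  at_min <- candidates[cand_prices == p_min]
  ward <- if (length(at_min) == 1L) at_min else {
    at_min[rs_draw(rng, "tiebreak", sample.int(length(at_min), 1L))]
  }
  structure(list(
    patient_id = patient$patient_id %||% NA_character_,
    ward = ward, price_paid = p_min, lowest_price = p_min,
    specialty_price = unname(specialty_price), multiplier = multiplier,
    reason = "lowest_price"
  ), class = "selection_outcome")
}

#' Closed-form specialty selection probability
#'
#' For a vacant specialty ward priced at `ratio * p_min` and multiplier
#' uniform on `[lo, hi]`, the probability the physician accepts the specialty
#' premium is `min(1, max(0, (hi - ratio) / (hi - lo)))` (and 1 when
#' `ratio <= lo`). Used as the analytic reference for the Monte Carlo checks.
#'
#' @param ratio Specialty price divided by the minimum competing price.
#' @param lo,hi Multiplier support.
#' @return Probability in `[0, 1]`.
#' @export
specialty_selection_prob <- function(ratio, lo = 1.0, hi = 2.0) {
  if (ratio <= lo) return(1)
  if (ratio >= hi) return(0)
  (hi - ratio) / (hi - lo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
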