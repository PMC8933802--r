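# Configuration loading (YAML/JSON, strict schema), event-log serialization
# (JSON-lines + CSV), replay schedules, and run manifests: the reproducibility
# surface of the artifact.

.known_config_keys <- c(
  "illnesses", "severities", "weights", "wards", "arrivals_per_day",
  "mean_los_days", "n_days", "multiplier_range", "arrival_distribution",
  "policies", "discharge_timing", "show_other_prices", "seed"
)

#' Load a scenario configuration file
#'
#' Reads a YAML or JSON scenario file (chosen by extension), applies defaults
#' for omitted fields, validates every invariant via [validate_config()], and
#' rejects unknown keys (strict schema: a typo never silently becomes a
#' default). See the bundled `paper_default.yaml` under
#' `system.file("extdata", package = "tokenward")` for the full schema.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `scenario_config`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    stop("scenario file must be .yaml, .yml or .json: ", path, call. = FALSE)
  }
  unknown <- setdiff(names(raw), .known_config_keys)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- list()
  if (!is.null(raw$illnesses)) args$illnesses <- as.character(unlist(raw$illnesses))
  if (!is.null(raw$severities)) args$severities <- as.character(unlist(raw$severities))
  sev <- args$severities %||% default_severities()
  if (!is.null(raw$weights)) {
    m <- unlist(raw$weights$matched)
    mm <- unlist(raw$weights$mismatched)
    if (is.null(m) || is.null(mm)) {
      stop("weights must contain 'matched' and 'mismatched' maps", call. = FALSE)
    }
    args$weights <- weight_table(matched = m[sev], mismatched = mm[sev])
  }
  if (!is.null(raw$wards)) {
    wl <- raw$wards
    args$wards <- data.frame(
      id = vapply(wl, function(w) as.character(w$id), character(1)),
      specialty = vapply(wl, function(w) as.character(w$specialty), character(1)),
      capacity = vapply(wl, function(w) as.integer(w$capacity), integer(1)),
      stringsAsFactors = FALSE
    )
  }
  for (k in c("arrivals_per_day", "mean_los_days", "n_days", "seed")) {
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  }
  if (!is.null(raw$multiplier_range)) {
    args$multiplier_range <- as.numeric(unlist(raw$multiplier_range))
  }
  if (!is.null(raw$arrival_distribution)) {
    args$arrival_distribution <- unlist(raw$arrival_distribution)
  }
  if (!is.null(raw$policies)) args$policies <- raw$policies
  if (!is.null(raw$discharge_timing)) args$discharge_timing <- raw$discharge_timing
  if (!is.null(raw$show_other_prices)) args$show_other_prices <- raw$show_other_prices
  do.call(scenario_config, args)
}

#' Write a scenario configuration to YAML
#' @param config A `scenario_config`.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_scenario <- function(config, path) {
  out <- list(
    illnesses = config$illnesses,
    severities = config$severities,
    weights = list(matched = as.list(config$weights$matched),
                   mismatched = as.list(config$weights$mismatched)),
    wards = lapply(seq_len(nrow(config$wards)), function(i) {
      list(id = config$wards$id[i], specialty = config$wards$specialty[i],
           capacity = config$wards$capacity[i])
    }),
    arrivals_per_day = config$arrivals_per_day,
    mean_los_days = config$mean_los_days,
    n_days = config$n_days,
    multiplier_range = config$multiplier_range,
    arrival_distribution = as.list(config$arrival_distribution),
    policies = config$policies,
    discharge_timing = config$discharge_timing,
    show_other_prices = config$show_other_prices,
    seed = config$seed
  )
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

# ---- event log serialization -----------------------------------------------

#' Write an event log as JSON-lines
#'
#' One JSON object per line, in (day, seq) order, `NA` fields omitted — the
#' canonical, stream-appendable on-disk form of a session. Identical sessions
#' serialize byte-identically.
#'
#' @param log Event-log data frame.
#' @param path Output path (conventionally `.jsonl`).
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  log <- log[order(log$day, log$seq), , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    row <- as.list(log[i, , drop = FALSE])
    row <- row[!vapply(row, function(v) is.na(v), logical(1))]
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), con,
               useBytes = TRUE)
  }
  invisible(path)
}

#' Read a JSON-lines event log
#' @param path Path written by [write_event_log()].
#' @return Event-log data frame with the standard columns.
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_event_log())
  rows <- lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
  df <- data.table::rbindlist(rows, fill = TRUE)
  data.table::setDF(df)
  tmpl <- empty_event_log()
  for (m in setdiff(names(tmpl), names(df))) {
    df[[m]] <- rep(tmpl[[m]][NA_integer_], length.out = nrow(df))
  }
  df <- df[, names(tmpl)]
  df$day <- as.integer(df$day); df$seq <- as.integer(df$seq)
  df$admit_day <- as.integer(df$admit_day)
  df[order(df$day, df$seq), , drop = FALSE]
}

#' Write an event log as tidy CSV
#' @param log Event-log data frame.
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_event_csv <- function(log, path) {
  utils::write.csv(log[order(log$day, log$seq), , drop = FALSE], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

# ---- schedules -------------------------------------------------------------

#' Read a price schedule CSV
#'
#' Schedules drive the `replay` pricing policy and are also the format in
#' which interactive sessions are recorded, so a human session can be
#' replayed bit-exactly.
#'
#' @param path CSV with columns `day`, `ward`, `illness`, `severity`, `price`.
#' @return Schedule data frame.
#' @export
read_schedule <- function(path) {
  sched <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("day", "ward", "illness", "severity", "price")
  missing <- setdiff(need, names(sched))
  if (length(missing)) {
    stop("schedule is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sched$day <- as.integer(sched$day)
  sched$price <- as.numeric(sched$price)
  sched
}

#' Extract the price schedule of a session's log
#'
#' The `price_set` events of a log, as a replayable schedule: running
#' a session whose wards use `replay` policies on this schedule (same seed)
#' reproduces the original session exactly.
#'
#' @param log Event-log data frame.
#' @return Schedule data frame (`day`, `ward`, `illness`, `severity`, `price`).
#' @export
schedule_from_log <- function(log) {
  ps <- log[log$kind == "price_set", , drop = FALSE]
  ps <- ps[order(ps$day, ps$seq), c("day", "ward", "illness", "severity", "price")]
  rownames(ps) <- NULL
  ps
}

#' Write a price schedule CSV
#'
#' Prices are written with full double precision so a recorded session
#' replays bit-exactly.
#'
#' @param schedule Schedule data frame.
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  out <- schedule
  out$price <- sprintf("%.17g", out$price)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# ---- snapshots -------------------------------------------------------------

#' Wide per-day snapshot table
#'
#' One row per (day, ward): day-start occupancy, workload, balance, and the
#' day's posted price for every pattern as `price: <illness / severity>`
#' columns.
#'
#' @param result A `session_result`.
#' @return Data frame.
#' @export
snapshot_table <- function(result) {
  snaps <- result$snapshots
  ps <- result$log[result$log$kind == "price_set", , drop = FALSE]
  grid <- pattern_grid(result$config)
  for (k in grid$key) {
    sel <- ps[pattern_key(ps$illness, ps$severity) == k, , drop = FALSE]
    idx <- match(paste(snaps$day, snaps$ward), paste(sel$day, sel$ward))
    snaps[[paste("price:", k)]] <- sel$price[idx]
  }
  snaps
}

# ---- manifest --------------------------------------------------------------

# FNV-1a 32-bit over the canonical JSON serialization of the config; double
# arithmetic with 16-bit split multiplication keeps everything exact.
.fnv1a32 <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Hash a scenario configuration
#'
#' Stable content hash of the canonical serialized form of a config; two
#' configs hash equal iff they describe the same scenario.
#'
#' @param config A `scenario_config`.
#' @return 8-hex-digit hash string.
#' @export
config_hash <- function(config) {
  canon <- jsonlite::toJSON(unclass(config)[order(names(unclass(config)))],
                            auto_unbox = TRUE, digits = I(15), force = TRUE)
  .fnv1a32(as.character(canon))
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run exactly: the config hash, the
#' seed actually used, the package version, a timestamp, and the inventory of
#' output files.
#'
#' @param config The `scenario_config` of the run.
#' @param files Character vector of output file names.
#' @param path Output path (`manifest.json`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, files, path) {
  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    package = "tokenward",
    version = as.character(utils::packageVersion("tokenward")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = as.list(basename(files))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write all artifacts of a session to a directory
#'
#' Emits the canonical output bundle: `events.jsonl`, `events.csv`,
#' `snapshots.csv`, `schedule.csv` (the session's own prices, replayable),
#' per-ward and hospital summary CSVs, and `manifest.json`.
#'
#' @param result A `session_result`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
save_session <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(name) file.path(dir, name)
  write_event_log(result$log, f("events.jsonl"))
  write_event_csv(result$log, f("events.csv"))
  utils::write.csv(snapshot_table(result), f("snapshots.csv"), row.names = FALSE)
  write_schedule(schedule_from_log(result$log), f("schedule.csv"))
  summ <- summarize_session(result)
  utils::write.csv(summ$wards, f("summary_wards.csv"), row.names = FALSE)
  utils::write.csv(summ$hospital, f("summary_hospital.csv"), row.names = FALSE)
  files <- c("events.jsonl", "events.csv", "snapshots.csv", "schedule.csv",
             "summary_wards.csv", "summary_hospital.csv")
  write_manifest(result$config, files, f("manifest.json"))
  invisible(dir)
}
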