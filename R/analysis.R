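# Price-workload signaling analysis: does a ward's posted price carry
# information about its hidden workload state? Pairs are reconstructed purely
# from the event log, so any recorded or replayed session can be analyzed.

#' Extract price-workload pairs from an event log
#'
#' Replays the log's admissions and discharges to track each ward's running
#' workload, and pairs every posted price with the poster's workload at the
#' moment of pricing — i.e. at day start, before that day's arrivals and
#' discharges. One pair per (day, ward, pattern).
#'
#' @param log An event-log data frame (from [run_session()] or
#'   [read_event_log()]).
#' @return Data frame with columns `day`, `ward`, `illness`, `severity`,
#'   `workload_at_pricing`, `price`. Zero rows (with a warning) if the log
#'   has no price events.
#' @export
extract_pairs <- function(log) {
  log <- log[order(log$day, log$seq), , drop = FALSE]
  if (!any(log$kind == "price_set")) {
    if (nrow(log)) warning("event log contains no price_set events", call. = FALSE)
    return(data.frame(day = integer(), ward = character(), illness = character(),
                      severity = character(), workload_at_pricing = numeric(),
                      price = numeric(), stringsAsFactors = FALSE))
  }
  workload <- new.env(parent = emptyenv())
  n_prices <- sum(log$kind == "price_set")
  out <- data.frame(day = integer(n_prices), ward = character(n_prices),
                    illness = character(n_prices), severity = character(n_prices),
                    workload_at_pricing = numeric(n_prices),
                    price = numeric(n_prices), stringsAsFactors = FALSE)
  j <- 0L
  wl <- function(wid) get0(wid, envir = workload, ifnotfound = 0)
  for (i in seq_len(nrow(log))) {
    kind <- log$kind[i]
    if (kind == "price_set") {
      j <- j + 1L
      out$day[j] <- log$day[i]
      out$ward[j] <- log$ward[i]
      out$illness[j] <- log$illness[i]
      out$severity[j] <- log$severity[i]
      out$workload_at_pricing[j] <- wl(log$ward[i])
      out$price[j] <- log$price[i]
    } else if (kind == "admission") {
      workload[[log$ward[i]]] <- wl(log$ward[i]) + log$increment[i]
    } else if (kind == "discharge") {
      workload[[log$ward[i]]] <- wl(log$ward[i]) - log$increment[i]
    }
  }
  out
}

#' Price-workload association per group
#'
#' Computes both Pearson's r (linear association) and Spearman's rho (rank
#' association) of posted price against workload at pricing time, within each
#' group. Both are reported because the signaling relationship need not be
#' linear, nor even monotone every day. Groups with fewer than 3 pairs or
#' with no variance in either variable are flagged, never fabricated.
#'
#' @param pairs Data frame from [extract_pairs()].
#' @param grouping `"ward"`, `"pattern"` (illness x severity, pooled across
#'   wards), `"ward_pattern"`, or `"pooled"`.
#' @return Data frame with one row per group: `group`, `n`, `pearson_r`,
#'   `spearman_rho`, `degenerate` in
#'   `{"none", "zero_price_variance", "zero_workload_variance", "too_few_points"}`.
#' @export
association <- function(pairs, grouping = c("ward", "pattern", "ward_pattern",
                                            "pooled")) {
  grouping <- match.arg(grouping)
  key <- switch(grouping,
    ward = pairs$ward,
    pattern = pattern_key(pairs$illness, pairs$severity),
    ward_pattern = paste(pairs$ward, pattern_key(pairs$illness, pairs$severity),
                         sep = " @ "),
    pooled = rep("pooled", nrow(pairs))
  )
  groups <- if (nrow(pairs)) unique(key) else character()
  rows <- lapply(groups, function(g) {
    sub <- pairs[key == g, , drop = FALSE]
    n <- nrow(sub)
    flag <- "none"
    r <- rho <- NA_real_
    if (n < 3L) {
      flag <- "too_few_points"
    } else if (stats::sd(sub$price) == 0) {
      flag <- "zero_price_variance"
    } else if (stats::sd(sub$workload_at_pricing) == 0) {
      flag <- "zero_workload_variance"
    } else {
      r <- stats::cor(sub$workload_at_pricing, sub$price, method = "pearson")
      rho <- stats::cor(sub$workload_at_pricing, sub$price, method = "spearman")
    }
    data.frame(group = g, n = n, pearson_r = r, spearman_rho = rho,
               degenerate = flag, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(group = character(), n = integer(), pearson_r = numeric(),
               spearman_rho = numeric(), degenerate = character(),
               stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Summarize a session
#'
#' Per ward: final token balance, mean and maximum day-start workload, mean
#' day-start occupancy, and the fraction of its admissions that matched its
#' specialty. Hospital-wide: empirical mean length of stay over completed
#' stays, and the rejection count.
#'
#' @param result A `session_result`.
#' @return List with `wards` (data frame) and `hospital` (data frame with
#'   `mean_los`, `n_completed_stays`, `rejections`, `total_issuance`).
#' @export
summarize_session <- function(result) {
  cfg <- result$config
  snaps <- result$snapshots
  log <- result$log
  adm <- log[log$kind == "admission", , drop = FALSE]
  dis <- log[log$kind == "discharge", , drop = FALSE]
  specialties <- stats::setNames(cfg$wards$specialty, cfg$wards$id)

  wards <- do.call(rbind, lapply(cfg$wards$id, function(wid) {
    s <- snaps[snaps$ward == wid, , drop = FALSE]
    a <- adm[adm$ward == wid, , drop = FALSE]
    data.frame(
      ward = wid,
      final_balance = result$ledger$ward_balances[[wid]],
      mean_workload = if (nrow(s)) mean(s$workload) else 0,
      max_workload = if (nrow(s)) max(s$workload) else 0,
      mean_occupancy = if (nrow(s)) mean(s$occupancy) else 0,
      n_admissions = nrow(a),
      specialty_match_fraction = if (nrow(a))
        mean(a$illness == specialties[[wid]]) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(wards) <- NULL

  stays <- if (nrow(dis)) dis$day - dis$admit_day else numeric()
  hospital <- data.frame(
    mean_los = if (length(stays)) mean(stays) else NA_real_,
    n_completed_stays = length(stays),
    rejections = result$rejections,
    total_issuance = result$ledger$hospital_issuance
  )
  list(wards = wards, hospital = hospital)
}

#' Plot posted price against workload
#'
#' Scatter of price versus workload at pricing time, one facet per
#' (illness, severity) pattern, points shaded by workload — the layout of the
#' signaling figure. Requires ggplot2.
#'
#' @param pairs Data frame from [extract_pairs()].
#' @return A ggplot object.
#' @export
plot_price_workload <- function(pairs) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  pairs$pattern <- pattern_key(pairs$illness, pairs$severity)
  ggplot2::ggplot(pairs,
                  ggplot2::aes(x = .data$workload_at_pricing, y = .data$price,
                               colour = .data$workload_at_pricing)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_gradient(low = "grey80", high = "grey20",
                                   name = "workload") +
    ggplot2::facet_wrap(~pattern) +
    ggplot2::labs(x = "workload at pricing time (points)",
                  y = "posted price (tokens)") +
    ggplot2::theme_minimal()
}
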