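# Abundance-to-biomass reconstruction.
#
# Pitfall catches are interval totals, not daily counts. Each interval count
# is spread uniformly over its in-window trap-days to give per-day per-trap
# specimen counts; lengths are then assigned per specimen from the auxiliary
# length dataset (or, in expectation mode, every specimen-equivalent carries
# the dataset's mean mass), converted to mass through taxon-specific power-law
# allometry, and summed into per-year daily abundance and biomass series
# averaged across active traps.

#' Spread interval catches uniformly over trap-days
#'
#' Each record's count is divided by its interval length (days) and that
#' daily share is attributed to every interval day that falls inside the
#' analysis window. Days outside the window are truncated: their shares are
#' dropped, not redistributed. Records whose interval lies wholly outside
#' the window are dropped with a message.
#'
#' @param catches data.frame with columns year, doy_start, doy_end, plot,
#'   trap, taxon, life_stage, count.
#' @param window Length-2 integer vector, analysis window in DOY
#'   (default `c(157, 238)`).
#' @return data.frame (year, doy, plot, trap, taxon, life_stage, count)
#'   with one row per in-window trap-day share; `count` is the (fractional)
#'   daily count. Attribute `n_dropped` records how many input rows were
#'   wholly outside the window.
#' @export
spread_interval_catches <- function(catches, window = c(157L, 238L)) {
  .check_columns(catches, c("year", "doy_start", "doy_end", "plot", "trap",
                            "taxon", "life_stage", "count"), "catch table")
  stopifnot(length(window) == 2L, window[1L] < window[2L])
  if (any(catches$doy_end < catches$doy_start)) {
    stop("invalid interval: doy_end < doy_start")
  }
  if (any(catches$count < 0)) stop("negative counts are not allowed")

  n_days <- catches$doy_end - catches$doy_start + 1L
  inside <- pmax(0L, pmin(catches$doy_end, window[2L]) -
                   pmax(catches$doy_start, window[1L]) + 1L)
  dropped <- inside == 0L
  if (any(dropped)) {
    message(sum(dropped), " record(s) wholly outside the window were dropped")
  }
  keep <- which(!dropped)
  if (length(keep) == 0L) {
    out <- catches[0L, c("year", "plot", "trap", "taxon", "life_stage")]
    out$doy <- integer(0L)
    out$count <- numeric(0L)
    out <- out[c("year", "doy", "plot", "trap", "taxon", "life_stage", "count")]
    attr(out, "n_dropped") <- sum(dropped)
    return(out)
  }

  idx <- rep(keep, inside[keep])
  first_in <- pmax(catches$doy_start[keep], window[1L])
  doy <- unlist(lapply(seq_along(keep), function(i) {
    first_in[i] + seq_len(inside[keep[i]]) - 1L
  }), use.names = FALSE)
  out <- data.frame(year = catches$year[idx], doy = doy,
                    plot = catches$plot[idx], trap = catches$trap[idx],
                    taxon = catches$taxon[idx],
                    life_stage = catches$life_stage[idx],
                    count = catches$count[idx] / n_days[idx],
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(dropped)
  out
}

#' Expected specimen length and mass per taxon/life stage
#'
#' @param lengths Length table (taxon, life_stage, length_mm).
#' @param allometry Allometry table (taxon, coeff_a, exponent_b).
#' @return data.frame (taxon, life_stage, mean_length_mm, mean_mass_mg) where
#'   mean mass is the table mean of coeff_a * length^exponent_b (the expected
#'   mass of a randomly assigned specimen, not the mass at the mean length).
#' @export
expected_specimen_mass <- function(lengths, allometry) {
  .check_columns(lengths, c("taxon", "life_stage", "length_mm"), "length table")
  .check_columns(allometry, c("taxon", "coeff_a", "exponent_b"), "allometry table")
  key <- unique(lengths[c("taxon", "life_stage")])
  key$mean_length_mm <- NA_real_
  key$mean_mass_mg <- NA_real_
  for (i in seq_len(nrow(key))) {
    lens <- lengths$length_mm[lengths$taxon == key$taxon[i] &
                                lengths$life_stage == key$life_stage[i]]
    j <- match(key$taxon[i], allometry$taxon)
    if (is.na(j)) stop("no allometric coefficients for taxon '", key$taxon[i], "'")
    key$mean_length_mm[i] <- mean(lens)
    key$mean_mass_mg[i] <- mean(length_to_mass(lens, allometry$coeff_a[j],
                                               allometry$exponent_b[j]))
  }
  rownames(key) <- NULL
  key
}

#' Assign body lengths to individual specimens
#'
#' Explodes each catch record into its individual specimens and assigns each
#' an independent length drawn with replacement from the taxon/life-stage
#' entry of the auxiliary length dataset.
#'
#' @param catches Catch table (see [spread_interval_catches()]); counts must
#'   be integers (lengths are drawn per physical specimen, before any
#'   interval spreading).
#' @param lengths Length table (taxon, life_stage, length_mm).
#' @param seed Integer seed; a fixed seed gives identical assignments.
#' @return data.frame with one row per specimen: the record's identifying
#'   columns plus `length_mm`.
#' @export
assign_lengths <- function(catches, lengths, seed = NULL) {
  .check_columns(catches, c("year", "doy_start", "doy_end", "plot", "trap",
                            "taxon", "life_stage", "count"), "catch table")
  .check_columns(lengths, c("taxon", "life_stage", "length_mm"), "length table")
  if (any(catches$count != round(catches$count))) {
    stop("assign_lengths requires integer counts (pre-spreading records)")
  }
  present <- unique(catches[catches$count > 0, c("taxon", "life_stage")])
  have <- unique(lengths[c("taxon", "life_stage")])
  miss <- !mapply(function(t, s) any(have$taxon == t & have$life_stage == s),
                  present$taxon, present$life_stage)
  if (length(miss) > 0L && any(miss)) {
    stop("no length data for taxon '", present$taxon[which(miss)[1L]],
         "' (", present$life_stage[which(miss)[1L]], ")")
  }
  if (!is.null(seed)) set.seed(derive_seeds(seed, 1L))
  idx <- rep(seq_len(nrow(catches)), catches$count)
  out <- catches[idx, c("year", "doy_start", "doy_end", "plot", "trap",
                        "taxon", "life_stage")]
  out$length_mm <- NA_real_
  # draw in a fixed (taxon, stage) order for reproducibility
  keys <- unique(out[c("taxon", "life_stage")])
  keys <- keys[order(keys$taxon, keys$life_stage), , drop = FALSE]
  for (i in seq_len(nrow(keys))) {
    pool <- lengths$length_mm[lengths$taxon == keys$taxon[i] &
                                lengths$life_stage == keys$life_stage[i]]
    sel <- out$taxon == keys$taxon[i] & out$life_stage == keys$life_stage[i]
    out$length_mm[sel] <- pool[sample.int(length(pool), sum(sel), replace = TRUE)]
  }
  rownames(out) <- NULL
  out
}

#' Convert body length to body mass by power-law allometry
#'
#' mass_mg = coeff_a * length_mm ^ exponent_b.
#'
#' @param length_mm Body length(s) in mm, > 0.
#' @param coeff_a Allometric multiplier (> 0).
#' @param exponent_b Allometric exponent.
#' @return Mass in mg.
#' @export
length_to_mass <- function(length_mm, coeff_a, exponent_b) {
  if (any(!is.finite(length_mm)) || any(length_mm <= 0)) {
    stop("lengths must be positive")
  }
  if (any(coeff_a <= 0)) stop("coeff_a must be positive")
  coeff_a * length_mm^exponent_b
}

#' Trap activity calendar implied by a catch table
#'
#' A trap is considered active on every day covered by one of its trapping
#' intervals (the generator emits records for every trap-interval cell,
#' including zero catches, so coverage is explicit).
#'
#' @param catches Catch table.
#' @param window Analysis window, DOY.
#' @return data.frame (year, doy, n_active_traps) for every window day of
#'   every year present.
#' @export
trap_activity_from_catches <- function(catches, window = c(157L, 238L)) {
  .check_columns(catches, c("year", "doy_start", "doy_end", "plot", "trap"),
                 "catch table")
  trap_id <- paste(catches$plot, catches$trap, sep = "/")
  cover <- unique(data.frame(year = catches$year, trap_id = trap_id,
                             doy_start = catches$doy_start,
                             doy_end = catches$doy_end))
  days <- window[1L]:window[2L]
  out <- expand.grid(doy = days, year = sort(unique(catches$year)),
                     KEEP.OUT.ATTRS = FALSE)[, c("year", "doy")]
  out$n_active_traps <- 0L
  for (yr in unique(out$year)) {
    cy <- cover[cover$year == yr, , drop = FALSE]
    n_active <- vapply(days, function(d) {
      length(unique(cy$trap_id[cy$doy_start <= d & cy$doy_end >= d]))
    }, integer(1L))
    out$n_active_traps[out$year == yr] <- n_active
  }
  out
}

#' Average per-day values across active traps
#'
#' @param contributions data.frame (year, doy, value): one row per
#'   contribution (a specimen's daily share of count or mass); rows are summed
#'   within (year, doy).
#' @param active_traps Trap activity calendar (year, doy, n_active_traps),
#'   e.g. from [trap_activity_from_catches()].
#' @param window Analysis window, DOY.
#' @param currency Label, `"abundance"` or `"biomass"`.
#' @return data.frame (year, currency, doy, value, n_active_traps) covering
#'   every window day of every calendar year; days with zero active traps
#'   carry `NA` (unsampled), not zero.
#' @export
build_daily_series <- function(contributions, active_traps,
                               window = c(157L, 238L),
                               currency = c("abundance", "biomass")) {
  currency <- match.arg(currency)
  .check_columns(contributions, c("year", "doy", "value"), "contribution table")
  .check_columns(active_traps, c("year", "doy", "n_active_traps"),
                 "trap activity calendar")
  out <- active_traps[active_traps$doy >= window[1L] &
                        active_traps$doy <= window[2L], , drop = FALSE]
  totals <- if (nrow(contributions) == 0L) {
    data.frame(year = integer(0L), doy = integer(0L), value = numeric(0L))
  } else {
    stats::aggregate(value ~ year + doy, data = contributions, FUN = sum)
  }
  m <- match(paste(out$year, out$doy), paste(totals$year, totals$doy))
  total <- ifelse(is.na(m), 0, totals$value[m])
  value <- ifelse(out$n_active_traps > 0L, total / out$n_active_traps, NA_real_)
  res <- data.frame(year = out$year, currency = currency, doy = out$doy,
                    value = value, n_active_traps = out$n_active_traps,
                    stringsAsFactors = FALSE)
  res <- res[order(res$year, res$doy), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Reconstruct daily abundance and biomass series from catch records
#'
#' End-to-end reconstruction: spread interval catches over trap-days inside
#' the window, attach specimen mass (expectation mode: fractional daily
#' counts weighted by the expected mass per specimen; stochastic mode:
#' independent length draws per physical specimen, the record's total drawn
#' mass spread uniformly like its count), and average across active traps.
#'
#' @param catches Catch table (integer interval counts).
#' @param lengths Length table (taxon, life_stage, length_mm).
#' @param allometry Allometry table (taxon, coeff_a, exponent_b).
#' @param window Analysis window, DOY.
#' @param mode `"expected"` (default) or `"stochastic"`.
#' @param seed Seed for stochastic length assignment.
#' @param n_reps In stochastic mode, number of independent length-assignment
#'   replicates to average the biomass series over (default 1).
#' @return data.frame (year, currency, doy, value, n_active_traps) stacking
#'   both currencies; abundance is specimens per trap-day, biomass mg per
#'   trap-day.
#' @export
reconstruct_daily_series <- function(catches, lengths, allometry,
                                     window = c(157L, 238L),
                                     mode = c("expected", "stochastic"),
                                     seed = NULL, n_reps = 1L) {
  mode <- match.arg(mode)
  activity <- trap_activity_from_catches(catches, window)
  daily <- spread_interval_catches(catches, window)

  ab <- build_daily_series(
    data.frame(year = daily$year, doy = daily$doy, value = daily$count),
    activity, window, "abundance")

  if (mode == "expected") {
    em <- expected_specimen_mass(lengths, allometry)
    m <- match(paste(daily$taxon, daily$life_stage),
               paste(em$taxon, em$life_stage))
    if (anyNA(m)) {
      bad <- which(is.na(m))[1L]
      stop("no length data for taxon '", daily$taxon[bad], "'")
    }
    bm <- build_daily_series(
      data.frame(year = daily$year, doy = daily$doy,
                 value = daily$count * em$mean_mass_mg[m]),
      activity, window, "biomass")
  } else {
    stopifnot(.is_count(n_reps))
    rep_seeds <- derive_seeds(seed %||% 1L, n_reps)
    acc <- NULL
    for (r in seq_len(n_reps)) {
      specimens <- assign_lengths(catches, lengths, seed = rep_seeds[r])
      j <- match(specimens$taxon, allometry$taxon)
      specimens$mass_mg <- length_to_mass(specimens$length_mm,
                                          allometry$coeff_a[j],
                                          allometry$exponent_b[j])
      # per-record total drawn mass, spread uniformly like the counts
      rec_key <- paste(specimens$year, specimens$doy_start, specimens$doy_end,
                       specimens$plot, specimens$trap, specimens$taxon,
                       specimens$life_stage)
      mass_by_rec <- tapply(specimens$mass_mg, rec_key, sum)
      cat_key <- paste(catches$year, catches$doy_start, catches$doy_end,
                       catches$plot, catches$trap, catches$taxon,
                       catches$life_stage)
      rec_mass <- as.numeric(mass_by_rec[cat_key])
      rec_mass[is.na(rec_mass)] <- 0
      mass_catches <- catches
      mass_catches$count <- rec_mass
      daily_mass <- suppressMessages(spread_interval_catches(mass_catches, window))
      bm_r <- build_daily_series(
        data.frame(year = daily_mass$year, doy = daily_mass$doy,
                   value = daily_mass$count),
        activity, window, "biomass")
      acc <- if (is.null(acc)) bm_r$value else acc + bm_r$value
    }
    bm <- build_daily_series(
      data.frame(year = daily$year, doy = daily$doy, value = 0),
      activity, window, "biomass")
    bm$value <- acc / n_reps
  }
  rbind(ab, bm)
}
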