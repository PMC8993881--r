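#' Daily outdoor tracking coverage
#'
#' Sums tracked outdoor time per local calendar day. The device has no
#' on/off log, so coverage is reconstructed from the fix stream: for every
#' pair of consecutive fixes on the same day the elapsed time contributes,
#' capped at `gap_cap` seconds so that a single stray pair of fixes hours
#' apart cannot claim a whole afternoon of coverage. A day with exactly one
#' fix contributes 0 h but still counts as a day with data.
#'
#' @param track a `cat_track`, already filtered to outdoor fixes.
#' @param gap_cap maximum seconds a single between-fix gap may contribute
#'   (default 1800 s = 30 min).
#' @return data frame with columns `cat_id`, `date` (local calendar day),
#'   `outdoor_hours`.
#' @export
daily_coverage <- function(track, gap_cap = 1800) {
  stopifnot(gap_cap > 0)
  n <- nrow(track$fixes)
  empty <- data.frame(cat_id = character(), date = as.Date(character()),
                      outdoor_hours = numeric())
  if (!n) return(empty)
  dates <- track_dates(track)
  t_sec <- as.numeric(track$fixes$timestamp)
  days <- sort(unique(dates))
  hours <- vapply(days, function(d) {
    ts <- t_sec[dates == d]
    if (length(ts) < 2) return(0)
    sum(pmin(diff(ts), gap_cap)) / 3600
  }, numeric(1))
  data.frame(cat_id = track$cat_id, date = days, outdoor_hours = hours)
}

#' Per-cat aggregation weight
#'
#' The weight used when stacking individual utilization distributions into
#' the population surface: the cat's mean fraction of a 24-h day with outdoor
#' tracking data, averaged over days with data. Days without any data are
#' assumed to involve a typical amount of outdoor time that simply was not
#' tracked, so they do not enter the mean; the resulting population surface
#' is therefore a minimum-use estimate.
#'
#' @param coverages data frame from [daily_coverage()] (one cat).
#' @return one-row data frame `cat_id`, `n_days` (days with data), `w` in
#'   `[0, 1]`.
#' @export
outdoor_weight <- function(coverages) {
  if (!nrow(coverages)) stop("no days with data: cannot compute outdoor weight")
  if (length(unique(coverages$cat_id)) != 1)
    stop("outdoor_weight expects coverage rows for a single cat")
  w <- mean(coverages$outdoor_hours / 24)
  if (w < 0 || w > 1) stop("outdoor weight outside [0, 1]")
  data.frame(cat_id = coverages$cat_id[1], n_days = nrow(coverages), w = w)
}
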