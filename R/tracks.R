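#' GPS track container
#'
#' A `cat_track` holds one cat's time-ordered GPS fixes plus the deployment
#' metadata needed by the pre-processing filters. Fixes live in a data frame
#' with columns `timestamp` (POSIXct, UTC), `x`, `y` (projected meters),
#' `elevation` (m) and `ehpe` (estimated horizontal position error, device
#' units). Timestamps are strictly increasing.
#'
#' Calendar-day logic (settling-in days, download days, daily coverage) uses
#' the study's local time zone `tz`, because day boundaries differ between
#' UTC and the field site.
#'
#' @param cat_id cat identifier.
#' @param fixes data frame with the columns above.
#' @param deployment_start `Date` the collar went on; defaults to the local
#'   date of the first fix.
#' @param download_dates `Date` vector of days the unit was retrieved for
#'   data download (fixes on those days are discarded by
#'   [filter_download_days()]).
#' @param crs_tag identifier of the projected CRS of `x`/`y`.
#' @param tz Olson time zone used for calendar-day computations. The default
#'   `"Etc/GMT-2"` is fixed UTC+2 (central European summer time).
#' @return an object of class `cat_track`.
#' @export
cat_track <- function(cat_id, fixes, deployment_start = NULL,
                      download_dates = as.Date(character()),
                      crs_tag = "local", tz = "Etc/GMT-2") {
  stopifnot(is.data.frame(fixes))
  needed <- c("timestamp", "x", "y", "elevation", "ehpe")
  miss <- setdiff(needed, names(fixes))
  if (length(miss))
    stop("fixes is missing column(s): ", paste(miss, collapse = ", "))
  fixes <- fixes[needed]
  if (!inherits(fixes$timestamp, "POSIXct"))
    stop("timestamp column must be POSIXct")
  if (anyNA(fixes$timestamp)) stop("timestamps must be finite")
  if (any(!is.finite(fixes$x)) || any(!is.finite(fixes$y)))
    stop("x and y must be finite")
  if (any(!is.finite(fixes$ehpe)) || any(fixes$ehpe < 0))
    stop("ehpe must be finite and nonnegative")
  o <- order(fixes$timestamp)
  fixes <- fixes[o, , drop = FALSE]
  if (nrow(fixes) > 1 && any(diff(as.numeric(fixes$timestamp)) <= 0))
    stop("timestamps must be strictly increasing (no duplicates)")
  rownames(fixes) <- NULL
  if (is.null(deployment_start)) {
    deployment_start <- if (nrow(fixes)) as.Date(fixes$timestamp[1], tz = tz)
                        else as.Date(NA)
  }
  structure(
    list(cat_id = as.character(cat_id), fixes = fixes,
         deployment_start = as.Date(deployment_start),
         download_dates = as.Date(download_dates),
         crs_tag = crs_tag, tz = tz),
    class = "cat_track"
  )
}

#' @export
print.cat_track <- function(x, ...) {
  cat(sprintf("cat_track %s: %d fixes", x$cat_id, nrow(x$fixes)))
  if (nrow(x$fixes))
    cat(sprintf(" (%s to %s)", format(x$fixes$timestamp[1], tz = "UTC"),
                format(x$fixes$timestamp[nrow(x$fixes)], tz = "UTC")))
  cat("\n")
  invisible(x)
}

#' Number of fixes in a track
#' @param track a `cat_track`.
#' @export
n_fixes <- function(track) nrow(track$fixes)

# local calendar date of each fix
track_dates <- function(track) as.Date(track$fixes$timestamp, tz = track$tz)

# replace the fix table, keeping metadata (used by all filters)
replace_fixes <- function(track, keep) {
  track$fixes <- track$fixes[keep, , drop = FALSE]
  rownames(track$fixes) <- NULL
  track
}

#' Read GPS fixes from CSV into tracks
#'
#' Expects a comma-separated file with header
#' `cat_id,timestamp,x,y,elevation,ehpe` and ISO-8601 timestamps (either
#' `"2021-05-03T06:00:00"` or `"2021-05-03 06:00:00"`, interpreted as UTC).
#' Rows are partitioned by `cat_id` into one [cat_track()] each, sorted by
#' timestamp; exact duplicate `(cat_id, timestamp)` rows are collapsed to the
#' first occurrence (field units occasionally re-log a fix).
#'
#' @param path CSV file path.
#' @param crs_tag projected-CRS identifier recorded on each track.
#' @param download_dates optional named list: `cat_id -> character/Date`
#'   vector of download days (see [read_download_dates()]).
#' @param tz local time zone for calendar-day logic.
#' @return named list of `cat_track`, one per cat, in order of first
#'   appearance.
#' @export
read_tracks <- function(path, crs_tag = "local", download_dates = list(),
                        tz = "Etc/GMT-2") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("cat_id", "timestamp", "x", "y", "elevation", "ehpe")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("input CSV is missing column(s): ", paste(miss, collapse = ", "))
  tracks_from_df(df, crs_tag = crs_tag, download_dates = download_dates, tz = tz)
}

#' Build tracks from an in-memory fix table
#'
#' Same contract as [read_tracks()] but starting from a data frame, which is
#' how the synthetic generator hands fixes to the pipeline.
#'
#' @inheritParams read_tracks
#' @param df data frame with columns `cat_id,timestamp,x,y,elevation,ehpe`.
#' @export
tracks_from_df <- function(df, crs_tag = "local", download_dates = list(),
                           tz = "Etc/GMT-2") {
  ts <- df$timestamp
  if (!inherits(ts, "POSIXct")) {
    ts <- as.POSIXct(strptime(gsub("T", " ", as.character(ts)),
                              "%Y-%m-%d %H:%M:%S", tz = "UTC"))
    bad <- which(is.na(ts))
    if (length(bad))
      stop("unparseable timestamp at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  df$timestamp <- ts
  ids <- unique(df$cat_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$cat_id == id, , drop = FALSE]
    sub <- sub[order(sub$timestamp), , drop = FALSE]
    sub <- sub[!duplicated(sub$timestamp), , drop = FALSE]
    dl <- download_dates[[id]]
    cat_track(id, sub[c("timestamp", "x", "y", "elevation", "ehpe")],
              download_dates = if (is.null(dl)) as.Date(character())
                               else as.Date(dl),
              crs_tag = crs_tag, tz = tz)
  })
  names(out) <- ids
  out
}

#' Flatten tracks to a fix table / write to CSV
#'
#' @param tracks list of `cat_track`.
#' @return data frame `cat_id,timestamp,x,y,elevation,ehpe` (timestamps
#'   formatted ISO-8601 UTC by `write_tracks`).
#' @export
tracks_to_df <- function(tracks) {
  if (inherits(tracks, "cat_track")) tracks <- list(tracks)
  do.call(rbind, lapply(tracks, function(tr) {
    if (!nrow(tr$fixes)) return(NULL)
    cbind(data.frame(cat_id = tr$cat_id, stringsAsFactors = FALSE), tr$fixes)
  }))
}

#' @rdname tracks_to_df
#' @param path output CSV path.
#' @export
write_tracks <- function(tracks, path) {
  df <- tracks_to_df(tracks)
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read longitude/latitude fixes and project to local meters
#'
#' Secondary reader for GPX-style CSV (`cat_id,timestamp,lon,lat,elevation,
#' ehpe`). Coordinates are projected with a local equirectangular projection
#' about a reference point, accurate to well under a meter over a
#' neighbourhood-sized (few km) study area.
#'
#' @inheritParams read_tracks
#' @param ref_lonlat length-2 numeric `(lon0, lat0)` projection origin;
#'   defaults to the centroid of the data.
#' @export
read_tracks_lonlat <- function(path, ref_lonlat = NULL, crs_tag = "local-eqc",
                               download_dates = list(), tz = "Etc/GMT-2") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("cat_id", "timestamp", "lon", "lat", "elevation", "ehpe")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("input CSV is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(ref_lonlat)) ref_lonlat <- c(mean(df$lon), mean(df$lat))
  r_earth <- 6371008.8
  df$x <- r_earth * cos(ref_lonlat[2] * pi / 180) *
    (df$lon - ref_lonlat[1]) * pi / 180
  df$y <- r_earth * (df$lat - ref_lonlat[2]) * pi / 180
  tracks_from_df(df[c("cat_id", "timestamp", "x", "y", "elevation", "ehpe")],
                 crs_tag = crs_tag, download_dates = download_dates, tz = tz)
}

#' Pre-processing filters for GPS tracks
#'
#' The four standard removal rules applied to raw collar data before any
#' analysis, plus greedy thinning:
#'
#' * `filter_elevation()` drops fixes with elevation outside the closed
#'   interval `[min_elev, max_elev]` (defaults 0-300 m, the plausible range
#'   for a low-lying coastal study area).
#' * `filter_first_days()` drops fixes during the first `n_days` calendar
#'   days of tracking (default 2; collar-habituation period).
#' * `filter_download_days()` drops fixes on days the unit was retrieved for
#'   data download.
#' * `filter_ehpe()` drops fixes whose estimated horizontal position error
#'   is `>= max_ehpe` (default 5000, device units).
#' * `thin_track()` greedily subsamples to a minimum fix interval: the first
#'   fix is kept and each later fix only if it is at least `min_interval`
#'   seconds after the last kept one (default 120 s, the conventional
#'   interval for Brownian-bridge fitting of 30-s data).
#'
#' All filters are idempotent and (except for their interaction through
#' `deployment_start`, which none of them modifies) order-independent.
#'
#' @param track a `cat_track`.
#' @param min_elev,max_elev closed elevation bounds (m).
#' @return the filtered `cat_track` (possibly with zero fixes).
#' @export
filter_elevation <- function(track, min_elev = 0, max_elev = 300) {
  e <- track$fixes$elevation
  replace_fixes(track, e >= min_elev & e <= max_elev)
}

#' @rdname filter_elevation
#' @param n_days number of initial calendar days to drop.
#' @export
filter_first_days <- function(track, n_days = 2) {
  if (!nrow(track$fixes)) return(track)
  start <- track$deployment_start
  if (is.na(start)) start <- as.Date(track$fixes$timestamp[1], tz = track$tz)
  replace_fixes(track, track_dates(track) >= start + n_days)
}

#' @rdname filter_elevation
#' @export
filter_download_days <- function(track) {
  if (!nrow(track$fixes) || !length(track$download_dates)) return(track)
  replace_fixes(track, !(track_dates(track) %in% track$download_dates))
}

#' @rdname filter_elevation
#' @param max_ehpe fixes with `ehpe >= max_ehpe` are removed.
#' @export
filter_ehpe <- function(track, max_ehpe = 5000) {
  replace_fixes(track, track$fixes$ehpe < max_ehpe)
}

#' @rdname filter_elevation
#' @param min_interval minimum retained fix interval (seconds).
#' @export
thin_track <- function(track, min_interval = 120) {
  n <- nrow(track$fixes)
  if (n <= 1) return(track)
  t_sec <- as.numeric(track$fixes$timestamp)
  keep <- logical(n)
  keep[1] <- TRUE
  last <- t_sec[1]
  for (i in 2:n) {
    if (t_sec[i] >= last + min_interval) {
      keep[i] <- TRUE
      last <- t_sec[i]
    }
  }
  replace_fixes(track, keep)
}
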