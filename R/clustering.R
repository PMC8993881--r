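#' Sequential position-cluster detection
#'
#' Scans a time-ordered track for sequential position clusters: runs of
#' fixes that stay within a small radius of a running centroid. Collars that
#' are left on indoors produce exactly such clusters at the residence, so
#' clusters whose centroid falls within the home footprint are used to excise
#' indoor activity ([remove_home_clusters()]).
#'
#' Algorithm (running-centroid, time-windowed): fixes are visited in time
#' order. A fix joins an open cluster if it lies within `radius` meters of
#' that cluster's running centroid (recomputed after every addition) and
#' within `window` seconds of the cluster's last member; if several open
#' clusters qualify it joins the nearest centroid. A fix that joins nothing
#' seeds a new cluster together with the immediately preceding fix, provided
#' that fix is still unassigned and lies within `radius` and `window`. A
#' cluster closes once `window` elapses past its last member; closed clusters
#' with fewer than `min_points` members are discarded. Every fix belongs to
#' at most one cluster. A cluster may thus span several stationary bouts at
#' the same spot (e.g. nightly indoor periods on consecutive days) with
#' excursions in between.
#'
#' @param track a `cat_track` (time-ordered by construction).
#' @param radius cluster radius in meters; the default 10 m matches the
#'   device's nominal position error.
#' @param window maximum seconds between a cluster's last member and a
#'   joining fix (default 24 h).
#' @param min_points minimum cluster size (default 2).
#' @return list of `position_cluster` objects, each with `cluster_id`,
#'   `cat_id`, `member_indices` (into the track's fix rows), `centroid`
#'   (x, y), `start_time`, `end_time`, `n`.
#' @export
find_sequential_clusters <- function(track, radius = 10, window = 24 * 3600,
                                     min_points = 2) {
  stopifnot(radius > 0, window > 0, min_points >= 1)
  n <- nrow(track$fixes)
  if (!n) return(list())
  x <- track$fixes$x; y <- track$fixes$y
  t_sec <- as.numeric(track$fixes$timestamp)
  assigned <- logical(n)
  open <- list()   # each: list(members, sx, sy, last_t)
  done <- list()
  r2 <- radius^2

  close_expired <- function(open, now) {
    keep <- vapply(open, function(cl) now - cl$last_t <= window, logical(1))
    list(open = open[keep], closed = open[!keep])
  }
  finalize <- function(cl) {
    m <- length(cl$members)
    if (m < min_points) { assigned[cl$members] <<- FALSE; return(NULL) }
    cl
  }

  for (i in seq_len(n)) {
    sp <- close_expired(open, t_sec[i])
    open <- sp$open
    for (cl in sp$closed) {
      cl <- finalize(cl)
      if (!is.null(cl)) done[[length(done) + 1L]] <- cl
    }
    # try joining an open cluster (nearest qualifying centroid)
    best <- 0L; best_d2 <- Inf
    for (k in seq_along(open)) {
      cl <- open[[k]]
      m <- length(cl$members)
      d2 <- (x[i] - cl$sx / m)^2 + (y[i] - cl$sy / m)^2
      if (d2 <= r2 && d2 < best_d2) { best <- k; best_d2 <- d2 }
    }
    if (best > 0L) {
      cl <- open[[best]]
      cl$members <- c(cl$members, i)
      cl$sx <- cl$sx + x[i]; cl$sy <- cl$sy + y[i]
      cl$last_t <- t_sec[i]
      open[[best]] <- cl
      assigned[i] <- TRUE
    } else if (i > 1L && !assigned[i - 1L] &&
               t_sec[i] - t_sec[i - 1L] <= window &&
               (x[i] - x[i - 1L])^2 + (y[i] - y[i - 1L])^2 <= r2) {
      open[[length(open) + 1L]] <- list(
        members = c(i - 1L, i), sx = x[i - 1L] + x[i], sy = y[i - 1L] + y[i],
        last_t = t_sec[i])
      assigned[c(i - 1L, i)] <- TRUE
    }
  }
  for (cl in open) {
    cl <- finalize(cl)
    if (!is.null(cl)) done[[length(done) + 1L]] <- cl
  }
  # order by first member and wrap
  if (!length(done)) return(list())
  done <- done[order(vapply(done, function(cl) cl$members[1], numeric(1)))]
  lapply(seq_along(done), function(k) {
    cl <- done[[k]]
    m <- length(cl$members)
    structure(list(
      cluster_id = k, cat_id = track$cat_id,
      member_indices = cl$members,
      centroid = c(x = cl$sx / m, y = cl$sy / m),
      start_time = track$fixes$timestamp[cl$members[1]],
      end_time = track$fixes$timestamp[cl$members[m]],
      n = m), class = "position_cluster")
  })
}

#' @export
print.position_cluster <- function(x, ...) {
  cat(sprintf("position_cluster %d [%s]: %d fixes, centroid (%.1f, %.1f)\n",
              x$cluster_id, x$cat_id, x$n, x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Excise indoor activity at the owner's residence
#'
#' Removes all member fixes of clusters whose centroid lies inside (or
#' exactly on the boundary of) the home building footprint, leaving only
#' fixes attributable to outdoor activity. The time gap left behind is real:
#' downstream bridge construction will not interpolate across it beyond its
#' maximum-lag rule.
#'
#' @param track the `cat_track` the clusters were computed from.
#' @param clusters result of [find_sequential_clusters()] on `track`.
#' @param home_polygon building-footprint polygon (two-column vertex matrix).
#' @return the track with indoor-cluster fixes removed.
#' @export
remove_home_clusters <- function(track, clusters, home_polygon) {
  home_polygon <- validate_polygon(home_polygon)
  if (!length(clusters)) return(track)
  drop <- integer()
  for (cl in clusters) {
    if (point_in_polygon(cl$centroid[1], cl$centroid[2], home_polygon))
      drop <- c(drop, cl$member_indices)
  }
  if (!length(drop)) return(track)
  replace_fixes(track, -sort(unique(drop)))
}
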