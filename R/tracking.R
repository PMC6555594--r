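# Tracking: axial filtering, gap-free nearest-neighbour linking, and
# per-track residence times / pole distances.

#' Filter localizations by axial position
#'
#' Retains only localizations whose astigmatism-derived axial position
#' lies within the membrane slab, by default -0.2 um to +0.2 um around
#' the membrane plane. Bounds are inclusive and row order is preserved.
#'
#' @param locs localization table with a `z_um` column.
#' @param z_min,z_max inclusive axial bounds, um.
#' @return The filtered table.
#' @examples
#' locs <- data.frame(frame = 0:4, x_um = 0, y_um = 0,
#'                    z_um = c(-0.3, -0.2, 0, 0.2, 0.3))
#' nrow(filter_axial(locs))  # 3
#' @export
filter_axial <- function(locs, z_min = -0.2, z_max = 0.2) {
  if (!"z_um" %in% names(locs)) {
    stop("`locs` has no `z_um` column; axial filtering needs 3D data",
         call. = FALSE)
  }
  check_number(z_min, "z_min")
  check_number(z_max, "z_max")
  out <- locs[locs$z_um >= z_min & locs$z_um <= z_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Link localizations into gap-free single-molecule tracks
#'
#' A localization in frame `f + 1` extends a track ending in frame `f`
#' if their lateral (x, y) distance is at most `radius` (default 320 nm,
#' strict `<=`). Within each frame pair, candidate links are assigned
#' greedily in ascending distance, with ties broken by lower track id
#' and then lower row index, so linking is fully deterministic.
#' Unlinked localizations start new tracks. No gaps are permitted:
#' `max_gap` is part of the interface but only 0 is accepted, and a
#' molecule that blinks off for one frame yields two tracks.
#'
#' @param locs localization table with integer `frame`, `x_um`, `y_um`.
#' @param radius linking radius, um.
#' @param max_gap must be 0 (gap-free tracking).
#' @return `locs` with a `track_id` column (integer, 1-based, numbered
#'   by order of track birth), class `"track_table"`. Every input row
#'   belongs to exactly one track.
#' @examples
#' locs <- data.frame(frame = c(0L, 1L, 1L), x_um = c(0, 0.1, 5),
#'                    y_um = 0)
#' link_localizations(locs)$track_id  # 1 1 2
#' @export
link_localizations <- function(locs, radius = 0.32, max_gap = 0) {
  check_columns(locs, c("frame", "x_um", "y_um"), "`locs`")
  check_number(radius, "radius", lower = 0)
  if (!isTRUE(all.equal(max_gap, 0))) {
    stop("no gaps within tracks are permitted: `max_gap` must be 0",
         call. = FALSE)
  }
  if (nrow(locs) && any(locs$frame != round(locs$frame))) {
    stop("`frame` must be integer-valued", call. = FALSE)
  }
  if (anyDuplicated(locs[, c("frame", "x_um", "y_um")])) {
    warning("duplicate (frame, x, y) localizations present; kept as-is")
  }
  n <- nrow(locs)
  track_id <- integer(n)
  if (n == 0L) {
    locs$track_id <- track_id
    class(locs) <- unique(c("track_table", class(locs)))
    return(locs)
  }
  frames <- sort(unique(locs$frame))
  row_by_frame <- split(seq_len(n), factor(locs$frame, levels = frames))
  next_id <- 1L
  prev_rows <- integer(0)   # rows in previous frame, carrying track ids
  prev_frame <- NA_integer_
  for (fi in seq_along(frames)) {
    rows <- row_by_frame[[fi]]
    linked <- rep(FALSE, length(rows))
    if (length(prev_rows) && isTRUE(prev_frame == frames[fi] - 1)) {
      px <- locs$x_um[prev_rows]; py <- locs$y_um[prev_rows]
      cx <- locs$x_um[rows]; cy <- locs$y_um[rows]
      dmat <- sqrt(outer(px, cx, "-")^2 + outer(py, cy, "-")^2)
      cand <- which(dmat <= radius, arr.ind = TRUE)
      if (nrow(cand)) {
        dd <- dmat[cand]
        ord <- order(dd, track_id[prev_rows][cand[, 1]], cand[, 2])
        used_prev <- rep(FALSE, length(prev_rows))
        for (k in ord) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (!used_prev[i] && !linked[j]) {
            track_id[rows[j]] <- track_id[prev_rows[i]]
            used_prev[i] <- TRUE
            linked[j] <- TRUE
          }
        }
      }
    }
    if (any(!linked)) {
      fresh <- rows[!linked]
      track_id[fresh] <- seq.int(next_id, length.out = length(fresh))
      next_id <- next_id + length(fresh)
    }
    prev_rows <- rows
    prev_frame <- frames[fi]
  }
  locs$track_id <- track_id
  class(locs) <- unique(c("track_table", class(locs)))
  locs
}

#' Effective residence time of a track
#'
#' The effective residence time is `(n - 1) * tau_TL`, where `n` is the
#' number of consecutive localizations: a molecule seen in a single
#' frame has zero measured residence.
#'
#' @param n number of localizations in the track (or a track data.frame,
#'   in which case its row count is used).
#' @param tau_TL time-lapse period, s (> 0).
#' @return Residence time in seconds.
#' @examples
#' effective_residence_time(6, 0.22)   # 1.1
#' effective_residence_time(56, 0.02)  # 1.1
#' @export
effective_residence_time <- function(n, tau_TL) {
  if (is.data.frame(n)) n <- nrow(n)
  stopifnot(all(n >= 1), all(n == round(n)))
  check_number(tau_TL, "tau_TL", lower = 1e-12)
  (n - 1) * tau_TL
}

#' Build a cell centerline
#'
#' @param x,y coordinates of the pole-to-pole polyline, um (>= 2 points,
#'   positive total arclength).
#' @return An object of class `"centerline"`.
#' @export
centerline <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  len <- sum(sqrt(diff(x)^2 + diff(y)^2))
  if (!is.finite(len) || len <= 0) {
    stop("degenerate centerline: total arclength must be > 0",
         call. = FALSE)
  }
  structure(list(x = x, y = y, arclength = len), class = "centerline")
}

#' Arclength distance from the nearest cell pole
#'
#' Projects a point (by convention, a track's *first* localization) onto
#' the centerline polyline and returns the arclength from the nearer
#' pole, i.e. folded into `[0, arclength / 2]`.
#'
#' @param x,y point coordinates, um (vectorised).
#' @param cl a [centerline()].
#' @return Distances in um.
#' @examples
#' cl <- centerline(c(0, 10), c(0, 0))
#' distance_from_pole(2.5, 0.3, cl)  # 2.5
#' @export
distance_from_pole <- function(x, y, cl) {
  stopifnot(inherits(cl, "centerline"), length(x) == length(y))
  nx <- length(cl$x)
  seg_dx <- diff(cl$x); seg_dy <- diff(cl$y)
  seg_len <- sqrt(seg_dx^2 + seg_dy^2)
  cum0 <- c(0, cumsum(seg_len))[seq_len(nx - 1)]
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    best_d2 <- Inf; best_s <- 0
    for (s in seq_len(nx - 1)) {
      if (seg_len[s] == 0) next
      t <- ((x[i] - cl$x[s]) * seg_dx[s] + (y[i] - cl$y[s]) * seg_dy[s]) /
        seg_len[s]^2
      t <- min(max(t, 0), 1)
      px <- cl$x[s] + t * seg_dx[s]; py <- cl$y[s] + t * seg_dy[s]
      d2 <- (x[i] - px)^2 + (y[i] - py)^2
      if (d2 < best_d2) {
        best_d2 <- d2
        best_s <- cum0[s] + t * seg_len[s]
      }
    }
    out[i] <- min(best_s, cl$arclength - best_s)
  }
  out
}

#' Summarise a track table
#'
#' One row per track: length `n`, effective residence time, and (when a
#' centerline is supplied) the arclength distance of the track's first
#' localization from the nearest pole.
#'
#' @param tracks a `"track_table"` from [link_localizations()].
#' @param tau_TL time-lapse period, s.
#' @param cl optional [centerline()].
#' @return data.frame with `track_id`, `n`, `t_eff_s`, `x_start_um`,
#'   `y_start_um` and, if `cl` is given, `distance_from_pole_um`.
#' @export
track_summary <- function(tracks, tau_TL, cl = NULL) {
  check_columns(tracks, c("track_id", "frame", "x_um", "y_um"),
                "`tracks`")
  check_number(tau_TL, "tau_TL", lower = 1e-12)
  ord <- order(tracks$track_id, tracks$frame)
  tr <- tracks[ord, , drop = FALSE]
  first <- !duplicated(tr$track_id)
  n <- as.vector(table(tr$track_id)[as.character(tr$track_id[first])])
  out <- data.frame(track_id = tr$track_id[first], n = n,
                    t_eff_s = (n - 1) * tau_TL,
                    x_start_um = tr$x_um[first],
                    y_start_um = tr$y_um[first])
  if (!is.null(cl)) {
    out$distance_from_pole_um <-
      distance_from_pole(out$x_start_um, out$y_start_um, cl)
  }
  rownames(out) <- NULL
  out
}
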