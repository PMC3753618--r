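#' Track-ensemble container
#'
#' A `track_ensemble` bundles the observation table of one tracking
#' experiment (or simulation) with its sampling interval and bookkeeping:
#' whether trajectories have been synchronized to the focus-splitting event,
#' the per-cell split times and left-right orientation flags, and a log of
#' excluded trajectories with reasons.
#'
#' The observation table has one row per focus per frame with columns
#' `cell_id`, `frame`, `t_min`, `channel`, `focus_id`, `x_rel`,
#' `cell_length_um`.  `x_rel` is the long-axis position as a fraction of
#' cell length from mid-cell and must lie in \[-0.5, 0.5\]; `focus_id` is 0
#' for the single pre-split focus and 0 (left) / 1 (right) afterwards;
#' `channel` distinguishes the tracked locus (`"ori"`) from the fiducial
#' orientation marker (`"fid"`).
#'
#' @param obs data.frame of observations (columns above).
#' @param delta_t sampling interval in minutes.
#' @param synchronized logical; `TRUE` when `t_min` is measured relative to
#'   the split (t = 0 at the first sustained two-focus frame).
#' @param splits data.frame with columns `cell_id`, `t_split` (min), or NULL.
#' @param orientation data.frame with columns `cell_id`, `orientation`
#'   (+1/-1), or NULL.
#' @param exclusions data.frame with columns `cell_id`, `reason`, or NULL.
#' @return An object of class `track_ensemble`.
#' @export
track_ensemble <- function(obs, delta_t = 1, synchronized = FALSE,
                           splits = NULL, orientation = NULL,
                           exclusions = NULL) {
  obs <- as.data.frame(obs)
  required <- c("cell_id", "frame", "t_min", "channel", "focus_id", "x_rel")
  missing <- setdiff(required, names(obs))
  if (length(missing) > 0L) {
    stop("observation table is missing columns: ",
         paste(missing, collapse = ", "))
  }
  if (!"cell_length_um" %in% names(obs)) obs$cell_length_um <- NA_real_
  if (!is.numeric(delta_t) || length(delta_t) != 1L || delta_t <= 0) {
    stop("delta_t must be a single positive number")
  }
  obs$cell_id <- as.character(obs$cell_id)
  obs <- obs[order(obs$cell_id, obs$channel, obs$frame, obs$focus_id), ,
             drop = FALSE]
  rownames(obs) <- NULL
  structure(
    list(
      obs = obs,
      delta_t = delta_t,
      synchronized = isTRUE(synchronized),
      splits = splits %||%
        data.frame(cell_id = character(), t_split = numeric()),
      orientation = orientation %||%
        data.frame(cell_id = character(), orientation = integer()),
      exclusions = exclusions %||%
        data.frame(cell_id = character(), reason = character())
    ),
    class = "track_ensemble"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.track_ensemble <- function(x, ...) {
  n_cells <- length(unique(x$obs$cell_id))
  cat("<track_ensemble> ", n_cells, " cells, ", nrow(x$obs),
      " observations, delta_t = ", x$delta_t, " min, ",
      if (x$synchronized) "synchronized (t = 0 at split)" else "unsynchronized",
      "\n", sep = "")
  if (nrow(x$exclusions) > 0L) {
    cat("  excluded trajectories: ", nrow(x$exclusions), "\n", sep = "")
  }
  invisible(x)
}

#' Number of cells in an ensemble
#' @param ensemble a `track_ensemble`.
#' @return integer count of distinct cell ids.
#' @export
n_cells <- function(ensemble) length(unique(ensemble$obs$cell_id))

#' Cell-cycle interval scheme
#'
#' The four analysis windows of locus motion, as half-open intervals
#' \[t_min, t_max) in minutes relative to the focus split: Pre-Replication
#' (t < -10), Cohesion (-10 <= t < 0), Rapid-Translocation (0 <= t < 10) and
#' Post-Segregation (t >= 10).  Windows must be disjoint and ordered.
#'
#' @param names interval labels.
#' @param t_min,t_max lower (inclusive) and upper (exclusive) window edges.
#' @return data.frame with class `interval_scheme`.
#' @export
interval_scheme <- function(names = c("pre", "cohesion", "rapid", "post"),
                            t_min = c(-Inf, -10, 0, 10),
                            t_max = c(-10, 0, 10, Inf)) {
  stopifnot(length(names) == length(t_min), length(t_min) == length(t_max))
  if (any(t_max <= t_min)) stop("interval windows must have t_min < t_max")
  o <- order(t_min)
  names <- names[o]; t_min <- t_min[o]; t_max <- t_max[o]
  if (any(t_min[-1] < t_max[-length(t_max)])) {
    stop("interval windows overlap")
  }
  structure(data.frame(name = names, t_min = t_min, t_max = t_max,
                       stringsAsFactors = FALSE),
            class = c("interval_scheme", "data.frame"))
}

#' Assign a time point to a cell-cycle interval
#'
#' Maps a time (minutes relative to the split) to its interval label under
#' the half-open \[t_min, t_max) convention, so the split frame t = 0
#' belongs to Rapid-Translocation under the default scheme.
#'
#' @param t numeric vector of times (min relative to split).
#' @param scheme an [interval_scheme()].
#' @return character vector of interval labels (NA where no window covers t).
#' @export
assign_interval <- function(t, scheme = interval_scheme()) {
  out <- rep(NA_character_, length(t))
  for (i in seq_len(nrow(scheme))) {
    hit <- t >= scheme$t_min[i] & t < scheme$t_max[i]
    out[hit & !is.na(hit)] <- scheme$name[i]
  }
  out
}

# Window [a, b) for one named interval; errors on unknown label.
interval_window <- function(interval, scheme = interval_scheme()) {
  i <- match(interval, scheme$name)
  if (is.na(i)) {
    stop("unknown interval '", interval, "'; expected one of: ",
         paste(scheme$name, collapse = ", "))
  }
  c(scheme$t_min[i], scheme$t_max[i])
}

# Restrict the locus-channel observations to an interval window (or keep all
# frames when interval is NULL) and split into per-(cell, focus) series of
# positions on the integer frame grid.  Post-split windows that open at
# t = 0 start at `post_split_start` because the split frame itself cannot be
# resolved into two distinct foci.
series_list <- function(ensemble, interval = NULL,
                        scheme = interval_scheme(),
                        channel = "ori", post_split_start = 1) {
  obs <- ensemble$obs[ensemble$obs$channel == channel, , drop = FALSE]
  if (!is.null(interval)) {
    if (!ensemble$synchronized) {
      stop("interval selection requires a synchronized ensemble")
    }
    w <- interval_window(interval, scheme)
    lo <- w[1]
    if (lo == 0 && !is.null(post_split_start)) lo <- post_split_start
    obs <- obs[obs$t_min >= lo & obs$t_min < w[2], , drop = FALSE]
  }
  if (nrow(obs) == 0L) return(list())
  key <- paste(obs$cell_id, obs$focus_id, sep = "\r")
  lapply(split(obs, key), function(d) {
    d <- d[order(d$t_min), , drop = FALSE]
    list(cell_id = d$cell_id[1], focus_id = d$focus_id[1],
         idx = as.integer(round(d$t_min / ensemble$delta_t)),
         x = d$x_rel, t = d$t_min)
  })
}

# Apply the post-split focus selection rule to a series list.
#   "right"  : after the split only the right-destined focus (id 1);
#   "mirror" : left-destined focus contributes with negated positions;
#   "all"    : both foci as-is.
# Series of unsplit trajectories (single focus throughout) pass unchanged.
apply_selection <- function(series, selection = c("right", "mirror", "all"),
                            split_cells = character()) {
  selection <- match.arg(selection)
  if (selection == "all") return(series)
  out <- lapply(series, function(s) {
    post_split <- s$cell_id %in% split_cells && any(s$t >= 0)
    if (!post_split) return(s)
    if (s$focus_id == 0) {
      if (selection == "right") return(NULL)
      s$x <- -s$x                       # mirror-pool the left focus
    }
    s
  })
  out[!vapply(out, is.null, logical(1))]
}
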