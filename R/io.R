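#' Read a track table
#'
#' Reads a delimited track table (one row per focus per frame; mandatory
#' header with columns `cell_id`, `frame`, `t_min`, `channel`, `focus_id`,
#' `x_rel`, `cell_length_um`) and returns a validated [track_ensemble()].
#'
#' Validation drops (never clamps) rows whose `x_rel` falls outside
#' \[-0.5, 0.5\] — clamping would bias tail statistics — and logs the count.
#' With `filter_splits = TRUE` (the full-cell-cycle filter), trajectories
#' whose locus-channel focus count does not show exactly one sustained
#' splitting event (one focus at birth, two until the end of the record) are
#' excluded with a reason; set it to `FALSE` for ensembles that are not
#' split-cycle data (e.g. plain diffusive tracks).
#'
#' @param path path to the delimited file.
#' @param sep field separator (default tab).
#' @param delta_t sampling interval in minutes; inferred from the time
#'   column when NULL.
#' @param filter_splits apply the one-splitting-event trajectory filter.
#' @param sustain minimum number of consecutive two-focus frames for a
#'   split to count as real rather than a transient double detection.
#' @param channel locus channel name used for split detection.
#' @param quiet suppress the message summarizing dropped rows/cells.
#' @return a [track_ensemble()].
#' @export
load_tracks <- function(path, sep = "\t", delta_t = NULL,
                        filter_splits = TRUE, sustain = 2,
                        channel = "ori", quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  obs <- read.delim(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE, check.names = TRUE)
  required <- c("cell_id", "frame", "t_min", "channel", "focus_id", "x_rel")
  missing <- setdiff(required, names(obs))
  if (length(missing) > 0L) {
    stop("malformed track table header; missing columns: ",
         paste(missing, collapse = ", "))
  }
  obs$cell_id <- as.character(obs$cell_id)

  bad <- !is.finite(obs$x_rel) | obs$x_rel < -0.5 | obs$x_rel > 0.5
  n_bad <- sum(bad)
  obs <- obs[!bad, , drop = FALSE]

  if (is.null(delta_t)) {
    dts <- diff(sort(unique(obs$t_min)))
    delta_t <- if (length(dts) > 0L) min(dts[dts > 0]) else 1
  }

  exclusions <- data.frame(cell_id = character(), reason = character())
  if (filter_splits && nrow(obs) > 0L) {
    for (cid in unique(obs$cell_id)) {
      d <- obs[obs$cell_id == cid & obs$channel == channel, , drop = FALSE]
      det <- detect_split(d, sustain = sustain)
      if (is.na(det$t_split)) {
        exclusions <- rbind(exclusions,
                            data.frame(cell_id = cid, reason = det$reason))
      }
    }
    obs <- obs[!obs$cell_id %in% exclusions$cell_id, , drop = FALSE]
  }
  if (!quiet && (n_bad > 0L || nrow(exclusions) > 0L)) {
    message("load_tracks: dropped ", n_bad, " out-of-range rows; excluded ",
            nrow(exclusions), " trajectories")
  }
  track_ensemble(obs, delta_t = delta_t, exclusions = exclusions)
}

#' Write a track table
#'
#' Writes the observation table of an ensemble as delimited text (the format
#' [load_tracks()] reads) and, optionally, a JSON metadata sidecar with the
#' sampling interval, counts, synchronization state and exclusion log.
#'
#' @param ensemble a [track_ensemble()].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @param sidecar write `<path>.json` with ensemble metadata.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ensemble, path, sep = "\t", sidecar = FALSE) {
  obs <- ensemble$obs
  cols <- c("cell_id", "frame", "t_min", "channel", "focus_id", "x_rel",
            "cell_length_um")
  write.table(obs[, cols], path, sep = sep, quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  if (sidecar) {
    meta <- list(
      delta_t = ensemble$delta_t,
      synchronized = ensemble$synchronized,
      n_cells = n_cells(ensemble),
      n_obs = nrow(obs),
      exclusions = ensemble$exclusions
    )
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
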