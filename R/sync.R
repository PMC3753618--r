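# Split detection and trajectory preparation: synchronization to the
# focus-splitting event and left-right orientation from the fiducial marker.

# Detect the splitting event in one cell's locus-channel observations.
# The two-focus state must persist for >= `sustain` consecutive frames to
# count (transient double detections are a tracking reality); a valid
# full-cycle trajectory has exactly one such sustained run, it does not
# start at the first frame, and it lasts to the end of the record (one
# focus at birth, two at division).  Returns list(t_split, frame, reason).
detect_split <- function(d, sustain = 2) {
  if (nrow(d) == 0L) {
    return(list(t_split = NA_real_, frame = NA_integer_, reason = "no_data"))
  }
  counts <- tapply(d$focus_id, d$frame, function(f) length(unique(f)))
  frames <- as.integer(names(counts))
  o <- order(frames)
  frames <- frames[o]; counts <- as.integer(counts[o])

  two <- counts >= 2L
  r <- rle(two)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= sustain)
  if (length(runs) == 0L) {
    return(list(t_split = NA_real_, frame = NA_integer_, reason = "no_split"))
  }
  if (length(runs) > 1L) {
    return(list(t_split = NA_real_, frame = NA_integer_,
                reason = "multiple_splitting_events"))
  }
  if (ends[runs] != length(two)) {
    return(list(t_split = NA_real_, frame = NA_integer_,
                reason = "foci_remerged"))
  }
  if (starts[runs] == 1L) {
    return(list(t_split = NA_real_, frame = NA_integer_,
                reason = "two_foci_at_birth"))
  }
  k <- starts[runs]
  split_frame <- frames[k]
  t_split <- d$t_min[match(split_frame, d$frame)]
  list(t_split = t_split, frame = split_frame, reason = NA_character_)
}

#' Synchronize trajectories to the focus-splitting event
#'
#' Shifts each trajectory's time axis so that t = 0 is the first frame of
#' the sustained two-focus run (the split).  Trajectories without a valid
#' single splitting event are excluded with a reason.  Idempotent: a
#' synchronized ensemble is returned unchanged.
#'
#' @param ensemble a [track_ensemble()].
#' @param sustain minimum consecutive two-focus frames for a real split.
#' @param channel locus channel used for split detection.
#' @return a synchronized [track_ensemble()] with per-cell `t_split`
#'   recorded (the original absolute split time).
#' @export
synchronize <- function(ensemble, sustain = 2, channel = "ori") {
  if (ensemble$synchronized) return(ensemble)
  obs <- ensemble$obs
  splits <- data.frame(cell_id = character(), t_split = numeric())
  exclusions <- ensemble$exclusions
  keep <- character()

  for (cid in unique(obs$cell_id)) {
    d <- obs[obs$cell_id == cid & obs$channel == channel, , drop = FALSE]
    det <- detect_split(d, sustain = sustain)
    if (is.na(det$t_split)) {
      exclusions <- rbind(exclusions,
                          data.frame(cell_id = cid, reason = det$reason))
      next
    }
    obs$t_min[obs$cell_id == cid] <- obs$t_min[obs$cell_id == cid] - det$t_split
    splits <- rbind(splits, data.frame(cell_id = cid, t_split = det$t_split))
    keep <- c(keep, cid)
  }
  obs <- obs[obs$cell_id %in% keep, , drop = FALSE]
  track_ensemble(obs, delta_t = ensemble$delta_t, synchronized = TRUE,
                 splits = splits, orientation = ensemble$orientation,
                 exclusions = exclusions)
}

#' Orient trajectories by the chromosome's left-right polarity
#'
#' Uses the fiducial-channel marker (a locus on one chromosome arm) to fix
#' each cell's left-right orientation: cells whose fiducial mean position is
#' negative are mirrored (`x_rel` negated in every channel) so that after
#' orientation the fiducial mean is non-negative.  Mirroring twice restores
#' the original ensemble.
#'
#' @param ensemble a [track_ensemble()].
#' @param fiducial_channel channel name of the orientation marker.
#' @return an oriented [track_ensemble()] with per-cell orientation flags
#'   (+1 kept, -1 mirrored).
#' @export
orient <- function(ensemble, fiducial_channel = "fid") {
  obs <- ensemble$obs
  cells <- unique(obs$cell_id)
  flags <- data.frame(cell_id = cells, orientation = 1L)
  n_missing <- 0L
  for (i in seq_along(cells)) {
    fid <- obs$x_rel[obs$cell_id == cells[i] & obs$channel == fiducial_channel]
    if (length(fid) == 0L) { n_missing <- n_missing + 1L; next }
    if (mean(fid) < 0) {
      obs$x_rel[obs$cell_id == cells[i]] <- -obs$x_rel[obs$cell_id == cells[i]]
      flags$orientation[i] <- -1L
    }
  }
  if (n_missing > 0L) {
    warning(n_missing, " cell(s) lack the fiducial channel; ",
            "orientation left at +1")
  }
  track_ensemble(obs, delta_t = ensemble$delta_t,
                 synchronized = ensemble$synchronized,
                 splits = ensemble$splits, orientation = flags,
                 exclusions = ensemble$exclusions)
}

#' Mirror an ensemble
#'
#' Negates every position (`x_rel` in all channels).  Downstream, mirroring
#' negates drift velocities and leaves MSD curves unchanged, since the MSD
#' depends only on squared displacements.
#'
#' @param ensemble a [track_ensemble()].
#' @return the mirrored [track_ensemble()].
#' @export
mirror_ensemble <- function(ensemble) {
  ensemble$obs$x_rel <- -ensemble$obs$x_rel
  ensemble
}

#' Relabel post-split foci by destination side
#'
#' Fixes focus identity at the split by the sign of each focus's mean
#' post-split position: left-destined focus gets id 0, right-destined id 1.
#' Applied after [orient()] so "right" is well defined.
#'
#' @param ensemble a synchronized [track_ensemble()].
#' @param channel locus channel.
#' @return the relabelled [track_ensemble()].
#' @export
label_foci <- function(ensemble, channel = "ori") {
  if (!ensemble$synchronized) stop("label_foci requires a synchronized ensemble")
  obs <- ensemble$obs
  for (cid in ensemble$splits$cell_id) {
    sel <- obs$cell_id == cid & obs$channel == channel & obs$t_min >= 0
    d <- obs[sel, , drop = FALSE]
    if (length(unique(d$focus_id)) != 2L) next
    means <- tapply(d$x_rel, d$focus_id, mean)
    right_id <- as.integer(names(means)[which.max(means)])
    new_id <- ifelse(d$focus_id == right_id, 1L, 0L)
    obs$focus_id[sel] <- new_id
  }
  ensemble$obs <- obs
  ensemble
}
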