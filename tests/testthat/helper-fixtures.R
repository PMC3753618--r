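# Fixtures are built in code: small deterministic track tables plus
# memoized mid-size simulations shared across test files.

# Build a track_ensemble from a list of per-cell position vectors
# (single focus, unit sampling); list names become cell ids.
toy_ensemble <- function(xs, delta_t = 1, channel = "ori",
                         synchronized = FALSE, t0 = 0) {
  obs <- do.call(rbind, lapply(names(xs), function(cid) {
    x <- xs[[cid]]
    data.frame(cell_id = cid, frame = seq_along(x) - 1L,
               t_min = t0 + (seq_along(x) - 1L) * delta_t,
               channel = channel, focus_id = 0L, x_rel = x,
               cell_length_um = NA_real_)
  }))
  track_ensemble(obs, delta_t = delta_t, synchronized = synchronized)
}

# One split-cycle cell written by hand: single focus for `n_pre` frames,
# then two foci until frame n_pre + n_post - 1.  Positions are smooth and
# in range so no validation drops rows.
toy_split_cell <- function(cid = "c1", n_pre = 15, n_post = 15,
                           fid = TRUE) {
  t_pre <- seq_len(n_pre) - 1L
  t_post <- n_pre + seq_len(n_post) - 1L
  rows <- rbind(
    data.frame(cell_id = cid, frame = t_pre, t_min = t_pre, channel = "ori",
               focus_id = 0L, x_rel = 0.02 * sin(t_pre / 3),
               cell_length_um = 2.5),
    data.frame(cell_id = cid, frame = t_post, t_min = t_post,
               channel = "ori", focus_id = 0L,
               x_rel = -0.25 + 0.02 * cos(t_post / 4), cell_length_um = 2.6),
    data.frame(cell_id = cid, frame = t_post, t_min = t_post,
               channel = "ori", focus_id = 1L,
               x_rel = 0.25 + 0.02 * sin(t_post / 4), cell_length_um = 2.6)
  )
  if (fid) {
    t_all <- c(t_pre, t_post)
    rows <- rbind(rows, data.frame(
      cell_id = cid, frame = t_all, t_min = t_all, channel = "fid",
      focus_id = 0L, x_rel = 0.2 + 0.01 * sin(t_all / 5),
      cell_length_um = NA_real_))
  }
  rows
}

.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# shared mid-size ensembles
split_ens <- function() cached_sim("split400", {
  synchronize(simulate_split_cycle(sim_config(
    n_cells = 400, include_fiducial = FALSE, sigma_loc = 0, seed = 101)))
})

ou_ens <- function() cached_sim("ou400", {
  simulate_ou_tracks(n_tracks = 400, n_frames = 100, tau = 10, D = 2.5e-4,
                     seed = 102)
})
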