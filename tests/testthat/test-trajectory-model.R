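test_that("track tables round-trip through write and load", {
  obs <- rbind(toy_split_cell("c1"), toy_split_cell("c2"))
  ens <- track_ensemble(obs, delta_t = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tracks(ens, f, sidecar = TRUE)
  back <- load_tracks(f, quiet = TRUE)
  expect_equal(n_cells(back), 2)
  expect_equal(back$delta_t, 1)
  expect_equal(back$obs$x_rel, ens$obs$x_rel, tolerance = 1e-12)
  expect_equal(back$obs$cell_id, ens$obs$cell_id)
  expect_equal(back$obs$focus_id, ens$obs$focus_id)
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$n_cells, 2)
})

test_that("out-of-range positions are dropped, never clamped", {
  obs <- toy_split_cell("c1")
  bad <- obs[1, ]; bad$x_rel <- 0.7; bad$focus_id <- 0L
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tracks(track_ensemble(rbind(obs, bad)), f)
  expect_message(ens <- load_tracks(f), "dropped 1 out-of-range")
  expect_true(all(abs(ens$obs$x_rel) <= 0.5))
  expect_equal(nrow(ens$obs), nrow(obs))
})

test_that("the one-splitting-event trajectory filter is enforced", {
  # focus count 1 -> 2 -> 1 -> 2, each state sustained: two splitting events
  remerge <- toy_split_cell("bad", n_pre = 5, n_post = 5, fid = FALSE)
  tail_rows <- remerge[remerge$t_min >= 5 & remerge$focus_id == 0L, ]
  tail_rows$t_min <- tail_rows$t_min + 5; tail_rows$frame <- tail_rows$frame + 5L
  tail2 <- remerge[remerge$t_min >= 5, ]
  tail2$t_min <- tail2$t_min + 10; tail2$frame <- tail2$frame + 10L
  obs <- rbind(remerge, tail_rows, tail2, toy_split_cell("good"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tracks(track_ensemble(obs), f)
  ens <- load_tracks(f, quiet = TRUE)
  expect_equal(unique(ens$obs$cell_id), "good")
  expect_true("bad" %in% ens$exclusions$cell_id)
  expect_match(ens$exclusions$reason[ens$exclusions$cell_id == "bad"],
               "multiple_splitting_events")

  # no split at all -> excluded too
  ou <- toy_ensemble(list(flat = rep(0.1, 10)))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_tracks(ou, f2)
  ens2 <- load_tracks(f2, quiet = TRUE)
  expect_equal(n_cells(ens2), 0)
  expect_equal(ens2$exclusions$reason, "no_split")

  # empty table with a valid header parses to an empty ensemble
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("cell_id\tframe\tt_min\tchannel\tfocus_id\tx_rel\tcell_length_um", f3)
  expect_equal(n_cells(load_tracks(f3, quiet = TRUE)), 0)

  # malformed header is a format error
  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a\tb\tc", f4)
  expect_error(load_tracks(f4), "missing columns")
})

test_that("synchronization shifts the split frame to t = 0 and is idempotent", {
  obs <- toy_split_cell("c1", n_pre = 62, n_post = 20)
  ens <- synchronize(track_ensemble(obs))
  expect_true(ens$synchronized)
  expect_equal(ens$splits$t_split, 62)
  expect_equal(min(ens$obs$t_min), -62)
  ori <- ens$obs[ens$obs$channel == "ori", ]
  counts <- tapply(ori$focus_id, ori$t_min, function(f) length(unique(f)))
  expect_equal(unname(counts[["0"]]), 2L)   # two foci at t = 0
  expect_identical(synchronize(ens), ens)   # idempotent
})

test_that("split detection requires a sustained two-focus run", {
  # counts 1,1,2,1,2,2,2: the lone frame-2 detection is transient, the
  # split is called at the first frame of the final sustained run
  mk <- function(frame, focus) data.frame(
    cell_id = "c", frame = frame, t_min = frame, channel = "ori",
    focus_id = focus, x_rel = 0.1, cell_length_um = NA_real_)
  obs <- rbind(mk(0, 0L), mk(1, 0L), mk(2, 0L), mk(2, 1L), mk(3, 0L),
               mk(4, 0L), mk(4, 1L), mk(5, 0L), mk(5, 1L),
               mk(6, 0L), mk(6, 1L))
  det <- locusdrift:::detect_split(obs, sustain = 2)
  expect_equal(det$frame, 4L)
  expect_equal(det$t_split, 4)
})

test_that("orientation mirrors cells with negative fiducial mean and is an involution", {
  obs <- rbind(toy_split_cell("right"), toy_split_cell("left"))
  obs$x_rel[obs$cell_id == "left"] <- -obs$x_rel[obs$cell_id == "left"]
  ens <- track_ensemble(obs)
  or <- orient(ens)
  expect_equal(or$orientation$orientation[or$orientation$cell_id == "left"], -1L)
  expect_equal(or$orientation$orientation[or$orientation$cell_id == "right"], 1L)
  for (cid in c("left", "right")) {
    fid <- or$obs$x_rel[or$obs$cell_id == cid & or$obs$channel == "fid"]
    expect_gte(mean(fid), 0)
  }
  # mirroring the oriented ensemble twice restores it
  expect_equal(mirror_ensemble(mirror_ensemble(or))$obs$x_rel, or$obs$x_rel)
  # orientation of an already-oriented ensemble changes nothing
  expect_equal(orient(or)$obs$x_rel, or$obs$x_rel)
  # missing fiducial -> warning, flag +1
  nofid <- track_ensemble(toy_split_cell("c9", fid = FALSE))
  expect_warning(o2 <- orient(nofid), "fiducial")
  expect_equal(o2$orientation$orientation, 1L)
})

test_that("synchronization commutes with orientation", {
  obs <- rbind(toy_split_cell("a"), toy_split_cell("b"))
  obs$x_rel[obs$cell_id == "b"] <- -obs$x_rel[obs$cell_id == "b"]
  ens <- track_ensemble(obs)
  e1 <- orient(synchronize(ens))
  e2 <- synchronize(orient(ens))
  expect_equal(e1$obs$x_rel, e2$obs$x_rel)
  expect_equal(e1$obs$t_min, e2$obs$t_min)
})

test_that("interval assignment follows the half-open window convention", {
  sch <- interval_scheme()
  expect_equal(assign_interval(-15, sch), "pre")
  expect_equal(assign_interval(-10, sch), "cohesion")
  expect_equal(assign_interval(-0.5, sch), "cohesion")
  expect_equal(assign_interval(0, sch), "rapid")    # split frame
  expect_equal(assign_interval(5, sch), "rapid")
  expect_equal(assign_interval(10, sch), "post")
  expect_equal(assign_interval(c(-15, 5), sch), c("pre", "rapid"))
  expect_error(interval_scheme(names = c("a", "b"), t_min = c(0, 5),
                               t_max = c(10, 15)),
               "overlap")
})

test_that("mirroring negates drift profiles and leaves the MSD unchanged end-to-end", {
  ens <- ou_ens()
  mir <- mirror_ensemble(ens)
  dp <- compute_drift_profile(ens, NULL, min_count = 25)
  dpm <- compute_drift_profile(mir, NULL, min_count = 25)
  # mirrored bins are the reflected bins with opposite velocity
  m <- match(round(-dpm$x, 6), round(dp$x, 6))
  expect_true(all(!is.na(m)))
  expect_equal(dpm$v, -dp$v[m], tolerance = 1e-12)
  msd <- compute_msd(ens, NULL, 10)
  msdm <- compute_msd(mir, NULL, 10)
  expect_equal(msd$msd, msdm$msd, tolerance = 1e-12)
})
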