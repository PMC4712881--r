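# construct a geometry with the turn already taken
turned_geom <- function(L1 = 100, Rt = 10, L2 = 50, r_um = 10) {
  spec <- dtc_path_spec(turn_radius_um = Rt,
                        radius_times = c(0, 1), radius_values = c(r_um, r_um),
                        initial_length_um = 1)
  g <- gonad_geometry(spec)
  g$L1 <- L1
  g$turn_started <- TRUE
  g$dtc_arclength <- L1 + pi * Rt + L2
  g
}

test_that("path arclength composes straight limbs and the semicircle", {
  g <- turned_geom(L1 = 100, Rt = 10, L2 = 50)
  expect_equal(path_total_length(g), 100 + 10 * pi + 50)
  # start of the return limb, antiparallel to the distal axis
  p_end_arc <- drop(path_point(g, 100 + pi * 10))
  expect_equal(p_end_arc, c(100, 20, 0), tolerance = 1e-12)
  p_tip <- dtc_position(g)
  expect_equal(p_tip, c(50, 20, 0), tolerance = 1e-12)
})

test_that("projection recovers cylinder geometry on the first limb", {
  g <- turned_geom()
  pr <- project_to_path(g, c(50, 3, 0))
  expect_equal(pr$s, 50)
  expect_equal(pr$rho, 3)
  on_path <- project_to_path(g, path_point(g, c(5, 100 + 5, 120)))
  expect_equal(on_path$rho, rep(0, 3), tolerance = 1e-12)
  expect_equal(on_path$s, c(5, 105, 120), tolerance = 1e-9)
})

test_that("projection agrees with a dense-sampling oracle", {
  set.seed(17)
  g <- turned_geom(L1 = 60, Rt = 12, L2 = 40)
  s_grid <- seq(0, path_total_length(g), length.out = 10000L)
  pts <- path_point(g, s_grid)
  x <- cbind(runif(100, -20, 80), runif(100, -15, 40), runif(100, -15, 15))
  pr <- project_to_path(g, x)
  for (i in 1:100) {
    d2 <- (pts[, 1] - x[i, 1])^2 + (pts[, 2] - x[i, 2])^2 +
      (pts[, 3] - x[i, 3])^2
    j <- which.min(d2)
    expect_equal(pr$rho[i], sqrt(d2[j]), tolerance = 0.1)
    expect_equal(pr$s[i], s_grid[j], tolerance = 0.1)
  }
})

test_that("tube enforcement keeps every cell inside the boundary", {
  set.seed(29)
  g <- turned_geom(r_um = 10)
  radius <- runif(60, 1, 3)
  x <- cbind(runif(60, -30, 130), runif(60, -30, 50), runif(60, -25, 25))
  interior <- project_to_path(g, x)
  x2 <- enforce_tube(g, x, radius, t = 0.5)
  pr <- project_to_path(g, x2)
  expect_true(all(pr$rho + radius <= 10 + 1e-9))
  expect_true(all(pr$s <= path_total_length(g) + 1e-9))
  # interior cells are untouched
  keep <- which(interior$rho + radius <= 10)
  expect_equal(x2[keep, ], x[keep, ])
  # surface contact: a cell exactly on the boundary moves in by its radius
  y <- matrix(c(50, 10, 0), 1, 3)
  y2 <- enforce_tube(g, y, 2, t = 0.5)
  expect_equal(y2[1, ], c(50, 8, 0))
})

test_that("rachis annulus applies distal to and within the turn only", {
  g <- turned_geom(L1 = 100, Rt = 10, L2 = 50, r_um = 10)
  # distal arm: an on-axis cell is pushed out to r - 2 radius
  axis_distal <- matrix(c(80, 20, 0), 1, 3)   # on the return limb axis
  out <- enforce_rachis(g, axis_distal, 2.7, t = 0.5)
  pr <- project_to_path(g, out)
  expect_equal(pr$rho, 10 - 2 * 2.7, tolerance = 1e-9)
  # proximal of the turn: unchanged no matter how central
  axis_prox <- matrix(c(50, 0, 0), 1, 3)
  expect_equal(enforce_rachis(g, axis_prox, 2.7, t = 0.5), axis_prox)
  # tube thinner than two radii: constraint skipped
  expect_equal(enforce_rachis(g, axis_distal, 6, t = 0.5), axis_distal)
})

test_that("tube and rachis jointly bracket the radial position", {
  set.seed(41)
  g <- turned_geom(L1 = 100, Rt = 10, L2 = 50, r_um = 10)
  radius <- rep(2.7, 80)
  x <- cbind(runif(80, 40, 120), runif(80, -5, 45), runif(80, -12, 12))
  x <- enforce_tube(g, x, radius, 0.5)
  x <- enforce_rachis(g, x, radius, 0.5)
  pr <- project_to_path(g, x)
  distal <- pr$s >= g$L1
  expect_true(all(pr$rho[distal] >= 10 - 2 * 2.7 - 1e-9))
  expect_true(all(pr$rho + radius <= 10 + 1e-9))
})

test_that("the DTC advances at the stage rate and pauses at a one-CD gap", {
  spec <- dtc_path_spec()
  g <- gonad_geometry(spec)
  cd <- spec$cell_diameter_um
  # abutting cells: full advance at the L3 rate (7 um/h)
  g2 <- update_dtc(g, t = 20, dt = 0.1, cell_s = g$dtc_arclength)
  expect_equal(g2$dtc_arclength - g$dtc_arclength, 0.7)
  # gap already one CD: no advance
  g3 <- update_dtc(g, t = 20, dt = 0.1, cell_s = g$dtc_arclength - cd)
  expect_equal(g3$dtc_arclength, g$dtc_arclength)
  # gap 0.3 um short of one CD, target 0.7: advance exactly 0.3
  g4 <- update_dtc(g, t = 20, dt = 0.1,
                   cell_s = g$dtc_arclength - (cd - 0.3))
  expect_equal(g4$dtc_arclength - g$dtc_arclength, 0.3)
  # pausing disabled: full advance regardless
  g5 <- update_dtc(g, t = 20, dt = 0.1, cell_s = g$dtc_arclength - 2 * cd,
                   pausing = FALSE)
  expect_equal(g5$dtc_arclength - g$dtc_arclength, 0.7)
})

test_that("the turn is fixed wherever the DTC is at the prescribed time", {
  g <- gonad_geometry(dtc_path_spec())
  g <- update_dtc(g, t = g$spec$turn_time_hph, dt = 0.01,
                  cell_s = g$dtc_arclength)
  expect_true(g$turn_started)
  expect_equal(g$L1, 20)   # paused DTC turns closer to the center
})

test_that("stretching lengthens both limbs and advects the frame", {
  spec <- dtc_path_spec(stretch_window = c(10, 20),
                        stretch_rate_um_per_h = 4, turn_radius_um = 10)
  g <- gonad_geometry(spec)
  g$L1 <- 50; g$turn_started <- TRUE
  g$dtc_arclength <- 50 + 10 * pi + 30
  pos <- rbind(c(25, 0, 0),                  # mid proximal limb
               c(50 + 10, 10, 0),           # mid-turn
               c(30, 20, 0))                # return limb
  len0 <- path_total_length(g)
  out <- apply_stretch(g, t = 15, dt = 0.5, pos = pos)
  delta <- 4 * 0.5
  expect_equal(path_total_length(out$geom), len0 + 2 * delta)
  expect_equal(out$geom$L1, 50 + delta)
  expect_equal(out$pos[1, 1], 25 * (50 + delta) / 50)  # affine in limb1
  expect_equal(out$pos[2, 1], 60 + delta)              # rigid with the turn
  expect_equal(out$pos[3, ], c(30, 20, 0))             # return limb fixed
  # distances from the DTC are preserved for return-limb material
  pr0 <- project_to_path(g, pos)
  pr1 <- project_to_path(out$geom, out$pos)
  expect_equal(g$dtc_arclength - pr0$s[3],
               out$geom$dtc_arclength - pr1$s[3], tolerance = 1e-9)
  # outside the window: no change
  same <- apply_stretch(g, t = 25, dt = 0.5, pos = pos)
  expect_identical(same$geom, g)
  expect_identical(same$pos, pos)
})

test_that("a full stretch window doubles the proximal limb", {
  spec <- dtc_path_spec(stretch_window = c(0, 10),
                        stretch_rate_um_per_h = 5, turn_radius_um = 10)
  g <- gonad_geometry(spec)
  g$L1 <- 50; g$turn_started <- TRUE
  g$dtc_arclength <- 50 + 10 * pi + 5
  pos <- matrix(numeric(0), 0, 3)
  for (k in 1:1000) {
    out <- apply_stretch(g, t = (k - 1) * 0.01, dt = 0.01, pos = pos)
    g <- out$geom
  }
  expect_equal(g$L1, 100, tolerance = 1e-6)
})
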