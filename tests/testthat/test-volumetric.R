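y_backbone <- function(lv = 100, lh = 120, lp = 160) {
  build_backbone(list(vertical = rbind(c(0, 0, 0), c(0, 0, lv)),
                      horizontal = rbind(c(0, 0, 0), c(lh, 0, 0)),
                      pedcalyx = rbind(c(0, 0, 0), c(0, lp, 0))),
                 calyx_branch = "pedcalyx")
}

test_that("backbone branch lengths are polyline arc lengths", {
  bb <- y_backbone(100, 120, 160)
  expect_equal(vapply(bb$branches, `[[`, numeric(1), "length"),
               c(vertical = 100, horizontal = 120, pedcalyx = 160))
  # jittered polyline matches independent summation
  set.seed(31)
  P <- cbind(cumsum(runif(6, 5, 20)), rnorm(6), rnorm(6))
  P <- rbind(c(0, 0, 0), P)
  bb2 <- build_backbone(list(a = P, b = rbind(c(0, 0, 0), c(0, 10, 0))),
                        calyx_branch = "b")
  expect_equal(bb2$branches$a$length,
               sum(sqrt(rowSums(diff(P)^2))))
  # branches must share the junction
  expect_error(build_backbone(list(a = rbind(c(0, 0, 0), c(1, 0, 0)),
                                   b = rbind(c(5, 5, 5), c(6, 5, 5))),
                              calyx_branch = "b"),
               "junction")
})

test_that("backbone nodes are evenly spaced with a calyx-based coordinate", {
  bb <- y_backbone(100, 120, 160)
  nodes <- backbone_nodes(bb, spacing_um = 20)
  v <- nodes[nodes$branch == "vertical", ]
  expect_equal(v$arc_um, seq(0, 100, by = 20))
  expect_equal(v$dist_from_calyx_um, 160 + seq(0, 100, by = 20))
  p <- nodes[nodes$branch == "pedcalyx", ]
  expect_equal(p$dist_from_calyx_um, 160 - p$arc_um)
  expect_equal(sum(nodes$arc_um == 0), 1)  # junction emitted once
})

test_that("standardization averages branch lengths and scales spacings", {
  b1 <- y_backbone(100, 120, 160)
  b2 <- y_backbone(120, 120, 160)
  std <- standardize_backbones(list(b1, b2), spacing_um = 20)
  expect_equal(unname(std$branch_lengths["vertical"]), 110)
  pl <- std$placements[[1]]
  v <- pl[pl$branch == "vertical", ]
  expect_equal(v$arc_um, v$index * (100 / 110) * 20)
  expect_equal(v$standard_arc_um, v$index * 20)
  # single backbone: standard = itself
  std1 <- standardize_backbones(list(b1))
  expect_equal(unname(std1$branch_lengths),
               unname(vapply(b1$branches, `[[`, numeric(1), "length")))
  expect_equal(std1$placements[[1]]$scale,
               rep(1, nrow(std1$placements[[1]])))
  # idempotent: standardizing the standard returns itself
  std2 <- standardize_backbones(list(std1$standard))
  expect_equal(std2$branch_lengths, std1$branch_lengths)
  # random lengths: mean matches independent computation
  set.seed(5)
  ls <- runif(4, 80, 200)
  bs <- lapply(ls, function(l) y_backbone(lv = l))
  stdn <- standardize_backbones(bs)
  expect_equal(unname(stdn$branch_lengths["vertical"]), mean(ls))
  expect_error(standardize_backbones(list(
    b1, build_backbone(list(a = rbind(c(0, 0, 0), c(1, 0, 0)),
                            b = rbind(c(0, 0, 0), c(0, 1, 0))),
                       calyx_branch = "b"))),
    "topology")
})

test_that("voxel assignment is nearest-node with low-index tie break", {
  mask <- array(1, c(4, 4, 8))
  nodes <- data.frame(x = c(2, 6), y = c(2, 2), z = c(2, 2))
  seg <- assign_voxels(mask, nodes, voxel_size_um = c(1, 1, 1))
  # assignment plane bisects the two nodes at x = 4
  xs <- (seq_len(8) - 0.5)
  for (ix in seq_len(8)) {
    expected <- if (xs[ix] < 4) 1L else if (xs[ix] > 4) 2L else 1L
    expect_true(all(seg$labels[, , ix] == expected))
  }
  expect_equal(sum(seg$counts), length(mask))
  expect_error(assign_voxels(array(0, c(2, 2, 2)), nodes), "empty")
})

test_that("voxel assignment equals brute-force search on random fixtures", {
  set.seed(41)
  for (rep in 1:3) {
    mask <- array(stats::runif(16 * 12 * 10) < 0.5, c(16, 12, 10))
    nodes <- data.frame(x = runif(5, 0, 10), y = runif(5, 0, 12),
                        z = runif(5, 0, 16))
    vs <- c(0.8, 1.1, 1.3)
    seg <- assign_voxels(mask, nodes, voxel_size_um = vs)
    idx <- which(mask, arr.ind = TRUE)
    for (r in sample(nrow(idx), 50)) {
      p <- c((idx[r, 3] - 0.5) * vs[3], (idx[r, 2] - 0.5) * vs[2],
             (idx[r, 1] - 0.5) * vs[1])
      d <- sqrt((nodes$x - p[1])^2 + (nodes$y - p[2])^2 +
                  (nodes$z - p[3])^2)
      expect_equal(seg$labels[idx[r, 1], idx[r, 2], idx[r, 3]],
                   which.min(d))
    }
  }
})

make_test_seg <- function(dim = c(8, 10, 12), n_nodes = 4) {
  mask <- array(TRUE, dim)
  nodes <- data.frame(x = seq(1, dim[3] - 1, length.out = n_nodes),
                      y = dim[2] / 2, z = dim[1] / 2)
  assign_voxels(mask, nodes, voxel_size_um = c(1, 1, 1))
}

test_that("dF/F recovers constants, steps and generator truth", {
  seg <- make_test_seg()
  nt <- 10
  # constant movie -> dF/F 0
  flat <- make_synthetic_movie(seg, matrix(0, 4, nt), f0 = 80,
                               background = 30)
  p <- compute_dff(flat$movie, seg, background = 30, prestim_frames = 1:3)
  expect_equal(p$dff, matrix(0, 4, nt), ignore_attr = TRUE)
  # F doubling with zero background -> dF/F 1
  seg1 <- make_test_seg(n_nodes = 1)
  mov <- array(100, c(6, dim(seg1$labels)))
  mov[4:6, , , ] <- 200
  p2 <- compute_dff(mov, seg1, background = 0, prestim_frames = 1:3)
  expect_equal(unname(p2$dff[1, ]), c(0, 0, 0, 1, 1, 1))
  # generator round trip with background
  curves <- rbind(seq(0, 0.9, length.out = nt),
                  rep(0, nt),
                  c(rep(0, 4), rep(0.5, nt - 4)),
                  seq(0, -0.4, length.out = nt))
  gen <- make_synthetic_movie(seg, curves, f0 = 120, background = 50)
  p3 <- compute_dff(gen$movie, seg, background = 50, prestim_frames = 1)
  expect_equal(p3$dff, curves, ignore_attr = TRUE, tolerance = 1e-10)
  # conservation: node means x counts reproduce the in-mask total
  tot <- sum(gen$movie[3, , , ][seg$labels != 0])
  expect_equal(sum(p3$f[, 3] * seg$counts), tot)
})

test_that("dF/F is invariant to adding a constant to movie and background", {
  seg <- make_test_seg()
  curves <- matrix(stats::runif(4 * 8, -0.2, 0.8), 4, 8)
  curves[, 1:2] <- 0
  gen <- make_synthetic_movie(seg, curves, f0 = 90, background = 40)
  p1 <- compute_dff(gen$movie, seg, background = 40, prestim_frames = 1:2)
  p2 <- compute_dff(gen$movie + 17, seg, background = 57,
                    prestim_frames = 1:2)
  expect_equal(p1$dff, p2$dff, tolerance = 1e-12)
})

test_that("nodes with F0 at or below background become NaN with a warning", {
  seg <- make_test_seg(n_nodes = 2)
  mov <- array(50, c(5, dim(seg$labels)))
  expect_warning(p <- compute_dff(mov, seg, background = 50,
                                  prestim_frames = 1:2),
                 "F0 <= background")
  expect_true(all(is.nan(p$dff)))
})

test_that("boxcar smoothing spreads an impulse into a plateau", {
  seg <- make_test_seg(n_nodes = 1)
  dff <- matrix(0, 1, 15); dff[1, 8] <- 5
  prof <- structure(list(dff = dff, prestim_frames = 1:3,
                         channel = "green", frame_time_s = 0.2),
                    class = "dff_profile")
  sm <- smooth_and_interpolate(prof, "trace_boxcar_5frames")
  expect_equal(unname(sm$dff[1, 6:10]), rep(1, 5))
  expect_equal(unname(sm$dff[1, c(5, 11)]), c(0, 0))
  # mode none is the identity
  expect_equal(smooth_and_interpolate(prof, "none")$dff, dff)
  # 1 s boxcar at 0.2 s frames is 5 frames
  expect_equal(smooth_and_interpolate(prof, "trace_boxcar_1s")$dff,
               sm$dff)
  expect_error(smooth_and_interpolate(
    structure(list(dff = dff, frame_time_s = NULL), class = "dff_profile"),
    "trace_boxcar_1s"), "frame interval")
})

test_that("linear interpolation to 0.2 s matches the analytic signal", {
  t_in <- seq(0, 6, by = 0.33)
  dff <- matrix(sin(t_in), 1)
  prof <- structure(list(dff = dff, frame_time_s = 0.33),
                    class = "dff_profile")
  out <- smooth_and_interpolate(prof, "none", frame_time_out_s = 0.2)
  t_out <- seq(0, max(t_in), by = 0.2)
  expect_equal(ncol(out$dff), length(t_out))
  # linear interpolation error bound for sin: h^2/8 * max|f''|
  expect_lt(max(abs(out$dff[1, ] - sin(t_out))), 0.33^2 / 8 + 1e-9)
})

test_that("noisy-node exclusion enforces the channel thresholds", {
  mk <- function(sds, channel) {
    set.seed(77)
    pres <- sapply(sds, function(s) rnorm(2000, sd = s))
    pres <- t(pres) * sds / apply(t(pres), 1, sd)  # exact SDs
    structure(list(dff = cbind(pres, matrix(0, length(sds), 3)),
                   prestim_frames = 1:2000, channel = channel),
              class = "dff_profile")
  }
  expect_message(g <- exclude_noisy_nodes(mk(c(1.2, 0.9, 0), "green")),
                 "1 node")
  expect_equal(g$excluded, c(TRUE, FALSE, FALSE))
  expect_message(r <- exclude_noisy_nodes(mk(c(1.2, 0.9, 0), "red")),
                 "2 node")
  expect_equal(r$excluded, c(TRUE, TRUE, FALSE))
})

test_that("normalized inhibitory effect recovers a known suppression field", {
  seg <- make_test_seg()
  nt <- 20
  # plateau response so the smoothed peak equals the plateau height
  base <- c(rep(0, 5), rep(1, 12), rep(0.5, 3))
  odor <- matrix(rep(base, each = 4), 4)
  suppression <- c(0, -0.25, -0.5, -0.75)
  drug <- odor + outer(suppression, c(rep(0, 5), rep(1, 15)))
  g1 <- make_synthetic_movie(seg, odor, f0 = 100, background = 20)
  g2 <- make_synthetic_movie(seg, drug, f0 = 100, background = 20)
  p1 <- compute_dff(g1$movie, seg, 20, prestim_frames = 1:5)
  p2 <- compute_dff(g2$movie, seg, 20, prestim_frames = 1:5)
  eff <- normalized_inhibitory_effect(p1, p2, window_frames = 8:15)
  expect_equal(eff, suppression, tolerance = 1e-6, ignore_attr = TRUE)
  # identical profiles -> 0; halving a flat-peak response -> -0.5
  expect_equal(normalized_inhibitory_effect(p1, p1, window_frames = 8:15),
               rep(0, 4), tolerance = 1e-12, ignore_attr = TRUE)
  # non-positive peak -> NaN with warning
  odor0 <- matrix(0, 4, nt)
  z <- make_synthetic_movie(seg, odor0, f0 = 100, background = 20)
  pz <- compute_dff(z$movie, seg, 20, prestim_frames = 1:5)
  expect_warning(effz <- normalized_inhibitory_effect(pz, p2, 8:15),
                 "non-positive peak")
  expect_true(all(is.nan(effz)))
})

test_that("integer shifts are recovered by cross-correlation alignment", {
  set.seed(91)
  ref <- array(rnorm(16 * 16 * 16), c(16, 16, 16))
  ref[4:10, 5:12, 6:13] <- ref[4:10, 5:12, 6:13] + 4  # structure
  shifted <- aplspread:::shift_array3(ref, c(2, -1, 0))
  off <- align_recordings(list(ref, ref, shifted), max_shift = 4)
  expect_equal(off[1, ], c(dz = 0L, dy = 0L, dx = 0L))
  expect_equal(off[2, ], c(dz = 0L, dy = 0L, dx = 0L))
  expect_equal(off[3, ], c(dz = 2L, dy = -1L, dx = 0L))
  # robust to 10% noise
  noisy <- shifted + array(rnorm(length(ref), sd = 0.4), dim(ref))
  off2 <- align_recordings(list(ref, noisy), max_shift = 4)
  expect_equal(off2[2, ], c(dz = 2L, dy = -1L, dx = 0L))
  expect_error(align_recordings(list(array(1, c(4, 4, 4)))), "flat")
})
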