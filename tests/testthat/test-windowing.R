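test_that("segmentation recovers a noisy disk with high overlap", {
  set.seed(5)
  truth <- mk_disk(40)
  img <- matrix(100, 128, 128)
  img[truth] <- 1000
  img <- pmax(img + matrix(rnorm(128^2, 0, 10), 128), 0)
  masks <- segment_cell(mk_stack(list(img)))
  iou <- sum(masks$data[1, , ] & truth) / sum(masks$data[1, , ] | truth)
  expect_gte(iou, 0.95)
})

test_that("only the largest of two bright blobs is kept", {
  img <- matrix(100, 128, 128)
  img[mk_disk(30, cy = 40, cx = 40)] <- 1000
  img[mk_disk(10, cy = 100, cx = 100)] <- 1000
  masks <- segment_cell(mk_stack(list(img)))
  expect_equal(sum(masks$data[1, , ] & mk_disk(10, cy = 100, cx = 100)), 0)
  expect_gt(sum(masks$data[1, , ] & mk_disk(30, cy = 40, cx = 40)), 2000)
})

test_that("a featureless frame raises the per-frame failure flag", {
  masks <- segment_cell(mk_stack(list(matrix(5, 64, 64))))
  expect_true(masks$failed[1])
})

test_that("sector counts on a disk match round(perimeter / width)", {
  masks <- mk_mask_stack(list(mk_disk(50), mk_disk(50)))
  g1 <- build_window_grid(masks, sector_width_um = 1)
  expect_equal(g1$n_sectors, 63) # round(2*pi*10 / 1)
  g5 <- build_window_grid(masks, sector_width_um = 5)
  expect_equal(g5$n_sectors, 13) # round(62.83 / 5)
})

test_that("perimeter estimate is within 1% of the analytic circle length", {
  masks <- mk_mask_stack(list(mk_disk(50)))
  g <- build_window_grid(masks, sector_width_um = 1)
  expect_equal(g$frames[[1]]$perimeter_um, 2 * pi * 10, tolerance = 0.01)
})

test_that("depth windows reach the configured depth where the cell allows", {
  masks <- mk_mask_stack(list(mk_disk(50)))
  g <- build_window_grid(masks, sector_width_um = 1, n_depths = 10)
  depths_present <- sort(unique(na.omit(as.vector(g$frames[[1]]$depth_map))))
  expect_equal(depths_present, 1:10)
})

test_that("uniform radial growth gives the closed-form sector velocity", {
  frames <- purrr::map(0:4, ~ mk_disk(50 + 0.5 * .x))
  masks <- mk_mask_stack(frames)
  g <- build_window_grid(masks, 1, 1, 5)
  ed <- compute_edge_dynamics(masks, g)
  v <- ed$velocity_um_per_s[ed$frame < 4]
  expect_lt(abs(mean(v) - 0.01), 0.002) # 0.1 um / 10 s
  # shrinking disk flips the sign
  masks_r <- mk_mask_stack(rev(frames))
  gr <- build_window_grid(masks_r, 1, 1, 5)
  vr <- compute_edge_dynamics(masks_r, gr)$velocity_um_per_s
  expect_lt(abs(mean(vr[ed$frame < 4]) + 0.01), 0.002)
})

test_that("a static mask yields identically zero displacement and velocity", {
  masks <- mk_mask_stack(purrr::map(1:3, ~ mk_disk(40)))
  g <- build_window_grid(masks, 1, 1, 5)
  ed <- compute_edge_dynamics(masks, g)
  expect_equal(max(abs(ed$displacement_um)), 0)
  expect_equal(max(abs(ed$velocity_um_per_s)), 0)
})

test_that("velocity telescopes exactly back to displacement", {
  frames <- purrr::map(0:4, ~ mk_disk(50 + 0.7 * .x))
  masks <- mk_mask_stack(frames)
  g <- build_window_grid(masks, 1, 1, 5)
  ed <- compute_edge_dynamics(masks, g)
  one <- ed[ed$sector == 5, ]
  rebuilt <- one$displacement_um[1] +
    cumsum(one$velocity_um_per_s[-nrow(one)]) * 10
  expect_equal(rebuilt, one$displacement_um[-1], tolerance = 1e-12)
})

test_that("window means reproduce a depth-banded image exactly", {
  mask <- mk_disk(50)
  masks <- mk_mask_stack(list(mask))
  g <- build_window_grid(masks, 1, 1, 10)
  din <- t(as.matrix(EBImage::distmap(t(mask) * 1)))
  band <- ceiling((din - 0.5) * 0.2 + 1e-9)
  band[band < 1] <- 1
  img <- band
  img[!mask] <- NA
  sw <- sample_window_means(mk_stack(list(img)), g, signal = "value")
  ok <- !is.na(sw$value)
  expect_true(all(abs(sw$value[ok] - sw$depth[ok]) < 1e-9))
})

test_that("a uniform map gives every window the same mean and empty windows stay missing", {
  mask <- mk_disk(30, n = 96)
  masks <- mk_mask_stack(list(mask))
  g <- build_window_grid(masks, 1, 1, 4)
  img <- matrix(7, 96, 96)
  img[!mask] <- NA
  sw <- sample_window_means(mk_stack(list(img)), g)
  expect_true(all(na.omit(sw$value) == 7))
  allna <- matrix(NA_real_, 96, 96)
  sw2 <- sample_window_means(mk_stack(list(allna)), g)
  expect_true(all(is.na(sw2$value)))
})

test_that("sector arc lengths are equal by construction and sum to the perimeter", {
  masks <- mk_mask_stack(list(mk_disk(50)))
  g <- build_window_grid(masks, 1)
  arc <- g$frames[[1]]$perimeter_um / g$n_sectors
  expect_equal(arc * g$n_sectors, g$frames[[1]]$perimeter_um, tolerance = 1e-9)
  expect_lt(abs(arc - 1), 0.2) # within +-20% of the 1-um target
})

test_that("centroid tracking reports migration speed in um/hour", {
  frames <- purrr::map(0:7, ~ mk_disk(30, cx = (128 + 1) / 2 + .x * 1.25))
  masks <- mk_mask_stack(frames)
  tc <- track_cell_center(masks)
  expect_equal(tc$speed_um_per_hour, 90, tolerance = 2)
  static <- mk_mask_stack(purrr::map(1:3, ~ mk_disk(30)))
  expect_equal(track_cell_center(static)$speed_um_per_hour, 0)
})

test_that("fixed-centroid shape change yields near-zero migration speed", {
  frames <- purrr::map(0:5, function(t) {
    mk_disk(30 + 2 * sin(t)) # breathing disk, centroid fixed
  })
  masks <- mk_mask_stack(frames)
  expect_lt(track_cell_center(masks)$speed_um_per_hour, 2)
})

test_that("a cell smaller than one window is rejected", {
  masks <- mk_mask_stack(list(mk_disk(1.1, n = 32)))
  expect_error(build_window_grid(masks, sector_width_um = 5, depth_um = 5),
               "smaller")
})
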