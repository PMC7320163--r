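test_that("flood fill marks only areas enclosed by closed shapes", {
  ring <- render_shape("ring", outer_r = 12, inner_r = 8)
  enc <- find_enclosed_regions(ring)
  expect_gt(sum(enc), 0)
  expect_true(all(enc + ring <= 1L))               # foreground excluded
  # every enclosed pixel lies inside the inner radius
  idx <- which(enc == 1L, arr.ind = TRUE)
  cr <- (nrow(ring) + 1) / 2; cc <- (ncol(ring) + 1) / 2
  expect_true(all(sqrt((idx[, 1] - cr)^2 + (idx[, 2] - cc)^2) < 8))

  open_c <- render_shape("open_c", outer_r = 12, inner_r = 8, gap_frac = 0.2)
  expect_equal(sum(find_enclosed_regions(open_c)), 0L)
})

test_that("helix lobe count matches the crossing geometry", {
  r <- get_helix()
  mask <- otsu_binarize(gaussian_blur(r$axis, 1))
  enc <- find_enclosed_regions(mask)
  lab <- label_components(enc, 4L)
  expected <- r$truth$n_lobes
  expect_gte(max(lab), expected - 1L)
  expect_lte(max(lab), expected + 1L)
})

test_that("sources land on the spline inside enclosed regions only", {
  # straight spline through a ring: sources confined to the interior span
  ring <- render_shape("ring", outer_r = 15, inner_r = 11)
  nr <- nrow(ring)
  line <- cbind(as.integer((nr + 1) / 2), 1:ncol(ring))
  sp <- fit_center_spline(line, 0, pixel_size_nm = 10)
  src <- select_sources(list(sp), find_enclosed_regions(ring), 10)
  expect_gt(nrow(src), 0)
  cc_px <- src$x_nm / 10 + 1
  cen <- (ncol(ring) + 1) / 2
  expect_true(all(abs(cc_px - cen) < 11))
  # normals are unit length and perpendicular to the horizontal tangent
  expect_equal(src$normal_x^2 + src$normal_y^2, rep(1, nrow(src)),
               tolerance = 1e-9)
  expect_lt(max(abs(src$normal_x)), 1e-6)

  empty <- matrix(0L, nr, ncol(ring))
  expect_equal(nrow(select_sources(list(sp), empty, 10)), 0L)

  # NULL enclosure keeps roughly one source per pixel of arc
  all_src <- select_sources(list(sp), NULL, 10)
  expect_equal(nrow(all_src), ncol(ring), tolerance = 2)
})

test_that("profiles sample perpendicular intensity with bounds checking", {
  cfg <- pipeline_config(min_distance_nm = 100, max_distance_nm = 1200)
  const <- channel_image(matrix(2.5, 200, 64), 16.12)
  src <- list(x_nm = 500, y_nm = 1600, normal_x = 0, normal_y = 1,
              line_id = 1L)
  p <- extract_profile(const, src, cfg)
  expect_true(p$ok)
  expect_true(all(abs(p$intensities - 2.5) < 1e-9))
  expect_equal(sum(p$offsets_nm == 0), 1L)         # odd length, 0 present
  expect_equal(diff(p$offsets_nm), rep(16.12 / 2, length(p$offsets_nm) - 1),
               tolerance = 1e-9)

  near_border <- list(x_nm = 500, y_nm = 100, normal_x = 0, normal_y = 1,
                      line_id = 1L)
  pb <- extract_profile(const, near_border, cfg)
  expect_false(pb$ok)
  expect_equal(pb$reason, "out_of_bounds")
})

test_that("peak-to-peak distances are exact for symmetric bimodal profiles", {
  offs <- seq(-1296, 1296, by = 16)        # +/- 400 lie exactly on the grid
  y <- exp(-(offs - 400)^2 / (2 * 60^2)) + exp(-(offs + 400)^2 / (2 * 60^2))
  d <- peak_to_peak_distance(list(offsets_nm = offs, intensities = y,
                                  ok = TRUE, reason = "ok"))
  expect_equal(d$distance_nm, 800, tolerance = 1e-6)
  expect_equal(d$center_nm, 0, tolerance = 1e-6)

  mono <- exp(-offs^2 / (2 * 100^2))
  dm <- peak_to_peak_distance(list(offsets_nm = offs, intensities = mono,
                                   ok = TRUE, reason = "ok"))
  expect_equal(dm$reason, "no_bimodal")
  expect_true(is.na(dm$distance_nm))
})

test_that("sub-pixel refinement recovers off-grid peaks on rendered ridges", {
  # true maxima at -402.3 / +397.7 nm on a 16.12 nm grid
  px <- 16.12
  img <- closed_form_ridges(1300 - 402.3, 1300 + 397.7, 40, px,
                            nrow_px = 180, ncol_px = 40)
  ci <- channel_image(img, px)
  cfg <- pipeline_config()
  src <- list(x_nm = 300, y_nm = 1300, normal_x = 0, normal_y = 1,
              line_id = 1L)
  p <- extract_profile(ci, src, cfg)
  d <- peak_to_peak_distance(p)
  expect_equal(d$distance_nm, 800, tolerance = 8)
})

test_that("the bounds filter flags without deleting", {
  mk <- function(d) list(distance_nm = d, center_nm = 0, kept = NA,
                         reason = "unfiltered")
  cfg <- pipeline_config()                         # 400-1200 nm
  out <- filter_distances(list(mk(300), mk(800), mk(1300)), cfg)
  expect_equal(vapply(out, `[[`, logical(1), "kept"), c(FALSE, TRUE, FALSE))
  expect_equal(vapply(out, `[[`, character(1), "reason"),
               c("below_min", "kept", "above_max"))
  cfg2 <- pipeline_config(min_distance_nm = 100, max_distance_nm = 400)
  out2 <- filter_distances(list(mk(300)), cfg2)
  expect_true(out2[[1L]]$kept)
  expect_length(filter_distances(list(), cfg), 0L)
})

test_that("alignment removes shifts before averaging", {
  offs <- seq(-1290, 1290, by = 15)
  base <- function(sh) exp(-(offs - sh - 420)^2 / (2 * 70^2)) +
    exp(-(offs - sh + 420)^2 / (2 * 70^2))
  shifts <- c(-30, -15, 0, 15, 30)
  profiles <- lapply(shifts, function(s)
    list(offsets_nm = offs, intensities = base(s),
         source = list(line_id = 1L), ok = TRUE, reason = "ok"))
  dists <- filter_distances(lapply(profiles, peak_to_peak_distance),
                            pipeline_config())
  avg <- align_and_average(profiles, dists)
  expect_equal(avg$overall$intensities, base(0), tolerance = 1e-5)
  # mirror-symmetric input stays symmetric
  sym <- avg$overall$intensities
  expect_lt(max(abs(sym - rev(sym))), 1e-9)

  # overall average is the count-weighted mean of per-line averages
  profiles2 <- profiles
  profiles2[[4L]]$source$line_id <- 2L
  profiles2[[5L]]$source$line_id <- 2L
  avg2 <- align_and_average(profiles2, dists)
  w <- vapply(avg2$per_line, `[[`, numeric(1), "n")
  stacked <- mapply(function(p, wk) p$intensities * wk, avg2$per_line, w)
  expect_equal(rowSums(stacked) / sum(w), avg2$overall$intensities,
               tolerance = 1e-9)

  none <- lapply(dists, function(d) { d$kept <- FALSE; d })
  expect_error(align_and_average(profiles, none), "nothing to average")
})

test_that("averaging two separations yields their midpoint separation", {
  offs <- seq(-1290, 1290, by = 15)
  two <- function(sep) exp(-(offs - sep / 2)^2 / (2 * 70^2)) +
    exp(-(offs + sep / 2)^2 / (2 * 70^2))
  profiles <- lapply(c(700, 900), function(s)
    list(offsets_nm = offs, intensities = two(s),
         source = list(line_id = 1L), ok = TRUE, reason = "ok"))
  dists <- filter_distances(lapply(profiles, peak_to_peak_distance),
                            pipeline_config())
  avg <- align_and_average(profiles, dists)
  d <- peak_to_peak_distance(c(avg$overall, list(ok = TRUE)))
  expect_equal(d$distance_nm, 800, tolerance = 15)
})

test_that("kept plus discarded equals the number of valid distances", {
  res <- get_helix_result()
  cnt <- res$counts
  expect_identical(cnt$distances_kept + cnt$distances_discarded,
                   cnt$distances_valid)
  dd <- res$distances
  expect_identical(sum(dd$kept), cnt$distances_kept)
  expect_identical(sum(!is.na(dd$distance_nm)), cnt$distances_valid)
  # projection can only underestimate: no kept distance above a + one step
  step <- get_helix()$axis$pixel_size_nm / 2
  expect_lte(max(dd$distance_nm[dd$kept]), get_helix()$truth$a_nm + step)
})

test_that("straight-ridge separations are recovered by the profiling chain", {
  cfg <- pipeline_config(enclosed_only = FALSE)
  for (sep in c(500, 700, 1000)) {
    img <- render_parallel_ridges(sep)
    res <- suppressWarnings(run_pipeline(img, config = cfg))
    med <- stats::median(res$distances$distance_nm[res$distances$kept])
    tol <- max(img$pixel_size_nm / 2, 0.01 * sep)
    expect_lt(abs(med - sep), tol)
  }
})
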