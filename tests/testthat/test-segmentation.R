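test_that("gaussian blur conserves mass and preserves structure", {
  const <- matrix(3.7, 32, 32)
  expect_equal(gaussian_blur(const, 1.5), const, tolerance = 1e-9)

  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  expect_equal(sum(gaussian_blur(imp, 2)), 1, tolerance = 1e-6)

  two <- matrix(0, 41, 41); two[21, 11] <- 1; two[21, 21] <- 1
  b <- gaussian_blur(two, 1)
  # closed-form sum of two Gaussians 10 px apart keeps maxima at the sources
  row <- b[21, ]
  peaks <- which(diff(sign(diff(row))) == -2) + 1
  expect_setequal(peaks, c(11, 21))
})

test_that("otsu threshold matches exhaustive between-class variance argmax", {
  # two-level image: threshold separates exactly the bright class
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10)
  mask <- otsu_binarize(img)
  expect_identical(unclass(mask), matrix(as.integer(img > 100), 10))

  expect_error(otsu_binarize(matrix(5, 8, 8)), "degenerate")

  # toy histogram fixture vs an independently coded brute-force oracle
  vals <- c(rep(10, 50), rep(100, 30), rep(200, 20))
  oracle <- function(v, levels = 256L) {
    lo <- min(v); hi <- max(v)
    bin <- pmin(levels, floor((v - lo) / (hi - lo) * levels) + 1L)
    best <- -Inf; best_t <- NA
    for (t in 1:(levels - 1L)) {
      g0 <- v[bin <= t]; g1 <- v[bin > t]
      if (!length(g0) || !length(g1)) next
      bcv <- length(g0) * length(g1) * (mean(g0) - mean(g1))^2
      if (bcv > best) { best <- bcv; best_t <- t }
    }
    lo + best_t * (hi - lo) / levels
  }
  th <- otsu_threshold(vals)
  expect_equal(th, oracle(vals), tolerance = (200 - 10) / 256 + 1e-9)
  expect_identical(vals > th, vals > oracle(vals))

  # dual route: EBImage's Otsu picks the same cut on a random image
  set.seed(42)
  img2 <- matrix(pmin(1, pmax(0, c(rnorm(300, .2, .05), rnorm(212, .7, .1)))),
                 16)
  th2 <- otsu_threshold(img2)
  th_eb <- EBImage::otsu(EBImage::Image(img2), range = range(img2))
  expect_identical(img2 > th2, img2 > th_eb)
})

test_that("skeletonization thins to the midline and preserves topology", {
  bar <- render_shape("bar", bar_width_px = 5, bar_length_px = 50)
  sk <- skeletonize_mask(bar)
  expect_true(all(sk <= bar))                      # subset of foreground
  expect_false(has_2x2_block(sk == 1L))            # thin
  mid_row <- which(rowSums(bar) > 0)[3L]           # midline of a 5-px bar
  expect_true(all(which(sk == 1L, arr.ind = TRUE)[, 1L] == mid_row))
  expect_equal(n_components(sk), 1L)

  ring <- render_shape("ring", outer_r = 30, inner_r = 20)
  skr <- skeletonize_mask(ring)
  expect_true(all(skr <= ring))
  expect_false(has_2x2_block(skr == 1L))
  expect_equal(n_components(skr), n_components(ring))  # 1 component
  expect_equal(n_holes(skr), n_holes(ring))            # 1 hole preserved

  px <- matrix(0L, 9, 9); px[5, 5] <- 1L
  expect_equal(sum(skeletonize_mask(px)), 1L)      # isolated pixel survives
  expect_error(skeletonize_mask(matrix(0L, 4, 4)), "empty")
})

test_that("line tracing orders pixels and splits at corners and junctions", {
  m <- matrix(0L, 10, 50); m[5, 4:43] <- 1L        # straight 40-px line
  tl <- trace_lines(m, 60, 10L)
  expect_length(tl, 1L)
  expect_equal(nrow(tl[[1L]]), 40L)
  steps <- abs(diff(tl[[1L]]))
  expect_true(all(steps <= 1L))                    # 8-adjacent and ordered

  L <- render_shape("L", arm_px = 40, thickness_px = 1)
  tlL <- trace_lines(L, 60, 10L)
  expect_length(tlL, 2L)                           # 90 deg > 60 deg splits

  # T junction: three arms, junction pixel excluded from all lines
  Tm <- matrix(0L, 41, 41)
  Tm[21, 1:41] <- 1L; Tm[21:41, 21] <- 1L
  tlT <- trace_lines(Tm, 60, 10L)
  expect_length(tlT, 3L)
  # 8-connectivity marks a small cluster around the crossing as junctions;
  # the crossing pixel itself is always one of them and belongs to no line
  expect_gte(attr(tlT, "junction_pixels"), 1L)
  all_px <- do.call(rbind, tlT)
  expect_false(any(all_px[, 1L] == 21 & all_px[, 2L] == 21))
  n_in_lines <- sum(vapply(tlT, nrow, integer(1L)))
  expect_identical(n_in_lines + attr(tlT, "junction_pixels") +
                     attr(tlT, "short_pixels"), sum(Tm))
})

test_that("trace_lines conserves every skeleton pixel", {
  r <- get_helix()
  blurred <- gaussian_blur(r$axis, 1)
  sk <- skeletonize_mask(otsu_binarize(blurred))
  tl <- trace_lines(sk, 60, 10L)
  n_in_lines <- sum(vapply(tl, nrow, integer(1L)))
  expect_identical(n_in_lines + attr(tl, "junction_pixels") +
                     attr(tl, "short_pixels"), sum(sk))
})

test_that("center splines interpolate, follow circles, and smooth jitter", {
  line <- cbind(5L, 3:22)                          # 20 collinear points
  sp <- fit_center_spline(line, smoothing = 0, pixel_size_nm = 1)
  ts <- seq(0, 1, length.out = 50)
  pos <- sp$evaluate(ts)
  expect_lt(max(abs(pos[, 2L] - 4)), 1e-6)         # stays on the row
  tan <- sp$tangent(ts)
  expect_lt(max(abs(tan[, 2L])), 1e-6)             # constant direction
  expect_equal(sqrt(rowSums(tan^2)), rep(1, 50), tolerance = 1e-9)

  # quarter arc of radius 50 px: tangents perpendicular to the radius
  ang <- seq(0, pi / 2, length.out = 60)
  arc <- cbind(60 + 50 * sin(ang), 60 + 50 * cos(ang))
  spc <- fit_center_spline(arc, smoothing = 0, pixel_size_nm = 1)
  ts <- seq(0.1, 0.9, length.out = 20)
  pos <- spc$evaluate(ts); tan <- spc$tangent(ts)
  rad <- cbind(pos[, 1L] - 59, pos[, 2L] - 59)
  rad <- rad / sqrt(rowSums(rad^2))
  dotp <- abs(rowSums(rad * tan))
  expect_lt(max(asin(pmin(1, dotp)) * 180 / pi), 2)

  # jittered straight line, smoothing on: residual small, direction true
  set.seed(3)
  jit <- cbind(round(30 + runif(80, -0.5, 0.5)), 11:90)
  spj <- fit_center_spline(jit, smoothing = 0.7, pixel_size_nm = 1)
  expect_lte(spj$residual_rms_px, 0.5)
  tanj <- spj$tangent(seq(0.1, 0.9, length.out = 20))
  ang_err <- abs(atan2(tanj[, 2L], tanj[, 1L])) * 180 / pi
  expect_lt(max(ang_err), 3)

  expect_error(fit_center_spline(cbind(1L, 1:3), 0, 1), "at least 4")
})

test_that("one-channel midline estimation finds the center of mass ridge", {
  cfg <- pipeline_config()
  # two parallel ridges +/- 10 px about the midline -> spline on the midline
  img <- render_parallel_ridges(separation_nm = 400, length_nm = 3000,
                                pixel_size_nm = 20, psf_sigma_nm = 30,
                                margin_nm = 400)
  truth_y <- attr(img, "truth")$midline_y_nm
  sps <- estimate_axis_one_channel(img, pipeline_config(max_distance_nm = 600,
                                                        min_distance_nm = 100))
  pos <- sps[[1L]]$evaluate(seq(0.2, 0.8, length.out = 20))
  expect_lt(max(abs(pos[, 2L] - truth_y)), 20)     # within 1 px

  # single ridge -> spline along that ridge
  one <- closed_form_ridges(400, 400, 60, 20, 41, 100)
  ci <- channel_image(one, 20)
  sps1 <- estimate_axis_one_channel(ci, pipeline_config(max_distance_nm = 600,
                                                        min_distance_nm = 100))
  pos1 <- sps1[[1L]]$evaluate(seq(0.2, 0.8, length.out = 20))
  expect_lt(max(abs(pos1[, 2L] - 400)), 20)

  # helix: midline tracked within 1 px away from the borders
  r <- get_helix()
  spsh <- estimate_axis_one_channel(r$axis, pipeline_config())
  posh <- spsh[[1L]]$evaluate(seq(0.1, 0.9, length.out = 50))
  expect_lt(max(abs(posh[, 2L] - r$truth$midline_y_nm)),
            r$axis$pixel_size_nm)
})

test_that("one- and two-channel splines agree when the central channel sits
          on the midline", {
  r <- get_helix()
  cfg <- pipeline_config()
  sp1 <- estimate_axis_one_channel(r$axis, cfg)[[1L]]
  sp2 <- lineprofiler:::segment_to_splines(r$central, cfg$blur_sigma_px,
                                           cfg)[[1L]]
  ts <- seq(0.1, 0.9, length.out = 40)
  d <- abs(sp1$evaluate(ts)[, 2L] - sp2$evaluate(ts)[, 2L])
  expect_lt(max(d), r$axis$pixel_size_nm)
})

test_that("fitted splines rotate with the image", {
  img <- render_parallel_ridges(500, length_nm = 3000, pixel_size_nm = 20,
                                psf_sigma_nm = 30, margin_nm = 300)
  cfg <- pipeline_config(max_distance_nm = 700, min_distance_nm = 100)
  sp <- estimate_axis_one_channel(img, cfg)[[1L]]
  rot <- channel_image(rotate90(img$pixels), img$pixel_size_nm)
  spr <- estimate_axis_one_channel(rot, cfg)[[1L]]
  ts <- seq(0, 1, length.out = 200)
  pos <- sp$evaluate(ts)
  posr <- spr$evaluate(ts)
  # rotating (x, y) by 90 deg in a (nr x nc) image maps x' = y and
  # y' = (nc-1)px - x, so the inverse is x = (nc-1)px - y', y = x'
  W <- (ncol(img$pixels) - 1) * img$pixel_size_nm
  back <- cbind(x = W - posr[, 2L], y = posr[, 1L])
  # compare y(x) of both splines over the common x span
  xs <- seq(max(min(pos[, 1]), min(back[, "x"])) + 50,
            min(max(pos[, 1]), max(back[, "x"])) - 50, length.out = 50)
  y1 <- approx(pos[, 1], pos[, 2], xout = xs)$y
  y2 <- approx(back[, "x"], back[, "y"], xout = xs)$y
  expect_lt(max(abs(y1 - y2)), 0.5 * img$pixel_size_nm)
})
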