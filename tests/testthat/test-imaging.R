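test_that("to_8bit scales min-max onto [0,255] and flags constant images", {
  ramp <- matrix(0:1023, 32, 32)
  out <- to_8bit(ramp)
  expect_equal(min(out), 0)
  expect_equal(max(out), 255)
  expect_equal(out[1024], 255)
  expect_equal(out[1], 0)
  expect_equal(out[513], round(512 * 255 / 1023))

  already <- matrix(c(0, 128, 255, 64), 2, 2)
  expect_equal(to_8bit(already), already)

  expect_warning(z <- to_8bit(matrix(7, 3, 3)), "constant")
  expect_true(all(z == 0))
})

test_that("auto_threshold matches exhaustive-search and mean oracles", {
  # two delta peaks at 50 and 200 with equal mass
  img <- matrix(rep(c(50, 200), each = 50), 10, 10)
  for (method in c("huang", "mean")) {
    at <- auto_threshold(img, method)
    expect_gte(at$threshold, 50)
    expect_lt(at$threshold, 200)
    expect_equal(unname(at$mask), unname(img == 200))
    expect_false(at$degenerate)
  }

  # mean rule: half 0 half 100 -> threshold 50
  img2 <- matrix(rep(c(0, 100), each = 32), 8, 8)
  at2 <- auto_threshold(img2, "mean")
  expect_equal(at2$threshold, 50)
  expect_equal(unname(at2$mask), unname(img2 == 100))

  # constant image is degenerate
  expect_warning(atc <- auto_threshold(matrix(9, 4, 4), "huang"),
                 "degenerate")
  expect_true(atc$degenerate)

  # Huang equals the exhaustive 0-255 search oracle on random histograms
  set.seed(55)
  for (k in 1:8) {
    img <- matrix(sample(0:255, 400, replace = TRUE,
                         prob = runif(256)^2), 20, 20)
    expect_equal(auto_threshold(img, "huang")$threshold,
                 oracle_huang_threshold(img))
  }
})

test_that("median_filter applies disc neighborhoods with edge replication", {
  expect_equal(median_filter(matrix(4, 6, 6), 2), matrix(4, 6, 6))

  imp <- matrix(10, 9, 9); imp[5, 5] <- 1000
  expect_equal(median_filter(imp, 2), matrix(10, 9, 9))

  # 5x5 hand grid vs brute-force neighborhood medians
  set.seed(2)
  g <- matrix(sample(0:50, 25), 5, 5)
  out <- median_filter(g, 2)
  off <- expand.grid(dy = -2:2, dx = -2:2)
  off <- off[off$dy^2 + off$dx^2 <= 4, ]
  expect_equal(nrow(off), 13L)
  for (r in 1:5) for (cc in 1:5) {
    vals <- mapply(function(dy, dx)
      g[min(max(r + dy, 1), 5), min(max(cc + dx, 1), 5)],
      off$dy, off$dx)
    expect_equal(out[r, cc], median(vals))
  }
})

test_that("binary_morph follows count-based 8-neighborhood semantics", {
  m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE
  e <- binary_morph(m, "erode", 1, 1)
  expect_equal(sum(e), 1L)
  expect_true(e[3, 3])

  expect_equal(binary_morph(matrix(FALSE, 4, 4), "erode", 3, 1),
               matrix(FALSE, 4, 4))

  # closing property: dilate x5 then erode x5 contains the original interior
  rect <- matrix(FALSE, 40, 40); rect[6:35, 6:35] <- TRUE
  closed <- binary_morph(binary_morph(rect, "dilate", 5, 1), "erode", 5, 1)
  expect_true(all(closed[rect]))

  # count semantics: with count=8 only isolated pixels erode
  iso <- matrix(FALSE, 5, 5); iso[3, 3] <- TRUE; iso[1, 1] <- TRUE
  pair <- iso; pair[1, 2] <- TRUE
  expect_equal(sum(binary_morph(iso, "erode", 1, 8)), 0L)
  e8 <- binary_morph(pair, "erode", 1, 8)
  expect_equal(sum(e8), 2L)   # the adjacent pair survives, isolated dies
})

test_that("analyze_particles filters by calibrated area, edges, and fills holes", {
  # 40 um^2 and 10 um^2 components at 0.1 um pixels (4000 px and 1000 px)
  m <- matrix(FALSE, 120, 120)
  m[11:60, 11:90] <- TRUE               # 50x80 = 4000 px = 40 um^2
  m[81:100, 81:130 - 31] <- TRUE        # 20x50 = 1000 px = 10 um^2
  ps <- analyze_particles(m, min_size = 30, pixel_size = 0.1)
  expect_equal(nrow(ps$table), 1L)
  expect_equal(ps$table$area, 40)

  # border-touching component removed when exclude is on, kept otherwise
  mb <- matrix(FALSE, 50, 50); mb[1:40, 10:45] <- TRUE
  expect_equal(nrow(analyze_particles(mb, 1, TRUE, TRUE, 0.1)$table), 0L)
  expect_equal(nrow(analyze_particles(mb, 1, FALSE, TRUE, 0.1)$table), 1L)

  # annulus: fill_holes counts the hole area
  ann <- matrix(FALSE, 60, 60)
  ann[15:45, 15:45] <- TRUE
  ann[25:35, 25:35] <- FALSE
  with_hole <- analyze_particles(ann, 1, TRUE, FALSE, 1)
  filled <- analyze_particles(ann, 1, TRUE, TRUE, 1)
  expect_equal(with_hole$table$area_px, 31 * 31 - 11 * 11)
  expect_equal(filled$table$area_px, 31 * 31)
})

test_that("particle counts equal a flood-fill oracle on random masks", {
  set.seed(77)
  for (k in 1:10) {
    m <- matrix(runif(64 * 64) < 0.35, 64, 64)
    ps <- analyze_particles(m, min_size = 0, exclude_edge_touching = FALSE,
                            fill_holes = FALSE, pixel_size = 1)
    expect_equal(nrow(ps$table), oracle_component_count(m, 8))
  }
})

test_that("make_roi builds eroded per-nucleus ROIs and respects edge exclusion", {
  s <- synth_nucleus_image(n_nuclei = 2, size = 260, h = 0.3, noise_sd = 2,
                           seed = 19)
  rs <- make_roi(s$image, "lamin")
  expect_equal(length(rs$rois), 2L)
  # each ROI strictly contained in its nucleus's truth mask (eroded)
  for (roi in rs$rois) {
    containments <- vapply(s$truth$masks, function(tm)
      all(tm[roi]), logical(1))
    expect_equal(sum(containments), 1L)
    hosting <- which(containments)
    expect_lt(sum(roi), sum(s$truth$masks[[hosting]]))
  }

  # a nucleus touching the image edge yields no ROI
  edge <- matrix(0, 120, 120)
  xs <- matrix(rep(1:120, each = 120), 120)
  ys <- matrix(rep(1:120, times = 120), 120)
  edge[(xs - 1)^2 + (ys - 60)^2 <= 45^2] <- 100   # circle crossing border
  expect_warning(re <- make_roi(edge, "lamin"), "no ROI")
  expect_equal(length(re$rois), 0L)

  # costain: ROIs identical to the lamin protocol on the source channel
  other <- s$image * 0.5 + 3
  rc <- make_roi(other, "costain", roi_source = s$image)
  expect_equal(rc$rois, rs$rois)
  expect_equal(rc$measure_image, to_8bit(other))
})

test_that("compute_di is SD/mean, zero for constant ROIs, scale-invariant", {
  img <- matrix(100, 30, 30)
  roi <- matrix(TRUE, 30, 30)
  expect_equal(compute_di(img, roi)$di, 0)

  # half 100 / half 200 over 5000 pixels
  img2 <- matrix(rep(c(100, 200), each = 2500), 50, 100)
  roi2 <- matrix(TRUE, 50, 100)
  r <- compute_di(img2, roi2)
  expect_equal(r$mean, 150)
  expect_equal(r$sd, sd(rep(c(100, 200), each = 2500)))
  expect_equal(r$di, r$sd / r$mean)
  expect_equal(round(r$di, 4), 0.3334)

  # scaling intensities leaves the D.I. unchanged
  expect_equal(compute_di(img2 * 2, roi2)$di, r$di)

  expect_error(compute_di(img, matrix(FALSE, 30, 30)), "empty ROI")
  expect_error(compute_di(img * 0, roi), "positive")
})

test_that("aggregate_individuals averages per individual and picks the right test", {
  di <- c(0.2, 0.3)
  expect_warning(
    agg <- aggregate_individuals(c(di, rep(0.25, 2), rep(0.3, 2),
                                   rep(0.35, 2)),
                                 rep(c("i1", "i2", "i3", "i4"), each = 2),
                                 rep(c("g1", "g2"), each = 4)),
    "outside 10-12")
  expect_equal(agg$individuals$mean_di[agg$individuals$individual == "i1"],
               0.25)
  expect_equal(agg$test$method, "Student t")

  # identical groups -> t = 0, p = 1
  di2 <- rep(c(0.2, 0.4), 6)
  suppressWarnings(
    agg2 <- aggregate_individuals(di2, rep(paste0("i", 1:6), each = 2),
                                  rep(c("a", "b"), each = 6)))
  expect_equal(agg2$test$statistic, 0)
  expect_equal(agg2$test$p_value, 1)

  # three groups: Tukey flags only pairs involving the shifted group
  set.seed(4)
  vals <- c(rnorm(33, 0.25, 0.005), rnorm(33, 0.25, 0.005),
            rnorm(33, 0.45, 0.005))
  suppressWarnings(
    agg3 <- aggregate_individuals(vals,
                                  rep(paste0("i", 1:9), each = 11),
                                  rep(c("wt", "ctrl", "mut"), each = 33)))
  expect_equal(agg3$test$method, "one-way ANOVA + Tukey HSD")
  tk <- agg3$test$tukey
  involves_mut <- grepl("mut", tk$comparison)
  expect_true(all(tk$p_adj[involves_mut] < 0.05))
  expect_true(all(tk$p_adj[!involves_mut] > 0.05))

  # group with a single individual errors
  expect_error(suppressWarnings(
    aggregate_individuals(c(0.2, 0.3, 0.4), c("i1", "i1", "i2"),
                          c("a", "a", "b"))), ">= 2 individuals")
})

test_that("synthetic nuclei give D.I. = 0 at h = 0 and strictly increasing D.I. in h", {
  s0 <- synth_nucleus_image(n_nuclei = 1, size = 160, h = 0, noise_sd = 0,
                            seed = 23)
  rs0 <- make_roi(s0$image, "lamin")
  expect_equal(length(rs0$rois), 1L)
  expect_equal(compute_di(rs0$measure_image, rs0$rois[[1]])$di, 0)

  dis <- vapply(c(0, 0.2, 0.4, 0.8), function(h) {
    s <- synth_nucleus_image(n_nuclei = 1, size = 160, h = h, noise_sd = 2,
                             seed = 23)
    rs <- make_roi(s$image, "lamin")
    compute_di(rs$measure_image, rs$rois[[1]])$di
  }, numeric(1))
  expect_equal(cor(dis, c(0, 0.2, 0.4, 0.8), method = "spearman"), 1)

  # eroded ROI is a strict subset of the thresholded nucleus mask
  expect_lt(sum(rs0$rois[[1]]), sum(s0$truth$masks[[1]]))
  expect_true(all(s0$truth$masks[[1]][rs0$rois[[1]]]))
})
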