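## Re-implementation of the published ImageJ macro steps used to quantify
## nuclear-envelope protein heterogeneity: 8-bit conversion, Huang and Mean
## auto-thresholds, disc median filter, count-based binary erosion/dilation,
## particle analysis, ROI construction, and the Distribution Index
## (D.I. = SD/mean of intensity within the eroded nuclear ROI).
##
## Images are numeric matrices (row = y, column = x), intensities >= 0.

#' Convert an image to 8-bit by linear min-max scaling
#'
#' The image range is mapped linearly onto \[0, 255\] and rounded to the
#' nearest integer. A degenerate (constant) image maps to all zeros with a
#' warning.
#'
#' @param image Numeric matrix of non-negative intensities.
#' @return Integer-valued matrix in \[0, 255\].
#' @export
to_8bit <- function(image) {
  lo <- min(image); hi <- max(image)
  if (hi == lo) {
    warning("constant image: 8-bit conversion maps all pixels to 0")
    return(matrix(0, nrow(image), ncol(image)))
  }
  round((image - lo) * (255 / (hi - lo)))
}

huang_fuzziness <- function(hist256, t) {
  g <- 0:255
  w <- hist256
  below <- g <= t
  if (sum(w[below]) == 0 || sum(w[!below]) == 0) return(Inf)
  mu0 <- sum(w[below] * g[below]) / sum(w[below])
  mu1 <- sum(w[!below] * g[!below]) / sum(w[!below])
  C <- max(g[w > 0]) - min(g[w > 0])
  mu_of <- ifelse(below, mu0, mu1)
  u <- 1 / (1 + abs(g - mu_of) / C)
  s <- ifelse(u <= 0 | u >= 1, 0, -u * log(u) - (1 - u) * log(1 - u))
  sum(w * s)
}

#' Automatic threshold (Huang fuzzy or Mean) of an 8-bit image
#'
#' `huang` picks the threshold minimizing Huang-Wang fuzziness (the Shannon
#' entropy of the fuzzy membership of each gray level to its class mean)
#' over the 256-bin histogram; `mean` thresholds at the mean intensity.
#' With a dark background the foreground is the set of pixels strictly
#' above the threshold.
#'
#' @param image8 8-bit image matrix (values in \[0, 255\]).
#' @param method `"huang"` or `"mean"`.
#' @param dark_background Foreground is above the threshold (only `TRUE`
#'   supported, matching the macro's `dark` variants).
#' @return A list of class `auto_threshold`: `mask` (logical matrix),
#'   `threshold`, `degenerate` (TRUE when fore- or background is empty).
#' @export
auto_threshold <- function(image8, method = c("huang", "mean"),
                           dark_background = TRUE) {
  method <- match.arg(method)
  stopifnot(dark_background)
  v <- as.integer(round(image8))
  h <- tabulate(v + 1L, nbins = 256L)
  if (method == "mean") {
    thr <- mean(image8)
  } else {
    fz <- vapply(0:254, function(t) huang_fuzziness(h, t), numeric(1))
    thr <- if (all(!is.finite(fz))) min(v) else (0:254)[which.min(fz)]
  }
  mask <- image8 > thr
  degenerate <- !any(mask) || all(mask)
  if (degenerate) warning("degenerate threshold: empty fore- or background")
  structure(list(mask = mask, threshold = thr, degenerate = degenerate),
            class = "auto_threshold")
}

disc_offsets <- function(radius) {
  d <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  d[d$dy^2 + d$dx^2 <= radius^2, , drop = FALSE]
}

#' Disc median filter with edge replication
#'
#' Each pixel is replaced by the median of the disc neighborhood of
#' Euclidean radius `radius` (13 pixels at radius 2); indices beyond the
#' border are clamped (edge replication).
#'
#' @param image Numeric matrix.
#' @param radius Disc radius in pixels (>= 1).
#' @return Filtered matrix.
#' @export
median_filter <- function(image, radius = 2) {
  stopifnot(radius >= 1)
  off <- disc_offsets(radius)
  nr <- nrow(image); nc <- ncol(image)
  stack <- vapply(seq_len(nrow(off)), function(k) {
    ri <- pmin(pmax(seq_len(nr) + off$dy[k], 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + off$dx[k], 1L), nc)
    as.vector(image[ri, ci])
  }, numeric(nr * nc))
  matrix(apply(stack, 1, stats::median), nr, nc)
}

neighbor_count <- function(mask, value = TRUE) {
  nr <- nrow(mask); nc <- ncol(mask)
  m <- if (value) mask else !mask
  p <- matrix(0L, nr + 2L, nc + 2L)
  if (!value) {                     # off-image neighbors count as background
    p[] <- 1L
    p[2:(nr + 1), 2:(nc + 1)] <- 0L
  }
  p[2:(nr + 1), 2:(nc + 1)] <- m * 1L
  acc <- matrix(0L, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    acc <- acc + p[(2:(nr + 1)) + dy, (2:(nc + 1)) + dx]
  }
  acc
}

#' Binary erosion/dilation with ImageJ count semantics
#'
#' 8-neighborhood morphology as in the binary Options of the macro: one
#' erosion pass removes a foreground pixel when at least `count` of its 8
#' neighbors are background; one dilation pass adds a background pixel when
#' at least `count` neighbors are foreground. Off-image neighbors are
#' background. The pass is applied `iterations` times.
#'
#' @param mask Logical matrix.
#' @param op `"erode"` or `"dilate"`.
#' @param iterations Number of passes (>= 1).
#' @param count Neighbor count threshold, 1..8.
#' @return Logical matrix.
#' @export
binary_morph <- function(mask, op = c("erode", "dilate"), iterations = 1L,
                         count = 1L) {
  op <- match.arg(op)
  stopifnot(iterations >= 1L, count >= 1L, count <= 8L)
  for (i in seq_len(iterations)) {
    if (op == "erode") {
      bg_n <- neighbor_count(mask, value = FALSE)
      mask <- mask & !(mask & bg_n >= count)
    } else {
      fg_n <- neighbor_count(mask, value = TRUE)
      mask <- mask | (!mask & fg_n >= count)
    }
  }
  mask
}

# 8-connected (foreground) or 4-connected (background) component labeling
# via the pixel adjacency graph
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  labels <- matrix(0L, nr, nc)
  if (!length(idx)) return(labels)
  pos <- match(seq_len(nr * nc), idx)   # pixel -> node id or NA
  offs <- if (connectivity == 8L)
    list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  else
    list(c(1L, 0L), c(0L, 1L))
  edges <- list()
  ri <- ((idx - 1L) %% nr) + 1L
  ci <- ((idx - 1L) %/% nr) + 1L
  for (o in offs) {
    r2 <- ri + o[1]; c2 <- ci + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    nb_node <- pos[nb]
    has <- !is.na(nb_node)
    edges[[length(edges) + 1L]] <-
      rbind(which(ok)[has], nb_node[has])
  }
  e <- do.call(cbind, edges)
  g <- igraph::make_graph(edges = as.vector(e), n = length(idx),
                          directed = FALSE)
  comp <- igraph::components(g)$membership
  labels[idx] <- comp
  labels
}

# fill holes: background regions (4-connected) not touching the border
fill_holes <- function(mask) {
  bg_lab <- label_components(!mask, connectivity = 4L)
  if (!any(bg_lab > 0L)) return(mask)
  border_labs <- unique(c(bg_lab[1, ], bg_lab[nrow(bg_lab), ],
                          bg_lab[, 1], bg_lab[, ncol(bg_lab)]))
  border_labs <- border_labs[border_labs > 0L]
  mask | (bg_lab > 0L & !(bg_lab %in% border_labs))
}

#' Particle analysis of a binary mask
#'
#' 8-connected components; holes are filled before area measurement when
#' `fill_holes = TRUE` (macro flag `include`); components touching the
#' image border are removed when `exclude_edge_touching = TRUE` (macro flag
#' `exclude`); components whose calibrated area is below `min_size` are
#' removed. Areas are calibrated (`pixels * pixel_size^2`, matching the
#' macro on a calibrated image); pass `pixel_size = 1` for pixel^2 units.
#'
#' @param mask Logical matrix.
#' @param min_size Minimum area in calibrated units^2.
#' @param exclude_edge_touching Drop border-touching components.
#' @param fill_holes Fill interior holes before measuring.
#' @param pixel_size Pixel edge length in micrometers (default 0.1).
#' @return A list of class `particle_set`: `labels` (integer matrix,
#'   relabeled 1..n over retained particles), `table` (`data.frame`: `id`,
#'   `area_px`, `area`, `touches_edge`), `mask` (logical matrix of retained
#'   particles).
#' @export
analyze_particles <- function(mask, min_size = 30,
                              exclude_edge_touching = TRUE,
                              fill_holes = TRUE, pixel_size = 0.1) {
  if (fill_holes) mask <- fill_holes(mask)
  lab <- label_components(mask, 8L)
  n <- max(lab)
  keep <- logical(n)
  if (n > 0L) {
    area_px <- tabulate(lab[lab > 0L], nbins = n)
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                       lab[, ncol(lab)]))
    touches <- seq_len(n) %in% border[border > 0L]
    keep <- area_px * pixel_size^2 >= min_size
    if (exclude_edge_touching) keep <- keep & !touches
  }
  new_lab <- matrix(0L, nrow(mask), ncol(mask))
  ids <- which(keep)
  tab <- data.frame(id = integer(), area_px = integer(), area = numeric(),
                    touches_edge = logical())
  if (length(ids)) {
    remap <- integer(n)
    remap[ids] <- seq_along(ids)
    new_lab[lab > 0L] <- remap[lab[lab > 0L]]
    tab <- data.frame(id = seq_along(ids),
                      area_px = area_px[ids],
                      area = area_px[ids] * pixel_size^2,
                      touches_edge = touches[ids])
  }
  structure(list(labels = new_lab, table = tab, mask = new_lab > 0L),
            class = "particle_set")
}

#' Build per-nucleus ROIs following the published macro protocols
#'
#' * `lamin`: 8-bit conversion, Huang dark threshold, particle analysis
#'   (min 30 calibrated units^2, exclude edge, include holes), erosion x5
#'   (count 1), particle analysis again; each retained particle is one ROI.
#'   Intensity is measured on the 8-bit converted image.
#' * `npc`: 8-bit conversion, disc median filter (radius 2), Mean dark
#'   threshold, particle analysis (min 5), dilation x5, particle analysis,
#'   erosion x10, particle analysis; intensity is measured on the
#'   median-filtered 8-bit image.
#' * `costain`: the `lamin` protocol applied to `roi_source` (e.g. a Lamin C
#'   co-stain), with the resulting ROIs transferred to `image`.
#'
#' @param image Single-channel intensity matrix (the measured channel).
#' @param protocol `"lamin"`, `"npc"` or `"costain"`.
#' @param roi_source ROI-defining channel for the `costain` protocol.
#' @param pixel_size Pixel edge length in micrometers.
#' @return A list of class `roi_set`: `rois` (list of logical masks, one
#'   per nucleus), `labels` (labeled matrix), `measure_image` (the image on
#'   which D.I. is measured).
#' @export
make_roi <- function(image, protocol = c("lamin", "npc", "costain"),
                     roi_source = NULL, pixel_size = 0.1) {
  protocol <- match.arg(protocol)
  if (protocol == "costain") {
    if (is.null(roi_source)) stop("costain protocol needs roi_source")
    src <- make_roi(roi_source, "lamin", pixel_size = pixel_size)
    measure <- to_8bit(image)
    return(structure(list(rois = src$rois, labels = src$labels,
                          measure_image = measure), class = "roi_set"))
  }
  img8 <- to_8bit(image)
  if (protocol == "lamin") {
    th <- auto_threshold(img8, "huang")
    ps <- analyze_particles(th$mask, 30, TRUE, TRUE, pixel_size)
    m <- binary_morph(ps$mask, "erode", 5L, 1L)
    ps2 <- analyze_particles(m, 30, TRUE, TRUE, pixel_size)
    measure <- img8
  } else {
    med <- median_filter(img8, 2)
    th <- auto_threshold(med, "mean")
    ps <- analyze_particles(th$mask, 5, TRUE, TRUE, pixel_size)
    m <- binary_morph(ps$mask, "dilate", 5L, 1L)
    ps <- analyze_particles(m, 5, TRUE, TRUE, pixel_size)
    m <- binary_morph(ps$mask, "erode", 10L, 1L)
    ps2 <- analyze_particles(m, 5, TRUE, TRUE, pixel_size)
    measure <- med
  }
  n <- max(ps2$labels)
  if (n == 0L) warning("no ROI found")
  rois <- lapply(seq_len(n), function(i) ps2$labels == i)
  structure(list(rois = rois, labels = ps2$labels,
                 measure_image = measure), class = "roi_set")
}

#' Distribution Index of an ROI
#'
#' D.I. = sample SD / mean of the pixel intensities within the ROI: the
#' coefficient of variation of the nuclear-envelope signal, 0 for a
#' perfectly homogeneous distribution and increasing with heterogeneity.
#'
#' @param image8 Intensity matrix (typically the protocol's 8-bit
#'   measurement image).
#' @param roi Logical matrix, non-empty, same dimensions as `image8`.
#' @return A one-row `data.frame`: `n_pixels`, `mean`, `sd`, `di`.
#' @export
compute_di <- function(image8, roi) {
  stopifnot(identical(dim(image8), dim(roi)))
  v <- image8[roi]
  if (!length(v)) stop("empty ROI")
  m <- mean(v)
  if (m <= 0) stop("ROI mean intensity must be positive")
  s <- stats::sd(v)
  data.frame(n_pixels = length(v), mean = m, sd = s, di = s / m)
}

#' Aggregate per-nucleus D.I. values per individual and test groups
#'
#' Per-individual mean D.I. is the unit of analysis (10-12 nuclei per
#' individual is the intended design; a warning is raised outside this
#' range). Two groups are compared with the unpaired two-tailed Student's
#' t test on individual means; more than two with one-way ANOVA followed by
#' Tukey's multiple comparison test.
#'
#' @param di Numeric vector of per-nucleus D.I. values.
#' @param individual Individual id per nucleus.
#' @param group Group label per nucleus (constant within individual).
#' @return A list: `individuals` (`data.frame`: `individual`, `group`,
#'   `n_nuclei`, `mean_di`) and `test` (a [ttest()] or [anova_tukey()]
#'   result).
#' @export
aggregate_individuals <- function(di, individual, group) {
  stopifnot(length(di) == length(individual), length(di) == length(group))
  key <- !duplicated(individual)
  ind_group <- stats::setNames(as.character(group)[key],
                               as.character(individual)[key])
  n_nuc <- table(individual)
  if (any(n_nuc < 10 | n_nuc > 12))
    warning("individual(s) with nucleus count outside 10-12: ",
            paste(names(n_nuc)[n_nuc < 10 | n_nuc > 12], collapse = ", "))
  means <- tapply(di, individual, mean)
  ind <- data.frame(individual = names(means),
                    group = ind_group[names(means)],
                    n_nuclei = as.integer(n_nuc[names(means)]),
                    mean_di = as.numeric(means),
                    stringsAsFactors = FALSE, row.names = NULL)
  by_group <- split(ind$mean_di, ind$group)
  if (any(lengths(by_group) < 2L))
    stop("every group needs >= 2 individuals")
  test <- if (length(by_group) == 2L)
    ttest(by_group[[1]], by_group[[2]])
  else
    anova_tukey(by_group)
  list(individuals = ind, test = test)
}

#' Read a single-channel TIFF or PNG image
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param bit_depth Bit depth used to rescale the \[0, 1\] values returned
#'   by the readers to integer intensities (default 8).
#' @return Numeric intensity matrix.
#' @export
read_image <- function(path, bit_depth = 8) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("package 'png' is required to read PNG images")
    png::readPNG(path)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("package 'tiff' is required to read TIFF images")
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img * (2^bit_depth - 1)
}
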