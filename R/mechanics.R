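#' Construct a microneedle manipulation trace
#'
#' @param time_s Frame times in seconds (strictly increasing; nominal
#'   interval 0.5 s).
#' @param tip_disp_um Flexible-tip displacement from its equilibrium point
#'   (micrometers); force = displacement x `k_tip`.
#' @param span_um Distance between the opposite sides of the nucleus
#'   (micrometers); deformation = baseline span - equilibrium span.
#' @param k_tip Calibrated tip stiffness in nN/um (> 0; 11.3 or 12.0 for
#'   the calibrated needles).
#' @param condition `"nucleus+cell"` or `"cell only"`.
#' @param cycles `data.frame` with frame-index columns `start`, `end`
#'   (1-based, inclusive) delimiting each press cycle; each cycle should
#'   begin with a few pre-press baseline frames.
#' @return A list of class `manipulation_trace`.
#' @export
manipulation_trace <- function(time_s, tip_disp_um, span_um, k_tip,
                               condition = c("nucleus+cell", "cell only"),
                               cycles) {
  condition <- match.arg(condition)
  stopifnot(k_tip > 0, all(diff(time_s) > 0),
            length(time_s) == length(tip_disp_um),
            length(time_s) == length(span_um))
  structure(list(time_s = time_s, tip_disp_um = tip_disp_um,
                 span_um = span_um, k_tip = k_tip, condition = condition,
                 cycles = cycles),
            class = "manipulation_trace")
}

#' Read a manipulation trace from CSV
#'
#' The CSV holds columns `time_s`, `tip_disp_um`, `span_um`; metadata lines
#' `# k_tip_nN_per_um: <value>` and `# condition: <label>` precede the
#' header. Cycle annotations come from a sidecar CSV with columns `start`,
#' `end`.
#'
#' @param path Trace CSV path.
#' @param cycles_path Sidecar CSV path with cycle frame indices.
#' @return A [manipulation_trace()].
#' @export
read_trace <- function(path, cycles_path) {
  hdr <- readLines(path, n = 10)
  meta <- hdr[startsWith(hdr, "#")]
  get <- function(key) {
    ln <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (!length(ln)) stop("missing metadata line: ", key)
    trimws(sub(".*:", "", ln[1]))
  }
  df <- utils::read.csv(path, comment.char = "#")
  cyc <- utils::read.csv(cycles_path)
  manipulation_trace(df$time_s, df$tip_disp_um, df$span_um,
                     k_tip = as.numeric(get("k_tip_nN_per_um")),
                     condition = get("condition"), cycles = cyc)
}

#' Write a manipulation trace (plus cycle sidecar) to CSV
#'
#' @param trace A [manipulation_trace()].
#' @param path Trace CSV path; the sidecar is written next to it as
#'   `<path>.cycles.csv` unless `cycles_path` is given.
#' @param cycles_path Optional sidecar path.
#' @export
write_trace <- function(trace, path, cycles_path = paste0(path,
                                                          ".cycles.csv")) {
  con <- file(path, "w")
  writeLines(c(sprintf("# k_tip_nN_per_um: %g", trace$k_tip),
               sprintf("# condition: %s", trace$condition)), con)
  utils::write.csv(data.frame(time_s = trace$time_s,
                              tip_disp_um = trace$tip_disp_um,
                              span_um = trace$span_um),
                   con, row.names = FALSE)
  close(con)
  utils::write.csv(trace$cycles, cycles_path, row.names = FALSE)
  invisible(path)
}

moving_average <- function(x, w) {
  if (w <= 1L || length(x) < w) return(x)
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
}

#' Extract equilibrium force-deformation points from a trace
#'
#' Per press cycle, the baseline span is the mean of the first
#' `plateau_window` frames of the cycle (cycles are annotated to start with
#' pre-press baseline frames, and the baseline is re-taken before each
#' cycle). The equilibrium plateau is the first frame, on the
#' moving-average-smoothed span, after which successive changes stay below
#' `plateau_eps` for `plateau_window` consecutive frames and whose level
#' differs from the baseline by more than `2 * plateau_eps` (so the
#' pre-press baseline itself never qualifies). Deformation is baseline
#' span minus the mean span over the plateau window; force is the mean tip
#' displacement over the window times `k_tip`. Cycles without a plateau
#' are skipped with a warning. The post-release residual deformation
#' (baseline minus the span just before the next cycle) is reported per
#' cycle as an elastic-recovery check.
#'
#' @param trace A [manipulation_trace()].
#' @param plateau_eps Span stability tolerance in micrometers.
#' @param plateau_window Number of consecutive stable frames (4 frames =
#'   2 s at the nominal 0.5-s interval).
#' @return A `data.frame` of class `force_deformation` with columns
#'   `cycle`, `deformation_um`, `force_nN`, `residual_um`; attribute
#'   `condition`.
#' @export
extract_points <- function(trace, plateau_eps = 0.1, plateau_window = 4L) {
  cyc <- trace$cycles
  if (is.null(cyc) || nrow(cyc) == 0L)
    stop("trace contains no annotated press cycle")
  span_s <- moving_average(trace$span_um, plateau_window)
  rows <- list()
  for (i in seq_len(nrow(cyc))) {
    a <- cyc$start[i]; b <- cyc$end[i]
    base <- mean(trace$span_um[a:min(a + plateau_window - 1L, b)])
    found <- NA_integer_
    for (j in if (b - plateau_window >= a) a:(b - plateau_window) else
         integer(0)) {
      seg <- span_s[j:(j + plateau_window)]
      if (anyNA(seg)) next
      if (all(abs(diff(seg)) < plateau_eps) &&
          abs(mean(seg) - base) > 2 * plateau_eps) {
        found <- j
        break
      }
    }
    if (is.na(found)) {
      warning("cycle ", i, ": no equilibrium plateau found; skipped")
      next
    }
    win <- found:min(found + plateau_window - 1L, b)
    deformation <- base - mean(trace$span_um[win])
    force <- mean(trace$tip_disp_um[win]) * trace$k_tip
    nxt <- if (i < nrow(cyc)) cyc$start[i + 1L] else length(trace$span_um) + 1L
    residual <- NA_real_
    if (nxt - 1L >= b + 1L) {
      tail_win <- max(b + 1L, nxt - plateau_window):(nxt - 1L)
      residual <- base - mean(trace$span_um[tail_win])
    }
    rows[[length(rows) + 1L]] <-
      data.frame(cycle = i, deformation_um = deformation, force_nN = force,
                 residual_um = residual)
  }
  if (!length(rows))
    stop("no cycle produced an equilibrium point")
  structure(do.call(rbind, rows), condition = trace$condition,
            class = c("force_deformation", "data.frame"))
}

#' Estimate stiffness from force-deformation points by linear regression
#'
#' Ordinary least squares of force on deformation, with an intercept by
#' default (`through_origin = TRUE` forces the fit through zero). The slope
#' is the structure's stiffness in nN/um. A warning is raised when
#' R^2 < 0.96 (the fit quality expected of these measurements).
#'
#' @param points A [extract_points()] result (or `data.frame` with
#'   `deformation_um`, `force_nN`).
#' @param through_origin Fit without intercept.
#' @return A list of class `stiffness_estimate`: `slope`, `intercept`,
#'   `r_squared`, `n`, `condition`.
#' @export
fit_stiffness <- function(points, through_origin = FALSE) {
  d <- points$deformation_um
  f <- points$force_nN
  if (length(d) < 2L || length(unique(d)) < 2L)
    stop("need >= 2 points with distinct deformations")
  fit <- if (through_origin) stats::lm(f ~ d + 0) else stats::lm(f ~ d)
  s <- summary(fit)
  slope <- unname(stats::coef(fit)[if (through_origin) "d" else "d"])
  intercept <- if (through_origin) 0 else unname(stats::coef(fit)[1])
  r2 <- s$r.squared
  if (is.nan(r2)) r2 <- 1   # exact fit with zero residual variance
  if (r2 < 0.96)
    warning(sprintf("fit quality below expectation: R^2 = %.3f", r2))
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 n = length(d),
                 condition = attr(points, "condition", exact = TRUE)),
            class = "stiffness_estimate")
}

#' @export
print.stiffness_estimate <- function(x, ...) {
  cat(sprintf("Stiffness %.3f nN/um (intercept %.3f nN, R^2 %.4f, n %d%s)\n",
              x$slope, x$intercept, x$r_squared, x$n,
              if (is.null(x$condition)) "" else paste0(", ", x$condition)))
  invisible(x)
}

#' Net nuclear stiffness after subtracting the non-nuclear contribution
#'
#' @param total Stiffness estimate of the `"nucleus+cell"` condition.
#' @param cell_only Matched stiffness estimate of the `"cell only"`
#'   condition (same needle geometry, neighboring location).
#' @return The slope difference in nN/um, with attribute `non_physical`
#'   set `TRUE` (and a warning) when the result is not positive.
#' @export
net_stiffness <- function(total, cell_only) {
  if (!is.null(total$condition) && total$condition != "nucleus+cell")
    stop("'total' must be the nucleus+cell condition")
  if (!is.null(cell_only$condition) && cell_only$condition != "cell only")
    stop("'cell_only' must be the cell only condition")
  k <- total$slope - cell_only$slope
  if (k <= 0) warning("non-physical net stiffness (<= 0); flagged")
  structure(k, non_physical = k <= 0)
}
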