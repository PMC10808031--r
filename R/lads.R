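#' Merge LAD-state intervals into lamina-associated domains
#'
#' Maximal runs of intervals decoded in the LAD (high-score) state are
#' merged into single domains; runs never cross a chromosome boundary. A
#' run of missing intervals flanked on both sides by LAD-state intervals is
#' bridged into the surrounding domain when `bridge_missing = TRUE`
#' (domains are drawn as continuous rectangles over short data gaps),
#' otherwise the gap splits the domain.
#'
#' @param fit A [fit_segment_hmm()] result, or its `path` data.frame
#'   (`chrom`, `start`, `end`, `state`, `missing`).
#' @param bridge_missing Bridge missing gaps inside LAD runs.
#' @return A `lad_set`: `data.frame` with `chrom`, `start`, `end`, sorted
#'   and non-overlapping, plus attribute `genotype` (settable later) and
#'   `resolution`.
#' @export
call_lads <- function(fit, bridge_missing = TRUE) {
  path <- if (inherits(fit, "segment_fit")) fit$path else fit
  if (is.null(path$missing)) path$missing <- FALSE
  if (nrow(path) == 0L)
    return(lad_set(data.frame(chrom = character(), start = integer(),
                              end = integer())))
  out <- lapply(split(path, factor(path$chrom, levels = unique(path$chrom))),
                function(p) {
    lad <- p$state == 2L & !p$missing
    if (bridge_missing && any(p$missing)) {
      r <- rle(p$missing)
      idx_end <- cumsum(r$lengths)
      idx_start <- idx_end - r$lengths + 1L
      for (k in seq_along(r$values)) {
        if (!r$values[k]) next
        before <- idx_start[k] - 1L
        after <- idx_end[k] + 1L
        if (before >= 1L && after <= nrow(p) && lad[before] && lad[after])
          lad[idx_start[k]:idx_end[k]] <- TRUE
      }
    }
    r <- rle(lad)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    keep <- which(r$values)
    if (!length(keep)) return(NULL)
    data.frame(chrom = p$chrom[1],
               start = p$start[idx_start[keep]],
               end = p$end[idx_end[keep]],
               stringsAsFactors = FALSE)
  })
  lad_set(rbind_all(out, template = empty_intervals()))
}

#' Construct/validate a LAD interval set
#'
#' @param intervals `data.frame` with `chrom`, `start`, `end` (0-based,
#'   half-open).
#' @param genotype Optional genotype tag.
#' @param resolution Optional resolution tag (`"bins"`/`"binless"`).
#' @return The validated `lad_set` (sorted by chromosome then start).
#' @export
lad_set <- function(intervals, genotype = NA_character_,
                    resolution = NA_character_) {
  if (is.null(intervals))
    intervals <- data.frame(chrom = character(), start = integer(),
                            end = integer(), stringsAsFactors = FALSE)
  intervals <- intervals[order(intervals$chrom, intervals$start), ,
                         drop = FALSE]
  row.names(intervals) <- NULL
  if (nrow(intervals) > 1L) {
    same <- intervals$chrom[-1L] == intervals$chrom[-nrow(intervals)]
    if (any(same & intervals$start[-1L] < intervals$end[-nrow(intervals)]))
      stop("LAD intervals overlap within a set")
  }
  if (any(intervals$end <= intervals$start))
    stop("LAD intervals must have positive width")
  structure(intervals, genotype = genotype, resolution = resolution,
            class = c("lad_set", "data.frame"))
}

#' Count and mean length of a LAD set
#'
#' @param lads A `lad_set` (or plain interval data.frame).
#' @return List with `count` and `mean_length_kb` (`NA` for an empty set,
#'   never 0).
#' @export
lad_stats <- function(lads) {
  n <- nrow(lads)
  list(count = n,
       mean_length_kb = if (n == 0L) NA_real_
                        else mean(lads$end - lads$start) / 1000)
}

#' Write a LAD set (or classified LADs) as BED
#'
#' @param lads Interval `data.frame`; an optional `class` column becomes
#'   the BED name field.
#' @param path Output path.
#' @export
write_bed <- function(lads, path) {
  name <- if (!is.null(lads$class)) lads$class else "."
  utils::write.table(
    data.frame(lads$chrom, lads$start, lads$end, name),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a UCSC cytoBand table
#'
#' @param path Path to a tab-separated cytoBand file (`chrom`, `start`,
#'   `end`, `band name`, `gieStain`), optionally gzipped.
#' @return `data.frame` with those five columns.
#' @export
read_cytoband <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "gieStain"),
                          quote = "", comment.char = "#")
  df
}

#' Partition chromosomes into arm / centromere / telomere regions
#'
#' The cytoband source defines band coordinates but not which bands make up
#' the functional peri-centromere, so the mapping is an explicit,
#' documented configuration: bands whose stain is in `centromere_stains` or
#' whose name matches `centromere_pattern` are labeled `centromere`; a span
#' of `telomere_span` bp at each chromosome end is labeled `telomere`; the
#' remainder of each chromosome is `arm`.
#'
#' @param bands A [read_cytoband()] table.
#' @param centromere_stains gieStain values treated as centromeric.
#' @param centromere_pattern Case-insensitive regex on band names treated
#'   as centromeric.
#' @param telomere_span Width in bp of the telomeric span at each
#'   chromosome end.
#' @return A `region_partition`: `data.frame` with `chrom`, `start`, `end`,
#'   `region` in `{arm, centromere, telomere}`, disjoint within chromosome.
#' @export
region_partition <- function(bands, centromere_stains = "acen",
                             centromere_pattern = "cen",
                             telomere_span = 200000L) {
  out <- lapply(split(bands, bands$chrom), function(b) {
    len <- max(b$end)
    cen <- b[b$gieStain %in% centromere_stains |
               grepl(centromere_pattern, b$name, ignore.case = TRUE), ,
             drop = FALSE]
    regions <- data.frame(chrom = b$chrom[1],
                          start = c(0L, max(0L, len - telomere_span)),
                          end = c(min(telomere_span, len), len),
                          region = "telomere", stringsAsFactors = FALSE)
    if (nrow(cen))
      regions <- rbind(regions,
                       data.frame(chrom = b$chrom[1], start = min(cen$start),
                                  end = max(cen$end), region = "centromere",
                                  stringsAsFactors = FALSE))
    regions
  })
  labeled <- rbind_all(out)
  structure(labeled, seqlengths = tapply(bands$end, bands$chrom, max),
            class = c("region_partition", "data.frame"))
}

# region of an interval midpoint: telomere/centromere label if inside one,
# else arm
region_of <- function(partition, chrom, mid) {
  region <- rep("arm", length(chrom))
  # centromere takes precedence over telomere if spans overlap
  for (lab in c("telomere", "centromere")) {
    p <- partition[partition$region == lab, , drop = FALSE]
    if (!nrow(p)) next
    for (i in seq_len(nrow(p))) {
      hit <- chrom == p$chrom[i] & mid >= p$start[i] & mid < p$end[i]
      region[hit] <- lab
    }
  }
  region
}

#' Compare DamID score distributions across chromosome regions
#'
#' Assigns every non-missing interval of a score track to the region
#' (arm / centromere / telomere) containing its midpoint and compares all
#' region pairs with the Wilcoxon rank-sum (Mann-Whitney U) test: exact
#' two-sided p for small untied samples, normal approximation with tie
#' correction otherwise.
#'
#' @param track A [score_track()] result.
#' @param partition A [region_partition()].
#' @param regions Region labels to compare (default all three).
#' @return List with `scores` (named list per region), `medians`, and
#'   `pairwise` (`data.frame`: region_a, region_b, U, p_value, exact).
#' @export
region_comparison <- function(track, partition,
                              regions = c("arm", "centromere", "telomere")) {
  ok <- !is.na(track$score)
  mid <- (track$start + track$end) / 2
  lab <- region_of(partition, track$chrom, mid)
  scores <- lapply(stats::setNames(regions, regions),
                   function(rg) track$score[ok & lab == rg])
  empty <- names(scores)[lengths(scores) == 0L]
  if (length(empty))
    stop("region(s) with no non-missing interval: ",
         paste(empty, collapse = ", "))
  pairs <- utils::combn(regions, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    mw <- mann_whitney(scores[[a]], scores[[b]])
    data.frame(region_a = a, region_b = b, U = mw$statistic,
               p_value = mw$p_value, exact = mw$exact,
               stringsAsFactors = FALSE)
  }))
  list(scores = scores,
       medians = vapply(scores, stats::median, numeric(1)),
       pairwise = pw)
}
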