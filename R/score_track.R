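#' Normalization settings for DamID scoring
#'
#' @param per_million Scale each count column to counts per million before
#'   forming ratios (default `TRUE`); the score is then invariant to library
#'   size.
#' @param pseudocount Pseudocount `c > 0` added, in scaled units, to both
#'   channels of every interval before taking `log2`.
#' @param missing_rule How an interval is declared missing. The default
#'   (`"zero_any_replicate"`) marks an interval missing when its raw counts
#'   are zero in both channels of any replicate; `"never"` disables missing
#'   marking.
#' @return A list of class `norm_config`.
#' @export
norm_config <- function(per_million = TRUE, pseudocount = 1,
                        missing_rule = c("zero_any_replicate", "never")) {
  stopifnot(pseudocount > 0)
  structure(list(per_million = per_million, pseudocount = pseudocount,
                 missing_rule = match.arg(missing_rule)),
            class = "norm_config")
}

# midpoint-based fragment -> uniform-bin assignment; returns bin index
# within chromosome given chromosome length and bin width
bin_of_midpoint <- function(start, end, width) {
  mid <- (start + end) / 2
  as.integer(floor(mid / width)) + 1L
}

# uniform bins tiling [0, len) per chromosome (terminal bin may be short)
make_bins <- function(seqlengths, width) {
  out <- lapply(names(seqlengths), function(chrom) {
    len <- seqlengths[[chrom]]
    starts <- seq(0L, len - 1L, by = width)
    data.frame(chrom = chrom, start = starts,
               end = pmin(starts + width, len), stringsAsFactors = FALSE)
  })
  rbind_all(out)
}

#' Compute a replicate-averaged log2(Dam-Lam/Dam) DamID score track
#'
#' The DamID score of an interval is `log2(Dam-Lam/Dam)`: methylation by the
#' lamin-tethered Dam fusion relative to freely diffusing Dam. Per replicate,
#' each count column is scaled to counts per million, fragment values are
#' summed into uniform bins by fragment midpoint (bin mode) or kept
#' per-fragment (binless mode), the ratio is formed with a pseudocount in
#' both channels, and the per-replicate log2 ratios are averaged
#' arithmetically across replicates. Intervals whose raw counts are zero in
#' both channels of any replicate are reported as missing (`NA` score),
#' which is what the downstream HMM marginalizes over.
#'
#' @param damlam,dam Lists of one-column [fragment_counts()] objects, one
#'   per biological replicate, in matching order. All tables must share one
#'   fragment set.
#' @param mode `"bins"` (uniform bins, default) or `"binless"`
#'   (per-fragment).
#' @param bin_width Bin width in bp for bin mode (default 100 kb).
#' @param norm A [norm_config()].
#' @return An object of class `score_track`: a `data.frame` with columns
#'   `chrom`, `start`, `end`, `score` plus attributes `resolution`
#'   (`"bins"`/`"binless"`), `replicate_scores` (matrix of per-replicate
#'   scores) and `seqlengths`.
#' @export
score_track <- function(damlam, dam, mode = c("bins", "binless"),
                        bin_width = 100000L, norm = norm_config()) {
  mode <- match.arg(mode)
  if (inherits(damlam, "fragment_counts")) damlam <- list(damlam)
  if (inherits(dam, "fragment_counts")) dam <- list(dam)
  if (length(damlam) != length(dam) || length(damlam) < 1L)
    stop("need >=1 replicate pair of Dam-Lam and Dam count tables")
  ref <- damlam[[1]]$fragments
  for (fc in c(damlam, dam)) {
    if (!identical(fc$fragments[c("chrom", "start", "end")],
                   ref[c("chrom", "start", "end")]))
      stop("all count tables must share one fragment set")
    if (sum(fc$counts) == 0)
      stop("a count column has zero total reads")
  }
  n_rep <- length(damlam)
  seqlengths <- damlam[[1]]$seqlengths

  if (mode == "bins") {
    bins <- make_bins(seqlengths, bin_width)
    n_bins_chrom <- table(factor(bins$chrom, levels = names(seqlengths)))
    offset <- stats::setNames(cumsum(c(0, n_bins_chrom[-length(n_bins_chrom)])),
                              names(seqlengths))
    frag_bin <- offset[ref$chrom] +
      bin_of_midpoint(ref$start, ref$end, bin_width)
    frag_bin[frag_bin < 1 | frag_bin > nrow(bins)] <- NA
    intervals <- bins
    aggregate_col <- function(x)
      as.vector(tapply(x, factor(frag_bin, levels = seq_len(nrow(bins))),
                       sum, default = 0))
  } else {
    intervals <- ref
    aggregate_col <- identity
  }

  c0 <- norm$pseudocount
  rep_scores <- matrix(NA_real_, nrow(intervals), n_rep)
  missing <- rep(FALSE, nrow(intervals))
  for (r in seq_len(n_rep)) {
    L_raw <- aggregate_col(as.numeric(damlam[[r]]$counts[, 1]))
    D_raw <- aggregate_col(as.numeric(dam[[r]]$counts[, 1]))
    if (norm$missing_rule == "zero_any_replicate")
      missing <- missing | (L_raw == 0 & D_raw == 0)
    L <- if (norm$per_million) L_raw * 1e6 / sum(damlam[[r]]$counts) else L_raw
    D <- if (norm$per_million) D_raw * 1e6 / sum(dam[[r]]$counts) else D_raw
    rep_scores[, r] <- log2((L + c0) / (D + c0))
  }
  score <- rowMeans(rep_scores)
  score[missing] <- NA_real_
  rep_scores[missing, ] <- NA_real_
  colnames(rep_scores) <- paste0("rep", seq_len(n_rep))

  structure(data.frame(intervals, score = score, stringsAsFactors = FALSE),
            resolution = mode, replicate_scores = rep_scores,
            seqlengths = seqlengths,
            class = c("score_track", "data.frame"))
}

#' Extract a single-replicate score track
#'
#' @param track A [score_track()] result fitted from >=1 replicates.
#' @param r Replicate index.
#' @return A `score_track` whose `score` column is the per-replicate score.
#' @export
replicate_track <- function(track, r) {
  rs <- attr(track, "replicate_scores")
  stopifnot(!is.null(rs), r >= 1, r <= ncol(rs))
  out <- track
  out$score <- rs[, r]
  attr(out, "replicate_scores") <- rs[, r, drop = FALSE]
  out
}

#' Pearson correlation between two replicate score tracks
#'
#' @param track_r1,track_r2 `score_track` objects over identical interval
#'   sets (e.g. from [replicate_track()]).
#' @return A list with `r` (Pearson correlation over intervals non-missing
#'   in both tracks) and `n_used`.
#' @export
replicate_correlation <- function(track_r1, track_r2) {
  if (!identical(track_r1[c("chrom", "start", "end")],
                 track_r2[c("chrom", "start", "end")]))
    stop("tracks must share an identical interval set")
  ok <- !is.na(track_r1$score) & !is.na(track_r2$score)
  if (sum(ok) < 3L)
    stop("fewer than 3 shared non-missing intervals")
  list(r = stats::cor(track_r1$score[ok], track_r2$score[ok]),
       n_used = sum(ok))
}
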