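#' Construct a per-fragment count table
#'
#' @param fragments `data.frame` with `chrom`, `start`, `end` (0-based,
#'   half-open GATC fragments).
#' @param counts Non-negative integer vector (one column) or matrix with one
#'   column per sample/replicate.
#' @param seqlengths Named integer vector of chromosome lengths.
#' @param unassigned Number of MAPQ-passing alignments that could not be
#'   assigned to a fragment (0 for synthetic tables).
#' @return An object of class `fragment_counts`.
#' @export
fragment_counts <- function(fragments, counts, seqlengths, unassigned = 0L) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == nrow(fragments), all(counts >= 0))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  structure(list(fragments = fragments, counts = counts,
                 seqlengths = seqlengths,
                 totals = colSums(counts), unassigned = unassigned),
            class = "fragment_counts")
}

#' @export
print.fragment_counts <- function(x, ...) {
  cat("Fragment counts:", nrow(x$fragments), "fragments x",
      ncol(x$counts), "column(s); totals:",
      paste(x$totals, collapse = ", "), "\n")
  invisible(x)
}

#' Read alignments from BAM or SAM
#'
#' Returns the minimal alignment table consumed by [count_fragments()]:
#' 0-based half-open reference intervals, strand and MAPQ. SAM input is
#' converted with [Rsamtools::asBam()] on the fly.
#'
#' @param path Path to a BAM or SAM file.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `mapq` (unmapped records dropped).
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "qwidth", "cigar", "strand", "mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  w <- cigar_ref_width(b$cigar, b$qwidth)
  data.frame(chrom = as.character(b$rname),
             start = b$pos - 1L,              # SAM pos is 1-based
             end = b$pos - 1L + w,
             strand = as.character(b$strand),
             mapq = b$mapq,
             stringsAsFactors = FALSE)
}

# reference span consumed by a CIGAR (M/D/N/=/X advance the reference)
cigar_ref_width <- function(cigar, qwidth) {
  ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)
  vapply(seq_along(cigar), function(i) {
    if (is.na(cigar[i]) || cigar[i] == "*") return(as.integer(qwidth[i]))
    m <- regmatches(cigar[i], ops[i])[[1]]
    n <- as.integer(sub("[MIDNSHP=X]", "", m))
    op <- sub("[0-9]+", "", m)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}

#' Count MAPQ-filtered alignments per GATC fragment
#'
#' Alignments with MAPQ <= 10 are excluded (the filter is strictly
#' "quality > 10"). In the default `anchored` mode a read is counted for the
#' fragment whose bounding motif coincides with the read's 5'-most aligned
#' base: a forward alignment whose start equals a motif start is assigned to
#' the fragment beginning at that motif, and a reverse alignment whose end
#' equals a motif start + 4 is assigned to the fragment ending at that motif
#' (the fragment the read extends into). Trimmed DamID reads begin with the
#' motif itself, so perfectly aligned reads always anchor. `containment`
#' mode instead assigns each read to the fragment containing its 5'-most
#' aligned base. Reads passing the MAPQ filter but assignable to no internal
#' fragment are tallied as `unassigned`.
#'
#' @param alignments `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`), `mapq`.
#' @param gatc_map A [build_gatc_map()] result.
#' @param mode `"anchored"` (default) or `"containment"`.
#' @param min_mapq Exclusive MAPQ threshold (reads kept when `mapq > min_mapq`).
#' @return A one-column [fragment_counts()] object; the `unassigned` field
#'   holds the tally of MAPQ-passing but unassignable reads.
#' @export
count_fragments <- function(alignments, gatc_map,
                            mode = c("anchored", "containment"),
                            min_mapq = 10L) {
  mode <- match.arg(mode)
  stopifnot(inherits(gatc_map, "gatc_map"))
  if (nrow(gatc_map$fragments) == 0L)
    stop("gatc_map contains no internal fragments")
  unknown <- setdiff(unique(alignments$chrom), names(gatc_map$sites))
  if (length(unknown))
    stop("alignments refer to chromosome(s) absent from the GATC map: ",
         paste(unknown, collapse = ", "))

  aln <- alignments[alignments$mapq > min_mapq, , drop = FALSE]
  frags <- gatc_map$fragments
  counts <- integer(nrow(frags))
  # per-chromosome fragment index by start
  frag_idx <- split(seq_len(nrow(frags)), frags$chrom)
  unassigned <- 0L

  for (chrom in unique(aln$chrom)) {
    a <- aln[aln$chrom == chrom, , drop = FALSE]
    s <- gatc_map$sites[[chrom]]
    fi <- frag_idx[[chrom]]
    if (is.null(fi) || length(s) < 2L) {
      unassigned <- unassigned + nrow(a)
      next
    }
    fstart <- frags$start[fi]
    if (mode == "anchored") {
      fwd <- a$strand != "-"
      # forward: alignment start at motif start -> fragment starting there
      i_fwd <- match(a$start[fwd], fstart)
      # reverse: alignment end at motif start + 4 -> fragment ending there
      fend <- frags$end[fi]
      i_rev <- match(a$end[!fwd] - 4L, fend)
      idx <- integer(nrow(a))
      idx[fwd] <- i_fwd
      idx[!fwd] <- i_rev
    } else {
      pos5 <- ifelse(a$strand != "-", a$start, a$end - 1L)
      idx <- findInterval(pos5, fstart)
      idx[idx == 0L] <- NA_integer_
      # last fragment is half-open; positions at/after the final motif start
      # but outside [last start, last end) are terminal
      fend <- frags$end[fi]
      idx[!is.na(idx) & pos5 >= fend[pmax(idx, 1L)]] <- NA_integer_
    }
    ok <- !is.na(idx)
    unassigned <- unassigned + sum(!ok)
    tab <- tabulate(idx[ok], nbins = length(fi))
    counts[fi] <- counts[fi] + tab
  }

  fragment_counts(frags, matrix(counts, ncol = 1),
                  gatc_map$seqlengths, unassigned = unassigned)
}

#' Write a fragment count table as TSV
#'
#' @param fc A [fragment_counts()] object.
#' @param path Output path.
#' @export
write_fragment_counts <- function(fc, path) {
  df <- cbind(fc$fragments, as.data.frame(fc$counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write intervals + values as bedGraph
#'
#' @param intervals `data.frame` with `chrom`, `start`, `end`.
#' @param values Numeric vector; `NA` intervals are skipped.
#' @param path Output path.
#' @param name Track name written in the header line.
#' @export
write_bedgraph <- function(intervals, values, path, name = "track") {
  keep <- !is.na(values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  utils::write.table(
    data.frame(intervals$chrom[keep], intervals$start[keep],
               intervals$end[keep], signif(values[keep], 7)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
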