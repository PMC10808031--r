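#' Locate GATC motifs and derive DamID fragments from a genome
#'
#' DamID methylation is deposited at GATC motifs, so the unit of DamID signal
#' is the genomic interval between two consecutive motifs. `build_gatc_map()`
#' scans each chromosome for every occurrence of `GATC` (the motif is its own
#' reverse complement, so a single forward scan suffices) and derives the
#' internal fragments as half-open intervals
#' `[motif_i_start, motif_{i+1}_start)`. The sub-motif stretches before the
#' first and after the last motif do not lie between two motifs; they are
#' recorded as terminal spans and excluded from fragment counting.
#'
#' @param genome A named character vector of chromosome sequences, or a
#'   [Biostrings::DNAStringSet]. Only `A`, `C`, `G`, `T` and `N` are allowed.
#' @return An object of class `gatc_map`: a list with
#'   \describe{
#'     \item{sites}{named list of 0-based motif start positions (sorted
#'       integer vectors), one per chromosome}
#'     \item{fragments}{`data.frame` with columns `chrom`, `start`, `end`
#'       (0-based, half-open) of the internal fragments}
#'     \item{seqlengths}{named integer vector of chromosome lengths}
#'   }
#' @examples
#' m <- build_gatc_map(c(toy = "AAGATCTTTTGATCAA"))
#' m$sites$toy        # 2 10
#' m$fragments        # one fragment [2, 10)
#' @export
build_gatc_map <- function(genome) {
  if (is.character(genome)) {
    if (is.null(names(genome)) || anyDuplicated(names(genome)))
      stop("genome must have unique chromosome names")
    bad <- grepl("[^ACGTNacgtn]", genome)
    if (any(bad))
      stop("non-DNA characters (other than N) in chromosome(s): ",
           paste(names(genome)[bad], collapse = ", "))
    genome <- Biostrings::DNAStringSet(toupper(genome))
  }
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a named character vector or DNAStringSet")
  if (any(Biostrings::width(genome) == 0L))
    stop("genome sequences must be non-empty")

  hits <- Biostrings::vmatchPattern("GATC", genome)
  sites <- lapply(seq_along(genome), function(i)
    as.integer(BiocGenerics::start(hits[[i]])) - 1L)  # 0-based
  names(sites) <- names(genome)

  frags <- lapply(names(sites), function(chrom) {
    s <- sites[[chrom]]
    if (length(s) < 2L) return(NULL)
    data.frame(chrom = chrom, start = s[-length(s)], end = s[-1L],
               stringsAsFactors = FALSE)
  })
  frags <- rbind_all(frags, template = empty_intervals())

  structure(list(sites = sites, fragments = frags,
                 seqlengths = stats::setNames(Biostrings::width(genome),
                                              names(genome))),
            class = "gatc_map")
}

#' @export
print.gatc_map <- function(x, ...) {
  cat("GATC map:", length(x$sites), "chromosome(s),",
      sum(lengths(x$sites)), "motifs,", nrow(x$fragments),
      "internal fragments\n")
  invisible(x)
}

#' Read a genome FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that keeps only the
#' first word of each FASTA header as the chromosome name.
#'
#' @param path Path to a FASTA file (plain or gzip-compressed).
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}
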