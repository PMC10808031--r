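#' Read a FASTQ file into a read table
#'
#' @param path Path to a FASTQ file (plain or gzip-compressed).
#' @return A `data.frame` with columns `id`, `sequence` and `quality`
#'   (Phred+33 encoded string, same length as `sequence`).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a read table to FASTQ
#'
#' @param reads A read table as returned by [read_fastq()].
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$sequence),
    Biostrings::PhredQuality(reads$quality))
  names(x) <- reads$id
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' DamID adaptor sequences
#'
#' The 17-nt DamID adaptor found at the 5' end of informative reads (its last
#' four bases are the GATC motif itself), and the reverse complement seen at
#' the 3' end of reads that run through the opposite adaptor.
#' @export
DAMID_ADAPTOR <- "GGTCGCGGCCGAGGATC"

#' @rdname DAMID_ADAPTOR
#' @export
DAMID_ADAPTOR_RC <- "GATCCTCGGCCGCGACC"

#' Select and trim adaptor-anchored DamID reads
#'
#' DamID amplicons carry a 17-nt adaptor at their 5' end whose final four
#' bases are the GATC motif; only mates that begin with this adaptor are
#' informative. Paired mates are split and treated as independent single
#' reads (mate 1 records first, then mate 2, each in input order). For each
#' retained read the first `head_trim` bases are removed, leaving the
#' adaptor's terminal `GATC` at the 5' end so the read aligns starting at a
#' genomic GATC motif. The 3' end is then quality-trimmed (trailing bases
#' with Phred quality below `qual_cut` are removed) and any 3' occurrence of
#' the complementary adaptor is cut off. Reads shorter than `min_len` are
#' discarded.
#'
#' An `N` base never matches the adaptor anchor (matching is exact).
#'
#' @param r1,r2 Read tables (columns `id`, `sequence`, `quality`); `r2` may
#'   be `NULL` for single-end input. Both mates of a pair must be present in
#'   equal number.
#' @param damid_adaptor 5' DamID adaptor (17 nt by default).
#' @param three_prime_adaptor Adaptor sequence removed from the 3' end.
#' @param head_trim Number of 5' bases removed from retained reads; must be
#'   smaller than `nchar(damid_adaptor)`.
#' @param min_len Minimum read length after trimming.
#' @param qual_cut Phred quality cutoff for 3' quality trimming.
#' @param min_adaptor_overlap Minimum length of a 3'-terminal partial
#'   adaptor match that is trimmed.
#' @return A read table of surviving trimmed reads, input order preserved.
#' @examples
#' r <- data.frame(id = "a",
#'   sequence = paste0(DAMID_ADAPTOR, "ACGTACGTACGTACGTACGTACGT"),
#'   quality = strrep("I", 41))
#' preprocess_reads(r)$sequence  # 28 nt, begins with GATC
#' @export
preprocess_reads <- function(r1, r2 = NULL,
                             damid_adaptor = DAMID_ADAPTOR,
                             three_prime_adaptor = DAMID_ADAPTOR_RC,
                             head_trim = 13L, min_len = 22L, qual_cut = 20L,
                             min_adaptor_overlap = 3L) {
  if (grepl("[^ACGT]", damid_adaptor) || grepl("[^ACGT]", three_prime_adaptor))
    stop("adaptors must be plain DNA (A/C/G/T)")
  if (head_trim >= nchar(damid_adaptor))
    stop("head_trim must be smaller than the DamID adaptor length")
  if (!is.null(r2) && nrow(r1) != nrow(r2))
    stop("mate files have different numbers of reads")

  reads <- if (is.null(r2)) r1 else rbind(r1, r2)
  if (nrow(reads) == 0L)
    return(reads)

  keep <- startsWith(reads$sequence, damid_adaptor)
  reads <- reads[keep, , drop = FALSE]
  if (nrow(reads) == 0L) return(reads)

  seqs <- substring(reads$sequence, head_trim + 1L)
  quals <- substring(reads$quality, head_trim + 1L)

  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    q <- quals[i]
    # 3' quality trim: drop trailing bases until quality >= cutoff
    ph <- utf8ToInt(q) - 33L
    n <- length(ph)
    while (n > 0L && ph[n] < qual_cut) n <- n - 1L
    s <- substr(s, 1L, n)
    q <- substr(q, 1L, n)
    # 3' adaptor removal: first full occurrence, else terminal partial match
    cut <- regexpr(three_prime_adaptor, s, fixed = TRUE)
    if (cut > 0L) {
      s <- substr(s, 1L, cut - 1L)
      q <- substr(q, 1L, cut - 1L)
    } else {
      len <- nchar(s)
      for (k in seq(min(nchar(three_prime_adaptor) - 1L, len),
                    min_adaptor_overlap)) {
        if (substr(s, len - k + 1L, len) ==
            substr(three_prime_adaptor, 1L, k)) {
          s <- substr(s, 1L, len - k)
          q <- substr(q, 1L, len - k)
          break
        }
      }
    }
    out[[i]] <- c(s, q)
  }
  seqs <- vapply(out, `[`, character(1), 1L)
  quals <- vapply(out, `[`, character(1), 2L)
  ok <- nchar(seqs) >= min_len
  data.frame(id = reads$id[ok], sequence = seqs[ok], quality = quals[ok],
             stringsAsFactors = FALSE, row.names = NULL)
}
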