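test_that("build_gatc_map records exactly the GATC motifs and internal fragments", {
  m <- build_gatc_map(c(toy = "AAGATCTTTTGATCAA"))
  expect_equal(m$sites$toy, c(2L, 10L))
  expect_equal(m$fragments$start, 2L)
  expect_equal(m$fragments$end, 10L)

  m2 <- build_gatc_map(c(a = "GATCGATC"))
  expect_equal(m2$sites$a, c(0L, 4L))
  expect_equal(m2$fragments$start, 0L)
  expect_equal(m2$fragments$end, 4L)

  m3 <- build_gatc_map(c(none = "AAAATTTTCCCC"))
  expect_length(m3$sites$none, 0)
  expect_equal(nrow(m3$fragments), 0L)

  expect_error(build_gatc_map(c(bad = "ACGTXXGATC")), "non-DNA")
})

test_that("build_gatc_map agrees with a regex scan oracle on random sequences", {
  set.seed(101)
  for (len in c(50, 500, 5000, 10000)) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    m <- build_gatc_map(c(chr = s))
    expect_equal(m$sites$chr, oracle_gatc_starts(s))
    if (length(m$sites$chr) >= 2) {
      # fragments tile the span between first and last motif
      expect_equal(m$fragments$start, utils::head(m$sites$chr, -1))
      expect_equal(m$fragments$end, m$sites$chr[-1])
    }
  }
})

test_that("preprocess_reads applies the anchor/trim/length rules", {
  r <- make_reads(paste0(DAMID_ADAPTOR, "ACGTACGTACGTACGTACGTACGT"))
  out <- preprocess_reads(r)
  expect_equal(out$sequence, "GATCACGTACGTACGTACGTACGTACGT")
  expect_equal(nchar(out$sequence), 28L)
  expect_equal(nchar(out$quality), 28L)

  # no adaptor anchor -> discarded
  out2 <- preprocess_reads(make_reads(strrep("T", 60)))
  expect_equal(nrow(out2), 0L)

  # adaptor + 10 nt -> post-trim 14 < 22 -> discarded
  out3 <- preprocess_reads(make_reads(paste0(DAMID_ADAPTOR, "ACGTACGTAC")))
  expect_equal(nrow(out3), 0L)

  # N never matches the anchor
  nread <- paste0("N", substr(DAMID_ADAPTOR, 2, 17), strrep("A", 30))
  expect_equal(nrow(preprocess_reads(make_reads(nread))), 0L)

  # empty input is not an error
  empty <- make_reads(character(0))
  expect_equal(nrow(preprocess_reads(empty)), 0L)

  # mismatched mate counts error
  expect_error(preprocess_reads(r, make_reads(character(0))), "mates|number")
})

test_that("preprocess_reads quality-trims the 3' end then removes the 3' adaptor", {
  genomic <- strrep("ACGT", 10)                       # 40 nt
  seq <- paste0(DAMID_ADAPTOR, genomic)
  qual <- paste0(strrep("I", 17 + 34), strrep("#", 6))  # last 6 bases Q2
  r <- data.frame(id = "q", sequence = seq, quality = qual)
  out <- preprocess_reads(r)
  expect_equal(nchar(out$sequence), 4 + 34)           # GATC + 34 kept

  # full 3' adaptor occurrence is removed
  seq2 <- paste0(DAMID_ADAPTOR, strrep("ACGT", 8), DAMID_ADAPTOR_RC, "TT")
  out2 <- preprocess_reads(make_reads(seq2))
  expect_equal(out2$sequence, paste0("GATC", strrep("ACGT", 8)))

  # survivors all begin with GATC and keep input order
  set.seed(11)
  seqs <- c(paste0(DAMID_ADAPTOR, strrep("A", 30)),
            strrep("C", 47),
            paste0(DAMID_ADAPTOR, strrep("G", 25)))
  out3 <- preprocess_reads(make_reads(seqs))
  expect_true(all(startsWith(out3$sequence, "GATC")))
  expect_equal(out3$id, c("r001", "r003"))
})

test_that("count_fragments enforces the strict MAPQ>10 filter and anchoring rules", {
  m <- build_gatc_map(c(toy = "AAGATCTTTTGATCAA"))
  aln <- data.frame(chrom = "toy",
                    start = c(2L, 2L, 2L, 10L),
                    end = c(10L, 10L, 14L, 14L),
                    strand = c("+", "+", "-", "-"),
                    mapq = c(60L, 10L, 60L, 60L))
  fc <- count_fragments(aln, m)
  # MAPQ=10 excluded; forward@2 -> [2,10); reverse ending at 14 (motif
  # [10,14)) -> fragment ending at 10, i.e. [2,10); reverse ending at 14
  # duplicated once more
  expect_equal(sum(fc$counts), 3L)
  expect_equal(unname(fc$counts[1, 1]), 3L)
  expect_equal(fc$unassigned, 0L)

  # unknown chromosome errors; empty map errors
  expect_error(count_fragments(data.frame(chrom = "zz", start = 0, end = 4,
                                          strand = "+", mapq = 60), m),
               "absent")
  m_empty <- build_gatc_map(c(x = "AAAA"))
  expect_error(count_fragments(aln, m_empty), "no internal fragments")
})

test_that("counts plus unassigned equals the number of MAPQ-passing alignments", {
  set.seed(21)
  g <- synth_genome(c(c1 = 4000, c2 = 3000), seed = 8)
  m <- build_gatc_map(g)
  starts <- unlist(lapply(names(m$sites), function(ch)
    sample(0:(m$seqlengths[[ch]] - 40), 60)))
  chroms <- rep(names(m$sites), each = 60)
  aln <- data.frame(chrom = chroms, start = starts, end = starts + 36L,
                    strand = sample(c("+", "-"), 120, replace = TRUE),
                    mapq = sample(c(0L, 10L, 11L, 60L), 120, replace = TRUE))
  for (mode in c("anchored", "containment")) {
    fc <- count_fragments(aln, m, mode = mode)
    expect_equal(sum(fc$counts) + fc$unassigned, sum(aln$mapq > 10L))
  }
})

test_that("containment mode assigns reads by 5'-end fragment membership", {
  m <- build_gatc_map(c(toy = "AAGATCTTTTGATCAA"))
  aln <- data.frame(chrom = "toy",
                    start = c(5L, 0L, 11L),
                    end = c(9L, 4L, 15L),
                    strand = "+",
                    mapq = 60L)
  fc <- count_fragments(aln, m, mode = "containment")
  # 5' base 5 inside [2,10); 5' base 0 before first motif; 5' base 11 in the
  # terminal region
  expect_equal(unname(fc$counts[1, 1]), 1L)
  expect_equal(fc$unassigned, 2L)
})

test_that("alignments round-trip through SAM via read_alignments", {
  sam <- file.path(tempdir(), "toy.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:toy\tLN:16",
    "r1\t0\ttoy\t3\t60\t8M\t*\t0\t0\tGATCTTTT\tIIIIIIII",
    "r2\t16\ttoy\t7\t60\t8M\t*\t0\t0\tTTTTGATC\tIIIIIIII",
    "r3\t0\ttoy\t3\t5\t8M\t*\t0\t0\tGATCTTTT\tIIIIIIII"), sam)
  aln <- read_alignments(sam)
  expect_equal(nrow(aln), 3L)
  expect_equal(aln$start, c(2L, 6L, 2L))
  expect_equal(aln$end, c(10L, 14L, 10L))
  expect_equal(aln$strand, c("+", "-", "+"))
  m <- build_gatc_map(c(toy = "AAGATCTTTTGATCAA"))
  fc <- count_fragments(aln, m)
  expect_equal(unname(fc$counts[1, 1]), 2L)   # r3 fails MAPQ; r1 fwd + r2 rev anchor
})

test_that("FASTQ writer and reader round-trip read tables", {
  r <- make_reads(c(paste0(DAMID_ADAPTOR, strrep("ACGT", 10)),
                    strrep("GATC", 12)))
  fq <- file.path(tempdir(), "toy.fastq")
  write_fastq(r, fq)
  back <- read_fastq(fq)
  expect_equal(back$sequence, r$sequence)
  expect_equal(back$quality, r$quality)
  expect_equal(back$id, r$id)
})
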