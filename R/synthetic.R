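## Seeded generators emulating the statistical structure of each pipeline
## input: DamID fragment counts with planted LADs, adaptor-bearing DamID
## reads, nuclear surface images with a tunable heterogeneity field, toy
## gene models, and force-deformation traces with known stiffnesses. Every
## generator is deterministic given (parameters, seed) and returns a truth
## object alongside the data.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' dm6-like toy chromosome arm lengths (120 Mb total)
#'
#' Five major arms scaled so that 100-kb binning yields ~1200 bins, the
#' desk-scale counterpart of the fly genome.
#' @export
TOY_CHROM_LENGTHS <- c(chr2L = 22e6, chr2R = 24e6, chr3L = 26e6,
                       chr3R = 28e6, chrX = 20e6)

#' Plant LAD intervals on a chromosome set
#'
#' Draws non-overlapping blocks aligned to `align` bp covering roughly
#' `coverage` of each chromosome, emulating the megabase-scale domain
#' blocks of a fly genome.
#'
#' @param chrom_lengths Named chromosome lengths.
#' @param coverage Target fraction of each chromosome inside LADs.
#' @param len_range Range of block lengths in bp (rounded to `align`).
#' @param align Alignment grid in bp (100 kb by default so that planted
#'   domains coincide with score bins).
#' @param seed Random seed.
#' @return Interval `data.frame` (`chrom`, `start`, `end`).
#' @export
plant_lads <- function(chrom_lengths, coverage = 0.3,
                       len_range = c(3e5, 12e5), align = 1e5, seed = 1L) {
  with_seed(seed, {
    out <- lapply(names(chrom_lengths), function(chrom) {
      len <- chrom_lengths[[chrom]]
      target <- coverage * len
      placed <- 0
      blocks <- list()
      cursor <- 0
      while (placed < target && cursor < len) {
        gap <- round(stats::runif(1, 2e5, 1.2e6) / align) * align
        w <- round(stats::runif(1, len_range[1], len_range[2]) / align) *
          align
        start <- cursor + gap
        if (start + w > len) break
        blocks[[length(blocks) + 1L]] <-
          data.frame(chrom = chrom, start = start, end = start + w)
        cursor <- start + w
        placed <- placed + w
      }
      rbind_all(blocks)
    })
    rbind_all(out, template = empty_intervals())
  })
}

#' Simulate DamID fragment counts with planted LADs
#'
#' GATC motif positions are drawn with exponential spacing; Dam counts are
#' negative-binomial around a uniform per-fragment rate; Dam-Lam counts are
#' negative-binomial with the rate scaled by `2^delta` per fragment, where
#' `delta` is `delta_in` inside a planted LAD (fragment midpoint rule) and
#' `delta_out` outside. Replicates are independent draws. The dispersion is
#' the negative-binomial overdispersion (`size = 1/dispersion`), emulating
#' sequencing count noise.
#'
#' @param chrom_lengths Named chromosome lengths.
#' @param mean_gatc_spacing Mean motif spacing in bp.
#' @param planted_lads Interval `data.frame`; defaults to
#'   [plant_lads()] on the same seed.
#' @param delta_in,delta_out Inside/outside log2 enrichments of the
#'   Dam-Lam channel (`delta_in > delta_out`).
#' @param dispersion Negative-binomial dispersion (0 = Poisson limit).
#' @param library_size Expected reads per count column.
#' @param replicates Number of biological replicates.
#' @param seed Random seed.
#' @return A list: `damlam` and `dam` (lists of one-column
#'   [fragment_counts()], one per replicate) and `truth` (class
#'   `sim_damid_truth`: planted intervals, per-fragment LAD membership,
#'   parameters, seed).
#' @export
synth_damid_counts <- function(chrom_lengths = TOY_CHROM_LENGTHS,
                               mean_gatc_spacing = 400,
                               planted_lads = NULL,
                               delta_in = 1.5, delta_out = -0.5,
                               dispersion = 0.2, library_size = 2e6,
                               replicates = 2L, seed = 1L) {
  stopifnot(delta_in > delta_out)
  if (is.null(planted_lads))
    planted_lads <- plant_lads(chrom_lengths, seed = seed)
  with_seed(seed + 1L, {
    frags <- lapply(names(chrom_lengths), function(chrom) {
      len <- chrom_lengths[[chrom]]
      n_exp <- ceiling(len / mean_gatc_spacing * 1.3) + 10
      pos <- cumsum(stats::rexp(n_exp, 1 / mean_gatc_spacing))
      pos <- floor(pos[pos < len - 4])
      data.frame(chrom = chrom, start = pos[-length(pos)], end = pos[-1])
    })
    frags <- rbind_all(frags)
    mid <- (frags$start + frags$end) / 2
    in_lad <- rep(FALSE, nrow(frags))
    for (i in seq_len(nrow(planted_lads))) {
      hit <- frags$chrom == planted_lads$chrom[i] &
        mid >= planted_lads$start[i] & mid < planted_lads$end[i]
      in_lad[in_lad | hit] <- TRUE
    }
    delta <- ifelse(in_lad, delta_in, delta_out)

    n <- nrow(frags)
    size <- if (dispersion > 0) 1 / dispersion else Inf
    draw <- function(rate) {
      mu <- rate / sum(rate) * library_size
      if (is.finite(size)) stats::rnbinom(n, mu = mu, size = size)
      else stats::rpois(n, mu)
    }
    dam <- vector("list", replicates)
    damlam <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      dam[[r]] <- fragment_counts(frags, draw(rep(1, n)), chrom_lengths)
      damlam[[r]] <- fragment_counts(frags, draw(2^delta), chrom_lengths)
      colnames(dam[[r]]$counts) <- paste0("Dam_rep", r)
      colnames(damlam[[r]]$counts) <- paste0("DamLam_rep", r)
    }
    truth <- structure(list(planted_lads = planted_lads,
                            fragment_in_lad = in_lad,
                            delta_in = delta_in, delta_out = delta_out,
                            dispersion = dispersion,
                            library_size = library_size,
                            replicates = replicates, seed = seed),
                       class = "sim_damid_truth")
    list(damlam = damlam, dam = dam, truth = truth)
  })
}

#' Bin-level F1 of called LADs against planted truth
#'
#' Both the called and the planted intervals are rasterized onto the
#' uniform bin grid of a score track (bin midpoint membership), and
#' precision/recall/F1 are computed over bins.
#'
#' @param lads Called `lad_set`.
#' @param planted Planted interval `data.frame`.
#' @param track The score track whose bins define the grid.
#' @return A list: `precision`, `recall`, `f1`, `n_bins`.
#' @export
lad_recovery_f1 <- function(lads, planted, track) {
  mid <- (track$start + track$end) / 2
  member <- function(set) {
    m <- rep(FALSE, nrow(track))
    for (i in seq_len(nrow(set))) {
      hit <- track$chrom == set$chrom[i] &
        mid >= set$start[i] & mid < set$end[i]
      m <- m | hit
    }
    m
  }
  called <- member(lads)
  truth <- member(planted)
  tp <- sum(called & truth)
  prec <- if (sum(called)) tp / sum(called) else NA_real_
  rec <- if (sum(truth)) tp / sum(truth) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  list(precision = prec, recall = rec, f1 = f1, n_bins = nrow(track))
}

#' Simulate a random genome with natural GATC motifs
#'
#' @param chrom_lengths Named chromosome lengths (small, e.g. kb-scale).
#' @param seed Random seed.
#' @return Named character vector of uppercase DNA.
#' @export
synth_genome <- function(chrom_lengths, seed = 1L) {
  with_seed(seed, {
    vapply(chrom_lengths, function(len)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), character(1))
  })
}

#' Generate adaptor-bearing DamID read pairs for a fragment count table
#'
#' Per fragment with count `c`, emits `floor(c/2)` read pairs whose two
#' mates carry the DamID adaptor and read inward from the two fragment
#' ends (mate 1 forward from the left motif, mate 2 reverse from the right
#' motif), plus, when `c` is odd, one pair whose second mate is a random
#' non-adaptor filler - emulating libraries in which the adaptor is present
#' in read 1 or read 2. After adaptor trimming every well-formed read
#' begins at a genomic GATC motif, so perfect alignment and anchored
#' counting reproduce the input counts exactly.
#'
#' @param counts A one-column [fragment_counts()] on `gatc_map`.
#' @param gatc_map [build_gatc_map()] of `genome`.
#' @param genome Named character vector of chromosome sequences.
#' @param adaptor DamID adaptor prepended to each informative mate.
#' @param read_length Raw read length in nt (reads over short fragments
#'   are truncated and flagged in the truth object).
#' @param seed Random seed (for filler mates only).
#' @return A list: `r1`, `r2` (read tables), `truth` (class
#'   `sim_fastq_truth`: `alignments` of the well-formed mates
#'   (`chrom`, `start`, `end`, `strand`, `mapq`), `n_adaptor_reads`,
#'   `truncated` fragment indices).
#' @export
synth_damid_fastq <- function(counts, gatc_map, genome,
                              adaptor = DAMID_ADAPTOR, read_length = 75L,
                              seed = 1L) {
  frags <- counts$fragments
  stopifnot(identical(frags, gatc_map$fragments))
  with_seed(seed, {
    r1 <- list(); r2 <- list(); aln <- list()
    truncated <- integer(0)
    gen_len <- read_length - nchar(adaptor)
    qual <- strrep("I", read_length)
    filler <- function() paste(sample(c("A", "C", "T"), read_length,
                                      replace = TRUE), collapse = "")
    k <- 0L
    for (i in seq_len(nrow(frags))) {
      cnt <- counts$counts[i, 1]
      if (cnt == 0) next
      chrom <- frags$chrom[i]
      s <- frags$start[i]; e <- frags$end[i]
      # genomic stretch available inward from each end (incl. far motif)
      avail <- e + 4L - s
      glen <- min(gen_len + 4L, avail)      # incl. the anchoring motif
      if (glen < gen_len + 4L) truncated <- c(truncated, i)
      fwd_seq <- substr(genome[[chrom]], s + 1L, s + glen)
      rev_seq <- revcomp(substr(genome[[chrom]], e + 4L - glen + 1L,
                                e + 4L))
      head13 <- substr(adaptor, 1L, nchar(adaptor) - 4L)
      n_pairs <- ceiling(cnt / 2)
      for (p in seq_len(n_pairs)) {
        k <- k + 1L
        id <- sprintf("frag%06d_p%03d", i, p)
        mate1 <- paste0(head13, fwd_seq)
        r1[[length(r1) + 1L]] <-
          data.frame(id = id, sequence = mate1,
                     quality = strrep("I", nchar(mate1)))
        aln[[length(aln) + 1L]] <-
          data.frame(chrom = chrom, start = s, end = s + glen,
                     strand = "+", mapq = 60L)
        both <- 2L * p <= cnt
        if (both) {
          mate2 <- paste0(head13, rev_seq)
          aln[[length(aln) + 1L]] <-
            data.frame(chrom = chrom, start = e + 4L - glen, end = e + 4L,
                       strand = "-", mapq = 60L)
        } else {
          mate2 <- filler()
        }
        r2[[length(r2) + 1L]] <-
          data.frame(id = id, sequence = mate2,
                     quality = strrep("I", nchar(mate2)))
      }
    }
    r1 <- rbind_all(r1)
    r2 <- rbind_all(r2)
    aln <- rbind_all(aln, template = data.frame(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), mapq = integer()))
    if (is.null(r1))
      r1 <- r2 <- data.frame(id = character(), sequence = character(),
                             quality = character())
    n_adaptor <- sum(counts$counts)
    truth <- structure(list(alignments = aln, n_adaptor_reads = n_adaptor,
                            truncated = unique(truncated), seed = seed),
                       class = "sim_fastq_truth")
    list(r1 = r1, r2 = r2, truth = truth)
  })
}

revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Exactly align trimmed reads to a small genome
#'
#' A perfect aligner for synthetic round trips: each read is located by
#' exact string matching on both strands. Reads with no or multiple
#' matches get MAPQ 0; unique matches get MAPQ 60.
#'
#' @param reads Read table (trimmed reads beginning with GATC).
#' @param genome Named character vector of chromosome sequences.
#' @return Alignment `data.frame` (`chrom`, `start`, `end`, `strand`,
#'   `mapq`), one row per read with at least one match.
#' @export
align_exact <- function(reads, genome) {
  subject <- Biostrings::DNAStringSet(toupper(unlist(genome)))
  names(subject) <- names(genome)
  out <- list()
  for (i in seq_len(nrow(reads))) {
    seqf <- reads$sequence[i]
    hits <- list()
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") seqf else revcomp(seqf)
      m <- Biostrings::vmatchPattern(pat, subject)
      for (ch in names(subject)) {
        st <- BiocGenerics::start(m[[match(ch, names(subject))]])
        for (s1 in st)
          hits[[length(hits) + 1L]] <-
            data.frame(chrom = ch, start = s1 - 1L,
                       end = s1 - 1L + nchar(seqf), strand = strand,
                       mapq = 60L)
      }
    }
    if (!length(hits)) next
    h <- do.call(rbind, hits)
    if (nrow(h) > 1L) h$mapq <- 0L
    out[[length(out) + 1L]] <- h
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      mapq = integer()))
  rbind_all(out)
}

# separable Gaussian smoothing with edge replication
gaussian_smooth <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(x) {            # rows convolved
    nr <- nrow(x)
    out <- matrix(0, nr, ncol(x))
    for (j in -r:r) {
      ri <- pmin(pmax(seq_len(nr) + j, 1L), nr)
      out <- out + k[j + r + 1L] * x[ri, , drop = FALSE]
    }
    out
  }
  t(pad_conv(t(pad_conv(m))))
}

#' Simulate a nuclear-surface image with tunable heterogeneity
#'
#' Nuclei are filled ellipses of base intensity `base` on a zero
#' background (the en-face view of the nuclear-envelope sheet). Inside
#' each nucleus the intensity is multiplied by `exp(h * G)` where `G` is a
#' Gaussian-smoothed, unit-variance random field with correlation length
#' `blob_scale` pixels; `h = 0` gives a perfectly homogeneous envelope and
#' increasing `h` gives increasingly heterogeneous (patchy) signal, so the
#' D.I. grows monotonically with `h`. Gaussian read noise of SD `noise_sd`
#' is added everywhere and intensities clipped at zero.
#'
#' @param n_nuclei Number of nuclei.
#' @param size Canvas size in pixels (square).
#' @param radius_range Ellipse semi-axis range in pixels (default 38-46 so
#'   nuclei still pass the macro's 30-um^2 particle filter after the
#'   5-pixel ROI erosion at 0.1 um pixels).
#' @param base Base intensity of the envelope signal.
#' @param h Heterogeneity amplitude (>= 0).
#' @param blob_scale Smoothing sigma of the heterogeneity field, pixels.
#' @param noise_sd Additive Gaussian noise SD.
#' @param pixel_size Pixel edge length in micrometers.
#' @param margin Minimum distance of nucleus bounding boxes from the
#'   border, pixels.
#' @param max_tries Placement rejection retries before failing.
#' @param seed Random seed.
#' @return A list: `image` (matrix) and `truth` (class `sim_image_truth`:
#'   `masks` (list of logical matrices), `h`, `base`, `noise_sd`,
#'   `pixel_size`, `seed`).
#' @export
synth_nucleus_image <- function(n_nuclei = 3L, size = 300L,
                                radius_range = c(38, 46), base = 100,
                                h = 0.3, blob_scale = 5, noise_sd = 2,
                                pixel_size = 0.1, margin = 6L,
                                max_tries = 500L, seed = 1L) {
  stopifnot(h >= 0)
  with_seed(seed, {
    centers <- list()
    radii <- list()
    for (i in seq_len(n_nuclei)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        rx <- stats::runif(1, radius_range[1], radius_range[2])
        ry <- stats::runif(1, radius_range[1], radius_range[2])
        cx <- stats::runif(1, margin + rx + 1, size - margin - rx)
        cy <- stats::runif(1, margin + ry + 1, size - margin - ry)
        ok <- TRUE
        for (j in seq_along(centers)) {
          d <- sqrt((cx - centers[[j]][1])^2 + (cy - centers[[j]][2])^2)
          if (d < rx + radii[[j]][1] + 2 * margin) { ok <- FALSE; break }
        }
        if (ok) {
          centers[[i]] <- c(cx, cy)
          radii[[i]] <- c(max(rx, ry), rx, ry)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place ", n_nuclei, " nuclei without overlap")
    }
    xs <- matrix(rep(seq_len(size), each = size), size, size)  # column = x
    ys <- matrix(rep(seq_len(size), times = size), size, size) # row = y
    img <- matrix(0, size, size)
    masks <- vector("list", n_nuclei)
    for (i in seq_len(n_nuclei)) {
      cx <- centers[[i]][1]; cy <- centers[[i]][2]
      rx <- radii[[i]][2]; ry <- radii[[i]][3]
      inside <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
      masks[[i]] <- inside
      field <- gaussian_smooth(matrix(stats::rnorm(size * size), size),
                               blob_scale)
      field <- (field - mean(field)) / stats::sd(field)
      img[inside] <- base * exp(h * field[inside])
    }
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(size * size, sd = noise_sd), size)
    img <- pmax(img, 0)
    truth <- structure(list(masks = masks, h = h, base = base,
                            noise_sd = noise_sd, pixel_size = pixel_size,
                            seed = seed),
                       class = "sim_image_truth")
    list(image = img, truth = truth)
  })
}

#' Simulate a toy gene model (plus GFF3 export)
#'
#' Genes are placed left to right with intergenic gaps; each has 2-4 exons
#' with intron gaps. Coding genes carry a CDS spanning the interior exons
#' with a 5'UTR at the start of the first exon and a 3'UTR at the end of
#' the last; a stated fraction of genes lack any CDS (non-coding). All
#' structural identities (introns = exon gaps, features within gene body)
#' hold by construction.
#'
#' @param n_genes Number of genes.
#' @param chrom Chromosome name.
#' @param exon_count_range Exons per gene (inclusive range).
#' @param exon_len_range,intron_len_range,gap_range Length ranges, bp.
#' @param utr_len 5'/3' UTR length within terminal exons, bp.
#' @param noncoding_fraction Fraction of genes without CDS.
#' @param gff3_path Optional path; when given the model is also written as
#'   GFF3.
#' @param seed Random seed.
#' @return A list: `model` (a [gene_model()]), `chrom_length`, and
#'   `gff3_path` (or `NULL`).
#' @export
synth_gene_model <- function(n_genes = 10L, chrom = "chr2L",
                             exon_count_range = c(2L, 4L),
                             exon_len_range = c(300L, 800L),
                             intron_len_range = c(200L, 600L),
                             gap_range = c(500L, 2000L),
                             utr_len = 100L, noncoding_fraction = 0.2,
                             gff3_path = NULL, seed = 1L) {
  with_seed(seed, {
    cursor <- 1000L
    genes <- list(); feats <- list()
    n_noncoding <- round(noncoding_fraction * n_genes)
    coding_flag <- sample(rep(c(FALSE, TRUE),
                              c(n_noncoding, n_genes - n_noncoding)))
    for (g in seq_len(n_genes)) {
      gid <- sprintf("gene%03d", g)
      tid <- sprintf("tx%03d", g)
      strand <- sample(c("+", "-"), 1)
      n_ex <- sample(exon_count_range[1]:exon_count_range[2], 1)
      exon_starts <- integer(n_ex); exon_ends <- integer(n_ex)
      p <- cursor + sample(gap_range[1]:gap_range[2], 1)
      for (e in seq_len(n_ex)) {
        w <- sample(exon_len_range[1]:exon_len_range[2], 1)
        exon_starts[e] <- p
        exon_ends[e] <- p + w - 1L
        p <- exon_ends[e] + 1L +
          if (e < n_ex) sample(intron_len_range[1]:intron_len_range[2], 1)
          else 0L
      }
      gene_start <- exon_starts[1]; gene_end <- exon_ends[n_ex]
      cursor <- gene_end
      genes[[g]] <- data.frame(gid = gid, tid = tid, strand = strand,
                               start = gene_start, end = gene_end,
                               coding = coding_flag[g])
      add <- function(type, s, e)
        feats[[length(feats) + 1L]] <<-
          data.frame(chrom = chrom, start = s, end = e, type = type,
                     gid = gid, tid = tid, strand = strand)
      for (e in seq_len(n_ex)) add("exon", exon_starts[e], exon_ends[e])
      if (coding_flag[g]) {
        # 5'UTR at transcription start, 3'UTR at transcription end
        utr5_exon <- if (strand == "+") 1L else n_ex
        utr3_exon <- if (strand == "+") n_ex else 1L
        if (strand == "+") {
          add("five_prime_UTR", exon_starts[1], exon_starts[1] + utr_len - 1L)
          add("three_prime_UTR", exon_ends[n_ex] - utr_len + 1L,
              exon_ends[n_ex])
          cds_s <- exon_starts[1] + utr_len
          cds_e <- exon_ends[n_ex] - utr_len
        } else {
          add("five_prime_UTR", exon_ends[n_ex] - utr_len + 1L,
              exon_ends[n_ex])
          add("three_prime_UTR", exon_starts[1], exon_starts[1] + utr_len - 1L)
          cds_s <- exon_starts[1] + utr_len
          cds_e <- exon_ends[n_ex] - utr_len
        }
        for (e in seq_len(n_ex)) {
          s <- max(exon_starts[e], cds_s)
          en <- min(exon_ends[e], cds_e)
          if (s <= en) add("CDS", s, en)
        }
      }
    }
    chrom_length <- cursor + 5000L
    genes_df <- do.call(rbind, genes)
    feats_df <- do.call(rbind, feats)

    gr_genes <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(genes_df$start, genes_df$end),
      strand = genes_df$strand)
    gr_genes$gene_id <- genes_df$gid
    gr_genes$coding <- genes_df$coding

    type_map <- c(exon = "exon", CDS = "CDS",
                  five_prime_UTR = "five_UTR",
                  three_prime_UTR = "three_UTR")
    gr_feats <- GenomicRanges::GRanges(
      feats_df$chrom, IRanges::IRanges(feats_df$start, feats_df$end),
      strand = feats_df$strand)
    gr_feats$type <- unname(type_map[feats_df$type])
    gr_feats$gene_id <- feats_df$gid
    gr_feats$transcript_id <- feats_df$tid
    # derive introns as exon gaps
    introns <- list()
    for (g in seq_len(n_genes)) {
      ex <- feats_df[feats_df$gid == genes_df$gid[g] &
                       feats_df$type == "exon", ]
      if (nrow(ex) > 1L) {
        ex <- ex[order(ex$start), ]
        for (e in seq_len(nrow(ex) - 1L))
          introns[[length(introns) + 1L]] <-
            data.frame(chrom = chrom, start = ex$end[e] + 1L,
                       end = ex$start[e + 1L] - 1L,
                       gid = genes_df$gid[g], tid = genes_df$tid[g],
                       strand = genes_df$strand[g])
      }
    }
    if (length(introns)) {
      idf <- do.call(rbind, introns)
      gi <- GenomicRanges::GRanges(idf$chrom,
                                   IRanges::IRanges(idf$start, idf$end),
                                   strand = idf$strand)
      gi$type <- "intron"
      gi$gene_id <- idf$gid
      gi$transcript_id <- idf$tid
      gr_feats <- c(gr_feats, gi)
    }
    model <- gene_model(gr_genes, gr_feats)

    if (!is.null(gff3_path)) {
      lines <- c("##gff-version 3")
      for (g in seq_len(n_genes)) {
        gd <- genes_df[g, ]
        lines <- c(lines, sprintf(
          "%s\tsynth\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
          chrom, gd$start, gd$end, gd$strand, gd$gid), sprintf(
          "%s\tsynth\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
          chrom, if (gd$coding) "mRNA" else "ncRNA", gd$start, gd$end,
          gd$strand, gd$tid, gd$gid))
        fg <- feats_df[feats_df$gid == gd$gid, ]
        for (r in seq_len(nrow(fg)))
          lines <- c(lines, sprintf(
            "%s\tsynth\t%s\t%d\t%d\t.\t%s\t%s\tParent=%s",
            chrom, fg$type[r], fg$start[r], fg$end[r], fg$strand[r],
            if (fg$type[r] == "CDS") "0" else ".", fg$tid[r]))
      }
      writeLines(lines, gff3_path)
    }
    list(model = model, chrom_length = chrom_length, gff3_path = gff3_path)
  })
}

#' Simulate paired microneedle traces with known stiffnesses
#'
#' Generates a `"nucleus+cell"` trace whose force-deformation slope is
#' `k_nucleus + k_cell` and a matched `"cell only"` trace with slope
#' `k_cell`. Each press cycle has pre-press baseline frames, a loading
#' ramp, a plateau of `plateau_frames` frames at the target deformation
#' (where tip deflection = slope x deformation / `k_tip`), and a release
#' ramp back to baseline. Gaussian noise of SD `noise_sd` is added to the
#' span and tip-displacement channels.
#'
#' @param k_nucleus,k_cell True nuclear and non-nuclear stiffness, nN/um.
#' @param k_tip Calibrated tip stiffness, nN/um.
#' @param cycle_magnitudes Target deformations of successive cycles, um.
#' @param baseline_span Resting nuclear span, um.
#' @param dt Frame interval, s.
#' @param baseline_frames,ramp_frames,plateau_frames Frames per phase.
#' @param noise_sd Gaussian noise SD on span and tip displacement, um.
#' @param seed Random seed.
#' @return A list: `total` and `cell_only` ([manipulation_trace()]s) and
#'   `truth` (class `sim_trace_truth`).
#' @export
synth_force_trace <- function(k_nucleus = 4.0, k_cell = 0.7, k_tip = 12.0,
                              cycle_magnitudes = 1:7,
                              baseline_span = 20, dt = 0.5,
                              baseline_frames = 4L, ramp_frames = 3L,
                              plateau_frames = 8L, noise_sd = 0,
                              seed = 1L) {
  stopifnot(k_nucleus > 0, k_cell > 0, k_tip > 0)
  build <- function(slope, condition, seed_off) {
    span <- numeric(0); tip <- numeric(0)
    cyc_start <- integer(0); cyc_end <- integer(0)
    for (d in cycle_magnitudes) {
      cyc_start <- c(cyc_start, length(span) + 1L)
      span <- c(span, rep(baseline_span, baseline_frames))
      tip <- c(tip, rep(0, baseline_frames))
      ramp <- seq_len(ramp_frames) / ramp_frames
      span <- c(span, baseline_span - d * ramp)
      tip <- c(tip, slope * d * ramp / k_tip)
      span <- c(span, rep(baseline_span - d, plateau_frames))
      tip <- c(tip, rep(slope * d / k_tip, plateau_frames))
      cyc_end <- c(cyc_end, length(span))
      span <- c(span, baseline_span - d * rev(ramp)[-1], baseline_span)
      tip <- c(tip, slope * d * rev(ramp)[-1] / k_tip, 0)
      # post-release settle frames so elastic recovery is measurable
      span <- c(span, rep(baseline_span, baseline_frames))
      tip <- c(tip, rep(0, baseline_frames))
    }
    n <- length(span)
    if (noise_sd > 0) {
      with_seed(seed + seed_off, {
        span <- span + stats::rnorm(n, sd = noise_sd)
        tip <- tip + stats::rnorm(n, sd = noise_sd)
      })
    }
    manipulation_trace(time_s = seq_len(n) * dt - dt, tip_disp_um = tip,
                       span_um = span, k_tip = k_tip,
                       condition = condition,
                       cycles = data.frame(start = cyc_start,
                                           end = cyc_end))
  }
  total <- build(k_nucleus + k_cell, "nucleus+cell", 0L)
  cell <- build(k_cell, "cell only", 1000L)
  truth <- structure(list(k_nucleus = k_nucleus, k_cell = k_cell,
                          k_tip = k_tip,
                          cycle_magnitudes = cycle_magnitudes,
                          noise_sd = noise_sd, seed = seed),
                     class = "sim_trace_truth")
  list(total = total, cell_only = cell, truth = truth)
}
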