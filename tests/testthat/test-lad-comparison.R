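iv <- function(starts, ends, chrom = "c") {
  lad_set(data.frame(chrom = chrom, start = starts, end = ends))
}

test_that("classify_lads handles identity, disjoint, and overlap cases", {
  s5 <- iv((0:4) * 1000, (0:4) * 1000 + 400)
  id <- classify_lads(s5, s5)
  expect_equal(unname(id$counts), c(5L, 0L, 0L))

  a <- iv(c(0, 1000, 2000), c(400, 1400, 2400))
  b <- iv(c(500, 1500, 2500, 3500), c(900, 1900, 2900, 3900))
  dis <- classify_lads(a, b)
  expect_equal(unname(dis$counts), c(0L, 3L, 4L))

  wt <- iv(0, 10)
  mut <- iv(c(5, 20), c(15, 30))
  mix <- classify_lads(wt, mut)
  expect_equal(unname(mix$counts["cLAD"]), 1L)
  expect_equal(unname(mix$counts["fLAD"]), 0L)
  expect_equal(unname(mix$counts["fiLAD"]), 1L)
  expect_equal(unname(mix$clad_count_by_basis["mut"]), 1L)

  # overlapping intervals within one input set are rejected
  expect_error(classify_lads(
    data.frame(chrom = "c", start = c(0, 5), end = c(10, 15)), mut),
    "overlap")
})

test_that("min_overlap controls the overlap criterion", {
  wt <- iv(0, 100)
  mut <- iv(99, 300)       # 1 bp overlap
  expect_equal(unname(classify_lads(wt, mut)$counts["cLAD"]), 1L)
  expect_equal(unname(classify_lads(wt, mut, min_overlap = 2)$counts["cLAD"]),
               0L)
})

test_that("classification identities hold on random interval sets", {
  set.seed(31)
  random_set <- function() {
    n <- sample(3:12, 1)
    starts <- sort(sample(seq(0, 1e6, by = 1000), n))
    ends <- starts + sample(seq(200, 900, by = 100), n, replace = TRUE)
    ends <- pmin(ends, c(starts[-1], 1.1e6))  # keep disjoint
    keep <- ends > starts
    iv(starts[keep], ends[keep])
  }
  for (k in 1:100) {
    wt <- random_set(); mut <- random_set()
    cl <- classify_lads(wt, mut)
    expect_equal(unname(cl$counts["fLAD"] + cl$counts["cLAD"]), nrow(wt))
    expect_equal(unname(cl$counts["fiLAD"] +
                          cl$clad_count_by_basis[["mut"]]), nrow(mut))
    # symmetry: swapping inputs exchanges fLAD and fiLAD
    sw <- classify_lads(mut, wt)
    expect_equal(unname(sw$counts["fLAD"]), unname(cl$counts["fiLAD"]))
    expect_equal(unname(sw$counts["fiLAD"]), unname(cl$counts["fLAD"]))
  }
})

test_that("annotate_lads assigns macro feature combinations on a toy gene model", {
  g <- synth_gene_model(n_genes = 10, noncoding_fraction = 0.3, seed = 5)
  model <- g$model
  genes <- model$genes
  feats <- model$features

  # a LAD strictly between two gene bodies
  gaps <- GenomicRanges::gaps(GenomicRanges::reduce(genes,
                                                    ignore.strand = TRUE))
  gaps <- gaps[BiocGenerics::strand(gaps) == "*" &
                 BiocGenerics::width(gaps) > 50]
  gap <- gaps[2]
  lad1 <- data.frame(chrom = "chr2L",
                     start = BiocGenerics::start(gap) + 9,
                     end = BiocGenerics::start(gap) + 29)
  a1 <- annotate_lads(lad1, model)
  expect_equal(a1$per_lad$combination, "inter_gene")

  # a LAD strictly inside one intron of a coding gene
  intr <- feats[feats$type == "intron" &
                  feats$gene_id %in% genes$gene_id[genes$coding]]
  intr <- intr[BiocGenerics::width(intr) > 50][1]
  lad2 <- data.frame(chrom = "chr2L",
                     start = BiocGenerics::start(intr) + 4,
                     end = BiocGenerics::start(intr) + 24)
  a2 <- annotate_lads(lad2, model)
  expect_equal(a2$per_lad$combination, "intron")

  # a LAD spanning a CDS-exon/intron junction (every intron of a coding
  # gene borders CDS on its left in this construction: terminal UTRs are
  # short interior segments of long exons)
  junction <- BiocGenerics::start(intr[1])
  lad3 <- data.frame(chrom = "chr2L", start = junction - 10,
                     end = junction + 10)
  a3 <- annotate_lads(lad3, model)
  expect_setequal(strsplit(a3$per_lad$combination, "+", fixed = TRUE)[[1]],
                  c("intron", "CDS"))

  # chromosome absent from the model errors
  expect_error(annotate_lads(data.frame(chrom = "chrZ", start = 0, end = 10),
                             model), "chrZ")
})

test_that("every LAD on a fully annotated toy genome gets a non-empty combination", {
  g <- synth_gene_model(n_genes = 12, noncoding_fraction = 0.25, seed = 8)
  set.seed(8)
  starts <- sort(sample(seq(0, g$chrom_length - 2000, by = 500), 20))
  lads <- data.frame(chrom = "chr2L", start = starts, end = starts + 1500)
  lads <- lads[c(TRUE, diff(starts) > 1500), ]
  ann <- annotate_lads(lads, g$model)
  expect_true(all(nchar(ann$per_lad$combination) > 0))
  expect_equal(sum(ann$combinations$count), nrow(lads))
})

test_that("genes_in_lads honors the overlap rule", {
  g <- synth_gene_model(n_genes = 6, seed = 3)
  genes <- g$model$genes
  g1 <- genes[1]
  s <- BiocGenerics::start(g1); e <- BiocGenerics::end(g1)

  expect_equal(genes_in_lads(data.frame(chrom = character(),
                                        start = integer(),
                                        end = integer()), g$model),
               character(0))

  # gene fully inside a LAD: included under both rules
  big <- data.frame(chrom = "chr2L", start = s - 100, end = e + 100)
  expect_true(g1$gene_id %in% genes_in_lads(big, g$model))
  expect_true(g1$gene_id %in% genes_in_lads(big, g$model, "containment"))

  # 1 bp overlap: any_overlap yes, containment no
  one <- data.frame(chrom = "chr2L", start = s - 1 - 50, end = s)
  expect_true(g1$gene_id %in% genes_in_lads(one, g$model))
  expect_false(g1$gene_id %in% genes_in_lads(one, g$model, "containment"))

  # ids are unique and sorted
  ids <- genes_in_lads(data.frame(chrom = "chr2L", start = 0,
                                  end = g$chrom_length), g$model)
  expect_equal(ids, sort(unique(ids)))
  expect_equal(length(ids), 6L)
})

test_that("synthetic gene models satisfy structural identities and round-trip GFF3", {
  gff <- file.path(tempdir(), "toy_model.gff3")
  g <- synth_gene_model(n_genes = 9, noncoding_fraction = 0.3,
                        gff3_path = gff, seed = 12)
  feats <- g$model$features
  for (gid in g$model$genes$gene_id) {
    n_ex <- sum(feats$type == "exon" & feats$gene_id == gid)
    n_in <- sum(feats$type == "intron" & feats$gene_id == gid)
    expect_equal(n_in, n_ex - 1L)
  }
  # introns never overlap exons of the same transcript
  ex <- feats[feats$type == "exon"]
  intr <- feats[feats$type == "intron"]
  ov <- IRanges::findOverlaps(intr, ex)
  same_tx <- intr$transcript_id[S4Vectors::queryHits(ov)] ==
    ex$transcript_id[S4Vectors::subjectHits(ov)]
  expect_false(any(same_tx))

  back <- read_gene_model(gff)
  expect_equal(length(back$genes), length(g$model$genes))
  expect_equal(sort(back$genes$gene_id), sort(g$model$genes$gene_id))
  expect_equal(sum(back$genes$coding), sum(g$model$genes$coding))
  expect_equal(sum(back$features$type == "intron"),
               sum(feats$type == "intron"))
  # annotation agrees between generated and re-imported models
  lad <- data.frame(chrom = "chr2L", start = 0, end = g$chrom_length)
  a1 <- annotate_lads(lad, g$model)
  a2 <- annotate_lads(lad, back)
  expect_equal(a1$per_lad$combination, a2$per_lad$combination)
})
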