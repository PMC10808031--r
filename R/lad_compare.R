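lads_to_granges <- function(lads) {
  GenomicRanges::GRanges(lads$chrom,
                         IRanges::IRanges(lads$start + 1L, lads$end))
}

granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             stringsAsFactors = FALSE)
}

#' Classify LADs between two genotypes into cLAD / fLAD / fiLAD
#'
#' Using any overlap of at least `min_overlap` bp: a WT LAD overlapping no
#' mutant LAD is an fLAD (lost in the mutant); a mutant LAD overlapping no
#' WT LAD is an fiLAD (ectopic in the mutant); LADs shared by both
#' genotypes are cLADs. The cLAD count depends on the counting basis; the
#' default counts WT LADs with mutant overlap (`wt` basis), and the mutant
#' basis and the merged-intersection basis (number of intervals in the
#' intersection of the two sets) are always reported alongside.
#'
#' @param wt,mut `lad_set` objects on the same assembly.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return A list of class `lad_classification`:
#'   `clad_count` (WT basis), `clad_count_by_basis` (named vector: wt, mut,
#'   merged_intersection), `clad` / `flad` / `filad` interval data.frames,
#'   and `counts` (named vector cLAD/fLAD/fiLAD, cLAD on the WT basis).
#' @export
classify_lads <- function(wt, mut, min_overlap = 1L) {
  wt <- lad_set(as.data.frame(wt))    # validates non-overlap
  mut <- lad_set(as.data.frame(mut))
  gw <- lads_to_granges(wt)
  gm <- lads_to_granges(mut)
  wt_hit <- IRanges::overlapsAny(gw, gm, minoverlap = min_overlap)
  mut_hit <- IRanges::overlapsAny(gm, gw, minoverlap = min_overlap)
  inter <- GenomicRanges::reduce(GenomicRanges::intersect(gw, gm))
  inter <- inter[BiocGenerics::width(inter) >= min_overlap]
  basis <- c(wt = sum(wt_hit), mut = sum(mut_hit),
             merged_intersection = length(inter))
  out <- list(
    clad_count = unname(basis["wt"]),
    clad_count_by_basis = basis,
    clad = as.data.frame(wt)[wt_hit, , drop = FALSE],
    flad = as.data.frame(wt)[!wt_hit, , drop = FALSE],
    filad = as.data.frame(mut)[!mut_hit, , drop = FALSE],
    counts = c(cLAD = unname(basis["wt"]), fLAD = sum(!wt_hit),
               fiLAD = sum(!mut_hit)))
  class(out) <- "lad_classification"
  out
}

#' @export
print.lad_classification <- function(x, ...) {
  cat("LAD classification: cLAD", x$counts["cLAD"], "(WT basis), fLAD",
      x$counts["fLAD"], ", fiLAD", x$counts["fiLAD"], "\n")
  invisible(x)
}

#' Annotate LADs with overlapped gene-model feature combinations
#'
#' Each LAD receives the set of feature categories it touches:
#' `intron`, `CDS`, `5UTR`, `3UTR` when it overlaps at least 1 bp of that
#' feature in any transcript; `inter_gene` when at least 1 bp of the LAD
#' lies outside all gene bodies; `no_CDS` when it overlaps at least one
#' gene without any coding sequence (a non-coding gene). Combinations are
#' aggregated into an UpSet-style count table.
#'
#' @param lads A `lad_set` (or interval data.frame).
#' @param genes A `gene_model` (see [read_gene_model()] /
#'   [synth_gene_model()]).
#' @return A list with `per_lad` (`data.frame`: interval columns plus
#'   `combination`, a `+`-joined sorted label) and `combinations`
#'   (`data.frame`: `combination`, `count`, decreasing).
#' @export
annotate_lads <- function(lads, genes) {
  stopifnot(inherits(genes, "gene_model"))
  lads <- as.data.frame(lads)
  missing_chr <- setdiff(unique(lads$chrom),
                         unique(as.character(
                           GenomeInfoDb::seqnames(genes$genes))))
  if (length(missing_chr))
    stop("chromosome(s) absent from the gene model: ",
         paste(missing_chr, collapse = ", "))
  if (nrow(lads) == 0L)
    return(list(per_lad = cbind(lads, combination = character(0)),
                combinations = data.frame(combination = character(0),
                                          count = integer(0))))
  gl <- lads_to_granges(lads)
  feats <- genes$features
  combo <- character(nrow(lads))
  gene_bodies <- genes$genes
  noncoding <- gene_bodies[!gene_bodies$coding]
  cats <- list(intron = "intron", CDS = "CDS",
               `5UTR` = "five_UTR", `3UTR` = "three_UTR")
  hit <- sapply(cats, function(ty)
    IRanges::overlapsAny(gl, feats[feats$type == ty]))
  hit <- matrix(hit, nrow = length(gl),
                dimnames = list(NULL, names(cats)))
  # >=1 bp outside all gene bodies
  covered <- GenomicRanges::reduce(gene_bodies, ignore.strand = TRUE)
  ov <- IRanges::findOverlaps(gl, covered)
  inside_bp <- integer(length(gl))
  if (length(ov)) {
    w <- BiocGenerics::width(IRanges::pintersect(
      gl[S4Vectors::queryHits(ov)], covered[S4Vectors::subjectHits(ov)]))
    inside_bp <- as.integer(tapply(w, factor(S4Vectors::queryHits(ov),
                                             levels = seq_along(gl)),
                                   sum, default = 0L))
  }
  inter_gene <- BiocGenerics::width(gl) - inside_bp >= 1L
  no_cds <- IRanges::overlapsAny(gl, noncoding)
  for (i in seq_along(gl)) {
    parts <- c(names(cats)[hit[i, ]],
               if (inter_gene[i]) "inter_gene",
               if (no_cds[i]) "no_CDS")
    combo[i] <- paste(parts, collapse = "+")
  }
  per_lad <- cbind(lads, combination = combo, stringsAsFactors = FALSE)
  tab <- sort(table(combo), decreasing = TRUE)
  list(per_lad = per_lad,
       combinations = data.frame(combination = names(tab),
                                 count = as.integer(tab),
                                 stringsAsFactors = FALSE))
}

#' List genes overlapping LADs
#'
#' @param lads A `lad_set` (or interval data.frame).
#' @param genes A `gene_model`.
#' @param rule `"any_overlap"` (>= 1 bp, default) or `"containment"`
#'   (gene body fully inside a LAD).
#' @return Sorted unique gene ids (for export to external GO tools).
#' @export
genes_in_lads <- function(lads, genes, rule = c("any_overlap", "containment")) {
  rule <- match.arg(rule)
  stopifnot(inherits(genes, "gene_model"))
  lads <- as.data.frame(lads)
  if (nrow(lads) == 0L) return(character(0))
  gl <- lads_to_granges(lads)
  gb <- genes$genes
  hit <- if (rule == "any_overlap")
    IRanges::overlapsAny(gb, gl)
  else
    IRanges::overlapsAny(gb, gl, type = "within")
  sort(unique(gb$gene_id[hit]))
}
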