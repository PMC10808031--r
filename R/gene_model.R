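#' Construct a gene model container
#'
#' @param genes `GRanges` of gene bodies with metadata columns `gene_id`
#'   and logical `coding`.
#' @param features `GRanges` of per-transcript features with metadata
#'   columns `type` (one of `exon`, `intron`, `CDS`, `five_UTR`,
#'   `three_UTR`), `gene_id`, `transcript_id`.
#' @return A list of class `gene_model`.
#' @export
gene_model <- function(genes, features) {
  stopifnot(all(c("gene_id", "coding") %in%
                  names(S4Vectors::mcols(genes))),
            all(c("type", "gene_id", "transcript_id") %in%
                  names(S4Vectors::mcols(features))))
  structure(list(genes = genes, features = features), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("Gene model:", length(x$genes), "genes (",
      sum(x$genes$coding), "coding ),",
      length(x$features), "feature intervals\n")
  invisible(x)
}

#' Read a gene model from GFF3 or GTF
#'
#' Imports with [rtracklayer::import()] (which parses both attribute
#' dialects: `ID=`/`Parent=` and `gene_id`/`transcript_id`), then builds
#' the gene/feature container used by [annotate_lads()]. Introns are
#' derived per transcript as the gaps between its exons; UTR feature types
#' (`five_prime_UTR`/`three_prime_UTR` in GFF3, `5UTR`/`3UTR` or
#' `five_UTR`/`three_UTR` elsewhere) are normalized. A gene is coding when
#' at least one of its transcripts has a CDS.
#'
#' @param path Path to a GFF3 or GTF file.
#' @return A [gene_model()].
#' @export
read_gene_model <- function(path) {
  gff <- rtracklayer::import(path)
  type <- as.character(gff$type)
  id_of <- function(g) {
    if (!is.null(g$gene_id)) return(as.character(g$gene_id))
    as.character(g$ID)
  }
  parent_of <- function(g) {
    if (!is.null(g$Parent) && any(lengths(g$Parent) > 0))
      return(vapply(as.list(g$Parent),
                    function(p) if (length(p)) p[[1]] else NA_character_,
                    character(1)))
    if (!is.null(g$transcript_id)) return(as.character(g$transcript_id))
    rep(NA_character_, length(g))
  }

  genes_raw <- gff[type == "gene"]
  tx_raw <- gff[type %in% c("mRNA", "transcript", "ncRNA")]
  tx_id <- id_of(tx_raw)
  tx_gene <- parent_of(tx_raw)
  if (length(genes_raw) == 0L) {      # GTF without explicit gene lines
    g <- S4Vectors::split(tx_raw, tx_gene)
    genes_raw <- unlist(range(g))
    genes_raw$ID <- names(g)
  }
  gene_ids <- id_of(genes_raw)

  sub <- gff[type %in% c("exon", "CDS", "five_prime_UTR",
                         "three_prime_UTR", "5UTR", "3UTR",
                         "five_UTR", "three_UTR")]
  sub_tx <- parent_of(sub)
  sub_type <- as.character(sub$type)
  sub_type[sub_type %in% c("five_prime_UTR", "5UTR")] <- "five_UTR"
  sub_type[sub_type %in% c("three_prime_UTR", "3UTR")] <- "three_UTR"
  sub_gene <- tx_gene[match(sub_tx, tx_id)]
  # features attached directly to a gene record
  direct <- is.na(sub_gene) & sub_tx %in% gene_ids
  sub_gene[direct] <- sub_tx[direct]

  feats <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(sub),
                                  IRanges::ranges(sub),
                                  strand = BiocGenerics::strand(sub))
  feats$type <- sub_type
  feats$gene_id <- sub_gene
  feats$transcript_id <- sub_tx

  # derive introns per transcript from exon gaps
  ex <- feats[feats$type == "exon" & !is.na(feats$transcript_id)]
  introns <- GenomicRanges::GRanges()
  if (length(ex)) {
    by_tx <- S4Vectors::split(ex, ex$transcript_id)
    intr_list <- GenomicRanges::psetdiff(unlist(range(by_tx)), by_tx)
    intr <- unlist(intr_list)
    if (length(intr)) {
      tx_of <- rep(names(intr_list), lengths(intr_list))
      introns <- GenomicRanges::granges(intr)
      introns$type <- "intron"
      introns$gene_id <- feats$gene_id[match(tx_of, feats$transcript_id)]
      introns$transcript_id <- tx_of
    }
  }

  coding_genes <- unique(feats$gene_id[feats$type == "CDS"])
  genes <- GenomicRanges::granges(genes_raw)
  genes$gene_id <- gene_ids
  genes$coding <- gene_ids %in% coding_genes

  all_feats <- c(feats, introns)
  gene_model(genes, all_feats)
}
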