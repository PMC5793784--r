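#' Genome model: genes, transcripts, exons and derived introns
#'
#' A `genome_model` is the package's source of truth for annotated splice
#' junctions. Internally all coordinates are 0-based half-open; conversion
#' to/from the 1-based inclusive GTF convention happens only at the parse and
#' write boundaries.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open) and logical flags `rp`
#'   (ribosomal-protein gene) and `intron_containing`.
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open).
#' @return An object of class `genome_model` with components `genes`,
#'   `exons` and the derived `introns` table. Each intron is the gap between
#'   consecutive exons of a transcript; the donor (5'SS) is the intron end
#'   nearer the transcript 5' end, so on the minus strand the donor is the
#'   highest intron coordinate.
#' @export
genome_model <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes)))
  if (is.null(genes$rp)) genes$rp <- FALSE
  if (is.null(genes$intron_containing)) genes$intron_containing <- NA
  stopifnot(all(genes$strand %in% c("+", "-")))
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  introns <- derive_introns(exons)
  n_int <- table(introns$gene_id)
  genes$intron_containing <- genes$gene_id %in% introns$gene_id
  structure(list(genes = genes, exons = exons, introns = introns),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d genes (%d intron-containing, %d RP), %d exons, %d introns\n",
              nrow(x$genes), sum(x$genes$intron_containing), sum(x$genes$rp),
              nrow(x$exons), nrow(x$introns)))
  invisible(x)
}

# Gaps between consecutive exons of each transcript, with donor/acceptor in
# transcript orientation. Overlapping exons within a transcript invalidate it.
derive_introns <- function(exons) {
  out <- list()
  for (tx in unique(exons$transcript_id)) {
    ex <- exons[exons$transcript_id == tx, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) < 2) next
    if (any(ex$start[-1] < ex$end[-nrow(ex)])) {
      warning("transcript ", tx, " has overlapping exons; skipped")
      next
    }
    n <- nrow(ex) - 1
    ist <- ex$end[-(n + 1)]
    ien <- ex$start[-1]
    strand <- ex$strand[1]
    # rank 1 = nearest transcript 5' end
    rank <- if (strand == "+") seq_len(n) else rev(seq_len(n))
    out[[tx]] <- data.frame(
      transcript_id = tx, gene_id = ex$gene_id[1], chrom = ex$chrom[1],
      strand = strand, start = ist, end = ien, intron_rank = rank,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(intron_id = character(), transcript_id = character(),
                      gene_id = character(), chrom = character(),
                      strand = character(), start = integer(), end = integer(),
                      intron_rank = integer(), bp = integer(),
                      stringsAsFactors = FALSE))
  }
  introns <- do.call(rbind, out)
  rownames(introns) <- NULL
  introns$intron_id <- paste0(introns$transcript_id, ".i", introns$intron_rank)
  introns$bp <- NA_integer_
  introns[, c("intron_id", "transcript_id", "gene_id", "chrom", "strand",
              "start", "end", "intron_rank", "bp")]
}

#' Parse a GTF annotation into a genome model
#'
#' Reads a 1-based inclusive GTF (via rtracklayer) and derives introns.
#' Records with unknown strand are dropped; transcripts with overlapping
#' exons are rejected with a warning.
#'
#' @param path GTF file path.
#' @param gene_meta optional data.frame (or TSV path) with columns
#'   `gene_id`, `rp` giving the ribosomal-protein flag; genes absent from the
#'   table are treated as non-RP.
#' @return A [genome_model()].
#' @export
parse_gtf <- function(path, gene_meta = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  keep <- as.character(BiocGenerics::strand(ex)) %in% c("+", "-")
  if (!all(keep)) warning(sum(!keep), " exon record(s) with unknown strand dropped")
  ex <- ex[keep]
  exons <- data.frame(
    transcript_id = as.character(ex$transcript_id),
    gene_id = as.character(ex$gene_id),
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(BiocGenerics::strand(ex)),
    start = BiocGenerics::start(ex) - 1L,  # 1-based inclusive -> 0-based half-open
    end = BiocGenerics::end(ex),
    stringsAsFactors = FALSE)
  genes <- do.call(rbind, lapply(split(exons, exons$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1], strand = d$strand[1],
               start = min(d$start), end = max(d$end), stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  genes$rp <- FALSE
  if (!is.null(gene_meta)) {
    if (is.character(gene_meta)) gene_meta <- utils::read.delim(gene_meta)
    genes$rp <- genes$gene_id %in% gene_meta$gene_id[as.logical(gene_meta$rp)]
  }
  genome_model(genes, exons)
}

#' Write a genome model as GTF (1-based inclusive)
#'
#' Emits gene, transcript and exon records. Inverse of [parse_gtf()] up to
#' attribute ordering.
#'
#' @param genome a [genome_model()].
#' @param path output file path.
#' @export
write_gtf <- function(genome, path) {
  ex <- genome$exons
  ex <- ex[order(ex$chrom, ex$start), , drop = FALSE]
  attr_str <- sprintf('gene_id "%s"; transcript_id "%s";',
                      ex$gene_id, ex$transcript_id)
  lines <- sprintf("%s\tsplicefid\texon\t%d\t%d\t.\t%s\t.\t%s",
                   ex$chrom, ex$start + 1L, ex$end, ex$strand, attr_str)
  g <- genome$genes
  glines <- sprintf('%s\tsplicefid\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                    g$chrom, g$start + 1L, g$end, g$strand, g$gene_id)
  writeLines(c(glines, lines), path)
}

# Transcript-oriented donor (first intron base) and acceptor (last intron
# base) genomic positions for an intron row.
intron_donor <- function(introns) {
  ifelse(introns$strand == "+", introns$start, introns$end - 1L)
}
intron_acceptor <- function(introns) {
  ifelse(introns$strand == "+", introns$end - 1L, introns$start)
}

#' Fetch a transcript-oriented subsequence from a genome
#'
#' @param seqs a named `DNAStringSet` (one entry per contig).
#' @param chrom contig name.
#' @param start,end 0-based half-open genomic span.
#' @param strand "+" or "-"; minus-strand spans are reverse-complemented.
#' @return list with `seq` (character) and `truncated` (logical, TRUE when
#'   the requested span ran off the contig and was clipped).
#' @export
fetch_seq <- function(seqs, chrom, start, end, strand = "+") {
  if (!chrom %in% names(seqs)) stop("unknown contig: ", chrom)
  len <- Biostrings::width(seqs[chrom])
  s <- max(0L, as.integer(start)); e <- min(len, as.integer(end))
  truncated <- (s != start) || (e != end)
  if (e <= s) return(list(seq = "", truncated = TRUE))
  sub <- Biostrings::subseq(seqs[[chrom]], start = s + 1L, end = e)
  if (strand == "-") sub <- Biostrings::reverseComplement(sub)
  list(seq = as.character(sub), truncated = truncated)
}
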