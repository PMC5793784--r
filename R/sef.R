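#' Splicing error frequency for events in intron-containing genes
#'
#' SEF = novel-junction unique reads / annotated-junction unique reads,
#' computed on replicate-pooled counts (summed within strain before the
#' ratio; pooling then dividing is the maximum-likelihood estimate for a
#' binomial ratio, unlike averaging per-replicate ratios).
#'
#' @param novel,annotated pooled unique-read counts (vectors recycle).
#' @return data.frame with `novel`, `annotated`, `sef`, `undefined` (TRUE
#'   when the annotated count is 0 — never silently 0 or Inf).
#' @export
compute_sef_intronic <- function(novel, annotated) {
  undef <- annotated == 0
  sef <- ifelse(undef, NA_real_, novel / annotated)
  data.frame(novel = novel, annotated = annotated, sef = sef,
             undefined = undef)
}

#' Splicing error frequency for cryptic introns in intron-less genes
#'
#' SEF = cryptic-junction unique reads / RPKM of the host transcript. The
#' units (reads per RPKM) are sequencing-depth dependent: doubling depth at a
#' fixed transcript mix doubles the value. `normalized = TRUE` divides by
#' millions of mapped reads to remove that dependence (off by default; the
#' plain ratio is the conventional form).
#'
#' @param reads cryptic-junction unique reads (pooled).
#' @param rpkm host-transcript RPKM.
#' @param normalized divide by mapped-read millions as well.
#' @param mapped_millions required when `normalized = TRUE`.
#' @return data.frame with `sef` and `undefined` (RPKM of 0).
#' @export
compute_sef_cryptic <- function(reads, rpkm, normalized = FALSE,
                                mapped_millions = NULL) {
  undef <- rpkm == 0
  sef <- ifelse(undef, NA_real_, reads / rpkm)
  if (normalized) {
    stopifnot(!is.null(mapped_millions))
    sef <- sef / mapped_millions
  }
  data.frame(sef = sef, undefined = undef)
}

#' Reads per kilobase per million mapped reads
#'
#' @param reads read count for the feature.
#' @param length_nt feature length in nucleotides (> 0).
#' @param total_mapped total mapped reads in the library (> 0).
#' @return RPKM (synonymous with FPKM here; fragments are treated as reads).
#' @export
compute_rpkm <- function(reads, length_nt, total_mapped) {
  if (any(length_nt <= 0)) stop("length_nt must be positive")
  if (any(total_mapped <= 0)) stop("total_mapped must be positive")
  reads / (length_nt / 1000) / (total_mapped / 1e6)
}

#' Classify a read against a gene model
#'
#' Read classes follow the pre-mRNA accounting: a split read whose gap
#' equals an annotated intron is a `junction` read (mature mRNA only); a
#' contiguous read straddling an exon-intron border is a `boundary` read and
#' one fully inside an intron is an `intron` read (pre-mRNA only); a read
#' fully within exons that spans no junction is `exonic` (informative for
#' neither). Anything else (no overlap, unannotated gap) is `ambiguous`.
#'
#' @param blocks integer matrix with columns `start`, `end` (0-based
#'   half-open aligned blocks, ordered), one row per block.
#' @param gene_id host gene id.
#' @param genome a [genome_model()].
#' @return one of "junction", "boundary", "intron", "exonic", "ambiguous".
#' @export
classify_read <- function(blocks, gene_id, genome) {
  ex <- genome$exons[genome$exons$gene_id == gene_id, , drop = FALSE]
  ints <- genome$introns[genome$introns$gene_id == gene_id, , drop = FALSE]
  if (!nrow(ex)) return("ambiguous")
  g <- genome$genes[genome$genes$gene_id == gene_id, ]
  span <- range(blocks)
  if (span[1] >= g$end || span[2] <= g$start) return("ambiguous")
  if (nrow(blocks) >= 2) {
    gaps_start <- blocks[-nrow(blocks), "end"]
    gaps_end <- blocks[-1, "start"]
    ok <- mapply(function(s, e) any(ints$start == s & ints$end == e),
                 gaps_start, gaps_end)
    return(if (all(ok)) "junction" else "ambiguous")
  }
  s <- blocks[1, "start"]; e <- blocks[1, "end"]
  in_intron <- any(ints$start <= s & ints$end >= e)
  if (in_intron) return("intron")
  straddles <- any((ints$start > s & ints$start < e) |
                     (ints$end > s & ints$end < e))
  if (straddles) return("boundary")
  in_exon <- any(ex$start <= s & ex$end >= e)
  if (in_exon) return("exonic")
  "ambiguous"
}

#' Pre-mRNA fraction from read-class counts
#'
#' fraction = (boundary + intron) / (boundary + intron + junction). Exonic
#' reads belong to both forms and are excluded. Undefined (flagged) when no
#' informative read exists.
#'
#' @param boundary,intron,junction per-gene read-class counts.
#' @return data.frame with `fraction` in \[0, 1\] and `undefined`.
#' @export
premrna_fraction <- function(boundary, intron, junction) {
  denom <- boundary + intron + junction
  undef <- denom == 0
  frac <- ifelse(undef, NA_real_, (boundary + intron) / denom)
  data.frame(fraction = frac, undefined = undef)
}

#' Exon-skipping frequency for a two-intron transcript
#'
#' exon1-exon3 junction reads divided by exon1-exon2 junction reads (first
#' intron splicing); the exon2-exon3 denominator is supported as an
#' alternative.
#'
#' @param skip_reads exon1-exon3 junction reads.
#' @param ref_reads denominator junction reads (exon1-exon2 by default).
#' @return data.frame with `frequency` and `undefined` (denominator 0).
#' @export
exon_skip_frequency <- function(skip_reads, ref_reads) {
  undef <- ref_reads == 0
  data.frame(frequency = ifelse(undef, NA_real_, skip_reads / ref_reads),
             undefined = undef)
}

#' Long/short isoform ratio (junction reads over FPKM)
#'
#' Ratio of spliced (long) isoform junction reads to the FPKM of the
#' shorter isoform.
#'
#' @param junction_reads long-isoform junction reads.
#' @param short_fpkm FPKM of the short isoform.
#' @return data.frame with `ratio` and `undefined` (FPKM 0).
#' @export
isoform_ratio <- function(junction_reads, short_fpkm) {
  undef <- short_fpkm == 0
  data.frame(ratio = ifelse(undef, NA_real_, junction_reads / short_fpkm),
             undefined = undef)
}

#' Per-event, per-strain SEF table
#'
#' Pools replicates within strain, pairs each novel event with its annotated
#' junction counts (intron-containing hosts) or host RPKM (cryptic introns
#' in intron-less hosts), and applies the strict support filter: an event
#' passes iff some strain has at least `strict_min` novel reads in every
#' replicate.
#'
#' @param events event table from [classify_events()].
#' @param jset the (filtered) `junction_set` the events came from.
#' @param genome a [genome_model()].
#' @param gene_counts optional data.frame (`gene_id`, `sample`, `reads`)
#'   used for RPKM of intron-less hosts; without it cryptic SEFs are NA.
#' @param strict_min strict-filter read threshold (default 5).
#' @return data.frame with one row per event x strain: counts, `sef`,
#'   `sef_type` ("intronic" or "cryptic"), `undefined`,
#'   `passes_strict_filter`.
#' @export
sef_table <- function(events, jset, genome, gene_counts = NULL,
                      strict_min = 5L) {
  empty <- data.frame(event_id = character(), gene_id = character(),
                      event_class = character(), label = character(),
                      rp = logical(), strain = character(), novel = integer(),
                      annotated = integer(), sef = numeric(),
                      sef_type = character(), undefined = logical(),
                      passes_strict_filter = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(events)) return(empty)
  samp <- jset$samples
  strains <- unique(samp$strain)
  jid <- rownames(jset$counts)
  ikey <- paste(genome$introns$chrom, genome$introns$start,
                genome$introns$end, sep = ":")
  rpkm_tab <- NULL
  if (!is.null(gene_counts)) {
    totals <- tapply(gene_counts$reads, gene_counts$sample, sum)
    g <- genome$genes
    glen <- vapply(g$gene_id, function(id) {
      ex <- genome$exons[genome$exons$gene_id == id, ]
      sum(ex$end - ex$start)
    }, numeric(1))
    names(glen) <- g$gene_id
    gene_counts$rpkm <- compute_rpkm(
      gene_counts$reads, glen[gene_counts$gene_id],
      as.numeric(totals[gene_counts$sample]))
    rpkm_tab <- gene_counts
  }
  rows <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (ev$event_class %in% c("annotated", "unassigned")) next
    jrow <- match(paste(ev$chrom, ev$start, ev$end, sep = ":"), jid)
    novel_by_sample <- jset$counts[jrow, ]
    # strict filter: >= strict_min in BOTH replicates of >= 1 strain
    strict <- any(vapply(strains, function(st) {
      reps <- samp$sample[samp$strain == st]
      all(novel_by_sample[reps] >= strict_min)
    }, logical(1)))
    use_cryptic <- ev$event_class == "cryptic_intron" &&
      !isTRUE(ev$host_has_introns)
    for (st in strains) {
      reps <- samp$sample[samp$strain == st]
      novel <- sum(novel_by_sample[reps])
      if (!use_cryptic && !is.na(ev$paired_intron)) {
        idx <- match(ev$paired_intron, genome$introns$intron_id)
        arow <- match(ikey[idx], paste(jset$junctions$chrom,
                                       jset$junctions$start,
                                       jset$junctions$end, sep = ":"))
        annot <- if (is.na(arow)) 0L else sum(jset$counts[arow, reps])
        s <- compute_sef_intronic(novel, annot)
        rows[[length(rows) + 1]] <- data.frame(
          event_id = ev$event_id, gene_id = ev$gene_id,
          event_class = ev$event_class, label = ev$label, rp = ev$rp,
          strain = st, novel = novel, annotated = annot, sef = s$sef,
          sef_type = "intronic", undefined = s$undefined,
          passes_strict_filter = strict, stringsAsFactors = FALSE)
      } else if (use_cryptic && !is.null(rpkm_tab)) {
        sub <- rpkm_tab[rpkm_tab$gene_id == ev$gene_id &
                          rpkm_tab$sample %in% reps, ]
        rpkm <- mean(sub$rpkm)
        s <- compute_sef_cryptic(novel, rpkm)
        rows[[length(rows) + 1]] <- data.frame(
          event_id = ev$event_id, gene_id = ev$gene_id,
          event_class = ev$event_class, label = ev$label, rp = ev$rp,
          strain = st, novel = novel, annotated = NA_integer_, sef = s$sef,
          sef_type = "cryptic", undefined = s$undefined,
          passes_strict_filter = strict, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          event_id = ev$event_id, gene_id = ev$gene_id,
          event_class = ev$event_class, label = ev$label, rp = ev$rp,
          strain = st, novel = novel, annotated = NA_integer_,
          sef = NA_real_, sef_type = if (use_cryptic) "cryptic" else "intronic",
          undefined = TRUE, passes_strict_filter = strict,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
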