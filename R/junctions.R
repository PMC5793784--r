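#' Parse a STAR-style SJ.out.tab junction file
#'
#' The dialect has 9 tab-separated columns: contig, first intron base
#' (1-based), last intron base (1-based), strand code (0 = undefined,
#' 1 = +, 2 = -), splice-motif code 0-6, annotated flag, unique-read count,
#' multimapping-read count, maximum overhang. Coordinates are converted to
#' the internal 0-based half-open convention. Strand code 0 is resolved from
#' the motif code when canonical (odd codes are +, even nonzero are -),
#' otherwise the record is flagged `strand = "*"` (undetermined).
#' Multimapping counts are retained but used in no statistic.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open intron span), `strand`, `motif`, `annotated` (0/1 as in the
#'   file), `unique_reads`, `multi_reads`, `max_overhang`.
#' @export
parse_sj_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), motif = integer(),
                      annotated = integer(), unique_reads = integer(),
                      multi_reads = integer(), max_overhang = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9L)
  if (length(bad)) stop("malformed SJ row at line ", bad[1], " of ", path)
  m <- matrix(unlist(parts), ncol = 9, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 2:9, drop = FALSE], 2, as.integer))
  if (is.null(dim(num))) num <- matrix(num, nrow = 1)
  if (anyNA(num)) stop("non-integer field in SJ row at line ",
                       which(rowSums(is.na(num)) > 0)[1], " of ", path)
  strand_code <- num[, 3]
  motif <- num[, 4]
  strand <- c("*", "+", "-")[strand_code + 1L]
  # strand 0: canonical motifs imply a strand (1,3,5 = +; 2,4,6 = -)
  undef <- strand_code == 0L
  strand[undef & motif %in% c(1L, 3L, 5L)] <- "+"
  strand[undef & motif %in% c(2L, 4L, 6L)] <- "-"
  data.frame(chrom = m[, 1],
             start = num[, 1] - 1L,  # first intron base, 1-based -> 0-based
             end = num[, 2],         # last intron base, 1-based closed -> half-open end
             strand = strand, motif = motif, annotated = num[, 5],
             unique_reads = num[, 6], multi_reads = num[, 7],
             max_overhang = num[, 8], stringsAsFactors = FALSE)
}

#' Write junction records in the SJ.out.tab dialect
#'
#' Inverse of [parse_sj_tab()]; internal 0-based half-open spans become
#' 1-based closed intron coordinates.
#'
#' @param sj data.frame as returned by [parse_sj_tab()].
#' @param path output path.
#' @export
write_sj_tab <- function(sj, path) {
  strand_code <- match(sj$strand, c("*", "+", "-")) - 1L
  lines <- sprintf("%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%d",
                   sj$chrom, sj$start + 1L, sj$end, strand_code, sj$motif,
                   sj$annotated, sj$unique_reads, sj$multi_reads,
                   sj$max_overhang)
  writeLines(lines, path)
}

#' Merge per-sample junction tables into one junction set
#'
#' @param tables named list of per-sample data.frames from [parse_sj_tab()];
#'   names are sample ids.
#' @param samples data.frame with columns `sample`, `strain`, `replicate`
#'   describing the design; rownames of the count matrices follow junctions,
#'   columns follow `samples$sample`.
#' @return A `junction_set`: list with `junctions` (chrom/start/end/strand/
#'   motif/annotated), `counts` and `overhang` matrices (junction x sample),
#'   and `samples`.
#' @export
junction_set <- function(tables, samples) {
  stopifnot(all(samples$sample %in% names(tables)))
  keys <- unique(do.call(rbind, lapply(tables, function(d)
    d[, c("chrom", "start", "end", "strand", "motif", "annotated")])))
  keys <- keys[order(keys$chrom, keys$start, keys$end), , drop = FALSE]
  rownames(keys) <- NULL
  key_id <- function(d) paste(d$chrom, d$start, d$end, sep = ":")
  ids <- key_id(keys)
  counts <- matrix(0L, nrow(keys), nrow(samples),
                   dimnames = list(ids, samples$sample))
  overhang <- counts
  for (s in samples$sample) {
    d <- tables[[s]]
    i <- match(key_id(d), ids)
    counts[i, s] <- d$unique_reads
    overhang[i, s] <- d$max_overhang
  }
  structure(list(junctions = keys, counts = counts, overhang = overhang,
                 samples = samples), class = "junction_set")
}

#' @export
print.junction_set <- function(x, ...) {
  cat(sprintf("junction_set: %d junctions x %d samples (%d annotated)\n",
              nrow(x$junctions), nrow(x$samples), sum(x$junctions$annotated)))
  invisible(x)
}

#' Re-annotate junctions against a genome model
#'
#' Sets the `annotated` flag to 1 exactly when the junction span equals an
#' annotated intron of the model (chrom, start, end and compatible strand).
#' The flag carried in SJ files is advisory; the genome model is the source
#' of truth downstream.
#'
#' @param jset a `junction_set`.
#' @param genome a [genome_model()].
#' @return the junction set with `annotated` recomputed.
#' @export
annotate_junctions <- function(jset, genome) {
  ikey <- paste(genome$introns$chrom, genome$introns$start, genome$introns$end,
                genome$introns$strand, sep = ":")
  jkey <- paste(jset$junctions$chrom, jset$junctions$start, jset$junctions$end,
                jset$junctions$strand, sep = ":")
  jset$junctions$annotated <- as.integer(jkey %in% ikey)
  jset
}

#' Filter junctions by read support, overhang and contig exclusion
#'
#' A junction is kept iff its unique-read count reaches `min_reads` in at
#' least one sample, its maximum overhang (over samples) is at least
#' `overhang_annotated` when annotated or strictly greater than
#' `overhang_novel` when novel, and its contig is not excluded (the
#' mitochondrial decoy by default, since mitochondrial junctions are not
#' spliceosomal).
#'
#' @param jset a `junction_set` (run [annotate_junctions()] first).
#' @param min_reads minimum unique reads in >= 1 sample (default 5).
#' @param overhang_annotated minimum overhang for annotated junctions
#'   (default 3; kept iff overhang >= 3).
#' @param overhang_novel overhang bound for novel junctions (default 12;
#'   kept iff overhang > 12).
#' @param exclude_contigs contigs dropped entirely.
#' @return the filtered `junction_set`.
#' @export
filter_junctions <- function(jset, min_reads = 5L, overhang_annotated = 3L,
                             overhang_novel = 12L,
                             exclude_contigs = c("chrM", "Mito")) {
  j <- jset$junctions
  max_count <- apply(jset$counts, 1, max)
  max_over <- apply(jset$overhang, 1, max)
  keep <- max_count >= min_reads &
    ifelse(j$annotated == 1L, max_over >= overhang_annotated,
           max_over > overhang_novel) &
    !(j$chrom %in% exclude_contigs)
  jset$junctions <- j[keep, , drop = FALSE]
  jset$counts <- jset$counts[keep, , drop = FALSE]
  jset$overhang <- jset$overhang[keep, , drop = FALSE]
  rownames(jset$junctions) <- NULL
  jset
}

# Host-gene assignment for one junction: genes overlapping the span; prefer
# a gene sharing a splice site, then the largest overlap, then lexicographic
# gene id (deterministic).
assign_host_gene <- function(chrom, start, end, strand, genome) {
  g <- genome$genes
  cand <- which(g$chrom == chrom & g$strand == strand &
                  g$start < end & g$end > start)
  if (!length(cand)) return(NA_character_)
  if (length(cand) == 1L) return(g$gene_id[cand])
  ids <- g$gene_id[cand]
  ints <- genome$introns[genome$introns$gene_id %in% ids, , drop = FALSE]
  shares <- vapply(ids, function(id) {
    gi <- ints[ints$gene_id == id, , drop = FALSE]
    any(gi$start == start | gi$end == end)
  }, logical(1))
  if (any(shares)) ids <- ids[shares]
  if (length(ids) == 1L) return(ids)
  ov <- vapply(ids, function(id) {
    r <- g[g$gene_id == id, ]
    min(end, r$end) - max(start, r$start)
  }, numeric(1))
  ids <- ids[ov == max(ov)]
  sort(ids)[1]
}

#' Classify novel junctions into splice-event classes
#'
#' Each junction that is not annotated is matched against the introns of its
#' host gene and classified, in transcript orientation, as an alternative
#' 5'SS or 3'SS event (upstream = toward the transcript 5' end), an
#' exon-skipping junction (exon n to exon n+2 of a multi-intron transcript),
#' or a cryptic intron (host gene intron-less, or neither end shared with an
#' annotated intron; the latter carries `host_has_introns = TRUE`).
#' Labels follow the "u3-7" / "d5-4" convention: class letter + site,
#' dash, absolute offset in nucleotides.
#'
#' @param jset a filtered, annotated `junction_set`.
#' @param genome a [genome_model()].
#' @return data.frame of events: `event_id`, `junction_id`, `chrom`,
#'   `start`, `end`, `strand`, `event_class`, `gene_id`, `rp`,
#'   `paired_intron`, `offset` (signed; positive = downstream), `label`,
#'   `host_has_introns`. Junctions overlapping no gene are returned with
#'   `event_class = "unassigned"` (reported, not analyzed).
#' @export
classify_events <- function(jset, genome) {
  j <- jset$junctions
  novel <- which(j$annotated == 0L)
  out <- vector("list", length(novel))
  for (k in seq_along(novel)) {
    i <- novel[k]
    out[[k]] <- classify_junction_event(
      j$chrom[i], j$start[i], j$end[i], j$strand[i], genome,
      junction_id = rownames(jset$counts)[i])
  }
  ev <- if (length(out)) do.call(rbind, out) else empty_events()
  rownames(ev) <- NULL
  if (nrow(ev)) ev$event_id <- sprintf("ev%04d", seq_len(nrow(ev)))
  ev[, c("event_id", setdiff(names(ev), "event_id"))]
}

empty_events <- function() {
  data.frame(event_id = character(), junction_id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), event_class = character(),
             gene_id = character(), rp = logical(), paired_intron = character(),
             offset = integer(), label = character(),
             host_has_introns = logical(), stringsAsFactors = FALSE)
}

#' Classify one junction (scalar form)
#'
#' @param chrom,start,end,strand junction span, internal coordinates.
#' @param genome a [genome_model()].
#' @param junction_id carried through to the output row.
#' @return one-row data.frame; see [classify_events()].
#' @export
classify_junction_event <- function(chrom, start, end, strand, genome,
                                    junction_id = NA_character_) {
  row <- function(class, gene = NA_character_, paired = NA_character_,
                  offset = NA_integer_, label = NA_character_,
                  host_has_introns = NA) {
    rp <- if (!is.na(gene)) genome$genes$rp[match(gene, genome$genes$gene_id)] else NA
    data.frame(junction_id = junction_id, chrom = chrom, start = start,
               end = end, strand = strand, event_class = class, gene_id = gene,
               rp = rp, paired_intron = paired, offset = offset, label = label,
               host_has_introns = host_has_introns, stringsAsFactors = FALSE)
  }
  gene <- assign_host_gene(chrom, start, end, strand, genome)
  if (is.na(gene)) return(row("unassigned"))
  ints <- genome$introns[genome$introns$gene_id == gene, , drop = FALSE]
  if (!nrow(ints)) return(row("cryptic_intron", gene, host_has_introns = FALSE))
  exact <- ints$start == start & ints$end == end
  if (any(exact)) return(row("annotated", gene, paired = ints$intron_id[which(exact)[1]]))

  # exon skipping: donor of intron r joined to acceptor of intron r+1
  ints_tx <- ints[order(ints$intron_rank), , drop = FALSE]
  if (nrow(ints_tx) >= 2) {
    for (r in seq_len(nrow(ints_tx) - 1)) {
      a <- ints_tx[r, ]; b <- ints_tx[r + 1, ]
      if (strand == "+") {
        hit <- start == a$start && end == b$end
      } else {
        hit <- start == b$start && end == a$end
      }
      if (hit) return(row("exon_skip", gene, paired = a$intron_id,
                          label = sprintf("skip-e%d", a$intron_rank + 1L)))
    }
  }

  donor_match <- if (strand == "+") ints$start == start else ints$end == end
  acc_match <- if (strand == "+") ints$end == end else ints$start == start
  if (any(donor_match)) {
    ann <- ints[which(donor_match)[1], ]
    # 3'SS moved; offset in transcript orientation (positive = downstream)
    offset <- if (strand == "+") end - ann$end else ann$start - start
    cls <- if (offset < 0) "alt3_up" else "alt3_down"
    lab <- sprintf("%s3-%d", if (offset < 0) "u" else "d", abs(offset))
    return(row(cls, gene, paired = ann$intron_id, offset = offset, label = lab))
  }
  if (any(acc_match)) {
    ann <- ints[which(acc_match)[1], ]
    offset <- if (strand == "+") start - ann$start else ann$end - end
    cls <- if (offset < 0) "alt5_up" else "alt5_down"
    lab <- sprintf("%s5-%d", if (offset < 0) "u" else "d", abs(offset))
    return(row(cls, gene, paired = ann$intron_id, offset = offset, label = lab))
  }
  row("cryptic_intron", gene, host_has_introns = TRUE)
}
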