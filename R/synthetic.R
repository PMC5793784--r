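#' Simulation configuration for the synthetic yeast-like universe
#'
#' Defaults describe a small budding-yeast-like transcriptome: mostly short
#' single-intron genes with strong 5'SS (GUAUGU), branch (UACUAAC) and 3'SS
#' (YAG) consensus motifs, a minority of ribosomal-protein genes, two
#' biological replicates for each of three strains (WT plus fast and slow
#' RNA-polymerase-II elongation mutants, both planted with reduced splicing
#' fidelity), and a mitochondrial decoy contig to exercise the contig
#' exclusion filter.
#'
#' @param n_genes number of genes (default 80).
#' @param frac_intron_containing fraction of genes with an intron (0.5).
#' @param frac_rp fraction of ribosomal-protein genes (0.3).
#' @param frac_two_intron fraction of intron-containing genes with two
#'   introns, hosting exon-skipping events (0.05; rare, as in yeast).
#' @param intron_length_range nucleotides, low/high (c(80, 200)).
#' @param exon_length_range nucleotides (c(200, 500)).
#' @param consensus_strength probability that a degenerate motif position
#'   carries the consensus base (0.9); 1 = exact consensus everywhere.
#' @param base_sef_range planted true SEF range (c(1e-3, 5e-2), matching
#'   the non-RP error regime; RP events are scaled by `rp_sef_factor`).
#' @param rp_sef_factor multiplier on RP-event SEF (0.2; RP transcripts are
#'   spliced more faithfully).
#' @param strain_fold_changes named multipliers on the true SEF per strain;
#'   the first name is the reference (c(WT = 1, fast = 2, slow = 2)).
#' @param annotated_depth_range per-gene junction read depth range
#'   (c(2000, 20000)), sampled log-uniformly.
#' @param dispersion negative-binomial dispersion of annotated counts (0.1).
#' @param n_replicates replicates per strain (2).
#' @param n_cryptic cryptic introns planted in intron-less genes (5).
#' @param sef_model "abundance" couples SEF inversely to gene abundance
#'   (the anti-correlation seen in real data); "features" makes log2 SEF a
#'   decreasing function of annotated intron length and 3'SS quality plus
#'   Gaussian noise; "uniform" draws SEF independently.
#' @param feature_coefs for `sef_model = "features"`: named vector
#'   `c(length = -1.2, ss3 = -0.8, noise_sd = 0.5)` in log2 units per SD of
#'   the planted covariate.
#' @param seed integer; fixes every downstream draw.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 80L,
                              frac_intron_containing = 0.5,
                              frac_rp = 0.3,
                              frac_two_intron = 0.05,
                              intron_length_range = c(80L, 200L),
                              exon_length_range = c(200L, 500L),
                              consensus_strength = 0.9,
                              base_sef_range = c(1e-3, 5e-2),
                              rp_sef_factor = 0.2,
                              strain_fold_changes = c(WT = 1, fast = 2, slow = 2),
                              annotated_depth_range = c(2000L, 20000L),
                              dispersion = 0.1,
                              n_replicates = 2L,
                              n_cryptic = 5L,
                              sef_model = c("abundance", "features", "uniform"),
                              feature_coefs = c(length = -1.2, ss3 = -0.8,
                                                noise_sd = 0.5),
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              frac_intron_containing = frac_intron_containing,
              frac_rp = frac_rp, frac_two_intron = frac_two_intron,
              intron_length_range = as.integer(intron_length_range),
              exon_length_range = as.integer(exon_length_range),
              consensus_strength = consensus_strength,
              base_sef_range = base_sef_range,
              rp_sef_factor = rp_sef_factor,
              strain_fold_changes = strain_fold_changes,
              annotated_depth_range = as.numeric(annotated_depth_range),
              dispersion = dispersion,
              n_replicates = as.integer(n_replicates),
              n_cryptic = as.integer(n_cryptic),
              sef_model = match.arg(sef_model),
              feature_coefs = feature_coefs,
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2]
  stopifnot(cfg$n_genes >= 1,
            cfg$frac_intron_containing >= 0, cfg$frac_intron_containing <= 1,
            cfg$frac_rp >= 0, cfg$frac_rp <= 1,
            cfg$consensus_strength >= 0, cfg$consensus_strength <= 1,
            rng_ok(cfg$intron_length_range), rng_ok(cfg$exon_length_range),
            rng_ok(cfg$base_sef_range), rng_ok(cfg$annotated_depth_range),
            all(cfg$strain_fold_changes > 0), cfg$n_replicates >= 1)
  if (cfg$intron_length_range[1] < 30)
    stop("intron_length_range too small to host 5'SS/BP/3'SS motifs (need >= 30 nt)")
  if (max(cfg$base_sef_range) * max(cfg$strain_fold_changes) >= 1)
    stop("SEF x strain multiplier reaches 1; reduce base_sef_range or fold changes")
  invisible(cfg)
}

rand_seq <- function(n) paste(sample(NUCS, n, replace = TRUE), collapse = "")

# Draw a motif with per-position consensus probability; `fixed` marks
# positions never mutated (canonical dinucleotides).
draw_motif <- function(consensus, strength, fixed = rep(FALSE, nchar(consensus))) {
  cons <- strsplit(consensus, "")[[1]]
  out <- cons
  for (i in seq_along(cons)) {
    if (!fixed[i] && stats::runif(1) > strength) {
      out[i] <- sample(setdiff(NUCS, cons[i]), 1)
    }
  }
  paste(out, collapse = "")
}

# Build one intron (transcript orientation) of length L. Layout: GUAUGU-like
# 5'SS at 1..6, UACUAAC-like BP ending 10-45 nt before the 3' end, an 8-nt
# polypyrimidine tract, then YAG. Returns the sequence plus planted truth
# (branch-A offset, 3'SS pyrimidine quality).
build_intron <- function(L, strength, ppt_quality) {
  s <- strsplit(rand_seq(L), "")[[1]]
  gap3 <- sample(10:min(45L, L - 20L), 1)
  ppt <- (L - 10):(L - 3)
  s[ppt] <- ifelse(stats::runif(8) < ppt_quality,
                   sample(c("C", "T"), 8, replace = TRUE),
                   sample(c("A", "G"), 8, replace = TRUE))
  bp_end <- L - gap3
  bp_motif <- strsplit(draw_motif("TACTAAC", strength,
                                  fixed = c(F, F, F, F, F, TRUE, F)), "")[[1]]
  s[(bp_end - 6):bp_end] <- bp_motif
  s[1:6] <- strsplit(draw_motif("GTATGT", strength,
                                fixed = c(TRUE, TRUE, F, F, F, F)), "")[[1]]
  y <- if (stats::runif(1) < strength) sample(c("C", "T"), 1) else sample(c("A", "G"), 1)
  s[(L - 2):L] <- c(y, "A", "G")
  # a real intron has one branch point: scrub accidental extra copies of
  # the exact consensus arising from the random background
  seq_str <- paste(s, collapse = "")
  repeat {
    occ <- gregexpr("TACTAAC", seq_str, fixed = TRUE)[[1]]
    occ <- occ[occ > 0 & occ != bp_end - 6L]
    if (!length(occ)) break
    substr(seq_str, occ[1] + 3L, occ[1] + 3L) <- "G"
  }
  s <- strsplit(seq_str, "")[[1]]
  ss3_quality <- sum(s[ppt] %in% c("C", "T")) + (y %in% c("C", "T"))
  list(seq = paste(s, collapse = ""), branch_offset = bp_end - 1L,
       ss3_quality = ss3_quality)
}

#' Generate the synthetic genome, annotation and planted event truth
#'
#' Lays out genes (with the configured intron structure and motif
#' degeneracy) on two nuclear contigs plus a mitochondrial decoy, plants one
#' novel splice event per intron-containing gene (classes drawn uniformly
#' from u5/d5/u3/d3, exon skipping for two-intron genes) and cryptic introns
#' in a subset of intron-less genes, and assigns every event a true SEF per
#' strain. All randomness derives from `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with `genome` (a [genome_model()] whose introns carry BP
#'   positions), `seqs` (`DNAStringSet`), and `truth` (events with true
#'   per-strain SEF, per-gene abundance, planted feature coefficients,
#'   decoy junction spans).
#' @export
make_genome <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  cfg <- config
  n <- cfg$n_genes
  is_ic <- stats::runif(n) < cfg$frac_intron_containing
  is_rp <- stats::runif(n) < cfg$frac_rp
  two_intron <- is_ic & (stats::runif(n) < cfg$frac_two_intron)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  chrom_of <- ifelse(seq_len(n) <= ceiling(n / 2), "chrI", "chrII")

  genes <- list(); exons <- list(); bp_rows <- list(); ev_rows <- list()
  offsets <- c(chrI = 0L, chrII = 0L)
  chrom_seq <- list(chrI = character(), chrII = character())
  for (g in seq_len(n)) {
    gid <- sprintf("GENE%03d", g)
    tid <- paste0(gid, ".t1")
    chrom <- chrom_of[g]
    n_int <- if (!is_ic[g]) 0L else if (two_intron[g]) 2L else 1L
    ex_len <- sample(cfg$exon_length_range[1]:cfg$exon_length_range[2],
                     n_int + 1L, replace = TRUE)
    parts <- list(); truthi <- list()
    tx <- character(0)
    for (k in seq_len(n_int + 1L)) {
      tx <- c(tx, rand_seq(ex_len[k]))
      parts[[length(parts) + 1]] <- list(type = "exon", len = ex_len[k])
      if (k <= n_int) {
        L <- sample(cfg$intron_length_range[1]:cfg$intron_length_range[2], 1)
        intr <- build_intron(L, cfg$consensus_strength, stats::runif(1, 0.3, 1))
        tx <- c(tx, intr$seq)
        parts[[length(parts) + 1]] <- list(type = "intron", len = L,
                                           branch_offset = intr$branch_offset,
                                           ss3_quality = intr$ss3_quality)
      }
    }
    tx_seq <- paste(tx, collapse = "")
    glen <- nchar(tx_seq)
    gap <- sample(100:300, 1)
    gstart <- offsets[chrom] + gap
    gend <- gstart + glen
    gseq <- if (strands[g] == "+") tx_seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx_seq)))
    chrom_seq[[chrom]] <- c(chrom_seq[[chrom]], rand_seq(gap), gseq)
    offsets[chrom] <- gend

    # transcript offset -> genomic span, 0-based half-open
    tx2gen <- function(t0, t1) {
      if (strands[g] == "+") c(gstart + t0, gstart + t1)
      else c(gend - t1, gend - t0)
    }
    off <- 0L; ex_spans <- list(); int_info <- list()
    for (p in parts) {
      span <- tx2gen(off, off + p$len)
      if (p$type == "exon") {
        ex_spans[[length(ex_spans) + 1]] <- span
      } else {
        bp_t <- off + p$branch_offset - 1L  # 0-based transcript offset of branch A
        bp_g <- if (strands[g] == "+") gstart + bp_t else gend - 1L - bp_t
        int_info[[length(int_info) + 1]] <-
          list(t0 = off, t1 = off + p$len, span = span, bp = bp_g,
               ss3_quality = p$ss3_quality, len = p$len)
      }
      off <- off + p$len
    }
    genes[[g]] <- data.frame(gene_id = gid, chrom = chrom, strand = strands[g],
                             start = gstart, end = gend, rp = is_rp[g],
                             intron_containing = is_ic[g],
                             stringsAsFactors = FALSE)
    exons[[g]] <- do.call(rbind, lapply(ex_spans, function(sp)
      data.frame(transcript_id = tid, gene_id = gid, chrom = chrom,
                 strand = strands[g], start = sp[1], end = sp[2],
                 stringsAsFactors = FALSE)))
    for (ii in int_info) {
      bp_rows[[length(bp_rows) + 1]] <- data.frame(
        chrom = chrom, start = ii$span[1], end = ii$span[2], bp = ii$bp,
        stringsAsFactors = FALSE)
    }

    # plant one novel event per intron-containing gene
    if (n_int == 1L) {
      ii <- int_info[[1]]
      cls <- sample(c("u3", "d3", "u5", "d5"), 1)
      kmax <- switch(cls, u3 = ii$len - 25L, d5 = ii$len - 25L,
                     d3 = ex_len[2] - 20L, u5 = ex_len[1] - 20L)
      k <- sample(3:max(3L, min(30L, kmax)), 1)
      nt <- switch(cls,
                   u3 = c(ii$t0, ii$t1 - k), d3 = c(ii$t0, ii$t1 + k),
                   u5 = c(ii$t0 - k, ii$t1), d5 = c(ii$t0 + k, ii$t1))
      span <- tx2gen(nt[1], nt[2])
      ev_rows[[length(ev_rows) + 1]] <- data.frame(
        gene_id = gid, chrom = chrom, strand = strands[g],
        start = span[1], end = span[2], class = paste0("alt",
          substr(cls, 2, 2), "_", if (substr(cls, 1, 1) == "u") "up" else "down"),
        offset = k, ann_start = ii$span[1], ann_end = ii$span[2],
        ann_length = ii$len, ann_ss3_quality = ii$ss3_quality,
        stringsAsFactors = FALSE)
    } else if (n_int == 2L) {
      i1 <- int_info[[1]]; i2 <- int_info[[2]]
      span <- tx2gen(i1$t0, i2$t1)
      ev_rows[[length(ev_rows) + 1]] <- data.frame(
        gene_id = gid, chrom = chrom, strand = strands[g],
        start = span[1], end = span[2], class = "exon_skip", offset = NA,
        ann_start = i1$span[1], ann_end = i1$span[2], ann_length = i1$len,
        ann_ss3_quality = i1$ss3_quality, stringsAsFactors = FALSE)
    }
  }

  # cryptic introns inside intron-less genes
  il <- which(!is_ic)
  n_cr <- min(cfg$n_cryptic, length(il))
  for (g in if (n_cr) sample(il, n_cr) else integer(0)) {
    grow <- genes[[g]]
    L <- sample(cfg$intron_length_range[1]:cfg$intron_length_range[2], 1)
    glen <- grow$end - grow$start
    if (glen < L + 40L) next
    s0 <- grow$start + sample(10:(glen - L - 10L), 1)
    ev_rows[[length(ev_rows) + 1]] <- data.frame(
      gene_id = grow$gene_id, chrom = grow$chrom, strand = grow$strand,
      start = s0, end = s0 + L, class = "cryptic_intron", offset = NA,
      ann_start = NA, ann_end = NA, ann_length = NA, ann_ss3_quality = NA,
      stringsAsFactors = FALSE)
  }

  # mitochondrial decoy contig with junctions
  chrM_len <- 2000L
  decoy <- data.frame(chrom = "chrM", start = c(300L, 700L, 1200L),
                      end = c(400L, 800L, 1300L), stringsAsFactors = FALSE)
  seqs <- Biostrings::DNAStringSet(c(
    chrI = paste(chrom_seq$chrI, collapse = ""),
    chrII = paste(chrom_seq$chrII, collapse = ""),
    chrM = rand_seq(chrM_len)))

  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)
  genome <- genome_model(genes, exons)
  if (length(bp_rows)) {
    bp_tab <- do.call(rbind, bp_rows)
    key <- paste(genome$introns$chrom, genome$introns$start,
                 genome$introns$end, sep = ":")
    genome$introns$bp <- bp_tab$bp[match(
      key, paste(bp_tab$chrom, bp_tab$start, bp_tab$end, sep = ":"))]
  }

  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else NULL
  truth <- assign_true_sef(genome, events, cfg)
  truth$decoy_junctions <- decoy
  list(genome = genome, seqs = seqs, truth = truth)
}

# Per-gene abundance and per-event true SEF under the configured model.
assign_true_sef <- function(genome, events, cfg) {
  g <- genome$genes
  lo <- log(cfg$annotated_depth_range[1]); hi <- log(cfg$annotated_depth_range[2])
  abundance <- setNames(exp(stats::runif(nrow(g), lo, hi)), g$gene_id)
  if (is.null(events)) {
    return(list(events = NULL, abundance = abundance,
                coefs = cfg$feature_coefs, config = cfg))
  }
  slo <- log(cfg$base_sef_range[1]); shi <- log(cfg$base_sef_range[2])
  m <- nrow(events)
  base <- switch(cfg$sef_model,
    uniform = exp(stats::runif(m, slo, shi)),
    abundance = {
      # inverse coupling: abundant genes make fewer splicing errors
      q <- (log(abundance[events$gene_id]) - lo) / max(hi - lo, 1e-9)
      exp(shi - q * (shi - slo) + stats::rnorm(m, 0, 0.25))
    },
    features = {
      z <- function(v) {
        v <- as.numeric(v); v[is.na(v)] <- mean(v, na.rm = TRUE)
        if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
      }
      co <- cfg$feature_coefs
      mid <- (shi + slo) / 2 / log(2)
      log2sef <- mid + co[["length"]] * z(events$ann_length) +
        co[["ss3"]] * z(events$ann_ss3_quality) +
        stats::rnorm(m, 0, co[["noise_sd"]])
      2^log2sef
    })
  base <- pmin(pmax(base, cfg$base_sef_range[1] / 10), cfg$base_sef_range[2])
  rp <- g$rp[match(events$gene_id, g$gene_id)]
  base[rp] <- base[rp] * cfg$rp_sef_factor
  events$event_id <- sprintf("true_ev%03d", seq_len(m))
  events$true_sef <- base
  for (st in names(cfg$strain_fold_changes)) {
    p <- base * cfg$strain_fold_changes[[st]]
    if (any(p >= 1)) stop("true SEF x strain multiplier >= 1; invalid config")
    events[[paste0("sef_", st)]] <- p
  }
  list(events = events, abundance = abundance, coefs = cfg$feature_coefs,
       config = cfg)
}

#' Simulate per-sample junction counts in the SJ.out.tab dialect
#'
#' Annotated-junction reads are negative binomial around the gene abundance
#' (dispersion from the config); novel-junction reads are binomial given the
#' annotated count with success probability = true SEF x strain multiplier;
#' cryptic-junction reads are binomial given the host gene's read count.
#' Replicates are independent. Junctions with zero reads in a sample are
#' absent from that sample's table, as an aligner would emit.
#'
#' @param genome,truth from [make_genome()].
#' @param config the same [simulation_config()].
#' @return list with `tables` (named list of per-sample SJ data.frames),
#'   `samples` (sample/strain/replicate design), `gene_counts` (per-gene
#'   per-sample read counts for RPKM), and `truth` passed through.
#' @export
simulate_junction_counts <- function(genome, truth, config) {
  set.seed(config$seed + 1L)
  cfg <- config
  strains <- names(cfg$strain_fold_changes)
  samples <- expand.grid(replicate = seq_len(cfg$n_replicates),
                         strain = strains, stringsAsFactors = FALSE)
  samples$sample <- paste0(samples$strain, "_r", samples$replicate)
  samples <- samples[, c("sample", "strain", "replicate")]
  ints <- genome$introns
  ev <- truth$events
  size <- 1 / cfg$dispersion
  tables <- list(); gene_counts <- list()
  for (s in seq_len(nrow(samples))) {
    st <- samples$strain[s]
    mult <- cfg$strain_fold_changes[[st]]
    rows <- list()
    # annotated junctions
    ann_reads <- integer(nrow(ints))
    if (nrow(ints)) {
      mu <- truth$abundance[ints$gene_id]
      ann_reads <- stats::rnbinom(nrow(ints), mu = mu, size = size)
      keep <- ann_reads > 0
      if (any(keep)) {
        rows[[length(rows) + 1]] <- data.frame(
          chrom = ints$chrom[keep], start = ints$start[keep],
          end = ints$end[keep], strand = ints$strand[keep],
          motif = ifelse(ints$strand[keep] == "+", 1L, 2L), annotated = 1L,
          unique_reads = ann_reads[keep], multi_reads = 0L,
          max_overhang = sample(20:40, sum(keep), replace = TRUE),
          stringsAsFactors = FALSE)
      }
    }
    # per-gene read counts (RPKM denominators)
    greads <- stats::rnbinom(nrow(genome$genes),
                             mu = truth$abundance[genome$genes$gene_id],
                             size = size)
    gene_counts[[length(gene_counts) + 1]] <- data.frame(
      gene_id = genome$genes$gene_id, sample = samples$sample[s],
      reads = greads, stringsAsFactors = FALSE)
    # novel events
    if (!is.null(ev) && nrow(ev)) {
      nov <- integer(nrow(ev))
      for (i in seq_len(nrow(ev))) {
        p <- min(ev$true_sef[i] * mult, 1 - 1e-9)
        if (ev$class[i] == "cryptic_intron") {
          ntrials <- greads[match(ev$gene_id[i], genome$genes$gene_id)]
        } else {
          arow <- which(ints$chrom == ev$chrom[i] &
                          ints$start == ev$ann_start[i] &
                          ints$end == ev$ann_end[i])[1]
          ntrials <- if (!is.na(arow)) ann_reads[arow] else 0L
        }
        nov[i] <- if (ntrials > 0) stats::rbinom(1, ntrials, p) else 0L
      }
      keep <- nov > 0
      if (any(keep)) {
        rows[[length(rows) + 1]] <- data.frame(
          chrom = ev$chrom[keep], start = ev$start[keep], end = ev$end[keep],
          strand = ev$strand[keep],
          motif = ifelse(ev$strand[keep] == "+", 1L, 2L), annotated = 0L,
          unique_reads = nov[keep], multi_reads = 0L,
          max_overhang = sample(13:30, sum(keep), replace = TRUE),
          stringsAsFactors = FALSE)
      }
    }
    # mitochondrial decoys
    dec <- truth$decoy_junctions
    rows[[length(rows) + 1]] <- data.frame(
      chrom = dec$chrom, start = dec$start, end = dec$end, strand = "+",
      motif = 1L, annotated = 0L,
      unique_reads = sample(10:100, nrow(dec), replace = TRUE),
      multi_reads = 0L, max_overhang = 20L, stringsAsFactors = FALSE)
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$chrom, tab$start, tab$end), , drop = FALSE]
    rownames(tab) <- NULL
    tables[[samples$sample[s]]] <- tab
  }
  list(tables = tables, samples = samples,
       gene_counts = do.call(rbind, gene_counts), truth = truth)
}

#' Simulate labelled read intervals for the pre-mRNA fraction
#'
#' Draws reads of the four classes (junction, boundary, intron, exonic)
#' from intron-containing genes at a requested mixture, with the generating
#' class recorded, so the read classifier and the pre-mRNA fraction can be
#' checked against ground truth.
#'
#' @param genome,seqs from [make_genome()] (`seqs` unused; reads are
#'   intervals only).
#' @param config the [simulation_config()].
#' @param n_reads total reads (default 2000).
#' @param mixture named class probabilities, summing to 1.
#' @param read_len contiguous read length (default 50; shortened when an
#'   intron is too small).
#' @return data.frame: `read_id`, `gene_id`, `chrom`, `strand`, `blocks`
#'   ("start-end" 0-based half-open, comma-separated), `true_class`.
#' @export
simulate_interval_reads <- function(genome, config, n_reads = 2000L,
                                    mixture = c(junction = 0.25, boundary = 0.25,
                                                intron = 0.25, exonic = 0.25),
                                    read_len = 50L) {
  set.seed(config$seed + 2L)
  stopifnot(abs(sum(mixture) - 1) < 1e-8)
  ints <- genome$introns
  if (!nrow(ints)) stop("genome has no introns")
  classes <- sample(names(mixture), n_reads, replace = TRUE, prob = mixture)
  rows <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    r <- ints[sample(nrow(ints), 1), ]
    ex <- genome$exons[genome$exons$gene_id == r$gene_id, ]
    cls <- classes[i]
    blocks <- switch(cls,
      junction = {
        k <- sample(10:(read_len - 10L), 1)
        sprintf("%d-%d,%d-%d", r$start - k, r$start, r$end, r$end + (read_len - k))
      },
      boundary = {
        # contiguous read straddling the donor-side exon-intron border
        s0 <- r$start - sample(10:(read_len - 10L), 1)
        sprintf("%d-%d", s0, s0 + read_len)
      },
      intron = {
        len <- min(read_len, r$end - r$start - 2L)
        s0 <- r$start + sample(1:max(1L, r$end - r$start - len - 1L), 1)
        sprintf("%d-%d", s0, s0 + len)
      },
      exonic = {
        e <- ex[sample(nrow(ex), 1), ]
        len <- min(read_len, e$end - e$start - 2L)
        s0 <- e$start + sample(1:max(1L, e$end - e$start - len - 1L), 1)
        sprintf("%d-%d", s0, s0 + len)
      })
    rows[[i]] <- data.frame(read_id = sprintf("r%05d", i), gene_id = r$gene_id,
                            chrom = r$chrom, strand = r$strand, blocks = blocks,
                            true_class = cls, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Parse a blocks string back into a block matrix
#' @param blocks "start-end,start-end" 0-based half-open.
#' @return integer matrix with columns `start`, `end`.
#' @export
parse_blocks <- function(blocks) {
  parts <- strsplit(strsplit(blocks, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, as.integer))
  colnames(m) <- c("start", "end")
  m
}

#' Write a full simulation to disk (FASTA, GTF, SJ tables, metadata)
#'
#' @param sim output of [make_genome()].
#' @param counts output of [simulate_junction_counts()].
#' @param dir output directory (created).
#' @return `dir`, invisibly. Files: `genome.fa`, `annotation.gtf`,
#'   `gene_meta.tsv`, `SJ.<sample>.tab`, `samples.tsv`, `gene_counts.tsv`,
#'   `truth.json`.
#' @export
write_simulation <- function(sim, counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$seqs, file.path(dir, "genome.fa"))
  write_gtf(sim$genome, file.path(dir, "annotation.gtf"))
  g <- sim$genome$genes
  utils::write.table(data.frame(gene_id = g$gene_id, rp = as.integer(g$rp),
                                intron_containing = as.integer(g$intron_containing)),
                     file.path(dir, "gene_meta.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (s in names(counts$tables)) {
    write_sj_tab(counts$tables[[s]], file.path(dir, paste0("SJ.", s, ".tab")))
  }
  utils::write.table(counts$samples, file.path(dir, "samples.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(counts$gene_counts, file.path(dir, "gene_counts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  truth <- counts$truth
  truth$config$strain_fold_changes <- as.list(truth$config$strain_fold_changes)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", force = TRUE)
  invisible(dir)
}
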