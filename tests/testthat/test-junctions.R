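test_that("parse_gtf derives introns with 0-based half-open coordinates", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chrI\tx\texon\t1\t100\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t";',
    'chrI\tx\texon\t201\t300\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t";',
    'chrI\tx\texon\t401\t500\t.\t+\t.\tgene_id "g2"; transcript_id "g2.t";'),
    gtf)
  g <- parse_gtf(gtf)
  expect_equal(nrow(g$introns), 1)
  expect_equal(g$introns$start, 100L)
  expect_equal(g$introns$end, 200L)
  # single-exon gene contributes no intron and is flagged intron-less
  expect_false(g$genes$intron_containing[g$genes$gene_id == "g2"])
})

test_that("parse_gtf rejects overlapping-exon transcripts with a warning", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chrI\tx\texon\t1\t100\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t";',
    'chrI\tx\texon\t50\t200\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t";'),
    gtf)
  expect_warning(g <- parse_gtf(gtf), "overlapping")
  expect_equal(nrow(g$introns), 0)
})

test_that("parse_sj_tab implements the 9-column dialect", {
  f <- tempfile()
  writeLines(c("chrI\t101\t200\t1\t1\t1\t42\t7\t25",
               "chrI\t301\t400\t0\t2\t0\t5\t0\t20",
               "chrI\t501\t600\t0\t0\t0\t5\t0\t20"), f)
  sj <- parse_sj_tab(f)
  expect_equal(sj$start[1], 100L)   # 1-based first base -> 0-based
  expect_equal(sj$end[1], 200L)     # 1-based last base -> half-open end
  expect_equal(sj$strand[1], "+")
  expect_equal(sj$unique_reads[1], 42L)
  expect_equal(sj$multi_reads[1], 7L)
  # strand code 0 resolved from canonical motif; non-canonical stays "*"
  expect_equal(sj$strand[2], "-")
  expect_equal(sj$strand[3], "*")
})

test_that("malformed SJ rows error with the line number", {
  f <- tempfile()
  writeLines(c("chrI\t101\t200\t1\t1\t1\t42\t7\t25", "chrI\t5\t6"), f)
  expect_error(parse_sj_tab(f), "line 2")
})

test_that("SJ write -> parse round-trips generator output exactly", {
  cfg <- simulation_config(n_genes = 20, seed = 42)
  sim <- make_genome(cfg)
  counts <- simulate_junction_counts(sim$genome, sim$truth, cfg)
  tab <- counts$tables[[1]]
  f <- tempfile()
  write_sj_tab(tab, f)
  back <- parse_sj_tab(f)
  expect_equal(back, tab)
})

test_that("filter_junctions applies each clause of the support filter", {
  j <- data.frame(
    chrom = c("chrI", "chrI", "chrI", "chrI", "chrM"),
    start = c(100L, 300L, 500L, 700L, 100L),
    end = c(200L, 400L, 600L, 800L, 200L),
    strand = "+", motif = 1L,
    annotated = c(0L, 0L, 1L, 0L, 0L), stringsAsFactors = FALSE)
  counts <- rbind(c(4, 4, 4, 4, 4, 4),   # novel, never reaches 5 -> out
                  c(0, 0, 0, 0, 0, 5),   # novel, 5 in one sample -> in
                  c(50, 50, 50, 50, 50, 50),  # annotated
                  c(50, 50, 50, 50, 50, 50),  # novel, low overhang
                  c(99, 99, 99, 99, 99, 99))  # chrM decoy
  over <- rbind(rep(25, 6), rep(13, 6), rep(2, 6), rep(12, 6), rep(25, 6))
  colnames(counts) <- paste0(rep(c("WT", "fast", "slow"), each = 2),
                             "_r", 1:2)
  jset <- make_jset(j, counts, over)
  out <- filter_junctions(jset)
  keys <- paste(out$junctions$start, out$junctions$end)
  expect_setequal(keys, "300 400")
  # annotated junction with overhang 2 excluded, overhang 3 retained
  over[3, ] <- 3
  out2 <- filter_junctions(make_jset(j, counts, over))
  expect_true("500 600" %in% paste(out2$junctions$start, out2$junctions$end))
  # novel with overhang exactly 12 excluded (needs > 12)
  expect_false("700 800" %in% paste(out2$junctions$start, out2$junctions$end))
})

test_that("event classification is definitional on the plus strand", {
  g <- tiny_genome()
  # annotated intron [100,200); same donor, acceptor 7 nt upstream
  ev <- classify_junction_event("chrT", 100L, 193L, "+", g)
  expect_equal(ev$event_class, "alt3_up")
  expect_equal(ev$label, "u3-7")
  expect_equal(ev$offset, -7L)
  # same acceptor, donor 5 nt downstream (into the intron)
  ev <- classify_junction_event("chrT", 105L, 200L, "+", g)
  expect_equal(ev$event_class, "alt5_down")
  expect_equal(ev$label, "d5-5")
  # both ends annotated
  expect_equal(classify_junction_event("chrT", 100L, 200L, "+", g)$event_class,
               "annotated")
  # neither end shared, intron-containing host
  ev <- classify_junction_event("chrT", 120L, 180L, "+", g)
  expect_equal(ev$event_class, "cryptic_intron")
  expect_true(ev$host_has_introns)
})

test_that("minus-strand offsets follow transcript orientation", {
  g <- tiny_genome()
  # GENE_M intron [500,600), donor at 599, acceptor at 500.
  # donor 4 nt downstream (3'-ward) on - strand: intron end shrinks to 596
  ev <- classify_junction_event("chrT", 500L, 596L, "-", g)
  expect_equal(ev$event_class, "alt5_down")
  expect_equal(ev$label, "d5-4")
  # acceptor 7 nt upstream (toward transcript 5' = higher coordinate)
  ev <- classify_junction_event("chrT", 507L, 600L, "-", g)
  expect_equal(ev$event_class, "alt3_up")
  expect_equal(ev$label, "u3-7")
  # brute-force check against the mirrored plus-strand genome: reflect all
  # coordinates through the contig midpoint and flip strand; classes and
  # labels must agree (classification is transcript-oriented).
  W <- 700L
  refl_genes <- g$genes
  refl_genes$strand <- chartr("+-", "-+", refl_genes$strand)
  tmp <- W - refl_genes$end; refl_genes$end <- W - refl_genes$start
  refl_genes$start <- tmp
  refl_ex <- g$exons
  refl_ex$strand <- chartr("+-", "-+", refl_ex$strand)
  tmp <- W - refl_ex$end; refl_ex$end <- W - refl_ex$start; refl_ex$start <- tmp
  gr <- genome_model(refl_genes, refl_ex)
  cases <- data.frame(start = c(100L, 105L, 500L, 507L),
                      end = c(193L, 200L, 596L, 600L),
                      strand = c("+", "+", "-", "-"))
  for (i in seq_len(nrow(cases))) {
    orig <- classify_junction_event("chrT", cases$start[i], cases$end[i],
                                    cases$strand[i], g)
    refl <- classify_junction_event("chrT", W - cases$end[i],
                                    W - cases$start[i],
                                    chartr("+-", "-+", cases$strand[i]), gr)
    expect_equal(refl$event_class, orig$event_class)
    expect_equal(refl$label, orig$label)
  }
})

test_that("exon1-exon3 junctions of two-intron transcripts are exon_skip", {
  genes <- data.frame(gene_id = "g2i", chrom = "chrT", strand = "+",
                      start = 0L, end = 500L, rp = FALSE,
                      intron_containing = TRUE, stringsAsFactors = FALSE)
  exons <- data.frame(transcript_id = "g2i.t", gene_id = "g2i", chrom = "chrT",
                      strand = "+", start = c(0L, 200L, 400L),
                      end = c(100L, 300L, 500L), stringsAsFactors = FALSE)
  g <- genome_model(genes, exons)
  ev <- classify_junction_event("chrT", 100L, 400L, "+", g)
  expect_equal(ev$event_class, "exon_skip")
})

test_that("junctions overlapping no gene land in the unassigned bucket", {
  g <- tiny_genome()
  ev <- classify_junction_event("chrT", 320L, 380L, "+", g)
  expect_equal(ev$event_class, "unassigned")
})

test_that("recovered event classes equal planted classes on generator output", {
  sim <- cached("sim_classify", {
    cfg <- simulation_config(n_genes = 60, frac_intron_containing = 0.8,
                             frac_two_intron = 0.1, seed = 5)
    s <- make_genome(cfg)
    list(sim = s,
         counts = simulate_junction_counts(s$genome, s$truth, cfg))
  })
  jset <- annotate_junctions(junction_set(sim$counts$tables,
                                          sim$counts$samples), sim$sim$genome)
  jset <- filter_junctions(jset)
  ev <- classify_events(jset, sim$sim$genome)
  tr <- sim$sim$truth$events
  key <- function(d) paste(d$chrom, d$start, d$end, sep = ":")
  m <- match(key(ev), key(tr))
  expect_true(all(!is.na(m)))
  expect_equal(ev$event_class, tr$class[m])
  # every filtered junction maps to exactly one bucket
  expect_true(all(ev$event_class %in%
    c("alt5_up", "alt5_down", "alt3_up", "alt3_down", "cryptic_intron",
      "exon_skip", "annotated", "unassigned")))
})
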