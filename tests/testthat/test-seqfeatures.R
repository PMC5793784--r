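test_that("site windows use the stated anchors and spans", {
  chars <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
  seqs <- Biostrings::DNAStringSet(c(chrW = paste(chars, collapse = "")))
  # + strand intron [100, 200): 5'SS window = positions [96, 107)
  w <- extract_site_windows("chrW", 100L, 200L, "+", seqs, bp = 160L)
  expect_equal(w$ss5$seq, paste(chars[97:107], collapse = ""))
  expect_equal(nchar(w$ss5$seq), 11)
  expect_equal(w$ss3$seq, paste(chars[184:203], collapse = ""))
  expect_equal(nchar(w$ss3$seq), 20)
  expect_equal(w$bp$seq, paste(chars[154:163], collapse = ""))
  expect_equal(nchar(w$bp$seq), 10)
  # - strand: brute-force strand flip — reverse-complement the contig,
  # mirror the coordinates, and expect identical windows
  rc <- Biostrings::reverseComplement(seqs[[1]])
  seqs_rc <- Biostrings::DNAStringSet(c(chrW = as.character(rc)))
  W <- 400L
  w_minus <- extract_site_windows("chrW", W - 200L, W - 100L, "-", seqs_rc,
                                  bp = W - 1L - 160L)
  expect_equal(w_minus$ss5$seq, w$ss5$seq)
  expect_equal(w_minus$ss3$seq, w$ss3$seq)
  expect_equal(w_minus$bp$seq, w$bp$seq)
  # contig-edge windows are truncated and flagged
  w_edge <- extract_site_windows("chrW", 2L, 60L, "+", seqs)
  expect_true(w_edge$ss5$truncated)
})

test_that("PWM training implements pseudocount normalization", {
  p0 <- train_pwm(rep("ACG", 10), alpha = 0)
  expect_equal(unname(p0["A", 1]), 1)
  expect_equal(unname(p0["C", 2]), 1)
  p <- train_pwm("A", alpha = 0.5)
  expect_equal(unname(p["A", 1]), 1.5 / 3)
  expect_equal(unname(p["C", 1]), 0.5 / 3)
  set.seed(2)
  pr <- train_pwm(replicate(20, random_dna(8)))
  expect_equal(unname(colSums(pr)), rep(1, 8))
  expect_error(train_pwm(c("AA", "AAA")), "equal length")
})

test_that("sequence scoring equals the direct product oracle", {
  unif <- matrix(0.25, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(score_sequence(unif, "ACGT"), -8)
  expect_equal(score_sequence(train_pwm(rep("TTTT", 5), alpha = 0), "TTTT"), 0)
  set.seed(3)
  for (i in 1:20) {
    pwm <- train_pwm(replicate(10, random_dna(6)))
    s <- random_dna(6)
    direct <- log2(prod(vapply(1:6, function(j)
      pwm[substr(s, j, j), j], numeric(1))))
    expect_equal(score_sequence(pwm, s), direct, tolerance = 1e-12)
  }
})

test_that("rescaled scores span 0 to 100 and preserve order", {
  expect_equal(rescale_scores(c(-10, -5, 0)), c(0, 50, 100))
  set.seed(5)
  x <- rnorm(30)
  y <- rescale_scores(x)
  expect_equal(y[which.max(x)], 100)
  expect_equal(y[which.min(x)], 0)
  expect_equal(cor(x, y, method = "spearman"), 1)
  # invariance under affine transforms of X
  expect_equal(rescale_scores(3 * x - 7), y)
  d <- rescale_scores(rep(1.5, 4))
  expect_equal(as.numeric(d), rep(100, 4))
  expect_true(attr(d, "degenerate"))
})

test_that("branch-point search finds the consensus and breaks ties 3'-ward", {
  intron <- paste0("GTATGT", strrep("G", 30), "TACTAAC", strrep("G", 14),
                   "TAG")
  pos <- find_branch_point(intron)
  expect_equal(substr(intron, pos, pos), "A")
  expect_equal(pos, 6 + 30 + 6)  # branch A = 6th base of the motif
  two <- paste0("GTATGT", strrep("G", 10), "TACTAAC", strrep("G", 10),
                "TACTAAC", strrep("G", 14), "TAG")
  expect_equal(find_branch_point(two), 6 + 10 + 7 + 10 + 6)
  expect_true(is.na(find_branch_point(paste0(strrep("G", 40), "TAG"))))
})

test_that("planted branch points are recovered in consensus-strength-1 introns", {
  cfg <- simulation_config(n_genes = 40, frac_intron_containing = 1,
                           consensus_strength = 1, seed = 17)
  sim <- make_genome(cfg)
  ints <- sim$genome$introns
  hits <- vapply(seq_len(nrow(ints)), function(i) {
    iseq <- fetch_seq(sim$seqs, ints$chrom[i], ints$start[i], ints$end[i],
                      ints$strand[i])$seq
    pos <- find_branch_point(iseq)
    if (is.na(pos)) return(FALSE)
    bp_genomic <- if (ints$strand[i] == "+") ints$start[i] + pos - 1L
                  else ints$end[i] - pos
    bp_genomic == ints$bp[i]
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("k-mer frequencies cover the 84-entry registry", {
  expect_length(kmer_registry(), 84)
  f <- kmer_frequencies("AAAA")
  expect_equal(unname(f[c("A", "AA", "AAA")]), c(1, 1, 1))
  expect_equal(sum(f > 0), 3)
  f2 <- kmer_frequencies("ACGT")
  expect_equal(unname(f2[c("A", "C", "G", "T")]), rep(0.25, 4))
  expect_length(kmer_frequencies(random_dna(50)), 84)
  # one-mer frequencies sum to 1 for any sequence
  expect_equal(sum(kmer_frequencies(random_dna(33))[1:4]), 1)
  # too-short sequences leave higher k missing
  expect_true(all(is.na(kmer_frequencies("AC")[
    nchar(kmer_registry()) == 3])))
})

test_that("folding proxy equals exhaustive structure enumeration", {
  expect_equal(fold_energy_proxy("AAAA"), 0)
  expect_equal(fold_energy_proxy("GGGCCC"), -1 / 6)
  set.seed(19)
  for (i in 1:40) {
    s <- random_dna(sample(4:12, 1))
    expect_equal(fold_energy_proxy(s) * nchar(s), -pairs_oracle(s),
                 info = s)
  }
  # more self-complementary sequences fold lower; proxy is never positive
  expect_lt(fold_energy_proxy(paste0("GCGCGC", "AAAA", "GCGCGC")),
            fold_energy_proxy("GCAAGCAAAAGCAAGC"))
  for (i in 1:10) expect_lte(fold_energy_proxy(random_dna(30)), 0)
  # pluggable engine hook normalizes per nucleotide
  expect_equal(fold_energy_proxy("ACGTACGT", engine = function(s) -4), -0.5)
})

test_that("feature matrix has the documented registry and no gaps on generator events", {
  sim <- cached("sim_features", {
    cfg <- simulation_config(n_genes = 30, frac_intron_containing = 1,
                             frac_two_intron = 0, seed = 23)
    s <- make_genome(cfg)
    list(sim = s, cfg = cfg,
         counts = simulate_junction_counts(s$genome, s$truth, cfg))
  })
  jset <- filter_junctions(annotate_junctions(
    junction_set(sim$counts$tables, sim$counts$samples), sim$sim$genome))
  ev <- classify_events(jset, sim$sim$genome)
  fm <- build_feature_matrix(ev, sim$sim$genome, sim$sim$seqs)
  expect_equal(ncol(fm), 180)
  expect_equal(sum(grepl("^ann_k_|^nov_k_", colnames(fm))), 168)
  expect_true(all(is.finite(fm[, "nov_length"])))
  expect_true(all(fm[, grepl("_k_", colnames(fm))] >= 0 &
                    fm[, grepl("_k_", colnames(fm))] <= 1, na.rm = TRUE))
  # annotated intron lengths match the model
  ints <- sim$sim$genome$introns
  m <- match(ev$paired_intron[match(rownames(fm), ev$event_id)],
             ints$intron_id)
  expect_equal(unname(fm[, "ann_length"]), ints$end[m] - ints$start[m])
})
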