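#' @useDynLib splicefid, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

NUCS <- c("A", "C", "G", "T")

# Fixed windows around the three splice signals, in transcript orientation.
# Anchors: 5'SS = first intron base, 3'SS = last intron base, BP = branch
# adenosine. A window spans anchor-u .. anchor+d-1 inclusive (the anchor
# counts toward the downstream side), giving lengths 11 / 20 / 10.
WINDOWS <- list(ss5 = c(u = 4L, d = 7L),
                ss3 = c(u = 16L, d = 4L),
                bp  = c(u = 7L,  d = 3L))

# Genomic half-open span of a transcript-oriented window around an anchor.
tx_window_span <- function(anchor, strand, u, d) {
  if (strand == "+") c(anchor - u, anchor + d) else c(anchor - d + 1L, anchor + u + 1L)
}

#' Extract 5'SS, 3'SS and BP windows for an intron
#'
#' Windows are 4 nt upstream + 7 nt downstream of the 5'SS (11 nt),
#' 16 nt upstream + 4 nt downstream of the 3'SS (20 nt) and 7 nt upstream +
#' 3 nt downstream of the branch adenosine (10 nt), all in transcript
#' orientation (minus-strand spans reverse-complemented) with the anchor
#' base counted on the downstream side. Windows running off the contig are
#' truncated and flagged.
#'
#' @param chrom,start,end,strand intron span, internal 0-based half-open.
#' @param seqs genome `DNAStringSet`.
#' @param bp genomic 0-based position of the branch adenosine, or NA to
#'   omit the BP window.
#' @return list with `ss5`, `ss3`, `bp` (each a list `seq`, `truncated`;
#'   `bp` is NULL when no BP is given).
#' @export
extract_site_windows <- function(chrom, start, end, strand, seqs, bp = NA) {
  donor <- if (strand == "+") start else end - 1L
  acceptor <- if (strand == "+") end - 1L else start
  w5 <- tx_window_span(donor, strand, WINDOWS$ss5["u"], WINDOWS$ss5["d"])
  w3 <- tx_window_span(acceptor, strand, WINDOWS$ss3["u"], WINDOWS$ss3["d"])
  out <- list(ss5 = fetch_seq(seqs, chrom, w5[1], w5[2], strand),
              ss3 = fetch_seq(seqs, chrom, w3[1], w3[2], strand),
              bp = NULL)
  if (!is.na(bp)) {
    wb <- tx_window_span(as.integer(bp), strand, WINDOWS$bp["u"], WINDOWS$bp["d"])
    out$bp <- fetch_seq(seqs, chrom, wb[1], wb[2], strand)
  }
  out
}

#' Train a position weight matrix from aligned windows
#'
#' Per-position empirical nucleotide frequencies with a pseudocount added
#' to each nucleotide before normalization. Non-ACGT characters are ignored
#' at their position (flagged via the `skipped` attribute).
#'
#' @param seqs character vector of equal-length sequences.
#' @param alpha pseudocount per nucleotide (default 0.5).
#' @return a `pwm`: 4 x k numeric matrix (rows A, C, G, T), columns summing
#'   to 1.
#' @export
train_pwm <- function(seqs, alpha = 0.5) {
  stopifnot(length(seqs) >= 1)
  k <- unique(nchar(seqs))
  if (length(k) != 1) stop("sequences must have equal length")
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  skipped <- FALSE
  w <- matrix(0, 4, k, dimnames = list(NUCS, NULL))
  for (j in seq_len(k)) {
    col <- chars[, j]
    ok <- col %in% NUCS
    if (!all(ok)) skipped <- TRUE
    cnt <- table(factor(col[ok], levels = NUCS)) + alpha
    w[, j] <- cnt / sum(cnt)
  }
  structure(w, class = c("pwm", "matrix"), skipped = skipped)
}

#' Log2 probability of a sequence under a PWM
#'
#' X = sum over positions of log2 p_i(s_i), assuming positional
#' independence. Sequences containing non-ACGT characters score NA.
#'
#' @param pwm a [train_pwm()] matrix.
#' @param seq character sequence of length `ncol(pwm)`.
#' @return log2 probability (scalar).
#' @export
score_sequence <- function(pwm, seq) {
  s <- strsplit(toupper(seq), "")[[1]]
  if (length(s) != ncol(pwm)) stop("sequence length != PWM width")
  if (!all(s %in% NUCS)) return(NA_real_)
  sum(log2(pwm[cbind(match(s, NUCS), seq_along(s))]))
}

#' Rescale log2 PWM scores linearly to 0-100
#'
#' Y = (X - min X) / (max X - min X) * 100 over the score set; the set
#' maximum maps to 100 and the minimum to 0. A degenerate set (max = min)
#' maps everything to 100 (every member is maximal) with attribute
#' `degenerate = TRUE`.
#'
#' @param x numeric vector of log2 scores (NAs pass through).
#' @return rescaled scores in \[0, 100\].
#' @export
rescale_scores <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[1] == rng[2]) {
    return(structure(ifelse(is.na(x), NA_real_, 100), degenerate = TRUE))
  }
  (x - rng[1]) / (rng[2] - rng[1]) * 100
}

# Seed BP matrix: canonical branch motif (UACUAAC, branch adenosine at its
# 6th position) laid out so the branch A sits at the window anchor
# (position u+1 = 8 of the 10-nt window); uniform elsewhere.
bp_seed_pwm <- function(strength = 0.9) {
  w <- matrix(0.25, 4, 10, dimnames = list(NUCS, NULL))
  cons <- c("T", "A", "C", "T", "A", "A", "C")  # window pos 3..9, branch A at 8
  for (i in seq_along(cons)) {
    w[, i + 2] <- (1 - strength) / 3
    w[cons[i], i + 2] <- strength
  }
  structure(w, class = c("pwm", "matrix"))
}

#' Locate the branch-point adenosine in an intron
#'
#' Scans candidate adenosines (transcript orientation, excluding the final
#' 3 nt of the intron) and returns the position whose BP window scores
#' highest under the PWM; ties break toward the 3'-most site (the
#' biologically typical 10-45 nt BP-to-3'SS geometry). Candidates whose
#' window would leave the intron are skipped. Annotated BPs should be used
#' when available; this search is the fallback.
#'
#' @param intron_seq intron sequence, transcript orientation.
#' @param bp_pwm 10-column PWM (default: consensus-seeded).
#' @return 1-based position of the branch A within the intron, or NA when
#'   no eligible adenosine exists.
#' @export
find_branch_point <- function(intron_seq, bp_pwm = bp_seed_pwm()) {
  n <- nchar(intron_seq)
  u <- WINDOWS$bp["u"]; d <- WINDOWS$bp["d"]
  s <- strsplit(toupper(intron_seq), "")[[1]]
  cand <- which(s == "A")
  cand <- cand[cand > u & cand + d - 1 <= n & cand <= n - 3]
  if (!length(cand)) return(NA_integer_)
  scores <- vapply(cand, function(pos) {
    win <- substr(intron_seq, pos - u, pos + d - 1)
    score_sequence(bp_pwm, win)
  }, numeric(1))
  best <- max(scores)
  cand[max(which(scores >= best - 1e-12))]  # 3'-most maximal
}

#' The 84-entry k-mer registry (4 one-mers, 16 two-mers, 64 three-mers)
#' @return character vector of length 84 in lexicographic order within k.
#' @export
kmer_registry <- function() {
  k2 <- as.vector(outer(NUCS, NUCS, paste0))
  k3 <- as.vector(outer(as.vector(outer(NUCS, NUCS, paste0)), NUCS, paste0))
  c(NUCS, sort(k2), sort(k3))
}

#' k-mer frequencies of a sequence
#'
#' For k in 1..3, each k-mer count divided by (L - k + 1). Sequences
#' shorter than k leave those entries NA.
#'
#' @param seq character sequence.
#' @return named numeric vector of length 84 following [kmer_registry()].
#' @export
kmer_frequencies <- function(seq) {
  reg <- kmer_registry()
  out <- setNames(rep(NA_real_, length(reg)), reg)
  L <- nchar(seq)
  seq <- toupper(seq)
  for (k in 1:3) {
    if (L < k) next
    subs <- substring(seq, 1:(L - k + 1), k:L)
    mers <- reg[nchar(reg) == k]
    cnt <- table(factor(subs, levels = mers))
    out[mers] <- as.numeric(cnt) / (L - k + 1)
  }
  out
}

#' Folding free-energy proxy (base-pair maximization), per nucleotide
#'
#' The default engine maximizes the number of nested Watson-Crick or GU
#' pairs with a minimum hairpin loop of 3 unpaired bases (Nussinov dynamic
#' program) and scores -`pair_weight` per pair; the result is divided by
#' sequence length. More self-complementary sequences give more negative
#' values; the proxy is always <= 0. An external thermodynamic engine can
#' be plugged in as a function returning a total free energy, which is
#' normalized per nucleotide the same way.
#'
#' @param seq character sequence (T and U both accepted).
#' @param min_loop minimum unpaired bases in a hairpin loop (default 3).
#' @param pair_weight energy units per pair (default 1).
#' @param engine optional `function(seq) -> total dG` override.
#' @return ΔG-like score per nucleotide (<= 0 for the built-in proxy).
#' @export
fold_energy_proxy <- function(seq, min_loop = 3L, pair_weight = 1,
                              engine = NULL) {
  n <- nchar(seq)
  if (n == 0) return(0)
  total <- if (is.null(engine)) {
    -pair_weight * .nussinov_max_pairs(seq, as.integer(min_loop))
  } else {
    engine(seq)
  }
  total / n
}

# Scalar features of one intron span (transcript orientation sequence
# handling inside). Returns log2 PWM scores (rescaling happens at the
# matrix level) plus length and folding proxies.
intron_scalar_features <- function(chrom, start, end, strand, seqs, pwms,
                                   bp_genomic = NA) {
  len <- end - start
  iseq <- fetch_seq(seqs, chrom, start, end, strand)
  if (is.na(bp_genomic)) {
    pos <- find_branch_point(iseq$seq, pwms$bp %||% bp_seed_pwm())
    if (!is.na(pos)) {
      bp_genomic <- if (strand == "+") start + pos - 1L else end - pos
    }
  }
  win <- extract_site_windows(chrom, start, end, strand, seqs, bp = bp_genomic)
  x5 <- if (!win$ss5$truncated) score_sequence(pwms$ss5, win$ss5$seq) else NA_real_
  x3 <- if (!win$ss3$truncated) score_sequence(pwms$ss3, win$ss3$seq) else NA_real_
  xb <- if (!is.null(win$bp) && !win$bp$truncated)
    score_sequence(pwms$bp, win$bp$seq) else NA_real_
  dg_intron <- fold_energy_proxy(iseq$seq)
  # BP-3'SS region: from the base after the branch A to the intron end
  dg_bp3 <- NA_real_
  if (!is.na(bp_genomic)) {
    span <- if (strand == "+") c(bp_genomic + 1L, end) else c(start, bp_genomic)
    if (span[2] > span[1]) {
      r <- fetch_seq(seqs, chrom, span[1], span[2], strand)
      dg_bp3 <- fold_energy_proxy(r$seq)
    }
  }
  list(length = len, dg_intron = dg_intron, dg_bp3 = dg_bp3,
       x5 = x5, x3 = x3, xbp = xb, kmers = kmer_frequencies(iseq$seq))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train splice-signal PWMs from a genome's annotated introns
#'
#' 5'SS and 3'SS windows come straight from the annotation; BP windows from
#' annotated BP positions when present, otherwise from a consensus-seeded
#' scan of each intron ([find_branch_point()]) followed by one retraining
#' pass on the found windows.
#'
#' @param genome a [genome_model()].
#' @param seqs genome `DNAStringSet`.
#' @param alpha PWM pseudocount.
#' @return list of `pwm`s: `ss5`, `ss3`, `bp`.
#' @export
train_site_pwms <- function(genome, seqs, alpha = 0.5) {
  ints <- genome$introns
  if (!nrow(ints)) stop("genome has no introns to train on")
  w5 <- character(); w3 <- character(); wb <- character()
  for (i in seq_len(nrow(ints))) {
    bp <- ints$bp[i]
    if (is.na(bp)) {
      iseq <- fetch_seq(seqs, ints$chrom[i], ints$start[i], ints$end[i],
                        ints$strand[i])
      pos <- find_branch_point(iseq$seq)
      if (!is.na(pos)) {
        bp <- if (ints$strand[i] == "+") ints$start[i] + pos - 1L
              else ints$end[i] - pos
      }
    }
    win <- extract_site_windows(ints$chrom[i], ints$start[i], ints$end[i],
                                ints$strand[i], seqs, bp = bp)
    if (!win$ss5$truncated) w5 <- c(w5, win$ss5$seq)
    if (!win$ss3$truncated) w3 <- c(w3, win$ss3$seq)
    if (!is.null(win$bp) && !win$bp$truncated) wb <- c(wb, win$bp$seq)
  }
  list(ss5 = train_pwm(w5, alpha), ss3 = train_pwm(w3, alpha),
       bp = if (length(wb)) train_pwm(wb, alpha) else bp_seed_pwm())
}

#' Per-event sequence-feature matrix
#'
#' One row per novel event; columns are the 6 scalar features (intron
#' length, ΔG per nt for the intron and the BP-3'SS region, and the
#' rescaled 0-100 5'SS / 3'SS / BP scores) plus the 84 k-mer frequencies,
#' each computed for the annotated (paired) intron and for the novel
#' intron: 180 columns. Score rescaling pools annotated and novel windows
#' per site class, so 0 and 100 are the set extremes. Missing features
#' (truncated windows, absent paired intron) are NA; imputation is left to
#' model time.
#'
#' @param events event table from [classify_events()].
#' @param genome a [genome_model()].
#' @param seqs genome `DNAStringSet`.
#' @param pwms PWMs from [train_site_pwms()] (trained on annotated introns
#'   when omitted).
#' @return numeric matrix with rownames = event ids and the registry
#'   serialized in the `registry` attribute.
#' @export
build_feature_matrix <- function(events, genome, seqs, pwms = NULL) {
  if (is.null(pwms)) pwms <- train_site_pwms(genome, seqs)
  keep <- !(events$event_class %in% c("annotated", "unassigned"))
  events <- events[keep, , drop = FALSE]
  scal_names <- c("length", "dg_intron", "dg_bp3", "score5", "score3", "scorebp")
  reg <- c(paste0("ann_", scal_names), paste0("ann_k_", kmer_registry()),
           paste0("nov_", scal_names), paste0("nov_k_", kmer_registry()))
  n <- nrow(events)
  feats_ann <- vector("list", n); feats_nov <- vector("list", n)
  for (i in seq_len(n)) {
    ev <- events[i, ]
    feats_nov[[i]] <- intron_scalar_features(ev$chrom, ev$start, ev$end,
                                             ev$strand, seqs, pwms)
    if (!is.na(ev$paired_intron)) {
      a <- genome$introns[match(ev$paired_intron, genome$introns$intron_id), ]
      feats_ann[[i]] <- intron_scalar_features(a$chrom, a$start, a$end,
                                               a$strand, seqs, pwms,
                                               bp_genomic = a$bp)
    }
  }
  # pool annotated + novel log2 scores per site class, then rescale 0-100
  pull <- function(lst, what) vapply(lst, function(f)
    if (is.null(f)) NA_real_ else f[[what]], numeric(1))
  resc <- function(xa, xn) {
    y <- rescale_scores(c(xa, xn))
    list(a = y[seq_along(xa)], n = y[length(xa) + seq_along(xn)])
  }
  s5 <- resc(pull(feats_ann, "x5"), pull(feats_nov, "x5"))
  s3 <- resc(pull(feats_ann, "x3"), pull(feats_nov, "x3"))
  sb <- resc(pull(feats_ann, "xbp"), pull(feats_nov, "xbp"))
  block <- function(lst, sc5, sc3, scb) {
    do.call(rbind, lapply(seq_along(lst), function(i) {
      f <- lst[[i]]
      if (is.null(f)) return(rep(NA_real_, 6 + 84))
      c(f$length, f$dg_intron, f$dg_bp3, sc5[i], sc3[i], scb[i], f$kmers)
    }))
  }
  mat <- cbind(block(feats_ann, s5$a, s3$a, sb$a),
               block(feats_nov, s5$n, s3$n, sb$n))
  dimnames(mat) <- list(events$event_id, reg)
  structure(mat, registry = reg)
}
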