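#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided P by the minimum-likelihood convention: conditioning on
#' the margins, sum the hypergeometric probabilities of all tables whose
#' probability does not exceed that of the observed table (with a 1e-7
#' relative slack for floating-point ties).
#'
#' @param a,b,c,d nonnegative integer cells, row-wise: \code{rbind(c(a, b),
#'   c(c, d))}. Vectors recycle.
#' @return two-sided P value(s) in (0, 1\]. Empty-margin tables return P = 1
#'   (degenerate; there is only one table with those margins).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(c(a, b, c, d) < 0)) stop("cells must be nonnegative")
  vapply(seq_len(n), function(i) {
    r1 <- a[i] + b[i]; c1 <- a[i] + c[i]; tot <- a[i] + b[i] + c[i] + d[i]
    if (r1 == 0 || c1 == 0 || r1 == tot || c1 == tot) return(1)
    support <- max(0, c1 - (tot - r1)):min(r1, c1)
    probs <- stats::dhyper(support, c1, tot - c1, r1)
    obs <- probs[match(a[i], support)]
    min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg step-up q-values
#'
#' q_i = min over j with p_(j) >= p_(i) of p_(j) * m / rank(j), clipped to
#' \[0, 1\]; the standard monotone step-up adjustment.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (!m) return(numeric(0))
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Mutant-vs-WT contrasts on pooled junction counts
#'
#' For each event, builds the 2x2 table (novel, annotated) x (mutant, WT)
#' from replicate-pooled counts, computes the two-sided Fisher P, BH q
#' across the tested events of the contrast, the log2 SEF ratio mutant/WT,
#' and the fidelity direction.
#'
#' @param sef per-event-per-strain table from [sef_table()] (intronic
#'   events with defined counts are tested; strict-filter failures are
#'   excluded, mirroring the robustness filter).
#' @param wt name of the reference strain (default "WT").
#' @param mutants strains contrasted against WT; default all others.
#' @param p_cut,q_cut significance thresholds (defaults 0.01 and 0.03).
#' @return data.frame with one row per event x contrast: the 2x2 cells
#'   (`novel_mut`, `annot_mut`, `novel_wt`, `annot_wt`), `p`, `q`,
#'   `log2_ratio`, `direction` in \{reduced_fidelity, increased_fidelity,
#'   ns\}.
#' @export
contrast_strains <- function(sef, wt = "WT", mutants = NULL,
                             p_cut = 0.01, q_cut = 0.03) {
  if (is.null(mutants)) mutants <- setdiff(unique(sef$strain), wt)
  sef <- sef[sef$sef_type == "intronic" & !sef$undefined &
               sef$passes_strict_filter, , drop = FALSE]
  out <- list()
  for (mut in mutants) {
    m <- sef[sef$strain == mut, ]
    w <- sef[sef$strain == wt, ]
    common <- intersect(m$event_id, w$event_id)
    if (!length(common)) next
    m <- m[match(common, m$event_id), ]
    w <- w[match(common, w$event_id), ]
    p <- fisher_exact_2x2(m$novel, m$annotated, w$novel, w$annotated)
    q <- bh_fdr(p)
    log2_ratio <- log2(m$sef) - log2(w$sef)
    dir <- call_direction(p, q, m$sef, w$sef, m$novel, w$novel,
                          p_cut = p_cut, q_cut = q_cut)
    out[[mut]] <- data.frame(
      event_id = common, gene_id = m$gene_id, event_class = m$event_class,
      label = m$label, rp = m$rp, contrast = paste0(mut, "-vs-", wt),
      novel_mut = m$novel, annot_mut = m$annotated, novel_wt = w$novel,
      annot_wt = w$annotated, sef_mut = m$sef, sef_wt = w$sef,
      p = p, q = q, log2_ratio = log2_ratio, direction = dir,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fidelity direction call for a contrast
#'
#' Significant iff P < `p_cut` and q < `q_cut`; then `reduced_fidelity`
#' when the mutant SEF exceeds WT (more splicing errors) and
#' `increased_fidelity` when it is lower. When either SEF is zero or
#' undefined the sign is taken from the novel-read counts.
#'
#' @param p,q per-event P and q values.
#' @param sef_mut,sef_wt per-event SEF in mutant and WT.
#' @param novel_mut,novel_wt pooled novel counts (sign fallback).
#' @param p_cut,q_cut thresholds.
#' @return character vector in \{"reduced_fidelity", "increased_fidelity",
#'   "ns"\}.
#' @export
call_direction <- function(p, q, sef_mut, sef_wt, novel_mut = NULL,
                           novel_wt = NULL, p_cut = 0.01, q_cut = 0.03) {
  sig <- p < p_cut & q < q_cut
  delta <- sef_mut - sef_wt
  bad <- is.na(delta) | delta == 0
  if (any(bad) && !is.null(novel_mut)) {
    delta[bad] <- (novel_mut - novel_wt)[bad]
  }
  out <- rep("ns", length(p))
  out[sig & !is.na(delta) & delta > 0] <- "reduced_fidelity"
  out[sig & !is.na(delta) & delta < 0] <- "increased_fidelity"
  out[is.na(delta)] <- "ns"
  out
}

#' Stratify contrast calls by RP status and fidelity direction
#'
#' @param contrasts output of [contrast_strains()].
#' @return data.frame per contrast x \{RP, non-RP\}: counts of reduced and
#'   increased fidelity calls and their ratio (NA when the increased count
#'   is 0 — flagged, not infinite).
#' @export
stratify <- function(contrasts) {
  if (is.null(contrasts) || !nrow(contrasts)) return(data.frame())
  grid <- expand.grid(contrast = unique(contrasts$contrast),
                      rp = c(TRUE, FALSE), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sub <- contrasts[contrasts$contrast == grid$contrast[i] &
                       contrasts$rp == grid$rp[i], ]
    red <- sum(sub$direction == "reduced_fidelity")
    inc <- sum(sub$direction == "increased_fidelity")
    data.frame(contrast = grid$contrast[i],
               stratum = if (grid$rp[i]) "RP" else "non-RP",
               n_events = nrow(sub), reduced = red, increased = inc,
               significant = red + inc,
               ratio = if (inc > 0) red / inc else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
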