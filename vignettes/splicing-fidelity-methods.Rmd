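---
title: "Models and methods behind splicefid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind splicefid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Splicing is accurate but not perfect: deep RNA-seq of yeast strains in
which nonsense-mediated decay is disabled reveals low-frequency use of
unannotated 5′ and 3′ splice sites, cryptic introns in normally
intron-less transcripts, and rare exon skipping. splicefid quantifies
these errors, tests whether their frequency changes between strains
(e.g. RNA polymerase II elongation-rate mutants versus wild type), and
asks which intron sequence features predict error-proneness.

# The SEF statistic

For a novel junction inside an intron-containing gene,

$$\mathrm{SEF} = \frac{\text{unique reads on the novel junction}}
                     {\text{unique reads on the annotated junction}}.$$

Replicates are **pooled by summation within strain before the ratio**.
The source literature reports per-strain SEF without stating pooling; for
a binomial "error per splicing event" model the pooled ratio is the
maximum-likelihood estimate, whereas averaging per-replicate ratios is
not, and the two genuinely differ on unbalanced replicates (a fixture in
the test suite pins this choice down).

For cryptic introns in intron-less genes there is no annotated junction;
the statistic is `cryptic reads / RPKM` of the host transcript, exactly
as conventionally printed. These units are sequencing-depth dependent
(doubling depth doubles the value at fixed transcript mix — a test
documents this); a per-million-mapped normalized variant is available but
off by default to match the conventional form.

An event enters downstream analyses only if some strain shows at least 5
novel reads in *both* replicates (the robustness filter), on top of the
junction-level filters: ≥ 5 unique reads in at least one sample, aligner
overhang ≥ 3 (annotated) or > 12 (novel), and exclusion of mitochondrial
contigs, whose junctions are not spliceosomal.

# Event taxonomy and coordinates

Internally every interval is 0-based half-open; conversions to the
1-based inclusive GTF and SJ conventions happen only at parse/write
boundaries, which removes a whole class of off-by-one ambiguity.
Classification is transcript-oriented: "upstream" always means toward
the transcript 5′ end, so a `u3-7` label (alternative 3′SS 7 nt upstream)
means the same thing on either genomic strand. A junction sharing its
donor with an annotated intron but not its acceptor is an alternative
3′SS event; sharing the acceptor only, an alternative 5′SS event; joining
the donor of intron *k* to the acceptor of intron *k + 1*, exon skipping.
A junction sharing neither end is classed `cryptic_intron`; when the host
gene does have introns this is flagged `host_has_introns` rather than
silently merged — the literature pools these, and we preserve the
distinction instead of guessing.

When a junction overlaps two genes we assign the gene sharing a splice
site, then the larger overlap, then the lexicographically smaller id —
an arbitrary but deterministic tie-break.

# Differential fidelity

Each event is tested mutant-vs-WT on the 2×2 table (novel, annotated) ×
(mutant, WT) of pooled counts with a two-sided Fisher's exact test using
the minimum-likelihood summation convention (two-sided exact conventions
differ between tools; ours sums all tables whose conditional probability
does not exceed the observed one, with a 1e-7 relative tie slack). The
FDR procedure is Benjamini–Hochberg — the source names only "FDR", and
BH is the standard choice for this design. Defaults `P < 0.01`,
`FDR < 0.03`. Significant events with higher mutant SEF are
`reduced_fidelity`, lower are `increased_fidelity`; when a SEF is zero on
one side the direction falls back to the novel-count comparison.
Both test and FDR are implemented in the package (not delegated to
`stats`) so that the test suite can check them against genuinely
independent oracles: exhaustive enumeration via log binomial coefficients
for Fisher, and the literal step-up definition for BH.

# Sequence features

Windows are anchored on the first intron base (5′SS), the last intron
base (3′SS) and the branch adenosine (BP), spanning 4 + 7, 16 + 4 and
7 + 3 nt with the anchor counted on the downstream side (lengths 11, 20,
10). The anchor convention is not fully specified in the source — only
the offsets are — and this choice is fixed because it places the
canonical GUAUGU / YAG / UACUAAC content inside the windows.

PWMs are per-position empirical frequencies with pseudocount α = 0.5 per
nucleotide (α is our choice; it prevents −∞ log-scores for unseen bases).
Scores are `X = Σ log2 p_i(s_i)`, rescaled linearly over the score set to
[0, 100]; the set maximum is exactly 100, the minimum exactly 0, and a
degenerate set (all equal) maps to 100 with a flag. Rescaling pools the
annotated and novel windows of the analysed events, so both feature
blocks share one scale per site class.

Branch points are taken from annotation when present; otherwise a
consensus-seeded PWM scan over intron adenosines (excluding the final
3 nt) selects the maximal site, breaking ties toward the 3′-most
position, consistent with the typical 10–45 nt BP-to-3′SS geometry. PWMs
used by the pipeline are then retrained on the found windows.

The folding term is a **proxy**, not a thermodynamic model: Nussinov
base-pair maximization (Watson–Crick + GU, minimum hairpin loop 3),
−1 energy unit per pair, divided by sequence length. It is always ≤ 0
and more negative for more self-complementary sequences; a hook accepts
any external engine returning a total ΔG. Acceptance is against the
proxy's own exhaustive-structure enumeration oracle, never against a
thermodynamic reference.

The feature registry is 6 scalars (length, ΔG/nt of the intron, ΔG/nt of
the BP–3′SS region, 5′SS, 3′SS, BP scores) plus 84 k-mer frequencies,
for the annotated and the novel intron: 180 columns. The printed figure
of "176 features" in the source cannot be reconstructed from its own
feature list (plausible groupings give 90, 174, or 180); the registry is
serialized with every matrix and the discrepancy is documented rather
than resolved.

# The SEF predictor

A regression random forest predicts `log2(mean SEF over strains)` for
events passing the strict filter. No random-forest package is available
in the target environment, so the package ships its own (Rcpp): bootstrap
CART trees, variance-reduction splits, `mtry = ⌊√p⌋`, minimum node size
5, 500 trees, impurity importances normalized to sum 1, all randomness
from a dedicated mt19937 stream so a seed fixes the report exactly.
Threefold cross-validation uses stratified-by-target-quantile fold
assignment; reported R is the pooled out-of-fold Pearson correlation
(per-fold values are also reported, since the source does not say which
convention its headline correlation uses). Missing features are imputed
with the *training-fold* column median.

# The synthetic world

The generator emulates a small yeast-like transcriptome: 80 genes by
default (half intron-containing, 30% ribosomal-protein), single short
introns (80–200 nt) carrying GUAUGU-like 5′SS, UACUAAC-like BP ending
10–45 nt before the 3′SS, an 8-nt polypyrimidine tract and YAG end;
motif positions deviate from consensus with probability
`1 − consensus_strength` (default 0.9). Each intron has exactly one
branch point: accidental extra exact copies of the BP consensus arising
from the random background are scrubbed, because a world with two equally
perfect branch points has no well-defined planted truth. Two replicates ×
three strains (WT, fast, slow) mirror the motivating design; both mutants
default to a 2× SEF increase (reduced fidelity predominates in the real
data for both directions of elongation-rate change). Annotated-junction
counts are negative binomial (dispersion 0.1) around a log-uniform
per-gene abundance (2k–20k reads); novel counts are binomial given the
annotated count with success probability `true SEF × strain multiplier`,
rejected at configuration time if that product reaches 1. RP events are
scaled by 0.2, reflecting the much lower error rates of RP transcripts.

Three SEF worlds are available: `uniform` (log-uniform in 1e-3–5e-2 —
the non-RP error regime), `abundance` (inverse log-linear coupling to
expression with 0.25 log-noise, emulating the observed SEF–abundance
anti-correlation), and `features` (log2 SEF decreasing in annotated
intron length and 3′SS quality, Gaussian noise σ = 0.5 log2 units —
chosen a priori to put the theoretical recovery ceiling near R ≈ 0.94,
the same regime as the observed real-data R ≈ 0.8).

What the generator does **not** model: base-call errors, alignment
artifacts, multimapping, fragment-length effects, decay kinetics. A green
test therefore establishes correctness of counting, classification,
statistics and inference given junction-level evidence — not robustness
to upstream alignment pathologies.

# Acceptance-test design notes

* The planted-SEF recovery criterion runs in the `uniform` world, where
  the planted SEF is exact; the `abundance` world deliberately jitters it.
* The predictor-recovery criterion runs with `frac_rp = 0`: its stated
  world is "SEF a monotone function of intron length and 3′SS score plus
  noise", and the RP scaling would add variance those features cannot
  explain. Its planted-feature check accepts the annotated- or
  novel-intron column of each planted driver, which are nearly collinear
  by construction (novel introns differ by ≤ 30 nt).
* Simulation sizes in the test suite (e.g. 300-gene genomes for the
  predictor, 3 × 400 genes for null calibration) are chosen to meet each
  criterion's stated problem size within a single-CPU time budget.

# Known limitations

* The folding proxy ignores stacking thermodynamics; ΔG magnitudes are
  not comparable to mfold/ViennaRNA outputs (signs and ordering are).
* Branch-point discovery is a PWM scan; lariat-sequencing-grade cryptic
  BP inference is out of scope.
* Cryptic-SEF units are depth-dependent by construction (documented
  above).
* The junction parser trusts the aligner's overhang and unique-read
  accounting; BAM-level re-counting is out of scope.
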