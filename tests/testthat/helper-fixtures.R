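# Shared fixtures: a tiny hand-built genome and junction-set builders.

# Two genes: GENE_P on + (exons [0,100) + [200,300)), GENE_M on - strand
# (exons [400,500) + [600,700)), so GENE_P intron = [100,200) with donor at
# 100, GENE_M intron = [500,600) with donor at 599 (transcript 5' end is at
# high coordinates on the minus strand).
tiny_genome <- function(rp = c(FALSE, FALSE)) {
  genes <- data.frame(
    gene_id = c("GENE_P", "GENE_M"), chrom = "chrT",
    strand = c("+", "-"), start = c(0L, 400L), end = c(300L, 700L),
    rp = rp, intron_containing = TRUE, stringsAsFactors = FALSE)
  exons <- data.frame(
    transcript_id = rep(c("GENE_P.t1", "GENE_M.t1"), each = 2),
    gene_id = rep(c("GENE_P", "GENE_M"), each = 2),
    chrom = "chrT", strand = rep(c("+", "-"), each = 2),
    start = c(0L, 200L, 400L, 600L), end = c(100L, 300L, 500L, 700L),
    stringsAsFactors = FALSE)
  genome_model(genes, exons)
}

# junction_set from a compact spec: one row per junction, counts given as a
# matrix (junction x sample).
make_jset <- function(junctions, counts, overhang = NULL,
                      samples = NULL) {
  if (is.null(samples)) {
    samples <- data.frame(sample = colnames(counts),
                          strain = sub("_r[0-9]+$", "", colnames(counts)),
                          replicate = as.integer(sub(".*_r", "", colnames(counts))),
                          stringsAsFactors = FALSE)
  }
  if (is.null(overhang)) overhang <- matrix(25L, nrow(counts), ncol(counts))
  ids <- paste(junctions$chrom, junctions$start, junctions$end, sep = ":")
  dimnames(counts) <- list(ids, samples$sample)
  dimnames(overhang) <- dimnames(counts)
  structure(list(junctions = junctions, counts = counts, overhang = overhang,
                 samples = samples), class = "junction_set")
}

# Cached small simulations so several test files can share one generator run.
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}
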