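# Independent oracles and tiny in-code fixtures shared across tests.

# translate through Biostrings' sequence machinery (a different code path
# than the package's lookup table)
oracle_translate <- function(codon) {
  as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                     no.init.codon = TRUE))
}

# brute-force effect classification: translate both codons and compare
oracle_classify <- function(codon, pos, alt) {
  mut <- codon
  substr(mut, pos, pos) <- alt
  aa_ref <- oracle_translate(codon)
  aa_mut <- oracle_translate(mut)
  if (aa_mut == "*") "nonsense"
  else if (aa_mut == aa_ref) "synonymous"
  else "nonsynonymous"
}

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

non_stop_codons <- function() {
  cds <- all_codons()
  cds[vapply(cds, oracle_translate, character(1)) != "*"]
}

# exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# choose(nx+ny, nx) group assignments of the pooled sample (no ties)
oracle_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  u_of <- function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    sum(outer(xx, yy, ">"))
  }
  combs <- utils::combn(length(pooled), nx)
  us <- apply(combs, 2L, u_of)
  u_obs <- sum(outer(x, y, ">"))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# cache shared across acceptance tests (one full-scale gene set)
acc_cache <- new.env(parent = emptyenv())

# a hand-built two-gene genome fixture written to tempdir; returns paths
# and the expected gene table pieces.
#   contig layout (1-based): 1-4 spacer TTTT, 5-13 geneA (+) ATGGAACTG,
#   14-17 spacer ACGT, 18-26 geneB (-) with gene-strand cds ATGCCTGAA
#   (genome slice = revcomp = TTCAGGCAT), 27-30 spacer GGGG
toy_genome_fixture <- function(dir = tempfile("toyfix")) {
  dir.create(dir, showWarnings = FALSE)
  geneA <- "ATGGAACTG"
  geneB <- "ATGCCTGAA"
  genome <- paste0("TTTT", geneA, "ACGT",
                   synmut::reverse_complement(geneB), "GGGG")
  fa <- file.path(dir, "toy.fa")
  writeLines(c(">chr", genome), fa)
  gff <- file.path(dir, "toy.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr\ttest\tCDS\t5\t13\t.\t+\t0\tID=geneA",
    "chr\ttest\tCDS\t18\t26\t.\t-\t0\tID=geneB"), gff)
  list(dir = dir, fa = fa, gff = gff, genome = genome,
       geneA = geneA, geneB = geneB)
}

# small cohort used by several suites; deterministic
small_cohort <- function(n_genes = 40, n_sub = 80, seed = 101,
                         rate_mode = "length_null") {
  params <- cohort_params(n_genes = n_genes, n_substitutions = n_sub,
                          rate_mode = rate_mode)
  gg <- generate_genes(params, seed = seed)
  ex <- generate_experiment(gg$genes, params, seed = seed + 1L)
  list(params = params, genes = gg$genes, genome = gg$genome,
       mutations = ex$mutations, truth = ex$truth, model = ex$model)
}
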