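test_that("load_annotations round-trips the toy fixture", {
  fix <- toy_genome_fixture()
  genes <- load_annotations(fix$fa, fix$gff)
  expect_s3_class(genes, "gene_table")
  expect_identical(nrow(genes), 2L)
  expect_identical(genes$cds[genes$gene_id == "geneA"], fix$geneA)
  # minus-strand cds equals the reverse complement of the genome slice
  expect_identical(genes$cds[genes$gene_id == "geneB"], fix$geneB)
  expect_identical(substr(fix$genome, 18, 26),
                   reverse_complement(fix$geneB))
  expect_identical(genes$start, c(4L, 17L))  # 0-based half-open
  expect_identical(genes$end, c(13L, 26L))
  expect_identical(nrow(attr(genes, "rejects")), 0L)
})

test_that("invalid CDS features are rejected with named reasons", {
  fix <- toy_genome_fixture()
  gff <- file.path(fix$dir, "bad.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr\ttest\tCDS\t5\t13\t.\t+\t0\tID=geneA",
    "chr\ttest\tCDS\t5\t14\t.\t+\t0\tID=badLen",     # 10 bp
    "chr\ttest\tCDS\t5\t200\t.\t+\t0\tID=badRange",  # beyond contig
    "chrX\ttest\tCDS\t5\t13\t.\t+\t0\tID=badContig"), gff)
  expect_warning(genes <- load_annotations(fix$fa, gff), "excluded")
  rejects <- attr(genes, "rejects")
  expect_identical(genes$gene_id, "geneA")
  expect_setequal(rejects$gene_id, c("badLen", "badRange", "badContig"))
  expect_identical(rejects$reason[rejects$gene_id == "badLen"],
                   "not divisible by 3")
})

test_that("annotation is codon- and strand-aware on hand-worked examples", {
  fix <- toy_genome_fixture()
  genes <- load_annotations(fix$fa, fix$gff)
  genome <- c(chr = fix$genome)

  # + strand geneA (starts at offset 4): genome position 7 is codon 1
  # position 3; ATG -> ATA is Met -> Ile, nonsynonymous
  m1 <- data.frame(contig = "chr", position = 7L, ref_base = "G",
                   alt_base = "A", clone_id = "c1",
                   lineage_class = "nonmutator")
  a1 <- annotate_mutations(m1, genes, genome = genome)
  expect_identical(a1$gene_id, "geneA")
  expect_identical(a1$codon_index, 1L)
  expect_identical(a1$codon_position, 3L)
  expect_identical(a1$effect, "nonsynonymous")

  # - strand geneB, gene-strand codon 3 is GAA; its third base sits at
  # genome position 18 on the genome strand as complement(A) = T... the
  # gene-strand change G->A at codon 2 position 3 (CCT -> CCA? no):
  # work from the genome: genome position 21 = C; gene-strand offset =
  # end - position = 26 - 21 = 5 -> codon 2, position 3: CCT -> gene
  # base T; genome C -> T means gene-strand A... instead place a clean
  # synonymous case: gene-strand codon 2 CCT -> CCC (Pro/Pro) is gene
  # change T->C at offset 5, genome position end - offset = 26 - 5 = 21,
  # genome bases complement: A -> G
  expect_identical(substr(fix$genome, 21, 21), "A")
  m2 <- data.frame(contig = "chr", position = 21L, ref_base = "A",
                   alt_base = "G", clone_id = "c1",
                   lineage_class = "nonmutator")
  a2 <- annotate_mutations(m2, genes, genome = genome)
  expect_identical(a2$gene_id, "geneB")
  expect_identical(a2$codon_index, 2L)
  expect_identical(a2$codon_position, 3L)
  expect_identical(a2$effect, "synonymous")
  # spectrum from genome-strand bases A>G: AT_to_GC (same class either way)
  expect_identical(a2$spectrum, "AT_to_GC")

  # intergenic mutation keeps its spectrum, no effect, not core
  m3 <- data.frame(contig = "chr", position = 2L, ref_base = "T",
                   alt_base = "C", clone_id = "c1",
                   lineage_class = "nonmutator")
  a3 <- annotate_mutations(m3, genes, genome = genome)
  expect_true(is.na(a3$gene_id))
  expect_identical(a3$effect, "intergenic")
  expect_identical(a3$spectrum, "AT_to_GC")
  expect_false(a3$in_core)

  # reference mismatch against the ancestor is an error naming the spot
  m4 <- data.frame(contig = "chr", position = 7L, ref_base = "C",
                   alt_base = "A", clone_id = "c1",
                   lineage_class = "nonmutator")
  expect_error(annotate_mutations(m4, genes, genome = genome),
               "ref mismatch at chr:7")
})

test_that("overlapping genes resolve deterministically with a flag", {
  fix <- toy_genome_fixture()
  gff <- file.path(fix$dir, "overlap.gff3")
  # two + strand CDS sharing positions 5..13
  writeLines(c(
    "##gff-version 3",
    "chr\ttest\tCDS\t5\t13\t.\t+\t0\tID=gZZ",
    "chr\ttest\tCDS\t5\t13\t.\t+\t0\tID=gAA"), gff)
  genes <- load_annotations(fix$fa, gff)
  m <- data.frame(contig = "chr", position = 7L, ref_base = "G",
                  alt_base = "A", clone_id = "c", lineage_class = "x")
  ann <- annotate_mutations(m, genes)
  expect_identical(ann$gene_id, "gAA")  # lexicographically smallest
  expect_true(ann$ambiguous)
})

test_that("event conservation and effect round-trip hold on a cohort", {
  sc <- small_cohort()
  ann <- annotate_mutations(sc$mutations, sc$genes, genome = sc$genome)
  expect_identical(sum(!is.na(ann$gene_id)) + sum(is.na(ann$gene_id)),
                   nrow(sc$mutations))
  # re-extract each codon from the stored cds and re-classify
  for (i in which(!is.na(ann$gene_id))) {
    g <- sc$genes[sc$genes$gene_id == ann$gene_id[i], ]
    codon <- substr(g$cds, (ann$codon_index[i] - 1) * 3 + 1,
                    ann$codon_index[i] * 3)
    alt <- if (g$strand == "+") ann$alt_base[i] else
      reverse_complement(ann$alt_base[i])
    expect_identical(classify_substitution(codon, ann$codon_position[i],
                                           alt), ann$effect[i])
  }
})

test_that("annotation is invariant under full genome reverse-complement", {
  sc <- small_cohort(n_genes = 12, n_sub = 40, seed = 303)
  L <- nchar(sc$genome)
  ann <- annotate_mutations(sc$mutations, sc$genes, genome = sc$genome)

  # mirror the world: revcomp genome, flip strands and coordinates
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc_genome <- stats::setNames(reverse_complement(unname(sc$genome)),
                               names(sc$genome))
  g <- sc$genes
  genes_rc <- gene_table(g$gene_id, g$contig,
                         start = L - g$end, end = L - g$start,
                         strand = ifelse(g$strand == "+", "-", "+"),
                         cds = g$cds, theta_s = g$theta_s,
                         expression = g$expression)
  m <- sc$mutations
  m_rc <- transform(m, position = L - position + 1L,
                    ref_base = unname(comp[ref_base]),
                    alt_base = unname(comp[alt_base]))
  ann_rc <- annotate_mutations(m_rc, genes_rc, genome = rc_genome)
  expect_identical(ann_rc$gene_id, ann$gene_id)
  expect_identical(ann_rc$effect, ann$effect)
  expect_identical(ann_rc$spectrum, ann$spectrum)
  expect_identical(ann_rc$codon_index, ann$codon_index)
  expect_identical(ann_rc$codon_position, ann$codon_position)
})

test_that("core_synonymous_set keeps exactly core synonymous events", {
  base <- data.frame(
    contig = "chr", position = 1:6, ref_base = "A", alt_base = "G",
    clone_id = c("c1", "c1", "c2", "c2", "c3", "c3"),
    lineage_class = "nonmutator",
    gene_id = paste0("g", 1:6),
    codon_index = 1L, codon_position = 3L,
    effect = c("synonymous", "synonymous", "synonymous", "nonsynonymous",
               "nonsynonymous", "synonymous"),
    spectrum = "AT_to_GC",
    in_core = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  out <- core_synonymous_set(base)
  expect_identical(nrow(out), 3L)
  expect_setequal(out$gene_id, c("g1", "g2", "g3"))
  expect_identical(sum(attr(out, "per_gene")$n_syn), 3L)
  empty <- core_synonymous_set(base[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("VCF and TSV mutation readers behave and skip non-SNVs", {
  d <- tempfile("muts"); dir.create(d)
  f <- file.path(d, "clone.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "Ara-1", sep = "\t"),
    "chr\t10\t.\tA\tG\t.\tPASS\t.\tGT\t1",
    "chr\t20\t.\tAT\tA\t.\tPASS\t.\tGT\t1",   # indel: skipped
    "chr\t30\t.\tC\tT\t.\tPASS\t.\tGT\t1"), f)
  expect_message(m <- read_mutations(f), "skipped 1 non-SNV")
  expect_identical(nrow(m), 2L)
  expect_identical(unique(m$clone_id), "Ara-1")  # from the sample column
  expect_identical(m$position, c(10L, 30L))

  tsv <- file.path(d, "muts.tsv")
  utils::write.table(
    data.frame(contig = "chr", position = 5L, ref_base = "G",
               alt_base = "T"),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  mt <- read_mutations(tsv, clone_id = "cX", lineage_class = "nonmutator")
  expect_identical(mt$clone_id, "cX")
  expect_identical(mt$lineage_class, "nonmutator")

  # empty VCF reads as zero rows without error
  fe <- file.path(d, "empty.vcf")
  write_vcf(data.frame(contig = character(0), position = integer(0),
                       ref_base = character(0), alt_base = character(0)),
            fe, sample_id = "none")
  expect_identical(nrow(read_mutations(fe)), 0L)
})
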