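# Ground-truth-labeled synthetic inputs: a gene complement with realistic
# length / theta_s / expression distributions, an ancestral genome with
# GFF3 annotation, natural-isolate codon alignments under an infinite-sites
# amino-acid-invariant model, and experimental mutation cohorts drawn from
# configurable per-gene rate models and lineage-specific spectra.
#
# The default cohort mirrors the scale of the 40,000-generation experiment:
# 2,834 core genes, 12 clones (4 mismatch-repair hypermutators, 2 mutT
# hypermutators, 6 nonmutators), 1,069 core synonymous substitutions of
# which ~1,055 fall in hypermutator lineages.

.non_stop_codons <- local({
  all64 <- names(.codon_table)
  all64[.codon_table != "*"]
})

# default per-lineage spectrum probabilities over the six collapsed classes
.default_spectra <- list(
  MMR_hypermutator = c(AT_to_GC = 0.35, CG_to_TA = 0.55, AT_to_CG = 0.025,
                       AT_to_TA = 0.025, CG_to_AT = 0.025, CG_to_GC = 0.025),
  mutT_hypermutator = c(AT_to_GC = 0.02, CG_to_TA = 0.02, AT_to_CG = 0.90,
                        AT_to_TA = 0.02, CG_to_AT = 0.02, CG_to_GC = 0.02),
  nonmutator = c(AT_to_GC = 0.20, CG_to_TA = 0.30, AT_to_CG = 0.125,
                 AT_to_TA = 0.125, CG_to_AT = 0.125, CG_to_GC = 0.125)
)

# default 12-clone complement: 4 MMR-deficient, 2 mutT-deficient,
# 6 nonmutator; expected event shares put ~1,055 of 1,069 substitutions in
# the hypermutator lineages
.default_clones <- function() {
  data.frame(
    clone_id = c("Ara-2", "Ara-3", "Ara-4", "Ara+3", "Ara-1", "Ara+6",
                 paste0("non", 1:6)),
    lineage_class = c(rep("MMR_hypermutator", 4), rep("mutT_hypermutator", 2),
                      rep("nonmutator", 6)),
    weight = c(rep(200, 4), rep(127.5, 2), rep(14 / 6, 6)),
    stringsAsFactors = FALSE)
}

#' Parameters of a synthetic evolution-experiment cohort
#'
#' Defaults state the emulated world: ~2,834 protein-coding genes with a
#' lognormal length distribution (median ~950 bp, truncated to 150-6,000 bp,
#' multiples of 3), per-gene theta_s spanning at least 20-fold, expression
#' weakly rank-coupled to gene length (target Pearson r = 0.09), 1,069
#' synonymous substitutions distributed under a chosen rate model, and a
#' 12-clone lineage mix with class-specific mutation spectra. `N_e`, `mu`
#' and `t` document the neutral expectations (2 N_e mu differences between
#' two natural isolates; t mu substitutions along an experimental lineage);
#' when `n_substitutions` is `NULL` the expected count `t * mu * total
#' coding sites` is used.
#'
#' @param n_genes Number of genes (>= 2).
#' @param length_meanlog,length_sdlog,length_range Lognormal gene-length
#'   law and truncation bounds (bp).
#' @param theta_meanlog,theta_sdlog Lognormal theta_s law.
#' @param theta_fold_range Guaranteed minimum max/min ratio of theta_s.
#' @param expression_meanlog,expression_sdlog Lognormal expression law.
#' @param expression_length_r Target Pearson correlation between
#'   expression and gene length.
#' @param rate_mode Rate model used to place substitutions (see
#'   [build_rate_model()]).
#' @param n_substitutions Total substitutions to draw (`NULL` = t mu L).
#' @param clones data.frame `clone_id`, `lineage_class`, `weight`.
#' @param spectra Named list: lineage_class -> probability vector over
#'   [SPECTRUM_CLASSES], each summing to 1.
#' @param N_e Effective (haploid) population size of the natural cohort.
#' @param mu Per-site per-generation point-mutation rate.
#' @param t Generations of experimental evolution.
#' @param spacer_range Intergenic spacer length bounds (bp).
#' @param contig Name of the synthetic chromosome.
#' @return List of class `cohort_params`.
#' @export
cohort_params <- function(n_genes = 2834,
                          length_meanlog = log(950), length_sdlog = 0.55,
                          length_range = c(150, 6000),
                          theta_meanlog = log(0.02), theta_sdlog = 0.6,
                          theta_fold_range = 20,
                          expression_meanlog = log(100),
                          expression_sdlog = 1,
                          expression_length_r = 0.09,
                          rate_mode = "length_null",
                          n_substitutions = 1069,
                          clones = .default_clones(),
                          spectra = .default_spectra,
                          N_e = 2.5e7, mu = 8.9e-11, t = 40000,
                          spacer_range = c(50, 200),
                          contig = "chr_syn") {
  if (n_genes < 2) stop("n_genes must be >= 2", call. = FALSE)
  for (cls in unique(clones$lineage_class)) {
    pr <- spectra[[cls]]
    if (is.null(pr) || abs(sum(pr) - 1) > 1e-9 || any(pr < 0)) {
      stop("spectrum probabilities for class ", cls,
           " must be nonnegative and sum to 1", call. = FALSE)
    }
  }
  if (any(c(N_e, mu, t) < 0)) stop("rates must be >= 0", call. = FALSE)
  structure(list(n_genes = n_genes, length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog, length_range = length_range,
                 theta_meanlog = theta_meanlog, theta_sdlog = theta_sdlog,
                 theta_fold_range = theta_fold_range,
                 expression_meanlog = expression_meanlog,
                 expression_sdlog = expression_sdlog,
                 expression_length_r = expression_length_r,
                 rate_mode = rate_mode, n_substitutions = n_substitutions,
                 clones = clones, spectra = spectra,
                 N_e = N_e, mu = mu, t = t, spacer_range = spacer_range,
                 contig = contig),
            class = "cohort_params")
}

# Gaussian copula: couple expression to the rank of gene length. The
# Pearson target attenuates through the nonlinear margins; to first
# Hermite order r = rho * lambda_len * lambda_expr, where
# lambda_expr = cor(Z, lognormal(Z)) = s e^{s^2/2} / sqrt(e^{s^2}(e^{s^2}-1))
# in closed form and lambda_len = cor(normal scores, length) is computed
# from the drawn lengths, so rho is calibrated analytically, not tuned.
# Consumes RNG state.
.coupled_expression <- function(len, params) {
  n <- length(len)
  z_len <- stats::qnorm((rank(len, ties.method = "average") - 0.5) / n)
  s <- params$expression_sdlog
  lambda_expr <- s * exp(s^2 / 2) / sqrt(exp(s^2) * (exp(s^2) - 1))
  lambda_len <- stats::cor(z_len, len)
  rho <- min(params$expression_length_r / (lambda_expr * lambda_len), 0.99)
  z_expr <- rho * z_len + sqrt(1 - rho^2) * stats::rnorm(n)
  stats::qlnorm(stats::pnorm(z_expr), params$expression_meanlog,
                params$expression_sdlog)
}

#' Draw length-coupled expression values
#'
#' The generator's expression model in isolation: lognormal expression
#' rank-coupled to the supplied gene lengths through a Gaussian copula
#' calibrated to `params$expression_length_r`.
#'
#' @param length_bp Gene lengths (bp).
#' @param params A [cohort_params()].
#' @param seed Integer seed.
#' @return Numeric vector of expression values.
#' @export
draw_coupled_expression <- function(length_bp, params, seed) {
  with_seed(seed, .coupled_expression(length_bp, params))
}

.random_cds <- function(length_bp) {
  n_codon <- length_bp %/% 3L
  paste(c("ATG", sample(.non_stop_codons, n_codon - 1L, replace = TRUE)),
        collapse = "")
}

#' Generate the synthetic gene complement and ancestral genome
#'
#' Gene lengths are lognormal (truncated, rounded to multiples of 3);
#' theta_s is lognormal, stretched in log space when needed so the max/min
#' ratio meets `theta_fold_range`; expression is coupled to length through
#' a Gaussian copula on length ranks, calibrated to the target Pearson
#' correlation. Coding sequences are an ATG followed by random non-stop
#' codons, tiled onto one synthetic chromosome with random intergenic
#' spacers and random strands.
#'
#' @param params A [cohort_params()].
#' @param seed Integer seed.
#' @return List: `genes` (a [gene_table()] with `theta_s` and `expression`
#'   filled), `genome` (named character vector of contig sequences).
#' @export
generate_genes <- function(params, seed) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_genes
  with_seed(seed, {
    len <- stats::rlnorm(n, params$length_meanlog, params$length_sdlog)
    len <- pmin(pmax(len, params$length_range[1]), params$length_range[2])
    len <- pmax(round(len / 3) * 3, 150L)

    theta <- stats::rlnorm(n, params$theta_meanlog, params$theta_sdlog)
    fold <- max(theta) / min(theta)
    if (fold < params$theta_fold_range) {
      # stretch around the geometric mean to exactly hit the target range
      f <- log(params$theta_fold_range) / log(fold)
      theta <- exp(mean(log(theta)) + f * (log(theta) - mean(log(theta))))
    }

    expression <- .coupled_expression(len, params)

    strand <- sample(c("+", "-"), n, replace = TRUE)
    cds <- vapply(len, .random_cds, character(1))
    spacers <- sample(params$spacer_range[1]:params$spacer_range[2], n + 1L,
                      replace = TRUE)
    spacer_seq <- vapply(spacers, function(k)
      paste(sample(DNA_BASES, k, replace = TRUE), collapse = ""),
      character(1))

    pieces <- character(2L * n + 1L)
    start <- integer(n); pos <- 0L
    for (i in seq_len(n)) {
      pieces[2L * i - 1L] <- spacer_seq[i]
      pos <- pos + spacers[i]
      start[i] <- pos
      genome_slice <- if (strand[i] == "-") reverse_complement(cds[i]) else
        cds[i]
      pieces[2L * i] <- genome_slice
      pos <- pos + len[i]
    }
    pieces[2L * n + 1L] <- spacer_seq[n + 1L]
    genome <- stats::setNames(paste(pieces, collapse = ""), params$contig)

    ids <- sprintf("gene%04d", seq_len(n))
    genes <- gene_table(ids, params$contig, start, start + len, strand, cds,
                        theta_s = theta, expression = expression)
    list(genes = genes, genome = genome)
  })
}

#' Simulate a natural-isolate codon alignment for one gene
#'
#' Infinite-sites, amino-acid-invariant model: the number of synonymous
#' segregating sites is Poisson with mean `theta_true * a_n * L_syn`
#' (`a_n` the Watterson harmonic number), each site is a distinct codon
#' chosen uniformly among synonymous-capable codons, the derived base is a
#' uniformly chosen synonymous alternative, and the derived allele is
#' carried by a uniform 1..n-1 random subset of isolates. Amino-acid
#' sequences are identical across isolates by construction.
#'
#' @param gene One row of a [gene_table()] (or any list with `gene_id`,
#'   `cds`, `syn_sites`).
#' @param n_isolates Number of isolates (>= 2).
#' @param theta_true True per-synonymous-site diversity (>= 0).
#' @param seed Integer seed.
#' @return A [codon_alignment()].
#' @export
generate_alignment <- function(gene, n_isolates, theta_true, seed) {
  stopifnot(n_isolates >= 2, theta_true >= 0)
  cds <- gene$cds
  L_syn <- gene$syn_sites
  if (L_syn <= 0) {
    warning("gene ", gene$gene_id, " has no synonymous sites; ",
            "returning an invariant alignment", call. = FALSE)
    return(codon_alignment(gene$gene_id, rep(cds, n_isolates)))
  }
  cand <- synonymous_candidates(cds)
  with_seed(seed, {
    a_n <- harmonic_number(n_isolates - 1)
    S <- stats::rpois(1, theta_true * a_n * L_syn)
    capable <- unique(cand$codon_index)
    if (S > length(capable)) S <- length(capable)
    seqs <- matrix(rep(strsplit(cds, "")[[1]], n_isolates),
                   nrow = n_isolates, byrow = TRUE)
    if (S > 0) {
      codon_hit <- sample(capable, S)
      for (ci in codon_hit) {
        opts <- cand[cand$codon_index == ci, , drop = FALSE]
        pick <- opts[sample.int(nrow(opts), 1L), ]
        k <- sample.int(n_isolates - 1L, 1L)
        carriers <- sample.int(n_isolates, k)
        seqs[carriers, pick$site] <- pick$alt
      }
    }
    codon_alignment(gene$gene_id, apply(seqs, 1L, paste, collapse = ""))
  })
}

#' Enumerate synonymous single-base changes along a coding sequence
#'
#' @param cds Coding sequence (no internal stops).
#' @return data.frame: `codon_index`, `codon_position`, `site` (1-based
#'   nucleotide position in the cds), `ref`, `alt`, `spectrum`
#'   (strand-collapsed class, identical on both strands).
#' @export
synonymous_candidates <- function(cds) {
  codons <- .split_codons(cds)
  out <- list()
  for (cd in unique(codons)) {
    ch <- synonymous_changes(cd)
    if (nrow(ch) == 0L) next
    idx <- which(codons == cd)
    block <- ch[rep(seq_len(nrow(ch)), times = length(idx)), , drop = FALSE]
    block$codon_index <- rep(idx, each = nrow(ch))
    out[[length(out) + 1L]] <- block
  }
  if (length(out) == 0L) {
    return(data.frame(codon_index = integer(0), codon_position = integer(0),
                      site = integer(0), ref = character(0),
                      alt = character(0), spectrum = character(0)))
  }
  res <- do.call(rbind, out)
  res$codon_position <- res$position
  res$site <- (res$codon_index - 1L) * 3L + res$position
  res$spectrum <- vapply(seq_len(nrow(res)), function(i)
    as.character(spectrum_class(res$ref[i], res$alt[i])), character(1))
  rownames(res) <- NULL
  res[, c("codon_index", "codon_position", "site", "ref", "alt", "spectrum")]
}

#' Simulate the evolution-experiment mutation cohort
#'
#' Distributes substitutions over genes by a multinomial draw from the
#' rate model implied by `params$rate_mode`, assigns each event a clone
#' (probability proportional to the clone weights), draws a spectrum class
#' from the clone's lineage spectrum and places the event uniformly among
#' the gene's synonymous changes of that class (rejection sampling over
#' classes, bounded retries, falling back to any synonymous change).
#' Events are emitted in genome coordinates with correct strand handling.
#'
#' @param genes A [gene_table()] with `theta_s` filled (theta rate modes).
#' @param params A [cohort_params()].
#' @param seed Integer seed.
#' @return List: `mutations` (data.frame `contig`, `position`, `ref_base`,
#'   `alt_base`, `clone_id`, `lineage_class` in genome coordinates),
#'   `truth` (data.frame adding `gene_id`, `codon_index`,
#'   `codon_position`, `effect`, `spectrum`), `model` (the
#'   [build_rate_model()] used).
#' @export
generate_experiment <- function(genes, params, seed) {
  stopifnot(inherits(genes, "gene_table"), inherits(params, "cohort_params"))
  model <- build_rate_model(genes, params$rate_mode)
  n_sub <- params$n_substitutions
  if (is.null(n_sub)) {
    n_sub <- round(params$t * params$mu * sum(genes$length_bp))
  }
  clones <- params$clones
  with_seed(seed, {
    per_gene <- as.vector(stats::rmultinom(1, n_sub, model$weights))
    names(per_gene) <- model$gene_ids
    clone_pick <- sample.int(nrow(clones), n_sub, replace = TRUE,
                             prob = clones$weight)
    rows <- vector("list", n_sub)
    ev <- 0L
    for (gi in which(per_gene > 0)) {
      gid <- model$gene_ids[gi]
      g <- genes[genes$gene_id == gid, ]
      cand <- synonymous_candidates(g$cds)
      if (nrow(cand) == 0L) {
        stop("gene ", gid, " has no synonymous changes available",
             call. = FALSE)
      }
      for (k in seq_len(per_gene[gi])) {
        ev <- ev + 1L
        cl <- clones[clone_pick[ev], ]
        probs <- params$spectra[[cl$lineage_class]][SPECTRUM_CLASSES]
        pick <- NULL
        for (try in 1:20) {
          cls <- sample(SPECTRUM_CLASSES, 1L, prob = probs)
          opts <- cand[cand$spectrum == cls, , drop = FALSE]
          if (nrow(opts) > 0L) {
            pick <- opts[sample.int(nrow(opts), 1L), ]
            break
          }
        }
        if (is.null(pick)) {  # spectrum incompatible with this gene
          pick <- cand[sample.int(nrow(cand), 1L), ]
        }
        off <- pick$site - 1L                    # 0-based offset in cds
        if (g$strand == "+") {
          pos0 <- g$start + off
          ref <- pick$ref; alt <- pick$alt
        } else {
          pos0 <- g$end - 1L - off
          ref <- .complement[[pick$ref]]
          alt <- .complement[[pick$alt]]
        }
        rows[[ev]] <- data.frame(
          contig = g$contig, position = pos0 + 1L,
          ref_base = ref, alt_base = alt,
          clone_id = cl$clone_id, lineage_class = cl$lineage_class,
          gene_id = gid, codon_index = pick$codon_index,
          codon_position = pick$codon_position,
          effect = "synonymous", spectrum = pick$spectrum,
          stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
    list(mutations = truth[, c("contig", "position", "ref_base", "alt_base",
                               "clone_id", "lineage_class")],
         truth = truth, model = model)
  })
}

#' Generate and write a complete synthetic cohort
#'
#' Writes genome FASTA, features GFF3, one VCF per clone, a theta_s table,
#' an expression table, a core-gene id list and a ground-truth JSON under
#' `out_dir`. Deterministic given `params` + `seed`.
#'
#' @param params A [cohort_params()].
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the in-memory objects (`genes`, `genome`,
#'   `mutations`, `truth`, `model`) plus `files` naming everything written.
#' @export
simulate_cohort <- function(params, seed, out_dir) {
  gg <- generate_genes(params, seed = derive_seed(seed, 1L))
  exp_ <- generate_experiment(gg$genes, params, seed = derive_seed(seed, 2L))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list(
    genome = file.path(out_dir, "genome.fa"),
    gff = file.path(out_dir, "genes.gff3"),
    theta = file.path(out_dir, "theta_s.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    core = file.path(out_dir, "core_genes.txt"),
    truth = file.path(out_dir, "ground_truth.json"),
    clones = file.path(out_dir, "clones.tsv"))
  write_genome_fasta(gg$genome, files$genome)
  write_gff3(gg$genes, files$gff)
  write_theta_table(gg$genes[, c("gene_id", "theta_s")], files$theta)
  utils::write.table(gg$genes[, c("gene_id", "expression")],
                     files$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(gg$genes$gene_id, files$core)
  utils::write.table(params$clones, files$clones, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  vcf_files <- character(0)
  for (cl in params$clones$clone_id) {
    sub <- exp_$mutations[exp_$mutations$clone_id == cl, , drop = FALSE]
    f <- file.path(out_dir, paste0("clone_", gsub("[^A-Za-z0-9+-]", "_", cl),
                                   ".vcf"))
    write_vcf(sub, f, sample_id = cl)
    vcf_files <- c(vcf_files, f)
  }
  files$vcf <- vcf_files
  jsonlite::write_json(exp_$truth, files$truth, digits = NA)
  invisible(c(gg, exp_, list(files = files)))
}

#' Write a genome as FASTA
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path,
                              width = 70)
  invisible(path)
}

#' Write gene CDS features as GFF3
#' @param genes A [gene_table()].
#' @param path Output path.
#' @export
write_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(genes$contig,
    IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  gr$type <- "CDS"
  gr$ID <- genes$gene_id
  gr$source <- "synmut"
  gr$phase <- 0L
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write point mutations as a minimal single-sample VCF
#' @param muts data.frame `contig`, `position`, `ref_base`, `alt_base`.
#' @param path Output path.
#' @param sample_id Sample column name.
#' @export
write_vcf <- function(muts, path, sample_id = "sample") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=synmut",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample_id, sep = "\t")), con)
  if (nrow(muts) > 0L) {
    ord <- order(muts$contig, muts$position)
    m <- muts[ord, ]
    writeLines(paste(m$contig, m$position, ".", m$ref_base, m$alt_base,
                     ".", "PASS", ".", "GT", "1", sep = "\t"), con)
  }
  invisible(path)
}
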