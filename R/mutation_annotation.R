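# Placement of point mutations on the annotated ancestral genome:
# codon-aware and strand-aware effect classification, spectrum assignment
# on genome-strand bases, and restriction to the core-gene set.
#
# Coordinate convention: GFF3 and VCF are 1-based inclusive on disk; all
# internal arithmetic uses 0-based half-open intervals, converted at the
# single load/annotate boundary.

#' Construct a gene-annotation table
#'
#' The pipeline's central per-gene container: one row per core gene with
#' coordinates (0-based half-open), strand, coding sequence (already
#' reverse-complemented for minus-strand genes), length, Nei-Gojobori
#' synonymous-site count, and optional theta_s and expression.
#'
#' @param gene_id,contig Identifiers.
#' @param start,end Integer 0-based half-open genome coordinates.
#' @param strand `"+"` or `"-"`.
#' @param cds Gene-strand coding sequences.
#' @param theta_s,expression Optional numeric per-gene values.
#' @param syn_sites Optional; computed from `cds` when missing.
#' @param in_core Logical, membership in the core-gene set.
#' @return data.frame of class `gene_table`.
#' @export
gene_table <- function(gene_id, contig, start, end, strand, cds,
                       theta_s = NA_real_, expression = NA_real_,
                       syn_sites = NULL, in_core = TRUE) {
  length_bp <- end - start
  if (any(length_bp != nchar(cds))) {
    stop("cds length must equal end - start", call. = FALSE)
  }
  if (any(length_bp %% 3L != 0L)) {
    stop("gene length must be divisible by 3", call. = FALSE)
  }
  if (is.null(syn_sites)) {
    syn_sites <- vapply(cds, gene_synonymous_sites, numeric(1),
                        USE.NAMES = FALSE)
  }
  out <- data.frame(gene_id = as.character(gene_id),
                    contig = as.character(contig),
                    start = as.integer(start), end = as.integer(end),
                    strand = as.character(strand), cds = as.character(cds),
                    length_bp = as.integer(length_bp),
                    syn_sites = syn_sites,
                    theta_s = theta_s, expression = expression,
                    in_core = in_core, stringsAsFactors = FALSE)
  class(out) <- c("gene_table", "data.frame")
  out
}

#' Load gene annotations from a genome FASTA and GFF3 features
#'
#' CDS features are converted from 1-based inclusive to 0-based half-open
#' coordinates; minus-strand coding sequences are reverse-complemented.
#' Genes failing invariants (missing contig, out of range, length not a
#' multiple of 3, internal stop codons, ambiguous bases) are excluded with
#' a per-gene reason collected in the `rejects` attribute.
#'
#' @param genome_fasta Path to the ancestral genome FASTA.
#' @param gff Path to a GFF3 file; features with type `CDS` are used and
#'   `ID` (fallback `locus_tag`, `Name`) provides the gene id.
#' @param core_ids Optional character vector of core gene ids; genes not
#'   listed are retained with `in_core = FALSE`. `NULL` marks all genes
#'   core.
#' @return A [gene_table()] with attribute `rejects` (data.frame
#'   `gene_id`, `reason`).
#' @export
load_annotations <- function(genome_fasta, gff, core_ids = NULL) {
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  feats <- rtracklayer::import(gff)
  feats <- feats[feats$type == "CDS"]
  ids <- as.character(feats$ID)
  if (all(is.na(ids)) && !is.null(feats$locus_tag)) {
    ids <- as.character(feats$locus_tag)
  }
  if (all(is.na(ids)) && !is.null(feats$Name)) ids <- as.character(feats$Name)
  rej <- list(); keep <- list()
  for (i in seq_along(feats)) {
    gid <- ids[i]
    contig <- as.character(GenomicRanges::seqnames(feats)[i])
    s1 <- GenomicRanges::start(feats)[i]  # 1-based inclusive
    e1 <- GenomicRanges::end(feats)[i]
    strand <- as.character(GenomicRanges::strand(feats)[i])
    if (!(contig %in% names(genome))) {
      rej[[length(rej) + 1L]] <- data.frame(gene_id = gid,
        reason = "missing contig"); next
    }
    if (s1 < 1L || e1 > length(genome[[contig]])) {
      rej[[length(rej) + 1L]] <- data.frame(gene_id = gid,
        reason = "out of contig range"); next
    }
    len <- e1 - s1 + 1L
    if (len %% 3L != 0L) {
      rej[[length(rej) + 1L]] <- data.frame(gene_id = gid,
        reason = "not divisible by 3"); next
    }
    slice <- as.character(Biostrings::subseq(genome[[contig]], s1, e1))
    cds <- if (strand == "-") reverse_complement(slice) else slice
    if (!grepl("^[ACGT]*$", cds)) {
      rej[[length(rej) + 1L]] <- data.frame(gene_id = gid,
        reason = "ambiguous bases"); next
    }
    ss <- tryCatch(gene_synonymous_sites(cds), error = function(e) e)
    if (inherits(ss, "error")) {
      rej[[length(rej) + 1L]] <- data.frame(gene_id = gid,
        reason = conditionMessage(ss)); next
    }
    keep[[length(keep) + 1L]] <- data.frame(gene_id = gid, contig = contig,
      start = s1 - 1L, end = e1, strand = strand, cds = cds,
      syn_sites = ss, stringsAsFactors = FALSE)
  }
  if (length(keep) == 0L) stop("no usable CDS features in ", gff,
                               call. = FALSE)
  k <- do.call(rbind, keep)
  in_core <- if (is.null(core_ids)) TRUE else k$gene_id %in% core_ids
  out <- gene_table(k$gene_id, k$contig, k$start, k$end, k$strand, k$cds,
                    syn_sites = k$syn_sites, in_core = in_core)
  rejects <- if (length(rej) > 0L) do.call(rbind, rej) else
    data.frame(gene_id = character(0), reason = character(0))
  if (nrow(rejects) > 0L) {
    warning(sprintf("%d CDS feature(s) excluded; see attr(x, 'rejects')",
                    nrow(rejects)), call. = FALSE)
  }
  attr(out, "rejects") <- rejects
  out
}

#' Attach theta_s and expression values to a gene table
#'
#' @param genes A [gene_table()].
#' @param theta Optional data.frame (`gene_id`, `theta_s`).
#' @param expression Optional data.frame (`gene_id`, `expression`).
#' @return The gene table with the columns filled by id-match.
#' @export
attach_gene_values <- function(genes, theta = NULL, expression = NULL) {
  if (!is.null(theta)) {
    genes$theta_s <- theta$theta_s[match(genes$gene_id, theta$gene_id)]
  }
  if (!is.null(expression)) {
    genes$expression <-
      expression$expression[match(genes$gene_id, expression$gene_id)]
  }
  genes
}

#' Read point mutations from VCF or tab-delimited tables
#'
#' Only single-nucleotide variants are retained; multi-nucleotide and indel
#' records are skipped with a logged count. VCF is parsed from its text
#' representation (CHROM/POS/REF/ALT); a TSV needs columns `contig`,
#' `position`, `ref_base`, `alt_base` and optionally `clone_id` and
#' `lineage_class`.
#'
#' @param path File path (`.vcf` or tab-delimited).
#' @param clone_id Clone identifier applied to every record (overrides any
#'   column).
#' @param lineage_class One of `"MMR_hypermutator"`, `"mutT_hypermutator"`,
#'   `"nonmutator"`, applied to every record (overrides any column).
#' @return data.frame: `contig`, `position` (1-based), `ref_base`,
#'   `alt_base`, `clone_id`, `lineage_class`.
#' @export
read_mutations <- function(path, clone_id = NULL, lineage_class = NULL) {
  first <- readLines(path, n = 1L)
  is_vcf <- grepl("\\.vcf$", path) || startsWith(first, "##fileformat=VCF")
  if (is_vcf) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "##")]
    header <- sub("^#", "", lines[1])
    body <- lines[-1]
    body <- body[nzchar(body)]
    cols <- strsplit(header, "\t")[[1]]  # raw names, ids kept verbatim
    if (length(body) == 0L) {
      muts <- data.frame(contig = character(0), position = integer(0),
                         ref_base = character(0), alt_base = character(0),
                         stringsAsFactors = FALSE)
    } else {
      tab <- utils::read.table(text = body, sep = "\t",
                               stringsAsFactors = FALSE,
                               colClasses = "character")
      muts <- data.frame(contig = tab[[1]],
                         position = as.integer(tab[[2]]),
                         ref_base = toupper(tab[[4]]),
                         alt_base = toupper(tab[[5]]),
                         stringsAsFactors = FALSE)
    }
    if (is.null(clone_id) && length(cols) >= 10L && nrow(muts) > 0L) {
      # single-sample VCF: the sample column name identifies the clone
      muts$clone_id <- cols[10]
    }
  } else {
    # all-character parse so bases "T"/"F" are not read as logicals
    muts <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE,
                              colClasses = "character")
    req <- c("contig", "position", "ref_base", "alt_base")
    if (!all(req %in% names(muts))) {
      stop("mutation TSV needs columns ", paste(req, collapse = ", "),
           call. = FALSE)
    }
    muts$position <- as.integer(muts$position)
    muts$ref_base <- toupper(muts$ref_base)
    muts$alt_base <- toupper(muts$alt_base)
  }
  snv <- nchar(muts$ref_base) == 1L & nchar(muts$alt_base) == 1L &
    muts$ref_base %in% DNA_BASES & muts$alt_base %in% DNA_BASES
  if (any(!snv)) {
    message(sprintf("skipped %d non-SNV record(s) in %s", sum(!snv), path))
    muts <- muts[snv, , drop = FALSE]
  }
  nr <- nrow(muts)
  if (!is.null(clone_id)) muts$clone_id <- rep(clone_id, nr)
  if (is.null(muts$clone_id)) muts$clone_id <- rep(NA_character_, nr)
  if (!is.null(lineage_class)) muts$lineage_class <- rep(lineage_class, nr)
  if (is.null(muts$lineage_class)) {
    muts$lineage_class <- rep(NA_character_, nr)
  }
  rownames(muts) <- NULL
  muts[, c("contig", "position", "ref_base", "alt_base", "clone_id",
           "lineage_class")]
}

.genes_granges <- function(genes) {
  GenomicRanges::GRanges(genes$contig,
    IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = "*")
}

#' Annotate point mutations against a gene table
#'
#' Each mutation is mapped into its containing gene (if any). For
#' minus-strand genes, ref/alt bases are complemented before the codon
#' lookup; the spectrum class is always computed on the original
#' genome-strand bases (it is strand-collapsed, so this is a convention,
#' not a choice of answer). A mutation inside overlapping genes is assigned
#' deterministically to the lexicographically smallest gene id and flagged
#' `ambiguous`.
#'
#' @param muts data.frame as from [read_mutations()]; `position` 1-based.
#' @param genes A [gene_table()].
#' @param genome Optional named character vector or `DNAStringSet` of
#'   contig sequences; when supplied, each `ref_base` is checked against
#'   the ancestral genome and a mismatch is an error.
#' @return data.frame with the input columns plus `gene_id` (NA when
#'   intergenic), `codon_index`, `codon_position` (1-based within gene),
#'   `effect` (`synonymous`/`nonsynonymous`/`nonsense`/`intergenic`),
#'   `spectrum`, `in_core`, `ambiguous`.
#' @export
annotate_mutations <- function(muts, genes, genome = NULL) {
  stopifnot(inherits(genes, "gene_table"))
  n <- nrow(muts)
  if (!is.null(genome)) {
    if (inherits(genome, "DNAStringSet")) {
      genome <- stats::setNames(as.character(genome),
                                sub("\\s.*$", "", names(genome)))
    }
    for (i in seq_len(n)) {
      gb <- substr(genome[[muts$contig[i]]], muts$position[i],
                   muts$position[i])
      if (gb != muts$ref_base[i]) {
        stop(sprintf(
          "ref mismatch at %s:%d: genome has %s, mutation table has %s",
          muts$contig[i], muts$position[i], gb, muts$ref_base[i]),
          call. = FALSE)
      }
    }
  }
  gr_mut <- GenomicRanges::GRanges(muts$contig,
    IRanges::IRanges(start = muts$position, width = 1L))
  hits <- GenomicRanges::findOverlaps(gr_mut, .genes_granges(genes))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  gene_idx <- rep(NA_integer_, n)
  ambiguous <- rep(FALSE, n)
  if (length(qh) > 0L) {
    for (q in unique(qh)) {
      cand <- sh[qh == q]
      if (length(cand) > 1L) {
        ambiguous[q] <- TRUE
        cand <- cand[order(genes$gene_id[cand])][1]
      }
      gene_idx[q] <- cand
    }
  }
  out <- muts
  out$gene_id <- ifelse(is.na(gene_idx), NA_character_,
                        genes$gene_id[gene_idx])
  out$codon_index <- NA_integer_
  out$codon_position <- NA_integer_
  out$effect <- "intergenic"
  out$spectrum <- vapply(seq_len(n), function(i)
    as.character(spectrum_class(muts$ref_base[i], muts$alt_base[i])),
    character(1))
  out$in_core <- FALSE
  out$ambiguous <- ambiguous
  for (i in which(!is.na(gene_idx))) {
    g <- gene_idx[i]
    pos0 <- muts$position[i] - 1L               # 0-based genome coordinate
    if (genes$strand[g] == "+") {
      off <- pos0 - genes$start[g]
      ref <- muts$ref_base[i]; alt <- muts$alt_base[i]
    } else {
      off <- genes$end[g] - 1L - pos0
      ref <- .complement[[muts$ref_base[i]]]
      alt <- .complement[[muts$alt_base[i]]]
    }
    ci <- off %/% 3L + 1L
    cp <- off %% 3L + 1L
    codon <- substr(genes$cds[g], (ci - 1L) * 3L + 1L, ci * 3L)
    cref <- substr(codon, cp, cp)
    if (cref != ref) {
      stop(sprintf("ref mismatch in gene %s at %s:%d (cds has %s, got %s)",
                   genes$gene_id[g], muts$contig[i], muts$position[i],
                   cref, ref), call. = FALSE)
    }
    out$codon_index[i] <- ci
    out$codon_position[i] <- cp
    if (is_stop_codon(codon)) {
      # change within a reference stop codon: stop-retaining changes are
      # synonymous by the amino-acid-identity rule, stop losses nonsynonymous
      mut <- codon
      substr(mut, cp, cp) <- alt
      out$effect[i] <- if (is_stop_codon(mut)) "synonymous" else
        "nonsynonymous"
    } else {
      out$effect[i] <- classify_substitution(codon, cp, alt)
    }
    out$in_core[i] <- genes$in_core[g]
  }
  out
}

#' Restrict annotated mutations to core-genome synonymous substitutions
#'
#' @param annotated Output of [annotate_mutations()].
#' @return The rows with `effect == "synonymous"` and `in_core`, with
#'   attributes `per_gene` (data.frame `gene_id`, `n_syn`) and `per_clone`
#'   (data.frame `clone_id`, `n_syn`).
#' @export
core_synonymous_set <- function(annotated) {
  keep <- annotated$effect == "synonymous" & annotated$in_core
  out <- annotated[keep, , drop = FALSE]
  rownames(out) <- NULL
  count_by <- function(v, key) {
    tab <- table(v)
    d <- data.frame(as.character(names(tab)), as.integer(tab),
                    stringsAsFactors = FALSE)
    names(d) <- c(key, "n_syn")
    d
  }
  pg <- count_by(out$gene_id, "gene_id")
  pc <- count_by(out$clone_id, "clone_id")
  attr(out, "per_gene") <- pg
  attr(out, "per_clone") <- pc
  out
}

#' Per-gene substitution counts over a gene table
#'
#' Zero-filled named count vector aligned to `genes$gene_id`.
#'
#' @param annotated Annotated (typically core-synonymous) mutations.
#' @param genes A [gene_table()].
#' @return Named integer vector, one entry per gene.
#' @export
per_gene_counts <- function(annotated, genes) {
  tab <- table(factor(annotated$gene_id, levels = genes$gene_id))
  stats::setNames(as.integer(tab), genes$gene_id)
}
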