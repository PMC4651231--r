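# Per-gene synonymous nucleotide diversity (theta_s) from codon alignments
# of natural isolates. A closed-form Watterson estimator restricted to
# synonymous sites stands in for model-based estimation: downstream analyses
# use theta_s only as a per-gene ranking and weighting quantity, and a
# pre-computed theta_s table is accepted as a drop-in replacement.

#' Construct a codon alignment
#'
#' @param gene_id Gene identifier.
#' @param sequences Character vector of n >= 2 aligned coding sequences of
#'   equal length divisible by 3 (uppercased internally).
#' @param isolate_ids Optional isolate identifiers (defaults to names of
#'   `sequences` or `iso1..isoN`).
#' @return A `codon_alignment` object.
#' @export
codon_alignment <- function(gene_id, sequences, isolate_ids = NULL) {
  sequences <- toupper(as.character(sequences))
  n <- length(sequences)
  if (n < 2L) stop("a codon alignment needs at least 2 sequences",
                   call. = FALSE)
  len <- unique(nchar(sequences))
  if (length(len) != 1L) stop("aligned sequences must have equal length",
                              call. = FALSE)
  if (len %% 3L != 0L) stop("alignment length must be divisible by 3",
                            call. = FALSE)
  if (is.null(isolate_ids)) {
    isolate_ids <- names(sequences)
    if (is.null(isolate_ids)) isolate_ids <- paste0("iso", seq_len(n))
  }
  structure(list(gene_id = as.character(gene_id), sequences = unname(sequences),
                 isolate_ids = as.character(isolate_ids)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment '%s': %d sequences x %d bp (%d codons)\n",
              x$gene_id, length(x$sequences), nchar(x$sequences[1]),
              nchar(x$sequences[1]) %/% 3L))
  invisible(x)
}

# alignment as a codon matrix: rows = sequences, cols = codon columns;
# returns list(codons = matrix of codon strings, keep = logical per codon
# column: TRUE where every sequence has an unambiguous gap-free codon)
.codon_matrix <- function(aln) {
  n <- length(aln$sequences)
  ncod <- nchar(aln$sequences[1]) %/% 3L
  codons <- matrix(vapply(aln$sequences, .split_codons, character(ncod)),
                   nrow = ncod, ncol = n)
  codons <- t(codons)
  clean <- grepl("^[ACGT]{3}$", codons)
  dim(clean) <- dim(codons)
  keep <- apply(clean, 2L, all)
  list(codons = codons, keep = keep)
}

#' Count synonymous segregating sites and synonymous sites in an alignment
#'
#' A nucleotide column counts as a synonymous segregating site iff it is
#' polymorphic and the codon containing it translates to the same amino acid
#' in every sequence. Codon columns containing gaps or ambiguity codes in
#' any sequence are dropped from both the segregating-site count and the
#' site total before estimation; codon columns with amino-acid polymorphism
#' contribute to the site total but never to S. `L_syn` is the Nei-Gojobori
#' synonymous-site count averaged over sequences.
#'
#' @param aln A [codon_alignment()].
#' @return List with `S_syn` (integer) and `L_syn` (fractional sites).
#' @export
count_segregating_synonymous_sites <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  cm <- .codon_matrix(aln)
  orig_col <- which(cm$keep)
  codons <- cm$codons[, cm$keep, drop = FALSE]
  n_seq <- nrow(codons)
  if (ncol(codons) == 0L) return(list(S_syn = 0L, L_syn = 0))
  # stops only tolerated as a shared trailing stop in the last codon column
  aa <- matrix(unname(.codon_table[codons]), nrow = nrow(codons))
  stop_cols <- which(apply(aa == "*", 2L, any))
  internal_stop <- stop_cols[orig_col[stop_cols] < ncol(cm$codons)]
  if (length(internal_stop) > 0L) {
    stop(sprintf("internal stop codon in gene '%s' at codon column %d",
                 aln$gene_id, orig_col[internal_stop[1]]), call. = FALSE)
  }
  if (length(stop_cols) > 0L) {  # trailing stop column: drop it
    codons <- codons[, -stop_cols, drop = FALSE]
    aa <- aa[, -stop_cols, drop = FALSE]
  }
  if (ncol(codons) == 0L) return(list(S_syn = 0L, L_syn = 0))
  S <- 0L
  for (j in seq_len(ncol(codons))) {
    if (length(unique(aa[, j])) != 1L) next  # amino-acid polymorphism
    cds <- codons[, j]
    if (length(unique(cds)) == 1L) next      # monomorphic codon
    for (pos in 1:3) {
      if (length(unique(substr(cds, pos, pos))) > 1L) S <- S + 1L
    }
  }
  # per-sequence synonymous sites over retained codon columns
  ss <- matrix(.syn_sites_table()[codons], nrow = n_seq)
  list(S_syn = S, L_syn = mean(rowSums(ss)))
}

#' Watterson's estimator of per-site diversity
#'
#' \eqn{\hat\theta = S / (a_n L)} with \eqn{a_n = \sum_{i=1}^{n-1} 1/i}.
#'
#' @param S Number of segregating sites (>= 0).
#' @param n Number of sequences (>= 2).
#' @param L Number of surveyed sites (> 0), may be fractional.
#' @return Per-site diversity estimate.
#' @examples
#' watterson_theta(7, 5, 420)  # 0.008
#' @export
watterson_theta <- function(S, n, L) {
  if (length(S) != 1L || S < 0) stop("S must be a nonnegative scalar",
                                     call. = FALSE)
  if (length(n) != 1L || n < 2) stop("n must be >= 2", call. = FALSE)
  if (length(L) != 1L || L <= 0) stop("L must be > 0", call. = FALSE)
  S / (harmonic_number(n - 1) * L)
}

#' Harmonic number \eqn{a_n = \sum_{i=1}^{n} 1/i}
#' @param n Nonnegative integer.
#' @return Numeric scalar.
#' @export
harmonic_number <- function(n) {
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  if (n == 0) return(0)
  sum(1 / seq_len(n))
}

#' Estimate per-gene synonymous diversity from a codon alignment
#'
#' Combines [count_segregating_synonymous_sites()] and [watterson_theta()].
#' Genes with no usable synonymous sites (`L_syn = 0`) get `theta_s = NA`
#' and `ok = FALSE`, mirroring exclusion of genes that fail estimation.
#'
#' @param aln A [codon_alignment()].
#' @return One-row data.frame: `gene_id`, `n`, `S_syn`, `L_syn`, `theta_s`,
#'   `ok`.
#' @export
estimate_theta_s <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  counts <- count_segregating_synonymous_sites(aln)
  n <- length(aln$sequences)
  if (counts$L_syn <= 0) {
    theta <- NA_real_; ok <- FALSE
  } else {
    theta <- watterson_theta(counts$S_syn, n, counts$L_syn); ok <- TRUE
  }
  data.frame(gene_id = aln$gene_id, n = n, S_syn = counts$S_syn,
             L_syn = counts$L_syn, theta_s = theta, ok = ok,
             stringsAsFactors = FALSE)
}

#' Read a per-gene codon alignment from a multi-FASTA file
#'
#' @param path FASTA file of aligned coding sequences for one gene.
#' @param gene_id Gene identifier; defaults to the file name without
#'   extension.
#' @return A [codon_alignment()].
#' @export
read_alignment_fasta <- function(path, gene_id = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (is.null(gene_id)) {
    gene_id <- tools::file_path_sans_ext(basename(path))
  }
  codon_alignment(gene_id, as.character(seqs), names(seqs))
}

#' Estimate theta_s for every alignment in a directory
#'
#' @param dir Directory of per-gene multi-FASTA alignments (`.fa`, `.fasta`,
#'   `.fna`).
#' @return data.frame, one row per gene, as from [estimate_theta_s()].
#' @export
estimate_theta_s_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|fasta|fna)$", full.names = TRUE)
  if (length(files) == 0L) stop("no FASTA alignments found in ", dir,
                                call. = FALSE)
  do.call(rbind, lapply(files, function(f) estimate_theta_s(
    read_alignment_fasta(f))))
}

#' Write / read a theta_s table
#'
#' Tab-delimited with a header; a pre-computed two-column table
#' (`gene_id`, `theta_s`) is accepted as a drop-in replacement for the
#' estimator's output.
#'
#' @param x data.frame with at least `gene_id` and `theta_s`.
#' @param path File path.
#' @return `read_theta_table` returns the data.frame.
#' @export
write_theta_table <- function(x, path) {
  stopifnot(all(c("gene_id", "theta_s") %in% names(x)))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_theta_table
#' @export
read_theta_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("gene_id", "theta_s") %in% names(x))) {
    stop("theta table needs columns gene_id and theta_s", call. = FALSE)
  }
  x
}
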