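# Genetic-code engine: translation (bacterial code, table 11 -- identical
# codon table to the standard code), effect classification of single-base
# changes, Nei-Gojobori fractional synonymous-site counting, and the six
# strand-collapsed base-substitution spectrum classes.

DNA_BASES <- c("A", "C", "G", "T")

#' The six strand-collapsed base-substitution classes
#'
#' Two transitions (`AT_to_GC`, `CG_to_TA`) and four transversions, each
#' covering a change and its strand complement (e.g. `A>C` and `T>G` are both
#' `AT_to_CG`).
#'
#' @format Character vector of length 6.
#' @export
SPECTRUM_CLASSES <- c("AT_to_GC", "CG_to_TA", "AT_to_CG",
                      "AT_to_TA", "CG_to_AT", "CG_to_GC")

# codon -> one-letter amino acid ('*' = stop), standard/bacterial table
.codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.assert_base <- function(b, what = "base") {
  if (!is.character(b) || length(b) != 1L || !(b %in% DNA_BASES)) {
    stop(sprintf("invalid %s: must be one of A, C, G, T", what), call. = FALSE)
  }
  invisible(b)
}

.assert_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || is.na(codon)) {
    stop("codon must be a single character string", call. = FALSE)
  }
  if (nchar(codon) != 3L) {
    stop(sprintf("codon must have exactly 3 bases, got '%s'", codon),
         call. = FALSE)
  }
  if (!all(strsplit(codon, "")[[1]] %in% DNA_BASES)) {
    stop(sprintf("codon '%s' contains characters outside {A,C,G,T}", codon),
         call. = FALSE)
  }
  invisible(codon)
}

#' Translate a codon under the bacterial genetic code
#'
#' @param codon Single string of 3 bases over `{A,C,G,T}`; ambiguity codes
#'   are rejected.
#' @return One-letter amino-acid symbol, or `"*"` for a stop codon.
#' @examples
#' translate_codon("ATG")  # "M"
#' translate_codon("TAA")  # "*"
#' @export
translate_codon <- function(codon) {
  .assert_codon(codon)
  unname(.codon_table[[codon]])
}

#' Is a codon a stop codon?
#' @inheritParams translate_codon
#' @return Logical scalar.
#' @export
is_stop_codon <- function(codon) {
  translate_codon(codon) == "*"
}

#' Classify the effect of a single-base change within a codon
#'
#' A change is `synonymous` when the mutated codon encodes the same amino
#' acid, `nonsense` when it creates a stop codon, and `nonsynonymous`
#' otherwise. Changes destroying a stop codon are not classified: the
#' reference codon must not be a stop.
#'
#' @inheritParams translate_codon
#' @param position Codon position of the change, 1, 2 or 3.
#' @param alt_base Replacement base; must differ from the reference base at
#'   `position`.
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"nonsense"`.
#' @examples
#' classify_substitution("GAA", 3, "G")  # synonymous (Glu -> Glu)
#' classify_substitution("TGG", 2, "A")  # nonsense  (Trp -> stop)
#' @export
classify_substitution <- function(codon, position, alt_base) {
  .assert_codon(codon)
  if (!(position %in% 1:3)) {
    stop("position must be 1, 2 or 3", call. = FALSE)
  }
  .assert_base(alt_base, "alt_base")
  if (is_stop_codon(codon)) {
    stop(sprintf("reference codon '%s' is a stop codon", codon), call. = FALSE)
  }
  bases <- strsplit(codon, "")[[1]]
  if (bases[position] == alt_base) {
    stop("alt_base equals the reference base at that position", call. = FALSE)
  }
  bases[position] <- alt_base
  mut_aa <- .codon_table[[paste(bases, collapse = "")]]
  ref_aa <- .codon_table[[codon]]
  if (mut_aa == "*") "nonsense"
  else if (mut_aa == ref_aa) "synonymous"
  else "nonsynonymous"
}

# Per-codon enumeration of all nine single-base neighbors, memoised for the
# 64 codons: data.frame(position, ref, alt, effect).
.codon_neighbors <- local({
  cache <- new.env(parent = emptyenv())
  function(codon) {
    if (!is.null(cache[[codon]])) return(cache[[codon]])
    bases <- strsplit(codon, "")[[1]]
    rows <- vector("list", 9L)
    k <- 0L
    for (pos in 1:3) {
      for (alt in setdiff(DNA_BASES, bases[pos])) {
        k <- k + 1L
        rows[[k]] <- data.frame(position = pos, ref = bases[pos], alt = alt,
                                effect = classify_substitution(codon, pos, alt),
                                stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    cache[[codon]] <- out
    out
  }
})

#' Nei-Gojobori fractional synonymous-site count of a codon
#'
#' Each codon position contributes (number of synonymous single-base
#' changes at that position) / 3; changes creating a stop codon count as
#' nonsynonymous (the classic site-counting convention), so per-codon
#' synonymous + nonsynonymous sites total exactly 3.
#'
#' @inheritParams translate_codon
#' @return Fractional site count in `[0, 3]`.
#' @examples
#' synonymous_sites("TTT")  # 1/3
#' synonymous_sites("CTG")  # 4/3
#' @export
synonymous_sites <- function(codon) {
  .assert_codon(codon)
  if (is_stop_codon(codon)) {
    stop(sprintf("codon '%s' is a stop codon", codon), call. = FALSE)
  }
  nb <- .codon_neighbors(codon)
  sum(nb$effect == "synonymous") / 3
}

.split_codons <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# lazily built lookup: codon -> fractional synonymous sites (61 non-stops)
.syn_sites_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      codons <- names(.codon_table)[.codon_table != "*"]
      tab <<- stats::setNames(
        vapply(codons, synonymous_sites, numeric(1)), codons)
    }
    tab
  }
})

#' Fractional synonymous-site count of a coding sequence
#'
#' Sums [synonymous_sites()] over all codons. A trailing stop codon, if
#' present, is excluded from the count; internal stops are an error.
#'
#' @param cds Coding sequence string, length divisible by 3, bases over
#'   `{A,C,G,T}`.
#' @return Fractional synonymous site count.
#' @export
gene_synonymous_sites <- function(cds) {
  if (!is.character(cds) || length(cds) != 1L) {
    stop("cds must be a single string", call. = FALSE)
  }
  if (nchar(cds) %% 3L != 0L) {
    stop(sprintf("cds length %d is not divisible by 3", nchar(cds)),
         call. = FALSE)
  }
  codons <- .split_codons(cds)
  if (!all(codons %in% names(.codon_table))) {
    bad <- which(!codons %in% names(.codon_table))[1]
    stop(sprintf("codon %d ('%s') contains characters outside {A,C,G,T}",
                 bad, codons[bad]), call. = FALSE)
  }
  aa <- unname(.codon_table[codons])
  n <- length(codons)
  stops <- aa == "*"
  if (any(stops[-n])) {
    stop(sprintf("internal stop codon at codon index %d",
                 which(stops[-n])[1]), call. = FALSE)
  }
  if (n > 0L && stops[n]) codons <- codons[-n]
  if (length(codons) == 0L) return(0)
  sum(.syn_sites_table()[codons])
}

#' Strand-collapsed spectrum class of a base substitution
#'
#' The two strand-complementary representations of a change map to the same
#' class: `C>T` and `G>A` are both `CG_to_TA`.
#'
#' @param ref_base,alt_base Single bases over `{A,C,G,T}`, unequal.
#' @return A length-1 character vector naming the class, with attribute
#'   `kind` equal to `"transition"` or `"transversion"`.
#' @examples
#' spectrum_class("C", "T")  # CG_to_TA (transition)
#' spectrum_class("T", "G")  # AT_to_CG (transversion)
#' @export
spectrum_class <- function(ref_base, alt_base) {
  .assert_base(ref_base, "ref_base")
  .assert_base(alt_base, "alt_base")
  if (ref_base == alt_base) {
    stop("ref_base and alt_base must differ", call. = FALSE)
  }
  # collapse onto the A/C representative of the ref pair
  if (ref_base %in% c("T", "G")) {
    ref_base <- .complement[[ref_base]]
    alt_base <- .complement[[alt_base]]
  }
  label <- switch(paste0(ref_base, alt_base),
    AG = "AT_to_GC", CT = "CG_to_TA",
    AC = "AT_to_CG", AT = "AT_to_TA",
    CA = "CG_to_AT", CG = "CG_to_GC")
  structure(label, kind = if (label %in% c("AT_to_GC", "CG_to_TA"))
    "transition" else "transversion")
}

#' Is a spectrum class a transition?
#' @param label A class label from [SPECTRUM_CLASSES].
#' @return Logical scalar.
#' @export
is_transition <- function(label) {
  label <- match.arg(label, SPECTRUM_CLASSES)
  label %in% c("AT_to_GC", "CG_to_TA")
}

#' Enumerate the synonymous single-base changes of a codon
#'
#' Used by the synthetic-data generator to place synonymous events.
#'
#' @inheritParams translate_codon
#' @return data.frame with columns `position`, `ref`, `alt`, one row per
#'   synonymous neighbor (possibly zero rows).
#' @export
synonymous_changes <- function(codon) {
  .assert_codon(codon)
  if (is_stop_codon(codon)) {
    stop(sprintf("codon '%s' is a stop codon", codon), call. = FALSE)
  }
  nb <- .codon_neighbors(codon)
  nb[nb$effect == "synonymous", c("position", "ref", "alt"), drop = FALSE]
}

#' Reverse complement of a DNA string
#' @param x Single DNA string.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
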