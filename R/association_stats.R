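# Expression / gene-length association analyses: presence-absence gene
# grouping, Welch's t, Wilcoxon rank-sum, Pearson r, Kendall's tau-b and
# the partial Kendall rank-correlation controlling for a third variable.

#' Partition genes by presence of synonymous substitutions
#'
#' @param counts Named per-gene substitution counts covering the core set.
#' @return List with character vectors `with_syn` (count >= 1 in at least
#'   one clone) and `without_syn`.
#' @export
group_genes <- function(counts) {
  ids <- names(counts)
  if (is.null(ids)) stop("counts must be named by gene_id", call. = FALSE)
  list(with_syn = ids[counts > 0], without_syn = ids[counts == 0])
}

#' Welch's unequal-variance t-test
#'
#' Thin, contract-checked wrapper around [stats::t.test()] with
#' `var.equal = FALSE` (Welch-Satterthwaite degrees of freedom, two-sided).
#'
#' @param x,y Numeric samples, each of size >= 2, with nonzero variance in
#'   at least one sample.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("both samples need >= 2 observations", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = Inf, p = 1))
    stop("both samples have zero variance", call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration when the pooled sample is small (`nx + ny <= 12`) with
#' no ties; otherwise the normal approximation with midranks, tie
#' correction and continuity correction (via [stats::wilcox.test()]).
#'
#' @param x,y Nonempty numeric samples.
#' @return List with `W` (rank-sum statistic of `x`, Mann-Whitney U
#'   convention as in [stats::wilcox.test()]), `p` (two-sided), `exact`
#'   (logical).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y)) <= 12L && !ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(W = unname(ht$statistic), p = unname(ht$p.value), exact = exact)
}

#' Pearson product-moment correlation
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("degenerate variance", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Kendall's tau-b rank correlation
#'
#' Tie-corrected concordance statistic, as computed by
#' [stats::cor()] with `method = "kendall"`.
#'
#' @param x,y Numeric vectors of equal length >= 3; a fully tied variable
#'   is an error.
#' @return tau-b in `[-1, 1]`.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("all-tied variable", call. = FALSE)
  }
  stats::cor(x, y, method = "kendall")
}

#' Partial Kendall rank-correlation controlling for a third variable
#'
#' \deqn{\tau_{xy\cdot z} = \frac{\tau_{xy} - \tau_{xz}\tau_{yz}}
#'   {\sqrt{(1-\tau_{xz}^2)(1-\tau_{yz}^2)}}}
#' Significance is assessed assuming normality, reusing the ordinary-tau
#' null variance \eqn{2(2n+5)/(9n(n-1))} for the z-score — a classical
#' approximation, documented as such.
#'
#' @param x,y Variables of interest (e.g. per-gene synonymous substitution
#'   count and expression level).
#' @param z Control variable (e.g. gene length).
#' @return List with `tau_xy`, `tau_xz`, `tau_yz`, `tau_partial`,
#'   `z_score`, `p_two_sided`, `n`.
#' @export
partial_kendall_tau <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n || n < 10L) {
    stop("x, y, z must have equal length >= 10", call. = FALSE)
  }
  t_xy <- kendall_tau(x, y)
  t_xz <- kendall_tau(x, z)
  t_yz <- kendall_tau(y, z)
  denom <- (1 - t_xz^2) * (1 - t_yz^2)
  if (denom <= 0) {
    stop("degenerate control: |tau_xz| or |tau_yz| equals 1", call. = FALSE)
  }
  tp <- (t_xy - t_xz * t_yz) / sqrt(denom)
  se <- sqrt(2 * (2 * n + 5) / (9 * n * (n - 1)))
  zs <- tp / se
  list(tau_xy = t_xy, tau_xz = t_xz, tau_yz = t_yz, tau_partial = tp,
       z_score = zs, p_two_sided = 2 * stats::pnorm(-abs(zs)), n = n)
}

#' Run the full association analysis on a per-gene table
#'
#' Reproduces the expression/length analysis: Welch's t and Wilcoxon
#' rank-sum comparing genes with vs without synonymous substitutions (for
#' expression and for length), Pearson r between expression and length,
#' and the partial Kendall correlation between substitutions and
#' expression controlling for length. The substitution variable entering
#' the partial correlation is the per-gene count by default; `binary =
#' TRUE` uses the 0/1 presence indicator instead.
#'
#' @param genes A [gene_table()] with `expression` filled in.
#' @param counts Named per-gene synonymous substitution counts.
#' @param binary Use presence/absence instead of counts in the partial
#'   correlation.
#' @return List of results: `grouping`, `welch_expression`,
#'   `wilcoxon_length`, `mean_length_with`, `mean_length_without`,
#'   `mean_expr_with`, `mean_expr_without`, `pearson_expr_length`,
#'   `partial_tau`.
#' @export
association_analysis <- function(genes, counts, binary = FALSE) {
  counts <- counts[genes$gene_id]
  counts[is.na(counts)] <- 0
  names(counts) <- genes$gene_id
  grp <- group_genes(counts)
  with_i <- genes$gene_id %in% grp$with_syn
  if (!any(with_i) || all(with_i)) {
    stop("grouping is degenerate: need genes both with and without ",
         "synonymous substitutions", call. = FALSE)
  }
  expr <- genes$expression
  len <- genes$length_bp
  subst <- if (binary) as.numeric(counts > 0) else as.numeric(counts)
  list(
    grouping = grp,
    welch_expression = welch_t(expr[with_i], expr[!with_i]),
    wilcoxon_length = wilcoxon_rank_sum(len[with_i], len[!with_i]),
    mean_length_with = mean(len[with_i]),
    mean_length_without = mean(len[!with_i]),
    mean_expr_with = mean(expr[with_i]),
    mean_expr_without = mean(expr[!with_i]),
    pearson_expr_length = pearson_r(expr, len),
    partial_tau = partial_kendall_tau(subst, expr, len),
    binary = binary
  )
}
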