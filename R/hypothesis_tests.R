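# Rate models over theta_s-ranked genes, observed vs expected cumulative
# substitution distributions, Kolmogorov-Smirnov comparisons (asymptotic
# Kolmogorov tail and Monte-Carlo multinomial null), lineage subgroup
# reanalysis, and mutation-spectrum summaries.

#' The four per-gene rate-model modes
#' @format Character vector of length 4.
#' @export
RATE_MODES <- c("length_null", "syn_sites_null", "theta_per_site",
                "theta_per_gene")

#' Build a per-gene multinomial rate model
#'
#' Genes are ordered by ascending `theta_s` (ties broken by `gene_id` for a
#' total order) and assigned probability weights by mode:
#' `length_null` (weight proportional to gene length), `syn_sites_null`
#' (proportional to synonymous-site count), `theta_per_site`
#' (proportional to `theta_s * syn_sites`; theta_s is a per-site quantity,
#' so this is the default theta mode), or `theta_per_gene` (proportional to
#' `theta_s` alone).
#'
#' @param genes A [gene_table()]; theta modes (and the ordering) require a
#'   finite `theta_s` for every gene.
#' @param mode One of `r paste(RATE_MODES, collapse = ", ")`.
#' @return A `rate_model`: list with `gene_ids` (theta_s-ascending order),
#'   `weights` (sum to 1), `mode`, and `theta_s` in the same order.
#' @export
build_rate_model <- function(genes, mode = c("length_null", "syn_sites_null",
                                             "theta_per_site",
                                             "theta_per_gene")) {
  mode <- match.arg(mode)
  if (anyNA(genes$theta_s)) {
    bad <- genes$gene_id[is.na(genes$theta_s)]
    stop("theta_s missing for gene(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ...", call. = FALSE)
  }
  ord <- order(genes$theta_s, genes$gene_id)
  g <- genes[ord, , drop = FALSE]
  w <- switch(mode,
    length_null    = g$length_bp,
    syn_sites_null = g$syn_sites,
    theta_per_site = g$theta_s * g$syn_sites,
    theta_per_gene = g$theta_s)
  if (any(w < 0)) stop("negative weights", call. = FALSE)
  if (sum(w) <= 0) stop("all-zero weights under mode ", mode, call. = FALSE)
  structure(list(gene_ids = g$gene_id, weights = w / sum(w), mode = mode,
                 theta_s = g$theta_s),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("rate_model '%s': %d genes, weights sum %.12f\n",
              x$mode, length(x$gene_ids), sum(x$weights)))
  invisible(x)
}

#' Observed cumulative substitution curve over the model's gene ordering
#'
#' @param counts Named per-gene substitution counts (names = gene ids);
#'   total must be >= 1 and every counted gene must appear in the model.
#' @param model A [build_rate_model()] result supplying the
#'   theta_s-ascending ordering.
#' @return A `cumulative_curve`: list with `gene_ids` and nondecreasing
#'   `cumulative` ending at exactly 1.
#' @export
observed_curve <- function(counts, model) {
  stopifnot(inherits(model, "rate_model"))
  counted <- names(counts)[counts > 0]
  missing <- setdiff(counted, model$gene_ids)
  if (length(missing) > 0L) {
    stop("gene(s) in counts absent from the model ordering: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  v <- counts[model$gene_ids]
  v[is.na(v)] <- 0
  total <- sum(v)
  if (total < 1) stop("counts total must be >= 1", call. = FALSE)
  cum <- cumsum(v) / total
  cum[length(cum)] <- 1  # guard fp drift
  structure(list(gene_ids = model$gene_ids, cumulative = unname(cum)),
            class = "cumulative_curve")
}

#' Model-implied cumulative curve
#' @param model A [build_rate_model()] result.
#' @return A `cumulative_curve` of the model CDF.
#' @export
model_curve <- function(model) {
  cum <- cumsum(model$weights)
  cum[length(cum)] <- 1
  structure(list(gene_ids = model$gene_ids, cumulative = unname(cum)),
            class = "cumulative_curve")
}

# Kolmogorov asymptotic tail: P(D > d) for effective sample size n, using
# lambda = (sqrt(n) + 0.12 + 0.11/sqrt(n)) * d and
# Q(lambda) = 2 * sum_{j>=1} (-1)^{j-1} exp(-2 j^2 lambda^2).
.kolmogorov_pvalue <- function(d, n) {
  if (d <= 0) return(1)
  lam <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * d
  j <- 1:101
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lam^2))
  min(max(p, 0), 1)
}

#' Kolmogorov-Smirnov comparison of an observed curve against a rate model
#'
#' `D` is the sup-difference between the observed and model cumulative
#' distributions over the shared theta_s-ordered discrete gene axis; the
#' asymptotic p-value treats each of the `n` substitutions as one draw from
#' the multinomial rate model (it is conservative on a discrete axis, which
#' is why the Monte-Carlo null of [monte_carlo_pvalue()] is the preferred
#' p-value and is reported alongside when `mc_reps > 0`).
#'
#' @param obs A `cumulative_curve` from [observed_curve()].
#' @param model The [build_rate_model()] it is compared against (orderings
#'   must match).
#' @param n Substitution count behind the observed curve.
#' @param mc_reps Monte-Carlo replicates for the multinomial null
#'   (0 = skip).
#' @param seed Seed for the Monte-Carlo null (required when `mc_reps > 0`).
#' @return A `ks_result`: list with `D`, `n`, `p_asymptotic`, and (when
#'   requested) `p_montecarlo`, `mc_reps`, `seed`.
#' @export
ks_compare <- function(obs, model, n, mc_reps = 0, seed = NULL) {
  stopifnot(inherits(obs, "cumulative_curve"), inherits(model, "rate_model"))
  if (!identical(obs$gene_ids, model$gene_ids)) {
    stop("curve and model orderings differ", call. = FALSE)
  }
  D <- max(abs(obs$cumulative - model_curve(model)$cumulative))
  res <- list(D = D, n = as.integer(n),
              p_asymptotic = .kolmogorov_pvalue(D, n))
  if (mc_reps > 0) {
    if (is.null(seed)) stop("seed required for the Monte-Carlo null",
                            call. = FALSE)
    res$p_montecarlo <- monte_carlo_pvalue(model, n, D, mc_reps, seed)
    res$mc_reps <- as.integer(mc_reps)
    res$seed <- as.integer(seed)
  }
  structure(res, class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("KS: D = %.4g, n = %d, p_asymptotic = %.4g", x$D, x$n,
              x$p_asymptotic))
  if (!is.null(x$p_montecarlo)) {
    cat(sprintf(", p_mc = %.4g (%d reps, seed %d)", x$p_montecarlo,
                x$mc_reps, x$seed))
  }
  cat("\n")
  invisible(x)
}

# D statistic for a vector of per-gene counts against the model CDF
.ks_d <- function(counts_in_order, model_cdf) {
  max(abs(cumsum(counts_in_order) / sum(counts_in_order) - model_cdf))
}

#' Monte-Carlo p-value for the discrete KS statistic
#'
#' Draws `reps` multinomial samples of size `n` from the model weights,
#' recomputes D for each, and returns the add-one estimator
#' `(1 + #\{D_sim >= D_obs\}) / (reps + 1)`.
#'
#' @param model A [build_rate_model()] result.
#' @param n Substitutions per simulated sample.
#' @param D_obs Observed statistic.
#' @param reps Number of replicates (>= 1).
#' @param seed Integer seed; same seed, same answer.
#' @return Estimated p-value in `(0, 1]`.
#' @export
monte_carlo_pvalue <- function(model, n, D_obs, reps, seed) {
  stopifnot(inherits(model, "rate_model"), reps >= 1)
  cdf <- model_curve(model)$cumulative
  sims <- with_seed(seed, {
    draws <- stats::rmultinom(reps, n, model$weights)
    apply(draws, 2L, function(cts) max(abs(cumsum(cts) / n - cdf)))
  })
  (1 + sum(sims >= D_obs - 1e-12)) / (reps + 1)
}

#' Run the KS comparison separately per lineage class
#'
#' Re-runs [observed_curve()] + [ks_compare()] restricted to each lineage
#' class present in the annotated mutations; empty groups are skipped with
#' a warning.
#'
#' @param annotated Core-synonymous annotated mutations (with
#'   `lineage_class`).
#' @param genes A [gene_table()].
#' @param model A [build_rate_model()] result.
#' @param groups Lineage classes to test (default: all present).
#' @param mc_reps,seed Passed to [ks_compare()].
#' @return Named list of `ks_result`, one per non-empty group.
#' @export
subgroup_tests <- function(annotated, genes, model, groups = NULL,
                           mc_reps = 0, seed = NULL) {
  if (is.null(groups)) groups <- unique(annotated$lineage_class)
  out <- list()
  for (grp in groups) {
    sub <- annotated[annotated$lineage_class == grp, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("no substitutions in lineage class ", grp, "; skipped",
              call. = FALSE)
      next
    }
    counts <- per_gene_counts(sub, genes)
    obs <- observed_curve(counts, model)
    out[[grp]] <- ks_compare(obs, model, sum(counts), mc_reps = mc_reps,
                             seed = seed)
  }
  out
}

#' Mutation-spectrum summary table
#'
#' Counts per strand-collapsed spectrum class, by clone (or any grouping
#' column). Row totals conserve the input size.
#'
#' @param annotated Annotated mutations (any subset).
#' @param by Grouping column name, default `"clone_id"`.
#' @return data.frame: one row per group, six class-count columns plus
#'   `total`.
#' @export
spectrum_summary <- function(annotated, by = "clone_id") {
  groups <- if (nrow(annotated) > 0L) sort(unique(annotated[[by]])) else
    character(0)
  out <- data.frame(group = groups, stringsAsFactors = FALSE)
  names(out) <- by
  for (cl in SPECTRUM_CLASSES) {
    out[[cl]] <- vapply(groups, function(g)
      sum(annotated[[by]] == g & annotated$spectrum == cl), integer(1),
      USE.NAMES = FALSE)
  }
  out$total <- if (length(groups) > 0L)
    as.integer(rowSums(out[SPECTRUM_CLASSES])) else integer(0)
  out
}

#' Exact multinomial tail probability of the discrete KS statistic
#'
#' Exhaustive enumeration of all compositions of `n` over the model's
#' genes; feasible only for small problems (<= 3 genes, n <= ~12). Serves
#' as the independent oracle for [monte_carlo_pvalue()].
#'
#' @param model A [build_rate_model()] result with few genes.
#' @param n Sample size.
#' @param D_obs Observed statistic.
#' @return Exact `P(D >= D_obs)` under the multinomial model.
#' @export
exact_ks_tail <- function(model, n, D_obs) {
  k <- length(model$gene_ids)
  if (k > 4L) stop("exhaustive enumeration limited to <= 4 genes",
                   call. = FALSE)
  cdf <- model_curve(model)$cumulative
  comps <- .compositions(n, k)
  p <- 0
  for (i in seq_len(nrow(comps))) {
    cts <- comps[i, ]
    D <- max(abs(cumsum(cts) / n - cdf))
    if (D >= D_obs - 1e-12) {
      p <- p + stats::dmultinom(cts, prob = model$weights)
    }
  }
  p
}

# all k-part compositions of n (rows)
.compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1L))
  out <- list()
  for (first in 0:n) {
    rest <- .compositions(n - first, k - 1L)
    out[[length(out) + 1L]] <- cbind(first, rest)
  }
  m <- do.call(rbind, out)
  dimnames(m) <- NULL
  m
}
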