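# Seeded generator for pulldown DIA protein-intensity matrices with
# cluster-structured binding profiles and intensity-dependent missingness.
#
# Emulates the statistical structure of quadruplicate chain-type pulldowns:
# most proteins bind all baits equally (null background), a minority carry
# one of a small number of binding-preference profiles across the chain
# types, and low-abundance measurements are more likely to be missing
# (left-censoring, the assumption behind Gaussian-downshift imputation).

#' Design of a synthetic pulldown intensity matrix
#'
#' @param n_proteins Number of protein rows.
#' @param groups Chain-type labels of the pulldown baits (default the three
#'   tetramer baits: branched K48-K63, unbranched K48, unbranched K63).
#' @param replicates Replicates per group (default 4, quadruplicate).
#' @param n_clusters Number of binding-preference clusters among the
#'   differential proteins (default 6).
#' @param frac_differential Fraction of proteins that carry a cluster
#'   profile; the rest are null (exchangeable across groups).
#' @param effect Log2 effect size of a preferred bait relative to baseline
#'   (default 3, i.e. 8-fold enrichment; about 6 replicate SDs).
#' @param replicate_sd Between-replicate standard deviation (log2).
#' @param base_mean,base_sd Mean and SD of per-protein baseline log2
#'   abundance.
#' @param miss_mid,miss_scale Logistic missingness model: an entry with true
#'   log2 intensity x is missing with probability
#'   `plogis((miss_mid - x) / miss_scale)`; lower-intensity entries are
#'   missing more often.
#' @param peptide_lambda Poisson rate for `1 + rpois()` unique-peptide
#'   counts (some proteins land at 1 and are filtered by preprocessing).
#' @return Object of class `dia_design`.
#' @export
dia_design <- function(n_proteins = 1000L,
                       groups = c("K48K63_branched", "48Ub4", "63Ub4"),
                       replicates = 4L, n_clusters = 6L,
                       frac_differential = 0.15, effect = 3,
                       replicate_sd = 0.5, base_mean = 24, base_sd = 1.5,
                       miss_mid = 21, miss_scale = 1, peptide_lambda = 4) {
  stopifnot(n_proteins >= 1L, length(groups) >= 2L, replicates >= 2L,
            n_clusters >= 1L, frac_differential >= 0, frac_differential <= 1,
            replicate_sd >= 0, miss_scale > 0)
  structure(list(n_proteins = as.integer(n_proteins), groups = groups,
                 replicates = as.integer(replicates),
                 n_clusters = as.integer(n_clusters),
                 frac_differential = frac_differential, effect = effect,
                 replicate_sd = replicate_sd, base_mean = base_mean,
                 base_sd = base_sd, miss_mid = miss_mid,
                 miss_scale = miss_scale, peptide_lambda = peptide_lambda),
            class = "dia_design")
}

# distinct mean-offset profiles (clusters x groups): each cluster prefers a
# different subset of baits
cluster_offsets <- function(n_clusters, n_groups, effect) {
  subsets <- list()
  # all non-trivial, non-full subsets of groups, singletons first
  for (size in seq_len(max(1L, n_groups - 1L))) {
    subsets <- c(subsets, utils::combn(n_groups, size, simplify = FALSE))
  }
  if (n_clusters > length(subsets)) {
    stop("too many clusters for the number of groups: at most ",
         length(subsets), " distinct preference profiles exist",
         call. = FALSE)
  }
  off <- matrix(0, n_clusters, n_groups)
  for (k in seq_len(n_clusters)) off[k, subsets[[k]]] <- effect
  off
}

#' Simulate a pulldown intensity matrix
#'
#' Generates raw (linear-scale) protein intensities with the structure given
#' by the design, applies the intensity-dependent missingness model, and
#' returns the ground truth separately.
#'
#' @param design A [dia_design()].
#' @param seed Integer seed; the generator is a pure function of
#'   (design, seed).
#' @return A list of class `intensity_matrix`: `values` (proteins x samples,
#'   raw intensities with `NA` for missing), `unique_peptides` (integer per
#'   protein), `groups` (chain type per sample), `replicate` (index per
#'   sample), `log2` (FALSE: values are raw), and `truth` (data frame with
#'   `protein`, `differential`, `cluster`).
#' @export
simulate_dia_matrix <- function(design = dia_design(), seed = 1L) {
  stopifnot(inherits(design, "dia_design"))
  with_seed(seed, {
    n_g <- length(design$groups)
    n_s <- n_g * design$replicates
    grp <- rep(design$groups, each = design$replicates)
    rep_idx <- rep(seq_len(design$replicates), times = n_g)
    n_diff <- round(design$n_proteins * design$frac_differential)
    cluster <- rep(NA_integer_, design$n_proteins)
    if (n_diff > 0L) {
      cluster[seq_len(n_diff)] <-
        rep_len(seq_len(design$n_clusters), n_diff)
    }
    off <- cluster_offsets(design$n_clusters, n_g, design$effect)
    base <- stats::rnorm(design$n_proteins, design$base_mean, design$base_sd)
    mu <- matrix(base, design$n_proteins, n_s)
    gi <- match(grp, design$groups)
    diff_rows <- which(!is.na(cluster))
    for (i in diff_rows) mu[i, ] <- mu[i, ] + off[cluster[i], gi]
    x <- mu + matrix(stats::rnorm(design$n_proteins * n_s, 0,
                                  design$replicate_sd),
                     design$n_proteins, n_s)
    p_miss <- stats::plogis((design$miss_mid - x) / design$miss_scale)
    miss <- matrix(stats::runif(length(x)) < p_miss,
                   design$n_proteins, n_s)
    vals <- 2^x
    vals[miss] <- NA_real_
    peptides <- 1L + stats::rpois(design$n_proteins, design$peptide_lambda)
    proteins <- sprintf("P%04d", seq_len(design$n_proteins))
    dimnames(vals) <- list(proteins,
                           paste0(grp, "_r", rep_idx))
    structure(
      list(values = vals,
           unique_peptides = stats::setNames(peptides, proteins),
           groups = grp, replicate = rep_idx, log2 = FALSE,
           truth = data.frame(protein = proteins,
                              differential = !is.na(cluster),
                              cluster = cluster,
                              stringsAsFactors = FALSE)),
      class = "intensity_matrix")
  })
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d proteins x %d samples (%s scale), %.1f%% missing\n",
              nrow(x$values), ncol(x$values),
              if (isTRUE(x$log2)) "log2" else "raw",
              100 * mean(is.na(x$values))))
  cat("  groups:", paste(unique(x$groups), collapse = ", "), "\n")
  invisible(x)
}
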