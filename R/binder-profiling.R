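# Pulldown binder-profiling statistics: unique-peptide filtering, log2
# transform and median normalization, left-censored Gaussian imputation,
# per-protein one-way ANOVA with Benjamini-Hochberg control, Z-scoring and
# Euclidean hierarchical clustering into binding-preference clusters.

#' Filter, log-transform and median-normalize an intensity matrix
#'
#' Removes proteins identified with fewer than two unique peptides, applies
#' log2 (when the matrix holds raw intensities) and centers each sample at
#' zero median over its observed values.
#'
#' @param x An `intensity_matrix` (see [simulate_dia_matrix()] or
#'   [read_intensity_matrix()]).
#' @param min_peptides Minimum unique peptides per protein (default 2).
#' @return The preprocessed `intensity_matrix` (log2 scale, median
#'   centered).
#' @export
preprocess_intensity <- function(x, min_peptides = 2L) {
  stopifnot(inherits(x, "intensity_matrix"))
  keep <- x$unique_peptides[rownames(x$values)] >= min_peptides
  keep[is.na(keep)] <- FALSE
  v <- x$values[keep, , drop = FALSE]
  if (!isTRUE(x$log2)) v <- log2(v)
  n_obs <- colSums(!is.na(v))
  if (any(n_obs == 0L)) {
    stop("sample(s) with no observed values: ",
         paste(colnames(v)[n_obs == 0L], collapse = ", "), call. = FALSE)
  }
  med <- apply(v, 2L, stats::median, na.rm = TRUE)
  v <- sweep(v, 2L, med)
  out <- x
  out$values <- v
  out$unique_peptides <- x$unique_peptides[rownames(v)]
  out$log2 <- TRUE
  out$truth <- if (!is.null(x$truth)) {
    x$truth[x$truth$protein %in% rownames(v), , drop = FALSE]
  }
  out
}

#' Impute missing values from a downshifted Gaussian
#'
#' Left-censored imputation: missing entries of each sample are drawn from
#' `Normal(median - downshift * sd, (width * sd)^2)`, where the median and
#' standard deviation are computed from that sample's observed values. The
#' defaults (downshift 1.8, width 0.3) place imputed values in the lower
#' tail of the observed distribution, reflecting that missingness is
#' concentrated at low abundance. Observed entries are never altered.
#'
#' @param x A preprocessed (log2) `intensity_matrix`.
#' @param downshift,width Imputation parameters, in units of the per-sample
#'   standard deviation.
#' @param seed Integer seed for the draws (`NULL` for the ambient RNG).
#' @return A complete `intensity_matrix`; attribute `imputed` marks the
#'   filled-in entries.
#' @export
impute_missing <- function(x, downshift = 1.8, width = 0.3, seed = NULL) {
  stopifnot(inherits(x, "intensity_matrix"), width > 0)
  if (!isTRUE(x$log2)) {
    stop("impute_missing expects a preprocessed (log2) matrix",
         call. = FALSE)
  }
  v <- x$values
  mask <- is.na(v)
  with_seed(seed, {
    for (j in seq_len(ncol(v))) {
      obs <- v[!mask[, j], j]
      if (!any(mask[, j])) next
      if (length(obs) < 3L) {
        stop("sample ", colnames(v)[j], " has fewer than 3 observed values; ",
             "imputation parameters undefined", call. = FALSE)
      }
      mu <- stats::median(obs) - downshift * stats::sd(obs)
      v[mask[, j], j] <- stats::rnorm(sum(mask[, j]), mu,
                                      width * stats::sd(obs))
    }
  })
  out <- x
  out$values <- v
  attr(out, "imputed") <- mask
  out
}

#' Per-protein one-way ANOVA across chain-type groups
#'
#' Classic fixed-effects one-way ANOVA per protein (vectorized over the
#' matrix), with Benjamini-Hochberg step-up adjustment across proteins and
#' a significance call at the adjusted-p cutoff.
#'
#' @param x A complete `intensity_matrix`.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return Data frame with columns `protein`, `F`, `p`, `p_adj`,
#'   `significant`.
#' @export
test_differential <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "intensity_matrix"))
  v <- x$values
  if (anyNA(v)) stop("matrix has missing values; impute first", call. = FALSE)
  g <- factor(x$groups)
  k <- nlevels(g)
  n <- ncol(v)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2L)) stop("every group needs >= 2 replicates",
                               call. = FALSE)
  gm <- t(rowsum(t(v), g) / as.vector(table(g)))  # proteins x groups
  grand <- rowMeans(v)
  ssb <- as.vector((gm - grand)^2 %*% as.numeric(table(g)))
  fitted <- gm[, as.integer(g), drop = FALSE]
  ssw <- rowSums((v - fitted)^2)
  df1 <- k - 1L
  df2 <- n - k
  Fstat <- (ssb / df1) / (ssw / df2)
  Fstat[ssw == 0 & ssb == 0] <- 0
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  p[is.na(Fstat)] <- 1
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(protein = rownames(v), F = Fstat, p = p, p_adj = p_adj,
             significant = p_adj < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Z-score binding profiles
#'
#' Standardizes each protein's profile across all samples: subtract the row
#' mean, divide by the row standard deviation.
#'
#' @param x A complete `intensity_matrix`.
#' @param subset Optional character vector of proteins to keep (typically
#'   the significant ones) before scaling.
#' @return Numeric matrix of Z scores (proteins x samples).
#' @export
zscore_profiles <- function(x, subset = NULL) {
  stopifnot(inherits(x, "intensity_matrix"))
  v <- x$values
  if (anyNA(v)) stop("matrix has missing values; impute first", call. = FALSE)
  if (!is.null(subset)) v <- v[rownames(v) %in% subset, , drop = FALSE]
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("constant row(s): ",
         paste(utils::head(rownames(v)[sds == 0]), collapse = ", "),
         "; Z score undefined", call. = FALSE)
  }
  t(scale(t(v)))[, , drop = FALSE]
}

#' Hierarchically cluster binding profiles
#'
#' Agglomerative clustering on pairwise Euclidean distances, applied to
#' proteins (rows) and to samples (columns); the protein tree is cut into
#' `k` binding-preference clusters. Deterministic given the input order and
#' the linkage criterion.
#'
#' @param z Z-score matrix from [zscore_profiles()].
#' @param k Number of protein clusters (default 6).
#' @param linkage Linkage criterion passed to [stats::hclust()] (default
#'   `"average"`).
#' @return List of class `cluster_result`: `clusters` (named integer
#'   vector), `protein_order`, `sample_order` (dendrogram leaf orders),
#'   `protein_hclust`, `sample_hclust`.
#' @export
cluster_profiles <- function(z, k = 6L, linkage = "average") {
  stopifnot(is.matrix(z), nrow(z) >= 1L)
  if (k > nrow(z)) stop("k exceeds the number of proteins", call. = FALSE)
  if (nrow(z) == 1L) {
    return(structure(list(
      clusters = stats::setNames(1L, rownames(z)),
      protein_order = rownames(z), sample_order = colnames(z),
      protein_hclust = NULL, sample_hclust = NULL),
      class = "cluster_result"))
  }
  hp <- stats::hclust(stats::dist(z, method = "euclidean"),
                      method = linkage)
  hs <- stats::hclust(stats::dist(t(z), method = "euclidean"),
                      method = linkage)
  structure(list(
    clusters = stats::cutree(hp, k = k),
    protein_order = rownames(z)[hp$order],
    sample_order = colnames(z)[hs$order],
    protein_hclust = hp, sample_hclust = hs),
    class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>", length(x$clusters), "proteins in",
      length(unique(x$clusters)), "clusters\n")
  print(table(x$clusters))
  invisible(x)
}

#' Read / write an intensity matrix as TSV
#'
#' The TSV layout: one row per protein; a `protein` id column, a
#' `unique_peptides` column, then one column per sample named
#' `<group>_r<replicate>`. Missing values are empty fields or `NA`.
#'
#' @param path File path.
#' @return An `intensity_matrix` (raw or log2 according to `log2`).
#' @param log2 Whether the stored values are already log2-transformed.
#' @export
read_intensity_matrix <- function(path, log2 = FALSE) {
  tab <- utils::read.delim(path, check.names = FALSE)
  stopifnot(all(c("protein", "unique_peptides") %in% names(tab)))
  samp <- setdiff(names(tab), c("protein", "unique_peptides"))
  v <- as.matrix(tab[, samp, drop = FALSE])
  rownames(v) <- tab$protein
  grp <- sub("_r[0-9]+$", "", samp)
  rep_idx <- as.integer(sub("^.*_r", "", samp))
  structure(list(values = v,
                 unique_peptides = stats::setNames(tab$unique_peptides,
                                                   tab$protein),
                 groups = grp, replicate = rep_idx, log2 = log2,
                 truth = NULL),
            class = "intensity_matrix")
}

#' @rdname read_intensity_matrix
#' @param x An `intensity_matrix` to write.
#' @export
write_intensity_matrix <- function(x, path) {
  stopifnot(inherits(x, "intensity_matrix"))
  tab <- data.frame(protein = rownames(x$values),
                    unique_peptides =
                      as.integer(x$unique_peptides[rownames(x$values)]),
                    x$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
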