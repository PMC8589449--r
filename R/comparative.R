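# Replicate-level QC: pairwise Pearson correlation of log2 5'-end counts
# at well-covered positions, hierarchical clustering of the correlation
# matrix, and PCA of per-promoter shift profiles across mutants.

#' Pearson correlation of two libraries at well-covered positions
#'
#' Restricts to genome positions carrying at least `min_count` reads in
#' BOTH libraries (default 3, i.e. "greater than two counts"), then
#' correlates the log2-transformed counts. Positions are pooled across
#' strands. With fewer than 3 qualifying shared positions the correlation
#' is undefined and `NA` is returned rather than 0.
#'
#' @param a,b `tss_signal` tibbles.
#' @param min_count Minimum count per library for a position to qualify.
#' @return Pearson r, or `NA_real_` if undefined.
#' @export
correlate_pair <- function(a, b, min_count = 3) {
  shared <- dplyr::inner_join(
    dplyr::filter(as_tibble(a), .data$count >= min_count),
    dplyr::filter(as_tibble(b), .data$count >= min_count),
    by = c("chrom", "strand", "pos"), suffix = c("_a", "_b")
  )
  if (nrow(shared) < 3) return(NA_real_)
  la <- log2(shared$count_a); lb <- log2(shared$count_b)
  if (stats::sd(la) == 0 || stats::sd(lb) == 0) return(NA_real_)
  stats::cor(la, lb)
}

#' All-pairs correlation matrix for a set of libraries
#'
#' @param signals Named list of `tss_signal` tibbles.
#' @param min_count Passed to [correlate_pair()].
#' @return A `tss_corr` object wrapping the symmetric r matrix (diagonal
#'   1); undefined pairs are `NA`.
#' @export
correlation_matrix <- function(signals, min_count = 3) {
  if (is.null(names(signals)) || any(!nzchar(names(signals)))) {
    names(signals) <- paste0("lib", seq_along(signals))
  }
  k <- length(signals)
  r <- diag(1, k)
  dimnames(r) <- list(names(signals), names(signals))
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in seq.int(i + 1, k)) {
        r[i, j] <- r[j, i] <- correlate_pair(signals[[i]], signals[[j]],
                                             min_count = min_count)
      }
    }
  }
  structure(list(r = r, labels = names(signals), min_count = min_count),
            class = "tss_corr")
}

#' @export
print.tss_corr <- function(x, ...) {
  cat(sprintf("Pairwise Pearson r (log2 counts, positions >= %d reads in both)\n",
              x$min_count))
  print(round(x$r, 3))
  invisible(x)
}

#' @method tidy tss_corr
#' @export
tidy.tss_corr <- function(x, ...) {
  as_tibble(as.data.frame.table(x$r, responseName = "r",
                                stringsAsFactors = FALSE)) |>
    dplyr::rename(library_a = "Var1", library_b = "Var2")
}

#' Hierarchically cluster the rows of a correlation matrix
#'
#' Agglomerative clustering of the matrix rows under Euclidean distance
#' (average linkage; the linkage choice is recorded on the result).
#' Replicates of the same genotype are expected to be mutual nearest
#' neighbours — r above the acceptance threshold and adjacent leaves.
#'
#' @param corr A `tss_corr` object or a complete numeric matrix.
#' @param method Linkage method passed to [stats::hclust()].
#' @return A `tss_clust` list: `hclust`, `leaf_order` (labels), `newick`
#'   (the tree as a Newick string), `linkage`.
#' @export
cluster_rows <- function(corr, method = "average") {
  r <- if (inherits(corr, "tss_corr")) corr$r else as.matrix(corr)
  if (anyNA(r)) abort("correlation matrix has missing cells; cannot cluster")
  hc <- stats::hclust(stats::dist(r, method = "euclidean"), method = method)
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hclust = hc, leaf_order = hc$labels[hc$order],
                 newick = newick, linkage = method),
            class = "tss_clust")
}

#' @export
print.tss_clust <- function(x, ...) {
  cat("Hierarchical clustering (Euclidean distance, ", x$linkage,
      " linkage)\nleaf order: ", paste(x$leaf_order, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Assemble a mutants x promoters shift-profile matrix
#'
#' @param shift_tables Named list of `tss_shifts` tibbles, one per mutant.
#' @return A tibble with column `mutant` then one column per promoter
#'   (shift in nt; `NA` where undefined).
#' @export
shift_profile_matrix <- function(shift_tables) {
  if (is.null(names(shift_tables))) {
    names(shift_tables) <- paste0("mutant", seq_along(shift_tables))
  }
  purrr::imap(shift_tables, function(s, nm) {
    tibble(mutant = nm, promoter_id = s$promoter_id, shift = s$shift)
  }) |>
    dplyr::bind_rows() |>
    tidyr::pivot_wider(names_from = "promoter_id", values_from = "shift")
}

#' PCA of per-promoter shift profiles across mutants
#'
#' Column-centred principal component analysis of the mutants x promoters
#' shift matrix. Missing shifts are imputed as 0 nt (no measurable shift)
#' for the PCA only. Mutant classes that move TSSs in opposite directions
#' separate along the leading components.
#'
#' @param m Output of [shift_profile_matrix()] (tibble with `mutant`
#'   column), or a numeric matrix with mutant rownames.
#' @return A `tss_pca` list: `scores` tibble (mutant, PC1..), `var_frac`
#'   (explained-variance fractions), and the underlying `prcomp` fit.
#' @export
pca_shifts <- function(m) {
  if (is.data.frame(m)) {
    mat <- as.matrix(m[, setdiff(names(m), "mutant"), drop = FALSE])
    rownames(mat) <- m$mutant
  } else {
    mat <- as.matrix(m)
  }
  if (nrow(mat) < 2) abort("PCA needs at least 2 mutants")
  mat[is.na(mat)] <- 0
  fit <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  var_frac <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- dplyr::bind_cols(tibble(mutant = rownames(mat)),
                             as_tibble(fit$x))
  structure(list(scores = scores, var_frac = var_frac, fit = fit),
            class = "tss_pca")
}

#' @export
print.tss_pca <- function(x, ...) {
  cat("PCA of TSS shift profiles\n")
  cat("variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$var_frac[seq_len(min(4, length(x$var_frac)))]),
            collapse = ", "), "\n")
  print(x$scores[, seq_len(min(4, ncol(x$scores)))])
  invisible(x)
}

#' @method tidy tss_pca
#' @export
tidy.tss_pca <- function(x, ...) {
  x$scores |>
    tidyr::pivot_longer(-"mutant", names_to = "component",
                        values_to = "score")
}

#' @method glance tss_pca
#' @export
glance.tss_pca <- function(x, ...) {
  tibble(n_mutants = nrow(x$scores),
         n_components = length(x$var_frac),
         pc1_var = x$var_frac[1],
         pc2_var = if (length(x$var_frac) >= 2) x$var_frac[2] else NA_real_)
}
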