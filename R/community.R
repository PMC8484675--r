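#' Bray-Curtis dissimilarity of a copy-number table
#'
#' BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i), computed on the copy numbers
#' as-is (no relative-abundance standardisation; an optional square-root
#' transform is available for sensitivity analyses). A pair of all-zero
#' samples has an undefined ratio and is set to 0 with a warning.
#'
#' @param mat Non-negative numeric matrix, samples x taxa (e.g. the
#'   `copies_per_ml` element of a [quantify_table()] result).
#' @param transform `"none"` (default) or `"sqrt"`.
#' @return A `dist` object of Bray-Curtis dissimilarities in [0, 1].
#' @export
bray_curtis <- function(mat, transform = c("none", "sqrt")) {
  transform <- match.arg(transform)
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("abundances must be non-negative")
  if (transform == "sqrt") mat <- sqrt(mat)
  d <- suppressWarnings(vegan::vegdist(mat, method = "bray"))
  if (anyNA(d)) {
    warning("all-zero sample pair(s): dissimilarity set to 0")
    d[is.na(d)] <- 0
  }
  d
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Embeds samples in `k` dimensions preserving dissimilarity ranks, by
#' minimising Kruskal stress-1 over `n_starts` random restarts and keeping
#' the best configuration. Coordinates are centred.
#'
#' @param d A `dist` (e.g. from [bray_curtis()]); needs >= 4 samples.
#' @param k Embedding dimension (default 2).
#' @param n_starts Random restarts (default 50).
#' @param seed RNG seed; fixed seed gives identical coordinates.
#' @return List of class `ordination`: `points` (n x k matrix), `stress`
#'   (stress-1), `n_starts`, `converged`.
#' @export
nmds <- function(d, k = 2, n_starts = 50, seed = 1L) {
  if (attr(d, "Size") < 4) stop("NMDS needs at least 4 samples")
  set.seed(seed)
  m <- vegan::metaMDS(d, k = k, try = n_starts, trymax = n_starts,
                      trace = FALSE, autotransform = FALSE, wascores = FALSE)
  pts <- scale(m$points, center = TRUE, scale = FALSE)
  structure(
    list(points = pts, stress = m$stress, n_starts = n_starts,
         converged = isTRUE(m$converged) || m$converged > 0, seed = seed),
    class = "ordination"
  )
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %d samples in %d-D, stress = %.3f (%d starts)\n",
              nrow(x$points), ncol(x$points), x$stress, x$n_starts))
  invisible(x)
}

#' Permutational multivariate analysis of variance
#'
#' Partitions the squared dissimilarities among and within groups (Anderson's
#' pseudo-F via the Gower-centred matrix) and evaluates significance by free
#' permutation of sample labels: p = (#{F_perm >= F_obs} + 1)/(n_perm + 1).
#'
#' @param d A `dist`.
#' @param groups Factor of group labels (>= 2 non-empty groups).
#' @param n_perm Number of permutations (default 999).
#' @param seed RNG seed; results are exactly reproducible for a fixed seed.
#' @return List of class `permanova`: `f`, `p_value`, `n_perm`, `df`, `r2`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) == 0)) stop("groups must be non-empty")
  set.seed(seed)
  df <- data.frame(groups = groups)
  res <- vegan::adonis2(d ~ groups, data = df, permutations = n_perm)
  structure(
    list(f = res$F[1], p_value = res$`Pr(>F)`[1], n_perm = n_perm,
         df = res$Df[1], r2 = res$R2[1], table = as.data.frame(res)),
    class = "permanova"
  )
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("<permanova> F = %.3f (df = %d), p = %.4g (%d permutations)\n",
              x$f, x$df, x$p_value, x$n_perm))
  invisible(x)
}
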