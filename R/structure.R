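#' Principal component analysis of a genotype matrix
#'
#' Missing codes are imputed with the per-site mean, columns are
#' mean-centered (no unit-variance scaling), and scores come from the
#' eigen-decomposition of the sample covariance matrix. Variance explained
#' is eigenvalue over total variance. Sign convention: the loading of
#' largest magnitude of each component is made positive, so results do not
#' depend on sample or site order.
#'
#' @param gm genotype_matrix with at least 2 samples and 1 polymorphic site.
#' @param k number of components to return.
#' @return list of class `pca_result` with `scores` (samples x k),
#'   `variance_explained` (length k) and `loadings`.
#' @export
pca <- function(gm, k = 2) {
  X <- impute_center(gm)
  if (nrow(X) < 2) stop("PCA needs at least two samples")
  if (all(abs(X) < 1e-12)) stop("all sites are monomorphic")
  k <- min(k, nrow(X) - 1L, ncol(X))
  S <- cov(X)
  eg <- eigen(S, symmetric = TRUE)
  total <- sum(diag(S))
  ve <- pmax(eg$values, 0) / total
  load <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  scores <- X %*% load
  rownames(scores) <- gm$samples$sample_id
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, variance_explained = ve[seq_len(k)],
                 loadings = load),
            class = "pca_result")
}

impute_center <- function(gm) {
  X <- gm$geno
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  sweep(X, 2, mu)
}

#' Restrict a genotype matrix to one subgenome
#'
#' @param gm genotype_matrix.
#' @param s subgenome, one of `"A"`, `"B"`, `"D"`, `"unanchored"`.
#' @return genotype_matrix with matching sites; a warning is raised when no
#'   site matches.
#' @export
subgenome_subset <- function(gm, s = c("A", "B", "D", "unanchored")) {
  s <- match.arg(s)
  keep <- gm$sites$subgenome == s
  if (!any(keep)) warning("no sites on subgenome ", s)
  gm_subset(gm, sites = keep)
}

#' Randomly sub-sample SNPs
#'
#' Uniform sampling without replacement, deterministic under `seed`;
#' original site order is preserved.
#'
#' @param gm genotype_matrix.
#' @param n number of sites to keep.
#' @param seed integer seed.
#' @return genotype_matrix with `n` sites.
#' @export
subsample_sites <- function(gm, n = 3500, seed = 1) {
  if (n > ncol(gm$geno))
    stop("cannot sample ", n, " sites from ", ncol(gm$geno))
  idx <- with_seed(seed, sample.int(ncol(gm$geno), n))
  gm_subset(gm, sites = sort(idx))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Classical multidimensional scaling on identity-by-state distances
#'
#' Pairwise distance is 1 - IBS, where IBS between two samples is the mean
#' over sites non-missing in both of `(2 - |g_i - g_j|) / 2`. Coordinates
#' are the top-2 axes of classical (metric) MDS, i.e. eigenvectors of the
#' double-centered squared-distance matrix scaled by the square root of
#' their eigenvalues; these are the stratification covariates of the GWAS.
#'
#' @param gm genotype_matrix with at least 3 samples.
#' @return list of class `mds_coordinates` with `coords` (samples x 2) and
#'   `eigenvalues`.
#' @export
mds_coordinates <- function(gm) {
  if (nrow(gm$geno) < 3) stop("MDS needs at least three samples")
  D <- ibs_distance(gm)
  md <- cmdscale(as.dist(D), k = 2, eig = TRUE)
  coords <- md$points
  rownames(coords) <- gm$samples$sample_id
  colnames(coords) <- c("C1", "C2")
  structure(list(coords = coords, eigenvalues = md$eig),
            class = "mds_coordinates")
}

ibs_distance <- function(gm) {
  G <- gm$geno
  storage.mode(G) <- "double"
  M <- !is.na(G)
  G0 <- G
  G0[!M] <- 0
  n_shared <- tcrossprod(M * 1)
  if (any(n_shared == 0)) {
    bad <- which(n_shared == 0, arr.ind = TRUE)[1, ]
    stop("samples ", gm$samples$sample_id[bad[1]], " and ",
         gm$samples$sample_id[bad[2]], " share no non-missing site")
  }
  # sum over shared sites of |g_i - g_j| via the identity
  # |a-b| = a + b - 2*min(a,b); genotype codes are 0/1/2, so accumulate
  # min(a,b) from indicator matrices of (g>=1) and (g==2).
  A1 <- (G0 >= 1) * M
  A2 <- (G0 == 2) * M
  sum_i <- G0 %*% t(M)      # sum of g_i over sites shared with j
  sum_j <- t(sum_i)
  min_ab <- tcrossprod(A1) + tcrossprod(A2)
  sum_abs <- sum_i + sum_j - 2 * min_ab
  ibs <- 1 - sum_abs / (2 * n_shared)
  D <- 1 - ibs
  diag(D) <- 0
  D
}
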