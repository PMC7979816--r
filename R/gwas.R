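#' Scan configuration
#'
#' @param maf_min minor-allele-frequency filter (default 0.05, strict
#'   `"gt"` comparator as in the study's 18,260-SNP GWAS set).
#' @param maf_comparator `"gt"` or `"ge"`.
#' @param n_covariates number of MDS axes used as covariates (default 2).
#' @param alpha genome-wide significance threshold (default 1e-5).
#' @return list of class `scan_config`.
#' @export
scan_config <- function(maf_min = 0.05, maf_comparator = "gt",
                        n_covariates = 2, alpha = 1e-5) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(maf_min = maf_min, maf_comparator = maf_comparator,
                 n_covariates = n_covariates, alpha = alpha),
            class = "scan_config")
}

#' Case/control logistic association scan
#'
#' For every SNP passing the MAF filter, fits by maximum likelihood
#' `red ~ intercept + genotype + covariates` (additive coding: the
#' alt-allele count enters linearly on the log-odds scale) on the samples
#' non-missing for that site, using iteratively reweighted least squares
#' (Newton-type; convergence when the log-likelihood change drops below
#' 1e-8 or after 25 iterations). The p-value is the Wald test of the
#' genotype coefficient. Fits hit by separation (a Mendelian-grade locus
#' drives the ML estimate to infinity, where the Wald statistic collapses)
#' or non-convergence are flagged and fall back to the likelihood-ratio
#' test of the genotype term, mirroring the fallback strategy of standard
#' association tools; the `method` column records which test produced each
#' p.
#'
#' @param gm genotype_matrix.
#' @param phen named vector sample_id -> `"red"`/`"white"` (`NA` dropped).
#' @param covs mds_coordinates (or a numeric matrix with rownames), or
#'   `NULL` for an unadjusted scan.
#' @param cfg scan_config.
#' @return data.frame of class `assoc_result`: `chrom`, `pos`,
#'   `site_index`, `beta`, `se`, `p`, `n_used`, `converged`.
#' @export
logistic_scan <- function(gm, phen, covs = NULL, cfg = scan_config()) {
  ids <- intersect(gm$samples$sample_id, names(phen)[!is.na(phen)])
  if (!length(ids)) stop("no phenotyped samples in the cohort")
  y <- as.integer(phen[ids] == "red")
  if (all(y == 1L) || all(y == 0L))
    stop("phenotype has no variation (all-case or all-control)")
  sub <- gm_subset(gm, samples = match(ids, gm$samples$sample_id))
  C <- NULL
  if (!is.null(covs)) {
    M <- if (inherits(covs, "mds_coordinates")) covs$coords else as.matrix(covs)
    if (is.null(rownames(M))) stop("covariates need sample ids as rownames")
    C <- M[ids, seq_len(min(cfg$n_covariates, ncol(M))), drop = FALSE]
  }
  maf <- site_maf(sub)
  pass <- if (cfg$maf_comparator == "gt") maf > cfg$maf_min else maf >= cfg$maf_min
  idx <- which(pass)
  out <- lapply(idx, function(s) {
    g <- sub$geno[, s]
    ok <- !is.na(g)
    X <- cbind(g = g[ok], C[ok, , drop = FALSE])
    fit <- tryCatch(
      suppressWarnings(glm(y[ok] ~ X, family = binomial(),
                           control = list(epsilon = 1e-8, maxit = 25))),
      error = function(e) NULL)
    row <- data.frame(chrom = sub$sites$chrom[s], pos = sub$sites$pos[s],
                      site_index = s, beta = NA_real_, se = NA_real_,
                      p = NA_real_, n_used = sum(ok), converged = FALSE,
                      method = NA_character_, stringsAsFactors = FALSE)
    if (is.null(fit)) return(row)
    b <- coef(fit)[2] # genotype is the first column after the intercept
    se <- sqrt(diag(vcov(fit)))[2]
    separated <- !fit$converged || !is.finite(se) || se > 10 || abs(b) > 15
    row$beta <- unname(b)
    row$se <- unname(se)
    row$converged <- !separated
    if (!separated) {
      z2 <- (b / se)^2
      row$p <- unname(pchisq(z2, df = 1, lower.tail = FALSE))
      row$method <- "wald"
    } else {
      # likelihood-ratio fallback: drop the genotype column, same samples
      null_fit <- tryCatch(suppressWarnings({
        if (ncol(X) > 1)
          glm(y[ok] ~ X[, -1, drop = FALSE], family = binomial(),
              control = list(epsilon = 1e-8, maxit = 25))
        else
          glm(y[ok] ~ 1, family = binomial(),
              control = list(epsilon = 1e-8, maxit = 25))
      }), error = function(e) NULL)
      if (!is.null(null_fit)) {
        lrt <- null_fit$deviance - fit$deviance
        row$p <- pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
        row$method <- "lrt"
      }
    }
    row
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(0), pos = integer(0),
                      site_index = integer(0), beta = numeric(0),
                      se = numeric(0), p = numeric(0), n_used = integer(0),
                      converged = logical(0), method = character(0))
  rownames(res) <- NULL
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' Quantile-quantile data and genomic inflation factor
#'
#' @param pvals numeric p-values (`NA` dropped).
#' @return list with `points` (data.frame of `expected` and `observed`
#'   -log10 quantiles, observed ascending p) and `lambda`, the genomic
#'   inflation factor median(observed chi-square) / median(null
#'   chi-square).
#' @export
qq_data <- function(pvals) {
  p <- sort(pvals[!is.na(pvals)])
  if (!length(p)) stop("no valid p-values")
  n <- length(p)
  expected <- seq_len(n) / (n + 1)
  chi <- qchisq(p, df = 1, lower.tail = FALSE)
  list(points = data.frame(expected = -log10(expected),
                           observed = -log10(p)),
       lambda = median(chi) / qchisq(0.5, df = 1))
}

#' Group significant SNPs into peak intervals
#'
#' Sites with `p < alpha` are grouped per chromosome into maximal runs in
#' which consecutive significant sites are less than `gap` bases apart;
#' each run is reported as the physical interval of its members. The gap
#' rule is this pipeline's convention for delimiting an association peak.
#'
#' @param results assoc_result.
#' @param cfg scan_config (supplies `alpha`).
#' @param gap maximum distance between consecutive significant sites in a
#'   peak (default 5 Mb).
#' @return data.frame with `chrom`, `start`, `end`, `n_sites`, `top_pos`,
#'   `top_p`; zero rows when nothing is significant.
#' @export
significant_interval <- function(results, cfg = scan_config(), gap = 5e6) {
  stopifnot(nrow(results) > 0)
  sig <- results[!is.na(results$p) & results$p < cfg$alpha, , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_sites = integer(0),
                      top_pos = integer(0), top_p = numeric(0))
  if (!nrow(sig)) return(empty)
  sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
  rows <- lapply(split(sig, sig$chrom), function(d) {
    brk <- c(0, cumsum(diff(d$pos) >= gap))
    do.call(rbind, lapply(split(d, brk), function(run) {
      top <- which.min(run$p)
      data.frame(chrom = run$chrom[1], start = min(run$pos),
                 end = max(run$pos), n_sites = nrow(run),
                 top_pos = run$pos[top], top_p = run$p[top],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
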