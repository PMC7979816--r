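#' Hypergeometric projection of one site's allele counts
#'
#' Projects a site observed with `k` derived alleles out of `n` sampled
#' alleles down to `m` alleles: mass at `j` is the probability of drawing
#' `j` derived alleles in `m` draws without replacement. Projection lets
#' sites with missing calls contribute fractional mass at a common sample
#' size instead of being dropped.
#'
#' @param k derived-allele count at the site (0..n).
#' @param n total non-missing alleles at the site.
#' @param m projection target; when `m > n` the site cannot be projected
#'   and `NULL` is returned (drop signal, not an error).
#' @return numeric vector of `m + 1` masses summing to 1, or `NULL`.
#' @export
project_site <- function(k, n, m) {
  stopifnot(k >= 0, k <= n, m >= 0)
  if (m > n) return(NULL)
  dhyper(0:m, k, n - k, m)
}

#' Folded joint site-frequency spectrum for a population pair
#'
#' Per site, each population's allele counts (over non-missing calls) are
#' projected independently to the target sizes; the outer product of the
#' two projection vectors is accumulated on an `(n_a+1) x (n_b+1)` grid.
#' Because the ancestral state is unknown the grid is folded: mass at
#' `(i, j)` with `i + j > (n_a + n_b) / 2` is reflected onto
#' `(n_a - i, n_b - j)`; mass exactly on the fold line stays in the cell
#' with the smaller `i` (ties: smaller `j`). The monomorphic corners
#' `(0, 0)` and `(n_a, n_b)` are zeroed after folding and the removed mass
#' recorded. Cells that cannot carry mass after folding (beyond the fold
#' line, the reflected-away half of the line, and the two corners) are
#' masked.
#'
#' @param gm genotype_matrix.
#' @param pop_a,pop_b disjoint character vectors of sample ids.
#' @param n_a,n_b projected haploid sample sizes (at least 2 each).
#' @param labels length-2 population labels for reporting.
#' @return object of class `folded_sfs_2d`: `grid`, logical `mask`
#'   (`TRUE` = invalid cell), `n_a`, `n_b`, `labels`, `n_segregating`
#'   (total unmasked mass), `removed_mass`, `n_sites_used`.
#' @export
folded_sfs_2d <- function(gm, pop_a, pop_b, n_a, n_b,
                          labels = c("popA", "popB")) {
  stopifnot(n_a >= 2, n_b >= 2)
  if (length(intersect(pop_a, pop_b)))
    stop("populations must be disjoint")
  if (!length(pop_a) || !length(pop_b))
    stop("populations must be nonempty")
  ia <- match(pop_a, gm$samples$sample_id)
  ib <- match(pop_b, gm$samples$sample_id)
  if (anyNA(ia) || anyNA(ib)) stop("unknown sample id in population spec")
  if (n_a > 2 * length(ia) || n_b > 2 * length(ib))
    stop("projection target exceeds available alleles")
  ga <- gm$geno[ia, , drop = FALSE]
  gb <- gm$geno[ib, , drop = FALSE]
  grid <- matrix(0, n_a + 1, n_b + 1)
  used <- 0L
  for (s in seq_len(ncol(gm$geno))) {
    ta <- 2L * sum(!is.na(ga[, s]))
    tb <- 2L * sum(!is.na(gb[, s]))
    if (ta < n_a || tb < n_b) next
    va <- project_site(sum(ga[, s], na.rm = TRUE), ta, n_a)
    vb <- project_site(sum(gb[, s], na.rm = TRUE), tb, n_b)
    grid <- grid + tcrossprod(va, vb)
    used <- used + 1L
  }
  finish_folded_sfs(grid, n_a, n_b, labels, n_sites_used = used)
}

# fold an unfolded (n_a+1) x (n_b+1) grid, zero monomorphic corners,
# return the folded_sfs_2d structure shared by observed and expected paths
finish_folded_sfs <- function(grid, n_a, n_b, labels, n_sites_used = NA_integer_) {
  fm <- fold_map(n_a, n_b)
  acc <- rowsum(as.vector(grid), fm$target)
  folded <- matrix(0, n_a + 1, n_b + 1)
  folded[as.integer(rownames(acc))] <- acc
  removed <- folded[1, 1] + folded[n_a + 1, n_b + 1]
  folded[1, 1] <- 0
  folded[n_a + 1, n_b + 1] <- 0
  structure(list(grid = folded, mask = fm$mask, n_a = n_a, n_b = n_b,
                 labels = labels, n_segregating = sum(folded),
                 removed_mass = removed, n_sites_used = n_sites_used),
            class = "folded_sfs_2d")
}

# linear index map sending every cell to its post-fold destination, and the
# mask of cells that cannot carry mass after folding (memoized; the map is
# recomputed for every objective evaluation otherwise)
.fold_cache <- new.env(parent = emptyenv())

fold_map <- function(n_a, n_b) {
  key <- paste0(n_a, "_", n_b)
  hit <- .fold_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- fold_map_build(n_a, n_b)
  .fold_cache[[key]] <- out
  out
}

fold_map_build <- function(n_a, n_b) {
  i <- rep(0:n_a, times = n_b + 1)
  j <- rep(0:n_b, each = n_a + 1)
  half <- (n_a + n_b) / 2
  refl <- (n_b - j) * (n_a + 1) + (n_a - i) + 1
  self <- j * (n_a + 1) + i + 1
  over <- (i + j) > half
  online <- (i + j) == half
  move_line <- online & (i > (n_a - i) | (i == (n_a - i) & j > (n_b - j)))
  target <- ifelse(over | move_line, refl, self)
  mask <- over | move_line
  mask[self == 1] <- TRUE                       # (0,0)
  mask[self == (n_a + 1) * (n_b + 1)] <- TRUE   # (n_a, n_b)
  list(target = target, mask = matrix(mask, n_a + 1, n_b + 1))
}

#' @export
print.folded_sfs_2d <- function(x, ...) {
  cat("folded 2D SFS ", x$labels[1], " (n=", x$n_a, ") x ", x$labels[2],
      " (n=", x$n_b, "); segregating mass ", format(x$n_segregating), "\n",
      sep = "")
  invisible(x)
}

#' Observed folded pairwise spectra for a three-population cohort
#'
#' Convenience wrapper building the three pairwise folded spectra
#' (Asia/CentralEurope, Asia/Iberia, CentralEurope/Iberia) that the
#' demographic fit consumes, from a cohort whose `population` labels carry
#' those three names.
#'
#' @param gm genotype_matrix with populations Asia, CentralEurope, Iberia.
#' @param proj projected haploid sample sizes, in the order
#'   (Asia, CentralEurope, Iberia).
#' @return named list of three folded_sfs_2d (`asia_ce`, `asia_ib`,
#'   `ce_ib`), the order [fit_model()] expects.
#' @export
observed_sfs_triple <- function(gm, proj) {
  pops <- split(gm$samples$sample_id, gm$samples$population)
  need <- c("Asia", "CentralEurope", "Iberia")
  miss <- setdiff(need, names(pops))
  if (length(miss))
    stop("cohort lacks population(s): ", paste(miss, collapse = ", "))
  list(
    asia_ce = folded_sfs_2d(gm, pops$Asia, pops$CentralEurope,
                            proj[1], proj[2], c("Asia", "CentralEurope")),
    asia_ib = folded_sfs_2d(gm, pops$Asia, pops$Iberia,
                            proj[1], proj[3], c("Asia", "Iberia")),
    ce_ib = folded_sfs_2d(gm, pops$CentralEurope, pops$Iberia,
                          proj[2], proj[3], c("CentralEurope", "Iberia")))
}

#' Write / read a folded 2D SFS in a dadi-style flat text layout
#'
#' Line 1: `n_a+1 n_b+1 folded "labelA" "labelB"`; line 2: the grid masses
#' in row-major (a-fastest) order; line 3: the mask as 0/1.
#'
#' @param sfs folded_sfs_2d.
#' @param path file path.
#' @return `path` (write) or a folded_sfs_2d (read).
#' @export
write_sfs <- function(sfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(sfs$n_a + 1, sfs$n_b + 1, "folded",
                   shQuote(sfs$labels[1]), shQuote(sfs$labels[2])), con)
  writeLines(paste(format(as.vector(sfs$grid), digits = 17), collapse = " "), con)
  writeLines(paste(as.integer(as.vector(sfs$mask)), collapse = " "), con)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  hdr <- scan(text = lines[1], what = "character", quiet = TRUE)
  n_a <- as.integer(hdr[1]) - 1L
  n_b <- as.integer(hdr[2]) - 1L
  labels <- gsub("'", "", hdr[4:5])
  grid <- matrix(scan(text = lines[2], quiet = TRUE), n_a + 1, n_b + 1)
  mask <- matrix(scan(text = lines[3], quiet = TRUE) > 0, n_a + 1, n_b + 1)
  structure(list(grid = grid, mask = mask, n_a = n_a, n_b = n_b,
                 labels = labels, n_segregating = sum(grid),
                 removed_mass = NA_real_, n_sites_used = NA_integer_),
            class = "folded_sfs_2d")
}
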