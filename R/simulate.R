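#' Cohort specification for the synthetic-data generator
#'
#' The generator emulates the study's three-population diversity panel:
#' diploid samples from Asia, Central Europe and Iberia, unlinked biallelic
#' SNPs from the package's own coalescent simulator, positions spaced at
#' least 20 kb apart on synthetic chromosomes 1A..7D, and missing calls
#' at a fixed per-call rate (missing completely at random; the study gives
#' no missingness mechanism). The default missing rate (0.15) is below the
#' 20% site filter so simulated sites survive it.
#'
#' @param n_diploid named integer vector `c(asia=, ce=, ib=)` of diploid
#'   sample counts per population (each at least 1).
#' @param model demographic_model genotypes are simulated under.
#' @param n_sites number of segregating SNPs.
#' @param missing_rate per-call missing probability in \[0, 1).
#' @param seed integer seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_diploid = c(asia = 18, ce = 162, ib = 29),
                        model = default_truth_model(),
                        n_sites = 1000, missing_rate = 0.15, seed = 1) {
  stopifnot(length(n_diploid) == 3, all(n_diploid >= 1),
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_diploid = n_diploid, model = model, n_sites = n_sites,
                 missing_rate = missing_rate, seed = seed),
            class = "cohort_spec")
}

#' Default generating model for synthetic cohorts
#'
#' Independent origins of Central European and Iberian spelt from the Asian
#' gene pool, with split times matching the study's reported divergence
#' estimates (1023 and 1218 generations) and diploid sizes chosen once as
#' plausible for a crop gene pool.
#'
#' @return demographic_model.
#' @export
default_truth_model <- function() {
  build_model("independent_origins", "asian",
              c(N_asia = 2000, N_ce = 1500, N_ib = 800,
                t_ce = 1023, t_ib = 1218))
}

#' Simulate a genotyped cohort
#'
#' Haploid lineages are simulated with [simulate_genotypes()] and paired
#' into diploids within each population; missingness is applied
#' independently per call. Site positions are laid out left to right on
#' chromosomes 1A..7D with gaps of at least 20 kb, so thinning and
#' subgenome operations are exercised downstream. Deterministic under the
#' spec seed.
#'
#' The result carries attributes `n_loci` (the implied number of mutational
#' targets, `n_sites / (mu * mean_total_length)`, used as the scale anchor
#' when refitting demographic models to this cohort) and
#' `mean_total_length`.
#'
#' @param spec cohort_spec.
#' @return genotype_matrix with populated sample metadata.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_sites == 0L) {
    warning("n_sites is zero; returning an empty cohort")
    ids <- cohort_sample_ids(spec$n_diploid)
    return(empty_gm(ids$sample_id, ids))
  }
  hap <- 2L * as.integer(spec$n_diploid)
  sim <- simulate_genotypes(spec$model, hap, spec$n_sites, seed = spec$seed)
  # pair consecutive haploid lineages into diploids within each population
  geno <- sim$alleles[seq(1, sum(hap), by = 2), , drop = FALSE] +
    sim$alleles[seq(2, sum(hap), by = 2), , drop = FALSE]
  samples <- cohort_sample_ids(spec$n_diploid)
  sites <- synth_site_table(spec$n_sites, seed = spec$seed + 1L)
  if (spec$missing_rate > 0) {
    drop <- with_seed(spec$seed + 2L,
                      matrix(runif(length(geno)) < spec$missing_rate,
                             nrow(geno)))
    geno[drop] <- NA_integer_
  }
  gm <- genotype_matrix(geno, samples, sites)
  attr(gm, "n_loci") <- spec$n_sites / (spec$model$mu * sim$mean_total_length)
  attr(gm, "mean_total_length") <- sim$mean_total_length
  gm
}

cohort_sample_ids <- function(n_diploid) {
  pops <- c("Asia", "CentralEurope", "Iberia")
  prefix <- c("AS", "CE", "IB")
  rows <- lapply(1:3, function(p)
    data.frame(sample_id = sprintf("%s%03d", prefix[p], seq_len(n_diploid[p])),
               subspecies = "spelta", origin = pops[p], population = pops[p],
               stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# positions >= 20 kb apart, chromosomes 1A..7D in sorted order
synth_site_table <- function(n_sites, seed) {
  chroms <- sort(paste0(rep(1:7, each = 3), c("A", "B", "D")))
  per <- rep(ceiling(n_sites / length(chroms)), length(chroms))
  take <- pmin(per, pmax(n_sites - c(0, cumsum(per))[seq_along(per)], 0))
  with_seed(seed, {
    rows <- lapply(seq_along(chroms), function(ci) {
      k <- take[ci]
      if (!k) return(NULL)
      pos <- cumsum(as.integer(runif(k, 20000, 30000)))
      bases <- c("A", "C", "G", "T")
      ref <- sample(bases, k, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
      data.frame(chrom = chroms[ci], pos = pos, ref = ref, alt = unname(alt),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Phenotype specification and injection
#'
#' Glume color follows a dominant model at one causal SNP: carriers of at
#' least one alt allele are red with probability `penetrance`, non-carriers
#' are red with probability `phenocopy_rate`. Samples with a missing call
#' at the causal site are treated as non-carriers. Deterministic under the
#' spec seed.
#'
#' @param causal_site column index of the causal SNP.
#' @param model inheritance model; only `"dominant"` is supported.
#' @param penetrance probability a carrier is red.
#' @param phenocopy_rate probability a non-carrier is red.
#' @param seed integer seed.
#' @return list of class `pheno_spec`.
#' @export
pheno_spec <- function(causal_site, model = "dominant", penetrance = 1,
                       phenocopy_rate = 0, seed = 1) {
  model <- match.arg(model, "dominant")
  stopifnot(penetrance >= 0, penetrance <= 1,
            phenocopy_rate >= 0, phenocopy_rate <= 1)
  structure(list(causal_site = causal_site, model = model,
                 penetrance = penetrance, phenocopy_rate = phenocopy_rate,
                 seed = seed),
            class = "pheno_spec")
}

#' @param gm genotype_matrix.
#' @param spec pheno_spec.
#' @return named character vector sample_id -> `"red"`/`"white"`.
#' @rdname pheno_spec
#' @export
inject_phenotype <- function(gm, spec) {
  stopifnot(inherits(spec, "pheno_spec"))
  if (spec$causal_site < 1 || spec$causal_site > ncol(gm$geno))
    stop("causal site index out of range")
  g <- gm$geno[, spec$causal_site]
  obs <- g[!is.na(g)]
  if (length(unique(obs)) < 2)
    stop("causal site is monomorphic")
  carrier <- !is.na(g) & g >= 1L
  p_red <- ifelse(carrier, spec$penetrance, spec$phenocopy_rate)
  red <- with_seed(spec$seed, runif(length(g)) < p_red)
  setNames(ifelse(red, "red", "white"), gm$samples$sample_id)
}
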