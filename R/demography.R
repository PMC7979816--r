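#' Demographic models for the three spelt gene pools
#'
#' Three evolutionary scenarios for the origin of Central European and
#' Iberian spelt, each with the ancestral population taken either as the
#' sampled Asian gene pool or as an unsampled "ghost" population, give six
#' models:
#'
#' * `single_introduction`: one westward migration; a European lineage
#'   leaves the ancestral population at `t_intro` and splits into Central
#'   European and Iberian spelt at `t_div` (`t_div < t_intro`).
#' * `independent_origins`: Central European and Iberian spelt derive from
#'   the ancestral population at independent times `t_ce` and `t_ib`.
#' * `hybrid_geneflow`: the single-introduction topology plus one recent
#'   admixture pulse from Asia into Iberia at `t_pulse` with proportion
#'   `m_pulse`.
#'
#' Ghost variants add an unsampled ancestor of size `N_ghost` which the
#' Asian population itself joins at `t_anc` (later than every other event).
#' Sizes `N_asia`, `N_ce`, `N_ib` are diploid; times are generations.
#'
#' @param scenario one of `"single_introduction"`, `"independent_origins"`,
#'   `"hybrid_geneflow"`.
#' @param ancestral `"asian"` or `"ghost"`.
#' @param params named numeric vector covering `model_param_names(scenario,
#'   ancestral)`.
#' @param mu mutation rate per site per generation (default 1.3e-8).
#' @return object of class `demographic_model`.
#' @export
build_model <- function(scenario = c("single_introduction",
                                     "independent_origins",
                                     "hybrid_geneflow"),
                        ancestral = c("asian", "ghost"),
                        params, mu = 1.3e-8) {
  scenario <- match.arg(scenario)
  ancestral <- match.arg(ancestral)
  need <- model_param_names(scenario, ancestral)
  miss <- setdiff(need, names(params))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  params <- params[need]
  if (any(params[startsWith(need, "t_") | startsWith(need, "N_")] <= 0))
    stop("sizes and times must be strictly positive")
  if ("m_pulse" %in% need && (params[["m_pulse"]] <= 0 || params[["m_pulse"]] >= 1))
    stop("m_pulse must lie in (0, 1)")
  structure(list(id = paste(scenario, ancestral, sep = "."),
                 scenario = scenario, ancestral = ancestral,
                 params = params, mu = mu),
            class = "demographic_model")
}

#' @rdname build_model
#' @export
model_param_names <- function(scenario, ancestral) {
  base <- c("N_asia", "N_ce", "N_ib")
  sc <- switch(scenario,
               single_introduction = c("t_div", "t_intro"),
               independent_origins = c("t_ce", "t_ib"),
               hybrid_geneflow = c("t_div", "t_intro", "t_pulse", "m_pulse"),
               stop("unknown scenario: ", scenario))
  gh <- if (ancestral == "ghost") c("N_ghost", "t_anc") else character(0)
  c(base, sc, gh)
}

#' Enumerate the model registry
#'
#' @return data.frame with one row per (scenario, ancestral) combination
#'   and the free-parameter count `k` of each model.
#' @export
model_registry <- function() {
  grid <- expand.grid(scenario = c("single_introduction", "independent_origins",
                                   "hybrid_geneflow"),
                      ancestral = c("asian", "ghost"),
                      stringsAsFactors = FALSE)
  grid$model_id <- paste(grid$scenario, grid$ancestral, sep = ".")
  grid$k <- mapply(function(s, a) length(model_param_names(s, a)),
                   grid$scenario, grid$ancestral)
  grid
}

# translate a model into the engine's event matrix
# (time, type 0=merge/1=pulse, a, b, x); populations 0-based:
# 0 = Asia, 1 = CentralEurope, 2 = Iberia. A merge a -> a with x > 0 is a
# pure size change (relabels the slot as the ghost ancestor).
# Returns NULL when the parameters violate the topology's time ordering.
model_events <- function(model) {
  p <- as.list(model$params)
  rows <- switch(model$scenario,
    single_introduction = {
      if (p$t_div >= p$t_intro) return(NULL)
      list(c(p$t_div, 0, 2, 1, -1),
           if (model$ancestral == "asian") c(p$t_intro, 0, 1, 0, -1)
           else c(p$t_intro, 0, 1, 1, p$N_ghost))
    },
    independent_origins = {
      if (model$ancestral == "asian") {
        list(c(p$t_ce, 0, 1, 0, -1), c(p$t_ib, 0, 2, 0, -1))
      } else {
        # the earlier-merging slot becomes the ghost ancestor
        first <- if (p$t_ce <= p$t_ib) 1 else 2
        second <- 3 - first
        t1 <- min(p$t_ce, p$t_ib)
        t2 <- max(p$t_ce, p$t_ib)
        list(c(t1, 0, first, first, p$N_ghost),
             c(t2, 0, second, first, -1))
      }
    },
    hybrid_geneflow = {
      if (p$t_pulse >= p$t_div || p$t_div >= p$t_intro) return(NULL)
      list(c(p$t_pulse, 1, 2, 0, p$m_pulse),
           c(p$t_div, 0, 2, 1, -1),
           if (model$ancestral == "asian") c(p$t_intro, 0, 1, 0, -1)
           else c(p$t_intro, 0, 1, 1, p$N_ghost))
    })
  if (is.null(rows)) return(NULL)
  if (model$ancestral == "ghost") {
    tmax <- max(vapply(rows, `[`, numeric(1), 1))
    if (p$t_anc <= tmax) return(NULL)
    ghost_slot <- switch(model$scenario,
                         single_introduction = 1,
                         hybrid_geneflow = 1,
                         independent_origins = if (p$t_ce <= p$t_ib) 1 else 2)
    rows <- c(rows, list(c(p$t_anc, 0, 0, ghost_slot, -1)))
  }
  ev <- do.call(rbind, rows)
  ev[order(ev[, 1]), , drop = FALSE]
}

#' Simulate genealogies and accumulate the joint branch profile
#'
#' Backwards-in-time Kingman coalescent under the model: exponential
#' waiting times at rate `choose(k,2) / (2 N)` within each population,
#' lineage movement at split events, and probabilistic lineage movement at
#' the admixture pulse. For each genealogy the branch length subtending
#' every joint descendant configuration (i from Asia, j from Central
#' Europe, k from Iberia) is accumulated; the mean profile times the
#' mutation rate is the expected unfolded joint SFS under infinite sites.
#'
#' @param model demographic_model.
#' @param sample_sizes haploid sample sizes per population
#'   (Asia, CentralEurope, Iberia); zeros allowed.
#' @param n_genealogies number of simulated genealogies.
#' @param seed integer seed (deterministic).
#' @return list with `profile` (3D array of mean branch lengths, in
#'   generations) and `mean_total_length`.
#' @export
simulate_coalescent <- function(model, sample_sizes, n_genealogies = 1e4,
                                seed = 1) {
  stopifnot(inherits(model, "demographic_model"))
  ev <- model_events(model)
  if (is.null(ev)) stop("parameter values violate the model's event ordering")
  sizes <- unname(model$params[c("N_asia", "N_ce", "N_ib")])
  .coal_branch_profile(as.integer(sample_sizes), as.numeric(sizes), ev,
                       as.integer(n_genealogies), as.numeric(seed))
}

#' Expected folded pairwise spectra under a demographic model
#'
#' Marginalizes the simulated 3D branch profile to the three population
#' pairs, folds each 2D spectrum, zeroes the monomorphic corners,
#' floors zero-mass unmasked cells at `eps = 1 / (10 * n_genealogies)` and
#' renormalizes to probability spectra (unmasked cells sum to 1).
#'
#' @inheritParams simulate_coalescent
#' @return list with `pairs` (list of three folded_sfs_2d probability
#'   spectra named `asia_ce`, `asia_ib`, `ce_ib`), `branch_mass` (the
#'   unmasked folded branch mass per pair, in generations; times the
#'   mutation rate and a locus count this is the expected segregating mass
#'   of each observed spectrum) and `mean_total_length`.
#' @export
expected_sfs <- function(model, sample_sizes, n_genealogies = 1e4, seed = 1) {
  sim <- simulate_coalescent(model, sample_sizes, n_genealogies, seed)
  if (sum(sim$profile) <= 0) stop("model produced no polymorphism")
  eps <- 1 / (10 * n_genealogies)
  labs <- c("Asia", "CentralEurope", "Iberia")
  prof <- sim$profile
  d <- dim(prof)
  marg <- list(
    asia_ce = matrix(rowSums(matrix(prof, d[1] * d[2], d[3])), d[1], d[2]),
    asia_ib = matrix(colSums(aperm(prof, c(2, 1, 3))), d[1], d[3]),
    ce_ib = matrix(colSums(matrix(prof, d[1], d[2] * d[3])), d[2], d[3]))
  pairs <- lapply(names(marg), function(nm) {
    ij <- switch(nm, asia_ce = c(1, 2), asia_ib = c(1, 3), ce_ib = c(2, 3))
    grid2 <- marg[[nm]]
    sfs <- finish_folded_sfs(grid2, dim(grid2)[1] - 1L, dim(grid2)[2] - 1L,
                             labs[ij])
    g <- sfs$grid
    g[!sfs$mask & g <= 0] <- eps
    g[sfs$mask] <- 0
    sfs$branch_mass <- sfs$n_segregating
    sfs$grid <- g / sum(g)
    sfs$n_segregating <- 1
    sfs
  })
  names(pairs) <- names(marg)
  list(pairs = pairs,
       branch_mass = vapply(pairs, `[[`, numeric(1), "branch_mass"),
       mean_total_length = sim$mean_total_length)
}

#' Composite log-likelihood of observed spectra
#'
#' Multinomial composite log-likelihood summed over the three population
#' pairs: `sum(observed_mass * log(expected_probability))` over unmasked
#' cells. When `n_loci` (the number of mutational targets behind the
#' observed spectra) is supplied, a Poisson term on the total observed
#' segregating mass, with expectation `mu * n_loci * sum(expected unmasked
#' branch mass)`, anchors the absolute time/size scale, which a pure
#' multinomial leaves unidentified. Both sides of the anchor are defined on
#' the same (projected) sample configuration, so they are consistent by
#' construction.
#'
#' @param observed list of three folded_sfs_2d (observed masses).
#' @param expected output of [expected_sfs()] (or its `pairs` element,
#'   in which case no anchor term is available).
#' @param n_loci number of mutational targets (optional).
#' @param mu mutation rate per site per generation.
#' @return composite log-likelihood (scalar).
#' @export
composite_loglik <- function(observed, expected, n_loci = NULL,
                             mu = 1.3e-8) {
  exp_pairs <- if (!is.null(expected$pairs)) expected$pairs else expected
  stopifnot(length(observed) == length(exp_pairs))
  ll <- 0
  for (i in seq_along(observed)) {
    o <- observed[[i]]
    e <- exp_pairs[[i]]
    if (!all(dim(o$grid) == dim(e$grid)))
      stop("observed/expected spectrum shapes differ for pair ", i)
    cells <- !o$mask
    ll <- ll + sum(o$grid[cells] * log(e$grid[cells]))
  }
  if (!is.null(n_loci) && !is.null(expected$branch_mass)) {
    s_obs <- sum(vapply(observed, function(o) sum(o$grid), numeric(1)))
    lambda <- mu * n_loci * sum(expected$branch_mass)
    ll <- ll + dpois_log(s_obs, lambda)
  }
  ll
}

dpois_log <- function(x, lambda) x * log(lambda) - lambda - lgamma(x + 1)

#' Default search space for a model's free parameters
#'
#' Sizes and times are searched on the log scale; the admixture proportion
#' on the unit interval. Bounds are deliberately wide; they can be
#' overridden per parameter.
#'
#' @param scenario,ancestral model coordinates (see [build_model()]).
#' @return data.frame of class `search_space` with columns `param`,
#'   `lower`, `upper`, `log_scale`.
#' @export
default_search_space <- function(scenario, ancestral) {
  pn <- model_param_names(scenario, ancestral)
  lower <- ifelse(startsWith(pn, "N_"), 50,
                  ifelse(pn == "m_pulse", 0.01, 50))
  upper <- ifelse(startsWith(pn, "N_"), 50000,
                  ifelse(pn == "m_pulse", 0.9, 20000))
  log_scale <- pn != "m_pulse"
  out <- data.frame(param = pn, lower = lower, upper = upper,
                    log_scale = log_scale, stringsAsFactors = FALSE)
  class(out) <- c("search_space", "data.frame")
  out
}

space_to_internal <- function(theta, space) {
  ifelse(space$log_scale, log(theta), theta)
}

space_from_internal <- function(u, space) {
  setNames(ifelse(space$log_scale, exp(u), u), space$param)
}

#' Fit a demographic model to observed folded spectra
#'
#' Multi-start bounded direct search replacing the original tool's ECM
#' optimizer: each run draws a uniform start in the (log-scaled) search
#' box and maximizes the composite log-likelihood with Nelder-Mead on the
#' internal scale, with the expected spectra evaluated under common random
#' numbers (one fixed simulation seed per run) so the objective is
#' deterministic within a run. Out-of-box or topology-violating proposals
#' are rejected with a large penalty. The best run wins.
#'
#' @param observed list of three folded_sfs_2d in the order
#'   `asia_ce`, `asia_ib`, `ce_ib`.
#' @param scenario,ancestral model coordinates.
#' @param sample_sizes haploid sample sizes (Asia, CentralEurope, Iberia)
#'   matching the observed spectra dimensions.
#' @param space search_space (default [default_search_space()]).
#' @param n_runs independent optimization runs (study setting: 20).
#' @param n_genealogies simulations per objective evaluation.
#' @param seed integer seed; run seeds derive from it.
#' @param n_loci,mu Poisson scale anchor, see [composite_loglik()].
#' @param eval_budget Nelder-Mead iteration budget per run.
#' @param n_screen when positive, this many uniform draws in the search box
#'   are scored first and the best `n_runs` of them seed the Nelder-Mead
#'   runs (instead of raw uniform starts); cheap screening spends the
#'   budget where the surface is promising.
#' @return object of class `fit_result`: `model_id`, `estimates`,
#'   `loglik`, `k`, `aic`, `runs` (per-run table), `seed`.
#' @export
fit_model <- function(observed, scenario, ancestral, sample_sizes,
                      space = default_search_space(scenario, ancestral),
                      n_runs = 20, n_genealogies = 1e4, seed = 1,
                      n_loci = NULL, mu = 1.3e-8,
                      eval_budget = 150, n_screen = 0) {
  pn <- model_param_names(scenario, ancestral)
  if (!setequal(space$param, pn))
    stop("search space does not cover the model's free parameters")
  space <- space[match(pn, space$param), , drop = FALSE]
  lo <- space_to_internal(space$lower, space)
  hi <- space_to_internal(space$upper, space)

  objective <- function(u, sim_seed) {
    if (any(u < lo) || any(u > hi))
      return(1e10 + 1e6 * sum(pmax(lo - u, 0) + pmax(u - hi, 0)))
    theta <- space_from_internal(u, space)
    model <- try(build_model(scenario, ancestral, theta, mu = mu), silent = TRUE)
    if (inherits(model, "try-error")) return(1e10)
    if (is.null(model_events(model))) return(1e10)
    ex <- expected_sfs(model, sample_sizes, n_genealogies, sim_seed)
    -composite_loglik(observed, ex, n_loci = n_loci, mu = mu)
  }

  runs <- vector("list", n_runs)
  n_draw <- max(n_screen, n_runs)
  starts <- with_seed(seed, matrix(runif(n_draw * length(pn)), n_draw))
  starts <- sweep(sweep(starts, 2, hi - lo, `*`), 2, lo, `+`)
  if (n_screen > 0) {
    screen_seed <- (seed * 1009) %% .Machine$integer.max
    sc <- apply(starts, 1, objective, sim_seed = screen_seed)
    starts <- starts[order(sc)[seq_len(n_runs)], , drop = FALSE]
  }
  for (r in seq_len(n_runs)) {
    sim_seed <- (seed * 1009 + r * 7919) %% .Machine$integer.max
    u0 <- starts[r, ]
    opt <- optim(u0, objective, sim_seed = sim_seed, method = "Nelder-Mead",
                 control = list(maxit = eval_budget, reltol = 1e-4))
    runs[[r]] <- list(par = space_from_internal(opt$par, space),
                      loglik = -opt$value, convergence = opt$convergence)
  }
  ll <- vapply(runs, `[[`, numeric(1), "loglik")
  best <- which.max(ll)
  k <- length(pn)
  res <- list(model_id = paste(scenario, ancestral, sep = "."),
              scenario = scenario, ancestral = ancestral,
              estimates = runs[[best]]$par,
              loglik = ll[best], k = k, aic = 2 * k - 2 * ll[best],
              runs = data.frame(run = seq_len(n_runs), loglik = ll,
                                convergence = vapply(runs, `[[`, numeric(1),
                                                     "convergence")),
              seed = seed)
  class(res) <- "fit_result"
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit of", x$model_id, "- loglik", format(x$loglik),
      "AIC", format(x$aic), "\n")
  print(round(x$estimates, 3))
  invisible(x)
}

#' Rank fitted models by AIC
#'
#' Ascending AIC; ties broken by fewer parameters, then model id.
#'
#' @param fits list of fit_result objects.
#' @return data.frame with columns `model_id`, `k`, `loglik`, `aic`,
#'   `delta_aic`, in ranked order.
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 1)
  tab <- data.frame(model_id = vapply(fits, `[[`, character(1), "model_id"),
                    k = vapply(fits, `[[`, numeric(1), "k"),
                    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                    aic = vapply(fits, `[[`, numeric(1), "aic"),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$aic, tab$k, tab$model_id), , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  tab
}

#' Parametric bootstrap confidence intervals
#'
#' Simulates `n_boot` data sets from the fitted model (same haploid sample
#' configuration and segregating-site count as the observed data), refits
#' each, and reports percentile confidence intervals per parameter.
#' Replicates whose refit fails are excluded with a warning; more than 20%
#' failures is an error.
#'
#' @param fit fit_result at the MLE.
#' @param sample_sizes haploid sample sizes per population.
#' @param n_sites segregating sites per replicate data set.
#' @param n_boot bootstrap replicates (study setting: 100).
#' @param n_runs,n_genealogies,eval_budget scaled refit settings.
#' @param seed integer seed.
#' @param level confidence level (default 0.95, percentile 2.5/97.5).
#' @return object of class `bootstrap_result`: per-parameter `point`,
#'   `lower`, `upper`, plus the matrix of replicate estimates.
#' @export
parametric_bootstrap <- function(fit, sample_sizes, n_sites, n_boot = 100,
                                 n_runs = 3, n_genealogies = 2000,
                                 eval_budget = 60, seed = 1, level = 0.95) {
  stopifnot(inherits(fit, "fit_result"))
  model <- build_model(fit$scenario, fit$ancestral, fit$estimates)
  est <- matrix(NA_real_, n_boot, length(fit$estimates),
                dimnames = list(NULL, names(fit$estimates)))
  n_loci_hat <- NULL
  for (b in seq_len(n_boot)) {
    bseed <- (seed * 131 + b * 524287) %% .Machine$integer.max
    sim <- simulate_genotypes(model, sample_sizes, n_sites, seed = bseed)
    obs <- haploid_folded_pairs(sim$alleles, sample_sizes)
    n_loci_hat <- n_sites / (model$mu * sim$mean_total_length)
    ft <- try(fit_model(obs, fit$scenario, fit$ancestral, sample_sizes,
                        n_runs = n_runs, n_genealogies = n_genealogies,
                        seed = bseed %% 100000,
                        n_loci = n_loci_hat, eval_budget = eval_budget),
              silent = TRUE)
    if (inherits(ft, "try-error")) next
    est[b, ] <- ft$estimates[colnames(est)]
  }
  ok <- complete.cases(est)
  if (mean(!ok) > 0.2)
    stop("more than 20% of bootstrap refits failed (",
         sum(!ok), "/", n_boot, ")")
  if (any(!ok))
    warning(sum(!ok), " bootstrap refit(s) failed and were excluded")
  est <- est[ok, , drop = FALSE]
  alpha <- (1 - level) / 2
  # inverse-ECDF quantiles: with n_boot = 2 the CI is exactly the range
  ci <- t(apply(est, 2, quantile, probs = c(alpha, 1 - alpha), type = 1))
  out <- data.frame(param = names(fit$estimates),
                    point = unname(fit$estimates),
                    lower = ci[, 1], upper = ci[, 2])
  flag <- out$point < out$lower | out$point > out$upper
  if (any(flag))
    warning("percentile CI excludes the point estimate for: ",
            paste(out$param[flag], collapse = ", "))
  structure(list(table = out, replicates = est, n_boot = n_boot,
                 n_used = sum(ok), seed = seed),
            class = "bootstrap_result")
}

#' Simulate haploid genotypes under a demographic model
#'
#' One independent genealogy per site; a single mutation is placed on a
#' branch chosen proportional to its length, so every site segregates among
#' the sampled lineages (infinite-sites, unlinked SNPs).
#'
#' @inheritParams simulate_coalescent
#' @param n_sites number of segregating sites to draw.
#' @return list with `alleles` (haploid 0/1 matrix, lineages x sites,
#'   ordered Asia, CentralEurope, Iberia) and `mean_total_length`.
#' @export
simulate_genotypes <- function(model, sample_sizes, n_sites, seed = 1) {
  stopifnot(inherits(model, "demographic_model"))
  ev <- model_events(model)
  if (is.null(ev)) stop("parameter values violate the model's event ordering")
  sizes <- unname(model$params[c("N_asia", "N_ce", "N_ib")])
  .coal_genotypes(as.integer(sample_sizes), as.numeric(sizes), ev,
                  as.integer(n_sites), as.numeric(seed))
}

# observed folded pairwise spectra straight from haploid alleles (no
# projection needed: targets equal the sample sizes)
haploid_folded_pairs <- function(alleles, sample_sizes) {
  n1 <- sample_sizes[1]; n2 <- sample_sizes[2]; n3 <- sample_sizes[3]
  idx <- list(asia = seq_len(n1), ce = n1 + seq_len(n2), ib = n1 + n2 + seq_len(n3))
  counts <- function(rows) colSums(alleles[rows, , drop = FALSE])
  ka <- counts(idx$asia); kc <- counts(idx$ce); ki <- counts(idx$ib)
  labs <- c("Asia", "CentralEurope", "Iberia")
  pair <- function(k1, k2, m1, m2, l1, l2) {
    grid <- matrix(0, m1 + 1, m2 + 1)
    for (s in seq_along(k1))
      grid[k1[s] + 1, k2[s] + 1] <- grid[k1[s] + 1, k2[s] + 1] + 1
    finish_folded_sfs(grid, m1, m2, c(l1, l2), n_sites_used = length(k1))
  }
  list(asia_ce = pair(ka, kc, n1, n2, labs[1], labs[2]),
       asia_ib = pair(ka, ki, n1, n3, labs[1], labs[3]),
       ce_ib = pair(kc, ki, n2, n3, labs[2], labs[3]))
}
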