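indep_model <- function() default_truth_model()

test_that("the model registry enumerates six distinct models", {
  reg <- model_registry()
  expect_equal(nrow(reg), 6)
  expect_equal(anyDuplicated(reg$model_id), 0)
  expect_setequal(reg$scenario,
                  c("single_introduction", "independent_origins",
                    "hybrid_geneflow"))
})

test_that("model construction validates parameters and ordering", {
  expect_error(build_model("independent_origins", "asian",
                           c(N_asia = 1000, N_ce = 1000, N_ib = 1000,
                             t_ce = 100)),
               "missing parameter")
  expect_error(build_model("independent_origins", "asian",
                           c(N_asia = -5, N_ce = 1000, N_ib = 1000,
                             t_ce = 100, t_ib = 100)),
               "positive")
  bad <- build_model("single_introduction", "asian",
                     c(N_asia = 1000, N_ce = 1000, N_ib = 1000,
                       t_div = 500, t_intro = 100))
  expect_error(simulate_coalescent(bad, c(4, 4, 4), 10), "ordering")
})

test_that("pairwise coalescence time matches 2N within Monte-Carlo error", {
  mod <- build_model("independent_origins", "asian",
                     c(N_asia = 1500, N_ce = 1000, N_ib = 1000,
                       t_ce = 10, t_ib = 10))
  # two Asian lineages only: E[TMRCA] = 2N, total length = 2 TMRCA
  batches <- vapply(1:20, function(b)
    simulate_coalescent(mod, c(2, 0, 0), 1500, seed = b)$mean_total_length,
    numeric(1))
  se <- sd(batches) / sqrt(length(batches))
  expect_lt(abs(mean(batches) - 2 * 2 * 1500), 3 * se)
})

test_that("total branch length at n = 4 matches the Kingman closed form", {
  mod <- build_model("independent_origins", "asian",
                     c(N_asia = 1000, N_ce = 1000, N_ib = 1000,
                       t_ce = 10, t_ib = 10))
  batches <- vapply(1:20, function(b)
    simulate_coalescent(mod, c(4, 0, 0), 1500, seed = b)$mean_total_length,
    numeric(1))
  se <- sd(batches) / sqrt(length(batches))
  expect_lt(abs(mean(batches) - 2 * 2000 * (1 + 1/2 + 1/3)), 3 * se)
})

test_that("shared polymorphism shrinks as the split deepens", {
  shared <- vapply(c(200, 1000, 5000), function(tau) {
    mod <- build_model("independent_origins", "asian",
                       c(N_asia = 1000, N_ce = 1000, N_ib = 1000,
                         t_ce = tau, t_ib = 2 * tau))
    prof <- simulate_coalescent(mod, c(6, 6, 0), 8000, seed = 5)$profile
    m <- apply(prof, c(1, 2), sum)
    sum(m[2:6, 2:6]) / sum(m) # mass segregating in both populations
  }, numeric(1))
  expect_true(all(diff(shared) < 0))
})

test_that("engine agrees with an independent pure-R coalescent", {
  mod <- build_model("independent_origins", "asian",
                     c(N_asia = 800, N_ce = 600, N_ib = 1000,
                       t_ce = 700, t_ib = 1e7))
  prof <- simulate_coalescent(mod, c(4, 4, 0), 20000, seed = 3)$profile
  cpp <- apply(prof, c(1, 2), sum)
  oracle <- r_coal_profile(4, 4, 800, 600, 700, 4000, seed = 8)
  # compare relative folded masses of segregating cells
  p1 <- cpp / sum(cpp)
  p2 <- oracle / sum(oracle)
  expect_lt(max(abs(p1 - p2)), 0.015)
})

test_that("expected spectra are normalized probability spectra", {
  ex <- expected_sfs(indep_model(), c(8, 8, 8), 2000, seed = 2)
  for (s in ex$pairs) {
    expect_equal(sum(s$grid), 1, tolerance = 1e-12)
    expect_true(all(s$grid[s$mask] == 0))
    expect_true(all(s$grid[!s$mask] > 0)) # epsilon floor
  }
  ex2 <- expected_sfs(indep_model(), c(8, 8, 8), 2000, seed = 2)
  expect_identical(ex$pairs[[1]]$grid, ex2$pairs[[1]]$grid)
})

test_that("hybrid model with a vanishing pulse nests single introduction", {
  base <- c(N_asia = 1000, N_ce = 1000, N_ib = 1000,
            t_div = 500, t_intro = 900)
  single <- build_model("single_introduction", "asian", base)
  hybrid <- build_model("hybrid_geneflow", "asian",
                        c(base, t_pulse = 100, m_pulse = 0.001))
  es <- expected_sfs(single, c(6, 6, 6), 30000, seed = 4)
  eh <- expected_sfs(hybrid, c(6, 6, 6), 30000, seed = 4)
  for (k in 1:3)
    expect_lt(max(abs(es$pairs[[k]]$grid - eh$pairs[[k]]$grid)), 0.02)
})

test_that("composite likelihood obeys the Gibbs inequality", {
  ex <- expected_sfs(indep_model(), c(6, 6, 6), 3000, seed = 9)
  obs <- lapply(ex$pairs, function(s) {
    s$grid <- s$grid * 500 # observed masses proportional to expected
    s
  })
  base <- composite_loglik(obs, ex)
  set.seed(1)
  for (i in 1:100) {
    pert <- ex
    pert$pairs <- lapply(pert$pairs, function(s) {
      g <- s$grid
      g[!s$mask] <- g[!s$mask] * exp(runif(sum(!s$mask), -0.3, 0.3))
      s$grid <- g / sum(g)
      s
    })
    expect_lt(composite_loglik(obs, pert), base)
  }
})

test_that("composite likelihood closed forms hold", {
  ex <- expected_sfs(indep_model(), c(4, 4, 4), 2000, seed = 1)
  # all observed mass on one unmasked cell
  obs <- lapply(ex$pairs, function(s) {
    g <- 0 * s$grid
    cell <- which(!s$mask)[3]
    g[cell] <- 10
    s$grid <- g
    s
  })
  expected_ll <- sum(vapply(seq_along(obs), function(k) {
    cell <- which(!ex$pairs[[k]]$mask)[3]
    10 * log(ex$pairs[[k]]$grid[cell])
  }, numeric(1)))
  expect_equal(composite_loglik(obs, ex), expected_ll, tolerance = 1e-9)

  # uniform expected: S * log(1/c)
  unif <- ex
  unif$pairs <- lapply(unif$pairs, function(s) {
    c0 <- sum(!s$mask)
    s$grid[!s$mask] <- 1 / c0
    s$grid[s$mask] <- 0
    s
  })
  s_tot <- sum(vapply(obs, function(o) sum(o$grid), numeric(1)))
  ll_unif <- sum(vapply(seq_along(obs), function(k)
    sum(obs[[k]]$grid) * log(1 / sum(!obs[[k]]$mask)), numeric(1)))
  expect_equal(composite_loglik(obs, unif), ll_unif, tolerance = 1e-9)

  short <- obs[1:2]
  expect_error(composite_loglik(short, ex))
})

test_that("fitting is deterministic and satisfies the AIC identity", {
  sim <- simulate_genotypes(indep_model(), c(8, 8, 8), 150, seed = 21)
  obs <- speltpop:::haploid_folded_pairs(sim$alleles, c(8, 8, 8))
  n_loci <- 150 / (1.3e-8 * sim$mean_total_length)
  args <- list(obs, "independent_origins", "asian", c(8, 8, 8),
               n_runs = 2, n_genealogies = 400, seed = 5, n_loci = n_loci,
               eval_budget = 40)
  f1 <- do.call(fit_model, args)
  f2 <- do.call(fit_model, args)
  expect_identical(f1$estimates, f2$estimates)
  expect_equal(f1$aic, 2 * f1$k - 2 * f1$loglik, tolerance = 1e-9)
  expect_equal(f1$loglik, max(f1$runs$loglik))
  expect_error(do.call(fit_model, c(args[1:4], list(
    space = default_search_space("single_introduction", "asian")))),
    "does not cover")
})

test_that("the objective profiles smoothly around the true split time", {
  sim <- simulate_genotypes(indep_model(), c(12, 12, 12), 600, seed = 33)
  obs <- speltpop:::haploid_folded_pairs(sim$alleles, c(12, 12, 12))
  n_loci <- 600 / (1.3e-8 * sim$mean_total_length)
  truth <- indep_model()$params
  grid <- exp(seq(log(150), log(8000), length.out = 20))
  prof <- vapply(grid, function(tau) {
    m <- build_model("independent_origins", "asian",
                     replace(truth, "t_ce", tau))
    composite_loglik(obs, expected_sfs(m, c(12, 12, 12), 4000, seed = 6),
                     n_loci = n_loci)
  }, numeric(1))
  best <- grid[which.max(prof)]
  expect_gt(best, truth[["t_ce"]] / 2)
  expect_lt(best, truth[["t_ce"]] * 2)
  # profile falls away from its peak on both flanks
  peak <- which.max(prof)
  expect_gt(prof[peak], prof[1] + 2)
  expect_gt(prof[peak], prof[length(prof)] + 2)
})

test_that("model ranking orders by AIC with parameter-count tie-break", {
  f <- function(id, k, ll) structure(list(model_id = id, k = k, loglik = ll,
                                          aic = 2 * k - 2 * ll),
                                     class = "fit_result")
  rk <- select_model(list(f("big", 6, -100), f("small", 4, -100)))
  expect_identical(rk$model_id[1], "small")
  single <- select_model(list(f("only", 5, -10)))
  expect_equal(nrow(single), 1)
})

test_that("parametric bootstrap: percentile CIs, determinism, n_boot = 2", {
  sim <- simulate_genotypes(indep_model(), c(6, 6, 6), 120, seed = 2)
  obs <- speltpop:::haploid_folded_pairs(sim$alleles, c(6, 6, 6))
  n_loci <- 120 / (1.3e-8 * sim$mean_total_length)
  fit <- fit_model(obs, "independent_origins", "asian", c(6, 6, 6),
                   n_runs = 2, n_genealogies = 300, seed = 3,
                   n_loci = n_loci, eval_budget = 30)
  b1 <- suppressWarnings(parametric_bootstrap(
    fit, c(6, 6, 6), 120, n_boot = 2, n_runs = 1, n_genealogies = 300,
    eval_budget = 25, seed = 9))
  b2 <- suppressWarnings(parametric_bootstrap(
    fit, c(6, 6, 6), 120, n_boot = 2, n_runs = 1, n_genealogies = 300,
    eval_budget = 25, seed = 9))
  expect_identical(b1$table, b2$table)
  # with two replicates the percentile CI degenerates to their range
  expect_equal(b1$table$lower, unname(apply(b1$replicates, 2, min)),
               tolerance = 1e-12)
  expect_equal(b1$table$upper, unname(apply(b1$replicates, 2, max)),
               tolerance = 1e-12)
})
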