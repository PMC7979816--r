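# shared builders for small in-memory fixtures

toy_samples <- function(n, prefix = "S") {
  data.frame(sample_id = paste0(prefix, seq_len(n)),
             subspecies = "spelta", origin = "CentralEurope",
             population = "CentralEurope", stringsAsFactors = FALSE)
}

toy_gm <- function(geno, chrom = NULL, pos = NULL) {
  geno <- as.matrix(geno)
  ns <- ncol(geno)
  if (is.null(chrom)) chrom <- rep("1B", ns)
  if (is.null(pos)) pos <- seq_len(ns) * 1000L
  genotype_matrix(geno, toy_samples(nrow(geno)),
                  data.frame(chrom = chrom, pos = pos,
                             ref = rep("A", ns), alt = rep("G", ns),
                             stringsAsFactors = FALSE))
}

# small three-population cohort reused across structure/gwas tests
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(cohort_spec(
        n_diploid = c(asia = 10, ce = 10, ib = 10),
        n_sites = 400, missing_rate = 0.1, seed = 2024))
    cache
  }
})

# exhaustive projection oracle: distribution of derived counts in all
# subsamples of size m from n alleles with k derived
project_enum <- function(k, n, m) {
  alleles <- c(rep(1, k), rep(0, n - k))
  subs <- combn(n, m)
  counts <- colSums(matrix(alleles[subs], nrow = m))
  tabulate(counts + 1, nbins = m + 1) / ncol(subs)
}

# independent pure-R Kingman coalescent for a two-population split model
# (pop2 merges into pop1 at t_split); expected joint branch profile
r_coal_profile <- function(n1, n2, N1, N2, t_split, n_genealogies, seed) {
  set.seed(seed)
  prof <- matrix(0, n1 + 1, n2 + 1)
  for (g in seq_len(n_genealogies)) {
    pop <- rep(1:2, c(n1, n2))
    desc <- lapply(seq_along(pop), function(i)
      c(as.integer(i <= n1), as.integer(i > n1)))
    t <- 0
    merged <- FALSE
    while (length(pop) > 1) {
      k1 <- sum(pop == 1); k2 <- sum(pop == 2)
      rate <- k1 * (k1 - 1) / (4 * N1) + k2 * (k2 - 1) / (4 * N2)
      w <- if (rate > 0) rexp(1, rate) else Inf
      if (!merged && t + w >= t_split) {
        dt <- t_split - t
        for (i in seq_along(pop)) {
          d <- desc[[i]]
          prof[d[1] + 1, d[2] + 1] <- prof[d[1] + 1, d[2] + 1] + dt
        }
        t <- t_split
        pop[pop == 2] <- 1
        merged <- TRUE
        next
      }
      for (i in seq_along(pop)) {
        d <- desc[[i]]
        prof[d[1] + 1, d[2] + 1] <- prof[d[1] + 1, d[2] + 1] + w
      }
      t <- t + w
      p <- if (runif(1) < (k1 * (k1 - 1) / (4 * N1)) / rate) 1 else 2
      idx <- which(pop == p)
      pair <- sample(idx, 2)
      desc[[pair[1]]] <- desc[[pair[1]]] + desc[[pair[2]]]
      pop <- pop[-pair[2]]
      desc <- desc[-pair[2]]
    }
    prof[1, 1] <- prof[1, 1] # no-op, keeps structure explicit
  }
  prof / n_genealogies
}

# brute-force least-squares topology search for additive distances:
# enumerate all unrooted topologies by sequential leaf insertion, fit
# branch lengths by least squares on path distances, return the
# minimum-RSS tree (ape::phylo); on an additive matrix the generating
# topology is the unique zero-RSS fit
bruteforce_nj_oracle <- function(D) {
  n <- nrow(D)
  labels <- rownames(D)
  best <- NULL
  enumerate_trees(n, function(edges) {
    fit <- fit_branch_lengths(edges, n, D)
    if (is.null(best) || fit$rss < best$rss - 1e-9)
      best <<- list(edges = edges, len = fit$len, rss = fit$rss)
  })
  edges_to_phylo(best$edges, best$len, labels)
}

# unrooted binary trees via leaf insertion: start with the 3-leaf star,
# insert leaf i on each existing edge
enumerate_trees <- function(n, callback) {
  recurse <- function(edges, next_leaf, next_internal) {
    if (next_leaf > n) {
      callback(edges)
      return(invisible(NULL))
    }
    for (e in seq_len(nrow(edges))) {
      v <- next_internal
      new_edges <- rbind(edges[-e, , drop = FALSE],
                         c(edges[e, 1], v), c(v, edges[e, 2]),
                         c(v, next_leaf))
      recurse(new_edges, next_leaf + 1L, next_internal + 1L)
    }
  }
  # leaves 1..n; internal nodes numbered from n+1
  root <- as.integer(n + 1)
  edges0 <- cbind(rep(root, 3), 1:3)
  recurse(edges0, 4L, as.integer(n + 2))
}

fit_branch_lengths <- function(edges, n, D) {
  m <- nrow(edges)
  pairs <- combn(n, 2)
  A <- matrix(0, ncol(pairs), m)
  for (pi in seq_len(ncol(pairs))) {
    path <- tree_path(edges, pairs[1, pi], pairs[2, pi])
    A[pi, path] <- 1
  }
  d <- D[t(pairs)]
  len <- tryCatch(qr.solve(A, d), error = function(e) {
    qr.coef(qr(A), d)
  })
  len[is.na(len)] <- 0
  rss <- sum((A %*% len - d)^2)
  list(len = len, rss = rss)
}

tree_path <- function(edges, from, to) {
  # BFS over the edge list, returning edge indices along the path
  nbr <- list()
  for (e in seq_len(nrow(edges))) {
    a <- as.character(edges[e, 1]); b <- as.character(edges[e, 2])
    nbr[[a]] <- rbind(nbr[[a]], c(edges[e, 2], e))
    nbr[[b]] <- rbind(nbr[[b]], c(edges[e, 1], e))
  }
  prev <- list()
  visited <- as.character(from)
  queue <- list(list(node = from, path = integer(0)))
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    if (cur$node == to) return(cur$path)
    for (r in seq_len(nrow(nbr[[as.character(cur$node)]]))) {
      nxt <- nbr[[as.character(cur$node)]][r, 1]
      if (as.character(nxt) %in% visited) next
      visited <- c(visited, as.character(nxt))
      queue <- c(queue, list(list(node = nxt,
                                  path = c(cur$path,
                                           nbr[[as.character(cur$node)]][r, 2]))))
    }
  }
  stop("disconnected tree")
}

edges_to_phylo <- function(edges, len, labels) {
  n <- length(labels)
  nodes <- sort(unique(as.vector(edges)))
  internal <- nodes[nodes > n]
  remap <- c(seq_len(n), seq_along(internal) + n)
  names(remap) <- c(as.character(seq_len(n)), as.character(internal))
  ed <- cbind(remap[as.character(edges[, 1])], remap[as.character(edges[, 2])])
  # ape wants edges oriented parent -> child from a root; re-root at the
  # first internal node via DFS
  root <- n + 1L
  oriented <- matrix(0L, nrow(ed), 2)
  olen <- numeric(nrow(ed))
  k <- 0L
  visited <- rep(FALSE, max(remap))
  stack <- root
  visited[root] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (e in seq_len(nrow(ed))) {
      other <- if (ed[e, 1] == v && !visited[ed[e, 2]]) ed[e, 2]
               else if (ed[e, 2] == v && !visited[ed[e, 1]]) ed[e, 1]
               else next
      k <- k + 1L
      oriented[k, ] <- c(v, other)
      olen[k] <- len[e]
      visited[other] <- TRUE
      stack <- c(stack, other)
    }
  }
  structure(list(edge = oriented, edge.length = olen,
                 Nnode = length(internal), tip.label = labels),
            class = "phylo")
}

# additive distances from a random binary tree with positive branch lengths
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.5, 3))
  tr$tip.label <- paste0("t", seq_len(n))
  D <- cophenetic(tr)
  D <- D[tr$tip.label, tr$tip.label]
  list(tree = tr, D = D)
}
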