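# Independent brute-force oracles used to validate the HMM, the sampler and
# the metrics. Everything here enumerates explicitly and avoids the package's
# rank-1 / scaled recursions.

# Full pair-state enumeration oracle. States are ordered pairs coded
# s = (k - 1) * K + j. Returns the marginal likelihood and per-marker
# posteriors over states, computed by summing over every one of the
# (K^2)^M state paths.
oracle_pair_hmm <- function(alleles, g, theta, e) {
  K <- nrow(alleles); M <- ncol(alleles)
  S <- K * K
  Tm <- function(th) outer(seq_len(K), seq_len(K),
                           function(a, b) (1 - th) * (a == b) + th / K)
  em <- function(m) {
    v <- numeric(S)
    for (k in seq_len(K)) for (j in seq_len(K))
      v[(k - 1) * K + j] <- emission_prob(g[m], alleles[j, m], alleles[k, m], e)
    v
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), M)))
  pr <- em(1)[paths[, 1]] / S
  for (m in seq_len(M)[-1]) {
    Tp <- kronecker(Tm(theta[m - 1]), Tm(theta[m - 1]))
    pr <- pr * Tp[cbind(paths[, m - 1], paths[, m])] * em(m)[paths[, m]]
  }
  lik <- sum(pr)
  post <- array(0, dim = c(K, K, M))
  for (m in seq_len(M)) {
    tp <- tapply(pr, paths[, m], sum)
    full <- numeric(S)
    full[as.integer(names(tp))] <- tp
    post[, , m] <- matrix(full / lik, K, K)
  }
  list(likelihood = lik, posteriors = post, path_probs = pr, paths = paths)
}

# Haploid enumeration oracle: posterior P(allele 1) per marker by summing
# over all K^M template paths.
oracle_haploid <- function(hap, panel, theta, e) {
  K <- nrow(panel); M <- ncol(panel)
  emit <- function(m, j) {
    if (is.na(hap[m])) 1 else if (panel[j, m] == hap[m]) 1 - e else e
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), M)))
  pr <- rep(1 / K, nrow(paths))
  for (m in seq_len(M)) {
    for (j in seq_len(K)) {
      sel <- paths[, m] == j
      pr[sel] <- pr[sel] * emit(m, j)
    }
    if (m > 1) {
      th <- theta[m - 1]
      stay <- paths[, m] == paths[, m - 1]
      pr <- pr * ifelse(stay, (1 - th) + th / K, th / K)
    }
  }
  lik <- sum(pr)
  sapply(seq_len(M), function(m) {
    p1 <- 0
    for (j in seq_len(K)) {
      pj <- sum(pr[paths[, m] == j]) / lik
      p1 <- p1 + pj * (if (panel[j, m] == 1) 1 - e else e)
    }
    p1
  })
}

# Direct re-implementation of switch-error counting from its definition.
oracle_switch_errors <- function(true_pair, inferred_pair) {
  M <- ncol(true_pair)
  n <- 0L
  prev <- NA
  for (m in seq_len(M)) {
    td <- true_pair[1, m] + true_pair[2, m]
    id <- inferred_pair[1, m] + inferred_pair[2, m]
    if (is.na(td) || td != 1 || is.na(id) || id != 1) next
    agree <- inferred_pair[1, m] == true_pair[1, m]
    if (!is.na(prev) && agree != prev) n <- n + 1L
    prev <- agree
  }
  n
}

# O(M^2) maximal-run scan for sharing runs.
oracle_sharing_runs <- function(gA, gB, kind, missing_matches = TRUE) {
  M <- length(gA)
  cond <- function(m) {
    if (is.na(gA[m]) || is.na(gB[m])) return(missing_matches)
    if (kind == "double") gA[m] == gB[m] else abs(gA[m] - gB[m]) <= 1
  }
  runs <- list()
  m <- 1L
  while (m <= M) {
    if (cond(m) && (m == 1L || !cond(m - 1L))) {
      end <- m
      while (end < M && cond(end + 1L)) end <- end + 1L
      runs[[length(runs) + 1L]] <- c(start = m - 1L, end = end)
      m <- end + 1L
    } else m <- m + 1L
  }
  if (!length(runs)) return(data.frame(start = integer(0), end = integer(0)))
  do.call(rbind.data.frame, lapply(runs, as.list))
}

# Exhaustive per-marker best-match recomputation.
oracle_best_match <- function(d, kind, missing_matches = TRUE) {
  N <- nrow(d); M <- ncol(d)
  best <- matrix(0L, N, M)
  for (a in seq_len(N)) for (b in seq_len(N)) {
    if (a == b) next
    runs <- oracle_sharing_runs(d[a, ], d[b, ], kind, missing_matches)
    if (!nrow(runs)) next
    for (m in seq_len(M)) {
      for (r in seq_len(nrow(runs))) {
        if (m > runs$start[r] && m <= runs$end[r]) {
          len <- runs$end[r] - runs$start[r]
          if (len > best[a, m]) best[a, m] <- len
        }
      }
    }
  }
  best
}

# Random small HMM instance (pool alleles, genotypes with occasional missing).
random_hmm_instance <- function(K, M, p_missing = 0.15) {
  al <- matrix(rbinom(K * M, 1, 0.5), K, M)
  g <- rbinom(M, 2, 0.5)
  g[runif(M) < p_missing] <- NA
  list(alleles = al, g = as.integer(g))
}

view_of <- function(alleles, mate = rep(NA_integer_, nrow(alleles))) {
  list(alleles = alleles, mate = as.integer(mate),
       rows = seq_len(nrow(alleles)))
}

# Shared fixture for the twins / sibling / parents mode-comparison studies:
# one phasing run per (scenario, seed, mode), switch errors of the original
# parents scored on typed markers. Cached per session because three
# acceptance checks and the error-map check consume the same runs.
mode_study <- local({
  cache <- list()
  function(scenario, seeds = 1:10, n_parents = 16L, n_markers = 300L,
           n_iterations = 30L, with_imputation = FALSE) {
    key <- paste(scenario, n_parents, n_markers, n_iterations,
                 paste(seeds, collapse = ","), with_imputation, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    out <- lapply(seeds, function(seed) {
      spec <- scenario_spec(scenario, n_parents = n_parents,
                            n_markers = n_markers, seed = seed)
      ts <- mask_every_second(build_scenario(spec))
      runs <- lapply(c(original = "original", mirror = "mirror"), function(md) {
        cfg <- phasing_config(n_iterations = n_iterations, mode = md,
                              seed = seed * 100L)
        res <- suppressWarnings(run_phasing(ts$genotypes, config = cfg))
        reps <- cohort_switch_errors(ts, res)
        imp_err <- NA_integer_
        if (with_imputation) {
          pp <- hmm_params(theta = res$params_final$theta,
                           error_rate = res$params_final$error_rate)
          imp <- impute_dataset(res, ts$reference, ts$genotypes$mask,
                                params = pp)
          td <- ts$genotypes$truth[seq_len(n_parents), ts$genotypes$mask,
                                   drop = FALSE]
          imp_err <- sum(pmin(abs(td - imp$best_guess[seq_len(n_parents), ,
                                                      drop = FALSE]), 2L))
        }
        list(total_switches = sum(vapply(reps, `[[`, 0L, "n_switches")),
             reports = reps, imputation_errors = imp_err)
      })
      runs
    })
    cache[[key]] <<- out
    out
  }
})
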