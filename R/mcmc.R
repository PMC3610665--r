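#' Phasing configuration
#'
#' @param n_iterations number of MCMC sweeps over the cohort (default 60;
#'   gains beyond a modest count are small, 60 covers near-asymptotic
#'   behaviour at desk scale).
#' @param mode sampling rule: `"original"` backward sampling or `"mirror"`
#'   mirror-subtraction sampling.
#' @param seed integer RNG seed; every source of randomness in a run flows
#'   from it.
#' @param theta_init initial per-interval template-switch probability.
#' @param e_init initial per-allele miscopy rate.
#' @param update_params re-estimate `theta` and `e` after each iteration from
#'   the iteration's sampled paths?
#' @param output_rule `"final_sample"` (score the last sampled haplotypes, the
#'   conventional choice) or `"consensus"` (majority vote over a ring of
#'   recent samples).
#' @param epsilon_rel relative mirror floor.
#' @param ring_size number of recent samples kept per individual when
#'   `output_rule = "consensus"`.
#' @return A `phasing_config` list.
#' @export
phasing_config <- function(n_iterations = 60L, mode = c("original", "mirror"),
                           seed = 1L, theta_init = 0.01, e_init = 0.005,
                           update_params = TRUE,
                           output_rule = c("final_sample", "consensus"),
                           epsilon_rel = 1e-10, ring_size = 5L) {
  mode <- match.arg(mode)
  output_rule <- match.arg(output_rule)
  stopifnot(n_iterations >= 1, theta_init >= 0, theta_init < 1,
            e_init >= 0, e_init < 0.5, epsilon_rel > 0, ring_size >= 1)
  structure(list(n_iterations = as.integer(n_iterations), mode = mode,
                 seed = as.integer(seed), theta_init = theta_init,
                 e_init = e_init, update_params = isTRUE(update_params),
                 output_rule = output_rule, epsilon_rel = epsilon_rel,
                 ring_size = as.integer(ring_size)),
            class = "phasing_config")
}

#' Random haplotype initialization
#'
#' Builds the initial study haplotype pool from unphased genotypes:
#' homozygous sites are set to the genotype allele on both haplotypes,
#' heterozygous sites are oriented by a fair coin, and missing sites are
#' drawn from the marker's allele frequency among non-missing dosages
#' (0.5 when a marker is entirely missing). Owner and mate maps pair the
#' rows `2i - 1, 2i` per individual.
#'
#' @param genotypes a [genotype_matrix()] with at least 2 individuals.
#' @return A [haplotype_pool()] of `2N` study haplotypes.
#' @export
initialize_haplotypes <- function(genotypes) {
  d <- genotypes$dosage
  N <- nrow(d); M <- ncol(d)
  if (N < 2) stop("phasing needs at least 2 study individuals")
  freq <- colMeans(d, na.rm = TRUE) / 2
  freq[is.nan(freq)] <- 0.5
  alleles <- matrix(0L, 2L * N, M)
  for (i in seq_len(N)) {
    g <- d[i, ]
    h1 <- ifelse(is.na(g), NA_integer_, g %/% 2L)  # hom: g/2; het: 0 placeholder
    h2 <- h1
    het <- !is.na(g) & g == 1L
    if (any(het)) {
      coin <- runif(sum(het)) < 0.5
      h1[het] <- as.integer(coin)
      h2[het] <- 1L - h1[het]
    }
    mis <- is.na(g)
    if (any(mis)) {
      h1[mis] <- as.integer(runif(sum(mis)) < freq[mis])
      h2[mis] <- as.integer(runif(sum(mis)) < freq[mis])
    }
    alleles[2L * i - 1L, ] <- h1
    alleles[2L * i, ] <- h2
  }
  haplotype_pool(alleles)
}

#' Re-estimate per-interval switch probabilities
#'
#' Posterior-mean style update with Jeffreys-like pseudocounts:
#' `theta_m = (c_m + 0.5) / (n_transits + 1)` clamped to
#' `[1e-6, 0.5]`, where `c_m` is the number of sampled template changes in
#' interval `m` summed over chromatids and individuals, and `n_transits` is
#' twice the number of individuals updated this iteration.
#'
#' @param switch_counts integer vector of per-interval template changes.
#' @param n_transits integer, `2 x` individuals updated.
#' @param bounds length-2 clamp, default `c(1e-6, 0.5)`.
#' @return Updated theta vector.
#' @export
update_theta <- function(switch_counts, n_transits, bounds = c(1e-6, 0.5)) {
  th <- (switch_counts + 0.5) / (n_transits + 1)
  pmin(pmax(th, bounds[1]), bounds[2])
}

#' Re-estimate the per-allele miscopy rate
#'
#' `e = (mismatch_total + 0.5) / (comparisons_total + 1)` clamped to
#' `[1e-4, 0.05]`; comparisons are per-allele template-vs-output comparisons
#' at non-missing sites.
#'
#' @param mismatch_total total template/genotype conflicts this iteration.
#' @param comparisons_total total per-allele comparisons.
#' @param bounds length-2 clamp, default `c(1e-4, 0.05)`.
#' @return Updated error rate (scalar).
#' @export
update_error_rate <- function(mismatch_total, comparisons_total,
                              bounds = c(1e-4, 0.05)) {
  e <- (mismatch_total + 0.5) / (comparisons_total + 1)
  min(max(e, bounds[1]), bounds[2])
}

#' Run MCMC phasing
#'
#' The iterative driver: haplotypes are initialized randomly, then in each
#' iteration every study individual is revisited in a fresh random
#' permutation; its haplotypes are resampled from the pair HMM conditioned
#' on all other current haplotypes (self-excluded) plus any reference
#' haplotypes, using the configured sampling rule. After each iteration the
#' switch and error parameters are optionally re-estimated from the sampled
#' paths.
#'
#' @param genotypes a [genotype_matrix()] (masked markers stored as missing).
#' @param reference optional [haplotype_pool()] of pre-phased haplotypes,
#'   aligned to the same markers; treated as fixed templates.
#' @param config a [phasing_config()].
#' @return A `phasing_result`: `haplotypes` (study [haplotype_pool()]),
#'   `params_final`, `trace` (per-iteration data frame of switch totals,
#'   mismatch totals and parameter estimates), `config`, and `samples_kept`
#'   when the consensus rule is active.
#' @param .sever_mates internal: drop all mate links from the conditioning
#'   pool, making mirror mode degenerate to original mode (used to verify
#'   that equivalence).
#' @export
run_phasing <- function(genotypes, reference = NULL, config = phasing_config(),
                        .sever_mates = FALSE) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "phasing_config"))
  N <- nrow(genotypes$dosage); M <- ncol(genotypes$dosage)
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "haplotype_pool"))
    if (ncol(reference$alleles) != M)
      stop("reference panel markers do not align with the study genotypes")
  }
  set.seed(config$seed)
  study <- initialize_haplotypes(genotypes)

  if (!is.null(reference)) {
    Hs <- nrow(study$alleles)
    pool <- haplotype_pool(
      rbind(study$alleles, reference$alleles),
      owner = c(study$owner, max(study$owner) + reference$owner),
      mate = c(study$mate, Hs + reference$mate),
      fixed = c(rep(FALSE, Hs), rep(TRUE, nrow(reference$alleles))))
  } else pool <- study

  params <- hmm_params(theta = rep(config$theta_init, M - 1),
                       error_rate = config$e_init,
                       epsilon_rel = config$epsilon_rel)
  trace <- data.frame(iteration = integer(0), switches = integer(0),
                      mismatches = integer(0), error_rate = numeric(0),
                      theta_mean = numeric(0))
  ring <- if (config$output_rule == "consensus")
    lapply(seq_len(N), function(i) list()) else NULL

  for (it in seq_len(config$n_iterations)) {
    perm <- sample.int(N)
    c_m <- integer(M - 1)
    mis_tot <- 0L; cmp_tot <- 0L; sw_tot <- 0L
    for (i in perm) {
      v <- pool_view(pool, i)
      if (.sever_mates) v$mate[] <- NA_integer_
      g <- genotypes$dosage[i, ]
      fwd <- forward(g, v, params)
      path <- backward_sample(fwd, params, mode = config$mode)
      smp <- haplotypes_from_path(path, v, g)
      pool$alleles[2L * i - 1L, ] <- smp$hap1
      pool$alleles[2L * i, ] <- smp$hap2
      c_m <- c_m + smp$switch_count_per_interval
      sw_tot <- sw_tot + sum(smp$switch_count_per_interval)
      mis_tot <- mis_tot + smp$mismatch_count
      cmp_tot <- cmp_tot + 2L * sum(!is.na(g))
      if (!is.null(ring)) {
        ring[[i]] <- c(ring[[i]], list(rbind(smp$hap1, smp$hap2)))
        if (length(ring[[i]]) > config$ring_size)
          ring[[i]] <- ring[[i]][-1]
      }
    }
    stopifnot(pool_consistent(pool, genotypes))
    if (config$update_params) {
      params$theta <- update_theta(c_m, 2L * N)
      params$error_rate <- update_error_rate(mis_tot, cmp_tot)
      if (any(params$theta >= 0.5))
        warning("theta hit its ceiling in ", sum(params$theta >= 0.5),
                " interval(s) at iteration ", it)
    }
    trace <- rbind(trace, data.frame(
      iteration = it, switches = sw_tot, mismatches = mis_tot,
      error_rate = params$error_rate, theta_mean = mean(params$theta)))
  }

  haps <- haplotype_pool(pool$alleles[seq_len(2L * N), , drop = FALSE])
  if (config$output_rule == "consensus") {
    for (i in seq_len(N)) {
      cons <- consensus_haplotypes(ring[[i]])
      haps$alleles[2L * i - 1L, ] <- cons[1, ]
      haps$alleles[2L * i, ] <- cons[2, ]
    }
  }
  structure(list(haplotypes = haps, params_final = params, trace = trace,
                 config = config, samples_kept = ring),
            class = "phasing_result")
}

# hard consistency check: every stored study pair reproduces its genotype
pool_consistent <- function(pool, genotypes) {
  N <- nrow(genotypes$dosage)
  s <- pool$alleles[seq(1, 2 * N, by = 2), , drop = FALSE] +
       pool$alleles[seq(2, 2 * N, by = 2), , drop = FALSE]
  all(s == genotypes$dosage | is.na(genotypes$dosage))
}

#' @export
print.phasing_result <- function(x, ...) {
  n <- max(x$haplotypes$owner)
  cat(sprintf("<phasing_result> %d individuals, %d markers, %d iterations (%s mode)\n",
              n, ncol(x$haplotypes$alleles), nrow(x$trace), x$config$mode))
  cat(sprintf("  final e = %.4g, mean theta = %.4g\n",
              x$params_final$error_rate, mean(x$params_final$theta)))
  invisible(x)
}

#' Consensus haplotypes from a ring of kept samples
#'
#' Aligns every kept sample to the first by the wholesale orientation (pair
#' swap) that minimizes heterozygous-site disagreement, then takes a
#' per-site majority vote over orientations; ties fall back to the first
#' sample. Homozygous and missing sites are taken from the first sample
#' (all samples agree there by genotype consistency).
#'
#' @param samples non-empty list of 2 x M haplotype matrices for one
#'   individual.
#' @return A 2 x M consensus haplotype matrix.
#' @export
consensus_haplotypes <- function(samples) {
  if (!length(samples)) stop("empty sample ring")
  first <- samples[[1]]
  if (length(samples) == 1L) return(first)
  M <- ncol(first)
  het <- first[1, ] != first[2, ]
  if (!any(het)) return(first)
  # orientation bit per het site: does hap1 carry allele 1?
  o1 <- first[1, het]
  votes <- rep(0L, sum(het))       # votes for orientation "same as first"
  for (s in samples) {
    os <- s[1, het]
    agree <- sum(os == o1)
    if (2 * agree < sum(het)) os <- 1L - os   # swap-align to first
    votes <- votes + as.integer(os == o1)
  }
  same <- votes * 2L >= length(samples)       # tie -> first sample's orientation
  out <- first
  h1 <- ifelse(same, o1, 1L - o1)
  out[1, het] <- h1
  out[2, het] <- 1L - h1
  out
}
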