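#' Genotype emission probability
#'
#' Probability of observing dosage `g` given an ordered pair of template
#' alleles, under the per-allele miscopy model: each observed allele copies
#' its template correctly with probability `1 - e` and flips with probability
#' `e`. Missing genotypes are uninformative (probability 1).
#'
#' @param g observed dosage in \{0, 1, 2\} or `NA`.
#' @param a_j,a_k template alleles in \{0, 1\}.
#' @param e per-allele miscopy probability in \[0, 0.5).
#' @return The emission probability.
#' @export
emission_prob <- function(g, a_j, a_k, e) {
  if (!a_j %in% c(0, 1) || !a_k %in% c(0, 1)) stop("template alleles must be 0/1")
  stopifnot(e >= 0, e < 0.5)
  if (is.na(g)) return(1.0)
  if (!g %in% c(0, 1, 2)) stop("invalid dosage value: ", g)
  q <- function(x, a) if (x == a) 1 - e else e
  if (g == 0) return(q(0, a_j) * q(0, a_k))
  if (g == 2) return(q(1, a_j) * q(1, a_k))
  q(0, a_j) * q(1, a_k) + q(1, a_j) * q(0, a_k)
}

#' Template-switch transition probability
#'
#' One chromatid of the Li & Stephens jump process: with probability
#' `1 - theta_m` the copy continues from the same template, with probability
#' `theta_m` it jumps to a template drawn uniformly from the pool (possibly
#' the same one). The pair transition is the product of the two chromatid
#' factors.
#'
#' @param j,j2 template indices (1-based).
#' @param theta_m per-interval switch probability in \[0, 1).
#' @param K pool size.
#' @return The transition probability from `j` to `j2`.
#' @export
transition_prob <- function(j, j2, theta_m, K) {
  stopifnot(K >= 1, theta_m >= 0, theta_m < 1)
  (1 - theta_m) * (j == j2) + theta_m / K
}

# Pool view for study individual i: drop i's own two haplotypes (self-exclusion),
# keep everything else including fixed references. Returns alleles (K x M),
# the remapped mate vector, and row indices into the full pool.
pool_view <- function(pool, individual) {
  own <- which(pool$owner == individual & !pool$fixed)
  keep <- setdiff(seq_len(nrow(pool$alleles)), own)
  if (length(keep) < 2) stop("conditioning pool must contain at least 2 haplotypes")
  remap <- match(pool$mate[keep], keep)  # NA where the mate was dropped/undefined
  list(alleles = pool$alleles[keep, , drop = FALSE],
       mate = as.integer(remap), rows = keep)
}

#' Scaled forward pass of the haplotype-pair HMM
#'
#' Computes per-marker scaled forward probabilities over ordered template
#' pairs `(j, k)` for one study individual, conditioned on a pool of
#' candidate templates. Each marker slice is renormalized to sum 1; the
#' product of the per-marker scale factors equals the marginal likelihood of
#' the genotype vector. The transition sums exploit the rank-1 structure of
#' the jump process, giving O(K^2) work per marker.
#'
#' @param genotypes_i length-M dosage vector (`NA` = missing).
#' @param pool either a [haplotype_pool()] (used in full) or a pool view as
#'   produced internally for one individual.
#' @param params an [hmm_params()].
#' @return A `forward_matrix`: list with `F` (K x K x M array), `scale`
#'   (length-M), and the pool view used.
#' @export
forward <- function(genotypes_i, pool, params) {
  v <- as_view(pool)
  K <- nrow(v$alleles); M <- ncol(v$alleles)
  if (K < 2) stop("conditioning pool must contain at least 2 haplotypes")
  if (M < 2) stop("the HMM needs at least 2 markers")
  g <- as.integer(genotypes_i)
  th <- expand_theta(params, M)
  res <- cpp_forward(v$alleles, g, th, params$error_rate)
  structure(list(F = res$F, scale = res$scale, K = K, M = M,
                 view = v, genotypes = g, theta = th,
                 error_rate = params$error_rate),
            class = "forward_matrix")
}

# accept either a full pool or a prebuilt view
as_view <- function(pool) {
  if (inherits(pool, "haplotype_pool"))
    list(alleles = pool$alleles, mate = pool$mate,
         rows = seq_len(nrow(pool$alleles)))
  else pool
}

#' Marginal likelihood from a forward matrix
#' @param fwd a `forward_matrix` from [forward()].
#' @param log return the log-likelihood?
#' @return The data likelihood (product of scale factors).
#' @export
forward_likelihood <- function(fwd, log = FALSE) {
  ll <- sum(base::log(fwd$scale))
  if (log) ll else exp(ll)
}

#' Forward-backward pair posteriors
#'
#' Per-marker posterior distributions over ordered template pairs given the
#' whole genotype vector; each marker slice sums to 1. Used as the exact
#' reference for validating the backward sampler and as the basis of the
#' haploid imputation posteriors.
#'
#' @param fwd a `forward_matrix` from [forward()] on the same inputs.
#' @return A K x K x M array of posteriors.
#' @export
forward_backward_posteriors <- function(fwd) {
  stopifnot(inherits(fwd, "forward_matrix"))
  cpp_forward_backward(fwd$F, fwd$view$alleles, fwd$genotypes, fwd$theta,
                       fwd$error_rate)
}
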