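#' Mirror-subtraction weight adjustment
#'
#' The sampling-rule remedy for chain lock-in under double genotype sharing:
#' for each ordered template pair `(j, k)` whose members both have a defined
#' mate (the other haplotype of the same individual), the unadjusted weight
#' of the mirror pair `(mate(j), mate(k))` is subtracted, and the result is
#' floored at `epsilon_rel` times the total unadjusted weight. A pair that
#' carries no more mass than its mirror is phase-uninformative — any
#' orientation of the contributing individuals would match the genotypes —
#' so its weight is driven to the floor rather than allowed to dominate.
#' Pairs with an undefined mate are left unchanged. The output is
#' renormalized to sum 1.
#'
#' @param weights non-negative K x K matrix of sampling weights over ordered
#'   pairs (not all zero).
#' @param mate integer mate map of the pool (1-based, `NA` where undefined).
#' @param epsilon_rel relative floor (> 0).
#' @return The adjusted, renormalized K x K weight matrix.
#' @export
mirror_adjust <- function(weights, mate, epsilon_rel) {
  stopifnot(epsilon_rel > 0)
  cpp_mirror_adjust(as.matrix(weights), as.integer(mate), epsilon_rel)
}

#' Backward sampling of a template-pair path
#'
#' Samples a state path from the posterior implied by a forward matrix,
#' starting at the last marker and walking backwards; at each interior
#' marker the weights are the forward values times the two chromatid
#' transition factors towards the previously sampled state. In `"mirror"`
#' mode, [mirror_adjust()] is applied to the weight vector at every marker
#' before sampling. Consumes exactly M uniforms from R's RNG.
#'
#' @param fwd a `forward_matrix` from [forward()].
#' @param params an [hmm_params()] (supplies `epsilon_rel`).
#' @param mode `"original"` or `"mirror"`.
#' @param mirror_on where the subtraction acts in mirror mode: `"forward"`
#'   (default) adjusts the forward slice before the transition factors are
#'   applied, so a copy pair — whose forward mass always equals its mirror's
#'   by symmetry — is floored at every marker and the chain cannot settle in
#'   the copy-pair feedback loop, not even by sliding in through a half-copy
#'   state; `"conditional"` adjusts the conditional weight vector after the
#'   transition factors (kept for comparison; it fails to suppress re-entry
#'   into a copy pair from an adjacent half-copy state).
#' @return A `state_path`: M x 2 integer matrix of ordered pool indices
#'   (columns `j`, `k`), indices into the conditioning pool view.
#' @export
backward_sample <- function(fwd, params, mode = c("original", "mirror"),
                            mirror_on = c("forward", "conditional")) {
  mode <- match.arg(mode)
  mirror_on <- match.arg(mirror_on)
  stopifnot(inherits(fwd, "forward_matrix"))
  out <- cpp_backward_sample(fwd$F, fwd$K, fwd$M, fwd$theta, fwd$view$mate,
                             if (mode == "mirror") 1L else 0L,
                             params$epsilon_rel, 1L,
                             mirror_on == "forward")
  path <- cbind(j = out[1, seq_len(fwd$M)], k = out[1, fwd$M + seq_len(fwd$M)])
  class(path) <- c("state_path", class(path))
  path
}

#' Convert a sampled state path into a haplotype pair
#'
#' Reads the template alleles along the path and reconciles them with the
#' observed genotype: homozygous sites take the genotype's allele on both
#' haplotypes; heterozygous sites with discordant template alleles copy the
#' template orientation; heterozygous sites where both templates carry the
#' same allele are template mismatches — orientation is decided by a fair
#' coin (one RNG draw per such site, in marker order) and the mismatch is
#' counted. Missing sites copy the templates unchanged. Template changes of
#' each chromatid are tallied per interval.
#'
#' @param path a `state_path` from [backward_sample()].
#' @param pool the pool (or pool view) the path indexes into.
#' @param genotypes_i length-M dosage vector.
#' @return A `sampled_haplotypes` list: `hap1`, `hap2` (length-M 0/1),
#'   `mismatch_count` (template alleles conflicting with the genotype),
#'   `switch_count_per_interval` (length M-1, chromatid-summed).
#' @export
haplotypes_from_path <- function(path, pool, genotypes_i) {
  v <- as_view(pool)
  M <- ncol(v$alleles)
  stopifnot(nrow(path) == M)
  g <- as.integer(genotypes_i)
  aj <- v$alleles[cbind(path[, 1], seq_len(M))]
  ak <- v$alleles[cbind(path[, 2], seq_len(M))]
  hap1 <- aj; hap2 <- ak
  mismatch <- 0L

  hom <- !is.na(g) & g != 1L
  if (any(hom)) {
    a <- g[hom] %/% 2L
    mismatch <- mismatch + sum(aj[hom] != a) + sum(ak[hom] != a)
    hap1[hom] <- a; hap2[hom] <- a
  }
  het <- !is.na(g) & g == 1L
  amb <- het & aj == ak      # template mismatch: one allele must be flipped
  if (any(amb)) {
    mismatch <- mismatch + sum(amb)
    flip <- runif(sum(amb)) < 0.5
    hap1[amb] <- ifelse(flip, 1L, 0L)
    hap2[amb] <- 1L - hap1[amb]
  }
  ord <- het & aj != ak
  hap1[ord] <- aj[ord]; hap2[ord] <- ak[ord]

  switches <- (diff(path[, 1]) != 0) + (diff(path[, 2]) != 0)
  res <- list(hap1 = as.integer(hap1), hap2 = as.integer(hap2),
              mismatch_count = as.integer(mismatch),
              switch_count_per_interval = as.integer(switches))
  ok <- is.na(g) | (res$hap1 + res$hap2 == g)
  if (!all(ok))
    stop("internal error: sampled haplotypes inconsistent with genotypes at marker ",
         which(!ok)[1])
  class(res) <- "sampled_haplotypes"
  res
}
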