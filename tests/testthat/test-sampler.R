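test_that("mirror adjustment floors uninformative pairs and renormalizes", {
  # when every pair carries exactly its mirror's weight, nothing is
  # informative: all adjusted weights hit the floor, i.e. uniform
  w <- matrix(0.25, 2, 2)
  adj <- mirror_adjust(w, mate = c(2L, 1L), epsilon_rel = 1e-10)
  expect_equal(adj, matrix(0.25, 2, 2))
  expect_equal(sum(adj), 1)

  # no mated competitors: subtraction of zero, output is the renormalized input
  w2 <- matrix(c(0.4, 0.1, 0.3, 0.2), 2, 2)
  adj2 <- mirror_adjust(w2, mate = c(NA_integer_, NA_integer_), epsilon_rel = 1e-10)
  expect_equal(adj2, w2 / sum(w2))

  expect_error(mirror_adjust(matrix(0, 2, 2), c(2L, 1L), 1e-10), "zero")
})

test_that("mirror adjustment computes max(w - w_mirror, eps) elementwise", {
  # two mated pairs (1,2) and (3,4); weights concentrated on the cross block
  eps_rel <- 1e-10
  w <- matrix(0, 4, 4)
  w[1, 3] <- 0.4; w[1, 4] <- 0.1; w[2, 3] <- 0.2; w[2, 4] <- 0.3
  mate <- c(2L, 1L, 4L, 3L)
  adj <- mirror_adjust(w, mate, eps_rel)
  eps_abs <- eps_rel * sum(w)
  expected <- matrix(eps_abs, 4, 4)
  expected[1, 3] <- max(w[1, 3] - w[2, 4], eps_abs)   # 0.1
  expected[1, 4] <- max(w[1, 4] - w[2, 3], eps_abs)   # eps
  expected[2, 3] <- max(w[2, 3] - w[1, 4], eps_abs)   # 0.1
  expected[2, 4] <- max(w[2, 4] - w[1, 3], eps_abs)   # eps
  expected <- expected / sum(expected)
  expect_equal(adj, expected, tolerance = 1e-12)
  # no state is strictly precluded
  expect_true(all(adj > 0))
  expect_equal(sum(adj), 1)
})

test_that("degenerate posteriors are sampled deterministically in both modes", {
  # theta = 0, e = 0, exactly one cross-individual pair consistent with all
  # genotypes: haplotype 1 of individual X with haplotype 1 of individual Y
  M <- 5
  h1 <- c(0L, 1L, 0L, 1L, 1L); h2 <- c(1L, 1L, 0L, 0L, 1L)
  g <- h1 + h2                           # (1, 2, 0, 1, 2)
  junk <- c(0L, 0L, 1L, 1L, 0L)          # inconsistent wherever it matters
  al <- rbind(h1, junk, h2, junk)        # X = (h1, junk), Y = (h2, junk)
  suppressWarnings(pp <- hmm_params(theta = 0, error_rate = 0))
  v <- view_of(al, mate = c(2L, 1L, 4L, 3L))
  fwd <- forward(g, v, pp)
  for (mode in c("original", "mirror")) {
    set.seed(5)
    path <- backward_sample(fwd, pp, mode)
    expect_true(all(path[, 1] == 1 & path[, 2] == 3) ||
                all(path[, 1] == 3 & path[, 2] == 1))
  }
})

test_that("original-mode sampling frequencies track the exact posteriors", {
  set.seed(77)
  inst <- random_hmm_instance(3, 4, p_missing = 0.2)
  pp <- hmm_params(theta = 0.15, error_rate = 0.03)
  v <- view_of(inst$alleles)
  fwd <- forward(inst$g, v, pp)
  post <- forward_backward_posteriors(fwd)
  n <- 30000
  draws <- mirrorphase:::cpp_backward_sample(fwd$F, 3L, 4L, fwd$theta, v$mate,
                                             0L, 1e-10, as.integer(n), TRUE)
  for (m in 1:4) {
    freq <- tabulate((draws[, 4 + m] - 1) * 3 + draws[, m], nbins = 9) / n
    tv <- 0.5 * sum(abs(freq - as.vector(post[, , m])))
    expect_lt(tv, 0.02)
  }
})

test_that("with no mates, mirror mode equals original mode draw for draw", {
  set.seed(88)
  inst <- random_hmm_instance(4, 5)
  pp <- hmm_params(theta = 0.1, error_rate = 0.02)
  v <- view_of(inst$alleles)  # empty mate map
  fwd <- forward(inst$g, v, pp)
  set.seed(123); p1 <- backward_sample(fwd, pp, "original")
  set.seed(123); p2 <- backward_sample(fwd, pp, "mirror")
  expect_identical(unclass(p1), unclass(p2))
})

test_that("mirror mode suppresses copy pairs in the duplicate construction", {
  # individuals A and B genotype-identical across all markers; several
  # informative individuals carrying single-haplotype matches are present
  set.seed(99)
  M <- 30
  anc <- matrix(rbinom(6 * M, 1, 0.5), 6, M)
  hB <- anc[1:2, , drop = FALSE]               # B holds A's true haplotypes
  g <- as.integer(hB[1, ] + hB[2, ])
  oth <- anc[c(1, 3, 2, 4, 1, 5, 2, 6, 3, 4), ]  # 5 informative individuals
  al <- rbind(hB, oth)                         # view: B = rows 1,2
  eps_rel <- 1e-10
  pp <- hmm_params(theta = 0.02, error_rate = 0.005, epsilon_rel = eps_rel)
  v <- view_of(al, mate = as.integer(seq_len(12) + c(1, -1)))
  fwd <- forward(g, v, pp)

  # direct weight comparison at an interior marker: the adjusted forward
  # weight of each copy pair is at most 100 * eps_rel times its unadjusted
  # (original-mode) weight
  mid <- 15
  w <- fwd$F[, , mid]
  expect_gt(w[1, 2] + w[2, 1], 0.1)     # copy pairs carry real mass
  adj <- mirror_adjust(w, v$mate, eps_rel)
  for (cp in list(c(1, 2), c(2, 1))) {
    ratio <- adj[cp[1], cp[2]] / w[cp[1], cp[2]]
    expect_lt(ratio, 100 * eps_rel)
  }

  # and sampled paths never settle on a copy pair
  set.seed(7)
  copy_hits <- 0
  for (r in 1:200) {
    p <- backward_sample(fwd, pp, "mirror")
    copy_hits <- copy_hits + sum(p[2:(M - 1), 1] %in% 1:2 &
                                 p[2:(M - 1), 2] %in% 1:2)
  }
  expect_identical(copy_hits, 0)
})

test_that("sampled paths convert to genotype-consistent haplotypes", {
  set.seed(111)
  for (r in 1:20) {
    inst <- random_hmm_instance(4, 6)
    pp <- hmm_params(theta = 0.1, error_rate = 0.02)
    v <- view_of(inst$alleles)
    fwd <- forward(inst$g, v, pp)
    path <- backward_sample(fwd, pp, "original")
    smp <- haplotypes_from_path(path, v, inst$g)
    ok <- is.na(inst$g) | (smp$hap1 + smp$hap2 == inst$g)
    expect_true(all(ok))
    expect_lte(smp$mismatch_count, 2 * 6)
  }
})

test_that("haplotype extraction handles homozygous, consistent and switching paths", {
  # all-homozygous: output is the genotype itself, mismatches counted
  al <- rbind(c(0L, 1L, 0L), c(1L, 1L, 0L))
  g <- c(0L, 2L, 0L)
  path <- cbind(j = c(1L, 1L, 1L), k = c(2L, 2L, 2L))
  smp <- haplotypes_from_path(path, view_of(al), g)
  expect_identical(smp$hap1, c(0L, 1L, 0L))
  expect_identical(smp$hap2, c(0L, 1L, 0L))
  # independent recount: per-allele disagreements at homozygous sites
  recount <- sum(al[1, ] != g %/% 2) + sum(al[2, ] != g %/% 2)
  expect_identical(smp$mismatch_count, as.integer(recount))

  # e=0-consistent path: templates reproduce the genotype exactly
  h1 <- c(0L, 1L, 1L); h2 <- c(1L, 0L, 1L)
  al2 <- rbind(h1, h2)
  smp2 <- haplotypes_from_path(cbind(c(1L, 1L, 1L), c(2L, 2L, 2L)),
                               view_of(al2), h1 + h2)
  expect_identical(smp2$mismatch_count, 0L)
  expect_identical(smp2$hap1, h1)
  expect_identical(smp2$hap2, h2)
  expect_identical(smp2$switch_count_per_interval, c(0L, 0L))

  # one template change on chromatid 1 between markers 2 and 3
  path3 <- cbind(c(1L, 1L, 2L, 2L), c(2L, 2L, 2L, 2L))
  smp3 <- haplotypes_from_path(path3, view_of(matrix(0L, 2, 4)),
                               rep(0L, 4))
  expect_identical(smp3$switch_count_per_interval, c(0L, 1L, 0L))
})

test_that("random orientation at template-equal heterozygous sites is seeded", {
  al <- matrix(1L, 2, 4)   # templates always equal -> every het site ambiguous
  g <- rep(1L, 4)
  path <- cbind(rep(1L, 4), rep(2L, 4))
  set.seed(42); a <- haplotypes_from_path(path, view_of(al), g)
  set.seed(42); b <- haplotypes_from_path(path, view_of(al), g)
  expect_identical(a, b)
  expect_identical(a$mismatch_count, 4L)
})
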