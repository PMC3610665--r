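test_that("switch errors follow the Marchini flip convention", {
  h <- rbind(c(0L, 1L, 0L, 1L, 0L, 1L), c(1L, 0L, 1L, 0L, 1L, 0L))  # all het
  expect_identical(switch_errors(h, h)$n_switches, 0L)
  # wholesale swap is not an error: phase is defined up to pair order
  expect_identical(switch_errors(h, h[2:1, ])$n_switches, 0L)

  # 5 het sites, orientation flipped from site 3 onward -> 1 switch
  h5 <- rbind(c(0L, 0L, 0L, 0L, 0L), c(1L, 1L, 1L, 1L, 1L))
  inf1 <- h5; inf1[, 3:5] <- h5[2:1, 3:5]
  r1 <- switch_errors(h5, inf1)
  expect_identical(r1$n_switches, 1L)
  expect_identical(which(r1$per_marker), 3L)   # attributed to the right-hand site

  # flipped only at site 3 -> 2 switches (in and back out)
  inf2 <- h5; inf2[, 3] <- h5[2:1, 3]
  r2 <- switch_errors(h5, inf2)
  expect_identical(r2$n_switches, 2L)
  expect_identical(which(r2$per_marker), c(3L, 4L))

  expect_error(switch_errors(h5, h5[, 1:3]), "length")
})

test_that("switch scoring skips genotype-mismatched and missing sites", {
  truth <- rbind(c(0L, 0L, 1L, 0L), c(1L, 1L, 1L, 1L))  # het at 1,2,4
  inf <- rbind(c(0L, 0L, 0L, 0L), c(1L, 1L, 0L, 1L))    # dosage wrong at 3
  r <- switch_errors(truth, inf)
  expect_identical(r$n_scored, 3L)
  expect_identical(r$skipped_sites, 0L)   # site 3 not het in truth? it is dosage 2 -> not het
  truth2 <- rbind(c(0L, 1L), c(1L, 0L))
  inf2 <- rbind(c(0L, 1L), c(1L, 1L))     # site 2 dosage mismatch
  r2 <- switch_errors(truth2, inf2)
  expect_identical(r2$n_scored, 1L)
  expect_identical(r2$skipped_sites, 1L)
})

test_that("switch errors match the direct recount oracle and its invariances", {
  set.seed(120)
  for (r in 1:200) {
    M <- sample(5:40, 1)
    t1 <- rbinom(M, 1, 0.5); t2 <- rbinom(M, 1, 0.5)
    truth <- rbind(t1, t2)
    i1 <- rbinom(M, 1, 0.5); i2 <- rbinom(M, 1, 0.5)
    inf <- rbind(i1, i2)
    expect_identical(switch_errors(truth, inf)$n_switches,
                     oracle_switch_errors(truth, inf))
    expect_identical(switch_errors(truth, inf)$n_switches,
                     switch_errors(truth[2:1, ], inf)$n_switches)
    expect_identical(switch_errors(truth, inf)$n_switches,
                     switch_errors(truth, inf[2:1, ])$n_switches)
    expect_identical(switch_errors(inf, inf)$n_switches, 0L)
  }
})

test_that("sharing runs detect double and single IBS segments", {
  g <- c(0L, 1L, 2L, 1L, 0L)
  # twins: one double run covering everything
  r <- sharing_runs(g, g, "double")
  expect_identical(nrow(r), 1L)
  expect_identical(c(r$start, r$end), c(0L, 5L))

  # opposing homozygotes break single sharing exactly there
  gB <- c(0L, 1L, 0L, 1L, 0L)   # (2,0) at site 3
  rs <- sharing_runs(g, gB, "single")
  expect_identical(rs$start, c(0L, 3L))
  expect_identical(rs$end, c(2L, 5L))

  # double runs are always contained in single runs
  set.seed(130)
  for (r in 1:100) {
    M <- sample(10:80, 1)
    a <- rbinom(M, 2, 0.5); b <- rbinom(M, 2, 0.5)
    a[runif(M) < 0.05] <- NA
    dd <- sharing_runs(a, b, "double")
    ss <- sharing_runs(a, b, "single")
    if (nrow(dd)) for (i in seq_len(nrow(dd)))
      expect_true(any(ss$start <= dd$start[i] & ss$end >= dd$end[i]))
    # brute-force maximal-run oracle agreement
    for (kind in c("double", "single")) {
      mine <- sharing_runs(a, b, kind)
      orc <- oracle_sharing_runs(a, b, kind)
      expect_identical(mine$start, as.integer(orc$start))
      expect_identical(mine$end, as.integer(orc$end))
    }
  }
})

test_that("missingness either joins or breaks runs as configured", {
  a <- c(1L, NA, 1L); b <- c(1L, 0L, 1L)
  expect_identical(nrow(sharing_runs(a, b, "double")), 1L)
  expect_identical(nrow(sharing_runs(a, b, "double", missing_matches = FALSE)), 2L)
})

test_that("best-match statistics agree with exhaustive recomputation", {
  # twins: best-match mean and max equal M for the twin pair
  spec <- scenario_spec("twins_all", n_parents = 4, n_markers = 30,
                        n_reference = 0, genotyping_error = 0, seed = 16)
  ts <- build_scenario(spec)
  bm <- best_match_stats(ts$genotypes, "double")
  tw <- which(!is.na(ts$pedigree$twin_of))
  expect_true(all(bm$per_individual$mean_len[tw] == 30))
  expect_true(all(bm$per_individual$max_len[tw] == 30))
  expect_identical(bm$longest_run, 30L)

  # a cohort with no sharing at all scores zero
  d <- rbind(rep(0L, 10), rep(2L, 10), rep(0:2, length.out = 10) * 0L + 2L)
  d[3, ] <- rep(c(0L, 2L), 5)
  bm0 <- best_match_stats(rbind(rep(0L, 10), rep(2L, 10)), "double")
  expect_true(all(bm0$per_individual$mean_len == 0))
  expect_identical(bm0$longest_run, 0L)

  set.seed(140)
  for (r in 1:20) {
    N <- sample(3:5, 1); M <- sample(10:60, 1)
    d <- matrix(rbinom(N * M, 2, 0.5), N, M)
    for (kind in c("double", "single")) {
      mine <- best_match_stats(d, kind)
      best <- oracle_best_match(d, kind)
      expect_equal(mine$per_individual$mean_len, rowMeans(best))
      expect_equal(mine$per_individual$max_len, apply(best, 1, max))
    }
  }
})

test_that("per-marker error maps localize switches per method", {
  mk <- function(per) structure(list(n_switches = sum(per),
                                     per_marker = per, n_scored = 10L,
                                     skipped_sites = 0L),
                                class = "switch_error_report")
  none <- lapply(1:30, function(i) mk(rep(FALSE, 10)))
  tab <- per_marker_error_map(list(original = none))
  expect_true(all(tab$original == 0))

  one <- none
  one[[5]] <- mk(replace(rep(FALSE, 10), 7, TRUE))
  tab2 <- per_marker_error_map(list(original = one, mirror = none))
  expect_equal(tab2$original[7], 1 / 30)
  expect_equal(sum(tab2$original), 1 / 30)
  expect_true(all(tab2$mirror == 0))
})

test_that("cross-validation flips vanish for identical subsets and seeds", {
  set.seed(150)
  spec <- scenario_spec("parents_only", n_parents = 8, n_markers = 60, seed = 17)
  ts <- build_scenario(spec)
  cfg <- phasing_config(n_iterations = 3, mode = "mirror", seed = 5)
  res <- suppressWarnings(crossval_flip_rate(
    ts$genotypes, cfg, k_subsets = 2, holdout_fraction = 0.25,
    subsets = list(1:6, 1:6), subset_seeds = c(9, 9), window_size = 20))
  expect_true(all(res$per_individual == 0))
  expect_true(all(res$per_window == 0))
})

test_that("cross-validation flips concentrate where two individuals duplicate", {
  set.seed(160)
  spec <- scenario_spec("parents_only", n_parents = 12, n_markers = 150, seed = 18)
  ts <- build_scenario(spec)
  d <- ts$genotypes$dosage
  dup <- 51:110                      # make individuals 1 and 2 identical here
  d[2, dup] <- d[1, dup]
  gm <- genotype_matrix(d)
  cfg <- phasing_config(n_iterations = 12, mode = "original", seed = 6)
  res <- suppressWarnings(crossval_flip_rate(
    gm, cfg, k_subsets = 2, holdout_fraction = 0.2, window_size = 25,
    subsets = list(1:10, c(1:8, 11:12))))
  expect_true(all(res$per_individual >= 0))
  expect_identical(dim(res$per_window), c(12L, 6L))
  in_reg <- 3:5   # windows covering markers 51-125
  out_reg <- c(1, 2, 6)
  pair_flips <- colSums(res$per_window[1:2, , drop = FALSE])
  expect_gt(median(pair_flips[in_reg]), median(pair_flips[out_reg]))
})
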