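#' Switch-error report for one individual
#'
#' Compares an inferred haplotype pair to the true pair the standard way:
#' scoring is restricted to sites heterozygous in truth where the inferred
#' dosage equals the true dosage; each scored site gets an agreement bit
#' (does the inferred orientation match the truth?), and a switch is counted
#' whenever adjacent scored sites disagree. Phase is defined only up to the
#' order of the pair, so a wholesale swap of either argument changes nothing.
#' Each switch is attributed to the right-hand site of its disagreeing pair
#' (for per-marker localization). Sites excluded for genotype mismatch or
#' missingness are counted in `skipped_sites`.
#'
#' @param true_pair,inferred_pair 2 x M haplotype matrices.
#' @return A `switch_error_report`: `n_switches`, `per_marker` (logical
#'   length-M switch attribution), `n_scored`, `skipped_sites`.
#' @export
switch_errors <- function(true_pair, inferred_pair) {
  true_pair <- as.matrix(true_pair); inferred_pair <- as.matrix(inferred_pair)
  if (!identical(dim(true_pair), dim(inferred_pair)))
    stop("haplotype pairs differ in length")
  M <- ncol(true_pair)
  td <- true_pair[1, ] + true_pair[2, ]
  id <- inferred_pair[1, ] + inferred_pair[2, ]
  het <- !is.na(td) & td == 1L
  scored <- het & !is.na(id) & id == 1L
  skipped <- sum(het & !scored)
  per_marker <- rep(FALSE, M)
  n_sw <- 0L
  if (sum(scored) >= 2) {
    idx <- which(scored)
    agree <- inferred_pair[1, idx] == true_pair[1, idx]
    sw <- diff(agree) != 0
    n_sw <- sum(sw)
    per_marker[idx[-1][sw]] <- TRUE
  }
  structure(list(n_switches = as.integer(n_sw), per_marker = per_marker,
                 n_scored = as.integer(sum(scored)),
                 skipped_sites = as.integer(skipped)),
            class = "switch_error_report")
}

#' Cohort switch errors against a truth set
#'
#' Convenience wrapper: scores [switch_errors()] for a set of individuals
#' (default: the original parents — individuals without a twin/child role,
#' matching the convention of scoring only the founder generation).
#'
#' @param truth a `truth_set` from [build_scenario()].
#' @param result a `phasing_result` (or study [haplotype_pool()]).
#' @param individuals indices to score; default founders only.
#' @param markers marker indices to score over; defaults to the typed
#'   (unmasked) markers, matching the convention that phase is scored on the
#'   markers the phaser actually saw.
#' @return List of `switch_error_report`, one per scored individual, with
#'   attribute `individuals`.
#' @export
cohort_switch_errors <- function(truth, result,
                                 individuals = which(is.na(truth$pedigree$twin_of) &
                                                     is.na(truth$pedigree$father)),
                                 markers = setdiff(seq_len(ncol(truth$genotypes$dosage)),
                                                   truth$genotypes$mask)) {
  pool <- if (inherits(result, "phasing_result")) result$haplotypes else result
  out <- lapply(individuals, function(i) {
    switch_errors(truth$haplotypes$alleles[c(2L * i - 1L, 2L * i), markers, drop = FALSE],
                  pool$alleles[c(2L * i - 1L, 2L * i), markers, drop = FALSE])
  })
  attr(out, "individuals") <- individuals
  out
}

#' Imputed-allele error count
#'
#' Per masked genotype, the error contribution is `|true - imputed|` dosage
#' difference under best-guess calls, capped at 2 (both alleles wrong);
#' totals are summed over individuals and masked sites.
#'
#' @param truth a [genotype_matrix()] (its retained `truth` is used) or a
#'   plain dosage matrix.
#' @param imputed an `imputation_result` from [impute_dataset()].
#' @return Integer total allele error count.
#' @export
imputed_allele_errors <- function(truth, imputed) {
  stopifnot(inherits(imputed, "imputation_result"))
  td <- if (inherits(truth, "genotype_matrix")) {
    if (!is.null(truth$truth)) truth$truth else truth$dosage
  } else as.matrix(truth)
  if (nrow(td) != nrow(imputed$best_guess))
    stop("truth and imputation cover different individuals")
  if (max(imputed$mask) > ncol(td)) stop("mask extends beyond truth markers")
  sum(pmin(abs(td[, imputed$mask, drop = FALSE] - imputed$best_guess), 2L),
      na.rm = TRUE)
}

#' Genotype-sharing runs between two individuals
#'
#' Maximal runs of markers where the two dosage vectors satisfy the sharing
#' condition: `"double"` requires identical genotypes at every marker (the
#' identical-by-state condition that makes a pair mutually uninformative for
#' phase); `"single"` requires no opposing homozygotes (|gA - gB| <= 1,
#' compatible with sharing one haplotype). Missing sites count as matching
#' by default, so missingness does not break a true sharing tract.
#'
#' @param gA,gB equal-length dosage vectors.
#' @param kind `"double"` or `"single"`.
#' @param missing_matches treat `NA` sites as satisfying the condition?
#' @return Data frame of runs (`start`, `end` 0-based half-open, `kind`),
#'   sorted by start.
#' @export
sharing_runs <- function(gA, gB, kind = c("double", "single"),
                         missing_matches = TRUE) {
  kind <- match.arg(kind)
  stopifnot(length(gA) == length(gB))
  ok <- if (kind == "double") gA == gB else abs(gA - gB) <= 1L
  ok[is.na(ok)] <- missing_matches
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             kind = rep(kind, sum(keep)))
}

#' Best-match sharing statistics over a cohort
#'
#' For each individual and marker, the best match length is the longest
#' `kind`-sharing run containing that marker against any other individual
#' (0 if the marker is in no run). Reports per-individual mean (over
#' markers) and max, cohort mean/max of those, and the single longest run
#' over all pairs — the run-length statistics that quantify how much
#' double/single genotype sharing a dataset carries.
#'
#' @param genotypes a [genotype_matrix()] or dosage matrix.
#' @param kind `"double"` or `"single"`.
#' @param missing_matches passed to [sharing_runs()].
#' @return List: `per_individual` (data frame `mean_len`, `max_len`),
#'   `cohort_mean`, `cohort_max`, `longest_run`.
#' @export
best_match_stats <- function(genotypes, kind = c("double", "single"),
                             missing_matches = TRUE) {
  kind <- match.arg(kind)
  d <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage
       else as.matrix(genotypes)
  N <- nrow(d); M <- ncol(d)
  if (N < 2) stop("need at least 2 individuals")
  best <- matrix(0L, N, M)           # best run length covering each marker
  longest <- 0L
  for (a in seq_len(N - 1)) for (b in (a + 1):N) {
    runs <- sharing_runs(d[a, ], d[b, ], kind, missing_matches)
    if (!nrow(runs)) next
    lens <- runs$end - runs$start
    longest <- max(longest, max(lens))
    for (r in seq_len(nrow(runs))) {
      span <- (runs$start[r] + 1L):runs$end[r]
      ln <- lens[r]
      upd <- best[a, span] < ln
      if (any(upd)) best[a, span[upd]] <- ln
      upd <- best[b, span] < ln
      if (any(upd)) best[b, span[upd]] <- ln
    }
  }
  per <- data.frame(mean_len = rowMeans(best), max_len = apply(best, 1, max))
  list(per_individual = per, cohort_mean = mean(per$mean_len),
       cohort_max = max(per$max_len), longest_run = as.integer(longest))
}

#' Per-marker switch-error localization map
#'
#' For each marker and each method, the fraction of scored individuals with
#' a switch attributed there — the per-marker view in which chain lock-in
#' shows up as contiguous blocks of repeated errors.
#'
#' @param reports named list; each element is a list of
#'   `switch_error_report`s (one per individual) for one method.
#' @return Data frame with `marker` and one error-rate column per method.
#' @export
per_marker_error_map <- function(reports) {
  stopifnot(length(reports) >= 1)
  cols <- lapply(reports, function(rs) {
    Reduce(`+`, lapply(rs, function(r) as.numeric(r$per_marker))) / length(rs)
  })
  M <- length(cols[[1]])
  out <- data.frame(marker = seq_len(M))
  nm <- names(reports)
  if (is.null(nm)) nm <- paste0("method", seq_along(reports))
  for (i in seq_along(cols)) out[[nm[i]]] <- cols[[i]]
  out
}

# longest run of rates strictly above a threshold (default: their median);
# the block-structure statistic used to compare error maps between sampling
# modes. For a two-method comparison the threshold must be shared (pooled
# median), otherwise a method with median 0 is scored on any error at all.
longest_above_median_run <- function(rates, threshold = median(rates)) {
  above <- rates > threshold
  if (!any(above)) return(0L)
  r <- rle(above)
  as.integer(max(r$lengths[r$values]))
}

#' Cross-validation flip-rate diagnostic
#'
#' Phases `k_subsets` random subsets of the cohort, each omitting a fraction
#' of individuals, and counts switch disagreements ("flips") between the
#' inferred phasings of individuals common to each pair of subsets. Genomic
#' regions where flips concentrate are phased from too little independent
#' information — the symptom of insufficient chain mixing — even when no
#' truth is available.
#'
#' @param genotypes a [genotype_matrix()].
#' @param config a [phasing_config()] used for every subset run (the seed is
#'   offset per subset).
#' @param k_subsets number of subsets (>= 2).
#' @param holdout_fraction fraction of individuals omitted per subset, in
#'   (0, 0.5].
#' @param window_size markers per window for localization.
#' @param subsets optional list of retained individual indices, one element
#'   per subset (overrides the random draw).
#' @param subset_seeds optional per-subset phasing seeds (default
#'   `config$seed + 1:k`).
#' @return List: `per_individual` (named flip totals),
#'   `per_window` (individual x window matrix), `windows` (data frame of
#'   window bounds), `subsets` (list of retained indices).
#' @export
crossval_flip_rate <- function(genotypes, config, k_subsets = 2L,
                               holdout_fraction = 0.2, window_size = 25L,
                               subsets = NULL, subset_seeds = NULL) {
  stopifnot(k_subsets >= 2, holdout_fraction > 0, holdout_fraction <= 0.5)
  N <- nrow(genotypes$dosage); M <- ncol(genotypes$dosage)
  n_hold <- max(1L, round(holdout_fraction * N))
  if (N - n_hold < 2) stop("cohort too small for this holdout fraction")

  set.seed(config$seed)
  if (is.null(subsets))
    subsets <- lapply(seq_len(k_subsets), function(s)
      sort(sample.int(N, N - n_hold)))
  k_subsets <- length(subsets)
  if (is.null(subset_seeds)) subset_seeds <- config$seed + seq_len(k_subsets)
  results <- lapply(seq_len(k_subsets), function(s) {
    cfg <- config; cfg$seed <- subset_seeds[s]
    gm <- genotype_matrix(genotypes$dosage[subsets[[s]], , drop = FALSE])
    run_phasing(gm, config = cfg)
  })

  breaks <- seq(0L, M, by = window_size)
  if (breaks[length(breaks)] < M) breaks <- c(breaks, M)
  n_win <- length(breaks) - 1L
  win_of <- pmin(ceiling(seq_len(M) / window_size), n_win)

  flips <- setNames(rep(0L, N), seq_len(N))
  per_window <- matrix(0L, N, n_win)
  for (a in seq_len(k_subsets - 1)) for (b in (a + 1):k_subsets) {
    common <- intersect(subsets[[a]], subsets[[b]])
    for (i in common) {
      ia <- match(i, subsets[[a]]); ib <- match(i, subsets[[b]])
      pa <- results[[a]]$haplotypes$alleles[c(2 * ia - 1, 2 * ia), , drop = FALSE]
      pb <- results[[b]]$haplotypes$alleles[c(2 * ib - 1, 2 * ib), , drop = FALSE]
      rep_i <- switch_errors(pa, pb)
      flips[i] <- flips[i] + rep_i$n_switches
      w <- tabulate(win_of[rep_i$per_marker], nbins = n_win)
      per_window[i, ] <- per_window[i, ] + w
    }
  }
  list(per_individual = flips, per_window = per_window,
       windows = data.frame(start = breaks[-length(breaks)] + 1L,
                            end = breaks[-1]),
       subsets = subsets)
}
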