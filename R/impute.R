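#' Haploid imputation of one haplotype against a reference panel
#'
#' Minimac-style haploid Li & Stephens pass: the pre-phased study haplotype
#' is modeled as a mosaic copy of the panel haplotypes, with emission
#' `1 - e` / `e` at typed sites and 1 at masked (missing) sites. The
#' returned posterior at site `m` is the probability that the underlying
#' allele is 1, error-adjusted over the panel:
#' `sum_j post_m(j) * (a_j (1 - e) + (1 - a_j) e)`.
#'
#' @param hap length-M allele vector with `NA` at masked sites.
#' @param panel a fixed, phased [haplotype_pool()] (or 0/1 matrix, haplotypes
#'   in rows) covering the same markers.
#' @param params an [hmm_params()].
#' @return Numeric length-M vector of allele-1 posterior probabilities.
#' @export
impute_haplotype <- function(hap, panel, params) {
  al <- if (inherits(panel, "haplotype_pool")) panel$alleles else as.matrix(panel)
  storage.mode(al) <- "integer"
  if (nrow(al) < 1) stop("empty reference panel")
  M <- ncol(al)
  th <- expand_theta(params, M)
  cpp_haploid_posterior(as.integer(hap), al, th, params$error_rate)
}

#' Impute masked genotypes for a pre-phased cohort
#'
#' Runs [impute_haplotype()] on each of the `2N` study haplotypes with their
#' masked sites set to missing; the per-individual best-guess dosage at a
#' masked marker is the sum of the two haplotypes' hard calls (posterior
#' `> 0.5` calls allele 1; a tie calls 0). When truth is supplied, the
#' allele error count over all masked genotypes is reported
#' (`|true - imputed|` per genotype, each contributing 0, 1 or 2).
#'
#' @param prephased a `phasing_result` from [run_phasing()] or a
#'   [haplotype_pool()] of study haplotypes.
#' @param panel fixed phased reference panel covering the same markers.
#' @param mask integer vector of masked marker indices (1-based).
#' @param truth optional [genotype_matrix()] (its `truth` or `dosage` is
#'   scored at masked sites).
#' @param params an [hmm_params()].
#' @return An `imputation_result`: `dosage_posterior` (2N x |mask| allele-1
#'   posteriors), `best_guess` (N x |mask| dosages), `error_count`.
#' @export
impute_dataset <- function(prephased, panel, mask, truth = NULL,
                           params = hmm_params()) {
  pool <- if (inherits(prephased, "phasing_result")) prephased$haplotypes
          else prephased
  stopifnot(inherits(pool, "haplotype_pool"))
  al <- pool$alleles
  M <- ncol(al)
  mask <- sort(unique(as.integer(mask)))
  if (length(mask) && (min(mask) < 1 || max(mask) > M))
    stop("mask indices out of marker range")
  N <- nrow(al) %/% 2L

  post <- matrix(NA_real_, nrow(al), length(mask))
  for (h in seq_len(nrow(al))) {
    hv <- al[h, ]
    hv[mask] <- NA_integer_
    post[h, ] <- impute_haplotype(hv, panel, params)[mask]
  }
  calls <- matrix(as.integer(post > 0.5), nrow(al), length(mask))
  best <- calls[seq(1, 2 * N, by = 2), , drop = FALSE] +
          calls[seq(2, 2 * N, by = 2), , drop = FALSE]

  err <- NA_integer_
  if (!is.null(truth)) {
    td <- if (inherits(truth, "genotype_matrix")) {
      if (!is.null(truth$truth)) truth$truth else truth$dosage
    } else as.matrix(truth)
    if (nrow(td) != N || ncol(td) != M)
      stop("truth does not align with the imputed cohort")
    err <- sum(pmin(abs(td[, mask, drop = FALSE] - best), 2L), na.rm = TRUE)
  }
  structure(list(dosage_posterior = post, best_guess = best,
                 mask = mask, error_count = as.integer(err)),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result> %d haplotypes x %d masked markers",
              nrow(x$dosage_posterior), length(x$mask)))
  if (!is.na(x$error_count))
    cat(sprintf("; %d allele errors vs truth", x$error_count))
  cat("\n")
  invisible(x)
}
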