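#' Marker map
#'
#' Describes the markers of a single chromosome: identifiers, physical
#' positions (base pairs, strictly increasing) and genetic positions
#' (centimorgans, non-decreasing). All alleles in the package are coded
#' 0 (reference) / 1 (alternate).
#'
#' @param marker_id character vector of marker names.
#' @param position_bp integer positions in base pairs, strictly increasing.
#' @param position_cm genetic positions in centimorgans, non-decreasing.
#'   Defaults to 0.01 cM per interval.
#' @return A `marker_map` object (a data frame with one row per marker).
#' @export
marker_map <- function(marker_id, position_bp,
                       position_cm = (seq_along(marker_id) - 1) * 0.01) {
  M <- length(marker_id)
  stopifnot(length(position_bp) == M, length(position_cm) == M)
  if (M >= 2) {
    if (any(diff(position_bp) <= 0))
      stop("physical positions must be strictly increasing")
    if (any(diff(position_cm) < 0))
      stop("genetic positions must be non-decreasing")
  }
  out <- data.frame(marker_id = as.character(marker_id),
                    position_bp = as.integer(position_bp),
                    position_cm = as.numeric(position_cm),
                    stringsAsFactors = FALSE)
  class(out) <- c("marker_map", "data.frame")
  out
}

#' Number of markers in a map
#' @param map a [marker_map()].
#' @return integer marker count.
#' @export
n_markers <- function(map) nrow(map)

#' Haplotype pool
#'
#' The set of all haplotypes visible to the phasing engine: an `H x M` 0/1
#' allele matrix together with per-haplotype metadata. `mate[j]` is the index
#' of the other haplotype of the same individual (an involution), `owner[j]`
#' the individual index, and `fixed[j]` marks pre-phased reference haplotypes
#' that are never resampled.
#'
#' @param alleles integer `H x M` matrix over \{0, 1\}.
#' @param owner integer vector: owning individual per haplotype.
#' @param mate integer vector: partner haplotype index, `NA` if undefined.
#' @param fixed logical vector: `TRUE` for reference haplotypes.
#' @return A `haplotype_pool` object.
#' @export
haplotype_pool <- function(alleles,
                           owner = rep(seq_len(nrow(alleles) / 2), each = 2),
                           mate = as.integer(seq_len(nrow(alleles)) +
                                             c(1L, -1L)[(seq_len(nrow(alleles)) - 1L) %% 2L + 1L]),
                           fixed = rep(FALSE, nrow(alleles))) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  H <- nrow(alleles)
  if (H < 2) stop("a haplotype pool needs at least 2 haplotypes")
  if (!all(alleles %in% c(0L, 1L))) stop("alleles must be coded 0/1")
  stopifnot(length(owner) == H, length(mate) == H, length(fixed) == H)
  def <- which(!is.na(mate))
  if (length(def)) {
    if (any(mate[def] == def)) stop("a haplotype cannot be its own mate")
    if (any(mate[mate[def]] != def)) stop("mate map must be an involution")
    if (any(owner[mate[def]] != owner[def]))
      stop("mated haplotypes must share an owner")
  }
  structure(list(alleles = alleles, owner = as.integer(owner),
                 mate = as.integer(mate), fixed = as.logical(fixed)),
            class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf("<haplotype_pool> %d haplotypes x %d markers (%d fixed, %d individuals)\n",
              nrow(x$alleles), ncol(x$alleles), sum(x$fixed),
              length(unique(x$owner))))
  invisible(x)
}

#' Genotype matrix
#'
#' Unordered biallelic dosages (\{0, 1, 2\}, `NA` for missing) for `N` study
#' individuals at `M` markers, plus the set of markers cleared (masked) for
#' imputation testing. Masked entries are stored as missing in `dosage`;
#' the pre-masking truth is retained in `truth` for scoring.
#'
#' @param dosage integer `N x M` matrix over \{0, 1, 2, NA\}.
#' @param mask integer vector of masked marker indices (1-based), or empty.
#' @param truth optional `N x M` dosage matrix holding pre-masking values.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosage, mask = integer(0), truth = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  ok <- dosage %in% c(0L, 1L, 2L) | is.na(dosage)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  mask <- sort(unique(as.integer(mask)))
  if (length(mask) && (min(mask) < 1 || max(mask) > ncol(dosage)))
    stop("mask indices out of range")
  if (!is.null(truth)) {
    truth <- as.matrix(truth)
    storage.mode(truth) <- "integer"
    stopifnot(identical(dim(truth), dim(dosage)))
  }
  structure(list(dosage = dosage, mask = mask, truth = truth),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d markers (%d masked, %.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage), length(x$mask),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Mask every second marker for imputation testing
#'
#' Clears the markers at even 1-based positions (2, 4, 6, ...), i.e. odd
#' 0-based indices, storing them as missing while retaining the original
#' dosages as truth. Applied to a whole truth set, the genotype component is
#' masked in place.
#'
#' @param x a [genotype_matrix()] or a truth set from [build_scenario()].
#' @return The same kind of object with the mask set.
#' @export
mask_every_second <- function(x) {
  if (inherits(x, "truth_set")) {
    x$genotypes <- mask_every_second(x$genotypes)
    return(x)
  }
  stopifnot(inherits(x, "genotype_matrix"))
  M <- ncol(x$dosage)
  if (M < 2) stop("need at least 2 markers to mask")
  mask <- seq(2L, M, by = 2L)
  truth <- if (is.null(x$truth)) x$dosage else x$truth
  dosage <- x$dosage
  dosage[, mask] <- NA_integer_
  genotype_matrix(dosage, mask = mask, truth = truth)
}

#' Restore masked genotypes from retained truth
#' @param x a masked [genotype_matrix()].
#' @return An unmasked `genotype_matrix`.
#' @export
unmask <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (!length(x$mask)) return(x)
  if (is.null(x$truth)) stop("no retained truth to restore from")
  genotype_matrix(x$truth, mask = integer(0), truth = NULL)
}

#' HMM parameters
#'
#' Parameters of the haplotype-copying model: per-interval template-switch
#' probabilities `theta` (the transition parameter standing in for historical
#' recombination), a per-allele miscopy/error rate `e`, and the relative
#' mirror floor `epsilon_rel` used by mirror-subtraction sampling.
#'
#' @param theta numeric: scalar or length-(M-1) vector of per-interval switch
#'   probabilities in \[0, 1).
#' @param error_rate per-allele miscopy probability in \[0, 0.5).
#' @param epsilon_rel relative mirror floor (> 0); the absolute floor used at
#'   a sampling step is `epsilon_rel` times the unadjusted weight sum.
#' @return An `hmm_params` object.
#' @export
hmm_params <- function(theta = 0.01, error_rate = 0.005, epsilon_rel = 1e-10) {
  stopifnot(all(theta >= 0), all(theta < 1),
            error_rate >= 0, error_rate < 0.5, epsilon_rel > 0)
  if (error_rate == 0)
    warning("error_rate = 0 permits impossible genotypes with zero likelihood; ",
            "consider the default floor 1e-4")
  structure(list(theta = as.numeric(theta), error_rate = error_rate,
                 epsilon_rel = epsilon_rel), class = "hmm_params")
}

# expand scalar theta to the M-1 intervals of a run
expand_theta <- function(params, M) {
  th <- params$theta
  if (length(th) == 1L) th <- rep(th, M - 1L)
  if (length(th) != M - 1L) stop("theta must be scalar or length M - 1")
  th
}
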