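#' Synthetic scenario specification
#'
#' Describes one of the four study designs used to demonstrate chain
#' lock-in under double genotype sharing: unrelated parents only; parents
#' plus one trio child per couple; a monozygotic duplicate for part of the
#' cohort (sibling-equivalent sharing, chromosome-wide for half the
#' parents); or a duplicate of every parent.
#'
#' @param name one of `"parents_only"`, `"with_children"`,
#'   `"sibling_twins_half"`, `"twins_all"`.
#' @param n_parents even number of founder parents (default 30, paired into
#'   couples).
#' @param n_markers marker count (default 1000, dense-chip style).
#' @param ancestral_pool_size number of ancestral haplotypes the founders
#'   mosaic-copy from; small pools give strong haplotype sharing and LD.
#' @param mosaic_switch_rate per-interval probability that a founder's copy
#'   jumps to a new ancestral template (expected shared-tract length is its
#'   reciprocal, in intervals).
#' @param cm_per_interval genetic map distance between adjacent markers, cM.
#' @param genotyping_error symmetric per-allele flip probability applied when
#'   genotypes are formed from the true haplotypes.
#' @param n_twins number of duplicated parents in `sibling_twins_half`
#'   (default `n_parents / 2`).
#' @param n_reference individuals in the phased reference panel generated
#'   alongside the cohort (from the same ancestral pool) for imputation;
#'   0 disables.
#' @param seed integer seed; scenarios are fully deterministic given the spec.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(name = c("parents_only", "with_children",
                                   "sibling_twins_half", "twins_all"),
                          n_parents = 30L, n_markers = 1000L,
                          ancestral_pool_size = 8L,
                          mosaic_switch_rate = 0.005,
                          cm_per_interval = 0.01,
                          genotyping_error = 0.002,
                          n_twins = n_parents %/% 2L,
                          n_reference = 30L,
                          seed = 1L) {
  name <- match.arg(name)
  stopifnot(n_parents >= 2, n_parents %% 2 == 0, n_markers >= 2,
            ancestral_pool_size >= 2, mosaic_switch_rate >= 0,
            mosaic_switch_rate <= 1, cm_per_interval >= 0,
            genotyping_error >= 0, genotyping_error < 0.5,
            n_twins >= 0, n_twins <= n_parents, n_reference >= 0)
  structure(list(name = name, n_parents = as.integer(n_parents),
                 n_markers = as.integer(n_markers),
                 ancestral_pool_size = as.integer(ancestral_pool_size),
                 mosaic_switch_rate = mosaic_switch_rate,
                 cm_per_interval = cm_per_interval,
                 genotyping_error = genotyping_error,
                 n_twins = as.integer(n_twins),
                 n_reference = as.integer(n_reference),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

# draw one ancestral pool: iid allele frequency 0.5 per site
draw_ancestral_pool <- function(spec) {
  matrix(as.integer(runif(spec$ancestral_pool_size * spec$n_markers) < 0.5),
         spec$ancestral_pool_size, spec$n_markers)
}

# one founder haplotype: mosaic copy of the ancestral pool; the template
# index vector is attached for tract-length diagnostics
mosaic_haplotype <- function(anc, rate) {
  P <- nrow(anc); M <- ncol(anc)
  tpl <- integer(M)
  tpl[1] <- sample.int(P, 1L)
  if (M > 1) {
    jump <- runif(M - 1) < rate
    for (m in 2:M) tpl[m] <- if (jump[m - 1]) sample.int(P, 1L) else tpl[m - 1]
  }
  structure(anc[cbind(tpl, seq_len(M))], template = tpl)
}

#' Simulate LD-rich founder haplotypes
#'
#' Draws an ancestral pool of `ancestral_pool_size` haplotypes with i.i.d.
#' allele frequency 0.5 per site, then builds each founder haplotype as a
#' mosaic copy of the pool with per-interval switch probability
#' `mosaic_switch_rate`. Founders thereby share single-haplotype tracts of
#' expected length `1 / mosaic_switch_rate` intervals — the sharing that
#' haplotype-copying phasers require to work at all.
#'
#' @param spec a [scenario_spec()].
#' @param n_haplotypes how many founder haplotypes to draw (default
#'   `2 * n_parents`).
#' @param ancestral optional pre-drawn ancestral pool matrix (to share one
#'   pool across founder sets).
#' @return An `n_haplotypes x n_markers` 0/1 matrix.
#' @export
simulate_founders <- function(spec, n_haplotypes = 2L * spec$n_parents,
                              ancestral = NULL) {
  if (is.null(ancestral)) ancestral <- draw_ancestral_pool(spec)
  haps <- lapply(seq_len(n_haplotypes),
                 function(i) mosaic_haplotype(ancestral, spec$mosaic_switch_rate))
  out <- do.call(rbind, haps)
  attr(out, "templates") <- do.call(rbind, lapply(haps, attr, "template"))
  out
}

#' Generate one gamete by Haldane recombination
#' @keywords internal
make_gamete <- function(hap1, hap2, map) {
  M <- length(hap1)
  cur <- sample.int(2L, 1L)
  out <- integer(M)
  out[1] <- if (cur == 1L) hap1[1] else hap2[1]
  if (M > 1) {
    d <- diff(map$position_cm)
    pswitch <- (1 - exp(-2 * d / 100)) / 2
    cross <- runif(M - 1) < pswitch
    for (m in 2:M) {
      if (cross[m - 1]) cur <- 3L - cur
      out[m] <- if (cur == 1L) hap1[m] else hap2[m]
    }
  }
  out
}

#' Simulate a trio child
#'
#' One gamete per parent: a recombinant of the parent's two haplotypes with
#' crossover probability between adjacent markers given by Haldane's map
#' function, `(1 - exp(-2 d / 100)) / 2` for distance `d` cM, starting
#' chromatid chosen by fair coin.
#'
#' @param parent1,parent2 2 x M haplotype matrices (rows = the two
#'   chromatids).
#' @param map a [marker_map()] shared by both parents.
#' @return A 2 x M haplotype matrix (row 1 from parent1, row 2 from parent2).
#' @export
make_child <- function(parent1, parent2, map) {
  stopifnot(ncol(parent1) == nrow(map), ncol(parent2) == nrow(map))
  rbind(make_gamete(parent1[1, ], parent1[2, ], map),
        make_gamete(parent2[1, ], parent2[2, ], map))
}

#' Build a synthetic truth set for one scenario
#'
#' Generates founder couples from a shared ancestral pool, applies the
#' scenario's augmentation (children / partial duplication / full
#' duplication), forms dosage genotypes with optional symmetric allele-flip
#' genotyping error, and duplicates twins at the genotype level *after*
#' error injection so that twin pairs are exactly genotype-identical — the
#' double-sharing condition that defeats classical backward sampling. A
#' phased reference panel (`n_reference` individuals from the same
#' ancestral pool) is generated alongside for imputation experiments.
#'
#' @param spec a [scenario_spec()].
#' @return A `truth_set`: `haplotypes` (study [haplotype_pool()], true
#'   phase), `genotypes` ([genotype_matrix()]), `pedigree` (data frame with
#'   `id`, `father`, `mother`, `twin_of`), `markers` ([marker_map()]),
#'   `reference` (fixed [haplotype_pool()] or `NULL`), and the `spec`.
#' @export
build_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  M <- spec$n_markers; P <- spec$n_parents
  map <- marker_map(sprintf("m%04d", seq_len(M)),
                    position_bp = seq_len(M) * 1000L,
                    position_cm = (seq_len(M) - 1) * spec$cm_per_interval)
  anc <- draw_ancestral_pool(spec)
  founders <- simulate_founders(spec, n_haplotypes = 2L * P, ancestral = anc)

  haps <- vector("list", P)                     # per-individual 2 x M
  for (i in seq_len(P)) haps[[i]] <- founders[c(2L * i - 1L, 2L * i), , drop = FALSE]
  ped <- data.frame(id = seq_len(P), father = NA_integer_,
                    mother = NA_integer_, twin_of = NA_integer_)

  twin_src <- integer(0)
  if (spec$name == "with_children") {
    for (c_i in seq_len(P %/% 2L)) {
      f <- 2L * c_i - 1L; m <- 2L * c_i
      haps[[length(haps) + 1L]] <- make_child(haps[[f]], haps[[m]], map)
      ped <- rbind(ped, data.frame(id = length(haps), father = f, mother = m,
                                   twin_of = NA_integer_))
    }
  } else if (spec$name == "sibling_twins_half") {
    twin_src <- seq_len(spec$n_twins)
  } else if (spec$name == "twins_all") {
    twin_src <- seq_len(P)
  }
  for (s in twin_src) {
    haps[[length(haps) + 1L]] <- haps[[s]]
    ped <- rbind(ped, data.frame(id = length(haps), father = NA_integer_,
                                 mother = NA_integer_, twin_of = s))
  }

  N <- length(haps)
  alleles <- do.call(rbind, haps)
  dosage <- matrix(0L, N, M)
  for (i in seq_len(N)) {
    if (!is.na(ped$twin_of[i])) next          # twins copy genotypes post-error
    h <- haps[[i]]
    if (spec$genotyping_error > 0) {
      flip1 <- runif(M) < spec$genotyping_error
      flip2 <- runif(M) < spec$genotyping_error
      dosage[i, ] <- abs(h[1, ] - flip1) + abs(h[2, ] - flip2)
    } else dosage[i, ] <- h[1, ] + h[2, ]
  }
  for (i in which(!is.na(ped$twin_of))) dosage[i, ] <- dosage[ped$twin_of[i], ]

  reference <- NULL
  if (spec$n_reference > 0) {
    ref <- simulate_founders(spec, n_haplotypes = 2L * spec$n_reference,
                             ancestral = anc)
    reference <- haplotype_pool(ref, fixed = rep(TRUE, nrow(ref)))
  }

  structure(list(haplotypes = haplotype_pool(alleles),
                 genotypes = genotype_matrix(dosage),
                 pedigree = ped, markers = map, reference = reference,
                 spec = spec),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("<truth_set> scenario '%s': %d individuals x %d markers",
              x$spec$name, nrow(x$genotypes$dosage), x$spec$n_markers))
  if (!is.null(x$reference))
    cat(sprintf(" (+%d reference individuals)", nrow(x$reference$alleles) / 2))
  cat("\n")
  invisible(x)
}
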