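#' Read biallelic genotypes from a VCF
#'
#' Accepts phased or unphased GT fields on biallelic SNP records; dosage is
#' the count of alternate alleles, `./.` (or `.|.`) becomes missing.
#' Multi-allelic or non-SNP records and duplicated positions are rejected
#' with the offending markers named.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param cm_per_interval genetic distance assigned between adjacent markers
#'   (VCFs carry no genetic map).
#' @return List: `genotypes` ([genotype_matrix()]), `markers`
#'   ([marker_map()]), `samples` (character), and `phased` logical matrix.
#' @export
read_genotypes_vcf <- function(path, cm_per_interval = 0.01) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  bad <- nchar(ref) != 1 | nchar(alt) != 1 | grepl(",", alt) |
    !ref %in% c("A", "C", "G", "T") | !alt %in% c("A", "C", "G", "T")
  if (any(bad))
    stop("non-SNP or multi-allelic records at: ",
         paste(fix[bad, "ID"], collapse = ", "))
  pos <- as.integer(fix[, "POS"])
  if (anyDuplicated(pos))
    stop("duplicated positions at: ",
         paste(unique(pos[duplicated(pos)]), collapse = ", "))

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  phased <- t(matrix(grepl("|", gt, fixed = TRUE), nrow(gt), ncol(gt)))
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  typed <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  bad_gt <- !typed & !(a1 == "." | is.na(gt))
  if (any(bad_gt))
    stop("unsupported GT values (ploidy != 2 or allele > 1) in ",
         sum(bad_gt), " cells")
  dos[typed] <- as.integer(a1[typed]) + as.integer(a2[typed])
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- sprintf("m%06d", pos[is.na(ids) | ids == "."])
  map <- marker_map(ids, pos, (seq_along(pos) - 1) * cm_per_interval)
  attr(map, "ref") <- ref; attr(map, "alt") <- alt
  attr(map, "chrom") <- fix[, "CHROM"]
  list(genotypes = genotype_matrix(t(dos)), markers = map,
       samples = colnames(gt), phased = phased)
}

vcf_fixed_cols <- function(markers) {
  chrom <- attr(markers, "chrom"); ref <- attr(markers, "ref")
  alt <- attr(markers, "alt")
  M <- nrow(markers)
  if (is.null(chrom)) chrom <- rep("1", M)
  if (is.null(ref)) ref <- rep("A", M)
  if (is.null(alt)) alt <- rep("G", M)
  cbind(chrom, markers$position_bp, markers$marker_id, ref, alt,
        ".", "PASS", ".", "GT")
}

vcf_header <- function(source_line, samples, timestamp = TRUE) {
  c("##fileformat=VCFv4.2",
    if (timestamp) paste0("##fileDate=", format(Sys.Date(), "%Y%m%d")),
    source_line,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

#' Write phased haplotypes to a VCF
#'
#' Emits phased GT fields (`h1|h2`); haplotype 1 stays left of the bar at
#' every marker, so phase continuity across markers is the payload.
#'
#' @param pool a [haplotype_pool()] of study haplotypes (rows `2i-1, 2i` per
#'   individual).
#' @param markers a [marker_map()].
#' @param path output file.
#' @param samples sample names (default `ind1..indN`).
#' @param source_info character noted in the `##source=` header line (tool,
#'   mode, seed).
#' @param timestamp write a `##fileDate` line?
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(pool, markers, path,
                             samples = NULL, source_info = "mirrorphase",
                             timestamp = TRUE) {
  al <- pool$alleles
  N <- nrow(al) %/% 2L
  if (is.null(samples)) samples <- sprintf("ind%d", seq_len(N))
  gt <- matrix("", nrow(markers), N)
  for (i in seq_len(N))
    gt[, i] <- paste0(al[2L * i - 1L, ], "|", al[2L * i, ])
  body <- cbind(vcf_fixed_cols(markers), gt)
  writeLines(c(vcf_header(paste0("##source=", source_info), samples, timestamp),
               apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Write unphased genotypes to a VCF
#'
#' Dosages become unphased GT (`0/0`, `0/1`, `1/1`); missing (including
#' masked) entries become `./.`.
#'
#' @inheritParams write_phased_vcf
#' @param genotypes a [genotype_matrix()].
#' @export
write_genotypes_vcf <- function(genotypes, markers, path,
                                samples = NULL, source_info = "mirrorphase",
                                timestamp = TRUE) {
  d <- genotypes$dosage
  N <- nrow(d)
  if (is.null(samples)) samples <- sprintf("ind%d", seq_len(N))
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", ncol(d), N)
  for (i in seq_len(N)) {
    g <- d[i, ]
    gt[!is.na(g), i] <- code[g[!is.na(g)] + 1L]
  }
  body <- cbind(vcf_fixed_cols(markers), gt)
  writeLines(c(vcf_header(paste0("##source=", source_info), samples, timestamp),
               apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read/write the plain haplotype matrix text format
#'
#' One haplotype per line as a space-free 0/1 string; consecutive line pairs
#' belong to one individual. A minimal interchange format for tests and
#' documentation.
#'
#' @param path text file.
#' @return [haplotype_pool()] for the reader; `path` for the writer.
#' @export
read_haplotypes_txt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 2 != 0) stop("haplotype file must pair lines per individual")
  al <- do.call(rbind, lapply(lines, function(l)
    as.integer(strsplit(l, "")[[1]])))
  haplotype_pool(al)
}

#' @rdname read_haplotypes_txt
#' @param pool a [haplotype_pool()].
#' @export
write_haplotypes_txt <- function(pool, path) {
  writeLines(apply(pool$alleles, 1, paste, collapse = ""), path)
  invisible(path)
}
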