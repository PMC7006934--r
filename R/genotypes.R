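#' Genotype container
#'
#' A light container for a dosage matrix plus its marker map. The dosage
#' matrix is samples x markers with entries 0, 1, 2 or `NA` (missing); fully
#' homozygous inbred parents carry only 0 and 2. The map is a tibble with one
#' row per marker giving chromosome and physical position (1-based bp).
#'
#' @param dosage numeric matrix, samples in rows, markers in columns; row and
#'   column names are sample and marker ids.
#' @param map tibble with columns `marker_id`, `chrom`, `pos` matching the
#'   columns of `dosage`; built from column names if omitted.
#' @param role `"parents"` or `"hybrids"`; some QC steps are only meaningful
#'   for one role.
#' @param groups optional character vector of group labels per sample
#'   (e.g. heterotic group), named by sample id.
#'
#' @return An object of class `geno`.
#' @export
geno <- function(dosage, map = NULL, role = c("parents", "hybrids"),
                 groups = NULL) {
  role <- match.arg(role)
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  }
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- paste0("M", seq_len(ncol(dosage)))
  }
  if (is.null(map)) {
    map <- tibble::tibble(
      marker_id = colnames(dosage),
      chrom = 1L,
      pos = seq_len(ncol(dosage))
    )
  }
  stopifnot(all(c("marker_id", "chrom", "pos") %in% names(map)))
  if (!identical(as.character(map$marker_id), colnames(dosage))) {
    stop("map$marker_id must match the dosage column names, in order")
  }
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop("dosage entries must be 0, 1, 2 or NA")
  if (any(map$pos < 0)) stop("positions must be >= 0")
  ok_sorted <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = !is.unsorted(.data$pos, strictly = FALSE)) |>
    dplyr::pull(.data$ok)
  if (!all(ok_sorted)) stop("positions must be sorted within chromosome")
  if (!is.null(groups)) {
    groups <- groups[rownames(dosage)]
    if (anyNA(groups)) stop("groups must be named by sample id and cover all samples")
  }
  structure(
    list(dosage = dosage, map = tibble::as_tibble(map), role = role,
         groups = groups),
    class = "geno"
  )
}

#' @export
print.geno <- function(x, ...) {
  cat(sprintf(
    "<geno: %d %s x %d markers on %d chromosome(s); %.2f%% missing>\n",
    nrow(x$dosage), x$role, ncol(x$dosage),
    dplyr::n_distinct(x$map$chrom),
    100 * mean(is.na(x$dosage))
  ))
  invisible(x)
}

#' @export
dim.geno <- function(x) dim(x$dosage)

#' Subset a genotype object by samples and/or markers
#'
#' @param g a [geno] object.
#' @param samples sample ids or indices to keep (default all).
#' @param markers marker ids or indices to keep (default all).
#' @return A [geno] object.
#' @export
geno_subset <- function(g, samples = NULL, markers = NULL) {
  d <- g$dosage
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  if (!is.null(markers)) d <- d[, markers, drop = FALSE]
  map <- g$map[match(colnames(d), g$map$marker_id), ]
  grp <- if (is.null(g$groups)) NULL else g$groups[rownames(d)]
  geno(d, map, role = g$role, groups = grp)
}

#' Per-marker summary statistics
#'
#' Call rate, allele frequency of the dosage-2 allele, minor allele frequency,
#' observed heterozygosity and (for complete data) the 1-df Hardy-Weinberg
#' chi-square p-value.
#'
#' @param g a [geno] object.
#' @return A tibble with one row per marker.
#' @export
marker_stats <- function(g) {
  d <- g$dosage
  n <- nrow(d)
  call_rate <- colMeans(!is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  het <- colMeans(d == 1, na.rm = TRUE)
  hwe_p <- if (anyNA(d)) rep(NA_real_, ncol(d)) else hwe_test(g)$p_hwe
  tibble::tibble(
    marker_id = colnames(d), chrom = g$map$chrom, pos = g$map$pos,
    call_rate = unname(call_rate), freq = unname(p), maf = unname(maf),
    het = unname(het), hwe_p = unname(hwe_p)
  )
}

#' Read genotypes from a dosage TSV plus a marker map
#'
#' The dosage file is markers x samples: first column `marker_id`, remaining
#' columns one per sample, entries 0/1/2 or NA. The map file has columns
#' `marker_id`, `chrom`, `pos`.
#'
#' @param dosage_file,map_file paths to tab-separated files.
#' @inheritParams geno
#' @return A [geno] object.
#' @export
read_geno_tsv <- function(dosage_file, map_file,
                          role = c("parents", "hybrids")) {
  dos <- utils::read.delim(dosage_file, check.names = FALSE)
  map <- tibble::as_tibble(utils::read.delim(map_file, check.names = FALSE))
  m <- as.matrix(dos[, -1, drop = FALSE])
  rownames(m) <- dos[[1]]
  m <- t(m)                                   # samples x markers
  map <- map[match(colnames(m), map$marker_id), ]
  geno(m, map, role = match.arg(role))
}

#' Write genotypes as a dosage TSV plus marker map TSV
#'
#' @param g a [geno] object.
#' @param dosage_file,map_file output paths.
#' @return Invisibly, the file paths.
#' @export
write_geno_tsv <- function(g, dosage_file, map_file) {
  out <- data.frame(marker_id = colnames(g$dosage), t(g$dosage),
                    check.names = FALSE)
  utils::write.table(out, dosage_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(g$map, map_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(dosage_file, map_file))
}

#' Read genotypes from a VCF
#'
#' Converts the GT field to dosages (count of ALT alleles); biallelic sites
#' only. Multiallelic records are dropped with a message.
#'
#' @param file path to a VCF (uncompressed or bgzipped).
#' @inheritParams geno
#' @return A [geno] object.
#' @export
read_geno_vcf <- function(file, role = c("parents", "hybrids")) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  biallelic <- !grepl(",", vcfR::getALT(v), fixed = TRUE)
  if (!all(biallelic)) {
    message(sum(!biallelic), " multiallelic record(s) dropped")
    v <- v[biallelic, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    ifelse(is.na(x) | x %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(gsub("\\|", "/", x), "/", fixed = FALSE),
                  function(a) sum(a == "1"), numeric(1)))
  }
  dos <- apply(gt, 2, count_alt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = nrow(gt),
                                       dimnames = dimnames(gt))
  ids <- vcfR::getID(v)
  ids[is.na(ids)] <- paste0(vcfR::getCHROM(v), "_", vcfR::getPOS(v))[is.na(ids)]
  rownames(dos) <- ids
  map <- tibble::tibble(marker_id = ids,
                        chrom = vcfR::getCHROM(v),
                        pos = vcfR::getPOS(v))
  ord <- order(map$chrom, map$pos)
  geno(t(dos)[, ord, drop = FALSE], map[ord, ], role = match.arg(role))
}

#' Additive ({-1,0,1}) marker coding
#'
#' @param dosage dosage matrix (samples x markers) or [geno] object.
#' @return Numeric matrix, dosage minus one.
#' @export
code_additive <- function(dosage) {
  if (inherits(dosage, "geno")) dosage <- dosage$dosage
  dosage - 1
}

#' Dominance ({0,1,0}) marker coding
#'
#' Heterozygote indicator: aa = 0, Aa = 1, AA = 0.
#'
#' @inheritParams code_additive
#' @return Numeric 0/1 matrix.
#' @export
code_dominance <- function(dosage) {
  if (inherits(dosage, "geno")) dosage <- dosage$dosage
  (dosage == 1) * 1
}
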