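#' Genotype matrix of minor-allele counts
#'
#' The network input representation: an `n x m` integer matrix of
#' minor-allele counts (0/1/2) for unphased diploid data, or a `2n x m`
#' matrix of 0/1 haplotypes (two adjacent rows per individual) when phased.
#' Columns are SNPs ordered by strictly increasing genomic position.
#'
#' @param counts Integer matrix of allele counts.
#' @param positions Strictly increasing genomic positions, one per column.
#' @param sample_ids Character vector of sample identifiers (`nrow(counts)`
#'   for unphased data, `nrow(counts) / 2` for phased).
#' @param phased Logical flag.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(counts, positions, sample_ids, phased = FALSE) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  vals <- if (phased) 0:1 else 0:2
  if (!all(counts %in% vals)) {
    abort_config(sprintf(
      "Genotype entries must be in {%s} for %s data.",
      paste(vals, collapse = ","), if (phased) "phased" else "unphased"
    ))
  }
  if (length(positions) != ncol(counts)) {
    abort_config("`positions` must have one entry per SNP column.")
  }
  if (ncol(counts) > 1 && any(diff(positions) <= 0)) {
    abort_config("`positions` must be strictly increasing.")
  }
  n <- if (phased) nrow(counts) / 2L else nrow(counts)
  if (length(sample_ids) != n) {
    abort_config(sprintf("Expected %d sample ids, got %d.", n, length(sample_ids)))
  }
  structure(
    list(
      counts = counts,
      positions = as.numeric(positions),
      sample_ids = as.character(sample_ids),
      phased = isTRUE(phased)
    ),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs (%s)\n",
              length(x$sample_ids), ncol(x$counts),
              if (x$phased) "phased 0/1" else "unphased 0/1/2"))
  invisible(x)
}

#' Number of samples / SNPs in a genotype matrix
#' @param g A [genotype_matrix()].
#' @return Integer count.
#' @export
n_samples <- function(g) length(g$sample_ids)

#' @rdname n_samples
#' @export
n_snps <- function(g) ncol(g$counts)

#' Read a VCF into a minor-allele-count genotype matrix
#'
#' Parses biallelic SNP records from a VCF file (multiallelic or non-SNP
#' records are skipped with a warning) and encodes each site as counts of
#' its minor allele. When the ALT allele frequency exceeds 0.5 the REF
#' allele is counted instead; at a frequency of exactly 0.5 the ALT allele
#' is kept (deterministic, VCF-native tie rule). Sites with more than 10%
#' missing genotypes are dropped; remaining missing entries are imputed to
#' the rounded per-site mean count, with a message reporting how many.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param phased Return per-haplotype 0/1 rows; requires all genotypes to
#'   use the `|` separator.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, phased = FALSE) {
  if (!file.exists(path)) {
    abort_runtime(sprintf("VCF file not found: %s", path),
                  class = "dispersr_error_io")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1L & nchar(alt) == 1L
  n_skipped <- sum(!biallelic)
  if (n_skipped > 0) {
    warn(sprintf("Skipped %d non-biallelic-SNP record(s).", n_skipped))
  }
  if (!any(biallelic)) {
    abort_runtime("No biallelic SNP records in VCF.",
                  class = "dispersr_error_empty_input")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  pos <- as.numeric(fix[biallelic, "POS"])
  samples <- colnames(gt)

  if (phased && any(grepl("/", gt[!is.na(gt)], fixed = TRUE))) {
    abort_config("phased = TRUE but the VCF contains '/' separated genotypes.")
  }
  first <- substr(gt, 1L, 1L)
  third <- substr(gt, 3L, 3L)
  if (any(nchar(gt[!is.na(gt)]) != 3L)) {
    abort_config("Only diploid genotypes (two alleles per call) are supported.",
                 class = "dispersr_error_ploidy")
  }
  a1 <- suppressWarnings(as.integer(first))
  a2 <- suppressWarnings(as.integer(third))
  dim(a1) <- dim(a2) <- dim(gt)
  if (any(!is.na(a1) & a1 > 1L) || any(!is.na(a2) & a2 > 1L)) {
    abort_config("Allele indices > 1 found in a record marked biallelic.")
  }

  # per-site ordering; VCFs are expected position-sorted but we enforce it
  ord <- order(pos)
  dup <- duplicated(pos[ord])
  if (any(dup)) {
    warn(sprintf("Dropped %d record(s) with duplicated positions.", sum(dup)))
    ord <- ord[!dup]
  }
  a1 <- a1[ord, , drop = FALSE]
  a2 <- a2[ord, , drop = FALSE]
  pos <- pos[ord]

  miss <- is.na(a1) | is.na(a2)
  miss_frac <- rowMeans(miss)
  keep <- miss_frac <= 0.10
  if (any(!keep)) {
    warn(sprintf("Dropped %d site(s) with > 10%% missing genotypes.", sum(!keep)))
  }
  if (!any(keep)) {
    abort_runtime("No sites left after missingness filtering.",
                  class = "dispersr_error_empty_input")
  }
  a1 <- a1[keep, , drop = FALSE]
  a2 <- a2[keep, , drop = FALSE]
  pos <- pos[keep]
  miss <- miss[keep, , drop = FALSE]

  # polarization on ALT dosage, computed from non-missing calls
  alt_count <- rowSums(a1, na.rm = TRUE) + rowSums(a2, na.rm = TRUE)
  n_called <- 2L * rowSums(!miss)
  flip <- alt_count / n_called > 0.5
  a1[flip, ] <- 1L - a1[flip, , drop = FALSE]
  a2[flip, ] <- 1L - a2[flip, , drop = FALSE]

  n_missing <- sum(miss)
  if (n_missing > 0) {
    inform(sprintf("Imputed %d missing genotype call(s) to per-site means.",
                   n_missing))
  }
  if (phased) {
    hap <- matrix(0L, ncol(a1) * 2L, nrow(a1))
    hap[seq(1L, nrow(hap), 2L), ] <- t(a1)
    hap[seq(2L, nrow(hap), 2L), ] <- t(a2)
    if (n_missing > 0) {
      site_mean <- round(colMeans(hap, na.rm = TRUE))
      na_idx <- which(is.na(hap), arr.ind = TRUE)
      hap[na_idx] <- as.integer(site_mean[na_idx[, 2]])
    }
    return(genotype_matrix(hap, pos, samples, phased = TRUE))
  }
  dosage <- t(a1 + a2) # samples x SNPs
  if (n_missing > 0) {
    site_mean <- round(colMeans(dosage, na.rm = TRUE))
    na_idx <- which(is.na(dosage), arr.ind = TRUE)
    dosage[na_idx] <- as.integer(site_mean[na_idx[, 2]])
  }
  genotype_matrix(dosage, pos, samples, phased = FALSE)
}

#' Read a per-sample coordinate table
#'
#' Reads a delimited text table (comma, tab or whitespace separated) with
#' one row per sample: two numeric coordinate columns and an optional id
#' column. When `sample_ids` is given, rows are aligned to that order (by id
#' if an id column is present, by row order otherwise) and mismatches are
#' errors. With `lonlat = TRUE` the two columns are interpreted as latitude
#' and longitude in degrees and projected to planar kilometres with
#' [project_coordinates()].
#'
#' @param path Text file path.
#' @param sample_ids Optional character vector (e.g. from a VCF) the table
#'   must align to.
#' @param lonlat Interpret the numeric columns as (latitude, longitude).
#' @return A tibble with `sample_id`, `x`, `y` (and `raw_lat`, `raw_long`
#'   when `lonlat = TRUE`).
#' @export
read_locations <- function(path, sample_ids = NULL, lonlat = FALSE) {
  if (!file.exists(path)) {
    abort_runtime(sprintf("Locations file not found: %s", path),
                  class = "dispersr_error_io")
  }
  first_line <- readLines(path, n = 1L)
  delim <- if (grepl(",", first_line)) "," else NULL
  tab <- if (is.null(delim)) {
    readr::read_table(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                      progress = FALSE)
  } else {
    readr::read_delim(path, delim = delim, col_names = FALSE,
                      col_types = readr::cols(.default = "c"),
                      trim_ws = TRUE, progress = FALSE)
  }
  # drop a header row if its would-be coordinates are not numeric
  num1 <- suppressWarnings(as.numeric(unlist(tab[1, ])))
  if (sum(!is.na(num1)) < 2L && nrow(tab) > 1L) tab <- tab[-1L, , drop = FALSE]

  is_num <- vapply(tab, function(col) all(!is.na(suppressWarnings(as.numeric(col)))),
                   logical(1))
  if (sum(is_num) < 2L) {
    abort_config("Locations table needs two numeric coordinate columns.",
                 class = "dispersr_error_parse")
  }
  num_cols <- which(is_num)[1:2]
  id_col <- setdiff(seq_along(tab), num_cols)[1]
  ids <- if (!is.na(id_col)) as.character(tab[[id_col]]) else NULL

  c1 <- as.numeric(tab[[num_cols[1]]])
  c2 <- as.numeric(tab[[num_cols[2]]])

  if (!is.null(sample_ids)) {
    if (!is.null(ids)) {
      pos <- match(sample_ids, ids)
      if (anyNA(pos)) {
        abort_config(sprintf(
          "Locations table is missing sample id(s): %s",
          paste(utils::head(sample_ids[is.na(pos)], 5), collapse = ", ")
        ), class = "dispersr_error_alignment")
      }
      c1 <- c1[pos]; c2 <- c2[pos]; ids <- ids[pos]
    } else {
      if (length(c1) != length(sample_ids)) {
        abort_config(sprintf(
          "Locations table has %d rows but %d samples were expected.",
          length(c1), length(sample_ids)
        ), class = "dispersr_error_alignment")
      }
      ids <- sample_ids
    }
  } else if (is.null(ids)) {
    ids <- as.character(seq_along(c1))
  }

  if (lonlat) {
    proj <- project_coordinates(c1, c2)
    tibble::tibble(sample_id = ids, x = proj$x, y = proj$y,
                   raw_lat = c1, raw_long = c2)
  } else {
    tibble::tibble(sample_id = ids, x = c1, y = c2)
  }
}

#' Project latitude/longitude onto a local flat surface
#'
#' Equirectangular projection about a reference point (default: the sample
#' centroid): `x = R * cos(lat0) * (long - long0)`, `y = R * (lat - lat0)`
#' in radians, with Earth radius `R = 6371` km. Accurate to well under 1%
#' for sampling areas up to a few hundred kilometres, which covers the
#' spatial scale of dispersal studies.
#'
#' @param lat,long Numeric vectors of degrees; `abs(lat) <= 90`.
#' @param reference Optional `c(lat0, long0)`; defaults to the centroid.
#' @return A tibble with planar `x`, `y` in kilometres.
#' @examples
#' project_coordinates(c(0, 0), c(0, 1)) # ~111.32 km apart in x
#' @export
project_coordinates <- function(lat, long, reference = NULL) {
  if (any(!is.finite(lat)) || any(abs(lat) > 90)) {
    abort_config("Latitudes must be finite and within [-90, 90].",
                 class = "dispersr_error_coordinate")
  }
  if (any(!is.finite(long))) {
    abort_config("Longitudes must be finite.", class = "dispersr_error_coordinate")
  }
  if (is.null(reference)) reference <- c(mean(lat), mean(long))
  R <- 6371
  to_rad <- pi / 180
  tibble::tibble(
    x = R * cos(reference[1] * to_rad) * (long - reference[2]) * to_rad,
    y = R * (lat - reference[1]) * to_rad
  )
}

#' Uniformly subsample SNP columns
#'
#' Draws `m_target` columns without replacement, preserving genomic order.
#'
#' @param g A [genotype_matrix()].
#' @param m_target Number of SNPs to keep (`<= n_snps(g)`).
#' @param rng_seed Integer seed.
#' @return A [genotype_matrix()] with `m_target` columns.
#' @export
subsample_snps <- function(g, m_target, rng_seed = 1L) {
  stopifnot(inherits(g, "genotype_matrix"))
  check_number(m_target, "m_target", min = 1, integer = TRUE)
  m <- n_snps(g)
  if (m_target > m) {
    abort_runtime(sprintf("Requested %d SNPs but only %d are available.",
                          m_target, m),
                  class = "dispersr_error_too_few_snps")
  }
  keep <- sort(with_seed_(rng_seed, sample.int(m, m_target)))
  genotype_matrix(g$counts[, keep, drop = FALSE], g$positions[keep],
                  g$sample_ids, g$phased)
}

#' Euclidean distance between two samples
#'
#' @param loc A locations tibble with `x` and `y` columns.
#' @param i,j Row indices.
#' @return Planar Euclidean distance in map units.
#' @export
pair_distance <- function(loc, i, j) {
  n <- nrow(loc)
  if (any(c(i, j) < 1) || any(c(i, j) > n)) {
    abort_config(sprintf("Sample index out of range 1..%d.", n),
                 class = "dispersr_error_index")
  }
  sqrt((loc$x[i] - loc$x[j])^2 + (loc$y[i] - loc$y[j])^2)
}

# All pairwise distances in canonical pair order (internal).
all_pair_distances <- function(loc, pairs) {
  sqrt((loc$x[pairs[, 1]] - loc$x[pairs[, 2]])^2 +
         (loc$y[pairs[, 1]] - loc$y[pairs[, 2]])^2)
}
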