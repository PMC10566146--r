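write_toy_vcf <- function(path, records, samples = c("s1", "s2", "s3", "s4")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, records), path)
}

vcf_line <- function(pos, ref, alt, gts) {
  paste(c("1", pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

test_that("VCF dosages match an independent line-by-line parse", {
  path <- withr::local_tempfile(fileext = ".vcf")
  set.seed(5)
  gt_codes <- c("0/0", "0/1", "1/0", "1/1")
  lines <- character(10)
  raw_gt <- matrix("", 10, 4)
  for (i in 1:10) {
    raw_gt[i, ] <- sample(gt_codes, 4, replace = TRUE)
    lines[i] <- vcf_line(i * 100, "A", "G", raw_gt[i, ])
  }
  write_toy_vcf(path, lines)
  g <- read_vcf(path)
  # independent oracle: parse allele characters, count ALT, then fold to
  # the minor allele per site
  alt_dos <- apply(raw_gt, c(1, 2), function(s)
    as.integer(substr(s, 1, 1)) + as.integer(substr(s, 3, 3)))
  expected <- sapply(1:10, function(i) {
    d <- alt_dos[i, ]
    if (sum(d) / 8 > 0.5) 2L - d else d
  })
  expect_identical(unname(g$counts), expected)
  expect_equal(g$positions, (1:10) * 100)
  expect_equal(g$sample_ids, c("s1", "s2", "s3", "s4"))
})

test_that("a 0/0,0/1,1/1 site at the 0.5 tie keeps the ALT allele counted", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path, vcf_line(10, "A", "T", c("0/0", "0/1", "1/1")),
                samples = c("a", "b", "c"))
  g <- read_vcf(path)
  expect_identical(sort(as.vector(g$counts)), 0:2)
  expect_identical(as.vector(g$counts), c(0L, 1L, 2L)) # ALT dosage kept at tie
})

test_that("a high-frequency ALT is folded onto the REF allele", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path, vcf_line(10, "A", "T", c("1/1", "1/1", "0/1")),
                samples = c("a", "b", "c"))
  g <- read_vcf(path)
  expect_identical(as.vector(g$counts), c(0L, 0L, 1L)) # 2 - ALT dosage
})

test_that("multiallelic records are skipped and bad inputs error", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path, c(
    vcf_line(10, "A", "T", c("0/1", "0/0", "0/0")),
    vcf_line(20, "A", "T,G", c("0/1", "0/2", "0/0")),
    vcf_line(30, "AC", "A", c("0/1", "0/0", "0/0"))
  ), samples = c("a", "b", "c"))
  expect_warning(g <- read_vcf(path), "Skipped 2")
  expect_equal(n_snps(g), 1)

  expect_error(read_vcf(withr::local_tempfile(fileext = ".vcf")),
               class = "dispersr_error_io")

  only_bad <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(only_bad, vcf_line(10, "A", "T,G", c("0/1", "0/0", "0/0")),
                samples = c("a", "b", "c"))
  expect_error(suppressWarnings(read_vcf(only_bad)),
               class = "dispersr_error_empty_input")
})

test_that("missingness is filtered per site and imputed per entry", {
  many <- paste0("t", 1:12)
  path <- withr::local_tempfile(fileext = ".vcf")
  # site 1: one missing call of 12 (8% -> imputed); site 2: 3 of 12 (25% -> dropped)
  write_toy_vcf(path, c(
    vcf_line(10, "A", "T", c("./.", rep("0/1", 6), rep("0/0", 5))),
    vcf_line(20, "A", "T", c("./.", "./.", "./.", rep("0/1", 9)))
  ), samples = many)
  expect_warning(expect_message(g <- read_vcf(path), "Imputed 1"), "Dropped 1")
  expect_equal(n_snps(g), 1)
  # imputed entry equals the rounded per-site mean minor-allele count
  expect_equal(g$counts[1, 1], round(mean(c(rep(1, 6), rep(0, 5)))))
})

test_that("phased reading returns haplotype rows and enforces separators", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path, c(
    vcf_line(10, "A", "T", c("0|1", "1|0", "0|0")),
    vcf_line(20, "C", "G", c("1|1", "0|1", "0|0"))
  ), samples = c("a", "b", "c"))
  g <- read_vcf(path, phased = TRUE)
  expect_true(g$phased)
  expect_equal(dim(g$counts), c(6L, 2L))
  expect_identical(g$counts[, 1], c(0L, 1L, 1L, 0L, 0L, 0L))
  unph <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(unph, vcf_line(10, "A", "T", c("0/1", "1|0", "0|0")),
                samples = c("a", "b", "c"))
  expect_error(read_vcf(unph, phased = TRUE), class = "dispersr_error_config")
})

test_that("locations tables align to VCF sample order by id or row order", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("s3 1.5 2.5", "s1 0.5 0.25", "s2 3 4"), path)
  loc <- read_locations(path, sample_ids = c("s1", "s2", "s3"))
  expect_equal(loc$sample_id, c("s1", "s2", "s3"))
  expect_equal(loc$x, c(0.5, 3, 1.5))
  expect_equal(loc$y, c(0.25, 4, 2.5))

  # comma separated, no ids: aligned by row order
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y", "1,2", "3,4"), p2)
  loc2 <- read_locations(p2, sample_ids = c("a", "b"))
  expect_equal(loc2$sample_id, c("a", "b"))
  expect_equal(loc2$x, c(1, 3))

  # row-count mismatch
  expect_error(read_locations(p2, sample_ids = c("a", "b", "c")),
               class = "dispersr_error_alignment")
  # missing id
  expect_error(read_locations(path, sample_ids = c("s1", "s9", "s3")),
               class = "dispersr_error_alignment")
})

test_that("equirectangular projection matches great-circle oracles locally", {
  # the reference point maps to the origin
  p0 <- project_coordinates(45, -120, reference = c(45, -120))
  expect_equal(p0$x, 0)
  expect_equal(p0$y, 0)
  # one degree of longitude at the equator: 2 pi R / 360 with R = 6371
  p1 <- project_coordinates(c(0, 0), c(0, 1), reference = c(0, 0))
  expect_equal(p1$x[2], 2 * pi * 6371 / 360, tolerance = 1e-6)
  expect_equal(p1$y[2], 0)

  # planar distances agree with the haversine within 1% under 100 km
  haversine <- function(lat1, lon1, lat2, lon2) {
    to_rad <- pi / 180
    dphi <- (lat2 - lat1) * to_rad
    dlmb <- (lon2 - lon1) * to_rad
    a <- sin(dphi / 2)^2 +
      cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlmb / 2)^2
    2 * 6371 * asin(sqrt(a))
  }
  set.seed(3)
  lat <- 44 + runif(20, 0, 0.6)
  lon <- 7 + runif(20, 0, 0.6)
  proj <- project_coordinates(lat, lon)
  for (k in 2:20) {
    planar <- sqrt((proj$x[k] - proj$x[1])^2 + (proj$y[k] - proj$y[1])^2)
    gc <- haversine(lat[1], lon[1], lat[k], lon[k])
    expect_lt(abs(planar - gc) / gc, 0.01)
  }
  expect_error(project_coordinates(91, 0), class = "dispersr_error_coordinate")
})

test_that("SNP subsampling preserves order and is seed-reproducible", {
  g <- make_toy_dataset(4, 40, seed = 2)$genotypes
  expect_identical(subsample_snps(g, 40, rng_seed = 1)$counts, g$counts)
  s1 <- subsample_snps(g, 13, rng_seed = 5)
  s2 <- subsample_snps(g, 13, rng_seed = 5)
  expect_identical(s1$counts, s2$counts)
  expect_true(all(diff(s1$positions) > 0))
  expect_true(all(s1$positions %in% g$positions))
  one <- subsample_snps(g, 1, rng_seed = 2)
  expect_equal(n_snps(one), 1)
  expect_error(subsample_snps(g, 41), class = "dispersr_error_too_few_snps")
})

test_that("pair distances are Euclidean, symmetric and translation-invariant", {
  loc <- tibble::tibble(sample_id = c("a", "b"), x = c(0, 3), y = c(0, 4))
  expect_equal(pair_distance(loc, 1, 2), 5)
  expect_equal(pair_distance(loc, 2, 1), 5)
  expect_equal(pair_distance(loc, 1, 1), 0)
  shifted <- dplyr::mutate(loc, x = x + 11.3, y = y - 2.7)
  expect_equal(pair_distance(shifted, 1, 2), 5)
  expect_error(pair_distance(loc, 1, 3), class = "dispersr_error_index")
})

test_that("genotype matrices validate encoding and positions", {
  expect_error(
    genotype_matrix(matrix(3L, 2, 2), c(1, 2), c("a", "b")),
    class = "dispersr_error_config"
  )
  expect_error(
    genotype_matrix(matrix(0L, 2, 2), c(2, 2), c("a", "b")),
    class = "dispersr_error_config"
  )
  expect_error(
    genotype_matrix(matrix(0L, 2, 2), c(1, 2), c("a", "b", "c")),
    class = "dispersr_error_config"
  )
})
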