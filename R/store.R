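#' Binary training-dataset store
#'
#' Training datasets (genotypes, locations, true sigma) are written to a
#' single little-endian binary file so they can be streamed efficiently
#' during training. The layout is versioned:
#'
#' * header: magic `"DSPRSTOR"` (8 bytes), `version`, `n`, `m`, `count`,
#'   `phased` (int32 each), `habitat_width` (float64);
#' * per record: record byte length (int32), `sigma_true`, `sigma_f`
#'   (float64), `m` positions (float64), `n` x-coordinates then `n`
#'   y-coordinates (float64), the genotype matrix row-major as uint8, and
#'   `n` length-prefixed UTF-8 sample ids.
#'
#' All records must share the same `n`, `m` and phasing. The round trip
#' `read_store(write_store(...)$path)` reproduces every record exactly.
#'
#' @param records List of `dispersal_dataset` objects (or lists with
#'   `genotypes`, `locations`, `sigma_true`, `sigma_f`).
#' @param path Output file path.
#' @param habitat_width Habitat width recorded in the header (used to scale
#'   pair distances during training).
#' @return A `dataset_store`: list with `path`, `n`, `m`, `count`, `phased`,
#'   `habitat_width` and the `records` themselves.
#' @export
write_store <- function(records, path, habitat_width = NA_real_) {
  if (length(records) > 0) {
    n <- length(records[[1]]$genotypes$sample_ids)
    m <- n_snps(records[[1]]$genotypes)
    phased <- records[[1]]$genotypes$phased
    for (r in records) {
      g <- r$genotypes
      if (length(g$sample_ids) != n || n_snps(g) != m || g$phased != phased) {
        abort_config("All records in a store must share the same n, m and phasing.")
      }
    }
  } else {
    n <- 0L; m <- 0L; phased <- FALSE
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("DSPRSTOR"), con)
  writeBin(c(1L, as.integer(n), as.integer(m), length(records),
             as.integer(phased)), con, size = 4L, endian = "little")
  writeBin(as.double(habitat_width), con, size = 8L, endian = "little")
  for (r in records) {
    payload <- serialize_record(r, n, m)
    writeBin(length(payload), con, size = 4L, endian = "little")
    writeBin(payload, con)
  }
  store <- structure(
    list(path = path, n = as.integer(n), m = as.integer(m),
         count = length(records), phased = phased,
         habitat_width = habitat_width, records = records),
    class = "dataset_store"
  )
  invisible(store)
}

serialize_record <- function(r, n, m) {
  g <- r$genotypes
  ids <- g$sample_ids
  id_raw <- lapply(ids, function(s) {
    b <- charToRaw(enc2utf8(s))
    c(writeBin(length(b), raw(), size = 4L, endian = "little"), b)
  })
  c(
    writeBin(as.double(c(r$sigma_true, r$sigma_f, g$positions,
                         r$locations$x, r$locations$y)),
             raw(), size = 8L, endian = "little"),
    as.raw(as.vector(t(g$counts))),
    unlist(id_raw)
  )
}

#' @rdname write_store
#' @export
read_store <- function(path) {
  if (!file.exists(path)) {
    abort_runtime(sprintf("Store file not found: %s", path),
                  class = "dispersr_error_io")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (!identical(magic, charToRaw("DSPRSTOR"))) {
    abort_runtime("Not a dispersr dataset store (bad magic bytes).",
                  class = "dispersr_error_integrity")
  }
  hdr <- readBin(con, "integer", 5L, size = 4L, endian = "little")
  if (length(hdr) < 5L) {
    abort_runtime("Truncated store header.", class = "dispersr_error_integrity")
  }
  version <- hdr[1]
  if (version != 1L) {
    abort_runtime(sprintf("Unsupported store format version %d (expected 1).",
                          version),
                  class = "dispersr_error_version")
  }
  n <- hdr[2]; m <- hdr[3]; count <- hdr[4]; phased <- as.logical(hdr[5])
  habitat_width <- readBin(con, "double", 1L, size = 8L, endian = "little")
  records <- vector("list", count)
  offset <- 8L + 5L * 4L + 8L
  for (k in seq_len(count)) {
    len <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(len) < 1L) {
      abort_runtime(
        sprintf("Store truncated at byte offset %d (record %d of %d).",
                offset, k, count),
        class = "dispersr_error_integrity"
      )
    }
    payload <- readBin(con, "raw", len)
    if (length(payload) < len) {
      abort_runtime(
        sprintf("Store truncated at byte offset %d (record %d of %d).",
                offset + 4L, k, count),
        class = "dispersr_error_integrity"
      )
    }
    records[[k]] <- deserialize_record(payload, n, m, phased)
    offset <- offset + 4L + len
  }
  structure(
    list(path = path, n = n, m = m, count = count, phased = phased,
         habitat_width = habitat_width, records = records),
    class = "dataset_store"
  )
}

deserialize_record <- function(payload, n, m, phased) {
  n_rows <- if (phased) 2L * n else n
  pos <- 1L
  take_dbl <- function(k) {
    out <- readBin(payload[pos:(pos + 8L * k - 1L)], "double", k,
                   size = 8L, endian = "little")
    pos <<- pos + 8L * k
    out
  }
  head <- take_dbl(2L + m + 2L * n)
  sigma_true <- head[1]
  sigma_f <- head[2]
  positions <- head[2L + seq_len(m)]
  x <- head[2L + m + seq_len(n)]
  y <- head[2L + m + n + seq_len(n)]
  counts <- matrix(as.integer(payload[pos:(pos + n_rows * m - 1L)]),
                   nrow = n_rows, ncol = m, byrow = TRUE)
  pos <- pos + n_rows * m
  ids <- character(n)
  for (i in seq_len(n)) {
    nb <- readBin(payload[pos:(pos + 3L)], "integer", 1L, size = 4L,
                  endian = "little")
    pos <- pos + 4L
    ids[i] <- rawToChar(payload[pos:(pos + nb - 1L)])
    pos <- pos + nb
  }
  structure(
    list(
      genotypes = genotype_matrix(counts, positions, ids, phased),
      locations = tibble::tibble(sample_id = ids, x = x, y = y),
      sigma_true = sigma_true,
      sigma_f = sigma_f
    ),
    class = "dispersal_dataset"
  )
}

#' @export
print.dataset_store <- function(x, ...) {
  cat(sprintf("<dataset_store> %d dataset(s), n = %d, m = %d, %s\n",
              x$count, x$n, x$m, if (x$phased) "phased" else "unphased"))
  cat(sprintf("  path: %s\n", x$path))
  invisible(x)
}

#' True sigma labels of a store
#' @param store A `dataset_store`.
#' @return Numeric vector of `sigma_true` labels, one per record.
#' @export
store_labels <- function(store) {
  vapply(store$records, function(r) r$sigma_true, numeric(1))
}
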