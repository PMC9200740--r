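#' Read a chromosome-sizes table
#'
#' Parses a two-column whitespace-separated file of chromosome name and
#' length in base pairs (UCSC `chrom.sizes` convention).
#'
#' @param path Path to the chrom.sizes file.
#' @param sex_chroms Character vector of chromosome names treated as sex
#'   chromosomes (used to partition X vs autosomes downstream).
#' @return A tibble with columns `name`, `length`, `is_sex`.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("chr1 195471971", "chrX 171031299"), f)
#' read_chromsizes(f)
read_chromsizes <- function(path, sex_chroms = c("chrX", "chrY", "X", "Y")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort("no chromosomes in chrom.sizes file")
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(map_int(fields, length) < 2L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed chrom.sizes line %d: %s", bad[1], lines[bad[1]]))
  }
  name <- map_chr_(fields, 1L)
  len <- suppressWarnings(as.numeric(map_chr_(fields, 2L)))
  bad <- which(is.na(len) | len <= 0)
  if (length(bad) > 0L) {
    abort(sprintf("malformed chrom.sizes line %d: non-positive or non-numeric length", bad[1]))
  }
  if (anyDuplicated(name)) {
    abort(sprintf("duplicate chromosome name: %s", name[duplicated(name)][1]))
  }
  chromsizes(setNames(len, name), sex_chroms = sex_chroms)
}

map_chr_ <- function(x, i) vapply(x, `[[`, character(1), i)

#' Build a chromosome-sizes table from a named vector
#'
#' @param sizes Named numeric vector of chromosome lengths (bp).
#' @inheritParams read_chromsizes
#' @return A tibble with columns `name`, `length`, `is_sex`.
#' @export
chromsizes <- function(sizes, sex_chroms = c("chrX", "chrY", "X", "Y")) {
  stopifnot(!is.null(names(sizes)), all(sizes > 0))
  if (anyDuplicated(names(sizes))) abort("duplicate chromosome names")
  tibble(
    name = names(sizes),
    length = as.numeric(sizes),
    is_sex = names(sizes) %in% sex_chroms
  )
}

#' Tile chromosomes into fixed-width bins
#'
#' Produces the genome-wide bin table used by all binned analyses. Bins are
#' 0-based half-open; the last bin of each chromosome may be short.
#'
#' @param sizes Chromosome-sizes tibble from [chromsizes()] or
#'   [read_chromsizes()].
#' @param bin_size Bin width in base pairs (e.g. 25000 for compartments,
#'   10000 for loops/interactions).
#' @return A tibble with columns `bin_id` (1-based, genome-wide), `chrom`,
#'   `start`, `end`; attribute `bin_size` records the width.
#' @export
make_bins <- function(sizes, bin_size) {
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0) {
    abort("bin_size must be a single positive number")
  }
  per_chrom <- map2(sizes$name, sizes$length, function(nm, len) {
    starts <- seq(0, len - 1, by = bin_size)
    tibble(chrom = nm, start = starts, end = pmin(starts + bin_size, len))
  })
  bins <- list_rbind(per_chrom)
  bins <- mutate(bins, bin_id = row_number(), .before = 1)
  attr(bins, "bin_size") <- bin_size
  attr(bins, "chromsizes") <- sizes
  bins
}

bin_size_of <- function(bins) {
  bs <- attr(bins, "bin_size")
  if (is.null(bs)) bs <- max(bins$end - bins$start)
  bs
}

#' Locate genomic positions in a bin table
#'
#' @param bins Bin table from [make_bins()].
#' @param chrom,pos Vectors of chromosome names and 0-based positions.
#' @return Integer vector of `bin_id`s (NA where outside the assembly).
#' @export
locate_bin <- function(bins, chrom, pos) {
  bs <- bin_size_of(bins)
  key <- paste0(bins$chrom, ":", bins$start %/% bs)
  idx <- match(paste0(chrom, ":", pos %/% bs), key)
  out <- bins$bin_id[idx]
  out[!is.na(idx) & (pos < 0)] <- NA_integer_
  out
}

#' Read a BED file of intervals
#'
#' Accepts BED3 and BED6 (name/score/strand columns optional). Coordinates
#' stay 0-based half-open.
#'
#' @param path Path to the BED file.
#' @param sizes Optional chromosome-sizes tibble; when supplied, records on
#'   unknown chromosomes are dropped with a message (`strict = FALSE`) or
#'   raise an error (`strict = TRUE`).
#' @param strict Error on unknown chromosomes instead of dropping them.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path, sizes = NULL, strict = FALSE) {
  raw <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = "character", quote = "",
                    col.names = paste0("V", 1:6), fill = TRUE)
  x <- tibble(
    chrom = raw$V1,
    start = as.numeric(raw$V2),
    end = as.numeric(raw$V3),
    name = ifelse(is.na(raw$V4) | raw$V4 == "", ".", raw$V4),
    score = suppressWarnings(as.numeric(raw$V5)),
    strand = ifelse(raw$V6 %in% c("+", "-"), raw$V6, ".")
  )
  if (any(is.na(x$start) | is.na(x$end))) abort("malformed BED coordinates")
  if (any(x$start >= x$end)) abort("BED interval with start >= end")
  if (any(x$start < 0)) abort("negative BED start")
  if (!is.null(sizes)) {
    unknown <- !(x$chrom %in% sizes$name)
    if (any(unknown)) {
      if (strict) abort(sprintf("interval on unknown chromosome: %s", x$chrom[unknown][1]))
      inform(sprintf("dropping %d interval(s) on unknown chromosomes", sum(unknown)))
      x <- x[!unknown, , drop = FALSE]
    }
  }
  x
}

#' Write intervals to BED
#'
#' @param x Interval tibble (`chrom`, `start`, `end`, optional `name`,
#'   `score`, `strand`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  out <- data.frame(
    chrom = x$chrom,
    start = format(x$start, scientific = FALSE, trim = TRUE),
    end = format(x$end, scientific = FALSE, trim = TRUE),
    name = if ("name" %in% names(x)) x$name else ".",
    score = if ("score" %in% names(x)) ifelse(is.na(x$score), 0, x$score) else 0,
    strand = if ("strand" %in% names(x)) x$strand else "."
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write paired anchors (loops/interactions) to BEDPE
#'
#' Any columns beyond the six coordinates are appended after the standard
#' name/score/strand fields.
#'
#' @param x Tibble with `chrom1`, `start1`, `end1`, `chrom2`, `start2`,
#'   `end2` plus optional extra columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedpe <- function(x, path) {
  std <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  stopifnot(all(std %in% names(x)))
  extra <- setdiff(names(x), std)
  out <- as.data.frame(x[, c(std, extra)])
  for (cc in c("start1", "end1", "start2", "end2")) {
    out[[cc]] <- format(out[[cc]], scientific = FALSE, trim = TRUE)
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a per-bin track to bedGraph
#'
#' @param track Tibble with `chrom`, `start`, `end` and a value column.
#' @param path Output path.
#' @param value Name of the value column (default the fourth column).
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path, value = NULL) {
  value <- value %||% setdiff(names(track), c("chrom", "start", "end"))[1]
  out <- data.frame(
    chrom = track$chrom,
    start = format(track$start, scientific = FALSE, trim = TRUE),
    end = format(track$end, scientific = FALSE, trim = TRUE),
    value = track[[value]]
  )
  out <- out[!is.na(out$value), , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# --- interval arithmetic (IRanges-backed; chromosome-aware) ----------------

iranges_of <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)  # 1-based closed
}

#' Count overlapping intervals per query interval
#'
#' @param query,subject Interval tibbles (`chrom`, `start`, `end`).
#' @return Integer vector: for each query row, the number of subject
#'   intervals on the same chromosome that overlap it.
#' @export
count_overlaps <- function(query, subject) {
  out <- integer(nrow(query))
  for (cc in unique(query$chrom)) {
    qi <- which(query$chrom == cc)
    si <- which(subject$chrom == cc)
    if (length(si) == 0L) next
    out[qi] <- IRanges::countOverlaps(
      iranges_of(query[qi, ]), iranges_of(subject[si, ])
    )
  }
  out
}

#' Distance from interval edges to the nearest point
#'
#' Edge-to-point distance: 0 when the point falls inside the interval.
#' Used by the enhancer proxy rule (ATAC peak more than a cutoff away from
#' every TSS).
#'
#' @param x Interval tibble.
#' @param points Tibble with `chrom` and `pos` (0-based point).
#' @return Numeric vector of distances (Inf when the chromosome holds no
#'   point).
#' @export
nearest_point_distance <- function(x, points) {
  out <- rep(Inf, nrow(x))
  for (cc in unique(x$chrom)) {
    xi <- which(x$chrom == cc)
    pi <- which(points$chrom == cc)
    if (length(pi) == 0L) next
    ir <- iranges_of(x[xi, ])
    pr <- IRanges::IRanges(start = points$pos[pi] + 1L, width = 1L)
    d <- IRanges::distanceToNearest(ir, pr)
    dd <- rep(Inf, length(xi))
    dd[S4Vectors_queryHits(d)] <- S4Vectors_mcols_distance(d)
    out[xi] <- dd
  }
  out
}

# thin indirection so the S4 Hits accessors stay in one place
S4Vectors_queryHits <- function(h) S4Vectors::from(h)
S4Vectors_mcols_distance <- function(h) S4Vectors::mcols(h)$distance

#' Bookkeeping: genomic span of a set of flagged bins
#'
#' @param n_bins Number of flagged bins.
#' @param bin_size Bin width (bp).
#' @return Span in megabases.
#' @export
span_mb <- function(n_bins, bin_size) n_bins * bin_size / 1e6

#' Bookkeeping: percentage of a set overlapping another
#'
#' @param n_overlap Size of the overlap.
#' @param n_total Size of the reference set.
#' @return Percentage (0-100).
#' @export
overlap_percent <- function(n_overlap, n_total) {
  if (n_total <= 0) abort("n_total must be positive")
  100 * n_overlap / n_total
}
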