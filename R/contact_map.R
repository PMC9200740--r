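#' Construct a binned Hi-C contact map
#'
#' The container used by every matrix-level operation: a genome bin table
#' plus an upper-triangle pixel list of non-negative counts (cis and trans).
#' Symmetry is implicit — a pixel `(i, j, c)` with `i <= j` represents both
#' orientations.
#'
#' @param bins Bin table from [make_bins()].
#' @param pixels Tibble with `bin1`, `bin2` (genome-wide bin ids) and
#'   `count`. Pairs are symmetrized and duplicates summed.
#' @param weights Optional per-bin balancing weights (NA = filtered bin).
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(bins, pixels, weights = NULL) {
  stopifnot(all(c("bin1", "bin2", "count") %in% names(pixels)))
  if (nrow(pixels) > 0) {
    if (any(pixels$count < 0)) abort("negative contact count")
    bad <- pixels$bin1 < 1 | pixels$bin1 > nrow(bins) |
      pixels$bin2 < 1 | pixels$bin2 > nrow(bins)
    if (any(bad)) abort(sprintf("pixel %d references a bin out of range", which(bad)[1]))
    b1 <- pmin(pixels$bin1, pixels$bin2)
    b2 <- pmax(pixels$bin1, pixels$bin2)
    # base-R aggregation: the pixel lists are large and this runs per replicate
    o <- order(b1, b2)
    b1 <- b1[o]; b2 <- b2[o]; cnt0 <- pixels$count[o]
    new_grp <- c(TRUE, b1[-1] != b1[-length(b1)] | b2[-1] != b2[-length(b2)])
    cnt <- as.vector(rowsum(cnt0, cumsum(new_grp), reorder = TRUE))
    keep <- cnt > 0
    pixels <- tibble(bin1 = as.integer(b1[new_grp])[keep],
                     bin2 = as.integer(b2[new_grp])[keep],
                     count = cnt[keep])
  } else {
    pixels <- tibble(bin1 = integer(), bin2 = integer(), count = numeric())
  }
  structure(
    list(bins = bins, pixels = pixels, weights = weights,
         total = sum(pixels$count)),
    class = "contact_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d bins (%d chromosomes), %d pixels, %s contacts%s\n",
              nrow(x$bins), length(unique(x$bins$chrom)), nrow(x$pixels),
              format(x$total, big.mark = ","),
              if (is.null(x$weights)) "" else ", balanced"))
  invisible(x)
}

#' Tidy a contact map into its pixel table
#'
#' @param x A `contact_map`.
#' @param ... Unused.
#' @return A tibble of pixels with bin coordinates joined in.
#' @export
tidy.contact_map <- function(x, ...) {
  b <- x$bins |> select(bin_id, chrom, start)
  x$pixels |>
    left_join(rename(b, bin1 = bin_id, chrom1 = chrom, start1 = start), by = "bin1") |>
    left_join(rename(b, bin2 = bin_id, chrom2 = chrom, start2 = start), by = "bin2")
}

#' One-row summary of a contact map
#'
#' @param x A `contact_map`.
#' @param ... Unused.
#' @return A tibble with totals and the cis fraction.
#' @export
glance.contact_map <- function(x, ...) {
  tf <- trans_fraction(x)
  tibble(
    n_bins = nrow(x$bins), n_pixels = nrow(x$pixels),
    total_contacts = x$total,
    cis_fraction = tf$cis_fraction, trans_fraction = tf$trans_fraction,
    balanced = !is.null(x$weights)
  )
}

#' Load contacts from triplet text
#'
#' Reads whitespace-separated records `chrom1 start1 chrom2 start2 count`
#' where `start` is the 0-based bin start coordinate.
#'
#' @param path Path to the triplet file.
#' @param bins Bin table from [make_bins()].
#' @return A `contact_map`.
#' @export
load_contacts <- function(path, bins) {
  raw <- read.table(path, header = FALSE, colClasses = "character",
                    col.names = paste0("V", 1:5))
  b1 <- locate_bin(bins, raw$V1, as.numeric(raw$V2))
  b2 <- locate_bin(bins, raw$V3, as.numeric(raw$V4))
  cnt <- as.numeric(raw$V5)
  bad <- which(is.na(b1) | is.na(b2) | is.na(cnt) | cnt < 0)
  if (length(bad) > 0L) {
    abort(sprintf("record %d: unknown bin or bad count", bad[1]))
  }
  contact_map(bins, tibble(bin1 = b1, bin2 = b2, count = cnt))
}

#' Write a contact map as triplet text
#'
#' @param map A `contact_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_contacts <- function(map, path) {
  px <- tidy(map)
  out <- data.frame(px$chrom1, format(px$start1, scientific = FALSE, trim = TRUE),
                    px$chrom2, format(px$start2, scientific = FALSE, trim = TRUE),
                    px$count)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

chrom_bin_ids <- function(bins, chrom) bins$bin_id[bins$chrom == chrom]

#' Dense cis matrix for one chromosome
#'
#' @param map A `contact_map`.
#' @param chrom Chromosome name.
#' @param balanced Multiply counts by the balancing weights (requires
#'   [balance_map()] first). Filtered bins come back as NA rows/columns.
#' @return A symmetric dense matrix over the chromosome's bins.
#' @export
cis_matrix <- function(map, chrom, balanced = FALSE) {
  ids <- chrom_bin_ids(map$bins, chrom)
  if (length(ids) == 0L) abort(sprintf("unknown chromosome: %s", chrom))
  off <- min(ids) - 1L
  n <- length(ids)
  M <- matrix(0, n, n)
  px <- filter(map$pixels, .data$bin1 >= min(ids), .data$bin1 <= max(ids),
               .data$bin2 >= min(ids), .data$bin2 <= max(ids))
  if (nrow(px) > 0) {
    i <- px$bin1 - off; j <- px$bin2 - off
    M[cbind(i, j)] <- px$count
    M[cbind(j, i)] <- px$count
  }
  if (balanced) {
    if (is.null(map$weights)) abort("map is not balanced; call balance_map() first")
    w <- map$weights[ids]
    M <- M * outer(w, w)
  }
  M
}

cis_mask <- function(map, chrom) {
  ids <- chrom_bin_ids(map$bins, chrom)
  if (is.null(map$weights)) rep(TRUE, length(ids)) else !is.na(map$weights[ids])
}

#' Balance a contact map by iterative correction
#'
#' Computes per-bin multiplicative weights, per chromosome on the cis
#' matrix, such that row sums of the balanced matrix equalize across
#' non-filtered bins. Bins whose raw marginal is below `filter_frac` of the
#' chromosome's median positive marginal are filtered (weight NA). Weights
#' are rescaled so the balanced total equals the raw total, keeping the
#' balanced signal on a count-like scale.
#'
#' @param map A `contact_map`.
#' @param max_iter Maximum iterations (default 500).
#' @param tol Convergence tolerance on the coefficient of variation of the
#'   non-filtered margins (default 1e-6).
#' @param filter_frac Low-coverage filter as a fraction of the median
#'   positive marginal (default 0.02).
#' @return The map with `weights` filled in; attribute `converged` is a
#'   named logical per chromosome.
#' @export
balance_map <- function(map, max_iter = 500, tol = 1e-6, filter_frac = 0.02) {
  if (map$total == 0) abort("empty matrix: nothing to balance")
  w_all <- rep(NA_real_, nrow(map$bins))
  conv <- logical(0)
  for (cc in unique(map$bins$chrom)) {
    ids <- chrom_bin_ids(map$bins, cc)
    M <- cis_matrix(map, cc)
    marg <- rowSums(M)
    pos <- marg[marg > 0]
    keep <- marg > 0 & marg >= filter_frac * median(pos)
    conv_c <- FALSE
    if (sum(keep) >= 2) {
      A <- M[keep, keep, drop = FALSE]
      w <- rep(1, nrow(A))
      for (it in seq_len(max_iter)) {
        m <- as.vector(A %*% w) * w
        mu <- mean(m)
        if (mu == 0) break
        cv <- sd(m) / mu
        if (is.na(cv)) break
        if (cv < tol) { conv_c <- TRUE; break }
        w <- w / sqrt(m / mu)
      }
      # rescale so the balanced total matches the raw total on kept bins
      bal_tot <- as.numeric(t(w) %*% A %*% w)
      raw_tot <- sum(A)
      if (bal_tot > 0) w <- w * sqrt(raw_tot / bal_tot)
      w_all[ids[keep]] <- w
    }
    conv <- c(conv, setNames(conv_c, cc))
  }
  if (!all(conv)) {
    warn(sprintf("balancing did not converge for: %s",
                 paste(names(conv)[!conv], collapse = ", ")))
  }
  map$weights <- w_all
  attr(map, "converged") <- conv
  map
}

#' Mean signal per genomic distance
#'
#' For each chromosome and bin separation `d`, the mean signal over all
#' pairs of non-filtered bins at that separation (zeros included in the
#' mean; pairs touching filtered bins excluded).
#'
#' @param map A `contact_map`.
#' @param use_weights Compute on the balanced signal (default TRUE when the
#'   map carries weights).
#' @return A tibble with `chrom`, `d` (bin separation), `expected`,
#'   `n_pairs`; attribute `use_weights`.
#' @export
expected_by_distance <- function(map, use_weights = !is.null(map$weights)) {
  if (use_weights && is.null(map$weights)) abort("map has no weights")
  out <- list()
  for (cc in unique(map$bins$chrom)) {
    M <- cis_matrix(map, cc, balanced = use_weights)
    mask <- cis_mask(map, cc)
    n <- nrow(M)
    sums <- numeric(n); npairs <- numeric(n)
    for (d in 0:(n - 1)) {
      i <- seq_len(n - d)
      valid <- mask[i] & mask[i + d]
      npairs[d + 1] <- sum(valid)
      v <- M[cbind(i[valid], i[valid] + d)]
      sums[d + 1] <- sum(v, na.rm = TRUE)
    }
    out[[cc]] <- tibble(chrom = cc, d = 0:(n - 1),
                        expected = ifelse(npairs > 0, sums / npairs, NA_real_),
                        n_pairs = npairs)
  }
  res <- list_rbind(out)
  attr(res, "use_weights") <- use_weights
  res
}

#' Distance-normalized signal map
#'
#' Computes `z(i, j) = (observed + 1) / (expected + 1)` for every cis pair,
#' where `observed` is the balanced signal when the map carries weights
#' (raw counts otherwise) and `expected` is the per-distance mean from
#' [expected_by_distance()]. The result holds dense per-chromosome `z` and
#' raw-count matrices; filtered bins are NA.
#'
#' @param map A `contact_map`.
#' @param expected Optional precomputed expected profile (must match the
#'   map's bins and weighting flag).
#' @param use_weights Use balanced signal for observed/expected.
#' @return An object of class `dist_norm`.
#' @export
distance_normalize <- function(map, expected = NULL,
                               use_weights = !is.null(map$weights)) {
  if (map$total == 0) abort("empty matrix")
  if (is.null(expected)) {
    expected <- expected_by_distance(map, use_weights = use_weights)
  } else {
    if (!identical(attr(expected, "use_weights"), use_weights)) {
      abort("expected profile computed under a different weighting flag")
    }
    if (!setequal(unique(expected$chrom), unique(map$bins$chrom))) {
      abort("expected profile does not match the map's chromosomes")
    }
  }
  chroms <- unique(map$bins$chrom)
  z <- list(); obs <- list(); exp_vec <- list(); masks <- list()
  for (cc in chroms) {
    M <- cis_matrix(map, cc, balanced = use_weights)
    raw <- cis_matrix(map, cc, balanced = FALSE)
    mask <- cis_mask(map, cc)
    e <- expected$expected[expected$chrom == cc]
    n <- nrow(M)
    D <- abs(outer(seq_len(n), seq_len(n), "-"))
    E <- matrix(e[D + 1], n, n)
    Z <- (M + 1) / (E + 1)
    Z[!mask, ] <- NA; Z[, !mask] <- NA
    z[[cc]] <- Z; obs[[cc]] <- raw; exp_vec[[cc]] <- e; masks[[cc]] <- mask
  }
  structure(
    list(bins = map$bins, z = z, obs = obs, expected = exp_vec,
         mask = masks, total = map$total, use_weights = use_weights),
    class = "dist_norm"
  )
}

#' @export
print.dist_norm <- function(x, ...) {
  cat(sprintf("<dist_norm> %d chromosomes, %d bins, (obs+1)/(exp+1) on %s signal\n",
              length(x$z), nrow(x$bins),
              if (x$use_weights) "balanced" else "raw"))
  invisible(x)
}

#' Tidy a distance-normalized map into a long pixel table
#'
#' @param x A `dist_norm` object.
#' @param min_z Keep pixels with z at or above this value (the map is dense;
#'   the default 0 keeps everything).
#' @param ... Unused.
#' @return Tibble with `chrom`, `bin1`, `bin2` (chromosome-local), `z`.
#' @export
tidy.dist_norm <- function(x, min_z = 0, ...) {
  out <- imap(x$z, function(Z, cc) {
    idx <- which(upper.tri(Z, diag = TRUE) & !is.na(Z) & Z >= min_z, arr.ind = TRUE)
    tibble(chrom = cc, bin1 = idx[, 1], bin2 = idx[, 2], z = Z[idx])
  })
  list_rbind(out)
}

#' Downsample a contact map to a target depth
#'
#' Exact sampling of individual contacts without replacement, so the new
#' total equals `target_total` and each pixel's expectation is proportional
#' to its original count (multivariate hypergeometric margins).
#'
#' @param map A `contact_map`.
#' @param target_total Number of contacts to keep.
#' @param seed Integer seed.
#' @return A `contact_map` with total `target_total` (weights dropped).
#' @export
downsample_map <- function(map, target_total, seed = 0) {
  if (target_total > map$total) abort("target exceeds total contacts")
  if (target_total == map$total) {
    map$weights <- NULL
    return(map)
  }
  cnt <- map$pixels$count
  cs <- cumsum(cnt)
  new_cnt <- local_seed_eval(seed, {
    picks <- sample.int(map$total, target_total)
    idx <- findInterval(picks - 0.5, c(0, cs))
    tabulate(idx, nbins = length(cnt))
  })
  contact_map(map$bins,
              tibble(bin1 = map$pixels$bin1, bin2 = map$pixels$bin2,
                     count = new_cnt))
}

#' Replicate-to-replicate distances on distance-normalized signal
#'
#' Euclidean distance between log2-transformed z values over the union of
#' informative pixels (observed in at least one map), with a 2-D principal
#' coordinate embedding — the sample-to-sample distance view used to check
#' that biological replicates cluster by group.
#'
#' @param zmaps Named list of `dist_norm` objects on identical bins.
#' @param groups Optional character vector of group labels (same order);
#'   when given, mean within- and between-group distances are reported.
#' @return List with `dist` (matrix), `embedding` (tibble of the first two
#'   principal coordinates), and optionally `within`, `between`.
#' @export
replicate_distances <- function(zmaps, groups = NULL) {
  if (length(zmaps) < 2L) abort("need >=2 maps")
  b0 <- zmaps[[1]]$bins
  for (m in zmaps) {
    if (!identical(dim(m$bins), dim(b0)) || !all(m$bins$chrom == b0$chrom)) {
      abort("bin tables differ between maps")
    }
  }
  if (is.null(names(zmaps))) names(zmaps) <- paste0("map", seq_along(zmaps))
  feats <- map(names(zmaps), function(nm) {
    x <- zmaps[[nm]]
    vals <- imap(x$z, function(Z, cc) {
      keep <- upper.tri(Z, diag = TRUE)
      v <- Z[keep]
      inf <- x$obs[[cc]][keep] > 0
      list(v = v, informative = inf & !is.na(v))
    })
    vals
  })
  # union of informative pixels across maps, per chromosome
  X <- map(seq_along(zmaps[[1]]$z), function(k) {
    inf <- Reduce(`|`, map(feats, ~ .x[[k]]$informative))
    do.call(rbind, map(feats, ~ log2(.x[[k]]$v[inf])))
  })
  X <- do.call(cbind, X)
  X[is.na(X)] <- 0
  D <- as.matrix(dist(X))
  dimnames(D) <- list(names(zmaps), names(zmaps))
  # degenerate configurations (e.g. identical maps) have zero spread;
  # cmdscale then returns fewer axes than requested
  emb <- suppressWarnings(cmdscale(D, k = min(2, length(zmaps) - 1)))
  if (ncol(emb) < 2) {
    emb <- cbind(emb, matrix(0, nrow(D), 2 - ncol(emb)))
  }
  out <- list(
    dist = D,
    embedding = tibble(sample = names(zmaps), pc1 = emb[, 1], pc2 = emb[, 2],
                       group = groups %||% NA_character_)
  )
  if (!is.null(groups)) {
    same <- outer(groups, groups, "==")
    ut <- upper.tri(D)
    out$within <- mean(D[ut & same])
    out$between <- mean(D[ut & !same])
  }
  out
}

#' Cis/trans contact composition
#'
#' @param map A `contact_map`.
#' @param by_chromosome Also return the per-chromosome trans ratio (trans
#'   contacts over all contacts touching that chromosome).
#' @return A tibble with `cis_fraction`, `trans_fraction`; when
#'   `by_chromosome`, attribute `per_chrom` holds the per-chromosome table.
#' @export
trans_fraction <- function(map, by_chromosome = FALSE) {
  ch <- map$bins$chrom
  c1 <- ch[map$pixels$bin1]; c2 <- ch[map$pixels$bin2]
  is_trans <- c1 != c2
  tot <- map$total
  trans_tot <- sum(map$pixels$count[is_trans])
  res <- tibble(
    cis_fraction = if (tot > 0) 1 - trans_tot / tot else NA_real_,
    trans_fraction = if (tot > 0) trans_tot / tot else NA_real_
  )
  if (by_chromosome) {
    per <- map(unique(ch), function(cc) {
      touch <- c1 == cc | c2 == cc
      tt <- sum(map$pixels$count[touch])
      tr <- sum(map$pixels$count[touch & is_trans])
      tibble(chrom = cc, contacts = tt,
             trans_ratio = if (tt > 0) tr / tt else NA_real_)
    })
    attr(res, "per_chrom") <- list_rbind(per)
  }
  res
}

#' Pool several contact maps by summing counts
#'
#' @param maps List of `contact_map`s on identical bins.
#' @return A single pooled `contact_map`.
#' @export
pool_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  px <- list_rbind(map(maps, ~ .x$pixels))
  contact_map(maps[[1]]$bins, px)
}
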