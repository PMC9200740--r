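# Gaussian smoothing of a matrix (truncated kernel, radius 3*sigma),
# NA-aware: missing pixels are excluded from the kernel average.
gauss_smooth <- function(M, sigma = 1) {
  if (sigma <= 0) return(M)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- nrow(M)
  na <- is.na(M)
  M0 <- M; M0[na] <- 0
  W <- matrix(1, n, ncol(M)); W[na] <- 0
  conv1 <- function(X) {
    out <- matrix(0, nrow(X), ncol(X))
    for (o in -r:r) {
      w <- k[o + r + 1]
      src <- seq_len(nrow(X)) + o
      ok <- src >= 1 & src <= nrow(X)
      out[ok, ] <- out[ok, ] + w * X[src[ok], ]
    }
    out
  }
  num <- t(conv1(t(conv1(M0))))
  den <- t(conv1(t(conv1(W))))
  S <- num / den
  S[na] <- NA
  S
}

# running sum over row offsets a..b (zero-padded at the edges)
shift_sum <- function(X, a, b) {
  out <- matrix(0, nrow(X), ncol(X))
  for (o in a:b) {
    src <- seq_len(nrow(X)) + o
    ok <- src >= 1 & src <= nrow(X)
    out[ok, ] <- out[ok, ] + X[src[ok], ]
  }
  out
}

# NA-aware box sums: value sum and valid-pixel count over a (2r+1)^2 window
box_stats <- function(M, r) {
  na <- is.na(M)
  M0 <- M; M0[na] <- 0
  W <- matrix(1, nrow(M), ncol(M)); W[na] <- 0
  list(sum = t(shift_sum(t(shift_sum(M0, -r, r)), -r, r)),
       n = t(shift_sum(t(shift_sum(W, -r, r)), -r, r)))
}

# the eight half-band regions flanking the 3x3 peak region inside a
# (2w+1)^2 window: above/below/left/right of the peak, each split in two.
# Scanning them separately guards against compartment-block edges and
# corners: enrichment that extends along a whole half-band (a block, a
# stripe) is background, not a focal peak.
half_band_regions <- function(w) {
  list(c(-w, -2, -w, 0), c(-w, -2, 0, w),
       c(2, w, -w, 0), c(2, w, 0, w),
       c(-w, 0, -w, -2), c(0, w, -w, -2),
       c(-w, 0, 2, w), c(0, w, 2, w))
}

# region sum of M (NA as 0) over offsets rows ra..rb, cols ca..cb
region_sum <- function(M0, reg) {
  t(shift_sum(t(shift_sum(M0, reg[1], reg[2])), reg[3], reg[4]))
}

# per-pixel local background from the half-band with the highest mean z:
# its mean z (`bg`), its summed balanced counts (`s`) and summed expected
# (`e`), for use in a conditional binomial peak test.
band_background <- function(Z, balM, E1, w) {
  na <- is.na(Z)
  Z0 <- Z; Z0[na] <- 0
  B0 <- balM; B0[na] <- 0
  E0 <- E1; E0[na] <- 0
  W <- matrix(1, nrow(Z), ncol(Z)); W[na] <- 0
  best <- matrix(-Inf, nrow(Z), ncol(Z))
  bs <- be <- matrix(NA_real_, nrow(Z), ncol(Z))
  for (reg in half_band_regions(w)) {
    k <- region_sum(W, reg)
    m <- region_sum(Z0, reg) / k
    m[k == 0] <- NA
    upd <- !is.na(m) & m > best
    best[upd] <- m[upd]
    s <- region_sum(B0, reg); e <- region_sum(E0, reg)
    bs[upd] <- s[upd]; be[upd] <- e[upd]
  }
  best[!is.finite(best)] <- NA
  list(bg = best, s = bs, e = be)
}

#' Call punctate loops on a distance-normalized map
#'
#' Every cis pixel in the tested separation range is scored against a
#' directional local background: of the eight half-bands flanking the
#' pixel's 3x3 peak region inside a `(2*window_r + 1)^2` window, the one
#' with the highest mean distance-normalized signal is taken — so
#' enrichment that extends along a band (a compartment block edge or
#' stripe) raises the background instead of reading as a focal peak. The
#' peak's summed balanced counts are compared with that band's summed
#' counts by a conditional binomial test (the exact two-Poisson rate
#' comparison, so background-estimation noise is part of the model).
#' Benjamini-Hochberg correction runs over the full pixel family
#' genome-wide; a loop is reported at each pixel that is significant at
#' `fdr`, has Gaussian-smoothed z above `z_floor`, and is the regional
#' maximum of the background-corrected enhancement in its neighborhood.
#'
#' @param zmap A `dist_norm` from [distance_normalize()].
#' @param smooth_sigma Gaussian sigma in bins (default 1).
#' @param window_r Neighborhood / background-window radius in bins (default 6).
#' @param z_floor Minimum smoothed z for a candidate (default 1.2).
#' @param fdr BH threshold (default 0.01).
#' @param min_dist Minimum anchor separation in bins (default 5, i.e. 50 kb
#'   at 10-kb bins) to avoid diagonal artefacts.
#' @param max_span Maximum anchor separation in bins (default 2000).
#' @return A tibble of class `loop_set`: `chrom`, `bin1`, `bin2`
#'   (chromosome-local), anchor coordinates, `z`, `p`, `q`.
#' @export
call_loops <- function(zmap, smooth_sigma = 1, window_r = 6, z_floor = 1.2,
                       fdr = 0.01, min_dist = 5, max_span = 2000) {
  stopifnot(inherits(zmap, "dist_norm"))
  if (zmap$total == 0) abort("empty matrix")
  bs <- bin_size_of(zmap$bins)
  w <- window_r
  tested <- list()
  en_by <- list()
  for (cc in names(zmap$z)) {
    Z <- zmap$z[[cc]]
    n <- nrow(Z)
    S <- gauss_smooth(Z, smooth_sigma)
    ev <- zmap$expected[[cc]]
    D <- outer(seq_len(n), seq_len(n), function(i, j) j - i)
    # balanced counts and their per-cell expected, on matching scales
    E1 <- matrix(ev[abs(D) + 1], n, n) + 1
    E1[is.na(Z)] <- NA
    balM <- Z * E1 - 1
    # directional local background (half-band with the highest mean z)
    bb <- band_background(Z, balM, E1, w)
    ring_z <- bb$bg
    ring_z[!is.finite(ring_z)] <- 1
    eligible <- D >= min_dist & D <= max_span & !is.na(Z)
    idx <- which(eligible)
    if (length(idx) == 0) next
    # peak statistic: balanced counts summed over the 3x3 region, compared
    # with the background band's counts by a conditional binomial test
    # (two-Poisson comparison, so background estimation noise is part of
    # the model)
    obs3 <- box_stats(balM, 1)
    e3 <- box_stats(E1, 1)
    x <- pmax(round(obs3$sum[idx]), 0)
    b <- pmax(round(bb$s[idx]), 0)
    wt <- e3$sum[idx] / (e3$sum[idx] + bb$e[idx])
    ok <- is.finite(wt) & wt > 0 & wt < 1
    p <- rep(1, length(idx))
    p[ok] <- pbinom(x[ok] - 1, x[ok] + b[ok], wt[ok], lower.tail = FALSE)
    rc <- arrayInd(idx, dim(Z))
    # enhancement: smoothed z over local background, for peak localisation
    EN <- S / ring_z
    en_by[[cc]] <- EN
    tested[[cc]] <- tibble(chrom = cc, bin1 = rc[, 1], bin2 = rc[, 2],
                           z = Z[idx], s = S[idx], p = p)
  }
  if (length(tested) == 0) {
    res <- tibble(chrom = character(), bin1 = integer(), bin2 = integer(),
                  z = numeric(), p = numeric(), q = numeric())
  } else {
    res <- list_rbind(tested)
    res$q <- p.adjust(res$p, method = "BH")
    res <- filter(res, .data$q <= fdr, .data$s >= z_floor)
    # keep only regional maxima of the background-corrected enhancement
    if (nrow(res) > 0) {
      keep <- map_lgl(seq_len(nrow(res)), function(r) {
        EN <- en_by[[res$chrom[r]]]
        i <- res$bin1[r]; j <- res$bin2[r]; n <- nrow(EN)
        nb <- EN[max(1, i - w):min(n, i + w), max(1, j - w):min(n, j + w)]
        EN[i, j] >= max(nb, na.rm = TRUE)
      })
      res <- res[keep, , drop = FALSE]
    }
    res <- select(res, -"s")
  }
  res <- add_anchor_coords(res, zmap$bins)
  attr(res, "params") <- list(smooth_sigma = smooth_sigma, window_r = window_r,
                              z_floor = z_floor, fdr = fdr,
                              min_dist = min_dist, max_span = max_span,
                              bin_size = bs)
  class(res) <- c("loop_set", class(res))
  res
}

# attach genomic anchor coordinates to chromosome-local (bin1, bin2) records
add_anchor_coords <- function(x, bins) {
  bs <- bin_size_of(bins)
  lens <- bins |> group_by(.data$chrom) |> summarise(len = max(.data$end))
  x |>
    left_join(lens, by = "chrom") |>
    mutate(start1 = (.data$bin1 - 1) * bs, end1 = pmin(.data$bin1 * bs, .data$len),
           start2 = (.data$bin2 - 1) * bs, end2 = pmin(.data$bin2 * bs, .data$len)) |>
    select(-"len")
}

#' Merge per-sample loop sets into a master list
#'
#' Single-linkage clustering of loops whose two anchors both lie within
#' `radius` of each other (bp distance between anchor bin starts); each
#' cluster is represented by its highest-z member. Idempotent.
#'
#' @param loop_sets A list of `loop_set` tibbles (or a single one).
#' @param radius Merge radius in bp (default 25000).
#' @return A master `loop_set` with a `provenance` column (sample indices).
#' @export
merge_master <- function(loop_sets, radius = 25000) {
  if (is_tibble(loop_sets)) loop_sets <- list(loop_sets)
  if (is.null(names(loop_sets))) names(loop_sets) <- paste0("s", seq_along(loop_sets))
  all <- list_rbind(imap(loop_sets, ~ mutate(.x, sample = .y)))
  if (nrow(all) == 0) return(all)
  n <- nrow(all)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (cc in unique(all$chrom)) {
    ii <- which(all$chrom == cc)
    if (length(ii) < 2) next
    ord <- ii[order(all$start1[ii])]
    for (a in seq_along(ord)) {
      for (b in seq_len(length(ord) - a)) {
        i <- ord[a]; j <- ord[a + b]
        if (all$start1[j] - all$start1[i] > radius) break
        if (abs(all$start2[i] - all$start2[j]) <= radius) {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  comp <- map_int(seq_len(n), find)
  all$cluster <- match(comp, unique(comp))
  master <- all |>
    group_by(.data$cluster) |>
    arrange(desc(.data$z), .by_group = TRUE) |>
    summarise(chrom = first(.data$chrom), bin1 = first(.data$bin1),
              bin2 = first(.data$bin2), z = first(.data$z),
              p = first(.data$p), q = first(.data$q),
              start1 = first(.data$start1), end1 = first(.data$end1),
              start2 = first(.data$start2), end2 = first(.data$end2),
              provenance = paste(sort(unique(.data$sample)), collapse = ","),
              .groups = "drop") |>
    select(-"cluster") |>
    arrange(.data$chrom, .data$bin1, .data$bin2)
  attr(master, "radius") <- radius
  class(master) <- c("loop_set", class(master))
  master
}

# max z in the 3x3 neighborhood around a pixel (absorbs 1-bin peak drift)
z_at_pixel <- function(zmap, chrom, bin1, bin2, halo = 1) {
  Z <- zmap$z[[chrom]]
  n <- nrow(Z)
  ii <- max(1, bin1 - halo):min(n, bin1 + halo)
  jj <- max(1, bin2 - halo):min(n, bin2 + halo)
  v <- suppressWarnings(max(Z[ii, jj], na.rm = TRUE))
  if (!is.finite(v)) NA_real_ else v
}

#' Differential loops between two conditions
#'
#' For each master loop, the distance-normalized signal is read in both
#' conditions as the maximum over a 3x3 pixel neighborhood; a loop is
#' flagged differential when the larger signal exceeds `min_z` and the
#' fold change (max/min) is at least `min_fold`.
#'
#' @param master A master `loop_set` from [merge_master()].
#' @param zmap_a,zmap_b `dist_norm` maps for the two conditions.
#' @param min_z Signal threshold (default 2).
#' @param min_fold Fold-change threshold (default 2.5).
#' @param labels Condition names used for the `direction` column.
#' @return A tibble of class `diff_loops` with `z_a`, `z_b`, `fold`,
#'   `direction`, `flagged`.
#' @export
diff_loops <- function(master, zmap_a, zmap_b, min_z = 2, min_fold = 2.5,
                       labels = c("A", "B")) {
  za <- map_dbl(seq_len(nrow(master)), function(r) {
    z_at_pixel(zmap_a, master$chrom[r], master$bin1[r], master$bin2[r])
  })
  zb <- map_dbl(seq_len(nrow(master)), function(r) {
    z_at_pixel(zmap_b, master$chrom[r], master$bin1[r], master$bin2[r])
  })
  hi <- pmax(za, zb); lo <- pmin(za, zb)
  fold <- hi / lo
  out <- master |>
    mutate(z_a = za, z_b = zb, fold = fold,
           direction = case_when(
             is.na(fold) ~ NA_character_,
             za >= zb ~ paste0(labels[1], "-specific"),
             TRUE ~ paste0(labels[2], "-specific")
           ),
           flagged = !is.na(fold) & hi > min_z & fold >= min_fold)
  attr(out, "params") <- list(min_z = min_z, min_fold = min_fold)
  class(out) <- c("diff_loops", class(out))
  out
}

#' Annotate loop anchors with ATAC peaks and CTCF motifs
#'
#' Each anchor is tested for overlap with at least one ATAC peak and at
#' least one CTCF motif; the loop's category is the conjunction over both
#' anchors (`both`, `CTCF_only`, `ATAC_only`, `neither`). Motif strands
#' give the orientation class: `convergent` (+ at the left anchor, - at the
#' right), `tandem` (same strands), `divergent` (- then +), `ambiguous`
#' when either anchor lacks a stranded motif.
#'
#' @param loops A `loop_set`.
#' @param atac Optional ATAC peak intervals.
#' @param ctcf Optional stranded motif intervals (BED6-style `strand`).
#' @return The loop tibble with `category` and `convergence` columns;
#'   attribute `composition` holds the category percentage table.
#' @export
annotate_anchors <- function(loops, atac = NULL, ctcf = NULL) {
  anchor <- function(which) {
    tibble(chrom = loops$chrom,
           start = loops[[paste0("start", which)]],
           end = loops[[paste0("end", which)]])
  }
  a1 <- anchor(1); a2 <- anchor(2)
  has_atac1 <- if (is.null(atac)) rep(FALSE, nrow(loops)) else count_overlaps(a1, atac) > 0
  has_atac2 <- if (is.null(atac)) rep(FALSE, nrow(loops)) else count_overlaps(a2, atac) > 0
  strands_at <- function(aa) {
    if (is.null(ctcf)) return(rep(list(character()), nrow(aa)))
    map(seq_len(nrow(aa)), function(r) {
      sel <- ctcf$chrom == aa$chrom[r] & ctcf$start < aa$end[r] & ctcf$end > aa$start[r]
      ctcf$strand[sel]
    })
  }
  s1 <- strands_at(a1); s2 <- strands_at(a2)
  has_ctcf1 <- map_lgl(s1, ~ length(.x) > 0)
  has_ctcf2 <- map_lgl(s2, ~ length(.x) > 0)
  atac_both <- has_atac1 & has_atac2
  ctcf_both <- has_ctcf1 & has_ctcf2
  category <- case_when(
    atac_both & ctcf_both ~ "both",
    ctcf_both ~ "CTCF_only",
    atac_both ~ "ATAC_only",
    TRUE ~ "neither"
  )
  convergence <- map2(s1, s2, function(x, y) {
    x <- x[x %in% c("+", "-")]; y <- y[y %in% c("+", "-")]
    if (length(x) == 0 || length(y) == 0) return("ambiguous")
    if ("+" %in% x && "-" %in% y) return("convergent")
    if (any(x == y[1]) && length(unique(c(x, y))) == 1) return("tandem")
    if ("-" %in% x && "+" %in% y) return("divergent")
    "tandem"
  })
  out <- mutate(loops, category = category, convergence = unlist(convergence))
  comp <- out |>
    group_by(.data$category) |>
    summarise(n = n(), .groups = "drop") |>
    mutate(percent = 100 * n / sum(n))
  attr(out, "composition") <- comp
  out
}

#' Aggregate peak analysis (APA)
#'
#' Element-wise mean of `(2*half_window + 1)^2` windows of the
#' distance-normalized map centered on each site; the APA score is the
#' center pixel of the aggregate. Sites closer than `half_window` bins to
#' the diagonal or to a matrix edge are excluded. A corner ratio (center
#' over the mean of the lower-left `3x3` corner) is reported as a secondary
#' statistic.
#'
#' @param zmap A `dist_norm`.
#' @param sites Tibble with `chrom`, `bin1`, `bin2` (chromosome-local).
#' @param half_window Half-width in bins (default 10).
#' @return List with `aggregate` (matrix), `score`, `corner_ratio`,
#'   `n_sites`.
#' @export
apa <- function(zmap, sites, half_window = 10) {
  if (nrow(sites) == 0) abort("no sites supplied")
  h <- half_window
  acc <- matrix(0, 2 * h + 1, 2 * h + 1)
  wsum <- matrix(0, 2 * h + 1, 2 * h + 1)
  used <- 0L
  for (r in seq_len(nrow(sites))) {
    cc <- sites$chrom[r]
    Z <- zmap$z[[cc]]
    if (is.null(Z)) next
    n <- nrow(Z)
    i <- sites$bin1[r]; j <- sites$bin2[r]
    if (is.na(i) || is.na(j)) next
    if (i - h < 1 || j + h > n || (j - i) <= 2 * h) next # clear of diagonal/edges
    Wn <- Z[(i - h):(i + h), (j - h):(j + h)]
    ok <- !is.na(Wn)
    Wn[!ok] <- 0
    acc <- acc + Wn
    wsum <- wsum + ok
    used <- used + 1L
  }
  if (used == 0L) abort("all sites excluded (too close to diagonal or edges)")
  agg <- acc / wsum
  center <- agg[h + 1, h + 1]
  corner <- mean(agg[(2 * h - 1):(2 * h + 1), 1:3]) # lower-left corner
  list(aggregate = agg, score = center,
       corner_ratio = center / corner, n_sites = used)
}

#' Insulation score track
#'
#' For each bin, the mean balanced signal in the `window x window` square
#' bridging the bin (upstream rows x downstream columns), log2-scaled to
#' the chromosome-wide mean of such squares. Minima mark domain boundaries.
#'
#' @param map A balanced `contact_map`.
#' @param window Window size in bins (default 20).
#' @return A tibble with `chrom`, `bin`, `start`, `end`, `insulation`.
#' @export
insulation <- function(map, window = 20) {
  if (is.null(map$weights)) abort("map must be balanced")
  out <- list()
  for (cc in unique(map$bins$chrom)) {
    M <- cis_matrix(map, cc, balanced = TRUE)
    n <- nrow(M)
    if (2 * window + 1 > n) abort(sprintf("window exceeds chromosome %s span", cc))
    sub_bins <- filter(map$bins, .data$chrom == cc)
    sq <- rep(NA_real_, n)
    for (i in (window + 1):(n - window)) {
      block <- M[(i - window):(i - 1), (i + 1):(i + window)]
      sq[i] <- mean(block, na.rm = TRUE)
    }
    mu <- mean(sq, na.rm = TRUE)
    out[[cc]] <- tibble(chrom = cc, bin = seq_len(n),
                        start = sub_bins$start, end = sub_bins$end,
                        insulation = log2(sq / mu))
  }
  list_rbind(out)
}

#' Aggregate domain analysis (ADA)
#'
#' Mean of coordinate-rescaled z submatrices over supplied domains, padded
#' by half the domain size on each side so the interior sits in the middle
#' third of the aggregate.
#'
#' @param zmap A `dist_norm`.
#' @param domains Tibble with `chrom`, `start_bin`, `end_bin`
#'   (chromosome-local).
#' @param size Output matrix size per domain axis (default 30).
#' @return List with `aggregate`, `interior_mean`, `exterior_mean`,
#'   `n_domains`.
#' @export
aggregate_domains <- function(zmap, domains, size = 30) {
  if (nrow(domains) == 0) abort("no domains supplied")
  acc <- matrix(0, size, size); wsum <- matrix(0, size, size)
  used <- 0L
  for (r in seq_len(nrow(domains))) {
    Z <- zmap$z[[domains$chrom[r]]]
    if (is.null(Z)) next
    n <- nrow(Z)
    a <- domains$start_bin[r]; b <- domains$end_bin[r]
    w <- b - a + 1
    lo <- a - w %/% 2; hi <- b + w %/% 2
    if (lo < 1 || hi > n) next
    idx <- round(seq(lo, hi, length.out = size))
    Wn <- Z[idx, idx]
    ok <- !is.na(Wn); Wn[!ok] <- 0
    acc <- acc + Wn; wsum <- wsum + ok
    used <- used + 1L
  }
  if (used == 0L) abort("all domains excluded")
  agg <- acc / wsum
  third <- round(size / 3)
  interior <- agg[(third + 1):(size - third), (third + 1):(size - third)]
  mask <- matrix(TRUE, size, size)
  mask[(third + 1):(size - third), (third + 1):(size - third)] <- FALSE
  list(aggregate = agg, interior_mean = mean(interior, na.rm = TRUE),
       exterior_mean = mean(agg[mask], na.rm = TRUE), n_domains = used)
}
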