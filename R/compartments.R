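#' Call A/B compartment eigenvectors
#'
#' Per chromosome: the balanced cis matrix is converted to
#' observed/expected, the Pearson correlation matrix of the O/E columns is
#' computed over non-filtered bins, and the eigenvector of the
#' largest-magnitude eigenvalue is taken. The sign is oriented so the
#' eigenvector correlates positively with an activity-density track (ATAC
#' peak or TSS counts per bin), and the vector is scaled to unit standard
#' deviation over unmasked bins; positive values are the A compartment.
#'
#' @param map A balanced `contact_map` (see [balance_map()]).
#' @param orient_track Optional interval tibble (e.g. ATAC peaks or TSSs as
#'   1-bp intervals); per-bin counts orient the sign. When absent the track
#'   is unoriented and flagged via the `oriented` attribute.
#' @param min_bins Chromosomes with fewer unmasked bins are skipped with a
#'   warning.
#' @return A tibble of class `eigen_track`: `chrom`, `bin` (chromosome-
#'   local), `start`, `end`, `e`, `label` ("A"/"B"/NA), `masked`.
#' @export
call_eigenvector <- function(map, orient_track = NULL, min_bins = 10) {
  if (is.null(map$weights)) abort("map must be balanced before compartment calling")
  bs <- bin_size_of(map$bins)
  expected <- expected_by_distance(map, use_weights = TRUE)
  oriented <- !is.null(orient_track)
  out <- list()
  for (cc in unique(map$bins$chrom)) {
    sub_bins <- filter(map$bins, .data$chrom == cc)
    n <- nrow(sub_bins)
    res <- tibble(chrom = cc, bin = seq_len(n),
                  start = sub_bins$start, end = sub_bins$end,
                  e = NA_real_, label = NA_character_, masked = TRUE)
    M <- cis_matrix(map, cc, balanced = TRUE)
    mask <- cis_mask(map, cc)
    e_prof <- expected$expected[expected$chrom == cc]
    D <- abs(outer(seq_len(n), seq_len(n), "-"))
    OE <- M / matrix(e_prof[D + 1], n, n)
    OE[!is.finite(OE)] <- NA
    keep <- mask & apply(OE, 1, function(r) sum(is.finite(r)) > 1)
    # drop zero-variance columns (they break the correlation)
    sds <- apply(OE[keep, keep, drop = FALSE], 2, sd, na.rm = TRUE)
    keep[keep][is.na(sds) | sds == 0] <- FALSE
    if (sum(keep) < min_bins) {
      warn(sprintf("chromosome %s: fewer than %d usable bins, skipped", cc, min_bins))
      out[[cc]] <- res
      next
    }
    C <- suppressWarnings(cor(OE[keep, keep, drop = FALSE],
                              use = "pairwise.complete.obs"))
    C[!is.finite(C)] <- 0
    eg <- eigen(C, symmetric = TRUE)
    lead <- which.max(abs(eg$values))
    v <- eg$vectors[, lead]
    if (oriented) {
      act <- bin_activity(sub_bins, orient_track)
      s <- suppressWarnings(cor(v, act[keep]))
      if (is.finite(s) && s < 0) v <- -v
    }
    v <- v / sd(v)
    res$e[keep] <- v
    res$label[keep] <- ifelse(v > 0, "A", "B")
    res$masked[keep] <- FALSE
    out[[cc]] <- res
  }
  track <- list_rbind(out)
  attr(track, "bin_size") <- bs
  attr(track, "oriented") <- oriented
  class(track) <- c("eigen_track", class(track))
  track
}

# per-bin count of track elements (intervals or points)
bin_activity <- function(sub_bins, track) {
  if ("pos" %in% names(track) && !("start" %in% names(track))) {
    track <- mutate(track, start = .data$pos, end = .data$pos + 1)
  }
  count_overlaps(sub_bins, track)
}

#' Differential compartments between two conditions
#'
#' Flags bins whose eigenvector difference exceeds a threshold; the default
#' 0.42 is the quartile-shift criterion (a bin moving from one quartile of
#' the eigenvector distribution to another). `tau = "auto"` derives the
#' threshold as the interquartile distance of the pooled eigenvector
#' distribution.
#'
#' @param track_a,track_b `eigen_track`s on the same bins (unit-SD scaled).
#' @param tau Threshold on `|e_a - e_b|`, or `"auto"`.
#' @return A tibble of class `diff_compartments` with `delta`, `flagged`;
#'   attributes `tau` and `summary` (per-chromosome flagged count and Mb).
#' @export
diff_compartments <- function(track_a, track_b, tau = 0.42) {
  if (nrow(track_a) != nrow(track_b) ||
      !all(track_a$chrom == track_b$chrom & track_a$bin == track_b$bin)) {
    abort("tracks are not on the same bins")
  }
  sda <- sd(track_a$e, na.rm = TRUE); sdb <- sd(track_b$e, na.rm = TRUE)
  if (is.finite(sda) && is.finite(sdb) && abs(sda - sdb) > 0.1 * max(sda, sdb)) {
    warn("eigenvector scales differ by >10%; comparison proceeds")
  }
  if (identical(tau, "auto")) {
    pooled <- c(track_a$e, track_b$e)
    tau <- IQR(pooled, na.rm = TRUE)
  }
  bs <- attr(track_a, "bin_size") %||% (track_a$end - track_a$start)[1]
  out <- tibble(
    chrom = track_a$chrom, bin = track_a$bin,
    start = track_a$start, end = track_a$end,
    e_a = track_a$e, e_b = track_b$e,
    delta = track_a$e - track_b$e,
    flagged = !is.na(track_a$e) & !is.na(track_b$e) &
      abs(track_a$e - track_b$e) > tau
  )
  summ <- out |>
    group_by(.data$chrom) |>
    summarise(n_bins = sum(!is.na(.data$delta)),
              n_flagged = sum(.data$flagged),
              mb = span_mb(sum(.data$flagged), bs),
              .groups = "drop")
  attr(out, "tau") <- tau
  attr(out, "bin_size") <- bs
  attr(out, "summary") <- summ
  class(out) <- c("diff_compartments", class(out))
  out
}

#' Compare differential-compartment magnitude between bin groups
#'
#' Two-sided Wilcoxon rank-sum test on per-bin `|delta|` between two
#' partitions of the genome (canonically X chromosome vs autosomes).
#'
#' @param diffs A `diff_compartments` tibble.
#' @param partition Logical vector (one per row of `diffs`, TRUE = group 1),
#'   or NULL to use the sex-chromosome flag from chromosome names
#'   (`chrX`/`X` = group 1).
#' @return A tibble with medians per group, the W statistic, and p-value.
#' @export
compare_groups <- function(diffs, partition = NULL) {
  if (is.null(partition)) {
    partition <- diffs$chrom %in% c("chrX", "chrY", "X", "Y")
  }
  ok <- !is.na(diffs$delta)
  g1 <- abs(diffs$delta[ok & partition])
  g2 <- abs(diffs$delta[ok & !partition])
  if (length(g1) == 0 || length(g2) == 0) abort("a partition group is empty")
  wt <- wilcox.test(g1, g2, alternative = "two.sided", exact = length(g1) < 50 && length(g2) < 50)
  tibble(
    median_group1 = median(g1), median_group2 = median(g2),
    n_group1 = length(g1), n_group2 = length(g2),
    statistic = unname(wt$statistic), p_value = wt$p.value
  )
}

#' Direction concordance between two condition comparisons
#'
#' Over bins flagged in either comparison, the fraction whose eigenvector
#' deltas share a sign, plus a Spearman rank correlation — the check that,
#' e.g., proestrus-vs-dioestrus shifts track male-vs-dioestrus shifts.
#'
#' @param diffs1,diffs2 `diff_compartments` tibbles on the same bins.
#' @return A tibble with `n_bins`, `agreement`, `rho`, `rho_p`; all NA with
#'   a message when no bin is flagged.
#' @export
direction_concordance <- function(diffs1, diffs2) {
  if (nrow(diffs1) != nrow(diffs2)) abort("comparisons are not on the same bins")
  sel <- (diffs1$flagged | diffs2$flagged) &
    !is.na(diffs1$delta) & !is.na(diffs2$delta)
  if (!any(sel)) {
    inform("no flagged bins in either comparison; concordance undefined")
    return(tibble(n_bins = 0L, agreement = NA_real_, rho = NA_real_, rho_p = NA_real_))
  }
  d1 <- diffs1$delta[sel]; d2 <- diffs2$delta[sel]
  nz <- d1 != 0 & d2 != 0
  agree <- mean(sign(d1[nz]) == sign(d2[nz]))
  ct <- suppressWarnings(cor.test(d1, d2, method = "spearman"))
  tibble(n_bins = sum(sel), agreement = agree,
         rho = unname(ct$estimate), rho_p = ct$p.value)
}

#' Per-gene eigenvector signal
#'
#' Length-weighted mean of the eigenvector over the bins a gene body
#' overlaps; genes falling only on masked bins get NA.
#'
#' @param track An `eigen_track`.
#' @param genes Interval tibble (`chrom`, `start`, `end`, optional `name`).
#' @return A tibble with one row per gene and column `e`.
#' @export
gene_eigen <- function(track, genes) {
  bs <- attr(track, "bin_size") %||% (track$end - track$start)[1]
  e_of <- function(cc, s, en) {
    tb <- track[track$chrom == cc, ]
    if (nrow(tb) == 0) return(NA_real_)
    ov_w <- pmin(tb$end, en) - pmax(tb$start, s)
    sel <- ov_w > 0 & !is.na(tb$e)
    if (!any(sel)) return(NA_real_)
    sum(tb$e[sel] * ov_w[sel]) / sum(ov_w[sel])
  }
  genes |>
    mutate(e = map_dbl(row_number(),
                       ~ e_of(genes$chrom[.x], genes$start[.x], genes$end[.x])))
}
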