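#' Call significant interactions with a binomial distance model
#'
#' A one-pass distance model in the Fit-Hi-C style: cis bin pairs are
#' grouped into equal-occupancy distance strata (contiguous distance
#' ranges holding roughly equal total contacts); within a stratum the
#' per-pair contact probability is
#' `p_d = stratum contact sum / (N_total * possible pairs in stratum)`.
#' Each observed pair (count >= 1) is tested by the upper tail of
#' `Binomial(N_total, p_d)`; BH correction runs across all tested pairs
#' and calls with `q < q_max` are kept.
#'
#' @param map A `contact_map` (10-kb bins in the canonical analysis).
#' @param q_max BH threshold (default 0.05).
#' @param n_strata Number of equal-occupancy distance strata (default 100).
#' @param min_dist,max_dist Tested separation range in bins (defaults 2 and
#'   2000).
#' @param zmap Optional `dist_norm` on the same bins; when given, each
#'   interaction also carries its distance-normalized `z`.
#' @return A tibble of class `interaction_set` with `chrom`, `bin1`,
#'   `bin2`, `count`, `expected_p`, `p`, `q` (and `z` when `zmap` given).
#' @export
call_significant <- function(map, q_max = 0.05, n_strata = 100,
                             min_dist = 2, max_dist = 2000, zmap = NULL) {
  per_chrom <- list()
  for (cc in unique(map$bins$chrom)) {
    ids <- chrom_bin_ids(map$bins, cc)
    off <- min(ids) - 1L
    n <- length(ids)
    px <- filter(map$pixels, .data$bin1 >= min(ids), .data$bin1 <= max(ids),
                 .data$bin2 >= min(ids), .data$bin2 <= max(ids))
    d <- px$bin2 - px$bin1
    keep <- d >= min_dist & d <= max_dist
    px <- px[keep, , drop = FALSE]
    dmax <- min(max_dist, n - 1)
    if (dmax < min_dist) next
    dd <- min_dist:dmax
    sums <- tapply(px$count, factor(px$bin2 - px$bin1, levels = dd), sum)
    sums[is.na(sums)] <- 0
    per_chrom[[cc]] <- list(
      tab = tibble(chrom = cc, d = dd, n_pairs = n - dd, sum = as.numeric(sums)),
      px = mutate(px, chrom = cc, b1 = .data$bin1 - off, b2 = .data$bin2 - off)
    )
  }
  if (length(per_chrom) == 0) abort("no testable pairs")
  tab <- list_rbind(map(per_chrom, "tab")) |> arrange(.data$d)
  px <- list_rbind(map(per_chrom, "px"))
  n_total <- sum(tab$sum)
  empty <- tibble(chrom = character(), bin1 = integer(), bin2 = integer(),
                  count = numeric(), expected_p = numeric(),
                  p = numeric(), q = numeric())
  if (n_total == 0 || nrow(px) == 0) {
    out <- add_anchor_coords(empty, map$bins)
    class(out) <- c("interaction_set", class(out))
    return(out)
  }
  # equal-occupancy strata over distance (pooled across chromosomes)
  dist_tab <- tab |>
    group_by(.data$d) |>
    summarise(n_pairs = sum(.data$n_pairs), sum = sum(.data$sum), .groups = "drop") |>
    arrange(.data$d)
  target <- n_total / n_strata
  stratum <- integer(nrow(dist_tab))
  s <- 1L; acc <- 0
  for (k in seq_len(nrow(dist_tab))) {
    stratum[k] <- s
    acc <- acc + dist_tab$sum[k]
    if (acc >= target && s < n_strata) { s <- s + 1L; acc <- 0 }
  }
  dist_tab$stratum <- stratum
  strata <- dist_tab |>
    group_by(.data$stratum) |>
    summarise(pairs = sum(.data$n_pairs), contacts = sum(.data$sum), .groups = "drop") |>
    mutate(p_hat = .data$contacts / (n_total * pmax(.data$pairs, 1)))
  dist_tab <- left_join(dist_tab, select(strata, "stratum", "p_hat"), by = "stratum")
  px <- px |>
    mutate(d = .data$b2 - .data$b1) |>
    left_join(select(dist_tab, "d", "p_hat"), by = "d") |>
    mutate(p = pbinom(.data$count - 1, n_total, .data$p_hat, lower.tail = FALSE))
  px$q <- p.adjust(px$p, method = "BH")
  out <- px |>
    filter(.data$q < q_max) |>
    select(chrom, bin1 = "b1", bin2 = "b2", count,
           expected_p = "p_hat", p, q) |>
    arrange(.data$chrom, .data$bin1, .data$bin2)
  out <- add_anchor_coords(out, map$bins)
  if (!is.null(zmap)) {
    out$z <- map_dbl(seq_len(nrow(out)), function(r) {
      zmap$z[[out$chrom[r]]][out$bin1[r], out$bin2[r]]
    })
  }
  attr(out, "params") <- list(q_max = q_max, n_strata = n_strata,
                              min_dist = min_dist, max_dist = max_dist,
                              n_total = n_total, n_tested = nrow(px))
  class(out) <- c("interaction_set", class(out))
  out
}

#' Exclude interactions that sit at CTCF loops
#'
#' Drops any interaction whose anchors are both within `radius` (bp,
#' anchor-start distance) of some loop's corresponding anchors — these are
#' better explained as CTCF loops than as enhancer-promoter contacts.
#'
#' @param interactions An `interaction_set`.
#' @param loops A `loop_set`.
#' @param radius Exclusion radius in bp (default 20000).
#' @return The filtered interaction tibble.
#' @export
exclude_loops <- function(interactions, loops, radius = 20000) {
  if (nrow(interactions) == 0 || nrow(loops) == 0) return(interactions)
  drop <- map_lgl(seq_len(nrow(interactions)), function(r) {
    sel <- loops$chrom == interactions$chrom[r]
    if (!any(sel)) return(FALSE)
    any(abs(loops$start1[sel] - interactions$start1[r]) <= radius &
          abs(loops$start2[sel] - interactions$start2[r]) <= radius)
  })
  out <- interactions[!drop, , drop = FALSE]
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Annotate bins as promoter / enhancer
#'
#' A bin is a promoter bin when it contains at least one TSS. A bin is an
#' enhancer bin when it lacks a TSS and holds at least one ATAC peak lying
#' more than `enhancer_dist` bp (edge-to-point) from every TSS — the distal
#' accessible-chromatin proxy for enhancers.
#'
#' @param bins Bin table from [make_bins()].
#' @param atac ATAC peak intervals.
#' @param tss Tibble of TSS points (`chrom`, `pos`).
#' @param enhancer_dist Minimum peak-to-TSS distance in bp (default 10000,
#'   strict inequality).
#' @return The bin table with `has_promoter` and `has_enhancer` columns.
#' @export
annotate_bins <- function(bins, atac, tss, enhancer_dist = 10000) {
  tss_iv <- tibble(chrom = tss$chrom, start = tss$pos, end = tss$pos + 1)
  has_promoter <- count_overlaps(bins, tss_iv) > 0
  dist_to_tss <- nearest_point_distance(atac, tss)
  distal <- atac[dist_to_tss > enhancer_dist, , drop = FALSE]
  has_peak <- count_overlaps(bins, distal) > 0
  mutate(bins, has_promoter = has_promoter,
         has_enhancer = has_peak & !has_promoter)
}

#' Classify interactions by anchor annotation
#'
#' @param interactions An `interaction_set` (chromosome-local bins).
#' @param bin_ann Annotated bin table from [annotate_bins()].
#' @return The interaction tibble with a `category` column in
#'   `{"E-P", "E-E", "P-P", "other"}`; attribute `category_counts`.
#' @export
classify_interactions <- function(interactions, bin_ann) {
  ann <- bin_ann |>
    group_by(.data$chrom) |>
    mutate(local_bin = row_number()) |>
    ungroup() |>
    select("chrom", "local_bin", "has_promoter", "has_enhancer")
  x <- interactions |>
    left_join(rename(ann, bin1 = "local_bin", prom1 = "has_promoter",
                     enh1 = "has_enhancer"), by = c("chrom", "bin1")) |>
    left_join(rename(ann, bin2 = "local_bin", prom2 = "has_promoter",
                     enh2 = "has_enhancer"), by = c("chrom", "bin2"))
  x <- x |>
    mutate(category = case_when(
      (enh1 & prom2) | (prom1 & enh2) ~ "E-P",
      enh1 & enh2 ~ "E-E",
      prom1 & prom2 ~ "P-P",
      TRUE ~ "other"
    )) |>
    select(-"prom1", -"prom2", -"enh1", -"enh2")
  attr(x, "category_counts") <- x |>
    group_by(.data$category) |>
    summarise(n = n(), .groups = "drop")
  x
}

#' Differential interactions between two conditions
#'
#' Same rule as [diff_loops()]: distance-normalized signal above `min_z` in
#' the stronger condition and fold change at least `min_fold` (signal read
#' as the 3x3 neighborhood maximum).
#'
#' @param interactions An `interaction_set`.
#' @param zmap_a,zmap_b `dist_norm` maps for the two conditions.
#' @inheritParams diff_loops
#' @return The interaction tibble with `z_a`, `z_b`, `fold`, `direction`,
#'   `flagged`.
#' @export
diff_interactions <- function(interactions, zmap_a, zmap_b,
                              min_z = 2, min_fold = 2.5, labels = c("A", "B")) {
  out <- diff_loops(interactions, zmap_a, zmap_b,
                    min_z = min_z, min_fold = min_fold, labels = labels)
  class(out) <- setdiff(class(out), "diff_loops")
  class(out) <- c("diff_interactions", class(out))
  out
}

#' Per-gene enhancer connectivity
#'
#' Counts the distinct enhancer bins linked by E-P interactions to each
#' gene's promoter bin(s), bins genes by connection count
#' (`0,1,2,3,4,5,>5`), and joins expression when supplied.
#'
#' @param interactions Classified interaction tibble (only `E-P` rows are
#'   used).
#' @param gene_promoters Tibble mapping `gene` to promoter bin
#'   (`chrom`, `bin`, chromosome-local).
#' @param bin_ann Annotated bin table from [annotate_bins()] (identifies
#'   which side of each interaction is the enhancer).
#' @param expression Optional tibble with `gene` and a TPM column named by
#'   `tpm_col`.
#' @param tpm_col Name of the expression column (default "female").
#' @return Tibble with `gene`, `n_enhancers`, `connectivity_bin`, and
#'   `tpm` when expression is given; attribute `bin_summary` holds mean TPM
#'   per connectivity bin, attribute `correlation` a Spearman test of count
#'   vs TPM.
#' @export
gene_connectivity <- function(interactions, gene_promoters, bin_ann,
                              expression = NULL, tpm_col = "female") {
  ep <- filter(interactions, .data$category == "E-P")
  ann <- bin_ann |>
    group_by(.data$chrom) |>
    mutate(local_bin = row_number()) |>
    ungroup()
  enh_key <- paste(ann$chrom[ann$has_enhancer], ann$local_bin[ann$has_enhancer])
  links <- if (nrow(ep) > 0) {
    bind_rows(
      tibble(chrom = ep$chrom, pbin = ep$bin1, ebin = ep$bin2),
      tibble(chrom = ep$chrom, pbin = ep$bin2, ebin = ep$bin1)
    ) |>
      filter(paste(.data$chrom, .data$ebin) %in% enh_key) |>
      distinct()
  } else {
    tibble(chrom = character(), pbin = integer(), ebin = integer())
  }
  counts <- gene_promoters |>
    left_join(links, by = c("chrom", "bin" = "pbin"),
              relationship = "many-to-many") |>
    group_by(.data$gene) |>
    summarise(n_enhancers = sum(!is.na(.data$ebin) & !duplicated(.data$ebin)),
              .groups = "drop")
  counts <- counts |>
    mutate(connectivity_bin = ifelse(.data$n_enhancers > 5, ">5",
                                     as.character(.data$n_enhancers)),
           connectivity_bin = factor(.data$connectivity_bin,
                                     levels = c(as.character(0:5), ">5")))
  corr <- NULL
  if (!is.null(expression)) {
    counts <- left_join(counts,
                        select(expression, "gene", tpm = dplyr::all_of(tpm_col)),
                        by = "gene")
    bin_summary <- counts |>
      group_by(.data$connectivity_bin) |>
      summarise(n_genes = n(), mean_tpm = mean(.data$tpm, na.rm = TRUE),
                .groups = "drop")
    attr(counts, "bin_summary") <- bin_summary
    ok <- !is.na(counts$tpm)
    if (sum(ok) >= 3 && sd(counts$n_enhancers[ok]) > 0) {
      corr <- suppressWarnings(
        cor.test(counts$n_enhancers[ok], counts$tpm[ok], method = "spearman"))
      attr(counts, "correlation") <- tibble(rho = unname(corr$estimate),
                                            p_value = corr$p.value)
    }
  }
  counts
}

#' Hypergeometric overlap test between two gene sets
#'
#' @param set1,set2 Character vectors of genes, subsets of `universe`.
#' @param universe Character vector of all eligible genes.
#' @return Tibble with `overlap`, `expected`, `p_value` (upper tail).
#' @export
overlap_test <- function(set1, set2, universe) {
  if (length(universe) == 0) abort("empty universe")
  set1 <- unique(set1); set2 <- unique(set2); universe <- unique(universe)
  if (!all(set1 %in% universe) || !all(set2 %in% universe)) {
    abort("sets must be subsets of the universe")
  }
  k <- length(intersect(set1, set2))
  n <- length(universe)
  p <- phyper(k - 1, length(set1), n - length(set1), length(set2),
              lower.tail = FALSE)
  tibble(overlap = k,
         expected = length(set1) * length(set2) / n,
         p_value = p)
}
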