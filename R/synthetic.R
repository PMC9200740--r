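#' Specification for a synthetic two-condition Hi-C experiment
#'
#' Defines the generative model behind every recovery test: power-law
#' distance decay, checkerboard compartments, planted punctate loops,
#' planted distance-level pairwise enrichments (enhancer-promoter style),
#' uniform trans contacts, and per-condition effects (compartment sign
#' flips, loop fold changes, interaction fold changes). Contacts are drawn
#' by a single multinomial over all cell probabilities, so each replicate's
#' total equals `depth` exactly and equal-depth comparisons hold by
#' construction.
#'
#' Cell probabilities are proportional to
#' `d^-decay_exponent * (1 + gamma * e_i * e_j) * fold(loops) * fold(interactions)`
#' for cis pairs at bin separation `d >= 1`, and uniform across trans pairs
#' with total trans mass `trans_rate`.
#'
#' @param chrom_sizes Named vector of chromosome lengths in bp. The default
#'   is two 12.5-Mb toy chromosomes, one autosome and one X.
#' @param bin_size Bin width (bp).
#' @param depth Total contacts per replicate.
#' @param decay_exponent Power-law exponent of the distance decay.
#' @param gamma Checkerboard strength in `[0, 1)`.
#' @param compartment_period Square-wave period of the compartment profile,
#'   in bins.
#' @param n_loops Number of planted loops (split across chromosomes).
#' @param loop_fold Contact-probability multiplier at loop pixels.
#' @param n_interactions Number of planted pairwise enrichments.
#' @param interaction_fold Multiplier at interaction pixels.
#' @param trans_rate Fraction of contacts that are trans.
#' @param replicates Replicates per condition.
#' @param conditions Character vector of condition names.
#' @param flip_windows Tibble (`chrom`, `start_bin`, `end_bin`,
#'   chromosome-local bins) whose compartment sign is inverted in the second
#'   condition; NULL plants no compartment effect.
#' @param diff_loop_fold Fold applied in the second condition to the loops
#'   marked differential (see `n_diff_loops`).
#' @param n_diff_loops Number of loops whose fold changes in condition 2.
#' @param diff_interaction_fold,n_diff_interactions Same for interactions.
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec` (a list).
#' @export
synthetic_spec <- function(chrom_sizes = c(chr1 = 12.5e6, chrX = 12.5e6),
                           bin_size = 25000,
                           depth = 2e6,
                           decay_exponent = 1,
                           gamma = 0.4,
                           compartment_period = 40,
                           n_loops = 0,
                           loop_fold = 5,
                           n_interactions = 0,
                           interaction_fold = 5,
                           trans_rate = 0.26,
                           replicates = 3,
                           conditions = c("A", "B"),
                           flip_windows = NULL,
                           diff_loop_fold = 1,
                           n_diff_loops = 0,
                           diff_interaction_fold = 1,
                           n_diff_interactions = 0,
                           seed = 0) {
  stopifnot(decay_exponent > 0, gamma >= 0, gamma < 1, depth > 0,
            loop_fold >= 1, interaction_fold >= 1, trans_rate >= 0,
            trans_rate < 1, replicates >= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

# square-wave compartment profile for one chromosome; block edges are
# softened with a small Gaussian so transitions span a few bins, as real
# eigenvector profiles do (a knife-edge checkerboard would create
# pixel-scale corner artefacts no real map has)
square_wave <- function(n, period, edge_sigma = 1) {
  e <- rep_len(rep(c(1, -1), each = max(1L, period %/% 2L)), n)
  if (edge_sigma > 0) {
    r <- ceiling(3 * edge_sigma)
    k <- exp(-(-r:r)^2 / (2 * edge_sigma^2))
    k <- k / sum(k)
    pad <- c(rep(e[1], r), e, rep(e[n], r))
    e <- as.numeric(stats::filter(pad, k, sides = 2))[(r + 1):(r + n)]
    e <- e / max(abs(e))
  }
  e
}

# place planted pairs on a chromosome: anchors centered inside compartment
# half-blocks (so planted peaks never straddle a block edge), far from the
# diagonal, and on distinct lattice phases so loops and interactions never
# collide. Separation alternates between one and two half-periods.
plant_pairs <- function(n_bins, k, period = 40, phase = 0) {
  if (k == 0) return(tibble(bin1 = integer(), bin2 = integer()))
  half <- max(4L, period %/% 2L)
  slots <- seq(half %/% 2 + phase, n_bins - 2 * period, by = half)
  slots <- slots[slots >= half]
  if (length(slots) < k) abort("chromosome too short for the requested planted pairs")
  b1 <- slots[round(seq(1, length(slots), length.out = k))]
  sep <- ifelse(seq_len(k) %% 2 == 0, half, 2L * half)
  tibble(bin1 = as.integer(b1), bin2 = as.integer(b1 + sep))
}

#' Generate a synthetic two-condition Hi-C dataset
#'
#' Draws replicated contact maps per condition together with matching
#' annotation tracks (ATAC peaks, TSSs, stranded CTCF motifs), an
#' expression table with planted X escapees, and the ground-truth object
#' that recovery tests read.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `maps` (condition -> list of `contact_map`s),
#'   `bins`, `chromsizes`, `atac`, `tss`, `ctcf`, `expression`, and
#'   `truth`.
#' @export
generate_hic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sizes <- chromsizes(spec$chrom_sizes)
  bins <- make_bins(sizes, spec$bin_size)
  chroms <- sizes$name
  n_by_chrom <- map_int(chroms, ~ sum(bins$chrom == .x))
  names(n_by_chrom) <- chroms

  # latent compartment profile per chromosome (condition 1)
  e1 <- map(chroms, ~ square_wave(n_by_chrom[[.x]], spec$compartment_period))
  names(e1) <- chroms
  e2 <- e1
  if (!is.null(spec$flip_windows)) {
    for (r in seq_len(nrow(spec$flip_windows))) {
      fw <- spec$flip_windows[r, ]
      idx <- fw$start_bin:fw$end_bin
      e2[[fw$chrom]][idx] <- -e2[[fw$chrom]][idx]
    }
  }

  # planted loops / interactions, split round-robin over chromosomes
  alloc <- function(k, phase) {
    if (k == 0) return(tibble(chrom = character(), bin1 = integer(), bin2 = integer()))
    per <- diff(round(seq(0, k, length.out = length(chroms) + 1)))
    list_rbind(map(seq_along(chroms), function(ci) {
      p <- plant_pairs(n_by_chrom[[chroms[ci]]], per[ci],
                       period = spec$compartment_period, phase = phase)
      mutate(p, chrom = chroms[ci], .before = 1)
    }))
  }
  loops <- alloc(spec$n_loops, phase = 0)
  # interactions occupy a shifted lattice phase so they never collide
  ints <- alloc(spec$n_interactions, phase = 5)

  loops$fold_1 <- rep(spec$loop_fold, nrow(loops))
  loops$fold_2 <- loops$fold_1
  loops$differential <- FALSE
  if (spec$n_diff_loops > 0 && nrow(loops) > 0) {
    di <- seq_len(min(spec$n_diff_loops, nrow(loops)))
    loops$fold_2[di] <- spec$diff_loop_fold
    loops$differential[di] <- TRUE
  }
  ints$fold_1 <- rep(spec$interaction_fold, nrow(ints))
  ints$fold_2 <- ints$fold_1
  ints$differential <- FALSE
  if (spec$n_diff_interactions > 0 && nrow(ints) > 0) {
    di <- seq_len(min(spec$n_diff_interactions, nrow(ints)))
    ints$fold_2[di] <- spec$diff_interaction_fold
    ints$differential[di] <- TRUE
  }

  # cell probability table per condition
  build_cells <- function(cond_idx) {
    e <- if (cond_idx == 1) e1 else e2
    lf <- if (cond_idx == 1) loops$fold_1 else loops$fold_2
    itf <- if (cond_idx == 1) ints$fold_1 else ints$fold_2
    cis <- list_rbind(map(chroms, function(cc) {
      n <- n_by_chrom[[cc]]
      ij <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
      d <- ij[, 2] - ij[, 1]
      p <- d^(-spec$decay_exponent) *
        (1 + spec$gamma * e[[cc]][ij[, 1]] * e[[cc]][ij[, 2]])
      tibble(chrom1 = cc, i = ij[, 1], chrom2 = cc, j = ij[, 2], p = p)
    }))
    key <- paste(cis$chrom1, cis$i, cis$j)
    if (nrow(loops) > 0) {
      # punctate but not single-pixel: a narrow Gaussian footprint
      # (sigma 0.75 bins) around each loop pixel, full fold at the center
      off <- expand.grid(di = -2:2, dj = -2:2)
      fpw <- exp(-(off$di^2 + off$dj^2) / (2 * 0.75^2))
      for (k in seq_len(nrow(off))) {
        m <- match(paste(loops$chrom, loops$bin1 + off$di[k],
                         loops$bin2 + off$dj[k]), key)
        ok <- !is.na(m)
        cis$p[m[ok]] <- cis$p[m[ok]] * (1 + (lf[ok] - 1) * fpw[k])
      }
    }
    if (nrow(ints) > 0) {
      m <- match(paste(ints$chrom, ints$bin1, ints$bin2), key)
      cis$p[m] <- cis$p[m] * itf
    }
    cis$p <- cis$p / sum(cis$p) * (1 - spec$trans_rate)
    tr <- NULL
    if (spec$trans_rate > 0 && length(chroms) > 1) {
      combos <- utils::combn(chroms, 2)
      tr <- list_rbind(map(seq_len(ncol(combos)), function(k) {
        c1 <- combos[1, k]; c2 <- combos[2, k]
        g <- expand.grid(i = seq_len(n_by_chrom[[c1]]),
                         j = seq_len(n_by_chrom[[c2]]))
        tibble(chrom1 = c1, i = g$i, chrom2 = c2, j = g$j, p = 1)
      }))
      tr$p <- tr$p / sum(tr$p) * spec$trans_rate
    }
    bind_rows(cis, tr)
  }

  offs <- setNames(cumsum(c(0, n_by_chrom[-length(n_by_chrom)])), chroms)
  draw_map <- function(cells, n_rep) {
    counts <- rmultinom(n_rep, size = spec$depth, prob = cells$p)
    b1 <- offs[cells$chrom1] + cells$i
    b2 <- offs[cells$chrom2] + cells$j
    map(seq_len(n_rep), function(r) {
      keep <- counts[, r] > 0
      contact_map(bins, tibble(bin1 = b1[keep], bin2 = b2[keep],
                               count = counts[keep, r]))
    })
  }

  maps <- local_seed_eval(spec$seed, {
    out <- list()
    for (ci in seq_along(spec$conditions)) {
      cells <- build_cells(min(ci, 2))
      out[[spec$conditions[ci]]] <- draw_map(cells, spec$replicates)
    }
    out
  })

  ann <- synthetic_annotations(spec, bins, e1, loops, ints)

  truth <- list(
    compartments = list_rbind(map(chroms, function(cc) {
      tibble(chrom = cc, bin = seq_len(n_by_chrom[[cc]]),
             e_1 = e1[[cc]], e_2 = e2[[cc]],
             flipped = e1[[cc]] != e2[[cc]])
    })),
    loops = loops,
    interactions = ints,
    trans_rate = spec$trans_rate,
    escapees = ann$escapee_truth,
    spec = spec
  )

  list(maps = maps, bins = bins, chromsizes = sizes,
       atac = ann$atac, tss = ann$tss, ctcf = ann$ctcf,
       expression = ann$expression, truth = truth)
}

# annotation files consistent with the planted structure:
#  - ATAC peaks in every A-compartment bin, at loop anchors, and at planted
#    enhancer bins (interaction anchor 1)
#  - TSSs at planted promoter bins (interaction anchor 2) and in a sparse
#    background of A bins
#  - convergent CTCF motifs at loop anchors
#  - TPM table: connectivity-driven genes plus X escapees
synthetic_annotations <- function(spec, bins, e1, loops, ints) {
  bs <- spec$bin_size
  chroms <- names(e1)
  bin_center <- function(cc, b) (b - 1) * bs + bs / 2

  prom_bins <- ints |> select(chrom, bin = bin2) |> distinct()
  enh_bins <- ints |> select(chrom, bin = bin1) |> distinct()
  loop_anchor_bins <- bind_rows(
    select(loops, chrom, bin = bin1),
    select(loops, chrom, bin = bin2)
  ) |> distinct()

  # TSSs: planted promoters + background every 10th A bin (kept >= 2 bins
  # away from enhancer bins so the >10 kb proxy stays clean)
  bg_tss <- list_rbind(map(chroms, function(cc) {
    a_bins <- which(e1[[cc]] > 0)
    a_bins <- a_bins[seq_along(a_bins) %% 10 == 0]
    tibble(chrom = cc, bin = a_bins)
  }))
  near_enh <- function(tb) {
    if (nrow(enh_bins) == 0) return(rep(FALSE, nrow(tb)))
    map_lgl(seq_len(nrow(tb)), function(r) {
      any(enh_bins$chrom == tb$chrom[r] & abs(enh_bins$bin - tb$bin[r]) <= 2)
    })
  }
  bg_tss <- bg_tss[!near_enh(bg_tss), , drop = FALSE]
  tss_bins <- bind_rows(prom_bins, bg_tss) |> distinct() |> arrange(chrom, bin)
  tss <- tss_bins |>
    mutate(pos = bin_center(chrom, bin),
           name = paste0("gene_", chrom, "_", bin)) |>
    select(chrom, pos, name, bin)

  # ATAC peaks (400 bp, centered in the bin)
  atac_bins <- bind_rows(
    list_rbind(map(chroms, function(cc) tibble(chrom = cc, bin = which(e1[[cc]] > 0)))),
    loop_anchor_bins, enh_bins
  ) |> distinct() |> arrange(chrom, bin)
  atac <- atac_bins |>
    mutate(start = bin_center(chrom, bin) - 200,
           end = bin_center(chrom, bin) + 200,
           name = paste0("peak_", chrom, "_", bin)) |>
    select(chrom, start, end, name)

  # convergent CTCF motifs: + at anchor1, - at anchor2
  ctcf <- bind_rows(
    loops |> mutate(start = bin_center(chrom, bin1) - 10,
                    end = bin_center(chrom, bin1) + 9, strand = "+"),
    loops |> mutate(start = bin_center(chrom, bin2) - 10,
                    end = bin_center(chrom, bin2) + 9, strand = "-")
  ) |>
    select(chrom, start, end, strand) |>
    distinct() |>
    mutate(name = "CTCF", score = 0, .before = "strand")

  # expression: promoter genes with TPM rising in their planted
  # connectivity; X escapees follow the female-high rule, matched
  # non-escapee X genes do not
  conn <- ints |> group_by(chrom, bin = bin2) |> summarise(k = n(), .groups = "drop")
  genes <- tss |> left_join(conn, by = c("chrom", "bin")) |>
    mutate(k = ifelse(is.na(k), 0L, k))
  base_tpm <- 2^(genes$k) # monotone in connectivity
  expression <- tibble(
    gene = genes$name,
    female = base_tpm,
    male = base_tpm
  )
  escapee_truth <- tibble(gene = character(), escapee = logical())
  x_names <- genes$name[genes$chrom == "chrX"]
  if (length(x_names) >= 6) {
    esc <- x_names[1:3]; non <- x_names[4:6]
    expression$female[expression$gene %in% esc] <- 4
    expression$male[expression$gene %in% esc] <- 1.5
    expression$female[expression$gene %in% non] <- 4
    expression$male[expression$gene %in% non] <- 4
    escapee_truth <- tibble(gene = x_names[1:6],
                            escapee = x_names[1:6] %in% esc)
  }

  list(atac = atac, tss = tss, ctcf = ctcf, expression = expression,
       escapee_truth = escapee_truth)
}

#' Generate a matched null pair of conditions
#'
#' Two conditions drawn from identical parameters (no planted differential
#' effects), used to calibrate the differential callers' false-positive
#' rates.
#'
#' @param spec A [synthetic_spec()]; any condition effects in it are
#'   stripped.
#' @param seed Integer seed (overrides the spec's).
#' @return Same structure as [generate_hic()]; `truth` has zero
#'   differential flags.
#' @export
null_pair <- function(spec, seed = spec$seed) {
  spec$flip_windows <- NULL
  spec$n_diff_loops <- 0
  spec$n_diff_interactions <- 0
  spec$diff_loop_fold <- 1
  spec$diff_interaction_fold <- 1
  spec$seed <- seed
  generate_hic(spec)
}

#' Write a synthetic dataset to disk
#'
#' Emits triplet contact files per condition/replicate, BED annotations,
#' the TPM table, and the truth object as JSON-free plain TSVs.
#'
#' @param sim Output of [generate_hic()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cond in names(sim$maps)) {
    for (r in seq_along(sim$maps[[cond]])) {
      write_contacts(sim$maps[[cond]][[r]],
                     file.path(dir, sprintf("contacts_%s_rep%d.tsv", cond, r)))
    }
  }
  write_bed(sim$atac, file.path(dir, "atac_peaks.bed"))
  write_bed(mutate(sim$tss, start = pos, end = pos + 1),
            file.path(dir, "tss.bed"))
  write_bed(sim$ctcf, file.path(dir, "ctcf_motifs.bed"))
  write.table(sim$expression, file.path(dir, "expression_tpm.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(
    data.frame(name = sim$chromsizes$name,
               length = format(sim$chromsizes$length, scientific = FALSE, trim = TRUE)),
    file.path(dir, "chrom.sizes"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
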