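#' Pipeline configuration with the canonical thresholds
#'
#' All defaults are the published analysis parameters: 25-kb compartments
#' with the 0.42 quartile-shift threshold, 10-kb loops at FDR 0.01 merged
#' at 25 kb, differential rule z > 2 and fold >= 2.5, interactions at
#' q < 0.05 with 20-kb loop exclusion, the >10-kb TSS enhancer proxy, and
#' the escapee rule TPM >= 1 with >= 1.5-fold female excess.
#'
#' @param tau Differential-compartment threshold on eigenvector deltas.
#' @param loop_fdr Loop-caller BH threshold.
#' @param merge_radius Master-list merge radius (bp).
#' @param min_z,min_fold Differential signal and fold thresholds.
#' @param q_max Interaction q-value threshold.
#' @param exclusion_radius Loop-exclusion radius for interactions (bp).
#' @param enhancer_dist Enhancer proxy distance from TSS (bp).
#' @param escapee_tpm,escapee_fold Escapee rule thresholds.
#' @param seed Seed for the stochastic steps (downsampling).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(tau = 0.42, loop_fdr = 0.01, merge_radius = 25000,
                            min_z = 2, min_fold = 2.5, q_max = 0.05,
                            exclusion_radius = 20000, enhancer_dist = 10000,
                            escapee_tpm = 1, escapee_fold = 1.5, seed = 0) {
  cfg <- as.list(environment())
  stopifnot(all(map_lgl(cfg, ~ is.numeric(.x) && .x >= 0)))
  structure(cfg, class = "pipeline_config")
}

#' Run the full multi-level differential analysis
#'
#' Orchestrates the three levels on a two-condition (or more) dataset:
#' equal-depth downsampling and per-condition pooling; balancing and
#' distance normalization; compartment eigenvectors and differential
#' compartments (with X-vs-autosome comparison); loop calling, master-list
#' merge, differential loops and anchor annotation; significant
#' interactions with loop exclusion, classification, differential calls and
#' gene connectivity; escapee calls when expression and X genes exist.
#' Deterministic given the config seed.
#'
#' @param data A list shaped like [generate_hic()] output: `maps`
#'   (condition -> list of `contact_map` replicates), `bins`, plus optional
#'   `atac`, `tss`, `ctcf`, `expression`.
#' @param config A [pipeline_config()].
#' @return A list of class `hic_report` holding each stage's tibble.
#' @export
run_pipeline <- function(data, config = pipeline_config()) {
  conds <- names(data$maps)
  stopifnot(length(conds) >= 1)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # replicate QC on raw replicates
  rep_z <- NULL
  all_reps <- unlist(data$maps, recursive = FALSE)
  rep_groups <- rep(conds, times = map_int(data$maps, length))
  if (length(all_reps) >= 2) {
    rep_z <- stage("replicate_qc", {
      zs <- map(all_reps, ~ distance_normalize(.x, use_weights = FALSE))
      names(zs) <- paste0(rep_groups, "_rep", unlist(map(data$maps, seq_along)))
      replicate_distances(zs, groups = rep_groups)
    })
  }

  # pool replicates, downsample to the shallowest condition
  pooled <- stage("pooling", map(data$maps, pool_maps))
  depth <- min(map_dbl(pooled, ~ .x$total))
  pooled <- stage("downsampling", imap(pooled, function(m, nm) {
    downsample_map(m, depth, seed = config$seed + match(nm, conds))
  }))
  balanced <- stage("balancing", map(pooled, balance_map))
  zmaps <- stage("normalization", map(balanced, distance_normalize))

  cis_trans <- stage("cis_trans", {
    list_rbind(imap(pooled, function(m, nm) {
      tf <- trans_fraction(m, by_chromosome = TRUE)
      mutate(tf, condition = nm, .before = 1)
    }))
  })

  # compartments
  orient <- data$atac %||% data$tss
  eigen_tracks <- stage("compartments",
                        map(balanced, call_eigenvector, orient_track = orient))
  diffs <- NULL; x_vs_auto <- NULL
  if (length(conds) >= 2) {
    diffs <- stage("diff_compartments",
                   diff_compartments(eigen_tracks[[1]], eigen_tracks[[2]],
                                     tau = config$tau))
    if (any(diffs$chrom %in% c("chrX", "X")) && any(!diffs$chrom %in% c("chrX", "X"))) {
      x_vs_auto <- stage("x_vs_autosomes", compare_groups(diffs))
    }
  }

  # loops
  loop_sets <- stage("loops", map(zmaps, call_loops, fdr = config$loop_fdr))
  master <- stage("master_merge", merge_master(loop_sets, radius = config$merge_radius))
  dloops <- NULL
  if (length(conds) >= 2 && nrow(master) > 0) {
    dloops <- stage("diff_loops",
                    diff_loops(master, zmaps[[1]], zmaps[[2]],
                               min_z = config$min_z, min_fold = config$min_fold,
                               labels = conds[1:2]))
  }
  anchors <- NULL
  if (nrow(master) > 0) {
    anchors <- stage("anchor_annotation",
                     annotate_anchors(master, atac = data$atac, ctcf = data$ctcf))
  }

  # interactions
  ints <- stage("interactions",
                call_significant(pooled[[1]], q_max = config$q_max,
                                 zmap = zmaps[[1]]))
  ints <- stage("loop_exclusion",
                exclude_loops(ints, master, radius = config$exclusion_radius))
  bin_ann <- NULL; connectivity <- NULL
  if (!is.null(data$atac) && !is.null(data$tss)) {
    bin_ann <- stage("bin_annotation",
                     annotate_bins(data$bins, data$atac, data$tss,
                                   enhancer_dist = config$enhancer_dist))
    ints <- stage("classification", classify_interactions(ints, bin_ann))
    if (!is.null(data$expression) && "bin" %in% names(data$tss)) {
      gp <- tibble(gene = data$tss$name, chrom = data$tss$chrom, bin = data$tss$bin)
      connectivity <- stage("gene_connectivity",
                            gene_connectivity(ints, gp, bin_ann,
                                              expression = data$expression))
    }
  }
  dints <- NULL
  if (length(conds) >= 2 && nrow(ints) > 0) {
    dints <- stage("diff_interactions",
                   diff_interactions(ints, zmaps[[1]], zmaps[[2]],
                                     min_z = config$min_z,
                                     min_fold = config$min_fold,
                                     labels = conds[1:2]))
  }

  escapees <- NULL
  if (!is.null(data$expression) &&
      all(c("female", "male") %in% names(data$expression)) &&
      !is.null(data$tss) && any(data$tss$chrom %in% c("chrX", "X"))) {
    xg <- data$tss$name[data$tss$chrom %in% c("chrX", "X")]
    xg <- intersect(xg, data$expression$gene)
    if (length(xg) > 0) {
      escapees <- stage("escapees",
                        call_escapees(data$expression, "female", "male", xg,
                                      min_tpm = config$escapee_tpm,
                                      min_fold = config$escapee_fold))
    }
  }

  if (length(conds) < 2) {
    inform("single condition: differential stages skipped")
  }

  structure(
    list(config = config, conditions = conds, depth = depth,
         replicate_qc = rep_z, cis_trans = cis_trans,
         eigen_tracks = eigen_tracks, diff_compartments = diffs,
         x_vs_autosomes = x_vs_auto,
         loops = loop_sets, master_loops = master, diff_loops = dloops,
         anchor_annotation = anchors,
         interactions = ints, diff_interactions = dints,
         connectivity = connectivity, escapees = escapees),
    class = "hic_report"
  )
}

#' @export
print.hic_report <- function(x, ...) {
  g <- glance(x)
  cat("<hic_report>\n")
  for (nm in names(g)) cat(sprintf("  %s: %s\n", nm, format(g[[nm]])))
  invisible(x)
}

#' One-row numeric summary of a pipeline report
#'
#' @param x An `hic_report`.
#' @param ... Unused.
#' @return A one-row tibble of headline counts.
#' @export
glance.hic_report <- function(x, ...) {
  tibble(
    conditions = paste(x$conditions, collapse = ","),
    depth = x$depth,
    cis_fraction = mean(x$cis_trans$cis_fraction),
    n_master_loops = if (is.null(x$master_loops)) 0L else nrow(x$master_loops),
    n_diff_loops = if (is.null(x$diff_loops)) NA_integer_ else sum(x$diff_loops$flagged),
    n_diff_compartment_bins = if (is.null(x$diff_compartments)) NA_integer_ else
      sum(x$diff_compartments$flagged),
    n_interactions = if (is.null(x$interactions)) 0L else nrow(x$interactions),
    n_diff_interactions = if (is.null(x$diff_interactions)) NA_integer_ else
      sum(x$diff_interactions$flagged),
    n_escapees = if (is.null(x$escapees)) NA_integer_ else sum(x$escapees$flagged)
  )
}

#' Write a report's tables to disk
#'
#' Emits bedGraph eigenvector tracks, BED of flagged differential bins,
#' BEDPE loop and interaction tables, and TSV summaries. Every number in
#' the printed summary traces to one of these files.
#'
#' @param report An `hic_report`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$eigen_tracks)) {
    write_bedgraph(report$eigen_tracks[[nm]],
                   file.path(dir, sprintf("eigenvector_%s.bedgraph", nm)),
                   value = "e")
  }
  if (!is.null(report$diff_compartments)) {
    flagged <- filter(report$diff_compartments, .data$flagged)
    write_bed(select(flagged, "chrom", "start", "end"),
              file.path(dir, "differential_compartment_bins.bed"))
    write.table(attr(report$diff_compartments, "summary"),
                file.path(dir, "diff_compartment_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  bedpe_of <- function(x) {
    mutate(x, chrom1 = .data$chrom, chrom2 = .data$chrom) |>
      select("chrom1", "start1", "end1", "chrom2", "start2", "end2",
             dplyr::any_of(c("z", "q", "category", "convergence",
                             "z_a", "z_b", "fold", "direction", "flagged")))
  }
  if (!is.null(report$master_loops) && nrow(report$master_loops) > 0) {
    write_bedpe(bedpe_of(report$master_loops), file.path(dir, "master_loops.bedpe"))
  }
  if (!is.null(report$diff_loops)) {
    write_bedpe(bedpe_of(report$diff_loops), file.path(dir, "diff_loops.bedpe"))
  }
  if (!is.null(report$interactions) && nrow(report$interactions) > 0) {
    write_bedpe(bedpe_of(report$interactions), file.path(dir, "interactions.bedpe"))
  }
  if (!is.null(report$diff_interactions)) {
    write_bedpe(bedpe_of(report$diff_interactions),
                file.path(dir, "diff_interactions.bedpe"))
  }
  if (!is.null(report$connectivity)) {
    write.table(report$connectivity, file.path(dir, "gene_connectivity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$escapees)) {
    write.table(report$escapees, file.path(dir, "escapees.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(as.data.frame(glance(report)), file.path(dir, "summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
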