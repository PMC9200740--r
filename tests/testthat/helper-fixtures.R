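# Lazily built, cached synthetic fixtures shared across test files.
# Everything is generated in code at test time; nothing is stored on disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- maker()
  .fixtures[[name]]
}

# 10-kb two-chromosome world used by loop/interaction tests
loop_world <- function(seed = 1, n_loops = 12, n_interactions = 0,
                       loop_fold = 5, ...) {
  synthetic_spec(chrom_sizes = c(chr1 = 5e6, chrX = 5e6), bin_size = 10000,
                 n_loops = n_loops, n_interactions = n_interactions,
                 loop_fold = loop_fold, seed = seed, ...)
}

fx_loop_sim <- function() {
  fixture("loop_sim", function() {
    sim <- generate_hic(loop_world(seed = 2))
    sim$z <- distance_normalize(balance_map(sim$maps$A[[1]]))
    sim
  })
}

fx_int_sim <- function() {
  fixture("int_sim", function() {
    sim <- generate_hic(loop_world(seed = 2, n_loops = 0, n_interactions = 12))
    sim$map <- sim$maps$A[[1]]
    sim$z <- distance_normalize(balance_map(sim$map))
    sim
  })
}

# 25-kb two-condition world with planted compartment flips and
# differential loops/interactions, plus the full pipeline report
fx_diff_sim <- function() {
  fixture("diff_sim", function() {
    spec <- synthetic_spec(
      n_loops = 12, n_interactions = 12, seed = 5,
      flip_windows = tibble::tibble(chrom = "chrX",
                                    start_bin = c(161, 241, 321),
                                    end_bin = c(200, 280, 360)),
      n_diff_loops = 4, diff_loop_fold = 1,
      n_diff_interactions = 4, diff_interaction_fold = 1
    )
    generate_hic(spec)
  })
}

fx_diff_report <- function() {
  fixture("diff_report", function() run_pipeline(fx_diff_sim()))
}

# small deterministic contact map: two chromosomes, smooth decay, no noise
toy_map <- function(n = 40, chroms = c(toyA = NULL), decay = function(d) 100 / (d + 1)) {
  sizes <- chromsizes(c(toy = n * 1000))
  bins <- make_bins(sizes, 1000)
  ij <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  px <- tibble::tibble(bin1 = ij[, 1], bin2 = ij[, 2],
                       count = decay(ij[, 2] - ij[, 1]))
  contact_map(bins, px)
}

# random contact map over one chromosome
random_map <- function(n = 50, seed = 42, lambda = 5) {
  withr::with_seed(seed, {
    sizes <- chromsizes(c(rnd = n * 1000))
    bins <- make_bins(sizes, 1000)
    ij <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
    px <- tibble::tibble(bin1 = ij[, 1], bin2 = ij[, 2],
                         count = stats::rpois(nrow(ij), lambda))
    contact_map(bins, px)
  })
}

# brute-force per-diagonal mean of a dense symmetric matrix (all bins kept)
brute_expected <- function(M) {
  n <- nrow(M)
  vapply(0:(n - 1), function(d) {
    i <- seq_len(n - d)
    mean(M[cbind(i, i + d)])
  }, numeric(1))
}

# brute-force single-linkage transitive closure of loop merging
brute_merge_clusters <- function(loops, radius) {
  n <- nrow(loops)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- loops$chrom[i] == loops$chrom[j] &&
      abs(loops$start1[i] - loops$start1[j]) <= radius &&
      abs(loops$start2[i] - loops$start2[j]) <= radius
  }
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0 | reach
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  match(apply(reach, 1, function(r) paste(which(r), collapse = ",")),
        unique(apply(reach, 1, function(r) paste(which(r), collapse = ","))))
}
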