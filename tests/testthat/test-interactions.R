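test_that("significant interactions recover planted enrichments", {
  sim <- fx_int_sim()
  ints <- call_significant(sim$map, zmap = sim$z)
  tr <- sim$truth$interactions
  hit <- vapply(seq_len(nrow(tr)), function(r) {
    any(ints$chrom == tr$chrom[r] & ints$bin1 == tr$bin1[r] &
          ints$bin2 == tr$bin2[r])
  }, logical(1))
  expect_gte(mean(hit), 0.8)
  expect_true(all(ints$q < 0.05))
  expect_true(all(ints$p <= ints$q))
  # BH monotonicity: q non-decreasing when ordered by p
  o <- order(ints$p)
  expect_true(all(diff(ints$q[o]) >= -1e-12))
})

test_that("the distance model controls the false-positive rate under the null", {
  fracs <- vapply(1:5, function(s) {
    m <- generate_hic(loop_world(seed = 40 + s, n_loops = 0, gamma = 0))$maps$A[[1]]
    ints <- call_significant(m)
    nrow(ints) / attr(ints, "params")$n_tested
  }, numeric(1))
  expect_lte(mean(fracs), 2 * 0.05)
})

test_that("an all-zero map yields zero interactions", {
  bins <- make_bins(chromsizes(c(z = 50000)), 10000)
  m <- contact_map(bins, tibble::tibble(bin1 = integer(), bin2 = integer(),
                                        count = numeric()))
  expect_equal(nrow(call_significant(m)), 0)
})

mk_ints <- function(chrom, s1, s2, bin_size = 10000) {
  tibble::tibble(chrom = chrom,
                 bin1 = s1 / bin_size + 1, bin2 = s2 / bin_size + 1,
                 count = 10, expected_p = 1e-6, p = 1e-4, q = 1e-3,
                 start1 = s1, end1 = s1 + bin_size,
                 start2 = s2, end2 = s2 + bin_size)
}

test_that("loop exclusion removes interactions within 20 kb of a loop", {
  loops <- tibble::tibble(chrom = "c1", start1 = 100000, start2 = 500000)
  ints <- mk_ints("c1", c(100000, 120000, 130000, 80000),
                  c(500000, 520000, 530000, 470000))
  kept <- exclude_loops(ints, loops, radius = 20000)
  # exact pixel and both-anchors-at-20kb removed; 30-kb one kept
  expect_equal(kept$start1, c(130000, 80000))
  expect_equal(attr(kept, "n_excluded"), 2)

  # radius 0 removes only the exact pixel
  kept0 <- exclude_loops(ints, loops, radius = 0)
  expect_equal(nrow(kept0), 3)

  # never increases the count; brute-force agreement on random sets
  set.seed(13)
  ri <- mk_ints("c1", sample(0:400, 300, TRUE) * 10000,
                (sample(0:400, 300, TRUE) + 450) * 10000)
  rl <- tibble::tibble(chrom = "c1", start1 = sample(0:400, 80, TRUE) * 10000,
                       start2 = (sample(0:400, 80, TRUE) + 450) * 10000)
  got <- exclude_loops(ri, rl, radius = 20000)
  drop <- vapply(seq_len(nrow(ri)), function(i) {
    any(abs(rl$start1 - ri$start1[i]) <= 20000 &
          abs(rl$start2 - ri$start2[i]) <= 20000)
  }, logical(1))
  expect_equal(nrow(got), sum(!drop))
  expect_lte(nrow(got), nrow(ri))
})

test_that("bin annotation applies the distal-peak enhancer proxy", {
  bins <- make_bins(chromsizes(c(c1 = 100000)), 10000)
  tss <- tibble::tibble(chrom = "c1", pos = 5000)
  atac <- tibble::tibble(chrom = "c1",
                         start = c(4000, 14000, 30000, 90000),
                         end = c(4400, 14400, 30400, 90400))
  ann <- annotate_bins(bins, atac, tss, enhancer_dist = 10000)
  expect_true(ann$has_promoter[1])
  expect_false(ann$has_enhancer[1])      # promoter bin can never be enhancer
  expect_false(ann$has_enhancer[2])      # peak ~10 kb from the TSS: too close
  expect_true(ann$has_enhancer[4])       # far peak
  expect_false(any(ann$has_enhancer & ann$has_promoter))

  # boundary: gap of exactly 10 kb is not ">10 kb"
  atac_b <- tibble::tibble(chrom = "c1", start = c(15001, 15002),
                           end = c(15101, 15102))
  d <- nearest_point_distance(atac_b, tss)
  expect_equal(d, c(10000, 10001))
  ann_b <- annotate_bins(bins, atac_b, tss, enhancer_dist = 10000)
  # bin 2 holds both peaks; only the >10-kb one makes it an enhancer bin
  expect_true(ann_b$has_enhancer[2])
  ann_b1 <- annotate_bins(bins, atac_b[1, ], tss, enhancer_dist = 10000)
  expect_false(ann_b1$has_enhancer[2])
})

test_that("interaction categories partition into E-P / E-E / P-P / other", {
  bins <- make_bins(chromsizes(c(c1 = 100000)), 10000)
  tss <- tibble::tibble(chrom = "c1", pos = c(5000, 15000))
  atac <- tibble::tibble(chrom = "c1", start = c(45000, 55000),
                         end = c(45400, 55400))
  ann <- annotate_bins(bins, atac, tss)
  ints <- mk_ints("c1", c(0, 0, 40000, 40000, 80000),
                  c(40000, 10000, 50000, 80000, 90000))
  cl <- classify_interactions(ints, ann)
  expect_equal(cl$category, c("E-P", "P-P", "E-E", "other", "other"))
  expect_true(all(table(cl$category) ==
                    attr(cl, "category_counts")$n[order(attr(cl, "category_counts")$category)]))

  # synthetic truth: planted pairs classify as E-P
  sim <- fx_int_sim()
  ann2 <- annotate_bins(sim$bins, sim$atac, sim$tss)
  tr <- sim$truth$interactions
  planted <- mk_ints(tr$chrom, (tr$bin1 - 1) * 10000, (tr$bin2 - 1) * 10000)
  cl2 <- classify_interactions(planted, ann2)
  expect_true(all(cl2$category == "E-P"))
})

test_that("differential interactions share the loop rule and its boundaries", {
  ints <- mk_ints("c1", 190000, 390000)
  za <- function(v) {
    Z <- matrix(1, 60, 60); Z[20, 40] <- Z[40, 20] <- v
    bins <- make_bins(chromsizes(c(c1 = 600000)), 10000)
    structure(list(bins = bins, z = list(c1 = Z),
                   obs = list(c1 = matrix(10, 60, 60)),
                   expected = list(c1 = rep(10, 60)),
                   mask = list(c1 = rep(TRUE, 60)), total = 1000,
                   use_weights = FALSE), class = "dist_norm")
  }
  expect_true(diff_interactions(ints, za(3.0), za(1.0))$flagged)
  expect_false(diff_interactions(ints, za(2.4), za(1.0))$flagged) # fold 2.4
  expect_false(diff_interactions(ints, za(1.9), za(0.5))$flagged) # max z <= 2

  # null pair: flagged fraction under 1%
  np <- fixture("null_pair", function() {
    null_pair(synthetic_spec(n_loops = 12, n_interactions = 12, seed = 11),
              seed = 11)
  })
  pool <- lapply(np$maps, function(x) balance_map(pool_maps(x)))
  zs <- lapply(pool, distance_normalize)
  ints2 <- call_significant(pool$A, zmap = zs$A)
  di <- diff_interactions(ints2, zs$A, zs$B)
  expect_lt(mean(di$flagged), 0.01)
})

test_that("gene connectivity counts distinct enhancers and tracks expression", {
  bins <- make_bins(chromsizes(c(c1 = 200000)), 10000)
  tss <- tibble::tibble(chrom = "c1", pos = 5000)
  atac <- tibble::tibble(chrom = "c1", start = (3:19) * 10000 + 2000,
                         end = (3:19) * 10000 + 2400)
  ann <- annotate_bins(bins, atac, tss)
  gp <- tibble::tibble(gene = "g1", chrom = "c1", bin = 1)
  # six enhancer links -> ">5" bin
  ints <- mk_ints("c1", rep(0, 6), (4:9) * 10000)
  cl <- classify_interactions(ints, ann)
  gc <- gene_connectivity(cl, gp, ann)
  expect_equal(gc$n_enhancers, 6)
  expect_equal(as.character(gc$connectivity_bin), ">5")

  # no E-P interactions at all -> zero counts
  gc0 <- gene_connectivity(cl[0, ], gp, ann)
  expect_equal(gc0$n_enhancers, 0)

  # synthetic: expression rises with planted connectivity
  sim <- fx_int_sim()
  ann2 <- annotate_bins(sim$bins, sim$atac, sim$tss)
  tr <- sim$truth$interactions
  planted <- classify_interactions(
    mk_ints(tr$chrom, (tr$bin1 - 1) * 10000, (tr$bin2 - 1) * 10000), ann2)
  gp2 <- tibble::tibble(gene = sim$tss$name, chrom = sim$tss$chrom,
                        bin = sim$tss$bin)
  gc2 <- gene_connectivity(planted, gp2, ann2, expression = sim$expression)
  corr <- attr(gc2, "correlation")
  expect_gt(corr$rho, 0)
  expect_lt(corr$p_value, 0.05)
})

test_that("gene-set overlaps follow the hypergeometric model", {
  u <- paste0("g", 1:2000)
  s1 <- u[1:250]
  expect_equal(overlap_test(s1, s1, u)$overlap, 250)
  expect_lt(overlap_test(s1, s1, u)$p_value, 1e-100)

  s2 <- u[251:430]
  expect_equal(overlap_test(s1, s2, u)$overlap, 0)
  expect_error(overlap_test(s1, s2, character()), "empty universe")
  expect_error(overlap_test(c(s1, "nope"), s2, u), "subsets")

  # random sets: mean overlap within 3 SE of |s1||s2|/N = 22.5
  set.seed(19)
  ovs <- replicate(1000, {
    a <- sample(u, 250); b <- sample(u, 180)
    length(intersect(a, b))
  })
  expect_lt(abs(mean(ovs) - 22.5), 3 * sd(ovs) / sqrt(1000))
  # and the test is calibrated against those draws
  p_mid <- overlap_test(sample(u, 250), sample(u, 180), u)$p_value
  expect_gt(p_mid, 1e-6)
})
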