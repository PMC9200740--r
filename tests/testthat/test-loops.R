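test_that("a single extreme pixel on a flat background yields exactly one loop", {
  n <- 120
  bins <- make_bins(chromsizes(c(fl = n * 1000)), 1000)
  ij <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  cnt <- rep(20, nrow(ij))
  cnt[ij[, 1] == 40 & ij[, 2] == 80] <- 1000 # z ~ 50 on a flat field
  m <- contact_map(bins, tibble::tibble(bin1 = ij[, 1], bin2 = ij[, 2],
                                        count = cnt))
  z <- distance_normalize(m, use_weights = FALSE)
  loops <- call_loops(z)
  expect_equal(nrow(loops), 1)
  expect_equal(c(loops$bin1, loops$bin2), c(40, 80))
})

test_that("planted loops are recovered with high recall and precision", {
  sim <- fx_loop_sim()
  loops <- call_loops(sim$z)
  tr <- sim$truth$loops
  hit <- vapply(seq_len(nrow(tr)), function(r) {
    any(loops$chrom == tr$chrom[r] & abs(loops$bin1 - tr$bin1[r]) <= 1 &
          abs(loops$bin2 - tr$bin2[r]) <= 1)
  }, logical(1))
  tp <- vapply(seq_len(nrow(loops)), function(r) {
    any(tr$chrom == loops$chrom[r] & abs(tr$bin1 - loops$bin1[r]) <= 1 &
          abs(tr$bin2 - loops$bin2[r]) <= 1)
  }, logical(1))
  expect_gte(mean(hit), 0.9)
  expect_gte(mean(tp), 0.9)
})

test_that("loop calls are stable under uniform count scaling", {
  sim <- fx_loop_sim()
  loops1 <- call_loops(sim$z)
  m <- sim$maps$A[[1]]
  m3 <- contact_map(m$bins, dplyr::mutate(m$pixels, count = count * 3))
  z3 <- distance_normalize(balance_map(m3))
  loops3 <- call_loops(z3)
  key <- function(x) paste(x$chrom, x$bin1, x$bin2)
  # every call at the original depth is still called at triple depth
  expect_true(all(key(loops1) %in% key(loops3)))
})

mk_loopset <- function(chrom, s1, s2, z = 1, bin_size = 10000) {
  x <- tibble::tibble(chrom = chrom,
                      bin1 = s1 / bin_size + 1, bin2 = s2 / bin_size + 1,
                      z = z, p = 0.001, q = 0.001,
                      start1 = s1, end1 = s1 + bin_size,
                      start2 = s2, end2 = s2 + bin_size)
  class(x) <- c("loop_set", class(x))
  x
}

test_that("master merging applies the 25-kb rule by single linkage", {
  a <- mk_loopset("c1", 100000, 500000, z = 3)
  b20 <- mk_loopset("c1", 120000, 520000, z = 2)
  b30 <- mk_loopset("c1", 130000, 530000, z = 2)

  expect_equal(nrow(merge_master(list(a, b20))), 1)
  expect_equal(nrow(merge_master(list(a, b30))), 2)
  # representative is the strongest member
  expect_equal(merge_master(list(a, b20))$z, 3)

  # idempotence
  m1 <- merge_master(list(a, b20, b30))
  expect_equal(nrow(merge_master(m1)), nrow(m1))

  # brute-force transitive closure on random loop sets
  set.seed(4)
  rnd <- mk_loopset("c1",
                    s1 = sample(0:200, 120, TRUE) * 10000,
                    s2 = (sample(0:200, 120, TRUE) + 300) * 10000,
                    z = runif(120, 1, 5))
  got <- merge_master(list(rnd), radius = 25000)
  want_k <- length(unique(brute_merge_clusters(rnd, 25000)))
  expect_equal(nrow(got), want_k)
})

fake_z <- function(vals, n = 60, chrom = "c1") {
  Z <- matrix(1, n, n)
  for (v in vals) Z[v[1], v[2]] <- Z[v[2], v[1]] <- v[3]
  bins <- make_bins(chromsizes(setNames(n * 10000, chrom)), 10000)
  structure(list(bins = bins, z = setNames(list(Z), chrom),
                 obs = setNames(list(matrix(10, n, n)), chrom),
                 expected = setNames(list(rep(10, n)), chrom),
                 mask = setNames(list(rep(TRUE, n)), chrom),
                 total = 1000, use_weights = FALSE),
            class = "dist_norm")
}

test_that("the differential rule needs both signal > 2 and fold >= 2.5", {
  master <- mk_loopset("c1", 190000, 390000)
  za <- fake_z(list(c(20, 40, 2.6)))
  zb10 <- fake_z(list(c(20, 40, 1.0)))
  zb12 <- fake_z(list(c(20, 40, 1.2)))

  d1 <- diff_loops(master, za, zb10)
  expect_true(d1$flagged)            # fold 2.6, max z 2.6
  expect_equal(d1$direction, "A-specific")
  expect_equal(d1$fold, 2.6)

  d2 <- diff_loops(master, za, zb12)
  expect_false(d2$flagged)           # fold ~2.17 < 2.5

  # weak signal never flags even at huge fold
  d3 <- diff_loops(master, fake_z(list(c(20, 40, 1.9))),
                   fake_z(list(c(20, 40, 0.4))))
  expect_false(d3$flagged)

  # self-comparison flags nothing
  d4 <- diff_loops(master, za, za)
  expect_false(any(d4$flagged))
})

test_that("differential signal is read as the 3x3 neighborhood maximum", {
  master <- mk_loopset("c1", 190000, 390000)
  # peak drifted one bin: still read
  za <- fake_z(list(c(21, 41, 3.0)))
  d <- diff_loops(master, za, fake_z(list()))
  expect_equal(d$z_a, 3.0)
  expect_true(d$flagged)
})

test_that("anchor annotation composes ATAC/CTCF categories and orientation", {
  loops <- mk_loopset("c1", 100000, 400000)
  atac <- tibble::tibble(chrom = "c1", start = c(102000, 401000),
                         end = c(102500, 401500))
  ctcf <- tibble::tibble(chrom = "c1", start = c(103000, 402000),
                         end = c(103020, 402020),
                         name = "CTCF", score = 0, strand = c("+", "-"))
  ann <- annotate_anchors(loops, atac, ctcf)
  expect_equal(ann$category, "both")
  expect_equal(ann$convergence, "convergent")

  # no annotations at all
  ann0 <- annotate_anchors(loops)
  expect_equal(ann0$category, "neither")
  expect_equal(ann0$convergence, "ambiguous")

  # tandem and divergent orientations
  ctcf_t <- dplyr::mutate(ctcf, strand = c("+", "+"))
  expect_equal(annotate_anchors(loops, atac, ctcf_t)$convergence, "tandem")
  ctcf_d <- dplyr::mutate(ctcf, strand = c("-", "+"))
  expect_equal(annotate_anchors(loops, atac, ctcf_d)$convergence, "divergent")

  # generator-planted anchors are convergent by construction
  sim <- fx_loop_sim()
  tr <- sim$truth$loops
  planted <- mk_loopset(tr$chrom, (tr$bin1 - 1) * 10000, (tr$bin2 - 1) * 10000)
  ap <- annotate_anchors(planted, sim$atac, sim$ctcf)
  expect_true(all(ap$convergence == "convergent"))
  expect_true(all(ap$category == "both"))
})

test_that("APA scores a flat map at 1 and planted loops near their fold", {
  flat <- fake_z(list(), n = 100)
  sites <- tibble::tibble(chrom = "c1", bin1 = c(20, 30), bin2 = c(60, 80))
  a <- apa(flat, sites)
  expect_equal(a$score, 1)
  expect_equal(a$n_sites, 2)

  # all sites hugging the diagonal are rejected
  near <- tibble::tibble(chrom = "c1", bin1 = 20, bin2 = 25)
  expect_error(apa(flat, near), "excluded")

  sim3 <- fixture("apa_sim", function() {
    s <- generate_hic(loop_world(seed = 3, loop_fold = 3))
    s$z <- distance_normalize(balance_map(s$maps$A[[1]]))
    s
  })
  ap <- apa(sim3$z, sim3$truth$loops)
  expect_gte(ap$score, 2.4)
  expect_lte(ap$score, 3.6)

  # random (non-loop) sites on the same map aggregate to ~1
  rnd <- withr::with_seed(9, tibble::tibble(
    chrom = sample(c("chr1", "chrX"), 40, TRUE),
    bin1 = sample(30:300, 40)))
  rnd$bin2 <- rnd$bin1 + withr::with_seed(10, sample(30:60, 40, TRUE))
  ar <- apa(sim3$z, rnd)
  expect_gte(ar$score, 0.9)
  expect_lte(ar$score, 1.1)
})

test_that("insulation dips at the junction of two independent blocks", {
  n <- 80
  bins <- make_bins(chromsizes(c(bk = n * 1000)), 1000)
  ij <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  same_block <- (ij[, 1] <= 40) == (ij[, 2] <= 40)
  cnt <- ifelse(same_block, 50, 1)
  m <- balance_map(contact_map(bins, tibble::tibble(bin1 = ij[, 1],
                                                    bin2 = ij[, 2],
                                                    count = cnt)))
  ins <- insulation(m, window = 10)
  expect_equal(ins$bin[which.min(ins$insulation)], 40, tolerance = 1)

  # a uniform map is flat
  mu <- balance_map(toy_map(60, decay = function(d) 30))
  iu <- insulation(mu, window = 10)
  expect_lt(max(abs(iu$insulation), na.rm = TRUE), 0.05)

  expect_error(insulation(mu, window = 40), "window exceeds")
})

test_that("aggregate domain analysis enriches the interior of planted blocks", {
  sim <- fx_loop_sim()
  # same-sign compartment blocks act as interaction domains
  e <- sim$truth$compartments
  doms <- tibble::tibble(chrom = "chr1",
                         start_bin = seq(41, 361, by = 80),
                         end_bin = seq(60, 380, by = 80))
  ada <- aggregate_domains(sim$z, doms)
  expect_gt(ada$interior_mean, ada$exterior_mean)
})
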