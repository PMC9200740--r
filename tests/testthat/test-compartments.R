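# deterministic checkerboard map: counts = f(d) * (1 + g * e_i * e_j)
checker_map <- function(n = 80, period = 40, g = 0.9) {
  e <- rep_len(rep(c(1, -1), each = period / 2), n)
  bins <- make_bins(chromsizes(c(ck = n * 1000)), 1000)
  ij <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  d <- ij[, 2] - ij[, 1]
  cnt <- 1000 / (d + 1) * (1 + g * e[ij[, 1]] * e[ij[, 2]])
  list(map = contact_map(bins, tibble::tibble(bin1 = ij[, 1], bin2 = ij[, 2],
                                              count = cnt)),
       e = e, bins = bins)
}

test_that("a perfect checkerboard yields an exactly block-matched eigenvector", {
  ck <- checker_map()
  mb <- balance_map(ck$map)
  # orient with a peak in every positive-block bin
  act <- tibble::tibble(chrom = "ck", start = which(ck$e > 0) * 1000 - 600,
                        end = which(ck$e > 0) * 1000 - 400)
  ev <- call_eigenvector(mb, orient_track = act)
  expect_false(any(ev$masked))
  expect_equal(sign(ev$e), ck$e)
  expect_equal(ev$label, ifelse(ck$e > 0, "A", "B"))
  expect_equal(sd(ev$e), 1)
})

test_that("eigenvector recovery beats 95% sign agreement on noisy data", {
  sim <- fixture("comp_sim", function() generate_hic(synthetic_spec(seed = 3)))
  mb <- balance_map(sim$maps$A[[1]])
  ev <- call_eigenvector(mb, orient_track = sim$atac)
  tr <- sim$truth$compartments
  ok <- !ev$masked & !is.na(ev$e)
  agreement <- mean(sign(ev$e[ok]) == sign(tr$e_1[ok]))
  expect_gte(agreement, 0.95)
})

test_that("eigenvector is invariant to uniform scaling of the counts", {
  ck <- checker_map(60)
  m1 <- balance_map(ck$map)
  px <- ck$map$pixels
  m3 <- balance_map(contact_map(ck$map$bins,
                                dplyr::mutate(px, count = count * 3)))
  act <- tibble::tibble(chrom = "ck", start = which(ck$e > 0) * 1000 - 600,
                        end = which(ck$e > 0) * 1000 - 400)
  e1 <- call_eigenvector(m1, orient_track = act)$e
  e3 <- call_eigenvector(m3, orient_track = act)$e
  expect_equal(e1, e3, tolerance = 1e-6)
})

test_that("degenerate chromosomes are masked with a warning", {
  m <- toy_map(30, decay = function(d) 10)
  mb <- balance_map(m)
  expect_warning(ev <- call_eigenvector(mb), "skipped|usable")
  expect_true(all(ev$masked))
})

fake_track <- function(e, chrom = "t") {
  x <- tibble::tibble(chrom = chrom, bin = seq_along(e),
                      start = (seq_along(e) - 1) * 25000,
                      end = seq_along(e) * 25000, e = e,
                      label = ifelse(e > 0, "A", "B"),
                      masked = is.na(e))
  attr(x, "bin_size") <- 25000
  class(x) <- c("eigen_track", class(x))
  x
}

test_that("the quartile-shift rule flags exactly |delta| > tau", {
  a <- fake_track(c(0.5, 0.3, -0.2, NA, 1))
  b <- fake_track(c(0.0, 0.0, -0.2, 0.1, 1))
  d <- suppressWarnings(diff_compartments(a, b, tau = 0.42))
  expect_equal(d$flagged, c(TRUE, FALSE, FALSE, FALSE, FALSE))

  # self-comparison flags nothing
  d0 <- diff_compartments(a, a)
  expect_equal(sum(d0$flagged), 0)

  # auto mode derives tau from the pooled interquartile distance
  set.seed(1)
  e <- rnorm(2000)
  aa <- fake_track(e); bb <- fake_track(e + rnorm(2000, sd = 0.05))
  dauto <- diff_compartments(aa, bb, tau = "auto")
  expect_equal(attr(dauto, "tau"), IQR(c(aa$e, bb$e)))
})

test_that("flagged span bookkeeping ties Mb to flagged bins times bin size", {
  sim <- fx_diff_sim()
  rep <- fx_diff_report()
  dc <- rep$diff_compartments
  summ <- attr(dc, "summary")
  expect_equal(summ$mb, summ$n_flagged * 25000 / 1e6)

  # planted 120-bin flip window on chrX is recovered at >= 90%
  tr <- sim$truth$compartments
  win <- dc$chrom == "chrX" & tr$flipped[match(paste(dc$chrom, dc$bin),
                                               paste(tr$chrom, tr$bin))]
  expect_gte(mean(dc$flagged[win], na.rm = TRUE), 0.9)
  # and the false-flag rate elsewhere stays low
  expect_lt(mean(dc$flagged[!win], na.rm = TRUE), 0.02)
})

test_that("X-versus-autosome comparison behaves under null and planted shifts", {
  # null: no p-value inflation over repeated draws
  set.seed(6)
  ps <- replicate(30, {
    d <- fake_track(rnorm(200))
    d2 <- fake_track(rnorm(200))
    dd <- suppressWarnings(diff_compartments(d, d2, tau = 0.42))
    dd$chrom <- rep(c("chr1", "chrX"), each = 100)
    compare_groups(dd)$p_value
  })
  expect_lt(mean(ps < 0.05), 0.2)

  # planted X-only flips separate the groups
  rep <- fx_diff_report()
  expect_lt(rep$x_vs_autosomes$p_value, 0.05)
  expect_gt(rep$x_vs_autosomes$median_group1, rep$x_vs_autosomes$median_group2)

  # single-bin groups use the exact small-sample path without error
  a <- fake_track(c(0.9, 0.1)); b <- fake_track(c(0.2, 0.1))
  d <- suppressWarnings(diff_compartments(a, b))
  d$chrom <- c("chrX", "chr1")
  expect_s3_class(compare_groups(d), "tbl_df")
  expect_error(compare_groups(d, partition = c(TRUE, TRUE)), "empty")
})

test_that("direction concordance is 1 on identity, 0 on negation, ~0.5 on noise", {
  set.seed(8)
  a <- fake_track(rnorm(500)); b <- fake_track(rnorm(500))
  d1 <- suppressWarnings(diff_compartments(a, b))
  d2_same <- d1
  expect_equal(direction_concordance(d1, d2_same)$agreement, 1)

  neg <- d1
  neg$delta <- -neg$delta
  expect_equal(direction_concordance(d1, neg)$agreement, 0)

  # independent noise: agreement near 1/2 (deltas from disjoint tracks)
  cc <- fake_track(rnorm(500)); dd <- fake_track(rnorm(500))
  d3 <- suppressWarnings(diff_compartments(cc, dd))
  res <- direction_concordance(d1, d3)
  se <- sqrt(0.25 / res$n_bins)
  expect_lt(abs(res$agreement - 0.5), 4 * se + 0.05)

  # nothing flagged -> undefined, reported as such
  z1 <- diff_compartments(fake_track(rep(0.1, 10)), fake_track(rep(0.1, 10)))
  expect_message(out <- direction_concordance(z1, z1), "undefined")
  expect_true(is.na(out$agreement))
})

test_that("gene-level eigenvector signal is the length-weighted bin mean", {
  tr <- fake_track(c(1, -1, 0.5, 2))
  # gene inside one bin
  g1 <- tibble::tibble(chrom = "t", start = 1000, end = 2000)
  expect_equal(gene_eigen(tr, g1)$e, 1)
  # gene spanning two bins 25% / 75%
  g2 <- tibble::tibble(chrom = "t", start = 18750, end = 43750)
  expect_equal(gene_eigen(tr, g2)$e, (0.25 * 1 + 0.75 * (-1)) / 1)
  # oracle: random genes against a brute-force overlap computation
  set.seed(12)
  e <- rnorm(100)
  trk <- fake_track(e)
  gs <- tibble::tibble(chrom = "t", start = sample(0:(95 * 25000), 100))
  gs$end <- gs$start + sample.int(120000, 100)
  gs$end <- pmin(gs$end, 100 * 25000)
  got <- gene_eigen(trk, gs)$e
  want <- vapply(seq_len(100), function(i) {
    ov <- pmin(trk$end, gs$end[i]) - pmax(trk$start, gs$start[i])
    sel <- ov > 0
    sum(e[sel] * ov[sel]) / sum(ov[sel])
  }, numeric(1))
  expect_equal(got, want)
})
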