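# Windowed F_ST from heterozygosities and between-strain diversity.

test_that("per-site F_ST matches its defining cases", {
  expect_equal(fst_site(0.3, 0.3)$fst, 0)
  expect_equal(fst_site(0, 1)$fst, 1)
  # (p1-p2)^2 / (4 pbar (1-pbar)) = 0.36 / 1.0
  expect_equal(fst_site(0.2, 0.8)$fst, 0.36)
  expect_true(is.na(fst_site(0, 0)$fst))     # H_T = 0 flagged undefined
  expect_error(fst_site(1.2, 0.5), "outside")
})

test_that("the heterozygosity identity H_T - H_S = (p1-p2)^2/2 holds", {
  set.seed(5150)
  p1 <- runif(1e5); p2 <- runif(1e5)
  h <- fst_site(p1, p2)
  expect_lt(max(abs((h$H_T - h$H_S) - (p1 - p2)^2 / 2)), 1e-12)
})

test_that("window aggregation is a ratio of sums with NA conventions", {
  h <- fst_site(rep(0, 5), rep(1, 5))
  expect_equal(fst_window(h$H_T, h$H_S), 1)
  expect_true(is.na(fst_window(numeric(0), numeric(0))))
  expect_true(is.na(fst_window(c(0, 0), c(0, 0))))
  # single-SNP window equals the per-site value
  one <- fst_site(0.2, 0.8)
  expect_equal(fst_window(one$H_T, one$H_S), one$fst)
  expect_equal(fst_window(one$H_T, one$H_S, method = "mean_of_ratios"),
               one$fst)
})

test_that("d_xy matches its defining cases", {
  expect_equal(dxy_window(1, 0, 10), 0.1)
  expect_equal(dxy_window(rep(1, 4), rep(1, 4), 100), 0)
  expect_equal(dxy_window(0.5, 0.5, 1), 0.5)
  expect_error(dxy_window(0.5, 0.5, 0), "length")
})

test_that("windows tile an arm on the step grid", {
  sites <- make_sites("2L", c(500L, 15000L), freq_R = 1, freq_C = 0)
  sc <- scan_genome(sites, c("2L" = 20000L), window = 10000L, step = 1000L)
  expect_identical(nrow(sc), 11L)
  expect_identical(sc$start, seq(1L, 10001L, by = 1000L))
  expect_true(all(sc$end == sc$start + 9999L))
  # a trailing partial window appears when the arm overhangs the grid
  sc2 <- scan_genome(sites, c("2L" = 20500L), window = 10000L, step = 1000L)
  expect_identical(nrow(sc2), 12L)
  expect_identical(sc2$end[12], 20500L)
  expect_identical(sc2$start[12], 11001L)
})

test_that("scan equals a brute-force per-window recomputation", {
  set.seed(77)
  n <- 1000
  sites <- make_sites("2L", sort(sample.int(50000L, n)),
                      freq_R = runif(n), freq_C = runif(n))
  sc <- scan_genome(sites, c("2L" = 50000L), window = 10000L, step = 1000L)
  for (i in sample.int(nrow(sc), 12)) {
    w <- sites[sites$pos >= sc$start[i] & sites$pos <= sc$end[i], ]
    h1 <- 2 * w$freq_R * (1 - w$freq_R)
    h2 <- 2 * w$freq_C * (1 - w$freq_C)
    pb <- (w$freq_R + w$freq_C) / 2
    ht <- 2 * pb * (1 - pb)
    hs <- (h1 + h2) / 2
    expect_identical(sc$n_snps[i], nrow(w))
    expect_equal(sc$fst[i], (sum(ht) - sum(hs)) / sum(ht), tolerance = 1e-12)
    expect_equal(sc$dxy[i],
                 sum(w$freq_R * (1 - w$freq_C) + w$freq_C * (1 - w$freq_R)) /
                   (sc$end[i] - sc$start[i] + 1),
                 tolerance = 1e-12)
  }
  # estimates bounded in [0, 1] or NA
  expect_true(all(is.na(sc$fst) | (sc$fst >= 0 & sc$fst <= 1)))
})

test_that("doubling the step yields a subset of the original windows", {
  set.seed(78)
  n <- 400
  sites <- make_sites("2L", sort(sample.int(40000L, n)),
                      freq_R = runif(n), freq_C = runif(n))
  a <- scan_genome(sites, c("2L" = 40000L), window = 10000L, step = 1000L)
  b <- scan_genome(sites, c("2L" = 40000L), window = 10000L, step = 2000L)
  key <- function(d) paste(d$arm, d$start, d$end)
  expect_true(all(key(b) %in% key(a)))
  m <- match(key(b), key(a))
  expect_equal(b$fst, a$fst[m])
  expect_equal(b$dxy, a$dxy[m])
})

test_that("monomorphic genomes flag nothing and arm U is excluded", {
  sites <- make_sites(c("2L", "2L", "U"), c(100L, 200L, 50L),
                      freq_R = c(0.5, 0.5, 1), freq_C = c(0.5, 0.5, 0))
  sc <- scan_genome(sites, c("2L" = 20000L, "U" = 10000L))
  expect_false(any(sc$arm == "U"))
  expect_false(any(sc$extreme))   # identical frequencies, F_ST = 0
  # unsorted input is an error, never silently sorted
  bad <- make_sites("2L", c(200L, 100L))
  expect_error(scan_genome(bad, c("2L" = 20000L)), "sorted")
})

test_that("a strongly selected locus is flagged extreme", {
  cfg <- sim_config(arm_names = "2L", genome_length = 1e5, n_genes = 0,
                    generations = 150, mutation_rate = 1e-8,
                    selected_loci = data.frame(arm = "2L", pos = 50000,
                                               s = 0.2),
                    seed = 1001)
  sim <- simulate_study(cfg)
  sc <- scan_genome(sim$sites, c("2L" = 1e5))
  hit <- sc[sc$start <= 50000 & sc$end >= 50000, ]
  expect_true(any(hit$extreme))
})
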