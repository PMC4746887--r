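test_that("jc_correct matches the closed form and its series expansion", {
  expect_equal(jc_correct(0), 0)
  ## independent evaluation of the printed formula K = -300/4 ln(1 - 4D/300)
  grid <- seq(0, 70, by = 0.5)
  expect_equal(jc_correct(grid), -300 / 4 * log(1 - grid * 4 / 300),
               tolerance = 1e-12)
  ## series oracle K = sum_n D^n / (n * 75^(n-1)) from -75 log(1 - D/75)
  D <- 10
  n <- 1:12
  series <- sum(D^n / (n * 75^(n - 1)))
  expect_equal(jc_correct(10), series, tolerance = 1e-9)
  ## domain
  expect_true(is.finite(jc_correct(74.9)))
  expect_error(jc_correct(75), "domain")
  expect_error(jc_correct(-1), "non-negative")
})

test_that("jc_correct is increasing, convex, and bounded below by D", {
  d <- seq(0, 74, by = 0.25)
  k <- jc_correct(d)
  expect_true(all(diff(k) > 0))
  expect_true(all(diff(diff(k)) > 0))
  expect_true(all(k[-1] > d[-1]))
  expect_equal(k[1], 0)
})

test_that("substitution rates round-trip through measurement and correction", {
  ## evolve 100 kb at k substitutions/site (Poisson, with multiple hits),
  ## measure the raw mismatch proportion, correct it back
  withr::with_seed(64, {
    anc <- rand_dna(100000)
    for (k in c(0.05, 0.10, 0.20)) {
      D <- realized_divergence(evolve_jc(anc, k), anc)
      expect_lt(abs(jc_correct(D) - 100 * k), 0.5)
    }
  })
})

test_that("landscape bins hit bp by corrected divergence", {
  hits <- data.frame(start = 1, end = 500, divergence_D = 9.0,
                     te_class = "DNA", stringsAsFactors = FALSE)
  out <- landscape(hits, genome_length = 50000)
  expect_equal(nrow(out), 1L)
  expect_equal(out$k_low, 9)  # K(9) = 9.57 -> bin [9,10)
  expect_equal(out$bp, 500)
  expect_equal(out$genome_fraction, 0.01)
  ## all-zero divergence collapses to [0,1)
  h0 <- data.frame(start = c(1, 1000), end = c(400, 1400),
                   divergence_D = 0, te_class = "DNA",
                   stringsAsFactors = FALSE)
  out0 <- landscape(h0, 50000)
  expect_equal(out0$k_low, 0)
  expect_equal(out0$bp, 801)
})

test_that("landscape conserves mass and diverts uncorrectable hits", {
  withr::with_seed(65, {
    n <- 50
    hits <- data.frame(
      start = seq(1, by = 1000, length.out = n),
      end = seq(1, by = 1000, length.out = n) + sample(50:400, n, TRUE),
      divergence_D = c(stats::runif(n - 2, 0, 40), 80, 76),
      te_class = sample(c("DNA", "LINE"), n, TRUE),
      stringsAsFactors = FALSE)
    expect_warning(out <- landscape(hits, 1e6), "spill")
    good <- hits$divergence_D < 75
    expect_equal(sum(out$bp) + attr(out, "spill_bp"),
                 sum(hits$end - hits$start + 1))
    for (cl in unique(hits$te_class[good])) {
      expect_equal(sum(out$bp[out$group == cl]),
                   sum((hits$end - hits$start + 1)[good &
                                                     hits$te_class == cl]))
    }
  })
})

test_that("end-to-end landscape peaks at the planted divergence", {
  ## 10% point-mass simulation -> mask -> landscape: modal K bin in [9,12)
  sim <- small_sim(seed = 66, copies = 60, glen = 250000)
  hits <- mask_genome(sim$genome, sim$library)
  out <- landscape(hits, 250000, group_by = "superfamily")
  peak <- out[which.max(out$bp), ]
  expect_gte(peak$k_low, 9)
  expect_lt(peak$k_low, 12)
  expect_identical(peak$group, "hAT")
})

test_that("coverage rollup reproduces additive totals", {
  children <- data.frame(count = c(3, 2), bp = c(300, 200))
  tot <- coverage_rollup(children, genome_length = 10000)
  expect_equal(tot$count, 5)
  expect_equal(tot$bp, 500)
  expect_equal(tot$pct, 5)
})

test_that("coverage_table is hierarchical and exactly additive", {
  withr::with_seed(67, {
    hits <- data.frame(
      start = seq(1, by = 500, length.out = 40),
      end = seq(1, by = 500, length.out = 40) + 99,
      divergence_D = 5,
      te_class = rep(c("DNA", "DNA", "LINE", "LTR"), 10),
      superfamily = rep(c("hAT", "TcMar", "L2", NA), 10),
      stringsAsFactors = FALSE)
    tab <- coverage_table(hits, 100000)
    ## parent = sum of children, at every level
    for (p in unique(tab$group[tab$level == 1])) {
      kids <- tab[tab$level == 2 & tab$parent == p, ]
      par <- tab[tab$level == 1 & tab$group == p, ]
      expect_equal(sum(kids$count), par$count)
      expect_equal(sum(kids$bp), par$bp)
    }
    tot <- tab[tab$level == 0, ]
    expect_equal(tot$count, 40L)
    expect_equal(tot$bp, 4000)
    expect_equal(tot$pct, 4)
    ## NA superfamily reported as Unclassified
    expect_true("Unclassified" %in% tab$group[tab$level == 2])
    expect_equal(nrow(coverage_table(empty_hits(), 1000)), 0L)
  })
})

test_that("size~TE regression recovers closed-form slope and correlation", {
  pts <- data.frame(species = c("a", "b", "c", "d"),
                    genome_size = c(350, 460, 870, 1370),
                    te_fraction = c(7.1, 14.2, 33.7, 56.5))
  got <- size_te_regression(pts)
  ## hand-computed covariance oracle
  sx <- pts$genome_size; sy <- pts$te_fraction
  slope <- sum((sx - mean(sx)) * (sy - mean(sy))) / sum((sx - mean(sx))^2)
  r <- sum((sx - mean(sx)) * (sy - mean(sy))) /
    sqrt(sum((sx - mean(sx))^2) * sum((sy - mean(sy))^2))
  expect_equal(got$slope, slope)
  expect_equal(got$pearson_r, r)
  expect_gt(got$pearson_r, 0)
  ## collinear points: |r| = 1
  lin <- data.frame(species = c("a", "b", "c"),
                    genome_size = c(100, 200, 300),
                    te_fraction = c(5, 10, 15))
  expect_equal(abs(size_te_regression(lin)$pearson_r), 1)
  expect_error(size_te_regression(pts[1:2, ]), "at least 3")
  flat <- transform(lin, te_fraction = 5)
  expect_error(size_te_regression(flat), "zero variance")
})
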