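test_that("initiation probability is bounded and monotone in both arguments", {
  expect_equal(initiation_prob(0, 5), 0)
  expect_equal(initiation_prob(1, log(2)), 0.5)
  expect_lte(initiation_prob(1, 50), 1)
  expect_gt(initiation_prob(1, 50), 0.999)
  s <- seq(0, 1, by = 0.1)
  expect_true(all(diff(initiation_prob(s, 2)) > 0))
  es <- c(0.5, 1, 2, 4)
  expect_true(all(diff(initiation_prob(0.3, es)) > 0))
})

test_that("expected distribution implements flux depletion and survival", {
  # single certain site at step 0 captures the whole flux
  m <- scan_model(c(1), efficiency = 50, continuation = 1, flux = 1000)
  ed <- expected_distribution(m)
  expect_equal(ed$expected[1], 1000 * initiation_prob(1, 50))
  # uniform p with c < 1 decays geometrically with ratio c(1-p)
  p <- 0.1; c <- 0.9
  s <- rep(-log(1 - p), 30)  # strengths chosen so p_k = 0.1 exactly
  mu <- expected_distribution(scan_model(s, efficiency = 1,
                                         continuation = c,
                                         flux = 1e6))$expected
  ratio <- mu[-1] / mu[-length(mu)]
  expect_equal(ratio, rep(c * (1 - p), length(ratio)), tolerance = 1e-9)
  # normalized geometric: median step 3, p10 0, p90 10, spread 11 at r=0.81
  longer <- expected_distribution(scan_model(rep(-log(1 - p), 401),
                                             efficiency = 1,
                                             continuation = c,
                                             flux = 1e6))$expected
  expect_equal(percentile_position(longer, 50, offsets = 0:400), 3L)
  expect_equal(percentile_position(longer, 10, offsets = 0:400), 0L)
  expect_equal(percentile_position(longer, 90, offsets = 0:400), 10L)
  expect_equal(tss_spread(longer, offsets = 0:400), 11L)
})

test_that("a hard processivity cap truncates the expected distribution", {
  s <- rep(0.05, 50)
  capped <- scan_model(s, continuation = 0.99, flux = 1e4, max_distance = 20)
  mu <- expected_distribution(capped)
  expect_true(all(mu$expected[mu$step > 20] == 0))
  expect_gt(mu$expected[mu$step == 20], 0)
})

test_that("simulation conserves forays and matches expectation", {
  # deterministic corner cases
  m1 <- scan_model(c(1), efficiency = 1e6, continuation = 1, flux = 1000,
                   seed = 4)
  out1 <- simulate_scan(m1)
  expect_equal(out1$counts$count[1], 1000)
  expect_equal(out1$n_no_product, 0)
  m0 <- scan_model(rep(0, 20), flux = 500, seed = 4)
  out0 <- simulate_scan(m0)
  expect_equal(sum(out0$counts$count), 0)
  expect_equal(out0$n_no_product, 500)

  # conservation on random models, every run
  set.seed(19)
  for (i in 1:10) {
    m <- scan_model(runif(60, 0, 0.2), efficiency = runif(1, 0.5, 2),
                    continuation = runif(1, 0.9, 1), flux = 2000,
                    seed = sample.int(1e6, 1))
    out <- simulate_scan(m)
    expect_identical(sum(out$counts$count) + out$n_no_product, m$flux)
  }

  # multinomial agreement with the closed form at deep flux: 4 sigma bands
  m <- scan_model(rep(-log(0.9), 100), continuation = 0.9, flux = 1e6,
                  seed = 2024)
  out <- simulate_scan(m)
  q <- out$counts$expected / m$flux
  sigma <- sqrt(m$flux * q * (1 - q))
  dev <- abs(out$counts$count - out$counts$expected)
  expect_true(all(dev <= 4 * sigma + 3))  # +3 covers near-empty cells
})

test_that("seeded simulation is reproducible and leaves the session RNG alone", {
  m <- scan_model(runif(50, 0, 0.1), flux = 5000, seed = 77)
  a <- simulate_scan(m); b <- simulate_scan(m)
  expect_identical(a$counts$count, b$counts$count)
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_scan(m)); after <- runif(1)
  expect_identical(before, after)
})

test_that("efficiency up shifts expected distributions upstream and narrower", {
  # uniform-strength closed form: E2 > E1 implies median and spread shrink
  s <- rep(0.05, 200)
  for (c in c(0.95, 0.99)) {
    med <- spr <- numeric(0)
    for (E in c(0.5, 1, 2, 4)) {
      mu <- expected_distribution(scan_model(s, efficiency = E,
                                             continuation = c,
                                             flux = 1e6))$expected
      med <- c(med, percentile_position(mu, 50, offsets = 0:199))
      spr <- c(spr, tss_spread(mu, offsets = 0:199))
    }
    expect_true(all(diff(med) <= 0))
    expect_true(all(diff(spr) <= 0))
  }
})

test_that("higher continuation widens and shifts expected distributions downstream", {
  s <- rep(0.02, 200)
  med <- spr <- numeric(0)
  for (c in c(0.9, 0.95, 0.99)) {
    mu <- expected_distribution(scan_model(s, continuation = c,
                                           flux = 1e6))$expected
    med <- c(med, percentile_position(mu, 50, offsets = 0:199))
    spr <- c(spr, tss_spread(mu, offsets = 0:199))
  }
  expect_true(all(diff(med) > 0))
  expect_true(all(diff(spr) > 0))
})

test_that("lowering continuation truncates multiplicatively, sparing step 0", {
  set.seed(8)
  s <- runif(100, 0, 0.1)
  c1 <- 0.93; c2 <- 0.99
  mu1 <- expected_distribution(scan_model(s, continuation = c1,
                                          flux = 1e6))$expected
  mu2 <- expected_distribution(scan_model(s, continuation = c2,
                                          flux = 1e6))$expected
  ok <- mu2 > 0
  k <- (0:99)[ok]
  expect_equal(mu1[ok] / mu2[ok], (c1 / c2)^k, tolerance = 1e-9)
  expect_equal(mu1[1], mu2[1])  # step 0 untouched
  # normalized upstream usage increases under truncation
  expect_gt(mu1[ok][1] / sum(mu1), mu2[ok][1] / sum(mu2))
})

test_that("simulate agrees with the closed form across an (E, c) sweep", {
  set.seed(31)
  s <- runif(80, 0, 0.12)
  for (E in c(0.5, 1, 2)) {
    for (c in c(0.85, 0.95, 1.0)) {
      m <- scan_model(s, efficiency = E, continuation = c, flux = 2e5,
                      seed = round(E * 1000 + c * 100))
      out <- simulate_scan(m)
      q <- out$counts$expected / m$flux
      sigma <- sqrt(m$flux * q * (1 - q))
      expect_true(all(abs(out$counts$count - out$counts$expected) <=
                        4 * sigma + 3))
    }
  }
})

test_that("emitted libraries round-trip exactly through the count table", {
  set.seed(6)
  pset <- synthetic_promoters(6, seed = 12)
  lib <- emit_library(pset, "wt", flux = 5e3, seed = 3)
  ct <- build_count_table(lib, pset$promoters)
  # rebuild the per-promoter simulated counts independently
  for (i in seq_len(nrow(pset$promoters))) {
    pr <- pset$promoters[i, ]
    model <- scan_model(pset$strengths[[pr$promoter_id]], flux = 5e3,
                        seed = (3 * 10007 + i) %% 2147483647)
    sim <- simulate_scan(model)$counts
    row <- as.integer(ct[i, as.character(sim$offset)])
    expect_identical(row, sim$count)
  }
})

test_that("minus-strand promoters yield mirrored positions but identical rows", {
  pset <- synthetic_promoters(2, seed = 9)
  pset$promoters$strand <- c("+", "-")
  pset$strengths[[2]] <- pset$strengths[[1]]
  lib <- emit_library(pset, "wt", flux = 2e3, seed = 5)
  # same seed per promoter index differs, so equalize: simulate directly
  m <- scan_model(pset$strengths[[1]], flux = 2e3, seed = 1)
  sim <- simulate_scan(m)$counts
  plus_sig <- tibble::tibble(chrom = "chrS1", strand = "+",
                             pos = pset$promoters$anchor[1] + sim$offset,
                             count = sim$count)
  minus_sig <- tibble::tibble(chrom = "chrS1", strand = "-",
                              pos = pset$promoters$anchor[2] - sim$offset,
                              count = sim$count)
  both <- as_stranded_signal(dplyr::bind_rows(plus_sig, minus_sig))
  ct <- build_count_table(both, pset$promoters)
  expect_identical(as.numeric(ct[1, -1]), as.numeric(ct[2, -1]))
})

test_that("replicate libraries at deep flux correlate strongly", {
  pset <- synthetic_promoters(20, seed = 2)
  r1 <- emit_library(pset, "wt", flux = 1e4, depth_factor = 10, seed = 101)
  r2 <- emit_library(pset, "wt", flux = 1e4, depth_factor = 10, seed = 202)
  expect_gt(correlate_pair(r1, r2), 0.9)
})

test_that("overlapping synthetic promoters are rejected by the generator", {
  expect_error(synthetic_promoters(5, spacing = 300), "overlap")
  expect_error(emit_library(synthetic_promoters(2), depth_factor = 0),
               "depth_factor")
})
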