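test_that("binning follows the half-open convention with 1.0 in the last bin", {
  bd <- bin_relative_positions(c(0.05, 0.05, 0.95, 1.0))
  expect_equal(bd$counts, c(2, 0, 0, 0, 0, 0, 0, 0, 0, 2))
  expect_equal(bin_relative_positions(0.1)$counts[2], 1)  # edge goes right
  expect_error(bin_relative_positions(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(sum(bin_relative_positions(numeric(0))$counts), 0)
  # uniform fill: each bin within 4 SD of n/10
  set.seed(12)
  bu <- bin_relative_positions(runif(10000))
  expect_true(all(abs(bu$counts - 1000) < 4 * sqrt(10000 * 0.1 * 0.9)))
})

test_that("KL divergence matches closed forms and errors on empty-Q support", {
  flat <- rep(1, 10)
  expect_equal(kl_divergence(flat, flat), 0)
  expect_equal(kl_divergence(c(1, rep(0, 9)), flat), log(10))
  expect_equal(round(kl_divergence(c(0.2, 0.8), c(0.5, 0.5)), 4), 0.1927)
  expect_error(kl_divergence(c(1, 1), c(2, 0)), "infinite divergence")
  expect_equal(kl_divergence(c(1, 1), c(2, 0), pseudocount = TRUE),
               sum(c(0.5, 0.5) * log(c(0.5, 0.5) / c(5/6, 1/6))))
  expect_error(kl_divergence(c(0, 0), c(1, 1)), "no observations")
  expect_error(kl_divergence(c(1, 1, 1), c(1, 1)), "same number of bins")
})

test_that("plug-in KL agrees with the high-precision oracle", {
  set.seed(33)
  for (k in 1:200) {
    p <- rmultinom(1, 500, runif(10) + 0.05)[, 1]
    q <- p + rpois(10, 3) + 1  # guarantees support
    expect_equal(kl_divergence(p, q), kl_oracle(p, q), tolerance = 1e-12)
    expect_gte(kl_divergence(p, q), 0)
  }
  # zero iff equal
  expect_identical(kl_divergence(c(3, 7), c(3, 7)), 0)
})

test_that("kl_to_flat reports per-chromosome and pooled divergences", {
  map <- toy_map()
  ev <- data.frame(individual = "i1", chrom = "c1", left_marker = "m1",
                   right_marker = "m2", start = 0, end = 5e6,
                   point = rep(5e5, 12))
  # all events in bin 1 of c1 -> ln 10 there; c2 has none -> NA
  expect_message(kf <- kl_to_flat(ev, map), "zero crossovers")
  expect_equal(unname(kf$per_chromosome["c1"]), log(10))
  expect_true(is.na(kf$per_chromosome["c2"]))
  expect_equal(kf$pooled, log(10))
  # perfectly flat counts give zero
  ev2 <- ev[1:10, ]
  ev2$point <- seq(0.05, 0.95, by = 0.1) * 1e7
  expect_equal(suppressMessages(kl_to_flat(ev2, map))$per_chromosome[["c1"]], 0)
})

test_that("distal landscapes diverge more from flatness than flat ones", {
  wins <- 0L
  for (k in 1:10) {
    d <- sim_pop("distal", n = 300, seed = 400 + k)$pop
    f <- sim_pop("flat", n = 300, seed = 500 + k)$pop
    wins <- wins + (kl_to_flat(d)$pooled > kl_to_flat(f)$pooled)
  }
  expect_gte(wins, 10 * 0.95)
})

test_that("flatness p-value is exact for degenerate cases and reproducible", {
  # observed KL = 0 exactly -> p = 1
  pos <- rep(seq(0.05, 0.95, by = 0.1), 3)
  fp <- flatness_pvalue(pos, n_randomizations = 200, seed = 1)
  expect_equal(fp$kl, 0)
  expect_equal(fp$p_value, 1)
  # all positions in one bin is never matched by 500-crossover null draws
  fp2 <- flatness_pvalue(rep(0.01, 500), n_randomizations = 1000, seed = 2)
  expect_lte(fp2$p_value, 1 / 1000)
  expect_output(print(fp2), "< 0.001")
  # seed determinism
  x <- runif(200)
  a <- flatness_pvalue(x, n_randomizations = 300, seed = 9)
  b <- flatness_pvalue(x, n_randomizations = 300, seed = 9)
  expect_identical(a$p_value, b$p_value)
})

test_that("the null KL to flatness shrinks with crossover count", {
  set.seed(61)
  kl_at <- function(n) median(replicate(60, {
    kl <- meiodiv:::kl_to_uniform(bin_relative_positions(runif(n))$counts)
  }))
  expect_lt(kl_at(5000), kl_at(500))
})

test_that("bootstrap of a statistic is consistent and deterministic", {
  pop <- sim_pop(n = 200, seed = 71)$pop
  # constant statistic -> degenerate distribution
  cst <- bootstrap_kl_distribution(pop, function(ev, n, map) 4.2, B = 50, seed = 1)
  expect_true(all(cst == 4.2))
  # mean-crossovers statistic: bootstrap SD within 20% of sd/sqrt(N)
  stat <- function(ev, n, map) nrow(ev) / n
  bs <- bootstrap_kl_distribution(pop, stat, B = 400, seed = 2)
  per_ind <- tabulate(factor(pop$events$individual,
                             levels = rownames(pop$genotypes)), pop$n)
  se <- sd(per_ind) / sqrt(pop$n)
  expect_lt(abs(sd(bs) - se) / se, 0.2)
  expect_identical(bootstrap_kl_distribution(pop, stat, B = 50, seed = 3),
                   bootstrap_kl_distribution(pop, stat, B = 50, seed = 3))
})

test_that("ordering test ties identical populations and splits distinct ones", {
  d <- sim_pop("distal", n = 300, seed = 81)$pop
  f <- sim_pop("flat", n = 300, seed = 82)$pop
  # same data twice: raw p near 0.5, same letter
  same <- ordering_test(list(a = d, b = d), B = 400, seed = 4)
  expect_gt(same$pairs$raw_p, 0.3)
  expect_lt(same$pairs$raw_p, 0.7)
  expect_identical(unname(same$letters["a"]), unname(same$letters["b"]))
  # distal vs flat separate cleanly
  ot <- ordering_test(list(distal = d, flat = f), B = 400, seed = 5)
  expect_false(ot$letters[["distal"]] == ot$letters[["flat"]])
  expect_gt(ot$kl[["distal"]], ot$kl[["flat"]])
  # three populations with monotone true KL reproduce the order
  m <- sim_pop(marey = cbind(c(0, 0.25, 0.5, 0.75, 1), c(0, 0.35, 0.5, 0.65, 1)),
               n = 300, seed = 83)$pop
  o3 <- ordering_test(list(flat = f, mid = m, distal = d), B = 400, seed = 6)
  expect_identical(names(sort(unlist(o3$kl), decreasing = TRUE)),
                   c("distal", "mid", "flat"))
})

test_that("pairwise landscape KL is zero on itself and CI-covered across pairs", {
  a <- sim_pop("distal", n = 300, seed = 91)$pop
  b <- sim_pop("distal", n = 300, seed = 92)$pop
  self <- pairwise_landscape_kl(a, a, B = 200, seed = 7)
  expect_equal(self$kl, 0)
  ab <- pairwise_landscape_kl(a, b, B = 400, seed = 8)
  ba <- pairwise_landscape_kl(b, a, B = 400, seed = 8)
  expect_false(isTRUE(all.equal(ab$kl, ba$kl)))  # asymmetry of KL
  expect_lte(ab$ci[1], ab$ci[2])
  # CI from replicate pairs covers the point estimate's scale
  expect_gt(ab$ci[2], ab$kl / 3)
})
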