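test_that("zero-length chromosome yields no crossovers and bad models error", {
  ch0 <- chromosome_model("z", 1e6, 0)
  expect_identical(sample_bivalent_crossovers(ch0), numeric(0))
  expect_error(chromosome_model("z", 1e6, -1), "genetic_length")
  expect_error(chromosome_model("z", 1e6, Inf), "genetic_length")
  expect_error(sample_bivalent_crossovers(chromosome_model("z", 1e6, 1), nu = 0.5),
               "nu")
})

test_that("bivalent crossover counts match the Poisson(2L) oracle at nu = 1", {
  ch <- chromosome_model("A", 1e6, 1)
  set.seed(101)
  counts <- replicate(10000, length(sample_bivalent_crossovers(ch, nu = 1)))
  # mean within 3 SE of 2.0 (Poisson rate 2 per Morgan on 1 Morgan)
  se <- sqrt(2 / 10000)
  expect_lt(abs(mean(counts) - 2), 3 * se)
  # chi-squared goodness of fit to Poisson(2) at the 1% level
  lv <- 0:7
  obs <- tabulate(pmin(counts, 7) + 1, 8)
  pr <- dpois(lv, 2); pr[8] <- 1 - ppois(6, 2)
  gof <- suppressWarnings(chisq.test(obs, p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("interference (nu = 10) underdisperses the crossover count", {
  ch <- chromosome_model("A", 1e6, 1)
  set.seed(202)
  v1 <- var(replicate(10000, length(sample_bivalent_crossovers(ch, nu = 1))))
  v10 <- var(replicate(10000, length(sample_bivalent_crossovers(ch, nu = 10))))
  expect_lt(v10, v1)
})

test_that("chromatid thinning behaves as binomial p-thinning", {
  ch <- chromosome_model("A", 1e6, 1)
  set.seed(7)
  x <- sample_bivalent_crossovers(ch)
  expect_identical(thin_to_gamete(x, 0), numeric(0))
  expect_identical(thin_to_gamete(x, 1), x)
  expect_error(thin_to_gamete(x, 1.5), "p must")
  set.seed(303)
  kept <- replicate(10000, length(thin_to_gamete(sample_bivalent_crossovers(ch), 0.5)))
  expect_lt(abs(mean(kept) - 1), 3 * sqrt(1 / 10000) * sqrt(1.5))
})

test_that("Marey warp inverts correctly", {
  flat <- chromosome_model("A", 40e6, 2, marey = "flat")
  expect_equal(genetic_to_physical(flat, 1), 20e6)
  warped <- chromosome_model("A", 10e6, 1,
                             marey = cbind(c(0, 0.5, 1), c(0, 0.9, 1)))
  expect_equal(genetic_to_physical(warped, 0.9), 0.5 * 10e6)
  expect_error(genetic_to_physical(warped, 1.2), "outside")
  # round trip through random monotone anchors
  set.seed(11)
  for (k in 1:20) {
    a <- sort(runif(3)); b <- sort(runif(3))
    ch <- chromosome_model("A", 1e8, 1.5,
                           marey = cbind(c(0, a, 1), c(0, b, 1)))
    bp <- runif(50, 0, 1e8)
    expect_equal(genetic_to_physical(ch, physical_to_genetic(ch, bp)), bp,
                 tolerance = 1e-9)
  }
})

test_that("simulated genotypes reflect the true crossovers", {
  # zero crossovers on a chromosome: all marker calls identical per gamete
  ch <- chromosome_model("A01", 30e6, 0)
  cfg <- sim_config(list(ch), 10, seed = 5)
  sim <- simulate_population(cfg)
  expect_true(all(apply(sim$genotypes, 1, function(r) length(unique(r)) == 1L)))
  expect_identical(nrow(sim$truth), 0L)
  # a single crossover flips the calls at exactly its interval
  set.seed(6)
  ch1 <- chromosome_model("A01", 30e6, 1)
  cfg1 <- sim_config(list(ch1), 200, seed = 6)
  sim1 <- simulate_population(cfg1)
  pop1 <- suppressMessages(crossover_population(sim1$genotypes, sim1$map))
  one <- names(which(table(sim1$truth$individual) == 1))
  for (id in head(one, 20)) {
    tr <- sim1$truth[sim1$truth$individual == id, ]
    ev <- pop1$events[pop1$events$individual == id, ]
    expect_identical(nrow(ev), 1L)
    expect_true(ev$start <= tr$bp && tr$bp < ev$end)
  }
})

test_that("called crossovers recover nearly all true ones with dense markers", {
  chroms <- lapply(1:10, function(i) chromosome_model(sprintf("A%02d", i), 30e6, 1))
  cfg <- sim_config(chroms, 500, seed = 77)
  dense <- simulation_marker_map(chroms, spacing = 0.02 * 30e6)
  sim <- simulate_population(cfg, dense)
  pop <- suppressMessages(crossover_population(sim$genotypes, sim$map))
  # called <= true always; detectable fraction >= 0.95 with dense markers
  expect_lte(nrow(pop$events), nrow(sim$truth))
  expect_gte(nrow(pop$events) / nrow(sim$truth), 0.95)
  # called mean per meiocyte within 3 SE of 2 * 10 * detectable fraction
  m <- summary(pop)$mean_per_meiocyte
  expect_lt(abs(m - 2 * nrow(pop$events) / 500), 1e-12)
  se <- 2 * sd(table(factor(pop$events$individual,
                            levels = rownames(pop$genotypes)))) / sqrt(500)
  expect_lt(abs(m - 20 * nrow(pop$events) / nrow(sim$truth)), 3 * se + 0.5)
})

test_that("per-gamete crossover counts are Poisson at nu = 1", {
  ch <- chromosome_model("A01", 30e6, 2)
  cfg <- sim_config(list(ch), 2000, seed = 99, thinning = 1)
  sim <- simulate_population(cfg)
  counts <- tabulate(factor(sim$truth$individual,
                            levels = rownames(sim$genotypes)), 2000)
  lv <- 0:9
  obs <- tabulate(pmin(counts, 9) + 1, 10)
  pr <- dpois(lv, 4); pr[10] <- 1 - ppois(8, 4)
  gof <- suppressWarnings(chisq.test(obs, p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("identical config and seed give byte-identical simulations", {
  f <- sim_pop(seed = 123, n = 30)
  g <- sim_pop(seed = 123, n = 30)
  expect_identical(f$sim$genotypes, g$sim$genotypes)
  expect_identical(f$sim$truth, g$sim$truth)
  h <- sim_pop(seed = 124, n = 30)
  expect_false(identical(f$sim$genotypes, h$sim$genotypes))
})

test_that("markers outside chromosome bounds are an invalid-map error", {
  ch <- chromosome_model("A01", 10e6, 1)
  bad <- marker_map(data.frame(marker = c("a", "b"), chrom = "A01",
                               pos = c(0, 12e6)),
                    chrom_lengths = c(A01 = 12e6))
  cfg <- sim_config(list(ch), 5, seed = 1)
  expect_error(simulate_population(cfg, bad), "bounds")
})
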