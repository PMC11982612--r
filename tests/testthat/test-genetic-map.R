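test_that("Kosambi distances match closed forms and dominate 100r", {
  expect_equal(kosambi_cm(0), 0)
  expect_equal(kosambi_cm(0.1), 25 * log(1.5))
  expect_equal(round(kosambi_cm(0.1), 3), 10.137)
  expect_equal(round(kosambi_cm(0.25), 3), 27.465)
  expect_error(kosambi_cm(0.5), "0.5")
  expect_error(kosambi_cm(-0.01), "0.5")
  r <- seq(0, 0.499, length.out = 10000)
  d <- kosambi_cm(r)
  expect_true(all(diff(d) > 0))                 # strictly increasing
  expect_true(all(d[-1] > 100 * r[-1]))         # kosambi > naive off zero
  expect_true(all(diff(diff(d)) > 0))           # convex on the grid
})

test_that("build_map turns interval recombinants into Kosambi cM", {
  map <- marker_map(data.frame(marker = paste0("m", 1:3), chrom = "c1",
                               pos = c(0, 1e6, 2e6)))
  mk_ev <- function(k_left, k_right) {
    rbind(
      if (k_left) data.frame(individual = sprintf("i%d", 1:k_left),
                             chrom = "c1", left_marker = "m1",
                             right_marker = "m2", start = 0, end = 1e6,
                             point = 5e5),
      if (k_right) data.frame(individual = sprintf("j%d", 1:k_right),
                              chrom = "c1", left_marker = "m2",
                              right_marker = "m3", start = 1e6, end = 2e6,
                              point = 1.5e6))
  }
  gm <- build_map(mk_ev(10, 10), 100, map)
  expect_equal(gm$intervals$r, c(0.1, 0.1))
  expect_equal(gm$intervals$cM, rep(25 * log(1.5), 2))
  expect_equal(gm$total_cm, 2 * 25 * log(1.5))
  expect_equal(gm$intervals$cum_right, cumsum(rep(25 * log(1.5), 2)))
  # empty map is all zero
  gm0 <- build_map(mk_ev(1, 1)[0, ], 100, map)
  expect_equal(gm0$total_cm, 0)
  # r >= 0.5 is flagged and excluded with a warning
  expect_warning(gm5 <- build_map(mk_ev(50, 10), 100, map), "r >= 0.5")
  expect_true(is.na(gm5$intervals$cM[1]))
  expect_equal(gm5$total_cm, 25 * log(1.5))
})

test_that("interval heterogeneity is the uncorrected Pearson 2x2 test", {
  res <- sim_pop(n = 30, seed = 55, n_chrom = 1)
  popA <- res$pop
  # closed-form check on a fixed table via the internal statistic
  p2 <- meiodiv:::pearson_2x2
  expect_equal(p2(30, 100, 70, 100)$statistic, 32)
  expect_equal(p2(30, 100, 70, 100)$p_value,
               pchisq(32, 1, lower.tail = FALSE))
  expect_equal(p2(10, 100, 10, 100)$statistic, 0)
  expect_equal(p2(10, 100, 10, 100)$p_value, 1)
  expect_false(p2(0, 100, 0, 100)$testable)
  # dual route: matches chisq.test(correct = FALSE)
  ct <- chisq.test(rbind(c(30, 70), c(70, 30)), correct = FALSE)
  expect_equal(p2(30, 100, 70, 100)$statistic, unname(ct$statistic))
  # self-comparison has no significant interval
  het <- interval_heterogeneity(popA, popA)
  expect_false(any(het$significant))
})

test_that("map comparison separates populations by true rate difference", {
  shared <- simulation_marker_map(
    lapply(1:3, function(i) chromosome_model(sprintf("A%02d", i), 30e6, 1)),
    spacing = 5e6)
  mk <- function(gl, seed) {
    chroms <- lapply(1:3, function(i) chromosome_model(sprintf("A%02d", i), 30e6, gl))
    sim <- simulate_population(sim_config(chroms, 200, seed = seed), shared)
    suppressMessages(crossover_population(sim$genotypes, sim$map))
  }
  lo1 <- mk(0.6, 1); lo2 <- mk(0.6, 2); hi <- mk(1.8, 3)  # 3-fold rate gap
  cmp <- maplength_comparison(list(low_a = lo1, low_b = lo2, high = hi))
  expect_true(cmp$pairs$differ[cmp$pairs$pop_a == "low_a" &
                               cmp$pairs$pop_b == "high"])
  expect_true(cmp$pairs$differ[cmp$pairs$pop_a == "low_b" &
                               cmp$pairs$pop_b == "high"])
  expect_false(cmp$pairs$differ[cmp$pairs$pop_a == "low_a" &
                                cmp$pairs$pop_b == "low_b"])
  expect_identical(cmp$letters[["low_a"]], cmp$letters[["low_b"]])
  expect_false(cmp$letters[["high"]] == cmp$letters[["low_a"]])
  # self-comparison shares a letter by construction
  cmp2 <- maplength_comparison(list(a = lo1, b = lo1))
  expect_identical(unname(cmp2$letters["a"]), unname(cmp2$letters["b"]))
  # symmetric in population order
  cmp3 <- maplength_comparison(list(high = hi, low_a = lo1, low_b = lo2))
  expect_identical(sort(paste(cmp3$letters)), sort(paste(cmp$letters)))
})

test_that("compact letter display reproduces textbook groupings", {
  nm <- c("w", "x", "y", "z")
  differ <- matrix(FALSE, 4, 4, dimnames = list(nm, nm))
  differ["w", "z"] <- differ["z", "w"] <- TRUE
  differ["w", "y"] <- differ["y", "w"] <- TRUE
  cl <- compact_letter_display(differ, nm)
  expect_identical(unname(cl["w"]), "a")
  expect_true(grepl("a", cl["x"]) && grepl("b", cl["x"]))  # bridges both
  expect_false(grepl("a", cl["y"]))
  expect_false(grepl("a", cl["z"]))
  # all-different chain gets distinct singleton letters
  d2 <- matrix(TRUE, 3, 3, dimnames = list(nm[1:3], nm[1:3]))
  diag(d2) <- FALSE
  expect_identical(unname(compact_letter_display(d2, nm[1:3])), c("a", "b", "c"))
})

test_that("crossover-size regression matches hand OLS", {
  fit <- regress_crossovers_vs_size(c(1, 2, 2), c(1, 2, 3))
  expect_equal(fit$slope, 0.5)
  expect_equal(fit$intercept, 2 / 3)
  expect_equal(fit$r_squared, 0.75)
  exact <- regress_crossovers_vs_size(c(1, 2, 3), c(1, 2, 3))
  expect_equal(exact$r_squared, 1)
  flat <- regress_crossovers_vs_size(c(2, 2, 2), c(1, 2, 3))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_error(regress_crossovers_vs_size(c(1, 2, 3), c(2, 2, 2)), "degenerate")
  expect_error(regress_crossovers_vs_size(c(1, 2), c(1, 2)), ">= 3")
})

test_that("centromere-distance regression detects a distal landscape", {
  with_cen <- function(marey, seed) {
    chroms <- lapply(1:5, function(i)
      chromosome_model(sprintf("A%02d", i), 30e6, 1, marey = marey))
    mm <- simulation_marker_map(chroms)
    attr(mm, "centromeres") <- data.frame(chrom = sprintf("A%02d", 1:5),
                                          start = 14e6, end = 16e6)
    sim <- simulate_population(sim_config(chroms, 300, seed = seed), mm)
    suppressMessages(crossover_population(sim$genotypes, mm))
  }
  for (s in 11:13) {
    distal <- regress_rate_vs_centromere_distance(with_cen("distal", s))
    expect_gt(distal$slope, 0)
    expect_lt(distal$p_value, 0.01)
  }
  flat_ok <- sum(sapply(1:5, function(s)
    regress_rate_vs_centromere_distance(with_cen("flat", s))$p_value > 0.05))
  expect_gte(flat_ok, 4L)
  # no centromeres recorded is an error
  pop <- sim_pop(n = 20, seed = 3)$pop
  expect_error(regress_rate_vs_centromere_distance(pop), "centromere")
})
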