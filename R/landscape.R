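#' Relative physical crossover positions
#'
#' Each event's point position (interval midpoint) expressed as a fraction
#' of its chromosome's physical length; pooling across chromosomes is plain
#' concatenation of these fractions.
#'
#' @param events crossover events data.frame.
#' @param map a [marker_map()].
#' @return numeric vector in `[0, 1]`.
#' @export
relative_positions <- function(events, map) {
  stopifnot(inherits(map, "marker_map"))
  lens <- chrom_lengths(map)
  events$point / lens[events$chrom]
}

#' Bin relative positions into a 10-bin distribution
#'
#' Bin k (k = 1..n_bins) receives positions in `[(k-1)/n, k/n)`, except the
#' last bin which also includes 1.0 (half-open convention; a position
#' exactly on an internal bin edge goes right).
#'
#' @param positions numeric vector of relative positions in `[0, 1]`.
#' @param n_bins number of bins (default 10).
#' @return object of class `binned_distribution` with `counts`, `prob`
#'   (NULL when there are no observations), `n_bins`.
#' @export
#' @examples
#' bin_relative_positions(c(0.05, 0.05, 0.95, 1.0))$counts
bin_relative_positions <- function(positions, n_bins = 10) {
  if (length(positions) && (any(!is.finite(positions)) ||
                            any(positions < 0) || any(positions > 1)))
    stopf("relative positions must lie in [0, 1]")
  idx <- pmin(floor(positions * n_bins) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  binned_distribution(counts)
}

#' Binned distribution constructor
#'
#' @param counts non-negative integer vector of bin counts.
#' @return object of class `binned_distribution`.
#' @export
binned_distribution <- function(counts) {
  if (any(counts < 0)) stopf("bin counts must be non-negative")
  total <- sum(counts)
  structure(list(counts = as.numeric(counts),
                 prob = if (total > 0) counts / total else NULL,
                 n_bins = length(counts)),
            class = "binned_distribution")
}

#' @export
print.binned_distribution <- function(x, ...) {
  cat(sprintf("<binned_distribution> %d bins, %g observations\n",
              x$n_bins, sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' @noRd
as_prob <- function(x, pseudocount = FALSE, what = "distribution") {
  if (inherits(x, "binned_distribution")) x <- x$counts
  x <- as.numeric(x)
  if (any(x < 0) || any(!is.finite(x))) stopf("invalid %s", what)
  if (pseudocount) x <- x + 0.5
  s <- sum(x)
  if (s == 0) stopf("%s has no observations: probabilities undefined", what)
  x / s
}

#' Kullback-Leibler divergence between binned distributions
#'
#' Plug-in estimator KL(P, Q) = sum_i P_i log(P_i / Q_i) in nats (natural
#' logarithm), with 0 log 0 := 0. A bin where P is occupied but Q is empty
#' makes the divergence infinite: this is reported as an error (never
#' silently capped); optionally a pseudocount of 0.5 per bin is added to
#' both count vectors first.
#'
#' @param P,Q [binned_distribution()] objects, count vectors, or
#'   probability vectors of equal length.
#' @param pseudocount add 0.5 to every bin before normalizing (default
#'   FALSE; off because the estimator is the plain plug-in).
#' @return divergence in nats (>= 0, 0 iff P = Q).
#' @export
#' @examples
#' kl_divergence(c(0.2, 0.8), c(0.5, 0.5))
kl_divergence <- function(P, Q, pseudocount = FALSE) {
  p <- as_prob(P, pseudocount, "P")
  q <- as_prob(Q, pseudocount, "Q")
  if (length(p) != length(q)) stopf("P and Q must have the same number of bins")
  bad <- p > 0 & q == 0
  if (any(bad))
    stopf("infinite divergence: P occupied but Q empty in bin %s",
          paste(which(bad), collapse = ", "))
  i <- p > 0
  sum(p[i] * log(p[i] / q[i]))
}

#' @noRd
kl_to_uniform <- function(counts) {
  s <- sum(counts)
  p <- counts[counts > 0] / s
  sum(p * log(p * length(counts)))
}

#' KL divergence of crossover landscapes to flatness
#'
#' Bins each chromosome's crossover positions (relative physical) into
#' `n_bins` bins of identical physical size and computes the plug-in KL
#' divergence to the flat landscape Q_i = 1/n_bins, per chromosome and for
#' all chromosomes pooled. Units with zero crossovers are undefined and
#' reported as `NA`.
#'
#' @param pop a [crossover_population()], or an events data.frame (then
#'   supply `map`).
#' @param map a [marker_map()] (when `pop` is an events data.frame).
#' @param n_bins bins per chromosome (default 10).
#' @return list with `per_chromosome` (named numeric) and `pooled`.
#' @export
kl_to_flat <- function(pop, map = NULL, n_bins = 10) {
  if (inherits(pop, "crossover_population")) {
    events <- pop$events; map <- pop$map
  } else events <- pop
  stopifnot(inherits(map, "marker_map"))
  rel <- relative_positions(events, map)
  chroms <- unique(map$chrom)
  per <- vapply(chroms, function(ch) {
    r <- rel[events$chrom == ch]
    if (!length(r)) return(NA_real_)
    kl_to_uniform(bin_relative_positions(r, n_bins)$counts)
  }, 0)
  if (anyNA(per))
    logf("kl_to_flat", "%d chromosome(s) with zero crossovers: KL undefined",
         sum(is.na(per)))
  pooled <- if (length(rel))
    kl_to_uniform(bin_relative_positions(rel, n_bins)$counts) else NA_real_
  list(per_chromosome = per, pooled = pooled)
}

#' Randomization test of landscape flatness
#'
#' Tests H0 "flat landscape": every crossover's relative position is
#' redrawn uniformly on `[0, 1]` (a flat landscape looks the same on every
#' chromosome once positions are made relative), the KL divergence to
#' flatness is recomputed for each of `n_randomizations` randomizations,
#' and the p-value is the proportion of null KL values at least as large as
#' the observed one.
#'
#' @param pop a [crossover_population()], or a numeric vector of relative
#'   positions in `[0, 1]`.
#' @param n_randomizations number of randomizations (default 10000).
#' @param seed integer seed (the test is deterministic given it).
#' @param n_bins bins (default 10).
#' @return object of class `kl_flatness`: `kl`, `p_value`,
#'   `n_randomizations`, `n_crossovers`, `seed`.
#' @export
flatness_pvalue <- function(pop, n_randomizations = 10000, seed = NULL,
                            n_bins = 10) {
  rel <- if (inherits(pop, "crossover_population"))
    relative_positions(pop$events, pop$map) else as.numeric(pop)
  n <- length(rel)
  if (n < 1L) stopf("no crossovers: flatness is untestable")
  obs <- kl_to_uniform(bin_relative_positions(rel, n_bins)$counts)
  null_kl <- with_seed(seed, {
    vapply(seq_len(n_randomizations), function(b) {
      kl_to_uniform(tabulate(pmin(floor(stats::runif(n) * n_bins) + 1L, n_bins),
                             nbins = n_bins))
    }, 0)
  })
  structure(list(kl = obs, p_value = mean(null_kl >= obs),
                 n_randomizations = n_randomizations, n_crossovers = n,
                 seed = seed),
            class = "kl_flatness")
}

#' @export
print.kl_flatness <- function(x, ...) {
  p <- if (x$p_value < 1 / x$n_randomizations)
    sprintf("< %.3g", 1 / x$n_randomizations) else sprintf("%.4g", x$p_value)
  cat(sprintf("KL divergence to flat landscape: %.4f nats (n = %d crossovers)\n",
              x$kl, x$n_crossovers))
  cat(sprintf("Randomization p-value (H0: flat, %d randomizations): %s\n",
              x$n_randomizations, p))
  invisible(x)
}

#' @noRd
events_by_individual <- function(pop) {
  split(seq_len(nrow(pop$events)),
        factor(pop$events$individual, levels = rownames(pop$genotypes)))
}

#' Bootstrap distribution of a population statistic
#'
#' Draws `B` resamples of the population's N individuals with replacement
#' (each individual's full crossover set travels with it) and recomputes
#' `statistic` on every resample.
#'
#' @param pop a [crossover_population()] with N >= 2 individuals.
#' @param statistic function of `(events, n, map)` returning a scalar.
#' @param B number of bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @return numeric vector of length `B`.
#' @export
bootstrap_kl_distribution <- function(pop, statistic, B = 10000, seed = NULL) {
  stopifnot(inherits(pop, "crossover_population"))
  if (pop$n < 2L) stopf("need at least 2 individuals to bootstrap")
  rows <- events_by_individual(pop)
  with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- unlist(rows[sample.int(pop$n, pop$n, replace = TRUE)],
                    use.names = FALSE)
      statistic(pop$events[idx, , drop = FALSE], pop$n, pop$map)
    }, 0)
  })
}

#' Per-individual landscape bin counts (fast bootstrap backbone)
#' @noRd
individual_bin_counts <- function(pop, n_bins = 10) {
  rel <- relative_positions(pop$events, pop$map)
  idx <- pmin(floor(rel * n_bins) + 1L, n_bins)
  ind <- factor(pop$events$individual, levels = rownames(pop$genotypes))
  C <- matrix(0, nrow = pop$n, ncol = n_bins)
  tab <- table(ind, factor(idx, levels = seq_len(n_bins)))
  C[, ] <- as.numeric(tab)
  C
}

#' Bootstrap KL-to-flat stream for one population
#' @noRd
boot_kl_flat <- function(C, B, n_bins) {
  n <- nrow(C)
  out <- numeric(B)
  redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      cnt <- colSums(C[sample.int(n, n, replace = TRUE), , drop = FALSE])
      if (sum(cnt) > 0) break
      redrawn <- redrawn + 1L
      if (redrawn > 1000L) stopf("bootstrap degenerate: resamples without crossovers")
    }
    out[b] <- kl_to_uniform(cnt)
  }
  if (redrawn) logf("bootstrap", "redrew %d zero-crossover resamples", redrawn)
  out
}

#' Bootstrap ordering test of KL-to-flatness across populations
#'
#' Orders populations by their KL divergence to the flat landscape and
#' tests each pairwise ordering: each population is bootstrapped over
#' individuals (`B` replicates, independent streams paired by replicate
#' index), and the raw p-value for a pair is k/B where k counts replicates
#' whose ordering is opposite to the observed one. Bonferroni adjustment
#' multiplies by the number of pairs; letter groups summarize the adjusted
#' decisions at `alpha` (letters run from highest KL to lowest).
#'
#' @param populations named list of [crossover_population()] objects.
#' @param B bootstrap replicates (default 10000).
#' @param seed integer seed.
#' @param n_bins landscape bins (default 10).
#' @param alpha significance threshold on adjusted p-values (default 0.05).
#' @return object of class `kl_ordering`: `kl` (observed, named), `pairs`
#'   (raw and adjusted p per pair), `letters`, `boot` (B x populations
#'   matrix), `B`, `seed`.
#' @export
ordering_test <- function(populations, B = 10000, seed = NULL, n_bins = 10,
                          alpha = 0.05) {
  stopifnot(length(populations) >= 2L)
  if (is.null(names(populations)))
    names(populations) <- paste0("pop", seq_along(populations))
  nm <- names(populations)
  obs <- vapply(populations, function(p) kl_to_flat(p, n_bins = n_bins)$pooled, 0)
  boot <- with_seed(seed, {
    vapply(populations, function(p)
      boot_kl_flat(individual_bin_counts(p, n_bins), B, n_bins), numeric(B))
  })
  finish_ordering(obs, boot, nm, alpha, B, seed)
}

#' Shared tail of the two ordering tests: pairwise p-values and letters
#' @noRd
finish_ordering <- function(obs, boot, nm, alpha, B, seed) {
  pairs <- utils::combn(nm, 2L)
  tab <- data.frame(pop_a = pairs[1L, ], pop_b = pairs[2L, ],
                    raw_p = NA_real_, adj_p = NA_real_, differ = NA)
  n_pairs <- ncol(pairs)
  diff_mat <- matrix(FALSE, length(nm), length(nm), dimnames = list(nm, nm))
  for (k in seq_len(n_pairs)) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    d_obs <- obs[[a]] - obs[[b]]
    d_boot <- boot[, a] - boot[, b]
    kk <- if (d_obs >= 0) sum(d_boot < 0) else sum(d_boot > 0)
    tab$raw_p[k] <- kk / B
    tab$adj_p[k] <- min(1, kk / B * n_pairs)
    tab$differ[k] <- tab$adj_p[k] < alpha
    diff_mat[a, b] <- diff_mat[b, a] <- tab$differ[k]
  }
  letters_tab <- compact_letter_display(diff_mat, nm[order(-unlist(obs))])
  structure(list(kl = obs, pairs = tab, letters = letters_tab[nm],
                 boot = boot, B = B, seed = seed),
            class = "kl_ordering")
}

#' @export
print.kl_ordering <- function(x, ...) {
  cat(sprintf("<kl_ordering> %d populations, %d bootstrap replicates\n",
              length(x$kl), x$B))
  print(data.frame(population = names(x$kl), KL = round(unlist(x$kl), 4),
                   group = x$letters[names(x$kl)], row.names = NULL))
  invisible(x)
}

#' Pairwise KL divergence between two crossover landscapes
#'
#' Point estimate KL(P_A, Q_B) where both histograms come from the data
#' (pooled relative positions, `n_bins` bins), with a bootstrap confidence
#' interval: both populations are resampled over individuals in `B` paired
#' replicates and the 2.5% / 97.5% quantiles of the replicate KL values
#' form the interval. Replicates in which the resampled Q has an empty bin
#' where the resampled P is occupied are redrawn and counted. Note KL is
#' asymmetric: call the function both ways if both directions are wanted.
#'
#' @param popA,popB [crossover_population()] objects.
#' @param B bootstrap replicates (default 10000).
#' @param seed integer seed.
#' @param n_bins bins (default 10).
#' @param pseudocount add 0.5 per bin (default FALSE).
#' @return object of class `kl_pair`: `kl`, `ci`, `B`, `n_redrawn`, `seed`.
#' @export
pairwise_landscape_kl <- function(popA, popB, B = 10000, seed = NULL,
                                  n_bins = 10, pseudocount = FALSE) {
  pa <- bin_relative_positions(relative_positions(popA$events, popA$map), n_bins)
  qb <- bin_relative_positions(relative_positions(popB$events, popB$map), n_bins)
  kl <- kl_divergence(pa, qb, pseudocount = pseudocount)
  CA <- individual_bin_counts(popA, n_bins)
  CB <- individual_bin_counts(popB, n_bins)
  redrawn <- 0L
  boot <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      repeat {
        ca <- colSums(CA[sample.int(nrow(CA), nrow(CA), replace = TRUE), ,
                         drop = FALSE])
        cb <- colSums(CB[sample.int(nrow(CB), nrow(CB), replace = TRUE), ,
                         drop = FALSE])
        if (pseudocount) { ca <- ca + 0.5; cb <- cb + 0.5 }
        ok <- sum(ca) > 0 && sum(cb) > 0 && !any(ca > 0 & cb == 0)
        if (ok) break
        redrawn <<- redrawn + 1L
        if (redrawn > 100L * B) stopf("bootstrap stuck on empty-bin resamples")
      }
      p <- ca / sum(ca); q <- cb / sum(cb); i <- p > 0
      sum(p[i] * log(p[i] / q[i]))
    }, 0)
  })
  if (redrawn) logf("pairwise_landscape_kl", "redrew %d degenerate resamples", redrawn)
  structure(list(kl = kl, ci = stats::quantile(boot, c(0.025, 0.975), names = FALSE),
                 boot = boot, B = B, n_redrawn = redrawn, seed = seed),
            class = "kl_pair")
}

#' @export
print.kl_pair <- function(x, ...) {
  cat(sprintf("KL(P, Q) = %.4f nats; 95%% bootstrap CI [%.4f, %.4f] (B = %d)\n",
              x$kl, x$ci[1], x$ci[2], x$B))
  invisible(x)
}
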