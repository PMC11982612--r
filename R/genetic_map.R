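#' Kosambi map distance
#'
#' Converts a recombination fraction r into centimorgans under the Kosambi
#' mapping function, d = 25 ln((1 + 2r) / (1 - 2r)), which assumes moderate
#' crossover interference.
#'
#' @param r numeric vector of recombination fractions in `[0, 0.5)`.
#' @return genetic distances in cM.
#' @export
#' @examples
#' kosambi_cm(c(0, 0.1, 0.25))
kosambi_cm <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r >= 0.5))
    stopf("recombination fraction must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Count recombinant individuals per adjacent-marker interval
#' @noRd
interval_recombinants <- function(events, map) {
  iv <- map_intervals(map)
  key <- paste(iv$chrom, iv$left_marker)
  cnt <- table(factor(paste(events$chrom, events$left_marker), levels = key))
  iv$rec <- as.integer(cnt)
  iv
}

#' Build a per-interval Kosambi genetic map
#'
#' For every adjacent-marker interval the recombination fraction is
#' r = (individuals with a call change in the interval) / n, converted to cM
#' with [kosambi_cm()]; cumulative positions and chromosome/genome totals
#' follow by addition. Intervals with r >= 0.5 cannot be mapped: they are
#' flagged, their distance is reported as `NA` and excluded from totals,
#' with a warning.
#'
#' @param x a [crossover_population()], or an events data.frame (then
#'   supply `n_individuals` and `map`).
#' @param n_individuals population size (when `x` is an events data.frame).
#' @param map a [marker_map()] (when `x` is an events data.frame).
#' @return an object of class `genetic_map`: list with `intervals`
#'   (chrom, markers, r, cM, cumulative cM), `chromosome_cm`, `total_cm`,
#'   `n`.
#' @export
build_map <- function(x, n_individuals = NULL, map = NULL) {
  if (inherits(x, "crossover_population")) {
    events <- x$events; n_individuals <- x$n; map <- x$map
  } else events <- x
  stopifnot(inherits(map, "marker_map"), n_individuals >= 1)
  iv <- interval_recombinants(events, map)
  iv$r <- iv$rec / n_individuals
  iv$mappable <- iv$r < 0.5
  if (any(!iv$mappable))
    warnf("%d interval(s) with r >= 0.5 flagged and excluded from totals",
          sum(!iv$mappable))
  iv$cM <- ifelse(iv$mappable, kosambi_cm(ifelse(iv$mappable, iv$r, 0)), NA_real_)
  cum <- unlist(lapply(split(ifelse(iv$mappable, iv$cM, 0), iv$chrom)[unique(iv$chrom)],
                       cumsum), use.names = FALSE)
  iv$cum_right <- cum
  iv$cum_left <- cum - ifelse(iv$mappable, iv$cM, 0)
  chrom_cm <- tapply(ifelse(iv$mappable, iv$cM, 0), iv$chrom, sum)[unique(iv$chrom)]
  structure(list(intervals = iv, chromosome_cm = chrom_cm,
                 total_cm = sum(chrom_cm), n = n_individuals),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("<genetic_map> %d intervals on %d chromosomes, total %.1f cM (n = %d)\n",
              nrow(x$intervals), length(x$chromosome_cm), x$total_cm, x$n))
  invisible(x)
}

#' @export
summary.genetic_map <- function(object, ...) {
  data.frame(chrom = names(object$chromosome_cm),
             n_intervals = as.integer(table(object$intervals$chrom)[names(object$chromosome_cm)]),
             cM = as.numeric(object$chromosome_cm), row.names = NULL)
}

#' @export
plot.genetic_map <- function(x, ...) {
  iv <- x$intervals
  mid <- (iv$start + iv$end) / 2e6
  rate <- iv$cM / ((iv$end - iv$start) / 1e6)
  graphics::plot(mid, rate, col = factor(iv$chrom), pch = 16,
                 xlab = "physical midpoint (Mbp)", ylab = "cM / Mbp", ...)
  invisible(x)
}

#' Pearson 2x2 chi-squared on recombinant counts (no continuity correction)
#' @noRd
pearson_2x2 <- function(a, nA, b, nB) {
  tab <- c(a, nA - a, b, nB - b)
  N <- nA + nB
  c1 <- a + b; c2 <- N - c1
  if (c1 == 0 || c2 == 0 || nA == 0 || nB == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, testable = FALSE))
  stat <- N * (a * (nB - b) - b * (nA - a))^2 / (nA * nB * c1 * c2)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       testable = TRUE)
}

#' Per-interval heterogeneity test between two populations
#'
#' For every shared adjacent-marker interval, tests homogeneity of the
#' recombinant proportion between two populations with a Pearson 2x2
#' chi-squared (1 df, no continuity correction). Intervals with a zero
#' margin are reported as not testable.
#'
#' @param popA,popB [crossover_population()] objects on the same map.
#' @param threshold per-interval significance threshold (default 0.05).
#' @return data.frame: one row per interval with counts, statistic, raw p,
#'   significance flag at `threshold`, testability.
#' @export
interval_heterogeneity <- function(popA, popB, threshold = 0.05) {
  if (!identical(popA$map$marker, popB$map$marker))
    stopf("populations are genotyped on different maps")
  ia <- interval_recombinants(popA$events, popA$map)
  ib <- interval_recombinants(popB$events, popB$map)
  res <- mapply(function(a, b) unlist(pearson_2x2(a, popA$n, b, popB$n)),
                ia$rec, ib$rec)
  out <- data.frame(ia[, c("chrom", "left_marker", "right_marker", "start", "end")],
                    rec_A = ia$rec, n_A = popA$n, rec_B = ib$rec, n_B = popB$n,
                    statistic = as.numeric(res["statistic", ]),
                    p_value = as.numeric(res["p_value", ]),
                    testable = as.logical(res["testable", ]))
  out$significant <- out$testable & !is.na(out$p_value) & out$p_value < threshold
  out
}

#' Compare total map lengths across populations
#'
#' Operationalizes the conservative genome/chromosome-scale comparison: two
#' populations differ at a given scale iff at least one adjacent-marker
#' interval is significant at the Bonferroni threshold
#' 0.05 / (number of intervals at that scale). Letter groups summarize the
#' pairwise decision matrix (compact letter display, ordered by total cM,
#' longest map first).
#'
#' @param populations named list of [crossover_population()] objects sharing
#'   one map.
#' @param scale `"genome"` (all intervals) or `"chromosome"` (one comparison
#'   per chromosome, Bonferroni over that chromosome's intervals).
#' @param alpha family-wise threshold before Bonferroni division (default
#'   0.05).
#' @return for `"genome"`: object of class `map_comparison` with `totals`
#'   (cM), `pairs` (per-pair decision table), `letters`; for
#'   `"chromosome"`: named list of `map_comparison`, one per chromosome.
#' @export
maplength_comparison <- function(populations, scale = c("genome", "chromosome"),
                                 alpha = 0.05) {
  scale <- match.arg(scale)
  stopifnot(length(populations) >= 2L)
  if (is.null(names(populations)))
    names(populations) <- paste0("pop", seq_along(populations))
  ref <- populations[[1L]]$map
  for (p in populations)
    if (!identical(p$map$marker, ref$marker))
      stopf("all populations must share one marker map")
  if (scale == "chromosome") {
    out <- lapply(unique(ref$chrom), function(ch) {
      sub <- lapply(populations, subset_population_chrom, ch)
      maplength_comparison(sub, scale = "genome", alpha = alpha)
    })
    names(out) <- unique(ref$chrom)
    return(out)
  }
  n_iv <- nrow(map_intervals(ref))
  thr <- alpha / n_iv
  nm <- names(populations)
  totals <- vapply(populations, function(p) build_map(p)$total_cm, 0)
  pairs <- utils::combn(nm, 2L)
  pair_tab <- data.frame(pop_a = pairs[1L, ], pop_b = pairs[2L, ],
                         n_significant = NA_integer_, min_p = NA_real_,
                         differ = NA)
  diff_mat <- matrix(FALSE, length(nm), length(nm), dimnames = list(nm, nm))
  for (k in seq_len(ncol(pairs))) {
    het <- interval_heterogeneity(populations[[pairs[1L, k]]],
                                  populations[[pairs[2L, k]]],
                                  threshold = thr)
    pair_tab$n_significant[k] <- sum(het$significant)
    pair_tab$min_p[k] <- suppressWarnings(min(het$p_value, na.rm = TRUE))
    pair_tab$differ[k] <- any(het$significant)
    diff_mat[pairs[1L, k], pairs[2L, k]] <- pair_tab$differ[k]
    diff_mat[pairs[2L, k], pairs[1L, k]] <- pair_tab$differ[k]
  }
  ord <- nm[order(-totals)]
  letters_tab <- compact_letter_display(diff_mat, ord)
  structure(list(totals = totals, n_intervals = n_iv, threshold = thr,
                 pairs = pair_tab, letters = letters_tab[nm]),
            class = "map_comparison")
}

#' @noRd
subset_population_chrom <- function(pop, ch) {
  keep <- pop$map$chrom == ch
  sub_map <- marker_map(pop$map[keep, c("marker", "chrom", "pos")],
                        chrom_lengths = chrom_lengths(pop$map)[ch],
                        centromeres = attr(pop$map, "centromeres"))
  structure(list(events = pop$events[pop$events$chrom == ch, , drop = FALSE],
                 genotypes = pop$genotypes[, keep, drop = FALSE],
                 map = sub_map, n = pop$n, segregation = NULL),
            class = "crossover_population")
}

#' @export
print.map_comparison <- function(x, ...) {
  cat(sprintf("<map_comparison> Bonferroni threshold %.2g over %d intervals\n",
              x$threshold, x$n_intervals))
  print(data.frame(population = names(x$totals), total_cM = round(x$totals, 1),
                   group = x$letters[names(x$totals)], row.names = NULL))
  invisible(x)
}

#' Compact letter display from a pairwise difference matrix
#'
#' Insert-and-absorb algorithm: populations sharing a letter are pairwise
#' non-different; every significantly different pair carries disjoint
#' letters. Letters are assigned following the supplied ordering (typically
#' highest statistic first, labelled "a").
#'
#' @param differ logical symmetric matrix, `TRUE` where the pair differs.
#' @param order character vector: row/col names in display order.
#' @return named character vector of letter groups.
#' @export
compact_letter_display <- function(differ, order = rownames(differ)) {
  stopifnot(is.matrix(differ), identical(rownames(differ), colnames(differ)))
  items <- order
  cols <- list(items)
  pr <- which(differ & upper.tri(differ), arr.ind = TRUE)
  for (k in seq_len(nrow(pr))) {
    i <- rownames(differ)[pr[k, 1L]]; j <- colnames(differ)[pr[k, 2L]]
    nxt <- list()
    for (cl in cols) {
      if (i %in% cl && j %in% cl) {
        nxt <- c(nxt, list(setdiff(cl, i)), list(setdiff(cl, j)))
      } else nxt <- c(nxt, list(cl))
    }
    nxt <- nxt[lengths(nxt) > 0L]
    # absorb: drop columns contained in another column
    keep <- rep(TRUE, length(nxt))
    for (a in seq_along(nxt)) for (b in seq_along(nxt)) {
      if (a != b && keep[a] && keep[b] && all(nxt[[a]] %in% nxt[[b]]) &&
          !(all(nxt[[b]] %in% nxt[[a]]) && a < b)) keep[a] <- FALSE
    }
    cols <- unique(nxt[keep])
  }
  first_pos <- vapply(cols, function(cl) min(match(cl, items)), 0)
  cols <- cols[order(first_pos)]
  out <- stats::setNames(rep("", length(items)), items)
  for (k in seq_along(cols))
    out[cols[[k]]] <- paste0(out[cols[[k]]], letters[k])
  out
}

#' Regression of per-chromosome crossover number on physical size
#'
#' Ordinary least squares of the average number of crossovers formed per
#' chromosome pair per meiosis on the physical length covered by markers
#' (Mbp). Larger chromosomes form more crossovers; the slope measures the
#' per-Mbp gain.
#'
#' @param mean_crossovers per-chromosome mean crossovers per meiosis.
#' @param covered_mbp per-chromosome marker-covered length in Mbp.
#' @return object of class `xo_regression`: slope, intercept, r_squared,
#'   p_value (F test), and the underlying `lm` fit.
#' @export
regress_crossovers_vs_size <- function(mean_crossovers, covered_mbp) {
  if (length(mean_crossovers) < 3L) stopf("need >= 3 chromosomes")
  if (length(unique(covered_mbp)) < 2L) stopf("degenerate design: constant x")
  fit <- stats::lm(mean_crossovers ~ covered_mbp)
  sm <- suppressWarnings(summary(fit))  # perfect fits are valid input here
  p <- if (nrow(sm$coefficients) < 2L || sm$sigma == 0) {
    if (stats::coef(fit)[2L] == 0) 1 else 0
  } else stats::pf(sm$fstatistic[1L], sm$fstatistic[2L], sm$fstatistic[3L],
                   lower.tail = FALSE)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = sm$r.squared, p_value = unname(p), fit = fit),
            class = "xo_regression")
}

#' @export
print.xo_regression <- function(x, ...) {
  cat(sprintf("y = %.4fx + %.4f; R^2 = %.2f (F test p = %.3g)\n",
              x$slope, x$intercept, x$r_squared, x$p_value))
  invisible(x)
}

#' Per-chromosome crossover means and marker-covered sizes
#'
#' @param pop a [crossover_population()].
#' @return data.frame: chrom, mean_crossovers (per meiosis, 2 x count / n),
#'   covered_mbp.
#' @export
per_chromosome_stats <- function(pop) {
  stopifnot(inherits(pop, "crossover_population"))
  chroms <- unique(pop$map$chrom)
  cnt <- table(factor(pop$events$chrom, levels = chroms))
  span <- vapply(chroms, function(ch) diff(range(pop$map$pos[pop$map$chrom == ch])), 0)
  data.frame(chrom = chroms, mean_crossovers = 2 * as.integer(cnt) / pop$n,
             covered_mbp = span / 1e6, row.names = NULL)
}

#' Regression of interval recombination rate on centromere distance
#'
#' Tests whether crossover rates increase away from centromeres: per
#' interval, the relative recombination rate (interval share of its
#' chromosome's crossovers, normalized so each chromosome sums to 100%) is
#' regressed on the relative distance of the interval midpoint from the
#' nearest centromere edge (% of the arm length). Chromosomes without any
#' crossover contribute no intervals (normalization is undefined there).
#'
#' @param pop a [crossover_population()] whose map carries centromere
#'   intervals (see [marker_map()]).
#' @return an `xo_regression` (slope, R^2, F-test p).
#' @export
regress_rate_vs_centromere_distance <- function(pop) {
  stopifnot(inherits(pop, "crossover_population"))
  cen <- attr(pop$map, "centromeres")
  if (is.null(cen)) stopf("marker map carries no centromere positions")
  iv <- interval_recombinants(pop$events, pop$map)
  lens <- chrom_lengths(pop$map)
  rate <- dist <- numeric(0)
  for (ch in unique(iv$chrom)) {
    sub <- iv[iv$chrom == ch, , drop = FALSE]
    tot <- sum(sub$rec)
    if (tot == 0) next
    cc <- cen[cen$chrom == ch, , drop = FALSE]
    if (!nrow(cc)) stopf("no centromere recorded for chromosome %s", ch)
    mid <- (sub$start + sub$end) / 2
    d <- ifelse(mid < cc$start[1L],
                100 * (cc$start[1L] - mid) / cc$start[1L],
                ifelse(mid > cc$end[1L],
                       100 * (mid - cc$end[1L]) / (lens[[ch]] - cc$end[1L]),
                       0))
    rate <- c(rate, 100 * sub$rec / tot)
    dist <- c(dist, d)
  }
  if (length(rate) < 3L) stopf("need >= 3 intervals with crossovers")
  if (length(unique(dist)) < 2L)
    stopf("degenerate design: all intervals equidistant from centromeres")
  regress_crossovers_vs_size(rate, dist)
}
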