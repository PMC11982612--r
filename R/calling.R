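#' Per-marker Mendelian segregation check
#'
#' In a testcross each marker should transmit the two parental states in a
#' 1:1 ratio. For counts a, b of the two states the chi-squared statistic
#' (1 df) is (a - b)^2 / (a + b); markers with p < 0.05 are flagged.
#' Missing calls are excluded per marker; a marker with no non-missing call
#' is reported as not testable.
#'
#' @param genotypes genotype matrix ("A"/"B"/NA).
#' @return data.frame: marker, n_A, n_B, statistic, p_value, flagged,
#'   testable.
#' @export
check_mendelian_segregation <- function(genotypes) {
  g <- unclass(genotypes)
  a <- colSums(g == "A", na.rm = TRUE)
  b <- colSums(g == "B", na.rm = TRUE)
  n <- a + b
  stat <- ifelse(n > 0, (a - b)^2 / n, NA_real_)
  p <- ifelse(n > 0, stats::pchisq(stat, df = 1, lower.tail = FALSE), NA_real_)
  data.frame(marker = colnames(g), n_A = a, n_B = b, statistic = stat,
             p_value = p, flagged = !is.na(p) & p < 0.05, testable = n > 0,
             row.names = NULL)
}

#' Discard individuals with missing genotype calls
#'
#' Crossover calling requires complete rows: an unknown call hides the
#' parental state over a stretch of markers and would bias the minimal
#' crossover count. Individuals with any missing call are removed (logged).
#'
#' @param genotypes genotype matrix.
#' @return the filtered genotype matrix.
#' @export
drop_incomplete_individuals <- function(genotypes) {
  keep <- rowSums(is.na(unclass(genotypes))) == 0L
  if (!any(keep)) stopf("all individuals have missing calls: empty population")
  if (any(!keep))
    logf("drop_incomplete_individuals", "removed %d of %d individuals with missing calls",
         sum(!keep), length(keep))
  genotypes[keep, , drop = FALSE]
}

#' Call crossovers from a testcross genotype matrix
#'
#' Emits one crossover event for every adjacent-marker pair whose calls
#' differ within an individual. This is the minimal crossover count
#' consistent with the data: even numbers of exchanges inside one interval
#' are invisible to two-state genotypes. The event interval is
#' `[left marker bp, right marker bp)` (0-based half-open) and the point
#' position used downstream is the interval midpoint.
#'
#' @param genotypes complete genotype matrix (run
#'   [drop_incomplete_individuals()] first).
#' @param map the [marker_map()] the columns are aligned to.
#' @return data.frame of events: individual, chrom, left_marker,
#'   right_marker, start, end, point.
#' @export
call_crossovers <- function(genotypes, map) {
  stopifnot(inherits(map, "marker_map"))
  g <- unclass(genotypes)
  if (!identical(colnames(g), map$marker))
    stopf("genotype columns are not aligned to the marker map")
  if (anyNA(g))
    stopf("missing calls present; run drop_incomplete_individuals() first")
  out <- vector("list", length(unique(map$chrom)))
  names(out) <- unique(map$chrom)
  for (ch in unique(map$chrom)) {
    cols <- which(map$chrom == ch)
    if (length(cols) < 2L) next
    sub <- g[, cols, drop = FALSE]
    chg <- sub[, -1L, drop = FALSE] != sub[, -length(cols), drop = FALSE]
    idx <- which(chg, arr.ind = TRUE)
    if (!nrow(idx)) next
    li <- cols[idx[, 2L]]
    out[[ch]] <- data.frame(
      individual = rownames(g)[idx[, 1L]],
      chrom = ch,
      left_marker = map$marker[li],
      right_marker = map$marker[li + 1L],
      start = map$pos[li],
      end = map$pos[li + 1L],
      stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(ev))
    ev <- data.frame(individual = character(), chrom = character(),
                     left_marker = character(), right_marker = character(),
                     start = numeric(), end = numeric())
  ev$point <- (ev$start + ev$end) / 2
  rownames(ev) <- NULL
  ev[order(ev$chrom, ev$start, ev$individual), , drop = FALSE]
}

#' Assemble a crossover population
#'
#' The central constructor of the package: takes a genotype matrix and its
#' marker map, optionally drops incomplete individuals and
#' segregation-distorted markers, calls crossovers, and returns a classed
#' object that every downstream analysis (genetic maps, landscape and
#' interference divergence) consumes.
#'
#' @param genotypes genotype matrix ("A"/"B"/NA).
#' @param map a [marker_map()].
#' @param drop_incomplete drop individuals with missing calls (default TRUE;
#'   crossover calling requires complete rows).
#' @param drop_distorted drop markers failing the Mendelian segregation
#'   check at 5% (default FALSE: distorted markers are flagged in the
#'   result but kept, since removal is a policy choice).
#' @return an object of class `crossover_population`: list with `events`,
#'   `genotypes`, `map`, `n` (individuals), `segregation` (per-marker test
#'   table).
#' @export
#' @examples
#' cfg <- sim_config(chromosome_model("A01", 30e6, 1), 50, seed = 1)
#' sim <- simulate_population(cfg)
#' pop <- crossover_population(sim$genotypes, sim$map)
#' summary(pop)
crossover_population <- function(genotypes, map, drop_incomplete = TRUE,
                                 drop_distorted = FALSE) {
  stopifnot(inherits(map, "marker_map"))
  if (drop_incomplete && anyNA(unclass(genotypes)))
    genotypes <- drop_incomplete_individuals(genotypes)
  seg <- check_mendelian_segregation(genotypes)
  if (drop_distorted && any(seg$flagged)) {
    bad <- seg$marker[seg$flagged]
    logf("crossover_population", "removed %d segregation-distorted markers", length(bad))
    keep <- setdiff(map$marker, bad)
    map <- marker_map(map[map$marker %in% keep, c("marker", "chrom", "pos")],
                      chrom_lengths = chrom_lengths(map),
                      centromeres = attr(map, "centromeres"))
    genotypes <- genotypes[, map$marker, drop = FALSE]
  }
  events <- call_crossovers(genotypes, map)
  structure(list(events = events, genotypes = genotypes, map = map,
                 n = nrow(genotypes), segregation = seg),
            class = "crossover_population")
}

#' @export
print.crossover_population <- function(x, ...) {
  cat(sprintf("<crossover_population> %d individuals, %d markers, %d crossovers (%.1f per meiocyte)\n",
              x$n, nrow(x$map), nrow(x$events), 2 * nrow(x$events) / x$n))
  invisible(x)
}

#' @export
summary.crossover_population <- function(object, ...) {
  summarize_population(object$events, object$n, object$map)
}

#' @export
plot.crossover_population <- function(x, n_bins = 10, ...) {
  pos <- relative_positions(x$events, x$map)
  bd <- bin_relative_positions(pos, n_bins)
  graphics::barplot(bd$prob * n_bins, names.arg = seq_len(n_bins),
                    xlab = "chromosome bin (pooled)",
                    ylab = "relative recombination rate", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Population-level crossover summary
#'
#' The mean number of crossovers per male meiocyte is obtained by doubling
#' the per-gamete total: each testcross progeny reveals a single gamete, so
#' mean = 2 x total / n. Also tabulates, per chromosome, how many
#' individuals carry 0, 1, 2, ... crossovers.
#'
#' @param events crossover events data.frame.
#' @param n_individuals population size (>= 1).
#' @param map optional [marker_map()] (gives the chromosome universe for the
#'   frequency table).
#' @return an object of class `population_summary`.
#' @export
summarize_population <- function(events, n_individuals, map = NULL) {
  if (n_individuals < 1) stopf("n_individuals must be >= 1")
  total <- nrow(events)
  chroms <- if (!is.null(map)) unique(map$chrom) else sort(unique(events$chrom))
  freq <- lapply(chroms, function(ch) {
    cnt <- table(factor(events$individual[events$chrom == ch]))
    per_ind <- c(as.integer(cnt), integer(n_individuals - length(cnt)))
    tab <- table(factor(per_ind, levels = 0:max(c(per_ind, 1))))
    as.integer(tab)
  })
  names(freq) <- chroms
  structure(list(n_individuals = n_individuals, total_crossovers = total,
                 mean_per_meiocyte = 2 * total / n_individuals,
                 per_chromosome_freq = freq),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("Population of %d testcross individuals\n", x$n_individuals))
  cat(sprintf("Total crossovers detected: %d\n", x$total_crossovers))
  cat(sprintf("Average crossovers per male meiocyte (2 x total / n): %.1f\n",
              x$mean_per_meiocyte))
  invisible(x)
}

#' Share of a crossover-rate difference explained by an intermediate hybrid
#'
#' Places a test population's mean between a low and a high reference on a
#' 0-100% scale: 100 x (mean_test - mean_low) / (mean_high - mean_low),
#' computed on unrounded means.
#'
#' @param mean_test,mean_low,mean_high per-meiocyte crossover means.
#' @return percentage (may fall outside \[0, 100\] if the test mean does).
#' @export
variation_explained <- function(mean_test, mean_low, mean_high) {
  if (mean_high == mean_low) stopf("degenerate reference means")
  100 * (mean_test - mean_low) / (mean_high - mean_low)
}

#' Fraction of the marker-covered genome without crossovers
#'
#' Sums the physical lengths of adjacent-marker intervals containing zero
#' events and divides by the total marker-covered length.
#'
#' @param events crossover events data.frame.
#' @param map a [marker_map()] (>= 2 markers per chromosome).
#' @return percentage of covered genome with no crossover.
#' @export
zero_recombination_fraction <- function(events, map) {
  stopifnot(inherits(map, "marker_map"))
  iv <- map_intervals(map)
  key <- paste(events$chrom, events$left_marker)
  hit <- paste(iv$chrom, iv$left_marker) %in% key
  100 * sum(iv$end[!hit] - iv$start[!hit]) / sum(iv$end - iv$start)
}

#' Adjacent-marker intervals of a map
#'
#' @param map a [marker_map()].
#' @return data.frame: chrom, left_marker, right_marker, start, end.
#' @export
map_intervals <- function(map) {
  stopifnot(inherits(map, "marker_map"))
  out <- lapply(unique(map$chrom), function(ch) {
    sub <- map[map$chrom == ch, , drop = FALSE]
    k <- nrow(sub)
    data.frame(chrom = ch, left_marker = sub$marker[-k],
               right_marker = sub$marker[-1L],
               start = sub$pos[-k], end = sub$pos[-1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
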