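#' Genetic positions of crossover events
#'
#' Places each event on the genetic axis: cumulative cM at its physical
#' midpoint by linear interpolation between the flanking markers' cumulative
#' positions, then normalized by the chromosome's total genetic length.
#'
#' @param events crossover events data.frame.
#' @param gmap a [build_map()] result built on the same population.
#' @return `events` with columns `g_cm` (cM) and `rel_g` (fraction of the
#'   chromosome's genetic length).
#' @export
crossover_genetic_positions <- function(events, gmap) {
  stopifnot(inherits(gmap, "genetic_map"))
  iv <- gmap$intervals
  key <- match(paste(events$chrom, events$left_marker),
               paste(iv$chrom, iv$left_marker))
  if (anyNA(key)) stopf("event outside the mapped span")
  if (any(!iv$mappable[key]))
    stopf("event falls in an unmappable interval (r >= 0.5)")
  frac <- (events$point - iv$start[key]) / (iv$end[key] - iv$start[key])
  events$g_cm <- iv$cum_left[key] + frac * iv$cM[key]
  tot <- gmap$chromosome_cm[events$chrom]
  if (any(tot <= 0)) stopf("chromosome with zero genetic length")
  events$rel_g <- as.numeric(events$g_cm / tot)
  events
}

#' Inter-crossover distances within gametes
#'
#' For every individual x chromosome carrying at least two crossovers,
#' the distances between successive crossovers, expressed as fractions of
#' that chromosome's genetic length; units with fewer than two crossovers
#' contribute nothing. The pooled list concatenates all chromosomes
#' (distances never span chromosomes).
#'
#' @param events events carrying `rel_g` (see
#'   [crossover_genetic_positions()]).
#' @return object of class `intercross_sample`: `distances` (pooled numeric
#'   in (0, 1\]), `n_units` (individual-chromosome pairs contributing),
#'   `n_crossovers`.
#' @export
inter_crossover_distances <- function(events) {
  if (is.null(events$rel_g)) stopf("events lack rel_g; run crossover_genetic_positions()")
  ord <- order(events$chrom, events$individual, events$rel_g)
  x <- events$rel_g[ord]
  u <- paste(events$chrom, events$individual)[ord]
  same <- u[-1] == u[-length(u)]
  d <- diff(x)[same]
  n_units <- if (length(d)) length(unique(u[c(same, FALSE) | c(FALSE, same)])) else 0L
  if (!length(d))
    logf("inter_crossover_distances", "no individual-chromosome unit with >= 2 crossovers")
  structure(list(distances = d, n_units = n_units, n_crossovers = nrow(events)),
            class = "intercross_sample")
}

#' @export
print.intercross_sample <- function(x, ...) {
  cat(sprintf("<intercross_sample> %d inter-crossover distances from %d units\n",
              length(x$distances), x$n_units))
  invisible(x)
}

#' @noRd
bin_distances <- function(d, n_bins) {
  tabulate(pmin(floor(pmin(pmax(d, 0), 1) * n_bins) + 1L, n_bins), nbins = n_bins)
}

#' Internal shuffle backbone: positions + fixed unit labels per chromosome
#' @noRd
shuffle_frame <- function(events) {
  ord <- order(events$chrom, events$individual)
  u <- paste(events$chrom, events$individual)[ord]
  list(chrom = events$chrom[ord],
       unit = match(u, unique(u)),
       pos = events$rel_g[ord],
       chrom_index = split(seq_along(ord), events$chrom[ord]))
}

#' One crossover shuffle: permute positions within chromosomes, units fixed
#' @noRd
shuffle_assignment <- function(fr) {
  x <- fr$pos
  for (ix in fr$chrom_index) x[ix] <- x[ix][sample.int(length(ix))]
  x
}

#' Inter-crossover distances of an assignment, optionally detection-filtered
#'
#' Called crossovers sit at interval midpoints and a gamete can show at most
#' one call change per marker interval: an even number of exchanges in one
#' interval is invisible to two-state genotypes. A shuffled gamete, however,
#' can receive several crossovers with the same midpoint. The detection
#' filter re-applies the genotyping parity rule to shuffled gametes (keep a
#' position iff its within-gamete multiplicity is odd), so the null
#' distribution describes interference-free crossovers as seen through the
#' same detection process as the data.
#' @noRd
assignment_distances <- function(unit, x, detection_filter = TRUE) {
  o <- order(unit, x)
  xs <- x[o]; us <- unit[o]
  if (detection_filter && length(xs) > 1L) {
    new_run <- c(TRUE, us[-1] != us[-length(us)] | xs[-1] != xs[-length(xs)])
    run_id <- cumsum(new_run)
    mult <- tabulate(run_id)
    keep <- new_run & (mult[run_id] %% 2L == 1L)
    xs <- xs[keep]; us <- us[keep]
  }
  if (length(xs) < 2L) return(numeric(0))
  diff(xs)[us[-1] == us[-length(us)]]
}

#' Shuffle-constructed no-interference null
#'
#' Removes all correlations between crossovers while keeping the
#' recombination landscape fixed: per shuffle and per chromosome, the
#' pooled multiset of crossover positions is permuted across individuals,
#' preserving each individual's crossover count. The reference distribution
#' Q is the binned distribution of inter-crossover distances pooled over
#' all `n_shuffles` shuffles; the per-shuffle binned samples are returned
#' for p-value computation.
#'
#' @param events events carrying `rel_g`.
#' @param n_shuffles number of shuffles (default 10000).
#' @param seed integer seed.
#' @param n_bins bins (default 10).
#' @param detection_filter re-apply the genotyping parity rule to shuffled
#'   gametes (default TRUE): positions sharing a marker-interval midpoint
#'   within one gamete cancel pairwise, exactly as even numbers of
#'   exchanges in one interval are invisible in the observed data. Without
#'   it the null is anti-conservative on called crossovers.
#' @return list: `Q` ([binned_distribution()] pooled over shuffles),
#'   `shuffle_counts` (n_shuffles x n_bins matrix), `n_shuffles`.
#' @export
shuffle_null <- function(events, n_shuffles = 10000, seed = NULL, n_bins = 10,
                         detection_filter = TRUE) {
  fr <- shuffle_frame(events)
  counts <- with_seed(seed, {
    t(vapply(seq_len(n_shuffles), function(s)
      bin_distances(assignment_distances(fr$unit, shuffle_assignment(fr),
                                         detection_filter), n_bins),
      numeric(n_bins)))
  })
  list(Q = binned_distribution(colSums(counts)), shuffle_counts = counts,
       n_shuffles = n_shuffles)
}

#' KL divergence to the no-interference null
#'
#' P is the binned distribution of observed inter-crossover distances
#' (genetic, normalized per chromosome, chromosomes pooled); Q is the
#' shuffle-constructed no-interference reference of [shuffle_null()]. The
#' p-value for H0 "no interference" is the fraction of shuffles S whose own
#' distance distribution P_S satisfies KL(P_S, Q) >= KL(P, Q).
#'
#' @param pop a [crossover_population()].
#' @param gmap optional pre-built [build_map()] for the population.
#' @param n_shuffles shuffles (default 10000).
#' @param seed integer seed.
#' @param n_bins bins (default 10).
#' @param pseudocount add 0.5 per bin in the KL computations (default
#'   FALSE; an occupied-P/empty-Q bin is otherwise an error).
#' @param detection_filter see [shuffle_null()] (default TRUE).
#' @return object of class `kl_interference`: `kl`, `p_value`,
#'   `n_shuffles`, `Q`, `n_distances`, `seed`.
#' @export
kl_to_no_interference <- function(pop, gmap = NULL, n_shuffles = 10000,
                                  seed = NULL, n_bins = 10,
                                  pseudocount = FALSE, detection_filter = TRUE) {
  stopifnot(inherits(pop, "crossover_population"))
  if (is.null(gmap)) gmap <- build_map(pop)
  ev <- crossover_genetic_positions(pop$events, gmap)
  ics <- inter_crossover_distances(ev)
  if (!length(ics$distances))
    stopf("no inter-crossover distances: interference is untestable")
  P <- bin_distances(ics$distances, n_bins)
  null <- shuffle_null(ev, n_shuffles = n_shuffles, seed = seed, n_bins = n_bins,
                       detection_filter = detection_filter)
  Qc <- null$Q$counts
  kl <- kl_divergence(P, Qc, pseudocount = pseudocount)
  q <- if (pseudocount) (Qc + 0.5) / sum(Qc + 0.5) else Qc / sum(Qc)
  kl_s <- apply(null$shuffle_counts, 1L, function(cs) {
    if (pseudocount) cs <- cs + 0.5
    p <- cs / sum(cs); i <- p > 0
    sum(p[i] * log(p[i] / q[i]))
  })
  structure(list(kl = kl, p_value = mean(kl_s >= kl),
                 n_shuffles = n_shuffles, Q = null$Q,
                 n_distances = length(ics$distances), seed = seed),
            class = "kl_interference")
}

#' @export
print.kl_interference <- function(x, ...) {
  p <- if (x$p_value < 1 / x$n_shuffles)
    sprintf("< %.3g", 1 / x$n_shuffles) else sprintf("%.4g", x$p_value)
  cat(sprintf("KL divergence to no-interference null: %.4f nats (%d distances)\n",
              x$kl, x$n_distances))
  cat(sprintf("Shuffle p-value (H0: no interference, %d shuffles): %s\n",
              x$n_shuffles, p))
  invisible(x)
}

#' Bootstrap ordering test of interference strength
#'
#' Orders populations by their KL divergence to the no-interference null
#' and tests the pairwise orderings by bootstrap over individuals. Because
#' the null Q depends on the sample, each bootstrap replicate recomputes Q
#' on the resample with a reduced number of shuffles
#' (`shuffles_per_replicate`, default 100 — the full-depth null at every
#' replicate is configurable but computationally disproportionate).
#' Pairwise p-values, Bonferroni adjustment and letter groups are formed as
#' in [ordering_test()].
#'
#' @param populations named list of [crossover_population()] objects.
#' @param B bootstrap replicates (default 10000).
#' @param seed integer seed.
#' @param n_bins bins (default 10).
#' @param shuffles_per_replicate shuffles for the per-replicate null
#'   (default 100).
#' @param n_shuffles shuffles for the observed KL values (default 10000).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param detection_filter see [shuffle_null()] (default TRUE).
#' @return object of class `kl_ordering` (see [ordering_test()]).
#' @export
interference_ordering_test <- function(populations, B = 10000, seed = NULL,
                                       n_bins = 10,
                                       shuffles_per_replicate = 100,
                                       n_shuffles = 10000, alpha = 0.05,
                                       detection_filter = TRUE) {
  stopifnot(length(populations) >= 2L)
  if (is.null(names(populations)))
    names(populations) <- paste0("pop", seq_along(populations))
  nm <- names(populations)
  prep <- lapply(populations, function(p) {
    gmap <- build_map(p)
    ev <- crossover_genetic_positions(p$events, gmap)
    list(ev = ev, ids = rownames(p$genotypes),
         rows = split(seq_len(nrow(ev)),
                      factor(ev$individual, levels = rownames(p$genotypes))))
  })
  obs <- vapply(seq_along(populations), function(i)
    kl_to_no_interference(populations[[i]], n_shuffles = n_shuffles,
                          seed = if (is.null(seed)) NULL else
                            substream_seed(seed, paste0("obs", nm[i])),
                          n_bins = n_bins,
                          detection_filter = detection_filter)$kl, 0)
  names(obs) <- nm
  boot <- with_seed(seed, {
    vapply(seq_along(populations), function(i) {
      pr <- prep[[i]]
      n <- length(pr$ids)
      vapply(seq_len(B), function(b) {
        tries <- 0L
        repeat {
          take <- sample.int(n, n, replace = TRUE)
          idx <- unlist(pr$rows[take], use.names = FALSE)
          # relabel so resampled copies of one individual stay distinct units
          copy <- rep(seq_along(take), lengths(pr$rows[take]))
          ev <- pr$ev[idx, , drop = FALSE]
          ev$individual <- sprintf("bs%04d", copy)
          ics <- inter_crossover_distances(ev)
          ok <- length(ics$distances) > 0
          if (ok) {
            P <- bin_distances(ics$distances, n_bins)
            null <- shuffle_null(ev, n_shuffles = shuffles_per_replicate,
                                 n_bins = n_bins,
                                 detection_filter = detection_filter)
            ok <- !any(P > 0 & null$Q$counts == 0)
          }
          if (ok) break
          tries <- tries + 1L
          if (tries > 100L) stopf("degenerate bootstrap resamples for %s", nm[i])
        }
        if (tries) logf("interference_ordering", "redrew %d resamples", tries)
        kl_divergence(P, null$Q$counts)
      }, 0)
    }, numeric(B))
  })
  colnames(boot) <- nm
  finish_ordering(obs, boot, nm, alpha, B, seed)
}
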