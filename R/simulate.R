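#' Sample crossover positions on a bivalent
#'
#' Draws crossover positions along one chromosome of a single meiosis from a
#' stationary gamma renewal process: inter-crossover genetic distances are
#' i.i.d. Gamma with shape `nu` and mean 1/2 Morgan, i.e. a bivalent rate of
#' 2 crossovers per Morgan. `nu = 1` is the no-interference (Poisson) case;
#' larger `nu` makes successive crossovers more regularly spaced, emulating
#' crossover interference. Stationarity is achieved by starting the renewal
#' chain at a burn-in origin 5 Morgans before the chromosome start and
#' keeping events in `[0, genetic_length]` (the residual bias is negligible
#' for `nu <= 20`).
#'
#' Uses the current RNG stream; seed at a higher level (see
#' [simulate_population()]).
#'
#' @param chrom a [chromosome_model()].
#' @param nu gamma shape (interference strength), `>= 1`.
#' @return sorted numeric vector of genetic positions in Morgans.
#' @export
#' @examples
#' set.seed(1)
#' sample_bivalent_crossovers(chromosome_model("A01", 30e6, 1), nu = 5)
sample_bivalent_crossovers <- function(chrom, nu = 1) {
  stopifnot(inherits(chrom, "chromosome_model"))
  if (!is.finite(nu) || nu < 1) stopf("nu must be finite and >= 1")
  L <- chrom$genetic_length
  if (!is.finite(L) || L < 0) stopf("invalid chromosome model: bad genetic length")
  if (L == 0) return(numeric(0))
  burnin <- 5
  span <- L + burnin
  # expected 2*span events; draw with generous headroom, extend if needed
  n0 <- ceiling(2 * span + 6 * sqrt(2 * span)) + 10L
  pos <- -burnin + cumsum(stats::rgamma(n0, shape = nu, rate = 2 * nu))
  while (pos[length(pos)] < L) {
    pos <- c(pos, pos[length(pos)] +
               cumsum(stats::rgamma(n0, shape = nu, rate = 2 * nu)))
  }
  pos[pos >= 0 & pos <= L]
}

#' Thin bivalent crossovers to a single gamete
#'
#' Each crossover on the bivalent involves two of the four chromatids, so a
#' random gamete inherits it with probability 1/2. Retains each position
#' independently with probability `p`, preserving order.
#'
#' @param positions sorted numeric vector of genetic positions (Morgans).
#' @param p retention probability in `[0, 1]` (default 1/2).
#' @return the retained positions, still sorted.
#' @export
thin_to_gamete <- function(positions, p = 0.5) {
  if (!is.finite(p) || p < 0 || p > 1) stopf("p must be in [0, 1]")
  positions[stats::runif(length(positions)) < p]
}

#' Simulation configuration
#'
#' @param chromosomes list of [chromosome_model()] objects.
#' @param n_individuals number of gametes (testcross progenies) to simulate.
#' @param nu gamma interference shape, `>= 1` (`1` = no interference).
#' @param thinning chromatid thinning probability (default 1/2).
#' @param seed integer seed; the simulation is fully deterministic given it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(chromosomes, n_individuals, nu = 1, thinning = 0.5,
                       seed = NULL) {
  if (inherits(chromosomes, "chromosome_model")) chromosomes <- list(chromosomes)
  stopifnot(all(vapply(chromosomes, inherits, TRUE, "chromosome_model")))
  if (n_individuals < 1) stopf("n_individuals must be >= 1")
  if (!is.finite(nu) || nu < 1) stopf("nu must be >= 1")
  if (thinning < 0 || thinning > 1) stopf("thinning must be in [0, 1]")
  structure(list(chromosomes = chromosomes,
                 n_individuals = as.integer(n_individuals),
                 nu = nu, thinning = thinning, seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d chromosomes, %d individuals, nu = %g, thinning = %g\n",
              length(x$chromosomes), x$n_individuals, x$nu, x$thinning))
  invisible(x)
}

#' Default evenly spaced marker map for simulated chromosomes
#'
#' Places one marker every `spacing` bp from the chromosome start to its end
#' (ends included), mirroring a SNP panel with homogeneous coverage.
#'
#' @param chromosomes list of [chromosome_model()] objects.
#' @param spacing target inter-marker distance in bp (default 1.5 Mbp).
#' @return a [marker_map()].
#' @export
simulation_marker_map <- function(chromosomes, spacing = 1.5e6) {
  if (inherits(chromosomes, "chromosome_model")) chromosomes <- list(chromosomes)
  tabs <- lapply(chromosomes, function(ch) {
    n <- max(2L, ceiling(ch$physical_length / spacing) + 1L)
    pos <- round(seq(0, ch$physical_length, length.out = n))
    data.frame(marker = sprintf("%s_m%03d", ch$name, seq_len(n)),
               chrom = ch$name, pos = pos, stringsAsFactors = FALSE)
  })
  lens <- vapply(chromosomes, function(ch) ch$physical_length, 0)
  names(lens) <- vapply(chromosomes, function(ch) ch$name, "")
  marker_map(do.call(rbind, tabs), chrom_lengths = lens)
}

#' Simulate a testcross population
#'
#' Generates `n_individuals` gametes under the configured gamma-renewal
#' crossover model, warps crossover positions to the physical axis through
#' each chromosome's Marey map, and genotypes every gamete at the marker
#' positions: the founder parental state is drawn with probability 1/2 per
#' chromosome and flips at each crossover. The true crossovers are returned
#' alongside the genotype matrix for oracle comparisons.
#'
#' @param config a [sim_config()].
#' @param markers a [marker_map()] covering every simulated chromosome with
#'   at least two markers; by default an evenly spaced map from
#'   [simulation_marker_map()].
#' @return an object of class `meiosis_sim`: list with `genotypes`
#'   (individuals x markers character matrix of "A"/"B"), `truth`
#'   (data.frame: individual, chrom, g_pos in Morgans, bp), `map`, `config`.
#' @export
#' @examples
#' cfg <- sim_config(chromosome_model("A01", 30e6, 1), 20, seed = 1)
#' sim <- simulate_population(cfg)
#' dim(sim$genotypes)
simulate_population <- function(config, markers = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(markers)) markers <- simulation_marker_map(config$chromosomes)
  stopifnot(inherits(markers, "marker_map"))
  chrom_names <- vapply(config$chromosomes, function(ch) ch$name, "")
  for (ch in config$chromosomes) {
    pos <- markers$pos[markers$chrom == ch$name]
    if (length(pos) < 2L)
      stopf("invalid map: chromosome %s must carry >= 2 markers", ch$name)
    if (any(pos < 0) || any(pos > ch$physical_length))
      stopf("invalid map: marker outside the bounds of chromosome %s", ch$name)
  }
  n <- config$n_individuals
  ids <- sprintf("ind%04d", seq_len(n))
  with_seed(config$seed, {
    geno <- matrix(NA_character_, nrow = n, ncol = nrow(markers),
                   dimnames = list(ids, markers$marker))
    truth <- vector("list", length(config$chromosomes) * n)
    k <- 0L
    for (ch in config$chromosomes) {
      mcols <- which(markers$chrom == ch$name)
      mpos <- markers$pos[mcols]
      for (i in seq_len(n)) {
        biv <- sample_bivalent_crossovers(ch, config$nu)
        gam <- thin_to_gamete(biv, config$thinning)
        bp <- genetic_to_physical(ch, gam)
        founder <- if (stats::runif(1) < 0.5) "A" else "B"
        flips <- findInterval(mpos, bp)  # crossovers at or left of each marker
        states <- c("A", "B")
        base <- match(founder, states) - 1L
        geno[i, mcols] <- states[(base + flips) %% 2L + 1L]
        if (length(gam)) {
          k <- k + 1L
          truth[[k]] <- data.frame(individual = ids[i], chrom = ch$name,
                                   g_pos = gam, bp = bp,
                                   stringsAsFactors = FALSE)
        }
      }
    }
    truth <- if (k) do.call(rbind, truth[seq_len(k)]) else
      data.frame(individual = character(), chrom = character(),
                 g_pos = numeric(), bp = numeric())
    structure(list(genotypes = geno, truth = truth, map = markers,
                   config = config),
              class = "meiosis_sim")
  })
}

#' @export
print.meiosis_sim <- function(x, ...) {
  cat(sprintf("<meiosis_sim> %d gametes x %d markers, %d true crossovers\n",
              nrow(x$genotypes), ncol(x$genotypes), nrow(x$truth)))
  invisible(x)
}

#' Write true simulated crossovers as a BED-like TSV
#'
#' True crossovers are points; each is written as a 1-bp 0-based half-open
#' interval (chrom, start, end, individual), sorted by chromosome then start.
#'
#' @param sim a `meiosis_sim`.
#' @param path output path.
#' @export
write_true_crossovers <- function(sim, path) {
  stopifnot(inherits(sim, "meiosis_sim"))
  tr <- sim$truth
  bed <- data.frame(chrom = tr$chrom, start = floor(tr$bp),
                    end = floor(tr$bp) + 1, individual = tr$individual)
  bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
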