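#' Read a pipeline run configuration
#'
#' YAML with top-level keys: `seed` (mandatory), `output_dir`, `bins`,
#' `randomizations`, `bootstraps`, `shuffles`, and `populations` — a list
#' whose entries either point to data (`genotypes`, `map` TSV paths) or
#' request a simulation (`simulate:` with `n_individuals`, `nu`, `marey`,
#' `n_chromosomes`, `physical_length`, `genetic_length`, `thinning`).
#'
#' @param path YAML path.
#' @return config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stopf("config must set a seed")
  cfg
}

#' @noRd
config_population <- function(entry, name, seed) {
  if (!is.null(entry$simulate)) {
    s <- entry$simulate
    n_chrom <- if (is.null(s$n_chromosomes)) 10L else as.integer(s$n_chromosomes)
    chroms <- lapply(seq_len(n_chrom), function(i)
      chromosome_model(sprintf("A%02d", i),
                       if (is.null(s$physical_length)) 30e6 else as.numeric(s$physical_length),
                       if (is.null(s$genetic_length)) 1 else as.numeric(s$genetic_length),
                       marey = if (is.null(s$marey)) "flat" else s$marey))
    cfg <- sim_config(chroms,
                      n_individuals = as.integer(s$n_individuals),
                      nu = if (is.null(s$nu)) 1 else as.numeric(s$nu),
                      thinning = if (is.null(s$thinning)) 0.5 else as.numeric(s$thinning),
                      seed = substream_seed(seed, paste0("simulate/", name)))
    sim <- simulate_population(cfg)
    crossover_population(sim$genotypes, sim$map)
  } else {
    map <- read_marker_map(entry$map)
    crossover_population(read_genotypes(entry$genotypes, map), map)
  }
}

#' @noRd
write_report <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load, crossover calling, genetic maps, interval
#' heterogeneity, landscape divergence and interference divergence from one
#' configuration with one master seed (per-stage substreams), writing
#' deterministic TSV reports: `population_summary.tsv`, `genetic_map.tsv`,
#' `interval_heterogeneity.tsv`, `landscape_kl.tsv`, `interference_kl.tsv`,
#' plus per-population BED event files. Rerunning with the same config and
#' seed reproduces the bundle byte for byte.
#'
#' @param config a config list or YAML path (see [read_run_config()]).
#' @param outdir output directory (overrides `config$output_dir`).
#' @param stages subset of `c("summary", "map", "heterogeneity",
#'   "landscape", "interference")`; default all.
#' @return (invisibly) named list of result objects.
#' @export
run_pipeline <- function(config, outdir = NULL,
                         stages = c("summary", "map", "heterogeneity",
                                    "landscape", "interference")) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$seed)) stopf("config must set a seed")
  seed <- as.integer(config$seed)
  outdir <- if (!is.null(outdir)) outdir else
    if (!is.null(config$output_dir)) config$output_dir else "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  bins <- if (is.null(config$bins)) 10L else as.integer(config$bins)
  n_rand <- if (is.null(config$randomizations)) 10000L else as.integer(config$randomizations)
  n_boot <- if (is.null(config$bootstraps)) 10000L else as.integer(config$bootstraps)
  n_shuf <- if (is.null(config$shuffles)) 10000L else as.integer(config$shuffles)
  stages <- match.arg(stages, several.ok = TRUE)
  pops_cfg <- config$populations
  if (is.null(pops_cfg) || length(pops_cfg) < 1L) stopf("config lists no populations")
  nm <- vapply(seq_along(pops_cfg), function(i) {
    if (!is.null(pops_cfg[[i]]$name)) pops_cfg[[i]]$name else sprintf("pop%d", i)
  }, "")
  prov <- sprintf("meiodiv pipeline | seed=%d bins=%d randomizations=%d bootstraps=%d shuffles=%d",
                  seed, bins, n_rand, n_boot, n_shuf)
  pops <- lapply(seq_along(pops_cfg), function(i) {
    logf("pipeline", "stage load/simulate: population %s", nm[i])
    tryCatch(config_population(pops_cfg[[i]], nm[i], seed),
             error = function(e) stopf("stage load [%s]: %s", nm[i], conditionMessage(e)))
  })
  names(pops) <- nm
  for (i in seq_along(pops))
    write_crossovers(pops[[i]]$events,
                     file.path(outdir, sprintf("events_%s.bed", nm[i])))
  results <- list(populations = pops)

  if ("summary" %in% stages) {
    tab <- do.call(rbind, lapply(nm, function(p) {
      s <- summary(pops[[p]])
      data.frame(population = p, n_individuals = s$n_individuals,
                 total_crossovers = s$total_crossovers,
                 mean_per_meiocyte = round(s$mean_per_meiocyte, 1))
    }))
    write_report(tab, file.path(outdir, "population_summary.tsv"), prov)
    results$summary <- tab
  }
  if ("map" %in% stages) {
    maps <- lapply(pops, build_map)
    tab <- do.call(rbind, lapply(nm, function(p) {
      iv <- maps[[p]]$intervals
      data.frame(population = p, iv[, c("chrom", "left_marker", "right_marker",
                                        "r", "cM")])
    }))
    write_report(tab, file.path(outdir, "genetic_map.tsv"), prov)
    results$maps <- maps
    if (length(pops) >= 2L) {
      cmp <- maplength_comparison(pops)
      write_report(data.frame(population = names(cmp$totals),
                              total_cM = round(cmp$totals, 2),
                              group = cmp$letters[names(cmp$totals)]),
                   file.path(outdir, "maplength_comparison.tsv"), prov)
      results$maplength <- cmp
    }
  }
  if ("heterogeneity" %in% stages && length(pops) >= 2L) {
    prs <- utils::combn(nm, 2L)
    tab <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
      het <- interval_heterogeneity(pops[[prs[1L, k]]], pops[[prs[2L, k]]])
      data.frame(pop_a = prs[1L, k], pop_b = prs[2L, k],
                 het[, c("chrom", "left_marker", "right_marker", "statistic",
                         "p_value", "significant")])
    }))
    write_report(tab, file.path(outdir, "interval_heterogeneity.tsv"), prov)
    results$heterogeneity <- tab
  }
  if ("landscape" %in% stages) {
    flat <- lapply(nm, function(p)
      flatness_pvalue(pops[[p]], n_randomizations = n_rand,
                      seed = substream_seed(seed, paste0("flatness/", p)),
                      n_bins = bins))
    names(flat) <- nm
    lg <- if (length(pops) >= 2L)
      ordering_test(pops, B = n_boot, seed = substream_seed(seed, "landscape-order"),
                    n_bins = bins) else NULL
    tab <- data.frame(population = nm, scope = "pooled",
                      kl_to_flat = vapply(flat, function(f) f$kl, 0),
                      p_value = vapply(flat, function(f) f$p_value, 0),
                      group = if (is.null(lg)) "" else lg$letters[nm])
    write_report(tab, file.path(outdir, "landscape_kl.tsv"), prov)
    results$landscape <- list(flatness = flat, ordering = lg)
  }
  if ("interference" %in% stages) {
    intf <- lapply(nm, function(p)
      kl_to_no_interference(pops[[p]], n_shuffles = n_shuf,
                            seed = substream_seed(seed, paste0("interference/", p)),
                            n_bins = bins))
    names(intf) <- nm
    io <- if (length(pops) >= 2L)
      interference_ordering_test(pops, B = n_boot,
                                 seed = substream_seed(seed, "interference-order"),
                                 n_bins = bins, n_shuffles = n_shuf) else NULL
    tab <- data.frame(population = nm, scope = "pooled",
                      kl_to_no_interference = vapply(intf, function(f) f$kl, 0),
                      p_value = vapply(intf, function(f) f$p_value, 0),
                      n_shuffles = n_shuf,
                      group = if (is.null(io)) "" else io$letters[nm])
    write_report(tab, file.path(outdir, "interference_kl.tsv"), prov)
    results$interference <- list(tests = intf, ordering = io)
  }
  invisible(results)
}
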