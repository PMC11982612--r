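#' Marker map constructor
#'
#' The coordinate backbone of every analysis: ordered physical SNP positions
#' per chromosome, with optional per-chromosome physical lengths and
#' centromere intervals. Positions are validated to be strictly increasing
#' within each chromosome and marker ids to be unique; every chromosome must
#' carry at least two markers.
#'
#' All physical coordinates are bp; intervals are handled 0-based half-open
#' internally (BED convention).
#'
#' @param x data.frame with columns `marker`, `chrom`, `pos` (bp).
#' @param chrom_lengths optional named numeric vector of chromosome physical
#'   lengths (bp); defaults to the last marker position per chromosome.
#' @param centromeres optional data.frame with columns `chrom`, `start`,
#'   `end` (bp, 0-based half-open).
#' @return a data.frame of class `marker_map` with attributes
#'   `chrom_lengths` and (optionally) `centromeres`.
#' @export
marker_map <- function(x, chrom_lengths = NULL, centromeres = NULL) {
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(x)))
    stopf("marker map needs columns: %s", paste(need, collapse = ", "))
  x <- data.frame(marker = as.character(x$marker), chrom = as.character(x$chrom),
                  pos = as.numeric(x$pos), stringsAsFactors = FALSE)
  if (anyDuplicated(x$marker))
    stopf("duplicated marker id: %s", x$marker[duplicated(x$marker)][1])
  if (any(!is.finite(x$pos)) || any(x$pos < 0))
    stopf("marker positions must be finite and >= 0")
  x <- x[order(match(x$chrom, unique(x$chrom)), x$pos), , drop = FALSE]
  rownames(x) <- NULL
  for (ch in unique(x$chrom)) {
    p <- x$pos[x$chrom == ch]
    if (length(p) < 2L) stopf("chromosome %s has < 2 markers", ch)
    if (any(diff(p) <= 0))
      stopf("marker positions not strictly increasing on chromosome %s", ch)
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(x$pos, x$chrom, max)
    chrom_lengths <- chrom_lengths[unique(x$chrom)]
  } else {
    miss <- setdiff(unique(x$chrom), names(chrom_lengths))
    if (length(miss)) stopf("chrom_lengths missing for: %s", paste(miss, collapse = ", "))
    bad <- vapply(unique(x$chrom), function(ch)
      any(x$pos[x$chrom == ch] > chrom_lengths[[ch]]), TRUE)
    if (any(bad))
      stopf("marker position beyond chromosome length on %s",
            paste(unique(x$chrom)[bad], collapse = ", "))
  }
  cl <- unlist(chrom_lengths)
  attr(x, "chrom_lengths") <- stats::setNames(as.numeric(cl), names(cl))
  if (!is.null(centromeres)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(centromeres)))
    attr(x, "centromeres") <- as.data.frame(centromeres)
  }
  class(x) <- c("marker_map", "data.frame")
  x
}

#' @export
print.marker_map <- function(x, ...) {
  cat(sprintf("<marker_map> %d markers on %d chromosomes\n",
              nrow(x), length(unique(x$chrom))))
  NextMethod()
}

#' Chromosome physical lengths of a marker map
#' @param map a [marker_map()].
#' @return named numeric vector of bp lengths.
#' @export
chrom_lengths <- function(map) attr(map, "chrom_lengths")

#' Read a marker map from TSV
#'
#' Expects a header with columns `marker`, `chrom`, `pos_bp`; optional
#' columns `chrom_length`, `cen_start`, `cen_end` supply chromosome lengths
#' and centromere intervals.
#'
#' @param path TSV path.
#' @return a [marker_map()].
#' @export
read_marker_map <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("marker", "chrom", "pos_bp")
  if (!all(need %in% names(x)))
    stopf("malformed marker map %s: need columns %s", path,
          paste(need, collapse = ", "))
  if (any(!is.finite(suppressWarnings(as.numeric(x$pos_bp)))))
    stopf("malformed marker map %s: non-numeric pos_bp at line %d", path,
          which(!is.finite(suppressWarnings(as.numeric(x$pos_bp))))[1] + 1L)
  lens <- NULL
  if ("chrom_length" %in% names(x)) {
    lens <- tapply(as.numeric(x$chrom_length), x$chrom, max)
    lens <- lens[unique(x$chrom)]
  }
  cen <- NULL
  if (all(c("cen_start", "cen_end") %in% names(x))) {
    cc <- unique(data.frame(chrom = x$chrom,
                            start = as.numeric(x$cen_start),
                            end = as.numeric(x$cen_end)))
    cen <- cc[is.finite(cc$start) & is.finite(cc$end), , drop = FALSE]
    if (!nrow(cen)) cen <- NULL
  }
  marker_map(data.frame(marker = x$marker, chrom = x$chrom,
                        pos = as.numeric(x$pos_bp)),
             chrom_lengths = lens, centromeres = cen)
}

#' Write a marker map to TSV
#'
#' @param map a [marker_map()].
#' @param path output path.
#' @export
write_marker_map <- function(map, path) {
  stopifnot(inherits(map, "marker_map"))
  out <- data.frame(marker = map$marker, chrom = map$chrom, pos_bp = map$pos,
                    chrom_length = chrom_lengths(map)[map$chrom])
  cen <- attr(map, "centromeres")
  if (!is.null(cen)) {
    out$cen_start <- cen$start[match(map$chrom, cen$chrom)]
    out$cen_end <- cen$end[match(map$chrom, cen$chrom)]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a testcross genotype matrix from TSV
#'
#' First column = individual id; remaining columns = marker calls coded
#' `A` / `B` (the two parental states) or `-` (missing). Columns are aligned
#' to the marker map order; a permuted column order is realigned silently
#' (logged). Unknown call symbols and markers absent from the map are
#' rejected.
#'
#' @param path TSV path.
#' @param map a [marker_map()].
#' @return character matrix (individuals x markers) with `NA` for missing,
#'   of class `genotype_matrix`.
#' @export
read_genotypes <- function(path, map) {
  stopifnot(inherits(map, "marker_map"))
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(x) < 2L) stopf("genotype file %s has no marker columns", path)
  ids <- as.character(x[[1]])
  g <- as.matrix(x[, -1, drop = FALSE])
  extra <- setdiff(colnames(g), map$marker)
  if (length(extra))
    stopf("genotype column(s) absent from marker map: %s",
          paste(extra, collapse = ", "))
  miss <- setdiff(map$marker, colnames(g))
  if (length(miss))
    stopf("marker(s) missing from genotype file: %s", paste(miss, collapse = ", "))
  if (!identical(colnames(g), map$marker)) {
    logf("read_genotypes", "realigned %d genotype columns to map order", ncol(g))
    g <- g[, map$marker, drop = FALSE]
  }
  bad <- !(g %in% c("A", "B", "-"))
  if (any(bad)) {
    idx <- which(bad)[1]
    stopf("unknown call symbol '%s' (individual %s, marker %s)",
          g[idx], ids[(idx - 1) %% nrow(g) + 1],
          colnames(g)[(idx - 1) %/% nrow(g) + 1])
  }
  g[g == "-"] <- NA_character_
  rownames(g) <- ids
  class(g) <- c("genotype_matrix", class(g))
  g
}

#' Write a testcross genotype matrix to TSV
#'
#' Missing calls are written as `-` (spreadsheet-safe).
#'
#' @param genotypes character matrix from [read_genotypes()] or
#'   [simulate_population()].
#' @param path output path.
#' @export
write_genotypes <- function(genotypes, path) {
  g <- unclass(genotypes)
  g[is.na(g)] <- "-"
  out <- data.frame(individual = rownames(g), g, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write crossover events as a BED-style TSV
#'
#' Columns: chrom, start, end, individual, left_marker, right_marker.
#' Coordinates are 0-based half-open; rows are sorted by chromosome then
#' start. An empty event list yields a header-only file.
#'
#' @param events data.frame of crossover events (see [call_crossovers()]).
#' @param path output path.
#' @export
write_crossovers <- function(events, path) {
  cols <- c("chrom", "start", "end", "individual", "left_marker", "right_marker")
  if (nrow(events)) {
    events <- events[order(events$chrom, events$start), cols, drop = FALSE]
  } else {
    events <- events[, cols, drop = FALSE]
  }
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read crossover events written by [write_crossovers()]
#'
#' @param path BED-style TSV path.
#' @param map optional [marker_map()] used to restore interval midpoints.
#' @return events data.frame.
#' @export
read_crossovers <- function(path, map = NULL) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  x$point <- (x$start + x$end) / 2
  x
}
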