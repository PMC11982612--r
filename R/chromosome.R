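#' Chromosome model for meiosis simulation
#'
#' Describes one chromosome by its physical length (bp), genetic length
#' (Morgans) and a Marey map linking the two scales. The Marey map is given
#' as ordered anchors `(physical fraction, cumulative genetic fraction)`;
#' piecewise-linear interpolation between anchors defines where along the
#' physical axis crossovers sampled on the genetic axis land, i.e. the
#' landscape shape. The `"flat"` preset is the identity (uniform landscape);
#' the `"distal"` preset concentrates genetic length near the chromosome
#' ends, emulating the distally biased, pericentromerically suppressed
#' pattern typical of large-genome crops.
#'
#' @param name chromosome name.
#' @param physical_length physical length in bp (> 0).
#' @param genetic_length genetic length in Morgans (>= 0).
#' @param marey `"flat"`, `"distal"`, or a two-column matrix of anchors
#'   (physical fraction, genetic fraction) starting at (0,0), ending at
#'   (1,1), both columns non-decreasing.
#' @return an object of class `chromosome_model`.
#' @export
#' @examples
#' chromosome_model("A01", 30e6, 1, marey = "distal")
chromosome_model <- function(name, physical_length, genetic_length,
                             marey = "flat") {
  if (!is.finite(physical_length) || physical_length <= 0)
    stopf("physical_length must be a positive finite number of bp")
  if (!is.finite(genetic_length) || genetic_length < 0)
    stopf("invalid chromosome model: genetic_length must be finite and >= 0")
  anchors <- marey_anchors(marey)
  structure(
    list(name = as.character(name),
         physical_length = as.numeric(physical_length),
         genetic_length = as.numeric(genetic_length),
         anchors = anchors),
    class = "chromosome_model")
}

#' Marey anchor presets
#'
#' @param marey preset name or anchor matrix (see [chromosome_model()]).
#' @return a two-column numeric matrix of anchors.
#' @export
marey_anchors <- function(marey) {
  if (is.character(marey)) {
    marey <- match.arg(marey, c("flat", "distal"))
    a <- switch(marey,
      flat   = cbind(c(0, 1), c(0, 1)),
      distal = cbind(c(0, 0.25, 0.5, 0.75, 1), c(0, 0.45, 0.5, 0.55, 1)))
  } else {
    a <- as.matrix(marey)
  }
  if (ncol(a) != 2L) stopf("anchors must have two columns")
  if (any(a[1, ] != 0) || any(a[nrow(a), ] != 1))
    stopf("anchors must start at (0,0) and end at (1,1)")
  if (any(diff(a[, 1]) < 0) || any(diff(a[, 2]) < 0))
    stopf("anchor coordinates must be non-decreasing")
  dimnames(a) <- list(NULL, c("physical", "genetic"))
  a
}

#' @export
print.chromosome_model <- function(x, ...) {
  cat(sprintf("<chromosome_model> %s: %.3g Mbp, %.3g cM, %d Marey anchors\n",
              x$name, x$physical_length / 1e6, 100 * x$genetic_length,
              nrow(x$anchors)))
  invisible(x)
}

#' Convert genetic positions to physical positions
#'
#' Inverts the chromosome's Marey map: a position `g` (Morgans) along the
#' genetic axis is mapped to bp by piecewise-linear interpolation of the
#' anchors, scaled to the physical length. Monotone non-decreasing in `g`.
#'
#' @param chrom a [chromosome_model()].
#' @param g numeric vector of genetic positions in `[0, genetic_length]`
#'   (Morgans).
#' @return numeric vector of physical positions in bp.
#' @export
#' @examples
#' ch <- chromosome_model("A01", 30e6, 1)
#' genetic_to_physical(ch, 0.5)  # identity warp: mid-chromosome
genetic_to_physical <- function(chrom, g) {
  stopifnot(inherits(chrom, "chromosome_model"))
  if (length(g) == 0L) return(numeric(0))
  if (any(!is.finite(g)) || any(g < 0) || any(g > chrom$genetic_length + 1e-12))
    stopf("genetic position outside [0, genetic_length]")
  gf <- if (chrom$genetic_length > 0) g / chrom$genetic_length else rep(0, length(g))
  gf <- pmin(pmax(gf, 0), 1)
  pf <- stats::approx(chrom$anchors[, "genetic"], chrom$anchors[, "physical"],
                      xout = gf, ties = "ordered", rule = 2)$y
  pf * chrom$physical_length
}

#' Convert physical positions to genetic positions
#'
#' Forward Marey map, the inverse of [genetic_to_physical()].
#'
#' @inheritParams genetic_to_physical
#' @param bp numeric vector of physical positions in `[0, physical_length]`.
#' @return numeric vector of genetic positions in Morgans.
#' @export
physical_to_genetic <- function(chrom, bp) {
  stopifnot(inherits(chrom, "chromosome_model"))
  if (length(bp) == 0L) return(numeric(0))
  if (any(!is.finite(bp)) || any(bp < 0) || any(bp > chrom$physical_length + 1e-6))
    stopf("physical position outside [0, physical_length]")
  pf <- bp / chrom$physical_length
  gf <- stats::approx(chrom$anchors[, "physical"], chrom$anchors[, "genetic"],
                      xout = pf, ties = "ordered", rule = 2)$y
  gf * chrom$genetic_length
}
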