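## Chromosome geometry, unit conversions and per-cell stochastic realizations
## of the random-link model (Poisson linkages, Rabl state, tether topology).

#' Chromosome geometry specification
#'
#' Describes one chromosome carrying a fluorescently tagged locus.  All
#' coordinates are base pairs measured from the left telomere.
#'
#' @param name Chromosome (or locus) label.
#' @param length_bp Chromosome length in base pairs.
#' @param centromere_bp Centromere position in bp from the left telomere.
#' @param locus_bp Tagged-locus position in bp from the left telomere.
#' @return An object of class `chromosome_spec`.
#' @examples
#' chromosome_spec("chrV", 577000, 152000, 116000)
#' @export
chromosome_spec <- function(name, length_bp, centromere_bp, locus_bp) {
  stopifnot(is.character(name), length(name) == 1L)
  for (v in c(length_bp, centromere_bp, locus_bp))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("chromosome coordinates must be finite scalars")
  if (!(centromere_bp > 0 && centromere_bp < length_bp))
    stop("centromere_bp must lie strictly inside (0, length_bp)")
  if (!(locus_bp > 0 && locus_bp < length_bp))
    stop("locus_bp must lie strictly inside (0, length_bp)")
  structure(list(name = name, length_bp = length_bp,
                 centromere_bp = centromere_bp, locus_bp = locus_bp),
            class = "chromosome_spec")
}

#' @export
print.chromosome_spec <- function(x, ...) {
  cat(sprintf("<chromosome_spec> %s: %d kb, CEN at %d kb, locus at %d kb\n",
              x$name, round(x$length_bp / 1000), round(x$centromere_bp / 1000),
              round(x$locus_bp / 1000)))
  invisible(x)
}

#' Packaged chromosome table
#'
#' Returns the bundled table of tagged yeast chromosomes: Chr. V carrying the
#' URA3 tag (577 kb, locus 116 kb from the left telomere, near CEN5) and
#' Chr. II carrying the LYS2 tag (813 kb, locus 343 kb from its nearer, right
#' telomere).  Centromere positions default to reference-genome values and can
#' be overridden by supplying a different file.
#'
#' @param file Path to a tab-separated table with columns `name`, `length_bp`,
#'   `centromere_bp`, `locus_bp`, `locus_name`.  Defaults to the packaged one.
#' @return A data.frame, one row per chromosome.
#' @export
yeast_chromosomes <- function(file = system.file("extdata", "chromosomes.tsv",
                                                 package = "homolink")) {
  tab <- read.csv(file, sep = "\t", stringsAsFactors = FALSE)
  need <- c("name", "length_bp", "centromere_bp", "locus_bp", "locus_name")
  if (!all(need %in% names(tab)))
    stop("chromosome table must have columns: ", paste(need, collapse = ", "))
  tab
}

#' Look up a packaged chromosome by name or tagged-locus name
#'
#' @param name Chromosome name (e.g. `"chrV"`) or locus name (e.g. `"URA3"`).
#' @param table Chromosome table, as from [yeast_chromosomes()].
#' @return A [chromosome_spec()].
#' @export
lookup_chromosome <- function(name, table = yeast_chromosomes()) {
  i <- match(name, table$name)
  if (is.na(i)) i <- match(name, table$locus_name)
  if (is.na(i)) stop("unknown chromosome or locus: ", name)
  chromosome_spec(table$name[i], table$length_bp[i],
                  table$centromere_bp[i], table$locus_bp[i])
}

#' Physical parameters of the polymer model
#'
#' Bundles the physical constants of the confined viscoelastic Rouse model.
#' Lengths are carried in the units in which the field reports them (Kuhn
#' length and resolution in nm, sphere radius in um); internal computations
#' use um and seconds.
#'
#' @param kuhn_length_b Kuhn length, nm.
#' @param compaction_c Linear compaction of the meiotic chromosome, nm of
#'   contour per bp (default 0.0317 nm/bp, i.e. 31.6 bp/nm from nucleosome
#'   geometry; see [compaction_from_nucleosome()]).
#' @param sphere_radius_a Nuclear confinement radius, um.
#' @param alpha Viscoelastic exponent of the medium (particle MSD ~ t^alpha);
#'   locus motion then scales as t^(alpha/2).
#' @param D0 Subdiffusion prefactor, um^2 / s^(alpha/2).  Normalisation
#'   contract: a free locus pair has MSCD = 6 * D0 * t^(alpha/2) (per-axis
#'   relative-coordinate contribution D0 * t^(alpha/2), summed over 3 axes
#'   and doubled for two loci).
#' @param k_rabl Rate of exit from the Rabl configuration, per hour.
#' @param resolution Two-focus resolution limit, nm; foci closer than this
#'   merge into one diffraction-limited spot.
#' @param mscd_floor Censoring threshold for MSCD values, um^2.  Defaults to
#'   (resolution/1000)^2.
#' @return An object of class `polymer_params`.
#' @examples
#' polymer_params()
#' @export
polymer_params <- function(kuhn_length_b = 250, compaction_c = 0.0317,
                           sphere_radius_a = 1.59, alpha = 0.48,
                           D0 = 0.04, k_rabl = 0.605, resolution = 250,
                           mscd_floor = (resolution / 1000)^2) {
  vals <- c(kuhn_length_b = kuhn_length_b, compaction_c = compaction_c,
            sphere_radius_a = sphere_radius_a, alpha = alpha, D0 = D0,
            k_rabl = k_rabl, resolution = resolution, mscd_floor = mscd_floor)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all polymer parameters must be finite and strictly positive")
  if (alpha > 1) stop("alpha must satisfy 0 < alpha <= 1")
  structure(as.list(vals), class = "polymer_params")
}

#' @export
print.polymer_params <- function(x, ...) {
  cat(sprintf(paste0("<polymer_params> b=%g nm, c=%g nm/bp, a=%g um, ",
                     "alpha=%g, D0=%g, k_rabl=%g/h, resolution=%g nm\n"),
              x$kuhn_length_b, x$compaction_c, x$sphere_radius_a, x$alpha,
              x$D0, x$k_rabl, x$resolution))
  invisible(x)
}

#' Linear compaction from nucleosome geometry
#'
#' The chromatin fiber is modelled as nucleosome repeats in which only the
#' linker DNA contributes contour length: `linker_bp` bp of linker at `rise`
#' nm/bp, while `wrapped_bp` bp are compacted into the nucleosome and
#' contribute zero length.
#'
#' @param linker_bp Linker length, bp.
#' @param rise Helical rise of linker DNA, nm/bp (B-DNA: 0.34).
#' @param wrapped_bp Base pairs wrapped per nucleosome.
#' @return Linear compaction in nm of contour per bp.
#' @examples
#' compaction_from_nucleosome(15, 0.34, 146)  # 0.0317 nm/bp
#' @export
compaction_from_nucleosome <- function(linker_bp, rise, wrapped_bp) {
  if (any(linker_bp < 0) || any(wrapped_bp < 0) ||
      any(linker_bp + wrapped_bp <= 0))
    stop("repeat length must be positive (linker_bp, wrapped_bp >= 0, not both 0)")
  if (any(rise < 0)) stop("rise must be nonnegative")
  linker_bp * rise / (linker_bp + wrapped_bp)
}

#' Convert a genomic distance to Kuhn segments
#'
#' @param distance_bp Genomic distance, bp (nonnegative).
#' @param params A [polymer_params()] supplying the compaction `c` (nm/bp)
#'   and Kuhn length `b` (nm).
#' @return Dimensionless number of Kuhn segments, `distance_bp * c / b`.
#' @examples
#' bp_to_kuhn(116000, polymer_params())  # about 14.7
#' @export
bp_to_kuhn <- function(distance_bp, params = polymer_params()) {
  if (any(distance_bp < 0)) stop("distance_bp must be nonnegative")
  distance_bp * params$compaction_c / params$kuhn_length_b
}

#' Kuhn length equivalent under an alternative compaction
#'
#' Rescales the Kuhn length so that the number of Kuhn segments per base pair
#' (hence the chain discretisation and its dynamics) is preserved when the
#' linear compaction changes from `c` to `c_alt`.
#'
#' Note on units: interphase compactions are commonly quoted as bp per nm
#' (e.g. "53 to 65"); pass them as `c_alt = 1/53` etc. so that both
#' compactions are in nm/bp.
#'
#' @param b Reference Kuhn length, nm.
#' @param c Reference compaction, nm/bp.
#' @param c_alt Alternative compaction, nm/bp.
#' @return Equivalent Kuhn length in nm: `b * c_alt / c`.
#' @examples
#' equivalent_kuhn_length(250, 0.0317, 1 / 65)  # about 121 nm
#' @export
equivalent_kuhn_length <- function(b, c, c_alt) {
  if (any(c(b, c, c_alt) <= 0)) stop("all arguments must be positive")
  b * c_alt / c
}

#' Extension of a chromatin loop tip from its axis
#'
#' Contour length of a fully extended loop of `loop_kb` kilobases at linear
#' compaction `nm_per_kb`; the loop tip sits at half the loop contour from
#' the axis.
#'
#' @param loop_kb Loop size, kb.
#' @param nm_per_kb Compaction, nm of contour per kb.
#' @return Tip-to-axis distance in nm.
#' @examples
#' loop_tip_extension(25, 16)  # 400 nm
#' @export
loop_tip_extension <- function(loop_kb, nm_per_kb) {
  if (any(loop_kb < 0) || any(nm_per_kb < 0)) stop("arguments must be nonnegative")
  loop_kb * nm_per_kb
}

#' Classify the effective tether topology of a tagged locus
#'
#' Given interhomolog linkage positions along the chromosome (Kuhn-length
#' coordinates) and the tagged-locus coordinate, determines whether the two
#' homologous loci are effectively untethered, joined by a linear chain
#' (nearest linkage on one side only), or isolated inside an effective ring
#' (linkages on both sides).  A linkage connects *homologous* coordinates, so
#' the tether path locus -> linkage -> homologous locus doubles the genomic
#' distance: `nL = 2 * d` for a linear tether and `(n1, n2) = (2 * d_left,
#' 2 * d_right)` for a ring.
#'
#' @param linkage_positions Numeric vector of linkage coordinates, Kuhn
#'   lengths (any order).
#' @param locus_kuhn Tagged-locus coordinate, Kuhn lengths.
#' @return A list with `topology` (`"unlinked"`, `"linear"` or `"ring"`),
#'   `segments` (named numeric: `nL`, or `n1`/`n2`), and `pinned` (`TRUE`
#'   when a linkage coincides exactly with the locus, giving a zero ring
#'   segment).
#' @examples
#' classify_topology(c(4, 13), 10)  # ring, n1 = 12, n2 = 6
#' @export
classify_topology <- function(linkage_positions, locus_kuhn) {
  stopifnot(length(locus_kuhn) == 1L, is.finite(locus_kuhn))
  pos <- sort(as.numeric(linkage_positions))
  if (length(pos) == 0L)
    return(list(topology = "unlinked", segments = numeric(0), pinned = FALSE))
  d <- pos - locus_kuhn
  if (any(d == 0)) {
    return(list(topology = "ring", segments = c(n1 = 0, n2 = 0), pinned = TRUE))
  }
  dl <- if (any(d < 0)) min(-d[d < 0]) else NA_real_
  dr <- if (any(d > 0)) min(d[d > 0]) else NA_real_
  if (is.na(dl) || is.na(dr)) {
    nL <- 2 * min(dl, dr, na.rm = TRUE)
    list(topology = "linear", segments = c(nL = nL), pinned = FALSE)
  } else {
    list(topology = "ring", segments = c(n1 = 2 * dl, n2 = 2 * dr),
         pinned = FALSE)
  }
}

#' Sample one model cell: linkages, Rabl state and topology
#'
#' Draws a Poisson(`mu`) number of interhomolog linkages at i.i.d. uniform
#' positions along the chromosome (both homologs share each linkage
#' coordinate), a Bernoulli(`p_rabl`) Rabl state (centromeres tethered to the
#' nuclear envelope), and classifies the resulting tether topology of the
#' tagged locus.  Uses the current R random number stream.
#'
#' @param chrom A [chromosome_spec()].
#' @param params A [polymer_params()].
#' @param mu Mean number of linkages (Poisson mean), nonnegative.
#' @param p_rabl Probability that the cell is still in the Rabl
#'   configuration.
#' @return An object of class `cell_realization`: a list with
#'   `linkage_positions` (Kuhn), `rabl`, `topology`, `segments`, `pinned`,
#'   `locus_kuhn` and `chrom_kuhn`.
#' @examples
#' set.seed(1)
#' sample_cell(lookup_chromosome("URA3"), polymer_params(), mu = 3.36,
#'             p_rabl = 0.05)
#' @export
sample_cell <- function(chrom, params, mu, p_rabl = 0) {
  stopifnot(inherits(chrom, "chromosome_spec"), inherits(params, "polymer_params"))
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu < 0)
    stop("mu must be a nonnegative scalar")
  if (p_rabl < 0 || p_rabl > 1) stop("p_rabl must lie in [0, 1]")
  n_kuhn <- bp_to_kuhn(chrom$length_bp, params)
  locus <- bp_to_kuhn(chrom$locus_bp, params)
  k <- rpois(1L, mu)
  pos <- if (k > 0) runif(k, 0, n_kuhn) else numeric(0)
  rabl <- runif(1) < p_rabl
  topo <- classify_topology(pos, locus)
  structure(list(linkage_positions = sort(pos), rabl = rabl,
                 topology = topo$topology, segments = topo$segments,
                 pinned = topo$pinned, locus_kuhn = locus,
                 chrom_kuhn = n_kuhn),
            class = "cell_realization")
}

#' @export
print.cell_realization <- function(x, ...) {
  seg <- if (length(x$segments))
    paste(sprintf("%s=%.2f", names(x$segments), x$segments), collapse = ", ")
  else "-"
  cat(sprintf("<cell_realization> %d linkage(s), rabl=%s, topology=%s (%s)\n",
              length(x$linkage_positions), x$rabl, x$topology, seg))
  invisible(x)
}
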