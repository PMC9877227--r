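#' Radial distribution function between a reference selection and species
#' markers
#'
#' Standard pair-distance histogram with minimal-image distances, normalized
#' per frame by the spherical-shell volume `4 pi r^2 dr` (at the bin center)
#' and the target number density in the box, then averaged over the window.
#' For protein-anchored RDFs the conventional reference is the Calpha of the
#' deepest inserted residue (see [insertion_depth()]).
#'
#' @param system a [membrane_system()].
#' @param ref_idx integer atom indices of the reference selection.
#' @param species target species name (marker atoms are the targets).
#' @param window integer frame indices.
#' @param dr bin width (A), default 0.1.
#' @param r_max maximum distance (A); must not exceed half the smallest box
#'   length. Default `min(box)/2`.
#' @param leaflet optional leaflet restriction for the targets.
#' @param lateral if `TRUE`, use 2D in-plane distances with ring-area
#'   normalization `2 pi r dr` and the leaflet's area density (for
#'   leaflet-restricted, in-plane analyses). Default `FALSE` (3D).
#' @return object of class `rdf_result`: `r` (bin centers), `g`, `dr`,
#'   `r_max`, `frames`, `reference`, `species`.
#' @export
rdf <- function(system, ref_idx, species,
                window = seq_len(n_frames(system)), dr = 0.1, r_max = NULL,
                leaflet = NULL, lateral = FALSE) {
  if (length(window) == 0L) stop("empty frame window")
  if (!length(ref_idx)) stop("empty selection: reference")
  boxes <- system$box[window, , drop = FALSE]
  half <- min(boxes[, 1:3]) / 2
  if (is.null(r_max)) r_max <- half
  if (r_max > half + 1e-9)
    stop("r_max = ", r_max, " exceeds half the smallest box length (", half,
         ")")
  nb <- ceiling(r_max / dr)
  edges <- seq(0, by = dr, length.out = nb + 1L)
  centers <- edges[-1L] - dr / 2
  gacc <- numeric(nb)
  for (wi in seq_along(window)) {
    f <- window[wi]
    mk <- if (is.null(leaflet)) marker_table(system, f)
    else .leaflet_markers(system, f, leaflet)
    tgt <- mk[mk$species == species, , drop = FALSE]
    if (!nrow(tgt)) stop("empty selection: no ", species, " targets")
    box <- system$box[f, ]
    A <- system$coords[ref_idx, , f, drop = FALSE][, , 1]
    B <- as.matrix(tgt[, c("x", "y", "z")])
    if (lateral) {
      A2 <- cbind(A[, 1:2, drop = FALSE], 0)
      B2 <- cbind(B[, 1:2, drop = FALSE], 0)
      D <- mi_cross_dist(A2, B2, c(box[1], box[2], 1))
      dens <- nrow(B) / (box[1] * box[2])
      shell <- 2 * pi * centers * dr
    } else {
      D <- mi_cross_dist(A, B, box)
      dens <- nrow(B) / prod(box)
      shell <- 4 * pi * centers^2 * dr
    }
    # self-pairs (reference atom also a target) excluded via zero distance
    d <- D[D > 1e-9 & D <= r_max]
    h <- tabulate(pmin(floor(d / dr) + 1L, nb), nbins = nb)
    gacc <- gacc + h / (length(ref_idx) * shell * dens)
  }
  structure(list(r = centers, g = gacc / length(window), dr = dr,
                 r_max = r_max, frames = length(window),
                 reference = paste(length(ref_idx), "atoms"),
                 species = species, lateral = lateral),
            class = "rdf_result")
}

#' Lipid-lipid RDF within a leaflet
#'
#' Same estimator as [rdf()] restricted to the marker atoms of one leaflet;
#' self-pairs are excluded when `species_a == species_b`.
#'
#' @param system a [membrane_system()].
#' @param species_a,species_b species names.
#' @param leaflet leaflet label.
#' @inheritParams rdf
#' @return an `rdf_result`.
#' @export
lipid_lipid_rdf <- function(system, species_a, species_b, leaflet = "upper",
                            window = seq_len(n_frames(system)), dr = 0.1,
                            r_max = NULL, lateral = FALSE) {
  mk1 <- .leaflet_markers(system, window[1], leaflet)
  ref <- mk1$idx[mk1$species == species_a]
  if (!length(ref)) stop("empty selection: no ", species_a, " in ", leaflet)
  out <- rdf(system, ref, species_b, window, dr, r_max, leaflet = leaflet,
             lateral = lateral)
  out$reference <- paste(species_a, "markers,", leaflet)
  out
}

#' @export
print.rdf_result <- function(x, ...) {
  cat(sprintf("rdf_result: %s vs %s markers, %d frames, dr %.2f, r_max %.1f%s\n",
              x$reference, x$species, x$frames, x$dr, x$r_max,
              if (isTRUE(x$lateral)) " (2D lateral)" else ""))
  pk <- which.max(x$g)
  cat(sprintf("  first/global peak: g = %.2f at r = %.2f A\n",
              x$g[pk], x$r[pk]))
  invisible(x)
}

#' @export
plot.rdf_result <- function(x, ...) {
  graphics::plot(x$r, x$g, type = "l", xlab = "r (A)", ylab = "g(r)",
                 main = paste("RDF:", x$reference, "vs", x$species), ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}
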