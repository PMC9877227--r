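#' Local lipid composition under the protein
#'
#' Counts the lipids of each species whose binding-leaflet headgroup marker
#' falls inside a region — either the protein's xy-projection mask or a
#' lateral radius about the protein axis — per frame, and reports window
#' means, regional mole fractions, all pairwise composition ratios, and the
#' enrichment index of each species (regional mole fraction divided by bulk
#' leaflet mole fraction) with block-averaged standard errors.
#'
#' @param system a [membrane_system()].
#' @param window integer frame indices.
#' @param region either a [protein_mask()] or a list
#'   `list(type = "radius", r = <A>)` for a disk about the protein's xy
#'   center of geometry (per frame). `list(type = "all")` selects the whole
#'   leaflet.
#' @param leaflet binding leaflet (default auto-detected).
#' @param blocks blocks for standard errors.
#' @return object of class `fingerprint_report`: `counts` (per-species mean
#'   count, se), `mole_fraction`, `bulk_fraction`, `enrichment`, `ratios`
#'   (matrix, entry \[a, b\] = count_a : count_b as a float), `region`,
#'   `window`.
#' @export
local_composition <- function(system, window = seq_len(n_frames(system)),
                              region = list(type = "radius", r = 15),
                              leaflet = NULL, blocks = 5L) {
  if (length(window) == 0L) stop("empty frame window")
  if (is.null(leaflet)) leaflet <- detect_binding_leaflet(system)$leaflet
  if (is.na(leaflet)) stop("binding leaflet undetermined (no contact)")
  spn <- names(system$species)
  cnt <- matrix(0, length(window), length(spn), dimnames = list(NULL, spn))
  bulk <- matrix(0, length(window), length(spn), dimnames = list(NULL, spn))
  for (wi in seq_along(window)) {
    f <- window[wi]
    mk <- .leaflet_markers(system, f, leaflet)
    box <- system$box[f, ]
    inside <- if (inherits(region, "protein_mask")) {
      ix <- pmin(floor(wrap_coords(mk$x, box[1]) / box[1] *
                         region$bins_x) + 1L, region$bins_x)
      iy <- pmin(floor(wrap_coords(mk$y, box[2]) / box[2] *
                         region$bins_y) + 1L, region$bins_y)
      region$mask[cbind(ix, iy)]
    } else if (identical(region$type, "radius")) {
      ph <- protein_heavy_idx(system)
      if (!length(ph)) stop("region 'radius' requires a protein")
      cx <- mean(system$coords[ph, 1, f]); cy <- mean(system$coords[ph, 2, f])
      dx <- mk$x - cx; dx <- dx - box[1] * round(dx / box[1])
      dy <- mk$y - cy; dy <- dy - box[2] * round(dy / box[2])
      sqrt(dx^2 + dy^2) <= region$r
    } else if (identical(region$type, "all")) {
      rep(TRUE, nrow(mk))
    } else stop("unknown region definition")
    cnt[wi, ] <- as.integer(table(factor(mk$species[inside], levels = spn)))
    bulk[wi, ] <- as.integer(table(factor(mk$species, levels = spn)))
  }
  if (all(cnt == 0)) stop("region never populated in the window")
  mean_cnt <- colMeans(cnt)
  mf <- mean_cnt / sum(mean_cnt)
  bulk_frac <- colMeans(bulk) / sum(colMeans(bulk))
  enr <- ifelse(bulk_frac > 0, mf / bulk_frac, NA_real_)
  ratios <- outer(mean_cnt, mean_cnt,
                  function(a, b) ifelse(b > 0, a / b, NA_real_))
  dimnames(ratios) <- list(spn, spn)
  region_desc <- if (inherits(region, "protein_mask"))
    sprintf("protein mask (%.0f A^2)", region$area)
  else if (identical(region$type, "radius"))
    sprintf("radius %.1f A about protein axis", region$r)
  else "full leaflet"
  structure(list(
    counts = data.frame(species = spn, mean_count = mean_cnt,
                        se = apply(cnt, 2, block_se, blocks = blocks),
                        row.names = NULL),
    mole_fraction = mf, bulk_fraction = bulk_frac, enrichment = enr,
    ratios = ratios, region = region_desc, leaflet = leaflet,
    window = range(window)), class = "fingerprint_report")
}

#' @export
print.fingerprint_report <- function(x, ...) {
  cat("fingerprint_report —", x$region, "—", x$leaflet, "leaflet, frames",
      x$window[1], "to", x$window[2], "\n")
  df <- x$counts
  df$mole_fraction <- round(x$mole_fraction, 4)
  df$enrichment <- round(x$enrichment, 3)
  print(df, row.names = FALSE)
  cat("key ratios: DOPE:PIP2 =",
      round(x$ratios["DOPE", "PIP2"], 3),
      "; DOPC:PIP2 =", round(x$ratios["DOPC", "PIP2"], 3), "\n")
  invisible(x)
}

#' Change in the lipid fingerprint between two windows
#'
#' Bookkeeping over two [local_composition()] reports computed with the same
#' region definition and species set: per-species change in mole fraction
#' and enrichment, and the before/after pairwise ratios.
#'
#' @param report_initial,report_final `fingerprint_report` objects.
#' @return data.frame with columns `species`, `molfrac_initial`,
#'   `molfrac_final`, `delta_molfrac`, `enrichment_initial`,
#'   `enrichment_final`, `delta_enrichment`.
#' @export
fingerprint_delta <- function(report_initial, report_final) {
  stopifnot(inherits(report_initial, "fingerprint_report"),
            inherits(report_final, "fingerprint_report"))
  spi <- report_initial$counts$species
  spf <- report_final$counts$species
  if (!identical(spi, spf))
    stop("mismatched species sets between reports")
  if (!identical(report_initial$region, report_final$region))
    stop("mismatched region definitions between reports")
  data.frame(
    species = spi,
    molfrac_initial = unname(report_initial$mole_fraction),
    molfrac_final = unname(report_final$mole_fraction),
    delta_molfrac = unname(report_final$mole_fraction -
                             report_initial$mole_fraction),
    enrichment_initial = unname(report_initial$enrichment),
    enrichment_final = unname(report_final$enrichment),
    delta_enrichment = unname(report_final$enrichment -
                                report_initial$enrichment))
}
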