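#' Domain center-of-mass distance to the binding-leaflet phosphate plane
#'
#' Per frame, the absolute z-separation between the Calpha center of mass of
#' one protein domain and the mean z of the binding leaflet's headgroup
#' marker atoms. The z-plane convention matches distance curves that plateau
#' near zero at binding.
#'
#' @param system a [membrane_system()].
#' @param domain domain label from the system's domain table.
#' @param window integer frame indices.
#' @param leaflet binding leaflet label; default auto-detected via
#'   [detect_binding_leaflet()].
#' @return numeric vector of distances (A), one per frame of `window`.
#' @export
domain_com_distance <- function(system, domain,
                                window = seq_len(n_frames(system)),
                                leaflet = NULL) {
  if (length(window) == 0L) stop("empty frame window")
  if (!domain %in% system$domains$label)
    stop("unknown domain label: ", domain)
  if (is.null(leaflet)) leaflet <- detect_binding_leaflet(system)$leaflet
  if (is.na(leaflet)) stop("binding leaflet undetermined (no contact)")
  ca <- ca_idx(system)
  dres <- system$atoms$resid[ca]
  sel <- ca[domain_of(system, dres) == domain]
  if (!length(sel)) stop("no Calpha atoms in domain ", domain)
  vapply(window, function(f) {
    mi <- leaflet_marker_idx(system, f, leaflet)
    abs(mean(system$coords[sel, 3, f]) - mean(system$coords[mi, 3, f]))
  }, 0)
}

#' Per-residue contact frequency with the binding leaflet
#'
#' A residue is in contact in a frame when its Calpha lies within `cutoff`
#' (inclusive) of any headgroup marker atom of the binding leaflet, by
#' minimal-image distance. Frequencies are percentages of the window; the
#' standard error comes from block averages of the per-frame indicator.
#'
#' @inheritParams domain_com_distance
#' @param cutoff contact cutoff (A), default 12.
#' @param blocks number of blocks for the standard error.
#' @return data.frame with columns `resid`, `domain`, `pct_time`, `se`.
#' @export
residue_contact_frequency <- function(system,
                                      window = seq_len(n_frames(system)),
                                      cutoff = 12, leaflet = NULL,
                                      blocks = 5L) {
  if (length(window) == 0L) stop("empty frame window")
  if (is.null(leaflet)) leaflet <- detect_binding_leaflet(system)$leaflet
  if (is.na(leaflet)) stop("binding leaflet undetermined (no contact)")
  ca <- ca_idx(system)
  resid <- system$atoms$resid[ca]
  hits <- matrix(0, length(window), length(ca))
  for (wi in seq_along(window)) {
    f <- window[wi]
    mi <- leaflet_marker_idx(system, f, leaflet)
    D <- mi_cross_dist(system$coords[ca, , f, drop = FALSE][, , 1],
                       system$coords[mi, , f, drop = FALSE][, , 1],
                       system$box[f, ])
    hits[wi, ] <- as.numeric(apply(D, 1, min) <= cutoff)
  }
  data.frame(resid = resid,
             domain = domain_of(system, resid),
             pct_time = 100 * colMeans(hits),
             se = 100 * apply(hits, 2, block_se, blocks = blocks))
}

#' Domain-by-species contact counts
#'
#' Per frame, the number of (protein heavy atom, lipid marker atom) pairs
#' within `cutoff` (inclusive, minimal image), counted against the marker
#' atoms of each species in the binding leaflet and summed per protein
#' domain; reported as the per-frame mean over the window with block-average
#' standard errors. Linker residues (outside all domain ranges) are
#' excluded.
#'
#' @inheritParams residue_contact_frequency
#' @return data.frame with columns `domain`, `species`, `mean_contacts`,
#'   `se`.
#' @export
domain_species_contacts <- function(system,
                                    window = seq_len(n_frames(system)),
                                    cutoff = 12, leaflet = NULL,
                                    blocks = 5L) {
  if (length(window) == 0L) stop("empty frame window")
  if (is.null(leaflet)) leaflet <- detect_binding_leaflet(system)$leaflet
  if (is.na(leaflet)) stop("binding leaflet undetermined (no contact)")
  ph <- protein_heavy_idx(system)
  pdom <- domain_of(system, system$atoms$resid[ph])
  keep <- pdom %in% system$domains$label
  ph <- ph[keep]; pdom <- pdom[keep]
  doms <- system$domains$label
  spn <- names(system$species)
  acc <- array(0, c(length(window), length(doms), length(spn)),
               dimnames = list(NULL, doms, spn))
  for (wi in seq_along(window)) {
    f <- window[wi]
    mk <- marker_table(system, f)
    la <- assign_leaflets(system, f)
    mk <- mk[la$leaflet[as.character(mk$resuid)] == leaflet, ]
    if (!nrow(mk)) next
    D <- mi_cross_dist(system$coords[ph, , f, drop = FALSE][, , 1],
                       as.matrix(mk[, c("x", "y", "z")]), system$box[f, ])
    inC <- D <= cutoff
    for (d in doms) {
      rows <- pdom == d
      if (!any(rows)) next
      hits <- colSums(inC[rows, , drop = FALSE])
      tab <- tapply(hits, factor(mk$species, levels = spn), sum)
      tab[is.na(tab)] <- 0
      acc[wi, d, ] <- tab
    }
  }
  out <- expand.grid(domain = doms, species = spn, stringsAsFactors = FALSE)
  out$mean_contacts <- mapply(function(d, s) mean(acc[, d, s]),
                              out$domain, out$species)
  out$se <- mapply(function(d, s) block_se(acc[, d, s], blocks),
                   out$domain, out$species)
  out
}

#' Residue insertion depth profile
#'
#' Signed depth of each protein residue relative to the binding leaflet's
#' marker plane, averaged over the window: positive values mean the Calpha
#' has inserted past the marker plane toward the bilayer core. Only residues
#' that come within `cutoff` of the binding-leaflet markers at least once in
#' the window are profiled. The deepest residue is the argmax of mean depth
#' (ties broken by lowest residue id).
#'
#' @inheritParams residue_contact_frequency
#' @return list of class `depth_profile` with `profile` (data.frame `resid`,
#'   `domain`, `depth`, `se`) and `deepest` (residue id).
#' @export
insertion_depth <- function(system, window = seq_len(n_frames(system)),
                            cutoff = 12, leaflet = NULL, blocks = 5L) {
  if (length(window) == 0L) stop("empty frame window")
  if (is.null(leaflet)) leaflet <- detect_binding_leaflet(system)$leaflet
  if (is.na(leaflet)) stop("binding leaflet undetermined (no contact)")
  ca <- ca_idx(system)
  resid <- system$atoms$resid[ca]
  sgn <- if (leaflet == "upper") 1 else -1
  depth <- matrix(NA_real_, length(window), length(ca))
  ever <- rep(FALSE, length(ca))
  for (wi in seq_along(window)) {
    f <- window[wi]
    mi <- leaflet_marker_idx(system, f, leaflet)
    plane <- mean(system$coords[mi, 3, f])
    depth[wi, ] <- sgn * (plane - system$coords[ca, 3, f])
    D <- mi_cross_dist(system$coords[ca, , f, drop = FALSE][, , 1],
                       system$coords[mi, , f, drop = FALSE][, , 1],
                       system$box[f, ])
    ever <- ever | apply(D, 1, min) <= cutoff
  }
  if (!any(ever)) stop("no residue ever within ", cutoff,
                       " A of the binding leaflet")
  prof <- data.frame(resid = resid[ever],
                     domain = domain_of(system, resid[ever]),
                     depth = colMeans(depth[, ever, drop = FALSE]),
                     se = apply(depth[, ever, drop = FALSE], 2, block_se,
                                blocks = blocks))
  prof <- prof[order(prof$resid), ]
  deepest <- prof$resid[which.max(prof$depth)]
  structure(list(profile = prof, deepest = deepest, leaflet = leaflet,
                 window = window), class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat("depth_profile:", nrow(x$profile), "residues;",
      "deepest residue", x$deepest,
      sprintf("(%.2f A past the %s marker plane)\n",
              max(x$profile$depth), x$leaflet))
  invisible(x)
}

# window coordinates of a Calpha selection as a bio3d-style xyz matrix
.ca_xyz <- function(system, sel, window) {
  out <- matrix(NA_real_, length(window), 3L * length(sel))
  for (wi in seq_along(window))
    out[wi, ] <- as.vector(t(system$coords[sel, , window[wi]]))
  out
}

#' RMSD time series and per-residue RMSF
#'
#' Both metrics are computed on Calpha atoms after rigid-body least-squares
#' superposition (translation + rotation) onto the reference: `rmsd_series()`
#' superposes every frame onto `ref_frame` and reports the Calpha RMSD;
#' `rmsf()` superposes onto `ref_frame`, then measures each residue's
#' root-mean-square fluctuation about its window-mean position.
#'
#' @param system a [membrane_system()].
#' @param domain optional domain label restricting the Calpha selection
#'   (default: whole protein).
#' @param window integer frame indices.
#' @param ref_frame reference frame index (default: first frame of window).
#' @return `rmsd_series()`: numeric vector (A) along `window`; `rmsf()`:
#'   data.frame `resid`, `domain`, `rmsf`.
#' @export
rmsd_series <- function(system, domain = NULL,
                        window = seq_len(n_frames(system)),
                        ref_frame = window[1]) {
  sel <- .ca_sel(system, domain)
  xyz <- .ca_xyz(system, sel, unique(c(ref_frame, window)))
  fit <- bio3d::fit.xyz(fixed = xyz[1, ], mobile = xyz,
                        fixed.inds = seq_len(ncol(xyz)),
                        mobile.inds = seq_len(ncol(xyz)))
  r <- bio3d::rmsd(xyz[1, ], fit)
  r[match(window, unique(c(ref_frame, window)))]
}

#' @rdname rmsd_series
#' @export
rmsf <- function(system, domain = NULL, window = seq_len(n_frames(system)),
                 ref_frame = window[1]) {
  sel <- .ca_sel(system, domain)
  xyz <- .ca_xyz(system, sel, window)
  ref <- .ca_xyz(system, sel, ref_frame)
  fit <- bio3d::fit.xyz(fixed = ref[1, ], mobile = xyz,
                        fixed.inds = seq_len(ncol(xyz)),
                        mobile.inds = seq_len(ncol(xyz)))
  mu <- colMeans(fit)
  dev2 <- sweep(fit, 2, mu)^2
  per_atom <- sqrt(rowSums(matrix(colMeans(dev2), ncol = 3, byrow = TRUE)))
  resid <- system$atoms$resid[sel]
  data.frame(resid = resid, domain = domain_of(system, resid),
             rmsf = per_atom)
}

.ca_sel <- function(system, domain) {
  sel <- ca_idx(system)
  if (!is.null(domain)) {
    if (!domain %in% system$domains$label)
      stop("unknown domain label: ", domain)
    sel <- sel[domain_of(system, system$atoms$resid[sel]) == domain]
  }
  if (!length(sel)) stop("empty Calpha selection")
  sel
}
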