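#' Cumulative 2D maps over the membrane plane
#'
#' `density_map()` accumulates headgroup marker positions of one species
#' (one sample per frame) into a 2D histogram; `height_map()` maps the mean
#' relative height z_f = z - z_o, where z_o is the mean z of the selection
#' in the first frame of the window; `charge_map()` deposits each species'
#' formal headgroup charge at its marker position and accumulates.
#'
#' Binning uses fractional (box-relative) coordinates with half-open bins,
#' so the count-conservation identity `sum(cells) = N_selected x frames`
#' holds exactly even when the box fluctuates; physical cell areas are
#' reported using the window-mean box.
#'
#' @param system a [membrane_system()].
#' @param species species name (for `density_map()`), or `NULL` for all.
#' @param leaflet `"upper"` or `"lower"`.
#' @param window integer frame indices.
#' @param bins number of bins per axis (default 100).
#' @return object of class `grid_map`: `kind`, `values` (bins x bins matrix,
#'   x indexes rows), `samples` (per-cell sample counts), `frames`,
#'   `leaflet`, `species`, `bins`, `box_mean`, `cell_area`.
#' @export
density_map <- function(system, species = NULL, leaflet = "upper",
                        window = seq_len(n_frames(system)), bins = 100L) {
  sel_fun <- function(mk) if (is.null(species)) mk else {
    if (!species %in% names(system$species))
      stop("unknown species: ", species)
    mk[mk$species == species, , drop = FALSE]
  }
  acc <- .accumulate_grid(system, window, bins, leaflet, sel_fun,
                          value_fun = function(mk, f) rep(1, nrow(mk)))
  structure(list(kind = "density", values = acc$sum, samples = acc$n,
                 frames = length(window), leaflet = leaflet,
                 species = species %||% "all", bins = bins,
                 box_mean = acc$box_mean, cell_area = acc$cell_area),
            class = "grid_map")
}

#' @rdname density_map
#' @param include_sterols whether sterol hydroxyl markers join the phosphate
#'   markers in the height selection.
#' @export
height_map <- function(system, leaflet = "upper",
                       window = seq_len(n_frames(system)), bins = 100L,
                       include_sterols = TRUE) {
  sterols <- names(Filter(function(s) length(s$hydrophilic) == 0L,
                          system$species))
  sel_fun <- function(mk) {
    if (include_sterols) mk else mk[!(mk$species %in% sterols), ,
                                    drop = FALSE]
  }
  mk1 <- sel_fun(.leaflet_markers(system, window[1], leaflet))
  if (!nrow(mk1)) stop("empty selection for height map")
  z_o <- mean(mk1$z)
  acc <- .accumulate_grid(system, window, bins, leaflet, sel_fun,
                          value_fun = function(mk, f) mk$z - z_o)
  vals <- acc$sum / acc$n          # mean z_f; NaN where unsampled
  vals[acc$n == 0L] <- NA_real_
  structure(list(kind = "height", values = vals, samples = acc$n,
                 frames = length(window), leaflet = leaflet,
                 species = if (include_sterols) "all" else "phospholipid",
                 bins = bins, z_o = z_o,
                 box_mean = acc$box_mean, cell_area = acc$cell_area),
            class = "grid_map")
}

#' @rdname density_map
#' @export
charge_map <- function(system, leaflet = "upper",
                       window = seq_len(n_frames(system)), bins = 100L) {
  chg <- vapply(system$species, function(s) as.numeric(s$charge), 0)
  if (any(is.na(chg))) stop("species missing formal charge")
  sel_fun <- function(mk) mk
  acc <- .accumulate_grid(system, window, bins, leaflet, sel_fun,
                          value_fun = function(mk, f) chg[mk$species])
  structure(list(kind = "charge", values = acc$sum, samples = acc$n,
                 frames = length(window), leaflet = leaflet,
                 species = "all", bins = bins,
                 box_mean = acc$box_mean, cell_area = acc$cell_area),
            class = "grid_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.leaflet_markers <- function(system, frame, leaflet) {
  mk <- marker_table(system, frame)
  la <- assign_leaflets(system, frame)
  mk[la$leaflet[as.character(mk$resuid)] == leaflet, , drop = FALSE]
}

# shared accumulation engine: one sample per selected marker per frame,
# binned in fractional xy with half-open bins
.accumulate_grid <- function(system, window, bins, leaflet, sel_fun,
                             value_fun) {
  if (length(window) == 0L) stop("empty frame window")
  ssum <- matrix(0, bins, bins)
  n <- matrix(0L, bins, bins)
  for (f in window) {
    mk <- sel_fun(.leaflet_markers(system, f, leaflet))
    if (!nrow(mk)) next
    box <- system$box[f, ]
    fx <- wrap_coords(mk$x, box[1]) / box[1]
    fy <- wrap_coords(mk$y, box[2]) / box[2]
    ix <- pmin(floor(fx * bins) + 1L, bins)
    iy <- pmin(floor(fy * bins) + 1L, bins)
    v <- value_fun(mk, f)
    for (q in seq_along(ix)) {
      ssum[ix[q], iy[q]] <- ssum[ix[q], iy[q]] + v[q]
      n[ix[q], iy[q]] <- n[ix[q], iy[q]] + 1L
    }
  }
  box_mean <- colMeans(system$box[window, , drop = FALSE])
  list(sum = ssum, n = n, box_mean = box_mean,
       cell_area = box_mean[1] * box_mean[2] / bins^2)
}

#' @export
print.grid_map <- function(x, ...) {
  cat(sprintf("grid_map (%s): %dx%d bins, %d frame(s), leaflet %s, %s\n",
              x$kind, x$bins, x$bins, x$frames, x$leaflet, x$species))
  cat(sprintf("  cell area %.2f A^2; total %s = %.1f\n", x$cell_area,
              if (x$kind == "height") "sampled cells"
              else x$kind,
              if (x$kind == "height") sum(!is.na(x$values))
              else sum(x$values)))
  invisible(x)
}

#' @export
plot.grid_map <- function(x, ...) {
  graphics::image(seq(0, x$box_mean[1], length.out = x$bins),
                  seq(0, x$box_mean[2], length.out = x$bins),
                  x$values, xlab = "x (A)", ylab = "y (A)",
                  main = paste(x$kind, "map,", x$leaflet, "leaflet,",
                               x$species), useRaster = TRUE, ...)
  invisible(x)
}

#' Write a grid map as CSV + JSON metadata
#' @param map a `grid_map`.
#' @param path CSV output path (metadata goes to `<path>.json`).
#' @export
write_grid_map <- function(map, path) {
  utils::write.table(map$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- map[c("kind", "frames", "leaflet", "species", "bins",
                "box_mean", "cell_area")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Protein xy-projection mask
#'
#' Marks every grid cell whose center lies within the xy-disk (van der
#' Waals radius) of any protein heavy atom; the window version is the union
#' over frames. The projected area is `covered cells x cell area`.
#'
#' @param system a [membrane_system()].
#' @param window frame indices (single frame or window; union over frames).
#' @param bins grid bins per axis; mutually exclusive with `cell`.
#' @param cell cell edge length in A (used when `bins` is `NULL`).
#' @return object of class `protein_mask`: logical `mask` matrix, `bins_x`,
#'   `bins_y`, `area` (A^2), `cell_area`, `box_mean`, `window`.
#' @export
protein_mask <- function(system, window = seq_len(n_frames(system)),
                         bins = NULL, cell = 1.0) {
  if (length(window) == 0L) stop("no frames for protein mask")
  ph <- protein_heavy_idx(system)
  if (!length(ph)) stop("no protein atoms in system")
  box_mean <- colMeans(system$box[window, , drop = FALSE])
  if (is.null(bins)) {
    bx <- max(1L, round(box_mean[1] / cell))
    by <- max(1L, round(box_mean[2] / cell))
  } else bx <- by <- bins
  m <- matrix(FALSE, bx, by)
  for (f in window) {
    box <- system$box[f, ]
    m <- m | .raster_disks(system$coords[ph, 1, f], system$coords[ph, 2, f],
                           system$atoms$vdw[ph], box, bx, by)
  }
  cell_area <- box_mean[1] * box_mean[2] / (bx * by)
  structure(list(mask = m, bins_x = bx, bins_y = by,
                 area = sum(m) * cell_area, cell_area = cell_area,
                 box_mean = box_mean, window = window),
            class = "protein_mask")
}

#' @export
print.protein_mask <- function(x, ...) {
  cat(sprintf("protein_mask: %dx%d cells, projected area %.1f A^2 (%d frames)\n",
              x$bins_x, x$bins_y, x$area, length(x$window)))
  invisible(x)
}

# periodic disk rasterization: TRUE for cells whose center is within a disk
.raster_disks <- function(x, y, r, box, bx, by) {
  m <- matrix(FALSE, bx, by)
  cwx <- box[1] / bx; cwy <- box[2] / by
  for (q in seq_along(x)) {
    i0 <- floor(wrap_coords(x[q], box[1]) / cwx)       # 0-based cell of atom
    j0 <- floor(wrap_coords(y[q], box[2]) / cwy)
    ri <- ceiling(r[q] / cwx) + 1L
    rj <- ceiling(r[q] / cwy) + 1L
    ii <- (i0 - ri):(i0 + ri)
    jj <- (j0 - rj):(j0 + rj)
    ci <- (ii + 0.5) * cwx
    cj <- (jj + 0.5) * cwy
    dx <- ci - x[q]; dx <- dx - box[1] * round(dx / box[1])
    dy <- cj - y[q]; dy <- dy - box[2] * round(dy / box[2])
    hit <- outer(dx^2, dy^2, "+") <= r[q]^2
    iw <- (ii %% bx) + 1L
    jw <- (jj %% by) + 1L
    m[iw, jw] <- m[iw, jw] | hit
  }
  m
}
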