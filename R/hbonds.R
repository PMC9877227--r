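#' Enumerate hydrogen-bond donors and acceptors
#'
#' Donors are N/O atoms with at least one bonded hydrogen; acceptors are all
#' N/O atoms. For protein atoms, bonded hydrogens are inferred by a covalent
#' distance criterion (< 1.2 A in the first frame); for lipids, by the
#' name-pairing declared in the species configuration (`donor_pairs`), since
#' the coarse lipid beads carry no hydrogens unless declared.
#'
#' @param system a [membrane_system()].
#' @return list with `donors` (data.frame `donor`, `hydrogen` atom indices)
#'   and `acceptors` (integer atom indices).
#' @export
find_donors_acceptors <- function(system) {
  a <- system$atoms
  no <- which(a$element %in% c("N", "O") &
                a$segment %in% c("protein", "lipid"))
  hyd <- which(a$element == "H" & a$segment %in% c("protein", "lipid"))
  donors <- NULL
  if (length(hyd)) {
    # protein (and any explicit-H) side: covalent pairing by distance
    D <- mi_cross_dist(system$coords[no, , 1, drop = FALSE][, , 1],
                       system$coords[hyd, , 1, drop = FALSE][, , 1],
                       system$box[1, ])
    pair <- which(D < 1.2, arr.ind = TRUE)
    if (length(hyd) && any(!(seq_along(hyd) %in% pair[, 2])))
      stop("hydrogen atom(s) with no resolvable parent donor")
    if (nrow(pair))
      donors <- data.frame(donor = no[pair[, 1]], hydrogen = hyd[pair[, 2]])
  }
  # lipid side: name-declared donor pairs
  for (s in system$species) {
    dp <- s$donor_pairs
    if (is.null(dp)) next
    for (dn in names(dp)) {
      di <- which(a$species == s$name & a$name == dn)
      hi <- which(a$species == s$name & a$name == dp[[dn]])
      if (length(di) != length(hi))
        stop("species ", s$name, ": donor/hydrogen name mismatch for ", dn)
      donors <- rbind(donors, data.frame(donor = di, hydrogen = hi))
    }
  }
  if (is.null(donors))
    donors <- data.frame(donor = integer(), hydrogen = integer())
  list(donors = donors[order(donors$donor), , drop = FALSE], acceptors = no)
}

#' Detect protein-lipid hydrogen bonds in one frame
#'
#' Geometric criterion: a (donor, hydrogen, acceptor) triple is a hydrogen
#' bond when the donor-acceptor heavy-atom minimal-image distance is at most
#' `d_cut` (default 3.2 A) and the D-H...A angle deviates from linearity by
#' at most `angle_cut` degrees (default 30, i.e. the angle at the hydrogen
#' is at least 150 degrees). Only pairs crossing the protein/lipid divide
#' are reported, and donor and acceptor must belong to different residues.
#'
#' @param system a [membrane_system()].
#' @param frame frame index.
#' @param d_cut donor-acceptor distance cutoff (A).
#' @param angle_cut maximum deviation from 180 degrees (degrees).
#' @param da optional precomputed [find_donors_acceptors()] result.
#' @return data.frame with one row per bond, ordered by (donor, acceptor):
#'   `frame`, `donor`, `hydrogen`, `acceptor`, `distance`, `angle`,
#'   `donor_side`, `acceptor_species` (species for lipid acceptors, domain
#'   label for protein acceptors).
#' @export
detect_hbonds <- function(system, frame = 1L, d_cut = 3.2, angle_cut = 30,
                          da = find_donors_acceptors(system)) {
  a <- system$atoms
  box <- system$box[frame, ]
  empty <- data.frame(frame = integer(), donor = integer(),
                      hydrogen = integer(), acceptor = integer(),
                      distance = numeric(), angle = numeric(),
                      donor_side = character(),
                      acceptor_species = character())
  if (!nrow(da$donors) || !length(da$acceptors)) return(empty)
  dseg <- a$segment[da$donors$donor]
  aseg <- a$segment[da$acceptors]
  D <- mi_cross_dist(system$coords[da$donors$donor, , frame,
                                   drop = FALSE][, , 1],
                     system$coords[da$acceptors, , frame,
                                   drop = FALSE][, , 1], box)
  cross <- outer(dseg, aseg, "!=")    # protein<->lipid only
  same_res <- outer(a$resuid[da$donors$donor], a$resuid[da$acceptors], "==")
  cand <- which(D <= d_cut & cross & !same_res, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  recs <- lapply(seq_len(nrow(cand)), function(r) {
    i <- cand[r, 1]; j <- cand[r, 2]
    Dp <- system$coords[da$donors$donor[i], , frame]
    Hp <- system$coords[da$donors$hydrogen[i], , frame]
    Ap <- system$coords[da$acceptors[j], , frame]
    # minimal-image displacement of A relative to H
    w2 <- Ap - Hp; w2 <- w2 - box * round(w2 / box)
    w1 <- Dp - Hp; w1 <- w1 - box * round(w1 / box)
    ang <- acos(max(-1, min(1, sum(w1 * w2) /
                              sqrt(sum(w1^2) * sum(w2^2))))) * 180 / pi
    if (180 - ang > angle_cut) return(NULL)
    acc <- da$acceptors[j]
    acc_lab <- if (a$segment[acc] == "lipid") a$species[acc]
    else domain_of(system, a$resid[acc])
    data.frame(frame = frame, donor = da$donors$donor[i],
               hydrogen = da$donors$hydrogen[i], acceptor = acc,
               distance = D[i, j], angle = ang,
               donor_side = dseg[i], acceptor_species = acc_lab)
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) return(empty)
  out[order(out$donor, out$acceptor), , drop = FALSE]
}

#' Protein-lipid hydrogen-bond counts per species over a window
#'
#' Per-frame bond counts aggregated by lipid species (the lipid partner's
#' species, whichever side donates), with window means, totals and
#' block-averaged standard errors. Also reports unique donor-acceptor pair
#' counts alongside (D,H,A) triple counts.
#'
#' @param system a [membrane_system()].
#' @param window integer frame indices.
#' @param d_cut,angle_cut criterion parameters, see [detect_hbonds()].
#' @param blocks number of blocks for standard errors.
#' @return data.frame with columns `species`, `mean`, `se`, `total`,
#'   `mean_unique_pairs`.
#' @export
count_hbonds_by_species <- function(system,
                                    window = seq_len(n_frames(system)),
                                    d_cut = 3.2, angle_cut = 30,
                                    blocks = 5L) {
  if (length(window) == 0L) stop("empty frame window")
  da <- find_donors_acceptors(system)
  a <- system$atoms
  spn <- names(system$species)
  cnt <- matrix(0, length(window), length(spn),
                dimnames = list(NULL, spn))
  ucnt <- cnt
  for (wi in seq_along(window)) {
    rec <- detect_hbonds(system, window[wi], d_cut, angle_cut, da)
    if (!nrow(rec)) next
    lip_sp <- ifelse(rec$donor_side == "lipid",
                     a$species[rec$donor], a$species[rec$acceptor])
    tab <- table(factor(lip_sp, levels = spn))
    cnt[wi, ] <- as.integer(tab)
    uu <- !duplicated(rec[, c("donor", "acceptor")])
    ucnt[wi, ] <- as.integer(table(factor(lip_sp[uu], levels = spn)))
  }
  data.frame(species = spn,
             mean = colMeans(cnt),
             se = apply(cnt, 2, block_se, blocks = blocks),
             total = colSums(cnt),
             mean_unique_pairs = colMeans(ucnt),
             row.names = NULL)
}

#' Compare hydrogen bonding between two windows
#'
#' Convenience wrapper producing the initial-versus-final comparison of
#' per-species hydrogen-bond counts.
#'
#' @param system a [membrane_system()].
#' @param window_initial,window_final frame-index windows.
#' @param ... passed to [count_hbonds_by_species()].
#' @return data.frame with per-species `mean_initial`, `se_initial`,
#'   `mean_final`, `se_final`, `delta`.
#' @export
compare_hbond_windows <- function(system, window_initial, window_final, ...) {
  ci <- count_hbonds_by_species(system, window_initial, ...)
  cf <- count_hbonds_by_species(system, window_final, ...)
  data.frame(species = ci$species,
             mean_initial = ci$mean, se_initial = ci$se,
             mean_final = cf$mean, se_final = cf$se,
             delta = cf$mean - ci$mean)
}
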