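# Conformer-ensemble statistics: distance satisfaction, hydrogen-bond
# occupancy, Kabsch superposition and RMSD k-means clustering.

#' Read a conformer ensemble from a multi-model PDB file
#'
#' All models must share one atom roster; coordinates are stored bio3d
#' style as a models x (3 * n_atoms) matrix.
#'
#' @param path PDB file with MODEL/ENDMDL records (a single-model file
#'   yields a one-model ensemble).
#' @return object of class `conformer_ensemble` with elements `atoms`
#'   (data frame: chain, resno, resid, elety) and `xyz`.
#' @export
read_ensemble <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  conformer_ensemble(pdb$atom[, c("chain", "resno", "resid", "elety")],
                     xyz)
}

#' Construct a conformer ensemble from an atom table and coordinates
#'
#' @param atoms data frame with columns `chain`, `resno`, `resid`, `elety`.
#' @param xyz numeric matrix, one row per model, 3 * n_atoms columns
#'   (x1, y1, z1, x2, ...), Angstrom.
#' @return `conformer_ensemble`.
#' @export
conformer_ensemble <- function(atoms, xyz) {
  stopifnot(is.data.frame(atoms),
            all(c("chain", "resno", "resid", "elety") %in% names(atoms)))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("xyz must have 3 * n_atoms columns")
  if (nrow(xyz) < 1L) stop("ensemble needs at least one model")
  structure(list(atoms = atoms, xyz = xyz), class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("Conformer ensemble: %d models, %d atoms\n",
              nrow(x$xyz), nrow(x$atoms)))
  invisible(x)
}

n_models <- function(ens) nrow(ens$xyz)

# model coordinates as an n_atoms x 3 matrix
model_coords <- function(ens, i) {
  matrix(ens$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' Resolve an atom selector to a single atom index
#'
#' Selectors are `"chain:resid:atomname"`, e.g. `"B:16:H2"`.
#'
#' @param ens a `conformer_ensemble`.
#' @param selector selector string.
#' @return integer atom index (1-based).
#' @export
resolve_selector <- function(ens, selector) {
  parts <- strsplit(selector, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L)
    stop(sprintf("malformed selector '%s' (want chain:resid:atomname)",
                 selector))
  hit <- which(ens$atoms$chain == parts[1] &
               ens$atoms$resno == as.integer(parts[2]) &
               ens$atoms$elety == parts[3])
  if (length(hit) == 0L)
    stop(sprintf("selector '%s' matches no atom", selector))
  if (length(hit) > 1L)
    stop(sprintf("selector '%s' is ambiguous (%d atoms)",
                 selector, length(hit)))
  hit
}

#' Per-model distance between two selected protons
#'
#' @param ens a `conformer_ensemble`.
#' @param pair character vector of two selectors (`"chain:resid:atomname"`).
#' @return numeric vector of Euclidean distances (Angstrom), one per model
#'   in model order.
#' @export
interproton_distances <- function(ens, pair) {
  stopifnot(length(pair) == 2L)
  i <- resolve_selector(ens, pair[1])
  j <- resolve_selector(ens, pair[2])
  ix <- 3 * (i - 1) + 1:3
  jx <- 3 * (j - 1) + 1:3
  sqrt(rowSums((ens$xyz[, ix, drop = FALSE] -
                ens$xyz[, jx, drop = FALSE])^2))
}

#' Fraction of conformations satisfying distance thresholds
#'
#' For each threshold t the percentage of models with distance strictly
#' below t, mirroring a "< 4 Angstrom" NOE-visibility requirement.
#'
#' @param distances numeric vector of per-model distances (Angstrom).
#' @param thresholds numeric vector of thresholds (Angstrom); default the
#'   five conditions `c(2.5, 3, 3.5, 4, 4.5)`.
#' @return data frame with `threshold_A` and `percent`.
#' @export
satisfaction_fractions <- function(distances,
                                   thresholds = c(2.5, 3, 3.5, 4, 4.5)) {
  if (length(distances) == 0L || length(thresholds) == 0L)
    stop("distances and thresholds must be non-empty")
  data.frame(threshold_A = thresholds,
             percent = vapply(thresholds, function(t)
               100 * mean(distances < t), numeric(1)))
}

#' Ensemble distance-satisfaction report
#'
#' Runs [interproton_distances()] + [satisfaction_fractions()] for each
#' proton pair, with the pair's calibrated NOE distance alongside.
#'
#' @param ens a `conformer_ensemble`.
#' @param pairs data frame with columns `proton_a`, `proton_b` and
#'   optionally `calibrated_distance_A`.
#' @param thresholds thresholds in Angstrom.
#' @return long-format data frame: pair, calibrated distance, threshold,
#'   percent of models below threshold.
#' @export
satisfaction_report <- function(ens, pairs,
                                thresholds = c(2.5, 3, 3.5, 4, 4.5)) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    d <- interproton_distances(ens,
                               c(pairs$proton_a[i], pairs$proton_b[i]))
    sf <- satisfaction_fractions(d, thresholds)
    data.frame(proton_a = pairs$proton_a[i], proton_b = pairs$proton_b[i],
               calibrated_distance_A =
                 if ("calibrated_distance_A" %in% names(pairs))
                   pairs$calibrated_distance_A[i] else NA_real_,
               mean_distance_A = mean(d),
               threshold_A = sf$threshold_A, percent = sf$percent)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Hydrogen-bond criterion
#'
#' Common trajectory-analysis convention: donor-acceptor distance cutoff
#' plus minimum donor-hydrogen-acceptor angle.
#'
#' @param max_DA_distance maximum D...A distance (Angstrom, default 3.5).
#' @param min_DHA_angle minimum D-H...A angle (degrees, default 135).
#' @return list of class `hbond_criterion`.
#' @export
hbond_criterion <- function(max_DA_distance = 3.5, min_DHA_angle = 135) {
  if (max_DA_distance <= 0) stop("max_DA_distance must be positive")
  if (min_DHA_angle <= 0 || min_DHA_angle > 180)
    stop("min_DHA_angle must lie in (0, 180]")
  structure(list(max_DA_distance = max_DA_distance,
                 min_DHA_angle = min_DHA_angle),
            class = "hbond_criterion")
}

#' Hydrogen-bond occupancy over an ensemble
#'
#' Percentage of models in which the donor-acceptor distance is at most
#' `max_DA_distance` and the D-H...A angle (vertex at H) is at least
#' `min_DHA_angle`.
#'
#' @param ens a `conformer_ensemble`.
#' @param donor selector of the donor heavy atom D.
#' @param hydrogen selector of the donor-bound hydrogen H.
#' @param acceptor selector of the acceptor heavy atom A.
#' @param crit an [hbond_criterion()].
#' @return occupancy percent in `[0, 100]`.
#' @export
hbond_occupancy <- function(ens, donor, hydrogen, acceptor,
                            crit = hbond_criterion()) {
  iD <- resolve_selector(ens, donor)
  iH <- resolve_selector(ens, hydrogen)
  iA <- resolve_selector(ens, acceptor)
  ok <- vapply(seq_len(n_models(ens)), function(m) {
    xyz <- model_coords(ens, m)
    D <- xyz[iD, ]; H <- xyz[iH, ]; A <- xyz[iA, ]
    dDA <- sqrt(sum((D - A)^2))
    if (dDA > crit$max_DA_distance) return(FALSE)
    v1 <- D - H; v2 <- A - H
    cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    ang >= crit$min_DHA_angle
  }, logical(1))
  100 * mean(ok)
}

#' Minimum RMSD between two structures under rigid superposition
#'
#' Kabsch algorithm: both coordinate sets are centred, the optimal rotation
#' is obtained from the SVD of the covariance matrix (with the determinant
#' correction that excludes reflections), and the RMSD of the superposed
#' sets is returned.
#'
#' @param a,b numeric n x 3 coordinate matrices with matching atom order.
#' @return RMSD in the coordinate units (Angstrom).
#' @export
kabsch_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3L)
    stop("invalid selection: coordinate sets must be matching n x 3")
  if (nrow(a) < 3L)
    stop("invalid selection: at least 3 atoms are required")
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(bc, ac))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fit <- bc %*% R
  sqrt(mean(rowSums((ac - fit)^2)))
}

# superpose every model onto model `ref` over the selected atoms,
# returning a models x (3*length(sel)) matrix of fitted selected coords
superpose_selection <- function(ens, sel, ref = 1L) {
  refxyz <- model_coords(ens, ref)[sel, , drop = FALSE]
  refc <- sweep(refxyz, 2, colMeans(refxyz))
  out <- t(vapply(seq_len(n_models(ens)), function(m) {
    x <- model_coords(ens, m)[sel, , drop = FALSE]
    xc <- sweep(x, 2, colMeans(x))
    s <- svd(crossprod(xc, refc))
    d <- sign(det(s$u %*% t(s$v)))
    R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    as.numeric(t(xc %*% R))
  }, numeric(3L * length(sel))))
  out
}

#' RMSD k-means clustering of an ensemble with low-population pruning
#'
#' Selected atoms of every model are superposed onto the first model, the
#' fitted coordinates are flattened into feature vectors and clustered with
#' k-means (Euclidean distance on superposed coordinates is proportional to
#' RMSD x sqrt(n_atoms)). Clusters holding less than
#' `min_population_fraction` of the surviving models are pruned and the
#' clustering repeated until stable. Each cluster is represented by its
#' medoid: the member model minimising the summed pairwise [kabsch_rmsd()]
#' to the other members.
#'
#' @param ens a `conformer_ensemble`.
#' @param k number of clusters requested (default 4, one per stacking
#'   orientation).
#' @param selection integer atom indices or character selectors; default
#'   all atoms.
#' @param min_population_fraction clusters below this fraction are removed
#'   (default 0.05).
#' @param seed integer seed for the k-means starts.
#' @param max_prune_rounds safety cap on prune/recluster iterations.
#' @return list of class `cluster_result`: `labels` (per-model index, NA
#'   for pruned models), `populations`, `medoids` (model indices),
#'   `pruned` (model indices removed).
#' @export
cluster_ensemble <- function(ens, k = 4, selection = NULL,
                             min_population_fraction = 0.05, seed = 1,
                             max_prune_rounds = 20) {
  nm <- n_models(ens)
  if (k < 1) stop("invalid parameter: k must be >= 1")
  if (k > nm) stop("invalid parameter: k exceeds the number of models")
  sel <- if (is.null(selection)) seq_len(nrow(ens$atoms))
         else if (is.character(selection))
           vapply(selection, function(s) resolve_selector(ens, s),
                  integer(1))
         else as.integer(selection)
  feats <- superpose_selection(ens, sel)
  keep <- seq_len(nm)
  set.seed(seed)
  labels_keep <- NULL
  for (round in seq_len(max_prune_rounds)) {
    x <- feats[keep, , drop = FALSE]
    kk <- min(k, length(keep), nrow(unique(x)))
    if (kk < 1) stop("no models left after pruning")
    km <- suppressWarnings(stats::kmeans(x, centers = kk, nstart = 20,
                                         iter.max = 100))
    labels_keep <- km$cluster
    pops <- tabulate(labels_keep, nbins = kk)
    low <- which(pops > 0 & pops / length(keep) < min_population_fraction)
    if (length(low) == 0L) break
    keep <- keep[!labels_keep %in% low]
    if (length(keep) == 0L) stop("pruning removed all models")
  }
  # relabel clusters 1..K by decreasing population
  pops <- tabulate(labels_keep)
  ord <- order(pops, decreasing = TRUE)
  ord <- ord[pops[ord] > 0]
  relabel <- integer(length(pops)); relabel[ord] <- seq_along(ord)
  labels_keep <- relabel[labels_keep]
  labels <- rep(NA_integer_, nm)
  labels[keep] <- labels_keep
  populations <- tabulate(labels_keep, nbins = max(labels_keep))
  medoids <- vapply(seq_along(populations), function(cl) {
    members <- keep[labels_keep == cl]
    if (length(members) == 1L) return(members)
    dsum <- vapply(members, function(i) {
      sum(vapply(members, function(j) {
        if (i == j) return(0)
        kabsch_rmsd(model_coords(ens, i)[sel, , drop = FALSE],
                    model_coords(ens, j)[sel, , drop = FALSE])
      }, numeric(1)))
    }, numeric(1))
    members[which.min(dsum)]
  }, integer(1))
  structure(list(labels = labels, populations = populations,
                 medoids = medoids,
                 pruned = setdiff(seq_len(nm), keep)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Clusters: %d (populations %s); %d model(s) pruned\n",
              length(x$populations),
              paste(x$populations, collapse = "/"),
              length(x$pruned)))
  invisible(x)
}

#' Write a conformer ensemble to a multi-model PDB file
#'
#' @param ens a `conformer_ensemble`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(n_models(ens))) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- model_coords(ens, m)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(nrow(ens$atoms)),
      formatC(ens$atoms$elety, width = -4),
      ens$atoms$resid, ens$atoms$chain, ens$atoms$resno,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
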