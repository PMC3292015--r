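#' Backbone RMSD versus a reference frame
#'
#' Root-mean-square deviation of the selected atoms after optimal
#' least-squares superposition (rigid rotation + translation removed), per
#' frame, relative to a reference structure — by default the first frame,
#' standing in for the initial minimized structure.
#'
#' @param ens an `"mmensemble"`.
#' @param top an `"mmtopology"` (atom names for the selection).
#' @param ref reference: a frame index into `ens` or an N x 3 matrix.
#' @param selection character vector of backbone atom names; the conventional
#'   heavy backbone is N, CA, C.
#' @param include_o if `TRUE`, add the carbonyl O to the selection.
#' @return numeric vector, one RMSD (A) per frame.
#' @export
backbone_rmsd <- function(ens, top, ref = 1,
                          selection = c("N", "CA", "C"), include_o = FALSE) {
  if (include_o) selection <- unique(c(selection, "O"))
  idx <- which(top$atoms$name %in% selection)
  if (!length(idx)) stop("selection matches no atoms")
  if (length(idx) < 3) stop("underdetermined: superposition needs >= 3 atoms")
  refm <- if (is.matrix(ref)) ref[idx, , drop = FALSE]
          else ens$frames[[ref]][idx, , drop = FALSE]
  vapply(ens$frames, function(f)
    kabsch_rmsd(refm, f[idx, , drop = FALSE]), 0)
}

#' Least-squares superposed RMSD of two coordinate sets
#'
#' Kabsch algorithm: optimal proper rotation (SVD with reflection guard) after
#' centering, then root-mean-square deviation.
#'
#' @param a,b N x 3 coordinate matrices (reference, mobile).
#' @return RMSD in the coordinate units.
#' @export
kabsch_rmsd <- function(a, b) {
  if (nrow(a) != nrow(b)) stop("coordinate sets differ in size")
  if (nrow(a) < 3) stop("underdetermined: superposition needs >= 3 atoms")
  A0 <- sweep(a, 2, colMeans(a))
  B0 <- sweep(b, 2, colMeans(b))
  s <- svd(t(B0) %*% A0)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((B0 %*% R - A0)^2)))
}

#' Hydrogen-bond occupancy over an ensemble
#'
#' A frame counts toward a donor/acceptor pair when the heavy-donor to
#' acceptor distance is below `dist_cut` (3.5 A) and the donor-H...acceptor
#' angle, measured at the hydrogen, exceeds `angle_cut` (120 deg). Reported
#' distance and angle means are over qualifying frames only.
#'
#' @param ens an `"mmensemble"`.
#' @param top an `"mmtopology"`; each donor hydrogen must be bonded to its
#'   donor heavy atom.
#' @param pairs data.frame with columns `donor` (heavy atom index), `hydrogen`
#'   and `acceptor` (atom indices).
#' @param dist_cut donor-acceptor distance criterion (A).
#' @param angle_cut angle criterion (degrees).
#' @return data.frame of class `"mmhbonds"`: one row per pair with `donor`,
#'   `hydrogen`, `acceptor` (atom labels), `mean_distance`, `mean_angle`,
#'   `occupancy` (percent of frames).
#' @export
hbond_occupancy <- function(ens, top, pairs, dist_cut = 3.5, angle_cut = 120) {
  pairs <- as.data.frame(pairs)
  bmat <- as.matrix(top$bonds[c("i", "j")])
  bkey <- .pair_key(bmat[, 1], bmat[, 2])
  lab <- function(i) paste0(top$atoms$resname[i], top$atoms$resno[i], "-",
                            top$atoms$name[i])
  out <- lapply(seq_len(nrow(pairs)), function(p) {
    d <- pairs$donor[p]; h <- pairs$hydrogen[p]; a <- pairs$acceptor[p]
    if (!(.pair_key(d, h) %in% bkey))
      stop("donor hydrogen ", h, " is not bonded to donor heavy atom ", d)
    dist <- ang <- numeric(length(ens$frames))
    for (f in seq_along(ens$frames)) {
      xyz <- ens$frames[[f]]
      dist[f] <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
      v1 <- xyz[d, ] - xyz[h, ]; v2 <- xyz[a, ] - xyz[h, ]
      ang[f] <- .rad2deg(acos(pmin(1, pmax(-1,
        sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))))
    }
    ok <- dist < dist_cut & ang > angle_cut
    data.frame(donor = lab(d), hydrogen = lab(h), acceptor = lab(a),
               mean_distance = if (any(ok)) mean(dist[ok]) else NA_real_,
               mean_angle = if (any(ok)) mean(ang[ok]) else NA_real_,
               occupancy = 100 * mean(ok))
  })
  structure(do.call(rbind, out), class = c("mmhbonds", "data.frame"))
}
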