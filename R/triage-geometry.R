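# Rigid-body superposition (Kabsch) and multi-model consistency RMSD.

#' Least-squares rigid superposition of paired point sets
#'
#' Kabsch algorithm: finds the proper rotation (determinant +1) and
#' translation minimising the RMSD between `moving` and `reference` after
#' transformation `moving %*% t(R) + t`, via the SVD of the covariance of
#' the centred coordinates.
#'
#' @param reference n x 3 matrix of reference coordinates (angstroms).
#' @param moving n x 3 matrix of coordinates to superpose; same row order
#'   (point i pairs with reference point i); n >= 3 and not all collinear.
#' @return A list with `rotation` (3 x 3, det +1), `translation` (length
#'   3), `rmsd` (angstroms, after applying the transform) and `transformed`
#'   (the superposed moving coordinates).
#' @examples
#' pts <- matrix(rnorm(15), 5, 3)
#' superpose(pts, pts)$rmsd  # 0
#' @export
superpose <- function(reference, moving) {
  reference <- as.matrix(reference); moving <- as.matrix(moving)
  if (ncol(reference) != 3L || ncol(moving) != 3L)
    stop("coordinates must be n x 3 matrices")
  if (nrow(reference) != nrow(moving))
    stop(sprintf("point counts differ: %d reference vs %d moving",
                 nrow(reference), nrow(moving)))
  if (nrow(reference) < 3L)
    stop("superposition needs at least 3 paired points")
  cref <- colMeans(reference); cmov <- colMeans(moving)
  a <- sweep(reference, 2, cref); b <- sweep(moving, 2, cmov)
  # planar sets are fine; collinear sets leave the rotation underdetermined
  sd_a <- svd(a)$d
  if (sum(sd_a > 1e-8 * max(sd_a, 1e-30)) < 2L)
    stop("reference points are collinear; superposition is degenerate")
  h <- crossprod(b, a)  # 3x3 covariance, moving -> reference
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cref - as.numeric(rot %*% cmov)
  transformed <- moving %*% t(rot) + matrix(trans, nrow(moving), 3,
                                            byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((transformed - reference)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd,
       transformed = transformed)
}

# Alpha-carbon coordinates of a chain set, in residue order; skip_missing
# residues lacking a CA are dropped (the caller aligns the two models'
# residue sets first).
ca_coords <- function(model, chains) {
  at <- model$atoms
  sel <- at$chain %in% chains & at$elety == "CA"
  key <- paste(at$chain[sel], at$resno[sel])
  m <- as.matrix(at[sel, c("x", "y", "z")])
  rownames(m) <- key
  m
}

#' Cross-model consistency of the candidate-chain placement
#'
#' Measures whether independent predictions of a complex agree on where the
#' candidate chain sits on the bait. For every pair of models, the pair is
#' superposed on the bait-chain alpha-carbon backbone ([superpose()]); the
#' candidate-chain alpha-carbon RMSD is then computed in that frame without
#' further fitting. Residues missing a CA in either model of a pair are
#' skipped. Returns the median over model pairs, robust to one divergent
#' model among three.
#'
#' @param bundle A [prediction_bundle()] with >= 2 models.
#' @return Median pairwise candidate-chain RMSD in angstroms. The full
#'   pairwise vector is attached as attribute `"pairwise"`.
#' @export
model_consistency <- function(bundle) {
  stopifnot(inherits(bundle, "prediction_bundle"))
  models <- bundle$models
  if (length(models) < 2L)
    stop("model consistency needs at least 2 models")
  bait <- bundle$chain_map$bait
  cand <- bundle$chain_map$candidate
  pairs <- utils::combn(length(models), 2)
  rmsds <- apply(pairs, 2, function(ij) {
    mi <- models[[ij[1]]]; mj <- models[[ij[2]]]
    bi <- ca_coords(mi, bait); bj <- ca_coords(mj, bait)
    common_b <- intersect(rownames(bi), rownames(bj))
    if (length(common_b) < 3L)
      stop("fewer than 3 shared bait alpha-carbons; cannot superpose")
    sp <- superpose(bi[common_b, , drop = FALSE],
                    bj[common_b, , drop = FALSE])
    ci <- ca_coords(mi, cand); cj <- ca_coords(mj, cand)
    common_c <- intersect(rownames(ci), rownames(cj))
    if (!length(common_c))
      stop("no shared candidate alpha-carbons between models")
    cj_t <- cj[common_c, , drop = FALSE] %*% t(sp$rotation) +
      matrix(sp$translation, length(common_c), 3, byrow = TRUE)
    sqrt(mean(rowSums((cj_t - ci[common_c, , drop = FALSE])^2)))
  })
  out <- stats::median(rmsds)
  attr(out, "pairwise") <- rmsds
  out
}
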