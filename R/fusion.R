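# Bead-based co-registration of the two deskewed views and fusion into a
# single volume with a dual-view overlap mask.

#' Match bead centres between two views
#'
#' Maps `centres_b` into the frame of `centres_a` through `init`, then pairs
#' points by mutual nearest neighbours within `radius_um`. Matching is
#' greedy by increasing distance and each point is used at most once.
#'
#' @param centres_a,centres_b matrices with columns (x, y, z) in um.
#' @param init an [AffineTransform3D-class] mapping the b frame into the a
#'   frame (default identity).
#' @param radius_um maximum pairing distance in um.
#' @return List with `pairs` (integer matrix of row indices `a`, `b`),
#'   `points_a`, `points_b` (the matched coordinates, untransformed), and
#'   `residual_um`, the RMS distance of the matches after `init`.
#' @export
matchBeads <- function(centres_a, centres_b, init = AffineTransform3D(),
                       radius_um = 1) {
  .check_positive(radius_um = radius_um)
  a <- as.matrix(centres_a); b <- as.matrix(centres_b)
  if (!nrow(a) || !nrow(b))
    return(list(pairs = matrix(integer(), 0, 2,
                               dimnames = list(NULL, c("a", "b"))),
                points_a = a[integer(0), , drop = FALSE],
                points_b = b[integer(0), , drop = FALSE],
                residual_um = NA_real_))
  bt <- applyTransform(init, b)
  d2 <- outer(rowSums(a^2), rep(1, nrow(bt))) +
        outer(rep(1, nrow(a)), rowSums(bt^2)) - 2 * a %*% t(bt)
  d2[d2 < 0] <- 0
  nn_ab <- max.col(-d2)                     # nearest b for each a
  nn_ba <- max.col(-t(d2))                  # nearest a for each b
  ia <- seq_len(nrow(a))
  mutual <- ia[nn_ba[nn_ab] == ia]
  dist <- sqrt(d2[cbind(mutual, nn_ab[mutual])])
  keep <- dist <= radius_um
  mutual <- mutual[keep]; dist <- dist[keep]
  ord <- order(dist)
  used_b <- logical(nrow(b))
  pairs <- matrix(integer(), 0, 2)
  for (i in ord) {
    j <- nn_ab[mutual[i]]
    if (!used_b[j]) {
      used_b[j] <- TRUE
      pairs <- rbind(pairs, c(mutual[i], j))
    }
  }
  colnames(pairs) <- c("a", "b")
  res <- if (nrow(pairs))
    sqrt(mean(rowSums((a[pairs[, 1], , drop = FALSE] -
                       bt[pairs[, 2], , drop = FALSE])^2))) else NA_real_
  list(pairs = pairs,
       points_a = a[pairs[, 1], , drop = FALSE],
       points_b = b[pairs[, 2], , drop = FALSE],
       residual_um = res)
}

#' Estimate the transform between matched bead centres
#'
#' Least-squares fit of the map `p_a -> M p_a + t` minimising
#' `sum || M a_i + t - b_i ||^2` over the correspondences. The default
#' `"similarity"` model (rotation, isotropic scale, translation; solved by
#' the SVD/Umeyama construction) reflects the physical relation between the
#' two views; `"affine"` fits all 12 parameters and can absorb calibration
#' error.
#'
#' @param corr a correspondence list from [matchBeads()], or a list with
#'   elements `points_a`, `points_b`.
#' @param type `"similarity"` or `"affine"`.
#' @return An [AffineTransform3D-class] with attribute `residual_um` (RMS).
#' @export
estimateAffine <- function(corr, type = c("similarity", "affine")) {
  type <- match.arg(type)
  a <- as.matrix(corr$points_a); b <- as.matrix(corr$points_b)
  n <- nrow(a)
  if (n < 4L)
    stop("degenerate geometry: at least 4 correspondences required",
         call. = FALSE)
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  if (qr(cbind(ac))$rank < 3L)
    stop("degenerate geometry: correspondences are coplanar", call. = FALSE)
  if (type == "similarity") {
    S <- t(bc) %*% ac / n
    sv <- svd(S)
    d <- sign(det(sv$u %*% t(sv$v)))
    D <- diag(c(1, 1, d))
    R <- sv$u %*% D %*% t(sv$v)
    var_a <- mean(rowSums(ac^2))
    scale <- sum(diag(D) * sv$d) / var_a
    M <- scale * R
  } else {
    M <- t(qr.solve(ac, bc))                 # 3x3 least squares
  }
  t_off <- cb - as.numeric(M %*% ca)
  tf <- AffineTransform3D(matrix = M, offset = t_off)
  pred <- applyTransform(tf, a)
  attr(tf, "residual_um") <- sqrt(mean(rowSums((pred - b)^2)))
  tf
}

#' Register two bead-centre sets by iterative match-and-fit
#'
#' Alternates [matchBeads()] and [estimateAffine()]: the first pass matches
#' under the initial transform, each subsequent pass re-matches under the
#' previous fit. This recovers transforms whose displacements are
#' comparable to the bead spacing, where a single mutual-nearest-neighbour
#' pass would mismatch.
#'
#' @param centres_a,centres_b matrices with columns (x, y, z) in um.
#' @param radius_um maximum pairing distance for the matching passes.
#' @param type `"similarity"` or `"affine"`; see [estimateAffine()].
#' @param init initial guess for the b-to-a mapping.
#' @param iterations number of match/fit passes.
#' @return An [AffineTransform3D-class] mapping a-frame points into the b
#'   frame (as [estimateAffine()]), with attributes `residual_um` and
#'   `n_pairs`.
#' @export
registerBeads <- function(centres_a, centres_b, radius_um = 1,
                          type = c("similarity", "affine"),
                          init = AffineTransform3D(), iterations = 2L) {
  type <- match.arg(type)
  b_to_a <- init
  tf <- NULL
  for (i in seq_len(iterations)) {
    corr <- matchBeads(centres_a, centres_b, init = b_to_a,
                       radius_um = radius_um)
    if (nrow(corr$pairs) < 4L) {
      if (is.null(tf))
        stop("registration failed: fewer than 4 correspondences",
             call. = FALSE)
      break
    }
    tf <- estimateAffine(corr, type = type)
    attr(tf, "n_pairs") <- nrow(corr$pairs)
    b_to_a <- invertTransform(tf)
  }
  tf
}

#' Fuse two registered views into one volume
#'
#' Resamples `vol_b` onto `vol_a`'s grid through the transform `tf` (mapping
#' a-frame world coordinates into the b frame, as returned by
#' [estimateAffine()] on (a, b) correspondences) and blends. The fused value
#' is the mean of the valid contributions (or their maximum for
#' `mode = "max"`); voxels valid in only one view keep that view's value.
#' The overlap mask — the parallelepiped-shaped region imaged by both views
#' — is the exact intersection of the two validity masks after resampling.
#'
#' @param vol_a,vol_b [ImageVolume-class] objects.
#' @param tf an [AffineTransform3D-class]; identity by default.
#' @param mode `"mean"` or `"max"`.
#' @param interpolation `"cubic"` or `"trilinear"`.
#' @return List with `volume` (fused [ImageVolume-class], validity = union)
#'   and `overlap` (logical array, the dual-view mask).
#' @export
fuseViews <- function(vol_a, vol_b, tf = AffineTransform3D(),
                      mode = c("mean", "max"),
                      interpolation = c("cubic", "trilinear")) {
  mode <- match.arg(mode)
  interpolation <- match.arg(interpolation)
  stopifnot(is(vol_a, "ImageVolume"), is(vol_b, "ImageVolume"))
  db <- dim(vol_b@voxels); da <- dim(vol_a@voxels)
  # world(a) -> world(b) -> fractional index of b, in b's [z, y, x] order
  idx_of_world_b <- AffineTransform3D(
    matrix = diag(1 / vol_b@voxel_um[c(3, 2, 1)]) %*%
      matrix(c(0, 0, 1, 0, 1, 0, 1, 0, 0), 3, 3),
    offset = -vol_b@origin_um[c(3, 2, 1)] / vol_b@voxel_um[c(3, 2, 1)])
  comp <- composeTransform(idx_of_world_b, tf)
  res <- .affineResample(vol_b@voxels, as.integer(db), comp@matrix,
                         comp@offset, as.integer(da), vol_a@voxel_um,
                         vol_a@origin_um,
                         if (interpolation == "trilinear") 0L else 1L, 0)
  b_on_a <- res$values
  b_valid <- .affineResampleMask(vol_b@valid, as.integer(db),
                                 comp@matrix, comp@offset,
                                 as.integer(da), vol_a@voxel_um,
                                 vol_a@origin_um)
  overlap <- vol_a@valid & b_valid
  if (!any(overlap))
    warning("fused views have empty overlap", call. = FALSE)
  fused <- vol_a@voxels
  only_b <- b_valid & !vol_a@valid
  fused[only_b] <- b_on_a[only_b]
  if (mode == "mean") {
    fused[overlap] <- (vol_a@voxels[overlap] + b_on_a[overlap]) / 2
  } else {
    fused[overlap] <- pmax(vol_a@voxels[overlap], b_on_a[overlap])
  }
  vol <- ImageVolume(fused, voxel_um = vol_a@voxel_um,
                     origin_um = vol_a@origin_um,
                     valid = vol_a@valid | b_valid)
  list(volume = vol, overlap = overlap)
}

#' Serialize / restore an affine transform
#'
#' Writes the 12 numbers (row-major 3x3 matrix then offset) as JSON, the
#' interchange record used to duplicate one channel's transform across
#' channels.
#'
#' @param tf an [AffineTransform3D-class].
#' @param path file path.
#' @return `readTransform` returns an [AffineTransform3D-class].
#' @export
writeTransform <- function(tf, path) {
  stopifnot(is(tf, "AffineTransform3D"))
  jsonlite::write_json(list(matrix = as.numeric(t(tf@matrix)),
                            offset = tf@offset),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  AffineTransform3D(matrix = matrix(rec$matrix, 3, 3, byrow = TRUE),
                    offset = rec$offset)
}
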