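#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the sum of squared
#' distances between paired points; reflections are rejected, so a
#' mirror-image point set gets the best proper rotation with a non-zero
#' residual.  At least three point pairs are required; colinear point sets
#' are allowed but flagged with a warning because the rotation about the
#' common axis is then unresolved.
#'
#' @param mobile n x 3 matrix of points to move.
#' @param target n x 3 matrix of reference points (paired by row).
#' @return list with \code{transform} (a [RigidTransform-class]) and
#'   \code{rmsd} (Angstrom, after the fit).
#' @export
superpose <- function(mobile, target) {
  mobile <- rbind(mobile); target <- rbind(target)
  if (nrow(mobile) != nrow(target))
    stop("mobile and target must have the same number of points")
  if (nrow(mobile) < 3L)
    stop("at least 3 point pairs are required")
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  sv <- svd(crossprod(P, Q))  # H = P^T Q = U D V^T
  if (sv$d[2] < 1e-9)
    warning("colinear point set: rotation about the axis is unresolved")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- new("RigidTransform", rotation = R,
            translation = as.numeric(ct - R %*% cm))
  moved <- applyTransform(tr, mobile)
  list(transform = tr,
       rmsd = sqrt(mean(rowSums((moved - target)^2))))
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a [RigidTransform-class].
#' @param coords n x 3 matrix (or length-3 vector).
#' @return transformed coordinates, same shape.
#' @export
applyTransform <- function(transform, coords) {
  stopifnot(is(transform, "RigidTransform"))
  v <- is.null(dim(coords))
  coords <- rbind(coords)
  out <- sweep(coords %*% t(transform@rotation), 2,
               -transform@translation)
  if (v) as.numeric(out) else out
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying \code{first}, then
#' \code{second}.
#' @param second,first [RigidTransform-class] objects.
#' @return a [RigidTransform-class].
#' @export
composeTransforms <- function(second, first) {
  new("RigidTransform",
      rotation = second@rotation %*% first@rotation,
      translation = as.numeric(second@rotation %*% first@translation +
                               second@translation))
}

#' Invert a rigid transform
#' @param transform a [RigidTransform-class].
#' @return a [RigidTransform-class].
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  new("RigidTransform", rotation = Rt,
      translation = as.numeric(-Rt %*% transform@translation))
}

identityTransform <- function() {
  new("RigidTransform", rotation = diag(3), translation = numeric(3))
}

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform\n  rotation:\n")
  print(round(object@rotation, 4))
  cat("  translation:", paste(round(object@translation, 4), collapse = " "),
      "\n")
})
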