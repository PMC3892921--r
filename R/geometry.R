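# Rigid-body geometry: least-squares superposition (SVD method of the
# classic point-set registration literature), transforms and RMSD.

#' Create a rigid transform
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation length-3 numeric vector (Angstrom).
#' @return Object of class \code{cleft_transform}; applying it maps a
#'   coordinate row \code{x} to \code{rotation \%*\% x + translation}.
#' @export
new_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    cm_runtime_error("transform rotation is not proper orthogonal")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "cleft_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 coordinate matrix.
#' @param transform a \code{cleft_transform}.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, transform) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  sweep(xyz %*% t(transform$rotation), 2, -transform$translation)
}

#' Invert a rigid transform
#' @param transform a \code{cleft_transform}.
#' @return The inverse \code{cleft_transform}.
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  new_transform(rt, -rt %*% transform$translation)
}

compose_transform <- function(second, first) {
  # (second o first)(x) = R2 (R1 x + t1) + t2
  new_transform(second$rotation %*% first$rotation,
                second$rotation %*% first$translation + second$translation)
}

#' @export
print.cleft_transform <- function(x, ...) {
  cat("rigid transform (rotation | translation):\n")
  print(round(cbind(x$rotation, x$translation), 6))
  invisible(x)
}

format_transform <- function(transform) {
  m <- cbind(transform$rotation, transform$translation)
  paste(apply(m, 1, function(r) paste(sprintf("%12.7f", r), collapse = " ")),
        collapse = "\n")
}

#' Least-squares rigid superposition of paired points
#'
#' Computes the proper rotation and translation minimizing the squared
#' deviation between paired coordinates via the singular value decomposition
#' of the cross-covariance matrix; a reflection, if obtained, is corrected by
#' flipping the sign of the smallest singular direction.
#'
#' @param moving n x 3 coordinates to be moved.
#' @param fixed n x 3 reference coordinates (same row pairing).
#' @return A \code{cleft_transform} mapping \code{moving} onto \code{fixed}.
#' @export
superpose_arun <- function(moving, fixed) {
  moving <- matrix(as.numeric(as.matrix(moving)), ncol = 3)
  fixed <- matrix(as.numeric(as.matrix(fixed)), ncol = 3)
  if (nrow(moving) != nrow(fixed))
    cm_input_error("superposition: coordinate lists differ in length")
  if (nrow(moving) < 3)
    cm_input_error("degenerate superposition: need at least 3 point pairs")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  h <- crossprod(sweep(moving, 2, cm), sweep(fixed, 2, cf))
  sv <- svd(h)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    cm_input_error("degenerate superposition: points are collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  new_transform(rot, cf - rot %*% cm)
}

#' Root-mean-square deviation of paired coordinates
#'
#' @param x,y n x 3 coordinate matrices with identical row pairing.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(x, y) {
  x <- matrix(as.numeric(as.matrix(x)), ncol = 3)
  y <- matrix(as.numeric(as.matrix(y)), ncol = 3)
  if (nrow(x) != nrow(y)) cm_input_error("rmsd: coordinate lists differ in length")
  if (!nrow(x)) cm_input_error("rmsd: empty coordinate lists")
  sqrt(mean(rowSums((x - y)^2)))
}

# Deterministic random proper rotation (for fixtures and tests).
random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_transform <- function(translation_scale = 20) {
  new_transform(random_rotation(), stats::runif(3, -translation_scale,
                                                translation_scale))
}
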