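# Voxel geometry: quaternion <-> affine conversion per the NIfTI-1 reference
# method, the unlocalized default, and the grid-contiguity rule.

#' Voxel geometry
#'
#' A 4x4 affine mapping 0-based voxel indices (i, j, k) at voxel centers to
#' spatial coordinates in millimeters, plus the NIfTI frame code saying what
#' those coordinates mean (0 unknown, 1 scanner-anatomical, 4 standard
#' template space).
#'
#' @param affine 4x4 numeric matrix.
#' @param frame_code integer.
#' @return An object of class `mrs_geometry`.
#' @export
geometry <- function(affine, frame_code = 1L) {
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)), is.numeric(affine))
  if (frame_code > 0 && abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 100)
    stop_mrs("affine rotation-scale block is singular", "mrs_geometry_error")
  structure(list(affine = affine, frame_code = as.integer(frame_code)),
            class = "mrs_geometry")
}

#' Build an affine from NIfTI quaternion header fields
#'
#' Reconstructs the qform affine: the first quaternion component is
#' `a = sqrt(max(0, 1 - b^2 - c^2 - d^2))`, the rotation matrix follows the
#' NIfTI-1 reference formula, columns are scaled by the voxel sizes with the
#' third column multiplied by `qfac` (the handedness sign stored in
#' `pixdim[0]`), and the translation is the offset triple.
#'
#' @param b,c,d quaternion components.
#' @param qfac +1 or -1.
#' @param pixdim numeric(3) voxel sizes (mm).
#' @param offsets numeric(3) `qoffset_{x,y,z}` (mm).
#' @param frame_code integer stored alongside (default scanner-anatomical).
#' @return An `mrs_geometry`.
#' @export
affine_from_quaternion <- function(b, c, d, qfac, pixdim, offsets,
                                   frame_code = 1L) {
  stopifnot(qfac %in% c(-1, 1), length(pixdim) == 3L, length(offsets) == 3L)
  nrm <- b^2 + c^2 + d^2
  if (nrm > 1 + 1e-6)
    stop_mrs(sprintf("quaternion norm b^2+c^2+d^2 = %.8f exceeds 1", nrm),
             "mrs_quaternion_error")
  a <- sqrt(max(0, 1 - nrm))
  R <- matrix(c(
    a*a + b*b - c*c - d*d, 2*(b*c - a*d),         2*(b*d + a*c),
    2*(b*c + a*d),         a*a + c*c - b*b - d*d, 2*(c*d - a*b),
    2*(b*d - a*c),         2*(c*d + a*b),         a*a + d*d - b*b - c*c
  ), nrow = 3L, byrow = TRUE)
  M <- R %*% diag(c(pixdim[1], pixdim[2], qfac * pixdim[3]))
  aff <- rbind(cbind(M, as.numeric(offsets)), c(0, 0, 0, 1))
  geometry(aff, frame_code = frame_code)
}

#' Decompose an affine into NIfTI quaternion header fields
#'
#' Inverse of [affine_from_quaternion()]: extracts positive column scales,
#' sets `qfac = -1` (negating the third column) when the rotation block is
#' left-handed, checks that the remainder is orthonormal (the qform cannot
#' encode shear), and converts the rotation to a unit quaternion with
#' `a >= 0`.
#'
#' @param geom an `mrs_geometry` or 4x4 affine.
#' @param tol orthonormality tolerance for the shear check.
#' @return List with `b`, `c`, `d`, `qfac`, `pixdim` (3 scales), `offsets`.
#' @export
quaternion_from_affine <- function(geom, tol = 1e-5) {
  aff <- if (inherits(geom, "mrs_geometry")) geom$affine else as.matrix(geom)
  M <- aff[1:3, 1:3]
  scales <- sqrt(colSums(M^2))
  if (any(scales == 0))
    stop_mrs("affine has a zero-length column", "mrs_geometry_error")
  R <- sweep(M, 2L, scales, "/")
  qfac <- 1
  if (det(R) < 0) {
    qfac <- -1
    R[, 3] <- -R[, 3]
  }
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop_mrs("affine contains shear; the qform can only encode rotations and scales",
             "mrs_shear_error")
  # rotation -> quaternion, branch on the largest diagonal term for stability
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    a <- s / 4
    b <- (R[3, 2] - R[2, 3]) / s
    c <- (R[1, 3] - R[3, 1]) / s
    d <- (R[2, 1] - R[1, 2]) / s
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    a <- (R[3, 2] - R[2, 3]) / s
    b <- s / 4
    c <- (R[1, 2] + R[2, 1]) / s
    d <- (R[1, 3] + R[3, 1]) / s
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    a <- (R[1, 3] - R[3, 1]) / s
    b <- (R[1, 2] + R[2, 1]) / s
    c <- s / 4
    d <- (R[2, 3] + R[3, 2]) / s
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    a <- (R[2, 1] - R[1, 2]) / s
    b <- (R[1, 3] + R[3, 1]) / s
    c <- (R[2, 3] + R[3, 2]) / s
    d <- s / 4
  }
  if (a < 0) { b <- -b; c <- -c; d <- -d }   # sign convention: a >= 0
  list(b = b, c = c, d = d, qfac = qfac, pixdim = scales,
       offsets = aff[1:3, 4])
}

# The unlocalized voxel-size default, meters.
UNLOCALIZED_SIZE_M <- 10

#' Default geometry for unlocalized data
#'
#' Data with no meaningful real-world position (simulated data, coil-limited
#' localization) is stored with `qform_code = 0` and a default voxel size of
#' 10 m in each spatial direction — 10000 in the millimeter header unit.
#'
#' @return An `mrs_geometry` with `frame_code = 0` and the 10 m default on
#'   the diagonal.
#' @export
default_unlocalized_geometry <- function() {
  mm <- UNLOCALIZED_SIZE_M * 1000
  geometry(diag(c(mm, mm, mm, 1)), frame_code = 0L)
}

#' Voxel sizes of a geometry in meters
#'
#' @param geom an `mrs_geometry`.
#' @return numeric(3), meters.
#' @export
voxel_size_m <- function(geom) {
  sqrt(colSums(geom$affine[1:3, 1:3]^2)) / 1000
}

# Fill the qform (and mirrored sform) header fields from a geometry.
apply_geometry <- function(hdr, geom) {
  stopifnot(inherits(geom, "mrs_geometry"))
  if (geom$frame_code == 0L) {
    hdr$qform_code <- 0L
    hdr$sform_code <- 0L
    hdr$pixdim[1] <- 1
    hdr$pixdim[2:4] <- sqrt(colSums(geom$affine[1:3, 1:3]^2))
    hdr$quatern <- c(b = 0, c = 0, d = 0)
    hdr$qoffset <- c(x = 0, y = 0, z = 0)
    hdr$srow <- matrix(0, 3, 4)
  } else {
    q <- quaternion_from_affine(geom)
    hdr$qform_code <- geom$frame_code
    hdr$sform_code <- geom$frame_code   # sform mirrored for viewer compatibility
    hdr$pixdim[1] <- q$qfac
    hdr$pixdim[2:4] <- q$pixdim
    hdr$quatern <- c(b = q$b, c = q$c, d = q$d)
    hdr$qoffset <- c(x = q$offsets[1], y = q$offsets[2], z = q$offsets[3])
    hdr$srow <- geom$affine[1:3, ]
  }
  hdr
}

# Geometry carried by a header (qform authoritative; warn if a populated
# sform disagrees beyond 1e-3 mm).
header_geometry <- function(hdr) {
  if (hdr$qform_code > 0) {
    g <- affine_from_quaternion(hdr$quatern[["b"]], hdr$quatern[["c"]],
                                hdr$quatern[["d"]], hdr$pixdim[1],
                                hdr$pixdim[2:4], hdr$qoffset,
                                frame_code = hdr$qform_code)
    if (hdr$sform_code > 0 && max(abs(hdr$srow - g$affine[1:3, ])) > 1e-3)
      warning("qform and sform disagree by more than 1e-3 mm; using qform")
    return(g)
  }
  if (hdr$sform_code > 0)
    return(geometry(rbind(hdr$srow, c(0, 0, 0, 1)), frame_code = hdr$sform_code))
  geometry(diag(c(hdr$pixdim[2:4], 1)), frame_code = 0L)
}

#' Check that a set of voxel origins forms a contiguous grid
#'
#' The NIfTI format cannot store spatially noncontiguous data (gaps between
#' voxels or slices) in a single file; converters use this check to refuse
#' multi-slab inputs. Origins are contiguous when they occupy every node of
#' a dense rectilinear lattice with constant spacing along each axis.
#'
#' @param origins numeric matrix, one row per voxel, 3 columns (mm). A
#'   vector is taken as a single origin.
#' @param spacing optional numeric(3): the voxel size along each axis (mm).
#'   When given, lattice node spacing must equal it — this is what catches a
#'   gap between slices that are individually evenly spaced (e.g. two slices
#'   15 mm apart with 10 mm slice thickness).
#' @param tol relative spacing tolerance.
#' @return `TRUE` or `FALSE`.
#' @examples
#' g <- as.matrix(expand.grid(x = c(0, 10), y = c(0, 10), z = 0))
#' check_contiguity(g, spacing = c(10, 10, 10))   # TRUE
#' check_contiguity(g[c(1, 4), ])                 # FALSE: corners only
#' @export
check_contiguity <- function(origins, spacing = NULL, tol = 1e-6) {
  if (is.null(dim(origins))) origins <- matrix(origins, nrow = 1L)
  origins <- as.matrix(origins)
  stopifnot(ncol(origins) == 3L)
  n <- nrow(origins)
  if (n <= 1L) return(TRUE)
  if (anyDuplicated(round(origins, 9)) > 0L) return(FALSE)
  axes <- lapply(1:3, function(j) {
    u <- sort(unique(origins[, j]))
    if (length(u) > 1L) {
      gaps <- diff(u)
      scale <- max(abs(u[length(u)] - u[1]), 1)
      if (max(gaps) - min(gaps) > tol * scale) return(NULL)  # uneven spacing
      if (!is.null(spacing) && abs(gaps[1] - spacing[j]) > tol * max(spacing[j], 1))
        return(NULL)   # even spacing but with a gap relative to voxel size
    }
    u
  })
  if (any(vapply(axes, is.null, logical(1)))) return(FALSE)
  if (prod(lengths(axes)) != n) return(FALSE)
  # every lattice node must be occupied
  lattice <- as.matrix(expand.grid(axes))
  key <- function(m) apply(round(m, 9), 1L, paste, collapse = "/")
  setequal(key(lattice), key(origins))
}
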