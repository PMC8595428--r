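#' @title Axis orientation handling
#' @description Orientation codes are three-letter strings, one letter per
#'   array axis, drawn from the anatomical direction pairs R/L
#'   (right/left), A/P (anterior/posterior), S/I (superior/inferior). The
#'   letter names the direction the array axis points toward, so `"RAS"`
#'   means axis 1 runs left-to-right, axis 2 posterior-to-anterior, axis 3
#'   inferior-to-superior. There are 48 valid signed permutations.
#' @name orientation
NULL

.axis_letters <- list(c("R", "L"), c("A", "P"), c("S", "I"))

letter_world_axis <- function(ch) {
  for (i in 1:3) if (ch %in% .axis_letters[[i]]) return(i)
  NA_integer_
}

letter_sign <- function(ch) if (ch %in% c("R", "A", "S")) 1 else -1

opposite_letter <- function(ch) {
  i <- letter_world_axis(ch)
  setdiff(.axis_letters[[i]], ch)
}

check_orientation <- function(code) {
  ok <- is.character(code) && length(code) == 1 && nchar(code) == 3
  if (ok) {
    ax <- vapply(strsplit(code, "")[[1]], letter_world_axis, integer(1))
    ok <- !anyNA(ax) && length(unique(ax)) == 3
  }
  if (!ok) stop(sprintf("invalid orientation code '%s'", code))
  invisible(code)
}

# 3x3 signed permutation matrix: column i = world direction of array axis i
orientation_matrix <- function(code) {
  check_orientation(code)
  letters3 <- strsplit(code, "")[[1]]
  m <- matrix(0, 3, 3)
  for (i in 1:3)
    m[letter_world_axis(letters3[i]), i] <- letter_sign(letters3[i])
  m
}

#' Flip a series along one array axis
#'
#' Reverses the data along `axis` and inverts the corresponding orientation
#' letter. Applying the same flip twice is the identity.
#'
#' @param series A `volume_series`.
#' @param axis Array axis 1, 2 or 3.
#' @return The flipped `volume_series`.
#' @export
flip_axis <- function(series, axis) {
  stopifnot(axis %in% 1:3)
  idx <- rep(list(quote(expr = )), 4)
  idx[[axis]] <- rev(seq_len(dim(series$data)[axis]))
  series$data <- do.call(`[`, c(list(series$data), idx, drop = FALSE))
  letters3 <- strsplit(series$orientation, "")[[1]]
  letters3[axis] <- opposite_letter(letters3[axis])
  series$orientation <- paste(letters3, collapse = "")
  series
}

#' Reorient a series to the canonical radiological convention
#'
#' Permutes and flips the array axes so the orientation code equals
#' `convention` (default `"LAS"`, a radiological display convention). After
#' both subjects of a dual acquisition are reoriented, voxel `(i, j, k)` is
#' spatially analogous across subjects, which is what the inter-brain
#' correlation assumes. The operation is idempotent: an already-canonical
#' series is returned unchanged.
#'
#' @param series A `volume_series`.
#' @param convention Target three-letter orientation code.
#' @return A `volume_series` in the target convention.
#' @export
reorient_to_radiological <- function(series, convention = "LAS") {
  check_orientation(convention)
  check_orientation(series$orientation)
  if (identical(series$orientation, convention)) return(series)
  src <- strsplit(series$orientation, "")[[1]]
  tgt <- strsplit(convention, "")[[1]]
  src_world <- vapply(src, letter_world_axis, integer(1))
  perm <- integer(3)
  flip <- logical(3)
  for (j in 1:3) {
    i <- which(src_world == letter_world_axis(tgt[j]))
    perm[j] <- i
    flip[j] <- src[i] != tgt[j]
  }
  data <- aperm(series$data, c(perm, 4))
  for (j in which(flip)) {
    idx <- rep(list(quote(expr = )), 4)
    idx[[j]] <- rev(seq_len(dim(data)[j]))
    data <- do.call(`[`, c(list(data), idx, drop = FALSE))
  }
  out <- series
  out$data <- data
  out$voxel_size_mm <- series$voxel_size_mm[perm]
  out$orientation <- convention
  out
}

#' Geometry of two subjects sharing one field of view
#'
#' Describes where each subject's head sits in the combined acquisition
#' volume and how the subjects face each other. The positioning platform
#' this models allows rotation about the scanner y-axis in 5-degree
#' increments up to 180 degrees and 1-91 cm of separation; face-to-face at
#' 11 cm is the configuration used for social imaging.
#'
#' @param boxes List of two 3x2 integer matrices, each row an axis, columns
#'   the 0-based inclusive start and exclusive end voxel index.
#' @param facing_angles_deg Two rotations about the scanner y-axis, in
#'   multiples of 5 on `[0, 180]`. A difference of 180 means face-to-face.
#' @param separation_cm Distance between subjects, in `[1, 91]` cm.
#' @param subject_ids Two identifier strings.
#' @return An object of class `subject_layout`.
#' @export
subject_layout <- function(boxes, facing_angles_deg = c(0, 180),
                           separation_cm = 11, subject_ids = c("A", "B")) {
  stopifnot(length(boxes) == 2, length(facing_angles_deg) == 2,
            length(subject_ids) == 2)
  boxes <- lapply(boxes, function(b) {
    b <- matrix(as.integer(b), 3, 2)
    if (any(b[, 2] <= b[, 1]) || any(b[, 1] < 0)) stop("degenerate box")
    b
  })
  if (all(pmax(boxes[[1]][, 1], boxes[[2]][, 1]) <
          pmin(boxes[[1]][, 2], boxes[[2]][, 2])))
    stop("subject boxes overlap")
  if (any(facing_angles_deg %% 5 != 0) ||
      any(facing_angles_deg < 0 | facing_angles_deg > 180))
    stop("facing angles must be multiples of 5 in [0, 180]")
  if (separation_cm < 1 || separation_cm > 91)
    stop("separation must be within [1, 91] cm")
  structure(list(boxes = boxes, facing_angles_deg = facing_angles_deg,
                 separation_cm = separation_cm, subject_ids = subject_ids),
            class = "subject_layout")
}

reverse_pe <- function(pe) paste(rev(strsplit(pe, "")[[1]]), collapse = "")

#' Split a dual-field-of-view acquisition into per-subject series
#'
#' Extracts each subject's bounding box from the combined volume. The second
#' subject of a face-to-face layout (180-degree relative rotation about the
#' scanner y-axis) has its orientation letters inverted on the two axes
#' orthogonal to the rotation axis and its phase-encode polarity reversed,
#' reflecting the physically opposite placement; a later
#' [reorient_to_radiological()] then makes voxel indices spatially analogous
#' across subjects.
#'
#' @param series Combined `volume_series`.
#' @param layout A [subject_layout()].
#' @return List of two `volume_series`, named by the layout's subject ids.
#' @export
split_dual_fov <- function(series, layout) {
  stopifnot(inherits(layout, "subject_layout"))
  d <- dim(series$data)[1:3]
  rel <- abs(diff(layout$facing_angles_deg))
  out <- vector("list", 2)
  for (s in 1:2) {
    b <- layout$boxes[[s]]
    if (any(b[, 2] > d)) stop(sprintf("box %d out of volume extent", s))
    data <- series$data[(b[1, 1] + 1):b[1, 2], (b[2, 1] + 1):b[2, 2],
                        (b[3, 1] + 1):b[3, 2], , drop = FALSE]
    orient <- series$orientation
    pe <- series$phase_encode
    if (s == 2 && rel == 180) {
      # rotation about y flips the R/L and S/I axes
      letters3 <- strsplit(orient, "")[[1]]
      for (i in 1:3)
        if (letter_world_axis(letters3[i]) %in% c(1, 3))
          letters3[i] <- opposite_letter(letters3[i])
      orient <- paste(letters3, collapse = "")
      pe <- reverse_pe(pe)
    }
    v <- volume_series(data, voxel_size_mm = series$voxel_size_mm,
                       tr_s = series$tr_s, orientation = orient,
                       subject_id = layout$subject_ids[s],
                       run_id = series$run_id, phase_encode = pe)
    attr(v, "facing_angle_deg") <- layout$facing_angles_deg[s]
    out[[s]] <- v
  }
  names(out) <- layout$subject_ids
  out
}
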