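#' Volume containers for 3D muscle image data
#'
#' All volumes in myomatrix share one internal convention: the data array is a
#' 3D array indexed `[long, row, col]` (1-based), where the *first* axis is the
#' muscle's longitudinal axis, so slicing along axis 1 yields muscle
#' cross-sections. Voxel sizes are stored in nanometres in the same order
#' `(d_long, d_row, d_col)`.
#'
#' Three concrete types exist:
#' * `labeled_volume`: non-negative integer labels, 0 = background, one unique
#'   label per myofibrillar segment.
#' * `mask_volume`: binary 0/1 data plus a `structure_name` tag
#'   (`"contractile"`, `"mitochondria"`, `"srt"`, `"cell"`, or `"other"`).
#' * `probability_volume`: per-voxel class probabilities in `[0, 1]`.
#'
#' @param data 3D array of the appropriate value type.
#' @param voxel_size numeric length-3, voxel edge lengths in nm,
#'   `(d_long, d_row, d_col)`. All entries must be positive.
#' @param structure_name structure tag for masks.
#' @return An object of class `labeled_volume`, `mask_volume` or
#'   `probability_volume` (all also inherit `muscle_volume`).
#' @name volumes
NULL

new_volume <- function(data, voxel_size, class, extra = list()) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("volume data must be a 3D array (got ",
         paste(dim(data), collapse = "x"), ")", call. = FALSE)
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("voxel_size must be 3 positive values (nm)", call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("all volume dimensions must be >= 1",
                                call. = FALSE)
  obj <- c(list(data = data, voxel_size = voxel_size), extra)
  structure(obj, class = c(class, "muscle_volume"))
}

#' @rdname volumes
#' @export
labeled_volume <- function(data, voxel_size = c(10, 10, 10)) {
  if (is.logical(data)) storage.mode(data) <- "integer"
  if (is.double(data)) {
    if (any(abs(data - round(data)) > 1e-9, na.rm = TRUE)) {
      stop("labeled_volume requires integer labels", call. = FALSE)
    }
    storage.mode(data) <- "integer"
  }
  if (any(data < 0L, na.rm = TRUE)) {
    stop("negative labels are not allowed", call. = FALSE)
  }
  new_volume(data, voxel_size, "labeled_volume")
}

#' @rdname volumes
#' @export
mask_volume <- function(data, voxel_size = c(10, 10, 10),
                        structure_name = "other") {
  structure_name <- match.arg(structure_name,
                              c("contractile", "mitochondria", "srt",
                                "cell", "other"))
  if (is.logical(data)) storage.mode(data) <- "integer"
  if (!all(data %in% c(0L, 1L))) {
    stop("mask_volume data must contain only 0/1", call. = FALSE)
  }
  storage.mode(data) <- "integer"
  new_volume(data, voxel_size, "mask_volume",
             list(structure_name = structure_name))
}

#' @rdname volumes
#' @export
probability_volume <- function(data, voxel_size = c(10, 10, 10)) {
  storage.mode(data) <- "double"
  if (any(data < 0 | data > 1, na.rm = TRUE)) {
    stop("probability values must lie in [0, 1]", call. = FALSE)
  }
  new_volume(data, voxel_size, "probability_volume")
}

#' Labels present in a labeled volume
#'
#' @param vol a `labeled_volume`.
#' @return Sorted integer vector of positive labels present (background 0 is
#'   excluded); integer(0) for an empty volume.
#' @export
label_set <- function(vol) {
  stopifnot(inherits(vol, "labeled_volume"))
  u <- sort(unique(as.vector(vol$data)))
  u[u > 0L]
}

#' @export
print.muscle_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<", class(x)[1], "> ", d[1], " x ", d[2], " x ", d[3],
      " voxels @ (", paste(x$voxel_size, collapse = ", "), ") nm\n", sep = "")
  if (inherits(x, "labeled_volume")) {
    cat("  labels: ", length(label_set(x)), "\n", sep = "")
  }
  if (inherits(x, "mask_volume")) {
    cat("  structure: ", x$structure_name,
        ", foreground voxels: ", sum(x$data), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.muscle_volume <- function(x) dim(x$data)

# internal: rebuild an object of the same volume class with new data/voxels
rewrap_volume <- function(template, data, voxel_size = template$voxel_size) {
  if (inherits(template, "mask_volume")) {
    mask_volume(data, voxel_size, template$structure_name)
  } else if (inherits(template, "probability_volume")) {
    probability_volume(data, voxel_size)
  } else {
    labeled_volume(data, voxel_size)
  }
}
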