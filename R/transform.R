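#' Reorient a volume so the longitudinal axis is axis 1
#'
#' Pure axis permutation plus optional per-axis flips; no resampling is ever
#' performed, so label values are untouched and the multiset of voxel values
#' is preserved exactly. After reorientation, slicing along axis 1 yields
#' muscle cross-sections. The two transverse axes keep their relative order.
#'
#' Flips are specified per *input* axis and applied before the permutation.
#'
#' @param vol a `muscle_volume`.
#' @param long_axis which input axis (1, 2 or 3) is the muscle's long axis.
#' @param flip logical length-3, whether to reverse each input axis.
#' @return A volume of the same class with the long axis first and
#'   `voxel_size` permuted accordingly.
#' @examples
#' v <- labeled_volume(array(0L, c(4, 5, 6)))
#' dim(reorient_longitudinal(v, long_axis = 3))  # 6 4 5
#' @export
reorient_longitudinal <- function(vol, long_axis = 1L,
                                  flip = c(FALSE, FALSE, FALSE)) {
  stopifnot(inherits(vol, "muscle_volume"))
  if (!(length(long_axis) == 1L && long_axis %in% 1:3)) {
    stop("long_axis must be 1, 2 or 3", call. = FALSE)
  }
  if (length(flip) != 3L || !is.logical(flip)) {
    stop("flip must be a logical vector of length 3", call. = FALSE)
  }
  d <- vol$data
  dm <- dim(d)
  idx <- lapply(1:3, function(a) if (flip[a]) rev(seq_len(dm[a])) else
                  seq_len(dm[a]))
  if (any(flip)) d <- d[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  perm <- c(long_axis, setdiff(1:3, long_axis))
  if (!identical(perm, 1:3)) d <- aperm(d, perm)
  rewrap_volume(vol, d, vol$voxel_size[perm])
}

#' Downsample (bin) a volume by integer factors
#'
#' Reduces each `factor[1] x factor[2] x factor[3]` block to a single voxel.
#' The reducer defaults to the only sensible choice per volume type:
#' modal label for `labeled_volume` (background is excluded from the mode
#' unless the block is entirely background; ties break to the smallest label,
#' so results are deterministic), `max` for masks, and `mean` for probability
#' volumes. Output shape is `ceiling(dim / factor)`; edge blocks are reduced
#' over the voxels actually present. Voxel sizes are multiplied by the factor,
#' e.g. 10 nm voxels binned by 2 become 20 nm voxels.
#'
#' @param vol a `muscle_volume`.
#' @param factor positive integer scalar or length-3 vector of binning factors.
#' @param reducer `"auto"` (default, per type as above) or one of
#'   `"mode_label"`, `"max"`, `"mean"`.
#' @return A volume of the same class.
#' @export
bin_volume <- function(vol, factor = 2L, reducer = c("auto", "mode_label",
                                                     "max", "mean")) {
  stopifnot(inherits(vol, "muscle_volume"))
  reducer <- match.arg(reducer)
  factor <- as.integer(rep_len(factor, 3L))
  if (any(is.na(factor)) || any(factor < 1L)) {
    stop("binning factor must be >= 1 per axis", call. = FALSE)
  }
  if (reducer == "auto") {
    reducer <- if (inherits(vol, "labeled_volume")) "mode_label"
    else if (inherits(vol, "mask_volume")) "max"
    else "mean"
  }
  dm <- dim(vol$data)
  if (all(factor == 1L)) return(vol)
  odim <- as.integer(ceiling(dm / factor))
  # block index of every voxel, in output linear order
  bi <- (seq_len(dm[1]) - 1L) %/% factor[1]
  bj <- (seq_len(dm[2]) - 1L) %/% factor[2]
  bk <- (seq_len(dm[3]) - 1L) %/% factor[3]
  block <- outer(outer(bi, bj * odim[1], "+"), bk * (odim[1] * odim[2]), "+")
  block <- as.vector(block) + 1L
  v <- as.vector(vol$data)
  out <- switch(reducer,
    mean = {
      s <- rowsum(v, block, reorder = TRUE)
      n <- rowsum(rep(1, length(v)), block, reorder = TRUE)
      as.vector(s / n)
    },
    max = vapply(split(v, block), max, numeric(1)),
    mode_label = vapply(split(v, block), modal_label, numeric(1))
  )
  out <- array(out, odim)
  if (inherits(vol, "labeled_volume")) storage.mode(out) <- "integer"
  if (inherits(vol, "mask_volume")) storage.mode(out) <- "integer"
  rewrap_volume(vol, out, vol$voxel_size * factor)
}

# modal positive label of a block; 0 only if the block is all background;
# ties break to the smallest label
modal_label <- function(v) {
  v <- v[v > 0L]
  if (length(v) == 0L) return(0)
  tb <- table(v)
  as.numeric(names(tb)[which.max(tb)])  # which.max: first max = smallest label
}
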