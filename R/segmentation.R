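#' Binarize a probability map
#'
#' A voxel is foreground iff its probability is greater than or equal to
#' `threshold` (so a voxel at exactly 0.5 is foreground under the default).
#'
#' @param prob a [probability_volume()].
#' @param threshold in `[0, 1]`; default 0.5.
#' @param structure_name tag for the resulting mask.
#' @return a [mask_volume()].
#' @export
threshold_probability <- function(prob, threshold = 0.5,
                                  structure_name = "other") {
  stopifnot(inherits(prob, "probability_volume"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop("threshold must be a single value in [0, 1]", call. = FALSE)
  }
  mask_volume(array(as.integer(prob$data >= threshold), dim(prob$data)),
              prob$voxel_size, structure_name)
}

#' Remove outlier voxels slice by slice
#'
#' Within each cross-section, a voxel whose value deviates from the median
#' of its disk neighborhood (radius `radius` pixels) by more than
#' `k_sd` times the slice's global standard deviation is replaced by that
#' median. On binary masks this removes isolated specks smaller than the
#' neighborhood scale while leaving bulk structures intact; on a uniform
#' volume it is the identity. Defaults sit inside the conventional
#' 3-10 px radius / 1.5-2 SD working range for EM mask cleanup.
#'
#' @param vol a [mask_volume()] or [probability_volume()].
#' @param radius neighborhood radius in pixels (>= 1).
#' @param k_sd deviation threshold in slice standard deviations (> 0).
#' @return volume of the same class.
#' @export
remove_outliers <- function(vol, radius = 3L, k_sd = 2) {
  stopifnot(inherits(vol, "mask_volume") ||
              inherits(vol, "probability_volume"))
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1", call. = FALSE)
  if (k_sd <= 0) stop("k_sd must be > 0", call. = FALSE)
  d <- vol$data
  nr <- dim(d)[2]; nc <- dim(d)[3]
  if (2L * radius + 1L > min(nr, nc)) {
    stop("radius larger than the slice extent", call. = FALSE)
  }
  off <- disk_offsets(radius, radius)
  out <- d
  for (z in seq_len(dim(d)[1])) {
    sl <- d[z, , ]
    sdv <- stats::sd(sl)
    if (!is.finite(sdv) || sdv == 0) next
    med <- neighborhood_median(sl, off)
    bad <- abs(sl - med) > k_sd * sdv
    if (any(bad)) {
      sl[bad] <- med[bad]
      out[z, , ] <- sl
    }
  }
  if (inherits(vol, "mask_volume")) storage.mode(out) <- "integer"
  rewrap_volume(vol, out)
}

# median over a disk neighborhood, edges clipped (median of available pixels)
neighborhood_median <- function(sl, off) {
  nr <- nrow(sl); nc <- ncol(sl)
  m <- matrix(NA_real_, nr * nc, nrow(off))
  for (k in seq_len(nrow(off))) {
    dr <- off[k, 1]; dc <- off[k, 2]
    sh <- matrix(NA_real_, nr, nc)
    r_src <- max(1L, 1L - dr):min(nr, nr - dr)
    c_src <- max(1L, 1L - dc):min(nc, nc - dc)
    sh[r_src + dr, c_src + dc] <- sl[r_src, c_src]
    m[, k] <- sh
  }
  matrix(matrixStats::rowMedians(m, na.rm = TRUE), nr, nc)
}

#' Assign voxels to structure classes by maximum probability
#'
#' Per-class probability exports can overlap after independent thresholding;
#' this resolves each voxel to its maximum-probability class (ties broken by
#' the priority order given, default contractile > mitochondria > srt), then
#' keeps the voxel only if the winning probability passes `threshold`. The
#' resulting masks are disjoint by construction, as [volume_fractions()]
#' requires.
#'
#' @param probs named list of [probability_volume()]s.
#' @param threshold winning-class probability cutoff (default 0.5).
#' @param priority tie-break order; defaults to `names(probs)`.
#' @return named list of disjoint [mask_volume()]s.
#' @export
classify_structures <- function(probs, threshold = 0.5,
                                priority = names(probs)) {
  stopifnot(is.list(probs), length(probs) >= 1L, !is.null(names(probs)))
  probs <- probs[priority]
  dims <- dim(probs[[1]]$data)
  best <- array(-Inf, dims); win <- array(0L, dims)
  for (i in seq_along(probs)) {
    p <- probs[[i]]$data
    upd <- p > best          # strict: earlier (higher-priority) class keeps ties
    best[upd] <- p[upd]
    win[upd] <- i
  }
  keep <- best >= threshold
  out <- lapply(seq_along(probs), function(i) {
    nm <- names(probs)[i]
    sn <- if (nm %in% c("contractile", "mitochondria", "srt", "cell")) nm
          else "other"
    mask_volume(array(as.integer(win == i & keep), dims),
                probs[[i]]$voxel_size, sn)
  })
  names(out) <- names(probs)
  out
}

#' Cellular volume-fraction composition
#'
#' Percent of the cell volume occupied by the contractile apparatus,
#' mitochondria, and the sarcotubular system, plus the unassigned remainder.
#' Structure masks must be disjoint (see [classify_structures()]).
#'
#' @param contractile,mitochondria,srt structure [mask_volume()]s.
#' @param cell cell [mask_volume()]; must be nonempty.
#' @return object of class `volume_fraction_report`: data.frame of voxel
#'   counts and percentages (summing to 100 exactly) plus `cell_voxels`.
#' @export
volume_fractions <- function(contractile, mitochondria, srt, cell) {
  vols <- list(contractile = contractile, mitochondria = mitochondria,
               srt = srt, cell = cell)
  for (v in vols) stopifnot(inherits(v, "mask_volume"))
  dims <- dim(cell$data)
  for (v in vols) {
    if (!identical(dim(v$data), dims)) {
      stop("all masks must share one grid", call. = FALSE)
    }
  }
  n_cell <- sum(cell$data)
  if (n_cell == 0L) stop("cell mask is empty", call. = FALSE)
  overlap <- sum(contractile$data + mitochondria$data + srt$data > 1L)
  if (overlap > 0L) {
    stop(overlap, " voxels are claimed by more than one structure mask; ",
         "resolve overlaps first (see classify_structures)", call. = FALSE)
  }
  counts <- c(
    contractile = sum(contractile$data & cell$data),
    mitochondria = sum(mitochondria$data & cell$data),
    srt = sum(srt$data & cell$data))
  pct <- 100 * counts / n_cell
  res <- list(
    table = data.frame(structure = c(names(counts), "other"),
                       voxels = c(counts, n_cell - sum(counts)),
                       percent = c(pct, 100 - sum(pct)),
                       row.names = NULL),
    cell_voxels = n_cell)
  class(res) <- "volume_fraction_report"
  res
}

#' @export
print.volume_fraction_report <- function(x, ...) {
  cat("<volume_fraction_report> cell voxels: ", x$cell_voxels, "\n", sep = "")
  with(x$table, cat(sprintf("  %-13s %6.1f%%\n", structure, percent),
                    sep = ""))
  invisible(x)
}
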