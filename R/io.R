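#' Read a volumetric image (multi-page TIFF stack or HDF5)
#'
#' Supported on-disk formats are uncompressed grayscale multi-page TIFF
#' (8/16/32-bit unsigned integer or 32-bit float, one page per cross-section)
#' and HDF5 (one 3D dataset per structure). Volumes written by
#' [write_volume()] round-trip exactly, including voxel-size metadata, which
#' is carried in the TIFF ImageDescription tag / HDF5 dataset attributes.
#'
#' The returned class is chosen from explicit metadata when present,
#' otherwise: integer data whose values are all 0/1 become a [mask_volume()],
#' other integer data a [labeled_volume()], and floating-point data a
#' [probability_volume()]. 8-bit files tagged (or declared via `type`) as
#' probabilities are rescaled linearly from 0..255 to 0..1.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"tiff_stack"` or `"hdf5"`.
#' @param voxel_size optional length-3 voxel size in nm `(d_long, d_row,
#'   d_col)`; overrides any metadata stored in the file. Defaults to stored
#'   metadata, or `c(10, 10, 10)` when the file carries none.
#' @param type `"auto"`, `"labels"`, `"mask"` or `"probability"`.
#' @param dataset HDF5 dataset name (default: first 3D dataset in the file).
#' @return A [labeled_volume()], [mask_volume()] or [probability_volume()].
#' @export
read_volume <- function(path, format = c("auto", "tiff_stack", "hdf5"),
                        voxel_size = NULL,
                        type = c("auto", "labels", "mask", "probability"),
                        dataset = NULL) {
  format <- match.arg(format)
  type <- match.arg(type)
  if (!file.exists(path)) {
    stop("cannot read volume: file not found: ", path, call. = FALSE)
  }
  if (format == "auto") format <- guess_format(path)
  parsed <- if (format == "hdf5") read_hdf5_volume(path, dataset)
            else read_tiff_stack(path)
  meta <- parsed$meta
  data <- parsed$data
  if (length(dim(data)) != 3L) {
    stop("input is not a 3D volume: ", path, call. = FALSE)
  }
  if (is.null(voxel_size)) {
    voxel_size <- if (!is.null(meta$voxel_size_nm)) meta$voxel_size_nm
                  else c(10, 10, 10)
  }
  if (type == "auto") {
    type <- if (!is.null(meta$type)) meta$type
    else if (is.double(data)) "probability"
    else if (all(data %in% c(0L, 1L))) "mask"
    else "labels"
  }
  switch(type,
    labels = {
      if (any(data < 0)) stop("negative labels in ", path, call. = FALSE)
      labeled_volume(data, voxel_size)
    },
    mask = mask_volume(data, voxel_size,
                       structure_name = meta$structure_name %||% "other"),
    probability = {
      if (is.integer(data)) data <- data / 255  # 8-bit probability convention
      probability_volume(data, voxel_size)
    })
}

#' Write a volume to disk
#'
#' Inverse of [read_volume()]: `read_volume(write_volume(v, p), p)`
#' reproduces data and metadata exactly. Labeled volumes are stored at the
#' smallest sufficient unsigned integer depth (8/16/32 bit), masks at 8 bit,
#' and probability volumes as 8-bit files with values quantized to the
#' nearest 1/255 (the convention of 8-bit probability exports).
#'
#' @param vol a `muscle_volume`.
#' @param path destination file.
#' @param format `"auto"` (by extension), `"tiff_stack"` or `"hdf5"`.
#' @param dataset HDF5 dataset name; defaults to `"labels"`, the mask's
#'   structure name (`"cell"`, `"srt"`, `"mito"`, `"contractile"`, `"other"`)
#'   or `"prob/probability"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "tiff_stack", "hdf5"),
                         dataset = NULL) {
  stopifnot(inherits(vol, "muscle_volume"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format == "hdf5") write_hdf5_volume(vol, path, dataset)
  else write_tiff_stack(vol, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("h5", "hdf5", "he5")) "hdf5"
  else if (ext %in% c("tif", "tiff")) "tiff_stack"
  else stop("cannot guess format from extension of ", path,
            " (use format=)", call. = FALSE)
}

volume_type_string <- function(vol) {
  if (inherits(vol, "labeled_volume")) "labels"
  else if (inherits(vol, "mask_volume")) "mask"
  else "probability"
}

# ---------------------------------------------------------------------------
# HDF5 backend (rhdf5)
# ---------------------------------------------------------------------------

h5_default_dataset <- function(vol) {
  if (inherits(vol, "labeled_volume")) return("labels")
  if (inherits(vol, "probability_volume")) return("prob/probability")
  switch(vol$structure_name,
         mitochondria = "mito",
         vol$structure_name)
}

write_hdf5_volume <- function(vol, path, dataset = NULL) {
  dataset <- dataset %||% h5_default_dataset(vol)
  if (!file.exists(path)) rhdf5::h5createFile(path)
  ls <- tryCatch(rhdf5::h5ls(path, recursive = TRUE)$name, error = function(e) character())
  if (dataset %in% ls || any(endsWith(paste0("/", ls), dataset))) {
    try(rhdf5::h5delete(path, dataset), silent = TRUE)
  }
  if (grepl("/", dataset)) {
    grp <- sub("/[^/]*$", "", dataset)
    if (!grp %in% rhdf5::h5ls(path)$name) {
      try(rhdf5::h5createGroup(path, grp), silent = TRUE)
    }
  }
  rhdf5::h5write(vol$data, path, dataset)
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  did <- rhdf5::H5Dopen(fid, dataset)
  on.exit(rhdf5::H5Dclose(did), add = TRUE, after = FALSE)
  rhdf5::h5writeAttribute(vol$voxel_size, did, "voxel_size_nm")
  rhdf5::h5writeAttribute(volume_type_string(vol), did, "myomatrix_type")
  if (inherits(vol, "mask_volume")) {
    rhdf5::h5writeAttribute(vol$structure_name, did, "structure_name")
  }
  invisible(path)
}

read_hdf5_volume <- function(path, dataset = NULL) {
  if (is.null(dataset)) {
    info <- rhdf5::h5ls(path)
    cand <- info[info$otype == "H5I_DATASET", ]
    ndim <- vapply(strsplit(cand$dim, " x "), length, integer(1))
    cand <- cand[ndim == 3L, ]
    if (nrow(cand) == 0L) {
      stop("no 3D dataset found in ", path, call. = FALSE)
    }
    dataset <- file.path(cand$group[1], cand$name[1])
    dataset <- sub("^/", "", gsub("^/+", "", dataset))
  }
  data <- rhdf5::h5read(path, dataset)
  attrs <- tryCatch(rhdf5::h5readAttributes(path, dataset),
                    error = function(e) list())
  data <- if (is.double(data) || is.integer(data)) data else {
    storage.mode(data) <- "integer"; data
  }
  if (is.double(data) && all(data == round(data)) && max(abs(data)) > 1) {
    # integer payload stored as float by a foreign writer
    storage.mode(data) <- "integer"
  }
  data <- array(data, dim(data))
  meta <- list(
    voxel_size_nm = as.numeric(attrs$voxel_size_nm) %||% NULL,
    type = as.character(attrs$myomatrix_type) %||% NULL,
    structure_name = as.character(attrs$structure_name) %||% NULL
  )
  if (length(meta$voxel_size_nm) != 3L) meta$voxel_size_nm <- NULL
  if (length(meta$type) != 1L) meta$type <- NULL
  if (length(meta$structure_name) != 1L) meta$structure_name <- NULL
  list(data = data, meta = meta)
}

# ---------------------------------------------------------------------------
# Minimal baseline TIFF backend (uncompressed grayscale, little-endian writer,
# endian-agnostic reader). No pre-installed R package reads TIFF in this
# stack, hence the self-contained implementation.
# ---------------------------------------------------------------------------

tiff_description <- function(vol) {
  paste0("myomatrix\nvoxel_size_nm=",
         paste(format(vol$voxel_size, digits = 12), collapse = ","),
         "\ntype=", volume_type_string(vol),
         if (inherits(vol, "mask_volume"))
           paste0("\nstructure=", vol$structure_name) else "",
         "\n")
}

u16le <- function(x) as.raw(c(x %% 256L, x %/% 256L))
u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

tiff_entry <- function(tag, type, count, value_raw4) {
  c(u16le(tag), u16le(type), u32le(count), value_raw4)
}

encode_pixels <- function(v, bits) {
  if (bits == 8L) return(as.raw(v))
  if (bits == 16L) {
    out <- raw(2L * length(v))
    out[seq(1L, length(out), 2L)] <- as.raw(v %% 256L)
    out[seq(2L, length(out), 2L)] <- as.raw(v %/% 256L)
    return(out)
  }
  # 32-bit unsigned
  v <- as.numeric(v)
  out <- raw(4L * length(v))
  out[seq(1L, length(out), 4L)] <- as.raw(v %% 256)
  out[seq(2L, length(out), 4L)] <- as.raw((v %/% 256) %% 256)
  out[seq(3L, length(out), 4L)] <- as.raw((v %/% 65536) %% 256)
  out[seq(4L, length(out), 4L)] <- as.raw((v %/% 16777216) %% 256)
  out
}

write_tiff_stack <- function(vol, path) {
  d <- vol$data
  nz <- dim(d)[1]; nr <- dim(d)[2]; nc <- dim(d)[3]
  if (inherits(vol, "probability_volume")) {
    pix <- round(d * 255)          # quantize to nearest 1/255
    bits <- 8L
  } else {
    pix <- d
    mx <- max(d)
    bits <- if (mx < 256) 8L else if (mx < 65536) 16L else 32L
  }
  desc <- charToRaw(tiff_description(vol))
  if (length(desc) %% 2L == 1L) desc <- c(desc, as.raw(0L))
  bytes_per_px <- bits / 8L
  strip_len <- nr * nc * bytes_per_px
  # layout: header(8) | description | page1 data | IFD1 | page2 data | IFD2 ...
  desc_off <- 8L
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  chunks <- vector("list", 2L + 2L * nz)
  chunks[[1]] <- c(charToRaw("II"), u16le(42L), u32le(8L + length(desc) +
                                                       strip_len))
  chunks[[2]] <- desc
  pos <- 8L + length(desc)
  for (z in seq_len(nz)) {
    sl <- pix[z, , , drop = TRUE]
    if (is.null(dim(sl))) sl <- matrix(sl, nr, nc)
    strip <- encode_pixels(as.vector(t(sl)), bits)  # row-major
    strip_off <- pos
    ifd_off <- pos + strip_len
    next_ifd <- if (z < nz) ifd_off + ifd_size + strip_len else 0
    entries <- c(
      tiff_entry(256L, 4L, 1L, u32le(nc)),               # ImageWidth
      tiff_entry(257L, 4L, 1L, u32le(nr)),               # ImageLength
      tiff_entry(258L, 3L, 1L, c(u16le(bits), u16le(0))),# BitsPerSample
      tiff_entry(259L, 3L, 1L, c(u16le(1L), u16le(0))),  # Compression: none
      tiff_entry(262L, 3L, 1L, c(u16le(1L), u16le(0))),  # Photometric
      tiff_entry(270L, 2L, length(desc), u32le(desc_off)), # Description
      tiff_entry(273L, 4L, 1L, u32le(strip_off)),        # StripOffsets
      tiff_entry(278L, 4L, 1L, u32le(nr)),               # RowsPerStrip
      tiff_entry(279L, 4L, 1L, u32le(strip_len)),        # StripByteCounts
      tiff_entry(339L, 3L, 1L, c(u16le(1L), u16le(0)))   # SampleFormat: uint
    )
    ifd <- c(u16le(n_entries), entries, u32le(next_ifd))
    chunks[[2L * z + 1L]] <- strip
    chunks[[2L * z + 2L]] <- ifd
    pos <- ifd_off + ifd_size
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(unlist(chunks), con)
  invisible(path)
}

# --- reader helpers operating on a raw vector --------------------------------

rd_u16 <- function(raw, off, le) {
  b <- as.integer(raw[off + 1:2])
  if (le) b[1] + 256L * b[2] else b[2] + 256L * b[1]
}
rd_u32 <- function(raw, off, le) {
  b <- as.numeric(raw[off + 1:4])
  if (le) b[1] + 256 * b[2] + 65536 * b[3] + 16777216 * b[4]
  else b[4] + 256 * b[3] + 65536 * b[2] + 16777216 * b[1]
}

read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file: ", path, call. = FALSE)
  magic <- rawToChar(raw[1:2])
  le <- magic == "II"
  if (!le && magic != "MM") stop("not a TIFF file: ", path, call. = FALSE)
  if (rd_u16(raw, 2L, le) != 42L) stop("not a TIFF file: ", path,
                                       call. = FALSE)
  ifd_off <- rd_u32(raw, 4L, le)
  pages <- list()
  desc <- NULL
  while (ifd_off != 0) {
    n <- rd_u16(raw, ifd_off, le)
    tags <- list()
    for (i in seq_len(n)) {
      eoff <- ifd_off + 2L + (i - 1L) * 12L
      tag <- rd_u16(raw, eoff, le)
      typ <- rd_u16(raw, eoff + 2L, le)
      cnt <- rd_u32(raw, eoff + 4L, le)
      tags[[as.character(tag)]] <- list(type = typ, count = cnt,
                                        voff = eoff + 8L)
    }
    gettag <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) return(default)
      tsize <- c(1L, 1L, 2L, 4L)[t$type]   # BYTE, ASCII, SHORT, LONG
      if (is.null(tsize) || is.na(tsize)) return(default)
      total <- tsize * t$count
      off <- if (total <= 4L) t$voff else rd_u32(raw, t$voff, le)
      if (t$type == 2L) return(rawToChar(raw[off + seq_len(t$count)][
        raw[off + seq_len(t$count)] != as.raw(0)]))
      vals <- numeric(t$count)
      for (k in seq_len(t$count)) {
        vals[k] <- if (t$type == 3L) rd_u16(raw, off + (k - 1L) * 2L, le)
                   else if (t$type == 4L) rd_u32(raw, off + (k - 1L) * 4L, le)
                   else as.integer(raw[off + k])
      }
      vals
    }
    width <- gettag(256L); height <- gettag(257L)
    bits <- gettag(258L, 8L)[1]
    compression <- gettag(259L, 1L)
    fmt <- gettag(339L, 1L)[1]
    if (is.null(width) || is.null(height)) {
      stop("malformed TIFF (missing dimensions): ", path, call. = FALSE)
    }
    if (compression != 1L) {
      stop("only uncompressed TIFF is supported: ", path, call. = FALSE)
    }
    if (is.null(desc)) desc <- gettag(270L)
    offs <- gettag(273L); cnts <- gettag(279L)
    strip_raw <- raw(sum(cnts))
    at <- 0L
    for (k in seq_along(offs)) {
      strip_raw[at + seq_len(cnts[k])] <- raw[offs[k] + seq_len(cnts[k])]
      at <- at + cnts[k]
    }
    npx <- width * height
    v <- decode_pixels(strip_raw, bits, fmt, npx, le)
    pages[[length(pages) + 1L]] <- matrix(v, nrow = height, ncol = width,
                                          byrow = TRUE)
    ifd_off <- rd_u32(raw, ifd_off + 2L + n * 12L, le)
  }
  if (length(pages) < 2L) {
    stop("2D-only TIFF input (", length(pages),
         " page); a volume needs >= 2 cross-sections: ", path, call. = FALSE)
  }
  nr <- nrow(pages[[1]]); nc <- ncol(pages[[1]])
  data <- array(if (is.double(pages[[1]])) 0 else 0L,
                c(length(pages), nr, nc))
  for (z in seq_along(pages)) data[z, , ] <- pages[[z]]
  list(data = data, meta = parse_tiff_description(desc))
}

decode_pixels <- function(strip, bits, fmt, npx, le) {
  if (bits == 8L) return(as.integer(strip[seq_len(npx)]))
  if (bits == 16L) {
    b <- matrix(as.integer(strip[seq_len(2L * npx)]), nrow = 2L)
    return(if (le) b[1, ] + 256L * b[2, ] else b[2, ] + 256L * b[1, ])
  }
  if (bits == 32L && fmt == 3L) {       # float32
    return(readBin(strip, "double", n = npx, size = 4L,
                   endian = if (le) "little" else "big"))
  }
  if (bits == 32L) {
    b <- matrix(as.numeric(strip[seq_len(4L * npx)]), nrow = 4L)
    v <- if (le) b[1, ] + 256 * b[2, ] + 65536 * b[3, ] + 16777216 * b[4, ]
         else b[4, ] + 256 * b[3, ] + 65536 * b[2, ] + 16777216 * b[1, ]
    return(as.integer(v))
  }
  stop("unsupported TIFF bit depth: ", bits, call. = FALSE)
}

parse_tiff_description <- function(desc) {
  meta <- list()
  if (is.null(desc) || !grepl("myomatrix", desc, fixed = TRUE)) return(meta)
  lines <- strsplit(desc, "\n", fixed = TRUE)[[1]]
  kv <- strsplit(lines[grepl("=", lines, fixed = TRUE)], "=", fixed = TRUE)
  for (p in kv) {
    key <- p[1]; val <- p[2]
    if (key == "voxel_size_nm") {
      meta$voxel_size_nm <- as.numeric(strsplit(val, ",")[[1]])
    } else if (key == "type") meta$type <- val
    else if (key == "structure") meta$structure_name <- val
  }
  meta
}
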