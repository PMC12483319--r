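# Volume I/O: MRC2014, HDF5 and TIFF with voxel-size bookkeeping.
#
# MRC is read/written directly (1024-byte header, modes 0/1/2/6); pixel
# spacing is stored in the header cell dimensions in Angstrom and converted
# to nm. HDF5 datasets carry a "voxel_size" attribute; TIFF has no portable
# volumetric spacing tag, so reading TIFF requires an explicit voxel size.

format_of <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    mrc = , rec = , st = "mrc",
    h5 = , hdf5 = , hdf = "hdf5",
    tif = , tiff = "tiff",
    abort(paste0("unsupported volume format: .", ext))
  )
}

#' Read a volume or label image
#'
#' Formats are inferred from the file extension: MRC2014 (`.mrc`, `.rec`),
#' HDF5 (`.h5`, `.hdf5`) and TIFF (`.tif`, `.tiff`). 3D data are returned in
#' (z, y, x) axis order with per-axis voxel sizes in nm. MRC voxel sizes come
#' from the header; HDF5 from a `voxel_size` dataset attribute when present.
#' When the file carries no voxel size (TIFF always, HDF5 without the
#' attribute), `voxel_size` must be supplied -- it is never defaulted.
#'
#' @param path File to read.
#' @param dataset_key HDF5 dataset name; defaults to `"raw"` (`"labels"` when
#'   `labels = TRUE`).
#' @param voxel_size Per-axis voxel size in nm, mandatory when the file
#'   carries none.
#' @param labels Read as an instance segmentation (`syn_labels`)?
#' @return A [new_volume()] or [new_labels()] object.
#' @export
read_volume <- function(path, dataset_key = NULL, voxel_size = NULL,
                        labels = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  fmt <- format_of(path)
  res <- switch(fmt,
    mrc = read_mrc(path),
    hdf5 = read_h5(path, dataset_key %||% if (labels) "labels" else "raw"),
    tiff = read_tiff(path, labels)
  )
  vs <- res$voxel_size %||% voxel_size
  if (is.null(vs)) {
    abort(paste0(
      "no voxel size stored in ", basename(path),
      "; supply voxel_size= explicitly (nm)"))
  }
  if (labels) {
    arr <- res$data
    storage.mode(arr) <- "integer"
    new_labels(arr, vs)
  } else {
    new_volume(res$data, vs, provenance = basename(path))
  }
}

#' Write a volume or label image
#'
#' The on-disk file round-trips through [read_volume()] with equal data
#' (bit-exact for integer labels) and voxel size. Integer data are stored in
#' integer sample formats where the format allows.
#'
#' @param vol A `syn_volume` or `syn_labels`.
#' @param path Destination; format inferred from the extension.
#' @param dataset_key HDF5 dataset name (default `"raw"`/`"labels"`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, dataset_key = NULL) {
  if (!dir.exists(dirname(path))) {
    abort(paste0("directory does not exist: ", dirname(path)))
  }
  is_lab <- inherits(vol, "syn_labels")
  if (!is_lab && !inherits(vol, "syn_volume")) {
    abort("expected a syn_volume or syn_labels")
  }
  fmt <- format_of(path)
  switch(fmt,
    mrc = write_mrc(vol, path),
    hdf5 = write_h5(vol, path,
                    dataset_key %||% if (is_lab) "labels" else "raw"),
    tiff = write_tiff(vol, path)
  )
  invisible(path)
}

# ---- MRC2014 ----------------------------------------------------------------

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]; mode <- ints[4]
  mx <- ints[8]; my <- ints[9]; mz <- ints[10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  if (any(is.na(c(nx, ny, nz))) || nx <= 0 || ny <= 0 || nz <= 0) {
    abort(paste0("unreadable MRC header in ", basename(path)))
  }
  seek(con, 1024)
  n <- as.double(nx) * ny * nz
  vals <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2, signed = FALSE,
                  endian = "little"),
    abort(paste0("unsupported MRC mode ", mode))
  )
  if (length(vals) < n) abort(paste0("truncated MRC data in ", basename(path)))
  # file order is x fastest; convert to internal (z, y, x)
  arr <- array(vals, c(nx, ny, nz))
  if (nz == 1L) {
    arr <- t(arr[, , 1])          # (y, x)
    px <- c(cella[2] / my, cella[1] / mx) / 10
  } else {
    arr <- aperm(arr, c(3, 2, 1)) # (z, y, x)
    px <- c(cella[3] / mz, cella[2] / my, cella[1] / mx) / 10
  }
  vs <- if (all(is.finite(px)) && all(px > 0)) px else NULL
  list(data = arr, voxel_size = vs)
}

write_mrc <- function(vol, path) {
  is_lab <- inherits(vol, "syn_labels")
  arr <- if (is_lab) vol$labels else vol$data
  nd <- length(dim(arr))
  if (nd == 2L) {
    a3 <- array(t(arr), c(ncol(arr), nrow(arr), 1L)) # (x, y, 1)
    vs3 <- c(vol$voxel_size[2], vol$voxel_size[1], mean(vol$voxel_size))
  } else {
    a3 <- aperm(arr, c(3, 2, 1))                     # (x, y, z)
    vs3 <- vol$voxel_size[c(3, 2, 1)]
  }
  dms <- dim(a3)
  mode <- 2L
  if (is_lab || is.integer(arr)) {
    rng <- range(arr)
    mode <- if (rng[1] >= -32768 && rng[2] <= 32767) 1L else 2L
    if (mode == 2L && rng[2] >= 2^24) {
      abort("label ids too large for exact MRC storage; use HDF5")
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(dms, mode, 0L, 0L, 0L, dms)), con, size = 4,
           endian = "little")
  writeBin(c(dms * vs3 * 10, 90, 90, 90), con, size = 4, endian = "little")
  writeBin(c(1L, 2L, 3L), con, size = 4, endian = "little")
  vals <- as.numeric(a3)
  writeBin(c(min(vals), max(vals), mean(vals)), con, size = 4,
           endian = "little")
  writeBin(c(1L, 0L), con, size = 4, endian = "little")         # ispg, nsymbt
  writeBin(raw(100), con)                                       # extra
  writeBin(c(0, 0, 0), con, size = 4, endian = "little")        # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)              # little endian
  writeBin(stats::sd(vals), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")                # nlabl
  writeBin(raw(800), con)                                       # labels
  if (mode == 1L) {
    writeBin(as.integer(a3), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(a3), con, size = 4, endian = "little")
  }
  invisible(path)
}

# ---- HDF5 -------------------------------------------------------------------

read_h5 <- function(path, key) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  names_in_file <- paste0(sub("^/$", "", contents$group), "/", contents$name)
  if (!paste0("/", key) %in% c(names_in_file, paste0("/", contents$name))) {
    if (!key %in% contents$name) {
      abort(paste0("dataset '", key, "' not found in ", basename(path)))
    }
  }
  arr <- rhdf5::h5read(path, key)
  att <- tryCatch(rhdf5::h5readAttributes(path, key), error = function(e) list())
  vs <- att$voxel_size
  list(data = arr, voxel_size = if (!is.null(vs)) as.numeric(vs) else NULL)
}

write_h5 <- function(vol, path, key) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  is_lab <- inherits(vol, "syn_labels")
  arr <- if (is_lab) vol$labels else vol$data
  if (!file.exists(path)) rhdf5::h5createFile(path)
  if (key %in% rhdf5::h5ls(path)$name) {
    rhdf5::h5delete(path, key)
  }
  rhdf5::h5write(arr, path, key)
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, key)
  rhdf5::h5writeAttribute(vol$voxel_size, did, "voxel_size")
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

# ---- TIFF -------------------------------------------------------------------

read_tiff <- function(path, labels) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = labels)
  if (!is.list(frames)) frames <- list(frames)
  if (length(frames) == 1L) {
    arr <- frames[[1]]
  } else {
    arr <- array(0, c(length(frames), dim(frames[[1]])))
    for (k in seq_along(frames)) arr[k, , ] <- frames[[k]]
  }
  list(data = arr, voxel_size = NULL)
}

write_tiff <- function(vol, path) {
  is_lab <- inherits(vol, "syn_labels")
  arr <- if (is_lab) vol$labels else vol$data
  nd <- length(dim(arr))
  if (is_lab) {
    if (max(arr) > 65535L) abort("label ids exceed 16-bit TIFF range; use HDF5")
    prep <- function(m) m / 65535
    bits <- 16L
  } else {
    if (min(arr) < 0 || max(arr) > 1) {
      abort(paste0(
        "TIFF float samples only represent values in [0, 1]; ",
        "rescale the data or use MRC/HDF5"))
    }
    prep <- function(m) m
    bits <- 32L
  }
  if (nd == 2L) {
    tiff::writeTIFF(prep(arr), path, bits.per.sample = bits)
  } else {
    slices <- lapply(seq_len(dim(arr)[1]), function(k) prep(arr[k, , ]))
    tiff::writeTIFF(slices, path, bits.per.sample = bits)
  }
  invisible(path)
}
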