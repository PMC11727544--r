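# Tractogram I/O: TRK (TrackVis) and TCK (MRtrix) dialects, NIfTI masks and
# grids, and two-column label sidecars.
#
# TRK stores points in "voxmm" coordinates with the origin at the corner of
# voxel (0,0,0): voxel = p / voxel_size - 0.5. The in-memory model is always
# world mm, so that corner-origin quirk is normalised here at read time and
# re-applied at write time; TCK stores world (scanner) mm directly.

trk_fmt_error <- function(path, offset, why) {
  abort(sprintf("TRK format error in '%s' at byte offset %d: %s",
                path, offset, why))
}

#' Read a tractogram from TRK or TCK
#'
#' Streamline coordinates are returned in world mm, consistent with the
#' file's header affine; ids are assigned in file order. For TRK the voxmm
#' corner-origin convention is converted to world mm via the stored
#' `vox_to_ras` matrix. A label sidecar (`<path>.labels.csv`) is attached
#' when present.
#'
#' @param path Path to a `.trk` or `.tck` file.
#' @param format `"trk"`, `"tck"`, or `"auto"` (from the file extension).
#' @return A [tractogram()].
#' @export
read_tractogram <- function(path, format = c("auto", "trk", "tck")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("trk", "tck")) {
      abort(sprintf("cannot infer tractogram format from '%s'", path))
    }
  }
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  t <- switch(format, trk = read_trk(path), tck = read_tck(path))
  sidecar <- paste0(path, ".labels.csv")
  if (file.exists(sidecar)) t$labels <- normalize_labels(read_labels(sidecar), n_streamlines(t))
  t
}

#' Write a tractogram to TRK or TCK
#'
#' @param t A [tractogram()].
#' @param path Output path (`.trk` or `.tck`).
#' @param format `"trk"`, `"tck"`, or `"auto"` (from the file extension).
#' @param labels Write a `<path>.labels.csv` sidecar when the tractogram
#'   carries labels (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(t, path, format = c("auto", "trk", "tck"),
                             labels = TRUE) {
  stopifnot(inherits(t, "tractogram"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("trk", "tck")) {
      abort(sprintf("cannot infer tractogram format from '%s'", path))
    }
  }
  switch(format, trk = write_trk(t, path), tck = write_tck(t, path))
  if (labels && !is.null(t$labels)) {
    write_labels(tract_labels(t), paste0(path, ".labels.csv"))
  }
  invisible(path)
}

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 1000L)
  if (length(hdr) < 1000L) trk_fmt_error(path, length(hdr), "truncated header")
  magic <- rawToChar(hdr[1:5])
  if (magic != "TRACK") trk_fmt_error(path, 0L, "missing TRACK magic")
  rd_i16 <- function(off, n) readBin(hdr[(off + 1):(off + 2 * n)], "integer", n, size = 2, endian = "little")
  rd_f32 <- function(off, n) readBin(hdr[(off + 1):(off + 4 * n)], "double", n, size = 4, endian = "little")
  rd_i32 <- function(off, n) readBin(hdr[(off + 1):(off + 4 * n)], "integer", n, size = 4, endian = "little")
  dims <- rd_i16(6L, 3L)
  voxel_size <- rd_f32(12L, 3L)
  n_scalars <- rd_i16(36L, 1L)
  n_properties <- rd_i16(238L, 1L)
  vox_to_ras <- matrix(rd_f32(440L, 16L), 4, 4, byrow = TRUE)
  n_count <- rd_i32(988L, 1L)
  hdr_size <- rd_i32(996L, 1L)
  if (hdr_size != 1000L) trk_fmt_error(path, 996L, sprintf("hdr_size %d != 1000", hdr_size))
  if (any(voxel_size <= 0)) trk_fmt_error(path, 12L, "non-positive voxel size")
  if (all(vox_to_ras == 0)) {
    # TRK v1 files leave vox_to_ras zeroed; fall back to a scaled identity.
    vox_to_ras <- diag(c(voxel_size, 1))
  }
  grid <- ref_grid(pmax(dims, 1L), vox_to_ras)
  streamlines <- vector("list", max(n_count, 0L))
  i <- 0L
  offset <- 1000L
  repeat {
    npt_raw <- readBin(con, "integer", 1L, size = 4, endian = "little")
    if (length(npt_raw) == 0L) break
    if (npt_raw < 2L) trk_fmt_error(path, offset, sprintf("streamline with %d point(s)", npt_raw))
    need <- npt_raw * (3L + n_scalars)
    vals <- readBin(con, "double", need, size = 4, endian = "little")
    if (length(vals) < need) trk_fmt_error(path, offset + 4L, "truncated streamline body")
    if (n_properties > 0) {
      pr <- readBin(con, "double", n_properties, size = 4, endian = "little")
      if (length(pr) < n_properties) trk_fmt_error(path, offset, "truncated properties")
    }
    pm <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    # voxmm -> 0-based voxel -> world
    vox <- sweep(pm, 2, voxel_size, "/") - 0.5
    i <- i + 1L
    if (i > length(streamlines)) streamlines <- c(streamlines, vector("list", 64L))
    streamlines[[i]] <- voxel_to_world(grid, vox)
    offset <- offset + 4L + 4L * need + 4L * n_properties
  }
  if (n_count > 0L && i != n_count) {
    trk_fmt_error(path, offset, sprintf("header promises %d streamlines, found %d", n_count, i))
  }
  tractogram(streamlines[seq_len(i)], grid, validate = FALSE)
}

write_trk <- function(t, path) {
  voxel_size <- grid_voxel_size(t$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- raw(1000L)
  put <- function(h, off, bytes) { h[(off + 1):(off + length(bytes))] <- bytes; h }
  w_i16 <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "little")
  w_i32 <- function(v) writeBin(as.integer(v), raw(), size = 4, endian = "little")
  w_f32 <- function(v) writeBin(as.numeric(v), raw(), size = 4, endian = "little")
  hdr <- put(hdr, 0L, c(charToRaw("TRACK"), as.raw(0)))
  hdr <- put(hdr, 6L, w_i16(t$grid$dims))
  hdr <- put(hdr, 12L, w_f32(voxel_size))
  hdr <- put(hdr, 24L, w_f32(c(0, 0, 0)))       # origin (unused by readers)
  hdr <- put(hdr, 36L, w_i16(0L))               # n_scalars
  hdr <- put(hdr, 238L, w_i16(0L))              # n_properties
  hdr <- put(hdr, 440L, w_f32(as.numeric(t(t$grid$affine))))
  hdr <- put(hdr, 948L, c(charToRaw("RAS"), as.raw(0)))
  hdr <- put(hdr, 988L, w_i32(n_streamlines(t)))
  hdr <- put(hdr, 992L, w_i32(2L))              # version
  hdr <- put(hdr, 996L, w_i32(1000L))
  writeBin(hdr, con)
  for (s in t$streamlines) {
    vox <- world_to_voxel(t$grid, s)
    pm <- sweep(vox + 0.5, 2, voxel_size, "*")
    writeBin(as.integer(nrow(pm)), con, size = 4, endian = "little")
    writeBin(as.numeric(t(pm)), con, size = 4, endian = "little")
  }
  invisible(path)
}

read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!identical(first, "mrtrix tracks")) {
    abort(sprintf("TCK format error in '%s' at byte offset 0: missing 'mrtrix tracks' magic", path))
  }
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) abort(sprintf("TCK format error in '%s': header not terminated by END", path))
    if (identical(line, "END")) break
    kv <- sub(":.*$", "", line)
    fields[[kv]] <- trimws(sub("^[^:]*:", "", line))
  }
  if (is.null(fields$file)) abort(sprintf("TCK format error in '%s': missing 'file' field", path))
  dtype <- fields$datatype %||% "Float32LE"
  if (!dtype %in% c("Float32LE", "Float32BE")) {
    abort(sprintf("TCK format error in '%s': unsupported datatype %s", path, dtype))
  }
  endian <- if (dtype == "Float32LE") "little" else "big"
  data_offset <- as.integer(sub("^\\. ", "", fields$file))
  seek(con, data_offset)
  vals <- readBin(con, "double", n = file.size(path), size = 4, endian = endian)
  if (length(vals) %% 3 != 0) {
    abort(sprintf("TCK format error in '%s' at byte offset %d: body not a whole number of triples",
                  path, data_offset + 4 * length(vals)))
  }
  pm <- matrix(vals, ncol = 3, byrow = TRUE)
  is_nan <- rowSums(is.nan(pm)) > 0
  is_inf <- is.infinite(pm[, 1])
  term <- which(is_inf)
  if (length(term) == 0L) {
    abort(sprintf("TCK format error in '%s': missing Inf terminator", path))
  }
  pm <- pm[seq_len(term[1] - 1L), , drop = FALSE]
  is_nan <- is_nan[seq_len(term[1] - 1L)]
  breaks <- c(0L, which(is_nan), nrow(pm) + 1L)
  streamlines <- list()
  for (b in seq_len(length(breaks) - 1L)) {
    if (breaks[b + 1L] - breaks[b] <= 1L) next
    rows <- seq.int(breaks[b] + 1L, breaks[b + 1L] - 1L)
    if (length(rows) < 2L) {
      abort(sprintf("TCK format error in '%s' at byte offset %d: streamline with %d point(s)",
                    path, data_offset + 12L * (breaks[b]), length(rows)))
    }
    streamlines[[length(streamlines) + 1L]] <- pm[rows, , drop = FALSE]
  }
  grid_sidecar <- paste0(path, ".grid.nii.gz")
  grid <- if (file.exists(grid_sidecar)) {
    mask_grid(read_mask(grid_sidecar))
  } else {
    default_tck_grid(streamlines)
  }
  tractogram(streamlines, grid, validate = FALSE)
}

# TCK carries no voxel grid; when no grid sidecar exists, synthesize a 1 mm
# grid whose extents cover the streamlines.
default_tck_grid <- function(streamlines) {
  if (!length(streamlines)) return(ref_grid(c(1L, 1L, 1L)))
  pts <- do.call(rbind, streamlines)
  lo <- floor(apply(pts, 2, min)) - 2
  hi <- ceiling(apply(pts, 2, max)) + 2
  aff <- diag(4)
  aff[1:3, 4] <- lo
  ref_grid(hi - lo + 1, aff)
}

write_tck <- function(t, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_lines <- c("mrtrix tracks", "datatype: Float32LE",
                 sprintf("count: %d", n_streamlines(t)))
  # the 'file' field records the byte offset of the binary body; pad to a
  # fixed-width offset so it can be written before the body
  probe <- paste0(paste(hdr_lines, collapse = "\n"), "\nfile: . ", "XXXXXX", "\nEND\n")
  offset <- nchar(probe, type = "bytes")
  hdr <- paste0(paste(hdr_lines, collapse = "\n"),
                "\nfile: . ", formatC(offset, width = 6, flag = "0"), "\nEND\n")
  writeChar(hdr, con, eos = NULL)
  sep <- rep(NaN, 3)
  for (s in t$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4, endian = "little")
    writeBin(as.numeric(sep), con, size = 4, endian = "little")
  }
  writeBin(as.numeric(rep(Inf, 3)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read and write per-streamline label sidecars
#'
#' Labels travel as a two-column CSV (`id`, `label`).
#'
#' @param path CSV path.
#' @return `read_labels()`: a tibble with columns `id` (integer) and `label`.
#' @export
read_labels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(df))) {
    abort(sprintf("'%s' must have columns id,label", path))
  }
  tibble(id = as.integer(df$id), label = as.character(df$label))
}

#' @rdname read_labels
#' @param labels A data frame with columns `id` and `label`.
#' @export
write_labels <- function(labels, path) {
  write.csv(labels[c("id", "label")], path, row.names = FALSE)
  invisible(path)
}

#' Binary mask on a reference grid
#'
#' @param grid A [ref_grid()].
#' @param array Logical array with dimensions `grid$dims` (flagged voxels).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(grid, array) {
  stopifnot(inherits(grid, "ref_grid"))
  if (!identical(dim(array), as.integer(grid$dims))) {
    abort("mask array dimensions must match the grid")
  }
  storage.mode(array) <- "logical"
  structure(list(grid = grid, array = array), class = "binary_mask")
}

mask_grid <- function(mask) mask$grid

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", sum(x$array), " / ", prod(x$grid$dims),
      " voxels flagged\n", sep = "")
  invisible(x)
}

#' Read and write binary masks as NIfTI
#'
#' Nonzero voxels are flagged; the NIfTI sform (or qform) provides the grid
#' affine.
#'
#' @param path NIfTI path (`.nii` / `.nii.gz`).
#' @return `read_mask()`: a [binary_mask()].
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  arr <- array(as.array(img) != 0, dim = dim(img)[1:3])
  binary_mask(ref_grid(dim(img)[1:3], matrix(as.numeric(aff), 4, 4)), arr)
}

#' @rdname read_mask
#' @param mask A [binary_mask()].
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$array), dim = mask$grid$dims))
  RNifti::qform(img) <- structure(mask$grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
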