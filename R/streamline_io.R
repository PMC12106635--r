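#' Streamline file I/O: TCK and TRK
#'
#' TCK stores world-mm float32 triplets after a text header, with NaN
#' triplets separating streamlines and an Inf triplet terminating the file.
#' TRK (TrackVis) stores a fixed 1000-byte binary header and per-streamline
#' point counts; its coordinates live in "voxmm" space (voxel index times
#' voxel size, with the centre of voxel 0 at half a voxel), which is
#' converted to/from world mm through the header's voxel-to-RAS matrix.
#'
#' @name streamline-io
NULL

#' Write a bundle as TCK
#'
#' @param bundle a `streamline_bundle` (world-mm coordinates).
#' @param path output path.
#' @export
write_tck <- function(bundle, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  count <- length(bundle$streamlines)
  header <- paste0("mrtrix tracks\n",
                   "datatype: Float32LE\n",
                   "count: ", count, "\n")
  # offset points at the first binary byte; pad header so the offset is stable
  offset_line <- function(off) paste0("file: . ", off, "\nEND\n")
  off <- nchar(header, type = "bytes") +
    nchar(offset_line(100000), type = "bytes")
  header <- paste0(header, offset_line(off))
  pad <- off - nchar(header, type = "bytes")
  header <- paste0(header, strrep(" ", pad))
  writeChar(header, con, eos = NULL)
  for (s in bundle$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a TCK tractogram
#'
#' @param path TCK file path.
#' @param name bundle name (default: file base name).
#' @return a `streamline_bundle` in world mm.
#' @export
read_tck <- function(path, name = sub("\\.tck$", "", basename(path))) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  # header is ASCII up to the END keyword; locate the data offset
  hdr_end <- grepRaw("END\n", raw_all, fixed = TRUE)
  if (!length(hdr_end)) stop("TCK header lacks END", call. = FALSE)
  header_txt <- rawToChar(raw_all[seq_len(hdr_end + 3L)])
  if (!startsWith(header_txt, "mrtrix tracks")) {
    stop("not a TCK file", call. = FALSE)
  }
  m <- regmatches(header_txt, regexpr("file: \\. [0-9]+", header_txt))
  if (!length(m)) stop("TCK header lacks a file offset", call. = FALSE)
  off <- as.integer(sub("file: \\. ", "", m))
  dt <- regmatches(header_txt, regexpr("datatype: [A-Za-z0-9]+", header_txt))
  endian <- if (length(dt) && grepl("BE$", dt)) "big" else "little"
  vals <- readBin(raw_all[(off + 1):length(raw_all)], "numeric",
                  n = (length(raw_all) - off) / 4, size = 4, endian = endian)
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  is_sep <- apply(pts, 1, function(r) any(is.nan(r)))
  is_end <- apply(pts, 1, function(r) any(is.infinite(r)))
  stop_at <- which(is_end)[1]
  if (!is.na(stop_at)) pts <- pts[seq_len(stop_at - 1), , drop = FALSE]
  is_sep <- is_sep[seq_len(nrow(pts))]
  grp <- cumsum(c(TRUE, is_sep[-length(is_sep)]))
  keep <- !is_sep
  streamlines <- lapply(split(which(keep), grp[keep]), function(ix) {
    pts[ix, , drop = FALSE]
  })
  streamline_bundle(unname(streamlines), name)
}

#' Write a bundle as TRK (TrackVis)
#'
#' @param bundle a `streamline_bundle` (world-mm coordinates).
#' @param path output path.
#' @param dim reference grid dimensions (voxels).
#' @param voxel_mm voxel size in mm.
#' @param affine voxel-to-world (RAS) matrix; world points are converted to
#'   the TRK voxmm convention through its inverse.
#' @export
write_trk <- function(bundle, path, dim, voxel_mm,
                      affine = default_affine(voxel_mm)) {
  voxel_mm <- rep(voxel_mm, length.out = 3)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, eos = NULL)
  writeBin(raw(1), con)
  writeBin(as.integer(dim), con, size = 2, endian = "little")
  writeBin(as.numeric(voxel_mm), con, size = 4, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")      # origin
  writeBin(0L, con, size = 2, endian = "little")              # n_scalars
  writeBin(raw(200), con)                                     # scalar names
  writeBin(0L, con, size = 2, endian = "little")              # n_properties
  writeBin(raw(200), con)                                     # property names
  writeBin(as.numeric(t(affine)), con, size = 4, endian = "little")
  writeBin(raw(444), con)                                     # reserved
  writeChar("RAS", con, eos = NULL); writeBin(raw(1), con)    # voxel_order
  writeBin(raw(4), con)                                       # pad2
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4, endian = "little")
  writeBin(raw(2), con)                                       # pad1
  writeBin(raw(6), con)                                       # invert/swap
  writeBin(length(bundle$streamlines), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")              # version
  writeBin(1000L, con, size = 4, endian = "little")           # hdr_size
  inv <- solve(affine)
  for (s in bundle$streamlines) {
    vox <- cbind(s, 1) %*% t(inv)                # 0-based voxel coords
    voxmm <- sweep(vox[, 1:3, drop = FALSE] + 0.5, 2, voxel_mm, `*`)
    writeBin(nrow(s), con, size = 4, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a TRK tractogram
#'
#' @param path TRK file path.
#' @param name bundle name (default: file base name).
#' @return a `streamline_bundle` in world mm (converted through the
#'   header's voxel-to-RAS matrix; identity with a warning when absent).
#' @export
read_trk <- function(path, name = sub("\\.trk$", "", basename(path))) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 5, useBytes = TRUE)
  if (!identical(magic, "TRACK")) stop("not a TRK file", call. = FALSE)
  readBin(con, "raw", 1)
  invisible(readBin(con, "integer", 3, size = 2, endian = "little"))
  voxel_mm <- readBin(con, "numeric", 3, size = 4, endian = "little")
  invisible(readBin(con, "numeric", 3, size = 4, endian = "little"))
  n_scalars <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "raw", 200)
  n_props <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "raw", 200)
  vox2ras <- matrix(readBin(con, "numeric", 16, size = 4, endian = "little"),
                    4, 4, byrow = TRUE)
  readBin(con, "raw", 444)
  readBin(con, "raw", 4)  # voxel_order
  readBin(con, "raw", 4 + 24 + 2 + 6)
  n_count <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 2, size = 4, endian = "little")  # version, hdr_size
  if (all(vox2ras == 0)) {
    warning("TRK header lacks a voxel-to-RAS matrix; assuming identity")
    vox2ras <- default_affine(voxel_mm)
  }
  streamlines <- list()
  repeat {
    npts <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(npts) == 0) break
    vals <- readBin(con, "numeric", npts * (3 + n_scalars), size = 4,
                    endian = "little")
    if (n_props > 0) readBin(con, "numeric", n_props, size = 4,
                             endian = "little")
    pm <- matrix(vals, ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(pm, 2, voxel_mm, `/`) - 0.5
    world <- cbind(vox, 1) %*% t(vox2ras)
    streamlines[[length(streamlines) + 1]] <- world[, 1:3, drop = FALSE]
    if (n_count > 0 && length(streamlines) >= n_count) break
  }
  streamline_bundle(streamlines, name)
}
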