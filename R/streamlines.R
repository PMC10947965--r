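#' Streamline sets
#'
#' A tractogram is stored as a list of polylines, each an n x 3 numeric
#' matrix of points in world RAS millimetres (n >= 2). Both supported file
#' dialects are normalised to this one convention on read: TCK stores world
#' mm natively; TRK stores voxel-mm with a half-voxel offset and a stored
#' voxel-to-world transform, which is applied on read and inverted on write.
#'
#' @param streamlines List of numeric matrices, each n x 3 with n >= 2.
#' @param space Declared coordinate space tag; only `"world_mm"` is used by
#'   the package.
#' @return An object of class `uwmc_streamlines`.
#' @export
streamline_set <- function(streamlines, space = "world_mm") {
  streamlines <- lapply(streamlines, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 3L || nrow(p) < 2L)
      abort("each streamline must be an n x 3 matrix with n >= 2")
    if (!all(is.finite(p))) abort("streamline coordinates must be finite")
    storage.mode(p) <- "double"
    dimnames(p) <- NULL
    p
  })
  structure(list(streamlines = streamlines, space = space),
            class = "uwmc_streamlines")
}

#' @export
print.uwmc_streamlines <- function(x, ...) {
  cat(sprintf("<uwmc_streamlines> %d streamlines (%s)\n",
              length(x$streamlines), x$space))
  invisible(x)
}

#' @export
length.uwmc_streamlines <- function(x) length(x$streamlines)

#' Read a tractogram (TCK or TRK) into world millimetres
#'
#' The dialect is chosen by file magic, not extension. Unknown datatypes or
#' an absent/invalid stored transform (TRK version 1 files) raise an error;
#' the reader never guesses a coordinate space.
#'
#' @param path Path to a `.tck` or `.trk` file.
#' @return An `uwmc_streamlines` object in world mm.
#' @export
read_streamlines <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 20L)
  close(con); on.exit()
  if (identical(magic[1:13], charToRaw("mrtrix tracks")))
    return(read_tck(path))
  if (identical(magic[1:5], charToRaw("TRACK")))
    return(read_trk(path))
  abort("unrecognised tractogram format (expected TCK or TRK magic)")
}

read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw_head <- readBin(con, "raw", min(file.size(path), 65536L))
  end_at <- grepRaw("\nEND\n", raw_head, fixed = TRUE)
  if (!length(end_at)) abort("TCK header has no END line")
  txt <- rawToChar(raw_head[seq_len(end_at - 1L)])
  header <- strsplit(txt, "\n")[[1]][-1]
  kv <- strsplit(header, ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ": "), "")
  dt <- vals[keys == "datatype"]
  if (!length(dt) || dt != "Float32LE")
    abort(paste0("unsupported TCK datatype: ", if (length(dt)) dt else "<missing>"))
  filef <- vals[keys == "file"]
  if (!length(filef)) abort("TCK header missing 'file' field")
  offset <- as.integer(sub("^\\. ", "", filef))
  seek(con, offset)
  n_float <- (file.size(path) - offset) / 4
  v <- readBin(con, "numeric", n_float, size = 4L, endian = "little")
  pts <- matrix(v, ncol = 3, byrow = TRUE)
  streamlines <- list()
  start <- 1L
  for (i in seq_len(nrow(pts))) {
    if (is.nan(pts[i, 1]) || is.infinite(pts[i, 1])) {
      if (i > start)
        streamlines[[length(streamlines) + 1L]] <- pts[start:(i - 1L), , drop = FALSE]
      start <- i + 1L
      if (is.infinite(pts[i, 1])) break
    }
  }
  streamline_set(streamlines)
}

write_tck <- function(set, path) {
  n <- length(set$streamlines)
  body_header <- function(offset) {
    sprintf("mrtrix tracks\ndatatype: Float32LE\ncount: %d\nfile: . %d\nEND\n", n, offset)
  }
  offset <- nchar(body_header(0L))
  while (nchar(body_header(offset)) != offset) offset <- nchar(body_header(offset))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(body_header(offset), con, eos = NULL)
  for (p in set$streamlines) {
    writeBin(as.numeric(t(p)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(what, n, size) readBin(con, what, n, size = size, endian = "little")
  id <- rawToChar(readBin(con, "raw", 6L)[1:5])
  if (id != "TRACK") abort("not a TRK file")
  invisible(rd("integer", 3L, 2L))                    # dim
  voxel_size <- rd("numeric", 3L, 4L)
  invisible(rd("numeric", 3L, 4L))                    # origin (unused per spec)
  n_scalars <- rd("integer", 1L, 2L)
  invisible(readBin(con, "raw", 200L))
  n_props <- rd("integer", 1L, 2L)
  invisible(readBin(con, "raw", 200L))
  vox2ras <- matrix(rd("numeric", 16L, 4L), 4, 4, byrow = TRUE)
  invisible(readBin(con, "raw", 444L + 4L + 4L))      # reserved, voxel_order, pad2
  invisible(rd("numeric", 6L, 4L))                    # image_orientation_patient
  invisible(readBin(con, "raw", 2L + 6L))             # pad1, inversion/swap flags
  n_count <- rd("integer", 1L, 4L)
  version <- rd("integer", 1L, 4L)
  hdr_size <- rd("integer", 1L, 4L)
  if (!identical(hdr_size, 1000L))
    abort("TRK header size is not 1000; unsupported dialect or endianness")
  if (version < 2L || vox2ras[4, 4] == 0)
    abort("TRK file stores no voxel-to-world transform; cannot determine space")
  if (any(voxel_size <= 0)) abort("TRK voxel sizes must be positive")
  streamlines <- list()
  repeat {
    np <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (!length(np)) break
    vals <- rd("numeric", np * (3L + n_scalars), 4L)
    if (n_props > 0) invisible(rd("numeric", n_props, 4L))
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    # TRK voxel-mm -> voxel (center-based) -> world RAS
    v <- sweep(m, 2, voxel_size, "/") - 0.5
    w <- cbind(v, 1) %*% t(vox2ras)
    streamlines[[length(streamlines) + 1L]] <- w[, 1:3, drop = FALSE]
    if (n_count > 0 && length(streamlines) == n_count) break
  }
  streamline_set(streamlines)
}

write_trk <- function(set, path, affine, dim) {
  affine <- check_affine(affine)
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  inv <- solve(affine)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, size) writeBin(x, con, size = size, endian = "little")
  writeBin(c(charToRaw("TRACK"), as.raw(0)), con)
  wr(as.integer(dim), 2L)
  wr(as.numeric(voxel_size), 4L)
  wr(numeric(3), 4L)                                  # origin
  wr(0L, 2L); writeBin(raw(200L), con)                # n_scalars, names
  wr(0L, 2L); writeBin(raw(200L), con)                # n_properties, names
  wr(as.numeric(t(affine)), 4L)                       # vox_to_ras, row-major
  writeBin(raw(444L), con)
  writeBin(c(charToRaw("RAS"), as.raw(0)), con)       # voxel_order
  writeBin(raw(4L), con)                              # pad2
  wr(numeric(6), 4L)                                  # image_orientation_patient
  writeBin(raw(2L + 6L), con)                         # pad1 + flags
  wr(length(set$streamlines), 4L)                     # n_count
  wr(2L, 4L)                                          # version
  wr(1000L, 4L)                                       # hdr_size
  for (p in set$streamlines) {
    v <- cbind(p, 1) %*% t(inv)
    m <- sweep(v[, 1:3, drop = FALSE] + 0.5, 2, voxel_size, "*")
    wr(nrow(p), 4L)
    wr(as.numeric(t(m)), 4L)
  }
  invisible(path)
}

#' Write a tractogram to TCK or TRK
#'
#' @param set An `uwmc_streamlines` object in world mm.
#' @param path Output path; format chosen by `.tck` / `.trk` extension.
#' @param reference For TRK output only: an `uwmc_volume` (or a list with
#'   `affine` and `data`) supplying the grid the TRK header must describe.
#' @return `path`, invisibly.
#' @export
write_streamlines <- function(set, path, reference = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "tck") return(write_tck(set, path))
  if (ext == "trk") {
    if (is.null(reference))
      abort("TRK output needs a `reference` volume for its header transform")
    return(write_trk(set, path, reference$affine, dim(reference$data)))
  }
  abort("unsupported tractogram extension (use .tck or .trk)")
}
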