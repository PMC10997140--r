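#' Read and write streamline files (TCK / TRK dialects)
#'
#' Two on-disk dialects are supported. `tck` (MRtrix) stores world-mm (RAS)
#' coordinates directly. `trk` (TrackVis) stores "voxmm" coordinates —
#' continuous voxel indices with the origin at the corner of voxel (0,0,0),
#' scaled by the voxel size — so reading applies the half-voxel offset and
#' the header affine to recover world mm, and writing inverts that. All
#' in-memory coordinates are world mm; dialect offsets exist only at this
#' boundary. Round trips are lossless to single precision (the on-disk
#' datatype of both dialects).
#'
#' Per-streamline metadata (provenance, weights, labels and any extra meta
#' columns) are persisted in a plain-text sidecar table `<path>.meta.tsv`,
#' one row per streamline, keyed by index — portable across dialects and
#' diffable.
#'
#' @param path file path
#' @param dialect `"tck"` or `"trk"` (default: from the file extension)
#' @param set a [streamline_set()]
#' @param grid optional [volume_grid()] supplying the reference affine for
#'   the `trk` dialect (identity, 1 mm voxels if omitted)
#' @param sidecar write/read the metadata sidecar (default `TRUE`)
#' @return `read_streamlines()` returns a `streamline_set` (empty payloads
#'   give a 0-streamline set); `write_streamlines()` returns `path`
#'   invisibly.
#' @export
read_streamlines <- function(path, dialect = c("auto", "tck", "trk"),
                             sidecar = TRUE) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.trk$", path, ignore.case = TRUE)) "trk" else "tck"
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- switch(dialect, tck = read_tck(path), trk = read_trk(path))
  sc <- paste0(path, ".meta.tsv")
  if (sidecar && file.exists(sc)) {
    meta <- tibble::as_tibble(utils::read.delim(sc, sep = "\t"))
    if (nrow(meta) != n_streamlines(set))
      stop("sidecar row count (", nrow(meta), ") != streamline count (",
           n_streamlines(set), ")", call. = FALSE)
    meta$index <- NULL
    set$meta <- meta
  }
  set
}

#' @rdname read_streamlines
#' @export
write_streamlines <- function(set, path, dialect = c("auto", "tck", "trk"),
                              grid = NULL, sidecar = TRUE) {
  stopifnot(inherits(set, "streamline_set"))
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.trk$", path, ignore.case = TRUE)) "trk" else "tck"
  for (p in set$streamlines)
    if (any(!is.finite(p))) stop("streamline contains non-finite coordinates", call. = FALSE)
  switch(dialect,
         tck = write_tck(set, path),
         trk = write_trk(set, path, grid))
  if (sidecar && ncol(set$meta) > 0) {
    meta <- cbind(index = seq_len(n_streamlines(set)), as.data.frame(set$meta))
    utils::write.table(meta, paste0(path, ".meta.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

## ---- TCK (MRtrix track file) ------------------------------------------

write_tck <- function(set, path) {
  n <- n_streamlines(set)
  header_for <- function(offset) {
    paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ", n,
           "\nfile: . ", offset, "\nEND\n")
  }
  offset <- nchar(header_for(0))
  while (nchar(header_for(offset)) != offset)
    offset <- nchar(header_for(offset))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header_for(offset), con, eos = NULL)
  for (p in set$streamlines) {
    writeBin(as.numeric(t(p)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
}

read_tck <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  end <- grepRaw("END\n", raw, fixed = TRUE)
  if (length(end) == 0) stop("malformed tck header: no END marker", call. = FALSE)
  hdr <- strsplit(rawToChar(raw[1:(end[1] + 3)]), "\n")[[1]]
  if (hdr[1] != "mrtrix tracks")
    stop("malformed tck header: first line is not 'mrtrix tracks'", call. = FALSE)
  fields <- hdr[grepl(":", hdr, fixed = TRUE)]
  kv <- do.call(rbind, lapply(strsplit(fields, ":\\s*"), function(x)
    c(x[1], paste(x[-1], collapse = ":"))))
  get_field <- function(key) {
    v <- kv[kv[, 1] == key, 2]
    if (length(v) == 0) stop("malformed tck header: missing field '", key, "'", call. = FALSE)
    v[1]
  }
  dt <- get_field("datatype")
  if (dt != "Float32LE")
    stop("unsupported tck datatype '", dt, "' (field 'datatype')", call. = FALSE)
  file_field <- get_field("file")
  offset <- as.integer(sub("^\\.\\s+", "", file_field))
  if (is.na(offset)) stop("malformed tck header: unparseable field 'file'", call. = FALSE)
  n_float <- (length(raw) - offset) %/% 4
  vals <- readBin(raw[(offset + 1):length(raw)], "numeric", n = n_float,
                  size = 4, endian = "little")
  triplets <- matrix(vals[seq_len((length(vals) %/% 3) * 3)], ncol = 3, byrow = TRUE)
  split_triplets(triplets)
}

split_triplets <- function(triplets) {
  is_nan <- is.nan(triplets[, 1])
  is_inf <- is.infinite(triplets[, 1])
  stop_at <- which(is_inf)[1]
  if (!is.na(stop_at)) {
    triplets <- triplets[seq_len(stop_at - 1), , drop = FALSE]
    is_nan <- is_nan[seq_len(stop_at - 1)]
  }
  if (nrow(triplets) == 0) return(streamline_set(list()))
  grp <- cumsum(c(TRUE, is_nan[-length(is_nan)]))
  keep <- !is_nan
  pts <- lapply(split.data.frame(triplets[keep, , drop = FALSE], grp[keep]),
                function(m) unname(as.matrix(m)))
  streamline_set(unname(pts))
}

## ---- TRK (TrackVis track file) ----------------------------------------
## 1000-byte header, version 2 (vox_to_ras present). Points on disk are in
## voxmm: world = affine %*% (voxmm / voxel_size - 0.5).

write_trk <- function(set, path, grid = NULL) {
  if (is.null(grid)) grid <- volume_grid(array(0, dim = c(1, 1, 1)), diag(4))
  aff <- grid$affine
  vs <- voxel_size(grid)
  inv <- solve(aff)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, nchars = 5, eos = NULL); writeBin(as.raw(0), con)
  writeBin(as.integer(grid_shape(grid)), con, size = 2, endian = "little")
  writeBin(as.numeric(vs), con, size = 4, endian = "little")
  writeBin(rep(0, 3), con, size = 4, endian = "little")              # origin
  writeBin(0L, con, size = 2, endian = "little")                     # n_scalars
  writeBin(raw(200), con)
  writeBin(0L, con, size = 2, endian = "little")                     # n_properties
  writeBin(raw(200), con)
  writeBin(as.numeric(t(aff)), con, size = 4, endian = "little")     # row-major
  writeBin(raw(444), con)
  writeChar("RAS", con, nchars = 3, eos = NULL); writeBin(as.raw(0), con)
  writeBin(raw(4), con)
  writeBin(rep(0, 6), con, size = 4, endian = "little")
  writeBin(raw(2), con)
  writeBin(raw(6), con)
  writeBin(n_streamlines(set), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")
  writeBin(1000L, con, size = 4, endian = "little")
  for (p in set$streamlines) {
    ijk <- apply_affine(inv, p)
    voxmm <- sweep(ijk + 0.5, 2, vs, `*`)
    writeBin(nrow(p), con, size = 4, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4, endian = "little")
  }
}

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- readChar(con, 5, useBytes = TRUE); readBin(con, "raw", 1)
  if (!identical(id, "TRACK"))
    stop("malformed trk header: id_string is not 'TRACK'", call. = FALSE)
  readBin(con, "integer", 3, size = 2, endian = "little")            # dim
  vs <- readBin(con, "numeric", 3, size = 4, endian = "little")
  readBin(con, "numeric", 3, size = 4, endian = "little")            # origin
  n_scalars <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "raw", 200)
  n_props <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "raw", 200)
  aff <- matrix(readBin(con, "numeric", 16, size = 4, endian = "little"),
                4, 4, byrow = TRUE)
  readBin(con, "raw", 444 + 4 + 4)
  readBin(con, "numeric", 6, size = 4, endian = "little")
  readBin(con, "raw", 2 + 6)
  n_count <- readBin(con, "integer", 1, size = 4, endian = "little")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(hdr_size, 1000L))
    stop("malformed trk header: hdr_size is ", hdr_size, ", expected 1000", call. = FALSE)
  legacy <- version < 2 || all(aff == 0)
  if (legacy) {
    warning("trk file lacks a vox_to_ras affine; assuming voxmm == world mm")
    aff <- diag(4); diag(aff)[1:3] <- vs
    aff[1:3, 4] <- -vs / 2
  }
  if (any(vs <= 0)) stop("malformed trk header: non-positive voxel_size", call. = FALSE)
  pts <- list()
  repeat {
    npts <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(npts) == 0) break
    vals <- readBin(con, "numeric", npts * (3 + n_scalars), size = 4,
                    endian = "little")
    if (n_props > 0) readBin(con, "numeric", n_props, size = 4, endian = "little")
    m <- matrix(vals, ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    ijk <- sweep(m, 2, vs, `/`) - 0.5
    pts[[length(pts) + 1]] <- apply_affine(aff, ijk)
  }
  if (n_count > 0 && length(pts) != n_count)
    warning("trk header count (", n_count, ") != streamlines read (", length(pts), ")")
  streamline_set(pts)
}
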