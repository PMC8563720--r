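# Minimal multi-page TIFF codec (little-endian, uncompressed, single strip
# per page, one sample per pixel). Supports unsigned 16/32-bit integer and
# 32-bit float pages -- exactly what the pipeline writes. Implemented here
# because no TIFF reader/writer is available in the supported dependency
# set; the subset written is plain baseline TIFF readable by standard tools.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, StripOffsets = 273L,
               SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L, SampleFormat = 339L)

tiff_dtype <- function(type) {
  switch(type,
         uint16 = list(bits = 16L, fmt = 1L, size = 2L),
         uint32 = list(bits = 32L, fmt = 1L, size = 4L),
         float32 = list(bits = 32L, fmt = 3L, size = 4L),
         stop("unsupported TIFF sample type: ", type, call. = FALSE))
}

# Write a list of equally sized matrices as a multi-page TIFF. Page data are
# written row-major (scanlines), matching the (row, col) matrix convention.
write_tiff_pages <- function(pages, path, type = c("uint16", "uint32",
                                                   "float32")) {
  type <- match.arg(type)
  dt <- tiff_dtype(type)
  stopifnot(length(pages) > 0)
  h <- nrow(pages[[1]]); wd <- ncol(pages[[1]])
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  n_tags <- 10L
  ifd_size <- 2L + 12L * n_tags + 4L
  data_bytes <- h * wd * dt$size
  # layout: header(8) then per page [pixel data][IFD]
  offs_data <- 8L + (seq_along(pages) - 1L) * (data_bytes + ifd_size)
  offs_ifd <- offs_data + data_bytes
  writeBin(offs_ifd[1], con, size = 4, endian = "little")
  wtag <- function(tag, typ, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(typ), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (typ == 3L) {  # SHORT, left-justified in the 4-byte value field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (p in seq_along(pages)) {
    m <- pages[[p]]
    if (nrow(m) != h || ncol(m) != wd)
      stop("all pages must have identical dimensions", call. = FALSE)
    v <- as.vector(t(m))  # row-major scanlines
    if (type == "float32") {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else {
      writeBin(as.integer(v), con, size = dt$size, endian = "little")
    }
    writeBin(n_tags, con, size = 2, endian = "little")
    wtag(TIFF_TAGS["ImageWidth"], 4L, 1L, wd)
    wtag(TIFF_TAGS["ImageLength"], 4L, 1L, h)
    wtag(TIFF_TAGS["BitsPerSample"], 3L, 1L, dt$bits)
    wtag(TIFF_TAGS["Compression"], 3L, 1L, 1L)
    wtag(TIFF_TAGS["Photometric"], 3L, 1L, 1L)
    wtag(TIFF_TAGS["StripOffsets"], 4L, 1L, offs_data[p])
    wtag(TIFF_TAGS["SamplesPerPixel"], 3L, 1L, 1L)
    wtag(TIFF_TAGS["RowsPerStrip"], 4L, 1L, h)
    wtag(TIFF_TAGS["StripByteCounts"], 4L, 1L, data_bytes)
    wtag(TIFF_TAGS["SampleFormat"], 3L, 1L, dt$fmt)
    next_off <- if (p < length(pages)) offs_ifd[p + 1] else 0L
    writeBin(as.integer(next_off), con, size = 4, endian = "little")
  }
  invisible(path)
}

rd_int <- function(raw, off, size, signed = (size == 4)) {
  readBin(raw[(off + 1):(off + size)], "integer", size = size,
          signed = signed, endian = "little")
}

# Read a multi-page TIFF written by write_tiff_pages (baseline subset:
# little-endian, uncompressed, one strip, one sample). Returns list(pages,
# type).
read_tiff_pages <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8 || rawToChar(raw[1:2]) != "II")
    stop("not a little-endian TIFF: ", path, call. = FALSE)
  if (rd_int(raw, 2, 2) != 42L) stop("bad TIFF magic in ", path,
                                     call. = FALSE)
  off <- rd_int(raw, 4, 4)
  pages <- list()
  type <- NULL
  page_i <- 0L
  while (off != 0L) {
    page_i <- page_i + 1L
    n_tags <- rd_int(raw, off, 2)
    tags <- list()
    for (i in seq_len(n_tags)) {
      base <- off + 2L + (i - 1L) * 12L
      tag <- rd_int(raw, base, 2)
      typ <- rd_int(raw, base + 2L, 2)
      val <- if (typ == 3L) rd_int(raw, base + 8L, 2)
             else rd_int(raw, base + 8L, 4)
      tags[[as.character(tag)]] <- val
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(TIFF_TAGS[[tag]])]]
      if (is.null(v)) {
        if (is.null(default))
          stop(sprintf("TIFF page %d missing tag %s", page_i, tag),
               call. = FALSE)
        default
      } else v
    }
    wd <- need("ImageWidth"); h <- need("ImageLength")
    bits <- need("BitsPerSample"); comp <- need("Compression", 1L)
    fmt <- need("SampleFormat", 1L)
    if (comp != 1L)
      stop(sprintf("TIFF page %d: unsupported compression %d", page_i, comp),
           call. = FALSE)
    this_type <- if (fmt == 3L && bits == 32L) "float32"
      else if (fmt == 1L && bits == 16L) "uint16"
      else if (fmt == 1L && bits == 32L) "uint32"
      else stop(sprintf("TIFF page %d: unsupported sample format %d/%d bits",
                        page_i, fmt, bits), call. = FALSE)
    if (is.null(type)) type <- this_type
    else if (type != this_type)
      stop(sprintf("TIFF page %d: mixed sample types", page_i),
           call. = FALSE)
    doff <- need("StripOffsets"); dlen <- need("StripByteCounts")
    dt <- tiff_dtype(type)
    n_px <- h * wd
    if (dlen != n_px * dt$size)
      stop(sprintf("TIFF page %d: strip size mismatch", page_i),
           call. = FALSE)
    bytes <- raw[(doff + 1):(doff + dlen)]
    v <- if (type == "float32") {
      readBin(bytes, "numeric", n = n_px, size = 4, endian = "little")
    } else if (type == "uint16") {
      readBin(bytes, "integer", n = n_px, size = 2, signed = FALSE,
              endian = "little")
    } else {
      readBin(bytes, "integer", n = n_px, size = 4, endian = "little")
    }
    pages[[page_i]] <- matrix(v, nrow = h, ncol = wd, byrow = TRUE)
    off <- rd_int(raw, off + 2L + n_tags * 12L, 4)
  }
  list(pages = pages, type = type)
}

#' Write a TCSPC cube as multi-page TIFF plus JSON sidecar
#'
#' One TIFF page per time bin, in time order, 16-bit unsigned (promoted to
#' 32-bit with a metadata flag if any count exceeds 65535), plus a JSON
#' sidecar with the same basename carrying acquisition metadata, provenance
#' and the pile-up check. Round-trip safe with [read_cube()].
#'
#' @param cube A [tcspc_cube()].
#' @param path Destination `.tif` path; the sidecar is written next to it.
#' @return Invisibly, a character vector `c(tiff, sidecar)` of the two paths.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "tcspc_cube"))
  d <- dim(cube$counts)
  type <- if (max(cube$counts) > 65535L) "uint32" else "uint16"
  pages <- lapply(seq_len(d[1]), function(t) cube$counts[t, , ])
  write_tiff_pages(pages, path, type)
  sidecar <- sidecar_path(path)
  meta <- list(format = "flimfret-tcspc-cube", version = 1L,
               dtype = type, n_bins = cube$acq$n_bins,
               bin_width_ns = cube$acq$bin_width,
               period_ns = cube$acq$period,
               pileup_budget = cube$acq$pileup_budget,
               n_excitations = cube$acq$n_excitations,
               shape = d, provenance = cube$provenance)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(path, sidecar))
}

sidecar_path <- function(path)
  paste0(tools::file_path_sans_ext(path), ".json")

#' Read a TCSPC cube written by [write_cube()]
#'
#' Validates the invariants (non-negative integer counts, page count equal to
#' the metadata's number of time bins) and reconstructs the
#' [tcspc_cube()] including acquisition metadata from the JSON sidecar.
#'
#' @param path Path to the `.tif` file.
#' @return A [tcspc_cube()].
#' @export
read_cube <- function(path) {
  sidecar <- sidecar_path(path)
  if (!file.exists(sidecar))
    stop("cube sidecar not found; expected ", sidecar, call. = FALSE)
  if (!file.exists(path))
    stop("cube TIFF not found: ", path, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  tp <- read_tiff_pages(path)
  if (length(tp$pages) != meta$n_bins)
    stop(sprintf("cube has %d pages but metadata declares %d time bins",
                 length(tp$pages), meta$n_bins), call. = FALSE)
  for (i in seq_along(tp$pages)) {
    if (any(tp$pages[[i]] < 0) || any(tp$pages[[i]] != round(tp$pages[[i]])))
      stop(sprintf("negative or non-integer counts on page %d", i),
           call. = FALSE)
  }
  d2 <- dim(tp$pages[[1]])
  counts <- array(0L, c(length(tp$pages), d2[1], d2[2]))
  for (t in seq_along(tp$pages)) counts[t, , ] <- tp$pages[[t]]
  acq <- acq_config(n_bins = meta$n_bins, bin_width = meta$bin_width_ns,
                    period = meta$period_ns,
                    pileup_budget = meta$pileup_budget,
                    n_excitations = meta$n_excitations)
  tcspc_cube(counts, acq, provenance = meta$provenance)
}

#' Write a float map as single-page 32-bit TIFF
#'
#' NA pixels are written as NaN.
#'
#' @param m Numeric matrix.
#' @param path Destination path.
#' @return Invisibly, the path.
#' @export
write_map_tiff <- function(m, path) {
  m[is.na(m)] <- NaN
  write_tiff_pages(list(m), path, "float32")
  invisible(path)
}

#' Read a single-page float map TIFF
#'
#' @param path Path written by [write_map_tiff()].
#' @return Numeric matrix with NaN restored to NA.
#' @export
read_map_tiff <- function(path) {
  tp <- read_tiff_pages(path)
  m <- tp$pages[[1]]
  m[is.nan(m)] <- NA
  m
}

#' Write a rendered class map as a portable pixmap (PPM) with JSON legend
#'
#' Plain-text (P3) PPM plus a JSON legend mapping class labels to colors.
#'
#' @param img RGB array from [render_class_map()].
#' @param path Destination `.ppm` path; legend written with suffix
#'   `_legend.json`.
#' @return Invisibly, `c(ppm, legend)` paths.
#' @export
write_class_ppm <- function(img, path) {
  d <- dim(img)
  hdr <- sprintf("P3\n%d %d\n255", d[2], d[1])
  # PPM is row-major with channels interleaved per pixel
  px <- aperm(round(255 * img), c(3, 2, 1))  # (channel, col, row)
  writeLines(c(hdr, paste(as.integer(px), collapse = " ")), path)
  legend_path <- paste0(tools::file_path_sans_ext(path), "_legend.json")
  leg <- attr(img, "legend")
  if (!is.null(leg))
    jsonlite::write_json(leg, legend_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(path, legend_path))
}
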