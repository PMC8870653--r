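# Minimal multi-page TIFF I/O for phase-map and hologram stacks.
# Classic little-endian TIFF, uncompressed, one sample per pixel,
# 32-bit float (default) or 16-bit unsigned; acquisition metadata is a
# JSON object stored in the ImageDescription tag of the first page.
# No TIFF library is available in the target R environment, so the
# format subset needed by the pipeline is implemented here and verified
# against an independent reader in the test suite.

tiff_types <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L)

pack_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                 endian = "little")
pack_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                 endian = "little")

ifd_entry <- function(tag, type, count, value_raw4) {
  c(pack_u16(tag), pack_u16(type), pack_u32(count), value_raw4)
}

#' Write an image stack as multi-page TIFF
#'
#' Writes a lossless 32-bit float (or scaled 16-bit unsigned) multi-page
#' TIFF with metadata as JSON in the ImageDescription field.  The pixel
#' pitch is mandatory: downstream dry-mass quantification needs it.
#'
#' @param path output file path.
#' @param images a matrix or list of equally sized matrices
#'   (rows = y, columns = x).
#' @param metadata named list; must include `pixel_pitch_um`; typically
#'   also `wavelength_nm` and `time_h`.
#' @param type `"float32"` (lossless) or `"uint16"` (values scaled by
#'   `(2^16 - 1) / max`, the scale stored as `uint16_scale` so reading
#'   restores the original units).
#' @return `path`, invisibly.
#' @export
write_stack <- function(path, images, metadata = list(),
                        type = c("float32", "uint16")) {
  type <- match.arg(type)
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1, all(vapply(images, is.matrix, logical(1))))
  if (is.null(metadata$pixel_pitch_um))
    stop_config("metadata$pixel_pitch_um is required")
  nx <- ncol(images[[1]]); ny <- nrow(images[[1]])
  if (!all(vapply(images, function(m)
    ncol(m) == nx && nrow(m) == ny, logical(1))))
    stop_data("all pages must share dimensions")

  if (type == "uint16") {
    mx <- max(unlist(lapply(images, max)), 1e-12)
    scale <- 65535 / mx
    metadata$uint16_scale <- scale
  }
  desc <- charToRaw(jsonlite::toJSON(metadata, auto_unbox = TRUE,
                                     digits = NA))
  desc <- c(desc, as.raw(0))
  if (length(desc) %% 2) desc <- c(desc, as.raw(0))

  bps <- if (type == "float32") 32L else 16L
  bytes_px <- bps / 8L
  data_len <- nx * ny * bytes_px
  pad <- data_len %% 2L

  n_pages <- length(images)
  # layout: header | per page: [desc (page 1)] [pixel data] [IFD]
  pos <- 8L
  desc_off <- integer(n_pages); data_off <- integer(n_pages)
  ifd_off <- integer(n_pages)
  for (i in seq_len(n_pages)) {
    if (i == 1L) { desc_off[i] <- pos; pos <- pos + length(desc) }
    data_off[i] <- pos; pos <- pos + data_len + pad
    n_entries <- if (i == 1L) 11L else 10L
    ifd_off[i] <- pos; pos <- pos + 2L + 12L * n_entries + 4L
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42), con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off[1]), con, size = 4, endian = "little")

  short_val <- function(x) c(pack_u16(x), pack_u16(0))
  for (i in seq_len(n_pages)) {
    if (i == 1L) writeBin(desc, con)
    px <- as.vector(t(images[[i]]))       # row-major pixel order
    if (type == "float32") {
      writeBin(as.numeric(px), con, size = 4, endian = "little")
    } else {
      v <- as.integer(round(pmax(0, pmin(65535, px * scale))))
      writeBin(v, con, size = 2, endian = "little")
    }
    if (pad) writeBin(as.raw(0), con)
    entries <- list(
      ifd_entry(256, tiff_types["LONG"], 1, pack_u32(nx)),
      ifd_entry(257, tiff_types["LONG"], 1, pack_u32(ny)),
      ifd_entry(258, tiff_types["SHORT"], 1, short_val(bps)),
      ifd_entry(259, tiff_types["SHORT"], 1, short_val(1)),
      ifd_entry(262, tiff_types["SHORT"], 1, short_val(1)))
    if (i == 1L)
      entries <- c(entries, list(
        ifd_entry(270, tiff_types["ASCII"], length(desc),
                  pack_u32(desc_off[i]))))
    entries <- c(entries, list(
      ifd_entry(273, tiff_types["LONG"], 1, pack_u32(data_off[i])),
      ifd_entry(277, tiff_types["SHORT"], 1, short_val(1)),
      ifd_entry(278, tiff_types["LONG"], 1, pack_u32(ny)),
      ifd_entry(279, tiff_types["LONG"], 1, pack_u32(data_len)),
      ifd_entry(339, tiff_types["SHORT"], 1,
                short_val(if (type == "float32") 3 else 1))))
    writeBin(as.integer(length(entries)), con, size = 2, endian = "little")
    for (e in entries) writeBin(e, con)
    writeBin(as.integer(if (i < n_pages) ifd_off[i + 1] else 0), con,
             size = 4, endian = "little")
  }
  invisible(path)
}

read_u <- function(con, size) {
  v <- readBin(con, "integer", n = 1, size = size, endian = "little",
               signed = size >= 4)
  if (v < 0) v + 2^(8 * size) else v
}

#' Read a multi-page TIFF stack
#'
#' Reads the uncompressed little-endian subset written by
#' [write_stack()]: 32-bit float, or 8/16-bit unsigned integer promoted
#' to float (divided by the stored `uint16_scale` when present, raw
#' counts otherwise).
#'
#' @param path TIFF file path.
#' @param require_pitch error when the metadata lacks `pixel_pitch_um`
#'   (default TRUE; the pitch is required for dry-mass quantification).
#' @return list with `images` (list of matrices) and `metadata`.
#' @export
read_stack <- function(path, require_pitch = TRUE) {
  if (!file.exists(path)) stop_data("no such file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  if (rawToChar(magic) == "MM")
    stop_data("big-endian TIFF not supported: %s", path)
  if (rawToChar(magic) != "II" || read_u(con, 2) != 42)
    stop_data("not a TIFF file: %s", path)
  next_ifd <- read_u(con, 4)
  images <- list(); metadata <- list(); page <- 0L
  while (next_ifd != 0) {
    page <- page + 1L
    seek(con, next_ifd)
    n <- read_u(con, 2)
    tags <- vector("list", n)
    for (k in seq_len(n)) {
      tag <- read_u(con, 2); type <- read_u(con, 2); count <- read_u(con, 4)
      val_raw <- readBin(con, "raw", 4)
      tags[[k]] <- list(tag = tag, type = type, count = count,
                        raw = val_raw)
    }
    next_ifd <- read_u(con, 4)
    get_vals <- function(t) {
      if (is.null(t)) return(NULL)
      sz <- c(1L, 1L, 2L, 4L)[t$type]
      total <- sz * t$count
      if (total <= 4) {
        rcon <- rawConnection(t$raw)
        on.exit(close(rcon), add = TRUE)
        if (t$type == 2L) return(readBin(rcon, "character"))
        vapply(seq_len(t$count), function(i)
          read_u(rcon, sz), numeric(1))
      } else {
        off <- readBin(t$raw, "integer", size = 4, endian = "little")
        seek(con, off)
        if (t$type == 2L) {
          raw_s <- readBin(con, "raw", t$count)
          return(rawToChar(raw_s[raw_s != as.raw(0)]))
        }
        vapply(seq_len(t$count), function(i) read_u(con, sz), numeric(1))
      }
    }
    find <- function(tag) {
      for (t in tags) if (t$tag == tag) return(t)
      NULL
    }
    nx <- get_vals(find(256)); ny <- get_vals(find(257))
    if (is.null(nx) || is.null(ny))
      stop_data("page %d: missing dimension tags", page)
    comp <- get_vals(find(259)) %||% 1
    if (comp != 1) stop_data("page %d: compressed TIFF not supported", page)
    bps <- get_vals(find(258)) %||% 1
    fmt <- get_vals(find(339)) %||% 1
    offs <- get_vals(find(273))
    counts <- get_vals(find(279))
    if (is.null(offs) || is.null(counts))
      stop_data("page %d: missing strip tags", page)
    if (page == 1L) {
      d <- find(270)
      if (!is.null(d)) {
        txt <- get_vals(d)
        md <- tryCatch(jsonlite::fromJSON(txt), error = function(e) NULL)
        if (is.list(md)) metadata <- md
      }
    }
    px <- numeric(0)
    for (s in seq_along(offs)) {
      seek(con, offs[s])
      if (fmt == 3 && bps == 32) {
        px <- c(px, readBin(con, "double", n = counts[s] / 4, size = 4,
                            endian = "little"))
      } else if (fmt == 1 && bps == 16) {
        v <- readBin(con, "integer", n = counts[s] / 2, size = 2,
                     signed = FALSE, endian = "little")
        px <- c(px, as.numeric(v))
      } else if (fmt == 1 && bps == 8) {
        v <- readBin(con, "integer", n = counts[s], size = 1,
                     signed = FALSE, endian = "little")
        px <- c(px, as.numeric(v))
      } else {
        stop_data("page %d: unsupported sample format (%d-bit, format %d)",
                  page, bps, fmt)
      }
    }
    if (length(px) != nx * ny)
      stop_data("page %d: pixel count mismatch", page)
    if (bps == 16 && !is.null(metadata$uint16_scale))
      px <- px / metadata$uint16_scale
    images[[page]] <- matrix(px, nrow = ny, ncol = nx, byrow = TRUE)
  }
  if (require_pitch && is.null(metadata$pixel_pitch_um))
    stop_data("TIFF metadata lacks pixel_pitch_um (required for dry mass)")
  list(images = images, metadata = metadata)
}
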