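# Minimal baseline TIFF I/O (uncompressed, little-endian, 8-bit), enough for
# pyramidal RGB slides and single-channel label rasters. No TIFF-capable R
# package is available in the supported environment, so the subset needed here
# is implemented directly; files are readable by any baseline TIFF reader
# (verified against Python tifffile in the test suite).

tiff_types <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L)

write_tiff_pages <- function(pages, path, photometric) {
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L)
  # layout: [header 8][page1 strip][page1 extras][page1 IFD][page2 strip]...
  offset <- 8L
  strips <- list(); extras <- list(); ifd_off <- integer(length(pages))
  sizes <- list()
  for (i in seq_along(pages)) {
    img <- pages[[i]]
    spp <- if (length(dim(img)) == 3) dim(img)[3] else 1L
    H <- dim(img)[1]; W <- dim(img)[2]
    bytes <- if (spp == 1) as.raw(t(img)) else as.raw(aperm(img, c(3, 2, 1)))
    n_entries <- 9L
    strip_off <- offset
    bps_off <- strip_off + length(bytes)
    extra_len <- if (spp == 3) 6L else 0L
    ifd_off[i] <- bps_off + extra_len
    offset <- ifd_off[i] + 2L + 12L * n_entries + 4L
    strips[[i]] <- bytes
    sizes[[i]] <- list(H = H, W = W, spp = spp, strip_off = strip_off,
                       bps_off = bps_off, n_entries = n_entries)
  }
  w4(ifd_off[1])
  entry <- function(tag, type, count, value) {
    w2(tag); w2(tiff_types[[type]]); w4(count)
    if (type == "SHORT" && count == 1) { w2(value); w2(0L) } else w4(value)
  }
  for (i in seq_along(pages)) {
    s <- sizes[[i]]
    writeBin(strips[[i]], con)
    if (s$spp == 3) w2(c(8L, 8L, 8L))          # BitsPerSample array
    w2(s$n_entries)
    entry(256L, "LONG", 1L, s$W)               # ImageWidth
    entry(257L, "LONG", 1L, s$H)               # ImageLength
    if (s$spp == 3) entry(258L, "SHORT", 3L, s$bps_off) else
      entry(258L, "SHORT", 1L, 8L)             # BitsPerSample
    entry(259L, "SHORT", 1L, 1L)               # Compression: none
    entry(262L, "SHORT", 1L, photometric)      # Photometric
    entry(273L, "LONG", 1L, s$strip_off)       # StripOffsets
    entry(277L, "SHORT", 1L, s$spp)            # SamplesPerPixel
    entry(278L, "LONG", 1L, s$H)               # RowsPerStrip
    entry(279L, "LONG", 1L, length(strips[[i]])) # StripByteCounts
    w4(if (i < length(pages)) ifd_off[i + 1] else 0L)
  }
  invisible(path)
}

read_tiff_pages <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8 || rawToChar(raw[1:2]) != "II")
    fq_stop("fq_format_error", "%s: not a little-endian TIFF", path)
  u16 <- function(off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
  u32 <- function(off) as.integer(raw[off + 1]) + 256 * as.integer(raw[off + 2]) +
    65536 * as.integer(raw[off + 3]) + 16777216 * as.integer(raw[off + 4])
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (k in seq_len(n)) {
      e <- ifd + 2 + 12 * (k - 1)
      tag <- u16(e); type <- u16(e + 2); count <- u32(e + 4)
      val <- if (type == tiff_types[["SHORT"]] && count == 1) u16(e + 8) else u32(e + 8)
      tags[[as.character(tag)]] <- list(type = type, count = count, value = val)
    }
    g <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) default else t$value
    }
    if (g(259, 1L) != 1L)
      fq_stop("fq_format_error", "%s: only uncompressed TIFF is supported", path)
    H <- g(257); W <- g(256); spp <- g(277, 1L)
    so <- tags[["273"]]; sc <- tags[["279"]]
    offs <- if (so$count == 1) so$value else
      vapply(seq_len(so$count) - 1L, function(j) u32(so$value + 4 * j), 0)
    lens <- if (sc$count == 1) sc$value else
      vapply(seq_len(sc$count) - 1L, function(j) u32(sc$value + 4 * j), 0)
    bytes <- unlist(lapply(seq_along(offs),
                           function(j) raw[offs[j] + seq_len(lens[j])]))
    vals <- as.integer(bytes)
    pages[[length(pages) + 1]] <- if (spp == 1) {
      matrix(vals, H, W, byrow = TRUE)
    } else {
      arr <- array(0L, dim = c(H, W, spp))
      for (ch in seq_len(spp))
        arr[, , ch] <- matrix(vals[seq(ch, length(vals), by = spp)], H, W, byrow = TRUE)
      arr
    }
    ifd <- u32(ifd + 2 + 12 * n)
  }
  pages
}

#' Write / read a slide pyramid as a multi-page TIFF
#'
#' Each pyramid level becomes one page (8-bit RGB, uncompressed baseline
#' TIFF), full resolution first.
#'
#' @param pyramid an `fq_pyramid`.
#' @param path file path.
#' @return `write_slide_tiff` returns `path` invisibly; `read_slide_tiff`
#'   returns an `fq_pyramid` (scales inferred from level sizes).
#' @export
write_slide_tiff <- function(pyramid, path) {
  write_tiff_pages(pyramid$levels, path, photometric = 2L)
}

#' @rdname write_slide_tiff
#' @export
read_slide_tiff <- function(path) {
  pages <- read_tiff_pages(path)
  if (length(pages) == 0 || length(dim(pages[[1]])) != 3)
    fq_stop("fq_format_error", "%s holds no RGB pages", path)
  w0 <- ncol(pages[[1]][, , 1])
  structure(list(levels = pages,
                 scales = vapply(pages, function(p) round(w0 / dim(p)[2]), 0)),
            class = "fq_pyramid")
}

# single-channel helpers (label rasters)
write_gray_tiff <- function(mat, path) {
  write_tiff_pages(list(mat), path, photometric = 1L)
}

read_gray_tiff <- function(path) {
  read_tiff_pages(path)[[1]]
}

#' Write / read ground truth (label raster + JSON sidecar)
#'
#' The label map goes to a single-channel TIFF; a JSON sidecar at
#' `<path>.json` records the label legend, pixel size and realized fractions.
#'
#' @param gt an `fq_ground_truth`.
#' @param path TIFF path.
#' @return `write_ground_truth` returns `path` invisibly; `read_ground_truth`
#'   returns an `fq_ground_truth` (without the material map, which is a
#'   generator-internal detail not part of the interchange format).
#' @export
write_ground_truth <- function(gt, path) {
  write_gray_tiff(gt$label_map, path)
  jsonlite::write_json(list(labels = as.list(FQ_GT_LABELS),
                            pixel_size_um = gt$pixel_size_um,
                            mass_fraction = gt$mass_fraction,
                            collagen_fraction = gt$collagen_fraction),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  structure(list(label_map = read_gray_tiff(path), material_map = NULL,
                 pixel_size_um = meta$pixel_size_um,
                 mass_fraction = meta$mass_fraction,
                 collagen_fraction = meta$collagen_fraction,
                 classes = names(FQ_GT_LABELS)),
            class = "fq_ground_truth")
}
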