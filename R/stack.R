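#' Multi-channel image stacks and 2D projection
#'
#' A `channel_stack` holds a multi-channel, optionally multi-plane
#' fluorescence image as an array indexed `(plane, channel, row, col)`; a
#' `projected_image` is its 2D counterpart indexed `(channel, row, col)`.
#' All quantification in this package operates on projected images, the way
#' confocal Z-stacks are collapsed to a single 2D picture per channel before
#' region measurement.
#'
#' @param pixels Numeric array. Accepted shapes: `(row, col)` (one plane,
#'   one channel), `(channel, row, col)` (one plane) or
#'   `(plane, channel, row, col)`. Intensities must be non-negative.
#' @param channel_names Optional character vector of cell-type labels, one
#'   per channel; autogenerated (`"CH1"`, ...) when absent.
#' @param pixel_size Optional physical pixel edge length in micrometres
#'   (isotropic); must be positive when given.
#' @param source_path Provenance string.
#' @return An object of class `channel_stack`.
#' @seealso [read_stack()], [project()]
#' @export
channel_stack <- function(pixels, channel_names = NULL, pixel_size = NULL,
                          source_path = NA_character_) {
  d <- dim(pixels)
  if (is.null(d) || length(d) == 2) {
    pixels <- array(pixels, dim = c(1L, 1L, dim(as.matrix(pixels))))
  } else if (length(d) == 3) {
    pixels <- array(pixels, dim = c(1L, d))
  } else if (length(d) != 4) {
    stop("pixels must have 2, 3 or 4 dimensions")
  }
  d <- dim(pixels)
  if (min(pixels) < 0) stop("intensities must be non-negative")
  channel_names <- channel_names %||% paste0("CH", seq_len(d[2]))
  if (length(channel_names) != d[2]) {
    stop("channel_names length (", length(channel_names),
         ") does not match channel count (", d[2], ")")
  }
  if (!is.null(pixel_size) && pixel_size <= 0) stop("pixel_size must be > 0")
  structure(
    list(pixels = pixels, channel_names = channel_names,
         pixel_size = pixel_size, source_path = source_path),
    class = "channel_stack"
  )
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<channel_stack> ", d[1], " plane(s) x ", d[2], " channel(s) [",
      paste(x$channel_names, collapse = ", "), "] x ", d[3], "x", d[4], " px",
      if (!is.null(x$pixel_size)) paste0(", ", x$pixel_size, " um/px"),
      "\n", sep = "")
  invisible(x)
}

#' @rdname channel_stack
#' @param img For `projected_image()`: a `(channel, row, col)` array.
#' @param projection_method Tag recording how the projection was made.
#' @export
projected_image <- function(img, channel_names = NULL, pixel_size = NULL,
                            projection_method = "none") {
  d <- dim(img)
  if (length(d) == 2) img <- array(img, dim = c(1L, d))
  d <- dim(img)
  if (length(d) != 3) stop("projected pixels must be (channel, row, col)")
  channel_names <- channel_names %||% paste0("CH", seq_len(d[1]))
  if (length(channel_names) != d[1]) stop("channel_names length mismatch")
  structure(
    list(pixels = img, channel_names = channel_names, pixel_size = pixel_size,
         projection_method = projection_method),
    class = "projected_image"
  )
}

#' @export
print.projected_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<projected_image> ", d[1], " channel(s) [",
      paste(x$channel_names, collapse = ", "), "] x ", d[2], "x", d[3],
      " px, projection: ", x$projection_method, "\n", sep = "")
  invisible(x)
}

image_shape <- function(x) {
  d <- dim(x$pixels)
  d[(length(d) - 1):length(d)]
}

# channel matrix (row, col) by index or name
channel_matrix <- function(img, channel) {
  if (is.character(channel)) {
    idx <- match(channel, img$channel_names)
    if (is.na(idx)) {
      stop("unknown channel '", channel, "'; available: ",
           paste(img$channel_names, collapse = ", "))
    }
    channel <- idx
  }
  img$pixels[channel, , ]
}

#' Project a stack to one 2D image per channel
#'
#' Collapses the plane axis independently for every channel, never mixing
#' channels. The default is the per-pixel maximum, the standard choice for
#' sparse fluorescent structures because it preserves thin sprouts that
#' appear in only one optical section; `sum` and `mean` are also available.
#'
#' @param stack A [channel_stack()].
#' @param method `"max"` (default), `"sum"` or `"mean"`.
#' @return A [projected_image()] carrying the stack's channel names and
#'   pixel size.
#' @examples
#' st <- channel_stack(array(1:24, c(2, 3, 2, 2)))
#' project(st)$pixels[1, , ]
#' @export
project <- function(stack, method = "max") {
  stopifnot(inherits(stack, "channel_stack"))
  methods <- c("max", "sum", "mean")
  if (!method %in% methods) {
    stop("unknown projection method '", method, "'; supported: ",
         paste(methods, collapse = ", "))
  }
  d <- dim(stack$pixels)
  out <- array(0, dim = d[2:4])
  f <- switch(method, max = max, sum = sum, mean = mean)
  for (ch in seq_len(d[2])) {
    if (d[1] == 1) {
      out[ch, , ] <- stack$pixels[1, ch, , ]
    } else {
      out[ch, , ] <- apply(stack$pixels[, ch, , , drop = FALSE], c(3, 4), f)
    }
  }
  projected_image(out, channel_names = stack$channel_names,
                  pixel_size = stack$pixel_size, projection_method = method)
}

# Lift a projected image back to a one-plane stack (for re-projection).
as_stack <- function(img) {
  stopifnot(inherits(img, "projected_image"))
  d <- dim(img$pixels)
  channel_stack(array(img$pixels, dim = c(1L, d)),
                channel_names = img$channel_names, pixel_size = img$pixel_size)
}

#' Read a multi-channel TIFF / OME-TIFF as a channel stack
#'
#' Pages are mapped onto plane and channel axes using, in order of
#' preference: embedded OME-XML metadata (`SizeC`, `SizeZ`, channel names,
#' `PhysicalSizeX`), then the length of `channel_names`, then the
#' convention that a file with at most 5 pages and no metadata is a
#' single-plane multi-channel image. Anything else is reported as an
#' ambiguous axis layout.
#'
#' @param path TIFF file path.
#' @param channel_names Optional channel names; when metadata is absent
#'   their length fixes the channel-axis extent.
#' @return A [channel_stack()].
#' @seealso [write_stack()]
#' @export
read_stack <- function(path, channel_names = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, function(p) is.matrix(p), logical(1)))) {
    stop("ambiguous axis layout in '", path,
         "': pages with a sample axis (RGB TIFF) are not supported; ",
         "write one grayscale page per channel")
  }
  info <- tiff::readTIFF(path, all = TRUE, payload = FALSE)
  desc <- if (is.data.frame(info) && "description" %in% names(info)) {
    info$description[1]
  } else NULL
  meta <- parse_ome_description(desc)
  n_pages <- length(pages)

  if (!is.null(meta$size_c)) {
    n_c <- meta$size_c
    n_z <- meta$size_z %||% (n_pages %/% n_c)
  } else if (!is.null(channel_names)) {
    n_c <- length(channel_names)
    n_z <- n_pages %/% n_c
  } else if (n_pages <= 5) {
    n_c <- n_pages
    n_z <- 1L
  } else {
    stop("ambiguous axis layout in '", path, "': ", n_pages,
         " pages but no OME metadata and no channel_names to split the ",
         "channel axis from the plane axis")
  }
  if (n_c * n_z != n_pages) {
    stop("axis layout mismatch in '", path, "': ", n_pages,
         " pages cannot be split into ", n_c, " channel(s) x ", n_z,
         " plane(s)")
  }
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  px <- array(0, dim = c(n_z, n_c, H, W))
  k <- 1L
  for (z in seq_len(n_z)) for (ch in seq_len(n_c)) {  # C fastest (XYCZT)
    px[z, ch, , ] <- pages[[k]]
    k <- k + 1L
  }
  channel_stack(
    px,
    channel_names = channel_names %||% meta$channel_names,
    pixel_size = meta$pixel_size,
    source_path = path
  )
}

#' Write a channel stack (or projected image) as an OME-TIFF
#'
#' Pixel data is written as 16-bit grayscale pages (channel axis fastest,
#' XYCZT order) with a minimal OME-XML ImageDescription recording axis
#' sizes, channel names and the physical pixel size, so that
#' [read_stack()] round-trips the object bit-exactly. Intensities above
#' 65535 are an error; non-integer intensities are written as 32-bit floats.
#'
#' @param x A [channel_stack()] or [projected_image()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path) {
  if (inherits(x, "projected_image")) x <- as_stack(x)
  stopifnot(inherits(x, "channel_stack"))
  d <- dim(x$pixels)
  mx <- max(x$pixels)
  integral <- all(x$pixels == round(x$pixels))
  if (integral && mx > 65535) stop("integer intensities above 65535 cannot be written as 16-bit")
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (z in seq_len(d[1])) for (ch in seq_len(d[2])) {
    m <- x$pixels[z, ch, , ]
    pages[[k]] <- if (integral) m / 65535 else m / max(mx, 1)
    k <- k + 1L
  }
  if (!integral) {
    # float path: rescale is lossy; store scale in the description
    stop("non-integer intensity stacks are not supported by write_stack(); ",
         "round or rescale to integers first")
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  desc <- ome_description(
    size_z = d[1], size_c = d[2], size_y = d[3], size_x = d[4],
    channel_names = x$channel_names, pixel_size = x$pixel_size
  )
  tiff_set_description(path, desc)
  invisible(path)
}

ome_description <- function(size_z, size_c, size_y, size_x, channel_names,
                            pixel_size = NULL) {
  doc <- xml2::xml_new_root("OME",
    xmlns = "http://www.openmicroscopy.org/Schemas/OME/2016-06")
  img <- xml2::xml_add_child(doc, "Image", ID = "Image:0")
  px <- xml2::xml_add_child(
    img, "Pixels", ID = "Pixels:0", DimensionOrder = "XYCZT", Type = "uint16",
    SizeX = as.character(size_x), SizeY = as.character(size_y),
    SizeC = as.character(size_c), SizeZ = as.character(size_z), SizeT = "1"
  )
  if (!is.null(pixel_size)) {
    xml2::xml_set_attr(px, "PhysicalSizeX", format(pixel_size))
    xml2::xml_set_attr(px, "PhysicalSizeY", format(pixel_size))
  }
  for (i in seq_along(channel_names)) {
    xml2::xml_add_child(px, "Channel", ID = paste0("Channel:0:", i - 1L),
                        Name = channel_names[i])
  }
  as.character(doc)
}

parse_ome_description <- function(desc) {
  empty <- list(size_c = NULL, size_z = NULL, channel_names = NULL,
                pixel_size = NULL)
  if (is.null(desc) || is.na(desc) || !grepl("<OME", desc, fixed = TRUE)) {
    return(empty)
  }
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(empty)
  xml2::xml_ns_strip(doc)
  px <- xml2::xml_find_first(doc, ".//Pixels")
  if (is.na(px)) return(empty)
  num_attr <- function(node, a) {
    v <- xml2::xml_attr(node, a)
    if (is.na(v)) NULL else as.numeric(v)
  }
  chn <- xml2::xml_attr(xml2::xml_find_all(px, ".//Channel"), "Name")
  list(
    size_c = {
      v <- num_attr(px, "SizeC"); if (is.null(v)) NULL else as.integer(v)
    },
    size_z = {
      v <- num_attr(px, "SizeZ"); if (is.null(v)) NULL else as.integer(v)
    },
    channel_names = if (length(chn) > 0 && !anyNA(chn)) chn else NULL,
    pixel_size = num_attr(px, "PhysicalSizeX")
  )
}

# The tiff package cannot write an ImageDescription tag, so it is patched
# into the first IFD in place: a new IFD (old entries + tag 270, sorted) is
# appended at EOF together with the description bytes, and the header's
# first-IFD pointer is redirected. All other offsets are absolute and stay
# valid.
tiff_set_description <- function(path, description) {
  raw <- readBin(path, "raw", file.size(path))
  if (rawToChar(raw[1:2]) != "II") stop("expected a little-endian TIFF")
  u16 <- function(i) readBin(raw[i + (1:2)], "integer", size = 2,
                             endian = "little", signed = FALSE)
  u32 <- function(i) readBin(raw[i + (1:4)], "integer", size = 4,
                             endian = "little")
  w16 <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), raw(), size = 4, endian = "little")

  ifd_off <- u32(4)
  n <- u16(ifd_off)
  entries <- lapply(seq_len(n), function(i) {
    e <- ifd_off + 2 + (i - 1) * 12
    list(tag = u16(e), bytes = raw[(e + 1):(e + 12)])
  })
  next_ptr <- raw[ifd_off + 2 + n * 12 + (1:4)]

  desc_raw <- c(charToRaw(description), as.raw(0))
  desc_off <- length(raw)                     # append description at EOF
  new_ifd_off <- desc_off + length(desc_raw)
  if (new_ifd_off %% 2 == 1) {                # word-align the IFD
    desc_raw <- c(desc_raw, as.raw(0))
    new_ifd_off <- new_ifd_off + 1
  }
  desc_entry <- c(w16(270), w16(2), w32(nchar(description) + 1L), w32(desc_off))
  entries <- c(entries, list(list(tag = 270L, bytes = desc_entry)))
  entries <- entries[order(vapply(entries, `[[`, 0L, "tag"))]
  new_ifd <- c(w16(length(entries)),
               unlist(lapply(entries, `[[`, "bytes")),
               next_ptr)
  out <- c(raw, desc_raw, new_ifd)
  out[5:8] <- w32(new_ifd_off)
  writeBin(out, path)
  invisible(path)
}
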