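# Minimal baseline TIFF codec: little-endian, uncompressed, single-sample
# grayscale, one strip per page, uint16 or float32. This covers the
# camera-native containers of this domain; no compression or palette support.

tiff_write_entry <- function(con, tag, type, value) {
  # type 3 = SHORT, 4 = LONG
  writeBin(as.integer(tag), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(1L, con, size = 4, endian = "little")
  if (type == 3L) {
    writeBin(as.integer(value), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
}

#' Write a multi-page TIFF
#'
#' Uncompressed grayscale baseline TIFF, little-endian, one page per frame.
#'
#' @param frames 3-D numeric array `[ny, nx, n]` (or a matrix for one page).
#' @param path Output path.
#' @param dtype `"float32"` (lossless for float data) or `"uint16"`.
#' @param scale,offset For `uint16`: stored value = `round((v - offset) /
#'   scale)`; computed from the data range when `NULL`.
#' @return List with the quantization `scale` and `offset` used (1 and 0 for
#'   float32), invisibly.
#' @export
write_tiff <- function(frames, path, dtype = c("float32", "uint16"),
                       scale = NULL, offset = NULL) {
  dtype <- match.arg(dtype)
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1))
  ny <- dim(frames)[1]; nx <- dim(frames)[2]; n <- dim(frames)[3]
  if (dtype == "uint16") {
    if (is.null(offset)) offset <- min(frames)
    if (is.null(scale)) {
      rng <- max(frames) - offset
      scale <- if (rng > 0) rng / 65535 else 1
    }
  } else {
    scale <- 1; offset <- 0
  }
  bytes_px <- if (dtype == "uint16") 2L else 4L
  page_bytes <- ny * nx * bytes_px
  ifd_bytes <- 2L + 10L * 12L + 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  first_ifd <- 8L + n * page_bytes
  writeBin(first_ifd, con, size = 4, endian = "little")
  for (j in seq_len(n)) {
    v <- as.vector(t(frames[, , j]))          # TIFF is row-major
    if (dtype == "uint16") {
      iv <- as.integer(pmin(pmax(round((v - offset) / scale), 0), 65535))
      writeBin(iv, con, size = 2, endian = "little")
    } else {
      writeBin(as.double(v), con, size = 4, endian = "little")
    }
  }
  for (j in seq_len(n)) {
    writeBin(10L, con, size = 2, endian = "little")
    tiff_write_entry(con, 256L, 4L, nx)
    tiff_write_entry(con, 257L, 4L, ny)
    tiff_write_entry(con, 258L, 3L, bytes_px * 8L)
    tiff_write_entry(con, 259L, 3L, 1L)       # no compression
    tiff_write_entry(con, 262L, 3L, 1L)       # black is zero
    tiff_write_entry(con, 273L, 4L, 8L + (j - 1L) * page_bytes)
    tiff_write_entry(con, 277L, 3L, 1L)
    tiff_write_entry(con, 278L, 4L, ny)
    tiff_write_entry(con, 279L, 4L, page_bytes)
    tiff_write_entry(con, 339L, 3L, if (dtype == "uint16") 1L else 3L)
    next_ifd <- if (j < n) first_ifd + j * ifd_bytes else 0L
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
  }
  invisible(list(scale = scale, offset = offset))
}

tiff_read_u <- function(raw, at, size) {
  # unsigned little-endian integer from a raw vector, 1-based offset
  sum(as.integer(raw[at:(at + size - 1)]) * 256^(0:(size - 1)))
}

#' Read a multi-page TIFF
#'
#' Reads the subset of baseline TIFF written by [write_tiff()]:
#' little-endian, uncompressed grayscale, uint16 or float32, any number of
#' strips.
#'
#' @param path TIFF file path.
#' @return 3-D numeric array `[ny, nx, n]`; `attr(, "dtype")` records the
#'   stored sample format.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8 || rawToChar(raw[1:2]) != "II" || tiff_read_u(raw, 3, 2) != 42) {
    stop("not a little-endian TIFF file")
  }
  ifd <- tiff_read_u(raw, 5, 4)
  # tag values as a numeric vector; SHORT (3) and LONG (4) supported; arrays
  # that do not fit in the 4 value bytes live at an offset
  tag_values <- function(type, count, at) {
    size <- if (type == 3) 2L else if (type == 4) 4L else return(NULL)
    start <- if (count * size <= 4) at + 8 else tiff_read_u(raw, at + 8, 4) + 1
    vapply(seq_len(count) - 1L,
           function(i) tiff_read_u(raw, start + i * size, size), numeric(1))
  }
  pages <- list()
  dtypes <- character(0)
  while (ifd != 0) {
    n_ent <- tiff_read_u(raw, ifd + 1, 2)
    tags <- list()
    for (e in seq_len(n_ent)) {
      at <- ifd + 3 + (e - 1) * 12
      tag <- tiff_read_u(raw, at, 2)
      type <- tiff_read_u(raw, at + 2, 2)
      count <- tiff_read_u(raw, at + 4, 4)
      v <- tag_values(type, count, at)
      if (!is.null(v)) tags[[as.character(tag)]] <- v
    }
    need <- c("256", "257", "258", "273", "279")
    if (!all(need %in% names(tags))) stop("TIFF page is missing required tags")
    nx <- tags[["256"]][1]; ny <- tags[["257"]][1]
    bps <- unique(tags[["258"]])
    spp <- if (!is.null(tags[["277"]])) tags[["277"]][1] else 1
    if (length(bps) != 1 || spp != 1) {
      stop("only single-sample grayscale TIFF is supported")
    }
    if (!is.null(tags[["259"]]) && tags[["259"]][1] != 1) {
      stop("compressed TIFF is not supported")
    }
    sf <- if (!is.null(tags[["339"]])) tags[["339"]][1] else 1
    dtype <- if (bps == 16 && sf == 1) "uint16"
             else if (bps == 32 && sf == 3) "float32"
             else stop(sprintf("unsupported sample format (bits=%d, format=%d)", bps, sf))
    dtypes <- c(dtypes, dtype)
    bytes_px <- if (dtype == "uint16") 2L else 4L
    offs <- tags[["273"]]
    byte_counts <- tags[["279"]]
    v <- unlist(lapply(seq_along(offs), function(i) {
      npx_i <- byte_counts[i] / bytes_px
      if (dtype == "uint16") {
        readBin(raw[(offs[i] + 1):(offs[i] + byte_counts[i])], "integer",
                npx_i, size = 2, signed = FALSE, endian = "little")
      } else {
        readBin(raw[(offs[i] + 1):(offs[i] + byte_counts[i])], "double",
                npx_i, size = 4, endian = "little")
      }
    }))
    if (length(v) != ny * nx) stop("TIFF strip data does not match the page size")
    pages[[length(pages) + 1]] <- matrix(v, ny, nx, byrow = TRUE)
    ifd <- tiff_read_u(raw, ifd + 3 + n_ent * 12, 4)
  }
  if (length(pages) == 0) stop("TIFF file contains no pages")
  if (length(unique(dtypes)) > 1) stop("mixed sample formats across TIFF pages")
  out <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (j in seq_along(pages)) out[, , j] <- pages[[j]]
  attr(out, "dtype") <- dtypes[1]
  out
}

#' Write a frame stack to TIFF with a JSON sidecar
#'
#' The sidecar (`<path>.json`) records dtype, quantization scale/offset and
#' the per-frame metadata (orientation, timestamp, frame index, blink flag),
#' plus any extra fields supplied (e.g. true shifts and the seed for
#' synthetic stacks).
#'
#' @param stack A [frame_stack()].
#' @param path Output TIFF path.
#' @param dtype `"float32"` or `"uint16"`.
#' @param extra Named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, dtype = c("float32", "uint16"),
                        extra = list()) {
  dtype <- match.arg(dtype)
  qz <- write_tiff(stack$frames, path, dtype)
  meta <- c(list(dtype = dtype, scale = qz$scale, offset = qz$offset,
                 orientation = stack$orientation,
                 timestamp = stack$timestamp,
                 frame_index = stack$frame_index,
                 blink = stack$blink), extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a frame stack written by [write_stack()]
#'
#' Restores intensity scaling from the sidecar. Without a sidecar the
#' orientation labels are inferred by block arithmetic from `frame_rate` and
#' `switching_rate`.
#'
#' @param path TIFF path.
#' @param frame_rate,switching_rate,orientations Used to infer orientation
#'   blocks when no sidecar is present.
#' @return A [frame_stack()]; sidecar extras are kept in `attr(, "meta")`.
#' @export
read_stack <- function(path, frame_rate = NULL, switching_rate = NULL,
                       orientations = c(45, -45)) {
  frames <- read_tiff(path)
  n <- dim(frames)[3]
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (meta$dtype == "uint16") frames <- frames * meta$scale + meta$offset
    ts <- if (!is.null(meta$timestamp)) meta$timestamp else seq_len(n) - 1
    ori <- suppressWarnings(as.numeric(meta$orientation))
    st <- frame_stack(frames, orientation = ori, timestamp = ts,
                      frame_index = meta$frame_index,
                      blink = as.logical(meta$blink))
    attr(st, "meta") <- meta
    return(st)
  }
  if (attr(frames, "dtype") == "uint16") {
    # raw camera counts; no scale information without a sidecar
    frames <- frames * 1.0
  }
  if (is.null(frame_rate) || is.null(switching_rate)) {
    stop("no sidecar: frame_rate and switching_rate are needed to infer orientations")
  }
  fpb <- frame_rate / switching_rate
  if (abs(fpb - round(fpb)) > 1e-9) stop("frame_rate / switching_rate must be an integer")
  blocks <- floor((seq_len(n) - 1) / round(fpb))
  ori <- orientations[(blocks %% length(orientations)) + 1]
  frame_stack(frames, orientation = ori, timestamp = (seq_len(n) - 1) / frame_rate)
}
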