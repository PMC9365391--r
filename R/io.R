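# Readers and writers for the pipeline's on-disk formats: trajectory /
# binding-event / force-extension CSV, and 16-bit grayscale TIFF
# kymographs with a JSON sidecar. The TIFF codec is a deliberately
# minimal baseline implementation (uncompressed, single strip,
# little-endian) because no TIFF package is available in the target
# environment; it round-trips exactly with itself and with standard
# readers.

#' Write trajectories to CSV
#'
#' Columns: trace_id, frame, time_s, x_um, interpolated. Comma
#' separated, dot decimal, header row.
#'
#' @param trajs a [trajectory()] or list of them.
#' @param path output file.
#' @export
write_trajectory_csv <- function(trajs, path) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  rows <- lapply(trajs, function(tr) {
    data.frame(trace_id = attr(tr, "id"), frame = tr$frame,
               time_s = tr$time_s, x_um = tr$x_um,
               interpolated = tr$interpolated)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read trajectories from CSV
#'
#' @param path CSV written by [write_trajectory_csv()].
#' @return named list of [trajectory()] objects, one per trace_id.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trace_id", "time_s", "x_um")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have columns ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$trace_id), function(d)
    as_trajectory(d, id = d$trace_id[1]))
  out[unique(df$trace_id)]
}

#' Write binding events to CSV
#' @param events a `binding_events` data.frame.
#' @param path output file.
#' @export
write_binding_events_csv <- function(events, path) {
  df <- as.data.frame(events)
  df$concentration_M <- attr(events, "concentration_M")
  df$dna_length_bp <- attr(events, "dna_length_bp")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read binding events from CSV
#' @param path CSV written by [write_binding_events_csv()].
#' @return a `binding_events` data.frame.
#' @export
read_binding_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  conc <- df$concentration_M[1]; len <- df$dna_length_bp[1]
  df$concentration_M <- NULL; df$dna_length_bp <- NULL
  structure(df, class = c("binding_events", "data.frame"),
            concentration_M = conc, dna_length_bp = len)
}

#' Write a force-extension curve to CSV
#' @param curve a `force_extension` data.frame.
#' @param path output file.
#' @export
write_force_extension_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a force-extension curve from CSV
#' @param path CSV with columns force_pN, distance_um (and optionally
#'   segment).
#' @return a `force_extension` data.frame.
#' @export
read_force_extension_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(df, class = c("force_extension", "data.frame"))
}

# --- minimal baseline TIFF (16-bit grayscale, single strip) ----------

#' Write a kymograph as a 16-bit grayscale TIFF
#'
#' Rows are pixels (space), columns scan lines (time). Pixel size and
#' line time go into a JSON sidecar at `paste0(path, ".json")`, never
#' into TIFF tags, together with any extra metadata supplied.
#'
#' @param kymo a [kymograph()].
#' @param path output .tif path.
#' @param metadata optional named list merged into the sidecar.
#' @export
write_kymograph_tiff <- function(kymo, path, metadata = list()) {
  stopifnot(inherits(kymo, "kymograph"))
  m <- kymo$counts
  if (any(m > 65535)) stop("counts exceed 16-bit range")
  h <- nrow(m); w <- ncol(m)
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2,
                             endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4,
                             endian = "little")
  writeBin(charToRaw("II"), con); w2(42L); w4(8L)  # header, IFD at 8
  n_tags <- 8L
  ifd_size <- 2 + n_tags * 12 + 4
  data_off <- 8 + ifd_size
  tag <- function(id, type, count, value) {
    w2(id); w2(type); w4(count); w4(value)
  }
  w2(n_tags)
  tag(256L, 3L, 1L, w)                 # ImageWidth
  tag(257L, 3L, 1L, h)                 # ImageLength
  tag(258L, 3L, 1L, 16L)               # BitsPerSample
  tag(259L, 3L, 1L, 1L)                # Compression: none
  tag(262L, 3L, 1L, 1L)                # Photometric: BlackIsZero
  tag(273L, 4L, 1L, data_off)          # StripOffsets
  tag(277L, 3L, 1L, 1L)                # SamplesPerPixel
  tag(279L, 4L, 1L, 2L * w * h)        # StripByteCounts
  w4(0L)                               # no next IFD
  # row-major pixel data (row = spatial pixel); map to signed 16-bit
  # two's complement for writeBin
  v <- as.integer(t(m))
  v[v > 32767L] <- v[v > 32767L] - 65536L
  writeBin(v, con, size = 2, endian = "little")
  meta <- c(list(pixel_size_um = kymo$pixel_size_um,
                 line_time_s = kymo$line_time_s,
                 n_pixels = h, n_lines = w), metadata)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a kymograph from a 16-bit grayscale TIFF
#'
#' Understands uncompressed single-sample baseline TIFF (both byte
#' orders, 8 or 16 bit, one or more strips). Pixel size and line time
#' are taken from the JSON sidecar; if absent they must be supplied.
#'
#' @param path .tif path.
#' @param pixel_size_um,line_time_s overrides when there is no sidecar.
#' @return a [kymograph()].
#' @export
read_kymograph_tiff <- function(path, pixel_size_um = NULL,
                                line_time_s = NULL) {
  raw <- readBin(path, "raw", file.info(path)$size)
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big"
            else stop("not a TIFF file")
  rd <- function(off, size, n = 1L)
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n,
            size = size, endian = endian, signed = size >= 4L)
  if (rd(2, 2) != 42L) stop("not a TIFF file")
  ifd <- rd(4, 4)
  n_tags <- rd(ifd, 2)
  tags <- list()
  for (i in seq_len(n_tags)) {
    base <- ifd + 2 + (i - 1) * 12
    id <- rd(base, 2); type <- rd(base + 2, 2); count <- rd(base + 4, 4)
    val <- if (type == 3L && count == 1L) rd(base + 8, 2)
           else rd(base + 8, 4)
    tags[[as.character(id)]] <- list(type = type, count = count,
                                     value = val, off = base + 8)
  }
  need <- function(id, default = NULL) {
    t <- tags[[as.character(id)]]
    if (is.null(t)) {
      if (is.null(default)) stop("missing TIFF tag ", id)
      return(default)
    }
    t$value
  }
  w <- need(256); h <- need(257)
  bits <- need(258, 1L); comp <- need(259, 1L)
  if (comp != 1L) stop("only uncompressed TIFF is supported")
  if (!bits %in% c(8L, 16L)) stop("only 8/16-bit TIFF is supported")
  spp <- need(277, 1L)
  if (spp != 1L) stop("only single-sample (grayscale) TIFF is supported")
  bytes <- bits / 8L
  so_tag <- tags[["273"]]; sc_tag <- tags[["279"]]
  get_vec <- function(t, size) {
    if (t$count == 1L) return(t$value)
    rd(t$value, size, n = t$count)
  }
  offsets <- get_vec(so_tag, 4L)
  counts <- get_vec(sc_tag, 4L)
  px <- unlist(lapply(seq_along(offsets), function(k)
    rd(offsets[k], bytes, n = counts[k] / bytes)))
  m <- matrix(as.integer(px), nrow = h, byrow = TRUE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(pixel_size_um)) pixel_size_um <- meta$pixel_size_um
    if (is.null(line_time_s)) line_time_s <- meta$line_time_s
  }
  if (is.null(pixel_size_um) || is.null(line_time_s))
    stop("no sidecar; supply pixel_size_um and line_time_s")
  kymograph(m, pixel_size_um, line_time_s)
}
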