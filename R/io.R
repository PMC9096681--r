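# Readers/writers: PLY (ascii + binary_little_endian), XYZ text, float32
# grayscale TIFF, CSV temperature grids, calibration JSON/YAML.
# Property names `reflectance` and `temperature` are the stable external
# contract; unknown PLY vertex properties ride along in cloud$extra.

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

#' Read a point cloud from PLY or XYZ
#'
#' PLY vertex elements must carry `x`, `y`, `z`; `reflectance` and
#' `temperature` properties are mapped to the cloud attributes of the same
#' name, any other vertex property is preserved in the `extra` table.
#' XYZ files are whitespace-separated text with 3 (coordinates),
#' 4 (+reflectance) or 5 (+temperature) columns.
#'
#' @param path input file.
#' @param format `"ply"`, `"xyz"`, or `"auto"` (by extension).
#' @return A [point_cloud()].
#' @export
read_point_cloud <- function(path, format = c("auto", "ply", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "xyz") return(read_xyz(path))
  read_ply(path)
}

read_xyz <- function(path) {
  tab <- tryCatch(read.table(path, header = FALSE),
                  error = function(e) stop("format error reading XYZ: ",
                                           conditionMessage(e)))
  if (ncol(tab) < 3) stop("format error: XYZ needs at least 3 columns")
  point_cloud(as.matrix(tab[, 1:3]),
              reflectance = if (ncol(tab) >= 4) tab[[4]],
              temperature = if (ncol(tab) >= 5) tab[[5]])
}

read_ply <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  # locate the end of the header ("end_header\n") in the byte stream
  mark <- grepRaw("end_header\n", raw, fixed = TRUE)
  mark_len <- 11L
  if (length(mark) == 0) {
    mark <- grepRaw("end_header\r\n", raw, fixed = TRUE)
    mark_len <- 12L
  }
  if (length(mark) == 0) stop("format error: PLY header not terminated")
  data_off <- mark[1] + mark_len - 1L
  header <- strsplit(rawToChar(raw[seq_len(data_off)]), "\r?\n")[[1]]
  if (!identical(trimws(header[1]), "ply"))
    stop("format error: missing 'ply' magic")
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1) stop("format error: missing format line")
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("format error: unsupported PLY format '", fmt, "'")

  # parse elements/properties (list properties unsupported)
  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0) next
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  prop_names = character(), prop_types = character())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list")
        stop("format error: PLY list properties are not supported")
      cur$prop_types <- c(cur$prop_types, tok[2])
      cur$prop_names <- c(cur$prop_names, tok[3])
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  vert <- elements[["vertex"]]
  if (is.null(vert)) stop("format error: no vertex element")
  if (!all(c("x", "y", "z") %in% vert$prop_names))
    stop("format error: vertex element lacks x, y, z")
  if (!all(vert$prop_types %in% names(ply_type_size)))
    stop("format error: unknown property type")

  np <- length(vert$prop_names)
  if (vert$count == 0) {
    vals <- matrix(numeric(0), 0, np)
  } else if (fmt == "ascii") {
    body <- rawToChar(raw[(data_off + 1):length(raw)])
    tab <- tryCatch(
      read.table(text = body, header = FALSE, nrows = vert$count,
                 col.names = vert$prop_names,
                 colClasses = rep("numeric", np)),
      error = function(e) stop("corrupt file: ", conditionMessage(e)))
    if (nrow(tab) != vert$count)
      stop("corrupt file: expected ", vert$count, " vertices, got ",
           nrow(tab))
    vals <- as.matrix(tab)
  } else {
    sizes <- ply_type_size[vert$prop_types]
    row_size <- sum(sizes)
    raw <- raw[(data_off + 1):length(raw)]
    if (length(raw) < row_size * vert$count)
      stop("corrupt file: truncated binary vertex data")
    offsets <- c(0L, cumsum(sizes))[seq_len(np)]
    row_starts <- (seq_len(vert$count) - 1L) * row_size
    vals <- matrix(0, vert$count, np)
    for (p in seq_len(np)) {
      sz <- sizes[p]
      idx <- as.vector(outer(seq_len(sz), row_starts + offsets[p], "+"))
      bytes <- raw[idx]
      ty <- vert$prop_types[p]
      vals[, p] <- switch(ty,
        float = , float32 = readBin(bytes, "numeric", n = vert$count,
                                    size = 4, endian = "little"),
        double = , float64 = readBin(bytes, "numeric", n = vert$count,
                                     size = 8, endian = "little"),
        char = , int8 = readBin(bytes, "integer", n = vert$count, size = 1,
                                signed = TRUE, endian = "little"),
        uchar = , uint8 = readBin(bytes, "integer", n = vert$count, size = 1,
                                  signed = FALSE, endian = "little"),
        short = , int16 = readBin(bytes, "integer", n = vert$count, size = 2,
                                  signed = TRUE, endian = "little"),
        ushort = , uint16 = readBin(bytes, "integer", n = vert$count,
                                    size = 2, signed = FALSE,
                                    endian = "little"),
        readBin(bytes, "integer", n = vert$count, size = 4,
                endian = "little"))
    }
    colnames(vals) <- vert$prop_names
  }
  colnames(vals) <- vert$prop_names
  known <- c("x", "y", "z", "reflectance", "temperature")
  extra_names <- setdiff(vert$prop_names, known)
  point_cloud(vals[, c("x", "y", "z"), drop = FALSE],
              reflectance = if ("reflectance" %in% vert$prop_names)
                vals[, "reflectance"],
              temperature = if ("temperature" %in% vert$prop_names)
                vals[, "temperature"],
              extra = if (length(extra_names))
                as.data.frame(vals[, extra_names, drop = FALSE]))
}

#' Write a point cloud to PLY or XYZ
#'
#' PLY stores coordinates and reflectance as 64-bit floats and temperature
#' as a 32-bit float property named `temperature`; the out-of-view sentinel
#' value is written verbatim, never dropped.
#'
#' @param cloud a [point_cloud()].
#' @param path output file.
#' @param format `"ply_ascii"`, `"ply_binary"`, or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud,
                              path,
                              format = c("ply_ascii", "ply_binary", "xyz")) {
  format <- match.arg(format)
  n <- n_points(cloud)
  if (format == "xyz") {
    # columns are positional: temperature implies a reflectance column
    refl <- cloud$reflectance
    if (is.null(refl) && !is.null(cloud$temperature))
      refl <- rep(0, n)
    cols <- cbind(cloud$points, refl, cloud$temperature)
    write.table(format(cols, digits = 17, trim = TRUE, scientific = FALSE),
                path, row.names = FALSE, col.names = FALSE,
                quote = FALSE)
    return(invisible(path))
  }
  props <- c("property double x", "property double y", "property double z")
  if (!is.null(cloud$reflectance))
    props <- c(props, "property double reflectance")
  if (!is.null(cloud$temperature))
    props <- c(props, "property float temperature")
  header <- c("ply",
              paste("format",
                    if (format == "ply_ascii") "ascii"
                    else "binary_little_endian", "1.0"),
              "comment written by thermocloud",
              paste("element vertex", n),
              props,
              "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (n == 0) return(invisible(path))
  if (format == "ply_ascii") {
    fields <- list(sprintf("%.17g", cloud$points[, 1]),
                   sprintf("%.17g", cloud$points[, 2]),
                   sprintf("%.17g", cloud$points[, 3]))
    if (!is.null(cloud$reflectance))
      fields <- c(fields, list(sprintf("%.17g", cloud$reflectance)))
    if (!is.null(cloud$temperature))
      fields <- c(fields, list(sprintf("%.9g", cloud$temperature)))
    writeLines(do.call(paste, fields), con, sep = "\n")
  } else {
    for (i in seq_len(n)) {
      writeBin(cloud$points[i, ], con, size = 8, endian = "little")
      if (!is.null(cloud$reflectance))
        writeBin(cloud$reflectance[i], con, size = 8, endian = "little")
      if (!is.null(cloud$temperature))
        writeBin(cloud$temperature[i], con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' Read a radiometric thermal image
#'
#' Pixel values must already be in degrees C (radiometric export); no
#' rescaling is applied. Supported formats: 32-bit float grayscale TIFF
#' and rectangular CSV grids.
#'
#' @param path input file.
#' @param format `"tiff32"`, `"csv"`, or `"auto"` (by extension).
#' @return A [thermal_image()].
#' @export
read_thermal_image <- function(path, format = c("auto", "tiff32", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE))
      "tiff32" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    rows <- strsplit(lines, ",")
    ncols <- lengths(rows)
    if (length(unique(ncols)) != 1)
      stop("format error: non-rectangular CSV grid")
    vals <- matrix(as.numeric(unlist(rows)), nrow = length(rows),
                   byrow = TRUE)
    if (anyNA(vals)) stop("format error: non-numeric CSV entries")
    return(thermal_image(vals))
  }
  thermal_image(read_tiff_f32(path))
}

#' Write a radiometric thermal image
#'
#' @param image a [thermal_image()].
#' @param path output file.
#' @param format `"tiff32"` (32-bit float grayscale TIFF) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_thermal_image <- function(image, path, format = c("tiff32", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    write.table(format(image$values, digits = 17, trim = TRUE,
                       scientific = FALSE),
                path, sep = ",", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
    return(invisible(path))
  }
  write_tiff_f32(image$values, path)
  invisible(path)
}

# --- minimal baseline TIFF, 32-bit IEEE float, single sample -------------
# The r-tiff package clamps values into [0,1] on write, which destroys
# radiometric degC grids, hence this small reader/writer pair.

write_tiff_f32 <- function(values, path) {
  h <- nrow(values); w <- ncol(values)
  con <- file(path, "wb")
  on.exit(close(con))
  data_offset <- 8L
  nbytes <- 4L * w * h
  ifd_offset <- data_offset + nbytes
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  # pixel data, row-major (row = image row, top first)
  writeBin(as.numeric(t(values)), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) { # SHORT padded to 4 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  tags <- list(
    c(256, 4, w),       # ImageWidth
    c(257, 4, h),       # ImageLength
    c(258, 3, 32),      # BitsPerSample
    c(259, 3, 1),       # Compression: none
    c(262, 3, 1),       # Photometric: BlackIsZero
    c(273, 4, 8),       # StripOffsets
    c(277, 3, 1),       # SamplesPerPixel
    c(278, 4, h),       # RowsPerStrip
    c(279, 4, nbytes),  # StripByteCounts
    c(339, 3, 3))       # SampleFormat: IEEE float
  writeBin(length(tags), con, size = 2, endian = "little")
  for (tg in tags) entry(tg[1], tg[2], 1, tg[3])
  writeBin(0L, con, size = 4, endian = "little") # no next IFD
  invisible(path)
}

read_tiff_f32 <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("format error: not a TIFF")
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stop("format error: not a TIFF")
  rint <- function(at, size, n = 1)
    readBin(raw[(at + 1):(at + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size == 4)
  if (rint(2, 2) != 42L) stop("format error: bad TIFF magic")
  ifd <- rint(4, 4)
  n_entries <- rint(ifd, 2)
  tags <- list()
  for (e in seq_len(n_entries)) {
    at <- ifd + 2 + (e - 1) * 12
    tag <- rint(at, 2); type <- rint(at + 2, 2); count <- rint(at + 4, 4)
    size <- c(1L, 1L, 2L, 4L)[match(type, c(1, 2, 3, 4))]
    if (is.na(size)) next
    if (size * count <= 4) {
      val <- rint(at + 8, size, count)
    } else {
      off <- rint(at + 8, 4)
      val <- rint(off, size, count)
    }
    tags[[as.character(tag)]] <- val
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("format error: missing TIFF tag ", tag)
      default
    } else v
  }
  w <- need(256); h <- need(257)
  bits <- need(258, 32); fmt <- need(339, 1)
  if (need(259, 1) != 1) stop("format error: compressed TIFF unsupported")
  if (!(all(bits == 32) && all(fmt == 3)))
    stop("format error: only 32-bit float TIFF supported")
  offsets <- need(273); counts <- need(279, w * h * 4)
  data <- raw(0)
  for (s in seq_along(offsets))
    data <- c(data, raw[(offsets[s] + 1):(offsets[s] + counts[s])])
  vals <- readBin(data, "numeric", n = w * h, size = 4, endian = endian)
  if (length(vals) != w * h) stop("corrupt file: truncated TIFF data")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a calibration file (intrinsics + extrinsics)
#'
#' Keys: `fx, fy, cx, cy, k1, k2, k3, p1, p2, R` (row-major 9), `t` (3),
#' `units`, plus a free-form `metadata` block. Round-trips losslessly.
#'
#' @param intrinsics a [camera_intrinsics()].
#' @param extrinsics a [rigid_transform()] (LiDAR to camera), or NULL.
#' @param path output file, `.json` or `.yaml`/`.yml`.
#' @param metadata optional named list (pattern spec, creation info).
#' @return `path`, invisibly.
#' @export
write_calibration <- function(intrinsics, extrinsics = NULL, path,
                              metadata = list()) {
  obj <- list(fx = intrinsics$fx, fy = intrinsics$fy,
              cx = intrinsics$cx, cy = intrinsics$cy,
              k1 = intrinsics$k1, k2 = intrinsics$k2, k3 = intrinsics$k3,
              p1 = intrinsics$p1, p2 = intrinsics$p2,
              units = "m", metadata = metadata)
  if (!is.null(extrinsics)) {
    obj$R <- as.numeric(t(extrinsics$R)) # row-major
    obj$t <- extrinsics$t
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    writeLines(yaml::as.yaml(obj, precision = 17), path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a calibration file
#'
#' @param path a `.json` or `.yaml`/`.yml` file written by
#'   [write_calibration()] (or following the same keys).
#' @return List with `intrinsics` ([camera_intrinsics()]), `extrinsics`
#'   ([rigid_transform()] or NULL) and `metadata`.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  intr <- camera_intrinsics(fx = obj$fx, fy = obj$fy, cx = obj$cx,
                            cy = obj$cy, k1 = obj$k1 %||% 0,
                            k2 = obj$k2 %||% 0, k3 = obj$k3 %||% 0,
                            p1 = obj$p1 %||% 0, p2 = obj$p2 %||% 0)
  extr <- NULL
  if (!is.null(obj$R))
    extr <- rigid_transform(t(matrix(as.numeric(obj$R), 3, 3)),
                            as.numeric(obj$t))
  list(intrinsics = intr, extrinsics = extr,
       metadata = obj$metadata %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
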