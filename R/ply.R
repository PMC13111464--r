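# PLY vertex I/O (ASCII and binary little-endian).
#
# Scope: files whose first element is "vertex" with float x,y,z, uchar
# red,green,blue and an optional scalar "label" property — the layout written
# by common point-cloud editors for labeled colored clouds. Coordinates are
# stored as 32-bit floats, the format's conventional width.

.ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                    short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                    int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_column <- function(body, offsets, type, n) {
  sz <- .ply_type_size[[type]]
  idx <- as.vector(outer(seq_len(sz), offsets, `+`)) - 1L
  bytes <- body[idx]
  switch(type,
    char = , int8 = readBin(bytes, "integer", n, size = 1L, signed = TRUE),
    uchar = , uint8 = as.integer(bytes),
    short = , int16 = readBin(bytes, "integer", n, size = 2L,
                              signed = TRUE, endian = "little"),
    ushort = , uint16 = readBin(bytes, "integer", n, size = 2L,
                                signed = FALSE, endian = "little"),
    int = , int32 = , uint = , uint32 =
      readBin(bytes, "integer", n, size = 4L, endian = "little"),
    float = , float32 = readBin(bytes, "numeric", n, size = 4L,
                                endian = "little"),
    double = , float64 = readBin(bytes, "numeric", n, size = 8L,
                                 endian = "little"))
}

#' Read a PLY point cloud
#'
#' Parses the vertex element of an ASCII or binary little-endian PLY file into
#' a [point_cloud()]. The header must declare float `x`, `y`, `z` and uchar
#' `red`, `green`, `blue`; a scalar `label` property is picked up when
#' present.
#'
#' @param path path to a `.ply` file.
#' @return a `point_cloud`; `labels` is non-`NULL` iff the file has a `label`
#'   property.
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL; nvert <- NULL
  props <- character(); types <- character()
  in_vertex <- FALSE
  header_bytes <- nchar(magic, type = "bytes") + 1L
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L)
      stop(sprintf("malformed PLY header (no end_header) at byte %d",
                   header_bytes))
    header_bytes <- header_bytes + nchar(line, type = "bytes") + 1L
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(tok) == 0L) next
    if (tok[1L] == "comment") next
    if (tok[1L] == "format") {
      fmt <- tok[2L]
      if (!fmt %in% c("ascii", "binary_little_endian"))
        stop("unsupported PLY format: ", fmt)
    } else if (tok[1L] == "element") {
      if (tok[2L] == "vertex") {
        in_vertex <- TRUE
        nvert <- as.integer(tok[3L])
      } else {
        if (!in_vertex && is.null(nvert))
          stop("PLY element '", tok[2L], "' precedes the vertex element")
        in_vertex <- FALSE
      }
    } else if (tok[1L] == "property" && in_vertex) {
      if (tok[2L] == "list") stop("list properties on vertices unsupported")
      if (!tok[2L] %in% names(.ply_type_size))
        stop("unknown PLY property type: ", tok[2L])
      types <- c(types, tok[2L])
      props <- c(props, tok[3L])
    } else if (tok[1L] == "end_header") break
  }
  need <- c("x", "y", "z", "red", "green", "blue")
  missing <- setdiff(need, props)
  if (length(missing))
    stop("PLY vertex element lacks propert",
         if (length(missing) > 1) "ies: " else "y: ",
         paste(missing, collapse = ", "))
  if (is.null(nvert)) stop("PLY file has no vertex element")

  if (fmt == "ascii") {
    txt <- readLines(con, n = nvert)
    if (length(txt) < nvert)
      stop(sprintf("truncated PLY body: %d of %d vertex rows (from byte %d)",
                   length(txt), nvert, header_bytes))
    vals <- scan(text = txt, what = numeric(), quiet = TRUE)
    if (length(vals) != nvert * length(props))
      stop(sprintf("malformed ASCII vertex rows near byte %d", header_bytes))
    m <- matrix(vals, ncol = length(props), byrow = TRUE)
    colnames(m) <- props
    cols <- lapply(props, function(p) m[, p])
    names(cols) <- props
  } else {
    row_size <- sum(.ply_type_size[types])
    body <- readBin(con, "raw", n = row_size * nvert + 1L)
    if (length(body) < row_size * nvert)
      stop(sprintf(
        "truncated PLY body at byte %d: expected %d bytes, found %d",
        header_bytes + length(body), row_size * nvert, length(body)))
    starts <- cumsum(c(0L, .ply_type_size[types]))[seq_along(props)]
    offs0 <- (seq_len(nvert) - 1L) * row_size
    cols <- lapply(seq_along(props), function(j)
      .ply_read_column(body, offs0 + starts[j] + 1L, types[j], nvert))
    names(cols) <- props
  }
  point_cloud(cbind(cols$x, cols$y, cols$z),
              cbind(cols$red, cols$green, cols$blue),
              labels = if ("label" %in% props) as.integer(cols$label))
}

#' Write a point cloud to PLY
#'
#' Emits float32 `x,y,z`, uchar `red,green,blue` and, when the cloud is
#' labeled, an int32 `label` property. Binary files round-trip through
#' [read_ply()] bit-exactly for float-representable coordinates; ASCII uses 9
#' significant digits (deviation below 1e-6 mm at bench scale).
#'
#' @param cloud a `point_cloud`.
#' @param path output path.
#' @param format `"binary_le"` (default) or `"ascii"`.
#' @return `invisible(path)`.
#' @export
write_ply <- function(cloud, path, format = c("binary_le", "ascii")) {
  format <- match.arg(format)
  n <- n_points(cloud)
  labeled <- !is.null(cloud$labels)
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (format == "ascii") "ascii" else "binary_little_endian"),
           sprintf("element vertex %d", n),
           "property float x", "property float y", "property float z",
           "property uchar red", "property uchar green", "property uchar blue",
           if (labeled) "property int label",
           "end_header")
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (n == 0L) return(invisible(path))
  if (format == "ascii") {
    rows <- sprintf("%.9g %.9g %.9g %d %d %d",
                    cloud$coords[, 1], cloud$coords[, 2], cloud$coords[, 3],
                    cloud$colors[, 1], cloud$colors[, 2], cloud$colors[, 3])
    if (labeled) rows <- paste(rows, cloud$labels)
    writeLines(rows, con, sep = "\n")
  } else {
    coords_raw <- matrix(writeBin(as.numeric(t(cloud$coords)), raw(),
                                  size = 4L, endian = "little"), nrow = 12L)
    colors_raw <- matrix(as.raw(t(cloud$colors)), nrow = 3L)
    if (labeled) {
      lab_raw <- matrix(writeBin(cloud$labels, raw(), size = 4L,
                                 endian = "little"), nrow = 4L)
      body <- rbind(coords_raw, colors_raw, lab_raw)
    } else {
      body <- rbind(coords_raw, colors_raw)
    }
    writeBin(as.vector(body), con)
  }
  invisible(path)
}
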