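## PLY (Polygon File Format) reader/writer, ASCII and binary_little_endian.
## Only the vertex element is interpreted; other elements are skipped.

.plyTypeSize <- c(
  char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
  short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
  int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
  float = 4L, float32 = 4L, double = 8L, float64 = 8L
)

.plyReadBin <- function(raw, type, n) {
  switch(type,
    char = , int8 = readBin(raw, "integer", n, size = 1, signed = TRUE),
    uchar = , uint8 = readBin(raw, "integer", n, size = 1, signed = FALSE),
    short = , int16 = readBin(raw, "integer", n, size = 2, signed = TRUE, endian = "little"),
    ushort = , uint16 = readBin(raw, "integer", n, size = 2, signed = FALSE, endian = "little"),
    int = , int32 = readBin(raw, "integer", n, size = 4, endian = "little"),
    uint = , uint32 = {
      v <- readBin(raw, "integer", n, size = 4, endian = "little")
      ifelse(v < 0, v + 2^32, as.double(v))
    },
    float = , float32 = readBin(raw, "double", n, size = 4, endian = "little"),
    double = , float64 = readBin(raw, "double", n, size = 8, endian = "little"),
    stop("unsupported PLY property type: ", type)
  )
}

.parsePlyHeader <- function(con) {
  magic <- readLines(con, n = 1)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file (missing 'ply' magic)")
  format <- NULL
  elements <- list()
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("malformed PLY header: no end_header")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "comment" || tok[1] == "obj_info") next
    if (tok[1] == "format") {
      format <- tok[2]
      if (!format %in% c("ascii", "binary_little_endian")) {
        stop("unsupported PLY format: ", format)
      }
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("malformed PLY header: property before element")
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[5], type = "list", countType = tok[3], itemType = tok[4])
      } else {
        cur$props[[length(cur$props) + 1]] <- list(name = tok[3], type = tok[2])
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    } else {
      stop("malformed PLY header line: ", line)
    }
  }
  if (is.null(format)) stop("malformed PLY header: no format line")
  list(format = format, elements = elements)
}

#' Read a PLY point cloud
#'
#' Reads ASCII or binary (little-endian) PLY files. The vertex element must
#' provide \code{x,y,z} coordinates; colors are taken from
#' \code{red,green,blue} (or \code{r,g,b}) properties and normalized to
#' \[0, 1\] (8-bit integer channels are divided by 255, float channels are
#' taken as-is). Optional \code{nx,ny,nz} normals and an optional integer
#' \code{label} property are read into the corresponding slots. Point order
#' is preserved. A file without color properties loads with a warning and
#' no colors.
#'
#' @param path path to a PLY file.
#' @return A [PointCloud-class].
#' @seealso [writePLY()]
#' @export
readPLY <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- .parsePlyHeader(con)
  if (!"vertex" %in% names(hdr$elements)) stop("PLY has no vertex element")

  cols <- list()
  for (el in hdr$elements) {
    pnames <- vapply(el$props, `[[`, "", "name")
    if (hdr$format == "ascii") {
      if (any(vapply(el$props, function(p) p$type == "list", TRUE))) {
        lines <- readLines(con, n = el$count)
        vals <- NULL
      } else {
        vals <- scan(con, what = double(), n = el$count * length(el$props), quiet = TRUE)
        vals <- matrix(vals, nrow = el$count, ncol = length(el$props), byrow = TRUE)
      }
      if (el$name == "vertex") {
        if (is.null(vals)) stop("list properties on the vertex element are not supported")
        colnames(vals) <- pnames
        cols <- lapply(seq_along(pnames), function(j) vals[, j])
        names(cols) <- pnames
      }
    } else {
      hasList <- any(vapply(el$props, function(p) p$type == "list", TRUE))
      if (!hasList) {
        sizes <- vapply(el$props, function(p) .plyTypeSize[[p$type]], 1L)
        rowsize <- sum(sizes)
        raw <- readBin(con, "raw", n = as.double(el$count) * rowsize)
        if (length(raw) < el$count * rowsize) stop("truncated PLY data for element ", el$name)
        if (el$name == "vertex") {
          offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
          base <- rep((0:(el$count - 1)) * rowsize, each = 1)
          for (j in seq_along(el$props)) {
            sz <- sizes[j]
            idx <- as.vector(outer(seq_len(sz), base + offs[j], `+`))
            cols[[pnames[j]]] <- .plyReadBin(raw[idx], el$props[[j]]$type, el$count)
          }
        }
      } else {
        # skip list-bearing element row by row
        for (i in seq_len(el$count)) {
          for (p in el$props) {
            if (p$type == "list") {
              cnt <- .plyReadBin(
                readBin(con, "raw", .plyTypeSize[[p$countType]]), p$countType, 1
              )
              invisible(readBin(con, "raw", cnt * .plyTypeSize[[p$itemType]]))
            } else {
              invisible(readBin(con, "raw", .plyTypeSize[[p$type]]))
            }
          }
        }
        if (el$name == "vertex") stop("list properties on the vertex element are not supported")
      }
    }
  }

  if (!all(c("x", "y", "z") %in% names(cols))) {
    stop("PLY vertex element lacks x,y,z coordinate properties")
  }
  xyz <- cbind(cols$x, cols$y, cols$z)

  vprops <- hdr$elements$vertex$props
  ptype <- vapply(vprops, `[[`, "", "type")
  names(ptype) <- vapply(vprops, `[[`, "", "name")
  rgbNames <- if (all(c("red", "green", "blue") %in% names(cols))) {
    c("red", "green", "blue")
  } else if (all(c("r", "g", "b") %in% names(cols))) c("r", "g", "b") else NULL
  colors <- NULL
  if (!is.null(rgbNames)) {
    colors <- cbind(cols[[rgbNames[1]]], cols[[rgbNames[2]]], cols[[rgbNames[3]]])
    intTypes <- c("char", "uchar", "int8", "uint8", "short", "ushort",
                  "int16", "uint16", "int", "uint", "int32", "uint32")
    if (ptype[[rgbNames[1]]] %in% intTypes) colors <- colors / 255
    colors <- pmin(pmax(colors, 0), 1)
  } else {
    warning("PLY vertex element has no color properties; loading without colors")
  }
  normals <- NULL
  if (all(c("nx", "ny", "nz") %in% names(cols))) {
    normals <- cbind(cols$nx, cols$ny, cols$nz)
    nn <- sqrt(rowSums(normals^2))
    bad <- !is.finite(nn) | nn == 0
    normals[bad, ] <- NA_real_
    normals[!bad, ] <- normals[!bad, , drop = FALSE] / nn[!bad]
  }
  labels <- if ("label" %in% names(cols)) as.integer(cols$label) else NULL
  pointCloud(xyz, colors = colors, normals = normals, labels = labels)
}

#' Write a PLY point cloud
#'
#' Writes coordinates as float properties and colors (if present) as 8-bit
#' \code{red,green,blue}. Normals and labels are written when present in the
#' cloud (as \code{nx,ny,nz} float and \code{label} int properties) unless
#' disabled.
#'
#' @param cloud a nonempty [PointCloud-class].
#' @param path output path.
#' @param ascii write the ASCII dialect (default); otherwise
#'   binary_little_endian.
#' @param writeNormals,writeLabels include normals / labels if present.
#' @return \code{path}, invisibly.
#' @seealso [readPLY()]
#' @export
writePLY <- function(cloud, path, ascii = TRUE, writeNormals = TRUE,
                     writeLabels = TRUE) {
  stopifnot(is(cloud, "PointCloud"))
  n <- nPoints(cloud)
  if (n == 0) stop("refusing to write an empty PointCloud")
  hasCol <- nrow(cloud@colors) > 0
  hasNrm <- writeNormals && nrow(cloud@normals) > 0 && !anyNA(cloud@normals)
  hasLab <- writeLabels && length(cloud@labels) > 0

  hdr <- c(
    "ply",
    sprintf("format %s 1.0", if (ascii) "ascii" else "binary_little_endian"),
    sprintf("element vertex %d", n),
    "property float x", "property float y", "property float z"
  )
  if (hasCol) hdr <- c(hdr, "property uchar red", "property uchar green", "property uchar blue")
  if (hasNrm) hdr <- c(hdr, "property float nx", "property float ny", "property float nz")
  if (hasLab) hdr <- c(hdr, "property int label")
  hdr <- c(hdr, "end_header")

  col8 <- if (hasCol) round(cloud@colors * 255) else NULL
  if (ascii) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    parts <- list(
      format(cloud@coords[, 1], trim = TRUE, digits = 9),
      format(cloud@coords[, 2], trim = TRUE, digits = 9),
      format(cloud@coords[, 3], trim = TRUE, digits = 9)
    )
    if (hasCol) parts <- c(parts, list(col8[, 1], col8[, 2], col8[, 3]))
    if (hasNrm) {
      parts <- c(parts, lapply(1:3, function(j) {
        format(cloud@normals[, j], trim = TRUE, digits = 9)
      }))
    }
    if (hasLab) parts <- c(parts, list(cloud@labels))
    writeLines(do.call(paste, parts), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    specs <- list(list(v = as.vector(t(cloud@coords)), size = 4L, per = 3L, int = FALSE))
    if (hasCol) specs <- c(specs, list(list(v = as.integer(t(col8)), size = 1L, per = 3L, int = TRUE)))
    if (hasNrm) specs <- c(specs, list(list(v = as.vector(t(cloud@normals)), size = 4L, per = 3L, int = FALSE)))
    if (hasLab) specs <- c(specs, list(list(v = as.integer(cloud@labels), size = 4L, per = 1L, int = TRUE)))
    blobs <- lapply(specs, function(s) {
      b <- writeBin(if (s$int) as.integer(s$v) else as.double(s$v),
                    raw(), size = s$size, endian = "little")
      matrix(b, nrow = s$per * s$size, ncol = n)
    })
    writeBin(as.vector(do.call(rbind, blobs)), con)
  }
  invisible(path)
}

#' Read a camera track
#'
#' Plain-text table of camera positions: three numeric columns (x, y, z in
#' meters, same frame as the point cloud), whitespace- or comma-separated,
#' \code{#} comments allowed. Row order is the travel order.
#'
#' @param path path to the track file.
#' @return A [CameraTrack-class].
#' @export
readCameraTrack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) stop("camera track file has no data rows")
  rows <- lapply(keep, function(i) {
    tok <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    v <- suppressWarnings(as.numeric(tok))
    if (length(v) != 3 || anyNA(v)) {
      stop(sprintf("camera track parse error at line %d: '%s'", i, trimws(lines[i])))
    }
    v
  })
  cameraTrack(do.call(rbind, rows))
}

#' Write a camera track
#'
#' @param cameras a [CameraTrack-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCameraTrack <- function(cameras, path) {
  stopifnot(is(cameras, "CameraTrack"))
  p <- cameraPositions(cameras)
  writeLines(
    c("# camera track: x y z [m]",
      sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])),
    path
  )
  invisible(path)
}

#' Read / write a label sidecar file
#'
#' One integer label per line, aligned with the point order of the
#' corresponding cloud; \code{#} comments allowed. Useful for clouds
#' produced by tools that cannot carry a label vertex property.
#'
#' @param path sidecar path.
#' @return \code{readLabelSidecar}: integer vector.
#' @export
readLabelSidecar <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  v <- suppressWarnings(as.integer(lines))
  if (anyNA(v)) stop("non-integer entry in label sidecar")
  v
}

#' @rdname readLabelSidecar
#' @param labels integer vector of labels.
#' @export
writeLabelSidecar <- function(labels, path) {
  writeLines(as.character(as.integer(labels)), path)
  invisible(path)
}
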