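#' Triangle mesh container
#'
#' A light S3 record for a triangulated surface: an `n x 3` matrix of vertex
#' coordinates and an `m x 3` integer matrix of 1-based vertex indices.
#' All surface operations in the package accept and return this class.
#'
#' @param vertices numeric matrix, `n x 3`.
#' @param faces integer matrix, `m x 3`, 1-based indices into `vertices`.
#' @param id optional provenance identifier (specimen id, file path).
#' @return A `trimesh` object.
#' @export
trimesh <- function(vertices, faces, id = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) abort("`vertices` must have 3 columns")
  if (ncol(faces) != 3L) abort("`faces` must have 3 columns")
  if (!all(is.finite(vertices))) abort("non-finite vertex coordinates")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    abort("face indices out of range")
  structure(list(vertices = vertices, faces = faces, id = id),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh%s: %d vertices, %d faces>\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' @export
format.trimesh <- function(x, ...) {
  sprintf("<trimesh: %dV/%dF>", nrow(x$vertices), nrow(x$faces))
}

#' Per-face areas and bounding-box diagonal
#'
#' @param mesh a [trimesh()].
#' @return `face_areas()`: numeric vector of triangle areas.
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @rdname face_areas
#' @return `bbox_diagonal()`: length of the axis-aligned bounding-box diagonal.
#' @export
bbox_diagonal <- function(mesh) {
  v <- if (inherits(mesh, "trimesh")) mesh$vertices else as.matrix(mesh)
  sqrt(sum((apply(v, 2, max) - apply(v, 2, min))^2))
}

centroid_size <- function(points) {
  ctr <- colMeans(points)
  sqrt(sum(sweep(points, 2, ctr)^2))
}

# ---- PLY ------------------------------------------------------------------

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_bin <- function(con, type, n) {
  switch(type,
    char = , int8 = readBin(con, "integer", n, size = 1L, signed = TRUE,
                            endian = "little"),
    uchar = , uint8 = readBin(con, "integer", n, size = 1L, signed = FALSE,
                              endian = "little"),
    short = , int16 = readBin(con, "integer", n, size = 2L, signed = TRUE,
                              endian = "little"),
    ushort = , uint16 = readBin(con, "integer", n, size = 2L, signed = FALSE,
                                endian = "little"),
    int = , int32 = , uint = , uint32 =
      readBin(con, "integer", n, size = 4L, endian = "little"),
    float = , float32 = readBin(con, "double", n, size = 4L,
                                endian = "little"),
    double = , float64 = readBin(con, "double", n, size = 8L,
                                 endian = "little"),
    abort(sprintf("unsupported PLY property type '%s'", type)))
}

#' Read a triangle mesh from a PLY file
#'
#' Supports `ascii 1.0` and `binary_little_endian 1.0` PLY with `vertex`
#' (x, y, z plus any extra scalar properties, which are ignored) and `face`
#' elements. Polygonal faces with more than three vertices are fan
#' triangulated. Coordinate units are preserved as stored.
#'
#' @param path path to a `.ply` file.
#' @param id provenance id recorded on the mesh; defaults to the file name.
#' @return A [trimesh()].
#' @export
read_mesh <- function(path, id = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))

  line1 <- readLines(con, n = 1L)
  if (!identical(trimws(line1), "ply"))
    abort(sprintf("malformed PLY header at line 1: '%s'", line1))

  fmt <- NULL
  elements <- list()   # each: list(name, count, props = list(...))
  cur <- NULL
  lineno <- 1L
  repeat {
    ln <- readLines(con, n = 1L)
    lineno <- lineno + 1L
    if (length(ln) == 0L)
      abort("malformed PLY header: end_header not found (truncated file)")
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    } else if (tok[1] == "format") {
      if (length(tok) < 2L || !tok[2] %in% c("ascii", "binary_little_endian"))
        abort(sprintf("unsupported PLY format at line %d: '%s'", lineno, ln))
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (length(tok) != 3L || is.na(suppressWarnings(as.integer(tok[3]))))
        abort(sprintf("malformed PLY header at line %d: '%s'", lineno, ln))
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur))
        abort(sprintf("malformed PLY header at line %d: '%s'", lineno, ln))
      if (tok[2] == "list") {
        if (length(tok) != 5L)
          abort(sprintf("malformed PLY header at line %d: '%s'", lineno, ln))
        cur$props[[tok[5]]] <- list(name = tok[5], list = TRUE,
                                    count_type = tok[3], item_type = tok[4])
      } else {
        if (length(tok) != 3L)
          abort(sprintf("malformed PLY header at line %d: '%s'", lineno, ln))
        cur$props[[tok[3]]] <- list(name = tok[3], list = FALSE, type = tok[2])
      }
    } else {
      abort(sprintf("malformed PLY header at line %d: '%s'", lineno, ln))
    }
  }
  if (is.null(fmt)) abort("malformed PLY header: no format line")
  if (is.null(elements$vertex)) abort("PLY has no vertex element")
  if (is.null(elements$face)) abort("PLY has no face element")

  parse_ascii <- function() {
    txt <- readLines(con)
    out <- list()
    pos <- 1L
    for (el in elements) {
      if (pos + el$count - 1L > length(txt))
        abort(sprintf("truncated PLY: element '%s' expects %d rows",
                      el$name, el$count))
      rows <- txt[seq(pos, length.out = el$count)]
      pos <- pos + el$count
      has_list <- any(vapply(el$props, `[[`, TRUE, "list"))
      if (!has_list) {
        m <- matrix(as.numeric(unlist(strsplit(trimws(rows), "\\s+"))),
                    nrow = el$count, byrow = TRUE)
        if (anyNA(m)) abort(sprintf("truncated or corrupt PLY element '%s'",
                                    el$name))
        colnames(m) <- names(el$props)
        out[[el$name]] <- m
      } else {
        out[[el$name]] <- lapply(strsplit(trimws(rows), "\\s+"), function(tk) {
          v <- as.numeric(tk)
          if (anyNA(v) || length(v) < 1L || length(v) != v[1] + 1L)
            abort(sprintf("corrupt PLY face row: '%s'",
                          paste(tk, collapse = " ")))
          v[-1]
        })
      }
    }
    out
  }

  parse_binary <- function() {
    out <- list()
    for (el in elements) {
      has_list <- any(vapply(el$props, `[[`, TRUE, "list"))
      if (!has_list) {
        types <- vapply(el$props, `[[`, "", "type")
        m <- matrix(NA_real_, nrow = el$count, ncol = length(types),
                    dimnames = list(NULL, names(el$props)))
        if (length(unique(types)) == 1L) {
          vals <- ply_read_bin(con, types[1], el$count * length(types))
          if (length(vals) < el$count * length(types))
            abort(sprintf("truncated PLY element '%s'", el$name))
          m[] <- matrix(vals, ncol = length(types), byrow = TRUE)
        } else {
          for (i in seq_len(el$count))
            for (j in seq_along(types))
              m[i, j] <- ply_read_bin(con, types[j], 1L)
        }
        out[[el$name]] <- m
      } else {
        prop <- el$props[[which(vapply(el$props, `[[`, TRUE, "list"))[1]]]
        rows <- vector("list", el$count)
        for (i in seq_len(el$count)) {
          k <- ply_read_bin(con, prop$count_type, 1L)
          if (length(k) < 1L) abort("truncated PLY face data")
          v <- ply_read_bin(con, prop$item_type, k)
          if (length(v) < k) abort("truncated PLY face data")
          rows[[i]] <- v
        }
        out[[el$name]] <- rows
      }
    }
    out
  }

  dat <- if (fmt == "ascii") parse_ascii() else parse_binary()

  vm <- dat$vertex
  need <- c("x", "y", "z")
  if (!all(need %in% colnames(vm)))
    abort("PLY vertex element lacks x/y/z properties")
  vertices <- vm[, need, drop = FALSE]

  frows <- dat$face
  if (length(frows) == 0L) abort("empty mesh: PLY has zero faces")
  tri <- do.call(rbind, lapply(frows, function(ix) {
    ix <- as.integer(ix) + 1L   # PLY is 0-based
    if (length(ix) < 3L) abort("PLY face with fewer than 3 vertices")
    if (length(ix) == 3L) matrix(ix, 1L)
    else cbind(ix[1], ix[2:(length(ix) - 1L)], ix[3:length(ix)])  # fan
  }))
  trimesh(vertices, tri, id = id %||% basename(path))
}

#' Write a triangle mesh to an ascii PLY file
#'
#' @param mesh a [trimesh()].
#' @param path output path.
#' @param quality optional per-vertex scalar written as a `quality` property
#'   (used for deviation heat maps).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, quality = NULL) {
  stopifnot(inherits(mesh, "trimesh"))
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  if (!is.null(quality) && length(quality) != nv)
    abort("`quality` must have one value per vertex")
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           if (!is.null(quality)) "property float quality",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  vm <- mesh$vertices
  if (!is.null(quality)) vm <- cbind(vm, quality)
  vtxt <- apply(format(vm, trim = TRUE, digits = 9, scientific = FALSE),
                1, paste, collapse = " ")
  ftxt <- sprintf("3 %d %d %d",
                  mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                  mesh$faces[, 3] - 1L)
  writeLines(c(hdr, vtxt, ftxt), path)
  invisible(path)
}
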