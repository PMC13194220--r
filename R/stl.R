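# STL reading/writing.  Both the binary and the ASCII dialect are supported
# and auto-detected on read.  No R package on CRAN/Bioconductor in our
# dependency set parses STL, so the (simple) format is handled here.

.is_binary_stl <- function(path) {
  size <- file.info(path)$size
  if (is.na(size) || size < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80L)
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  expected <- 84 + as.numeric(n) * 50
  # An ASCII file beginning with "solid" can still be binary-sized by
  # coincidence; trust the facet-count arithmetic first.
  if (!is.na(n) && n > 0 && expected == size) return(TRUE)
  txt <- tolower(rawToChar(header[header != as.raw(0)]))
  !startsWith(trimws(txt), "solid")
}

.read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (is.na(n) || n < 1L) stop("corrupt binary STL: bad facet count")
  rec <- readBin(con, "raw", n * 50L)
  if (length(rec) < n * 50L) stop("corrupt binary STL: truncated facets")
  rec <- matrix(rec, nrow = 50L)
  vals <- readBin(as.vector(rec[1:48, ]), "numeric", size = 4L,
                  n = 12L * n, endian = "little")
  vals <- matrix(vals, nrow = 12L)  # per facet: normal, v1, v2, v3
  verts <- rbind(t(vals[4:6, , drop = FALSE]),
                 t(vals[7:9, , drop = FALSE]),
                 t(vals[10:12, , drop = FALSE]))
  idx <- seq_len(n)
  list(vertices = verts, faces = cbind(idx, idx + n, idx + 2L * n))
}

.read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("corrupt ASCII STL: vertex lines not a multiple of 3")
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(tok) {
    x <- suppressWarnings(as.numeric(tok[-1]))
    if (length(x) != 3L || anyNA(x)) stop("corrupt ASCII STL: bad vertex line")
    x
  })
  v <- do.call(rbind, nums)
  n <- nrow(v) / 3L
  f <- matrix(seq_len(3L * n), ncol = 3L, byrow = TRUE)
  list(vertices = v, faces = f)
}

#' Read an STL file
#'
#' Auto-detects binary vs ASCII, welds duplicate vertices (STL stores each
#' facet independently), drops degenerate faces and validates the result.
#'
#' @param path path to an STL file.
#' @param weld_tol vertex welding tolerance in mm.
#' @return A [tri_mesh()].
#' @export
load_stl <- function(path, weld_tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- if (.is_binary_stl(path)) .read_stl_binary(path) else
    .read_stl_ascii(path)
  mesh <- weld_vertices(tri_mesh(raw$vertices, raw$faces), tol = weld_tol)
  if (nrow(mesh$vertices) < 4L || nrow(mesh$faces) < 4L)
    stop("degenerate mesh: fewer than 4 vertices or 4 faces after cleanup")
  mesh
}

#' Write an STL file
#'
#' @param mesh a [tri_mesh()].
#' @param path output path.
#' @param format `"binary"` (default) or `"ascii"`.
#' @param name solid name for the ASCII dialect.
#' @return Invisibly, `path`.
#' @export
save_stl <- function(mesh, path, format = c("binary", "ascii"),
                     name = "osteoplate") {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (nrow(mesh$faces) == 0L) stop("refusing to write an empty mesh")
  format <- match.arg(format)
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  len <- pmax(sqrt(nx^2 + ny^2 + nz^2), 1e-30)
  normals <- cbind(nx / len, ny / len, nz / len)
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    tri <- cbind(normals,
                 v[f[, 1], , drop = FALSE],
                 v[f[, 2], , drop = FALSE],
                 v[f[, 3], , drop = FALSE])
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(tri[i, ]), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    fmt_pt <- function(p) sprintf("      vertex %.9g %.9g %.9g",
                                  p[1], p[2], p[3])
    out <- character(7L * nrow(f) + 2L)
    out[1] <- paste("solid", name)
    k <- 2L
    for (i in seq_len(nrow(f))) {
      out[k] <- sprintf("  facet normal %.9g %.9g %.9g",
                        normals[i, 1], normals[i, 2], normals[i, 3])
      out[k + 1L] <- "    outer loop"
      out[k + 2L] <- fmt_pt(v[f[i, 1], ])
      out[k + 3L] <- fmt_pt(v[f[i, 2], ])
      out[k + 4L] <- fmt_pt(v[f[i, 3], ])
      out[k + 5L] <- "    endloop"
      out[k + 6L] <- "  endfacet"
      k <- k + 7L
    }
    out[k] <- paste("endsolid", name)
    writeLines(out, path)
  }
  invisible(path)
}
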