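#' Read a triangular mesh from PLY or STL
#'
#' Supports ASCII and binary-little-endian PLY (vertex and face elements;
#' extra per-vertex or per-face properties are skipped) and ASCII or
#' binary STL.  STL stores one vertex triple per facet, so vertices are
#' merged back by exact coordinate equality by default; pass a small
#' `merge_tolerance` to merge near-coincident vertices instead.
#'
#' @param path file path.
#' @param format one of `"auto"` (default; decided from the file
#'   extension, falling back to content sniffing), `"ply"` or `"stl"`.
#' @param merge_tolerance vertex merge tolerance for STL input, in mm.
#'   `0` (default) merges only bitwise-identical coordinates, which keeps
#'   write/read round trips exact.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "ply", "stl"),
                      merge_tolerance = 0) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("ply", "stl")) ext else .sniff_format(path)
  }
  switch(format,
         ply = .read_ply(path),
         stl = .read_stl(path, merge_tolerance))
}

.sniff_format <- function(path) {
  head_raw <- readBin(path, "raw", 16L)
  if (length(head_raw) >= 3 &&
      identical(rawToChar(head_raw[1:3]), "ply")) return("ply")
  "stl"
}

#' Write a triangular mesh to PLY or STL
#'
#' PLY output is ASCII with `double` vertex properties printed at full
#' precision (`%.17g`), so a write/read round trip reproduces the vertex
#' and face arrays bit-exactly.  STL output is ASCII.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @param format `"ply"` (default) or `"stl"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("ply", "stl")) {
  format <- match.arg(format)
  stopifnot(inherits(mesh, "triangle_mesh"))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open for writing: ",
                                           path, call. = FALSE))
  on.exit(close(con))
  if (format == "ply") .write_ply_ascii(mesh, con) else .write_stl_ascii(mesh, con)
  invisible(path)
}

.write_ply_ascii <- function(mesh, con) {
  V <- mesh$vertices; F <- mesh$faces
  writeLines(c("ply",
               "format ascii 1.0",
               "comment written by eggscore",
               paste("element vertex", nrow(V)),
               "property double x",
               "property double y",
               "property double z",
               paste("element face", nrow(F)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
}

.write_stl_ascii <- function(mesh, con) {
  V <- mesh$vertices; F <- mesh$faces; N <- mesh$face_normals
  writeLines("solid eggscore", con)
  for (i in seq_len(nrow(F))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                       N[i, 1], N[i, 2], N[i, 3]), con)
    writeLines("    outer loop", con)
    for (j in 1:3) {
      v <- V[F[i, j], ]
      writeLines(sprintf("      vertex %.17g %.17g %.17g",
                         v[1], v[2], v[3]), con)
    }
    writeLines(c("    endloop", "  endfacet"), con)
  }
  writeLines("endsolid eggscore", con)
}

# ---- PLY reader ------------------------------------------------------------

.ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                    short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                    int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_bin_scalar <- function(con, type) {
  sz <- .ply_type_size[[type]]
  signed <- !(type %in% c("uchar", "uint8", "ushort", "uint16", "uint", "uint32"))
  what <- if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
  if (type %in% c("uint", "uint32")) {
    # readBin can't do unsigned 32-bit; read signed and fix up
    v <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (v < 0) v <- v + 2^32
    return(v)
  }
  readBin(con, what, 1L, size = sz, signed = signed || sz >= 4L,
          endian = "little")
}

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  line1 <- readLines(con, 1L)
  if (!identical(trimws(line1), "ply"))
    stop("not a PLY file (missing 'ply' magic): ", path, call. = FALSE)
  fmt <- NULL
  elements <- list()   # list of list(name, count, props = list(name,type,list_count_type,list_item_type))
  cur <- NULL
  repeat {
    ln <- readLines(con, 1L)
    if (length(ln) == 0L)
      stop("corrupt PLY header (no end_header): ", path, call. = FALSE)
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment" || tok[1] == "obj_info") next
    if (tok[1] == "format") {
      fmt <- tok[2]
      if (!fmt %in% c("ascii", "binary_little_endian"))
        stop("unsupported PLY format '", fmt, "' in ", path, call. = FALSE)
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur))
        stop("corrupt PLY header: property before element", call. = FALSE)
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], item_type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    } else {
      stop("corrupt PLY header: unknown keyword '", tok[1], "'", call. = FALSE)
    }
  }
  if (is.null(fmt)) stop("corrupt PLY header: no format line", call. = FALSE)
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY lacks vertex or face element: ", path, call. = FALSE)
  if (elements$vertex$count == 0L || elements$face$count == 0L)
    stop("empty mesh in ", path, call. = FALSE)

  if (fmt == "ascii") .read_ply_ascii_body(con, elements, path)
  else .read_ply_binary_body(con, elements, path)
}

.read_ply_ascii_body <- function(con, elements, path) {
  V <- NULL; F <- NULL
  for (el in elements) {
    lns <- readLines(con, el$count)
    if (length(lns) < el$count)
      stop("corrupt PLY: truncated element '", el$name, "'", call. = FALSE)
    if (el$name == "vertex") {
      pn <- vapply(el$props, `[[`, "", "name")
      ix <- match(c("x", "y", "z"), pn)
      if (anyNA(ix))
        stop("PLY vertex element lacks x/y/z properties", call. = FALSE)
      sc <- scan(text = lns, quiet = TRUE)
      m <- matrix(sc, nrow = el$count, byrow = TRUE)
      V <- m[, ix, drop = FALSE]
    } else if (el$name == "face") {
      F <- matrix(0L, el$count, 3L)
      for (i in seq_len(el$count)) {
        nums <- scan(text = lns[i], quiet = TRUE)
        k <- nums[1]
        if (is.na(k) || k != 3L)
          stop("PLY face ", i, " is not a triangle (", k, " vertices)",
               call. = FALSE)
        F[i, ] <- as.integer(nums[2:4]) + 1L
      }
    }
  }
  triangle_mesh(V, F)
}

.read_ply_binary_body <- function(con, elements, path) {
  V <- NULL; F <- NULL
  for (el in elements) {
    if (el$name == "vertex") {
      pn <- vapply(el$props, `[[`, "", "name")
      V <- matrix(NA_real_, el$count, 3L)
      for (i in seq_len(el$count)) {
        for (j in seq_along(el$props)) {
          p <- el$props[[j]]
          if (p$list) {
            k <- .ply_read_bin_scalar(con, p$count_type)
            for (q in seq_len(k)) .ply_read_bin_scalar(con, p$item_type)
          } else {
            v <- .ply_read_bin_scalar(con, p$type)
            if (pn[j] == "x") V[i, 1] <- v
            else if (pn[j] == "y") V[i, 2] <- v
            else if (pn[j] == "z") V[i, 3] <- v
          }
        }
      }
      if (anyNA(V))
        stop("PLY vertex element lacks x/y/z properties", call. = FALSE)
    } else if (el$name == "face") {
      F <- matrix(0L, el$count, 3L)
      for (i in seq_len(el$count)) {
        got <- FALSE
        for (p in el$props) {
          if (p$list) {
            k <- .ply_read_bin_scalar(con, p$count_type)
            idx <- numeric(k)
            for (q in seq_len(k)) idx[q] <- .ply_read_bin_scalar(con, p$item_type)
            if (!got) {
              if (k != 3L)
                stop("PLY face ", i, " is not a triangle (", k, " vertices)",
                     call. = FALSE)
              F[i, ] <- as.integer(idx) + 1L
              got <- TRUE
            }
          } else .ply_read_bin_scalar(con, p$type)
        }
      }
    } else {
      # skip unknown element payload
      for (i in seq_len(el$count)) {
        for (p in el$props) {
          if (p$list) {
            k <- .ply_read_bin_scalar(con, p$count_type)
            for (q in seq_len(k)) .ply_read_bin_scalar(con, p$item_type)
          } else .ply_read_bin_scalar(con, p$type)
        }
      }
    }
  }
  triangle_mesh(V, F)
}

# ---- STL reader ------------------------------------------------------------

.read_stl <- function(path, merge_tolerance = 0) {
  sz <- file.info(path)$size
  raw_head <- readBin(path, "raw", min(sz, 512L))
  txt_head <- suppressWarnings(rawToChar(raw_head[raw_head != as.raw(0)]))
  is_ascii <- grepl("^\\s*solid", txt_head) && grepl("facet", txt_head)
  tri <- if (is_ascii) .read_stl_ascii(path) else .read_stl_binary(path, sz)
  if (nrow(tri) == 0L) stop("empty mesh in ", path, call. = FALSE)
  .weld_vertices(tri, merge_tolerance)
}

.read_stl_ascii <- function(path) {
  lns <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lns, value = TRUE)
  if (length(vlines) %% 3 != 0)
    stop("corrupt ASCII STL (vertex count not a multiple of 3): ", path,
         call. = FALSE)
  nums <- scan(text = sub("^\\s*vertex\\s+", "", vlines), quiet = TRUE)
  matrix(nums, ncol = 3L, byrow = TRUE)
}

.read_stl_binary <- function(path, sz) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  nfac <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (is.na(nfac) || nfac < 0 || 84 + 50 * nfac > sz)
    stop("corrupt binary STL (bad facet count): ", path, call. = FALSE)
  tri <- matrix(0, 3L * nfac, 3L)
  for (i in seq_len(nfac)) {
    rec <- readBin(con, "double", 12L, size = 4L, endian = "little")
    tri[(3L * i - 2L):(3L * i), ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
    readBin(con, "raw", 2L)  # attribute byte count
  }
  tri
}

# merge duplicated corner vertices of an unindexed triangle soup
.weld_vertices <- function(tri, tol = 0) {
  if (tol > 0) tri_key <- round(tri / tol) else tri_key <- tri
  key <- paste(tri_key[, 1], tri_key[, 2], tri_key[, 3], sep = "|")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  V <- tri[first, , drop = FALSE]
  F <- matrix(idx, ncol = 3L, byrow = TRUE)
  deg <- F[, 1] == F[, 2] | F[, 1] == F[, 3] | F[, 2] == F[, 3]
  if (any(deg)) F <- F[!deg, , drop = FALSE]
  if (nrow(F) == 0L) stop("STL collapsed to no valid triangles", call. = FALSE)
  triangle_mesh(V, F)
}
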