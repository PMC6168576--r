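#' Triangulated surface mesh
#'
#' Builds a `tri_mesh` from vertex positions and counter-clockwise oriented
#' triangular faces, deriving the unique edge list (lexicographic order),
#' the hinge list (pairs of faces sharing an interior edge with their two
#' opposite vertices), boundary flags and the vertex adjacency used by the
#' contact term.  All invariants of a manifold, consistently oriented
#' triangle surface are checked at construction.
#'
#' @param vertices numeric matrix, n x 3, positions in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @return an object of class `tri_mesh` with components `vertices`,
#'   `faces`, `edges` (E x 2), `hinges` (H x 4: the shared edge's two
#'   vertices then the two opposite vertices), `hinge_faces` (H x 2),
#'   `hinge_edge` (hinge -> edge index), `edge_hinge` (edge -> hinge index,
#'   NA for boundary edges), `face_edges` (m x 3), `boundary_edge` and
#'   `boundary_vertex` logical masks, and the CSR vertex adjacency
#'   (`adj_ptr`, `adj_idx`).
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) == 2) vertices <- cbind(vertices, 0)
  if (ncol(vertices) != 3) stopf("vertices must be n x 3")
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(faces) != 3) stopf("faces must be m x 3 (triangles only)")
  n <- nrow(vertices)
  if (nrow(faces) > 0) {
    if (min(faces) < 1L || max(faces) > n)
      stopf("face vertex index out of range (1..%d)", n)
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3]))
      stopf("degenerate face with repeated vertices")
  }
  topo <- build_topology(n, faces)
  structure(c(list(vertices = vertices, faces = faces), topo),
            class = "tri_mesh")
}

build_topology <- function(n, faces) {
  m <- nrow(faces)
  if (m == 0) {
    return(list(edges = matrix(integer(), 0, 2),
                hinges = matrix(integer(), 0, 4),
                hinge_faces = matrix(integer(), 0, 2),
                hinge_edge = integer(), edge_hinge = integer(),
                face_edges = matrix(integer(), 0, 3),
                boundary_edge = logical(), boundary_vertex = logical(n),
                adj_ptr = rep(1L, n + 1L), adj_idx = integer()))
  }
  # directed half-edges with their face and opposite vertex
  from <- c(faces[, 1], faces[, 2], faces[, 3])
  to   <- c(faces[, 2], faces[, 3], faces[, 1])
  opp  <- c(faces[, 3], faces[, 1], faces[, 2])
  fid  <- rep.int(seq_len(m), 3L)
  u <- pmin(from, to)
  v <- pmax(from, to)
  key <- (as.numeric(u) - 1) * n + as.numeric(v)
  ord <- order(u, v)
  ukey <- unique(key[ord])
  edges <- cbind(u[ord], v[ord])[!duplicated(key[ord]), , drop = FALSE]
  storage.mode(edges) <- "integer"
  eid <- match(key, ukey)
  cnt <- tabulate(eid, nbins = length(ukey))
  if (any(cnt > 2))
    stopf("non-manifold edge shared by %d faces", max(cnt))
  fwd <- from < to
  nf_fwd <- tabulate(eid[fwd], nbins = length(ukey))
  nf_bwd <- cnt - nf_fwd
  if (any(nf_fwd > 1) || any(nf_bwd > 1))
    stopf("inconsistent face orientation: an edge is traversed twice in the same direction")
  boundary_edge <- cnt == 1L
  ne <- length(ukey)
  # hinge assembly for interior edges
  interior <- which(!boundary_edge)
  opp_fwd <- opp_bwd <- face_fwd <- face_bwd <- integer(ne)
  opp_fwd[eid[fwd]] <- opp[fwd]
  face_fwd[eid[fwd]] <- fid[fwd]
  opp_bwd[eid[!fwd]] <- opp[!fwd]
  face_bwd[eid[!fwd]] <- fid[!fwd]
  hinges <- cbind(edges[interior, 1], edges[interior, 2],
                  opp_fwd[interior], opp_bwd[interior])
  storage.mode(hinges) <- "integer"
  hinge_faces <- cbind(face_fwd[interior], face_bwd[interior])
  storage.mode(hinge_faces) <- "integer"
  hinge_edge <- interior
  edge_hinge <- rep(NA_integer_, ne)
  edge_hinge[interior] <- seq_along(interior)
  face_edges <- matrix(eid, ncol = 3)  # per face: edges (1,2),(2,3),(3,1)
  storage.mode(face_edges) <- "integer"
  boundary_vertex <- logical(n)
  boundary_vertex[edges[boundary_edge, ]] <- TRUE
  # CSR vertex adjacency (sorted neighbour lists, 1-based offsets)
  nb_from <- c(edges[, 1], edges[, 2])
  nb_to   <- c(edges[, 2], edges[, 1])
  o <- order(nb_from, nb_to)
  nb_from <- nb_from[o]
  nb_to <- nb_to[o]
  deg <- tabulate(nb_from, nbins = n)
  adj_ptr <- c(1L, cumsum(deg) + 1L)
  list(edges = edges, hinges = hinges, hinge_faces = hinge_faces,
       hinge_edge = as.integer(hinge_edge), edge_hinge = edge_hinge,
       face_edges = face_edges, boundary_edge = boundary_edge,
       boundary_vertex = boundary_vertex,
       adj_ptr = as.integer(adj_ptr), adj_idx = as.integer(nb_to))
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces, %d edges (%d boundary), %d hinges\n",
              nrow(x$vertices), nrow(x$faces), nrow(x$edges),
              sum(x$boundary_edge), nrow(x$hinges)))
  invisible(x)
}

#' Edge lengths and face areas of a mesh
#'
#' @param mesh a `tri_mesh`.
#' @param positions optional alternative vertex positions (defaults to the
#'   mesh's own).
#' @return numeric vector of edge lengths (mm) / face areas (mm^2).
#' @export
edge_lengths <- function(mesh, positions = NULL) {
  p <- positions %||% mesh$vertices
  d <- p[mesh$edges[, 2], , drop = FALSE] - p[mesh$edges[, 1], , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' @rdname edge_lengths
#' @export
face_areas <- function(mesh, positions = NULL) {
  p <- positions %||% mesh$vertices
  a <- p[mesh$faces[, 1], , drop = FALSE]
  b <- p[mesh$faces[, 2], , drop = FALSE]
  cc <- p[mesh$faces[, 3], , drop = FALSE]
  u <- b - a
  v <- cc - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

# Coefficient of variation of the edge lengths (std/mean).
edge_length_cv <- function(mesh, positions = NULL) {
  l <- edge_lengths(mesh, positions)
  stats::sd(l) / mean(l)
}

# Per-vertex area-weighted unit normals.
vertex_normals <- function(mesh) {
  p <- mesh$vertices
  f <- mesh$faces
  a <- p[f[, 1], , drop = FALSE]
  b <- p[f[, 2], , drop = FALSE]
  cc <- p[f[, 3], , drop = FALSE]
  u <- b - a
  v <- cc - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  nrm <- matrix(0, nrow(p), 3)
  for (k in 1:3) {
    for (c in 1:3) {
      acc <- tapply(cr[, c], f[, k], sum)
      idx <- as.integer(names(acc))
      nrm[idx, c] <- nrm[idx, c] + acc
    }
  }
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm / len
}

#' Regular triangulated grid mesh
#'
#' Equilateral-triangle grid in the `(x, y)` plane with optional height
#' function, the workhorse fixture and the sampling mesh for synthetic
#' substrates.
#'
#' @param nx,ny number of vertex columns and rows.
#' @param spacing edge length of the underlying equilateral lattice (mm).
#' @param height optional `function(x, y)` returning z (mm).
#' @param origin 2-vector, position of the first vertex.
#' @return a `tri_mesh`.
#' @examples
#' m <- grid_mesh(5, 4, spacing = 0.5,
#'                height = function(x, y) 0.1 * sin(2 * x))
#' m
#' range(edge_lengths(m))
#' @export
grid_mesh <- function(nx, ny, spacing = 1, height = NULL, origin = c(0, 0)) {
  stopifnot(nx >= 2, ny >= 2, spacing > 0)
  j <- rep(seq_len(ny) - 1L, each = nx)
  i <- rep(seq_len(nx) - 1L, times = ny)
  x <- origin[1] + (i + 0.5 * (j %% 2L)) * spacing
  y <- origin[2] + j * spacing * sqrt(3) / 2
  z <- if (is.null(height)) rep(0, length(x)) else height(x, y)
  id <- function(ii, jj) jj * nx + ii + 1L
  fl <- vector("list", ny - 1L)
  for (jj in seq_len(ny - 1L) - 1L) {
    ii <- seq_len(nx - 1L) - 1L
    if (jj %% 2L == 0L) {
      f1 <- cbind(id(ii, jj), id(ii + 1L, jj), id(ii, jj + 1L))
      f2 <- cbind(id(ii + 1L, jj), id(ii + 1L, jj + 1L), id(ii, jj + 1L))
    } else {
      f1 <- cbind(id(ii, jj), id(ii + 1L, jj), id(ii + 1L, jj + 1L))
      f2 <- cbind(id(ii, jj), id(ii + 1L, jj + 1L), id(ii, jj + 1L))
    }
    fl[[jj + 1L]] <- rbind(f1, f2)
  }
  tri_mesh(cbind(x, y, z), do.call(rbind, fl))
}

#' Read a triangle mesh from OFF, OBJ or PLY (ASCII)
#'
#' Non-triangular faces are rejected explicitly rather than silently
#' triangulated; parse failures report the offending line.
#'
#' @param path file path.
#' @param format one of `"off"`, `"obj"`, `"ply"`; inferred from the file
#'   extension when omitted.
#' @return a `tri_mesh`.
#' @examples
#' path <- tempfile(fileext = ".off")
#' write_mesh(grid_mesh(4, 4, 1), path)
#' load_mesh(path)
#' unlink(path)
#' @export
load_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stopf("mesh file not found: %s", path)
  format <- tolower(format %||% tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  switch(format,
         off = parse_off(lines, path),
         obj = parse_obj(lines, path),
         ply = parse_ply(lines, path),
         stopf("unsupported mesh format '%s' (use off, obj or ply)", format))
}

split_fields <- function(line) strsplit(trimws(line), "[[:space:]]+")[[1]]

parse_off <- function(lines, path) {
  lines <- sub("#.*", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stopf("%s: empty OFF file", path)
  first <- trimws(lines[keep[1]])
  idx <- keep
  if (toupper(first) == "OFF") {
    idx <- idx[-1]
  } else if (startsWith(toupper(first), "OFF")) {
    lines[idx[1]] <- sub("^[Oo][Ff][Ff]", "", first)
  } else stopf("%s line %d: missing OFF header", path, keep[1])
  counts <- suppressWarnings(as.numeric(split_fields(lines[idx[1]])))
  if (length(counts) < 2 || anyNA(counts))
    stopf("%s line %d: bad OFF count line", path, idx[1])
  nv <- counts[1]; nf <- counts[2]
  if (length(idx) < 1 + nv + nf)
    stopf("%s: OFF file truncated (expected %d vertices, %d faces)", path, nv, nf)
  vl <- lines[idx[1 + seq_len(nv)]]
  verts <- matrix(NA_real_, nv, 3)
  for (i in seq_len(nv)) {
    f <- suppressWarnings(as.numeric(split_fields(vl[i])))
    if (length(f) < 3 || anyNA(f[1:3]))
      stopf("%s line %d: bad vertex line", path, idx[1 + i])
    verts[i, ] <- f[1:3]
  }
  fl <- lines[idx[1 + nv + seq_len(nf)]]
  faces <- matrix(NA_integer_, nf, 3)
  for (i in seq_len(nf)) {
    f <- suppressWarnings(as.numeric(split_fields(fl[i])))
    if (length(f) < 1 || anyNA(f[1]))
      stopf("%s line %d: bad face line", path, idx[1 + nv + i])
    if (f[1] != 3)
      stopf("%s line %d: non-triangular face (%d vertices); triangles only",
            path, idx[1 + nv + i], f[1])
    faces[i, ] <- as.integer(f[2:4]) + 1L
  }
  tri_mesh(verts, faces)
}

parse_obj <- function(lines, path) {
  verts <- list()
  faces <- list()
  for (ln in seq_along(lines)) {
    f <- split_fields(lines[ln])
    if (!length(f) || startsWith(f[1], "#")) next
    if (f[1] == "v") {
      xyz <- suppressWarnings(as.numeric(f[2:4]))
      if (anyNA(xyz)) stopf("%s line %d: bad vertex line", path, ln)
      verts[[length(verts) + 1L]] <- xyz
    } else if (f[1] == "f") {
      ref <- f[-1]
      if (length(ref) != 3)
        stopf("%s line %d: non-triangular face (%d vertices); triangles only",
              path, ln, length(ref))
      ids <- suppressWarnings(as.integer(sub("/.*", "", ref)))
      if (anyNA(ids)) stopf("%s line %d: bad face line", path, ln)
      faces[[length(faces) + 1L]] <- ids
    }
  }
  if (!length(verts)) stopf("%s: no vertices found", path)
  tri_mesh(do.call(rbind, verts), do.call(rbind, faces))
}

parse_ply <- function(lines, path) {
  if (!length(lines) || trimws(lines[1]) != "ply")
    stopf("%s line 1: missing 'ply' magic", path)
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stopf("%s: missing end_header", path)
  hdr <- lines[seq_len(hdr_end)]
  fmt <- grep("^format", trimws(hdr), value = TRUE)
  if (!length(fmt) || !grepl("ascii", fmt[1]))
    stopf("%s: only ASCII PLY is supported", path)
  nv <- nf <- NA_integer_
  cur <- ""
  vprops <- character()
  for (hline in hdr) {
    f <- split_fields(hline)
    if (!length(f)) next
    if (f[1] == "element") {
      cur <- f[2]
      if (cur == "vertex") nv <- as.integer(f[3])
      if (cur == "face") nf <- as.integer(f[3])
    } else if (f[1] == "property" && cur == "vertex" && f[2] != "list") {
      vprops <- c(vprops, f[3])
    }
  }
  if (is.na(nv) || is.na(nf)) stopf("%s: missing vertex/face elements", path)
  ix <- match(c("x", "y", "z"), vprops)
  if (anyNA(ix)) stopf("%s: vertex element lacks x/y/z properties", path)
  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) stopf("%s: PLY file truncated", path)
  verts <- matrix(NA_real_, nv, 3)
  for (i in seq_len(nv)) {
    f <- suppressWarnings(as.numeric(split_fields(body[i])))
    if (anyNA(f[ix])) stopf("%s: bad vertex line %d", path, hdr_end + i)
    verts[i, ] <- f[ix]
  }
  faces <- matrix(NA_integer_, nf, 3)
  for (i in seq_len(nf)) {
    f <- suppressWarnings(as.numeric(split_fields(body[nv + i])))
    if (anyNA(f[1])) stopf("%s: bad face line %d", path, hdr_end + nv + i)
    if (f[1] != 3)
      stopf("%s: non-triangular face with %d vertices; triangles only",
            path, f[1])
    faces[i, ] <- as.integer(f[2:4]) + 1L
  }
  tri_mesh(verts, faces)
}

#' Write a triangle mesh to OFF, OBJ or ASCII PLY
#'
#' @param mesh a `tri_mesh`.
#' @param path output file path.
#' @param format inferred from the extension when omitted.
#' @param edge_attr optional data frame of per-edge attributes appended as
#'   comments in OFF/OBJ (PLY writes them as an `edge` element).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, edge_attr = NULL) {
  format <- tolower(format %||% tools::file_ext(path))
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  fmtnum <- function(m) apply(m, 1, function(r) paste(format(r, digits = 17,
                                                             trim = TRUE),
                                                      collapse = " "))
  if (format == "off") {
    writeLines("OFF", con)
    writeLines(sprintf("%d %d 0", nrow(v), nrow(f)), con)
    writeLines(fmtnum(v), con)
    writeLines(paste("3", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else if (format == "obj") {
    writeLines(paste("v", fmtnum(v)), con)
    writeLines(paste("f", f[, 1], f[, 2], f[, 3]), con)
  } else if (format == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices"), con)
    if (!is.null(edge_attr)) {
      writeLines(sprintf("element edge %d", nrow(mesh$edges)), con)
      writeLines("property int vertex1", con)
      writeLines("property int vertex2", con)
      for (nm in names(edge_attr))
        writeLines(sprintf("property double %s", nm), con)
    }
    writeLines("end_header", con)
    writeLines(fmtnum(v), con)
    writeLines(paste("3", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
    if (!is.null(edge_attr)) {
      ea <- cbind(mesh$edges - 1L, as.matrix(edge_attr))
      writeLines(fmtnum(ea), con)
    }
  } else stopf("unsupported mesh format '%s'", format)
  invisible(path)
}
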