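#' Read a claw mesh from disk
#'
#' Supported dialects:
#' * Abaqus INP subset: `*NODE`, `*ELEMENT, TYPE=C3D4`, `*NSET`
#'   (comma-separated ids). `*NSET` blocks populate the mesh's named node
#'   region sets (lower-cased); boundary facets whose three nodes all
#'   belong to a set inherit it as a facet set. Any non-C3D4 element type
#'   is a format error naming the offending type.
#' * Gmsh MSH v2.2: `$Nodes` / `$Elements` with element type 4
#'   (4-node tet); type 15 (points) and 1/2 (lines/triangles) are skipped,
#'   other volume types are a format error.
#' * STL (ASCII or binary), PLY (ASCII) and OFF surface meshes: yield a
#'   surface-only mesh (zero tets, boundary facets populated), suitable
#'   for measurement but not FE solves.
#'
#' On-disk indices (1-based in INP/MSH, 0-based in PLY/OFF) are converted
#' to the internal 1-based convention. Inverted tets are repaired by a
#' vertex swap with a message.
#'
#' @param path file path.
#' @param format_hint one of `"inp"`, `"msh"`, `"stl"`, `"ply"`, `"off"`;
#'   default guesses from the extension.
#' @return a [tet_mesh()].
#' @export
read_mesh <- function(path, format_hint = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- tolower(format_hint %||% tools::file_ext(path))
  switch(fmt,
         inp = read_inp(path),
         msh = read_msh(path),
         stl = read_stl(path),
         ply = read_ply(path),
         off = read_off(path),
         stop("unsupported mesh format: '", fmt, "'"))
}

#' Write a mesh to disk
#'
#' INP writes nodes, C3D4 elements and one `*NSET` per node region set
#' (facet region sets are written as node sets of their vertices, and
#' recovered as facet sets on re-read). STL (ASCII) and OFF write the
#' boundary surface only.
#'
#' @param mesh a [tet_mesh()].
#' @param path output path; format from extension (`.inp`, `.stl`,
#'   `.off`).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  fmt <- tolower(tools::file_ext(path))
  switch(fmt,
         inp = write_inp(mesh, path),
         stl = write_stl(mesh, path),
         off = write_off(mesh, path),
         stop("unsupported output format: '", fmt, "'"))
  invisible(path)
}

# ---------------------------------------------------------------- INP ----

read_inp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*\\*\\*", lines)]        # comments
  is_kw <- grepl("^\\s*\\*", lines)
  kw_at <- which(is_kw)
  nodes <- NULL; elems <- NULL; nsets <- list()
  for (k in seq_along(kw_at)) {
    start <- kw_at[k]
    end <- if (k < length(kw_at)) kw_at[k + 1L] - 1L else length(lines)
    head_ <- toupper(gsub("\\s", "", lines[start]))
    body <- lines[(start + 1L):end]
    body <- body[nzchar(trimws(body))]
    if (start == end || length(body) == 0L) body <- character()
    if (startsWith(head_, "*NODE")) {
      df <- parse_csv_block(body)
      nodes <- rbind(nodes, df)
    } else if (startsWith(head_, "*ELEMENT")) {
      type <- sub(".*TYPE=([A-Z0-9]+).*", "\\1", head_)
      if (type != "C3D4")
        stop("unsupported element type '", type,
             "': only C3D4 tetrahedra are supported")
      elems <- rbind(elems, parse_csv_block(body))
    } else if (startsWith(head_, "*NSET")) {
      name <- tolower(sub(".*NSET=([^,]+).*", "\\1", head_))
      ids <- as.integer(unlist(strsplit(paste(body, collapse = ","), ",")))
      nsets[[name]] <- ids[!is.na(ids)]
    }
  }
  if (is.null(nodes)) stop("INP file has no *NODE block")
  ord <- order(nodes[, 1L])
  nodes <- nodes[ord, , drop = FALSE]
  id_map <- integer(max(nodes[, 1L]))
  id_map[as.integer(nodes[, 1L])] <- seq_len(nrow(nodes))
  coords <- nodes[, 2:4, drop = FALSE]
  tets <- NULL
  if (!is.null(elems)) {
    if (ncol(elems) != 5L)
      stop("C3D4 elements must have 4 node ids per row")
    tets <- matrix(id_map[as.integer(elems[, 2:5])], ncol = 4L)
    tets <- repair_orientation(coords, tets)
  }
  regions <- list(nodes = lapply(nsets, function(ids) id_map[ids]))
  mesh <- tet_mesh(coords, tets, regions = regions,
                   provenance = paste0("inp:", basename(path)))
  mesh$regions$facets <- facet_sets_from_node_sets(mesh)
  mesh
}

parse_csv_block <- function(body) {
  if (length(body) == 0L) stop("empty data block in INP file")
  vals <- lapply(strsplit(body, ","), function(x) as.numeric(trimws(x)))
  ncols <- unique(lengths(vals))
  if (length(ncols) != 1L) stop("ragged data block in INP file")
  matrix(unlist(vals), ncol = ncols, byrow = TRUE)
}

repair_orientation <- function(coords, tets) {
  v <- tet_volumes(coords, tets)
  if (any(v == 0)) stop("mesh contains zero-volume (degenerate) tets")
  inv <- which(v < 0)
  if (length(inv)) {
    message("repaired orientation of ", length(inv),
            " inverted tet(s) by vertex swap")
    tets[inv, 3:4] <- tets[inv, 4:3]
  }
  tets
}

facet_sets_from_node_sets <- function(mesh) {
  out <- list()
  fac <- mesh$boundary
  if (nrow(fac) == 0L) return(out)
  for (name in names(mesh$regions$nodes)) {
    set <- mesh$regions$nodes[[name]]
    inside <- matrix(fac %in% set, nrow(fac))
    rows <- which(rowSums(inside) == 3L)
    if (length(rows)) out[[name]] <- rows
  }
  out
}

write_inp <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("*HEADING", con)
  writeLines(paste0("** ", mesh$provenance), con)
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.12g, %.12g, %.12g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1L], mesh$nodes[, 2L], mesh$nodes[, 3L]),
             con)
  if (nrow(mesh$tets)) {
    writeLines("*ELEMENT, TYPE=C3D4", con)
    writeLines(sprintf("%d, %d, %d, %d, %d", seq_len(nrow(mesh$tets)),
                       mesh$tets[, 1L], mesh$tets[, 2L], mesh$tets[, 3L],
                       mesh$tets[, 4L]), con)
  }
  sets <- mesh$regions$nodes
  for (name in names(mesh$regions$facets)) {
    rows <- mesh$regions$facets[[name]]
    sets[[name]] <- sort(unique(c(sets[[name]],
                                  as.vector(mesh$boundary[rows, ]))))
  }
  for (name in names(sets)) {
    ids <- sets[[name]]
    if (!length(ids)) next
    writeLines(sprintf("*NSET, NSET=%s", toupper(name)), con)
    chunks <- split(ids, ceiling(seq_along(ids) / 8))
    writeLines(vapply(chunks, paste, character(1L), collapse = ", "), con)
  }
}

# ---------------------------------------------------------------- MSH ----

read_msh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sect <- function(tag) {
    a <- which(lines == paste0("$", tag))
    b <- which(lines == paste0("$End", tag))
    if (length(a) != 1L || length(b) != 1L)
      stop("MSH file lacks a $", tag, " section")
    lines[(a + 1L):(b - 1L)]
  }
  nb <- sect("Nodes")
  n <- as.integer(nb[1L])
  nd <- matrix(scan(text = nb[-1L], quiet = TRUE), ncol = 4L, byrow = TRUE)
  ord <- order(nd[, 1L])
  nd <- nd[ord, , drop = FALSE]
  id_map <- integer(max(nd[, 1L]))
  id_map[as.integer(nd[, 1L])] <- seq_len(nrow(nd))
  eb <- sect("Elements")
  tets <- list()
  for (ln in eb[-1L]) {
    v <- as.integer(strsplit(trimws(ln), "\\s+")[[1L]])
    type <- v[2L]; ntags <- v[3L]
    conn <- v[-(seq_len(3L + ntags))]
    if (type == 4L) {
      tets[[length(tets) + 1L]] <- id_map[conn]
    } else if (!type %in% c(1L, 2L, 15L)) {
      stop("unsupported MSH element type ", type,
           ": only 4-node tetrahedra (type 4) are read")
    }
  }
  tets <- if (length(tets)) do.call(rbind, tets) else NULL
  if (!is.null(tets)) tets <- repair_orientation(nd[, 2:4], tets)
  tet_mesh(nd[, 2:4, drop = FALSE], tets,
           provenance = paste0("msh:", basename(path)))
}

# -------------------------------------------------- surface formats ----

surface_mesh <- function(verts, faces, provenance) {
  # merge exactly duplicated vertices (common in STL)
  key <- paste(verts[, 1L], verts[, 2L], verts[, 3L])
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  verts <- verts[uk, , drop = FALSE]
  faces <- matrix(map[faces], ncol = 3L)
  degen <- faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
    faces[, 1L] == faces[, 3L]
  if (any(degen)) faces <- faces[!degen, , drop = FALSE]
  tet_mesh(verts, NULL, boundary = faces, provenance = provenance)
}

read_stl <- function(path) {
  head_raw <- readBin(path, "raw", n = 5L)
  ascii <- identical(rawToChar(head_raw), "solid") && is_ascii_stl(path)
  if (ascii) read_stl_ascii(path) else read_stl_binary(path)
}

is_ascii_stl <- function(path) {
  # a binary STL can also start with "solid"; check for "facet" nearby
  txt <- tryCatch(readLines(path, n = 10L, warn = FALSE),
                  error = function(e) character())
  any(grepl("facet", txt))
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (length(vl) %% 3L != 0L) stop("malformed ASCII STL: vertex count not x3")
  nums <- matrix(scan(text = gsub("^\\s*vertex\\s+", "", vl), quiet = TRUE),
                 ncol = 3L, byrow = TRUE)
  faces <- matrix(seq_len(nrow(nums)), ncol = 3L, byrow = TRUE)
  surface_mesh(nums, faces, paste0("stl:", basename(path)))
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80L))
  ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (is.na(ntri) || ntri <= 0L) stop("malformed binary STL header")
  verts <- matrix(NA_real_, ntri * 3L, 3L)
  for (i in seq_len(ntri)) {
    rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    invisible(readBin(con, "raw", n = 2L))
    verts[(i - 1L) * 3L + 1:3, ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
  }
  faces <- matrix(seq_len(ntri * 3L), ncol = 3L, byrow = TRUE)
  surface_mesh(verts, faces, paste0("stl:", basename(path)))
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (toupper(trimws(lines[1L])) != "PLY") stop("not a PLY file")
  if (!any(grepl("format\\s+ascii", lines[1:10])))
    stop("only ASCII PLY is supported")
  endh <- which(trimws(lines) == "end_header")[1L]
  nv <- as.integer(sub(".*element vertex\\s+(\\d+).*", "\\1",
                       grep("element vertex", lines[1:endh], value = TRUE)[1L]))
  nf <- as.integer(sub(".*element face\\s+(\\d+).*", "\\1",
                       grep("element face", lines[1:endh], value = TRUE)[1L]))
  body <- lines[(endh + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vd <- matrix(scan(text = body[seq_len(nv)], quiet = TRUE),
               nrow = nv, byrow = TRUE)
  verts <- vd[, 1:3, drop = FALSE]
  faces <- list()
  for (ln in body[nv + seq_len(nf)]) {
    v <- as.integer(strsplit(trimws(ln), "\\s+")[[1L]])
    k <- v[1L]; poly <- v[1L + seq_len(k)] + 1L   # 0-based on disk
    for (t in seq_len(k - 2L))                    # fan triangulation
      faces[[length(faces) + 1L]] <- c(poly[1L], poly[t + 1L], poly[t + 2L])
  }
  surface_mesh(verts, do.call(rbind, faces), paste0("ply:", basename(path)))
}

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (toupper(trimws(lines[1L])) != "OFF") stop("not an OFF file")
  counts <- as.integer(strsplit(trimws(lines[2L]), "\\s+")[[1L]])
  nv <- counts[1L]; nf <- counts[2L]
  verts <- matrix(scan(text = lines[2L + seq_len(nv)], quiet = TRUE),
                  nrow = nv, byrow = TRUE)[, 1:3, drop = FALSE]
  faces <- list()
  for (ln in lines[2L + nv + seq_len(nf)]) {
    v <- as.integer(strsplit(trimws(ln), "\\s+")[[1L]])
    k <- v[1L]; poly <- v[1L + seq_len(k)] + 1L
    for (t in seq_len(k - 2L))
      faces[[length(faces) + 1L]] <- c(poly[1L], poly[t + 1L], poly[t + 2L])
  }
  surface_mesh(verts, do.call(rbind, faces), paste0("off:", basename(path)))
}

write_stl <- function(mesh, path) {
  fac <- mesh$boundary
  if (nrow(fac) == 0L) stop("mesh has no boundary facets to write")
  na <- facet_normals_areas(mesh$nodes, fac)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid clawfsa", con)
  for (i in seq_len(nrow(fac))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                       na$normal[i, 1L], na$normal[i, 2L], na$normal[i, 3L]),
               con)
    writeLines("    outer loop", con)
    for (j in 1:3) {
      v <- mesh$nodes[fac[i, j], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", v[1L], v[2L], v[3L]),
                 con)
    }
    writeLines(c("    endloop", "  endfacet"), con)
  }
  writeLines("endsolid clawfsa", con)
}

write_off <- function(mesh, path) {
  fac <- mesh$boundary
  if (nrow(fac) == 0L) stop("mesh has no boundary facets to write")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$nodes), nrow(fac)), con)
  writeLines(sprintf("%.12g %.12g %.12g", mesh$nodes[, 1L], mesh$nodes[, 2L],
                     mesh$nodes[, 3L]), con)
  writeLines(sprintf("3 %d %d %d", fac[, 1L] - 1L, fac[, 2L] - 1L,
                     fac[, 3L] - 1L), con)
}
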