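#' Read and write meshes in ASCII OFF / PLY format
#'
#' Minimal readers/writers for the two classic text mesh formats.
#' Only triangular faces are supported; PLY is ASCII 1.0 with
#' `float vertex x y z` and `uchar int vertex_indices` face lists.
#'
#' @param path file path.
#' @param mesh a `triangle_mesh`.
#' @name mesh_io
NULL

#' @rdname mesh_io
#' @export
read_off <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (toupper(ln[1]) != "OFF") stop("not an OFF file: ", path)
  counts <- scan(text = ln[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  nums <- scan(text = ln[3:(2 + nv)], quiet = TRUE)
  v <- matrix(nums, ncol = 3, byrow = TRUE)
  fl <- scan(text = ln[(3 + nv):(2 + nv + nf)], quiet = TRUE)
  fm <- matrix(fl, ncol = 4, byrow = TRUE)
  if (any(fm[, 1] != 3)) stop("non-triangular face in OFF file")
  triangle_mesh(v, fm[, 2:4] + 1L)
}

#' @rdname mesh_io
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(format(r, digits = 17), collapse = " ")), con)
  writeLines(apply(mesh$faces - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

#' @rdname mesh_io
#' @export
read_ply <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (trimws(ln[1]) != "ply") stop("not a PLY file: ", path)
  hdr_end <- which(trimws(ln) == "end_header")[1]
  hdr <- trimws(ln[1:hdr_end])
  if (!any(grepl("^format ascii", hdr))) stop("only ASCII PLY supported")
  ev <- regmatches(hdr, regexec("^element vertex ([0-9]+)", hdr))
  nv <- as.integer(unlist(lapply(ev, `[`, 2)))
  nv <- nv[!is.na(nv)][1]
  ef <- regmatches(hdr, regexec("^element face ([0-9]+)", hdr))
  nf <- as.integer(unlist(lapply(ef, `[`, 2)))
  nf <- nf[!is.na(nf)][1]
  body <- trimws(ln[(hdr_end + 1):length(ln)])
  body <- body[nzchar(body)]
  v <- matrix(scan(text = body[1:nv], quiet = TRUE), ncol = 3, byrow = TRUE)
  fl <- scan(text = body[(nv + 1):(nv + nf)], quiet = TRUE)
  fm <- matrix(fl, ncol = 4, byrow = TRUE)
  if (any(fm[, 1] != 3)) stop("non-triangular face in PLY file")
  triangle_mesh(v, fm[, 2:4] + 1L)
}

#' @rdname mesh_io
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(format(r, digits = 17), collapse = " ")), con)
  writeLines(apply(mesh$faces - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

#' Per-vertex scalar maps as plain text
#'
#' One value per line, ordered by vertex index.
#' @param x numeric per-vertex vector.
#' @param path file path.
#' @export
write_vertex_map <- function(x, path) {
  writeLines(format(x, digits = 17, trim = TRUE, scientific = FALSE),
             path)
  invisible(path)
}

#' @rdname write_vertex_map
#' @export
read_vertex_map <- function(path) {
  as.numeric(readLines(path, warn = FALSE))
}

#' Serialize / load a simulation trace
#'
#' The trace container is a directory: `index.json` holds the parameter
#' set, the times and the area series; each snapshot gets an OFF mesh
#' plus one-value-per-line text files for `u`, `v` and the curvature.
#'
#' @param sim a `cortical_sim`.
#' @param dir container directory (created if needed).
#' @export
write_trace <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(sim$snapshots)) {
    s <- sim$snapshots[[i]]
    tag <- sprintf("snap%04d", i)
    write_off(s$mesh, file.path(dir, paste0(tag, ".off")))
    write_vertex_map(s$u, file.path(dir, paste0(tag, "_u.txt")))
    write_vertex_map(s$v, file.path(dir, paste0(tag, "_v.txt")))
    if (!is.null(s$curvature))
      write_vertex_map(s$curvature,
                       file.path(dir, paste0(tag, "_curvature.txt")))
  }
  gs <- sim$params$gray_scott; dp <- sim$params$deformation
  idx <- list(snapshots = length(sim$snapshots), times = sim$times,
              area = sim$area,
              gray_scott = gs[c("F", "k", "Du", "Dv", "dt")],
              deformation = dp[c("alpha", "driver", "refinement_threshold",
                                 "snapshot_every")],
              horizon = sim$params$horizon,
              lumped_mass = isTRUE(sim$params$lumped_mass))
  jsonlite::write_json(idx, file.path(dir, "index.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_trace
#' @export
read_trace <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "index.json"),
                             simplifyVector = TRUE)
  snaps <- lapply(seq_len(idx$snapshots), function(i) {
    tag <- sprintf("snap%04d", i)
    mesh <- read_off(file.path(dir, paste0(tag, ".off")))
    cpath <- file.path(dir, paste0(tag, "_curvature.txt"))
    list(time = idx$times[i], mesh = mesh,
         u = read_vertex_map(file.path(dir, paste0(tag, "_u.txt"))),
         v = read_vertex_map(file.path(dir, paste0(tag, "_v.txt"))),
         curvature = if (file.exists(cpath)) read_vertex_map(cpath))
  })
  gs <- do.call(gray_scott_params, as.list(idx$gray_scott))
  dp <- do.call(deformation_params, as.list(idx$deformation))
  last <- snaps[[length(snaps)]]
  structure(list(snapshots = snaps, times = idx$times, area = idx$area,
                 mesh = last$mesh,
                 state = morphogen_state(last$u, last$v, time = last$time),
                 params = list(gray_scott = gs, deformation = dp,
                               horizon = as.integer(idx$horizon),
                               lumped_mass = isTRUE(idx$lumped_mass))),
            class = "cortical_sim")
}
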