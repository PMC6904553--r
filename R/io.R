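# File formats: transforms (JSON or 4-line plain text), intrinsics (JSON),
# labeled point sets (XYZ text or JSON), point clouds (XYZ, PLY, OBJ),
# hand-eye pose pairs (JSON).

#' Write a rigid transform to JSON
#'
#' Format: `{"from": "I", "to": "P", "matrix": [[...], ...]}` with the
#' homogeneous 4x4 matrix row-major.
#'
#' @param t a `rigid_transform`.
#' @param path output file.
#' @export
write_transform_json <- function(t, path) {
  stopifnot(inherits(t, "rigid_transform"))
  jsonlite::write_json(
    list(from = t$from, to = t$to,
         matrix = apply(as.matrix(t), 1, function(r) r, simplify = FALSE)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rigid transform
#'
#' Accepts the JSON format of [write_transform_json()] or a plain-text
#' file of 4 whitespace-separated rows of the homogeneous matrix (frame
#' labels must then be supplied).
#'
#' @param path input file.
#' @param from,to frame labels; required for plain-text input, override
#'   the stored labels for JSON input when non-`NULL`.
#' @return a `rigid_transform`.
#' @export
read_transform <- function(path, from = NULL, to = NULL) {
  first <- readChar(path, nchars = 1L)
  if (identical(first, "{")) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    m <- if (is.matrix(obj$matrix)) obj$matrix else
      matrix(unlist(obj$matrix), 4, 4, byrow = TRUE)
    return(rt_from_matrix(m, from %||% obj$from, to %||% obj$to))
  }
  if (is.null(from) || is.null(to))
    stop("plain-text transform files carry no frame labels; ",
         "supply from= and to=")
  m <- as.matrix(utils::read.table(path, nrows = 4L))
  stopifnot(ncol(m) == 4L)
  rt_from_matrix(unname(m), from, to)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write camera intrinsics to JSON
#'
#' @param k `camera_intrinsics`.
#' @param path output file.
#' @export
write_intrinsics_json <- function(k, path) {
  stopifnot(inherits(k, "camera_intrinsics"))
  jsonlite::write_json(unclass(k), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read camera intrinsics from JSON
#'
#' Expects an object with fields `fx, fy, cx, cy, width, height`.
#'
#' @param path input file.
#' @return `camera_intrinsics`.
#' @export
read_intrinsics_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  camera_intrinsics(o$fx, o$fy, o$cx, o$cy, o$width, o$height)
}

#' Write labeled points as plain-text XYZ
#'
#' One point per line: `label x y z` (mm).
#'
#' @param pts labeled points data.frame.
#' @param path output file.
#' @export
write_points_xyz <- function(pts, path) {
  stopifnot(is.data.frame(pts), all(c("label", "x", "y", "z") %in% names(pts)))
  utils::write.table(pts[, c("label", "x", "y", "z")], path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read labeled points from plain-text XYZ
#'
#' @param path input file: lines of `label x y z`.
#' @return labeled points data.frame.
#' @export
read_points_xyz <- function(path) {
  d <- utils::read.table(path, col.names = c("label", "x", "y", "z"),
                         colClasses = c("character", "numeric", "numeric",
                                        "numeric"))
  labeled_points(d$label, cbind(d$x, d$y, d$z))
}

#' Read an unlabeled point cloud
#'
#' Dispatches on the extension: `.xyz`/`.txt` (3 numeric columns, or 4
#' with a leading label), `.ply` (ASCII, vertex elements), `.obj`
#' (`v x y z` lines), `.json` (array of 3-vectors).
#'
#' @param path input file.
#' @return n x 3 numeric matrix, mm.
#' @export
read_point_cloud <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xyz", "txt", "")) {
    d <- utils::read.table(path)
    if (ncol(d) == 4L) d <- d[, 2:4]
    stopifnot(ncol(d) == 3L)
    return(unname(as.matrix(d)))
  }
  if (ext == "json") {
    m <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(matrix(as.numeric(m), ncol = 3L))
  }
  if (ext == "ply") return(read_ply_vertices(path))
  if (ext == "obj") return(read_obj_vertices(path))
  stop("unsupported point cloud format: .", ext)
}

# minimal ASCII PLY vertex reader (positions only)
read_ply_vertices <- function(path) {
  lines <- readLines(path)
  if (!identical(trimws(lines[1]), "ply"))
    stop("not a PLY file: ", path)
  if (!any(grepl("^format\\s+ascii", lines)))
    stop("only ASCII PLY is supported")
  vline <- grep("^element\\s+vertex\\s+\\d+", lines, value = TRUE)[1]
  nv <- as.integer(sub("^element\\s+vertex\\s+(\\d+).*", "\\1", vline))
  end <- grep("^end_header", lines)[1]
  vals <- strsplit(trimws(lines[end + seq_len(nv)]), "\\s+")
  m <- t(vapply(vals, function(v) as.numeric(v[1:3]), numeric(3)))
  unname(m)
}

# minimal OBJ vertex reader
read_obj_vertices <- function(path) {
  lines <- readLines(path)
  v <- grep("^v\\s", lines, value = TRUE)
  if (length(v) == 0L) stop("no vertices found in OBJ file: ", path)
  m <- t(vapply(strsplit(trimws(sub("^v", "", v)), "\\s+"),
                function(x) as.numeric(x[x != ""][1:3]), numeric(3)))
  unname(m)
}

#' Write hand-eye pose pairs to JSON
#'
#' @param pairs list of [pose_pair()] objects.
#' @param path output file.
#' @export
write_pose_pairs_json <- function(pairs, path) {
  check_pose_pairs(pairs)
  enc <- lapply(pairs, function(p) {
    list(tracker_to_marker = list(
           from = "O", to = "M",
           matrix = apply(as.matrix(p$tracker_to_marker), 1, function(r) r,
                          simplify = FALSE)),
         plate_to_camera = list(
           from = "C", to = "O",
           matrix = apply(as.matrix(p$plate_to_camera), 1, function(r) r,
                          simplify = FALSE)))
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read hand-eye pose pairs from JSON
#'
#' @param path input file written by [write_pose_pairs_json()].
#' @return list of [pose_pair()] objects.
#' @export
read_pose_pairs_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(p) {
    mt <- matrix(unlist(p$tracker_to_marker$matrix), 4, 4, byrow = TRUE)
    mp <- matrix(unlist(p$plate_to_camera$matrix), 4, 4, byrow = TRUE)
    pose_pair(rt_from_matrix(mt, "O", "M"), rt_from_matrix(mp, "C", "O"))
  })
}

#' Reference per-marker fiducial localization errors
#'
#' Per-marker FLE values (mm) recorded for three observers (subjects A-C)
#' annotating the 15 cauterization marks (a-o) on intraoperative CT liver
#' models across porcine trials, shipped with the package as a worked
#' example for the FLE summaries.
#'
#' @return data.frame with columns `subject`, `mark`, `fle_mm`.
#' @export
fle_reference <- function() {
  path <- system.file("extdata", "fle_reference.csv", package = "arnav",
                      mustWork = TRUE)
  utils::read.csv(path, colClasses = c("character", "character", "numeric"))
}
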