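#' Streamline sets
#'
#' A `streamline_set` holds fiber-track polylines in world coordinates
#' (RAS mm) together with per-streamline provenance: subject id, analysis
#' group (hemisphere or C/I/IE/II) and bundle label. Points are n x 3
#' matrices with at least two distinct consecutive vertices each.
#'
#' @param points list of n_i x 3 numeric matrices (world mm).
#' @param subject,group,bundle character vectors recycled to one value per
#'   streamline.
#' @return A `streamline_set`: list with `points` (list of matrices) and
#'   `meta` (tibble with columns `streamline`, `subject`, `group`, `bundle`).
#' @examples
#' s <- streamline_set(list(cbind(0:5, 0, 0)), group = "C")
#' n_streamlines(s)
#' @export
streamline_set <- function(points, subject = NA_character_,
                           group = NA_character_, bundle = NA_character_) {
  stopifnot(is.list(points))
  points <- lapply(points, as_points_matrix)
  for (p in points) {
    if (nrow(p) < 2) stop("every streamline needs >= 2 points", call. = FALSE)
    seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    if (any(seg == 0)) {
      stop("streamline has zero-length segments (repeated points)",
           call. = FALSE)
    }
  }
  n <- length(points)
  meta <- tibble::tibble(
    streamline = seq_len(n),
    subject = rep_len(as.character(subject), n),
    group = rep_len(as.character(group), n),
    bundle = rep_len(as.character(bundle), n)
  )
  structure(list(points = points, meta = meta), class = "streamline_set")
}

#' @rdname streamline_set
#' @param x a `streamline_set`.
#' @export
n_streamlines <- function(x) {
  stopifnot(inherits(x, "streamline_set"))
  length(x$points)
}

#' @export
print.streamline_set <- function(x, ...) {
  n <- n_streamlines(x)
  cat(sprintf("<streamline_set> %d streamlines\n", n))
  if (n > 0) {
    len <- vapply(x$points, arc_length, numeric(1))
    cat(sprintf("  length %.1f-%.1f mm (median %.1f)\n",
                min(len), max(len), stats::median(len)))
    grp <- table(x$meta$group, useNA = "ifany")
    cat("  groups:", paste(names(grp), grp, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Subset a streamline set
#' @param x a [streamline_set()].
#' @param keep logical or integer index over streamlines.
#' @return a [streamline_set()] with the selected streamlines.
#' @export
filter_streamlines <- function(x, keep) {
  stopifnot(inherits(x, "streamline_set"))
  pts <- x$points[keep]
  meta <- x$meta[keep, , drop = FALSE]
  meta$streamline <- seq_along(pts)
  structure(list(points = pts, meta = meta), class = "streamline_set")
}

#' Arc length of a streamline
#'
#' Sum of Euclidean segment lengths of the polyline, in mm.
#'
#' @param streamline n x 3 matrix of points (world mm).
#' @return length in mm.
#' @examples
#' arc_length(cbind(c(0, 10), 0, 0))
#' @export
arc_length <- function(streamline) {
  p <- as_points_matrix(streamline)
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Densify a polyline by arc length
#'
#' Inserts linearly interpolated points so that no segment exceeds
#' `max_step_mm`, keeping all original vertices. Used for robust
#' streamline-mask intersection tests.
#' @noRd
densify_polyline <- function(p, max_step_mm) {
  p <- as_points_matrix(p)
  n <- nrow(p)
  if (n < 2) return(p)
  segs <- p[-1, , drop = FALSE] - p[-n, , drop = FALSE]
  len <- sqrt(rowSums(segs^2))
  nsub <- pmax(1L, ceiling(len / max_step_mm))
  if (all(nsub == 1L)) return(p)
  rep_i <- rep.int(seq_len(n - 1), nsub)
  t <- (sequence(nsub) - 1) / nsub[rep_i]
  rbind(p[rep_i, , drop = FALSE] + t * segs[rep_i, , drop = FALSE],
        p[n, , drop = FALSE])
}

# ---------------------------------------------------------------------------
# TRK (TrackVis) and TCK (MRtrix) file formats
# ---------------------------------------------------------------------------

trk_orientation_code <- function(affine) {
  letters_pos <- c("R", "A", "S")
  letters_neg <- c("L", "P", "I")
  code <- character(3)
  rot <- affine[1:3, 1:3]
  for (j in 1:3) {
    ax <- which.max(abs(rot[, j]))
    code[j] <- if (rot[ax, j] >= 0) letters_pos[ax] else letters_neg[ax]
  }
  paste(code, collapse = "")
}

#' Read and write streamline files (TRK / TCK)
#'
#' The dialect is inferred from the file extension. TRK stores points in
#' voxel-scaled mm with a corner origin; they are converted to world RAS mm
#' on read using the header's voxel-to-RAS matrix and voxel sizes (and back
#' on write), so in-memory coordinates are always world mm. TCK stores world
#' mm natively. The TRK header written here is version 2 with the voxel
#' order matching the affine.
#'
#' @param path file path ending in `.trk` or `.tck`.
#' @return `read_streamlines()` returns a [streamline_set()];
#'   `write_streamlines()` returns `path` invisibly.
#' @export
read_streamlines <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    trk = read_trk(path),
    tck = read_tck(path),
    stop("unknown streamline format: .", ext, " (use .trk or .tck)",
         call. = FALSE)
  )
}

#' @rdname read_streamlines
#' @param x a [streamline_set()].
#' @param reference for TRK: a [scalar_volume()] supplying grid geometry for
#'   the header. Ignored for TCK.
#' @export
write_streamlines <- function(x, path, reference = NULL) {
  stopifnot(inherits(x, "streamline_set"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    trk = write_trk(x, path, reference),
    tck = write_tck(x, path),
    stop("unknown streamline format: .", ext, " (use .trk or .tck)",
         call. = FALSE)
  )
  invisible(path)
}

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- readBin(con, "raw", 6)
  if (!identical(rawToChar(id[1:5]), "TRACK")) {
    stop("not a TRK file (bad magic): ", path, call. = FALSE)
  }
  dim3 <- readBin(con, "integer", 3, size = 2)
  zooms <- readBin(con, "numeric", 3, size = 4)
  readBin(con, "numeric", 3, size = 4) # origin (unused per format doc)
  n_scalars <- readBin(con, "integer", 1, size = 2)
  readBin(con, "raw", 200)
  n_props <- readBin(con, "integer", 1, size = 2)
  readBin(con, "raw", 200)
  m <- readBin(con, "numeric", 16, size = 4)
  vox_to_ras <- matrix(m, 4, 4, byrow = TRUE)
  readBin(con, "raw", 444 + 4 + 4 + 24 + 2 + 6)
  n_count <- readBin(con, "integer", 1, size = 4)
  version <- readBin(con, "integer", 1, size = 4)
  hdr_size <- readBin(con, "integer", 1, size = 4)
  if (hdr_size != 1000L) {
    stop("corrupt TRK header (hdr_size != 1000, maybe wrong endianness)",
         call. = FALSE)
  }
  if (version < 2 || max(abs(vox_to_ras)) == 0) {
    stop("TRK file lacks a voxel-to-RAS matrix (version < 2)", call. = FALSE)
  }
  if (any(zooms <= 0)) stop("corrupt TRK header (non-positive voxel size)",
                            call. = FALSE)
  pts <- list()
  repeat {
    n <- readBin(con, "integer", 1, size = 4)
    if (length(n) == 0) break
    raw <- readBin(con, "numeric", n * (3 + n_scalars), size = 4)
    if (n_props > 0) readBin(con, "numeric", n_props, size = 4)
    p <- matrix(raw, ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    # voxmm (corner origin) -> voxel -> world RAS mm
    vox <- sweep(p, 2, zooms, "/") - 0.5
    pts[[length(pts) + 1]] <-
      t(vox_to_ras[1:3, 1:3] %*% t(vox) + vox_to_ras[1:3, 4])
  }
  if (n_count > 0 && length(pts) != n_count) {
    warning("TRK header announced ", n_count, " tracks but file holds ",
            length(pts))
  }
  if (length(pts) == 0) {
    return(structure(list(points = list(), meta = empty_meta()),
                     class = "streamline_set"))
  }
  streamline_set(pts)
}

empty_meta <- function() {
  tibble::tibble(
    streamline = integer(), subject = character(),
    group = character(), bundle = character()
  )
}

write_trk <- function(x, path, reference = NULL) {
  if (is.null(reference)) {
    affine <- diag(4)
    dim3 <- c(1L, 1L, 1L)
  } else {
    affine <- reference$affine
    dim3 <- dim(reference$data)
  }
  zooms <- affine_voxel_size(affine)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), as.raw(0)), con)
  writeBin(as.integer(dim3), con, size = 2)
  writeBin(as.numeric(zooms), con, size = 4)
  writeBin(numeric(3), con, size = 4) # origin
  writeBin(0L, con, size = 2) # n_scalars
  writeBin(raw(200), con)
  writeBin(0L, con, size = 2) # n_properties
  writeBin(raw(200), con)
  writeBin(as.numeric(t(affine)), con, size = 4)
  writeBin(raw(444), con)
  vo <- trk_orientation_code(affine)
  writeBin(c(charToRaw(vo), as.raw(0)), con) # voxel_order
  writeBin(raw(4), con) # pad2
  writeBin(numeric(6), con, size = 4) # image_orientation_patient
  writeBin(raw(2 + 6), con) # pad1 + invert/swap flags
  writeBin(length(x$points), con, size = 4)
  writeBin(2L, con, size = 4) # version
  writeBin(1000L, con, size = 4)
  inv <- solve(affine)
  for (p in x$points) {
    vox <- t(inv[1:3, 1:3] %*% t(p) + inv[1:3, 4])
    voxmm <- sweep(vox + 0.5, 2, zooms, "*")
    writeBin(nrow(p), con, size = 4)
    writeBin(as.numeric(t(voxmm)), con, size = 4)
  }
}

read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1)
  if (!grepl("^mrtrix tracks", first)) {
    stop("not a TCK file (bad magic): ", path, call. = FALSE)
  }
  offset <- NA_real_
  datatype <- "Float32LE"
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("corrupt TCK header (no END)", call. = FALSE)
    if (line == "END") break
    kv <- sub("^([^:]+):\\s*(.*)$", "\\1\t\\2", line)
    kv <- strsplit(kv, "\t")[[1]]
    if (length(kv) == 2) {
      if (kv[1] == "file") {
        offset <- as.numeric(sub("^\\.\\s+", "", kv[2]))
      } else if (kv[1] == "datatype") {
        datatype <- kv[2]
      }
    }
  }
  if (!datatype %in% c("Float32LE", "Float32")) {
    stop("unsupported TCK datatype: ", datatype, call. = FALSE)
  }
  if (!is.finite(offset)) stop("corrupt TCK header (no file offset)",
                               call. = FALSE)
  seek(con, offset)
  vals <- readBin(con, "numeric", file.size(path), size = 4)
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  breaks <- which(!is.finite(m[, 1]))
  pts <- list()
  start <- 1
  for (b in breaks) {
    if (b > start) pts[[length(pts) + 1]] <- m[start:(b - 1), , drop = FALSE]
    start <- b + 1
    if (all(is.infinite(m[b, ]))) break
  }
  if (length(pts) == 0) {
    return(structure(list(points = list(), meta = empty_meta()),
                     class = "streamline_set"))
  }
  streamline_set(pts)
}

write_tck <- function(x, path) {
  header <- paste0(
    "mrtrix tracks\n",
    "datatype: Float32LE\n",
    "count: ", length(x$points), "\n"
  )
  # 'file: . <offset>' must state its own end position; fix by padding
  offset <- nchar(header) + nchar("file: . \nEND\n") + 6
  header <- paste0(header, sprintf("file: . %6d\nEND\n", offset))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  for (p in x$points) {
    writeBin(as.numeric(t(p)), con, size = 4)
    writeBin(rep(NaN, 3), con, size = 4)
  }
  writeBin(rep(Inf, 3), con, size = 4)
}
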