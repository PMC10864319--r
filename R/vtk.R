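# Minimal legacy-ASCII VTK I/O for point-cloud field data.
#
# Fields are exchanged as UNSTRUCTURED_GRID files whose points are cell
# centres (mm) carrying per-point scalar arrays (POINT_DATA). The reader
# additionally accepts CELL_DATA on meshes with connectivity, in which case
# values are attached to cell centroids. This covers probe-style exports
# from external VOF solvers; sub-cell geometry is never reconstructed.

#' Write a point-cloud field to a legacy VTK file
#'
#' @param centers n x 3 matrix of point coordinates (mm)
#' @param data named list of per-point numeric vectors (scalar arrays)
#' @param file output path
#' @param title dataset title line
#' @return the path, invisibly
#' @export
write_vtk_points <- function(centers, data, file, title = "shakeflask field") {
  centers <- as.matrix(centers)
  n <- nrow(centers)
  stopifnot(ncol(centers) == 3, all(vapply(data, length, 1L) == n))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  utils::write.table(format(centers, digits = 10, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(paste("CELLS", n, 2L * n), con)
  utils::write.table(cbind(1L, seq_len(n) - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(paste("CELL_TYPES", n), con)
  writeLines(as.character(rep(1L, n)), con)
  writeLines(paste("POINT_DATA", n), con)
  for (nm in names(data)) {
    writeLines(c(paste("SCALARS", nm, "double", 1),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(data[[nm]], digits = 12, trim = TRUE,
                      scientific = TRUE), con)
  }
  invisible(file)
}

#' Read a legacy ASCII VTK file
#'
#' Parses POINTS, CELLS and the scalar arrays under POINT_DATA or
#' CELL_DATA. Point-data values are attached to the points themselves;
#' cell-data values are attached to cell centroids.
#'
#' @param file path to a legacy ASCII VTK file
#' @return list with `centers` (n x 3, mm) and `data` (named list of
#'   numeric vectors)
#' @export
read_vtk <- function(file) {
  ln <- readLines(file, warn = FALSE)
  if (length(ln) < 5 || !grepl("^# vtk DataFile", ln[1]))
    stop("not a legacy VTK file: ", file)
  if (toupper(trimws(ln[3])) != "ASCII")
    stop("only ASCII legacy VTK is supported")
  toks_after <- function(i, n_vals) {
    # collect n_vals whitespace-separated numbers starting at line i+1
    vals <- numeric(0); j <- i
    while (length(vals) < n_vals && j < length(ln)) {
      j <- j + 1L
      v <- suppressWarnings(as.numeric(strsplit(trimws(ln[j]), "\\s+")[[1]]))
      vals <- c(vals, v)
    }
    if (length(vals) < n_vals) stop("truncated VTK array near line ", i)
    list(vals = vals[seq_len(n_vals)], next_line = j + 1L)
  }
  pts <- NULL; cells <- NULL; arrays <- list(); mode <- NULL
  i <- 4L
  while (i <= length(ln)) {
    l <- trimws(ln[i])
    if (grepl("^POINTS", l)) {
      n <- as.integer(strsplit(l, "\\s+")[[1]][2])
      r <- toks_after(i, 3L * n)
      pts <- matrix(r$vals, ncol = 3, byrow = TRUE)
      i <- r$next_line
    } else if (grepl("^CELLS", l)) {
      hdr <- as.integer(strsplit(l, "\\s+")[[1]][2:3])
      r <- toks_after(i, hdr[2])
      # unpack connectivity: [n_pts, id...] repeated
      conn <- list(); p <- 1L
      for (ci in seq_len(hdr[1])) {
        np <- r$vals[p]
        conn[[ci]] <- r$vals[p + seq_len(np)] + 1L
        p <- p + np + 1L
      }
      cells <- conn
      i <- r$next_line
    } else if (grepl("^(POINT_DATA|CELL_DATA)", l)) {
      mode <- sub("\\s.*", "", l)
      i <- i + 1L
    } else if (grepl("^SCALARS", l)) {
      nm <- strsplit(l, "\\s+")[[1]][2]
      nvals <- if (identical(mode, "CELL_DATA")) length(cells) else nrow(pts)
      skip <- if (grepl("^LOOKUP_TABLE", trimws(ln[i + 1L]))) 1L else 0L
      r <- toks_after(i + skip, nvals)
      arrays[[nm]] <- structure(r$vals, vtk_mode = mode)
      i <- r$next_line
    } else {
      i <- i + 1L
    }
  }
  if (is.null(pts)) stop("no POINTS section in ", file)
  cell_mode <- any(vapply(arrays, function(a)
    identical(attr(a, "vtk_mode"), "CELL_DATA"), logical(1)))
  centers <- pts
  if (cell_mode && !is.null(cells)) {
    centers <- t(vapply(cells, function(id) colMeans(pts[id, , drop = FALSE]),
                        numeric(3)))
    arrays <- lapply(arrays, function(a) {
      if (identical(attr(a, "vtk_mode"), "CELL_DATA")) as.numeric(a)
      else stop("mixed POINT_DATA and CELL_DATA arrays are not supported")
    })
  } else {
    arrays <- lapply(arrays, as.numeric)
  }
  list(centers = centers, data = arrays)
}

# Nearest-neighbour sampler over a set of points, chunked to bound memory.
nearest_point_sampler <- function(centers, values, max_dist = Inf) {
  force(centers); force(values)
  function(x, y, z) {
    n <- length(x)
    out <- numeric(n)
    chunk <- 2000L
    for (s in seq(1L, n, by = chunk)) {
      e <- min(s + chunk - 1L, n)
      d2 <- outer(x[s:e]^2 + y[s:e]^2 + z[s:e]^2,
                  rowSums(centers^2), "+") -
        2 * (cbind(x[s:e], y[s:e], z[s:e]) %*% t(centers))
      j <- max.col(-d2, ties.method = "first")
      v <- values[j]
      if (is.finite(max_dist))
        v[d2[cbind(seq_along(j), j)] > max_dist^2] <- NA_real_
      out[s:e] <- v
    }
    out
  }
}

#' Volume-fraction field from a VTK file
#'
#' Nearest-cell sampling of a liquid volume fraction array stored in a
#' legacy ASCII VTK file (point or cell data), as written by
#' [write_field_vtk()] or exported probe-style by an external solver.
#'
#' @param file VTK path
#' @param geometry bounding [flask_geometry()]
#' @param array name of the volume-fraction array
#' @return an [alpha_field()]
#' @export
read_alpha_vtk <- function(file, geometry, array = "alpha") {
  v <- read_vtk(file)
  if (is.null(v$data[[array]]))
    stop("VTK file ", file, " carries no array named '", array,
         "' (found: ", paste(names(v$data), collapse = ", "), ")")
  alpha_field(nearest_point_sampler(v$centers, v$data[[array]]),
              geometry, meta = list(source = file))
}

#' Field set from a VTK file
#'
#' Builds a dissipation-ready [field_set()] from the arrays `alpha`, `V`
#' (cell volume, m^3), and `S2`, `k`, `omega` where present.
#'
#' @param file VTK path
#' @param fluid a [fluid_properties()]
#' @return a [field_set()]
#' @export
read_field_vtk <- function(file, fluid) {
  v <- read_vtk(file)
  need <- c("alpha", "V")
  miss <- setdiff(need, names(v$data))
  if (length(miss))
    stop("VTK file ", file, " is missing required array(s): ",
         paste(miss, collapse = ", "))
  zero <- rep(0, nrow(v$centers))
  field_set(volume = v$data$V, alpha = v$data$alpha, fluid = fluid,
            S2 = if (is.null(v$data$S2)) zero else v$data$S2,
            k = if (is.null(v$data$k)) zero else v$data$k,
            omega = if (is.null(v$data$omega)) zero else v$data$omega)
}
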