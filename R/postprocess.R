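#' Regular field-reconstruction grid
#'
#' @param origin Node `(x, y)` of the lower-left grid node, m.
#' @param spacing Node spacing, m (> 0).
#' @param nx,ny Node counts.
#' @return A `field_grid` list; interpolation fills in per-node fields.
#' @export
field_grid <- function(origin, spacing, nx, ny) {
  stopifnot(length(origin) == 2, spacing > 0, nx >= 1, ny >= 1)
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 nx = as.integer(nx), ny = as.integer(ny)),
            class = "field_grid")
}

#' Default grid covering a scene at the lattice spacing
#' @param scene An `sph_scene`.
#' @return A [field_grid()] spanning the scene's domain box.
#' @export
scene_grid <- function(scene) {
  b <- scene$ps$box
  s <- scene$spacing
  field_grid(c(b[1], b[3]), s,
             floor((b[2] - b[1]) / s) + 1, floor((b[4] - b[3]) / s) + 1)
}

grid_xy <- function(grid) {
  list(x = grid$origin[1] + (0:(grid$nx - 1)) * grid$spacing,
       y = grid$origin[2] + (0:(grid$ny - 1)) * grid$spacing)
}

interp_call <- function(ps, kernel, grid, mask_rel = 1e-6) {
  if (anyNA(ps$rho)) stop("densities are not current; run compute_density()")
  bx <- ps_box(ps)
  cpp_grid_interp(ps$x, ps$y, ps$vx, ps$vy, ps$mass, ps$rho,
                  kernel$h, grid$origin[1], grid$origin[2], grid$spacing,
                  grid$nx, grid$ny, bx$xlo, bx$xhi, bx$periodic, mask_rel)
}

#' Interpolate the velocity field onto a grid
#'
#' Shepard-normalized SPH interpolation of particle velocities; nodes with
#' (near) zero kernel weight are masked. The normalization makes constant
#' fields exact on unmasked nodes.
#'
#' @param ps A [particle_system()] with current densities.
#' @param kernel A [kernel_spec()].
#' @param grid A [field_grid()].
#' @return The grid with matrices `ux`, `uy`, `speed` (ny rows, nx columns)
#'   and logical `mask` (TRUE = no data).
#' @export
interpolate_grid <- function(ps, kernel, grid) {
  r <- interp_call(ps, kernel, grid)
  shape <- function(v) matrix(v, nrow = grid$ny, ncol = grid$nx, byrow = TRUE)
  grid$ux <- shape(r$ux)
  grid$uy <- shape(r$uy)
  grid$speed <- sqrt(grid$ux^2 + grid$uy^2)
  grid$mask <- shape(r$mask)
  grid
}

#' Shear-stress field
#'
#' \eqn{\tau_{xy} = \mu (\partial u_x/\partial y + \partial u_y/\partial x)}
#' from first-order-consistent (moving-least-squares) SPH velocity
#' gradients, exact for linear velocity fields.
#'
#' @param ps A [particle_system()] with current densities.
#' @param kernel A [kernel_spec()].
#' @param grid A [field_grid()].
#' @param mu Dynamic viscosity, Pa s.
#' @return The grid with matrices `tau` (signed) and `tau_abs`, plus `mask`.
#' @export
shear_stress_field <- function(ps, kernel, grid, mu) {
  r <- interp_call(ps, kernel, grid)
  shape <- function(v) matrix(v, nrow = grid$ny, ncol = grid$nx, byrow = TRUE)
  grid$tau <- mu * (shape(r$dudy) + shape(r$dvdx))
  grid$tau_abs <- abs(grid$tau)
  grid$mask <- shape(r$mask)
  grid
}

#' Membrane kinematics time series
#'
#' Opening width (Euclidean distance between the two leaflet tip particles,
#' the particles farthest along each chain from its anchor), tip positions,
#' and a symmetry index `|y_tip_upper + y_tip_lower| / Z` for each snapshot.
#'
#' @param snapshots List of snapshot data frames (as written by
#'   [write_snapshot()]) or of [particle_system()] objects.
#' @param leaflets List with id vectors `upper` and `lower` (root to tip).
#' @param Z Channel half-thickness, m (for the symmetry index).
#' @param times Optional snapshot times; defaults to attribute `time` or
#'   the snapshot index.
#' @return Data frame with columns `time, x_tip_upper, y_tip_upper,
#'   x_tip_lower, y_tip_lower, opening, symmetry_index`.
#' @export
membrane_kinematics <- function(snapshots, leaflets, Z, times = NULL) {
  if (inherits(snapshots, "particle_system") || is.data.frame(snapshots))
    snapshots <- list(snapshots)
  if (length(snapshots) == 0) stop("at least one snapshot is required")
  rows <- lapply(seq_along(snapshots), function(q) {
    sn <- snapshots[[q]]
    df <- if (inherits(sn, "particle_system")) as.data.frame(sn) else sn
    if (!any(df$kind == "MEMBRANE"))
      stop("snapshot ", q, " contains no membrane particles")
    tu <- leaflets$upper[length(leaflets$upper)]
    tl <- leaflets$lower[length(leaflets$lower)]
    tm <- if (!is.null(times)) times[q]
          else if (!is.null(attr(sn, "time"))) attr(sn, "time")
          else if (inherits(sn, "particle_system")) sn$time else q
    data.frame(time = tm,
               x_tip_upper = df$x[tu], y_tip_upper = df$y[tu],
               x_tip_lower = df$x[tl], y_tip_lower = df$y[tl],
               opening = sqrt((df$x[tu] - df$x[tl])^2 + (df$y[tu] - df$y[tl])^2),
               symmetry_index = abs(df$y[tu] + df$y[tl]) / Z)
  })
  do.call(rbind, rows)
}

#' Per-cycle opening maxima
#' @param kin Output of [membrane_kinematics()].
#' @param period Forcing period, s.
#' @return Data frame with `cycle` and `max_opening`.
#' @export
opening_maxima <- function(kin, period) {
  cyc <- floor(kin$time / period)
  agg <- tapply(kin$opening, cyc, max)
  data.frame(cycle = as.integer(names(agg)), max_opening = as.numeric(agg))
}

#' Write a particle snapshot
#'
#' CSV format: columns `id, kind, x, y, vx, vy, rho, p` with 17 significant
#' digits (value-preserving round trip). VTK legacy POLYDATA: points with
#' point-data scalars `kind`, `speed` and `pressure`, loadable by standard
#' VTK readers.
#'
#' @param ps A [particle_system()] or snapshot data frame.
#' @param path Output file path.
#' @param format `"csv"` or `"vtk"`.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(ps, path, format = c("csv", "vtk")) {
  format <- match.arg(format)
  df <- if (inherits(ps, "particle_system")) as.data.frame(ps) else ps
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("id,kind,x,y,vx,vy,rho,p", con)
    if (nrow(df) > 0) {
      num <- function(v) sprintf("%.17g", v)
      writeLines(paste(df$id, df$kind, num(df$x), num(df$y), num(df$vx),
                       num(df$vy), num(df$rho), num(df$p), sep = ","), con)
    }
  } else {
    n <- nrow(df)
    num <- function(v) sprintf("%.9g", v)
    lines <- c("# vtk DataFile Version 3.0",
               "sphvalve particle snapshot", "ASCII", "DATASET POLYDATA",
               paste("POINTS", n, "double"))
    if (n > 0)
      lines <- c(lines, paste(num(df$x), num(df$y), "0"))
    lines <- c(lines,
               paste("VERTICES", n, 2 * n))
    if (n > 0) lines <- c(lines, paste(1, 0:(n - 1)))
    lines <- c(lines, paste("POINT_DATA", n),
               "SCALARS kind int 1", "LOOKUP_TABLE default")
    if (n > 0) lines <- c(lines, as.character(kind_code(df$kind)))
    lines <- c(lines, "SCALARS speed double 1", "LOOKUP_TABLE default")
    if (n > 0) lines <- c(lines, num(sqrt(df$vx^2 + df$vy^2)))
    lines <- c(lines, "SCALARS pressure double 1", "LOOKUP_TABLE default")
    if (n > 0) lines <- c(lines, num(df$p))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a CSV particle snapshot
#'
#' @param path CSV file written by [write_snapshot()].
#' @return Snapshot data frame with columns `id, kind, x, y, vx, vy, rho, p`.
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != "id,kind,x,y,vx,vy,rho,p")
    stop("malformed snapshot header at line 1 of ", path)
  if (length(lines) == 1)
    return(data.frame(id = integer(0), kind = character(0), x = numeric(0),
                      y = numeric(0), vx = numeric(0), vy = numeric(0),
                      rho = numeric(0), p = numeric(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines[-1], ",", fixed = TRUE)
  bad <- which(lengths(parts) != 8)
  if (length(bad))
    stop("malformed snapshot row at line ", bad[1] + 1, " of ", path)
  m <- do.call(rbind, parts)
  kinds <- m[, 2]
  if (!all(kinds %in% PARTICLE_KINDS))
    stop("unknown particle kind at line ",
         which(!(kinds %in% PARTICLE_KINDS))[1] + 1, " of ", path)
  num <- function(col, name) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v) && any(is.na(v) & m[, col] != "NA"))
      stop("non-numeric ", name, " at line ",
           which(is.na(v) & m[, col] != "NA")[1] + 1, " of ", path)
    v
  }
  data.frame(id = as.integer(m[, 1]), kind = kinds,
             x = num(3, "x"), y = num(4, "y"), vx = num(5, "vx"),
             vy = num(6, "vy"), rho = num(7, "rho"), p = num(8, "p"),
             stringsAsFactors = FALSE)
}
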