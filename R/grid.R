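ROW_LABELS <- c("A", "B", "C", "D", "E", "F", "G")
COL_LABELS <- c("J", "K", "L", "M", "N", "O", "P")

#' Marker grid layout of the anterior chest wall
#'
#' The 45-marker grid spans seven cranio-caudal rows (A, at the clavicles,
#' through G, at the anterior iliac spines) and seven columns (J through P,
#' right midaxillary to left midaxillary; M is the midline). Interior rows
#' B-F carry all seven columns; the boundary rows A and G carry the central
#' five (K-O), for 45 nodes in total. Row E (the lower costal margin) is the
#' border between the rib-cage (RC, rows A-E) and abdominal (AB, rows E-G)
#' compartments.
#'
#' @return A tibble with one row per grid node: `node` (e.g. `"E-M"`), `row`,
#'   `col`, `row_idx` (1 = A, cranial), `col_idx` (1 = J, subject's right;
#'   4 = M, midline).
#' @examples
#' nrow(grid_layout())  # 45
#' @export
grid_layout <- function() {
  rows <- lapply(seq_along(ROW_LABELS), function(r) {
    cols <- if (r %in% c(1L, 7L)) 2:6 else 1:7
    tibble(
      node = paste0(ROW_LABELS[r], "-", COL_LABELS[cols]),
      row = ROW_LABELS[r], col = COL_LABELS[cols],
      row_idx = r, col_idx = cols
    )
  })
  bind_rows(rows)
}

#' IMU-to-grid-node assignment
#'
#' Maps the nine IMUs onto grid nodes, mirror-symmetric about the midline:
#' IMU 1 on the upper sternum (B-M; this is the unit tapped for stream
#' synchronisation), IMUs 2/3 lateral on the rib cage (C-K, C-O), IMU 4 on
#' the xiphoid line (D-M), IMU 5 centrally on the lower costal margin (E-M),
#' IMUs 6 and 8 on the abdominal midline (F-M, G-M), and IMUs 7/9 lateral on
#' the abdomen (F-K, F-O).
#'
#' @return Named character vector `imu1` ... `imu9` of grid node labels.
#' @export
imu_node_map <- function() {
  c(imu1 = "B-M", imu2 = "C-K", imu3 = "C-O", imu4 = "D-M", imu5 = "E-M",
    imu6 = "F-M", imu7 = "F-K", imu8 = "G-M", imu9 = "F-O")
}

#' Build the 64-triangle chest-wall mesh
#'
#' Triangulates the marker grid into 64 non-overlapping triangles arranged
#' mirror-symmetrically about the midline. Each interior row gap (B-C, C-D,
#' D-E, E-F) contributes six quadrilaterals (12 triangles); the boundary
#' strips A-B and F-G triangulate only the central four column gaps (8
#' triangles each). Within each quadrilateral the diagonal runs toward
#' column M, mirrored across the midline, which makes the triangulation
#' exactly symmetric. Triangles between rows A and E belong to the rib cage
#' (RC, 44 triangles); those between rows E and G to the abdomen (AB, 20).
#'
#' @param grid A grid layout tibble from [grid_layout()].
#' @return A tibble of class `resp_mesh` with columns `triangle`, `n1`,
#'   `n2`, `n3` (node labels) and `compartment` (`"RC"`/`"AB"`).
#' @examples
#' mesh <- build_grid_mesh()
#' nrow(mesh)                  # 64
#' table(mesh$compartment)     # AB 20, RC 44
#' @export
build_grid_mesh <- function(grid = grid_layout()) {
  check_grid(grid)
  node_at <- function(r, c) paste0(ROW_LABELS[r], "-", COL_LABELS[c])
  tris <- list()
  for (r in 1:6) {
    col_gaps <- if (r %in% c(1L, 6L)) 2:5 else 1:6
    for (cg in col_gaps) {
      a <- node_at(r, cg);      b <- node_at(r, cg + 1)
      d <- node_at(r + 1, cg);  e <- node_at(r + 1, cg + 1)
      # diagonal toward the midline column (M = index 4), mirrored about it
      if (cg <= 3) {
        two <- list(c(a, e, d), c(a, b, e))
      } else {
        two <- list(c(a, b, d), c(b, e, d))
      }
      comp <- if (r <= 4) "RC" else "AB"
      tris <- c(tris, lapply(two, function(tr) {
        tibble(n1 = tr[1], n2 = tr[2], n3 = tr[3], compartment = comp)
      }))
    }
  }
  mesh <- bind_rows(tris)
  mesh <- tibble(triangle = seq_len(nrow(mesh)), mesh)
  stopifnot(nrow(mesh) == 64L)
  class(mesh) <- c("resp_mesh", class(mesh))
  attr(mesh, "grid") <- grid
  mesh
}

check_grid <- function(grid) {
  if (nrow(grid) != 45L) abort("Grid must contain exactly 45 nodes.")
  counts <- table(grid$row)
  full <- ROW_LABELS[2:6]
  if (any(counts[full] != 7L) || any(counts[c("A", "G")] != 5L)) {
    abort("Rows B-F must carry 7 nodes (J-P); rows A and G must carry 5 (K-O).")
  }
  mirrored <- paste0(grid$row, "-", COL_LABELS[8L - grid$col_idx])
  if (!setequal(mirrored, grid$node)) {
    abort("Grid must be mirror-symmetric about column M.")
  }
  invisible(grid)
}

#' Per-compartment prism volumes for one marker frame
#'
#' Each triangle contributes the volume of the vertical prism between the
#' reference plane and the triangle: (area of its horizontal projection) x
#' (mean height of its three vertices above the plane). Compartment volumes
#' are sums over the labelled triangles, so `CW = RC + AB` holds exactly.
#' Degenerate triangles (zero projected area) contribute zero and raise a
#' warning.
#'
#' @param mesh A `resp_mesh`.
#' @param positions Numeric matrix (45 x 3, metres) with rownames matching
#'   the grid node labels; columns are x (cranial), y (lateral), z (vertical,
#'   height above the bed plane).
#' @param reference_height Height (m) of the reference plane (default 0, the
#'   bed plane). Any fixed reference yields volume series differing only by
#'   a constant.
#' @return Named numeric vector `c(CW =, RC =, AB =)` in litres.
#' @examples
#' mesh <- build_grid_mesh()
#' pos <- grid_node_template(scale = 1)
#' frame_volume(mesh, pos)
#' @export
frame_volume <- function(mesh, positions, reference_height = 0) {
  stopifnot(is.matrix(positions), ncol(positions) == 3)
  missing <- setdiff(unique(c(mesh$n1, mesh$n2, mesh$n3)), rownames(positions))
  if (length(missing)) {
    abort(paste0("Positions missing for node(s): ", paste(missing, collapse = ", ")))
  }
  p1 <- positions[mesh$n1, , drop = FALSE]
  p2 <- positions[mesh$n2, , drop = FALSE]
  p3 <- positions[mesh$n3, , drop = FALSE]
  area <- 0.5 * abs((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
                      (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2]))
  if (any(area == 0)) {
    warning("Degenerate triangle(s) with zero projected area contribute 0 volume.")
  }
  height <- (p1[, 3] + p2[, 3] + p3[, 3]) / 3 - reference_height
  vol <- 1000 * area * height  # m^3 -> L
  rc <- sum(vol[mesh$compartment == "RC"])
  ab <- sum(vol[mesh$compartment == "AB"])
  c(CW = rc + ab, RC = rc, AB = ab)
}

#' Compartmental volume series from marker trajectories
#'
#' Applies the prism-volume computation frame by frame, using the bed plane
#' (z = 0) as reference. Marker coordinates are taken in millimetres (the
#' native marker unit) and converted internally; volumes are in litres.
#'
#' @param markers Marker tibble: a `time` column plus `<NODE>_X/_Y/_Z`
#'   columns in mm for all 45 grid nodes. Frames with missing (gap) samples
#'   must be filled beforehand (see [fill_gaps()]).
#' @param mesh A `resp_mesh` (default the standard 64-triangle mesh).
#' @param rate Sampling rate (Hz); taken from the `rate` attribute of
#'   `markers` if absent.
#' @return A tibble of class `resp_volumes` with columns `time`, `V_CW`,
#'   `V_RC`, `V_AB` (L) and a `rate` attribute.
#' @export
compute_volume_series <- function(markers, mesh = build_grid_mesh(),
                                  rate = attr(markers, "rate")) {
  if (anyNA(markers)) {
    abort("Marker series contains unfilled gaps; run fill_gaps() first.")
  }
  nodes <- unique(c(mesh$n1, mesh$n2, mesh$n3))
  get_mat <- function(axis) {
    cols <- paste0(nodes, "_", axis)
    miss <- setdiff(cols, names(markers))
    if (length(miss)) {
      abort(paste0("Marker columns missing: ", paste(miss, collapse = ", ")))
    }
    as.matrix(markers[, cols]) / 1000  # mm -> m
  }
  X <- get_mat("X"); Y <- get_mat("Y"); Z <- get_mat("Z")
  colnames(X) <- colnames(Y) <- colnames(Z) <- nodes
  rc <- ab <- numeric(nrow(markers))
  for (k in seq_len(nrow(mesh))) {
    i1 <- mesh$n1[k]; i2 <- mesh$n2[k]; i3 <- mesh$n3[k]
    area <- 0.5 * abs((X[, i2] - X[, i1]) * (Y[, i3] - Y[, i1]) -
                        (X[, i3] - X[, i1]) * (Y[, i2] - Y[, i1]))
    vol <- 1000 * area * (Z[, i1] + Z[, i2] + Z[, i3]) / 3
    if (mesh$compartment[k] == "RC") rc <- rc + vol else ab <- ab + vol
  }
  out <- tibble(time = markers$time, V_CW = rc + ab, V_RC = rc, V_AB = ab)
  attr(out, "rate") <- rate
  class(out) <- c("resp_volumes", class(out))
  out
}

#' Export a mesh as an indexed-triangle table
#'
#' @param mesh A `resp_mesh`.
#' @return A plain tibble (triangle, n1, n2, n3, compartment), convenient for
#'   writing to CSV for inspection.
#' @export
mesh_as_tibble <- function(mesh) {
  out <- as_tibble(unclass(mesh)[setdiff(names(mesh), character(0))])
  out[c("triangle", "n1", "n2", "n3", "compartment")]
}
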