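# Source-space and sensor geometry plus the single-sphere MEG forward model.

#' Source space: triangulated surface carrying the candidate dipoles
#'
#' A source space is a triangle mesh whose vertices host current dipoles
#' oriented along the local outward surface normal (the usual cortical
#' orientation constraint).  Vertex areas are barycentric-lumped: each vertex
#' owns one third of the area of every incident triangle.
#'
#' @param vertices numeric matrix, n x 3, vertex positions in metres.
#' @param triangles integer matrix, m x 3, 1-based vertex indices.
#' @param normals optional n x 3 matrix of unit vertex normals; when `NULL`
#'   they are computed as area-weighted averages of incident triangle normals
#'   and re-oriented to point away from the mesh centroid.
#' @return An object of class `source_space` with fields `vertices`,
#'   `triangles`, `normals`, `vertex_area` (m^2), `total_area` (m^2).
#' @export
source_space <- function(vertices, triangles, normals = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  n <- nrow(vertices)
  if (min(triangles) < 1L || max(triangles) > n)
    stop("triangle indices out of range [1, ", n, "]")
  if (!all(seq_len(n) %in% as.vector(triangles)))
    stop("every vertex must belong to at least one triangle")

  tri_geom <- triangle_geometry(vertices, triangles)
  vertex_area <- numeric(n)
  for (k in 1:3) {
    contrib <- tapply(tri_geom$area, triangles[, k], sum)
    idx <- as.integer(names(contrib))
    vertex_area[idx] <- vertex_area[idx] + contrib / 3
  }
  if (any(vertex_area <= 0)) stop("degenerate mesh: some vertex areas are zero")

  if (is.null(normals)) {
    # area-weighted average of incident triangle normals, re-oriented outward
    normals <- matrix(0, n, 3)
    w <- tri_geom$normal * tri_geom$area
    for (k in 1:3) {
      s <- rowsum(w, triangles[, k])
      idx <- as.integer(rownames(s))
      normals[idx, ] <- normals[idx, ] + s
    }
    ctr <- colMeans(vertices)
    out <- sweep(vertices, 2, ctr)
    flip <- rowSums(normals * out) < 0
    normals[flip, ] <- -normals[flip, ]
  } else {
    normals <- as.matrix(normals)
  }
  normals <- normals / sqrt(rowSums(normals^2))

  structure(
    list(vertices = vertices, triangles = triangles, normals = normals,
         vertex_area = vertex_area, total_area = sum(tri_geom$area)),
    class = "source_space")
}

# per-triangle unit normals and areas
triangle_geometry <- function(vertices, triangles) {
  p1 <- vertices[triangles[, 1], , drop = FALSE]
  p2 <- vertices[triangles[, 2], , drop = FALSE]
  p3 <- vertices[triangles[, 3], , drop = FALSE]
  cr <- cross3(p2 - p1, p3 - p1)
  nrm <- sqrt(rowSums(cr^2))
  list(area = nrm / 2, normal = cr / nrm)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("source_space: %d vertices, %d triangles, total area %.2f cm^2\n",
              nrow(x$vertices), nrow(x$triangles), x$total_area * 1e4))
  invisible(x)
}

#' Build a spherical (icosphere) source space
#'
#' Subdivides a regular icosahedron `subdivision_level` times, projecting the
#' new vertices back onto the sphere, and orients all dipole normals radially
#' outward.  Vertex counts follow the icosphere series 12, 42, 162, 642, ...
#' (`10 * 4^level + 2`).
#'
#' @param subdivision_level non-negative integer; 0 gives the icosahedron.
#' @param radius sphere radius in metres.
#' @param center length-3 numeric, sphere centre (default origin).
#' @return A [source_space()].
#' @examples
#' ss <- build_sphere_source_space(2, radius = 0.08)
#' nrow(ss$vertices)  # 162
#' @export
build_sphere_source_space <- function(subdivision_level, radius,
                                      center = c(0, 0, 0)) {
  stopifnot(subdivision_level >= 0, radius > 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))

  for (lev in seq_len(subdivision_level)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- lapply(seq_len(nv), function(i) v[i, ])
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j), sep = "-")
      hit <- edge_mid[[key]]
      if (!is.null(hit)) return(hit)
      m <- (vlist[[i]] + vlist[[j]]) / 2
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1]] <<- m
      idx <- length(vlist)
      edge_mid[[key]] <- idx
      idx
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c3 <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf[(t - 1) * 4 + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }

  vertices <- sweep(v * radius, 2, center, `+`)
  normals <- v  # unit radial directions
  source_space(vertices, f, normals = normals)
}

#' Build a folded ("wrinkled") spherical cortical stand-in surface
#'
#' A perfect sphere is a degenerate source space for orientation-constrained
#' MEG: with a concentric spherical conductor every surface normal is radial,
#' and radial dipoles produce no external field, so the whole lead field
#' vanishes.  Real cortex is folded, which is what makes normally-oriented
#' sources visible.  This generator emulates that by modulating the icosphere
#' radius with a fixed smooth angular function,
#' `r(u) = radius * (1 + wrinkle_amplitude * f(u))`, and recomputing vertex
#' normals from the resulting mesh, so dipole orientations acquire tangential
#' components everywhere except at the isolated extrema of `f`.
#'
#' @inheritParams build_sphere_source_space
#' @param wrinkle_amplitude relative radial modulation depth (default 0.12).
#' @param wrinkle_order angular frequency of the modulation (default 6);
#'   larger values give finer folds and larger normal tilts.
#' @return A [source_space()] with mesh-derived (non-radial) normals.
#' @export
build_cortical_source_space <- function(subdivision_level, radius,
                                        center = c(0, 0, 0),
                                        wrinkle_amplitude = 0.12,
                                        wrinkle_order = 6) {
  stopifnot(wrinkle_amplitude >= 0, wrinkle_amplitude < 0.5)
  base <- build_sphere_source_space(subdivision_level, 1, c(0, 0, 0))
  u <- base$vertices
  # fixed smooth folding pattern: skewed-axis sinusoids, no randomness
  e1 <- c(1, 0.3, -0.2); e2 <- c(-0.25, 1, 0.35); e3 <- c(0.2, -0.3, 1)
  e1 <- e1 / sqrt(sum(e1^2)); e2 <- e2 / sqrt(sum(e2^2)); e3 <- e3 / sqrt(sum(e3^2))
  f <- (sin(wrinkle_order * (u %*% e1)) +
        sin(wrinkle_order * (u %*% e2) + 1.0) +
        sin(wrinkle_order * (u %*% e3) + 2.0)) / 3
  r <- radius * (1 + wrinkle_amplitude * as.vector(f))
  vertices <- sweep(u * r, 2, center, `+`)
  source_space(vertices, base$triangles)
}

#' Read a triangle mesh as a source space
#'
#' Accepts Wavefront OBJ (`v`/`f` records, triangular faces only; `f` entries
#' may carry `/` texture/normal slots, which are ignored) and FreeSurfer ASCII
#' surfaces (optional `#!ascii` header line, then vertex/face counts, vertex
#' rows `x y z 0`, and 0-based triangle rows).  Normals are recomputed from
#' the triangulation, outward from the centroid.
#'
#' @param path file path.
#' @param format `"auto"` (default, by extension/content), `"obj"` or
#'   `"fsascii"`.
#' @return A [source_space()].
#' @export
load_mesh <- function(path, format = c("auto", "obj", "fsascii")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mesh file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.obj$", path, ignore.case = TRUE) ||
                  any(grepl("^\\s*v\\s", lines[seq_len(min(50, length(lines)))])))
      "obj" else "fsascii"
  }
  if (format == "obj") parse_obj(lines) else parse_fs_ascii(lines)
}

parse_obj <- function(lines) {
  vs <- list(); fs <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    tok <- strsplit(ln, "\\s+")[[1]]
    if (tok[1] == "v") {
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (length(tok) < 4 || anyNA(xyz))
        stop("malformed OBJ vertex at line ", i, ": ", lines[i])
      vs[[length(vs) + 1]] <- xyz
    } else if (tok[1] == "f") {
      idx <- suppressWarnings(as.integer(sub("/.*$", "", tok[-1])))
      if (anyNA(idx)) stop("malformed OBJ face at line ", i, ": ", lines[i])
      if (length(idx) != 3)
        stop("unsupported format: non-triangular face (", length(idx),
             " vertices) at line ", i)
      fs[[length(fs) + 1]] <- idx
    }
  }
  if (!length(vs) || !length(fs)) stop("no vertices/faces found in OBJ input")
  source_space(do.call(rbind, vs), do.call(rbind, fs))
}

parse_fs_ascii <- function(lines) {
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  counts <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(counts) < 2 || anyNA(counts))
    stop("malformed FreeSurfer ASCII header line: ", lines[1])
  nv <- counts[1]; nf <- counts[2]
  if (length(lines) < 1 + nv + nf) stop("truncated FreeSurfer ASCII surface")
  vmat <- matrix(NA_real_, nv, 3)
  for (i in seq_len(nv)) {
    tok <- suppressWarnings(as.numeric(strsplit(trimws(lines[1 + i]), "\\s+")[[1]]))
    if (length(tok) < 3 || anyNA(tok[1:3]))
      stop("malformed vertex at line ", 1 + i)
    vmat[i, ] <- tok[1:3]
  }
  fmat <- matrix(NA_integer_, nf, 3)
  for (i in seq_len(nf)) {
    tok <- suppressWarnings(as.integer(strsplit(trimws(lines[1 + nv + i]), "\\s+")[[1]]))
    if (length(tok) < 3 || anyNA(tok[1:3]))
      stop("malformed face at line ", 1 + nv + i)
    fmat[i, ] <- tok[1:3] + 1L  # FreeSurfer faces are 0-based
  }
  source_space(vmat, fmat)
}

#' Write a source space as Wavefront OBJ
#' @param ss a [source_space()].
#' @param path output file.
#' @export
write_mesh_obj <- function(ss, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g",
                     ss$vertices[, 1], ss$vertices[, 2], ss$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     ss$triangles[, 1], ss$triangles[, 2], ss$triangles[, 3]), con)
  invisible(path)
}

#' Sensor array on a spherical cap
#'
#' Places `n_sensors` quasi-uniformly (Fibonacci lattice) on the upper cap of
#' a sphere of radius `shell_radius`, the cap covering `coverage_fraction` of
#' the full sphere area, centred on the +z pole.  Default sensors are radial
#' magnetometers; axial gradiometers subtract the field at a second coil
#' displaced `baseline` metres along the sensing direction.
#'
#' @param n_sensors number of channels.
#' @param shell_radius sensor shell radius in metres.
#' @param coverage_fraction fraction (0, 1] of the sphere covered by the cap.
#' @param sensor_type `"magnetometer"` or `"axial_gradiometer"`.
#' @param baseline gradiometer baseline in metres (default 0.05).
#' @param center sphere centre.
#' @param conductor_radius conductor sphere radius used for the sanity check
#'   that sensors sit outside the head (default 0.09 m).
#' @return An object of class `sensor_array` with `positions`, `orientations`
#'   (unit rows), `sensor_type`, `baseline`, `center`.
#' @export
build_sensor_cap <- function(n_sensors, shell_radius, coverage_fraction = 0.6,
                             sensor_type = c("magnetometer", "axial_gradiometer"),
                             baseline = 0.05, center = c(0, 0, 0),
                             conductor_radius = 0.09) {
  sensor_type <- match.arg(sensor_type)
  stopifnot(n_sensors >= 1, coverage_fraction > 0, coverage_fraction <= 1)
  if (shell_radius <= conductor_radius)
    stop("geometry error: shell_radius must exceed the conductor radius")
  i <- seq_len(n_sensors)
  # uniform in z over the cap z in [1 - 2*coverage, 1]
  z <- 1 - (i - 0.5) / n_sensors * 2 * coverage_fraction
  golden <- pi * (3 - sqrt(5))
  theta <- golden * (i - 1)
  r_xy <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r_xy * cos(theta), r_xy * sin(theta), z)
  positions <- sweep(dirs * shell_radius, 2, center, `+`)
  structure(
    list(positions = positions, orientations = dirs,
         sensor_type = sensor_type,
         baseline = if (sensor_type == "axial_gradiometer") baseline else NA_real_,
         center = center),
    class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("sensor_array: %d %ss on shell radius %.3g m\n",
              nrow(x$positions), x$sensor_type,
              sqrt(sum((x$positions[1, ] - x$center)^2))))
  invisible(x)
}

#' Write a plain-text sensor table
#'
#' One row per channel: `x y z ox oy oz` (tab-separated, metres / unit
#' vector).
#' @param sa a `sensor_array`.
#' @param path output file.
#' @export
write_sensor_table <- function(sa, path) {
  df <- data.frame(x = sa$positions[, 1], y = sa$positions[, 2],
                   z = sa$positions[, 3], ox = sa$orientations[, 1],
                   oy = sa$orientations[, 2], oz = sa$orientations[, 3])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Magnetic field of a current dipole in a spherically symmetric conductor
# (Sarvas closed form).  `r0` is the dipole position and `q` its moment, both
# relative to the sphere centre; `sensors` is an n x 3 matrix of field points.
# Returns an n x 3 matrix of B-field vectors (tesla for SI inputs).
sarvas_field <- function(r0, q, sensors) {
  mu0_4pi <- 1e-7
  a_vec <- sweep(sensors, 2, r0)
  a <- sqrt(rowSums(a_vec^2))
  r <- sqrt(rowSums(sensors^2))
  if (any(a < 1e-12)) stop("singular geometry: source coincides with a sensor")
  ar <- rowSums(a_vec * sensors)
  r0r <- as.vector(sensors %*% r0)
  F_ <- a * (r * a + r^2 - r0r)
  gradF <- sweep(sensors, 1, (a^2 / r + ar / a + 2 * a + 2 * r), `*`) -
    outer(a + 2 * r + ar / a, r0)
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  qxr0_r <- as.vector(sensors %*% qxr0)
  B <- (outer(F_, qxr0) - sweep(gradF, 1, qxr0_r, `*`)) * (mu0_4pi / F_^2)
  B
}

#' Single-sphere MEG lead field with cortical orientation constraint
#'
#' For every source vertex, computes the magnetic field of a unit-moment
#' current dipole oriented along the vertex normal using the closed-form
#' spherically-symmetric-conductor (Sarvas) solution, projected onto each
#' sensor's sensing direction.  Axial gradiometers take the difference
#' between the projected field at the coil and at `coil + baseline *
#' orientation`.  Radial dipoles are silent in this model, which is the
#' classic property of the spherical conductor.
#'
#' @param ss a [source_space()]; all vertices must lie strictly inside the
#'   conductor sphere.
#' @param sa a `sensor_array` strictly outside the conductor sphere.
#' @param sphere_center conductor sphere centre (default the sensor array
#'   centre).
#' @param conductor_radius conductor radius in metres (default 0.09).
#' @return An object of class `lead_field` with `gain` (channels x sources,
#'   tesla per A*m), `source_space`, `sensor_array`, `sphere_center`.
#' @export
compute_lead_field <- function(ss, sa, sphere_center = NULL,
                               conductor_radius = 0.09) {
  if (is.null(sphere_center)) sphere_center <- sa$center
  src <- sweep(ss$vertices, 2, sphere_center)
  sens <- sweep(sa$positions, 2, sphere_center)
  src_r <- sqrt(rowSums(src^2))
  sens_r <- sqrt(rowSums(sens^2))
  if (any(src_r >= conductor_radius))
    stop("all sources must lie strictly inside the conductor sphere")
  if (any(sens_r <= conductor_radius))
    stop("all sensors must lie strictly outside the conductor sphere")
  if (any(src_r < 1e-9))
    stop("singular geometry: source at the sphere centre")

  n_chan <- nrow(sa$positions)
  n_src <- nrow(ss$vertices)
  gain <- matrix(0, n_chan, n_src)
  grad <- identical(sa$sensor_type, "axial_gradiometer")
  sens2 <- if (grad) sens + sa$baseline * sa$orientations else NULL
  for (j in seq_len(n_src)) {
    B <- sarvas_field(src[j, ], ss$normals[j, ], sens)
    val <- rowSums(B * sa$orientations)
    if (grad) {
      B2 <- sarvas_field(src[j, ], ss$normals[j, ], sens2)
      val <- val - rowSums(B2 * sa$orientations)
    }
    gain[, j] <- val
  }
  if (!all(is.finite(gain))) stop("non-finite lead-field entries")
  structure(
    list(gain = gain, source_space = ss, sensor_array = sa,
         sphere_center = sphere_center, conductor_radius = conductor_radius),
    class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("lead_field: %d channels x %d sources (single-sphere model)\n",
              nrow(x$gain), ncol(x$gain)))
  invisible(x)
}

#' Grow a cortical patch of prescribed surface area
#'
#' Breadth-first growth over mesh edges from `seed`: vertices are visited in
#' order of edge-hop distance, ties within a ring broken by Euclidean
#' distance to the seed, and added one at a time until the accumulated
#' barycentric vertex area reaches `target_area`.  `target_area = 0` yields a
#' point-like source (the seed alone).
#'
#' @param ss a [source_space()].
#' @param seed seed vertex index (1-based).
#' @param target_area target patch area in cm^2.
#' @return An object of class `patch` with `seed_vertex`, `member_vertices`
#'   (in growth order), `target_area` and `achieved_area` (cm^2).
#' @export
grow_patch <- function(ss, seed, target_area) {
  stopifnot(target_area >= 0, seed >= 1, seed <= nrow(ss$vertices))
  target_m2 <- target_area * 1e-4
  if (target_m2 > ss$total_area * (1 + 1e-9))
    stop("insufficient mesh: target area ", target_area,
         " cm^2 exceeds total mesh area ", ss$total_area * 1e4, " cm^2")

  members <- integer(0)
  acc <- 0
  if (target_area == 0) {
    members <- seed
    acc <- ss$vertex_area[seed]
  } else {
    adj <- mesh_adjacency(ss)
    hop <- rep(NA_integer_, nrow(ss$vertices))
    hop[seed] <- 0L
    frontier <- seed
    d_eucl <- sqrt(rowSums(sweep(ss$vertices, 2, ss$vertices[seed, ])^2))
    repeat {
      ring <- frontier[order(d_eucl[frontier])]
      for (v in ring) {
        members <- c(members, v)
        acc <- acc + ss$vertex_area[v]
        if (acc >= target_m2) break
      }
      if (acc >= target_m2) break
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[is.na(hop[nxt])]
      if (!length(nxt))
        stop("insufficient mesh: disconnected component smaller than target area")
      hop[nxt] <- hop[frontier[1]] + 1L
      frontier <- nxt
    }
  }
  structure(
    list(seed_vertex = seed, member_vertices = members,
         target_area = target_area, achieved_area = acc * 1e4),
    class = "patch")
}

#' @export
print.patch <- function(x, ...) {
  cat(sprintf("patch: seed %d, %d vertices, %.2f cm^2 (target %.2f)\n",
              x$seed_vertex, length(x$member_vertices),
              x$achieved_area, x$target_area))
  invisible(x)
}

# vertex adjacency list from the triangulation (cached on the source space
# in the calling frame is not needed; construction is O(m))
mesh_adjacency <- function(ss) {
  tr <- ss$triangles
  edges <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  edges <- rbind(edges, edges[, 2:1])
  split(edges[, 2], edges[, 1])
}
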