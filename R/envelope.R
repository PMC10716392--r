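## Star-shaped scattering envelope on a triangulated icosphere: construction
## at a fixed distance from the solute Van-der-Waals surface, point
## membership, nesting for density profiles.

## recursively subdivided icosahedron; level L has 20 * 4^L faces.
## cached per level (level 6 = 81920 faces is used for density profiles
## matching the reference tooling's resolution).
icosphere <- function(subdivision_level = 4) {
  key <- paste0("ico", subdivision_level)
  cached <- .hydrosas_env[[key]]
  if (!is.null(cached)) return(cached)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdivision_level)) {
    nv <- nrow(v)
    edge_key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
    mid_env <- new.env(parent = emptyenv(), size = 4 * nrow(f))
    newv <- list()
    midpoint <- function(i, j) {
      k <- edge_key(i, j)
      id <- mid_env[[k]]
      if (!is.null(id)) return(id)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      id <- nv + length(newv)
      mid_env[[k]] <- id
      id
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[4 * t - 3, ] <- c(a, ab, ca)
      nf[4 * t - 2, ] <- c(b, bc, ab)
      nf[4 * t - 1, ] <- c(c, ca, bc)
      nf[4 * t, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  ## orient all faces outward (positive determinant)
  d <- v[f[, 1], 1] * (v[f[, 2], 2] * v[f[, 3], 3] - v[f[, 2], 3] * v[f[, 3], 2]) -
       v[f[, 1], 2] * (v[f[, 2], 1] * v[f[, 3], 3] - v[f[, 2], 3] * v[f[, 3], 1]) +
       v[f[, 1], 3] * (v[f[, 2], 1] * v[f[, 3], 2] - v[f[, 2], 2] * v[f[, 3], 1])
  flip <- d < 0
  f[flip, c(2, 3)] <- f[flip, c(3, 2)]
  ## solid angle per face (van Oosterom-Strackee)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  num <- rowSums(a * cross3(b, cc))
  den <- 1 + rowSums(a * b) + rowSums(b * cc) + rowSums(cc * a)
  omega <- 2 * atan2(abs(num), den)
  ## unique edges (vertex index pairs) and their unit midpoints, for the
  ## enclosure lift during construction
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  mid <- v[e[, 1], ] + v[e[, 2], ]
  mid <- mid / sqrt(rowSums(mid^2))
  out <- list(directions = v, faces = f, solid_angle = omega,
              edges = e, edge_mid = mid)
  .hydrosas_env[[key]] <- out
  out
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

## largest radius (from `center`, along each unit direction in `dirs`) of the
## union of balls of radius rho_j about atoms at `pos`; -Inf where a ray
## misses every ball
.ball_support <- function(dirs, pos, rho, center) {
  a <- sweep(pos, 2, center)
  u <- a %*% t(dirs)                    # n_atoms x n_dirs
  a2 <- rowSums(a^2)
  disc <- rho^2 - (a2 - u^2)
  hit <- disc >= 0
  cand <- u + sqrt(pmax(disc, 0))
  cand[!hit] <- -Inf
  apply(cand, 2, max)
}

#' Build a star-shaped scattering envelope
#'
#' Constructs the closed surface at a fixed distance from the Van-der-Waals
#' surface of all solute atoms across the supplied frames: per icosphere
#' vertex direction, the radial distance is the largest support of the balls
#' of radius (vdW radius + `distance`) about the solute atoms; vertex radii
#' are then lifted where the interpolated surface would dip below the
#' required support at edge midpoints, so the surface never cuts inside a
#' required ball.  Concave pockets are conservatively over-covered (the
#' radial distance is only ever inflated, never deflated).
#'
#' @param frames A single [atomic_configuration()] or a list of them; every
#'   frame's solute atoms are enclosed.
#' @param distance Envelope distance from the Van-der-Waals surface, nm;
#'   default 0.9 nm (9 Angstrom).
#' @param subdivision_level Icosphere recursion depth; level L gives
#'   20 * 4^L triangular faces (level 6: 81920).
#' @param use_vdw Add the per-species Van-der-Waals radius to `distance`
#'   (default); `FALSE` measures from atom centers.
#' @return Object of class `sas_envelope` with fields `directions`, `faces`,
#'   `radial_distance`, `center`, `build_distance`.
#' @export
build_envelope <- function(frames, distance = 0.9, subdivision_level = 4,
                           use_vdw = TRUE) {
  it <- as_frame_iter(frames)
  frames <- lapply(seq_len(it$n), it$get)
  stopifnot(length(frames) >= 1, distance > 0)
  ico <- icosphere(subdivision_level)
  first <- frames[[1]]
  sol1 <- first$positions[first$role == "solute", , drop = FALSE]
  if (nrow(sol1) == 0) stop("no solute atoms in the first frame")
  center <- colMeans(sol1)
  radial <- rep(-Inf, nrow(ico$directions))
  radial_mid <- rep(-Inf, nrow(ico$edge_mid))
  for (fr in frames) {
    sel <- fr$role == "solute"
    pos <- fr$positions[sel, , drop = FALSE]
    vdw <- if (use_vdw) species_params(fr)$vdw_nm[sel] else 0
    radial <- pmax(radial, .ball_support(ico$directions, pos, vdw + distance, center))
    radial_mid <- pmax(radial_mid,
                       .ball_support(ico$edge_mid, pos, vdw + distance, center))
  }
  if (any(!is.finite(radial))) {
    warning("envelope not star-shaped-representable along some directions; inflating")
    radial[!is.finite(radial)] <- max(radial[is.finite(radial)])
  }
  ## enclosure lift: where the linear radial interpolation would dip below
  ## the required support at an edge midpoint, raise both endpoint radii
  deficit <- radial_mid - (radial[ico$edges[, 1]] + radial[ico$edges[, 2]]) / 2
  deficit[!is.finite(deficit)] <- 0
  if (any(deficit > 0)) {
    lift <- numeric(length(radial))
    for (side in 1:2) {
      agg <- tapply(pmax(deficit, 0), ico$edges[, side], max)
      idx <- as.integer(names(agg))
      lift[idx] <- pmax(lift[idx], as.numeric(agg))
    }
    radial <- radial + lift
  }
  structure(list(directions = ico$directions, faces = ico$faces,
                 solid_angle = ico$solid_angle,
                 radial_distance = radial, center = center,
                 build_distance = distance,
                 subdivision_level = subdivision_level),
            class = "sas_envelope")
}

#' @export
print.sas_envelope <- function(x, ...) {
  cat(sprintf("<sas_envelope> %d faces, build distance %.3g nm, volume %.4g nm^3\n",
              nrow(x$faces), x$build_distance, envelope_volume(x)))
  invisible(x)
}

## surface radius along the direction of each point (relative to center)
envelope_surface_radius <- function(env, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  surface_radius_kernel(env$directions, env$faces, env$radial_distance,
                        sweep(points, 2, env$center))
}

#' Point-in-envelope test
#'
#' A point is inside iff its distance from the envelope center does not
#' exceed the piecewise-planar surface radius along its direction.
#'
#' @param env A `sas_envelope`.
#' @param points n x 3 matrix (nm), or a length-3 vector.
#' @return Logical vector of length n.
#' @export
envelope_inside <- function(env, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  r <- sqrt(rowSums(sweep(points, 2, env$center)^2))
  r <= envelope_surface_radius(env, points)
}

#' Envelope volume from the triangulated surface
#'
#' Integrates r(d)^3/3 over the sphere for the barycentric-linear radial
#' field: per face, the solid angle times the exact simplex average of the
#' interpolated radius cubed.  Exact for a constant radius (a sphere).
#'
#' @param env A `sas_envelope`.
#' @return Volume in nm^3.
#' @export
envelope_volume <- function(env) {
  r1 <- env$radial_distance[env$faces[, 1]]
  r2 <- env$radial_distance[env$faces[, 2]]
  r3 <- env$radial_distance[env$faces[, 3]]
  ## E[(lambda . r)^3] over the uniform simplex = (sum of all degree-3
  ## monomials of r1, r2, r3) / 10
  m3 <- (r1^3 + r2^3 + r3^3 +
           r1^2 * r2 + r1^2 * r3 + r2^2 * r1 + r2^2 * r3 +
           r3^2 * r1 + r3^2 * r2 + r1 * r2 * r3) / 10
  sum(env$solid_angle * m3) / 3
}

#' Series of strictly nested envelopes
#'
#' Envelopes at distances `start_distance + k * spacing` (k = 0 .. count-1)
#' from the Van-der-Waals surface, sharing one direction set so shells
#' between adjacent envelopes are well defined.
#'
#' @inheritParams build_envelope
#' @param start_distance First envelope distance, nm (0 = the vdW surface).
#' @param spacing Distance increment, nm (> 0).
#' @param count Number of envelopes (>= 2).
#' @return List of `sas_envelope`, innermost first.
#' @export
nested_envelopes <- function(frames, start_distance, spacing, count,
                             subdivision_level = 4, use_vdw = TRUE) {
  stopifnot(spacing > 0, count >= 2)
  envs <- lapply(seq_len(count) - 1L, function(k) {
    d <- start_distance + k * spacing
    if (d <= 0) d <- 1e-9   # the vdW surface itself
    build_envelope(frames, distance = d, subdivision_level = subdivision_level,
                   use_vdw = use_vdw)
  })
  ## the enclosure lift is stronger on bumpier (inner) surfaces; restore
  ## strict nesting by inflating outward, never deflating
  for (k in seq_len(count - 1)) {
    envs[[k + 1]]$radial_distance <- pmax(envs[[k + 1]]$radial_distance,
                                          envs[[k]]$radial_distance)
    if (any(envs[[k + 1]]$radial_distance < envs[[k]]$radial_distance)) {
      stop("nested envelopes are not monotone")
    }
  }
  envs
}

#' Write an envelope as an OFF-style text mesh
#'
#' @param env A `sas_envelope`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_envelope_off <- function(env, path) {
  p <- sweep(env$radial_distance * env$directions, 2, env$center, `+`)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(p), nrow(env$faces)), con)
  writeLines(sprintf("%.8g %.8g %.8g", p[, 1], p[, 2], p[, 3]), con)
  writeLines(sprintf("3 %d %d %d", env$faces[, 1] - 1L, env$faces[, 2] - 1L,
                     env$faces[, 3] - 1L), con)
  invisible(path)
}
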