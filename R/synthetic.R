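## Synthetic solute+solvent generator: toy configurations with a controlled
## hydration-shell excess that stand in for MD trajectory frames.

#' Specification of a synthetic solute-in-solvent system
#'
#' Defines the toy system emulated by the generator: a rigid pseudo-atom
#' solute on a cubic lattice, single-site pseudo-water solvent at a stated
#' bulk electron density, and a uniform hydration-shell slab of stated
#' thickness and fractional excess density adjacent to the solute
#' Van-der-Waals surface.
#'
#' Defaults emulate a small protein-like particle: electron density of the
#' solute above bulk water (positive SAXS contrast), per-atom neutron
#' scattering length chosen so the solute's nsl density lies below that of
#' D2O (negative SANS/D2O contrast) and slightly above H2O, a ~6% denser
#' shell of one-to-two water layers' width, and the experimental bulk water
#' density of 334 e/nm^3.
#'
#' @param solute_shape `"sphere"`, `"hollow_cylinder"`, or `"point_set"`.
#' @param solute_radius Sphere (or cylinder outer) radius, nm.
#' @param solute_atom_spacing Cubic lattice constant, nm.
#' @param solute_electrons_per_atom Electrons per solute pseudo-atom.
#' @param solute_nsl_per_atom Coherent neutron scattering length per solute
#'   pseudo-atom, fm (may be negative, like hydrogen-rich matter).
#' @param shell_thickness Hydration-shell thickness measured from the solute
#'   Van-der-Waals surface, nm.
#' @param shell_excess Fractional density excess of the shell (0.06 = +6%).
#' @param bulk_electron_density Bulk solvent electron density, e/nm^3.
#' @param box_edge Cubic periodic box edge, nm (box centered at the origin).
#' @param n_frames Default ensemble size.
#' @param seed Integer seed; identical spec + seed gives bit-identical frames.
#' @param solute_vdw_radius Van-der-Waals radius of solute pseudo-atoms, nm.
#' @param exclusion_radius No solvent is placed within this distance of a
#'   solute atom center; defaults to `solute_vdw_radius`.  Kept small so the
#'   displaced-solvent contrast stays co-located with the solute atoms.
#' @param electrons_per_solvent Electrons per pseudo-water (10).
#' @param envelope_margin Extra clearance (nm) the box must leave around
#'   solute + shell for a later scattering envelope; validated here.
#' @param jitter_sd Std. dev. (nm) of the optional Gaussian solute jitter in
#'   ensembles (emulates restrained vs free solute); default 0 (static).
#' @param cylinder_inner_radius,cylinder_length Hollow-cylinder geometry, nm.
#' @param points Optional n x 3 matrix for `solute_shape = "point_set"`.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(solute_shape = c("sphere", "hollow_cylinder", "point_set"),
                           solute_radius = 1.0,
                           solute_atom_spacing = 0.25,
                           solute_electrons_per_atom = 8,
                           solute_nsl_per_atom = -2.5,
                           shell_thickness = 0.3,
                           shell_excess = 0.06,
                           bulk_electron_density = 334,
                           box_edge = 4.8,
                           n_frames = 100,
                           seed = 1,
                           solute_vdw_radius = 0.1,
                           exclusion_radius = NULL,
                           electrons_per_solvent = 10,
                           envelope_margin = 0.9,
                           jitter_sd = 0,
                           cylinder_inner_radius = solute_radius / 2,
                           cylinder_length = 2 * solute_radius,
                           points = NULL) {
  spec <- list(solute_shape = match.arg(solute_shape),
               solute_radius = solute_radius,
               solute_atom_spacing = solute_atom_spacing,
               solute_electrons_per_atom = solute_electrons_per_atom,
               solute_nsl_per_atom = solute_nsl_per_atom,
               shell_thickness = shell_thickness,
               shell_excess = shell_excess,
               bulk_electron_density = bulk_electron_density,
               box_edge = box_edge,
               n_frames = n_frames,
               seed = as.integer(seed),
               solute_vdw_radius = solute_vdw_radius,
               exclusion_radius = exclusion_radius %||% solute_vdw_radius,
               electrons_per_solvent = electrons_per_solvent,
               envelope_margin = envelope_margin,
               jitter_sd = jitter_sd,
               cylinder_inner_radius = cylinder_inner_radius,
               cylinder_length = cylinder_length,
               points = points)
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  stopifnot(spec$shell_excess >= -1,
            spec$shell_thickness >= 0,
            spec$solute_atom_spacing > 0,
            spec$bulk_electron_density > 0,
            spec$electrons_per_solvent > 0,
            spec$n_frames >= 1,
            spec$jitter_sd >= 0)
  extent <- switch(spec$solute_shape,
                   sphere = spec$solute_radius,
                   hollow_cylinder = max(spec$solute_radius, spec$cylinder_length / 2),
                   point_set = if (is.null(spec$points)) 0 else
                     max(sqrt(rowSums(spec$points^2))))
  need <- 2 * (extent + spec$solute_vdw_radius + spec$shell_thickness +
                 spec$envelope_margin)
  if (spec$box_edge <= need) {
    stop(sprintf("box_edge %.3g nm too small: need > %.3g nm for solute + shell + envelope margin",
                 spec$box_edge, need))
  }
  if (spec$shell_excess > 20) stop("shell_excess too high for feasible placement")
  invisible(spec)
}

## species registry for synthetic systems: the default table plus the
## solute pseudo-atom "CG" parameterized from the spec
synthetic_species_table <- function(spec) {
  tab <- species_table()
  cg <- data.frame(label = "CG",
                   electrons = spec$solute_electrons_per_atom,
                   b_fm = spec$solute_nsl_per_atom,
                   n_exch_h = 0, exch_class = "none",
                   vdw_nm = spec$solute_vdw_radius,
                   stringsAsFactors = FALSE)
  rbind(cg, tab)
}

#' Single atomistic frame
#'
#' Positions in nm with the cubic box centered at the origin; positions are
#' wrapped into `[-box/2, box/2)`.  `species` labels index into the attached
#' species table (see [species_table()]); `role` is one of `"solute"`,
#' `"solvent"`, `"ion"`.
#'
#' @param positions n x 3 numeric matrix (nm).
#' @param species Character vector of species labels, length n.
#' @param role Character vector (`"solute"`, `"solvent"`, `"ion"`), length n.
#' @param box Numeric length-3 box edge lengths (nm).
#' @param frame_id Integer frame index (0-based in ensembles).
#' @param species_table Registry data.frame; defaults to [species_table()].
#' @return Object of class `atomic_config`.
#' @export
atomic_configuration <- function(positions, species, role, box, frame_id = 0L,
                                 species_table = hydrosas::species_table()) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  if (length(box) == 1) box <- rep(box, 3)
  stopifnot(length(species) == nrow(positions),
            length(role) == nrow(positions),
            all(role %in% c("solute", "solvent", "ion")))
  ## wrap into the centered box
  if (nrow(positions)) {
    for (k in 1:3) {
      positions[, k] <- ((positions[, k] + box[k] / 2) %% box[k]) - box[k] / 2
    }
  }
  structure(list(positions = positions, species = as.character(species),
                 role = as.character(role), box = as.numeric(box),
                 frame_id = as.integer(frame_id)),
            species_table = species_table,
            class = "atomic_config")
}

#' @export
print.atomic_config <- function(x, ...) {
  cat(sprintf("<atomic_config> frame %d: %d atoms (%d solute, %d solvent, %d ion), box %.3g x %.3g x %.3g nm\n",
              x$frame_id, nrow(x$positions), sum(x$role == "solute"),
              sum(x$role == "solvent"), sum(x$role == "ion"),
              x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Build the solute pseudo-atom set
#'
#' Pseudo-atoms on a cubic lattice cut to the requested shape and centered at
#' the origin.  Deterministic for a given spec.
#'
#' @param spec A [synthetic_spec()].
#' @return An [atomic_configuration()] containing solute atoms only.
#' @export
make_solute <- function(spec) {
  validate_synthetic_spec(spec)
  a <- spec$solute_atom_spacing
  R <- spec$solute_radius
  if (spec$solute_shape != "point_set" && a > R) {
    stop("empty solute: atom spacing exceeds the solute dimensions")
  }
  pos <- switch(spec$solute_shape,
    sphere = {
      g <- seq(-floor(R / a) * a, floor(R / a) * a, by = a)
      p <- as.matrix(expand.grid(x = g, y = g, z = g))
      p[rowSums(p^2) <= R^2, , drop = FALSE]
    },
    hollow_cylinder = {
      L <- spec$cylinder_length
      g <- seq(-floor(R / a) * a, floor(R / a) * a, by = a)
      gz <- seq(-floor(L / 2 / a) * a, floor(L / 2 / a) * a, by = a)
      p <- as.matrix(expand.grid(x = g, y = g, z = gz))
      rho <- sqrt(p[, 1]^2 + p[, 2]^2)
      p[rho <= R & rho >= spec$cylinder_inner_radius, , drop = FALSE]
    },
    point_set = {
      if (is.null(spec$points)) matrix(0, 1, 3) else {
        p <- matrix(as.numeric(spec$points), ncol = 3)
        sweep(p, 2, colMeans(p))
      }
    })
  if (nrow(pos) == 0) {
    stop("empty solute: atom spacing exceeds the solute dimensions")
  }
  dimnames(pos) <- NULL
  atomic_configuration(pos, rep("CG", nrow(pos)), rep("solute", nrow(pos)),
                       box = spec$box_edge, frame_id = 0L,
                       species_table = synthetic_species_table(spec))
}

## target relative solvent density (vs bulk) at minimum distance `d` from the
## nearest solute atom center
.relative_density <- function(d, spec) {
  out <- rep(1, length(d))
  out[d <= spec$exclusion_radius] <- 0
  shell <- d > spec$exclusion_radius &
    (d - spec$solute_vdw_radius) <= spec$shell_thickness
  out[shell] <- 1 + spec$shell_excess
  out
}

#' Add pseudo-water solvent around a solute
#'
#' Solvent pseudo-atoms are placed by thinned Poisson sampling: uniform at
#' the bulk number density (bulk electron density / electrons per
#' pseudo-water) far from the solute, at bulk times (1 + `shell_excess`)
#' within `shell_thickness` of the solute Van-der-Waals surface, and zero
#' within the exclusion radius of any solute atom center.  Seeded and
#' reproducible.
#'
#' @param solute An [atomic_configuration()] of solute atoms.
#' @param spec The [synthetic_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @param frame_id Frame index stamped on the result.
#' @return An [atomic_configuration()] with solute + solvent atoms.
#' @export
solvate <- function(solute, spec, seed = spec$seed, frame_id = solute$frame_id) {
  validate_synthetic_spec(spec)
  n_bulk <- spec$bulk_electron_density / spec$electrons_per_solvent
  vol <- prod(rep(spec$box_edge, 3))
  rate_max <- n_bulk * max(1, 1 + spec$shell_excess)
  sol_pos <- solute$positions[solute$role == "solute", , drop = FALSE]
  water <- with_seed(seed, {
    m <- rpois(1, rate_max * vol)
    cand <- matrix(runif(3 * m, -spec$box_edge / 2, spec$box_edge / 2), ncol = 3)
    d <- min_dist_kernel(cand, sol_pos)
    keep <- runif(m) < .relative_density(d, spec) * (n_bulk / rate_max)
    cand[keep, , drop = FALSE]
  })
  exp_shell <- n_bulk * (1 + spec$shell_excess)
  if (nrow(water) == 0 && exp_shell * vol > 10) {
    stop("solvent placement failed: no atoms accepted")
  }
  pos <- rbind(sol_pos, water)
  atomic_configuration(
    pos,
    c(solute$species[solute$role == "solute"], rep("W", nrow(water))),
    c(rep("solute", nrow(sol_pos)), rep("solvent", nrow(water))),
    box = spec$box_edge, frame_id = frame_id,
    species_table = attr(solute, "species_table"))
}

#' Matched pure-solvent (buffer) box
#'
#' Pseudo-water at the bulk density throughout the box, no solute; the same
#' box size as the system so that any envelope fitting the system also fits
#' the buffer.
#'
#' @inheritParams solvate
#' @return An [atomic_configuration()] of solvent atoms only.
#' @export
make_buffer <- function(spec, seed = spec$seed, frame_id = 0L) {
  validate_synthetic_spec(spec)
  n_bulk <- spec$bulk_electron_density / spec$electrons_per_solvent
  vol <- prod(rep(spec$box_edge, 3))
  pos <- with_seed(seed, {
    m <- rpois(1, n_bulk * vol)
    matrix(runif(3 * m, -spec$box_edge / 2, spec$box_edge / 2), ncol = 3)
  })
  atomic_configuration(pos, rep("W", nrow(pos)), rep("solvent", nrow(pos)),
                       box = spec$box_edge, frame_id = frame_id,
                       species_table = synthetic_species_table(spec))
}

#' Ensemble of statistically independent frames
#'
#' Repeated independent redraws of the solvent around a fixed (optionally
#' jittered) solute, standing in for decorrelated trajectory frames.
#' `generator` may be `"system"`, `"buffer"`, `"bulk_reference"`, or a
#' function `function(frame_id, seed)` returning an
#' [atomic_configuration()].
#'
#' @param generator Frame generator (see Details above).
#' @param n_frames Number of frames (>= 1).
#' @param seed Master seed; per-frame seeds are derived from it.
#' @param spec The [synthetic_spec()] (required for the built-in generators).
#' @param lazy If `TRUE`, return a `frame_ensemble` generator object that
#'   materializes frames on demand (same frames, constant memory) instead of
#'   a list; accepted by the scattering and profile routines.
#' @return List of [atomic_configuration()] with sequential 0-based
#'   `frame_id`s, or a `frame_ensemble` if `lazy`.
#' @export
make_ensemble <- function(generator = "system", n_frames = NULL, seed = NULL,
                          spec = NULL, lazy = FALSE) {
  if (is.character(generator)) {
    stopifnot(!is.null(spec))
    n_frames <- n_frames %||% spec$n_frames
    seed <- seed %||% spec$seed
    generator <- match.arg(generator, c("system", "buffer", "bulk_reference"))
    if (generator == "system") {
      solute0 <- make_solute(spec)
      gen <- function(i, s) {
        sol <- solute0
        if (spec$jitter_sd > 0) {
          sol$positions <- with_seed(s + 1L, {
            sol$positions + matrix(rnorm(length(sol$positions), sd = spec$jitter_sd),
                                   ncol = 3)
          })
        }
        sol$frame_id <- i
        solvate(sol, spec, seed = s, frame_id = i)
      }
    } else if (generator == "buffer") {
      gen <- function(i, s) make_buffer(spec, seed = s, frame_id = i)
    } else {
      ref <- make_bulk_reference(spec, seed = seed)
      gen <- function(i, s) {
        buf <- make_buffer(spec, seed = s, frame_id = i)
        atomic_configuration(rbind(ref$positions, buf$positions),
                             c(ref$species, buf$species),
                             c(ref$role, buf$role),
                             box = spec$box_edge, frame_id = i,
                             species_table = attr(buf, "species_table"))
      }
    }
  } else {
    stopifnot(is.function(generator), n_frames >= 1)
    gen <- generator
    seed <- seed %||% 1L
  }
  stopifnot(n_frames >= 1)
  if (lazy) {
    structure(list(frame = function(i) gen(i, frame_seed(seed, i)),
                   n = as.integer(n_frames)),
              class = "frame_ensemble")
  } else {
    lapply(seq_len(n_frames) - 1L, function(i) gen(i, frame_seed(seed, i)))
  }
}

#' @export
length.frame_ensemble <- function(x) x$n

#' @export
print.frame_ensemble <- function(x, ...) {
  cat(sprintf("<frame_ensemble> %d frames (lazy)\n", x$n))
  invisible(x)
}

## uniform accessor over frame lists and lazy frame ensembles
as_frame_iter <- function(x) {
  if (inherits(x, "frame_ensemble")) {
    list(n = x$n, get = function(i) x$frame(i - 1L))
  } else if (inherits(x, "atomic_config")) {
    list(n = 1L, get = function(i) x)
  } else {
    list(n = length(x), get = function(i) x[[i]])
  }
}

#' Frozen bulk-water reference region
#'
#' A tagged region of bulk water (all pseudo-waters of one buffer draw lying
#' within the solute radius of the box center), frozen and relabeled as a
#' reference "solute" so that density profiles around it probe the structure
#' of bulk water itself.  This is a synthetic analogue of restraining a
#' solute-sized volume of bulk water; no restraint dynamics is modeled.
#'
#' @inheritParams solvate
#' @return An [atomic_configuration()] with role `"solute"` reference sites.
#' @export
make_bulk_reference <- function(spec, seed = spec$seed) {
  buf <- make_buffer(spec, seed = frame_seed(seed, -1L))
  r <- sqrt(rowSums(buf$positions^2))
  keep <- r <= spec$solute_radius
  if (!any(keep)) stop("no bulk water inside the reference volume")
  atomic_configuration(buf$positions[keep, , drop = FALSE],
                       rep("W", sum(keep)), rep("solute", sum(keep)),
                       box = spec$box_edge, frame_id = 0L,
                       species_table = attr(buf, "species_table"))
}
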