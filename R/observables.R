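## Hydration-shell observables: block statistics, DeltaRg / DeltaRg(SAS)
## reports, consensus averages, and solvent density profiles versus distance
## from the solute Van-der-Waals surface.

#' Block-averaged statistic with standard error
#'
#' Partitions an ensemble (list of frames, or numeric vector of per-frame
#' values) into `n_blocks` contiguous blocks and evaluates `statistic` per
#' block; if a `buffer` ensemble is supplied it is partitioned likewise and
#' the statistic is evaluated on index-paired (system block, buffer block)
#' pairs, so each evaluation uses an independent buffer block.  Returns the
#' block mean and SE = sd / sqrt(n_blocks).
#'
#' @param ensemble List (frames) or numeric vector.
#' @param n_blocks Number of blocks (default 10; must be >= 2).
#' @param statistic `function(block)` or `function(block, buffer_block)`
#'   returning a numeric scalar or vector.
#' @param buffer Optional buffer ensemble, partitioned in parallel.
#' @return List with `mean`, `se`, and the per-block `values` matrix
#'   (statistic components x blocks).
#' @export
block_statistics <- function(ensemble, n_blocks = 10, statistic, buffer = NULL) {
  if (n_blocks < 2) stop("n_blocks must be at least 2")
  n <- length(ensemble)
  if (n < n_blocks) stop("fewer frames than blocks")
  split_blocks <- function(x) {
    b <- 1L + ((seq_along(x) - 1L) * n_blocks) %/% length(x)
    lapply(seq_len(n_blocks), function(k) x[b == k])
  }
  sys_b <- split_blocks(ensemble)
  buf_b <- if (!is.null(buffer)) {
    if (length(buffer) < n_blocks) stop("fewer buffer frames than blocks")
    split_blocks(buffer)
  } else NULL
  vals <- lapply(seq_len(n_blocks), function(k) {
    if (is.null(buf_b)) statistic(sys_b[[k]]) else statistic(sys_b[[k]], buf_b[[k]])
  })
  V <- do.call(cbind, lapply(vals, as.numeric))
  list(mean = rowMeans(V), se = apply(V, 1, sd) / sqrt(n_blocks), values = V)
}

#' Hydration-shell Rg report
#'
#' Collects per-modality SAS-derived radii of gyration and forms the
#' hydration-shell observables: DeltaRg = Rg(SAS) - Rg(solute) per modality,
#' and DeltaRg(SAS) = Rg(SAXS) - Rg(SANS) per SANS solvent, the
#' bare-structure-independent footprint of the hydration-shell contrast.
#' Standard errors are combined in quadrature; when per-block Rg values are
#' supplied for both modalities of a difference, the SE of the difference is
#' taken from the block-paired differences instead, which absorbs any
#' correlation from shared frames.
#'
#' @param sas_results Named list (names: `SAXS`, `SANS_H2O`, `SANS_D2O`; any
#'   subset) of lists with elements `Rg`, `se`, and optionally `blocks` (a
#'   numeric vector of per-block Rg values).
#' @param rg_prot Direct-space Rg of the bare solute, nm.
#' @param rg_prot_se Its SE (default 0; exact for a rigid solute).
#' @return Object of class `delta_rg_report`.
#' @export
delta_rg_report <- function(sas_results, rg_prot, rg_prot_se = 0) {
  stopifnot(length(sas_results) >= 1, !is.null(names(sas_results)))
  get_rg <- function(x) if (inherits(x, "guinier_result")) {
    list(Rg = x$Rg, se = x$Rg_SE %||% NA_real_, blocks = NULL)
  } else x
  res <- lapply(sas_results, get_rg)
  rg <- vapply(res, function(x) x$Rg, numeric(1))
  se <- vapply(res, function(x) as.numeric(x$se %||% NA_real_), numeric(1))
  n_blocks <- max(c(0, vapply(res, function(x) length(x$blocks %||% numeric(0)),
                              integer(1))))
  d_rg <- rg - rg_prot
  d_rg_se <- sqrt(se^2 + rg_prot_se^2)
  d_sas <- d_sas_se <- setNames(numeric(0), character(0))
  if ("SAXS" %in% names(res)) {
    for (m in intersect(c("SANS_H2O", "SANS_D2O"), names(res))) {
      dv <- rg[["SAXS"]] - rg[[m]]
      bx <- res[["SAXS"]]$blocks
      by <- res[[m]]$blocks
      dse <- if (!is.null(bx) && !is.null(by) && length(bx) == length(by)) {
        sd(bx - by) / sqrt(length(bx))
      } else sqrt(se[["SAXS"]]^2 + se[[m]]^2)
      d_sas <- c(d_sas, setNames(dv, m))
      d_sas_se <- c(d_sas_se, setNames(dse, m))
    }
  }
  structure(list(Rg = rg, Rg_se = se, Rg_prot = rg_prot,
                 Rg_prot_se = rg_prot_se,
                 dRg = d_rg, dRg_se = d_rg_se,
                 dRg_SAS = d_sas, dRg_SAS_se = d_sas_se,
                 n_blocks = n_blocks),
            class = "delta_rg_report")
}

#' @export
print.delta_rg_report <- function(x, ...) {
  cat("Hydration-shell Rg report (nm, errors 1 SE)\n")
  cat(sprintf("  Rg(solute) = %.4f +- %.4f\n", x$Rg_prot, x$Rg_prot_se))
  for (m in names(x$Rg)) {
    cat(sprintf("  Rg(%s) = %.4f +- %.4f   dRg = %+.4f +- %.4f\n",
                m, x$Rg[[m]], x$Rg_se[[m]], x$dRg[[m]], x$dRg_se[[m]]))
  }
  for (m in names(x$dRg_SAS)) {
    cat(sprintf("  dRg_SAS (SAXS - %s) = %+.4f +- %.4f\n",
                m, x$dRg_SAS[[m]], x$dRg_SAS_se[[m]]))
  }
  invisible(x)
}

#' Unweighted consensus average of several estimates
#'
#' Mean over members (e.g. force-field combinations) with an SE from the
#' between-member scatter, sd / sqrt(n).
#'
#' @param values List of length-2 vectors `c(value, se)`, or a 2-column
#'   matrix/data.frame, or a plain numeric vector (SEs taken as 0).
#' @return List with `mean`, `se` (between-member scatter), and
#'   `se_members` (quadrature mean of the member SEs, for reference).
#' @export
consensus_average <- function(values) {
  if (length(values) == 0) stop("empty value list")
  if (is.list(values) && !is.data.frame(values)) {
    values <- do.call(rbind, lapply(values, function(v) {
      if (length(v) == 1) c(v, 0) else v[1:2]
    }))
  }
  if (is.null(dim(values))) values <- cbind(values, 0)
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 1) stop("empty value list")
  list(mean = mean(values[, 1]),
       se = if (n > 1) sd(values[, 1]) / sqrt(n) else values[1, 2],
       se_members = sqrt(mean(values[, 2]^2) / n))
}

#' Solvent density profile versus distance from the solute surface
#'
#' Builds a series of nested envelopes at increasing distances from the
#' solute Van-der-Waals surface and reports, per shell between adjacent
#' envelopes, the frame-averaged scattering-relevant solvent content divided
#' by the shell volume (from the triangulated envelopes): electron density
#' for SAXS, scattering-length density for SANS.
#'
#' @param frames List of [atomic_configuration()] (solvent positions vary).
#' @param solute An [atomic_configuration()] providing the reference surface;
#'   defaults to the first frame (its solute atoms).
#' @param spacing Shell width, nm (default 0.05).
#' @param n_shells Number of shells (default 12).
#' @param modality A [modality_spec()] or modality name (default SAXS).
#' @param subdivision_level Icosphere recursion for the envelopes.
#' @return Object of class `density_profile`: data.frame with `R` (shell
#'   midpoint distance from the vdW surface, nm), `density`, `se`, plus shell
#'   volumes and counts as attributes.
#' @export
density_profile <- function(frames, solute = NULL, spacing = 0.05,
                            n_shells = 12, modality = "SAXS",
                            subdivision_level = 4) {
  it <- as_frame_iter(frames)
  stopifnot(it$n >= 1, spacing > 0, n_shells >= 1)
  solute <- solute %||% it$get(1)
  ms <- as_modality_spec(modality)
  envs <- nested_envelopes(solute, start_distance = 0, spacing = spacing,
                           count = n_shells + 1L,
                           subdivision_level = subdivision_level)
  vols <- vapply(envs, envelope_volume, numeric(1))
  shell_vols <- diff(vols)
  nf <- it$n
  content <- matrix(0, n_shells, nf)
  for (i in seq_len(nf)) {
    fr <- it$get(i)
    solv <- fr$role != "solute"
    pos <- fr$positions[solv, , drop = FALSE]
    w <- scattering_weights(fr, ms)[solv]
    cum <- vapply(envs, function(e) {
      sum(w[envelope_inside(e, pos)])
    }, numeric(1))
    content[, i] <- diff(cum)
  }
  dens <- rowMeans(content) / shell_vols
  se <- if (nf > 1) apply(content, 1, sd) / sqrt(nf) / shell_vols else rep(0, n_shells)
  structure(data.frame(R = (seq_len(n_shells) - 0.5) * spacing,
                       density = dens, se = se),
            shell_volumes = shell_vols, spacing = spacing,
            modality = ms$modality, n_frames = nf,
            mean_content = rowMeans(content),
            class = c("density_profile", "data.frame"))
}

#' Difference between a density profile and a bulk reference profile
#'
#' Pointwise `profile - reference` with SEs propagated in quadrature; the
#' reference is resampled onto the profile grid by linear interpolation if
#' the grids differ by less than half a bin, and rejected otherwise.
#'
#' @param profile,reference `density_profile` objects.
#' @return A `density_profile` of differences.
#' @export
relative_profile <- function(profile, reference) {
  R <- profile$R
  if (length(reference$R) == length(R) && max(abs(reference$R - R)) < 1e-9) {
    dref <- reference$density
    sref <- reference$se
  } else {
    if (min(R) < min(reference$R) - attr(profile, "spacing") / 2 ||
        max(R) > max(reference$R) + attr(profile, "spacing") / 2) {
      stop("profile grids differ beyond resampling tolerance")
    }
    dref <- approx(reference$R, reference$density, xout = R, rule = 2)$y
    sref <- approx(reference$R, reference$se, xout = R, rule = 2)$y
  }
  structure(data.frame(R = R, density = profile$density - dref,
                       se = sqrt(profile$se^2 + sref^2)),
            shell_volumes = attr(profile, "shell_volumes"),
            spacing = attr(profile, "spacing"),
            modality = attr(profile, "modality"),
            n_frames = attr(profile, "n_frames"),
            class = c("density_profile", "data.frame"))
}
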