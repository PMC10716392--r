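## Explicit-solvent scattering: amplitudes over orientations, solvent density
## correction, and buffer-subtracted intensities with block errors.

#' Quasi-uniform unit vectors for the orientational average
#'
#' Spherical Fibonacci points, rigidly rotated by a seeded random rotation so
#' different seeds decorrelate the direction sets while each set stays
#' quasi-uniform.  Deterministic given `n` and `seed`.
#'
#' @param n Number of directions (default 200).
#' @param seed Integer seed for the random rotation; `NULL` keeps the
#'   canonical orientation.
#' @return n x 3 matrix of unit vectors.
#' @export
generate_q_directions <- function(n = 200, seed = NULL) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  r <- sqrt(pmax(1 - z^2, 0))
  d <- cbind(r * cos(phi), r * sin(phi), z)
  if (!is.null(seed)) {
    rot <- with_seed(seed, qr.Q(qr(matrix(rnorm(9), 3, 3))))
    if (det(rot) < 0) rot[, 1] <- -rot[, 1]
    d <- d %*% rot
  }
  d
}

#' Scattering amplitude of one configuration
#'
#' A(q) = sum_j f_j exp(i q . r_j) over the solute atoms plus the solvent and
#' ion atoms inside the envelope.  Solvent form factors are scaled by the
#' density-correction factor.
#'
#' @param config An [atomic_configuration()].
#' @param envelope A `sas_envelope`, or `NULL` to include every atom
#'   (vacuum-style calculation).
#' @param q_vectors m x 3 matrix of scattering vectors (nm^-1).
#' @param modality_spec A [modality_spec()] or modality name.
#' @param solvent_factor Multiplicative density-correction factor applied to
#'   solvent atom weights (default 1).
#' @return Complex vector of length m.
#' @export
sas_amplitude <- function(config, envelope, q_vectors,
                          modality_spec = "SAXS", solvent_factor = 1) {
  ms <- as_modality_spec(modality_spec)
  q_vectors <- matrix(as.numeric(q_vectors), ncol = 3)
  check_envelope_fits(envelope, config)
  sel <- in_envelope_selection(config, envelope)
  w <- scattering_weights(config, ms)
  w[config$role == "solvent"] <- w[config$role == "solvent"] * solvent_factor
  pos <- config$positions[sel, , drop = FALSE]
  a <- amplitude_kernel(pos, matrix(w[sel], ncol = 1), q_vectors)
  as.vector(a[, 1])
}

## solute atoms always contribute; solvent/ion atoms only inside the envelope
in_envelope_selection <- function(config, envelope) {
  if (is.null(envelope)) return(rep(TRUE, length(config$role)))
  sel <- config$role == "solute"
  other <- which(!sel)
  if (length(other)) {
    sel[other] <- envelope_inside(envelope, config$positions[other, , drop = FALSE])
  }
  sel
}

check_envelope_fits <- function(envelope, config) {
  if (is.null(envelope)) return(invisible(TRUE))
  half <- config$box / 2
  p <- envelope$radial_distance * envelope$directions
  p <- sweep(p, 2, envelope$center, `+`)
  if (any(abs(p) > matrix(half, nrow(p), 3, byrow = TRUE) + 1e-9)) {
    stop("envelope extends beyond the simulation box; use a larger box")
  }
  invisible(TRUE)
}

#' Solvent density correction factor
#'
#' Ratio of the target bulk scattering density to the measured mean
#' in-envelope solvent density of the buffer ensemble.  Applied
#' multiplicatively to solvent scattering factors in both the system and the
#' buffer amplitudes, it enforces exact buffer matching and corrects solvent
#' models whose density differs from the experimental 334 e/nm^3 (SAXS); for
#' SANS the analogous correction in scattering-length units is applied by
#' default.
#'
#' @param buffer_ensemble List of buffer [atomic_configuration()]s.
#' @param envelope A `sas_envelope`.
#' @param modality_spec A [modality_spec()] or modality name.
#' @param max_frames Measure on at most this many buffer frames (the
#'   factor's residual statistical error enters the buffer-subtracted
#'   difference only, so a few hundred frames suffice).
#' @return Scalar factor, with attributes `measured` and `target`.
#' @export
density_correction_factor <- function(buffer_ensemble, envelope, modality_spec,
                                      max_frames = 200) {
  ms <- as_modality_spec(modality_spec)
  it <- as_frame_iter(buffer_ensemble)
  stopifnot(it$n >= 1)
  vol <- envelope_volume(envelope)
  tot <- 0
  e_tot <- 0
  nf <- min(it$n, max_frames)
  for (i in seq_len(nf)) {
    fr <- it$get(i)
    sel <- fr$role != "solute" & envelope_inside(envelope, fr$positions)
    w <- scattering_weights(fr, ms)
    tot <- tot + sum(w[sel])
    e_tot <- e_tot + sum(species_params(fr)$electrons[sel])
  }
  measured <- tot / nf / vol
  if (abs(measured) < 1e-12) stop("measured in-envelope solvent density is zero")
  target <- ms$target_bulk_density
  if (is.null(target)) {
    if (ms$modality == "SAXS") {
      target <- 334
    } else {
      ## analogous nsl correction: rescale so the solvent amounts to
      ## 334 e/nm^3 worth of solvent particles
      e_density <- e_tot / nf / vol
      target <- measured * 334 / e_density
    }
  }
  structure(target / measured, measured = measured, target = target)
}

## ---- the ensemble workhorse -------------------------------------------

#' Buffer-subtracted SAS curves for several modalities in one pass
#'
#' For each |q| on `q_grid`, amplitudes A (system) and B (buffer) are
#' accumulated over `n_directions` quasi-uniform q-vectors and over the
#' frames of each of `n_blocks` contiguous blocks; system and buffer blocks
#' are paired by index, so the blocks are statistically independent of each
#' other.  The per-block buffer-subtracted intensity is
#'
#'   I(q) = |<A> - <B>|^2 + Var(A) - Var(B)
#'
#' (angle brackets: within-block frame means; Var: within-block amplitude
#' variance over frames; the squared mean difference is debiased by the
#' variances of the means).  The subtraction of the buffer's own fluctuation
#' term makes buffer-vs-buffer intensities statistically zero, mirroring
#' experimental buffer subtraction.  The reported curve is the block mean,
#' with per-q sigma = sd/sqrt(n_blocks).
#'
#' With `variance_reduction = TRUE` (default) the amplitude-mean difference
#' is estimated with a zero-mean control variate: away from the solute
#' (beyond `bulk_margin` of any solute atom) both ensembles hold bulk
#' solvent at the same corrected density, so the measured mismatch of their
#' in-envelope bulk-region solvent weights is pure noise with expectation
#' zero.  Its projection onto the bulk region's form amplitude E_R(q)
#' (computed once per call by seeded Monte-Carlo integration) is subtracted
#' from the block mean difference, removing the dominant solvent-number
#' shot-noise mode from both the block estimates and the pooled curve
#' without changing any expectation; block scatter therefore remains an
#' honest error estimate for the reported curve.
#'
#' @param system_ensemble List of system frames ([atomic_configuration()]).
#' @param buffer_ensemble List of buffer frames, or `NULL` for a vacuum
#'   calculation (no solvent, no subtraction).
#' @param envelope A `sas_envelope`, or `NULL` to include all atoms.
#' @param q_grid Strictly increasing |q| values, nm^-1.
#' @param n_directions q-vectors per |q| (default 200).
#' @param modalities Named list of [modality_spec()]s (or character vector of
#'   modality names).
#' @param seed Seed for the direction set.
#' @param n_blocks Number of blocks for the error estimate (default 10); 1
#'   disables block statistics (sigma = 0).
#' @param variance_reduction Apply the control-variate correction described
#'   above (default TRUE; ignored for vacuum calculations).
#' @param bulk_margin Distance from the solute atom centers (nm) beyond
#'   which in-envelope solvent is treated as pure bulk for the control
#'   variate; default 0.6 times the envelope build distance.  Must exceed
#'   the hydration-shell extent for the variate to have zero mean.
#' @return Named list of `sas_curve` objects (one per modality), each a
#'   data.frame with columns `q`, `I`, `sigma` plus metadata attributes
#'   (including per-block intensities in `attr(, "blocks")`).
#' @export
sas_curves <- function(system_ensemble, buffer_ensemble, envelope, q_grid,
                       n_directions = 200, modalities = c("SAXS"),
                       seed = 1, n_blocks = 10, variance_reduction = TRUE,
                       bulk_margin = NULL) {
  sys_it <- as_frame_iter(system_ensemble)
  buf_it <- if (is.null(buffer_ensemble)) NULL else as_frame_iter(buffer_ensemble)
  if (is.character(modalities)) {
    modalities <- setNames(lapply(modalities, modality_spec), modalities)
  }
  stopifnot(sys_it$n >= 1, is.numeric(q_grid),
            all(diff(q_grid) > 0), all(q_grid >= 0))
  nsys <- sys_it$n
  nbuf <- if (is.null(buf_it)) 0L else buf_it$n
  if (n_blocks > 1 && (nsys < n_blocks || (nbuf > 0 && nbuf < n_blocks))) {
    stop("fewer frames than blocks")
  }
  K <- length(modalities)
  nq <- length(q_grid)
  dirs <- generate_q_directions(n_directions, seed)
  Q <- q_grid[rep(seq_len(nq), each = n_directions)] *
    dirs[rep(seq_len(n_directions), times = nq), , drop = FALSE]
  M <- nrow(Q)

  first_sys <- sys_it$get(1)
  check_envelope_fits(envelope, first_sys)
  if (nbuf > 0) check_envelope_fits(envelope, buf_it$get(1))

  ## per-species scattering weights are identical across frames of an
  ## ensemble (fractional deuteration); cache them per modality by label
  weight_map <- function(template) {
    tab <- attr(template, "species_table")
    probe <- atomic_configuration(matrix(0, nrow(tab), 3), tab$label,
                                  rep("solute", nrow(tab)),
                                  box = max(template$box),
                                  species_table = tab)
    lapply(modalities, function(ms) {
      setNames(scattering_weights(probe, ms), tab$label)
    })
  }

  ## uniform |q| ladders take a recursion fast path in the C++ kernel
  dq <- if (nq > 1) q_grid[2] - q_grid[1] else 0
  uniform_q <- nq > 1 && max(abs(diff(q_grid) - dq)) < 1e-9 * max(dq, 1)
  amp <- function(pos, W) {
    if (uniform_q) amplitude_ladder_kernel(pos, W, dirs, q_grid[1], dq, nq)
    else amplitude_kernel(pos, W, Q)
  }

  ## solvent density correction per modality (from the buffer ensemble)
  factors <- vapply(modalities, function(ms) {
    if (nbuf == 0 || !as_modality_spec(ms)$density_correction) return(1)
    as.numeric(density_correction_factor(buffer_ensemble, envelope, ms))
  }, numeric(1))

  ## bulk-region form amplitude E_R(qvec) for the zero-mean control
  ## variate: a seeded Monte-Carlo average of exp(i q.r) over the part of
  ## the envelope interior farther than bulk_margin from any solute atom
  Ehat <- NULL
  ref_pos <- first_sys$positions[first_sys$role == "solute", , drop = FALSE]
  if (variance_reduction && !is.null(envelope) && nbuf > 0) {
    bulk_margin <- bulk_margin %||% (0.6 * envelope$build_distance)
    Ehat <- envelope_form_amplitude(envelope, Q, amp, seed = seed,
                                    exclude_ref = ref_pos,
                                    exclude_margin = bulk_margin)
    if (is.null(Ehat)) bulk_margin <- NA_real_
  }
  sampled <- any(vapply(modalities, function(ms)
    identical(as_modality_spec(ms)$deuteration_mode, "sampled"), logical(1)))

  accumulate <- function(iter, is_buffer) {
    n <- iter$n
    nb <- if (n_blocks > 1) n_blocks else 1L
    sumA <- array(0 + 0i, dim = c(M, K, nb))
    sumA2 <- array(0, dim = c(M, K, nb))
    sumAW <- array(0 + 0i, dim = c(M, K, nb))
    sumW <- matrix(0, K, nb)
    sumW2 <- matrix(0, K, nb)
    cnt <- integer(nb)
    wmaps <- NULL
    for (i in seq_len(n)) {
      fr <- iter$get(i)
      if (is.null(wmaps) && !sampled) wmaps <- weight_map(fr)
      b <- min(nb, 1L + ((i - 1L) * nb) %/% n)
      sel <- in_envelope_selection(fr, envelope)
      if (is_buffer) sel <- sel & fr$role != "solute"
      pos <- fr$positions[sel, , drop = FALSE]
      fluct <- fr$role[sel] != "solute"      # the set that varies over frames
      solv <- fr$role[sel] == "solvent"
      spc <- fr$species[sel]
      W <- matrix(0, nrow(pos), K)
      for (k in seq_len(K)) {
        w <- if (sampled) {
          scattering_weights(fr, modalities[[k]],
                             seed = frame_seed(seed, i))[sel]
        } else unname(wmaps[[k]][spc])
        w[solv] <- w[solv] * factors[k]
        W[, k] <- w
      }
      A <- if (nrow(pos)) amp(pos, W) else matrix(0 + 0i, M, K)
      sumA[, , b] <- sumA[, , b] + A
      sumA2[, , b] <- sumA2[, , b] + Mod(A)^2
      if (!is.null(Ehat)) {
        ## control scalar: solvent weight in the in-envelope bulk region
        fpos <- pos[fluct, , drop = FALSE]
        keep <- if (nrow(ref_pos) == 0 || nrow(fpos) == 0) {
          rep(TRUE, nrow(fpos))
        } else min_dist_kernel(fpos, ref_pos) > bulk_margin
        wf <- colSums(W[fluct, , drop = FALSE][keep, , drop = FALSE])
        sumAW[, , b] <- sumAW[, , b] + A * matrix(wf, M, K, byrow = TRUE)
        sumW[, b] <- sumW[, b] + wf
        sumW2[, b] <- sumW2[, b] + wf^2
      }
      cnt[b] <- cnt[b] + 1L
    }
    list(sum = sumA, sum2 = sumA2, sumAW = sumAW, sumW = sumW,
         sumW2 = sumW2, cnt = cnt)
  }

  sys <- accumulate(sys_it, is_buffer = FALSE)
  buf <- if (nbuf > 0) accumulate(buf_it, is_buffer = TRUE) else NULL
  nb <- dim(sys$sum)[3]

  ## per-block raw mean, bulk-region weight mean, raw variance, and the
  ## residual variance of the control-variated amplitude
  block_stats <- function(acc, b) {
    n <- acc$cnt[b]
    mA <- matrix(acc$sum[, , b, drop = FALSE][, , 1] / n, M, K)
    mA2 <- matrix(acc$sum2[, , b, drop = FALSE][, , 1] / n, M, K)
    vA <- if (n > 1) (mA2 - Mod(mA)^2) * n / (n - 1) else matrix(0, M, K)
    mW <- matrix(0, M, K)
    v_res <- vA
    if (!is.null(Ehat) && n > 1) {
      mWs <- acc$sumW[, b] / n
      vW <- (acc$sumW2[, b] / n - mWs^2) * n / (n - 1)
      mAW <- matrix(acc$sumAW[, , b, drop = FALSE][, , 1] / n, M, K)
      covAW <- (mAW - mA * matrix(mWs, M, K, byrow = TRUE)) * n / (n - 1)
      mW <- matrix(mWs, M, K, byrow = TRUE)
      v_res <- vA - 2 * Re(Conj(Ehat) * covAW) +
        Mod(Ehat)^2 * matrix(vW, M, K, byrow = TRUE)
      v_res <- pmax(v_res, 0)
    }
    list(n = n, m = mA, mW = mW, v = vA, v_res = v_res)
  }

  shell_index <- rep(seq_len(nq), each = n_directions)
  I_blocks <- array(NA_real_, dim = c(nq, K, nb))
  for (b in seq_len(nb)) {
    s <- block_stats(sys, b)
    if (!is.null(buf)) {
      bb <- block_stats(buf, b)
      diff <- s$m - bb$m
      if (!is.null(Ehat)) diff <- diff - Ehat * (s$mW - bb$mW)
      Iq <- Mod(diff)^2 - s$v_res / s$n - bb$v_res / bb$n + s$v - bb$v
    } else {
      Iq <- Mod(s$m)^2 + s$v * (1 - 1 / s$n)   # = <|A|^2> for a raw ensemble
    }
    for (k in seq_len(K)) {
      I_blocks[, k, b] <- as.vector(tapply(Iq[, k], shell_index, mean))
    }
  }

  out <- vector("list", K)
  names(out) <- names(modalities)
  for (k in seq_len(K)) {
    Ib <- matrix(I_blocks[, k, ], nq, nb)
    I <- rowMeans(Ib)
    sigma <- if (nb > 1) apply(Ib, 1, sd) / sqrt(nb) else rep(0, nq)
    out[[k]] <- sas_curve(q_grid, I, sigma,
                          modality = as_modality_spec(modalities[[k]])$modality,
                          n_directions = n_directions,
                          metadata = list(n_system_frames = nsys,
                                          n_buffer_frames = nbuf,
                                          n_blocks = nb,
                                          solvent_factor = factors[[k]],
                                          envelope_distance =
                                            if (is.null(envelope)) NA_real_
                                            else envelope$build_distance,
                                          seed = seed),
                          blocks = Ib)
  }
  out
}

## Monte-Carlo estimate of the normalized form amplitude
## E(qvec) = (1/V) int_R exp(i q.r) dV of the in-envelope region farther
## than `exclude_margin` from every reference atom, via seeded rejection
## sampling in the envelope bounding box; `amp` evaluates sum exp(i q.r).
## NULL when the region is (nearly) empty.
envelope_form_amplitude <- function(envelope, Q, amp, seed, n_points = 20000,
                                    exclude_ref = NULL, exclude_margin = 0) {
  rmax <- max(envelope$radial_distance)
  pts <- with_seed(frame_seed(seed, -99L), {
    acc <- matrix(0, 0, 3)
    for (it in 1:50) {
      cand <- matrix(runif(3 * 4 * n_points, -rmax, rmax), ncol = 3)
      cand <- sweep(cand, 2, envelope$center, `+`)
      cand <- cand[envelope_inside(envelope, cand), , drop = FALSE]
      if (!is.null(exclude_ref) && nrow(exclude_ref) > 0 && nrow(cand) > 0) {
        cand <- cand[min_dist_kernel(cand, exclude_ref) > exclude_margin, ,
                     drop = FALSE]
      }
      acc <- rbind(acc, cand)
      if (nrow(acc) >= n_points) break
    }
    acc[seq_len(min(n_points, nrow(acc))), , drop = FALSE]
  })
  if (nrow(pts) < 100) return(NULL)
  as.vector(amp(pts, matrix(1, nrow(pts), 1))[, 1]) / nrow(pts)
}

#' Buffer-subtracted intensity for one modality
#'
#' Thin wrapper around [sas_curves()]; see there for the estimator and the
#' block error model.
#'
#' @inheritParams sas_curves
#' @param modality_spec A [modality_spec()] or modality name.
#' @return A `sas_curve`.
#' @export
buffer_subtracted_intensity <- function(system_ensemble, buffer_ensemble,
                                        envelope, q_grid, n_directions = 200,
                                        modality_spec = "SAXS", seed = 1,
                                        n_blocks = 10,
                                        variance_reduction = TRUE) {
  ms <- as_modality_spec(modality_spec)
  sas_curves(system_ensemble, buffer_ensemble, envelope, q_grid,
             n_directions = n_directions,
             modalities = setNames(list(ms), ms$modality),
             seed = seed, n_blocks = n_blocks,
             variance_reduction = variance_reduction)[[1]]
}

#' Debye double-sum intensity of a fixed configuration
#'
#' Exact orientational average I(q) = sum_jk f_j f_k sinc(q r_jk) for a
#' fixed set of atoms (no solvent model, no subtraction); the closed-form
#' cross-check for the direction-sampled estimator.
#'
#' @param config An [atomic_configuration()].
#' @param q Momentum transfer grid, nm^-1.
#' @param modality_spec A [modality_spec()] or modality name.
#' @return Numeric vector I(q) in e^2 (SAXS) or fm^2 (SANS).
#' @export
debye_intensity <- function(config, q, modality_spec = "SAXS") {
  w <- scattering_weights(config, modality_spec)
  debye_kernel(config$positions, w, q)
}

#' Scattering curve container
#'
#' @param q,I,sigma Equal-length numeric vectors: momentum transfer (nm^-1,
#'   strictly increasing), intensity (e^2 for SAXS, fm^2 i.e. nsl^2 for
#'   SANS), and one standard error per point.
#' @param modality Modality label.
#' @param n_directions Orientational-average direction count.
#' @param metadata Named list stored as an attribute.
#' @param blocks Optional per-block intensity matrix (nq x n_blocks).
#' @return data.frame of class `sas_curve`.
#' @export
sas_curve <- function(q, I, sigma = rep(0, length(q)), modality = "SAXS",
                      n_directions = NA_integer_, metadata = list(),
                      blocks = NULL) {
  stopifnot(length(q) == length(I), length(sigma) == length(q),
            all(diff(q) > 0), all(q >= 0), all(sigma >= 0 | is.na(sigma)))
  structure(data.frame(q = q, I = I, sigma = sigma),
            modality = modality, n_directions = n_directions,
            metadata = metadata, blocks = blocks,
            class = c("sas_curve", "data.frame"))
}
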