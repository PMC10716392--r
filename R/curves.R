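## Radii of gyration from scattering curves: Guinier fits, regularized P(r)
## inversion, and direct-space (coordinate) Rg.

#' Guinier fit of a scattering curve
#'
#' Weighted linear fit of ln I versus q^2 at small q: slope = -Rg^2/3,
#' intercept = ln I0.  The fit range is chosen iteratively so that
#' qmax * Rg <= `qrg_max` (community-standard validity rule; refit until the
#' range is a fixed point).  Per-point weights come from the curve's sigma
#' propagated to ln I; curves without errors are fit unweighted.
#'
#' @param curve A `sas_curve` (or data.frame with `q`, `I`, optional `sigma`).
#' @param qrg_max Guinier validity bound on qmax * Rg (default 1.3).
#' @param min_points Minimum number of points in the fit (default 4).
#' @return Object of class `guinier_result`: `Rg` (nm), `I0`, `Rg_SE`,
#'   `q_range_used`, `fit_residual`, `n_points`.
#' @export
guinier_fit <- function(curve, qrg_max = 1.3, min_points = 4) {
  q <- curve$q
  I <- curve$I
  sigma <- curve$sigma %||% rep(0, length(q))
  ## the small-q region must be positive to take logs; a systematically
  ## non-positive head indicates near-zero contrast (possible for SANS/D2O)
  head_n <- min(min_points, length(I))
  if (all(I[seq_len(head_n)] <= 0)) {
    stop("non-positive intensities in the small-q region; ",
         "check the contrast (P(r) analysis may still be possible)")
  }
  ok <- I > 0
  q <- q[ok]; I <- I[ok]; sigma <- sigma[ok]
  if (length(q) < min_points) stop("fewer than ", min_points, " positive points")

  x <- q^2
  y <- log(I)
  w <- if (any(sigma > 0)) {
    s <- sigma / I                       # sd of ln I
    s[s <= 0] <- min(s[s > 0])
    1 / s^2
  } else rep(1, length(q))

  fit_range <- function(idx) {
    f <- lm(y ~ x, weights = w, subset = idx)
    sl <- coef(f)[["x"]]
    list(fit = f, slope = sl, rg = if (sl < 0) sqrt(-3 * sl) else 0)
  }

  idx <- seq_along(q)
  last_n <- -1L
  res <- fit_range(idx)
  for (iter in 1:50) {
    if (res$rg <= 0) break
    keep <- which(q * res$rg <= qrg_max)
    if (length(keep) < min_points) keep <- seq_len(min_points)
    if (length(keep) == last_n) break
    last_n <- length(keep)
    idx <- keep
    res <- fit_range(idx)
  }
  f <- res$fit
  sl <- res$slope
  rg <- res$rg
  se_sl <- tryCatch(suppressWarnings(sqrt(vcov(f)[2, 2])),
                    error = function(e) NA_real_)
  rg_se <- if (rg > 0 && is.finite(se_sl)) 3 * se_sl / (2 * rg) else NA_real_
  structure(list(Rg = rg, I0 = exp(coef(f)[[1]]),
                 Rg_SE = rg_se,
                 q_range_used = range(q[idx]),
                 fit_residual = sum(w[idx] * residuals(f)^2),
                 n_points = length(idx)),
            class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("Guinier: Rg = %.4g nm (SE %.2g), I0 = %.4g, %d points, q in [%.3g, %.3g] nm^-1\n",
              x$Rg, x$Rg_SE, x$I0, x$n_points, x$q_range_used[1], x$q_range_used[2]))
  invisible(x)
}

#' Pair distance distribution by regularized indirect Fourier transform
#'
#' Fits P(r) on a fixed grid over [0, Dmax] to the curve through the forward
#' transform I(q) = 4 pi int P(r) sinc(q r) dr, with a second-derivative
#' smoothness penalty and the endpoint constraints P(0) = P(Dmax) = 0.
#' The regularization weight is chosen automatically at the L-curve corner
#' unless given.  Deterministic.
#'
#' @param curve A `sas_curve` (q in nm^-1).
#' @param Dmax Maximum particle dimension, nm (> 0).
#' @param n_r Number of r-grid points (default 201).
#' @param lambda Regularization weight, or `"auto"` (L-curve corner).
#' @return Object of class `pddf`: `r`, `P`, `Dmax`, `regularization_weight`,
#'   `Rg_from_P` (nm), `I0_from_P`.
#' @export
pddf_invert <- function(curve, Dmax, n_r = 201, lambda = "auto") {
  stopifnot(Dmax > 0, n_r >= 10)
  q <- curve$q
  I <- curve$I
  sigma <- curve$sigma %||% rep(0, length(q))
  if (max(q) * Dmax < pi) {
    warning("curve extends only to q*Dmax = ", round(max(q) * Dmax, 2),
            " < pi; P(r) inversion may be unstable")
  }
  r <- seq(0, Dmax, length.out = n_r)
  dr <- r[2] - r[1]
  ## forward matrix with trapezoid weights; endpoint columns dropped (P = 0)
  sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(x) / x)
  K <- 4 * pi * dr * outer(q, r, function(qq, rr) sinc(qq * rr))
  K[, c(1, n_r)] <- 0
  Kin <- K[, 2:(n_r - 1), drop = FALSE]
  w <- if (any(sigma > 0)) {
    s <- sigma
    s[s <= 0] <- min(s[s > 0])
    1 / s
  } else rep(1, length(q))
  ## scale-free weighting keeps lambda ranges comparable across curves
  Kw <- Kin * w
  yw <- I * w
  n_in <- n_r - 2
  L <- matrix(0, n_in, n_in)          # second difference incl. zero endpoints
  for (i in seq_len(n_in)) {
    L[i, i] <- -2
    if (i > 1) L[i, i - 1] <- 1
    if (i < n_in) L[i, i + 1] <- 1
  }
  L <- L / dr^2
  A <- crossprod(Kw)
  b <- crossprod(Kw, yw)
  R <- crossprod(L)
  solve_for <- function(lam) {
    p <- tryCatch(solve(A + lam * R, b),
                  error = function(e) stop("singular P(r) system at lambda = ",
                                           signif(lam, 3), ": ", conditionMessage(e)))
    as.vector(p)
  }
  if (identical(lambda, "auto")) {
    scale0 <- sum(diag(A)) / max(sum(diag(R)), 1e-300)
    lams <- scale0 * 10^seq(-8, 2, length.out = 25)
    pts <- lapply(lams, function(l) {
      p <- solve_for(l)
      c(res = sum((yw - Kw %*% p)^2), rough = sum((L %*% p)^2))
    })
    lr <- log10(pmax(vapply(pts, `[[`, numeric(1), "res"), 1e-300))
    lg <- log10(pmax(vapply(pts, `[[`, numeric(1), "rough"), 1e-300))
    ## Menger curvature of the L-curve; corner = max curvature
    curv <- rep(-Inf, length(lams))
    for (i in 2:(length(lams) - 1)) {
      x1 <- lr[i - 1]; y1 <- lg[i - 1]; x2 <- lr[i]; y2 <- lg[i]
      x3 <- lr[i + 1]; y3 <- lg[i + 1]
      area2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
      d12 <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
      d23 <- sqrt((x3 - x2)^2 + (y3 - y2)^2)
      d13 <- sqrt((x3 - x1)^2 + (y3 - y1)^2)
      if (d12 * d23 * d13 > 0) curv[i] <- 2 * area2 / (d12 * d23 * d13)
    }
    lambda <- lams[which.max(curv)]
  }
  p_in <- solve_for(lambda)
  P <- c(0, p_in, 0)
  rg <- tryCatch(pddf_rg(r, P), error = function(e) NA_real_)
  structure(list(r = r, P = P, Dmax = Dmax,
                 regularization_weight = lambda,
                 Rg_from_P = rg,
                 I0_from_P = 4 * pi * dr * sum(P)),
            class = "pddf")
}

#' @export
print.pddf <- function(x, ...) {
  cat(sprintf("P(r): Dmax = %.3g nm, lambda = %.3g, Rg = %.4g nm\n",
              x$Dmax, x$regularization_weight, x$Rg_from_P))
  invisible(x)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

pddf_rg <- function(r, P) {
  norm <- trapz(r, P)
  if (abs(norm) < 1e-300) stop("P(r) integrates to zero; Rg undefined")
  rg2 <- trapz(r, r^2 * P) / (2 * norm)
  if (rg2 < 0) stop("negative Rg^2 from P(r)")
  sqrt(rg2)
}

#' Radius of gyration from a P(r) function
#'
#' Rg^2 = int r^2 P(r) dr / (2 int P(r) dr), by trapezoidal quadrature on
#' the P grid.
#'
#' @param p A `pddf` object (or list with `r`, `P`).
#' @return Rg in nm.
#' @export
rg_from_pddf <- function(p) pddf_rg(p$r, p$P)

#' Direct-space radius of gyration from coordinates
#'
#' sqrt( sum w_j |r_j - rbar|^2 / sum w_j ) with the weighted centroid rbar,
#' over a chosen atom subset.  Weighting by electron count is the SAXS-facing
#' convention for the bare-solute Rg.
#'
#' @param config An [atomic_configuration()].
#' @param weighting `"contrast_electrons"` (default), `"contrast_nsl"`, or
#'   `"uniform"`.
#' @param atom_subset Logical or integer index of atoms; default: the solute.
#' @return Rg in nm.
#' @export
rg_direct <- function(config, weighting = c("contrast_electrons", "contrast_nsl",
                                            "uniform"),
                      atom_subset = NULL) {
  weighting <- match.arg(weighting)
  if (is.null(atom_subset)) atom_subset <- config$role == "solute"
  pos <- config$positions[atom_subset, , drop = FALSE]
  if (nrow(pos) == 0) stop("empty atom subset")
  sp <- species_params(config)[atom_subset, , drop = FALSE]
  w <- switch(weighting,
              contrast_electrons = sp$electrons,
              contrast_nsl = sp$b_fm,
              uniform = rep(1, nrow(pos)))
  if (abs(sum(w)) < 1e-300) stop("total weight is zero")
  ctr <- colSums(pos * w) / sum(w)
  rg2 <- sum(w * rowSums(sweep(pos, 2, ctr)^2)) / sum(w)
  if (rg2 < 0) stop("negative weighted Rg^2")
  sqrt(rg2)
}
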