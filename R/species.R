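## Scattering species: electron counts, X-ray form factors, coherent neutron
## scattering lengths, and H/D exchangeability classes.

#' Coherent neutron scattering lengths
#'
#' Bound coherent scattering lengths in femtometres for the elements handled
#' by the package, from the standard Sears/NIST compilation.  Hydrogen and
#' deuterium are the values that drive all H/D-exchange arithmetic:
#' b(H) = -3.741 fm, b(D) = +6.671 fm.
#'
#' @return Named numeric vector of scattering lengths (fm).
#' @export
neutron_scattering_lengths <- function() {
  c(H = -3.741, D = 6.671, C = 6.646, N = 9.360, O = 5.803,
    S = 2.847, P = 5.130, `NA+` = 3.630, `CL-` = 9.577)
}

## Cromer-Mann 4-Gaussian X-ray form factor coefficients (International
## Tables for Crystallography, vol. C); f(s) = sum a_i exp(-b_i s^2) + c with
## s = q_Angstrom / (4 pi).  Only the elements that occur in protein systems
## are tabulated; everything else falls back to a constant factor equal to
## the electron count, which is exact at q = 0 and adequate in the small-q
## regime the hydration observables probe.
.cromer_mann <- list(
  H = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
           b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  S = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
           b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900),
  P = list(a = c(6.43450, 4.17910, 1.78000, 1.49080),
           b = c(1.90670, 27.1570, 0.526000, 68.1645), c = 1.11490))

#' X-ray atomic form factor
#'
#' Evaluates the Cromer-Mann parameterization for tabulated elements; for any
#' other species label the form factor is constant and equal to the electron
#' count (the pseudo-atom convention).
#'
#' @param label Species label (single string), e.g. `"C"` or `"W"`.
#' @param q Momentum transfer, nm^-1 (vector).
#' @param electrons Electron count used both as f(0) normalization check and
#'   as the constant fallback.
#' @return Numeric vector, same length as `q`, in electrons.
#' @export
xray_form_factor <- function(label, q, electrons) {
  base <- sub("[WPN]$", "", label)           # HW/HP/HN -> H
  cm <- .cromer_mann[[base]]
  if (is.null(cm)) return(rep(electrons, length(q)))
  s2 <- (q / 10 / (4 * pi))^2                # q in nm^-1 -> s in A^-1
  f <- cm$c + colSums(cm$a * exp(-outer(cm$b, s2)))
  ## renormalize so f(0) matches the integer electron count exactly
  f * (electrons / (cm$c + sum(cm$a)))
}

#' Default scattering species registry
#'
#' One row per species label with electron count, base (protonated) coherent
#' neutron scattering length, number of exchangeable hydrogens carried by the
#' site, exchangeability class, and Van-der-Waals radius.  The single-site
#' pseudo-water `"W"` carries 10 electrons and the whole-molecule scattering
#' length b(H2O) = b(O) + 2 b(H); its two hydrogens exchange in D2O, giving
#' b(D2O) = +19.145 fm.  Hydrogen sites are split by environment: `"HW"`
#' (water hydrogen), `"HP"` (polar, O/N/S-bonded), `"HN"` (backbone amide),
#' and `"H"` (non-exchangeable, carbon-bonded).
#'
#' @return data.frame with columns `label`, `electrons`, `b_fm`, `n_exch_h`,
#'   `exch_class`, `vdw_nm`.
#' @export
species_table <- function() {
  b <- neutron_scattering_lengths()
  df <- function(label, electrons, b_fm, n_exch_h, exch_class, vdw_nm) {
    b_fm <- unname(b_fm)
    data.frame(label = label, electrons = electrons, b_fm = b_fm,
               n_exch_h = n_exch_h, exch_class = exch_class,
               vdw_nm = vdw_nm, stringsAsFactors = FALSE)
  }
  rbind(
    df("W",   10, b["O"] + 2 * b["H"], 2, "water_H", 0.14),
    df("H",    1, b["H"], 0, "none",            0.11),
    df("HW",   1, b["H"], 1, "water_H",         0.11),
    df("HP",   1, b["H"], 1, "polar_H",         0.11),
    df("HN",   1, b["H"], 1, "backbone_amide_H", 0.11),
    df("C",    6, b["C"], 0, "none", 0.170),
    df("N",    7, b["N"], 0, "none", 0.155),
    df("O",    8, b["O"], 0, "none", 0.152),
    df("S",   16, b["S"], 0, "none", 0.180),
    df("P",   15, b["P"], 0, "none", 0.180),
    df("NA+", 10, b["NA+"], 0, "none", 0.227),
    df("CL-", 18, b["CL-"], 0, "none", 0.175))
}

## rows of the configuration's species table matched to its per-atom labels
species_params <- function(config) {
  tab <- attr(config, "species_table")
  idx <- match(config$species, tab$label)
  if (anyNA(idx)) {
    stop("unknown species label(s): ",
         paste(unique(config$species[is.na(idx)]), collapse = ", "))
  }
  tab[idx, , drop = FALSE]
}

#' Effective neutron scattering lengths under a solvent/deuteration model
#'
#' Implements H/D exchange for the three modalities.  In D2O, water and polar
#' hydrogens carry b(D); backbone-amide hydrogens are deuterated with
#' probability `amide_fraction` (default 0.90), either as the fractional mean
#' b = f b(D) + (1-f) b(H) (default, the ensemble average, free of sampling
#' variance) or Bernoulli-sampled per atom.  In H2O all hydrogens keep b(H).
#' SAXS leaves neutron lengths untouched.
#'
#' @param config An [atomic_configuration()].
#' @param modality_spec A [modality_spec()] (or modality string).
#' @param mode `"fractional"` or `"sampled"` amide deuteration.
#' @param seed Seed for `mode = "sampled"`.
#' @return Numeric vector: per-atom coherent scattering length (fm).
#' @export
assign_deuteration <- function(config, modality_spec, mode = NULL, seed = NULL) {
  ms <- as_modality_spec(modality_spec)
  mode <- mode %||% ms$deuteration_mode
  mode <- match.arg(mode, c("fractional", "sampled"))
  sp <- species_params(config)
  bad <- !sp$exch_class %in% c("none", "water_H", "polar_H", "backbone_amide_H")
  if (any(bad)) {
    stop("unknown exchangeable class: ", paste(unique(sp$exch_class[bad]), collapse = ", "))
  }
  b <- sp$b_fm
  if (ms$modality != "SANS_D2O") return(b)
  nsl <- neutron_scattering_lengths()
  shift <- unname(nsl["D"] - nsl["H"])
  p <- numeric(nrow(sp))
  p[sp$exch_class %in% c("water_H", "polar_H")] <- 1
  amide <- sp$exch_class == "backbone_amide_H"
  if (mode == "fractional") {
    p[amide] <- ms$amide_deuteration_fraction
    b + sp$n_exch_h * p * shift
  } else {
    p[amide] <- 1
    drawn <- with_seed(seed %||% 1L, {
      d <- rep(1, nrow(sp))
      d[amide] <- rbinom(sum(amide), 1, ms$amide_deuteration_fraction)
      d
    })
    b + sp$n_exch_h * p * drawn * shift
  }
}

#' Modality specification for a scattering calculation
#'
#' @param modality One of `"SAXS"`, `"SANS_H2O"`, `"SANS_D2O"`.
#' @param amide_deuteration_fraction Probability that a backbone-amide
#'   hydrogen is deuterated in D2O; default 0.90.
#' @param target_bulk_density Bulk solvent scattering density the buffer is
#'   corrected to: e/nm^3 for SAXS (default 334, the experimental water
#'   value), nsl (fm)/nm^3 for SANS.  `NULL` selects the default: 334 e/nm^3
#'   for SAXS and, for SANS, the analogous value obtained by scaling the
#'   buffer's solvent to 334 e/nm^3 worth of molecules.
#' @param deuteration_mode `"fractional"` (default) or `"sampled"`.
#' @param density_correction Apply the solvent density correction factor?
#' @return Object of class `modality_spec`.
#' @export
modality_spec <- function(modality = c("SAXS", "SANS_H2O", "SANS_D2O"),
                          amide_deuteration_fraction = 0.90,
                          target_bulk_density = NULL,
                          deuteration_mode = "fractional",
                          density_correction = TRUE) {
  modality <- match.arg(modality)
  stopifnot(amide_deuteration_fraction >= 0, amide_deuteration_fraction <= 1)
  structure(list(modality = modality,
                 amide_deuteration_fraction = amide_deuteration_fraction,
                 target_bulk_density = target_bulk_density,
                 deuteration_mode = deuteration_mode,
                 density_correction = density_correction),
            class = "modality_spec")
}

as_modality_spec <- function(x) {
  if (inherits(x, "modality_spec")) return(x)
  if (is.character(x) && length(x) == 1) return(modality_spec(x))
  stop("expected a modality_spec or a modality name")
}

## per-atom scattering weights for one modality at a single |q| (q = NULL or
## 0 gives the forward-scattering weights): Cromer-Mann electrons for SAXS,
## effective neutron lengths for SANS
scattering_weights <- function(config, modality_spec, q = NULL, seed = NULL) {
  ms <- as_modality_spec(modality_spec)
  if (ms$modality != "SAXS") return(assign_deuteration(config, ms, seed = seed))
  sp <- species_params(config)
  if (is.null(q) || length(q) != 1 || q == 0) return(sp$electrons)
  labs <- unique(config$species)
  f <- vapply(labs, function(l) {
    xray_form_factor(l, q, sp$electrons[match(l, config$species)])
  }, numeric(1))
  unname(f[match(config$species, labs)])
}
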