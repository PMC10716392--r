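## Small shared fixtures; everything is generated in code.

## a compact spec that keeps unit tests fast (small box, thin solvent)
small_spec <- function(...) {
  synthetic_spec(solute_radius = 0.6, solute_atom_spacing = 0.3,
                 box_edge = 4.0, envelope_margin = 0.9, ...)
}

## fixed-atom configuration in a huge box (vacuum-style scattering tests)
fixed_config <- function(pos, species = "C", box = 50) {
  pos <- matrix(pos, ncol = 3)
  atomic_configuration(pos, rep(species, length.out = nrow(pos)),
                       rep("solute", nrow(pos)), box = box)
}

## independent brute-force Debye sum written directly in R
debye_r <- function(pos, w, q) {
  n <- nrow(pos)
  sapply(q, function(qq) {
    acc <- sum(w^2)
    for (j in seq_len(n - 1)) {
      for (k in (j + 1):n) {
        r <- sqrt(sum((pos[j, ] - pos[k, ])^2))
        s <- if (qq * r < 1e-12) 1 else sin(qq * r) / (qq * r)
        acc <- acc + 2 * w[j] * w[k] * s
      }
    }
    acc
  })
}

## analytic sphere form factor (uniform density, radius R), normalized I/I0
sphere_ff <- function(q, R) {
  x <- q * R
  (3 * (sin(x) - x * cos(x)) / x^3)^2
}

## orientationally averaged intensity of a fixed configuration via the
## package's direction-sampling estimator
avg_intensity <- function(config, q, n_dir = 200, seed = 3, modality = "SAXS") {
  dirs <- generate_q_directions(n_dir, seed = seed)
  sapply(q, function(qq) {
    mean(Mod(sas_amplitude(config, NULL, qq * dirs, modality))^2)
  })
}

## Rg of an arbitrary (r, P) table through the exported quadrature
pddf_rg_wrap <- function(r, P) rg_from_pddf(list(r = r, P = P))
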