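## File formats: extended XYZ and multi-model PDB frames, three-column SAS
## curves, tabular P(r)/profile output, YAML run configuration.

NM_PER_ANGSTROM <- 0.1

## short stable digest of a configuration list, stamped into output headers
config_hash <- function(x) substr(rlang::hash(x), 1, 12)

## ---- extended XYZ ------------------------------------------------------

#' Write frames as extended XYZ
#'
#' One block per frame: atom count, a comment line carrying the periodic box
#' (`Lattice="..."`), the frame id, and the length unit, then one line per
#' atom: species, x, y, z, role.  Coordinates are written in nm.
#'
#' @param frames A single [atomic_configuration()] or a list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path) {
  if (inherits(frames, "atomic_config")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$positions)
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Lattice="%.8g 0 0 0 %.8g 0 0 0 %.8g" Properties=species:S:1:pos:R:3:role:S:1 frame_id=%d unit=nm',
      fr$box[1], fr$box[2], fr$box[3], fr$frame_id), con)
    if (n > 0) {
      writeLines(sprintf("%s %.8f %.8f %.8f %s", fr$species,
                         fr$positions[, 1], fr$positions[, 2],
                         fr$positions[, 3], fr$role), con)
    }
  }
  invisible(path)
}

#' Read frames from extended XYZ
#'
#' @param path Input file written by [write_xyz()] (or compatible).
#' @param unit Length unit of the file if its comment lines do not declare
#'   one: `"nm"` (default) or `"angstrom"`.
#' @param species_table Species registry attached to the frames.
#' @return List of [atomic_configuration()].
#' @export
read_xyz <- function(path, unit = c("nm", "angstrom"),
                     species_table = hydrosas::species_table()) {
  unit <- match.arg(unit)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    comment <- lines[i + 1L]
    lat <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]][2]
    if (is.na(lat)) stop("missing Lattice (box) in XYZ comment line")
    latv <- as.numeric(strsplit(trimws(lat), "\\s+")[[1]])
    box <- latv[c(1, 5, 9)]
    fid <- regmatches(comment, regexec("frame_id=([-0-9]+)", comment))[[1]][2]
    fid <- if (is.na(fid)) length(frames) else as.integer(fid)
    u <- regmatches(comment, regexec("unit=(\\w+)", comment))[[1]][2]
    scale <- if (!is.na(u) && u %in% c("A", "angstrom", "Angstrom")) NM_PER_ANGSTROM
             else if (!is.na(u)) 1
             else if (unit == "angstrom") NM_PER_ANGSTROM else 1
    rows <- if (n > 0) lines[(i + 2L):(i + 1L + n)] else character(0)
    parts <- strsplit(trimws(rows), "\\s+")
    species <- vapply(parts, `[[`, character(1), 1)
    pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    role <- vapply(parts, function(p) if (length(p) >= 5) p[[5]] else "solute",
                   character(1))
    frames[[length(frames) + 1L]] <- atomic_configuration(
      pos * scale, species, role, box * scale, frame_id = fid,
      species_table = species_table)
    i <- i + 2L + n
  }
  frames
}

## ---- multi-model PDB ---------------------------------------------------

## map internal species labels to PDB residue/atom names and back
.pdb_resname <- function(species, role) {
  ifelse(species == "W", "HOH",
         ifelse(role == "ion", ifelse(species == "NA+", "NA", "CL"),
                "MOL"))
}

#' Write frames as a multi-model PDB file
#'
#' Minimal writer: a CRYST1 record with the box (converted to Angstrom, as
#' the PDB standard requires), then one MODEL block per frame with HETATM
#' records.  Pseudo-waters become HOH/O sites; solute pseudo-atoms become
#' MOL/C sites; ions keep their element.
#'
#' @inheritParams write_xyz
#' @return `path`, invisibly.
#' @export
write_pdb_frames <- function(frames, path) {
  if (inherits(frames, "atomic_config")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  box <- frames[[1]]$box / NM_PER_ANGSTROM
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                     box[1], box[2], box[3]), con)
  for (fr in frames) {
    writeLines(sprintf("MODEL     %4d", fr$frame_id + 1L), con)
    n <- nrow(fr$positions)
    if (n > 0) {
      res <- .pdb_resname(fr$species, fr$role)
      elem <- ifelse(fr$species == "W", "O",
                     ifelse(fr$species == "CG", "C",
                            sub("[+-]$", "", sub("^(H)[WPN]$", "H", fr$species))))
      aname <- formatC(substr(elem, 1, 4), width = 4)
      p <- fr$positions / NM_PER_ANGSTROM
      writeLines(sprintf("HETATM%5d %s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                         (seq_len(n) - 1L) %% 99999 + 1L, aname, res,
                         (seq_len(n) - 1L) %% 9999 + 1L,
                         p[, 1], p[, 2], p[, 3], substr(elem, 1, 2)), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## residue-name sets used to assign roles when reading structures
.water_resnames <- c("HOH", "WAT", "SOL", "TIP", "TIP3", "TIP4", "SPC", "H2O")
.ion_resnames <- c("NA", "CL", "K", "MG", "ZN", "CA2", "SOD", "CLA", "NA+", "CL-")

#' Read frames from a (multi-model) PDB file
#'
#' Parses atoms with `bio3d::read.pdb` and the periodic box from the CRYST1
#' record.  Species, roles, and hydrogen exchangeability classes are assigned
#' from residue and atom names: water residues become solvent (their oxygens
#' are mapped to the single-site pseudo-water when `collapse_water = TRUE`,
#' their hydrogens to class water-H otherwise); monatomic ion residues become
#' ions; everything else is solute, with backbone amide H (atom names H/HN)
#' and polar H (named after O/N/S-bound positions) classified accordingly.
#'
#' @param path PDB file.
#' @param collapse_water Represent each water by its oxygen as a 10-electron
#'   pseudo-water site (default TRUE; matches the synthetic solvent model).
#' @param unknown_residue Policy for residues that fit no rule: `"solute"`
#'   (default) or `"error"`.
#' @param species_table Species registry attached to the frames.
#' @return List of [atomic_configuration()].
#' @export
read_pdb_frames <- function(path, collapse_water = TRUE,
                            unknown_residue = c("solute", "error"),
                            species_table = hydrosas::species_table()) {
  unknown_residue <- match.arg(unknown_residue)
  txt <- readLines(path)
  cr <- grep("^CRYST1", txt, value = TRUE)
  if (length(cr) == 0) stop("missing CRYST1 record: no periodic box")
  box <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                      substr(cr[1], 25, 33))) * NM_PER_ANGSTROM
  ## parse model by model (frames may have different atom counts, e.g. a
  ## grand-canonical solvent), each through bio3d
  starts <- grep("^MODEL", txt)
  ends <- grep("^ENDMDL", txt)
  pieces <- if (length(starts)) {
    mapply(function(s, e) txt[(s + 1):(e - 1)], starts, ends,
           SIMPLIFY = FALSE)
  } else list(grep("^(ATOM|HETATM|TER)", txt, value = TRUE))
  parse_model <- function(lines, fid) {
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf))
    writeLines(c(lines, "END"), tf)
    pdb <- bio3d::read.pdb(tf, verbose = FALSE)
    classify_pdb_atoms(pdb$atom, box, fid, collapse_water, unknown_residue,
                       species_table)
  }
  lapply(seq_along(pieces), function(i) parse_model(pieces[[i]], i - 1L))
}

classify_pdb_atoms <- function(at, box, frame_id, collapse_water,
                               unknown_residue, species_table) {
  resid <- toupper(at$resid)
  elety <- toupper(at$elety)
  elesy <- toupper(trimws(at$elesy %||% ""))
  elem <- ifelse(nzchar(elesy), elesy, substr(gsub("[0-9]", "", elety), 1, 1))
  is_water <- resid %in% .water_resnames
  is_ion <- resid %in% .ion_resnames & !is_water
  if (unknown_residue == "error") {
    known <- is_water | is_ion |
      resid %in% c("MOL", bio3d::aa.table$aa3) | elem %in% c("C", "N", "O", "S", "P", "H")
    if (any(!known)) stop("unknown residue(s): ",
                          paste(unique(resid[!known]), collapse = ", "))
  }
  species <- character(nrow(at))
  role <- ifelse(is_water, "solvent", ifelse(is_ion, "ion", "solute"))
  ## solvent
  species[is_water & elem == "O"] <- if (collapse_water) "W" else "O"
  species[is_water & elem == "H"] <- "HW"
  ## ions
  species[is_ion] <- ifelse(elem[is_ion] %in% c("N", "NA"), "NA+", "CL-")
  ## solute heavy atoms
  heavy <- !is_water & !is_ion & elem %in% c("C", "N", "O", "S", "P")
  species[heavy] <- elem[heavy]
  ## solute hydrogens: backbone amide H named H/HN; polar H by name pattern
  hsel <- !is_water & !is_ion & elem == "H"
  amide <- hsel & elety %in% c("H", "HN")
  polar_pat <- "^(H[GDEH][0-9]*$|HO|HH|HE[12]?$|HD1$|HZ[0-9]*$|HG1$)"
  polar <- hsel & !amide & grepl(polar_pat, elety)
  species[amide] <- "HN"
  species[polar] <- "HP"
  species[hsel & !amide & !polar] <- "H"
  drop <- is_water & elem == "H" & collapse_water
  pos <- cbind(at$x, at$y, at$z) * NM_PER_ANGSTROM
  atomic_configuration(pos[!drop, , drop = FALSE], species[!drop],
                       role[!drop], box, frame_id = frame_id,
                       species_table = species_table)
}

#' Generic frame reader
#'
#' Dispatches on `format` (or the file extension) to [read_pdb_frames()] or
#' [read_xyz()].
#'
#' @param path Input file.
#' @param format `"pdb"`, `"xyz"`, or `NULL` to infer from the extension.
#' @param ... Passed to the format-specific reader.
#' @return List of [atomic_configuration()].
#' @export
read_frames <- function(path, format = NULL, ...) {
  format <- format %||% tolower(tools::file_ext(path))
  switch(format,
         pdb = read_pdb_frames(path, ...),
         xyz = read_xyz(path, ...),
         stop("unsupported frame format: ", format))
}

## ---- curves, P(r), profiles -------------------------------------------

write_table_with_header <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header_lines), con)
  writeLines(paste0("# ", paste(names(df), collapse = " ")), con)
  writeLines(do.call(sprintf,
                     c(list(paste(rep("%.8g", ncol(df)), collapse = " ")),
                       unname(as.list(df)))), con)
  invisible(path)
}

#' Write a scattering curve as three-column text
#'
#' Columns q (nm^-1), I (e^2 for SAXS, nsl^2 = fm^2 for SANS), sigma (1 SE),
#' with a header naming the modality, units, and a configuration hash.
#'
#' @param curve A `sas_curve`.
#' @param path Output file.
#' @param config Optional configuration list hashed into the header.
#' @return `path`, invisibly.
#' @export
write_sas_curve <- function(curve, path, config = NULL) {
  mod <- attr(curve, "modality") %||% "SAXS"
  units <- if (mod == "SAXS") "e^2" else "nsl^2 (fm^2)"
  hdr <- c(sprintf("modality: %s", mod),
           sprintf("units: q [1/nm], I [%s], sigma [%s]", units, units),
           sprintf("config_hash: %s",
                   config_hash(config %||% attr(curve, "metadata"))))
  write_table_with_header(data.frame(q = curve$q, I = curve$I,
                                     sigma = curve$sigma), path, hdr)
}

#' Read a three-column scattering curve
#'
#' @param path Text file with columns q, I, sigma (comment lines start
#'   with `#`); q in nm^-1 unless the header or `unit` says Angstrom^-1.
#' @param unit `"nm"` (default) or `"angstrom"` for the q column.
#' @return A `sas_curve`.
#' @export
read_sas_curve <- function(path, unit = c("nm", "angstrom")) {
  unit <- match.arg(unit)
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  mod <- regmatches(hdr, regexec("modality:\\s*(\\S+)", hdr))
  mod <- unlist(lapply(mod, function(m) m[2]))
  mod <- if (length(mod) && !all(is.na(mod))) mod[!is.na(mod)][1] else "SAXS"
  dat <- utils::read.table(text = lines[!grepl("^\\s*#", lines)])
  q <- dat[[1]]
  if (unit == "angstrom" || any(grepl("1/A|A\\^-1", hdr))) q <- q * 10
  sas_curve(q, dat[[2]],
            if (ncol(dat) >= 3) dat[[3]] else rep(0, length(q)),
            modality = mod)
}

#' Write a P(r) function as tabular text
#' @param p A `pddf`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pddf <- function(p, path) {
  hdr <- c("pair distance distribution function",
           sprintf("Dmax_nm: %.8g  lambda: %.8g  Rg_nm: %.8g",
                   p$Dmax, p$regularization_weight, p$Rg_from_P),
           "columns: r [nm], P [curve units * nm^-1]")
  write_table_with_header(data.frame(r = p$r, P = p$P), path, hdr)
}

#' Write a density profile as three-column text
#' @param profile A `density_profile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_density_profile <- function(profile, path) {
  mod <- attr(profile, "modality") %||% "SAXS"
  units <- if (mod == "SAXS") "e/nm^3" else "fm/nm^3"
  hdr <- c(sprintf("solvent density vs distance R from the Van-der-Waals surface (%s)", mod),
           sprintf("columns: R [nm], density [%s], se [%s]", units, units))
  write_table_with_header(data.frame(R = profile$R, density = profile$density,
                                     se = profile$se), path, hdr)
}

## ---- run configuration -------------------------------------------------

#' Default pipeline configuration
#'
#' All defaults follow the reference protocol where one is stated: envelope
#' distance 0.9 nm, 200 q-vectors per |q|, 10 blocks, bulk density
#' 334 e/nm^3, 90% backbone-amide deuteration.  Lengths are nm; inputs in
#' Angstrom must be declared via `unit`.
#'
#' @param ... Overrides of the default fields.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    spec = list(),                  # synthetic_spec() arguments (generate mode)
    system_frames = NULL,           # or paths to frame files
    buffer_frames = NULL,
    n_frames = NULL,
    n_buffer_frames = NULL,
    envelope_distance = 0.9,
    subdivision_level = 4,
    q_min = 0.05, q_max = 1.5, n_q = 40,
    n_directions = 200,
    n_blocks = 10,
    modalities = c("SAXS", "SANS_H2O", "SANS_D2O"),
    amide_deuteration_fraction = 0.90,
    seed = 1,
    unit = "nm",
    profile = FALSE,
    profile_spacing = 0.05,
    profile_shells = 12,
    output_dir = "hydrosas_out")
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  structure(modifyList(cfg, over), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys mirror [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) run_config(yaml::read_yaml(path))

#' Write a pipeline configuration to YAML
#' @param config A `run_config`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
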