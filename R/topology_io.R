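# GROMACS-dialect file emission and parsing: molecule topologies (.itp),
# coordinates (.gro, fixed-column, nm) and run-parameter (.mdp) protocols.
# Formatting is bit-stable: fixed widths, one term per line, `;` comments
# carrying provenance (term label).

bead_index <- function(topology, name) match(name, topology$beads$name)

#' Write a CG topology as a GROMACS .itp file
#'
#' Sections: `[moleculetype]` (nrexcl 1), `[atoms]`, `[bonds]`,
#' `[constraints]`, `[angles]` (function type 1, harmonic in theta),
#' `[dihedrals]` (proper, function type 1), `[virtual_sitesn]`
#' (centre-of-geometry construction) and `[exclusions]` between each
#' virtual site and its ring beads.
#'
#' @param topology A `cg_topology` from [build_topology()].
#' @param path Output path.
#' @param angle_funct GROMACS angle function type (1 harmonic, 2 cosine-
#'   based); written as-is.
#' @return `path`, invisibly.
#' @export
write_itp <- function(topology, path, angle_funct = 1L) {
  t <- topology
  idx <- function(n) bead_index(t, n)
  res_names <- c(sub("^.*_", "", t$molecule), sub("_.*$", "", t$molecule))
  if (any(!nzchar(res_names)) || anyNA(res_names)) res_names <- c("RES1", "RES2")
  L <- c("[ moleculetype ]",
         "; molname       nrexcl",
         sprintf("%-15s %d", t$molecule, 1L),
         "",
         "[ atoms ]",
         ";  nr type  resnr residue atom cgnr  charge    mass")
  for (r in seq_len(nrow(t$beads))) {
    b <- t$beads[r, ]
    L <- c(L, sprintf("%5d %-5s %5d %-7s %-4s %4d %7.4f %9.4f",
                      r, b$type, b$residue, res_names[[b$residue]], b$name,
                      r, b$charge, b$mass))
  }
  L <- c(L, "", "[ bonds ]", ";   i    j funct        b0          kb ; term")
  for (r in seq_len(nrow(t$bonds))) {
    bb <- t$bonds[r, ]
    L <- c(L, sprintf("%5d %4d %5d %9.4f %11.4f ; %s",
                      idx(bb$i), idx(bb$j), 1L, bb$b0, bb$kb, bb$label))
  }
  L <- c(L, "", "[ constraints ]", ";   i    j funct    length ; term")
  for (r in seq_len(nrow(t$constraints))) {
    cc <- t$constraints[r, ]
    L <- c(L, sprintf("%5d %4d %5d %9.4f ; %s",
                      idx(cc$i), idx(cc$j), 1L, cc$length, cc$label))
  }
  L <- c(L, "", "[ angles ]",
         ";   i    j    k funct    theta0      ktheta ; term")
  for (r in seq_len(nrow(t$angles))) {
    aa <- t$angles[r, ]
    L <- c(L, sprintf("%5d %4d %4d %5d %9.4f %11.4f ; %s",
                      idx(aa$i), idx(aa$j), idx(aa$k), angle_funct,
                      aa$theta0, aa$ktheta, aa$label))
  }
  L <- c(L, "", "[ dihedrals ]",
         ";   i    j    k    l funct      phi0        kphi mult ; term")
  for (r in seq_len(nrow(t$dihedrals))) {
    dd <- t$dihedrals[r, ]
    L <- c(L, sprintf("%5d %4d %4d %4d %5d %9.4f %11.4f %4d ; %s",
                      idx(dd$i), idx(dd$j), idx(dd$k), idx(dd$l), 1L,
                      dd$phi0, dd$kphi, dd$mult, dd$label))
  }
  L <- c(L, "", "[ virtual_sitesn ]", "; site funct constructing-beads (COG)")
  for (vn in names(t$virtual_sites))
    L <- c(L, sprintf("%5d %5d %s", idx(vn), 1L,
                      paste(sprintf("%4d", vapply(t$virtual_sites[[vn]], idx, 1L)),
                            collapse = " ")))
  L <- c(L, "", "[ exclusions ]")
  for (vn in names(t$exclusions))
    L <- c(L, sprintf("%5d %s", idx(vn),
                      paste(sprintf("%4d", vapply(t$exclusions[[vn]], idx, 1L)),
                            collapse = " ")))
  writeLines(L, path)
  invisible(path)
}

#' Read a CG topology from a .itp file written by [write_itp()]
#'
#' @param path File path.
#' @return A `cg_topology`.  Malformed section content raises an error with
#'   the line number.
#' @export
read_itp <- function(path) {
  raw <- readLines(path, warn = FALSE)
  section <- NA_character_
  mol <- NULL
  beads <- list(); bonds <- list(); constraints <- list()
  angles <- list(); dihedrals <- list(); vsites <- list(); excl <- list()
  for (ln in seq_along(raw)) {
    line <- raw[ln]
    label <- if (grepl(";", line, fixed = TRUE))
      trimws(sub("^[^;]*;", "", line)) else NA_character_
    line <- trimws(sub(";.*$", "", line))
    if (!nzchar(line)) next
    if (grepl("^\\[", line)) {
      section <- tolower(gsub("[][ ]", "", line))
      next
    }
    tok <- strsplit(line, "[[:space:]]+")[[1L]]
    bad <- function(what) stop("line ", ln, ": malformed ", what, " entry")
    switch(section,
      moleculetype = { mol <- tok[[1L]] },
      atoms = {
        if (length(tok) != 8L) bad("[atoms]")
        beads[[length(beads) + 1L]] <- data.frame(
          name = tok[[5L]], type = tok[[2L]],
          residue = as.integer(tok[[3L]]), charge = as.numeric(tok[[7L]]),
          mass = as.numeric(tok[[8L]]), stringsAsFactors = FALSE)
      },
      bonds = {
        if (length(tok) != 5L) bad("[bonds]")
        bonds[[length(bonds) + 1L]] <- data.frame(
          label = label, i = as.integer(tok[[1L]]), j = as.integer(tok[[2L]]),
          b0 = as.numeric(tok[[4L]]), kb = as.numeric(tok[[5L]]),
          stringsAsFactors = FALSE)
      },
      constraints = {
        if (length(tok) != 4L) bad("[constraints]")
        constraints[[length(constraints) + 1L]] <- data.frame(
          label = label, i = as.integer(tok[[1L]]), j = as.integer(tok[[2L]]),
          length = as.numeric(tok[[4L]]), stringsAsFactors = FALSE)
      },
      angles = {
        if (length(tok) != 6L) bad("[angles]")
        angles[[length(angles) + 1L]] <- data.frame(
          label = label, i = as.integer(tok[[1L]]), j = as.integer(tok[[2L]]),
          k = as.integer(tok[[3L]]), theta0 = as.numeric(tok[[5L]]),
          ktheta = as.numeric(tok[[6L]]), stringsAsFactors = FALSE)
      },
      dihedrals = {
        if (length(tok) != 8L) bad("[dihedrals]")
        dihedrals[[length(dihedrals) + 1L]] <- data.frame(
          label = label, i = as.integer(tok[[1L]]), j = as.integer(tok[[2L]]),
          k = as.integer(tok[[3L]]), l = as.integer(tok[[4L]]),
          phi0 = as.numeric(tok[[6L]]), kphi = as.numeric(tok[[7L]]),
          mult = as.integer(tok[[8L]]), stringsAsFactors = FALSE)
      },
      virtual_sitesn = {
        if (length(tok) < 3L) bad("[virtual_sitesn]")
        vsites[[length(vsites) + 1L]] <-
          list(site = as.integer(tok[[1L]]),
               from = as.integer(tok[-(1:2)]))
      },
      exclusions = {
        if (length(tok) < 2L) bad("[exclusions]")
        excl[[length(excl) + 1L]] <-
          list(site = as.integer(tok[[1L]]), with = as.integer(tok[-1L]))
      },
      stop("line ", ln, ": content outside a recognised section"))
  }
  if (is.null(mol)) stop("no [moleculetype] section found")
  beads <- do.call(rbind, beads)
  name_of <- function(i) beads$name[i]
  fix_names <- function(df, cols) {
    if (is.null(df)) return(NULL)
    for (cl in cols) df[[cl]] <- name_of(df[[cl]])
    df
  }
  vs <- setNames(lapply(vsites, function(v) name_of(v$from)),
                 vapply(vsites, function(v) name_of(v$site), ""))
  ex <- setNames(lapply(excl, function(v) name_of(v$with)),
                 vapply(excl, function(v) name_of(v$site), ""))
  structure(list(molecule = mol, beads = beads,
                 constraints = fix_names(do.call(rbind, constraints), c("i", "j")),
                 bonds = fix_names(do.call(rbind, bonds), c("i", "j")),
                 angles = fix_names(do.call(rbind, angles), c("i", "j", "k")),
                 dihedrals = fix_names(do.call(rbind, dihedrals),
                                       c("i", "j", "k", "l")),
                 virtual_sites = vs, exclusions = ex),
            class = "cg_topology")
}

# ---- GRO coordinates -------------------------------------------------------

#' Write coordinates in GRO format
#'
#' Fixed-column GRO (nm, three decimals, velocities omitted).  Names longer
#' than five characters are truncated with a warning.
#'
#' @param coords Numeric matrix (atoms x 3, nm), rows named by atom/bead.
#' @param box Orthorhombic box edge lengths (nm, length 3).
#' @param path Output path.
#' @param atom_names,res_ids,res_names Per-atom metadata; recycled.
#' @param title Title line; a `t= <ps>` suffix is appended when `time` is
#'   given.
#' @param time Optional frame time in ps.
#' @param append Append as an extra frame (multi-frame GRO trajectory).
#' @return `path`, invisibly.
#' @export
write_gro <- function(coords, box, path, atom_names = rownames(coords),
                      res_ids = 1L, res_names = "MOL", title = "cgsugar",
                      time = NULL, append = FALSE) {
  n <- nrow(coords)
  res_ids <- rep_len(res_ids, n)
  res_names <- rep_len(res_names, n)
  atom_names <- rep_len(atom_names, n)
  too_long <- nchar(atom_names) > 5L | nchar(res_names) > 5L
  if (any(too_long)) {
    warning("truncating overlong atom/residue names to 5 characters")
    atom_names <- substr(atom_names, 1L, 5L)
    res_names <- substr(res_names, 1L, 5L)
  }
  lines <- c(if (is.null(time)) title else sprintf("%s t= %.3f", title, time),
             sprintf("%5d", n),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     res_ids %% 100000L, res_names, atom_names,
                     seq_len(n) %% 100000L, coords[, 1L], coords[, 2L],
                     coords[, 3L]),
             sprintf("%10.5f%10.5f%10.5f", box[[1L]], box[[2L]], box[[3L]]))
  if (append) cat(lines, file = path, sep = "\n", append = TRUE)
  else writeLines(lines, path)
  invisible(path)
}

parse_gro_block <- function(lines, id_style = c("name", "residue")) {
  id_style <- match.arg(id_style)
  n <- as.integer(trimws(lines[[2L]]))
  if (length(lines) < n + 3L) stop("truncated GRO frame")
  al <- lines[3:(n + 2L)]
  coords <- cbind(as.numeric(substr(al, 21L, 28L)),
                  as.numeric(substr(al, 29L, 36L)),
                  as.numeric(substr(al, 37L, 44L)))
  atoms <- data.frame(res_id = as.integer(substr(al, 1L, 5L)),
                      res_name = trimws(substr(al, 6L, 10L)),
                      name = trimws(substr(al, 11L, 15L)),
                      stringsAsFactors = FALSE)
  rownames(coords) <- if (id_style == "residue")
    paste0(atoms$res_id, ":", atoms$name) else make.unique(atoms$name, sep = "|")
  boxtok <- strsplit(trimws(lines[[n + 3L]]), "[[:space:]]+")[[1L]]
  tm <- if (grepl("t=", lines[[1L]]))
    as.numeric(sub(".*t=\\s*([0-9.eE+-]+).*", "\\1", lines[[1L]])) else NA_real_
  list(coords = coords, atoms = atoms,
       box = as.numeric(boxtok[1:3]), time = tm, nlines = n + 3L)
}

#' Read a single-frame GRO file
#'
#' @param path File path.
#' @param id_style Row naming for `coords`: `"name"` (atom names, made
#'   unique) or `"residue"` (`"<res_id>:<name>"`, matching `atom_graph`
#'   ids).
#' @return List with `coords` (matrix, nm), `atoms` (data frame: res_id,
#'   res_name, name), `box`, `time`.
#' @export
read_gro <- function(path, id_style = c("name", "residue")) {
  fr <- parse_gro_block(readLines(path, warn = FALSE), id_style)
  fr$nlines <- NULL
  fr
}

#' Read a multi-frame GRO trajectory
#'
#' Consecutive GRO blocks in one file are read as trajectory frames.
#'
#' @param path File path.
#' @param id_style Row naming, as in [read_gro()].
#' @return Atom trajectory: list with `coords` array `[atoms, 3, frames]`
#'   (atom names as first dimnames), `atoms`, `box` (from the last frame),
#'   `times`.
#' @export
read_gro_traj <- function(path, id_style = c("name", "residue")) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); pos <- 1L
  while (pos + 1L <= length(lines) && nzchar(trimws(lines[[pos + 1L]]))) {
    fr <- parse_gro_block(lines[pos:length(lines)], id_style)
    frames[[length(frames) + 1L]] <- fr
    pos <- pos + fr$nlines
    if (pos > length(lines)) break
  }
  if (!length(frames)) stop("no GRO frames found in ", path)
  a1 <- frames[[1L]]
  arr <- array(NA_real_, dim = c(nrow(a1$coords), 3L, length(frames)),
               dimnames = list(rownames(a1$coords), NULL, NULL))
  for (k in seq_along(frames)) arr[, , k] <- frames[[k]]$coords
  list(coords = arr, atoms = a1$atoms, box = a1$box,
       times = vapply(frames, `[[`, 0, "time"))
}

#' Read coordinates from a PDB file
#'
#' Thin wrapper over `bio3d::read.pdb` returning coordinates in nm.
#'
#' @param path PDB file path.
#' @return List with `coords` (matrix, nm; rows named by atom name),
#'   `atoms` (element/residue metadata), `box = NULL`.
#' @export
read_coords_pdb <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB files requires the 'bio3d' package")
  pdb <- bio3d::read.pdb(path)
  xyz <- matrix(pdb$xyz[1L, ], ncol = 3L, byrow = TRUE) / 10  # Angstrom -> nm
  rownames(xyz) <- make.unique(pdb$atom$elety, sep = "|")
  list(coords = xyz,
       atoms = data.frame(name = pdb$atom$elety, res_name = pdb$atom$resid,
                          res_id = pdb$atom$resno, stringsAsFactors = FALSE),
       box = NULL)
}

# ---- run protocols ---------------------------------------------------------

#' Emit a CG run-parameter (.mdp-style) file
#'
#' Encodes the two equilibration-and-production protocols used for the CG
#' disaccharide systems.  The "simple" protocol is 500 steps of steepest
#' descent, 100 ns NVT equilibration and a 1 microsecond NPT production run
#' (300 K, 1 bar, 20 fs timestep).  The "soft" protocol relaxes the ring
#' constraints to flexible bonds through staged NVT equilibration: 25 ns at
#' 10 fs, 50 ns at 20 fs (both flexible) and 50 ns at 20 fs with ring
#' constraints restored.  Nonbonded settings follow the reaction-field
#' scheme: 1.1 nm cutoffs, dielectric constant 15, potential-shifted
#' van der Waals.
#'
#' @param kind `"simple"` or `"soft"`.
#' @param stage For `"simple"`: `"minimization"`, `"equilibration"`,
#'   `"production"`.  For `"soft"`: `"minimization"`, `"stage1"`,
#'   `"stage2"`, `"stage3"`, `"production"`.
#' @param path Optional output path.
#' @return Character vector of `key = value` lines (invisibly written to
#'   `path` when given).
#' @export
write_run_protocol <- function(kind = c("simple", "soft"),
                               stage, path = NULL) {
  kind <- match.arg(kind)
  stages <- if (kind == "simple") c("minimization", "equilibration", "production")
            else c("minimization", "stage1", "stage2", "stage3", "production")
  stage <- match.arg(stage, stages)
  kv <- function(...) {
    x <- c(...)
    sprintf("%-22s = %s", names(x), unname(x))
  }
  nonbonded <- kv(c(cutoff_scheme = "Verlet", coulombtype = "Reaction-Field",
                    rcoulomb = "1.1", epsilon_r = "15", rvdw = "1.1",
                    `vdw-modifier` = "Potential-shift-Verlet"))
  thermo <- kv(c(tcoupl = "v-rescale", `tau-t` = "1.0", `ref-t` = "300"))
  baro <- kv(c(pcoupl = "parrinello-rahman", `tau-p` = "12.0",
               `ref-p` = "1.0", compressibility = "3e-4"))
  ringcon <- kv(c(`constraint-algorithm` = "lincs"))
  flex <- kv(c(define = "-DFLEXIBLE"))
  lines <- switch(paste(kind, stage),
    "simple minimization" = ,
    "soft minimization" = c(
      kv(c(integrator = "steep", nsteps = "500", emtol = "10")),
      nonbonded,
      if (kind == "soft") flex else ringcon),
    "simple equilibration" = c(   # 100 ns NVT at dt = 20 fs
      kv(c(integrator = "md", dt = "0.02", nsteps = "5000000")),
      nonbonded, thermo, kv(c(pcoupl = "no")), ringcon),
    "simple production" = c(      # 1 us NPT at dt = 20 fs
      kv(c(integrator = "md", dt = "0.02", nsteps = "50000000")),
      nonbonded, thermo, baro, ringcon),
    "soft stage1" = c(            # 25 ns NVT at dt = 10 fs, flexible rings
      kv(c(integrator = "md", dt = "0.01", nsteps = "2500000")),
      nonbonded, thermo, kv(c(pcoupl = "no")), flex),
    "soft stage2" = c(            # 50 ns NVT at dt = 20 fs, flexible rings
      kv(c(integrator = "md", dt = "0.02", nsteps = "2500000")),
      nonbonded, thermo, kv(c(pcoupl = "no")), flex),
    "soft stage3" = c(            # 50 ns NVT at dt = 20 fs, rings constrained
      kv(c(integrator = "md", dt = "0.02", nsteps = "2500000")),
      nonbonded, thermo, kv(c(pcoupl = "no")), ringcon),
    "soft production" = c(
      kv(c(integrator = "md", dt = "0.02", nsteps = "50000000")),
      nonbonded, thermo, baro, ringcon))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Parse a key = value protocol file or line vector
#'
#' @param x Path or character vector of lines.
#' @return Named character vector.
#' @export
read_run_protocol <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE) else x
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  setNames(vals, keys)
}
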