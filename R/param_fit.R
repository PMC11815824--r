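# Boltzmann inversion of measured bonded distributions into Martini 3
# bonded parameters.
#
# A term sampled from a harmonic potential at temperature T is Gaussian with
# Var = kB*T/k (equipartition), so the inversion is eq = sample mean,
# k = kB*T/Var.  Bonds in nm give k in kJ/mol/nm^2; angles and dihedrals are
# converted to radians for the variance so k comes out in kJ/mol/rad^2
# (dihedral k in kJ/mol for the single proper periodic term, multiplicity 1).

fitted_term <- function(kind, eq_value, force_constant = NA_real_,
                        multiplicity = NA_integer_, n = NA_integer_,
                        diagnostics = list()) {
  structure(list(kind = kind, eq_value = eq_value,
                 force_constant = force_constant, multiplicity = multiplicity,
                 n = n, diagnostics = diagnostics), class = "fitted_term")
}

#' @export
print.fitted_term <- function(x, ...) {
  cat(sprintf("<fitted_term> %s eq=%.4f k=%s n=%d\n", x$kind, x$eq_value,
              if (is.na(x$force_constant)) "-" else sprintf("%.1f", x$force_constant),
              x$n))
  invisible(x)
}

# overlap between the sample histogram and the mass of the fitted Gaussian
# on the same bins; the package's own histogram-overlap statistic doubles as
# the normality screen (the automated route checks only for a normally
# distributed population, so multimodal distributions are what it guards
# against)
gaussian_overlap <- function(samples, mu, sigma, bins = NULL) {
  if (sigma == 0) return(1)
  # square-root binning rule, capped: a fixed fine grid would starve the
  # per-bin mass at moderate sample sizes and bias the overlap low
  if (is.null(bins)) bins <- max(10L, min(100L, floor(sqrt(length(samples)))))
  edges <- seq(min(samples), max(samples), length.out = bins + 1L)
  h <- bin_masses(samples, edges)
  gm <- diff(pnorm(edges, mean = mu, sd = sigma))
  gm <- gm / sum(gm)
  sum(pmin(h, gm))
}

check_n <- function(samples, min_n = 100L) {
  if (length(samples) < min_n)
    stop("need at least ", min_n, " samples, got ", length(samples))
}

#' Fit a harmonic bond from sampled lengths
#'
#' Equilibrium length = sample mean; force constant from Boltzmann/
#' equipartition inversion `k = kB*T / Var`.  Distributions failing the
#' normality screen (histogram overlap with the fitted Gaussian below
#' `normality_min`) are rejected with an error, mirroring an automated
#' pipeline that only accepts normally distributed populations.  Zero
#' variance, or a force constant above `k_max`, routes the term to the
#' constraint classification instead.
#'
#' @param samples Bond lengths in nm (>= 100 samples).
#' @param ctx A [thermo_context()].
#' @param normality_min Minimum Gaussian-overlap to accept the fit.
#' @param k_max Cap (kJ/mol/nm^2) above which the term is emitted as a
#'   constraint for numerical stability.
#' @return A `fitted_term` of kind `"bond"` (or `"constraint"`).
#' @examples
#' x <- rnorm(1e4, 0.48, 0.02)
#' fit_bond(x)$eq_value  # ~0.48 nm
#' @export
fit_bond <- function(samples, ctx = thermo_context(), normality_min = 0.8,
                     k_max = 5e4) {
  check_n(samples)
  m <- mean(samples); v <- var(samples)
  if (v < 1e-12)
    return(fitted_term("constraint", m, n = length(samples),
                       diagnostics = list(sd = 0, gaussian_overlap = 1)))
  ov <- gaussian_overlap(samples, m, sqrt(v))
  if (ov < normality_min)
    stop(structure(class = c("cgsugar_fit_error", "error", "condition"),
                   list(message = sprintf(
                     paste0("bond distribution fails the normality screen ",
                            "(Gaussian overlap %.2f < %.2f); fit a manual or ",
                            "tabulated potential instead"), ov, normality_min),
                     call = sys.call(-1))))
  k <- ctx$kT / v
  if (k > k_max) {
    message("force constant ", round(k), " kJ/mol/nm^2 exceeds cap ", k_max,
            "; emitting constraint")
    return(fitted_term("constraint", m, n = length(samples),
                       diagnostics = list(sd = sqrt(v), gaussian_overlap = ov)))
  }
  fitted_term("bond", m, k, n = length(samples),
              diagnostics = list(sd = sqrt(v), gaussian_overlap = ov,
                                 normal_ok = TRUE))
}

#' Fit a harmonic angle from sampled angles
#'
#' Mean and variance are taken in radian space for the inversion
#' `k = kB*T / Var`; the equilibrium value is reported in degrees.  A
#' multimodality diagnostic (Gaussian overlap) is recorded but, unlike
#' bonds, does not block emission: the single-Gaussian fit is returned with
#' `normal_ok = FALSE`.
#'
#' @param samples Angles in degrees (>= 100 samples).
#' @param ctx A [thermo_context()].
#' @param jacobian Apply the sin(theta) Jacobian reweighting before taking
#'   moments.  Off by default: the plain angle-space inversion is the
#'   simplest self-consistent convention for CG angles.
#' @param normality_min Threshold for the diagnostic flag.
#' @return A `fitted_term` of kind `"angle"` (force constant kJ/mol/rad^2).
#' @export
fit_angle <- function(samples, ctx = thermo_context(), jacobian = FALSE,
                      normality_min = 0.8) {
  check_n(samples)
  if (jacobian) {
    w <- 1 / sin(pmax(1e-6, samples * pi / 180))
    w <- w / sum(w)
    m <- sum(w * samples)
    v_deg <- sum(w * (samples - m)^2) / (1 - sum(w^2))
  } else {
    m <- mean(samples)
    v_deg <- var(samples)
  }
  if (v_deg < 1e-12)
    return(fitted_term("constraint", m, n = length(samples),
                       diagnostics = list(sd = 0, gaussian_overlap = 1)))
  ov <- gaussian_overlap(samples, m, sqrt(v_deg))
  v <- v_deg * (pi / 180)^2
  fitted_term("angle", m, ctx$kT / v, n = length(samples),
              diagnostics = list(sd = sqrt(v_deg), gaussian_overlap = ov,
                                 normal_ok = ov >= normality_min))
}

#' Fit a proper periodic dihedral from sampled torsions
#'
#' Uses the circular mean as the phase (so samples straddling the +/-180
#' wrap are handled without artefacts) and the variance of the wrapped
#' deviations, in radians, for `k = kB*T / Var`.  Emitted as a single
#' proper periodic term with multiplicity 1; a bimodality diagnostic is
#' recorded but does not block emission.
#'
#' @param samples Dihedral angles in degrees on (-180, 180] (>= 100).
#' @param ctx A [thermo_context()].
#' @param normality_min Threshold for the diagnostic flag.
#' @return A `fitted_term` of kind `"dihedral"` (force constant kJ/mol,
#'   multiplicity 1).
#' @export
fit_dihedral <- function(samples, ctx = thermo_context(), normality_min = 0.8) {
  check_n(samples)
  rad <- samples * pi / 180
  cm <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  dev <- wrap_deg(samples - cm)
  v_deg <- sum(dev^2) / (length(dev) - 1L)
  if (v_deg < 1e-12)
    return(fitted_term("constraint", cm, n = length(samples),
                       diagnostics = list(sd = 0, gaussian_overlap = 1)))
  ov <- gaussian_overlap(dev, 0, sqrt(v_deg))
  v <- v_deg * (pi / 180)^2
  fitted_term("dihedral", cm, ctx$kT / v, multiplicity = 1L,
              n = length(samples),
              diagnostics = list(sd = sqrt(v_deg), gaussian_overlap = ov,
                                 normal_ok = ov >= normality_min))
}

#' Fit every measured term of a disaccharide
#'
#' Convenience driver applying [fit_bond()] to the inter-monomer distance,
#' constraint-style fits to the six ring distances (mean length only), and
#' [fit_angle()] / [fit_dihedral()] to the remaining terms.
#'
#' @param terms A `term_samples` from [measure_terms()].
#' @param ctx A [thermo_context()].
#' @param ... Passed on to the individual `fit_*` functions.
#' @return Named list of `fitted_term` objects.
#' @export
fit_terms <- function(terms, ctx = thermo_context(), ...) {
  stopifnot(inherits(terms, "term_samples"))
  out <- list()
  for (lab in names(terms$samples)) {
    s <- terms$samples[[lab]]
    out[[lab]] <- switch(terms$kind[[lab]],
      constraint = fitted_term("constraint", mean(s), n = length(s),
                               diagnostics = list(sd = sd(s))),
      bond = fit_bond(s, ctx, ...),
      angle = fit_angle(s, ctx),
      dihedral = fit_dihedral(s, ctx))
  }
  out
}

#' Classify fitted distance terms into constraints and bonds
#'
#' The six ring-edge distance terms become constraints at their mean
#' lengths; the single inter-monomer distance term remains a harmonic bond.
#'
#' @param connectivity A `cg_connectivity`.
#' @param fitted Named list of `fitted_term`s covering at least the seven
#'   distance labels.
#' @return List with data frames `constraints` (label, i, j, length) and
#'   `bonds` (label, i, j, b0, kb).
#' @export
classify_terms <- function(connectivity, fitted) {
  d <- connectivity$distances
  miss <- setdiff(d$label, names(fitted))
  if (length(miss))
    stop("fitted terms missing for: ", paste(miss, collapse = ", "))
  is_ring <- d$kind == "constraint"
  constraints <- data.frame(
    label = d$label[is_ring], i = d$i[is_ring], j = d$j[is_ring],
    length = vapply(fitted[d$label[is_ring]], `[[`, 0, "eq_value"),
    stringsAsFactors = FALSE, row.names = NULL)
  bl <- d$label[!is_ring]
  bonds <- data.frame(
    label = bl, i = d$i[!is_ring], j = d$j[!is_ring],
    b0 = vapply(fitted[bl], `[[`, 0, "eq_value"),
    kb = vapply(fitted[bl], `[[`, 0, "force_constant"),
    stringsAsFactors = FALSE, row.names = NULL)
  # a flexible term whose fit collapsed to a constraint keeps zero spread
  if (anyNA(bonds$kb)) {
    constraints <- rbind(constraints,
                         data.frame(label = bonds$label[is.na(bonds$kb)],
                                    i = bonds$i[is.na(bonds$kb)],
                                    j = bonds$j[is.na(bonds$kb)],
                                    length = bonds$b0[is.na(bonds$kb)]))
    bonds <- bonds[!is.na(bonds$kb), , drop = FALSE]
  }
  list(constraints = constraints, bonds = bonds)
}

#' Assemble a CG topology from mapping, connectivity and fitted terms
#'
#' @param mapping A `cg_mapping`.
#' @param connectivity A `cg_connectivity`.
#' @param fitted Named list of `fitted_term`s for all twelve bonded labels.
#' @param name Molecule name (defaults to the mapping's).
#' @param bead_mass Mass for real (small) beads; Martini 3 convention 54.
#' @return An object of class `cg_topology` with `molecule`, `beads`
#'   (data frame: name, type, residue, charge, mass), `constraints`,
#'   `bonds`, `angles`, `dihedrals`, `virtual_sites`, `exclusions`.
#' @export
build_topology <- function(mapping, connectivity, fitted,
                           name = mapping$molecule, bead_mass = 54) {
  cls <- classify_terms(connectivity, fitted)
  beads <- data.frame(
    name = vapply(mapping$beads, `[[`, "", "name"),
    type = vapply(mapping$beads, `[[`, "", "bead_type"),
    residue = vapply(mapping$beads, `[[`, 1L, "residue"),
    charge = 0,
    mass = ifelse(vapply(mapping$beads, `[[`, TRUE, "is_virtual"), 0, bead_mass),
    stringsAsFactors = FALSE)
  an <- connectivity$angles
  angles <- data.frame(
    label = an$label, i = an$i, j = an$j, k = an$k,
    theta0 = vapply(fitted[an$label], `[[`, 0, "eq_value"),
    ktheta = vapply(fitted[an$label], `[[`, 0, "force_constant"),
    stringsAsFactors = FALSE, row.names = NULL)
  dh <- connectivity$dihedrals
  dihedrals <- data.frame(
    label = dh$label, i = dh$i, j = dh$j, k = dh$k, l = dh$l,
    phi0 = vapply(fitted[dh$label], `[[`, 0, "eq_value"),
    kphi = vapply(fitted[dh$label], `[[`, 0, "force_constant"),
    mult = vapply(fitted[dh$label], function(f)
      if (is.na(f$multiplicity)) 1L else f$multiplicity, 1L),
    stringsAsFactors = FALSE, row.names = NULL)
  vs <- mapping$virtual_sites
  structure(list(molecule = name, beads = beads,
                 constraints = cls$constraints, bonds = cls$bonds,
                 angles = angles, dihedrals = dihedrals,
                 virtual_sites = vs,
                 exclusions = vs),  # each VS excluded from its ring beads
            class = "cg_topology")
}
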