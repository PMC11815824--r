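# GROMACS topology / coordinate / run-protocol emission and parsing.

topo_for <- function(spec, n_frames = 500L, seed = 31L) {
  tr <- gen_pseudo_aa_traj(generator_spec(spec = spec, n_frames = n_frames,
                                          seed = seed))
  tm <- measure_terms(tr, tr$mapping, tr$connectivity, tr$graph)
  list(traj = tr, topo = build_topology(tr$mapping, tr$connectivity,
                                        fit_terms(tm)))
}

test_that("every enumerated topology satisfies the structural invariant", {
  # section counts (constraints, bonds, angles, dihedrals, virtual sites)
  # = (6, 1, 4, 1, 2); virtual sites massless
  for (s in all_specs()) {
    g <- build_atom_graph(s)
    m <- assign_beads(g)
    cn <- build_connectivity(m, g)
    # synthetic fitted terms: rigid rings, nominal flexible terms
    fitted <- list()
    for (k in seq_len(nrow(cn$distances))) {
      lab <- cn$distances$label[k]
      fitted[[lab]] <- if (cn$distances$kind[k] == "constraint")
        cgsugar:::fitted_term("constraint", 0.35, n = 1000L)
      else cgsugar:::fitted_term("bond", 0.45, 5000, n = 1000L)
    }
    for (lab in cn$angles$label)
      fitted[[lab]] <- cgsugar:::fitted_term("angle", 110, 300, n = 1000L)
    fitted[["dihedral0"]] <- cgsugar:::fitted_term("dihedral", -60, 15,
                                                   multiplicity = 1L,
                                                   n = 1000L)
    topo <- build_topology(m, cn, fitted)
    expect_identical(nrow(topo$constraints), 6L)
    expect_identical(nrow(topo$bonds), 1L)
    expect_identical(nrow(topo$angles), 4L)
    expect_identical(nrow(topo$dihedrals), 1L)
    expect_length(topo$virtual_sites, 2L)
    expect_identical(nrow(topo$beads), 8L)
    expect_equal(topo$beads$mass[7:8], c(0, 0))
    expect_true(all(topo$beads$charge == 0))
  }
})

test_that("itp files round-trip through write and read", {
  tt <- topo_for(trehalose_spec())
  f <- withr::local_tempfile(fileext = ".itp")
  write_itp(tt$topo, f)
  t2 <- read_itp(f)
  expect_identical(t2$molecule, "1GA_0GA")
  expect_identical(t2$beads$name, tt$topo$beads$name)
  expect_identical(t2$beads$type, tt$topo$beads$type)
  expect_equal(t2$beads$mass, tt$topo$beads$mass)
  for (sec in c("constraints", "bonds", "angles", "dihedrals")) {
    a <- tt$topo[[sec]]; b <- t2[[sec]]
    expect_identical(b$label, a$label)
    expect_identical(b$i, a$i); expect_identical(b$j, a$j)
    num <- names(a)[vapply(a, is.numeric, TRUE)]
    for (cl in num) expect_equal(b[[cl]], a[[cl]], tolerance = 1e-4)
  }
  expect_identical(t2$virtual_sites, tt$topo$virtual_sites)
  expect_identical(t2$exclusions, tt$topo$exclusions)
})

test_that("malformed itp sections report the line number", {
  f <- withr::local_tempfile(fileext = ".itp")
  writeLines(c("[ moleculetype ]", "MOL 1", "[ bonds ]", "1 2 1"), f)
  expect_error(read_itp(f), "line 4")
})

test_that("gro files round-trip to three decimals", {
  tt <- topo_for(trehalose_spec(), n_frames = 100L)
  beads <- project_frame(tt$traj$coords[, , 1], tt$traj$mapping)
  f <- withr::local_tempfile(fileext = ".gro")
  res <- vapply(tt$traj$mapping$beads, `[[`, 1L, "residue")
  write_gro(beads, tt$traj$box, f, res_ids = res, res_names = "1GA",
            time = 0)
  g <- read_gro(f)
  expect_identical(nrow(g$coords), 8L)
  expect_equal(g$coords, round(beads, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(g$box, tt$traj$box)
  expect_identical(rownames(g$coords), rownames(beads))
  # second round trip is exact
  write_gro(g$coords, g$box, f)
  expect_equal(read_gro(f)$coords, g$coords, ignore_attr = TRUE)
})

test_that("overlong names are truncated with a warning", {
  coords <- matrix(0, 1, 3, dimnames = list("VERYLONGNAME", NULL))
  f <- withr::local_tempfile(fileext = ".gro")
  expect_warning(write_gro(coords, c(5, 5, 5), f), "truncat")
  expect_identical(rownames(read_gro(f)$coords), "VERYL")
})

test_that("multi-frame gro trajectories read back frame by frame", {
  tr <- small_traj(50L)
  prefix <- withr::local_tempfile()
  write_fixture_files(tr, prefix)
  back <- read_gro_traj(paste0(prefix, ".gro"), id_style = "residue")
  expect_identical(dim(back$coords), dim(tr$coords))
  expect_identical(dimnames(back$coords)[[1]], dimnames(tr$coords)[[1]])
  expect_equal(back$coords, tr$coords, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(back$times, tr$times)
  # mapped frame written then read projects to identical positions (3 dp)
  p1 <- project_frame(tr$coords[, , 3], tr$mapping)
  p2 <- project_frame(back$coords[, , 3], tr$mapping)
  expect_equal(p2, p1, tolerance = 2e-3)
})

test_that("an emitted itp parses under an independent topology parser", {
  tt <- topo_for(maltose_spec())
  itp <- withr::local_tempfile(fileext = ".itp")
  gro <- withr::local_tempfile(fileext = ".gro")
  write_itp(tt$topo, itp)
  beads <- project_frame(tt$traj$coords[, , 1], tt$traj$mapping)
  res <- vapply(tt$traj$mapping$beads, `[[`, 1L, "residue")
  write_gro(beads, tt$traj$box, gro, res_ids = res, res_names = "4GB")
  py <- paste(
    "import warnings, MDAnalysis as mda",
    "warnings.filterwarnings('ignore', category=DeprecationWarning)",
    "warnings.filterwarnings('ignore', category=UserWarning)",
    sprintf("u = mda.Universe(%s, %s, topology_format='ITP', format='GRO')",
            shQuote(itp), shQuote(gro)),
    "print(len(u.atoms), len(u.bonds), len(u.angles), len(u.dihedrals))",
    sep = "; ")
  out <- suppressWarnings(system2("python", c("-c", shQuote(py)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0L)
  counts <- strsplit(tail(out, 1), " ")[[1]]
  expect_identical(counts, c("8", "7", "4", "1"))  # 6 constraints + 1 bond
})

test_that("run protocols encode the reference simulation settings", {
  prod <- read_run_protocol(write_run_protocol("simple", "production"))
  expect_identical(unname(prod["dt"]), "0.02")            # 20 fs
  expect_identical(unname(prod["nsteps"]), "50000000")    # 1 us
  expect_identical(unname(prod["coulombtype"]), "Reaction-Field")
  expect_identical(unname(prod["rcoulomb"]), "1.1")
  expect_identical(unname(prod["epsilon_r"]), "15")
  expect_identical(unname(prod["ref-t"]), "300")
  expect_identical(unname(prod["ref-p"]), "1.0")
  expect_identical(unname(prod["constraint-algorithm"]), "lincs")

  minim <- read_run_protocol(write_run_protocol("simple", "minimization"))
  expect_identical(unname(minim["integrator"]), "steep")
  expect_identical(unname(minim["nsteps"]), "500")

  eq <- read_run_protocol(write_run_protocol("simple", "equilibration"))
  expect_identical(unname(eq["nsteps"]), "5000000")       # 100 ns at 20 fs
  expect_identical(unname(eq["pcoupl"]), "no")            # NVT

  s1 <- read_run_protocol(write_run_protocol("soft", "stage1"))
  expect_identical(unname(s1["dt"]), "0.01")              # 10 fs
  expect_identical(unname(s1["nsteps"]), "2500000")       # 25 ns
  expect_identical(unname(s1["define"]), "-DFLEXIBLE")
  s3 <- read_run_protocol(write_run_protocol("soft", "stage3"))
  expect_identical(unname(s3["dt"]), "0.02")              # 50 ns at 20 fs
  expect_identical(unname(s3["constraint-algorithm"]), "lincs")
  expect_error(write_run_protocol("simple", "stage1"))
})
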