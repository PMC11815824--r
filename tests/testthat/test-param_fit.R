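# Boltzmann inversion of bonded distributions.

test_that("thermal energy at 300 K is kB * T", {
  ctx <- thermo_context()
  expect_equal(ctx$kT, 0.0083145 * 300, tolerance = 1e-12)
  expect_error(thermo_context(-10), "positive")
})

test_that("harmonic bond fitting recovers mean and equipartition constant", {
  set.seed(42)
  x <- rnorm(1e5, 0.48, 0.02)
  f <- fit_bond(x)
  expect_identical(f$kind, "bond")
  expect_equal(round(f$eq_value, 2), 0.48)
  expect_equal(round(f$diagnostics$sd, 2), 0.02)
  # k = kB T / Var; at sd exactly 0.02 this is 2.4944/0.0004 ~ 6236
  expect_equal(f$force_constant, thermo_context()$kT / var(x), tolerance = 1e-9)
  expect_equal(f$force_constant, 6236, tolerance = 0.02)
})

test_that("resampling from the emitted potential refits the same parameters", {
  # equipartition oracle: draw from the Boltzmann distribution of the
  # emitted harmonic potential and refit
  set.seed(7)
  ctx <- thermo_context()
  f <- fit_bond(rnorm(1e5, 0.48, 0.02), ctx)
  resampled <- rnorm(1e5, f$eq_value, sqrt(ctx$kT / f$force_constant))
  f2 <- fit_bond(resampled, ctx)
  expect_equal(f2$eq_value, f$eq_value, tolerance = 0.01)
  expect_equal(f2$force_constant, f$force_constant, tolerance = 0.05)
  # same property for angles (radian-space inversion)
  fa <- fit_angle(rnorm(1e5, 120, 5), ctx)
  sd_deg <- sqrt(ctx$kT / fa$force_constant) * 180 / pi
  fa2 <- fit_angle(rnorm(1e5, fa$eq_value, sd_deg), ctx)
  expect_equal(fa2$eq_value, fa$eq_value, tolerance = 0.01)
  expect_equal(fa2$force_constant, fa$force_constant, tolerance = 0.05)
})

test_that("constant samples route to the constraint classification", {
  f <- fit_bond(rep(0.32, 200))
  expect_identical(f$kind, "constraint")
  expect_equal(f$eq_value, 0.32)
  expect_true(is.na(f$force_constant))
})

test_that("an excessive force constant is capped into a constraint", {
  set.seed(1)
  expect_message(f <- fit_bond(rnorm(1e4, 0.3, 1e-4)), "cap")
  expect_identical(f$kind, "constraint")
})

test_that("bimodal bond distributions fail the normality screen", {
  set.seed(3)
  bimodal <- c(rnorm(5e3, 0.30, 0.01), rnorm(5e3, 0.50, 0.01))
  err <- tryCatch(fit_bond(bimodal), error = identity)
  expect_s3_class(err, "cgsugar_fit_error")
  expect_match(conditionMessage(err), "normality")
  # angles only flag: the single-Gaussian fit is still returned
  bimodal_a <- c(rnorm(5e3, 80, 2), rnorm(5e3, 140, 2))
  fa <- fit_angle(bimodal_a)
  expect_false(fa$diagnostics$normal_ok)
  expect_identical(fa$kind, "angle")
})

test_that("angle fitting recovers the mean in degrees", {
  set.seed(5)
  fa <- fit_angle(rnorm(1e5, 120, 5))
  expect_equal(round(fa$eq_value), 120)
  # inversion done in radians
  expect_equal(fa$force_constant,
               thermo_context()$kT / (5 * pi / 180)^2, tolerance = 0.05)
})

test_that("dihedral fitting handles the +/-180 wrap via the circular mean", {
  set.seed(6)
  raw <- rnorm(1e4, 180, 8)          # unwrapped samples around 180
  wrapped <- cgsugar:::wrap_deg(raw) # straddles the boundary
  expect_true(any(wrapped < -150) && any(wrapped > 150))
  f <- fit_dihedral(wrapped)
  # oracle: mean of the unwrapped samples, mapped back to (-180, 180]
  expect_equal(abs(f$eq_value), abs(cgsugar:::wrap_deg(mean(raw))),
               tolerance = 0.01)
  expect_gt(abs(f$eq_value), 150)  # no artefact near 0
  expect_identical(f$multiplicity, 1L)
  # spread measured on wrapped deviations, not raw values
  expect_equal(f$diagnostics$sd, 8, tolerance = 0.05)
})

test_that("fits are invariant to sample order and scale as units demand", {
  set.seed(8)
  x <- rnorm(1e4, 0.48, 0.02)
  f1 <- fit_bond(x); f2 <- fit_bond(sample(x))
  expect_equal(f1$eq_value, f2$eq_value)
  expect_equal(f1$force_constant, f2$force_constant)
  # nm -> Angstrom -> nm rescaling changes k by exactly 100x
  fA <- fit_bond(x * 10)
  expect_equal(fA$force_constant * 100, f1$force_constant, tolerance = 1e-9)
})

test_that("fewer than 100 samples are refused", {
  expect_error(fit_bond(rnorm(50, 0.4, 0.01)), "at least 100")
  expect_error(fit_angle(rnorm(10, 120, 5)), "at least 100")
  expect_error(fit_dihedral(numeric(0)), "at least 100")
})

test_that("classification yields 6 ring constraints plus the harmonic bond", {
  tr <- small_traj(2000L)
  tm <- measure_terms(tr, tr$mapping, tr$connectivity, tr$graph)
  fitted <- fit_terms(tm)
  cls <- classify_terms(tr$connectivity, fitted)
  expect_identical(nrow(cls$constraints), 6L)
  expect_identical(nrow(cls$bonds), 1L)
  expect_identical(cls$bonds$label, "bond3")
  # constraint lengths equal the generator's rigid ring edges
  for (k in seq_len(6)) {
    lab <- cls$constraints$label[k]
    expect_equal(cls$constraints$length[k], tr$manifest$targets[[lab]][1],
                 tolerance = 1e-3)
  }
  # trehalose symmetry: matching ring edges agree across residues to the
  # precision of the prescribed edge lengths
  lens <- setNames(cls$constraints$length, cls$constraints$label)
  expect_equal(unname(lens["bond1"]), unname(lens["bond5"]), tolerance = 1e-6)
})

test_that("generator -> projection -> fit round trip recovers all targets", {
  # core recovery property: means within 1%, force constants within 5%
  gs <- generator_spec(n_frames = 20000L, seed = 23L)
  tr <- gen_pseudo_aa_traj(gs)
  tm <- measure_terms(tr, tr$mapping, tr$connectivity, tr$graph)
  fitted <- fit_terms(tm)
  ctx <- thermo_context()
  for (lab in names(tr$manifest$targets)) {
    tgt <- tr$manifest$targets[[lab]]
    expect_equal(fitted[[lab]]$eq_value, tgt[1], tolerance = 0.01,
                 label = paste(lab, "eq"))
    if (!is.na(tgt[2]) && tgt[2] > 0) {
      k_true <- if (grepl("bond", lab)) ctx$kT / tgt[2]^2
                else ctx$kT / (tgt[2] * pi / 180)^2
      expect_equal(fitted[[lab]]$force_constant, k_true, tolerance = 0.05,
                   label = paste(lab, "k"))
    }
  }
  # implied junction angles recover their target means too
  for (lab in c("angle1", "angle3"))
    expect_equal(fitted[[lab]]$eq_value, tr$manifest$implied_means[[lab]],
                 tolerance = 0.01, label = lab)
})
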