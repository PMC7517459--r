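test_that("a homogeneous sweep makes configurations indistinguishable", {
  spec <- sweep_spec(c1h_grid = seq(1, 101, by = 20),
                     cp_source = "homogeneous")
  sw <- run_sweep(spec, fx$membrane, fx$environment)
  a_cols <- grep("_A(_|$)", names(sw), value = TRUE)
  a_cols <- setdiff(a_cols, c("rayleigh_A", "regime_A", "delta_A"))
  for (a in a_cols) {
    b <- sub("_A", "_B", a)
    expect_identical(sw[[a]], sw[[b]])
  }
  expect_true(all(abs(sw$xi_11) < 1e-12))
})

test_that("a 100-point profile sweep completes with A/B agreement at the crossing", {
  grid <- seq(1, 100, length.out = 100)
  spec <- sweep_spec(c1h_grid = grid)
  sw <- run_sweep(spec, fx$membrane, fx$environment)
  expect_identical(nrow(sw), 100L)
  expect_identical(attr(sw, "n_errors"), 0L)
  i <- which.min(abs(sw$c1bar - 9.24))
  expect_equal(sw$R11_A_strict[i], sw$R11_B_strict[i], tolerance = 0.05)
  expect_equal(sw$r12_A[i], sw$r12_B[i], tolerance = 0.05)
  expect_equal(sw$zeta1_A[i], sw$zeta1_B[i], tolerance = 0.05)
  # regime flips across the density-matching point, oppositely per config
  expect_identical(sw$regime_A[1], "unstable_convective")
  expect_identical(sw$regime_B[1], "stable_nonconvective")
  expect_identical(sw$regime_A[100], "stable_nonconvective")
  expect_identical(sw$regime_B[100], "unstable_convective")
})

test_that("matrix-variant choice affects only the rescaled columns", {
  grid <- seq(1, 101, by = 25)
  s_strict <- run_sweep(sweep_spec(c1h_grid = grid,
                                   variant = "strict_inverse"),
                        fx$membrane, fx$environment)
  s_printed <- run_sweep(sweep_spec(c1h_grid = grid,
                                    variant = "as_printed"),
                         fx$membrane, fx$environment)
  # shared entries identical across variants
  for (lbl in c("11", "12", "13", "22", "23", "32", "33"))
    expect_identical(s_strict[[paste0("R", lbl, "_A_strict")]],
                     s_printed[[paste0("R", lbl, "_A_printed")]])
  # rescaled entries differ by the mean concentrations
  expect_equal(s_printed$R21_A_printed / s_printed$c1bar,
               s_strict$R21_A_strict)
  expect_equal(s_printed$R31_A_printed / s_printed$c2bar,
               s_strict$R31_A_strict)
  # xi and coupling columns are scale-invariant, hence variant-independent
  expect_equal(s_strict$xi_21, s_printed$xi_21)
  expect_equal(s_strict$r12_A, s_printed$r12_A)
})

test_that("sweep CSV output is byte-identical across repeated runs", {
  spec <- sweep_spec(c1h_grid = seq(1, 41, by = 10))
  sw <- run_sweep(spec, fx$membrane, fx$environment)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_sweep_csv(sw, f1)
  write_sweep_csv(run_sweep(spec, fx$membrane, fx$environment), f2)
  expect_identical(readLines(f1), readLines(f2))
  header <- readLines(f1, n = 2L)
  expect_match(header[1], "^# ")
  expect_match(header[2], "^C1h,c1bar,")
})

test_that("configuration files round-trip every documented key", {
  path <- tempfile(fileext = ".yml")
  write_kkp_config(fx$membrane, fx$environment, fx$baths, path)
  back <- read_kkp_config(path)
  expect_equal(back$membrane, fx$membrane)
  expect_equal(back$baths, fx$baths)
  expect_equal(back$environment$RT, fx$environment$RT)
  expect_equal(back$environment$D, fx$environment$D)
  expect_error(read_kkp_config(tempfile()), class = "kkp_config_error")
  # the shipped reference config matches the in-code parameter set
  shipped <- system.file("extdata", "nephrophan.yml", package = "kkpeusner")
  ref <- read_kkp_config(shipped)
  expect_equal(ref$membrane, fx$membrane)
  expect_equal(ref$baths, fx$baths)
})

test_that("the command line interface wires the subcommands together", {
  cfg <- tempfile(fileext = ".yml")
  expect_identical(suppressMessages(kkp_cli(c("fixture", "--out", cfg))), 0L)
  expect_true(file.exists(cfg))

  out <- tempfile(fileext = ".json")
  code <- suppressMessages(kkp_cli(c("compute", "--config", cfg,
                                     "--out", out, "--seed", "7")))
  expect_identical(code, 0L)
  res <- jsonlite::read_json(out)
  # fixture point: c1bar = 9.24, c2bar = 37.71
  det_ref <- rform_matrix(fx$membrane, cp_homogeneous(),
                          fx$baths$c1bar, fx$baths$c2bar)$det
  expect_equal(res$resistance$det, det_ref, tolerance = 1e-10)
  expect_length(res$resistance$entries, 9L)

  csv <- tempfile(fileext = ".csv")
  code <- suppressMessages(kkp_cli(c("sweep", "--config", cfg,
                                     "--grid", "1,41,10", "--out", csv)))
  expect_identical(code, 0L)
  expect_identical(length(readLines(csv)), 7L)  # comment + header + 5 rows

  cls <- tempfile(fileext = ".json")
  code <- suppressMessages(kkp_cli(c("classify", "--config", cfg,
                                     "--out", cls)))
  expect_identical(code, 0L)
  cj <- jsonlite::read_json(cls)
  expect_length(cj$xi_rows, 10L)  # nine entries plus the determinant row

  # zero driving forces report zero fluxes
  cfg0 <- tempfile(fileext = ".yml")
  b0 <- bath_state(1, 1, 1, 1, dP = 0)
  write_kkp_config(fx$membrane, fx$environment, b0, cfg0)
  out0 <- tempfile(fileext = ".json")
  expect_identical(suppressMessages(
    kkp_cli(c("compute", "--config", cfg0, "--out", out0))), 0L)
  fl <- jsonlite::read_json(out0)$fluxes
  expect_true(all(unlist(fl) == 0))

  # error paths: bad config -> 2, unknown subcommand -> 1
  expect_identical(suppressMessages(
    kkp_cli(c("compute", "--config", tempfile()))), 2L)
  bad <- tempfile(fileext = ".yml")
  yaml::write_yaml(list(membrane = list(Lp = 1e-12)), bad)
  expect_identical(suppressMessages(
    kkp_cli(c("compute", "--config", bad))), 2L)
  expect_identical(suppressMessages(kkp_cli("frobnicate")), 1L)
  expect_identical(suppressMessages(kkp_cli(c("sweep", "--config", cfg))),
                   2L)
})
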