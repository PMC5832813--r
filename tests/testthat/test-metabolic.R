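test_that("size-to-mass conversion applies the power law and propagates CIs", {
  m <- size_measurement("sp", "shell_length_mm", 10, 0)
  rule <- mass_conversion_rule("sp", p = 1, q = 1)
  out <- convert_size_to_mass(m, rule)
  expect_equal(out$value, 10)
  expect_equal(out$ci95, 0)

  # q = 2: ci = |q * p * size^(q-1)| * ci_size = 2 * 16 * 2 = 64
  m2 <- size_measurement("sp", "shell_length_mm", 16, 2)
  out2 <- convert_size_to_mass(m2, mass_conversion_rule("sp", 1, 2))
  expect_equal(out2$value, 256)
  expect_equal(out2$ci95, 64, tolerance = 1e-6)

  # lugworm rule calibrated to the packaged dataset's (wet weight, AFDW) pairs
  rules <- load_config()$conversion_rules
  am <- size_measurement("A. marina", "wet_weight_mg", 160, 8)
  expect_equal(convert_size_to_mass(am, rules[["A. marina"]])$value,
    16.34,
    tolerance = 0.005
  )

  expect_error(
    convert_size_to_mass(m, mass_conversion_rule("other", 1, 1)),
    "species"
  )
  expect_error(size_measurement("sp", "shell_length_mm", -1), "positive")
  expect_error(mass_conversion_rule("sp", p = 0, q = 1), "positive")
})

test_that("allometric metabolic rate evaluates a * M^b and is homogeneous", {
  expect_equal(metabolic_rate(qci(1), metabolic_model_spec(a = 1, b = 0.75))$value, 1)
  expect_equal(
    metabolic_rate(qci(100), metabolic_model_spec(a = 0.01, b = 0.75))$value,
    0.01 * 100^0.75
  )
  # scaling M by s scales I by s^b
  spec <- metabolic_model_spec(a = 0.011, b = 0.75)
  for (s in c(2, 10, 0.5)) {
    expect_equal(
      metabolic_rate(qci(s * 30), spec)$value,
      s^0.75 * metabolic_rate(qci(30), spec)$value
    )
  }
  expect_no_error(metabolic_rate(qci(1e-9), spec))
  expect_error(metabolic_rate(qci(0.5, 0), metabolic_model_spec(a = -1)), "positive")
})

test_that("packaged lugworm rates realise a ~0.85 size-scaling exponent", {
  am <- flume_tab[flume_tab$species == "A. marina", ]
  i_small <- unique(am$I_mW[am$mass_mg_afdw == min(am$mass_mg_afdw)])
  i_mid <- unique(am$I_mW[round(am$mass_mg_afdw, 2) == 169.04])
  b_realised <- log(i_mid / i_small) / log(169.04 / 16.34)
  expect_equal(b_realised, 0.85, tolerance = 0.005)
})

test_that("ln-linear empirical form evaluates coefficient tables in J/day and converts to mW", {
  # intercept-only table: exp(log(86400/1000)) J/day is exactly 1 mW
  spec1 <- metabolic_model_spec("ln_linear_empirical",
    coefficients = c(intercept = log(86.4))
  )
  expect_equal(metabolic_rate(qci(5), spec1)$value, 1, tolerance = 1e-10)

  # ln-mass slope of 1 makes the rate proportional to mass
  spec2 <- metabolic_model_spec("ln_linear_empirical",
    coefficients = c(intercept = 0, ln_mass = 1)
  )
  expect_equal(metabolic_rate(qci(20), spec2)$value, 20 * 1000 / 86400)

  # inverse-temperature term reproduces Boltzmann-Arrhenius scaling
  E <- 0.65
  spec3 <- metabolic_model_spec("ln_linear_empirical",
    coefficients = c(intercept = 0, inv_temp = -E / boltzmann_k)
  )
  r18 <- metabolic_rate(qci(1), spec3, temperature_c = 18)$value
  r21 <- metabolic_rate(qci(1), spec3, temperature_c = 21)$value
  expect_equal(r21 / r18, arrhenius_factor(18, 21, E), tolerance = 1e-10)

  # unknown covariate must be supplied as a trait
  spec4 <- metabolic_model_spec("ln_linear_empirical",
    coefficients = c(intercept = 0, is_sessile = 0.2)
  )
  expect_error(metabolic_rate(qci(1), spec4), "is_sessile")
  expect_equal(
    metabolic_rate(qci(1), spec4, traits = list(is_sessile = 1))$value,
    exp(0.2) * 1000 / 86400
  )
  expect_error(metabolic_model_spec("ln_linear_empirical"), "intercept")
})

test_that("Arrhenius factor has the expected fixed points and monotonicity", {
  expect_identical(arrhenius_factor(18, 18, 0.65), 1)
  expect_equal(arrhenius_factor(18, 7.2, 0.65), 0.3686, tolerance = 1e-3)
  expect_equal(arrhenius_factor(18, 21, 0.65), 1.3024, tolerance = 1e-3)

  temps <- seq(-2, 40, by = 3)
  f <- arrhenius_factor(18, temps, 0.65)
  expect_true(all(diff(f) > 0)) # strictly increasing in T for E > 0
  expect_true(all(arrhenius_factor(18, temps, 0) == 1)) # constant when E = 0
  expect_error(arrhenius_factor(18, -300, 0.65), "absolute zero")
})

test_that("Arrhenius factors compose along temperature chains", {
  for (E in c(0.2, 0.65, 1.1)) {
    t1 <- 18
    t2 <- 7.2
    t3 <- 25
    expect_equal(
      arrhenius_factor(t1, t2, E) * arrhenius_factor(t2, t3, E),
      arrhenius_factor(t1, t3, E),
      tolerance = 1e-12
    )
  }
})
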