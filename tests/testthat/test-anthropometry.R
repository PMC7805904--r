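test_that("segment masses conserve total body mass and scale linearly", {
  segs <- segments_a()
  masses <- vapply(segs, `[[`, 0, "mass")
  expect_equal(sum(masses), 54.1, tolerance = 1e-9)

  # fractions over the whole body sum to one by construction
  tab <- bsp_table("female")
  expect_equal(sum(tab$mass_frac * ifelse(tab$paired, 2, 1)), 1,
               tolerance = 1e-12)
  tab_m <- bsp_table("male")
  expect_equal(sum(tab_m$mass_frac * ifelse(tab_m$paired, 2, 1)), 1,
               tolerance = 1e-12)

  # head mass pinned against the shipped regression table: the raw female
  # head fraction 0.0668 renormalized by the raw whole-body sum 0.9999
  expect_equal(segs$head$mass, 54.1 * 0.0668 / 0.9999, tolerance = 1e-9)

  # mass scaling: total_mass * k scales every segment mass by k
  segs2 <- de_leva_parameters(subject_anthropometry("female", 2 * 54.1, 1.68))
  expect_equal(vapply(segs2, `[[`, 0, "mass"), 2 * masses,
               tolerance = 1e-12, ignore_attr = TRUE)

  # height scaling: lengths scale with k, inertia with k^2 at fixed mass
  k <- 1.1
  segs3 <- de_leva_parameters(subject_anthropometry("female", 54.1, 1.68 * k))
  expect_equal(vapply(segs3, `[[`, 0, "length"),
               k * vapply(segs, `[[`, 0, "length"),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(segs3$thigh_l$inertia, k^2 * segs$thigh_l$inertia,
               tolerance = 1e-12)
  expect_equal(segs3$thigh_l$com_offset, k * segs$thigh_l$com_offset,
               tolerance = 1e-12)
})

test_that("anthropometry inputs are validated", {
  expect_error(subject_anthropometry("female", 54.1, 1.68, leg_length = 1.7),
               "leg_length")
  expect_error(subject_anthropometry("female", -1, 1.68))
  expect_error(subject_anthropometry("male", 80, 1.8,
                                     prosthesis = list(side = "right",
                                                       mass_ratio = 0)),
               "mass_ratio")
  expect_error(subject_anthropometry("male", 80, 1.8,
                                     prosthesis = list(side = "up",
                                                       mass_ratio = 0.5)),
               "side")
})

test_that("prosthesis scaling hits the requested leg mass ratio", {
  leg_mass <- function(segs, sfx)
    sum(vapply(segs[paste0(c("thigh", "shank", "foot"), sfx)], `[[`, 0,
               "mass"))
  anthroC <- subject_anthropometry("male", 92.0, 1.79, 0.825)
  segs0 <- de_leva_parameters(anthroC)
  M <- leg_mass(segs0, "_r")

  segs <- apply_prosthesis(segs0, list(side = "right", mass_ratio = 0.35))
  expect_equal(leg_mass(segs, "_r") / leg_mass(segs, "_l"), 0.35,
               tolerance = 1e-12)
  # contralateral side untouched
  expect_identical(segs$thigh_l, segs0$thigh_l)
  # whole-body mass drops by the removed limb mass (direct summation oracle)
  expect_equal(sum(vapply(segs, `[[`, 0, "mass")), 92.0 - 0.65 * M,
               tolerance = 1e-9)
  # inertia scales with the same factor as mass
  expect_equal(segs$shank_r$inertia,
               0.35 * segs0$shank_r$inertia, tolerance = 1e-12)

  # identity case
  segs1 <- apply_prosthesis(segs0, list(side = "right", mass_ratio = 1))
  expect_equal(vapply(segs1, `[[`, 0, "mass"),
               vapply(segs0, `[[`, 0, "mass"), tolerance = 1e-12)

  expect_error(apply_prosthesis(segs0, list(side = "right",
                                            mass_ratio = -0.2)), "positive")
})

test_that("per-segment prosthesis overrides are honoured exactly", {
  anthro <- subject_anthropometry("male", 92.0, 1.79)
  segs0 <- de_leva_parameters(anthro)
  ov <- list(shank = list(mass = 1.2, inertia = diag(c(0.01, 0.01, 0.001))))
  segs <- apply_prosthesis(segs0, list(side = "right", mass_ratio = 0.35,
                                       overrides = ov))
  expect_equal(segs$shank_r$mass, 1.2)
  expect_equal(segs$shank_r$inertia, ov$shank$inertia)
  leg_mass <- function(s, sfx)
    sum(vapply(s[paste0(c("thigh", "shank", "foot"), sfx)], `[[`, 0, "mass"))
  expect_equal(leg_mass(segs, "_r") / leg_mass(segs, "_l"), 0.35,
               tolerance = 1e-12)
})

test_that("subject YAML round-trips through read_subject", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(sex = "male", mass_kg = 92, height_m = 1.79,
                        leg_length_m = 0.825,
                        prosthesis = list(side = "right", mass_ratio = 0.35)),
                   path)
  a <- read_subject(path)
  expect_s3_class(a, "subject_anthro")
  expect_equal(a$total_mass, 92)
  expect_equal(a$prosthesis$mass_ratio, 0.35)
})
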