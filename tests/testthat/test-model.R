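test_that("full and reduced models carry the expected degrees of freedom", {
  mf <- full_model()
  mr <- reduced_model()
  expect_equal(mf$n_dof, 43)
  expect_equal(mf$n_act, 37)
  expect_equal(mr$n_dof, 34)
  expect_equal(mr$n_act, 28)
  # joint accounting oracle: 6 base + 11 ball joints + 4 hinge joints
  expect_equal(6 + 11 * 3 + 4 * 1, mf$n_dof)
  expect_equal(mf$n_dof - (3 + 2 * 3), mr$n_dof)  # lock xiphoid + wrists
})

test_that("model reduction conserves mass and composites inertia correctly", {
  mf <- full_model()
  mr <- reduced_model()
  expect_equal(mr$total_mass, mf$total_mass, tolerance = 1e-12)

  # two-body composite oracle: COM of the merged trunk body equals the
  # mass-weighted COM of mid and upper trunk in the mid-trunk frame
  segs <- segments_a()
  host <- mr$seg_body[["mid_trunk"]]
  dec <- gaitbench:::mcI_decompose(mr$I[[host]])
  up_off <- c(0, 0, segs$mid_trunk$length)  # xiphoid in the mid-trunk frame
  com_expect <- (segs$mid_trunk$mass * segs$mid_trunk$com_offset +
                   segs$upper_trunk$mass * (up_off + segs$upper_trunk$com_offset)) /
    (segs$mid_trunk$mass + segs$upper_trunk$mass)
  expect_equal(dec$m, segs$mid_trunk$mass + segs$upper_trunk$mass,
               tolerance = 1e-12)
  expect_equal(dec$c, com_expect, tolerance = 1e-12)
})

test_that("foot contact points span a triangle", {
  for (m in list(full_model(), planar_model())) {
    for (s in c("left", "right")) {
      cp <- m$contacts[m$contacts$side == s, ]
      v1 <- c(cp$x[2] - cp$x[1], cp$y[2] - cp$y[1], cp$z[2] - cp$z[1])
      v2 <- c(cp$x[3] - cp$x[1], cp$y[3] - cp$y[1], cp$z[3] - cp$z[1])
      expect_gt(sqrt(sum(gaitbench:::cross3(v1, v2)^2)), 1e-6)
    }
  }
})

test_that("missing segments abort model construction", {
  segs <- segments_a()
  broken <- segs[names(segs) != "head"]
  class(broken) <- "segment_params"
  attr(broken, "anthro") <- attr(segs, "anthro")
  expect_error(build_full_model(broken), "head")
})

test_that("model YAML export rebuilds an identical model", {
  m <- reduced_model()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_yaml(m, path)
  m2 <- read_model_yaml(path)
  expect_equal(m2$n_dof, m$n_dof)
  expect_equal(m2$total_mass, m$total_mass, tolerance = 1e-12)
  set.seed(11)
  q <- standing_pose(m) + rnorm(m$n_dof, 0, 0.2)
  expect_equal(gaitbench:::crba(m2, q), gaitbench:::crba(m, q),
               tolerance = 1e-12)
  expect_equal(m2$contacts$x, m$contacts$x, tolerance = 1e-12)
})
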