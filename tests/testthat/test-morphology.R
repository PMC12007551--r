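test_that("ball-and-stick geometry follows the node/internode/terminal partition", {
  ## axon 100 um, d = 1: node(1) + internode(29) + terminal(70)
  m <- generate_ball_and_stick(100, 1, soma_diameter = 10)
  kinds <- vapply(m$sections, function(s) s$kind, character(1))
  lens <- vapply(m$sections, section_length_for_test, numeric(1))
  expect_equal(kinds, c("soma", "node_of_ranvier", "myelin_internode",
                        "axon_terminal"))
  expect_equal(lens[-1], c(1, 29, 70), tolerance = 1e-12)

  ## equivalent full-cell stand-in: l = 760, d = 15 spans z in [0, -760]
  bs <- generate_ball_and_stick(760, 15, soma_diameter = 20)
  pts <- do.call(rbind, lapply(bs$sections, function(s) s$points))
  expect_equal(range(pts[, 3]), c(-760, 0))
  total <- sum(vapply(bs$sections[-1], section_length_for_test, numeric(1)))
  expect_equal(total, 760, tolerance = 1e-9)

  expect_tms_error(generate_ball_and_stick(0, 1), "tms_geometry_error")
  expect_tms_error(generate_ball_and_stick(100, -1), "tms_config_error")
})

test_that("myelination partitions a long axon into alternating internodes and nodes", {
  ## 1010 um, d = 1: internode(100)/node(1) alternation, boundary remainder,
  ## 70 um terminal; arc length conserved exactly
  m <- straight_cable(1010, 1, kind = "axon_unmyelinated")
  my <- myelinate_axon(m, myelination_params(), initial_segment = 0)
  kinds <- vapply(my$sections, function(s) s$kind, character(1))
  lens <- vapply(my$sections, section_length_for_test, numeric(1))
  expect_equal(kinds[1], "myelin_internode")
  expect_equal(kinds[length(kinds)], "axon_terminal")
  expect_equal(lens[length(lens)], 70, tolerance = 1e-9)
  expect_equal(lens[kinds == "node_of_ranvier"], rep(1, 9), tolerance = 1e-9)
  inter <- lens[kinds == "myelin_internode"]
  expect_equal(inter[-length(inter)], rep(100, length(inter) - 1),
               tolerance = 1e-9)
  expect_equal(sum(lens), 1010, tolerance = 1e-9 * 1010)
  ## alternation: no two consecutive sections of the same myelin kind
  expect_false(any(kinds[-1] == kinds[-length(kinds)]))
})

test_that("myelination conserves axonal arc length on branched arbors", {
  cells <- generate_synthetic_population(3, "pyramidal_like", seed = 11)
  for (m in cells) {
    kinds <- vapply(m$sections, function(s) s$kind, character(1))
    ax <- sum(vapply(m$sections[kinds %in% c("axon_unmyelinated",
                                             "myelin_internode",
                                             "node_of_ranvier",
                                             "axon_terminal")],
                     section_length_for_test, numeric(1)))
    expect_gt(ax, 0)
  }
  ## direct conservation on a single jittered polyline axon
  set.seed(2)
  zs <- seq(0, -900, length.out = 10)
  pts <- cbind(cumsum(rnorm(10, 0, 5)), cumsum(rnorm(10, 0, 5)), zs)
  m <- morphology(list(section("axon_unmyelinated", pts, rep(1.2, 10), NA)))
  L0 <- section_length_for_test(m$sections[[1]])
  my <- myelinate_axon(m, initial_segment = 0)
  L1 <- sum(vapply(my$sections, section_length_for_test, numeric(1)))
  expect_lt(abs(L1 - L0) / L0, 1e-3)
})

test_that("myelinating a dendrite-only morphology warns and is a no-op", {
  m <- straight_cable(200, 2, kind = "dendrite")
  expect_warning(out <- myelinate_axon(m), class = "tms_no_axon_warning")
  expect_equal(out$sections[[1]]$points, m$sections[[1]]$points)
})

test_that("per-part scaling acts on the named part only", {
  m <- generate_ball_and_stick(200, 2, soma_diameter = 10)
  id <- apply_scaling(m, list())
  expect_equal(id$sections, m$sections)
  sc <- apply_scaling(m, list(axon_diameter = 2))
  for (i in seq_along(m$sections)) {
    s0 <- m$sections[[i]]; s1 <- sc$sections[[i]]
    if (s0$kind == "soma") expect_equal(s1$diam, s0$diam)
    else {
      expect_equal(s1$diam, 2 * s0$diam)
      expect_equal(s1$points, s0$points)  # lengths unchanged
    }
  }
  ln <- apply_scaling(m, list(axon_length = 1.5))
  expect_equal(sum(vapply(ln$sections[-1], section_length_for_test, numeric(1))),
               1.5 * 200, tolerance = 1e-9)
  expect_tms_error(apply_scaling(m, list(axon_diameter = -1)),
                   "tms_config_error")
  expect_tms_error(apply_scaling(m, list(banana = 2)), "tms_config_error")
})

test_that("seeded population generation is reproducible and archetypes differ in shape", {
  a <- generate_synthetic_population(5, "pyramidal_like", seed = 42)
  b <- generate_synthetic_population(5, "pyramidal_like", seed = 42)
  expect_identical(a, b)
  c_ <- generate_synthetic_population(5, "pyramidal_like", seed = 43)
  expect_false(identical(a, c_))

  aspect <- function(m) {
    pts <- do.call(rbind, lapply(m$sections, function(s) s$points))
    (max(pts[, 3]) - min(pts[, 3])) / (2 * max(sqrt(pts[, 1]^2 + pts[, 2]^2)))
  }
  bk <- generate_synthetic_population(5, "basket_like", seed = 42)
  expect_gt(median(vapply(a, aspect, numeric(1))),
            median(vapply(bk, aspect, numeric(1))))
  expect_gt(median(vapply(a, aspect, numeric(1))), 1)

  expect_tms_error(generate_synthetic_population(0, "pyramidal_like"),
                   "tms_config_error")
  expect_tms_error(generate_synthetic_population(1, "stellate"),
                   "tms_config_error")
})

test_that("discretization respects the compartment-length limit and conserves length", {
  m <- straight_cable(100, 2)
  cm <- discretize(m, 20)
  expect_equal(length(cm$length), 5L)
  expect_equal(cm$length, rep(20, 5))

  m2 <- straight_cable(101, 2)
  cm2 <- discretize(m2, 20)
  expect_equal(length(cm2$length), 6L)
  expect_true(all(cm2$length <= 20 + 1e-9))
  expect_equal(sum(cm2$length), 101, tolerance = 1e-9)

  ## independent recount oracle on the ball-and-stick cell
  bs <- generate_ball_and_stick(760, 15, soma_diameter = 20)
  cmb <- discretize(bs, 20)
  recount <- 1L + sum(vapply(bs$sections[-1], function(s)
    as.integer(ceiling(section_length_for_test(s) / 20 - 1e-9)), integer(1)))
  expect_equal(length(cmb$length), recount)
  ## per-section conservation within 0.1%
  for (si in seq_along(bs$sections)[-1]) {
    ls <- sum(cmb$length[cmb$section == si])
    expect_lt(abs(ls - section_length_for_test(bs$sections[[si]])) /
                section_length_for_test(bs$sections[[si]]), 1e-3)
  }
  ## membrane roles
  expect_true(all(cmb$role[cmb$kind == "node_of_ranvier"] == "active_node"))
  expect_true(all(cmb$role[cmb$kind == "myelin_internode"] == "passive_myelin"))
  expect_true(all(cmb$role[cmb$kind == "soma"] == "passive_soma_dendrite"))
  ## connected tree with parents preceding children
  expect_true(all(cmb$parent[-1] < seq_along(cmb$length)[-1]))
})

test_that("morphology invariants are enforced", {
  expect_tms_error(morphology(list()), "tms_topology_error")
  s1 <- section("soma", matrix(c(0, 0, 0), 1), 10, NA)
  s2 <- section("dendrite", rbind(c(0, 0, 0), c(0, 0, 50)), c(2, 2), NA)
  expect_tms_error(morphology(list(s1, s2)), "tms_topology_error")  # two roots
  expect_tms_error(section("dendrite", rbind(c(0, 0, 0), c(0, 0, 1)),
                           c(2, -1)), "tms_geometry_error")
  expect_tms_error(section("dendrite", matrix(c(0, 0, 0), 1), 2),
                   "tms_geometry_error")  # single point non-soma
})
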