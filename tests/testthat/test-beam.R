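test_that("element stiffness matches the closed-form Hermite matrix and has
           the rigid-body null space", {
  nd <- needle_spec()
  Le <- nd$element_length
  ke <- element_stiffness(nd$elastic_modulus, nd$I, Le)

  expect_equal(ke, t(ke))
  expect_equal(ke[1, 1], 12 * nd$elastic_modulus * nd$I / Le^3)
  expect_equal(ke[2, 2], 4 * nd$elastic_modulus * nd$I / Le)
  expect_equal(ke[1, 2], 6 * nd$elastic_modulus * nd$I / Le^2)

  # uniform translation and rigid rotation produce no elastic force
  expect_equal(as.numeric(ke %*% c(1, 0, 1, 0)), rep(0, 4))
  th <- 0.013
  expect_equal(as.numeric(ke %*% c(0, th, Le * th, th)), rep(0, 4),
               tolerance = 1e-12)

  expect_error(element_stiffness(-1, nd$I, Le), "positive")
  expect_error(element_stiffness(nd$elastic_modulus, nd$I, 0), "positive")
})

test_that("cantilever tip deflection under a tip point load is nodally exact
           for any element count", {
  P <- 0.25
  for (nel in c(1L, 5L, 47L)) {
    nd <- needle_spec(n_elements = nel)
    load <- numeric(2 * nd$n_nodes)
    load[2 * nd$n_nodes - 1] <- P
    sys <- beam_system(nd, constrained_dofs = c(1L, 2L), load = load)
    u <- assemble_and_solve(sys)
    tip <- u[2 * nd$n_nodes - 1]
    exact <- P * nd$length^3 / (3 * nd$elastic_modulus * nd$I)
    expect_equal(tip, exact, tolerance = 1e-8)
  }
})

test_that("zero load yields the zero solution and constrained DOFs are
           exactly zero", {
  nd <- needle_spec(n_elements = 6)
  sys <- beam_system(nd, constrained_dofs = c(1L, 2L))
  expect_equal(assemble_and_solve(sys), numeric(2 * nd$n_nodes))

  springs <- data.frame(node = 4L, k = 0.2, z0 = 1.5)
  load <- numeric(2 * nd$n_nodes); load[2 * nd$n_nodes - 1] <- 0.1
  sys <- beam_system(nd, springs, constrained_dofs = c(1L, 2L, 5L),
                     load = load)
  u <- assemble_and_solve(sys)
  expect_identical(u[c(1, 2, 5)], c(0, 0, 0))
})

test_that("a tip spring combines with the cantilever in series stiffness", {
  nd <- needle_spec(n_elements = 10)
  P <- 0.4; k <- 0.05
  load <- numeric(2 * nd$n_nodes)
  load[2 * nd$n_nodes - 1] <- P
  springs <- data.frame(node = nd$n_nodes, k = k, z0 = 0)
  sys <- beam_system(nd, springs, constrained_dofs = c(1L, 2L), load = load)
  u <- assemble_and_solve(sys)
  k_cant <- 3 * nd$elastic_modulus * nd$I / nd$length^3
  expect_equal(u[2 * nd$n_nodes - 1], P / (k + k_cant), tolerance = 1e-10)
})

test_that("an unconstrained mechanism is reported as singular", {
  nd <- needle_spec(n_elements = 3)
  load <- numeric(2 * nd$n_nodes); load[1] <- 1
  sys <- beam_system(nd, load = load)
  expect_error(assemble_and_solve(sys), "singular")
})

test_that("the solution is linear and odd in loads and rest deflections", {
  nd <- needle_spec(n_elements = 8)
  set.seed(99)
  springs <- data.frame(node = sample(3:9, 4), k = runif(4, 0, 0.3),
                        z0 = rnorm(4, 0, 0.5))
  load <- rnorm(2 * nd$n_nodes, 0, 0.05)
  fixed <- c(1L, 2L, 3L)
  u1 <- assemble_and_solve(beam_system(nd, springs, fixed, load))
  s2 <- transform(springs, z0 = 2 * z0)
  u2 <- assemble_and_solve(beam_system(nd, s2, fixed, 2 * load))
  expect_equal(u2, 2 * u1, tolerance = 1e-10)
  sm <- transform(springs, z0 = -z0)
  um <- assemble_and_solve(beam_system(nd, sm, fixed, -load))
  expect_identical(um, -u1)
})

test_that("solver agrees with an independent dense solve for small meshes", {
  set.seed(17)
  for (nel in 1:3) {
    for (rep in 1:5) {
      nd <- needle_spec(n_elements = nel)
      n_spr <- sample(0:3, 1)
      springs <- data.frame(node = sample(seq_len(nd$n_nodes), n_spr,
                                          replace = TRUE),
                            k = runif(n_spr, 0, 1),
                            z0 = rnorm(n_spr))
      load <- rnorm(2 * nd$n_nodes, 0, 0.1)
      u_pkg <- assemble_and_solve(beam_system(nd, springs, c(1L, 2L), load))
      u_ref <- oracle_dense_solve(nel, nd$elastic_modulus * nd$I,
                                  nd$element_length, springs, c(1L, 2L),
                                  load)
      expect_equal(u_pkg, u_ref, tolerance = 1e-10)
    }
  }
})
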