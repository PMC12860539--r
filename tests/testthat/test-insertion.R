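test_that("bevel cutting force follows the wedge compression law", {
  expect_identical(cutting_force(0, 1.27, 30), 0)
  # hand evaluation: 0.1 * 1.27^2 / (4 tan 15deg)
  expect_equal(cutting_force(0.1, 1.27, 30), 0.1504856, tolerance = 1e-6)
  # homogeneity in the tip modulus
  expect_equal(cutting_force(0.08, 1.1, 45), 2 * cutting_force(0.04, 1.1, 45))
  expect_error(cutting_force(0.1, 1.27, 0), "alpha")
  expect_error(cutting_force(0.1, 1.27, 180), "alpha")
  expect_error(cutting_force(-0.1, 1.27, 30), "non-negative")
})

test_that("deflecting force resolves the cutting force through beta", {
  expect_equal(deflecting_force(1.3, 30, 0), 1.3 * cos(pi / 6))
  expect_identical(deflecting_force(0, 30, 0.4), 0)
  # alpha + theta summing to a right angle kills the deflecting component
  expect_equal(deflecting_force(0.7, 30, pi / 3), 0, tolerance = 1e-15)
  expect_error(deflecting_force(-1, 30, 0), "non-negative")
})

test_that("guided-region constraints pin the out-of-tissue segment", {
  nd <- needle_spec()
  # at 120 mm depth the proximal 20 mm of the needle is outside the tissue
  dofs <- guided_region_constraints(120, nd)
  guided_nodes <- which(nd$node_positions <= 20 + 1e-9)
  expect_setequal(dofs, sort(unique(c(2L * guided_nodes - 1L, 2L))))
  expect_length(guided_nodes, 7)

  # depth 0: every node pinned, no free mechanism
  expect_setequal(guided_region_constraints(0, nd),
                  sort(c(2L * seq_len(nd$n_nodes) - 1L, 2L)))

  # constrained set shrinks monotonically with depth
  sizes <- vapply(1:125, function(d) length(guided_region_constraints(d, nd)),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("zero-stiffness tissue produces identically zero deflection", {
  traj <- simulate_insertion(needle_spec(), tissue_profile(rep(0, 125)), 80)
  expect_identical(max(abs(traj$W)), 0)
  expect_identical(max(abs(traj$Theta)), 0)
  expect_identical(max(abs(traj$tip$Fc)), 0)
})

test_that("flipping the bevel direction negates every deflection exactly", {
  set.seed(5)
  profile <- anatomy_to_profile(sample_anatomy())
  up <- simulate_insertion(needle_spec(), profile, 70, bevel_direction = 1)
  dn <- simulate_insertion(needle_spec(), profile, 70, bevel_direction = -1)
  expect_identical(up$W, -dn$W)
  expect_identical(up$Theta, -dn$Theta)
})

test_that("identical inputs give bit-identical trajectories", {
  set.seed(31)
  profile <- anatomy_to_profile(sample_anatomy())
  a <- simulate_insertion(needle_spec(), profile, 60)
  b <- simulate_insertion(needle_spec(), profile, 60)
  expect_identical(a$W, b$W)
  expect_identical(a$springs, b$springs)
})

test_that("out-of-tissue nodes have exactly zero deflection at every state", {
  set.seed(6)
  nd <- needle_spec()
  traj <- simulate_insertion(nd, anatomy_to_profile(sample_anatomy()), 125)
  for (depth in c(1, 7, 33, 64, 101, 125)) {
    guided <- which(nd$node_positions <= nd$length - depth + 1e-9)
    expect_identical(max(abs(traj$W[depth, guided])), 0)
  }
})

test_that("every spring's force is continuous across the shift toward the
           base", {
  set.seed(8)
  nd <- needle_spec()
  traj <- simulate_insertion(nd, anatomy_to_profile(sample_anatomy()), 100)
  Le <- nd$element_length
  # shifts occur at the steps where cumulative advance reaches Le
  shift_depths <- which(diff(c(0, floor((1:100) / Le))) > 0)
  shift_depths <- setdiff(shift_depths, 100)
  expect_gt(length(shift_depths), 20)
  for (n in shift_depths) {
    pre <- traj$springs[traj$springs$depth == n, ]
    post <- traj$springs[traj$springs$depth == n + 1 &
                           traj$springs$slot <= n, ]
    w <- traj$W[n, ]
    expect_identical(post$k, pre$k)
    expect_identical(post$node, pre$node - 1)  # moved one node to the base
    f_before <- pre$k * (w[pre$node] - pre$z0)
    f_after <- post$k * (w[post$node] - post$z0)
    expect_equal(f_after, f_before, tolerance = 1e-12)
  }
})

test_that("each converged state is in static equilibrium and matches the R
           assembly of the same system", {
  set.seed(12)
  nd <- needle_spec()
  traj <- simulate_insertion(nd, anatomy_to_profile(sample_anatomy()), 90)
  for (depth in c(10, 45, 90)) {
    springs <- traj$springs[traj$springs$depth == depth, c("node", "k", "z0")]
    load <- numeric(2 * nd$n_nodes)
    load[2 * nd$n_nodes - 1] <- traj$tip$Fcz[depth]
    sys <- beam_system(nd, springs, guided_region_constraints(depth, nd),
                       load)
    u <- numeric(2 * nd$n_nodes)
    u[seq(1, 2 * nd$n_nodes, 2)] <- traj$W[depth, ]
    u[seq(2, 2 * nd$n_nodes, 2)] <- traj$Theta[depth, ]
    # the compiled state solves the R-assembled equations
    expect_equal(assemble_and_solve(sys), u, tolerance = 1e-9)
    # transverse force balance: tip load + spring forces + guide reactions
    r <- reaction_forces(sys, u)
    w_reactions <- r[as.integer(sub("dof", "", names(r))) %% 2 == 1]
    spring_f <- -springs$k * (traj$W[depth, springs$node] - springs$z0)
    expect_equal(traj$tip$Fcz[depth] + sum(spring_f) + sum(w_reactions), 0,
                 tolerance = 1e-8)
  }
})

test_that("full insertions match the independent brute-force step ledger", {
  set.seed(23)
  for (rep in 1:2) {
    profile <- anatomy_to_profile(sample_anatomy())
    traj <- simulate_insertion(needle_spec(), profile, 40)
    W_ref <- oracle_insertion(as.numeric(profile), 40)
    expect_equal(traj$W, W_ref, tolerance = 1e-10)
  }
})

test_that("the optional fixed-point tip-slope iteration converges to a
           self-consistent cutting force", {
  set.seed(44)
  profile <- anatomy_to_profile(sample_anatomy(n_layers = 2))
  traj <- simulate_insertion(needle_spec(), profile, 60, fixed_point = TRUE)
  d <- 60
  expect_equal(traj$tip$Fcz[d],
               deflecting_force(traj$tip$Fc[d], 30, traj$tip$theta_tip[d]),
               tolerance = 1e-6)
  # close to, but not identical with, the explicit one-pass update
  expl <- simulate_insertion(needle_spec(), profile, 60)
  expect_lt(max(abs(traj$W - expl$W)), 0.05)
  expect_false(identical(traj$W, expl$W))
})

test_that("input validation names the offending argument", {
  nd <- needle_spec()
  pr <- tissue_profile(rep(0.05, 125))
  expect_error(simulate_insertion(nd, pr, 0), "target_depth")
  expect_error(simulate_insertion(nd, pr, 126), "target_depth")
  expect_error(simulate_insertion(nd, pr, 10.5), "target_depth")
  expect_error(simulate_insertion(nd, pr, 50, bevel_direction = 2),
               "bevel_direction")
  expect_error(tissue_profile(rep(0.05, 120)), "125")
  expect_error(tissue_profile(c(rep(0.05, 124), -0.01)), "non-negative")
})

test_that("trajectories tidy into long form and export as text", {
  traj <- simulate_insertion(needle_spec(), tissue_profile(rep(0.08, 125)),
                             25)
  df <- as.data.frame(traj)
  expect_identical(nrow(df), 25L * 48L)
  expect_identical(df$deflection_mm[df$depth_mm == 25 & df$node_index == 48],
                   traj$W[25, 48])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(traj, path)
  back <- read.delim(path)
  expect_equal(back$deflection_mm, df$deflection_mm)
})
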