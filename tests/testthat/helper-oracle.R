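# Independent reference implementations used as oracles. These are written
# from the model equations directly -- plain R, explicit loops, their own
# bookkeeping -- and never call into the package's solver paths.

# Dense solve of a beam + springs + point loads system by elimination.
oracle_dense_solve <- function(n_elements, EI, Le, springs, fixed_dofs,
                               load) {
  n_nodes <- n_elements + 1L
  nd <- 2L * n_nodes
  l2 <- Le^2
  ke <- (EI / Le^3) * matrix(c(
    12, 6 * Le, -12, 6 * Le,
    6 * Le, 4 * l2, -6 * Le, 2 * l2,
    -12, -6 * Le, 12, -6 * Le,
    6 * Le, 2 * l2, -6 * Le, 4 * l2), 4, 4, byrow = TRUE)
  K <- matrix(0, nd, nd)
  for (e in seq_len(n_elements)) {
    ix <- (2L * e - 1L):(2L * e + 2L)
    K[ix, ix] <- K[ix, ix] + ke
  }
  F <- load
  if (!is.null(springs) && nrow(springs)) {
    for (i in seq_len(nrow(springs))) {
      wd <- 2L * springs$node[i] - 1L
      K[wd, wd] <- K[wd, wd] + springs$k[i]
      F[wd] <- F[wd] + springs$k[i] * springs$z0[i]
    }
  }
  free <- setdiff(seq_len(nd), fixed_dofs)
  u <- numeric(nd)
  u[free] <- solve(K[free, free], F[free])
  u
}

# Brute-force step ledger for the whole insertion: advance 1 mm per step,
# attach a spring behind the tip, apply the bevel cutting force, solve,
# and shift springs toward the base after each element length of advance.
oracle_insertion <- function(modulus, target_depth,
                             L = 140, n_el = 47L, E = 35000,
                             d = 1.27, di = 0.838, alpha_deg = 30,
                             t_ref = 1, bevel = 1) {
  n_nodes <- n_el + 1L
  Le <- L / n_el
  EI <- E * pi * (d^4 - di^4) / 64
  alpha <- alpha_deg * pi / 180
  pos <- (0:(n_nodes - 1L)) * Le
  springs <- data.frame(node = integer(0), k = numeric(0), z0 = numeric(0))
  u <- numeric(2L * n_nodes)
  th_tip <- 0
  adv <- 0
  W <- matrix(0, target_depth, n_nodes)
  for (depth in seq_len(target_depth)) {
    C <- modulus[depth]
    springs <- rbind(springs,
                     data.frame(node = n_nodes - 1L, k = C * t_ref,
                                z0 = u[2L * (n_nodes - 1L) - 1L]))
    load <- numeric(2L * n_nodes)
    Fc <- C * d^2 / (4 * tan(alpha / 2))
    load[2L * n_nodes - 1L] <- bevel * Fc * cos(alpha + bevel * th_tip)
    fixed_w_nodes <- which(pos <= L - depth + 1e-9)
    fixed <- sort(c(2L * fixed_w_nodes - 1L, 2L))
    u <- oracle_dense_solve(n_el, EI, Le, springs, fixed, load)
    W[depth, ] <- u[seq(1L, 2L * n_nodes, by = 2L)]
    adv <- adv + 1
    if (adv >= Le) {
      adv <- adv - Le
      for (i in seq_len(nrow(springs))) {
        old <- springs$node[i]
        new <- old - 1L
        springs$z0[i] <- u[2L * new - 1L] + (springs$z0[i] - u[2L * old - 1L])
        springs$node[i] <- new
      }
    }
    th_tip <- u[2L * n_nodes]
  }
  W
}

# Closed-form mean of a normal truncated below at 0.
oracle_truncnorm_mean <- function(mu, sigma) {
  a <- (0 - mu) / sigma
  mu + sigma * dnorm(a) / (1 - pnorm(a))
}
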