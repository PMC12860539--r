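#' Euler-Bernoulli beam element stiffness matrix
#'
#' Standard 4x4 Hermite (cubic) bending element over the in-plane nodal
#' degrees of freedom `(w_i, theta_i, w_j, theta_j)`, with `w` the
#' transverse deflection (mm) and `theta = dw/dx` the cross-section
#' rotation (rad).
#'
#' @param E Elastic modulus, MPa.
#' @param I Second moment of area, mm^4.
#' @param L Element length, mm.
#' @return Symmetric 4x4 matrix; forces in N, moments in N mm.
#' @export
element_stiffness <- function(E, I, L) {
  if (any(c(E, I, L) <= 0)) stop("E, I and L must all be positive")
  (E * I / L^3) * matrix(c(
     12,    6 * L,   -12,    6 * L,
      6 * L, 4 * L^2, -6 * L, 2 * L^2,
    -12,   -6 * L,    12,   -6 * L,
      6 * L, 2 * L^2, -6 * L, 4 * L^2), 4, 4, byrow = TRUE)
}

#' Assemble a supported-beam system
#'
#' Builds the global state for a needle-shaped beam resting on discrete
#' preloaded tissue springs. Degrees of freedom are interleaved:
#' node `i` (1-based) owns DOFs `2i - 1` (deflection `w`) and `2i`
#' (rotation `theta`).
#'
#' Each spring acts on its node's `w` DOF with force
#' `f = -k (w - z0)`: `k` is the spring stiffness (N/mm) and `z0` the
#' rest deflection (mm) at which the spring carries no load, which is how
#' the tissue channel cut by an advancing needle keeps its memory.
#' In the assembled equations a spring adds `k` to the diagonal and
#' `k z0` to the load vector.
#'
#' @param needle A [needle_spec()].
#' @param springs `data.frame` with columns `node` (1-based index), `k`
#'   (N/mm, non-negative) and `z0` (mm); zero rows allowed.
#' @param constrained_dofs Integer DOF indices prescribed to zero.
#' @param load Numeric load vector of length `2 * n_nodes` (N on `w`
#'   DOFs, N mm on `theta` DOFs), or `NULL` for no load.
#' @return A list of class `beam_system` with the assembled (pre-
#'   constraint) stiffness `K`, the effective load `F`, and the inputs.
#' @export
beam_system <- function(needle, springs = NULL, constrained_dofs = integer(0),
                        load = NULL) {
  stopifnot(inherits(needle, "needle_spec"))
  nd <- 2L * needle$n_nodes
  if (is.null(load)) load <- numeric(nd)
  stopifnot(length(load) == nd)
  ke <- element_stiffness(needle$elastic_modulus, needle$I,
                          needle$element_length)
  K <- matrix(0, nd, nd)
  for (e in seq_len(needle$n_elements)) {
    idx <- (2L * e - 1L):(2L * e + 2L)
    K[idx, idx] <- K[idx, idx] + ke
  }
  F <- load
  if (is.null(springs))
    springs <- data.frame(node = integer(0), k = numeric(0), z0 = numeric(0))
  if (nrow(springs)) {
    stopifnot(all(springs$k >= 0),
              all(springs$node >= 1), all(springs$node <= needle$n_nodes))
    for (s in seq_len(nrow(springs))) {
      wd <- 2L * springs$node[s] - 1L
      K[wd, wd] <- K[wd, wd] + springs$k[s]
      F[wd] <- F[wd] + springs$k[s] * springs$z0[s]
    }
  }
  constrained_dofs <- sort(unique(as.integer(constrained_dofs)))
  stopifnot(all(constrained_dofs >= 1), all(constrained_dofs <= nd))
  structure(list(needle = needle, K = K, F = F, springs = springs,
                 constrained_dofs = constrained_dofs),
            class = "beam_system")
}

#' Solve a supported-beam system
#'
#' Linear static solve of `(K_beam + K_springs) u = F_ext + k z0` with the
#' constrained DOFs eliminated (prescribed to zero). The system is at most
#' 96 DOF, so a dense solve is used.
#'
#' @param system A [beam_system()].
#' @return Numeric vector `u` of length `2 * n_nodes`; odd entries are
#'   nodal deflections `w` (mm), even entries rotations `theta` (rad).
#'   Constrained DOFs are exactly zero.
#' @export
assemble_and_solve <- function(system) {
  stopifnot(inherits(system, "beam_system"))
  nd <- nrow(system$K)
  fixed <- system$constrained_dofs
  free <- setdiff(seq_len(nd), fixed)
  u <- numeric(nd)
  if (length(free)) {
    Kff <- system$K[free, free, drop = FALSE]
    ok <- tryCatch({
      u[free] <- solve(Kff, system$F[free])
      TRUE
    }, error = function(e) FALSE)
    if (!ok)
      stop("singular beam system: the unconstrained mechanism involves DOFs ",
           paste(utils::head(free, 6), collapse = ", "),
           if (length(free) > 6) ", ..." else "",
           "; add constraints or springs")
  }
  u
}

#' Reaction forces of a solved system
#'
#' Residual `K u - F` at the constrained DOFs: the forces the template
#' grid (guide) must supply to hold the out-of-tissue nodes straight.
#'
#' @param system A [beam_system()].
#' @param u Solution from [assemble_and_solve()].
#' @return Named numeric vector over the constrained DOFs.
#' @export
reaction_forces <- function(system, u) {
  r <- as.numeric(system$K %*% u - system$F)
  stats::setNames(r[system$constrained_dofs],
                  paste0("dof", system$constrained_dofs))
}
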