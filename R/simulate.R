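#' Bevel-tip cutting force
#'
#' Force exerted on the needle tip by the tissue it compresses ahead of
#' the bevel, treating the bevel as a wedge:
#' `F_c = C_tip d^2 / (4 tan(alpha / 2))`, with `C_tip` the tissue elastic
#' modulus at the tip depth.
#'
#' @param C_tip Tissue elastic modulus at the tip, MPa.
#' @param d Needle outer diameter, mm.
#' @param alpha Bevel angle, degrees.
#' @return Cutting force, N (non-negative, linear in `C_tip`).
#' @export
cutting_force <- function(C_tip, d, alpha) {
  if (any(C_tip < 0)) stop("C_tip must be non-negative")
  if (d <= 0) stop("d must be positive")
  if (alpha <= 0 || alpha >= 180) stop("alpha must lie in (0, 180) degrees")
  C_tip * d^2 / (4 * tan(alpha * pi / 360))
}

#' Deflecting component of the cutting force
#'
#' The component of the cutting force acting along the deflection
#' direction: `F_cz = F_c cos(beta)` with `beta = alpha + theta_tip`, the
#' angle between the cutting force and the deflection direction
#' (`alpha` converted to radians before the sum).
#'
#' @param F_c Cutting force, N (non-negative).
#' @param alpha Bevel angle, degrees.
#' @param theta_tip Needle slope at the tip, rad.
#' @return Deflecting force, N.
#' @export
deflecting_force <- function(F_c, alpha, theta_tip) {
  if (any(F_c < 0)) stop("F_c must be non-negative")
  F_c * cos(alpha * pi / 180 + theta_tip)
}

#' Guided-region constraints at a given insertion depth
#'
#' The part of the needle not yet inside the tissue is held straight by
#' the template grid: deflection `w` is fixed to zero at every node whose
#' distance from the base is at most `length - depth`, and the rotation is
#' fixed at the base node only.
#'
#' @param depth Insertion depth, mm (0 to 125).
#' @param needle A [needle_spec()].
#' @return Sorted integer vector of constrained DOF indices (1-based;
#'   node `i` owns DOFs `2i - 1` for `w` and `2i` for `theta`).
#' @export
guided_region_constraints <- function(depth, needle = needle_spec()) {
  stopifnot(depth >= 0, depth <= TISSUE_DEPTH_MM)
  guided <- which(needle$node_positions <= needle$length - depth + 1e-9)
  sort(unique(c(2L * guided - 1L, 2L)))
}

#' Simulate a quasi-static needle insertion
#'
#' Advances the needle in 1-mm steps through a per-millimetre tissue
#' profile. At each step: (1) a spring with stiffness proportional to the
#' local tissue modulus is attached to the node just behind the tip, at
#' rest at that node's current deflection; (2) the bevel cutting force is
#' computed from the modulus at the tip depth and resolved along the
#' deflection direction using the tip slope of the previous state;
#' (3) the beam-on-springs system is solved with the guided region held
#' straight; (4) after each full element length of advance, all springs
#' shift one node toward the base with their rest deflections updated so
#' every spring force is continuous across the shift.
#'
#' @param needle A [needle_spec()].
#' @param tissue A [tissue_profile()] (or anything coercible via
#'   [anatomy_to_profile()] for a [layered_anatomy()]).
#' @param target_depth Final integer insertion depth, mm (1 to 125).
#' @param bevel_direction +1 or -1: side toward which the bevel deflects
#'   the needle. Flipping it negates every deflection exactly.
#' @param t_ref Tributary tissue thickness per spring, mm; spring
#'   stiffness is `modulus * t_ref` so the default 1 mm makes `k` (N/mm)
#'   numerically equal to the local modulus (MPa).
#' @param fixed_point If `TRUE`, iterate the tip-slope/cutting-force
#'   coupling at each step to tolerance `fp_tol` instead of the default
#'   one-pass explicit update.
#' @param fp_tol,fp_maxit Fixed-point tolerance (rad) and iteration cap.
#' @param record_springs Keep the full per-depth spring registry (needed
#'   for introspection; disable for bulk dataset generation).
#' @return An object of class `needle_trajectory`: deflection matrix `W`
#'   (`target_depth` x `n_nodes`, mm), rotation matrix `Theta` (rad), a
#'   per-depth `tip` data frame (`depth`, `theta_tip`, `beta`, `Fc`,
#'   `Fcz`, `tip_deflection`), the spring registry `springs` (columns
#'   `depth`, `slot`, `node`, `k`, `z0`) and the inputs.
#' @export
simulate_insertion <- function(needle, tissue, target_depth,
                               bevel_direction = 1, t_ref = 1,
                               fixed_point = FALSE, fp_tol = 1e-8,
                               fp_maxit = 50, record_springs = TRUE) {
  stopifnot(inherits(needle, "needle_spec"))
  if (inherits(tissue, "layered_anatomy")) tissue <- anatomy_to_profile(tissue)
  stopifnot(inherits(tissue, "tissue_profile"))
  if (length(target_depth) != 1 || target_depth != round(target_depth) ||
      target_depth < 1 || target_depth > TISSUE_DEPTH_MM)
    stop("target_depth must be an integer between 1 and ", TISSUE_DEPTH_MM)
  if (!bevel_direction %in% c(-1, 1))
    stop("bevel_direction must be +1 or -1")
  stopifnot(t_ref > 0)

  res <- cpp_simulate_insertion(
    n_nodes = needle$n_nodes, needle_length = needle$length,
    EI = needle$elastic_modulus * needle$I, d_outer = needle$outer_diameter,
    alpha_deg = needle$bevel_angle, bevel_dir = bevel_direction,
    modulus = as.numeric(tissue), target_depth = as.integer(target_depth),
    t_ref = t_ref, fixed_point = fixed_point, fp_tol = fp_tol,
    fp_maxit = as.integer(fp_maxit), record_springs = record_springs)

  tip <- data.frame(depth = seq_len(target_depth),
                    theta_tip = as.numeric(res$theta_tip),
                    beta = as.numeric(res$beta),
                    Fc = as.numeric(res$Fc),
                    Fcz = as.numeric(res$Fcz),
                    tip_deflection = res$W[, needle$n_nodes])
  springs <- NULL
  if (record_springs) {
    springs <- as.data.frame(res$springs)
    names(springs) <- c("depth", "slot", "node", "k", "z0")
  }
  structure(list(needle = needle, tissue = tissue,
                 target_depth = as.integer(target_depth),
                 bevel_direction = bevel_direction, t_ref = t_ref,
                 W = res$W, Theta = res$Theta, tip = tip, springs = springs),
            class = "needle_trajectory")
}

#' @export
print.needle_trajectory <- function(x, ...) {
  cat(sprintf("<needle_trajectory> depth %d mm, %d nodes\n",
              x$target_depth, x$needle$n_nodes))
  cat(sprintf("  final tip deflection: %.4f mm (tip slope %.5f rad)\n",
              x$tip$tip_deflection[x$target_depth],
              x$tip$theta_tip[x$target_depth]))
  invisible(x)
}

#' Tidy a trajectory into long form
#'
#' @param x A `needle_trajectory`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return Data frame with one row per node per depth: `depth_mm`,
#'   `node_index`, `axial_position_mm`, `deflection_mm`, `slope_rad`.
#' @export
as.data.frame.needle_trajectory <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  n <- x$needle$n_nodes
  D <- x$target_depth
  data.frame(depth_mm = rep(seq_len(D), each = n),
             node_index = rep(seq_len(n), D),
             axial_position_mm = rep(x$needle$node_positions, D),
             deflection_mm = as.numeric(t(x$W)),
             slope_rad = as.numeric(t(x$Theta)))
}

#' Write a trajectory as tab-separated text
#'
#' @param trajectory A `needle_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.table(as.data.frame(trajectory), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
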