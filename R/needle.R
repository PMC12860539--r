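#' Biopsy needle specification
#'
#' Geometry and material constants of the simulated needle. Defaults
#' describe an 18-gauge nitinol biopsy needle: a 140-mm tube of outer
#' diameter 1.27 mm, inner diameter 0.838 mm, elastic modulus 35 000 MPa
#' and a 30-degree bevel tip, discretized into 47 planar Euler-Bernoulli
#' beam elements (48 nodes).
#'
#' Units are millimetres, Newtons and MPa (= N/mm^2) throughout the
#' package, so the bending stiffness `E I` carries units of N mm^2.
#'
#' @param length Needle length from base (held in the template grid) to
#'   tip, mm.
#' @param outer_diameter,inner_diameter Tube cross-section diameters, mm.
#' @param elastic_modulus Young's modulus of the needle material, MPa.
#' @param bevel_angle Bevel tip angle, degrees.
#' @param n_elements Number of beam elements; the mesh has
#'   `n_elements + 1` nodes, node 1 at the base, the last node at the tip.
#'
#' @return An object of class `needle_spec`: a list with the arguments
#'   plus derived fields `n_nodes`, `element_length` (mm), `I` (second
#'   moment of area of the annular cross-section, mm^4) and
#'   `node_positions` (mm from base).
#' @examples
#' nd <- needle_spec()
#' nd$I                       # annulus second moment of area
#' nd$element_length          # 140 / 47 mm
#' @export
needle_spec <- function(length = 140,
                        outer_diameter = 1.27,
                        inner_diameter = 0.838,
                        elastic_modulus = 35000,
                        bevel_angle = 30,
                        n_elements = 47) {
  stopifnot(length > 0, outer_diameter > 0, elastic_modulus > 0,
            n_elements >= 1, n_elements == as.integer(n_elements))
  if (inner_diameter < 0 || inner_diameter >= outer_diameter)
    stop("inner_diameter must lie in [0, outer_diameter)")
  if (bevel_angle <= 0 || bevel_angle >= 180)
    stop("bevel_angle must lie in (0, 180) degrees")
  n_elements <- as.integer(n_elements)
  I <- pi * (outer_diameter^4 - inner_diameter^4) / 64
  obj <- list(
    length = length,
    outer_diameter = outer_diameter,
    inner_diameter = inner_diameter,
    elastic_modulus = elastic_modulus,
    bevel_angle = bevel_angle,
    n_elements = n_elements,
    n_nodes = n_elements + 1L,
    element_length = length / n_elements,
    I = I,
    node_positions = seq(0, length, length.out = n_elements + 1L)
  )
  class(obj) <- "needle_spec"
  obj
}

#' @export
print.needle_spec <- function(x, ...) {
  cat(sprintf(
    "<needle_spec> %g mm, OD %g / ID %g mm, E = %g MPa, bevel %g deg\n",
    x$length, x$outer_diameter, x$inner_diameter,
    x$elastic_modulus, x$bevel_angle))
  cat(sprintf("  %d elements (%d nodes), element length %.4f mm, I = %.5f mm^4\n",
              x$n_elements, x$n_nodes, x$element_length, x$I))
  invisible(x)
}

#' Tissue depth covered by the standard per-millimetre profile, mm.
#' @keywords internal
TISSUE_DEPTH_MM <- 125L
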