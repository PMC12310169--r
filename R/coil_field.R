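#' Solenoid winding geometry
#'
#' Describes a layered solenoid winding to be expanded into filamentary
#' current loops. Lengths are in metres. The inner winding diameter names the
#' inner surface of the innermost layer's wire; successive layers advance by
#' one wire diameter. The default arguments describe the head drive coil used
#' throughout the package: 3 layers of 18 turns of 4 mm hollow copper wire,
#' 11 cm long, 27 cm inner winding diameter.
#'
#' @param n_layers Number of winding layers.
#' @param turns_per_layer Turns in each layer.
#' @param coil_length Axial length of the winding (m).
#' @param inner_winding_diameter Diameter of the inner surface of the first
#'   layer's wire (m).
#' @param wire_outer_diameter Outer diameter of the wire (m).
#' @return An object of class `coil_geometry`.
#' @examples
#' coil_geometry()
#' @export
coil_geometry <- function(n_layers = 3L, turns_per_layer = 18L,
                          coil_length = 0.11, inner_winding_diameter = 0.27,
                          wire_outer_diameter = 0.004) {
  n_layers <- as.integer(n_layers)
  turns_per_layer <- as.integer(turns_per_layer)
  if (n_layers < 1L || turns_per_layer < 1L)
    stop("n_layers and turns_per_layer must be positive integers")
  if (coil_length <= 0 || inner_winding_diameter <= 0 || wire_outer_diameter <= 0)
    stop("all lengths must be positive")
  if (coil_length < wire_outer_diameter)
    stop("coil_length must be at least one wire diameter")
  structure(list(n_layers = n_layers, turns_per_layer = turns_per_layer,
                 coil_length = coil_length,
                 inner_winding_diameter = inner_winding_diameter,
                 wire_outer_diameter = wire_outer_diameter),
            class = "coil_geometry")
}

#' Expand a winding into filamentary loops
#'
#' Each turn becomes one circular filament at the wire centre. Layer `k`
#' (k = 0, 1, ...) sits at radius
#' `inner_winding_diameter/2 + wire_outer_diameter/2 + k * wire_outer_diameter`.
#' Turn centres are spaced evenly so they span the full coil length, centred
#' on z = 0. (Close-winding 18 turns of 4 mm wire would span only 72 mm,
#' inconsistent with the stated 110 mm length, so the winding is treated as
#' spread out.)
#'
#' @param geometry A [coil_geometry()].
#' @return An object of class `loop_stack`: a data.frame with columns
#'   `radius_m` and `z_m`, one row per turn, carrying the wire radius as an
#'   attribute for singularity checks.
#' @examples
#' stack <- build_loop_stack(coil_geometry())
#' nrow(stack)  # 54 turns
#' @export
build_loop_stack <- function(geometry) {
  stopifnot(inherits(geometry, "coil_geometry"))
  g <- geometry
  radii <- g$inner_winding_diameter / 2 + g$wire_outer_diameter / 2 +
    (seq_len(g$n_layers) - 1L) * g$wire_outer_diameter
  z <- if (g$turns_per_layer == 1L) 0 else
    seq(-g$coil_length / 2, g$coil_length / 2, length.out = g$turns_per_layer)
  loops <- expand.grid(radius_m = radii, z_m = z, KEEP.OUT.ATTRS = FALSE)
  loops <- loops[order(loops$radius_m, loops$z_m), , drop = FALSE]
  rownames(loops) <- NULL
  structure(loops, class = c("loop_stack", "data.frame"),
            wire_radius_m = g$wire_outer_diameter / 2)
}

mu0 <- 4e-7 * pi

## Field of a single circular filament carrying 1 A, radius a, centred at the
## origin in the z = 0 plane, evaluated at cylindrical (r, z). Complete
## elliptic integral form; reduces exactly to the on-axis closed form
## mu0 a^2 / (2 (a^2 + z^2)^(3/2)) at r = 0.
loop_field_1A <- function(a, r, z) {
  if (r < 1e-14) {
    return(c(Br = 0, Bz = mu0 * a^2 / (2 * (a^2 + z^2)^1.5)))
  }
  m <- 4 * a * r / ((a + r)^2 + z^2)
  ke <- pracma::ellipke(m)
  den <- (a - r)^2 + z^2
  pref <- mu0 / (2 * pi * sqrt((a + r)^2 + z^2))
  Bz <- pref * (ke$k + ke$e * (a^2 - r^2 - z^2) / den)
  Br <- pref * z / r * (-ke$k + ke$e * (a^2 + r^2 + z^2) / den)
  c(Br = Br, Bz = Bz)
}

#' Field efficiency at a point
#'
#' Per-ampere magnetic field of a loop stack at cylindrical position (r, z),
#' by superposition of circular-filament fields (complete elliptic
#' integrals). Efficiency is reported as the field magnitude |B| in uT/A, as
#' a three-axis magnetometer measurement would give; on axis this equals
#' |Bz|.
#'
#' @param stack A [build_loop_stack()] result.
#' @param r Radial offset from the coil axis (m).
#' @param z Axial offset from the coil centre (m).
#' @return A list of class `field_sample` with `r_m`, `z_m`, `Br_uT_per_A`,
#'   `Bz_uT_per_A`, `efficiency_uT_per_A`.
#' @examples
#' field_at(build_loop_stack(coil_geometry()), 0, 0)
#' @export
field_at <- function(stack, r, z) {
  stopifnot(inherits(stack, "loop_stack"), length(r) == 1L, length(z) == 1L)
  wr <- attr(stack, "wire_radius_m")
  if (is.null(wr)) wr <- 1e-6
  d2 <- (r - stack$radius_m)^2 + (z - stack$z_m)^2
  if (any(d2 <= wr^2))
    stop("evaluation point lies on (or inside) a wire filament; field is singular there")
  comp <- vapply(seq_len(nrow(stack)),
                 function(i) loop_field_1A(stack$radius_m[i], r, z - stack$z_m[i]),
                 numeric(2))
  Br <- sum(comp[1L, ]) * 1e6
  Bz <- sum(comp[2L, ]) * 1e6
  structure(list(r_m = r, z_m = z, Br_uT_per_A = Br, Bz_uT_per_A = Bz,
                 efficiency_uT_per_A = sqrt(Br^2 + Bz^2)),
            class = "field_sample")
}

#' Field efficiency profile along the radial or axial axis
#'
#' Evaluates [field_at()] along a line: radially in the coil midplane
#' (z = 0) or axially on the coil axis (r = 0).
#'
#' @param stack A [build_loop_stack()] result.
#' @param axis `"radial"` (vary r at z = 0) or `"axial"` (vary z at r = 0).
#' @param positions Offsets along the chosen axis (m).
#' @return A data.frame with columns `r_m`, `z_m`, `Br_uT_per_A`,
#'   `Bz_uT_per_A`, `mag_uT_per_A`, ordered as `positions`.
#' @export
efficiency_profile <- function(stack, axis = c("radial", "axial"), positions) {
  axis <- match.arg(axis)
  rows <- lapply(positions, function(p) {
    s <- if (axis == "radial") field_at(stack, p, 0) else field_at(stack, 0, p)
    data.frame(r_m = s$r_m, z_m = s$z_m, Br_uT_per_A = s$Br_uT_per_A,
               Bz_uT_per_A = s$Bz_uT_per_A, mag_uT_per_A = s$efficiency_uT_per_A)
  })
  do.call(rbind, rows)
}

#' Write a field map to CSV
#'
#' @param profile A data.frame from [efficiency_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field_map <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.field_sample <- function(x, ...) {
  cat(sprintf("field sample at (r = %g m, z = %g m): %.1f uT/A (Br = %.2f, Bz = %.2f)\n",
              x$r_m, x$z_m, x$efficiency_uT_per_A, x$Br_uT_per_A, x$Bz_uT_per_A))
  invisible(x)
}
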