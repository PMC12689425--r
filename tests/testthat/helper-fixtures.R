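# Shared fixtures and independent oracles used across the test files.

# small clean mosaic for fast tests
tiny_mosaic <- function(spacing = 10, seed = 1, h = 128, w = 128, ...) {
  generate_mosaic(mosaic_spec(height_px = h, width_px = w, spacing_px = spacing,
                              seed = seed, ...))
}

# Independent paraxial oracle: surface-by-surface ray trace using the scalar
# refraction equation n2 u2 = n1 u1 - y (n2 - n1) / R (no matrix products).
# Returns micrometres of retina per degree of visual angle.
oracle_um_per_degree <- function(b) {
  trace <- function(y, u) {
    refract <- function(y, u, n1, n2, R) (n1 * u - y * (n2 - n1) / R) / n2
    u <- refract(y, u, 1, b$n_aqueous, b$corneal_radius_mm)
    y <- y + b$anterior_chamber_depth_mm * u
    u <- refract(y, u, b$n_aqueous, b$n_lens, b$lens_radius_anterior_mm)
    y <- y + b$lens_thickness_mm * u
    u <- refract(y, u, b$n_lens, b$n_vitreous, b$lens_radius_posterior_mm)
    c(y = y, u = u)
  }
  # u_out is affine in the entry height y1 at fixed entry angle u = 1:
  # solve u_out(y1) = 1 for the nodal ray, then intersect it with the axis.
  r0 <- trace(0, 1); r1 <- trace(1, 1)
  slope <- r1[["u"]] - r0[["u"]]
  y_star <- (1 - r0[["u"]]) / slope
  out <- trace(y_star, 1)
  z_nodal <- b$anterior_chamber_depth_mm + b$lens_thickness_mm - out[["y"]] / out[["u"]]
  (b$axial_length_mm - z_nodal) * pi / 180 * 1000
}

# numeric one-tailed p oracle by integrating the t density
oracle_p_greater <- function(t_stat, df) {
  stats::integrate(function(x) stats::dt(x, df), t_stat, Inf,
                   rel.tol = 1e-10)$value
}

# mass of the histogram bins containing the given angles (degrees)
mass_at <- function(h, angles) {
  sum(h$mass[unique(pmin(findInterval(angles, h$bin_edges),
                         length(h$mass)))])
}
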