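#' Ocular biometry for the three-surface schematic eye
#'
#' A simplified paraxial model eye with three refracting surfaces: a single
#' corneal surface and the two lens surfaces. The three per-subject measured
#' values (axial length, anterior corneal radius, anterior chamber depth)
#' personalise the model; the remaining constants default to the
#' Gullstrand-Emsley simplified schematic eye and are exposed as arguments.
#'
#' @param axial_length_mm corneal vertex to retina distance.
#' @param corneal_radius_mm anterior corneal radius of curvature.
#' @param anterior_chamber_depth_mm corneal vertex to anterior lens surface.
#' @param lens_thickness_mm axial lens thickness.
#' @param lens_radius_anterior_mm,lens_radius_posterior_mm lens surface radii
#'   (sign convention: positive when the centre of curvature lies behind the
#'   surface, so the posterior radius is negative).
#' @param n_aqueous,n_lens,n_vitreous refractive indices.
#' @return An `eye_biometry` object.
#' @export
eye_biometry <- function(axial_length_mm = 23.89, corneal_radius_mm = 7.8,
                         anterior_chamber_depth_mm = 3.6,
                         lens_thickness_mm = 3.6,
                         lens_radius_anterior_mm = 10.0,
                         lens_radius_posterior_mm = -6.0,
                         n_aqueous = 4 / 3, n_lens = 1.416,
                         n_vitreous = 4 / 3) {
  if (axial_length_mm <= 0 || anterior_chamber_depth_mm <= 0 ||
      lens_thickness_mm <= 0 || abs(corneal_radius_mm) <= 0) {
    stop("all lengths must be positive", call. = FALSE)
  }
  if (axial_length_mm <= anterior_chamber_depth_mm + lens_thickness_mm) {
    stop("axial length must exceed chamber depth plus lens thickness", call. = FALSE)
  }
  structure(list(axial_length_mm = axial_length_mm,
                 corneal_radius_mm = corneal_radius_mm,
                 anterior_chamber_depth_mm = anterior_chamber_depth_mm,
                 lens_thickness_mm = lens_thickness_mm,
                 lens_radius_anterior_mm = lens_radius_anterior_mm,
                 lens_radius_posterior_mm = lens_radius_posterior_mm,
                 n_aqueous = n_aqueous, n_lens = n_lens,
                 n_vitreous = n_vitreous),
            class = "eye_biometry")
}

# Paraxial elements acting on the ray vector (y, u) with true (unreduced)
# angles, so det(refraction) = n1/n2 and det(translation) = 1 exactly.
paraxial_refraction <- function(n1, n2, radius_mm) {
  P <- (n2 - n1) / radius_mm
  matrix(c(1, -P / n2, 0, n1 / n2), 2, 2)
}

paraxial_translation <- function(d_mm) {
  matrix(c(1, 0, d_mm, 1), 2, 2)
}

#' Retinal magnification scale from a paraxial ray trace
#'
#' Builds the three-surface paraxial system, locates the second nodal point
#' (the axial point through which an exiting ray keeps the entering ray's
#' angle), and converts the posterior nodal distance to micrometres of retina
#' per degree of visual angle:
#' `um_per_degree = (axial_length - nodal_point) * pi / 180 * 1000`.
#' With a field of view and pixel count, also derives micrometres per pixel.
#'
#' @param biometry an [eye_biometry()].
#' @param fov_deg,n_pixels optional field of view (degrees) and pixel count
#'   across it, e.g. 1.5 degrees sampled by 512 A-scans.
#' @return A `retinal_scale`: `um_per_degree`, `nodal_point_mm` (from the
#'   corneal vertex), `posterior_nodal_distance_mm`, and `um_per_pixel` when
#'   the field geometry is given.
#' @export
retinal_scale <- function(biometry, fov_deg = NULL, n_pixels = NULL) {
  stopifnot(inherits(biometry, "eye_biometry"))
  b <- biometry
  M <- paraxial_refraction(b$n_lens, b$n_vitreous, b$lens_radius_posterior_mm) %*%
       paraxial_translation(b$lens_thickness_mm) %*%
       paraxial_refraction(b$n_aqueous, b$n_lens, b$lens_radius_anterior_mm) %*%
       paraxial_translation(b$anterior_chamber_depth_mm) %*%
       paraxial_refraction(1, b$n_aqueous, b$corneal_radius_mm)
  A <- M[1, 1]; B <- M[1, 2]; C <- M[2, 1]; D <- M[2, 2]
  # ray (y1, u) entering at the corneal vertex plane exits with u2 = u when
  # y1 = u (1 - D) / C; the exiting ray y(z) = y2 + u z crosses the axis at
  # z' = -y2 / u behind the last surface: the second nodal point.
  if (abs(C) < 1e-12) stop("afocal system: nodal point undefined", call. = FALSE)
  z_prime <- -(A * (1 - D) / C + B)
  nodal_mm <- b$anterior_chamber_depth_mm + b$lens_thickness_mm + z_prime
  pnd <- b$axial_length_mm - nodal_mm
  if (pnd <= 0) {
    stop("non-physical biometry: posterior nodal distance is not positive",
         call. = FALSE)
  }
  um_per_degree <- pnd * pi / 180 * 1000
  out <- list(um_per_degree = um_per_degree, nodal_point_mm = nodal_mm,
              posterior_nodal_distance_mm = pnd,
              um_per_pixel = NULL, fov_deg = fov_deg, n_pixels = n_pixels)
  if (!is.null(fov_deg) && !is.null(n_pixels)) {
    if (n_pixels <= 0) stop("`n_pixels` must be positive", call. = FALSE)
    out$um_per_pixel <- um_per_degree * fov_deg / n_pixels
  }
  structure(out, class = "retinal_scale")
}

#' @export
print.retinal_scale <- function(x, ...) {
  cat(sprintf("<retinal_scale> %.2f um/deg (nodal point %.3f mm, PND %.3f mm)\n",
              x$um_per_degree, x$nodal_point_mm, x$posterior_nodal_distance_mm))
  if (!is.null(x$um_per_pixel)) {
    cat(sprintf("  %.4f um/px over %.3g deg / %d px\n",
                x$um_per_pixel, x$fov_deg, x$n_pixels))
  }
  invisible(x)
}

#' Convert a pixel spacing to retinal micrometres
#'
#' `spacing_um = spacing_px * (fov_deg / n_pixels) * um_per_degree`.
#'
#' @param spacing_px spacing in pixels (non-negative).
#' @param fov_deg field of view in degrees.
#' @param n_pixels_across_fov pixels sampling the field of view.
#' @param scale a [retinal_scale()].
#' @return Spacing in micrometres.
#' @export
spacing_px_to_um <- function(spacing_px, fov_deg, n_pixels_across_fov, scale) {
  stopifnot(inherits(scale, "retinal_scale"))
  if (n_pixels_across_fov <= 0) stop("`n_pixels_across_fov` must be positive", call. = FALSE)
  if (fov_deg <= 0) stop("`fov_deg` must be positive", call. = FALSE)
  spacing_px * (fov_deg / n_pixels_across_fov) * scale$um_per_degree
}

#' Read per-subject biometry from a YAML or CSV file
#'
#' YAML files hold named fields; CSV files hold one subject per row. Fields
#' `axial_length_mm`, `corneal_radius_mm` and `anterior_chamber_depth_mm` are
#' required; any other [eye_biometry()] argument may be supplied to override
#' the schematic defaults.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.csv`.
#' @return An `eye_biometry` (YAML) or list of them, one per CSV row.
#' @export
read_biometry <- function(path) {
  ext <- tolower(tools::file_ext(path))
  build <- function(rec) {
    rec <- rec[!vapply(rec, function(x) is.null(x) || is.na(x), logical(1))]
    need <- c("axial_length_mm", "corneal_radius_mm", "anterior_chamber_depth_mm")
    if (!all(need %in% names(rec))) {
      stop("biometry file must provide ", paste(need, collapse = ", "), call. = FALSE)
    }
    do.call(eye_biometry, rec[names(rec) %in% names(formals(eye_biometry))])
  }
  if (ext %in% c("yaml", "yml")) {
    build(yaml::read_yaml(path))
  } else if (ext == "csv") {
    df <- utils::read.csv(path)
    lapply(seq_len(nrow(df)), function(i) build(as.list(df[i, , drop = FALSE])))
  } else {
    stop("unsupported biometry format: ", ext, call. = FALSE)
  }
}
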