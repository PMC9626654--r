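#' Ventricular wall slab model
#'
#' A flat slab stand-in for the left-ventricular wall: the endocardial
#' surface is the plane z = 0 and the myocardium occupies
#' `0 <= z <= wall_thickness`. Lesion phantoms are attached to the
#' endocardial surface and must fit inside the slab.
#'
#' @param wall_thickness wall thickness in mm (> 0). The default 16 mm
#'   accommodates the deepest lesions seen after high-power ablation
#'   (up to ~15 mm).
#' @param lateral_extent length-2 numeric, lateral slab size (mm) in x and y,
#'   centred on the origin.
#' @return An object of class `wall_model`.
#' @export
wall_model <- function(wall_thickness = 16, lateral_extent = c(40, 40)) {
  stopifnot(is.numeric(wall_thickness), length(wall_thickness) == 1L,
            wall_thickness > 0,
            is.numeric(lateral_extent), length(lateral_extent) == 2L,
            all(lateral_extent > 0))
  structure(list(wall_thickness = as.numeric(wall_thickness),
                 lateral_extent = as.numeric(lateral_extent)),
            class = "wall_model")
}

#' Parametric ground-truth lesion
#'
#' Defines a radiofrequency ablation lesion as a solid of revolution about
#' the depth axis, pinned to the four landmark dimensions used in lesion
#' morphometry:
#'
#' * `A` - maximum depth: distance from the catheter contact point on the
#'   endocardium to the deepest point (apex) of the lesion;
#' * `B` - maximum width, reached at depth `C`;
#' * `C` - depth of the maximum diameter;
#' * `D` - estuary: the lesion's surface opening diameter, the hollow left
#'   in the endocardium by catheter pressure.
#'
#' The radius profile (see [radius_profile()]) interpolates the landmarks
#' smoothly, so the ground-truth dimensions and volume are exact by
#' construction and can serve as the reference for any measurement method.
#'
#' @param lesion_id positive integer identifier.
#' @param A,B,C,D landmark dimensions in mm; must satisfy `0 < C < A` and
#'   `0 <= D <= B`.
#' @param contact_point length-2 numeric (mm), catheter contact (x, y) on the
#'   endocardial plane.
#' @param heart_id optional identifier of the heart the lesion belongs to.
#' @return An object of class `lesion_spec` with fields `A_true`, `B_true`,
#'   `C_true`, `D_true` (equal to `A`..`D` for unperturbed lesions) and
#'   `V_true` (mm^3), plus the base profile parameters.
#' @seealso [perturb_steam_pop()], [fused_pair()], [true_volume()]
#' @export
lesion_spec <- function(lesion_id, A, B, C, D, contact_point = c(0, 0),
                        heart_id = NA_integer_) {
  stopifnot(length(lesion_id) == 1L, length(A) == 1L, length(B) == 1L,
            length(C) == 1L, length(D) == 1L,
            is.numeric(contact_point), length(contact_point) == 2L)
  if (!all(is.finite(c(A, B, C, D))) || A <= 0 || B <= 0)
    stop("A and B must be positive and finite")
  if (C <= 0 || C >= A)
    stop(sprintf("lesion %s: need 0 < C < A (got C = %g, A = %g)",
                 lesion_id, C, A))
  if (D < 0 || D > B)
    stop(sprintf("lesion %s: need 0 <= D <= B (got D = %g, B = %g)",
                 lesion_id, D, B))
  spec <- structure(list(lesion_id = as.integer(lesion_id),
                         heart_id = as.integer(heart_id),
                         A = as.numeric(A), B = as.numeric(B),
                         C = as.numeric(C), D = as.numeric(D),
                         contact_point = as.numeric(contact_point),
                         perturbation = NULL,
                         A_true = as.numeric(A), B_true = as.numeric(B),
                         C_true = as.numeric(C), D_true = as.numeric(D),
                         V_true = NA_real_),
                    class = "lesion_spec")
  spec$V_true <- true_volume(spec)
  spec
}

#' Axisymmetric radius profile of a lesion
#'
#' Radius of the (unperturbed) lesion solid at depth `z` below the
#' endocardial surface. The profile models the classic shape of an RF
#' lesion - a narrow surface opening indented by the catheter tip, widening
#' quickly into an ovoid body - with three pieces:
#'
#' * a short *estuary neck* on `0 <= z <= h`, `h = min(1, C/2)` mm: a
#'   sixth-order cosine easing from the estuary radius `D/2` to the ovoid
#'   body. The easing starts flat (the radius leaves `D/2` only at sixth
#'   order in `z`), which is what makes the estuary measurable from a
#'   voxelized mask - the surface layer of the raster still has radius
#'   essentially `D/2`;
#' * the lower quarter-ellipse body on `h <= z <= C`, rising to the maximum
#'   radius `B/2` at depth `C`;
#' * the upper quarter-ellipse cap on `C <= z <= A`, closing to 0 at the
#'   apex.
#'
#' Consequently `r(0) = D/2`, `r(C) = B/2 = max r`, `r(A) = 0`, and `r` is
#' continuous on `[0, A]` (0 outside).
#'
#' @param spec a [lesion_spec()].
#' @param z depth(s) in mm; any real values are accepted (radius is 0 outside
#'   `[0, A]`).
#' @return numeric vector of radii (mm), same length as `z`.
#' @export
radius_profile <- function(spec, z) {
  stopifnot(inherits(spec, "lesion_spec"), is.numeric(z))
  A <- spec$A; B <- spec$B; C <- spec$C; D <- spec$D
  h <- min(1, C / 2)
  r_ell <- function(zz) (B / 2) * sqrt(pmax(0, 1 - ((C - zz) / C)^2))
  r <- numeric(length(z))
  nk <- which(z >= 0 & z <= h)
  md <- which(z > h & z <= C)
  hi <- which(z > C & z <= A)
  if (length(nk)) {
    e <- ((1 - cos(pi * z[nk] / h)) / 2)^3
    r[nk] <- D / 2 + (r_ell(h) - D / 2) * e
  }
  if (length(md)) r[md] <- r_ell(z[md])
  if (length(hi))
    r[hi] <- (B / 2) * sqrt(pmax(0, 1 - ((z[hi] - C) / (A - C))^2))
  r
}

#' Full (possibly azimuthally modulated) lesion radius
#'
#' For unperturbed lesions this equals [radius_profile()]. A steam-pop
#' perturbation multiplies the profile by a smooth positive azimuthal
#' modulation `1 + a * taper(z) * s(theta)` (see [perturb_steam_pop()]).
#'
#' @param spec a [lesion_spec()].
#' @param z depth(s) in mm.
#' @param theta azimuth(s) in radians, recycled against `z`.
#' @return numeric vector of radii (mm).
#' @export
lesion_radius <- function(spec, z, theta = 0) {
  r <- radius_profile(spec, z)
  p <- spec$perturbation
  if (is.null(p) || !identical(p$type, "steam_pop")) return(r)
  r * steam_pop_modulation(p, spec$A, z, theta)
}

## modulation of the radius field for a steam-pop perturbation:
## 1 + amplitude * sin(pi z / A) * s(theta), s in [0, 1]
steam_pop_modulation <- function(p, A, z, theta) {
  taper <- ifelse(z >= 0 & z <= A, sin(pi * pmin(pmax(z, 0), A) / A), 0)
  s <- 0
  for (phi in p$phases) s <- s + ((1 + cos(theta - phi)) / 2)^2
  1 + p$amplitude * taper * s / length(p$phases)
}

#' Ground-truth lesion volume
#'
#' Volume of the lesion solid in mm^3. For unperturbed lesions this is
#' `pi * integral of r(z)^2 dz` over `[0, A]`, evaluated by adaptive
#' quadrature on each smooth branch (relative tolerance 1e-9). For
#' steam-pop-perturbed lesions the solid is star-shaped about the depth axis
#' and the volume is the exact double integral
#' `1/2 * integral of rho(theta, z)^2 dtheta dz`, evaluated on a fine
#' trapezoidal (z) x periodic-trapezoidal (theta) grid; the azimuthal rule is
#' spectrally accurate for the smooth low-order modulation used here.
#'
#' @param spec a [lesion_spec()].
#' @return volume in mm^3.
#' @export
true_volume <- function(spec) {
  stopifnot(inherits(spec, "lesion_spec"))
  p <- spec$perturbation
  if (is.null(p) || !identical(p$type, "steam_pop")) {
    f <- function(z) radius_profile(spec, z)^2
    brk <- c(0, min(1, spec$C / 2), spec$C, spec$A)  # piecewise-smooth knots
    v <- sum(vapply(seq_len(3), function(i)
      stats::integrate(f, brk[i], brk[i + 1], rel.tol = 1e-9,
                       subdivisions = 400L)$value, numeric(1)))
    return(pi * v)
  }
  zs <- seq(0, spec$A, length.out = 2001L)
  nth <- 720L
  th <- seq(0, 2 * pi, length.out = nth + 1L)[-(nth + 1L)]
  r <- radius_profile(spec, zs)
  ## rho^2 summed over theta (periodic trapezoid = plain mean * 2*pi)
  g <- vapply(zs, function(z) {
    m <- steam_pop_modulation(p, spec$A, z, th)
    mean(m^2)
  }, numeric(1))
  integrand <- r^2 * g * pi  # (1/2) * 2*pi * mean(rho^2)
  trapz(zs, integrand)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Apply a steam-pop perturbation to a lesion
#'
#' High-power ablation can rupture the myocardium ("steam pop"), producing
#' irregular, badly bounded lesions. This is emulated by multiplying the
#' radius profile by a smooth positive azimuthal modulation
#' `1 + amplitude_frac * sin(pi z / A) * s(theta)`, where `s` averages
#' `n_lobes` raised-cosine bumps at random azimuths. The depth taper vanishes
#' at the surface and at the apex, so the rupture spreads the lesion in width
#' rather than depth: `A_true` and `D_true` are unchanged, while `B_true`,
#' `C_true` and `V_true` are recomputed from the perturbed solid.
#'
#' @param spec an unperturbed [lesion_spec()].
#' @param amplitude_frac modulation amplitude, in `[0, 1]`; 0 returns the
#'   spec unchanged.
#' @param n_lobes number of azimuthal lobes (>= 1).
#' @param seed integer seed for the random lobe azimuths; a given seed always
#'   yields the same perturbed lesion.
#' @return A perturbed `lesion_spec`.
#' @export
perturb_steam_pop <- function(spec, amplitude_frac, n_lobes, seed) {
  stopifnot(inherits(spec, "lesion_spec"))
  if (!is.null(spec$perturbation))
    stop("lesion is already perturbed")
  if (amplitude_frac < 0 || amplitude_frac > 1)
    stop("amplitude_frac must be within [0, 1]")
  if (n_lobes < 1) stop("n_lobes must be >= 1")
  if (amplitude_frac == 0) return(spec)
  phases <- withr::with_seed(as.integer(seed),
                             stats::runif(as.integer(n_lobes), 0, 2 * pi))
  spec$perturbation <- list(type = "steam_pop",
                            amplitude = as.numeric(amplitude_frac),
                            n_lobes = as.integer(n_lobes),
                            seed = as.integer(seed),
                            phases = phases)
  ## recompute effective width/depth-of-width from the perturbed solid:
  ## per depth, the caliper width is max over directions of
  ## rho(theta) + rho(theta + pi)
  nth <- 720L
  th <- seq(0, 2 * pi, length.out = nth + 1L)[-(nth + 1L)]
  half <- nth %/% 2L
  zs <- seq(0, spec$A, length.out = 1601L)
  widths <- vapply(zs, function(z) {
    rho <- lesion_radius(spec, z, th)
    max(rho + rho[(seq_len(nth) + half - 1L) %% nth + 1L])
  }, numeric(1))
  k <- which.max(widths)  # ties resolve to the smallest depth
  spec$B_true <- widths[k]
  spec$C_true <- zs[k]
  spec$V_true <- true_volume(spec)
  spec
}

#' Create the partner of a fused lesion pair
#'
#' Overlapping ablations produce fused lesion pairs whose binary union is a
#' single connected blob while the label map still distinguishes them.
#' `fused_pair()` clones (or takes) a second lesion and places it at a given
#' lateral offset from the first; when the offset is smaller than the sum of
#' the two maximal radii the rasterized union is connected.
#'
#' @param spec the first [lesion_spec()].
#' @param partner_id lesion id for the partner.
#' @param center_offset length-2 numeric (mm), lateral offset of the partner
#'   contact point relative to `spec`'s.
#' @param partner optional `lesion_spec` supplying the partner's dimensions;
#'   by default the partner is a copy of `spec`.
#' @return A list of the two `lesion_spec`s, each tagged with a `fused`
#'   perturbation record naming its partner.
#' @export
fused_pair <- function(spec, partner_id, center_offset, partner = NULL) {
  stopifnot(inherits(spec, "lesion_spec"),
            is.numeric(center_offset), length(center_offset) == 2L)
  second <- if (is.null(partner)) spec else partner
  second$lesion_id <- as.integer(partner_id)
  second$contact_point <- spec$contact_point + as.numeric(center_offset)
  spec$fused_with <- as.integer(partner_id)
  second$fused_with <- spec$lesion_id
  list(spec, second)
}

#' @export
print.lesion_spec <- function(x, ...) {
  pert <- if (is.null(x$perturbation)) "none" else x$perturbation$type
  cat(sprintf(paste0("<lesion_spec #%d> A=%.2f B=%.2f C=%.2f D=%.2f mm, ",
                     "V=%.1f mm^3, perturbation: %s\n"),
              x$lesion_id, x$A_true, x$B_true, x$C_true, x$D_true,
              x$V_true, pert))
  invisible(x)
}
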