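#' Configuration for a synthetic lesion study
#'
#' Bundles every tunable of the end-to-end synthetic pipeline: the cohort
#' (how many hearts and lesions, the target dimension distributions, the
#' steam-pop mix), the two emulated acquisitions (thin-slice MRI-like and
#' thick-slice pathology-like), the observer emulation (two observers, three
#' repeats, per-dimension repeat noise and per-observer bias), and the
#' significance level of the statistical stage.
#'
#' Defaults emulate a 99-lesion, 10-heart ex vivo study: lesion dimensions
#' are drawn around depth 9.0 +/- 2.8 mm, width 11.1 +/- 2.8 mm, depth of
#' the maximum diameter 4.8 +/- 1.6 mm and estuary 2.0 +/- 0.9 mm
#' (truncated to mutually consistent ranges); the MRI-like stack uses
#' 1.0 mm slices with a 100/256 mm in-plane pixel (a 100 mm field of view on
#' a 256 x 256 matrix), and the pathology emulation cuts 3-5 mm slabs whose
#' cut faces are sampled at the same in-plane scale. Observer biases default
#' to a ~1.1 mm inter-observer width gap (and proportionally smaller gaps
#' for the other dimensions) with 0.15-0.3 mm repeat noise, yielding the
#' typical pattern of significant inter-observer but negligible
#' intra-observer differences.
#'
#' @param n_hearts number of hearts.
#' @param n_lesions total number of lesions across hearts.
#' @param dims named list of `c(mean, sd)` targets for `A`, `B`, `C`, `D`
#'   in mm.
#' @param wall_thickness wall slab thickness in mm.
#' @param steam_pop list with `frac` (fraction of lesions perturbed),
#'   `amplitude`, `n_lobes`.
#' @param mri list: `slice_thickness`, `in_plane` (mm), `contrast`
#'   (core/border/myocardium), `border_width`, `noise_sd`, `min_contrast`,
#'   `min_size` (mm^3), `ghost_depth` (lesions shallower than this render
#'   nearly isointense and go unrecognized), `ghost_offset`.
#' @param patho list: `thickness_range` (mm, within `[3, 5]`), `in_plane`,
#'   `cut_aim` (mm; the prosector aims each cut at the visible lesion
#'   centre with a uniform error within `+/- cut_aim`). The default
#'   (`NULL`) resolves to `sqrt(t^2 - p^2)/2` for MRI slice thickness `t`
#'   and face pixel `p`, so that the aiming error plus the face
#'   quantization has exactly the variance of the MRI slice offset - both
#'   modalities then sample the lesion plane with matched offset spread
#'   and the emulation introduces no method effect. `min_face_area`
#'   (mm^2) is the recognition threshold on the best face.
#' @param measurement list: `n_observers`, `n_repeats`, `repeat_sd` (named
#'   per dimension, mm), `observer_bias` (observers x dimensions matrix,
#'   mm).
#' @param volume_cv coefficient of variation of the per-record
#'   point-by-point outlining noise.
#' @param alpha significance level for the statistical stage.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(
    n_hearts = 10L,
    n_lesions = 99L,
    dims = list(A = c(9.008, 2.823), B = c(11.125, 2.801),
                C = c(4.783, 1.648), D = c(2.001, 0.872)),
    wall_thickness = 16,
    steam_pop = list(frac = 0.15, amplitude = 0.5, n_lobes = 3L),
    mri = list(slice_thickness = 1.0, in_plane = 100 / 256,
               contrast = c(core = 0.9, border = 0.15, myocardium = 0.55),
               border_width = 1.0, noise_sd = 0.02,
               min_contrast = 0.15, min_size = 5,
               ghost_depth = 4.5, ghost_offset = 0.03),
    patho = list(thickness_range = c(3, 5), in_plane = 100 / 256,
                 cut_aim = NULL, min_face_area = 1.0),
    measurement = list(
      n_observers = 2L, n_repeats = 3L,
      repeat_sd = c(A = 0.30, B = 0.30, C = 0.30, D = 0.15),
      observer_bias = rbind(`1` = c(A = -0.393, B = -0.550,
                                    C = -0.136, D = 0.057),
                            `2` = c(A = 0.393, B = 0.550,
                                    C = 0.136, D = -0.057))),
    volume_cv = 0.03,
    alpha = 0.05) {
  stopifnot(n_hearts >= 1L,
            all(vapply(dims, length, integer(1)) == 2L),
            wall_thickness > 0,
            steam_pop$frac >= 0, steam_pop$frac <= 1,
            mri$slice_thickness > 0, mri$in_plane > 0,
            patho$thickness_range[1] >= 3, patho$thickness_range[2] <= 5,
            patho$in_plane > 0,
            measurement$n_repeats >= 1L, measurement$n_observers >= 1L,
            all(measurement$repeat_sd >= 0),
            alpha > 0, alpha < 1)
  if (n_lesions < 1L) stop("n_lesions must be at least 1")
  if (is.null(patho$cut_aim)) {
    ## the aimed cut plane is continuous (the pipeline aligns a face layer
    ## centre with it), so matching the MRI slice-offset distribution
    ## U(-t/2, t/2) just means aiming within half a slice thickness
    patho$cut_aim <- mri$slice_thickness / 2
  }
  structure(list(n_hearts = as.integer(n_hearts),
                 n_lesions = as.integer(n_lesions),
                 dims = dims, wall_thickness = wall_thickness,
                 steam_pop = steam_pop, mri = mri, patho = patho,
                 measurement = measurement, volume_cv = volume_cv,
                 alpha = alpha),
            class = "pipeline_config")
}

#' Simulate a lesion cohort with exact ground truth
#'
#' Draws `n_lesions` lesion specifications across `n_hearts` hearts from the
#' configured dimension distributions (Gaussian, truncated to mutually
#' consistent ranges so every spec is geometrically valid), places them on a
#' 20-mm lateral grid within each heart, and applies the configured fraction
#' of steam-pop perturbations. A fixed seed reproduces the cohort exactly.
#'
#' @param config a [pipeline_config()].
#' @param seed integer seed.
#' @return list with `specs` (list of [lesion_spec()]), `truth` (data.frame
#'   of exact per-lesion dimensions and volume), and `wall` (the per-heart
#'   [wall_model()]).
#' @export
simulate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "pipeline_config"))
  withr::with_seed(as.integer(seed), simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n_lesions
  hearts <- sort(rep_len(seq_len(config$n_hearts), n))
  d <- config$dims
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      A <- stats::rnorm(1, d$A[1], d$A[2])
      B <- stats::rnorm(1, d$B[1], d$B[2])
      C <- stats::rnorm(1, d$C[1], d$C[2])
      D <- stats::rnorm(1, d$D[1], d$D[2])
      ok <- A > 3.2 && A < config$wall_thickness - 0.5 &&
        B > 4.5 && B < 17.5 &&
        C > 0.8 && C < A - 0.8 &&
        D > 0.3 && D < B - 1
      if (ok) break
    }
    slot <- sum(hearts[seq_len(i)] == hearts[i]) - 1L
    cp <- c((slot %% 5L) * 20 - 40, (slot %/% 5L) * 20 - 10) +
      stats::runif(2, -1.5, 1.5)
    spec <- lesion_spec(i, A, B, C, D, contact_point = cp,
                        heart_id = hearts[i])
    if (stats::runif(1) < config$steam_pop$frac)
      spec <- perturb_steam_pop(spec, config$steam_pop$amplitude,
                                config$steam_pop$n_lobes,
                                seed = sample.int(2^31 - 1, 1))
    specs[[i]] <- spec
  }
  truth <- do.call(rbind, lapply(specs, function(s)
    data.frame(lesion_id = s$lesion_id, heart_id = s$heart_id,
               A_true = s$A_true, B_true = s$B_true, C_true = s$C_true,
               D_true = s$D_true, V_true = s$V_true,
               perturbation = perturbation_label(s))))
  list(specs = specs, truth = truth,
       wall = wall_model(config$wall_thickness, c(100, 60)))
}
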