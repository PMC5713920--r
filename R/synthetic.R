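# Synthetic "measured" verification fixtures: noisy depth-dose and profile
# curves and point-dose sets, generated from analytic models that share no
# machinery with the transport engine, so curve-agreement tests are
# non-circular.

# default generating-model parameters (textbook 6 MV beam shape)
PD_FIX_PDD_ALPHA <- 2.6 # buildup rate 1/cm; with dmax = 1.5 cm gives PDD(10)/PDD(dmax) ~ 0.65
PD_FIX_PDD_DMAX_CM <- 1.5
PD_FIX_PENUMBRA_SIGMA_CM <- 0.35

# unit-mean multiplicative lognormal noise
#' @noRd
.pd_lognoise <- function(n, sd) {
  if (sd == 0) {
    return(rep(1, n))
  }
  exp(stats::rnorm(n, mean = -sd^2 / 2, sd = sd))
}

#' Generate a synthetic measured depth-dose curve
#'
#' Analytic buildup-attenuation model
#' `PDD(d) = N (1 - exp(-alpha d)) exp(-beta d)`, with `beta` fixed by the
#' requested depth of maximum `beta = alpha / (exp(alpha dmax) - 1)`,
#' multiplied by unit-mean lognormal noise. With the default parameters the
#' noiseless curve peaks at 1.5 cm and has `PDD(10)/PDD(dmax)` of about 0.65.
#'
#' @param field_size nominal square field side in cm (metadata only; the
#'   generating model does not vary with field size)
#' @param depths depths in cm
#' @param noise_sd relative noise standard deviation, in `[0, 0.05]`
#' @param seed integer seed (required)
#' @param alpha buildup rate in 1/cm
#' @param dmax_cm depth of maximum of the noiseless model
#' @return a `pd_pdd` tibble: `depth_cm`, `dose` (relative, noiseless max 1),
#'   `pdd`; attributes `dmax_cm`, `alpha`, `beta`, `noise_sd`, `seed`
#' @export
generate_reference_pdd <- function(field_size = 10,
                                   depths = pd_default_depths(),
                                   noise_sd = 0.02, seed,
                                   alpha = PD_FIX_PDD_ALPHA,
                                   dmax_cm = PD_FIX_PDD_DMAX_CM) {
  if (missing(seed)) stop("generate_reference_pdd() requires an explicit seed")
  stopifnot(noise_sd >= 0, noise_sd <= 0.05)
  beta <- alpha / (expm1(alpha * dmax_cm))
  shape <- function(d) (1 - exp(-alpha * d)) * exp(-beta * d)
  peak <- shape(dmax_cm)
  set.seed(seed)
  dose <- shape(depths) / peak * .pd_lognoise(length(depths), noise_sd)
  out <- tibble::tibble(
    depth_cm = depths,
    dose = dose,
    pdd = 100 * dose
  )
  class(out) <- c("pd_pdd", class(out))
  attr(out, "dmax_cm") <- dmax_cm
  attr(out, "pdd10") <- 100 * shape(10) / peak
  attr(out, "field_size") <- field_size
  attr(out, "alpha") <- alpha
  attr(out, "beta") <- beta
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- seed
  out
}

#' Generate a synthetic measured lateral profile
#'
#' Flat plateau with error-function penumbrae,
#' `p(x) = Phi((hw - x)/sigma) + Phi((hw + x)/sigma) - 1`, where the
#' half-width `hw` is the nominal field half-size projected to the
#' measurement depth (divergent geometry, source at 100 cm). The noiseless
#' curve passes through 50% of the plateau at `x = +-hw` exactly.
#'
#' @param field_size square field side in cm (defined at 100 cm)
#' @param depth measurement depth in cm
#' @param offsets lateral positions in cm
#' @param noise_sd relative noise standard deviation, in `[0, 0.05]`
#' @param seed integer seed (required)
#' @param sigma_cm penumbra width parameter in cm
#' @return a `pd_profile` tibble: `position_cm`, `dose` (plateau 1);
#'   attributes `depth_cm`, `half_width_cm`, `sigma_cm`, `noise_sd`, `seed`
#' @export
generate_reference_profile <- function(field_size = 10, depth = 10,
                                       offsets = seq(-9, 9, by = 0.25),
                                       noise_sd = 0.02, seed,
                                       sigma_cm = PD_FIX_PENUMBRA_SIGMA_CM) {
  if (missing(seed)) {
    stop("generate_reference_profile() requires an explicit seed")
  }
  stopifnot(noise_sd >= 0, noise_sd <= 0.05)
  hw <- (field_size / 2) * (PD_SAD_CM + depth) / PD_SAD_CM
  shape <- stats::pnorm((hw - offsets) / sigma_cm) +
    stats::pnorm((hw + offsets) / sigma_cm) - 1
  set.seed(seed)
  out <- tibble::tibble(
    position_cm = offsets,
    dose = shape * .pd_lognoise(length(offsets), noise_sd)
  )
  class(out) <- c("pd_profile", class(out))
  attr(out, "depth_cm") <- depth
  attr(out, "field_size") <- field_size
  attr(out, "half_width_cm") <- hw
  attr(out, "sigma_cm") <- sigma_cm
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- seed
  out
}

#' Generate a synthetic point-dose measurement set
#'
#' Perturbs a set of computed point doses multiplicatively with unit-mean
#' lognormal noise, emulating a dosimeter reading of each point (reader
#' sensitivity spread of a few percent).
#'
#' @param doses computed point doses (numeric vector, or a tibble with
#'   columns `distance_cm` and `dose_cgy` such as the output of
#'   [run_tld_verification()])
#' @param relative_sd relative noise standard deviation, in `[0, 0.2]`
#' @param seed integer seed (required)
#' @param distances positions in cm assigned to a bare numeric `doses`
#' @return tibble with `distance_cm`, `dose_cgy`; attributes `relative_sd`,
#'   `seed`
#' @export
generate_tld_fixture <- function(doses, relative_sd = 0.04, seed,
                                 distances = seq(15, 40, by = 5)) {
  if (missing(seed)) stop("generate_tld_fixture() requires an explicit seed")
  stopifnot(relative_sd >= 0, relative_sd <= 0.2)
  if (is.data.frame(doses)) {
    distances <- doses$distance_cm
    doses <- doses$dose_cgy
  }
  stopifnot(length(doses) == length(distances))
  set.seed(seed)
  tibble::tibble(
    distance_cm = distances,
    dose_cgy = doses * .pd_lognoise(length(doses), relative_sd)
  ) |>
    structure(relative_sd = relative_sd, seed = seed)
}
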