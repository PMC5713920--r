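# R-side driver for the analog photon transport engine.

PD_GY_PER_MEV_G <- 1.602176634e-10

#' Run analog photon transport
#'
#' Tracks photons through a geometry with analog sampling of photoelectric
#' absorption, Klein-Nishina (Compton) scattering and pair production, down
#' to a 10 keV cutoff, without electron transport (collision kerma
#' approximates absorbed dose under charged-particle equilibrium). Histories
#' are split into batches; tally means and relative errors are estimated from
#' the batch spread. Tallies per cell: collision kerma (track-length estimator
#' of energy transferred per unit mass), total track-length fluence and
#' uncollided (primary) fluence.
#'
#' @param geom a `pd_geometry`
#' @param particles tibble or matrix of source photons with columns
#'   `x, y, z, ux, uy, uz, energy, weight` (as produced by [emit_beam()]);
#'   an optional `in_field` logical column marks photons belonging to the
#'   open aperture -- photons with `in_field = FALSE` (collimator leakage)
#'   are excluded from the uncollided (primary) fluence tally
#' @param seed integer seed; required, so every transport run is reproducible
#' @param n_batches number of statistical batches
#' @param cutoff photon energy cutoff in MeV
#' @return a `pd_tally` tibble: one row per cell with `cell`, `organ`,
#'   `material`, `mass_g`, `kerma_mev_g` (per source history),
#'   `kerma_rel_err`, `flux` (cm^-2 per history), `flux_rel_err`,
#'   `primary_flux`, `n_histories`. Attribute `energy_balance` holds the
#'   per-batch source/deposited/cutoff/escaped energy ledger.
#' @export
run_transport <- function(geom, particles, seed, n_batches = 20,
                          cutoff = 0.01) {
  stopifnot(inherits(geom, "pd_geometry"))
  if (missing(seed)) {
    stop(
      "run_transport() requires an explicit integer seed; ",
      "unseeded transport runs are not reproducible"
    )
  }
  cols <- c("x", "y", "z", "ux", "uy", "uz", "energy", "weight")
  if (is.data.frame(particles)) {
    if ("in_field" %in% names(particles)) {
      particles$primary <- as.numeric(particles$in_field)
      cols <- c(cols, "primary")
    }
    particles <- as.matrix(particles[, cols])
  }
  stopifnot(ncol(particles) %in% c(8L, 9L))
  n <- nrow(particles)
  nb <- as.integer(n_batches)
  stopifnot(nb >= 2, n >= nb)
  set.seed(seed)
  batch <- rep(seq_len(nb), length.out = n)
  res <- pd_cpp_transport(
    particles, batch, unclass(geom), .pd_xs_pack(geom$materials),
    nb, cutoff
  )
  nb_hist <- tabulate(batch, nb)
  per_hist <- function(m) sweep(m, 2, nb_hist, "/")
  stat <- function(m) {
    m <- per_hist(m)
    mu <- rowMeans(m)
    sem <- apply(m, 1, stats::sd) / sqrt(nb)
    list(mean = mu, rel = ifelse(mu > 0, sem / mu, NA_real_))
  }
  k <- stat(res$kerma)
  f <- stat(res$flux)
  p <- stat(res$primary_flux)
  out <- tibble::tibble(
    cell = geom$label,
    organ = geom$organ,
    material = geom$material,
    mass_g = geom$mass,
    kerma_mev_g = k$mean,
    kerma_rel_err = k$rel,
    flux = f$mean,
    flux_rel_err = f$rel,
    primary_flux = p$mean,
    n_histories = n
  )
  class(out) <- c("pd_tally", class(out))
  attr(out, "energy_balance") <- res$energy_balance
  attr(out, "n_batches") <- nb
  attr(out, "seed") <- seed
  out
}

#' Energy bookkeeping of a transport run
#'
#' @param tally a `pd_tally` from [run_transport()]
#' @return tibble with per-batch `source`, `deposited`, `cutoff`, `escaped`
#'   energies (MeV) and their imbalance
#' @export
energy_balance <- function(tally) {
  eb <- attr(tally, "energy_balance")
  tibble::tibble(
    batch = seq_len(ncol(eb)),
    source = eb[1, ],
    deposited = eb[2, ],
    cutoff = eb[3, ],
    escaped = eb[4, ],
    imbalance = eb[1, ] - eb[2, ] - eb[3, ] - eb[4, ]
  )
}

#' @export
print.pd_tally <- function(x, ...) {
  cat(
    "<pd_tally>", nrow(x), "cells,", x$n_histories[1], "histories,",
    attr(x, "n_batches"), "batches (seed", attr(x, "seed"), ")\n"
  )
  NextMethod()
}

#' @rdname tidy_peridose
#' @export
tidy.pd_tally <- function(x, ...) {
  tibble::as_tibble(x)[, c(
    "cell", "organ", "kerma_mev_g", "kerma_rel_err", "flux", "flux_rel_err",
    "primary_flux"
  )]
}

#' @rdname tidy_peridose
#' @export
glance.pd_tally <- function(x, ...) {
  eb <- attr(x, "energy_balance")
  tibble::tibble(
    n_histories = x$n_histories[1],
    n_batches = attr(x, "n_batches"),
    n_cells = nrow(x),
    median_rel_err = stats::median(x$kerma_rel_err, na.rm = TRUE),
    fraction_deposited = sum(eb[2, ]) / sum(eb[1, ]),
    fraction_escaped = sum(eb[4, ]) / sum(eb[1, ])
  )
}
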