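#' Observed edema type labels
#'
#' The five fluid configurations actually observed in center-involving DME,
#' in order of increasing fluid extent/depth, plus the fluid-free control
#' used by the phantom suite.
#'
#' @return character vector of the five observed type labels.
#' @export
observed_types <- function() {
  c("FC/NF", "PC/NF", "PC/DF", "DF/DF", "DF/DF + SF")
}

# per-type randomized geometry, drawn from the *current* RNG stream.
# Constraints keep each configuration inside its extent class:
#   FC: all fluid within the 0.5 mm foveal circle
#   PC: beyond 0.5 mm but within the 1.5 mm parafoveal circle
#   DF: beyond 1.5 mm
preset_fluid <- function(type) {
  ring_pairs <- function(n, rho, rad) {
    ang <- stats::runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = n + 1L)[-1L]
    unlist(lapply(ang, function(a) {
      ctr <- c(rho * cos(a), rho * sin(a))
      list(fluid_pocket("Henle", "cystoid_cluster", ctr, rad),
           fluid_pocket("INL", "cystoid_cluster", ctr, rad))
    }), recursive = FALSE)
  }
  switch(type,
    "control" = list(),
    "FC/NF" = list(
      fluid_pocket("Henle", "cystoid_cluster", c(0, 0),
                   stats::runif(1, 0.25, 0.42))),
    "PC/NF" = c(
      list(fluid_pocket("Henle", "cystoid_cluster", c(0, 0),
                        stats::runif(1, 0.2, 0.35))),
      ring_pairs(sample(4:7, 1), stats::runif(1, 0.65, 0.95),
                 stats::runif(1, 0.22, 0.35))),
    "PC/DF" = c(
      list(fluid_pocket("Henle", "cystoid_cluster", c(0, 0),
                        stats::runif(1, 0.2, 0.35))),
      ring_pairs(sample(4:7, 1), stats::runif(1, 0.65, 0.95),
                 stats::runif(1, 0.22, 0.35)),
      list(fluid_pocket("ONL", "diffuse_sheet", c(0, 0),
                        stats::runif(1, 1.8, 2.2)))),
    "DF/DF" = list(
      fluid_pocket("Henle", "diffuse_sheet", c(0, 0),
                   stats::runif(1, 1.7, 2.1)),
      fluid_pocket("INL", "diffuse_sheet", c(0, 0),
                   stats::runif(1, 1.6, 2.0)),
      fluid_pocket("ONL", "diffuse_sheet", c(0, 0),
                   stats::runif(1, 1.8, 2.2))),
    "DF/DF + SF" = list(
      fluid_pocket("Henle", "diffuse_sheet", c(0, 0),
                   stats::runif(1, 1.7, 2.1)),
      fluid_pocket("INL", "diffuse_sheet", c(0, 0),
                   stats::runif(1, 1.6, 2.0)),
      fluid_pocket("ONL", "diffuse_sheet", c(0, 0),
                   stats::runif(1, 1.8, 2.2))),
    stop("unknown preset type '", type, "'"))
}

# cohort rates observed per type (ERM incidence, EZ disruption, incomplete
# PVD), used to decorate preset phantoms with realistic covariates
preset_rates <- function() {
  data.frame(
    type = observed_types(),
    erm = c(9, 12, 8, 19, 12) / c(24, 25, 16, 37, 26),
    ez = c(0, 5, 5, 25, 25) / c(24, 25, 16, 37, 26),
    pvd = c(10, 8, 7, 16, 17) / c(24, 25, 16, 37, 26))
}

#' Build a phantom spec for one of the observed edema types
#'
#' Draws a randomized (within type constraints) [phantom_spec()] for a
#' given type from the current RNG stream.  Epiretinal membrane, an
#' ellipsoid-zone gap and incomplete PVD are added with the per-type
#' incidence observed in the reference cohort.
#'
#' @param type one of [observed_types()] or `"control"`.
#' @param speckle multiplicative speckle amplitude (0 = noise free).
#' @param seed when given, all randomized geometry is drawn under this
#'   seed (and it also seeds the speckle), making the spec reproducible on
#'   its own; when `NULL` the current RNG stream is used, as
#'   [preset_cohort()] does.
#' @param ... further arguments passed to [phantom_spec()] (e.g. `n_ascans`).
#' @return a [phantom_spec()].
#' @export
preset_spec <- function(type, speckle = 0.15, seed = NULL, ...) {
  if (!is.null(seed)) {
    return(with_local_seed(seed,
      preset_spec(type, speckle = speckle, seed = NULL, ...)))
  }
  rates <- preset_rates()
  known <- type %in% rates$type
  if (!known && type != "control") stop("unknown preset type '", type, "'")
  seed <- sample.int(.Machine$integer.max - 1L, 1L)
  fluid <- preset_fluid(type)
  srf <- NULL
  if (type == "DF/DF + SF") {
    srf <- list(center_mm = stats::runif(2, -0.2, 0.2),
                radius_mm = stats::runif(1, 0.6, 0.9),
                height_um = stats::runif(1, 75, 90))
  }
  erm <- NULL; gap <- NULL; pvd <- "complete"
  if (known) {
    rt <- rates[rates$type == type, ]
    if (stats::runif(1) < rt$erm) {
      erm <- list(fold_depth_um = stats::runif(1, 25, 70),
                  fold_spacing_um = stats::runif(1, 500, 800))
    }
    if (stats::runif(1) < rt$ez) {
      rad <- stats::runif(1, 0.15, 0.4)
      gap <- list(center_mm = stats::runif(2, -rad / 2, rad / 2) /
                    sqrt(2), radius_mm = rad)
    }
    if (stats::runif(1) < rt$pvd) pvd <- "incomplete"
  }
  phantom_spec(fluid_config = fluid, erm_config = erm, ez_gap_config = gap,
               srf_config = srf, pvd_label = pvd,
               noise = list(amplitude = speckle, seed = seed), ...)
}

#' Factory for a cohort of preset phantoms
#'
#' Generates the requested number of phantoms of each observed type (and
#' optionally `"control"`), with geometry randomized within the type
#' constraints.  The same seed reproduces the identical cohort.
#'
#' @param n_per_type named integer vector, names from [observed_types()]
#'   and/or `"control"`.
#' @param seed integer seed controlling all randomization.
#' @param speckle speckle amplitude passed to every spec.
#' @param as `"phantom"` returns generated `(volume, truth)` pairs;
#'   `"spec"` returns the [phantom_spec()] list only (preferred for large
#'   cohorts, generating one volume at a time).
#' @param ... passed to [phantom_spec()] via [preset_spec()].
#' @return list, one element per phantom, ordered by type then replicate.
#' @export
preset_cohort <- function(n_per_type, seed = 1L, speckle = 0.15,
                          as = c("phantom", "spec"), ...) {
  as <- match.arg(as)
  if (is.null(names(n_per_type)) ||
      !all(names(n_per_type) %in% c(observed_types(), "control"))) {
    stop("n_per_type must be named with observed types or 'control'")
  }
  if (any(n_per_type < 0)) stop("n_per_type must be non-negative")
  with_local_seed(seed, {
    specs <- list()
    for (type in names(n_per_type)) {
      for (i in seq_len(n_per_type[[type]])) {
        specs[[length(specs) + 1L]] <- preset_spec(type, speckle = speckle, ...)
      }
    }
    if (as == "spec") specs else lapply(specs, generate_phantom)
  })
}
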