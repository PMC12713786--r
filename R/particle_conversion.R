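#' Particle size estimation from reported size information
#'
#' Toxicity studies report microplastic size in heterogeneous ways; these
#' conventions reduce them to a single characteristic diameter (um):
#' particles sieved through a mesh of size U are assigned U/2 (the sieved
#' fraction is assumed roughly symmetric below the mesh); a sieve band or
#' size range \[L, U\] is assigned its midpoint; a reported median diameter
#' (d50) is used as-is; size-class proportions give the weighted mean of the
#' class midpoints.
#'
#' @param info a list with `kind` (one of `"d50"`, `"sieve_upper"`,
#'   `"sieve_band"`, `"range"`, `"proportions"`) and, depending on kind:
#'   `value` (d50 or the mesh size), `bounds` (length-2 numeric, in either
#'   order), or `classes` (matrix/data.frame with columns `lower`, `upper`)
#'   plus `weights` summing to 1.
#' @return characteristic diameter in micrometers.
#' @export
estimate_diameter <- function(info) {
  kind <- match.arg(info$kind,
                    c("d50", "sieve_upper", "sieve_band", "range",
                      "proportions"))
  mid <- function(b) {
    if (is.null(b) || length(b) != 2L || any(!is.finite(b)) || any(b <= 0)) {
      stop_mp("size bounds must be two positive numbers", class = "mp_size_error")
    }
    mean(range(b))
  }
  switch(kind,
    d50 = {
      v <- info$value
      if (is.null(v) || !is.finite(v) || v <= 0)
        stop_mp("d50 value missing or nonpositive", class = "mp_size_error")
      v
    },
    sieve_upper = {
      v <- info$value
      if (is.null(v) || !is.finite(v) || v <= 0)
        stop_mp("sieve mesh size missing or nonpositive", class = "mp_size_error")
      v / 2
    },
    sieve_band = mid(info$bounds),
    range = mid(info$bounds),
    proportions = {
      cls <- info$classes
      w <- info$weights
      if (is.null(cls) || is.null(w))
        stop_mp("proportions need 'classes' and 'weights'", class = "mp_size_error")
      cls <- as.matrix(as.data.frame(cls)[, c("lower", "upper")])
      if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
        stop_mp("weights must be nonnegative and sum to 1", class = "mp_size_error")
      sum(w * rowMeans(cls))
    }
  )
}

#' Particle volume from shape and dimensions
#'
#' Spheres use `(4/3) pi (d/2)^3`; fibers are cylinders `pi (d/2)^2 L`;
#' films are square-faced slabs `L^2 t` (set `width` for rectangular faces).
#' Dimensions in micrometers, result in cm^3 (1 um^3 = 1e-12 cm^3).
#'
#' @param spec list with `shape` (`"sphere"`, `"fiber"`, `"film"`) and
#'   dimensions in um: `diameter` (sphere/fiber), `length` (fiber length or
#'   film side), `thickness` (film), optional `width` (film).
#' @return particle volume in cm^3.
#' @export
particle_volume <- function(spec) {
  shape <- match.arg(spec$shape, c("sphere", "fiber", "film"))
  need <- function(v, what) {
    if (is.null(v) || is.na(v) || !is.finite(v) || v <= 0) {
      stop_mp("%s particle needs a positive %s", shape, what,
              class = "mp_particle_error")
    }
    v
  }
  um3 <- switch(shape,
    sphere = (4 / 3) * pi * (need(spec$diameter, "diameter") / 2)^3,
    fiber = pi * (need(spec$diameter, "diameter") / 2)^2 *
      need(spec$length, "length"),
    film = need(spec$length, "length") *
      (if (!is.null(spec$width) && !is.na(spec$width)) need(spec$width, "width")
       else need(spec$length, "length")) *
      need(spec$thickness, "thickness")
  )
  um3 * 1e-12
}

#' Convert between mass and particle-number concentrations
#'
#' A concentration of `c` mg of plastic per kg dry weight corresponds to
#' `c * 1e-3 / (density * volume)` particles per kg, where `density`
#' (g/cm^3) times `volume` (cm^3) is the mass of one particle in grams.
#' `number_to_mass()` is the exact inverse (used to pin the round-trip
#' property).
#'
#' @param conc_mg_per_kg mass concentration, mg per kg dry weight (>= 0).
#' @param conc_nb_per_kg number concentration, particles per kg dry weight.
#' @param spec particle spec as in [particle_volume()] plus `density`
#'   (g/cm^3).
#' @return the converted concentration.
#' @export
mass_to_number <- function(conc_mg_per_kg, spec) {
  if (any(conc_mg_per_kg < 0)) {
    stop_mp("mass concentration must be >= 0", class = "mp_precondition_error")
  }
  conc_mg_per_kg * 1e-3 / particle_mass_g(spec)
}

#' @rdname mass_to_number
#' @export
number_to_mass <- function(conc_nb_per_kg, spec) {
  if (any(conc_nb_per_kg < 0)) {
    stop_mp("number concentration must be >= 0", class = "mp_precondition_error")
  }
  conc_nb_per_kg * particle_mass_g(spec) * 1e3
}

particle_mass_g <- function(spec) {
  dens <- spec$density
  if (is.null(dens) || is.na(dens) || dens <= 0) {
    stop_mp("particle density must be positive", class = "mp_particle_error")
  }
  m <- dens * particle_volume(spec)
  if (m <= 0) stop_mp("particle mass must be positive", class = "mp_particle_error")
  m
}

#' Polymer density lookup
#'
#' An entry-provided density always wins; otherwise the polymer is looked up
#' in the density table. The shipped default table
#' (`inst/extdata/densities.csv`) carries standard literature densities for
#' common polymers; it is an editable stand-in, not measured data.
#'
#' @param polymer polymer code, e.g. `"PE"`.
#' @param table named numeric vector or data.frame with columns `polymer`,
#'   `density_g_per_cm3`; default [default_density_table()].
#' @param entry_density optional density from the source study (g/cm^3).
#' @return density in g/cm^3.
#' @export
default_density <- function(polymer, table = default_density_table(),
                            entry_density = NA_real_) {
  if (!is.na(entry_density)) {
    if (entry_density <= 0) stop_mp("entry density must be positive",
                                    class = "mp_particle_error")
    return(entry_density)
  }
  if (is.data.frame(table)) {
    table <- stats::setNames(table$density_g_per_cm3, table$polymer)
  }
  if (is.na(polymer) || !polymer %in% names(table)) {
    stop_mp("unknown polymer '%s' and no entry density; known polymers: %s",
            polymer %||% "NA", paste(sort(names(table)), collapse = ", "),
            class = "mp_particle_error")
  }
  unname(table[[polymer]])
}

#' @rdname default_density
#' @export
default_density_table <- function() {
  path <- system.file("extdata", "densities.csv", package = "mpsoilrisk")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Build a particle spec list from the particle_* columns of a toxicity row.
particle_spec_from_row <- function(row, densities = default_density_table(),
                                   default_fiber_diameter_um = 20) {
  shape <- row$particle_shape
  if (is.na(shape) || !nzchar(shape)) {
    stop_mp("entry '%s': particle shape required for mg/kg conversion",
            row$entry_id, class = "mp_particle_error")
  }
  diameter <- row$particle_diameter_um
  if (identical(shape, "fiber") && (is.na(diameter) || diameter <= 0)) {
    diameter <- default_fiber_diameter_um  # common reported fiber diameter
  }
  dens <- default_density(row$particle_polymer %||% NA_character_,
                          densities,
                          entry_density = row$particle_density_g_cm3 %||% NA_real_)
  list(shape = shape, diameter = diameter, length = row$particle_length_um,
       thickness = row$particle_thickness_um, density = dens)
}
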