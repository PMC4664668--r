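# Species and material constants, electronic stopping power, CSDA range and
# its inverse for the therapy ions (p, d, He-4, Li-7, C-12) in water.

# Bethe constants (MeV-based units)
.K_BETHE <- 0.307075   # 4 pi N_A r_e^2 m_e c^2, MeV cm^2 / g (per Z/A)
.M_ELECTRON <- 0.510999 # MeV

# validity window for the stopping model, MeV/u
.E_MIN <- 1
.E_MAX <- 500

.pkg_cache <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "minibeamtx")
  if (!nzchar(path)) stop("missing package data file: ", file, call. = FALSE)
  path
}

.species_table <- function() {
  if (is.null(.pkg_cache$species_table)) {
    .pkg_cache$species_table <- utils::read.delim(
      .extdata("ion_species.tsv"), comment.char = "#",
      stringsAsFactors = FALSE
    )
  }
  .pkg_cache$species_table
}

.materials_table <- function() {
  if (is.null(.pkg_cache$materials_table)) {
    .pkg_cache$materials_table <- utils::read.delim(
      .extdata("materials.tsv"), comment.char = "#",
      stringsAsFactors = FALSE
    )
  }
  .pkg_cache$materials_table
}

#' Ion species used in minibeam therapy calculations
#'
#' Looks up one of the five supported therapy ions (proton, deuteron,
#' helium-4, lithium-7, carbon-12) from the species table shipped with the
#' package, or constructs a custom species from explicit constants.
#'
#' @param name Species name or alias (e.g. `"proton"`, `"p"`, `"li7"`,
#'   `"carbon12"`). Case-insensitive.
#' @param z Charge number (only for a custom species).
#' @param a Mass number (only for a custom species).
#' @param m_u Rest energy per nucleon in MeV (only for a custom species).
#' @return An object of class `ion_species` with fields `name`, `z`, `a`,
#'   `m_u` (MeV per nucleon).
#' @examples
#' ion_species("proton")
#' ion_species("li7")
#' @export
ion_species <- function(name, z = NULL, a = NULL, m_u = NULL) {
  if (!is.null(z) || !is.null(a) || !is.null(m_u)) {
    stopifnot(is.numeric(z), is.numeric(a), is.numeric(m_u))
    sp <- list(name = as.character(name), z = z, a = a, m_u = m_u)
  } else {
    tab <- .species_table()
    key <- tolower(as.character(name))
    hit <- which(tolower(tab$name) == key |
                   vapply(strsplit(tab$aliases, ";"),
                          function(al) key %in% tolower(al), logical(1)))
    if (length(hit) != 1L)
      stop("unknown ion species: ", name, call. = FALSE)
    sp <- list(name = tab$name[hit], z = tab$z[hit], a = tab$a[hit],
               m_u = tab$m_u[hit])
  }
  if (sp$z < 1 || sp$a < sp$z)
    stop("invalid species constants: need z >= 1 and a >= z", call. = FALSE)
  if (abs(sp$m_u - 931.5) / 931.5 > 0.01)
    stop("rest energy per nucleon must be within 1% of 931.5 MeV",
         call. = FALSE)
  structure(sp, class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("<ion_species> %s (z=%d, a=%d, m_u=%.3f MeV)\n",
              x$name, x$z, x$a, x$m_u))
  invisible(x)
}

#' Target material
#'
#' Constructs a material description for the transport and stopping models.
#' The default instance, [water_material()], is liquid water, the reference
#' medium for all depth-dose work here.
#'
#' @param name Material name; must be present in the shipped materials table
#'   unless all constants are given.
#' @param density Mass density in g/cm^3.
#' @param radiation_length Radiation length in g/cm^2.
#' @param mean_excitation_energy Mean excitation energy I in eV.
#' @param electrons_per_gram Electron density in 1/g.
#' @return An object of class `material`.
#' @export
material <- function(name, density = NULL, radiation_length = NULL,
                     mean_excitation_energy = NULL,
                     electrons_per_gram = NULL) {
  if (is.null(density)) {
    tab <- .materials_table()
    hit <- which(tolower(tab$name) == tolower(name))
    if (length(hit) != 1L)
      stop("unknown material: ", name, call. = FALSE)
    m <- as.list(tab[hit, ])
  } else {
    m <- list(name = name, density = density,
              radiation_length = radiation_length,
              mean_excitation_energy = mean_excitation_energy,
              electrons_per_gram = electrons_per_gram)
  }
  vals <- unlist(m[c("density", "radiation_length",
                     "mean_excitation_energy", "electrons_per_gram")])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("material constants must all be positive", call. = FALSE)
  structure(m, class = "material")
}

#' @rdname material
#' @export
water_material <- function() {
  if (is.null(.pkg_cache$water)) .pkg_cache$water <- material("water")
  .pkg_cache$water
}

#' Beam energy specification
#'
#' @param kinetic_energy_per_nucleon Kinetic energy in MeV per nucleon.
#' @param energy_spread_fwhm FWHM of the energy distribution in MeV/u
#'   (0 for a monoenergetic beam).
#' @return An object of class `energy_spec`.
#' @export
energy_spec <- function(kinetic_energy_per_nucleon, energy_spread_fwhm = 0) {
  stopifnot(kinetic_energy_per_nucleon > 0, energy_spread_fwhm >= 0)
  structure(list(kinetic_energy_per_nucleon = kinetic_energy_per_nucleon,
                 energy_spread_fwhm = energy_spread_fwhm),
            class = "energy_spec")
}

.as_energy <- function(E) {
  if (inherits(E, "energy_spec")) E$kinetic_energy_per_nucleon else as.numeric(E)
}

.check_E <- function(E) {
  if (any(E < .E_MIN | E > .E_MAX))
    stop(sprintf("energy outside stopping-model validity [%g, %g] MeV/u",
                 .E_MIN, .E_MAX), call. = FALSE)
  E
}

# beta^2 and gamma^2 from kinetic energy per nucleon
.kinematics <- function(E, m_u) {
  g <- 1 + E / m_u
  list(beta2 = 1 - 1 / g^2, gamma2 = g^2)
}

#' Electronic stopping power
#'
#' Plain Bethe electronic stopping power of an ion in a material, without
#' shell or density-effect corrections (sub-percent at therapy energies).
#' For water the mean excitation energy is 75 eV.
#'
#' @param species An [ion_species()].
#' @param E Kinetic energy in MeV per nucleon, in `[1, 500]`. Vectorised.
#' @param material A [material()]; defaults to water.
#' @return Stopping power of the whole ion in MeV/cm.
#' @examples
#' stopping_power(ion_species("proton"), 109)
#' @export
stopping_power <- function(species, E, material = water_material()) {
  stopifnot(inherits(species, "ion_species"))
  E <- .check_E(.as_energy(E))
  k <- .kinematics(E, species$m_u)
  I <- material$mean_excitation_energy * 1e-6 # eV -> MeV
  za <- material$electrons_per_gram / 6.02214e23 # Z/A of the medium
  .K_BETHE * species$z^2 * za * material$density / k$beta2 *
    (log(2 * .M_ELECTRON * k$beta2 * k$gamma2 / I) - k$beta2)
}

# cached monotone splines E <-> cumulative CSDA range for a species/material
.range_tables <- function(species, material) {
  key <- paste(species$name, species$z, species$a, material$name, sep = "|")
  tab <- .pkg_cache$range_tables
  if (is.null(tab)) tab <- list()
  if (is.null(tab[[key]])) {
    # log-spaced quadrature grid from the 1 MeV/u cutoff (residual range
    # below the cutoff treated as zero; < 0.1 mm)
    Eg <- exp(seq(log(.E_MIN), log(.E_MAX), length.out = 600))
    inv_s <- species$a / stopping_power(species, Eg, material) # cm per MeV/u
    R <- c(0, cumsum(diff(Eg) * (inv_s[-1] + inv_s[-length(inv_s)]) / 2))
    tab[[key]] <- list(
      E_to_R = stats::splinefun(Eg, R, method = "hyman"),
      R_to_E = stats::splinefun(R, Eg, method = "hyman"),
      R_max = max(R)
    )
    .pkg_cache$range_tables <- tab
  }
  tab[[key]]
}

#' CSDA range in a material
#'
#' Continuous-slowing-down range, `R(E) = integral of dE'/S(E')` from a
#' 1 MeV/u cutoff, by trapezoidal quadrature on a log-spaced energy grid.
#'
#' @inheritParams stopping_power
#' @return Range in cm. Vectorised over `E`.
#' @examples
#' csda_range(ion_species("proton"), 109) # about 9 cm in water
#' @export
csda_range <- function(species, E, material = water_material()) {
  stopifnot(inherits(species, "ion_species"))
  E <- .check_E(.as_energy(E))
  .range_tables(species, material)$E_to_R(E)
}

#' Energy whose CSDA range equals a given depth
#'
#' Inverse of [csda_range()] by root finding on the cached range table;
#' round-trip residual is below 0.01 cm.
#'
#' @inheritParams stopping_power
#' @param R Target range in cm, in `[0.5, 40]`.
#' @return Kinetic energy in MeV per nucleon. Vectorised over `R`.
#' @examples
#' energy_for_range(ion_species("proton"), 10) # about 116 MeV
#' @export
energy_for_range <- function(species, R, material = water_material()) {
  stopifnot(inherits(species, "ion_species"))
  R <- as.numeric(R)
  if (any(R < 0.5 | R > 40))
    stop("range outside supported window [0.5, 40] cm", call. = FALSE)
  rt <- .range_tables(species, material)
  if (any(R > rt$R_max))
    stop("range not achievable within the stopping-model validity window",
         call. = FALSE)
  E0 <- rt$R_to_E(R)
  # one refinement pass against the forward table
  vapply(seq_along(R), function(i) {
    stats::uniroot(function(e) rt$E_to_R(e) - R[i],
                   lower = max(.E_MIN, E0[i] * 0.9),
                   upper = min(.E_MAX, E0[i] * 1.1),
                   tol = 1e-10, extendInt = "upX")$root
  }, numeric(1))
}

#' Relativistic momentum times velocity
#'
#' The product p*beta*c of the whole ion in MeV, the kinematic quantity
#' entering the Highland scattering formula. Closed form
#' `a * (E^2 + 2 E m_u) / (E + m_u)` with E the kinetic energy per nucleon.
#'
#' @inheritParams stopping_power
#' @param E Kinetic energy in MeV per nucleon (> 0). Vectorised.
#' @return p*beta*c in MeV (total, for the whole ion).
#' @export
momentum_beta <- function(species, E) {
  stopifnot(inherits(species, "ion_species"))
  E <- .as_energy(E)
  if (any(E <= 0)) stop("energy must be positive", call. = FALSE)
  species$a * (E^2 + 2 * E * species$m_u) / (E + species$m_u)
}
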