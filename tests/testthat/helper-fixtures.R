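# Shared study-condition fixtures: the canonical beams used throughout the
# test suite. Geometry parameters (0.3-mm incident width, 1.0 / 1.05-mm
# on-center spacings, 10-cm range, 109 MeV protons, 6.5-mm rabbit target)
# are the reference conditions and are never adjusted per test.

fx_proton_pencil_109 <- function() {
  beam_spec("proton", 109, shape = "pencil", incident_width_fwhm = 0.3)
}

fx_planar_10cm <- function(species, spacing = 1.0) {
  sp <- ion_species(species)
  beam_spec(sp, energy_for_range(sp, 10), shape = "planar",
            incident_width_fwhm = 0.3, spacing_on_center = spacing)
}

fx_pencil_10cm <- function(species, spacing = 0.5) {
  sp <- ion_species(species)
  beam_spec(sp, energy_for_range(sp, 10), shape = "pencil",
            incident_width_fwhm = 0.3, spacing_on_center = spacing)
}

# rabbit-geometry interleave plan: carbon, 6.5-mm target centred in a
# 78.5-mm phantom, 1.05-mm on-center spacing, 14-Gy pedestal, RBE 3
fx_rabbit_plan <- function(phantom_half_size = 39.25,
                           directions = c("+x", "-x", "+y", "-y")) {
  interleave_plan("carbon12", target_size = c(6.5, 6.5),
                  phantom_half_size = phantom_half_size,
                  incident_width_fwhm = 0.3, spacing_on_center = 1.05,
                  pedestal_dose_gy = 14, pedestal_to_sobp_ratio = 20 / 14,
                  rbe = 3.0, directions = directions)
}

# carbon energy of the distal rabbit SOBP layer (range = 42.5 mm)
fx_carbon_rabbit_energy <- function() {
  energy_for_range(ion_species("carbon12"), 4.25)
}
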