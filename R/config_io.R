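# Configuration files, canonical fixtures, artifact export with metadata
# headers, and the verb dispatcher behind the command-line interface.

.CONFIG_SCHEMA <- list(
  beam = c("species", "energy_mev_u", "range_cm", "shape",
           "incident_width_fwhm_mm", "spacing_on_center_mm",
           "angular_divergence_mrad", "incident_profile"),
  phantom = c("depth_mm", "dz_mm", "lateral_resolution_mm"),
  plan = c("target_center_mm", "target_size_mm", "phantom_half_size_mm",
           "directions", "pedestal_dose_gy", "pedestal_to_sobp_ratio",
           "rbe", "width_limit_mm"),
  sobp = c("proximal_mm", "distal_mm", "n_layers"),
  model = c("merge_rule", "merge_threshold", "sparing_factor"),
  seed = NULL, provenance = NULL, name = NULL
)

.BEAM_DEFAULTS <- list(shape = "planar", incident_width_fwhm_mm = 0.3,
                       spacing_on_center_mm = 0,
                       angular_divergence_mrad = 0,
                       incident_profile = "gaussian")
.PHANTOM_DEFAULTS <- list(depth_mm = 80, dz_mm = 0.1,
                          lateral_resolution_mm = 0.01)
.MODEL_DEFAULTS <- list(merge_rule = "valley_peak_threshold",
                        merge_threshold = 0.95, sparing_factor = 7)
.PLAN_DEFAULTS <- list(target_center_mm = c(0, 0),
                       target_size_mm = c(6.5, 6.5),
                       phantom_half_size_mm = 39.25,
                       directions = c("+x", "-x", "+y", "-y"),
                       pedestal_dose_gy = 14,
                       pedestal_to_sobp_ratio = 20 / 14,
                       rbe = 3.0, width_limit_mm = 0.7)

.fill_defaults <- function(section, defaults) {
  for (k in names(defaults))
    if (is.null(section[[k]])) section[[k]] <- defaults[[k]]
  section
}

.validate_config <- function(cfg, path = "<config>") {
  bad_top <- setdiff(names(cfg), names(.CONFIG_SCHEMA))
  if (length(bad_top) > 0)
    stop(sprintf("%s: unknown config key(s): %s", path,
                 paste(bad_top, collapse = ", ")), call. = FALSE)
  for (sec in intersect(names(cfg),
                        c("beam", "phantom", "plan", "sobp", "model"))) {
    bad <- setdiff(names(cfg[[sec]]), .CONFIG_SCHEMA[[sec]])
    if (length(bad) > 0)
      stop(sprintf("%s: unknown key(s) in '%s': %s", path, sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (is.null(cfg$beam) || is.null(cfg$beam$species))
    stop(path, ": config needs a beam section with a species",
         call. = FALSE)
  if (is.null(cfg$beam$energy_mev_u) && is.null(cfg$beam$range_cm))
    stop(path, ": beam needs either energy_mev_u or range_cm",
         call. = FALSE)
  invisible(cfg)
}

#' Load a run configuration
#'
#' Reads a YAML configuration describing a beam, a water phantom and
#' (optionally) an interleave plan or SOBP, validates it against a strict
#' schema (unknown keys are rejected by name), and fills in all defaults
#' (0.3-mm incident width, planar shape, zero divergence, valley/peak 0.95
#' merge rule, sparing factor 7).
#'
#' @param path Path to a YAML file.
#' @return An object of class `run_config` with all defaults explicit.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg, path = path)
}

#' @rdname load_config
#' @param cfg A bare list with the same structure as the YAML file.
#' @export
as_run_config <- function(cfg, path = "<config>") {
  .validate_config(cfg, path)
  cfg$beam <- .fill_defaults(cfg$beam, .BEAM_DEFAULTS)
  cfg$phantom <- .fill_defaults(if (is.null(cfg$phantom)) list()
                                else cfg$phantom, .PHANTOM_DEFAULTS)
  cfg$model <- .fill_defaults(if (is.null(cfg$model)) list()
                              else cfg$model, .MODEL_DEFAULTS)
  if (!is.null(cfg$plan))
    cfg$plan <- .fill_defaults(cfg$plan, .PLAN_DEFAULTS)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "run_config")
}

#' Save a run configuration
#'
#' Writes a `run_config` back to YAML; [load_config()] of the result
#' round-trips to an identical configuration.
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  writeLines(yaml::as.yaml(unclass(config), precision = 12), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(yaml::as.yaml(unclass(x), precision = 12))
  invisible(x)
}

# 32-bit FNV-1a hash of the canonical YAML text, as 8 hex digits
config_hash <- function(config) {
  txt <- yaml::as.yaml(unclass(config), precision = 12)
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256 # xor affects the low byte only (b < 256)
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit modular multiply in exact double arithmetic
    h16 <- h %% 65536
    h <- (h16 * 16777619 +
            (((h - h16) / 65536 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  # h can exceed .Machine$integer.max, so format as two 16-bit halves
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Build the beam described by a run configuration
#'
#' @param config A `run_config`.
#' @return A [beam_spec()].
#' @export
config_beam <- function(config) {
  stopifnot(inherits(config, "run_config"))
  b <- config$beam
  sp <- ion_species(b$species)
  E <- if (!is.null(b$energy_mev_u)) b$energy_mev_u
       else energy_for_range(sp, b$range_cm)
  beam_spec(sp, E, shape = b$shape,
            incident_width_fwhm = b$incident_width_fwhm_mm,
            spacing_on_center = b$spacing_on_center_mm,
            angular_divergence_rms = b$angular_divergence_mrad,
            incident_profile = b$incident_profile)
}

.config_plan <- function(config) {
  p <- config$plan
  if (is.null(p)) stop("config has no plan section", call. = FALSE)
  interleave_plan(config$beam$species,
                  target_center = unlist(p$target_center_mm),
                  target_size = unlist(p$target_size_mm),
                  phantom_half_size = p$phantom_half_size_mm,
                  incident_width_fwhm = config$beam$incident_width_fwhm_mm,
                  spacing_on_center = config$beam$spacing_on_center_mm,
                  directions = unlist(p$directions),
                  pedestal_dose_gy = p$pedestal_dose_gy,
                  pedestal_to_sobp_ratio = p$pedestal_to_sobp_ratio,
                  rbe = p$rbe, width_limit = p$width_limit_mm)
}

# the five canonical configurations
.fixture_list <- function() {
  list(
    list(name = "proton-pencil-109mev",
         provenance = paste("109-MeV proton pencil minibeam, 0.3-mm",
                            "incident size; film-stack broadening",
                            "benchmark"),
         beam = list(species = "proton", energy_mev_u = 109,
                     shape = "pencil"),
         phantom = list(depth_mm = 80)),
    list(name = "proton-planar-10cm",
         provenance = paste("planar proton minibeam array, 0.3 mm /",
                            "1.0 mm on-center, energy for 10-cm range"),
         beam = list(species = "proton", range_cm = 10, shape = "planar",
                     spacing_on_center_mm = 1.0),
         phantom = list(depth_mm = 90)),
    list(name = "li7-planar-10cm",
         provenance = paste("planar lithium-7 minibeam array, 0.3 mm /",
                            "1.0 mm on-center, energy for 10-cm range"),
         beam = list(species = "lithium7", range_cm = 10, shape = "planar",
                     spacing_on_center_mm = 1.0),
         phantom = list(depth_mm = 90)),
    list(name = "he4-pencil-10cm",
         provenance = paste("pencil helium-4 minibeam lattice, 0.3 mm /",
                            "0.5 mm on-center, energy for 10-cm range"),
         beam = list(species = "helium4", range_cm = 10, shape = "pencil",
                     spacing_on_center_mm = 0.5),
         phantom = list(depth_mm = 90)),
    list(name = "carbon-interleave-rabbit",
         provenance = paste("four-directional interleaved carbon",
                            "minibeams, 0.3 mm / 1.05 mm on-center, 6.5-mm",
                            "target at 36-mm depth, 14-Gy pedestal, RBE 3"),
         beam = list(species = "carbon12", range_cm = 4.25,
                     shape = "planar", spacing_on_center_mm = 1.05),
         phantom = list(depth_mm = 40),
         plan = list(target_size_mm = c(6.5, 6.5),
                     phantom_half_size_mm = 39.25,
                     pedestal_dose_gy = 14,
                     pedestal_to_sobp_ratio = 20 / 14,
                     rbe = 3.0))
  )
}

#' Generate the canonical fixture configurations
#'
#' Writes the five canonical configurations (single 109-MeV proton pencil
#' beam; 10-cm-range proton and Li-7 planar arrays; 10-cm-range He-4
#' pencil lattice; the four-directional interleaved carbon geometry) as
#' YAML files. Regeneration is deterministic and byte-identical.
#'
#' @param outdir Writable output directory (created if needed).
#' @return Invisibly, a list of `fixture` objects (`name`, `config`,
#'   `provenance`, `path`).
#' @export
generate_fixtures <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- lapply(.fixture_list(), function(fx) {
    cfg <- as_run_config(fx[setdiff(names(fx), character())])
    path <- file.path(outdir, paste0(fx$name, ".yaml"))
    save_config(cfg, path)
    structure(list(name = fx$name, config = cfg,
                   provenance = fx$provenance, path = path),
              class = "fixture")
  })
  invisible(out)
}

# ---- artifact writers -------------------------------------------------

.meta_header <- function(config, extra = character()) {
  c(sprintf("# minibeamtx %s",
            as.character(utils::packageVersion("minibeamtx"))),
    sprintf("# config_hash: %s", config_hash(config)),
    sprintf("# seed: %d", as.integer(config$seed)),
    sprintf("# %s", extra))
}

#' Export a width curve as CSV
#'
#' Two columns (`depth_mm`, `fwhm_mm`) under a comment header carrying the
#' package version, configuration hash, seed and beam metadata.
#'
#' @param wc A [width_curve()] result.
#' @param path Output path.
#' @param config Optional `run_config` for the metadata header.
#' @return The path, invisibly.
#' @export
write_width_curve <- function(wc, path, config = NULL) {
  stopifnot(inherits(wc, "width_curve"))
  b <- attr(wc, "beam")
  lines <- c(
    if (!is.null(config)) .meta_header(config),
    sprintf("# beam: %s %.6g MeV/u, %s, incident %.3g mm",
            b$species$name, b$energy$kinetic_energy_per_nucleon, b$shape,
            b$incident_width_fwhm),
    "depth_mm,fwhm_mm",
    sprintf("%.4f,%.6f", wc$depth, wc$fwhm))
  writeLines(lines, path)
  invisible(path)
}

.write_matrix_csv <- function(mat, row_vals, col_vals, row_name, col_name,
                              path, header = character()) {
  lines <- c(header,
             paste(c(paste0(row_name, "\\", col_name),
                     sprintf("%.4f", col_vals)), collapse = ","))
  body <- vapply(seq_along(row_vals), function(i)
    paste(c(sprintf("%.4f", row_vals[i]),
            sprintf("%.6g", mat[i, ])), collapse = ","),
    character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

# ---- verb dispatcher --------------------------------------------------

.VERBS <- c("broaden", "merge-depth", "array-map", "sobp",
            "compare-depth-dose", "plan-interleave", "fixtures")

.model_error <- function(e) {
  structure(class = c("minibeamtx_model_error", "error", "condition"),
            list(message = conditionMessage(e), call = NULL))
}

#' Run a command verb
#'
#' Programmatic equivalent of the command-line interface: executes one
#' verb against a configuration and writes CSV/JSON artifacts with
#' metadata headers (package version, seed, configuration hash).
#'
#' @param verb One of `"broaden"`, `"merge-depth"`, `"array-map"`,
#'   `"sobp"`, `"compare-depth-dose"`, `"plan-interleave"`,
#'   `"fixtures"`.
#' @param config A `run_config`, or a path to a YAML configuration
#'   (not needed for `"fixtures"`).
#' @param out Output file path (directory for `"fixtures"`); defaults to
#'   a verb-derived name in the working directory.
#' @return Invisibly, a list with the computed object and the artifact
#'   path(s).
#' @export
run_command <- function(verb, config = NULL, out = NULL) {
  if (!verb %in% .VERBS)
    stop(sprintf("unknown verb '%s' (expected one of: %s)", verb,
                 paste(.VERBS, collapse = ", ")), call. = FALSE)
  if (verb == "fixtures") {
    if (is.null(out)) out <- "fixtures"
    fx <- generate_fixtures(out)
    return(invisible(list(result = fx,
                          paths = vapply(fx, `[[`, "", "path"))))
  }
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  beam <- config_beam(config)
  R_mm <- csda_range(beam$species, beam$energy) * 10
  z_max <- min(config$phantom$depth_mm, .RANGE_FRACTION * R_mm)
  dz <- config$phantom$dz_mm

  if (verb == "broaden") {
    if (is.null(out)) out <- "width_curve.csv"
    wc <- width_curve(beam, z_max = z_max, dz = dz)
    write_width_curve(wc, out, config)
    return(invisible(list(result = wc, paths = out)))
  }
  if (verb == "merge-depth") {
    if (is.null(out)) out <- "merge_report.json"
    md <- merge_depth(beam, rule = config$model$merge_rule,
                      threshold = config$model$merge_threshold)
    rep <- list(meta = list(version = as.character(
                              utils::packageVersion("minibeamtx")),
                            config_hash = config_hash(config),
                            seed = config$seed),
                merge_depth_mm = md$merge_depth,
                merge_depth_fwhm_rule_mm = md$merge_depth_fwhm_rule,
                merge_depth_valley_rule_mm = md$merge_depth_valley_rule,
                rule = md$rule,
                valley_peak_threshold =
                  md$criterion_parameters$valley_peak_threshold)
    jsonlite::write_json(rep, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(list(result = md, paths = out)))
  }
  if (verb == "array-map") {
    if (is.null(out)) out <- "array_map.csv"
    depths <- seq(0, z_max, by = max(1, dz * 10))
    am <- array_dose_map(beam, depths,
                         grid_resolution =
                           config$phantom$lateral_resolution_mm * 5)
    .write_matrix_csv(am$dose, am$depths, am$positions, "depth_mm",
                      "x_mm", out, .meta_header(config))
    return(invisible(list(result = am, paths = out)))
  }
  if (verb == "sobp") {
    if (is.null(out)) out <- "sobp.csv"
    if (is.null(config$sobp))
      stop("config has no sobp section", call. = FALSE)
    s <- build_sobp(beam$species, config$sobp$proximal_mm,
                    config$sobp$distal_mm,
                    n_layers = if (is.null(config$sobp$n_layers)) 17
                               else config$sobp$n_layers)
    lines <- c(.meta_header(config,
                            sprintf("flatness: %.4f", s$flatness)),
               "depth_mm,dose_rel",
               sprintf("%.4f,%.6g", s$curve$depth, s$curve$dose))
    writeLines(lines, out)
    return(invisible(list(result = s, paths = out)))
  }
  if (verb == "compare-depth-dose") {
    if (is.null(out)) out <- "depth_dose_comparison.csv"
    if (is.null(config$sobp))
      stop("config has no sobp section", call. = FALSE)
    s <- build_sobp(beam$species, config$sobp$proximal_mm,
                    config$sobp$distal_mm,
                    n_layers = if (is.null(config$sobp$n_layers)) 17
                               else config$sobp$n_layers)
    cmp <- compose_depth_dose_comparison(
      s, beam, sparing_factor = config$model$sparing_factor,
      merge_rule = config$model$merge_rule)
    lines <- c(.meta_header(config,
                            sprintf("merge_depth_mm: %.2f",
                                    cmp$merge_depth_mm)),
               "depth_mm,photon,solid_sobp,minibeam_biological",
               sprintf("%.4f,%.6g,%.6g,%.6g", cmp$solid$depth,
                       cmp$photon$dose, cmp$solid$dose,
                       cmp$minibeam$dose))
    writeLines(lines, out)
    return(invisible(list(result = cmp, paths = out)))
  }
  if (verb == "plan-interleave") {
    if (is.null(out)) out <- "plan_report.json"
    plan <- .config_plan(config)
    map <- compose_interleaved_dose(plan, lateral_res = 0.25)
    rep <- map$report
    json <- list(meta = list(version = as.character(
                               utils::packageVersion("minibeamtx")),
                             config_hash = config_hash(config),
                             seed = config$seed),
                 width_at_proximal_edge_mm =
                   as.list(rep$width_at_proximal_edge),
                 covered = rep$covered, reason = rep$reason,
                 target_physical_dose_gy = rep$target_physical_dose,
                 target_gye = rep$target_gye,
                 incident_dose_factor_range =
                   as.list(rep$incident_dose_factor_range),
                 max_proximal_depth_mm = rep$max_proximal_depth)
    jsonlite::write_json(json, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    map_path <- sub("\\.json$", "_map.csv", out)
    .write_matrix_csv(map$dose, map$x, map$y, "x_mm", "y_mm", map_path,
                      .meta_header(config))
    return(invisible(list(result = map, paths = c(out, map_path))))
  }
}
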