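SCENARIO_KEYS <- c("name", "constants", "ion", "barrier", "leak",
                   "geometry", "sweep", "output_path")
SWEEP_KEYS <- c("kind", "axis", "G_grid", "axis_values",
                "channel_density_D", "transmission_mode")

#' Default scenario
#'
#' A fully populated scenario with the package's default parameter set:
#' sodium tunneling through a G = 2e-20 J, L = 1e-10 m intracellular gate
#' (n = 1) at D = 1e10 channels/cm2, the default basolateral leak profile
#' and axon geometry, and a gate-length barrier-height sweep over a 50-point
#' descending grid from 4e-20 to 1e-20 J.
#'
#' @return An object of class `scenario`.
#' @export
default_scenario <- function() {
  structure(list(
    name = "default",
    constants = physical_constants(),
    ion = ion("Na"),
    barrier = eckart_barrier(2e-20, 1e-10, 1L),
    leak = leak_profile(),
    geometry = axon_geometry(),
    sweep = list(kind = "ghk", axis = "gate_length",
                 G_grid = seq(4e-20, 1e-20, length.out = 50),
                 axis_values = NULL,
                 channel_density_D = 1e10,
                 transmission_mode = "approx"),
    output_path = NULL), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': ion %s, G = %g J, L = %g m, n = %d\n",
              x$name, x$ion$name, x$barrier$height_G,
              x$barrier$gate_length_L, x$barrier$gate_location_n))
  cat(sprintf("  sweep: %s along %s, %d G points, D = %g /cm2\n",
              x$sweep$kind, x$sweep$axis, length(x$sweep$G_grid),
              x$sweep$channel_density_D))
  invisible(x)
}

merge_known <- function(defaults, overrides, what, allowed = names(defaults)) {
  if (is.null(overrides)) return(defaults)
  if (!is.list(overrides)) stop(what, " must be a key-value mapping")
  unknown <- setdiff(names(overrides), allowed)
  if (length(unknown))
    stop("unknown key(s) in ", what, ": ", paste(unknown, collapse = ", "))
  defaults[names(overrides)] <- overrides
  defaults
}

scenario_from_list <- function(raw, origin = "scenario") {
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), SCENARIO_KEYS)
  if (length(unknown))
    stop("unknown key(s) in ", origin, ": ", paste(unknown, collapse = ", "))
  sc <- default_scenario()
  if (!is.null(raw$name)) sc$name <- as.character(raw$name)
  if (!is.null(raw$constants))
    sc$constants <- do.call(physical_constants,
      merge_known(unclass(physical_constants()), raw$constants, "constants"))
  if (!is.null(raw$ion)) {
    sc$ion <- if (is.character(raw$ion)) ion(raw$ion) else {
      d <- unclass(ion("Na"))[c("name", "mass_m", "valence",
                                "conc_extracellular", "conc_intracellular")]
      do.call(ion_species, merge_known(d, raw$ion, "ion"))
    }
  }
  if (!is.null(raw$barrier)) {
    d <- unclass(sc$barrier)
    sc$barrier <- do.call(eckart_barrier, merge_known(d, raw$barrier, "barrier"))
  }
  if (sc$barrier$gate_length_L >= 1e-8)
    stop("barrier gate_length_L = ", sc$barrier$gate_length_L,
         " m looks mis-scaled (expected < 1e-8 m, i.e. sub-nanometre)")
  if (!is.null(raw$leak))
    sc$leak <- do.call(leak_profile,
                       merge_known(unclass(leak_profile()), raw$leak, "leak"))
  if (!is.null(raw$geometry))
    sc$geometry <- do.call(axon_geometry,
      merge_known(unclass(axon_geometry()), raw$geometry, "geometry"))
  if (!is.null(raw$sweep)) {
    sw <- merge_known(sc$sweep, raw$sweep, "sweep", allowed = SWEEP_KEYS)
    if (!sw$kind %in% c("ghk", "synapse")) stop("sweep kind must be ghk or synapse")
    if (length(sw$G_grid) == 0) stop("sweep G_grid must be non-empty")
    sw$G_grid <- as.numeric(sw$G_grid)
    if (is.unsorted(rev(sw$G_grid)))
      stop("sweep G_grid must be sorted descending")
    if (any(sw$G_grid <= 0)) stop("sweep G_grid must be positive")
    if (sw$channel_density_D < 0) stop("channel_density_D must be >= 0")
    sc$sweep <- sw
  }
  if (!is.null(raw$output_path)) sc$output_path <- as.character(raw$output_path)
  sc
}

#' Load a scenario from a YAML or JSON file
#'
#' Reads a key-value scenario document, rejects unknown keys, validates all
#' physical values, and fills every unspecified field from
#' [default_scenario()]. An empty file yields the all-defaults scenario.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` scenario file.
#' @return An object of class `scenario`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  scenario_from_list(raw, origin = path)
}

scenario_to_list <- function(sc) {
  list(name = sc$name,
       constants = unclass(sc$constants),
       ion = unclass(sc$ion)[c("name", "mass_m", "valence",
                               "conc_extracellular", "conc_intracellular")],
       barrier = unclass(sc$barrier),
       leak = unclass(sc$leak),
       geometry = unclass(sc$geometry),
       sweep = sc$sweep[!vapply(sc$sweep, is.null, logical(1))],
       output_path = sc$output_path)
}

#' Write a scenario file
#'
#' Serialises a scenario to YAML (with a header documenting the meaning and
#' units of each block) so that [load_scenario()] reads it back equal
#' field-by-field.
#'
#' @param scenario A `scenario` object.
#' @param path Output path (.yaml).
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario"))
  header <- c(
    "# iontunnel scenario file",
    "# constants: h, hbar (J s); k_B (J/K); F (C/mol); R (J/(K mol)); N_A (/mol); T (K)",
    "# ion: mass_m (kg), valence (1|2), concentrations (mmol/L, out/in)",
    "# barrier: height_G (J), gate_length_L (m, potential falls to 0.42 G at L),",
    "#          gate_location_n (1-4; extracellular ions gain q*Vm/n)",
    "# leak: MC_* resting leak conductances (mS/cm2); concentrations (mmol/L)",
    "# geometry: axon radius/length (um), volume ratio, K+ ions per AP, D (/um2)",
    "# sweep: kind ghk|synapse; G_grid descending (J); channel_density_D (/cm2)")
  body <- yaml::as.yaml(scenario_to_list(scenario), precision = 15)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the default fixture scenarios
#'
#' Emits one scenario file per standard parameter sweep: the gate-length and
#' gate-location membrane-potential sweeps (`ghk_gate_length.yaml`,
#' `ghk_gate_location.yaml`) and the five quantum-synapse sweeps over gate
#' length, membrane potential, ions per channel, channel density and patch
#' count, plus `default.yaml`.
#'
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
make_scenarios <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  specs <- standard_sweep_specs()
  paths <- character(0)
  for (nm in names(specs)) {
    sc <- specs[[nm]]$scenario
    p <- file.path(dir, paste0(nm, ".yaml"))
    write_scenario(sc, p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "default.yaml")
  write_scenario(default_scenario(), p)
  invisible(c(paths, p))
}

# The standard sweep catalogue: two membrane-potential sweeps and five
# synapse sweeps. Curve-family values for the synapse sweeps (Vm, N_K, D, N)
# are the package's choices spanning the physiologically interesting decade
# around each base value.
standard_sweep_specs <- function() {
  g50 <- seq(4e-20, 1e-20, length.out = 50)
  mk <- function(kind, axis, axis_values = NULL) {
    sc <- default_scenario()
    sc$name <- paste0(kind, "_", axis)
    sc$sweep$kind <- kind
    sc$sweep$axis <- axis
    sc$sweep$G_grid <- g50
    sc$sweep$axis_values <- axis_values
    list(scenario = sc)
  }
  list(
    ghk_gate_length   = mk("ghk", "gate_length"),
    ghk_gate_location = mk("ghk", "gate_location"),
    synapse_L         = mk("synapse", "L", c(0.5, 1, 1.5, 2) * 1e-10),
    synapse_Vm        = mk("synapse", "Vm", c(0.055, 0.06, 0.065, 0.07)),
    synapse_N_K       = mk("synapse", "N_K", c(10, 50, 100, 500)),
    synapse_D_um2     = mk("synapse", "D_um2", c(1, 10, 100, 1000)),
    synapse_N_um2     = mk("synapse", "N_um2", c(1, 10, 100, 1000)))
}

#' Run a scenario's sweep
#'
#' Dispatches on the scenario's sweep kind: `"ghk"` runs
#' [sweep_barrier_height()] over Na/K/Ca, `"synapse"` runs
#' [sweep_induction()]. If `output_path` is set the table is also written as
#' CSV via [write_sweep_csv()].
#'
#' @param scenario A `scenario` object.
#' @return The sweep data.frame.
#' @export
run_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  sw <- scenario$sweep
  tab <- if (sw$kind == "ghk") {
    sweep_barrier_height(sw$G_grid, sweep_axis = sw$axis,
                         channel_density_D = sw$channel_density_D,
                         leak = scenario$leak,
                         constants = scenario$constants,
                         transmission_mode = sw$transmission_mode)
  } else {
    sweep_induction(axis = sw$axis, axis_values = sw$axis_values,
                    G_grid = sw$G_grid, constants = scenario$constants,
                    transmission_mode = sw$transmission_mode)
  }
  if (!is.null(scenario$output_path))
    write_sweep_csv(tab, scenario$output_path)
  tab
}

#' Write a sweep table as CSV
#'
#' Numeric columns are emitted with 10 significant digits in scientific
#' notation so that identical inputs produce byte-identical files.
#'
#' @param tab A sweep data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(tab, path) {
  out <- tab
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- sprintf("%.9e", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Regenerate the data behind a standard figure sweep
#'
#' `which` selects one of the package's standard sweeps: `"vm_gate_length"`
#' and `"vm_gate_location"` give the membrane-potential depolarization
#' curves Vm(G) for Na/K/Ca at the four gate lengths or the four gate
#' locations; `"p3_gate_length"`, `"p3_vm"`, `"p3_ions_per_channel"`,
#' `"p3_channel_density"` and `"p3_patch_count"` give the action-potential
#' induction probability P3(G) for the corresponding curve families.
#'
#' @param which Sweep name (see Details); also accepts the scenario-file
#'   names from [make_scenarios()].
#' @param G_points Number of points in the descending G grid.
#' @return The sweep data.frame.
#' @export
reproduce_figure <- function(which = c("vm_gate_length", "vm_gate_location",
                                       "p3_gate_length", "p3_vm",
                                       "p3_ions_per_channel",
                                       "p3_channel_density",
                                       "p3_patch_count"),
                             G_points = 50) {
  alias <- c(vm_gate_length = "ghk_gate_length",
             vm_gate_location = "ghk_gate_location",
             p3_gate_length = "synapse_L",
             p3_vm = "synapse_Vm",
             p3_ions_per_channel = "synapse_N_K",
             p3_channel_density = "synapse_D_um2",
             p3_patch_count = "synapse_N_um2")
  which <- match.arg(which[1], c(names(alias), unname(alias)))
  key <- if (which %in% names(alias)) alias[[which]] else which
  sc <- standard_sweep_specs()[[key]]$scenario
  sc$sweep$G_grid <- seq(4e-20, 1e-20, length.out = G_points)
  run_scenario(sc)
}

#' Validation report of the model's worked examples
#'
#' Recomputes every headline worked-example quantity of the model from its
#' inputs and compares it with the value conventionally quoted for it, at a
#' tolerance reflecting the quoted rounding: the classical resting potential
#' (0.073 V), the monovalent and divalent conductance quanta (3.88e-2 and
#' 15.52e-2 mS), the axon geometry chain (314 um2 surface, 52.6 um3
#' extracellular volume), the per-AP potassium rise (4.3e-2 mmol/L), the
#' ions-per-channel count (44), the threshold-tunneling coefficient
#' (9.64e-7 mmol/L) and threshold probability (2.24e-5), and the minimum
#' achievable tunneling fraction 1/44 = 2.27e-2 together with its exceeding
#' the threshold.
#'
#' @return A data.frame with columns
#'   `check, expected, computed, rel_dev, tol, pass`; deterministic order.
#' @export
validate_model <- function() {
  const <- physical_constants()
  leak <- leak_profile()
  geom <- axon_geometry()
  cyl <- cylinder_geometry(geom)
  k_ap <- k_release_concentration(geom$N_AP_total, cyl$extra_volume, const)
  nk <- ions_per_channel(geom$N_AP_total / cyl$surface_area,
                         geom$channel_density_Dum2)
  thr <- threshold_tunneling(signif(k_ap, 2), Vm_threshold = 0.055,
                             D = 1e8, leak = leak, constants = const)
  rows <- list(
    list("classical resting Vm (V)", 0.073, classical_vm(leak, const)$Vm, 0.01),
    list("monovalent conductance quantum q^2/h (mS)", 3.88e-2,
         unitary_conductance(ion("Na"), 1, const) * 1e3, 0.005),
    list("divalent conductance quantum q^2/h (mS)", 15.52e-2,
         unitary_conductance(ion("Ca"), 1, const) * 1e3, 0.005),
    list("axon lateral surface (um2)", 314, cyl$surface_area, 0.005),
    list("extracellular volume V_E (um3)", 52.6, cyl$extra_volume, 0.005),
    list("per-AP potassium rise [K]_AP (mmol/L)", 4.3e-2, k_ap, 0.02),
    list("ions per channel N_K", 44, nk$N_K, 0),
    list("threshold coefficient T_Q(Thr) x [K]_AP (mmol/L)", 9.64e-7,
         thr$coefficient, 0.02),
    list("threshold tunneling probability T_Q(Thr)", 2.24e-5,
         thr$T_Q_thr, 0.02),
    list("minimum tunneling fraction 1/N_K", 2.27e-2, 1 / nk$N_K, 0.005),
    list("1/N_K exceeds T_Q(Thr)", 1,
         as.numeric(1 / nk$N_K > thr$T_Q_thr), 0))
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(check = r[[1]], expected = r[[2]], computed = r[[3]],
               rel_dev = if (r[[2]] == 0) abs(r[[3]]) else
                 abs(r[[3]] - r[[2]]) / abs(r[[2]]),
               tol = r[[4]], stringsAsFactors = FALSE)))
  out$pass <- out$rel_dev <= out$tol
  out
}
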