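# Config parsing and strict CSV schemas. All CSVs are comma-delimited UTF-8
# with a header row; units are embedded in column names (flux_m_per_s,
# zeta_mV, rp_nm) so they cannot drift silently.

.known_membrane_keys <- c("rp_nm", "dx_eff_m", "eps_p", "c_entrance", "c_exit",
                          "x0", "w", "zeta_acid_mV", "zeta_base_mV",
                          "avg_target")
.known_species_keys <- c("z", "D_inf", "r_stokes_nm", "r_cav_nm", "pKa1", "pKa2")

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file with `membranes:` and `species:` sections and validates
#' it strictly: unknown keys are rejected and missing or ill-typed required
#' fields raise errors naming the offending field path (e.g.
#' `membranes.nf90.rp_nm`). A membrane entry either carries explicit profile
#' parameters (`c_entrance`, `c_exit`, `x0`, `w`, mol/m^3) or zeta potentials
#' (`zeta_acid_mV`, `zeta_base_mV`, optionally `avg_target`) from which the
#' profile is calibrated.
#'
#' @param path Path to a YAML config file.
#' @return List with `membranes` (named list of [membrane()]) and `species`
#'   (named list of [species()]).
#' @examples
#' cfg <- load_config(system.file("extdata", "membranes.yaml",
#'                                package = "sedenf"))
#' names(cfg$membranes)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), c("membranes", "species"))
  if (length(bad))
    stop("unknown top-level config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  num <- function(entry, key, path_str, required = TRUE) {
    v <- entry[[key]]
    if (is.null(v)) {
      if (required) stop("missing required field '", path_str, ".", key, "'",
                         call. = FALSE)
      return(NULL)
    }
    if (!is.numeric(v) || length(v) != 1L)
      stop("field '", path_str, ".", key, "' must be a single number",
           call. = FALSE)
    v
  }
  species_out <- lapply(names(raw$species), function(nm) {
    e <- raw$species[[nm]]
    p <- paste0("species.", nm)
    bad <- setdiff(names(e), .known_species_keys)
    if (length(bad)) stop("unknown key(s) in '", p, "': ",
                          paste(bad, collapse = ", "), call. = FALSE)
    rs <- num(e, "r_stokes_nm", p, required = FALSE)
    rc <- num(e, "r_cav_nm", p, required = FALSE)
    species(nm, z = num(e, "z", p), D_inf = num(e, "D_inf", p),
            r_stokes = if (!is.null(rs)) rs * 1e-9,
            r_cav = if (!is.null(rc)) rc * 1e-9,
            pKa1 = num(e, "pKa1", p, FALSE) %||% NA_real_,
            pKa2 = num(e, "pKa2", p, FALSE) %||% NA_real_)
  })
  names(species_out) <- names(raw$species)
  membranes_out <- lapply(names(raw$membranes), function(nm) {
    e <- raw$membranes[[nm]]
    p <- paste0("membranes.", nm)
    bad <- setdiff(names(e), .known_membrane_keys)
    if (length(bad)) stop("unknown key(s) in '", p, "': ",
                          paste(bad, collapse = ", "), call. = FALSE)
    rp <- num(e, "rp_nm", p) * 1e-9
    prof <- if (!is.null(e$c_entrance) || !is.null(e$c_exit)) {
      charge_profile(num(e, "c_entrance", p), num(e, "c_exit", p),
                     x0 = num(e, "x0", p, FALSE) %||% 0.65,
                     w = num(e, "w", p, FALSE) %||% 0.08)
    } else {
      calibrate_profile(num(e, "zeta_acid_mV", p) * 1e-3,
                        num(e, "zeta_base_mV", p) * 1e-3,
                        rp = rp, solution = zeta_electrolyte(),
                        target_average = num(e, "avg_target", p, FALSE),
                        w = num(e, "w", p, FALSE) %||% 0.08)
    }
    membrane(rp, num(e, "dx_eff_m", p), num(e, "eps_p", p), prof, name = nm)
  })
  names(membranes_out) <- names(raw$membranes)
  list(membranes = membranes_out, species = species_out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a rejection CSV with strict schema checks
#'
#' Expected columns: `membrane`, `tracer` (or `solute`), `flux_m_per_s` (or
#' `dP_MPa`), `rejection`. Non-finite values, negative fluxes and rejections
#' outside `[0, 1)` are rejected with the offending data line number.
#'
#' @param path CSV path.
#' @return Data frame (column `solute` renamed to `tracer`).
#' @export
read_rejection_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(d)) stop("empty input: ", path, call. = FALSE)
  if ("solute" %in% names(d) && !"tracer" %in% names(d))
    names(d)[names(d) == "solute"] <- "tracer"
  driver <- intersect(c("flux_m_per_s", "dP_MPa"), names(d))
  need <- c("membrane", "tracer", "rejection")
  miss <- setdiff(need, names(d))
  if (length(miss) || !length(driver))
    stop("missing column(s): ",
         paste(c(miss, if (!length(driver)) "flux_m_per_s|dP_MPa"),
               collapse = ", "), call. = FALSE)
  bad <- !is.finite(d[[driver[1]]]) | d[[driver[1]]] < 0 |
    !is.finite(d$rejection) | d$rejection < 0 | d$rejection >= 1
  if (any(bad))
    stop("malformed row(s) at data line(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  d
}

#' Write a characterization or curve report CSV
#'
#' Deterministic column order; radius columns (`rp_nm`, `rp_mean_nm`) are
#' rounded to 2 decimals for table reproduction, everything else written at
#' full precision.
#'
#' @param tab Data frame.
#' @param path Output CSV path.
#' @return Invisibly, the written data frame.
#' @export
write_report <- function(tab, path) {
  out <- tab
  for (col in intersect(c("rp_nm", "rp_mean_nm"), names(out)))
    out[[col]] <- round(out[[col]], 2)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
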