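#' Named experiment presets
#'
#' Returns the default configuration with the documented deltas applied:
#' \describe{
#'   \item{default / feedback_on}{the standard run: stretching, DTC pausing
#'     and contact inhibition all enabled.}
#'   \item{no_stretch_fast_dtc}{gonadogenesis by DTC migration alone:
#'     stretching disabled, the late-L4 migration rate raised to 46 um/h to
#'     compensate, pausing off — the DTC pulls ahead of the distal germ
#'     cells.}
#'   \item{no_stretch_pausing}{same raised rate with DTC pausing on — the
#'     DTC waits for germ cells, producing a shortened adult gonad.}
#'   \item{no_feedback_fixed_death}{contact inhibition disabled and a fixed
#'     per-hour death probability imposed (swept over `death_sweep` by the
#'     caller), the scenario in which proliferative cell numbers cannot be
#'     stabilized.}
#' }
#'
#' @param name preset name.
#' @param seed RNG seed.
#' @param death_prob fixed per-hour death probability for
#'   `no_feedback_fixed_death` (default: the first entry of the sweep list).
#' @return a [simulation_config()].
#' @export
preset <- function(name = c("default", "no_stretch_fast_dtc",
                            "no_stretch_pausing", "no_feedback_fixed_death",
                            "feedback_on"),
                   seed = 1L, death_prob = NULL) {
  name <- match.arg(name)
  cfg <- simulation_config(seed = seed)
  if (name %in% c("no_stretch_fast_dtc", "no_stretch_pausing")) {
    cfg$path$stretch_window <- c(0, 0)
    cfg$path$migration_rates[["lateL4"]] <- 46
    cfg$dtc_pausing <- name == "no_stretch_pausing"
  } else if (name == "no_feedback_fixed_death") {
    cfg$contact_inhibition <- FALSE
    cfg$fate$apoptosis_prob_per_h <-
      if (is.null(death_prob)) cfg$death_sweep[1L] else death_prob
  }
  cfg
}

# dotted keys whose values are printed quantities fixed by measurement;
# everything else is a free (fitted or unavailable) parameter
paper_fixed_keys <- c(
  "n_founders",
  "cc.total_cycle_larval", "cc.total_cycle_adult", "cc.s",
  "cc.arrest_volume_fraction",
  "sig.bound_threshold_um", "sig.absent_threshold_um",
  "fate.sex_decision_distance_um", "fate.sperm_time_threshold_hph",
  "fate.max_meiotic_radius_um", "fate.oocyte_mature_radius_um",
  "fate.proximal_protect_distance_um",
  "path.cell_diameter_um")

flatten_cfg <- function(x, prefix = "") {
  out <- character()
  for (nm in names(x)) {
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    v <- x[[nm]]
    if (is.list(v)) {
      out <- c(out, flatten_cfg(v, key))
    } else {
      val <- if (is.null(v)) "NULL"
      else if (is.numeric(v)) paste(sprintf("%.17g", v), collapse = ",")
      else if (is.logical(v)) paste(ifelse(v, "TRUE", "FALSE"),
                                    collapse = ",")
      else paste(as.character(v), collapse = ",")
      out <- c(out, setNames(val, key))
    }
  }
  out
}

assign_by_key <- function(x, parts, value) {
  nm <- parts[1L]
  if (length(parts) == 1L) {
    tmpl <- x[[nm]]
    if (identical(value, "NULL")) {
      x[nm] <- list(NULL)  # keep the element, unlike `[[<-` with NULL
      return(x)
    }
    x[[nm]] <- if (is.null(tmpl) || is.numeric(tmpl)) {
      v <- as.numeric(strsplit(value, ",", fixed = TRUE)[[1L]])
      if (is.integer(tmpl)) v <- as.integer(v)
      if (!is.null(tmpl)) names(v) <- names(tmpl)
      v
    } else if (is.logical(tmpl)) {
      as.logical(strsplit(value, ",", fixed = TRUE)[[1L]])
    } else {
      strsplit(value, ",", fixed = TRUE)[[1L]]
    }
  } else {
    x[[nm]] <- assign_by_key(x[[nm]], parts[-1L], value)
  }
  x
}

#' Write a configuration file
#'
#' Flat, diff-able `key = value` text with dotted namespaces and units in the
#' key names. Each key is annotated as `[paper-fixed]` (a printed measured
#' quantity) or `[free]` (fitted or unavailable, configurable).
#'
#' @param cfg a [simulation_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  fl <- flatten_cfg(unclass(cfg))
  tag <- ifelse(names(fl) %in% paper_fixed_keys, "[paper-fixed]", "[free]")
  writeLines(c("# germsim run configuration",
               sprintf("%s = %s  # %s", names(fl), fl, tag)), path)
  invisible(path)
}

#' Read a configuration file
#'
#' Parses a file written by [write_config()]; the default configuration acts
#' as the structural template, so a round trip reproduces the configuration
#' exactly.
#'
#' @param path file written by [write_config()].
#' @return a [simulation_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- unclass(simulation_config())
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop(sprintf("malformed config line: '%s'", ln),
                     call. = FALSE)
    key <- trimws(substr(ln, 1L, eq - 1L))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    cfg <- assign_by_key(cfg, strsplit(key, ".", fixed = TRUE)[[1L]], val)
  }
  # restore parameter classes lost by the flat representation
  class(cfg$cc) <- "cell_cycle_params"
  class(cfg$sig) <- "signaling_params"
  class(cfg$fate) <- "fate_params"
  class(cfg$force) <- "force_params"
  class(cfg$path) <- "dtc_path_spec"
  structure(cfg, class = "simulation_config")
}
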