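# Campaign runner and run records: per-row seeds are derived from the
# campaign seed by a counter-based rule, so results are identical whatever
# the worker count or execution order, and partial reruns are stable.

row_seed <- function(campaign_seed, row) {
  sub_seed(campaign_seed, paste0("row", row))
}

#' Run a simulation campaign over an experiment design
#'
#' One stand simulation per design row: for a `mixture` design each row is a
#' ref/diff point (pairs ordering) simulated as a 50/50 binary mixture; for
#' a `pure` design each row is a plant-scale genotype in pure stand. Each
#' row gets a deterministic seed derived from the campaign seed and row
#' index. Individual failures (e.g. out-of-bounds splits) are recorded and
#' the campaign continues.
#'
#' @param design a [lhs_maximin()] / [make_designs()] design (`kind`
#'   `"mixture"` or `"pure"`), or a bare matrix plus `kind`.
#' @param climate a [generate_climate()] series.
#' @param config a [sim_config()].
#' @param seed campaign seed.
#' @param kind `"mixture"` or `"pure"` (defaults to the design's).
#' @param n_plants,density plot setup per run.
#' @param dev developmental constants.
#' @param workers worker-process count for [parallel::mclapply()]; results
#'   are identical for any value.
#' @return data.frame with one row per design point: `row`, `seed`,
#'   `status` (`"ok"`/`"failed"`), `message`, `n_ears`, `l_perc`, `f_tot`.
#' @export
run_campaign <- function(design, climate, config = sim_config(), seed = 1L,
                         kind = NULL, n_plants = 110, density = 200,
                         dev = dev_defaults(), workers = 1L) {
  pts <- if (inherits(design, "design_matrix")) design$points else
    as.matrix(design)
  if (is.null(kind))
    kind <- if (inherits(design, "design_matrix")) design$kind else "pure"
  if (!kind %in% c("mixture", "pure"))
    stop_invalid("kind must be 'mixture' or 'pure'")
  one <- function(i) {
    rs <- row_seed(seed, i)
    res <- tryCatch({
      if (kind == "mixture") {
        gg <- split_refdiff(row_to_spec(pts[i, ]), dev)
        plt <- build_plot(gg[[1]], gg[[2]], n_plants, density, rs)
      } else {
        g <- row_to_genotype(pts[i, ], dev)
        plt <- build_plot(g, g, n_plants, density, rs)
      }
      out <- simulate_stand(plt, climate, config, rs)
      data.frame(row = i, seed = rs, status = "ok", message = "",
                 n_ears = out$n_ears, l_perc = out$l_perc, f_tot = out$f_tot)
    }, error = function(e) {
      data.frame(row = i, seed = rs, status = "failed",
                 message = conditionMessage(e),
                 n_ears = NA_real_, l_perc = NA_real_, f_tot = NA_real_)
    })
    res
  }
  rows <- if (workers > 1L) {
    parallel::mclapply(seq_len(nrow(pts)), one, mc.cores = workers)
  } else lapply(seq_len(nrow(pts)), one)
  do.call(rbind, rows)
}

canonical_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

md5_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(x), f)
  unname(tools::md5sum(f))
}

#' Create a run record for a single stand simulation
#'
#' A run record is the full serialized provenance of one simulation: the
#' genotype parameters, plot and climate configuration and all seeds, plus
#' the outputs — enough to reproduce the run exactly with
#' [replay_record()].
#'
#' @param run_id unique identifier within a project directory.
#' @param spec a [mixture_spec()] describing the stand (use `diff = 0` for a
#'   pure stand).
#' @param climate_params [climate_config()] list.
#' @param n_days climate series length.
#' @param climate_seed,sim_seed seeds of the climate draw and simulation.
#' @param n_plants,density plot setup.
#' @param config [sim_config()].
#' @param outputs a `stand_outputs` (optional; computed by
#'   [replay_record()] when absent).
#' @return list of class `run_record`.
#' @export
make_record <- function(run_id, spec, climate_params = climate_config(),
                        n_days = 330, climate_seed = 1L, sim_seed = 1L,
                        n_plants = 110, density = 200,
                        config = sim_config(), outputs = NULL) {
  payload <- list(
    schema_version = 1L, run_id = run_id,
    ref = as.list(spec$ref), diff = as.list(spec$diff),
    climate_params = climate_params, n_days = n_days,
    climate_seed = climate_seed, sim_seed = sim_seed,
    n_plants = n_plants, density = density, config = config,
    package_version = as.character(utils::packageVersion("canomix")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  payload$outputs <- if (!is.null(outputs)) {
    list(n_ears = outputs$n_ears, l_perc = outputs$l_perc,
         f_tot = outputs$f_tot)
  }
  core <- payload[c("run_id", "ref", "diff", "climate_params", "n_days",
                    "climate_seed", "sim_seed", "n_plants", "density",
                    "config")]
  payload$digest <- md5_of(canonical_json(core))
  structure(payload, class = "run_record")
}

#' Save a run record as JSON
#' @param record a [make_record()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_record <- function(record, path) {
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Load a run record from JSON
#'
#' Verifies the schema version and the configuration digest; a tampered
#' record loads with an integrity warning.
#'
#' @param path JSON file written by [save_record()].
#' @return a `run_record`.
#' @export
load_record <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(rec$schema_version) || rec$schema_version != 1L)
    stop("run-record schema version ", rec$schema_version,
         " not supported (expected 1); migrate the record first")
  core <- rec[c("run_id", "ref", "diff", "climate_params", "n_days",
                "climate_seed", "sim_seed", "n_plants", "density", "config")]
  core$config[c("layer_dz", "n_sky_directions", "gai_radius", "t_base",
                "regression_window", "regression_decay_days",
                "lperc_start_day")] <-
    lapply(core$config[c("layer_dz", "n_sky_directions", "gai_radius",
                         "t_base", "regression_window",
                         "regression_decay_days", "lperc_start_day")],
           as.numeric)
  if (!identical(unname(md5_of(canonical_json(core))), unname(rec$digest)))
    warning("run-record integrity check failed: digest mismatch")
  structure(rec, class = "run_record")
}

#' Replay a run record
#'
#' Re-executes the simulation a record describes from its serialized
#' configuration and seeds. Replaying a saved record reproduces its stored
#' outputs exactly.
#'
#' @param record a `run_record`.
#' @return a `stand_outputs`.
#' @export
replay_record <- function(record) {
  cp <- record$climate_params
  cp$temp_bounds <- as.numeric(cp$temp_bounds)
  climate <- generate_climate(record$n_days, record$climate_seed,
                              utils::modifyList(climate_config(), cp))
  spec <- mixture_spec(unlist(record$ref), unlist(record$diff))
  gg <- split_refdiff(spec)
  plt <- build_plot(gg[[1]], gg[[2]], record$n_plants, record$density,
                    record$sim_seed)
  cfg <- utils::modifyList(sim_config(), lapply(record$config, as.numeric))
  simulate_stand(plt, climate, cfg, record$sim_seed)
}
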