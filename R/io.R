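# Explicit-output TSV format, run manifests, and the command back ends used
# by the exec/ssakit command-line tool.
#
# TSV layout (tab-separated, '.' decimal, one header row):
#   time  fired_reaction  <one column per species>  a_<reaction>...
# plus n_<reaction> firing-count columns for tau-leap trajectories.
# fired_reaction holds the reaction name, or NA for the initial and
# terminal rows.

fmt_full <- function(x) formatC(x, digits = 17, format = "g")

#' Write a trajectory as explicit-output TSV
#'
#' @param trajectory An `ssa_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_explicit_tsv <- function(trajectory, path) {
  df <- data.frame(time = fmt_full(trajectory$times),
                   fired_reaction = ifelse(is.na(trajectory$fired), "NA",
                                           trajectory$reactions[trajectory$fired]),
                   stringsAsFactors = FALSE)
  for (sp in trajectory$species) df[[sp]] <- trajectory$states[, sp]
  for (rn in trajectory$reactions)
    df[[paste0("a_", rn)]] <- fmt_full(trajectory$propensities[, rn])
  if (!is.null(trajectory$firings))
    for (rn in trajectory$reactions)
      df[[paste0("n_", rn)]] <- trajectory$firings[, rn]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read an explicit-output TSV back into a trajectory
#'
#' Lossless inverse of [write_explicit_tsv()]: times at full precision,
#' integer states, propensities and fired channel. Files with
#' non-increasing times or a malformed header are rejected.
#'
#' @param path File in the explicit-output layout.
#' @return An `ssa_trajectory` (without a model reference).
#' @export
read_explicit_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  cn <- colnames(df)
  if (length(cn) < 3L || cn[1L] != "time" || cn[2L] != "fired_reaction")
    stop("schema mismatch: expected columns time, fired_reaction, ",
         "species..., a_<reaction>...")
  prop_cols <- grep("^a_", cn, value = TRUE)
  fir_cols <- grep("^n_", cn, value = TRUE)
  sp_cols <- setdiff(cn, c("time", "fired_reaction", prop_cols, fir_cols))
  if (!length(prop_cols)) stop("schema mismatch: no propensity columns")
  reactions <- sub("^a_", "", prop_cols)
  times <- as.numeric(df$time)
  dt <- diff(times)
  if (anyNA(times) || any(dt < 0))
    stop("malformed trajectory file: times must be increasing")
  # only the terminal non-event row may coincide with the last event
  if (any(dt[seq_len(max(length(dt) - 1L, 0L))] == 0))
    stop("malformed trajectory file: duplicated interior times")
  states <- as.matrix(df[, sp_cols, drop = FALSE])
  storage.mode(states) <- "integer"
  props <- as.matrix(df[, prop_cols, drop = FALSE])
  colnames(props) <- reactions
  fired <- match(df$fired_reaction, reactions)
  exact <- length(fir_cols) == 0L
  n <- length(times)
  terminal <- n >= 2L && is.na(fired[n])
  structure(list(times = times, states = states, propensities = props,
                 fired = fired,
                 firings = if (!exact) {
                   f <- as.matrix(df[, fir_cols, drop = FALSE])
                   colnames(f) <- sub("^n_", "", fir_cols)
                   storage.mode(f) <- "integer"
                   f
                 },
                 absorbing = FALSE, clipped = FALSE, exact = exact,
                 terminal = terminal,
                 end_mode = if (terminal) "time" else "steps",
                 end_value = if (terminal) times[n] else sum(!is.na(fired)),
                 species = sp_cols, reactions = reactions, model = NULL),
            class = "ssa_trajectory")
}

#' Write a lineage as per-segment TSVs plus a division-event table
#'
#' @param lineage An `ssa_lineage`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_lineage <- function(lineage, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in seq_along(lineage$segments))
    write_explicit_tsv(lineage$segments[[g]],
                       file.path(dir, sprintf("generation_%04d.tsv", g)))
  recs <- lineage$partition_records
  if (length(recs)) {
    sp <- names(recs[[1L]]$pre)
    tab <- data.frame(time = vapply(recs, `[[`, 0, "time"))
    for (s in sp) {
      tab[[paste0("pre_", s)]] <- vapply(recs, function(r) r$pre[[s]], 0)
      tab[[paste0("daughter_", s)]] <-
        vapply(recs, function(r) r$daughter[[s]], 0)
      tab[[paste0("discarded_", s)]] <-
        vapply(recs, function(r) r$discarded[[s]], 0)
    }
    utils::write.table(tab, file.path(dir, "divisions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Step plot of species time series
#'
#' Draws the copy-number trajectory as right-continuous steps, matching the
#' discrete-event semantics of the process.
#'
#' @param x An `ssa_trajectory`.
#' @param species Species names to draw (default: all).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ssa_trajectory <- function(x, species = x$species, ...) {
  idx <- vapply(species, function(s) resolve_species(x, s), 0L)
  ylim <- range(x$states[, idx])
  graphics::plot(NA, xlim = range(x$times), ylim = ylim,
                 xlab = "time (min)", ylab = "copy number", ...)
  for (k in seq_along(idx))
    graphics::lines(x$times, x$states[, idx[k]], type = "s", col = k)
  graphics::legend("topright", legend = species, col = seq_along(idx),
                   lty = 1, bty = "n")
  invisible(x)
}

write_manifest <- function(path, model_path, model, settings) {
  lines <- c(
    paste0("model_path\t", model_path),
    paste0("model_hash\t",
           substr(tools::md5sum(model_path)[[1]], 1, 32)),
    paste0("solver\t", settings$solver),
    paste0("end_mode\t", settings$mode),
    paste0("end_value\t", fmt_full(settings$end)),
    paste0("n_trajectories\t", settings$n_trajectories),
    paste0("seed\t", if (is.null(settings$seed)) "NA" else settings$seed),
    paste0("package_version\t", as.character(utils::packageVersion("ssakit"))),
    paste0("r_version\t", paste(R.version$major, R.version$minor, sep = ".")))
  writeLines(lines, path)
  invisible(path)
}

#' Run configuration for the command-line interface
#'
#' @param model_path Path to an MDL (or `.xml` SBML subset) model file.
#' @param solver,end_mode,end_value,n_trajectories,seed Simulation settings
#'   (see [solver_settings()]).
#' @param output_directory Where artifacts are written.
#' @param analyses Character vector of analysis requests, any of
#'   `"distributions"`, `"waiting_times"`, `"moments"`, `"acf"`,
#'   `"regrid"`.
#' @param regrid_n Grid size when `"regrid"` is requested.
#' @return A list of class `ssa_run_config`.
#' @export
run_config <- function(model_path, solver = "direct", end_mode = "steps",
                       end_value = 1000, n_trajectories = 1L, seed = 1L,
                       output_directory = ".", analyses = character(0),
                       regrid_n = 1000L) {
  ok <- c("distributions", "waiting_times", "moments", "acf", "regrid")
  bad <- setdiff(analyses, ok)
  if (length(bad)) stop("unknown analysis request: ", paste(bad, collapse = ", "))
  structure(list(model_path = model_path, solver = solver,
                 end_mode = end_mode, end_value = end_value,
                 n_trajectories = as.integer(n_trajectories),
                 seed = as.integer(seed),
                 output_directory = output_directory,
                 analyses = analyses, regrid_n = as.integer(regrid_n)),
            class = "ssa_run_config")
}

load_model_file <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  if (grepl("\\.xml$", path, ignore.case = TRUE)) import_sbml_subset(path)
  else parse_mdl(path = path)
}

#' Simulate from a run configuration and write all artifacts
#'
#' Writes one explicit-output TSV per trajectory, a `manifest.txt` (model
#' hash, solver, seed, versions) and any requested analysis tables into the
#' configured output directory. With a fixed seed the whole artifact set is
#' byte-identical across reruns.
#'
#' @param config An [run_config()] object.
#' @return Character vector of written file paths, invisibly.
#' @export
cmd_simulate <- function(config) {
  model <- load_model_file(config$model_path)
  settings <- solver_settings(end = config$end_value, mode = config$end_mode,
                              n_trajectories = config$n_trajectories,
                              seed = config$seed, solver = config$solver)
  dir.create(config$output_directory, showWarnings = FALSE, recursive = TRUE)
  trajs <- if (config$n_trajectories > 1L) run_ensemble(model, settings)
           else list(simulate_ssa(model, settings))
  written <- character(0)
  for (k in seq_along(trajs)) {
    f <- file.path(config$output_directory,
                   sprintf("trajectory_%04d.tsv", k))
    write_explicit_tsv(trajs[[k]], f)
    written <- c(written, f)
  }
  mf <- file.path(config$output_directory, "manifest.txt")
  write_manifest(mf, config$model_path, model, settings)
  written <- c(written, mf)
  if (length(config$analyses))
    written <- c(written,
                 cmd_analyze(written[grepl("trajectory_", written)],
                             config$analyses,
                             output_directory = config$output_directory,
                             regrid_n = config$regrid_n))
  invisible(written)
}

#' Analyze explicit-output trajectory files
#'
#' @param files Paths of explicit-output TSVs (e.g. from [cmd_simulate()]).
#' @param analyses Character vector of requests: `"distributions"`,
#'   `"waiting_times"`, `"moments"`, `"acf"`, `"regrid"`.
#' @param output_directory Where tables are written.
#' @param burn_in Burn-in fraction for stationary statistics.
#' @param regrid_n Grid size for `"regrid"`.
#' @return Character vector of written file paths, invisibly.
#' @export
cmd_analyze <- function(files, analyses = "moments", output_directory = ".",
                        burn_in = 0, regrid_n = 1000L) {
  dir.create(output_directory, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (f in files) {
    tr <- read_explicit_tsv(f)
    stem <- sub("\\.tsv$", "", basename(f))
    emit <- function(tab, suffix) {
      out <- file.path(output_directory, paste0(stem, "_", suffix, ".tsv"))
      utils::write.table(tab, out, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      written <<- c(written, out)
    }
    if ("moments" %in% analyses)
      emit(moments(tr, burn_in = burn_in), "moments")
    if ("distributions" %in% analyses) {
      for (sp in tr$species) {
        d <- species_distribution(tr, sp, burn_in = burn_in)
        emit(data.frame(value = d$support, probability = d$probability),
             paste0("dist_", sp))
      }
      for (rn in tr$reactions) {
        d <- propensity_distribution(tr, rn, burn_in = burn_in)
        emit(data.frame(value = d$support, probability = d$probability),
             paste0("propdist_", rn))
      }
    }
    if ("waiting_times" %in% analyses && tr$exact) {
      for (rn in tr$reactions) {
        iv <- event_waiting_times(tr, rn)
        if (length(iv) >= 10L)
          emit(waiting_time_pdf(iv), paste0("waiting_", rn))
      }
    }
    if ("acf" %in% analyses) {
      dur <- duration(tr)
      lags <- seq(0, dur / 20, length.out = 21L)
      for (sp in tr$species) {
        a <- tryCatch(autocorrelation(tr, sp, lags),
                      error = function(e) NULL)
        if (!is.null(a)) emit(a, paste0("acf_", sp))
      }
    }
    if ("regrid" %in% analyses) {
      g <- regrid_fixed_interval(tr, regrid_n)
      tab <- data.frame(time = g$times)
      for (sp in g$species) tab[[sp]] <- g$states[, sp]
      emit(tab, "regrid")
    }
  }
  invisible(written)
}
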