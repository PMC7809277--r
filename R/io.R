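# Keys accepted in a flat configuration file, with defaults applied by
# siem_config(). Event parameters use the event_* prefix; an
# `event_frequency` > 0 together with `event_duration` > 0 enables events.
config_keys <- c("epsilon", "n", "k", "timesteps", "seed",
                 "event_frequency", "event_duration", "event_strength",
                 "sign_mode", "drift_scale", "certainty_drift", "drift_all",
                 "gate_mode", "network_method", "store_opinions")

#' Load a simulation configuration from file
#'
#' Reads a flat key-value document (YAML, or JSON for `.json` paths),
#' validates it, applies defaults, and returns a [siem_config()]. Unknown
#' keys are rejected by name; out-of-range values raise the same errors as
#' [siem_config()].
#'
#' @param path path to a YAML or JSON configuration file.
#' @return A `siem_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("configuration file not found: %s", path), call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw) || is.null(names(raw)) || any(names(raw) == ""))
    stop(sprintf("%s: expected a flat key-value document", path),
         call. = FALSE)
  # YAML 1.1 parses a bare `n:` key as the boolean word "no" -> FALSE;
  # map it back to the population-size key.
  names(raw)[names(raw) == "FALSE"] <- "n"
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown))
    stop(sprintf("%s: unknown configuration key(s): %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (is.null(raw$epsilon))
    stop(sprintf("%s: `epsilon` is required", path), call. = FALSE)
  events <- NULL
  ef <- raw$event_frequency
  if (!is.null(ef) && ef > 0) {
    if (is.null(raw$event_duration) || is.null(raw$event_strength))
      stop(sprintf(paste0("%s: `event_duration` and `event_strength` are ",
                          "required when `event_frequency` > 0"), path),
           call. = FALSE)
    events <- event_process(ef, raw$event_duration, raw$event_strength,
                            sign_mode = raw$sign_mode %||% "random")
  }
  args <- list(epsilon = raw$epsilon, events = events)
  for (key in c("n", "k", "timesteps", "seed", "drift_scale",
                "certainty_drift", "drift_all", "gate_mode", "network_method",
                "store_opinions")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  do.call(siem_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a configuration to a YAML file
#'
#' Writes the flat key-value form read back by [load_config()];
#' `load_config(save_config(cfg, path))` reproduces `cfg`'s parameters.
#'
#' @param config a `siem_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "siem_config"))
  out <- list(epsilon = config$epsilon, n = config$n, k = config$k,
              timesteps = config$timesteps, seed = config$seed,
              drift_scale = config$drift_scale,
              certainty_drift = config$certainty_drift,
              drift_all = config$drift_all, gate_mode = config$gate_mode,
              network_method = config$network_method,
              store_opinions = config$store_opinions)
  if (!is.null(config$events)) {
    out$event_frequency <- config$events$frequency
    out$event_duration <- config$events$duration
    out$event_strength <- config$events$strength
    out$sign_mode <- config$events$sign_mode
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

# Full-precision numeric formatting so CSV round-trips are exact.
num_chr <- function(x) sprintf("%.17g", x)

#' Write run outputs to a directory
#'
#' Emits `conflict.csv` (columns `t,delta_O`), `events.csv` (one row per
#' event), `run_meta.json` (configuration echo, seed, package version), and
#' `opinions.csv` when the run stored its trajectory. Numbers are written at
#' full precision so reading them back reproduces the in-memory values
#' exactly.
#'
#' @param result a `siem_run`.
#' @param dir output directory (created if needed).
#' @return A `siem_manifest`: configuration echo, seed, version and an MD5
#'   checksum per written file.
#' @export
write_run <- function(result, dir) {
  stopifnot(inherits(result, "siem_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir))
    stop(sprintf("cannot create output directory: %s", dir), call. = FALSE)
  T <- result$config$timesteps
  conflict_path <- file.path(dir, "conflict.csv")
  utils::write.csv(data.frame(t = 0:T, delta_O = num_chr(result$conflict)),
                   conflict_path, row.names = FALSE, quote = FALSE)
  events_path <- file.path(dir, "events.csv")
  ev <- result$events
  ev$strength <- num_chr(ev$strength)
  ev$opinion <- num_chr(ev$opinion)
  utils::write.csv(ev, events_path, row.names = FALSE, quote = FALSE)
  files <- c(conflict_path, events_path)
  if (is.matrix(result$opinions)) {
    op_path <- file.path(dir, "opinions.csv")
    wide <- as.data.frame(t(result$opinions))
    names(wide) <- paste0("ind", seq_len(nrow(result$opinions)))
    wide[] <- lapply(wide, num_chr)
    utils::write.csv(cbind(t = 0:T, wide), op_path, row.names = FALSE,
                     quote = FALSE)
    files <- c(files, op_path)
  }
  meta_path <- file.path(dir, "run_meta.json")
  cfg <- result$config
  meta <- list(epsilon = cfg$epsilon, n = cfg$n, k = cfg$k,
               timesteps = cfg$timesteps, seed = cfg$seed,
               drift_scale = cfg$drift_scale,
               certainty_drift = cfg$certainty_drift,
               drift_all = cfg$drift_all, gate_mode = cfg$gate_mode,
               network_method = cfg$network_method,
               events = if (is.null(cfg$events)) NULL else
                 cfg$events[c("frequency", "duration", "strength",
                              "sign_mode")],
               package_version = as.character(utils::packageVersion("siem")))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, meta_path)
  checksums <- tools::md5sum(files)
  names(checksums) <- basename(files)
  structure(list(config = meta, seed = cfg$seed,
                 version = meta$package_version, checksums = checksums),
            class = "siem_manifest")
}

#' Read a conflict series back from disk
#' @param path a `conflict.csv` written by [write_run()].
#' @return Numeric vector of conflict values ordered by timestep.
#' @export
read_conflict <- function(path) {
  df <- utils::read.csv(path)
  df$delta_O[order(df$t)]
}

# Named small deterministic scenarios for the four qualitative regimes.
fixture_table <- list(
  consensus = list(epsilon = 0.9, events = NULL,
                   check = list(stat = "final_conflict", op = "<",
                                bound = 0.25)),
  fragmentation = list(epsilon = 0.2, events = NULL,
                       check = list(stat = "final_conflict", op = ">",
                                    bound = 0.2)),
  swings = list(epsilon = 0.8,
                events = list(frequency = 0.1, duration = 10,
                              strength = 0.8),
                check = list(stat = "conflict_range", op = ">",
                             bound = 0.2)),
  polarised = list(epsilon = 0.2,
                   events = list(frequency = 0.1, duration = 10,
                                 strength = 0.8),
                   check = list(stat = "final_conflict", op = ">",
                                bound = 0.3))
)

#' Small deterministic test scenario
#'
#' Returns a tiny configuration (14 individuals, 100 timesteps) matching one
#' of the four qualitative regimes — `consensus` (weak homophily, no events),
#' `fragmentation` (strong homophily, no events), `swings` (weak homophily,
#' strong events) and `polarised` (strong homophily, strong events) —
#' together with the qualitative check it is expected to satisfy.
#'
#' @param name one of `"consensus"`, `"fragmentation"`, `"swings"`,
#'   `"polarised"`.
#' @param seed run seed.
#' @return List with `config` (a `siem_config`) and `check` (list with
#'   `stat`, `op`, `bound`).
#' @export
make_fixture <- function(name, seed = 1L) {
  if (length(name) != 1 || !name %in% names(fixture_table))
    stop(sprintf("unknown fixture '%s'; valid fixtures: %s", name,
                 paste(names(fixture_table), collapse = ", ")),
         call. = FALSE)
  fx <- fixture_table[[name]]
  ev <- if (!is.null(fx$events))
    event_process(fx$events$frequency, fx$events$duration,
                  fx$events$strength)
  list(config = siem_config(epsilon = fx$epsilon, n = 14L, k = 5,
                            events = ev, timesteps = 100L, seed = seed),
       check = fx$check)
}

#' Evaluate a fixture's qualitative check against a run
#' @param run a `siem_run`.
#' @param check a check list from [make_fixture()].
#' @return `TRUE` when the run satisfies the check.
#' @export
check_fixture <- function(run, check) {
  stat <- switch(check$stat,
                 final_conflict = run$conflict[length(run$conflict)],
                 conflict_range = diff(range(run$conflict)),
                 stop(sprintf("unknown fixture statistic '%s'", check$stat),
                      call. = FALSE))
  switch(check$op,
         "<" = stat < check$bound,
         ">" = stat > check$bound,
         stop(sprintf("unknown fixture comparison '%s'", check$op),
              call. = FALSE))
}
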