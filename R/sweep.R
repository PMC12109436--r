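#' Benchtop reference result tables
#'
#' Loads the packaged transcription of the published benchtop result
#' matrices: entrainment rate (L/min) and jet relaxation time (s) over the
#' injected-volume x injection-rate grid, for continuous and pulsed
#' injections. Pulsed rows are keyed by per-burst volume; the published
#' pulsed table prints its second row label as "0.2", read here as the
#' 0.020 L (20 cc) burst volume.
#'
#' @return A list with `entrainment_continuous` and `entrainment_pulsed`
#'   ([entrainment_matrix()] objects) and `relaxation_continuous`,
#'   `relaxation_pulsed` (numeric matrices, rows V_inj, columns Q_inj).
#' @export
load_printed_tables <- function() {
  path <- system.file("extdata", "printed_tables.csv",
                      package = "fontanjet", mustWork = TRUE)
  raw <- readr::read_csv(path, show_col_types = FALSE)
  ent <- raw |> filter(.data$metric == "entrainment")
  rel <- raw |> filter(.data$metric == "relaxation")
  rel_matrix <- function(df) {
    vols <- sort(unique(df$v_inj)); rates <- sort(unique(df$q_inj))
    m <- matrix(NA_real_, length(vols), length(rates),
                dimnames = list(format(vols), format(rates)))
    for (i in seq_len(nrow(df))) {
      m[match(df$v_inj[i], vols), match(df$q_inj[i], rates)] <- df$value[i]
    }
    m
  }
  list(
    entrainment_continuous = entrainment_matrix(
      ent |> filter(.data$mode == "continuous") |> rename(q_ent = "value"),
      mode = "continuous"),
    entrainment_pulsed = entrainment_matrix(
      ent |> filter(.data$mode == "pulsed") |> rename(q_ent = "value"),
      mode = "pulsed"),
    relaxation_continuous = rel_matrix(rel |> filter(.data$mode == "continuous")),
    relaxation_pulsed = rel_matrix(rel |> filter(.data$mode == "pulsed"))
  )
}

# volume row key of a case in the result matrices: total volume for
# continuous runs, per-burst volume for pulsed runs
.case_volume_key <- function(protocol) {
  if (protocol$mode == "continuous") {
    injected_volume(protocol)
  } else {
    protocol$burst_volume / 1000
  }
}

# ground-truth programmed entrainment for a sweep case, looked up from the
# packaged benchtop tables
.programmed_entrainment <- function(protocol, tables = load_printed_tables()) {
  mat <- if (protocol$mode == "continuous") {
    tables$entrainment_continuous
  } else {
    tables$entrainment_pulsed
  }
  i <- match(TRUE, abs(mat$volumes - .case_volume_key(protocol)) < 1e-9)
  j <- match(TRUE, abs(mat$rates - protocol$rate_lmin) < 1e-9)
  if (is.na(i) || is.na(j)) {
    .fj_abort("case has no matching cell in the packaged tables",
              "fontanjet_incomplete_sweep")
  }
  mat$values[i, j]
}

#' Sweep configuration
#'
#' @param cases `"all"` or an integer vector of protocol case ids (1--20).
#' @param trials_per_case Trials per case (>= 1). Default 3.
#' @param base_seed Integer; per-trial seeds are derived deterministically
#'   from `base_seed`, the case id and the trial index.
#' @param params An [lpm_parameters()] object (tuned or to be used as-is).
#' @param sensor A [sensor_model()] (its `seed` is overridden per trial).
#' @param filter A [filter_config()].
#' @param tau_rise,tau_fall Ground-truth entrainment envelope time
#'   constants, seconds.
#' @param output_dir Optional directory; when given, per-trial CSV, matrix
#'   CSVs and a JSON manifest are written there.
#' @return A list of class `sweep_config`.
#' @export
sweep_config <- function(cases = "all",
                         trials_per_case = 3L,
                         base_seed = 1L,
                         params = lpm_parameters(),
                         sensor = sensor_model(),
                         filter = filter_config(),
                         tau_rise = 0.3,
                         tau_fall = 0.15,
                         output_dir = NULL) {
  if (identical(cases, "all")) cases <- 1:20
  if (!all(cases %in% 1:20)) {
    .fj_abort("`cases` must be ids within 1..20", "fontanjet_invalid_protocol")
  }
  if (trials_per_case < 1) {
    .fj_abort("`trials_per_case` must be >= 1", "fontanjet_invalid_parameter")
  }
  structure(
    list(cases = as.integer(cases), trials_per_case = as.integer(trials_per_case),
         base_seed = as.integer(base_seed), params = params, sensor = sensor,
         filter = filter, tau_rise = tau_rise, tau_fall = tau_fall,
         output_dir = output_dir),
    class = "sweep_config"
  )
}

#' @rdname sweep_config
#' @param case_id,trial Case id and trial index.
#' @export
trial_seed <- function(base_seed, case_id, trial) {
  as.integer((as.numeric(base_seed) + 7919 * case_id + 104729 * trial) %%
               2147483647)
}

#' Run a full injection sweep
#'
#' For every requested case and trial: emulate the mock-flow-loop record
#' (ground-truth entrainment programmed from the packaged benchtop tables),
#' filter it, segment stages and bursts (command-aligned), characterize the
#' jet step response and measure entrainment. Trial means are assembled
#' into entrainment and relaxation matrices. Re-running with an identical
#' configuration reproduces identical outputs; stage errors are caught,
#' reported in the `errors` element and the sweep continues.
#'
#' @param config A [sweep_config()].
#' @return A list of class `mfl_sweep` with `trials` (one row per
#'   case x trial), `entrainment_matrices`, `relaxation_matrices`,
#'   `manifest` and `errors`.
#' @export
run_sweep <- function(config = sweep_config()) {
  tables <- load_printed_tables()
  errors <- list()
  rows <- list()
  for (case_id in config$cases) {
    protocol <- case_protocol(case_id)
    e0 <- .programmed_entrainment(protocol, tables)
    for (trial in seq_len(config$trials_per_case)) {
      seed <- trial_seed(config$base_seed, case_id, trial)
      row <- tryCatch({
        sensor <- config$sensor
        sensor$seed <- seed
        rec <- emulate_mfl(config$params, protocol, sensor,
                           entrainment_emulation(e0, config$tau_rise,
                                                 config$tau_fall))
        filt <- filter_record(rec, config$filter)
        bounds <- segment_stages(filt, protocol, "command_aligned")
        bounds <- segment_bursts(bounds, filt, protocol)
        ent <- measure_entrainment(filt, bounds, protocol)
        jet <- characterize_jet(filt, bounds)
        tibble(
          case_id = case_id, trial = trial, seed = seed,
          mode = protocol$mode, q_inj = protocol$rate_lmin,
          v_inj = .case_volume_key(protocol),
          total_volume_l = injected_volume(protocol),
          e0_true = e0,
          q_meas_rpa = ent$q_meas_rpa, q_baseline_rpa = ent$q_baseline_rpa,
          q_ent = ent$q_ent, normalized = ent$normalized, label = ent$label,
          rise_time = jet$summary$rise_time,
          fall_time = jet$summary$fall_time,
          relaxation_time = jet$summary$relaxation_time,
          settling_value = jet$summary$settling_value,
          overshoot_pct = jet$summary$overshoot_pct
        )
      }, fontanjet_error = function(e) {
        errors[[length(errors) + 1]] <<- list(case_id = case_id,
                                              trial = trial,
                                              message = conditionMessage(e))
        NULL
      })
      rows[[length(rows) + 1]] <- row
    }
  }
  trials <- list_rbind(purrr::compact(rows))

  cell_means <- trials |>
    group_by(.data$mode, .data$v_inj, .data$q_inj) |>
    summarise(q_ent = mean(.data$q_ent),
              relaxation_time = mean(.data$relaxation_time),
              .groups = "drop")
  build_matrices <- function(md) {
    sub <- cell_means |> filter(.data$mode == md)
    if (nrow(sub) == 0) return(NULL)
    ent <- tryCatch(entrainment_matrix(sub, mode = md),
                    fontanjet_error = function(e) {
                      warn(paste0("incomplete ", md, " sweep: ",
                                  conditionMessage(e)))
                      NULL
                    })
    vols <- sort(unique(sub$v_inj)); rates <- sort(unique(sub$q_inj))
    rel <- matrix(NA_real_, length(vols), length(rates),
                  dimnames = list(format(vols), format(rates)))
    for (i in seq_len(nrow(sub))) {
      rel[match(sub$v_inj[i], vols), match(sub$q_inj[i], rates)] <-
        sub$relaxation_time[i]
    }
    list(entrainment = ent, relaxation = rel)
  }
  mats <- list(continuous = build_matrices("continuous"),
               pulsed = build_matrices("pulsed"))

  manifest <- list(
    base_seed = config$base_seed,
    cases = config$cases,
    trials_per_case = config$trials_per_case,
    seeds = trials[, c("case_id", "trial", "seed")],
    config_hash = rlang::hash(config[setdiff(names(config), "output_dir")]),
    n_errors = length(errors)
  )
  out <- structure(
    list(
      trials = trials,
      entrainment_matrices = list(
        continuous = mats$continuous$entrainment,
        pulsed = mats$pulsed$entrainment
      ),
      relaxation_matrices = list(
        continuous = mats$continuous$relaxation,
        pulsed = mats$pulsed$relaxation
      ),
      manifest = manifest,
      errors = errors
    ),
    class = "mfl_sweep"
  )
  if (!is.null(config$output_dir)) .write_sweep(out, config$output_dir)
  out
}

.write_sweep <- function(sweep, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sweep$trials, file.path(dir, "trials.csv"))
  for (md in c("continuous", "pulsed")) {
    ent <- sweep$entrainment_matrices[[md]]
    if (!is.null(ent)) {
      readr::write_csv(as_tibble(ent),
                       file.path(dir, paste0("entrainment_", md, ".csv")))
    }
    rel <- sweep$relaxation_matrices[[md]]
    if (!is.null(rel)) {
      df <- as.data.frame(rel)
      df <- cbind(v_inj = rownames(rel), df)
      readr::write_csv(as_tibble(df),
                       file.path(dir, paste0("relaxation_", md, ".csv")))
    }
  }
  writeLines(jsonlite::toJSON(sweep$manifest, auto_unbox = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @export
print.mfl_sweep <- function(x, ...) {
  cat(sprintf("<mfl_sweep> %d trial(s) over %d case(s), %d error(s)\n",
              nrow(x$trials), length(unique(x$trials$case_id)),
              length(x$errors)))
  for (md in c("continuous", "pulsed")) {
    if (!is.null(x$entrainment_matrices[[md]])) {
      print(x$entrainment_matrices[[md]])
    }
  }
  invisible(x)
}
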