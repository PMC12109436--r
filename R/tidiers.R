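#' Tidy a jet characterization
#'
#' @param x A `jet_characterization` from [characterize_jet()].
#' @param ... Unused.
#' @return Long tibble with one row per burst and metric: `burst`,
#'   `metric`, `value`.
#' @method tidy jet_characterization
#' @export
tidy.jet_characterization <- function(x, ...) {
  x$per_burst |>
    select(-"buildup_label") |>
    tidyr::pivot_longer(-"burst", names_to = "metric", values_to = "value")
}

#' @rdname tidy.jet_characterization
#' @return `glance()` returns the one-row burst-averaged summary with the
#'   baseline flow attached.
#' @method glance jet_characterization
#' @export
glance.jet_characterization <- function(x, ...) {
  bind_cols(tibble(n_bursts = nrow(x$per_burst)), x$summary)
}

#' Tidy an entrainment matrix
#'
#' @param x An [entrainment_matrix()].
#' @param ... Unused.
#' @return Long tibble with `v_inj`, `q_inj`, `q_ent`, `label`, `mode`.
#' @method tidy entrainment_matrix
#' @export
tidy.entrainment_matrix <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.entrainment_matrix
#' @return `glance()` returns one row with the cutoff rate and per-column
#'   count of entraining cells.
#' @method glance entrainment_matrix
#' @export
glance.entrainment_matrix <- function(x, ...) {
  tibble(
    mode = x$mode,
    n_cells = length(x$values),
    n_entraining = sum(x$values > 0),
    cutoff_rate = cutoff_rate(x)
  )
}

#' Tidy a sweep
#'
#' @param x An `mfl_sweep` from [run_sweep()].
#' @param ... Unused.
#' @return The per-trial results tibble.
#' @method tidy mfl_sweep
#' @export
tidy.mfl_sweep <- function(x, ...) {
  x$trials
}

#' @rdname tidy.mfl_sweep
#' @method glance mfl_sweep
#' @export
glance.mfl_sweep <- function(x, ...) {
  tibble(
    n_trials = nrow(x$trials),
    n_cases = length(unique(x$trials$case_id)),
    n_errors = length(x$errors),
    cutoff_continuous = if (!is.null(x$entrainment_matrices$continuous)) {
      cutoff_rate(x$entrainment_matrices$continuous)
    } else NA_real_,
    cutoff_pulsed = if (!is.null(x$entrainment_matrices$pulsed)) {
      cutoff_rate(x$entrainment_matrices$pulsed)
    } else NA_real_
  )
}
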