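#' Tidy a leave-one-participant-out evaluation
#'
#' @param x An `understanding_eval` object from [lopo_evaluate()].
#' @param ... Unused.
#' @return `tidy()` returns the per-participant estimates
#'   (`participant_id`, `U`, `U_hat`, `abs_error`, `estimator`);
#'   `glance()` returns a one-row summary (`estimator`, `n_participants`,
#'   `mae`).
#' @export
tidy.understanding_eval <- function(x, ...) {
  dplyr::mutate(x$estimates, estimator = x$estimator)
}

#' @rdname tidy.understanding_eval
#' @export
glance.understanding_eval <- function(x, ...) {
  tibble::tibble(estimator = x$estimator, n_participants = x$n_participants,
                 mae = x$mae)
}
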