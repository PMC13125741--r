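#' Runtime configuration
#'
#' Collects the numerical knobs shared by the inference routines. Every
#' result object carries the configuration it was produced under (in its
#' `meta` field) for provenance.
#'
#' @param mode `"auto"`, `"exact"` or `"normal"`. Under `"auto"` the exact
#'   discrete distribution is used whenever its projected number of mass
#'   points is at most `mass_point_threshold` (difference distributions:
#'   whenever the projected number of support pairs is at most `conv_cap`),
#'   otherwise the delta-method normal surrogate is used.
#' @param mass_point_threshold Mass-point count above which a single-score
#'   distribution switches to the normal surrogate under `mode = "auto"`.
#' @param conv_cap Maximum number of support pairs an exact difference
#'   convolution may enumerate.
#' @param trunc_eps Total binomial tail mass that may be truncated when
#'   enumerating a score distribution at large `N`.
#' @param tie_tol Absolute tolerance used when comparing minimum-tail
#'   statistics ("more extreme than" ties).
#' @param grid_step,refine_step Coarse and fine precision-parameter grid
#'   steps for the supremum over the iso-F-beta curve.
#' @param f0_grid_step Benchmark-score grid step for the outer supremum of
#'   the two-classifier conservative test.
#' @param n_max Cap on the sample size search.
#' @param lookahead Number of consecutive sample-size increments over which
#'   the target power must hold (guards against the sawtooth of discrete
#'   tests).
#' @param seed Optional integer seed recorded for simulation runs.
#' @param verbose Emit progress messages to stderr.
#'
#' @return A list of class `"fb_config"`.
#' @export
fb_config <- function(mode = c("auto", "exact", "normal"),
                      mass_point_threshold = 20000,
                      conv_cap = 5e7,
                      trunc_eps = 1e-12,
                      tie_tol = 1e-12,
                      grid_step = 1e-3,
                      refine_step = 1e-5,
                      f0_grid_step = 1e-3,
                      n_max = 1e6,
                      lookahead = 3L,
                      seed = NULL,
                      verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(mass_point_threshold > 0, conv_cap > 0, trunc_eps > 0,
            tie_tol > 0, grid_step > 0, refine_step > 0, f0_grid_step > 0,
            n_max > 0, lookahead >= 0)
  structure(list(mode = mode,
                 mass_point_threshold = mass_point_threshold,
                 conv_cap = conv_cap,
                 trunc_eps = trunc_eps,
                 tie_tol = tie_tol,
                 grid_step = grid_step,
                 refine_step = refine_step,
                 f0_grid_step = f0_grid_step,
                 n_max = n_max,
                 lookahead = as.integer(lookahead),
                 seed = seed,
                 verbose = isTRUE(verbose)),
            class = "fb_config")
}

config_meta <- function(config) {
  config[c("mode", "mass_point_threshold", "conv_cap", "trunc_eps", "tie_tol")]
}

vmsg <- function(config, ...) {
  if (isTRUE(config$verbose)) message(...)
}
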