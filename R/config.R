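#' Default pipeline configuration
#'
#' Flat named list of tuning parameters with the defaults used throughout:
#'
#' * `preprocess.threshold` (0): similarity threshold `T_h` for
#'   [reduce_target()]; target nodes need a similarity strictly above it.
#' * `preprocess.pseudo_sim_quantile` (0): quantile of positive scores
#'   defining "high" similarity in [insert_pseudo_edges()]; 0 accepts any
#'   positive score.
#' * `preprocess.enable_pseudo_edges` (TRUE): whether to re-connect the
#'   reduced target.
#' * `csrw.tol` (1e-10), `csrw.max_iter` (10000), `csrw.laziness` (0.5):
#'   power-method controls for [steady_state()].
#' * `seeds.n_q` (NA = query size): number of seed nodes.
#' * `extend.reduction` (0.05): a candidate is accepted only if it lowers
#'   the conductance by at least this fraction.
#' * `extend.cap_factor` (2): extension stops once the subnetwork would
#'   exceed `cap_factor` times the query size.
#' * `prune.threshold` (0): nodes with extension reward not exceeding this
#'   are removed (seeds are always kept).
#' * `conductance.mode` ("module"): conductance definition used during
#'   extension, see [conductance()].
#' * `eval.match_threshold` (0.5), `eval.p_threshold` (0.05),
#'   `eval.ic_min` (2): evaluation-metric defaults.
#'
#' @param ... `key = value` overrides of the defaults
#' @return named list
#' @export
default_config <- function(...) {
  cfg <- list(
    `preprocess.threshold` = 0,
    `preprocess.pseudo_sim_quantile` = 0,
    `preprocess.enable_pseudo_edges` = TRUE,
    `csrw.tol` = 1e-10,
    `csrw.max_iter` = 10000L,
    `csrw.laziness` = 0.5,
    `seeds.n_q` = NA_integer_,
    `extend.reduction` = 0.05,
    `extend.cap_factor` = 2,
    `prune.threshold` = 0L,
    `conductance.mode` = "module",
    `eval.match_threshold` = 0.5,
    `eval.p_threshold` = 0.05,
    `eval.ic_min` = 2
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(overrides)] <- overrides
  }
  cfg
}
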