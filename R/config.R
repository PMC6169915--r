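#' Default run configuration
#'
#' The full configuration schema with defaults: model selection, decision
#' variables, marker bands, trust-region parameters, protocol profile and
#' run controls.  The default marker bands are the selected experimental
#' ranges used for human-ventricular calibration: APD90 280-310 ms,
#' triangulation 44-112 ms, systolic calcium 0.602-2.01 uM (1 Hz) and
#' 0.523-1.68 uM (0.5 Hz), diastolic calcium 0.097-0.33 uM (1 Hz) and
#' 0.091-0.32 uM (0.5 Hz), and tau_slow 70-110 s.  Note the toy scenario
#' does not use these literature bands: its bands are generated around its
#' own baseline by [make_toy_scenario()].
#'
#' @return a nested named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    model = "toy",
    profile = "test",
    seed = 1L,
    workers = 1L,
    out_dir = "condcal_out",
    decision = list(
      names = c("G_Ca", "G_K", "G_K1", "G_NaK"),
      xL = -20 * log10(2), xU = 20 * log10(2)),
    markers = list(
      apd90 = c(280, 310), triangulation = c(44, 112),
      ca_sys_1hz = c(0.602, 2.01), ca_sys_05hz = c(0.523, 1.68),
      ca_dia_1hz = c(0.097, 0.33), ca_dia_05hz = c(0.091, 0.32),
      tau_slow = c(70, 110)),
    trust = list(delta0 = 2.0, delta_max = 6.0, rho_L = 0.25,
                 tol_step = 1e-3, tol_grad = 1e-3, tol_radius = 1e-3,
                 max_iterations = 20L),
    protocol = list(
      stim_amp = -40, stim_dur = 2,
      n_beats = list(test = 300L, paper = 3000L),
      adaptation = list(test = list(n_pre = 120L, n_post = 200L),
                        paper = list(n_pre = 480L, n_post = 800L)))),
    class = "run_config")
}

#' @keywords internal
#' @noRd
.merge_config <- function(base, override, path = "") {
  for (k in names(override)) {
    key <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base))
      stop("config: unknown key '", key, "'")
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- .merge_config(base[[k]], override[[k]], key)
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Read, validate and complete a run configuration
#'
#' Reads a YAML configuration, overlays it on the defaults from
#' [default_run_config()], and validates it; unknown keys and malformed
#' bands are reported by name.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("read_run_config: no such file: ", path)
    user <- yaml::read_yaml(path)
    cfg <- structure(.merge_config(unclass(cfg), user), class = "run_config")
  }
  validate_run_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @param cfg a `run_config` to validate or write.
#' @export
validate_run_config <- function(cfg) {
  if (!cfg$model %in% c("toy") && !grepl("^cellml:", cfg$model))
    stop("config: key 'model' must be 'toy' or 'cellml:<path>'")
  if (!cfg$profile %in% c("test", "paper"))
    stop("config: key 'profile' must be 'test' or 'paper'")
  for (mn in names(cfg$markers)) {
    b <- cfg$markers[[mn]]
    if (length(b) != 2 || !is.numeric(b) || b[1] >= b[2])
      stop("config: key 'markers.", mn, "' must be an increasing pair")
  }
  tr <- cfg$trust
  do.call(trust_region_params,
          list(tr$delta0, tr$delta_max, tr$rho_L, tr$tol_step, tr$tol_grad,
               tr$tol_radius, tr$max_iterations))
  invisible(cfg)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
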