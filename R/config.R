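#' Read a simulation/estimation configuration file
#'
#' YAML (or JSON) configuration with blocks:
#' \preformatted{
#' arm:        {l1: 0.29, r1: 0.132, m1: 1.99, Iz1: 0.0161,
#'              l2: 0.40, r2: 0.17,  m2: 1.10, Iz2: 0.0146}
#' trajectory: {mode: reach, start: [0.25, 0], target: [0.55, 0],
#'              t_total: 7.5, effective_duration: 1.5, t_mid: 2.5}
#' model:      {type: kv, K0: [29.5, 14.3, 14.3, 39.3],
#'              C0: [0.85, 0.25, 0.25, 0.44],
#'              gK: {name: sigmoid}, gC: {name: constant}, phi_deg: 0}
#' perturbation: {kind: force_impulse, magnitude: 5, duration: 0.02,
#'                direction: 3, t_onset: 2.5}
#' noise:      {mode: none, snr_db: 20}
#' fs: 4000
#' }
#' Matrices are row-major length-4 lists; `phi_deg` is the damping
#' eigenvector rotation in degrees; omitted blocks fall back to the package
#' defaults.
#'
#' @param path configuration file path
#' @return list with `params`, `traj_spec`, `model`, `pert`, `noise`, `fs`
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  params <- if (!is.null(cfg$arm)) arm_params_from_list(cfg$arm) else arm_params_default()
  tj <- cfg$trajectory
  traj_spec <- trajectory_spec(
    start = if (!is.null(tj$start)) unlist(tj$start) else c(0.25, 0),
    target = if (!is.null(tj$target)) unlist(tj$target) else c(0.55, 0),
    t_total = tj$t_total %||% 7.5,
    effective_duration = tj$effective_duration %||% 1.5,
    t_mid = tj$t_mid %||% 2.5,
    mode = tj$mode %||% "reach")
  model <- build_model(cfg$model)
  pt <- cfg$perturbation
  pert <- perturbation_spec(
    kind = pt$kind %||% "force_impulse",
    magnitude = pt$magnitude,
    duration = pt$duration,
    direction = if (!is.null(pt$direction)) unlist(pt$direction) else c(1, 0),
    t_onset = pt$t_onset %||% 2.5)
  nz <- cfg$noise
  noise <- noise_spec(mode = nz$mode %||% "none", snr_db = nz$snr_db %||% 20,
                      seed = nz$seed %||% 1L)
  list(params = params, traj_spec = traj_spec, model = model, pert = pert,
       noise = noise, fs = cfg$fs %||% 4000)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mat_rm <- function(v) matrix(as.numeric(unlist(v)), 2, 2, byrow = TRUE)

build_gain <- function(g) {
  if (is.null(g)) return(gain_profile("constant"))
  do.call(gain_profile, g)
}

build_model <- function(m) {
  if (is.null(m)) return(kv_reference())
  type <- m$type %||% "kv"
  switch(type,
    kv = {
      ref <- kv_reference()
      kv_model(K0 = if (!is.null(m$K0)) mat_rm(m$K0) else ref$K0,
               C0 = if (!is.null(m$C0)) mat_rm(m$C0) else ref$C0,
               gK = build_gain(m$gK), gC = build_gain(m$gC),
               phi = (m$phi_deg %||% 0) * pi / 180)
    },
    pt = {
      ref <- pt_reference()
      pt_model(K_t = if (!is.null(m$K_t)) mat_rm(m$K_t) else ref$K_t,
               K_f = if (!is.null(m$K_f)) mat_rm(m$K_f) else ref$K_f,
               C_f = if (!is.null(m$C_f)) mat_rm(m$C_f) else ref$C_f)
    },
    duffing = {
      ref <- duffing_reference()
      duffing_model(K = if (!is.null(m$K)) mat_rm(m$K) else ref$K,
                    C = if (!is.null(m$C)) mat_rm(m$C) else ref$C,
                    K3 = if (!is.null(m$K3)) mat_rm(m$K3) else ref$K3)
    },
    stop("unknown model type: ", type))
}
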