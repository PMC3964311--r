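# Steady-state stochastic simulator of the integrated transgene circuits.
# Snapshot model: per-cell multiplicative log-normal factors around a
# deterministic Hill-function steady state, not a kinetic trajectory.

# Hill activation of the bidirectional promoter by rtTA/Dox; 0 at dox = 0.
hill_activation <- function(dox, K, h) {
  ifelse(dox <= 0, 0, 1 / (1 + (K / dox)^h))
}

# Fraction of LacI still active (DNA-binding) at a given IPTG level; 1 at 0.
laci_active_fraction <- function(iptg, K, h) {
  ifelse(iptg <= 0, 1, 1 / (1 + (iptg / K)^h))
}

# Unique positive root of L * (1 + (f*L/K)^h) = U, vectorised over U.
# The left side is strictly increasing in L and the root lies in [0, U],
# so interval bisection always converges.
solve_feedback <- function(U, f, K, h, max_iter = 120L, rel_tol = 1e-14) {
  out <- numeric(length(U))
  active <- is.finite(U) & U > 0 & f > 0
  out[!active & is.finite(U)] <- U[!active & is.finite(U)]  # no repression
  if (any(active)) {
    u <- U[active]
    lo <- numeric(length(u))
    hi <- u
    for (iter in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      too_high <- mid * (1 + (f * mid / K)^h) > u
      hi[too_high] <- mid[too_high]
      lo[!too_high] <- mid[!too_high]
      if (max((hi - lo) / pmax(hi, .Machine$double.xmin)) < rel_tol) break
    }
    root <- (lo + hi) / 2
    resid <- abs(root * (1 + (f * root / K)^h) - u)
    if (max(resid / pmax(u, .Machine$double.xmin)) > 1e-8)
      stop("solve_feedback: fixed-point iteration did not converge; ",
           "parameters are pathological", call. = FALSE)
    out[active] <- root
  }
  out
}

#' Steady-state LacI level of a circuit
#'
#' For the negative-feedback architecture, returns the unique root `L` of
#' `L = n * v_green * A(dox) * e * i / (1 + (f(iptg) * L / laci_K)^laci_h)`,
#' where `A` is the Dox activation Hill term and `f` the active LacI
#' fraction under IPTG. For simple regulation LacI is produced
#' constitutively and the unrepressed closed form
#' `n * v_green * A(dox) * e * i` is returned.
#'
#' @param params a [circuit_params()] object.
#' @param condition a [well_condition()] object.
#' @param ext_factor,int_factor strictly positive multiplicative noise
#'   factors on the production rate (vectorised; recycled to a common
#'   length).
#' @return Steady-state LacI level(s) in the same arbitrary units as
#'   `v_green`.
#' @export
#' @examples
#' p <- circuit_params("negative_feedback")
#' steady_state_laci(p, well_condition(iptg = 25, dox = 5000))
steady_state_laci <- function(params, condition, ext_factor = 1,
                              int_factor = 1) {
  stopifnot(inherits(params, "circuit_params"),
            inherits(condition, "well_condition"))
  if (any(ext_factor <= 0) || any(int_factor <= 0))
    stop("steady_state_laci: noise factors must be strictly positive",
         call. = FALSE)
  A <- hill_activation(condition$dox, params$dox_K, params$dox_h)
  U <- params$copy_number * params$v_green * A * ext_factor * int_factor
  if (params$architecture == "simple_regulation") return(U)
  f <- laci_active_fraction(condition$iptg, params$iptg_K, params$iptg_h)
  solve_feedback(U, f, params$laci_K, params$laci_h)
}

#' Noise-free dose response of both reporters
#'
#' Deterministic steady state with every noise source switched off; the
#' oracle against which simulated population means are checked. Values are
#' fluorescence above background (protein level times channel gain).
#'
#' @inheritParams steady_state_laci
#' @return Named numeric vector with elements `green` and `red`.
#' @export
mean_dose_response <- function(params, condition) {
  stopifnot(inherits(params, "circuit_params"),
            inherits(condition, "well_condition"))
  A <- hill_activation(condition$dox, params$dox_K, params$dox_h)
  f <- laci_active_fraction(condition$iptg, params$iptg_K, params$iptg_h)
  L <- steady_state_laci(params, condition)
  if (params$architecture == "negative_feedback") {
    green <- L
    red <- params$copy_number * params$v_red * A
  } else {
    green <- L  # zsGreen1 co-expressed with constitutive LacI
    red <- params$copy_number * params$v_red * A /
      (1 + (f * L / params$laci_K)^params$laci_h)
  }
  c(green = params$gain_green * green, red = params$gain_red * red)
}

#' Simulate a flow-cytometry snapshot of one well
#'
#' Draws `n_cells` cells at steady state. Each cell shares one extrinsic
#' factor `exp(N(0, sigma_ext^2))` across both genes and has independent
#' per-gene intrinsic factors. The regulated transcript's intrinsic factor
#' enters the production rate (so feedback attenuates it); an additional
#' abundance-scaled gene-specific factor with log-variance
#' `int_abund / mean_protein` acts downstream of regulation. Fluorescence is
#' protein times gain plus Gaussian autofluorescence, and FSC/SSC are
#' log-normal with latent normals correlated (`scatter_corr`) to the
#' extrinsic factor's latent normal.
#'
#' The output is deterministic given `(params, condition, n_cells, seed)`;
#' the caller's RNG state is left untouched.
#'
#' @inheritParams steady_state_laci
#' @param n_cells number of cells (>= 1).
#' @param seed integer seed.
#' @param well_id well identifier stored in the event metadata.
#' @return An [event_table()] with `n_cells` rows.
#' @export
simulate_population <- function(params, condition, n_cells, seed,
                                well_id = "well") {
  stopifnot(inherits(params, "circuit_params"),
            inherits(condition, "well_condition"))
  n_cells <- as.integer(n_cells)
  if (n_cells < 1L) stop("simulate_population: 'n_cells' must be >= 1",
                         call. = FALSE)
  with_seed(seed, {
    z_ext <- stats::rnorm(n_cells)
    e <- exp(params$sigma_ext * z_ext)
    i_g <- exp(params$sigma_int_green * stats::rnorm(n_cells))
    i_r <- exp(params$sigma_int_red * stats::rnorm(n_cells))

    A <- hill_activation(condition$dox, params$dox_K, params$dox_h)
    f <- laci_active_fraction(condition$iptg, params$iptg_K, params$iptg_h)
    n <- params$copy_number
    if (params$architecture == "negative_feedback") {
      L <- solve_feedback(n * params$v_green * A * e * i_g, f,
                          params$laci_K, params$laci_h)
      green_protein <- L
      red_protein <- n * params$v_red * A * e * i_r
    } else {
      L <- n * params$v_green * A * e * i_g
      green_protein <- L
      red_protein <- n * params$v_red * A * e * i_r /
        (1 + (f * L / params$laci_K)^params$laci_h)
    }

    # abundance-scaled intrinsic component, downstream of regulation
    m <- mean_dose_response(params, condition)
    sd_ab_g <- if (params$int_abund > 0 && m[["green"]] > 0)
      sqrt(params$int_abund / (m[["green"]] / params$gain_green)) else 0
    sd_ab_r <- if (params$int_abund > 0 && m[["red"]] > 0)
      sqrt(params$int_abund / (m[["red"]] / params$gain_red)) else 0
    green_protein <- green_protein * exp(sd_ab_g * stats::rnorm(n_cells))
    red_protein <- red_protein * exp(sd_ab_r * stats::rnorm(n_cells))

    green <- params$gain_green * green_protein +
      stats::rnorm(n_cells, params$bg_mean_green, params$bg_sd_green)
    red <- params$gain_red * red_protein +
      stats::rnorm(n_cells, params$bg_mean_red, params$bg_sd_red)

    rho <- params$scatter_corr
    z_f <- rho * z_ext + sqrt(1 - rho^2) * stats::rnorm(n_cells)
    z_s <- rho * z_ext + sqrt(1 - rho^2) * stats::rnorm(n_cells)
    fsc <- params$scatter_mean * exp(params$scatter_sd * z_f)
    ssc <- params$scatter_mean * exp(params$scatter_sd * z_s)

    event_table(data.frame(well_id = well_id,
                           iptg_uM = condition$iptg,
                           dox_ng_ml = condition$dox,
                           replicate = condition$replicate,
                           fsc = fsc, ssc = ssc,
                           green = green, red = red,
                           stringsAsFactors = FALSE))
  })
}

#' Generate a two-reporter validation scenario
#'
#' Direct draws from the log-normal generative model used to validate the
#' decomposition: `log X = mean_log_x + alpha_true * eps + eta_x` and
#' `log Y = mean_log_y + eps + eta_y` with shared `eps ~ N(0, sigma_ext^2)`
#' and independent `eta_g ~ N(0, sigma_int_g^2)`. `"pure_extrinsic"`
#' requires both intrinsic s.d. to be zero (a single transcription strength
#' varied for both genes gives perfectly correlated reporters);
#' `"pure_intrinsic"` requires `sigma_ext = 0` (independent variation gives
#' uncorrelated reporters); `"mixture"` allows all components. X is stored
#' in the green channel, Y in the red channel; scatter channels are coupled
#' to `eps` as in [simulate_population()].
#'
#' @param kind `"pure_extrinsic"`, `"pure_intrinsic"` or `"mixture"`.
#' @param gen a [generative_params()] object.
#' @param n_cells number of cells.
#' @param seed integer seed.
#' @param iptg,dox,replicate,well_id metadata stored with the events.
#' @param scatter_corr coupling of scatter to the extrinsic latent normal.
#' @return An [event_table()].
#' @export
make_validation_scenario <- function(kind = c("pure_extrinsic",
                                              "pure_intrinsic", "mixture"),
                                     gen = generative_params(),
                                     n_cells, seed,
                                     iptg = NA_real_, dox = NA_real_,
                                     replicate = "r1", well_id = NULL,
                                     scatter_corr = 0.6) {
  kind <- match.arg(kind)
  stopifnot(inherits(gen, "generative_params"))
  if (kind == "pure_extrinsic" && (gen$sigma_int_x > 0 || gen$sigma_int_y > 0))
    stop("make_validation_scenario: 'pure_extrinsic' requires ",
         "sigma_int_x = sigma_int_y = 0", call. = FALSE)
  if (kind == "pure_intrinsic" && gen$sigma_ext > 0)
    stop("make_validation_scenario: 'pure_intrinsic' requires sigma_ext = 0",
         call. = FALSE)
  if (is.null(well_id)) well_id <- kind
  n_cells <- as.integer(n_cells)
  with_seed(seed, {
    z_eps <- stats::rnorm(n_cells)
    eps <- gen$sigma_ext * z_eps
    x <- exp(gen$mean_log_x + gen$alpha_true * eps +
               gen$sigma_int_x * stats::rnorm(n_cells))
    y <- exp(gen$mean_log_y + eps + gen$sigma_int_y * stats::rnorm(n_cells))
    rho <- scatter_corr
    z_f <- rho * z_eps + sqrt(1 - rho^2) * stats::rnorm(n_cells)
    z_s <- rho * z_eps + sqrt(1 - rho^2) * stats::rnorm(n_cells)
    event_table(data.frame(well_id = well_id, iptg_uM = iptg,
                           dox_ng_ml = dox, replicate = replicate,
                           fsc = 5e4 * exp(0.25 * z_f),
                           ssc = 5e4 * exp(0.25 * z_s),
                           green = x, red = y,
                           stringsAsFactors = FALSE))
  })
}

#' Ground-truth noise components of the generative model
#'
#' Closed-form log-variance components implied by [generative_params()]:
#' extrinsic `alpha_true^2 * sigma_ext^2` for X and `sigma_ext^2` for Y,
#' intrinsic `sigma_int_x^2` and `sigma_int_y^2`. Used as the oracle in
#' decomposition-recovery tests.
#'
#' @param gen a [generative_params()] object.
#' @return Named list with `ext_x`, `ext_y`, `int_x`, `int_y` and the
#'   implied log-covariance `cov_log = alpha_true * sigma_ext^2`.
#' @export
expected_noise_components <- function(gen) {
  stopifnot(inherits(gen, "generative_params"))
  list(ext_x = gen$alpha_true^2 * gen$sigma_ext^2,
       ext_y = gen$sigma_ext^2,
       int_x = gen$sigma_int_x^2,
       int_y = gen$sigma_int_y^2,
       cov_log = gen$alpha_true * gen$sigma_ext^2)
}

# Evaluate code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic splitting scheme used to give every (well, replicate) pair
#' its own independent stream: `(master + 104729 * index) mod (2^31 - 1)`.
#'
#' @param master master seed (integer).
#' @param index non-negative integer stream index.
#' @return Integer seed in `[0, 2^31 - 2]`.
#' @export
split_seed <- function(master, index) {
  as.integer((as.double(master) + 104729 * as.double(index)) %% 2147483647)
}
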