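#' Parameters of the synthetic transgene circuit simulator
#'
#' Builds a validated parameter set for the steady-state stochastic simulator
#' of the two integrated architectures: transcriptional negative
#' autoregulation (LacI represses its own bidirectional transcription unit,
#' zsGreen1 co-expressed via an IRES reads it out) and simple negative
#' regulation (constitutively produced LacI represses the dsRed reporter on
#' the opposite side of the promoter).
#'
#' Defaults depend on `architecture`. The repression parameters (`laci_K`,
#' `laci_h`) and the copy number are chosen per architecture so that the
#' regulated channel spans roughly a four- to eight-fold range over the
#' 0.0625--25 uM IPTG titration at saturating Dox, matching the fold ranges
#' these circuits exhibit; they are illustrative operating points, not fits.
#'
#' @param architecture `"negative_feedback"` (zsGreen1 regulated, dsRed
#'   constitutive) or `"simple_regulation"` (dsRed regulated, zsGreen1
#'   constitutive).
#' @param copy_number integer number of integrated transgene copies; default
#'   1 for negative feedback and 2 for simple regulation. Expression scales
#'   linearly with copy number.
#' @param v_green,v_red maximal per-copy expression rates in arbitrary
#'   fluorescence-proportional units.
#' @param dox_K,dox_h half-activation Dox concentration (ng/ml) and Hill
#'   coefficient of rtTA activation; a single activation term drives both
#'   directions of the bidirectional promoter.
#' @param laci_K,laci_h half-repression LacI level (a.u.) and Hill
#'   coefficient of operator binding.
#' @param iptg_K,iptg_h half-inactivation IPTG concentration (uM) and Hill
#'   coefficient; IPTG reduces the active LacI fraction
#'   `f(iptg) = 1 / (1 + (iptg/iptg_K)^iptg_h)`.
#' @param sigma_ext standard deviation of the shared log-normal extrinsic
#'   factor applied to both genes of a cell.
#' @param sigma_int_green,sigma_int_red standard deviations of the per-gene
#'   log-normal intrinsic (transcriptional) factors; these enter the
#'   production rates and are therefore attenuated by feedback.
#' @param int_abund coefficient of the abundance-scaled intrinsic component:
#'   each reporter receives additional gene-specific log-normal noise with
#'   log-variance `int_abund / mean_protein`, applied downstream of
#'   regulation. This is the birth--death-like component that makes noise
#'   scale inversely with protein abundance; set to 0 to disable.
#' @param gain_green,gain_red fluorescence units per protein unit.
#' @param bg_mean_green,bg_sd_green,bg_mean_red,bg_sd_red Gaussian
#'   autofluorescence background (a.u.).
#' @param scatter_mean,scatter_sd location and log-scale s.d. of the
#'   log-normal FSC/SSC distributions.
#' @param scatter_corr correlation between each scatter channel's latent
#'   normal and the extrinsic factor's latent normal (default 0.6), so that
#'   shrinking a scatter gate preferentially removes extrinsic variation.
#'
#' @return An object of class `circuit_params`.
#' @seealso [simulate_population()], [mean_dose_response()]
#' @export
#' @examples
#' p <- circuit_params("negative_feedback")
#' p$laci_K
circuit_params <- function(architecture = c("negative_feedback",
                                            "simple_regulation"),
                           copy_number = NULL,
                           v_green = 400, v_red = 400,
                           dox_K = 1000, dox_h = 2,
                           laci_K = NULL, laci_h = NULL,
                           iptg_K = 1, iptg_h = 2,
                           sigma_ext = 0.17,
                           sigma_int_green = 0.1, sigma_int_red = 0.14,
                           int_abund = 2,
                           gain_green = 1, gain_red = 1,
                           bg_mean_green = 5, bg_sd_green = 1,
                           bg_mean_red = 5, bg_sd_red = 1,
                           scatter_mean = 5e4, scatter_sd = 0.25,
                           scatter_corr = 0.6) {
  architecture <- match.arg(architecture)
  if (is.null(copy_number))
    copy_number <- if (architecture == "negative_feedback") 1L else 2L
  if (is.null(laci_K))
    laci_K <- if (architecture == "negative_feedback") 30 else 110
  if (is.null(laci_h))
    laci_h <- if (architecture == "negative_feedback") 2 else 1

  p <- list(architecture = architecture,
            copy_number = as.integer(copy_number),
            v_green = v_green, v_red = v_red,
            dox_K = dox_K, dox_h = dox_h,
            laci_K = laci_K, laci_h = laci_h,
            iptg_K = iptg_K, iptg_h = iptg_h,
            sigma_ext = sigma_ext,
            sigma_int_green = sigma_int_green,
            sigma_int_red = sigma_int_red,
            int_abund = int_abund,
            gain_green = gain_green, gain_red = gain_red,
            bg_mean_green = bg_mean_green, bg_sd_green = bg_sd_green,
            bg_mean_red = bg_mean_red, bg_sd_red = bg_sd_red,
            scatter_mean = scatter_mean, scatter_sd = scatter_sd,
            scatter_corr = scatter_corr)
  validate_circuit_params(p)
  structure(p, class = "circuit_params")
}

validate_circuit_params <- function(p) {
  pos <- c("v_green", "v_red", "dox_K", "dox_h", "laci_K", "laci_h",
           "iptg_K", "iptg_h", "gain_green", "gain_red",
           "scatter_mean", "scatter_sd")
  for (nm in pos)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0)
      stop("circuit_params: '", nm, "' must be a single strictly positive number",
           call. = FALSE)
  nonneg <- c("sigma_ext", "sigma_int_green", "sigma_int_red", "int_abund",
              "bg_mean_green", "bg_sd_green", "bg_mean_red", "bg_sd_red")
  for (nm in nonneg)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] < 0)
      stop("circuit_params: '", nm, "' must be a single non-negative number",
           call. = FALSE)
  if (p$copy_number < 1L)
    stop("circuit_params: 'copy_number' must be >= 1", call. = FALSE)
  if (abs(p$scatter_corr) >= 1)
    stop("circuit_params: 'scatter_corr' must lie in (-1, 1)", call. = FALSE)
  invisible(p)
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("Circuit parameters (", x$architecture, ", ", x$copy_number,
      if (x$copy_number == 1L) " copy)\n" else " copies)\n", sep = "")
  cat(sprintf("  activation : dox_K = %g ng/ml, dox_h = %g\n", x$dox_K, x$dox_h))
  cat(sprintf("  repression : laci_K = %g a.u., laci_h = %g; iptg_K = %g uM, iptg_h = %g\n",
              x$laci_K, x$laci_h, x$iptg_K, x$iptg_h))
  cat(sprintf("  noise      : sigma_ext = %g, sigma_int = (%g, %g), int_abund = %g\n",
              x$sigma_ext, x$sigma_int_green, x$sigma_int_red, x$int_abund))
  invisible(x)
}

#' Parameters of the log-normal two-reporter generative model
#'
#' The multiplicative noise model behind the decomposition: reporter X (the
#' regulated one) is `exp(mean_log_x + alpha_true * eps + eta_x)` and
#' reporter Y (constitutive) is `exp(mean_log_y + eps + eta_y)`, with
#' `eps ~ N(0, sigma_ext^2)` shared per cell and independent gene-specific
#' `eta_g ~ N(0, sigma_int_g^2)`. `alpha_true` is the regulated reporter's
#' sensitivity to the shared extrinsic variable; it equals 1 when the two
#' reporters are equally sensitive (e.g. at full induction).
#'
#' @param sigma_ext s.d. of the shared extrinsic latent normal.
#' @param sigma_int_x,sigma_int_y s.d. of the gene-specific latent normals.
#' @param alpha_true extrinsic sensitivity of reporter X (>= 0).
#' @param mean_log_x,mean_log_y location parameters of the log reporters.
#' @return An object of class `generative_params`.
#' @seealso [make_validation_scenario()], [expected_noise_components()]
#' @export
generative_params <- function(sigma_ext = 0.2,
                              sigma_int_x = 0.1, sigma_int_y = 0.14,
                              alpha_true = 0.7,
                              mean_log_x = log(200), mean_log_y = log(200)) {
  for (nm in c("sigma_ext", "sigma_int_x", "sigma_int_y"))
    if (get(nm) < 0 || !is.finite(get(nm)))
      stop("generative_params: '", nm, "' must be non-negative", call. = FALSE)
  if (alpha_true < 0 || !is.finite(alpha_true))
    stop("generative_params: 'alpha_true' must be non-negative", call. = FALSE)
  structure(list(sigma_ext = sigma_ext,
                 sigma_int_x = sigma_int_x, sigma_int_y = sigma_int_y,
                 alpha_true = alpha_true,
                 mean_log_x = mean_log_x, mean_log_y = mean_log_y),
            class = "generative_params")
}

#' @export
print.generative_params <- function(x, ...) {
  cat("Two-reporter generative model\n")
  cat(sprintf("  sigma_ext = %g, sigma_int_x = %g, sigma_int_y = %g, alpha_true = %g\n",
              x$sigma_ext, x$sigma_int_x, x$sigma_int_y, x$alpha_true))
  invisible(x)
}

#' Experimental condition of a well
#'
#' @param iptg IPTG concentration in uM (>= 0); inactivates LacI.
#' @param dox Doxycycline concentration in ng/ml (>= 0); activates the
#'   bidirectional promoter through rtTA.
#' @param replicate replicate label.
#' @return An object of class `well_condition`.
#' @export
well_condition <- function(iptg = 0, dox = 5000, replicate = "r1") {
  if (!is.numeric(iptg) || iptg < 0 || !is.finite(iptg))
    stop("well_condition: 'iptg' must be non-negative", call. = FALSE)
  if (!is.numeric(dox) || dox < 0 || !is.finite(dox))
    stop("well_condition: 'dox' must be non-negative", call. = FALSE)
  structure(list(iptg = iptg, dox = dox, replicate = as.character(replicate)),
            class = "well_condition")
}

#' Channel roles implied by the circuit architecture
#'
#' In the negative-feedback clone the zsGreen1 channel reads out the
#' regulated (self-repressing) transcript and dsRed is constitutive; in the
#' simple-regulation clone the roles are swapped.
#'
#' @param architecture circuit architecture string.
#' @return Channel name, `"green"` or `"red"`.
#' @export
regulated_channel <- function(architecture) {
  switch(match.arg(architecture, c("negative_feedback", "simple_regulation")),
         negative_feedback = "green", simple_regulation = "red")
}

#' @rdname regulated_channel
#' @export
constitutive_channel <- function(architecture) {
  switch(match.arg(architecture, c("negative_feedback", "simple_regulation")),
         negative_feedback = "red", simple_regulation = "green")
}
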