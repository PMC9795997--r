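#' Isotope ratio standards
#'
#' Isotope ratios of the international reference standards used for
#' delta-notation conversions: VSMOW for 18O/16O and VPDB for 13C/12C.
#'
#' @name standards
#' @keywords internal
NULL

#' @rdname standards
#' @export
R_VSMOW <- 2005.20e-6

#' @rdname standards
#' @export
R_VPDB <- 0.0111802

#' Convert between delta notation and isotope ratios
#'
#' All model arithmetic is carried out in isotope-ratio (R) space; per-mil
#' delta values appear only at input/output. `delta = R/R_std - 1`, reported
#' in per mil.
#'
#' @param delta Isotope composition in per mil relative to `R_std`.
#' @param R Isotope ratio (heavy/light).
#' @param R_std Ratio of the reference standard ([R_VSMOW] or [R_VPDB]).
#' @return `delta_to_ratio` returns a ratio; `ratio_to_delta` returns per mil.
#' @examples
#' ratio_to_delta(delta_to_ratio(-12, R_VSMOW), R_VSMOW)
#' @export
delta_to_ratio <- function(delta, R_std) {
  (delta / 1000 + 1) * R_std
}

#' @rdname delta_to_ratio
#' @export
ratio_to_delta <- function(R, R_std) {
  (R / R_std - 1) * 1000
}

#' Parameters of the oxygen-18 leaf water and sugar model
#'
#' Fractionation factors and leaf properties controlling 18O enrichment of
#' leaf water and its transfer to assimilates. Defaults are the values used
#' for mature Scots pine needles (all-sided leaf-area basis).
#'
#' @param epsilon_ks Kinetic fractionation for water vapour diffusion through
#'   stomata (per mil), default 28.
#' @param epsilon_kb Kinetic fractionation for diffusion through the leaf
#'   boundary layer (per mil), default 19.
#' @param f1 Ratio of evaporatively enriched to total needle water in the
#'   two-pool model (unitless, 0 < f1 <= 1), default 0.93.
#' @param L Effective mixing length of the Peclet model (m), default 0.03.
#' @param W Leaf mesophyll water content (mol m-2), default 5.6.
#' @param C_molar Molar density of liquid water (mol m-3).
#' @param D_H218O Diffusivity of H2-18O in liquid water (m2 s-1).
#' @param epsilon_wc_mode Biochemical fractionation between carbonyl oxygen
#'   and water: `"constant"` (27 per mil) or `"temperature"` (see
#'   [epsilon_wc()]).
#' @return A list of class `o18_params`.
#' @export
o18_params <- function(epsilon_ks = 28, epsilon_kb = 19, f1 = 0.93,
                       L = 0.03, W = 5.6, C_molar = 55.5e3,
                       D_H218O = 2.66e-9,
                       epsilon_wc_mode = c("constant", "temperature")) {
  epsilon_wc_mode <- match.arg(epsilon_wc_mode)
  stopifnot(f1 > 0, f1 <= 1, L > 0, W > 0, C_molar > 0, D_H218O > 0)
  structure(list(epsilon_ks = epsilon_ks, epsilon_kb = epsilon_kb,
                 f1 = f1, L = L, W = W, C_molar = C_molar,
                 D_H218O = D_H218O, epsilon_wc_mode = epsilon_wc_mode),
            class = "o18_params")
}

#' Parameters of the 13C discrimination model
#'
#' Fractionation factors of the discrimination model for net CO2 exchange
#' and the switches selecting its reduced variants.
#'
#' @param a_b Fractionation during diffusion of CO2 through the boundary
#'   layer (per mil), default 2.9.
#' @param a_s Fractionation during diffusion through stomata (per mil),
#'   default 4.4.
#' @param a_m Fractionation during transfer through mesophyll (per mil),
#'   default 1.8.
#' @param b Fractionation during carboxylation (per mil); 29 for the full
#'   model, 27 in the simple variant where it implicitly absorbs all
#'   photosynthetic fractionation processes.
#' @param f Fractionation during photorespiration (per mil), default 8.
#' @param e Fractionation during mitochondrial respiration (per mil),
#'   default -6.
#' @param use_mesophyll Use chloroplast CO2 (`C_c`) rather than assuming
#'   `C_c = C_i`.
#' @param use_photoresp Include the photorespiration term (`f`).
#' @param use_mito_resp Include mitochondrial respiration (`r_d` and `e`)
#'   in the discrimination; when `FALSE`, `r_d` is treated as zero.
#' @param simple_mode The most reduced formulation: sets `b = 27`,
#'   `C_c = C_i`, `f = 0` and `r_d = 0`.
#' @param mask_tol Steps with `|k C_a - r_d|` below this flux tolerance
#'   (umol m-2 s-1) are masked as numerically undefined (the day/night
#'   transition noise of the discrimination equation).
#' @return A list of class `c13_params`.
#' @export
c13_params <- function(a_b = 2.9, a_s = 4.4, a_m = 1.8, b = 29, f = 8,
                       e = -6, use_mesophyll = TRUE, use_photoresp = TRUE,
                       use_mito_resp = TRUE, simple_mode = FALSE,
                       mask_tol = 0.05) {
  if (simple_mode) {
    b <- 27
    f <- 0
    use_mesophyll <- FALSE
    use_photoresp <- FALSE
    use_mito_resp <- FALSE
  }
  if (!use_photoresp) f <- 0
  structure(list(a_b = a_b, a_s = a_s, a_m = a_m, b = b, f = f, e = e,
                 use_mesophyll = use_mesophyll,
                 use_photoresp = use_photoresp,
                 use_mito_resp = use_mito_resp,
                 simple_mode = simple_mode, mask_tol = mask_tol),
            class = "c13_params")
}

#' Parameters of the needle carbohydrate pools
#'
#' Sizes and fixed isotopic signatures of the needle sugar and pinitol
#' pools, and the cumulative-weight cutoff defining the signal formation
#' period.
#'
#' @param S_sug Concentration of needle sugar (umol C m-2, all-sided).
#'   Default 1.96e5 (the observed pool); the `"negligible"` variant uses a
#'   20-fold smaller value.
#' @param pinitol_ratio Ratio of pinitol to total sugar concentration,
#'   default 0.7, so `S_pin = 0.7 * S_sug`.
#' @param delta13C_pin Pinitol delta-13C (per mil VPDB), default -30.5.
#' @param delta18O_pin Pinitol delta-18O (per mil VSMOW), default 25.
#' @param cutoff Cumulative assimilate weight defining the formation
#'   period, default 0.95.
#' @param pool_size `"observed"` or `"negligible"` (S_sug / 20).
#' @return A list of class `pool_params` with fields `S_sug`, `S_pin`,
#'   `delta13C_pin`, `delta18O_pin`, `cutoff`.
#' @export
pool_params <- function(S_sug = 1.96e5, pinitol_ratio = 0.7,
                        delta13C_pin = -30.5, delta18O_pin = 25,
                        cutoff = 0.95,
                        pool_size = c("observed", "negligible")) {
  pool_size <- match.arg(pool_size)
  stopifnot(S_sug > 0, pinitol_ratio >= 0, cutoff > 0, cutoff < 1)
  S_pin <- pinitol_ratio * S_sug
  if (pool_size == "negligible") S_sug <- S_sug / 20
  structure(list(S_sug = S_sug, S_pin = S_pin,
                 delta13C_pin = delta13C_pin, delta18O_pin = delta18O_pin,
                 cutoff = cutoff, pool_size = pool_size),
            class = "pool_params")
}

#' Model variant configuration
#'
#' Switches selecting one member of the model-variant grid: the leaf water
#' 18O model, the steadiness assumption, the biochemical fractionation mode,
#' the 13C discrimination variant, mesophyll resistance, and the sugar pool
#' size.
#'
#' @param leafwater Leaf water 18O model: `"peclet"` (transpiration
#'   dependent f1), `"two_pool"` (constant f1) or `"craig_gordon"`
#'   (f1 = 1, evaporative-site enrichment).
#' @param steady `"nonsteady"` (dynamic leaf water, recommended) or
#'   `"steady"`.
#' @param epsilon_wc `"temperature"` or `"constant"` biochemical
#'   fractionation.
#' @param c13 Discrimination variant: `"full_mito"` (all terms),
#'   `"plus_photoresp"` (r_d = 0), `"diffusion_carbox"` (r_d = f = 0,
#'   b = 29) or `"simple_b27"` (r_d = f = 0, b = 27, C_c = C_i).
#' @param mesophyll `"on"` uses chloroplast CO2 in the discrimination,
#'   `"off"` sets C_c = C_i. Forced `"off"` by `c13 = "simple_b27"`.
#' @param pool `"observed"` or `"negligible"` sugar pool size.
#' @return A list of class `variant_config`.
#' @export
variant_config <- function(leafwater = c("peclet", "two_pool", "craig_gordon"),
                           steady = c("nonsteady", "steady"),
                           epsilon_wc = c("temperature", "constant"),
                           c13 = c("full_mito", "plus_photoresp",
                                   "diffusion_carbox", "simple_b27"),
                           mesophyll = c("on", "off"),
                           pool = c("observed", "negligible")) {
  cfg <- list(leafwater = match.arg(leafwater),
              steady = match.arg(steady),
              epsilon_wc = match.arg(epsilon_wc),
              c13 = match.arg(c13),
              mesophyll = match.arg(mesophyll),
              pool = match.arg(pool))
  if (cfg$c13 == "simple_b27") cfg$mesophyll <- "off"
  structure(cfg, class = "variant_config")
}

#' @export
print.variant_config <- function(x, ...) {
  cat("Model variant:\n")
  for (k in names(x)) cat(sprintf("  %-11s %s\n", k, x[[k]]))
  invisible(x)
}

# c13_params matching a variant_config
c13_params_for_variant <- function(config) {
  switch(config$c13,
    simple_b27 = c13_params(simple_mode = TRUE),
    diffusion_carbox = c13_params(use_photoresp = FALSE, use_mito_resp = FALSE,
                                  use_mesophyll = config$mesophyll == "on"),
    plus_photoresp = c13_params(use_mito_resp = FALSE,
                                use_mesophyll = config$mesophyll == "on"),
    full_mito = c13_params(use_mesophyll = config$mesophyll == "on"))
}
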