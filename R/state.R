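# Domain containers: lake state, kinetic parameters, lake geometry.

#' Lake state at one time point
#'
#' Concentrations of the seven modelled constituents. Chlorophyll-a and
#' phytoplankton carbon are tied by the fixed ratio `chl = chl_to_c * pc`;
#' supply either one and the other is derived (supplying both is accepted only
#' if consistent).
#'
#' @param pc Phytoplankton carbon (mg C/L).
#' @param chl Chlorophyll-a (µg/L). Derived from `pc` if missing.
#' @param dc Detritus carbon (mg C/L).
#' @param iss Inorganic suspended solids (mg/L).
#' @param nh4 Ammonium nitrogen (mg N/L).
#' @param no3 Nitrate nitrogen (mg N/L).
#' @param ip Inorganic phosphorus (mg P/L).
#' @param chl_to_c Fixed chlorophyll:carbon ratio (µg Chl-a per mg C).
#' @return An object of class `lake_state`.
#' @examples
#' lake_state(chl = 10, iss = 20, dc = 1, nh4 = 0.5, no3 = 1, ip = 0.05)
#' @export
lake_state <- function(pc = NULL, chl = NULL, dc = 0, iss = 0,
                       nh4 = 0, no3 = 0, ip = 0, chl_to_c = 25) {
  if (is.null(pc) && is.null(chl)) {
    pc <- 0
    chl <- 0
  } else if (is.null(pc)) {
    pc <- chl / chl_to_c
  } else if (is.null(chl)) {
    chl <- chl_to_c * pc
  } else if (abs(chl - chl_to_c * pc) > 1e-8 * max(1, abs(chl))) {
    stop("inconsistent chl and pc: the fixed-ratio closure requires chl = chl_to_c * pc")
  }
  vals <- c(chl = chl, pc = pc, dc = dc, iss = iss, nh4 = nh4, no3 = no3, ip = ip)
  bad <- names(vals)[!is.finite(vals) | vals < 0]
  if (length(bad)) {
    stop("negative or non-finite concentration for constituent '", bad[1], "'")
  }
  structure(
    list(chl = chl, pc = pc, dc = dc, iss = iss, nh4 = nh4, no3 = no3,
         ip = ip, chl_to_c = chl_to_c),
    class = "lake_state"
  )
}

#' @export
print.lake_state <- function(x, ...) {
  cat("lake state (chl ", format(x$chl, digits = 4), " ug/L, pc ",
      format(x$pc, digits = 4), ", dc ", format(x$dc, digits = 4),
      ", iss ", format(x$iss, digits = 4),
      " mg/L; nh4 ", format(x$nh4, digits = 4),
      ", no3 ", format(x$no3, digits = 4), " mg N/L; ip ",
      format(x$ip, digits = 4), " mg P/L)\n", sep = "")
  invisible(x)
}

#' Kinetic parameters of the eutrophication module
#'
#' The six calibrated rate constants (growth, death, temperature dependence of
#' growth, nitrogen and phosphorus half-saturations, detritus mineralization)
#' plus the closure constants the box model needs: fixed stoichiometry,
#' chlorophyll:carbon ratio, light half-saturation, settling velocities, the
#' ammonium-preference switch and an optional temperature dependence of
#' mineralization. The closures are package choices, documented here and
#' config-exposed; they are not part of the calibrated set.
#'
#' @param mypc Maximum phytoplankton C growth rate at 20 degC (1/day).
#' @param deac First-order phytoplankton death rate (1/day).
#' @param tetg Arrhenius theta for growth (dimensionless, in \[1, 1.3\]).
#' @param kn Half-saturation for nitrogen uptake (mg N/L).
#' @param kp Half-saturation for phosphorus uptake (mg P/L).
#' @param kmdm Detritus C mineralization rate (1/day).
#' @param chl_to_c Chlorophyll:carbon ratio (µg Chl-a per mg C). Closure.
#' @param n_to_c Nitrogen:carbon ratio (mg N per mg C, about Redfield). Closure.
#' @param p_to_c Phosphorus:carbon ratio (mg P per mg C, about Redfield). Closure.
#' @param i_k Light half-saturation (W/m²). Closure.
#' @param v_settle_iss ISS settling velocity (m/day). Closure.
#' @param v_settle_dc Detritus settling velocity (m/day). Closure.
#' @param nh4_pref Half-saturation of the smooth ammonium-first switch
#'   (mg N/L); nitrogen uptake is drawn from ammonium with weight
#'   `nh4 / (nh4 + nh4_pref)` and the remainder from nitrate, so small
#'   values approximate strict ammonium-first drawdown while conserving
#'   nitrogen. Closure.
#' @param tet_miner Arrhenius theta for mineralization; 1 disables the
#'   temperature dependence (default). Closure.
#' @return An object of class `eco_params`.
#' @export
eco_params <- function(mypc = 2.8, deac = 0.10, tetg = 1.14,
                       kn = 0.05, kp = 0.009, kmdm = 0.040,
                       chl_to_c = 25, n_to_c = 0.18, p_to_c = 0.024,
                       i_k = 80, v_settle_iss = 0.05, v_settle_dc = 0.1,
                       nh4_pref = 0.01, tet_miner = 1) {
  p <- list(mypc = mypc, deac = deac, tetg = tetg, kn = kn, kp = kp,
            kmdm = kmdm, chl_to_c = chl_to_c, n_to_c = n_to_c,
            p_to_c = p_to_c, i_k = i_k, v_settle_iss = v_settle_iss,
            v_settle_dc = v_settle_dc, nh4_pref = nh4_pref,
            tet_miner = tet_miner)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all kinetic parameters must be finite and non-negative")
  }
  if (tetg < 1 || tetg > 1.3) stop("tetg must lie in [1, 1.3]")
  if (kn <= 0 || kp <= 0) stop("half-saturation constants must be positive")
  if (chl_to_c <= 0) stop("chl_to_c must be positive")
  structure(p, class = "eco_params")
}

#' Lake geometry
#'
#' A single well-mixed box: storage volume, surface area and the mean depth
#' implied by their ratio.
#'
#' @param volume Storage volume (m³). Default 200000.
#' @param area Surface area (m²). Default 100000 (10 ha).
#' @param depth Mean depth (m); defaults to `volume / area` and must agree
#'   with it within 1%.
#' @return An object of class `lake_geometry`.
#' @export
lake_geometry <- function(volume = 200000, area = 100000,
                          depth = volume / area) {
  if (volume <= 0 || area <= 0 || depth <= 0) {
    stop("volume, area and depth must be positive")
  }
  if (abs(volume - area * depth) > 0.01 * volume) {
    stop("inconsistent geometry: volume must equal area * depth within 1%")
  }
  structure(list(volume = volume, area = area, depth = depth),
            class = "lake_geometry")
}

# Pack parameter and coefficient objects into the fixed-order numeric vectors
# the compiled simulation core expects. Order must match src/sim_core.cpp.
pack_params <- function(params) {
  c(params$mypc, params$deac, params$tetg, params$kn, params$kp, params$kmdm,
    params$chl_to_c, params$n_to_c, params$p_to_c, params$i_k,
    params$v_settle_iss, params$v_settle_dc, params$nh4_pref,
    params$tet_miner)
}

pack_optics <- function(coeffs) {
  c(coeffs$a_w, coeffs$a_phi, coeffs$a_iss, coeffs$a_dc,
    coeffs$b_w, coeffs$b_phi, coeffs$b_iss, coeffs$b_dc, coeffs$mu0)
}

state_vector <- function(state) {
  c(pc = state$pc, dc = state$dc, iss = state$iss,
    nh4 = state$nh4, no3 = state$no3, ip = state$ip)
}
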