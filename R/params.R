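## Parameter containers for the two models. Base quantities are stored;
## derived quantities (omega, K_D, P_cap, kon) are always recomputed from
## the stored fields so a parameter update can never leave a stale cache.

.micro_defaults <- function() {
  list(
    L_chain     = 1050e-9,  # nanochain length (m)
    W_chain     = 150e-9,   # nanochain width (m)
    domain_size = 15e-6,    # side of the square fluid domain (m)
    C_bulk      = 6.67e-8,  # initial antigen concentration (mol/m^3), 1 ng/mL at 15 kDa
    mu_fluid    = 1.8e-3,   # dynamic viscosity (Pa*s)
    rho_fluid   = 1000,     # density (kg/m^3)
    k_on        = 1,        # association rate constant (m^3/(mol*s))
    k_off       = 0.1,      # dissociation rate constant (1/s)
    freq        = 0,        # rotation frequency (Hz)
    Gamma_max   = 1e-8,     # maximum surface binding capacity (mol/m^2)
    t_end       = 360,      # simulated incubation time (s)
    spacing     = NULL,     # chain grid spacing (m); default domain_size/3
    D_analyte   = 1.1e-10,  # analyte diffusivity (m^2/s), Stokes-Einstein 15 kDa
    M_analyte   = 15000     # analyte molar mass (g/mol)
  )
}

.membrane_defaults <- function() {
  list(
    L_model        = 3e-3,    # membrane length before (and after) the test line (m)
    H_membrane     = 2.5e-3,  # strip height in the model plane (m)
    W_TL           = 1e-3,    # test line width (m)
    H_TL           = NULL,    # test line height (m); default H_membrane
    x_testline     = NULL,    # test line start (m); default L_model
    w_testline     = NULL,    # test line width (m); default W_TL
    porosity       = 0.75,
    k_perm         = 1e-13,   # permeability (m^2)
    pore_size      = 20e-6,   # pore size (m)
    rho_fluid      = 1000,    # fluid density (kg/m^3)
    eta_fluid      = 1e-3,    # fluid viscosity (Pa*s)
    gamma_surface  = 0.072,   # surface tension (N/m)
    C0_mol         = 7e-8,    # inflow nanochain concentration (mol/m^3)
    D0             = 2e-13,   # nanochain diffusivity (m^2/s)
    delta_smooth   = 100e-6,  # wetting-front smoothing width (m)
    power_contrast = 2,       # wet/dry permeability contrast exponent
    P_inlet        = 25000,   # inlet pressure (Pa)
    k_min          = 0.01,    # dry relative permeability floor
    C_Ab_init      = 1e-5,    # initial antibody concentration on the test line (mol/m^3)
    koff           = 1e-9,    # complex dissociation rate (1/s)
    N_Abs          = 100,     # binding-efficiency factor (dimensionless, sweep variable)
    k_recruit      = 7e4,     # cooperative recruitment constant (m^3/(mol*s), sweep variable)
    V_chain        = 2e-20,   # nanochain volume (m^3); stored, unused by the rate laws
    c3_max         = 70e-6,   # nominal complex capacity (mol/m^3); stored, unused
    d_z            = 3e-6     # out-of-plane thickness (m); cancels in the 2D model
  )
}

.check_pos <- function(p, fields, strict = TRUE) {
  for (f in fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter `", f, "` must be a single finite number", call. = FALSE)
    }
    if (strict && v <= 0) {
      stop("parameter `", f, "` must be > 0 (got ", v, ")", call. = FALSE)
    }
  }
  invisible(p)
}

.merge_params <- function(defaults, dots, what) {
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown)) {
    stop("unknown ", what, " parameter(s): ",
         paste0("`", unknown, "`", collapse = ", "), call. = FALSE)
  }
  ## store every numeric as double so config round trips are type-stable
  dots <- lapply(dots, function(v) if (is.integer(v)) as.numeric(v) else v)
  utils::modifyList(defaults, dots)
}

#' Microscale model parameters
#'
#' Houses every global parameter of the microscale (chain-stirred) model:
#' nine rotating nanochains in a 15 um square fluid domain, antigen at
#' 1 ng/mL of a 15 kDa analyte, and Langmuir-type surface uptake on chain
#' walls.  Unspecified parameters take the model defaults listed in the
#' argument section of [micro_derived()]'s help; `spacing` defaults to
#' `domain_size / 3`.  All values are SI.
#'
#' @param ... Named parameter overrides among `L_chain`, `W_chain`,
#'   `domain_size`, `C_bulk`, `mu_fluid`, `rho_fluid`, `k_on`, `k_off`,
#'   `freq`, `Gamma_max`, `t_end`, `spacing`, `D_analyte`, `M_analyte`.
#'   Unknown names are an error.
#' @return An object of class `micro_params` (a validated named list).
#' @examples
#' p <- micro_params(freq = 3)
#' micro_derived(p)$omega  # 2*pi*3
#' @seealso [membrane_params()], [micro_derived()], [update_params()]
#' @export
micro_params <- function(...) {
  p <- .merge_params(.micro_defaults(), list(...), "microscale")
  if (is.null(p$spacing)) p$spacing <- p$domain_size / 3
  .check_pos(p, c("L_chain", "W_chain", "domain_size", "C_bulk", "mu_fluid",
                  "rho_fluid", "k_on", "k_off", "Gamma_max", "t_end",
                  "spacing", "D_analyte", "M_analyte"))
  .check_pos(p, "freq", strict = FALSE)
  if (p$freq < 0) stop("`freq` must be >= 0", call. = FALSE)
  structure(p, class = "micro_params")
}

#' Derived microscale quantities
#'
#' Recomputed on every call from the stored base parameters (no caching):
#' angular velocity `omega = 2*pi*freq`, equilibrium dissociation constant
#' `K_D = k_off/k_on`, uptake velocity `k_on*Gamma_max`, chain tip radius,
#' tip speed, fluid area of the chain-perforated domain and the Reynolds
#' number `rho * u_tip * L_chain / mu` justifying the creeping-flow
#' approximation.
#'
#' @param p A [micro_params()] object.
#' @return A named list of derived quantities (SI units).
#' @export
micro_derived <- function(p) {
  stopifnot(inherits(p, "micro_params"))
  omega <- angular_velocity(p$freq)
  r_tip <- sqrt((p$L_chain / 2)^2 + (p$W_chain / 2)^2)
  u_tip <- omega * r_tip
  list(
    omega = omega,
    K_D = p$k_off / p$k_on,
    uptake_velocity = p$k_on * p$Gamma_max,
    r_tip = r_tip,
    u_tip = u_tip,
    fluid_area = p$domain_size^2 - 9 * p$L_chain * p$W_chain,
    chain_perimeter_total = 9 * 2 * (p$L_chain + p$W_chain),
    reynolds = p$rho_fluid * u_tip * p$L_chain / p$mu_fluid
  )
}

#' Membrane model parameters
#'
#' Houses every global parameter of the porous-membrane transport model:
#' a 7 mm nitrocellulose strip (3 mm + 1 mm test line + 3 mm) wetted by
#' capillary action, carrying nanochains to immobilised test-line
#' antibodies with optional cooperative recruitment.  Geometry defaults
#' tie the test line to the strip layout: `H_TL = H_membrane`,
#' `x_testline = L_model`, `w_testline = W_TL`.  All values are SI; the
#' association rate is derived from `N_Abs` via [si_association_rate()].
#'
#' `V_chain` and `c3_max` are accepted and stored for completeness, but no
#' rate law in the model consumes them; supplying them explicitly raises a
#' warning saying so rather than silently inventing physics for them.
#'
#' @param ... Named parameter overrides (see [micro_params()] for the
#'   convention); unknown names are an error.
#' @return An object of class `membrane_params`.
#' @examples
#' mp <- membrane_params()
#' membrane_derived(mp)$P_cap  # 7200 Pa
#' @export
membrane_params <- function(...) {
  dots <- list(...)
  defaults <- .membrane_defaults()
  housed <- intersect(c("V_chain", "c3_max"), names(dots))
  changed <- housed[!vapply(housed, function(k) {
    is.numeric(dots[[k]]) && length(dots[[k]]) == 1L &&
      as.numeric(dots[[k]]) == defaults[[k]]
  }, logical(1))]
  if (length(changed)) {
    warning(paste0("`", changed, "`", collapse = "/"),
            " is stored but not consumed by any rate law of the model",
            call. = FALSE)
  }
  p <- .merge_params(defaults, dots, "membrane")
  if (is.null(p$H_TL)) p$H_TL <- p$H_membrane
  if (is.null(p$x_testline)) p$x_testline <- p$L_model
  if (is.null(p$w_testline)) p$w_testline <- p$W_TL
  .check_pos(p, c("L_model", "H_membrane", "W_TL", "H_TL", "x_testline",
                  "w_testline", "k_perm", "pore_size", "rho_fluid",
                  "eta_fluid", "gamma_surface", "C0_mol", "D0",
                  "delta_smooth", "power_contrast", "P_inlet", "C_Ab_init",
                  "V_chain", "c3_max", "d_z"))
  .check_pos(p, c("porosity", "k_min", "koff", "N_Abs", "k_recruit"),
             strict = FALSE)
  if (p$porosity <= 0 || p$porosity >= 1) {
    stop("`porosity` must lie in (0, 1)", call. = FALSE)
  }
  if (p$k_min <= 0 || p$k_min > 1) {
    stop("`k_min` must lie in (0, 1]", call. = FALSE)
  }
  if (p$N_Abs < 0 || p$k_recruit < 0 || p$koff < 0) {
    stop("rate parameters must be >= 0", call. = FALSE)
  }
  structure(p, class = "membrane_params")
}

#' Derived membrane quantities
#'
#' Recomputed on each call: capillary pressure `P_cap = 2*gamma/pore`,
#' SI association rate `kon = N_Abs * 10`, total strip length
#' `2*L_model + W_TL`, and the fully wetted superficial Darcy velocity
#' `k_perm * P_inlet / (eta * strip_length)`.
#'
#' @param p A [membrane_params()] object.
#' @return A named list of derived quantities (SI units).
#' @export
membrane_derived <- function(p) {
  stopifnot(inherits(p, "membrane_params"))
  strip <- 2 * p$L_model + p$W_TL
  list(
    P_cap = capillary_pressure(p$gamma_surface, p$pore_size),
    kon = si_association_rate(p$N_Abs),
    strip_length = strip,
    u_wet = p$k_perm * p$P_inlet / (p$eta_fluid * strip)
  )
}

#' Update a parameter set
#'
#' Returns a new parameter object with the given fields replaced, passing
#' through full construction and validation, so every derived quantity
#' reflects the new values.
#'
#' @param p A `micro_params` or `membrane_params` object.
#' @param ... Named replacements.
#' @return An object of the same class as `p`.
#' @export
update_params <- function(p, ...) {
  dots <- list(...)
  if (inherits(p, "micro_params")) {
    do.call(micro_params, utils::modifyList(unclass(p), dots))
  } else if (inherits(p, "membrane_params")) {
    args <- utils::modifyList(unclass(p), dots)
    ## re-deriving tied geometry defaults unless explicitly pinned
    if (!"H_TL" %in% names(dots) && "H_membrane" %in% names(dots)) {
      args$H_TL <- NULL
    }
    if (!"x_testline" %in% names(dots) && "L_model" %in% names(dots)) {
      args$x_testline <- NULL
    }
    if (!"w_testline" %in% names(dots) && "W_TL" %in% names(dots)) {
      args$w_testline <- NULL
    }
    suppressWarnings(do.call(membrane_params, args))
  } else {
    stop("`p` must be a micro_params or membrane_params object",
         call. = FALSE)
  }
}

#' @export
print.micro_params <- function(x, ...) {
  d <- micro_derived(x)
  cat("Microscale model parameters (SI)\n")
  cat(sprintf("  domain %.3g m square, 9 chains %.3g x %.3g m, spacing %.3g m\n",
              x$domain_size, x$L_chain, x$W_chain, x$spacing))
  cat(sprintf("  C_bulk %.3g mol/m^3, D %.3g m^2/s, k_on %.3g, k_off %.3g (K_D %.3g)\n",
              x$C_bulk, x$D_analyte, x$k_on, x$k_off, d$K_D))
  cat(sprintf("  freq %.3g Hz (omega %.4g rad/s), Gamma_max %.3g mol/m^2, t_end %g s\n",
              x$freq, d$omega, x$Gamma_max, x$t_end))
  invisible(x)
}

#' @export
print.membrane_params <- function(x, ...) {
  d <- membrane_derived(x)
  cat("Membrane model parameters (SI)\n")
  cat(sprintf("  strip %.3g m x %.3g m, test line [%.3g, %.3g] m\n",
              d$strip_length, x$H_membrane, x$x_testline,
              x$x_testline + x$w_testline))
  cat(sprintf("  porosity %.3g, k_perm %.3g m^2, P_cap %.4g Pa, P_inlet %g Pa\n",
              x$porosity, x$k_perm, d$P_cap, x$P_inlet))
  cat(sprintf("  N_Abs %g (kon %.4g m^3/mol/s), koff %.3g, k_recruit %.3g\n",
              x$N_Abs, d$kon, x$koff, x$k_recruit))
  invisible(x)
}
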