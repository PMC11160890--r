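#' Parameter constructors for the half-sarcomere model
#'
#' These light-weight constructors collect and validate the constants of the
#' model: filament lattice geometry, filament spring stiffnesses, the
#' two-spring myosin head, the crossbridge state-transition rate constants,
#' and the exponential titin spring. All constructors return plain named
#' lists with a class attribute, so a configuration is fully serializable
#' (see [load_config()]).
#'
#' @name model-parameters
NULL

abort_config <- function(field, msg) {
  rlang::abort(sprintf("invalid configuration: `%s` %s", field, msg),
               class = "myolattice_config_error")
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    abort_config(field, "must be a single positive finite number")
  invisible(x)
}

#' @describeIn model-parameters Myofilament lattice geometry: filament counts,
#'   axial repeats (nm) and the rest length of the half sarcomere (nm).
#'   `crowns_per_thick` sets the number of myosin crowns (3 heads each) per
#'   thick filament; the default of 20 gives 240 heads in the repeating unit.
#' @param n_thick,n_thin number of thick and thin filaments in the periodic
#'   unit; the thin count must be twice the thick count.
#' @param crowns_per_thick myosin crowns per thick filament.
#' @param crown_spacing axial distance between adjacent crowns, nm.
#' @param site_spacing axial distance between actin binding sites, nm.
#' @param rest_half_sarcomere_length rest distance from M-line to Z-disk, nm.
#' @param r_thick_plus_r_thin combined thick + thin filament radii, nm,
#'   subtracted from the centre-to-centre distance to give face spacing.
#' @param lattice_class `"vertebrate"` or `"invertebrate_flight"`; selects the
#'   d10-to-centre-spacing geometry factor (2/3 or 1/sqrt(3)).
#' @export
geometry_config <- function(n_thick = 4L,
                            n_thin = 8L,
                            crowns_per_thick = 20L,
                            crown_spacing = 14.3,
                            site_spacing = 38.7,
                            rest_half_sarcomere_length = 1250,
                            r_thick_plus_r_thin = 12.5,
                            lattice_class = c("invertebrate_flight", "vertebrate")) {
  lattice_class <- match.arg(lattice_class)
  if (!is.numeric(n_thick) || n_thick < 1) abort_config("n_thick", "must be >= 1")
  if (n_thin != 2L * n_thick)
    abort_config("n_thin", "must equal 2 * n_thick")
  check_positive(crowns_per_thick, "crowns_per_thick")
  check_positive(crown_spacing, "crown_spacing")
  check_positive(site_spacing, "site_spacing")
  check_positive(rest_half_sarcomere_length, "rest_half_sarcomere_length")
  check_positive(r_thick_plus_r_thin, "r_thick_plus_r_thin")
  if (rest_half_sarcomere_length < crowns_per_thick * crown_spacing)
    abort_config("rest_half_sarcomere_length",
                 "must exceed the thick filament span crowns_per_thick * crown_spacing")
  structure(list(
    n_thick = as.integer(n_thick), n_thin = as.integer(n_thin),
    crowns_per_thick = as.integer(crowns_per_thick),
    crown_spacing = crown_spacing, site_spacing = site_spacing,
    rest_half_sarcomere_length = rest_half_sarcomere_length,
    r_thick_plus_r_thin = r_thick_plus_r_thin,
    lattice_class = lattice_class
  ), class = "geometry_config")
}

#' @describeIn model-parameters Thick/thin filament segment stiffnesses,
#'   pN/nm per segment (one crown repeat for thick, one site repeat for thin).
#' @param k_thick,k_thin per-segment spring constants, pN/nm.
#' @export
filament_params <- function(k_thick = 2020, k_thin = 1760) {
  check_positive(k_thick, "k_thick")
  check_positive(k_thin, "k_thin")
  structure(list(k_thick = k_thick, k_thin = k_thin), class = "filament_params")
}

#' @describeIn model-parameters Two-spring myosin head: a torsional spring at
#'   the base and a linear spring in the arm, each with pre- and post-power
#'   stroke equilibria (Table-style constants; angles given in degrees).
#'   Also carries the thermal energy scale `kT` (pN nm) and the state
#'   free-energy baseline offsets `alpha1` (weak) and `alpha2` (strong), in kT
#'   units; the offsets are calibration constants of this implementation
#'   (`alpha2` defaults to minus the post-stroke elastic energy at the
#'   binding locus at 15 nm face spacing, making the power stroke
#'   thermodynamically neutral where heads attach).
#' @param k_theta torsional stiffness, pN nm / rad.
#' @param k_r arm linear stiffness, pN / nm.
#' @param r_theta_pre,r_theta_post equilibrium base angles, degrees.
#' @param r_r_pre,r_r_post equilibrium arm lengths, nm.
#' @param kT thermal energy, pN nm.
#' @param alpha1,alpha2 free-energy baselines of the weakly and strongly
#'   bound states, kT units.
#' @export
spring_params <- function(k_theta = 4000, k_r = 16,
                          r_theta_pre = 47.16, r_theta_post = 73.20,
                          r_r_pre = 19.96, r_r_post = 16.47,
                          kT = 4.11, alpha1 = -2, alpha2 = -122.7) {
  check_positive(k_theta, "k_theta")
  check_positive(k_r, "k_r")
  check_positive(r_r_pre, "r_r_pre")
  check_positive(r_r_post, "r_r_post")
  check_positive(kT, "kT")
  if (r_theta_pre == r_theta_post && r_r_pre == r_r_post)
    abort_config("r_theta_post", "post-stroke equilibria must differ from pre-stroke")
  structure(list(
    k_theta = k_theta, k_r = k_r,
    r_theta_pre = r_theta_pre, r_theta_post = r_theta_post,
    r_r_pre = r_r_pre, r_r_post = r_r_post,
    theta_pre = r_theta_pre * pi / 180, theta_post = r_theta_post * pi / 180,
    kT = kT, alpha1 = alpha1, alpha2 = alpha2
  ), class = "spring_params")
}

#' @describeIn model-parameters Rate-function constants (per ms unless noted):
#'   `tau` and `baseline` parameterize the binding rate
#'   `r12 = tau * exp(-d^2) + baseline`; `A`, `C`, `D` the power-stroke rate;
#'   `G`, `H` the strong-state detachment rate `r31 = G*U2 + H`.
#' @param tau attachment rate scale, 1/ms.
#' @param baseline distance-independent attachment floor, 1/ms.
#' @param A power-stroke rate scale, 1/ms.
#' @param C,D power-stroke tanh shape constants (dimensionless).
#' @param G detachment rate per kT of strong-state free energy, 1/ms.
#' @param H detachment rate offset, 1/ms.
#' @param d_scale length scale dividing d in the binding-rate exponent, nm.
#' @export
rate_params <- function(tau = 72, baseline = 0.005, A = 0.8, C = 6, D = 0.2,
                        G = 0.6, H = 0.02, d_scale = 1) {
  for (f in c("tau", "baseline", "A", "C", "D", "G", "H")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      abort_config(f, "must be a single non-negative finite number")
  }
  check_positive(d_scale, "d_scale")
  structure(list(tau = tau, baseline = baseline, A = A, C = C, D = D,
                 G = G, H = H, d_scale = d_scale), class = "rate_params")
}

#' @describeIn model-parameters Titin exponential spring `F = a * exp(b * dL)`
#'   with `dL` the change in half-sarcomere length in micrometres.
#' @param a titin force at the rest length, pN.
#' @param b exponential stiffness, 1/um.
#' @export
titin_params <- function(a = 260, b = 4) {
  check_positive(a, "a")
  check_positive(b, "b")
  structure(list(a = a, b = b), class = "titin_params")
}

#' @describeIn model-parameters Equilibration solver settings: the node-force
#'   residual tolerance (pN), the iteration cap, and a step damping factor for
#'   the Newton update.
#' @param tolerance maximum residual force per node, pN.
#' @param max_iterations iteration cap before the solver errors.
#' @param relaxation multiplier on each Newton step (1 = full step).
#' @param kinetic_substeps number of kinetic (diffusion + transition)
#'   subcycles per mechanical step; the imposed boundary motion is applied in
#'   substep increments so transition hazards track the sliding geometry.
#' @export
solver_config <- function(tolerance = 1e-3, max_iterations = 100L,
                          relaxation = 1, kinetic_substeps = 8L) {
  check_positive(tolerance, "tolerance")
  check_positive(max_iterations, "max_iterations")
  check_positive(relaxation, "relaxation")
  check_positive(kinetic_substeps, "kinetic_substeps")
  structure(list(tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 relaxation = relaxation,
                 kinetic_substeps = as.integer(kinetic_substeps)),
            class = "solver_config")
}
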