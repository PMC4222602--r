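#' Lorentzian (Cauchy) intrinsic frequencies
#'
#' Samples intrinsic oscillator frequencies from a Lorentzian with location
#' `omega0` and half-width `gamma` by inverse-CDF:
#' `omega = omega0 + gamma * tan(pi * (u - 1/2))`. The heavy-tailed spread
#' is what makes the Ott-Antonsen reduction exact for the mean-field model.
#'
#' @param n sample count.
#' @param omega0 location (rad/day).
#' @param gamma half-width at half-maximum (rad/day), > 0.
#' @param seed RNG seed.
#' @return numeric vector of frequencies.
#' @export
sample_lorentzian <- function(n, omega0, gamma, seed = 1L) {
  if (gamma <= 0)
    stop_hw("gamma must be > 0", class = "hairwave_parameter_error")
  with_seed(seed, omega0 + gamma * tan(pi * (stats::runif(n) - 0.5)))
}

# Parameter bundle shared by the simulators.
coupled_params <- function(K_plus, K_minus, gamma, p, omega0 = 0) {
  list(K_plus = K_plus, K_minus = K_minus, gamma = gamma, p = p,
       omega0 = omega0)
}

#' Integrate the Ott-Antonsen reduced two-group model
#'
#' The mean-field model of positively and negatively coupled oscillator
#' groups reduces, for Lorentzian-spread intrinsic frequencies, to two
#' complex ODEs for the group order parameters (in the frame rotating at the
#' mean frequency `omega0`):
#' `dz_s/dt = -gamma * z_s + (K_s / 2) * (W - Conj(W) * z_s^2)`,
#' with mean field `W = p * z_plus + (1 - p) * z_minus`. Integration uses
#' adaptive Runge-Kutta 4/5 (`deSolve::ode`, method `"ode45"`).
#'
#' @param params list with `K_plus`, `K_minus` (rad/day; `K_minus < 0`),
#'   `gamma` (> 0), `p` (positive fraction), optional `omega0`.
#' @param z_plus0,z_minus0 complex initial order parameters, `|z| <= 1`.
#' @param t time vector (days) at which to report the state.
#' @param rtol,atol integrator tolerances.
#' @return data frame of class `reduced_trajectory`: `time`, complex
#'   `z_plus`, `z_minus`, `W`.
#' @export
simulate_reduced <- function(params, z_plus0 = 0.01 + 0i,
                             z_minus0 = -0.01 + 0i,
                             t = seq(0, 200, by = 0.5),
                             rtol = 1e-8, atol = 1e-10) {
  if (max(Mod(z_plus0), Mod(z_minus0)) > 1 + 1e-9)
    stop_hw("initial order parameters must lie in the unit disk",
            class = "hairwave_parameter_error")
  rhs <- function(tt, y, pr) {
    zp <- complex(real = y[1], imaginary = y[2])
    zm <- complex(real = y[3], imaginary = y[4])
    W <- pr$p * zp + (1 - pr$p) * zm
    dzp <- -pr$gamma * zp + (pr$K_plus / 2) * (W - Conj(W) * zp^2)
    dzm <- -pr$gamma * zm + (pr$K_minus / 2) * (W - Conj(W) * zm^2)
    list(c(Re(dzp), Im(dzp), Re(dzm), Im(dzm)))
  }
  y0 <- c(Re(z_plus0), Im(z_plus0), Re(z_minus0), Im(z_minus0))
  out <- deSolve::ode(y0, t, rhs, params, method = "ode45",
                      rtol = rtol, atol = atol)
  if (anyNA(out))
    stop_hw("reduced-model integration produced non-finite state",
            class = "hairwave_integration_error")
  zp <- complex(real = out[, 2], imaginary = out[, 3])
  zm <- complex(real = out[, 4], imaginary = out[, 5])
  if (max(Mod(zp), Mod(zm)) > 1 + 1e-6)
    stop_hw("order parameter escaped the unit disk (|z| = ",
            signif(max(Mod(zp), Mod(zm)), 6), ")",
            class = "hairwave_integration_error")
  df <- data.frame(time = out[, 1])
  df$z_plus <- zp
  df$z_minus <- zm
  df$W <- params$p * zp + (1 - params$p) * zm
  class(df) <- c("reduced_trajectory", "data.frame")
  df
}

#' Simulate the full N-oscillator mean-field system
#'
#' Direct integration of
#' `dtheta_j/dt = omega_j + K_{group(j)} * R * sin(Theta - theta_j)` with
#' `R exp(i Theta)` the ensemble order parameter and intrinsic frequencies
#' drawn from the Lorentzian. Used to validate the low-dimensional reduction
#' (the two agree up to finite-size fluctuations).
#'
#' @param params as in [simulate_reduced()]; `p` sets the positively coupled
#'   fraction.
#' @param n_osc total oscillator count.
#' @param t report times (days).
#' @param init_phases optional initial phases (length `n_osc`); default
#'   uniform random.
#' @param omegas optional intrinsic frequencies; default Lorentzian draws.
#' @param seed RNG seed for phases/frequencies.
#' @param rtol,atol integrator tolerances (looser than the reduced model by
#'   default: the attractor structure, not 8-digit trajectories, is the
#'   target at N = 1000).
#' @return list of class `full_trajectory`: `time`, complex `z_plus`,
#'   `z_minus`, `Z1`, `Z2`, group sizes, and the final phases.
#' @export
simulate_full <- function(params, n_osc = 1000L, t = seq(0, 150, by = 0.5),
                          init_phases = NULL, omegas = NULL, seed = 1L,
                          rtol = 1e-6, atol = 1e-8) {
  if (n_osc < 2)
    stop_hw("need at least 2 oscillators", class = "hairwave_parameter_error")
  n_plus <- round(params$p * n_osc)
  K <- c(rep(params$K_plus, n_plus), rep(params$K_minus, n_osc - n_plus))
  if (is.null(omegas))
    omegas <- sample_lorentzian(n_osc, params$omega0 %||% 0, params$gamma,
                                seed = derive_seed(seed, 1L))
  if (is.null(init_phases))
    init_phases <- with_seed(derive_seed(seed, 2L),
                             stats::runif(n_osc, 0, 2 * pi))
  stopifnot(length(init_phases) == n_osc, length(omegas) == n_osc)
  rhs <- function(tt, th, pr) {
    Z <- mean(exp(1i * th))
    list(omegas + K * Mod(Z) * sin(Arg(Z) - th))
  }
  out <- deSolve::ode(init_phases, t, rhs, NULL, method = "ode45",
                      rtol = rtol, atol = atol)
  if (anyNA(out))
    stop_hw("full-model integration produced non-finite state",
            class = "hairwave_integration_error")
  th <- out[, -1, drop = FALSE]
  e1 <- exp(1i * th)
  idx_p <- seq_len(n_plus)
  structure(list(time = out[, 1],
                 z_plus = rowMeans(e1[, idx_p, drop = FALSE]),
                 z_minus = rowMeans(e1[, -idx_p, drop = FALSE]),
                 Z1 = rowMeans(e1), Z2 = rowMeans(e1^2),
                 n_plus = n_plus, n_minus = n_osc - n_plus,
                 final_phases = unname(th[nrow(th), ])),
            class = "full_trajectory")
}

#' Solve the quasi-steady-state for the coupling parameters
#'
#' At the observed quasi-steady out-of-phase state the two group order
#' parameters can be placed on the real axis without loss of generality,
#' `z_plus = r_plus`, `z_minus = -r_minus`, and the reduced ODEs' left-hand
#' sides set to zero. With the mean field `W = p * r_plus - (1-p) * r_minus`
#' the two real fixed-point equations
#' `gamma * r_plus  = (K_plus / 2) * W * (1 - r_plus^2)` and
#' `gamma * r_minus = (|K_minus| / 2) * W * (1 - r_minus^2)`
#' are solved exactly: the first gives `gamma` (with the scale convention
#' `K_plus = 1` rad/day — the fixed point is invariant to a joint rescaling
#' of the couplings and `gamma`, so only relative strengths are
#' identifiable), the second gives `K_minus`. A configuration is physically
#' realizable iff the implied `gamma` is positive; assigning the smaller
#' cluster to positive coupling makes `W < 0` and hence `gamma < 0`, which
#' is how that configuration is rejected.
#'
#' @param r_plus,r_minus observed steady radii of the positively and
#'   negatively coupled cluster order parameters, in (0, 1).
#' @param p positive-coupled fraction, in (0, 1).
#' @param K_plus scale convention for the positive coupling (rad/day).
#' @return list: `K_plus`, `K_minus` (< 0 when realizable), `gamma`, `p`,
#'   `W`, `realizable`, `residual` (0: the solve is exact).
#' @export
solve_steady_parameters <- function(r_plus, r_minus, p, K_plus = 1) {
  stopifnot(r_plus > 0, r_plus < 1, r_minus > 0, r_minus < 1,
            p > 0, p < 1)
  W <- p * r_plus - (1 - p) * r_minus
  if (abs(W) < 1e-12)
    stop_hw("mean field W = 0: coupling parameters unidentifiable",
            class = "hairwave_unidentifiable_error")
  gamma <- K_plus * W * (1 - r_plus^2) / (2 * r_plus)
  K_minus <- -2 * gamma * r_minus / (W * (1 - r_minus^2))
  res <- c(gamma * r_plus - (K_plus / 2) * W * (1 - r_plus^2),
           gamma * r_minus - (abs(K_minus) / 2) * W * (1 - r_minus^2))
  list(K_plus = K_plus, K_minus = K_minus, gamma = gamma, p = p, W = W,
       realizable = gamma > 0 && K_minus < 0,
       residual = sqrt(sum(res^2)))
}

#' Fit the two-group coupled oscillator model to observed clusters
#'
#' Tries both assignments of the two observed phase clusters to the positive
#' and negative coupling groups, solves the quasi-steady-state parameters
#' for each ([solve_steady_parameters()]), and checks each configuration
#' numerically: a realizable configuration is integrated from a slightly
#' perturbed fixed point and declared stable if it returns to it. The
#' verdict names the stable configuration (for the hair system: negative
#' coupling of cluster 1, the smaller cluster).
#'
#' @param r_cluster1,r_cluster2 observed steady radii of the cluster order
#'   parameters.
#' @param n_cluster1,n_cluster2 cluster sizes.
#' @param omega0 mean frequency (rad/day), e.g. `2 * pi / period`; the
#'   reduced model runs in the frame rotating at `omega0`.
#' @param perturbation,return_tol stability-check controls: radius
#'   perturbation applied to the fixed point and the distance within which
#'   the trajectory must return.
#' @param t_check integration horizon for the stability check (days).
#' @return Object of class `coupled_fit`: per-configuration parameter
#'   solutions and stability results, and `verdict` (`"config1"`:
#'   cluster 1 negatively coupled, `"config2"`, or `"none"`).
#' @export
fit_coupled_model <- function(r_cluster1, r_cluster2, n_cluster1,
                              n_cluster2, omega0,
                              perturbation = 1e-3, return_tol = 1e-4,
                              t_check = 400) {
  configs <- list(
    config1 = list(pos = "cluster2", r_plus = r_cluster2,
                   r_minus = r_cluster1,
                   p = n_cluster2 / (n_cluster1 + n_cluster2)),
    config2 = list(pos = "cluster1", r_plus = r_cluster1,
                   r_minus = r_cluster2,
                   p = n_cluster1 / (n_cluster1 + n_cluster2)))
  out <- lapply(configs, function(cf) {
    sol <- solve_steady_parameters(cf$r_plus, cf$r_minus, cf$p)
    stable <- FALSE
    if (sol$realizable) {
      pr <- coupled_params(sol$K_plus, sol$K_minus, sol$gamma, sol$p, omega0)
      # relaxation time scales like 1/gamma near threshold: give the
      # trajectory long enough to settle when the fitted spread is small
      t_check <- max(t_check, 12 / sol$gamma)
      tr <- simulate_reduced(pr,
                             z_plus0 = cf$r_plus + perturbation,
                             z_minus0 = complex(real = -(cf$r_minus -
                                                           perturbation),
                                                imaginary = perturbation),
                             t = seq(0, t_check, by = 1))
      nlast <- nrow(tr)
      dist <- sqrt(Mod(tr$z_plus[nlast] - cf$r_plus)^2 +
                     Mod(tr$z_minus[nlast] - (-cf$r_minus))^2)
      # compare up to a global rotation: the pi-state is a circle of fixed
      # points, so measure radii and the inter-cluster angle instead
      sep <- circ_wrap(Arg(tr$z_plus[nlast]) - Arg(tr$z_minus[nlast]))
      dist_rot <- sqrt((Mod(tr$z_plus[nlast]) - cf$r_plus)^2 +
                         (Mod(tr$z_minus[nlast]) - cf$r_minus)^2 +
                         (abs(sep) - pi)^2)
      stable <- dist_rot < max(return_tol, 10 * perturbation)
      sol$stability_distance <- dist_rot
    }
    c(cf[c("pos", "p")], sol, list(stable = stable))
  })
  verdict <- if (out$config1$realizable && out$config1$stable) "config1"
             else if (out$config2$realizable && out$config2$stable) "config2"
             else "none"
  structure(list(configurations = out, verdict = verdict, omega0 = omega0,
                 r_cluster1 = r_cluster1, r_cluster2 = r_cluster2,
                 n_cluster1 = n_cluster1, n_cluster2 = n_cluster2),
            class = "coupled_fit")
}

#' @export
print.coupled_fit <- function(x, ...) {
  cat("<coupled_fit> two-group mean-field oscillator model\n")
  for (nm in names(x$configurations)) {
    cf <- x$configurations[[nm]]
    cat(sprintf("  %s (%s positively coupled, p = %.3f): K+ = %.3g, K- = %.3g, gamma = %.4g  [%s%s]\n",
                nm, cf$pos, cf$p, cf$K_plus, cf$K_minus, cf$gamma,
                if (cf$realizable) "realizable" else "unrealizable (gamma < 0)",
                if (isTRUE(cf$stable)) ", stable" else ""))
  }
  cat(sprintf("  verdict: %s\n", switch(x$verdict,
    config1 = "config1 stable (cluster 1, the smaller group, negatively coupled)",
    config2 = "config2 stable (cluster 1 positively coupled)",
    none = "no stable configuration")))
  invisible(x)
}

#' @export
coef.coupled_fit <- function(object, ...) {
  v <- object$verdict
  if (v == "none") return(NULL)
  cf <- object$configurations[[v]]
  c(K_plus = cf$K_plus, K_minus = cf$K_minus, gamma = cf$gamma, p = cf$p,
    omega0 = object$omega0)
}

#' Bifurcation scan of the reduced model over the positive fraction
#'
#' Holds the fitted couplings and frequency spread fixed, varies the
#' positively coupled fraction `p`, integrates the reduced model to long
#' time from a standard small random start, and classifies the attractor:
#' \describe{
#'   \item{incoherent}{both group radii decay to (near) zero;}
#'   \item{pi_state}{both groups synchronized, locked 180 degrees apart,
#'     mean field stationary in the rotating frame (system period
#'     `2 pi / omega0`);}
#'   \item{traveling_wave}{synchronized but drifting mean field: the phase
#'     pattern rotates at `Omega != 0` in the rotating frame and the system
#'     period `2 pi / (omega0 + Omega)` shortens.}
#' }
#' Trajectories with non-stationary radii at the end of the window are
#' labeled `"unresolved"`, never silently binned.
#'
#' @param fit_params list with `K_plus`, `K_minus`, `gamma` (e.g.
#'   `coef()` of a [fit_coupled_model()]).
#' @param omega0 mean frequency (rad/day) used to convert drift to periods.
#' @param p_grid fractions to scan.
#' @param t_long integration horizon (days); classification uses the last
#'   quarter of the window.
#' @param tol_in,tol_sync,tol_phase,tol_rot classification tolerances:
#'   incoherence radius, synchronization radius, phase-locking tolerance
#'   (rad) and drift tolerance (rad/day).
#' @param z0 small standard start (perturbed deterministically per p).
#' @return data frame of class `bifurcation_result`: `p`, `R1` (steady
#'   `|Z1|`), `r_plus`, `r_minus`, `separation_deg`, `Omega`, `state`,
#'   `period_days`; attribute `boundaries` lists estimated critical p
#'   values.
#' @export
bifurcation_diagram <- function(fit_params, omega0,
                                p_grid = seq(0.05, 0.95, by = 0.05),
                                t_long = 400,
                                tol_in = 0.01, tol_sync = 0.1,
                                tol_phase = 0.1, tol_rot = 1e-3,
                                z0 = 0.01) {
  rows <- lapply(p_grid, function(p) {
    pr <- coupled_params(fit_params$K_plus, fit_params$K_minus,
                         fit_params$gamma, p)
    dt <- 0.5
    tr <- simulate_reduced(pr, z_plus0 = z0 * exp(0.3i),
                           z_minus0 = z0 * exp(2.5i),
                           t = seq(0, t_long, by = dt))
    win <- tr$time >= 0.75 * t_long
    zp <- tr$z_plus[win]; zm <- tr$z_minus[win]
    rp <- Mod(zp); rm <- Mod(zm)
    nlast <- length(zp)
    drift <- function(z) {
      a <- diff(Arg(z)); mean(circ_wrap(a)) / dt
    }
    Omega <- drift(zp)
    sep <- abs(circ_wrap(Arg(zp[nlast]) - Arg(zm[nlast])))
    # stationarity of the radii over the window
    stat_ok <- max(diff(range(rp)), diff(range(rm))) < 0.02
    state <- if (max(mean(rp), mean(rm)) < max(tol_in, tol_sync * 0.1) &&
                 stat_ok) "incoherent"
      else if (!stat_ok) "unresolved"
      else if (min(mean(rp), mean(rm)) > tol_sync &&
               abs(sep - pi) < tol_phase && abs(Omega) < tol_rot) "pi_state"
      else if (abs(Omega) > tol_rot) "traveling_wave"
      else "unresolved"
    data.frame(p = p, R1 = mean(Mod(p * zp + (1 - p) * zm)),
               r_plus = mean(rp), r_minus = mean(rm),
               separation_deg = sep * 180 / pi, Omega = Omega,
               state = state,
               period_days = if (state == "incoherent") NA_real_
                             else 2 * pi / abs(omega0 + Omega))
  })
  res <- do.call(rbind, rows)
  # boundary estimates: midpoints of p where the label changes
  chg <- which(res$state[-1] != res$state[-nrow(res)])
  boundaries <- (res$p[chg] + res$p[chg + 1]) / 2
  structure(res, boundaries = boundaries, omega0 = omega0,
            class = c("bifurcation_result", "data.frame"))
}

#' @export
print.bifurcation_result <- function(x, ...) {
  cat("<bifurcation_result> attractor by positive fraction p:\n")
  print.data.frame(cbind(x[, c("p", "R1", "state")],
                         period = signif(x$period_days, 4)), row.names = FALSE)
  b <- attr(x, "boundaries")
  if (length(b)) cat("  state boundaries near p =",
                     paste(signif(b, 3), collapse = ", "), "\n")
  invisible(x)
}
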