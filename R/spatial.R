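#' Bouton geometry
#'
#' The simulated volume is a 0.5 x 0.5 x 4 um box of axon (an en passant
#' bouton); the long axis is x. The active zone sits on the y = 0 membrane
#' face at the box midpoint, with seven docked vesicles in a hexagonal
#' array (central vesicle plus six at 17.5 nm, largest centre-to-centre
#' distance 35 nm). The VDCC cluster centre lies at co-localization distance
#' `lc_nm` from the active-zone centre along x. Free calcium is clamped in
#' 20 nm slabs at both x-ends. A measurement probe sits 10 nm perpendicular
#' from the active zone.
#'
#' @param lc_nm centre-to-centre distance from active zone to channel
#'   cluster (10-400 nm)
#' @param box_um box dimensions c(long axis, width, height) in um
#' @param clamp_nm thickness of the clamped boundary slabs (nm)
#' @param probe_offset_nm perpendicular distance of the measurement probe
#'   from the active zone (nm)
#' @param probe_radius_nm radius of the spherical sampling volume used to
#'   convert local ion counts to a concentration (nm)
#' @return an object of class `bouton_geometry`
#' @export
bouton_geometry <- function(lc_nm = 250, box_um = c(4, 0.5, 0.5),
                            clamp_nm = 20, probe_offset_nm = 10,
                            probe_radius_nm = 50) {
  if (lc_nm < 10 || lc_nm > 400) {
    stop("lc_nm must lie within [10, 400] nm", call. = FALSE)
  }
  Lx <- box_um[1] * 1000; Ly <- box_um[2] * 1000; Lz <- box_um[3] * 1000
  az <- c(Lx / 2, 0, Lz / 2)
  ring <- 17.5
  ang <- seq(0, by = pi / 3, length.out = 6)
  ves <- rbind(c(az[1], 0.5, az[3]),
               cbind(az[1] + ring * cos(ang), 0.5, az[3] + ring * sin(ang)))
  colnames(ves) <- c("x", "y", "z")
  probe <- c(az[1], probe_offset_nm, az[3])
  structure(list(Lx = Lx, Ly = Ly, Lz = Lz, lc_nm = lc_nm,
                 az_center = az, vesicles = ves, probe = probe,
                 probe_radius_nm = probe_radius_nm,
                 cluster_center = c(az[1] + lc_nm, 0, az[3]),
                 clamp_nm = clamp_nm),
            class = "bouton_geometry")
}

#' @export
print.bouton_geometry <- function(x, ...) {
  cat(sprintf("<bouton_geometry> %g x %g x %g nm, l_c = %g nm, %d vesicles\n",
              x$Lx, x$Ly, x$Lz, x$lc_nm, nrow(x$vesicles)))
  invisible(x)
}

#' Mobile buffer (calbindin-D28k) parameters
#'
#' Calbindin is modelled with two independent high-affinity and two
#' medium-affinity binding sites per molecule. Rates are in the printed
#' laboratory units (association /M/s, dissociation /s).
#'
#' @param concentration_uM intracellular calbindin concentration
#' @param D_um2s diffusion constant (um^2/s)
#' @param kh_plus,kh_minus high-affinity site association / dissociation
#' @param km_plus,km_minus medium-affinity site association / dissociation
#' @param sites_high,sites_medium per-molecule stoichiometry
#' @return an object of class `buffer_params`
#' @export
buffer_params <- function(concentration_uM = 45, D_um2s = 28,
                          kh_plus = 0.55e7, kh_minus = 2.6,
                          km_plus = 4.35e7, km_minus = 35.8,
                          sites_high = 2, sites_medium = 2) {
  stopifnot(kh_plus > 0, kh_minus > 0, km_plus > 0, km_minus > 0,
            sites_high >= 1, sites_medium >= 1)
  structure(as.list(environment()), class = "buffer_params")
}

#' Plasma-membrane calcium pump (PMCA) parameters
#'
#' Four-step transport cycle: bind cytosolic calcium (kpm1), release it back
#' (kpm2), occlude and extrude it (kpm3), reset (kpm4); plus a counter-leak
#' that injects calcium at each pump site so that the resting level is
#' maintained. With `balance_leak = TRUE` (default) the leak rate actually
#' used is the per-pump extrusion flux at the resting concentration, which
#' balances the cycle exactly; the printed nominal rate is kept in
#' `kpm_leak`.
#'
#' @param density_um2 pump surface density (/um^2)
#' @param kpm1 association rate (/M/s)
#' @param kpm2,kpm3,kpm4 cycle rates (/s)
#' @param kpm_leak nominal leak rate (/s per pump)
#' @param balance_leak balance the leak against resting extrusion (logical)
#' @return an object of class `pump_params`
#' @export
pump_params <- function(density_um2 = 180, kpm1 = 1.5e7, kpm2 = 20,
                        kpm3 = 20, kpm4 = 100, kpm_leak = 12.5,
                        balance_leak = TRUE) {
  stopifnot(density_um2 >= 0, kpm1 > 0, kpm2 > 0, kpm3 > 0, kpm4 > 0)
  structure(as.list(environment()), class = "pump_params")
}

# per-pump extrusion flux (/s) of the cycle at fixed calcium (uM)
pump_cycle_flux <- function(pp, ca_uM) {
  r1 <- pp$kpm1 * ca_uM * 1e-6          # /s
  p1 <- r1 / (pp$kpm2 + pp$kpm3)
  p2 <- p1 * pp$kpm3 / pp$kpm4
  p1 * pp$kpm3 / (1 + p1 + p2)
}

#' Diffusion and time-step parameters
#'
#' @param D_ca_um2s free calcium diffusion constant (um^2/s)
#' @param dt_ca_us time step for calcium (us)
#' @param dt_other_us time step for all other molecules (us)
#' @param resting_uM resting intracellular calcium (uM)
#' @param t_fine_ms duration of the finely stepped phase; afterwards both
#'   steps are multiplied by `coarse_mult` (long runs spend most of their
#'   time near rest where fine stepping is not needed)
#' @param coarse_mult coarsening factor for the late phase
#' @param cell_nm edge length of the grid cells used for local
#'   concentrations in the binding step
#' @return an object of class `diffusion_params`
#' @export
diffusion_params <- function(D_ca_um2s = 220, dt_ca_us = 0.1,
                             dt_other_us = 1.0, resting_uM = 0.1,
                             t_fine_ms = Inf, coarse_mult = 10,
                             cell_nm = 62.5) {
  stopifnot(dt_ca_us <= dt_other_us, resting_uM > 0)
  structure(as.list(environment()), class = "diffusion_params")
}

#' Mass-action binding probability per time step
#'
#' Probability that a particle binds in `dt` given an on-rate and the local
#' free-site concentration: `1 - exp(-k_on * c * dt)`. Recovers the
#' macroscopic mass-action rate in a well-mixed volume. Errors if the
#' computed probability saturates, instructing a smaller step.
#'
#' @param k_on association rate (/M/s)
#' @param conc_uM local concentration of free sites (uM)
#' @param dt_ms time step (ms)
#' @return binding probability in [0, 1)
#' @export
binding_prob <- function(k_on, conc_uM, dt_ms) {
  if (k_on < 0) stop("k_on must be nonnegative", call. = FALSE)
  rate <- k_on * 1e-9 * conc_uM # /ms
  p <- -expm1(-rate * dt_ms)
  if (any(rate * dt_ms > 0.5)) {
    stop("binding probability saturates at this dt; reduce the time step",
         call. = FALSE)
  }
  p
}

#' Isotropic Brownian displacement step
#'
#' Displaces particles by Gaussian steps with per-axis variance `2 D dt`,
#' reflecting at box walls. Immobile species (D = 0) are returned unchanged.
#'
#' @param pos matrix or data frame with columns x, y, z (nm)
#' @param D_um2s diffusion constant (um^2/s)
#' @param dt_ms time step (ms)
#' @param box box dimensions c(Lx, Ly, Lz) in nm, or NULL for free space
#' @param seed integer seed
#' @return a tibble with displaced x, y, z
#' @export
step_brownian <- function(pos, D_um2s, dt_ms, box = NULL, seed = 1) {
  m <- as.matrix(pos[, c("x", "y", "z")])
  if (D_um2s == 0) return(tibble::as_tibble(as.data.frame(m)))
  b <- if (is.null(box)) c(-1, -1, -1) else box
  out <- cpp_brownian_steps(m, D_um2s * 1000, dt_ms, b,
                            derive_seeds(seed, 1, stream = 5L))
  colnames(out) <- c("x", "y", "z")
  tibble::as_tibble(as.data.frame(out))
}

# assemble the parameter list handed to the C++ engine (nm / ms / uM units)
spatial_engine_par <- function(buffer, pumps, diff) {
  leak <- if (isTRUE(pumps$balance_leak)) {
    pump_cycle_flux(pumps, diff$resting_uM)
  } else {
    pumps$kpm_leak
  }
  list(
    D_ca = diff$D_ca_um2s * 1000, D_cb = buffer$D_um2s * 1000,
    dt_ca = diff$dt_ca_us / 1000, dt_other = diff$dt_other_us / 1000,
    t_fine_ms = diff$t_fine_ms, coarse_mult = diff$coarse_mult,
    resting_uM = diff$resting_uM, clamp_uM = diff$resting_uM,
    cb_conc_uM = buffer$concentration_uM,
    kh_plus = buffer$kh_plus * 1e-9, kh_minus = buffer$kh_minus * 1e-3,
    km_plus = buffer$km_plus * 1e-9, km_minus = buffer$km_minus * 1e-3,
    sites_high = as.integer(buffer$sites_high),
    sites_medium = as.integer(buffer$sites_medium),
    pmca_density_per_nm2 = pumps$density_um2 * 1e-6,
    kpm1 = pumps$kpm1 * 1e-9, kpm2 = pumps$kpm2 * 1e-3,
    kpm3 = pumps$kpm3 * 1e-3, kpm4 = pumps$kpm4 * 1e-3,
    leak_per_ms = leak * 1e-3,
    cell_nm = diff$cell_nm)
}

#' Run the particle-based bouton engine
#'
#' Low-level driver of the reaction-diffusion engine: free calcium,
#' calbindin and PMCA pumps in the clamped box, with an optional ion
#' injection schedule (from channel gating) and optional tagged ions for
#' effective-diffusion measurements. Concentration traces are recorded at
#' the active-zone probe and at each docked vesicle.
#'
#' @param geometry a [bouton_geometry()]
#' @param buffer a [buffer_params()]
#' @param pumps a [pump_params()]
#' @param diffusion a [diffusion_params()]
#' @param injections tibble with columns `x`, `y`, `z`, `t_open`, `t_close`
#'   (channel positions and open intervals), or NULL for no influx
#' @param flux_open ions/ms injected at each open channel
#' @param t_end_ms simulated duration
#' @param out_dt_ms probe trace resolution
#' @param n_tagged number of tagged ions released at the box centre
#' @param tag_dt_ms sampling interval for tagged positions
#' @param seed integer seed; identical seeds give identical runs
#' @return an object of class `bouton_run` with elements `traces` (tibble:
#'   `time_ms`, `probe`, `conc_uM`), `bulk` (tibble), `tagged` (tibble of
#'   tracked positions) and `diag` (ion bookkeeping)
#' @export
run_spatial_engine <- function(geometry = bouton_geometry(),
                               buffer = buffer_params(),
                               pumps = pump_params(),
                               diffusion = diffusion_params(),
                               injections = NULL, flux_open = 0,
                               t_end_ms = 10, out_dt_ms = 0.1,
                               n_tagged = 0, tag_dt_ms = 0.05, seed = 1) {
  geom <- list(Lx = geometry$Lx, Ly = geometry$Ly, Lz = geometry$Lz,
               clamp_nm = geometry$clamp_nm)
  par <- spatial_engine_par(buffer, pumps, diffusion)
  if (!is.finite(par$t_fine_ms)) par$t_fine_ms <- t_end_ms + 1
  inj <- if (is.null(injections) || nrow(injections) == 0) {
    matrix(0, 0, 5)
  } else {
    as.matrix(injections[, c("x", "y", "z", "t_open", "t_close")])
  }
  probes <- rbind(
    c(geometry$probe, geometry$probe_radius_nm),
    cbind(geometry$vesicles[, "x"], geometry$vesicles[, "y"] + 10,
          geometry$vesicles[, "z"], geometry$probe_radius_nm))
  opt <- list(t_end_ms = t_end_ms, out_dt_ms = out_dt_ms,
              n_tagged = as.integer(n_tagged), tag_dt_ms = tag_dt_ms,
              tag_origin = c(geometry$Lx / 2, geometry$Ly / 2, geometry$Lz / 2))
  res <- cpp_simulate_bouton(geom, par, inj, flux_open, probes, opt,
                             derive_seeds(seed, 1, stream = 13L))
  probe_names <- c("az_probe", paste0("vesicle_", seq_len(nrow(geometry$vesicles))))
  traces <- tibble::as_tibble(as.data.frame(res$probe_uM)) |>
    setNames(probe_names) |>
    dplyr::mutate(time_ms = as.double(res$time_ms), .before = 1) |>
    tidyr::pivot_longer(-"time_ms", names_to = "probe", values_to = "conc_uM")
  tagged <- if (res$n_tag_rows > 0) {
    m <- res$tagged[seq_len(res$n_tag_rows), , drop = FALSE]
    tibble::tibble(ion = as.integer(m[, 1]), time_ms = m[, 2],
                   x = m[, 3], y = m[, 4], z = m[, 5])
  } else {
    tibble::tibble(ion = integer(), time_ms = double(),
                   x = double(), y = double(), z = double())
  }
  structure(list(
    traces = traces,
    bulk = tibble::tibble(time_ms = as.double(res$time_ms),
                          conc_uM = as.double(res$bulk_uM)),
    tagged = tagged,
    diag = res$diag,
    geometry = geometry), class = "bouton_run")
}

#' @export
print.bouton_run <- function(x, ...) {
  cat(sprintf("<bouton_run> %.1f ms, %d probes, %s tagged ions\n",
              max(x$bulk$time_ms), length(unique(x$traces$probe)),
              length(unique(x$tagged$ion))))
  invisible(x)
}

#' Local calcium trace at a probe
#'
#' Extracts the concentration time course recorded in the spherical sampling
#' volume around a named probe of a spatial run.
#'
#' @param run a [run_spatial_engine()] result
#' @param probe probe name (default the active-zone probe, 10 nm from the
#'   active zone)
#' @return a tibble with `time_ms`, `conc_uM`
#' @export
measure_local_ca <- function(run, probe = "az_probe") {
  stopifnot(inherits(run, "bouton_run"))
  hit <- dplyr::filter(run$traces, .data$probe == !!probe)
  if (nrow(hit) == 0) stop("unknown probe: ", probe, call. = FALSE)
  dplyr::select(hit, "time_ms", "conc_uM")
}

#' Simulate one spatial trial of a stimulus protocol
#'
#' Full pipeline for one trial: samples channel positions in the cluster,
#' simulates stochastic channel gating along the protocol voltage, converts
#' openings into an ion-injection schedule, and runs the reaction-diffusion
#' engine. Returns the engine run together with the channel trajectory.
#'
#' @param protocol a [make_train()] protocol
#' @param geometry a [bouton_geometry()]
#' @param channels a [vdcc_params()]
#' @param buffer,pumps,diffusion engine parameter sets
#' @param ap the action-potential template
#' @param t_end_ms simulated duration (defaults to the protocol duration)
#' @param seed integer seed (controls positions, gating and diffusion)
#' @param ... passed on to [run_spatial_engine()]
#' @return a `bouton_run` with an extra `channels` element
#' @export
simulate_bouton_trial <- function(protocol, geometry = bouton_geometry(),
                                  channels = vdcc_params(),
                                  buffer = buffer_params(),
                                  pumps = pump_params(),
                                  diffusion = diffusion_params(),
                                  ap = ap_waveform(),
                                  t_end_ms = protocol$duration_ms,
                                  seed = 1, ...) {
  volt <- voltage_trace(protocol, ap, dt_ms = 0.01)
  volt <- dplyr::filter(volt, .data$time_ms <= t_end_ms)
  traj <- simulate_channels(volt, channels, seed = seed)
  ints <- open_intervals(traj)
  pos <- sample_channel_positions(channels, geometry$cluster_center[c(1, 3)],
                                  seed = seed)
  inj <- if (nrow(ints) > 0) {
    dplyr::bind_cols(pos[ints$channel + 1, ], ints[, c("t_open", "t_close")])
  } else {
    NULL
  }
  run <- run_spatial_engine(geometry, buffer, pumps, diffusion,
                            injections = inj, flux_open = channels$flux_open,
                            t_end_ms = t_end_ms, seed = seed, ...)
  run$channels <- traj
  run
}

#' Calibrate the single-channel calcium flux
#'
#' The calcium conductance of one open channel is not an observable of the
#' gating model; it is fixed by requiring that the mean across-trial peak of
#' the local calcium transient at the active-zone probe (48 channels,
#' l_c = 250 nm, single action potential) matches a target value. Bisection
#' on the flux; the result is then frozen for all other experiments.
#'
#' @param target_peak_uM target mean local peak (uM); the reference value is
#'   12 uM
#' @param geometry,channels,buffer,pumps,diffusion model configuration
#' @param n_trials trials per flux evaluation
#' @param t_end_ms simulated duration per trial (the local transient peaks
#'   within the first few ms)
#' @param flux_range bracketing search range (ions/ms)
#' @param tol relative tolerance on the achieved peak
#' @param seed integer seed
#' @return a list with `flux_open`, `achieved_peak_uM`, `history` (tibble)
#' @export
calibrate_channel_flux <- function(target_peak_uM = 12,
                                   geometry = bouton_geometry(lc_nm = 250),
                                   channels = vdcc_params(n_channels = 48),
                                   buffer = buffer_params(),
                                   pumps = pump_params(),
                                   diffusion = diffusion_params(
                                     dt_ca_us = 1, dt_other_us = 10),
                                   n_trials = 8, t_end_ms = 8,
                                   flux_range = c(50, 20000), tol = 0.1,
                                   seed = 1) {
  if (target_peak_uM == 0) {
    return(list(flux_open = 0, achieved_peak_uM = 0,
                history = tibble::tibble()))
  }
  if (target_peak_uM < 0) stop("target peak must be nonnegative", call. = FALSE)
  protocol <- make_train(0, t_end_ms)
  protocol$onsets_ms <- 0
  mean_peak <- function(flux) {
    ch <- channels; ch$flux_open <- flux
    peaks <- vapply(seq_len(n_trials), function(i) {
      run <- simulate_bouton_trial(protocol, geometry, ch, buffer, pumps,
                                   diffusion, t_end_ms = t_end_ms,
                                   seed = seed * 1000 + i)
      max(measure_local_ca(run)$conc_uM)
    }, numeric(1))
    mean(peaks)
  }
  lo <- flux_range[1]; hi <- flux_range[2]
  p_lo <- mean_peak(lo); p_hi <- mean_peak(hi)
  if (p_lo > target_peak_uM || p_hi < target_peak_uM) {
    stop("flux search range does not bracket the target peak", call. = FALSE)
  }
  hist <- tibble::tibble(flux = c(lo, hi), peak = c(p_lo, p_hi))
  for (i in 1:8) {
    mid <- sqrt(lo * hi)
    p_mid <- mean_peak(mid)
    hist <- dplyr::bind_rows(hist, tibble::tibble(flux = mid, peak = p_mid))
    if (abs(p_mid - target_peak_uM) / target_peak_uM < tol) {
      return(list(flux_open = mid, achieved_peak_uM = p_mid, history = hist))
    }
    if (p_mid < target_peak_uM) lo <- mid else hi <- mid
  }
  mid <- sqrt(lo * hi)
  list(flux_open = mid, achieved_peak_uM = mean_peak(mid), history = hist)
}
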