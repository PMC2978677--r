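#' Dual calcium-sensor parameters
#'
#' Kinetics of the per-vesicle release machinery: a synchronous sensor with
#' five calcium binding sites (fast binding, fast unbinding, fusion rate
#' gamma when fully bound) and an asynchronous sensor with two sites (slow
#' unbinding and a 40-fold slower fusion rate `a * gamma`), plus a small
#' spontaneous fusion rate delta from the unbound state. Unbinding is
#' slowed by the cooperativity factor `b` per bound site
#' (`n * k_minus * b^(n-1)`). After any release the whole active zone is
#' refractory for an exponentially distributed interval with mean
#' `epsilon_ms`.
#'
#' Rates are given in laboratory units: association /M/s, dissociation and
#' fusion /s, epsilon in ms.
#'
#' @param ks_plus,ks_minus synchronous association / dissociation
#' @param ka_plus,ka_minus asynchronous association / dissociation
#' @param b cooperativity factor (0 < b <= 1)
#' @param gamma synchronous fusion rate (/s)
#' @param a asynchronous fusion factor (0 < a < 1; gamma_a = a * gamma)
#' @param delta spontaneous fusion rate (/s)
#' @param epsilon_ms refractory recovery time constant (ms)
#' @param n_sync_sites,n_async_sites binding-site counts (5 and 2)
#' @param b_async apply the cooperativity factor to asynchronous unbinding
#'   too (a single b is printed for the scheme; switchable)
#' @param delta_any allow spontaneous fusion from any occupancy state
#'   rather than only the fully unbound one
#' @return an object of class `sensor_params`
#' @export
sensor_params <- function(ks_plus = 0.612e8, ks_minus = 2.32e3,
                          ka_plus = 3.82e6, ka_minus = 13,
                          b = 0.25, gamma = 2e3, a = 0.025,
                          delta = 0.417e-3, epsilon_ms = 6.34,
                          n_sync_sites = 5, n_async_sites = 2,
                          b_async = TRUE, delta_any = FALSE) {
  stopifnot(b > 0, b <= 1, a > 0, a < 1, epsilon_ms > 0,
            ks_plus > 0, ka_plus > 0)
  structure(as.list(environment()), class = "sensor_params")
}

#' Phenomenological single-gate sensor for the whole active zone
#'
#' Alternative higher-level model in which the entire active zone has a
#' single gating mechanism: one dual-pathway sensor, equal fusion rate
#' gamma for the synchronous and asynchronous pathways, no per-vesicle
#' docking limit (infinite readily-releasable pool), and the same
#' refractory coupling. Eliminates the need for the asynchronous fusion
#' factor `a`.
#'
#' @inheritParams sensor_params
#' @param gamma1 spontaneous fusion rate of the single gate (/s)
#' @return an object of class `sensor_params` (phenomenological flavour)
#' @export
phenomenological_params <- function(ks_plus = 1.91e8, ks_minus = 7.25e3,
                                    ka_plus = 3.68e6, ka_minus = 26,
                                    b = 0.25, gamma = 6e3,
                                    gamma1 = 0.417e-3, epsilon_ms = 6.34,
                                    b_async = TRUE, delta_any = FALSE) {
  p <- sensor_params(ks_plus = ks_plus, ks_minus = ks_minus,
                     ka_plus = ka_plus, ka_minus = ka_minus, b = b,
                     gamma = gamma, a = 0.999, delta = gamma1,
                     epsilon_ms = epsilon_ms,
                     b_async = b_async, delta_any = delta_any)
  p$a <- 1
  p$phenomenological <- TRUE
  p
}

#' Active-zone configuration
#'
#' Bundles the sensor kinetics with the zone-level machinery: the number of
#' docked vesicles (readily-releasable pool), the refractory gate, and the
#' model variant.
#'
#' @param sensor a [sensor_params()] or [phenomenological_params()]
#' @param n_vesicles docked vesicle count (RRP size)
#' @param refractory apply the zone-wide refractory gate after each release
#' @param refractory_deterministic use a fixed dead time instead of an
#'   exponentially distributed closure
#' @param refractory_dead_ms dead time used when deterministic (ms)
#' @param depletion_free instantly replace each released vesicle
#' @param variant one of "wild-type", "sync-KO", "SAKO", "phenomenological"
#' @param baseline_uM resting calcium assumed when a trace is given as a
#'   stimulus component (uM)
#' @return an object of class `zone_config`
#' @export
zone_config <- function(sensor = sensor_params(), n_vesicles = 7,
                        refractory = TRUE,
                        refractory_deterministic = FALSE,
                        refractory_dead_ms = 6,
                        depletion_free = FALSE,
                        variant = c("wild-type", "sync-KO", "SAKO",
                                    "phenomenological"),
                        baseline_uM = 0.1) {
  variant <- match.arg(variant)
  cfg <- structure(
    list(sensor = sensor, n_vesicles = as.integer(n_vesicles),
         refractory = refractory,
         refractory_deterministic = refractory_deterministic,
         refractory_dead_ms = refractory_dead_ms,
         depletion_free = depletion_free,
         variant = "wild-type", baseline_uM = baseline_uM),
    class = "zone_config")
  apply_variant(cfg, variant)
}

#' Switch an active-zone configuration to a model variant
#'
#' `sync-KO` removes all synchronous-pathway states and fusion (the fast
#' sensor knock-out); `SAKO` removes the asynchronous pathway (simulated
#' asynchronous sensor knock-out); `phenomenological` swaps in the
#' single-gate whole-zone sensor with an infinite pool.
#'
#' @param config a [zone_config()]
#' @param variant variant name
#' @return the modified configuration
#' @export
apply_variant <- function(config, variant = c("wild-type", "sync-KO", "SAKO",
                                              "phenomenological")) {
  variant <- match.arg(variant)
  config$variant <- variant
  if (variant == "phenomenological" &&
      !isTRUE(config$sensor$phenomenological)) {
    config$sensor <- phenomenological_params()
  }
  config
}

#' @export
print.zone_config <- function(x, ...) {
  cat(sprintf("<zone_config> %s, %d vesicle(s), refractory %s%s\n",
              x$variant, x$n_vesicles, ifelse(x$refractory, "on", "off"),
              ifelse(x$depletion_free, ", depletion-free", "")))
  invisible(x)
}

# flattened parameter list for the C++ zone simulator (/ms, /uM/ms units)
zone_par_ms <- function(config) {
  s <- config$sensor
  phenom <- isTRUE(s$phenomenological) || config$variant == "phenomenological"
  list(
    ks_plus = s$ks_plus * 1e-9, ks_minus = s$ks_minus * 1e-3,
    ka_plus = s$ka_plus * 1e-9, ka_minus = s$ka_minus * 1e-3,
    b = s$b, gamma = s$gamma * 1e-3, a = s$a,
    async_gamma = s$a * s$gamma * 1e-3,
    delta = s$delta * 1e-3, epsilon_ms = s$epsilon_ms,
    n_sync = as.integer(s$n_sync_sites %||% 5),
    n_async = as.integer(s$n_async_sites %||% 2),
    n_vesicles = if (phenom) 1L else config$n_vesicles,
    b_async = isTRUE(s$b_async), delta_any = isTRUE(s$delta_any),
    refractory = isTRUE(config$refractory),
    refractory_deterministic = isTRUE(config$refractory_deterministic),
    refractory_dead_ms = config$refractory_dead_ms,
    depletion_free = isTRUE(config$depletion_free),
    sync_ko = config$variant == "sync-KO",
    async_ko = config$variant == "SAKO",
    phenomenological = phenom)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generator matrix of the sensor scheme at fixed calcium
#'
#' Builds the continuous-time Markov generator over the 18 occupancy states
#' (ns, na) of one vesicle plus three absorbing fusion sinks (synchronous,
#' asynchronous, spontaneous), at a fixed calcium concentration. Rates are
#' per ms. Rows sum to zero including the sinks.
#'
#' @param params a [sensor_params()]
#' @param ca_uM calcium concentration (uM, >= 0)
#' @param variant model variant (pathway knock-outs respected)
#' @return a square matrix with dimnames like `"ns2.na1"`, plus the sinks
#'   `"fused_sync"`, `"fused_async"`, `"fused_spont"`
#' @export
sensor_rate_matrix <- function(params = sensor_params(), ca_uM = 0.1,
                               variant = "wild-type") {
  if (ca_uM < 0) stop("calcium concentration must be nonnegative", call. = FALSE)
  ns_max <- params$n_sync_sites %||% 5
  na_max <- params$n_async_sites %||% 2
  ksp <- params$ks_plus * 1e-9; ksm <- params$ks_minus * 1e-3
  kap <- params$ka_plus * 1e-9; kam <- params$ka_minus * 1e-3
  gam <- params$gamma * 1e-3
  agam <- params$a * params$gamma * 1e-3
  del <- params$delta * 1e-3
  b <- params$b
  states <- expand.grid(ns = 0:ns_max, na = 0:na_max)
  lab <- sprintf("ns%d.na%d", states$ns, states$na)
  sinks <- c("fused_sync", "fused_async", "fused_spont")
  n <- nrow(states)
  Q <- matrix(0, n + 3, n + 3, dimnames = list(c(lab, sinks), c(lab, sinks)))
  id <- function(ns, na) which(states$ns == ns & states$na == na)
  for (k in seq_len(n)) {
    ns <- states$ns[k]; na <- states$na[k]
    if (variant != "sync-KO") {
      if (ns < ns_max) Q[k, id(ns + 1, na)] <- (ns_max - ns) * ksp * ca_uM
      if (ns > 0) Q[k, id(ns - 1, na)] <- ns * ksm * b^(ns - 1)
      if (ns == ns_max) Q[k, n + 1] <- gam
    }
    if (variant != "SAKO") {
      if (na < na_max) Q[k, id(ns, na + 1)] <- (na_max - na) * kap * ca_uM
      if (na > 0) {
        Q[k, id(ns, na - 1)] <-
          na * kam * (if (isTRUE(params$b_async)) b^(na - 1) else 1)
      }
      if (na == na_max) Q[k, n + 2] <- agam
    }
    if (isTRUE(params$delta_any) || (ns == 0 && na == 0)) Q[k, n + 3] <- del
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Steady-state spontaneous release rate of the active zone
#'
#' At clamped resting calcium the zone emits a steady trickle of fusion
#' events. Computed deterministically: fusion transitions are redirected to
#' the unbound state (a released vesicle is replaced at rest on average),
#' the stationary distribution of the resulting chain is solved by linear
#' algebra, and the stationary fusion flux is scaled by the vesicle count.
#'
#' @param params a [sensor_params()]
#' @param ca_uM clamped calcium concentration (uM)
#' @param n_vesicles number of docked vesicles
#' @return zone release rate in events per ms
#' @export
#' @examples
#' spontaneous_release_rate() # about 1.2e-4 per ms at 100 nM
spontaneous_release_rate <- function(params = sensor_params(), ca_uM = 0.1,
                                     n_vesicles = 7) {
  Q <- sensor_rate_matrix(params, ca_uM)
  n <- nrow(Q) - 3
  fus <- rowSums(Q[seq_len(n), n + (1:3), drop = FALSE])
  # transient block already carries the fusion outflow on its diagonal;
  # redirecting that flow into the unbound state makes rows sum to zero
  G <- Q[seq_len(n), seq_len(n), drop = FALSE]
  G[, 1] <- G[, 1] + fus            # fusion returns the vesicle to (0, 0)
  A <- t(G)
  A[n, ] <- 1
  pi <- solve(A, c(rep(0, n - 1), 1))
  n_vesicles * sum(pi * fus)
}

#' Simulate the active zone along calcium traces
#'
#' Exact stochastic simulation of the time-inhomogeneous sensor chain for
#' every docked vesicle, with the calcium concentration held piecewise
#' constant between trace samples. Releases remove the vesicle (unless
#' depletion-free), and with the refractory gate enabled every release
#' closes fusion zone-wide for an exponentially distributed interval while
#' calcium binding continues.
#'
#' @param ca a calcium trace tibble with `time_ms` and either one `conc_uM`
#'   column (shared by all vesicles) or one column per vesicle
#' @param config a [zone_config()]
#' @param n_trials number of independent trials
#' @param seed master seed; per-trial streams are derived deterministically
#' @param trial_scale optional per-trial multiplicative factors applied to
#'   the above-baseline part of the trace (length `n_trials`)
#' @return a tibble of release events: `trial` (0-based), `time_ms`,
#'   `vesicle` (0-based), `pathway` (factor: synchronous / asynchronous /
#'   spontaneous)
#' @export
simulate_active_zone <- function(ca, config = zone_config(), n_trials = 1,
                                 seed = 1, trial_scale = NULL) {
  stopifnot(is.data.frame(ca), "time_ms" %in% names(ca))
  par <- zone_par_ms(config)
  conc_cols <- setdiff(names(ca), "time_ms")
  if (!(length(conc_cols) %in% c(1L, par$n_vesicles))) {
    stop("need one calcium column or one per vesicle", call. = FALSE)
  }
  t <- ca$time_ms
  stim <- as.matrix(ca[conc_cols]) - config$baseline_uM
  stim[stim < 0] <- 0
  stim <- stim[-nrow(stim), , drop = FALSE] # left-value on each interval
  if (is.null(trial_scale)) trial_scale <- rep(1, n_trials)
  stopifnot(length(trial_scale) == n_trials)
  seeds <- derive_seeds(seed, n_trials, stream = 23L)
  ev <- cpp_simulate_zone(t, stim, par, as.integer(n_trials), seeds,
                          trial_scale, config$baseline_uM)
  tibble::tibble(
    trial = as.integer(ev$trial),
    time_ms = ev$time_ms,
    vesicle = as.integer(ev$vesicle),
    pathway = factor(c("synchronous", "asynchronous", "spontaneous")[ev$pathway],
                     levels = c("synchronous", "asynchronous", "spontaneous")))
}

#' Refractory gate schedule from release times
#'
#' Each release closes the zone gate for an exponentially distributed
#' interval with mean `epsilon_ms`; overlapping closures merge. Used to
#' reason about the gate in isolation from the full simulation.
#'
#' @param release_times_ms release event times (ms)
#' @param epsilon_ms mean closure duration (ms)
#' @param seed integer seed
#' @return a tibble of closed intervals with `t_close`, `t_reopen`
#' @export
refractory_schedule <- function(release_times_ms, epsilon_ms = 6.34,
                                seed = 1) {
  stopifnot(epsilon_ms > 0)
  if (length(release_times_ms) == 0) {
    return(tibble::tibble(t_close = double(), t_reopen = double()))
  }
  u <- derive_seeds(seed, length(release_times_ms), stream = 29L) / 2147483647
  dur <- -epsilon_ms * log(u)
  t0 <- sort(release_times_ms)
  t1 <- t0 + dur[order(release_times_ms)]
  # merge overlaps
  out0 <- t0[1]; out1 <- t1[1]
  res <- list()
  for (i in seq_along(t0)[-1]) {
    if (t0[i] <= out1) {
      out1 <- max(out1, t1[i])
    } else {
      res[[length(res) + 1]] <- c(out0, out1)
      out0 <- t0[i]; out1 <- t1[i]
    }
  }
  res[[length(res) + 1]] <- c(out0, out1)
  m <- do.call(rbind, res)
  tibble::tibble(t_close = m[, 1], t_reopen = m[, 2])
}
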