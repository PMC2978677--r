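as_events <- function(events) {
  if (inherits(events, "ensemble_result")) events$events else events
}

#' Release-rate histogram
#'
#' Bins release events at resolution `t_b` and converts counts to a release
#' rate per ms per trial, with the Poisson error rule: the standard
#' deviation of the count in a bin with r events is sqrt(r), so the rate
#' error is sqrt(r) / (N t_b).
#'
#' @param events release events (tibble or `ensemble_result`)
#' @param t_b bin width (ms), typically 1 or 10
#' @param n_trials ensemble size N (taken from an `ensemble_result`
#'   automatically)
#' @param window c(start, end) of the histogram (ms)
#' @return a `release_histogram` tibble with `t_start_ms`, `count`,
#'   `rate_per_ms`, `std_per_ms`
#' @export
release_histogram <- function(events, t_b = 10, n_trials = NULL,
                              window = NULL) {
  if (t_b <= 0) stop("bin width must be positive", call. = FALSE)
  if (is.null(n_trials) && inherits(events, "ensemble_result")) {
    n_trials <- events$n_trials
  }
  ev <- as_events(events)
  stopifnot(!is.null(n_trials))
  if (is.null(window)) {
    window <- c(0, max(c(ev$time_ms, t_b)))
  }
  n_bins <- max(1L, floor((window[2] - window[1]) / t_b + 1e-9))
  edges <- window[1] + t_b * (0:n_bins)
  counts <- if (nrow(ev) > 0) {
    tt <- ev$time_ms[ev$time_ms >= window[1] & ev$time_ms < max(edges)]
    tabulate(findInterval(tt, edges), nbins = n_bins)
  } else {
    rep(0L, n_bins)
  }
  out <- tibble::tibble(
    t_start_ms = edges[-length(edges)],
    count = as.integer(counts),
    rate_per_ms = counts / (n_trials * t_b),
    std_per_ms = sqrt(counts) / (n_trials * t_b))
  attr(out, "t_b") <- t_b
  attr(out, "n_trials") <- n_trials
  class(out) <- c("release_histogram", class(out))
  out
}

#' @export
autoplot.release_histogram <- function(object, log_y = FALSE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$t_start_ms,
                                            y = .data$rate_per_ms)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (ms)", y = "release rate (/ms)")
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Multi-exponential fit of a release decay
#'
#' Weighted nonlinear least squares of the binned release rate to
#' `a0 exp(-t/tau_fast) + a1 exp(-t/tau_slow) + a2` (2exp) or
#' `b0 exp(-t/tau_superfast) + b1 exp(-t/tau_fast) + b2 exp(-t/tau_slow)
#' + b3` (3exp), starting at `fit_start_ms` after the stimulus (release
#' lags the action potential by about 3 ms). Weights are 1/max(r, 1) per
#' bin. Component release fractions are the integrals of each component
#' over the fit window divided by the integral of the full fit.
#'
#' @param hist a [release_histogram()]
#' @param model "2exp" or "3exp"
#' @param fit_start_ms left edge of the fit window (ms)
#' @param fit_end_ms right edge of the fit window (ms)
#' @param constant NULL to fit the constant term freely, or a number to pin
#'   it (the constant is the base-level release rate, which is known
#'   independently from the spontaneous release rate of the zone; pinning it
#'   removes the ill-conditioned trade-off against the slow component)
#' @param weighting "model" (default) iterates weights from the fitted
#'   expected counts; "observed" uses the observed counts once (weights
#'   correlated with the Poisson noise bias the slow component)
#' @return a `release_fit` object; see [tidy()] and [glance()] methods
#' @export
fit_release_decay <- function(hist, model = c("2exp", "3exp"),
                              fit_start_ms = 3, fit_end_ms = NULL,
                              constant = NULL,
                              weighting = c("model", "observed")) {
  model <- match.arg(model)
  weighting <- match.arg(weighting)
  t_b <- attr(hist, "t_b")
  df <- dplyr::filter(tibble::as_tibble(hist),
                      .data$t_start_ms + t_b / 2 >= fit_start_ms)
  if (!is.null(fit_end_ms)) {
    df <- dplyr::filter(df, .data$t_start_ms < fit_end_ms)
  }
  if (nrow(df) < 6 || sum(df$count) == 0) {
    stop("histogram has too little data beyond the fit start", call. = FALSE)
  }
  t <- df$t_start_ms + t_b / 2
  y <- df$rate_per_ms
  w <- 1 / pmax(df$count, 1)

  # log-linear starters on the early and late segments
  seg_tau <- function(tt, yy) {
    ok <- yy > 0
    if (sum(ok) < 2) return(NA_real_)
    f <- stats::lm(log(yy[ok]) ~ tt[ok])
    tau <- -1 / unname(coef(f)[2])
    if (!is.finite(tau) || tau <= 0) NA_real_ else tau
  }
  tau_f0 <- seg_tau(t[t <= 25], y[t <= 25]); if (is.na(tau_f0)) tau_f0 <- 6
  tau_s0 <- seg_tau(t[t >= 80], y[t >= 80] - min(y))
  if (is.na(tau_s0) || tau_s0 < 3 * tau_f0) tau_s0 <- 160
  a2_0 <- max(min(y), 1e-12)

  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, maxfev = 4000)
  # average of a * exp(-t/tau) over a bin (exact; avoids the bias of
  # evaluating a fast exponential at the bin centre when tau ~ bin width)
  bin_exp <- function(a, tau, t0, t1) {
    a * tau * (exp(-t0 / tau) - exp(-t1 / tau)) / (t1 - t0)
  }
  t0 <- t - t_b / 2
  t1 <- t + t_b / 2
  pinned <- !is.null(constant)
  cname <- if (model == "2exp") "a2" else "b3"
  getc <- function(p) if (pinned) constant else p[[cname]]
  if (model == "2exp") {
    predfun <- function(p, tt) {
      p[["a0"]] * exp(-tt / p[["tf"]]) + p[["a1"]] * exp(-tt / p[["ts"]]) +
        p[["a2"]]
    }
    binfun <- function(p) {
      bin_exp(p[["a0"]], p[["tf"]], t0, t1) +
        bin_exp(p[["a1"]], p[["ts"]], t0, t1) + getc(p)
    }
    start <- list(a0 = max(y), tf = tau_f0, a1 = max(y) / 50,
                  ts = tau_s0, a2 = a2_0)
    lower <- c(0, 0.1, 0, 1, 0)
  } else {
    predfun <- function(p, tt) {
      p[["b0"]] * exp(-tt / p[["tsf"]]) + p[["b1"]] * exp(-tt / p[["tf"]]) +
        p[["b2"]] * exp(-tt / p[["ts"]]) + p[["b3"]]
    }
    binfun <- function(p) {
      bin_exp(p[["b0"]], p[["tsf"]], t0, t1) +
        bin_exp(p[["b1"]], p[["tf"]], t0, t1) +
        bin_exp(p[["b2"]], p[["ts"]], t0, t1) + getc(p)
    }
    start <- list(b0 = max(y), tsf = 0.7, b1 = max(y) / 10, tf = tau_f0,
                  b2 = max(y) / 200, ts = tau_s0, b3 = a2_0)
    lower <- c(0, 0.05, 0, 1, 0, 20, 0)
  }
  if (pinned) {
    start[[cname]] <- NULL
    lower <- lower[-length(lower)]
  }
  n_trials <- attr(hist, "n_trials")
  n_iter <- if (weighting == "model") 3L else 1L
  # multi-start over time-constant seeds: multi-exponential surfaces have
  # local minima when components are weak
  tau_seeds <- if (model == "2exp") {
    list(c(tf = tau_f0, ts = tau_s0), c(tf = 6, ts = 160),
         c(tf = 3, ts = 80), c(tf = 10, ts = 300))
  } else {
    list(c(tsf = 0.7, tf = tau_f0, ts = tau_s0),
         c(tsf = 0.4, tf = 6, ts = 160),
         c(tsf = 1.2, tf = 4, ts = 100),
         c(tsf = 0.7, tf = 10, ts = 300))
  }
  one_fit <- function(st) {
    w_it <- w
    fit <- NULL
    for (it in seq_len(n_iter)) {
      fit <- try(minpack.lm::nls.lm(
        par = st,
        fn = function(p) sqrt(w_it) * (y - binfun(p)),
        lower = lower, control = ctrl), silent = TRUE)
      if (inherits(fit, "try-error")) return(NULL)
      if (weighting == "model") {
        w_it <- 1 / pmax(binfun(as.list(coef(fit))) * n_trials * t_b, 0.5)
        st <- as.list(coef(fit))
      }
    }
    if (fit$info < 1 || fit$info > 4) return(NULL)
    # rank solutions by Poisson deviance of the binned counts
    mu <- pmax(binfun(as.list(coef(fit))) * n_trials * t_b, 1e-12)
    r <- y * n_trials * t_b
    dev <- 2 * sum(mu - r + ifelse(r > 0, r * log(r / mu), 0))
    list(fit = fit, score = dev)
  }
  fits <- list()
  for (ts_seed in tau_seeds) {
    st <- start
    for (nm in names(ts_seed)) st[[nm]] <- unname(ts_seed[[nm]])
    res <- one_fit(st)
    if (!is.null(res)) fits[[length(fits) + 1]] <- res
  }
  if (length(fits) == 0) {
    stop("release-decay fit failed to converge from all starts",
         call. = FALSE)
  }
  fit <- fits[[which.min(vapply(fits, function(f) f$score, numeric(1)))]]$fit
  cf <- coef(fit)
  if (pinned) cf[[cname]] <- constant
  window <- range(t) + c(-t_b / 2, t_b / 2)
  span <- diff(window)
  comp <- if (model == "2exp") {
    tibble::tibble(
      component = c("fast", "slow", "constant"),
      amplitude = unname(cf[c("a0", "a1", "a2")]),
      tau_ms = c(unname(cf[c("tf", "ts")]), NA))
  } else {
    tibble::tibble(
      component = c("superfast", "fast", "slow", "constant"),
      amplitude = unname(cf[c("b0", "b1", "b2", "b3")]),
      tau_ms = c(unname(cf[c("tsf", "tf", "ts")]), NA))
  }
  comp$integral <- ifelse(is.na(comp$tau_ms), comp$amplitude * span,
                          comp$amplitude * comp$tau_ms *
                            (exp(-window[1] / pmax(comp$tau_ms, 1e-9)) -
                               exp(-window[2] / pmax(comp$tau_ms, 1e-9))))
  comp$fraction <- comp$integral / sum(comp$integral)
  structure(list(fit = fit, coef = cf, predfun = predfun, model = model,
                 components = comp, window = window, t = t, y = y,
                 residual_norm = sqrt(sum(fit$fvec^2))),
            class = "release_fit")
}

#' @export
print.release_fit <- function(x, ...) {
  cat(sprintf("<release_fit> %s over [%.1f, %.1f] ms\n", x$model,
              x$window[1], x$window[2]))
  print(x$components)
  invisible(x)
}

#' @export
tidy.release_fit <- function(x, ...) {
  x$components
}

#' @export
glance.release_fit <- function(x, ...) {
  cf <- coef(x$fit)
  taus <- sort(unname(cf[grepl("^t", names(cf))]))
  out <- tibble::tibble(model = x$model, residual_norm = x$residual_norm)
  if (x$model == "2exp") {
    out$tau_fast <- taus[1]; out$tau_slow <- taus[2]
  } else {
    out$tau_superfast <- taus[1]; out$tau_fast <- taus[2]
    out$tau_slow <- taus[3]
  }
  out
}

#' @export
autoplot.release_fit <- function(object, ...) {
  pred <- tibble::tibble(
    t = seq(object$window[1], object$window[2], length.out = 400))
  pred$y <- object$predfun(object$coef, pred$t)
  ggplot2::ggplot() +
    ggplot2::geom_point(data = tibble::tibble(t = object$t, y = object$y),
                        ggplot2::aes(x = .data$t, y = .data$y), size = 0.8) +
    ggplot2::geom_line(data = pred,
                       ggplot2::aes(x = .data$t, y = .data$y),
                       colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (ms)", y = "release rate (/ms)")
}

#' Overall release probability
#'
#' Fraction of trials with at least one release event in the window — the
#' zone release probability p_r, as distinct from the per-vesicle
#' probability (see [binomial_independence()]).
#'
#' @param events release events (tibble or `ensemble_result`)
#' @param n_trials ensemble size
#' @param window c(start, end) in ms; NULL uses everything
#' @return scalar probability
#' @export
compute_pr <- function(events, n_trials = NULL, window = NULL) {
  if (is.null(n_trials) && inherits(events, "ensemble_result")) {
    n_trials <- events$n_trials
  }
  ev <- as_events(events)
  stopifnot(n_trials >= 1)
  if (!is.null(window)) {
    ev <- dplyr::filter(ev, .data$time_ms >= window[1],
                        .data$time_ms < window[2])
  }
  length(unique(ev$trial)) / n_trials
}

#' Distribution of the number of vesicles released per trial
#'
#' @param events release events (tibble or `ensemble_result`)
#' @param n_trials ensemble size
#' @return a tibble with `k`, `p`, `cum_p` (P(K <= k)); probabilities sum
#'   to 1
#' @export
vesicle_count_distribution <- function(events, n_trials = NULL) {
  if (is.null(n_trials) && inherits(events, "ensemble_result")) {
    n_trials <- events$n_trials
  }
  ev <- as_events(events)
  counts <- table(factor(ev$trial, levels = unique(ev$trial)))
  kmax <- if (length(counts)) max(counts) else 0
  k <- 0:kmax
  n_k <- vapply(k, function(kk) sum(counts == kk), numeric(1))
  n_k[1] <- n_trials - length(counts)
  tibble::tibble(k = k, p = n_k / n_trials, cum_p = cumsum(n_k) / n_trials)
}

#' Per-vesicle probability under independence
#'
#' If the zone releases with probability `pr_zone` and its n docked
#' vesicles were independent, each vesicle's release probability is
#' `p = 1 - (1 - pr_zone)^(1/n)` and the probability of multi-vesicular
#' release is `P(>=2) = 1 - (1-p)^n - n p (1-p)^(n-1)`.
#'
#' @param pr_zone zone release probability in [0, 1)
#' @param n_vesicles number of docked vesicles
#' @return a tibble with `p_vesicle`, `p_multi`
#' @export
#' @examples
#' binomial_independence(0.2, 7) # p ~ 0.031, P(>=2) ~ 0.02
binomial_independence <- function(pr_zone, n_vesicles = 7) {
  if (any(pr_zone < 0 | pr_zone >= 1)) {
    stop("pr_zone must lie in [0, 1)", call. = FALSE)
  }
  p <- 1 - (1 - pr_zone)^(1 / n_vesicles)
  p2 <- 1 - (1 - p)^n_vesicles - n_vesicles * p * (1 - p)^(n_vesicles - 1)
  tibble::tibble(pr_zone = pr_zone, n_vesicles = n_vesicles,
                 p_vesicle = p, p_multi = p2)
}

#' Facilitation across a stimulus train
#'
#' Splits the run into consecutive per-stimulus windows, totals release in
#' each, and expresses every stimulus as a percent change relative to the
#' first. The summary statistic is the maximum percent increase over
#' stimuli 2..k.
#'
#' @param events release events (tibble or `ensemble_result`)
#' @param n_stimuli number of stimuli in the train
#' @param window_ms per-stimulus window width (ms)
#' @param first_onset_ms onset of the first stimulus (ms)
#' @return a tibble with `stimulus`, `total`, `facilitation_pct`; the
#'   summary is in attribute `max_facilitation_pct` (also returned by
#'   [facilitation_pct()])
#' @export
facilitation <- function(events, n_stimuli, window_ms = 100,
                         first_onset_ms = 0) {
  if (n_stimuli < 2) stop("need at least two stimuli", call. = FALSE)
  ev <- as_events(events)
  edges <- first_onset_ms + window_ms * (0:n_stimuli)
  idx <- findInterval(ev$time_ms, edges)
  totals <- tabulate(idx[idx >= 1 & idx <= n_stimuli], nbins = n_stimuli)
  if (totals[1] == 0) stop("no release in the first window", call. = FALSE)
  fac <- 100 * (totals / totals[1] - 1)
  out <- tibble::tibble(stimulus = seq_len(n_stimuli), total = totals,
                        facilitation_pct = fac)
  attr(out, "max_facilitation_pct") <- max(fac[-1])
  out
}

#' @rdname facilitation
#' @export
facilitation_pct <- function(events, n_stimuli, window_ms = 100,
                             first_onset_ms = 0) {
  attr(facilitation(events, n_stimuli, window_ms, first_onset_ms),
       "max_facilitation_pct")
}

#' Calcium dose-response fit (Dodge-Rahamimoff)
#'
#' Fits the saturable power law `R = Rmax * (c / (c + K))^n` to the number
#' of vesicles released as a function of relative extracellular calcium
#' (channel-flux scaling), with the apparent cooperativity n and the
#' saturation constant K free.
#'
#' @param doses a tibble with columns `level` (relative calcium) and
#'   `releases` (mean vesicles released in the early window)
#' @return a `dr_fit` object with [tidy()] and [glance()] methods
#' @export
dodge_rahamimoff_fit <- function(doses) {
  stopifnot(all(c("level", "releases") %in% names(doses)))
  if (nrow(doses) < 4) {
    stop("need at least 4 dose levels", call. = FALSE)
  }
  if (is.unsorted(doses$releases[order(doses$level)])) {
    warning("dose-response is not monotone; fit may be unreliable")
  }
  # weights ~ inverse variance of a counted quantity; the low-dose points
  # carry most of the information about the exponent
  w <- 1 / pmax(doses$releases, max(doses$releases) / 200)
  resid_fn <- function(p) {
    sqrt(w) * (doses$releases -
                 p[["rmax"]] * (doses$level / (doses$level + p[["K"]]))^p[["n"]])
  }
  fits <- list()
  for (n0 in c(2, 4, 6)) {
    for (k0 in c(0.5, 1, 2) * stats::median(doses$level)) {
      f <- try(minpack.lm::nls.lm(
        par = list(rmax = max(doses$releases) * 2, K = k0, n = n0),
        fn = resid_fn, lower = c(1e-9, 1e-6, 0.2), upper = c(Inf, 50, 12),
        control = minpack.lm::nls.lm.control(maxiter = 1000)), silent = TRUE)
      if (!inherits(f, "try-error") && f$info >= 1 && f$info <= 4) {
        fits[[length(fits) + 1]] <- f
      }
    }
  }
  if (length(fits) == 0) stop("dose-response fit failed", call. = FALSE)
  fit <- fits[[which.min(vapply(fits, function(f) sum(f$fvec^2), numeric(1)))]]
  structure(list(fit = fit, doses = doses,
                 n = unname(coef(fit)["n"]), K = unname(coef(fit)["K"])),
            class = "dr_fit")
}

#' @export
print.dr_fit <- function(x, ...) {
  cat(sprintf("<dr_fit> apparent cooperativity n = %.2f, K = %.3g\n",
              x$n, x$K))
  invisible(x)
}

#' @export
tidy.dr_fit <- function(x, ...) {
  cf <- coef(x$fit)
  tibble::tibble(term = names(cf), estimate = unname(cf))
}

#' @export
glance.dr_fit <- function(x, ...) {
  tibble::tibble(n = x$n, K = x$K,
                 residual_norm = sqrt(sum(x$fit$fvec^2)))
}

#' @export
autoplot.dr_fit <- function(object, ...) {
  cf <- coef(object$fit)
  grid <- tibble::tibble(level = seq(min(object$doses$level),
                                     max(object$doses$level),
                                     length.out = 200))
  grid$releases <- cf[["rmax"]] *
    (grid$level / (grid$level + cf[["K"]]))^cf[["n"]]
  ggplot2::ggplot(object$doses,
                  ggplot2::aes(x = .data$level, y = .data$releases)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::labs(x = "relative extracellular calcium",
                  y = "vesicles released (early window)")
}

#' Effective diffusion constant from tagged-ion trajectories
#'
#' Fits the mean-squared displacement of tagged ions to `MSD(t) = 6 D t`
#' over the observation window (linear least squares through the origin).
#' With the mobile buffer present the apparent constant is far below the
#' free-calcium value because ions spend most of their time bound.
#'
#' The displacement statistic uses the long (4 um) box axis only, scaled to
#' the isotropic equivalent (3 times the per-axis MSD): the transverse box
#' dimensions are 0.5 um, which confines transverse spread within a
#' millisecond and would otherwise bias the estimate downward.
#'
#' @param tagged tibble of tracked positions with `ion`, `time_ms`, `x`,
#'   `y`, `z` (nm), e.g. the `tagged` element of [run_spatial_engine()]
#' @return a list with `D_eff_um2s`, `msd` (tibble), `fit` (lm)
#' @export
estimate_effective_D <- function(tagged) {
  stopifnot(all(c("ion", "time_ms", "x", "y", "z") %in% names(tagged)))
  origin <- tagged |>
    dplyr::group_by(.data$ion) |>
    dplyr::slice_min(.data$time_ms, n = 1) |>
    dplyr::ungroup() |>
    dplyr::select("ion", x0 = "x", y0 = "y", z0 = "z")
  msd <- tagged |>
    dplyr::left_join(origin, by = "ion") |>
    dplyr::mutate(r2 = 3 * (.data$x - .data$x0)^2) |>
    dplyr::group_by(.data$time_ms) |>
    dplyr::summarise(msd_nm2 = mean(.data$r2), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$time_ms > 0)
  fit <- stats::lm(msd_nm2 ~ 0 + time_ms, data = msd)
  # nm^2/ms -> um^2/s: 1e-6 um^2/nm^2 * 1e3 ms/s
  d <- unname(coef(fit)[1]) / 6 * 1e-3
  list(D_eff_um2s = d, msd = msd, fit = fit)
}

#' Split release events by pathway
#'
#' Histograms and totals per release pathway (synchronous, asynchronous,
#' spontaneous).
#'
#' @param events release events (tibble or `ensemble_result`)
#' @param t_b bin width (ms)
#' @param n_trials ensemble size
#' @param window histogram window (ms)
#' @return a list with `histograms` (tibble with `pathway` column),
#'   `totals` (tibble), `async_sync_ratio`
#' @export
pathway_split <- function(events, t_b = 10, n_trials = NULL, window = NULL) {
  if (is.null(n_trials) && inherits(events, "ensemble_result")) {
    n_trials <- events$n_trials
  }
  ev <- as_events(events)
  if (is.null(window)) window <- c(0, max(c(ev$time_ms, t_b)))
  hists <- purrr::map_dfr(levels(ev$pathway), function(pw) {
    h <- release_histogram(dplyr::filter(ev, .data$pathway == pw),
                           t_b = t_b, n_trials = n_trials, window = window)
    dplyr::mutate(tibble::as_tibble(h), pathway = pw, .before = 1)
  })
  totals <- ev |>
    dplyr::count(.data$pathway, name = "total", .drop = FALSE)
  n_sync <- totals$total[totals$pathway == "synchronous"]
  n_async <- totals$total[totals$pathway == "asynchronous"]
  list(histograms = hists, totals = totals,
       async_sync_ratio = if (length(n_sync) && n_sync > 0) {
         n_async / n_sync
       } else {
         NA_real_
       })
}
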