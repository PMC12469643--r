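# P2 autocorrelation of N-H unit vectors and its multi-exponential reduction.

# P2 ACF of one residue's unit-vector matrix V (n x 3), lags 0..K.
# C(k) = 1.5 * mean_s (v_s . v_{s+k})^2 - 0.5; the squared dot product is a
# sum over the six distinct coordinate products, each of which autocorrelates.
.p2_acf_one <- function(V, K, method) {
  n <- nrow(V)
  npairs <- n - 0:K
  if (method == "fft") {
    # all-origin sums sum_s p_s p_{s+k} of the six product series at once,
    # via zero-padded FFTs (batched over columns)
    P <- cbind(V[, 1]^2, V[, 2]^2, V[, 3]^2,
               V[, 1] * V[, 2], V[, 1] * V[, 3], V[, 2] * V[, 3])
    w <- c(1, 1, 1, 2, 2, 2)
    m <- stats::nextn(2 * n, 2)
    Pz <- rbind(P, matrix(0, m - n, 6))
    Fz <- stats::mvfft(Pz)
    S <- Re(stats::mvfft(Fz * Conj(Fz), inverse = TRUE)) / m
    raw <- as.numeric(S[seq_len(K + 1), , drop = FALSE] %*% w)
  } else {
    raw <- numeric(K + 1)
    for (k in 0:K) {
      d <- rowSums(V[seq_len(n - k), , drop = FALSE] *
                   V[seq_len(n - k) + k, , drop = FALSE])
      raw[k + 1] <- sum(d^2)
    }
  }
  1.5 * raw / npairs - 0.5
}

#' P2 autocorrelation functions of N-H vectors
#'
#' Computes, per residue, the second-Legendre orientational autocorrelation
#' function \eqn{C(t) = \langle P_2(\mu(s)\cdot\mu(s+t))\rangle}, averaged
#' over all time origins \eqn{s}, for lags from 0 to \code{lag_max_ns}.  For
#' an aligned trajectory the long-time plateau of \eqn{C(t)} is the internal
#' order parameter.
#'
#' The default path evaluates every origin explicitly; \code{method = "fft"}
#' computes the same all-origin average through zero-padded FFTs of the six
#' coordinate-product series (identical to the direct path to within
#' round-off, and much faster for long segments).
#'
#' @param vec an \code{nh_vectors} object.
#' @param lag_max_ns maximum lag in ns.  A common choice is 7 x tau_c; the
#'   segment should be at least about 10 x tau_c long for stable averages
#'   (a warning is emitted otherwise when \code{tau_c_ns} is supplied).
#' @param method \code{"direct"} (all origins, explicit) or \code{"fft"}.
#' @param tau_c_ns optional overall correlation time in ns, used only for
#'   the segment-length warning.
#' @return An object of class \code{acf_series}: list with \code{lags_ns},
#'   \code{values} (lags x residues matrix), \code{n_pairs},
#'   \code{residues}, \code{dt_ns}.
#' @export
compute_p2_acf <- function(vec, lag_max_ns, method = c("direct", "fft"),
                           tau_c_ns = NULL) {
  stopifnot(inherits(vec, "nh_vectors"))
  method <- match.arg(method)
  n <- dim(vec$vectors)[1]
  duration <- (n - 1) * vec$dt_ns
  if (lag_max_ns > duration)
    stop("lag_max_ns (", lag_max_ns, ") exceeds segment duration (",
         duration, " ns)")
  if (!is.null(tau_c_ns) && duration < 10 * tau_c_ns)
    warning("segment duration (", duration, " ns) is below 10 x tau_c; ",
            "ACF averages may be unstable")
  K <- floor(lag_max_ns / vec$dt_ns)
  nres <- dim(vec$vectors)[3]
  values <- matrix(NA_real_, K + 1, nres)
  for (j in seq_len(nres))
    values[, j] <- .p2_acf_one(vec$vectors[, , j], K, method)
  structure(list(lags_ns = (0:K) * vec$dt_ns, values = values,
                 n_pairs = n - 0:K, residues = vec$residues,
                 dt_ns = vec$dt_ns),
            class = "acf_series")
}

#' @export
print.acf_series <- function(x, ...) {
  cat(sprintf("P2 ACF: %d residues, %d lags (0..%g ns, dt = %g ns)\n",
              ncol(x$values), length(x$lags_ns), max(x$lags_ns), x$dt_ns))
  invisible(x)
}

# ---- multi-exponential fit --------------------------------------------------

# model C(t) = a0 + sum_j a_j exp(-t / tau_j), amplitudes on the simplex
.mexp_model <- function(lags, a0, a, tau) {
  out <- rep(a0, length(lags))
  for (j in seq_along(a)) out <- out + a[j] * exp(-lags / tau[j])
  out
}

# Fit for a fixed number of exponentials m >= 1.  Amplitudes are
# parameterized by softmax (simplex constraint exact by construction),
# internal times by log; BFGS from deterministic log-spaced initial taus.
.fit_mexp_fixed_m <- function(lags, values, m, n_starts = 3L) {
  stopifnot(m >= 1)
  unpack <- function(theta) {
    u <- theta[seq_len(m + 1)]
    amps <- exp(u - max(u)); amps <- amps / sum(amps)
    list(amps = amps, tau = exp(theta[m + 1 + seq_len(m)]))
  }
  obj <- function(theta) {
    p <- unpack(theta)
    sum((values - .mexp_model(lags, p$amps[1], p$amps[-1], p$tau))^2)
  }
  grad <- function(theta) {
    p <- unpack(theta)
    basis <- cbind(1, exp(-outer(lags, p$tau, `/`)))   # n x (m+1)
    r <- as.numeric(basis %*% p$amps) - values
    g_amp <- as.numeric(crossprod(basis, r))           # dSSE/da_i / 2
    du <- 2 * p$amps * (g_amp - sum(p$amps * g_amp))   # softmax chain rule
    dw <- vapply(seq_len(m), function(j)
      2 * p$amps[j + 1] * sum(r * basis[, j + 1] * lags / p$tau[j]),
      numeric(1))
    c(du, dw)
  }
  span <- range(lags[lags > 0])
  best <- NULL
  plateau <- max(min(mean(values[lags >= 0.75 * max(lags)]), 0.999), 1e-3)
  # time constants beyond the lag window are degenerate with the plateau
  # (exp(-t/tau) ~ 1 on the window), so tau is bounded by the window
  lower <- c(rep(-Inf, m + 1), rep(log(span[1] / 100), m))
  upper <- c(rep(Inf, m + 1), rep(log(span[2]), m))
  for (s in seq_len(n_starts)) {
    # taus log-spaced over [dt, lag_max], shifted per start
    tau0 <- exp(seq(log(span[1]), log(span[2]), length.out = m + 2))[1 + seq_len(m)]
    tau0 <- pmin(tau0 * (0.5 * s), span[2])
    amp0 <- c(plateau, rep((1 - plateau) / m, m))
    theta0 <- c(log(amp0), log(tau0))
    fit <- tryCatch(
      stats::optim(theta0, obj, gr = grad, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 10, maxit = 3000L)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) return(NULL)
  u <- best$par[seq_len(m + 1)]
  amps <- exp(u - max(u)); amps <- amps / sum(amps)
  tau <- exp(best$par[m + 1 + seq_len(m)])
  ord <- order(tau)
  list(a0 = amps[1], a = amps[-1][ord], tau = tau[ord], sse = best$value)
}

.aicc <- function(sse, n, k) {
  aic <- n * log(max(sse, 1e-300) / n) + 2 * k
  if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
}

#' Multi-exponential fit of a P2 autocorrelation function
#'
#' Fits \eqn{C(t) = A_0 + \sum_{j=1}^m A_j e^{-t/\tau_j}} with all
#' amplitudes non-negative and \eqn{A_0 + \sum A_j = 1} (enforced exactly by
#' a simplex parameterization).  The number of exponentials \eqn{m} is
#' selected from \code{0..m_max} by corrected AIC; \eqn{m = 0} is the
#' constant rigid model \eqn{C(t) \equiv 1}.  Initial internal times are
#' log-spaced over the lag range, so the fit is deterministic.
#'
#' @param acf an \code{acf_series} object (all residues are fitted), or a
#'   list with elements \code{lags_ns} and \code{values} (single residue).
#' @param m_max maximum number of exponentials (default 4).
#' @param m_fixed optional fixed \eqn{m}, bypassing model selection (used by
#'   the bootstrap for stability and speed).
#' @param max_points cap on the number of lag points entering the least
#'   squares (default 400); denser ACFs are thinned uniformly (lag 0 always
#'   kept).  The P2 ACF varies over a handful of timescales, so a few
#'   hundred points determine the fit; thinning only speeds it up.
#' @return For a single residue, an object of class \code{multiexp_fit}
#'   (fields \code{a0}, \code{a}, \code{tau_ns}, \code{m}, \code{sse},
#'   \code{aicc}, \code{lags_ns}, \code{values}, \code{fitted}); for an
#'   \code{acf_series} with several residues, a named list of such objects.
#' @export
fit_acf_multiexp <- function(acf, m_max = 4L, m_fixed = NULL,
                             max_points = 400L, n_starts = 3L) {
  if (inherits(acf, "acf_series") && ncol(acf$values) > 1) {
    fits <- lapply(seq_len(ncol(acf$values)), function(j)
      fit_acf_multiexp(list(lags_ns = acf$lags_ns,
                            values = acf$values[, j]),
                       m_max = m_max, m_fixed = m_fixed,
                       max_points = max_points, n_starts = n_starts))
    names(fits) <- as.character(acf$residues)
    return(fits)
  }
  lags <- acf$lags_ns
  values <- if (is.matrix(acf$values)) acf$values[, 1] else acf$values
  if (length(lags) < 10) stop("need at least 10 lag points to fit")
  if (length(lags) > max_points) {
    keep <- unique(c(1L, round(seq(1L, length(lags),
                                   length.out = max_points))))
    lags <- lags[keep]; values <- values[keep]
  }
  cand <- list()
  ms <- if (is.null(m_fixed)) 0:m_max else m_fixed
  for (m in ms) {
    if (m == 0) {
      sse <- sum((values - 1)^2)
      cand[[length(cand) + 1]] <-
        list(a0 = 1, a = numeric(0), tau = numeric(0), sse = sse, m = 0L,
             aicc = .aicc(sse, length(lags), 0))
    } else {
      f <- .fit_mexp_fixed_m(lags, values, m, n_starts = n_starts)
      if (!is.null(f)) {
        f$m <- as.integer(m)
        f$aicc <- .aicc(f$sse, length(lags), 2 * m)
        cand[[length(cand) + 1]] <- f
      }
    }
  }
  if (length(cand) == 0) stop("multi-exponential fit failed for all m")
  best <- cand[[which.min(vapply(cand, `[[`, numeric(1), "aicc"))]]
  structure(list(a0 = best$a0, a = best$a, tau_ns = best$tau, m = best$m,
                 sse = best$sse, aicc = best$aicc,
                 lags_ns = lags, values = values,
                 fitted = .mexp_model(lags, best$a0, best$a, best$tau)),
            class = "multiexp_fit")
}

#' @export
print.multiexp_fit <- function(x, ...) {
  cat(sprintf("Multi-exponential ACF fit (m = %d): A0 = %.4f", x$m, x$a0))
  if (x$m > 0)
    cat(";  ", paste(sprintf("A%d = %.4f (tau = %.3g ns)",
                             seq_along(x$a), x$a, x$tau_ns),
                     collapse = ", "))
  cat(sprintf("\n  SSE = %.3g over %d lags\n", x$sse, length(x$lags_ns)))
  invisible(x)
}

#' @export
coef.multiexp_fit <- function(object, ...) {
  out <- c(a0 = object$a0)
  if (object$m > 0) {
    names_a <- paste0("a", seq_along(object$a))
    names_t <- paste0("tau", seq_along(object$tau_ns), "_ns")
    out <- c(out, stats::setNames(object$a, names_a),
             stats::setNames(object$tau_ns, names_t))
  }
  out
}

#' @export
predict.multiexp_fit <- function(object, newdata = NULL, ...) {
  lags <- if (is.null(newdata)) object$lags_ns else
    if (is.list(newdata)) newdata$lags_ns else newdata
  .mexp_model(lags, object$a0, object$a, object$tau_ns)
}

#' @export
plot.multiexp_fit <- function(x, ...) {
  graphics::plot(x$lags_ns, x$values, pch = 16, cex = 0.4,
                 xlab = "lag (ns)", ylab = "C(t)", ...)
  graphics::lines(x$lags_ns, x$fitted, col = 2, lwd = 2)
  graphics::abline(h = x$a0, lty = 3)
  invisible(x)
}

#' @export
residuals.multiexp_fit <- function(object, ...) object$values - object$fitted

# ---- rates from fits --------------------------------------------------------

#' Back-calculate relaxation rates from ACF fits
#'
#' Converts each residue's multi-exponential ACF fit into a spectral density
#' (internal times combined with the overall tumbling time as
#' \eqn{\tau_j' = \tau_c\tau_j/(\tau_c+\tau_j)}) and evaluates R1, NOE and
#' eta_xy (optionally R2).
#'
#' @param fits a \code{multiexp_fit} or a (named) list of them, as returned
#'   by \code{\link{fit_acf_multiexp}} on an \code{acf_series}.
#' @param tau_c overall rotational correlation time in seconds (typically
#'   the experimental value).
#' @param k an \code{\link{interaction_constants}} object.
#' @param include_r2 also emit R2 (default FALSE).
#' @param j_zero passed to \code{\link{rate_eta_xy}}.
#' @return Data frame with columns \code{residue}, \code{r1}, \code{noe},
#'   \code{eta_xy} (and \code{r2} if requested).
#' @export
backcalc_segment_rates <- function(fits, tau_c, k, include_r2 = FALSE,
                                   j_zero = TRUE) {
  stopifnot(tau_c > 0)
  if (inherits(fits, "multiexp_fit")) fits <- list(`1` = fits)
  res <- names(fits)
  if (is.null(res)) res <- as.character(seq_along(fits))
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    spec <- multiexp_spectrum(a0 = f$a0, a = f$a, tau = f$tau_ns * 1e-9,
                              tau_c = tau_c, normalize_tol = 1e-3)
    r <- relaxation_rates(spec, k, j_zero = j_zero)
    out <- data.frame(residue = suppressWarnings(as.integer(res[i])),
                      r1 = r$r1, noe = r$noe, eta_xy = r$eta_xy)
    if (include_r2) out$r2 <- r$r2
    out
  })
  do.call(rbind, rows)
}

# ---- moving block bootstrap -------------------------------------------------

# resample frame indices as contiguous blocks with replacement
.block_resample_idx <- function(n, block) {
  n_blocks <- ceiling(n / block)
  starts <- sample.int(n - block + 1L, n_blocks, replace = TRUE)
  idx <- unlist(lapply(starts, function(s) s + 0:(block - 1L)))
  idx[seq_len(n)]
}

#' Moving-block bootstrap errors for back-calculated rates
#'
#' Estimates the sampling uncertainty of the trajectory-derived rates by
#' resampling contiguous frame blocks with replacement to the original
#' segment length, recomputing the ACF (FFT path), re-fitting the
#' multi-exponential model (with the per-residue \eqn{m} fixed at the value
#' selected on the full segment), and re-evaluating the rates for each
#' replicate.  Block resampling preserves the time correlation within
#' blocks, which an i.i.d. bootstrap would destroy.
#'
#' @param vec an \code{nh_vectors} object.
#' @param tau_c overall correlation time in seconds.
#' @param k an \code{\link{interaction_constants}} object.
#' @param lag_max_ns maximum ACF lag in ns (also the default block length).
#' @param block_ns block length in ns (default \code{lag_max_ns}); must be
#'   below one fifth of the segment duration.
#' @param n_boot number of bootstrap replicates (default 100).
#' @param seed RNG seed (required, for reproducibility).
#' @param m_max passed to the initial model selection.
#' @param include_r2,j_zero passed to \code{\link{backcalc_segment_rates}}.
#' @return List with \code{rates} (point estimates from the full segment,
#'   as \code{\link{backcalc_segment_rates}}), \code{errors} (data frame of
#'   bootstrap SDs: \code{residue}, \code{r1_err}, \code{noe_err},
#'   \code{eta_xy_err}, ...), and \code{n_boot}.
#' @export
bootstrap_rate_errors <- function(vec, tau_c, k, lag_max_ns,
                                  block_ns = lag_max_ns, n_boot = 100L,
                                  seed, m_max = 4L, include_r2 = FALSE,
                                  j_zero = TRUE) {
  stopifnot(inherits(vec, "nh_vectors"))
  if (missing(seed)) stop("'seed' is required for a reproducible bootstrap")
  n <- dim(vec$vectors)[1]
  duration <- (n - 1) * vec$dt_ns
  block <- max(2L, round(block_ns / vec$dt_ns))
  if (block >= n / 5)
    stop("block length (", block_ns, " ns) must be below one fifth of the ",
         "segment duration (", duration, " ns)")
  acf0 <- compute_p2_acf(vec, lag_max_ns, method = "fft")
  fits0 <- fit_acf_multiexp(acf0, m_max = m_max)
  if (inherits(fits0, "multiexp_fit"))
    fits0 <- stats::setNames(list(fits0), as.character(vec$residues[1]))
  rates0 <- backcalc_segment_rates(fits0, tau_c, k, include_r2 = include_r2,
                                   j_zero = j_zero)
  m_by_res <- vapply(fits0, `[[`, integer(1), "m")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  reps <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    idx <- .block_resample_idx(n, block)
    vb <- vec
    vb$vectors <- vec$vectors[idx, , , drop = FALSE]
    acfb <- compute_p2_acf(vb, lag_max_ns, method = "fft")
    fitsb <- lapply(seq_len(ncol(acfb$values)), function(j)
      fit_acf_multiexp(list(lags_ns = acfb$lags_ns,
                            values = acfb$values[, j]),
                       m_fixed = max(m_by_res[j], 0L), n_starts = 1L))
    names(fitsb) <- as.character(vec$residues)
    reps[[b]] <- backcalc_segment_rates(fitsb, tau_c, k,
                                        include_r2 = include_r2,
                                        j_zero = j_zero)
  }
  cols <- setdiff(names(rates0), "residue")
  errs <- data.frame(residue = rates0$residue)
  for (cl in cols) {
    m <- vapply(reps, function(r) r[[cl]], numeric(nrow(rates0)))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    errs[[paste0(cl, "_err")]] <- apply(m, 1, stats::sd)
  }
  list(rates = rates0, errors = errs, n_boot = n_boot)
}
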