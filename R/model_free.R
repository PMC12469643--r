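#' Per-residue (S2, tau_c) from experimental R1 and eta_xy
#'
#' Inverts the simple Lipari-Szabo forward model for one residue.  Under
#' \eqn{J(\omega) = S^2\tau_c/(1+(\omega\tau_c)^2)} every spectral density is
#' proportional to \eqn{S^2}, so the ratio \eqn{\eta_{xy}/R_1} depends on
#' \eqn{\tau_c} only.  The ratio is inverted by bisection on \eqn{\log\tau_c}
#' over \code{tauc_range} (the ratio is strictly monotone increasing in
#' \eqn{\tau_c} there), after which \eqn{S^2 = R_1 / R_1(\tau_c, S^2{=}1)}.
#'
#' @param r1 experimental R1 in s^-1 (> 0).
#' @param eta_xy experimental eta_xy in s^-1 (> 0).
#' @param k an \code{\link{interaction_constants}} object.
#' @param tauc_range search bracket for tau_c in seconds
#'   (default \code{c(0.5e-9, 100e-9)}).
#' @param tol relative tolerance on tau_c (default 1e-8).
#' @return List with \code{s2}, \code{tau_c} (s), \code{converged} (logical),
#'   and \code{unphysical} (TRUE when the recovered \code{s2} exceeds 1.05).
#'   \code{s2} in (1, 1.05] is returned with a warning; larger values error
#'   control flow only via the flag so that tabulated use can filter.
#' @examples
#' k <- interaction_constants()
#' truth <- model_free_params(s2_fast = 0.85, tau_c = 14.7e-9)
#' fit <- solve_s2_tauc(rate_R1(truth, k), rate_eta_xy(truth, k), k)
#' c(fit$s2, fit$tau_c * 1e9)
#' @export
solve_s2_tauc <- function(r1, eta_xy, k,
                          tauc_range = c(0.5e-9, 100e-9), tol = 1e-8) {
  stopifnot(inherits(k, "interaction_constants"))
  if (!is.finite(r1) || r1 <= 0) stop("'r1' must be positive")
  if (!is.finite(eta_xy) || eta_xy <= 0) stop("'eta_xy' must be positive")
  ratio_model <- function(tc) {
    rigid <- model_free_params(s2_fast = 1, tau_c = tc)
    rate_eta_xy(rigid, k) / rate_R1(rigid, k)
  }
  target <- eta_xy / r1
  lo <- log(tauc_range[1]); hi <- log(tauc_range[2])
  flo <- ratio_model(exp(lo)) - target
  fhi <- ratio_model(exp(hi)) - target
  if (flo * fhi > 0)
    stop("eta_xy/R1 ratio ", signif(target, 4),
         " is outside the range attainable for tau_c in [",
         signif(tauc_range[1] * 1e9, 3), ", ",
         signif(tauc_range[2] * 1e9, 3), "] ns")
  converged <- FALSE
  for (it in seq_len(200L)) {
    mid <- (lo + hi) / 2
    fmid <- ratio_model(exp(mid)) - target
    if (fmid == 0) { lo <- hi <- mid; converged <- TRUE; break }
    if (flo * fmid < 0) { hi <- mid; fhi <- fmid } else { lo <- mid; flo <- fmid }
    if ((hi - lo) < tol) { converged <- TRUE; break }
  }
  tau_c <- exp((lo + hi) / 2)
  s2 <- r1 / rate_R1(model_free_params(s2_fast = 1, tau_c = tau_c), k)
  unphysical <- s2 > 1.05
  if (s2 > 1 + 1e-6 && !unphysical)   # bisection tolerance headroom
    warning(sprintf("recovered S2 = %.3f slightly exceeds 1 (noise)", s2))
  list(s2 = s2, tau_c = tau_c, converged = converged,
       unphysical = unphysical)
}

#' Global rotational correlation time from a relaxation table
#'
#' Applies the per-residue \code{\link{solve_s2_tauc}} inversion to every
#' residue of a relaxation table, selects the rigid subset (recovered
#' \eqn{S^2} above \code{s2_min}, at most 1, and relative experimental errors
#' on both R1 and eta_xy at or below \code{max_rel_err}), and reports the
#' mean and dispersion of \eqn{\tau_c} over that subset.
#'
#' @param rates data frame with columns \code{residue}, \code{r1},
#'   \code{r1_err}, \code{eta_xy}, \code{eta_xy_err} (the standard rates
#'   schema of \code{\link{read_relaxation_table}}; \code{noe} columns are
#'   ignored here).  Missing rates (NA) exclude a residue.
#' @param k an \code{\link{interaction_constants}} object.
#' @param s2_min order-parameter threshold for the rigid set (default 0.8).
#' @param max_rel_err maximum relative experimental error on R1 and eta_xy
#'   (default 0.1); rows with zero rates or NA errors are dropped.
#' @param tauc_range,tol passed to \code{\link{solve_s2_tauc}}.
#' @return An object of class \code{tauc_fit}: list with \code{tau_c_mean},
#'   \code{tau_c_sd}, \code{tau_c_sem} (seconds), \code{n_selected},
#'   \code{selected} (residue ids), and \code{per_residue} (data frame with
#'   \code{residue}, \code{s2}, \code{tau_c_ns}, \code{selected}).
#' @export
estimate_global_tauc <- function(rates, k, s2_min = 0.8, max_rel_err = 0.1,
                                 tauc_range = c(0.5e-9, 100e-9), tol = 1e-8) {
  stopifnot(is.data.frame(rates),
            all(c("residue", "r1", "eta_xy") %in% names(rates)))
  r1_err <- if ("r1_err" %in% names(rates)) rates$r1_err else rep(0, nrow(rates))
  eta_err <- if ("eta_xy_err" %in% names(rates)) rates$eta_xy_err else
    rep(0, nrow(rates))
  n <- nrow(rates)
  s2 <- tau_c <- rep(NA_real_, n)
  ok <- is.finite(rates$r1) & rates$r1 > 0 &
    is.finite(rates$eta_xy) & rates$eta_xy > 0
  for (i in which(ok)) {
    fit <- tryCatch(
      suppressWarnings(solve_s2_tauc(rates$r1[i], rates$eta_xy[i], k,
                                     tauc_range = tauc_range, tol = tol)),
      error = function(e) NULL)
    if (is.null(fit)) { ok[i] <- FALSE; next }
    s2[i] <- fit$s2; tau_c[i] <- fit$tau_c
  }
  rel_ok <- ok &
    is.finite(r1_err) & is.finite(eta_err) &
    (r1_err / rates$r1) <= max_rel_err &
    (eta_err / rates$eta_xy) <= max_rel_err
  selected <- rel_ok & !is.na(s2) & s2 > s2_min & s2 <= 1 + 1e-6
  if (!any(selected))
    stop("no residues pass the S2 > ", s2_min,
         " and relative-error <= ", max_rel_err, " selection")
  tc_sel <- tau_c[selected]
  out <- structure(list(
    tau_c_mean = mean(tc_sel),
    tau_c_sd   = stats::sd(tc_sel),
    tau_c_sem  = stats::sd(tc_sel) / sqrt(sum(selected)),
    n_selected = sum(selected),
    selected   = rates$residue[selected],
    s2_min     = s2_min,
    max_rel_err = max_rel_err,
    per_residue = data.frame(residue = rates$residue,
                             s2 = s2, tau_c_ns = tau_c * 1e9,
                             selected = selected)
  ), class = "tauc_fit")
  out
}

#' @export
print.tauc_fit <- function(x, ...) {
  cat("Global rotational correlation time (simple Lipari-Szabo inversion)\n")
  cat(sprintf("  tau_c = %.2f +/- %.2f ns (SD; SEM %.3f ns)\n",
              x$tau_c_mean * 1e9, x$tau_c_sd * 1e9, x$tau_c_sem * 1e9))
  cat(sprintf("  %d residues selected (S2 > %.2f, rel. err <= %.0f%%)\n",
              x$n_selected, x$s2_min, 100 * x$max_rel_err))
  invisible(x)
}

#' @export
summary.tauc_fit <- function(object, ...) {
  print(object)
  pr <- object$per_residue
  cat("\nPer-residue tau_c over the selected set (ns):\n")
  print(summary(pr$tau_c_ns[pr$selected]))
  invisible(object)
}

#' Relaxation-rate profiles over a (tau_e, S2) grid
#'
#' Computes R1, NOE, R2, and eta_xy surfaces as functions of the internal
#' motion parameters \eqn{\tau_e} and \eqn{S^2 = S^2_{fast} S^2_{slow}}
#' under the extended Lipari-Szabo spectral density, with
#' \eqn{S^2_{fast}} held fixed.  Optionally adds a chemical-exchange offset
#' Rex to R2 to visualize how exchange broadening distorts an R2-based
#' analysis (which is why eta_xy is preferred).
#'
#' @param tau_e numeric vector of internal correlation times (seconds).
#' @param s2 numeric vector of total order parameters
#'   \eqn{S^2 = S^2_{fast} S^2_{slow}}; each must be <= \code{s2_fast}.
#' @param s2_fast fixed fast order parameter (default 0.9).
#' @param tau_c overall correlation time in seconds (default 14.7e-9).
#' @param k an \code{\link{interaction_constants}} object.
#' @param r_ex additive exchange contribution to R2 in s^-1 (default 0).
#' @return Object of class \code{relaxation_profiles}: list of matrices
#'   \code{r1}, \code{noe}, \code{eta_xy}, \code{r2} (rows = tau_e, cols =
#'   s2) plus the grid vectors.
#' @export
relaxation_profile_grid <- function(tau_e, s2, s2_fast = 0.9,
                                    tau_c = 14.7e-9, k, r_ex = 0) {
  stopifnot(length(tau_e) >= 1, length(s2) >= 1)
  if (any(s2 > s2_fast + 1e-12))
    stop("'s2' values must not exceed 's2_fast'")
  dims <- c(length(tau_e), length(s2))
  mats <- list(r1 = matrix(NA_real_, dims[1], dims[2]),
               noe = matrix(NA_real_, dims[1], dims[2]),
               eta_xy = matrix(NA_real_, dims[1], dims[2]),
               r2 = matrix(NA_real_, dims[1], dims[2]))
  for (i in seq_along(tau_e)) for (j in seq_along(s2)) {
    p <- model_free_params(s2_fast = s2_fast, s2_slow = s2[j] / s2_fast,
                           tau_e = tau_e[i], tau_c = tau_c)
    r <- relaxation_rates(p, k)
    mats$r1[i, j] <- r$r1
    mats$noe[i, j] <- r$noe
    mats$eta_xy[i, j] <- r$eta_xy
    mats$r2[i, j] <- r$r2 + r_ex
  }
  structure(c(mats, list(tau_e = tau_e, s2 = s2, s2_fast = s2_fast,
                         tau_c = tau_c, r_ex = r_ex)),
            class = "relaxation_profiles")
}

#' @export
plot.relaxation_profiles <- function(x, which = c("r1", "noe", "eta_xy", "r2"),
                                     ...) {
  which <- match.arg(which, several.ok = TRUE)
  nw <- length(which)
  op <- graphics::par(mfrow = c(if (nw > 2) 2 else 1, ceiling(nw / 2)))
  on.exit(graphics::par(op))
  labs <- c(r1 = "R1 (1/s)", noe = "NOE", eta_xy = "eta_xy (1/s)",
            r2 = "R2 (1/s)")
  for (w in which) {
    graphics::matplot(x$tau_e * 1e9, x[[w]], type = "l", lty = 1,
                      xlab = "tau_e (ns)", ylab = labs[[w]], ...)
  }
  invisible(x)
}
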