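# Comparison of experimental vs back-calculated rate sets and segment ranking.

# residue-matched pairs for one parameter; drops NA on either side
.match_rates <- function(exp, calc, param) {
  stopifnot(param %in% names(exp), param %in% names(calc))
  m <- merge(exp[, c("residue", param,
                     intersect(paste0(param, "_err"), names(exp)))],
             calc[, c("residue", param,
                      intersect(paste0(param, "_err"), names(calc)))],
             by = "residue", suffixes = c("_exp", "_calc"))
  m <- m[is.finite(m[[paste0(param, "_exp")]]) &
         is.finite(m[[paste0(param, "_calc")]]), , drop = FALSE]
  if (nrow(m) == 0) stop("no residues with '", param,
                         "' present in both tables")
  m[order(m$residue), , drop = FALSE]
}

# maximal runs of consecutive residues with |delta/sigma| > threshold
.runs_above <- function(residues, z, threshold) {
  hit <- abs(z) > threshold
  out <- data.frame(start = integer(0), end = integer(0),
                    length = integer(0))
  i <- 1L; n <- length(hit)
  while (i <= n) {
    if (hit[i]) {
      j <- i
      while (j < n && hit[j + 1L] && residues[j + 1L] == residues[j] + 1L)
        j <- j + 1L
      out <- rbind(out, data.frame(start = residues[i], end = residues[j],
                                   length = j - i + 1L))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

#' Per-residue deviations in units of experimental error
#'
#' For residue-matched experimental and back-calculated rates, computes
#' \eqn{\Delta/\sigma} = (calculated - experimental) / error, the yardstick
#' used to judge whether a trajectory segment reproduces a residue's
#' dynamics.  Outliers are summarized as maximal runs of consecutive
#' residues whose \eqn{|\Delta/\sigma|} exceeds 1, 2, and 3 (systematic
#' misfits show up as continuous stretches rather than isolated points).
#'
#' @param exp experimental rates data frame (standard schema with
#'   \code{residue}, \code{<param>}, \code{<param>_err}).
#' @param calc back-calculated rates data frame (same schema; the error
#'   column is optional).
#' @param param which rate to compare: \code{"eta_xy"} (default),
#'   \code{"r1"}, or \code{"noe"}.
#' @param sigma \code{"experimental"} (default) uses the experimental error
#'   alone; \code{"combined"} adds calculated errors in quadrature when
#'   present.
#' @return List with \code{table} (data frame: \code{residue}, \code{exp},
#'   \code{calc}, \code{sigma}, \code{z}), \code{max_abs_z}, and
#'   \code{stretches} (list of run data frames at the 1, 2, 3 sigma levels).
#' @export
delta_in_sigma <- function(exp, calc, param = "eta_xy",
                           sigma = c("experimental", "combined")) {
  sigma <- match.arg(sigma)
  m <- .match_rates(exp, calc, param)
  e <- m[[paste0(param, "_exp")]]
  c_ <- m[[paste0(param, "_calc")]]
  err_exp_col <- paste0(param, "_err_exp")
  err_col <- if (err_exp_col %in% names(m)) err_exp_col else
    paste0(param, "_err")
  if (!err_col %in% names(m))
    stop("experimental table lacks an error column for '", param, "'")
  s <- m[[err_col]]
  if (sigma == "combined") {
    cerr_col <- paste0(param, "_err_calc")
    if (cerr_col %in% names(m)) s <- sqrt(s^2 + m[[cerr_col]]^2)
  }
  usable <- is.finite(s) & s > 0
  if (!any(usable))
    stop("non-positive or missing errors for '", param, "'")
  if (!all(usable)) {
    warning(sum(!usable), " residue(s) dropped from the delta/sigma ",
            "analysis (non-positive or missing error)")
    m <- m[usable, , drop = FALSE]
    e <- e[usable]; c_ <- c_[usable]; s <- s[usable]
  }
  z <- (c_ - e) / s
  tab <- data.frame(residue = m$residue, exp = e, calc = c_,
                    sigma = s, z = z)
  list(table = tab,
       max_abs_z = max(abs(z)),
       stretches = list(`1sigma` = .runs_above(m$residue, z, 1),
                        `2sigma` = .runs_above(m$residue, z, 2),
                        `3sigma` = .runs_above(m$residue, z, 3)))
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples.  For small samples
#' (\code{min(n, m) <= 8}) without ties the exact null distribution of U is
#' used; otherwise the normal approximation with tie and continuity
#' corrections.  The U statistic reported is the number of (x, y) pairs
#' with x > y (plus half the ties).
#'
#' @param x,y numeric samples.
#' @param alternative \code{"two.sided"} (default), \code{"less"}, or
#'   \code{"greater"}.
#' @param exact force (\code{TRUE}) or forbid (\code{FALSE}) the exact
#'   path; \code{NULL} (default) chooses exact when \code{min(n, m) <= 8}
#'   and there are no ties.
#' @return List with \code{U}, \code{p_value}, \code{n}, \code{m}, and
#'   \code{method} ("exact" or "normal approximation").
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided", exact = NULL) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 1 || length(y) < 1) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- if (is.null(exact)) (min(length(x), length(y)) <= 8 && !ties)
               else (exact && !ties)
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = use_exact, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       n = length(x), m = length(y),
       method = if (use_exact) "exact" else "normal approximation")
}

#' Rank candidate trajectory segments against experiment
#'
#' Applies the Mann-Whitney U test to the experimental rate sample versus
#' each segment's back-calculated sample over residue-matched positions
#' (or, with \code{on_deltas = TRUE}, to the per-segment \eqn{\Delta}
#' values against zero-centered reference), computes all pairwise
#' segment-vs-segment p-values, and orders segments by descending p-value:
#' the top segment is the one least distinguishable from experiment.
#'
#' @param exp experimental rates data frame (standard schema).
#' @param calc named list of back-calculated rates data frames, one per
#'   candidate segment.
#' @param param rate to compare (default \code{"eta_xy"}).
#' @param alpha significance level for the accept/reject annotation
#'   (default 0.05).
#' @param on_deltas compare (calc - exp) differences between segments
#'   instead of raw rate samples for the pairwise tests (default FALSE:
#'   raw rate samples, matching how the test is applied to the data sets).
#' @param exact passed to \code{\link{mann_whitney_u}}.
#' @return Object of class \code{segment_ranking}: list with \code{table}
#'   (data frame: \code{segment}, \code{p_value}, \code{U}, \code{n_pairs},
#'   \code{accepted}, in ranked order), \code{pairwise} (matrix of
#'   segment-vs-segment p-values), \code{param}, \code{alpha}.
#' @export
rank_segments <- function(exp, calc, param = "eta_xy", alpha = 0.05,
                          on_deltas = FALSE, exact = NULL) {
  stopifnot(is.list(calc), length(calc) >= 1)
  segs <- names(calc)
  if (is.null(segs)) segs <- paste0("segment_", seq_along(calc))
  per <- lapply(calc, function(cc) .match_rates(exp, cc, param))
  rows <- lapply(seq_along(per), function(i) {
    m <- per[[i]]
    mw <- mann_whitney_u(m[[paste0(param, "_exp")]],
                         m[[paste0(param, "_calc")]], exact = exact)
    data.frame(segment = segs[i], p_value = mw$p_value, U = mw$U,
               n_pairs = nrow(m))
  })
  tab <- do.call(rbind, rows)
  tab$accepted <- tab$p_value > alpha
  tab <- tab[order(-tab$p_value), , drop = FALSE]
  rownames(tab) <- NULL
  pw <- matrix(NA_real_, length(segs), length(segs),
               dimnames = list(segs, segs))
  if (length(segs) > 1) {
    for (i in seq_along(segs)) for (j in seq_along(segs)) {
      if (i >= j) next
      if (on_deltas) {
        mi <- per[[i]]; mj <- per[[j]]
        common <- intersect(mi$residue, mj$residue)
        mi <- mi[mi$residue %in% common, ]
        mj <- mj[mj$residue %in% common, ]
        xi <- mi[[paste0(param, "_calc")]] - mi[[paste0(param, "_exp")]]
        xj <- mj[[paste0(param, "_calc")]] - mj[[paste0(param, "_exp")]]
      } else {
        xi <- per[[i]][[paste0(param, "_calc")]]
        xj <- per[[j]][[paste0(param, "_calc")]]
      }
      p <- mann_whitney_u(xi, xj, exact = exact)$p_value
      pw[i, j] <- pw[j, i] <- p
    }
  }
  structure(list(table = tab, pairwise = pw, param = param, alpha = alpha),
            class = "segment_ranking")
}

#' @export
print.segment_ranking <- function(x, ...) {
  cat(sprintf("Segment ranking on '%s' (Mann-Whitney U, alpha = %g)\n",
              x$param, x$alpha))
  tab <- x$table
  tab$p_value <- signif(tab$p_value, 5)
  print(tab, row.names = FALSE)
  cat("(accepted = experimental and back-calculated sets not",
      "distinguishable at alpha)\n")
  invisible(x)
}
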