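#' Lyman-Kutcher-Burman parameter set
#'
#' One organ's LKB parameters: the uniform whole-organ dose giving a 50%
#' complication probability (`d50`, Gy), the probit slope `m`, and the
#' volume-effect exponent `n_vol` (1 = parallel organ responding to the mean
#' dose, small values = serial organ responding to the near-maximum dose).
#'
#' @param organ organ name.
#' @param d50 dose in Gy (> 0).
#' @param m dimensionless slope (> 0).
#' @param n_vol volume exponent in (0, 1].
#' @return An object of class `lkb_parameters`.
#' @export
lkb_parameters <- function(organ, d50, m, n_vol) {
  if (!is.finite(d50) || d50 <= 0) stop("`d50` must be > 0", call. = FALSE)
  if (!is.finite(m) || m <= 0) stop("`m` must be > 0", call. = FALSE)
  if (!is.finite(n_vol) || n_vol <= 0 || n_vol > 1) {
    stop("`n_vol` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(organ = as.character(organ), d50 = as.numeric(d50),
                 m = as.numeric(m), n_vol = as.numeric(n_vol)),
            class = "lkb_parameters")
}

#' @export
print.lkb_parameters <- function(x, ...) {
  cat(sprintf("<lkb_parameters> %s: D50 = %g Gy, m = %g, n = %g\n",
              x$organ, x$d50, x$m, x$n_vol))
  invisible(x)
}

#' Default LKB parameter table for the pelvic organs at risk
#'
#' Rectum: D50 = 80 Gy, m = 0.15, n = 0.12 (strongly serial).
#' Bladder: D50 = 80 Gy, m = 0.11, n = 0.50.
#'
#' @return named list of [lkb_parameters()].
#' @export
default_lkb_parameters <- function() {
  list(rectum  = lkb_parameters("rectum", d50 = 80, m = 0.15, n_vol = 0.12),
       bladder = lkb_parameters("bladder", d50 = 80, m = 0.11, n_vol = 0.50))
}

#' Generalized equivalent uniform dose (gEUD)
#'
#' Power-mean reduction of the voxel doses inside a structure:
#' `gEUD = ( mean_i d_i^(1/n) )^n`. Computed in log space so that small
#' volume exponents (large powers) do not overflow. For a uniform dose the
#' gEUD equals that dose for every exponent; at `n_vol = 1` it is the mean
#' dose, and as `n_vol -> 0` it approaches the maximum dose.
#'
#' @param dose a [dose_grid()].
#' @param mask non-empty 3-D logical array on the dose geometry.
#' @param n_vol volume exponent in (0, 1].
#' @return gEUD in Gy.
#' @export
geud <- function(dose, mask, n_vol) {
  stopifnot(inherits(dose, "dose_grid"))
  if (!identical(as.integer(dim(mask)), dose$geometry$shape)) {
    stop_geometry_mismatch("dose grid and mask")
  }
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  if (!is.finite(n_vol) || n_vol <= 0 || n_vol > 1) {
    stop("`n_vol` must lie in (0, 1]", call. = FALSE)
  }
  d <- dose$values[mask]
  if (all(d == 0)) return(0)
  a <- log(d) / n_vol               # -Inf for zero-dose voxels
  mx <- max(a)
  exp(n_vol * (mx + log(mean(exp(a - mx)))))
}

#' Lyman-Kutcher-Burman complication probability
#'
#' The standard probit-on-gEUD form:
#' `t = (gEUD - D50) / (m * D50)`, `NTCP = Phi(t)` with `Phi` the standard
#' normal CDF. Returns the intermediates alongside the probability.
#'
#' @param dose accumulated EQD2 [dose_grid()].
#' @param mask non-empty organ mask.
#' @param params an [lkb_parameters()] set.
#' @return An object of class `ntcp_result` with fields `organ`, `geud`,
#'   `t_statistic`, `probability`.
#' @examples
#' d <- uniform_dose_grid(80)
#' m <- array(TRUE, dim(d$values))
#' lkb_ntcp(d, m, default_lkb_parameters()$rectum)$probability  # 0.5
#' @export
lkb_ntcp <- function(dose, mask, params) {
  stopifnot(inherits(params, "lkb_parameters"))
  g <- geud(dose, mask, params$n_vol)
  t_stat <- (g - params$d50) / (params$m * params$d50)
  structure(list(organ = params$organ, geud = g, t_statistic = t_stat,
                 probability = stats::pnorm(t_stat)),
            class = "ntcp_result")
}

#' @export
print.ntcp_result <- function(x, ...) {
  cat(sprintf("<ntcp_result> %s: gEUD = %.2f Gy, t = %.3f, NTCP = %.4g\n",
              x$organ, x$geud, x$t_statistic, x$probability))
  invisible(x)
}

#' Tidy an NTCP result into a one-row tibble
#'
#' @param x an `ntcp_result`.
#' @param ... unused.
#' @export
tidy.ntcp_result <- function(x, ...) {
  tibble::tibble(organ = x$organ, geud_gy = x$geud,
                 t_statistic = x$t_statistic, probability = x$probability)
}

#' Generic tidier (broom-style)
#' @param x object to tidy.
#' @param ... passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Uniform dose giving a target complication probability
#'
#' Root-finds the uniform whole-organ dose at which the LKB model returns the
#' requested probability, running the full gEUD + probit pipeline on a small
#' uniform grid at each iterate. Solving for probability 0.5 recovers D50 for
#' any volume exponent, a self-consistency check of the implementation.
#'
#' @param params an [lkb_parameters()] set.
#' @param probability target NTCP in (0, 1) (default 0.5).
#' @param interval search interval in Gy.
#' @param tol root tolerance in Gy (default 1e-9).
#' @return uniform dose in Gy.
#' @export
lkb_uniform_dose_for <- function(params, probability = 0.5,
                                 interval = c(1, 400), tol = 1e-9) {
  stopifnot(inherits(params, "lkb_parameters"))
  if (probability <= 0 || probability >= 1) {
    stop("`probability` must lie strictly between 0 and 1", call. = FALSE)
  }
  mask <- array(TRUE, c(4, 4, 4))
  f <- function(D) {
    lkb_ntcp(uniform_dose_grid(D, shape = c(4, 4, 4)), mask,
             params)$probability - probability
  }
  stats::uniroot(f, interval = interval, tol = tol)$root
}

#' Compare paired plan metrics with a Wilcoxon signed-rank test
#'
#' For each metric, tests the per-patient paired differences
#' (redesigned - conventional) with a two-sided Wilcoxon signed-rank test
#' (exact for small samples without ties, normal approximation with
#' continuity/tie correction otherwise) and reports the mean difference and
#' a significance flag.
#'
#' @param pairs data frame with columns `metric`, `conventional`,
#'   `redesigned` (one row per patient and metric); a `patient` column is
#'   allowed and ignored.
#' @param alpha significance level (default 0.05).
#' @return A tibble with columns `metric`, `n`, `mean_difference`,
#'   `p_value`, `significant`.
#' @export
compare_plans <- function(pairs, alpha = 0.05) {
  pairs <- as.data.frame(pairs)
  need <- c("metric", "conventional", "redesigned")
  if (!all(need %in% names(pairs))) {
    stop("`pairs` must have columns metric, conventional, redesigned",
         call. = FALSE)
  }
  if (any(!is.finite(pairs$conventional)) || any(!is.finite(pairs$redesigned))) {
    stop("paired values must be finite", call. = FALSE)
  }
  rows <- lapply(split(pairs, pairs$metric), function(df) {
    if (nrow(df) < 2) {
      stop(sprintf("metric '%s' has fewer than 2 pairs", df$metric[1]),
           call. = FALSE)
    }
    diffs <- df$redesigned - df$conventional
    p <- if (all(diffs == 0)) 1 else {
      suppressWarnings(
        stats::wilcox.test(df$redesigned, df$conventional, paired = TRUE,
                           alternative = "two.sided")$p.value)
    }
    tibble::tibble(metric = df$metric[1], n = nrow(df),
                   mean_difference = mean(diffs), p_value = p,
                   significant = p < alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
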