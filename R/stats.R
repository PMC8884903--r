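#' Two-sample Student's t test (pooled or Welch), two-tailed
#'
#' Classic two-group comparison for continuous data. `pooled = TRUE` (the
#' default) is Student's t with the pooled variance estimate and
#' `n_x + n_y - 2` degrees of freedom; `pooled = FALSE` is the
#' unequal-variance (Welch) form with Satterthwaite degrees of freedom.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param pooled Use the pooled-variance form? Default `TRUE`.
#' @return List with `statistic` (t), `df`, `p` (two-tailed), and the group
#'   means. Degenerate case: both variances zero and equal means gives
#'   `t = 0, p = 1`.
#' @export
two_sample_t <- function(x, y, pooled = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each group needs at least 2 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mx == my) {
      return(list(statistic = 0, df = nx + ny - 2, p = 1,
                  mean_x = mx, mean_y = my))
    }
    stop("zero variance in both groups with unequal means: t undefined")
  }
  if (pooled) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  tstat <- (mx - my) / se
  list(statistic = tstat, df = df,
       p = 2 * stats::pt(-abs(tstat), df),
       mean_x = mx, mean_y = my)
}

#' Log-rank test for two survival curves
#'
#' Standard log-rank comparison: at each distinct event time, observed events
#' in group A are compared with the hypergeometric expectation given the
#' numbers at risk; the statistic is (sum O - sum E)^2 / sum V on 1 df. The
#' returned `direction` names the group with the excess of observed over
#' expected events (the worse-surviving group), or `"none"` when O = E.
#'
#' @param times_a,events_a Follow-up times and event indicators (1 = death,
#'   0 = censored) for group A.
#' @param times_b,events_b Same for group B.
#' @return List with `statistic` (chi-square, 1 df), `p`, `direction`
#'   (`"A"`, `"B"`, or `"none"`), and per-group observed/expected events.
#' @export
log_rank <- function(times_a, events_a, times_b, events_b) {
  stopifnot(length(times_a) == length(events_a),
            length(times_b) == length(events_b))
  if (sum(events_a) + sum(events_b) == 0) stop("no events in either group")
  time <- c(times_a, times_b)
  if (any(time <= 0)) stop("times must be positive")
  event <- c(events_a, events_b)
  grp <- factor(rep(c("A", "B"), c(length(times_a), length(times_b))),
                levels = c("A", "B"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  obs <- sd$obs; exp <- sd$exp
  dir <- if (isTRUE(all.equal(obs[1L], exp[1L]))) "none" else
    if (obs[1L] > exp[1L]) "A" else "B"
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(statistic = unname(sd$chisq), p = p, direction = dir,
       observed = unname(obs), expected = unname(exp))
}

#' Split values at their median into high/low arms
#'
#' Values strictly above the median are labelled `"high"`; values at or below
#' the median (including ties at the median) are `"low"`, so the low arm is
#' never the smaller of the two.
#'
#' @param values Numeric vector, length >= 2, not all identical.
#' @return Character vector of `"high"` / `"low"` labels, same length.
#' @export
median_split <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values to split")
  if (anyNA(values)) stop("missing values not allowed")
  med <- stats::median(values)
  if (all(values == values[1L])) stop("all values identical: no split possible")
  ifelse(values > med, "high", "low")
}

#' Relative expression by the 2^-ddCt method
#'
#' qPCR relative quantification: ddCt = (Ct_target,case - Ct_ref,case) -
#' (Ct_target,control - Ct_ref,control), fold change = 2^-ddCt. A ddCt of 2
#' gives fold 0.25, i.e. expression in the case at 25% of the control.
#'
#' @param ct_target_case,ct_ref_case Target and reference-gene cycle
#'   thresholds in the case condition.
#' @param ct_target_ctrl,ct_ref_ctrl Same in the control condition.
#' @return Fold change (numeric). Vectorized over all four arguments.
#' @export
fold_change_ddct <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  args <- cbind(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(args))) stop("Ct values must be finite")
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
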