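#' @name downstream_stats
#' @title Downstream comparison statistics
#'
#' @description
#' Operates on long-format proportion tables with columns `subject`, `visit`
#' (`"pre"`/`"post"`), `stimulation`, `treatment_arm`, `method` (e.g.
#' `"manual"`/`"automated"`), `combo_label`, `proportion`. Background
#' correction subtracts the matched negative-control proportion (no
#' truncation of negative values, preserving the paired-difference symmetry
#' the screening model assumes); screening fits a linear mixed model per
#' combination and tests the visit-by-treatment interaction one-sided with a
#' Bonferroni correction.
NULL

LONG_KEYS <- c("subject", "visit", "stimulation", "treatment_arm",
               "method", "combo_label")

check_long <- function(tbl, need = c(LONG_KEYS, "proportion")) {
  miss <- setdiff(need, names(tbl))
  if (length(miss))
    stop(fcs_condition(paste0("missing column(s): ", paste(miss, collapse = ", ")),
                       "cytogate_schema_error"))
  invisible(tbl)
}

#' Background-correct stimulated proportions
#'
#' Each stimulated row is matched to its negative-control row on
#' (subject, visit, method, combo) and the control proportion subtracted.
#' Control rows are dropped; rows without a control match are excluded with a
#' message. Values may be negative.
#'
#' @param tbl long proportions table (see module description).
#' @param control_stim_label `stimulation` value of the negative control.
#' @return The corrected table (control rows removed).
#' @export
background_correct <- function(tbl, control_stim_label = "negctrl") {
  check_long(tbl)
  ctrl <- tbl[tbl$stimulation == control_stim_label, ]
  stim <- tbl[tbl$stimulation != control_stim_label, ]
  if (!nrow(ctrl))
    stop(fcs_condition(paste0("no control rows with stimulation = ",
                              control_stim_label), "cytogate_schema_error"))
  key <- function(d) paste(d$subject, d$visit, d$method, d$combo_label,
                           sep = "\r")
  ctrl_map <- ctrl$proportion[!duplicated(key(ctrl))]
  names(ctrl_map) <- key(ctrl)[!duplicated(key(ctrl))]
  m <- ctrl_map[key(stim)]
  dropped <- is.na(m)
  if (any(dropped))
    message(sum(dropped), " row(s) without a matched control excluded")
  out <- stim[!dropped, , drop = FALSE]
  out$proportion <- out$proportion - m[!dropped]
  rownames(out) <- NULL
  out
}

#' Paired post-minus-pre differences
#'
#' @param tbl long proportions table with both visits.
#' @return One row per (subject, stimulation, combo, method) with columns
#'   `treatment_arm` and `difference` (post - pre). Unpaired rows are
#'   excluded with a message.
#' @export
paired_difference <- function(tbl) {
  check_long(tbl)
  key <- function(d) paste(d$subject, d$stimulation, d$method, d$combo_label,
                           sep = "\r")
  pre <- tbl[tbl$visit == "pre", ]
  post <- tbl[tbl$visit == "post", ]
  m <- match(key(post), key(pre))
  unpaired <- is.na(m)
  if (any(unpaired))
    message(sum(unpaired), " unpaired post row(s) excluded")
  post <- post[!unpaired, , drop = FALSE]
  data.frame(subject = post$subject, stimulation = post$stimulation,
             combo_label = post$combo_label, method = post$method,
             treatment_arm = post$treatment_arm,
             difference = post$proportion - pre$proportion[m[!unpaired]],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen combinations for a vaccine-induced response
#'
#' Per combination, fits the linear mixed model
#' `proportion ~ visit * treatment_arm + (1 | subject)` (REML) to the
#' background-corrected proportions and tests the visit-by-treatment
#' interaction one-sided (greater than zero, Wald z). P-values are
#' Bonferroni-adjusted over combinations; combinations with adjusted
#' p <= `alpha` are selected. Singular or failed fits are skipped with a
#' message.
#'
#' @param tbl background-corrected long proportions (one `method`, one
#'   `stimulation` at a time is typical; extra strata simply add residual
#'   variance).
#' @param alpha significance level on the adjusted p-value.
#' @return data.frame (`combo_label`, `estimate`, `se`, `p`, `p_adj`,
#'   `selected`), one row per testable combination.
#' @export
screen_subsets <- function(tbl, alpha = 0.05) {
  check_long(tbl)
  if (length(unique(tbl$treatment_arm)) < 2)
    stop(fcs_condition("need >= 2 treatment arms", "cytogate_schema_error"))
  if (length(unique(tbl$visit)) < 2)
    stop(fcs_condition("need both visits", "cytogate_schema_error"))
  combos <- unique(tbl$combo_label)
  rows <- list()
  for (cb in combos) {
    d <- tbl[tbl$combo_label == cb, ]
    d$visit <- factor(d$visit, levels = c("pre", "post"))
    d$treatment_arm <- factor(d$treatment_arm)
    est <- tryCatch({
      fit <- suppressMessages(suppressWarnings(
        lme4::lmer(proportion ~ visit * treatment_arm + (1 | subject),
                   data = d, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore",
                                               calc.derivs = FALSE))))
      co <- summary(fit)$coefficients
      ia <- grep(":", rownames(co), fixed = TRUE)
      if (length(ia) != 1) stop("no unique interaction term")
      c(co[ia, "Estimate"], co[ia, "Std. Error"])
    }, error = function(e) {
      message("combo '", cb, "' skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(est) || !is.finite(est[2]) || est[2] <= 0) next
    z <- est[1] / est[2]
    # t reference with the between-subject df of the interaction contrast
    # (n_subjects - n_arms); a normal reference is anti-conservative enough
    # to double the familywise error at 50 subjects
    df <- max(length(unique(d$subject)) - nlevels(d$treatment_arm), 1)
    rows[[length(rows) + 1]] <- data.frame(
      combo_label = cb, estimate = est[1], se = est[2],
      p = stats::pt(z, df = df, lower.tail = FALSE), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(combo_label = character(0), estimate = numeric(0),
                      se = numeric(0), p = numeric(0), p_adj = numeric(0),
                      selected = logical(0)))
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * length(combos))
  out$selected <- out$p_adj <= alpha
  rownames(out) <- NULL
  out
}

#' Lin's concordance correlation coefficient
#'
#' `rho_c = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (n-denominator) moments. Equals 1 iff `x == y`; symmetric in
#' its arguments.
#'
#' @param x,y equal-length numeric vectors (n >= 3, finite).
#' @return Scalar in `[-1, 1]`.
#' @export
lin_ccc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop(fcs_condition("non-finite values", "cytogate_parameter_error"))
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) return(1)          # both constant at the same value
  if (vx == 0 && vy == 0) return(0)  # both constant, different values
  2 * cxy / denom
}

#' Two-sided paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped. With no ties among the absolute differences
#' and n <= 25 the exact signed-rank distribution is used; otherwise the
#' normal approximation with tie correction and continuity correction.
#' All-zero differences are degenerate and reported as p = 1 with
#' `zero_differences = TRUE`.
#'
#' @param x,y paired numeric vectors.
#' @return List with `p.value`, `statistic` (V, sum of positive ranks), `n`
#'   (non-zero pairs), `exact`, `zero_differences`.
#' @export
paired_wilcoxon <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(p.value = 1, statistic = NA_real_, n = 0L,
                exact = TRUE, zero_differences = TRUE))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (!ties && n <= 25) {
    p <- 2 * min(stats::psignrank(V, n),
                 stats::psignrank(V - 1, n, lower.tail = FALSE))
    p <- min(1, p)
    return(list(p.value = p, statistic = V, n = n, exact = TRUE,
                zero_differences = FALSE))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(p.value = p, statistic = V, n = n, exact = FALSE,
       zero_differences = FALSE)
}
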