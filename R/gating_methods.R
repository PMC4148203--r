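#' @name gating_methods
#' @title Data-driven gate fitters
#'
#' @description
#' Every fitter is a pure function of (data, args, seed): no hidden state,
#' identical output on repeated calls. Density-based fitters share one KDE
#' convention: Gaussian kernel, Silverman's rule-of-thumb bandwidth scaled by
#' `adjust`, evaluated on a 512-point grid, with local extrema detected after
#' 3-point smoothing and ties broken toward smaller x. Fitters operate on
#' parent-population events only; the template engine hands them exactly that.
NULL

KDE_GRID_N <- 512L

density_grid <- function(values, adjust = 1, from = NULL, to = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 50)
    stop(fcs_condition("need at least 50 finite values to fit a density gate",
                       "cytogate_parameter_error"))
  if (is.null(from)) from <- min(values)
  if (is.null(to)) to <- max(values)
  if (from >= to) {
    # degenerate support: widen a hair so density() is defined
    from <- from - 1e-6; to <- to + 1e-6
  }
  d <- stats::density(values, bw = "nrd0", adjust = adjust, n = KDE_GRID_N,
                      from = from, to = to)
  y_s <- as.numeric(stats::filter(d$y, rep(1 / 3, 3), sides = 2))
  y_s[1] <- d$y[1]; y_s[KDE_GRID_N] <- d$y[KDE_GRID_N]
  list(x = d$x, y = d$y, y_smooth = y_s)
}

local_maxima <- function(y, floor_frac = 0) {
  n <- length(y)
  idx <- which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
  if (floor_frac > 0 && length(idx))
    idx <- idx[y[idx] >= floor_frac * max(y[idx])]
  idx
}

local_minima <- function(y) local_maxima(-y)

# modes = local maxima that survive (a) a height floor relative to the
# tallest peak and (b) prominence merging: adjacent peaks whose separating
# valley is shallower than (1 - merge_depth) x the lower peak are one mode
prominent_modes <- function(y, floor_frac = 0.01, merge_depth = 0.05) {
  peaks <- local_maxima(y, floor_frac = floor_frac)
  repeat {
    if (length(peaks) < 2) return(peaks)
    merged <- FALSE
    for (i in seq_len(length(peaks) - 1)) {
      seg <- peaks[i]:peaks[i + 1]
      valley <- min(y[seg])
      lower <- min(y[peaks[i]], y[peaks[i + 1]])
      if (valley > (1 - merge_depth) * lower) {
        drop <- if (y[peaks[i]] <= y[peaks[i + 1]]) i else i + 1
        peaks <- peaks[-drop]
        merged <- TRUE
        break
      }
    }
    if (!merged) return(peaks)
  }
}

#' Minimum-density threshold (valley between the two dominant modes)
#'
#' Fits a kernel density and places the threshold at the density minimum
#' between the two highest local maxima; `[threshold, Inf)` is the positive
#' side.
#'
#' @param values numeric vector (>= 50 finite values), on the transformed
#'   scale.
#' @param gate_range optional length-2 numeric restricting the density grid.
#' @param adjust bandwidth multiplier.
#' @param peak_floor local maxima below this fraction of the tallest peak are
#'   not counted as modes (guards against sampling noise in KDE tails).
#' @return The threshold (numeric scalar).
#' @export
fit_mindensity <- function(values, gate_range = NULL, adjust = 1,
                           peak_floor = 0.01) {
  from <- to <- NULL
  if (!is.null(gate_range)) {
    stopifnot(length(gate_range) == 2)
    from <- min(gate_range); to <- max(gate_range)
  }
  g <- density_grid(values, adjust = adjust, from = from, to = to)
  peaks <- prominent_modes(g$y_smooth, floor_frac = peak_floor)
  if (length(peaks) >= 2) {
    top2 <- peaks[order(-g$y_smooth[peaks], g$x[peaks])][1:2]
    lo <- min(top2); hi <- max(top2)
    seg <- lo:hi
    thr <- g$x[seg[which.min(g$y_smooth[seg])]]
    return(thr)
  }
  # unimodal: fall back to the deepest interior minimum if a range was given
  if (!is.null(gate_range)) {
    mins <- setdiff(local_minima(g$y_smooth), c(1L, KDE_GRID_N))
    if (length(mins))
      return(g$x[mins[which.min(g$y_smooth[mins])]])
  }
  stop(fcs_condition("no valley found: density is unimodal",
                     "cytogate_fit_error"))
}

#' Tail threshold beyond the dominant density peak
#'
#' Walks from the dominant mode toward `side` along the normalised density
#' (peak = 1, support rescaled to unit width) and places the threshold at the
#' first grid point, past the steep shoulder, where the absolute slope falls
#' below `tol`. If the slope never drops below `tol`, the last grid point is
#' used with a warning.
#'
#' @param values numeric vector (>= 50 finite values).
#' @param tol slope tolerance on the normalised density (scale-free).
#' @param side `"right"` or `"left"`; the positive side is beyond the
#'   threshold.
#' @param adjust bandwidth multiplier.
#' @return The threshold (numeric scalar).
#' @export
fit_tailgate <- function(values, tol = 0.01, side = c("right", "left"),
                         adjust = 1) {
  side <- match.arg(side)
  if (side == "left")
    return(-tailgate_right(-values, tol = tol, adjust = adjust))
  tailgate_right(values, tol = tol, adjust = adjust)
}

# rightward walk: past the steep shoulder (directional slope <= -tol), stop at
# the first grid point where the descent has flattened (slope > -tol); this
# also stops at a density minimum before any secondary bump starts rising
tailgate_right <- function(values, tol, adjust) {
  g <- density_grid(values, adjust = adjust)
  y <- g$y_smooth / max(g$y_smooth)
  xn <- (g$x - g$x[1]) / (g$x[KDE_GRID_N] - g$x[1])
  slope <- c(diff(y) / diff(xn), 0)
  peak <- which.max(y)
  passed_steep <- FALSE
  for (i in seq(peak, KDE_GRID_N)) {
    if (slope[i] <= -tol) passed_steep <- TRUE
    else if (passed_steep) return(g$x[i])
  }
  warning("tailgate: slope never fell below tolerance; threshold at data edge")
  g$x[KDE_GRID_N]
}

#' Empirical quantile threshold
#'
#' @param values non-empty numeric vector.
#' @param probs probability in (0, 1]; linear-interpolation (type 7) quantile.
#' @return The threshold; the positive side is above it.
#' @export
fit_quantile_gate <- function(values, probs = 0.99) {
  if (!length(values)) stop("empty values", call. = FALSE)
  if (!is.numeric(probs) || length(probs) != 1 || probs <= 0 || probs > 1)
    stop(fcs_condition("probs must lie in (0, 1]", "cytogate_parameter_error"))
  unname(stats::quantile(values, probs = probs, type = 7, names = FALSE))
}

# iteratively reweighted least squares for the least-absolute-deviations line
lad_line <- function(x, y, iters = 30L) {
  if (stats::var(x) == 0)
    stop(fcs_condition("zero variance in x: cannot fit a line",
                       "cytogate_fit_error"))
  w <- rep(1, length(x))
  a <- b <- 0
  for (i in seq_len(iters)) {
    fit <- stats::lm.wfit(cbind(1, x), y, w)
    a_new <- fit$coefficients[1]; b_new <- fit$coefficients[2]
    r <- abs(y - a_new - b_new * x)
    w <- 1 / pmax(r, 1e-8)
    if (is.finite(a) && abs(a_new - a) + abs(b_new - b) < 1e-10) {
      a <- a_new; b <- b_new; break
    }
    a <- a_new; b <- b_new
  }
  c(intercept = unname(a), slope = unname(b))
}

#' Singlet gate in the area-height plane
#'
#' Singlets fall on a line of height against area; doublets show inflated area
#' at a given height. A least-absolute-deviations line is fitted and events
#' within `band` MADs of the residual spread are kept, as a parallelogram
#' spanning the observed area range.
#'
#' @param area,height paired numeric vectors (>= 100 events).
#' @param band half-width of the parallelogram in MADs of the residuals.
#' @param ch_area,ch_height channel names recorded in the gate.
#' @return A [polygon_gate()].
#' @export
fit_singlet_gate <- function(area, height, band = 2.5,
                             ch_area = "FSC-A", ch_height = "FSC-H") {
  stopifnot(length(area) == length(height))
  if (length(area) < 100)
    stop(fcs_condition("need >= 100 events for a singlet gate",
                       "cytogate_parameter_error"))
  co <- lad_line(area, height)
  resid <- height - co["intercept"] - co["slope"] * area
  hw <- band * max(stats::mad(resid), 1e-8 * max(abs(height), 1), 1e-12)
  xr <- range(area)
  xr <- xr + c(-1, 1) * 1e-9 * max(diff(xr), 1)  # keep edge events inside
  ylo <- co["intercept"] + co["slope"] * xr - hw
  yhi <- co["intercept"] + co["slope"] * xr + hw
  polygon_gate(ch_area, ch_height,
               rbind(c(xr[1], ylo[1]), c(xr[2], ylo[2]),
                     c(xr[2], yhi[2]), c(xr[1], yhi[1])))
}

#' Boundary-event removal gate
#'
#' Excludes events at or beyond the supplied instrument limits (events pinned
#' at a detector's minimum or maximum). A side without a supplied limit is
#' unbounded. The returned rectangle is strictly inside `[min, max]` in each
#' gated dimension.
#'
#' @param events an [event_matrix()] (used for the exclusion margin scale).
#' @param dims one or two channel names.
#' @param min,max named (or positionally matched) numeric limits per dim;
#'   `NULL` leaves that side open.
#' @return A [rectangle_gate()] (second dim unbounded if only one dim given).
#' @export
fit_boundary_gate <- function(events, dims, min = NULL, max = NULL) {
  stopifnot(length(dims) %in% 1:2)
  get_lim <- function(lim, i) {
    if (is.null(lim)) return(NULL)
    if (!is.null(names(lim)) && dims[i] %in% names(lim)) return(lim[[dims[i]]])
    if (length(lim) >= i) return(lim[[i]])
    NULL
  }
  bounds <- lapply(1:2, function(i) {
    if (i > length(dims)) return(c(-Inf, Inf))
    lo <- get_lim(min, i); hi <- get_lim(max, i)
    x <- events$events[, dims[i]]
    span <- base::max(abs(unlist(c(lo, hi, if (length(x)) range(x)))), 1)
    eps <- base::max(1e-9 * span, 1e-12)
    c(if (is.null(lo)) -Inf else lo + eps,
      if (is.null(hi)) Inf else hi)  # [*, hi) is half-open: pinned-at-hi excluded
  })
  if (any(vapply(bounds, function(b) b[1] >= b[2], logical(1))))
    stop(fcs_condition("boundary limits: min >= max", "cytogate_parameter_error"))
  rectangle_gate(dims[1], if (length(dims) == 2) dims[2] else dims[1],
                 xmin = bounds[[1]][1], xmax = bounds[[1]][2],
                 ymin = bounds[[2]][1], ymax = bounds[[2]][2])
}

# ---- bivariate Gaussian mixture by EM ---------------------------------------

dmvnorm2 <- function(x, mean, sigma) {
  det_s <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2] * sigma[2, 1]
  if (det_s <= 1e-300) return(rep(NA_real_, nrow(x)))
  inv <- matrix(c(sigma[2, 2], -sigma[1, 2], -sigma[2, 1], sigma[1, 1]),
                2, 2) / det_s
  d <- sweep(x, 2, mean)
  q <- rowSums((d %*% inv) * d)
  exp(-0.5 * q) / (2 * pi * sqrt(det_s))
}

em_gmm2d <- function(x, K, seed, max_iter = 200L, tol = 1e-8) {
  n <- nrow(x)
  set.seed(seed)
  km <- stats::kmeans(x, centers = K, nstart = 5, iter.max = 50)
  means <- km$centers
  covs <- lapply(seq_len(K), function(k) {
    xs <- x[km$cluster == k, , drop = FALSE]
    if (nrow(xs) < 3) return(diag(2) * stats::var(as.vector(x)))
    stats::cov(xs) + diag(2) * 1e-6
  })
  w <- as.numeric(table(factor(km$cluster, levels = seq_len(K)))) / n
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(K), function(k)
      w[k] * dmvnorm2(x, means[k, ], covs[[k]]), numeric(n))
    if (anyNA(dens)) return(NULL)  # degenerate covariance -> caller restarts
    tot <- rowSums(dens)
    if (any(tot <= 0)) tot[tot <= 0] <- 1e-300
    ll <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    if (any(nk < 3)) return(NULL)
    w <- nk / n
    for (k in seq_len(K)) {
      mu <- colSums(resp[, k] * x) / nk[k]
      d <- sweep(x, 2, mu)
      covs[[k]] <- crossprod(d * resp[, k], d) / nk[k] + diag(2) * 1e-9
      means[k, ] <- mu
    }
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(weights = w, means = means, covs = covs, loglik = ll)
}

#' Ellipse gate from a bivariate Gaussian mixture
#'
#' Fits a K-component bivariate Gaussian mixture by EM (k-means
#' initialisation, 10 seeded restarts, best log-likelihood kept) and returns
#' the chi-square `level` ellipse of the component whose mean is nearest
#' `target` (or the largest-weight component when no target is given). This is
#' a Gaussian stand-in for t-mixture model-based gating; heavy tails are not
#' modelled.
#'
#' @param events an [event_matrix()] (>= 200 events).
#' @param dims two channel names.
#' @param K number of mixture components.
#' @param target optional length-2 mode hint on the transformed scale.
#' @param level ellipse coverage level.
#' @param seed integer seed (fit is deterministic given data, args, seed).
#' @param restarts EM restarts.
#' @return An [ellipse_gate()].
#' @export
fit_mixture_gate <- function(events, dims, K = 2, target = NULL, level = 0.95,
                             seed = 1, restarts = 10L) {
  x <- events$events[, dims, drop = FALSE]
  if (nrow(x) < 200)
    stop(fcs_condition("need >= 200 events for a mixture gate",
                       "cytogate_parameter_error"))
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- em_gmm2d(x, K, seed = (seed * 131L + r) %% .Machine$integer.max)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  if (is.null(best))
    stop(fcs_condition("EM failed in all restarts (degenerate covariance)",
                       "cytogate_fit_error"))
  pick <- if (!is.null(target)) {
    which.min(colSums((t(best$means) - target)^2))
  } else which.max(best$weights)
  ellipse_gate(dims[1], dims[2], center = best$means[pick, ],
               covariance = best$covs[[pick]], level = level)
}

#' Copy a fitted gate onto other samples
#'
#' The reference-gate idiom: a gate fitted on a source sample (e.g. the 99th
#' percentile of expression in a non-stimulated control) is applied verbatim
#' (optionally shifted) to related samples.
#'
#' @param source_gate the fitted `Gate`.
#' @param offsets optional numeric shift(s): a scalar for threshold gates, a
#'   length-2 `c(x, y)` shift for 2-D gates.
#' @return A `Gate` of the same variant.
#' @export
ref_gate <- function(source_gate, offsets = NULL) {
  stopifnot(inherits(source_gate, "Gate"))
  if (is.null(offsets)) return(source_gate)
  g <- source_gate
  switch(class(g)[1],
    gate_threshold = {
      g$min <- g$min + offsets[1]; g$max <- g$max + offsets[1]
    },
    gate_rectangle = {
      o <- rep(offsets, length.out = 2)
      g$xmin <- g$xmin + o[1]; g$xmax <- g$xmax + o[1]
      g$ymin <- g$ymin + o[2]; g$ymax <- g$ymax + o[2]
    },
    gate_polygon = {
      o <- rep(offsets, length.out = 2)
      g$vertices <- sweep(g$vertices, 2, -o)
    },
    gate_ellipse = {
      g$center <- g$center + rep(offsets, length.out = 2)
    },
    stop("cannot offset this gate variant", call. = FALSE))
  g
}

# per-channel cuts for the DNA-DNA gate: lower and upper valleys around the
# dominant (singlet) peak
density_cuts <- function(values, adjust = 1) {
  g <- density_grid(values, adjust = adjust)
  peaks <- prominent_modes(g$y_smooth, floor_frac = 0.01)
  dominant <- peaks[which.max(g$y_smooth[peaks])]
  below <- peaks[peaks < dominant]; above <- peaks[peaks > dominant]
  # cut at the valley separating the dominant mode from its nearest
  # prominent neighbour on each side; no neighbour -> keep the data edge
  lo <- if (length(below)) {
    seg <- max(below):dominant
    g$x[seg[which.min(g$y_smooth[seg])]]
  } else g$x[1] - 1e-9
  hi <- if (length(above)) {
    seg <- dominant:min(above)
    g$x[seg[which.min(g$y_smooth[seg])]]
  } else g$x[KDE_GRID_N] + 1e-9
  c(lo = lo, hi = hi)
}

#' DNA-DNA singlet gate for mass cytometry
#'
#' The CyTOF analogue of a scatter singlet gate. Cell events sit in a tight
#' diagonal cloud in the two DNA intercalator channels; debris/background
#' falls below it and doublets above (roughly doubled DNA signal). Each DNA
#' channel is cut at the density valleys below and above its dominant peak,
#' and within that box a least-absolute-deviations diagonal band of half-width
#' `band` MADs keeps the singlet cloud.
#'
#' @param dna1,dna2 paired DNA channel intensities (transformed scale).
#' @param band diagonal band half-width in MADs of the fit residuals.
#' @param ch_dna1,ch_dna2 channel names recorded in the gate.
#' @param adjust KDE bandwidth multiplier for the per-channel cuts.
#' @return A [polygon_gate()] (diagonal band clipped to the valley box).
#' @export
fit_dna_gate <- function(dna1, dna2, band = 3,
                         ch_dna1 = "DNA1", ch_dna2 = "DNA2", adjust = 1) {
  stopifnot(length(dna1) == length(dna2))
  cut1 <- density_cuts(dna1, adjust); cut2 <- density_cuts(dna2, adjust)
  core <- dna1 >= cut1["lo"] & dna1 < cut1["hi"] &
          dna2 >= cut2["lo"] & dna2 < cut2["hi"]
  if (sum(core) < 100)
    stop(fcs_condition("too few events in the DNA core cloud",
                       "cytogate_fit_error"))
  co <- lad_line(dna1[core], dna2[core])
  resid <- dna2[core] - co["intercept"] - co["slope"] * dna1[core]
  hw <- band * max(stats::mad(resid), 1e-12)
  x1 <- cut1["lo"]; x2 <- cut1["hi"]
  ylo <- co["intercept"] + co["slope"] * c(x1, x2) - hw
  yhi <- co["intercept"] + co["slope"] * c(x1, x2) + hw
  verts <- rbind(c(x1, ylo[1]), c(x2, ylo[2]), c(x2, yhi[2]), c(x1, yhi[1]))
  verts <- clip_polygon_halfplane(verts, 0, -1, -cut2["lo"])   # y >= lo2
  verts <- clip_polygon_halfplane(verts, 0, 1, cut2["hi"])     # y <= hi2
  if (nrow(verts) < 3)
    stop(fcs_condition("DNA gate degenerated to an empty region",
                       "cytogate_fit_error"))
  polygon_gate(ch_dna1, ch_dna2, verts)
}

# ---- plug-in registry --------------------------------------------------------

.fitters <- new.env(parent = emptyenv())

#' Register a gating method plug-in
#'
#' Registered methods are resolvable from a template's `gating_method` column.
#' A fitter is called as `fit(events, dims, args, seed)` where `events` is the
#' parent-population [event_matrix()]; for `arity = 1` with sign expansion it
#' must return a single numeric threshold per dim (see
#' [apply_template()]), otherwise a `Gate`.
#'
#' @param name method name (template `gating_method` value).
#' @param fitter function `(events, dims, args, seed) -> Gate | numeric`.
#' @param arity 1 or 2 (number of dims the method consumes).
#' @param threshold does the method yield per-dim thresholds that support
#'   `+/-` sign expansion?
#' @param override allow replacing an existing registration.
#' @return The method name, invisibly.
#' @export
register_plugin <- function(name, fitter, arity = 1, threshold = arity == 1,
                            override = FALSE) {
  stopifnot(is.function(fitter), arity %in% 1:2)
  if (!override && exists(name, envir = .fitters))
    stop(fcs_condition(paste0("gating method already registered: ", name),
                       "cytogate_schema_error"))
  assign(name, list(fit = fitter, arity = arity, threshold = threshold),
         envir = .fitters)
  invisible(name)
}

#' Names of registered gating methods
#' @return Character vector.
#' @export
list_gating_methods <- function() sort(ls(.fitters))

get_fitter <- function(name) {
  if (!exists(name, envir = .fitters))
    stop(fcs_condition(paste0("unknown gating method: ", name),
                       "cytogate_schema_error"))
  get(name, envir = .fitters)
}

arg_or <- function(args, name, default) {
  if (!is.null(args[[name]])) args[[name]] else default
}

register_builtin_methods <- function() {
  reg <- function(...) register_plugin(..., override = TRUE)
  reg("mindensity", function(events, dims, args, seed) {
    vapply(dims, function(d) fit_mindensity(
      events$events[, d],
      gate_range = args$gate_range,
      adjust = arg_or(args, "adjust", 1),
      peak_floor = arg_or(args, "peak_floor", 0.01)), numeric(1))
  }, arity = 1, threshold = TRUE)
  reg("tailgate", function(events, dims, args, seed) {
    vapply(dims, function(d) fit_tailgate(
      events$events[, d],
      tol = arg_or(args, "tol", 0.01),
      side = arg_or(args, "side", "right"),
      adjust = arg_or(args, "adjust", 1)), numeric(1))
  }, arity = 1, threshold = TRUE)
  reg("quantileGate", function(events, dims, args, seed) {
    vapply(dims, function(d) fit_quantile_gate(
      events$events[, d], probs = arg_or(args, "probs", 0.99)), numeric(1))
  }, arity = 1, threshold = TRUE)
  reg("singletGate", function(events, dims, args, seed) {
    fit_singlet_gate(events$events[, dims[1]], events$events[, dims[2]],
                     band = arg_or(args, "wider_gate_band", 2.5),
                     ch_area = dims[1], ch_height = dims[2])
  }, arity = 2, threshold = FALSE)
  reg("boundary", function(events, dims, args, seed) {
    fit_boundary_gate(events, dims, min = args$min, max = args$max)
  }, arity = 2, threshold = FALSE)
  reg("flowClust2d", function(events, dims, args, seed) {
    target <- if (!is.null(args$target_x))
      c(args$target_x, args$target_y) else NULL
    fit_mixture_gate(events, dims, K = arg_or(args, "K", 2), target = target,
                     level = arg_or(args, "level", 0.95), seed = seed)
  }, arity = 2, threshold = FALSE)
  reg("dnaGate", function(events, dims, args, seed) {
    fit_dna_gate(events$events[, dims[1]], events$events[, dims[2]],
                 band = arg_or(args, "band", 3),
                 ch_dna1 = dims[1], ch_dna2 = dims[2],
                 adjust = arg_or(args, "adjust", 1))
  }, arity = 2, threshold = FALSE)
  # refGate is dispatched specially by the template engine (deferred source);
  # registered here so templates validate, with threshold semantics.
  reg("refGate", function(events, dims, args, seed) {
    stop("refGate is resolved by the template engine", call. = FALSE)
  }, arity = 1, threshold = TRUE)
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_methods()
}
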