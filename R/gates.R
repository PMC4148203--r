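#' @name gates
#' @title Gate geometries
#'
#' @description
#' A gate selects events by a region in one or two channels. Threshold and
#' rectangle gates use half-open intervals `[min, max)` so that the `+` and `-`
#' partitions of a marker are exactly disjoint and exhaustive, which makes the
#' `2^k` Boolean subset counts sum to the parent count. Polygon membership uses
#' the even-odd rule with boundary points counted inside; ellipse membership is
#' a Mahalanobis ball at the bivariate chi-square quantile of `level`.
NULL

#' One-dimensional threshold gate
#' @param channel channel name.
#' @param min,max half-open interval bounds `[min, max)`; either may be
#'   infinite.
#' @return A `Gate` of variant `gate_threshold`.
#' @export
threshold_gate <- function(channel, min = -Inf, max = Inf) {
  stopifnot(is.character(channel), length(channel) == 1, min < max)
  structure(list(channel = channel, min = min, max = max),
            class = c("gate_threshold", "Gate"))
}

#' Two-dimensional rectangle gate (half-open per dimension)
#' @param ch_x,ch_y channel names.
#' @param xmin,xmax,ymin,ymax bounds; membership is `[min, max)` in each dim.
#' @return A `Gate` of variant `gate_rectangle`.
#' @export
rectangle_gate <- function(ch_x, ch_y, xmin = -Inf, xmax = Inf,
                           ymin = -Inf, ymax = Inf) {
  stopifnot(xmin < xmax, ymin < ymax)
  structure(list(ch_x = ch_x, ch_y = ch_y, xmin = xmin, xmax = xmax,
                 ymin = ymin, ymax = ymax),
            class = c("gate_rectangle", "Gate"))
}

#' Polygon gate
#' @param ch_x,ch_y channel names.
#' @param vertices numeric matrix (>= 3 rows, 2 columns) of polygon vertices.
#' @return A `Gate` of variant `gate_polygon`.
#' @export
polygon_gate <- function(ch_x, ch_y, vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3)
  if (polygon_area(vertices) <= 0)
    stop("polygon must have positive area", call. = FALSE)
  structure(list(ch_x = ch_x, ch_y = ch_y, vertices = vertices),
            class = c("gate_polygon", "Gate"))
}

polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(seq_len(nrow(v))[-1], 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Ellipse gate
#' @param ch_x,ch_y channel names.
#' @param center length-2 numeric center.
#' @param covariance 2x2 symmetric positive-definite matrix.
#' @param level coverage level in (0, 1); membership is Mahalanobis distance
#'   squared `<= qchisq(level, df = 2)`.
#' @return A `Gate` of variant `gate_ellipse`.
#' @export
ellipse_gate <- function(ch_x, ch_y, center, covariance, level = 0.95) {
  covariance <- as.matrix(covariance)
  stopifnot(length(center) == 2, all(dim(covariance) == 2),
            level > 0, level < 1)
  if (max(abs(covariance - t(covariance))) > 1e-8)
    stop("covariance must be symmetric", call. = FALSE)
  if (any(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("covariance must be positive-definite", call. = FALSE)
  structure(list(ch_x = ch_x, ch_y = ch_y, center = as.numeric(center),
                 covariance = covariance, level = level),
            class = c("gate_ellipse", "Gate"))
}

#' Boolean combination gate
#'
#' @param expression character expression over population paths or names using
#'   `&`, `|`, `!` and parentheses, e.g. `"cd4/IFNg+ & !cd4/IL2+"`. Evaluated
#'   against a gating set's cached index vectors, restricted to the declared
#'   parent.
#' @return A `Gate` of variant `gate_boolean`.
#' @export
boolean_gate <- function(expression) {
  stopifnot(is.character(expression), length(expression) == 1)
  structure(list(expression = expression),
            class = c("gate_boolean", "Gate"))
}

#' @export
print.Gate <- function(x, ...) {
  cat("<", class(x)[1], "> ", sep = "")
  utils::str(unclass(x), give.attr = FALSE, indent.str = "  ")
  invisible(x)
}

gate_channels <- function(gate) {
  switch(class(gate)[1],
         gate_threshold = gate$channel,
         gate_boolean = character(0),
         c(gate$ch_x, gate$ch_y))
}

#' Evaluate a gate against a sample's events
#'
#' @param gate a `Gate` (boolean gates need a gating-set context and are
#'   rejected here; see [boolean_gate_eval()]).
#' @param events an [event_matrix()].
#' @return Logical vector with one entry per event.
#' @export
apply_gate <- function(gate, events) {
  stopifnot(inherits(gate, "Gate"), inherits(events, "EventMatrix"))
  miss <- setdiff(gate_channels(gate), events$channels)
  if (length(miss))
    stop(fcs_condition(paste0("gate channel not in sample: ",
                              paste(miss, collapse = ", ")),
                       "cytogate_schema_error"))
  UseMethod("apply_gate")
}

#' @export
apply_gate.gate_threshold <- function(gate, events) {
  x <- events$events[, gate$channel]
  x >= gate$min & x < gate$max
}

#' @export
apply_gate.gate_rectangle <- function(gate, events) {
  x <- events$events[, gate$ch_x]
  y <- events$events[, gate$ch_y]
  x >= gate$xmin & x < gate$xmax & y >= gate$ymin & y < gate$ymax
}

#' @export
apply_gate.gate_polygon <- function(gate, events) {
  pts <- events$events[, c(gate$ch_x, gate$ch_y), drop = FALSE]
  points_in_polygon(pts[, 1], pts[, 2], gate$vertices)
}

#' @export
apply_gate.gate_ellipse <- function(gate, events) {
  pts <- events$events[, c(gate$ch_x, gate$ch_y), drop = FALSE]
  d <- stats::mahalanobis(pts, center = gate$center, cov = gate$covariance)
  d <= stats::qchisq(gate$level, df = 2)
}

#' @export
apply_gate.gate_boolean <- function(gate, events) {
  stop(fcs_condition("boolean gates are evaluated within a GatingSet",
                     "cytogate_state_error"))
}

# Even-odd crossing test, vectorised over points; points on an edge or vertex
# count as inside (checked to a relative tolerance before the crossing test).
points_in_polygon <- function(px, py, vertices) {
  n <- length(px)
  if (n == 0) return(logical(0))
  vx <- vertices[, 1]; vy <- vertices[, 2]
  m <- length(vx)
  inside <- logical(n)
  on_edge <- logical(n)
  scale <- max(abs(vertices), 1)
  eps <- 1e-12 * scale
  j <- m
  for (i in seq_len(m)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # boundary: collinear with segment and within its bounding box
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    seg_len2 <- (x2 - x1)^2 + (y2 - y1)^2
    on_seg <- abs(cross) <= eps * max(sqrt(seg_len2), 1) &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    on_edge <- on_edge | on_seg
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside | on_edge
}

# Sutherland-Hodgman clip of a convex/simple polygon against the half-plane
# a*x + b*y <= c. Used by the DNA-DNA gate construction.
clip_polygon_halfplane <- function(vertices, a, b, c) {
  n <- nrow(vertices)
  out <- matrix(numeric(0), ncol = 2)
  val <- a * vertices[, 1] + b * vertices[, 2] - c
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    p <- vertices[i, ]; q <- vertices[j, ]
    pin <- val[i] <= 0; qin <- val[j] <= 0
    if (pin) out <- rbind(out, p)
    if (xor(pin, qin)) {
      t <- val[i] / (val[i] - val[j])
      out <- rbind(out, p + t * (q - p))
    }
  }
  out
}
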