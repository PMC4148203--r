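test_that("mindensity finds the valley of a balanced two-mode mixture", {
  set.seed(20)
  v <- c(rnorm(2500), rnorm(2500, 6))
  thr <- fit_mindensity(v)
  # fine-grid density oracle for the true valley near 3
  grid <- seq(1, 5, length.out = 20001)
  oracle <- grid[which.min(0.5 * dnorm(grid) + 0.5 * dnorm(grid, 6))]
  expect_gt(thr, 2.5); expect_lt(thr, 3.5)
  expect_lt(abs(thr - oracle), 0.5)
  # two point-masses with jitter separate cleanly
  v2 <- c(rnorm(2500, 0, 0.01), rnorm(2500, 10, 0.01))
  thr2 <- fit_mindensity(v2)
  expect_gt(thr2, 0); expect_lt(thr2, 10)
})

test_that("mindensity errors on unimodal data unless gate_range rescues it", {
  set.seed(21)
  v <- rnorm(5000)
  expect_error(fit_mindensity(v), class = "cytogate_fit_error")
  expect_error(fit_mindensity(rnorm(10)), class = "cytogate_parameter_error")
  # thresholds always lie within the data range
  set.seed(22)
  for (i in 1:5) {
    v <- c(rnorm(1000, 0), rnorm(1000, 4 + i))
    thr <- fit_mindensity(v)
    expect_gt(thr, min(v)); expect_lt(thr, max(v))
  }
})

test_that("tailgate isolates a rare positive tail", {
  set.seed(23)
  v <- c(rnorm(19800), rnorm(200, 5))
  thr <- fit_tailgate(v)
  expect_gt(thr, 1.5); expect_lt(thr, 4.5)
  expect_gte(mean(v[19801:20000] > thr), 0.9)
  # pure unimodal: threshold beyond the mode
  expect_gt(fit_tailgate(rnorm(5000)), 1)
  # tolerance monotonicity on fixed data
  expect_lte(fit_tailgate(v, tol = 0.1), fit_tailgate(v, tol = 0.001))
  # left side mirrors right
  expect_equal(fit_tailgate(-v, side = "left"), -fit_tailgate(v))
})

test_that("quantile gate matches hand-computable quantiles", {
  expect_identical(fit_quantile_gate(as.numeric(1:101), 0.5), 51)
  expect_identical(fit_quantile_gate(as.numeric(1:10), 1), 10)
  set.seed(24)
  u <- runif(100000)
  expect_lt(abs(fit_quantile_gate(u, 0.99) - 0.99), 0.005)
  expect_error(fit_quantile_gate(u, 0), class = "cytogate_parameter_error")
  expect_error(fit_quantile_gate(u, 1.1), class = "cytogate_parameter_error")
})

test_that("singlet gate keeps collinear events and rejects doublets", {
  set.seed(25)
  n <- 10000
  area <- runif(n, 10, 100)
  height <- 0.9 * area
  g <- fit_singlet_gate(area, height, ch_area = "a", ch_height = "h")
  ev <- event_matrix(cbind(a = area, h = height), sample_id = "s")
  expect_true(all(apply_gate(g, ev)))  # zero residuals: everything kept

  is_doublet <- runif(n) < 0.05
  area2 <- ifelse(is_doublet, 2 * area, area)
  height2 <- height + rnorm(n, 0, 1)
  g2 <- fit_singlet_gate(area2, height2, ch_area = "a", ch_height = "h")
  keep <- apply_gate(g2, event_matrix(cbind(a = area2, h = height2),
                                      sample_id = "d"))
  expect_gte(mean(keep[!is_doublet]), 0.99)
  expect_gte(mean(!keep[is_doublet]), 0.90)
  # widening the band never decreases the kept fraction
  g5 <- fit_singlet_gate(area2, height2, band = 5, ch_area = "a",
                         ch_height = "h")
  keep5 <- apply_gate(g5, event_matrix(cbind(a = area2, h = height2),
                                       sample_id = "d"))
  expect_gte(mean(keep5), mean(keep))
  expect_error(fit_singlet_gate(rep(1, 200), rnorm(200)),
               class = "cytogate_fit_error")
})

test_that("boundary gate excludes exactly the pinned events", {
  set.seed(26)
  n <- 2000
  x <- runif(n, 0, 26000)
  pinned <- runif(n) < 0.03
  x[pinned] <- 262143
  ev <- event_matrix(cbind(a = x, b = runif(n, 1, 100)), sample_id = "b")
  g <- fit_boundary_gate(ev, "a", max = 262143)
  keep <- apply_gate(g, ev)
  expect_identical(keep, !pinned)
  # no pinned events: all kept
  ev2 <- event_matrix(cbind(a = runif(n, 1, 1000), b = runif(n)),
                      sample_id = "b2")
  expect_true(all(apply_gate(fit_boundary_gate(ev2, "a", min = 0, max = 2000),
                             ev2)))
  # union semantics over two dims: pinned in either dim is excluded
  y <- runif(n, 0, 26000); ypin <- runif(n) < 0.02; y[ypin] <- 262143
  ev3 <- event_matrix(cbind(a = x, b = y), sample_id = "b3")
  g3 <- fit_boundary_gate(ev3, c("a", "b"), max = c(262143, 262143))
  expect_identical(apply_gate(g3, ev3), !(pinned | ypin))
  expect_error(fit_boundary_gate(ev3, "a", min = 5, max = 1),
               class = "cytogate_parameter_error")
})

test_that("mixture gate recovers a targeted component and is deterministic", {
  set.seed(27)
  x <- rbind(cbind(rnorm(5000), rnorm(5000)),
             cbind(rnorm(5000, 5), rnorm(5000, 5)))
  em <- event_matrix(x, channels = c("a", "b"), sample_id = "m")
  g <- fit_mixture_gate(em, c("a", "b"), K = 2, target = c(0, 0), seed = 3)
  expect_lt(sqrt(sum(g$center^2)), 0.1)
  g_far <- fit_mixture_gate(em, c("a", "b"), K = 2, target = c(5, 5), seed = 3)
  expect_lt(sqrt(sum((g_far$center - 5)^2)), 0.1)
  expect_identical(g, fit_mixture_gate(em, c("a", "b"), K = 2,
                                       target = c(0, 0), seed = 3))
  expect_error(fit_mixture_gate(event_matrix(cbind(a = rnorm(50),
                                                   b = rnorm(50)),
                                             sample_id = "tiny"),
                                c("a", "b")),
               class = "cytogate_parameter_error")
})

test_that("ref_gate copies and shifts gates exactly", {
  g <- threshold_gate("x", 1.5, Inf)
  expect_identical(ref_gate(g), g)
  expect_equal(ref_gate(g, 0.5)$min, 2.0)
  r <- rectangle_gate("x", "y", 0, 1, 0, 1)
  r2 <- ref_gate(r, c(1, -1))
  expect_equal(c(r2$xmin, r2$xmax, r2$ymin, r2$ymax), c(1, 2, -1, 0))
  e <- ellipse_gate("x", "y", c(0, 0), diag(2))
  expect_equal(ref_gate(e, c(2, 3))$center, c(2, 3))
})

test_that("DNA-DNA gate separates background, singlets, doublets", {
  set.seed(28)
  n <- 20000
  cls <- sample(c("bg", "s", "d"), n, TRUE, c(0.10, 0.85, 0.05))
  d1 <- ifelse(cls == "bg", rnorm(n, 1.2, 0.4),
               rnorm(n, ifelse(cls == "d", 4.7, 4), 0.15))
  d2 <- ifelse(cls == "bg", rnorm(n, 1.2, 0.4),
               0.02 + 0.99 * d1 + rnorm(n, 0, 0.05))
  g <- fit_dna_gate(d1, d2)
  keep <- apply_gate(g, event_matrix(cbind(DNA1 = d1, DNA2 = d2),
                                     sample_id = "c"))
  expect_gte(mean(keep[cls == "s"]), 0.95)
  expect_gte(mean(!keep[cls == "bg"]), 0.90)
  expect_gte(mean(!keep[cls == "d"]), 0.90)
  # no background, no doublets: nearly everything kept
  s1 <- rnorm(n, 4, 0.15); s2 <- 0.02 + 0.99 * s1 + rnorm(n, 0, 0.05)
  gk <- fit_dna_gate(s1, s2)
  expect_gte(mean(apply_gate(gk, event_matrix(cbind(DNA1 = s1, DNA2 = s2),
                                              sample_id = "k"))), 0.99)
  # widening the band never decreases the kept fraction
  g6 <- fit_dna_gate(d1, d2, band = 6)
  keep6 <- apply_gate(g6, event_matrix(cbind(DNA1 = d1, DNA2 = d2),
                                       sample_id = "c"))
  expect_gte(mean(keep6), mean(keep))
})

test_that("plugin registry resolves template methods and rejects collisions", {
  nm <- paste0("constGate", sample.int(1e6, 1))
  register_plugin(nm, function(events, dims, args, seed)
    rep(args$at, length(dims)), arity = 1)
  expect_true(nm %in% list_gating_methods())
  expect_error(register_plugin(nm, function(...) NULL),
               class = "cytogate_schema_error")
  # usable from a template row; the fitted gate equals the constant
  set.seed(29)
  s <- event_matrix(cbind(m1 = rnorm(500)), channels = "m1", sample_id = "s1")
  gs <- gating_set(create_store(list(s), tempfile()))
  tf <- tempfile(fileext = ".csv")
  writeLines(c(
    "alias,pop,parent,dims,gating_method,gating_args,collapseDataForGating,groupBy",
    sprintf("hi,m1+,root,m1,%s,at=0.25,FALSE,", nm)), tf)
  apply_template(gs, parse_template(tf), seed = 1)
  g <- cytogate:::sample_gate(gs$nodes[["/hi"]], "s1")
  expect_equal(g$min, 0.25)
})

test_that("a plugin raising during fit yields a missing population, not an abort", {
  nm <- paste0("bombGate", sample.int(1e6, 1))
  register_plugin(nm, function(events, dims, args, seed) stop("boom"),
                  arity = 1)
  s <- event_matrix(cbind(m1 = rnorm(500)), channels = "m1", sample_id = "s1")
  gs <- gating_set(create_store(list(s), tempfile()))
  tf <- tempfile(fileext = ".csv")
  writeLines(c(
    "alias,pop,parent,dims,gating_method,gating_args,collapseDataForGating,groupBy",
    sprintf("bad,m1+,root,m1,%s,,FALSE,", nm)), tf)
  expect_warning(apply_template(gs, parse_template(tf), seed = 1),
                 "marked missing")
  st <- population_stats(gs)
  expect_identical(st$flag[st$path == "/bad"], "missing")
})
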