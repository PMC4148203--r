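tiny_gs <- function(mat, channels = colnames(mat), ids = "s1") {
  samples <- lapply(ids, function(id)
    event_matrix(mat, channels = channels, sample_id = id))
  gating_set(create_store(samples, tempfile(fileext = ".bin")))
}

test_that("threshold and rectangle gates use half-open membership", {
  ev <- event_matrix(cbind(x = c(-1, 0, 0.5, 1, 2)), channels = "x",
                     sample_id = "t")
  g <- threshold_gate("x", 0, 1)
  expect_identical(apply_gate(g, ev), c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_true(all(apply_gate(threshold_gate("x"), ev)))
  # +/- partition is disjoint and exhaustive at the boundary
  pos <- apply_gate(threshold_gate("x", 0, Inf), ev)
  neg <- apply_gate(threshold_gate("x", -Inf, 0), ev)
  expect_identical(pos | neg, rep(TRUE, 5))
  expect_identical(pos & neg, rep(FALSE, 5))
  expect_error(apply_gate(threshold_gate("zz", 0), ev),
               class = "cytogate_schema_error")
})

test_that("polygon membership matches the ray-casting oracle", {
  set.seed(10)
  # unit square, 10,000 random points
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  px <- runif(10000, -0.5, 1.5); py <- runif(10000, -0.5, 1.5)
  ev <- event_matrix(cbind(x = px, y = py), sample_id = "p")
  expect_identical(apply_gate(polygon_gate("x", "y", sq), ev),
                   pip_oracle(px, py, sq))
  # non-convex polygon
  poly <- rbind(c(0, 0), c(4, 0), c(4, 3), c(2, 1), c(0, 3))
  px <- runif(5000, -1, 5); py <- runif(5000, -1, 4)
  ev <- event_matrix(cbind(x = px, y = py), sample_id = "p2")
  expect_identical(apply_gate(polygon_gate("x", "y", poly), ev),
                   pip_oracle(px, py, poly))
  # boundary points count inside
  evb <- event_matrix(cbind(x = c(0, 0.5, 1), y = c(0, 0, 1)), sample_id = "b")
  expect_true(all(apply_gate(polygon_gate("x", "y", sq), evb)))
})

test_that("ellipse gate covers `level` of a standard bivariate normal", {
  set.seed(11)
  z <- event_matrix(cbind(x = rnorm(1e5), y = rnorm(1e5)), sample_id = "z")
  g <- ellipse_gate("x", "y", c(0, 0), diag(2), level = 0.95)
  expect_lt(abs(mean(apply_gate(g, z)) - 0.95), 0.005)
  expect_error(ellipse_gate("x", "y", c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "positive-definite")
})

test_that("population tree construction enforces its invariants", {
  gs <- tiny_gs(cbind(x = rnorm(100), y = rnorm(100)))
  add_population(gs, "root", "a", threshold_gate("x", 0))
  expect_identical(gs_node_paths(gs), c("/", "/a"))
  expect_error(add_population(gs, "root", "a", threshold_gate("x", 1)),
               class = "cytogate_schema_error")
  expect_error(add_population(gs, "/nope", "b", threshold_gate("x", 0)),
               class = "cytogate_lookup_error")
  add_population(gs, "/a", "b", threshold_gate("y", 0))
  expect_identical(resolve_path(gs, "b"), "/a/b")
})

test_that("cached indices equal brute-force sequential filtering", {
  set.seed(12)
  mat <- cbind(x = rnorm(5000), y = rnorm(5000), z = rnorm(5000))
  gs <- tiny_gs(mat)
  add_population(gs, "root", "a", threshold_gate("x", 0))
  add_population(gs, "/a", "b", threshold_gate("y", -0.5))
  add_population(gs, "/a/b", "c", threshold_gate("z", 0, 1))

  idx <- compute_indices(gs, "s1", "/a/b/c")
  brute <- mat[, "x"] >= 0 & mat[, "y"] >= -0.5 &
    mat[, "z"] >= 0 & mat[, "z"] < 1
  # store holds float32; recompute brute on the stored values
  stored <- get_sample(gs$store, "s1")$events
  brute32 <- stored[, "x"] >= 0 & stored[, "y"] >= -0.5 &
    stored[, "z"] >= 0 & stored[, "z"] < 1
  expect_identical(idx, brute32)
  expect_identical(unname(which(brute)), which(brute32))  # same at this scale
  # root is all-true; cache hit returns the identical value
  expect_true(all(compute_indices(gs, "s1", "/")))
  expect_identical(compute_indices(gs, "s1", "/a/b/c"), idx)
  # monotone containment along every edge
  expect_true(all(compute_indices(gs, "s1", "/a") >= compute_indices(gs, "s1", "/a/b")))
})

test_that("cache invalidation then recompute equals cold compute", {
  set.seed(13)
  mat <- cbind(x = rnorm(2000), y = rnorm(2000))
  gs <- tiny_gs(mat)
  add_population(gs, "root", "a", threshold_gate("x", 0))
  add_population(gs, "/a", "b", threshold_gate("y", 0))
  warm <- compute_indices(gs, "s1", "/a/b")
  set_gate(gs, "/a", threshold_gate("x", 0.5))  # invalidates /a and /a/b
  new <- compute_indices(gs, "s1", "/a/b")
  gs2 <- tiny_gs(mat)
  add_population(gs2, "root", "a", threshold_gate("x", 0.5))
  add_population(gs2, "/a", "b", threshold_gate("y", 0))
  expect_identical(new, compute_indices(gs2, "s1", "/a/b"))
  expect_false(identical(warm, new))
})

test_that("population_stats satisfies its invariants", {
  set.seed(14)
  mat <- cbind(x = rnorm(3000), y = rnorm(3000))
  gs <- tiny_gs(mat, ids = c("s1", "s2"))
  add_population(gs, "root", "xy", rectangle_gate("x", "y"))
  for (sx in c("+", "-")) for (sy in c("+", "-")) {
    b <- function(s) if (s == "+") c(0, Inf) else c(-Inf, 0)
    add_population(gs, "/xy", paste0("x", sx, "y", sy),
                   rectangle_gate("x", "y", b(sx)[1], b(sx)[2],
                                  b(sy)[1], b(sy)[2]))
  }
  st <- population_stats(gs)
  expect_identical(nrow(st), 2L * 6L)
  root_rows <- st[st$path == "/", ]
  expect_true(all(root_rows$proportion_of_parent == 1))
  # disjoint quadrant children partition the parent exactly
  for (sid in c("s1", "s2")) {
    quad <- st[st$sample_id == sid & grepl("^/xy/", st$path), ]
    parent_n <- st$count[st$sample_id == sid & st$path == "/xy"]
    expect_identical(sum(quad$count), parent_n)
    expect_equal(sum(quad$proportion_of_parent), 1)
  }
  # determinism: gating twice yields identical tables
  expect_identical(population_stats(gs), st)
})

test_that("0-event parents propagate flagged 0-proportion children", {
  mat <- cbind(x = rnorm(100))
  gs <- tiny_gs(mat)
  add_population(gs, "root", "none", threshold_gate("x", 99))
  add_population(gs, "/none", "child", threshold_gate("x", 100))
  st <- population_stats(gs)
  child <- st[st$path == "/none/child", ]
  expect_identical(child$count, 0L)
  expect_identical(child$proportion_of_parent, 0)
  expect_match(child$flag, "empty_parent")
})

test_that("missing per-sample gates flag the population, not an error", {
  mat <- cbind(x = rnorm(100))
  gs <- tiny_gs(mat, ids = c("s1", "s2"))
  add_population(gs, "root", "a",
                 gate = list(s1 = threshold_gate("x", 0)))  # s2 missing
  st <- population_stats(gs)
  expect_identical(st$flag[st$sample_id == "s2" & st$path == "/a"], "missing")
  expect_identical(st$count[st$sample_id == "s2" & st$path == "/a"], 0L)
  expect_gt(st$count[st$sample_id == "s1" & st$path == "/a"], 0L)
})

test_that("boolean evaluation matches vector logic oracles", {
  set.seed(15)
  mat <- cbind(x = rnorm(2000), y = rnorm(2000))
  gs <- tiny_gs(mat)
  add_population(gs, "root", "A", threshold_gate("x", 0))
  add_population(gs, "root", "B", threshold_gate("y", 0.3))
  a <- compute_indices(gs, "s1", "/A")
  b <- compute_indices(gs, "s1", "/B")

  expect_identical(boolean_gate_eval(gs, "s1", "A & !A"), rep(FALSE, 2000))
  # De Morgan
  expect_identical(boolean_gate_eval(gs, "s1", "!(A | B)"),
                   boolean_gate_eval(gs, "s1", "!A & !B"))
  # truth table over 2 gates
  expect_identical(boolean_gate_eval(gs, "s1", "A & B"), a & b)
  expect_identical(boolean_gate_eval(gs, "s1", "A | B"), a | b)
  expect_identical(boolean_gate_eval(gs, "s1", "A & !B"), a & !b)
  expect_identical(boolean_gate_eval(gs, "s1", "!A & !B"), !a & !b)
  # restricted to a declared parent
  expect_identical(boolean_gate_eval(gs, "s1", "B", parent = "/A"), a & b)
  expect_error(boolean_gate_eval(gs, "s1", "A & nope"),
               class = "cytogate_lookup_error")
  # boolean gates as populations
  add_population(gs, "root", "AandB", boolean_gate("A & B"))
  expect_identical(compute_indices(gs, "s1", "/AandB"), a & b)
})

test_that("gating sets serialize to JSON and reload equivalently", {
  set.seed(16)
  mat <- cbind(x = rnorm(500), y = rnorm(500))
  gs <- tiny_gs(mat)
  add_population(gs, "root", "a", threshold_gate("x", 0))
  add_population(gs, "/a", "p", polygon_gate("x", "y",
                                             rbind(c(0, -1), c(2, -1), c(1, 2))))
  add_population(gs, "/a", "e",
                 ellipse_gate("x", "y", c(0, 0), diag(2), 0.9))
  f <- tempfile(fileext = ".json")
  save_gating_set(gs, f)
  gs2 <- load_gating_set(gs$store, f)
  expect_identical(gs_node_paths(gs2), gs_node_paths(gs))
  for (p in setdiff(gs_node_paths(gs), "/"))
    expect_identical(compute_indices(gs2, "s1", p),
                     compute_indices(gs, "s1", p))
})
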