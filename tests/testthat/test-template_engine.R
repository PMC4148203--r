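mk_row <- function(alias = "x", pop = "cd4+", parent = "root", dims = "CD4",
                   gating_method = "mindensity", gating_args = "",
                   collapseDataForGating = "FALSE", groupBy = "") {
  list(alias = alias, pop = pop, parent = parent, dims = dims,
       gating_method = gating_method, gating_args = gating_args,
       collapseDataForGating = collapseDataForGating, groupBy = groupBy)
}

write_tpl <- function(rows) {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "alias,pop,parent,dims,gating_method,gating_args,collapseDataForGating,groupBy",
    rows), f)
  f
}

test_that("gating_args cells parse with typed coercion", {
  a <- parse_gating_args("tol=0.01, K=2, side=right, collapse=TRUE, gate_range=1:3")
  expect_identical(a$tol, 0.01)
  expect_identical(a$K, 2)
  expect_identical(a$side, "right")
  expect_identical(a$collapse, TRUE)
  expect_identical(a$gate_range, c(1, 3))
  expect_identical(parse_gating_args(""), list())
  expect_error(parse_gating_args("oops"), class = "cytogate_schema_error")
})

test_that("pop specs expand to the declared populations", {
  # single fixed-sign population
  ex <- expand_pop(mk_row(pop = "IFNg+", dims = "IFNg", alias = "ifng"))
  expect_length(ex, 1)
  expect_identical(ex[[1]]$alias, "ifng")
  expect_identical(ex[[1]]$signs[[1]], c(IFNg = "+"))
  # 2x2 quadrant expansion shares the source row
  ex <- expand_pop(mk_row(pop = "cd4+/-cd8+/-", dims = "CD4,CD8"))
  expect_length(ex, 4)
  expect_setequal(vapply(ex, `[[`, character(1), "alias"),
                  c("CD4+CD8+", "CD4-CD8+", "CD4+CD8-", "CD4-CD8-"))
  # 1-dim split
  ex <- expand_pop(mk_row(pop = "cd4+/-", dims = "CD4"))
  expect_length(ex, 2)
  # marker matching ignores case and punctuation
  ex <- expand_pop(mk_row(pop = "ifn-g+", dims = "IFNg"))
  expect_identical(ex[[1]]$signs[[1]], c(IFNg = "+"))
  expect_error(expand_pop(mk_row(pop = "cd4+cd8+", dims = "CD4")),
               class = "cytogate_schema_error")
  expect_error(expand_pop(mk_row(pop = "cd4", dims = "CD4")),
               class = "cytogate_schema_error")
})

test_that("parse_template validates structure and names the offending row", {
  tpl <- parse_template(write_tpl(
    "cd3,cd3+,root,CD3,mindensity,,FALSE,"))
  expect_length(tpl$entries, 1)
  expect_identical(tpl$entries[[1]]$path, "/cd3")

  err <- tryCatch(parse_template(write_tpl(
    "cd3,cd3+,lymph,CD3,mindensity,,FALSE,")), error = identity)
  expect_s3_class(err, "cytogate_schema_error")
  expect_match(conditionMessage(err), "row 1")
  expect_match(conditionMessage(err), "lymph")

  expect_error(parse_template(write_tpl(
    "cd3,cd3+,root,CD3,notAMethod,,FALSE,")), "unknown gating method")

  # missing column
  f <- tempfile(fileext = ".csv")
  writeLines(c("alias,pop,parent,dims,gating_method,gating_args,collapseDataForGating",
               "a,b+,root,b,mindensity,,FALSE"), f)
  err <- tryCatch(parse_template(f), error = identity)
  expect_match(conditionMessage(err), "groupBy")
})

test_that("the ICS template parses to the expected tree", {
  tpl <- parse_template(write_ics_template())
  # adjacency: parent -> children aliases
  adj <- split(vapply(tpl$entries, `[[`, character(1), "alias"),
               vapply(tpl$entries, `[[`, character(1), "parent"))
  expect_identical(adj[["/"]], "boundary")
  expect_identical(adj[["/boundary/singlets/live"]], "cd3")
  expect_setequal(adj[["/boundary/singlets/live/cd3"]],
                  c("CD4+CD8+", "CD4-CD8+", "CD4+CD8-", "CD4-CD8-"))
  expect_setequal(adj[[CD4_PATH]], c("IFNg", "IL2", "TNFa", "GzB", "CD57"))
  expect_setequal(adj[[CD8_PATH]],
                  c("IFNg_8", "IL2_8", "TNFa_8", "GzB_8", "CD57_8"))
  # DOT export mirrors the adjacency
  dot <- template_to_dot(tpl)
  expect_identical(sum(gregexpr("->", dot, fixed = TRUE)[[1]] > 0),
                   length(tpl$entries))
  for (e in tpl$entries)
    expect_match(dot, sprintf("\"%s\" -> \"%s\";", e$parent, e$path),
                 fixed = TRUE)
})

test_that("quadrant expansion partitions the parent exactly", {
  fix <- gated_ics_fixture()
  st <- population_stats(fix$gs)
  for (sid in sample_ids(fix$gs$store)[1:4]) {
    quad <- st[st$sample_id == sid &
                 st$path %in% file.path("/boundary/singlets/live/cd3",
                                        c("CD4+CD8+", "CD4-CD8+",
                                          "CD4+CD8-", "CD4-CD8-")), ]
    parent_n <- st$count[st$sample_id == sid &
                           st$path == "/boundary/singlets/live/cd3"]
    expect_identical(sum(quad$count), parent_n)
  }
})

test_that("collapsed groups share bitwise-identical gates; reruns are identical", {
  fix <- gated_ics_fixture()
  gs <- fix$gs
  # all samples of one (PTID, VISITNO) share the same fitted cytokine gate
  sids <- sample_ids(gs$store)
  md <- lapply(gs$store$samples, function(r) r$metadata)
  grp <- paste(vapply(md, `[[`, character(1), "PTID"),
               vapply(md, `[[`, character(1), "VISITNO"))
  g1 <- grp == grp[1]
  node <- gs$nodes[[file.path(CD4_PATH, "IFNg")]]
  gates <- node$gate[sids[g1]]
  for (g in gates[-1]) expect_identical(g, gates[[1]])
  # different visit group fitted separately (thresholds differ numerically)
  other <- which(grp != grp[1])[1]
  expect_false(identical(node$gate[[sids[other]]]$min, gates[[1]]$min))

  # same template + same data + same seed: identical stats tables
  gs2 <- gating_set(open_store(gs$store$path))
  apply_template(gs2, parse_template(write_ics_template()), seed = 11)
  expect_identical(population_stats(gs2), population_stats(gs))
})

test_that("per-sample thresholds track drifted valleys; permutation-invariant", {
  # assay-realistic depth so valley sampling noise stays inside the bound
  scn <- ics_scenario(n_subjects = 1, n_events = 150000,
                      drift_marker = "GzB")
  sim <- simulate_ics(scn, seed = 31)
  samples <- sim$samples
  store <- create_store(samples, tempfile())
  gs <- gating_set(store)
  tpl <- parse_template(write_tpl(c(
    "cd3,cd3+,root,CD3,mindensity,,FALSE,",
    "cd8,cd8+,cd3,CD8,mindensity,,FALSE,",
    "gzb,GzB+,cd8,GzB,mindensity,adjust=2,FALSE,")))
  apply_template(gs, tpl, seed = 5)
  for (sid in sample_ids(store)) {
    thr <- gs$nodes[["/cd3/cd8/gzb"]]$gate[[sid]]$min
    expect_lt(abs(thr - sim$truth[[sid]]$valleys[["GzB"]]), 0.15)
  }
  # permuting sample order changes no per-sample statistic (collapse = FALSE)
  store_p <- create_store(rev(samples), tempfile())
  gs_p <- gating_set(store_p)
  apply_template(gs_p, tpl, seed = 5)
  a <- population_stats(gs)
  b <- population_stats(gs_p)
  b <- b[order(match(b$sample_id, a$sample_id), match(b$path, a$path)), ]
  rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("one template gates two independently simulated panels (data agnostic)", {
  tpl <- parse_template(write_ics_template())
  for (sd in c(41, 42)) {
    sim <- simulate_ics(ics_scenario(n_subjects = 1, n_events = 3000),
                        seed = sd)
    gs <- gating_set(create_store(sim$samples, tempfile()))
    apply_template(gs, tpl, seed = 1)
    expect_identical(gs_node_paths(gs),
                     c("/", "/boundary", "/boundary/singlets",
                       "/boundary/singlets/live", "/boundary/singlets/live/cd3",
                       file.path("/boundary/singlets/live/cd3",
                                 c("CD4+CD8+", "CD4-CD8+", "CD4+CD8-",
                                   "CD4-CD8-")),
                       CD4_CYTO, CD8_CYTO))
  }
})

test_that("refGate copies control-derived thresholds within groups", {
  sim <- simulate_cytof(cytof_scenario(n_events = 8000), seed = 51)
  gs <- gating_set(create_store(sim$samples, tempfile()))
  tpl <- parse_template(write_tpl(c(
    "dna,+,root,\"DNA1,DNA2\",dnaGate,,TRUE,",
    "ifng,IFNg+,dna,IFNg,refGate,\"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99\",FALSE,")))
  apply_template(gs, tpl, seed = 2)
  thr <- vapply(sample_ids(gs$store), function(s)
    gs$nodes[["/dna/ifng"]]$gate[[s]]$min, numeric(1))
  expect_identical(unname(thr[1]), unname(thr[2]))
  expect_identical(unname(thr[1]), unname(thr[3]))
  # control's threshold on stimulated samples: positive fraction rises
  st <- population_stats(gs)
  p <- function(s) st$proportion_of_parent[st$sample_id == s &
                                             st$path == "/dna/ifng"]
  expect_gt(p("stim1"), 3 * p("unstim"))
  # offset shifts the copied threshold by exactly its value
  tpl2 <- parse_template(write_tpl(c(
    "dna,+,root,\"DNA1,DNA2\",dnaGate,,TRUE,",
    "ifng,IFNg+,dna,IFNg,refGate,\"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99,offset=0.5\",FALSE,")))
  gs2 <- gating_set(open_store(gs$store$path))
  apply_template(gs2, tpl2, seed = 2)
  expect_equal(gs2$nodes[["/dna/ifng"]]$gate[["unstim"]]$min,
               thr[["unstim"]] + 0.5)
})

test_that("missing groupBy metadata errors loudly", {
  s <- event_matrix(cbind(m1 = rnorm(200)), channels = "m1", sample_id = "s1",
                    metadata = list())  # no PTID
  gs <- gating_set(create_store(list(s), tempfile()))
  tpl <- parse_template(write_tpl(
    "a,m1+,root,m1,quantileGate,probs=0.9,TRUE,PTID"))
  expect_error(apply_template(gs, tpl, seed = 1),
               class = "cytogate_schema_error")
})
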