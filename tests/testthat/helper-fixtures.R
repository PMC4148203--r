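# shared fixtures: all data are generated in code at test time

random_event_matrix <- function(n = 100, channels = c("FSC-A", "PE-A", "APC-A"),
                                sample_id = "s1", seed = 1, ...) {
  set.seed(seed)
  event_matrix(matrix(runif(n * length(channels)) * 1000, n),
               channels = channels, sample_id = sample_id, ...)
}

# the standard ICS template used across template/boolean/acceptance tests
write_ics_template <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c(
    "alias,pop,parent,dims,gating_method,gating_args,collapseDataForGating,groupBy",
    "boundary,+,root,\"FSC-A,SSC-A\",boundary,min=0:0,FALSE,",
    "singlets,+,boundary,\"FSC-A,FSC-H\",singletGate,,FALSE,",
    "live,-,singlets,ViViD,mindensity,,FALSE,",
    "cd3,+,live,CD3,mindensity,,FALSE,",
    "cd4cd8,cd4+/-cd8+/-,cd3,\"CD4,CD8\",mindensity,,FALSE,",
    "IFNg,+,CD4+CD8-,IFNg,tailgate,,TRUE,PTID:VISITNO",
    "IL2,+,CD4+CD8-,IL2,tailgate,,TRUE,PTID:VISITNO",
    "TNFa,+,CD4+CD8-,TNFa,tailgate,,TRUE,PTID:VISITNO",
    "GzB,+,CD4+CD8-,GzB,mindensity,adjust=2,TRUE,PTID:VISITNO",
    "CD57,+,CD4+CD8-,CD57,mindensity,,TRUE,PTID:VISITNO",
    "IFNg_8,IFNg+,CD4-CD8+,IFNg,tailgate,,TRUE,PTID:VISITNO",
    "IL2_8,IL2+,CD4-CD8+,IL2,tailgate,,TRUE,PTID:VISITNO",
    "TNFa_8,TNFa+,CD4-CD8+,TNFa,tailgate,,TRUE,PTID:VISITNO",
    "GzB_8,GzB+,CD4-CD8+,GzB,mindensity,adjust=2,TRUE,PTID:VISITNO",
    "CD57_8,CD57+,CD4-CD8+,CD57,mindensity,,TRUE,PTID:VISITNO"
  ), path)
  path
}

CD4_PATH <- "/boundary/singlets/live/cd3/CD4+CD8-"
CD8_PATH <- "/boundary/singlets/live/cd3/CD4-CD8+"
CD4_CYTO <- file.path(CD4_PATH, c("IFNg", "IL2", "TNFa", "GzB", "CD57"))
CD8_CYTO <- file.path(CD8_PATH, c("IFNg_8", "IL2_8", "TNFa_8", "GzB_8", "CD57_8"))

# small gated ICS gating set, memoised per session to keep the suite fast
gated_ics_fixture <- local({
  cache <- NULL
  function(n_subjects = 2, n_events = 3000, seed = 7) {
    if (!is.null(cache)) return(cache)
    sim <- simulate_ics(ics_scenario(n_subjects = n_subjects,
                                     n_events = n_events), seed = seed)
    store <- create_store(sim$samples, tempfile(fileext = ".bin"))
    gs <- gating_set(store)
    apply_template(gs, parse_template(write_ics_template()), seed = 11)
    cache <<- list(gs = gs, sim = sim)
    cache
  }
})

# independent point-in-polygon oracle: scalar even-odd ray casting, one point
# at a time, with explicit boundary handling
pip_oracle <- function(px, py, verts) {
  m <- nrow(verts)
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    inside <- FALSE
    j <- m
    for (k in seq_len(m)) {
      x1 <- verts[j, 1]; y1 <- verts[j, 2]
      x2 <- verts[k, 1]; y2 <- verts[k, 2]
      # boundary check
      d <- abs((x - x1) * (y2 - y1) - (y - y1) * (x2 - x1))
      if (d < 1e-12 && x >= min(x1, x2) - 1e-12 && x <= max(x1, x2) + 1e-12 &&
          y >= min(y1, y2) - 1e-12 && y <= max(y1, y2) + 1e-12)
        return(TRUE)
      if ((y1 > y) != (y2 > y) && x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
        inside <- !inside
      j <- k
    }
    inside
  }, logical(1))
}
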