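#' @name synthetic_data
#' @title Seeded synthetic cytometry data with ground truth
#'
#' @description
#' Fixture generators emulating (i) a standardized intracellular cytokine
#' staining (ICS) vaccine-trial design -- two arms, two visits, three antigen
#' stimulations plus a negative control per subject, a
#' lymphocyte/live/CD3/CD4/CD8 hierarchy, rare cytokine-positive tails,
#' optional per-sample staining drift of a marker's negative peak -- and (ii) a
#' CyTOF T-cell panel -- DNA-DNA singlet structure, four maturational subsets,
#' nine functional markers, an unstimulated sample usable as a reference-gate
#' source. Marker intensities are generated directly on the transformed
#' (arcsinh-like) scale so gate truth bookkeeping is exact; scatter channels
#' are on the linear instrument scale. Every generator is a pure function of
#' (scenario, seed) and returns events plus per-event ground-truth labels and
#' per-sample true thresholds.
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

sub_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 10007 + index * 97) %% 2147483629)
}

marker_spec <- function(neg_mean, neg_sd, pos_mean, pos_sd, rate) {
  list(neg_mean = neg_mean, neg_sd = neg_sd,
       pos_mean = pos_mean, pos_sd = pos_sd, rate = rate)
}

#' True density valley of a two-component marker model
#'
#' Brute-force minimisation of the mixture density between the component
#' means on a fine grid; this is the generator's ground truth for
#' valley-seeking thresholds.
#'
#' @param spec list with `neg_mean`, `neg_sd`, `pos_mean`, `pos_sd`, `rate`.
#' @return The valley location (numeric scalar).
#' @export
true_valley <- function(spec) {
  grid <- seq(spec$neg_mean, spec$pos_mean, length.out = 4001)
  f <- (1 - spec$rate) * stats::dnorm(grid, spec$neg_mean, spec$neg_sd) +
    spec$rate * stats::dnorm(grid, spec$pos_mean, spec$pos_sd)
  grid[which.min(f)]
}

#' Per-sample staining drift of a marker's negative peak
#'
#' Emulates sample-to-sample variability in both the position and the width
#' of a marker's negative peak (as seen for perforin-like stains): the
#' negative mean is shifted by a seeded uniform offset, its SD scaled by a
#' seeded log-uniform factor, and the positives are shifted coherently.
#'
#' @param base_spec a marker spec (see [true_valley()]).
#' @param sample_index 1-based sample index (drives the per-sample stream).
#' @param seed scenario seed.
#' @param shift maximum absolute shift of the negative mean (transformed
#'   units).
#' @param scale maximum absolute log SD-scale factor.
#' @return The drifted marker spec.
#' @export
drifted_negative <- function(base_spec, sample_index, seed = 1,
                             shift = 0.5, scale = 0.3) {
  with_seed(sub_seed(seed, 7919 + sample_index), {
    off <- stats::runif(1, -shift, shift)
    fac <- exp(stats::runif(1, -scale, scale))
    sp <- base_spec
    sp$neg_mean <- sp$neg_mean + off
    sp$neg_sd <- sp$neg_sd * fac
    sp$pos_mean <- sp$pos_mean + off
    sp
  })
}

#' ICS trial scenario
#'
#' The stated world for the synthetic ICS trial: 8 subjects split over two
#' vaccine regimens, visits pre/post, three antigen stimulations plus a
#' negative control (64 samples), 20,000 events per sample, a 12-channel
#' panel, rare cytokine responses with an absolute +0.01 positivity spike in
#' the responding arm at post-vaccination for the spiked stimulations.
#'
#' @param n_subjects number of subjects (arms alternate).
#' @param n_events events per sample (>= 1000).
#' @param response_rate absolute increase of IFNg/IL2 positivity in the
#'   responding arm, post visit, spiked stimulations.
#' @param spiked_stims stimulations carrying the response.
#' @param drift_marker optional cytokine marker whose negative peak drifts
#'   per sample (e.g. `"GzB"`); `NULL` disables drift.
#' @param drift_shift,drift_scale drift amplitudes (see [drifted_negative()]).
#' @param doublet_frac,debris_frac,dead_frac,pinned_frac event-class
#'   fractions.
#' @return A `SimScenario` list.
#' @export
ics_scenario <- function(n_subjects = 8, n_events = 20000,
                         response_rate = 0.01,
                         spiked_stims = c("GAG", "POL"),
                         drift_marker = NULL,
                         drift_shift = 0.8, drift_scale = 0.3,
                         doublet_frac = 0.03, debris_frac = 0.04,
                         dead_frac = 0.05, pinned_frac = 0.005) {
  stopifnot(n_events >= 1000)
  channels <- c("FSC-A", "FSC-H", "SSC-A", "AmCyan-A", "APC-Cy7-A",
                "PerCP-A", "FITC-A", "PE-A", "APC-A", "PE-Cy7-A",
                "V450-A", "QDot605-A")
  markers <- c("AmCyan-A" = "ViViD", "APC-Cy7-A" = "CD3", "PerCP-A" = "CD4",
               "FITC-A" = "CD8", "PE-A" = "IFNg", "APC-A" = "IL2",
               "PE-Cy7-A" = "TNFa", "V450-A" = "GzB", "QDot605-A" = "CD57")
  cytokines <- c("IFNg", "IL2", "TNFa", "GzB", "CD57")
  cyto_specs <- list(
    IFNg = marker_spec(0.30, 0.35, 2.8, 0.50, 0.004),
    IL2  = marker_spec(0.30, 0.35, 2.8, 0.50, 0.003),
    TNFa = marker_spec(0.30, 0.35, 2.8, 0.50, 0.005),
    GzB  = marker_spec(0.35, 0.40, 3.0, 0.50, 0.12),
    CD57 = marker_spec(0.30, 0.40, 2.5, 0.55, 0.15))
  list(kind = "ics",
       n_subjects = n_subjects, n_events = n_events,
       arms = c("PennvaxB", "PennvaxB_IL12"),
       visits = c("pre", "post"),
       stims = c("negctrl", "ENV", "GAG", "POL"),
       spiked_stims = spiked_stims, responding_arm = "PennvaxB_IL12",
       response_rate = response_rate, response_markers = c("IFNg", "IL2"),
       channels = channels, markers = markers, cytokines = cytokines,
       cyto_specs = cyto_specs,
       pheno_specs = list(
         ViViD = marker_spec(0.5, 0.30, 3.0, 0.40, dead_frac),
         CD3 = marker_spec(0.5, 0.35, 3.2, 0.40, 0.75),
         CD4 = marker_spec(0.5, 0.35, 3.0, 0.40, 0.60),
         CD8 = marker_spec(0.4, 0.35, 3.1, 0.40, 0.30)),
       drift_marker = drift_marker, drift_shift = drift_shift,
       drift_scale = drift_scale,
       doublet_frac = doublet_frac, debris_frac = debris_frac,
       dead_frac = dead_frac, pinned_frac = pinned_frac,
       scatter_max = 262143)
}

# one ICS sample on the stated panel; cyto_specs already include any drift
simulate_ics_sample <- function(scn, sample_id, metadata, cyto_specs,
                                cyto_rates, seed) {
  with_seed(seed, {
    n <- scn$n_events
    ps <- scn$pheno_specs
    is_debris <- stats::runif(n) < scn$debris_frac
    is_doublet <- !is_debris & stats::runif(n) < scn$doublet_frac
    is_dead <- !is_debris & stats::runif(n) < ps$ViViD$rate
    is_cd3 <- !is_debris & !is_dead & stats::runif(n) < ps$CD3$rate
    u <- stats::runif(n)
    lineage <- ifelse(!is_cd3, "nonT",
                      ifelse(u < ps$CD4$rate, "CD4",
                             ifelse(u < ps$CD4$rate + ps$CD8$rate, "CD8", "DN")))

    ev <- matrix(0, nrow = n, ncol = length(scn$channels),
                 dimnames = list(NULL, scn$channels))
    # scatter (linear scale)
    fsc <- ifelse(is_debris, stats::rnorm(n, 28000, 6000),
                  stats::rnorm(n, 75000, 9000))
    fsc <- pmax(fsc, 1000)
    fsc_h <- 0.95 * fsc + stats::rnorm(n, 0, 2000)
    fsc[is_doublet] <- fsc[is_doublet] * 1.9
    ev[, "FSC-A"] <- fsc
    ev[, "FSC-H"] <- fsc_h
    ev[, "SSC-A"] <- pmax(ifelse(is_debris, stats::rnorm(n, 15000, 5000),
                                 stats::rnorm(n, 42000, 9000)), 500)
    pinned <- stats::runif(n) < scn$pinned_frac
    ev[pinned, "FSC-A"] <- scn$scatter_max

    draw <- function(spec, positive) {
      ifelse(positive,
             stats::rnorm(n, spec$pos_mean, spec$pos_sd),
             stats::rnorm(n, spec$neg_mean, spec$neg_sd))
    }
    mk_ch <- function(marker) names(scn$markers)[scn$markers == marker]
    ev[, mk_ch("ViViD")] <- draw(ps$ViViD, is_dead)
    ev[, mk_ch("CD3")] <- draw(ps$CD3, is_cd3)
    ev[, mk_ch("CD4")] <- draw(ps$CD4, lineage == "CD4")
    ev[, mk_ch("CD8")] <- draw(ps$CD8, lineage == "CD8")

    cyto_pos <- matrix(FALSE, n, length(scn$cytokines),
                       dimnames = list(NULL, scn$cytokines))
    tcell <- lineage %in% c("CD4", "CD8")
    for (m in scn$cytokines) {
      rate <- ifelse(lineage == "CD8", cyto_rates[[m]]["CD8"],
                     cyto_rates[[m]]["CD4"])
      cyto_pos[, m] <- tcell & stats::runif(n) < rate
      ev[, mk_ch(m)] <- draw(cyto_specs[[m]], cyto_pos[, m])
    }

    truth <- list(
      labels = data.frame(debris = is_debris, doublet = is_doublet,
                          dead = is_dead, lineage = lineage,
                          stringsAsFactors = FALSE),
      cyto_pos = cyto_pos,
      valleys = vapply(cyto_specs, true_valley, numeric(1)))
    list(sample = event_matrix(as_float32(ev), channels = scn$channels,
                               markers = scn$markers, sample_id = sample_id,
                               metadata = metadata),
         truth = truth)
  })
}

#' Simulate the ICS trial
#'
#' One sample per subject x visit x stimulation. Deterministic given
#' (scenario, seed): event matrices are byte-identical across runs.
#'
#' @param scenario an [ics_scenario()].
#' @param seed integer seed.
#' @return List with `samples` (list of [event_matrix()]), `truth` (named by
#'   sample id: per-event labels, cytokine positivity, true valleys), and
#'   `metadata` (data.frame of PTID/VISITNO/STIM/ARM per sample).
#' @export
simulate_ics <- function(scenario = ics_scenario(), seed = 1) {
  scn <- scenario
  grid <- expand.grid(stim = scn$stims, visit = scn$visits,
                      subject = seq_len(scn$n_subjects),
                      stringsAsFactors = FALSE)
  samples <- vector("list", nrow(grid))
  truth <- vector("list", nrow(grid))
  ids <- character(nrow(grid))
  md_rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    subj <- grid$subject[i]; visit <- grid$visit[i]; stim <- grid$stim[i]
    arm <- scn$arms[(subj - 1) %% length(scn$arms) + 1]
    sid <- sprintf("s%03d_%s_%s", subj, visit, stim)
    md <- list(PTID = sprintf("P%03d", subj), VISITNO = visit,
               STIM = stim, ARM = arm)
    # per-condition cytokine rates: the response spikes selected markers in
    # the responding arm, post visit, spiked stimulations
    rates <- lapply(scn$cytokines, function(m) {
      base <- scn$cyto_specs[[m]]$rate
      r <- c(CD4 = base, CD8 = base)
      if (m == "GzB") r <- c(CD4 = 0.02, CD8 = base)
      if (m == "CD57") r <- c(CD4 = 0.03, CD8 = base)
      if (m %in% scn$response_markers && arm == scn$responding_arm &&
          visit == "post" && stim %in% scn$spiked_stims)
        r <- r + scn$response_rate
      r
    })
    names(rates) <- scn$cytokines
    specs <- scn$cyto_specs
    if (!is.null(scn$drift_marker)) {
      specs[[scn$drift_marker]] <- drifted_negative(
        specs[[scn$drift_marker]], sample_index = i, seed = seed,
        shift = scn$drift_shift, scale = scn$drift_scale)
    }
    # valley truth depends on the realized positive rate; use the CD8 rate
    for (m in scn$cytokines) specs[[m]]$rate <- rates[[m]][["CD8"]]
    res <- simulate_ics_sample(scn, sid, md, specs, rates,
                               seed = sub_seed(seed, i))
    samples[[i]] <- res$sample
    truth[[i]] <- res$truth
    ids[i] <- sid
    md_rows[[i]] <- data.frame(sample_id = sid, PTID = md$PTID,
                               VISITNO = visit, STIM = stim, ARM = arm,
                               stringsAsFactors = FALSE)
  }
  names(truth) <- ids
  list(samples = samples, truth = truth,
       metadata = do.call(rbind, md_rows), scenario = scn)
}

#' CyTOF phenotyping scenario
#'
#' Stated world: one unstimulated and two stimulated samples, two DNA
#' intercalator channels with background/singlet/doublet structure, four
#' maturational CD8 T-cell subsets (TN, TCM, TEM, TEF) set by CD45RA/CCR7,
#' and nine functional markers. Unstimulated positivity is 1% per marker (so
#' a 99th-percentile reference threshold sits at the positivity boundary);
#' stimulated positivity rises with subset-specific rates giving naive cells
#' low and effector-memory cells high degrees of functionality.
#'
#' @param n_events events per sample.
#' @param background_frac,doublet_frac DNA event-class fractions.
#' @return A `SimScenario` list.
#' @export
cytof_scenario <- function(n_events = 20000, background_frac = 0.08,
                           doublet_frac = 0.05) {
  channels <- c("Ir191Di", "Ir193Di", "Cd110Di", "Cd112Di", "Nd143Di",
                "Sm149Di", "Gd156Di", "Gd158Di", "Tb159Di", "Dy164Di",
                "Er166Di", "Er168Di", "Tm169Di", "Yb172Di", "Yb174Di")
  markers <- c("Ir191Di" = "DNA1", "Ir193Di" = "DNA2", "Cd110Di" = "CD3",
               "Cd112Di" = "CD8", "Nd143Di" = "CD45RA", "Sm149Di" = "CCR7",
               "Gd156Di" = "TNFa", "Gd158Di" = "IFNg", "Tb159Di" = "MIP1b",
               "Dy164Di" = "MIP1a", "Er166Di" = "IL2", "Er168Di" = "GMCSF",
               "Tm169Di" = "CD107", "Yb172Di" = "GzB", "Yb174Di" = "Perforin")
  functionals <- unname(markers[7:15])
  list(kind = "cytof", n_events = n_events,
       channels = channels, markers = markers, functionals = functionals,
       samples = c("unstim", "stim1", "stim2"),
       background_frac = background_frac, doublet_frac = doublet_frac,
       subsets = c(TN = 0.30, TCM = 0.25, TEM = 0.30, TEF = 0.15),
       # positivity probability per functional marker by subset, stimulated
       stim_rates = c(TN = 0.03, TCM = 0.25, TEM = 0.55, TEF = 0.45),
       unstim_rate = 0.01,
       func_spec = marker_spec(0.30, 0.30, 2.8, 0.45, NA),
       pheno_spec = marker_spec(0.40, 0.30, 3.2, 0.40, NA),
       dna_singlet_mean = 4.0, dna_sd = 0.15, dna_doublet_shift = log(2),
       dna_background = marker_spec(1.2, 0.40, NA, NA, NA))
}

#' Simulate the CyTOF samples
#'
#' @param scenario a [cytof_scenario()].
#' @param seed integer seed.
#' @return List with `samples`, `truth` (per sample: event class, subset,
#'   functional positivity matrix), and `metadata`.
#' @export
simulate_cytof <- function(scenario = cytof_scenario(), seed = 1) {
  scn <- scenario
  out_samples <- list(); out_truth <- list(); md_rows <- list()
  for (i in seq_along(scn$samples)) {
    cond <- scn$samples[i]
    res <- with_seed(sub_seed(seed, 1000 + i), {
      n <- scn$n_events
      u <- stats::runif(n)
      class_ <- ifelse(u < scn$background_frac, "background",
                       ifelse(u < scn$background_frac + scn$doublet_frac,
                              "doublet", "singlet"))
      dna1 <- numeric(n); dna2 <- numeric(n)
      bg <- class_ == "background"
      dna1[bg] <- stats::rnorm(sum(bg), scn$dna_background$neg_mean,
                               scn$dna_background$neg_sd)
      dna2[bg] <- stats::rnorm(sum(bg), scn$dna_background$neg_mean,
                               scn$dna_background$neg_sd)
      for (cl in c("singlet", "doublet")) {
        sel <- class_ == cl
        mu <- scn$dna_singlet_mean + (cl == "doublet") * scn$dna_doublet_shift
        dna1[sel] <- stats::rnorm(sum(sel), mu, scn$dna_sd)
        dna2[sel] <- 0.02 + 0.99 * dna1[sel] + stats::rnorm(sum(sel), 0, 0.05)
      }
      cell <- class_ == "singlet"
      is_t <- cell & stats::runif(n) < 0.8
      is_cd8 <- is_t & stats::runif(n) < 0.65
      subset <- rep(NA_character_, n)
      subset[is_cd8] <- sample(names(scn$subsets), sum(is_cd8),
                               replace = TRUE, prob = scn$subsets)
      ra_pos <- subset %in% c("TN", "TEF")
      ccr7_pos <- subset %in% c("TN", "TCM")

      ev <- matrix(0, n, length(scn$channels),
                   dimnames = list(NULL, scn$channels))
      ev[, "Ir191Di"] <- dna1
      ev[, "Ir193Di"] <- dna2
      draw <- function(spec, positive) {
        ifelse(positive, stats::rnorm(n, spec$pos_mean, spec$pos_sd),
               stats::rnorm(n, spec$neg_mean, spec$neg_sd))
      }
      mk_ch <- function(marker) names(scn$markers)[scn$markers == marker]
      ev[, mk_ch("CD3")] <- draw(scn$pheno_spec, is_t)
      ev[, mk_ch("CD8")] <- draw(scn$pheno_spec, is_cd8)
      ev[, mk_ch("CD45RA")] <- draw(scn$pheno_spec, ra_pos)
      ev[, mk_ch("CCR7")] <- draw(scn$pheno_spec, ccr7_pos)

      func_pos <- matrix(FALSE, n, length(scn$functionals),
                         dimnames = list(NULL, scn$functionals))
      for (m in scn$functionals) {
        rate <- rep(0, n)
        if (cond == "unstim") {
          rate[is_cd8] <- scn$unstim_rate
        } else {
          rate[is_cd8] <- scn$stim_rates[subset[is_cd8]]
        }
        func_pos[, m] <- stats::runif(n) < rate
        ev[, mk_ch(m)] <- draw(scn$func_spec, func_pos[, m])
      }
      list(sample = event_matrix(as_float32(ev), channels = scn$channels,
                                 markers = scn$markers,
                                 sample_id = cond,
                                 metadata = list(STIM = cond,
                                                 CONDITION = cond)),
           truth = list(class = class_, subset = subset,
                        func_pos = func_pos))
    })
    out_samples[[i]] <- res$sample
    out_truth[[cond]] <- res$truth
    md_rows[[i]] <- data.frame(sample_id = cond, STIM = cond,
                               stringsAsFactors = FALSE)
  }
  list(samples = out_samples, truth = out_truth,
       metadata = do.call(rbind, md_rows), scenario = scn)
}
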