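# Seeded synthetic-cohort generator. It emulates the structure of the
# ex vivo study: per-donor linear SCFA trajectories over 0-4 h with fiber-
# and SCFA-specific net rates, duplicate wells with multiplicative
# measurement noise, latent phenotype types separated on signature
# fiber:SCFA columns, a second visit correlated with the first, and a
# baseline OTU table with planted producer taxa and variable depth. Every
# emitted table is paired with a ground-truth record so each pipeline stage
# has a parameter-recovery test.

# Expected pair CV (%) of two iid lognormal replicates with log-sd sigma:
# CV_pair = 100 * sqrt(2) * |a-b| / (a+b) in expectation equals
# 100 * sqrt(2) * E|tanh(sigma * D / sqrt(2))| with D ~ N(0,1).
expected_pair_cv <- function(sigma) {
  if (sigma == 0) return(0)
  100 * sqrt(2) * 2 * integrate(function(d)
    tanh(sigma * d / sqrt(2)) * dnorm(d), 0, Inf)$value
}

#' Lognormal noise scale for a target replicate CV
#'
#' Solves for the log-scale sd `sigma` of multiplicative lognormal
#' measurement noise such that the expected per-pair coefficient of
#' variation (as computed by [replicate_cv()]) equals `target_cv` percent.
#'
#' @param target_cv Target overall replicate CV in percent.
#' @return `sigma` (log-scale sd).
#' @export
pair_cv_sigma <- function(target_cv) {
  stopifnot(target_cv >= 0)
  if (target_cv == 0) return(0)
  uniroot(function(s) expected_pair_cv(s) - target_cv,
          interval = c(1e-6, 3), tol = 1e-10)$root
}

default_type_spec <- function() {
  # Two fiber-specialist phenotypes with a producer/non-producer contrast:
  # each type ferments its preferred fiber into all three SCFAs well above
  # the cohort base rate and the opposite fiber at or near zero (rate draws
  # are truncated at 0, so roughly half the cohort are non-producers for a
  # given fiber:SCFA pair). Signature-column separation is well above 2
  # between-donor sd.
  base <- c("inulin:acetate" = 1.5, "inulin:propionate" = 1.1,
            "inulin:butyrate" = 0.9, "pectin:acetate" = 1.5,
            "pectin:propionate" = 1.1, "pectin:butyrate" = 0.9)
  sdv <- 0.7
  up <- c(acetate = 1.2, propionate = 1.1, butyrate = 0.9)
  shift <- function(fiber_up, fiber_dn) {
    s <- setNames(numeric(6), names(base))
    s[paste0(fiber_up, ":", names(up))] <- up
    s[paste0(fiber_dn, ":", names(up))] <- -up
    s
  }
  list(
    `Type I` = list(mean = base + shift("inulin", "pectin"), sd = sdv),
    `Type II` = list(mean = base + shift("pectin", "inulin"), sd = sdv)
  )
}

default_otu_spec <- function() {
  list(n_otus = 150L,
       meanlog_sd = 2,       # spread of OTU mean log-abundances
       donor_sd = 1,         # donor-to-donor log-abundance sd per OTU
       producers = list(
         # producer guilds: each linked phenotype has one strong, abundant
         # lead OTU (base_meanlog on the OTU mean log-abundance scale)
         # plus accessory members with smaller shifts — SCFA production
         # phenotypes associate with several taxa, not a single OTU
         list(otu = "OTU1", fiber = "inulin", scfa = "propionate",
              effect = 2, base_meanlog = 2,
              taxonomy = "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Prevotellaceae;Prevotella;copri-like (synthetic)"),
         list(otu = "OTU3", fiber = "inulin", scfa = "propionate",
              effect = 1, base_meanlog = 1,
              taxonomy = "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Prevotellaceae;Prevotella;unassigned"),
         list(otu = "OTU4", fiber = "inulin", scfa = "propionate",
              effect = 1, base_meanlog = 1,
              taxonomy = "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Bacteroidaceae;Bacteroides;unassigned"),
         list(otu = "OTU2", fiber = "inulin", scfa = "butyrate",
              effect = 2, base_meanlog = 2,
              taxonomy = "Bacteria;Firmicutes;Clostridia;Clostridiales;Lachnospiraceae;unassigned;unassigned"),
         list(otu = "OTU5", fiber = "inulin", scfa = "butyrate",
              effect = 1, base_meanlog = 1,
              taxonomy = "Bacteria;Firmicutes;Clostridia;Clostridiales;Lachnospiraceae;Roseburia;unassigned"),
         list(otu = "OTU6", fiber = "inulin", scfa = "butyrate",
              effect = 1, base_meanlog = 1,
              taxonomy = "Bacteria;Firmicutes;Clostridia;Clostridiales;Ruminococcaceae;Faecalibacterium;unassigned")
       ),
       # community-wide signature: fermentation phenotypes track broad
       # compositional structure, so several taxa are weakly enriched
       # (positive effect) or depleted (negative) in high producers
       signature = list(fiber = "inulin", scfa = "propionate",
                        n_up = 4L, n_down = 4L, effect = 0.7,
                        base_meanlog = 0.5),
       depth_meanlog = log(2e4), depth_sdlog = 0.5,
       shallow_fraction = 0.025, shallow_range = c(500L, 4999L))
}

#' Synthetic cohort configuration
#'
#' Collects and validates every knob of the generator. Defaults mirror the
#' study conditions: 40 donors, conditions control/cellulose/inulin/pectin
#' sampled at 0/2/4 h in duplicate, replicate noise targeting an overall
#' 23.5% CV, two latent phenotype types with signature-column separation of
#' 2 between-donor sd, a second visit with persistence 0.9, and a baseline
#' OTU table (150 OTUs, lognormal abundances, ~20k reads with a small
#' shallow-sample fraction) carrying two planted producer OTUs.
#'
#' @param seed Mandatory integer root seed; named substreams (rates, noise,
#'   otus, depths) are derived from it.
#' @param n_donors Number of donors (default 40).
#' @param timepoints Sampling times in hours (default 0, 2, 4).
#' @param replicates Wells per timepoint (default 2).
#' @param replicate_noise_cv Target overall replicate CV in percent
#'   (default 23.5); 0 gives noiseless data. Replicate noise is a per-well
#'   lognormal scale factor shared along a well's trajectory (duplicate
#'   wells are separate cultures whose inoculum density scales every
#'   measurement from that well; per-injection analytical error is small
#'   against this and absorbed into the factor).
#' @param type_spec Named list of phenotype types, each with `mean` (named
#'   vector over the six fiber:SCFA columns, mM/h) and `sd` (between-donor).
#' @param control_rate `c(mean, sd)` of per-donor control (no spike-in)
#'   production rates in mM/h (default 0.15, 0.08).
#' @param baseline_conc `c(mean, sd)` of the 0 h concentration in mM
#'   (default 1.0, 0.3).
#' @param donor_activity_sdlog Log-sd of a per-donor lognormal "overall
#'   fermentation activity" factor multiplying all of a donor's rates
#'   (microbial-load heterogeneity between stools; default 0.5).
#' @param visit2_persistence Correlation-like persistence rho in \[0, 1\]:
#'   visit-2 rates are `rho * visit1 + (1 - rho) * fresh draw` (the fresh
#'   draw has its own activity factor; default 0.9).
#' @param otu_spec OTU-table spec as in the default (see Details), or
#'   `NULL` to skip OTU generation.
#' @return Validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(seed,
                          n_donors = 40L,
                          timepoints = c(0, 2, 4),
                          replicates = 2L,
                          replicate_noise_cv = 23.5,
                          type_spec = default_type_spec(),
                          control_rate = c(mean = 0.15, sd = 0.08),
                          baseline_conc = c(mean = 1.0, sd = 0.3),
                          donor_activity_sdlog = 0.5,
                          visit2_persistence = 0.9,
                          otu_spec = default_otu_spec()) {
  problems <- character()
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    problems <- c(problems, "seed (mandatory integer)")
  if (!is.numeric(n_donors) || n_donors < 2) problems <- c(problems, "n_donors")
  if (length(timepoints) < 2L || any(timepoints < 0))
    problems <- c(problems, "timepoints")
  if (replicates < 1) problems <- c(problems, "replicates")
  if (replicate_noise_cv < 0) problems <- c(problems, "replicate_noise_cv")
  if (visit2_persistence < 0 || visit2_persistence > 1)
    problems <- c(problems, "visit2_persistence")
  if (donor_activity_sdlog < 0) problems <- c(problems, "donor_activity_sdlog")
  if (!is.list(type_spec) || !length(type_spec) ||
      !all(vapply(type_spec, function(t)
        is.numeric(t$mean) && length(t$mean) == 6L && is.numeric(t$sd),
        TRUE)))
    problems <- c(problems, "type_spec")
  if (length(problems))
    stop("invalid cohort config field(s): ", paste(problems, collapse = ", "))
  structure(list(seed = as.integer(seed), n_donors = as.integer(n_donors),
                 timepoints = timepoints, replicates = as.integer(replicates),
                 replicate_noise_cv = replicate_noise_cv,
                 type_spec = type_spec, control_rate = control_rate,
                 baseline_conc = baseline_conc,
                 donor_activity_sdlog = donor_activity_sdlog,
                 visit2_persistence = visit2_persistence,
                 otu_spec = otu_spec),
            class = "cohort_config")
}

# independent substreams from the root seed (kept below 2^31)
substream_seed <- function(seed, stream) {
  offs <- c(rates = 1L, noise = 2L, otus = 3L, depths = 4L)
  as.integer((as.numeric(seed) + offs[[stream]] * 1000003) %% 2147483647)
}

mmp_columns <- function() as.vector(t(outer(c("inulin", "pectin"),
                                            scfa_names(), paste, sep = ":")))

# one full rate draw: per-donor activity factor times truncated-normal
# type-conditional rates; also control rates (scaled by the same activity)
draw_rates <- function(config, types) {
  cols <- mmp_columns()
  n <- config$n_donors
  sg <- config$donor_activity_sdlog
  activity <- rlnorm(n, -sg^2 / 2, sg)
  phi <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  for (i in seq_len(n)) {
    spec <- config$type_spec[[types[i]]]
    phi[i, ] <- activity[i] * pmax(0, rnorm(length(cols), spec$mean[cols],
                                            spec$sd))
  }
  ctrl <- activity * matrix(pmax(0, rnorm(n * 3,
                                          config$control_rate[["mean"]],
                                          config$control_rate[["sd"]])),
                            n, 3, dimnames = list(NULL, scfa_names()))
  list(phi = phi, control = ctrl, activity = activity)
}

#' Generate a complete synthetic cohort
#'
#' Produces two visits of SCFA concentration data in the long layout of
#' [read_scfa_table()], an optional baseline OTU table with planted
#' producer OTUs, phenotype-type labels, and the full ground truth.
#' Concentrations follow `C(t) = C0 + (phi_control + phi_fiber) * t`
#' measured in duplicate with multiplicative lognormal noise calibrated by
#' [pair_cv_sigma()]; the cellulose condition has `phi_fiber = 0`. Producer
#' OTUs are shifted up in log-abundance (by `effect` donor-sd units) in
#' donors whose linked visit-1 rate is above the cohort median. Output is
#' byte-reproducible for a fixed seed.
#'
#' @param config A [cohort_config()].
#' @return List of class `"mmp_cohort"`: `scfa_visit1`, `scfa_visit2`
#'   (long data frames), `otu` ([otu_tab()] or `NULL`), `truth` (list:
#'   `types`, `phi_visit1`, `phi_visit2`, `control_phi`, `c0`,
#'   `producer_otus`, `depth_class`, `noise_sigma`), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  donors <- sprintf("D%02d", seq_len(config$n_donors))
  type_names <- rep_len(names(config$type_spec), config$n_donors)
  cols <- mmp_columns()

  truth <- withr::with_seed(substream_seed(config$seed, "rates"), {
    types <- setNames(type_names, donors)
    d1 <- draw_rates(config, type_names)
    # the visit-2 fresh component is a draw from the cohort marginal:
    # at rho = 0 a donor's phenotype (type membership included) is
    # unrelated to visit 1
    fresh_types <- sample(names(config$type_spec), config$n_donors,
                          replace = TRUE)
    fresh <- draw_rates(config, fresh_types)
    rho <- config$visit2_persistence
    name_rows <- function(m) { rownames(m) <- donors; m }
    c0 <- matrix(pmax(0, rnorm(config$n_donors * 3,
                               config$baseline_conc[["mean"]],
                               config$baseline_conc[["sd"]])),
                 config$n_donors, 3, dimnames = list(donors, scfa_names()))
    list(types = types,
         phi_visit1 = name_rows(d1$phi),
         phi_visit2 = name_rows(rho * d1$phi + (1 - rho) * fresh$phi),
         control_phi = name_rows(d1$control),
         control_phi_visit2 = name_rows(rho * d1$control +
                                          (1 - rho) * fresh$control),
         activity = setNames(d1$activity, donors), c0 = c0)
  })

  sigma <- pair_cv_sigma(config$replicate_noise_cv)
  truth$noise_sigma <- sigma

  grid <- expand.grid(replicate = seq_len(config$replicates),
                      timepoint_h = config$timepoints,
                      scfa = scfa_names(),
                      condition = condition_names(),
                      donor = donors,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("donor", "condition", "timepoint_h", "replicate", "scfa")]
  fiber_phi <- function(phi, donor, condition, scfa) {
    out <- numeric(length(donor))
    is_fib <- condition %in% c("inulin", "pectin")
    out[is_fib] <- phi[cbind(donor[is_fib],
                             paste(condition[is_fib], scfa[is_fib], sep = ":"))]
    out   # control and cellulose: no fiber-attributable production
  }
  # one culture well = (donor, condition, replicate); its lognormal scale
  # factor multiplies every timepoint and SCFA measured from that well
  well_id <- interaction(grid$donor, grid$condition, grid$replicate,
                         drop = TRUE)
  make_visit <- function(phi, ctrl) {
    ph <- fiber_phi(phi, grid$donor, grid$condition, grid$scfa) +
      ctrl[cbind(grid$donor, grid$scfa)]
    c_true <- truth$c0[cbind(grid$donor, grid$scfa)] + ph * grid$timepoint_h
    well_f <- if (sigma > 0)
      exp(sigma * rnorm(nlevels(well_id)) - sigma^2 / 2)[as.integer(well_id)]
    else 1
    data.frame(grid, conc_mM = c_true * well_f, stringsAsFactors = FALSE)
  }
  visits <- withr::with_seed(substream_seed(config$seed, "noise"),
                             list(make_visit(truth$phi_visit1,
                                             truth$control_phi),
                                  make_visit(truth$phi_visit2,
                                             truth$control_phi_visit2)))

  otu <- NULL
  if (!is.null(config$otu_spec)) {
    spec <- config$otu_spec
    otu_ids <- paste0("OTU", seq_len(spec$n_otus))
    logab <- withr::with_seed(substream_seed(config$seed, "otus"), {
      m <- rnorm(spec$n_otus, 0, spec$meanlog_sd)
      names(m) <- otu_ids
      for (p in spec$producers) m[p$otu] <- p$base_meanlog %||% 2
      la <- matrix(rnorm(config$n_donors * spec$n_otus, 0, spec$donor_sd),
                   config$n_donors, spec$n_otus,
                   dimnames = list(donors, otu_ids))
      sweep(la, 2L, m, "+")
    })
    sig <- spec$signature
    if (!is.null(sig)) {
      # signature OTUs take the next free IDs after the named producers
      used <- vapply(spec$producers, `[[`, "", "otu")
      free <- setdiff(otu_ids, used)
      sig_ids <- free[seq_len(sig$n_up + sig$n_down)]
      linked <- truth$phi_visit1[, paste(sig$fiber, sig$scfa, sep = ":")]
      hi <- (linked - mean(linked)) / sd(linked) >= 0
      eff <- rep(c(sig$effect, -sig$effect), c(sig$n_up, sig$n_down))
      for (j in seq_along(sig_ids)) {
        logab[, sig_ids[j]] <- logab[, sig_ids[j]] +
          (sig$base_meanlog - mean(logab[, sig_ids[j]]))
        logab[hi, sig_ids[j]] <- logab[hi, sig_ids[j]] +
          eff[j] * spec$donor_sd
      }
      truth$signature_otus <- setNames(eff, sig_ids)
    }
    producer_truth <- list()
    for (p in spec$producers) {
      # shift producers in donors that are high-class for the linked rate,
      # using the same z >= 0 rule that defines high/low downstream so the
      # planted between-class abundance effect keeps its stated size
      linked <- truth$phi_visit1[, paste(p$fiber, p$scfa, sep = ":")]
      hi <- (linked - mean(linked)) / sd(linked) >= 0
      logab[hi, p$otu] <- logab[hi, p$otu] + p$effect * spec$donor_sd
      producer_truth[[p$otu]] <- list(fiber = p$fiber, scfa = p$scfa,
                                      effect = p$effect,
                                      high_donors = donors[hi])
    }
    rel <- exp(logab) / rowSums(exp(logab))
    dres <- withr::with_seed(substream_seed(config$seed, "depths"), {
      shallow <- runif(config$n_donors) < spec$shallow_fraction
      depth <- ifelse(shallow,
                      round(runif(config$n_donors, spec$shallow_range[1L],
                                  spec$shallow_range[2L])),
                      round(rlnorm(config$n_donors, spec$depth_meanlog,
                                   spec$depth_sdlog)))
      counts <- t(vapply(seq_len(config$n_donors), function(i)
        rmultinom(1L, depth[i], rel[i, ])[, 1L], integer(spec$n_otus)))
      dimnames(counts) <- dimnames(rel)
      list(counts = counts, shallow = shallow)
    })
    taxonomy <- synthetic_taxonomy(otu_ids, spec,
                                   seed = substream_seed(config$seed, "otus"))
    otu <- otu_tab(dres$counts, taxonomy)
    truth$producer_otus <- producer_truth
    truth$depth_class <- setNames(ifelse(dres$shallow, "shallow", "normal"),
                                  donors)
    truth$rel_abundance <- rel
  }

  structure(list(scfa_visit1 = visits[[1L]], scfa_visit2 = visits[[2L]],
                 otu = otu, truth = truth, config = config),
            class = "mmp_cohort")
}

# deterministic synthetic lineages; producer OTUs keep their stated taxonomy
synthetic_taxonomy <- function(otu_ids, spec, seed) {
  phyla <- c("Firmicutes", "Bacteroidetes", "Actinobacteria",
             "Proteobacteria", "Verrucomicrobia")
  families <- c("Lachnospiraceae", "Ruminococcaceae", "Bacteroidaceae",
                "Prevotellaceae", "Bifidobacteriaceae", "Enterobacteriaceae",
                "Akkermansiaceae", "unassigned")
  tax <- withr::with_seed(seed, {
    ph <- sample(phyla, length(otu_ids), replace = TRUE)
    fa <- sample(families, length(otu_ids), replace = TRUE)
    sprintf("Bacteria;%s;class_%s;order_%s;%s;genus_%s;unassigned",
            ph, substr(ph, 1, 3), substr(fa, 1, 3), fa,
            seq_along(otu_ids))
  })
  names(tax) <- otu_ids
  for (p in spec$producers) tax[p$otu] <- p$taxonomy
  tax
}

#' Write a synthetic cohort to disk
#'
#' Emits the same formats [read_scfa_table()] and [read_otu_table()]
#' consume: `scfa_visit1.tsv`, `scfa_visit2.tsv`, `otu_counts.tsv`
#' (samples in columns, taxonomy as trailing column), `labels.tsv`
#' (donor, type) and `truth.json`.
#'
#' @param cohort An `"mmp_cohort"` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param dialect Sample-ID dialect for the SCFA tables.
#' @return Named vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, dialect = "A") {
  stopifnot(inherits(cohort, "mmp_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(scfa_visit1 = file.path(dir, "scfa_visit1.tsv"),
             scfa_visit2 = file.path(dir, "scfa_visit2.tsv"),
             labels = file.path(dir, "labels.tsv"),
             truth = file.path(dir, "truth.json"))
  write_scfa_table(cohort$scfa_visit1, paths[["scfa_visit1"]], dialect)
  write_scfa_table(cohort$scfa_visit2, paths[["scfa_visit2"]], dialect)
  write.table(data.frame(donor = names(cohort$truth$types),
                         type = unname(cohort$truth$types)),
              paths[["labels"]], sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$phi_visit1 <- as.data.frame(truth$phi_visit1)
  truth$phi_visit2 <- as.data.frame(truth$phi_visit2)
  truth$control_phi <- as.data.frame(truth$control_phi)
  truth$c0 <- as.data.frame(truth$c0)
  truth$rel_abundance <- NULL
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(cohort$otu)) {
    paths[["otu"]] <- file.path(dir, "otu_counts.tsv")
    write_otu_table(cohort$otu, paths[["otu"]])
  }
  invisible(paths)
}

#' Deterministic worked-example fixtures
#'
#' Small hand-constructed objects used across the documentation and test
#' suite: a two-donor wide SCFA table, a 3x5 OTU count table with taxonomy,
#' a 2x2 stability contingency table, and a four-donor MMP matrix made of
#' two exact duplicate row pairs.
#'
#' @return Named list `scfa_two_donor`, `otu_3x5`, `contingency`,
#'   `mmp_two_block`.
#' @export
generate_worked_examples <- function() {
  scfa <- data.frame(
    sample_id = c("A-Inul-02", "B-Inul-02"),
    replicate = c(1L, 1L),
    acetate = c(5.0, 7.5), propionate = c(2.0, 3.0), butyrate = c(1.0, 1.5),
    stringsAsFactors = FALSE)
  counts <- matrix(c(2L, 3L, 5L,
                     0L, 10L, 0L,
                     1L, 1L, 8L,
                     4L, 0L, 6L,
                     3L, 6L, 1L), nrow = 3L,
                   dimnames = list(paste0("S", 1:3), paste0("OTU", 1:5)))
  tax <- setNames(c(
    "Bacteria;Firmicutes;Clostridia;Clostridiales;Lachnospiraceae;Blautia;unassigned",
    "Bacteria;Firmicutes;Clostridia;Clostridiales;Lachnospiraceae;Roseburia;unassigned",
    "Bacteria;Firmicutes;Clostridia;Clostridiales;Lachnospiraceae;unassigned;unassigned",
    "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Prevotellaceae;Prevotella;copri-like (synthetic)",
    "Bacteria;Firmicutes;Clostridia;Clostridiales;Ruminococcaceae;Faecalibacterium;unassigned"),
    paste0("OTU", 1:5))
  mmp <- matrix(c(2, 2, -1, -1,
                  0, 0, 1, 1,
                  1, 1, 0, 0,
                  -1, -1, 2, 2,
                  0.5, 0.5, -0.5, -0.5,
                  0, 0, 0, 0),
                nrow = 4L,
                dimnames = list(c("D1", "D2", "D3", "D4"), mmp_columns()))
  attr(mmp, "scale") <- "raw"
  list(scfa_two_donor = scfa,
       otu_3x5 = otu_tab(counts, tax),
       contingency = matrix(c(3L, 1L, 1L, 3L), 2L,
                            dimnames = list(visit1 = c("high", "low"),
                                            visit2 = c("high", "low"))),
       mmp_two_block = mmp)
}
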