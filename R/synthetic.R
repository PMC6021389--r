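# severity positions of a node's states on [0, 1]
severity_scale <- function(k) if (k == 1L) 0 else (seq_len(k) - 1) / (k - 1)

# unimodal distribution over k ordered states peaked at position t in [0,1];
# w is the concentration (per squared level-unit distance): larger w = a
# sharper, stronger dependence
peaked_probs <- function(k, t, w) {
  d <- (severity_scale(k) - t) * (k - 1)
  p <- exp(-w * d^2)
  p / sum(p)
}

# CPT over child states given named parent severity maps and mixing weights
make_ordinal_cpt <- function(child, child_levels, parent_levels,
                             parent_severity, weights, w, shift = 0) {
  k <- length(child_levels)
  if (!length(parent_levels)) {
    probs <- peaked_probs(k, shift, w)
    dn <- stats::setNames(list(child_levels), child)
    return(array(probs, dim = k, dimnames = dn))
  }
  dims <- vapply(parent_levels, length, integer(1))
  q <- prod(dims)
  grid <- arrayInd(seq_len(q), .dim = dims)
  weights <- weights / sum(weights)
  probs <- matrix(NA_real_, k, q)
  for (j in seq_len(q)) {
    sev <- vapply(seq_along(dims), function(i) {
      parent_severity[[i]][grid[j, i]]
    }, numeric(1))
    t <- min(1, max(0, sum(weights * sev) + shift))
    probs[, j] <- peaked_probs(k, t, w)
  }
  dn <- c(stats::setNames(list(child_levels), child), parent_levels)
  array(probs, dim = c(k, dims), dimnames = dn)
}

#' Ground-truth generator network
#'
#' A nine-node discrete Bayesian network over the severity-modelling
#' variables: age and ApoE drive the imaging biomarkers (PiB-PET amyloid
#' burden, grey-matter atrophy, CSF volume), the biomarkers drive the
#' three-class CDR severity, and CDR drives the cognitive assessments (MMSE,
#' LMDR, LMIR, with an extra LMDR -> LMIR dependence).  Cognitive links are
#' strong and biomarker-to-severity links deliberately weaker, reproducing
#' the qualitative regime the pipeline is meant to detect.
#'
#' @param strength_cognitive concentration of the CDR -> assessment CPTs.
#' @param strength_biomarker concentration of the biomarker CPTs.
#' @param strength_severity concentration of the biomarker -> CDR CPT.
#' @return a fitted `bn_model` usable with [sample_from_network()] and
#'   [predict_class()].
#' @export
default_truth_network <- function(strength_cognitive = 3,
                                  strength_biomarker = 2,
                                  strength_severity = 1.8) {
  lv3 <- function(nm) paste0(nm, 1:3)
  nodes <- list(
    age = lv3("age"), ApoE = apoe_genotypes(),
    PiB_PET = lv3("pib"), GM = lv3("gm"), CSF = lv3("csf"),
    CDR = c("normal", "very mild", "mild/moderate"),
    MMSE = c("24-30", "19-23", "10-18", "0-9"),
    LMDR = lv3("lmdr"), LMIR = lv3("lmir"))
  sev <- lapply(nodes, function(lv) severity_scale(length(lv)))
  sev$ApoE <- c(0, 0.05, 0.75, 0.8, 1)   # epsilon-4 dose effect
  edges <- rbind(
    c("age", "PiB_PET"), c("age", "GM"), c("age", "CSF"),
    c("ApoE", "PiB_PET"),
    c("PiB_PET", "GM"), c("PiB_PET", "CSF"), c("GM", "CSF"),
    c("CSF", "CDR"), c("GM", "CDR"), c("PiB_PET", "CDR"),
    c("CDR", "MMSE"), c("CDR", "LMDR"), c("CDR", "LMIR"),
    c("LMDR", "LMIR"))
  colnames(edges) <- c("from", "to")
  cpt <- function(child, parents, weights, w, shift = 0) {
    make_ordinal_cpt(child, nodes[[child]],
                     stats::setNames(nodes[parents], parents),
                     sev[parents], weights, w, shift)
  }
  wb <- strength_biomarker; ws <- strength_severity; wc <- strength_cognitive
  cpts <- list(
    age = array(c(0.35, 0.40, 0.25), dim = 3,
                dimnames = stats::setNames(list(nodes$age), "age")),
    ApoE = array(c(0.12, 0.55, 0.03, 0.25, 0.05), dim = 5,
                 dimnames = stats::setNames(list(nodes$ApoE), "ApoE")),
    PiB_PET = cpt("PiB_PET", c("age", "ApoE"), c(0.25, 0.75), wb),
    GM = cpt("GM", c("age", "PiB_PET"), c(0.5, 0.5), wb),
    CSF = cpt("CSF", c("age", "GM", "PiB_PET"), c(0.3, 0.4, 0.3), wb),
    CDR = cpt("CDR", c("CSF", "GM", "PiB_PET"), c(0.45, 0.35, 0.2), ws,
              shift = -0.22),
    MMSE = cpt("MMSE", "CDR", 1, wc),
    LMDR = cpt("LMDR", "CDR", 1, wc * 0.85),
    LMIR = cpt("LMIR", c("CDR", "LMDR"), c(0.6, 0.4), wc * 0.7))
  structure(list(nodes = nodes, edges = edges, cpts = cpts,
                 score_used = "generator", score_value = NA_real_),
            class = "bn_model")
}

# continuous emission models that map a network node's discrete state to a
# raw feature value, plus CDR-independent noise models for the remaining
# dictionary features
default_feature_models <- function() {
  emission <- function(node, means, sd) {
    list(type = "emission", node = node, means = means, sd = sd)
  }
  noise <- function(mean, sd) list(type = "noise", mean = mean, sd = sd)
  cat_noise <- function(levels, probs) {
    list(type = "cat_noise", levels = levels, probs = probs)
  }
  blood_means <- c(cholesterol = 5.2, hdl = 1.4, ldl = 3.1,
                   triglycerides = 1.5, glucose = 5.4, hba1c = 5.6,
                   creatinine = 80, urea = 6.0, haemoglobin = 140,
                   platelets = 250, wbc_count = 6.5, vitamin_b12 = 350)
  blood_sds <- c(1.0, 0.35, 0.9, 0.7, 0.9, 0.5, 15, 1.6, 12, 55, 1.7, 120)
  models <- list(
    age = emission("age", c(68, 75, 82), 3),
    ApoE = list(type = "direct", node = "ApoE"),
    GM = emission("GM", c(640, 600, 560), 18),
    CSF = emission("CSF", c(280, 320, 360), 18),
    PiB_PET = emission("PiB_PET", c(300, 900, 1600), 180),
    MMSE = emission("MMSE", c(27.5, 21, 14, 5), 1.5),
    LMIR = emission("LMIR", c(12, 7, 3), 1.8),
    LMDR = emission("LMDR", c(11, 6, 2), 1.8),
    sex = cat_noise(c("F", "M"), c(0.55, 0.45)),
    WM = noise(480, 40)
  )
  for (i in seq_along(blood_means)) {
    models[[names(blood_means)[i]]] <- noise(blood_means[[i]], blood_sds[[i]])
  }
  for (f in c("hypertension", "diabetes", "stroke_history", "depression",
              "cardiovascular_disease", "thyroid_disorder", "smoking_history",
              "arthritis", "cancer_history", "neurological_history")) {
    p <- switch(f, hypertension = 0.35, diabetes = 0.10, depression = 0.15,
                smoking_history = 0.30, arthritis = 0.25, 0.08)
    models[[f]] <- cat_noise(c("no", "yes"), c(1 - p, p))
  }
  models
}

# missingness is modality-structured, as in real ageing cohorts: a skipped
# MRI session drops all three volume features at once, a skipped PET scan
# drops the amyloid count, a missed blood draw drops the whole panel
default_missing_blocks <- function() {
  list(mri = c("GM", "WM", "CSF"),
       pet = "PiB_PET",
       blood_panel = c("cholesterol", "hdl", "ldl", "triglycerides",
                       "glucose", "hba1c", "creatinine", "urea",
                       "haemoglobin", "platelets", "wbc_count",
                       "vitamin_b12"),
       medical_history = c("hypertension", "diabetes", "stroke_history",
                           "depression", "cardiovascular_disease",
                           "thyroid_disorder", "smoking_history",
                           "arthritis", "cancer_history",
                           "neurological_history"))
}

default_missing_rates <- function() {
  rates <- stats::setNames(rep(0, length(default_dictionary())),
                           names(default_dictionary()))
  rates[default_missing_blocks()$mri] <- 0.25
  rates["PiB_PET"] <- 0.35
  rates[default_missing_blocks()$blood_panel] <- 0.05
  rates[default_missing_blocks()$medical_history] <- 0.03
  rates["ApoE"] <- 0.02
  rates[c("MMSE", "LMIR", "LMDR")] <- 0.01
  rates
}

# P(diagnosis | raw CDR); columns HC / MCI / AD
default_diagnosis_model <- function() {
  m <- rbind(`0`   = c(0.950, 0.045, 0.005),
             `0.5` = c(0.150, 0.700, 0.150),
             `1`   = c(0.020, 0.180, 0.800),
             `2`   = c(0.005, 0.045, 0.950))
  colnames(m) <- c("HC", "MCI", "AD")
  m
}

#' Simulation specification for a synthetic cohort
#'
#' Defaults emulate the shape of a community ageing study: 861 subjects at
#' baseline with 18-monthly follow-up retention of roughly 30\% / 26\% /
#' 17\%, a severity mix dominated by cognitively normal subjects
#' (prevalences 0.72 / 0.21 / 0.05 / 0.02 over CDR 0 / 0.5 / 1 / 2), a
#' small per-visit probability of progressing one severity class, and
#' modality-structured missingness (the MRI volume block 25\%, amyloid PET
#' 35\%, the blood panel 5\%, lighter rates elsewhere).
#'
#' @param n_subjects number of subjects enrolled at baseline.
#' @param visit_retention named probabilities of follow-up at M18/M36/M54.
#' @param class_prevalence probabilities over raw CDR classes 0/0.5/1/2
#'   (must sum to 1 within 1e-9).
#' @param progression_drift per-visit probability of moving up one class.
#' @param missing_rate named per-feature masking probabilities.
#' @param missing_blocks list of feature blocks masked jointly (one draw per
#'   block per record, at the block's maximum member rate).
#' @param truth the generator network ([default_truth_network()]).
#' @param feature_models per-feature emission / noise models.
#' @param diagnosis_model P(diagnosis | raw CDR) matrix.
#' @param seed integer seed.
#' @return an object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_subjects = 861L,
                            visit_retention = c(M18 = 0.30, M36 = 0.26, M54 = 0.17),
                            class_prevalence = c(`0` = 0.72, `0.5` = 0.21,
                                                 `1` = 0.05, `2` = 0.02),
                            progression_drift = 0.08,
                            missing_rate = default_missing_rates(),
                            missing_blocks = default_missing_blocks(),
                            truth = default_truth_network(),
                            feature_models = default_feature_models(),
                            diagnosis_model = default_diagnosis_model(),
                            seed = 1L) {
  bad <- character()
  if (!is.numeric(n_subjects) || n_subjects < 1) bad <- c(bad, "n_subjects")
  if (length(visit_retention) != 3L || any(visit_retention < 0) ||
      any(visit_retention > 1)) bad <- c(bad, "visit_retention")
  if (abs(sum(class_prevalence) - 1) > 1e-9 || any(class_prevalence < 0))
    bad <- c(bad, "class_prevalence")
  if (progression_drift < 0 || progression_drift > 1)
    bad <- c(bad, "progression_drift")
  if (any(missing_rate < 0) || any(missing_rate >= 1))
    bad <- c(bad, "missing_rate")
  sds <- unlist(lapply(feature_models, function(m) m$sd))
  if (any(sds <= 0)) bad <- c(bad, "feature_models")
  if (length(bad))
    stop_adbn("adbn_validation_error", "invalid simulation spec field(s): %s",
              paste(bad, collapse = ", "))
  structure(list(n_subjects = as.integer(n_subjects),
                 visit_retention = visit_retention,
                 class_prevalence = class_prevalence,
                 progression_drift = progression_drift,
                 missing_rate = missing_rate,
                 missing_blocks = missing_blocks,
                 truth = truth, feature_models = feature_models,
                 diagnosis_model = diagnosis_model, seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

# sample the truth network conditionally on a vector of required CDR states
# (exact conditional draws by batched rejection sampling)
conditional_network_sample <- function(truth, cdr_states, seed) {
  n <- length(cdr_states)
  nodes <- names(truth$nodes)
  out <- as.data.frame(matrix(NA_character_, n, length(nodes),
                              dimnames = list(NULL, nodes)),
                       stringsAsFactors = FALSE)
  need <- table(factor(cdr_states, levels = truth$nodes$CDR))
  batch_seed <- substream_seed(seed, "conditional_sample")
  pool <- list()
  attempt <- 0L
  while (any(vapply(truth$nodes$CDR, function(cl) {
    got <- if (is.null(pool[[cl]])) 0L else nrow(pool[[cl]])
    got < need[[cl]]
  }, TRUE))) {
    attempt <- attempt + 1L
    if (attempt > 200L)
      stop_adbn("adbn_validation_error",
                "conditional sampling failed: a CDR class has negligible mass")
    draw <- sample_from_network(truth, max(5000L, 4L * n),
                                seed = batch_seed + attempt)
    for (cl in truth$nodes$CDR) {
      sel <- draw[draw$CDR == cl, , drop = FALSE]
      pool[[cl]] <- if (is.null(pool[[cl]])) sel else rbind(pool[[cl]], sel)
    }
  }
  used <- stats::setNames(rep(0L, length(truth$nodes$CDR)), truth$nodes$CDR)
  for (i in seq_len(n)) {
    cl <- cdr_states[i]
    used[cl] <- used[cl] + 1L
    out[i, ] <- vapply(nodes, function(v) as.character(pool[[cl]][[v]][used[cl]]),
                       "")
  }
  out
}

merge_cdr <- function(raw) {
  map <- c("0" = "normal", "0.5" = "very mild",
           "1" = "mild/moderate", "2" = "mild/moderate", "3" = NA)
  unname(map[as.character(raw)])
}

#' Generate a synthetic longitudinal cohort
#'
#' Per subject-visit the raw CDR score is drawn from the class prevalences
#' (with per-visit progression drift); the eight signal features (age, ApoE,
#' GM, CSF, PiB-PET, MMSE, LMIR, LMDR) are then drawn jointly from the
#' ground-truth network conditional on the merged CDR class and emitted as
#' continuous values around state-specific means; the remaining dictionary
#' features are severity-independent noise; finally values are masked at the
#' per-feature missing rates.  Fully reproducible for a fixed seed.
#'
#' @param spec a [cohort_sim_spec()].
#' @return a [cohort_table()] carrying the generating discrete states as
#'   attribute `latent_states`.
#' @export
generate_cohort <- function(spec = cohort_sim_spec()) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  dict <- default_dictionary()
  n <- spec$n_subjects
  subj <- sprintf("S%04d", seq_len(n))

  # visit structure
  set.seed(substream_seed(spec$seed, "visits"))
  visits <- data.frame(subject_id = subj, visit = "BL",
                       stringsAsFactors = FALSE)
  for (v in c("M18", "M36", "M54")) {
    keep <- stats::runif(n) < spec$visit_retention[[v]]
    visits <- rbind(visits, data.frame(subject_id = subj[keep], visit = v))
  }
  visits <- visits[order(visits$subject_id,
                         match(visits$visit, visit_levels())), ]
  rownames(visits) <- NULL
  m <- nrow(visits)

  # raw CDR per subject-visit, with progression drift
  set.seed(substream_seed(spec$seed, "cdr"))
  raw_levels <- names(spec$class_prevalence)
  baseline_cdr <- sample(raw_levels, n, replace = TRUE,
                         prob = spec$class_prevalence)
  names(baseline_cdr) <- subj
  cdr <- character(m)
  current <- baseline_cdr
  for (v in visit_levels()) {
    rows <- which(visits$visit == v)
    if (v != "BL") {
      subset_ids <- visits$subject_id[rows]
      move <- stats::runif(length(rows)) < spec$progression_drift
      pos <- match(current[subset_ids], raw_levels)
      pos <- pmin(pos + move, length(raw_levels))
      current[subset_ids] <- raw_levels[pos]
    }
    cdr[rows] <- current[visits$subject_id[rows]]
  }

  merged <- merge_cdr(cdr)
  latent <- conditional_network_sample(spec$truth, merged,
                                       substream_seed(spec$seed, "latent"))

  # emissions and noise features
  set.seed(substream_seed(spec$seed, "emission"))
  df <- visits
  for (f in names(dict)) {
    fm <- spec$feature_models[[f]]
    if (f == "CDR") {
      df[[f]] <- as.numeric(cdr)
    } else if (is.null(fm)) {
      df[[f]] <- NA
    } else if (fm$type == "emission") {
      lev <- match(latent[[fm$node]], spec$truth$nodes[[fm$node]])
      df[[f]] <- fm$means[lev] + stats::rnorm(m, 0, fm$sd)
    } else if (fm$type == "direct") {
      df[[f]] <- latent[[fm$node]]
    } else if (fm$type == "noise") {
      df[[f]] <- stats::rnorm(m, fm$mean, fm$sd)
    } else {
      df[[f]] <- sample(fm$levels, m, replace = TRUE, prob = fm$probs)
    }
  }
  # keep assessments in their scoring ranges
  if ("MMSE" %in% names(df)) df$MMSE <- pmin(pmax(df$MMSE, 0), 30)
  for (f in c("LMIR", "LMDR"))
    if (f %in% names(df)) df[[f]] <- pmax(df[[f]], 0)

  # diagnosis conditional on raw CDR
  set.seed(substream_seed(spec$seed, "diagnosis"))
  dm <- spec$diagnosis_model
  df$diagnosis <- vapply(cdr, function(cl) {
    sample(colnames(dm), 1L, prob = dm[cl, ])
  }, "")

  # missingness: one draw per modality block per record (the block rate is
  # the maximum member rate), then independent draws for unblocked features
  set.seed(substream_seed(spec$seed, "missing"))
  blocked <- character()
  for (block in spec$missing_blocks) {
    members <- intersect(block, names(dict))
    rate <- max(c(0, unlist(spec$missing_rate[members])))
    blocked <- c(blocked, members)
    if (rate > 0) {
      mask <- stats::runif(m) < rate
      for (f in members) df[[f]][mask] <- NA
    }
  }
  for (f in setdiff(names(dict), blocked)) {
    rate <- spec$missing_rate[[f]] %||% 0
    if (rate > 0) df[[f]][stats::runif(m) < rate] <- NA
  }

  tab <- cohort_table(df, dict)
  attr(tab, "latent_states") <- latent
  tab
}
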