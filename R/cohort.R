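#' Feature specification
#'
#' A single entry of the cohort data dictionary: the feature's name, its
#' measurement kind, its category labels (for discrete kinds), its unit, and
#' the domain block it belongs to.
#'
#' @param name feature identifier (unique within a dictionary).
#' @param kind one of `"continuous"`, `"ordinal"`, `"categorical"`.
#' @param categories ordered character vector of category labels; required
#'   (length >= 2) for discrete kinds, disallowed for continuous ones.
#' @param unit free-text unit.
#' @param domain_block one of `"demographics"`, `"medical_history"`,
#'   `"blood"`, `"psychological"`, `"imaging"`, `"target"`.
#' @return an object of class `feature_spec`.
#' @export
feature_spec <- function(name, kind, categories = NULL, unit = "",
                         domain_block = "blood") {
  kind <- match.arg(kind, c("continuous", "ordinal", "categorical"))
  domain_block <- match.arg(domain_block, c("demographics", "medical_history",
                                            "blood", "psychological",
                                            "imaging", "target"))
  if (kind == "continuous" && !is.null(categories))
    stop_adbn("adbn_spec_error", "continuous feature '%s' must not list categories", name)
  if (kind != "continuous" && (is.null(categories) || length(categories) < 2L))
    stop_adbn("adbn_spec_error", "discrete feature '%s' needs >= 2 categories", name)
  structure(list(name = name, kind = kind,
                 categories = as.character(categories %||% character()),
                 unit = unit, domain_block = domain_block),
            class = "feature_spec")
}

#' Default cohort data dictionary
#'
#' The 33-feature analysis dictionary used throughout the pipeline:
#' 2 demographics, 10 medical-history flags, 13 blood measures (including the
#' ApoE genotype), 4 psychological/functional assessments (including the CDR
#' severity target) and 4 imaging summaries.
#'
#' @return a named list of [feature_spec()] objects (class `adbn_dictionary`).
#' @export
default_dictionary <- function() {
  yn <- c("no", "yes")
  specs <- c(
    list(
      feature_spec("age", "continuous", unit = "years", domain_block = "demographics"),
      feature_spec("sex", "categorical", c("F", "M"), domain_block = "demographics")
    ),
    lapply(c("hypertension", "diabetes", "stroke_history", "depression",
             "cardiovascular_disease", "thyroid_disorder", "smoking_history",
             "arthritis", "cancer_history", "neurological_history"),
           function(nm) feature_spec(nm, "categorical", yn,
                                     domain_block = "medical_history")),
    list(feature_spec("ApoE", "categorical", apoe_genotypes(),
                      domain_block = "blood")),
    lapply(c("cholesterol", "hdl", "ldl", "triglycerides", "glucose", "hba1c",
             "creatinine", "urea", "haemoglobin", "platelets", "wbc_count",
             "vitamin_b12"),
           function(nm) feature_spec(nm, "continuous", unit = "assay units",
                                     domain_block = "blood")),
    list(
      feature_spec("MMSE", "continuous", unit = "score 0-30", domain_block = "psychological"),
      feature_spec("LMIR", "continuous", unit = "score", domain_block = "psychological"),
      feature_spec("LMDR", "continuous", unit = "score", domain_block = "psychological"),
      feature_spec("CDR", "ordinal", c("0", "0.5", "1", "2", "3"),
                   domain_block = "target"),
      feature_spec("GM", "continuous", unit = "ml", domain_block = "imaging"),
      feature_spec("WM", "continuous", unit = "ml", domain_block = "imaging"),
      feature_spec("CSF", "continuous", unit = "ml", domain_block = "imaging"),
      feature_spec("PiB_PET", "continuous", unit = "active voxels", domain_block = "imaging")
    )
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(names(specs)))
    stop_adbn("adbn_spec_error", "duplicate feature names in dictionary")
  structure(specs, class = "adbn_dictionary")
}

#' The five ApoE allele combinations, ordered by epsilon-4 load
#' @return character vector of genotype labels.
#' @export
apoe_genotypes <- function() {
  c("e3e2", "e3e3", "e4e2", "e4e3", "e4e4")
}

#' Valid CDR scores and visit labels
#' @name cohort-constants
#' @export
cdr_levels <- function() c(0, 0.5, 1, 2, 3)

#' @rdname cohort-constants
#' @export
visit_levels <- function() c("BL", "M18", "M36", "M54")

mandatory_columns <- function() c("subject_id", "visit", "diagnosis")

#' Construct and validate a cohort table
#'
#' One row per subject-visit; columns `subject_id`, `visit`, `diagnosis`
#' followed by the dictionary features (the CDR target is a dictionary
#' feature, held as numeric scores).
#'
#' @param df a data.frame with the mandatory and feature columns.
#' @param dictionary a dictionary from [default_dictionary()].
#' @return the validated data.frame with class `cohort_table` and the
#'   dictionary attached as attribute `dictionary`.
#' @export
cohort_table <- function(df, dictionary = default_dictionary()) {
  miss <- setdiff(c(mandatory_columns(), names(dictionary)), names(df))
  if (length(miss))
    stop_adbn("adbn_schema_error", "missing mandatory columns: %s",
              paste(miss, collapse = ", "))
  if (anyDuplicated(df[c("subject_id", "visit")]))
    stop_adbn("adbn_integrity_error", "duplicate (subject_id, visit) pairs")
  bad_visit <- !df$visit %in% visit_levels()
  if (any(bad_visit))
    stop_adbn("adbn_integrity_error", "invalid visit labels: %s",
              paste(unique(df$visit[bad_visit]), collapse = ", "))
  cdr <- df[["CDR"]]
  bad_cdr <- !is.na(cdr) & !cdr %in% cdr_levels()
  if (any(bad_cdr))
    stop_adbn("adbn_integrity_error", "CDR values outside {0, 0.5, 1, 2, 3}: %s",
              paste(unique(cdr[bad_cdr]), collapse = ", "))
  df <- df[c(mandatory_columns(), names(dictionary),
             setdiff(names(df), c(mandatory_columns(), names(dictionary))))]
  rownames(df) <- NULL
  structure(df, class = c("cohort_table", "data.frame"),
            dictionary = dictionary)
}

#' Read a cohort table from CSV
#'
#' Cells that cannot be parsed under the dictionary (non-numeric text in a
#' continuous column, an unlisted category label) become missing values; the
#' number of such cells is attached as attribute `parse_warnings` and
#' reported once via [warning()].  Structural problems (missing columns,
#' duplicated subject-visit pairs, CDR scores outside the five-value set)
#' are errors.
#'
#' @param path CSV file path (UTF-8, header row).
#' @param dictionary the data dictionary the file must conform to.
#' @return a [cohort_table()].
#' @export
read_cohort <- function(path, dictionary = default_dictionary()) {
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("NA", ""), check.names = FALSE)
  miss <- setdiff(c(mandatory_columns(), names(dictionary)), names(raw))
  if (length(miss))
    stop_adbn("adbn_schema_error", "missing mandatory columns: %s",
              paste(miss, collapse = ", "))
  n_warn <- 0L
  out <- raw
  for (spec in dictionary) {
    col <- raw[[spec$name]]
    if (spec$name == "CDR" || spec$kind == "continuous") {
      val <- suppressWarnings(as.numeric(col))
      n_warn <- n_warn + sum(is.na(val) & !is.na(col))
      out[[spec$name]] <- val
    } else {
      ok <- is.na(col) | col %in% spec$categories
      n_warn <- n_warn + sum(!ok)
      col[!ok] <- NA
      out[[spec$name]] <- col
    }
  }
  dg <- out$diagnosis
  bad_dg <- !is.na(dg) & !dg %in% c("HC", "MCI", "AD")
  if (any(bad_dg)) {
    n_warn <- n_warn + sum(bad_dg)
    out$diagnosis[bad_dg] <- NA
  }
  tab <- cohort_table(out, dictionary)
  attr(tab, "parse_warnings") <- n_warn
  if (n_warn > 0L)
    warning(sprintf("read_cohort: %d unparseable cells set to missing", n_warn),
            call. = FALSE)
  tab
}

#' Write a cohort table to CSV
#'
#' @param table a [cohort_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "NA")
  invisible(path)
}

lookup_features <- function(table, features) {
  dict <- attr(table, "dictionary")
  unknown <- setdiff(features, names(dict))
  if (length(unknown))
    stop_adbn("adbn_lookup_error", "unknown feature(s): %s",
              paste(unknown, collapse = ", "))
  features
}

#' Keep only subject-visit records complete in the requested features
#'
#' No imputation is performed anywhere in the pipeline; analyses are
#' complete-case with respect to the features they use.
#'
#' @param table a [cohort_table()].
#' @param features feature names that must be non-missing; an empty vector
#'   returns the table unchanged.
#' @return the filtered [cohort_table()], row order preserved.
#' @export
complete_case_filter <- function(table, features) {
  features <- lookup_features(table, features)
  if (!length(features)) return(table)
  keep <- stats::complete.cases(as.data.frame(table)[features])
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the longitudinal analysis groups
#'
#' Group 1 pools records complete at baseline with, per subject, the earliest
#' record complete at a later visit (subjects need not overlap between the
#' two sets).  Group 2 keeps subjects complete at baseline *and* at one or
#' more later visits, pairing the baseline record with the earliest complete
#' later record.  Group 3 keeps subjects complete at all four visits.
#'
#' @param table a [cohort_table()] with visit labels.
#' @param features the feature set defining completeness.
#' @return a list of three `group_assignment` objects, each carrying
#'   `group_id`, integer `baseline_rows` / `later_rows` into `table`, and the
#'   subject identifiers involved.
#' @export
assemble_groups <- function(table, features) {
  features <- lookup_features(table, features)
  df <- as.data.frame(table)
  complete <- if (length(features))
    stats::complete.cases(df[features]) else rep(TRUE, nrow(df))
  visit <- factor(df$visit, levels = visit_levels())
  later <- as.integer(visit) > 1L
  bl_rows <- which(complete & !later)

  # earliest complete later record per subject
  cand <- which(complete & later)
  cand <- cand[order(df$subject_id[cand], as.integer(visit[cand]))]
  first_later <- cand[!duplicated(df$subject_id[cand])]

  bl_subjects <- df$subject_id[bl_rows]
  later_subjects <- df$subject_id[first_later]
  g2_subjects <- intersect(bl_subjects, later_subjects)
  g2_bl <- bl_rows[match(g2_subjects, bl_subjects)]
  g2_later <- first_later[match(g2_subjects, later_subjects)]

  per_subject_visits <- tapply(as.integer(visit)[complete],
                               df$subject_id[complete],
                               function(v) length(unique(v)))
  g3_subjects <- names(per_subject_visits)[per_subject_visits == 4L]
  g3_rows <- which(complete & df$subject_id %in% g3_subjects)
  g3_bl <- g3_rows[!later[g3_rows]]
  g3_later <- g3_rows[later[g3_rows]]

  mk <- function(id, bl, lt, subj) {
    structure(list(group_id = id, baseline_rows = unname(bl),
                   later_rows = unname(lt), subjects = unname(subj)),
              class = "group_assignment")
  }
  list(mk(1L, bl_rows, first_later, union(bl_subjects, later_subjects)),
       mk(2L, g2_bl, g2_later, g2_subjects),
       mk(3L, g3_bl, g3_later, g3_subjects))
}
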