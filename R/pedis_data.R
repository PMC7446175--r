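# Domain types and I/O for PEDIS-coded diabetic foot ulcer cohorts.
#
# A cohort is a data.frame of class "pedis_cohort" with one row per patient:
# patient_id, age, gender, the five PEDIS grades, the two six-month outcomes
# and a lost-to-follow-up flag. Grade ranges follow the IWGDF PEDIS
# classification: perfusion/extent/depth 1-3, infection 1-4, sensation 1-2.

PEDIS_FACTORS <- c("perfusion", "extent", "depth", "infection", "sensation")

GRADE_RANGE <- list(
  perfusion = c(1L, 3L), extent = c(1L, 3L), depth = c(1L, 3L),
  infection = c(1L, 4L), sensation = c(1L, 2L)
)

COHORT_COLUMNS <- c("patient_id", "age", "gender", PEDIS_FACTORS,
                    "outcome_any", "outcome_major", "lost_to_followup")

#' Validate one raw patient row
#'
#' Coerces a raw row (named list or one-row data.frame) to a typed, range
#' checked patient record. Grades are coerced to integers and checked against
#' the PEDIS ranges (perfusion, extent, depth 1-3; infection 1-4; sensation
#' 1-2); age must be at least 18; gender must be `"female"` or `"male"`. A
#' missing outcome is only allowed when `lost_to_followup` is set, and a
#' major amputation implies an any amputation.
#'
#' @param raw_row Named list or one-row data.frame with fields `patient_id`,
#'   `age`, `gender`, the five PEDIS grades, `outcome_any`, `outcome_major`
#'   and optionally `lost_to_followup` (default `FALSE`).
#' @return A named list of class `"pedis_record"`.
#' @examples
#' validate_record(list(patient_id = "p1", age = 66, gender = "male",
#'   perfusion = 2, extent = 2, depth = 1, infection = 1, sensation = 1,
#'   outcome_any = 0, outcome_major = 0))
#' @export
validate_record <- function(raw_row) {
  raw_row <- as.list(raw_row)
  required <- c("patient_id", "age", "gender", PEDIS_FACTORS,
                "outcome_any", "outcome_major")
  missing_fields <- setdiff(required, names(raw_row))
  if (length(missing_fields) > 0L) {
    stop("missing field(s): ", paste(missing_fields, collapse = ", "))
  }
  rec <- list(patient_id = as.character(raw_row$patient_id))

  age <- suppressWarnings(as.numeric(raw_row$age))
  if (is.na(age) || age < 18) {
    stop("invalid age: ", raw_row$age, " (must be a number >= 18)")
  }
  rec$age <- age

  gender <- as.character(raw_row$gender)
  if (!gender %in% c("female", "male")) {
    stop("invalid gender: ", gender, " (must be 'female' or 'male')")
  }
  rec$gender <- gender

  for (f in PEDIS_FACTORS) {
    g <- suppressWarnings(as.numeric(raw_row[[f]]))
    rng <- GRADE_RANGE[[f]]
    if (is.na(g) || g != round(g) || g < rng[1] || g > rng[2]) {
      stop("grade out of range for ", f, ": ", raw_row[[f]],
           " (allowed ", rng[1], "-", rng[2], ")")
    }
    rec[[f]] <- as.integer(g)
  }

  lost <- isTRUE(as.logical(raw_row$lost_to_followup)) ||
    identical(suppressWarnings(as.numeric(raw_row$lost_to_followup)), 1)
  rec$lost_to_followup <- lost

  coerce_outcome <- function(x, name) {
    if (is.null(x) || is.na(x) || identical(x, "")) return(NA_integer_)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v) || !v %in% c(0, 1)) stop("invalid ", name, ": ", x)
    as.integer(v)
  }
  rec$outcome_any <- coerce_outcome(raw_row$outcome_any, "outcome_any")
  rec$outcome_major <- coerce_outcome(raw_row$outcome_major, "outcome_major")

  if (lost) {
    # lost to follow-up: outcomes are unknown by definition
    rec$outcome_any <- NA_integer_
    rec$outcome_major <- NA_integer_
  } else {
    if (is.na(rec$outcome_any) || is.na(rec$outcome_major)) {
      stop("missing outcome for patient ", rec$patient_id,
           " without lost_to_followup flag")
    }
    if (rec$outcome_major == 1L && rec$outcome_any != 1L) {
      stop("outcome_major = 1 requires outcome_any = 1 (patient ",
           rec$patient_id, ")")
    }
  }
  class(rec) <- "pedis_record"
  rec
}

#' Assemble a validated cohort
#'
#' Validates every row of a raw data.frame and returns a `"pedis_cohort"`,
#' a data.frame carrying `provenance` ("observed" or "synthetic") and a free
#' text `label` as attributes. Patient identifiers must be unique.
#'
#' @param records data.frame with the columns of [validate_record()].
#' @param provenance `"observed"` or `"synthetic"`.
#' @param label Free-text cohort label.
#' @return A `pedis_cohort` data.frame.
#' @export
as_cohort <- function(records, provenance = c("observed", "synthetic"),
                      label = "") {
  provenance <- match.arg(provenance)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) == 0L) stop("cohort must contain at least one record")
  required <- c("patient_id", "age", "gender", PEDIS_FACTORS,
                "outcome_any", "outcome_major")
  missing_fields <- setdiff(required, names(records))
  if (length(missing_fields) > 0L) {
    stop("missing field(s): ", paste(missing_fields, collapse = ", "))
  }
  if (is.null(records$lost_to_followup)) records$lost_to_followup <- FALSE

  # vectorised equivalent of validate_record(), row index reported on failure
  fail <- function(i, msg) stop("record ", i, " (patient ",
                                records$patient_id[i], "): ", msg)
  out <- data.frame(patient_id = as.character(records$patient_id),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$patient_id)) {
    stop("duplicate patient_id: ",
         paste(unique(out$patient_id[duplicated(out$patient_id)]), collapse = ", "))
  }
  out$age <- suppressWarnings(as.numeric(records$age))
  bad <- which(is.na(out$age) | out$age < 18)
  if (length(bad) > 0L) fail(bad[1], "invalid age (must be a number >= 18)")
  out$gender <- as.character(records$gender)
  bad <- which(!out$gender %in% c("female", "male"))
  if (length(bad) > 0L) fail(bad[1], "invalid gender (must be 'female' or 'male')")
  for (f in PEDIS_FACTORS) {
    g <- suppressWarnings(as.numeric(records[[f]]))
    rng <- GRADE_RANGE[[f]]
    bad <- which(is.na(g) | g != round(g) | g < rng[1] | g > rng[2])
    if (length(bad) > 0L) {
      fail(bad[1], paste0("grade out of range for ", f, " (allowed ",
                          rng[1], "-", rng[2], ")"))
    }
    out[[f]] <- as.integer(g)
  }
  lost <- records$lost_to_followup
  lost <- if (is.logical(lost)) lost else
    suppressWarnings(as.numeric(lost)) == 1
  lost[is.na(lost)] <- FALSE
  out$lost_to_followup <- lost
  coerce_outcome <- function(x, name) {
    x[!is.na(x) & x == ""] <- NA
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & (is.na(v) | !v %in% c(0, 1)))
    if (length(bad) > 0L) fail(bad[1], paste0("invalid ", name))
    as.integer(v)
  }
  out$outcome_any <- coerce_outcome(records$outcome_any, "outcome_any")
  out$outcome_major <- coerce_outcome(records$outcome_major, "outcome_major")
  out$outcome_any[lost] <- NA_integer_
  out$outcome_major[lost] <- NA_integer_
  bad <- which(!lost & (is.na(out$outcome_any) | is.na(out$outcome_major)))
  if (length(bad) > 0L) fail(bad[1], "missing outcome without lost_to_followup flag")
  bad <- which(!lost & out$outcome_major == 1L & out$outcome_any != 1L)
  if (length(bad) > 0L) fail(bad[1], "outcome_major = 1 requires outcome_any = 1")

  out <- out[, COHORT_COLUMNS]
  rownames(out) <- NULL
  structure(out, provenance = provenance, label = label,
            class = c("pedis_cohort", "data.frame"))
}

#' @export
print.pedis_cohort <- function(x, ...) {
  cat(sprintf("<pedis_cohort> %d patients (%s%s), %d fit-eligible\n",
              nrow(x), attr(x, "provenance"),
              if (nzchar(attr(x, "label"))) paste0(": ", attr(x, "label")) else "",
              nrow(fit_eligible(x))))
  NextMethod()
}

#' Fit-eligible records of a cohort
#'
#' Records lost to follow-up are retained in files for bookkeeping but carry
#' no outcome, so they are excluded from any model fitting or outcome-grouped
#' summary.
#'
#' @param cohort A `pedis_cohort`.
#' @return The subset of rows with observed outcomes.
#' @export
fit_eligible <- function(cohort) {
  cohort[!cohort$lost_to_followup & !is.na(cohort$outcome_any), , drop = FALSE]
}

#' PEDIS sum score
#'
#' Sum of the five PEDIS grades; ranges from 5 (all minimal) to 15 (all
#' maximal). Vectorised over the rows of a cohort or data.frame.
#'
#' @param x A `pedis_record`, or a data.frame with the five grade columns.
#' @return Integer score(s) in `[5, 15]`.
#' @examples
#' pedis_sum(data.frame(perfusion = 2, extent = 2, depth = 1,
#'                      infection = 1, sensation = 1))  # 7
#' @export
pedis_sum <- function(x) {
  if (inherits(x, "pedis_record")) x <- as.data.frame(unclass(x)[PEDIS_FACTORS])
  as.integer(rowSums(as.data.frame(x)[, PEDIS_FACTORS, drop = FALSE]))
}

#' Select the index ulcer among multiple ulcers of one patient
#'
#' When a patient presents with several ulcers, the one with the highest
#' PEDIS sum score is the index ulcer; ties are broken by the first
#' occurrence in input order.
#'
#' @param ulcers data.frame of ulcer rows (grade columns required), all for
#'   the same patient.
#' @return The selected row.
#' @export
select_index_ulcer <- function(ulcers) {
  ulcers <- as.data.frame(ulcers)
  if (nrow(ulcers) == 0L) stop("no ulcers supplied")
  if ("patient_id" %in% names(ulcers) &&
      length(unique(ulcers$patient_id)) > 1L) {
    stop("ulcers belong to more than one patient")
  }
  scores <- pedis_sum(ulcers)
  ulcers[which.max(scores), , drop = FALSE]  # which.max takes the first tie
}

#' Outcome code map for ICD-9-CM amputation procedures
#'
#' Maps lower-extremity amputation procedure codes (84.NN) to the two binary
#' study outcomes. Two presets ship:
#' \describe{
#'   \item{`as_reported`}{the source cohort's printed coding: any-amputation
#'     84.11-84.19; major-amputation 84.11-84.12. Note this labels 84.11
#'     (toe) and 84.12 (through foot) as "above the ankle", which inverts
#'     standard ICD-9-CM semantics; it is kept verbatim as the default so
#'     the reported analysis is reproduced, and flagged here.}
#'   \item{`standard`}{standard ICD-9-CM semantics: any-amputation
#'     84.11-84.19 (84.11 dropped when `exclude_lesser_toes`); major
#'     (through/above ankle) 84.13-84.19.}
#' }
#'
#' @param preset `"as_reported"` (default) or `"standard"`.
#' @param exclude_lesser_toes Drop 84.11 from the any-amputation range.
#'   Ignored (kept `FALSE`) for `as_reported`, where 84.11 belongs to the
#'   major range and ICD-9 codes cannot distinguish lesser from great toes.
#' @return A list of class `"outcome_code_map"` with integer range tables
#'   `any_codes`, `major_codes` (columns `lo`, `hi` over the NN code part).
#' @export
outcome_code_map <- function(preset = c("as_reported", "standard"),
                             exclude_lesser_toes = NULL) {
  preset <- match.arg(preset)
  if (preset == "as_reported") {
    map <- list(any_codes = data.frame(lo = c(13L, 11L), hi = c(19L, 12L)),
                major_codes = data.frame(lo = 11L, hi = 12L),
                exclude_lesser_toes = FALSE, preset = preset)
  } else {
    excl <- isTRUE(exclude_lesser_toes) || is.null(exclude_lesser_toes)
    map <- list(any_codes = data.frame(lo = if (excl) 12L else 11L, hi = 19L),
                major_codes = data.frame(lo = 13L, hi = 19L),
                exclude_lesser_toes = excl, preset = preset)
  }
  in_any <- all(vapply(seq_len(nrow(map$major_codes)), function(i) {
    any(map$any_codes$lo <= map$major_codes$lo[i] &
          map$any_codes$hi >= map$major_codes$hi[i])
  }, logical(1)))
  if (!in_any) stop("major_codes must be a subset of any_codes")
  class(map) <- "outcome_code_map"
  map
}

#' Classify amputation outcomes from procedure codes
#'
#' @param procedure_codes Character vector of ICD-9-CM procedure codes of the
#'   form `"84.NN"` (may be empty).
#' @param map An [outcome_code_map()].
#' @return Named integer vector `c(outcome_any = , outcome_major = )`.
#' @examples
#' classify_outcome(c("84.15"), outcome_code_map())  # any = 1, major = 0
#' @export
classify_outcome <- function(procedure_codes, map = outcome_code_map()) {
  stopifnot(inherits(map, "outcome_code_map"))
  if (length(procedure_codes) == 0L) {
    return(c(outcome_any = 0L, outcome_major = 0L))
  }
  ok <- grepl("^84\\.[0-9]{2}$", procedure_codes)
  if (!all(ok)) {
    stop("unparseable procedure code(s): ",
         paste(procedure_codes[!ok], collapse = ", "))
  }
  nn <- as.integer(substr(procedure_codes, 4L, 5L))
  hit <- function(ranges) {
    any(vapply(nn, function(v) any(v >= ranges$lo & v <= ranges$hi), logical(1)))
  }
  c(outcome_any = as.integer(hit(map$any_codes)),
    outcome_major = as.integer(hit(map$major_codes)))
}

#' Descriptive cohort summary
#'
#' Stage counts and percentages per PEDIS factor, gender counts, and mean/SD
#' of age and the PEDIS sum score, overall and by outcome group (non-amputees
#' and amputees for each outcome). All percentages — including subgroup
#' percentages — are relative to the total number of fit-eligible patients,
#' so the amputee and non-amputee shares of a stage add up to the overall
#' share. Lost-to-follow-up records are excluded. The SD of a single-record
#' group is reported as 0.
#'
#' @param cohort A `pedis_cohort`.
#' @return A list of class `"dfu_summary"`: `n` (named group sizes), `stages`
#'   (factor/stage counts and percentages per group), `gender`, `continuous`
#'   (mean/SD of age and PEDIS sum per group).
#' @export
descriptive_summary <- function(cohort) {
  eligible <- fit_eligible(cohort)
  if (nrow(eligible) == 0L) stop("no fit-eligible records to summarise")
  n_total <- nrow(eligible)
  groups <- list(
    overall   = rep(TRUE, n_total),
    any_non   = eligible$outcome_any == 0L,
    any_amp   = eligible$outcome_any == 1L,
    major_non = eligible$outcome_major == 0L,
    major_amp = eligible$outcome_major == 1L
  )
  n <- vapply(groups, sum, integer(1))

  stages <- do.call(rbind, lapply(PEDIS_FACTORS, function(f) {
    rng <- GRADE_RANGE[[f]]
    do.call(rbind, lapply(seq(rng[1], rng[2]), function(s) {
      row <- data.frame(factor = f, stage = s, stringsAsFactors = FALSE)
      for (g in names(groups)) {
        cnt <- sum(eligible[[f]][groups[[g]]] == s)
        row[[paste0(g, "_n")]] <- cnt
        row[[paste0(g, "_pct")]] <- 100 * cnt / n_total
      }
      row
    }))
  }))

  gender <- do.call(rbind, lapply(c("female", "male"), function(sex) {
    row <- data.frame(gender = sex, stringsAsFactors = FALSE)
    for (g in names(groups)) {
      cnt <- sum(eligible$gender[groups[[g]]] == sex)
      row[[paste0(g, "_n")]] <- cnt
      row[[paste0(g, "_pct")]] <- 100 * cnt / n_total
    }
    row
  }))

  sums <- pedis_sum(eligible)
  continuous <- do.call(rbind, lapply(c("age", "pedis_sum"), function(v) {
    vals <- if (v == "age") eligible$age else sums
    do.call(rbind, lapply(names(groups), function(g) {
      x <- vals[groups[[g]]]
      data.frame(variable = v, group = g, n = length(x), mean = mean(x),
                 sd = if (length(x) > 1L) stats::sd(x) else 0,
                 stringsAsFactors = FALSE)
    }))
  }))

  structure(list(n = n, stages = stages, gender = gender,
                 continuous = continuous),
            class = "dfu_summary")
}

#' @export
print.dfu_summary <- function(x, digits = 2, ...) {
  cat(sprintf("Cohort summary (N = %d fit-eligible)\n", x$n[["overall"]]))
  cat(sprintf("  any-amputation: %d (%.1f%%);  major-amputation: %d (%.1f%%)\n",
              x$n[["any_amp"]], 100 * x$n[["any_amp"]] / x$n[["overall"]],
              x$n[["major_amp"]], 100 * x$n[["major_amp"]] / x$n[["overall"]]))
  cont <- x$continuous
  for (v in unique(cont$variable)) {
    r <- cont[cont$variable == v & cont$group == "overall", ]
    cat(sprintf("  %s: mean %.*f (SD %.*f)\n", v, digits, r$mean, digits, r$sd))
  }
  st <- x$stages
  cat("  stage percentages (of total N):\n")
  for (f in unique(st$factor)) {
    rows <- st[st$factor == f, ]
    cat(sprintf("    %-9s %s\n", f,
                paste(sprintf("%d: %.1f%%", rows$stage, rows$overall_pct),
                      collapse = "  ")))
  }
  invisible(x)
}

#' Write a summary's tables to CSV files
#'
#' @param summary A `"dfu_summary"` from [descriptive_summary()].
#' @param path Base path; `_stages.csv`, `_gender.csv`, `_continuous.csv`
#'   suffixes are appended.
#' @return Invisibly, the written file paths.
#' @export
write_summary <- function(summary, path) {
  paths <- paste0(path, c("_stages.csv", "_gender.csv", "_continuous.csv"))
  utils::write.csv(summary$stages, paths[1], row.names = FALSE)
  utils::write.csv(summary$gender, paths[2], row.names = FALSE)
  utils::write.csv(summary$continuous, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Expected PEDIS sum from marginal stage counts
#'
#' By linearity of expectation, the mean PEDIS sum of a group equals the sum
#' over factors of the count-weighted mean stage, so it is computable from
#' marginal stage counts alone — the form in which published cohort tables
#' report grades. Each factor's counts must sum to the same group size.
#'
#' @param marginals data.frame with columns `factor`, `stage`, and the count
#'   column named by `group` (see [dfu_reference_marginals()]).
#' @param group Name of the count column to use.
#' @return The expected PEDIS sum (numeric scalar).
#' @examples
#' expected_pedis_sum(dfu_reference_marginals(), "overall")  # 10.76
#' @export
expected_pedis_sum <- function(marginals, group = "overall") {
  if (!group %in% names(marginals)) stop("no count column named ", group)
  counts <- marginals[[group]]
  per_factor_n <- tapply(counts, marginals$factor, sum)
  if (length(unique(per_factor_n)) != 1L) {
    stop("factor counts do not sum to a common group size")
  }
  n <- per_factor_n[[1]]
  sum(marginals$stage * counts) / n
}

#' Read / write a cohort CSV
#'
#' The cohort CSV has the columns `patient_id, age, gender, perfusion,
#' extent, depth, infection, sensation, outcome_any, outcome_major,
#' lost_to_followup`, with gender written as `female`/`male` and missing
#' outcomes as empty cells. Reading validates every row; writing then
#' reading restores an identical cohort.
#'
#' @param path File path.
#' @param provenance,label Cohort metadata applied on read.
#' @return `read_cohort()` returns a `pedis_cohort`; `write_cohort()`
#'   invisibly returns `path`.
#' @export
read_cohort <- function(path, provenance = c("observed", "synthetic"),
                        label = basename(path)) {
  provenance <- match.arg(provenance)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character"))
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("cohort file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  as_cohort(raw[, COHORT_COLUMNS], provenance = provenance, label = label)
}

#' @rdname read_cohort
#' @param cohort A `pedis_cohort` to write.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)[, COHORT_COLUMNS]
  out$lost_to_followup <- as.integer(out$lost_to_followup)
  out$age <- sprintf("%.17g", out$age)  # full precision: round-trip lossless
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
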