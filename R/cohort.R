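#' @title Exclusion accounting, stratified splits, frozen manifests
#' @description Subject-wise (never record-wise) stratified splitting into
#'   Train/Validation/Test(lock-box) sets, with exclusion-stage accounting
#'   and a preregistration-style manifest: canonical JSON plus a SHA-256
#'   hash, so any later tampering with the split is detectable before
#'   evaluation.
#' @name cohort
NULL

#' Apply exclusion criteria with stage accounting
#'
#' Eligibility = all subjects, minus those flagged for medical exclusion
#' criteria, minus those labelled `atypical` (too rare a class for
#' training). Returns the eligible ids and a count at every stage.
#'
#' @param cohort data.frame of subject records (from [read_cohort()] or
#'   equivalent) with `subject_id` and `label`.
#' @param medical_flags named logical vector, one entry per subject id,
#'   `TRUE` = medically excluded.
#' @return list with `eligible_ids` (character) and `accounting`
#'   (data.frame of stage, n).
#' @export
apply_exclusions <- function(cohort, medical_flags) {
  ids <- cohort$subject_id
  unknown <- setdiff(names(medical_flags), ids)
  if (length(unknown) > 0L) {
    stop("apply_exclusions: flags reference unknown id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  missing_ids <- setdiff(ids, names(medical_flags))
  if (length(missing_ids) > 0L) {
    stop("apply_exclusions: flags must cover all ids; missing ",
         length(missing_ids), " id(s)", call. = FALSE)
  }
  excl_med <- ids[medical_flags[ids]]
  remaining <- setdiff(ids, excl_med)
  atypical <- cohort$subject_id[cohort$label == "atypical"]
  excl_atyp <- intersect(remaining, atypical)
  eligible <- setdiff(remaining, excl_atyp)
  accounting <- data.frame(
    stage = c("enrolled", "medical_exclusions", "after_medical",
              "atypical_fm_exclusions", "eligible"),
    n = c(length(ids), length(excl_med), length(remaining),
          length(excl_atyp), length(eligible)),
    stringsAsFactors = FALSE)
  list(eligible_ids = eligible, accounting = accounting)
}

# largest-remainder allocation of n items to fractions; returns counts
largest_remainder <- function(n, fractions, tie_order) {
  q <- n * fractions
  base <- floor(q)
  leftover <- n - sum(base)
  if (leftover > 0) {
    rem <- q - base
    ord <- order(-rem, tie_order)
    base[ord[seq_len(leftover)]] <- base[ord[seq_len(leftover)]] + 1L
  }
  as.integer(base)
}

#' Stratified subject-wise Train/Val/Test split
#'
#' Within each stratum cell (label crossed with `strata$sex` when
#' available) members are shuffled with the seeded generator and allocated
#' to the three splits by largest-remainder rounding. If any cell is
#' smaller than the number of splits, stratification falls back to
#' label-only with a warning. Splits are disjoint, cover all ids, and each
#' split's positive-class prevalence stays within 2.5 percentage points of
#' the global prevalence (checked, warned otherwise).
#'
#' @param ids character vector of eligible subject ids.
#' @param labels vector of labels aligned with `ids` (`FM_minus` is the
#'   positive class).
#' @param strata optional data.frame aligned with `ids`; a `sex` column, if
#'   present, enters the stratification cells.
#' @param fractions numeric length-3 (train, val, test) summing to 1.
#' @param seed integer seed; the allocation is deterministic given
#'   (ids, labels, strata, fractions, seed).
#' @return An object of class `kin_manifest`.
#' @export
stratified_split <- function(ids, labels, strata = NULL,
                             fractions = c(train = 0.70, val = 0.10, test = 0.20),
                             seed = 1L) {
  assert_that(abs(sum(fractions) - 1) < 1e-9, "fractions must sum to 1")
  assert_that(length(ids) == length(labels), "ids/labels length mismatch")
  assert_that(!anyDuplicated(ids), "duplicate subject ids")
  labels <- as.character(labels)
  split_names <- c("train", "val", "test")

  cell_key <- labels
  if (!is.null(strata) && "sex" %in% names(strata)) {
    cell_key <- paste(labels, as.character(strata$sex), sep = "|")
  }
  cells <- split(seq_along(ids), cell_key)
  if (any(vapply(cells, length, integer(1)) < length(split_names)) &&
      !identical(cell_key, labels)) {
    warning("stratified_split: a stratum cell is too small; ",
            "falling back to label-only stratification")
    cells <- split(seq_along(ids), labels)
  }

  assignment <- character(length(ids))
  with_seed(seed, {
    for (cell in cells) {
      members <- cell[sample.int(length(cell))]
      counts <- largest_remainder(length(members), fractions,
                                  tie_order = sample.int(3L))
      assignment[members] <- rep(split_names, counts)
    }
  })

  # guarantee each split holds >= 1 of each class when the cohort allows it:
  # swap a member in from the richest split (size-preserving, deterministic)
  for (cls in c("FM_minus", "FM_plus")) {
    if (sum(labels == cls) < length(split_names)) next
    for (s in split_names) {
      while (sum(labels == cls & assignment == s) == 0L) {
        counts <- vapply(split_names, function(z)
          sum(labels == cls & assignment == z), integer(1))
        donor <- split_names[which.max(counts)]
        give <- which(labels == cls & assignment == donor)
        give <- give[order(ids[give])][1]
        take <- which(labels != cls & assignment == s)
        take <- take[order(ids[take])][1]
        assignment[give] <- s
        assignment[take] <- donor
      }
    }
  }

  splits <- lapply(split_names, function(s) sort(ids[assignment == s]))
  names(splits) <- split_names
  prev <- vapply(split_names, function(s) {
    lab <- labels[assignment == s]
    if (length(lab) == 0L) return(NA_real_)
    mean(lab == "FM_minus")
  }, numeric(1))
  global_prev <- mean(labels == "FM_minus")
  if (any(abs(prev - global_prev) > 0.025, na.rm = TRUE)) {
    warning("stratified_split: a split's prevalence deviates more than ",
            "2.5 percentage points from the global prevalence")
  }

  strata_summary <- NULL
  if (!is.null(strata)) {
    strata_summary <- lapply(split_names, function(s) {
      sub <- strata[assignment == s, , drop = FALSE]
      lapply(sub, function(col) {
        if (is.numeric(col)) list(mean = mean(col), sd = stats::sd(col))
        else as.list(table(col) / length(col))
      })
    })
    names(strata_summary) <- split_names
  }

  manifest <- list(
    schema_version = KIN_SCHEMA_VERSION,
    splits = splits,
    fractions = as.list(fractions),
    sizes = lapply(splits, length),
    prevalence = as.list(prev),
    global_prevalence = global_prev,
    strata_summary = strata_summary,
    seed = as.integer(seed)
    # no timestamp inside the manifest: freezing must be byte-reproducible;
    # the run log records when the freeze happened
  )
  manifest$hash <- manifest_hash(manifest)
  class(manifest) <- "kin_manifest"
  manifest
}

# hash covers the reproducible core only (not the timestamp)
manifest_hash <- function(manifest) {
  core <- manifest[c("schema_version", "splits", "fractions", "sizes",
                     "prevalence", "global_prevalence", "seed")]
  sha256_of(as.character(canonical_json(core)))
}

#' @export
print.kin_manifest <- function(x, ...) {
  cat(sprintf(
    "kin_manifest: train %d / val %d / test %d, prevalence %.1f%%/%.1f%%/%.1f%%\n  hash %s\n",
    x$sizes$train, x$sizes$val, x$sizes$test,
    100 * x$prevalence$train, 100 * x$prevalence$val, 100 * x$prevalence$test,
    x$hash))
  invisible(x)
}

#' Freeze a split manifest to disk
#'
#' Writes the manifest as canonical JSON (sorted keys, sorted id lists)
#' with its SHA-256 content hash. [verify_manifest()] recomputes the hash
#' and refuses a tampered manifest.
#'
#' @param manifest a `kin_manifest`.
#' @param path output JSON path.
#' @return the hash, invisibly.
#' @export
freeze_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "kin_manifest"))
  writeLines(as.character(canonical_json(unclass(manifest))), path)
  invisible(manifest$hash)
}

#' Verify a frozen manifest
#'
#' @param path path written by [freeze_manifest()].
#' @return the manifest (class `kin_manifest`) if the hash checks out;
#'   otherwise a hard error.
#' @export
verify_manifest <- function(path) {
  m <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expected <- manifest_hash(m)
  if (!identical(expected, m$hash)) {
    stop("verify_manifest: hash mismatch — manifest has been modified since ",
         "freezing (expected ", expected, ", found ", m$hash, ")",
         call. = FALSE)
  }
  m$splits <- lapply(m$splits, function(s) unlist(s, use.names = FALSE))
  class(m) <- "kin_manifest"
  m
}
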