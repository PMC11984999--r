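#' Patient-wise split specification
#'
#' @param fractions `(train, val, test)` patient fractions, positive and
#'   summing to 1 (default `c(0.70, 0.20, 0.10)`).
#' @param seed integer seed.
#' @return list of class `fm_split_spec`.
#' @export
split_spec <- function(fractions = c(0.70, 0.20, 0.10), seed = 1L) {
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-9)
    stop_fm("fractions must be positive and sum to 1")
  structure(list(fractions = fractions, seed = as.integer(seed)),
            class = "fm_split_spec")
}

#' Apply the cohort exclusion filters
#'
#' Drops every image labeled BIRADS 0 or 6, and every image of a patient
#' flagged with an implant or an incorrect scan — exclusions operate at the
#' patient level, as clinical review does.
#'
#' @param manifest data.frame with columns `patient_id`, `birads`,
#'   `implant_flag`, `mis_scan_flag`.
#' @return list: `manifest` (filtered), `report` (named counts per
#'   exclusion reason: `birads_0_or_6`, `implant`, `mis_scan`).
#' @export
filter_cohort <- function(manifest) {
  stopifnot(all(c("patient_id", "birads", "implant_flag", "mis_scan_flag")
                %in% names(manifest)))
  bad_birads <- manifest$birads %in% c(0, 6)
  implant_patients <- unique(manifest$patient_id[manifest$implant_flag])
  mis_patients <- unique(manifest$patient_id[manifest$mis_scan_flag])
  drop_implant <- manifest$patient_id %in% implant_patients
  drop_mis <- manifest$patient_id %in% mis_patients
  keep <- !(bad_birads | drop_implant | drop_mis)
  if (!any(keep)) stop_fm("cohort is empty after exclusion filtering")
  list(manifest = manifest[keep, , drop = FALSE],
       report = c(birads_0_or_6 = sum(bad_birads),
                  implant = sum(drop_implant & !bad_birads),
                  mis_scan = sum(drop_mis & !drop_implant & !bad_birads)))
}

#' Patient-wise train/validation/test split
#'
#' Partitions patients (never images) into the three sets with
#' largest-remainder rounding of the target counts, so all images of one
#' patient share a set and no information leaks across sets. Patients are
#' processed grouped by BIRADS label (best-effort stratification) and
#' assigned, in seeded-shuffled order, to whichever set is furthest below
#' its target — which reproduces the target counts exactly.
#'
#' @param manifest data.frame with `patient_id` and `birads` columns.
#' @param spec an [split_spec()].
#' @return list of three data.frames: `train`, `val`, `test` (subsets of
#'   `manifest`), with the patient assignment in
#'   `attr(, "patient_assignment")`.
#' @export
patientwise_split <- function(manifest, spec = split_spec()) {
  patients <- unique(manifest$patient_id)
  n <- length(patients)
  if (n < 3) stop_fm("need at least 3 patients to form 3 sets, got %d", n)
  # largest-remainder target counts, ties by set order (train, val, test)
  raw <- n * spec$fractions
  counts <- floor(raw)
  rem <- raw - counts
  short <- n - sum(counts)
  if (short > 0) {
    give <- order(-rem, seq_along(rem))[seq_len(short)]
    counts[give] <- counts[give] + 1
  }
  # with n >= 3 every set must be non-empty: move one patient from the
  # largest set into any set the rounding left empty
  while (any(counts == 0)) {
    counts[which.max(counts)] <- max(counts) - 1
    counts[which(counts == 0)[1]] <- 1
  }
  pat_birads <- manifest$birads[match(patients, manifest$patient_id)]
  ord <- withr::with_seed(derive_seed(spec$seed, 71L), {
    shuffled <- sample.int(n)
    shuffled[order(pat_birads[shuffled])] # stratify: spread classes across sets
  })
  assignment <- integer(n)
  filled <- c(0, 0, 0)
  for (p in ord) {
    deficit <- counts - filled
    set <- which.max(deficit / pmax(counts, 1))
    assignment[p] <- set
    filled[set] <- filled[set] + 1
  }
  names_ <- c("train", "val", "test")
  assign_df <- data.frame(patient_id = patients,
                          set = names_[assignment],
                          stringsAsFactors = FALSE)
  out <- lapply(1:3, function(s) {
    manifest[manifest$patient_id %in% patients[assignment == s], ,
             drop = FALSE]
  })
  names(out) <- names_
  attr(out, "patient_assignment") <- assign_df
  out
}

#' Assemble a federation dataset from per-hospital splits
#'
#' Each training hospital contributes its train and validation sets as one
#' federated client; every hospital — including test-only ones, which stand
#' for data providers too small to train on — contributes a separately
#' named test set so performance can be evaluated per data provider.
#'
#' @param per_hospital_splits named list (one entry per hospital) of
#'   [patientwise_split()] results, or for test-only hospitals a list with
#'   a single `test` element.
#' @param test_only character vector of hospital names excluded from
#'   training.
#' @return object of class `fm_federation`: `clients` (named list with
#'   `train` and `val` manifests) and `test_sets` (named list of manifests).
#' @export
assemble_federation <- function(per_hospital_splits, test_only = character(0)) {
  hospitals <- names(per_hospital_splits)
  if (is.null(hospitals) || any(!nzchar(hospitals)))
    stop_fm("per_hospital_splits must be a named list")
  training <- setdiff(hospitals, test_only)
  if (length(training) == 0) stop_fm("at least one training hospital required")
  clients <- lapply(per_hospital_splits[training], function(s) {
    list(train = s$train, val = s$val)
  })
  test_sets <- lapply(hospitals, function(h) {
    s <- per_hospital_splits[[h]]
    if (h %in% test_only) # all of a test-only hospital's data is one test set
      do.call(rbind, s[intersect(names(s), c("train", "val", "test"))])
    else s$test
  })
  names(test_sets) <- hospitals
  structure(list(clients = clients, test_sets = test_sets),
            class = "fm_federation")
}

#' @export
print.fm_federation <- function(x, ...) {
  cat(sprintf("<fm_federation %d clients (%s), %d test sets (%s)>\n",
              length(x$clients), paste(names(x$clients), collapse = ", "),
              length(x$test_sets), paste(names(x$test_sets), collapse = ", ")))
  invisible(x)
}
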