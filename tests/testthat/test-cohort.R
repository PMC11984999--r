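make_manifest <- function(n_patients, images_per_patient = 1,
                          birads = NULL, implant = NULL, mis_scan = NULL,
                          hospital = "H1") {
  pid <- rep(sprintf("P%03d", seq_len(n_patients)), each = images_per_patient)
  n <- length(pid)
  data.frame(patient_id = pid, hospital_id = hospital,
             birads = if (is.null(birads))
               rep_len(c(1, 2, 3, 4, 5), n) else rep(birads,
                                                     each = images_per_patient),
             implant_flag = if (is.null(implant)) rep(FALSE, n)
               else rep(implant, each = images_per_patient),
             mis_scan_flag = if (is.null(mis_scan)) rep(FALSE, n)
               else rep(mis_scan, each = images_per_patient),
             image_index = seq_len(n), stringsAsFactors = FALSE)
}

test_that("exclusion filtering drops BIRADS 0/6 images and flagged patients", {
  man <- make_manifest(10)
  man$birads[4] <- 0
  r <- filter_cohort(man)
  expect_equal(nrow(r$manifest), 9)
  expect_equal(unname(r$report["birads_0_or_6"]), 1)

  man2 <- make_manifest(4, images_per_patient = 3,
                        implant = c(TRUE, FALSE, FALSE, FALSE))
  r2 <- filter_cohort(man2)
  expect_equal(nrow(r2$manifest), 9) # all 3 images of the implant patient gone
  expect_false("P001" %in% r2$manifest$patient_id)
  expect_equal(unname(r2$report["implant"]), 3)

  clean <- make_manifest(6)
  expect_identical(filter_cohort(clean)$manifest, clean)
  allbad <- make_manifest(2, birads = c(0, 6))
  expect_error(filter_cohort(allbad), "empty")
})

test_that("patient-wise splitting hits the 70/20/10 protocol exactly", {
  man <- make_manifest(10, images_per_patient = 2)
  sp <- patientwise_split(man, split_spec(seed = 5))
  asg <- attr(sp, "patient_assignment")
  expect_equal(unname(table(asg$set)[c("train", "val", "test")]),
               c(7L, 2L, 1L), ignore_attr = TRUE)
  # partition: every patient in exactly one set
  expect_setequal(asg$patient_id, unique(man$patient_id))
  expect_equal(anyDuplicated(asg$patient_id), 0)
  all_ids <- c(sp$train$patient_id, sp$val$patient_id, sp$test$patient_id)
  expect_equal(sort(all_ids), sort(man$patient_id))
  # determinism
  expect_identical(sp, patientwise_split(man, split_spec(seed = 5)))
  expect_error(patientwise_split(make_manifest(2), split_spec()),
               "at least 3")
})

test_that("split proportions hold at scale and stratify over classes", {
  man <- make_manifest(100, images_per_patient = 1)
  sp <- patientwise_split(man, split_spec(seed = 9))
  expect_equal(length(unique(sp$train$patient_id)), 70)
  expect_equal(length(unique(sp$val$patient_id)), 20)
  expect_equal(length(unique(sp$test$patient_id)), 10)
  # best-effort stratification: train class shares track the cohort's
  cohort_share <- table(factor(man$birads, 1:5)) / 100
  train_share <- table(factor(sp$train$birads, 1:5)) / 70
  expect_true(all(abs(cohort_share - train_share) < 0.05))
})

test_that("federation assembly separates clients and named test sets", {
  splits <- list(
    H1 = patientwise_split(make_manifest(10, hospital = "H1"),
                           split_spec(seed = 1)),
    H2 = patientwise_split(make_manifest(12, hospital = "H2"),
                           split_spec(seed = 2)),
    H3 = list(test = make_manifest(4, hospital = "H3")))
  fed <- assemble_federation(splits, test_only = "H3")
  expect_length(fed$clients, 2)
  expect_named(fed$clients, c("H1", "H2"))
  expect_length(fed$test_sets, 3)
  expect_named(fed$test_sets, c("H1", "H2", "H3"))
  # a test-only hospital contributes all of its data
  expect_equal(nrow(fed$test_sets$H3), 4)
  # no test patient appears in the same hospital's train or val set
  for (nm in c("H1", "H2"))
    expect_length(intersect(fed$test_sets[[nm]]$patient_id,
                            c(fed$clients[[nm]]$train$patient_id,
                              fed$clients[[nm]]$val$patient_id)), 0)
  # degenerate: one hospital federates to centralized
  solo <- assemble_federation(splits["H1"])
  expect_length(solo$clients, 1)
  expect_error(assemble_federation(splits, test_only = c("H1", "H2", "H3")),
               "at least one training hospital")
})
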