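#' Default end-to-end demo configuration
#'
#' A desk-scale configuration: two heterogeneous hospitals (disjoint
#' intensity ranges, one MONOCHROME1), a small patient cohort, 64x64
#' working resolution, a compact UNet and classifier, and a short FedAvg
#' schedule.
#'
#' @param out_dir output directory.
#' @param seed master seed; every stage derives its own stream from it.
#' @param n_patients,images_per_patient cohort size.
#' @param image_size phantom size.
#' @param input_size classifier input size.
#' @param use_bad run the breast-area-detection cleaning stage (turn off
#'   for the minimal-preprocessing ablation path).
#' @return config list for [run_end_to_end()].
#' @export
demo_config <- function(out_dir = tempfile("fedmammo_demo_"), seed = 1L,
                        n_patients = 60L, images_per_patient = 1L,
                        image_size = c(64, 64), input_size = c(64, 64),
                        use_bad = TRUE) {
  list(out_dir = out_dir, seed = as.integer(seed),
       n_patients = as.integer(n_patients),
       images_per_patient = as.integer(images_per_patient),
       image_size = as.integer(image_size),
       preproc_size = as.integer(input_size * 2L),
       input_size = as.integer(input_size),
       profiles = list(
         hospital_profile("H1", intensity_range = c(0, 1023),
                          photometric = "MONOCHROME1", label_prob = 0.6,
                          clip_prob = 0.25, implant_prob = 0.05,
                          mis_scan_prob = 0.05),
         hospital_profile("H2", intensity_range = c(2000, 4095),
                          photometric = "MONOCHROME2", label_prob = 0.2,
                          clip_prob = 0.10, implant_prob = 0.05,
                          mis_scan_prob = 0.05)),
       seg = list(epochs = 6L, batch_size = 4L, lr = 1e-3,
                  depth = 2L, base = 8L, train_frac = 0.7, val_frac = 0.2),
       fl = list(rounds = 5L, local_epochs = 2L, lr = 1e-3, batch_size = 10L),
       use_bad = use_bad)
}

stage_fail <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_fm("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the full synthetic pipeline end to end
#'
#' synth -> preprocess -> bad-bootstrap -> bad-train -> bad-apply ->
#' split -> fed-train -> evaluate, all driven by one seed. Every stage
#' writes its artifacts under `config$out_dir` and the run closes with a
#' manifest listing each output file with a content hash, the seeds used
#' and the configuration snapshot.
#'
#' @param config a [demo_config()] (or a list with the same fields).
#' @return the run manifest (list), invisibly also written to
#'   `manifest.json`.
#' @export
run_end_to_end <- function(config = demo_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(...) file.path(config$out_dir, ...)

  cohort <- stage_fail("synth", {
    generate_cohort(config$n_patients, config$images_per_patient,
                    config$profiles, seed = derive_seed(config$seed, 1L),
                    image_size = config$image_size)
  })
  write.csv(cohort$manifest, outfile("cohort_manifest.csv"), row.names = FALSE)

  pre <- stage_fail("preprocess", {
    lapply(cohort$records, preprocess, target_size = config$preproc_size)
  })

  if (isTRUE(config$use_bad)) {
    auld <- stage_fail("bad-bootstrap", {
      build_auld(pre, cfg = augmentation_config(seed = derive_seed(config$seed, 2L)))
    })
    write.csv(auld$manifest, outfile("auld_manifest.csv"), row.names = FALSE)

    seg_fit <- stage_fail("bad-train", {
      n_sources <- length(unique(auld$manifest$source_id))
      n_train <- max(1, round(config$seg$train_frac * n_sources)) * 5L
      n_val <- max(1, round(config$seg$val_frac * n_sources)) * 5L
      scfg <- seg_train_config(n_train = n_train, n_val = n_val,
                               epochs = config$seg$epochs,
                               lr = config$seg$lr,
                               batch_size = config$seg$batch_size,
                               seed = derive_seed(config$seed, 3L),
                               depth = config$seg$depth,
                               base = config$seg$base)
      sp <- split_auld(auld, scfg)
      train_unet(auld$samples[sp$train], auld$samples[sp$val], scfg)
    })
    write.csv(seg_fit$history, outfile("seg_history.csv"), row.names = FALSE)

    cls_images <- stage_fail("bad-apply", {
      lapply(pre, function(rec) {
        m <- predict_mask(seg_fit, rec$pixels)
        if (!any(m)) resize2d(rec$pixels, config$input_size)
        else clean_and_crop(rec$pixels, m, out_size = config$input_size)
      })
    })
  } else {
    seg_fit <- NULL
    cls_images <- lapply(pre, function(rec)
      resize2d(rec$pixels, config$input_size))
  }

  split_stage <- stage_fail("split", {
    filt <- filter_cohort(cohort$manifest)
    hospitals <- sort(unique(filt$manifest$hospital_id))
    splits <- lapply(hospitals, function(h) {
      patientwise_split(filt$manifest[filt$manifest$hospital_id == h, ],
                        split_spec(seed = derive_seed(config$seed, 4L,
                                                      match(h, hospitals))))
    })
    names(splits) <- hospitals
    list(fed = assemble_federation(splits),
         assignments = lapply(splits, attr, "patient_assignment"))
  })
  fed <- split_stage$fed
  jsonlite::write_json(split_stage$assignments, outfile("splits.json"))

  fed_fit <- stage_fail("fed-train", {
    build <- function(man) list(x = cls_images[man$image_index],
                                y = as.integer(man$birads))
    clients <- lapply(fed$clients, function(s) build(s$train))
    norm <- federated_norm_stats(clients)
    apply_norm <- function(ds) {
      ds$x <- lapply(ds$x, normalize_image, stats = norm)
      ds
    }
    clients <- lapply(clients, apply_norm)
    tests <- lapply(fed$test_sets, function(man) apply_norm(build(man)))
    model <- build_model(input_size = config$input_size,
                         seed = derive_seed(config$seed, 5L))
    cfg <- fl_config(rounds = config$fl$rounds,
                     local_epochs = config$fl$local_epochs,
                     client_config = train_config(lr = config$fl$lr,
                                                  batch_size = config$fl$batch_size,
                                                  epochs = 1L,
                                                  seed = derive_seed(config$seed, 6L)),
                     seed = derive_seed(config$seed, 6L))
    fit <- run_federated(clients, tests, model, cfg)
    attr(fit, "final_f1") <- {
      final <- tail(fit$rounds, 1)
      setNames(vapply(names(tests),
                      function(nm) final[[paste0("f1_", nm)]], 0),
               names(tests))
    }
    fit
  })
  write.csv(fed_fit$rounds, outfile("fl_rounds.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(attr(fed_fit, "final_f1")),
                       outfile("final_f1.json"), auto_unbox = TRUE,
                       digits = NA)

  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[!basename(files) %in% "manifest.json"]
  manifest <- list(
    tool_version = as.character(utils::packageVersion("fedmammo")),
    seed = config$seed,
    config = config[setdiff(names(config), "profiles")],
    hospitals = vapply(config$profiles, `[[`, "", "hospital_id"),
    stages = c("synth", "preprocess",
               if (isTRUE(config$use_bad))
                 c("bad-bootstrap", "bad-train", "bad-apply"),
               "split", "fed-train", "evaluate"),
    final_f1 = as.list(attr(fed_fit, "final_f1")),
    outputs = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, outfile("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
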