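#' Federated learning configuration
#'
#' `rounds * local_epochs` is the total number of local passes each client
#' makes over its data; the reference protocol compares `(100, 1)`,
#' `(50, 2)` and `(20, 5)`, all totalling 100.
#'
#' @param rounds number of FedAvg rounds (>= 1).
#' @param local_epochs local epochs per round (>= 1).
#' @param weighting `"sample_size"` (canonical FedAvg) or `"uniform"`.
#' @param client_config an [train_config()] shared by all clients.
#' @param seed integer seed for the broadcast initial model.
#' @return list of class `fm_fl_config`.
#' @export
fl_config <- function(rounds = 50L, local_epochs = 2L,
                      weighting = c("sample_size", "uniform"),
                      client_config = train_config(), seed = 1L) {
  weighting <- match.arg(weighting)
  if (rounds < 1 || local_epochs < 1)
    stop_fm("rounds and local_epochs must be >= 1")
  structure(list(rounds = as.integer(rounds),
                 local_epochs = as.integer(local_epochs),
                 weighting = weighting, client_config = client_config,
                 seed = as.integer(seed)),
            class = "fm_fl_config")
}

#' FedAvg parameter merge
#'
#' Every parameter of the output model is the weighted average of the
#' corresponding client parameters — uniform weights, or proportional to
#' client sample counts (canonical FedAvg).
#'
#' @param models list of parameter lists (or objects with a `$params`
#'   element) with identical architectures.
#' @param sample_counts positive client sample counts (required for
#'   `weighting = "sample_size"`).
#' @param weighting `"sample_size"` or `"uniform"`.
#' @return merged parameter list.
#' @export
fedavg_merge <- function(models, sample_counts = NULL,
                         weighting = c("sample_size", "uniform")) {
  weighting <- match.arg(weighting)
  params <- lapply(models, function(m) if (!is.null(m$params)) m$params else m)
  ref <- params[[1]]
  for (p in params[-1]) {
    if (!identical(names(p), names(ref)) ||
        !all(mapply(function(a, b) identical(dim(a) %||% length(a),
                                             dim(b) %||% length(b)), p, ref)))
      stop_fm("client model architectures do not match; cannot merge")
  }
  w <- if (weighting == "uniform") {
    rep(1 / length(params), length(params))
  } else {
    if (is.null(sample_counts) || length(sample_counts) != length(params) ||
        any(sample_counts <= 0))
      stop_fm("sample_size weighting needs one positive count per client")
    sample_counts / sum(sample_counts)
  }
  # anchored form of the weighted mean: exact when all clients coincide
  # (merging K copies of one model returns that model bit for bit)
  out <- ref
  if (length(params) > 1) {
    for (nm in names(ref)) {
      acc <- params[[1]][[nm]]
      for (k in 2:length(params))
        acc <- acc + w[k] * (params[[k]][[nm]] - params[[1]][[nm]])
      out[[nm]] <- acc
    }
  }
  out
}

#' Run an in-process FedAvg simulation
#'
#' Synchronous rounds: broadcast the current global model, let every client
#' train `local_epochs` passes over its local data, merge with
#' [fedavg_merge()], then evaluate the merged model on every named test
#' set. Client optimizer state persists across rounds, so a single-client
#' federation reproduces centralized training exactly. Each client's data
#' order is reshuffled every local epoch with a global-epoch-indexed seed.
#'
#' @param clients named list of client training datasets
#'   (from [make_dataset()]).
#' @param test_sets named list of evaluation datasets.
#' @param model an [build_model()] result used as the broadcast initial
#'   model.
#' @param cfg an [fl_config()].
#' @param verbose print per-round progress.
#' @return object of class `fm_fed_fit`: `params` (final merged model),
#'   `config`, `rounds` (data.frame: round, per-client local loss,
#'   per-test-set macro F1), `client_epochs` (named total local epochs).
#' @export
run_federated <- function(clients, test_sets, model, cfg = fl_config(),
                          verbose = FALSE) {
  stopifnot(inherits(model, "fm_cnn"), inherits(cfg, "fm_fl_config"))
  if (length(clients) == 0) stop_fm("need at least one client")
  empty <- vapply(clients, function(d) length(d$x) == 0, TRUE)
  if (any(empty))
    stop_fm("client dataset(s) empty before round 1: %s",
            paste(names(clients)[empty], collapse = ", "))
  counts <- vapply(clients, function(d) length(d$x), 0)
  global <- model$params
  states <- lapply(clients, function(d) adam_init(global))
  epoch_log <- setNames(rep(0L, length(clients)), names(clients))
  records <- list()
  for (r in seq_len(cfg$rounds)) {
    locals <- vector("list", length(clients))
    losses <- numeric(length(clients))
    for (k in seq_along(clients)) {
      res <- cnn_run_epochs(global, states[[k]], model$config, clients[[k]],
                            cfg$client_config, cfg$local_epochs,
                            global_epoch0 = (r - 1L) * cfg$local_epochs)
      locals[[k]] <- res$params
      states[[k]] <- res$state
      losses[k] <- tail(res$losses, 1)
      epoch_log[k] <- epoch_log[k] + cfg$local_epochs
    }
    global <- fedavg_merge(locals, counts, cfg$weighting)
    merged_fit <- structure(list(params = global, config = model$config),
                            class = "fm_cnn_fit")
    f1s <- vapply(test_sets, function(ds) {
      macro_f1(ds$y, predict(merged_fit, ds))
    }, 0)
    row <- data.frame(round = r)
    for (k in seq_along(clients))
      row[[paste0("loss_", names(clients)[k])]] <- losses[k]
    for (nm in names(test_sets)) row[[paste0("f1_", nm)]] <- f1s[nm]
    records[[r]] <- row
    if (verbose)
      message(sprintf("round %3d  losses [%s]  F1 [%s]", r,
                      paste(sprintf("%.3f", losses), collapse = ", "),
                      paste(sprintf("%.3f", f1s), collapse = ", ")))
  }
  structure(list(params = global, config = model$config, fl_config = cfg,
                 rounds = do.call(rbind, records),
                 client_epochs = epoch_log),
            class = "fm_fed_fit")
}

#' @export
print.fm_fed_fit <- function(x, ...) {
  cat(sprintf("<fm_fed_fit %d rounds x %d local epochs, %d clients>\n",
              x$fl_config$rounds, x$fl_config$local_epochs,
              length(x$client_epochs)))
  invisible(x)
}

#' Rounds-versus-epochs trade-off sweep
#'
#' Runs [run_federated()] once per `(rounds, local_epochs)` combination
#' from a common initial model and reports the final macro F1 per test set
#' for each, plus the per-round F1 traces. Combinations whose total local
#' epochs differ are flagged with a warning (not comparable).
#'
#' @param clients,test_sets,model as in [run_federated()].
#' @param combos list of `c(rounds, epochs)` pairs, default the reference
#'   protocol `list(c(100, 1), c(50, 2), c(20, 5))`.
#' @param cfg base [fl_config()] supplying weighting and client config.
#' @return list: `table` (data.frame: rounds, epochs, one F1 column per
#'   test set), `traces` (list of per-round histories), `fits`.
#' @export
rounds_epochs_sweep <- function(clients, test_sets, model,
                                combos = list(c(100, 1), c(50, 2), c(20, 5)),
                                cfg = fl_config()) {
  totals <- vapply(combos, prod, 0)
  if (length(unique(totals)) > 1)
    warning("combos differ in total local epochs (",
            paste(totals, collapse = ", "),
            "); final models are not comparable", call. = FALSE)
  rows <- list(); traces <- list(); fits <- list()
  for (i in seq_along(combos)) {
    ci <- cfg
    ci$rounds <- as.integer(combos[[i]][1])
    ci$local_epochs <- as.integer(combos[[i]][2])
    fit <- run_federated(clients, test_sets, model, ci)
    final <- tail(fit$rounds, 1)
    row <- data.frame(rounds = ci$rounds, epochs = ci$local_epochs)
    for (nm in names(test_sets)) row[[paste0("f1_", nm)]] <- final[[paste0("f1_", nm)]]
    rows[[i]] <- row
    traces[[i]] <- fit$rounds
    fits[[i]] <- fit
  }
  list(table = do.call(rbind, rows), traces = traces, fits = fits)
}

#' Shared normalization statistics across clients
#'
#' Computes min/max per client and merges them into global statistics —
#' the harmonization step of exchanging normalization values between
#' hospitals before round 1.
#'
#' @param client_datasets named list of datasets.
#' @return an `fm_norm` with the global min and max.
#' @export
federated_norm_stats <- function(client_datasets) {
  per_client <- lapply(client_datasets, compute_norm_stats)
  structure(list(pixel_min = min(vapply(per_client, `[[`, 0, "pixel_min")),
                 pixel_max = max(vapply(per_client, `[[`, 0, "pixel_max"))),
            class = "fm_norm")
}

#' Harmonization ablation on a heterogeneous synthetic federation
#'
#' Trains two federations on the same cohort: (A) minimal pre-processing —
#' raw stored pixels resized to the model input; (B) the full harmonization
#' pipeline — metadata-driven preprocessing (rescale, inversion, windowing,
#' laterality), breast-mask cleaning and peripheral cropping. Both use the
#' same split, the same shared normalization protocol and the same FL
#' configuration, so any performance difference is attributable to
#' harmonization. Reports per-hospital F1 for both conditions, the
#' worst-hospital F1 and the inter-hospital spread.
#'
#' @param records,manifest a cohort from [generate_cohort()].
#' @param profiles the hospital profiles that generated the cohort (used
#'   only to warn when they are identical and the ablation is vacuous).
#' @param model an [build_model()] result (its `input_size` sets the
#'   working resolution).
#' @param cfg an [fl_config()].
#' @param mask_fun function(image) -> logical mask used for BAD cleaning in
#'   condition B; defaults to the quality-filtered K-means bootstrap with
#'   fallback to the full-image mask.
#' @param seed split seed.
#' @param tail_rounds per-hospital F1 is averaged over the last
#'   `tail_rounds` rounds rather than taken from the final round alone —
#'   round-to-round jitter on small test sets otherwise dominates the
#'   comparison.
#' @return list: `per_hospital` (data.frame: condition, hospital, f1),
#'   `worst` and `spread` (named by condition), `fits`.
#' @export
harmonization_ablation <- function(records, manifest, profiles, model,
                                   cfg = fl_config(), mask_fun = NULL,
                                   seed = 1L, tail_rounds = 10L) {
  if (length(unique(vapply(profiles, function(p) {
    paste(format(p$intensity_range), p$photometric, collapse = " ")
  }, ""))) == 1)
    warning("hospital profiles are identical; the ablation contrasts nothing",
            call. = FALSE)
  input_size <- model$input_size
  if (is.null(mask_fun)) {
    mask_fun <- function(img) {
      m <- tryCatch(kmeans_mask(img), error = function(e) NULL)
      if (is.null(m)) return(matrix(TRUE, nrow(img), ncol(img)))
      qf <- quality_filter(masked_mammogram(img, m))
      if (qf$accept && any(m)) m else matrix(TRUE, nrow(img), ncol(img))
    }
  }
  prep <- list(
    minimal = function(rec) resize2d(rec$pixels, input_size),
    harmonized = function(rec) {
      pp <- preprocess(rec, target_size = 2L * input_size)
      m <- mask_fun(pp$pixels)
      clean_and_crop(pp$pixels, m, out_size = input_size)
    })

  filt <- filter_cohort(manifest)
  hospitals <- sort(unique(filt$manifest$hospital_id))
  splits <- lapply(hospitals, function(h) {
    patientwise_split(filt$manifest[filt$manifest$hospital_id == h, ],
                      split_spec(seed = derive_seed(seed, match(h, hospitals))))
  })
  names(splits) <- hospitals
  fed <- assemble_federation(splits)

  out_rows <- list(); fits <- list()
  for (cond in names(prep)) {
    imgs <- lapply(records, prep[[cond]])
    build <- function(man) {
      list(x = imgs[man$image_index], y = as.integer(man$birads))
    }
    clients <- lapply(fed$clients, function(s) build(s$train))
    norm <- federated_norm_stats(clients)
    apply_norm <- function(ds) {
      ds$x <- lapply(ds$x, normalize_image, stats = norm)
      ds
    }
    clients <- lapply(clients, apply_norm)
    # evaluate on each hospital's val + test patients: FL clients train on
    # the train split only, so the val patients stay held out, and the
    # larger evaluation set stabilizes the per-hospital F1 estimate
    tests <- lapply(names(fed$test_sets), function(h) {
      man <- fed$test_sets[[h]]
      if (!is.null(fed$clients[[h]])) man <- rbind(fed$clients[[h]]$val, man)
      apply_norm(build(man))
    })
    names(tests) <- names(fed$test_sets)
    fit <- run_federated(clients, tests, model, cfg)
    last <- tail(fit$rounds, min(tail_rounds, nrow(fit$rounds)))
    f1 <- vapply(names(tests), function(nm) mean(last[[paste0("f1_", nm)]]), 0)
    out_rows[[cond]] <- data.frame(condition = cond, hospital = names(tests),
                                   f1 = unname(f1), stringsAsFactors = FALSE)
    fits[[cond]] <- fit
  }
  per_hospital <- do.call(rbind, out_rows)
  rownames(per_hospital) <- NULL
  worst <- vapply(split(per_hospital$f1, per_hospital$condition), min, 0)
  spread <- vapply(split(per_hospital$f1, per_hospital$condition),
                   function(v) max(v) - min(v), 0)
  list(per_hospital = per_hospital, worst = worst, spread = spread,
       fits = fits)
}
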