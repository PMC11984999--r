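# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the default run stays fast.

two_hospital_profiles <- function(label_prob = c(0.6, 0.2),
                                  clip_prob = c(0.25, 0.10),
                                  implant_prob = c(0, 0),
                                  mis_scan_prob = c(0, 0)) {
  list(hospital_profile("H1", intensity_range = c(0, 1023),
                        photometric = "MONOCHROME1",
                        label_prob = label_prob[1], clip_prob = clip_prob[1],
                        implant_prob = implant_prob[1],
                        mis_scan_prob = mis_scan_prob[1]),
       hospital_profile("H2", intensity_range = c(2000, 4095),
                        photometric = "MONOCHROME2",
                        label_prob = label_prob[2], clip_prob = clip_prob[2],
                        implant_prob = implant_prob[2],
                        mis_scan_prob = mis_scan_prob[2]))
}

clean_profile <- function(id = "H0", range = c(0, 4095)) {
  hospital_profile(id, intensity_range = range, label_prob = 0,
                   clip_prob = 0, implant_prob = 0, mis_scan_prob = 0)
}

# a two-level blob image: bright half-ellipse on dark background
two_level_image <- function(n = 64, fg = 0.8, bg = 0.1, noise_sd = 0) {
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  mask <- ((rr - n / 2) / (0.4 * n))^2 + ((cc - 1) / (0.55 * n))^2 <= 1
  img <- matrix(bg, n, n)
  img[mask] <- fg
  if (noise_sd > 0) img <- img + matrix(rnorm(n * n, sd = noise_sd), n, n)
  list(image = img, mask = mask)
}

# labeled dataset with a known linear class structure, for F1 checks
constant_prediction_fit <- function(class_idx, n_classes = 5L) {
  model <- build_model(n_classes = n_classes, input_size = c(16, 16),
                       channels = c(2L, 2L), seed = 1)
  params <- model$params
  for (nm in names(params)) params[[nm]] <- params[[nm]] * 0
  params$head_b[class_idx] <- 10
  structure(list(params = params, config = model$config),
            class = "fm_cnn_fit")
}

tiny_dataset <- function(n, n_classes = 5L, size = 16L, seed = 1) {
  withr::with_seed(seed, {
    list(x = replicate(n, matrix(runif(size * size), size, size),
                       simplify = FALSE),
         y = sample.int(n_classes, n, replace = TRUE))
  })
}
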