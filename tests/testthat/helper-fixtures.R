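# Shared fixtures. Heavy objects (trained models, full pipeline runs) are
# built once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small random volume with exactly float64-representable values
rand_volume <- function(shape = c(4, 8, 16), seed = 1) {
  octseg:::with_seed(seed, {
    arr <- array(stats::runif(prod(shape)), shape)
    oct_volume(arr, spacing = c(1.4, 14.0, 0.78), metadata = list(mode = "healthy"))
  })
}

# noiseless healthy phantom: every nuisance off, no ONH (surfaces never
# converge), smooth topography kept
noiseless_params <- function(shape = c(8, 64, 448)) {
  phantom_params(shape = shape, mode = "healthy", speckle_shape = Inf,
                 noise_sd = 0, jitter_sd_voxels = 0, n_vessels = 0,
                 onh_radius_mm = 0, onh_depth_um = 0)
}

# LD severity field ramping smoothly into a fully ablated right-hand region;
# returns list(sev, region_cols)
ld_ramp_severity <- function(shape, ramp_start_frac = 0.45, ramp_cols = 20L,
                             base = 0.74) {
  X <- shape[2]
  x0 <- round(X * ramp_start_frac)
  ramp <- pmin(1, pmax(0, ((1:X) - x0) / ramp_cols))
  sev <- matrix(base + (1 - base) * rep(ramp, each = shape[1]), shape[1], X)
  list(sev = sev, region_cols = (x0 + ramp_cols + 1):X)
}

# small trained healthy pipeline (shared by pipeline tests)
small_healthy_fit <- function() {
  memo("small_healthy_fit", function() {
    shape <- c(12, 64, 448)
    ptrain <- generate_phantom(phantom_params(shape = shape), seed = 11)
    ptest <- generate_phantom(phantom_params(shape = shape), seed = 22)
    rater <- rater_model(sd_um = 1.0, spacing_px = 4)
    delin <- simulate_rater(ptrain$truth, rater,
                            slice_ids = c(1, 3, 5, 7, 9, 11), seed = 5)
    models <- train_segmentation_models(ptrain$volume, delin, "healthy",
                                        seed = 42)
    seg <- segment_retina(ptest$volume, "healthy", models)
    list(ptrain = ptrain, ptest = ptest, models = models, seg = seg)
  })
}

# acceptance-scale fixtures (25 x 128 x 512)
acc_shape <- c(25, 128, 512)

acc_healthy_fit <- function() {
  memo("acc_healthy_fit", function() {
    ptrain <- generate_phantom(phantom_params(shape = acc_shape), seed = 101)
    ptest <- generate_phantom(phantom_params(shape = acc_shape), seed = 202)
    rater <- rater_model(sd_um = 1.0, spacing_px = 8)
    delin <- simulate_rater(ptrain$truth, rater,
                            slice_ids = c(2, 6, 10, 14, 18, 22), seed = 7)
    models <- train_segmentation_models(ptrain$volume, delin, "healthy",
                                        seed = 42)
    seg <- segment_retina(ptest$volume, "healthy", models)
    list(ptrain = ptrain, ptest = ptest, models = models, seg = seg)
  })
}

acc_ld_fit <- function() {
  memo("acc_ld_fit", function() {
    lr <- ld_ramp_severity(acc_shape)
    pars <- phantom_params(shape = acc_shape, mode = "ld", ld_severity = lr$sev)
    ptrain <- generate_phantom(pars, seed = 303)
    ptest <- generate_phantom(pars, seed = 404)
    rater <- rater_model(sd_um = 1.0, spacing_px = 8)
    delin <- simulate_rater(ptrain$truth, rater,
                            slice_ids = c(2, 6, 10, 14, 18, 22), seed = 7)
    models <- train_segmentation_models(ptrain$volume, delin, "ld", seed = 42)
    seg <- segment_retina(ptest$volume, "ld", models)
    list(ptrain = ptrain, ptest = ptest, models = models, seg = seg,
         region_cols = lr$region_cols)
  })
}

# random feasible small instance for the oracle-equivalence suite
random_instance <- function(seed) {
  octseg:::with_seed(seed, {
    repeat {
      ns <- sample(1:3, 1)
      dims <- list(c(1, 2), c(1, 3), c(2, 2), c(1, 4), c(2, 3), c(1, 8))[[sample(6, 1)]]
      Z <- sample(4:10, 1)
      if (Z^(ns * prod(dims)) > 5e5) next
      costs <- lapply(seq_len(ns), function(s)
        array(sample(0:9, prod(dims) * Z, TRUE), c(dims, Z)))
      ms <- if (ns > 1) sample(0:2, ns - 1, TRUE) else NULL
      mx <- if (ns > 1) ms + sample(0:4, ns - 1, TRUE) else NULL
      cons <- constraint_spec(sample(0:3, ns, TRUE), sample(0:3, ns, TRUE),
                              ms, mx, n_surfaces = ns)
      feasible <- tryCatch({
        octseg:::.feasible_ranges(cons, Z)
        TRUE
      }, error = function(e) FALSE)
      if (feasible) return(list(costs = costs, cons = cons))
    }
  })
}
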