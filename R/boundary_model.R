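# Random-forest boundary classifiers: voxels near a delineated surface are
# labelled with that surface, everything else inside the ROI is background;
# class probabilities are mapped to graph costs as 1 - P.

#' Train a per-stage boundary classifier
#'
#' Voxels within +/- 1 voxel (axial) of a delineated surface receive that
#' surface's label; all other voxels of the traced B-scans inside the ROI
#' band are background. Classes are balanced by subsampling before a
#' probability random forest is grown. Training is deterministic given the
#' seed. Delineation coordinates must be in the voxel units of the feature
#' stacks (the working resolution).
#'
#' @param stacks list of [extract_features()] stacks, one per training
#'   volume.
#' @param delineations list of [delineation()]s parallel to `stacks`.
#' @param stage_surfaces surface names this stage segments (the class list
#'   is `background` plus these, in order).
#' @param mode `"healthy"` or `"ld"`; recorded so that control and LD
#'   scans use disjoint model families.
#' @param seed integer seed for subsampling and forest growth.
#' @param num_trees forest size.
#' @param max_per_class cap on training voxels per class.
#' @param label_band axial labelling half-width in voxels.
#' @return an object of class `boundary_model` with the fitted forest, the
#'   class list, the feature recipe id and the out-of-bag accuracy.
#' @export
train_boundary_classifier <- function(stacks, delineations, stage_surfaces,
                                      mode = c("healthy", "ld"), seed = 1L,
                                      num_trees = 100L, max_per_class = 2000L,
                                      label_band = 1) {
  mode <- match.arg(mode)
  if (inherits(stacks, "feature_stack")) stacks <- list(stacks)
  if (inherits(delineations, "delineation")) delineations <- list(delineations)
  stopifnot(length(stacks) == length(delineations), length(stacks) >= 1L)

  feats <- list(); labels <- list()
  for (v in seq_along(stacks)) {
    st <- stacks[[v]]
    B <- st$dims[1]; X <- st$dims[2]; nz <- st$dims[3]
    zs <- st$zmin + seq_len(nz) - 1L
    traced <- delineation_to_surface(delineations[[v]], x_grid = 0:(X - 1))
    slice_bs <- sort(unique(vapply(delineations[[v]]$slices, function(s) s$b, 0L)))
    for (b in slice_bs) {
      # rows of stack for this b: b fastest, then x, then z
      row_idx <- rep(b + 1L, X * nz) + (rep(seq_len(X) - 1L, nz)) * B +
        (rep(seq_len(nz) - 1L, each = X)) * B * X
      lab <- rep("background", X * nz)
      zmat <- matrix(rep(zs, each = X), X, nz)        # (x, z) grid of depths
      best <- matrix(Inf, X, nz)
      for (nm in names(traced)) {
        tr <- traced[[nm]][[as.character(b)]]
        if (is.null(tr) || !nm %in% stage_surfaces) next
        dist <- abs(zmat - tr)                         # recycles tr down columns
        dist[is.na(dist) | dist > label_band] <- Inf
        # overlapping bands (near-coincident surfaces) go to the nearer one
        upd <- which(dist < best - 1e-9)
        lab[upd] <- nm
        best[upd] <- dist[upd]
      }
      feats[[length(feats) + 1L]] <- st$X[row_idx, , drop = FALSE]
      labels[[length(labels) + 1L]] <- lab
    }
  }
  Xall <- do.call(rbind, feats)
  yall <- unlist(labels, use.names = FALSE)

  missing <- setdiff(stage_surfaces, unique(yall))
  if (length(missing))
    stop("no annotations found for stage surface(s): ",
         paste(missing, collapse = ", "))
  classes <- c("background", stage_surfaces)
  if (length(unique(yall)) < 2L)
    stop("training data contain a single class; need at least 2")

  with_seed(seed, {
    keep <- unlist(lapply(split(seq_along(yall), yall), function(ix) {
      if (length(ix) > max_per_class) sample(ix, max_per_class) else ix
    }), use.names = FALSE)
    dat <- data.frame(Xall[keep, , drop = FALSE])
    dat$.y <- factor(yall[keep], levels = classes)
    forest <- ranger::ranger(
      dependent.variable.name = ".y", data = dat, probability = TRUE,
      num.trees = num_trees, seed = seed, num.threads = 1L
    )
    oob <- forest$predictions
    ok <- stats::complete.cases(oob)
    oob_acc <- mean(colnames(oob)[max.col(oob[ok, , drop = FALSE])] ==
                      as.character(dat$.y)[ok])
    structure(list(forest = forest, classes = classes,
                   stage_surfaces = stage_surfaces, mode = mode,
                   recipe = .FEATURE_RECIPE, seed = seed,
                   oob_accuracy = oob_acc),
              class = "boundary_model")
  })
}

#' @export
print.boundary_model <- function(x, ...) {
  cat(sprintf("<boundary_model> mode %s, surfaces: %s\n", x$mode,
              paste(x$stage_surfaces, collapse = ", ")))
  cat(sprintf("  %d trees, OOB accuracy %.3f, recipe %s\n",
              x$forest$num.trees, x$oob_accuracy, x$recipe))
  invisible(x)
}

#' Predict per-surface cost volumes from a boundary classifier
#'
#' Produces one cost volume per stage surface over the feature stack's depth
#' band: `cost = 1 - P(surface)`, a bounded monotone transform of the class
#' probability.
#'
#' @param model a [train_boundary_classifier()] model.
#' @param stack an [extract_features()] stack with a matching feature
#'   recipe.
#' @return named list of 3-D cost arrays `(B, X, nz)` over the stack's
#'   band, ordered as the stage surfaces.
#' @export
predict_costs <- function(model, stack) {
  stopifnot(inherits(model, "boundary_model"), inherits(stack, "feature_stack"))
  if (!identical(model$recipe, stack$recipe))
    stop("feature recipe mismatch: model ", model$recipe,
         " vs stack ", stack$recipe)
  pr <- stats::predict(model$forest, data = data.frame(stack$X),
                       num.threads = 1L)$predictions
  out <- lapply(model$stage_surfaces, function(nm) {
    array(1 - pr[, nm], stack$dims)
  })
  names(out) <- model$stage_surfaces
  out
}

#' Persist / load a boundary model
#'
#' The model is stored as a single serialized file embedding its metadata
#' (class list, feature recipe, mode, seed) alongside the forest.
#'
#' @param model a `boundary_model`.
#' @param path file path.
#' @return `save_boundary_model` returns `path` invisibly;
#'   `load_boundary_model` the model.
#' @export
save_boundary_model <- function(model, path) {
  stopifnot(inherits(model, "boundary_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_boundary_model
#' @export
load_boundary_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "boundary_model")) stop("not a boundary model: ", path)
  m
}
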