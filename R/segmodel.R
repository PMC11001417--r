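#' Instance segmentation backends
#'
#' The training stage is defined against a backend contract (initialize,
#' one optimization step, per-pixel probability maps). The registered
#' `"ref"` backend is a lightweight encoder-decoder that runs on CPU at
#' desk scale: a fixed multi-scale convolutional feature encoder (Gaussian
#' pyramid, difference-of-Gaussians band-pass maps, gradient magnitude,
#' local standard deviation) followed by a trainable per-class logistic
#' pixel decoder, optimized by stochastic gradient descent with momentum
#' on a class-balanced binary cross-entropy loss. Instances are extracted
#' from the thresholded probability map as 8-connected components, each
#' scored by its mean interior probability.
#'
#' @name segmentation-backends
NULL

.backend_registry <- new.env(parent = emptyenv())

register_backend <- function(id, spec) assign(id, spec, envir = .backend_registry)

available_backends <- function() ls(.backend_registry)

get_backend <- function(id) {
  if (!exists(id, envir = .backend_registry)) {
    abort(sprintf("unknown backend `%s`; available backends: %s",
                  id, paste(available_backends(), collapse = ", ")))
  }
  get(id, envir = .backend_registry)
}

# Feature encoder -------------------------------------------------------------

REF_FEATURE_NAMES <- c("contrast", "dog_fine", "dog_mid", "dog_coarse",
                       "grad_fine", "grad_coarse", "local_sd", "global")

# gradient magnitude by central differences
grad_mag <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- (m[, c(2:nc, nc)] - m[, c(1, 1:(nc - 1))]) / 2
  gy <- (m[c(2:nr, nr), ] - m[c(1, 1:(nr - 1)), ]) / 2
  sqrt(gx^2 + gy^2)
}

gblur_mat <- function(m, sigma) {
  EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = sigma))
}

# Per-feature gains put every channel on a comparable O(1) scale for the
# logistic decoder; `gain` is the backend's global input gain, part of the
# fixed feature specification (a reparameterization of the decoder, chosen
# once so that the default learning-rate regime converges at these image
# sizes).
ref_encode <- function(img, gain = 6) {
  x <- as_gray(img)
  g1 <- gblur_mat(x, 1); g2 <- gblur_mat(x, 2)
  g4 <- gblur_mat(x, 4); g8 <- gblur_mat(x, 8)
  sd_local <- sqrt(pmax(0, gblur_mat(x^2, 2) - g2^2))
  feats <- list(
    contrast   = (x - g8) * 5,
    dog_fine   = (g1 - g2) * 12,
    dog_mid    = (g2 - g4) * 9,
    dog_coarse = (g4 - g8) * 7,
    grad_fine  = grad_mag(g1) * 15,
    grad_coarse = grad_mag(g4) * 30,
    local_sd   = sd_local * 10,
    global     = (x - mean(x)) * 4
  )
  arr <- array(0, c(nrow(x), ncol(x), length(feats)))
  for (k in seq_along(feats)) arr[, , k] <- feats[[k]] * gain
  arr
}

register_backend("ref", list(
  id = "ref",
  n_features = length(REF_FEATURE_NAMES),
  encode = ref_encode,
  description = "multi-scale feature encoder + logistic pixel decoder"
))

# Model state ------------------------------------------------------------------

#' Initialize a segmentation model
#'
#' @param backend_id registered backend (`"ref"`).
#' @param class_set character vector of classes the model predicts. The
#'   default single class `"crystal"` matches any ground-truth label
#'   starting with `"crystal"` during training.
#' @param warm_start an existing `crystal_model` to copy parameters from
#'   (transfer learning); its lineage is inherited. If its class set
#'   differs, matching heads are copied and the others re-initialized,
#'   with a warning.
#' @param seed seed for the random parameter initialization.
#' @return object of class `crystal_model`.
#' @export
init_model <- function(backend_id = "ref", class_set = "crystal",
                       warm_start = NULL, seed = 1) {
  backend <- get_backend(backend_id)
  nf <- backend$n_features
  nc <- length(class_set)
  W <- with_seed(seed, matrix(rnorm((nf + 1) * nc, 0, 0.01), nf + 1, nc))
  W[1, ] <- -2  # bias towards background (foreground is sparse)
  colnames(W) <- class_set
  lineage <- tibble(fingerprint = character(), role = character(),
                    epochs = integer(), learning_rate = numeric(),
                    n_images = integer())
  if (!is.null(warm_start)) {
    stopifnot(inherits(warm_start, "crystal_model"))
    if (warm_start$backend_id != backend_id) {
      abort("warm start requires the same backend")
    }
    shared <- intersect(class_set, warm_start$class_set)
    if (!setequal(class_set, warm_start$class_set)) {
      warn(sprintf("class set differs from warm-start model; re-initializing head(s): %s",
                   paste(setdiff(class_set, shared), collapse = ", ")))
    }
    for (cs in shared) W[, cs] <- warm_start$weights[, cs]
    lineage <- warm_start$lineage
  }
  structure(
    list(backend_id = backend_id, class_set = class_set, weights = W,
         feature_gain = 6, lineage = lineage, seed = as.integer(seed),
         prob_threshold = 0.5, min_component_px = 5L),
    class = "crystal_model"
  )
}

#' @export
print.crystal_model <- function(x, ...) {
  cat(sprintf("<crystal_model> backend `%s`, classes: %s\n",
              x$backend_id, paste(x$class_set, collapse = ", ")))
  if (nrow(x$lineage) == 0L) {
    cat("  untrained\n")
  } else {
    for (i in seq_len(nrow(x$lineage))) {
      l <- x$lineage[i, ]
      cat(sprintf("  %d. %s: %d images, %d epochs @ lr %g (data %s)\n",
                  i, l$role, l$n_images, l$epochs, l$learning_rate, l$fingerprint))
    }
  }
  invisible(x)
}

# Training protocol ------------------------------------------------------------

#' Define a training protocol
#'
#' Defaults reproduce the screening pipeline's standard training recipe:
#' primary and combined
#' trainings run 40 epochs at learning rate 1e-3; a secondary (incremental)
#' training continues an already-trained model for 10 epochs at 1e-3 (or
#' the alternative 1e-4); batch size is one image; the mask loss is binary
#' cross-entropy; augmentation is random horizontal/vertical flips and
#' random cropping.
#'
#' @param role `"primary"`, `"secondary"` or `"combined"`.
#' @param epochs number of passes over the training set (default 40, or 10
#'   for `role = "secondary"`).
#' @param learning_rate SGD learning rate (default 1e-3).
#' @param batch_size images per optimization step (the recipe uses 1).
#' @param loss mask loss; only `"BCE"` is defined.
#' @param augmentations subset of `c("hflip", "vflip", "random_crop")`.
#' @param momentum SGD momentum (default 0.9, constant learning rate).
#' @param seed seed for epoch shuffling and augmentation draws.
#' @return object of class `training_protocol`.
#' @export
training_protocol <- function(role = c("primary", "secondary", "combined"),
                              epochs = NULL, learning_rate = 1e-3,
                              batch_size = 1L, loss = "BCE",
                              augmentations = c("hflip", "vflip", "random_crop"),
                              momentum = 0.9, seed = 1) {
  role <- match.arg(role)
  epochs <- as.integer(epochs %||% if (role == "secondary") 10L else 40L)
  if (epochs < 1L) abort("`epochs` must be >= 1")
  if (!is_scalar_number(learning_rate) || learning_rate <= 0) {
    abort("`learning_rate` must be a positive number")
  }
  if (!identical(loss, "BCE")) abort("only the BCE mask loss is defined")
  if (!all(augmentations %in% c("hflip", "vflip", "random_crop"))) {
    abort("`augmentations` must be a subset of hflip, vflip, random_crop")
  }
  structure(
    list(role = role, epochs = epochs, learning_rate = learning_rate,
         batch_size = as.integer(batch_size), loss = loss,
         augmentations = augmentations, momentum = momentum,
         seed = as.integer(seed)),
    class = "training_protocol"
  )
}

# Dataset preparation ----------------------------------------------------------

# Resolve a training input (manifest, list of annotated images, or an
# already-prepped dataset) to cached feature arrays and per-class targets.
prep_dataset <- function(dataset, model) {
  if (inherits(dataset, "prepped_dataset")) {
    if (!identical(attr(dataset, "class_set"), model$class_set)) {
      abort("prepped dataset was built for a different class set")
    }
    return(dataset)
  }
  if (inherits(dataset, "dataset_manifest")) dataset <- load_manifest_images(dataset)
  if (!is.list(dataset) || length(dataset) == 0L) abort("the training dataset is empty")
  backend <- get_backend(model$backend_id)
  items <- lapply(dataset, function(ann) {
    stopifnot(inherits(ann, "annotated_image"))
    if (is.null(ann$image)) abort("training images must carry pixel data")
    shape <- c(ann$height, ann$width)
    targets <- lapply(model$class_set, function(cs) {
      sel <- class_label_matches(ann$instances$label, cs)
      mask_union(polygons_to_masks(ann$instances$polygon[sel], shape), shape)
    })
    names(targets) <- model$class_set
    list(features = backend$encode(ann$image, gain = model$feature_gain),
         targets = targets,
         has_instances = any(vapply(targets, any, logical(1))))
  })
  if (!any(vapply(items, function(x) x$has_instances, logical(1)))) {
    warn("no training image contains an instance of the model's classes")
  }
  fp <- content_hash(c(length(dataset),
                       vapply(dataset, function(a) as.character(a$provenance), character(1))))
  structure(items, class = "prepped_dataset",
            class_set = model$class_set, fingerprint = fp)
}

class_label_matches <- function(labels, class_name) {
  if (class_name == "crystal") grepl("^crystal", labels) else labels == class_name
}

# Augmentation -----------------------------------------------------------------

#' Augment one training sample
#'
#' Random horizontal and vertical flips (probability 0.5 each) and random
#' cropping (crop keeps at least 50 percent of the image area; the crop is
#' re-drawn up to 10 times if it would remove every instance of an
#' annotated sample). Polygons, masks and boxes transform consistently
#' with the image.
#'
#' @param image numeric matrix (grayscale).
#' @param instances instance tibble with `polygon` list-column (as in
#'   [annotated_image()]).
#' @param protocol a [training_protocol()]; its `augmentations` field says
#'   which transforms may fire.
#' @param seed integer seed for the draws.
#' @return list with elements `image` and `instances`.
#' @export
augment_sample <- function(image, instances, protocol, seed) {
  with_seed(seed, {
    draws <- augment_draws(protocol, nrow(image), ncol(image),
                           has_instances = nrow(instances) > 0L,
                           instances = instances)
    apply_augment_image(image, instances, draws)
  })
}

# Draw the augmentation parameters; crop is re-drawn (<= 10 tries) if it
# would leave an annotated sample without any instance.
augment_draws <- function(protocol, nr, nc, has_instances, instances = NULL,
                          fg_mask = NULL) {
  aug <- protocol$augmentations
  hflip <- ("hflip" %in% aug) && runif(1) < 0.5
  vflip <- ("vflip" %in% aug) && runif(1) < 0.5
  crop <- NULL
  if ("random_crop" %in% aug) {
    for (try in seq_len(10L)) {
      f <- runif(1, sqrt(0.5), 1)  # linear scale; area fraction f^2 >= 0.5
      ch <- max(16L, as.integer(round(nr * f)))
      cw <- max(16L, as.integer(round(nc * f)))
      r0 <- sample.int(nr - ch + 1L, 1L)
      c0 <- sample.int(nc - cw + 1L, 1L)
      cand <- list(r0 = r0, c0 = c0, ch = ch, cw = cw)
      if (!has_instances || crop_keeps_instances(cand, instances, fg_mask, nr, nc, hflip, vflip)) {
        crop <- cand
        break
      }
    }
  }
  list(hflip = hflip, vflip = vflip, crop = crop)
}

crop_keeps_instances <- function(crop, instances, fg_mask, nr, nc, hflip, vflip) {
  if (!is.null(fg_mask)) {
    m <- fg_mask
    if (hflip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    if (vflip) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    return(any(m[crop$r0:(crop$r0 + crop$ch - 1L), crop$c0:(crop$c0 + crop$cw - 1L)]))
  }
  if (is.null(instances) || nrow(instances) == 0L) return(TRUE)
  xmin <- crop$c0 - 1; xmax <- crop$c0 - 1 + crop$cw
  ymin <- crop$r0 - 1; ymax <- crop$r0 - 1 + crop$ch
  for (poly in instances$polygon) {
    p <- poly
    if (hflip) p[, 1] <- nc - p[, 1]
    if (vflip) p[, 2] <- nr - p[, 2]
    ctr <- polygon_centroid(p)
    if (ctr[1] >= xmin && ctr[1] <= xmax && ctr[2] >= ymin && ctr[2] <= ymax) return(TRUE)
  }
  FALSE
}

apply_augment_image <- function(image, instances, draws) {
  nr <- nrow(image); nc <- ncol(image)
  if (draws$hflip) {
    image <- image[, rev(seq_len(nc)), drop = FALSE]
    instances$polygon <- lapply(instances$polygon, function(p) { p[, 1] <- nc - p[, 1]; p })
  }
  if (draws$vflip) {
    image <- image[rev(seq_len(nr)), , drop = FALSE]
    instances$polygon <- lapply(instances$polygon, function(p) { p[, 2] <- nr - p[, 2]; p })
  }
  if (!is.null(draws$crop)) {
    cr <- draws$crop
    image <- image[cr$r0:(cr$r0 + cr$ch - 1L), cr$c0:(cr$c0 + cr$cw - 1L), drop = FALSE]
    instances$polygon <- lapply(instances$polygon,
                                function(p) translate_polygon(p, -(cr$c0 - 1L), -(cr$r0 - 1L)))
    keep <- vapply(instances$polygon, function(p) {
      ctr <- polygon_centroid(p)
      ctr[1] >= 0 && ctr[1] <= cr$cw && ctr[2] >= 0 && ctr[2] <= cr$ch
    }, logical(1))
    instances <- instances[keep, , drop = FALSE]
  }
  list(image = image, instances = instances)
}

# feature-space version used in the training loop: the encoder's filters are
# reflection-symmetric and translation-invariant, so flipping the cached
# feature maps equals encoding the flipped image, and cropping them equals
# encoding the crop up to a border band of one filter support
apply_augment_features <- function(features, targets, draws) {
  flip_arr <- function(a, dim1, dim2) {
    if (dim1) a <- a[rev(seq_len(nrow(a))), , , drop = FALSE]
    if (dim2) a <- a[, rev(seq_len(ncol(a))), , drop = FALSE]
    a
  }
  flip_mat <- function(m, dim1, dim2) {
    if (dim1) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    if (dim2) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    m
  }
  features <- flip_arr(features, draws$vflip, draws$hflip)
  targets <- lapply(targets, flip_mat, dim1 = draws$vflip, dim2 = draws$hflip)
  if (!is.null(draws$crop)) {
    cr <- draws$crop
    rows <- cr$r0:(cr$r0 + cr$ch - 1L)
    cols <- cr$c0:(cr$c0 + cr$cw - 1L)
    features <- features[rows, cols, , drop = FALSE]
    targets <- lapply(targets, function(m) m[rows, cols, drop = FALSE])
  }
  list(features = features, targets = targets)
}

# Training ---------------------------------------------------------------------

#' Train a segmentation model
#'
#' Runs `epochs` passes over the dataset at batch size one (one SGD step
#' per image), minimizing a class-balanced binary cross-entropy between the
#' per-pixel class probabilities and the rasterized ground truth. Appends a
#' record of the dataset fingerprint and protocol to the model's lineage.
#' Fixed protocol seed reproduces the loss trajectory exactly.
#'
#' @param model a [init_model()] state; pass a trained model to continue
#'   training (incremental/secondary protocol).
#' @param dataset a `dataset_manifest`, a list of [annotated_image()]s, or
#'   a prepped dataset.
#' @param protocol a [training_protocol()].
#' @return list with elements `model` (the updated state) and `log`
#'   (tibble of class `training_log`: `epoch`, `mean_loss`).
#' @export
train_model <- function(model, dataset, protocol = training_protocol("primary")) {
  stopifnot(inherits(model, "crystal_model"), inherits(protocol, "training_protocol"))
  prepped <- prep_dataset(dataset, model)
  n <- length(prepped)
  W <- model$weights
  V <- matrix(0, nrow(W), ncol(W))
  lr <- protocol$learning_rate
  mom <- protocol$momentum
  losses <- numeric(protocol$epochs)
  with_seed(child_seed(protocol$seed, 777L), {
    for (epoch in seq_len(protocol$epochs)) {
      order <- sample.int(n)
      step_losses <- numeric(n)
      for (si in seq_along(order)) {
        item <- prepped[[order[si]]]
        draws <- augment_draws(protocol, dim(item$features)[1], dim(item$features)[2],
                               has_instances = item$has_instances,
                               fg_mask = Reduce(`|`, item$targets))
        aug <- apply_augment_features(item$features, item$targets, draws)
        step <- sgd_step(W, V, aug$features, aug$targets, lr, mom)
        if (!is.finite(step$loss)) {
          abort(sprintf("non-finite loss at epoch %d, step %d (learning rate %g); training aborted",
                        epoch, si, lr))
        }
        W <- step$W; V <- step$V
        step_losses[si] <- step$loss
      }
      losses[epoch] <- mean(step_losses)
    }
  })
  model$weights <- W
  model$lineage <- bind_rows(model$lineage, tibble(
    fingerprint = attr(prepped, "fingerprint"), role = protocol$role,
    epochs = protocol$epochs, learning_rate = lr, n_images = n
  ))
  log <- tibble(epoch = seq_len(protocol$epochs), mean_loss = losses)
  class(log) <- c("training_log", class(log))
  list(model = model, log = log)
}

# One SGD-with-momentum step on the class-balanced BCE of a single image.
sgd_step <- function(W, V, features, targets, lr, mom) {
  d <- dim(features)
  npix <- d[1] * d[2]
  X <- cbind(1, matrix(features, npix, d[3]))
  Y <- vapply(targets, function(m) as.numeric(m), numeric(npix))
  if (is.null(dim(Y))) Y <- matrix(Y, npix, 1)
  P <- plogis(X %*% W)
  # class-balanced weights: foreground pixels are rare, so each side of the
  # label contributes half of the loss (weight capped for near-empty images)
  WT <- matrix(1, npix, ncol(Y))
  for (k in seq_len(ncol(Y))) {
    pi_k <- mean(Y[, k])
    wpos <- 0.5 / max(pi_k, 0.01)
    wneg <- 0.5 / max(1 - pi_k, 0.01)
    WT[, k] <- ifelse(Y[, k] > 0, wpos, wneg)
  }
  eps <- 1e-12
  loss <- mean(WT * -(Y * log(P + eps) + (1 - Y) * log(1 - P + eps)))
  G <- crossprod(X, WT * (P - Y)) / npix
  V <- mom * V - lr * G
  W <- W + V
  list(W = W, V = V, loss = loss)
}

# Prediction -------------------------------------------------------------------

#' Predict crystal instances in an image
#'
#' Computes the per-pixel class probability maps, thresholds them at the
#' model's probability threshold (0.5), extracts 8-connected components,
#' discards components smaller than the minimum size (5 px), scores each
#' component by its mean interior probability, and keeps detections with
#' score at or above `score_threshold`. Deterministic for a fixed model
#' state.
#'
#' @param object a trained `crystal_model`.
#' @param image numeric matrix, `annotated_image`, or image file path.
#' @param score_threshold minimum objectness score (default 0.7).
#' @param ... unused.
#' @return tibble of class `crystal_predictions`, sorted by descending
#'   score, with columns `label`, `score`, `mask` (list of logical masks),
#'   and the tight bounding box `xmin`, `ymin`, `xmax`, `ymax` (0-based,
#'   inclusive).
#' @export
predict.crystal_model <- function(object, image, score_threshold = 0.7, ...) {
  if (nrow(object$lineage) == 0L) {
    abort("model has not been trained; call train_model() first")
  }
  if (is.character(image)) image <- read_image_file(image)
  if (inherits(image, "annotated_image")) image <- image$image
  backend <- get_backend(object$backend_id)
  feats <- backend$encode(image, gain = object$feature_gain)
  d <- dim(feats)
  X <- cbind(1, matrix(feats, d[1] * d[2], d[3]))
  P <- plogis(X %*% object$weights)
  out <- list()
  for (k in seq_along(object$class_set)) {
    pmap_k <- matrix(P[, k], d[1], d[2])
    fg <- pmap_k >= object$prob_threshold
    if (!any(fg)) next
    lab <- label_components8(fg)
    for (id in seq_len(max(lab))) {
      comp <- lab == id
      sz <- sum(comp)
      if (sz < object$min_component_px) next
      score <- mean(pmap_k[comp])
      bb <- mask_bbox(comp)
      out[[length(out) + 1L]] <- tibble(
        label = object$class_set[k], score = score, mask = list(comp),
        xmin = bb["xmin"], ymin = bb["ymin"], xmax = bb["xmax"], ymax = bb["ymax"]
      )
    }
  }
  preds <- if (length(out) > 0L) bind_rows(out) else tibble(
    label = character(), score = numeric(), mask = list(),
    xmin = integer(), ymin = integer(), xmax = integer(), ymax = integer()
  )
  preds <- preds[preds$score >= score_threshold, , drop = FALSE]
  preds <- preds[order(-preds$score), , drop = FALSE]
  class(preds) <- c("crystal_predictions", class(preds))
  preds
}

# 8-connected component labelling: 4-connected pass (EBImage::bwlabel),
# then union of labels that touch diagonally.
label_components8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  maxlab <- max(lab)
  if (maxlab <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]     # down-right diagonal
  c_ <- lab[-1, -nc]; d_ <- lab[-nr, -1]   # up-right diagonal
  pairs <- rbind(
    cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b]),
    cbind(c_[c_ > 0 & d_ > 0 & c_ != d_], d_[c_ > 0 & d_ > 0 & c_ != d_])
  )
  if (nrow(pairs) > 0L) {
    parent <- seq_len(maxlab)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    roots <- vapply(seq_len(maxlab), find, numeric(1))
    remap <- match(roots, sort(unique(roots)))
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  lab
}

# Checkpoints ------------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Single-file JSON archive holding the decoder weights (full-precision
#' decimal strings, so save/load/predict is bit-identical), the class set,
#' the training lineage and the backend configuration. Versioned schema.
#'
#' @param model a `crystal_model`.
#' @param path checkpoint file path (`.json`).
#' @return `path` (save) or the restored `crystal_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "crystal_model"))
  doc <- list(
    schema = jsonlite::unbox("cellcryst-checkpoint-1"),
    backend_id = jsonlite::unbox(model$backend_id),
    class_set = model$class_set,
    weights = sprintf("%.17g", as.numeric(model$weights)),
    weights_dim = dim(model$weights),
    feature_gain = jsonlite::unbox(model$feature_gain),
    prob_threshold = jsonlite::unbox(model$prob_threshold),
    min_component_px = jsonlite::unbox(model$min_component_px),
    seed = jsonlite::unbox(model$seed),
    lineage = model$lineage
  )
  writeLines(jsonlite::toJSON(doc, digits = NA, pretty = TRUE), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- jsonlite::fromJSON(path)
  if (!identical(doc$schema, "cellcryst-checkpoint-1")) {
    abort(sprintf("unrecognized checkpoint schema in %s", path))
  }
  W <- matrix(as.numeric(doc$weights), doc$weights_dim[1], doc$weights_dim[2])
  colnames(W) <- doc$class_set
  lineage <- as_tibble(doc$lineage)
  if (nrow(lineage) > 0L) {
    lineage$epochs <- as.integer(lineage$epochs)
    lineage$n_images <- as.integer(lineage$n_images)
  } else {
    lineage <- tibble(fingerprint = character(), role = character(),
                      epochs = integer(), learning_rate = numeric(),
                      n_images = integer())
  }
  structure(
    list(backend_id = doc$backend_id, class_set = doc$class_set, weights = W,
         feature_gain = doc$feature_gain, lineage = lineage,
         seed = as.integer(doc$seed), prob_threshold = doc$prob_threshold,
         min_component_px = as.integer(doc$min_component_px)),
    class = "crystal_model"
  )
}
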