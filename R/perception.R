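#' Generate synthetic stimulus prototypes
#'
#' Stands in for a pretrained ConvNet feature extractor: each stimulus
#' class is a fixed non-negative, unit-norm prototype feature vector, and
#' observations are the prototype plus clipped Gaussian noise. Prototypes
#' are built on disjoint coordinate blocks, so distinct classes are exactly
#' orthogonal (pairwise Euclidean distance `sqrt(2)`), comfortably clear of
#' the required `4 * sigma_noise` separation.
#'
#' @param K Number of classes (>= 1).
#' @param ell Feature dimension (>= 2 and >= K, so each class gets at least
#'   one private coordinate).
#' @param sigma_noise Observation noise s.d. (>= 0); must satisfy
#'   `4 * sigma_noise < sqrt(2)`.
#' @param seed Integer seed; the prototype set is a pure function of
#'   `(K, ell, sigma_noise, seed)`.
#' @return List of `K` objects of class `stimulus_prototype`, each with
#'   fields `index`, `name`, `mu` (length-`ell` prototype) and
#'   `sigma_noise`.
#' @export
make_prototypes <- function(K, ell = 64L, sigma_noise = 0.05, seed = 1L) {
  stopifnot(is.numeric(K), K >= 1, is.numeric(ell), ell >= 2,
            is.numeric(sigma_noise), sigma_noise >= 0)
  K <- as.integer(K); ell <- as.integer(ell)
  if (ell < K) {
    stop("infeasible: need at least one feature per class (ell >= K)",
         call. = FALSE)
  }
  if (4 * sigma_noise >= sqrt(2)) {
    stop("infeasible: 4 * sigma_noise must be below the prototype distance sqrt(2)",
         call. = FALSE)
  }
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  blocks <- split(seq_len(ell), rep(seq_len(K), length.out = ell))
  lapply(seq_len(K), function(i) {
    mu <- numeric(ell)
    mu[blocks[[i]]] <- abs(stats::rnorm(length(blocks[[i]]))) + 0.1
    mu <- mu / sqrt(sum(mu^2))
    structure(
      list(index = i, name = paste0("stimulus_", i), mu = mu,
           sigma_noise = sigma_noise),
      class = "stimulus_prototype"
    )
  })
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Draw one observation frame
#'
#' Returns the prototype plus additive Gaussian noise, clipped at 0 to
#' respect firing-rate non-negativity. With `proto = NULL` a background
#' frame is produced: pure clipped noise of magnitude `sigma_noise`
#' (exactly zero when `sigma_noise = 0`).
#'
#' @param proto A `stimulus_prototype`, or `NULL` for background.
#' @param ell Feature dimension, required only when `proto` is `NULL`.
#' @param sigma_noise Noise s.d. used for background frames; ignored when a
#'   prototype is given (its own `sigma_noise` applies).
#' @return Non-negative feature vector. Uses the session RNG; seed the
#'   session for reproducible streams.
#' @export
observe <- function(proto = NULL, ell = NULL, sigma_noise = 0) {
  if (is.null(proto)) {
    stopifnot(!is.null(ell))
    if (sigma_noise == 0) return(numeric(ell))
    return(pmax(0, stats::rnorm(ell, 0, sigma_noise)))
  }
  stopifnot(inherits(proto, "stimulus_prototype"))
  if (proto$sigma_noise == 0) return(proto$mu)
  pmax(0, proto$mu + stats::rnorm(length(proto$mu), 0, proto$sigma_noise))
}

#' Construct a Hebbian classification layer
#'
#' A single fully connected layer `v = H u` mapping feature vectors to
#' class activities, trained online by name supervision with either the
#' Oja rule (Model A) or the BCM rule (Model B). `H` starts at zero.
#'
#' @param K Number of classes.
#' @param ell Feature dimension.
#' @param rule `"oja"` or `"bcm"`.
#' @param theta_H Heaviside readout threshold for the Oja layer. `NA` until
#'   calibrated, see [calibrate_theta_H()].
#' @param bcm Optional [bcm_params()] used by the BCM layer.
#' @param oja Optional [oja_params()] used by the Oja layer.
#' @return An object of class `hebbian_layer` with fields `H` (K x ell),
#'   `rule`, `theta` (length-K BCM thresholds), `theta_H`, `oja`, `bcm`.
#' @export
hebbian_layer <- function(K, ell = 64L, rule = c("oja", "bcm"),
                          theta_H = NA_real_, bcm = bcm_params(),
                          oja = oja_params()) {
  rule <- match.arg(rule)
  K <- as.integer(K); ell <- as.integer(ell)
  structure(
    list(H = matrix(0, K, ell), rule = rule,
         theta = rep(bcm$theta0, K), theta_H = theta_H,
         oja = oja, bcm = bcm),
    class = "hebbian_layer"
  )
}

#' @export
print.hebbian_layer <- function(x, ...) {
  cat(sprintf("<hebbian_layer> rule = %s, K = %d, ell = %d\n",
              x$rule, nrow(x$H), ncol(x$H)))
  invisible(x)
}

#' Binary stimulus recognition
#'
#' Computes the raw class responses `H u` and thresholds them to a binary
#' presence/absence vector, which is what the Ring receives as drive. The
#' Oja layer uses a single fixed Heaviside threshold `theta_H`. The BCM
#' layer thresholds each class at `0.5 * sqrt(theta_i)`: the sliding
#' threshold tracks the square of the trained response, so its square root
#' is the scale of the response to the class prototype, and half of it
#' sits inside the margin between presence and absence. Classes whose
#' threshold is still at zero (never trained) are never recognized.
#'
#' @param layer A [hebbian_layer()].
#' @param u Feature vector of length `ell`.
#' @param l Unused by the binary readout; retained so the signature matches
#'   the other drive producers.
#' @return Binary (0/1) vector of length `K`.
#' @export
recognize <- function(layer, u, l = 0.1) {
  stopifnot(inherits(layer, "hebbian_layer"))
  if (length(u) != ncol(layer$H)) {
    stop("`u` must have length ell", call. = FALSE)
  }
  raw <- as.numeric(layer$H %*% u)
  if (layer$rule == "oja") {
    if (is.na(layer$theta_H)) {
      stop("Oja readout threshold `theta_H` has not been calibrated",
           call. = FALSE)
    }
    # direct comparison rather than heaviside(): the sentinel thresholds
    # (Inf for an uncalibrated or untrained class) are legitimate here
    as.numeric(raw >= layer$theta_H)
  } else {
    thr <- ifelse(layer$theta > 0, 0.5 * sqrt(layer$theta), Inf)
    as.numeric(raw >= thr)
  }
}

#' Supervised naming step
#'
#' Implements the naming channel: when a stimulus is shown together with
#' its name, the labeled class unit is clamped to `v = 1` and the layer's
#' plasticity rule is applied to its row of `H` (for BCM, including that
#' row's sliding threshold) with the frame as presynaptic input.
#' Plasticity is gated by the supervision signal: rows of unnamed classes
#' are left untouched. Letting them learn from their own noise-driven
#' responses would slide their BCM thresholds towards the noise floor
#' during other classes' naming steps, collapsing the recognition margin.
#'
#' @param layer A [hebbian_layer()].
#' @param u Feature vector.
#' @param label_index Index of the named class (must be in `1..K`).
#' @param dt Step size for the plasticity update.
#' @return The updated `hebbian_layer`.
#' @export
learn_label <- function(layer, u, label_index, dt = 1) {
  stopifnot(inherits(layer, "hebbian_layer"))
  K <- nrow(layer$H)
  if (!(label_index >= 1 && label_index <= K)) {
    stop("`label_index` is not a registered class", call. = FALSE)
  }
  i <- label_index
  v <- 1
  if (layer$rule == "oja") {
    layer$H[i, ] <- oja_update(layer$H[i, ], v, u, layer$oja, dt)
  } else {
    upd <- bcm_update(layer$H[i, ], layer$theta[i], v, u, layer$bcm, dt)
    layer$H[i, ] <- upd$w
    layer$theta[i] <- upd$theta
  }
  layer
}

#' Calibrate the Oja readout threshold
#'
#' Sets `theta_H` to half the smallest trained response across the given
#' prototypes: the fixed-threshold Heaviside readout is brittle, so the
#' synthetic front end calibrates it once after the naming stage.
#'
#' @param layer A trained Oja [hebbian_layer()].
#' @param protos List of `stimulus_prototype` objects (one per class, in
#'   class order).
#' @return The layer with `theta_H` set.
#' @export
calibrate_theta_H <- function(layer, protos) {
  stopifnot(inherits(layer, "hebbian_layer"), layer$rule == "oja")
  responses <- vapply(
    seq_along(protos),
    function(i) sum(layer$H[i, ] * protos[[i]]$mu),
    numeric(1)
  )
  # an untrained row has zero response; a zero threshold would make the
  # Heaviside readout fire on silence, so calibration then disables readout
  layer$theta_H <- if (min(responses) > 0) 0.5 * min(responses) else Inf
  layer
}

#' Construct a name vocabulary
#'
#' Registry mapping stimulus names to class indices, filled first-free-slot
#' as new names arrive through the supervision channel.
#'
#' @param capacity Maximum number of names (`K`).
#' @return An object of class `vocabulary`.
#' @export
vocabulary <- function(capacity) {
  stopifnot(is.numeric(capacity), capacity >= 1)
  structure(list(names = character(0), capacity = as.integer(capacity)),
            class = "vocabulary")
}

#' Register (or look up) a stimulus name
#'
#' Returns the index of a known name, or assigns the first free slot to a
#' new one. Registration is idempotent.
#'
#' @param vocab A [vocabulary()].
#' @param name Character scalar.
#' @return List with elements `vocab` (possibly updated) and `index`.
#' @export
register_pattern <- function(vocab, name) {
  stopifnot(inherits(vocab, "vocabulary"), is.character(name),
            length(name) == 1L)
  hit <- match(name, vocab$names)
  if (!is.na(hit)) return(list(vocab = vocab, index = hit))
  if (length(vocab$names) >= vocab$capacity) {
    stop("vocabulary capacity exhausted", call. = FALSE)
  }
  vocab$names <- c(vocab$names, name)
  list(vocab = vocab, index = length(vocab$names))
}

#' Serialize prototypes and vocabulary to JSON
#'
#' @param protos List of `stimulus_prototype` objects.
#' @param vocab Optional [vocabulary()].
#' @param path Optional file path; when omitted the JSON string is
#'   returned.
#' @return JSON string (invisibly, when written to `path`).
#' @export
prototypes_to_json <- function(protos, vocab = NULL, path = NULL) {
  payload <- list(
    prototypes = lapply(protos, function(p) {
      list(index = p$index, name = p$name, mu = p$mu,
           sigma_noise = p$sigma_noise)
    }),
    vocabulary = if (is.null(vocab)) NULL else
      list(names = vocab$names, capacity = vocab$capacity)
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Restore prototypes and vocabulary from JSON
#'
#' @param json JSON string or path to a JSON file produced by
#'   [prototypes_to_json()].
#' @return List with elements `prototypes` and `vocabulary`.
#' @export
prototypes_from_json <- function(json) {
  payload <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  protos <- lapply(payload$prototypes, function(p) {
    structure(
      list(index = p$index, name = p$name, mu = as.numeric(p$mu),
           sigma_noise = p$sigma_noise),
      class = "stimulus_prototype"
    )
  })
  vocab <- NULL
  if (!is.null(payload$vocabulary)) {
    vocab <- structure(
      list(names = as.character(payload$vocabulary$names),
           capacity = as.integer(payload$vocabulary$capacity)),
      class = "vocabulary"
    )
  }
  list(prototypes = protos, vocabulary = vocab)
}
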